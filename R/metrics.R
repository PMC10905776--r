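#' Reconstruction quality metrics
#'
#' Benchmarks a reconstructed spectral block against the original with the
#' standard trio: mean squared error per wavelength (MSE), mean absolute
#' percentage error (MAPE, %), and Pearson's correlation with its two-sided
#' p-value, computed over all paired sample-wavelength values. Spectra are
#' compared exactly as given — standardize both identically first
#' ([standardize()]) when intensity differences should not count.
#'
#' MAPE excludes wavelengths where the original magnitude falls below
#' `epsilon`: standardized spectra cross zero, and unguarded percentage errors
#' diverge there. The number of excluded values is reported.
#'
#' @param original,reconstructed spectra tibbles on the same grid with the
#'   same samples in the same order.
#' @param epsilon magnitude guard for the MAPE denominator.
#' @param by_sample if `TRUE`, return one row per sample (metrics over that
#'   sample's wavelengths) instead of one pooled row; median per-sample MAPE
#'   is the robust summary when standardized spectra cross zero.
#' @return a one-row tibble: `mse`, `mape`, `pearson_r`, `p_value`,
#'   `n_samples`, `n_wavelengths`, `n_excluded`; or, with `by_sample = TRUE`,
#'   one row per sample with a `sample_id` column.
#' @examples
#' o <- spectra_tbl(matrix(c(1, 2, 4), 1, 3), c(400, 500, 600))
#' r <- spectra_tbl(matrix(c(1.1, 1.8, 4.4), 1, 3), c(400, 500, 600))
#' reconstruction_metrics(o, r)
#' @export
reconstruction_metrics <- function(original, reconstructed, epsilon = 1e-6,
                                   by_sample = FALSE) {
  validate_spectra(original)
  validate_spectra(reconstructed)
  wl_o <- spectra_wavelengths(original)
  wl_r <- spectra_wavelengths(reconstructed)
  if (length(wl_o) != length(wl_r) || !isTRUE(all.equal(wl_o, wl_r)) ||
      nrow(original) != nrow(reconstructed)) {
    abort_ts("Original and reconstructed blocks must share grid and samples.",
             "shape")
  }
  o <- spectra_matrix(original)
  r <- spectra_matrix(reconstructed)
  if (by_sample) {
    rows <- purrr::map(seq_len(nrow(o)), function(i) {
      one <- reconstruction_metrics(
        set_spectra_matrix(original[i, , drop = FALSE], o[i, , drop = FALSE]),
        set_spectra_matrix(reconstructed[i, , drop = FALSE], r[i, , drop = FALSE]),
        epsilon = epsilon
      )
      dplyr::bind_cols(tibble(sample_id = original$sample_id[i]), one)
    })
    return(dplyr::bind_rows(rows))
  }
  d <- o - r
  mse <- mean(d^2)
  keep <- abs(o) >= epsilon
  if (!any(keep)) {
    abort_ts("All original magnitudes fall below `epsilon`; MAPE is undefined.",
             "degenerate")
  }
  mape <- mean(100 * abs(d)[keep] / abs(o)[keep])
  ov <- as.numeric(o)
  rv <- as.numeric(r)
  if (sd(ov) == 0 || sd(rv) == 0) {
    pearson_r <- NA_real_
    p_value <- NA_real_
  } else if (max(abs(d)) == 0) {
    pearson_r <- 1
    p_value <- 0
  } else {
    ct <- suppressWarnings(cor.test(ov, rv))
    pearson_r <- unname(ct$estimate)
    p_value <- ct$p.value
  }
  tibble(
    mse = mse,
    mape = mape,
    pearson_r = pearson_r,
    p_value = p_value,
    n_samples = nrow(o),
    n_wavelengths = ncol(o),
    n_excluded = sum(!keep)
  )
}

#' Hold-out reconstruction benchmark
#'
#' Runs both directions of a fitted model on hold-out fruits and reports the
#' reconstruction metrics per target, in the shape of a benchmark table: the
#' whole-tomato spectrum reconstructed from the tissue spectra, and each
#' tissue spectrum decomposed from the whole-tomato spectrum. All comparisons
#' are made on identically standardized (per-spectrum) preprocessed spectra,
#' so intensity differences do not count. Both the pooled MAPE and the median
#' per-sample MAPE are reported; the median is the robust summary, since
#' standardized spectra cross zero and inflate pooled percentage errors.
#'
#' @param model a [fit_tomography()] model.
#' @param blocks a hold-out [block_set()] on the training grid.
#' @param epsilon MAPE magnitude guard.
#' @return a tibble with one row per target (`tomato`, `skin`, `pulp`,
#'   `seed`): `mse`, `mape`, `mape_median`, `pearson_r`, `p_value`.
#' @export
evaluate_reconstruction <- function(model, blocks, epsilon = 1e-6) {
  if (!inherits(blocks, "block_set")) blocks <- align_blocks(blocks)
  recon <- list(
    tomato = reconstruct_tomato(model, blocks[c("skin", "pulp", "seed")])
  )
  recon <- c(recon, decompose_tomato(model, blocks$tomato))
  rows <- purrr::imap(recon, function(rec, role) {
    obs <- standardize(preprocess_block(model, blocks[[role]], role))
    rec <- standardize(rec)
    pooled <- reconstruction_metrics(obs, rec, epsilon = epsilon)
    per <- reconstruction_metrics(obs, rec, epsilon = epsilon, by_sample = TRUE)
    dplyr::bind_cols(
      tibble(target = role),
      pooled[, c("mse", "mape")],
      tibble(mape_median = median(per$mape)),
      pooled[, c("pearson_r", "p_value")]
    )
  })
  dplyr::bind_rows(rows)
}

#' Latent-space stability of query samples
#'
#' Measures knowledge-base representativeness: for each query fruit, the
#' Euclidean distance to its nearest training sample in the superset space `T`
#' (queries projected from tissue spectra) and in the whole-fruit feature
#' space `U` (queries projected from whole-fruit spectra). Hold-out or
#' cross-validation samples far from every training sample sit outside the
#' model's knowledge base and their reconstructions should be trusted less.
#'
#' @param model a [fit_tomography()] model.
#' @param tissues optional named list (`skin`, `pulp`, `seed`) of query tissue
#'   spectra for distances in `T`.
#' @param tomato optional query whole-fruit spectra for distances in `U`.
#' @return a list: `distances` (tibble `sample_id`, `space`, `distance`) and
#'   `summary` (tibble `space`, `median`, `p90`).
#' @export
latent_stability <- function(model, tissues = NULL, tomato = NULL) {
  if (is.null(tissues) && is.null(tomato)) {
    abort_ts("Supply `tissues` (for T) and/or `tomato` (for U).", "parameter")
  }
  rows <- list()
  if (!is.null(tissues)) {
    pre <- purrr::imap(tissues[c("skin", "pulp", "seed")],
                       ~ preprocess_block(model, .x, .y))
    tq <- superset_project(model$superset, pre)
    rows$T <- tibble(
      sample_id = tissues$skin$sample_id,
      space = "T",
      distance = nearest_distance(model$superset$T, tq)
    )
  }
  if (!is.null(tomato)) {
    pre <- preprocess_block(model, tomato, "tomato")
    uq <- predict(model$association$tomato_model, pre)
    rows$U <- tibble(
      sample_id = tomato$sample_id,
      space = "U",
      distance = nearest_distance(model$association$U_train, uq)
    )
  }
  distances <- dplyr::bind_rows(rows)
  summary <- distances |>
    dplyr::group_by(.data$space) |>
    dplyr::summarise(
      median = median(.data$distance),
      p90 = as.numeric(quantile(.data$distance, 0.9)),
      .groups = "drop"
    )
  list(distances = distances, summary = summary)
}

nearest_distance <- function(train, query) {
  train <- as.matrix(train)
  query <- as.matrix(query)
  if (ncol(train) != ncol(query)) {
    abort_ts("Query scores do not match the model space dimensionality.", "shape")
  }
  apply(query, 1, function(q) sqrt(min(colSums((t(train) - q)^2))))
}
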