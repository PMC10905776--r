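#' Band-ratio pigment indices
#'
#' Dry-lab pigment proxies from the visible range: the chlorophyll index is
#' the ratio of the mean intensity over the green band (520-570 nm) to the
#' mean over the red band (571-700 nm); the lycopene index is the reciprocal
#' ratio. Both bands are closed intervals and band means are unweighted
#' averages of the grid points inside them. For strictly positive spectra both
#' indices are strictly positive and their product is exactly 1.
#'
#' Indices should be computed on scatter-corrected, non-standardized spectra:
#' standardized spectra cross zero and break ratio positivity. For log-MSC
#' output use [msc_linear()] first to return to the positive linear scale.
#'
#' @param ds a spectra tibble with positive intensities over both bands.
#' @param green_band,red_band band limits in nm (closed intervals).
#' @return a tibble: `sample_id`, `tissue`, `stage`, `chlorophyll_index`,
#'   `lycopene_index`.
#' @examples
#' ds <- spectra_tbl(matrix(1, 2, 301), 400:700)
#' pigment_indices(ds)
#' @export
pigment_indices <- function(ds, green_band = c(520, 570), red_band = c(571, 700)) {
  validate_spectra(ds)
  wl <- spectra_wavelengths(ds)
  x <- spectra_matrix(ds)
  in_green <- wl >= green_band[1] & wl <= green_band[2]
  in_red <- wl >= red_band[1] & wl <= red_band[2]
  if (!any(in_green)) {
    abort_ts(sprintf("The grid has no wavelength in the green band [%s, %s] nm.",
                     green_band[1], green_band[2]), "coverage")
  }
  if (!any(in_red)) {
    abort_ts(sprintf("The grid has no wavelength in the red band [%s, %s] nm.",
                     red_band[1], red_band[2]), "coverage")
  }
  green <- unname(rowMeans(x[, in_green, drop = FALSE]))
  red <- unname(rowMeans(x[, in_red, drop = FALSE]))
  if (any(green <= 0) || any(red <= 0)) {
    abort_ts("Non-positive band mean; pigment ratios need positive intensities.",
             "domain")
  }
  tibble(
    sample_id = ds$sample_id,
    tissue = if ("tissue" %in% names(ds)) ds$tissue else NA_character_,
    stage = if ("stage" %in% names(ds)) ds$stage else NA_character_,
    chlorophyll_index = green / red,
    lycopene_index = red / green
  )
}

#' Back-transform log-MSC spectra to the positive linear scale
#'
#' Exponentiates scatter-corrected log-domain spectra, giving positive
#' scatter-free intensities suitable for band-ratio indices.
#'
#' @param ds a log-MSC corrected spectra tibble.
#' @return a spectra tibble with `exp()` applied to the intensities.
#' @export
msc_linear <- function(ds) {
  set_spectra_matrix(ds, exp(spectra_matrix(ds)))
}

#' Quality-parameter prediction benchmark
#'
#' Reproduces the quality-prediction protocol on a paired block set: for each
#' property and each spectral block, samples are split (stratified by
#' maturation stage) into a training and a validation part, a PLS model with
#' leave-one-out LV selection is fitted on the training part, and validation
#' metrics are reported — Pearson `r`, out-of-sample `R^2 = 1 - SS_res/SS_tot`,
#' MSE (property units squared), MAPE (%) and the chosen LV count.
#'
#' Two datasets are benchmarked: `"original"` uses the preprocessed measured
#' spectra as predictors; `"reconstructed"` uses the model's whole-fruit
#' reconstruction (for the tomato block) and tissue decompositions (for skin,
#' pulp, seed). Targets: soluble solids content and puncture force are
#' measured on the whole fruit only, so tissue rows for them are excluded
#' (`NA` metrics, the dash of a report table); chlorophyll and lycopene are
#' dry-lab band-ratio indices ([pigment_indices()]) computed per block from
#' the original spectra and predicted from the reconstructed dataset.
#'
#' @param blocks a [block_set()].
#' @param properties tibble with `sample_id`, `ssc_percent`,
#'   `puncture_force_N` (property values may be `NA` for at most 10% of
#'   samples).
#' @param model a [fit_tomography()] model fitted on (a superset of) these
#'   samples' conditions; used for preprocessing and reconstruction.
#' @param split_fraction training fraction of the stratified split.
#' @param seed integer seed for the split.
#' @param max_lv largest candidate LV count per PLS fit.
#' @return a tibble: `dataset`, `property`, `block`, `r`, `r_squared`, `mse`,
#'   `mape`, `n_lv` (`NA` rows mark excluded property-block combinations).
#' @export
quality_benchmark <- function(blocks, properties, model, split_fraction = 0.7,
                              seed = 1, max_lv = 10) {
  if (!inherits(blocks, "block_set")) blocks <- align_blocks(blocks)
  check_number(split_fraction, "split_fraction", lower = 0.1, upper = 0.95)
  ids <- blocks$tomato$sample_id
  properties <- as_tibble(properties)
  if (!all(c("sample_id", "ssc_percent", "puncture_force_N") %in%
           names(properties))) {
    abort_ts("`properties` needs sample_id, ssc_percent and puncture_force_N.",
             "validation")
  }
  prop <- properties[match(ids, properties$sample_id), ]
  for (col in c("ssc_percent", "puncture_force_N")) {
    if (mean(is.na(prop[[col]])) > 0.10) {
      abort_ts(sprintf("Property '%s' is missing for more than 10%% of samples.",
                       col), "validation")
    }
  }
  roles <- tissue_levels
  original <- purrr::imap(unclass(blocks), ~ preprocess_block(model, .x, .y))
  reconstructed <- c(
    list(tomato = reconstruct_tomato(model, blocks[c("skin", "pulp", "seed")])),
    decompose_tomato(model, blocks$tomato)
  )[roles]
  ## pigment targets from the original spectra of each block, linear scale
  to_linear <- function(ds) if (model$preprocess == "log_msc") msc_linear(ds) else ds
  pigments <- purrr::map(original, ~ pigment_indices(to_linear(.x)))
  targets <- list(
    ssc = prop$ssc_percent,
    puncture_force = prop$puncture_force_N
  )
  stage <- blocks$tomato$stage
  train_idx <- stratified_split(length(ids), stage, split_fraction, seed)
  grid <- tidyr::expand_grid(
    dataset = c("original", "reconstructed"),
    property = c("ssc", "puncture_force", "chlorophyll", "lycopene"),
    block = roles
  )
  results <- purrr::pmap(grid, function(dataset, property, block) {
    pigment <- property %in% c("chlorophyll", "lycopene")
    included <- if (pigment) {
      dataset == "reconstructed"
    } else {
      block == "tomato"
    }
    if (!included) return(rep(NA_real_, 5))
    y <- if (pigment) pigments[[block]][[paste0(property, "_index")]]
         else targets[[property]]
    x <- spectra_matrix(if (dataset == "original") original[[block]]
                        else reconstructed[[block]])
    ok <- !is.na(y)
    tr <- intersect(train_idx, which(ok))
    va <- setdiff(which(ok), tr)
    lv_cap <- min(max_lv, length(tr) - 1L, ncol(x))
    fit <- fit_pls(x[tr, , drop = FALSE], y[tr], max_lv = lv_cap)
    pred <- predict(fit, x[va, , drop = FALSE])
    obs <- y[va]
    ss_res <- sum((obs - pred)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    keep <- abs(obs) >= 1e-6
    c(
      r = if (sd(pred) == 0) NA_real_ else cor(obs, pred),
      r_squared = 1 - ss_res / ss_tot,
      mse = mean((obs - pred)^2),
      mape = mean(100 * abs(obs - pred)[keep] / abs(obs)[keep]),
      n_lv = fit$n_lv
    )
  })
  metrics <- do.call(rbind, results)
  colnames(metrics) <- c("r", "r_squared", "mse", "mape", "n_lv")
  dplyr::bind_cols(grid, as_tibble(metrics))
}

## stage-stratified train/validation split; returns training row indices
stratified_split <- function(n, stage, fraction, seed) {
  if (is.null(stage)) stage <- rep("all", n)
  stage[is.na(stage)] <- "unknown"
  set.seed(derive_seed(seed, 202))
  train <- integer(0)
  for (g in unique(stage)) {
    idx <- which(stage == g)
    n_tr <- max(1L, round(length(idx) * fraction))
    n_tr <- min(n_tr, length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  if (length(train) == n) train <- train[-length(train)]
  train
}
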