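#' Fuse tissue latent spaces into a superset latent space
#'
#' Fits a PCA model per tissue block (skin `X1`, pulp `X2`, seed `X3`), each
#' with `n_sub` components: `X_j = t_j p_j' + e_j`. Then, dimension by
#' dimension, the i-th score columns of the three tissues are stacked into an
#' n x 3 block `[t1_i | t2_i | t3_i]`, column-centred and scaled to unit
#' variance (so no tissue dominates by score magnitude alone), and decomposed
#' by SVD: `t_f = T_i P_i'`. The smallest number of fused directions `d_i`
#' whose cumulative variance reaches `fusion_variance_threshold` is retained —
#' one direction when the three tissues carry the same information in that
#' dimension, up to three when they disagree. The superset scores `T` are the
#' column-concatenation `[T_1 ... T_n]` over all sub-dimensions.
#'
#' @param blocks a [block_set()] or a named list with at least `skin`, `pulp`
#'   and `seed` spectra tibbles, paired sample-by-sample.
#' @param n_sub retained components per tissue (equal across tissues); the
#'   default 8 matches the usual working size for Vis-NIR fruit spectra.
#' @param fusion_variance_threshold cumulative-variance cutoff selecting
#'   `d_i`; 1.0 makes the fusion lossless.
#' @param max_fused upper bound on `d_i` (at most 3).
#' @return an object of class `superset_model`: `tissue_models` (one
#'   [fit_pca()] model per tissue), `fusion` (per sub-dimension: loadings `P`
#'   with orthonormal columns, centring/scaling of the stacked scores, `d`,
#'   variance profile), `T` (samples x sum(d_i) fused scores), `n_sub`,
#'   `sample_id`, `fusion_variance_threshold`.
#' @export
build_superset <- function(blocks, n_sub = 8, fusion_variance_threshold = 0.95,
                           max_fused = 3) {
  tissues <- c("skin", "pulp", "seed")
  if (!all(tissues %in% names(blocks))) {
    abort_ts("`blocks` needs skin, pulp and seed elements.", "pairing")
  }
  ids <- purrr::map(blocks[tissues], "sample_id")
  if (!all(purrr::map_lgl(ids[-1], identical, ids[[1]]))) {
    abort_ts("Tissue blocks are not paired (sample ids differ).", "pairing")
  }
  check_number(fusion_variance_threshold, "fusion_variance_threshold",
               lower = 1e-6, upper = 1)
  max_fused <- min(as.integer(max_fused), 3L)
  models <- purrr::map(blocks[tissues], fit_pca, n_components = n_sub)
  n <- nrow(blocks$skin)
  fusion <- vector("list", n_sub)
  t_blocks <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- vapply(models, function(m) m$scores[, i], numeric(n))
    ctr <- colMeans(s)
    scl <- apply(s, 2, sd)
    scl[!is.finite(scl) | scl < 1e-10] <- 1
    z <- sweep(sweep(s, 2, ctr), 2, scl, "/")
    sv <- svd(z)
    vars <- sv$d^2
    if (sum(vars) < 1e-20) {
      d_i <- 1L
      p <- matrix(c(1, 0, 0), 3, 1)
    } else {
      cum <- cumsum(vars) / sum(vars)
      d_i <- min(which(cum >= fusion_variance_threshold - 1e-12), max_fused)
      p <- sv$v[, seq_len(d_i), drop = FALSE]
      for (j in seq_len(d_i)) {
        peak <- which.max(abs(p[, j]))
        if (p[peak, j] < 0) p[, j] <- -p[, j]
      }
    }
    t_blocks[[i]] <- z %*% p
    colnames(t_blocks[[i]]) <- paste0("dim", i, ".", seq_len(ncol(p)))
    fusion[[i]] <- list(P = p, center = ctr, scale = scl, d = ncol(p),
                        variance = if (sum(vars) < 1e-20) c(1, 0, 0)
                                   else vars / sum(vars))
  }
  t_all <- do.call(cbind, t_blocks)
  rownames(t_all) <- blocks$skin$sample_id
  structure(list(
    tissue_models = models,
    fusion = fusion,
    T = t_all,
    n_sub = as.integer(n_sub),
    sample_id = blocks$skin$sample_id,
    fusion_variance_threshold = fusion_variance_threshold
  ), class = "superset_model")
}

#' @export
print.superset_model <- function(x, ...) {
  d <- purrr::map_int(x$fusion, "d")
  cat(sprintf("<superset_model> %d sub-dimensions per tissue, fused dims: %s (total %d)\n",
              x$n_sub, paste(d, collapse = " "), sum(d)))
  invisible(x)
}

#' @export
tidy.superset_model <- function(x, ...) {
  tibble(
    dimension = seq_along(x$fusion),
    d = purrr::map_int(x$fusion, "d"),
    leading_variance = purrr::map_dbl(x$fusion, ~ .x$variance[1])
  )
}

## project preprocessed tissue spectra into the fused superset space
superset_project <- function(superset, tissues) {
  roles <- c("skin", "pulp", "seed")
  scores <- purrr::map2(superset$tissue_models, tissues[roles],
                        function(m, ds) predict(m, ds))
  n <- nrow(scores[[1]])
  out <- vector("list", superset$n_sub)
  for (i in seq_len(superset$n_sub)) {
    s <- matrix(vapply(scores, function(sc) sc[, i], numeric(n)), nrow = n)
    f <- superset$fusion[[i]]
    z <- sweep(sweep(s, 2, f$center), 2, f$scale, "/")
    out[[i]] <- z %*% f$P
  }
  do.call(cbind, out)
}

## expand fused superset scores back into the three per-tissue score matrices
superset_expand <- function(superset, t_query) {
  t_query <- as.matrix(t_query)
  d <- purrr::map_int(superset$fusion, "d")
  if (ncol(t_query) != sum(d)) {
    abort_ts(sprintf("Superset scores have %d columns; the model expects %d.",
                     ncol(t_query), sum(d)), "shape")
  }
  n <- nrow(t_query)
  sub <- purrr::map(1:3, ~ matrix(0, n, superset$n_sub))
  offset <- 0L
  for (i in seq_len(superset$n_sub)) {
    f <- superset$fusion[[i]]
    ti <- t_query[, offset + seq_len(f$d), drop = FALSE]
    z <- ti %*% t(f$P)
    s <- sweep(sweep(z, 2, f$scale, "*"), 2, f$center, "+")
    for (j in 1:3) sub[[j]][, i] <- s[, j]
    offset <- offset + f$d
  }
  names(sub) <- c("skin", "pulp", "seed")
  sub
}

#' Associate the superset space T with the whole-fruit feature space U
#'
#' Fits a PCA model to the whole-tomato block, `Y = U C' `, and bridges the
#' fused tissue space `T` and the tomato feature space `U`, which are expected
#' to carry near-identical latent structure. Two association modes:
#' `"linear"` solves the least-squares maps `U = T b` and `T = U c`;
#' `"knn"` stores the paired training scores and propagates queries through
#' the `k` nearest neighbours (inverse-distance weighted).
#'
#' @param superset a [build_superset()] model.
#' @param tomato the paired whole-tomato spectra tibble (same samples, same
#'   order as the superset training samples).
#' @param mode `"knn"` (default) or `"linear"`.
#' @param n_tomato_components components of the tomato PCA; defaults to the
#'   fused dimensionality of `T` (capped by the rank bound).
#' @param k neighbour count for knn mode.
#' @return an object of class `association_map`: `mode`, `b`, `c` (linear
#'   maps, `NULL` in knn mode), `k`, `tomato_model`, `T_train`, `U_train`.
#' @export
fit_association <- function(superset, tomato, mode = c("knn", "linear"),
                            n_tomato_components = NULL, k = 5) {
  mode <- match.arg(mode)
  if (!identical(tomato$sample_id, superset$sample_id)) {
    abort_ts("The tomato block is not paired with the superset training samples.",
             "pairing")
  }
  bound <- min(nrow(tomato) - 1L, length(spectra_wavelengths(tomato)))
  if (is.null(n_tomato_components)) {
    n_tomato_components <- min(ncol(superset$T), bound)
  }
  if (n_tomato_components > bound) {
    abort_ts(sprintf("`n_tomato_components` (%d) exceeds the rank bound %d.",
                     n_tomato_components, bound), "rank")
  }
  tomato_model <- fit_pca(tomato, n_tomato_components)
  map <- associate_scores(superset$T, tomato_model$scores, mode = mode, k = k)
  map$tomato_model <- tomato_model
  map
}

#' @rdname fit_association
#' @param T_train,U_train paired score matrices (rows = samples).
#' @export
associate_scores <- function(T_train, U_train, mode = c("knn", "linear"), k = 5) {
  mode <- match.arg(mode)
  T_train <- as.matrix(T_train)
  U_train <- as.matrix(U_train)
  if (nrow(T_train) != nrow(U_train)) {
    abort_ts("T and U must have the same number of rows.", "shape")
  }
  b <- NULL
  c_map <- NULL
  if (mode == "linear") {
    b <- ls_solve(T_train, U_train)
    c_map <- ls_solve(U_train, T_train)
  } else {
    check_number(k, "k", lower = 1, upper = nrow(T_train))
  }
  structure(list(mode = mode, b = b, c = c_map, k = as.integer(k),
                 T_train = T_train, U_train = U_train,
                 tomato_model = NULL), class = "association_map")
}

## propagate scores between the two latent spaces
map_association <- function(assoc, scores, from = c("T", "U")) {
  from <- match.arg(from)
  scores <- as.matrix(scores)
  if (assoc$mode == "linear") {
    if (from == "T") scores %*% assoc$b else scores %*% assoc$c
  } else {
    if (from == "T") knn_map(assoc$T_train, assoc$U_train, scores, assoc$k)
    else knn_map(assoc$U_train, assoc$T_train, scores, assoc$k)
  }
}

#' Fit the full bi-directional tissue/whole-fruit model
#'
#' The end-to-end pipeline: optional logarithm multiplicative scatter
#' correction per block (references fitted on the training data and frozen),
#' per-tissue PCA, dimension-wise fusion into the superset `T`
#' ([build_superset()]) and association of `T` with the whole-fruit feature
#' space `U` ([fit_association()]). The returned model reconstructs a
#' whole-fruit spectrum from tissue spectra ([reconstruct_tomato()]) and
#' decomposes a whole-fruit spectrum into tissue spectra
#' ([decompose_tomato()]).
#'
#' @param blocks a [block_set()] (or list accepted by [align_blocks()]).
#' @param n_sub components per tissue sub-space.
#' @param fusion_variance_threshold see [build_superset()].
#' @param mode association mode, `"knn"` or `"linear"`.
#' @param k neighbour count for knn association.
#' @param n_tomato_components see [fit_association()].
#' @param preprocess `"log_msc"` (default) or `"none"`. With `"log_msc"`,
#'   model spaces live on the corrected log scale and the per-block references
#'   are stored for hold-out application.
#' @return an object of class `tomography_model`.
#' @export
fit_tomography <- function(blocks, n_sub = 8, fusion_variance_threshold = 0.95,
                           mode = c("knn", "linear"), k = 5,
                           n_tomato_components = NULL,
                           preprocess = c("log_msc", "none")) {
  mode <- match.arg(mode)
  preprocess <- match.arg(preprocess)
  if (!inherits(blocks, "block_set")) blocks <- align_blocks(blocks)
  msc_refs <- NULL
  work <- unclass(blocks)
  if (preprocess == "log_msc") {
    work <- purrr::map(work, log_msc)
    msc_refs <- purrr::map(work, msc_reference)
  }
  superset <- build_superset(work, n_sub = n_sub,
                             fusion_variance_threshold = fusion_variance_threshold)
  association <- fit_association(superset, work$tomato, mode = mode,
                                 n_tomato_components = n_tomato_components, k = k)
  structure(list(
    preprocess = preprocess,
    msc_refs = msc_refs,
    superset = superset,
    association = association,
    config = list(n_sub = n_sub,
                  fusion_variance_threshold = fusion_variance_threshold,
                  mode = mode, k = k,
                  n_tomato_components = association$tomato_model$n_components)
  ), class = "tomography_model")
}

#' @export
print.tomography_model <- function(x, ...) {
  cat(sprintf("<tomography_model> n_sub = %d, fused T dim = %d, U dim = %d, %s association, preprocess = %s\n",
              x$superset$n_sub, ncol(x$superset$T),
              x$association$tomato_model$n_components,
              x$association$mode, x$preprocess))
  invisible(x)
}

#' @export
glance.tomography_model <- function(x, ...) {
  tibble(
    n_samples = length(x$superset$sample_id),
    n_sub = x$superset$n_sub,
    t_dim = ncol(x$superset$T),
    u_dim = x$association$tomato_model$n_components,
    mode = x$association$mode,
    preprocess = x$preprocess
  )
}

## apply the model's frozen preprocessing to one block
preprocess_block <- function(model, ds, role) {
  if (model$preprocess == "log_msc") {
    log_msc(ds, reference = model$msc_refs[[role]])
  } else {
    ds
  }
}

#' Reconstruct whole-fruit spectra from tissue spectra
#'
#' The forward direction: tissue spectra are projected into their sub-spaces,
#' fused through the stored per-dimension loadings into superset scores `T`,
#' propagated to the whole-fruit feature space `U` (linear map `T b` or
#' inverse-distance-weighted k-nearest-neighbour lookup), and expanded to
#' spectra as `Y = U C' + mean`.
#'
#' @param model a [fit_tomography()] model.
#' @param tissues a named list with `skin`, `pulp`, `seed` spectra tibbles on
#'   the training grid and raw intensity scale (preprocessing is applied with
#'   the frozen training references).
#' @return a spectra tibble of reconstructed whole-fruit spectra, on the
#'   model's preprocessed scale.
#' @export
reconstruct_tomato <- function(model, tissues) {
  roles <- c("skin", "pulp", "seed")
  if (!all(roles %in% names(tissues))) {
    abort_ts("`tissues` needs skin, pulp and seed elements.", "pairing")
  }
  ids <- purrr::map(tissues[roles], "sample_id")
  if (!all(purrr::map_lgl(ids[-1], identical, ids[[1]]))) {
    abort_ts("Tissue queries are not paired (sample ids differ).", "pairing")
  }
  pre <- purrr::imap(tissues[roles], ~ preprocess_block(model, .x, .y))
  t_query <- superset_project(model$superset, pre)
  u_query <- map_association(model$association, t_query, from = "T")
  stage <- if ("stage" %in% names(tissues$skin)) tissues$skin$stage else NULL
  inverse_transform(model$association$tomato_model, u_query,
                    sample_id = tissues$skin$sample_id, stage = stage)
}

#' Decompose whole-fruit spectra into tissue spectra
#'
#' The backward direction: whole-fruit spectra are projected into the feature
#' space `U`, propagated to the superset space `T` (linear map `U c` or knn),
#' expanded dimension-wise through the fusion loadings into the per-tissue
#' score matrices `[t1_i | t2_i | t3_i] = T_i P_i'`, and mapped to spectra
#' through each tissue's PCA basis, `X_j = t_j p_j' + mean`.
#'
#' @param model a [fit_tomography()] model.
#' @param tomato a spectra tibble of whole-fruit spectra on the training grid
#'   and raw intensity scale.
#' @return a named list with `skin`, `pulp`, `seed` spectra tibbles on the
#'   model's preprocessed scale.
#' @export
decompose_tomato <- function(model, tomato) {
  pre <- preprocess_block(model, tomato, "tomato")
  u_query <- predict(model$association$tomato_model, pre)
  t_query <- map_association(model$association, u_query, from = "U")
  sub_scores <- superset_expand(model$superset, t_query)
  stage <- if ("stage" %in% names(tomato)) tomato$stage else NULL
  purrr::imap(sub_scores, function(sc, role) {
    inverse_transform(model$superset$tissue_models[[role]], sc,
                      sample_id = tomato$sample_id, stage = stage)
  })
}

#' Choose the sub-space size by leave-one-out cross-validation
#'
#' For every candidate number of per-tissue components `1..max_sub`, each
#' sample is left out in turn, the full model is refitted on the remainder,
#' the held-out whole-fruit spectrum is decomposed, and the per-tissue
#' reconstruction error `e = [e1, e2, e3]` (mean squared error on the
#' preprocessed scale) is recorded. The chosen size is the smallest candidate
#' whose summed CV error is within a relative tolerance of the minimum —
#' growth past the informative dimensions only propagates random structure
#' into the superset, so parsimony is preferred at ties.
#'
#' @param blocks a [block_set()] with at least 5 paired samples.
#' @param max_sub largest candidate sub-space size.
#' @param fusion_variance_threshold,mode,k,preprocess passed to
#'   [fit_tomography()]; the association defaults to `"linear"` here, the
#'   deterministic algebraic reading, so the error curves are smooth in the
#'   candidate size.
#' @return a list: `n_sub` (chosen size), `curves` (tibble with `n_sub`,
#'   `tissue`, `cv_mse`), `total` (summed CV error per candidate).
#' @export
optimize_components_cv <- function(blocks, max_sub = 6,
                                   fusion_variance_threshold = 0.95,
                                   mode = "linear", k = 5,
                                   preprocess = c("log_msc", "none")) {
  preprocess <- match.arg(preprocess)
  if (!inherits(blocks, "block_set")) blocks <- align_blocks(blocks)
  n <- nrow(blocks$tomato)
  if (n < 5L) abort_ts("Leave-one-out sizing needs at least 5 paired samples.",
                       "insufficient_data")
  bound <- min(n - 2L, length(spectra_wavelengths(blocks$tomato)))
  max_sub <- as.integer(max_sub)
  if (max_sub > bound) {
    abort_ts(sprintf("`max_sub` (%d) exceeds the leave-one-out rank bound %d.",
                     max_sub, bound), "rank")
  }
  tissues <- c("skin", "pulp", "seed")
  err <- array(NA_real_, c(max_sub, 3), dimnames = list(NULL, tissues))
  for (ns in seq_len(max_sub)) {
    fold <- matrix(NA_real_, n, 3, dimnames = list(NULL, tissues))
    for (i in seq_len(n)) {
      train <- purrr::map(unclass(blocks), ~ .x[-i, , drop = FALSE])
      m <- fit_tomography(block_set(train$tomato, train$skin, train$pulp,
                                    train$seed),
                          n_sub = ns,
                          fusion_variance_threshold = fusion_variance_threshold,
                          mode = mode, k = min(k, n - 1L),
                          preprocess = preprocess)
      decomp <- decompose_tomato(m, blocks$tomato[i, , drop = FALSE])
      for (tj in tissues) {
        obs <- preprocess_block(m, blocks[[tj]][i, , drop = FALSE], tj)
        fold[i, tj] <- mean((spectra_matrix(decomp[[tj]]) - spectra_matrix(obs))^2)
      }
    }
    err[ns, ] <- colMeans(fold)
  }
  total <- rowSums(err)
  chosen <- min(which(total <= min(total) * (1 + 1e-6) + 1e-12))
  list(
    n_sub = chosen,
    curves = tibble(
      n_sub = rep(seq_len(max_sub), 3),
      tissue = rep(tissues, each = max_sub),
      cv_mse = as.numeric(err)
    ),
    total = total
  )
}
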