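#' Principal component analysis of a spectral block
#'
#' Mean-centres the intensity matrix and decomposes it by singular value
#' decomposition, `X = U S V'`: the scores (latent structures) are `t = U S`
#' and the loadings (basis eigenvectors) `p' = V'`. Components are ordered by
#' decreasing singular value. Each loading vector is oriented so that its
#' largest-magnitude element is positive, which removes the SVD sign ambiguity
#' and makes the fit fully deterministic.
#'
#' @param ds a spectra tibble with at least 2 samples.
#' @param n_components number of components to retain; at most
#'   `min(n_samples - 1, n_wavelengths)`.
#' @return an object of class `spec_pca` with elements `mean` (per-wavelength
#'   centring vector), `loadings` (wavelengths x components), `singular_values`,
#'   `scores` (samples x components, `t = U S`), `explained_variance`,
#'   `total_variance`, `wavelengths`, `sample_id`, `tissue`, `n_components`.
#' @examples
#' ds <- spectra_tbl(matrix(rnorm(60, 10), 6, 10), 401:410)
#' fit <- fit_pca(ds, 3)
#' glance(fit)
#' @export
fit_pca <- function(ds, n_components) {
  validate_spectra(ds)
  x <- spectra_matrix(ds)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) abort_ts("PCA needs at least 2 samples.", "insufficient_data")
  bound <- min(n - 1L, p)
  check_number(n_components, "n_components", lower = 1)
  n_components <- as.integer(n_components)
  if (n_components > bound) {
    abort_ts(sprintf("`n_components` (%d) exceeds the rank bound min(n - 1, p) = %d.",
                     n_components, bound), "rank")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  loadings <- sv$v
  scores <- sv$u %*% diag(d, n_components, n_components)
  ## deterministic orientation: largest-|.| loading element positive
  for (j in seq_len(n_components)) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(sv$d^2) / (n - 1)
  structure(list(
    mean = mu,
    loadings = loadings,
    singular_values = d,
    scores = scores,
    explained_variance = d^2 / (n - 1),
    total_variance = total_var,
    wavelengths = spectra_wavelengths(ds),
    sample_id = ds$sample_id,
    tissue = if ("tissue" %in% names(ds)) ds$tissue[1] else NA_character_,
    n_samples = n,
    n_components = n_components
  ), class = "spec_pca")
}

#' @export
print.spec_pca <- function(x, ...) {
  cat(sprintf("<spec_pca> %d components on %d samples x %d wavelengths\n",
              x$n_components, x$n_samples, length(x$wavelengths)))
  ev <- 100 * x$explained_variance / x$total_variance
  cat("  variance explained (%):", paste(sprintf("%.1f", ev), collapse = " "), "\n")
  invisible(x)
}

#' Project spectra into a fitted PCA space
#'
#' Computes scores `(X - mean) %*% loadings`. Applied to the training data
#' this reproduces the stored scores.
#'
#' @param object a [fit_pca()] model.
#' @param newdata a spectra tibble on the same wavelength grid.
#' @param ... unused.
#' @return a numeric score matrix (samples x components), rownames = sample ids.
#' @export
predict.spec_pca <- function(object, newdata, ...) {
  validate_spectra(newdata)
  wl <- spectra_wavelengths(newdata)
  if (length(wl) != length(object$wavelengths) ||
      !isTRUE(all.equal(wl, object$wavelengths))) {
    abort_ts("The wavelength grid does not match the fitted model.", "grid")
  }
  x <- spectra_matrix(newdata)
  scores <- sweep(x, 2, object$mean) %*% object$loadings
  rownames(scores) <- newdata$sample_id
  scores
}

#' Map PCA scores back to spectra
#'
#' Returns `mean + scores %*% t(loadings)`: the rank-limited reconstruction
#' `X = t p' + e` with the residual `e` discarded. A spectrum lying in the
#' retained subspace round-trips exactly through
#' `inverse_transform(model, predict(model, ds))`.
#'
#' @param model a [fit_pca()] model.
#' @param scores score matrix with at most `n_components` columns.
#' @param sample_id optional sample ids for the output rows.
#' @param stage optional stage labels for the output rows.
#' @return a spectra tibble on the model grid.
#' @export
inverse_transform <- function(model, scores, sample_id = NULL, stage = NULL) {
  stopifnot(inherits(model, "spec_pca"))
  scores <- as.matrix(scores)
  if (ncol(scores) > model$n_components) {
    abort_ts(sprintf("`scores` has %d columns but the model retains %d components.",
                     ncol(scores), model$n_components), "shape")
  }
  load_sub <- model$loadings[, seq_len(ncol(scores)), drop = FALSE]
  x <- sweep(scores %*% t(load_sub), 2, model$mean, "+")
  if (is.null(sample_id)) {
    sample_id <- rownames(scores)
    if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(scores)))
  }
  spectra_tbl(x, model$wavelengths, sample_id = sample_id,
              tissue = model$tissue, stage = stage)
}

#' @export
tidy.spec_pca <- function(x, ...) {
  tibble(
    component = rep(seq_len(x$n_components), each = length(x$wavelengths)),
    wavelength = rep(x$wavelengths, x$n_components),
    loading = as.numeric(x$loadings)
  )
}

#' @export
glance.spec_pca <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_wavelengths = length(x$wavelengths),
    n_components = x$n_components,
    prop_variance = sum(x$explained_variance) / x$total_variance
  )
}

#' Randomization test for the number of non-random components
#'
#' Decides how many leading principal components carry non-random structure,
#' reading the data as `X = t p' + e` with `e` random. For each permutation,
#' every wavelength column of the centred matrix is independently row-shuffled
#' — destroying inter-wavelength covariance while preserving each column's
#' marginal — and the leading component variances of the permuted matrix are
#' recorded. Component `j` is non-random when its observed variance exceeds
#' the `(1 - alpha)` quantile of the permuted `j`-th component variances, and
#' `retained` counts the leading consecutive non-random components. Comparing
#' each component with the same-index eigenvalue of the permuted matrix keeps
#' the test conservative after strong components, whose variance the
#' permutations spread across all null eigenvalues.
#'
#' @param ds a spectra tibble with at least 3 samples.
#' @param n_permutations number of permutations per component (>= 20).
#' @param alpha test level; default 0.05.
#' @param seed integer seed for the permutation stream.
#' @param max_components largest component index tested; default 8.
#' @return a list of class `randomization_result`: `observed_variances`,
#'   `null_quantiles`, `retained`, `n_permutations`, `alpha`, `seed`.
#' @examples
#' ds <- spectra_tbl(matrix(rnorm(300), 10, 30), 401:430)
#' select_components_randomization(ds, n_permutations = 50, seed = 1)$retained
#' @export
select_components_randomization <- function(ds, n_permutations = 200,
                                            alpha = 0.05, seed = 1,
                                            max_components = 8) {
  validate_spectra(ds)
  x <- spectra_matrix(ds)
  n <- nrow(x)
  if (n < 3L) abort_ts("The randomization test needs at least 3 samples.",
                       "insufficient_data")
  check_number(n_permutations, "n_permutations", lower = 20)
  check_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  max_components <- min(as.integer(max_components), n - 1L, ncol(x))
  xd <- sweep(x, 2, colMeans(x))
  observed <- svd(xd, nu = 0, nv = 0)$d[seq_len(max_components)]^2 / (n - 1)
  set.seed(derive_seed(seed, 101))
  null_stats <- matrix(vapply(seq_len(n_permutations), function(b) {
    xp <- vapply(seq_len(ncol(xd)), function(col) xd[sample.int(n), col],
                 numeric(n))
    svd(xp, nu = 0, nv = 0)$d[seq_len(max_components)]^2 / (n - 1)
  }, numeric(max_components)), nrow = n_permutations, byrow = TRUE)
  quantiles <- as.numeric(apply(null_stats, 2, quantile, probs = 1 - alpha))
  nonrandom <- observed > quantiles & observed > 1e-12
  retained <- which.max(c(!nonrandom, TRUE)) - 1L
  structure(list(
    observed_variances = observed,
    null_quantiles = quantiles,
    retained = retained,
    n_permutations = as.integer(n_permutations),
    alpha = alpha,
    seed = as.integer(seed)
  ), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> retained %d component(s) (alpha = %g, %d permutations)\n",
              x$retained, x$alpha, x$n_permutations))
  invisible(x)
}
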