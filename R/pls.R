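## accept either a spectra tibble or a plain matrix as the predictor block
as_x_matrix <- function(x) {
  if (is.data.frame(x)) spectra_matrix(x) else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}

#' Partial least squares regression (NIPALS)
#'
#' Fits a univariate-response PLS model by the NIPALS algorithm: each latent
#' variable maximises the covariance between the spectra `X` and the response
#' `y`; `X` (and `y`) are deflated after every extraction so successive score
#' vectors are orthogonal. The regression vector `b_pls` in `y = X b_pls` is
#' assembled from the weights and loadings by the usual oblique projection,
#' `b = W (P' W)^{-1} q`.
#'
#' The number of latent variables is chosen by leave-one-out cross-validation:
#' the LV count minimising the cross-validated RMSE (equivalently PRESS, since
#' `PRESS = n * RMSE^2`); exact ties go to the smaller count.
#'
#' @param x spectra tibble or numeric predictor matrix (samples x variables).
#' @param y numeric response vector.
#' @param max_lv largest candidate LV count; at most `min(n - 1, p)`.
#' @param select `"loocv"` (default) or `"none"` (keep `max_lv`).
#' @return an object of class `spec_pls`: `x_mean`, `y_mean`, `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `b_pls` (at `n_lv`), `coefficients`
#'   (list of `b` per LV count), `n_lv`, `press_curve`, `rmse_curve`.
#' @examples
#' x <- matrix(rnorm(80), 20, 4)
#' y <- x %*% c(1, -1, 0, 0) + rnorm(20, sd = 0.1)
#' fit <- fit_pls(x, y, max_lv = 4)
#' fit$n_lv
#' @export
fit_pls <- function(x, y, max_lv = 10, select = c("loocv", "none")) {
  select <- match.arg(select)
  x <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3L) abort_ts("PLS needs at least 3 samples.", "insufficient_data")
  if (length(y) != n) abort_ts("`y` must have one value per row of `x`.", "shape")
  if (sd(y) == 0) abort_ts("`y` has zero variance.", "degenerate")
  bound <- min(n - 1L, ncol(x))
  max_lv <- as.integer(max_lv)
  if (max_lv < 1L || max_lv > bound) {
    abort_ts(sprintf("`max_lv` must be between 1 and the rank bound %d.", bound),
             "rank")
  }
  core <- nipals_pls(x, y, max_lv)
  press <- rmse <- rep(NA_real_, core$n_lv_fit)
  if (select == "loocv") {
    sse <- numeric(core$n_lv_fit)
    for (i in seq_len(n)) {
      f <- nipals_pls(x[-i, , drop = FALSE], y[-i], core$n_lv_fit)
      xc <- x[i, ] - f$x_mean
      for (a in seq_len(core$n_lv_fit)) {
        b <- f$coefficients[[min(a, f$n_lv_fit)]]
        pred <- f$y_mean + sum(xc * b)
        sse[a] <- sse[a] + (y[i] - pred)^2
      }
    }
    press <- sse
    rmse <- sqrt(sse / n)
    n_lv <- which.min(rmse)
  } else {
    n_lv <- core$n_lv_fit
  }
  structure(c(core[c("x_mean", "y_mean", "weights", "x_loadings", "y_loadings",
                     "scores", "coefficients")],
              list(n_lv = as.integer(n_lv),
                   b_pls = core$coefficients[[n_lv]],
                   press_curve = press,
                   rmse_curve = rmse,
                   max_lv = max_lv,
                   n_samples = n)),
            class = "spec_pls")
}

## NIPALS core for a univariate response; stops early if X is exhausted
nipals_pls <- function(x, y, max_lv) {
  n <- nrow(x)
  p <- ncol(x)
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xd <- sweep(x, 2, x_mean)
  yd <- y - y_mean
  w_mat <- matrix(0, p, 0)
  p_mat <- matrix(0, p, 0)
  q_vec <- numeric(0)
  t_mat <- matrix(0, n, 0)
  for (a in seq_len(max_lv)) {
    w <- as.numeric(t(xd) %*% yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_a <- as.numeric(xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-20) break
    p_a <- as.numeric(t(xd) %*% t_a) / tt
    q_a <- sum(yd * t_a) / tt
    xd <- xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
    w_mat <- cbind(w_mat, w)
    p_mat <- cbind(p_mat, p_a)
    q_vec <- c(q_vec, q_a)
    t_mat <- cbind(t_mat, t_a)
  }
  n_lv_fit <- ncol(w_mat)
  if (n_lv_fit == 0L) {
    abort_ts("NIPALS extracted no latent variable (X'y is zero).", "degenerate")
  }
  coefficients <- purrr::map(seq_len(n_lv_fit), function(a) {
    wa <- w_mat[, seq_len(a), drop = FALSE]
    pa <- p_mat[, seq_len(a), drop = FALSE]
    as.numeric(wa %*% solve(t(pa) %*% wa, q_vec[seq_len(a)]))
  })
  list(x_mean = x_mean, y_mean = y_mean, weights = w_mat, x_loadings = p_mat,
       y_loadings = q_vec, scores = t_mat, coefficients = coefficients,
       n_lv_fit = n_lv_fit)
}

#' @export
print.spec_pls <- function(x, ...) {
  cat(sprintf("<spec_pls> %d latent variable(s) (of %d candidates), n = %d\n",
              x$n_lv, x$max_lv, x$n_samples))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Returns `y_mean + (X - x_mean) %*% b_pls`.
#'
#' @param object a [fit_pls()] model.
#' @param newdata spectra tibble or matrix with the fitted variable count.
#' @param n_lv LV count to predict with; defaults to the selected one.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.spec_pls <- function(object, newdata, n_lv = object$n_lv, ...) {
  x <- as_x_matrix(newdata)
  if (ncol(x) != length(object$x_mean)) {
    abort_ts("`newdata` does not match the fitted variable count.", "shape")
  }
  b <- object$coefficients[[n_lv]]
  as.numeric(object$y_mean + sweep(x, 2, object$x_mean) %*% b)
}

#' @export
tidy.spec_pls <- function(x, ...) {
  tibble(
    term = seq_along(x$b_pls),
    estimate = x$b_pls
  )
}

#' @export
glance.spec_pls <- function(x, ...) {
  tibble(
    n_lv = x$n_lv,
    press = x$press_curve[x$n_lv],
    rmse_cv = x$rmse_curve[x$n_lv],
    n_samples = x$n_samples
  )
}

#' Principal component regression
#'
#' Ordinary least squares of `y` on the leading PCA scores of `X`; at full
#' rank this equals OLS on `X` itself. Used as the latent-structure benchmark
#' against PLS.
#'
#' @inheritParams fit_pls
#' @param n_components number of principal components to regress on.
#' @return an object of class `spec_pcr`.
#' @export
fit_pcr <- function(x, y, n_components) {
  x <- as_x_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3L) abort_ts("PCR needs at least 3 samples.", "insufficient_data")
  if (sd(y) == 0) abort_ts("`y` has zero variance.", "degenerate")
  bound <- min(n - 1L, ncol(x))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > bound) {
    abort_ts(sprintf("`n_components` must be between 1 and the rank bound %d.",
                     bound), "rank")
  }
  x_mean <- colMeans(x)
  xc <- sweep(x, 2, x_mean)
  sv <- svd(xc, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  fit <- lm.fit(cbind(1, scores), y)
  structure(list(
    x_mean = x_mean,
    loadings = sv$v,
    coefficients = fit$coefficients,
    n_components = n_components,
    fitted = fit$fitted.values
  ), class = "spec_pcr")
}

#' @export
predict.spec_pcr <- function(object, newdata, ...) {
  x <- as_x_matrix(newdata)
  scores <- sweep(x, 2, object$x_mean) %*% object$loadings
  as.numeric(cbind(1, scores) %*% object$coefficients)
}

#' Similarity-based prediction in a feature space
#'
#' Predicts a property as the inverse-distance-weighted mean of the `k`
#' nearest training samples' values, with Euclidean distance in the latent
#' feature space. A query coinciding with a training sample returns that
#' sample's value. Predictions are convex combinations of training values, so
#' they stay inside `[min(train_y), max(train_y)]`.
#'
#' @param train_scores training feature-space coordinates (samples x dims).
#' @param train_y training property values.
#' @param query_scores query coordinates.
#' @param k neighbour count, between 1 and the training size.
#' @return numeric vector of predictions.
#' @export
predict_similarity <- function(train_scores, train_y, query_scores, k) {
  train_y <- as.numeric(train_y)
  if (length(train_y) != nrow(as.matrix(train_scores))) {
    abort_ts("`train_y` must have one value per training row.", "shape")
  }
  as.numeric(knn_map(train_scores, matrix(train_y, ncol = 1), query_scores, k))
}
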