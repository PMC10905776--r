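test_that("PLS fits rank-1 and full-rank problems exactly", {
  # rank-1 X with y = 3 x: one LV, exact training fit, effective coefficient 3
  v <- c(1, 2, 3, 4, 5)
  x <- outer(v, c(1, 0, 0, 0))
  y <- 3 * v
  f <- fit_pls(x, y, max_lv = 1, select = "none")
  expect_equal(predict(f, x), y, tolerance = 1e-10)
  expect_equal(f$b_pls[1], 3, tolerance = 1e-10)

  # full rank: training predictions equal ordinary least squares
  set.seed(51)
  x2 <- matrix(rnorm(15 * 5), 15, 5)
  y2 <- rnorm(15)
  f2 <- fit_pls(x2, y2, max_lv = 5, select = "none")
  ols <- lm.fit(cbind(1, x2), y2)
  expect_lt(max(abs(predict(f2, x2, n_lv = 5) - ols$fitted.values)), 1e-6)
  resid_pls <- y2 - predict(f2, x2, n_lv = 5)
  expect_lt(max(abs(resid_pls - ols$residuals)), 1e-6)

  expect_error(fit_pls(x2, rep(1, 15), max_lv = 2), class = "tomospec_degenerate")
  expect_error(fit_pls(x2, y2, max_lv = 20), class = "tomospec_rank")
})

test_that("the first PLS weight is the dominant eigenvector of X'y y'X", {
  set.seed(52)
  x <- matrix(rnorm(5 * 4), 5, 4)
  y <- rnorm(5)
  f <- fit_pls(x, y, max_lv = 2, select = "none")
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  m <- (t(xc) %*% yc) %*% (t(yc) %*% xc)
  e1 <- eigen(m, symmetric = TRUE)$vectors[, 1]
  w1 <- f$weights[, 1]
  expect_equal(abs(sum(w1 * e1)), 1, tolerance = 1e-8)
})

test_that("PLS predictions agree with an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(53)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("w", 1:8)))
  y <- as.numeric(x %*% rnorm(8) + rnorm(20, sd = 0.2))
  f <- fit_pls(x, y, max_lv = 3, select = "none")
  ref <- mixOmics::pls(x, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, x)$predict[, 1, 3]
  expect_lt(max(abs(predict(f, x, n_lv = 3) - pred_ref)), 1e-6)
})

test_that("PLS centring and duplication behave predictably", {
  set.seed(54)
  x <- matrix(rnorm(12 * 6), 12, 6)
  y <- rnorm(12)
  f <- fit_pls(x, y, max_lv = 3, select = "none")
  expect_equal(predict(f, matrix(f$x_mean, 1)), f$y_mean, tolerance = 1e-10)
  q <- x[c(2, 2, 7), ]
  p <- predict(f, q)
  expect_identical(p[1], p[2])
})

test_that("LOOCV RMSE selection recovers the planted latent dimension", {
  set.seed(55)
  n <- 30
  t2 <- matrix(rnorm(n * 2), n, 2)
  a <- matrix(rnorm(2 * 20), 2, 20)
  signal <- t2 %*% a
  x <- signal + matrix(rnorm(n * 20, 0, sqrt(mean(signal^2) / 100)), n, 20)
  y <- as.numeric(t2 %*% c(1, -0.7) + rnorm(n, 0.1))
  f <- fit_pls(x, y, max_lv = 6)
  expect_identical(f$n_lv, 2L)
  expect_equal(f$press_curve, n * f$rmse_curve^2, tolerance = 1e-10)
  expect_identical(which.min(f$rmse_curve), 2L)
})

test_that("PCR equals OLS at full rank and grows monotonically in fit", {
  set.seed(56)
  x <- matrix(rnorm(15 * 5), 15, 5)
  y <- rnorm(15)
  pcr <- fit_pcr(x, y, 5)
  ols <- lm.fit(cbind(1, x), y)
  expect_lt(max(abs(predict(pcr, x) - ols$fitted.values)), 1e-6)

  v <- c(1, 2, 3, 4, 5)
  x1 <- outer(v, c(2, 1))
  expect_equal(predict(fit_pcr(x1, 3 * v, 1), x1), 3 * v, tolerance = 1e-10)

  r2 <- vapply(1:5, function(k) {
    fit <- fit_pcr(x, y, k)
    1 - sum((y - fit$fitted)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("similarity prediction is a convex combination with exact-match lookup", {
  set.seed(57)
  scores <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(10)
  expect_equal(predict_similarity(scores, y, scores[4, , drop = FALSE], k = 1),
               y[4])
  # all distances equal: prediction is the plain mean
  eq <- rbind(diag(3), -diag(3))
  expect_equal(predict_similarity(eq, 1:6, matrix(0, 1, 3), k = 6), mean(1:6))
  q <- matrix(rnorm(20 * 3), 20, 3)
  p <- predict_similarity(scores, y, q, k = 4)
  expect_true(all(p >= min(y) - 1e-12 & p <= max(y) + 1e-12))
  expect_error(predict_similarity(scores, y, q, k = 11),
               class = "tomospec_parameter")
})

test_that("pigment indices follow the band-ratio definition", {
  wl <- 400:700
  flat <- spectra_tbl(matrix(1, 2, length(wl)), wl)
  pf <- pigment_indices(flat)
  expect_equal(pf$chlorophyll_index, c(1, 1))
  expect_equal(pf$lycopene_index, c(1, 1))

  # green band mean 2, red band mean 1
  x <- rep(1, length(wl))
  x[wl >= 520 & wl <= 570] <- 2
  stepped <- spectra_tbl(matrix(x, 1), wl)
  ps <- pigment_indices(stepped)
  expect_equal(ps$chlorophyll_index, 2)
  expect_equal(ps$lycopene_index, 0.5)

  # reciprocal identity on arbitrary positive spectra
  ds <- rand_spectra(6, 301, seed = 58, wl_start = 400)
  pr <- pigment_indices(ds)
  expect_lt(max(abs(pr$chlorophyll_index * pr$lycopene_index - 1)), 1e-10)
  expect_true(all(pr$chlorophyll_index > 0))

  narrow <- spectra_tbl(matrix(1, 1, 11), 700:710)
  expect_error(pigment_indices(narrow), class = "tomospec_coverage")
})

test_that("the quality benchmark is deterministic and excludes fruit-only targets", {
  cfg <- noiseless_cfg(n = 24, seed = 61, noise_sd = 0.01, scatter = TRUE,
                       mixing = "geometric", opacity = 0.3,
                       ssc_noise_sd = 0.2, puncture_noise_sd = 0.3)
  batch <- generate_dataset(cfg)
  m <- fit_tomography(batch$blocks, n_sub = 2, mode = "knn", k = 3)
  rep1 <- quality_benchmark(batch$blocks, batch$properties, m, seed = 5,
                            max_lv = 4)
  rep2 <- quality_benchmark(batch$blocks, batch$properties, m, seed = 5,
                            max_lv = 4)
  expect_identical(rep1, rep2)

  # SSC and puncture force exist for the whole fruit only: tissue rows carry
  # the dash (NA); pigment targets are predicted on the reconstructed dataset
  fruit_only <- dplyr::filter(rep1, property %in% c("ssc", "puncture_force"))
  expect_true(all(is.na(dplyr::filter(fruit_only, block != "tomato")$r)))
  expect_true(all(!is.na(dplyr::filter(fruit_only, block == "tomato")$n_lv)))
  pig <- dplyr::filter(rep1, property %in% c("chlorophyll", "lycopene"))
  expect_true(all(is.na(dplyr::filter(pig, dataset == "original")$r)))
  expect_true(all(!is.na(dplyr::filter(pig, dataset == "reconstructed")$r)))
})

test_that("a noiseless linear spectral functional is predicted with R^2 near 1", {
  cfg <- noiseless_cfg(n = 30, seed = 62)
  batch <- generate_dataset(cfg)
  m <- fit_tomography(batch$blocks, n_sub = 2, fusion_variance_threshold = 1,
                      mode = "linear", preprocess = "none")
  x <- spectra_matrix(batch$blocks$tomato)
  w <- seq(-1, 1, length.out = ncol(x))
  props <- tibble::tibble(
    sample_id = batch$blocks$tomato$sample_id,
    ssc_percent = as.numeric(x %*% w),
    puncture_force_N = batch$properties$puncture_force_N
  )
  rep <- quality_benchmark(batch$blocks, props, m, seed = 9, max_lv = 4)
  row <- dplyr::filter(rep, dataset == "original",
                       property == "ssc", block == "tomato")
  expect_gte(row$r_squared, 0.999)
})
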