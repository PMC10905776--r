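# rank-1 tissue block whose PCA score vector is (up to sign) `v`
rank1_block <- function(v, shape, tissue, wl = 401:430) {
  spectra_tbl(outer(v, shape) + 5, wl, tissue = tissue)
}

# reconstruct the stacked raw sub-scores of dimension i from the fusion fields
stacked_from_fusion <- function(ss, i) {
  d <- vapply(ss$fusion, function(f) f$d, integer(1))
  offset <- c(0, cumsum(d))[i]
  ti <- ss$T[, offset + seq_len(d[i]), drop = FALSE]
  f <- ss$fusion[[i]]
  sweep(sweep(ti %*% t(f$P), 2, f$scale, "*"), 2, f$center, "+")
}

test_that("aligned sub-scores collapse onto a single fused direction", {
  set.seed(31)
  v <- rnorm(10)
  b <- rank1_block(v, seq(1, 2, length.out = 30), "skin")
  blocks <- list(skin = b, pulp = b, seed = b)
  ss <- build_superset(blocks, n_sub = 1, fusion_variance_threshold = 0.95)
  f <- ss$fusion[[1]]
  expect_identical(f$d, 1L)
  expect_equal(abs(f$P[, 1]), rep(1 / sqrt(3), 3), tolerance = 1e-10)
  expect_equal(f$variance[1], 1, tolerance = 1e-10)
  # fused scores proportional to the shared score vector
  expect_equal(abs(cor(ss$T[, 1], v)), 1, tolerance = 1e-10)
})

test_that("orthogonal equal-norm sub-scores need three fused directions", {
  set.seed(32)
  raw <- matrix(rnorm(12 * 3), 12, 3)
  raw <- sweep(raw, 2, colMeans(raw))
  q <- qr.Q(qr(raw))            # zero-mean orthonormal columns
  q <- sweep(q, 2, colMeans(q)) # keep columns exactly centred
  shape <- seq(2, 1, length.out = 30)
  blocks <- list(skin = rank1_block(q[, 1], shape, "skin"),
                 pulp = rank1_block(q[, 2], shape, "pulp"),
                 seed = rank1_block(q[, 3], shape, "seed"))
  ss <- build_superset(blocks, n_sub = 1, fusion_variance_threshold = 0.95)
  f <- ss$fusion[[1]]
  expect_identical(f$d, 3L)
  # brute-force oracle: eigenvalues of the 3x3 covariance of the unit-scaled
  # stacked scores; orthogonal equal-norm vectors give an isotropic covariance
  s <- scale(q)
  ev <- eigen(stats::cov(s), symmetric = TRUE)$values
  expect_equal(f$variance, ev / sum(ev), tolerance = 1e-8)
  expect_equal(f$variance, rep(1 / 3, 3), tolerance = 1e-8)
})

test_that("full-rank fusion is lossless and fused loadings stay orthonormal", {
  cfg <- noiseless_cfg(n = 14, seed = 3, noise_sd = 0.02, scatter = TRUE)
  batch <- generate_dataset(cfg)
  ss <- build_superset(batch$blocks, n_sub = 3, fusion_variance_threshold = 1)
  for (i in 1:3) {
    f <- ss$fusion[[i]]
    expect_lt(max(abs(crossprod(f$P) - diag(f$d))), 1e-8)
    stacked <- vapply(ss$tissue_models, function(m) m$scores[, i],
                      numeric(length(ss$sample_id)))
    expect_lt(max(abs(stacked_from_fusion(ss, i) - stacked)), 1e-8)
  }
})

test_that("linear association solves the bi-directional least squares maps", {
  set.seed(41)
  t_train <- matrix(rnorm(20 * 4), 20, 4)

  # U = T: both maps are the identity
  eye <- associate_scores(t_train, t_train, mode = "linear")
  expect_lt(max(abs(eye$b - diag(4))), 1e-8)
  expect_lt(max(abs(eye$c - diag(4))), 1e-8)

  # U = T M: b recovers M (normal-equations oracle)
  m <- matrix(rnorm(4 * 3), 4, 3)
  u <- t_train %*% m
  lin <- associate_scores(t_train, u, mode = "linear")
  oracle <- solve(crossprod(t_train)) %*% t(t_train) %*% u
  expect_lt(max(abs(lin$b - m)), 1e-6)
  expect_lt(max(abs(lin$b - oracle)), 1e-8)

  expect_error(associate_scores(t_train, u, mode = "knn", k = 21),
               class = "tomospec_parameter")
})

test_that("knn with k = 1 is an exact lookup on training queries, both directions", {
  cfg <- noiseless_cfg(n = 16, seed = 9, noise_sd = 0.01, scatter = TRUE,
                       mixing = "geometric", opacity = 0.3)
  batch <- generate_dataset(cfg)
  m <- fit_tomography(batch$blocks, n_sub = 3, fusion_variance_threshold = 1,
                      mode = "knn", k = 1)
  i <- 5
  # forward: a training fruit's tissue triplet returns the model's own
  # representation of that fruit's tomato spectrum
  tissues_i <- purrr::map(batch$blocks[c("skin", "pulp", "seed")],
                          ~ .x[i, , drop = FALSE])
  rec <- reconstruct_tomato(m, tissues_i)
  own <- inverse_transform(m$association$tomato_model,
                           m$association$U_train[i, , drop = FALSE])
  expect_gt(cor(as.numeric(spectra_matrix(rec)),
                as.numeric(spectra_matrix(own))), 0.999)
  expect_lt(max(abs(spectra_matrix(rec) - spectra_matrix(own))), 1e-8)

  # backward: a training tomato spectrum returns the rank-limited tissue
  # reconstructions of that fruit
  dec <- decompose_tomato(m, batch$blocks$tomato[i, , drop = FALSE])
  for (role in c("skin", "pulp", "seed")) {
    tm <- m$superset$tissue_models[[role]]
    own_tissue <- inverse_transform(tm, tm$scores[i, , drop = FALSE])
    expect_lt(max(abs(spectra_matrix(dec[[role]]) -
                        spectra_matrix(own_tissue))), 1e-8)
  }
})

test_that("the training-mean tomato decomposes to the tissue means (linear mode)", {
  cfg <- noiseless_cfg(n = 14, seed = 17)
  batch <- generate_dataset(cfg)
  m <- fit_tomography(batch$blocks, n_sub = 2, fusion_variance_threshold = 1,
                      mode = "linear", preprocess = "none")
  mean_tomato <- spectra_tbl(
    matrix(colMeans(spectra_matrix(batch$blocks$tomato)), 1,
           ncol(spectra_matrix(batch$blocks$tomato))),
    spectra_wavelengths(batch$blocks$tomato)
  )
  dec <- decompose_tomato(m, mean_tomato)
  for (role in c("skin", "pulp", "seed")) {
    expect_lt(max(abs(spectra_matrix(dec[[role]]) -
                        colMeans(spectra_matrix(batch$blocks[[role]])))), 1e-8)
  }
})

test_that("reconstruction is equivariant under query-row permutation", {
  cfg <- noiseless_cfg(n = 12, seed = 23, noise_sd = 0.01, scatter = TRUE)
  batch <- generate_dataset(cfg)
  parts <- split_blocks(batch$blocks, 1:8)
  m <- fit_tomography(parts$train, n_sub = 2, mode = "knn", k = 3)
  tissues <- parts$holdout[c("skin", "pulp", "seed")]
  rec <- reconstruct_tomato(m, tissues)
  perm <- c(3, 1, 4, 2)
  tissues_p <- purrr::map(tissues, ~ .x[perm, , drop = FALSE])
  rec_p <- reconstruct_tomato(m, tissues_p)
  expect_equal(spectra_matrix(rec_p), spectra_matrix(rec)[perm, ],
               tolerance = 1e-12)
})

test_that("leave-one-out sizing recovers the planted two-factor dimension", {
  cfg <- noiseless_cfg(n = 12, seed = 5)
  batch <- generate_dataset(cfg)
  cv <- optimize_components_cv(batch$blocks, max_sub = 3,
                               fusion_variance_threshold = 1,
                               mode = "linear", preprocess = "none")
  expect_identical(cv$n_sub, 2L)
  # complete error curves: every candidate x tissue combination reported
  expect_identical(nrow(cv$curves), 9L)
  expect_false(anyNA(cv$curves$cv_mse))
  expect_lt(cv$total[2], 10 * .Machine$double.eps)
})

test_that("pure-noise wavelengths do not change the chosen sub-space size", {
  unchanged <- vapply(1:5, function(s) {
    cfg <- noiseless_cfg(n = 12, seed = 100 + s)
    batch <- generate_dataset(cfg)
    set.seed(s)
    # detector-scale pure-noise wavelengths appended to every block
    noisy_blocks <- purrr::map(unclass(batch$blocks), function(b) {
      extra <- matrix(rnorm(nrow(b) * 10, 10, 0.02), nrow(b), 10)
      wl <- spectra_wavelengths(b)
      spectra_tbl(cbind(spectra_matrix(b), extra),
                  c(wl, max(wl) + 1:10),
                  sample_id = b$sample_id, tissue = b$tissue[1],
                  stage = b$stage)
    })
    blocks <- block_set(noisy_blocks$tomato, noisy_blocks$skin,
                        noisy_blocks$pulp, noisy_blocks$seed)
    cv <- optimize_components_cv(blocks, max_sub = 3,
                                 fusion_variance_threshold = 1,
                                 mode = "linear", preprocess = "none")
    cv$n_sub == 2L
  }, logical(1))
  expect_gte(sum(unchanged), 4L)
})

test_that("reconstruction metrics match hand arithmetic and affine identities", {
  o <- spectra_tbl(matrix(c(1, 2, 4), 1, 3), c(400, 500, 600))
  r <- spectra_tbl(matrix(c(1.1, 1.8, 4.4), 1, 3), c(400, 500, 600))
  m <- reconstruction_metrics(o, r)
  expect_equal(m$mape, 10, tolerance = 1e-10)
  expect_equal(m$mse, 0.07, tolerance = 1e-10)

  ident <- reconstruction_metrics(o, o)
  expect_equal(ident$mse, 0)
  expect_equal(ident$mape, 0)
  expect_equal(ident$pearson_r, 1)

  doubled <- set_spectra_matrix(o, 2 * spectra_matrix(o))
  m2 <- reconstruction_metrics(o, doubled)
  expect_equal(m2$pearson_r, 1, tolerance = 1e-12)
  expect_equal(m2$mape, 100, tolerance = 1e-10)

  bad <- spectra_tbl(matrix(1:4, 1, 4), c(400, 500, 600, 700))
  expect_error(reconstruction_metrics(o, bad), class = "tomospec_shape")

  # per-sample mode: one row per sample, pooled values for a single row agree
  two <- spectra_tbl(matrix(c(1, 2, 4, 2, 3, 5), 2, 3, byrow = TRUE),
                     c(400, 500, 600), sample_id = c("a", "b"))
  per <- reconstruction_metrics(two, two, by_sample = TRUE)
  expect_identical(per$sample_id, c("a", "b"))
  expect_equal(per$mape, c(0, 0))
})

test_that("latent distances vanish for training samples and ignore global gain", {
  cfg <- noiseless_cfg(n = 14, seed = 29, noise_sd = 0.01, scatter = TRUE,
                       mixing = "geometric", opacity = 0.3)
  batch <- generate_dataset(cfg)
  parts <- split_blocks(batch$blocks, 1:10)
  m <- fit_tomography(parts$train, n_sub = 2, mode = "knn", k = 3)

  st_train <- latent_stability(m, tissues = parts$train[c("skin", "pulp", "seed")],
                               tomato = parts$train$tomato)
  expect_lt(max(st_train$distances$distance), 1e-8)

  ho <- parts$holdout
  st <- latent_stability(m, tissues = ho[c("skin", "pulp", "seed")],
                         tomato = ho$tomato)
  expect_true(all(st$distances$distance >= 0))
  expect_identical(sort(unique(st$distances$space)), c("T", "U"))

  # a global x10 intensity gain is absorbed by the scatter correction
  scaled <- purrr::map(unclass(ho), ~ set_spectra_matrix(.x, 10 * spectra_matrix(.x)))
  st10 <- latent_stability(m, tissues = scaled[c("skin", "pulp", "seed")],
                           tomato = scaled$tomato)
  expect_equal(st10$distances$distance, st$distances$distance, tolerance = 1e-8)
})

test_that("a fitted model survives the JSON round trip", {
  cfg <- noiseless_cfg(n = 12, seed = 37, noise_sd = 0.01, scatter = TRUE)
  batch <- generate_dataset(cfg)
  parts <- split_blocks(batch$blocks, 1:9)
  for (mode in c("knn", "linear")) {
    m <- fit_tomography(parts$train, n_sub = 2, mode = mode, k = 3)
    path <- withr::local_tempfile(fileext = ".json")
    write_tomography_json(m, path)
    back <- read_tomography_json(path)
    rec1 <- reconstruct_tomato(m, parts$holdout[c("skin", "pulp", "seed")])
    rec2 <- reconstruct_tomato(back, parts$holdout[c("skin", "pulp", "seed")])
    expect_equal(spectra_matrix(rec1), spectra_matrix(rec2), tolerance = 1e-12)
    dec1 <- decompose_tomato(m, parts$holdout$tomato)
    dec2 <- decompose_tomato(back, parts$holdout$tomato)
    expect_equal(spectra_matrix(dec1$pulp), spectra_matrix(dec2$pulp),
                 tolerance = 1e-12)
  }
})

test_that("hold-out evaluation reports the four targets with finite metrics", {
  cfg <- noiseless_cfg(n = 16, seed = 43, noise_sd = 0.01, scatter = TRUE,
                       mixing = "geometric", opacity = 0.3)
  batch <- generate_dataset(cfg)
  parts <- split_blocks(batch$blocks, 1:12)
  m <- fit_tomography(parts$train, n_sub = 2, mode = "knn", k = 3)
  ev <- evaluate_reconstruction(m, parts$holdout)
  expect_identical(ev$target, c("tomato", "skin", "pulp", "seed"))
  expect_true(all(is.finite(ev$mse)))
  expect_true(all(ev$mse >= 0))
  expect_true(all(ev$mape_median >= 0))
  expect_true(all(abs(ev$pearson_r) <= 1))
})
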