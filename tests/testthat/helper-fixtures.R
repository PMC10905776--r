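# in-code fixtures shared across the suite

# small strictly positive random spectra table
rand_spectra <- function(n, p, seed = 1, tissue = "tomato", wl_start = 401,
                         level = 10) {
  set.seed(seed)
  spectra_tbl(matrix(runif(n * p, level, 2 * level), n, p),
              seq(wl_start, by = 1, length.out = p), tissue = tissue)
}

# a clean, noise-free two-factor batch (linear mixing, no scatter)
noiseless_cfg <- function(n = 30, seed = 42, ...) {
  n3 <- c(green = ceiling(n * 0.4), turning = ceiling(n * 0.4))
  n3 <- c(n3, red = n - sum(n3))
  defaults <- list(
    n_samples = n, stage_counts = n3,
    scatter = FALSE, noise_sd = 0, weight_jitter_sd = 0,
    mixing = "linear", opacity = 0,
    ssc_noise_sd = 0, puncture_noise_sd = 0,
    wl_min = 400, wl_max = 700, wl_step = 5,
    seed = seed
  )
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# split a block set into train/hold-out block sets by row index
split_blocks <- function(blocks, train_idx) {
  sub <- function(i) {
    parts <- purrr::map(unclass(blocks), ~ .x[i, , drop = FALSE])
    block_set(parts$tomato, parts$skin, parts$pulp, parts$seed)
  }
  list(train = sub(train_idx),
       holdout = sub(setdiff(seq_len(nrow(blocks$tomato)), train_idx)))
}

# per-sample Pearson correlation between two spectra tables
row_cors <- function(a, b) {
  ma <- spectra_matrix(a)
  mb <- spectra_matrix(b)
  vapply(seq_len(nrow(ma)), function(i) cor(ma[i, ], mb[i, ]), numeric(1))
}
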