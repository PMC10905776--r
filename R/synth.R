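#' Configuration of the synthetic fruit-spectra generator
#'
#' Describes a batch of paired Vis-NIR measurements: per-tissue reflectance
#' spectra (skin, pulp, seed) and the whole-fruit spectrum mixed from them,
#' across a green / turning / red maturation gradient. Each tissue spectrum is
#' a smooth positive baseline minus Gaussian pigment absorption bands:
#' chlorophyll features near 480 and 680 nm whose depth decays with the
#' maturation parameter `m`, and a carotenoid/lycopene feature near 530 nm
#' whose depth grows with `m`; the skin carries the strongest pigment signal.
#' A second per-sample latent factor (structural/size) tilts the baseline, so
#' the noiseless data have exactly two latent drivers. Measurement artefacts
#' are per-sample multiplicative gain and additive offset (scatter), detector
#' noise, and — for the whole fruit — per-sample jitter of the tissue mixing
#' weights, emulating probe-position variability, plus an opacity attenuation
#' that grows towards the green stage.
#'
#' @param n_samples number of fruits; the `stage_counts` must sum to it.
#' @param stage_counts named integer vector over `green`, `turning`, `red`.
#' @param wl_min,wl_max,wl_step wavelength grid in nm (default 380-780, 1 nm).
#' @param stage_m centre of the maturation parameter per stage.
#' @param m_jitter half-width of the uniform within-stage jitter of `m`.
#' @param structure_sd sd of the structural latent factor.
#' @param scatter logical; apply per-sample gain/offset scatter.
#' @param gain_log_sd sd of the log-normal per-sample gain.
#' @param offset_sd sd of the additive per-sample offset.
#' @param noise_sd sd of the additive detector noise.
#' @param mixing `"geometric"` (weighted geometric mean, the default —
#'   multiplicative attenuation along the light path) or `"linear"` (weighted
#'   arithmetic mean, lossless for round-trip checks).
#' @param mixing_weights tissue contribution weights (skin, pulp, seed).
#' @param weight_jitter_sd sd of the per-sample log-normal jitter on the
#'   mixing weights (0 disables).
#' @param opacity attenuation coefficient of the whole-fruit signal towards
#'   `m = 0` (geometric mode only): factor `1 - opacity * (1 - m)`.
#' @param ssc_noise_sd,puncture_noise_sd measurement noise of the quality
#'   targets (soluble solids %, puncture force N).
#' @param seed integer seed; every random draw derives from it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 118,
                         stage_counts = c(green = 53, turning = 60, red = 5),
                         wl_min = 380, wl_max = 780, wl_step = 1,
                         stage_m = c(green = 0.1, turning = 0.5, red = 0.9),
                         m_jitter = 0.08,
                         structure_sd = 1,
                         scatter = TRUE,
                         gain_log_sd = 0.08,
                         offset_sd = 0.01,
                         noise_sd = 0.01,
                         mixing = c("geometric", "linear"),
                         mixing_weights = c(skin = 0.35, pulp = 0.45, seed = 0.20),
                         weight_jitter_sd = 0.2,
                         opacity = 0.35,
                         ssc_noise_sd = 0.3,
                         puncture_noise_sd = 0.4,
                         seed = 1) {
  mixing <- match.arg(mixing)
  stage_counts <- unlist(stage_counts)   # accept YAML/JSON config lists
  cfg <- list(
    n_samples = as.integer(n_samples),
    stage_counts = stage_counts,
    wavelengths = seq(wl_min, wl_max, by = wl_step),
    stage_m = stage_m,
    m_jitter = m_jitter,
    structure_sd = structure_sd,
    scatter = isTRUE(scatter),
    gain_log_sd = gain_log_sd,
    offset_sd = offset_sd,
    noise_sd = noise_sd,
    mixing = mixing,
    mixing_weights = mixing_weights,
    weight_jitter_sd = weight_jitter_sd,
    opacity = opacity,
    ssc_noise_sd = ssc_noise_sd,
    puncture_noise_sd = puncture_noise_sd,
    seed = as.integer(seed),
    ## pigment absorption bands: centre (nm), width (nm, Gaussian sd),
    ## per-tissue depth, and the maturation driver of the depth
    bands = list(
      chlorophyll_blue = list(center = 480, width = 18,
                              amp = c(skin = 0.45, pulp = 0.30, seed = 0.15),
                              driver = "chlorophyll"),
      chlorophyll_red = list(center = 680, width = 12,
                             amp = c(skin = 0.35, pulp = 0.25, seed = 0.12),
                             driver = "chlorophyll"),
      lycopene = list(center = 530, width = 22,
                      amp = c(skin = 0.40, pulp = 0.30, seed = 0.12),
                      driver = "lycopene")
    ),
    baseline_level = c(skin = 1.0, pulp = 0.9, seed = 0.8),
    baseline_slope = 0.10,
    structure_tilt = 0.05,
    structure_level = 0.03
  )
  if (sum(cfg$stage_counts) != cfg$n_samples) {
    abort_ts("`stage_counts` must sum to `n_samples`.", "config")
  }
  if (!all(names(cfg$stage_counts) %in% stage_levels)) {
    abort_ts("`stage_counts` names must be maturation stages.", "config")
  }
  nonneg <- c(cfg$m_jitter, cfg$structure_sd, cfg$gain_log_sd, cfg$offset_sd,
              cfg$noise_sd, cfg$weight_jitter_sd, cfg$opacity,
              cfg$ssc_noise_sd, cfg$puncture_noise_sd)
  if (any(nonneg < 0)) abort_ts("Noise and scatter scales must be >= 0.", "config")
  if (any(cfg$mixing_weights < 0) || sum(cfg$mixing_weights) <= 0) {
    abort_ts("`mixing_weights` must be non-negative and not all zero.", "config")
  }
  if (any(cfg$stage_m < 0) || any(cfg$stage_m > 1)) {
    abort_ts("`stage_m` values must lie in [0, 1].", "config")
  }
  if (length(cfg$wavelengths) < 2) {
    abort_ts("The wavelength grid needs at least 2 points.", "config")
  }
  structure(cfg, class = "synth_config")
}

## noiseless spectrum matrix of one tissue given maturation m and structure s
tissue_noiseless <- function(cfg, role, m, s) {
  wl <- cfg$wavelengths
  lam <- (wl - mean(wl)) / (diff(range(wl)) / 2)
  base <- cfg$baseline_level[[role]] + cfg$baseline_slope * lam
  out <- matrix(rep(base, each = length(m)), length(m), length(wl))
  out <- out + outer(s, cfg$structure_tilt * lam + cfg$structure_level)
  for (band in cfg$bands) {
    depth <- band$amp[[role]] *
      (if (band$driver == "chlorophyll") 1 - m else m)
    shape <- exp(-0.5 * ((wl - band$center) / band$width)^2)
    out <- out - outer(depth, shape)
  }
  pmax(out, 1e-3)
}

## per-sample gain/offset scatter plus detector noise, clipped positive
apply_scatter_noise <- function(cfg, x) {
  n <- nrow(x)
  p <- ncol(x)
  gain <- if (cfg$scatter) exp(rnorm(n, 0, cfg$gain_log_sd)) else rep(1, n)
  offset <- if (cfg$scatter) rnorm(n, 0, cfg$offset_sd) else rep(0, n)
  noise <- if (cfg$noise_sd > 0) matrix(rnorm(n * p, 0, cfg$noise_sd), n, p)
           else matrix(0, n, p)
  pmax(x * gain + offset + noise, 1e-3)
}

#' Generate paired tissue spectra with ground truth
#'
#' Draws the maturation parameter `m` per fruit (stage centre plus uniform
#' jitter, clamped to `[0, 1]`) and the structural factor, builds the
#' noiseless skin/pulp/seed spectra, and applies scatter and detector noise.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a list: `tissues` (named list of skin/pulp/seed spectra tibbles)
#'   and `ground_truth` (list with `sample_id`, `stage`, `m`, `structure`,
#'   `wavelengths`, and `noiseless`, the named list of noiseless intensity
#'   matrices).
#' @export
generate_tissue_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, 1))
  n <- cfg$n_samples
  stage <- rep(names(cfg$stage_counts), cfg$stage_counts)
  sample_id <- sprintf("s%03d", seq_len(n))
  m <- pmin(pmax(cfg$stage_m[stage] + runif(n, -cfg$m_jitter, cfg$m_jitter), 0), 1)
  names(m) <- NULL
  s <- rnorm(n, 0, cfg$structure_sd)
  roles <- c("skin", "pulp", "seed")
  noiseless <- purrr::map(setNames(roles, roles),
                          ~ tissue_noiseless(cfg, .x, m, s))
  tissues <- purrr::imap(noiseless, function(x, role) {
    spectra_tbl(apply_scatter_noise(cfg, x), cfg$wavelengths,
                sample_id = sample_id, tissue = role, stage = stage)
  })
  list(
    tissues = tissues,
    ground_truth = list(sample_id = sample_id, stage = stage, m = m,
                        structure = s, wavelengths = cfg$wavelengths,
                        noiseless = noiseless)
  )
}

#' Mix tissue spectra into a whole-fruit spectrum
#'
#' Combines (noiseless) tissue spectra into the whole-fruit spectrum. In
#' geometric mode (default) the mix is the weighted geometric mean — light
#' attenuates multiplicatively along the path through the tissues — scaled by
#' the opacity factor `1 - opacity * (1 - m)`, which darkens green fruit. In
#' linear mode it is the weighted arithmetic mean with no opacity term, a
#' lossless convex combination for round-trip tests. Mixing weights get
#' per-sample log-normal jitter when `cfg$weight_jitter_sd > 0` (the probe
#' never samples the tissues in exactly the nominal proportion); scatter and
#' detector noise are applied afterwards.
#'
#' @param tissues named list (`skin`, `pulp`, `seed`) of spectra tibbles.
#' @param cfg a [synth_config()].
#' @param m optional per-sample maturation parameter for the opacity factor;
#'   when `NULL` no opacity attenuation is applied.
#' @return a whole-fruit spectra tibble (observed scale); the noiseless mixed
#'   matrix is attached as attribute `"noiseless"`.
#' @export
mix_whole_tomato <- function(tissues, cfg, m = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  roles <- c("skin", "pulp", "seed")
  mats <- purrr::map(tissues[roles], spectra_matrix)
  n <- nrow(mats$skin)
  p <- ncol(mats$skin)
  set.seed(derive_seed(cfg$seed, 2))
  w0 <- cfg$mixing_weights[roles] / sum(cfg$mixing_weights[roles])
  w <- matrix(rep(w0, each = n), n, 3)
  if (cfg$weight_jitter_sd > 0) {
    w <- w * exp(matrix(rnorm(n * 3, 0, cfg$weight_jitter_sd), n, 3))
    w <- w / rowSums(w)
  }
  if (cfg$mixing == "geometric") {
    if (any(purrr::map_lgl(mats, ~ any(.x <= 0)))) {
      abort_ts("Geometric mixing needs strictly positive tissue spectra.",
               "domain")
    }
    logy <- w[, 1] * log(mats$skin) + w[, 2] * log(mats$pulp) +
      w[, 3] * log(mats$seed)
    y <- exp(logy)
    if (!is.null(m)) {
      fac <- 1 - cfg$opacity * (1 - m)
      if (any(fac <= 0)) abort_ts("Opacity factor is non-positive.", "config")
      y <- y * fac
    }
  } else {
    y <- w[, 1] * mats$skin + w[, 2] * mats$pulp + w[, 3] * mats$seed
  }
  observed <- apply_scatter_noise(cfg, y)
  out <- spectra_tbl(observed, spectra_wavelengths(tissues$skin),
                     sample_id = tissues$skin$sample_id, tissue = "tomato",
                     stage = tissues$skin$stage)
  attr(out, "noiseless") <- y
  out
}

#' Generate a full paired synthetic dataset
#'
#' The complete study batch: four paired spectral blocks (whole tomato plus
#' skin, pulp, seed — the tomato mixed from the *noiseless* tissue spectra,
#' then given its own scatter and noise), quality properties (soluble solids
#' content increasing with maturation, puncture force decreasing), and the
#' generating ground truth.
#'
#' @param cfg a [synth_config()].
#' @return a list: `blocks` (a [block_set()]), `properties` (tibble with
#'   `sample_id`, `stage`, `ssc_percent`, `puncture_force_N`), and
#'   `ground_truth` (as in [generate_tissue_spectra()], plus
#'   `noiseless$tomato`, `true_ssc`, `true_puncture`).
#' @examples
#' batch <- generate_dataset(synth_config(n_samples = 12,
#'   stage_counts = c(green = 5, turning = 5, red = 2), seed = 7))
#' batch$blocks
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  ts <- generate_tissue_spectra(cfg)
  gt <- ts$ground_truth
  noiseless_tissues <- purrr::imap(gt$noiseless, function(x, role) {
    spectra_tbl(x, gt$wavelengths, sample_id = gt$sample_id,
                tissue = role, stage = gt$stage)
  })
  tomato <- mix_whole_tomato(noiseless_tissues, cfg, m = gt$m)
  gt$noiseless$tomato <- attr(tomato, "noiseless")
  set.seed(derive_seed(cfg$seed, 3))
  gt$true_ssc <- 4 + 6 * gt$m
  gt$true_puncture <- 9 - 6 * gt$m
  properties <- tibble(
    sample_id = gt$sample_id,
    stage = gt$stage,
    ssc_percent = gt$true_ssc + rnorm(cfg$n_samples, 0, cfg$ssc_noise_sd),
    puncture_force_N = gt$true_puncture +
      rnorm(cfg$n_samples, 0, cfg$puncture_noise_sd)
  )
  blocks <- block_set(tomato, ts$tissues$skin, ts$tissues$pulp, ts$tissues$seed)
  list(blocks = blocks, properties = properties, ground_truth = gt)
}
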