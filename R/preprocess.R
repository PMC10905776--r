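#' Logarithm multiplicative scatter correction
#'
#' Normalises spectra against multiplicative and additive scattering. Each
#' spectrum is first log-transformed (natural log), then regressed by ordinary
#' least squares on a reference log-spectrum, `y = a + b * r`; the corrected
#' spectrum is `(y - a) / b`. Per-sample gains become intercept shifts in the
#' log domain and are absorbed into `a`, so the correction is invariant to
#' positive per-sample scaling of the raw intensities.
#'
#' When no reference is supplied the mean log-spectrum of `ds` is used and
#' returned (as the `msc_reference` attribute of the result) so the identical
#' reference can be frozen and reapplied to hold-out data — fitting the
#' reference on training data only avoids leaking information into validation
#' metrics.
#'
#' @param ds a spectra tibble with strictly positive intensities.
#' @param reference optional reference from a previous `log_msc()` call (the
#'   `msc_reference` attribute of its result, or that result itself).
#' @return the corrected spectra tibble (log-domain scale), with attribute
#'   `msc_reference`: a list with `wavelengths` and `reference` (the log-domain
#'   reference spectrum). Retrieve it with [msc_reference()].
#' @examples
#' ds <- spectra_tbl(matrix(runif(40, 1, 2), 4, 10), 401:410)
#' corrected <- log_msc(ds)
#' ref <- msc_reference(corrected)
#' holdout <- log_msc(ds[1, ], reference = ref)
#' @export
log_msc <- function(ds, reference = NULL) {
  validate_spectra(ds)
  x <- spectra_matrix(ds)
  wl <- spectra_wavelengths(ds)
  if (any(x <= 0)) {
    abort_ts("All intensities must be strictly positive for the log transform.",
             "domain")
  }
  y <- log(x)
  if (!is.null(reference)) {
    ref <- msc_reference(reference)
    if (is.null(ref)) {
      abort_ts("`reference` is not an MSC reference.", "parameter")
    }
    if (length(ref$reference) != length(wl) ||
        !isTRUE(all.equal(ref$wavelengths, wl))) {
      abort_ts("The MSC reference grid does not match the data grid.", "grid")
    }
    r <- ref$reference
  } else {
    r <- colMeans(y)
  }
  if (any(!is.finite(r))) {
    abort_ts("The MSC reference must be finite.", "domain")
  }
  r_c <- r - mean(r)
  denom <- sum(r_c^2)
  if (denom < 1e-24) {
    abort_ts("The MSC reference is constant; the slope is undefined.",
             "degenerate")
  }
  corrected <- t(apply(y, 1, function(row) {
    b <- sum(r_c * (row - mean(row))) / denom
    if (abs(b) < 1e-12) {
      abort_ts("Degenerate MSC slope (|b| < 1e-12) for a spectrum.", "degenerate")
    }
    a <- mean(row) - b * mean(r)
    (row - a) / b
  }))
  out <- set_spectra_matrix(ds, corrected, wl)
  attr(out, "msc_reference") <- list(wavelengths = wl, reference = as.numeric(r))
  out
}

#' @rdname log_msc
#' @param x a result of `log_msc()` or an MSC reference list.
#' @export
msc_reference <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(c("wavelengths", "reference") %in% names(x))) {
    return(x)
  }
  attr(x, "msc_reference")
}

#' Standardize spectra to zero mean, unit standard deviation
#'
#' Applies `(x - mean) / sd` (sample sd, `n - 1` denominator) either within
#' each spectrum (row) or within each wavelength (column). The per-spectrum
#' mode removes per-sample signal-intensity differences and is the default;
#' per-wavelength rescales variables instead.
#'
#' @param ds a spectra tibble.
#' @param axis `"per_spectrum"` (default) or `"per_wavelength"`.
#' @return the standardized spectra tibble.
#' @examples
#' standardize(spectra_tbl(matrix(c(1, 2, 3), 1, 3), c(400, 500, 600)))
#' @export
standardize <- function(ds, axis = c("per_spectrum", "per_wavelength")) {
  axis <- match.arg(axis)
  validate_spectra(ds)
  x <- spectra_matrix(ds)
  if (axis == "per_spectrum") {
    if (ncol(x) < 2L) abort_ts("Need at least 2 wavelengths per spectrum.", "shape")
    s <- apply(x, 1, sd)
    if (any(s <= 0)) {
      abort_ts(sprintf("Zero variance in spectrum of sample '%s'.",
                       ds$sample_id[which(s <= 0)[1]]), "degenerate")
    }
    out <- (x - rowMeans(x)) / s
  } else {
    if (nrow(x) < 2L) abort_ts("Need at least 2 samples per wavelength.", "shape")
    s <- apply(x, 2, sd)
    if (any(s <= 0)) {
      wl <- spectra_wavelengths(ds)
      abort_ts(sprintf("Zero variance at wavelength %s nm.",
                       wl[which(s <= 0)[1]]), "degenerate")
    }
    out <- sweep(sweep(x, 2, colMeans(x)), 2, s, "/")
  }
  set_spectra_matrix(ds, out)
}
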