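#' Plot spectra as intensity curves
#'
#' One line per sample over the wavelength grid, coloured by maturation stage
#' (or any metadata column).
#'
#' @param ds a spectra tibble.
#' @param colour metadata column to colour by; default `"stage"`.
#' @return a ggplot object.
#' @export
plot_spectra <- function(ds, colour = "stage") {
  validate_spectra(ds)
  long <- ds |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(names(ds)[is_wavelength_name(names(ds))]),
      names_to = "wavelength", values_to = "intensity"
    ) |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$intensity,
    group = .data$sample_id,
    colour = if (colour %in% names(long)) .data[[colour]] else NULL
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity", colour = colour) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spec_pca <- function(object, ...) {
  scores <- object$scores
  df <- tibble(
    sample_id = object$sample_id,
    pc1 = scores[, 1],
    pc2 = if (object$n_components >= 2) scores[, 2] else 0
  )
  ev <- 100 * object$explained_variance / object$total_variance
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ev[1]),
      y = if (object$n_components >= 2) sprintf("PC2 (%.1f%%)", ev[2]) else "",
      title = sprintf("Feature space (%s)", object$tissue)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spec_pls <- function(object, ...) {
  df <- tibble(
    n_lv = seq_along(object$rmse_curve),
    rmse = object$rmse_curve
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_lv, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_lv, linetype = "dashed") +
    ggplot2::labs(x = "latent variables", y = "LOOCV RMSE") +
    ggplot2::theme_minimal()
}

#' Overlay an original and a reconstructed spectrum
#'
#' @param original,reconstructed spectra tibbles on the same grid.
#' @param sample_id sample to plot; defaults to the first.
#' @return a ggplot object.
#' @export
plot_reconstruction <- function(original, reconstructed, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- original$sample_id[1]
  pick <- function(ds, label) {
    row <- ds[ds$sample_id == sample_id, , drop = FALSE]
    tibble(
      wavelength = spectra_wavelengths(ds),
      intensity = as.numeric(spectra_matrix(row)),
      series = label
    )
  }
  df <- dplyr::bind_rows(pick(original, "original"),
                         pick(reconstructed, "reconstructed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$intensity,
                                   colour = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity", colour = NULL,
                  linetype = NULL, title = sample_id) +
    ggplot2::theme_minimal()
}
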