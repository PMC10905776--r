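#' Spectral data tables
#'
#' A spectral dataset is an ordinary tibble in wide format: the metadata
#' columns `sample_id`, `tissue` and `stage`, followed by one numeric column
#' per wavelength whose name is the wavelength in nanometres (e.g. `"400"`,
#' `"400.5"`). All toolkit functions take and return this shape, so spectra
#' flow through dplyr pipelines unchanged.
#'
#' `spectra_tbl()` builds such a table from an intensity matrix;
#' `spectra_wavelengths()` extracts the wavelength grid (nm) and
#' `spectra_matrix()` the samples-by-wavelengths intensity matrix.
#'
#' @param intensities numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing,
#'   all positive, length at least 2.
#' @param sample_id character vector of unique sample identifiers. Defaults to
#'   `"s1"`, `"s2"`, ...
#' @param tissue tissue role of every sample: one of `"tomato"`, `"skin"`,
#'   `"pulp"`, `"seed"`.
#' @param stage optional per-sample maturation stage; either the six-colour
#'   scale (`green`, `breakers`, `turning`, `pink`, `light-red`, `red`) or the
#'   three-level scale (`green`, `turning`, `red`). `NA` allowed.
#' @return A tibble with columns `sample_id`, `tissue`, `stage`, then one
#'   column per wavelength.
#' @examples
#' ds <- spectra_tbl(matrix(1:6, 2, 3), c(400, 500, 600))
#' spectra_wavelengths(ds)
#' spectra_matrix(ds)
#' @export
spectra_tbl <- function(intensities, wavelengths, sample_id = NULL,
                        tissue = "tomato", stage = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(intensities)))
  if (is.null(stage)) stage <- rep(NA_character_, nrow(intensities))
  stage <- as.character(stage)
  tissue <- rep_len(as.character(tissue), nrow(intensities))
  if (length(stage) == 1L) stage <- rep(stage, nrow(intensities))
  out <- tibble(
    sample_id = as.character(sample_id),
    tissue = tissue,
    stage = stage
  )
  mat <- as_tibble(intensities, .name_repair = "minimal")
  names(mat) <- as.character(wavelengths)
  out <- dplyr::bind_cols(out, mat)
  validate_spectra(out)
  out
}

#' Maturation stage vocabulary
#'
#' The six-colour ripeness scale; the three-level scale used for modelling is
#' the subset `green`, `turning`, `red`.
#' @export
stage_levels <- c("green", "breakers", "turning", "pink", "light-red", "red")

tissue_levels <- c("tomato", "skin", "pulp", "seed")

is_wavelength_name <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

#' @rdname spectra_tbl
#' @param ds a spectra tibble.
#' @export
spectra_wavelengths <- function(ds) {
  as.numeric(names(ds)[is_wavelength_name(names(ds))])
}

#' @rdname spectra_tbl
#' @export
spectra_matrix <- function(ds) {
  cols <- names(ds)[is_wavelength_name(names(ds))]
  m <- as.matrix(ds[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ds$sample_id
  m
}

## replace the wavelength block of a spectra tibble, keeping metadata
set_spectra_matrix <- function(ds, mat, wavelengths = NULL) {
  meta <- ds[, intersect(c("sample_id", "tissue", "stage"), names(ds)), drop = FALSE]
  if (is.null(wavelengths)) wavelengths <- spectra_wavelengths(ds)
  mat <- as.matrix(mat)
  body <- as_tibble(mat, .name_repair = "minimal")
  names(body) <- as.character(wavelengths)
  dplyr::bind_cols(meta, body)
}

#' Validate a spectra tibble
#'
#' Checks the wavelength grid (strictly increasing, positive, length >= 2),
#' sample id uniqueness and the stage vocabulary. Returns the input invisibly
#' so it can sit inside a pipeline.
#'
#' @param ds a spectra tibble.
#' @return `ds`, invisibly.
#' @export
validate_spectra <- function(ds) {
  if (!is.data.frame(ds) || !"sample_id" %in% names(ds)) {
    abort_ts("A spectra table needs a `sample_id` column.", "validation")
  }
  wl <- spectra_wavelengths(ds)
  if (length(wl) < 2L) {
    abort_ts("The wavelength grid must contain at least 2 wavelengths.", "grid")
  }
  if (any(wl <= 0)) {
    abort_ts("Wavelengths must all be positive.", "grid")
  }
  if (any(diff(wl) <= 0)) {
    abort_ts("Wavelengths must be strictly increasing.", "grid")
  }
  if (anyDuplicated(ds$sample_id)) {
    dup <- ds$sample_id[duplicated(ds$sample_id)][1]
    abort_ts(sprintf("Duplicate sample id: '%s'.", dup), "validation")
  }
  if ("stage" %in% names(ds)) {
    bad <- setdiff(unique(ds$stage[!is.na(ds$stage)]), stage_levels)
    if (length(bad) > 0) {
      abort_ts(sprintf("Unknown stage label(s): %s.",
                       paste0("'", bad, "'", collapse = ", ")), "validation")
    }
  }
  invisible(ds)
}

#' Read and write wide-format spectra CSV files
#'
#' The on-disk dialect is the same wide shape as [spectra_tbl()]: metadata
#' columns `sample_id`, `tissue`, `stage` (tissue and stage may be absent or
#' empty), then wavelength columns whose headers are decimal nm values. UTF-8,
#' `.` decimal separator.
#'
#' @param path file path.
#' @param tissue_role optional tissue role to assign (overrides any `tissue`
#'   column in the file).
#' @return `read_spectra_csv()` returns a spectra tibble with rows in file
#'   order; `write_spectra_csv()` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path, tissue_role = NULL) {
  if (!file.exists(path)) {
    abort_ts(sprintf("File not found: '%s'.", path), "io")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  meta_cols <- intersect(c("sample_id", "tissue", "stage"), header)
  other <- setdiff(header, meta_cols)
  if (!all(is_wavelength_name(other))) {
    bad <- other[!is_wavelength_name(other)][1]
    abort_ts(sprintf("Non-numeric wavelength header: '%s'.", bad), "format")
  }
  types <- do.call(readr::cols, c(
    setNames(rep(list(readr::col_character()), length(meta_cols)), meta_cols),
    list(.default = readr::col_double())
  ))
  ds <- readr::read_csv(path, col_types = types, name_repair = "minimal")
  if (!"sample_id" %in% names(ds)) {
    abort_ts("Missing `sample_id` column.", "format")
  }
  if (!"tissue" %in% names(ds)) ds$tissue <- NA_character_
  if (!"stage" %in% names(ds)) ds$stage <- NA_character_
  if (!is.null(tissue_role)) ds$tissue <- tissue_role
  ds$stage[!is.na(ds$stage) & ds$stage == ""] <- NA_character_
  ds <- ds[, c("sample_id", "tissue", "stage",
               setdiff(names(ds), c("sample_id", "tissue", "stage")))]
  validate_spectra(ds)
  ds
}

#' @rdname read_spectra_csv
#' @param ds a spectra tibble.
#' @export
write_spectra_csv <- function(ds, path) {
  validate_spectra(ds)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_ts(sprintf("Directory does not exist: '%s'.", dir), "io")
  }
  readr::write_csv(ds, path, na = "")
  invisible(path)
}

#' Restrict a spectral dataset to a wavelength window
#'
#' Keeps exactly the wavelengths in the closed interval `[lo, hi]` — typically
#' the illuminated 380-780 nm window of a white-LED source, out of a wider
#' spectrometer grid. Sample metadata is unchanged.
#'
#' @param ds a spectra tibble.
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return the cropped spectra tibble.
#' @examples
#' ds <- spectra_tbl(matrix(1:8, 2, 4), c(300, 400, 500, 800))
#' spectra_wavelengths(crop_wavelengths(ds, 380, 780))
#' @export
crop_wavelengths <- function(ds, lo, hi) {
  check_number(lo, "lo")
  check_number(hi, "hi")
  if (lo >= hi) abort_ts("`lo` must be smaller than `hi`.", "parameter")
  wl <- spectra_wavelengths(ds)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) {
    abort_ts(sprintf("No wavelength lies in [%s, %s] nm.", lo, hi), "grid")
  }
  if (sum(keep) < 2L) {
    abort_ts(sprintf("Cropping to [%s, %s] nm leaves fewer than 2 wavelengths.",
                     lo, hi), "grid")
  }
  set_spectra_matrix(ds, spectra_matrix(ds)[, keep, drop = FALSE], wl[keep])
}

#' Paired tissue and whole-fruit blocks
#'
#' A block set bundles the four paired spectral blocks of a fruit batch — the
#' whole `tomato` spectrum and its `skin`, `pulp` and `seed` tissues — with
#' the guarantee that all four share identical sample ids in identical order
#' and one common wavelength grid (the measurements are paired per fruit).
#'
#' @param tomato,skin,pulp,seed spectra tibbles.
#' @return a named list of the four spectra tibbles, class `"block_set"`.
#' @export
block_set <- function(tomato, skin, pulp, seed) {
  blocks <- list(tomato = tomato, skin = skin, pulp = pulp, seed = seed)
  purrr::walk(blocks, validate_spectra)
  ids <- purrr::map(blocks, "sample_id")
  if (!all(purrr::map_lgl(ids[-1], identical, ids[[1]]))) {
    abort_ts("All four blocks must share identical sample ids in identical order.",
             "pairing")
  }
  grids <- purrr::map(blocks, spectra_wavelengths)
  if (!all(purrr::map_lgl(grids[-1], ~ isTRUE(all.equal(.x, grids[[1]]))))) {
    abort_ts("All four blocks must share an identical wavelength grid.", "grid")
  }
  structure(blocks, class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  wl <- spectra_wavelengths(x$tomato)
  cat(sprintf("<block_set> %d paired fruits, %d wavelengths (%.4g-%.4g nm)\n",
              nrow(x$tomato), length(wl), min(wl), max(wl)))
  invisible(x)
}

#' Align paired blocks onto common samples and a common grid
#'
#' Restricts the four blocks to the intersection of their sample ids (ordered
#' as in the tomato block) and interpolates every block linearly onto the
#' tomato wavelength grid where grids differ. No extrapolation: the common
#' grid is limited to wavelengths covered by all blocks.
#'
#' @param blocks a named list with elements `tomato`, `skin`, `pulp`, `seed`
#'   (a `block_set` or any list of compatible spectra tibbles).
#' @return a validated [block_set()].
#' @export
align_blocks <- function(blocks) {
  blocks <- blocks[tissue_levels]
  if (any(purrr::map_lgl(blocks, is.null))) {
    abort_ts("`blocks` needs elements tomato, skin, pulp and seed.", "pairing")
  }
  purrr::walk(blocks, validate_spectra)
  ids <- Reduce(intersect, purrr::map(blocks, "sample_id"))
  if (length(ids) == 0) {
    abort_ts("The blocks share no common sample id.", "pairing")
  }
  ids <- blocks$tomato$sample_id[blocks$tomato$sample_id %in% ids]
  target <- spectra_wavelengths(blocks$tomato)
  lo <- max(purrr::map_dbl(blocks, ~ min(spectra_wavelengths(.x))))
  hi <- min(purrr::map_dbl(blocks, ~ max(spectra_wavelengths(.x))))
  target <- target[target >= lo & target <= hi]
  if (length(target) < 2L) {
    abort_ts("The block grids do not overlap on at least 2 wavelengths.", "grid")
  }
  aligned <- purrr::map(blocks, function(b) {
    b <- b[match(ids, b$sample_id), , drop = FALSE]
    wl <- spectra_wavelengths(b)
    m <- spectra_matrix(b)
    if (isTRUE(all.equal(wl, target))) {
      out <- m
    } else {
      out <- t(apply(m, 1, function(row) approx(wl, row, xout = target)$y))
    }
    set_spectra_matrix(b, out, target)
  })
  block_set(aligned$tomato, aligned$skin, aligned$pulp, aligned$seed)
}
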