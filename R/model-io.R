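## explicit matrix <-> list encoding so JSON round trips are shape-exact
mat_enc <- function(m) {
  if (is.null(m)) return(NULL)
  m <- as.matrix(m)
  list(nrow = nrow(m), ncol = ncol(m), data = as.numeric(m))
}

mat_dec <- function(x) {
  if (is.null(x)) return(NULL)
  matrix(as.numeric(x$data), nrow = x$nrow, ncol = x$ncol)
}

pca_enc <- function(m) {
  list(mean = as.numeric(m$mean), loadings = mat_enc(m$loadings),
       singular_values = as.numeric(m$singular_values),
       scores = mat_enc(m$scores),
       explained_variance = as.numeric(m$explained_variance),
       total_variance = m$total_variance,
       wavelengths = as.numeric(m$wavelengths), sample_id = m$sample_id,
       tissue = m$tissue, n_samples = m$n_samples,
       n_components = m$n_components)
}

pca_dec <- function(x) {
  structure(list(
    mean = as.numeric(x$mean), loadings = mat_dec(x$loadings),
    singular_values = as.numeric(x$singular_values),
    scores = mat_dec(x$scores),
    explained_variance = as.numeric(x$explained_variance),
    total_variance = x$total_variance,
    wavelengths = as.numeric(x$wavelengths),
    sample_id = as.character(x$sample_id),
    tissue = x$tissue, n_samples = as.integer(x$n_samples),
    n_components = as.integer(x$n_components)
  ), class = "spec_pca")
}

#' Save and load a fitted model as JSON
#'
#' Persists a [fit_tomography()] model as a single JSON document with nested
#' numeric arrays: per-block scatter-correction references, per-tissue PCA
#' means/loadings/scores, fusion loadings, association coefficients (or
#' training scores for knn), and a configuration echo. Numbers are written at
#' full precision, so a load reproduces the model within floating-point
#' round-off of the decimal encoding.
#'
#' @param model a `tomography_model`.
#' @param path file path of the JSON document.
#' @return `write_tomography_json()` returns `path` invisibly;
#'   `read_tomography_json()` returns the restored `tomography_model`.
#' @export
write_tomography_json <- function(model, path) {
  stopifnot(inherits(model, "tomography_model"))
  ss <- model$superset
  doc <- list(
    format = "tomospec_model",
    version = 1L,
    preprocess = model$preprocess,
    msc_refs = model$msc_refs,
    superset = list(
      n_sub = ss$n_sub,
      fusion_variance_threshold = ss$fusion_variance_threshold,
      sample_id = ss$sample_id,
      T = mat_enc(ss$T),
      fusion = purrr::map(ss$fusion, function(f) {
        list(P = mat_enc(f$P), center = as.numeric(f$center),
             scale = as.numeric(f$scale), d = f$d,
             variance = as.numeric(f$variance))
      }),
      tissue_models = purrr::map(ss$tissue_models, pca_enc)
    ),
    association = list(
      mode = model$association$mode,
      b = mat_enc(model$association$b),
      c = mat_enc(model$association$c),
      k = model$association$k,
      T_train = mat_enc(model$association$T_train),
      U_train = mat_enc(model$association$U_train),
      tomato_model = pca_enc(model$association$tomato_model)
    ),
    config = model$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tomography_json
#' @export
read_tomography_json <- function(path) {
  if (!file.exists(path)) abort_ts(sprintf("File not found: '%s'.", path), "io")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "tomospec_model")) {
    abort_ts("Not a tomospec model document.", "format")
  }
  ss <- doc$superset
  superset <- structure(list(
    tissue_models = purrr::map(ss$tissue_models, pca_dec),
    fusion = purrr::map(ss$fusion, function(f) {
      list(P = mat_dec(f$P), center = as.numeric(f$center),
           scale = as.numeric(f$scale), d = as.integer(f$d),
           variance = as.numeric(f$variance))
    }),
    T = mat_dec(ss$T),
    n_sub = as.integer(ss$n_sub),
    sample_id = as.character(ss$sample_id),
    fusion_variance_threshold = ss$fusion_variance_threshold
  ), class = "superset_model")
  rownames(superset$T) <- superset$sample_id
  msc_refs <- doc$msc_refs
  if (!is.null(msc_refs)) {
    msc_refs <- purrr::map(msc_refs, function(r) {
      list(wavelengths = as.numeric(r$wavelengths),
           reference = as.numeric(r$reference))
    })
  }
  association <- structure(list(
    mode = doc$association$mode,
    b = mat_dec(doc$association$b),
    c = mat_dec(doc$association$c),
    k = as.integer(doc$association$k),
    T_train = mat_dec(doc$association$T_train),
    U_train = mat_dec(doc$association$U_train),
    tomato_model = pca_dec(doc$association$tomato_model)
  ), class = "association_map")
  structure(list(
    preprocess = doc$preprocess,
    msc_refs = msc_refs,
    superset = superset,
    association = association,
    config = doc$config
  ), class = "tomography_model")
}
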