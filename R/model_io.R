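MODEL_SCHEMA_VERSION <- 1L

#' Serialize a fitted model to JSON
#'
#' Writes every field of a [cyto_pls()] fit to a versioned JSON file with
#' full numeric precision, so a model fitted on one dataset can be stored
#' and later re-loaded to score other cohorts.
#'
#' @param model A `cyto_pls` fit.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cyto_pls"))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    class = "cyto_pls",
    ncomp = model$ncomp, rotated = model$rotated,
    y_type = model$y_type,
    case_label = model$case_label, control_label = model$control_label,
    analytes = model$analytes, sample_ids = model$sample_ids,
    groups = model$groups,
    weights = model$weights, x_loadings = model$x_loadings,
    projection = model$projection, scores = model$scores,
    y_loadings = model$y_loadings, y_mean = model$y_mean,
    rotation = model$rotation, theta = model$theta,
    y = model$y,
    scaling_center = model$scaling$center, scaling_scale = model$scaling$scale
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null",
                       matrix = "rowmajor")
  invisible(path)
}

read_model_field <- function(obj, field) {
  if (!field %in% names(obj)) stop("model file is missing field '", field, "'")
  obj[[field]]
}

#' Load a serialized model
#'
#' @param path Path written by [write_model()].
#' @return A `cyto_pls` object; scores/weights agree with the original to
#'   better than 1e-12 relative error.
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(as.integer(read_model_field(obj, "schema_version")),
                 MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version: ", obj$schema_version)
  ncomp <- as.integer(read_model_field(obj, "ncomp"))
  analytes <- as.character(read_model_field(obj, "analytes"))
  p <- length(analytes)
  lvn <- paste0("LV", seq_len(ncomp))
  as_mat <- function(field, nr, dn) {
    m <- as.matrix(read_model_field(obj, field))
    if (nrow(m) != nr) stop("model field '", field, "' has wrong shape")
    m <- matrix(as.numeric(m), nrow = nr)
    dimnames(m) <- dn
    m
  }
  sample_ids <- as.character(read_model_field(obj, "sample_ids"))
  structure(list(
    weights = as_mat("weights", p, list(analytes, lvn)),
    x_loadings = as_mat("x_loadings", p, list(analytes, lvn)),
    projection = as_mat("projection", p, list(analytes, lvn)),
    scores = as_mat("scores", length(sample_ids), list(sample_ids, lvn)),
    y_loadings = as.numeric(read_model_field(obj, "y_loadings")),
    y_mean = as.numeric(read_model_field(obj, "y_mean")),
    rotation = as_mat("rotation", ncomp, NULL),
    theta = as.numeric(read_model_field(obj, "theta")),
    scaling = list(center = stats::setNames(as.numeric(read_model_field(obj, "scaling_center")), analytes),
                   scale = stats::setNames(as.numeric(read_model_field(obj, "scaling_scale")), analytes)),
    analytes = analytes, sample_ids = sample_ids,
    y = as.numeric(read_model_field(obj, "y")),
    y_type = as.character(read_model_field(obj, "y_type")),
    groups = if (is.null(obj$groups)) NULL else as.character(obj$groups),
    case_label = if (is.null(obj$case_label)) NULL else as.character(obj$case_label),
    control_label = if (is.null(obj$control_label)) NULL else as.character(obj$control_label),
    ncomp = ncomp, rotated = isTRUE(obj$rotated)
  ), class = "cyto_pls")
}
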