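# Structured-text (JSON) serialization of fitted model objects, with a
# format/version tag, so training-fit parameters can be stored, compared
# byte-for-byte, and reloaded without any binary artifacts.

SERIAL_FORMAT <- "mhscca-model"
SERIAL_VERSION <- "1"

serializable_fields <- function(model) {
  lapply(unclass(model), function(x) {
    if (inherits(x, "penalty_pair")) unclass(x) else x
  })
}

#' Serialize a fitted model to a versioned JSON container
#'
#' Supports `scca_model`, `weighted_pca_model`, `residualizer_model` and
#' `rank_weights` objects. Numeric payloads are written at full precision.
#'
#' @param model the fitted model object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  cls <- class(model)[1L]
  supported <- c("scca_model", "weighted_pca_model", "residualizer_model",
                 "rank_weights")
  if (!cls %in% supported) {
    stop("unsupported model class: ", cls)
  }
  payload <- list(format = SERIAL_FORMAT,
                  version = SERIAL_VERSION,
                  class = cls,
                  fields = serializable_fields(model))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model serialized with [write_model_json()]
#' @param path JSON file path.
#' @return the reconstructed model object.
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (!identical(payload$format, SERIAL_FORMAT)) {
    stop("not an mhscca model container: ", path)
  }
  fields <- payload$fields
  cls <- payload$class
  if (cls == "scca_model") {
    fields$u <- as.matrix(fields$u)
    fields$v <- as.matrix(fields$v)
    if (!is.null(fields$penalties)) {
      fields$penalties <- penalty_pair(fields$penalties$c_brain,
                                       fields$penalties$c_behavior)
    }
  } else if (cls == "weighted_pca_model") {
    fields$eigenvectors <- as.matrix(fields$eigenvectors)
  } else if (cls == "residualizer_model") {
    fields$coefficients <- as.matrix(fields$coefficients)
    colnames(fields$coefficients) <- NULL
    rownames(fields$coefficients) <- fields$design_columns
  }
  structure(fields, class = cls)
}
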