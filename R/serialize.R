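## Single-file model containers. Every stage model is wrapped with a
## format tag, a container version and the feature/UBM configuration
## hash it was built against, so cross-stage mismatches are caught at
## load time rather than silently corrupting decisions.

CONTAINER_FORMAT <- "acufall-model"
CONTAINER_VERSION <- 1L

#' Save a stage model to a single-file container
#'
#' @param object A `gmm_ubm`, `ocsvm_model`, `template_set` or
#'   `fall_detector`.
#' @param path Output file path.
#' @param config_hash Optional configuration hash to stamp on the
#'   container (detectors and template sets carry their own).
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path, config_hash = NA_character_) {
  if (inherits(object, "fall_detector")) config_hash <- object$config_hash
  if (inherits(object, "template_set")) config_hash <- object$config_hash
  saveRDS(list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
               class = class(object)[1], config_hash = config_hash,
               payload = object),
          path)
  invisible(path)
}

#' Load a stage model container
#'
#' @param path Container file written by [write_model].
#' @param expect_hash Optional configuration hash; a stored hash that
#'   disagrees is a hard error.
#' @return The stored model object, with the stored hash attached as
#'   attribute `config_hash`.
#' @export
read_model <- function(path, expect_hash = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, CONTAINER_FORMAT)) {
    stop("read_model: not an acufall model container: ", path)
  }
  if (obj$version > CONTAINER_VERSION) {
    stop("read_model: container version ", obj$version, " is newer than supported")
  }
  if (!is.null(expect_hash) && !is.na(obj$config_hash) &&
      !identical(obj$config_hash, expect_hash)) {
    stop("read_model: configuration hash mismatch (model built against a ",
         "different feature/UBM configuration)")
  }
  out <- obj$payload
  attr(out, "config_hash") <- obj$config_hash
  out
}
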