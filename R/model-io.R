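#' Serialize a HAT model to JSON
#'
#' Writes a single text artifact holding the HAT name, window geometry,
#' flattened substitution matrix (row-major over the 22-symbol alphabet),
#' position weights, positive training peptides and calibrated thresholds.
#' Integer fields round-trip bit-exactly through [read_hat_model()].
#'
#' @param model A `hat_model`.
#' @param path Output path (conventionally `<hat>.model.json`).
#' @export
write_hat_model <- function(model, path) {
  stopifnot(inherits(model, "hat_model"))
  obj <- list(
    format = "hatsite-model", version = 1L,
    hat = model$hat, m = model$m, n = model$n,
    alphabet = AA_ALPHABET,
    matrix = as.integer(t(model$matrix)),
    weights = as.integer(model$weights),
    positives = model$positives,
    thresholds = as.list(model$thresholds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a serialized HAT model
#'
#' @param path Path to a JSON file written by [write_hat_model()].
#' @return A `hat_model`.
#' @export
read_hat_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hatsite-model")) {
    stop(path, " is not a hatsite model file")
  }
  if (!identical(as.character(obj$alphabet), AA_ALPHABET)) {
    stop("model file uses an unexpected residue alphabet")
  }
  mat <- matrix(as.integer(obj$matrix), nrow = 22L, byrow = TRUE,
                dimnames = list(AA_ALPHABET, AA_ALPHABET))
  get1 <- function(k) {
    v <- obj$thresholds[[k]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }
  th <- c(high = get1("high"), medium = get1("medium"), low = get1("low"))
  positives <- as.data.frame(obj$positives, stringsAsFactors = FALSE)
  positives$position <- as.integer(positives$position)
  new_hat_model(obj$hat, as.integer(obj$m), as.integer(obj$n), positives,
                matrix = mat, weights = as.integer(obj$weights),
                thresholds = th)
}

#' Read all models from a model directory
#'
#' Loads every `*.model.json` in a directory, optionally guided by a
#' `models_index.json` listing the files.
#'
#' @param dir Directory of model files.
#' @return Named list of `hat_model` objects (names are HAT names).
#' @export
read_model_dir <- function(dir) {
  index <- file.path(dir, "models_index.json")
  files <- if (file.exists(index)) {
    file.path(dir, unlist(jsonlite::read_json(index,
                                              simplifyVector = TRUE)$models))
  } else {
    list.files(dir, pattern = "\\.model\\.json$", full.names = TRUE)
  }
  if (length(files) == 0L) stop("no model files found in ", dir)
  models <- lapply(files, read_hat_model)
  stats::setNames(models, vapply(models, `[[`, character(1), "hat"))
}

#' Write a directory of models plus an index
#'
#' @param models Named or unnamed list of `hat_model` objects.
#' @param dir Output directory.
#' @export
write_model_dir <- function(models, dir) {
  models <- as_model_list(models)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(models, function(mo) {
    f <- paste0(tolower(mo$hat), ".model.json")
    write_hat_model(mo, file.path(dir, f))
    f
  }, character(1))
  jsonlite::write_json(list(models = files), file.path(dir,
                                                       "models_index.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
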