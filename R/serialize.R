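#' Serialize fitted scoring models to a JSON model file
#'
#' Writes an asset model, education scaler, income brackets or rescale
#' scheme (or a named list of them) to JSON so a fitted rubric can score
#' new cohorts identically. Numbers are written at full precision.
#'
#' @param model A `wami_asset_model`, `education_scaler`,
#'   `income_brackets`, `rescale_scheme`, or a named list of such objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_model <- function(model, path) {
  serializable <- c("wami_asset_model", "education_scaler",
                    "income_brackets", "rescale_scheme")
  pack <- function(m) {
    cls <- intersect(class(m), serializable)
    if (length(cls) != 1L) {
      stop_ses("cannot serialize object of class ",
               paste(class(m), collapse = "/"), class = "model_io_error")
    }
    c(list(.class = cls), unclass(m))
  }
  payload <- if (inherits(model, serializable)) {
    pack(model)
  } else {
    lapply(model, pack)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model file written by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return The reconstructed object (or named list of objects).
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(x) {
    cls <- x$.class
    x$.class <- NULL
    if (cls == "wami_asset_model") {
      for (f in c("column_means", "column_sds", "loadings")) {
        x[[f]] <- stats::setNames(as.numeric(x[[f]]), x$asset_names)
      }
    }
    structure(x, class = cls)
  }
  if (!is.null(raw$.class)) unpack(raw) else lapply(raw, unpack)
}
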