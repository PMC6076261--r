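# File I/O: multi-page TIFF fields with a JSON ground-truth/metadata
# sidecar, and CSV assay tables with unit-suffixed columns.

FIELD_TIFF_SCALE <- 65535

#' Write / read a field as multi-page TIFF with JSON sidecar
#'
#' One 16-bit TIFF page per channel (intensities divided by 65535); the
#' channel roles, page order and scale go into `<path>.json`, which
#' [readFieldTiff()] uses to restore the [LabeledField-class].
#'
#' @param field a [LabeledField-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeFieldTiff <- function(field, path) {
  pages <- lapply(field@channels, function(m)
    pmin(pmax(round(m) / FIELD_TIFF_SCALE, 0), 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  meta <- list(channels = names(field@channels), scale = FIELD_TIFF_SCALE,
               provenance = field@provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFieldTiff
#' @export
readFieldTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  ch <- lapply(pages, function(p) round(p * meta$scale))
  names(ch) <- meta$channels
  LabeledField(ch, provenance = if (is.null(meta$provenance) ||
                                    is.na(meta$provenance)) path
               else meta$provenance)
}

#' Write ground truth to a JSON + CSV sidecar pair
#'
#' @param truth a [FieldTruth-class].
#' @param prefix output path prefix; writes `<prefix>_truth.json` (cells)
#'   and `<prefix>_puncta.csv` (puncta).
#' @export
writeTruth <- function(truth, prefix) {
  jsonlite::write_json(list(seed = truth@seed, cells = truth@cells),
                       paste0(prefix, "_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  utils::write.csv(truth@puncta, paste0(prefix, "_puncta.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Write / read an assay table CSV
#'
#' Column names are unit-suffixed (`substrate_uM`, `rate_M_per_s`,
#' `conc_uM`, `time_h`, `conc_plasma_uM`, ...) so the units travel with
#' the file.
#'
#' @param assay a [SimulatedAssay-class] or plain data.frame.
#' @param path CSV path.
#' @export
writeAssayCsv <- function(assay, path) {
  df <- if (is(assay, "SimulatedAssay")) assayData(assay) else assay
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssayCsv
#' @param required optional character vector of columns that must exist.
#' @export
readAssayCsv <- function(path, required = NULL) {
  df <- utils::read.csv(path)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("table ", path, " lacks column(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

fitResultToList <- function(fr) {
  list(model = fr@model, estimates = as.list(fr@estimates),
       ci = if (ncol(fr@ci)) as.list(as.data.frame(fr@ci)) else NULL,
       converged = fr@converged, flags = as.list(fr@flags),
       nobs = fr@nobs)
}

#' Write a FitResult to JSON
#'
#' @param fr a [FitResult-class].
#' @param path output path.
#' @param extra named list appended to the JSON object (e.g. seed).
#' @export
writeFitJson <- function(fr, path, extra = list()) {
  jsonlite::write_json(c(fitResultToList(fr), extra), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
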