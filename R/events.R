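#' Construct an EventTable
#'
#' The atomic cytometry object: a cells x markers matrix of raw (nonnegative)
#' intensities plus sample metadata. The arcsinh-transformed matrix is
#' attached by [arcsinh_transform()] and kept alongside the raw values.
#' Event (row) indices are stable across all downstream operations; gating
#' masks and signature-selection masks index into this row space.
#'
#' @param intensities numeric matrix, cells x markers, raw scale, >= 0.
#' @param markers character vector of marker names (defaults to colnames).
#' @param sample_id,subject_id,visit_id,condition,batch_id metadata scalars;
#'   `condition` is "T0" or "T6".
#' @param is_anchor logical; TRUE for the batch anchor pseudo-subject.
#' @return an object of class `event_table`.
#' @export
event_table <- function(intensities, markers = colnames(intensities),
                        sample_id = NA_character_, subject_id = NA_character_,
                        visit_id = NA_integer_, condition = NA_character_,
                        batch_id = NA_character_, is_anchor = FALSE) {
  intensities <- as.matrix(intensities)
  if (is.null(markers)) stop("marker names are required")
  if (nrow(intensities) > 0 && any(intensities < 0, na.rm = TRUE)) {
    stop("raw intensities must be nonnegative")
  }
  colnames(intensities) <- markers
  structure(
    list(sample_id = sample_id, subject_id = subject_id, visit_id = visit_id,
         condition = condition, batch_id = batch_id, is_anchor = is_anchor,
         markers = markers, intensities = intensities, transformed = NULL,
         cofactor = NULL),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s: %d cells x %d markers (%s%s)\n",
              x$sample_id, nrow(x$intensities), length(x$markers),
              ifelse(is.null(x$transformed), "raw", "raw+arcsinh"),
              if (isTRUE(x$is_anchor)) ", anchor" else ""))
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$intensities)

#' Read cytometry events from disk
#'
#' Reads a delimited cells x markers table (CSV/TSV, optionally gzipped,
#' header row = marker names) into an [event_table()]. FCS containers are not
#' supported in this build (no FCS parser available); requesting
#' `format = "fcs"` raises an informative error.
#'
#' @param path file path.
#' @param format "csv", "tsv" or "fcs".
#' @param panel_map optional named character vector mapping file column names
#'   (short names) to panel marker names (long names).
#' @param required_markers optional character vector; an error naming the
#'   missing markers is raised if any are absent after mapping.
#' @param ... metadata fields passed to [event_table()].
#' @return an `event_table`.
#' @export
read_events <- function(path, format = c("csv", "tsv", "fcs"),
                        panel_map = NULL, required_markers = NULL, ...) {
  format <- match.arg(format)
  if (format == "fcs") {
    stop("FCS reading is not available in this build; export events as ",
         "CSV/TSV (cells x markers with a marker header) instead")
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(panel_map)) {
    hit <- colnames(m) %in% names(panel_map)
    colnames(m)[hit] <- unname(panel_map[colnames(m)[hit]])
  }
  if (!is.null(required_markers)) {
    stop_missing(setdiff(required_markers, colnames(m)), "markers")
  }
  event_table(m, markers = colnames(m), ...)
}

#' Write events to a delimited file
#'
#' Writes the raw intensity matrix with marker header; `.gz` suffix gives a
#' gzipped file. Inverse of [read_events()] up to float formatting.
#'
#' @param events an `event_table`.
#' @param path destination; extension `.csv[.gz]` or `.tsv[.gz]`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(as.data.frame(events$intensities), con, row.names = FALSE)
  invisible(path)
}

#' Arcsinh transform of raw intensities
#'
#' The standard cytometry variance-stabilizing transform
#' `asinh(x / cofactor)` with cofactor 5. The raw matrix is retained; the
#' transformed matrix is stored in `$transformed`.
#'
#' @param events an `event_table`.
#' @param cofactor positive scale divisor (default 5).
#' @return the `event_table` with `$transformed` and `$cofactor` set.
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  stopifnot(inherits(events, "event_table"), cofactor > 0)
  events$transformed <- asinh(events$intensities / cofactor)
  events$cofactor <- cofactor
  events
}

#' Median marker intensity (MMI) within a population
#'
#' Median of one marker over the member cells of a gated population, on the
#' raw or arcsinh scale. Even-sized populations use the midpoint convention.
#'
#' @param events an `event_table` (transformed if `scale = "arcsinh"`).
#' @param population logical membership mask over cells (or NULL for all).
#' @param marker marker name.
#' @param scale "raw" or "arcsinh".
#' @return the median, or `NA_real_` for an empty population.
#' @export
marker_mmi <- function(events, population = NULL, marker,
                       scale = c("raw", "arcsinh")) {
  scale <- match.arg(scale)
  if (!marker %in% events$markers) stop("unknown marker: ", marker)
  mat <- if (scale == "raw") events$intensities else {
    if (is.null(events$transformed)) stop("events are not arcsinh transformed")
    events$transformed
  }
  v <- mat[, marker]
  if (!is.null(population)) v <- v[population]
  if (length(v) == 0) return(NA_real_)
  stats::median(v)
}
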