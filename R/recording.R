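#' Construct a multi-sensor pressure recording
#'
#' A `sensor_recording` holds synchronized pressure readings from a set of
#' labeled sensors sampled at a fixed rate, plus the device reading range
#' (pressures outside it are physically impossible for the device; values
#' beyond it are clamped by [clean_recording()] before analysis).
#'
#' @param readings numeric matrix, one row per time sample, one column per
#'   sensor, values in kPa. Column names, if present, are used as sensor
#'   labels unless `sensor_labels` is given.
#' @param sensor_labels character vector of unique sensor labels, one per
#'   column of `readings`.
#' @param sampling_rate sampling frequency in Hz (positive scalar).
#' @param reading_range closed interval `c(lo, hi)` in kPa with `lo < hi`;
#'   the device saturation range. Default 0--64 kPa.
#' @return an object of class `sensor_recording`: a list with elements
#'   `readings` (matrix with sensor labels as column names),
#'   `sensor_labels`, `sampling_rate`, `reading_range`.
#' @export
sensor_recording <- function(readings, sensor_labels = colnames(readings),
                             sampling_rate = 100, reading_range = c(0, 64)) {
  readings <- as.matrix(readings)
  storage.mode(readings) <- "double"
  if (is.null(sensor_labels)) {
    sensor_labels <- paste0("s", seq_len(ncol(readings)))
  }
  sensor_labels <- as.character(sensor_labels)
  if (length(sensor_labels) != ncol(readings)) {
    stop_data("number of sensor labels (", length(sensor_labels),
              ") does not match number of columns (", ncol(readings), ")")
  }
  if (anyDuplicated(sensor_labels)) {
    dup <- sensor_labels[duplicated(sensor_labels)][1]
    stop_data("duplicate sensor label: '", dup, "'")
  }
  if (!all(is.finite(readings))) {
    bad <- which(!is.finite(readings), arr.ind = TRUE)[1, ]
    stop_data("non-finite reading at sample ", bad[1], ", sensor '",
              sensor_labels[bad[2]], "'")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop_config("sampling_rate must be a positive finite scalar")
  }
  if (length(reading_range) != 2 || !all(is.finite(reading_range)) ||
      reading_range[1] >= reading_range[2]) {
    stop_config("reading_range must be c(lo, hi) with lo < hi")
  }
  colnames(readings) <- sensor_labels
  structure(
    list(readings = readings, sensor_labels = sensor_labels,
         sampling_rate = as.numeric(sampling_rate),
         reading_range = as.numeric(reading_range)),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %d sensors x %d samples @ %g Hz, range [%g, %g] kPa\n",
    ncol(x$readings), nrow(x$readings), x$sampling_rate,
    x$reading_range[1], x$reading_range[2]))
  cat("  sensors:", paste(x$sensor_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sensor_recording <- function(x) dim(x$readings)

#' Read a sensor recording from CSV
#'
#' The CSV must have a header row of sensor labels and one row per time
#' sample; every cell must be numeric. An optional sidecar JSON file
#' `<path>.json` (or the file named by `sidecar`) may supply
#' `sampling_rate` and `reading_range`; defaults are 100 Hz and
#' \[0, 64\] kPa.
#'
#' @param path path to the CSV file.
#' @param unit_factor multiplicative unit-conversion factor applied to
#'   every value (e.g. `0.001` for Pa to kPa). Default 1.
#' @param sampling_rate,reading_range override the sidecar/defaults.
#' @param sidecar path to the sidecar JSON; default `<path>.json`.
#' @return a [sensor_recording()].
#' @export
read_recording <- function(path, unit_factor = 1, sampling_rate = NULL,
                           reading_range = NULL, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop_data("CSV must have a header and at least one row: ", path)
  labels <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  if (anyDuplicated(labels)) {
    stop_data("duplicate sensor label in header: '",
              labels[duplicated(labels)][1], "'")
  }
  p <- length(labels)
  body <- lines[-1]
  cells <- strsplit(body, ",", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != p)) {
    r <- which(nc != p)[1]
    stop_data("row ", r, " has ", nc[r], " cells, expected ", p)
  }
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1] - 1L
    stop_data("non-numeric cell at row ", bad %/% p + 1L,
              ", column '", labels[bad %% p + 1L], "'")
  }
  readings <- matrix(vals, ncol = p, byrow = TRUE) * unit_factor

  meta <- list()
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
  }
  if (is.null(sampling_rate)) sampling_rate <- meta$sampling_rate %||% 100
  if (is.null(reading_range)) reading_range <- meta$reading_range %||% c(0, 64)
  sensor_recording(readings, labels, sampling_rate, reading_range)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sensor recording to CSV (with sidecar JSON)
#'
#' Values are printed at full precision (17 significant digits) so that
#' [read_recording()] round-trips exactly.
#'
#' @param rec a [sensor_recording()].
#' @param path output CSV path; the sidecar with `sampling_rate` and
#'   `reading_range` is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  rows <- apply(rec$readings, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(c(paste(rec$sensor_labels, collapse = ","), rows), path)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate, reading_range = rec$reading_range),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Clamp readings into the device reading range
#'
#' Out-of-range values are clamped rather than rejected: socket pressure
#' sensors visibly saturate at the ceiling of their configured range, so
#' ceiling values are meaningful data, not artifacts. Idempotent.
#'
#' @param rec a [sensor_recording()].
#' @return the recording with every value in `[lo, hi]`.
#' @export
clean_recording <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  rec$readings[] <- pmin(pmax(rec$readings, rec$reading_range[1]),
                         rec$reading_range[2])
  rec
}

#' Slice a recording into consecutive fixed-length frames
#'
#' Frames are consecutive, non-overlapping, equal-length windows starting
#' at sample 1; a trailing remainder shorter than `frame_length` is
#' discarded (never padded). Each frame is the clustering unit: one column
#' per sensor is one input series.
#'
#' @param rec a [sensor_recording()].
#' @param frame_length frame length in samples (>= 2).
#' @return list of `pressure_frame` objects, each a list with `data`
#'   (matrix `frame_length` x sensors), `start_index` (0-based sample
#'   offset), `sensor_labels`.
#' @export
slice_frames <- function(rec, frame_length = 500) {
  stopifnot(inherits(rec, "sensor_recording"))
  frame_length <- as.integer(frame_length)
  if (frame_length < 2) stop_config("frame_length must be >= 2")
  n <- nrow(rec$readings)
  n_frames <- n %/% frame_length
  if (n_frames < 1) {
    stop_data("no complete frame: recording has ", n,
              " samples, frame_length is ", frame_length)
  }
  lapply(seq_len(n_frames) - 1L, function(i) {
    idx <- (i * frame_length + 1L):((i + 1L) * frame_length)
    structure(
      list(data = rec$readings[idx, , drop = FALSE],
           start_index = i * frame_length,
           sensor_labels = rec$sensor_labels),
      class = "pressure_frame")
  })
}

#' @export
print.pressure_frame <- function(x, ...) {
  cat(sprintf("<pressure_frame> %d samples x %d sensors, start offset %d\n",
              nrow(x$data), ncol(x$data), x$start_index))
  invisible(x)
}
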