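#' Construct a labeled acceleration recording
#'
#' A recording is one continuous 3-axis wrist-acceleration bout for a
#' single (subject, set, motion) combination, nominally 10 s at 100 Hz
#' in the study protocol (duration is not enforced on arbitrary input).
#'
#' @param samples data.frame with numeric columns `t` (seconds, strictly
#'   increasing), `x`, `y`, `z` (acceleration in G).
#' @param subject_id character scalar.
#' @param set_index integer in 1..5 in the study protocol (any positive
#'   integer accepted).
#' @param label motion label code (see [motion_labels()]).
#' @param sample_rate_hz nominal sampling rate, positive (default 100).
#' @return An object of class `"har_recording"`.
#' @export
recording <- function(samples, subject_id, set_index, label,
                      sample_rate_hz = 100) {
  stopifnot(is.data.frame(samples))
  need <- c("t", "x", "y", "z")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("samples is missing column(s): ", paste(miss, collapse = ", "))
  }
  samples <- samples[need]
  if (nrow(samples) > 0) {
    if (any(!vapply(samples, is.numeric, logical(1)))) {
      stop("all sample columns must be numeric")
    }
    if (anyNA(samples)) stop("samples contain missing values")
    dt <- diff(samples$t)
    if (any(dt <= 0)) {
      stop("timestamps must be strictly increasing (first violation at row ",
           which(dt <= 0)[1] + 1L, ")")
    }
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive")
  }
  structure(
    list(samples = samples,
         subject_id = as.character(subject_id),
         set_index = as.integer(set_index),
         label = as.character(as_motion_label(label)),
         sample_rate_hz = sample_rate_hz),
    class = "har_recording")
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> subject %s, set %d, motion %s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$set_index, x$label, nrow(x$samples),
              x$sample_rate_hz, nrow(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Read a sensor log into a recording
#'
#' Sensor logs are plain CSV with header `t,x,y,z`: time in seconds and
#' the three acceleration axes in G. Metadata (subject, set, label,
#' rate) comes from the accompanying manifest entry.
#'
#' @param path path to the CSV file.
#' @param manifest_entry one row of a manifest (see [read_manifest()]),
#'   or a list with `subject_id`, `set_index`, `label`,
#'   `sample_rate_hz`.
#' @return A [recording()].
#' @export
read_recording <- function(path, manifest_entry) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  need <- c("t", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  num <- suppressWarnings(lapply(df[need], as.numeric))
  for (col in need) {
    bad <- which(is.na(num[[col]]) & !(df[[col]] %in% c("NA", "")))
    if (length(bad) > 0) {
      stop("parse error in ", path, ": non-numeric value in column '",
           col, "' at data line ", bad[1])
    }
    if (anyNA(num[[col]])) {
      stop("parse error in ", path, ": missing value in column '", col,
           "' at data line ", which(is.na(num[[col]]))[1])
    }
  }
  dt <- diff(num$t)
  if (any(dt <= 0)) {
    stop("parse error in ", path,
         ": timestamps not strictly increasing at data line ",
         which(dt <= 0)[1] + 1L)
  }
  recording(as.data.frame(num),
            subject_id = manifest_entry$subject_id,
            set_index = manifest_entry$set_index,
            label = manifest_entry$label,
            sample_rate_hz = manifest_entry$sample_rate_hz)
}

#' Write a recording to a sensor-log CSV
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param digits significant digits used for serialization (default 10;
#'   round-trip error is below 1e-9 G for signals of order 1 G).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "har_recording"))
  df <- rec$samples
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  out <- data.frame(t = fmt(df$t), x = fmt(df$x), y = fmt(df$y),
                    z = fmt(df$z), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dataset manifests
#'
#' A manifest maps sensor-log files to their metadata: one row per
#' recording with columns `file_path`, `subject_id`, `set_index`,
#' `label`, `sample_rate_hz`. File paths are interpreted relative to
#' the manifest's own directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with one row per recording and an attribute
#'   `"manifest_dir"` holding the directory for resolving paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file_path", "subject_id", "set_index", "label",
            "sample_rate_hz")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(m$file_path)) {
    stop("manifest file paths are not unique")
  }
  as_motion_label(m$label)  # validates
  m$set_index <- as.integer(m$set_index)
  attr(m, "manifest_dir") <- dirname(normalizePath(path))
  m
}

#' @rdname read_manifest
#' @param manifest data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("file_path", "subject_id", "set_index", "label",
            "sample_rate_hz")
  utils::write.csv(manifest[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load every recording listed in a manifest
#'
#' @param manifest data.frame from [read_manifest()].
#' @return list of [recording()] objects, in manifest order.
#' @export
load_recordings <- function(manifest) {
  dir <- attr(manifest, "manifest_dir")
  lapply(seq_len(nrow(manifest)), function(i) {
    entry <- manifest[i, ]
    p <- entry$file_path
    if (!is.null(dir) && !file.exists(p)) p <- file.path(dir, p)
    read_recording(p, entry)
  })
}
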