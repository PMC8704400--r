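#' Windowing configuration
#'
#' The classifier consumes fixed-length windows cut from each recording
#' by sample index. The defaults — 64 samples with a stride of 64, i.e.
#' non-overlapping 0.64 s windows at 100 Hz — are the protocol values.
#'
#' @param window_size window length in samples (>= 1).
#' @param stride offset between consecutive window starts (>= 1).
#' @return list of class `"har_windowing"`.
#' @export
windowing_config <- function(window_size = 64, stride = 64) {
  window_size <- as.integer(window_size)
  stride <- as.integer(stride)
  stopifnot(window_size >= 1L, stride >= 1L)
  structure(list(window_size = window_size, stride = stride),
            class = "har_windowing")
}

#' Segment a recording into fixed windows
#'
#' Cuts `floor((N - window_size)/stride) + 1` windows from the `N`
#' samples of one recording. Windows never span recordings, so they
#' never span a label change. A trailing partial window is dropped, not
#' padded. A recording shorter than the window size yields an empty
#' window set with a warning.
#'
#' @param rec a [recording()].
#' @param config a [windowing_config()].
#' @return A `"har_window_set"`: list with `values` (array n x W x 3,
#'   window x time x axis, in G), `label`, `subject_id`, `set_index`
#'   (parallel vectors), `window_size`, `sample_rate_hz`.
#' @export
segment_recording <- function(rec, config = windowing_config()) {
  stopifnot(inherits(rec, "har_recording"),
            inherits(config, "har_windowing"))
  w <- config$window_size
  s <- config$stride
  n <- nrow(rec$samples)
  if (n < w) {
    warning(sprintf(
      "recording (%s set %d %s) has %d samples, shorter than window size %d; no windows",
      rec$subject_id, rec$set_index, rec$label, n, w))
    return(empty_window_set(w, rec$sample_rate_hz))
  }
  starts <- seq.int(0L, n - w, by = s)
  mat <- as.matrix(rec$samples[c("x", "y", "z")])
  vals <- array(NA_real_, dim = c(length(starts), w, 3L),
                dimnames = list(NULL, NULL, c("x", "y", "z")))
  for (i in seq_along(starts)) {
    vals[i, , ] <- mat[(starts[i] + 1L):(starts[i] + w), ]
  }
  new_window_set(vals,
                 label = rep(rec$label, length(starts)),
                 subject_id = rep(rec$subject_id, length(starts)),
                 set_index = rep(rec$set_index, length(starts)),
                 sample_rate_hz = rec$sample_rate_hz)
}

new_window_set <- function(values, label, subject_id, set_index,
                           sample_rate_hz) {
  structure(list(values = values,
                 label = as.character(label),
                 subject_id = as.character(subject_id),
                 set_index = as.integer(set_index),
                 window_size = dim(values)[2],
                 sample_rate_hz = sample_rate_hz),
            class = "har_window_set")
}

empty_window_set <- function(window_size, sample_rate_hz = 100) {
  new_window_set(array(numeric(0), dim = c(0L, window_size, 3L)),
                 character(0), character(0), integer(0), sample_rate_hz)
}

#' Number of windows in a window set
#' @param ws a `"har_window_set"`.
#' @export
n_windows <- function(ws) dim(ws$values)[1]

#' @export
print.har_window_set <- function(x, ...) {
  cat(sprintf("<har_window_set> %d windows of %d samples x 3 axes (%d subject(s))\n",
              n_windows(x), x$window_size, length(unique(x$subject_id))))
  if (n_windows(x) > 0) {
    print(table(factor(x$label, levels = motion_labels())))
  }
  invisible(x)
}

#' Combine window sets
#'
#' @param ... `"har_window_set"` objects with equal window sizes.
#' @return One combined `"har_window_set"`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "har_window_set")) {
    sets <- sets[[1]]
  }
  sets <- Filter(function(s) n_windows(s) > 0, sets)
  if (length(sets) == 0) return(empty_window_set(64L))
  w <- unique(vapply(sets, function(s) s$window_size, integer(1)))
  stopifnot(length(w) == 1L)
  ntot <- sum(vapply(sets, n_windows, integer(1)))
  vals <- array(NA_real_, dim = c(ntot, w, 3L))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    vals[(at + 1L):(at + k), , ] <- s$values
    at <- at + k
  }
  new_window_set(vals,
                 label = unlist(lapply(sets, `[[`, "label")),
                 subject_id = unlist(lapply(sets, `[[`, "subject_id")),
                 set_index = unlist(lapply(sets, `[[`, "set_index")),
                 sample_rate_hz = sets[[1]]$sample_rate_hz)
}

#' Subset a window set
#' @param ws a `"har_window_set"`.
#' @param idx logical or integer index over windows.
#' @export
subset_windows <- function(ws, idx) {
  new_window_set(ws$values[idx, , , drop = FALSE],
                 ws$label[idx], ws$subject_id[idx], ws$set_index[idx],
                 ws$sample_rate_hz)
}

#' Flatten one window to the single-channel model layout
#'
#' The network input is a single-channel sequence of length
#' `3 * window_size` (192 for the default 64-sample window): the model
#' input layout that reproduces the published architecture shapes. The
#' layout is axis-major — all x samples, then all y, then all z.
#'
#' @param window numeric `window_size x 3` matrix (time x axis).
#' @return numeric vector of length `3 * window_size`.
#' @export
flatten_window <- function(window) {
  stopifnot(is.matrix(window) || (is.array(window) && length(dim(window)) == 2),
            ncol(window) == 3, !anyNA(window))
  c(window[, 1], window[, 2], window[, 3])
}

#' Recover the time-by-axis window from its flattened layout
#' @param flat numeric vector of length `3 * window_size`.
#' @return `window_size x 3` matrix.
#' @export
unflatten_window <- function(flat) {
  stopifnot(length(flat) %% 3 == 0)
  matrix(flat, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

#' Convert a window set to a model input tensor
#'
#' @param ws a `"har_window_set"`.
#' @param layout `"flat192"` (default): one channel of length
#'   `3 * window_size`, axis-major; or `"multichannel"`: length
#'   `window_size` with 3 channels. The flat layout is the one that
#'   reproduces the published architecture shapes.
#' @return array of dim (length, channels, n windows).
#' @export
windows_to_tensor <- function(ws, layout = c("flat192", "multichannel")) {
  layout <- match.arg(layout)
  n <- n_windows(ws)
  w <- ws$window_size
  if (layout == "flat192") {
    x <- array(NA_real_, dim = c(3L * w, 1L, n))
    for (i in seq_len(n)) x[, 1L, i] <- flatten_window(ws$values[i, , ])
  } else {
    x <- array(NA_real_, dim = c(w, 3L, n))
    for (i in seq_len(n)) x[, , i] <- ws$values[i, , ]
  }
  x
}
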