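# Hand-crafted time/frequency window descriptors: the classic HAR
# feature inventory used by the random-forest baseline. 175 features
# per window: 55 time-domain + 120 frequency-domain. The inventory and
# every convention (population moments, excess kurtosis, type-7
# quantiles, mean-removed zero crossings, non-adjacent second spectral
# maximum, degenerate statistics imputed as 0) are frozen by tests.

#' Frequency band specifications
#'
#' The spectral features are computed in four regions: the full
#' one-sided spectrum up to Nyquist ("all") and three fixed bands —
#' low 0-4.2 Hz, mid 4.2-8.4 Hz, high 8.4-12.6 Hz. Bands are
#' closed-left/open-right, so they are disjoint; the DC bin is always
#' excluded.
#'
#' @param rate_hz sampling rate, used for the Nyquist limit.
#' @return named list of bands, each `list(name, lo_hz, hi_hz)`.
#' @export
band_specs <- function(rate_hz = 100) {
  list(all = list(name = "all", lo_hz = 0, hi_hz = rate_hz / 2 + 1e-9),
       low = list(name = "low", lo_hz = 0, hi_hz = 4.2),
       mid = list(name = "mid", lo_hz = 4.2, hi_hz = 8.4),
       high = list(name = "high", lo_hz = 8.4, hi_hz = 12.6))
}

# population central moments; skewness and excess kurtosis imputed 0
# on (near-)constant input so features are always defined
.skewness <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 < 1e-12) return(0)
  mean((v - mean(v))^3) / m2^1.5
}
.kurtosis_excess <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 < 1e-12) return(0)
  mean((v - mean(v))^4) / m2^2 - 3
}
# sign changes of the mean-removed signal over N-1 adjacent pairs;
# mean removal keeps the gravity offset from zeroing the rate
.zcr <- function(v) {
  s <- v - mean(v)
  sum(s[-length(s)] * s[-1] < 0) / (length(s) - 1)
}
.safe_cor <- function(a, b) {
  if (length(a) < 2 || stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    return(0)
  }
  stats::cor(a, b)
}

.axis_time_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(v), absmean = mean(abs(v)), sd = stats::sd(v),
    abssd = stats::sd(abs(v)), min = min(v), max = max(v),
    rms = sqrt(mean(v^2)), q1 = q[1], median = q[2], q3 = q[3],
    iqr = q[3] - q[1], first = v[1], last = v[length(v)],
    skewness = .skewness(v), kurtosis = .kurtosis_excess(v),
    zcr = .zcr(v))
}

#' Time-domain features of one window
#'
#' Per axis: mean, mean of absolute values, standard deviation (sample,
#' n-1), standard deviation of absolute values, min, max, RMS,
#' quartiles (type-7 linear interpolation), interquartile range, first
#' and last value, skewness and excess kurtosis (population moments,
#' imputed 0 for variance below 1e-12), and zero-crossing rate of the
#' mean-removed signal over n-1 pairs (16 x 3). Per axis pair:
#' correlation and correlation of absolute values (3 + 3). Per frame:
#' intensity, the mean Euclidean norm of the 3-axis vector (1).
#' Total 55.
#'
#' @param window numeric `window_size x 3` matrix (time x axis, in G).
#' @return named numeric vector of length 55.
#' @export
time_features <- function(window) {
  stopifnot(ncol(window) == 3, nrow(window) >= 2, !anyNA(window))
  ax <- c("x", "y", "z")
  out <- numeric(0)
  for (a in 1:3) {
    st <- .axis_time_stats(window[, a])
    names(st) <- paste0("t.", ax[a], ".", names(st))
    out <- c(out, st)
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pn <- c("xy", "xz", "yz")
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    out[paste0("t.", pn[i], ".cor")] <-
      .safe_cor(window[, p[1]], window[, p[2]])
  }
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    out[paste0("t.", pn[i], ".abscor")] <-
      .safe_cor(abs(window[, p[1]]), abs(window[, p[2]]))
  }
  out["t.frame.intensity"] <- mean(sqrt(rowSums(window^2)))
  out
}

.band_bins <- function(freqs, band) {
  which(freqs >= band$lo_hz & freqs < band$hi_hz)
}

.axis_band_stats <- function(mag, freqs, bins) {
  if (length(bins) == 0) {
    return(c(max = 0, fmax = 0, max2 = 0, fmax2 = 0, sd = 0,
             q1 = 0, median = 0, q3 = 0, iqr = 0))
  }
  m <- mag[bins]
  f <- freqs[bins]
  i1 <- which.max(m)
  # second maximum: largest in-band bin not adjacent to the argmax bin
  # (adjacency in global bin index), so spectral leakage of the main
  # peak is not reported twice
  elig <- which(abs(bins - bins[i1]) > 1)
  if (length(elig) == 0) {
    max2 <- 0; fmax2 <- 0
  } else {
    i2 <- elig[which.max(m[elig])]
    max2 <- m[i2]; fmax2 <- f[i2]
  }
  q <- stats::quantile(m, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(max = m[i1], fmax = f[i1], max2 = max2, fmax2 = fmax2,
    sd = if (length(m) > 1) stats::sd(m) else 0,
    q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1])
}

#' Frequency-domain features of one window
#'
#' Each axis is Fourier transformed; features are computed on the
#' one-sided magnitude spectrum with the DC bin excluded, within each
#' band of [band_specs()]. Per axis per band: maximum magnitude and its
#' frequency, second maximum (largest bin not adjacent to the argmax
#' bin) and its frequency, standard deviation, quartiles and IQR of the
#' in-band magnitudes (9 x 3 axes x 4 bands = 108). Per axis pair per
#' band: correlation of in-band magnitudes (3 x 4 = 12). Total 120.
#' A band containing no FFT bin yields all-zero features with a
#' warning.
#'
#' @param window numeric `window_size x 3` matrix.
#' @param rate_hz sampling rate in Hz.
#' @param bands band list from [band_specs()].
#' @return named numeric vector of length 120.
#' @export
frequency_features <- function(window, rate_hz = 100,
                               bands = band_specs(rate_hz)) {
  stopifnot(ncol(window) == 3, !anyNA(window))
  n <- nrow(window)
  kmax <- n %/% 2
  freqs <- (1:kmax) * rate_hz / n
  mags <- lapply(1:3, function(a) {
    Mod(stats::fft(window[, a]))[2:(kmax + 1)]
  })
  ax <- c("x", "y", "z")
  pn <- c("xy", "xz", "yz")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- numeric(0)
  for (b in bands) {
    bins <- .band_bins(freqs, b)
    if (length(bins) == 0) {
      warning("band '", b$name, "' contains no FFT bin; features set to 0")
    }
    for (a in 1:3) {
      st <- .axis_band_stats(mags[[a]], freqs, bins)
      names(st) <- paste0("f.", b$name, ".", ax[a], ".", names(st))
      out <- c(out, st)
    }
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      val <- if (length(bins) == 0) 0 else
        .safe_cor(mags[[p[1]]][bins], mags[[p[2]]][bins])
      out[paste0("f.", b$name, ".", pn[i], ".cor")] <- val
    }
  }
  out
}

#' Extract the full feature vector of a window
#'
#' Concatenates [time_features()] (55) and [frequency_features()]
#' (120): 175 named values, in an order that is identical for every
#' window.
#'
#' @param window numeric `window_size x 3` matrix.
#' @param rate_hz sampling rate in Hz.
#' @return named numeric vector of length 175.
#' @export
extract_features <- function(window, rate_hz = 100) {
  c(time_features(window), frequency_features(window, rate_hz))
}

#' Names of the 175 window features
#' @param window_size,rate_hz window geometry used to realize names.
#' @return character vector of length 175.
#' @export
feature_names <- function(window_size = 64, rate_hz = 100) {
  names(extract_features(matrix(stats::rnorm(window_size * 3),
                                ncol = 3), rate_hz))
}

#' Feature table of a whole window set
#'
#' @param ws a `"har_window_set"`.
#' @return data.frame: `subject_id`, `set_index`, `label`, then the 175
#'   feature columns.
#' @export
featurize_windows <- function(ws) {
  stopifnot(inherits(ws, "har_window_set"))
  n <- n_windows(ws)
  feat <- t(vapply(seq_len(n), function(i) {
    extract_features(ws$values[i, , ], ws$sample_rate_hz)
  }, numeric(175)))
  cbind(data.frame(subject_id = ws$subject_id,
                   set_index = ws$set_index,
                   label = ws$label, stringsAsFactors = FALSE),
        as.data.frame(feat))
}
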