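# Straight-from-definition oracles, independent of the package's
# implementation paths: O(N^2) direct-summation DFT, moment formulas,
# interpolated quantiles, and a double-precision R re-implementation of
# the CNN forward pass. Used only to cross-check.

oracle_dft_mag <- function(v) {
  n <- length(v)
  k <- 1:(n %/% 2)                      # one-sided, DC excluded
  vapply(k, function(kk) {
    re <- sum(v * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(v * sin(-2 * pi * kk * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

oracle_quantile <- function(v, p) {
  # type-7 linear interpolation written out from its definition
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_sd <- function(v) sqrt(sum((v - sum(v) / length(v))^2) / (length(v) - 1))

oracle_cor <- function(a, b) {
  if (oracle_sd(a) < 1e-12 || oracle_sd(b) < 1e-12) return(0)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

oracle_time_features <- function(w) {
  out <- c()
  for (a in 1:3) {
    v <- w[, a]
    n <- length(v)
    m2 <- sum((v - mean(v))^2) / n
    m3 <- sum((v - mean(v))^3) / n
    m4 <- sum((v - mean(v))^4) / n
    s <- v - mean(v)
    out <- c(out,
      mean(v), mean(abs(v)), oracle_sd(v), oracle_sd(abs(v)),
      min(v), max(v), sqrt(sum(v^2) / n),
      oracle_quantile(v, 0.25), oracle_quantile(v, 0.5),
      oracle_quantile(v, 0.75),
      oracle_quantile(v, 0.75) - oracle_quantile(v, 0.25),
      v[1], v[n],
      if (m2 < 1e-12) 0 else m3 / m2^1.5,
      if (m2 < 1e-12) 0 else m4 / m2^2 - 3,
      sum(s[-n] * s[-1] < 0) / (n - 1))
  }
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    out <- c(out, oracle_cor(w[, p[1]], w[, p[2]]))
  }
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    out <- c(out, oracle_cor(abs(w[, p[1]]), abs(w[, p[2]])))
  }
  c(out, mean(sqrt(w[, 1]^2 + w[, 2]^2 + w[, 3]^2)))
}

oracle_band_stats <- function(mag, freqs, lo, hi) {
  bins <- which(freqs >= lo & freqs < hi)
  if (length(bins) == 0) return(rep(0, 9))
  m <- mag[bins]; f <- freqs[bins]
  i1 <- which.max(m)
  elig <- which(abs(bins - bins[i1]) > 1)
  if (length(elig) == 0) {
    mx2 <- 0; fx2 <- 0
  } else {
    i2 <- elig[which.max(m[elig])]
    mx2 <- m[i2]; fx2 <- f[i2]
  }
  c(m[i1], f[i1], mx2, fx2,
    if (length(m) > 1) oracle_sd(m) else 0,
    oracle_quantile(m, 0.25), oracle_quantile(m, 0.5),
    oracle_quantile(m, 0.75),
    oracle_quantile(m, 0.75) - oracle_quantile(m, 0.25))
}

oracle_frequency_features <- function(w, rate) {
  n <- nrow(w)
  freqs <- (1:(n %/% 2)) * rate / n
  mags <- lapply(1:3, function(a) oracle_dft_mag(w[, a]))
  bands <- list(c(0, rate / 2 + 1e-9), c(0, 4.2), c(4.2, 8.4),
                c(8.4, 12.6))
  out <- c()
  for (b in bands) {
    for (a in 1:3) out <- c(out, oracle_band_stats(mags[[a]], freqs,
                                                   b[1], b[2]))
    bins <- which(freqs >= b[1] & freqs < b[2])
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      out <- c(out, if (length(bins) == 0) 0 else
        oracle_cor(mags[[p[1]]][bins], mags[[p[2]]][bins]))
    }
  }
  out
}

oracle_all_features <- function(w, rate = 100) {
  c(oracle_time_features(w), oracle_frequency_features(w, rate))
}

# double-precision forward pass over an engine layer list
oracle_forward <- function(layers, x) {
  # x: length x channels matrix for ONE sample; returns softmax probs
  A <- t(x)  # channels x length
  for (l in layers) {
    if (l$kind == "conv") {
      k <- l$kernel; pad <- (k - 1) / 2
      Cin <- nrow(A); L <- ncol(A)
      cols <- matrix(0, k * Cin, L)
      for (j in 1:k) {
        for (pos in 1:L) {
          src <- pos + (j - 1) - pad
          if (src >= 1 && src <= L) {
            cols[((j - 1) * Cin + 1):(j * Cin), pos] <- A[, src]
          }
        }
      }
      Z <- l$W %*% cols + l$b
      A <- pmax(Z, 0)
    } else if (l$kind == "maxpool") {
      L <- ncol(A) %/% 2
      A <- vapply(1:L, function(p) pmax(A[, 2 * p - 1], A[, 2 * p]),
                  numeric(nrow(A)))
      if (is.null(dim(A))) A <- matrix(A, nrow = 1)
    } else if (l$kind == "gap") {
      A <- matrix(rowMeans(A), ncol = 1)
    } else if (l$kind == "flatten") {
      A <- matrix(as.vector(A), ncol = 1)
    } else if (l$kind == "dense") {
      Z <- l$W %*% A + l$b
      A <- if (identical(l$activation, "relu")) pmax(Z, 0) else Z
    }
  }
  z <- A[, 1]
  e <- exp(z - max(z))
  e / sum(e)
}

random_window <- function(n = 64, sd = 0.5, offset = c(0, 0, -1)) {
  sweep(matrix(rnorm(n * 3, 0, sd), ncol = 3), 2, offset, `+`)
}
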