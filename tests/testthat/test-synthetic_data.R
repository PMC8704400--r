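test_that("noise-free standing is a constant gravity vector", {
  p <- subject_profile("A", 1, noise_sd_g = 0)
  rec <- generate_recording(p, class_signal_specs()$ST, 2, 100)
  expect_equal(diff(range(rec$samples$x)), 0)
  expect_equal(diff(range(rec$samples$y)), 0)
  expect_equal(diff(range(rec$samples$z)), 0)
  # norm of the constant vector is 1 G (gravity, tilted)
  expect_equal(sqrt(rec$samples$x[1]^2 + rec$samples$y[1]^2 +
                      rec$samples$z[1]^2), 1, tolerance = 1e-12)
})

test_that("two-leg jump has its dominant vertical peak at the bounce frequency", {
  p <- subject_profile("A", 7, bounce_freq_hz = 2.0, tilt_rad = 0)
  rec <- generate_recording(p, class_signal_specs()$TJ, 10, 100)
  v <- rec$samples$z - mean(rec$samples$z)
  mag <- Mod(stats::fft(v))[2:(length(v) %/% 2 + 1)]
  freqs <- seq_along(mag) * 100 / length(v)
  expect_lt(abs(freqs[which.max(mag)] - 2.0), 0.1)
})

test_that("left and right one-leg jumps are exact mirrors in the lateral axis", {
  p <- subject_profile("B", 123)
  lj <- generate_recording(p, class_signal_specs()$LJ, 3, 100, set_index = 2)
  rj <- generate_recording(p, class_signal_specs()$RJ, 3, 100, set_index = 2)
  # the one-leg classes share one random stream, so the mirror is exact
  expect_equal(rj$samples$x, lj$samples$x)
  expect_equal(rj$samples$z, lj$samples$z)
  expect_equal(rj$samples$y, -lj$samples$y)
})

test_that("cohort generation is a pure function of its seed", {
  c1 <- generate_cohort(2, 1, seed = 31, duration_s = 1)
  c2 <- generate_cohort(2, 1, seed = 31, duration_s = 1)
  c3 <- generate_cohort(2, 1, seed = 32, duration_s = 1)
  expect_identical(c1$recordings[[4]]$samples, c2$recordings[[4]]$samples)
  expect_false(identical(c1$recordings[[4]]$samples,
                         c3$recordings[[4]]$samples))
  # on-disk determinism: byte-identical CSVs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(2, 1, seed = 31, duration_s = 1, out_dir = d1)
  generate_cohort(2, 1, seed = 31, duration_s = 1, out_dir = d2)
  f <- list.files(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  expect_error(generate_cohort(2, 1, seed = 31, duration_s = 1,
                               out_dir = d1), "not empty")
})

test_that("a default cohort has the protocol layout", {
  cohort <- tiny_cohort()
  expect_equal(length(cohort$recordings),
               3 * 2 * 6)
  m <- cohort$manifest
  expect_equal(sort(unique(m$subject_id)), c("A", "B", "C"))
  expect_setequal(unique(m$label), motion_labels())
  # motions appear in protocol order within each set
  first_set <- m[m$subject_id == "A" & m$set_index == 1, ]
  expect_equal(first_set$label, motion_labels())
  # subjects draw distinct bounce frequencies
  freqs <- vapply(cohort$profiles, `[[`, numeric(1), "bounce_freq_hz")
  expect_equal(length(unique(freqs)), length(freqs))
})

test_that("generated classes have the intended separability structure", {
  ws <- tiny_windows()
  intensity <- vapply(seq_len(n_windows(ws)), function(i) {
    mean(sqrt(rowSums(ws$values[i, , ]^2)))
  }, numeric(1))
  by_class <- tapply(intensity, ws$label, mean)
  expect_lt(by_class[["ST"]], by_class[["WL"]])
  expect_lt(by_class[["WL"]], by_class[["TJ"]])

  # marching carries more sub-harmonic (half-bounce) lateral energy
  # than the two-leg jump, keeping MR/one-leg confusions realistic
  # sub-harmonic energy needs the full bout: a 0.64 s window cannot
  # resolve 0.6-1.3 Hz, but a whole recording can
  cohort <- tiny_cohort()
  profiles <- cohort$profiles
  sub_energy <- function(label) {
    recs <- Filter(function(r) r$label == label, cohort$recordings)
    mean(vapply(recs, function(r) {
      y <- r$samples$y
      n <- length(y)
      mag <- Mod(stats::fft(y - mean(y)))[2:(n %/% 2 + 1)]
      freqs <- (1:(n %/% 2)) * r$sample_rate_hz / n
      # below 3/4 of this subject's bounce frequency: catches the f/2
      # sub-harmonic, excludes the carrier
      f0 <- profiles[[r$subject_id]]$bounce_freq_hz
      sum(mag[freqs < f0 * 0.75]^2)
    }, numeric(1)))
  }
  expect_gt(sub_energy("MR"), sub_energy("TJ"))
})
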