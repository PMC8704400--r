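test_that("recording validates samples and metadata", {
  df <- data.frame(t = (0:9) / 100, x = rnorm(10), y = rnorm(10),
                   z = rnorm(10))
  rec <- recording(df, "A", 1, "TJ")
  expect_s3_class(rec, "har_recording")
  expect_equal(nrow(rec$samples), 10)

  dup <- df; dup$t[5] <- dup$t[4]
  expect_error(recording(dup, "A", 1, "TJ"), "strictly increasing")
  expect_error(recording(df[, -2], "A", 1, "TJ"), "missing column")
  expect_error(recording(df, "A", 1, "XX"), "unknown motion label")
})

test_that("sensor-log round-trip preserves samples to 1e-9 G", {
  set.seed(11)
  df <- data.frame(t = (0:999) / 100,
                   x = rnorm(1000), y = rnorm(1000),
                   z = rnorm(1000) - 1)
  rec <- recording(df, "B", 2, "MR")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, list(subject_id = "B", set_index = 2,
                                    label = "MR", sample_rate_hz = 100))
  expect_equal(nrow(back$samples), 1000)
  expect_lt(max(abs(back$samples$x - df$x)), 1e-9)
  expect_lt(max(abs(back$samples$z - df$z)), 1e-9)
  expect_identical(back$label, "MR")
})

test_that("malformed sensor logs raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0.1,0.2,0.3", "0.01,oops,0.2,0.3"), path)
  entry <- list(subject_id = "A", set_index = 1, label = "ST",
                sample_rate_hz = 100)
  expect_error(read_recording(path, entry), "non-numeric.*line 2")

  writeLines(c("t,x,y,z", "0,0.1,0.2,0.3", "0,0.1,0.2,0.3"), path)
  expect_error(read_recording(path, entry), "not strictly increasing")

  writeLines(c("t,x,y", "0,0.1,0.2"), path)
  expect_error(read_recording(path, entry), "missing column")
})

test_that("segmentation yields floor((N-W)/S)+1 windows, matching enumeration", {
  mk <- function(n) recording(data.frame(t = (seq_len(n) - 1) / 100,
                                         x = seq_len(n), y = 0, z = -1),
                              "A", 1, "TJ")
  # brute-force offset enumeration over a grid of (N, W, S)
  set.seed(3)
  for (i in 1:60) {
    n <- sample(1:500, 1)
    w <- sample(1:100, 1)
    s <- sample(1:100, 1)
    rec <- mk(n)
    ws <- suppressWarnings(segment_recording(rec, windowing_config(w, s)))
    starts <- 0
    expected <- if (n < w) integer(0) else seq(0, n - w, by = s)
    expect_equal(n_windows(ws), length(expected),
                 info = sprintf("N=%d W=%d S=%d", n, w, s))
    if (length(expected) > 0) {
      # x axis carries the sample index, so window contents locate starts
      got_starts <- unname(ws$values[, 1, 1]) - 1
      expect_equal(got_starts, expected)
    }
  }
  # protocol case: 10 s at 100 Hz, W = S = 64 -> 15 windows, last at 896
  ws <- segment_recording(mk(1000))
  expect_equal(n_windows(ws), 15)
  expect_equal(unname(ws$values[15, 1, 1]) - 1, 896)
  # boundary and short cases
  expect_equal(n_windows(segment_recording(mk(64))), 1)
  expect_warning(short <- segment_recording(mk(63)), "shorter than")
  expect_equal(n_windows(short), 0)
})

test_that("windows inherit metadata and concatenation rebuilds the signal", {
  rec <- tiny_cohort()$recordings[[1]]
  ws <- segment_recording(rec)
  expect_true(all(ws$label == rec$label))
  expect_true(all(ws$subject_id == rec$subject_id))
  expect_true(all(ws$set_index == rec$set_index))
  n_keep <- n_windows(ws) * 64
  rebuilt <- do.call(rbind, lapply(seq_len(n_windows(ws)),
                                   function(i) ws$values[i, , ]))
  expect_equal(unname(rebuilt),
               unname(as.matrix(rec$samples[1:n_keep, c("x", "y", "z")])))
})

test_that("flatten_window is axis-major and invertible", {
  w <- cbind(x = rep(1, 64), y = rep(2, 64), z = rep(3, 64))
  flat <- flatten_window(w)
  expect_length(flat, 192)
  expect_equal(flat, rep(c(1, 2, 3), each = 64))
  set.seed(8)
  w2 <- matrix(rnorm(192), ncol = 3)
  expect_equal(unname(unflatten_window(flatten_window(w2))), w2)
})

test_that("manifest round-trip and loading work end to end", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(2, 1, seed = 9, out_dir = dir,
                            duration_s = 2)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 12)
  recs <- load_recordings(m)
  expect_length(recs, 12)
  expect_equal(recs[[1]]$samples$x, cohort$recordings[[1]]$samples$x,
               tolerance = 1e-9)
  # duplicated paths refused
  m2 <- m; m2$file_path[2] <- m2$file_path[1]
  p <- file.path(dir, "bad.csv")
  write_manifest(m2, p)
  expect_error(read_manifest(p), "not unique")
})
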