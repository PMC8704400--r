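test_that("leave-one-subject-out folds partition the subjects", {
  ids <- c("A", "B", "C", "D", "E", "F", "G", "H")
  folds <- loso_split(rep(ids, each = 3))
  expect_length(folds, 8)
  for (f in folds) {
    expect_length(f$train, 7)
    expect_false(f$test %in% f$train)
  }
  expect_setequal(vapply(folds, `[[`, character(1), "test"), ids)
  expect_error(loso_split("A"), ">= 2 subjects")
})

test_that("confusion matrices follow the predicted-rows convention", {
  pred <- c("ST", "ST", "WL", "MR")
  truth <- c("ST", "WL", "WL", "MR")
  cm <- confusion_matrix(pred, truth)
  expect_equal(dim(cm), c(6, 6))
  expect_equal(sum(cm), 4)
  expect_equal(cm["ST", "WL"], 1)  # predicted ST, correct WL
  expect_equal(cm["WL", "ST"], 0)
  expect_error(confusion_matrix(c("ST", "XX"), c("ST", "ST")),
               "outside the given label set")
})

test_that("metrics match a brute-force row/column summation oracle", {
  set.seed(66)
  for (rep in 1:10) {
    m <- matrix(sample(0:50, 36, replace = TRUE), 6, 6,
                dimnames = list(motion_labels(), motion_labels()))
    met <- suppressWarnings(cm_metrics(m))
    for (c in 1:6) {
      p <- 100 * m[c, c] / sum(m[c, ])
      r <- 100 * m[c, c] / sum(m[, c])
      expect_equal(met$per_class$precision[c], p)
      expect_equal(met$per_class$recall[c], r)
      if (p + r > 0) {
        expect_equal(met$per_class$f_measure[c], 2 * p * r / (p + r))
      }
    }
    expect_equal(met$accuracy, 100 * sum(diag(m)) / sum(m))
  }
  # degenerate cases
  expect_error(cm_metrics(matrix(0, 6, 6)), "all zero")
  m <- diag(c(10, 10, 10, 10, 10, 0))
  dimnames(m) <- list(motion_labels(), motion_labels())
  expect_warning(expect_warning(met <- cm_metrics(m), "precision"),
                 "recall")
  expect_equal(met$per_class$precision[6], 0)
  perfect <- diag(rep(10, 6))
  dimnames(perfect) <- list(motion_labels(), motion_labels())
  met <- cm_metrics(perfect)
  expect_true(all(met$per_class$f_measure == 100))
  expect_equal(met$accuracy, 100)
})

test_that("label merging conserves counts and never lowers pooled accuracy", {
  set.seed(31)
  m <- matrix(sample(0:80, 36, replace = TRUE), 6, 6,
              dimnames = list(motion_labels(), motion_labels()))
  merged <- merge_labels(m, list("ST", "WL", "MR", "TJ",
                                 jump1 = c("LJ", "RJ")))
  expect_equal(dim(merged), c(5, 5))
  expect_equal(sum(merged), sum(m))
  acc0 <- suppressWarnings(cm_metrics(m))$accuracy
  acc1 <- suppressWarnings(cm_metrics(merged))$accuracy
  expect_gte(acc1, acc0)
  # merging everything is the degenerate perfect classifier
  all_one <- merge_labels(m, list(all = motion_labels()))
  expect_equal(suppressWarnings(cm_metrics(all_one))$accuracy, 100)
  # non-partitions are refused
  expect_error(merge_labels(m, list(c("ST", "WL"))), "partition")
  expect_error(merge_labels(m, list(motion_labels(), "ST")), "partition")
})

test_that("reported reference matrices reproduce their published metrics", {
  # the published RF matrix: every complete row/column checks out
  cm <- reference_confusion("rf")
  ref <- reference_metrics("rf")
  m <- as.matrix(cm)
  known <- !is.na(m)
  prec <- 100 * diag(m) / rowSums(m)
  rec <- 100 * diag(m) / colSums(m)
  for (c in which(apply(known, 1, all))) {
    expect_equal(unname(round(prec[c], 1)), ref$precision[c],
                 tolerance = 0.051)
  }
  for (c in which(apply(known, 2, all))) {
    expect_equal(unname(round(rec[c], 1)), ref$recall[c],
                 tolerance = 0.051)
  }
})

test_that("evaluation reports are additive and conserve window counts", {
  ws <- tiny_windows()
  cfg <- har_train_config(epochs = 2, seed = 10)
  rep <- run_loso(ws, "rf", cfg, verbose = FALSE)
  expect_s3_class(rep, "har_eval_report")
  expect_length(rep$per_subject, 3)
  # pooled = sum of per-subject matrices; total = all windows
  summed <- Reduce(`+`, lapply(rep$per_subject, function(s) as.matrix(s$cm)))
  expect_equal(unname(as.matrix(rep$pooled)), unname(summed))
  expect_equal(sum(rep$pooled), n_windows(ws))
  expect_equal(rep$avg_accuracy,
               mean(vapply(rep$per_subject, `[[`, numeric(1), "accuracy")))
  # report rendering and JSON round trip
  lines <- render_confusion(rep$pooled)
  expect_length(lines, 1 + 6 + 2)
  expect_match(lines[1], "Pre.\\\\Cor.")
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$avg_accuracy, rep$avg_accuracy)
})
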