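#' Build a confusion matrix (predicted rows, correct columns)
#'
#' Rows are predicted classes, columns are correct classes — the
#' "Pre.\\Cor." convention used throughout the package's reports.
#'
#' @param predicted,truth factors or character vectors of labels.
#' @param labels label order (default the canonical six motions).
#' @return integer matrix of class `"har_confusion"`.
#' @export
confusion_matrix <- function(predicted, truth, labels = motion_labels()) {
  stopifnot(length(predicted) == length(truth))
  p <- factor(as.character(predicted), levels = labels)
  t <- factor(as.character(truth), levels = labels)
  if (anyNA(p) || anyNA(t)) stop("labels outside the given label set")
  cm <- table(Predicted = p, Correct = t)
  structure(unclass(cm), class = "har_confusion")
}

as_confusion <- function(m, labels = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (!is.null(labels)) dimnames(m) <- list(Predicted = labels,
                                            Correct = labels)
  structure(m, class = "har_confusion")
}

#' Per-class precision, recall, F-measure and accuracy
#'
#' Precision of class c is the diagonal count over the row (predicted)
#' sum, recall over the column (correct) sum, F the harmonic mean of
#' the two, accuracy the trace over the total. Percentages. A class
#' with a zero denominator gets 0 with a warning.
#'
#' @param cm confusion matrix (predicted rows x correct columns).
#' @return list of class `"har_metrics"`: `per_class` data.frame
#'   (`label`, `precision`, `recall`, `f_measure`), `accuracy`.
#' @export
cm_metrics <- function(cm) {
  m <- as.matrix(cm)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  if (sum(m) == 0) stop("confusion matrix is all zero")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("class", seq_len(nrow(m)))
  d <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  div0 <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(what, " undefined (zero denominator) for: ",
              paste(labs[den == 0], collapse = ", "), "; reported as 0")
    }
    out
  }
  precision <- div0(d, rs, "precision") * 100
  recall <- div0(d, cs, "recall") * 100
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  structure(list(per_class = data.frame(label = labs,
                                        precision = precision,
                                        recall = recall,
                                        f_measure = f,
                                        row.names = NULL),
                 accuracy = 100 * sum(d) / sum(m)),
            class = "har_metrics")
}

#' @export
print.har_metrics <- function(x, ...) {
  df <- x$per_class
  df[-1] <- lapply(df[-1], function(v) sprintf("%.1f", v))
  print(df, row.names = FALSE)
  cat(sprintf("accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' Merge label groups in a confusion matrix
#'
#' Sums rows and columns over each group of a partition of the labels,
#' e.g. treating the two one-leg jumps as a single target. The total
#' count is preserved; merging mutually confused classes moves their
#' cross-terms onto the diagonal, so pooled accuracy never decreases.
#'
#' @param cm confusion matrix over the original labels.
#' @param groups named list of character vectors forming a partition of
#'   the labels; unnamed groups are named by joining their members with
#'   `+`.
#' @return merged `"har_confusion"`.
#' @export
merge_labels <- function(cm, groups) {
  m <- as.matrix(cm)
  labs <- rownames(m)
  flat <- unlist(groups)
  if (length(flat) != length(labs) || anyDuplicated(flat) ||
      !setequal(flat, labs)) {
    stop("groups must form a partition of the matrix labels")
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- rep("", length(groups))
  nm[nm == ""] <- vapply(groups[nm == ""], paste, character(1),
                         collapse = "+")
  k <- length(groups)
  out <- matrix(0L, k, k, dimnames = list(Predicted = nm, Correct = nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- sum(m[labs %in% groups[[i]], labs %in% groups[[j]],
                         drop = FALSE])
    }
  }
  as_confusion(out, nm)
}

#' @export
print.har_confusion <- function(x, ...) {
  cat(render_confusion(x), sep = "\n")
  invisible(x)
}

#' Render a confusion matrix report table
#'
#' Text table in the package's report layout: predicted rows, correct
#' columns, a trailing precision column and bottom recall / F-measure
#' rows (percentages, one decimal, with the overall accuracy in the
#' corner).
#'
#' @param cm a `"har_confusion"`.
#' @return character vector of lines.
#' @export
render_confusion <- function(cm) {
  m <- as.matrix(cm)
  met <- suppressWarnings(cm_metrics(m))
  labs <- rownames(m)
  wid <- max(5L, nchar(labs) + 1L)
  f1 <- function(v) sprintf("%.1f", v)
  pad <- function(s, w = wid) formatC(s, width = w)
  header <- paste0(pad("Pre.\\Cor.", 12),
                   paste(vapply(labs, pad, character(1)), collapse = ""),
                   pad("Precision[%]", 14))
  body <- vapply(seq_along(labs), function(i) {
    paste0(pad(labs[i], 12),
           paste(vapply(m[i, ], function(v) pad(format(v)), character(1)),
                 collapse = ""),
           pad(f1(met$per_class$precision[i]), 14))
  }, character(1))
  recall <- paste0(pad("Recall[%]", 12),
                   paste(vapply(met$per_class$recall, function(v) pad(f1(v)),
                                character(1)), collapse = ""),
                   pad(f1(met$accuracy), 14))
  fmeas <- paste0(pad("F-meas.[%]", 12),
                  paste(vapply(met$per_class$f_measure, function(v) pad(f1(v)),
                               character(1)), collapse = ""))
  c(header, body, recall, fmeas)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject is the test set, all others
#' train. Requires at least two subjects.
#'
#' @param subjects character vector of subject ids (e.g.
#'   `manifest$subject_id` or a window set's `subject_id`); duplicates
#'   collapse.
#' @return list of folds, each `list(train = ids, test = id)`.
#' @export
loso_split <- function(subjects) {
  if (is.data.frame(subjects)) subjects <- subjects$subject_id
  ids <- unique(as.character(subjects))
  if (length(ids) < 2) stop("leave-one-subject-out needs >= 2 subjects")
  lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
}

new_eval_report <- function(per_subject, label_order) {
  pooled <- Reduce(`+`, lapply(per_subject, function(x) as.matrix(x$cm)))
  acc <- vapply(per_subject, `[[`, numeric(1), "accuracy")
  structure(list(per_subject = per_subject,
                 pooled = as_confusion(pooled, label_order),
                 avg_accuracy = mean(acc)),
            class = "har_eval_report")
}

#' @export
print.har_eval_report <- function(x, ...) {
  cat("<har_eval_report>\n")
  for (s in names(x$per_subject)) {
    cat(sprintf("  subject %s: accuracy %.1f%%\n", s,
                x$per_subject[[s]]$accuracy))
  }
  cat(sprintf("  average accuracy over subjects: %.1f%%\n",
              x$avg_accuracy))
  cat(sprintf("  pooled accuracy: %.1f%%\n",
              suppressWarnings(cm_metrics(x$pooled))$accuracy))
  cat("  pooled confusion matrix:\n")
  cat(paste0("  ", render_confusion(x$pooled)), sep = "\n")
  invisible(x)
}

# fit the requested model kind on a training window set
fit_model_kind <- function(model, train_ws, config, layout) {
  if (inherits(model, "har_model_spec")) {
    return(har_train(model, train_ws, config = config, layout = layout))
  }
  if (identical(model, "rf")) {
    feat <- featurize_windows(train_ws)
    return(har_train_rf(feat, factor(train_ws$label,
                                     levels = motion_labels()),
                        seed = config$seed))
  }
  spec <- if (startsWith(model, "depth:")) {
    build_depth_variant(as.integer(sub("depth:", "", model)))
  } else {
    switch(model,
           ours = build_ours(),
           simple = build_simple_cnn(),
           vgg16fc = build_vgg16_fc(),
           stop("unknown model kind: ", model))
  }
  har_train(spec, train_ws, config = config, layout = layout)
}

predict_model <- function(fit, test_ws) {
  if (inherits(fit, "har_rf_fit")) {
    predict(fit, featurize_windows(test_ws))
  } else {
    predict(fit, test_ws)
  }
}

#' Leave-one-subject-out evaluation of a model
#'
#' For each fold, trains the requested model on all other subjects'
#' windows and evaluates on the held-out subject, then assembles the
#' per-subject confusion matrices, the unweighted subject-mean accuracy
#' (the headline number of this protocol) and the pooled matrix. The
#' subject mean and the pooled accuracy generally differ; both are
#' reported and labeled.
#'
#' @param windows a `"har_window_set"` covering all subjects.
#' @param model `"ours"`, `"simple"`, `"vgg16fc"`, `"rf"`,
#'   `"depth:<k>"`, or a `"har_model_spec"`.
#' @param config a [har_train_config()]; each fold derives its own seed
#'   from it (logged via message).
#' @param layout input layout for CNN models.
#' @param keep_fits keep each fold's fitted model in the result
#'   (needed to reuse fold models as personalization baselines).
#' @param verbose log per-fold progress.
#' @return `"har_eval_report"`; if `keep_fits`, also `fits`, a named
#'   list of per-fold fitted models.
#' @export
run_loso <- function(windows, model = "ours",
                     config = har_train_config(), layout = "flat192",
                     keep_fits = FALSE, verbose = TRUE) {
  stopifnot(inherits(windows, "har_window_set"))
  folds <- loso_split(windows$subject_id)
  # features do not depend on the fold: compute once for the RF
  feats <- if (identical(model, "rf")) featurize_windows(windows)
  per_subject <- list()
  fits <- list()
  for (fold in folds) {
    fold_seed <- derive_seed(config$seed, "fold", fold$test)
    fold_config <- config
    fold_config$seed <- fold_seed
    if (verbose) {
      message(sprintf("LOSO fold: test subject %s (fold seed %d)",
                      fold$test, fold_seed))
    }
    in_train <- windows$subject_id %in% fold$train
    if (identical(model, "rf")) {
      fit <- har_train_rf(feats[in_train, ],
                          factor(windows$label[in_train],
                                 levels = motion_labels()),
                          seed = fold_config$seed)
      pred <- predict(fit, feats[!in_train, ])
      cm <- confusion_matrix(pred, windows$label[!in_train])
    } else {
      train_ws <- subset_windows(windows, in_train)
      test_ws <- subset_windows(windows, !in_train)
      fit <- fit_model_kind(model, train_ws, fold_config, layout)
      pred <- predict_model(fit, test_ws)
      cm <- confusion_matrix(pred, test_ws$label)
    }
    per_subject[[fold$test]] <-
      list(accuracy = suppressWarnings(cm_metrics(cm))$accuracy,
           cm = cm)
    if (keep_fits) fits[[fold$test]] <- fit
  }
  rep <- new_eval_report(per_subject, motion_labels())
  if (keep_fits) rep$fits <- fits
  rep
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `"har_eval_report"`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  plain <- function(m) unclass(as.matrix(m))
  x <- list(
    avg_accuracy = report$avg_accuracy,
    pooled_accuracy = suppressWarnings(cm_metrics(report$pooled))$accuracy,
    pooled_confusion = plain(report$pooled),
    per_subject = lapply(report$per_subject, function(s) {
      list(accuracy = s$accuracy, confusion = plain(s$cm))
    }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
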