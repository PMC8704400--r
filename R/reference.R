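# Reference results from a published smartwatch trampoline-motion
# study, shipped as plain-text inputs. The counts let cm_metrics() be
# validated against independently reported precision/recall/F values;
# they are data, not anything this package computes.

#' Published reference confusion matrices
#'
#' Leave-one-subject-out confusion matrices reported for a published
#' eight-subject trampoline-motion study: one for a random-forest
#' classifier on hand-crafted features, one for the GAP-headed CNN.
#' Rows are predicted classes, columns correct classes. One cell of
#' the random-forest matrix (predicted WL, correct RJ) was not
#' reported and is NA; metrics depending on it cannot be recomputed.
#'
#' @param model `"cnn"` or `"rf"`.
#' @return `"har_confusion"` matrix (integer counts, NA for the one
#'   unreported cell).
#' @export
reference_confusion <- function(model = c("cnn", "rf")) {
  model <- match.arg(model)
  path <- system.file("extdata",
                      paste0("ref_confusion_", model, ".csv"),
                      package = "trampohar", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$predicted
  as_confusion(m, df$predicted)
}

#' Published reference per-class metrics
#'
#' The precision, recall and F-measure values (percent, one decimal)
#' reported alongside [reference_confusion()]. A handful of these are
#' not arithmetically consistent with the reported counts (rounding or
#' typesetting slips in the source); [cm_metrics()] recomputation is
#' only expected to match the consistent ones.
#'
#' @param model `"cnn"` or `"rf"`.
#' @return data.frame with `label`, `precision`, `recall`, `f_measure`.
#' @export
reference_metrics <- function(model = c("cnn", "rf")) {
  model <- match.arg(model)
  path <- system.file("extdata",
                      paste0("ref_metrics_", model, ".csv"),
                      package = "trampohar", mustWork = TRUE)
  utils::read.csv(path)
}
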