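#' Motion label set
#'
#' The six trampoline motion classes recognized by the package, in the
#' fixed protocol order used everywhere (model outputs, confusion
#' matrices, reports): two-leg standing (ST), walking (WL), marching
#' (MR), two-leg jumping (TJ), one-leg jumping left (LJ) and one-leg
#' jumping right (RJ).
#'
#' @return Character vector of the six label codes, in canonical order.
#' @export
#' @examples
#' motion_labels()
motion_labels <- function() {
  c("ST", "WL", "MR", "TJ", "LJ", "RJ")
}

#' @rdname motion_labels
#' @return `motion_label_names()`: named character vector mapping each
#'   code to a human-readable display name.
#' @export
motion_label_names <- function() {
  c(ST = "stand", WL = "walk", MR = "march",
    TJ = "two-leg jump", LJ = "one-leg jump (left)",
    RJ = "one-leg jump (right)")
}

#' Coerce labels to the canonical motion-label factor
#'
#' @param x character vector or factor of label codes.
#' @return Factor with levels in the canonical `motion_labels()` order.
#' @export
as_motion_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), motion_labels())
  if (length(bad) > 0) {
    stop("unknown motion label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = motion_labels())
}

# Acceleration unit convention: sensors report in G; exposed for users
# who need SI, never applied internally.

#' Standard gravity conversion constant
#'
#' Wrist accelerometers report acceleration in G. All computation in
#' this package stays in G; this constant (9.8 m/s^2 per G) is exposed
#' for callers who need SI units.
#' @export
G_TO_MS2 <- 9.8
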