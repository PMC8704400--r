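#' Personalize a motion classifier with a user's own sets
#'
#' Emulates on-device personalization: a general model is trained on
#' everyone else, then a few of the target user's sets (default: sets
#' 1-3) are made available for adaptation and the remaining sets are
#' held out for evaluation. Four schemes:
#'
#' * `None` — the general model, unchanged (no-op).
#' * `FT` — fine-tune all weights on the user's adaptation sets.
#' * `FT-Classifier` — fine-tune only the softmax classifier layer;
#'   all feature-extractor weights stay bitwise identical.
#' * `Mixin` — retrain from scratch on the other subjects' data pooled
#'   with the user's adaptation sets.
#'
#' @param windows `"har_window_set"` covering the whole cohort.
#' @param subject target subject id.
#' @param scheme one of `"None"`, `"FT"`, `"FT-Classifier"`, `"Mixin"`.
#' @param base_model optional `"har_cnn_fit"` already trained on the
#'   other subjects (e.g. a fold model from [run_loso()] with
#'   `keep_fits = TRUE`); trained here when missing.
#' @param config [har_train_config()] for base/Mixin training.
#' @param ft_epochs epochs for the fine-tuning schemes (default 20 —
#'   the adaptation set is small; the published protocol prints no
#'   fine-tuning schedule).
#' @param adapt_sets set indices available for adaptation (default
#'   1:3, the deterministic first-three choice); evaluation uses the
#'   user's remaining sets.
#' @param rotate_sets if TRUE, repeats the analysis over every
#'   3-of-n choice of adaptation sets and averages the accuracy.
#' @param spec model spec for base/Mixin training when no base model is
#'   given.
#' @param layout CNN input layout.
#' @return `"har_personalization"`: `scheme`, `subject`, `model`,
#'   `accuracy`, `cm`, `eval_sets` (and `rotations` when rotated).
#' @export
personalize <- function(windows, subject,
                        scheme = c("None", "FT", "FT-Classifier", "Mixin"),
                        base_model = NULL,
                        config = har_train_config(),
                        ft_epochs = 20,
                        adapt_sets = 1:3,
                        rotate_sets = FALSE,
                        spec = build_ours(),
                        layout = "flat192") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(windows, "har_window_set"),
            subject %in% windows$subject_id)
  user_sets <- sort(unique(windows$set_index[windows$subject_id == subject]))
  if (rotate_sets) {
    choices <- utils::combn(user_sets, length(adapt_sets),
                            simplify = FALSE)
    runs <- lapply(choices, function(ch) {
      personalize(windows, subject, scheme, base_model, config,
                  ft_epochs, adapt_sets = ch, rotate_sets = FALSE,
                  spec = spec, layout = layout)
    })
    out <- runs[[1]]
    out$accuracy <- mean(vapply(runs, `[[`, numeric(1), "accuracy"))
    out$rotations <- runs
    return(out)
  }
  if (length(setdiff(user_sets, adapt_sets)) < 1) {
    stop("subject ", subject,
         " has no sets left for evaluation after adaptation")
  }
  others <- subset_windows(windows, windows$subject_id != subject)
  adapt <- subset_windows(windows, windows$subject_id == subject &
                            windows$set_index %in% adapt_sets)
  eval_ws <- subset_windows(windows, windows$subject_id == subject &
                              !(windows$set_index %in% adapt_sets))
  if (scheme != "Mixin" && is.null(base_model)) {
    base_model <- har_train(spec, others, config = config,
                            layout = layout)
  }
  ft_config <- config
  ft_config$epochs <- as.integer(ft_epochs)
  ft_config$seed <- derive_seed(config$seed, "ft", subject, scheme)
  model <- switch(scheme,
    "None" = base_model,
    "FT" = har_train(base_model, adapt, config = ft_config),
    "FT-Classifier" = har_train(base_model, adapt, config = ft_config,
                                trainable = classifier_layer_mask(base_model$spec)),
    "Mixin" = har_train(spec, bind_window_sets(others, adapt),
                        config = config, layout = layout))
  pred <- predict(model, eval_ws)
  cm <- confusion_matrix(pred, eval_ws$label)
  structure(list(scheme = scheme, subject = subject, model = model,
                 accuracy = suppressWarnings(cm_metrics(cm))$accuracy,
                 cm = cm,
                 eval_sets = setdiff(user_sets, adapt_sets)),
            class = "har_personalization")
}

#' @export
print.har_personalization <- function(x, ...) {
  cat(sprintf("<har_personalization> subject %s, scheme %s: accuracy %.1f%% on set(s) %s\n",
              x$subject, x$scheme, x$accuracy,
              paste(x$eval_sets, collapse = ", ")))
  invisible(x)
}
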