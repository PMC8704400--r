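#' Training configuration
#'
#' Defaults are the published protocol: Adam with learning rate 1e-3,
#' categorical cross-entropy, minibatch size 20, 100 epochs. All
#' examples and tests in this package use a reduced epoch count, stated
#' where they do.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training windows.
#' @param seed integer seed governing weight initialization and batch
#'   shuffling.
#' @return list of class `"har_train_config"`.
#' @export
har_train_config <- function(learning_rate = 1e-3, batch_size = 20,
                             epochs = 100, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "har_train_config")
}

# He-normal initial weights: spec layers -> engine layer list.
init_cnn_layers <- function(spec, seed) {
  C <- spec$input_shape[2]
  L <- spec$input_shape[1]
  with_seed(derive_seed(seed, "init", spec$name), {
    lapply(spec$layers, function(l) {
      switch(l$kind,
        conv = {
          fan_in <- l$kernel * C
          W <- matrix(stats::rnorm(l$filters * fan_in, 0,
                                   sqrt(2 / fan_in)),
                      nrow = l$filters)
          out <- list(kind = "conv", W = W,
                      b = numeric(l$filters), kernel = l$kernel,
                      trainable = TRUE)
          C <<- l$filters
          out
        },
        maxpool = { L <<- L %/% l$size; list(kind = "maxpool", size = l$size) },
        gap = { L <<- 1L; list(kind = "gap") },
        flatten = { C <<- C * L; L <<- 1L; list(kind = "flatten") },
        dense = {
          W <- matrix(stats::rnorm(l$units * C, 0, sqrt(2 / C)),
                      nrow = l$units)
          out <- list(kind = "dense", W = W, b = numeric(l$units),
                      activation = l$activation, trainable = TRUE)
          C <<- l$units
          out
        },
        softmax = {
          W <- matrix(stats::rnorm(l$units * C, 0, sqrt(1 / C)),
                      nrow = l$units)
          out <- list(kind = "dense", W = W, b = numeric(l$units),
                      activation = "linear", trainable = TRUE)
          C <<- l$units
          out
        })
    })
  })
}

check_training_labels <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("training labels contain a single class")
  absent <- setdiff(levels(y), unique(as.character(y)))
  if (length(absent) > 0) {
    stop("class(es) absent from training data: ",
         paste(absent, collapse = ", "),
         "; refusing to train a model that can never predict them")
  }
  y
}

#' Train a CNN on labeled windows
#'
#' Fits a model spec (or continues training a fitted model) with Adam
#' on categorical cross-entropy. Training is deterministic given
#' `config$seed`: it fixes the He-normal weight initialization and the
#' epoch shuffling, and the single-threaded engine accumulates in a
#' fixed order.
#'
#' @param model a `"har_model_spec"` to fit from scratch, or a
#'   `"har_cnn_fit"` whose weights are the starting point
#'   (fine-tuning).
#' @param windows a `"har_window_set"`, or a numeric array
#'   (length x channels x n) matching the spec's input shape.
#' @param labels factor of class labels (required when `windows` is an
#'   array; taken from the window set otherwise). Every factor level
#'   must occur.
#' @param config a [har_train_config()].
#' @param layout input layout for window sets (see
#'   [windows_to_tensor()]).
#' @param trainable optional logical vector (one entry per spec layer):
#'   FALSE freezes that layer's weights. Used by the classifier-only
#'   personalization scheme.
#' @return `"har_cnn_fit"`: `spec`, `layers` (trained weights),
#'   `classes`, `loss` (per-epoch mean cross-entropy), `config`,
#'   `layout`.
#' @export
har_train <- function(model, windows, labels = NULL,
                      config = har_train_config(),
                      layout = c("flat192", "multichannel"),
                      trainable = NULL) {
  layout <- match.arg(layout)
  if (inherits(model, "har_cnn_fit")) {
    spec <- model$spec
    layers <- model$layers
    layout <- model$layout
    classes <- model$classes
  } else {
    stopifnot(inherits(model, "har_model_spec"))
    spec <- model
    layers <- init_cnn_layers(spec, config$seed)
    classes <- NULL
  }
  if (inherits(windows, "har_window_set")) {
    if (is.null(labels)) {
      labels <- factor(windows$label, levels = motion_labels())
    }
    X <- windows_to_tensor(windows, layout)
  } else {
    X <- windows
  }
  stopifnot(length(dim(X)) == 3,
            dim(X)[1] == spec$input_shape[1],
            dim(X)[2] == spec$input_shape[2])
  y <- check_training_labels(labels)
  if (!is.null(classes)) {
    y <- factor(as.character(y), levels = classes)
    if (anyNA(y)) stop("labels outside the fitted model's class set")
  } else if (nlevels(y) != spec$n_classes) {
    stop("spec has ", spec$n_classes, " output classes but labels have ",
         nlevels(y), " levels")
  }
  if (!is.null(trainable)) {
    stopifnot(length(trainable) == length(layers))
    for (i in seq_along(layers)) {
      if (layers[[i]]$kind %in% c("conv", "dense")) {
        layers[[i]]$trainable <- isTRUE(trainable[i])
      }
    }
  }
  res <- cpp_cnn_train(layers, X, as.integer(y) - 1L,
                       n_classes = nlevels(y),
                       epochs = config$epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate,
                       seed = derive_seed(config$seed, "shuffle"))
  structure(list(spec = spec, layers = res$layers,
                 classes = levels(y), loss = as.numeric(res$loss),
                 config = config, layout = layout),
            class = "har_cnn_fit")
}

#' @export
print.har_cnn_fit <- function(x, ...) {
  cat(sprintf("<har_cnn_fit> '%s' (%d classes); final training loss %.4f after %d epoch(s)\n",
              x$spec$name, length(x$classes), x$loss[length(x$loss)],
              length(x$loss)))
  invisible(x)
}

#' Predict motion classes with a fitted CNN
#'
#' Softmax probabilities or hard labels. Ties on equal probabilities
#' resolve to the lowest class index (fixed canonical label order), so
#' prediction is deterministic.
#'
#' @param object a `"har_cnn_fit"`.
#' @param newdata a `"har_window_set"` or input tensor array.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @export
predict.har_cnn_fit <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "har_window_set")) {
    windows_to_tensor(newdata, object$layout)
  } else newdata
  P <- cpp_cnn_predict(object$layers, X)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

# which spec layers belong to the classifier head (the final softmax
# projection); everything before it is the feature extractor
classifier_layer_mask <- function(spec) {
  n <- length(spec$layers)
  mask <- rep(FALSE, n)
  mask[n] <- TRUE   # the softmax projection
  mask
}

#' Train the random-forest baseline on hand-crafted features
#'
#' Wraps the classic random-forest learner behind the same interface as
#' the CNN. The published baseline names no forest hyperparameters;
#' this package defaults to 300 trees with the standard mtry.
#'
#' @param features data.frame or matrix of feature columns (e.g. from
#'   [featurize_windows()]; metadata columns `subject_id`, `set_index`,
#'   `label` are dropped automatically).
#' @param labels factor of class labels.
#' @param seed integer seed.
#' @param ntree number of trees.
#' @param ... passed to [randomForest::randomForest()].
#' @return `"har_rf_fit"` wrapping the forest.
#' @export
har_train_rf <- function(features, labels, seed = 1, ntree = 300, ...) {
  feat <- as.data.frame(features)
  feat <- feat[setdiff(names(feat),
                       c("subject_id", "set_index", "label"))]
  bad <- names(feat)[vapply(feat, function(v) any(!is.finite(v)),
                            logical(1))]
  if (length(bad) > 0) {
    stop("non-finite feature column(s): ", paste(bad, collapse = ", "))
  }
  y <- check_training_labels(labels)
  fit <- with_seed(derive_seed(seed, "rf"), {
    randomForest::randomForest(x = feat, y = y, ntree = ntree, ...)
  })
  structure(list(forest = fit, classes = levels(y),
                 feature_names = names(feat)),
            class = "har_rf_fit")
}

#' @export
predict.har_rf_fit <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  feat <- as.data.frame(newdata)
  feat <- feat[intersect(names(feat), object$feature_names)]
  stats::predict(object$forest, feat,
                 type = if (type == "prob") "prob" else "response")
}
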