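# Layer-by-layer CNN descriptions. A spec is backend-neutral data; the
# C++ engine consumes it after weight initialization. Hidden layers
# use ReLU and same-padding kernel-3 convolutions (the VGG convention;
# the published table prints only filter counts and output shapes).

spec_layer <- function(kind, ...) c(list(kind = kind), list(...))

new_model_spec <- function(name, layers, input_shape, n_classes = 6) {
  structure(list(name = name, layers = layers,
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes)),
            class = "har_model_spec")
}

#' The GAP-headed VGG-derived 1D CNN
#'
#' The package's main classifier: thirteen same-padding kernel-3
#' convolutions in five blocks (filter counts 16,16 | 32,32 | 64,64,64
#' | 128,128,128 | 128,128,128), a size-2 max pool after each block, a
#' global-average-pooling head of width 128 and a softmax output over
#' the six motions. With the default single-channel 192-sample input
#' the sequence length halves at each pool: 192, 96, 48, 24, 12, 6.
#'
#' @param input_shape integer (length, channels); the default
#'   `c(192, 1)` is the axis-major flattened 64-sample window. Use
#'   `c(64, 3)` for the three-channel layout.
#' @param n_classes number of output classes.
#' @return A `"har_model_spec"`.
#' @export
build_ours <- function(input_shape = c(192, 1), n_classes = 6) {
  blocks <- list(c(16, 16), c(32, 32), c(64, 64, 64),
                 c(128, 128, 128), c(128, 128, 128))
  layers <- list()
  for (blk in blocks) {
    for (f in blk) layers <- c(layers, list(spec_layer("conv", filters = f, kernel = 3)))
    layers <- c(layers, list(spec_layer("maxpool", size = 2)))
  }
  layers <- c(layers, list(spec_layer("gap"),
                           spec_layer("softmax", units = n_classes)))
  new_model_spec("ours", layers, input_shape, n_classes)
}

#' The fully-connected-head variant
#'
#' Identical feature extractor to [build_ours()], but the GAP head is
#' replaced by the original VGG-style head: flatten, two 128-unit ReLU
#' dense layers, softmax. Strictly more parameters than the GAP model.
#'
#' @inheritParams build_ours
#' @param fc_units width of the two dense layers.
#' @return A `"har_model_spec"`.
#' @export
build_vgg16_fc <- function(input_shape = c(192, 1), n_classes = 6,
                           fc_units = 128) {
  base <- build_ours(input_shape, n_classes)
  extractor <- base$layers[seq_len(length(base$layers) - 2L)]
  layers <- c(extractor,
              list(spec_layer("flatten"),
                   spec_layer("dense", units = fc_units, activation = "relu"),
                   spec_layer("dense", units = fc_units, activation = "relu"),
                   spec_layer("softmax", units = n_classes)))
  new_model_spec("vgg16fc", layers, input_shape, n_classes)
}

#' A small three-convolution baseline CNN
#'
#' Three kernel-3 convolutions (32, 64, 128 filters) with one size-2
#' max pool after the first convolution and a flatten + 100-unit dense
#' head. The published comparison names such a three-layer model but
#' not its internals, so these hyperparameters are this package's
#' documented reconstruction; comparisons against it are
#' reconstruction-dependent.
#'
#' @inheritParams build_ours
#' @return A `"har_model_spec"`.
#' @export
build_simple_cnn <- function(input_shape = c(192, 1), n_classes = 6) {
  layers <- list(
    spec_layer("conv", filters = 32, kernel = 3),
    spec_layer("maxpool", size = 2),
    spec_layer("conv", filters = 64, kernel = 3),
    spec_layer("conv", filters = 128, kernel = 3),
    spec_layer("flatten"),
    spec_layer("dense", units = 100, activation = "relu"),
    spec_layer("softmax", units = n_classes))
  new_model_spec("simple", layers, input_shape, n_classes)
}

#' Variable-depth CNN family for the depth sweep
#'
#' Builds the depth-sweep variant with `n_conv` convolutions: layers
#' come in groups of three, the filter count starts at 16 and doubles
#' with every group, and a size-2 max pool follows each completed group
#' of three (no pool after a trailing partial group). GAP + softmax
#' head as in [build_ours()].
#'
#' @param n_conv number of convolutional layers, 1 to 19.
#' @inheritParams build_ours
#' @return A `"har_model_spec"`.
#' @export
build_depth_variant <- function(n_conv, input_shape = c(192, 1),
                                n_classes = 6) {
  if (!is.numeric(n_conv) || n_conv != round(n_conv) ||
      n_conv < 1 || n_conv > 19) {
    stop("n_conv must be an integer in 1..19")
  }
  n_conv <- as.integer(n_conv)
  layers <- list()
  for (i in seq_len(n_conv)) {
    g <- (i - 1L) %/% 3L
    layers <- c(layers, list(spec_layer("conv", filters = 16L * 2L^g,
                                        kernel = 3)))
    if (i %% 3L == 0L) {
      layers <- c(layers, list(spec_layer("maxpool", size = 2)))
    }
  }
  layers <- c(layers, list(spec_layer("gap"),
                           spec_layer("softmax", units = n_classes)))
  new_model_spec(paste0("depth:", n_conv), layers, input_shape, n_classes)
}

#' Propagate shapes through a model spec
#'
#' Chains the (sequence length, channels) shape through every layer —
#' same-padding convolutions keep the length, size-2 pools halve it
#' (floor), GAP and flatten collapse it.
#'
#' @param spec a `"har_model_spec"`.
#' @return data.frame with `kind`, `out_length`, `out_channels` per
#'   layer.
#' @export
spec_shapes <- function(spec) {
  stopifnot(inherits(spec, "har_model_spec"))
  L <- spec$input_shape[1]
  C <- spec$input_shape[2]
  rows <- lapply(spec$layers, function(l) {
    switch(l$kind,
      conv = { C <<- l$filters },
      maxpool = { L <<- L %/% l$size },
      gap = { L <<- 1L },
      flatten = { C <<- L * C; L <<- 1L },
      dense = { C <<- l$units },
      softmax = { C <<- l$units },
      stop("unknown layer kind: ", l$kind))
    data.frame(kind = l$kind, out_length = L, out_channels = C)
  })
  do.call(rbind, rows)
}

#' Count trainable parameters of a model spec
#'
#' @param spec a `"har_model_spec"`.
#' @return integer: total weights + biases.
#' @export
spec_n_params <- function(spec) {
  L <- spec$input_shape[1]
  C <- spec$input_shape[2]
  total <- 0
  for (l in spec$layers) {
    switch(l$kind,
      conv = { total <- total + (l$kernel * C + 1) * l$filters
               C <- l$filters },
      maxpool = { L <- L %/% l$size },
      gap = { L <- 1L },
      flatten = { C <- L * C; L <- 1L },
      dense = { total <- total + (C + 1) * l$units; C <- l$units },
      softmax = { total <- total + (C + 1) * l$units; C <- l$units })
  }
  as.integer(total)
}

#' @export
print.har_model_spec <- function(x, ...) {
  cat(sprintf("<har_model_spec> '%s': input (%d x %d ch), %d classes, %d parameters\n",
              x$name, x$input_shape[1], x$input_shape[2], x$n_classes,
              spec_n_params(x)))
  sh <- spec_shapes(x)
  info <- vapply(seq_along(x$layers), function(i) {
    l <- x$layers[[i]]
    extra <- switch(l$kind,
      conv = sprintf(" %d filters, kernel %d", l$filters, l$kernel),
      maxpool = sprintf(" size %d", l$size),
      dense = sprintf(" %d units (%s)", l$units, l$activation),
      softmax = sprintf(" %d units", l$units), "")
    sprintf("  %-9s%-22s-> length %d x %d ch", l$kind, extra,
            sh$out_length[i], sh$out_channels[i])
  }, character(1))
  cat(info, sep = "\n")
  cat("\n")
  invisible(x)
}

#' Serialize / restore a model spec as JSON
#'
#' @param spec a `"har_model_spec"`.
#' @param path file path.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  new_model_spec(x$name, x$layers, unlist(x$input_shape), x$n_classes)
}
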