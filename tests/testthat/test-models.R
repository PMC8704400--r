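test_that("the GAP model reproduces the published layer shapes", {
  spec <- build_ours()
  sh <- spec_shapes(spec)
  # sequence length after each pool: 96, 48, 24, 12, 6
  expect_equal(sh$out_length[sh$kind == "maxpool"], c(96, 48, 24, 12, 6))
  expect_equal(sh$out_length[sh$kind == "conv"],
               c(192, 192, 96, 96, 48, 48, 48, 24, 24, 24, 12, 12, 12))
  expect_equal(sh$out_channels[sh$kind == "conv"],
               c(16, 16, 32, 32, 64, 64, 64, 128, 128, 128, 128, 128, 128))
  expect_equal(sum(sh$kind == "conv"), 13)
  expect_equal(sh$out_channels[sh$kind == "gap"], 128)
  expect_equal(sh$out_channels[nrow(sh)], 6)
})

test_that("the FC variant shares the extractor and has strictly more parameters", {
  ours <- build_ours()
  fc <- build_vgg16_fc()
  n_ext <- length(ours$layers) - 2  # up to the last pool
  expect_identical(fc$layers[seq_len(n_ext)], ours$layers[seq_len(n_ext)])
  expect_gt(spec_n_params(fc), spec_n_params(ours))
  # the GAP head costs only the softmax projection: 128*6+6
  extractor_only <- spec_n_params(ours) - (128 * 6 + 6)
  expect_equal(spec_n_params(ours), extractor_only + 774)
})

test_that("the small baseline has three convolutions and more parameters than ours", {
  simple <- build_simple_cnn()
  kinds <- vapply(simple$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv"), 3)
  expect_gt(spec_n_params(simple), spec_n_params(build_ours()))
})

test_that("depth variants follow the groups-of-three doubling rule", {
  chan <- function(spec) {
    vapply(Filter(function(l) l$kind == "conv", spec$layers),
           `[[`, numeric(1), "filters")
  }
  pools <- function(spec) {
    sum(vapply(spec$layers, `[[`, character(1), "kind") == "maxpool")
  }
  expect_equal(chan(build_depth_variant(1)), 16)
  expect_equal(pools(build_depth_variant(1)), 0)
  expect_equal(chan(build_depth_variant(3)), rep(16, 3))
  expect_equal(pools(build_depth_variant(3)), 1)
  expect_equal(chan(build_depth_variant(7)), c(16, 16, 16, 32, 32, 32, 64))
  expect_equal(pools(build_depth_variant(7)), 2)
  expect_equal(chan(build_depth_variant(19)),
               c(rep(16, 3), rep(32, 3), rep(64, 3), rep(128, 3),
                 rep(256, 3), rep(512, 3), 1024))
  expect_equal(pools(build_depth_variant(19)), 6)
  expect_error(build_depth_variant(0), "1..19")
  expect_error(build_depth_variant(20), "1..19")
})

test_that("forward pass matches a double-precision reference and sums to one", {
  set.seed(99)
  for (spec in list(build_depth_variant(2, input_shape = c(24, 1), n_classes = 4),
                    build_simple_cnn(input_shape = c(16, 2), n_classes = 3))) {
    layers <- trampohar:::init_cnn_layers(spec, seed = 17)
    n <- 6
    X <- array(rnorm(prod(spec$input_shape) * n),
               dim = c(spec$input_shape, n))
    P <- trampohar:::cpp_cnn_predict(layers, X)
    expect_equal(rowSums(P), rep(1, n), tolerance = 1e-6)
    for (i in seq_len(n)) {
      want <- oracle_forward(layers, matrix(X[, , i],
                                            ncol = spec$input_shape[2]))
      expect_equal(unname(P[i, ]), want, tolerance = 1e-5)
    }
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(123)
  for (spec in list(build_depth_variant(2, input_shape = c(16, 2), n_classes = 3),
                    build_simple_cnn(input_shape = c(16, 2), n_classes = 3))) {
  layers <- trampohar:::init_cnn_layers(spec, seed = 31)
  n <- 8
  X <- array(rnorm(16 * 2 * n, 0, 1), dim = c(16, 2, n))
  y <- as.integer(sample(0:2, n, replace = TRUE))
  g <- trampohar:::cpp_cnn_grad(layers, X, y, 3)
  eps <- 2e-2
  for (li in seq_along(layers)) {
    if (!layers[[li]]$kind %in% c("conv", "dense")) next
    W <- layers[[li]]$W
    # probe a handful of weights per layer
    probes <- cbind(sample(nrow(W), 4, replace = TRUE),
                    sample(ncol(W), 4, replace = TRUE))
    for (k in seq_len(nrow(probes))) {
      i <- probes[k, 1]; j <- probes[k, 2]
      lp <- layers; lp[[li]]$W[i, j] <- W[i, j] + eps
      lm <- layers; lm[[li]]$W[i, j] <- W[i, j] - eps
      fd <- (trampohar:::cpp_cnn_grad(lp, X, y, 3)$loss -
               trampohar:::cpp_cnn_grad(lm, X, y, 3)$loss) / (2 * eps)
      an <- g$grads[[li]]$dW[i, j]
      expect_lt(abs(fd - an), 2e-2 * max(1, abs(an)) + 2e-3)
    }
  }
  }
})

test_that("training is deterministic, drives the loss down, and separates a toy problem", {
  toy <- separable_toy()
  spec <- build_depth_variant(1, n_classes = 2)
  cfg <- har_train_config(epochs = 60, seed = 4)
  fit1 <- har_train(spec, toy$X, toy$y, config = cfg)
  fit2 <- har_train(spec, toy$X, toy$y, config = cfg)
  expect_identical(fit1$layers, fit2$layers)
  expect_lt(fit1$loss[length(fit1$loss)], fit1$loss[1])
  pred <- predict(fit1, toy$X)
  expect_gte(mean(pred == toy$y), 0.99)
  probs <- predict(fit1, toy$X, type = "prob")
  expect_equal(rowSums(probs), rep(1, dim(toy$X)[3]), tolerance = 1e-6)
})

test_that("training refuses single-class or incomplete label sets", {
  toy <- separable_toy(10)
  spec <- build_depth_variant(1, n_classes = 2)
  one <- factor(rep("A", 20), levels = c("A"))
  expect_error(har_train(spec, toy$X, one), "single class")
  absent <- factor(rep("A", 20), levels = c("A", "B"))
  expect_error(har_train(spec, toy$X, absent), "absent")
})

test_that("the random-forest baseline learns separable features and rejects bad input", {
  set.seed(55)
  n <- 60
  feat <- data.frame(f1 = c(rnorm(n, -2), rnorm(n, 2)),
                     f2 = rnorm(2 * n))
  y <- factor(rep(c("a", "b"), each = n))
  fit <- har_train_rf(feat, y, seed = 3)
  holdout <- data.frame(f1 = c(rnorm(20, -2), rnorm(20, 2)),
                        f2 = rnorm(40))
  pred <- predict(fit, holdout)
  expect_gte(mean(pred == rep(c("a", "b"), each = 20)), 0.95)
  # duplicating training rows leaves probe predictions unchanged
  fit2 <- har_train_rf(rbind(feat, feat), rep(y, 2), seed = 3)
  expect_equal(as.character(predict(fit2, holdout)), as.character(pred))
  # refusals
  bad <- feat; bad$f2[3] <- NaN
  expect_error(har_train_rf(bad, y), "non-finite feature column")
  expect_error(har_train_rf(feat, factor(rep("a", 2 * n))), "single class")
})
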