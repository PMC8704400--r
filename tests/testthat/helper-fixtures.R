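# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small but structurally complete cohort: 3 subjects x 2 sets x 6
# motions, 3 s at 100 Hz -> 4 windows per recording, 144 windows
tiny_cohort <- function() {
  cached("tiny_cohort", generate_cohort(3, 2, seed = 2024,
                                        duration_s = 3))
}

tiny_windows <- function() {
  cached("tiny_windows", cohort_windows(tiny_cohort()))
}

# a cheap spec for training-path tests
tiny_spec <- function(n_classes = 6) build_depth_variant(1, n_classes = n_classes)

# two linearly separable classes in the flat 192 x 1 layout
separable_toy <- function(n_per_class = 40, seed = 5) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- array(rnorm(192 * n, 0, 0.1), dim = c(192, 1, n))
    X[, , 1:n_per_class] <- X[, , 1:n_per_class] + 1
    X[, , (n_per_class + 1):n] <- X[, , (n_per_class + 1):n] - 1
    list(X = X, y = factor(rep(c("A", "B"), each = n_per_class)))
  })
}
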