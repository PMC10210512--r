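# Shared fixtures and utilities. All fixtures are generated in code.

# central-difference gradient of f: R^n -> R at x (vector view)
num_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# check a tape-built scalar loss against numeric gradients on one leaf
expect_tape_grad <- function(build, value, tol = 1e-5, h = 1e-5) {
  tp <- ocra:::new_tape()
  leaf <- ocra:::tp_leaf(tp, value)
  loss <- build(tp, leaf)
  ocra::tp_backward(tp, loss)
  f <- function(v) {
    tp2 <- ocra:::new_tape()
    l2 <- ocra:::tp_leaf(tp2, array(v, dim = dim(value)))
    as.numeric(build(tp2, l2)$value)
  }
  ng <- num_grad(f, as.numeric(value), h = h)
  expect_lt(max(abs(as.numeric(leaf$grad) - ng)), tol)
}

tiny_config <- function(task = "multimnist", variant = "full", ...) {
  ocra_config(task, variant = variant, recurrent_size = 24L,
              n_primary = 5L, primary_dim = 4L, class_dim = 6L,
              glimpse_size = 10L, patch_size = 10L,
              timesteps = if (variant == "feedforward") 1L else 2L, ...)
}

# random pose whose filter grid keeps substantial mass on the image (far
# off-image rows underflow to zero under the documented eps-floor, so
# row-stochasticity is only meaningful for on-image windows)
random_pose <- function(image_shape = c(36, 36), grid_size = 18) {
  attention_pose(c(stats::runif(2, -0.3, 0.3), stats::runif(1, -1.5, -0.4),
                   stats::runif(1, -0.5, 0.5)),
                 image_shape, grid_size)
}

# small shared glyph source (built once per test run)
glyph_cache <- local({
  env <- new.env()
  function(n = 120, seed = 1, split = "train") {
    key <- paste(n, seed, split, sep = "_")
    if (is.null(env[[key]]))
      env[[key]] <- gen_fixture_glyphs(n, seed = seed, split = split)
    env[[key]]
  }
})
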