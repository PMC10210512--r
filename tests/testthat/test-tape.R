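# Every autodiff primitive is validated against central differences; the
# composites (LSTM step, CNN stack) are covered through the same harness.

test_that("elementwise and linear-algebra primitives backpropagate correctly", {
  set.seed(11)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)

  expect_tape_grad(function(tp, x)
    ocra:::t_sum(tp, ocra:::t_matmul(tp, x, ocra:::tp_const(tp, B))), A)
  expect_tape_grad(function(tp, x)
    ocra:::t_sum(tp, ocra:::t_mul(tp, x, ocra:::tp_const(tp, A + 1))), A)
  expect_tape_grad(function(tp, x)
    ocra:::t_sum(tp, ocra:::t_tanh(tp, x)), A)
  expect_tape_grad(function(tp, x)
    ocra:::t_sum(tp, ocra:::t_sigmoid(tp, x)), A)
  expect_tape_grad(function(tp, x)
    ocra:::t_sum(tp, ocra:::t_exp(tp, ocra:::t_scale(tp, x, 0.5))), A)
  expect_tape_grad(function(tp, x)
    ocra:::t_mean(tp, ocra:::t_mul(tp, x, x)), A)
  expect_tape_grad(function(tp, x) {
    y <- ocra:::t_cbind(tp, ocra:::t_cols(tp, x, 2:3), x)
    ocra:::t_sum(tp, ocra:::t_mul(tp, y, y))
  }, A)
  expect_tape_grad(function(tp, x) {
    y <- ocra:::t_reshape(tp, x, 4, 3)
    ocra:::t_sum(tp, ocra:::t_matmul(tp, y, ocra:::tp_const(tp, A)))
  }, A)
  # relu at points away from the kink
  Ar <- A + sign(A) * 0.3
  expect_tape_grad(function(tp, x)
    ocra:::t_sum(tp, ocra:::t_relu(tp, x)), Ar)
})

test_that("conv2d and maxpool2 backpropagate correctly", {
  set.seed(12)
  H <- 6L; W <- 6L; cin <- 2L; cout <- 3L; k <- 3L
  x <- matrix(rnorm(H * W * cin), H * W, cin)
  w <- matrix(rnorm(k * k * cin * cout, sd = 0.5), k * k * cin, cout)
  b <- matrix(rnorm(cout), 1, cout)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_conv2d(tp, v, ocra:::tp_const(tp, w),
                                     ocra:::tp_const(tp, b), H, W, k)), x)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_conv2d(tp, ocra:::tp_const(tp, x), v,
                                     ocra:::tp_const(tp, b), H, W, k)), w)
  # pooling: perturbations small enough not to change the argmax
  xp <- x + matrix(seq_len(H * W * cin) * 1e-3, H * W, cin)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_maxpool2(tp, v, H, W)), xp, h = 1e-6)
})

test_that("attention-filter primitives backpropagate correctly", {
  set.seed(13)
  offs <- ocra:::filter_offsets(6)
  pose_raw <- matrix(c(14.2, 1.7, 1.3), 1)  # center, stride, variance
  wconst <- matrix(rnorm(6 * 20), 6, 20)
  build <- function(tp, v) {
    ctr <- ocra:::t_cols(tp, v, 1L)
    str <- ocra:::t_cols(tp, v, 2L)
    vv <- ocra:::t_cols(tp, v, 3L)
    mu <- ocra:::t_filter_centers(tp, ctr, str, offs)
    Fm <- ocra:::t_gauss_filters(tp, mu, vv, 20L)
    ocra:::t_sum(tp, ocra:::t_mul(tp, Fm, ocra:::tp_const(tp, wconst)))
  }
  expect_tape_grad(build, pose_raw, tol = 1e-4)
})

test_that("capsule primitives backpropagate correctly", {
  set.seed(15)
  K <- 3L; D <- 4L; P <- 5L; pd <- 2L
  d <- matrix(rnorm(K * D), K, D)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_mul(tp, ocra:::t_squash_rows(tp, v),
                                  ocra:::tp_const(tp, d + 2))), d)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_rownorm(tp, v)), d)

  raw <- matrix(rnorm(P * K), P, K)
  wmat <- matrix(rnorm(P * K), P, K)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_mul(tp, ocra:::t_maxmin_rows(tp, v),
                                  ocra:::tp_const(tp, wmat))), raw,
    tol = 1e-4)

  prim <- matrix(rnorm(P * pd), P, pd)
  Warr <- array(rnorm(pd * K * D * P, sd = 0.5), dim = c(pd, K * D, P))
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_caps_predict(tp, v, ocra:::tp_const(tp, Warr))),
    prim)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_caps_predict(tp, ocra:::tp_const(tp, prim), v)),
    Warr)

  uhat <- matrix(rnorm(P * K * D), P, K * D)
  cpl <- matrix(runif(P * K, 0.1, 1), P, K)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_route_mix(tp, v, ocra:::tp_const(tp, cpl),
                                        K, D)), uhat)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_route_mix(tp, ocra:::tp_const(tp, uhat), v,
                                        K, D)), cpl)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_agree(tp, v, ocra:::tp_const(tp, d), K, D)),
    uhat)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_agree(tp, ocra:::tp_const(tp, uhat), v, K, D)),
    d)

  mags <- sqrt(rowSums(d * d))
  wv <- matrix(rnorm(K * D), 1, K * D)
  expect_tape_grad(function(tp, v)
    ocra:::t_sum(tp, ocra:::t_mul(tp, ocra:::t_mask_argmax(tp, v, mags),
                                  ocra:::tp_const(tp, wv))), d)
})

test_that("an LSTM step backpropagates through state and weights", {
  set.seed(16)
  hs <- 4L; ins <- 3L
  x <- matrix(rnorm(ins), 1)
  Wx <- matrix(rnorm(ins * 4 * hs, sd = 0.5), ins, 4 * hs)
  Wh <- matrix(rnorm(hs * 4 * hs, sd = 0.5), hs, 4 * hs)
  b <- matrix(rnorm(4 * hs, sd = 0.2), 1)
  h0 <- matrix(rnorm(hs), 1); c0 <- matrix(rnorm(hs), 1)
  run <- function(tp, xn, Wxn) {
    st <- ocra:::t_lstm_step(tp, xn, ocra:::tp_const(tp, h0),
                             ocra:::tp_const(tp, c0), Wxn,
                             ocra:::tp_const(tp, Wh),
                             ocra:::tp_const(tp, b), hs)
    st2 <- ocra:::t_lstm_step(tp, xn, st$h, st$c, Wxn,
                              ocra:::tp_const(tp, Wh),
                              ocra:::tp_const(tp, b), hs)
    ocra:::t_sum(tp, ocra:::t_mul(tp, st2$h, st2$h))
  }
  expect_tape_grad(function(tp, v)
    run(tp, v, ocra:::tp_const(tp, Wx)), x)
  expect_tape_grad(function(tp, v)
    run(tp, ocra:::tp_const(tp, x), v), Wx)
})

test_that("the tape rejects non-finite intermediate values", {
  tp <- ocra:::new_tape()
  x <- ocra:::tp_leaf(tp, matrix(c(1, 900), 1))
  expect_error(ocra:::t_exp(tp, x), "non-finite")
})
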