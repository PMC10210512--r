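# Capsule routing: normalization, squash, routing vs. an independent
# straight-line oracle, masking.

# Independent transcription of the routing update equations, written
# against the stated algorithm (not the package code): per iteration,
# normalize accumulators per primary capsule, mix predictions, squash,
# add agreements. Scalar loops only.
oracle_route <- function(primary, transforms, iterations = 3,
                         lb = 0.01, ub = 1.0) {
  P <- nrow(primary); pd <- ncol(primary)
  cd <- dim(transforms)[2]; K <- dim(transforms)[4]
  uhat <- array(0, c(P, K, cd))
  for (i in 1:P) for (j in 1:K) for (dd in 1:cd) {
    acc <- 0
    for (q in 1:pd) acc <- acc + primary[i, q] * transforms[q, dd, i, j]
    uhat[i, j, dd] <- acc
  }
  b <- matrix(0, P, K)
  for (it in 1:iterations) {
    cc <- matrix(0, P, K)
    for (i in 1:P) {
      mx <- max(b[i, ]); mn <- min(b[i, ])
      if (mx - mn < 1e-12) cc[i, ] <- (lb + ub) / 2
      else cc[i, ] <- lb + (ub - lb) * (b[i, ] - mn) / (mx - mn)
    }
    v <- matrix(0, K, cd)
    for (j in 1:K) for (dd in 1:cd)
      for (i in 1:P) v[j, dd] <- v[j, dd] + cc[i, j] * uhat[i, j, dd]
    d <- matrix(0, K, cd)
    for (j in 1:K) {
      s2 <- sum(v[j, ]^2)
      d[j, ] <- (s2 / (1 + s2)) * v[j, ] / sqrt(s2 + 1e-9)
    }
    for (i in 1:P) for (j in 1:K) {
      ag <- 0
      for (dd in 1:cd) ag <- ag + d[j, dd] * uhat[i, j, dd]
      b[i, j] <- b[i, j] + ag
    }
  }
  list(post_squash = d, couplings = cc, raw = b)
}

test_that("max-min normalization maps rows onto [lb, ub] as printed", {
  expect_equal(maxmin_normalize(c(0.2, 0.5, 0.8)), c(0.01, 0.505, 1.0))
  expect_equal(maxmin_normalize(c(0, 1)), c(0.01, 1.0))
  expect_equal(maxmin_normalize(c(3, 3, 3)), rep(0.505, 3))
  expect_error(maxmin_normalize(c(1, NaN)), "finite")
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(2:10, 1))
    y <- maxmin_normalize(x)
    if (max(x) - min(x) >= 1e-12) {
      expect_equal(max(y), 1.0)
      expect_equal(min(y), 0.01)
    }
    expect_true(all(y >= 0.01 & y <= 1.0))
  }
})

test_that("squash matches its closed form and stays below unit norm", {
  expect_equal(squash(c(3, 4)), c(15 / 26, 20 / 26), tolerance = 1e-7)
  expect_equal(sqrt(sum(squash(c(3, 4))^2)), 25 / 26, tolerance = 1e-7)
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- c(60, 80)  # norm 100
  expect_equal(sqrt(sum(squash(v)^2)), 10000 / 10001, tolerance = 1e-7)
  set.seed(32)
  m <- matrix(rnorm(1e4 * 4, sd = 10), ncol = 4)
  mags <- sqrt(rowSums(squash(m)^2))
  expect_true(all(mags < 1))
  # squashed vectors stay parallel to their inputs
  sq <- squash(m)
  cosang <- rowSums(sq * m) / (sqrt(rowSums(sq^2)) * sqrt(rowSums(m^2)))
  expect_true(all(abs(cosang - 1) < 1e-8))
})

test_that("route matches the independent oracle on 100 random instances", {
  set.seed(33)
  for (rep in 1:100) {
    P <- sample(2:4, 1); K <- sample(2:3, 1)
    pd <- sample(2:3, 1); cd <- sample(2:4, 1)
    primary <- matrix(rnorm(P * pd), P, pd)
    W <- array(rnorm(pd * cd * P * K), c(pd, cd, P, K))
    got <- route_capsules(primary, W, iterations = 3)
    want <- oracle_route(primary, W, iterations = 3)
    expect_lt(max(abs(got$post_squash - want$post_squash)), 1e-6)
    expect_lt(max(abs(got$couplings - want$couplings)), 1e-6)
    expect_lt(max(abs(got$raw - want$raw)), 1e-6)
    expect_true(all(got$magnitudes < 1))
    expect_true(all(got$couplings >= 0.01 & got$couplings <= 1.0))
  }
})

test_that("agreeing predictions capture full coupling, orthogonal ones lose it", {
  set.seed(34)
  P <- 6L; pd <- 2L; cd <- 4L
  primary <- matrix(1, P, pd)
  # class 1 predictions: identical vector u for every primary capsule;
  # class 2: random vectors orthogonal to u (they cancel in the mix)
  u <- c(2, 0, 0, 0)
  W <- array(0, c(pd, cd, P, 2))
  for (i in 1:P) {
    W[1, , i, 1] <- u / 2  # primary rows are (1,1): u = p_i %*% W
    w2 <- c(0, rnorm(cd - 1))
    W[1, , i, 2] <- w2 / 2
  }
  out <- route_capsules(primary, W, iterations = 3)
  expect_true(all(out$couplings[, 1] == 1.0))
  expect_true(all(out$couplings[, 2] == 0.01))
})

test_that("a single routing pass is uniform at the coupling midpoint", {
  set.seed(35)
  primary <- matrix(rnorm(8), 4, 2)
  W <- array(rnorm(2 * 3 * 4 * 2), c(2, 3, 4, 2))
  out <- route_capsules(primary, W, iterations = 1)
  expect_true(all(out$couplings == 0.505))
})

test_that("routing is equivariant under primary-capsule permutation", {
  set.seed(36)
  P <- 4L
  primary <- matrix(rnorm(P * 3), P, 3)
  W <- array(rnorm(3 * 4 * P * 3), c(3, 4, P, 3))
  perm <- sample(P)
  out1 <- route_capsules(primary, W)
  out2 <- route_capsules(primary[perm, , drop = FALSE],
                         W[, , perm, , drop = FALSE])
  expect_equal(out2$post_squash, out1$post_squash, tolerance = 1e-12)
  expect_equal(out2$couplings, out1$couplings[perm, ], tolerance = 1e-12)
})

test_that("mask_most_active keeps only the winning block with stated ties", {
  d <- rbind(c(0.3, 0.4), c(0.05, 0.05), c(0.1, 0))
  out <- mask_most_active(d)
  expect_equal(out, c(0.3, 0.4, 0, 0, 0, 0))
  # all-zero capsules: zero vector, block 1 selected by the tie rule
  expect_equal(mask_most_active(matrix(0, 3, 2)), rep(0, 6))
  # exact two-way tie keeps the lower-index block
  d2 <- rbind(c(0.3, 0.4), c(0.4, 0.3))
  expect_equal(mask_most_active(d2), c(0.3, 0.4, 0, 0))
})

test_that("tape-side routing agrees with the plain implementation", {
  set.seed(37)
  P <- 5L; pd <- 3L; cd <- 4L; K <- 3L
  primary <- matrix(rnorm(P * pd), P, pd)
  W4 <- array(rnorm(pd * cd * P * K), c(pd, cd, P, K))
  plain <- route_capsules(primary, W4, iterations = 3)
  # tape layout: (pd, K*cd, P) with class blocks along columns
  Wt <- array(0, c(pd, K * cd, P))
  for (i in 1:P) for (j in 1:K)
    Wt[, (j - 1) * cd + seq_len(cd), i] <- W4[, , i, j]
  tp <- ocra:::new_tape()
  pm <- ocra:::tp_const(tp, primary)
  uhat <- ocra:::t_caps_predict(tp, pm, ocra:::tp_const(tp, Wt))
  rt <- ocra:::tape_route(tp, uhat, P, K, cd, 3L, 0.01, 1.0)
  expect_equal(rt$d$value, plain$post_squash, tolerance = 1e-12)
  expect_equal(rt$couplings$value, plain$couplings, tolerance = 1e-12)
  expect_equal(as.numeric(rt$mags$value), plain$magnitudes,
               tolerance = 1e-6)
})
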