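# Vector capsules: max-min normalized dynamic routing by agreement.
#
# A capsule is a vector whose magnitude codes the presence of a visual
# entity and whose orientation codes its properties. Primary ("part")
# capsules are read linearly from the encoder state; class ("whole",
# object-file) capsules are formed by iteratively routing primary-capsule
# predictions by agreement. Unlike the softmax of classic dynamic routing,
# coupling coefficients here are max-min normalized onto [lb, ub] across the
# class dimension, which keeps them well differentiated.

#' Max-min normalize coupling coefficients onto [lb, ub]
#'
#' `out = lb + (ub - lb) * (x - min) / (max - min)` applied per primary
#' capsule across the class dimension, so for every non-degenerate row the
#' maximum maps exactly to `ub` and the minimum exactly to `lb`. Degenerate
#' rows (`max - min < 1e-12`, e.g. the all-zero accumulator on the first
#' routing pass) map to the constant midpoint `(lb + ub) / 2`, giving
#' uniform routing.
#'
#' @param x numeric vector, or matrix normalized rowwise.
#' @param lb,ub normalization bounds; defaults 0.01 and 1.0.
#' @return Same shape as `x`, entries in `[lb, ub]`.
#' @export
#' @examples
#' maxmin_normalize(c(0.2, 0.5, 0.8))  # 0.01, 0.505, 1.0
maxmin_normalize <- function(x, lb = 0.01, ub = 1.0) {
  if (any(!is.finite(x)))
    stop("non-finite coupling coefficients", call. = FALSE)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1) else x
  mx <- apply(m, 1, max); mn <- apply(m, 1, min)
  r <- mx - mn
  deg <- r < 1e-12
  # divide before scaling so the row maximum maps to ub exactly
  out <- lb + (ub - lb) * ((m - mn) / ifelse(deg, 1, r))
  out[deg, ] <- (lb + ub) / 2
  if (vec) as.numeric(out) else out
}

#' Squash nonlinearity for class capsules
#'
#' `squash(v) = (||v||^2 / (1 + ||v||^2)) * v / ||v||` with an eps-guarded
#' norm: the output is parallel to the input with magnitude in `[0, 1)`, so
#' a capsule magnitude can be read as the probability that its entity is
#' present in the current glimpse. The zero vector maps to zero.
#'
#' @param v numeric vector, or matrix squashed rowwise.
#' @param eps guard added under the square root; default 1e-9.
#' @return Same shape as `v`.
#' @export
#' @examples
#' squash(c(3, 4))          # magnitude 25/26
squash <- function(v, eps = 1e-9) {
  vec <- is.null(dim(v))
  m <- if (vec) matrix(v, 1) else v
  s2 <- rowSums(m * m)
  out <- m * (s2 / ((1 + s2) * sqrt(s2 + eps)))
  if (vec) as.numeric(out) else out
}

#' Route primary capsules to class capsules by agreement
#'
#' Predictions `u_hat[i, j, ] = primary[i, ] %*% transforms[, , i, j]` are
#' combined into class capsules over `iterations` rounds. Each round: the
#' raw agreement accumulators are max-min normalized per primary capsule
#' into coupling coefficients `c_ij`; the pre-squash class capsule is
#' `v_j = sum_i c_ij * u_hat[i, j, ]`; `d_j = squash(v_j)`; the accumulator
#' is then incremented by the agreement `d_j . u_hat[i, j, ]`. Accumulators
#' start at zero, so the first round routes uniformly (coupling midpoint).
#'
#' @param primary P x pd matrix of primary capsules (not squashed).
#' @param transforms 4-d array `(pd, cd, P, K)` of per-pair prediction
#'   transforms (no bias terms).
#' @param iterations routing rounds; default 3.
#' @param lb,ub coupling normalization bounds.
#' @return List of class `"class_capsules"`: `pre_squash` (K x cd),
#'   `post_squash` (K x cd), `magnitudes` (K, each in `[0, 1)`),
#'   `couplings` (P x K, the coefficients that produced the returned
#'   capsules) and `raw` (P x K final accumulators).
#' @export
route_capsules <- function(primary, transforms, iterations = 3,
                           lb = 0.01, ub = 1.0) {
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  dm <- dim(transforms)
  P <- nrow(primary); pd <- ncol(primary)
  if (length(dm) != 4L || dm[1] != pd || dm[3] != P)
    stop("transform array does not match primary capsules", call. = FALSE)
  cd <- dm[2]; K <- dm[4]
  uhat <- array(0, dim = c(P, K, cd))
  for (i in seq_len(P))
    for (j in seq_len(K))
      uhat[i, j, ] <- primary[i, ] %*% transforms[, , i, j]
  raw <- matrix(0, P, K)
  cpl <- v <- d <- NULL
  for (it in seq_len(iterations)) {
    cpl <- maxmin_normalize(raw, lb, ub)
    v <- matrix(0, K, cd)
    for (j in seq_len(K))
      v[j, ] <- crossprod(matrix(uhat[, j, ], P, cd), cpl[, j])
    d <- squash(v)
    agree <- matrix(0, P, K)
    for (j in seq_len(K))
      agree[, j] <- matrix(uhat[, j, ], P, cd) %*% d[j, ]
    raw <- raw + agree
  }
  structure(list(pre_squash = v, post_squash = d,
                 magnitudes = sqrt(rowSums(d * d)),
                 couplings = cpl, raw = raw),
            class = "class_capsules")
}

#' Mask all but the most active class capsule
#'
#' Concatenates the K post-squash capsule vectors into one flat vector of
#' length `K * cd`, zeroing every block except the capsule with the largest
#' magnitude (ties broken by lowest index). This is the object-file
#' bottleneck: only one object's bound representation is forwarded to the
#' decoder per timestep.
#'
#' @param capsules a `"class_capsules"` object or a K x cd matrix.
#' @param magnitudes optional magnitudes (computed if missing).
#' @return numeric vector of length `K * cd`.
#' @export
mask_most_active <- function(capsules, magnitudes = NULL) {
  d <- if (inherits(capsules, "class_capsules")) capsules$post_squash else capsules
  if (is.null(magnitudes))
    magnitudes <- if (inherits(capsules, "class_capsules"))
      capsules$magnitudes else sqrt(rowSums(d * d))
  K <- nrow(d); cd <- ncol(d)
  w <- which.max(magnitudes)   # first maximum = lowest-index tie break
  out <- numeric(K * cd)
  out[(w - 1L) * cd + seq_len(cd)] <- d[w, ]
  out
}
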