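# Minimal reverse-mode autodiff on a linear tape.
#
# Nodes hold plain numeric arrays (usually matrices). The tape records nodes
# in creation order, which is a topological order of the forward graph, so
# the backward pass is a single reverse sweep. Every primitive's gradient is
# checked against central differences in test-tape.R.

#' Create a fresh autodiff tape
#'
#' A tape records every operation applied to its nodes so that
#' [tp_backward()] can compute gradients of a scalar node with respect to any
#' leaf. Tapes are cheap; training builds one per sample.
#'
#' @return An environment of class `"ocra_tape"`.
#' @keywords internal
#' @export
new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  class(tp) <- "ocra_tape"
  tp
}

tp_register <- function(tape, value, parents = list(), backward = NULL,
                        leaf = FALSE) {
  # leaves (parameters) are validated by the optimizer's NaN halt instead;
  # checking multi-megabyte arrays per sample dominates runtime
  if (!leaf && !all(is.finite(value)))
    stop("non-finite value entered the computation graph", call. = FALSE)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$leaf <- leaf
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

#' @rdname new_tape
#' @param tape a tape from [new_tape()]
#' @param value numeric array
#' @export
tp_const <- function(tape, value) tp_register(tape, value)

#' @rdname new_tape
#' @export
tp_leaf <- function(tape, value) tp_register(tape, value, leaf = TRUE)

#' Reverse sweep: accumulate gradients of `loss` into every reachable node
#'
#' @param tape the tape that recorded the forward pass
#' @param loss a 1x1 node on `tape`
#' @keywords internal
#' @export
tp_backward <- function(tape, loss) {
  n <- tape$n
  for (i in seq_len(n)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- array(1, dim = dim(as.matrix(loss$value)))
  for (i in rev(seq_len(n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# ---- elementwise & linear algebra primitives --------------------------------

t_add <- function(tape, a, b) {
  tp_register(tape, a$value + b$value, list(a, b),
              function(g) list(g, g))
}

t_sub <- function(tape, a, b) {
  tp_register(tape, a$value - b$value, list(a, b),
              function(g) list(g, -g))
}

t_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  tp_register(tape, av * bv, list(a, b),
              function(g) list(g * bv, g * av))
}

# scale / shift by plain constants
t_scale <- function(tape, a, k) {
  tp_register(tape, a$value * k, list(a), function(g) list(g * k))
}

t_shift <- function(tape, a, k) {
  tp_register(tape, a$value + k, list(a), function(g) list(g))
}

# elementwise multiply by a constant array (e.g. a fixed mask)
t_cmul <- function(tape, a, m) {
  tp_register(tape, a$value * m, list(a), function(g) list(g * m))
}

t_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  tp_register(tape, av %*% bv, list(a, b),
              function(g) list(tcrossprod(g, bv), crossprod(av, g)))
}

t_transpose <- function(tape, a) {
  tp_register(tape, t(a$value), list(a), function(g) list(t(g)))
}

t_tanh <- function(tape, a) {
  y <- tanh(a$value)
  tp_register(tape, y, list(a), function(g) list(g * (1 - y * y)))
}

t_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$value))
  tp_register(tape, y, list(a), function(g) list(g * y * (1 - y)))
}

t_relu <- function(tape, a) {
  v <- a$value
  y <- pmax(v, 0)
  tp_register(tape, y, list(a), function(g) list(g * (v > 0)))
}

t_exp <- function(tape, a) {
  y <- exp(a$value)
  tp_register(tape, y, list(a), function(g) list(g * y))
}

t_sum <- function(tape, a) {
  d <- dim(a$value)
  tp_register(tape, matrix(sum(a$value), 1, 1), list(a),
              function(g) list(array(as.numeric(g), dim = d)))
}

t_mean <- function(tape, a) {
  d <- dim(a$value); nl <- length(a$value)
  tp_register(tape, matrix(mean(a$value), 1, 1), list(a),
              function(g) list(array(as.numeric(g) / nl, dim = d)))
}

t_cols <- function(tape, a, idx) {
  d <- dim(a$value)
  tp_register(tape, a$value[, idx, drop = FALSE], list(a),
              function(g) {
                out <- matrix(0, d[1], d[2])
                out[, idx] <- g
                list(out)
              })
}

t_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  tp_register(tape, cbind(a$value, b$value), list(a, b),
              function(g) list(g[, seq_len(na), drop = FALSE],
                               g[, -seq_len(na), drop = FALSE]))
}

t_reshape <- function(tape, a, nr, nc) {
  d <- dim(a$value)
  tp_register(tape, matrix(as.numeric(a$value), nr, nc), list(a),
              function(g) list(matrix(as.numeric(g), d[1], d[2])))
}

# ---- convolution / pooling --------------------------------------------------

# feature maps are stored as (H*W) x C matrices with R's column-major
# linearization of the H x W plane (index = r + (col-1)*H)

.conv_idx_cache <- new.env(parent = emptyenv())

conv_im2col_index <- function(H, W, k) {
  key <- paste(H, W, k, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L          # 'same' padding, odd k
  npix <- H * W
  pad_id <- npix + 1L           # extra zero row stands in for padding
  idx <- matrix(pad_id, npix, k * k)
  q <- 0L
  for (dc in seq_len(k) - 1L - p) {
    for (dr in seq_len(k) - 1L - p) {
      q <- q + 1L
      rr <- rep(seq_len(H), W) + dr
      cc <- rep(seq_len(W), each = H) + dc
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      col <- rep(pad_id, npix)
      col[ok] <- rr[ok] + (cc[ok] - 1L) * H
      idx[, q] <- col
    }
  }
  .conv_idx_cache[[key]] <- idx
  idx
}

# x: (H*W) x Cin node, w: (k*k*Cin) x Cout leaf, b: 1 x Cout leaf
t_conv2d <- function(tape, x, w, b, H, W, k) {
  cin <- ncol(x$value)
  idx <- conv_im2col_index(H, W, k)
  k2 <- k * k
  npix <- H * W
  xpad <- rbind(x$value, 0)
  col <- matrix(0, npix, k2 * cin)
  for (c in seq_len(cin)) {
    xc <- xpad[, c]
    col[, (c - 1L) * k2 + seq_len(k2)] <- matrix(xc[idx], npix, k2)
  }
  wv <- w$value
  y <- col %*% wv
  y <- sweep(y, 2, as.numeric(b$value), "+")
  tp_register(tape, y, list(x, w, b), function(g) {
    dw <- crossprod(col, g)
    db <- matrix(colSums(g), 1)
    dcol <- tcrossprod(g, wv)
    dxpad <- matrix(0, npix + 1L, cin)
    for (c in seq_len(cin)) {
      for (q in seq_len(k2)) {
        dxpad[idx[, q], c] <- dxpad[idx[, q], c] + dcol[, (c - 1L) * k2 + q]
      }
    }
    list(dxpad[seq_len(npix), , drop = FALSE], dw, db)
  })
}

.pool_idx_cache <- new.env(parent = emptyenv())

pool_index <- function(H, W) {
  key <- paste(H, W, sep = "_")
  hit <- .pool_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r0 <- rep(2L * seq_len(Ho) - 1L, Wo)
  c0 <- rep(2L * seq_len(Wo) - 1L, each = Ho)
  lin <- function(r, c) r + (c - 1L) * H
  out <- list(Ho = Ho, Wo = Wo,
              i = cbind(lin(r0, c0), lin(r0 + 1L, c0),
                        lin(r0, c0 + 1L), lin(r0 + 1L, c0 + 1L)))
  .pool_idx_cache[[key]] <- out
  out
}

# 2x2 max pool, stride 2, trailing row/col dropped when odd
t_maxpool2 <- function(tape, x, H, W) {
  pi <- pool_index(H, W)
  C <- ncol(x$value)
  xv <- x$value
  best <- xv[pi$i[, 1], , drop = FALSE]
  argm <- matrix(1L, nrow(best), C)
  for (q in 2:4) {
    cand <- xv[pi$i[, q], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    argm[upd] <- q
  }
  npix <- H * W
  tp_register(tape, best, list(x), function(g) {
    dx <- matrix(0, npix, C)
    for (q in 1:4) {
      sel <- argm == q
      if (!any(sel)) next
      rows <- pi$i[, q]
      for (c in seq_len(C)) {
        s <- sel[, c]
        if (any(s)) dx[rows[s], c] <- dx[rows[s], c] + g[s, c]
      }
    }
    list(dx)
  })
}

# ---- attention filter primitives -------------------------------------------

# filter centers mu_i = center + offs_i * stride ; center, stride 1x1 nodes
t_filter_centers <- function(tape, center, stride, offs) {
  cv <- as.numeric(center$value); sv <- as.numeric(stride$value)
  tp_register(tape, matrix(cv + offs * sv, 1), list(center, stride),
              function(g) list(matrix(sum(g), 1, 1),
                               matrix(sum(g * offs), 1, 1)))
}

# N x L row-normalized Gaussian filter matrix from centers mu (1xN) and
# variance (1x1); eps floors the normalizer (off-image centers)
t_gauss_filters <- function(tape, mu, var, len, eps = 1e-8) {
  muv <- as.numeric(mu$value)
  vv <- as.numeric(var$value)
  ax <- seq_len(len)
  D <- outer(muv, ax, function(m, a) a - m)       # N x L, a - mu_i
  G <- exp(-D * D / (2 * vv))
  s <- rowSums(G) + eps
  F <- G / s
  tp_register(tape, F, list(mu, var), function(g) {
    # through the row normalization
    dG <- g / s - (rowSums(g * G) / (s * s))
    dmu <- rowSums(dG * G * (-D) / vv) * (-1)     # dD/dmu = -1 => dG/dmu = G*D/vv
    dvar <- sum(dG * G * D * D / (2 * vv * vv))
    list(matrix(dmu, 1), matrix(dvar, 1, 1))
  })
}

# ---- capsule primitives -----------------------------------------------------

# squash every row: y = (s2/(1+s2)) * x / sqrt(s2 + eps)
t_squash_rows <- function(tape, x, eps = 1e-9) {
  xv <- x$value
  s2 <- rowSums(xv * xv)
  nrm <- sqrt(s2 + eps)
  alpha <- s2 / ((1 + s2) * nrm)
  y <- xv * alpha
  tp_register(tape, y, list(x), function(g) {
    # y = alpha(s2) x ; dy/dx = alpha I + 2 alpha'(s2) x x^T (rowwise)
    da <- alpha * (1 / pmax(s2, 1e-300) - 1 / (1 + s2) - 1 / (2 * (s2 + eps)))
    da[s2 < 1e-30] <- 0
    gx <- rowSums(g * xv)
    list(g * alpha + xv * (2 * da * gx))
  })
}

# rowwise L2 norm (K x D -> K x 1), eps-guarded
t_rownorm <- function(tape, x, eps = 1e-12) {
  xv <- x$value
  nrm <- sqrt(rowSums(xv * xv) + eps)
  tp_register(tape, matrix(nrm, ncol = 1), list(x), function(g) {
    list(xv * (as.numeric(g) / nrm))
  })
}

# rowwise max-min normalization onto [lb, ub]; degenerate rows map to the
# constant (lb+ub)/2 and carry zero gradient
t_maxmin_rows <- function(tape, x, lb = 0.01, ub = 1.0, tol = 1e-12) {
  xv <- x$value
  P <- nrow(xv); K <- ncol(xv)
  imax <- max.col(xv, ties.method = "first")
  imin <- max.col(-xv, ties.method = "first")
  mx <- xv[cbind(seq_len(P), imax)]
  mn <- xv[cbind(seq_len(P), imin)]
  r <- mx - mn
  deg <- r < tol
  y <- lb + (ub - lb) * ((xv - mn) / ifelse(deg, 1, r))
  y[deg, ] <- (lb + ub) / 2
  tp_register(tape, y, list(x), function(g) {
    dx <- g * ((ub - lb) / r)
    rs <- rowSums(g)
    wsum <- rowSums(g * (xv - mn))          # sum_k g_k (x_k - mn)
    dx[cbind(seq_len(P), imin)] <- dx[cbind(seq_len(P), imin)] -
      (ub - lb) * rs / r + (ub - lb) * wsum / (r * r)
    dx[cbind(seq_len(P), imax)] <- dx[cbind(seq_len(P), imax)] -
      (ub - lb) * wsum / (r * r)
    dx[deg, ] <- 0
    list(dx)
  })
}

# capsule predictions: primary (P x pd), W 3-d array (pd, K*cd, P)
# uhat[i, ] = primary[i, ] %*% W[, , i]
t_caps_predict <- function(tape, primary, W) {
  pv <- primary$value
  Wv <- W$value
  P <- nrow(pv); KD <- dim(Wv)[2]
  uhat <- matrix(0, P, KD)
  for (i in seq_len(P)) uhat[i, ] <- pv[i, ] %*% Wv[, , i]
  tp_register(tape, uhat, list(primary, W), function(g) {
    dp <- matrix(0, P, ncol(pv))
    dW <- array(0, dim = dim(Wv))
    for (i in seq_len(P)) {
      gi <- g[i, ]
      dp[i, ] <- Wv[, , i] %*% gi
      dW[, , i] <- outer(pv[i, ], gi)
    }
    list(dp, dW)
  })
}

# mix predictions into class capsules: v[j, ] = sum_i c[i, j] * uhat[i, blk_j]
t_route_mix <- function(tape, uhat, cpl, K, D) {
  uv <- uhat$value; cv <- cpl$value
  v <- matrix(0, K, D)
  for (j in seq_len(K)) {
    blk <- (j - 1L) * D + seq_len(D)
    v[j, ] <- crossprod(uv[, blk, drop = FALSE], cv[, j])
  }
  tp_register(tape, v, list(uhat, cpl), function(g) {
    du <- matrix(0, nrow(uv), ncol(uv))
    dc <- matrix(0, nrow(cv), ncol(cv))
    for (j in seq_len(K)) {
      blk <- (j - 1L) * D + seq_len(D)
      du[, blk] <- outer(cv[, j], g[j, ])
      dc[, j] <- uv[, blk, drop = FALSE] %*% g[j, ]
    }
    list(du, dc)
  })
}

# agreement: A[i, j] = uhat[i, blk_j] . d[j, ]
t_agree <- function(tape, uhat, d, K, D) {
  uv <- uhat$value; dv <- d$value
  A <- matrix(0, nrow(uv), K)
  for (j in seq_len(K)) {
    blk <- (j - 1L) * D + seq_len(D)
    A[, j] <- uv[, blk, drop = FALSE] %*% dv[j, ]
  }
  tp_register(tape, A, list(uhat, d), function(g) {
    du <- matrix(0, nrow(uv), ncol(uv))
    dd <- matrix(0, K, D)
    for (j in seq_len(K)) {
      blk <- (j - 1L) * D + seq_len(D)
      du[, blk] <- outer(g[, j], dv[j, ])
      dd[j, ] <- crossprod(uv[, blk, drop = FALSE], g[, j])
    }
    list(du, dd)
  })
}

# keep only the most-active capsule's block (ties -> lowest index); the
# magnitudes drive selection only, so gradient flows through d alone
t_mask_argmax <- function(tape, d, magnitudes) {
  dv <- d$value
  K <- nrow(dv); D <- ncol(dv)
  w <- which.max(magnitudes)           # first max = lowest-index tie break
  out <- matrix(0, 1, K * D)
  blk <- (w - 1L) * D + seq_len(D)
  out[1, blk] <- dv[w, ]
  tp_register(tape, out, list(d), function(g) {
    dd <- matrix(0, K, D)
    dd[w, ] <- g[1, blk]
    list(dd)
  })
}

# ---- composite: one LSTM step (single combined bias per gate stack) --------

t_lstm_step <- function(tape, x, h_prev, c_prev, Wx, Wh, b, hsize) {
  z <- t_add(tape, t_add(tape, t_matmul(tape, x, Wx),
                         t_matmul(tape, h_prev, Wh)), b)
  i_g <- t_sigmoid(tape, t_cols(tape, z, seq_len(hsize)))
  f_g <- t_sigmoid(tape, t_cols(tape, z, hsize + seq_len(hsize)))
  g_g <- t_tanh(tape, t_cols(tape, z, 2L * hsize + seq_len(hsize)))
  o_g <- t_sigmoid(tape, t_cols(tape, z, 3L * hsize + seq_len(hsize)))
  c_new <- t_add(tape, t_mul(tape, f_g, c_prev), t_mul(tape, i_g, g_g))
  h_new <- t_mul(tape, o_g, t_tanh(tape, c_new))
  list(h = h_new, c = c_new)
}
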