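# Same-different (SVRT-Task-1-style) stimuli: 64x64 binary-stroke images
# containing two procedurally generated shapes. "same" images show one
# shape rendered at two non-overlapping positions (identical up to
# translation); "different" images show two independent shapes from the
# same family. Nine in-distribution families are used for training and four
# held-out families for out-of-distribution testing.
#
# The family parameterizations here are synthetic stand-ins: the benchmark
# they emulate defers shape statistics to external code, so these
# definitions are the package's own, named and fixed in configuration.

#' Named shape families
#'
#' @param set `"train"` (nine in-distribution families), `"ood"` (four
#'   held-out families) or `"all"`.
#' @return character vector of family names.
#' @export
svrt_families <- function(set = c("train", "ood", "all")) {
  set <- match.arg(set)
  train <- c("blob", "polygon", "star", "quad", "triangle", "ellipse",
             "cross", "hook", "wave")
  ood <- c("arrow", "polyline", "squashed_ellipse", "filled_blob")
  switch(set, train = train, ood = ood, all = c(train, ood))
}

# rasterize an open or closed path given as dense (x, y) samples: 1-px stroke
raster_path <- function(xs, ys) {
  # upsample so consecutive samples are < 0.5 px apart
  n <- length(xs)
  segl <- sqrt(diff(xs)^2 + diff(ys)^2)
  reps <- pmax(1L, ceiling(segl / 0.4))
  ux <- unlist(lapply(seq_len(n - 1L), function(i)
    seq(xs[i], xs[i + 1], length.out = reps[i] + 1L)[-1]))
  uy <- unlist(lapply(seq_len(n - 1L), function(i)
    seq(ys[i], ys[i + 1], length.out = reps[i] + 1L)[-1]))
  ux <- c(xs[1], ux); uy <- c(ys[1], uy)
  px <- round(ux); py <- round(uy)
  sz <- max(px, py, 1) + 1L
  m <- matrix(0, sz, sz)
  m[cbind(pmax(py, 1), pmax(px, 1))] <- 1
  m
}

crop_mask <- function(m) {
  b <- ink_box(m)
  m[b[1]:b[2], b[3]:b[4], drop = FALSE]
}

radial_points <- function(K, r0, sdlog = 0.25) {
  th <- sort(stats::runif(K, 0, 2 * pi))
  r <- r0 * exp(stats::rnorm(K, 0, sdlog))
  list(theta = th, r = r)
}

# periodic radius function through control points, sampled at nth angles
radial_curve <- function(rp, nth = 720L, smooth = TRUE) {
  th <- c(rp$theta, rp$theta[1] + 2 * pi)
  r <- c(rp$r, rp$r[1])
  grid <- seq(0, 2 * pi, length.out = nth)
  shift <- grid + rp$theta[1]
  r_at <- if (smooth && length(rp$r) >= 4)
    stats::splinefun(th, r, method = "periodic")(th[1] + grid)
  else stats::approx(th, r, xout = pmin(pmax(th[1] + grid, th[1]),
                                        th[length(th)]))$y
  list(theta = th[1] + grid, r = pmax(r_at, 1))
}

make_shape <- function(family) {
  r0 <- stats::runif(1, 6, 10)
  cx <- 16; cy <- 16
  closed_outline <- function(rp, smooth) {
    rc <- radial_curve(rp, smooth = smooth)
    raster_path(cx + rc$r * cos(rc$theta), cy + rc$r * sin(rc$theta))
  }
  poly_outline <- function(rp) {
    xs <- cx + rp$r * cos(rp$theta); ys <- cy + rp$r * sin(rp$theta)
    raster_path(c(xs, xs[1]), c(ys, ys[1]))
  }
  m <- switch(family,
    blob = closed_outline(radial_points(sample(6:12, 1), r0), TRUE),
    polygon = poly_outline(radial_points(sample(5:9, 1), r0)),
    star = {
      K <- sample(4:7, 1)
      th <- seq(0, 2 * pi, length.out = 2 * K + 1)[-(2 * K + 1)] +
        stats::runif(1, 0, pi)
      r <- rep(c(r0, r0 / 2.5), K) * exp(stats::rnorm(2 * K, 0, 0.08))
      raster_path(cx + c(r, r[1]) * cos(c(th, th[1])),
                  cy + c(r, r[1]) * sin(c(th, th[1])))
    },
    quad = poly_outline(radial_points(4, r0, 0.2)),
    triangle = poly_outline(radial_points(3, r0, 0.2)),
    ellipse = {
      a <- r0; b <- r0 * stats::runif(1, 0.6, 0.95)
      ph <- stats::runif(1, 0, pi)
      th <- seq(0, 2 * pi, length.out = 360)
      raster_path(cx + a * cos(th) * cos(ph) - b * sin(th) * sin(ph),
                  cy + a * cos(th) * sin(ph) + b * sin(th) * cos(ph))
    },
    cross = {
      w <- stats::runif(1, 0.25, 0.45) * r0
      a <- r0
      xs <- c(-w, -w, -a, -a, -w, -w, w, w, a, a, w, w, -w)
      ys <- c(-a, -w, -w, w, w, a, a, w, w, -w, -w, -a, -a)
      ph <- stats::runif(1, 0, pi / 2)
      raster_path(cx + xs * cos(ph) - ys * sin(ph),
                  cy + xs * sin(ph) + ys * cos(ph))
    },
    hook = {
      phi <- stats::runif(1, 3, 5.5)
      th <- seq(0, phi, length.out = 240) + stats::runif(1, 0, 2 * pi)
      r <- seq(r0, r0 * stats::runif(1, 0.3, 0.6), length.out = 240)
      raster_path(cx + r * cos(th), cy + r * sin(th))
    },
    wave = {
      K <- sample(5:7, 1)
      xs <- seq(cx - r0, cx + r0, length.out = K)
      ys <- cy + rep(c(-1, 1), length.out = K) * r0 *
        stats::runif(K, 0.35, 0.75)
      raster_path(xs, ys)
    },
    arrow = {
      th <- stats::runif(1, 0, 2 * pi)
      hx <- cx + r0 * cos(th); hy <- cy + r0 * sin(th)
      tx <- cx - r0 * cos(th); ty <- cy - r0 * sin(th)
      ha <- th + pi + c(-0.45, 0.45)
      hl <- r0 * 0.55
      m1 <- raster_path(c(tx, hx), c(ty, hy))
      m2 <- raster_path(c(hx, hx + hl * cos(ha[1])),
                        c(hy, hy + hl * sin(ha[1])))
      m3 <- raster_path(c(hx, hx + hl * cos(ha[2])),
                        c(hy, hy + hl * sin(ha[2])))
      sz <- max(nrow(m1), nrow(m2), nrow(m3), ncol(m1), ncol(m2), ncol(m3))
      pad <- function(m) {
        out <- matrix(0, sz, sz)
        out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
        out
      }
      pmax(pad(m1), pad(m2), pad(m3))
    },
    polyline = {
      K <- sample(4:6, 1)
      raster_path(cx + stats::runif(K, -r0, r0), cy + stats::runif(K, -r0, r0))
    },
    squashed_ellipse = {
      a <- r0; b <- r0 * stats::runif(1, 0.15, 0.35)
      ph <- stats::runif(1, 0, pi)
      th <- seq(0, 2 * pi, length.out = 360)
      raster_path(cx + a * cos(th) * cos(ph) - b * sin(th) * sin(ph),
                  cy + a * cos(th) * sin(ph) + b * sin(th) * cos(ph))
    },
    filled_blob = {
      rp <- radial_points(sample(6:10, 1), r0 * 0.8)
      rc <- radial_curve(rp)
      rf <- stats::approxfun(rc$theta - rc$theta[1], rc$r, rule = 2)
      g <- expand.grid(y = 1:32, x = 1:32)
      ang <- (atan2(g$y - cy, g$x - cx) - rc$theta[1]) %% (2 * pi)
      rad <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
      matrix(as.numeric(rad <= rf(ang)), 32, 32)
    },
    stop("unknown shape family '", family, "'", call. = FALSE))
  crop_mask(m)
}

place_two <- function(size, m1, m2, max_tries = 100L) {
  for (k in seq_len(max_tries)) {
    t1 <- sample.int(max(size - nrow(m1), 1L), 1)
    l1 <- sample.int(max(size - ncol(m1), 1L), 1)
    t2 <- sample.int(max(size - nrow(m2), 1L), 1)
    l2 <- sample.int(max(size - ncol(m2), 1L), 1)
    b1 <- c(t1, t1 + nrow(m1) - 1L, l1, l1 + ncol(m1) - 1L)
    b2 <- c(t2, t2 + nrow(m2) - 1L, l2, l2 + ncol(m2) - 1L)
    if (box_overlap(b1, b2, "min") == 0) {
      img <- matrix(0, size, size)
      img <- place(img, m1, t1, l1)
      img <- place(img, m2, t2, l2)
      return(list(img = img, boxes = rbind(b1, b2)))
    }
  }
  NULL
}

#' Generate same-different reasoning stimuli
#'
#' Class-balanced (Bernoulli 0.5 labels) 64x64 binary-stroke images. A
#' "same" sample renders one generated shape at two non-overlapping random
#' positions (the two connected components are pixel-identical up to
#' translation); a "different" sample renders two independently generated
#' shapes from the same family. Shapes that cannot be placed after bounded
#' retries are resampled.
#'
#' @param n number of images.
#' @param seed integer seed.
#' @param families shape family names; defaults to the nine training
#'   families ([svrt_families()]).
#' @param ood convenience switch: use the four held-out families.
#' @param image_size canvas side; default 64.
#' @return An `"ocra_dataset"` with labels `"same"` / `"different"` and
#'   per-sample family and placement metadata.
#' @export
gen_svrt1 <- function(n, seed = 1L, families = NULL, ood = FALSE,
                      image_size = 64L) {
  if (is.null(families))
    families <- svrt_families(if (ood) "ood" else "train")
  if (length(families) == 0L) stop("no shape families given", call. = FALSE)
  images <- vector("list", n)
  labels <- vector("list", n)
  meta <- vector("list", n)
  for (idx in seq_len(n)) {
    s <- mix_seed(seed, idx, 29L)
    out <- with_seed(s, {
      fam <- sample(families, 1)
      same <- stats::runif(1) < 0.5
      repeat {
        m1 <- make_shape(fam)
        m2 <- if (same) m1 else {
          repeat {
            cand <- make_shape(fam)
            if (!identical(dim(cand), dim(m1)) || any(cand != m1)) break
          }
          cand
        }
        if (max(nrow(m1), ncol(m1), nrow(m2), ncol(m2)) > image_size - 4L)
          next
        pl <- place_two(image_size, m1, m2)
        if (!is.null(pl)) break
      }
      list(img = pl$img, label = if (same) "same" else "different",
           meta = list(family = fam, boxes = pl$boxes, seed = s, index = idx))
    })
    images[[idx]] <- out$img
    labels[[idx]] <- out$label
    meta[[idx]] <- out$meta
  }
  new_dataset("reasoning", c(image_size, image_size), images, labels, meta,
              seed, if (ood) "ood" else "train")
}
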