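# Benchmark dataset generators: overlapping digits on a 36x36 canvas and
# digits-in-clutter on a 100x100 canvas. Composite is pixelwise max, so
# overlaid strokes never exceed 1. Every sample is reproducible from
# (seed, index) and carries enough metadata to be regenerated.

new_dataset <- function(task, image_shape, images, labels, meta, seed,
                        split = "train") {
  structure(list(task = task, image_shape = image_shape, images = images,
                 labels = labels, meta = meta, seed = seed, split = split),
            class = "ocra_dataset")
}

#' @export
length.ocra_dataset <- function(x) length(x$labels)

#' @export
print.ocra_dataset <- function(x, ...) {
  cat("<ocra_dataset> task=", x$task, " n=", length(x$labels),
      " canvas=", paste(x$image_shape, collapse = "x"),
      " split=", x$split, "\n", sep = "")
  invisible(x)
}

ink_box <- function(img) {
  nz <- which(img > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(c(1, 1, 1, 1))
  c(min(nz[, 1]), max(nz[, 1]), min(nz[, 2]), max(nz[, 2]))
}

place <- function(canvas, img, top, left) {
  h <- nrow(img); w <- ncol(img)
  rr <- top:(top + h - 1L); cc <- left:(left + w - 1L)
  canvas[rr, cc] <- pmax(canvas[rr, cc], img)
  canvas
}

#' Generate an overlapping-two-digit dataset (MultiMNIST-style)
#'
#' Each sample overlays two source digits of different classes on a 36x36
#' canvas. Each digit is shifted independently by integer offsets uniform in
#' `[-4, 4]` on both axes (so two 28x28 digits on a 36x36 canvas), and the
#' composite is the pixelwise maximum. With full 28x28 digit frames this
#' geometry yields an expected frame-box overlap (intersection over the
#' smaller box) of about 80%.
#'
#' @param digit_source a source such as [gen_fixture_glyphs()] (28x28
#'   images with labels). Splits must be kept consistent: build training
#'   data only from a training source.
#' @param n number of samples.
#' @param seed integer seed.
#' @param keep_images store the composite images (set `FALSE` to generate
#'   only labels + geometry metadata, e.g. for overlap statistics at scale).
#' @return An `"ocra_dataset"`; labels are length-2 integer vectors
#'   (distinct classes), `meta` records source ids, offsets and both frame
#'   and ink bounding boxes of each placed digit.
#' @export
gen_multimnist <- function(digit_source, n, seed = 1L, keep_images = TRUE) {
  if (is.null(digit_source$images) || length(digit_source$images) < 2L)
    stop("digit source missing or exhausted; use gen_fixture_glyphs() ",
         "for a no-download source", call. = FALSE)
  src_imgs <- digit_source$images
  src_lab <- digit_source$labels
  ns <- length(src_imgs)
  dh <- nrow(src_imgs[[1]]); dw <- ncol(src_imgs[[1]])
  H <- dh + 8L; W <- dw + 8L          # 36x36 for 28x28 digits
  base <- 5L                          # centered top-left before shifting
  images <- if (keep_images) vector("list", n) else NULL
  labels <- vector("list", n)
  meta <- vector("list", n)
  for (idx in seq_len(n)) {
    s <- mix_seed(seed, idx, 7L)
    out <- with_seed(s, {
      i1 <- sample.int(ns, 1)
      repeat {
        i2 <- sample.int(ns, 1)
        if (src_lab[i2] != src_lab[i1]) break
      }
      sh <- matrix(sample(-4:4, 4, replace = TRUE), 2, 2)  # row: digit; col: (dy, dx)
      tops <- base + sh[, 1]; lefts <- base + sh[, 2]
      frame <- cbind(tops, tops + dh - 1L, lefts, lefts + dw - 1L)
      ib1 <- ink_box(src_imgs[[i1]]); ib2 <- ink_box(src_imgs[[i2]])
      ink <- rbind(ib1, ib2) + cbind(tops, tops, lefts, lefts) - 1L
      img <- NULL
      if (keep_images) {
        img <- matrix(0, H, W)
        img <- place(img, src_imgs[[i1]], tops[1], lefts[1])
        img <- place(img, src_imgs[[i2]], tops[2], lefts[2])
      }
      list(img = img,
           labels = sort(c(src_lab[i1], src_lab[i2])),
           meta = list(src = c(i1, i2), labels = c(src_lab[i1], src_lab[i2]),
                       offsets = sh, frame_boxes = frame, ink_boxes = ink,
                       seed = s, index = idx))
    })
    if (keep_images) images[[idx]] <- out$img
    labels[[idx]] <- out$labels
    meta[[idx]] <- out$meta
  }
  new_dataset("multimnist", c(H, W), images, labels, meta, seed,
              digit_source$split %||% "train")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a digits-in-clutter dataset
#'
#' Two full source digits (same or different classes) and `n_clutter`
#' 8x8 patches randomly cropped from other source digits are placed at
#' uniform-random positions, fully inside a 100x100 blank canvas; the
#' composite is the pixelwise maximum. Clutter crops never come from the
#' two digits placed on the same canvas.
#'
#' @inheritParams gen_multimnist
#' @param n_clutter clutter pieces per image (default 6; a test hook allows
#'   0).
#' @param canvas_size side of the square canvas; default 100.
#' @return An `"ocra_dataset"` with length-2 integer label multisets
#'   (possibly `{c, c}`).
#' @export
gen_cluttered <- function(digit_source, n, seed = 1L, n_clutter = 6L,
                          canvas_size = 100L, keep_images = TRUE) {
  if (is.null(digit_source$images) || length(digit_source$images) < n_clutter + 2L)
    stop("digit source missing or exhausted; use gen_fixture_glyphs() ",
         "for a no-download source", call. = FALSE)
  src_imgs <- digit_source$images
  src_lab <- digit_source$labels
  ns <- length(src_imgs)
  dh <- nrow(src_imgs[[1]]); dw <- ncol(src_imgs[[1]])
  H <- W <- as.integer(canvas_size)
  cs <- 8L
  images <- if (keep_images) vector("list", n) else NULL
  labels <- vector("list", n)
  meta <- vector("list", n)
  for (idx in seq_len(n)) {
    s <- mix_seed(seed, idx, 13L)
    out <- with_seed(s, {
      dig <- sample.int(ns, 2, replace = FALSE)   # digits may share a class
      tops <- sample.int(H - dh + 1L, 2, replace = TRUE)
      lefts <- sample.int(W - dw + 1L, 2, replace = TRUE)
      cl_src <- integer(n_clutter); cl_pos <- matrix(0L, n_clutter, 4)
      img <- if (keep_images) matrix(0, H, W) else NULL
      if (keep_images) {
        img <- place(img, src_imgs[[dig[1]]], tops[1], lefts[1])
        img <- place(img, src_imgs[[dig[2]]], tops[2], lefts[2])
      }
      for (c in seq_len(n_clutter)) {
        repeat {
          j <- sample.int(ns, 1)
          if (!(j %in% dig)) break
        }
        cr <- sample.int(dh - cs + 1L, 1); cc <- sample.int(dw - cs + 1L, 1)
        pt <- sample.int(H - cs + 1L, 1); pl <- sample.int(W - cs + 1L, 1)
        cl_src[c] <- j; cl_pos[c, ] <- c(cr, cc, pt, pl)
        if (keep_images) {
          patch <- src_imgs[[j]][cr:(cr + cs - 1L), cc:(cc + cs - 1L)]
          img <- place(img, patch, pt, pl)
        }
      }
      list(img = img, labels = sort(src_lab[dig]),
           meta = list(src = dig, labels = src_lab[dig],
                       tops = tops, lefts = lefts,
                       clutter_src = cl_src, clutter_pos = cl_pos,
                       seed = s, index = idx))
    })
    if (keep_images) images[[idx]] <- out$img
    labels[[idx]] <- out$labels
    meta[[idx]] <- out$meta
  }
  new_dataset("cluttered", c(H, W), images, labels, meta, seed,
              digit_source$split %||% "train")
}

box_overlap <- function(b1, b2, metric = c("iou", "min")) {
  metric <- match.arg(metric)
  ih <- max(0, min(b1[2], b2[2]) - max(b1[1], b2[1]) + 1)
  iw <- max(0, min(b1[4], b2[4]) - max(b1[3], b2[3]) + 1)
  inter <- ih * iw
  a1 <- (b1[2] - b1[1] + 1) * (b1[4] - b1[3] + 1)
  a2 <- (b2[2] - b2[1] + 1) * (b2[4] - b2[3] + 1)
  if (metric == "iou") inter / (a1 + a2 - inter) else inter / min(a1, a2)
}

#' Mean bounding-box overlap of an overlapping-digit dataset
#'
#' The overlap between the two placed digits' boxes, averaged over samples.
#' Boxes can be the full digit frames (`box = "frame"`, e.g. the whole
#' 28x28 source image) or tight ink boxes (`box = "ink"`); the metric can
#' be intersection-over-union (`"iou"`) or intersection over the smaller
#' box (`"min"`). With `box = "frame", metric = "min"` the statistic is
#' purely geometric (digit-source independent) with expectation
#' `E[(28-|dx|)(28-|dy|)]/784 ~= 0.80` under the +/-4 pixel shifts.
#'
#' @param dataset an `"ocra_dataset"` from [gen_multimnist()].
#' @param box `"ink"` or `"frame"`.
#' @param metric `"iou"` or `"min"`.
#' @return mean overlap in `[0, 1]`.
#' @export
overlap_statistic <- function(dataset, box = c("ink", "frame"),
                              metric = c("iou", "min")) {
  box <- match.arg(box); metric <- match.arg(metric)
  key <- if (box == "ink") "ink_boxes" else "frame_boxes"
  mean(vapply(dataset$meta, function(m) {
    b <- m[[key]]
    box_overlap(b[1, ], b[2, ], metric)
  }, numeric(1)))
}
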