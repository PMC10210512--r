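# Procedural fixture glyphs: a no-download stand-in for a handwritten-digit
# source. Ten classes are drawn as jittered seven-segment skeletons with
# variable stroke thickness, so every pipeline (overlay, clutter, training)
# runs offline with class-discriminable 28x28 images in [0, 1].

# deterministic per-(seed, index) sub-seed, kept below 2^31
mix_seed <- function(seed, index, salt = 0L) {
  ((as.numeric(seed) * 48271 + as.numeric(index) * 30269 +
      as.numeric(salt) * 16807) %% 2147483399) + 1
}

# segment endpoints of the 7-segment skeleton in the unit box (x right,
# y down): A top, B top-right, C bottom-right, D bottom, E bottom-left,
# F top-left, G middle
seven_segments <- matrix(c(
  0.15, 0.08, 0.85, 0.08,   # A
  0.85, 0.08, 0.85, 0.50,   # B
  0.85, 0.50, 0.85, 0.92,   # C
  0.15, 0.92, 0.85, 0.92,   # D
  0.15, 0.50, 0.15, 0.92,   # E
  0.15, 0.08, 0.15, 0.50,   # F
  0.15, 0.50, 0.85, 0.50    # G
), ncol = 4, byrow = TRUE,
dimnames = list(c("A", "B", "C", "D", "E", "F", "G"), NULL))

glyph_segment_map <- list(
  `0` = c("A", "B", "C", "D", "E", "F"),
  `1` = c("B", "C"),
  `2` = c("A", "B", "G", "E", "D"),
  `3` = c("A", "B", "G", "C", "D"),
  `4` = c("F", "G", "B", "C"),
  `5` = c("A", "F", "G", "C", "D"),
  `6` = c("A", "F", "G", "E", "C", "D"),
  `7` = c("A", "B", "C"),
  `8` = c("A", "B", "C", "D", "E", "F", "G"),
  `9` = c("A", "B", "C", "D", "F", "G"))

# soft-edged thick segments: ink = clamp((thickness - distance) / 0.7)
draw_segments <- function(size, segs, thickness) {
  px <- rep(seq_len(size), each = size)   # x (column)
  py <- rep(seq_len(size), size)          # y (row)
  ink <- numeric(size * size)
  for (s in seq_len(nrow(segs))) {
    x1 <- segs[s, 1]; y1 <- segs[s, 2]; x2 <- segs[s, 3]; y2 <- segs[s, 4]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    tt <- if (L2 < 1e-12) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
    d <- sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
    ink <- pmax(ink, pmin(1, pmax(0, (thickness - d) / 0.7)))
  }
  matrix(ink, size, size)   # column-major: [row, col] = [y, x]
}

render_glyph <- function(class, size = 28L) {
  segs <- seven_segments[glyph_segment_map[[as.character(class)]], ,
                         drop = FALSE]
  scale <- stats::runif(1, 17, 21)
  off_x <- stats::runif(1, 3.5, 6.5)
  off_y <- stats::runif(1, 3.5, 6.5)
  th <- stats::runif(1, 1.2, 2.2)
  segs <- segs * scale
  segs[, c(1, 3)] <- segs[, c(1, 3)] + off_x
  segs[, c(2, 4)] <- segs[, c(2, 4)] + off_y
  segs <- segs + matrix(stats::rnorm(length(segs), 0, 0.6),
                        nrow(segs), ncol(segs))
  draw_segments(size, segs, th)
}

#' Procedural digit-like fixture glyphs
#'
#' Generates a deterministic source of 28x28 pseudo-digit images (ten
#' synthetic classes drawn as jittered seven-segment glyphs) exposing the
#' same interface as a real handwritten-digit source, so the overlay,
#' clutter and training pipelines run with no download. Train and test
#' splits draw from disjoint random streams, mirroring the source-set
#' separation a real digit corpus enforces.
#'
#' @param n number of images.
#' @param seed integer seed; `(seed, split, index)` fully determines each
#'   image.
#' @param split `"train"` or `"test"`.
#' @return A digit source: list with `images` (list of 28x28 matrices in
#'   `[0,1]`), `labels` (integer 0-9), `split`, `ids`.
#' @export
gen_fixture_glyphs <- function(n, seed = 1L, split = "train") {
  split <- match.arg(split, c("train", "test"))
  salt <- if (split == "train") 101L else 202L
  labels <- integer(n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    labels[i] <- (i - 1L) %% 10L
    images[[i]] <- with_seed(mix_seed(seed, i, salt),
                             render_glyph(labels[i]))
  }
  structure(list(images = images, labels = labels, split = split,
                 ids = paste0(split, "-", seq_len(n))),
            class = "glyph_source")
}
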