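# Gaussian-filterbank read/write attention ("zoom lens" glimpses).
#
# Coordinate conventions, used everywhere in the package: images are
# row-major H x W matrices, origin top-left, and filter-center algebra is
# 1-based (pixel centers at 1..H / 1..W).

#' Map four raw attention parameters to a valid pose
#'
#' The attention window is controlled by four parameters: its center
#' (`center_x`, `center_y`), the spacing between adjacent Gaussian filters
#' (`stride`, delta) and the filter variance (`variance`, sigma^2). The raw
#' values come from an unconstrained linear readout of the decoder state, so
#' they are mapped to guaranteed-valid poses: centers by an affine map onto
#' the 1-based pixel axes, stride and variance through an exponential, which
#' keeps both strictly positive for any finite input.
#'
#' With all-zero raw input the pose is centered at the image midpoint with a
#' stride spreading the grid over the whole image and unit variance, so an
#' untrained model's first glimpse covers most of the image.
#'
#' @param raw numeric length 4: raw x-center, y-center, log-stride factor,
#'   log-variance.
#' @param image_shape integer length 2, `c(H, W)`.
#' @param grid_size number of filters per axis (N).
#' @return An object of class `"attention_pose"`: list with `center_x`,
#'   `center_y`, `stride`, `variance`.
#' @export
#' @examples
#' attention_pose(c(0, 0, 0, 0), c(36, 36), 18)
attention_pose <- function(raw, image_shape, grid_size) {
  if (length(raw) != 4L)
    stop("raw pose must have exactly 4 values", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("non-finite raw pose values", call. = FALSE)
  H <- image_shape[1]; W <- image_shape[2]
  N <- grid_size
  structure(list(
    center_x = (W + 1) * (raw[1] + 1) / 2,
    center_y = (H + 1) * (raw[2] + 1) / 2,
    stride   = exp(raw[3]) * (max(H, W) - 1) / max(N - 1, 1),
    variance = exp(raw[4])
  ), class = "attention_pose")
}

#' Compute an attention pose from a hidden state via a linear projection
#'
#' @param hidden numeric vector, typically the previous-step decoder state.
#' @param projection list with `W` (length(hidden) x 4 matrix) and `b`
#'   (length-4 bias).
#' @inheritParams attention_pose
#' @return An `"attention_pose"`.
#' @export
pose_from_hidden <- function(hidden, projection, image_shape, grid_size) {
  if (any(!is.finite(hidden)))
    stop("non-finite hidden state passed to pose projection", call. = FALSE)
  if (ncol(projection$W) != 4L || length(projection$b) != 4L)
    stop("pose projection must output exactly 4 raw values", call. = FALSE)
  raw <- as.numeric(matrix(hidden, 1) %*% projection$W) + as.numeric(projection$b)
  attention_pose(raw, image_shape, grid_size)
}

filter_offsets <- function(N) seq_len(N) - N / 2 - 0.5

gauss_filter_matrix <- function(centers, variance, len, eps = 1e-8) {
  ax <- seq_len(len)
  D <- outer(centers, ax, function(m, a) a - m)
  G <- exp(-D * D / (2 * variance))
  G / (rowSums(G) + eps)
}

#' Build the N x N grid of Gaussian read/write filters for a pose
#'
#' Filter `i` along an axis is centered at
#' `mu_i = center + (i - N/2 - 0.5) * stride`; each filter row is
#' L1-normalized (with a 1e-8 floor on the normalizer so off-image centers
#' stay finite), making every row a convex combination of pixels.
#'
#' @param pose an [attention_pose()].
#' @param grid_size filters per axis (N >= 1).
#' @param image_shape `c(H, W)`, both >= 1.
#' @return An object of class `"filter_grid"`: list with `row_filters`
#'   (N x H), `col_filters` (N x W), `grid_size`, `image_height`,
#'   `image_width` and the `pose`.
#' @export
build_filters <- function(pose, grid_size, image_shape) {
  N <- as.integer(grid_size)
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  if (N < 1L || H < 1L || W < 1L)
    stop("grid size and image dimensions must be >= 1", call. = FALSE)
  offs <- filter_offsets(N)
  structure(list(
    row_filters = gauss_filter_matrix(pose$center_y + offs * pose$stride,
                                      pose$variance, H),
    col_filters = gauss_filter_matrix(pose$center_x + offs * pose$stride,
                                      pose$variance, W),
    grid_size = N, image_height = H, image_width = W, pose = pose
  ), class = "filter_grid")
}

check_grid_image <- function(image, grid) {
  if (nrow(image) != grid$image_height || ncol(image) != grid$image_width)
    stop("image shape does not match filter grid (",
         grid$image_height, "x", grid$image_width, ")", call. = FALSE)
}

#' Read an N x N glimpse from an image through a filter grid
#'
#' `glimpse = row_filters %*% image %*% t(col_filters)`; linear in the image,
#' and because filter rows sum to one each glimpse pixel is a convex
#' combination of image pixels.
#'
#' @param image H x W numeric matrix.
#' @param grid a [build_filters()] grid.
#' @return N x N glimpse matrix.
#' @export
read_glimpse <- function(image, grid) {
  check_grid_image(image, grid)
  grid$row_filters %*% image %*% t(grid$col_filters)
}

#' Write an M x M patch onto an H x W canvas increment
#'
#' The adjoint of [read_glimpse()] under the same grid:
#' `increment = t(row_filters) %*% patch %*% col_filters`, so
#' `sum(write(p) * x) == sum(p * read(x))` for any image `x` and patch `p`.
#'
#' @param patch M x M matrix; M must equal the grid's `grid_size`.
#' @param grid a [build_filters()] grid.
#' @return H x W canvas increment.
#' @export
write_patch <- function(patch, grid) {
  if (nrow(patch) != grid$grid_size || ncol(patch) != grid$grid_size)
    stop("patch size does not match grid size ", grid$grid_size, call. = FALSE)
  t(grid$row_filters) %*% patch %*% grid$col_filters
}

#' Image-space coverage of a filter grid
#'
#' Retrojects an all-ones patch through the grid and rescales so the maximum
#' entry is 1. The episode-average of read-grid coverages is the
#' reconstruction mask used by the cluttered-task loss: the model is only
#' penalized for failing to reconstruct areas it actually glimpsed.
#'
#' @param grid a [build_filters()] grid.
#' @return H x W coverage map with maximum entry 1.
#' @export
retroject_coverage <- function(grid) {
  cov <- write_patch(matrix(1, grid$grid_size, grid$grid_size), grid)
  mx <- max(cov)
  if (mx > 0) cov <- cov / mx
  cov
}

#' Bounding box of an attention window in image coordinates
#'
#' The box spans `center +/- (N - 1) / 2 * stride` on each axis (the extent
#' of the filter centers), matching the green/red box overlays in the
#' visualization panels.
#'
#' @param pose an [attention_pose()].
#' @param grid_size filters per axis.
#' @return numeric length 4: `c(top, bottom, left, right)` (unclipped).
#' @export
pose_box <- function(pose, grid_size) {
  half <- (grid_size - 1) / 2 * pose$stride
  c(top = pose$center_y - half, bottom = pose$center_y + half,
    left = pose$center_x - half, right = pose$center_x + half)
}
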