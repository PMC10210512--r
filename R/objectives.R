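# Margin classification loss, (optionally masked) reconstruction loss, and
# their weighted combination. The margin loss acts on cumulative (summed
# over timesteps) capsule magnitudes: a class present twice has target 2,
# which is only attainable cumulatively since per-step magnitudes are < 1.

#' Loss configuration
#'
#' @param margin hinge margin `m` in (0, 1); default 0.1.
#' @param lambda_absent down-weighting of the absent-class term; default 0.5.
#' @param lambda_recon weight of the reconstruction term in the total loss;
#'   default 10 (keeps the two terms within an order of magnitude at
#'   initialization for the shipped tasks).
#' @param masked if `TRUE`, the reconstruction loss is weighted by the
#'   episode-averaged read-glimpse coverage (used for the cluttered task).
#' @return List of class `"loss_config"`.
#' @export
loss_config <- function(margin = 0.1, lambda_absent = 0.5,
                        lambda_recon = 10, masked = FALSE) {
  stopifnot(margin > 0, margin < 1, lambda_absent >= 0, lambda_recon >= 0)
  structure(list(margin = margin, lambda_absent = lambda_absent,
                 lambda_recon = lambda_recon, masked = isTRUE(masked)),
            class = "loss_config")
}

#' Margin classification loss on cumulative capsule magnitudes
#'
#' For each class `j` with integer target count `T_j` (0, 1 or 2 instances
#' present) and cumulative score `s_j`:
#' `min(T_j, 1) * max(0, (T_j - m) - s_j)^2 +
#'  lambda_absent * max(0, 1 - T_j) * max(0, s_j - m)^2`,
#' summed over classes. The present-term is active iff `T_j >= 1` and pushes
#' the score above `T_j - m`; the absent-term is active iff `T_j == 0` and
#' pushes the score below `m`. Classes with `active = FALSE` (e.g.
#' non-response capsules in the reasoning task) contribute nothing and
#' receive zero gradient.
#'
#' @param scores nonnegative K-vector of cumulative magnitudes.
#' @param targets nonnegative integer K-vector of instance counts.
#' @param cfg a [loss_config()].
#' @param active logical K-vector; defaults to all `TRUE`.
#' @return scalar loss.
#' @export
margin_loss <- function(scores, targets, cfg = loss_config(),
                        active = NULL) {
  if (length(scores) != length(targets))
    stop("scores and targets must have the same length", call. = FALSE)
  if (is.null(active)) active <- rep(TRUE, length(scores))
  m <- cfg$margin
  present <- pmax(0, pmin(targets, 1)) * pmax(0, (targets - m) - scores)^2
  absent <- cfg$lambda_absent * pmax(0, 1 - targets) * pmax(0, scores - m)^2
  sum((present + absent)[active])
}

#' Mean-squared reconstruction loss, optionally coverage-masked
#'
#' Unmasked: `mean((canvas - image)^2)`. Masked:
#' `mean(mask * (canvas - image)^2)` over all pixels, with `mask` the
#' episode-averaged [retroject_coverage()] of the read grids (entries in
#' `[0, 1]`, kept graded rather than binarized) -- the model is accountable
#' only for areas it glimpsed.
#'
#' @param canvas,image H x W matrices.
#' @param mask optional H x W coverage weights in `[0, 1]`.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(canvas, image, mask = NULL) {
  if (!all(dim(canvas) == dim(image)))
    stop("canvas and image shapes differ", call. = FALSE)
  sq <- (canvas - image)^2
  if (is.null(mask)) return(mean(sq))
  if (!all(dim(mask) == dim(image)))
    stop("mask shape differs from image", call. = FALSE)
  mean(mask * sq)
}

#' Combined training loss
#'
#' `total = class_loss + lambda_recon * recon_loss`.
#'
#' @param class_loss,recon_loss scalar components.
#' @param cfg a [loss_config()].
#' @return scalar.
#' @export
total_loss <- function(class_loss, recon_loss, cfg = loss_config()) {
  stopifnot(is.finite(class_loss), is.finite(recon_loss))
  class_loss + cfg$lambda_recon * recon_loss
}

#' Target counts for a recognition label multiset
#'
#' @param labels integer vector of 2 class labels (0-based), possibly equal.
#' @param n_class number of classes.
#' @return K-vector of counts summing to 2.
#' @export
targets_from_labels <- function(labels, n_class) {
  counts <- numeric(n_class)
  for (l in labels) counts[l + 1L] <- counts[l + 1L] + 1
  counts
}
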