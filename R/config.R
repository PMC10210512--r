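# Model configuration: task variants, architecture sizes, ablations.

task_image_shape <- function(task) {
  switch(task,
         multimnist = c(36L, 36L),
         cluttered  = c(100L, 100L),
         reasoning  = c(64L, 64L))
}

task_timesteps <- function(task) {
  switch(task, multimnist = 3L, cluttered = 5L, reasoning = 10L)
}

#' Assemble and validate a model configuration
#'
#' The reference recognition configuration (multimnist, variant "full")
#' uses an 18x18 glimpse and write patch, a two-layer 32-channel CNN
#' (kernels 5 and 3, each followed by 2x2/stride-2 max pooling and ReLU),
#' 512-unit LSTM encoder and decoder, 40 primary capsules of dimension 8 and
#' 10 class capsules of dimension 16, for 3,873,260 trainable parameters.
#'
#' Variants (ablations):
#' * `"full"` -- glimpse attention + recurrence + capsules.
#' * `"recurrent_noglimpse"` -- the whole image is input at every step and
#'   the decoder writes the whole canvas; no read/write attention (the CNN
#'   is sized for the full image, hence more parameters than "full").
#' * `"feedforward"` -- a single pass on the full image, dense layers
#'   replacing the recurrences, capsules decoded without masking.
#' * `"no_capsules"` -- the capsule pair is replaced by two fully connected
#'   layers of 320 and 160 units with a sigmoid classification readout per
#'   step; everything else unchanged.
#'
#' The reasoning task uses 4 class capsules, two of which are designated
#' response capsules (same / different); the remaining two are free slots
#' (gist / temporary object) that receive no supervision. The
#' decoder-to-encoder feedback connection defaults to on only for reasoning.
#'
#' @param task `"multimnist"`, `"cluttered"` or `"reasoning"`.
#' @param variant ablation variant, see above.
#' @param timesteps number of glimpses T; defaults 3 (multimnist),
#'   5 (cluttered), 10 (reasoning), 1 (feedforward).
#' @param glimpse_size,patch_size read grid N and write patch M; default 18.
#' @param conv_channels,conv_kernels CNN widths and kernel sizes.
#' @param recurrent_size LSTM width; default 512.
#' @param n_primary,primary_dim primary capsule count and dimension.
#' @param n_class,class_dim class capsule count (10 recognition /
#'   4 reasoning) and dimension (16).
#' @param feedback feed the previous decoder state back into the encoder.
#' @param response_idx the two response capsules (same, different), 1-based;
#'   reasoning only.
#' @param routing_iterations dynamic-routing rounds; default 3.
#' @param coupling_lb,coupling_ub max-min normalization bounds.
#' @return List of class `"ocra_config"`.
#' @export
ocra_config <- function(task = c("multimnist", "cluttered", "reasoning"),
                        variant = c("full", "recurrent_noglimpse",
                                    "feedforward", "no_capsules"),
                        timesteps = NULL,
                        glimpse_size = 18L, patch_size = 18L,
                        conv_channels = c(32L, 32L),
                        conv_kernels = c(5L, 3L),
                        recurrent_size = 512L,
                        n_primary = 40L, primary_dim = 8L,
                        n_class = NULL, class_dim = 16L,
                        feedback = NULL,
                        response_idx = c(1L, 2L),
                        routing_iterations = 3L,
                        coupling_lb = 0.01, coupling_ub = 1.0) {
  task <- match.arg(task)
  variant <- match.arg(variant)
  if (is.null(n_class)) n_class <- if (task == "reasoning") 4L else 10L
  if (is.null(feedback)) feedback <- task == "reasoning"
  if (is.null(timesteps))
    timesteps <- if (variant == "feedforward") 1L else task_timesteps(task)
  if (variant == "feedforward" && timesteps != 1L)
    stop("the feedforward variant makes exactly one pass", call. = FALSE)
  if (task == "reasoning") {
    if (n_class != 4L)
      stop("the reasoning task uses 4 class capsules", call. = FALSE)
    if (length(response_idx) != 2L || anyDuplicated(response_idx) ||
        any(response_idx < 1L) || any(response_idx > n_class))
      stop("reasoning needs 2 distinct designated response capsules",
           call. = FALSE)
    if (variant %in% c("recurrent_noglimpse", "feedforward"))
      stop("variant '", variant, "' is not defined for the reasoning task",
           call. = FALSE)
  }
  if (feedback && task != "reasoning" && variant == "feedforward")
    stop("feedback requires recurrence", call. = FALSE)
  image_shape <- task_image_shape(task)
  structure(list(
    task = task, variant = variant, timesteps = as.integer(timesteps),
    image_shape = image_shape,
    glimpse_size = as.integer(glimpse_size),
    patch_size = as.integer(patch_size),
    conv_channels = as.integer(conv_channels),
    conv_kernels = as.integer(conv_kernels),
    recurrent_size = as.integer(recurrent_size),
    n_primary = as.integer(n_primary), primary_dim = as.integer(primary_dim),
    n_class = as.integer(n_class), class_dim = as.integer(class_dim),
    feedback = isTRUE(feedback),
    response_idx = as.integer(response_idx),
    routing_iterations = as.integer(routing_iterations),
    coupling_lb = coupling_lb, coupling_ub = coupling_ub
  ), class = "ocra_config")
}

# pixels of one conv stack output: two same-padded convs, each followed by
# 2x2/stride-2 pooling with trailing row/col dropped
conv_out_side <- function(side) (side %/% 2L) %/% 2L

conv_feature_len <- function(cfg, side) {
  conv_out_side(side)^2 * cfg$conv_channels[2]
}

# side length of the CNN input for a variant
cnn_input_side <- function(cfg) {
  if (cfg$variant %in% c("recurrent_noglimpse", "feedforward"))
    cfg$image_shape[1] else cfg$glimpse_size
}

encoder_input_len <- function(cfg) {
  n <- conv_feature_len(cfg, cnn_input_side(cfg))
  if (cfg$feedback && cfg$variant %in% c("full", "no_capsules",
                                         "recurrent_noglimpse"))
    n <- n + cfg$recurrent_size
  n
}

decoder_input_len <- function(cfg) {
  if (cfg$variant == "no_capsules") 160L else cfg$n_class * cfg$class_dim
}
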