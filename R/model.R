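# The full timestep loop: read -> CNN -> encoder recurrence -> capsules ->
# routing -> mask -> decoder recurrence -> write, with task variants and
# ablations. The forward pass is recorded on an autodiff tape so training
# gradients flow end to end, including through the Gaussian attention
# filters and the routing iterations.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

#' Initialize a model from a configuration
#'
#' Weights are Glorot-uniform; biases are zero. Zero pose biases mean the
#' first glimpse of an untrained model is centered and covers most of the
#' image (the "gist" glimpse); the initial pose is learned through the pose
#' projection bias rather than hard-coded.
#'
#' @param config an [ocra_config()].
#' @param seed integer seed for the initialization (reproducible).
#' @return List of class `"ocra_model"` with elements `config` and `params`
#'   (named list of numeric arrays).
#' @export
ocra_model <- function(config, seed = 1L) {
  cfg <- config
  k1 <- cfg$conv_kernels[1]; k2 <- cfg$conv_kernels[2]
  C1 <- cfg$conv_channels[1]; C2 <- cfg$conv_channels[2]
  R <- cfg$recurrent_size
  P <- cfg$n_primary; pd <- cfg$primary_dim
  K <- cfg$n_class; cd <- cfg$class_dim
  HW <- prod(cfg$image_shape)
  M <- cfg$patch_size
  enc_in <- encoder_input_len(cfg)
  dec_in <- decoder_input_len(cfg)
  has_glimpse <- cfg$variant %in% c("full", "no_capsules")
  recurrent <- cfg$variant != "feedforward"
  capsules <- cfg$variant != "no_capsules"

  params <- with_seed(seed, {
    p <- list(
      conv1_w = glorot(k1 * k1 * 1L, C1), conv1_b = matrix(0, 1, C1),
      conv2_w = glorot(k2 * k2 * C1, C2), conv2_b = matrix(0, 1, C2))
    if (has_glimpse) {
      p$read_pose_W <- glorot(R, 4L);  p$read_pose_b <- matrix(0, 1, 4)
      p$write_pose_W <- glorot(R, 4L); p$write_pose_b <- matrix(0, 1, 4)
    }
    if (recurrent) {
      p$enc_Wx <- glorot(enc_in, 4L * R)
      p$enc_Wh <- glorot(R, 4L * R)
      p$enc_b <- matrix(0, 1, 4L * R)
      p$dec_Wx <- glorot(dec_in, 4L * R)
      p$dec_Wh <- glorot(R, 4L * R)
      p$dec_b <- matrix(0, 1, 4L * R)
    } else {
      p$enc_fc_W <- glorot(enc_in, R); p$enc_fc_b <- matrix(0, 1, R)
      p$dec_fc_W <- glorot(dec_in, R); p$dec_fc_b <- matrix(0, 1, R)
    }
    if (capsules) {
      p$prim_W <- glorot(R, P * pd); p$prim_b <- matrix(0, 1, P * pd)
      l <- sqrt(6 / (pd + cd))
      p$route_W <- array(stats::runif(pd * K * cd * P, -l, l),
                         dim = c(pd, K * cd, P))
    } else {
      p$fc1_W <- glorot(R, 320L); p$fc1_b <- matrix(0, 1, 320)
      p$fc2_W <- glorot(320L, 160L); p$fc2_b <- matrix(0, 1, 160)
      p$readout_W <- glorot(160L, K); p$readout_b <- matrix(0, 1, K)
    }
    if (has_glimpse) {
      p$write_W <- glorot(R, M * M); p$write_b <- matrix(0, 1, M * M)
    } else {
      p$write_W <- glorot(R, HW); p$write_b <- matrix(0, 1, HW)
    }
    p
  })
  structure(list(config = cfg, params = params), class = "ocra_model")
}

#' Count trainable parameters
#'
#' @param x an `"ocra_model"` or an `"ocra_config"` (assembled on the fly).
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "ocra_config")) x <- ocra_model(x, seed = 0L)
  sum(vapply(x$params, length, integer(1)))
}

# tape-side pose: raw 1x4 node -> list(Fy, Fx, pose numbers)
tape_filters <- function(tape, raw, H, W, N) {
  gx <- t_cols(tape, raw, 1L); gy <- t_cols(tape, raw, 2L)
  ld <- t_cols(tape, raw, 3L); lv <- t_cols(tape, raw, 4L)
  cx <- t_scale(tape, t_shift(tape, gx, 1), (W + 1) / 2)
  cy <- t_scale(tape, t_shift(tape, gy, 1), (H + 1) / 2)
  stride <- t_scale(tape, t_exp(tape, ld), (max(H, W) - 1) / max(N - 1, 1))
  vv <- t_exp(tape, lv)
  offs <- filter_offsets(N)
  Fy <- t_gauss_filters(tape, t_filter_centers(tape, cy, stride, offs), vv, H)
  Fx <- t_gauss_filters(tape, t_filter_centers(tape, cx, stride, offs), vv, W)
  list(Fy = Fy, Fx = Fx,
       pose = structure(list(center_x = as.numeric(cx$value),
                             center_y = as.numeric(cy$value),
                             stride = as.numeric(stride$value),
                             variance = as.numeric(vv$value)),
                        class = "attention_pose"))
}

# CNN stack: x (side^2 x 1) node -> 1 x feature-length node
tape_cnn <- function(tape, x, pn, cfg, side) {
  k1 <- cfg$conv_kernels[1]; k2 <- cfg$conv_kernels[2]
  c1 <- t_relu(tape, t_conv2d(tape, x, pn$conv1_w, pn$conv1_b, side, side, k1))
  s1 <- side %/% 2L
  p1 <- t_maxpool2(tape, c1, side, side)
  c2 <- t_relu(tape, t_conv2d(tape, p1, pn$conv2_w, pn$conv2_b, s1, s1, k2))
  s2 <- s1 %/% 2L
  p2 <- t_maxpool2(tape, c2, s1, s1)
  t_reshape(tape, p2, 1L, s2 * s2 * cfg$conv_channels[2])
}

# tape-side routing; returns list(d, mags, couplings)
tape_route <- function(tape, uhat, P, K, cd, iterations, lb, ub) {
  b_acc <- tp_const(tape, matrix(0, P, K))
  d <- cpl <- NULL
  for (r in seq_len(iterations)) {
    cpl <- t_maxmin_rows(tape, b_acc, lb, ub)
    v <- t_route_mix(tape, uhat, cpl, K, cd)
    d <- t_squash_rows(tape, v)
    b_acc <- t_add(tape, b_acc, t_agree(tape, uhat, d, K, cd))
  }
  list(d = d, mags = t_rownorm(tape, d), couplings = cpl)
}

#' Run the model on one image, recording the full forward pass
#'
#' Executes the timestep loop and returns the per-step traces, the
#' cumulative class scores (elementwise sum over timesteps of the class
#' capsule magnitudes, each step's term in `[0, 1)`), and the accumulated
#' reconstruction canvas. When `targets` is given, the combined margin +
#' reconstruction loss is also built on the tape so [ocra_grad()] can
#' backpropagate it.
#'
#' @param model an [ocra_model()].
#' @param image H x W matrix matching the task canvas size.
#' @param targets optional K-vector of class instance counts (see
#'   [targets_from_labels()]); `NA` entries mark unsupervised capsules.
#' @param loss_cfg a [loss_config()]; required with `targets`.
#' @return List of class `"ocra_episode"`: `traces` (one per timestep, each
#'   with `read_pose`, `glimpse`, `conv_features`, `class_magnitudes`,
#'   `most_active`, `write_pose`, `canvas_increment`), `cumulative_scores`,
#'   `canvas`, `coverage` (episode-averaged read coverage), and -- when a
#'   loss was requested -- `loss` components plus internal tape handles.
#' @export
run_episode <- function(model, image, targets = NULL, loss_cfg = NULL) {
  cfg <- model$config
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  if (nrow(image) != H || ncol(image) != W)
    stop("image must be ", H, "x", W, " for task '", cfg$task, "'",
         call. = FALSE)
  N <- cfg$glimpse_size; M <- cfg$patch_size
  R <- cfg$recurrent_size
  P <- cfg$n_primary; pd <- cfg$primary_dim
  K <- cfg$n_class; cd <- cfg$class_dim
  has_glimpse <- cfg$variant %in% c("full", "no_capsules")
  recurrent <- cfg$variant != "feedforward"
  capsules <- cfg$variant != "no_capsules"
  side <- cnn_input_side(cfg)

  tape <- new_tape()
  pn <- lapply(model$params, function(p) tp_leaf(tape, p))
  img <- tp_const(tape, image)
  zero_h <- tp_const(tape, matrix(0, 1, R))
  h_enc <- c_enc <- h_dec <- c_dec <- zero_h
  canvas <- tp_const(tape, matrix(0, H, W))
  scores <- tp_const(tape, matrix(0, K, 1))
  coverage <- matrix(0, H, W)
  traces <- vector("list", cfg$timesteps)

  for (tstep in seq_len(cfg$timesteps)) {
    step <- function() {
      read_pose <- write_pose <- NULL
      if (has_glimpse) {
        raw_r <- t_add(tape, t_matmul(tape, h_dec, pn$read_pose_W),
                       pn$read_pose_b)
        fr <- tape_filters(tape, raw_r, H, W, N)
        read_pose <- fr$pose
        glimpse <- t_matmul(tape, t_matmul(tape, fr$Fy, img),
                            t_transpose(tape, fr$Fx))
        cov <- t(fr$Fy$value) %*% matrix(1, N, N) %*% fr$Fx$value
        if (max(cov) > 0) cov <- cov / max(cov)
        coverage <<- coverage + cov
      } else {
        glimpse <- img
        fr <- NULL
      }
      x <- t_reshape(tape, glimpse, side * side, 1L)
      feat <- tape_cnn(tape, x, pn, cfg, side)
      enc_in <- if (cfg$feedback) t_cbind(tape, feat, h_dec) else feat
      if (recurrent) {
        es <- t_lstm_step(tape, enc_in, h_enc, c_enc,
                          pn$enc_Wx, pn$enc_Wh, pn$enc_b, R)
        h_enc <<- es$h; c_enc <<- es$c
      } else {
        h_enc <<- t_tanh(tape, t_add(tape, t_matmul(tape, enc_in, pn$enc_fc_W),
                                     pn$enc_fc_b))
      }
      if (capsules) {
        prim <- t_add(tape, t_matmul(tape, h_enc, pn$prim_W), pn$prim_b)
        pm <- t_transpose(tape, t_reshape(tape, prim, pd, P))
        uhat <- t_caps_predict(tape, pm, pn$route_W)
        rt <- tape_route(tape, uhat, P, K, cd, cfg$routing_iterations,
                         cfg$coupling_lb, cfg$coupling_ub)
        mags <- rt$mags
        dec_in <- if (cfg$variant == "feedforward")
          t_reshape(tape, t_transpose(tape, rt$d), 1L, K * cd)
        else t_mask_argmax(tape, rt$d, as.numeric(mags$value))
      } else {
        f1 <- t_relu(tape, t_add(tape, t_matmul(tape, h_enc, pn$fc1_W),
                                 pn$fc1_b))
        f2 <- t_relu(tape, t_add(tape, t_matmul(tape, f1, pn$fc2_W),
                                 pn$fc2_b))
        mags <- t_transpose(tape, t_sigmoid(
          tape, t_add(tape, t_matmul(tape, f2, pn$readout_W), pn$readout_b)))
        dec_in <- f2
      }
      if (recurrent) {
        ds <- t_lstm_step(tape, dec_in, h_dec, c_dec,
                          pn$dec_Wx, pn$dec_Wh, pn$dec_b, R)
        h_dec <<- ds$h; c_dec <<- ds$c
      } else {
        h_dec <<- t_tanh(tape, t_add(tape, t_matmul(tape, dec_in, pn$dec_fc_W),
                                     pn$dec_fc_b))
      }
      scores <<- t_add(tape, scores, mags)
      patch_flat <- t_add(tape, t_matmul(tape, h_dec, pn$write_W), pn$write_b)
      if (has_glimpse) {
        patch <- t_reshape(tape, patch_flat, M, M)
        raw_w <- t_add(tape, t_matmul(tape, h_dec, pn$write_pose_W),
                       pn$write_pose_b)
        fw <- tape_filters(tape, raw_w, H, W, M)
        write_pose <- fw$pose
        inc <- t_matmul(tape, t_matmul(tape, t_transpose(tape, fw$Fy), patch),
                        fw$Fx)
      } else {
        inc <- t_reshape(tape, patch_flat, H, W)
      }
      canvas <<- t_add(tape, canvas, inc)
      list(read_pose = read_pose,
           glimpse = glimpse$value,
           conv_features = as.numeric(feat$value),
           class_magnitudes = as.numeric(mags$value),
           most_active = which.max(as.numeric(mags$value)),
           write_pose = write_pose,
           canvas_increment = inc$value)
    }
    traces[[tstep]] <- tryCatch(step(), error = function(e)
      stop("episode aborted at timestep ", tstep, ": ", conditionMessage(e),
           call. = FALSE))
  }
  if (has_glimpse) {
    coverage <- coverage / cfg$timesteps
    if (max(coverage) > 0) coverage <- coverage / max(coverage)
  } else coverage <- matrix(1, H, W)

  ep <- list(traces = traces,
             cumulative_scores = as.numeric(scores$value),
             canvas = canvas$value,
             coverage = coverage,
             config = cfg)

  if (!is.null(targets)) {
    if (is.null(loss_cfg)) loss_cfg <- loss_config()
    active <- !is.na(targets)
    tg <- ifelse(active, targets, 0)
    m <- loss_cfg$margin
    gate_p <- pmin(tg, 1) * active
    gate_a <- loss_cfg$lambda_absent * (tg == 0) * active
    pu <- t_relu(tape, t_sub(tape, tp_const(tape, matrix(tg - m, K, 1)),
                             scores))
    present <- t_cmul(tape, t_mul(tape, pu, pu), matrix(gate_p, K, 1))
    au <- t_relu(tape, t_shift(tape, scores, -m))
    absent <- t_cmul(tape, t_mul(tape, au, au), matrix(gate_a, K, 1))
    class_loss <- t_sum(tape, t_add(tape, present, absent))
    diff <- t_sub(tape, canvas, img)
    sq <- t_mul(tape, diff, diff)
    if (loss_cfg$masked) sq <- t_cmul(tape, sq, coverage)
    recon <- t_mean(tape, sq)
    total <- t_add(tape, class_loss, t_scale(tape, recon,
                                             loss_cfg$lambda_recon))
    ep$loss <- list(class_loss = as.numeric(class_loss$value),
                    recon_loss = as.numeric(recon$value),
                    total = as.numeric(total$value))
    ep$.tape <- tape
    ep$.total_node <- total
    ep$.param_nodes <- pn
  }
  class(ep) <- "ocra_episode"
  ep
}

#' Loss and parameter gradients for one sample
#'
#' Runs [run_episode()] with a loss and backpropagates it through the whole
#' timestep loop (attention filters, CNN, recurrences, routing, decoder).
#'
#' @inheritParams run_episode
#' @return List with `loss` (components) and `grads` (named list matching
#'   `model$params`; parameters not reached by the loss get zero arrays).
#' @export
ocra_grad <- function(model, image, targets, loss_cfg = loss_config()) {
  ep <- run_episode(model, image, targets = targets, loss_cfg = loss_cfg)
  tp_backward(ep$.tape, ep$.total_node)
  grads <- lapply(names(model$params), function(nm) {
    g <- ep$.param_nodes[[nm]]$grad
    if (is.null(g)) array(0, dim = dim(model$params[[nm]])) else g
  })
  names(grads) <- names(model$params)
  list(loss = ep$loss, grads = grads)
}

#' Decide the two digits from cumulative class scores
#'
#' Selects the top two of the multiset `{(j, s_j)} U {(j, s_j - 1)}`: the
#' same class is predicted twice iff its score exceeds every other score by
#' more than 1 (each instance of a class can contribute at most 1 per
#' timestep-normalized unit of evidence). Ties break toward the lowest
#' class index.
#'
#' @param cumulative_scores K-vector (K = 10 for digit tasks).
#' @return Integer vector of 2 class labels (0-based), sorted.
#' @export
predict_digits <- function(cumulative_scores) {
  s <- as.numeric(cumulative_scores)
  K <- length(s)
  cand_class <- c(seq_len(K), seq_len(K)) - 1L
  cand_score <- c(s, s - 1)
  ord <- order(-cand_score, cand_class)
  sort(cand_class[ord[1:2]])
}

#' Decide same vs. different from cumulative response-capsule scores
#'
#' Only the two designated response capsules matter; ties go to
#' `"different"`.
#'
#' @param cumulative_scores length-4 vector of cumulative magnitudes.
#' @param response_idx 1-based indices `c(i_same, i_diff)`.
#' @return `"same"` or `"different"`.
#' @export
predict_same_different <- function(cumulative_scores, response_idx = c(1L, 2L)) {
  s_same <- cumulative_scores[response_idx[1]]
  s_diff <- cumulative_scores[response_idx[2]]
  if (s_same > s_diff) "same" else "different"
}
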