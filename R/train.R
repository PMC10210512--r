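# Adam training of the combined margin + reconstruction loss, image-level
# evaluation, and multi-seed (mean +/- SEM) reporting.

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))),
       t = 0L)
}

adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

#' Margin-loss target vector for one sample
#'
#' Recognition: counts of each class among the two labels (sums to 2).
#' Reasoning: the matching response capsule gets target 1, the other
#' response capsule 0, and the non-response (gist/temporary) capsules get
#' `NA` -- they carry no supervision and receive zero loss gradient.
#'
#' @param config an [ocra_config()].
#' @param label length-2 integer labels (recognition) or `"same"` /
#'   `"different"` (reasoning).
#' @return numeric K-vector (with `NA` for unsupervised capsules).
#' @export
ocra_targets <- function(config, label) {
  if (config$task == "reasoning") {
    tg <- rep(NA_real_, config$n_class)
    same <- identical(label, "same")
    tg[config$response_idx[1]] <- as.numeric(same)
    tg[config$response_idx[2]] <- as.numeric(!same)
    tg
  } else {
    targets_from_labels(label, config$n_class)
  }
}

#' Train a model with Adam
#'
#' Minibatch gradients are accumulated sample by sample (the autodiff tape
#' is per-sample) and averaged for each Adam update. Loss components are
#' logged per epoch and optionally per update to a CSV training log. A
#' non-finite loss halts training with a diagnostic.
#'
#' @param model an [ocra_model()].
#' @param dataset an `"ocra_dataset"` whose task matches the model.
#' @param loss_cfg a [loss_config()]; `masked` is forced on for the
#'   cluttered task if not set explicitly.
#' @param epochs,batch_size,lr Adam optimization settings.
#' @param seed seed for the epoch shuffling.
#' @param log_csv optional path for a per-update CSV log (epoch, batch,
#'   class_loss, recon_loss, total).
#' @param verbose print per-epoch losses.
#' @return List: `model` (trained), `history` (per-epoch data.frame with
#'   mean `class_loss`, `recon_loss`, `total`).
#' @export
ocra_train <- function(model, dataset, loss_cfg = NULL, epochs = 1L,
                       batch_size = 32L, lr = 1e-3, seed = 1L,
                       log_csv = NULL, verbose = FALSE) {
  cfg <- model$config
  if (dataset$task != cfg$task)
    stop("dataset task '", dataset$task, "' does not match model task '",
         cfg$task, "'", call. = FALSE)
  if (is.null(loss_cfg))
    loss_cfg <- loss_config(masked = cfg$task == "cluttered")
  n <- length(dataset$labels)
  params <- model$params
  opt <- adam_init(params)
  hist <- data.frame()
  log_rows <- list()
  for (ep in seq_len(epochs)) {
    ord <- with_seed(mix_seed(seed, ep, 57L), sample.int(n))
    ep_loss <- c(class_loss = 0, recon_loss = 0, total = 0)
    nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      bidx <- ord[b0:min(b0 + batch_size - 1L, n)]
      acc <- NULL
      bl <- c(class_loss = 0, recon_loss = 0, total = 0)
      for (i in bidx) {
        gr <- ocra_grad(structure(list(config = cfg, params = params),
                                  class = "ocra_model"),
                        dataset$images[[i]],
                        ocra_targets(cfg, dataset$labels[[i]]), loss_cfg)
        if (!is.finite(gr$loss$total))
          stop("non-finite loss at epoch ", ep, ", sample ", i,
               " (class=", gr$loss$class_loss,
               ", recon=", gr$loss$recon_loss, ")", call. = FALSE)
        acc <- if (is.null(acc)) gr$grads else
          mapply(`+`, acc, gr$grads, SIMPLIFY = FALSE)
        bl <- bl + unlist(gr$loss)
      }
      acc <- lapply(acc, function(g) g / length(bidx))
      up <- adam_step(opt, params, acc, lr = lr)
      opt <- up$state; params <- up$params
      nb <- nb + 1L
      bl <- bl / length(bidx)
      ep_loss <- ep_loss + bl
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = ep, batch = nb, class_loss = bl[1],
                   recon_loss = bl[2], total = bl[3])
    }
    ep_loss <- ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, class_loss = ep_loss[1],
                                   recon_loss = ep_loss[2],
                                   total = ep_loss[3]))
    if (verbose)
      message(sprintf("epoch %d: class %.4f recon %.4f total %.4f",
                      ep, ep_loss[1], ep_loss[2], ep_loss[3]))
  }
  if (!is.null(log_csv))
    utils::write.csv(do.call(rbind, log_rows), log_csv, row.names = FALSE)
  rownames(hist) <- NULL
  list(model = structure(list(config = cfg, params = params),
                         class = "ocra_model"),
       history = hist)
}

multiset_equal <- function(a, b) identical(sort(a), sort(b))

#' Evaluate a model at the image level
#'
#' An image counts as correct only if the full predicted label multiset
#' matches the ground truth (recognition: both digits, order-free;
#' reasoning: the same/different response).
#'
#' @param model an `"ocra_model"` (or a predictor function mapping an image
#'   to a cumulative score vector, e.g. an oracle stub in tests).
#' @param dataset an `"ocra_dataset"` whose task matches.
#' @return List of class `"ocra_eval"`: `image_level_accuracy`, `n`,
#'   `predictions`, and for recognition a per-class `confusion` summary
#'   (counts of true instances vs. correctly recovered instances).
#' @export
ocra_evaluate <- function(model, dataset) {
  is_fun <- is.function(model)
  if (!is_fun && dataset$task != model$config$task)
    stop("dataset task does not match model task", call. = FALSE)
  task <- dataset$task
  n <- length(dataset$labels)
  correct <- logical(n)
  preds <- vector("list", n)
  K <- if (is_fun) NULL else model$config$n_class
  conf <- NULL
  if (task != "reasoning" && !is.null(K))
    conf <- matrix(0, K, 2, dimnames = list(NULL, c("true", "recovered")))
  for (i in seq_len(n)) {
    scores <- if (is_fun) model(dataset$images[[i]])
    else run_episode(model, dataset$images[[i]])$cumulative_scores
    if (task == "reasoning") {
      ri <- if (is_fun) c(1L, 2L) else model$config$response_idx
      preds[[i]] <- predict_same_different(scores, ri)
      correct[i] <- identical(preds[[i]], dataset$labels[[i]])
    } else {
      preds[[i]] <- predict_digits(scores)
      truth <- sort(dataset$labels[[i]])
      correct[i] <- multiset_equal(preds[[i]], truth)
      if (!is.null(conf)) {
        for (cl in unique(truth)) {
          nt <- sum(truth == cl)
          conf[cl + 1L, "true"] <- conf[cl + 1L, "true"] + nt
          conf[cl + 1L, "recovered"] <- conf[cl + 1L, "recovered"] +
            min(nt, sum(preds[[i]] == cl))
        }
      }
    }
  }
  structure(list(image_level_accuracy = mean(correct), n = n,
                 predictions = preds, correct = correct, confusion = conf),
            class = "ocra_eval")
}

#' Mean and standard error over per-seed accuracies
#'
#' @param accuracies numeric vector (one accuracy per training seed).
#' @return list with `n_runs`, `mean`, `sem`.
#' @export
summarize_accuracies <- function(accuracies) {
  n <- length(accuracies)
  list(n_runs = n, mean = mean(accuracies),
       sem = if (n > 1) stats::sd(accuracies) / sqrt(n) else NA_real_)
}

#' Train and evaluate across several seeds (mean +/- SEM reporting)
#'
#' @param config an [ocra_config()].
#' @param train_data,test_data datasets for the configured task.
#' @param seeds model-init/training seeds; default `0:4` (five runs).
#' @param ... passed to [ocra_train()].
#' @return list with `accuracies`, `summary` ([summarize_accuracies()]),
#'   and the per-seed trained models.
#' @export
ocra_run_seeds <- function(config, train_data, test_data, seeds = 0:4, ...) {
  acc <- numeric(length(seeds))
  models <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    fit <- ocra_train(ocra_model(config, seed = seeds[k]), train_data,
                      seed = seeds[k], ...)
    models[[k]] <- fit$model
    acc[k] <- ocra_evaluate(fit$model, test_data)$image_level_accuracy
  }
  list(accuracies = acc, summary = summarize_accuracies(acc),
       models = models)
}
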