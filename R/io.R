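# Dataset export/import (8-bit grayscale PNG + CSV manifest; the manifest
# is the source of truth), an RDS container for fast loading, checkpoints
# with a JSON config sidecar, and YAML run configurations.

#' Write a dataset as PNG images plus a CSV manifest
#'
#' @param dataset an `"ocra_dataset"` with images.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (is.null(dataset$images))
    stop("dataset was generated without images", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$labels)
  fn <- sprintf("img_%06d.png", seq_len(n))
  reasoning <- dataset$task == "reasoning"
  for (i in seq_len(n))
    png::writePNG(pmin(pmax(dataset$images[[i]], 0), 1),
                  file.path(dir, fn[i]))
  man <- data.frame(
    filename = fn, split = dataset$split, task = dataset$task,
    label1 = if (reasoning) NA_integer_ else
      vapply(dataset$labels, function(l) l[1], integer(1)),
    label2 = if (reasoning) NA_integer_ else
      vapply(dataset$labels, function(l) l[2], integer(1)),
    same_different = if (reasoning)
      vapply(dataset$labels, identity, character(1)) else NA_character_,
    family = vapply(dataset$meta, function(m) m$family %||% NA_character_,
                    character(1)),
    seed = dataset$seed,
    index = seq_len(n), stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return an `"ocra_dataset"` (8-bit quantized images).
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  images <- lapply(man$filename, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  task <- man$task[1]
  labels <- if (task == "reasoning") as.list(man$same_different)
  else lapply(seq_len(nrow(man)), function(i)
    c(man$label1[i], man$label2[i]))
  meta <- lapply(seq_len(nrow(man)), function(i)
    list(family = if (is.na(man$family[i])) NULL else man$family[i],
         index = man$index[i]))
  new_dataset(task, dim(images[[1]]), images, labels, meta,
              man$seed[1], man$split[1])
}

#' Fast single-file dataset container (RDS; runtime artifact, not shipped)
#' @param dataset an `"ocra_dataset"`.
#' @param path `.rds` path.
#' @export
save_dataset_rds <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset_rds
#' @export
load_dataset_rds <- function(path) readRDS(path)

#' Save / load a model checkpoint with a JSON config sidecar
#'
#' The checkpoint itself is an opaque binary (RDS); `<path>.json` records
#' the model configuration and seed in plain text so a run is auditable and
#' reproducible without deserializing the weights.
#'
#' @param model an `"ocra_model"`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @param extra optional named list merged into the sidecar (seed, task...).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(model, path)
  side <- c(list(config = unclass(model$config),
                 n_parameters = count_parameters(model)), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Read / write a run configuration (YAML)
#'
#' A run configuration bundles the model configuration, loss settings,
#' optimizer settings (Adam learning rate, batch size, epochs), dataset
#' generator settings, seed and output directory; a run is reproducible
#' from this file alone.
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param cfg named list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export coupling coefficients to CSV for inspection
#'
#' @param capsules a `"class_capsules"` object from [route_capsules()].
#' @param path CSV path.
#' @export
write_couplings_csv <- function(capsules, path) {
  utils::write.csv(as.data.frame(capsules$couplings), path,
                   row.names = FALSE)
  invisible(path)
}
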