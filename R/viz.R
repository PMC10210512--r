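# Glimpse-trajectory visualization: per-timestep panels showing the input
# with the read window (green box), the retrojected glimpse in image
# dimensions, and the cumulative canvas with the write window (red box),
# captioned with the most active capsule and its magnitude.

to_rgb <- function(img) {
  img <- pmin(pmax(img, 0), 1)
  array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
}

draw_box <- function(rgb, box, color = c(0, 1, 0)) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  r1 <- max(1L, round(box["top"])); r2 <- min(H, round(box["bottom"]))
  c1 <- max(1L, round(box["left"])); c2 <- min(W, round(box["right"]))
  if (r1 > H || r2 < 1L || c1 > W || c2 < 1L || r1 > r2 || c1 > c2)
    return(rgb)
  for (ch in 1:3) {
    rgb[r1, c1:c2, ch] <- color[ch]
    rgb[r2, c1:c2, ch] <- color[ch]
    rgb[r1:r2, c1, ch] <- color[ch]
    rgb[r1:r2, c2, ch] <- color[ch]
  }
  rgb
}

#' Visualize an episode's glimpse trajectory
#'
#' For each timestep, builds three image-sized panels: the input with the
#' read attention window overlaid as a green box; the read glimpse
#' retrojected into image dimensions through the read filters; and the
#' cumulative canvas with the write window as a red box. Panels are stacked
#' vertically per timestep and written one PNG per step plus a composite
#' strip, replicating the stepwise layout used to inspect attention
#' behavior. Captions (most active capsule and its magnitude, always in
#' `[0, 1)`) are returned alongside.
#'
#' @param model an `"ocra_model"`.
#' @param image input image for the model's task.
#' @param out_dir optional directory; when given, PNGs are written there.
#' @return Invisibly, a list with `panels` (per-step H x W x 3 arrays),
#'   `captions` (data.frame: step, capsule, magnitude), `files`.
#' @export
visualize_episode <- function(model, image, out_dir = NULL) {
  cfg <- model$config
  ep <- run_episode(model, image)
  T_ <- cfg$timesteps
  has_glimpse <- cfg$variant %in% c("full", "no_capsules")
  panels <- vector("list", T_)
  caps <- data.frame(step = seq_len(T_), capsule = NA_integer_,
                     magnitude = NA_real_)
  canvas_so_far <- matrix(0, nrow(image), ncol(image))
  files <- character(0)
  for (t in seq_len(T_)) {
    tr <- ep$traces[[t]]
    canvas_so_far <- canvas_so_far + tr$canvas_increment
    top <- to_rgb(image)
    mid <- to_rgb(image * 0)
    if (has_glimpse) {
      top <- draw_box(top, pose_box(tr$read_pose, cfg$glimpse_size),
                      c(0, 1, 0))
      grid <- build_filters(tr$read_pose, cfg$glimpse_size, cfg$image_shape)
      retro <- write_patch(tr$glimpse, grid)
      if (max(retro) > 0) retro <- retro / max(retro)
      mid <- to_rgb(retro)
    } else {
      mid <- to_rgb(tr$glimpse)
    }
    bot <- to_rgb(canvas_so_far)
    if (has_glimpse)
      bot <- draw_box(bot, pose_box(tr$write_pose, cfg$patch_size),
                      c(1, 0, 0))
    panel <- array(0, dim = c(3 * nrow(image) + 2, ncol(image), 3))
    panel[seq_len(nrow(image)), , ] <- top
    panel[nrow(image) + 1 + seq_len(nrow(image)), , ] <- mid
    panel[2 * nrow(image) + 2 + seq_len(nrow(image)), , ] <- bot
    panels[[t]] <- panel
    caps$capsule[t] <- tr$most_active
    caps$magnitude[t] <- tr$class_magnitudes[tr$most_active]
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, sprintf("step_%02d.png", t))
      png::writePNG(panel, f)
      files <- c(files, f)
    }
  }
  if (!is.null(out_dir)) {
    strip <- do.call(function(...) abind_cols(list(...)), panels)
    f <- file.path(out_dir, "episode.png")
    png::writePNG(strip, f)
    utils::write.csv(caps, file.path(out_dir, "captions.csv"),
                     row.names = FALSE)
    files <- c(files, f)
  }
  invisible(list(panels = panels, captions = caps, files = files))
}

# column-concatenate a list of equal-height H x W x 3 arrays with 2-px gaps
abind_cols <- function(arrs) {
  H <- dim(arrs[[1]])[1]
  Wtot <- sum(vapply(arrs, function(a) dim(a)[2], numeric(1))) +
    2L * (length(arrs) - 1L)
  out <- array(0, dim = c(H, Wtot, 3))
  at <- 1L
  for (a in arrs) {
    w <- dim(a)[2]
    out[, at:(at + w - 1L), ] <- a
    at <- at + w + 2L
  }
  out
}
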