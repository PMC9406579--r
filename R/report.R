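# Reporting: learning curves, per-case metric charts and overlay panels.

#' Learning-curve plot of a training history
#'
#' @param object An `rda_model` or its history tibble.
#' @param ... Unused.
#' @return A ggplot: loss and pixel accuracy against epoch, for the training
#'   and validation sets.
#' @method autoplot rda_model
#' @export
autoplot.rda_model <- function(object, ...) {
  plot_history(object$history)
}

#' @rdname autoplot.rda_model
#' @param history History tibble with columns `epoch`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`.
#' @export
plot_history <- function(history) {
  long <- tidyr::pivot_longer(history, -"epoch",
                              names_to = c("set", "metric"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-case metric bar chart
#'
#' @param cases Per-case metric tibble from [evaluate_run()].
#' @param metrics Which metric columns to show.
#' @export
plot_case_metrics <- function(cases, metrics = c("dsc", "iou", "acc")) {
  long <- tidyr::pivot_longer(cases, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$case_id, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# Four-panel overlay: original | ground truth | prediction | superposition.
overlay_panel <- function(image_norm, gt, pred) {
  orig <- array(rep(image_norm, 3), c(dim(image_norm), 3))
  p_gt <- overlay_contour(image_norm, gt, c(1, 1, 1))
  p_pr <- overlay_contour(image_norm, pred, c(1, 0, 0))
  p_both <- overlay_contour(image_norm, gt, c(1, 1, 1))
  bnd <- boundary_mask(pred) == 1
  for (ch in 1:3) {
    plane <- p_both[, , ch]
    plane[bnd] <- c(1, 0, 0)[ch]
    p_both[, , ch] <- plane
  }
  panel <- array(0, c(nrow(image_norm), 4 * ncol(image_norm), 3))
  w <- ncol(image_norm)
  panel[, 1:w, ] <- orig
  panel[, w + 1:w, ] <- p_gt
  panel[, 2 * w + 1:w, ] <- p_pr
  panel[, 3 * w + 1:w, ] <- p_both
  panel
}

#' Render a training/evaluation report
#'
#' Writes learning-curve and per-case bar-chart figures, and for each
#' requested sample a four-panel overlay PNG (original, ground-truth
#' contour, predicted contour, superposition). Rendering failures are
#' logged, not raised.
#'
#' @param model A trained `rda_model`.
#' @param eval Result of [evaluate_run()].
#' @param manifest Manifest the evaluation used.
#' @param out_dir Output directory.
#' @param overlay_ids Sample ids to render as overlays (default: first 4
#'   evaluated cases).
#' @param threshold Binarization threshold for the overlays.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(model, eval, manifest, out_dir,
                          overlay_ids = head(eval$cases$case_id, 4),
                          threshold = 0.5) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  try_write <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      message("report: could not render ", what, ": ", conditionMessage(e))
      NULL
    })
  }
  p1 <- file.path(out_dir, "learning_curves.png")
  try_write({
    ggplot2::ggsave(p1, plot_history(model$history), width = 7, height = 4, dpi = 120)
    paths <<- c(paths, p1)
  }, "learning curves")
  p2 <- file.path(out_dir, "case_metrics.png")
  try_write({
    ggplot2::ggsave(p2, plot_case_metrics(eval$cases), width = 7, height = 4, dpi = 120)
    paths <<- c(paths, p2)
  }, "case metrics")
  for (id in overlay_ids) {
    i <- match(id, manifest$sample_id)
    if (is.na(i)) next
    p <- file.path(out_dir, paste0("overlay_", id, ".png"))
    try_write({
      sm <- load_manifest_sample(manifest, i)
      pp <- prepare_sample(sm, model$arch$input_size, model$window,
                           model$cfg$target)
      fw <- net_forward(model$net, pp$x, training = FALSE)
      pred <- (fw$prob[, , 1, 1] >= threshold) * 1
      write_png(overlay_panel(pp$x, pp$y, pred), p)
      paths <<- c(paths, p)
    }, paste0("overlay ", id))
  }
  invisible(paths)
}
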