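# Print / summary / coef / plot methods for the package's classed objects.

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("Synthetic EMU scene: %d frames of %dx%d @ %g fps\n",
              x$frame_count, x$height, x$width, x$fps))
  cat(sprintf("  bed %g mm (+/- %g mm band), motion %.2f Hz (amp %g px)\n",
              x$bed_depth_mm, x$bed_band_halfwidth_mm, x$motion_freq_hz,
              x$motion_amp_px))
  cat(sprintf("  pepper %.3f, occluder: %s, class: %s, seed %d\n",
              x$pepper_fraction,
              if (is.null(x$occluder)) "none"
              else sprintf("%g mm", x$occluder$depth_mm),
              x$class_label, x$seed))
  invisible(x)
}

#' @export
print.crop_planes <- function(x, ...) {
  cat(sprintf(
    "Depth crop planes: bed axis %s, patient line %d\n", x$bed_axis,
    x$line_index))
  cat(sprintf("  line fit %.1f %+.3f t mm, sigma %.1f mm, half-width %.1f mm\n",
              x$line_fit[["intercept"]], x$line_fit[["slope"]], x$sigma,
              x$halfwidth))
  invisible(x)
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Fold %d: %d train / %d validation patients (",
              x$fold_id, length(x$train_patients), length(x$val_patients)))
  cat(paste(names(x$val_counts), as.integer(x$val_counts), sep = ":",
            collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf("%s seizure classifier (%d classes)%s\n",
              x$arch, x$spec$n_classes,
              if (x$trained) "" else " [untrained]"))
  pc <- parameter_counts(x)
  cat("  trainable parameters:",
      paste(names(pc), format(pc, big.mark = ","), sep = "=",
            collapse = ", "),
      sprintf("(total %s)\n", format(sum(pc), big.mark = ",")))
  if (x$trained && !is.null(x$best_epoch) && !is.na(x$best_epoch))
    cat(sprintf("  best epoch %d, val macro-F1 %.3f\n", x$best_epoch,
                x$history$val_macro_f1[x$best_epoch]))
  invisible(x)
}

#' @export
summary.seizure_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("Training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  if (!is.null(object$class_weights)) {
    cat("Class weights:\n")
    print(round(object$class_weights, 3))
  }
  invisible(object)
}

#' @export
coef.seizure_model <- function(object, ...) flatten_params(object$params)

#' Plot training curves of a fitted classifier
#'
#' @param x fitted `seizure_model` with a history.
#' @param ... passed to [graphics::plot()].
#' @export
plot.seizure_model <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stopf("model has no training history")
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  if (!all(is.na(h$val_macro_f1))) {
    graphics::plot(h$epoch, h$val_macro_f1, type = "l", xlab = "epoch",
                   ylab = "macro-F1", main = "validation macro-F1", ...)
    if (!is.null(x$best_epoch))
      graphics::abline(v = x$best_epoch, lty = 3)
  }
  invisible(x)
}

#' @export
print.seizure_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold subject-grouped CV, %s classifier, %d classes (%s)\n",
              nrow(x$per_fold), x$arch, x$n_classes,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  macro-F1: %.3f +/- %.3f\n",
              x$summary["mean", "macro_f1"], x$summary["sd", "macro_f1"]))
  invisible(x)
}

#' @export
summary.seizure_cv_report <- function(object, ...) {
  print(object)
  cat("\nPer fold:\n")
  print(object$per_fold, row.names = FALSE, digits = 3)
  cat("\nMean +/- sd over folds:\n")
  print(round(object$summary, 4))
  invisible(object)
}

#' @export
print.sample_store <- function(x, ...) {
  cat(sprintf("Sample store: %d clips from %d videos (variant %s)\n",
              length(x$clips),
              if (is.null(x$log)) 0L else nrow(x$log),
              x$config$variant))
  if (!is.null(x$log))
    cat(sprintf("  crop success %d/%d, detection success %d/%d\n",
                sum(x$log$crop_ok), nrow(x$log),
                sum(x$log$detect_ok), nrow(x$log)))
  invisible(x)
}

#' @export
print.feature_store <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("Feature store: %d sequences of %d x %d (%s)\n", d[1], d[2],
              d[3], paste(levels(x$labels), table(x$labels), sep = ":",
                          collapse = ", ")))
  invisible(x)
}
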