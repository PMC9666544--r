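# External interfaces: multi-page 16-bit TIFF stacks, JSON manifests and
# crop metadata, CSV/JSON metric reports, PNG QC montages.

#' Write / read a 16-bit grayscale stack as multi-page TIFF
#'
#' Values are stored as 16-bit samples (0..65535).
#'
#' @param stack H x W x T integer array.
#' @param path file path.
#' @export
write_stack16 <- function(stack, path) {
  v <- as_stack(stack, "stack")
  pages <- lapply(seq_len(dim(v)[3]), function(t) v[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_stack16
#' @export
read_stack16 <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) out[, , t] <- as.integer(pages[[t]])
  out
}

# 8-bit stack (for truth masks).
write_stack8 <- function(stack, path) {
  v <- as_stack(stack, "stack")
  pages <- lapply(seq_len(dim(v)[3]), function(t) (v[, , t] != 0) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

read_stack8 <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(FALSE, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) out[, , t] <- pages[[t]] > 0
  out
}

#' Write / read one synthetic scene to a directory
#'
#' Depth and IR stacks as multi-page 16-bit TIFF, the truth mask as an 8-bit
#' TIFF stack, and truth metadata (bed box, depth band, class) plus the
#' scene configuration as JSON.
#'
#' @param scene a [generate_scene()] result.
#' @param path directory to create.
#' @export
write_scene <- function(scene, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_stack16(scene$depth, file.path(path, "depth.tif"))
  write_stack16(scene$ir, file.path(path, "ir.tif"))
  write_stack8(scene$truth$patient_mask, file.path(path, "patient_mask.tif"))
  meta <- list(
    bed_bbox = unclass(scene$truth$bed_bbox),
    depth_band = as.list(scene$truth$depth_band),
    class_label = scene$truth$class_label,
    config = unclass(scene$config)
  )
  jsonlite::write_json(meta, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "truth.json"),
                              simplifyVector = TRUE)
  truth <- list(
    patient_mask = read_stack8(file.path(path, "patient_mask.tif")),
    bed_bbox = do.call(bbox, meta$bed_bbox[c("top", "left", "bottom",
                                             "right")]),
    depth_band = c(near_mm = meta$depth_band$near_mm,
                   far_mm = meta$depth_band$far_mm),
    class_label = meta$class_label
  )
  list(depth = read_stack16(file.path(path, "depth.tif")),
       ir = read_stack16(file.path(path, "ir.tif")),
       truth = truth, config = meta$config)
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return A list with `manifest` and (lazily empty) `videos`; scenes are
#'   loaded per video by [run_preprocess()] via their manifest paths.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(manifest = manifest, videos = list())
}

#' Write a cross-validation metrics report as CSV and JSON
#'
#' @param report a `"seizure_cv_report"`.
#' @param path output path without extension; `<path>.csv` gets the per-fold
#'   table and `<path>.json` the per-fold table plus the mean/sd summary and
#'   fold assignments.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.csv(report$per_fold, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_fold = report$per_fold,
         summary = cbind(stat = rownames(report$summary), report$summary),
         classes = report$classes, arch = report$arch,
         folds = lapply(report$folds, function(f)
           list(fold_id = f$fold_id, train_patients = f$train_patients,
                val_patients = f$val_patients))),
    paste0(path, ".json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a quality-control montage of a video crop
#'
#' Writes a PNG of 5 frames evenly spaced through the stack (always
#' including the first and last frame), normalised to [0, 1], with the crop
#' box drawn as a bright border. Needs the optional \pkg{png} package;
#' silently returns `NULL` otherwise.
#'
#' @param stack H x W x T array.
#' @param path output PNG path.
#' @param box optional [bbox()] to draw.
#' @export
save_qc_montage <- function(stack, path, box = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("package 'png' not available; QC montage skipped")
    return(invisible(NULL))
  }
  v <- as_stack(stack, "stack")
  TT <- dim(v)[3]
  idx <- unique(round(seq(1, TT, length.out = min(5L, TT))))
  rng <- range(v)
  norm <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  frames <- lapply(idx, function(t) {
    m <- norm[, , t]
    if (!is.null(box)) {
      m[c(box$top, box$bottom), box$left:box$right] <- 1
      m[box$top:box$bottom, c(box$left, box$right)] <- 1
    }
    m
  })
  png::writePNG(do.call(cbind, frames), path)
  invisible(path)
}

#' Serialize crop metadata (planes, boxes, detections) as JSON
#'
#' @param path output JSON path.
#' @param planes optional [compute_crop_planes()] result.
#' @param box optional expanded crop [bbox()].
#' @param detections optional list of [detection()] objects.
#' @export
write_crop_metadata <- function(path, planes = NULL, box = NULL,
                                detections = NULL) {
  meta <- list()
  if (!is.null(planes))
    meta$planes <- list(bed_axis = planes$bed_axis,
                        line_index = planes$line_index,
                        line_fit = as.list(planes$line_fit),
                        sigma = planes$sigma, halfwidth = planes$halfwidth)
  if (!is.null(box)) meta$crop_box <- unclass(box)
  if (!is.null(detections))
    meta$detections <- lapply(detections, function(d)
      list(label = d$label, confidence = d$confidence,
           box = unclass(d$box)))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a feature store
#'
#' Feature stores are persisted in R's native serialization.
#'
#' @param fstore a `"feature_store"`.
#' @param path file path (`.rds`).
#' @export
save_feature_store <- function(fstore, path) {
  stopifnot(inherits(fstore, "feature_store"))
  saveRDS(fstore, path)
  invisible(path)
}

#' @rdname save_feature_store
#' @export
load_feature_store <- function(path) {
  fs <- readRDS(path)
  stopifnot(inherits(fs, "feature_store"))
  fs
}

#' Save a classifier checkpoint
#'
#' Writes the model in R's native serialization next to a JSON dump of its
#' architecture spec and, when trained, its training curves as CSV.
#'
#' @param model a `seizure_model`.
#' @param path base path without extension: writes `<path>.rds`,
#'   `<path>.spec.json` and (if trained) `<path>.history.csv`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seizure_model"))
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(
    list(arch = model$arch, spec = model$spec, classes = model$classes,
         trained = model$trained,
         parameter_counts = as.list(parameter_counts(model))),
    paste0(path, ".spec.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    utils::write.csv(model$history, paste0(path, ".history.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(m, "seizure_model"))
  m
}
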