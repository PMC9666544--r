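#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations of a full run. The dataset variants
#' mirror the three preprocessing recipes: `"A"` applies only the
#' detector-driven bounding-box crop (the box is still computed on the
#' depth-cropped IR stream, so A and B share identical boxes), `"B"` adds
#' depth-band cropping, and `"B0.5"` is B with 50% window overlap (temporal
#' augmentation).
#'
#' @param variant `"A"`, `"B"` or `"B0.5"`.
#' @param n_classes 2 (FLE vs TLE) or 3 (adds Prepost).
#' @param arch classifier: `"lstm"`, `"lstm-ext"` or `"i3d-head"`.
#' @param extractor feature extractor object (default [mock_extractor()]).
#' @param target_size spatial side length of clip frames (default 224).
#' @param window,min_leftover temporal slicing parameters; the overlap is
#'   fixed by the variant.
#' @param min_halfwidth_mm minimum depth-band half-width.
#' @param denoise apply depth denoising before cropping.
#' @param expand_fraction bounding-box expansion (+30%).
#' @param k cross-validation folds.
#' @param val_per_class validation patients per class per fold (`NULL`:
#'   `floor(n/k)`, at least 1).
#' @param train a [train_config()].
#' @param seed global seed for folds and per-fold model initialisation.
#' @export
pipeline_config <- function(variant = c("B", "A", "B0.5"), n_classes = 3L,
                            arch = c("lstm", "lstm-ext", "i3d-head"),
                            extractor = mock_extractor(), target_size = 224L,
                            window = 60L, min_leftover = 10L,
                            min_halfwidth_mm = 100, denoise = TRUE,
                            expand_fraction = 0.30, k = 5L,
                            val_per_class = NULL, train = train_config(),
                            seed = 1L) {
  variant <- match.arg(variant)
  arch <- match.arg(arch)
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  structure(list(
    variant = variant, n_classes = as.integer(n_classes), arch = arch,
    extractor = extractor, target_size = as.integer(target_size),
    slicing = slicing_config(window,
                             overlap = if (variant == "B0.5") 0.5 else 0,
                             min_leftover = min_leftover),
    min_halfwidth_mm = min_halfwidth_mm, denoise = denoise,
    expand_fraction = expand_fraction, k = as.integer(k),
    val_per_class = val_per_class, train = train, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Preprocess a dataset of seizure videos into clip samples
#'
#' Per video: depth denoising and depth-band cropping, person/bed detection
#' on the first frame of the depth-cropped IR stream, box merging and +30%
#' expansion, bounding-box cropping of the IR stream (the raw stream for
#' variant A, the depth-cropped stream for B/B0.5), per-video 8-bit
#' conversion, spatial resizing to the target geometry, and temporal
#' slicing. Videos whose depth crop or detection fails are flagged in the
#' log for manual-crop substitution and the run continues.
#'
#' @param dataset a [generate_dataset()] result (manifest + videos), or a
#'   directory path containing one written with `dir =`.
#' @param cfg a [pipeline_config()].
#' @return Object of class `"sample_store"`: list with `clips` (each holding
#'   resized 8-bit frames and provenance), `log` (per-video data frame:
#'   crop success, expanded box, window count), and `config`.
#' @export
run_preprocess <- function(dataset, cfg = pipeline_config()) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  man <- dataset$manifest
  clips <- list()
  log_rows <- list()
  if (is.null(man) || nrow(man) == 0L) {
    warning("empty manifest: nothing to preprocess")
    return(structure(list(clips = list(), log = NULL, config = cfg),
                     class = "sample_store"))
  }
  for (i in seq_len(nrow(man))) {
    sid <- man$seizure_id[i]
    sc <- dataset$videos[[sid]]
    if (is.null(sc) && !is.na(man$path[i])) sc <- read_scene(man$path[i])
    entry <- data.frame(seizure_id = sid, crop_ok = FALSE, detect_ok = FALSE,
                        n_windows = 0L, box = NA_character_,
                        stringsAsFactors = FALSE)
    dc <- tryCatch(
      depth_crop(sc$depth, sc$ir, denoise = cfg$denoise,
                 min_halfwidth_mm = cfg$min_halfwidth_mm),
      error = function(e) e)
    if (inherits(dc, "error")) {
      entry$box <- conditionMessage(dc)
      log_rows[[sid]] <- entry
      next
    }
    entry$crop_ok <- TRUE
    det <- oracle_detector(sc$truth)
    dets <- detect(det, dc$ir[, , 1])
    box <- tryCatch(
      expand_box(select_and_merge(dets), cfg$expand_fraction, dim(sc$ir)[1:2]),
      error = function(e) e)
    if (inherits(box, "error")) {
      entry$box <- conditionMessage(box)
      log_rows[[sid]] <- entry
      next
    }
    entry$detect_ok <- TRUE
    entry$box <- format(box)
    ir_stream <- if (cfg$variant == "A") sc$ir else dc$ir
    cropped <- crop_video(ir_stream, box)
    v8 <- to_8bit(cropped)
    wins <- slice_windows(dim(v8)[3], cfg$slicing)
    entry$n_windows <- nrow(wins)
    for (wi in seq_len(nrow(wins))) {
      fr <- v8[, , wins$start[wi]:wins$end[wi], drop = FALSE]
      L <- dim(fr)[3]
      res <- array(0L, c(cfg$target_size, cfg$target_size, L))
      for (t in seq_len(L))
        res[, , t] <- as.integer(round(resize_pad(fr[, , t],
                                                  cfg$target_size)))
      clips[[length(clips) + 1L]] <- list(
        frames8 = res, patient_id = man$patient_id[i], seizure_id = sid,
        class = man$class[i], window = c(wins$start[wi], wins$end[wi]))
    }
    log_rows[[sid]] <- entry
  }
  structure(list(clips = clips, log = do.call(rbind, log_rows),
                 config = cfg),
            class = "sample_store")
}

#' Extract padded feature sequences from a sample store
#'
#' Streams over the stored clips: materialises each as a full
#' [make_clip_sample()] (3-channel, [-1, 1]), extracts its `k x 1024`
#' feature matrix, pre-pads to the fixed sequence shape and stacks
#' everything into a feature store.
#'
#' @param store a [run_preprocess()] result.
#' @param extractor feature extractor; defaults to the one in the store's
#'   config.
#' @param timesteps padded sequence length (7).
#' @return A `"feature_store"` (see [build_feature_store()]).
#' @export
run_extract <- function(store, extractor = NULL, timesteps = 7L) {
  extractor <- extractor %||% store$config$extractor
  n <- length(store$clips)
  if (n == 0L) stopf("sample store is empty")
  feats <- NULL
  labs <- pids <- sids <- character(n)
  wins <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    rec <- store$clips[[i]]
    clip <- make_clip_sample(rec$frames8, rec$patient_id, rec$seizure_id,
                             rec$class, rec$window,
                             target = dim(rec$frames8)[1])
    m <- pad_features(extract_features(extractor, clip), timesteps)
    if (is.null(feats)) feats <- array(0, c(n, timesteps, ncol(m)))
    feats[i, , ] <- m
    labs[i] <- as.character(rec$class)
    pids[i] <- rec$patient_id
    sids[i] <- rec$seizure_id
    wins[i, ] <- rec$window
  }
  structure(list(features = feats, labels = factor(labs), patient_id = pids,
                 seizure_id = sids, window = wins),
            class = "feature_store")
}

#' Run the subject-grouped cross-validated classification experiment
#'
#' Filters the requested classes (the 2-class scenario drops Prepost),
#' builds patient-disjoint folds, and per fold trains the requested
#' classifier with early stopping and evaluates macro metrics and per-class
#' sensitivity/specificity on the held-out patients' clips.
#'
#' @param fstore a feature store from [run_extract()] /
#'   [build_feature_store()].
#' @param cfg a [pipeline_config()].
#' @return Object of class `"seizure_cv_report"`: `per_fold` metrics,
#'   `summary` (mean/sd over folds), per-fold `confusions`, the fold
#'   assignments, and the class levels.
#' @export
run_experiment <- function(fstore, cfg = pipeline_config()) {
  keep_classes <- if (cfg$n_classes == 2L) c("FLE", "TLE")
  else c("FLE", "TLE", "Prepost")
  keep <- as.character(fstore$labels) %in% keep_classes
  if (!any(keep)) stopf("no samples left after class filtering")
  x <- fstore$features[keep, , , drop = FALSE]
  y <- factor(as.character(fstore$labels)[keep],
              levels = intersect(keep_classes,
                                 unique(as.character(fstore$labels)[keep])))
  if (nlevels(y) != cfg$n_classes)
    stopf("classes present (%d) do not match n_classes = %d",
          nlevels(y), cfg$n_classes)
  pid <- fstore$patient_id[keep]
  patients <- unique(data.frame(patient_id = pid, class = as.character(y),
                                stringsAsFactors = FALSE))
  folds <- make_cv_folds(patients, k = cfg$k,
                         val_per_class = cfg$val_per_class, seed = cfg$seed)
  fold_rows <- list()
  confusions <- list()
  model_seeds <- derive_seeds(cfg$seed, cfg$k)
  for (f in seq_along(folds)) {
    fa <- folds[[f]]
    tr <- pid %in% fa$train_patients
    va <- pid %in% fa$val_patients
    model <- switch(cfg$arch,
      "lstm" = build_lstm_classifier(cfg$n_classes, extended = FALSE,
                                     input_dim = dim(x)[3],
                                     seed = model_seeds[f]),
      "lstm-ext" = build_lstm_classifier(cfg$n_classes, extended = TRUE,
                                         input_dim = dim(x)[3],
                                         seed = model_seeds[f]),
      "i3d-head" = build_i3d_head(cfg$n_classes, input_dim = dim(x)[3],
                                  seed = model_seeds[f]))
    tc <- cfg$train
    tc$seed <- model_seeds[f]
    fit <- train_classifier(model, x[tr, , , drop = FALSE], y[tr],
                            x[va, , , drop = FALSE], y[va], tc)
    pred <- predict(fit, x[va, , , drop = FALSE], type = "class")
    cm <- confusion_matrix(factor(y[va], levels = levels(y)),
                           factor(pred, levels = levels(y)))
    mm <- macro_metrics(cm)
    ss <- sensitivity_specificity(cm)
    row <- data.frame(fold = f, n_train = sum(tr), n_val = sum(va),
                      macro_f1 = mm$macro_f1,
                      macro_precision = mm$macro_precision,
                      macro_recall = mm$macro_recall,
                      best_epoch = fit$best_epoch)
    for (ci in seq_len(nlevels(y))) {
      row[[paste0("sens_", levels(y)[ci])]] <- ss$sensitivity[ci]
      row[[paste0("spec_", levels(y)[ci])]] <- ss$specificity[ci]
    }
    fold_rows[[f]] <- row
    confusions[[f]] <- cm
  }
  per_fold <- do.call(rbind, fold_rows)
  structure(list(per_fold = per_fold,
                 summary = summarize_folds(per_fold[-1]),
                 confusions = confusions, folds = folds,
                 classes = levels(y), n_classes = cfg$n_classes,
                 arch = cfg$arch),
            class = "seizure_cv_report")
}

#' Run the full pipeline: preprocess, extract, cross-validated experiment
#'
#' @param dataset a [generate_dataset()] result or dataset directory.
#' @param cfg a [pipeline_config()].
#' @return List with the `"seizure_cv_report"` (`report`), the feature
#'   store, and the preprocessing log.
#' @export
run_pipeline <- function(dataset, cfg = pipeline_config()) {
  store <- run_preprocess(dataset, cfg)
  fstore <- run_extract(store)
  report <- run_experiment(fstore, cfg)
  list(report = report, features = fstore, log = store$log)
}
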