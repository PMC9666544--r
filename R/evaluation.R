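#' Subject-grouped cross-validation folds
#'
#' Builds `k` folds whose validation sets hold a fixed number of patients per
#' class, with all of a patient's seizures (and clips) on one side of the
#' split — grouping by patient prevents identity leakage between training
#' and validation. When a class has exactly `k * val_per_class` patients the
#' folds form an exact partition (each patient validated once); otherwise
#' validation slots are filled without replacement until the class pool is
#' exhausted and then replenished, so with a short pool every patient is
#' validated at least once. The shuffle is seeded.
#'
#' @param patients data frame with columns `patient_id` and `class` (one row
#'   per patient), or a [build_feature_store()] object.
#' @param k number of folds (default 5).
#' @param val_per_class named integer vector of validation patients per
#'   class; `NULL` uses `max(1, floor(n_class / k))` for each class.
#' @param seed shuffle seed.
#' @return List of `k` fold assignments (class `"fold_assignment"`), each
#'   with `fold_id`, `train_patients`, `val_patients` and per-class
#'   validation counts.
#' @export
make_cv_folds <- function(patients, k = 5L, val_per_class = NULL, seed = 1L) {
  if (inherits(patients, "feature_store"))
    patients <- unique(data.frame(patient_id = patients$patient_id,
                                  class = as.character(patients$labels),
                                  stringsAsFactors = FALSE))
  stopifnot(all(c("patient_id", "class") %in% names(patients)))
  if (anyDuplicated(patients$patient_id))
    stopf("patients must be unique (one row per patient)")
  k <- as.integer(k)
  classes <- sort(unique(patients$class))
  if (is.null(val_per_class)) {
    val_per_class <- vapply(classes, function(cl)
      max(1L, sum(patients$class == cl) %/% k), integer(1))
  }
  for (cl in classes) {
    n_cl <- sum(patients$class == cl)
    if (n_cl < val_per_class[[cl]] + 1L)
      stopf("class %s has %d patients; need more than val_per_class = %d",
            cl, n_cl, val_per_class[[cl]])
  }
  with_seed(seed, {
    pools <- lapply(classes, function(cl)
      sample(patients$patient_id[patients$class == cl]))
    names(pools) <- classes
    avail <- pools
    folds <- vector("list", k)
    for (f in seq_len(k)) {
      val <- character(0)
      for (cl in classes) {
        need <- val_per_class[[cl]]
        take <- character(0)
        if (length(avail[[cl]]) >= need) {
          take <- avail[[cl]][seq_len(need)]
          avail[[cl]] <- avail[[cl]][-seq_len(need)]
        } else {
          take <- avail[[cl]]
          refill <- sample(setdiff(pools[[cl]], take))
          extra <- refill[seq_len(need - length(take))]
          take <- c(take, extra)
          avail[[cl]] <- setdiff(refill, extra)
        }
        val <- c(val, take)
      }
      train <- setdiff(patients$patient_id, val)
      counts <- table(patients$class[patients$patient_id %in% val])
      folds[[f]] <- structure(
        list(fold_id = f, train_patients = train, val_patients = val,
             val_counts = counts),
        class = "fold_assignment")
      stopifnot(length(intersect(train, val)) == 0L)
    }
    folds
  })
}

#' Confusion matrix
#'
#' @param y_true,y_pred integer class indices in `1..n_classes`, or factors
#'   sharing levels.
#' @param n_classes number of classes; inferred from factor levels when
#'   omitted.
#' @return `n_classes x n_classes` matrix; entry `(i, j)` counts samples of
#'   true class `i` predicted as class `j`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  if (is.factor(y_true) || is.factor(y_pred)) {
    lv <- levels(y_true) %||% levels(y_pred)
    n_classes <- n_classes %||% length(lv)
    y_true <- as.integer(factor(y_true, levels = lv))
    y_pred <- as.integer(factor(y_pred, levels = lv))
  }
  if (is.null(n_classes)) stopf("n_classes required for integer labels")
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  if (any(is.na(y_true)) || any(is.na(y_pred)) ||
      any(y_true < 1) || any(y_true > n_classes) ||
      any(y_pred < 1) || any(y_pred > n_classes))
    stopf("labels out of range 1..%d", n_classes)
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true))
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  m
}

#' Macro-averaged precision, recall and F1
#'
#' One-vs-rest precision, recall and F1 per class, macro-averaged with equal
#' class weight (immune to class imbalance). Undefined ratios (zero
#' denominators) yield 0 and set the `zero_division` flag.
#'
#' @param conf square confusion matrix (true in rows, predicted in columns).
#' @return List with `per_class` (data frame: precision, recall, f1),
#'   `macro_precision`, `macro_recall`, `macro_f1`, and `zero_division`.
#' @export
macro_metrics <- function(conf) {
  stopifnot(is.matrix(conf), nrow(conf) == ncol(conf), sum(conf) >= 1)
  C <- nrow(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  zd <- FALSE
  safe_div <- function(a, b) {
    bad <- b == 0
    if (any(bad)) zd <<- TRUE
    out <- ifelse(bad, 0, a / ifelse(bad, 1, b))
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  list(per_class = data.frame(precision = precision, recall = recall,
                              f1 = f1),
       macro_precision = mean(precision), macro_recall = mean(recall),
       macro_f1 = mean(f1), zero_division = zd)
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest: `sens_c = TP / (TP + FN)`, `spec_c = TN / (TN + FP)`.
#' Zero denominators yield 0 with the `zero_division` attribute set.
#'
#' @param conf square confusion matrix.
#' @return Data frame with `sensitivity` and `specificity` per class.
#' @export
sensitivity_specificity <- function(conf) {
  stopifnot(is.matrix(conf), nrow(conf) == ncol(conf))
  C <- nrow(conf)
  N <- sum(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- N - tp - fp - fn
  zd <- any(tp + fn == 0) || any(tn + fp == 0)
  sens <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  spec <- ifelse(tn + fp == 0, 0, tn / (tn + fp))
  out <- data.frame(sensitivity = sens, specificity = spec)
  attr(out, "zero_division") <- zd
  out
}

#' Mean and standard deviation of per-fold metrics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' numeric column across folds; a single fold reports sd 0 with the
#' `single_fold` attribute set.
#'
#' @param fold_metrics data frame of per-fold metric values (one row per
#'   fold).
#' @return Data frame with rows `mean` and `sd`.
#' @export
summarize_folds <- function(fold_metrics) {
  stopifnot(nrow(fold_metrics) >= 1L)
  num <- vapply(fold_metrics, is.numeric, logical(1))
  m <- vapply(fold_metrics[num], mean, numeric(1))
  s <- if (nrow(fold_metrics) == 1L) m * 0
  else vapply(fold_metrics[num], stats::sd, numeric(1))
  out <- as.data.frame(rbind(mean = m, sd = s))
  attr(out, "single_fold") <- nrow(fold_metrics) == 1L
  out
}
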