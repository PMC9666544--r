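#' Mock spatio-temporal feature extractor
#'
#' Deterministic stand-in for a pretrained 3D-convolutional backbone, used to
#' exercise the classification stack on synthetic data. The clip is divided
#' into `clamp(floor(L / 8), 1, 7)` contiguous temporal blocks (matching the
#' backbone's temporal stride, 60 frames -> 7 timesteps). Per block it pools
#' simple intensity and motion statistics -- mean/sd intensity, mean/sd/max
#' absolute frame difference, and mean absolute centroid displacement per
#' axis -- and projects them to 1024 dimensions through a fixed,
#' seed-determined random matrix, so that clips with different motion
#' frequencies and amplitudes stay linearly separable.
#'
#' @param seed seed of the random projection; fixed per extractor so the same
#'   clip always yields the same features.
#' @param dim output feature dimension.
#' @return Object of class `"mock_extractor"`.
#' @export
mock_extractor <- function(seed = 42L, dim = 1024L) {
  n_stats <- 8L
  proj <- with_seed(seed, matrix(stats::rnorm(n_stats * dim) / sqrt(n_stats),
                                 n_stats, dim))
  structure(list(seed = as.integer(seed), dim = as.integer(dim),
                 n_stats = n_stats, proj = proj),
            class = "mock_extractor")
}

#' Extract a k x 1024 feature matrix from a clip sample
#'
#' @param extractor an extractor object ([mock_extractor()] or a user-supplied
#'   backend implementing this generic).
#' @param clip a [make_clip_sample()] result with `L` frames,
#'   `L >= min_frames`.
#' @param min_frames shortest admissible clip (default 10).
#' @param ... passed to methods.
#' @return `k x dim` numeric matrix, `k = clamp(floor(L / 8), 1, 7)`.
#' @export
extract_features <- function(extractor, clip, ...) UseMethod("extract_features")

#' @rdname extract_features
#' @export
extract_features.mock_extractor <- function(extractor, clip, min_frames = 10L,
                                            ...) {
  x <- clip$frames
  stopifnot(length(dim(x)) == 4L)
  L <- dim(x)[1]
  if (L < min_frames)
    stopf("clip has %d frames; at least %d required", L, min_frames)
  k <- clamp(L %/% 8L, 1L, 7L)
  gray <- x[, , , 1, drop = TRUE]            # channels are identical
  if (L == 1L) gray <- array(gray, c(1L, dim(x)[2], dim(x)[3]))
  H <- dim(gray)[2]
  # per-frame summaries
  f_mean <- apply(gray, 1, mean)
  f_cr <- f_cc <- numeric(L)
  for (t in seq_len(L)) {
    w <- gray[t, , ] + 1                     # shift to >= 0 for weighting
    sw <- sum(w)
    f_cr[t] <- sum(row(w) * w) / sw
    f_cc[t] <- sum(col(w) * w) / sw
  }
  d_int <- vapply(seq_len(L - 1) + 1L, function(t)
    mean(abs(gray[t, , ] - gray[t - 1L, , ])), numeric(1))
  bounds <- floor(seq_len(k) * L / k)
  lo <- c(1L, head(bounds, -1L) + 1L)
  out <- matrix(0, k, extractor$dim)
  for (j in seq_len(k)) {
    idx <- lo[j]:bounds[j]
    di <- d_int[pmax(idx[-1] - 1L, 1L)]
    if (!length(di)) di <- 0
    stats_j <- c(
      mean(f_mean[idx]),
      stats::sd(c(f_mean[idx], 0)),
      mean(di), max(di),
      if (length(di) > 1) stats::sd(di) else 0,
      mean(abs(diff(f_cr[idx]))) %||% 0,
      mean(abs(diff(f_cc[idx]))) %||% 0,
      diff(range(f_cc[idx]))
    )
    stats_j[!is.finite(stats_j)] <- 0
    # fixed a-priori scales so the heterogeneous statistics land on
    # comparable magnitudes before projection
    scales <- c(1, 1, 0.02, 0.02, 0.02, H / 50, H / 50, H / 25)
    out[j, ] <- (stats_j / scales) %*% extractor$proj
  }
  # -1 is reserved as the padding sentinel
  out[out == -1] <- -1 + 1e-6
  out
}

#' Adapter stub for a pretrained 3D-convolutional feature extractor
#'
#' Placeholder for wrapping a pretrained action-recognition backbone. No such
#' backend ships with this package, so construction raises a capability
#' error; use [mock_extractor()] for synthetic experiments.
#'
#' @export
i3d_extractor <- function() {
  stopf(paste("no pretrained 3D-convolutional backbone is available in this",
              "installation; use mock_extractor() or supply your own",
              "extract_features() method"))
}

#' Pre-pad a feature matrix to the fixed 7 x 1024 shape
#'
#' Clips shorter than 60 frames yield fewer than 7 timesteps; their feature
#' matrices are pre-padded with leading sentinel rows of -1 so every sequence
#' is exactly 7 x 1024. The sentinel rows are hidden from the classifiers by
#' the masking layer.
#'
#' @param matrix `k x d` feature matrix, `1 <= k <= 7`.
#' @param timesteps target number of rows, default 7.
#' @return `timesteps x d` matrix whose first `timesteps - k` rows are all
#'   -1 and whose last `k` rows equal the input; the pad count is attached
#'   as attribute `pad_rows`.
#' @export
pad_features <- function(matrix, timesteps = 7L) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L || nrow(matrix) > timesteps)
    stopf("feature matrix must have 1..%d rows", timesteps)
  k <- nrow(matrix)
  out <- rbind(base::matrix(-1, timesteps - k, ncol(matrix)), matrix)
  attr(out, "pad_rows") <- timesteps - k
  out
}

#' Build a feature store from preprocessed clips
#'
#' Runs the extractor over a list of clip samples and stacks the padded
#' sequences into one array, together with labels and provenance. This is
#' the container consumed by [train_classifier()] and [run_experiment()].
#'
#' @param clips list of [make_clip_sample()] objects.
#' @param extractor feature extractor, default [mock_extractor()].
#' @param timesteps sequence length after padding.
#' @return Object of class `"feature_store"`: list with `features`
#'   (`N x timesteps x dim`), `labels` (factor), `patient_id`, `seizure_id`,
#'   `window` (N x 2).
#' @export
build_feature_store <- function(clips, extractor = mock_extractor(),
                                timesteps = 7L) {
  n <- length(clips)
  if (n == 0L) stopf("no clips supplied")
  mats <- lapply(clips, function(cl)
    pad_features(extract_features(extractor, cl), timesteps))
  d <- ncol(mats[[1]])
  feats <- array(0, c(n, timesteps, d))
  for (i in seq_len(n)) feats[i, , ] <- mats[[i]]
  structure(list(
    features = feats,
    labels = factor(vapply(clips, function(cl) as.character(cl$class),
                           character(1))),
    patient_id = vapply(clips, function(cl) as.character(cl$patient_id),
                        character(1)),
    seizure_id = vapply(clips, function(cl) as.character(cl$seizure_id),
                        character(1)),
    window = t(vapply(clips, function(cl) cl$window, integer(2)))
  ), class = "feature_store")
}
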