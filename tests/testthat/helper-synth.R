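# Shared fixtures: small synthetic scenes and independent oracles.

small_scene <- function(frame_count = 4L, height = 64L, width = 80L,
                        pepper_fraction = 0, seed = 1L, ...) {
  generate_scene(scene_config(frame_count = frame_count, height = height,
                              width = width,
                              pepper_fraction = pepper_fraction,
                              seed = seed, ...))
}

tiny_dataset <- function(n = c(FLE = 2, TLE = 2, Prepost = 2),
                         seizures = 1L, len = c(70L, 80L), seed = 1L) {
  generate_dataset(n, seizures_per_patient = seizures, length_range = len,
                   height = 64L, width = 80L, pepper_fraction = 0.01,
                   seed = seed)
}

# Brute-force per-pixel depth-band check (independent of apply_depth_crop).
brute_force_band_mask <- function(frame, planes) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      t <- if (planes$bed_axis == "cols") j else i
      d <- frame[i, j]
      out[i, j] <- d > 0 && d >= planes$near[t] && d <= planes$far[t]
    }
  }
  out
}

# Brute-force grayscale dilation with a kh x kw window anchored one pixel
# above/left of centre for even sizes (window rows i-1..i+2 for k = 4).
brute_force_dilate <- function(m, kh = 4L, kw = 4L) {
  H <- nrow(m); W <- ncol(m)
  offr <- seq_len(kh) - (kh + 1L) %/% 2L
  offc <- seq_len(kw) - (kw + 1L) %/% 2L
  out <- m
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      rr <- i + offr; rr <- rr[rr >= 1 & rr <= H]
      cc <- j + offc; cc <- cc[cc >= 1 & cc <= W]
      out[i, j] <- max(m[rr, cc])
    }
  }
  out
}

# Counting-based one-vs-rest metrics straight from label vectors.
counting_metrics <- function(conf) {
  C <- nrow(conf)
  prec <- rec <- f1 <- sens <- spec <- numeric(C)
  N <- sum(conf)
  for (c in seq_len(C)) {
    tp <- conf[c, c]
    fp <- sum(conf[-c, c])
    fn <- sum(conf[c, -c])
    tn <- N - tp - fp - fn
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    sens[c] <- rec[c]
    spec[c] <- if (tn + fp > 0) tn / (tn + fp) else 0
  }
  list(precision = prec, recall = rec, f1 = f1, macro_f1 = mean(f1),
       sensitivity = sens, specificity = spec)
}

# Stride-based enumeration oracle for temporal slicing.
enumerate_windows <- function(L, window = 60L, stride = window,
                              min_leftover = 10L) {
  starts <- seq(1L, max(1L, L), by = stride)
  starts <- starts[starts + window - 1L <= L]
  ends <- starts + window - 1L
  last <- if (length(ends)) max(ends) else 0L
  if (L - last >= min_leftover) {
    starts <- c(starts, last + 1L)
    ends <- c(ends, L)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

# Synthetic feature store with class-separated means and two clips per
# patient, for experiment-level tests that skip the imaging stages.
make_fake_feature_store <- function(n_per_class = 8L, d = 24L, seed = 5L) {
  withr::with_seed(seed, {
    classes <- c("FLE", "TLE", "Prepost")
    N <- n_per_class * 3L
    mu <- matrix(rnorm(3 * d, sd = 2), 3, d)
    X <- array(0, c(N, 7, d))
    labs <- rep(classes, each = n_per_class)
    for (i in seq_len(N)) {
      ci <- match(labs[i], classes)
      X[i, , ] <- matrix(mu[ci, ], 7, d, byrow = TRUE) + rnorm(7 * d, sd = .2)
    }
    structure(list(
      features = X, labels = factor(labs, levels = classes),
      patient_id = paste0("P", rep(seq_len(n_per_class %/% 2 * 3),
                                   each = 2))[seq_len(N)],
      seizure_id = paste0("S", seq_len(N)),
      window = cbind(rep(1L, N), rep(60L, N))
    ), class = "feature_store")
  })
}

# Small linearly separable 3-class feature set for classifier tests:
# class means drawn once, low-noise samples around them, leading pad rows.
separable_features <- function(n_per_class = 12L, d = 128L, timesteps = 7L,
                               n_classes = 3L, noise = 0.1, seed = 99L) {
  withr::with_seed(seed, {
    mu <- matrix(rnorm(n_classes * d, sd = 1), n_classes, d)
    N <- n_per_class * n_classes
    X <- array(0, c(N, timesteps, d))
    y <- factor(rep(letters[1:n_classes], each = n_per_class))
    for (i in seq_len(N)) {
      k <- sample(3:timesteps, 1)            # valid timesteps
      m <- matrix(rnorm(k * d, sd = noise), k, d) +
        matrix(mu[as.integer(y[i]), ], k, d, byrow = TRUE)
      X[i, , ] <- rbind(matrix(-1, timesteps - k, d), m)
    }
    list(x = X, y = y)
  })
}
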