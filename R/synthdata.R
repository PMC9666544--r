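#' Configuration for a synthetic EMU bedside scene
#'
#' Describes one synthetic epilepsy-monitoring-unit (EMU) scene as recorded by
#' a wall-mounted, downward-tilted Kinect-v2-class sensor: pixel-aligned 16-bit
#' depth (millimetres, 0 = missing measurement) and infrared stacks at
#' 512 x 424 and 30 fps by default. The scene is procedural: a quadratic
#' floor-wall background, a planar bed slab occupying a depth band, an
#' ellipsoidal patient whose position oscillates laterally along the bed at
#' `motion_freq_hz`, i.i.d. zero-valued pepper noise on the depth stream, and
#' an optional near-camera occluder standing in for attending clinicians.
#'
#' @param frame_count number of frames.
#' @param height,width frame size in pixels.
#' @param bed_depth_mm distance from camera to the bed surface at frame
#'   centre, in mm.
#' @param bed_band_halfwidth_mm half-width of the depth band containing bed
#'   and patient; all noise-free patient/bed depths stay within
#'   `bed_depth_mm +/- bed_band_halfwidth_mm`.
#' @param camera_tilt camera tilt in degrees; its tangent scales the
#'   floor-bed-floor curvature of the background.
#' @param pepper_fraction fraction of depth pixels zeroed per frame, in [0, 1).
#' @param occluder `NULL`, or a list with `depth_mm` (must be nearer than the
#'   near side of the bed band), `size_px` (square side), and `frames`
#'   (indices where the occluder is present; default second half).
#' @param motion_freq_hz patient oscillation frequency in Hz.
#' @param motion_amp_px lateral oscillation amplitude in pixels.
#' @param fps frames per second.
#' @param seed integer seed; scenes are bit-reproducible given the config.
#' @param class_label optional class tag carried into the ground truth
#'   (`"FLE"`, `"TLE"` or `"Prepost"`).
#' @return An object of class `"scene_config"`.
#' @seealso [generate_scene()], [generate_dataset()]
#' @export
scene_config <- function(frame_count = 90L, height = 424L, width = 512L,
                         bed_depth_mm = 2000, bed_band_halfwidth_mm = 300,
                         camera_tilt = -45, pepper_fraction = 0.02,
                         occluder = NULL, motion_freq_hz = 1.0,
                         motion_amp_px = 6, fps = 30, seed = 1L,
                         class_label = NA_character_) {
  if (!is_count(frame_count)) stopf("frame_count must be a positive integer")
  if (!is_count(height) || !is_count(width) || height < 16 || width < 16)
    stopf("height and width must be integers >= 16")
  if (pepper_fraction < 0 || pepper_fraction >= 1)
    stopf("pepper_fraction must lie in [0, 1)")
  if (fps <= 0) stopf("fps must be positive")
  if (motion_freq_hz < 0 || motion_freq_hz > fps / 2)
    stopf("motion_freq_hz must lie in [0, fps/2]")
  if (!is.null(occluder)) {
    if (is.null(occluder$depth_mm) || is.null(occluder$size_px))
      stopf("occluder needs fields depth_mm and size_px")
    if (occluder$depth_mm >= bed_depth_mm - bed_band_halfwidth_mm)
      stopf("occluder depth (%g mm) must be nearer than the bed band (%g mm)",
            occluder$depth_mm, bed_depth_mm - bed_band_halfwidth_mm)
    if (is.null(occluder$frames))
      occluder$frames <- seq.int(max(2L, frame_count %/% 2L + 1L), frame_count)
  }
  structure(list(
    frame_count = as.integer(frame_count), height = as.integer(height),
    width = as.integer(width), bed_depth_mm = bed_depth_mm,
    bed_band_halfwidth_mm = bed_band_halfwidth_mm, camera_tilt = camera_tilt,
    pepper_fraction = pepper_fraction, occluder = occluder,
    motion_freq_hz = motion_freq_hz, motion_amp_px = motion_amp_px,
    fps = fps, seed = as.integer(seed), class_label = class_label
  ), class = "scene_config")
}

# Deterministic scene geometry derived from a config. The background is
# quadratic across rows (floor-bed-floor) and linear across columns
# (wall-bed), so the bed length direction is the column axis.
scene_geometry <- function(cfg) {
  H <- cfg$height; W <- cfg$width
  centre_r <- (H + 1) / 2
  centre_c <- (W + 1) / 2
  slope <- 120 / W                           # mm per px along the bed axis
  curv <- (680 / (H / 2)^2) * abs(tan(cfg$camera_tilt * pi / 180))
  bump_max <- (2 / 3) * cfg$bed_band_halfwidth_mm
  list(
    centre_r = centre_r, centre_c = centre_c,
    bed_rows = seq.int(max(1L, round(centre_r - H / 6)),
                       min(H, round(centre_r + H / 6))),
    plane = cfg$bed_depth_mm + slope * (seq_len(W) - centre_c),
    background = outer(cfg$bed_depth_mm + 900 + curv * (seq_len(H) - centre_r)^2,
                       slope * (seq_len(W) - centre_c), `+`),
    bump_max = bump_max,
    er = H / 8, ec = W / 4                   # patient ellipse semi-axes (px)
  )
}

#' Generate one synthetic depth + infrared scene with ground truth
#'
#' Renders the scene described by a [scene_config()]: per-frame 16-bit depth
#' and infrared stacks plus ground truth (per-frame patient mask, bed bounding
#' box, and the depth band bracketing all noise-free patient/bed depths).
#' Output is bit-identical for identical configurations.
#'
#' @param config a [scene_config()].
#' @return A list with integer arrays `depth` and `ir` (H x W x T), and
#'   `truth`: a list with `patient_mask` (H x W x T logical), `bed_bbox`
#'   ([bbox()]), `depth_band` (`c(near_mm, far_mm)`) and `class_label`.
#' @examples
#' sc <- generate_scene(scene_config(frame_count = 4, height = 64, width = 80))
#' range(sc$depth[sc$truth$patient_mask])  # inside sc$truth$depth_band
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  g <- scene_geometry(config)
  H <- config$height; W <- config$width; TT <- config$frame_count

  base <- g$background
  base[g$bed_rows, ] <- matrix(g$plane, length(g$bed_rows), W, byrow = TRUE)

  tex <- 0.15 * outer(sin(2 * pi * seq_len(H) / 9), cos(2 * pi * seq_len(W) / 9))
  depth <- array(0L, c(H, W, TT))
  ir <- array(0L, c(H, W, TT))
  mask <- array(FALSE, c(H, W, TT))

  occ <- config$occluder
  occ_rows <- occ_cols <- NULL
  if (!is.null(occ)) {
    half <- max(1L, occ$size_px %/% 2L)
    oc_r <- round(g$centre_r)
    oc_c <- round(g$centre_c + W / 5)
    occ_rows <- clamp(seq.int(oc_r - half, oc_r + half - 1L), 1L, H)
    occ_cols <- clamp(seq.int(oc_c - half, oc_c + half - 1L), 1L, W)
  }

  with_seed(config$seed, {
    for (t in seq_len(TT)) {
      m <- base
      c_p <- g$centre_c + config$motion_amp_px *
        sin(2 * pi * config$motion_freq_hz * (t - 1) / config$fps)
      rr <- seq.int(max(1L, floor(g$centre_r - g$er)),
                    min(H, ceiling(g$centre_r + g$er)))
      cc <- seq.int(max(1L, floor(c_p - g$ec)), min(W, ceiling(c_p + g$ec)))
      q <- outer(((rr - g$centre_r) / g$er)^2, ((cc - c_p) / g$ec)^2, `+`)
      bump <- g$bump_max * sqrt(pmax(0, 1 - q))
      m[rr, cc] <- m[rr, cc] - bump
      fm <- matrix(FALSE, H, W)
      fm[rr, cc] <- bump > 0
      if (!is.null(occ) && t %in% occ$frames) {
        m[occ_rows, occ_cols] <- occ$depth_mm
        fm[occ_rows, occ_cols] <- FALSE
      }
      ir_f <- 60000 * exp(-m / 4000)
      ir_f <- ir_f * (1 + tex * fm)
      if (config$pepper_fraction > 0) {
        z <- which(stats::runif(H * W) < config$pepper_fraction)
        m[z] <- 0
      }
      depth[, , t] <- as.integer(round(m))
      ir[, , t] <- as.integer(clamp(round(ir_f), 0, 65535))
      mask[, , t] <- fm
    }
  })

  near <- min(g$plane) - g$bump_max - 5
  far <- max(g$plane) + 5
  truth <- list(
    patient_mask = mask,
    bed_bbox = bbox(min(g$bed_rows), 1L, max(g$bed_rows), W),
    depth_band = c(near_mm = near, far_mm = far),
    class_label = config$class_label
  )
  pd <- depth[mask]
  pd <- pd[pd > 0]
  stopifnot(all(pd >= near), all(pd <= far))
  list(depth = depth, ir = ir, truth = truth, config = config)
}

#' Estimate the patient's oscillation frequency from ground-truth masks
#'
#' Tracks the per-frame centroid of the patient mask along the bed axis and
#' returns the dominant non-DC frequency of its discrete Fourier transform.
#'
#' @param patient_mask H x W x T logical array (or a numeric series of
#'   centroid positions).
#' @param fps frames per second of the stack.
#' @return Frequency in Hz.
#' @export
estimate_motion_frequency <- function(patient_mask, fps = 30) {
  if (is.array(patient_mask) && length(dim(patient_mask)) == 3L) {
    TT <- dim(patient_mask)[3]
    x <- vapply(seq_len(TT), function(t) {
      idx <- which(patient_mask[, , t], arr.ind = TRUE)
      if (nrow(idx) == 0L) NA_real_ else mean(idx[, 2])
    }, numeric(1))
  } else {
    x <- as.numeric(patient_mask)
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stopf("need at least 8 frames to estimate a frequency")
  spec <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2)]
  freqs <- (1:(n %/% 2 - 1)) * fps / n
  freqs[which.max(spec)]
}

#' Generate a labelled multi-patient synthetic seizure dataset
#'
#' Builds a manifest of synthetic seizure recordings across the three classes
#' (FLE, TLE, Prepost). Motion frequency is drawn per patient within a
#' class-specific range -- FLE movements are faster than TLE ones, and the
#' non-epileptic Prepost class gets low-amplitude motion with near-camera
#' occluder events (clinicians attending the patient) -- with small
#' per-seizure jitter. With `dir` set, stacks are written as multi-page 16-bit
#' TIFF and the manifest as JSON; otherwise videos are returned in memory.
#'
#' @param n_patients_per_class named integer vector, e.g.
#'   `c(FLE = 2, TLE = 2, Prepost = 2)`.
#' @param seizures_per_patient length-2 range (or single count) of seizures
#'   drawn uniformly per patient.
#' @param length_range length-2 range of video lengths in frames.
#' @param height,width,fps,pepper_fraction passed to each scene.
#' @param seed master seed; every scene gets a derived child seed.
#' @param dir optional output directory.
#' @return A list with `manifest` (data frame: patient_id, seizure_id, class,
#'   frames, motion_freq_hz, path) and `videos` (named list of
#'   [generate_scene()] outputs; empty when `dir` is used).
#' @export
generate_dataset <- function(n_patients_per_class,
                             seizures_per_patient = 2L,
                             length_range = c(120L, 240L),
                             height = 424L, width = 512L, fps = 30,
                             pepper_fraction = 0.02, seed = 1L, dir = NULL) {
  classes <- names(n_patients_per_class)
  if (is.null(classes) || length(classes) == 0L)
    stopf("n_patients_per_class must be a named vector of class counts")
  bad <- setdiff(classes, c("FLE", "TLE", "Prepost"))
  if (length(bad)) stopf("unknown classes: %s", paste(bad, collapse = ", "))
  if (any(n_patients_per_class < 1))
    stopf("every requested class needs at least one patient")
  if (length(seizures_per_patient) == 1L)
    seizures_per_patient <- rep(seizures_per_patient, 2L)

  # Class-conditional motion: TLE movements-of-interest span 0.4-1.8 Hz and
  # FLE ones are faster; Prepost segments show slow, low-amplitude motion
  # with clinicians intermittently occluding the camera.
  amp_scale <- width / 512
  class_par <- list(
    FLE = list(freq = c(2.0, 2.8), amp = max(3, round(6 * amp_scale)),
               occluder = FALSE),
    TLE = list(freq = c(0.4, 1.8), amp = max(3, round(6 * amp_scale)),
               occluder = FALSE),
    Prepost = list(freq = c(0.1, 0.4), amp = max(1, round(2 * amp_scale)),
                   occluder = TRUE)
  )

  n_total <- sum(n_patients_per_class) * seizures_per_patient[2]
  child <- derive_seeds(seed, n_total + sum(n_patients_per_class))
  rows <- list(); videos <- list()
  pid_n <- 0L; k <- 0L
  with_seed(seed + 1L, {
    for (cl in classes) {
      par <- class_par[[cl]]
      for (p in seq_len(n_patients_per_class[[cl]])) {
        pid_n <- pid_n + 1L
        pid <- sprintf("P%02d", pid_n)
        freq_p <- stats::runif(1, par$freq[1], par$freq[2])
        n_sz <- if (seizures_per_patient[1] == seizures_per_patient[2])
          seizures_per_patient[1]
        else sample(seizures_per_patient[1]:seizures_per_patient[2], 1L)
        for (s in seq_len(n_sz)) {
          k <- k + 1L
          sid <- sprintf("%s_S%02d", pid, s)
          len <- if (length_range[1] == length_range[2]) length_range[1]
          else sample(length_range[1]:length_range[2], 1L)
          freq <- clamp(freq_p + stats::runif(1, -0.05, 0.05), 0.05, fps / 4)
          occ <- if (par$occluder)
            list(depth_mm = 800, size_px = max(8L, round(height / 7)))
          else NULL
          cfg <- scene_config(
            frame_count = len, height = height, width = width,
            pepper_fraction = pepper_fraction, occluder = occ,
            motion_freq_hz = freq, motion_amp_px = par$amp, fps = fps,
            seed = child[k], class_label = cl
          )
          sc <- generate_scene(cfg)
          path <- NA_character_
          if (!is.null(dir)) {
            path <- file.path(dir, sid)
            write_scene(sc, path)
          } else {
            videos[[sid]] <- sc
          }
          rows[[sid]] <- data.frame(
            patient_id = pid, seizure_id = sid, class = cl,
            frames = len, motion_freq_hz = freq, path = path,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, videos = videos)
}
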