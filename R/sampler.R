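#' Temporal slicing configuration
#'
#' Seizure videos are sliced into fixed-length windows (default 60 frames,
#' i.e. 2 s at 30 fps) with optional fractional overlap; a shorter leftover
#' window at the end of the video is kept when it has at least
#' `min_leftover` frames (default 10, reading "more than 9 frames" as >= 10).
#'
#' @param window window length in frames.
#' @param overlap fractional overlap between consecutive windows, in [0, 1);
#'   0.5 gives the temporal-augmentation variant.
#' @param min_leftover minimum length of the trailing partial window.
#' @export
slicing_config <- function(window = 60L, overlap = 0, min_leftover = 10L) {
  if (!is_count(window)) stopf("window must be a positive integer")
  if (overlap < 0 || overlap >= 1) stopf("overlap must lie in [0, 1)")
  if (!is_count(min_leftover) || min_leftover > window)
    stopf("min_leftover must lie in 1..window")
  structure(list(window = as.integer(window), overlap = overlap,
                 min_leftover = as.integer(min_leftover)),
            class = "slicing_config")
}

#' Slice a video into temporal windows
#'
#' Emits full windows of `cfg$window` frames at stride
#' `window * (1 - overlap)` while they fit, then appends one leftover window
#' covering the remaining tail iff it is at least `cfg$min_leftover` frames
#' long. Windows never exceed the video; frame indices are 1-based inclusive.
#'
#' @param video_length length of the video in frames.
#' @param cfg a [slicing_config()].
#' @return Data frame with columns `start`, `end` (one row per window;
#'   zero rows when nothing qualifies).
#' @examples
#' slice_windows(120)                               # [1,60], [61,120]
#' slice_windows(120, slicing_config(overlap = .5)) # adds [31,90]
#' @export
slice_windows <- function(video_length, cfg = slicing_config()) {
  if (!is_count(video_length)) stopf("video_length must be >= 1")
  stride <- max(1L, as.integer(round(cfg$window * (1 - cfg$overlap))))
  starts <- integer(0)
  s <- 1L
  while (s + cfg$window - 1L <= video_length) {
    starts <- c(starts, s)
    s <- s + stride
  }
  out <- data.frame(start = starts, end = starts + cfg$window - 1L)
  last_end <- if (nrow(out)) max(out$end) else 0L
  tail_len <- video_length - last_end
  if (tail_len >= cfg$min_leftover)
    out <- rbind(out, data.frame(start = last_end + 1L, end = video_length))
  out
}

#' Convert a 16-bit stack to 8-bit by per-video min-max scaling
#'
#' Linear scaling of the whole video so its minimum maps to 0 and maximum to
#' 255 (rounded); a constant video maps to all zeros. The scaling is per
#' video, not per frame, so relative intensities across time are preserved.
#'
#' @param video numeric/integer stack.
#' @return Integer stack with values in 0..255.
#' @export
to_8bit <- function(video) {
  rng <- range(video)
  out <- if (rng[2] == rng[1]) array(0L, dim(video) %||% length(video))
  else array(as.integer(round((video - rng[1]) / (rng[2] - rng[1]) * 255)),
             dim(video) %||% length(video))
  out
}

#' Rescale 8-bit intensities to [-1, 1]
#'
#' Elementwise affine map `2 * x / 255 - 1`, the input normalisation expected
#' by the spatio-temporal feature extractor: 0 maps to -1, 255 to +1.
#'
#' @param frames values in [0, 255].
#' @return Numeric array of the same shape with values in [-1, 1].
#' @export
rescale_intensity <- function(frames) 2 * frames / 255 - 1

#' Resize a frame to a square with aspect-preserving bilinear interpolation
#'
#' The frame is bilinearly resized so its largest dimension equals `target`
#' (the minor dimension is rounded half up), then zero-padded symmetrically
#' to `target x target`, with any odd leftover pixel going to the
#' bottom/right. Padding happens before intensity rescaling, so padded pixels
#' become -1 downstream.
#'
#' @param frame 2-D numeric matrix.
#' @param target output side length, default 224.
#' @return `target x target` matrix.
#' @export
resize_pad <- function(frame, target = 224L) {
  if (!is.matrix(frame) || any(dim(frame) == 0L)) stopf("frame must be a matrix")
  H <- nrow(frame); W <- ncol(frame)
  if (H >= W) {
    nh <- target; nw <- as.integer(round_half_up(W * target / H))
  } else {
    nw <- target; nh <- as.integer(round_half_up(H * target / W))
  }
  r <- bilinear_resize(frame, nh, nw)
  out <- matrix(0, target, target)
  r0 <- (target - nh) %/% 2L
  c0 <- (target - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- r
  out
}

# Bilinear resampling with pixel-centre alignment (the convention used by
# the common imaging libraries): output centre i maps to input coordinate
# (i - 0.5) * H/nh + 0.5, clamped to the frame.
bilinear_resize <- function(m, nh, nw) {
  H <- nrow(m); W <- ncol(m)
  if (nh == H && nw == W) return(m)
  ry <- clamp((seq_len(nh) - 0.5) * H / nh + 0.5, 1, H)
  rx <- clamp((seq_len(nw) - 0.5) * W / nw + 0.5, 1, W)
  y0 <- pmin(floor(ry), H - 1L); x0 <- pmin(floor(rx), W - 1L)
  wy <- ry - y0; wx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1, drop = FALSE]
  c_ <- m[y0 + 1, x0, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  top <- a * (1 - matrix(wx, nh, nw, byrow = TRUE)) +
    b * matrix(wx, nh, nw, byrow = TRUE)
  bot <- c_ * (1 - matrix(wx, nh, nw, byrow = TRUE)) +
    d * matrix(wx, nh, nw, byrow = TRUE)
  top * (1 - wy) + bot * wy
}

#' Replicate a grayscale stack to three identical channels
#'
#' @param frames array `L x H x W` (or `H x W`).
#' @return Array with an extra trailing channel dimension of size 3; channel
#'   1 equals the input exactly.
#' @export
gray_to_3channel <- function(frames) {
  d <- dim(frames) %||% length(frames)
  array(rep(as.numeric(frames), 3L), c(d, 3L))
}

#' Assemble one preprocessed clip sample
#'
#' Takes a window of 8-bit single-channel frames and produces the
#' fixed-geometry clip fed to feature extraction: each frame is resized and
#' padded to `target x target` ([resize_pad()]), the stack is replicated to
#' three identical channels and rescaled to [-1, 1] ([rescale_intensity()]).
#'
#' @param frames8 `H x W x L` integer array, values 0..255.
#' @param patient_id,seizure_id,class provenance carried with the sample.
#' @param window `c(start, end)` frame indices of this clip in its video.
#' @param target spatial side length, default 224.
#' @return Object of class `"clip_sample"`: list with `frames`
#'   (`L x target x target x 3`, values in [-1, 1]) and the provenance
#'   fields.
#' @export
make_clip_sample <- function(frames8, patient_id = NA, seizure_id = NA,
                             class = NA, window = c(1L, dim(frames8)[3]),
                             target = 224L) {
  v <- as_stack(frames8, "clip frames")
  L <- dim(v)[3]
  res <- array(0, c(L, target, target))
  for (t in seq_len(L)) res[t, , ] <- resize_pad(v[, , t], target)
  frames <- rescale_intensity(gray_to_3channel(res))
  structure(list(frames = frames, patient_id = patient_id,
                 seizure_id = seizure_id, class = class,
                 window = as.integer(window)),
            class = "clip_sample")
}
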