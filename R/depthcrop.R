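#' Depth-stream denoising configuration
#'
#' The Kinect-v2 depth stream carries zero-valued pepper noise (missing
#' measurements). These holes are closed by grayscale morphological dilation
#' with a rectangular structuring element, by default 4 x 4 applied for two
#' iterations, before the depth-band crop is computed.
#'
#' @param struct_elem integer length-2 vector, structuring-element size
#'   (rows, cols).
#' @param iterations number of dilation passes, >= 1.
#' @export
denoise_config <- function(struct_elem = c(4L, 4L), iterations = 2L) {
  if (length(struct_elem) != 2L || any(struct_elem < 1))
    stopf("struct_elem must be two positive sizes")
  if (!is_count(iterations)) stopf("iterations must be >= 1")
  structure(list(struct_elem = as.integer(struct_elem),
                 iterations = as.integer(iterations)),
            class = "denoise_config")
}

# 1-D running max of the columns/rows of a matrix over a window of k offsets.
# For size k the window around index i covers i - ((k+1) %/% 2 - 1) .. upward,
# i.e. offsets -1..2 for k = 4 (anchor just above/left of centre); positions
# outside the frame are ignored.
shift_max <- function(m, k, along_rows) {
  offs <- seq_len(k) - (k + 1L) %/% 2L
  n <- if (along_rows) nrow(m) else ncol(m)
  out <- m
  for (d in offs) {
    if (d == 0L) next
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (along_rows) {
      out[ok, ] <- pmax(out[ok, ], m[src[ok], ])
    } else {
      out[, ok] <- pmax(out[, ok], m[, src[ok]])
    }
  }
  out
}

#' Close depth pepper noise by grayscale dilation
#'
#' Applies per-frame grayscale dilation with a rectangular structuring element
#' (separable running maximum). The output is pointwise >= the input and the
#' count of zero (missing) pixels never increases.
#'
#' @param video depth stack, H x W x T array (or single matrix) of
#'   non-negative integers in mm; 0 marks missing measurements.
#' @param cfg a [denoise_config()].
#' @return Denoised stack with the input's dimensions.
#' @export
denoise_depth <- function(video, cfg = denoise_config()) {
  v <- as_stack(video, "depth video")
  kh <- cfg$struct_elem[1]; kw <- cfg$struct_elem[2]
  for (t in seq_len(dim(v)[3])) {
    m <- v[, , t]
    for (i in seq_len(cfg$iterations)) {
      m <- shift_max(m, kh, along_rows = TRUE)
      m <- shift_max(m, kw, along_rows = FALSE)
    }
    v[, , t] <- m
  }
  if (is.matrix(video)) v[, , 1] else v
}

quad_fit <- function(idx, y) {
  X <- cbind(1, idx, idx^2)
  cf <- stats::lm.fit(X, y)$coefficients
  c(a2 = unname(cf[3]), a1 = unname(cf[2]), a0 = unname(cf[1]))
}

#' Fit per-axis min/max depth profiles of a frame
#'
#' For each image axis, takes the per-index minimum and maximum over the
#' non-zero depths (rows axis: profiles indexed by row, aggregated over
#' columns, and vice versa) and least-squares fits a 2nd-order polynomial to
#' each of the four profiles. Indices with no non-zero pixel are excluded
#' from the fits. In the assumed tilted-camera EMU geometry one axis sees a
#' flat wall-bed maximum profile and the other a strongly curved
#' floor-bed-floor profile; the four quadratics drive bed-axis selection and
#' patient-line location.
#'
#' @param frame single depth frame (matrix, mm, 0 = missing).
#' @return Object of class `"axis_profiles"`: for each of `rows`/`cols`, the
#'   usable indices, min/max profiles, and quadratic fits `(a2, a1, a0)`.
#' @export
fit_axis_profiles <- function(frame) {
  if (!is.matrix(frame)) stopf("frame must be a matrix")
  axis_prof <- function(over_rows) {
    n <- if (over_rows) nrow(frame) else ncol(frame)
    mn <- mx <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      v <- if (over_rows) frame[i, ] else frame[, i]
      v <- v[v > 0]
      if (length(v)) { mn[i] <- min(v); mx[i] <- max(v) }
    }
    ok <- which(!is.na(mn))
    if (length(ok) < 3L)
      stopf("degenerate geometry: fewer than 3 usable indices on an axis")
    list(idx = ok, min_profile = mn, max_profile = mx,
         min_fit = quad_fit(ok, mn[ok]), max_fit = quad_fit(ok, mx[ok]))
  }
  structure(list(rows = axis_prof(TRUE), cols = axis_prof(FALSE),
                 dim = dim(frame)),
            class = "axis_profiles")
}

#' Select the bed's length direction
#'
#' The axis whose max-profile quadratic has the smaller absolute 2nd-order
#' coefficient is the flat wall-bed direction, i.e. the length direction of
#' the bed; the curved floor-bed-floor direction is the cross axis. Exact
#' ties resolve to `"rows"`.
#'
#' @param profiles an [fit_axis_profiles()] result.
#' @return `"rows"` or `"cols"`.
#' @export
select_bed_axis <- function(profiles) {
  a2r <- abs(profiles$rows$max_fit[["a2"]])
  a2c <- abs(profiles$cols$max_fit[["a2"]])
  if (a2c < a2r) "cols" else "rows"
}

#' Locate the line where the patient lies
#'
#' The patient line is the stationary point (vertex) of the quadratic fitted
#' to the cross-axis minimum profile, rounded to the nearest index. When the
#' quadratic is degenerate (|a2| below `tol`, non-convex) or its vertex falls
#' outside the frame, the argmin of the raw cross-axis minimum profile is
#' used instead.
#'
#' @param profiles an [fit_axis_profiles()] result.
#' @param bed_axis `"rows"` or `"cols"`, from [select_bed_axis()].
#' @param tol curvature tolerance below which the vertex is not trusted.
#' @return Integer line index on the cross axis (a row index when the bed
#'   runs along columns).
#' @export
locate_patient_line <- function(profiles, bed_axis = select_bed_axis(profiles),
                                tol = 1e-8) {
  cross <- if (bed_axis == "cols") profiles$rows else profiles$cols
  n <- if (bed_axis == "cols") profiles$dim[1] else profiles$dim[2]
  a2 <- cross$min_fit[["a2"]]; a1 <- cross$min_fit[["a1"]]
  v <- if (is.finite(a2) && a2 > tol) -a1 / (2 * a2) else NA_real_
  if (is.finite(v) && v >= 1 && v <= n) {
    as.integer(round(v))
  } else {
    as.integer(cross$idx[which.min(cross$min_profile[cross$idx])])
  }
}

#' Compute the two parallel cropping planes from the patient line
#'
#' Models the bed/patient as a flat slab: fits a 1st-order polynomial to the
#' non-zero depths along the patient line and offsets it by twice the
#' standard deviation of those depths on either side, giving a near and a far
#' plane. The offset is floored at `min_halfwidth_mm` so a perfectly flat
#' line does not collapse the band.
#'
#' @param frame single depth frame.
#' @param bed_axis `"rows"` or `"cols"`.
#' @param line_index index of the patient line on the cross axis.
#' @param min_halfwidth_mm minimum half-width of the band, in mm.
#' @param sd_type `"population"` (default) or `"sample"` normalisation for
#'   the standard deviation of the line depths.
#' @return Object of class `"crop_planes"` with the line fit
#'   (intercept, slope), `sigma`, the applied `halfwidth`, and `near`/`far`
#'   plane depths along the bed axis.
#' @export
compute_crop_planes <- function(frame, bed_axis, line_index,
                                min_halfwidth_mm = 100,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  line <- if (bed_axis == "cols") frame[line_index, ] else frame[, line_index]
  pos <- which(line > 0)
  if (length(pos) < 2L)
    stopf(paste("patient line has fewer than 2 non-zero depths;",
                "automatic depth cropping failed - crop this video manually"))
  y <- line[pos]
  cf <- stats::lm.fit(cbind(1, pos), y)$coefficients
  sigma <- if (sd_type == "population") sd_pop(y) else stats::sd(y)
  halfwidth <- max(2 * sigma, min_halfwidth_mm)
  tt <- seq_along(line)
  fit <- cf[1] + cf[2] * tt
  structure(list(bed_axis = bed_axis, line_index = as.integer(line_index),
                 line_fit = c(intercept = unname(cf[1]), slope = unname(cf[2])),
                 sigma = sigma, halfwidth = halfwidth,
                 near = fit - halfwidth, far = fit + halfwidth),
            class = "crop_planes")
}

#' Crop a depth stack to the volume between the two planes
#'
#' A pixel is kept iff it is non-zero and its depth lies within
#' `[near(t), far(t)]`, where `t` is the pixel's coordinate along the bed
#' axis. The same planes (computed from the first frame) are applied to every
#' frame.
#'
#' @param depth H x W x T depth stack (or matrix).
#' @param planes a [compute_crop_planes()] result.
#' @return List with `depth` (pixels outside the band set to 0) and `mask`
#'   (logical array of kept pixels).
#' @export
apply_depth_crop <- function(depth, planes) {
  v <- as_stack(depth, "depth video")
  H <- dim(v)[1]; W <- dim(v)[2]
  if (planes$bed_axis == "cols") {
    stopifnot(length(planes$near) == W)
    nearM <- matrix(planes$near, H, W, byrow = TRUE)
    farM <- matrix(planes$far, H, W, byrow = TRUE)
  } else {
    stopifnot(length(planes$near) == H)
    nearM <- matrix(planes$near, H, W)
    farM <- matrix(planes$far, H, W)
  }
  mask <- array(FALSE, dim(v))
  for (t in seq_len(dim(v)[3])) {
    m <- v[, , t]
    keep <- m > 0 & m >= nearM & m <= farM
    m[!keep] <- 0L
    v[, , t] <- m
    mask[, , t] <- keep
  }
  if (is.matrix(depth)) list(depth = v[, , 1], mask = mask[, , 1])
  else list(depth = v, mask = mask)
}

#' Mask the infrared stream with a cropped depth stream
#'
#' @param ir infrared stack, same dimensions as `cropped_depth`.
#' @param cropped_depth depth stack already cropped with
#'   [apply_depth_crop()]; zeros mark removed pixels.
#' @return Infrared stack with removed pixels set to 0.
#' @export
crop_ir_with_depth <- function(ir, cropped_depth) {
  iv <- as_stack(ir, "IR video"); dv <- as_stack(cropped_depth, "depth video")
  if (!identical(dim(iv), dim(dv)))
    stopf("IR and depth stacks must have identical dimensions")
  out <- iv * (dv > 0)
  storage.mode(out) <- storage.mode(ir)
  if (is.matrix(ir)) out[, , 1] else out
}

#' Depth-band cropping of a depth (and infrared) stack
#'
#' End-to-end semi-specialized depth crop: denoise the depth stream, fit the
#' four axis-profile quadratics on the first frame, select the bed axis
#' (smaller |a2| of the max-profile fits), locate the patient line from the
#' stationary point of the cross-axis min-profile fit, derive the two
#' parallel cropping planes (line fit +/- max(2 sigma, `min_halfwidth_mm`)),
#' and keep only pixels inside the band; the cropped depth then masks the IR
#' stream. Planes come from the first frame and are reused for the whole
#' stack unless `per_frame = TRUE`, which refits line and planes on every
#' frame.
#'
#' @param depth H x W x T depth stack.
#' @param ir optional pixel-aligned IR stack.
#' @param denoise logical; apply [denoise_depth()] first (the denoised stream
#'   is used both for plane fitting and for the final masking).
#' @param denoise_cfg a [denoise_config()].
#' @param min_halfwidth_mm,sd_type passed to [compute_crop_planes()].
#' @param per_frame recompute the planes on every frame.
#' @return List with cropped `depth`, cropped `ir` (or `NULL`), `mask`,
#'   `planes`, and `profiles` of the first frame.
#' @export
depth_crop <- function(depth, ir = NULL, denoise = TRUE,
                       denoise_cfg = denoise_config(),
                       min_halfwidth_mm = 100, sd_type = "population",
                       per_frame = FALSE) {
  v <- as_stack(depth, "depth video")
  if (denoise) v <- denoise_depth(v, denoise_cfg)
  profiles <- fit_axis_profiles(v[, , 1])
  axis <- select_bed_axis(profiles)
  line <- locate_patient_line(profiles, axis)
  planes <- compute_crop_planes(v[, , 1], axis, line, min_halfwidth_mm, sd_type)
  if (!per_frame) {
    res <- apply_depth_crop(v, planes)
  } else {
    res <- list(depth = v, mask = array(FALSE, dim(v)))
    for (t in seq_len(dim(v)[3])) {
      pf <- fit_axis_profiles(v[, , t])
      ax <- select_bed_axis(pf)
      ln <- locate_patient_line(pf, ax)
      pl <- compute_crop_planes(v[, , t], ax, ln, min_halfwidth_mm, sd_type)
      r1 <- apply_depth_crop(v[, , t], pl)
      res$depth[, , t] <- r1$depth
      res$mask[, , t] <- r1$mask
    }
  }
  out_ir <- if (!is.null(ir)) crop_ir_with_depth(ir, res$depth) else NULL
  list(depth = res$depth, ir = out_ir, mask = res$mask,
       planes = planes, profiles = profiles)
}
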