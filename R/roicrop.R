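#' Rectangular bounding box
#'
#' Pixel rectangles use 1-based inclusive indices (`top <= bottom`,
#' `left <= right`), the native R matrix convention.
#'
#' @param top,left,bottom,right pixel indices.
#' @return Object of class `"bbox"`.
#' @export
bbox <- function(top, left, bottom, right) {
  if (top > bottom || left > right)
    stopf("invalid bbox: need top <= bottom and left <= right")
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(bottom), right = as.integer(right)),
            class = "bbox")
}

#' @export
format.bbox <- function(x, ...) {
  sprintf("bbox[rows %d..%d, cols %d..%d]", x$top, x$bottom, x$left, x$right)
}

#' @export
print.bbox <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

bbox_union <- function(a, b) {
  bbox(min(a$top, b$top), min(a$left, b$left),
       max(a$bottom, b$bottom), max(a$right, b$right))
}

bbox_contains <- function(outer, inner) {
  outer$top <= inner$top && outer$left <= inner$left &&
    outer$bottom >= inner$bottom && outer$right >= inner$right
}

#' A single person/bed detection
#'
#' @param label `"person"` or `"bed"`.
#' @param confidence score in [0, 1].
#' @param box a [bbox()].
#' @export
detection <- function(label = c("person", "bed"), confidence, box) {
  label <- match.arg(label)
  if (confidence < 0 || confidence > 1) stopf("confidence must be in [0, 1]")
  stopifnot(inherits(box, "bbox"))
  structure(list(label = label, confidence = confidence, box = box),
            class = "detection")
}

#' Select the best person and bed detections and merge their boxes
#'
#' Takes the highest-confidence person and the highest-confidence bed
#' detection (ties resolve to the first in input order) and returns the union
#' rectangle. If only one of the two labels is present, that box is returned
#' alone and a degradation message is emitted. An empty detection list is a
#' detection failure: such videos must be manually re-annotated.
#'
#' @param detections list of [detection()] objects.
#' @return A [bbox()].
#' @export
select_and_merge <- function(detections) {
  if (length(detections) == 0L)
    stopf("no detections: bounding-box cropping failed, manual re-annotation required")
  best <- list()
  for (lab in c("person", "bed")) {
    of <- Filter(function(d) d$label == lab, detections)
    if (length(of))
      best[[lab]] <- of[[which.max(vapply(of, `[[`, numeric(1), "confidence"))]]
  }
  if (length(best) == 1L) {
    message("only a ", names(best), " was detected; using its box alone")
    return(best[[1]]$box)
  }
  bbox_union(best$person$box, best$bed$box)
}

#' Expand a bounding box outward by a fraction of its extent
#'
#' Each side is moved outward by `fraction` times that dimension's extent
#' (default +30%, to keep violent movements inside the crop), rounded half
#' away from zero, then clamped to the frame. The output always contains the
#' input.
#'
#' @param box a [bbox()].
#' @param fraction expansion fraction per side.
#' @param frame_dims `c(H, W)` of the frame.
#' @return Expanded, clamped [bbox()].
#' @export
expand_box <- function(box, fraction = 0.30, frame_dims) {
  h <- box$bottom - box$top + 1L
  w <- box$right - box$left + 1L
  dh <- round_half_away(fraction * h)
  dw <- round_half_away(fraction * w)
  bbox(clamp(box$top - dh, 1L, frame_dims[1]),
       clamp(box$left - dw, 1L, frame_dims[2]),
       clamp(box$bottom + dh, 1L, frame_dims[1]),
       clamp(box$right + dw, 1L, frame_dims[2]))
}

#' Crop every frame of a video to a bounding box
#'
#' @param video H x W x T array (or matrix).
#' @param box a [bbox()] lying within the frame.
#' @return The sliced stack.
#' @export
crop_video <- function(video, box) {
  v <- as_stack(video, "video")
  if (box$top < 1 || box$left < 1 ||
      box$bottom > dim(v)[1] || box$right > dim(v)[2])
    stopf("crop box exceeds the frame")
  out <- v[box$top:box$bottom, box$left:box$right, , drop = FALSE]
  if (is.matrix(video)) out[, , 1] else out
}

#' Run a detector on a frame
#'
#' Detector backends implement this generic and return a list of
#' [detection()] objects for a single 2-D frame.
#'
#' @param detector a detector object.
#' @param frame a single 2-D frame.
#' @param ... passed to methods.
#' @export
detect <- function(detector, frame, ...) UseMethod("detect")

#' Ground-truth detector for synthetic scenes
#'
#' Reads person and bed boxes straight from a synthetic scene's ground truth
#' (the patient mask of `frame_index` and the bed box), standing in for an
#' instance-segmentation model in tests and synthetic experiments. Returns an
#' empty detection list on a blank (all-zero) frame.
#'
#' @param truth the `truth` element of a [generate_scene()] result.
#' @param frame_index which frame's patient mask defines the person box.
#' @return Object of class `"oracle_detector"`.
#' @export
oracle_detector <- function(truth, frame_index = 1L) {
  idx <- which(truth$patient_mask[, , frame_index], arr.ind = TRUE)
  dets <- list()
  if (nrow(idx) > 0L)
    dets <- c(dets, list(detection("person", 0.99,
      bbox(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2])))))
  dets <- c(dets, list(detection("bed", 0.98, truth$bed_bbox)))
  structure(list(detections = dets), class = "oracle_detector")
}

#' @export
detect.oracle_detector <- function(detector, frame, ...) {
  if (all(frame == 0)) return(list())
  detector$detections
}

#' Adapter stub for a pretrained instance-segmentation detector
#'
#' Placeholder for wrapping a pretrained person/bed instance-segmentation
#' model. No such backend is bundled with this package, so construction
#' raises a capability error; use [oracle_detector()] on synthetic scenes.
#'
#' @export
pretrained_detector <- function() {
  stopf(paste("no pretrained instance-segmentation backend is available",
              "in this installation; use oracle_detector() on synthetic",
              "scenes or supply your own detect() method"))
}
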