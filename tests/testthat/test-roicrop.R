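bbox_contains_test <- function(outer, inner) {
  outer$top <= inner$top && outer$left <= inner$left &&
    outer$bottom >= inner$bottom && outer$right >= inner$right
}

test_that("best person and bed boxes merge to their union rectangle", {
  b <- select_and_merge(list(
    detection("person", 0.9, bbox(11, 11, 100, 100)),
    detection("bed", 0.8, bbox(51, 51, 200, 300))))
  expect_equal(unclass(b), unclass(bbox(11, 11, 200, 300)))
})

test_that("a single detected label degrades to that box alone", {
  dets <- list(detection("person", 0.9, bbox(1, 1, 50, 50)),
               detection("person", 0.7, bbox(5, 5, 90, 90)))
  expect_message(b <- select_and_merge(dets), "person")
  expect_equal(unclass(b), unclass(bbox(1, 1, 50, 50)))
  expect_error(select_and_merge(list()), "manual re-annotation")
})

test_that("selection/merge matches a brute-force argmax/union oracle", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      dets <- lapply(1:100, function(i) {
        tl <- sample(1:200, 2)
        detection(sample(c("person", "bed"), 1), runif(1),
                  bbox(tl[1], tl[2], tl[1] + sample(1:100, 1),
                       tl[2] + sample(1:100, 1)))
      })
      labs <- vapply(dets, `[[`, character(1), "label")
      confs <- vapply(dets, `[[`, numeric(1), "confidence")
      bp <- dets[[which(labs == "person")[
        which.max(confs[labs == "person"])]]]$box
      bb <- dets[[which(labs == "bed")[which.max(confs[labs == "bed"])]]]$box
      want <- bbox(min(bp$top, bb$top), min(bp$left, bb$left),
                   max(bp$bottom, bb$bottom), max(bp$right, bb$right))
      expect_equal(unclass(select_and_merge(dets)), unclass(want))
    }
  })
})

test_that("box expansion moves each side out by 30% of its extent, clamped", {
  # a 40 x 40 box expands by 12 per side and clamps at the frame edge
  b <- expand_box(bbox(11, 11, 50, 50), 0.30, c(424, 512))
  expect_equal(unclass(b), unclass(bbox(1, 1, 62, 62)))
  inner <- bbox(100, 100, 139, 139)
  expect_equal(unclass(expand_box(inner, 0, c(424, 512))), unclass(inner))
  ex <- expand_box(inner, 0.30, c(424, 512))
  expect_equal(unclass(ex), unclass(bbox(88, 88, 151, 151)))
  expect_true(bbox_contains_test(ex, inner))
  edge <- expand_box(bbox(400, 500, 424, 512), 0.5, c(424, 512))
  expect_lte(edge$bottom, 424)
  expect_lte(edge$right, 512)
  expect_gte(edge$top, 1)
})

test_that("video cropping slices every frame to the same box", {
  v <- array(seq_len(424 * 512 * 5) %% 251, c(424, 512, 5))
  expect_equal(crop_video(v, bbox(1, 1, 424, 512)), v)
  cr <- crop_video(v, bbox(1, 1, 10, 10))
  expect_equal(dim(cr), c(10, 10, 5))
  for (t in 1:5) expect_equal(cr[, , t], v[1:10, 1:10, t])
  expect_error(crop_video(v, bbox(1, 1, 500, 10)), "exceeds")
})

test_that("the oracle detector reproduces truth boxes and handles blanks", {
  sc <- small_scene(seed = 2)
  det <- oracle_detector(sc$truth)
  dets <- detect(det, sc$ir[, , 1])
  expect_length(dets, 2L)
  confs <- vapply(dets, `[[`, numeric(1), "confidence")
  expect_true(all(confs >= 0 & confs <= 1))
  labs <- vapply(dets, `[[`, character(1), "label")
  bedbox <- dets[[which(labs == "bed")]]$box
  expect_equal(unclass(bedbox), unclass(sc$truth$bed_bbox))
  pbox <- dets[[which(labs == "person")]]$box
  idx <- which(sc$truth$patient_mask[, , 1], arr.ind = TRUE)
  expect_equal(pbox$top, min(idx[, 1]))
  expect_equal(pbox$right, max(idx[, 2]))
  expect_length(detect(det, sc$ir[, , 1] * 0), 0L)
  expect_error(pretrained_detector(), "backend")
})

test_that("the expanded oracle crop keeps every patient pixel in every frame", {
  sc <- small_scene(frame_count = 5, motion_amp_px = 4, seed = 12)
  box <- expand_box(select_and_merge(detect(oracle_detector(sc$truth),
                                            sc$ir[, , 1])),
                    0.30, dim(sc$ir)[1:2])
  for (t in 1:5) {
    idx <- which(sc$truth$patient_mask[, , t], arr.ind = TRUE)
    expect_true(all(idx[, 1] >= box$top & idx[, 1] <= box$bottom &
                      idx[, 2] >= box$left & idx[, 2] <= box$right))
  }
})
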