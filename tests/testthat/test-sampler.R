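test_that("intensity rescaling maps 0/127.5/255 to -1/0/+1 and inverts", {
  expect_equal(rescale_intensity(0), -1)
  expect_equal(rescale_intensity(255), 1)
  expect_equal(rescale_intensity(127.5), 0)
  x <- matrix(0:255, 16)
  y <- rescale_intensity(x)
  expect_equal((y + 1) * 255 / 2, x)         # affine, exactly invertible
})

test_that("8-bit conversion is per-video min-max and order-preserving", {
  v <- array(c(1000L, 3000L, 2000L, 1500L), c(2, 2, 1))
  v8 <- to_8bit(v)
  expect_equal(v8[1, 1, 1], 0L)
  expect_equal(v8[2, 1, 1], 255L)
  expect_equal(order(v), order(v8))
  expect_true(all(to_8bit(array(7L, c(3, 3, 2))) == 0L))
})

test_that("resize_pad scales the major dimension to 224 and pads the rest", {
  out <- resize_pad(matrix(1, 424, 512))
  expect_equal(dim(out), c(224L, 224L))
  # content region: 424 * 224 / 512 = 185.5 -> 186 rows, centred
  filled <- rowSums(out != 0) > 0
  expect_equal(sum(filled), 186)
  expect_equal(sum(colSums(out != 0) > 0), 224)
  expect_equal(sum(filled[1:19]), 0)         # 38 padded rows split 19/19
  expect_true(all(out[filled, ] == 1))       # constant content preserved

  sq <- matrix(runif(224^2), 224, 224)
  expect_equal(resize_pad(sq), sq)           # identity on target-sized input

  up <- resize_pad(matrix(1, 100, 100))
  expect_true(all(up == 1))                  # upscaled, no padding
})

test_that("resize preserves linear ramps and the content aspect ratio", {
  ramp <- matrix(rep(seq_len(400), each = 200), 200, 400)
  r <- seizevision:::bilinear_resize(ramp, 112, 224)
  expect_equal(dim(r), c(112L, 224L))
  d <- diff(r[50, ])
  expect_true(all(abs(d - d[1]) < 1e-9))     # still linear along columns
  out <- resize_pad(matrix(1, 300, 200))
  # content cols implied by the 3:2 aspect ratio, within one pixel
  expect_lte(abs(200 * 224 / 300 - sum(colSums(out != 0) > 0)), 1)
  expect_equal(sum(rowSums(out != 0) > 0), 224)
})

test_that("gray-to-RGB replication yields three identical channels", {
  x <- array(runif(2 * 5 * 4), c(2, 5, 4))
  y <- gray_to_3channel(x)
  expect_equal(dim(y), c(2, 5, 4, 3))
  expect_equal(y[, , , 1], x)
  expect_equal(y[, , , 2], x)
  expect_equal(y[, , , 3], x)
})

test_that("temporal slicing follows the 60-frame rule with >= 10-frame leftovers", {
  expect_equal(slice_windows(120),
               data.frame(start = c(1L, 61L), end = c(60L, 120L)))
  expect_equal(nrow(slice_windows(129)), 2L)  # 9-frame tail dropped
  s130 <- slice_windows(130)
  expect_equal(nrow(s130), 3L)                # 10-frame tail kept
  expect_equal(s130[3, ], data.frame(start = 121L, end = 130L),
               ignore_attr = TRUE)
  expect_equal(slice_windows(120, slicing_config(overlap = 0.5))$start,
               c(1L, 31L, 61L))
  expect_equal(nrow(slice_windows(59)), 1L)   # short video, one leftover
  expect_equal(nrow(slice_windows(9)), 0L)
})

test_that("window counts match the closed form and enumeration oracles", {
  for (L in c(1, 9, 10, 59, 60, 61, 69, 70, 119, 120, 130, 250, 500)) {
    got <- slice_windows(L)
    want_n <- L %/% 60 + as.integer(L %% 60 >= 10)
    expect_equal(nrow(got), want_n)
    expect_equal(got, enumerate_windows(L), ignore_attr = TRUE)
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] == head(got$end, -1) + 1))  # disjoint
    }
    gov <- slice_windows(L, slicing_config(overlap = 0.5))
    expect_equal(gov, enumerate_windows(L, stride = 30L), ignore_attr = TRUE)
    full <- gov[gov$end - gov$start + 1 == 60, ]
    if (nrow(full) > 1)
      expect_true(all(diff(full$start) == 30))  # 30 shared frames
  }
})

test_that("clip samples satisfy the geometry and range contract", {
  withr::with_seed(2, {
    fr <- array(sample(0:255, 20 * 24 * 12, replace = TRUE), c(20, 24, 12))
    clip <- make_clip_sample(fr, "P01", "P01_S01", "FLE", c(1L, 12L),
                             target = 64L)
    expect_s3_class(clip, "clip_sample")
    expect_equal(dim(clip$frames), c(12, 64, 64, 3))
    expect_true(all(clip$frames >= -1 & clip$frames <= 1))
    expect_equal(clip$frames[, , , 1], clip$frames[, , , 3])
    expect_equal(clip$window, c(1L, 12L))
  })
})
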