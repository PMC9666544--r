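test_that("dilation fixes hold: zeros, constants, single-hole closing", {
  z <- matrix(0L, 10, 12)
  expect_equal(denoise_depth(z), z)
  cst <- matrix(500L, 10, 12)
  expect_equal(denoise_depth(cst), cst)
  hole <- cst
  hole[5, 6] <- 0L
  out <- denoise_depth(hole, denoise_config(iterations = 1L))
  expect_equal(out[5, 6], 500L)
  expect_equal(out, cst)
})

test_that("dilation equals a brute-force windowed max and is monotone", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      m <- matrix(sample(0:3000, 15 * 17, replace = TRUE), 15, 17)
      one <- denoise_depth(m, denoise_config(iterations = 1L))
      expect_equal(one, brute_force_dilate(m))
      two <- denoise_depth(m, denoise_config(iterations = 2L))
      expect_true(all(two >= one) && all(one >= m))
      expect_lte(sum(two == 0), sum(one == 0))
      expect_lte(sum(one == 0), sum(m == 0))
    }
  })
})

test_that("denoising an empty stack errors", {
  expect_error(denoise_depth(array(0L, c(0, 4, 1))), "empty")
})

test_that("axis profiles recover a constructed polynomial max profile", {
  H <- 40; W <- 60
  frame <- matrix(1000, H, W)
  frame[1, ] <- 2000 + 3 * seq_len(W)        # column max profile 2000 + 3t
  pr <- fit_axis_profiles(frame)
  fit <- pr$cols$max_fit
  expect_lt(abs(fit[["a2"]]), 1e-6)
  expect_equal(fit[["a1"]], 3, tolerance = 1e-6)
  expect_equal(fit[["a0"]], 2000, tolerance = 1e-4)
})

test_that("transposing the frame swaps the rows/cols profiles", {
  sc <- small_scene(seed = 3)
  f <- sc$depth[, , 1]
  a <- fit_axis_profiles(f)
  b <- fit_axis_profiles(t(f))
  expect_equal(a$rows$min_fit, b$cols$min_fit)
  expect_equal(a$cols$max_fit, b$rows$max_fit)
})

test_that("zero-only indices are excluded from the fits", {
  sc <- small_scene(seed = 3)
  f <- sc$depth[, , 1]
  f[, 7] <- 0L
  pr <- fit_axis_profiles(f)
  expect_false(7 %in% pr$cols$idx)
})

test_that("frames with too few usable indices raise a degenerate-geometry error", {
  f <- matrix(0L, 10, 10)
  f[, 1:2] <- 100L
  expect_error(fit_axis_profiles(f), "degenerate")
})

test_that("bed axis selection picks the flat max profile, ties to rows", {
  sc <- small_scene(seed = 6)
  pr <- fit_axis_profiles(sc$depth[, , 1])
  expect_equal(select_bed_axis(pr), "cols")
  prT <- fit_axis_profiles(t(sc$depth[, , 1]))
  expect_equal(select_bed_axis(prT), "rows")
  tie <- pr
  tie$rows$max_fit[["a2"]] <- 0.2
  tie$cols$max_fit[["a2"]] <- -0.2
  expect_equal(select_bed_axis(tie), "rows")
})

test_that("patient line sits at the analytic stationary point", {
  H <- 300; W <- 30
  frame <- matrix(5000, H, W)
  r <- seq_len(H)
  frame[, 1] <- 0.01 * (r - 150)^2 + 800     # row min profile, vertex 150
  pr <- fit_axis_profiles(frame)
  expect_equal(locate_patient_line(pr, "cols"), 150L)
})

test_that("degenerate or out-of-frame vertices fall back to the raw argmin", {
  H <- 50; W <- 30
  frame <- matrix(5000, H, W)
  frame[, 1] <- 3000 - 10 * seq_len(H)       # linear: no stationary point
  frame[33, 1] <- 100                        # raw argmin at 33
  pr <- fit_axis_profiles(frame)
  expect_equal(locate_patient_line(pr, "cols"), 33L)
})

test_that("a symmetric synthetic bed yields the mid-frame patient line", {
  sc <- small_scene(seed = 8)
  pr <- fit_axis_profiles(sc$depth[, , 1])
  line <- locate_patient_line(pr, "cols")
  expect_lte(abs(line - (64 + 1) / 2), 1)
})

test_that("crop planes honour the sigma floor and the 2-sigma rule", {
  f <- matrix(0L, 20, 40)
  f[10, ] <- 2000L
  pl <- compute_crop_planes(f, "cols", 10L, min_halfwidth_mm = 100)
  expect_equal(pl$sigma, 0)
  expect_equal(unname(pl$near), rep(1900, 40))
  expect_equal(unname(pl$far), rep(2100, 40))

  f2 <- matrix(0L, 20, 40)
  f2[10, ] <- rep(c(1900L, 2100L), 20)
  pl2 <- compute_crop_planes(f2, "cols", 10L)
  expect_equal(pl2$sigma, 100)
  expect_equal(pl2$halfwidth, 200)
  mid <- pl2$line_fit[["intercept"]] + pl2$line_fit[["slope"]] * 20.5
  expect_equal(mid, 2000, tolerance = 1e-8)

  f3 <- matrix(0L, 20, 40)
  f3[10, 5] <- 2000L
  expect_error(compute_crop_planes(f3, "cols", 10L), "manual")
})

test_that("depth crop equals the brute-force band check and drops zeros", {
  withr::with_seed(31, {
    f <- matrix(sample(0:3000, 400, replace = TRUE), 20, 20)
    f[10, ] <- sample(1800:2200, 20, replace = TRUE)
    pl <- compute_crop_planes(f, "cols", 10L)
    res <- apply_depth_crop(f, pl)
    expect_equal(res$mask, brute_force_band_mask(f, pl))
    expect_true(all(f[res$mask] > 0))
    # boundary: a pixel one mm beyond far is zeroed
    f2 <- f
    f2[3, 7] <- as.integer(round(pl$far[7] + 1))
    res2 <- apply_depth_crop(f2, pl)
    expect_false(res2$mask[3, 7])
    expect_equal(res2$depth[3, 7], 0L)
  })
})

test_that("IR masking matches the elementwise oracle", {
  withr::with_seed(5, {
    ir <- array(sample(0:65535, 200, replace = TRUE), c(10, 10, 2))
    dep <- array(sample(c(0L, 2000L), 200, replace = TRUE), c(10, 10, 2))
    out <- crop_ir_with_depth(ir, dep)
    expect_equal(out, ir * (dep > 0))
    expect_equal(crop_ir_with_depth(ir, array(1L, dim(ir))), ir)
    expect_true(all(crop_ir_with_depth(ir, array(0L, dim(ir))) == 0))
    expect_error(crop_ir_with_depth(ir, dep[, , 1, drop = FALSE]),
                 "identical dimensions")
  })
})

test_that("the full depth crop is equivariant under transposition", {
  sc <- small_scene(frame_count = 2, seed = 13)
  a <- depth_crop(sc$depth, denoise = FALSE)
  dT <- aperm(sc$depth, c(2, 1, 3))
  b <- depth_crop(dT, denoise = FALSE)
  expect_equal(b$planes$bed_axis, "rows")
  expect_equal(b$mask, aperm(a$mask, c(2, 1, 3)))
})

test_that("depth crop recovers the truth band on noisy scenes with denoising", {
  # sensor-resolution frames: the 6-px dilation ring at object borders is
  # negligible relative to the bed region at 424 x 512
  for (s in 1:2) {
    sc <- generate_scene(scene_config(frame_count = 2, pepper_fraction = 0.03,
                                      seed = s))
    dc <- depth_crop(sc$depth, sc$ir)
    band <- sc$truth$depth_band
    clean <- generate_scene(scene_config(frame_count = 2, pepper_fraction = 0,
                                         seed = s))
    tm <- clean$depth >= band[1] & clean$depth <= band[2]
    iou <- sum(dc$mask & tm) / sum(dc$mask | tm)
    expect_gte(iou, 0.9)
  }
})
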