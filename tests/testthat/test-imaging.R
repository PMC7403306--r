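test_that("equivalent radius is exact for a binary disk mask", {
  # build a frame whose bubble mask is known pixel-for-pixel
  px <- matrix(1, 101, 101)
  d <- sqrt(outer((1:101 - 51) ^ 2, (1:101 - 51) ^ 2, `+`))
  px[d <= 30] <- 0
  frame <- lcr_frame(px, um_per_px = 1.5)
  seg <- segment_frame(frame)
  expect_identical(seg$area, sum(d <= 30))
  expect_identical(seg$equivalent_radius,
                   1.5 * sqrt(sum(d <= 30) / pi) * 1e-6)
  expect_false(seg$flags$no_bubble)
  expect_false(seg$flags$multiple_components)
  expect_false(seg$flags$touching_border)
})

test_that("render/segment round trip recovers the radius within a pixel", {
  for (r_px in c(12, 50, 90)) {
    fr <- render_synthetic_frame(r_px * 1e-6, um_per_px = 1,
                                 frame_dim = c(220L, 220L), blur_px = 2,
                                 noise_sigma = 0.05, seed = 100 + r_px)
    seg <- segment_frame(fr)
    expect_equal(seg$equivalent_radius * 1e6, r_px, tolerance = 1 / r_px)
  }
})

test_that("degenerate frames give a flagged no-bubble result, not an error", {
  uniform <- lcr_frame(matrix(0.7, 60, 60), um_per_px = 1)
  seg <- segment_frame(uniform)
  expect_true(seg$flags$no_bubble)
  expect_identical(seg$equivalent_radius, 0)
  # pure noise with no structure is also rejected by the contrast guard
  noisy <- lcr_frame(matrix(0.7 + 0.01 * rnorm(3600), 60, 60), um_per_px = 1)
  expect_true(segment_frame(noisy)$flags$no_bubble)
  blank <- render_synthetic_frame(0, um_per_px = 1, frame_dim = c(60L, 60L),
                                  noise_sigma = 0, seed = 1)
  expect_true(segment_frame(blank)$flags$no_bubble)
})

test_that("largest component wins and is flagged when satellites exist", {
  px <- matrix(0.9, 200, 200)
  d1 <- sqrt(outer((1:200 - 70) ^ 2, (1:200 - 70) ^ 2, `+`))
  d2 <- sqrt(outer((1:200 - 170) ^ 2, (1:200 - 170) ^ 2, `+`))
  px[d1 <= 50] <- 0.1
  px[d2 <= 10] <- 0.1
  seg <- segment_frame(lcr_frame(px, um_per_px = 1))
  expect_true(seg$flags$multiple_components)
  expect_equal(seg$equivalent_radius * 1e6, 50, tolerance = 1 / 50)
})

test_that("segmentation is invariant to global affine intensity rescaling", {
  fr <- render_synthetic_frame(40e-6, um_per_px = 1, frame_dim = c(120L, 120L),
                               blur_px = 1.5, noise_sigma = 0.04, seed = 5)
  seg1 <- segment_frame(fr)
  rescaled <- lcr_frame(3.7 * fr$pixels + 11, fr$um_per_px)
  seg2 <- segment_frame(rescaled)
  expect_identical(seg1$mask, seg2$mask)
  expect_identical(seg1$equivalent_radius, seg2$equivalent_radius)
})

test_that("renderer is deterministic per seed and respects the frame bounds", {
  f1 <- render_synthetic_frame(30e-6, 1, c(100L, 100L), seed = 9)
  f2 <- render_synthetic_frame(30e-6, 1, c(100L, 100L), seed = 9)
  expect_identical(f1$pixels, f2$pixels)
  f3 <- render_synthetic_frame(30e-6, 1, c(100L, 100L), seed = 10)
  expect_false(identical(f1$pixels, f3$pixels))
  expect_error(render_synthetic_frame(60e-6, 1, c(100L, 100L), seed = 1),
               "exceeds the frame")
})

test_that("dark and bright polarity select opposite classes", {
  px <- matrix(0.1, 80, 80)
  d <- sqrt(outer((1:80 - 40) ^ 2, (1:80 - 40) ^ 2, `+`))
  px[d <= 20] <- 0.9  # bright bubble on dark background
  fr <- lcr_frame(px, um_per_px = 1)
  expect_equal(segment_frame(fr, polarity = "bright")$equivalent_radius * 1e6,
               20, tolerance = 0.05)
  # dark polarity segments the background instead and touches the border
  expect_true(segment_frame(fr, polarity = "dark")$flags$touching_border)
})

test_that("frame series assembles into a sorted dataset and validates inputs", {
  mk <- function(r_um, delay, rep) render_synthetic_frame(
    r_um * 1e-6, 1, c(160L, 160L), blur_px = 1, noise_sigma = 0.03,
    seed = round(1000 * delay) + rep, delay = delay, replicate_id = rep,
    sample_id = "s1")
  frames <- list(mk(50, 3e-6, 2), mk(30, 1e-6, 1), mk(50, 3e-6, 1),
                 mk(45, 2e-6, 1))
  ds <- build_series(frames)
  expect_s3_class(ds, "lcr_dataset")
  expect_equal(nrow(ds), 4L)
  expect_true(!is.unsorted(ds$time))
  expect_equal(ds$time[order(ds$time, ds$replicate_id)], ds$time)
  expect_equal(unique(ds$sample_id), "s1")
  expect_error(build_series(list()), "no frames")
  bad_scale <- list(mk(30, 1e-6, 1),
                    render_synthetic_frame(30e-6, 2, c(160L, 160L), seed = 1,
                                           delay = 2e-6, replicate_id = 1,
                                           sample_id = "s1"))
  expect_error(build_series(bad_scale), "mixed pixel scales")
})

test_that("frames written to disk read back losslessly enough to segment", {
  dir <- withr::local_tempdir()
  fr <- render_synthetic_frame(35e-6, 1, c(120L, 120L), blur_px = 1,
                               noise_sigma = 0.02, seed = 3,
                               delay = 5e-6, replicate_id = 1L,
                               sample_id = "s1")
  png_path <- file.path(dir, "f.png")
  png::writePNG(fr$pixels, png_path)
  tif_path <- file.path(dir, "f.tif")
  tiff::writeTIFF(fr$pixels, tif_path)
  for (p in c(png_path, tif_path)) {
    back <- read_frame(p, 1, 5e-6, 1L, "s1")
    expect_equal(segment_frame(back)$equivalent_radius * 1e6, 35,
                 tolerance = 1 / 35)
  }
  expect_error(read_frame(file.path(dir, "f.bmp"), 1), "unsupported")
})
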