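test_that("target downsample factor is the MPP ratio", {
  expect_equal(target_downsample_factor(0.25, 1.0), 4.0)
  expect_equal(target_downsample_factor(1.0, 1.0), 1.0)
  # the Aperio AT2 example resolution
  expect_equal(target_downsample_factor(0.2530, 1.0), 1.0 / 0.2530)
  expect_equal(target_downsample_factor(0.2530, 1.0), 3.952569, tolerance = 1e-6)
  expect_error(target_downsample_factor(NA, 1.0), "MPP")
  expect_error(target_downsample_factor(0, 1.0), "MPP")
  expect_error(target_downsample_factor(1.0, 0.5), "upsampling")
})

test_that("downsample factors are multiplicative across resolutions", {
  f_ab <- target_downsample_factor(0.25, 1.0)
  f_bc <- target_downsample_factor(1.0, 5.0)
  f_ac <- target_downsample_factor(0.25, 5.0)
  expect_equal(f_ab * f_bc, f_ac)
})

test_that("pixel-to-mm conversions match the physical reference sizes", {
  # 10,000 px at 5 MPP is a 0.5 x 0.5 mm^2 square; 1600 px is 0.2 x 0.2 mm^2
  expect_equal(sqrt(pixels_to_mm(10000, 5, area = TRUE)), 0.5)
  expect_equal(sqrt(pixels_to_mm(1600, 5, area = TRUE)), 0.2)
  # a 7680 px inference tile at 1 MPP spans 7.68 mm
  expect_equal(pixels_to_mm(7680, 1), 7.68)
  expect_error(pixels_to_mm(-1, 5), "non-negative")
  expect_error(pixels_to_mm(10, 0), "positive")
})

test_that("region reads resample from the correct level with area averaging", {
  sl <- make_test_pyramid(w0 = 64, h0 = 64, mpp = 1)
  # factor-1 read of a stored tile is a byte-identical passthrough
  r <- read_region_at_mpp(sl, 1, 5, 3, 16, 16)
  expect_equal(r$pixels, sl$levels[[1]][4:19, 6:21, ])
  # factor-4 read equals the stored 4x level (already an exact box average)
  r4 <- read_region_at_mpp(sl, 4, 0, 0, 16, 16)
  expect_equal(max(abs(r4$pixels - sl$levels[[2]])), 0, tolerance = 1e-9)
  # factor-5 read comes from the 4x level resized 1.25x by area averaging
  dims <- slide_dims_at_mpp(sl, 5)
  r5 <- read_full_at_mpp(sl, 5)
  expect_equal(unname(dims), c(12, 12))
  expect_equal(unname(dim(r5$pixels)[1:2]), c(12, 12))
  # the 12-px target plane spans [0, 60) level-0 px = [0, 15) of the 4x level
  for (c in 1:3) {
    expect_equal(r5$pixels[, , c],
                 matrix(round(oracle_area_average(sl$levels[[2]][1:15, 1:15, c],
                                                  12, 12)), 12, 12),
                 tolerance = 1e-9)
  }
})

test_that("constant images are invariant under area-averaged reads", {
  lv <- array(200, c(40, 40, 3))
  sl <- slide_pyramid(list(lv), mpp_x = 1)
  r <- read_region_at_mpp(sl, 3.7, 1, 1, 9, 9)
  expect_true(all(r$pixels == 200))
  # global mean preserved within 1/255 for a random image
  sl2 <- make_test_pyramid(w0 = 60, h0 = 60, factors = 1L)
  full <- read_full_at_mpp(sl2, 3)
  expect_equal(mean(full$pixels), mean(sl2$levels[[1]]), tolerance = 1 / 255)
})

test_that("full-plane reads agree with direct sub-region reads", {
  sl <- make_test_pyramid(w0 = 64, h0 = 64)
  full <- read_full_at_mpp(sl, 2)
  sub <- read_region_at_mpp(sl, 2, 4, 6, 10, 12)
  expect_equal(unname(sub$pixels), unname(full$pixels[7:18, 5:14, ]),
               tolerance = 1e-9)
})

test_that("out-of-bounds regions and sub-level targets are rejected", {
  sl <- make_test_pyramid()
  expect_error(read_region_at_mpp(sl, 1, 60, 0, 10, 10), "out of bounds")
  expect_error(read_region_at_mpp(sl, 1, 0, 0, 0, 5), "positive size")
  expect_error(read_region_at_mpp(sl, 0.5, 0, 0, 5, 5), "upsampling")
})

test_that("slides round-trip through the pyramidal TIFF container", {
  sl <- make_test_pyramid(w0 = 32, h0 = 24, mpp = 0.2530)
  path <- file.path(tempdir(), "roundtrip.tif")
  write_slide(sl, path)
  back <- read_slide(path)
  expect_equal(back$mpp_x, 0.2530)
  expect_identical(length(back$levels), length(sl$levels))
  for (i in seq_along(sl$levels)) {
    expect_equal(back$levels[[i]], sl$levels[[i]])
  }
  # slides without MPP metadata are rejected
  file.remove(paste0(path, ".json"))
  expect_error(read_slide(path), "rejected")
  expect_error(slide_pyramid(list(array(0, c(4, 4, 3))), mpp_x = NA),
               "rejected")
})

test_that("mask and image PNG helpers round-trip", {
  m <- matrix(0L, 10, 12); m[3:6, 4:9] <- 1L
  p <- tempfile(fileext = ".png")
  write_mask_png(m, p)
  expect_identical(read_mask_png(p), m)
  img <- array(sample(0:255, 10 * 12 * 3, replace = TRUE), c(10, 12, 3))
  write_image_png(img, p)
  expect_equal(read_image_png(p), img)
})
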