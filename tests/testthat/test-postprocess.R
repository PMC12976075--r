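test_that("configuration preconditions are enforced", {
  expect_error(postprocess_config(low_threshold = 230, high_threshold = 229),
               "thresholds")
  expect_error(postprocess_config(min_shrink = 0), "min_shrink")
  cfg <- postprocess_config()
  expect_equal(cfg$low_threshold, 85L)
  expect_equal(cfg$high_threshold, 229L)
  expect_equal(cfg$pruning_threshold, 229L)
})

test_that("smoothing preserves constants and the shrink factor floors at 0.2", {
  cfg <- postprocess_config()
  img <- matrix(180L, 400, 300)
  out <- smooth_probability(img, cfg)
  expect_equal(dim(out), c(400, 300))
  expect_true(all(out == 180L))
  # area 25e6 gives exactly the minimum shrink factor 0.2
  expect_equal(max(0.2, sqrt(1e6 / 25e6)), 0.2)
  # area 1e6 sits exactly at the no-shrink boundary
  expect_equal(max(0.2, sqrt(1e6 / 1e6)), 1)
  expect_error(smooth_probability(matrix(0, 0, 0), cfg), "empty")
})

test_that("hysteresis grows strong seeds through weak connected pixels", {
  cfg <- postprocess_config()
  expect_true(all(hysteresis_segment(matrix(85L, 10, 10), cfg) == 0))
  expect_true(all(hysteresis_segment(matrix(255L, 10, 10), cfg) == 1))
  strip <- matrix(c(50L, 90L, 230L, 90L, 50L, 90L), 1, 6)
  expect_equal(as.vector(hysteresis_segment(strip, cfg)),
               c(0L, 1L, 1L, 1L, 0L, 0L))
})

test_that("region pruning keys on the 95th percentile", {
  cfg <- postprocess_config()
  m <- matrix(1L, 10, 10)
  expect_true(all(prune_regions(m, matrix(255L, 10, 10), cfg) == 1))
  expect_true(all(prune_regions(m, matrix(100L, 10, 10), cfg) == 0))
  # 100 px region: 96 at 250 and 4 at 90 -> 95th percentile 250 > 229: kept
  sm <- matrix(250L, 10, 10)
  sm[1, 1:4] <- 90L
  expect_true(all(prune_regions(m, sm, cfg) == 1))
  # boundary: all values exactly 229 are not > 229: removed
  expect_true(all(prune_regions(m, matrix(229L, 10, 10), cfg) == 0))
  # disabled pruning is the identity
  cfg_off <- postprocess_config(pruning_enabled = FALSE)
  expect_identical(prune_regions(m, matrix(0L, 10, 10), cfg_off), m)
})

test_that("final cleanup intersects with tissue and removes debris", {
  cfg <- postprocess_config()
  pred <- matrix(1L, 200, 200)
  expect_true(all(finalise_mask(pred, matrix(0L, 200, 200), cfg) == 0))
  # blob with hole: intersection keeps blob, hole is filled
  blob <- matrix(0L, 200, 200); blob[50:149, 50:149] <- 1L
  holed <- blob; holed[80:109, 80:109] <- 0L
  out <- finalise_mask(holed, blob, cfg)
  expect_true(all(out[50:149, 50:149] == 1))
  # surviving 35x35 blob (1225 px < 1600) is removed
  small <- matrix(0L, 200, 200); small[10:44, 10:44] <- 1L
  expect_true(all(finalise_mask(small, small, cfg) == 0))
  expect_error(finalise_mask(pred, matrix(0L, 10, 10), cfg), "mismatch")
})

test_that("final masks are always subsets of the tissue mask", {
  set.seed(19)
  cfg <- postprocess_config()
  for (i in 1:5) {
    pred <- matrix(as.integer(runif(120 * 120) < 0.5), 120, 120)
    tis <- matrix(as.integer(runif(120 * 120) < 0.6), 120, 120)
    out <- finalise_mask(pred, tis, cfg)
    # foreground can only appear where tissue was, or in holes fully
    # enclosed by kept prediction
    expect_true(all(out[tis == 0 & pred == 0] == 0))
  }
})

test_that("raising the low threshold never grows the segmented area", {
  set.seed(4)
  sm <- matrix(as.integer(runif(80 * 80, 0, 255)), 80, 80)
  sm <- quantise_u8(EBImage::filter2(sm, matrix(1 / 81, 9, 9),
                                     boundary = "replicate"))
  areas <- vapply(c(40L, 85L, 120L, 180L), function(lo) {
    cfg <- postprocess_config(low_threshold = lo, high_threshold = 229L)
    sum(hysteresis_segment(sm, cfg))
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("an ideal probability image survives the whole pipeline unchanged", {
  cfg <- postprocess_config()
  n <- 400
  prob1 <- matrix(0L, n * 2, n * 2)   # 1 MPP mosaic (will be downsampled x5)
  tissue <- matrix(1L, round(n * 2 / 5), round(n * 2 / 5))
  blob <- matrix(0L, nrow(tissue), ncol(tissue))
  blob[40:130, 30:120] <- 1L          # ~8200 px at 5 MPP
  # paint the blob at 1 MPP geometry
  for (y in 1:nrow(prob1)) for (x in 1:ncol(prob1)) NULL
  ys <- ceiling(seq_len(nrow(prob1)) / 5); xs <- ceiling(seq_len(ncol(prob1)) / 5)
  prob1 <- 255L * blob[ys, xs]
  res <- postprocess_mosaic(prob1, tissue, cfg)
  inter <- sum(res$mask & blob)
  expect_gt(2 * inter / (sum(res$mask) + sum(blob)), 0.97)
})

test_that("the threshold sweep enumerates 171 pairs with expected structure", {
  # binary 0/255 probability image: every pair yields the same mask
  sm <- matrix(0L, 120, 120); sm[30:90, 30:90] <- 255L
  tis <- matrix(1L, 120, 120)
  ref <- sm / 255L
  storage.mode(ref) <- "integer"
  sw <- threshold_sweep(list(sm), list(ref), list(tis),
                        postprocess_config(min_object = 100L))
  expect_equal(nrow(sw$grid), 171L)
  expect_equal(length(unique(sw$grid$mean_dsc)), 1L)
  expect_equal(sw$best$mean_dsc, 1)
  # monotone in the low threshold for fixed high threshold
  set.seed(6)
  sm2 <- quantise_u8(EBImage::filter2(matrix(runif(100 * 100, 0, 255), 100),
                                      matrix(1 / 81, 9, 9),
                                      boundary = "replicate"))
  cfg <- postprocess_config(min_object = 1L, hole_fill = 1L)
  areas <- vapply(seq(5, 85, 5), function(lo) {
    c2 <- cfg; c2$low_threshold <- as.integer(round(lo * 255 / 100))
    c2$high_threshold <- as.integer(round(90 * 255 / 100))
    sum(hysteresis_segment(sm2, c2))
  }, 0)
  expect_true(all(diff(areas) <= 0))
})
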