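test_that("oversampling equalises group totals with near-uniform multiplicities", {
  groups <- list(A = paste0("a", 1:3), B = paste0("b", 1:5))
  for (seed in 1:50) {
    s <- balance_by_oversampling(groups, seed)
    totals <- tapply(s$multiplicity, s$group, sum)
    expect_true(all(totals == 5))
    for (g in names(groups)) {
      m <- s$multiplicity[s$group == g]
      expect_lte(max(m) - min(m), 1L)
    }
  }
  # single group: all multiplicity 1
  one <- balance_by_oversampling(list(A = paste0("a", 1:4)), 1)
  expect_true(all(one$multiplicity == 1))
  expect_error(balance_by_oversampling(list(A = character(0), B = "b")), "non-empty")
})

test_that("oversampling is deterministic given the seed", {
  groups <- list(A = paste0("a", 1:7), B = paste0("b", 1:11))
  expect_identical(balance_by_oversampling(groups, 99),
                   balance_by_oversampling(groups, 99))
})

test_that("four groups balance to the majority size", {
  sizes <- c(colorectal = 3017, endometrial = 1939, lung = 3519, prostate = 2149)
  groups <- lapply(sizes, function(n) paste0("s", seq_len(n)))
  s <- balance_by_oversampling(groups, 7)
  totals <- tapply(s$multiplicity, s$group, sum)
  expect_true(all(totals == 3519))
})

test_that("background tiles are excluded unless annotated", {
  tiles <- data.frame(
    annotation_px = c(0L, 10L, 0L),
    background_frac = c(0.6, 0.9, 0.4)
  )
  kept <- exclude_background_tiles(tiles)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$background_frac %in% c(0.9, 0.4)))
})

test_that("dataset moments follow the mean-of-image-statistics definition", {
  # all images constant c
  imgs <- list(array(60, c(4, 4, 3)), array(60, c(2, 8, 3)))
  m <- dataset_moments(imgs)
  expect_equal(m$mu, rep(60 / 255, 3))
  expect_equal(m$sigma, rep(0, 3))
  # two 2-pixel single-channel images {0,255} and {255,255}
  m2 <- dataset_moments(list(matrix(c(0, 255), 1, 2), matrix(c(255, 255), 1, 2)))
  expect_equal(m2$mu, 0.75)
  expect_equal(m2$sigma, 0.5)
  # single image collapse
  img <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(dataset_moments(list(img))$mu, mean(img) / 255)
  expect_error(dataset_moments(list(matrix(5, 1, 1))), "single pixel")
  expect_error(dataset_moments(list()), "at least one")
})

test_that("dataset moments match a brute-force loop on a random corpus", {
  set.seed(21)
  imgs <- lapply(1:40, function(i) {
    array(sample(0:255, 48, replace = TRUE), c(4, 4, 3))
  })
  m <- dataset_moments(imgs)
  for (c in 1:3) {
    mus <- vars <- numeric(length(imgs))
    for (i in seq_along(imgs)) {
      v <- as.vector(imgs[[i]][, , c])
      mus[i] <- sum(v) / length(v)
      vars[i] <- sum((v - mus[i])^2) / (length(v) - 1)
    }
    expect_equal(m$mu[c], mean(mus) / 255, tolerance = 1e-12)
    expect_equal(m$sigma[c], sqrt(mean(vars)) / 255, tolerance = 1e-12)
  }
})

test_that("standardisation centres, scales and inverts exactly", {
  moments <- structure(list(mu = c(0.4, 0.5, 0.6), sigma = c(0.1, 0.2, 0.3)),
                       class = "dataset_moments")
  img <- array(0, c(3, 3, 3))
  for (c in 1:3) img[, , c] <- 255 * moments$mu[c]
  expect_true(all(abs(standardise_image(img, moments)) < 1e-12))
  ident <- structure(list(mu = c(0, 0, 0), sigma = c(1, 1, 1)),
                     class = "dataset_moments")
  rnd <- array(sample(0:255, 27, replace = TRUE), c(3, 3, 3))
  expect_equal(standardise_image(rnd, ident), rnd / 255)
  # round trip
  st <- standardise_image(rnd, moments)
  expect_equal(unstandardise_image(st, moments), rnd, tolerance = 1e-6)
  bad <- structure(list(mu = c(0, 0, 0), sigma = c(1, 0, 1)),
                   class = "dataset_moments")
  expect_error(standardise_image(rnd, bad), "positive")
})

test_that("tile corpora carry correct labels and background fractions", {
  spec <- synthetic_slide_spec(seed = 5, canvas_px = 768L,
                               lesion_radius_mm = c(0.06, 0.1),
                               n_lesions = 1L,
                               texture = list(lesion_margin_mm = 0.05))
  fx <- generate_slide(spec)
  tissue <- fx$tissue_gt
  prep <- prepare_tiles(fx$slide, fx$annotation, tissue, tile_px = 256L,
                        target_mpp = 1, mask_mpp = 5)
  man <- prep$manifest
  expect_equal(nrow(man), 9L)
  expect_true(all(man$background_frac >= 0 & man$background_frac <= 1))
  # kept rule is the exclusion rule
  expect_identical(man$kept,
                   man$annotation_px > 0 | man$background_frac < 0.5)
  # labels consistent with the annotation: tumour pixels only where annotated
  tumour_px <- sum(vapply(prep$tiles, function(t) sum(t$label == 2L), 0))
  expect_gt(tumour_px, 0)
})
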