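# Development-set preparation: group balancing, background tile exclusion,
# and channel standardisation statistics.

#' Balance slide groups by oversampling
#'
#' Minority groups are oversampled on the slide level so every group
#' contributes as many sampled slides as the largest group. Slides are
#' selected at random without replacement in whole permutations: no slide is
#' selected `n + 1` times before all slides in its group have been selected
#' `n` times. Within a group, per-slide multiplicities therefore differ by at
#' most 1.
#'
#' @param groups Named list mapping group name to a character vector of slide
#'   ids. Every group must be non-empty.
#' @param seed Integer seed; the sampling is deterministic given the seed.
#' @return A `slide_sampling` data frame with columns `group`, `slide_id`,
#'   `multiplicity` (>= 1).
#' @export
balance_by_oversampling <- function(groups, seed = 1L) {
  if (length(groups) == 0 || any(lengths(groups) == 0)) {
    stop("every group must be non-empty")
  }
  target <- max(lengths(groups))
  res <- with_seed(seed, {
    lapply(names(groups), function(g) {
      ids <- groups[[g]]
      n <- length(ids)
      base <- target %/% n
      rem <- target %% n
      extra <- if (rem > 0) sample(ids, rem) else character(0)
      data.frame(group = g, slide_id = ids,
                 multiplicity = base + as.integer(ids %in% extra))
    })
  })
  out <- do.call(rbind, res)
  class(out) <- c("slide_sampling", "data.frame")
  out
}

#' Keep tiles that are informative for training
#'
#' A tile is kept if it contains any tumour-annotated pixels, or, failing
#' that, if its white-background fraction is below 0.5.
#'
#' @param tiles Data frame with columns `annotation_px` (annotated pixel
#'   count in the tile) and `background_frac` (white-background fraction of
#'   the tile footprint, from the 5 MPP tissue mask transferred to the tile
#'   geometry).
#' @param max_background Background-fraction cutoff (default 0.5).
#' @return The kept subset of `tiles`.
#' @export
exclude_background_tiles <- function(tiles, max_background = 0.5) {
  stopifnot(all(c("annotation_px", "background_frac") %in% names(tiles)))
  keep <- tiles$annotation_px > 0 | tiles$background_frac < max_background
  tiles[keep, , drop = FALSE]
}

#' Per-channel dataset mean and standard deviation
#'
#' The dataset mean of a channel is the mean over images of per-image means;
#' the dataset variance is the mean over images of per-image unbiased
#' variances. Both statistics are computed on the raw 8-bit scale and divided
#' by 255 before use.
#'
#' @param images List of `[H, W, C]` arrays (or matrices, C = 1) with 0..255
#'   values; each image needs at least 2 pixels.
#' @return A `dataset_moments` object: list with `mu` and `sigma`, each of
#'   length C, on the `[0, 1]` scale.
#' @export
dataset_moments <- function(images) {
  if (length(images) == 0) stop("at least one image is required")
  stats <- lapply(images, function(img) {
    if (is.matrix(img)) img <- array(img, c(dim(img), 1))
    npix <- prod(dim(img)[1:2])
    if (npix < 2) stop("an image with a single pixel has undefined variance")
    ch <- dim(img)[3]
    mu <- vapply(seq_len(ch), function(c) mean(img[, , c]), 0)
    v <- vapply(seq_len(ch), function(c) stats::var(as.vector(img[, , c])), 0)
    list(mu = mu, v = v)
  })
  mu <- Reduce(`+`, lapply(stats, `[[`, "mu")) / length(stats)
  v <- Reduce(`+`, lapply(stats, `[[`, "v")) / length(stats)
  structure(list(mu = mu / 255, sigma = sqrt(v) / 255), class = "dataset_moments")
}

#' Standardise an 8-bit image with dataset moments
#'
#' Values are divided by 255, centred on the dataset mean and scaled by the
#' dataset standard deviation, identically during training and inference.
#'
#' @param img `[H, W, C]` array of 0..255 values.
#' @param moments A [dataset_moments()] object with `sigma > 0` everywhere.
#' @return Real-valued array of the same shape.
#' @export
standardise_image <- function(img, moments) {
  if (any(moments$sigma <= 0)) stop("sigma must be positive for all channels")
  if (is.matrix(img)) img <- array(img, c(dim(img), 1))
  out <- array(0, dim(img))
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- (img[, , c] / 255 - moments$mu[c]) / moments$sigma[c]
  }
  out
}

#' Invert [standardise_image()]
#'
#' @param x Standardised array.
#' @param moments The moments used for standardisation.
#' @return 0..255-scale array (not quantised).
#' @export
unstandardise_image <- function(x, moments) {
  out <- array(0, dim(x))
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- (x[, , c] * moments$sigma[c] + moments$mu[c]) * 255
  }
  out
}

# Nearest-neighbour projection of a mask onto a different grid size.
nn_project_mask <- function(mask, out_h, out_w) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(H, floor(((seq_len(out_h) - 0.5) * H) / out_h) + 1)
  ci <- pmin(W, floor(((seq_len(out_w) - 0.5) * W) / out_w) + 1)
  mask[ri, ci, drop = FALSE]
}

#' Cut a training tile corpus from a slide
#'
#' Reads the slide at the target resolution, tiles it with
#' [tile_grid()], transfers the 5 MPP tissue and annotation masks to each
#' tile footprint (nearest neighbour), computes per-tile annotation counts
#' and background fractions, and applies [exclude_background_tiles()].
#'
#' @param slide A [slide_pyramid()].
#' @param annotation Binary tumour annotation mask at `mask_mpp`.
#' @param tissue Binary tissue mask at `mask_mpp` (from
#'   [tissue_mask_from_image()]).
#' @param tile_px Tile side at `target_mpp` (the published setup uses 2048).
#' @param target_mpp Resolution tiles are sampled at (default 1).
#' @param mask_mpp Resolution of the masks (default 5).
#' @param min_overlap Minimum tile overlap (default 0 for training).
#' @param out_dir If non-`NULL`, tiles are also written to disk as JPG
#'   (quality 95) with PNG label tiles, mirroring the on-disk corpus layout.
#' @param slide_id Identifier used in the manifest and file names.
#' @return List with `tiles` (kept tiles; each has `img` `[h,w,3]` 0..255,
#'   `label` `[h,w]` in {0 background, 1 foreground, 2 tumour}) and
#'   `manifest` (per-tile data frame, including excluded tiles with
#'   `kept = FALSE`).
#' @export
prepare_tiles <- function(slide, annotation, tissue, tile_px = 2048L,
                          target_mpp = 1, mask_mpp = 5, min_overlap = 0L,
                          out_dir = NULL, slide_id = "slide") {
  dims <- slide_dims_at_mpp(slide, target_mpp)
  grid <- tile_grid(dims["width"], dims["height"], tile_px, min_overlap)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tiles <- list()
  man <- grid$tiles
  man$slide_id <- slide_id
  man$annotation_px <- 0L
  man$background_frac <- 0
  for (i in seq_len(nrow(man))) {
    t <- man[i, ]
    # 5 MPP masks mapped onto the tile footprint
    sc <- target_mpp / mask_mpp
    ann_t <- nn_project_mask(crop_mask_for_tile(annotation, t, sc), t$h, t$w)
    tis_t <- nn_project_mask(crop_mask_for_tile(tissue, t, sc), t$h, t$w)
    man$annotation_px[i] <- sum(ann_t)
    man$background_frac[i] <- mean(tis_t == 0)
    # pixel data are only read for tiles that survive the exclusion rule
    if (man$annotation_px[i] > 0 || man$background_frac[i] < 0.5) {
      img <- read_region_at_mpp(slide, target_mpp, t$x, t$y, t$w, t$h)$pixels
      tiles[[i]] <- list(img = img, label = classify_content(tis_t, ann_t))
    }
  }
  kept <- exclude_background_tiles(man)
  man$kept <- man$tile_id %in% kept$tile_id
  tiles <- tiles[man$kept]
  if (!is.null(out_dir)) {
    ki <- which(man$kept)
    for (j in seq_along(ki)) {
      base <- sprintf("%s_tile%04d", slide_id, man$tile_id[ki[j]])
      write_image_jpg(tiles[[j]]$img, file.path(out_dir, paste0(base, ".jpg")))
      png::writePNG(tiles[[j]]$label / 2, file.path(out_dir, paste0(base, "_label.png")))
    }
    write.csv(man, file.path(out_dir, paste0(slide_id, "_manifest.csv")),
              row.names = FALSE)
  }
  list(tiles = tiles, manifest = man)
}

# Crop the part of a mask-resolution plane covering one target-plane tile.
crop_mask_for_tile <- function(mask, t, scale) {
  H <- nrow(mask); W <- ncol(mask)
  r0 <- max(1, floor(t$y * scale) + 1)
  r1 <- min(H, ceiling((t$y + t$h) * scale))
  c0 <- max(1, floor(t$x * scale) + 1)
  c1 <- min(W, ceiling((t$x + t$w) * scale))
  mask[r0:r1, c0:c1, drop = FALSE]
}

#' Seeded uniform random crop of an image/label pair
#'
#' Training tiles are stored larger than the network input and cropped at a
#' uniformly random position each time they are drawn. This is the default
#' (and only built-in) distortion; additional distortions can be supplied to
#' [train_network()] via its `augment` hook.
#'
#' @param img `[H, W, C]` image array.
#' @param label `[H, W]` label matrix.
#' @param size Crop side in pixels (<= min(H, W)).
#' @return List with cropped `img` and `label`.
#' @export
random_crop <- function(img, label, size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (size > H || size > W) stop("crop larger than tile")
  y0 <- if (H == size) 0L else sample.int(H - size + 1L, 1L) - 1L
  x0 <- if (W == size) 0L else sample.int(W - size + 1L, 1L) - 1L
  list(img = img[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE],
       label = label[y0 + seq_len(size), x0 + seq_len(size), drop = FALSE])
}
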