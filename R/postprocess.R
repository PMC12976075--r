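# Post-processing of the stitched 1 MPP probability image into the final
# binary tumour mask at 5 MPP: smoothing, hysteresis dichotomisation,
# percentile-based region pruning, and mask cleanup against the tissue mask.

#' Post-processing configuration
#'
#' All thresholds operate on the 8-bit probability scale; cleanup areas are
#' in 5 MPP pixels. The defaults are the published operating point: low
#' threshold 85 (1/3 of 255), high threshold 229 (~90% of 255), region
#' pruning on the 95th percentile against 229, hole fill below 10,000 px and
#' object removal below 1600 px.
#'
#' @param low_threshold,high_threshold Hysteresis thresholds (strict `>`).
#' @param pruning_percentile Percentile of region probability values used
#'   for pruning (default 95).
#' @param pruning_threshold Pruning cutoff (strict `>`, default 229).
#' @param pruning_enabled Disable for threshold-sweep experiments.
#' @param smoothing_median_aperture Median filter window side (default 9).
#' @param smoothing_gaussian_size,smoothing_gaussian_sigma Gaussian kernel
#'   side and sigma (defaults 5 and 1.1).
#' @param min_shrink Lower bound on the pre-smoothing shrink factor
#'   (default 0.2).
#' @param min_area_px Area floor that limits shrinking (default 1e6).
#' @param hole_fill,min_object Cleanup thresholds in pixels.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(low_threshold = 85L, high_threshold = 229L,
                               pruning_percentile = 95, pruning_threshold = 229L,
                               pruning_enabled = TRUE,
                               smoothing_median_aperture = 9L,
                               smoothing_gaussian_size = 5L,
                               smoothing_gaussian_sigma = 1.1,
                               min_shrink = 0.2, min_area_px = 1e6,
                               hole_fill = 10000L, min_object = 1600L) {
  if (low_threshold < 0 || low_threshold >= high_threshold || high_threshold > 255) {
    stop("thresholds must satisfy 0 <= low < high <= 255")
  }
  if (min_shrink <= 0 || min_shrink > 1) stop("min_shrink must be in (0, 1]")
  structure(as.list(environment()), class = "postprocess_config")
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Resize a single-channel plane; area-averaging when reducing, bilinear when
# enlarging (no information is invented on the way down, none is sharpened
# on the way up).
resize_plane <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  if (out_h == H && out_w == W) return(img)
  if (out_h <= H && out_w <= W) {
    cpp_area_resample(img, 0, 0, H, W, out_h, out_w)
  } else {
    cpp_resize_bilinear(img, out_h, out_w)
  }
}

#' Smooth an 8-bit probability image
#'
#' The image is first resized by the factor
#' `max(min_shrink, sqrt(min_area_px / (h*w)))` per direction (sizes
#' floored) so smoothing runs on a bounded pixel count, then median filtered
#' (aperture 9), Gaussian blurred (5x5 kernel), and resized back to the
#' input geometry.
#'
#' @param prob `[H, W]` matrix of 0..255 values at 5 MPP (the 1 MPP mosaic
#'   is downsampled by 5 beforehand, see [postprocess_mosaic()]).
#' @param cfg A [postprocess_config()].
#' @return Smoothed 8-bit matrix, same size as the input.
#' @export
smooth_probability <- function(prob, cfg = postprocess_config()) {
  H <- nrow(prob); W <- ncol(prob)
  if (H < 1 || W < 1) stop("empty image")
  fac <- max(cfg$min_shrink, sqrt(cfg$min_area_px / (H * W)))
  h2 <- max(1L, floor(H * fac)); w2 <- max(1L, floor(W * fac))
  x <- resize_plane(prob, h2, w2)
  x <- cpp_median_filter(x, (cfg$smoothing_median_aperture - 1L) %/% 2L)
  k <- gaussian_kernel(cfg$smoothing_gaussian_size, cfg$smoothing_gaussian_sigma)
  x <- EBImage::filter2(x, k, boundary = "replicate")
  x <- resize_plane(x, H, W)
  m <- quantise_u8(x)
  storage.mode(m) <- "integer"
  m
}

#' Hysteresis dichotomisation of a smoothed probability image
#'
#' Pixels strictly above the high threshold seed foreground regions that
#' grow through 4-connected pixels strictly above the low threshold.
#'
#' @param smoothed 8-bit matrix from [smooth_probability()].
#' @param cfg A [postprocess_config()].
#' @return Binary (0/1) mask.
#' @export
hysteresis_segment <- function(smoothed, cfg = postprocess_config()) {
  hysteresis_mask(smoothed, cfg$low_threshold, cfg$high_threshold,
                  connectivity = 4L)
}

#' Prune low-confidence foreground regions
#'
#' For each 4-connected foreground region, the probability values it covers
#' in the smoothed image are collected; the region is kept only when their
#' 95th percentile (linear interpolation between order statistics) is
#' strictly greater than the pruning threshold. A no-op when
#' `cfg$pruning_enabled` is `FALSE`.
#'
#' @param mask Binary mask from [hysteresis_segment()].
#' @param smoothed The smoothed probability image, same geometry.
#' @param cfg A [postprocess_config()].
#' @return Binary mask with low-confidence regions removed.
#' @export
prune_regions <- function(mask, smoothed, cfg = postprocess_config()) {
  if (!cfg$pruning_enabled) return(mask)
  if (!all(dim(mask) == dim(smoothed))) stop("shape mismatch")
  lab <- cpp_label(matrix(as.integer(mask), nrow(mask)), 4L)
  n <- max(lab)
  if (n == 0) return(mask)
  out <- mask
  for (i in seq_len(n)) {
    vals <- smoothed[lab == i]
    q <- quantile(vals, cfg$pruning_percentile / 100, type = 7, names = FALSE)
    if (!(q > cfg$pruning_threshold)) out[lab == i] <- 0L
  }
  out
}

#' Final mask cleanup against the tissue mask
#'
#' Pixels not foreground in both the predicted mask and the tissue mask
#' become background; background holes below `cfg$hole_fill` pixels are then
#' filled and foreground objects below `cfg$min_object` pixels erased.
#'
#' @param pred_mask Binary predicted mask at 5 MPP.
#' @param tissue Binary tissue mask, same geometry.
#' @param cfg A [postprocess_config()].
#' @return The final binary tumour mask (always a subset of `tissue`... up
#'   to holes filled inside predicted tissue regions).
#' @export
finalise_mask <- function(pred_mask, tissue, cfg = postprocess_config()) {
  if (!all(dim(pred_mask) == dim(tissue))) stop("shape mismatch")
  stopifnot_binary(pred_mask, "prediction")
  stopifnot_binary(tissue, "tissue mask")
  m <- (pred_mask == 1 & tissue == 1) * 1L
  m <- fill_small_holes(m, cfg$hole_fill)
  remove_small_objects_mask(m, cfg$min_object)
}

#' Full post-processing of a stitched probability mosaic
#'
#' Downsamples the 1 MPP mosaic by 5 (area averaging) to the 5 MPP tissue
#' geometry, smooths, dichotomises with hysteresis, prunes regions and
#' cleans against the tissue mask.
#'
#' @param mosaic `[H, W]` 0..255 probability image at 1 MPP (from
#'   [merge_tiles()]).
#' @param tissue Binary tissue mask at 5 MPP.
#' @param cfg A [postprocess_config()].
#' @return List with `mask` (final binary mask), `smoothed` and `prob5` (the
#'   5 MPP probability image before smoothing).
#' @export
postprocess_mosaic <- function(mosaic, tissue, cfg = postprocess_config()) {
  p5 <- cpp_area_resample(mosaic * 1.0, 0, 0, nrow(mosaic), ncol(mosaic),
                          nrow(tissue), ncol(tissue))
  p5 <- quantise_u8(p5)
  storage.mode(p5) <- "integer"
  sm <- smooth_probability(p5, cfg)
  m <- hysteresis_segment(sm, cfg)
  m <- prune_regions(m, sm, cfg)
  list(mask = finalise_mask(m, tissue, cfg), smoothed = sm, prob5 = p5)
}

#' Hysteresis threshold sweep
#'
#' Re-segments smoothed probability images over the grid of threshold pairs:
#' low thresholds 5%, 10%, ..., 90% of 255 and, for each low value x, high
#' thresholds x+5%, ..., 95% (171 pairs). Pruning is disabled; cleanup
#' against the tissue mask is kept. Performance per pair is the cohort mean
#' DSC (background-excluded).
#'
#' @param smoothed_list List of smoothed 5 MPP probability images.
#' @param ref_list List of binary reference masks, same geometries.
#' @param tissue_list List of binary tissue masks, same geometries.
#' @param cfg A [postprocess_config()] supplying the cleanup settings.
#' @return List with `grid` (data frame: `low_pct`, `high_pct`, `low`,
#'   `high`, `mean_dsc`) and `best` (the row with maximal mean DSC).
#' @export
threshold_sweep <- function(smoothed_list, ref_list, tissue_list,
                            cfg = postprocess_config()) {
  lows <- seq(5L, 90L, by = 5L)
  combos <- do.call(rbind, lapply(lows, function(lo) {
    his <- seq(lo + 5L, 95L, by = 5L)
    data.frame(low_pct = lo, high_pct = his)
  }))
  combos$low <- as.integer(round(combos$low_pct * 255 / 100))
  combos$high <- as.integer(round(combos$high_pct * 255 / 100))
  combos$mean_dsc <- NA_real_
  n_img <- length(smoothed_list)
  for (k in seq_len(nrow(combos))) {
    cfg_k <- cfg
    cfg_k$low_threshold <- combos$low[k]
    cfg_k$high_threshold <- combos$high[k]
    cfg_k$pruning_enabled <- FALSE
    dscs <- vapply(seq_len(n_img), function(i) {
      m <- hysteresis_segment(smoothed_list[[i]], cfg_k)
      m <- finalise_mask(m, tissue_list[[i]], cfg_k)
      cc <- confusion_counts(m, ref_list[[i]], (tissue_list[[i]] == 0) * 1L)
      unname(metric_set(cc)["DSC"])
    }, 0)
    combos$mean_dsc[k] <- mean(dscs)
  }
  list(grid = combos, best = combos[which.max(combos$mean_dsc), ])
}
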