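# Tissue/background segmentation at 5 MPP.
#
# White glass background is separated from tissue (and artefacts) by Canny
# edge detection followed by morphological cleanup. The detector is
# deliberately sensitive: any structured region (including adipose tissue,
# pen marks, dust) becomes foreground; only homogeneous white areas stay
# background.

shift_mat <- function(p, dy, dx, H, W) {
  # p is the (H+2) x (W+2) replicate-padded image; returns the H x W view
  # shifted by (dy, dx) in {-1, 0, 1}
  p[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
}

#' Canny structure detection on a colour image
#'
#' Runs Canny edge detection (3x3 Sobel gradients, L2 magnitude,
#' non-maximum suppression, hysteresis with thresholds 10/50) on the luma of
#' an RGB image. Regions with structure produce many foreground pixels;
#' homogeneous regions produce none.
#'
#' @param rgb A `plane_image` or `[H, W, 3]` array with 0..255 values.
#' @param low,high Hysteresis thresholds on the gradient magnitude.
#' @return A binary (0/1) integer matrix of edge pixels.
#' @export
canny_foreground <- function(rgb, low = 10, high = 50) {
  if (inherits(rgb, "plane_image")) rgb <- rgb$pixels
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("canny_foreground expects a 3-channel image")
  }
  luma <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  H <- nrow(luma); W <- ncol(luma)
  p <- matrix(0, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- luma
  # replicate borders
  p[1, ] <- p[2, ]; p[H + 2, ] <- p[H + 1, ]
  p[, 1] <- p[, 2]; p[, W + 2] <- p[, W + 1]
  gx <- (shift_mat(p, -1, 1, H, W) + 2 * shift_mat(p, 0, 1, H, W) + shift_mat(p, 1, 1, H, W)) -
        (shift_mat(p, -1, -1, H, W) + 2 * shift_mat(p, 0, -1, H, W) + shift_mat(p, 1, -1, H, W))
  gy <- (shift_mat(p, 1, -1, H, W) + 2 * shift_mat(p, 1, 0, H, W) + shift_mat(p, 1, 1, H, W)) -
        (shift_mat(p, -1, -1, H, W) + 2 * shift_mat(p, -1, 0, H, W) + shift_mat(p, -1, 1, H, W))
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression along the quantised gradient direction
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  dir <- integer(length(ang))
  dir[(ang < 22.5) | (ang >= 157.5)] <- 0L  # horizontal gradient
  dir[ang >= 22.5 & ang < 67.5] <- 1L       # diagonal /
  dir[ang >= 67.5 & ang < 112.5] <- 2L      # vertical gradient
  dir[ang >= 112.5 & ang < 157.5] <- 3L     # diagonal \
  dir <- matrix(dir, H, W)
  pm <- matrix(0, H + 2, W + 2)
  pm[2:(H + 1), 2:(W + 1)] <- mag
  nb <- function(dy, dx) shift_mat(pm, dy, dx, H, W)
  keep <- matrix(FALSE, H, W)
  sel <- dir == 0L; keep[sel] <- mag[sel] >= nb(0, -1)[sel] & mag[sel] >= nb(0, 1)[sel]
  sel <- dir == 2L; keep[sel] <- mag[sel] >= nb(-1, 0)[sel] & mag[sel] >= nb(1, 0)[sel]
  sel <- dir == 1L; keep[sel] <- mag[sel] >= nb(-1, 1)[sel] & mag[sel] >= nb(1, -1)[sel]
  sel <- dir == 3L; keep[sel] <- mag[sel] >= nb(-1, -1)[sel] & mag[sel] >= nb(1, 1)[sel]
  thin <- mag * keep
  hysteresis_mask(thin, low, high, connectivity = 8L)
}

# Two-threshold region growing: pixels strictly above `high` seed regions
# that extend through connected pixels strictly above `low`.
hysteresis_mask <- function(values, low, high, connectivity = 4L) {
  cand <- (values > low) * 1L
  if (!any(cand == 1L)) return(matrix(0L, nrow(values), ncol(values)))
  lab <- cpp_label(matrix(as.integer(cand), nrow(values)), as.integer(connectivity))
  seeds <- unique(lab[values > high])
  seeds <- seeds[seeds > 0]
  out <- matrix(0L, nrow(values), ncol(values))
  if (length(seeds) > 0) out[lab %in% seeds] <- 1L
  out
}

#' Fill small background holes
#'
#' Holes are fully enclosed background components (4-connected, not
#' touching the image border); those with area strictly below `max_area`
#' pixels are relabelled as foreground.
#'
#' @param mask Binary (0/1) matrix.
#' @param max_area Area threshold in pixels.
#' @return Binary matrix with small holes filled.
#' @export
fill_small_holes <- function(mask, max_area) {
  stopifnot_binary(mask)
  inv <- matrix(as.integer(mask == 0), nrow(mask))
  lab <- cpp_label(inv, 4L)
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0])
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  small <- setdiff(which(areas < max_area), border[border > 0])
  out <- mask
  if (length(small) > 0) out[lab %in% small] <- 1L
  out
}

#' Remove small foreground objects
#'
#' Foreground components (4-connected) with area strictly below `min_area`
#' pixels are erased.
#'
#' @param mask Binary (0/1) matrix.
#' @param min_area Area threshold in pixels.
#' @return Binary matrix with small objects removed.
#' @export
remove_small_objects_mask <- function(mask, min_area) {
  stopifnot_binary(mask)
  lab <- cpp_label(matrix(as.integer(mask), nrow(mask)), 4L)
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < min_area)
  out <- mask
  if (length(small) > 0) out[lab %in% small] <- 0L
  out
}

#' Refine a structure mask into the final tissue mask
#'
#' Applies, in order: morphological closing with a square 9x9 structuring
#' element, filling of background holes below 10,000 px (0.5 x 0.5 mm^2 at
#' 5 MPP), morphological opening with the same element, and erasure of
#' foreground components below 1600 px (0.2 x 0.2 mm^2 at 5 MPP).
#'
#' @param edges Binary (0/1) matrix from [canny_foreground()].
#' @param hole_area,object_area Cleanup thresholds in pixels.
#' @return The binary tissue mask (1 = foreground).
#' @export
refine_foreground <- function(edges, hole_area = 10000L, object_area = 1600L) {
  stopifnot_binary(edges)
  brush <- EBImage::makeBrush(9L, "box")
  m <- EBImage::closing(edges * 1.0, brush)
  m <- fill_small_holes((m > 0) * 1L, hole_area)
  m <- EBImage::opening(m * 1.0, brush)
  remove_small_objects_mask((m > 0) * 1L, object_area)
}

#' Tissue mask of a 5 MPP slide image
#'
#' Convenience wrapper: [canny_foreground()] followed by
#' [refine_foreground()].
#'
#' @param rgb A `plane_image` or `[H, W, 3]` array of 0..255 values at 5 MPP.
#' @return Binary tissue mask (1 = tissue/artefact foreground).
#' @export
tissue_mask_from_image <- function(rgb) {
  refine_foreground(canny_foreground(rgb))
}

#' Three-way content classification
#'
#' Classifies every pixel as white background (0), foreground without
#' annotation (1), or foreground with annotation (2). Background dominates:
#' annotation over non-tissue is ignored.
#'
#' @param tissue Binary tissue mask.
#' @param annotation Binary tumour-annotation mask, same geometry.
#' @return Integer matrix with labels in `{0, 1, 2}`.
#' @export
classify_content <- function(tissue, annotation) {
  if (!all(dim(tissue) == dim(annotation))) stop("shape mismatch")
  stopifnot_binary(tissue, "tissue mask")
  stopifnot_binary(annotation, "annotation mask")
  out <- matrix(0L, nrow(tissue), ncol(tissue))
  out[tissue == 1 & annotation == 0] <- 1L
  out[tissue == 1 & annotation == 1] <- 2L
  out
}
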