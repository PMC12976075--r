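#' Construct an in-memory slide pyramid
#'
#' A slide pyramid is a multi-resolution image: a list of progressively
#' downsampled copies ("levels") of the level-0 plane, plus the physical
#' resolution (micrometres per pixel, MPP) of level 0 in each direction.
#' Level 0 has downsample factor 1 and factors strictly increase with level.
#'
#' @param levels List of `[H, W, 3]` arrays with 8-bit values (0..255),
#'   ordered from highest resolution (level 0) to lowest.
#' @param mpp_x,mpp_y Level-0 resolution in micrometres per pixel, per
#'   direction. Must be positive; slides without MPP metadata are not
#'   admissible (see [read_slide()]).
#' @return A `slide_pyramid` object with fields `levels`, `mpp_x`, `mpp_y`,
#'   `downsamples` (factor of each level relative to level 0) and `dims`
#'   (per-level `width`/`height` in pixels).
#' @export
slide_pyramid <- function(levels, mpp_x, mpp_y = mpp_x) {
  if (!is.list(levels) || length(levels) < 1) stop("levels must be a non-empty list")
  if (!is.numeric(mpp_x) || !is.numeric(mpp_y) || is.na(mpp_x) || is.na(mpp_y) ||
      mpp_x <= 0 || mpp_y <= 0) {
    stop("slide rejected: missing or invalid MPP metadata")
  }
  dims <- t(vapply(levels, function(l) {
    d <- dim(l)
    if (length(d) != 3 || d[3] != 3) stop("each level must be an [H, W, 3] array")
    c(width = d[2], height = d[1])
  }, c(width = 0, height = 0)))
  downs <- dims[1, "width"] / dims[, "width"]
  if (abs(downs[1] - 1) > 1e-9) stop("level-0 downsample factor must be 1")
  if (any(diff(downs) <= 0)) stop("downsample factors must strictly increase")
  structure(
    list(levels = levels, mpp_x = mpp_x, mpp_y = mpp_y,
         downsamples = as.numeric(downs),
         dims = as.data.frame(dims)),
    class = "slide_pyramid"
  )
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("slide_pyramid: %d levels, level-0 %d x %d px at %.4f/%.4f MPP\n",
              length(x$levels), x$dims$width[1], x$dims$height[1],
              x$mpp_x, x$mpp_y))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  level %d: %5d x %5d px, factor %g\n", i - 1,
                x$dims$width[i], x$dims$height[i], x$downsamples[i]))
  }
  invisible(x)
}

#' Target downsampling factor for a requested resolution
#'
#' The factor by which the level-0 plane must be downsampled to reach the
#' target resolution: `target_mpp / mpp_level0`. When the two directional
#' level-0 MPPs differ, the directional factors differ too.
#'
#' @param mpp_level0 Level-0 resolution (micrometres per pixel), > 0.
#' @param target_mpp Requested resolution, >= `mpp_level0` (slides are never
#'   upsampled).
#' @return The positive real downsampling factor.
#' @examples
#' target_downsample_factor(0.25, 1.0) # 4
#' @export
target_downsample_factor <- function(mpp_level0, target_mpp) {
  if (is.na(mpp_level0) || mpp_level0 <= 0) {
    stop("slide rejected: missing or invalid MPP metadata")
  }
  if (target_mpp < mpp_level0) stop("target_mpp below level-0 MPP: upsampling is not supported")
  target_mpp / mpp_level0
}

#' Plane dimensions of a slide at a target resolution
#'
#' @param slide A [slide_pyramid()].
#' @param target_mpp Target resolution in micrometres per pixel.
#' @return `c(width, height)` in pixels (floor of level-0 size divided by the
#'   directional target factors).
#' @export
slide_dims_at_mpp <- function(slide, target_mpp) {
  fx <- target_downsample_factor(slide$mpp_x, target_mpp)
  fy <- target_downsample_factor(slide$mpp_y, target_mpp)
  c(width = floor(slide$dims$width[1] / fx),
    height = floor(slide$dims$height[1] / fy))
}

#' Read a rectangular region at a target resolution
#'
#' Reads the region from the highest-resolution pyramid level whose stored
#' downsample factor does not exceed the (smaller directional) target factor,
#' then resizes it to the exact requested pixel size by area-averaging
#' interpolation, quantising back to 8 bits (round half to even). No
#' upsampling ever occurs and the output has exactly the requested
#' dimensions.
#'
#' @param slide A [slide_pyramid()].
#' @param target_mpp Target resolution (micrometres per pixel).
#' @param x,y,w,h Region in target-plane pixels: 0-based half-open rectangle
#'   `[x, x+w) x [y, y+h)`, x rightwards, y downwards.
#' @return A `plane_image`: list with `pixels` (`[h, w, 3]`, 0..255) and
#'   `mpp` (the target resolution).
#' @export
read_region_at_mpp <- function(slide, target_mpp, x, y, w, h) {
  stopifnot(inherits(slide, "slide_pyramid"))
  fx <- target_downsample_factor(slide$mpp_x, target_mpp)
  fy <- target_downsample_factor(slide$mpp_y, target_mpp)
  dims <- slide_dims_at_mpp(slide, target_mpp)
  if (w < 1 || h < 1) stop("region must have positive size")
  if (x < 0 || y < 0 || x + w > dims["width"] || y + h > dims["height"]) {
    stop("region out of bounds at target resolution")
  }
  eligible <- which(slide$downsamples <= min(fx, fy) + 1e-9)
  if (length(eligible) == 0) stop("no eligible pyramid level for target factor")
  lev <- max(eligible)
  fl <- slide$downsamples[lev]
  sx <- fx / fl
  sy <- fy / fl
  src <- slide$levels[[lev]]
  x <- unname(x); y <- unname(y); w <- unname(w); h <- unname(h)
  d <- dim(src)
  px <- cpp_area_resample_multi(src, d[1], d[2], 3L,
                                y * sy, x * sx, (y + h) * sy, (x + w) * sx,
                                h, w)
  px <- array(quantise_u8(px), c(h, w, 3))
  structure(list(pixels = px, mpp = target_mpp), class = "plane_image")
}

#' Read the full slide plane at a target resolution
#'
#' @inheritParams read_region_at_mpp
#' @return A `plane_image` covering the whole plane at `target_mpp`.
#' @export
read_full_at_mpp <- function(slide, target_mpp) {
  dims <- slide_dims_at_mpp(slide, target_mpp)
  read_region_at_mpp(slide, target_mpp, 0, 0, dims["width"], dims["height"])
}

#' Convert pixel measures to millimetres
#'
#' @param px Pixel count: a length (`area = FALSE`) or an area in px^2
#'   (`area = TRUE`). Must be non-negative.
#' @param mpp Resolution of the plane the pixels live on (micrometres per
#'   pixel), > 0.
#' @param area If `TRUE`, convert px^2 to mm^2, else px to mm.
#' @return Millimetres or square millimetres.
#' @examples
#' pixels_to_mm(10000, 5, area = TRUE) # 0.25 mm^2, i.e. 0.5 x 0.5 mm
#' @export
pixels_to_mm <- function(px, mpp, area = FALSE) {
  if (any(px < 0)) stop("pixel measure must be non-negative")
  if (mpp <= 0) stop("mpp must be positive")
  if (area) px * (mpp / 1000)^2 else px * mpp / 1000
}

#' Write a slide pyramid to disk
#'
#' The pixel data are stored as a multi-page 8-bit TIFF (one page per level,
#' highest resolution first); the MPP metadata and per-level downsample
#' factors go to a JSON sidecar at `<path>.json`, since baseline TIFF pages
#' written by the available writer carry no resolution tags.
#'
#' @param slide A [slide_pyramid()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_pyramid"))
  pages <- lapply(slide$levels, function(l) u8_to_unit(l))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  meta <- list(mpp_x = slide$mpp_x, mpp_y = slide$mpp_y,
               downsamples = slide$downsamples)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slide pyramid from disk
#'
#' Counterpart of [write_slide()]. A slide whose sidecar is missing or lacks
#' MPP metadata is rejected, mirroring the exclusion rule for scans without
#' resolution properties.
#'
#' @param path TIFF path written by [write_slide()].
#' @return A [slide_pyramid()].
#' @export
read_slide <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("slide rejected: missing or invalid MPP metadata")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$mpp_x) || is.null(meta$mpp_y)) {
    stop("slide rejected: missing or invalid MPP metadata")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  levels <- lapply(pages, function(p) {
    if (length(dim(p)) == 2) p <- array(rep(p, 3), c(dim(p), 3))
    if (dim(p)[3] > 3) p <- p[, , 1:3, drop = FALSE]
    round(p * 255)
  })
  slide_pyramid(levels, meta$mpp_x, meta$mpp_y)
}

#' Write an image or mask as PNG
#'
#' Masks are written single-channel with 0 = background and 255 = foreground;
#' images are written as 8-bit grey or RGB.
#'
#' @param img For `write_mask_png` a binary (0/1) matrix; for
#'   `write_image_png` a `[H, W]` matrix or `[H, W, 3]` array of 0..255
#'   values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(img, path) {
  stopifnot_binary(img)
  png::writePNG(img * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
write_image_png <- function(img, path) {
  png::writePNG(u8_to_unit(img), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' Any strictly positive pixel is foreground.
#'
#' @param path PNG path.
#' @return A binary (0/1) integer matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0) * 1L
}

#' Read an 8-bit image from PNG
#'
#' @param path PNG path.
#' @return A matrix or `[H, W, C]` array of 0..255 values.
#' @export
read_image_png <- function(path) {
  round(png::readPNG(path) * 255)
}

#' Write an RGB training tile as JPG (quality 95)
#'
#' @param img `[H, W, 3]` array of 0..255 values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_jpg <- function(img, path) {
  jpeg::writeJPEG(u8_to_unit(img), path, quality = 0.95)
  invisible(path)
}
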