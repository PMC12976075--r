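#' Equal-overlap tile intervals along one axis
#'
#' Partitions the half-open pixel range `[0, length)` into intervals of
#' `tile` pixels. Consecutive intervals overlap by exactly `min_overlap`
#' pixels, except possibly the last pair, which may overlap more so that the
#' final interval ends exactly at `length`. An axis shorter than the tile
#' yields a single full-axis interval (downstream consumers zero-pad at the
#' model boundary).
#'
#' @param length Axis length in pixels (>= 1).
#' @param tile Tile side in pixels (>= 1).
#' @param min_overlap Minimum overlap between consecutive tiles in pixels;
#'   must satisfy `0 <= min_overlap < tile`.
#' @return An integer matrix with columns `start` and `end`, one row per
#'   interval, each `[start, end)` half-open and 0-based.
#' @examples
#' tile_intervals(100, 40, 0)
#' tile_intervals(14336, 7680, 1024)
#' @export
tile_intervals <- function(length, tile, min_overlap = 0L) {
  length <- as.integer(length)
  tile <- as.integer(tile)
  min_overlap <- as.integer(min_overlap)
  if (length < 1L) stop("length must be >= 1")
  if (tile < 1L) stop("tile must be >= 1")
  if (min_overlap < 0L || min_overlap >= tile) {
    stop("min_overlap must satisfy 0 <= min_overlap < tile")
  }
  if (length <= tile) {
    return(cbind(start = 0L, end = length))
  }
  stride <- tile - min_overlap
  starts <- seq.int(0L, length - tile, by = stride)
  # drop any enumerated start whose tile would already reach the end; the
  # final tile is always placed flush with the axis end instead
  starts <- starts[starts + tile < length]
  starts <- c(starts, length - tile)
  cbind(start = starts, end = starts + tile)
}

#' Build a 2-D tile grid
#'
#' Applies [tile_intervals()] independently to each axis; the grid tiles are
#' the Cartesian product of the column (x) and row (y) intervals.
#'
#' @param width,height Plane size in pixels.
#' @param tile Tile side in pixels (square tiles).
#' @param min_overlap Minimum overlap in pixels, per axis.
#' @return A `tile_grid` object: list with `x_intervals`, `y_intervals`
#'   (matrices as from [tile_intervals()]), `tiles` (data frame with
#'   `tile_id`, `x`, `y`, `w`, `h`), `tile_size`, `min_overlap`, `width`,
#'   `height`.
#' @export
tile_grid <- function(width, height, tile, min_overlap = 0L) {
  xi <- tile_intervals(width, tile, min_overlap)
  yi <- tile_intervals(height, tile, min_overlap)
  tiles <- expand.grid(ix = seq_len(nrow(xi)), iy = seq_len(nrow(yi)))
  tiles <- data.frame(
    tile_id = seq_len(nrow(tiles)),
    x = xi[tiles$ix, "start"],
    y = yi[tiles$iy, "start"],
    w = xi[tiles$ix, "end"] - xi[tiles$ix, "start"],
    h = yi[tiles$iy, "end"] - yi[tiles$iy, "start"]
  )
  structure(
    list(
      x_intervals = xi, y_intervals = yi, tiles = tiles,
      tile_size = as.integer(tile), min_overlap = as.integer(min_overlap),
      width = as.integer(width), height = as.integer(height)
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "tile_grid: %d x %d px plane, %d x %d tiles (tile %d, min overlap %d)\n",
    x$width, x$height, nrow(x$x_intervals), nrow(x$y_intervals),
    x$tile_size, x$min_overlap
  ))
  invisible(x)
}

#' Export a tile manifest as CSV
#'
#' Writes one row per tile (`tile_id`, `x`, `y`, `w`, `h`, `target_mpp`) so
#' external tools can reproduce tile extraction exactly.
#'
#' @param grid A [tile_grid()] object.
#' @param path Output CSV path.
#' @param target_mpp Target resolution the grid's plane is defined at
#'   (micrometres per pixel); stored with each row.
#' @return `path`, invisibly.
#' @export
write_tile_manifest <- function(grid, path, target_mpp = NA_real_) {
  stopifnot(inherits(grid, "tile_grid"))
  df <- grid$tiles
  df$target_mpp <- target_mpp
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
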