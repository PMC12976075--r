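# Reconstruction of a full-plane probability image from overlapping score
# tiles. Each tile gets a weight image that decreases linearly with distance
# into each overlap band; after normalisation the weights form a partition
# of unity, so constant regions are conserved exactly.

#' Linear side weight inside an overlap band
#'
#' At distance `d` pixels into an overlap band of length `l`, the weight is
#' `1 - d / (1 + l)`; the `+1` keeps the weight strictly positive at the far
#' end. Pixels outside any overlap band have weight 1.
#'
#' @param d Distance into the band, `0 <= d <= l`.
#' @param l Band length in pixels (>= 0).
#' @return The weight value in (0, 1].
#' @export
side_weight <- function(d, l) {
  if (any(l < 0)) stop("overlap length must be non-negative")
  if (any(d < 0) || any(d > l)) stop("distance must lie within the overlap band")
  n <- max(length(d), length(l))
  d <- rep_len(d, n)
  l <- rep_len(l, n)
  out <- 1 - d / (1 + l)
  out[l == 0] <- 1
  out
}

# Per-interval 1-D weight vectors for one axis of a grid. For interval i,
# the right overlap band starts at the smallest start coordinate among
# overlapping intervals with a start greater than interval i's (and
# symmetrically for the left side).
axis_weights <- function(intervals) {
  starts <- intervals[, "start"]; ends <- intervals[, "end"]
  if (anyDuplicated(starts)) stop("invalid grid: tiles with identical placement")
  lapply(seq_len(nrow(intervals)), function(i) {
    s <- starts[i]; e <- ends[i]
    len <- e - s
    w <- rep(1, len)
    cand_r <- starts[starts > s & starts < e]
    if (length(cand_r) > 0) {
      b <- min(cand_r)            # global coordinate where right band starts
      l <- e - b
      d <- 0:(l - 1)
      w[(b - s + 1):len] <- w[(b - s + 1):len] * side_weight(d, l)
    }
    cand_l <- ends[ends < e & ends > s]
    if (length(cand_l) > 0) {
      b <- max(cand_l)            # global coordinate just past the left band
      l <- b - s
      d <- (l - 1):0              # distance from the interior border
      w[1:l] <- w[1:l] * side_weight(d, l)
    }
    w
  })
}

#' Normalised weight tiles for a tile grid
#'
#' Three-phase construction: initial per-tile weights as the product of the
#' four side-specific linear weights; a sum image accumulated over all
#' tiles; and per-tile normalisation by the sum image restricted to the tile
#' footprint. The returned weights sum to 1 at every plane pixel.
#'
#' @param grid A [tile_grid()].
#' @return List of `[h, w]` weight matrices, one per row of `grid$tiles`.
#' @export
build_weight_tiles <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  wx <- axis_weights(grid$x_intervals)
  wy <- axis_weights(grid$y_intervals)
  tiles <- grid$tiles
  nx <- nrow(grid$x_intervals)
  s <- matrix(0, grid$height, grid$width)
  raw <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    ix <- ((i - 1) %% nx) + 1
    iy <- ((i - 1) %/% nx) + 1
    w <- outer(wy[[iy]], wx[[ix]])
    raw[[i]] <- w
    t <- tiles[i, ]
    rows <- t$y + seq_len(t$h); cols <- t$x + seq_len(t$w)
    s[rows, cols] <- s[rows, cols] + w
  }
  lapply(seq_len(nrow(tiles)), function(i) {
    t <- tiles[i, ]
    rows <- t$y + seq_len(t$h); cols <- t$x + seq_len(t$w)
    raw[[i]] / s[rows, cols]
  })
}

#' Merge score tiles into a probability mosaic
#'
#' Accumulates `sum_i w_i * g_i` in floating point over the plane and
#' quantises to 8 bits with round-half-to-even.
#'
#' @param score_tiles List of `[h, w]` matrices with 0..255 values, in
#'   `grid$tiles` order.
#' @param grid The [tile_grid()] the tiles were cut with.
#' @param weights Weight tiles from [build_weight_tiles()] on the same grid;
#'   computed on the fly when omitted.
#' @return A `score_mosaic`: integer matrix `[height, width]` in 0..255.
#' @export
merge_tiles <- function(score_tiles, grid, weights = NULL) {
  stopifnot(inherits(grid, "tile_grid"))
  tiles <- grid$tiles
  if (length(score_tiles) != nrow(tiles)) {
    stop("one score tile per grid tile is required")
  }
  if (is.null(weights)) weights <- build_weight_tiles(grid)
  f <- matrix(0, grid$height, grid$width)
  for (i in seq_len(nrow(tiles))) {
    t <- tiles[i, ]
    g <- score_tiles[[i]]
    if (!all(dim(g) == c(t$h, t$w))) stop("placement mismatch for tile ", i)
    rows <- t$y + seq_len(t$h); cols <- t$x + seq_len(t$w)
    f[rows, cols] <- f[rows, cols] + weights[[i]] * g
  }
  m <- quantise_u8(f)
  storage.mode(m) <- "integer"
  structure(m, class = c("score_mosaic", class(m)))
}
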