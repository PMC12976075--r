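# Independent oracle implementations used to verify the package's
# primitives. These deliberately share no code with the implementations
# they check: plain loops and first-principles formulas only.

# Brute-force constraint checker for tile intervals. Returns NULL when all
# constraints hold, else a description of the first violation.
oracle_tile_check <- function(iv, len, tile, overlap) {
  if (len <= tile) {
    if (nrow(iv) != 1 || iv[1, 1] != 0 || iv[1, 2] != len) {
      return("short axis must give a single full-axis interval")
    }
    return(NULL)
  }
  if (iv[1, 1] != 0) return("first interval must start at 0")
  if (iv[nrow(iv), 2] != len) return("last interval must end at axis length")
  if (any(iv[, 2] - iv[, 1] != tile)) return("interval length must equal tile")
  covered <- rep(FALSE, len)
  for (i in seq_len(nrow(iv))) covered[(iv[i, 1] + 1):iv[i, 2]] <- TRUE
  if (!all(covered)) return("intervals must cover the axis")
  if (nrow(iv) >= 2) {
    ovl <- iv[-nrow(iv), 2] - iv[-1, 1]
    if (nrow(iv) > 2 && any(ovl[-length(ovl)] != overlap)) {
      return("all overlaps except the last pair must equal min_overlap")
    }
    if (ovl[length(ovl)] < overlap) {
      return("last overlap must be at least min_overlap")
    }
    if (any(diff(iv[, 1]) <= 0)) return("starts must strictly increase")
  }
  NULL
}

# Textbook Canny implementation with the same conventions as the package
# (replicate-border 3x3 Sobel, L2 magnitude, 4-direction NMS keeping
# plateaus, strict-threshold hysteresis with 8-connected linking), written
# as explicit per-pixel loops.
oracle_canny <- function(rgb, low = 10, high = 50) {
  lum <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  H <- nrow(lum); W <- ncol(lum)
  at <- function(y, x) lum[min(H, max(1, y)), min(W, max(1, x))]
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    gx[y, x] <- (at(y - 1, x + 1) + 2 * at(y, x + 1) + at(y + 1, x + 1)) -
      (at(y - 1, x - 1) + 2 * at(y, x - 1) + at(y + 1, x - 1))
    gy[y, x] <- (at(y + 1, x - 1) + 2 * at(y + 1, x) + at(y + 1, x + 1)) -
      (at(y - 1, x - 1) + 2 * at(y - 1, x) + at(y - 1, x + 1))
  }
  mag <- sqrt(gx^2 + gy^2)
  mat <- function(y, x) if (y < 1 || y > H || x < 1 || x > W) 0 else mag[y, x]
  thin <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    a <- atan2(gy[y, x], gx[y, x]) * 180 / pi
    if (a < 0) a <- a + 180
    if (a < 22.5 || a >= 157.5) {
      n1 <- mat(y, x - 1); n2 <- mat(y, x + 1)
    } else if (a < 67.5) {
      n1 <- mat(y - 1, x + 1); n2 <- mat(y + 1, x - 1)
    } else if (a < 112.5) {
      n1 <- mat(y - 1, x); n2 <- mat(y + 1, x)
    } else {
      n1 <- mat(y - 1, x - 1); n2 <- mat(y + 1, x + 1)
    }
    if (mag[y, x] >= n1 && mag[y, x] >= n2) thin[y, x] <- mag[y, x]
  }
  # hysteresis by repeated dilation of the strong set through the weak set
  strong <- thin > high
  weak <- thin > low
  repeat {
    grown <- strong
    for (y in 1:H) for (x in 1:W) {
      if (!weak[y, x] || strong[y, x]) next
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W && strong[yy, xx]) {
          grown[y, x] <- TRUE
        }
      }
    }
    if (identical(grown, strong)) break
    strong <- grown
  }
  (strong & weak) * 1L
}

# Flood-fill connected-component labelling (4-connectivity), BFS with an
# explicit queue in raster-scan order.
oracle_label4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (y in 1:H) for (x in 1:W) {
    if (mask[y, x] == 0 || lab[y, x] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- p[1] + d[1]; xx <- p[2] + d[2]
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
            mask[yy, xx] != 0 && lab[yy, xx] == 0) {
          lab[yy, xx] <- nxt
          queue <- c(queue, list(c(yy, xx)))
        }
      }
    }
  }
  lab
}

# Spearman correlation from first principles: midranks computed by sorting,
# then the explicit Pearson product-moment formula.
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in 1:n) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Tiny synthetic pyramid with exact box-average levels, for slide_io tests.
make_test_pyramid <- function(w0 = 64, h0 = 64, mpp = 1, seed = 7,
                              factors = c(1L, 4L)) {
  set.seed(seed)
  l0 <- array(sample(0:255, h0 * w0 * 3, replace = TRUE), c(h0, w0, 3))
  levels <- lapply(factors, function(f) {
    if (f == 1) return(l0)
    hh <- h0 %/% f; ww <- w0 %/% f
    out <- array(0, c(hh, ww, 3))
    for (c in 1:3) for (y in 1:hh) for (x in 1:ww) {
      out[y, x, c] <- mean(l0[((y - 1) * f + 1):(y * f),
                              ((x - 1) * f + 1):(x * f), c])
    }
    round(out)
  })
  slide_pyramid(levels, mpp_x = mpp, mpp_y = mpp)
}

# Independent fractional box-average of a single-channel plane.
oracle_area_average <- function(src, out_h, out_w) {
  H <- nrow(src); W <- ncol(src)
  bh <- H / out_h; bw <- W / out_w
  out <- matrix(0, out_h, out_w)
  for (oy in 1:out_h) for (ox in 1:out_w) {
    y0 <- (oy - 1) * bh; y1 <- oy * bh
    x0 <- (ox - 1) * bw; x1 <- ox * bw
    acc <- 0; wsum <- 0
    for (y in floor(y0):ceiling(y1 - 1e-12)) for (x in floor(x0):ceiling(x1 - 1e-12)) {
      if (y >= H || x >= W) next
      cy <- min(y + 1, y1) - max(y, y0)
      cx <- min(x + 1, x1) - max(x, x0)
      if (cy > 0 && cx > 0) {
        acc <- acc + cy * cx * src[y + 1, x + 1]
        wsum <- wsum + cy * cx
      }
    }
    out[oy, ox] <- acc / wsum
  }
  out
}

random_confusion_table <- function() {
  counts <- as.list(1 + rpois(4, lambda = sample(c(5, 50, 500), 4, replace = TRUE)))
  names(counts) <- c("TP", "FN", "FP", "TN")
  structure(list(N = counts$TP + counts$FN + counts$FP + counts$TN,
                 RP = counts$TP + counts$FN, RN = counts$FP + counts$TN,
                 PP = counts$TP + counts$FP, PN = counts$FN + counts$TN,
                 TP = counts$TP, FN = counts$FN, FP = counts$FP, TN = counts$TN),
            class = "confusion_counts")
}
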