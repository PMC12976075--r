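# Segmentation network: a pluggable encoder-decoder contract plus a small
# fully-convolutional default backbone, the Dice + top-90 cross-entropy
# loss, the warm-up/cosine step-length schedule, and SGD optimisation with
# Nesterov momentum. Forward and backward passes are written against the
# compiled kernels in src/ops.cpp; no external deep-learning runtime is
# used.
#
# Class convention everywhere: channel 1 = white background, channel 2 =
# non-annotated foreground, channel 3 = tumour-annotated foreground.

#' Zero-pad an image to the next multiples of 16
#'
#' Padding is added on the bottom and right only, and the returned record
#' allows exact removal after inference.
#'
#' @param img `[H, W, C]` array.
#' @return List with `img` (padded array) and `pad` (`c(h, w)` pixels
#'   added).
#' @export
pad_to_multiple16 <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ph <- (16 - H %% 16) %% 16
  pw <- (16 - W %% 16) %% 16
  if (ph == 0 && pw == 0) return(list(img = img, pad = c(h = 0L, w = 0L)))
  out <- array(0, c(H + ph, W + pw, dim(img)[3]))
  out[seq_len(H), seq_len(W), ] <- img
  list(img = out, pad = c(h = ph, w = pw))
}

#' Remove padding added by [pad_to_multiple16()]
#'
#' @param x Padded matrix or array.
#' @param pad The `pad` record.
#' @return The unpadded object.
#' @export
unpad <- function(x, pad) {
  H <- dim(x)[1] - pad["h"]; W <- dim(x)[2] - pad["w"]
  if (length(dim(x)) == 2) x[seq_len(H), seq_len(W), drop = FALSE]
  else x[seq_len(H), seq_len(W), , drop = FALSE]
}

#' Convolution weight initialisation samples
#'
#' Encoder convolutions are initialised from `Normal(0, 1/(c_i*h*w))` with
#' zero biases; decoder and segmentation-head convolutions (weights and
#' biases) from `Uniform(-a, a)` with `a = sqrt(3/(c_i*h*w))`. `c_i*h*w` is
#' the fan-in of the layer.
#'
#' @param c_i,h,w Input channels and kernel height/width (all >= 1).
#' @param kind `"encoder"` or `"decoder"`.
#' @param n Number of samples to draw.
#' @return Numeric vector of `n` weight samples.
#' @export
conv_init <- function(c_i, h, w, kind = c("encoder", "decoder"), n) {
  kind <- match.arg(kind)
  if (c_i < 1 || h < 1 || w < 1) stop("fan-in components must be >= 1")
  fan_in <- c_i * h * w
  if (kind == "encoder") {
    rnorm(n, 0, sqrt(1 / fan_in))
  } else {
    a <- sqrt(3 / fan_in)
    runif(n, -a, a)
  }
}

#' Step-length schedule specification
#'
#' Warm-up: the step length starts at `warmup_init` and is incremented by
#' `warmup_increment` every `warmup_period` steps until `warmup_end`, by
#' which point it has reached `peak`. Afterwards it follows cosine annealing
#' from `peak` to `eta_min` at `total_steps`.
#'
#' @param total_steps Termination step (default 500,000).
#' @param warmup_init,warmup_increment,warmup_period,warmup_end,peak,eta_min
#'   Schedule parameters; defaults are the published values (1e-4, 1e-4, 10,
#'   1000, 1e-2, 0).
#' @return A `schedule_spec` list.
#' @export
schedule_spec <- function(total_steps = 500000L, warmup_init = 1e-4,
                          warmup_increment = 1e-4, warmup_period = 10L,
                          warmup_end = 1000L, peak = 1e-2, eta_min = 0) {
  structure(as.list(environment()), class = "schedule_spec")
}

#' Step length at a 0-based optimisation step
#'
#' @param step Integer step, `0 <= step <= total_steps`.
#' @param spec A [schedule_spec()].
#' @return The step length (learning rate).
#' @examples
#' lr_at_step(0)       # 1e-4
#' lr_at_step(1000)    # 1e-2
#' @export
lr_at_step <- function(step, spec = schedule_spec()) {
  if (any(step < 0) || any(step > spec$total_steps)) stop("step out of range")
  warm <- pmin(spec$peak,
               spec$warmup_init +
                 spec$warmup_increment * floor(step / spec$warmup_period))
  cool <- spec$eta_min + (spec$peak - spec$eta_min) / 2 *
    (1 + cos(pi * (step - spec$warmup_end) /
               (spec$total_steps - spec$warmup_end)))
  ifelse(step < spec$warmup_end, warm, cool)
}

#' Top-90 cross entropy
#'
#' Discards the `floor(0.10 * N)` pixels with the lowest cross-entropy value
#' and averages the rest; pixels are pooled over the whole mini-batch.
#'
#' @param per_pixel_ce Numeric vector of per-pixel cross-entropy values
#'   (>= 1 value).
#' @return The scalar loss.
#' @examples
#' top90_cross_entropy(1:10) # mean of 2..10 = 6
#' @export
top90_cross_entropy <- function(per_pixel_ce) {
  n <- length(per_pixel_ce)
  if (n == 0) stop("at least one pixel is required")
  k <- floor(0.10 * n)
  if (k > 0) {
    mean(sort(per_pixel_ce)[-seq_len(k)])
  } else {
    mean(per_pixel_ce)
  }
}

#' Multiclass soft Dice loss
#'
#' `1 - mean_c(2 * sum(p_c y_c) / (sum(p_c) + sum(y_c)))` over the classes,
#' pooled over all supplied pixels. A class absent from both prediction and
#' reference contributes a perfect score.
#'
#' @param probs `[N, C]` matrix (or `[H, W, C]` array) of class
#'   probabilities summing to 1 per pixel.
#' @param reference One-hot reference of the same shape.
#' @return The scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, reference) {
  if (!all(dim(probs) == dim(reference))) stop("shape mismatch")
  C <- dim(probs)[length(dim(probs))]
  p <- matrix(probs, ncol = C)
  y <- matrix(reference, ncol = C)
  terms <- vapply(seq_len(C), function(c) {
    b <- sum(p[, c]) + sum(y[, c])
    if (b == 0) 1 else 2 * sum(p[, c] * y[, c]) / b
  }, 0)
  1 - mean(terms)
}

# ---------------------------------------------------------------------------
# Default backbone: a small fully-convolutional encoder-decoder.
# Encoder: three 3x3 conv + ReLU stages with 2x average pooling between
# them (output stride 8). Decoder: one 3x3 conv with group normalisation
# (groups of size 8) + ReLU, a 1x1 segmentation head, and nearest-neighbour
# upsampling of the class scores back to input resolution.

relu <- function(x) pmax(x, 0)

softmax3 <- function(z) {
  # z: [N, 3]
  m <- pmax(z[, 1], pmax(z[, 2], z[, 3]))
  e <- exp(z - m)
  e / rowSums(e)
}

#' Convert class scores to per-pixel probabilities
#'
#' Softmax over the three class channels; the probabilities sum to 1 at
#' every pixel.
#'
#' @param logits `[H, W, 3]` score array from [network_forward()].
#' @return `[H, W, 3]` probability array.
#' @export
softmax_probs <- function(logits) {
  d <- dim(logits)
  array(softmax3(matrix(logits, ncol = 3)), d)
}

#' Create the default small segmentation backbone
#'
#' A fully-convolutional encoder-decoder honouring the segmentation-network
#' contract: standardised RGB in (H, W divisible by 16), per-pixel scores
#' for {background, non-annotated foreground, tumour} out at input
#' resolution. Encoder convolutions use normal initialisation, decoder and
#' head use uniform initialisation, and the only normalisation layer is
#' group normalisation with groups of size 8. Roughly 18k parameters;
#' output stride 8 internally.
#'
#' @param seed Integer seed for the initialisation draws.
#' @param channels Stage widths: `c(enc1, enc2, enc3, enc4, dec)`.
#' @param group_size Group-normalisation group size (default 8; must divide
#'   the decoder width).
#' @return A `small_segnet` object.
#' @export
small_segnet <- function(seed = 1L, channels = c(8L, 12L, 24L, 32L, 24L),
                         group_size = 8L) {
  if (channels[5] %% group_size != 0) {
    stop("decoder width must be a multiple of the group size")
  }
  mk_conv <- function(cin, cout, kind) {
    w <- array(conv_init(cin, 3, 3, kind, n = 9 * cin * cout),
               c(3, 3, cin, cout))
    b <- if (kind == "encoder") rep(0, cout) else {
      a <- sqrt(3 / (cin * 9))
      runif(cout, -a, a)
    }
    list(w = w, b = b, cin = cin, cout = cout, kind = kind)
  }
  net <- with_seed(seed, {
    ch <- as.integer(channels)
    list(
      enc1 = mk_conv(3L, ch[1], "encoder"),
      enc2 = mk_conv(ch[1], ch[2], "encoder"),
      enc3 = mk_conv(ch[2], ch[3], "encoder"),
      enc4 = mk_conv(ch[3], ch[4], "encoder"),
      dec = mk_conv(ch[4], ch[5], "decoder"),
      gn = list(gamma = rep(1, ch[5]), beta = rep(0, ch[5]),
                group_size = as.integer(group_size), eps = 1e-5),
      head = {
        a <- sqrt(3 / ch[5])
        list(w = matrix(runif(ch[5] * 3, -a, a), ch[5], 3),
             b = runif(3, -a, a))
      }
    )
  })
  net$channels <- as.integer(channels)
  net$norm_layers <- "group_norm"
  class(net) <- "small_segnet"
  net
}

#' Number of adjustable parameters of a network
#'
#' @param net A `small_segnet`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  n <- 0
  for (l in net[c("enc1", "enc2", "enc3", "enc4", "dec")]) {
    n <- n + length(l$w) + length(l$b)
  }
  n + length(net$gn$gamma) + length(net$gn$beta) +
    length(net$head$w) + length(net$head$b)
}

group_norm_fw <- function(x, gn) {
  # x: [H, W, C] as array; returns list(y, cache)
  d <- dim(x)
  C <- d[3]
  xm <- matrix(x, ncol = C)
  ng <- C %/% gn$group_size
  y <- xm
  mu <- numeric(ng); istd <- numeric(ng)
  xhat <- xm
  for (g in seq_len(ng)) {
    idx <- ((g - 1) * gn$group_size + 1):(g * gn$group_size)
    xg <- xm[, idx]
    m <- mean(xg)
    v <- mean((xg - m)^2)
    is <- 1 / sqrt(v + gn$eps)
    xh <- (xg - m) * is
    xhat[, idx] <- xh
    y[, idx] <- sweep(sweep(xh, 2, gn$gamma[idx], `*`), 2, gn$beta[idx], `+`)
    mu[g] <- m; istd[g] <- is
  }
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, dim = d))
}

group_norm_bw <- function(dy, gn, cache) {
  d <- cache$dim
  C <- d[3]
  dym <- matrix(dy, ncol = C)
  xhat <- cache$xhat
  ng <- C %/% gn$group_size
  dx <- dym
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  for (g in seq_len(ng)) {
    idx <- ((g - 1) * gn$group_size + 1):(g * gn$group_size)
    dxh <- sweep(dym[, idx], 2, gn$gamma[idx], `*`)
    xh <- xhat[, idx]
    n <- length(xh)
    dx[, idx] <- cache$istd[g] / n *
      (n * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

conv_fw <- function(x, layer, relu = FALSE) {
  d <- dim(x)
  y <- cpp_conv3_fw(x, layer$w, layer$b, d[1], d[2], layer$cin, layer$cout,
                    relu)
  dim(y) <- c(d[1], d[2], layer$cout)
  y
}

conv_bw <- function(x, layer, dy) {
  d <- dim(x)
  g <- cpp_conv3_bw(x, layer$w, dy, d[1], d[2], layer$cin, layer$cout)
  dx <- g$dx; dim(dx) <- d
  dw <- g$dw; dim(dw) <- dim(layer$w)
  list(dx = dx, dw = dw, db = g$db)
}

pool_fw <- function(x) {
  d <- dim(x)
  y <- cpp_avgpool2_fw(x, d[1], d[2], d[3])
  dim(y) <- c(d[1] / 2, d[2] / 2, d[3])
  y
}

pool_bw <- function(dy, d_in) {
  dx <- cpp_avgpool2_bw(dy, d_in[1], d_in[2], d_in[3])
  dim(dx) <- d_in
  dx
}

#' Forward pass of a segmentation network
#'
#' The segmentation-network contract: input a standardised RGB image with
#' height and width divisible by 16, output per-pixel class scores
#' `[H, W, 3]` at input resolution. Deterministic in evaluation mode.
#' Alternative backbones plug in by implementing this generic.
#'
#' @param net The network object.
#' @param x Standardised `[H, W, 3]` input.
#' @param cache Keep intermediate activations for [network_backward()].
#' @return List with `logits` (`[H, W, 3]`) and, when requested, `cache`.
#' @export
network_forward <- function(net, x, cache = FALSE) UseMethod("network_forward")

#' @export
network_forward.small_segnet <- function(net, x, cache = FALSE) {
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop("input height and width must be divisible by 16 (see pad_to_multiple16)")
  }
  a1 <- conv_fw(x, net$enc1, relu = TRUE)
  p1 <- pool_fw(a1)
  a2 <- conv_fw(p1, net$enc2, relu = TRUE)
  p2 <- pool_fw(a2)
  a3 <- conv_fw(p2, net$enc3, relu = TRUE)
  p3 <- pool_fw(a3)
  a4 <- conv_fw(p3, net$enc4, relu = TRUE)
  z5 <- conv_fw(a4, net$dec)
  gnr <- group_norm_fw(z5, net$gn)
  a5 <- relu(gnr$y)
  d5 <- dim(a5)
  a5m <- matrix(a5, ncol = d5[3])
  zh <- sweep(a5m %*% net$head$w, 2, net$head$b, `+`)
  logits <- cpp_upsample_nearest(zh, d5[1], d5[2], 3L, 8L)
  dim(logits) <- c(d[1], d[2], 3)
  if (!cache) return(list(logits = logits))
  list(logits = logits,
       cache = list(x = x, a1 = a1, p1 = p1, a2 = a2, p2 = p2, a3 = a3,
                    p3 = p3, a4 = a4, z5 = z5, gn = gnr,
                    a5m = a5m, d5 = d5))
}

#' Backward pass of the default backbone
#'
#' @param net A `small_segnet`.
#' @param cache Cache from `network_forward(..., cache = TRUE)`.
#' @param dlogits Gradient of the loss w.r.t. the logits, `[H, W, 3]`.
#' @return Named list of parameter gradients.
#' @export
network_backward <- function(net, cache, dlogits) {
  d5 <- cache$d5
  dzh <- cpp_upsample_nearest_bw(dlogits, d5[1], d5[2], 3L, 8L)
  dzh <- matrix(dzh, ncol = 3)
  dhead_w <- t(cache$a5m) %*% dzh
  dhead_b <- colSums(dzh)
  da5 <- dzh %*% t(net$head$w)
  dim(da5) <- d5
  da5 <- da5 * (cache$gn$y > 0)
  gb <- group_norm_bw(da5, net$gn, cache$gn$cache)
  g5 <- conv_bw(cache$a4, net$dec, gb$dx)
  dz4 <- g5$dx * (cache$a4 > 0)
  g4 <- conv_bw(cache$p3, net$enc4, dz4)
  dz3 <- pool_bw(g4$dx, dim(cache$a3)) * (cache$a3 > 0)
  g3 <- conv_bw(cache$p2, net$enc3, dz3)
  dz2 <- pool_bw(g3$dx, dim(cache$a2)) * (cache$a2 > 0)
  g2 <- conv_bw(cache$p1, net$enc2, dz2)
  dz1 <- pool_bw(g2$dx, dim(cache$a1)) * (cache$a1 > 0)
  g1 <- conv_bw(cache$x, net$enc1, dz1)
  list(enc1 = g1[c("dw", "db")], enc2 = g2[c("dw", "db")],
       enc3 = g3[c("dw", "db")], enc4 = g4[c("dw", "db")],
       dec = g5[c("dw", "db")],
       gn = list(dgamma = gb$dgamma, dbeta = gb$dbeta),
       head = list(dw = dhead_w, db = dhead_b))
}

# Pooled loss and logit gradients over a mini-batch.
# probs: [N, 3], onehot: [N, 3]. Returns l1, l2 and [N, 3] gradient.
batch_loss_grad <- function(probs, onehot) {
  N <- nrow(probs)
  C <- ncol(probs)
  # Dice part, pooled per class over the batch
  A <- colSums(probs * onehot)
  B <- colSums(probs) + colSums(onehot)
  terms <- ifelse(B == 0, 1, 2 * A / B)
  l1 <- 1 - mean(terms)
  gp <- matrix(0, N, C)
  for (c in seq_len(C)) {
    if (B[c] > 0) {
      gp[, c] <- -(2 * onehot[, c] * B[c] - 2 * A[c]) / (C * B[c]^2)
    }
  }
  # chain rule through softmax: dz = p * (g - sum(g * p))
  dz1 <- probs * (gp - rowSums(gp * probs))
  # top-90 cross entropy
  py <- rowSums(probs * onehot)
  ce <- -log(pmax(py, 1e-12))
  k <- floor(0.10 * N)
  if (k > 0) {
    ord <- order(ce)
    kept <- ord[(k + 1):N]
  } else {
    kept <- seq_len(N)
  }
  l2 <- mean(ce[kept])
  dz2 <- matrix(0, N, C)
  dz2[kept, ] <- (probs[kept, , drop = FALSE] - onehot[kept, , drop = FALSE]) /
    length(kept)
  list(l1 = l1, l2 = l2, dz = dz1 + dz2)
}

label_to_onehot <- function(label) {
  H <- nrow(label); W <- ncol(label)
  y <- array(0, c(H, W, 3))
  for (c in 0:2) y[, , c + 1] <- (label == c) * 1
  y
}

#' Train a segmentation network with SGD and Nesterov momentum
#'
#' Mini-batches are drawn randomly without replacement, with the selection
#' reset at each epoch. The loss is the sum of the multiclass soft Dice
#' loss and the top-90 cross entropy, both pooled over all pixels of the
#' mini-batch. Updates use stochastic gradient descent with Nesterov
#' momentum 0.9 and weight decay 2e-5 (biases and normalisation parameters
#' are exempt from decay). The step length follows `schedule`.
#'
#' @param corpus List of tiles, each `list(img = [H,W,3] 0..255, label =
#'   [H,W] in {0,1,2})`, e.g. from [prepare_tiles()].
#' @param net A network created by [small_segnet()] (or any object
#'   implementing the forward/backward contract).
#' @param moments [dataset_moments()] of the training corpus.
#' @param steps Number of optimisation steps.
#' @param batch_size Tiles per step (default 24 in the published setup;
#'   choose smaller for desk-scale runs).
#' @param crop Side of the random crop fed to the network (must be
#'   divisible by 16).
#' @param schedule A [schedule_spec()]; its `total_steps` should equal
#'   `steps`.
#' @param momentum,weight_decay Optimiser constants (defaults 0.9, 2e-5).
#' @param augment Optional distortion hook `function(img, label)` applied
#'   after the random crop, only during optimisation.
#' @param seed Integer seed controlling batch order and crop positions.
#' @return List with `net` (trained network) and `trace` (data frame:
#'   `step`, `lr`, `l1`, `l2`, `loss`).
#' @export
train_network <- function(corpus, net, moments, steps = 500L,
                          batch_size = 8L, crop = 96L,
                          schedule = schedule_spec(total_steps = steps,
                                                   warmup_period = 1L,
                                                   warmup_end = 100L),
                          momentum = 0.9, weight_decay = 2e-5,
                          augment = NULL, seed = 1L) {
  if (length(corpus) == 0) stop("empty corpus")
  if (crop %% 16 != 0) stop("crop must be divisible by 16")
  param_names <- c("enc1", "enc2", "enc3", "enc4", "dec")
  vel <- list()
  trace <- data.frame(step = integer(steps), lr = numeric(steps),
                      l1 = numeric(steps), l2 = numeric(steps),
                      loss = numeric(steps))
  with_seed(seed, {
    perm <- sample(length(corpus))
    pos <- 1L
    for (step in seq_len(steps)) {
      idx <- integer(0)
      while (length(idx) < batch_size) {
        if (pos > length(perm)) { perm <- sample(length(corpus)); pos <- 1L }
        take <- min(batch_size - length(idx), length(perm) - pos + 1L)
        idx <- c(idx, perm[pos:(pos + take - 1L)])
        pos <- pos + take
      }
      caches <- vector("list", batch_size)
      probs_list <- vector("list", batch_size)
      y_list <- vector("list", batch_size)
      for (b in seq_len(batch_size)) {
        t <- corpus[[idx[b]]]
        cr <- random_crop(t$img, t$label, crop)
        if (!is.null(augment)) cr <- augment(cr$img, cr$label)
        x <- standardise_image(cr$img, moments)
        fw <- network_forward(net, x, cache = TRUE)
        caches[[b]] <- fw$cache
        probs_list[[b]] <- softmax3(matrix(fw$logits, ncol = 3))
        y_list[[b]] <- matrix(label_to_onehot(cr$label), ncol = 3)
      }
      probs <- do.call(rbind, probs_list)
      y <- do.call(rbind, y_list)
      lg <- batch_loss_grad(probs, y)
      npx <- crop * crop
      grads <- NULL
      for (b in seq_len(batch_size)) {
        dz <- array(lg$dz[((b - 1) * npx + 1):(b * npx), ], c(crop, crop, 3))
        g <- network_backward(net, caches[[b]], dz)
        grads <- if (is.null(grads)) g else accumulate_grads(grads, g)
      }
      lr <- lr_at_step(step - 1L, schedule)
      net <- sgd_update(net, grads, vel_env = environment(), lr = lr,
                        momentum = momentum, weight_decay = weight_decay)
      trace$step[step] <- step
      trace$lr[step] <- lr
      trace$l1[step] <- lg$l1
      trace$l2[step] <- lg$l2
      trace$loss[step] <- lg$l1 + lg$l2
    }
  })
  list(net = net, trace = trace)
}

accumulate_grads <- function(a, b) {
  for (nm in names(a)) {
    for (p in names(a[[nm]])) a[[nm]][[p]] <- a[[nm]][[p]] + b[[nm]][[p]]
  }
  a
}

# One SGD step with Nesterov momentum (PyTorch formulation):
#   v <- momentum * v + g;  w <- w - lr * (g + momentum * v)
# Velocity state is kept in `vel` within the caller's environment.
sgd_update <- function(net, grads, vel_env, lr, momentum, weight_decay) {
  upd <- function(w, g, key, decay) {
    if (decay > 0) g <- g + decay * w
    v <- vel_env$vel[[key]]
    if (is.null(v)) v <- g else v <- momentum * v + g
    vel_env$vel[[key]] <- v
    w - lr * (g + momentum * v)
  }
  for (nm in c("enc1", "enc2", "enc3", "enc4", "dec")) {
    net[[nm]]$w <- upd(net[[nm]]$w, grads[[nm]]$dw, paste0(nm, ".w"), weight_decay)
    net[[nm]]$b <- upd(net[[nm]]$b, grads[[nm]]$db, paste0(nm, ".b"), 0)
  }
  net$gn$gamma <- upd(net$gn$gamma, grads$gn$dgamma, "gn.gamma", 0)
  net$gn$beta <- upd(net$gn$beta, grads$gn$dbeta, "gn.beta", 0)
  net$head$w <- upd(net$head$w, grads$head$dw, "head.w", weight_decay)
  net$head$b <- upd(net$head$b, grads$head$db, "head.b", 0)
  net
}

#' Steps per epoch for sampling without replacement
#'
#' @param n_tiles Corpus size.
#' @param batch_size Batch size.
#' @return `floor(n_tiles / batch_size)`.
#' @examples
#' steps_per_epoch(2902032, 24) # 120918
#' @export
steps_per_epoch <- function(n_tiles, batch_size) n_tiles %/% batch_size

#' Apply a network to one inference tile
#'
#' Standardises the 8-bit tile, zero-pads to multiples of 16, runs the
#' forward pass, converts scores to probabilities, extracts the tumour
#' channel, multiplies by 255 and quantises to 8 bits (round half to even),
#' and removes the padding.
#'
#' @param net A trained network.
#' @param tile `[H, W, 3]` array of 0..255 values.
#' @param moments The [dataset_moments()] used during training.
#' @return Integer matrix `[H, W]` of tumour scores in 0..255.
#' @export
infer_tile <- function(net, tile, moments) {
  x <- standardise_image(tile, moments)
  pd <- pad_to_multiple16(x)
  fw <- network_forward(net, pd$img)
  p <- softmax3(matrix(fw$logits, ncol = 3))
  prob <- array(p[, 3], dim(pd$img)[1:2])
  prob <- unpad(prob, pd$pad)
  m <- quantise_u8(prob * 255)
  storage.mode(m) <- "integer"
  m
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the network weights, the dataset moments and the
#' training configuration, plus a content hash used to refuse mixed-version
#' inputs downstream.
#'
#' @param net Trained network.
#' @param moments [dataset_moments()].
#' @param config List of training settings (free-form).
#' @param path Destination file.
#' @return `path` invisibly; `load_checkpoint` returns the checkpoint list.
#' @export
save_checkpoint <- function(net, moments, config, path) {
  obj <- list(net = net, moments = moments, config = config)
  obj$hash <- config_hash(obj)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (is.null(obj$net) || is.null(obj$moments)) {
    stop("not a valid checkpoint")
  }
  if (!is.null(obj$hash) && !identical(obj$hash, config_hash(obj))) {
    stop("checkpoint refused: configuration hash mismatch")
  }
  obj
}

config_hash <- function(obj) {
  s <- paste(deparse(obj$config), collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000000007
}
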