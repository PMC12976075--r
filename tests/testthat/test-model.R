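test_that("padding to multiples of 16 is exact and reversible", {
  img <- array(runif(17 * 30 * 3), c(17, 30, 3))
  pd <- pad_to_multiple16(img)
  expect_equal(dim(pd$img)[1:2], c(32, 32))
  expect_equal(unname(pd$pad), c(15L, 2L))
  expect_equal(unpad(pd$img, pd$pad), img)
  # already-divisible sizes are untouched (the 1536 and 7680 setups)
  expect_equal(unname(pad_to_multiple16(array(0, c(1536, 1536, 3)))$pad), c(0L, 0L))
  expect_equal(unname(pad_to_multiple16(array(0, c(7680, 16, 3)))$pad), c(0L, 0L))
})

test_that("initialisation distributions have the prescribed spread", {
  set.seed(77)
  # encoder: Normal with sd sqrt(1/fan_in); fan_in = 4*2*2 = 16 -> sd 0.25
  enc <- conv_init(4, 2, 2, "encoder", n = 1e5)
  expect_equal(sd(enc), 0.25, tolerance = 0.01)
  expect_equal(mean(enc), 0, tolerance = 0.005)
  # decoder: Uniform(-a, a) with a = sqrt(3/fan_in); fan_in = 3 -> a = 1
  dec <- conv_init(3, 1, 1, "decoder", n = 1e5)
  expect_lte(max(abs(dec)), 1)
  expect_equal(sd(dec), 1 / sqrt(3), tolerance = 0.01)
  # fan_in 1 encoder has unit sd
  expect_equal(sd(conv_init(1, 1, 1, "encoder", n = 1e5)), 1, tolerance = 0.01)
  expect_error(conv_init(0, 1, 1, "encoder", n = 10), "fan-in")
})

test_that("top-90 cross entropy drops the lowest decile", {
  expect_equal(top90_cross_entropy(1:10), mean(2:10))
  expect_equal(top90_cross_entropy(rep(3.5, 40)), 3.5)
  expect_equal(top90_cross_entropy(7), 7)   # floor(0.1) = 0 dropped
  expect_error(top90_cross_entropy(numeric(0)), "at least one")
})

test_that("Dice loss matches hand-computed values", {
  onehot <- array(0, c(2, 2, 3))
  onehot[, , 1] <- 1
  expect_equal(dice_loss(onehot, onehot), 0)
  # disjoint one-hot prediction: per-class terms 0 for present classes
  pred <- array(0, c(2, 2, 3)); pred[, , 2] <- 1
  # class 3 absent from both contributes a perfect score
  expect_equal(dice_loss(pred, onehot), 1 - (0 + 0 + 1) / 3)
  # uniform prediction on a single-class reference, 2x2 image:
  # class 1: 2*(4/3)/(4/3+4) = 0.5; classes 2,3: 0
  unif <- array(1 / 3, c(2, 2, 3))
  expect_equal(dice_loss(unif, onehot), 1 - 0.5 / 3)
  expect_error(dice_loss(unif, array(0, c(3, 3, 3))), "mismatch")
})

test_that("the step-length schedule warms up then anneals", {
  sp <- schedule_spec()
  expect_equal(lr_at_step(0, sp), 1e-4)
  expect_equal(lr_at_step(9, sp), 1e-4)       # first increment at step 10
  expect_equal(lr_at_step(10, sp), 2e-4)
  expect_equal(lr_at_step(999, sp), 1e-2)     # plateau just before cosine
  expect_equal(lr_at_step(1000, sp), 1e-2)    # continuity at the handover
  expect_equal(lr_at_step(250500, sp), 5e-3)  # cosine midpoint
  expect_equal(lr_at_step(500000, sp), 0)
  expect_error(lr_at_step(-1, sp), "range")
  expect_error(lr_at_step(500001, sp), "range")
})

test_that("epoch bookkeeping matches the published tile counts", {
  expect_equal(steps_per_epoch(2902032, 24), 120918)
  expect_equal(steps_per_epoch(48, 24), 2)
})

test_that("the default backbone honours the network contract", {
  net <- small_segnet(seed = 3)
  expect_lt(count_parameters(net), 200000)
  expect_identical(net$norm_layers, "group_norm")
  expect_equal(net$gn$group_size, 8L)
  x <- array(rnorm(64 * 48 * 3), c(64, 48, 3))
  fw <- network_forward(net, x)
  expect_equal(dim(fw$logits), c(64, 48, 3))
  p <- softmax_probs(fw$logits)
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 64, 48), tolerance = 1e-12)
  # deterministic in evaluation mode
  expect_identical(network_forward(net, x)$logits, fw$logits)
  expect_error(network_forward(net, array(0, c(30, 32, 3))), "divisible")
})

test_that("analytic gradients match finite differences", {
  set.seed(55)
  net <- small_segnet(seed = 9, channels = c(4L, 4L, 8L, 8L, 8L))
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  label <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
  y <- matrix(slideseg:::label_to_onehot(label), ncol = 3)
  loss_of <- function(n) {
    fw <- network_forward(n, x)
    p <- slideseg:::softmax3(matrix(fw$logits, ncol = 3))
    lg <- slideseg:::batch_loss_grad(p, y)
    lg$l1 + lg$l2
  }
  fw <- network_forward(net, x, cache = TRUE)
  p <- slideseg:::softmax3(matrix(fw$logits, ncol = 3))
  lg <- slideseg:::batch_loss_grad(p, y)
  grads <- network_backward(net, fw$cache, array(lg$dz, c(16, 16, 3)))
  eps <- 1e-6
  check <- function(get, set, ganalytic, k = 4) {
    vals <- get(net)
    idx <- sample(length(vals), min(k, length(vals)))
    for (i in idx) {
      n2 <- set(net, i, vals[i] + eps)
      n3 <- set(net, i, vals[i] - eps)
      gnum <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
      expect_equal(ganalytic[i], gnum, tolerance = 1e-4)
    }
  }
  check(function(n) n$enc1$w,
        function(n, i, v) { n$enc1$w[i] <- v; n },
        as.vector(grads$enc1$dw))
  check(function(n) n$dec$w,
        function(n, i, v) { n$dec$w[i] <- v; n },
        as.vector(grads$dec$dw))
  check(function(n) n$gn$gamma,
        function(n, i, v) { n$gn$gamma[i] <- v; n },
        grads$gn$dgamma)
  check(function(n) n$gn$beta,
        function(n, i, v) { n$gn$beta[i] <- v; n },
        grads$gn$dbeta)
  check(function(n) n$head$w,
        function(n, i, v) { n$head$w[i] <- v; n },
        as.vector(grads$head$dw))
  check(function(n) n$enc3$b,
        function(n, i, v) { n$enc3$b[i] <- v; n },
        grads$enc3$db)
})

test_that("inference quantises probabilities with round-half-even", {
  const_net <- function(p_tumour) {
    structure(list(p = p_tumour), class = "const_net")
  }
  registerS3method("network_forward", "const_net",
                   function(net, x, cache = FALSE) {
                     d <- dim(x)
                     lg <- array(0, c(d[1], d[2], 3))
                     if (net$p == 1) {
                       lg[, , 3] <- 50
                     } else if (net$p == 0) {
                       lg[, , 3] <- -50
                       lg[, , 1] <- 50
                     } else {
                       # softmax((0, -inf, 0)) gives exactly one half
                       lg[, , 2] <- -1e6
                     }
                     list(logits = lg)
                   },
                   envir = asNamespace("slideseg"))
  moments <- structure(list(mu = c(0.5, 0.5, 0.5), sigma = c(0.25, 0.25, 0.25)),
                       class = "dataset_moments")
  tile <- array(128, c(20, 24, 3))
  expect_true(all(infer_tile(const_net(1), tile, moments) == 255L))
  expect_true(all(infer_tile(const_net(0), tile, moments) == 0L))
  # probability one half: 127.5 rounds half-to-even to 128
  expect_true(all(infer_tile(const_net(0.5), tile, moments) == 128L))
  # output geometry equals the (unpadded) tile
  expect_equal(dim(infer_tile(const_net(1), tile, moments)), c(20, 24))
})

test_that("short training runs reduce the loss on a toy corpus", {
  set.seed(123)
  mk_tile <- function() {
    img <- array(200 + rnorm(48 * 48 * 3, 0, 5), c(48, 48, 3))
    label <- matrix(0L, 48, 48)
    cy <- sample(12:36, 1); cx <- sample(12:36, 1)
    for (y in 1:48) for (x in 1:48) {
      if ((y - cy)^2 + (x - cx)^2 < 100) {
        label[y, x] <- 2L
        img[y, x, ] <- c(90, 60, 120) + rnorm(3, 0, 5)
      }
    }
    img <- pmin(pmax(img, 0), 255)
    list(img = img, label = label)
  }
  corpus <- replicate(12, mk_tile(), simplify = FALSE)
  moments <- dataset_moments(lapply(corpus, `[[`, "img"))
  net <- small_segnet(seed = 2, channels = c(4L, 4L, 8L, 8L, 8L))
  res <- train_network(corpus, net, moments, steps = 40L, batch_size = 4L,
                       crop = 32L,
                       schedule = schedule_spec(total_steps = 40L,
                                                warmup_period = 1L,
                                                warmup_end = 10L,
                                                peak = 5e-3),
                       seed = 11L)
  expect_equal(nrow(res$trace), 40L)
  expect_lt(mean(tail(res$trace$loss, 5)), res$trace$loss[1])
  # identical seeds give identical runs
  res2 <- train_network(corpus, net, moments, steps = 5L, batch_size = 4L,
                        crop = 32L,
                        schedule = schedule_spec(total_steps = 5L,
                                                 warmup_period = 1L,
                                                 warmup_end = 3L),
                        seed = 11L)
  res3 <- train_network(corpus, net, moments, steps = 5L, batch_size = 4L,
                        crop = 32L,
                        schedule = schedule_spec(total_steps = 5L,
                                                 warmup_period = 1L,
                                                 warmup_end = 3L),
                        seed = 11L)
  expect_identical(res2$net, res3$net)
  expect_error(train_network(list(), net, moments), "empty")
})

test_that("checkpoints round-trip with their moments and config", {
  net <- small_segnet(seed = 4, channels = c(4L, 4L, 8L, 8L, 8L))
  moments <- structure(list(mu = rep(0.5, 3), sigma = rep(0.2, 3)),
                       class = "dataset_moments")
  p <- tempfile(fileext = ".rds")
  save_checkpoint(net, moments, list(steps = 10), p)
  ck <- load_checkpoint(p)
  expect_identical(ck$net$enc1$w, net$enc1$w)
  expect_equal(ck$moments$mu, moments$mu)
  expect_false(is.null(ck$hash))
})
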