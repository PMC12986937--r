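# Temporal blocks: length preservation, causality, receptive field,
# zero-weight contract and gradient flow.

test_that("temporal blocks preserve temporal length for any geometry", {
  set.seed(21)
  for (k in c(2L, 3L, 5L)) {
    for (dil in c(1L, 2L, 4L)) {
      cfg <- temporal_block_config(3L, 5L, kernel_size = k, dilation = dil,
                                   dropout = 0)
      blk <- temporal_block_init(cfg, seed = k + dil)
      x <- matrix(rnorm(3 * 37), 3, 37)
      y <- temporal_block(x, blk)
      expect_identical(dim(y), c(5L, 37L))
    }
  }
})

test_that("evaluation-mode blocks are causal", {
  # batch norm in training mode couples time points through batch statistics,
  # so causality is a property of the evaluation-mode (running-stats) pass.
  set.seed(22)
  cfg <- temporal_block_config(2L, 4L, kernel_size = 3L, dilation = 2L,
                               dropout = 0)
  blk <- temporal_block_init(cfg, seed = 5)
  x <- matrix(rnorm(2 * 50), 2, 50)
  y0 <- temporal_block(x, blk)
  for (t0 in c(1L, 17L, 42L)) {
    x2 <- x
    x2[1, t0] <- x2[1, t0] + 1
    y2 <- temporal_block(x2, blk)
    changed <- which(colSums(abs(y2 - y0)) > 1e-12)
    expect_true(all(changed >= t0))
  }
})

test_that("a zeroed main path reduces to ReLU of the residual projection", {
  cfg <- temporal_block_config(2L, 3L, kernel_size = 3L, dilation = 1L,
                               use_norm_dropout = FALSE)
  blk <- temporal_block_init(cfg, seed = 6)
  blk$params$conv1$W[] <- 0
  blk$params$conv1$b[] <- 0
  blk$params$conv2$W[] <- 0
  blk$params$conv2$b[] <- 0
  set.seed(23)
  x <- matrix(rnorm(2 * 20), 2, 20)
  y <- temporal_block(x, blk)
  # hand-trace: main path is 0, so y = ReLU(1x1 residual projection of x)
  proj <- matrix(blk$params$down$W, 3, 2) %*% x + blk$params$down$b
  expect_equal(y, pmax(proj, 0))
})

test_that("the time encoder's receptive field is exactly 1 + 2(k-1)(1+2+4)", {
  set.seed(24)
  k <- 3L
  enc <- tcn_stack(1L, c(3L, 3L, 3L), kernel_size = k, dropout = 0,
                   use_norm_dropout = FALSE, seed = 9)
  rf <- tcn_receptive_field(enc)
  expect_identical(rf, 1L + 2L * (k - 1L) * 7L)
  # make every weight positive and the input positive so ReLU gates stay
  # open and the extreme filter taps provably transmit the perturbation
  for (i in seq_along(enc$blocks)) {
    for (nm in names(enc$blocks[[i]]$params)) {
      enc$blocks[[i]]$params[[nm]]$W <- abs(enc$blocks[[i]]$params[[nm]]$W)
      enc$blocks[[i]]$params[[nm]]$b[] <- 0
    }
  }
  T <- 80L
  x <- matrix(abs(rnorm(T)) + 0.1, 1, T)
  y0 <- tcn_forward(enc, x)
  t0 <- 40L
  x2 <- x
  x2[1, t0] <- x2[1, t0] + 1
  changed <- which(colSums(abs(tcn_forward(enc, x2) - y0)) != 0)
  # oracle: perturbation sweep; causal influence spans [t0, t0 + rf - 1]
  expect_identical(min(changed), t0)
  expect_identical(max(changed), t0 + rf - 1L)
})

test_that("stacks preserve length and evaluation passes are bit-identical", {
  set.seed(25)
  enc <- tcn_stack(2L, c(4L, 6L, 8L), seed = 3)
  x <- array(rnorm(2 * 33 * 2), c(2, 33, 2))
  y1 <- tcn_forward(enc, x)
  y2 <- tcn_forward(enc, x)
  expect_identical(dim(y1), c(8L, 33L, 2L))
  expect_identical(y1, y2)
})

test_that("channel mismatches are rejected", {
  blk <- temporal_block_init(temporal_block_config(3L, 4L), seed = 1)
  expect_error(temporal_block(matrix(0, 2, 10), blk), "channel mismatch")
})

test_that("block gradients match finite differences (with and without norm)", {
  set.seed(26)
  for (nd in c(FALSE, TRUE)) {
    cfg <- temporal_block_config(2L, 3L, kernel_size = 3L, dilation = 2L,
                                 dropout = 0, use_norm_dropout = nd)
    blk <- temporal_block_init(cfg, seed = 11)
    x <- array(rnorm(2 * 15 * 2), c(2, 15, 2))
    R <- array(rnorm(3 * 15 * 2), c(3, 15, 2))
    fw <- stae:::block_forward(blk, x, training = nd, keep = TRUE)
    bw <- stae:::block_backward(blk, R, fw$cache, training = nd)
    h <- 1e-5
    leaves <- list(c("conv1", "W"), c("conv2", "b"), c("down", "W"))
    if (nd) leaves <- c(leaves, list(c("bn1", "gamma"), c("bn2", "beta")))
    for (path in leaves) {
      ana <- bw$grads[[path[1]]][[path[2]]]
      for (i in sample(length(ana), min(4, length(ana)))) {
        b2 <- blk
        b2$params[[path[1]]][[path[2]]][i] <-
          b2$params[[path[1]]][[path[2]]][i] + h
        lp <- sum(stae:::block_forward(b2, x, training = nd)$y * R)
        b2$params[[path[1]]][[path[2]]][i] <-
          b2$params[[path[1]]][[path[2]]][i] - 2 * h
        lm <- sum(stae:::block_forward(b2, x, training = nd)$y * R)
        num <- (lp - lm) / (2 * h)
        expect_lt(abs(num - ana[i]) / max(1e-5, abs(num), abs(ana[i])),
                  1e-4, label = paste(path, collapse = "/"))
      }
    }
  }
})
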