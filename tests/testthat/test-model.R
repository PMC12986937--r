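# STAE assembly: fusion alignment, forward contracts, parameter count and
# end-to-end gradient flow.

test_that("fuse_features concatenates channels after frame alignment", {
  temporal <- matrix(rnorm(12 * 2), 12, 2)
  spectral <- matrix(rnorm(3 * 3), 3, 3)
  fused <- fuse_features(temporal, spectral, hop = 4L)
  expect_identical(dim(fused), c(12L, 5L))
  expect_identical(fused[, 1:2], temporal)
  # oracle: sample t (1-based) maps to frame floor((t-1)/hop)+1, clipped
  for (t in 1:12) {
    f <- min((t - 1) %/% 4 + 1, 3)
    expect_equal(fused[t, 3:5], spectral[f, ])
  }
  # frames == T with hop 1: alignment is the identity
  sp2 <- matrix(rnorm(12 * 3), 12, 3)
  expect_identical(fuse_features(temporal, sp2, hop = 1L)[, 3:5], sp2)
  expect_error(fuse_features(matrix(0, 0, 2), spectral, 4L), "temporal")
})

test_that("alignment index arithmetic matches direct computation on a grid", {
  for (T in c(5L, 16L, 33L)) {
    for (hop in c(1L, 3L, 8L)) {
      nfr <- max(1L, T %/% hop)
      idx <- stae:::frame_index(T, hop, nfr)
      want <- pmin((seq_len(T) - 1L) %/% hop + 1L, nfr)
      expect_identical(idx, want)
    }
  }
})

test_that("forward output shapes equal the input shape for x_hat and sigma", {
  cfg <- tiny_stae_config()
  model <- stae_init(cfg, seed = 2, quiet = TRUE)
  rec <- ecg_record(matrix(rnorm(2 * 40), 2, 40), 250)
  out <- stae_forward(model, rec)
  expect_s3_class(out, "reconstruction_output")
  expect_identical(dim(out$x_hat), dim(rec$samples))
  expect_identical(dim(out$sigma), dim(rec$samples))
  expect_true(all(is.finite(out$x_hat)))
  expect_true(all(is.finite(out$sigma)))
})

test_that("evaluation-mode forwards are bit-identical across calls", {
  cfg <- tiny_stae_config()
  model <- stae_init(cfg, seed = 3, quiet = TRUE)
  rec <- ecg_record(matrix(rnorm(2 * 48), 2, 48), 250)
  o1 <- stae_forward(model, rec)
  o2 <- stae_forward(model, rec)
  expect_identical(o1, o2)
})

test_that("lead and width misconfigurations are rejected at construction", {
  expect_error(stae_config(enc1d_widths = c(8L, 8L)), "3 blocks")
  expect_error(stae_config(enc2d_widths = c(8L, 8L, 8L)), "4 blocks")
  expect_error(stae_config(n_leads = 1L, enc1d_widths = c(8L, 8L, 9L),
                           heads = 2L),
               "model_dim")  # fused width 9 + 128 not divisible by heads
  model <- stae_init(tiny_stae_config(), seed = 1, quiet = TRUE)
  expect_error(stae_forward(model, ecg_record(matrix(0, 3, 40), 250)),
               "lead mismatch")
})

test_that("default full-size configuration lands in the documented
           parameter bracket", {
  model <- stae_init(stae_config(), seed = 1, quiet = TRUE)
  n <- stae_parameter_count(model)
  expect_gte(n, 1.0e6)
  expect_lte(n, 2.0e6)
})

test_that("a scalar loss produces finite, non-degenerate gradients for
           every parameter group", {
  cfg <- tiny_stae_config()
  model <- stae_init(cfg, seed = 5, quiet = TRUE)
  set.seed(41)
  x <- array(rnorm(2 * 40 * 2), c(2, 40, 2))
  spec_in <- stae:::spec_branch_input(x, 250, cfg$stft)
  fw <- stae:::stae_forward_batch(model, x, spec_in, training = TRUE,
                                  keep = TRUE)
  gl <- stae:::reconstruction_loss_grads(fw$x_hat, fw$sigma, x)
  grads <- stae:::stae_backward_batch(fw$model, fw$cache, gl$d_xhat,
                                      gl$d_sigma, training = TRUE)
  for (grp in c("enc1d", "enc2d", "attn", "mlp", "dec", "head")) {
    leaves <- stae:::tree_leaves(grads[[grp]])
    expect_true(all(vapply(leaves, function(g) all(is.finite(g)),
                           logical(1))), label = paste(grp, "finite"))
    expect_true(any(vapply(leaves, function(g) any(g != 0), logical(1))),
                label = paste(grp, "nonzero"))
  }
})

test_that("model-level gradients match finite differences", {
  # dense-mask attention geometry (block >= T) so differencing is not
  # polluted by large mask constants; dropout 0 and masking applied outside.
  cfg <- tiny_stae_config(block_size = 64L, stride = 1L)
  model <- stae_init(cfg, seed = 6, quiet = TRUE)
  set.seed(42)
  x <- array(rnorm(2 * 24 * 1), c(2, 24, 1))
  target <- array(rnorm(2 * 24 * 1), c(2, 24, 1))
  spec_in <- stae:::spec_branch_input(x, 250, cfg$stft)
  fw <- stae:::stae_forward_batch(model, x, spec_in, training = TRUE,
                                  keep = TRUE)
  gl <- stae:::reconstruction_loss_grads(fw$x_hat, fw$sigma, target)
  grads <- stae:::stae_backward_batch(fw$model, fw$cache, gl$d_xhat,
                                      gl$d_sigma, training = TRUE)
  params <- stae:::model_params(fw$model)
  loss_at <- function(p) {
    m2 <- stae:::model_set_params(model, p)
    f2 <- stae:::stae_forward_batch(m2, x, spec_in, training = TRUE)
    reconstruction_loss(f2$x_hat, f2$sigma, target)
  }
  h <- 1e-5
  paths <- list(list("enc1d", 1, "conv1", "W"),
                list("enc2d", 2, "bn1", "gamma"),
                list("attn", "Wv"), list("mlp", "W2"),
                list("dec", 1, "down", "W"), list("head", "W"))
  for (path in paths) {
    leaf_p <- params; leaf_g <- grads
    for (pp in path) {
      leaf_p <- leaf_p[[pp]]
      leaf_g <- leaf_g[[pp]]
    }
    for (i in sample(length(leaf_p), 2)) {
      bump <- function(delta) {
        p2 <- params
        # in-place nested assignment
        expr <- sprintf("p2[[%s]][%d] <- p2[[%s]][%d] + delta",
                        paste(sapply(path, function(z)
                          if (is.character(z)) sprintf("'%s'", z) else z),
                          collapse = "]][["), i,
                        paste(sapply(path, function(z)
                          if (is.character(z)) sprintf("'%s'", z) else z),
                          collapse = "]][["), i)
        eval(parse(text = expr))
        p2
      }
      num <- (loss_at(bump(h)) - loss_at(bump(-h))) / (2 * h)
      expect_lt(abs(num - leaf_g[i]) / max(1e-5, abs(num), abs(leaf_g[i])),
                5e-3, label = paste(paste(path, collapse = "/"), i))
    }
  }
})

test_that("with masking off and dropout 0, training and evaluation passes
           agree once running statistics converge", {
  # the only train/eval difference left is batch-norm statistics; running
  # estimates converge to the batch statistics exponentially (momentum 0.1),
  # up to the m/(m-1) unbiased-variance factor, hence the loose tolerance.
  cfg <- tiny_stae_config()
  model <- stae_init(cfg, seed = 7, quiet = TRUE)
  set.seed(43)
  x <- array(rnorm(2 * 40 * 4), c(2, 40, 4))
  spec_in <- stae:::spec_branch_input(x, 250, cfg$stft)
  for (i in 1:150) {
    fw <- stae:::stae_forward_batch(model, x, spec_in, training = TRUE)
    model <- fw$model
  }
  tr <- stae:::stae_forward_batch(model, x, spec_in, training = TRUE)
  ev <- stae:::stae_forward_batch(model, x, spec_in, training = FALSE)
  expect_equal(ev$x_hat, tr$x_hat, tolerance = 0.02)
  expect_equal(ev$sigma, tr$sigma, tolerance = 0.02)
})

test_that("the time-only variant drops the spectrogram branch", {
  cfg <- tiny_stae_config(branches = "time_only")
  model <- stae_init(cfg, seed = 8, quiet = TRUE)
  expect_null(model$enc2d)
  expect_identical(cfg$attention$model_dim, 4L)  # enc1d top width only
  rec <- ecg_record(matrix(rnorm(2 * 40), 2, 40), 250)
  out <- stae_forward(model, rec)
  expect_identical(dim(out$x_hat), dim(rec$samples))
})
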