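# Strided block attention: mask construction, the full mechanism, ablation
# variants and interaction accounting.

test_that("the vectorized mask equals the triple-loop transcription", {
  for (T in c(1L, 3L, 7L, 12L, 17L)) {
    for (B in 1:6) {
      for (S in 1:B) {
        expect_identical(build_strided_block_mask(T, B, S),
                         loop_mask(T, B, S),
                         info = sprintf("T=%d B=%d S=%d", T, B, S))
      }
    }
  }
})

test_that("mask examples: single position, block-diagonal, strided block", {
  expect_identical(build_strided_block_mask(1L, 3L, 2L), matrix(1, 1, 1))
  M <- build_strided_block_mask(4L, 2L, 1L)
  expect_identical(M, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                            c(0, 0, 1, 1), c(0, 0, 1, 1)))
  M2 <- build_strided_block_mask(6L, 6L, 2L)
  want <- matrix(0, 6, 6)
  want[c(1, 3, 5), c(1, 3, 5)] <- 1  # 0-based {0,2,4} x {0,2,4}
  expect_identical(M2, want)
})

test_that("the mask is symmetric for random geometries", {
  set.seed(12)
  for (i in 1:30) {
    T <- sample(1:40, 1)
    B <- sample(1:10, 1)
    S <- sample(1:B, 1)
    M <- build_strided_block_mask(T, B, S)
    expect_identical(M, t(M))
  }
})

test_that("effective interaction counts equal the mask popcount", {
  expect_identical(count_effective_interactions(8L, 4L, 2L), 8)
  expect_identical(count_effective_interactions(10L, 4L, 2L), 9)
  for (T in c(16L, 64L)) # dense case: S = 1, B = T
    expect_identical(count_effective_interactions(T, T, 1L), T^2)
  set.seed(13)
  for (i in 1:50) {
    T <- sample(1:50, 1)
    B <- sample(1:12, 1)
    S <- sample(1:B, 1)
    expect_identical(count_effective_interactions(T, B, S),
                     sum(loop_mask(T, B, S)),
                     info = sprintf("T=%d B=%d S=%d", T, B, S))
  }
  # closed form when S | B and B | T
  expect_identical(count_effective_interactions(24L, 8L, 4L), 3 * 2^2)
})

test_that("invalid mask and attention arguments are rejected", {
  expect_error(build_strided_block_mask(0L, 2L, 1L), "T")
  expect_error(build_strided_block_mask(4L, 2L, 3L), "S")
  expect_error(attention_config(heads = 3L, model_dim = 8L), "model_dim")
  expect_error(attention_config(mask_fill = -10), "mask_fill")
  cfg <- attention_config(heads = 2L, model_dim = 8L)
  X <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  expect_error(strided_block_attention(X, X, X, cfg), "model_dim")
})

test_that("with an all-ones mask the mechanism reduces to dense attention", {
  set.seed(14)
  for (H in c(1L, 2L, 4L)) {
    D <- 8L * H
    cfg <- attention_config(heads = H, model_dim = D, block_size = 64L,
                            stride = 1L, variant = "strided_block",
                            use_global_term = FALSE)
    params <- stae:::attention_init(cfg, seed = H)
    X <- array(rnorm(2 * 16 * D), c(2, 16, D))
    Y <- strided_block_attention(X, X, X, cfg, params = params)
    for (n in 1:2) {
      Yd <- dense_attention_oracle(matrix(X[n, , ], 16, D), params, H)
      expect_lt(max(abs(Y[n, , ] - Yd)), 1e-5)
    }
  }
})

test_that("block variant with B = T reduces to the standard variant", {
  set.seed(15)
  D <- 12L
  X <- array(rnorm(1 * 10 * D), c(1, 10, D))
  p <- stae:::attention_init(attention_config(heads = 2L, model_dim = D),
                             seed = 4)
  yb <- attention_variant(X, X, X,
                          attention_config(heads = 2L, model_dim = D,
                                           block_size = 10L, stride = 1L,
                                           variant = "block"), params = p)
  ys <- attention_variant(X, X, X,
                          attention_config(heads = 2L, model_dim = D,
                                           variant = "standard"), params = p)
  expect_lt(max(abs(yb - ys)), 1e-5)
})

test_that("all variants preserve shape and give unit probability rows", {
  set.seed(16)
  D <- 8L
  X <- array(rnorm(2 * 13 * D), c(2, 13, D))  # 13: partial final block
  for (v in c("standard", "block", "strided", "strided_block")) {
    cfg <- attention_config(heads = 2L, model_dim = D, block_size = 4L,
                            stride = 2L, variant = v)
    out <- strided_block_attention(X, X, X, cfg, return_trace = TRUE)
    expect_identical(dim(out$Y), dim(X))
    expect_true(all(is.finite(out$Y)))
    for (P in out$trace$P)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-5)
  }
})

test_that("the verbatim global term averages the filled logits per key", {
  set.seed(17)
  D <- 4L
  cfg <- attention_config(heads = 1L, model_dim = D, block_size = 3L,
                          stride = 2L, variant = "strided_block")
  X <- array(rnorm(1 * 7 * D), c(1, 7, D))
  out <- strided_block_attention(X, X, X, cfg, return_trace = TRUE)
  tr <- out$trace
  expect_equal(tr$G[[1]], colMeans(tr$A[[1]]))
  expect_equal(tr$At[[1]],
               sweep(tr$A[[1]], 2, colMeans(tr$A[[1]]), `+`))
})

test_that("permuting the batch permutes outputs identically", {
  set.seed(18)
  D <- 8L
  X <- array(rnorm(4 * 9 * D), c(4, 9, D))
  cfg <- attention_config(heads = 2L, model_dim = D, block_size = 4L,
                          stride = 2L)
  p <- stae:::attention_init(cfg, seed = 1)
  Y <- strided_block_attention(X, X, X, cfg, params = p)
  perm <- c(3L, 1L, 4L, 2L)
  Yp <- strided_block_attention(X[perm, , ], X[perm, , ], X[perm, , ],
                                cfg, params = p)
  expect_equal(Yp, Y[perm, , ])
})

test_that("the operation is deterministic with dropout 0", {
  set.seed(19)
  D <- 8L
  X <- array(rnorm(2 * 11 * D), c(2, 11, D))
  cfg <- attention_config(heads = 2L, model_dim = D, block_size = 4L,
                          stride = 2L)
  p <- stae:::attention_init(cfg, seed = 2)
  expect_identical(strided_block_attention(X, X, X, cfg, params = p),
                   strided_block_attention(X, X, X, cfg, params = p))
})

test_that("attention gradients match central finite differences", {
  # mask_fill is lowered to -1e6-1 here: differencing through logits holding
  # a -1e9 additive constant loses ~7 digits to rounding before the gradient
  # signal appears, while the analytic gradient is fill-invariant.
  set.seed(20)
  T <- 10L; D <- 8L
  cfg <- attention_config(heads = 2L, model_dim = D, block_size = 4L,
                          stride = 2L, variant = "strided_block",
                          mask_fill = -1e6 - 1)
  p <- stae:::attention_init(cfg, seed = 2)
  X <- matrix(rnorm(T * D), T, D)
  R <- matrix(rnorm(T * D), T, D)  # loss = sum(Y * R)
  M <- stae:::variant_mask(cfg, T)
  fw <- stae:::attn_forward_one(X, X, X, p, cfg, M, keep = TRUE)
  bb <- stae:::attn_backward_one(R, fw, p, cfg, X, X, X)
  h <- 1e-4
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    ana <- bb[[paste0("d", nm)]]
    for (i in sample(length(p[[nm]]), 5)) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + h
      lp <- sum(stae:::attn_forward_one(X, X, X, p2, cfg, M)$Y * R)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      lm <- sum(stae:::attn_forward_one(X, X, X, p2, cfg, M)$Y * R)
      num <- (lp - lm) / (2 * h)
      expect_lt(abs(num - ana[i]) / max(1e-4, abs(num), abs(ana[i])), 1e-3,
                label = sprintf("%s[%d] rel err", nm, i))
    }
  }
  # input gradient, all three roles fused
  dX <- bb$dXq + bb$dXk + bb$dXv
  for (i in sample(length(X), 6)) {
    X2 <- X
    X2[i] <- X2[i] + h
    lp <- sum(stae:::attn_forward_one(X2, X2, X2, p, cfg, M)$Y * R)
    X2[i] <- X2[i] - 2 * h
    lm <- sum(stae:::attn_forward_one(X2, X2, X2, p, cfg, M)$Y * R)
    num <- (lp - lm) / (2 * h)
    expect_lt(abs(num - dX[i]) / max(1e-4, abs(num), abs(dX[i])), 1e-3)
  }
})
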