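# Strided block attention with global mean-logit fusion, its ablation
# variants, and effective-interaction accounting.
#
# The sequence is partitioned into blocks of size B; inside each block only
# positions sampled every S steps interact. All other query-key logits are
# filled with a large negative constant. A global context term G -- the mean
# of the masked logits over the query dimension -- is added back to every
# logit before the row softmax, letting information flow across blocks at
# linear cost.

#' Attention configuration
#'
#' @param heads Number of attention heads H; must divide `model_dim`.
#' @param model_dim Model width D; head width is `D / H`.
#' @param block_size Block size B.
#' @param stride Stride S within a block, `1 <= S <= B`.
#' @param dropout Dropout rate on attention probabilities (training only).
#' @param mask_fill Large negative fill for suppressed logits (default -1e9;
#'   finite so downstream arithmetic never produces NaN).
#' @param variant One of `"strided_block"` (full mechanism), `"standard"`
#'   (dense, no mask, no global term), `"block"` (intra-block dense),
#'   `"strided"` (global stride, one block).
#' @param global_logits_over_valid_only If `TRUE`, the global term averages
#'   only unmasked logits instead of the verbatim mean over all (filled)
#'   logits. Default `FALSE` (verbatim).
#' @param use_global_term Apply the global mean-logit fusion in the
#'   `"strided_block"` variant? Default `TRUE`; turning it off reduces the
#'   mechanism to plain masked attention (used e.g. to verify equivalence
#'   with dense attention when the mask is all ones).
#' @return An `attention_config` list with `head_dim` precomputed.
#' @export
attention_config <- function(heads = 2L, model_dim = 32L, block_size = 64L,
                             stride = 8L, dropout = 0,
                             mask_fill = -1e9,
                             variant = c("strided_block", "standard",
                                         "block", "strided"),
                             global_logits_over_valid_only = FALSE,
                             use_global_term = TRUE) {
  check_count(heads, "heads")
  check_count(model_dim, "model_dim")
  if (model_dim %% heads != 0)
    abort_field("model_dim", "must be divisible by heads")
  check_count(block_size, "block_size")
  check_count(stride, "stride")
  if (stride > block_size)
    abort_field("stride", "must be <= block_size")
  check_number(dropout, "dropout", lower = 0)
  if (dropout >= 1) abort_field("dropout", "must be < 1")
  check_number(mask_fill, "mask_fill", upper = -1e6)
  variant <- match.arg(variant)
  structure(list(heads = as.integer(heads), model_dim = as.integer(model_dim),
                 head_dim = as.integer(model_dim %/% heads),
                 block_size = as.integer(block_size),
                 stride = as.integer(stride), dropout = dropout,
                 mask_fill = mask_fill, variant = variant,
                 global_logits_over_valid_only =
                   isTRUE(global_logits_over_valid_only),
                 use_global_term = isTRUE(use_global_term)),
            class = "attention_config")
}

#' Build the strided-block attention mask
#'
#' `M[i, j] = 1` iff positions `i` and `j` (0-based in the definition) lie in
#' the same block `[s, min(s + B, T))` with `s = b * B`, and both
#' `(i - s) mod S = 0` and `(j - s) mod S = 0`.
#'
#' @param T Sequence length.
#' @param B Block size.
#' @param S Stride, `1 <= S <= B`.
#' @return Binary `[T x T]` matrix (symmetric).
#' @export
build_strided_block_mask <- function(T, B, S) {
  check_count(T, "T")
  check_count(B, "B")
  check_count(S, "S")
  if (S > B) abort_field("S", "must be <= B")
  M <- matrix(0, T, T)
  n_b <- ceiling(T / B)
  for (b in seq_len(n_b) - 1L) {
    s <- b * B
    e <- min(s + B, T)
    on <- s + seq(0L, e - s - 1L, by = S)  # 0-based strided positions
    M[on + 1L, on + 1L] <- 1
  }
  M
}

#' Count effective attention interactions
#'
#' Exact number of unmasked query-key pairs of the strided-block mask:
#' `sum over blocks of ceil(len_b / S)^2`, where `len_b` is each block's
#' length. Scales as `O(T * (B/S)^2)`; when `S | B` and `B | T` it equals
#' `(T/B) * (B/S)^2` exactly, versus `T^2` for dense attention.
#'
#' @inheritParams build_strided_block_mask
#' @return Integer pair count.
#' @export
count_effective_interactions <- function(T, B, S) {
  check_count(T, "T")
  check_count(B, "B")
  check_count(S, "S")
  if (S > B) abort_field("S", "must be <= B")
  n_b <- ceiling(T / B)
  lens <- rep(B, n_b)
  if (T %% B != 0) lens[n_b] <- T %% B
  sum(ceiling(lens / S)^2)
}

# Numerically stable row softmax of a matrix.
row_softmax <- function(A) {
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  E / rowSums(E)
}

# Initialize attention projection weights W_Q, W_K, W_V, W_O ([D x D], no
# bias), uniform in +/- 1/sqrt(D) (standard linear-layer initialization).
attention_init <- function(cfg, seed = 1L) {
  D <- cfg$model_dim
  with_seed(seed, {
    lim <- 1 / sqrt(D)
    list(Wq = matrix(runif(D * D, -lim, lim), D, D),
         Wk = matrix(runif(D * D, -lim, lim), D, D),
         Wv = matrix(runif(D * D, -lim, lim), D, D),
         Wo = matrix(runif(D * D, -lim, lim), D, D))
  })
}

# Mask for a given variant ("standard" returns NULL = dense).
variant_mask <- function(cfg, T) {
  switch(cfg$variant,
         standard = NULL,
         block = build_strided_block_mask(T, cfg$block_size, 1L),
         strided = build_strided_block_mask(T, T, cfg$stride),
         strided_block = build_strided_block_mask(T, cfg$block_size,
                                                  cfg$stride))
}

# Core single-record forward. x_q/x_k/x_v: [T x D]. Returns Y and, when
# keep = TRUE, the per-head intermediates needed for backward/trace.
attn_forward_one <- function(x_q, x_k, x_v, params, cfg, M,
                             training = FALSE, dropmask = NULL,
                             keep = FALSE) {
  T <- nrow(x_q); D <- cfg$model_dim; H <- cfg$heads; dh <- cfg$head_dim
  q <- x_q %*% params$Wq
  k <- x_k %*% params$Wk
  v <- x_v %*% params$Wv
  Zc <- matrix(0, T, D)
  hs <- if (keep) vector("list", H) else NULL
  use_global <- cfg$variant == "strided_block" && cfg$use_global_term
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) /
      sqrt(dh)
    if (!is.null(M)) A <- A + cfg$mask_fill * (1 - M)
    G <- NULL
    if (use_global) {
      G <- if (cfg$global_logits_over_valid_only && !is.null(M)) {
        cs <- colSums(M)
        ifelse(cs > 0, colSums(A * M) / pmax(cs, 1), 0)
      } else colMeans(A)
      At <- sweep(A, 2L, G, `+`)
    } else At <- A
    P <- row_softmax(At)
    Pd <- P
    if (training && cfg$dropout > 0) {
      dm <- if (!is.null(dropmask)) dropmask[[h]] else
        matrix((runif(T * T) >= cfg$dropout) / (1 - cfg$dropout), T, T)
      Pd <- P * dm
      if (keep) hs[[h]]$dropmask <- dm
    }
    Zc[, cols] <- Pd %*% v[, cols, drop = FALSE]
    if (keep) {
      hs[[h]]$A <- A; hs[[h]]$G <- G; hs[[h]]$At <- At; hs[[h]]$P <- P
      hs[[h]]$Pd <- Pd
    }
  }
  Y <- Zc %*% params$Wo
  if (keep) list(Y = Y, q = q, k = k, v = v, Zc = Zc, heads = hs, M = M)
  else list(Y = Y)
}

# Backward for one record given cache from attn_forward_one(keep = TRUE).
# x_q/x_k/x_v are the corresponding forward inputs. Returns gradients w.r.t.
# the inputs and the four projections.
attn_backward_one <- function(dY, cache, params, cfg, x_q, x_k, x_v) {
  T <- nrow(dY); D <- cfg$model_dim; H <- cfg$heads; dh <- cfg$head_dim
  dWo <- crossprod(cache$Zc, dY)
  dZc <- tcrossprod(dY, params$Wo)
  dq <- matrix(0, T, D); dk <- matrix(0, T, D); dv <- matrix(0, T, D)
  use_global <- cfg$variant == "strided_block" && cfg$use_global_term
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    hc <- cache$heads[[h]]
    dZh <- dZc[, cols, drop = FALSE]
    dPd <- tcrossprod(dZh, cache$v[, cols, drop = FALSE])
    dv[, cols] <- crossprod(hc$Pd, dZh)
    dP <- if (!is.null(hc$dropmask)) dPd * hc$dropmask else dPd
    # softmax backward (row-wise)
    dAt <- hc$P * (dP - rowSums(dP * hc$P))
    dA <- dAt
    if (use_global) {
      gcol <- colSums(dAt)
      if (cfg$global_logits_over_valid_only && !is.null(cache$M)) {
        cs <- colSums(cache$M)
        add <- sweep(cache$M, 2L, ifelse(cs > 0, gcol / pmax(cs, 1), 0), `*`)
        dA <- dA + add
      } else {
        dA <- dA + matrix(gcol / T, T, T, byrow = TRUE)
      }
    }
    dA <- dA / sqrt(dh)
    dq[, cols] <- dA %*% cache$k[, cols, drop = FALSE]
    dk[, cols] <- crossprod(dA, cache$q[, cols, drop = FALSE])
  }
  list(dXq = tcrossprod(dq, params$Wq),
       dXk = tcrossprod(dk, params$Wk),
       dXv = tcrossprod(dv, params$Wv),
       dWq = crossprod(x_q, dq),
       dWk = crossprod(x_k, dk),
       dWv = crossprod(x_v, dv),
       dWo = dWo)
}

#' Strided block attention with global mean-logit fusion
#'
#' Multi-head scaled dot-product attention restricted by the strided-block
#' mask, with the mean of the masked logits over the query dimension added to
#' every logit before the softmax. Exactly the published procedure: head
#' projections, `A = Q K' / sqrt(d)`, masked fill with `mask_fill`,
#' `G = mean_query(A)`, `A~ = A + G`, row softmax over keys, dropout when
#' training, head merge and output projection.
#'
#' @param Q_in,K_in,V_in Arrays `[N x T x D]` (a `[T x D]` matrix is treated
#'   as `N = 1`).
#' @param cfg An [attention_config] (the `variant` field selects the
#'   ablation; see [attention_variant()]).
#' @param params Projection weights from `attention_init()`; freshly
#'   initialized (seed 1) when omitted.
#' @param training Apply dropout?
#' @param return_trace Also return per-head intermediates (mask `M`, logits
#'   `A`, global term `G`, fused logits `At`, probabilities `P`, output `Y`)
#'   for the first record?
#' @return Array `[N x T x D]`, or a list `(Y, trace)` when `return_trace`.
#' @export
strided_block_attention <- function(Q_in, K_in, V_in = K_in, cfg,
                                    params = NULL, training = FALSE,
                                    return_trace = FALSE) {
  stopifnot(inherits(cfg, "attention_config"))
  as3d <- function(x) {
    if (is.matrix(x)) array(x, c(1L, nrow(x), ncol(x))) else x
  }
  Q_in <- as3d(Q_in); K_in <- as3d(K_in); V_in <- as3d(V_in)
  if (length(dim(Q_in)) != 3L)
    stop("Q_in must be [N x T x D]", call. = FALSE)
  dq <- dim(Q_in)
  if (!identical(dq, dim(K_in)) || !identical(dq, dim(V_in)))
    stop(sprintf("shape mismatch: Q %s vs K %s vs V %s",
                 paste(dq, collapse = "x"),
                 paste(dim(K_in), collapse = "x"),
                 paste(dim(V_in), collapse = "x")), call. = FALSE)
  N <- dq[1]; T <- dq[2]; D <- dq[3]
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  if (D != cfg$model_dim)
    stop(sprintf("model_dim mismatch: expected %d, got %d",
                 cfg$model_dim, D), call. = FALSE)
  if (is.null(params)) params <- attention_init(cfg, seed = 1L)
  M <- variant_mask(cfg, T)
  Y <- array(0, dq)
  trace <- NULL
  for (n in seq_len(N)) {
    keep <- return_trace && n == 1L
    res <- attn_forward_one(matrix(Q_in[n, , ], T, D),
                            matrix(K_in[n, , ], T, D),
                            matrix(V_in[n, , ], T, D),
                            params, cfg, M, training = training, keep = keep)
    Y[n, , ] <- res$Y
    if (keep)
      trace <- list(M = if (is.null(M)) matrix(1, T, T) else M,
                    A = lapply(res$heads, `[[`, "A"),
                    G = lapply(res$heads, `[[`, "G"),
                    At = lapply(res$heads, `[[`, "At"),
                    P = lapply(res$heads, `[[`, "P"),
                    Y = res$Y)
  }
  if (return_trace) list(Y = Y, trace = trace) else Y
}

#' Ablation attention variants
#'
#' Dispatches on `cfg$variant`: `"standard"` is dense softmax attention (no
#' mask, no global term); `"block"` masks with the given block size and
#' stride 1 (intra-block dense); `"strided"` masks with one block of size `T`
#' and the given stride; `"strided_block"` is the full mechanism including
#' global mean-logit fusion. The global term is applied only in
#' `"strided_block"`.
#'
#' @inheritParams strided_block_attention
#' @return Array `[N x T x D]`.
#' @export
attention_variant <- function(Q_in, K_in, V_in = K_in, cfg, params = NULL,
                              training = FALSE) {
  strided_block_attention(Q_in, K_in, V_in, cfg, params, training)
}
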