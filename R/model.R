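# STAE assembly: masked dual-domain inputs -> dual TCN encoders -> feature
# concatenation -> sparse cross-fusion attention -> MLP -> TCN decoder
# emitting the reconstruction and a per-timepoint log-variance.

#' STAE model configuration
#'
#' Defaults correspond to the full-size model (12 leads at 500 Hz): encoder
#' widths (32, 64, 128) and (32, 64, 64, 128), kernel 3, dropout 0.1,
#' 4 attention heads over the concatenated width 256, MLP expansion factor 2.
#' The spectrogram encoder runs over the frame axis with frequency bins and
#' leads folded into input channels. `branches = "time_only"` removes the
#' spectrogram branch (purely temporal ablation).
#'
#' @param n_leads Number of ECG leads the model consumes.
#' @param enc1d_widths Three channel widths for the time-domain encoder.
#' @param enc2d_widths Four channel widths for the spectrogram encoder.
#' @param dec_widths Decoder channel widths (default mirrors `enc1d_widths`
#'   reversed).
#' @param kernel_size Convolution kernel size for every temporal block.
#' @param dropout Dropout rate in the encoders.
#' @param heads Attention heads; must divide the fused width.
#' @param block_size,stride Attention block size B and stride S.
#' @param attn_variant Attention variant (see [attention_config()]).
#' @param use_global_term Apply global mean-logit fusion (strided_block only).
#' @param attn_residual Add the fused sequence back to the attention output
#'   (residual connection) before the MLP? Default `FALSE`: the attention
#'   output alone feeds the MLP, so the fused sequence is re-expressed
#'   entirely through (sparse) attention context. The residual option is
#'   provided for experimentation; it eases exact reconstruction but
#'   weakens the context bottleneck that reconstruction-based anomaly
#'   scoring relies on.
#' @param mlp_hidden Hidden width of the two-layer MLP after attention;
#'   default twice the fused width.
#' @param mask A [mask_config()] used during training.
#' @param stft A [stft_params()] for the spectrogram branch.
#' @param branches `"dual"` (default) or `"time_only"`.
#' @return An `stae_config` list.
#' @export
stae_config <- function(n_leads = 12L,
                        enc1d_widths = c(32L, 64L, 128L),
                        enc2d_widths = c(32L, 64L, 64L, 128L),
                        dec_widths = rev(enc1d_widths),
                        kernel_size = 3L, dropout = 0.1,
                        heads = 4L, block_size = 64L, stride = 8L,
                        attn_variant = "strided_block",
                        use_global_term = TRUE,
                        attn_residual = FALSE,
                        mlp_hidden = NULL,
                        mask = mask_config(),
                        stft = stft_params(),
                        branches = c("dual", "time_only")) {
  check_count(n_leads, "n_leads")
  if (length(enc1d_widths) != 3L)
    abort_field("enc1d_widths", "the time-domain encoder has exactly 3 blocks")
  if (length(enc2d_widths) != 4L)
    abort_field("enc2d_widths", "the spectrogram encoder has exactly 4 blocks")
  branches <- match.arg(branches)
  c_t <- enc1d_widths[3]
  c_s <- if (branches == "dual") enc2d_widths[4] else 0L
  model_dim <- as.integer(c_t + c_s)
  if (is.null(mlp_hidden)) mlp_hidden <- 2L * model_dim
  check_count(mlp_hidden, "mlp_hidden")
  attention <- attention_config(heads = heads, model_dim = model_dim,
                                block_size = block_size, stride = stride,
                                dropout = 0, variant = attn_variant,
                                use_global_term = use_global_term)
  stopifnot(inherits(mask, "mask_config"), inherits(stft, "stft_params"))
  structure(list(n_leads = as.integer(n_leads),
                 enc1d_widths = as.integer(enc1d_widths),
                 enc2d_widths = as.integer(enc2d_widths),
                 dec_widths = as.integer(dec_widths),
                 kernel_size = as.integer(kernel_size), dropout = dropout,
                 attention = attention,
                 attn_residual = isTRUE(attn_residual),
                 mlp_hidden = as.integer(mlp_hidden),
                 mask = mask, stft = stft, branches = branches),
            class = "stae_config")
}

#' Initialize an STAE model
#'
#' Builds both encoders, the attention projections, the MLP and the decoder
#' (no batch norm/dropout) with a 1x1 output head producing two channels per
#' lead: the reconstruction and the log-variance. The total trainable
#' parameter count is reported via [stae_parameter_count()] and printed at
#' construction.
#'
#' @param cfg An [stae_config()].
#' @param seed Integer seed for all weight draws.
#' @param quiet Suppress the construction message?
#' @return An `stae_model`.
#' @export
stae_init <- function(cfg, seed = 1L, quiet = FALSE) {
  stopifnot(inherits(cfg, "stae_config"))
  n_bins <- cfg$stft$fft_size %/% 2L + 1L
  enc2d_in <- cfg$n_leads * n_bins
  model <- structure(list(cfg = cfg), class = "stae_model")
  model$enc1d <- tcn_stack(cfg$n_leads, cfg$enc1d_widths, cfg$kernel_size,
                           cfg$dropout, use_norm_dropout = TRUE,
                           seed = derive_seed(seed, "enc1d"))
  if (cfg$branches == "dual")
    model$enc2d <- tcn_stack(enc2d_in, cfg$enc2d_widths, cfg$kernel_size,
                             cfg$dropout, use_norm_dropout = TRUE,
                             seed = derive_seed(seed, "enc2d"))
  D <- cfg$attention$model_dim
  model$attn <- attention_init(cfg$attention, derive_seed(seed, "attn"))
  model$mlp <- with_seed(derive_seed(seed, "mlp"), {
    l1 <- init_linear(D, cfg$mlp_hidden)
    l2 <- init_linear(cfg$mlp_hidden, D)
    list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
  })
  model$dec <- tcn_stack(D, cfg$dec_widths, cfg$kernel_size, dropout = 0,
                         use_norm_dropout = FALSE,
                         seed = derive_seed(seed, "dec"))
  model$head <- with_seed(derive_seed(seed, "head"),
                          init_conv(2L * cfg$n_leads,
                                    cfg$dec_widths[length(cfg$dec_widths)],
                                    1L))
  if (!quiet)
    message(sprintf("stae model (%s): %s trainable parameters",
                    cfg$branches,
                    format(stae_parameter_count(model), big.mark = ",")))
  model
}

#' @export
print.stae_model <- function(x, ...) {
  cat(sprintf("<stae_model> %s, %d lead(s), fused width %d, %s parameters\n",
              x$cfg$branches, x$cfg$n_leads, x$cfg$attention$model_dim,
              format(stae_parameter_count(x), big.mark = ",")))
  invisible(x)
}

# --- parameter tree plumbing ----------------------------------------------

model_params <- function(model) {
  p <- list(enc1d = lapply(model$enc1d$blocks, `[[`, "params"),
            attn = model$attn, mlp = model$mlp,
            dec = lapply(model$dec$blocks, `[[`, "params"),
            head = model$head)
  if (!is.null(model$enc2d))
    p$enc2d <- lapply(model$enc2d$blocks, `[[`, "params")
  p
}

model_set_params <- function(model, p) {
  for (i in seq_along(model$enc1d$blocks))
    model$enc1d$blocks[[i]]$params <- p$enc1d[[i]]
  if (!is.null(model$enc2d))
    for (i in seq_along(model$enc2d$blocks))
      model$enc2d$blocks[[i]]$params <- p$enc2d[[i]]
  model$attn <- p$attn
  model$mlp <- p$mlp
  for (i in seq_along(model$dec$blocks))
    model$dec$blocks[[i]]$params <- p$dec[[i]]
  model$head <- p$head
  model
}

# Flatten a nested numeric-leaf list (depth-first, name order as stored).
tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), recursive = FALSE,
                         use.names = FALSE)
  else list(x)
}

#' Total trainable parameter count
#'
#' Exhaustive enumeration over every weight array of the model (batch-norm
#' running statistics are state, not parameters, and are excluded).
#'
#' @param model An [stae_init()] model.
#' @return Integer parameter count.
#' @export
stae_parameter_count <- function(model) {
  stopifnot(inherits(model, "stae_model"))
  sum(vapply(tree_leaves(model_params(model)), length, integer(1)))
}

# --- fusion ----------------------------------------------------------------

# Frame covering sample t (1-based): floor((t - 1)/hop) + 1, clipped.
frame_index <- function(T, hop, n_frames) {
  pmin((seq_len(T) - 1L) %/% hop + 1L, n_frames)
}

#' Fuse temporal and spectral feature sequences
#'
#' The spectral frame sequence is aligned to the temporal length by
#' nearest-frame repetition -- sample `t` takes the frame covering it,
#' `floor(t / hop)` (0-based) clipped to the last frame -- then the two
#' feature sets are concatenated channel-wise.
#'
#' @param temporal Matrix `[T x C_t]`.
#' @param spectral Matrix `[frames x C_s]`.
#' @param hop STFT hop used to produce the frames.
#' @return Fused matrix `[T x (C_t + C_s)]`.
#' @export
fuse_features <- function(temporal, spectral, hop) {
  if (!is.matrix(temporal) || nrow(temporal) < 1L)
    abort_field("temporal", "must be a nonempty [T x C_t] matrix")
  if (!is.matrix(spectral) || nrow(spectral) < 1L)
    abort_field("spectral", "must be a nonempty [frames x C_s] matrix")
  check_count(hop, "hop")
  idx <- frame_index(nrow(temporal), hop, nrow(spectral))
  cbind(temporal, spectral[idx, , drop = FALSE])
}

# --- batched forward / backward -------------------------------------------

# Build the spectrogram-branch input [leads*bins x frames x N] from a
# [leads x T x N] (already masked) signal array.
spec_branch_input <- function(x, fs, stftp, maskcfg = NULL) {
  d <- dim(x); L <- d[1]; T <- d[2]; N <- d[3]
  nfr <- stft_n_frames(T, stftp)
  nb <- stftp$fft_size %/% 2L + 1L
  out <- array(0, c(L * nb, nfr, N))
  for (n in seq_len(N)) {
    rec <- ecg_record(matrix(x[, , n], L, T), fs, record_id = "tmp")
    sp <- stft(rec, stftp)
    if (!is.null(maskcfg)) sp <- mask_spectrogram(sp, maskcfg)$masked
    out[, , n] <- matrix(aperm(sp$magnitude, c(2L, 1L, 3L)), L * nb, nfr)
  }
  out
}

# Full training/eval forward over a batch. x / x_masked: [leads x T x N];
# spec_in: [leads*bins x frames x N] or NULL (time_only). Returns outputs
# plus caches when keep = TRUE; running BN statistics advance when training.
stae_forward_batch <- function(model, x_masked, spec_in, training = FALSE,
                               keep = FALSE) {
  cfg <- model$cfg
  d <- dim(x_masked); L <- d[1]; T <- d[2]; N <- d[3]
  D <- cfg$attention$model_dim
  c_t <- cfg$enc1d_widths[3]
  r1 <- stack_forward(model$enc1d, x_masked, training = training, keep = keep)
  model$enc1d <- r1$stack
  fused <- array(0, c(D, T, N))
  fused[seq_len(c_t), , ] <- r1$y
  idx <- NULL
  if (cfg$branches == "dual") {
    r2 <- stack_forward(model$enc2d, spec_in, training = training,
                        keep = keep)
    model$enc2d <- r2$stack
    nfr <- dim(spec_in)[2]
    idx <- frame_index(T, cfg$stft$hop, nfr)
    fused[(c_t + 1L):D, , ] <- r2$y[, idx, , drop = FALSE]
  }
  M <- variant_mask(cfg$attention, T)
  attn_caches <- if (keep) vector("list", N) else NULL
  mlp_caches <- if (keep) vector("list", N) else NULL
  dec_in <- array(0, c(D, T, N))
  for (n in seq_len(N)) {
    xseq <- t(matrix(fused[, , n], D, T))
    ra <- attn_forward_one(xseq, xseq, xseq, model$attn, cfg$attention, M,
                           training = training, keep = keep)
    if (cfg$attn_residual) ra$Y <- ra$Y + xseq
    h1pre <- ra$Y %*% model$mlp$W1 +
      matrix(model$mlp$b1, T, cfg$mlp_hidden, byrow = TRUE)
    h1 <- relu_forward(h1pre)
    z <- h1 %*% model$mlp$W2 +
      matrix(model$mlp$b2, T, D, byrow = TRUE)
    dec_in[, , n] <- t(z)
    if (keep) {
      attn_caches[[n]] <- c(ra, list(xseq = xseq))
      mlp_caches[[n]] <- list(Y = ra$Y, h1pre = h1pre, h1 = h1)
    }
  }
  rd <- stack_forward(model$dec, dec_in, training = training, keep = keep)
  model$dec <- rd$stack
  out <- conv1d_forward(rd$y, model$head$W, model$head$b, 1L)
  x_hat <- out[seq_len(L), , , drop = FALSE]
  sigma <- out[L + seq_len(L), , , drop = FALSE]
  res <- list(x_hat = x_hat, sigma = sigma, model = model)
  if (keep)
    res$cache <- list(enc1d = r1$caches,
                      enc2d = if (cfg$branches == "dual") r2$caches,
                      enc2d_y = if (cfg$branches == "dual") r2$y,
                      idx = idx, fused = fused, attn = attn_caches,
                      mlp = mlp_caches, dec = rd$caches, dec_y = rd$y,
                      dims = d)
  res
}

# Backward from gradients on (x_hat, sigma); returns a gradient tree
# mirroring model_params(model).
stae_backward_batch <- function(model, cache, d_xhat, d_sigma,
                                training = TRUE) {
  cfg <- model$cfg
  d <- cache$dims; L <- d[1]; T <- d[2]; N <- d[3]
  D <- cfg$attention$model_dim
  c_t <- cfg$enc1d_widths[3]
  dout <- array(0, c(2L * L, T, N))
  dout[seq_len(L), , ] <- d_xhat
  dout[L + seq_len(L), , ] <- d_sigma
  hb <- conv1d_backward(dout, cache$dec_y, model$head$W, 1L)
  g_head <- list(W = hb$dW, b = hb$db)
  rd <- stack_backward(model$dec, hb$dx, cache$dec, training = training)
  g_dec <- rd$grads
  dZ <- rd$dx  # [D x T x N]
  g_attn <- list(Wq = 0, Wk = 0, Wv = 0, Wo = 0)
  g_mlp <- list(W1 = 0, b1 = 0, W2 = 0, b2 = 0)
  dfused <- array(0, c(D, T, N))
  for (n in seq_len(N)) {
    dz <- t(matrix(dZ[, , n], D, T))  # [T x D]
    mc <- cache$mlp[[n]]
    g_mlp$W2 <- g_mlp$W2 + crossprod(mc$h1, dz)
    g_mlp$b2 <- g_mlp$b2 + colSums(dz)
    dh1 <- relu_backward(tcrossprod(dz, model$mlp$W2), mc$h1pre)
    g_mlp$W1 <- g_mlp$W1 + crossprod(mc$Y, dh1)
    g_mlp$b1 <- g_mlp$b1 + colSums(dh1)
    dY <- tcrossprod(dh1, model$mlp$W1)
    ac <- cache$attn[[n]]
    ab <- attn_backward_one(dY, ac, model$attn, cfg$attention,
                            ac$xseq, ac$xseq, ac$xseq)
    g_attn$Wq <- g_attn$Wq + ab$dWq
    g_attn$Wk <- g_attn$Wk + ab$dWk
    g_attn$Wv <- g_attn$Wv + ab$dWv
    g_attn$Wo <- g_attn$Wo + ab$dWo
    dxseq <- ab$dXq + ab$dXk + ab$dXv
    if (cfg$attn_residual) dxseq <- dxseq + dY
    dfused[, , n] <- t(dxseq)
  }
  r1 <- stack_backward(model$enc1d,
                       dfused[seq_len(c_t), , , drop = FALSE],
                       cache$enc1d, training = training)
  grads <- list(enc1d = r1$grads, attn = g_attn, mlp = g_mlp,
                dec = g_dec, head = g_head)
  if (cfg$branches == "dual") {
    dal <- dfused[(c_t + 1L):D, , , drop = FALSE]
    nfr <- dim(cache$enc2d_y)[2]
    dsp <- array(0, dim(cache$enc2d_y))
    for (f in seq_len(nfr)) {
      cols <- which(cache$idx == f)
      if (length(cols))
        dsp[, f, ] <- apply(dal[, cols, , drop = FALSE], c(1, 3), sum)
    }
    r2 <- stack_backward(model$enc2d, dsp, cache$enc2d, training = training)
    grads$enc2d <- r2$grads
  }
  grads
}

#' Reconstruct an ECG record with an STAE model
#'
#' Evaluation-mode forward pass (no masking, no dropout, batch-norm running
#' statistics): produces the reconstruction and the per-timepoint
#' log-variance. When `training = TRUE`, random patch masking from
#' `model$cfg$mask` is applied to both domains first (as during training) and
#' batch statistics are used.
#'
#' @param model An [stae_init()] model.
#' @param record A preprocessed (normalized) [ecg_record].
#' @param training Training-mode flag.
#' @return A `reconstruction_output` list with `x_hat` and `sigma`, both
#'   `[leads x T]`.
#' @export
stae_forward <- function(model, record, training = FALSE) {
  stopifnot(inherits(model, "stae_model"), inherits(record, "ecg_record"))
  cfg <- model$cfg
  if (nrow(record$samples) != cfg$n_leads)
    stop(sprintf("lead mismatch: model expects %d, record has %d",
                 cfg$n_leads, nrow(record$samples)), call. = FALSE)
  x <- record
  if (training) x <- mask_time(record, cfg$mask)$masked
  xa <- array(x$samples, c(dim(x$samples), 1L))
  # when training, the spectral branch sees the spectrogram of the masked
  # signal, masked again in its own domain (as in the training loop)
  spec_in <- if (cfg$branches == "dual")
    spec_branch_input(xa, record$sampling_rate, cfg$stft,
                      maskcfg = if (training) cfg$mask else NULL)
  r <- stae_forward_batch(model, xa, spec_in, training = training)
  structure(list(x_hat = matrix(r$x_hat[, , 1L], cfg$n_leads),
                 sigma = matrix(r$sigma[, , 1L], cfg$n_leads)),
            class = "reconstruction_output")
}
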