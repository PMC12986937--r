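# Temporal blocks (dilated causal convolution units) and their stacks.
#
# A temporal block applies two dilated causal convolutions, each realized as
# left padding + convolution (equivalent to convolution followed by a chomp
# of the (k-1)*dilation trailing samples, so temporal length is preserved),
# each followed optionally by batch normalization and dropout, with ReLU
# activations, and a residual connection (1x1 projection when the channel
# counts differ) followed by a final ReLU.
#
# The time-domain encoder stacks three blocks (dilations 1, 2, 4), the
# spectrogram encoder four (1, 2, 4, 8) over the frame axis with frequency
# bins folded into channels, and the decoder mirrors the time encoder's depth
# without batch normalization or dropout.

#' Temporal block configuration
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel_size Convolution kernel size (default 3).
#' @param dilation Dilation factor (default 1).
#' @param dropout Dropout rate (used only when `use_norm_dropout`).
#' @param use_norm_dropout Include batch normalization and dropout (encoders
#'   `TRUE`, decoder `FALSE`)?
#' @return A `temporal_block_config` list.
#' @export
temporal_block_config <- function(in_channels, out_channels, kernel_size = 3L,
                                  dilation = 1L, dropout = 0.1,
                                  use_norm_dropout = TRUE) {
  check_count(in_channels, "in_channels")
  check_count(out_channels, "out_channels")
  check_count(kernel_size, "kernel_size")
  check_count(dilation, "dilation")
  check_number(dropout, "dropout", lower = 0)
  if (dropout >= 1) abort_field("dropout", "must be < 1")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 dilation = as.integer(dilation), dropout = dropout,
                 use_norm_dropout = isTRUE(use_norm_dropout)),
            class = "temporal_block_config")
}

#' Initialize a temporal block
#'
#' @param cfg A [temporal_block_config].
#' @param seed Integer seed for the weight draws.
#' @return A `temporal_block` list holding `cfg`, trainable `params` and
#'   batch-norm running statistics in `buffers`.
#' @export
temporal_block_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "temporal_block_config"))
  with_seed(seed, {
    params <- list(conv1 = init_conv(cfg$out_channels, cfg$in_channels,
                                     cfg$kernel_size),
                   conv2 = init_conv(cfg$out_channels, cfg$out_channels,
                                     cfg$kernel_size))
    if (cfg$use_norm_dropout) {
      params$bn1 <- list(gamma = rep(1, cfg$out_channels),
                         beta = rep(0, cfg$out_channels))
      params$bn2 <- list(gamma = rep(1, cfg$out_channels),
                         beta = rep(0, cfg$out_channels))
    }
    if (cfg$in_channels != cfg$out_channels)
      params$down <- init_conv(cfg$out_channels, cfg$in_channels, 1L)
    buffers <- if (cfg$use_norm_dropout)
      list(bn1 = list(run_mean = rep(0, cfg$out_channels),
                      run_var = rep(1, cfg$out_channels)),
           bn2 = list(run_mean = rep(0, cfg$out_channels),
                      run_var = rep(1, cfg$out_channels)))
    else list()
    structure(list(cfg = cfg, params = params, buffers = buffers),
              class = "temporal_block")
  })
}

# Internal forward. x [Cin x T x N]. Returns y, cache (when keep) and
# updated block (running stats advance in training mode).
block_forward <- function(block, x, training = FALSE, keep = FALSE) {
  cfg <- block$cfg; p <- block$params
  nd <- cfg$use_norm_dropout
  cache <- list(x = x)
  h <- conv1d_forward(x, p$conv1$W, p$conv1$b, cfg$dilation)
  if (keep) cache$c1 <- h
  if (nd) {
    bn <- bn_forward(h, p$bn1$gamma, p$bn1$beta, block$buffers$bn1, training)
    block$buffers$bn1 <- bn$state
    if (keep) cache$bn1 <- bn
    h <- bn$y
  }
  if (keep) cache$a1 <- h
  h <- relu_forward(h)
  if (nd && training && cfg$dropout > 0) {
    m1 <- dropout_mask(dim(h), cfg$dropout)
    h <- h * m1
    if (keep) cache$m1 <- m1
  }
  if (keep) cache$h1 <- h
  h2 <- conv1d_forward(h, p$conv2$W, p$conv2$b, cfg$dilation)
  if (keep) cache$c2 <- h2
  if (nd) {
    bn <- bn_forward(h2, p$bn2$gamma, p$bn2$beta, block$buffers$bn2, training)
    block$buffers$bn2 <- bn$state
    if (keep) cache$bn2 <- bn
    h2 <- bn$y
  }
  if (keep) cache$a2 <- h2
  h2 <- relu_forward(h2)
  if (nd && training && cfg$dropout > 0) {
    m2 <- dropout_mask(dim(h2), cfg$dropout)
    h2 <- h2 * m2
    if (keep) cache$m2 <- m2
  }
  res <- if (!is.null(p$down))
    conv1d_forward(x, p$down$W, p$down$b, 1L) else x
  s <- h2 + res
  if (keep) cache$s <- s
  y <- relu_forward(s)
  list(y = y, cache = if (keep) cache else NULL, block = block)
}

# Internal backward. Returns dx and a gradient list mirroring params.
block_backward <- function(block, dy, cache, training = FALSE) {
  cfg <- block$cfg; p <- block$params
  nd <- cfg$use_norm_dropout
  g <- list()
  ds <- relu_backward(dy, cache$s)
  # residual branch
  if (!is.null(p$down)) {
    cb <- conv1d_backward(ds, cache$x, p$down$W, 1L)
    g$down <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  } else dx <- ds
  # main branch, stage 2
  dh2 <- ds
  if (nd && training && cfg$dropout > 0) dh2 <- dh2 * cache$m2
  da2 <- relu_backward(dh2, cache$a2)
  if (nd) {
    bb <- bn_backward(da2, cache$bn2, p$bn2$gamma, training)
    g$bn2 <- list(gamma = bb$dgamma, beta = bb$dbeta)
    da2 <- bb$dx
  }
  cb <- conv1d_backward(da2, cache$h1, p$conv2$W, cfg$dilation)
  g$conv2 <- list(W = cb$dW, b = cb$db)
  dh1 <- cb$dx
  # stage 1
  if (nd && training && cfg$dropout > 0) dh1 <- dh1 * cache$m1
  da1 <- relu_backward(dh1, cache$a1)
  if (nd) {
    bb <- bn_backward(da1, cache$bn1, p$bn1$gamma, training)
    g$bn1 <- list(gamma = bb$dgamma, beta = bb$dbeta)
    da1 <- bb$dx
  }
  cb <- conv1d_backward(da1, cache$x, p$conv1$W, cfg$dilation)
  g$conv1 <- list(W = cb$dW, b = cb$db)
  dx <- dx + cb$dx
  list(dx = dx, grads = g)
}

#' Apply a temporal block
#'
#' @param x Numeric matrix `[channels x T]` (one record) or array
#'   `[channels x T x N]`.
#' @param block A [temporal_block_init()] block.
#' @param training Use batch statistics and dropout (`TRUE`) or running
#'   statistics with dropout disabled (`FALSE`)?
#' @return Output with the same temporal length, `[out_channels x T (x N)]`.
#' @export
temporal_block <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "temporal_block"))
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L || dim(x)[1] != block$cfg$in_channels)
    stop(sprintf("channel mismatch: block expects %d, got %d",
                 block$cfg$in_channels, dim(x)[1]), call. = FALSE)
  y <- block_forward(block, x, training = training)$y
  if (was_mat) matrix(y, dim(y)[1], dim(y)[2]) else y
}

#' Build a TCN encoder or decoder stack
#'
#' Stacks temporal blocks with dilations doubling per block (1, 2, 4, ...).
#'
#' @param in_channels Input channel count.
#' @param widths Output channel widths, one per block (three blocks for the
#'   time-domain encoder, four for the spectrogram encoder).
#' @param kernel_size Kernel size shared by all blocks.
#' @param dropout Dropout rate (ignored when `use_norm_dropout = FALSE`).
#' @param use_norm_dropout Batch norm + dropout in each block?
#' @param seed Integer seed.
#' @return A `tcn_stack` list of temporal blocks.
#' @export
tcn_stack <- function(in_channels, widths, kernel_size = 3L, dropout = 0.1,
                      use_norm_dropout = TRUE, seed = 1L) {
  blocks <- vector("list", length(widths))
  cin <- in_channels
  for (i in seq_along(widths)) {
    cfg <- temporal_block_config(cin, widths[i], kernel_size,
                                 dilation = 2L^(i - 1L), dropout = dropout,
                                 use_norm_dropout = use_norm_dropout)
    blocks[[i]] <- temporal_block_init(cfg, derive_seed(seed,
                                                        paste0("block", i)))
    cin <- widths[i]
  }
  structure(list(blocks = blocks, in_channels = as.integer(in_channels),
                 out_channels = as.integer(widths[length(widths)])),
            class = "tcn_stack")
}

# Internal stack forward/backward with caches.
stack_forward <- function(stack, x, training = FALSE, keep = FALSE) {
  caches <- if (keep) vector("list", length(stack$blocks)) else NULL
  for (i in seq_along(stack$blocks)) {
    r <- block_forward(stack$blocks[[i]], x, training = training, keep = keep)
    x <- r$y
    stack$blocks[[i]] <- r$block
    if (keep) caches[[i]] <- r$cache
  }
  list(y = x, caches = caches, stack = stack)
}

stack_backward <- function(stack, dy, caches, training = FALSE) {
  grads <- vector("list", length(stack$blocks))
  for (i in rev(seq_along(stack$blocks))) {
    r <- block_backward(stack$blocks[[i]], dy, caches[[i]],
                        training = training)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

#' Run a TCN stack over a signal
#'
#' @param stack A [tcn_stack()].
#' @param x Matrix `[channels x T]` or array `[channels x T x N]`.
#' @param training Training mode flag.
#' @return Features `[out_channels x T (x N)]`; temporal length preserved.
#' @export
tcn_forward <- function(stack, x, training = FALSE) {
  stopifnot(inherits(stack, "tcn_stack"))
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1L))
  y <- stack_forward(stack, x, training = training)$y
  if (was_mat) matrix(y, dim(y)[1], dim(y)[2]) else y
}

#' Receptive field of a TCN stack
#'
#' With kernel size `k` and dilations `d_1..d_n`, each block contributes two
#' convolutions of span `(k-1)*d_i`, so the receptive field is
#' `1 + 2*(k-1)*sum(d_i)` samples.
#'
#' @param stack A [tcn_stack()].
#' @return Integer receptive field in samples.
#' @export
tcn_receptive_field <- function(stack) {
  k <- stack$blocks[[1]]$cfg$kernel_size
  dil <- vapply(stack$blocks, function(b) b$cfg$dilation, integer(1))
  as.integer(1L + 2L * (k - 1L) * sum(dil))
}
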