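# Uncertainty-weighted reconstruction loss and the unsupervised training
# loop (AdamW) on normal records only.

#' Training configuration
#'
#' Defaults are the published full-training settings: 50 epochs, batch size
#' 32, AdamW with initial learning rate 5e-5 and weight decay 1e-4. Small
#' synthetic experiments override them (see the methods vignette).
#'
#' @param epochs Number of epochs.
#' @param batch_size Batch size (a batch larger than the dataset simply
#'   yields one batch per epoch).
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param seed Integer seed covering parameter initialization, shuffling,
#'   masking and dropout.
#' @param device Informational device tag (this implementation is CPU-only).
#' @param masked_loss_only Restrict the loss to masked time points? Default
#'   `FALSE`: the loss is taken over the whole signal.
#' @param checkpoint_every Write a checkpoint every this many epochs
#'   (0 = never).
#' @param checkpoint_dir Directory for checkpoints.
#' @param verbose Print per-epoch loss?
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L,
                         learning_rate = 5e-5, weight_decay = 1e-4,
                         seed = 1L, device = "cpu",
                         masked_loss_only = FALSE,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         verbose = FALSE) {
  check_count(epochs, "epochs")
  check_count(batch_size, "batch_size")
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(weight_decay, "weight_decay", lower = 0)
  check_number(seed, "seed")
  check_count(checkpoint_every, "checkpoint_every", lower = 0L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 device = device,
                 masked_loss_only = isTRUE(masked_loss_only),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Uncertainty-weighted reconstruction loss
#'
#' `mean(exp(-sigma) * (x_hat - x)^2 + sigma)` over all elements: the
#' exponential weighting rewards accurate reconstruction where the model is
#' confident, while the additive `sigma` term penalizes inflating the
#' predicted variance (for a fixed squared error `e0`, the minimizing
#' log-variance is `log(e0)`).
#'
#' @param x_hat Reconstruction, same shape as `x`.
#' @param sigma Log-variance, same shape as `x`.
#' @param x Target signal.
#' @param weights Optional nonnegative elementwise weights (e.g. a mask
#'   indicator); the loss becomes a weighted mean.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x_hat, sigma, x, weights = NULL) {
  if (!identical(dim(x_hat) %||% length(x_hat), dim(x) %||% length(x)) ||
      !identical(dim(sigma) %||% length(sigma), dim(x) %||% length(x)))
    stop(sprintf("shape mismatch: x_hat %s, sigma %s, x %s",
                 paste(dim(x_hat) %||% length(x_hat), collapse = "x"),
                 paste(dim(sigma) %||% length(sigma), collapse = "x"),
                 paste(dim(x) %||% length(x), collapse = "x")),
         call. = FALSE)
  el <- exp(-sigma) * (x_hat - x)^2 + sigma
  if (is.null(weights)) mean(el)
  else sum(weights * el) / max(sum(weights), .Machine$double.eps)
}

# Gradients of reconstruction_loss w.r.t. x_hat and sigma.
reconstruction_loss_grads <- function(x_hat, sigma, x, weights = NULL) {
  if (is.null(weights)) {
    M <- length(x)
    w <- 1 / M
  } else {
    w <- weights / max(sum(weights), .Machine$double.eps)
  }
  e <- exp(-sigma)
  diff <- x_hat - x
  list(d_xhat = 2 * w * e * diff,
       d_sigma = w * (1 - e * diff^2))
}

# --- AdamW over nested parameter trees ------------------------------------

tree_zeros <- function(x) {
  if (is.list(x)) lapply(x, tree_zeros) else x * 0
}

adamw_update <- function(p, g, m, v, lr, wd, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    keys <- if (!is.null(names(p)) && all(nzchar(names(p))))
      names(p) else seq_along(p)
    for (nm in keys) {
      r <- adamw_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, wd, t,
                        beta1, beta2, eps)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  p <- p - lr * wd * p - lr * mhat / (sqrt(vhat) + eps)
  list(p = p, m = m, v = v)
}

#' Train an STAE model on normal records
#'
#' Unsupervised masked-reconstruction training: every batch is masked in the
#' time domain (fresh random patches each step), its spectrogram is computed
#' from the masked signal and masked again, and the uncertainty-weighted
#' loss between the reconstruction and the *unmasked* original is minimized
#' with AdamW. Records labeled `"abnormal"` are rejected: the unsupervised
#' contract is training on normals only.
#'
#' @param records List of preprocessed [ecg_record]s (labels `"normal"` or
#'   `"unknown"`).
#' @param model_cfg An [stae_config()].
#' @param cfg A [train_config()].
#' @return List with `model` (trained), `history` (per-epoch mean loss) and
#'   the two configs. Deterministic given the seed.
#' @export
train_stae <- function(records, model_cfg, cfg = train_config()) {
  stopifnot(inherits(model_cfg, "stae_config"), inherits(cfg, "train_config"))
  if (!length(records)) stop("empty training set", call. = FALSE)
  labs <- vapply(records, `[[`, character(1), "label")
  if (any(labs == "abnormal"))
    stop(sprintf("%d record(s) labeled 'abnormal' in the training set; %s",
                 sum(labs == "abnormal"),
                 "training uses normal records only"), call. = FALSE)
  L <- nrow(records[[1]]$samples)
  T <- ncol(records[[1]]$samples)
  fs <- records[[1]]$sampling_rate
  for (r in records)
    if (nrow(r$samples) != L || ncol(r$samples) != T)
      stop("all training records must share [leads x T] shape", call. = FALSE)
  model <- stae_init(model_cfg, seed = derive_seed(cfg$seed, "init"),
                     quiet = !cfg$verbose)
  params <- model_params(model)
  mstate <- tree_zeros(params)
  vstate <- tree_zeros(params)
  step <- 0L
  history <- numeric(cfg$epochs)
  n <- length(records)
  set.seed(derive_seed(cfg$seed, "train-loop"))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0; ep_count <- 0L
    for (bs in starts) {
      ids <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
      N <- length(ids)
      x <- array(0, c(L, T, N))
      xm <- array(0, c(L, T, N))
      wts <- if (cfg$masked_loss_only) array(0, c(L, T, N)) else NULL
      for (j in seq_len(N)) {
        rec <- records[[ids[j]]]
        x[, , j] <- rec$samples
        mc <- model_cfg$mask
        mc$seed <- derive_seed(cfg$seed,
                               sprintf("mask-e%d-s%d-j%d", ep, bs, j))
        mt <- mask_time(rec, mc)
        xm[, , j] <- mt$masked$samples
        if (cfg$masked_loss_only) wts[, , j] <- mt$indicator
      }
      # the spectral branch sees the spectrogram of the time-masked signal,
      # masked again in its own domain: both domains are partially obscured
      # and neither branch can reveal the hidden time patches
      spec_in <- if (model_cfg$branches == "dual") {
        mc <- model_cfg$mask
        mc$seed <- derive_seed(cfg$seed, sprintf("maskspec-e%d-s%d", ep, bs))
        spec_branch_input(xm, fs, model_cfg$stft, maskcfg = mc)
      }
      fw <- stae_forward_batch(model, xm, spec_in, training = TRUE,
                               keep = TRUE)
      model <- fw$model
      loss <- reconstruction_loss(fw$x_hat, fw$sigma, x, weights = wts)
      gl <- reconstruction_loss_grads(fw$x_hat, fw$sigma, x, weights = wts)
      grads <- stae_backward_batch(model, fw$cache, gl$d_xhat, gl$d_sigma,
                                   training = TRUE)
      # order the gradient tree like the parameter tree
      params <- model_params(model)
      grads <- grads[names(params)]
      step <- step + 1L
      upd <- adamw_update(params, grads, mstate, vstate,
                          lr = cfg$learning_rate, wd = cfg$weight_decay,
                          t = step)
      params <- upd$p; mstate <- upd$m; vstate <- upd$v
      model <- model_set_params(model, params)
      ep_loss <- ep_loss + loss * N
      ep_count <- ep_count + N
    }
    history[ep] <- ep_loss / ep_count
    if (cfg$verbose)
      message(sprintf("epoch %3d/%d  mean loss %.6f", ep, cfg$epochs,
                      history[ep]))
    if (cfg$checkpoint_every > 0L && !is.null(cfg$checkpoint_dir) &&
        ep %% cfg$checkpoint_every == 0L) {
      dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_stae(model, file.path(cfg$checkpoint_dir,
                                 sprintf("epoch%03d.rds", ep)))
    }
  }
  list(model = model, history = history, model_cfg = model_cfg,
       train_cfg = cfg)
}

#' Save / load an STAE model
#'
#' The checkpoint embeds the full configuration, so the architecture is
#' reconstructible from the file alone.
#'
#' @param model An `stae_model`.
#' @param path File path.
#' @return `load_stae` returns the model; `save_stae` the path, invisibly.
#' @export
save_stae <- function(model, path) {
  stopifnot(inherits(model, "stae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_stae
#' @export
load_stae <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "stae_model"))
  model
}
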