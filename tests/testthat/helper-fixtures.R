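# Shared test fixtures and independent oracles.

# Literal triple-loop transcription of the strided-block mask construction
# (the independent oracle for the vectorized implementation).
loop_mask <- function(T, B, S) {
  M <- matrix(0, T, T)
  n_b <- ceiling(T / B)
  for (b in 0:(n_b - 1)) {
    s <- b * B
    e <- min(s + B, T)
    for (i in seq(s, e - 1, by = S))
      for (j in seq(s, e - 1, by = S))
        M[i + 1, j + 1] <- 1
  }
  M
}

# Brute-force dense multi-head attention sharing the package's projections.
dense_attention_oracle <- function(x, params, H) {
  D <- ncol(x)
  dh <- D / H
  q <- x %*% params$Wq
  k <- x %*% params$Wk
  v <- x %*% params$Wv
  Z <- matrix(0, nrow(x), D)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(dh)
    P <- exp(A - apply(A, 1, max))
    P <- P / rowSums(P)
    Z[, cols] <- P %*% v[, cols, drop = FALSE]
  }
  Z %*% params$Wo
}

# Minimal amplitude-threshold peak detector, independent of the package's
# detect_beats(): local maxima above 0.6 * max with a refractory period.
oracle_peaks <- function(x, fs, refractory = 0.3) {
  thr <- 0.6 * max(x)
  n <- length(x)
  cand <- which(x >= thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refractory * fs) {
      peaks <- c(peaks, i)
      last <- i
    }
  }
  peaks
}

# Spectral energy of a vector above a frequency cutoff (direct FFT).
band_energy_above <- function(x, fs, cutoff) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  sum(sp[freqs > cutoff & freqs <= fs / 2])
}

# A clean (noise-free, jitter-free) single-lead generator config.
clean_syn_config <- function(hr = 60, duration = 10, fs = 250, seed = 7) {
  synthetic_config(n_records = 1L, n_leads = 1L, duration = duration,
                   sampling_rate = fs, heart_rate_range = c(hr, hr),
                   rr_jitter_sd = 0, amplitude_jitter = 0,
                   baseline_wander_amp = 0, noise_sd = 0, seed = seed)
}

# A tiny dual-branch model configuration for structural tests.
tiny_stae_config <- function(...) {
  args <- list(n_leads = 2L, enc1d_widths = c(3L, 4L, 4L),
               enc2d_widths = c(3L, 3L, 4L, 4L),
               heads = 2L, block_size = 8L, stride = 2L, dropout = 0,
               mask = mask_config(mask_ratio = 0.2, time_patch_len = 5L,
                                  spec_patch = c(2L, 2L)),
               stft = stft_params(window_length = 16L, hop = 8L,
                                  fft_size = 16L))
  do.call(stae_config, utils::modifyList(args, list(...)))
}
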