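# Time-frequency representation (STFT magnitude) and random patch-based
# masking in both domains.

#' STFT parameters
#'
#' Defaults (window 64 samples, hop 16, Hann, FFT size 64, log1p magnitude)
#' resolve QRS-scale transients at 500 Hz while keeping the frame count
#' manageable; all are configurable.
#'
#' @param window_length Analysis window length in samples.
#' @param hop Hop between frames in samples.
#' @param fft_size FFT length (>= window_length; window is zero-padded).
#' @param log_scaled Apply `log1p` to the magnitude?
#' @return An `stft_params` list.
#' @export
stft_params <- function(window_length = 64L, hop = 16L, fft_size = 64L,
                        log_scaled = TRUE) {
  check_count(window_length, "window_length", lower = 2L)
  check_count(hop, "hop", lower = 1L)
  check_count(fft_size, "fft_size", lower = 2L)
  if (fft_size < window_length)
    abort_field("fft_size", "must be >= window_length")
  structure(list(window_length = as.integer(window_length),
                 hop = as.integer(hop), fft_size = as.integer(fft_size),
                 log_scaled = isTRUE(log_scaled)),
            class = "stft_params")
}

#' Number of STFT frames for a signal of length T
#'
#' `floor((T - window_length) / hop) + 1`, no padding.
#' @param T Signal length in samples.
#' @param params An [stft_params].
#' @return Integer frame count.
#' @export
stft_n_frames <- function(T, params) {
  as.integer(floor((T - params$window_length) / params$hop) + 1L)
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Per-lead magnitude spectrogram with a periodic Hann window and no padding:
#' frame `f` covers samples `[(f-1)*hop + 1, (f-1)*hop + window_length]`.
#' Non-negative magnitudes; optionally `log1p`-scaled.
#'
#' @param record An [ecg_record].
#' @param params An [stft_params].
#' @return An object of class `spectrogram` with fields `magnitude`
#'   (`[leads x freq_bins x frames]`), `freq_axis` (Hz per bin),
#'   `frame_times` (seconds, frame start), and `params`.
#' @export
stft <- function(record, params = stft_params()) {
  stopifnot(inherits(record, "ecg_record"), inherits(params, "stft_params"))
  T <- ncol(record$samples)
  win <- params$window_length
  if (win > T)
    abort_field("window_length", sprintf("(%d) exceeds signal length %d",
                                         win, T))
  nfr <- stft_n_frames(T, params)
  nb <- params$fft_size %/% 2L + 1L
  # periodic Hann window
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / win)
  starts <- (seq_len(nfr) - 1L) * params$hop
  idx <- outer(seq_len(win), starts, `+`)  # [win x frames]
  leads <- nrow(record$samples)
  mag <- array(0, c(leads, nb, nfr))
  for (l in seq_len(leads)) {
    frames <- matrix(record$samples[l, idx], win, nfr) * w
    if (params$fft_size > win)
      frames <- rbind(frames, matrix(0, params$fft_size - win, nfr))
    spec <- Mod(stats::mvfft(frames))[seq_len(nb), , drop = FALSE]
    mag[l, , ] <- if (params$log_scaled) log1p(spec) else spec
  }
  structure(list(
    magnitude = mag,
    freq_axis = (seq_len(nb) - 1L) * record$sampling_rate / params$fft_size,
    frame_times = starts / record$sampling_rate,
    params = params,
    sampling_rate = record$sampling_rate), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<spectrogram> %d lead(s) x %d freq bins x %d frames (win=%d hop=%d%s)\n",
              d[1], d[2], d[3], x$params$window_length, x$params$hop,
              if (x$params$log_scaled) ", log1p" else ""))
  invisible(x)
}

#' Masking configuration
#'
#' Random patch-based masking used during training in both domains. Patches
#' are non-overlapping and grid-aligned; the selected fraction approximates
#' `mask_ratio` to within one patch. Masked entries are set to 0.
#'
#' @param mask_ratio Fraction of entries to mask, in `[0, 1)`.
#' @param time_patch_len Time-domain patch length in samples.
#' @param spec_patch Length-2 vector `(freq_bins, frames)` patch size.
#' @param seed Integer seed; per-lead masks are drawn from streams derived
#'   from `(seed, lead index)`, so the mask pattern depends only on the lead
#'   slot, never on the data.
#' @return A `mask_config` list.
#' @export
mask_config <- function(mask_ratio = 0.3, time_patch_len = 50L,
                        spec_patch = c(4L, 4L), seed = 1L) {
  check_number(mask_ratio, "mask_ratio", lower = 0)
  if (mask_ratio >= 1) abort_field("mask_ratio", "must be < 1")
  check_count(time_patch_len, "time_patch_len")
  if (length(spec_patch) != 2L || any(spec_patch < 1) ||
      any(spec_patch != round(spec_patch)))
    abort_field("spec_patch", "must be two positive integers")
  check_number(seed, "seed")
  structure(list(mask_ratio = mask_ratio,
                 time_patch_len = as.integer(time_patch_len),
                 spec_patch = as.integer(spec_patch),
                 seed = as.integer(seed)),
            class = "mask_config")
}

# Choose `n_sel` cells out of `n_cells`, seeded; errors if infeasible.
select_patches <- function(n_cells, n_sel, seed) {
  if (n_sel > n_cells)
    stop(sprintf("mask_ratio requires %d patches but only %d fit",
                 n_sel, n_cells), call. = FALSE)
  if (n_sel == 0L) return(integer(0))
  with_seed(seed, sample.int(n_cells, n_sel))
}

#' Mask random time-domain patches
#'
#' Non-overlapping patches of `time_patch_len` samples on the aligned grid
#' are selected uniformly at random, independently per lead, until
#' approximately `mask_ratio` of the samples are covered; masked samples are
#' set to 0.
#'
#' @param record An [ecg_record].
#' @param cfg A [mask_config].
#' @return List with `masked` (an `ecg_record`) and `indicator` (0/1 matrix
#'   `[leads x T]`, 1 at masked positions).
#' @export
mask_time <- function(record, cfg) {
  stopifnot(inherits(record, "ecg_record"), inherits(cfg, "mask_config"))
  T <- ncol(record$samples)
  L <- cfg$time_patch_len
  n_cells <- T %/% L
  n_sel <- round(cfg$mask_ratio * T / L)
  ind <- matrix(0, nrow(record$samples), T)
  y <- record$samples
  for (l in seq_len(nrow(y))) {
    sel <- select_patches(n_cells, n_sel,
                          derive_seed(cfg$seed, sprintf("mask-time-lead-%d", l)))
    for (cidx in sel) {
      span <- ((cidx - 1L) * L + 1L):(cidx * L)
      ind[l, span] <- 1
      y[l, span] <- 0
    }
  }
  out <- record
  out$samples <- y
  list(masked = out, indicator = ind)
}

#' Mask random rectangular spectrogram patches
#'
#' As [mask_time()] but with rectangular `(freq_bins x frames)` patches on
#' the magnitude array, independently per lead.
#'
#' @param spec A [stft()] spectrogram.
#' @param cfg A [mask_config].
#' @return List with `masked` (a `spectrogram`) and `indicator`
#'   (0/1 array shaped like the magnitude).
#' @export
mask_spectrogram <- function(spec, cfg) {
  stopifnot(inherits(spec, "spectrogram"), inherits(cfg, "mask_config"))
  d <- dim(spec$magnitude)
  pf <- cfg$spec_patch[1]; pt <- cfg$spec_patch[2]
  nf <- d[2] %/% pf; nt <- d[3] %/% pt
  n_cells <- nf * nt
  n_sel <- round(cfg$mask_ratio * d[2] * d[3] / (pf * pt))
  ind <- array(0, d)
  mag <- spec$magnitude
  for (l in seq_len(d[1])) {
    sel <- select_patches(n_cells, n_sel,
                          derive_seed(cfg$seed, sprintf("mask-spec-lead-%d", l)))
    for (cidx in sel) {
      fi <- (cidx - 1L) %% nf
      ti <- (cidx - 1L) %/% nf
      fr <- (fi * pf + 1L):((fi + 1L) * pf)
      tr <- (ti * pt + 1L):((ti + 1L) * pt)
      ind[l, fr, tr] <- 1
      mag[l, fr, tr] <- 0
    }
  }
  out <- spec
  out$magnitude <- mag
  list(masked = out, indicator = ind)
}
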