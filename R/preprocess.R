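# ECG records and the preprocessing pipeline:
# denoise (high-pass -> notch -> low-pass, zero phase) -> quality filter ->
# per-lead min-max normalization to [-1, 1].

#' Construct an ECG record
#'
#' The package's basic container: a sample matrix with one row per lead, a
#' sampling rate, an identifier and an optional binary label.
#'
#' @param samples Numeric matrix `[leads x T]` of signal samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param record_id Character identifier.
#' @param label One of `"normal"`, `"abnormal"`, `"unknown"`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, record_id = "record",
                       label = c("unknown", "normal", "abnormal")) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    abort_field("samples", "must be a numeric matrix [leads x T]")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    abort_field("samples", "needs at least one lead and one sample")
  if (!all(is.finite(samples)))
    abort_field("samples", "must be finite")
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  label <- match.arg(label)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         record_id = as.character(record_id), label = label),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d lead(s) x %d samples @ %g Hz, label=%s\n",
              x$record_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, x$label))
  invisible(x)
}

#' Denoising filter configuration
#'
#' Cascade of a high-pass (baseline wander removal), a narrow band-stop notch
#' (power-line interference) and a low-pass (high-frequency noise). Each stage
#' is an order-2 Butterworth filter applied forward-backward (zero phase).
#'
#' @param highpass_cutoff High-pass cutoff in Hz (default 1).
#' @param lowpass_cutoff Low-pass cutoff in Hz (default 25).
#' @param notch_freq Notch center frequency in Hz (default 50, European mains).
#' @param notch_q Notch quality factor; stop-band width is `notch_freq/notch_q`.
#' @param filter_order Butterworth order per stage.
#' @return A `filter_config` list.
#' @export
filter_config <- function(highpass_cutoff = 1, lowpass_cutoff = 25,
                          notch_freq = 50, notch_q = 30, filter_order = 2) {
  check_number(highpass_cutoff, "highpass_cutoff", lower = 1e-9)
  check_number(lowpass_cutoff, "lowpass_cutoff", lower = 1e-9)
  check_number(notch_freq, "notch_freq", lower = 1e-9)
  check_number(notch_q, "notch_q", lower = 1e-9)
  check_count(filter_order, "filter_order")
  if (highpass_cutoff >= lowpass_cutoff)
    abort_field("highpass_cutoff", "must be below lowpass_cutoff")
  structure(list(highpass_cutoff = highpass_cutoff,
                 lowpass_cutoff = lowpass_cutoff,
                 notch_freq = notch_freq, notch_q = notch_q,
                 filter_order = as.integer(filter_order)),
            class = "filter_config")
}

# Steady-state initial filter state for unit step input (direct form II
# transposed), so filtering a constant yields that constant from sample one.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  a1 <- a[1]
  a <- c(a, rep(0, n + 1L - length(a))) / a1
  b <- c(b, rep(0, n + 1L - length(b))) / a1
  A <- matrix(0, n, n)
  A[1, ] <- -a[-1]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

# IIR filter in direct form II transposed with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b)) - 1L
  bb <- c(b, rep(0, n + 1L - length(b))) / a[1]
  aa <- c(a, rep(0, n + 1L - length(a))) / a[1]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- bb[1] * xi + z[1]
    if (n > 1)
      for (j in 1:(n - 1)) z[j] <- bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi
    z[n] <- bb[n + 1] * xi - aa[n + 1] * yi
    y[i] <- yi
  }
  y
}

# Zero-phase (forward-backward) filtering with odd-reflection padding and
# steady-state initial conditions, so edges carry no start-up transient.
filtfilt1 <- function(flt, x) {
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= nfact)
    stop(sprintf("signal too short to filter (need > %d samples)", nfact),
         call. = FALSE)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(nfact + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

#' Denoise an ECG record
#'
#' Applies, per lead and in order: high-pass, band-stop notch, low-pass.
#' All stages are zero-phase (forward-backward) Butterworth filters, so the
#' operation is linear and introduces no group delay.
#'
#' @param record An [ecg_record].
#' @param cfg A [filter_config].
#' @return A new `ecg_record` with filtered samples; shape preserved.
#' @export
denoise <- function(record, cfg = filter_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(cfg, "filter_config"))
  fs <- record$sampling_rate
  nyq <- fs / 2
  if (cfg$lowpass_cutoff >= nyq)
    abort_field("lowpass_cutoff", sprintf("must be below Nyquist (%g Hz)", nyq))
  if (cfg$notch_freq >= nyq)
    abort_field("notch_freq", sprintf("must be below Nyquist (%g Hz)", nyq))
  bw <- cfg$notch_freq / cfg$notch_q
  stop_lo <- max(cfg$notch_freq - bw / 2, 1e-6)
  stop_hi <- min(cfg$notch_freq + bw / 2, nyq * (1 - 1e-6))
  hp <- signal::butter(cfg$filter_order, cfg$highpass_cutoff / nyq,
                       type = "high")
  nf <- signal::butter(cfg$filter_order, c(stop_lo, stop_hi) / nyq,
                       type = "stop")
  lp <- signal::butter(cfg$filter_order, cfg$lowpass_cutoff / nyq,
                       type = "low")
  y <- record$samples
  for (l in seq_len(nrow(y))) {
    v <- filtfilt1(hp, y[l, ])
    v <- filtfilt1(nf, v)
    y[l, ] <- filtfilt1(lp, v)
  }
  out <- record
  out$samples <- y
  out
}

#' Per-lead min-max normalization to \[-1, 1\]
#'
#' Each lead is mapped affinely so its minimum becomes -1 and its maximum +1,
#' independently of all other leads and records. A constant (flatline) lead is
#' mapped to all zeros with a warning rather than an error, so batch pipelines
#' do not abort.
#'
#' @param record An [ecg_record].
#' @return A normalized `ecg_record`.
#' @export
normalize_minmax <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  y <- record$samples
  for (l in seq_len(nrow(y))) {
    lo <- min(y[l, ]); hi <- max(y[l, ])
    if (hi == lo) {
      warning(sprintf("lead %d of record '%s' is constant; normalized to 0",
                      l, record$record_id), call. = FALSE)
      y[l, ] <- 0
    } else {
      y[l, ] <- 2 * (y[l, ] - lo) / (hi - lo) - 1
    }
  }
  out <- record
  out$samples <- y
  out
}

#' Detect beats with a simple amplitude-threshold peak detector
#'
#' Utility detector used by the signal-quality filter: finds local maxima of
#' the (mean-removed) first lead exceeding half the maximum absolute
#' deflection, with a 250 ms refractory period.
#'
#' @param record An [ecg_record].
#' @param lead Lead index to analyse (default 1).
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
detect_beats <- function(record, lead = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples[lead, ]
  x <- x - mean(x)
  amp <- max(abs(x))
  if (amp <= 0) return(integer(0))
  # orient so the dominant deflection is positive
  if (max(x) < -min(x)) x <- -x
  thr <- 0.5 * max(x)
  n <- length(x)
  refr <- max(1L, round(0.25 * record$sampling_rate))
  cand <- which(x >= thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] >= x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      peaks <- c(peaks, i)
      last <- i
    } else if (x[i] > x[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
      last <- i
    }
  }
  peaks
}

#' Signal-quality exclusion filter
#'
#' Stand-in for an external signal-quality check: a record is kept iff a
#' simple peak detector finds at least `min_beats` beats and the implied mean
#' heart rate lies in `hr_range` bpm. Records failing the check are excluded
#' and their ids reported.
#'
#' @param records List of [ecg_record]s (assumed denoised).
#' @param min_beats Minimum number of detected beats (default 2).
#' @param hr_range Plausible heart-rate interval in bpm (default c(30, 220)).
#' @return List with `kept` (records) and `excluded_ids` (character).
#' @export
quality_filter <- function(records, min_beats = 2L, hr_range = c(30, 220)) {
  stopifnot(is.list(records))
  kept <- list(); excluded <- character(0)
  for (r in records) {
    stopifnot(inherits(r, "ecg_record"))
    pk <- detect_beats(r)
    ok <- FALSE
    if (length(pk) >= min_beats) {
      hr <- 60 / mean(diff(pk) / r$sampling_rate)
      ok <- is.finite(hr) && hr >= hr_range[1] && hr <= hr_range[2]
    }
    if (ok) kept[[length(kept) + 1L]] <- r
    else excluded <- c(excluded, r$record_id)
  }
  list(kept = kept, excluded_ids = excluded)
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: [denoise()] -> [quality_filter()] -> [normalize_minmax()].
#'
#' @param records List of [ecg_record]s.
#' @param cfg A [filter_config].
#' @param verbose Print stage summary?
#' @return List with `records` (processed) and `excluded_ids`.
#' @export
preprocess_records <- function(records, cfg = filter_config(),
                               verbose = FALSE) {
  den <- lapply(records, denoise, cfg = cfg)
  qf <- quality_filter(den)
  out <- lapply(qf$kept, normalize_minmax)
  if (verbose)
    message(sprintf("preprocess: %d in, %d kept, %d excluded",
                    length(records), length(out), length(qf$excluded_ids)))
  list(records = out, excluded_ids = qf$excluded_ids)
}
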