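# Synthetic quasi-periodic ECG generator and anomaly injection.
#
# Normal records are beat trains of three Gaussian bumps (P, QRS, T) at a
# per-record heart rate, with per-beat RR jitter and amplitude jitter,
# sinusoidal baseline wander and additive white noise. Three anomaly families
# can be injected with a severity in [0, 1]: rhythm irregularity (smooth
# random time warp), morphology distortion (widened/rescaled QRS complexes on
# a subset of beats) and high-frequency oscillation (band-limited noise).

#' Synthetic ECG generator configuration
#'
#' Defaults emulate resting 12-lead recordings (10 s at 500 Hz) of healthy
#' adults: heart rate 55-95 bpm, mild beat-to-beat RR jitter, small amplitude
#' jitter, slow sinusoidal baseline wander and white measurement noise.
#'
#' @param n_records Number of records to generate.
#' @param n_leads Leads per record.
#' @param duration Record duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param heart_rate_range Length-2 vector, min/max heart rate in bpm; each
#'   record draws one rate uniformly.
#' @param rr_jitter_sd SD of per-beat RR interval jitter in seconds.
#' @param amplitude_jitter Fractional per-beat amplitude jitter (uniform).
#' @param baseline_wander_amp Amplitude of sinusoidal baseline wander, in
#'   signal units (QRS peak is ~1).
#' @param noise_sd SD of additive white noise, signal units.
#' @param seed Integer master seed; record `i` uses the stream derived from
#'   `(seed, i)` so every record is independently reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_records = 10L, n_leads = 12L, duration = 10,
                             sampling_rate = 500,
                             heart_rate_range = c(55, 95),
                             rr_jitter_sd = 0.03, amplitude_jitter = 0.1,
                             baseline_wander_amp = 0.05, noise_sd = 0.02,
                             seed = 1L) {
  check_count(n_records, "n_records")
  check_count(n_leads, "n_leads")
  check_number(duration, "duration", lower = 1e-9)
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  if (!is.numeric(heart_rate_range) || length(heart_rate_range) != 2L ||
      any(!is.finite(heart_rate_range)) || any(heart_rate_range <= 0) ||
      heart_rate_range[1] > heart_rate_range[2])
    abort_field("heart_rate_range", "must be (min, max) bpm with min <= max > 0")
  check_number(rr_jitter_sd, "rr_jitter_sd", lower = 0)
  check_number(amplitude_jitter, "amplitude_jitter", lower = 0)
  check_number(baseline_wander_amp, "baseline_wander_amp", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  structure(list(n_records = as.integer(n_records),
                 n_leads = as.integer(n_leads),
                 duration = duration, sampling_rate = sampling_rate,
                 heart_rate_range = heart_rate_range,
                 rr_jitter_sd = rr_jitter_sd,
                 amplitude_jitter = amplitude_jitter,
                 baseline_wander_amp = baseline_wander_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Beat template: P (small, early), QRS (tall, narrow) and T (broad, late)
# Gaussian bumps; times in seconds relative to the QRS center.
.beat_bumps <- data.frame(
  amp    = c(0.12,  1.00, 0.30),
  center = c(-0.17, 0.00, 0.22),
  width  = c(0.025, 0.012, 0.060))

# Render one lead: sum of bumps at each beat center, on the time grid `tt`.
render_beats <- function(tt, centers, amps) {
  x <- numeric(length(tt))
  for (k in seq_along(centers)) {
    for (b in seq_len(nrow(.beat_bumps))) {
      mu <- centers[k] + .beat_bumps$center[b]
      w <- .beat_bumps$width[b]
      lo <- findInterval(mu - 5 * w, tt); hi <- findInterval(mu + 5 * w, tt)
      if (hi < 1L || lo >= length(tt)) next
      idx <- max(lo, 1L):min(hi + 1L, length(tt))
      x[idx] <- x[idx] +
        amps[k] * .beat_bumps$amp[b] * exp(-0.5 * ((tt[idx] - mu) / w)^2)
    }
  }
  x
}

#' Generate normal synthetic ECG records
#'
#' @param config A [synthetic_config].
#' @return List of `config$n_records` [ecg_record]s labeled `"normal"`, each
#'   `[n_leads x duration*sampling_rate]`. Bit-identical for identical
#'   `(config, seed)`.
#' @export
generate_normal <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$sampling_rate
  T <- round(config$duration * fs)
  tt <- (seq_len(T) - 1L) / fs
  lapply(seq_len(config$n_records), function(i) {
    with_seed(derive_seed(config$seed, sprintf("synthetic-record-%06d", i)), {
      hr <- runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
      rr <- 60 / hr
      n_beats <- ceiling(config$duration / rr) + 2L
      gaps <- rr + rnorm(n_beats, sd = config$rr_jitter_sd)
      gaps <- pmax(gaps, 0.3 * rr)
      centers <- cumsum(gaps) - gaps[1] / 2
      centers <- centers[centers < config$duration + 0.5]
      amps <- 1 + config$amplitude_jitter *
        runif(length(centers), -1, 1)
      base <- render_beats(tt, centers, amps)
      gains <- seq(0.6, 1.1, length.out = config$n_leads) *
        (1 + 0.05 * runif(config$n_leads, -1, 1))
      y <- matrix(0, config$n_leads, T)
      for (l in seq_len(config$n_leads)) {
        wander <- if (config$baseline_wander_amp > 0) {
          f_bw <- runif(1, 0.15, 0.4); ph <- runif(1, 0, 2 * pi)
          config$baseline_wander_amp * sin(2 * pi * f_bw * tt + ph)
        } else 0
        noise <- if (config$noise_sd > 0)
          rnorm(T, sd = config$noise_sd) else 0
        y[l, ] <- gains[l] * base + wander + noise
      }
      ecg_record(y, fs, record_id = sprintf("syn%06d", i), label = "normal")
    })
  })
}

#' Anomaly injection specification
#'
#' @param family One of `"rhythm_irregularity"`, `"morphology_distortion"`,
#'   `"hf_oscillation"`.
#' @param severity Real in `[0, 1]`; 0 leaves the record untouched, 1 is the
#'   strongest documented perturbation.
#' @param seed Integer seed for the injection's random draws.
#' @return An `anomaly_spec` list.
#' @export
anomaly_spec <- function(family, severity, seed = 1L) {
  families <- c("rhythm_irregularity", "morphology_distortion",
                "hf_oscillation")
  if (!is.character(family) || length(family) != 1L ||
      !(family %in% families))
    abort_field("family", paste("must be one of",
                                paste(families, collapse = ", ")))
  check_number(severity, "severity", lower = 0, upper = 1)
  check_number(seed, "seed")
  structure(list(family = family, severity = severity,
                 seed = as.integer(seed)),
            class = "anomaly_spec")
}

# Smooth random time warp: each output sample t takes the input sample
# nearest t + w(t), where w is a sum of two low-frequency sinusoids with
# amplitude `amp` seconds. Integer (nearest-sample) resampling is used
# deliberately: linear interpolation would low-pass the waveform and alter
# morphology, whereas the warp should only displace beat onsets.
warp_time <- function(samples, fs, amp) {
  T <- ncol(samples)
  tt <- (seq_len(T) - 1L) / fs
  f1 <- runif(1, 0.10, 0.25); f2 <- runif(1, 0.25, 0.45)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  w <- amp * (0.7 * sin(2 * pi * f1 * tt + p1) +
              0.3 * sin(2 * pi * f2 * tt + p2))
  src <- pmin(pmax(round((tt + w) * fs) + 1L, 1L), T)
  samples[, src, drop = FALSE]
}

#' Inject an anomaly into an ECG record
#'
#' The input record is never modified; a perturbed copy labeled `"abnormal"`
#' is returned with the same shape and sampling rate. Perturbation magnitude
#' scales linearly with `spec$severity`:
#' \describe{
#'   \item{rhythm_irregularity}{smooth random time warp of up to
#'     `0.12 * severity` seconds, perturbing beat onset times while preserving
#'     waveform shape.}
#'   \item{morphology_distortion}{a `severity/2` fraction of detected QRS
#'     complexes (at least one) is widened by `1 + severity` and rescaled by
#'     `1 + 0.8 * severity`.}
#'   \item{hf_oscillation}{adds band-limited (25-45 Hz, clipped below
#'     Nyquist) noise with SD `0.25 * severity` times the lead SD.}
#' }
#'
#' @param record An [ecg_record].
#' @param spec An [anomaly_spec].
#' @return A new `ecg_record`.
#' @export
inject_anomaly <- function(record, spec) {
  stopifnot(inherits(record, "ecg_record"))
  if (!inherits(spec, "anomaly_spec"))
    abort_field("spec", "must be an anomaly_spec")
  if (spec$severity == 0) return(record)
  fs <- record$sampling_rate
  out <- record
  out$label <- "abnormal"
  with_seed(derive_seed(spec$seed, paste0("inject-", spec$family, "-",
                                          record$record_id)), {
    if (spec$family == "rhythm_irregularity") {
      out$samples <- warp_time(record$samples, fs, 0.12 * spec$severity)
    } else if (spec$family == "morphology_distortion") {
      y <- record$samples
      peaks <- detect_beats(record)
      if (length(peaks)) {
        n_hit <- max(1L, round(length(peaks) * spec$severity / 2))
        hit <- sort(sample(peaks, n_hit))
        half <- round(0.08 * fs)
        widen <- 1 + spec$severity
        scale <- 1 + 0.8 * spec$severity
        for (p in hit) {
          lo <- max(1L, p - half); hi <- min(ncol(y), p + half)
          idx <- lo:hi
          rel <- idx - p
          for (l in seq_len(nrow(y))) {
            seg <- y[l, idx]
            wseg <- approx(rel, seg, xout = rel / widen, rule = 2)$y
            y[l, idx] <- scale * wseg
          }
        }
      }
      out$samples <- y
    } else { # hf_oscillation
      nyq <- fs / 2
      lo <- 25; hi <- min(45, 0.9 * nyq)
      if (lo >= hi) { lo <- 0.5 * nyq; hi <- 0.9 * nyq }
      bp <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
      y <- record$samples
      for (l in seq_len(nrow(y))) {
        base_sd <- stats::sd(y[l, ])
        if (base_sd == 0) base_sd <- 1
        hf <- filtfilt1(bp, rnorm(ncol(y)))
        hf_sd <- stats::sd(hf)
        if (hf_sd > 0)
          y[l, ] <- y[l, ] + 0.25 * spec$severity * base_sd * hf / hf_sd
      }
      out$samples <- y
    }
  })
  out
}

#' Build a labeled synthetic train/test split
#'
#' Convenience wrapper used by the end-to-end benchmark and the CLI: generates
#' `n_train + n_test_normal + n_test_anomalous` normal records and injects a
#' cycling mix of the three anomaly families (or a single chosen family) into
#' the anomalous portion.
#'
#' @param config A [synthetic_config]; `n_records` is overridden.
#' @param n_train,n_test_normal,n_test_anomalous Split sizes.
#' @param severity Injection severity for the anomalous portion.
#' @param families Families to cycle through (default all three).
#' @return List with `train`, `test` (records) and `test_labels` (0 normal /
#'   1 abnormal).
#' @export
synthetic_split <- function(config, n_train = 200L, n_test_normal = 50L,
                            n_test_anomalous = 50L, severity = 0.8,
                            families = c("rhythm_irregularity",
                                         "morphology_distortion",
                                         "hf_oscillation")) {
  cfg <- config
  cfg$n_records <- as.integer(n_train + n_test_normal + n_test_anomalous)
  recs <- generate_normal(cfg)
  train <- recs[seq_len(n_train)]
  test_norm <- recs[n_train + seq_len(n_test_normal)]
  test_anom <- recs[n_train + n_test_normal + seq_len(n_test_anomalous)]
  test_anom <- lapply(seq_along(test_anom), function(i) {
    fam <- families[((i - 1L) %% length(families)) + 1L]
    inject_anomaly(test_anom[[i]],
                   anomaly_spec(fam, severity,
                                seed = derive_seed(cfg$seed,
                                                   sprintf("anom-%d", i))))
  })
  list(train = train,
       test = c(test_norm, test_anom),
       test_labels = c(rep(0L, length(test_norm)),
                       rep(1L, length(test_anom))))
}
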