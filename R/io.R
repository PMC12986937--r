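# Record I/O: native fixture archives (gzipped CSV + JSON sidecar) and an
# optional minimal WFDB reader (header + 16-bit signal file, the layout used
# by 500 Hz 12-lead distribution records).

#' Write ECG records as fixture archives
#'
#' Each record becomes `<id>.csv.gz` (samples, one column per lead, T rows)
#' plus a `<id>.json` sidecar with id, sampling rate, lead count and label.
#'
#' @param records List of [ecg_record]s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written record ids.
#' @export
write_record_dir <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids))
    stop("duplicate record ids", call. = FALSE)
  for (r in records) {
    con <- gzfile(file.path(dir, paste0(r$record_id, ".csv.gz")), "w")
    utils::write.csv(as.data.frame(t(r$samples)), con, row.names = FALSE)
    close(con)
    jsonlite::write_json(
      list(record_id = r$record_id, sampling_rate = r$sampling_rate,
           n_leads = nrow(r$samples), n_samples = ncol(r$samples),
           label = r$label),
      file.path(dir, paste0(r$record_id, ".json")), auto_unbox = TRUE)
  }
  invisible(ids)
}

#' Read ECG records from a fixture directory
#'
#' @param dir Directory written by [write_record_dir()].
#' @return List of [ecg_record]s, in sidecar filename order.
#' @export
read_record_dir <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  metas <- lapply(sidecars, jsonlite::read_json, simplifyVector = TRUE)
  metas <- Filter(function(m) !is.null(m$record_id), metas)  # skip manifests
  lapply(metas, function(meta) {
    csv <- file.path(dir, paste0(meta$record_id, ".csv.gz"))
    if (!file.exists(csv))
      stop(sprintf("missing samples file for record '%s'", meta$record_id),
           call. = FALSE)
    m <- t(as.matrix(utils::read.csv(gzfile(csv))))
    dimnames(m) <- NULL
    ecg_record(m, as.numeric(meta$sampling_rate),
               record_id = meta$record_id, label = meta$label)
  })
}

#' Read a WFDB record (header + format-16 signal file)
#'
#' Minimal reader for the common single-segment WFDB layout: a `.hea` header
#' naming one binary signal file in format 16 (16-bit little-endian signed
#' integers, samples interleaved across signals), with per-signal gain and
#' baseline. Values are returned in physical units
#' `(adc - baseline) / gain`.
#'
#' @param hea_path Path to the `.hea` header file.
#' @param label Label to attach (`"unknown"` by default).
#' @return An [ecg_record] with one lead per signal.
#' @export
read_wfdb_record <- function(hea_path, label = "unknown") {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- hdr[1]
  n_sig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3) as.numeric(strsplit(hdr[3], "/")[[1]][1]) else 250
  n_samp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  sig <- lines[1 + seq_len(n_sig)]
  fields <- lapply(sig, function(s) strsplit(trimws(s), "\\s+")[[1]])
  files <- vapply(fields, `[[`, character(1), 1L)
  if (length(unique(files)) != 1L)
    stop("multi-file WFDB records are not supported", call. = FALSE)
  fmt <- vapply(fields, function(f) sub("x.*$", "", f[2]), character(1))
  if (!all(fmt == "16"))
    stop(sprintf("unsupported WFDB format(s): %s (only 16 supported)",
                 paste(unique(fmt), collapse = ", ")), call. = FALSE)
  # gain field looks like "1000(0)/mV" or "1000"
  gain <- vapply(fields, function(f) {
    if (length(f) < 3) return(200)  # WFDB default gain
    g <- as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", f[3]))
    if (!is.finite(g) || g == 0) 200 else g
  }, numeric(1))
  baseline <- vapply(fields, function(f) {
    if (length(f) < 3) return(0)
    b <- regmatches(f[3], regexec("\\(([-0-9]+)\\)", f[3]))[[1]]
    if (length(b) == 2) as.numeric(b[2]) else 0
  }, numeric(1))
  dat_path <- file.path(dirname(hea_path), files[1])
  raw_n <- file.size(dat_path) %/% 2L
  vals <- readBin(dat_path, "integer", n = raw_n, size = 2L,
                  signed = TRUE, endian = "little")
  n_frames <- length(vals) %/% n_sig
  if (is.finite(n_samp) && !is.na(n_samp)) n_frames <- min(n_frames, n_samp)
  m <- matrix(vals[seq_len(n_frames * n_sig)], nrow = n_sig)  # interleaved
  phys <- (m - baseline) / gain
  ecg_record(phys, fs, record_id = rec_name, label = label)
}
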