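# Run configuration (YAML), staged pipeline orchestration, and the
# end-to-end synthetic benchmark used for desk-scale validation.

take_fields <- function(src, allowed, where) {
  if (is.null(src)) return(list())
  extra <- setdiff(names(src), allowed)
  if (length(extra))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  src
}

#' Build a validated run configuration
#'
#' Accepts a nested list (e.g. parsed from YAML) with optional sections
#' `synthetic`, `filter`, `mask`, `stft`, `model`, `train`, `split`,
#' `scoring`, plus top-level `seed`, `out_dir` and `verbose`. Every
#' sub-config is validated by its constructor before any work starts;
#' unknown keys are rejected.
#'
#' @param x Nested list of settings (may be empty for all defaults).
#' @return A `run_config`.
#' @export
run_config <- function(x = list()) {
  x <- take_fields(x, c("seed", "out_dir", "verbose", "synthetic", "filter",
                        "mask", "stft", "model", "train", "split",
                        "scoring"), "top level")
  seed <- as.integer(x$seed %||% 1L)
  mask <- do.call(mask_config,
                  take_fields(x$mask, names(formals(mask_config)), "mask"))
  stftp <- do.call(stft_params,
                   take_fields(x$stft, names(formals(stft_params)), "stft"))
  model_args <- take_fields(x$model, setdiff(names(formals(stae_config)),
                                             c("mask", "stft")), "model")
  model_args$mask <- mask
  model_args$stft <- stftp
  for (f in intersect(names(model_args),
                      c("enc1d_widths", "enc2d_widths", "dec_widths")))
    model_args[[f]] <- as.integer(unlist(model_args[[f]]))
  structure(list(
    seed = seed,
    out_dir = x$out_dir %||% "stae_run",
    verbose = isTRUE(x$verbose),
    synthetic = do.call(synthetic_config,
                        take_fields(x$synthetic,
                                    names(formals(synthetic_config)),
                                    "synthetic")),
    filter = do.call(filter_config,
                     take_fields(x$filter, names(formals(filter_config)),
                                 "filter")),
    model = do.call(stae_config, model_args),
    train = do.call(train_config,
                    take_fields(x$train, names(formals(train_config)),
                                "train")),
    split = utils::modifyList(list(n_train = 200L, n_test_normal = 50L,
                                   n_test_anomalous = 50L, severity = 0.8),
                              take_fields(x$split,
                                          c("n_train", "n_test_normal",
                                            "n_test_anomalous", "severity"),
                                          "split")),
    scoring = utils::modifyList(list(epsilon = 1e-10),
                                take_fields(x$scoring, "epsilon", "scoring"))),
    class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

write_manifest <- function(stage_dir, stage, cfg, seed, inputs = character()) {
  input_hashes <- lapply(inputs, function(f)
    content_hash(paste(readLines(f, warn = FALSE), collapse = "\n")))
  names(input_hashes) <- basename(inputs)
  jsonlite::write_json(
    list(stage = stage,
         config_hash = content_hash(paste(utils::capture.output(utils::str(cfg)),
                                          collapse = "\n")),
         seed = seed, inputs = input_hashes),
    file.path(stage_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the staged pipeline
#'
#' Stages (each reads the previous stage's artifacts from the run
#' directory): `simulate` (synthetic train/test records), `preprocess`
#' (denoise, quality-filter, normalize), `train` (fit the model on the
#' normal training records), `score` (per-sample anomaly scores on the test
#' records), `evaluate` (normalized scores, Youden threshold, metrics ->
#' `report.json`). Each stage writes a manifest with config hash and seed;
#' deterministic stages reproduce identical artifacts on rerun.
#'
#' @param config A [run_config()] (or nested list coercible to one).
#' @param stages Character subset of
#'   `c("simulate", "preprocess", "train", "score", "evaluate")`.
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "train",
                                    "score", "evaluate")) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, producer) {
    if (!file.exists(path))
      stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                   path, producer), call. = FALSE)
  }
  if ("simulate" %in% stages) {
    syn <- config$synthetic
    syn$seed <- derive_seed(config$seed, "simulate")
    sp <- do.call(synthetic_split, c(list(config = syn), config$split))
    d <- file.path(out, "raw")
    write_record_dir(c(sp$train, sp$test), d)
    utils::write.csv(
      data.frame(record_id = vapply(sp$test, `[[`, character(1), "record_id"),
                 label = sp$test_labels),
      file.path(out, "test_labels.csv"), row.names = FALSE)
    write_manifest(d, "simulate", syn, syn$seed)
  }
  if ("preprocess" %in% stages) {
    need(file.path(out, "raw"), "simulate")
    recs <- read_record_dir(file.path(out, "raw"))
    pp <- preprocess_records(recs, config$filter, verbose = config$verbose)
    d <- file.path(out, "processed")
    write_record_dir(pp$records, d)
    jsonlite::write_json(list(excluded_ids = pp$excluded_ids),
                         file.path(out, "excluded.json"))
    write_manifest(d, "preprocess", config$filter, config$seed)
  }
  if ("train" %in% stages) {
    need(file.path(out, "processed"), "preprocess")
    recs <- read_record_dir(file.path(out, "processed"))
    train_recs <- Filter(function(r) r$label == "normal", recs)
    tc <- config$train
    tc$seed <- derive_seed(config$seed, "train")
    fit <- train_stae(train_recs, config$model, tc)
    save_stae(fit$model, file.path(out, "model.rds"))
    utils::write.csv(data.frame(epoch = seq_along(fit$history),
                                mean_loss = fit$history),
                     file.path(out, "loss_history.csv"), row.names = FALSE)
    write_manifest(out, "train", config$model, tc$seed)
  }
  if ("score" %in% stages) {
    need(file.path(out, "model.rds"), "train")
    need(file.path(out, "test_labels.csv"), "simulate")
    model <- load_stae(file.path(out, "model.rds"))
    labels <- utils::read.csv(file.path(out, "test_labels.csv"))
    recs <- read_record_dir(file.path(out, "processed"))
    recs <- recs[match(labels$record_id,
                       vapply(recs, `[[`, character(1), "record_id"))]
    s <- score_records(model, recs, config$scoring$epsilon)
    utils::write.csv(data.frame(record_id = labels$record_id, score = s),
                     file.path(out, "scores.csv"), row.names = FALSE)
  }
  if ("evaluate" %in% stages) {
    need(file.path(out, "scores.csv"), "score")
    need(file.path(out, "test_labels.csv"), "simulate")
    sc <- utils::read.csv(file.path(out, "scores.csv"))
    lb <- utils::read.csv(file.path(out, "test_labels.csv"))
    stopifnot(identical(sc$record_id, lb$record_id))
    norm <- normalize_scores(sc$score)
    rep <- evaluate_scores(norm, lb$label)
    utils::write.csv(rep$roc, file.path(out, "roc_points.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(auc = rep$auc, average_precision = rep$average_precision,
           threshold = rep$threshold, youden_j = rep$youden_j,
           accuracy = rep$accuracy, precision = rep$precision,
           recall = rep$recall, f1 = rep$f1,
           confusion = as.list(rep$confusion)),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Desk-scale synthetic anomaly-detection benchmark
#'
#' The package's end-to-end validation experiment: train a small STAE on
#' synthetic normal single-lead records (2 s at 250 Hz) and score held-out
#' normals against severity-`severity` anomalies. Model and optimizer
#' settings are scaled down for this problem size (encoder widths
#' (8, 12, 16) and (8, 12, 12, 16), 2 heads, block 50 / stride 5, no
#' dropout, batch 4, learning rate 5e-3, 10 epochs); see the methods
#' vignette for the rationale and for what this experiment does and does
#' not demonstrate.
#'
#' @param seed Master seed for generation, initialization and training.
#' @param n_train,n_test_normal,n_test_anomalous Split sizes.
#' @param epochs Training epochs.
#' @param severity Injection severity for the anomalous test records.
#' @param families Anomaly families to cycle through.
#' @param branches `"dual"` or `"time_only"` (ablation).
#' @param attn_variant Attention variant (ablation).
#' @param verbose Print progress?
#' @return List with `report` (an `eval_report` on normalized scores),
#'   `scores` (normalized), `labels`, `history` (training loss),
#'   `model`, and `n_parameters`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_train = 200L,
                                n_test_normal = 50L, n_test_anomalous = 50L,
                                epochs = 10L, severity = 0.8,
                                families = c("rhythm_irregularity",
                                             "morphology_distortion",
                                             "hf_oscillation"),
                                branches = "dual",
                                attn_variant = "strided_block",
                                verbose = FALSE) {
  syn <- synthetic_config(n_records = 1L, n_leads = 1L, duration = 2,
                          sampling_rate = 250,
                          seed = derive_seed(seed, "benchmark-data"))
  sp <- synthetic_split(syn, n_train = n_train,
                        n_test_normal = n_test_normal,
                        n_test_anomalous = n_test_anomalous,
                        severity = severity, families = families)
  train <- lapply(sp$train, normalize_minmax)
  test <- lapply(sp$test, normalize_minmax)
  mcfg <- stae_config(n_leads = 1L,
                      enc1d_widths = c(8L, 12L, 16L),
                      enc2d_widths = c(8L, 12L, 12L, 16L),
                      heads = 2L, block_size = 50L, stride = 5L,
                      dropout = 0,
                      attn_variant = attn_variant,
                      mask = mask_config(mask_ratio = 0.3,
                                         time_patch_len = 25L,
                                         spec_patch = c(4L, 4L)),
                      stft = stft_params(window_length = 64L, hop = 16L,
                                         fft_size = 64L),
                      branches = branches)
  tcfg <- train_config(epochs = epochs, batch_size = 4L,
                       learning_rate = 5e-3, weight_decay = 1e-4,
                       seed = derive_seed(seed, "benchmark-train"),
                       verbose = verbose)
  fit <- train_stae(train, mcfg, tcfg)
  raw_scores <- score_records(fit$model, test)
  scores <- normalize_scores(raw_scores)
  report <- evaluate_scores(scores, sp$test_labels)
  fam_of <- rep(families, length.out = n_test_anomalous)
  family_auc <- vapply(unique(fam_of), function(f) {
    idx <- c(seq_len(n_test_normal), n_test_normal + which(fam_of == f))
    evaluate_scores(scores[idx], sp$test_labels[idx])$auc
  }, numeric(1))
  list(report = report, scores = scores, raw_scores = raw_scores,
       labels = sp$test_labels, family_auc = family_auc,
       history = fit$history, model = fit$model,
       n_parameters = stae_parameter_count(fit$model))
}
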