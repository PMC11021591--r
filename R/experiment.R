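#' Experiment configuration
#'
#' Everything needed to run the augmentation-multiplier grid end to end on
#' either synthetic recordings or a directory of EDF files: windowing and
#' split settings, the model and augmentation configurations, the arms
#' (multipliers) to compare, and the replication seeds.
#'
#' The flow per arm and seed mirrors the augmentation protocol: segment and
#' balance, split 70/30 stratified, z-score per channel on training
#' statistics, pre-train the classifier on the raw training windows,
#' generate adversarial + mixup windows against it, then train the final
#' model on the amplified set and evaluate on the held-out windows. Arm 0
#' is exactly plain training on the raw set (no pre-training pass).
#'
#' @param data a list of [eeg_recording] objects, a [synth_config()] (used
#'   with [generate_dataset()]), or a directory of EDF files with matching
#'   `.ann` annotation files.
#' @param arms integer multipliers to compare (subset of 0:3 typically).
#' @param seeds one seed per replicate; results are mean +/- sd over them.
#' @param model_cfg a [model_config()].
#' @param aug_cfg an [augmentation_config()]; `multiplier` is overridden
#'   per arm.
#' @param n_recordings,seizure_fraction used when `data` is a
#'   [synth_config()].
#' @param window_s,overlap_s,label_rule segmentation settings.
#' @param train_frac,by_patient split settings.
#' @param balance `"undersample"` or `"none"`.
#' @param pretrain_epochs epochs of the raw-data pre-training pass that the
#'   adversarial generator attacks (kept short; the final training run uses
#'   `model_cfg$epochs`).
#' @param channels optional required channel list for the EDF path.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(data, arms = c(0L, 1L, 2L, 3L), seeds = 1:3,
                              model_cfg = model_config(),
                              aug_cfg = augmentation_config(),
                              n_recordings = 10L, seizure_fraction = 0.5,
                              window_s = 30, overlap_s = 0, label_rule = 0.5,
                              train_frac = 0.7, by_patient = FALSE,
                              balance = "undersample",
                              pretrain_epochs = 10L, channels = NULL) {
  if (!length(seeds)) stop_validation("need at least one seed")
  if (any(arms < 0)) stop_validation("arms must be >= 0")
  structure(list(data = data, arms = as.integer(arms),
                 seeds = as.integer(seeds), model_cfg = model_cfg,
                 aug_cfg = aug_cfg, n_recordings = as.integer(n_recordings),
                 seizure_fraction = seizure_fraction, window_s = window_s,
                 overlap_s = overlap_s, label_rule = label_rule,
                 train_frac = train_frac, by_patient = by_patient,
                 balance = balance, pretrain_epochs = as.integer(pretrain_epochs),
                 channels = channels),
            class = "experiment_config")
}

experiment_recordings <- function(cfg, seed) {
  if (inherits(cfg$data, "synth_config")) {
    generate_dataset(cfg$n_recordings, cfg$data,
                     seizure_fraction = cfg$seizure_fraction, seed = seed)
  } else if (is.character(cfg$data) && length(cfg$data) == 1L) {
    paths <- sort(list.files(cfg$data, pattern = "\\.edf$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(paths)) stop_validation("no EDF files in %s", cfg$data)
    recs <- list()
    for (p in paths) {
      ann <- sub("\\.edf$", ".ann", p, ignore.case = TRUE)
      rec <- tryCatch(
        read_edf(p, annotation_path = if (file.exists(ann)) ann else NULL,
                 channels = cfg$channels),
        ictalnet_validation_error = function(e) {
          warning(sprintf("skipping %s: %s", basename(p), conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    }
    recs
  } else if (is.list(cfg$data)) {
    cfg$data
  } else stop_validation("unsupported data source")
}

# one arm x seed cell: returns list(report, model, norm, split)
run_arm <- function(cfg, multiplier, seed) {
  sub <- derive_seeds(seed, 5L)
  recs <- experiment_recordings(cfg, sub[1])
  ws <- segment_all(recs, window_s = cfg$window_s, overlap_s = cfg$overlap_s,
                    label_rule = cfg$label_rule)
  ws <- balance_windows(ws, cfg$balance, seed = sub[2])
  sp <- split_windows(ws, train_frac = cfg$train_frac, seed = sub[3],
                      stratified = !cfg$by_patient, by_patient = cfg$by_patient)
  stopifnot(length(intersect(sp$train_idx, sp$test_idx)) == 0L,
            length(union(sp$train_idx, sp$test_idx)) == n_windows(ws))
  norm <- fit_normalizer(sp$train)
  train <- apply_normalizer(sp$train, norm)
  test <- apply_normalizer(sp$test, norm)

  mcfg <- cfg$model_cfg
  mcfg$seed <- sub[4]
  model <- build_model(mcfg, dim(train$windows)[2], dim(train$windows)[3])

  if (multiplier > 0L) {
    pre <- train_model(model, train, epochs = cfg$pretrain_epochs)
    acfg <- cfg$aug_cfg
    acfg$multiplier <- multiplier
    acfg$seed <- sub[5]
    data_final <- amplify(train, pre, acfg)
  } else {
    data_final <- train
  }
  fit <- train_model(model, data_final, epochs = mcfg$epochs)
  list(report = evaluate_model(fit, test), model = fit, norm = norm,
       split = sp, train_size = n_windows(data_final))
}

#' Run the augmentation-multiplier experiment grid
#'
#' For every arm (multiplier) and seed, runs the full pipeline and
#' evaluates on the held-out windows; test indices never enter
#' augmentation or training (asserted each run). A failed arm is logged
#' and skipped; the remaining arms still run.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print progress.
#' @return Data frame with one row per arm: mean and sd of ACC, SEN and
#'   AUC over seeds, plus window counts. Per-cell reports are attached as
#'   attribute `"runs"`, and a reproducibility manifest (config hash,
#'   seeds, package version) as attribute `"manifest"`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  runs <- list()
  rows <- list()
  for (arm in cfg$arms) {
    cell <- list()
    ok <- TRUE
    for (s in cfg$seeds) {
      res <- tryCatch(run_arm(cfg, arm, s), error = function(e) {
        warning(sprintf("arm %d seed %d failed: %s", arm, s,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(res)) { ok <- FALSE; next }
      cell[[as.character(s)]] <- res$report
      if (verbose)
        message(sprintf("arm %d seed %d: ACC %.3f SEN %.3f AUC %.3f",
                        arm, s, res$report$acc, res$report$sen,
                        res$report$auc))
    }
    runs[[as.character(arm)]] <- cell
    if (!length(cell)) next
    acc <- vapply(cell, `[[`, 0, "acc")
    sen <- vapply(cell, `[[`, 0, "sen")
    auc <- vapply(cell, `[[`, 0, "auc")
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, n_seeds = length(cell),
      acc_mean = mean(acc), acc_sd = if (length(acc) > 1) sd(acc) else NA_real_,
      sen_mean = mean(sen), sen_sd = if (length(sen) > 1) sd(sen) else NA_real_,
      auc_mean = mean(auc), auc_sd = if (length(auc) > 1) sd(auc) else NA_real_,
      complete = ok)
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  attr(out, "manifest") <- experiment_manifest(cfg)
  out
}

experiment_manifest <- function(cfg) {
  list(config_hash = object_hash(cfg[setdiff(names(cfg), "data")]),
       data_hash = object_hash(cfg$data),
       arms = cfg$arms, seeds = cfg$seeds,
       package = as.character(utils::packageVersion("ictalnet")),
       r_version = R.version.string)
}

#' Attention-ablation comparison
#'
#' Runs matched arms with the attention layer enabled and bypassed
#' (identity), holding everything else (data, seeds, splits) fixed, and
#' reports per-arm metric deltas (attention minus no-attention).
#'
#' @param cfg an [experiment_config()].
#' @param verbose print progress.
#' @return List with `with_attention`, `without_attention` (tables as from
#'   [run_experiment()]) and `delta` (one row per arm).
#' @export
ablation_experiment <- function(cfg, verbose = FALSE) {
  cfg_on <- cfg
  cfg_on$model_cfg$use_attention <- TRUE
  cfg_off <- cfg
  cfg_off$model_cfg$use_attention <- FALSE
  t_on <- run_experiment(cfg_on, verbose = verbose)
  t_off <- run_experiment(cfg_off, verbose = verbose)
  common <- intersect(t_on$arm, t_off$arm)
  delta <- data.frame(
    arm = common,
    d_acc = t_on$acc_mean[match(common, t_on$arm)] -
      t_off$acc_mean[match(common, t_off$arm)],
    d_sen = t_on$sen_mean[match(common, t_on$arm)] -
      t_off$sen_mean[match(common, t_off$arm)],
    d_auc = t_on$auc_mean[match(common, t_on$arm)] -
      t_off$auc_mean[match(common, t_off$arm)])
  list(with_attention = t_on, without_attention = t_off, delta = delta)
}

#' Clean-versus-noisy evaluation probe
#'
#' Trains once per seed on clean data (arm as configured), then evaluates
#' the same model on the clean test windows and on copies perturbed with
#' broadband noise and baseline drift ([add_window_noise()]), with matched
#' test indices. Mimics running detection on non-denoised signals.
#'
#' @param cfg an [experiment_config()] (first arm is used).
#' @param noise_sd,drift_amp evaluation-time perturbation amplitudes, in
#'   normalized units.
#' @param verbose print progress.
#' @return Data frame with one row per seed and condition
#'   (`clean`/`noisy`).
#' @export
noise_probe <- function(cfg, noise_sd = 2, drift_amp = 1, verbose = FALSE) {
  arm <- cfg$arms[1]
  rows <- list()
  for (s in cfg$seeds) {
    res <- run_arm(cfg, arm, s)
    test_clean <- apply_normalizer(res$split$test, res$norm)
    test_noisy <- add_window_noise(test_clean, noise_sd = noise_sd,
                                   drift_amp = drift_amp, seed = s)
    for (cond in c("clean", "noisy")) {
      rep <- evaluate_model(res$model,
                            if (cond == "clean") test_clean else test_noisy)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, condition = cond, acc = rep$acc, sen = rep$sen,
        spe = rep$spe, auc = rep$auc)
      if (verbose)
        message(sprintf("seed %d %s: ACC %.3f AUC %.3f",
                        s, cond, rep$acc, rep$auc))
    }
  }
  do.call(rbind, rows)
}
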