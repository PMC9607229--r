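# Orchestration ---------------------------------------------------------------
#
# One-command reproduction of the full synthetic experiment: simulate ->
# preprocess -> fuse -> LOOCV on the train/validation subjects -> final-model
# test on the held-out subject -> report. A single global seed fans out to the
# per-stage seeds via a fixed offset scheme (+1 simulation, +2 test-subject
# draw, +100+fold LOOCV folds, +200 final model).

#' Experiment configuration
#'
#' Collects every knob of the synthetic experiment. Unknown arguments are
#' rejected, and the configuration is fully serializable (YAML) so any report
#' can be regenerated from its archived config and seed.
#'
#' @param n_subjects cohort size (>= 3: one test subject plus >= 2
#'   train/validation subjects for LOOCV).
#' @param seed global seed.
#' @param protocol a [protocol_spec()].
#' @param noise_cv,outlier_rate,outlier_factor breath-noise model.
#' @param assist_reduction ground-truth assistance effect.
#' @param imu_rate,emg_rate,out_rate simulation and timeline rates, Hz.
#' @param window,stride window geometry, samples.
#' @param model a `cnn_spec` or `lstm_spec`.
#' @param train a [train_config()].
#' @param test_subject subject id to hold out (default: seeded random draw).
#' @param out optional output directory for artifacts.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 8, seed = 1L,
                              protocol = protocol_spec(),
                              noise_cv = 0.10, outlier_rate = 0.01,
                              outlier_factor = 3, assist_reduction = 0.10,
                              imu_rate = 100, emg_rate = 1000, out_rate = NULL,
                              window = 300, stride = 30,
                              model = cnn_spec(), train = train_config(),
                              test_subject = NULL, out = NULL) {
  if (n_subjects < 3)
    stop("`n_subjects` must be >= 3 (one test subject plus >= 2 LOOCV subjects)",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 protocol = protocol, noise_cv = noise_cv,
                 outlier_rate = outlier_rate, outlier_factor = outlier_factor,
                 assist_reduction = assist_reduction,
                 imu_rate = imu_rate, emg_rate = emg_rate, out_rate = out_rate,
                 window = window, stride = stride, model = model, train = train,
                 test_subject = test_subject, out = out),
            class = "experiment_config")
}

#' Run the full synthetic experiment
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return object of class `eval_report`: `loocv` ([run_loocv()] report),
#'   `test` ([evaluate_on_test()] result), `mse_by_condition`, `agreement`
#'   and `fit` (pooled LOOCV per-phase agreement), `config`, `cohort`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating cohort of %d subjects (seed %d)", config$n_subjects, config$seed)
  cohort <- make_cohort(config$n_subjects, seed = config$seed + 1L)
  trials <- simulate_cohort_trials(cohort, config$protocol,
                                   seed = config$seed + 1L,
                                   noise_cv = config$noise_cv,
                                   outlier_rate = config$outlier_rate,
                                   outlier_factor = config$outlier_factor,
                                   assist_reduction = config$assist_reduction,
                                   imu_rate = config$imu_rate,
                                   emg_rate = config$emg_rate)
  say("processing %d trials", length(trials))
  pc <- proc_config(out_rate = config$out_rate)
  band_cap <- 0.45 * config$emg_rate
  pc$emg_band[2] <- min(pc$emg_band[2], band_cap)
  processed <- lapply(trials, process_trial, config = pc)
  test_subject <- config$test_subject
  if (is.null(test_subject))
    test_subject <- with_seed(config$seed + 2L, sample(cohort$subject_id, 1))
  say("holding out subject %s for testing", test_subject)
  split <- split_cohort(processed, test_subject)
  tc <- config$train
  tc$seed <- config$seed + 100L
  say("LOOCV over %d train/validation subjects",
      length(unique(vapply(split$train_val, `[[`, character(1), "subject_id"))))
  loocv <- run_loocv(split$train_val, model_spec = config$model, train_cfg = tc,
                     window = config$window, stride = config$stride)
  tc$seed <- config$seed + 200L
  say("final model training and test-subject evaluation")
  test <- evaluate_on_test(split$train_val, split$test,
                           model_spec = config$model, train_cfg = tc,
                           window = config$window, stride = config$stride)
  pp <- phase_pairs(loocv$predictions)
  report <- structure(
    list(loocv = loocv, test = test,
         mse_by_condition = mse_by_condition(loocv$predictions),
         agreement = bland_altman(pp$target, pp$estimate),
         fit = linear_fit(pp$target, pp$estimate),
         test_subject = test_subject, cohort = cohort, config = config),
    class = "eval_report")
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' Serialize an evaluation report and its config snapshot
#'
#' Writes `report.json` (metrics, agreement, error matrix) and `config.yaml`
#' to `dir`.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    test_subject = report$test_subject,
    loocv = list(folds = report$loocv$folds, summary = report$loocv$summary),
    test_metrics = report$test$metrics,
    agreement = report$agreement[c("bias", "loa_low", "loa_high", "sd")],
    fit = report$fit,
    mse_by_condition = as.data.frame(report$mse_by_condition))
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- report$config
  cfg$protocol <- unclass(cfg$protocol)
  cfg$model <- c(kind = class(report$config$model)[1], unclass(cfg$model))
  cfg$train <- unclass(cfg$train)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

# Trial bundle I/O -------------------------------------------------------------

BUNDLE_SCHEMA <- "1.0"

#' Write a trial recording to a directory-of-CSV bundle
#'
#' Layout: `breath.csv`, `hr.csv`, `emg.csv`, `imu_<segment>.csv` and
#' `meta.json` (subject, condition, phases, MVC references, ground truth,
#' schema version). Round-trips losslessly to reading precision.
#'
#' @param trial a `gait_trial`.
#' @param dir bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(d, f) data.table::fwrite(d, file.path(dir, f))
  fw(data.frame(time = trial$breath$time, vo2 = trial$breath$vo2,
                vco2 = trial$breath$vco2), "breath.csv")
  fw(data.frame(time = trial$hr$time, bpm = trial$hr$bpm), "hr.csv")
  fw(as.data.frame(trial$emg), "emg.csv")
  for (s in names(trial$imu)) {
    m <- cbind(trial$imu[[s]]$acc, trial$imu[[s]]$gyro)
    colnames(m) <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
    fw(as.data.frame(m), sprintf("imu_%s.csv", s))
  }
  meta <- list(schema_version = trial$schema_version,
               subject = as.list(trial$subject),
               speed = trial$speed, assisted = trial$assisted,
               phases = trial$phases, mvc = as.list(trial$mvc),
               truth = as.list(trial$truth),
               imu_rate = trial$imu_rate, emg_rate = trial$emg_rate)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial bundle written by [write_trial_bundle()]
#'
#' @param dir bundle directory.
#' @return a `gait_trial`.
#' @export
read_trial_bundle <- function(dir) {
  metaf <- file.path(dir, "meta.json")
  if (!file.exists(metaf)) stop("bundle is missing meta.json", call. = FALSE)
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  if (!identical(meta$schema_version, BUNDLE_SCHEMA))
    stop(sprintf("unsupported bundle schema '%s' (reader supports '%s')",
                 meta$schema_version, BUNDLE_SCHEMA), call. = FALSE)
  need <- c("breath.csv", "hr.csv", "emg.csv",
            sprintf("imu_%s.csv", IMU_SEGMENTS))
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("bundle is missing: ", paste(missing, collapse = ", "), call. = FALSE)
  fr <- function(f) data.table::fread(file.path(dir, f), data.table = FALSE)
  breath <- fr("breath.csv")
  hr <- fr("hr.csv")
  emg <- as.matrix(fr("emg.csv"))
  imu <- lapply(IMU_SEGMENTS, function(s) {
    m <- as.matrix(fr(sprintf("imu_%s.csv", s)))
    acc <- m[, 1:3]; gyr <- m[, 4:6]
    colnames(acc) <- c("x", "y", "z"); colnames(gyr) <- c("x", "y", "z")
    list(acc = acc, gyro = gyr)
  })
  names(imu) <- IMU_SEGMENTS
  subject <- as.data.frame(meta$subject, stringsAsFactors = FALSE)
  structure(list(subject = subject, subject_id = subject$subject_id,
                 speed = meta$speed, assisted = meta$assisted,
                 phases = as.data.frame(meta$phases),
                 breath = list(time = breath$time, vo2 = breath$vo2,
                               vco2 = breath$vco2),
                 imu = imu, emg = emg, mvc = unlist(meta$mvc),
                 hr = list(time = hr$time, bpm = hr$bpm),
                 truth = unlist(meta$truth),
                 imu_rate = meta$imu_rate, emg_rate = meta$emg_rate,
                 schema_version = meta$schema_version),
            class = "gait_trial")
}

#' Write a processed trial as a flat table
#'
#' One CSV row per timeline sample: `time`, the 25 estimator channels, the
#' step EE target (`target_wkg`) and the phase label.
#'
#' @param pt a `processed_trial`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_processed_trial <- function(pt, path) {
  stopifnot(inherits(pt, "processed_trial"))
  df <- data.frame(time = pt$time, pt$channels,
                   target_wkg = pt$target$step, phase = pt$phase_label,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' JSON checkpoint holding the architecture spec, input geometry, flattened
#' parameters and training history; `load_model()` restores a model whose
#' predictions match the saved one's to full double precision.
#'
#' @param model a trained or untrained `ee_model`.
#' @param path checkpoint path (JSON).
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ee_model"))
  ck <- list(kind = model$kind,
             spec = unclass(model$spec),
             n_channels = model$n_channels, window = model$window,
             theta = unlist(model$params, use.names = FALSE),
             history = model$history)
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (ck$kind == "cnn")
    build_cnn(cnn_spec(n_filters = ck$spec$n_filters,
                       filter_length = ck$spec$filter_length,
                       fc_neurons = ck$spec$fc_neurons,
                       dropout_p = ck$spec$dropout_p),
              n_channels = ck$n_channels, window = ck$window, seed = 1L)
  else
    build_lstm(lstm_spec(hidden = ck$spec$hidden,
                         fc_neurons = ck$spec$fc_neurons,
                         dropout_p = ck$spec$dropout_p),
               n_channels = ck$n_channels, window = ck$window, seed = 1L)
  model$params <- utils::relist(ck$theta, model$params)
  model$history <- ck$history
  model
}

# Plots -------------------------------------------------------------------------

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Bland-Altman plot
#' @param ba a [bland_altman()] object.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  need_ggplot()
  ggplot2::ggplot(ba$pairs, ggplot2::aes(x = average, y = difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_low, ba$loa_high),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::labs(x = "mean of target and estimate (W/kg)",
                  y = "estimate - target (W/kg)")
}

#' MSE heatmap by speed and condition
#' @param m a [mse_by_condition()] matrix.
#' @return a ggplot object.
#' @export
plot_mse_heatmap <- function(m) {
  need_ggplot()
  df <- expand.grid(speed = rownames(m), condition = colnames(m))
  df$mse <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = speed, fill = mse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", mse))) +
    ggplot2::labs(x = NULL, y = "gait speed (m/s)", fill = "MSE\n(W/kg)^2")
}
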