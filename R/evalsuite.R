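# Evaluation harness -----------------------------------------------------------
#
# Leave-one-subject-out cross-validation with per-fold MSE / RMSE / NMSE /
# Spearman correlation, Bland-Altman agreement on per-phase steady-state pairs,
# linear-fit R-squared, and the speed x condition error decomposition.

#' Regression metrics against the calorimetry-derived target
#'
#' `mse` is the mean squared difference (dimensionally (W/kg)^2), `rmse` its
#' square root (W/kg), `nmse` the goodness-of-fit index `1 - SSE/SST` (1 =
#' perfect, 0 = no better than the target mean), and `scc` Spearman's rank
#' correlation (Pearson correlation of average-ranked values). For a constant
#' target, `nmse` and `scc` are undefined and returned as `NA`.
#'
#' @param target,estimate equal-length numeric vectors (>= 2 values), W/kg.
#' @return list with `mse`, `rmse`, `nmse`, `scc`.
#' @export
regression_metrics <- function(target, estimate) {
  if (length(target) != length(estimate) || length(target) < 2)
    stop("`target` and `estimate` must be equal-length vectors of >= 2 values",
         call. = FALSE)
  d <- estimate - target
  mse <- mean(d^2)
  sst <- sum((target - mean(target))^2)
  if (sst <= 0) {
    nmse <- NA_real_; scc <- NA_real_
  } else {
    nmse <- 1 - sum(d^2) / sst
    scc <- if (sd(estimate) == 0) NA_real_
           else cor(target, estimate, method = "spearman")
  }
  list(mse = mse, rmse = sqrt(mse), nmse = nmse, scc = scc)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = estimate - target`; bias is their mean and the 95% limits
#' of agreement are `bias +/- 1.959964 * SD(d)`. The (average, difference)
#' pairs are returned for plotting.
#'
#' @param target,estimate equal-length numeric vectors (>= 3 values).
#' @param z limit multiplier (1.959964 for 95% limits).
#' @return list of class `bland_altman`: `bias`, `loa_low`, `loa_high`, `sd`,
#'   `pairs` (data.frame with `average`, `difference`).
#' @export
bland_altman <- function(target, estimate, z = 1.959964) {
  if (length(target) != length(estimate) || length(target) < 3)
    stop("Bland-Altman needs >= 3 paired values", call. = FALSE)
  d <- estimate - target
  bias <- mean(d); s <- sd(d)
  structure(list(bias = bias, loa_low = bias - z * s, loa_high = bias + z * s,
                 sd = s,
                 pairs = data.frame(average = (target + estimate) / 2,
                                    difference = d)),
            class = "bland_altman")
}

#' Ordinary least-squares fit of estimate on target
#'
#' @param target,estimate equal-length numeric vectors (>= 3 values); target
#'   must not be constant.
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation).
#' @export
linear_fit <- function(target, estimate) {
  if (length(target) != length(estimate) || length(target) < 3)
    stop("linear fit needs >= 3 paired values", call. = FALSE)
  if (sd(target) == 0) stop("target is constant; linear fit undefined", call. = FALSE)
  fit <- lm(estimate ~ target)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = cor(target, estimate)^2)
}

#' Mean squared error by gait speed and walking condition
#'
#' Cell `(i, j)` holds the mean squared error over all prediction records with
#' speed `i` and condition `j`; empty cells are `NA` (missing, not zero). The
#' record-weighted mean of the cells equals the pooled MSE.
#'
#' @param predictions data.frame with columns `speed`, `assisted`, `target`,
#'   `estimate`.
#' @return speeds x conditions matrix with a `pooled_mse` attribute.
#' @export
mse_by_condition <- function(predictions) {
  stopifnot(all(c("speed", "assisted", "target", "estimate") %in% names(predictions)))
  speeds <- sort(unique(predictions$speed))
  conds <- c("non_assisted", "assisted")
  m <- matrix(NA_real_, length(speeds), 2,
              dimnames = list(format(speeds), conds))
  se <- (predictions$estimate - predictions$target)^2
  for (i in seq_along(speeds)) for (j in 1:2) {
    sel <- predictions$speed == speeds[i] &
      predictions$assisted == (conds[j] == "assisted")
    if (any(sel)) m[i, j] <- mean(se[sel])
  }
  attr(m, "pooled_mse") <- mean(se)
  m
}

#' Per-phase steady-state agreement pairs
#'
#' Aggregates window-level predictions to one (target, estimate) pair per trial
#' phase — the resolution at which steady-state agreement is assessed.
#'
#' @param predictions data.frame with `trial_id`, `phase`, `target`, `estimate`.
#' @return data.frame with one row per (trial_id, phase).
#' @export
phase_pairs <- function(predictions) {
  key <- interaction(predictions$trial_id, predictions$phase, drop = TRUE)
  data.frame(trial_id = tapply(predictions$trial_id, key, `[`, 1),
             phase = tapply(predictions$phase, key, `[`, 1),
             subject = tapply(predictions$subject, key, `[`, 1),
             target = as.numeric(tapply(predictions$target, key, mean)),
             estimate = as.numeric(tapply(predictions$estimate, key, mean)),
             row.names = NULL)
}

fit_fold_model <- function(model_spec, dataset, train_cfg, n_channels, window,
                           seed) {
  if (identical(model_spec, "stub"))
    return(train_stub(stub_regressor(), dataset))
  model <- build_regressor(model_spec, n_channels = n_channels,
                           window = window, seed = seed)
  cfg <- train_cfg
  cfg$seed <- seed
  train_regressor(model, dataset, cfg)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the min-max scaler and the regressor are fitted on the
#' remaining subjects' trials only, then evaluated on the held-out subject's
#' windows. Metrics are reported per fold and aggregated (mean and SD across
#' folds); the fitted per-fold scalers and seeds are retained for audit.
#'
#' @param trials list of `processed_trial` objects from >= 2 subjects.
#' @param model_spec a `cnn_spec` / `lstm_spec`, or `"stub"` for the
#'   mean-predicting stub (bookkeeping runs without training).
#' @param train_cfg a [train_config()]; per-fold seeds are derived as
#'   `train_cfg$seed + fold index`.
#' @param window,stride window geometry, samples.
#' @return object of class `loocv_report`: `folds` (per-fold metrics
#'   data.frame), `summary` (mean/SD), `predictions` (window-level records),
#'   `scalers`, `seeds`.
#' @export
run_loocv <- function(trials, model_spec = cnn_spec(),
                      train_cfg = train_config(), window = 300, stride = 30) {
  ids <- vapply(trials, `[[`, character(1), "subject_id")
  subjects <- unique(ids)
  if (length(subjects) < 2) stop("LOOCV needs >= 2 subjects", call. = FALSE)
  counts <- table(ids)
  if (any(counts == 0)) stop("subject without trials", call. = FALSE)
  folds <- list(); preds <- list(); scalers <- list(); seeds <- integer(0)
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    tr <- trials[ids != s]; va <- trials[ids == s]
    scaler <- fit_minmax(tr)
    ds_tr <- build_dataset(tr, scaler, length = window, stride = stride)
    seed_k <- train_cfg$seed + k
    model <- fit_fold_model(model_spec, ds_tr, train_cfg,
                            n_channels = dim(ds_tr$x)[3], window = window,
                            seed = seed_k)
    ds_va <- build_dataset(va, scaler, length = window, stride = stride)
    est <- predict(model, ds_va)
    met <- regression_metrics(ds_va$y, est)
    folds[[k]] <- data.frame(subject = s, mse = met$mse, rmse = met$rmse,
                             nmse = met$nmse, scc = met$scc)
    preds[[k]] <- data.frame(subject = ds_va$subject, trial_id = ds_va$trial_id,
                             speed = ds_va$speed, assisted = ds_va$assisted,
                             phase = ds_va$phase, target = ds_va$y,
                             estimate = est)
    scalers[[s]] <- scaler
    seeds[k] <- seed_k
  }
  folds <- do.call(rbind, folds)
  predictions <- do.call(rbind, preds)
  summary <- data.frame(
    metric = c("mse", "rmse", "nmse", "scc"),
    mean = vapply(c("mse", "rmse", "nmse", "scc"),
                  function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(c("mse", "rmse", "nmse", "scc"),
                function(m) sd(folds[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(folds = folds, summary = summary, predictions = predictions,
                 scalers = scalers, seeds = seeds),
            class = "loocv_report")
}

#' Evaluate a final model on the held-out test subject
#'
#' Fits the scaler and model on all train/validation trials, then reports
#' window-level metrics, per-phase Bland-Altman agreement and linear fit on the
#' test subject.
#'
#' @param train_val,test processed-trial lists from [split_cohort()].
#' @param model_spec,train_cfg,window,stride as in [run_loocv()].
#' @return list with `metrics`, `agreement`, `fit`, `predictions`, `model`,
#'   `scaler`.
#' @export
evaluate_on_test <- function(train_val, test, model_spec = cnn_spec(),
                             train_cfg = train_config(), window = 300,
                             stride = 30) {
  scaler <- fit_minmax(train_val)
  ds_tr <- build_dataset(train_val, scaler, length = window, stride = stride)
  model <- fit_fold_model(model_spec, ds_tr, train_cfg,
                          n_channels = dim(ds_tr$x)[3], window = window,
                          seed = train_cfg$seed)
  ds_te <- build_dataset(test, scaler, length = window, stride = stride)
  est <- predict(model, ds_te)
  predictions <- data.frame(subject = ds_te$subject, trial_id = ds_te$trial_id,
                            speed = ds_te$speed, assisted = ds_te$assisted,
                            phase = ds_te$phase, target = ds_te$y,
                            estimate = est)
  pp <- phase_pairs(predictions)
  list(metrics = regression_metrics(ds_te$y, est),
       agreement = bland_altman(pp$target, pp$estimate),
       fit = linear_fit(pp$target, pp$estimate),
       predictions = predictions, model = model, scaler = scaler)
}
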