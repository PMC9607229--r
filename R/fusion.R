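# Dataset assembly ------------------------------------------------------------
#
# Leakage-safe min-max scaling to [-1, 1] (fitted on training subjects only),
# sliding-window extraction, and subject-wise cohort splitting.

#' Fit a per-channel min-max scaler
#'
#' Channel minima/maxima are computed over all samples of the supplied
#' (training) trials; `transform` maps the fitted range onto `[-1, 1]`.
#' Constant channels map to 0. Held-out data are NOT clipped, so transformed
#' values may exceed `[-1, 1]`.
#'
#' @param trials list of `processed_trial` objects (>= 1).
#' @return object of class `minmax_scaler` with `min` and `max` per channel.
#' @export
fit_minmax <- function(trials) {
  if (length(trials) < 1) stop("need at least one training trial", call. = FALSE)
  mats <- lapply(trials, function(tr) tr$channels)
  mins <- do.call(pmin, lapply(mats, function(m) apply(m, 2, min)))
  maxs <- do.call(pmax, lapply(mats, function(m) apply(m, 2, max)))
  structure(list(min = mins, max = maxs), class = "minmax_scaler")
}

#' Apply / invert a min-max scaler
#'
#' @param scaler a [fit_minmax()] object.
#' @param x matrix with the scaler's channels as columns, or a
#'   `processed_trial` (its `channels` are transformed in place).
#' @return same shape as `x`, rescaled.
#' @export
minmax_transform <- function(scaler, x) {
  if (inherits(x, "processed_trial")) {
    x$channels <- minmax_transform(scaler, x$channels)
    return(x)
  }
  rng <- scaler$max - scaler$min
  ctr <- (scaler$max + scaler$min) / 2
  out <- sweep(x, 2, ctr)
  out <- sweep(out, 2, ifelse(rng > 0, rng / 2, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' @rdname minmax_transform
#' @export
minmax_inverse <- function(scaler, x) {
  rng <- scaler$max - scaler$min
  ctr <- (scaler$max + scaler$min) / 2
  out <- sweep(x, 2, ifelse(rng > 0, rng / 2, 1), "*")
  sweep(out, 2, ctr, "+")
}

#' Cut a processed trial into supervised windows
#'
#' Sliding windows of `length` samples at the given `stride`; each window's
#' target is the step-target value at its final sample (causal labeling), and
#' windows straddling a phase boundary are labeled by the final sample's phase.
#'
#' @param trial a `processed_trial` (scaled or raw).
#' @param length window length, samples.
#' @param stride window stride, samples.
#' @return object of class `windowed_dataset`: `x` (n x length x 25 array),
#'   `y` (W/kg), and per-window `subject`, `trial_id`, `speed`, `assisted`,
#'   `phase`.
#' @export
make_windows <- function(trial, length = 300, stride = 30) {
  n <- nrow(trial$channels)
  if (length > n)
    stop(sprintf("window length %d exceeds trial length %d", length, n), call. = FALSE)
  if (stride < 1) stop("`stride` must be >= 1", call. = FALSE)
  starts <- seq(1L, n - length + 1L, by = stride)
  ends <- starts + length - 1L
  x <- array(0, dim = c(base::length(starts), length, ncol(trial$channels)),
             dimnames = list(NULL, NULL, colnames(trial$channels)))
  for (i in seq_along(starts))
    x[i, , ] <- trial$channels[starts[i]:ends[i], ]
  trial_id <- paste(trial$subject_id, trial$speed,
                    if (trial$assisted) "assisted" else "non_assisted", sep = "_")
  structure(list(x = x,
                 y = trial$target$step[ends],
                 subject = rep(trial$subject_id, base::length(starts)),
                 trial_id = rep(trial_id, base::length(starts)),
                 speed = rep(trial$speed, base::length(starts)),
                 assisted = rep(trial$assisted, base::length(starts)),
                 phase = trial$phase_label[ends]),
            class = "windowed_dataset")
}

#' Concatenate windowed datasets
#' @param ... `windowed_dataset` objects (or one list of them).
#' @return a single `windowed_dataset` in deterministic (input) order.
#' @export
bind_windows <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && !inherits(ds[[1]], "windowed_dataset")) ds <- ds[[1]]
  stopifnot(all(vapply(ds, inherits, logical(1), "windowed_dataset")))
  ns <- vapply(ds, function(d) dim(d$x)[1], integer(1))
  d1 <- dim(ds[[1]]$x)
  x <- array(0, dim = c(sum(ns), d1[2], d1[3]),
             dimnames = list(NULL, NULL, dimnames(ds[[1]]$x)[[3]]))
  at <- 0L
  for (d in ds) {
    x[at + seq_len(dim(d$x)[1]), , ] <- d$x
    at <- at + dim(d$x)[1]
  }
  cat_field <- function(f) do.call(c, lapply(ds, `[[`, f))
  structure(list(x = x, y = cat_field("y"), subject = cat_field("subject"),
                 trial_id = cat_field("trial_id"), speed = cat_field("speed"),
                 assisted = cat_field("assisted"), phase = cat_field("phase")),
            class = "windowed_dataset")
}

#' Build a scaled windowed dataset from processed trials
#'
#' @param trials list of `processed_trial` objects.
#' @param scaler a fitted [fit_minmax()] scaler (fit it on training trials
#'   only).
#' @param length,stride window geometry, samples.
#' @return a `windowed_dataset`.
#' @export
build_dataset <- function(trials, scaler, length = 300, stride = 30) {
  bind_windows(lapply(trials, function(tr)
    make_windows(minmax_transform(scaler, tr), length = length, stride = stride)))
}

#' Split a cohort's trials into train/validation and test sets by subject
#'
#' All trials of `test_subject` are isolated; by contract, scaler fitting and
#' model training are restricted to the `train_val` side.
#'
#' @param trials list of trials (raw or processed) carrying `subject_id`.
#' @param test_subject subject id to hold out.
#' @return list with `train_val` and `test` trial lists.
#' @export
split_cohort <- function(trials, test_subject) {
  ids <- vapply(trials, `[[`, character(1), "subject_id")
  if (length(unique(ids)) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (!test_subject %in% ids)
    stop(sprintf("unknown subject id '%s'", test_subject), call. = FALSE)
  list(train_val = trials[ids != test_subject],
       test = trials[ids == test_subject])
}
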