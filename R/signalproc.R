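# Conditioning chains ---------------------------------------------------------
#
# Turns raw trial streams into the 25 estimator channels on a common timeline
# and the step-like steady-state energy-expenditure target:
#   - breath gas exchange -> Brockway power -> last-3-min CI-trimmed mean per
#     phase -> body-mass normalized step signal (W/kg);
#   - heart rate -> same steady-state extraction -> divided by age-predicted
#     maximal HR;
#   - IMU triplets -> 5 Hz zero-lag lowpass -> vector magnitude -> 0.1 Hz
#     lowpass;
#   - EMG -> 20-450 Hz zero-lag bandpass -> rectification -> 2 Hz envelope ->
#     MVC normalization -> 0.1 Hz lowpass -> per-side lower/upper-leg sums.

#' Brockway conversion of gas exchange to metabolic power
#'
#' `power = 16.58 * vo2 + 4.51 * vco2` with gas rates in mL/s and power in W
#' (coefficients are J per mL of gas).
#'
#' @param vo2,vco2 oxygen uptake and carbon-dioxide output, mL/s (>= 0),
#'   recycled element-wise.
#' @return metabolic power, W.
#' @export
brockway_power <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    stop("gas exchange rates must be non-negative", call. = FALSE)
  BROCKWAY_O2 * vo2 + BROCKWAY_CO2 * vco2
}

#' Steady-state value of a noisy series
#'
#' Restricts the series to the last `window` seconds before `phase_end`,
#' removes samples outside `mean +/- z(ci_level) * SD` in a single pass
#' (outlier trimming at the 95% confidence level by default), and returns the
#' mean of the survivors. If the trim would reject everything, the untrimmed
#' mean is returned with a warning.
#'
#' @param values numeric series.
#' @param time timestamps, seconds.
#' @param phase_end end of the phase, seconds.
#' @param window extraction window, seconds (default 180 = last 3 minutes).
#' @param ci_level confidence level of the trim (z = 1.959964 at 0.95).
#' @return scalar steady-state value.
#' @export
steady_state_value <- function(values, time, phase_end, window = 180,
                               ci_level = 0.95) {
  sel <- time > phase_end - window & time <= phase_end
  v <- values[sel]
  if (length(v) < 3)
    stop(sprintf("need >= 3 samples in the last %s s before t = %s (found %d)",
                 format(window), format(phase_end), length(v)), call. = FALSE)
  z <- qnorm(1 - (1 - ci_level) / 2)
  m <- mean(v); s <- sd(v)
  keep <- abs(v - m) <= z * s
  if (!any(keep)) {
    warning("confidence-interval trim rejected all samples; using untrimmed mean")
    return(m)
  }
  mean(v[keep])
}

#' Build the step-like steady-state EE target of a trial
#'
#' Per phase: Brockway power of the breath series, steady-state extraction over
#' the last `window` seconds (clipped to the phase length), normalized by body
#' mass; the value is held constant across the phase on the common timeline.
#'
#' @param breath list with `time`, `vo2`, `vco2` (see [synth_breath_series()]).
#' @param phases phase table.
#' @param body_mass kg (> 0).
#' @param rate timeline rate, Hz.
#' @param window,ci_level steady-state extraction parameters.
#' @return list of class `steady_state_target`: `values` (named per phase,
#'   W/kg), `step` (length `duration * rate`), `time`, `phases`.
#' @export
build_step_target <- function(breath, phases, body_mass, rate = 100,
                              window = 180, ci_level = 0.95) {
  assert_scalar_num(body_mass, "body_mass", lower = 1e-9)
  phases <- validate_phases(phases)
  power <- brockway_power(breath$vo2, breath$vco2)
  vals <- vapply(seq_len(nrow(phases)), function(i) {
    w <- min(window, phases$end[i] - phases$start[i])
    steady_state_value(power, breath$time, phases$end[i], window = w,
                       ci_level = ci_level) / body_mass
  }, numeric(1))
  names(vals) <- phases$label
  dur <- phases$end[nrow(phases)]
  n <- round(dur * rate)
  tl <- (seq_len(n) - 1) / rate
  step <- numeric(n)
  for (i in seq_len(nrow(phases)))
    step[tl >= phases$start[i] & tl < phases$end[i]] <- vals[i]
  structure(list(values = vals, step = step, time = tl, phases = phases),
            class = "steady_state_target")
}

#' Normalized heart-rate step channel
#'
#' Applies the same steady-state extraction as the EE target to the beat-level
#' heart-rate series, then divides by the subject's maximal heart rate.
#'
#' @param hr list with `time`, `bpm`.
#' @param subject cohort row with `hr_max`.
#' @param phases phase table.
#' @param rate timeline rate, Hz.
#' @param window,ci_level steady-state extraction parameters.
#' @return list: `values` (per phase, fraction of `hr_max`), `step`, `time`.
#' @export
process_hr <- function(hr, subject, phases, rate = 100, window = 180,
                       ci_level = 0.95) {
  if (is.null(subject$hr_max) || !is.finite(subject$hr_max) || subject$hr_max <= 0)
    stop("subject `hr_max` is undefined", call. = FALSE)
  if (any(hr$bpm <= 0)) stop("heart rate must be positive", call. = FALSE)
  phases <- validate_phases(phases)
  vals <- vapply(seq_len(nrow(phases)), function(i) {
    w <- min(window, phases$end[i] - phases$start[i])
    steady_state_value(hr$bpm, hr$time, phases$end[i], window = w,
                       ci_level = ci_level) / subject$hr_max
  }, numeric(1))
  names(vals) <- phases$label
  dur <- phases$end[nrow(phases)]
  n <- round(dur * rate)
  tl <- (seq_len(n) - 1) / rate
  step <- numeric(n)
  for (i in seq_len(nrow(phases)))
    step[tl >= phases$start[i] & tl < phases$end[i]] <- vals[i]
  list(values = vals, step = step, time = tl)
}

# steady-state initial conditions for an IIR filter (unit-step matching),
# solving the companion-form fixed point of the direct-form II transposed state
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1) return(numeric(0))
  zin <- diag(n - 1) - cbind(-a[-1], rbind(diag(n - 2), rep(0, n - 2)))
  zid <- b[-1] - a[-1] * b[1]
  solve(zin, zid)
}

#' Zero-lag Butterworth filtering
#'
#' Applies a Butterworth design once in each direction (zero net phase,
#' squared magnitude response) with odd-reflection padding and steady-state
#' initial conditions at each pass. The two pass orders (forward-backward and
#' backward-forward) are averaged, which makes time-reversal equivariance
#' `filter(rev(x)) == rev(filter(x))` exact in floating point and leaves
#' constants unchanged. A fourth-order zero-lag filter corresponds to the
#' default `order = 2` design applied in both directions.
#'
#' @param x numeric signal.
#' @param cutoff cutoff frequency in Hz (length 1 for `low`, length 2 for
#'   `pass`), strictly below the Nyquist rate.
#' @param rate sampling rate, Hz.
#' @param type `"low"` or `"pass"`.
#' @param order design order of the single-pass filter (effective order is
#'   doubled by the two-direction application).
#' @param padlen reflection padding length; defaults to one period of the
#'   lowest cutoff (at least three filter lengths), clipped to the signal.
#' @return filtered signal, same length as `x`.
#' @export
zero_lag_butterworth <- function(x, cutoff, rate, type = c("low", "pass"),
                                 order = 2, padlen = NULL) {
  type <- match.arg(type)
  if (any(cutoff >= rate / 2) || any(cutoff <= 0))
    stop(sprintf("cutoff (%s Hz) must lie strictly inside (0, Nyquist = %s Hz)",
                 paste(cutoff, collapse = ", "), rate / 2), call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  bf <- signal::butter(order, cutoff / (rate / 2), type = type)
  b <- bf$b / bf$a[1]; a <- bf$a / bf$a[1]
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b))); a <- c(a, rep(0, m - length(a)))
  zi <- lfilter_zi(b, a)
  n <- length(x)
  if (is.null(padlen))
    padlen <- max(3L * (m - 1L), ceiling(rate / min(cutoff)))
  padlen <- min(padlen, n - 1L)
  two_pass <- function(xs) {
    np <- length(xs)
    xp <- c(2 * xs[1] - xs[(padlen + 1):2], xs,
            2 * xs[np] - xs[(np - 1):(np - padlen)])
    y <- df2t_filter(b, a, xp, zi * xp[1])
    y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
    y[(padlen + 1):(padlen + np)]
  }
  (two_pass(x) + rev(two_pass(rev(x)))) / 2
}

#' Kinematic magnitude channels
#'
#' Per segment and per quantity (acceleration, angular velocity): component-wise
#' 5 Hz zero-lag lowpass, Euclidean magnitude, then 0.1 Hz lowpass preserving
#' the slow level changes of walking onset/offset.
#'
#' @param imu per-segment list with `acc` and `gyro` N x 3 matrices.
#' @param rate sampling rate, Hz.
#' @param component_lowpass,envelope_lowpass cutoffs, Hz.
#' @param order single-pass design order.
#' @return N x 16 matrix; columns `acc_<segment>` then `gyro_<segment>` in the
#'   fixed alphabetical segment order.
#' @export
process_kinematics <- function(imu, rate = 100, component_lowpass = 5,
                               envelope_lowpass = 0.1, order = 2) {
  missing <- setdiff(IMU_SEGMENTS, names(imu))
  if (length(missing))
    stop("missing IMU segments: ", paste(missing, collapse = ", "), call. = FALSE)
  one <- function(xyz) {
    f <- apply(xyz, 2, zero_lag_butterworth, cutoff = component_lowpass,
               rate = rate, type = "low", order = order)
    mag <- sqrt(rowSums(f^2))
    zero_lag_butterworth(mag, envelope_lowpass, rate, "low", order = order)
  }
  acc <- sapply(IMU_SEGMENTS, function(s) one(imu[[s]]$acc))
  gyr <- sapply(IMU_SEGMENTS, function(s) one(imu[[s]]$gyro))
  out <- cbind(acc, gyr)
  colnames(out) <- c(paste0("acc_", IMU_SEGMENTS), paste0("gyro_", IMU_SEGMENTS))
  out
}

#' MVC-normalized EMG sum channels
#'
#' Per channel: zero-lag bandpass (20-450 Hz by default, upper edge capped at
#' 45% of the sampling rate), full-wave rectification, 2 Hz lowpass envelope,
#' division by the muscle's MVC envelope reference, 0.1 Hz lowpass; then
#' per-side sums (lower leg = TA + GL, upper leg = BF + VL) decimated onto the
#' common timeline.
#'
#' @param emg N x 8 matrix with columns named by muscle
#'   (`ta/gl/bf/vl` x `_l/_r`).
#' @param mvc named positive per-muscle MVC envelope references.
#' @param rate EMG sampling rate, Hz.
#' @param out_rate output timeline rate, Hz (must divide `rate`).
#' @param band bandpass edges, Hz.
#' @param envelope_lowpass,smooth_lowpass cutoffs, Hz.
#' @param order single-pass design order.
#' @return (N * out_rate / rate) x 4 matrix, columns `lsll`, `lsul`, `rsll`,
#'   `rsul` (left/right sum of lower/upper leg).
#' @export
process_emg <- function(emg, mvc, rate = 1000, out_rate = 100,
                        band = c(20, 450), envelope_lowpass = 2,
                        smooth_lowpass = 0.1, order = 2) {
  if (ncol(emg) != 8)
    stop(sprintf("expected 8 EMG channels, got %d", ncol(emg)), call. = FALSE)
  missing <- setdiff(EMG_MUSCLES, colnames(emg))
  if (length(missing))
    stop("missing EMG channels: ", paste(missing, collapse = ", "), call. = FALSE)
  if (any(mvc[EMG_MUSCLES] <= 0) || any(!is.finite(mvc[EMG_MUSCLES])))
    stop("MVC references must be positive for all muscles", call. = FALSE)
  if (rate %% out_rate != 0)
    stop("`out_rate` must divide the EMG sampling rate", call. = FALSE)
  band[2] <- min(band[2], 0.45 * rate)
  env <- sapply(EMG_MUSCLES, function(m) {
    x <- zero_lag_butterworth(emg[, m], band, rate, "pass", order = order)
    x <- abs(x)
    x <- zero_lag_butterworth(x, envelope_lowpass, rate, "low", order = order)
    x <- x / mvc[[m]]
    zero_lag_butterworth(x, smooth_lowpass, rate, "low", order = order)
  })
  dec <- seq(1, nrow(env), by = rate / out_rate)
  out <- cbind(lsll = env[dec, "ta_l"] + env[dec, "gl_l"],
               lsul = env[dec, "bf_l"] + env[dec, "vl_l"],
               rsll = env[dec, "ta_r"] + env[dec, "gl_r"],
               rsul = env[dec, "bf_r"] + env[dec, "vl_r"])
  out
}

# fixed, documented channel order of the fused estimator set
channel_names <- function() {
  c(paste0("acc_", IMU_SEGMENTS), paste0("gyro_", IMU_SEGMENTS),
    "lsll", "lsul", "rsll", "rsul",
    "hr_norm", "speed", "gender", "age", "height")
}

#' Assemble the fused estimator channel set
#'
#' Emits exactly 25 channels on the common timeline, in a fixed documented
#' order: 16 kinematic magnitudes, 4 EMG sums, normalized HR, gait speed, and
#' the anthropometric constants gender (F = 0, M = 1), age and height.
#'
#' @param kinematics N x 16 matrix from [process_kinematics()].
#' @param emg_sums N x 4 matrix from [process_emg()].
#' @param hr_step normalized HR step signal, length N.
#' @param speed trial gait speed, m/s.
#' @param subject cohort row.
#' @return N x 25 matrix with `channel_names()` columns.
#' @export
assemble_channels <- function(kinematics, emg_sums, hr_step, speed, subject) {
  n <- nrow(kinematics)
  lens <- c(emg = nrow(emg_sums), hr = length(hr_step))
  if (any(lens != n))
    stop("timeline mismatch: ", paste(names(lens)[lens != n], collapse = ", "),
         " differ from the kinematic timeline", call. = FALSE)
  out <- cbind(kinematics, emg_sums,
               hr_norm = hr_step,
               speed = rep(speed, n),
               gender = rep(if (subject$gender == "M") 1 else 0, n),
               age = rep(as.numeric(subject$age), n),
               height = rep(as.numeric(subject$height), n))
  colnames(out) <- channel_names()
  out
}

#' Processing configuration
#'
#' All cutoffs, the steady-state window, the trim level, and the common
#' timeline rate in one place.
#'
#' @param out_rate common timeline rate, Hz; defaults to the trial's IMU rate.
#' @param kin_lowpass,smooth_lowpass,emg_band,emg_envelope_lowpass cutoffs, Hz.
#' @param ss_window steady-state window, seconds.
#' @param ci_level trim confidence level.
#' @param filter_order single-pass Butterworth design order.
#' @return list of class `proc_config`.
#' @export
proc_config <- function(out_rate = NULL, kin_lowpass = 5, smooth_lowpass = 0.1,
                        emg_band = c(20, 450), emg_envelope_lowpass = 2,
                        ss_window = 180, ci_level = 0.95, filter_order = 2) {
  structure(list(out_rate = out_rate, kin_lowpass = kin_lowpass,
                 smooth_lowpass = smooth_lowpass, emg_band = emg_band,
                 emg_envelope_lowpass = emg_envelope_lowpass,
                 ss_window = ss_window, ci_level = ci_level,
                 filter_order = filter_order),
            class = "proc_config")
}

#' Process one trial end to end
#'
#' Runs every conditioning chain and assembles the 25-channel estimator set
#' plus the step-like EE target.
#'
#' @param trial a `gait_trial`.
#' @param config a [proc_config()].
#' @return object of class `processed_trial`: `channels` (N x 25), `target`
#'   ([build_step_target()] result), plus trial metadata.
#' @export
process_trial <- function(trial, config = proc_config()) {
  stopifnot(inherits(trial, "gait_trial"))
  rate <- trial$imu_rate
  out_rate <- if (is.null(config$out_rate)) rate else config$out_rate
  if (rate %% out_rate != 0)
    stop("`out_rate` must divide the IMU rate", call. = FALSE)
  kin <- process_kinematics(trial$imu, rate = rate,
                            component_lowpass = config$kin_lowpass,
                            envelope_lowpass = config$smooth_lowpass,
                            order = config$filter_order)
  if (out_rate < rate)
    kin <- kin[seq(1, nrow(kin), by = rate / out_rate), , drop = FALSE]
  emg <- process_emg(trial$emg, trial$mvc, rate = trial$emg_rate,
                     out_rate = out_rate, band = config$emg_band,
                     envelope_lowpass = config$emg_envelope_lowpass,
                     smooth_lowpass = config$smooth_lowpass,
                     order = config$filter_order)
  target <- build_step_target(trial$breath, trial$phases,
                              trial$subject$body_mass, rate = out_rate,
                              window = config$ss_window,
                              ci_level = config$ci_level)
  hr <- process_hr(trial$hr, trial$subject, trial$phases, rate = out_rate,
                   window = config$ss_window, ci_level = config$ci_level)
  channels <- assemble_channels(kin, emg, hr$step, trial$speed, trial$subject)
  phase_lab <- character(nrow(channels))
  for (i in seq_len(nrow(trial$phases)))
    phase_lab[target$time >= trial$phases$start[i] &
              target$time < trial$phases$end[i]] <- trial$phases$label[i]
  structure(list(subject = trial$subject, subject_id = trial$subject_id,
                 speed = trial$speed, assisted = trial$assisted,
                 phases = trial$phases, time = target$time,
                 channels = channels, target = target,
                 phase_label = phase_lab, rate = out_rate,
                 truth = trial$truth),
            class = "processed_trial")
}
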