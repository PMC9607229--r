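# Synthetic multimodal gait-trial simulator -----------------------------------
#
# Emulates the study conditions the estimation pipeline assumes: a cohort of
# healthy adults performing 12-minute treadmill trials (3 min standing, 6 min
# walking at 0.22/0.33/0.44 m/s, 3 min recovery), with and without ankle-foot
# exoskeleton assistance, recorded by a breath-by-breath gas analyzer, 8
# inertial segments, 8 EMG channels and a beat-level heart-rate monitor.
# Ground-truth per-phase energy expenditure is carried along for
# parameter-recovery tests.

BROCKWAY_O2 <- 16.58   # J per mL O2
BROCKWAY_CO2 <- 4.51   # J per mL CO2

IMU_SEGMENTS <- c("foot_l", "foot_r", "lower_leg_l", "lower_leg_r",
                  "pelvis", "torso", "upper_leg_l", "upper_leg_r")
EMG_MUSCLES <- c("bf_l", "bf_r", "gl_l", "gl_r", "ta_l", "ta_r", "vl_l", "vl_r")

#' Experimental protocol specification
#'
#' Defaults mirror the treadmill protocol the pipeline targets: 3 minutes
#' standing (basal), 6 minutes walking, 3 minutes standing recovery, at slow
#' gait speeds of 0.22, 0.33 and 0.44 m/s, assisted and non-assisted.
#'
#' @param stand_duration,walk_duration,recover_duration phase lengths, seconds.
#' @param speeds treadmill speeds, m/s.
#' @param conditions walking conditions to simulate.
#' @return a list of class `protocol_spec`.
#' @export
protocol_spec <- function(stand_duration = 180, walk_duration = 360,
                          recover_duration = 180,
                          speeds = c(0.22, 0.33, 0.44),
                          conditions = c("non_assisted", "assisted")) {
  assert_scalar_num(stand_duration, "stand_duration", lower = 1e-9)
  assert_scalar_num(walk_duration, "walk_duration", lower = 1e-9)
  assert_scalar_num(recover_duration, "recover_duration", lower = 1e-9)
  if (any(speeds <= 0)) stop("speeds must be positive", call. = FALSE)
  conditions <- match.arg(conditions, c("non_assisted", "assisted"), several.ok = TRUE)
  structure(list(stand_duration = stand_duration, walk_duration = walk_duration,
                 recover_duration = recover_duration, speeds = speeds,
                 conditions = conditions),
            class = "protocol_spec")
}

#' Phase table of a protocol
#' @param protocol a [protocol_spec()].
#' @return data.frame with columns `label`, `start`, `end` (seconds).
#' @export
protocol_phases <- function(protocol) {
  d <- c(protocol$stand_duration, protocol$walk_duration, protocol$recover_duration)
  data.frame(label = c("stand", "walk", "recover"),
             start = cumsum(c(0, d[-3])), end = cumsum(d))
}

#' Generate a synthetic cohort of subject profiles
#'
#' Anthropometrics are drawn inside the eligibility bounds used for recruiting
#' (age >= 18 years, body mass 45-90 kg, height 150-190 cm), with
#' gender-specific mass/height distributions so that the cohort resembles a
#' balanced group of healthy young adults. Genders alternate F/M, so even `n`
#' gives an exactly balanced cohort. Maximum heart rate uses the age-predicted
#' formula `hr_max = 220 - age` (config-overridable). `basal_ee` is the
#' generator's ground-truth standing metabolic rate in W/kg.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; identical `(n_subjects, seed)` gives an identical
#'   cohort.
#' @param hr_max_fun function of age returning maximal heart rate (bpm).
#' @return data.frame with one row per subject: `subject_id`, `gender`, `age`,
#'   `height`, `body_mass`, `hr_max`, `basal_ee`.
#' @export
make_cohort <- function(n_subjects, seed = 1L, hr_max_fun = function(age) 220 - age) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1 ||
      n_subjects != round(n_subjects))
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  n <- as.integer(n_subjects)
  with_seed(seed, {
    gender <- rep(c("F", "M"), length.out = n)
    age <- pmax(18L, 18L + as.integer(round(rgamma(n, shape = 4, scale = 2))))
    rtrunc <- function(n, mean, sd, lo, hi)
      pmin(hi, pmax(lo, rnorm(n, mean, sd)))
    height <- ifelse(gender == "F",
                     rtrunc(n, 166, 5.7, 150, 190),
                     rtrunc(n, 176, 6.7, 150, 190))
    mass <- ifelse(gender == "F",
                   rtrunc(n, 59.5, 5.0, 45, 90),
                   rtrunc(n, 77.0, 4.0, 45, 90))
    basal <- rtrunc(n, 1.3, 0.12, 0.9, 1.8)
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               gender = gender, age = age,
               height = round(height, 1), body_mass = round(mass, 1),
               hr_max = hr_max_fun(age), basal_ee = round(basal, 4),
               stringsAsFactors = FALSE)
  })
}

#' Ground-truth per-phase energy expenditure for one trial
#'
#' Walking cost follows `basal + a*v + b*v^2`; assisted walking reduces the
#' walking increment by a fraction `assist_reduction`. The recovery plateau sits
#' slightly above basal (`recover_frac` of the walking increment) to reflect
#' excess post-exercise oxygen consumption at steady state. Defaults are chosen
#' so the cohort spans roughly 4 W/kg from basal to the fastest walk.
#'
#' @param subject one row of a [make_cohort()] data.frame.
#' @param speed gait speed, m/s (> 0).
#' @param assisted logical, exoskeleton-assisted walking.
#' @param coef_a,coef_b speed coefficients of the walking cost (W/kg per (m/s)
#'   and per (m/s)^2).
#' @param assist_reduction fraction in `[0, 1)` by which assistance reduces the
#'   walking increment.
#' @param recover_frac recovery elevation as a fraction of the walking
#'   increment.
#' @return named numeric vector `c(stand, walk, recover)` in W/kg.
#' @export
true_ee_profile <- function(subject, speed, assisted,
                            coef_a = 5, coef_b = 10,
                            assist_reduction = 0.10, recover_frac = 0.15) {
  assert_scalar_num(speed, "speed", lower = 1e-12)
  if (assist_reduction < 0 || assist_reduction >= 1)
    stop("`assist_reduction` must be in [0, 1)", call. = FALSE)
  basal <- subject$basal_ee
  inc <- coef_a * speed + coef_b * speed^2
  if (inc <= 0)
    stop("walking coefficients must produce walking EE above standing EE", call. = FALSE)
  if (isTRUE(assisted)) inc <- inc * (1 - assist_reduction)
  c(stand = basal, walk = basal + inc, recover = basal + recover_frac * inc)
}

#' Synthesize a breath-by-breath gas-exchange series
#'
#' Inverts the Brockway conversion at a fixed respiratory exchange ratio so
#' that, at zero noise, converting the series back to power and normalizing by
#' body mass reproduces the per-phase target exactly:
#' `vo2 = EE * mass / (16.58 + 4.51 * rer)`, `vco2 = rer * vo2`.
#' Breath intervals are uniform on 2-5 s. Multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` is applied per breath, and isolated
#' outlier breaths are inflated by `outlier_factor` at rate `outlier_rate`
#' (mimicking the occasional aberrant breaths of indirect calorimetry).
#'
#' @param phase_ee named per-phase EE (W/kg), names matching `phases$label`.
#' @param phases phase table (see [protocol_phases()]).
#' @param body_mass subject mass, kg (> 0).
#' @param rer respiratory exchange ratio in `[0.7, 1.0]`.
#' @param noise_cv coefficient of variation of breath noise (>= 0).
#' @param outlier_rate per-breath outlier probability.
#' @param outlier_factor multiplicative inflation of outlier breaths (>= 3).
#' @param seed integer seed.
#' @return list with `time`, `vo2`, `vco2` (mL/s) and attribute `outlier_idx`
#'   holding the indices of injected outliers.
#' @export
synth_breath_series <- function(phase_ee, phases, body_mass, rer = 0.85,
                                noise_cv = 0.10, outlier_rate = 0.01,
                                outlier_factor = 3, seed = 1L) {
  assert_scalar_num(body_mass, "body_mass", lower = 1e-9)
  assert_scalar_num(rer, "rer", lower = 0.7, upper = 1.0)
  assert_scalar_num(noise_cv, "noise_cv", lower = 0)
  assert_scalar_num(outlier_rate, "outlier_rate", lower = 0, upper = 1)
  if (outlier_factor < 3) stop("`outlier_factor` must be >= 3", call. = FALSE)
  phases <- validate_phases(phases)
  if (!all(phases$label %in% names(phase_ee)))
    stop("`phase_ee` must name every phase label", call. = FALSE)
  with_seed(seed, {
    time <- numeric(0); vo2 <- numeric(0); out_idx <- integer(0)
    for (i in seq_len(nrow(phases))) {
      t0 <- phases$start[i]; t1 <- phases$end[i]
      # draw enough intervals, then truncate to the phase
      n_max <- ceiling((t1 - t0) / 2) + 2
      tt <- t0 + cumsum(runif(n_max, 2, 5))
      tt <- tt[tt < t1]
      ee <- phase_ee[[phases$label[i]]]
      v0 <- ee * body_mass / (BROCKWAY_O2 + BROCKWAY_CO2 * rer)
      mult <- pmax(0.05, 1 + noise_cv * rnorm(length(tt)))
      is_out <- runif(length(tt)) < outlier_rate
      mult[is_out] <- mult[is_out] * outlier_factor
      out_idx <- c(out_idx, length(time) + which(is_out))
      time <- c(time, tt)
      vo2 <- c(vo2, v0 * mult)
    }
    structure(list(time = time, vo2 = vo2, vco2 = rer * vo2),
              outlier_idx = out_idx)
  })
}

# cadence (stride frequency, Hz) as a rising function of speed; slow-gait range
cadence_hz <- function(speed) 0.5 + 0.8 * speed

#' Synthesize motion, EMG and heart-rate streams for one trial
#'
#' Walking phases carry cadence-locked periodic components in the inertial
#' channels and burst-modulated noise in the EMG channels; standing phases are
#' near-baseline. Heart rate follows first-order kinetics toward a
#' speed-dependent plateau (time constant `hr_tau` seconds). Under assistance
#' the shank muscles of the assisted (right) leg show reduced burst amplitude.
#' Morphology is stylized: only the low-frequency envelope that survives the
#' conditioning chains is meant to be realistic.
#'
#' @param subject one cohort row.
#' @param speed gait speed, m/s; `speed = 0` yields a standing-only morphology.
#' @param assisted logical.
#' @param phases phase table.
#' @param imu_rate,emg_rate sampling rates, Hz.
#' @param hr_tau heart-rate time constant, seconds (30-60).
#' @param seed integer seed.
#' @return list with elements `imu` (per segment: `acc`, `gyro`, N x 3 each),
#'   `emg` (N x 8 matrix), `mvc` (named per-muscle reference), `hr`
#'   (list `time`, `bpm`), and `hr_plateau` (walking plateau used, bpm).
#' @export
synth_motion_and_emg_and_hr <- function(subject, speed, assisted, phases,
                                        imu_rate = 100, emg_rate = 1000,
                                        hr_tau = 35, seed = 1L) {
  phases <- validate_phases(phases)
  if (hr_tau < 30 || hr_tau > 60) stop("`hr_tau` must be within [30, 60] s", call. = FALSE)
  dur <- phases$end[nrow(phases)]
  with_seed(seed, {
    n_imu <- round(dur * imu_rate)
    t_imu <- (seq_len(n_imu) - 1) / imu_rate
    walk <- phases[phases$label == "walk", ]
    in_walk <- t_imu >= walk$start & t_imu < walk$end
    # smooth 5 s ramps at walking onset/offset (start/stop transitions)
    ramp <- pmin(1, pmax(0, (t_imu - walk$start) / 5)) *
      pmin(1, pmax(0, (walk$end - t_imu) / 5))
    ramp[!in_walk] <- 0
    f <- if (speed > 0) cadence_hz(speed) else 0

    seg_amp <- c(foot_l = 2.0, foot_r = 2.0, lower_leg_l = 1.4, lower_leg_r = 1.4,
                 pelvis = 0.5, torso = 0.3, upper_leg_l = 0.9, upper_leg_r = 0.9)
    imu <- lapply(IMU_SEGMENTS, function(s) {
      ph <- runif(1, 0, 2 * pi) + if (grepl("_l$", s)) pi else 0
      osc <- if (speed > 0)
        seg_amp[[s]] * speed / 0.33 *
          (sin(2 * pi * f * t_imu + ph) + 0.3 * sin(4 * pi * f * t_imu + 2 * ph)) * ramp
      else rep(0, n_imu)
      acc <- cbind(osc + rnorm(n_imu, 0, 0.05),
                   0.6 * osc + rnorm(n_imu, 0, 0.05),
                   9.81 + 0.8 * osc + rnorm(n_imu, 0, 0.05))
      gyr <- cbind(0.9 * osc + rnorm(n_imu, 0, 0.02),
                   0.5 * osc + rnorm(n_imu, 0, 0.02),
                   0.3 * osc + rnorm(n_imu, 0, 0.02))
      colnames(acc) <- c("x", "y", "z"); colnames(gyr) <- c("x", "y", "z")
      list(acc = acc, gyro = gyr)
    })
    names(imu) <- IMU_SEGMENTS

    n_emg <- round(dur * emg_rate)
    t_emg <- (seq_len(n_emg) - 1) / emg_rate
    in_walk_e <- t_emg >= walk$start & t_emg < walk$end
    ramp_e <- pmin(1, pmax(0, (t_emg - walk$start) / 5)) *
      pmin(1, pmax(0, (walk$end - t_emg) / 5))
    ramp_e[!in_walk_e] <- 0
    mvc <- stats::setNames(runif(8, 0.4, 1.2), EMG_MUSCLES) # mV-scale references
    muscle_phase <- stats::setNames(runif(8, 0, 2 * pi), EMG_MUSCLES)
    emg <- sapply(EMG_MUSCLES, function(m) {
      frac <- 0.25 + 0.5 * speed                     # burst amplitude, fraction of MVC
      if (isTRUE(assisted) && m %in% c("ta_r", "gl_r")) frac <- frac * 0.7
      burst <- if (speed > 0) {
        ph <- 2 * pi * f * t_emg + muscle_phase[[m]] + if (grepl("_l$", m)) pi else 0
        # raised-cosine burst train with ~35% duty cycle per stride
        cyc <- (ph / (2 * pi)) %% 1
        env <- ifelse(cyc < 0.35, 0.5 * (1 - cos(2 * pi * cyc / 0.35)), 0)
        frac * env * ramp_e
      } else rep(0, n_emg)
      (burst + 0.02) * mvc[[m]] * rnorm(n_emg)
    })
    colnames(emg) <- EMG_MUSCLES

    # heart rate: first-order kinetics toward phase-dependent targets
    hr_rest <- runif(1, 64, 76)
    hr_plateau <- min(subject$hr_max - 5,
                      hr_rest + if (speed > 0) 25 + 60 * speed else 0)
    recov <- phases[phases$label == "recover", ]
    dt <- 0.5
    tg <- seq(0, dur, by = dt)
    target <- ifelse(tg >= walk$start & tg < walk$end, hr_plateau, hr_rest)
    hr_inst <- numeric(length(tg)); hr_inst[1] <- hr_rest
    for (k in 2:length(tg))
      hr_inst[k] <- hr_inst[k - 1] + (target[k] - hr_inst[k - 1]) * dt / hr_tau
    # emit beats by integrating the instantaneous rate
    beat_t <- numeric(0); tcur <- 0
    while (tcur < dur) {
      rate <- hr_inst[min(length(hr_inst), floor(tcur / dt) + 1)]
      tcur <- tcur + 60 / rate
      if (tcur < dur) beat_t <- c(beat_t, tcur)
    }
    beat_hr <- hr_inst[pmin(length(hr_inst), floor(beat_t / dt) + 1)] +
      rnorm(length(beat_t), 0, 0.8)

    list(imu = imu, emg = emg, mvc = mvc,
         hr = list(time = beat_t, bpm = beat_hr),
         hr_plateau = hr_plateau)
  })
}

#' Simulate one multimodal gait trial
#'
#' Composes [true_ee_profile()], [synth_breath_series()] and
#' [synth_motion_and_emg_and_hr()] into a complete trial recording with
#' ground-truth per-phase EE attached.
#'
#' @param subject one cohort row.
#' @param speed,assisted trial condition.
#' @param protocol a [protocol_spec()].
#' @param noise_cv,outlier_rate,outlier_factor breath-noise parameters.
#' @param rer respiratory exchange ratio.
#' @param assist_reduction,coef_a,coef_b,recover_frac ground-truth EE model
#'   parameters (see [true_ee_profile()]).
#' @param imu_rate,emg_rate sampling rates, Hz.
#' @param seed integer seed; sub-streams use `seed + 1` (breath) and
#'   `seed + 2` (motion/EMG/HR).
#' @return object of class `gait_trial`.
#' @export
simulate_trial <- function(subject, speed, assisted, protocol = protocol_spec(),
                           noise_cv = 0.10, outlier_rate = 0.01, outlier_factor = 3,
                           rer = 0.85, assist_reduction = 0.10,
                           coef_a = 5, coef_b = 10, recover_frac = 0.15,
                           imu_rate = 100, emg_rate = 1000, seed = 1L) {
  phases <- protocol_phases(protocol)
  truth <- true_ee_profile(subject, speed, assisted,
                           coef_a = coef_a, coef_b = coef_b,
                           assist_reduction = assist_reduction,
                           recover_frac = recover_frac)
  breath <- synth_breath_series(truth, phases, subject$body_mass, rer = rer,
                                noise_cv = noise_cv, outlier_rate = outlier_rate,
                                outlier_factor = outlier_factor, seed = seed + 1L)
  streams <- synth_motion_and_emg_and_hr(subject, speed, assisted, phases,
                                         imu_rate = imu_rate, emg_rate = emg_rate,
                                         seed = seed + 2L)
  structure(list(subject = subject,
                 subject_id = subject$subject_id,
                 speed = speed, assisted = isTRUE(assisted),
                 phases = phases, breath = breath,
                 imu = streams$imu, emg = streams$emg, mvc = streams$mvc,
                 hr = streams$hr, truth = truth,
                 imu_rate = imu_rate, emg_rate = emg_rate,
                 schema_version = "1.0"),
            class = "gait_trial")
}

#' Simulate the full trial set of a cohort
#'
#' One trial per subject x speed x condition; per-trial seeds are derived from
#' the global seed by a fixed counter scheme (`seed + 1000 * trial_index`).
#'
#' @param cohort a [make_cohort()] data.frame.
#' @param protocol a [protocol_spec()].
#' @param seed integer global seed.
#' @param ... forwarded to [simulate_trial()].
#' @return list of `gait_trial` objects.
#' @export
simulate_cohort_trials <- function(cohort, protocol = protocol_spec(), seed = 1L, ...) {
  grid <- expand.grid(speed = protocol$speeds,
                      condition = protocol$conditions,
                      subject = cohort$subject_id,
                      stringsAsFactors = FALSE)
  trials <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    subj <- cohort[cohort$subject_id == grid$subject[i], , drop = FALSE]
    trials[[i]] <- simulate_trial(subj, grid$speed[i],
                                  grid$condition[i] == "assisted",
                                  protocol = protocol,
                                  seed = seed + 1000L * i, ...)
  }
  trials
}
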