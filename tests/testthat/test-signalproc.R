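test_that("Brockway conversion matches its defining coefficients", {
  expect_equal(brockway_power(0, 0), 0)
  expect_equal(brockway_power(1, 0), 16.58)
  expect_equal(brockway_power(0, 1), 4.51)
  expect_equal(brockway_power(3.0, 2.55), 16.58 * 3 + 4.51 * 2.55) # 61.2405
  expect_equal(brockway_power(c(1, 2), c(0, 1)), c(16.58, 2 * 16.58 + 4.51))
  expect_error(brockway_power(-1, 0), "non-negative")
})

test_that("steady-state extraction trims outliers like the brute-force rule", {
  # constant series passes through
  tt <- seq(0, 100, by = 1)
  expect_equal(steady_state_value(rep(4.2, length(tt)), tt, 100, window = 60), 4.2)

  # a single gross outlier among constant samples is removed
  v <- c(rep(5, 100), 50)
  tm <- seq(40.2, 100, length.out = 101)
  expect_equal(steady_state_value(v, tm, 100, window = 60), 5)

  # brute-force oracle: one-pass mean +/- z*sd trim, then mean of survivors
  set.seed(31)
  for (rep_i in 1:20) {
    vals <- rnorm(60, 8, 1) * sample(c(rep(1, 57), 3, 1, 1))
    tv <- sort(runif(60, 20, 100))
    z <- qnorm(0.975)
    inw <- tv > 100 - 60 & tv <= 100
    vv <- vals[inw]
    keep <- abs(vv - mean(vv)) <= z * sd(vv)
    expect_equal(steady_state_value(vals, tv, 100, window = 60),
                 mean(vv[keep]), tolerance = 1e-14)
  }

  # with plain Gaussian noise the trimmed mean stays near the untrimmed mean
  set.seed(32)
  v <- rnorm(200, 10, 0.8)
  tv <- seq(0.5, 100, length.out = 200)
  se <- 0.8 / sqrt(200)
  expect_lt(abs(steady_state_value(v, tv, 100, window = 100) - mean(v)), 3 * se)

  expect_error(steady_state_value(c(1, 2), c(1, 2), 10, window = 5), ">= 3 samples")
})

test_that("zero-lag Butterworth honours DC, reversal-symmetry and attenuation contracts", {
  set.seed(41)
  x <- rnorm(3000)
  stages <- list(list(c = 5, r = 100, t = "low"),
                 list(c = c(20, 450), r = 1000, t = "pass"),
                 list(c = 2, r = 1000, t = "low"),
                 list(c = 0.1, r = 100, t = "low"))
  for (st in stages) {
    y <- zero_lag_butterworth(x, st$c, st$r, st$t)
    yr <- rev(zero_lag_butterworth(rev(x), st$c, st$r, st$t))
    expect_lt(max(abs(y - yr)), 1e-10)
    if (st$t == "low") {
      cst <- zero_lag_butterworth(rep(3.7, 1500), st$c, st$r, "low")
      expect_lt(max(abs(cst - 3.7)), 1e-8)
    }
  }
  # 20 Hz sine through the 5 Hz lowpass at 100 Hz: > 95% RMS attenuation
  t <- (0:9999) / 100
  s <- sin(2 * pi * 20 * t)
  y <- zero_lag_butterworth(s, 5, 100, "low")
  expect_lt(sqrt(mean(y^2)) / sqrt(mean(s^2)), 0.05)

  expect_error(zero_lag_butterworth(x, 60, 100, "low"), "Nyquist")
  expect_error(zero_lag_butterworth(x, c(20, 500), 1000, "pass"), "Nyquist")
})

test_that("kinematic chain computes filtered magnitudes per segment", {
  n <- 500
  const_seg <- list(acc = cbind(rep(3, n), rep(4, n), rep(0, n)),
                    gyro = matrix(0, n, 3))
  imu <- rep(list(const_seg), 8)
  names(imu) <- gaitEE:::IMU_SEGMENTS
  k <- process_kinematics(imu, rate = 25)
  expect_equal(ncol(k), 16)
  # 3-4-5 identity for the constant triplet; zero in, zero out
  expect_equal(unname(k[, "acc_foot_l"]), rep(5, n), tolerance = 1e-8)
  expect_lt(max(abs(k[, "gyro_pelvis"])), 1e-8)

  imu$torso <- NULL
  expect_error(process_kinematics(imu, rate = 25), "torso")
})

test_that("walking raises the slow kinematic magnitude above standing", {
  pt <- small_processed_trials()[[2]]
  w <- pt$phase_label == "walk" & pt$time > 80 & pt$time < 160
  st <- pt$phase_label == "stand" & pt$time > 10 & pt$time < 50
  for (ch in c("acc_foot_r", "gyro_lower_leg_l"))
    expect_gt(mean(pt$channels[w, ch]), mean(pt$channels[st, ch]))
})

test_that("EMG chain is homogeneous, MVC-invariant and matches a rectify oracle", {
  set.seed(51)
  rate <- 250; n <- rate * 30
  mvc <- setNames(rep(1, 8), gaitEE:::EMG_MUSCLES)
  # all-zero input -> all-zero sums
  z <- matrix(0, n, 8, dimnames = list(NULL, gaitEE:::EMG_MUSCLES))
  ez <- process_emg(z, mvc, rate = rate, out_rate = 25, band = c(20, 110))
  expect_equal(max(abs(ez)), 0)
  expect_equal(colnames(ez), c("lsll", "lsul", "rsll", "rsul"))

  # burst train on two identical lower-leg muscles
  tt <- (seq_len(n) - 1) / rate
  env <- 0.4 * (1 + sin(2 * pi * 0.7 * tt)) / 2
  raw <- env * rnorm(n)
  emg <- z; emg[, "ta_l"] <- raw; emg[, "gl_l"] <- raw
  e1 <- process_emg(emg, mvc, rate = rate, out_rate = 25, band = c(20, 110))
  # identical muscles: the side sum is exactly twice a single-muscle envelope
  emg_single <- z; emg_single[, "ta_l"] <- raw
  es <- process_emg(emg_single, mvc, rate = rate, out_rate = 25, band = c(20, 110))
  expect_equal(e1[, "lsll"], 2 * es[, "lsll"], tolerance = 1e-12)

  # brute-force rectify-and-average oracle for the plateau level
  bp <- zero_lag_butterworth(raw, c(20, 110), rate, "pass")
  mid <- tt > 5 & tt < 25
  oracle <- mean(abs(bp[mid]))
  mid_dec <- seq(5 * 25, 25 * 25)
  expect_equal(mean(es[mid_dec, "lsll"]), oracle, tolerance = 0.1)
  # set the MVC reference so one muscle sits at 0.3 MVC: the two-muscle sum is ~0.6
  mvc2 <- mvc; mvc2[c("ta_l", "gl_l")] <- oracle / 0.3
  e2 <- process_emg(emg, mvc2, rate = rate, out_rate = 25, band = c(20, 110))
  expect_equal(mean(e2[mid_dec, "lsll"]), 0.6, tolerance = 0.06)

  # positive homogeneity: scaling raw data by k scales the envelope by k
  emg_k <- emg; emg_k[, c("ta_l", "gl_l")] <- 2.5 * emg[, c("ta_l", "gl_l")]
  ek <- process_emg(emg_k, mvc, rate = rate, out_rate = 25, band = c(20, 110))
  expect_equal(ek[, "lsll"], 2.5 * e1[, "lsll"], tolerance = 1e-10)

  # invariance when raw data and MVC references are rescaled identically
  ek2 <- process_emg(emg_k, mvc * 2.5, rate = rate, out_rate = 25, band = c(20, 110))
  expect_equal(ek2, e1, tolerance = 1e-12)

  expect_error(process_emg(emg[, 1:7], mvc, rate = rate), "8 EMG channels")
  mvc_bad <- mvc; mvc_bad["vl_r"] <- 0
  expect_error(process_emg(emg, mvc_bad, rate = rate), "positive")
})

test_that("channel assembly emits the 25 documented channels", {
  pt <- small_processed_trials()[[1]]
  expect_equal(ncol(pt$channels), 25)
  expect_equal(colnames(pt$channels), gaitEE:::channel_names())
  expect_equal(unique(pt$channels[, "speed"]), pt$speed)

  # two subjects differing only in gender differ only in the gender channel
  n <- 100
  kin <- matrix(rnorm(n * 16), n, 16)
  emg <- matrix(abs(rnorm(n * 4)), n, 4)
  hr <- rep(0.5, n)
  s1 <- data.frame(gender = "F", age = 25, height = 165)
  s2 <- data.frame(gender = "M", age = 25, height = 165)
  c1 <- assemble_channels(kin, emg, hr, 0.33, s1)
  c2 <- assemble_channels(kin, emg, hr, 0.33, s2)
  diffs <- which(colSums(abs(c1 - c2)) > 0)
  expect_equal(names(diffs), "gender")
  expect_equal(unique(c1[, "gender"]), 0)
  expect_equal(unique(c2[, "gender"]), 1)

  expect_error(assemble_channels(kin, emg[1:50, ], hr, 0.33, s1), "timeline mismatch")
})

test_that("HR processing normalizes phase plateaus in order", {
  s <- data.frame(hr_max = 200)
  phases <- data.frame(label = c("stand", "walk", "recover"),
                       start = c(0, 60, 180), end = c(60, 180, 240))
  # constant 120 bpm at hr_max 200 -> 0.600 everywhere
  hr <- list(time = seq(0.5, 239.5, by = 1), bpm = rep(120, 240))
  ph <- process_hr(hr, s, phases, rate = 25, window = 45)
  expect_equal(unname(ph$values), rep(0.6, 3))
  expect_equal(unique(ph$step), 0.6)

  # noisy plateaus 80 / 140 / 100 recover their ordering after normalization
  set.seed(61)
  lv <- ifelse(hr$time < 60, 80, ifelse(hr$time < 180, 140, 100))
  hr2 <- list(time = hr$time, bpm = lv + rnorm(240, 0, 2))
  ph2 <- process_hr(hr2, s, phases, rate = 25, window = 45)
  expect_true(ph2$values[["stand"]] < ph2$values[["recover"]])
  expect_true(ph2$values[["recover"]] < ph2$values[["walk"]])
  expect_equal(unname(ph2$values), c(80, 140, 100) / 200, tolerance = 0.02)

  expect_error(process_hr(hr, data.frame(hr_max = NA_real_), phases), "hr_max")
})

test_that("zero-noise simulation round-trips through the pipeline to 1e-9 W/kg", {
  tr <- zero_noise_trial()
  pt <- process_trial(tr, proc_config(emg_band = c(20, 110)))
  expect_lt(max(abs(pt$target$values - tr$truth)), 1e-9)
  # step target: exactly 3 constant levels with transitions at phase boundaries
  expect_equal(length(unique(pt$target$step)), 3)
  expect_equal(sort(unique(pt$target$step)), sort(unname(pt$target$values)))
  idx_change <- which(diff(pt$target$step) != 0)
  expect_equal(pt$target$time[idx_change + 1], c(180, 540))
})

test_that("trial processing is pure: order of processing does not matter", {
  trs <- small_raw_trials()[c(1, 5)]
  p_ab <- lapply(trs, process_trial, config = short_proc_config())
  p_ba <- lapply(rev(trs), process_trial, config = short_proc_config())
  expect_identical(p_ab[[1]], p_ba[[2]])
  expect_identical(p_ab[[2]], p_ba[[1]])
})
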