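# independent brute-force oracles ---------------------------------------------

rank_avg <- function(x) {
  # explicit average-rank computation
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}
pearson_raw <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
scc_brute <- function(a, b) pearson_raw(rank_avg(a), rank_avg(b))
nmse_brute <- function(y, yh) {
  sse <- 0; sst <- 0; ym <- mean(y)
  for (i in seq_along(y)) {
    sse <- sse + (y[i] - yh[i])^2
    sst <- sst + (y[i] - ym)^2
  }
  1 - sse / sst
}

test_that("metrics satisfy their defining identities", {
  y <- c(1.2, 1.8, 2.4, 3.3, 2.0, 1.1)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m), c(mse = 0, rmse = 0, nmse = 1, scc = 1))
  m2 <- regression_metrics(y, rep(mean(y), length(y)))
  expect_equal(m2$nmse, 0)
  expect_equal(m2$rmse^2, m2$mse, tolerance = 1e-12)
  # constant target: undefined markers, not numbers
  m3 <- regression_metrics(rep(2, 5), rnorm(5))
  expect_true(is.na(m3$nmse) && is.na(m3$scc))
  expect_error(regression_metrics(1:3, 1:4), "equal-length")
})

test_that("SCC and NMSE match brute-force implementations on random vectors", {
  set.seed(71)
  for (i in 1:25) {
    y <- rnorm(20); yh <- 0.6 * y + rnorm(20, 0, 0.5)
    m <- regression_metrics(y, yh)
    expect_equal(m$scc, scc_brute(y, yh), tolerance = 1e-12)
    expect_equal(m$nmse, nmse_brute(y, yh), tolerance = 1e-12)
  }
  # ties exercise average ranking
  y <- c(1, 2, 2, 3, 3, 3, 4); yh <- c(2, 1, 3, 3, 5, 4, 4)
  expect_equal(regression_metrics(y, yh)$scc, scc_brute(y, yh), tolerance = 1e-12)
})

test_that("SCC is invariant under strictly monotone transforms", {
  set.seed(72)
  y <- rnorm(30); yh <- y + rnorm(30)
  s0 <- regression_metrics(y, yh)$scc
  expect_equal(regression_metrics(exp(y), yh)$scc, s0, tolerance = 1e-12)
  expect_equal(regression_metrics(y, 3 * yh^3 + yh)$scc, s0, tolerance = 1e-12)
})

test_that("Bland-Altman agreement follows its defining arithmetic", {
  y <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(y, y)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba <- bland_altman(y, y + 0.5)
  expect_equal(ba$bias, 0.5)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0.5, 0.5))
  expect_equal(ba$pairs$difference, rep(0.5, 5))
  expect_equal(ba$pairs$average, y + 0.25)
  # limits bracket the bias
  set.seed(73)
  ba2 <- bland_altman(rnorm(50), rnorm(50))
  expect_true(ba2$loa_low <= ba2$bias && ba2$bias <= ba2$loa_high)
  expect_equal(ba2$loa_high - ba2$bias, 1.959964 * ba2$sd, tolerance = 1e-12)
  expect_error(bland_altman(1:2, 1:2), ">= 3")
})

test_that("linear fit recovers exact affine relations and matches 1 - SSE/SST", {
  y <- c(0.8, 1.5, 2.2, 3.0, 4.1)
  f1 <- linear_fit(y, y)
  expect_equal(c(f1$slope, f1$intercept, f1$r_squared), c(1, 0, 1), tolerance = 1e-12)
  f2 <- linear_fit(y, 2 * y + 1)
  expect_equal(c(f2$slope, f2$intercept, f2$r_squared), c(2, 1, 1), tolerance = 1e-12)
  set.seed(74)
  yy <- rnorm(50); ee <- yy + rnorm(50, 0, 0.4)
  fit <- lm(ee ~ yy)
  r2_brute <- 1 - sum(residuals(fit)^2) / sum((ee - mean(ee))^2)
  expect_equal(linear_fit(yy, ee)$r_squared, r2_brute, tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("NMSE coincides with linear-fit R-squared on identity-line fits", {
  # exact coincidence at a perfect identity fit
  y <- c(1.1, 1.9, 3.2, 2.4, 4.0)
  expect_equal(regression_metrics(y, y)$nmse, linear_fit(y, y)$r_squared)
  # residuals orthogonal to the target with zero mean => the OLS fit is the
  # identity line; with residual energy r = SSE/SST, NMSE = 1 - r while
  # R^2 = 1/(1 + r), so the two agree to O(r^2)
  set.seed(75)
  y <- rnorm(40, 2, 1)
  eps <- residuals(lm(rnorm(40, 0, 0.05) ~ y))
  yh <- y + eps
  m <- regression_metrics(y, yh)
  f <- linear_fit(y, yh)
  expect_equal(f$slope, 1, tolerance = 1e-10)
  expect_lt(abs(f$intercept), 1e-10)
  r <- sum(eps^2) / sum((y - mean(y))^2)
  expect_lt(abs(m$nmse - f$r_squared), max(2 * r^2, 1e-10))
})

test_that("MSE decomposes exactly over speed x condition cells", {
  set.seed(76)
  n <- 240
  preds <- data.frame(
    speed = sample(c(0.22, 0.33, 0.44), n, TRUE),
    assisted = sample(c(TRUE, FALSE), n, TRUE),
    target = rnorm(n, 2), estimate = rnorm(n, 2),
    trial_id = "t", phase = "walk", subject = "S")
  m <- mse_by_condition(preds)
  expect_equal(dim(m), c(3, 2))
  wsum <- 0
  for (i in rownames(m)) for (j in colnames(m)) {
    sel <- format(preds$speed) == i & preds$assisted == (j == "assisted")
    wsum <- wsum + m[i, j] * sum(sel)
  }
  expect_equal(wsum / n, attr(m, "pooled_mse"), tolerance = 1e-12)

  perfect <- preds; perfect$estimate <- perfect$target
  expect_true(all(mse_by_condition(perfect) == 0))

  single <- preds[1, ]
  ms <- mse_by_condition(single)
  expect_equal(sum(!is.na(ms)), 1)
  expect_equal(ms[format(single$speed), ifelse(single$assisted, "assisted", "non_assisted")],
               (single$estimate - single$target)^2)
})

test_that("LOOCV builds one fold per subject and never trains on the fold subject", {
  trials <- small_processed_trials()
  rep7 <- run_loocv(trials, model_spec = "stub", window = 50, stride = 100)
  expect_equal(nrow(rep7$folds), 4)
  expect_setequal(rep7$folds$subject, unique(vapply(trials, `[[`, character(1),
                                                    "subject_id")))
  # every subject validated exactly once
  expect_equal(anyDuplicated(rep7$folds$subject), 0)

  # duplicating one subject's trials under a new id adds exactly one fold
  dup <- lapply(trials[vapply(trials, `[[`, character(1), "subject_id") == "S01"],
                function(tr) { tr$subject_id <- "S99"; tr })
  rep8 <- run_loocv(c(trials, dup), model_spec = "stub", window = 50, stride = 100)
  expect_equal(nrow(rep8$folds), 5)
  expect_true("S99" %in% rep8$folds$subject)

  expect_error(run_loocv(trials[1:2][c()], model_spec = "stub"), ">= 2 subjects")
})

test_that("LOOCV fold spread is zero when all subjects carry identical data", {
  base <- small_processed_trials()[[1]]
  clones <- lapply(c("A", "B", "C"), function(id) {
    tr <- base; tr$subject_id <- id; tr$subject$subject_id <- id; tr
  })
  repc <- run_loocv(clones, model_spec = "stub", window = 50, stride = 100)
  expect_equal(repc$summary$sd[repc$summary$metric == "mse"], 0, tolerance = 1e-12)
})

test_that("per-phase pairs aggregate window predictions by trial and phase", {
  preds <- data.frame(
    subject = "S", trial_id = rep(c("t1", "t2"), each = 4),
    speed = 0.22, assisted = FALSE,
    phase = rep(c("stand", "walk"), 4),
    target = c(1, 3, 1, 3, 1.5, 3.5, 1.5, 3.5),
    estimate = c(1.1, 2.9, 0.9, 3.1, 1.6, 3.4, 1.4, 3.6))
  pp <- phase_pairs(preds)
  expect_equal(nrow(pp), 4)
  expect_equal(pp$target[pp$trial_id == "t1" & pp$phase == "stand"], 1)
  expect_equal(pp$estimate[pp$trial_id == "t2" & pp$phase == "walk"], 3.5)
})
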