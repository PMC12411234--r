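test_that("staircase thresholds average reversal intensities in the final window", {
  lad <- filament_ladder()
  expect_length(lad, 12L)
  expect_true(all(diff(lad) > 0))
  # log10(0.1 mg) transform: 0.02 g = 200 x 0.1 mg
  expect_equal(lad[2L], log10(0.02 * 1e4))

  # hand-built log: alternating correctness at the end creates reversals
  intens <- c(rep(3, 10), c(2.9, 3.0, 2.9, 3.0, 2.9, 3.0, 2.9, 3.0, 2.9, 3.0))
  corr <- c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  log <- data.frame(intensity = intens, correct = corr)
  thr <- staircase_threshold(log, ladder = lad, check_stop = FALSE)
  expect_equal(as.numeric(thr), mean(intens[12:20]))
  expect_identical(attr(thr, "n_reversals"), 9L)

  # always-correct observer descends to the ladder floor and pins there
  obs <- gen_behavior_observer(threshold = lad[1L] - 10, slope_scale = 1e-6,
                               task = "staircase", ladder = lad, seed = 2)
  expect_true(all(obs$correct))
  expect_equal(min(obs$intensity), lad[1L])
  thr0 <- staircase_threshold(obs, ladder = lad, check_stop = FALSE)
  expect_equal(as.numeric(thr0), lad[1L])

  # no reversal and non-constant final window is an error
  bad <- data.frame(intensity = seq(3, 1, length.out = 40),
                    correct = rep(TRUE, 40))
  expect_error(staircase_threshold(bad, check_stop = FALSE), "reversal")

  # stop rule: 100-trial cap reached when variability never settles
  obs2 <- gen_behavior_observer(threshold = lad[6L], slope_scale = 2,
                                lapse = 0.2, task = "staircase",
                                ladder = lad, seed = 3)
  expect_lte(nrow(obs2), 100L)
})

test_that("staircase estimator converges near the 3-down/1-up 79.4% point", {
  lad <- filament_ladder()
  step <- median(diff(lad))
  t0 <- lad[5L]
  ss <- step / 1.5
  est <- vapply(1:60, function(s) {
    o <- gen_behavior_observer(threshold = t0, slope_scale = ss,
                               task = "staircase", ladder = lad, seed = s)
    tryCatch(as.numeric(staircase_threshold(o, ladder = lad,
                                            check_stop = FALSE)),
             error = function(e) NA_real_)
  }, numeric(1))
  p794 <- t0 + ss * qlogis((0.794 - 0.5) / 0.5)
  expect_lt(abs(mean(est, na.rm = TRUE) - p794), step)
})

test_that("d-prime follows the normal-quantile rule with the stated corrections", {
  expect_equal(dprime(0.5, 0.5, 20, 20), 0)
  # fa = 0 replaced by 0.1
  expect_equal(dprime(0.9, 0, 20, 20), qnorm(0.9) - qnorm(0.1),
               tolerance = 1e-9)
  expect_equal(dprime(0.9, 0, 20, 20), 2.5631, tolerance = 1e-4)
  expect_equal(dprime(0.84, 0.16, 50, 50), qnorm(0.84) - qnorm(0.16))
  # hit = 1 clamped by the half-count rule
  expect_equal(dprime(1, 0.2, 25, 25), qnorm(1 - 1 / 50) - qnorm(0.2))

  # antisymmetry and monotonicity away from the corrections
  hs <- c(0.6, 0.7, 0.8)
  for (h in hs) expect_equal(dprime(h, 0.3, 99, 99),
                             -dprime(0.3, h, 99, 99))
  d <- vapply(hs, dprime, numeric(1), false_alarms = 0.2, n_signal = 99,
              n_noise = 99)
  expect_true(all(diff(d) > 0))
  expect_error(dprime(0.5, 0.5, 0, 10), "counts")
})

test_that("2PD thresholds come from the 50% point of a logistic fit", {
  set.seed(9)
  o <- gen_behavior_observer(threshold = 2.0, slope_scale = 0.15,
                             task = "2pd", reps = 50, seed = 4)
  test_trials <- o[o$spacing > 0, ]
  expect_identical(nrow(o[o$spacing == 0, ]), 50L)  # single-pin control
  thr <- two_point_threshold(test_trials$spacing, test_trials$two)
  expect_lt(abs(thr - 2.0), 0.1)

  # 90-trial block arithmetic: 8 spacings + control, 10 repetitions
  o90 <- gen_behavior_observer(threshold = 2.0, slope_scale = 0.15,
                               task = "2pd", reps = 10, seed = 5)
  expect_identical(nrow(o90), 90L)
  expect_identical(length(unique(o90$spacing)), 9L)

  # affine equivariance of the spacing axis
  sc <- test_trials$spacing * 3 + 1
  thr2 <- two_point_threshold(sc, test_trials$two)
  expect_equal(as.numeric(thr2), as.numeric(thr) * 3 + 1, tolerance = 1e-6)

  expect_warning(out <- two_point_threshold(c(1, 2, 3), c(TRUE, TRUE, TRUE)),
                 "identical")
  expect_true(is.nan(out))
  expect_error(two_point_threshold(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE)),
               "distinct")
})

test_that("skin indentation follows the power-law force model", {
  m <- skin_indentation(0.2368)
  expect_equal(m$delta, 1.0)
  expect_equal(m$amplitude, 3.0)
  # F = A * 2^b inverts to delta = 2 mm
  m2 <- skin_indentation(0.2368 * 2^2.0696)
  expect_equal(m2$delta, 2.0, tolerance = 1e-12)
  expect_equal(m2$amplitude, 6.0, tolerance = 1e-12)
  expect_error(skin_indentation(0), "positive")
  # literal product reading stays available but differs
  expect_equal(skin_indentation(0.2368, reading = "literal")$delta,
               1 / 2.0696)
})

test_that("grip time-on-target counts samples within the 2.5% band", {
  target <- rep(10, 2000)  # 20 s at 100 Hz
  expect_equal(grip_time_on_target(target, target), 20)
  expect_equal(grip_time_on_target(1.03 * target, target), 0)
  # square wave spending exactly half the samples in band
  force <- rep(c(10, 11), each = 1000)
  expect_equal(grip_time_on_target(force, target), 10)
  expect_error(grip_time_on_target(1:5, 1:4), "mismatch")
})
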