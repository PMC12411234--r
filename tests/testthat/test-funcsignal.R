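test_that("forward/reverse averaging restores the forward signal and halves noise", {
  # constructed mirror pair (generator, zero noise): average equals forward
  g <- gen_phase_encoded_bold(list(tr = 2, n_cycles = 8, cycle_s = 32),
                              noise_sd = 0, seed = 3)
  avg <- average_phase_runs(g$forward, g$reverse)
  expect_equal(avg$samples, g$forward$samples, tolerance = 1e-12)
  expect_identical(avg$direction, "forward")

  # all-zero runs average to zero
  z <- matrix(0, 3, 64)
  zf <- phase_series(z, 2, 8, 16, "forward", brightness = 1)
  zr <- phase_series(z, 2, 8, 16, "reverse", brightness = 1)
  expect_true(all(average_phase_runs(zf, zr)$samples == 0))

  # the shift is 2 samples at TR 2 s (4 seconds)
  expect_equal(round(4 / 2), 2)

  # noise variance halves over simulated independent pairs
  set.seed(11)
  ratio <- replicate(200, {
    a <- matrix(rnorm(64), 1)
    b <- matrix(rnorm(64), 1)
    f <- phase_series(a, 2, 8, 16, "forward", brightness = 1)
    r <- phase_series(b, 2, 8, 16, "reverse", brightness = 1)
    var(as.numeric(average_phase_runs(f, r)$samples)) /
      mean(c(var(as.numeric(a)), var(as.numeric(b))))
  })
  expect_equal(mean(ratio), 0.5, tolerance = 0.05)

  expect_error(average_phase_runs(zf, zf), "forward and .* reverse")
  zr2 <- phase_series(matrix(0, 2, 64), 2, 8, 16, "reverse", brightness = 1)
  expect_error(average_phase_runs(zf, zr2), "mismatch")
})

test_that("Fourier amplitude reproduces the closed-form percent chain", {
  nt <- 256L; tr <- 2; n_cyc <- 20L
  tt <- (seq_len(nt) - 1L) * tr

  # cosine with peak-to-peak 2 on brightness 100 -> amplitude 2%
  x <- 100 + cos(2 * pi * n_cyc * tt / (nt * tr))
  ps <- phase_series(matrix(x, 1), tr, n_cyc, nt * tr / n_cyc, "forward",
                     brightness = 100)
  fa <- fourier_amplitude(ps)
  expect_equal(fa$amplitude, 100 * 2 / 100, tolerance = 1e-6)
  expect_gt(fa$f_ratio, 1e6)

  # general oracle: peak-to-peak p on brightness B -> 100 * p / B
  p2p <- 3.4; B <- 250
  x2 <- B + (p2p / 2) * cos(2 * pi * n_cyc * tt / (nt * tr) + 0.7)
  ps2 <- phase_series(matrix(x2, 1), tr, n_cyc, nt * tr / n_cyc, "forward",
                      brightness = B)
  expect_equal(fourier_amplitude(ps2)$amplitude, 100 * p2p / B,
               tolerance = 1e-6)

  # all-zero series (on positive brightness) -> 0%
  ps0 <- phase_series(matrix(0, 1, nt), tr, n_cyc, nt * tr / n_cyc,
                      "forward", brightness = 100)
  expect_equal(fourier_amplitude(ps0)$amplitude, 0)

  # drift below the 0.005 Hz cutoff contributes nothing to the stimulus bin
  # (bin 1 of a 512-s run is ~0.00195 Hz, excluded from the noise set too)
  drift <- 100 + 5 * cos(2 * pi * 1 * tt / (nt * tr))
  psd <- phase_series(matrix(drift, 1), tr, n_cyc, nt * tr / n_cyc,
                      "forward", brightness = 100)
  fad <- fourier_amplitude(psd)
  expect_lt(fad$amplitude, 1e-10)

  expect_error(fourier_amplitude(phase_series(matrix(x, 1), tr, n_cyc,
                                              nt * tr / n_cyc, "forward",
                                              brightness = 0)),
               "brightness")
})

test_that("depth profiles calibrate against rest fluctuations", {
  task <- seq(1, 3, length.out = 21L)
  rest <- runif(21L, 0.8, 1.2)
  pr <- calibrated_depth_profile(task, rest)
  # monotone task profile: normalized endpoints exactly 0 and 1
  expect_equal(pr$normalized[c(1L, 21L)], c(0, 1))
  expect_true(all(pr$normalized >= 0 & pr$normalized <= 1))

  # rest identical to task: calibrated equals t / (t + 0.05) elementwise,
  # approximately constant (~1) wherever the normalized profile is away
  # from zero
  pr2 <- calibrated_depth_profile(task, task)
  expect_equal(pr2$calibrated, pr2$normalized / (pr2$normalized + 0.05),
               tolerance = 1e-12)
  hi <- pr2$normalized >= 0.5
  expect_lt(diff(range(pr2$calibrated[hi])), 0.1)

  # subtraction mode
  pr3 <- calibrated_depth_profile(task, task, mode = "subtract")
  expect_equal(pr3$calibrated, rep(0, 21L))

  expect_error(calibrated_depth_profile(task, rep(1, 21L)), "range")
})

test_that("peak/decay metrics integrate the calibrated curve over compartments", {
  fr <- seq(0, 1, length.out = 21L)
  lc <- make_compartments(c(0.3, 0.3, 0.4))
  flat <- structure(list(amplitude = rep(1, 21L), normalized = rep(0.5, 21L),
                         rest_normalized = rep(0.5, 21L),
                         calibrated = rep(1, 21L)),
                    class = "depth_response_profile")
  m <- peak_decay_metrics(flat, lc)
  expect_equal(m$peak, 0)
  expect_equal(m$decay, 0)

  # 20% superficial exclusion retains 17 of 21 depths
  expect_identical(sum(fr >= 0.2), 17L)

  # triangular bump centred in the middle compartment: analytic area
  centre <- (lc$f1 + lc$f2) / 2
  halfw <- 0.12
  cal <- pmax(0, 1 - abs(fr - centre) / halfw)
  tri <- structure(list(amplitude = cal, normalized = cal,
                        rest_normalized = rep(0.5, 21L), calibrated = cal),
                   class = "depth_response_profile")
  m2 <- peak_decay_metrics(tri, lc)
  med <- median(cal[fr >= 0.2])
  expect_equal(med, 0)          # bump occupies < half the retained depths
  expect_lt(abs(m2$peak - halfw), 0.02)  # triangle area = base*h/2
  expect_equal(m2$decay, 0)

  expect_error(peak_decay_metrics(tri, make_compartments(c(0.01, 0.02, 0.97)),
                                  depth_fractions = fr + 10))
})

test_that("noise ceiling follows the Spearman-Brown prophecy", {
  h <- rnorm(50)
  expect_equal(noise_ceiling(h, h), 1)

  # construct halves with exact correlation 0.5
  set.seed(5)
  a <- scale(rnorm(200))[, 1L]
  e <- residuals(lm(rnorm(200) ~ a))
  e <- e / sd(e)
  b <- 0.5 * a + sqrt(0.75) * e
  r <- cor(a, b)
  expect_equal(noise_ceiling(a, b), 2 * r / (1 + r))
  expect_equal(noise_ceiling(a, b), 2 / 3, tolerance = 0.02)

  # independent noise halves: ceiling near zero on average
  set.seed(6)
  ceilings <- replicate(200, noise_ceiling(rnorm(100), rnorm(100)))
  expect_lt(mean(ceilings), 0.15)
  expect_equal(median(ceilings), 0, tolerance = 0.1)

  expect_error(noise_ceiling(rep(1, 10), rnorm(10)), "constant")
})

test_that("RLC eigenvector centrality matches a dense eigendecomposition", {
  set.seed(8)
  # identical timecourses: equal centralities
  tc <- matrix(rep(rnorm(80), 4), 4, byrow = TRUE)
  expect_equal(ecm_rlc(tc), rep(0.5, 4))

  # hub topology: hub correlated with all, others mutually independent
  n <- 12L; nt <- 400L
  hub <- rnorm(nt)
  x <- rbind(hub, t(replicate(n - 1L, 0.9 * hub + sqrt(1 - 0.81) * rnorm(nt))))
  # make spokes mutually decorrelated by regressing out nothing; their shared
  # hub component keeps the hub most central
  cm <- ecm_rlc(x)
  expect_identical(which.max(cm), 1L)
  a <- cor(t(x)); a[a < 0] <- 0; diag(a) <- 0
  ev <- eigen(a, symmetric = TRUE)$vectors[, 1L]
  ev <- abs(ev) / sqrt(sum(ev^2))
  expect_equal(cm, ev, tolerance = 1e-8)

  # rectification: anti-correlated pair contributes zero adjacency
  y <- rbind(hub, -hub + 0.01 * rnorm(nt), rnorm(nt))
  a2 <- cor(t(y)); a2[a2 < 0] <- 0; diag(a2) <- 0
  expect_equal(a2[1L, 2L], 0)

  # permutation equivariance
  perm <- sample(n)
  expect_equal(ecm_rlc(x[perm, ]), cm[perm], tolerance = 1e-7)

  # mutually anti-correlated triple: all-zero adjacency, uniform centrality
  expect_warning(out <- ecm_rlc(rbind(c(1, -1, 0), c(-1, 0, 1), c(0, 1, -1))),
                 "uniform")
  expect_equal(out, rep(1 / sqrt(3), 3))
})
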