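test_that("dFF uses the filtered 5th-percentile baseline and is gain invariant", {
  # constant trace -> dFF identically zero
  f <- matrix(100, 1, 300)
  expect_lt(max(abs(delta_f_over_f(f))), 1e-12)

  # baseline 100 with brief transients to 200 (< 5% of samples)
  set.seed(3)
  tr <- rep(100, 3000)
  tr[sample(3000, 100)] <- 200
  d <- delta_f_over_f(matrix(tr, 1))
  f0 <- attr(d, "f0")
  expect_equal(f0, 100, tolerance = 2)
  expect_equal(max(d), 1.0, tolerance = 0.05)

  # gain invariance: multiplicative rescaling leaves dFF unchanged
  d2 <- delta_f_over_f(matrix(3.7 * tr, 1))
  expect_equal(as.numeric(d2), as.numeric(d), tolerance = 1e-12)

  # filter kernel: 61 taps (order 60), unit dc gain, symmetric (zero phase)
  k <- fir_lowpass_kernel(1, 30, 60L)
  expect_length(k, 61L)
  expect_equal(sum(k), 1)
  expect_equal(k, rev(k))

  # F0 <= 0 flags the neuron
  expect_warning(dneg <- delta_f_over_f(rbind(tr, rep(-5, 3000))),
                 "excluded")
  expect_identical(attr(dneg, "excluded"), 2L)
  expect_true(all(is.na(dneg[2L, ])))
})

test_that("movement labeling applies the three speed criteria and the 500-ms gap rule", {
  fs <- 30
  expect_false(any(label_movement_epochs(rep(0, 300), fs)))

  # sustained 0.6 cm/s for 3 s: movement over the bout's core
  sp <- rep(0, 450)
  sp[150:239] <- 0.6
  m <- label_movement_epochs(sp, fs)
  expect_true(all(m[180:209]))        # central second fully labeled
  expect_false(any(m[1:100]))
  expect_false(any(m[300:450]))

  # two bouts separated by 400 ms merge into one
  sp2 <- rep(0, 900)
  sp2[100:250] <- 2
  sp2[263:420] <- 2                   # 12-frame (400 ms) gap
  m2 <- label_movement_epochs(sp2, fs)
  r <- rle(m2)
  expect_identical(sum(r$values), 1L)

  # a 700-ms gap stays split
  sp3 <- rep(0, 900)
  sp3[100:250] <- 2
  sp3[272:430] <- 2                   # 21-frame gap
  expect_identical(sum(rle(label_movement_epochs(sp3, fs))$values), 2L)

  # raising the threshold can only shrink the raw mask
  set.seed(12)
  sp4 <- abs(rnorm(600)) + as.numeric(runif(600) < 0.1) * 2
  m_lo <- label_movement_epochs(sp4, fs, threshold = 0.5, fill_gaps = FALSE)
  m_hi <- label_movement_epochs(sp4, fs, threshold = 0.8, fill_gaps = FALSE)
  expect_true(all(m_lo | !m_hi))
})

test_that("double-vs-single classification recovers generated mixtures", {
  ca <- gen_calcium_traces(n_neurons = 60L, n_stim = 20L, seed = 14)
  dff <- delta_f_over_f(ca$f)
  cl <- classify_double_vs_single(dff, ca$onsets_double, ca$onsets_single,
                                  fs = ca$fs)
  truth <- as.numeric(table(ca$class)) / length(ca$class)
  expect_lte(max(abs(cl$proportions - truth)), 0.10)

  # double = single exactly, noiseless -> unchanged
  flat <- matrix(0, 1, 3000)
  flat[1, 300 + 0:5] <- 1
  flat[1, 1500 + 0:5] <- 1
  on_d <- c(10, 20, 30, 40, 50) + 0.0
  on_s <- c(60, 70, 80, 90, 99) - 5
  cl2 <- classify_double_vs_single(matrix(0, 1, 3300), on_d, on_s)
  expect_identical(as.character(cl2$class), "unchanged")

  # too few usable trials excludes the neuron
  cl3 <- classify_double_vs_single(matrix(rnorm(300), 1), c(1, 2), c(3, 4))
  expect_identical(cl3$n_excluded, 1L)
  expect_true(is.na(cl3$class[1L]))
})

test_that("null double/single populations stay mostly unchanged at the nominal level", {
  set.seed(15)
  fs <- 30
  nt <- 9000L
  on_d <- seq(10, 140, by = 10)
  on_s <- seq(155, 285, by = 10)
  n_neuron <- 80L
  dff <- matrix(rnorm(n_neuron * nt, sd = 0.2), n_neuron, nt)
  cl <- classify_double_vs_single(dff, on_d, on_s, fs = fs, alpha = 0.05)
  fpr <- 1 - cl$proportions[["unchanged"]]
  se <- sqrt(0.05 * 0.95 / n_neuron)
  expect_lte(abs(fpr - 0.05), 2.5 * se + 0.01)
})

test_that("histological densities bin depth positions and normalize to DAPI", {
  set.seed(16)
  pos <- runif(1000)
  bd <- bin_depth_density(pos, dapi_positions = runif(4000), n_bins = 10L)
  expect_identical(sum(bd$bins$count), 1000L)
  expect_true(all(abs(bd$bins$count - 100) < 40))  # ~binomial fluctuation

  # zero marker cells
  bd0 <- bin_depth_density(numeric(0), dapi_positions = runif(100),
                           n_bins = 5L)
  expect_true(all(bd0$layers$density == 0))
  expect_true(all(bd0$layers$percent_dapi == 0))

  # layer split at the demarcation fractions; density = count / span
  pos2 <- c(0.1, 0.2, 0.35, 0.5, 0.9)
  bd2 <- bin_depth_density(pos2, dapi_positions = pos2, n_bins = 4L,
                           demarcations = c(0.30, 0.45))
  expect_equal(bd2$layers$count, c(2, 1, 2))
  expect_equal(bd2$layers$density, c(2 / 0.30, 1 / 0.15, 2 / 0.55))
  expect_true(all(bd2$layers$percent_dapi == 100))

  expect_error(bin_depth_density(c(-0.1, 0.5), runif(5)), "0, 1")
})
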