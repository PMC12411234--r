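test_that("detrending and peak detection follow the prominence rule", {
  pos <- seq(0, 30, by = 0.25)

  # pure linear ramp: detrended identically zero, no peaks
  r <- detrend_and_detect_peaks(pos, 1800 + 12 * pos)
  expect_lt(max(abs(r$detrended)), 1e-9)
  expect_identical(nrow(r$peaks), 0L)

  # flat baseline with small ripple + one Gaussian bump well above threshold
  sigma_bump <- 1.2
  ripple <- 3 * sin(2 * pi * pos / 7)
  bump <- 60 * exp(-((pos - 12)^2) / (2 * sigma_bump^2))
  r2 <- detrend_and_detect_peaks(pos, 1800 + ripple + bump)
  expect_identical(nrow(r2$peaks), 1L)
  expect_lte(abs(r2$peaks$position - 12), 0.25)
  # FWHM of a Gaussian bump: 2.355 sigma (half-prominence width)
  expect_equal(r2$peaks$fwhm, 2.3548 * sigma_bump, tolerance = 0.08)

  # bump below the prominence threshold yields no peak: a concave arc sets
  # the threshold scale, the 5-ms bump stays under it
  arc <- 30 * ((pos - 15) / 15)^2
  r3 <- detrend_and_detect_peaks(pos, 1800 + arc +
                                   5 * exp(-((pos - 12)^2) / 2))
  expect_identical(nrow(r3$peaks), 0L)

  # constant signal: empty peak list, not an error
  r4 <- detrend_and_detect_peaks(pos, rep(1900, length(pos)))
  expect_identical(nrow(r4$peaks), 0L)

  # threshold switch: "2sd" reading is laxer for zero-mean-heavy signals
  expect_lte(detrend_and_detect_peaks(pos, 1800 + ripple + bump,
                                      threshold_rule = "2sd")$threshold,
             r2$threshold)
})

test_that("peak prominences match a definition-based oracle on random signals", {
  set.seed(77)
  for (rep in 1:200) {
    x <- cumsum(rnorm(60))
    mine <- find_peaks_prominence(x)
    orac <- oracle_peaks(x)
    expect_identical(mine$index, as.integer(orac$index))
    expect_equal(mine$prominence, orac$prominence, tolerance = 1e-12)
  }
})

test_that("peak grouping enforces the three-of-five and five-mm rules", {
  mk <- function(pos, prom = 50) {
    data.frame(index = seq_along(pos), position = pos,
               height = rep_len(prom, length(pos)),
               prominence = rep_len(prom, length(pos)),
               fwhm = rep_len(2, length(pos)))
  }
  none <- mk(numeric(0))

  # aligned peaks on 3 of 5 paths -> one border
  pk <- list(mk(10), mk(10), mk(10), none, none)
  b <- group_peaks_to_borders(pk)
  expect_length(b, 1L)
  expect_equal(b[[1L]]$position, 10)
  expect_identical(b[[1L]]$paths, c(1L, 2L, 3L))

  # only 2 paths -> no border
  expect_length(group_peaks_to_borders(list(mk(10), mk(10), none, none,
                                            none)), 0L)

  # 6-mm offsets between neighbours -> not grouped
  expect_length(group_peaks_to_borders(list(mk(4), mk(10), mk(16), none,
                                            none)), 0L)

  # with lateral offsets, the between-path separation counts: aligned peaks
  # on paths 4.75 mm apart group, but 5 mm apart do not
  pk5 <- list(mk(10), mk(10), mk(10), mk(10), mk(10))
  expect_length(group_peaks_to_borders(pk5,
                                       path_offsets = 4.75 * (0:4)), 1L)
  expect_length(group_peaks_to_borders(pk5,
                                       path_offsets = 5 * (0:4)), 0L)

  # each peak belongs to at most one border
  pk2 <- list(mk(c(10, 20)), mk(c(10, 20)), mk(c(10, 20)), none, none)
  b2 <- group_peaks_to_borders(pk2)
  expect_length(b2, 2L)
  expect_equal(sort(vapply(b2, `[[`, numeric(1), "position")), c(10, 20))

  expect_length(group_peaks_to_borders(list(none, none, none, none, none)),
                0L)
})

test_that("detection is translation-equivariant on the phantom", {
  bs <- lapply(c(9, 14), function(ypos) {
    ph <- small_phantom(septa = list(list(y = ypos, amplitude = 100,
                                          width = 1.5)), seed = 31)
    detect_low_myelin_borders(ph$mesh, small_seeds[1L],
                              small_seeds[2L])$borders
  })
  expect_true(all(lengths(bs) >= 1L))
  p1 <- bs[[1L]][[which.min(abs(vapply(bs[[1L]], `[[`, numeric(1),
                                       "position") - 9))]]$position
  p2 <- bs[[2L]][[which.min(abs(vapply(bs[[2L]], `[[`, numeric(1),
                                       "position") - 14))]]$position
  expect_equal(p2 - p1, 5, tolerance = 0.5)
})

test_that("borders are classified against label bands and featurized by member means", {
  mk <- function(pos, prom = 50) {
    data.frame(index = seq_along(pos), position = pos,
               height = rep_len(prom, length(pos)),
               prominence = rep_len(prom, length(pos)),
               fwhm = rep_len(2, length(pos)))
  }
  none <- mk(numeric(0))
  b <- group_peaks_to_borders(list(mk(10, 60), mk(10, 40), mk(10, 50),
                                   none, none))[[1L]]

  bands <- list(face = c(0, 9), thumb = c(11, 14), index = c(14, 17))
  cf <- classify_and_featurize(b, bands,
                               overlays = list(qt1 = function(p) {
                                 if (p < 10.5) 1850 else 1950
                               }, ecm = 0.4))
  expect_identical(cf$class, "hand_face")
  expect_equal(unname(cf$features[["qt1"]]), 1850)
  expect_equal(unname(cf$features[["ecm"]]), 0.4)
  expect_equal(unname(cf$features[["prominence"]]), 50)

  # border above the most inferior finger band: within-hand
  b2 <- group_peaks_to_borders(list(mk(20, 60), mk(20, 40), mk(20, 50),
                                    none, none))[[1L]]
  expect_identical(classify_and_featurize(b2, bands)$class, "within_hand")

  expect_error(classify_and_featurize(b, list(thumb = c(1, 2))), "face")

  # two members averaged: 1850/1950 -> 1900
  s <- summarize_border_features(list(
    classify_and_featurize(b2, bands, overlays = list(qt1 = 1850)),
    classify_and_featurize(b2, bands, overlays = list(qt1 = 1950))))
  expect_equal(unname(s$within_hand[["qt1"]]), 1900)
  expect_null(s$hand_face)
})
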