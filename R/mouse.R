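# Two-photon calcium quantification, movement labeling, response
# classification and depth-binned histology.

#' Delta-F-over-F from raw fluorescence traces
#'
#' Per neuron, the raw 30-Hz trace is smoothed with a zero-phase 60th-order
#' FIR low-pass at 1 Hz; the baseline `F0` is the 5th percentile of the
#' smoothed trace, and `dFF = (F - F0) / F0`. Neurons with `F0 <= 0` are
#' flagged and excluded (rows of `NA`).
#'
#' @param f fluorescence matrix, neurons x timepoints (a.u.).
#' @param fs sampling rate in Hz (default 30).
#' @param cutoff_hz smoothing cutoff (default 1).
#' @param order FIR filter order (default 60).
#' @param probs baseline percentile (default 0.05).
#' @return matrix of dFF values with attributes `f0` (per-neuron baseline)
#'   and `excluded` (indices of flagged neurons).
#' @export
delta_f_over_f <- function(f, fs = 30, cutoff_hz = 1, order = 60L,
                           probs = 0.05) {
  f <- rbind(f)
  if (ncol(f) <= order) stop("delta_f_over_f: trace shorter than filter order")
  kern <- fir_lowpass_kernel(cutoff_hz, fs, order)
  f0 <- numeric(nrow(f))
  out <- matrix(NA_real_, nrow(f), ncol(f))
  excluded <- integer(0)
  for (i in seq_len(nrow(f))) {
    sm <- filter_zero_phase(f[i, ], kern)
    f0[i] <- stats::quantile(sm, probs, names = FALSE)
    if (f0[i] <= 0) {
      excluded <- c(excluded, i)
      next
    }
    out[i, ] <- (f[i, ] - f0[i]) / f0[i]
  }
  if (length(excluded)) {
    warning(sprintf("delta_f_over_f: %d neuron(s) excluded (F0 <= 0)",
                    length(excluded)))
  }
  attr(out, "f0") <- f0
  attr(out, "excluded") <- excluded
  out
}

#' Label whisker-pad movement epochs
#'
#' A frame is movement when all three speed criteria hold: instantaneous
#' speed, 0.25-Hz low-pass filtered speed, and mean speed over a centred
#' 1-second window, each at least `threshold` cm/s. Inter-movement gaps
#' shorter than `gap_ms` are then also labeled movement.
#'
#' @param speed whisker-pad speed (cm/s), sampled at `fs` Hz, nonnegative.
#' @param fs sampling rate in Hz (default 30).
#' @param threshold speed criterion in cm/s (default 0.5).
#' @param gap_ms maximum gap merged into movement (default 500).
#' @param fill_gaps apply the gap rule (set `FALSE` for the raw mask).
#' @return logical movement mask.
#' @export
label_movement_epochs <- function(speed, fs = 30, threshold = 0.5,
                                  gap_ms = 500, fill_gaps = TRUE) {
  stopifnot(all(speed >= 0))
  n <- length(speed)
  kern <- fir_lowpass_kernel(0.25, fs, 60L)
  lp <- filter_zero_phase(speed, kern)
  half <- floor(fs / 2)
  win_mean <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(speed[lo:hi])
  }, numeric(1))
  mask <- speed >= threshold & lp >= threshold & win_mean >= threshold
  if (fill_gaps && any(mask)) {
    gap_n <- round(gap_ms / 1000 * fs)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k] && r$lengths[k] < gap_n &&
          k > 1L && k < length(r$values)) {
        mask[starts[k]:ends[k]] <- TRUE
      }
    }
  }
  mask
}

#' Classify neurons by double- versus single-whisker response
#'
#' Per neuron and trial, the evoked amplitude is the mean dFF in the
#' `(0, post_s]` window after stimulus onset minus the mean in the `pre_s`
#' window before it. Double- and single-condition trial amplitudes are
#' compared with a Welch two-sample t-test: `additive` when double > single
#' at level `alpha`, `reduced` when double < single, else `unchanged`.
#'
#' @param dff dFF matrix, neurons x timepoints.
#' @param onsets_double,onsets_single stimulus onset times (s) per condition.
#' @param fs sampling rate in Hz (default 30).
#' @param pre_s,post_s baseline and evoked window lengths in seconds.
#' @param alpha test level (default 0.05).
#' @param min_trials minimum usable trials per condition (default 5).
#' @return list with `class` (factor per neuron, `NA` for excluded),
#'   `proportions` (over classified neurons), `n_excluded`, and `amplitudes`
#'   (per-neuron mean evoked amplitude per condition).
#' @export
classify_double_vs_single <- function(dff, onsets_double, onsets_single,
                                      fs = 30, pre_s = 1, post_s = 1,
                                      alpha = 0.05, min_trials = 5L) {
  dff <- rbind(dff)
  n_neuron <- nrow(dff)
  nt <- ncol(dff)
  amp <- function(trace, onsets) {
    vapply(onsets, function(t0) {
      i0 <- round(t0 * fs)
      pre <- (i0 - round(pre_s * fs) + 1L):i0
      post <- (i0 + 1L):(i0 + round(post_s * fs))
      if (min(pre) < 1L || max(post) > nt) return(NA_real_)
      mean(trace[post]) - mean(trace[pre])
    }, numeric(1))
  }
  classes <- rep(NA_character_, n_neuron)
  mean_d <- mean_s <- rep(NA_real_, n_neuron)
  n_excluded <- 0L
  for (i in seq_len(n_neuron)) {
    ad <- amp(dff[i, ], onsets_double)
    as_ <- amp(dff[i, ], onsets_single)
    ad <- ad[is.finite(ad)]
    as_ <- as_[is.finite(as_)]
    if (length(ad) < min_trials || length(as_) < min_trials) {
      n_excluded <- n_excluded + 1L
      next
    }
    mean_d[i] <- mean(ad)
    mean_s[i] <- mean(as_)
    if (stats::sd(ad) == 0 && stats::sd(as_) == 0) {
      classes[i] <- "unchanged"
      next
    }
    tt <- stats::t.test(ad, as_, var.equal = FALSE)
    classes[i] <- if (tt$p.value < alpha) {
      if (mean_d[i] > mean_s[i]) "additive" else "reduced"
    } else {
      "unchanged"
    }
  }
  lev <- c("additive", "reduced", "unchanged")
  cl <- factor(classes, levels = lev)
  props <- prop.table(table(cl))
  list(class = cl,
       proportions = as.numeric(props) |> stats::setNames(lev),
       n_excluded = n_excluded,
       amplitudes = data.frame(double = mean_d, single = mean_s))
}

#' Depth-binned histological cell densities
#'
#' Marker-positive cell positions are normalized from the brain surface (0)
#' to the white matter (1), binned across depth, and summarized per layer
#' (outer/middle/inner, split at the supplied demarcation fractions) as raw
#' count, density (count per unit normalized area) and percent of the DAPI
#' count in the same layer.
#'
#' @param positions marker cell depth positions in \[0, 1\].
#' @param dapi_positions DAPI (all-nuclei) depth positions in \[0, 1\].
#' @param n_bins number of depth histogram bins (>= 2).
#' @param demarcations layer split fractions, default `c(0.30, 0.45)`
#'   (supragranular / granular and granular / infragranular).
#' @param section_area optional physical section area scaling the density.
#' @return list with `bins` (histogram data frame) and `layers` (per-layer
#'   data frame: `count`, `density`, `percent_dapi`).
#' @export
bin_depth_density <- function(positions, dapi_positions, n_bins = 10L,
                              demarcations = c(0.30, 0.45),
                              section_area = 1) {
  stopifnot(n_bins >= 2L, length(demarcations) == 2L,
            all(diff(c(0, demarcations, 1)) > 0))
  if (length(positions) && (min(positions) < 0 || max(positions) > 1)) {
    stop("bin_depth_density: positions must lie in [0, 1]")
  }
  if (length(dapi_positions) &&
      (min(dapi_positions) < 0 || max(dapi_positions) > 1)) {
    stop("bin_depth_density: DAPI positions must lie in [0, 1]")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- if (length(positions)) {
    tabulate(findInterval(positions, breaks, rightmost.closed = TRUE),
             nbins = n_bins)
  } else {
    integer(n_bins)
  }
  bins <- data.frame(lower = utils::head(breaks, -1L),
                     upper = utils::tail(breaks, -1L),
                     count = counts)
  edges <- c(0, demarcations, 1)
  layer_names <- c("outer", "middle", "inner")
  layer_row <- function(lo, hi) {
    nmark <- sum(positions >= lo & positions <= hi &
                   (positions > lo | lo == 0))
    ndapi <- sum(dapi_positions >= lo & dapi_positions <= hi &
                   (dapi_positions > lo | lo == 0))
    area <- (hi - lo) * section_area
    c(count = nmark, density = nmark / area,
      percent_dapi = if (ndapi > 0) 100 * nmark / ndapi else 0)
  }
  lay <- t(vapply(seq_len(3L),
                  function(k) layer_row(edges[k], edges[k + 1L]),
                  numeric(3)))
  layers <- data.frame(layer = layer_names, lay)
  list(bins = bins, layers = layers)
}
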