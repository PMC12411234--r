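# Phase-encoded BOLD analysis: run averaging, Fourier amplitude, calibrated
# depth-response profiles, eigenvector centrality.

#' Phase-encoded BOLD series container
#'
#' @param samples numeric matrix, vertices x timepoints.
#' @param tr repetition time in seconds.
#' @param n_cycles number of stimulation cycles in the run.
#' @param cycle_s cycle duration in seconds.
#' @param direction `"forward"` or `"reverse"`.
#' @param rest_s total rest-block duration in seconds (default 0).
#' @param brightness mean brightness of the dataset (signal units).
#' @return a `phase_series` object.
#' @export
phase_series <- function(samples, tr, n_cycles, cycle_s,
                         direction = c("forward", "reverse"),
                         rest_s = 0, brightness = mean(samples)) {
  direction <- match.arg(direction)
  samples <- rbind(samples)
  stopifnot(tr > 0, n_cycles >= 1)
  nt <- ncol(samples)
  expected <- n_cycles * cycle_s + rest_s
  if (abs(nt * tr - expected) > tr / 2) {
    stop(sprintf(
      "phase_series: %d timepoints x TR %.3g s != %d cycles x %.3g s + %.3g s rest",
      nt, tr, n_cycles, cycle_s, rest_s))
  }
  structure(list(samples = samples, tr = tr, n_cycles = n_cycles,
                 cycle_s = cycle_s, direction = direction, rest_s = rest_s,
                 brightness = brightness),
            class = "phase_series")
}

#' Average a forward and a time-reversed run
#'
#' The reverse-order run is reversed in time (the two directions are mirror
#' symmetric), then circularly shifted by `shift_s` seconds (default 4 s = two
#' TRs at TR 2 s) to compensate twice the hemodynamic delay, and averaged
#' timepoint by timepoint with the forward run.
#'
#' @param forward,reverse `phase_series` of matching geometry; one tagged
#'   forward and one reverse.
#' @param shift_s hemodynamic compensation shift in seconds (default 4).
#' @return a `phase_series` tagged `"forward"`.
#' @export
average_phase_runs <- function(forward, reverse, shift_s = 4) {
  stopifnot(inherits(forward, "phase_series"), inherits(reverse, "phase_series"))
  if (forward$direction != "forward" || reverse$direction != "reverse") {
    stop("average_phase_runs: needs one forward and one reverse run")
  }
  if (!identical(dim(forward$samples), dim(reverse$samples)) ||
      forward$tr != reverse$tr || forward$n_cycles != reverse$n_cycles) {
    stop("average_phase_runs: shape/TR/cycle mismatch between runs")
  }
  shift <- round(shift_s / forward$tr)
  nt <- ncol(forward$samples)
  rev_t <- reverse$samples[, nt:1, drop = FALSE]
  # advance by `shift` samples (circular): compensates the doubled lag that
  # time reversal introduces
  idx <- ((seq_len(nt) - 1L + shift) %% nt) + 1L
  shifted <- rev_t[, idx, drop = FALSE]
  out <- forward
  out$samples <- (forward$samples + shifted) / 2
  out$brightness <- (forward$brightness + reverse$brightness) / 2
  out$direction <- "forward"
  out
}

#' Fourier response amplitude, phase and F-ratio of a phase-encoded run
#'
#' Discrete Fourier transform per vertex; the stimulus bin is the
#' `n_cycles`-th harmonic of the run. The percent response amplitude is the
#' DFT magnitude at the stimulus bin multiplied by 2 (positive and negative
#' frequencies), again by 2 (peak-to-peak), divided by the number of
#' timepoints and by the mean brightness, times 100. The F-ratio compares
#' stimulus-bin power with the mean power over noise bins: frequencies of at
#' least `lo_cut_hz` (default 0.005 Hz, below which movement artifacts
#' dominate) up to the Nyquist limit, excluding the stimulus bin and its first
#' two harmonics.
#'
#' @param series a [phase_series()] (stimulation part only, no rest blocks).
#' @param lo_cut_hz low-frequency exclusion cutoff in Hz.
#' @return data frame per vertex: `amplitude` (percent), `phase` (radians),
#'   `f_ratio`.
#' @export
fourier_amplitude <- function(series, lo_cut_hz = 0.005) {
  stopifnot(inherits(series, "phase_series"))
  if (series$rest_s > 0) {
    stop("fourier_amplitude: strip rest blocks before Fourier analysis")
  }
  x <- series$samples
  nt <- ncol(x)
  if (series$brightness <= 0) {
    stop("fourier_amplitude: mean brightness must be positive")
  }
  k_stim <- series$n_cycles            # cycles per run = DFT bin index
  if (k_stim < 2L) stop("fourier_amplitude: need n_cycles >= 2")
  freqs <- (0:(nt %/% 2)) / (nt * series$tr)
  k_max <- nt %/% 2
  if (k_stim > k_max || freqs[k_stim + 1L] < lo_cut_hz) {
    stop("fourier_amplitude: stimulus bin outside the included frequency range")
  }
  ft <- t(apply(x, 1L, function(v) stats::fft(v)))
  if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
  bins <- 0:k_max
  included <- freqs >= lo_cut_hz
  harmonics <- intersect(c(k_stim, 2L * k_stim, 3L * k_stim), bins)
  noise_bins <- setdiff(bins[included], harmonics)
  stim_col <- k_stim + 1L
  amp_raw <- Mod(ft[, stim_col])
  phase <- Arg(ft[, stim_col])
  noise_pow <- rowMeans(Mod(ft[, noise_bins + 1L, drop = FALSE])^2)
  f_ratio <- ifelse(noise_pow > 0, Mod(ft[, stim_col])^2 / noise_pow, Inf)
  amplitude <- amp_raw * 2 * 2 / nt / series$brightness * 100
  data.frame(amplitude = amplitude, phase = phase, f_ratio = f_ratio)
}

#' Calibrated layer-specific depth-response profile
#'
#' Task and resting-state depth profiles (21 depths, superficial to deep) are
#' min-max normalized, and the normalized task profile is calibrated by the
#' normalized rest profile to control for depth-dependent baseline
#' fluctuations: elementwise division by `(rest + eps)` with
#' `eps = eps_frac * range(rest)` (default), or subtraction when
#' `mode = "subtract"`.
#'
#' @param task_profile percent-signal-change amplitude per 21 depths.
#' @param rest_profile resting-state fluctuation amplitude per 21 depths.
#' @param mode `"divide"` (default) or `"subtract"`.
#' @param eps_frac regularization as a fraction of the normalized rest range.
#' @return a `depth_response_profile`: list with `amplitude`, `normalized`,
#'   `rest_normalized`, `calibrated`.
#' @export
calibrated_depth_profile <- function(task_profile, rest_profile,
                                     mode = c("divide", "subtract"),
                                     eps_frac = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(task_profile) == length(rest_profile))
  task_n <- minmax_norm(task_profile)
  rest_n <- minmax_norm(rest_profile)
  cal <- if (mode == "divide") {
    eps <- eps_frac * diff(range(rest_n))
    task_n / (rest_n + eps)
  } else {
    task_n - rest_n
  }
  structure(list(amplitude = task_profile, normalized = task_n,
                 rest_normalized = rest_n, calibrated = cal),
            class = "depth_response_profile")
}

#' Peak and decay metrics of a calibrated depth-response profile
#'
#' Depths in the most superficial `superficial_cut` fraction (default 20%,
#' retaining 17 of 21 depths) are excluded to avoid superficial veins. The
#' peak metric is the trapezoidal area of `(calibrated - median)` over the
#' middle compartment; the decay metric is the mean over the outer and inner
#' flanks of the area of `(median - calibrated)`, each flank clipped at 0.
#'
#' @param profile a [calibrated_depth_profile()] result.
#' @param compartments a [compartmentalize_profile()] result (boundaries as
#'   fractions of the retained 19-depth range).
#' @param depth_fractions depth grid of the profile (default equidistant 21).
#' @param superficial_cut fraction of superficial depth excluded.
#' @return list with `peak` and `decay`.
#' @export
peak_decay_metrics <- function(profile, compartments,
                               depth_fractions = seq(0, 1, length.out = 21L),
                               superficial_cut = 0.2) {
  stopifnot(inherits(profile, "depth_response_profile"),
            inherits(compartments, "layer_compartments"))
  cal <- profile$calibrated
  stopifnot(length(cal) == length(depth_fractions))
  keep <- depth_fractions >= superficial_cut
  x <- depth_fractions[keep]
  y <- cal[keep]
  f1 <- compartments$f1
  f2 <- compartments$f2
  if (f2 <= min(x) || f1 >= max(x)) {
    stop("peak_decay_metrics: compartments do not overlap retained depths")
  }
  med <- stats::median(y)
  seg_auc <- function(lo, hi, vals) {
    lo <- max(lo, min(x)); hi <- min(hi, max(x))
    if (hi <= lo) return(0)
    xs <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
    ys <- stats::approx(x, vals, xout = xs)$y
    trapz(xs, ys)
  }
  peak <- seg_auc(f1, f2, y - med)
  dec_outer <- max(0, seg_auc(min(x), f1, med - y))
  dec_inner <- max(0, seg_auc(f2, max(x), med - y))
  list(peak = peak, decay = mean(c(dec_outer, dec_inner)))
}

#' Spearman-Brown noise ceiling
#'
#' Splits of the data (e.g. two half-runs) are correlated and the reliability
#' of the full-length series is prophesied as `2 r / (1 + r)`, floored at 0:
#' the maximum goodness of fit a model could achieve.
#'
#' @param half1,half2 equal-length numeric vectors.
#' @return ceiling in \[0, 1\].
#' @export
noise_ceiling <- function(half1, half2) {
  stopifnot(length(half1) == length(half2))
  if (stats::sd(half1) == 0 || stats::sd(half2) == 0) {
    stop("noise_ceiling: constant half series")
  }
  r <- stats::cor(half1, half2)
  max(0, 2 * r / (1 + r))
}

#' Eigenvector centrality with rectified linear unit correlation (RLC)
#'
#' Adjacency is the pairwise Pearson correlation rectified at zero with zero
#' diagonal; centrality is the principal eigenvector obtained by power
#' iteration (tolerance 1e-10), nonnegative and normalized to unit Euclidean
#' norm.
#'
#' @param timeseries numeric matrix, vertices x timepoints (>= 3 vertices).
#' @param tol power-iteration convergence tolerance.
#' @param max_iter iteration cap.
#' @return numeric vector of per-vertex centralities.
#' @export
ecm_rlc <- function(timeseries, tol = 1e-10, max_iter = 10000L) {
  x <- rbind(timeseries)
  n <- nrow(x)
  stopifnot(n >= 3L)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) stop("ecm_rlc: constant vertex time series")
  a <- stats::cor(t(x))
  a[a < 0] <- 0
  diag(a) <- 0
  if (all(a == 0)) {
    warning("ecm_rlc: all-zero adjacency; returning uniform centrality")
    return(rep(1 / sqrt(n), n))
  }
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(a %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  abs(v)
}
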