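# Synthetic cortical phantoms and observers: every input the pipeline
# consumes, generated with the statistical structure the study reports.

#' Cohort parameter sets for the cortical phantom
#'
#' Population means (and s.d.) behind the phantom: layer-specific cortical
#' thickness of the hand area (total/outer/middle/inner, mm) and compartment
#' qT1 means (ms). Thickness: younger 2.06 (0.41/0.56/1.10) mm, older
#' 1.94 (0.40/0.85/0.69) mm. qT1: younger middle 1874.4 / inner 1636.3 ms,
#' older middle 1783.2 / inner 1547.6 ms; the outer-compartment mean (2100
#' ms, equal for both cohorts) is a design choice since no group value is
#' reported for it.
#'
#' @param cohort `"younger"` or `"older"`.
#' @return list of cohort parameters.
#' @export
cohort_params <- function(cohort = c("younger", "older")) {
  cohort <- match.arg(cohort)
  if (cohort == "younger") {
    list(cohort = "younger", n = 20L,
         thickness = c(total = 2.06, outer = 0.41, middle = 0.56,
                       inner = 1.10),
         qt1 = c(outer = 2100, middle = 1874.4, inner = 1636.3))
  } else {
    list(cohort = "older", n = 19L,
         thickness = c(total = 1.94, outer = 0.40, middle = 0.85,
                       inner = 0.69),
         qt1 = c(outer = 2100, middle = 1783.2, inner = 1547.6))
  }
}

#' Phantom specification
#'
#' @param cohort `"younger"` or `"older"`; sets thickness and qT1 means.
#' @param nx,ny,pitch strip mesh geometry (vertices and mm pitch).
#' @param thickness_sd between-subject s.d. of total thickness (mm).
#' @param qt1_noise_sd total vertex-level qT1 noise s.d. per depth sample
#'   (ms), default 30. The noise decomposes into a columnar biological
#'   component (mesoscale myelin variation, coherent across depths, smooth
#'   along the surface) and independent per-depth measurement noise; the
#'   middle-compartment overlay used for border detection averages depths and
#'   therefore suppresses only the measurement part.
#' @param columnar_frac fraction of the noise variance that is columnar /
#'   biological (default 0.9).
#' @param noise_corr_mm correlation length of the columnar field along the
#'   inferior-superior (path) direction, mm (default 4).
#' @param noise_corr_x_mm correlation length across the anterior-posterior
#'   (path-family) direction, mm (default 0): in a null phantom there is by
#'   definition no qT1 structure coherent across neighbouring paths -- any
#'   such coherent ridge would be a real septum-like feature.
#' @param septa list of septa, each `list(y = mm, amplitude = ms,
#'   width = mm)`; a septum is a ridge of elevated qT1 at middle depths.
#' @param transition_sd depth-fraction width of the smooth plateau steps.
#' @param seed integer seed recorded in all outputs.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(cohort = "younger", nx = 81L, ny = 121L, pitch = 0.25,
                         thickness_sd = 0.05, qt1_noise_sd = 30,
                         columnar_frac = 0.9, noise_corr_mm = 4,
                         noise_corr_x_mm = 0, septa = list(),
                         transition_sd = 0.04, seed = 1L) {
  cp <- cohort_params(cohort)
  structure(list(cohort = cp$cohort, n = cp$n, thickness = cp$thickness,
                 qt1 = cp$qt1, nx = as.integer(nx), ny = as.integer(ny),
                 pitch = pitch, thickness_sd = thickness_sd,
                 qt1_noise_sd = qt1_noise_sd, columnar_frac = columnar_frac,
                 noise_corr_mm = noise_corr_mm,
                 noise_corr_x_mm = noise_corr_x_mm,
                 septa = septa, transition_sd = transition_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth unit-variance Gaussian noise field on the nx x ny grid, one column
# per depth; separable Gaussian smoothing with per-axis correlation lengths
# (in pixels). sigma_x = 0 leaves columns independent.
smooth_grid_noise <- function(nx, ny, d, sigma_x_px, sigma_y_px) {
  raw <- matrix(stats::rnorm(nx * ny * d), nx * ny, d)
  if (sigma_x_px <= 0 && sigma_y_px <= 0) return(raw)
  make_kernel <- function(sigma) {
    if (sigma <= 0) return(1)
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k / sum(k)
  }
  kx <- make_kernel(sigma_x_px)
  ky <- make_kernel(sigma_y_px)
  smooth1d <- function(m, k) {
    if (length(k) == 1L) return(m)
    half <- (length(k) - 1L) %/% 2L
    apply(m, 2L, function(v) {
      vp <- c(rep(v[1L], half), v, rep(v[length(v)], half))
      as.numeric(stats::convolve(vp, rev(k), type = "filter"))
    })
  }
  scale <- sqrt(sum(kx^2) * sum(ky^2))
  out <- matrix(0, nx * ny, d)
  for (j in seq_len(d)) {
    g <- matrix(raw[, j], nx, ny)
    g <- smooth1d(g, kx)       # along x (anterior-posterior)
    g <- t(smooth1d(t(g), ky)) # along y (inferior-superior, path direction)
    out[, j] <- as.numeric(g) / scale
  }
  out
}

# smooth three-plateau depth profile: value v1 above f1, v2 between, v3 below,
# logistic transitions of width sd
plateau_profile <- function(depth_fractions, f1, f2, values, sd) {
  s1 <- stats::plogis((depth_fractions - f1) / sd)
  s2 <- stats::plogis((depth_fractions - f2) / sd)
  values[1L] + (values[2L] - values[1L]) * s1 +
    (values[3L] - values[2L]) * s2
}

#' Generate a cortical strip phantom
#'
#' Rectangular cortical strip mesh with inferior face and superior finger
#' label bands, per-vertex 21-depth qT1 profiles built from the cohort's
#' three-plateau structure (compartment boundaries at the cohort thickness
#' fractions, smooth logistic transitions, Gaussian vertex noise), optional
#' low-myelin septa injected as Gaussian ridges of elevated qT1 at middle
#' depths, and ground truth (boundary fractions, per-subject thickness,
#' septum positions).
#'
#' @param spec a [phantom_spec()].
#' @return list with `mesh` (labels overlay: 0 face band, 1..5 finger bands;
#'   `qt1_mid` overlay: middle-depth qT1), `profiles` (vertices x 21 qT1
#'   matrix), `depth_fractions`, `truth` (list: `f1`, `f2`, `spans`,
#'   `total_thickness`, `septa`), and `spec`.
#' @export
gen_cortex_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  mesh <- grid_strip_mesh(spec$nx, spec$ny, spec$pitch)
  nv <- nrow(mesh$vertices)
  yy <- mesh$vertices[, 2L]
  y_max <- max(yy)
  th <- spec$thickness
  spans <- th[c("outer", "middle", "inner")] / sum(th[c("outer", "middle",
                                                        "inner")])
  f1 <- unname(spans[1L])
  f2 <- unname(spans[1L] + spans[2L])
  for (sp in spec$septa) {
    if (sp$y < 0 || sp$y > y_max) stop("gen_cortex_phantom: septum outside mesh")
  }
  d <- 21L
  # profiles are defined on the retained (19-depth) thickness range extended
  # to 21 depths: the two deepest depths continue the inner plateau
  depth_fractions <- seq(0, 1, length.out = d)
  retained_max <- depth_fractions[d - 2L]
  frac_retained <- pmin(depth_fractions / retained_max, 1)
  base <- plateau_profile(frac_retained, f1, f2,
                          unname(spec$qt1[c("outer", "middle", "inner")]),
                          spec$transition_sd)
  profiles <- matrix(rep(base, each = nv), nrow = nv)
  # septa: elevated qT1 ridge spanning the middle-compartment depths
  # (Gaussian along y, soft-edged plateau across the middle band in depth)
  mid_f <- (f1 + f2) / 2
  depth_w <- stats::plogis((frac_retained - f1) / 0.03) *
    (1 - stats::plogis((frac_retained - f2) / 0.03))
  for (sp in spec$septa) {
    ridge <- sp$amplitude * exp(-((yy - sp$y)^2) / (2 * sp$width^2))
    profiles <- profiles + outer(ridge, depth_w)
  }
  # noise: columnar biological field (shared across depths) + independent
  # per-depth measurement noise
  sd_bio <- spec$qt1_noise_sd * sqrt(spec$columnar_frac)
  sd_meas <- spec$qt1_noise_sd * sqrt(1 - spec$columnar_frac)
  bio <- sd_bio * smooth_grid_noise(spec$nx, spec$ny, 1L,
                                    sigma_x_px = spec$noise_corr_x_mm /
                                      spec$pitch,
                                    sigma_y_px = spec$noise_corr_mm /
                                      spec$pitch)[, 1L]
  profiles <- profiles + bio + matrix(stats::rnorm(nv * d, sd = sd_meas),
                                      nv, d)
  # labels: inferior third = face (0), rest split into 5 finger bands (1..5)
  labels <- integer(nv)
  face_cut <- y_max / 3
  fingers <- findInterval(yy, seq(face_cut, y_max,
                                  length.out = 6L)[-c(1L, 6L)]) + 1L
  labels[yy > face_cut] <- fingers[yy > face_cut]
  # middle-compartment overlay = mean qT1 over the middle-compartment depths
  mid_idx <- which(frac_retained > f1 & frac_retained < f2)
  if (length(mid_idx) == 0L) mid_idx <- which.min(abs(frac_retained - mid_f))
  mesh <- set_overlay(mesh, "labels", labels)
  mesh <- set_overlay(mesh, "qt1_mid",
                      rowMeans(profiles[, mid_idx, drop = FALSE]))
  total <- stats::rnorm(spec$n, th[["total"]], spec$thickness_sd)
  list(mesh = mesh, profiles = profiles, depth_fractions = depth_fractions,
       truth = list(f1 = f1, f2 = f2, spans = spans,
                    total_thickness = total,
                    septa = spec$septa),
       spec = spec)
}

#' Generate phase-encoded BOLD series with a laminar response peak
#'
#' Boxcar traveling-wave stimulation over finger positions, convolved with
#' the canonical HRF, scaled by a depth-dependent gain peaking at the middle
#' compartment, with AR(1) noise and a brightness offset. Rows of the output
#' are the 21 cortical depths of one ROI-average vertex. A matching rest
#' (noise-only) series is returned.
#'
#' @param design list with `tr` (s), `n_cycles`, `cycle_s` (s), and
#'   optionally `rest_s` (total rest seconds, stripped before analysis).
#'   Cohort-1 default: `tr = 2, n_cycles = 20, cycle_s = 25.6` (256 volumes);
#'   cohort-2: `tr = 2, n_cycles = 8, cycle_s = 32, rest_s = 64`
#'   (160 volumes).
#' @param peak_gain response gain at the middle-compartment peak (percent
#'   amplitude scale); older cohorts use a larger value to emulate the more
#'   pronounced sensory input peak.
#' @param depth_fractions depth grid (length 21).
#' @param mid_f depth fraction of the gain peak.
#' @param noise_sd AR(1) innovation s.d.; `rho` its coefficient.
#' @param brightness mean brightness offset.
#' @param seed integer seed.
#' @return list with `forward`, `reverse`, `rest` ([phase_series()] of
#'   21 depth rows, rest blocks already stripped), `gain` (ground-truth
#'   depth gain) and `n_volumes` (volumes per run including rest).
#' @export
gen_phase_encoded_bold <- function(design = list(tr = 2, n_cycles = 20,
                                                 cycle_s = 25.6),
                                   peak_gain = 2, depth_fractions =
                                     seq(0, 1, length.out = 21L),
                                   mid_f = 0.4, noise_sd = 0.5, rho = 0.4,
                                   brightness = 100, seed = 1L) {
  tr <- design$tr
  n_cycles <- design$n_cycles
  cycle_s <- design$cycle_s
  rest_s <- if (is.null(design$rest_s)) 0 else design$rest_s
  n_stim <- n_cycles * cycle_s / tr
  if (abs(n_stim - round(n_stim)) > 1e-9) {
    stop("gen_phase_encoded_bold: cycle duration not a multiple of TR")
  }
  n_stim <- as.integer(round(n_stim))
  n_vol <- n_stim + as.integer(round(rest_s / tr))
  set.seed(seed)
  nd <- length(depth_fractions)
  gain <- peak_gain * exp(-((depth_fractions - mid_f)^2) / (2 * 0.12^2))
  # traveling-wave boxcar: stimulus on during the first fifth of each cycle
  # (the ROI's preferred finger), HRF-convolved
  tt <- (seq_len(n_stim) - 1L) * tr
  phase <- (tt %% cycle_s) / cycle_s
  stim <- as.numeric(phase < 0.2)
  resp <- convolve_hrf(stim, tr)
  resp <- resp / max(resp)
  ar1 <- function(n) {
    e <- stats::rnorm(n, sd = noise_sd)
    as.numeric(stats::filter(e, rho, method = "recursive"))
  }
  mk <- function(signal_rows, direction) {
    s <- signal_rows + t(vapply(seq_len(nd), function(i) ar1(n_stim),
                                numeric(n_stim))) + brightness
    phase_series(s, tr, n_cycles, cycle_s, direction,
                 rest_s = 0, brightness = brightness)
  }
  sig_f <- outer(gain, resp)
  # reverse run: mirrored stimulus order; consistent with average_phase_runs
  # when reversed and advanced by the hemodynamic shift
  shift <- as.integer(round(4 / tr))
  sig_r <- sig_f[, rev(((seq_len(n_stim) - 1L - shift) %% n_stim) + 1L),
                 drop = FALSE]
  forward <- mk(sig_f, "forward")
  reverse <- mk(sig_r, "reverse")
  rest <- mk(matrix(0, nd, n_stim), "forward")
  list(forward = forward, reverse = reverse, rest = rest, gain = gain,
       n_volumes = n_vol)
}

#' Simulate a psychophysical observer
#'
#' Logistic psychometric observers for the 2AFC detection staircase and the
#' 2PD block design, with ground truth recorded.
#'
#' For `task = "staircase"`: a 3-down/1-up 2AFC session on the intensity
#' `ladder` with two interleaved staircases (starting by default at the
#' ladder values nearest 0.02 g and 0.4 g), stopping when the s.d. of the
#' last 30 intensities is at most one ladder step or at `max_trials`.
#' P(correct) = 0.5 + (0.5 - lapse) * plogis((x - threshold) / slope_scale).
#'
#' For `task = "2pd"`: `reps` repetitions of each pin spacing (plus a
#' single-pin control with false-alarm rate `fa_rate`);
#' P("two") = lapse/2 + (1 - lapse) * plogis((spacing - threshold) /
#' slope_scale).
#'
#' @param threshold observer threshold (intensity units or mm).
#' @param slope_scale logistic scale parameter.
#' @param lapse lapse rate (default 0).
#' @param task `"staircase"` or `"2pd"`.
#' @param ladder intensity ladder (staircase task).
#' @param start_intensities staircase starting intensities.
#' @param spacings pin spacings in mm (2PD task).
#' @param reps repetitions per spacing (2PD task).
#' @param fa_rate single-pin false-alarm rate (2PD task).
#' @param max_trials staircase trial cap (default 100).
#' @param seed integer seed.
#' @return a trial-log data frame; for the staircase: `trial`, `staircase`,
#'   `intensity`, `correct`; for 2PD: `trial`, `spacing`, `two` (logical;
#'   `spacing = 0` rows are the single-pin control). Ground truth in
#'   attribute `truth`.
#' @export
gen_behavior_observer <- function(threshold, slope_scale = 0.1, lapse = 0,
                                  task = c("staircase", "2pd"),
                                  ladder = filament_ladder(),
                                  start_intensities = NULL,
                                  spacings = seq(0.7, 2.8, by = 0.3),
                                  reps = 10L, fa_rate = 0.1,
                                  max_trials = 100L, seed = 1L) {
  task <- match.arg(task)
  set.seed(seed)
  if (task == "staircase") {
    if (is.null(start_intensities)) {
      start_intensities <- c(ladder[which.min(abs(ladder -
                                                    log10(0.02 * 1e4)))],
                             ladder[which.min(abs(ladder -
                                                    log10(0.4 * 1e4)))])
    }
    p_correct <- function(x) {
      0.5 + (0.5 - lapse) * stats::plogis((x - threshold) / slope_scale)
    }
    lev <- vapply(start_intensities,
                  function(s) which.min(abs(ladder - s)), integer(1))
    run_down <- c(0L, 0L)   # consecutive correct counts per staircase
    step <- stats::median(diff(ladder))
    log <- vector("list", max_trials)
    for (t in seq_len(max_trials)) {
      sc <- ((t - 1L) %% 2L) + 1L
      x <- ladder[lev[sc]]
      correct <- stats::runif(1) < p_correct(x)
      log[[t]] <- data.frame(trial = t, staircase = sc, intensity = x,
                             correct = correct)
      if (correct) {
        run_down[sc] <- run_down[sc] + 1L
        if (run_down[sc] == 3L) {
          lev[sc] <- max(1L, lev[sc] - 1L)
          run_down[sc] <- 0L
        }
      } else {
        lev[sc] <- min(length(ladder), lev[sc] + 1L)
        run_down[sc] <- 0L
      }
      if (t >= 30L) {
        ints <- vapply(log[(t - 29L):t], `[[`, numeric(1), "intensity")
        if (stats::sd(ints) <= step) break
      }
    }
    out <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
    attr(out, "truth") <- list(threshold = threshold,
                               slope_scale = slope_scale, lapse = lapse,
                               p794 = threshold + slope_scale *
                                 stats::qlogis((0.794 - 0.5) / (0.5 - lapse)),
                               seed = seed)
    out
  } else {
    p_two <- function(s) {
      lapse / 2 + (1 - lapse) * stats::plogis((s - threshold) / slope_scale)
    }
    sp <- rep(spacings, each = reps)
    two <- stats::runif(length(sp)) < p_two(sp)
    ctrl <- data.frame(trial = NA_integer_, spacing = 0,
                       two = stats::runif(reps) < fa_rate)
    out <- rbind(data.frame(trial = NA_integer_, spacing = sp, two = two),
                 ctrl)
    out$trial <- seq_len(nrow(out))
    attr(out, "truth") <- list(threshold = threshold,
                               slope_scale = slope_scale, lapse = lapse,
                               seed = seed)
    out
  }
}

#' Generate GCaMP-like calcium traces and a whisker-pad speed trace
#'
#' Per neuron: Poisson background events plus stimulus-locked events whose
#' amplitude in the double condition is scaled by a per-neuron factor drawn
#' from an additive / reduced / unchanged mixture; events are convolved with
#' an exponential indicator kernel (50-ms rise, 400-ms decay), set on a
#' constant baseline with Gaussian noise (10% of baseline), at 30 Hz. Onsets
#' use randomized 6-20 s inter-stimulus intervals. A synchronized synthetic
#' whisker-pad speed trace with movement bouts is returned.
#'
#' @param n_neurons number of neurons.
#' @param n_stim stimuli per condition (default 30).
#' @param mixture named proportions of `additive` / `reduced` / `unchanged`
#'   neurons.
#' @param double_scale response scaling in the double condition for additive
#'   (`> 1`) and reduced (`< 1`) neurons.
#' @param amp single-condition evoked event amplitude (dFF units of
#'   baseline).
#' @param baseline baseline fluorescence (a.u.).
#' @param noise_frac Gaussian noise s.d. as a fraction of baseline.
#' @param fs sampling rate in Hz (default 30).
#' @param seed integer seed.
#' @return list with `f` (neurons x timepoints fluorescence),
#'   `onsets_double`, `onsets_single` (s), `speed` (cm/s), `class`
#'   (ground-truth per-neuron class) and `fs`.
#' @export
gen_calcium_traces <- function(n_neurons = 60L, n_stim = 30L,
                               mixture = c(additive = 0.65, reduced = 0.13,
                                           unchanged = 0.22),
                               double_scale = c(additive = 1.5,
                                                reduced = 0.5),
                               amp = 0.8, baseline = 100, noise_frac = 0.1,
                               fs = 30, seed = 1L) {
  set.seed(seed)
  isi <- function(n) stats::runif(n, 6, 20)
  onsets_d <- cumsum(isi(n_stim)) + 5
  gap <- 10
  onsets_s <- max(onsets_d) + gap + cumsum(isi(n_stim))
  dur <- max(onsets_s) + 10
  nt <- as.integer(round(dur * fs))
  classes <- sample(names(mixture), n_neurons, replace = TRUE,
                    prob = mixture)
  kern_t <- seq(0, 2, by = 1 / fs)
  kern <- (1 - exp(-kern_t / 0.05)) * exp(-kern_t / 0.4)
  kern <- kern / max(kern)
  f <- matrix(0, n_neurons, nt)
  for (i in seq_len(n_neurons)) {
    ev <- numeric(nt)
    # background Poisson events at 0.05 Hz
    nbg <- stats::rpois(1L, 0.05 * dur)
    if (nbg > 0) {
      bg <- sample.int(nt, nbg)
      ev[bg] <- ev[bg] + amp * stats::runif(nbg, 0.5, 1)
    }
    scale_d <- switch(classes[i],
                      additive = double_scale[["additive"]],
                      reduced = double_scale[["reduced"]],
                      unchanged = 1)
    for (t0 in onsets_d) {
      j <- as.integer(round(t0 * fs)) + 1L
      if (j <= nt) ev[j] <- ev[j] + amp * scale_d * stats::runif(1, 0.8, 1.2)
    }
    for (t0 in onsets_s) {
      j <- as.integer(round(t0 * fs)) + 1L
      if (j <= nt) ev[j] <- ev[j] + amp * stats::runif(1, 0.8, 1.2)
    }
    tr <- stats::convolve(ev, rev(kern), type = "open")[seq_len(nt)]
    f[i, ] <- baseline * (1 + tr) +
      stats::rnorm(nt, sd = noise_frac * baseline)
  }
  # speed trace: rest with movement bouts of 1-3 s at 1-3 cm/s
  speed <- abs(stats::rnorm(nt, 0, 0.05))
  n_bouts <- max(1L, as.integer(dur / 30))
  for (b in seq_len(n_bouts)) {
    s0 <- sample.int(nt - 3L * fs, 1L)
    len <- as.integer(stats::runif(1, 1, 3) * fs)
    speed[s0:(s0 + len)] <- stats::runif(1, 1, 3)
  }
  list(f = f, onsets_double = onsets_d, onsets_single = onsets_s,
       speed = speed, class = factor(classes,
                                     levels = c("additive", "reduced",
                                                "unchanged")),
       fs = fs)
}
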