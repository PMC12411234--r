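# Psychophysics: staircases, d-prime, two-point discrimination, skin model,
# precision grip.

#' Semmes-Weinstein filament ladder in log10(0.1 mg) units
#'
#' The filament forces used for tactile detection (grams), transformed to a
#' logarithmic 1/10th-milligram scale: `log10(force_g * 1e4)`.
#'
#' @param forces_g filament forces in grams.
#' @return numeric intensity ladder, increasing.
#' @export
filament_ladder <- function(forces_g = c(0.008, 0.02, 0.04, 0.07, 0.16, 0.4,
                                         0.6, 1.0, 1.4, 2.0, 4.0, 6.0)) {
  sort(log10(forces_g * 1e4))
}

#' Detection threshold from a 3-down/1-up staircase trial log
#'
#' Reversal points are trials where response correctness changes
#' (correct to incorrect or incorrect to correct) within a staircase,
#' including the first change after the initial run. The threshold is the
#' mean stimulus intensity across reversal points within the period of stable
#' performance, the last `final_window` trials of the session. The stop rule
#' (standard deviation of intensity over the last 30 trials at most one
#' ladder step, or `max_trials` reached) is validated when a ladder is given.
#'
#' @param trials data frame with columns `intensity`, `correct` (logical) and
#'   optionally `staircase` (id of the interleaved staircase).
#' @param ladder optional intensity ladder used to validate the stop rule.
#' @param final_window number of final trials defining stable performance.
#' @param check_stop validate the stop rule (warning when violated).
#' @return threshold in intensity units, with attribute `n_reversals`.
#' @export
staircase_threshold <- function(trials, ladder = NULL, final_window = 10L,
                                check_stop = TRUE, max_trials = 100L) {
  stopifnot(is.data.frame(trials),
            all(c("intensity", "correct") %in% names(trials)))
  n <- nrow(trials)
  if (n < final_window) stop("staircase_threshold: session shorter than window")
  sc <- if ("staircase" %in% names(trials)) trials$staircase else rep(1L, n)
  reversal <- rep(FALSE, n)
  for (id in unique(sc)) {
    rows <- which(sc == id)
    corr <- trials$correct[rows]
    if (length(rows) >= 2L) {
      chg <- c(FALSE, corr[-1L] != corr[-length(corr)])
      reversal[rows] <- chg
    }
  }
  if (check_stop && !is.null(ladder) && n < max_trials) {
    last30 <- utils::tail(trials$intensity, 30L)
    step <- stats::median(diff(ladder))
    if (length(last30) >= 30L && stats::sd(last30) > step) {
      warning("staircase_threshold: stop rule not met ",
              "(sd of last 30 intensities exceeds one ladder step)")
    }
  }
  final_rows <- seq.int(n - final_window + 1L, n)
  rev_final <- final_rows[reversal[final_rows]]
  if (length(rev_final) == 0L) {
    fin <- trials$intensity[final_rows]
    if (stats::sd(fin) == 0) {
      # pinned at one ladder level (e.g. an always-correct observer at the
      # floor): the stable level is the threshold
      thr <- fin[1L]
      attr(thr, "n_reversals") <- 0L
      return(thr)
    }
    stop("staircase_threshold: no reversal within the final ", final_window,
         " trials; run a longer session")
  }
  thr <- mean(trials$intensity[rev_final])
  attr(thr, "n_reversals") <- length(rev_final)
  thr
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with standard-normal quantiles. A
#' false-alarm rate of 0 is replaced by 0.1 (task convention); rates of
#' exactly 1 (or a hit rate of 0) are clamped by the half-count rule
#' `1 - 1/(2 n)` (resp. `1/(2 n)`).
#'
#' @param hits hit rate in \[0, 1\].
#' @param false_alarms false-alarm rate in \[0, 1\].
#' @param n_signal,n_noise trial counts behind the two rates (> 0).
#' @return d-prime.
#' @export
dprime <- function(hits, false_alarms, n_signal, n_noise) {
  if (n_signal <= 0 || n_noise <= 0) stop("dprime: trial counts must be > 0")
  stopifnot(hits >= 0, hits <= 1, false_alarms >= 0, false_alarms <= 1)
  if (false_alarms == 0) false_alarms <- 0.1
  if (false_alarms == 1) false_alarms <- 1 - 1 / (2 * n_noise)
  if (hits == 1) hits <- 1 - 1 / (2 * n_signal)
  if (hits == 0) hits <- 1 / (2 * n_signal)
  stats::qnorm(hits) - stats::qnorm(false_alarms)
}

#' Two-point discrimination threshold from a trial log
#'
#' Binary logistic regression (logit link, maximum likelihood) of the
#' probability of answering "two pins" on pin spacing; the threshold is the
#' spacing at which the fitted sigmoid crosses 50%.
#'
#' @param spacing pin spacing per trial (mm).
#' @param response_two logical, answered "two pins".
#' @return threshold in mm; `NaN` with a warning when the fit does not cross
#'   50% within the tested range or is degenerate; attribute `separation` set
#'   when the fit separated perfectly.
#' @export
two_point_threshold <- function(spacing, response_two) {
  stopifnot(length(spacing) == length(response_two))
  if (length(unique(spacing)) < 2L) {
    stop("two_point_threshold: need >= 2 distinct spacings")
  }
  y <- as.integer(response_two)
  if (all(y == 1L) || all(y == 0L)) {
    warning("two_point_threshold: all responses identical; no finite threshold")
    return(NaN)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ spacing, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  b <- stats::coef(fit)
  if (!is.finite(b[2L]) || b[2L] <= 0) {
    warning("two_point_threshold: non-increasing psychometric fit")
    return(NaN)
  }
  thr <- unname(-b[1L] / b[2L])
  if (thr < min(spacing) || thr > max(spacing)) {
    warning("two_point_threshold: 50% point outside the tested spacing range")
    thr <- NaN
  }
  attr(thr, "separation") <- sep
  thr
}

#' Skin indentation from filament force
#'
#' Power-law force-indentation model `delta = (F / A)^(1 / b) * delta_hat`
#' with material constants `A = 0.2368 N`, `b = 2.0696` and reference
#' indentation `delta_hat = 1.00 mm`; the stimulation amplitude is `3 delta`
#' (clearly above threshold). A literal product reading
#' `(F / A) * (1 / b) * delta_hat` is available behind `reading = "literal"`
#' but is non-physical.
#'
#' @param force force in Newton, positive.
#' @param A,b,delta_hat model constants.
#' @param reading `"power"` (default) or `"literal"`.
#' @return list with `delta` (mm) and `amplitude` (mm, `3 * delta`).
#' @export
skin_indentation <- function(force, A = 0.2368, b = 2.0696, delta_hat = 1.0,
                             reading = c("power", "literal")) {
  reading <- match.arg(reading)
  if (any(force <= 0)) stop("skin_indentation: force must be positive")
  delta <- if (reading == "power") {
    (force / A)^(1 / b) * delta_hat
  } else {
    (force / A) * (1 / b) * delta_hat
  }
  list(delta = delta, amplitude = 3 * delta)
}

#' Time on target in the precision grip task
#'
#' Seconds during which the applied force stays within +-`band` (default
#' 2.5%) of the target force, at the given sampling rate.
#'
#' @param force_trace applied force (N), sampled at `fs` Hz.
#' @param target_trace target force (N), same length.
#' @param band tolerated relative deviation (default 0.025).
#' @param fs sampling rate in Hz (default 100).
#' @return time on target in seconds.
#' @export
grip_time_on_target <- function(force_trace, target_trace, band = 0.025,
                                fs = 100) {
  if (length(force_trace) != length(target_trace)) {
    stop("grip_time_on_target: trace length mismatch")
  }
  on <- abs(force_trace - target_trace) <= band * abs(target_trace)
  sum(on) / fs
}
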