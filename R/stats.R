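# Inference utilities: permutation Welch t-tests, Kendall-tau conversion,
# Theil-Sen regression.

# Welch t statistic and group-mean difference for pooled data z split by idx1
welch_t_stat <- function(z, idx1, n1, n2) {
  x <- z[idx1]
  y <- z[-idx1]
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se <- sqrt(vx / n1 + vy / n2)
  c(t = (mx - my) / se, diff = mx - my)
}

#' Monte Carlo permutation Welch t-test
#'
#' Welch's t on the observed samples; group labels are permuted `n_perm`
#' times (or enumerated exhaustively when `exhaustive = TRUE` and feasible)
#' and the two-sided equal-tail permutation p-value is
#' `2 * min(P(t* <= t), P(t* >= t))`, capped at 1 and floored at
#' `1 / n_perm`. The confidence interval for the group-mean difference is the
#' observed difference plus the percentile bounds of the centred permutation
#' distribution of difference estimates.
#'
#' @param x,y numeric samples (each n >= 2, finite).
#' @param n_perm number of Monte Carlo permutations (default 100000).
#' @param seed optional integer seed for the permutation RNG.
#' @param conf_level confidence level (default 0.95).
#' @param exhaustive enumerate all label assignments instead of sampling.
#' @return a `perm_test` object: list with `t`, `df`, `diff`, `p`, `ci`,
#'   `n_perm`, `seed`.
#' @export
perm_welch_t <- function(x, y, n_perm = 100000L, seed = NULL,
                         conf_level = 0.95, exhaustive = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("perm_welch_t: zero variance in both samples")
  }
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  n <- n1 + n2
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / n1 + vy / n2
  df <- se2^2 / ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
  obs <- welch_t_stat(z, seq_len(n1), n1, n2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  idx <- if (exhaustive) {
    combos <- utils::combn(n, n1)
    n_perm <- ncol(combos)
    combos
  } else {
    vapply(seq_len(n_perm), function(b) sample.int(n, n1), integer(n1))
  }
  # vectorized group statistics from pooled totals
  zi <- matrix(z[idx], nrow = n1)
  s_tot <- sum(z); ss_tot <- sum(z^2)
  s1 <- colSums(zi); ss1 <- colSums(zi^2)
  m1 <- s1 / n1; m2 <- (s_tot - s1) / n2
  v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
  v2 <- ((ss_tot - ss1) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  tp <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  dp <- m1 - m2
  ok <- is.finite(tp)
  tp <- tp[ok]; dp <- dp[ok]
  p_lo <- mean(tp <= obs[["t"]])
  p_hi <- mean(tp >= obs[["t"]])
  p <- min(1, 2 * min(p_lo, p_hi))
  p <- max(p, 1 / n_perm)
  a <- (1 - conf_level) / 2
  qd <- stats::quantile(dp - mean(dp), c(a, 1 - a), names = FALSE)
  structure(list(t = unname(obs[["t"]]), df = df, diff = unname(obs[["diff"]]),
                 p = p, ci = obs[["diff"]] + qd, n_perm = n_perm,
                 seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "perm Welch t-test: t = %.3f, df = %.1f, diff = %.4f, p_perm = %.4g\n",
    x$t, x$df, x$diff, x$p))
  cat(sprintf("  95%% CI_perm [%.4f, %.4f], %d permutations\n",
              x$ci[1L], x$ci[2L], x$n_perm))
  invisible(x)
}

#' Kendall's tau cutoff from a Pearson correlation cutoff
#'
#' Under bivariate normality, `tau = (2 / pi) * asin(r)`; used to translate
#' conventional Pearson effect-size cutoffs to the Kendall scale.
#'
#' @param r Pearson correlation coefficient(s) in \[-1, 1\].
#' @return Kendall's tau.
#' @export
tau_from_r <- function(r) {
  if (any(abs(r) > 1)) stop("tau_from_r: |r| must be <= 1")
  2 / pi * asin(r)
}

#' Theil-Sen robust linear regression
#'
#' Slope is the median of all pairwise slopes over point pairs with distinct
#' x; intercept is the median of `y - slope * x`.
#'
#' @param x,y numeric vectors of equal length (>= 2 distinct x).
#' @return list with `slope` and `intercept`.
#' @export
theil_sen_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L) stop("theil_sen_fit: all x values equal")
  n <- length(x)
  pairs <- utils::combn(n, 2L)
  dx <- x[pairs[2L, ]] - x[pairs[1L, ]]
  dy <- y[pairs[2L, ]] - y[pairs[1L, ]]
  keep <- dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}
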