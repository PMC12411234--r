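# One-dimensional population receptive field (pRF) fitting.

#' Stimulus design for 1-D pRF modeling
#'
#' @param aperture numeric matrix, stimulus-space positions x timepoints;
#'   entry (s, t) = 1 when position s is stimulated at time t.
#' @param space numeric vector of stimulus-space coordinates (covers
#'   \[-1, 1\]).
#' @param tr repetition time in seconds.
#' @return a `prf_design` object with the HRF-convolved aperture cached.
#' @export
prf_design <- function(aperture, space, tr) {
  aperture <- rbind(aperture)
  stopifnot(nrow(aperture) == length(space), tr > 0)
  conv <- t(apply(aperture, 1L, convolve_hrf, dt = tr))
  structure(list(aperture = aperture, space = space, tr = tr,
                 convolved = conv),
            class = "prf_design")
}

# predicted (HRF-convolved) time course of a Gaussian pRF (mu, sigma)
prf_predict <- function(design, mu, sigma) {
  w <- exp(-((design$space - mu)^2) / (2 * sigma^2))
  as.numeric(w %*% design$convolved)
}

#' Fit a 1-D Gaussian pRF by a two-stage coarse-to-fine procedure
#'
#' The observed time course is z-scored and linearly detrended. The coarse
#' stage grid-searches `(mu, sigma)` over `[-1.25, 1.25] x (0, 1.25]`
#' (default step 0.05), maximizing the Pearson correlation between the
#' observed series and the HRF-convolved prediction; the fine stage refines
#' the coarse optimum with derivative-free Nelder-Mead. Beta and baseline are
#' then estimated by least squares, `R^2` is the squared correlation, and
#' `nR^2 = R^2 / noise ceiling` when a ceiling is supplied.
#'
#' @param timecourse numeric vector (one vertex).
#' @param design a [prf_design()].
#' @param bounds search-space half-width (default 1.25).
#' @param grid_step coarse grid step in stimulus units.
#' @param ceiling optional noise ceiling from [noise_ceiling()].
#' @return a `prf_fit`: list with `mu`, `sigma`, `beta`, `baseline`,
#'   `r2`, `nr2`, `ceiling`, `degenerate`.
#' @export
fit_prf_1d <- function(timecourse, design, bounds = 1.25, grid_step = 0.05,
                       ceiling = NA_real_) {
  stopifnot(inherits(design, "prf_design"))
  if (any(!is.finite(timecourse))) {
    stop("fit_prf_1d: non-finite values in timecourse")
  }
  nt <- length(timecourse)
  stopifnot(nt == ncol(design$convolved))
  tt <- seq_len(nt)
  y <- as.numeric(stats::lm.fit(cbind(1, tt), timecourse)$residuals)
  sy <- stats::sd(y)
  if (sy <= 1e-10 * max(abs(timecourse), 1)) {
    return(structure(list(mu = NA_real_, sigma = NA_real_, beta = 0,
                          baseline = mean(timecourse), r2 = 0,
                          nr2 = NA_real_, ceiling = ceiling,
                          degenerate = TRUE),
                     class = "prf_fit"))
  }
  y <- y / sy  # z-scored, linearly detrended
  mus <- seq(-bounds, bounds, by = grid_step)
  sigmas <- seq(grid_step, bounds, by = grid_step)
  grid <- expand.grid(mu = mus, sigma = sigmas)
  preds <- mapply(function(m, s) prf_predict(design, m, s),
                  grid$mu, grid$sigma)
  psd <- apply(preds, 2L, stats::sd)
  ok <- psd > 0
  if (!any(ok)) {
    return(structure(list(mu = NA_real_, sigma = NA_real_, beta = 0,
                          baseline = mean(timecourse), r2 = 0,
                          nr2 = NA_real_, ceiling = ceiling,
                          degenerate = TRUE),
                     class = "prf_fit"))
  }
  cors <- rep(-Inf, nrow(grid))
  cors[ok] <- as.numeric(stats::cor(y, preds[, ok]))
  best <- which.max(cors)
  # fine stage: derivative-free local optimization of the correlation
  obj <- function(par) {
    mu <- par[1L]; sigma <- par[2L]
    if (abs(mu) > bounds || sigma <= 0 || sigma > bounds) return(1e6)
    p <- prf_predict(design, mu, sigma)
    if (stats::sd(p) == 0) return(1e6)
    -stats::cor(y, p)
  }
  opt <- stats::optim(c(grid$mu[best], grid$sigma[best]), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500L))
  mu <- opt$par[1L]
  sigma <- opt$par[2L]
  pred <- prf_predict(design, mu, sigma)
  fit <- stats::lm.fit(cbind(1, pred), y)
  r <- stats::cor(y, pred)
  r2 <- r^2
  structure(list(mu = mu, sigma = sigma,
                 beta = unname(fit$coefficients[2L]),
                 baseline = unname(fit$coefficients[1L]),
                 r2 = r2,
                 nr2 = if (is.na(ceiling) || ceiling <= 0) NA_real_
                       else r2 / ceiling,
                 ceiling = ceiling, degenerate = FALSE),
            class = "prf_fit")
}

#' Keep only pRF fits with positive beta
#'
#' Downstream summaries (mean pRF size per condition) use only vertices with
#' positive response amplitude.
#'
#' @param fits list of `prf_fit` objects.
#' @return the subset with finite parameters and `beta > 0`.
#' @export
filter_prf_fits <- function(fits) {
  Filter(function(f) {
    isFALSE(f$degenerate) && is.finite(f$beta) && f$beta > 0
  }, fits)
}
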