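# Equivolume depths, data-driven laminar compartments, layer thickness.

#' Equivolume cortical depth fractions
#'
#' Places `n_depths` intracortical depth fractions so that each lamina keeps a
#' constant volume fraction between an inner (GM/WM) and outer (CSF/GM)
#' boundary of given areas. For equispaced volume fractions rho the thickness
#' fraction is
#' `alpha(rho) = (sqrt(rho * A_out^2 + (1 - rho) * A_in^2) - A_in) / (A_out - A_in)`,
#' reducing to the equidistant grid in the flat-cortex limit `A_in = A_out`.
#'
#' @param inner_boundary_area,outer_boundary_area boundary surface areas
#'   (mm^2), both positive.
#' @param n_depths number of depths (>= 2); the study uses 21.
#' @return increasing vector of `n_depths` thickness fractions in \[0, 1\],
#'   index 1 = superficial (CSF/GM), last = deep (GM/WM).
#' @export
equivolume_depths <- function(inner_boundary_area, outer_boundary_area,
                              n_depths = 21L) {
  a_in <- inner_boundary_area
  a_out <- outer_boundary_area
  stopifnot(n_depths >= 2L)
  if (a_in <= 0 || a_out <= 0) {
    stop("equivolume_depths: boundary areas must be positive")
  }
  rho <- seq(0, 1, length.out = n_depths)
  if (isTRUE(all.equal(a_in, a_out))) return(rho)
  # rho is the volume fraction measured from the outer boundary; alpha is the
  # corresponding thickness fraction, with alpha increasing CSF -> WM
  (sqrt(rho * a_out^2 + (1 - rho) * a_in^2) - a_in) / (a_out - a_in)
}

#' Data-driven three-compartment segmentation of a qT1 depth profile
#'
#' Removes the two deepest of the 21 depths, differentiates the raw profile by
#' central differences ([num_gradient()]), and places the two compartment
#' boundaries at the first two interior local extrema of the first derivative
#' at which the derivative magnitude is locally maximal (the transition points
#' between plateaus); ties broken toward the superficial side. Boundary
#' locations are refined to continuous depth fractions by parabolic
#' interpolation around the discrete extremum. The result partitions the
#' retained depth range into an outer, a middle and an inner compartment.
#'
#' @param profile numeric vector of 21 positive qT1 values, index 1 =
#'   superficial (CSF/GM), index 21 = deep (GM/WM).
#' @param depth_fractions optional depth grid of the profile (length 21,
#'   increasing in \[0, 1\]); default equidistant.
#' @param n_drop_deep number of deepest depths removed before analysis.
#' @return a `layer_compartments` object: list with integer boundary indices
#'   `b1`, `b2` on the retained grid, continuous boundary fractions
#'   `f1`, `f2` (of the retained depth range), and `spans`
#'   (outer/middle/inner fractions summing to 1).
#' @export
compartmentalize_profile <- function(profile, depth_fractions = NULL,
                                     n_drop_deep = 2L) {
  d_total <- length(profile)
  stopifnot(d_total >= 7L)
  if (any(!is.finite(profile)) || any(profile <= 0)) {
    stop("compartmentalize_profile: qT1 profile must be finite and positive")
  }
  if (is.null(depth_fractions)) {
    depth_fractions <- seq(0, 1, length.out = d_total)
  }
  stopifnot(length(depth_fractions) == d_total)
  keep <- seq_len(d_total - n_drop_deep)
  y <- profile[keep]
  x <- depth_fractions[keep]
  d1 <- num_gradient(y, x)
  n <- length(d1)
  # interior local extrema of d1 where |d1| is also locally maximal:
  # the plateau-to-plateau transition points. eps guards against floating-
  # point wobble on exactly linear profiles.
  eps <- 1e-9 * max(abs(d1), 1e-300)
  is_ext <- logical(n)
  for (i in 2:(n - 1L)) {
    loc_max <- d1[i] >= d1[i - 1L] - eps && d1[i] > d1[i + 1L] + eps
    loc_min <- d1[i] <= d1[i - 1L] + eps && d1[i] < d1[i + 1L] - eps
    mag_max <- abs(d1[i]) >= abs(d1[i - 1L]) - eps &&
      abs(d1[i]) >= abs(d1[i + 1L]) - eps
    is_ext[i] <- (loc_max || loc_min) && mag_max
  }
  ext <- which(is_ext)
  if (length(ext) < 2L) {
    stop("no laminar structure: fewer than two transition extrema in the ",
         "first derivative of the qT1 profile")
  }
  b1 <- ext[1L]
  b2 <- ext[2L]
  f1 <- refine_extremum(x, d1, b1)
  f2 <- refine_extremum(x, d1, b2)
  span_range <- x[n] - x[1L]
  spans <- c(outer = (f1 - x[1L]) / span_range,
             middle = (f2 - f1) / span_range,
             inner = (x[n] - f2) / span_range)
  structure(list(b1 = b1, b2 = b2, f1 = f1, f2 = f2, spans = spans,
                 depth_fractions = x, n_drop_deep = n_drop_deep),
            class = "layer_compartments")
}

# parabolic (three-point) refinement of an extremum of |d1| around index i
refine_extremum <- function(x, d1, i) {
  n <- length(d1)
  if (i <= 1L || i >= n) return(x[i])
  v <- abs(d1[(i - 1L):(i + 1L)])
  denom <- v[1L] - 2 * v[2L] + v[3L]
  if (abs(denom) < .Machine$double.eps) return(x[i])
  delta <- 0.5 * (v[1L] - v[3L]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- if (delta >= 0) x[min(i + 1L, n)] - x[i] else x[i] - x[max(i - 1L, 1L)]
  x[i] + delta * h
}

#' @export
print.layer_compartments <- function(x, ...) {
  cat(sprintf(
    "layer_compartments: b1 = %d (f = %.3f), b2 = %d (f = %.3f)\n",
    x$b1, x$f1, x$b2, x$f2))
  cat(sprintf("  spans outer/middle/inner: %.3f / %.3f / %.3f\n",
              x$spans[1L], x$spans[2L], x$spans[3L]))
  invisible(x)
}

#' Layer-specific cortical thickness
#'
#' Converts compartment depth-fraction spans into millimetre thicknesses.
#' When boundary areas are supplied, spans are first mapped through the
#' equivolume model so that the millimetre split honours the volume
#' interpretation of the depth grid; by default spans are treated as thickness
#' fractions directly (whether the original analysis applied the correction is
#' not documented, so both modes are exposed).
#'
#' @param total_thickness total cortical thickness (mm), positive.
#' @param compartments a [compartmentalize_profile()] result.
#' @param inner_boundary_area,outer_boundary_area optional boundary areas
#'   enabling equivolume correction of the spans.
#' @return a `thickness_record`: list with `total`, `outer`, `middle`,
#'   `inner` (mm); compartment values sum to `total`.
#' @export
compartment_thickness <- function(total_thickness, compartments,
                                  inner_boundary_area = NULL,
                                  outer_boundary_area = NULL) {
  stopifnot(inherits(compartments, "layer_compartments"),
            total_thickness > 0)
  spans <- compartments$spans
  if (!is.null(inner_boundary_area) && !is.null(outer_boundary_area)) {
    # treat stored fractions as volume fractions; convert to thickness
    a_in <- inner_boundary_area; a_out <- outer_boundary_area
    alpha <- function(rho) {
      if (isTRUE(all.equal(a_in, a_out))) return(rho)
      (sqrt(rho * a_out^2 + (1 - rho) * a_in^2) - a_in) / (a_out - a_in)
    }
    cuts <- alpha(cumsum(c(0, spans)))
    spans <- diff(cuts) / (cuts[4L] - cuts[1L])
    names(spans) <- c("outer", "middle", "inner")
  }
  thick <- total_thickness * spans
  structure(list(total = total_thickness,
                 outer = unname(thick[1L]),
                 middle = unname(thick[2L]),
                 inner = unname(thick[3L])),
            class = "thickness_record")
}

#' @export
print.thickness_record <- function(x, ...) {
  cat(sprintf(
    "thickness_record: total %.3f mm (outer %.3f, middle %.3f, inner %.3f)\n",
    x$total, x$outer, x$middle, x$inner))
  invisible(x)
}
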