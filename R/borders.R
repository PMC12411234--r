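# Automated low-myelin border detection along parallel geodesic paths.

#' Detrend a path signal and detect prominent qT1 peaks
#'
#' The raw qT1 signal along a geodesic path is linearly detrended
#' (least-squares line removed) to control for the inferior-to-superior
#' cortical myelin gradient. Interior local maxima of the detrended signal are
#' then kept when their topographic prominence exceeds
#' `mean(|detrended|) + 2 * sd(|detrended|)` (default reading) or
#' `2 * sd(|detrended|)` when `threshold_rule = "2sd"`. The full width at half
#' maximum of each peak is measured at half-prominence below the peak on the
#' detrended signal, with linear interpolation of the crossing points.
#'
#' @param positions arc-length positions (mm), strictly increasing, uniform.
#' @param signal raw qT1 values (ms) at `positions` (>= 10 samples).
#' @param threshold_rule `"mean_plus_2sd"` (default) or `"2sd"`.
#' @return list with `positions`, `raw`, `detrended`, `threshold`, and
#'   `peaks`: data frame with `position` (mm), `height` (detrended ms),
#'   `prominence` (ms), `fwhm` (mm), `index`.
#' @export
detrend_and_detect_peaks <- function(positions, signal,
                                     threshold_rule = c("mean_plus_2sd",
                                                        "2sd")) {
  threshold_rule <- match.arg(threshold_rule)
  n <- length(signal)
  stopifnot(length(positions) == n, n >= 10L, all(diff(positions) > 0))
  fit <- stats::lm.fit(cbind(1, positions), signal)
  det <- as.numeric(fit$residuals)
  absd <- abs(det)
  thr <- if (threshold_rule == "mean_plus_2sd") {
    mean(absd) + 2 * stats::sd(absd)
  } else {
    2 * stats::sd(absd)
  }
  if (!is.finite(thr)) thr <- Inf
  pk <- find_peaks_prominence(det)
  keep <- pk$prominence > thr
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) > 0L) {
    pk$position <- positions[pk$index]
    pk$fwhm <- vapply(seq_len(nrow(pk)), function(i) {
      peak_width_at_half_prominence(positions, det, pk$index[i],
                                    pk$prominence[i])
    }, numeric(1))
  } else {
    pk$position <- numeric(0)
    pk$fwhm <- numeric(0)
  }
  list(positions = positions, raw = signal, detrended = det,
       threshold = thr,
       peaks = pk[, c("index", "position", "height", "prominence", "fwhm")])
}

#' Interior local maxima with topographic prominence
#'
#' Plateaus are reduced to their leftmost sample. Prominence of a peak is its
#' height minus the higher of the two base levels, where each base level is
#' the minimum of the signal between the peak and the nearest higher sample
#' (or the signal end) on that side.
#'
#' @param x numeric signal.
#' @return data frame with `index`, `height`, `prominence`.
#' @export
find_peaks_prominence <- function(x) {
  n <- length(x)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)  # leftmost of plateau
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prom <- vapply(idx, function(p) {
    h <- x[p]
    # left base
    l <- p
    lmin <- h
    while (l > 1L) {
      l <- l - 1L
      if (x[l] > h) break
      lmin <- min(lmin, x[l])
    }
    # right base
    r <- p
    rmin <- h
    while (r < n) {
      r <- r + 1L
      if (x[r] > h) break
      rmin <- min(rmin, x[r])
    }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

# width (in position units) of peak at half-prominence below the peak height
peak_width_at_half_prominence <- function(positions, x, p, prominence) {
  level <- x[p] - prominence / 2
  n <- length(x)
  # left crossing
  l <- p
  while (l > 1L && x[l - 1L] > level) l <- l - 1L
  left <- if (l == 1L) positions[1L] else {
    stats::approx(x[(l - 1L):l], positions[(l - 1L):l], xout = level)$y
  }
  r <- p
  while (r < n && x[r + 1L] > level) r <- r + 1L
  right <- if (r == n) positions[n] else {
    stats::approx(x[r:(r + 1L)], positions[r:(r + 1L)], xout = level)$y
  }
  right - left
}

#' Group peaks across parallel paths into low-myelin borders
#'
#' Greedy nearest-neighbour grouping: peaks are processed in order of
#' decreasing prominence; each seed peak recruits, on every other path, the
#' nearest unused peak on first and second neighbour paths whose distance to
#' the group reference is below `near_mm`. The reference position is the
#' member on the middle path when present, else the median member position.
#' Groups with members on at least `min_paths` distinct paths become borders;
#' every peak belongs to at most one border.
#'
#' @param peaks_per_path list (one element per path, ordered along the
#'   anterior-posterior family axis) of peak data frames from
#'   [detrend_and_detect_peaks()].
#' @param near_mm grouping distance threshold in mm (default 5).
#' @param min_paths minimum number of distinct member paths; default
#'   `ceiling(0.6 * n_paths)`, i.e. 3 of 5.
#' @param path_offsets optional per-path lateral (anterior-posterior)
#'   coordinates in mm; when given, the default metric is the geodesic
#'   (flat-patch Euclidean) distance `sqrt(d_arc^2 + d_lateral^2)` between
#'   peaks, so the between-path separation counts toward the 5-mm rule.
#' @param metric optional function `(path_i, pos_i, path_j, pos_j) -> mm`
#'   overriding the default metric (absolute arc-position difference when
#'   `path_offsets` is `NULL`).
#' @return list of `border` objects: list with `position` (group reference,
#'   mm), `paths`, `prominence`, `fwhm` (member means) and `members`
#'   (data frame).
#' @export
group_peaks_to_borders <- function(peaks_per_path, near_mm = 5,
                                   min_paths = NULL, path_offsets = NULL,
                                   metric = NULL) {
  n_paths <- length(peaks_per_path)
  if (n_paths == 0L) return(list())
  if (is.null(min_paths)) min_paths <- ceiling(0.6 * n_paths)
  if (n_paths < min_paths) {
    stop(sprintf("group_peaks_to_borders: need >= %d paths, got %d",
                 min_paths, n_paths))
  }
  all_pk <- do.call(rbind, lapply(seq_len(n_paths), function(k) {
    pk <- peaks_per_path[[k]]
    if (is.null(pk) || nrow(pk) == 0L) return(NULL)
    data.frame(path = k, position = pk$position, prominence = pk$prominence,
               fwhm = pk$fwhm, height = pk$height)
  }))
  if (is.null(all_pk) || nrow(all_pk) == 0L) return(list())
  dist_fun <- if (!is.null(metric)) {
    metric
  } else if (!is.null(path_offsets)) {
    stopifnot(length(path_offsets) == n_paths)
    function(pi, xi, pj, xj) {
      sqrt((xi - xj)^2 + (path_offsets[pi] - path_offsets[pj])^2)
    }
  } else {
    function(pi, xi, pj, xj) abs(xi - xj)
  }
  used <- rep(FALSE, nrow(all_pk))
  borders <- list()
  ord <- order(-all_pk$prominence)
  mid_path <- ceiling(n_paths / 2)
  for (s in ord) {
    if (used[s]) next
    members <- s
    ref_pos <- all_pk$position[s]
    # recruit nearest unused peak on each other path within 1st/2nd neighbours
    for (k in setdiff(seq_len(n_paths), all_pk$path[s])) {
      if (abs(k - all_pk$path[s]) > 2L) next  # first and second neighbours
      cand <- which(!used & all_pk$path == k)
      if (length(cand) == 0L) next
      d <- vapply(cand, function(j) {
        dist_fun(all_pk$path[s], ref_pos, k, all_pk$position[j])
      }, numeric(1))
      j <- cand[which.min(d)]
      if (min(d) < near_mm) members <- c(members, j)
    }
    mpaths <- all_pk$path[members]
    if (length(unique(mpaths)) >= min_paths) {
      used[members] <- TRUE
      mm <- all_pk[members, , drop = FALSE]
      ref <- if (mid_path %in% mm$path) {
        mm$position[match(mid_path, mm$path)]
      } else {
        stats::median(mm$position)
      }
      borders[[length(borders) + 1L]] <- structure(
        list(position = ref,
             paths = sort(unique(mpaths)),
             prominence = mean(mm$prominence),
             fwhm = mean(mm$fwhm),
             members = mm),
        class = "border")
    }
  }
  # report in anatomical order
  if (length(borders) > 1L) {
    borders <- borders[order(vapply(borders, `[[`, numeric(1), "position"))]
  }
  borders
}

#' End-to-end low-myelin border detection on a mesh
#'
#' Samples `n_paths` equally spaced geodesic paths between the seed pair,
#' detrends the middle-compartment qT1 signal along each, detects prominent
#' peaks, and groups them across paths with the geodesic 5-mm nearest
#' neighbour rule.
#'
#' @inheritParams sample_parallel_paths
#' @param overlay name of the middle-compartment qT1 overlay.
#' @inheritParams group_peaks_to_borders
#' @inheritParams detrend_and_detect_peaks
#' @return list with `borders`, `paths` and `peaks_per_path`.
#' @export
detect_low_myelin_borders <- function(mesh, inferior_seed, superior_seed,
                                      n_paths = 5L, overlay = "qt1_mid",
                                      roi_mask = NULL, near_mm = 5,
                                      threshold_rule = "mean_plus_2sd") {
  paths <- sample_parallel_paths(mesh, inferior_seed, superior_seed,
                                 n_paths = n_paths, roi_mask = roi_mask,
                                 overlay = overlay)
  pks <- lapply(paths, function(p) {
    detrend_and_detect_peaks(p$grid, p$signal,
                             threshold_rule = threshold_rule)$peaks
  })
  offs <- vapply(paths, `[[`, numeric(1), "offset_x")
  borders <- group_peaks_to_borders(pks, near_mm = near_mm,
                                    path_offsets = offs)
  list(borders = borders, paths = paths, peaks_per_path = pks)
}

#' Classify a border and complete its feature vector
#'
#' A border is a `hand_face` border when its reference position lies between
#' the face label band and the most inferior finger band along the path axis;
#' otherwise it is a `within_hand` border. The feature vector is the mean over
#' member peaks of each supplied overlay sampled at the member position, plus
#' the member-mean prominence and FWHM.
#'
#' @param border a `border` from [group_peaks_to_borders()].
#' @param label_bands named list mapping label names (must include `"face"`;
#'   finger labels such as `"thumb"`, ... ) to position intervals
#'   `c(lo, hi)` in mm along the path axis.
#' @param overlays named list of functions `position -> value` (or constant
#'   scalars) for qT1, ECM, signed QSM, nQSM, pQSM, aQSM at the sampled
#'   (middle-compartment) depth.
#' @return the border with `class` and `features` (named numeric) filled in.
#' @export
classify_and_featurize <- function(border, label_bands, overlays = list()) {
  stopifnot(inherits(border, "border"))
  if (is.null(label_bands[["face"]])) {
    stop("classify_and_featurize: missing overlay/label band 'face'")
  }
  finger_bands <- label_bands[setdiff(names(label_bands), "face")]
  if (length(finger_bands) == 0L) {
    stop("classify_and_featurize: no finger label bands supplied")
  }
  face_hi <- max(label_bands[["face"]])
  finger_lo <- min(vapply(finger_bands, min, numeric(1)))
  lo <- min(face_hi, finger_lo)
  hi <- max(face_hi, finger_lo)
  border$class <- if (border$position >= lo && border$position <= hi) {
    "hand_face"
  } else {
    "within_hand"
  }
  feats <- c(prominence = border$prominence, fwhm = border$fwhm)
  for (nm in names(overlays)) {
    f <- overlays[[nm]]
    vals <- if (is.function(f)) {
      vapply(border$members$position, f, numeric(1))
    } else {
      rep(as.numeric(f), nrow(border$members))
    }
    feats[[nm]] <- mean(vals)
  }
  border$features <- feats
  border
}

#' Average within-hand feature vectors per subject
#'
#' The study keeps one feature vector per subject for the hand-face border
#' and one for all within-hand borders combined (their mean).
#'
#' @param borders list of classified borders (see [classify_and_featurize()]).
#' @return named list with elements `hand_face` and `within_hand`, each a
#'   mean feature vector or `NULL` when no border of that class exists.
#' @export
summarize_border_features <- function(borders) {
  cls <- vapply(borders, `[[`, character(1), "class")
  out <- list(hand_face = NULL, within_hand = NULL)
  for (cl in c("hand_face", "within_hand")) {
    sel <- borders[cls == cl]
    if (length(sel) == 0L) next
    fm <- do.call(rbind, lapply(sel, `[[`, "features"))
    out[[cl]] <- colMeans(fm)
  }
  out
}
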