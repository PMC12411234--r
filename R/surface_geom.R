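# Surface meshes, geodesic paths and path sampling.

#' Triangulated cortical surface patch
#'
#' @param vertices numeric matrix (n x 3) of coordinates in mm. Convention:
#'   column 1 (`x`) runs anterior to posterior (the path-family direction),
#'   column 2 (`y`) runs inferior to superior (the path direction), column 3
#'   (`z`) is the surface normal direction.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices.
#' @param overlays named list of per-vertex scalar vectors (qT1 ms, QSM ppm,
#'   ECM, integer label maps, ...), each of length `nrow(vertices)`.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, overlays = list()) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, nrow(triangles) >= 1L)
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("surface_mesh: triangle indices out of range")
  }
  for (nm in names(overlays)) {
    if (length(overlays[[nm]]) != n) {
      stop(sprintf("surface_mesh: overlay '%s' length %d != %d vertices",
                   nm, length(overlays[[nm]]), n))
    }
  }
  edges <- mesh_edges(triangles)
  elen <- sqrt(rowSums((vertices[edges[, 1L], , drop = FALSE] -
                          vertices[edges[, 2L], , drop = FALSE])^2))
  if (any(elen <= 0)) stop("surface_mesh: zero-length edge (duplicate vertices)")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::E(g)$weight <- elen
  if (igraph::components(g)$no != 1L) {
    stop("surface_mesh: mesh edge graph is not connected")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 overlays = overlays, graph = g),
            class = "surface_mesh")
}

# unique undirected edges of a triangle soup
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, overlays: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (length(x$overlays)) paste(names(x$overlays), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Attach or replace an overlay on a mesh
#' @param mesh a [surface_mesh()].
#' @param name overlay name.
#' @param values per-vertex values.
#' @return the mesh with the overlay set.
#' @export
set_overlay <- function(mesh, name, values) {
  stopifnot(inherits(mesh, "surface_mesh"),
            length(values) == nrow(mesh$vertices))
  mesh$overlays[[name]] <- values
  mesh
}

#' Shortest geodesic path on the mesh edge graph
#'
#' Dijkstra shortest path between two vertices, with edge weights equal to
#' Euclidean edge lengths. This is the edge-graph approximation to the
#' polyhedral geodesic, adequate at phantom vertex pitch.
#'
#' @param mesh a [surface_mesh()].
#' @param start,end 1-based vertex indices, distinct.
#' @param step arc-length resampling step in mm (default 0.25).
#' @return a `geodesic_path`: list with `vertex_ids`, `arc` (cumulative arc
#'   length from 0, mm), `length` (total mm), `positions` (path vertex
#'   coordinates), `grid` (uniform arc grid) and `step`.
#' @export
shortest_geodesic_path <- function(mesh, start, end, step = 0.25) {
  stopifnot(inherits(mesh, "surface_mesh"), step > 0)
  n <- nrow(mesh$vertices)
  if (start == end) stop("shortest_geodesic_path: start and end must differ")
  if (start < 1L || start > n || end < 1L || end > n) {
    stop("shortest_geodesic_path: seed vertex outside mesh")
  }
  sp <- igraph::shortest_paths(mesh$graph, from = start, to = end,
                               weights = igraph::E(mesh$graph)$weight,
                               output = "vpath")
  ids <- as.integer(sp$vpath[[1L]])
  if (length(ids) == 0L) stop("shortest_geodesic_path: no path between seeds")
  pos <- mesh$vertices[ids, , drop = FALSE]
  seg <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                         pos[-nrow(pos), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  structure(list(vertex_ids = ids, arc = arc, length = arc[length(arc)],
                 positions = pos, grid = seq(0, arc[length(arc)], by = step),
                 step = step),
            class = "geodesic_path")
}

#' Geodesic distance between two vertices
#' @inheritParams shortest_geodesic_path
#' @return distance in mm.
#' @export
geodesic_distance <- function(mesh, start, end) {
  as.numeric(igraph::distances(mesh$graph, v = start, to = end,
                               weights = igraph::E(mesh$graph)$weight))
}

#' Sample an overlay along a geodesic path
#'
#' Overlay values along the path, linearly interpolated onto the path's
#' uniform arc-length grid. At each path vertex the value is the mean over
#' all candidate vertices within one vertex-to-vertex distance
#' (`lateral_mm`, default the mesh vertex pitch) of that point, mirroring
#' how vertices scattered around the sampling axis contribute to the signal.
#'
#' @param mesh a [surface_mesh()].
#' @param path a `geodesic_path`.
#' @param overlay overlay name.
#' @param lateral_mm candidate-vertex radius in mm; `0` samples the path
#'   vertices only.
#' @return list with `arc` (uniform grid, mm) and `signal`.
#' @export
sample_overlay_along_path <- function(mesh, path, overlay,
                                      lateral_mm = NULL) {
  if (is.null(mesh$overlays[[overlay]])) {
    stop(sprintf("overlay '%s' not present on mesh", overlay))
  }
  ov <- mesh$overlays[[overlay]]
  if (is.null(lateral_mm)) lateral_mm <- median_vertex_pitch(mesh)
  if (lateral_mm <= 0) {
    v <- ov[path$vertex_ids]
  } else {
    xy <- mesh$vertices
    a <- xy[path$vertex_ids, , drop = FALSE]
    r2 <- (lateral_mm + 1e-9)^2
    d2 <- outer(a[, 1L], xy[, 1L], "-")^2 +
      outer(a[, 2L], xy[, 2L], "-")^2 +
      outer(a[, 3L], xy[, 3L], "-")^2
    mask <- d2 <= r2
    v <- as.numeric(mask %*% ov) / rowSums(mask)
  }
  s <- stats::approx(path$arc, v, xout = path$grid, rule = 2)$y
  list(arc = path$grid, signal = s)
}

#' Family of equally spaced parallel geodesic paths
#'
#' Realizes "equally distant" paths by shifting the seed pair along the
#' anterior-posterior (`x`) coordinate in equal increments across the ROI and
#' re-running the shortest path. Seed vertices for each offset are the nearest
#' ROI vertices (within one vertex pitch of the target axis) on the start and
#' end rows.
#'
#' @param mesh a [surface_mesh()].
#' @param inferior_seed,superior_seed vertex ids of the central seed pair.
#' @param n_paths number of paths (>= 1).
#' @param roi_mask integer vector of ROI vertex ids (default: all vertices).
#' @param overlay optional overlay name to sample along each path.
#' @param spread total anterior-posterior extent of the family in mm
#'   (default: the ROI's x-extent shrunk by one vertex pitch per side).
#' @param step resampling step in mm.
#' @return list of `geodesic_path` objects ordered along x; each carries the
#'   sampled `signal` if `overlay` was given, and `offset_x`.
#' @export
sample_parallel_paths <- function(mesh, inferior_seed, superior_seed,
                                  n_paths = 5L, roi_mask = NULL,
                                  overlay = NULL, spread = NULL, step = 0.25) {
  stopifnot(inherits(mesh, "surface_mesh"), n_paths >= 1L)
  n <- nrow(mesh$vertices)
  if (is.null(roi_mask)) roi_mask <- seq_len(n)
  if (!(inferior_seed %in% roi_mask) || !(superior_seed %in% roi_mask)) {
    stop("sample_parallel_paths: seed pair must lie inside roi_mask")
  }
  if (n_paths == 1L) {
    p <- shortest_geodesic_path(mesh, inferior_seed, superior_seed, step)
    p$offset_x <- 0
    if (!is.null(overlay)) {
      sm <- sample_overlay_along_path(mesh, p, overlay)
      p$signal <- sm$signal
    }
    return(list(p))
  }
  xy <- mesh$vertices
  pitch <- median_vertex_pitch(mesh)
  if (is.null(spread)) {
    # equal spacing snapped down to the vertex grid so every seed pair lands
    # on a mesh vertex and neighbour spacing is exactly equal
    rx <- range(xy[roi_mask, 1L])
    spacing <- floor((rx[2L] - rx[1L] - 2 * pitch) /
                       (n_paths - 1L) / pitch) * pitch
    spread <- spacing * (n_paths - 1L)
  }
  if (spread <= 0 || spread / (n_paths - 1L) < pitch / 2) {
    achievable <- max(1L, floor(spread / (pitch / 2)) + 1L)
    stop(sprintf(
      "sample_parallel_paths: ROI too narrow for %d paths (achievable: %d)",
      n_paths, achievable))
  }
  x0 <- mean(xy[c(inferior_seed, superior_seed), 1L])
  offsets <- seq(-spread / 2, spread / 2, length.out = n_paths)
  y_inf <- xy[inferior_seed, 2L]
  y_sup <- xy[superior_seed, 2L]
  paths <- vector("list", n_paths)
  for (k in seq_len(n_paths)) {
    xt <- x0 + offsets[k]
    s1 <- nearest_roi_vertex(mesh, roi_mask, xt, y_inf, pitch)
    s2 <- nearest_roi_vertex(mesh, roi_mask, xt, y_sup, pitch)
    p <- shortest_geodesic_path(mesh, s1, s2, step)
    p$offset_x <- offsets[k]
    if (!is.null(overlay)) {
      sm <- sample_overlay_along_path(mesh, p, overlay)
      p$signal <- sm$signal
    }
    paths[[k]] <- p
  }
  paths
}

# nearest ROI vertex to target (x, y); candidate set restricted to within one
# vertex pitch of the sampling axis x = xt when possible
nearest_roi_vertex <- function(mesh, roi_mask, xt, yt, pitch) {
  xy <- mesh$vertices[roi_mask, , drop = FALSE]
  near_axis <- abs(xy[, 1L] - xt) <= pitch + 1e-9
  cand <- if (any(near_axis)) roi_mask[near_axis] else roi_mask
  cxy <- mesh$vertices[cand, , drop = FALSE]
  d2 <- (cxy[, 1L] - xt)^2 + (cxy[, 2L] - yt)^2
  cand[which.min(d2)]
}

#' Median vertex-to-vertex distance (vertex pitch)
#' @param mesh a [surface_mesh()].
#' @return median mesh edge length in mm.
#' @export
median_vertex_pitch <- function(mesh) {
  stats::median(igraph::E(mesh$graph)$weight)
}

#' Regular rectangular strip mesh
#'
#' Axis-aligned triangulated grid in the z = 0 plane: the basic cortical
#' phantom patch. `nx` columns along x (anterior-posterior), `ny` rows along y
#' (inferior-superior).
#'
#' @param nx,ny grid dimensions (vertices per side).
#' @param pitch vertex spacing in mm.
#' @return a [surface_mesh()]; vertex index of grid node (i, j) is
#'   `(j - 1) * nx + i`.
#' @export
grid_strip_mesh <- function(nx, ny, pitch = 1) {
  stopifnot(nx >= 2L, ny >= 2L, pitch > 0)
  xs <- (seq_len(nx) - 1L) * pitch
  ys <- (seq_len(ny) - 1L) * pitch
  vertices <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  ii <- rep(seq_len(nx - 1L), times = ny - 1L)
  jj <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- (jj - 1L) * nx + ii          # (i, j)
  b <- a + 1L                       # (i + 1, j)
  c_ <- a + nx                      # (i, j + 1)
  d <- c_ + 1L                      # (i + 1, j + 1)
  surface_mesh(vertices, rbind(cbind(a, b, c_), cbind(b, d, c_)))
}
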