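# Independent oracles and small fixture builders shared across tests.

# Exhaustive shortest simple path by depth-first enumeration with
# branch-and-bound pruning (an independent check on the Dijkstra route).
oracle_shortest_path_length <- function(mesh, start, end) {
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  el <- igraph::as_edgelist(mesh$graph)
  w <- igraph::E(mesh$graph)$weight
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, w[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[k]))
  }
  best <- Inf
  visited <- rep(FALSE, n)
  dfs <- function(v, len) {
    if (len >= best) return(invisible())
    if (v == end) {
      best <<- len
      return(invisible())
    }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1L]
      if (!visited[u]) dfs(u, len + nb[k, 2L])
    }
    visited[v] <<- FALSE
  }
  dfs(start, 0)
  best
}

# Definition-based prominence of every interior local maximum (O(n^2) scan):
# for peak i, walk each side until a strictly higher sample or the signal
# end; the base on that side is the minimum over the walked range.
oracle_peaks <- function(x) {
  n <- length(x)
  out <- NULL
  for (i in 2:(n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    left <- i; while (left > 1L && x[left - 1L] <= x[i]) left <- left - 1L
    lbase <- min(x[left:i])
    right <- i; while (right < n && x[right + 1L] <= x[i]) right <- right + 1L
    rbase <- min(x[i:right])
    out <- rbind(out, c(index = i, prominence = x[i] - max(lbase, rbase)))
  }
  as.data.frame(out)
}

# layer_compartments object with prescribed spans (for direct thickness tests)
make_compartments <- function(spans) {
  spans <- spans / sum(spans)
  structure(list(b1 = 2L, b2 = 3L,
                 f1 = spans[1L], f2 = spans[1L] + spans[2L],
                 spans = stats::setNames(spans, c("outer", "middle", "inner")),
                 depth_fractions = seq(0, 1, length.out = 19L),
                 n_drop_deep = 2L),
            class = "layer_compartments")
}

# small fast phantom for unit tests (1 mm pitch keeps meshes tiny)
small_phantom <- function(cohort = "younger", septa = list(), seed = 1L,
                          ...) {
  gen_cortex_phantom(phantom_spec(cohort, nx = 21L, ny = 31L, pitch = 1,
                                  septa = septa, seed = seed, ...))
}

# default seeds of the small phantom strip mesh: (x = 10, y = 0) and
# (x = 10, y = 30)
small_seeds <- c(11L, 30L * 21L + 11L)

# seeds of the default (0.25 mm pitch, 81 x 121) phantom
full_seeds <- c(41L, 120L * 81L + 41L)

# 1-D pRF design: traveling boxcar over [-1, 1], n_cycles cycles
make_prf_design <- function(n_t = 160L, tr = 2, cycle_len = 16L,
                            n_space = 101L, width = 0.1) {
  space <- seq(-1, 1, length.out = n_space)
  ap <- matrix(0, n_space, n_t)
  for (t in seq_len(n_t)) {
    pos <- -1 + 2 * ((t - 1L) %% cycle_len) / (cycle_len - 1L)
    ap[abs(space - pos) < width, t] <- 1
  }
  prf_design(ap, space, tr)
}
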