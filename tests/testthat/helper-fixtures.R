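# Shared fixtures, built once per test run.

# Default 14-tooth upper arch in standard pose.
fix_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_arch(generator_config(seed = 1))
    cache
  }
})

# Small library of arches for offset-model fitting in module tests.
fix_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scans <- lapply(1:8, function(s) {
        generate_arch(generator_config(seed = s))
      })
      cache <<- fit_offset_model(collect_offsets(scans))
    }
    cache
  }
})

# Tiny fast scan for crop sampling statistics (12-vertex icosphere teeth).
fix_tiny_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_arch(generator_config(
        seed = 5, points_per_tooth = 12L, gingiva_points = 120L
      ))
    }
    cache
  }
})

# Plain cross product (kept local so tests stay independent of internals).
cross_prod <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Component ids of a scan's surface (internal helper shortcut).
surface_comp_ids <- function(scan, vertices = NULL) {
  dentalarch:::surface_components(scan, vertices)
}

# Hand-built annotated scan from per-tooth point blocks.
# teeth: named list label -> matrix of points; gingiva: optional matrix.
make_point_scan <- function(teeth, gingiva = NULL, arch = "upper") {
  pts <- do.call(rbind, c(unname(teeth), list(gingiva)))
  inst <- unlist(lapply(seq_along(teeth), function(i) {
    rep(i, nrow(teeth[[i]]))
  }))
  fdi <- unlist(lapply(seq_along(teeth), function(i) {
    rep(as.integer(names(teeth)[i]), nrow(teeth[[i]]))
  }))
  if (!is.null(gingiva)) {
    inst <- c(inst, rep(-1L, nrow(gingiva)))
    fdi <- c(fdi, rep(0L, nrow(gingiva)))
  }
  annotated_scan(pts, NULL, inst, fdi, arch)
}

# Tight point cluster around a centroid (cluster mean == centroid exactly).
cluster_at <- function(centroid, k = 6L, r = 0.2) {
  ang <- 2 * pi * seq_len(k) / k
  ring <- cbind(r * cos(ang), r * sin(ang), 0)
  sweep(ring - matrix(colMeans(ring), k, 3, byrow = TRUE), 2, centroid, "+")
}

# Unwrap a polar-angle sequence so consecutive differences lie in (-pi, pi].
unwrap_angles <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

# Exhaustive minimum-cost label sequence (oracle for the DP), T <= 4.
brute_force_sequence <- function(costs) {
  tn <- nrow(costs$unary)
  stopifnot(tn <= 4L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(16L)), tn)))
  total <- rowSums(matrix(
    costs$unary[cbind(rep(seq_len(tn), each = nrow(grid)), as.vector(grid))],
    nrow(grid), tn
  ))
  if (tn > 1L) {
    for (t in seq_len(tn - 1L)) {
      total <- total +
        costs$pairwise[cbind(t, grid[, t], grid[, t + 1L])]
    }
  }
  best <- which.min(total) # ties: expand.grid varies the first index fastest,
  states <- grid[best, ] # so this matches lowest-label-first tie-breaking
  list(labels = costs$labels[states], total_cost = total[best],
    states = as.integer(states))
}

# Random cost tables for DP testing.
random_cost_tables <- function(tn, seed) {
  with_seed_t(seed, {
    un <- matrix(stats::runif(tn * 16L, 0, 10), tn, 16L)
    pw <- array(stats::runif(max(tn - 1L, 1L) * 256L, 0, 10),
      dim = c(max(tn - 1L, 0L), 16L, 16L)
    )
    cost_tables(un, pw, arch_sequence("upper"))
  })
}

# Seeded evaluation helper for test determinism.
with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  )
  set.seed(seed)
  expr
}
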