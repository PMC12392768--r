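#' Annotated intraoral scan container
#'
#' Bundles a surface (points, optional triangle faces) with per-vertex
#' instance ids and FDI labels. Instance id -1 and FDI label 0 denote
#' gingiva/background. Every instance carries exactly one FDI label, but a
#' label may span several disconnected surface patches of the same instance
#' (a clinically common situation, e.g. a broken-down tooth scanned as two
#' islands).
#'
#' @param points N x 3 numeric matrix of vertex coordinates (mm).
#' @param faces Optional M x 3 integer matrix of 1-based triangle indices.
#' @param vertex_instance Integer vector (length N); -1 = gingiva.
#' @param vertex_fdi Integer vector (length N); 0 = gingiva.
#' @param arch `"upper"` or `"lower"`.
#' @return An object of class `annotated_scan`.
#' @export
annotated_scan <- function(points, faces = NULL, vertex_instance, vertex_fdi,
                           arch = c("upper", "lower")) {
  arch <- match.arg(arch)
  points <- as_points_matrix(points)
  n <- nrow(points)
  vertex_instance <- as.integer(vertex_instance)
  vertex_fdi <- as.integer(vertex_fdi)
  if (length(vertex_instance) != n || length(vertex_fdi) != n) {
    stop("vertex_instance and vertex_fdi must match the vertex count",
      call. = FALSE
    )
  }
  dimnames(points) <- NULL
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    dimnames(faces) <- NULL
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) stop("faces must be M x 3", call. = FALSE)
    if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > n)) {
      stop("face indices out of range", call. = FALSE)
    }
  }
  bg <- vertex_instance < 0L
  if (any(vertex_fdi[bg] != 0L)) {
    stop("gingiva vertices must carry FDI label 0", call. = FALSE)
  }
  if (any(vertex_fdi[!bg] == 0L)) {
    stop("tooth vertices must carry a nonzero FDI label", call. = FALSE)
  }
  for (id in unique(vertex_instance[!bg])) {
    labs <- unique(vertex_fdi[vertex_instance == id])
    if (length(labs) != 1L) {
      stop("instance ", id, " carries multiple FDI labels: ",
        paste(labs, collapse = ", "),
        call. = FALSE
      )
    }
  }
  present <- unique(vertex_fdi[!bg])
  if (length(present)) {
    validate_fdi(present)
    if (any(arch_of(present) != arch)) {
      stop("scan contains labels outside the ", arch, " arch", call. = FALSE)
    }
  }
  structure(
    list(
      points = points, faces = faces,
      vertex_instance = vertex_instance, vertex_fdi = vertex_fdi,
      arch = arch
    ),
    class = "annotated_scan"
  )
}

#' @export
print.annotated_scan <- function(x, ...) {
  cat(
    "<annotated_scan> ", x$arch, " arch: ", nrow(x$points), " vertices, ",
    if (is.null(x$faces)) 0L else nrow(x$faces), " faces, ",
    length(scan_labels(x)), " teeth\n",
    sep = ""
  )
  invisible(x)
}

#' FDI labels present in a scan, in canonical arch order
#'
#' @param scan An [annotated_scan()].
#' @return Integer vector of present labels ordered along the arch.
#' @export
scan_labels <- function(scan) {
  present <- unique(scan$vertex_fdi[scan$vertex_fdi != 0L])
  seq16 <- arch_sequence(scan$arch)
  seq16[seq16 %in% present]
}

#' Per-tooth centroids of an annotated scan
#'
#' @param scan An [annotated_scan()].
#' @return K x 3 matrix of tooth centroids (mm), rownames = FDI labels,
#'   ordered along the canonical arch sequence.
#' @export
scan_tooth_centroids <- function(scan) {
  labs <- scan_labels(scan)
  out <- t(vapply(labs, function(l) {
    colMeans(scan$points[scan$vertex_fdi == l, , drop = FALSE])
  }, numeric(3)))
  rownames(out) <- labs
  out
}

#' Apply a rigid transform to a scan
#'
#' @param scan An [annotated_scan()].
#' @param transform A [rigid_transform()].
#' @return The transformed scan (labels unchanged).
#' @export
transform_scan <- function(scan, transform) {
  scan$points <- apply_transform(scan$points, transform)
  scan
}

#' Synthetic arch generator configuration
#'
#' Defaults describe a realistic adult arch: ~50 mm wide, ~40 mm deep,
#' 14 teeth (third molars absent, the most common adult presentation),
#' sub-millimetre anatomical variation of tooth positions.
#'
#' @param arch `"upper"` or `"lower"`.
#' @param present_labels Subset of the arch's 16 labels; default drops the
#'   third molars (positions 8).
#' @param points_per_tooth Approximate vertices per tooth (default 120).
#' @param gingiva_points Vertices in the gingiva band (default 600).
#' @param arch_width_mm Intermolar width of the arch (default 50).
#' @param arch_depth_mm Anterior-posterior depth (default 40).
#' @param centroid_jitter_mm SD of the per-tooth position jitter
#'   (default 0.3).
#' @param mesh Produce triangle faces (`TRUE`, default) or a bare point
#'   cloud.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(arch = "upper",
                             present_labels = NULL,
                             points_per_tooth = 120L,
                             gingiva_points = 600L,
                             arch_width_mm = 50,
                             arch_depth_mm = 40,
                             centroid_jitter_mm = 0.3,
                             mesh = TRUE,
                             seed = 0L) {
  arch <- match.arg(arch, c("upper", "lower"))
  seq16 <- arch_sequence(arch)
  if (is.null(present_labels)) {
    present_labels <- seq16[seq16 %% 10L != 8L]
  }
  present_labels <- validate_fdi(present_labels)
  if (!length(present_labels)) {
    stop("present_labels must be nonempty", call. = FALSE)
  }
  if (any(arch_of(present_labels) != arch)) {
    stop("present_labels must all belong to the ", arch, " arch",
      call. = FALSE
    )
  }
  stopifnot(
    points_per_tooth >= 4L, gingiva_points >= 0L,
    arch_width_mm > 0, arch_depth_mm > 0, centroid_jitter_mm >= 0
  )
  structure(
    list(
      arch = arch, present_labels = as.integer(present_labels),
      points_per_tooth = as.integer(points_per_tooth),
      gingiva_points = as.integer(gingiva_points),
      arch_width_mm = arch_width_mm, arch_depth_mm = arch_depth_mm,
      centroid_jitter_mm = centroid_jitter_mm,
      mesh = isTRUE(mesh), seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Mesiodistal crown widths (mm) by position 1..8, before scaling to the
# arch's arc length. Chosen for anatomical plausibility; configurable via
# the arch dimensions.
tooth_widths_mm <- c(8, 7, 8, 7, 7, 10, 10, 9)

#' Generate a synthetic annotated dental arch
#'
#' Teeth are ellipsoid-like surface clusters placed along a parabolic arch
#' curve (posterior toward +y, anterior toward -y, occlusal toward +z),
#' sized by tooth class (molars > premolars > incisors/canines) and joined
#' by a connected gingiva band so the mesh forms a single surface
#' component. The emitted scan is in the standard pose: re-running
#' [standard_pose_from_landmarks()] on it returns the identity transform
#' (when the four landmark teeth are present).
#'
#' @param config A [generator_config()].
#' @return An [annotated_scan()]; deterministic for a fixed config.
#' @export
generate_arch <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_arch_impl(config))
}

generate_arch_impl <- function(config) {
  seq16 <- arch_sequence(config$arch)
  half_w <- config$arch_width_mm / 2
  depth <- config$arch_depth_mm

  # arch curve: x runs +half_w -> -half_w along the canonical sequence,
  # y = depth * (x / half_w)^2 - depth / 2  (posterior arms at +y)
  tt <- seq(1, -1, length.out = 601L)
  cx <- half_w * tt
  cy <- depth * tt^2 - depth / 2
  seglen <- sqrt(diff(cx)^2 + diff(cy)^2)
  cumlen <- c(0, cumsum(seglen))
  total <- cumlen[length(cumlen)]

  # slot centres by cumulative mesiodistal width over the full 16-sequence
  pos16 <- quadrant_position(seq16)$position
  w16 <- tooth_widths_mm[pos16]
  w16 <- w16 * total / sum(w16)
  cum <- c(0, cumsum(w16))
  slot_mid <- (cum[-1] + cum[-17]) / 2
  slot_x <- stats::approx(cumlen, cx, xout = slot_mid)$y
  slot_y <- stats::approx(cumlen, cy, xout = slot_mid)$y
  # local tangent angle, for orienting crowns mesiodistally
  slot_ang <- atan2(
    stats::approx(cumlen, cy, xout = pmin(slot_mid + 0.5, total))$y - slot_y,
    stats::approx(cumlen, cx, xout = pmin(slot_mid + 0.5, total))$y - slot_x
  )

  present_mask <- seq16 %in% config$present_labels
  tooth_pts <- list()
  tooth_faces <- list()
  tooth_inst <- list()
  tooth_fdi <- list()
  inst_id <- 0L
  n_acc <- 0L

  sphere <- if (config$mesh) {
    icosphere(subdiv_for(config$points_per_tooth))
  } else {
    NULL
  }

  for (k in seq_len(16L)) {
    if (!present_mask[k]) next
    inst_id <- inst_id + 1L
    semi <- c(0.40 * w16[k], min(0.45 * w16[k], 4.5), 4.0)
    centre <- c(slot_x[k], slot_y[k], 0) +
      stats::rnorm(3, sd = config$centroid_jitter_mm)
    ca <- cos(slot_ang[k]); sa <- sin(slot_ang[k])
    rot_z <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
    if (config$mesh) {
      pts <- sphere$vertices
      fcs <- sphere$faces
    } else {
      g <- matrix(stats::rnorm(3L * config$points_per_tooth), ncol = 3L)
      pts <- g / sqrt(rowSums(g^2))
      fcs <- NULL
    }
    pts <- sweep(pts, 2L, semi, "*") %*% t(rot_z)
    pts <- sweep(pts, 2L, centre, "+")
    tooth_pts[[inst_id]] <- pts
    if (!is.null(fcs)) tooth_faces[[inst_id]] <- fcs + n_acc
    tooth_inst[[inst_id]] <- rep(inst_id, nrow(pts))
    tooth_fdi[[inst_id]] <- rep(seq16[k], nrow(pts))
    n_acc <- n_acc + nrow(pts)
  }
  if (inst_id == 0L) stop("no teeth generated", call. = FALSE)

  points <- do.call(rbind, tooth_pts)
  faces <- if (config$mesh) do.call(rbind, tooth_faces) else NULL
  vinst <- unlist(tooth_inst)
  vfdi <- unlist(tooth_fdi)

  # gingiva: triangulated ribbon under the tooth row, one connected band
  if (config$gingiva_points > 0L) {
    n_b <- 4L
    n_t <- max(2L, config$gingiva_points %/% n_b)
    s <- seq(0, total, length.out = n_t)
    gx <- stats::approx(cumlen, cx, xout = s)$y
    gy <- stats::approx(cumlen, cy, xout = s)$y
    tx <- c(diff(gx), diff(gx)[n_t - 1L])
    ty <- c(diff(gy), diff(gy)[n_t - 1L])
    tn <- sqrt(tx^2 + ty^2)
    # in-plane normal to the curve
    nx <- -ty / tn
    ny <- tx / tn
    off <- seq(-3, 3, length.out = n_b)
    gpts <- do.call(rbind, lapply(seq_len(n_b), function(b) {
      cbind(gx + off[b] * nx, gy + off[b] * ny, rep(-5, n_t))
    }))
    gfaces <- NULL
    if (config$mesh) {
      idx <- function(i, b) (b - 1L) * n_t + i
      gfaces <- do.call(rbind, lapply(seq_len(n_b - 1L), function(b) {
        i <- seq_len(n_t - 1L)
        rbind(
          cbind(idx(i, b), idx(i + 1L, b), idx(i, b + 1L)),
          cbind(idx(i + 1L, b), idx(i + 1L, b + 1L), idx(i, b + 1L))
        )
      }))
      gfaces <- gfaces + n_acc
    }
    points <- rbind(points, gpts)
    vinst <- c(vinst, rep(-1L, nrow(gpts)))
    vfdi <- c(vfdi, rep(0L, nrow(gpts)))
    if (config$mesh) {
      # weld each tooth to the ribbon so the surface is one component
      weld <- do.call(rbind, lapply(seq_len(inst_id), function(id) {
        vv <- which(vinst == id)
        base_v <- vv[which.min(points[vv, 3])]
        gg <- seq.int(n_acc + 1L, nrow(points))
        d2 <- (points[gg, 1] - points[base_v, 1])^2 +
          (points[gg, 2] - points[base_v, 2])^2
        near <- gg[order(d2)[1:2]]
        cbind(base_v, near[1], near[2])
      }))
      faces <- rbind(faces, gfaces, weld)
    }
  }

  scan <- annotated_scan(points, faces, vinst, vfdi, config$arch)

  # emit in the standard pose so standardization is a fixed point
  landmark <- landmark_labels(config$arch)
  if (all(landmark %in% config$present_labels)) {
    scan <- transform_scan(scan, standard_pose_from_landmarks(scan))
  } else {
    scan <- transform_scan(
      scan,
      rigid_transform(diag(3), -colMeans(scan$points))
    )
  }
  scan
}

subdiv_for <- function(points_per_tooth) {
  sizes <- c(12L, 42L, 162L, 642L)
  max(0L, min(which(sizes >= points_per_tooth), 4L) - 1L)
}

# Unit icosphere: icosahedron subdivided `subdiv` times, vertices on the
# unit sphere, faces 1-based.
icosphere <- function(subdiv = 1L) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1, phi, 0, 1, phi, 0, -1, -phi, 0, 1, -phi, 0,
    0, -1, phi, 0, 1, phi, 0, -1, -phi, 0, 1, -phi,
    phi, 0, -1, phi, 0, 1, -phi, 0, -1, -phi, 0, 1
  ), ncol = 3L, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
    2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
    4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
    5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2
  ), ncol = 3L, byrow = TRUE)
  for (s in seq_len(subdiv)) {
    midcache <- new.env(hash = TRUE)
    verts <- v
    nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(midcache[[key]])) {
        return(midcache[[key]])
      }
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      midcache[[key]] <- nrow(verts)
      nrow(verts)
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(cc, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  list(vertices = v, faces = f)
}

landmark_labels <- function(arch) {
  if (arch == "upper") c(16L, 26L, 11L, 21L) else c(36L, 46L, 31L, 41L)
}

#' Mock-predictor noise configuration
#'
#' Parameters of the seeded noise model converting ground-truth annotations
#' into network-like outputs.
#'
#' @param centroid_sigma_mm SD of isotropic Gaussian centroid noise
#'   (default 0).
#' @param logit_temperature Softmax temperature of the emitted logits
#'   (default 1); smaller = more confident.
#' @param logit_margin Peak-over-rest logit gap at temperature 1
#'   (default 5), emulating a confident classifier head.
#' @param label_confusion_rate Probability that an instance's peak logit is
#'   moved to an arch-neighbouring label (default 0).
#' @param boundary_flip_rate Probability that a tooth-boundary vertex is
#'   reassigned to the adjacent instance or gingiva (default 0).
#' @param drop_rate Probability of deleting an instance (default 0).
#' @param spurious_rate Expected count (Poisson) of small spurious gingiva
#'   instances (default 0).
#' @param seed Integer seed.
#' @return A `noise_config` list.
#' @export
noise_config <- function(centroid_sigma_mm = 0,
                         logit_temperature = 1,
                         logit_margin = 5,
                         label_confusion_rate = 0,
                         boundary_flip_rate = 0,
                         drop_rate = 0,
                         spurious_rate = 0,
                         seed = 0L) {
  stopifnot(
    centroid_sigma_mm >= 0, logit_temperature > 0, logit_margin > 0,
    label_confusion_rate >= 0, label_confusion_rate <= 1,
    boundary_flip_rate >= 0, boundary_flip_rate <= 1,
    drop_rate >= 0, drop_rate <= 1, spurious_rate >= 0
  )
  structure(
    list(
      centroid_sigma_mm = centroid_sigma_mm,
      logit_temperature = logit_temperature,
      logit_margin = logit_margin,
      label_confusion_rate = label_confusion_rate,
      boundary_flip_rate = boundary_flip_rate,
      drop_rate = drop_rate,
      spurious_rate = spurious_rate,
      seed = as.integer(seed)
    ),
    class = "noise_config"
  )
}

#' Predicted-instances container
#'
#' Network-output-shaped predictions: per instance a vertex set, a 3D
#' centroid (mm) and a 32-class logit vector ordered as [fdi_labels()];
#' plus a per-vertex predicted instance id (0 = background).
#'
#' @param instances List of lists with fields `vertices`, `centroid`,
#'   `logits`.
#' @param n_vertices Vertex count of the underlying scan.
#' @return A `predicted_instances` object.
#' @export
predicted_instances <- function(instances, n_vertices) {
  vmap <- integer(n_vertices)
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    stopifnot(
      length(inst$centroid) == 3L,
      length(inst$logits) == 32L
    )
    v <- as.integer(inst$vertices)
    if (length(v) && (min(v) < 1L || max(v) > n_vertices)) {
      stop("instance vertex indices out of range 1..", n_vertices,
        call. = FALSE
      )
    }
    if (length(v) && any(vmap[v] != 0L)) {
      stop("predicted instance vertex sets must be disjoint", call. = FALSE)
    }
    vmap[v] <- i
    instances[[i]]$vertices <- v
    instances[[i]]$centroid <- as.numeric(inst$centroid)
    instances[[i]]$logits <- as.numeric(inst$logits)
  }
  structure(
    list(instances = instances, vertex_instance = vmap),
    class = "predicted_instances"
  )
}

#' @export
print.predicted_instances <- function(x, ...) {
  cat(
    "<predicted_instances> ", length(x$instances), " instances over ",
    length(x$vertex_instance), " vertices\n",
    sep = ""
  )
  invisible(x)
}

#' Mock network predictor: perturb ground truth into predictions
#'
#' Converts an annotated scan into the shape of a segmentation network's
#' output, injecting controlled noise: instance drops, boundary-vertex
#' flips, centroid jitter, peak-logit confusion with an arch neighbour, and
#' spurious gingiva instances.
#'
#' @param scan An [annotated_scan()].
#' @param noise A [noise_config()].
#' @return A [predicted_instances()]; deterministic for fixed scan + noise.
#' @export
perturb_predictions <- function(scan, noise = noise_config()) {
  stopifnot(inherits(scan, "annotated_scan"), inherits(noise, "noise_config"))
  with_seed(noise$seed, perturb_predictions_impl(scan, noise))
}

perturb_predictions_impl <- function(scan, noise) {
  labs <- scan_labels(scan)
  seq16 <- arch_sequence(scan$arch)
  order32 <- fdi_labels()
  n <- nrow(scan$points)

  keep <- stats::runif(length(labs)) >= noise$drop_rate
  member <- lapply(labs, function(l) which(scan$vertex_fdi == l))

  # boundary flips on the kept teeth
  vert_owner <- scan$vertex_instance
  if (noise$boundary_flip_rate > 0 && any(keep)) {
    adj <- scan_adjacency_edges(scan)
    lab_of <- scan$vertex_fdi
    diff_edge <- lab_of[adj[, 1]] != lab_of[adj[, 2]]
    boundary <- unique(c(adj[diff_edge, 1], adj[diff_edge, 2]))
    boundary <- boundary[scan$vertex_instance[boundary] > 0L]
    flip <- boundary[stats::runif(length(boundary)) < noise$boundary_flip_rate]
    if (length(flip)) {
      # reassign to the owner of a random differing neighbour
      nb_tab <- rbind(adj, adj[, 2:1])
      for (v in flip) {
        nbs <- nb_tab[nb_tab[, 1] == v, 2]
        nbs <- nbs[lab_of[nbs] != lab_of[v]]
        if (length(nbs)) {
          vert_owner[v] <- scan$vertex_instance[nbs[[sample.int(length(nbs), 1L)]]]
        }
      }
    }
  }

  instances <- list()
  for (i in seq_along(labs)) {
    if (!keep[i]) next
    true_lab <- labs[i]
    verts <- if (noise$boundary_flip_rate > 0) {
      which(vert_owner == scan$vertex_instance[member[[i]][1]])
    } else {
      member[[i]]
    }
    if (!length(verts)) next
    centroid <- colMeans(scan$points[member[[i]], , drop = FALSE]) +
      stats::rnorm(3, sd = noise$centroid_sigma_mm)
    peak_lab <- true_lab
    if (stats::runif(1) < noise$label_confusion_rate) {
      k <- match(true_lab, seq16)
      nb <- c(k - 1L, k + 1L)
      nb <- nb[nb >= 1L & nb <= 16L]
      peak_lab <- seq16[nb[[sample.int(length(nb), 1L)]]]
    }
    logits <- numeric(32L)
    logits[match(peak_lab, order32)] <- noise$logit_margin
    logits <- logits / noise$logit_temperature
    instances[[length(instances) + 1L]] <-
      list(vertices = verts, centroid = centroid, logits = logits)
  }

  n_spur <- stats::rpois(1L, noise$spurious_rate)
  gingiva <- which(scan$vertex_instance < 0L)
  if (n_spur > 0L && length(gingiva) > 10L) {
    for (s in seq_len(n_spur)) {
      if (length(gingiva) < 10L) break
      seedv <- gingiva[[sample.int(length(gingiva), 1L)]]
      d2 <- rowSums(sweep(
        scan$points[gingiva, , drop = FALSE], 2L,
        scan$points[seedv, ], "-"
      )^2)
      verts <- gingiva[order(d2)[seq_len(min(10L, length(gingiva)))]]
      gingiva <- setdiff(gingiva, verts) # keep spurious instances disjoint
      logits <- stats::rnorm(32L, sd = 0.5)
      instances[[length(instances) + 1L]] <- list(
        vertices = verts,
        centroid = colMeans(scan$points[verts, , drop = FALSE]),
        logits = logits
      )
    }
  }
  predicted_instances(instances, n)
}

# Undirected vertex adjacency as a 2-column edge matrix: mesh edges when
# faces exist, otherwise an epsilon-radius graph with
# eps = 2 x median nearest-neighbour distance.
scan_adjacency_edges <- function(scan) {
  if (!is.null(scan$faces) && nrow(scan$faces) > 0L) {
    f <- scan$faces
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    return(unique(e))
  }
  pts <- scan$points
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  eps <- 2 * stats::median(apply(d, 1L, min))
  idx <- which(d <= eps & upper.tri(d), arr.ind = TRUE)
  cbind(idx[, 1], idx[, 2])
}

# Connected components of a scan's surface; returns a per-vertex component
# id vector (restricted to `vertices` when given).
surface_components <- function(scan, vertices = NULL) {
  edges <- scan_adjacency_edges(scan)
  n <- nrow(scan$points)
  if (!is.null(vertices)) {
    keepmask <- logical(n)
    keepmask[vertices] <- TRUE
    edges <- edges[keepmask[edges[, 1]] & keepmask[edges[, 2]], , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  if (!is.null(vertices)) comp[vertices] else comp
}
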