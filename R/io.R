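#' Write a mesh or point cloud to PLY
#'
#' Writes vertices (float32 x/y/z, mm) and optional triangle faces in
#' ascii or binary-little-endian PLY.
#'
#' @param path Output file path.
#' @param points N x 3 matrix (mm).
#' @param faces Optional M x 3 matrix of 1-based triangle indices (written
#'   0-based, as PLY requires).
#' @param binary Write binary-little-endian (`TRUE`, default) or ascii.
#' @return `path`, invisibly.
#' @export
write_ply <- function(path, points, faces = NULL, binary = TRUE) {
  points <- as_points_matrix(points)
  n <- nrow(points)
  m <- if (is.null(faces)) 0L else nrow(faces)
  header <- c(
    "ply",
    paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    if (m > 0L) {
      c(
        paste("element face", m),
        "property list uchar int vertex_indices"
      )
    },
    "end_header"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    writeBin(
      as.numeric(t(points)), con,
      size = 4L, endian = "little"
    )
    if (m > 0L) {
      f0 <- t(faces) - 1L
      for (i in seq_len(m)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[, i]), con, size = 4L, endian = "little")
      }
    }
  } else {
    writeLines(
      apply(points, 1L, function(p) {
        paste(format(p, digits = 9, trim = TRUE, scientific = FALSE),
          collapse = " "
        )
      }),
      con
    )
    if (m > 0L) {
      writeLines(
        apply(faces - 1L, 1L, function(f) paste(c(3L, f), collapse = " ")),
        con
      )
    }
  }
  invisible(path)
}

#' Read a PLY mesh or point cloud
#'
#' Parses ascii or binary-little-endian PLY. Extra scalar vertex
#' properties (e.g. color, normals) are read and discarded; only x/y/z
#' and the face index list are returned.
#'
#' @param path PLY file path.
#' @return List with `points` (N x 3 double, mm) and `faces` (M x 3
#'   1-based integer, or NULL).
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, open = "rb")
  on.exit(close(con))

  fmt <- NULL
  n_vert <- 0L
  n_face <- 0L
  vert_props <- character()
  vert_types <- character()
  in_vertex <- FALSE
  line <- readLines(con, n = 1L)
  if (!identical(line, "ply")) {
    stop("not a PLY file (missing magic): ", path, call. = FALSE)
  }
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated PLY header", call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian")) {
        stop("unsupported PLY format: ", fmt, call. = FALSE)
      }
    } else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") n_vert <- as.integer(tok[3])
      if (tok[2] == "face") n_face <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") {
        stop("list property on vertex element is unsupported", call. = FALSE)
      }
      vert_types <- c(vert_types, tok[2])
      vert_props <- c(vert_props, tok[3])
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (!all(c("x", "y", "z") %in% vert_props)) {
    stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
  }

  type_size <- c(
    char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
    float = 4L, float32 = 4L, double = 8L, float64 = 8L
  )
  read_scalar <- function(type, n) {
    sz <- type_size[[type]]
    if (is.null(sz)) stop("unsupported PLY type: ", type, call. = FALSE)
    what <- if (type %in% c("float", "float32", "double", "float64")) {
      "numeric"
    } else {
      "integer"
    }
    out <- readBin(con, what, n = n, size = sz, endian = "little",
      signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    if (length(out) != n) {
      stop("truncated PLY payload at byte ", seek(con), call. = FALSE)
    }
    out
  }

  if (fmt == "ascii") {
    txt <- readLines(con)
    if (length(txt) < n_vert + n_face) {
      stop("truncated PLY payload: expected ", n_vert + n_face,
        " data rows, found ", length(txt),
        call. = FALSE
      )
    }
    vert_rows <- lapply(txt[seq_len(n_vert)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    vmat <- do.call(rbind, vert_rows)
    if (ncol(vmat) < length(vert_props)) {
      stop("PLY vertex row has too few values", call. = FALSE)
    }
    points <- vmat[, match(c("x", "y", "z"), vert_props), drop = FALSE]
    faces <- NULL
    if (n_face > 0L) {
      frows <- lapply(
        txt[seq.int(n_vert + 1L, n_vert + n_face)],
        function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]])
      )
      faces <- do.call(rbind, lapply(frows, function(r) {
        if (r[1] != 3L) stop("non-triangular PLY face", call. = FALSE)
        r[2:4] + 1L
      }))
    }
  } else {
    k <- length(vert_props)
    if (length(unique(vert_types)) == 1L) {
      flat <- read_scalar(vert_types[1], n_vert * k)
      vmat <- matrix(as.numeric(flat), ncol = k, byrow = TRUE)
    } else {
      vmat <- matrix(0, n_vert, k)
      for (i in seq_len(n_vert)) {
        for (j in seq_len(k)) {
          vmat[i, j] <- as.numeric(read_scalar(vert_types[j], 1L))
        }
      }
    }
    points <- vmat[, match(c("x", "y", "z"), vert_props), drop = FALSE]
    faces <- NULL
    if (n_face > 0L) {
      faces <- matrix(0L, n_face, 3L)
      for (i in seq_len(n_face)) {
        cnt <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
        if (!length(cnt)) {
          stop("truncated PLY payload at byte ", seek(con), call. = FALSE)
        }
        if (cnt != 3L) stop("non-triangular PLY face", call. = FALSE)
        idx <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
        if (length(idx) != 3L) {
          stop("truncated PLY payload at byte ", seek(con), call. = FALSE)
        }
        faces[i, ] <- idx + 1L
      }
    }
  }
  storage.mode(points) <- "double"
  list(points = points, faces = faces)
}

#' Write a Teeth3DS-style JSON annotation sidecar
#'
#' Per-vertex `labels` (FDI, 0 = gingiva) and `instances` (0 = gingiva in
#' the file dialect; internal instance -1 maps to 0) plus the arch tag.
#'
#' @param scan An [annotated_scan()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(scan, path) {
  stopifnot(inherits(scan, "annotated_scan"))
  inst <- scan$vertex_instance
  inst[inst < 0L] <- 0L
  jsonlite::write_json(
    list(
      labels = scan$vertex_fdi,
      instances = inst,
      arch = scan$arch
    ),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a Teeth3DS-style JSON annotation sidecar
#'
#' Validates array lengths against the companion mesh's vertex count and
#' the one-FDI-label-per-instance invariant. File instance 0 (or -1) is
#' background and maps to internal -1.
#'
#' @param path JSON file with parallel `labels` and `instances` arrays.
#' @param vertex_count Vertex count of the companion mesh.
#' @return List with `labels`, `instances` (internal convention) and
#'   `arch` (possibly NULL).
#' @export
read_annotation <- function(path, vertex_count) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(ann$labels) || is.null(ann$instances)) {
    stop("annotation must contain 'labels' and 'instances' arrays",
      call. = FALSE
    )
  }
  labels <- as.integer(ann$labels)
  instances <- as.integer(ann$instances)
  if (length(labels) != vertex_count || length(instances) != vertex_count) {
    stop(
      "annotation arrays (", length(labels), ", ", length(instances),
      ") do not match the vertex count (", vertex_count, ")",
      call. = FALSE
    )
  }
  instances[instances <= 0L] <- -1L
  for (id in unique(instances[instances > 0L])) {
    labs <- unique(labels[instances == id])
    labs <- labs[labs != 0L]
    if (length(labs) != 1L) {
      stop("instance ", id, " carries labels ",
        paste(labs, collapse = ", "), " (exactly one expected)",
        call. = FALSE
      )
    }
  }
  list(labels = labels, instances = instances, arch = ann$arch)
}

#' Read a scan (PLY + annotation sidecar) as an annotated_scan
#'
#' @param ply_path PLY mesh path.
#' @param ann_path JSON annotation path.
#' @param arch Arch override when the sidecar lacks an arch tag.
#' @return An [annotated_scan()].
#' @export
read_scan <- function(ply_path, ann_path, arch = NULL) {
  mesh <- read_ply(ply_path)
  ann <- read_annotation(ann_path, nrow(mesh$points))
  if (is.null(arch)) arch <- ann$arch
  if (is.null(arch)) {
    nz <- ann$labels[ann$labels != 0L]
    if (!length(nz)) stop("cannot infer arch: no labels", call. = FALSE)
    arch <- names(which.max(table(arch_of(nz))))
  }
  annotated_scan(mesh$points, mesh$faces, ann$instances, ann$labels, arch)
}

#' Write a scan as PLY + annotation sidecar
#'
#' @param scan An [annotated_scan()].
#' @param ply_path,ann_path Output paths.
#' @param binary Binary-little-endian PLY (default TRUE).
#' @return Invisibly, `c(ply_path, ann_path)`.
#' @export
write_scan <- function(scan, ply_path, ann_path, binary = TRUE) {
  write_ply(ply_path, scan$points, scan$faces, binary = binary)
  write_annotation(scan, ann_path)
  invisible(c(ply_path, ann_path))
}

#' Write predicted instances to JSON
#'
#' Dialect: `{"instances": [{"centroid": [x,y,z], "logits": [32 floats],
#' "vertices": [0-based indices]}, ...], "n_vertices": N}`; an optional
#' `labels` array carries assigned FDI labels.
#'
#' @param pred A [predicted_instances()].
#' @param path Output path.
#' @param labels Optional integer FDI label per instance.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path, labels = NULL) {
  stopifnot(inherits(pred, "predicted_instances"))
  insts <- lapply(pred$instances, function(x) {
    list(
      centroid = x$centroid,
      logits = x$logits,
      vertices = x$vertices - 1L
    )
  })
  out <- list(instances = insts, n_vertices = length(pred$vertex_instance))
  if (!is.null(labels)) out$labels <- as.integer(labels)
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read predicted instances from JSON
#'
#' @param path JSON file in the [write_predictions()] dialect.
#' @return List with `pred` (a [predicted_instances()]) and `labels`
#'   (integer vector or NULL).
#' @export
read_predictions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$instances)) {
    stop("prediction file lacks 'instances'", call. = FALSE)
  }
  insts <- obj$instances
  if (is.data.frame(insts)) {
    insts <- lapply(seq_len(nrow(insts)), function(i) {
      list(
        centroid = unlist(insts$centroid[i]),
        logits = unlist(insts$logits[i]),
        vertices = unlist(insts$vertices[i])
      )
    })
  }
  insts <- lapply(insts, function(x) {
    list(
      centroid = as.numeric(x$centroid),
      logits = as.numeric(x$logits),
      vertices = as.integer(x$vertices) + 1L
    )
  })
  n <- obj$n_vertices
  if (is.null(n)) {
    n <- if (length(insts)) max(unlist(lapply(insts, `[[`, "vertices"))) else 0L
  }
  list(
    pred = predicted_instances(insts, as.integer(n)),
    labels = if (!is.null(obj$labels)) as.integer(obj$labels) else NULL
  )
}

#' Serialize a fitted offset model to JSON
#'
#' Dialect: `{"arch_pairs": {"11-21": {"mu": [...], "sigma": [[...]],
#' "k": n}, ...}, "ridge": eps, "fallback_cost": c, "pooled": {...}}`.
#'
#' @param model A fitted `offset_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offset_model <- function(model, path) {
  stopifnot(inherits(model, "offset_model"))
  if (!isTRUE(model$fitted)) {
    stop("fit the model before writing it", call. = FALSE)
  }
  pairs <- lapply(model$pairs, function(p) {
    list(
      mu = p$mu,
      sigma = apply(p$sigma, 1L, function(r) r, simplify = FALSE),
      k = p$k
    )
  })
  pooled <- lapply(model$pooled, function(p) {
    list(
      mu = p$mu,
      sigma = apply(p$sigma, 1L, function(r) r, simplify = FALSE),
      within = apply(p$within, 1L, function(r) r, simplify = FALSE),
      k = p$k
    )
  })
  jsonlite::write_json(
    list(
      arch_pairs = pairs, ridge = model$ridge,
      fallback_cost = model$fallback_cost, pooled = pooled
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a fitted offset model from JSON
#'
#' @param path JSON file in the [write_offset_model()] dialect.
#' @return A fitted `offset_model` (without the raw offset lists).
#' @export
read_offset_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$arch_pairs)) {
    stop("offset-model file lacks 'arch_pairs'", call. = FALSE)
  }
  # sigma arrives as a 3x3 structure; normalize robustly
  pairs <- lapply(obj$arch_pairs, function(p) {
    sg <- p$sigma
    if (is.list(sg)) sg <- do.call(rbind, sg)
    list(
      mu = as.numeric(p$mu),
      sigma = matrix(as.numeric(as.matrix(sg)), 3L, 3L),
      k = as.integer(p$k)
    )
  })
  pooled <- NULL
  if (!is.null(obj$pooled)) {
    pooled <- lapply(obj$pooled, function(p) {
      sg <- p$sigma
      if (is.list(sg)) sg <- do.call(rbind, sg)
      wi <- p$within
      if (is.list(wi)) wi <- do.call(rbind, wi)
      list(
        mu = as.numeric(p$mu),
        sigma = matrix(as.numeric(as.matrix(sg)), 3L, 3L),
        within = matrix(as.numeric(as.matrix(wi)), 3L, 3L),
        k = as.integer(p$k)
      )
    })
  }
  structure(
    list(
      offsets = list(), fitted = TRUE,
      ridge = obj$ridge, fallback_cost = obj$fallback_cost,
      pairs = pairs, pooled = pooled
    ),
    class = "offset_model"
  )
}
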