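#' Partial-arch crop configuration
#'
#' The augmentation crops a contiguous run of 2-12 teeth out of a
#' (near-)full arch and recenters it, emulating a clinical partial-arch
#' scan. It is applied with 90% probability; the tooth count is drawn from
#' a skewed distribution with higher probabilities for fewer teeth
#' (default: truncated geometric on 2..12 with ratio 0.75).
#'
#' @param apply_probability Probability the crop is applied (default 0.9).
#' @param min_teeth,max_teeth Bounds of the tooth count (defaults 2 and
#'   12).
#' @param count_distribution Optional probability vector over
#'   `min_teeth:max_teeth`; default truncated geometric
#'   `P(n) \propto ratio^(n - min_teeth)`.
#' @param ratio Geometric ratio of the default distribution (default
#'   0.75).
#' @param box_margin_mm Padding of the oriented bounding box (default 2),
#'   so the gingival collar around the selected teeth survives.
#' @param seed Integer seed.
#' @return A `crop_config` list.
#' @export
crop_config <- function(apply_probability = 0.9,
                        min_teeth = 2L, max_teeth = 12L,
                        count_distribution = NULL,
                        ratio = 0.75,
                        box_margin_mm = 2,
                        seed = 0L) {
  stopifnot(
    apply_probability >= 0, apply_probability <= 1,
    min_teeth >= 1L, max_teeth >= min_teeth,
    box_margin_mm >= 0, ratio > 0
  )
  support <- seq.int(min_teeth, max_teeth)
  if (is.null(count_distribution)) {
    count_distribution <- ratio^(support - min_teeth)
    count_distribution <- count_distribution / sum(count_distribution)
  }
  if (length(count_distribution) != length(support) ||
    any(count_distribution < 0) ||
    abs(sum(count_distribution) - 1) > 1e-9) {
    stop("count_distribution must be a probability vector over ",
      min_teeth, "..", max_teeth,
      call. = FALSE
    )
  }
  names(count_distribution) <- support
  structure(
    list(
      apply_probability = apply_probability,
      min_teeth = as.integer(min_teeth),
      max_teeth = as.integer(max_teeth),
      count_distribution = count_distribution,
      box_margin_mm = box_margin_mm,
      seed = as.integer(seed)
    ),
    class = "crop_config"
  )
}

#' Select a contiguous run of teeth for cropping
#'
#' Draws a tooth count from the config's skewed distribution (clipped to
#' the number of teeth available) and a uniform start position, and
#' returns labels consecutive in the scan's present-tooth sequence (the
#' canonical arch order restricted to present labels).
#'
#' @param scan An [annotated_scan()] with at least `min_teeth` teeth.
#' @param config A [crop_config()].
#' @return Integer vector of selected FDI labels.
#' @export
select_segment <- function(scan, config) {
  stopifnot(inherits(scan, "annotated_scan"), inherits(config, "crop_config"))
  present <- scan_labels(scan)
  if (length(present) < config$min_teeth) {
    stop("scan has fewer than ", config$min_teeth, " teeth", call. = FALSE)
  }
  support <- seq.int(config$min_teeth, config$max_teeth)
  count <- support[sample.int(
    length(support), 1L,
    prob = config$count_distribution
  )]
  count <- min(count, length(present))
  start <- sample.int(length(present) - count + 1L, 1L)
  present[seq.int(start, start + count - 1L)]
}

#' Crop a scan to a selected tooth segment
#'
#' Removes all surface outside the oriented bounding box of the selected
#' teeth (principal-axes box of their vertices, padded by
#' `box_margin_mm`), drops faces touching removed vertices, keeps only the
#' largest connected component of what remains (ties: the component whose
#' centroid is nearest the selected teeth), and recenters the result so
#' its vertex centroid is the origin. The applied recentering translation
#' is recorded as the ground-truth translation target for alignment
#' training.
#'
#' @param scan An [annotated_scan()].
#' @param selected Integer vector of FDI labels present in the scan.
#' @param config A [crop_config()].
#' @return A `crop_result`: `scan` (cropped, recentered),
#'   `selected_labels`, `applied = TRUE`, `translation_target` (the vector
#'   added to every vertex).
#' @export
crop_to_segment <- function(scan, selected, config = crop_config()) {
  stopifnot(inherits(scan, "annotated_scan"))
  if (!length(selected)) stop("empty tooth selection", call. = FALSE)
  selected <- validate_fdi(selected)
  present <- scan_labels(scan)
  if (!all(selected %in% present)) {
    stop("selected teeth not present in scan", call. = FALSE)
  }
  sel_verts <- which(scan$vertex_fdi %in% selected)
  sel_pts <- scan$points[sel_verts, , drop = FALSE]

  # oriented bounding box: principal axes of the selected teeth's vertices
  ctr <- colMeans(sel_pts)
  axes <- eigen(
    crossprod(sweep(sel_pts, 2L, ctr, "-")) / nrow(sel_pts),
    symmetric = TRUE
  )$vectors
  proj_sel <- sweep(sel_pts, 2L, ctr, "-") %*% axes
  lo <- apply(proj_sel, 2L, min) - config$box_margin_mm
  hi <- apply(proj_sel, 2L, max) + config$box_margin_mm
  proj_all <- sweep(scan$points, 2L, ctr, "-") %*% axes
  inside <- proj_all[, 1] >= lo[1] & proj_all[, 1] <= hi[1] &
    proj_all[, 2] >= lo[2] & proj_all[, 2] <= hi[2] &
    proj_all[, 3] >= lo[3] & proj_all[, 3] <= hi[3]
  if (!any(inside)) stop("crop removed all vertices", call. = FALSE)

  sub <- subset_scan(scan, which(inside))

  # annotation hygiene: the box margin can catch slivers of neighbouring
  # teeth; the arch segment is the selected teeth plus gingiva only.
  # Removing them first also stops a sliver from acting as a bridge that
  # would keep a surface fragment alive past the component filter.
  sliver <- sub$vertex_fdi != 0L & !(sub$vertex_fdi %in% selected)
  if (any(sliver)) {
    sub <- subset_scan(sub, which(!sliver))
  }

  # keep only the largest connected surface component
  comp <- surface_components(sub)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    sel_ctr <- colMeans(sub$points[sub$vertex_fdi %in% selected, ,
      drop = FALSE
    ])
    d2 <- vapply(best, function(b) {
      sum((colMeans(sub$points[comp == b, , drop = FALSE]) - sel_ctr)^2)
    }, numeric(1))
    best <- best[which.min(d2)]
  }
  sub <- subset_scan(sub, which(comp == best))

  shift <- -colMeans(sub$points)
  sub$points <- sweep(sub$points, 2L, shift, "+")
  structure(
    list(
      scan = sub, selected_labels = selected, applied = TRUE,
      translation_target = shift
    ),
    class = "crop_result"
  )
}

#' Apply the partial-arch crop with its configured probability
#'
#' @param scan An [annotated_scan()].
#' @param config A [crop_config()]; the crop (segment selection + box crop
#'   + recentering) is performed with probability `apply_probability`,
#'   otherwise the scan is returned unchanged with `applied = FALSE`.
#' @return A `crop_result`.
#' @export
maybe_crop <- function(scan, config = crop_config()) {
  stopifnot(inherits(scan, "annotated_scan"), inherits(config, "crop_config"))
  with_seed(config$seed, {
    if (stats::runif(1) >= config$apply_probability) {
      structure(
        list(
          scan = scan, selected_labels = scan_labels(scan),
          applied = FALSE, translation_target = c(0, 0, 0)
        ),
        class = "crop_result"
      )
    } else {
      crop_to_segment(scan, select_segment(scan, config), config)
    }
  })
}

# Restrict a scan to a vertex subset, re-indexing faces and dropping
# faces that touch removed vertices.
subset_scan <- function(scan, keep) {
  keep <- sort(unique(as.integer(keep)))
  newid <- integer(nrow(scan$points))
  newid[keep] <- seq_along(keep)
  faces <- NULL
  if (!is.null(scan$faces) && nrow(scan$faces)) {
    ok <- newid[scan$faces[, 1]] > 0L &
      newid[scan$faces[, 2]] > 0L &
      newid[scan$faces[, 3]] > 0L
    faces <- matrix(newid[scan$faces[ok, , drop = FALSE]], ncol = 3L)
  }
  # drop instances that lost all vertices; keep ids otherwise
  annotated_scan(
    scan$points[keep, , drop = FALSE], faces,
    scan$vertex_instance[keep], scan$vertex_fdi[keep], scan$arch
  )
}
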