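#' Order predicted teeth along the dental arch
#'
#' In the standardized frame (posterior toward +y, the arch wrapped around
#' the origin) the sequence starts at the most posterior tooth (maximum y,
#' ties broken by maximum x) and grows by repeatedly appending the
#' unvisited tooth whose origin-anchored xy-direction has the maximum
#' cosine similarity (minimum angle) to that of the last appended tooth.
#'
#' @param centroids T x 3 matrix of tooth centroids (mm) in the
#'   standardized frame.
#' @return A `tooth_ordering` list: `order` (permutation of row indices
#'   along the arch) and `direction` (`"right-to-left"`, `"left-to-right"`
#'   or `"unknown"`, by the x-coordinate trend).
#' @export
order_teeth <- function(centroids) {
  centroids <- as_points_matrix(centroids)
  n <- nrow(centroids)
  if (n == 0L) stop("no centroids supplied", call. = FALSE)
  dirs <- centroids[, 1:2, drop = FALSE]
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm < 1e-12] <- 1
  dirs <- dirs / nrm

  start_pool <- which(centroids[, 2] == max(centroids[, 2]))
  first <- start_pool[which.max(centroids[start_pool, 1])]
  ord <- integer(n)
  ord[1] <- first
  visited <- logical(n)
  visited[first] <- TRUE
  for (t in seq_len(n - 1L)) {
    last <- ord[t]
    cand <- which(!visited)
    cosim <- dirs[cand, , drop = FALSE] %*% dirs[last, ]
    nxt <- cand[which.max(cosim)]
    ord[t + 1L] <- nxt
    visited[nxt] <- TRUE
  }
  xtrend <- if (n > 1L) sum(diff(centroids[ord, 1])) else 0
  direction <- if (n < 2L || abs(xtrend) < 1e-9) {
    "unknown"
  } else if (xtrend < 0) {
    "right-to-left"
  } else {
    "left-to-right"
  }
  structure(list(order = ord, direction = direction),
    class = "tooth_ordering"
  )
}

#' Select the dental arch from predicted class logits
#'
#' Softmaxes each instance's 32-class logits and returns the arch with the
#' larger total probability mass summed over instances (ties: upper).
#'
#' @param instances A [predicted_instances()] object.
#' @return `"upper"` or `"lower"`.
#' @export
select_arch <- function(instances) {
  stopifnot(inherits(instances, "predicted_instances"))
  if (!length(instances$instances)) {
    stop("no instances to select an arch from", call. = FALSE)
  }
  upper_idx <- which(arch_of(fdi_labels()) == "upper")
  mass_upper <- 0
  mass_lower <- 0
  for (inst in instances$instances) {
    p <- softmax(inst$logits)
    mass_upper <- mass_upper + sum(p[upper_idx])
    mass_lower <- mass_lower + sum(p[-upper_idx])
  }
  if (mass_lower > mass_upper) "lower" else "upper"
}

softmax <- function(x) {
  if (any(!is.finite(x))) stop("non-finite logits", call. = FALSE)
  e <- exp(x - max(x))
  e / sum(e)
}

#' Tooth-number (unary) costs
#'
#' For each tooth in the ordering, restricts the 32-class logits to the 16
#' labels of the selected arch, softmaxes them, and returns the negative
#' log probabilities. Columns follow [arch_sequence()].
#'
#' @param instances A [predicted_instances()].
#' @param arch `"upper"` or `"lower"`.
#' @param ordering A `tooth_ordering` over the instances.
#' @return T x 16 matrix of costs, colnames = the arch's FDI labels, row t
#'   = t-th tooth of the ordering.
#' @export
unary_costs <- function(instances, arch, ordering) {
  stopifnot(
    inherits(instances, "predicted_instances"),
    inherits(ordering, "tooth_ordering")
  )
  labels16 <- arch_sequence(arch)
  cols <- match(labels16, fdi_labels())
  out <- t(vapply(ordering$order, function(i) {
    lg <- instances$instances[[i]]$logits
    if (any(!is.finite(lg))) stop("non-finite logits", call. = FALSE)
    x <- lg[cols]
    # -log softmax in log-space: stays finite for very confident logits
    m <- max(x)
    (m + log(sum(exp(x - m)))) - x
  }, numeric(16L)))
  colnames(out) <- labels16
  out
}

# --- offset model -----------------------------------------------------------

pair_key <- function(i, j) paste0(i, "-", j)

#' Collect tooth-pair centroid offsets from annotated standardized scans
#'
#' For every ordered pair of co-occurring FDI labels in a scan, stores the
#' centroid difference `centroid(j) - centroid(i)`. Each offset is also
#' copied to the midline-reflected pair (e.g. a 21-16 offset feeds 11-26)
#' with its x-component negated. Per annotated tooth, connected surface
#' components are found and their inter-component centroid offsets pooled
#' per arch; the pooled same-FDI set is assigned to every (i, i) pair of
#' that arch. These same-FDI offsets let the downstream relabeler accept
#' two predicted instances that are really fragments of one tooth.
#'
#' @param scans List of [annotated_scan()]s in the standard pose. When the
#'   landmark teeth are present a pose check is run and a warning (not an
#'   error) is emitted for unstandardized scans.
#' @return An unfitted `offset_model`; fit it with [fit_offset_model()].
#' @export
collect_offsets <- function(scans) {
  if (inherits(scans, "annotated_scan")) scans <- list(scans)
  pairs <- new.env(hash = TRUE, parent = emptyenv())
  add_off <- function(key, v) {
    pairs[[key]] <- c(pairs[[key]], list(v))
  }
  same_fdi <- list(upper = list(), lower = list())

  for (scan in scans) {
    stopifnot(inherits(scan, "annotated_scan"))
    lm <- landmark_labels(scan$arch)
    if (all(lm %in% scan_labels(scan))) {
      tf <- standard_pose_from_landmarks(scan)
      if (max(abs(tf$rotation - diag(3))) > 1e-3 ||
        max(abs(tf$translation)) > 0.5) {
        warning("scan does not appear to be in the standard pose",
          call. = FALSE
        )
      }
    }
    cent <- scan_tooth_centroids(scan)
    labs <- as.integer(rownames(cent))
    for (a in seq_along(labs)) {
      for (b in seq_along(labs)) {
        if (a == b) next
        off <- cent[b, ] - cent[a, ]
        add_off(pair_key(labs[a], labs[b]), off)
        add_off(
          pair_key(mirror_fdi(labs[a]), mirror_fdi(labs[b])),
          off * c(-1, 1, 1)
        )
      }
    }
    # same-FDI offsets from disconnected patches of one annotated tooth
    for (l in labs) {
      verts <- which(scan$vertex_fdi == l)
      comp <- surface_components(scan, verts)
      ids <- unique(comp)
      if (length(ids) < 2L) next
      cc <- t(vapply(ids, function(id) {
        colMeans(scan$points[verts[comp == id], , drop = FALSE])
      }, numeric(3)))
      for (a in seq_along(ids)) {
        for (b in seq_along(ids)) {
          if (a == b) next
          off <- cc[b, ] - cc[a, ]
          same_fdi[[scan$arch]] <- c(
            same_fdi[[scan$arch]],
            list(off), list(off * c(-1, 1, 1))
          )
        }
      }
    }
  }

  # pooled same-FDI offsets feed every (i, i) pair of the arch
  for (arch in c("upper", "lower")) {
    pool <- same_fdi[[arch]]
    if (!length(pool)) next
    for (l in arch_sequence(arch)) {
      pairs[[pair_key(l, l)]] <- c(pairs[[pair_key(l, l)]], pool)
    }
  }

  offsets <- lapply(
    as.list(pairs, all.names = TRUE),
    function(x) do.call(rbind, x)
  )
  structure(
    list(offsets = offsets, fitted = FALSE, ridge = NULL,
      fallback_cost = NULL, pairs = NULL, pooled = NULL),
    class = "offset_model"
  )
}

#' Fit the multivariate Gaussian offset model
#'
#' Per FDI pair with at least one offset: mean = sample mean, covariance =
#' maximum-likelihood estimate (divide by k) plus a ridge `epsilon * I`.
#' Sparse pairs (k < 4) shrink their covariance toward the pooled
#' within-arch covariance. Pairs never observed are flagged to use the
#' fallback cost at evaluation time.
#'
#' @param model An `offset_model` from [collect_offsets()].
#' @param ridge Ridge epsilon in mm^2 (default 0.01); must be nonnegative.
#' @param fallback_cost Cost floor for unobserved pairs (and replacement
#'   for non-finite densities), default 50.
#' @return The fitted `offset_model` with per-pair `mu`, `sigma`, `k` and
#'   per-arch pooled Gaussians.
#' @export
fit_offset_model <- function(model, ridge = 0.01, fallback_cost = 50) {
  stopifnot(inherits(model, "offset_model"))
  if (ridge < 0) stop("ridge must be nonnegative", call. = FALSE)

  ml_cov <- function(x) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu, "-")
    crossprod(xc) / nrow(x)
  }

  # pooled raw Gaussian and pooled centered covariance per arch
  pooled <- list()
  for (arch in c("upper", "lower")) {
    keys <- names(model$offsets)
    arch_keys <- keys[vapply(keys, function(k) {
      arch_of(as.integer(strsplit(k, "-")[[1]][1])) == arch
    }, logical(1))]
    if (!length(arch_keys)) next
    raw <- do.call(rbind, model$offsets[arch_keys])
    centered_ss <- matrix(0, 3L, 3L)
    ntot <- 0L
    for (k in arch_keys) {
      x <- model$offsets[[k]]
      mu <- colMeans(x)
      xc <- sweep(x, 2L, mu, "-")
      centered_ss <- centered_ss + crossprod(xc)
      ntot <- ntot + nrow(x)
    }
    pooled[[arch]] <- list(
      mu = colMeans(raw),
      sigma = ml_cov(raw) + ridge * diag(3),
      within = centered_ss / ntot,
      k = nrow(raw)
    )
  }

  fits <- lapply(names(model$offsets), function(key) {
    x <- model$offsets[[key]]
    arch <- arch_of(as.integer(strsplit(key, "-")[[1]][1]))
    k <- nrow(x)
    mu <- colMeans(x)
    sig <- if (k >= 2L) ml_cov(x) else matrix(0, 3L, 3L)
    if (k < 4L && !is.null(pooled[[arch]])) {
      lam <- k / 4
      sig <- lam * sig + (1 - lam) * pooled[[arch]]$within
    }
    list(mu = mu, sigma = sig + ridge * diag(3), k = k)
  })
  names(fits) <- names(model$offsets)

  model$pairs <- fits
  model$pooled <- pooled
  model$ridge <- ridge
  model$fallback_cost <- fallback_cost
  model$fitted <- TRUE
  model
}

#' @export
print.offset_model <- function(x, ...) {
  cat(
    "<offset_model> ", length(x$offsets), " FDI pairs, ",
    sum(vapply(x$offsets, nrow, integer(1))), " offsets, ",
    if (isTRUE(x$fitted)) "fitted" else "unfitted", "\n",
    sep = ""
  )
  invisible(x)
}

# Negative log density of N(mu, sigma) at x (3D), via Cholesky.
neg_log_dmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- backsolve(ch, x - mu, transpose = TRUE)
  0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(d^2))
}

#' Tooth-pair (pairwise) costs
#'
#' For each consecutive pair (t, t+1) of the ordering with observed offset
#' `delta = centroid(t+1) - centroid(t)`, evaluates the negative log
#' Gaussian density of `delta` under every of the arch's 16 x 16 FDI pair
#' models. Unobserved pairs fall back to the pooled-arch Gaussian density
#' floored at `fallback_cost`, keeping never-seen label pairs strongly
#' discouraged; non-finite entries are replaced by `fallback_cost`.
#'
#' @param centroids T x 3 matrix of predicted tooth centroids (mm).
#' @param ordering A `tooth_ordering`.
#' @param model A fitted `offset_model`.
#' @param arch `"upper"` or `"lower"`.
#' @return (T-1) x 16 x 16 array; `[t, i, j]` is the cost of labelling
#'   tooth t as label i and tooth t+1 as label j (labels in
#'   [arch_sequence()] order).
#' @export
pair_costs <- function(centroids, ordering, model, arch) {
  stopifnot(inherits(model, "offset_model"))
  if (!isTRUE(model$fitted)) {
    stop("offset model must be fitted first", call. = FALSE)
  }
  centroids <- as_points_matrix(centroids)
  labels16 <- arch_sequence(arch)
  tn <- length(ordering$order)
  out <- array(
    model$fallback_cost,
    dim = c(max(tn - 1L, 0L), 16L, 16L),
    dimnames = list(NULL, labels16, labels16)
  )
  if (tn < 2L) {
    return(out)
  }
  pool <- model$pooled[[arch]]
  for (t in seq_len(tn - 1L)) {
    delta <- centroids[ordering$order[t + 1L], ] -
      centroids[ordering$order[t], ]
    for (a in seq_len(16L)) {
      for (b in seq_len(16L)) {
        fit <- model$pairs[[pair_key(labels16[a], labels16[b])]]
        cost <- if (!is.null(fit)) {
          neg_log_dmvnorm(delta, fit$mu, fit$sigma)
        } else if (!is.null(pool)) {
          # unobserved pair: pooled-arch density, floored so that pairs
          # never seen in training stay strongly discouraged
          max(
            neg_log_dmvnorm(delta, pool$mu, pool$sigma),
            model$fallback_cost
          )
        } else {
          model$fallback_cost
        }
        if (!is.finite(cost)) cost <- model$fallback_cost
        out[t, a, b] <- cost
      }
    }
  }
  out
}

#' Cost tables for the minimum-cost FDI sequence
#'
#' @param unary T x 16 unary cost matrix from [unary_costs()].
#' @param pairwise (T-1) x 16 x 16 array from [pair_costs()].
#' @param labels Integer vector of the 16 arch labels (column order).
#' @param order Instance indices in arch order (from [order_teeth()]).
#' @return A `cost_tables` object.
#' @export
cost_tables <- function(unary, pairwise, labels, order = seq_len(nrow(unary))) {
  unary <- as.matrix(unary)
  tn <- nrow(unary)
  stopifnot(ncol(unary) == 16L, length(labels) == 16L)
  if (tn > 1L) {
    stopifnot(
      length(dim(pairwise)) == 3L,
      dim(pairwise)[1] == tn - 1L,
      dim(pairwise)[2] == 16L, dim(pairwise)[3] == 16L
    )
  }
  if (!all(is.finite(unary)) ||
    (tn > 1L && !all(is.finite(pairwise)))) {
    stop("cost tables must be finite", call. = FALSE)
  }
  structure(
    list(unary = unary, pairwise = pairwise,
      labels = as.integer(labels), order = as.integer(order)),
    class = "cost_tables"
  )
}

#' Minimum-cost FDI label sequence by dynamic programming
#'
#' Forward Viterbi-style recursion over the 16 label states: the cost of
#' the first tooth is its unary cost; each further tooth adds its unary
#' cost plus the pairwise cost from the predecessor label, minimized over
#' predecessors with the argmin recorded for backtracking. Repeated labels
#' are permitted (same-FDI pairs are part of the offset model). Ties break
#' toward the lower label index for determinism.
#'
#' @param costs A [cost_tables()] object.
#' @return A `label_assignment` list: `labels` (one FDI label per tooth, in
#'   ordering position), `total_cost`, and the `predecessors` matrix.
#' @export
optimal_fdi_sequence <- function(costs) {
  stopifnot(inherits(costs, "cost_tables"))
  tn <- nrow(costs$unary)
  if (tn == 0L) stop("empty cost tables", call. = FALSE)
  dp <- matrix(Inf, tn, 16L)
  pre <- matrix(NA_integer_, tn, 16L)
  dp[1L, ] <- costs$unary[1L, ]
  if (tn > 1L) {
    for (t in 2:tn) {
      for (j in seq_len(16L)) {
        tot <- dp[t - 1L, ] + costs$pairwise[t - 1L, , j]
        best <- which.min(tot) # first minimum = lowest label index
        dp[t, j] <- tot[best] + costs$unary[t, j]
        pre[t, j] <- best
      }
    }
  }
  states <- integer(tn)
  states[tn] <- which.min(dp[tn, ])
  if (tn > 1L) {
    for (t in tn:2) {
      states[t - 1L] <- pre[t, states[t]]
    }
  }
  structure(
    list(
      labels = costs$labels[states],
      total_cost = dp[tn, states[tn]],
      states = states,
      predecessors = pre
    ),
    class = "label_assignment"
  )
}

#' Relabel predicted instances with anatomically consistent FDI numbers
#'
#' The full postprocessing chain: select the arch from the logits, order
#' the teeth along the arch, build unary (softmax) and pairwise (Gaussian
#' offset) costs, and solve the minimum-cost label sequence by dynamic
#' programming.
#'
#' @param instances A [predicted_instances()] with centroids and 32-class
#'   logits.
#' @param model A fitted `offset_model`.
#' @return A `label_assignment` with `labels` in the original instance
#'   indexing, plus `arch`, `ordering` and `total_cost`.
#' @export
relabel <- function(instances, model) {
  stopifnot(
    inherits(instances, "predicted_instances"),
    inherits(model, "offset_model")
  )
  if (!isTRUE(model$fitted)) {
    stop("offset model must be fitted first", call. = FALSE)
  }
  arch <- select_arch(instances)
  centroids <- t(vapply(
    instances$instances, function(x) x$centroid, numeric(3)
  ))
  ordering <- order_teeth(centroids)
  un <- unary_costs(instances, arch, ordering)
  pw <- pair_costs(centroids, ordering, model, arch)
  assign <- optimal_fdi_sequence(
    cost_tables(un, pw, arch_sequence(arch), ordering$order)
  )
  labels <- integer(length(instances$instances))
  labels[ordering$order] <- assign$labels
  structure(
    list(
      labels = labels, arch = arch, ordering = ordering,
      total_cost = assign$total_cost
    ),
    class = "label_assignment"
  )
}

#' Per-instance argmax labels (no postprocessing)
#'
#' Baseline labeling: softmax argmax over the selected arch's 16 labels,
#' independently per instance.
#'
#' @param instances A [predicted_instances()].
#' @param arch Arch to restrict to; default from [select_arch()].
#' @return Integer vector of FDI labels per instance.
#' @export
argmax_labels <- function(instances, arch = NULL) {
  stopifnot(inherits(instances, "predicted_instances"))
  if (is.null(arch)) arch <- select_arch(instances)
  labels16 <- arch_sequence(arch)
  cols <- match(labels16, fdi_labels())
  vapply(instances$instances, function(x) {
    labels16[which.max(x$logits[cols])]
  }, integer(1))
}
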