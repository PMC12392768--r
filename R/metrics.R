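#' Optimal one-to-one assignment (Hungarian method)
#'
#' Solves the rectangular linear assignment problem by the shortest
#' augmenting path (Jonker-Volgenant) algorithm. Used to match predicted
#' to annotated teeth by IoU; written here because no assignment solver is
#' part of the package's dependency set.
#'
#' @param cost n x m cost matrix (finite), minimized.
#' @return Integer vector of length n: column assigned to each row, NA for
#'   unassigned rows (when n > m).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L || m == 0L) {
    return(rep(NA_integer_, n))
  }
  transposed <- FALSE
  if (n > m) {
    cost <- t(cost)
    tmp <- n; n <- nrow(cost); m <- ncol(cost)
    transposed <- TRUE
  }
  stopifnot(all(is.finite(cost)))
  inf <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L) # row matched to column (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    if (p[j] > 0L) assign_row[p[j]] <- j
  }
  if (transposed) {
    out <- rep(NA_integer_, tmp)
    for (i in seq_len(n)) {
      if (!is.na(assign_row[i])) out[assign_row[i]] <- i
    }
    out
  } else {
    assign_row
  }
}

#' Match predicted to annotated teeth by point-wise IoU
#'
#' Computes the IoU matrix between annotated and predicted instance vertex
#' sets, solves the optimal one-to-one assignment maximizing total IoU,
#' and discards pairs with IoU below 0.5 (matching is inclusive at exactly
#' 0.5). Unmatched annotated teeth are false negatives; unmatched
#' predicted teeth are false positives.
#'
#' @param gt An [annotated_scan()] (or an integer per-vertex instance
#'   vector with -1/0 = background).
#' @param pred A [predicted_instances()] or an integer per-vertex
#'   predicted instance vector (0 = background).
#' @param iou_threshold Minimum IoU for a match (default 0.5, inclusive).
#' @return A `match_result`: data.frame `pairs` (gt_id, pred_id, iou),
#'   `unmatched_gt`, `unmatched_pred`, and the instance vertex sets.
#' @export
match_teeth <- function(gt, pred, iou_threshold = 0.5) {
  gt_vec <- if (inherits(gt, "annotated_scan")) gt$vertex_instance else gt
  pred_vec <- if (inherits(pred, "predicted_instances")) {
    pred$vertex_instance
  } else {
    pred
  }
  if (length(gt_vec) != length(pred_vec)) {
    stop("ground truth and prediction differ in vertex count", call. = FALSE)
  }
  gt_ids <- sort(unique(gt_vec[gt_vec > 0L]))
  pred_ids <- sort(unique(pred_vec[pred_vec > 0L]))
  gt_sets <- lapply(gt_ids, function(id) which(gt_vec == id))
  pred_sets <- lapply(pred_ids, function(id) which(pred_vec == id))

  if (!length(gt_ids) || !length(pred_ids)) {
    return(structure(
      list(
        pairs = data.frame(
          gt_id = integer(), pred_id = integer(), iou = numeric()
        ),
        unmatched_gt = gt_ids, unmatched_pred = pred_ids,
        gt_sets = gt_sets, pred_sets = pred_sets,
        gt_ids = gt_ids, pred_ids = pred_ids
      ),
      class = "match_result"
    ))
  }

  iou <- matrix(0, length(gt_ids), length(pred_ids))
  for (a in seq_along(gt_ids)) {
    for (b in seq_along(pred_ids)) {
      inter <- length(intersect(gt_sets[[a]], pred_sets[[b]]))
      if (inter > 0L) {
        uni <- length(gt_sets[[a]]) + length(pred_sets[[b]]) - inter
        iou[a, b] <- inter / uni
      }
    }
  }
  assign <- solve_assignment(1 - iou)
  keep <- which(!is.na(assign) & iou[cbind(seq_along(assign), assign)] >=
    iou_threshold)
  pairs <- data.frame(
    gt_id = gt_ids[keep],
    pred_id = pred_ids[assign[keep]],
    iou = iou[cbind(keep, assign[keep])]
  )
  structure(
    list(
      pairs = pairs,
      unmatched_gt = setdiff(gt_ids, pairs$gt_id),
      unmatched_pred = setdiff(pred_ids, pairs$pred_id),
      gt_sets = gt_sets, pred_sets = pred_sets,
      gt_ids = gt_ids, pred_ids = pred_ids
    ),
    class = "match_result"
  )
}

#' Tooth detection F1 score
#'
#' `2 TP / (2 TP + FP + FN)` over matched/unmatched teeth; defined as 1
#' when nothing is annotated and nothing predicted.
#'
#' @param match A `match_result` from [match_teeth()].
#' @return Scalar in \[0, 1\].
#' @export
detection_f1 <- function(match) {
  stopifnot(inherits(match, "match_result"))
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  if (tp + fp + fn == 0L) {
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Mean point-wise Dice over matched teeth
#'
#' @param match A `match_result`.
#' @return Mean of `2|A n B| / (|A| + |B|)` over matched pairs; `NA` when
#'   there are no matched pairs.
#' @export
tooth_dice <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (!nrow(match$pairs)) {
    return(NA_real_)
  }
  dice <- vapply(seq_len(nrow(match$pairs)), function(k) {
    a <- match$gt_sets[[match(match$pairs$gt_id[k], match$gt_ids)]]
    b <- match$pred_sets[[match(match$pairs$pred_id[k], match$pred_ids)]]
    2 * length(intersect(a, b)) / (length(a) + length(b))
  }, numeric(1))
  mean(dice)
}

#' Macro-averaged label F1 over matched teeth
#'
#' Multi-class F1 of predicted vs annotated FDI labels restricted to
#' matched pairs, unweighted mean over the classes present in the
#' annotations.
#'
#' @param match A `match_result`.
#' @param gt_labels Named or positional map: FDI label of each annotated
#'   instance id.
#' @param pred_labels FDI label of each predicted instance id.
#' @return Scalar in \[0, 1\]; `NA` with no matched pairs.
#' @export
label_macro_f1 <- function(match, gt_labels, pred_labels) {
  stopifnot(inherits(match, "match_result"))
  if (!nrow(match$pairs)) {
    return(NA_real_)
  }
  y_true <- as.integer(gt_labels[as.character(match$pairs$gt_id)])
  y_pred <- as.integer(pred_labels[as.character(match$pairs$pred_id)])
  classes <- sort(unique(y_true))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_pred == cl & y_true != cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Macro-IoU over FDI labels
#'
#' Point-wise IoU of each FDI label's vertex sets (annotated vs
#' predicted), unweighted mean over labels present in either side. A label
#' predicted but absent from the annotation (or vice versa) contributes
#' IoU 0.
#'
#' @param gt_fdi Integer per-vertex annotated FDI labels (0 = background).
#' @param pred_fdi Integer per-vertex predicted FDI labels (0 =
#'   background).
#' @return Scalar in \[0, 1\]; 1 when no labels occur on either side.
#' @export
macro_iou <- function(gt_fdi, pred_fdi) {
  if (length(gt_fdi) != length(pred_fdi)) {
    stop("ground truth and prediction differ in vertex count", call. = FALSE)
  }
  labels <- sort(unique(c(gt_fdi[gt_fdi != 0L], pred_fdi[pred_fdi != 0L])))
  if (!length(labels)) {
    return(1)
  }
  iou <- vapply(labels, function(l) {
    a <- gt_fdi == l
    b <- pred_fdi == l
    inter <- sum(a & b)
    uni <- sum(a | b)
    inter / uni
  }, numeric(1))
  mean(iou)
}

#' Challenge metrics: TLA, TSA, TIR and the combined score
#'
#' Teeth localization accuracy (TLA) is the mean tooth-size-normalized
#' Euclidean distance between each annotated tooth centroid and the
#' closest predicted tooth centroid (`tla_raw`, lower is better), with a
#' fixed penalty per annotated tooth when no prediction exists; it is also
#' reported on the 0-1 higher-is-better scale as `tla = exp(-tla_raw)`.
#' Teeth segmentation accuracy (TSA) is the point-wise F1 of the binary
#' tooth-vs-background partition. Tooth identification rate (TIR) is the
#' percentage of annotated teeth whose closest predicted tooth lies within
#' normalized distance 0.5 and carries the same FDI label. The combined
#' score averages TLA, TSA and TIR on the 0-1 scale.
#'
#' @param gt An [annotated_scan()].
#' @param pred A [predicted_instances()] over the same vertices.
#' @param pred_labels Integer FDI label per predicted instance (e.g. from
#'   [relabel()] or [argmax_labels()]).
#' @param miss_penalty Normalized-distance penalty per annotated tooth
#'   when there are no predicted teeth (default 5).
#' @param tir_radius Normalized-distance radius for "closely predicted"
#'   (default 0.5).
#' @return List with `tla_raw`, `tla`, `tsa`, `tir` (percent), `score`.
#' @export
challenge_metrics <- function(gt, pred, pred_labels,
                              miss_penalty = 5, tir_radius = 0.5) {
  stopifnot(
    inherits(gt, "annotated_scan"),
    inherits(pred, "predicted_instances")
  )
  if (nrow(gt$points) != length(pred$vertex_instance)) {
    stop("ground truth and prediction differ in vertex count", call. = FALSE)
  }
  gt_labs <- scan_labels(gt)
  gt_cent <- scan_tooth_centroids(gt)
  gt_size <- vapply(gt_labs, function(l) {
    pts <- gt$points[gt$vertex_fdi == l, , drop = FALSE]
    sqrt(sum((apply(pts, 2L, max) - apply(pts, 2L, min))^2))
  }, numeric(1))

  n_pred <- length(pred$instances)
  if (length(gt_labs)) {
    if (n_pred) {
      pc <- t(vapply(pred$instances, function(x) x$centroid, numeric(3)))
      ndist <- numeric(length(gt_labs))
      closest <- integer(length(gt_labs))
      for (k in seq_along(gt_labs)) {
        d <- sqrt(rowSums(sweep(pc, 2L, gt_cent[k, ], "-")^2))
        closest[k] <- which.min(d)
        ndist[k] <- d[closest[k]] / gt_size[k]
      }
      tla_raw <- mean(ndist)
      hit <- ndist < tir_radius &
        as.integer(pred_labels)[closest] == gt_labs
      tir <- 100 * mean(hit)
    } else {
      tla_raw <- miss_penalty
      tir <- 0
    }
  } else {
    tla_raw <- 0
    tir <- 100
  }

  gt_bin <- gt$vertex_fdi != 0L
  pred_bin <- pred$vertex_instance > 0L
  tp <- sum(gt_bin & pred_bin)
  fp <- sum(!gt_bin & pred_bin)
  fn <- sum(gt_bin & !pred_bin)
  tsa <- if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)

  tla <- exp(-tla_raw)
  list(
    tla_raw = tla_raw, tla = tla, tsa = tsa, tir = tir,
    score = (tla + tsa + tir / 100) / 3
  )
}

#' Evaluate one scan: full metric report
#'
#' Runs the matched-teeth metrics (detection F1, tooth Dice, label
#' macro-F1), the point-wise macro-IoU, and the challenge metrics, and
#' collects the error counts (FP, FN, wrong labels).
#'
#' @param gt An [annotated_scan()].
#' @param pred A [predicted_instances()].
#' @param pred_labels Integer FDI label per predicted instance.
#' @return A `metric_report` list.
#' @export
evaluate_scan <- function(gt, pred, pred_labels) {
  match <- match_teeth(gt, pred)
  gt_ids <- sort(unique(gt$vertex_instance[gt$vertex_instance > 0L]))
  gt_label_map <- vapply(gt_ids, function(id) {
    gt$vertex_fdi[which(gt$vertex_instance == id)[1]]
  }, integer(1))
  names(gt_label_map) <- gt_ids
  pred_label_map <- as.integer(pred_labels)
  names(pred_label_map) <- seq_along(pred_labels)

  pred_fdi <- integer(nrow(gt$points))
  for (i in seq_along(pred$instances)) {
    pred_fdi[pred$instances[[i]]$vertices] <- pred_label_map[i]
  }

  wrong <- 0L
  if (nrow(match$pairs)) {
    wrong <- sum(
      gt_label_map[as.character(match$pairs$gt_id)] !=
        pred_label_map[as.character(match$pairs$pred_id)]
    )
  }
  chal <- challenge_metrics(gt, pred, pred_labels)
  structure(
    list(
      f1 = detection_f1(match),
      tooth_dice = tooth_dice(match),
      label_macro_f1 = label_macro_f1(match, gt_label_map, pred_label_map),
      macro_iou = macro_iou(gt$vertex_fdi, pred_fdi),
      tla_raw = chal$tla_raw, tla = chal$tla, tsa = chal$tsa,
      tir = chal$tir, score = chal$score,
      counts = list(
        tp = nrow(match$pairs),
        fp = length(match$unmatched_pred),
        fn = length(match$unmatched_gt),
        wrong_label = wrong
      ),
      match = match
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  detection F1   %.4f\n", x$f1))
  cat(sprintf("  tooth Dice     %.4f\n", x$tooth_dice))
  cat(sprintf("  label macro-F1 %.4f\n", x$label_macro_f1))
  cat(sprintf("  macro-IoU      %.4f\n", x$macro_iou))
  cat(sprintf(
    "  TLA %.4f (raw %.4f)  TSA %.4f  TIR %.1f%%  score %.4f\n",
    x$tla, x$tla_raw, x$tsa, x$tir, x$score
  ))
  cat(sprintf(
    "  TP %d  FP %d  FN %d  wrong labels %d\n",
    x$counts$tp, x$counts$fp, x$counts$fn, x$counts$wrong_label
  ))
  invisible(x)
}
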