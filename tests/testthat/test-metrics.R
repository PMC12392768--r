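# Brute-force optimal assignment over all permutations (oracle, n <= 6).
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  k <- min(n, m)
  perms <- function(v) {
    if (length(v) <= 1L) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  rowsets <- utils::combn(n, k, simplify = FALSE)
  colsets <- utils::combn(m, k, simplify = FALSE)
  for (rs in rowsets) {
    for (cs in colsets) {
      for (p in perms(cs)) {
        best <- min(best, sum(cost[cbind(rs, p)]))
      }
    }
  }
  best
}

test_that("the assignment solver matches brute force on small problems", {
  with_seed_t(1, {
    for (trial in 1:15) {
      n <- sample(1:4, 1L)
      m <- sample(1:4, 1L)
      cost <- matrix(stats::runif(n * m), n, m)
      sol <- solve_assignment(cost)
      assigned <- which(!is.na(sol))
      expect_length(assigned, min(n, m))
      expect_false(anyDuplicated(sol[assigned]) > 0)
      expect_equal(
        sum(cost[cbind(assigned, sol[assigned])]),
        brute_assignment_cost(cost),
        tolerance = 1e-12
      )
    }
  })
})

test_that("tooth matching thresholds IoU at 0.5 inclusively", {
  # identical maps: all matched at IoU 1
  gt <- c(rep(1L, 4), rep(2L, 4), rep(-1L, 4))
  m <- match_teeth(gt, pmax(gt, 0L))
  expect_equal(nrow(m$pairs), 2L)
  expect_equal(m$pairs$iou, c(1, 1))
  expect_length(m$unmatched_gt, 0L)
  expect_length(m$unmatched_pred, 0L)

  # equal-size half overlap: IoU = 1/3, not matched
  gt2 <- c(rep(1L, 4), rep(-1L, 4))
  pr2 <- c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L)
  m2 <- match_teeth(gt2, pr2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_gt, 1L)
  expect_equal(m2$unmatched_pred, 1L)

  # IoU exactly 0.5 counts as matched
  gt3 <- c(1L, 1L, -1L)
  pr3 <- c(1L, 0L, 0L)
  m3 <- match_teeth(gt3, pr3)
  expect_equal(nrow(m3$pairs), 1L)
  expect_equal(m3$pairs$iou, 0.5)

  expect_error(match_teeth(c(1L, 1L), c(1L)), "vertex count")
})

test_that("detection F1 follows 2TP/(2TP+FP+FN)", {
  gt <- rep(c(1L, 2L, -1L), each = 10)
  pred <- rep(c(1L, 2L, 0L), each = 10)
  m <- match_teeth(gt, pred)
  expect_equal(detection_f1(m), 1)
  # TP=2, FP=1, FN=1 -> 2/3
  gt2 <- c(rep(1L, 10), rep(2L, 10), rep(3L, 10), rep(-1L, 10))
  pr2 <- c(rep(1L, 10), rep(2L, 10), rep(0L, 10), rep(9L, 10))
  expect_equal(detection_f1(match_teeth(gt2, pr2)), 2 / 3, tolerance = 1e-6)
  # no predictions at all
  expect_equal(detection_f1(match_teeth(gt2, rep(0L, 40))), 0)
  # empty vs empty is perfect
  expect_equal(detection_f1(match_teeth(rep(-1L, 5), rep(0L, 5))), 1)
})

test_that("tooth Dice averages point-wise Dice over matched pairs", {
  gt <- c(rep(1L, 100), rep(2L, 50))
  pred <- c(rep(1L, 80), rep(0L, 20), rep(2L, 50))
  m <- match_teeth(gt, pred)
  # pair 1: |A|=100, |B|=80, inter=80 -> 2*80/180; pair 2: perfect
  expect_equal(tooth_dice(m), mean(c(160 / 180, 1)), tolerance = 1e-12)
  expect_true(is.na(tooth_dice(match_teeth(rep(1L, 4), rep(0L, 4)))))
})

test_that("label macro-F1 penalizes a systematically mislabelled class", {
  # three classes over matched pairs; class 13 always predicted as 12
  gt <- rep(1:6, each = 10)
  pred <- gt
  m <- match_teeth(gt, pred)
  gt_labels <- stats::setNames(c(11L, 11L, 12L, 12L, 13L, 13L), 1:6)
  pred_labels <- stats::setNames(c(11L, 11L, 12L, 12L, 12L, 12L), 1:6)
  # class 11: perfect (f1=1); class 12: tp=2 fp=2 -> f1=2*2/(4+2)=2/3;
  # class 13: tp=0 fn=2 -> 0
  expect_equal(
    label_macro_f1(m, gt_labels, pred_labels),
    mean(c(1, 2 / 3, 0)),
    tolerance = 1e-12
  )
  all_right <- label_macro_f1(m, gt_labels, gt_labels)
  expect_equal(all_right, 1)
})

test_that("macro-IoU averages per-label IoU including absent-label zeros", {
  gt <- c(rep(11L, 10), rep(12L, 10), rep(0L, 10))
  pred <- c(rep(11L, 10), rep(12L, 5), rep(0L, 15))
  # label 11: IoU 1; label 12: 5/10
  expect_equal(macro_iou(gt, pred), mean(c(1, 0.5)), tolerance = 1e-12)
  # label predicted but absent from the annotation contributes 0
  pred2 <- c(rep(11L, 10), rep(12L, 10), rep(21L, 10))
  expect_equal(macro_iou(gt, pred2), mean(c(1, 1, 0)), tolerance = 1e-12)
  expect_equal(macro_iou(rep(0L, 5), rep(0L, 5)), 1)
})

test_that("challenge metrics attain their maxima on perfect predictions", {
  scan <- fix_scan()
  pred <- perturb_predictions(scan, noise_config(seed = 1))
  labels <- scan_labels(scan)
  ch <- challenge_metrics(scan, pred, labels)
  expect_equal(ch$tla_raw, 0)
  expect_equal(ch$tla, 1)
  expect_equal(ch$tsa, 1)
  expect_equal(ch$tir, 100)
  expect_equal(ch$score, 1)
  # score is the arithmetic mean of the three 0-1 terms
  expect_equal(ch$score, (ch$tla + ch$tsa + ch$tir / 100) / 3)
})

test_that("a tooth displaced by its own size contributes normalized distance 1", {
  teeth <- list("11" = cluster_at(c(0, -10, 0), k = 8L, r = 1))
  scan <- make_point_scan(teeth)
  size <- sqrt(sum((apply(teeth[["11"]], 2, max) -
    apply(teeth[["11"]], 2, min))^2))
  pred <- predicted_instances(
    list(list(
      vertices = 1:8, centroid = c(0, -10, 0) + c(size, 0, 0),
      logits = rep(0, 32)
    )),
    nrow(scan$points)
  )
  ch <- challenge_metrics(scan, pred, 11L)
  expect_equal(ch$tla_raw, 1, tolerance = 1e-12)
  expect_equal(ch$tla, exp(-1), tolerance = 1e-12)
  expect_equal(ch$tir, 0) # too far to count as closely predicted
})

test_that("metrics are invariant to instance-id permutations and monotone in FP", {
  scan <- fix_scan()
  pred <- perturb_predictions(scan, noise_config(seed = 2))
  labels <- scan_labels(scan)
  base <- evaluate_scan(scan, pred, labels)

  # permute predicted instance order
  perm <- rev(seq_along(pred$instances))
  pred2 <- predicted_instances(pred$instances[perm], nrow(scan$points))
  r2 <- evaluate_scan(scan, pred2, labels[perm])
  expect_equal(r2$f1, base$f1)
  expect_equal(r2$tooth_dice, base$tooth_dice)
  expect_equal(r2$macro_iou, base$macro_iou)
  expect_equal(r2$score, base$score)

  # adding a spurious instance never increases detection F1
  spur <- perturb_predictions(
    scan, noise_config(spurious_rate = 2, seed = 3)
  )
  expect_lte(
    detection_f1(match_teeth(scan, spur)),
    detection_f1(match_teeth(scan, pred))
  )
  # deleting a matched prediction never increases it
  dropped <- predicted_instances(
    pred$instances[-1], nrow(scan$points)
  )
  expect_lt(
    detection_f1(match_teeth(scan, dropped)),
    detection_f1(match_teeth(scan, pred))
  )
})

test_that("the full pipeline closes at perfect metrics under zero noise", {
  scan <- generate_arch(generator_config(seed = 51))
  pred <- perturb_predictions(scan, noise_config(seed = 1))
  model <- fix_model()
  labels <- relabel(pred, model)$labels
  rep <- evaluate_scan(scan, pred, labels)
  expect_equal(rep$f1, 1)
  expect_equal(rep$tooth_dice, 1)
  expect_equal(rep$label_macro_f1, 1)
  expect_equal(rep$macro_iou, 1)
  expect_equal(rep$tsa, 1)
  expect_equal(rep$tir, 100)
  expect_equal(rep$score, 1)
  expect_equal(rep$counts$wrong_label, 0L)
})
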