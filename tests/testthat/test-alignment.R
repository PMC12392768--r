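test_that("landmark standardization aligns molars with x and the occlusal normal with z", {
  scan <- fix_scan()
  moved <- transform_scan(
    scan,
    compose_transforms(
      rigid_transform(diag(3), c(5, -3, 8)),
      random_rotation(seed = 7)
    )
  )
  tf <- standard_pose_from_landmarks(moved)
  std <- transform_scan(moved, tf)
  cent <- scan_tooth_centroids(std)
  m1 <- cent["16", ]
  m2 <- cent["26", ]
  expect_lt(abs(m1[2] - m2[2]), 1e-6)
  expect_lt(abs(m1[3] - m2[3]), 1e-6)
  # occlusal-plane normal maps to +z
  ci <- (cent["11", ] + cent["21", ]) / 2
  nrm <- cross_prod(m2 - m1, ci - m1)
  nrm <- nrm / sqrt(sum(nrm^2))
  expect_lt(min(sum((nrm - c(0, 0, 1))^2), sum((nrm + c(0, 0, 1))^2)), 1e-10)
  # anterior at -y, and the recovered points match the original scan
  expect_lt(ci[2], min(m1[2], m2[2]))
  expect_equal(std$points, scan$points, tolerance = 1e-6)
})

test_that("standardization requires all four landmark teeth", {
  no_molar <- generate_arch(generator_config(
    present_labels = setdiff(arch_sequence("upper")[2:15], 16L),
    points_per_tooth = 12L, gingiva_points = 100L, seed = 2
  ))
  expect_error(standard_pose_from_landmarks(no_molar), "landmark")
})

test_that("PCA rough alignment diagonalizes the covariance deterministically", {
  pts <- with_seed_t(5, {
    cbind(stats::rnorm(400, sd = 9), stats::rnorm(400, sd = 4),
      stats::rnorm(400, sd = 1))
  })
  tf <- pca_rough_align(pts)
  aligned <- apply_transform(pts, tf)
  cv <- stats::cov(aligned)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  expect_true(all(diff(diag(cv)) <= 1e-9)) # descending variance
  # spectral invariance: rotating the input does not change the aligned spectrum
  rot <- random_rotation(seed = 8)
  aligned2 <- apply_transform(apply_transform(pts, rot), pca_rough_align(apply_transform(pts, rot)))
  expect_equal(diag(stats::cov(aligned2)), diag(cv), tolerance = 1e-6)
  expect_error(pca_rough_align(cbind(1:9, 1:9, 1:9)), "collinear")
})

test_that("orientation loss matches its analytic values", {
  truth <- standard_pose()
  expect_equal(orient_loss(truth, truth), 0)
  flipped <- pose_params(-truth$forward, -truth$up)
  expect_equal(orient_loss(truth, flipped), 4)
  swapped <- pose_params(truth$up, truth$forward)
  expect_equal(orient_loss(truth, swapped), 2)
  # invariant to positive rescaling of the predictions
  pred <- pose_params(c(1, 2, 0.5), c(-1, 0.2, 3))
  expect_equal(
    orient_loss(truth, pred),
    orient_loss(truth, pose_params(7 * pred$forward, 0.01 * pred$up))
  )
  # nonnegativity over random predictions
  with_seed_t(6, {
    for (i in 1:50) {
      p <- pose_params(stats::rnorm(3), stats::rnorm(3))
      expect_gte(orient_loss(truth, p), 0)
    }
  })
  expect_error(
    orient_loss(truth, pose_params(c(1, 0, 0), c(1e-20, 0, 0))),
    "nonzero"
  )
})

test_that("alignment loss decomposes exactly into its four terms", {
  truth <- standard_pose()
  seg <- rep(c(0, 1), 50)
  perfect <- align_loss(truth, truth, seg, seg)
  expect_lt(perfect$total, 1e-5)

  shifted <- pose_params(truth$forward, truth$up, c(0.5, 0, 0))
  l <- align_loss(truth, shifted, seg, seg)
  expect_equal(l$smooth_l1, 0.5 * 0.5^2 / 3, tolerance = 1e-12)

  # random case: total equals independently recomputed terms
  with_seed_t(7, {
    pred <- pose_params(stats::rnorm(3), stats::rnorm(3), stats::rnorm(3))
    sp <- stats::runif(100)
    l <- align_loss(truth, pred, seg, sp)
    d <- abs(truth$translation - pred$translation)
    sl1 <- mean(ifelse(d < 1, 0.5 * d^2, d - 0.5))
    spc <- pmin(pmax(sp, 1e-7), 1 - 1e-7)
    bce <- -mean(seg * log(spc) + (1 - seg) * log(1 - spc))
    dice <- 1 - (2 * sum(seg * sp) + 1e-6) / (sum(seg) + sum(sp) + 1e-6)
    expect_equal(l$smooth_l1, sl1, tolerance = 1e-12)
    expect_equal(l$bce, bce, tolerance = 1e-12)
    expect_equal(l$dice, dice, tolerance = 1e-12)
    expect_equal(l$total, l$orient + l$smooth_l1 + l$bce + l$dice,
      tolerance = 1e-12
    )
  })
  expect_error(align_loss(truth, truth, c(0, 1), c(0.5)), "length")
})

test_that("standardization from pose parameters inverts a known rigid motion", {
  pts <- fix_scan()$points
  expect_equal(apply_standardization(pts, standard_pose()), pts,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  for (s in 1:25) {
    rot <- random_rotation(seed = 100 + s)$rotation
    t0 <- with_seed_t(200 + s, stats::rnorm(3, sd = 10))
    moved <- sweep(pts %*% t(rot), 2L, t0, "+")
    pred <- pose_params(
      as.numeric(rot %*% c(0, -1, 0)),
      as.numeric(rot %*% c(0, 0, 1)),
      t0
    )
    back <- apply_standardization(moved, pred)
    expect_lt(max(abs(back - pts)), 1e-6)
  }
  expect_error(
    apply_standardization(pts, pose_params(c(0, 0, 1), c(0, 0, 2))),
    "parallel"
  )
})
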