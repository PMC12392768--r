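test_that("tooth ordering starts posterior and matches the polar-angle oracle", {
  expect_equal(order_teeth(matrix(c(1, 2, 3), 1L))$order, 1L)
  expect_error(order_teeth(matrix(numeric(0), 0L, 3L)), "no centroids")
  for (s in c(1, 41, 42)) {
    cent <- scan_tooth_centroids(generate_arch(generator_config(seed = s)))
    perm <- with_seed_t(s, sample.int(nrow(cent)))
    shuffled <- cent[perm, , drop = FALSE]
    ord <- order_teeth(shuffled)$order
    expect_equal(as.integer(which.max(shuffled[, 2])), ord[1])
    # oracle: the greedy walk is an angular sort about the origin, i.e.
    # the polar angle along the returned order is strictly monotone
    expect_true(identical(sort(ord), seq_len(nrow(cent))))
    theta <- atan2(shuffled[, 2], shuffled[, 1])
    dtheta <- diff(unwrap_angles(theta[ord]))
    expect_true(all(dtheta < 0) || all(dtheta > 0))
  }
})

test_that("arch selection follows the total softmax mass", {
  scan <- fix_scan()
  pred <- perturb_predictions(scan, noise_config(seed = 1))
  expect_equal(select_arch(pred), "upper")
  low <- generate_arch(generator_config(arch = "lower", seed = 2))
  pred_low <- perturb_predictions(low, noise_config(seed = 1))
  expect_equal(select_arch(pred_low), "lower")
  # mixed seeded case equals brute-force mass comparison
  with_seed_t(9, {
    insts <- lapply(1:6, function(i) {
      list(
        vertices = integer(0), centroid = stats::rnorm(3),
        logits = stats::rnorm(32L, sd = 2)
      )
    })
  })
  pm <- predicted_instances(insts, 10L)
  mass <- sapply(pm$instances, function(x) {
    p <- exp(x$logits - max(x$logits))
    p <- p / sum(p)
    c(sum(p[1:16]), sum(p[17:32]))
  })
  expected <- if (sum(mass[1, ]) >= sum(mass[2, ])) "upper" else "lower"
  expect_equal(select_arch(pm), expected)
})

test_that("unary costs are negative log softmax over the arch's 16 labels", {
  mk <- function(logits) {
    predicted_instances(
      list(list(vertices = integer(0), centroid = c(0, 0, 0), logits = logits)),
      5L
    )
  }
  ord1 <- order_teeth(matrix(0, 1L, 3L))
  un <- unary_costs(mk(rep(0, 32)), "upper", ord1)
  expect_equal(as.numeric(un), rep(log(16), 16L), tolerance = 1e-12)
  # saturated logit: its cost ~ 0, all others large
  lg <- rep(0, 32)
  lg[match(16L, fdi_labels())] <- 1e3
  un2 <- unary_costs(mk(lg), "upper", ord1)
  expect_lt(un2[1, "16"], 1e-6)
  expect_true(all(un2[1, colnames(un2) != "16"] > 100))
  # random rows renormalize
  with_seed_t(10, {
    for (i in 1:20) {
      un3 <- unary_costs(mk(stats::rnorm(32, sd = 3)), "lower", ord1)
      expect_equal(sum(exp(-un3)), 1, tolerance = 1e-9)
    }
  })
  expect_error(unary_costs(mk(c(NA, rep(0, 31))), "upper", ord1), "non-finite")
})

test_that("offset collection stores pair differences and mirrored copies", {
  scan <- make_point_scan(list(
    "11" = cluster_at(c(-5, -20, 0)),
    "21" = cluster_at(c(5, -20, 0))
  ))
  model <- collect_offsets(list(scan))
  o <- model$offsets
  expect_equal(o[["11-21"]][1, ], c(10, 0, 0), ignore_attr = TRUE)
  # mirror of (11,21) is (21,11) with x negated; the direct (21,11) offset
  # coincides, so both stored rows equal (-10, 0, 0)
  expect_equal(nrow(o[["21-11"]]), 2L)
  expect_true(all(apply(o[["21-11"]], 1L, function(r) {
    isTRUE(all.equal(r, c(-10, 0, 0), check.attributes = FALSE))
  })))
})

test_that("disconnected patches of one tooth feed the same-FDI pools", {
  scan <- make_point_scan(list(
    "11" = rbind(cluster_at(c(-1.5, -20, 0)), cluster_at(c(1.5, -20, 0))),
    "16" = cluster_at(c(20, 5, 0))
  ))
  # single instance, one label, two components 3 mm apart
  model <- collect_offsets(list(scan))
  for (l in arch_sequence("upper")) {
    key <- paste0(l, "-", l)
    expect_false(is.null(model$offsets[[key]]))
    norms <- sqrt(rowSums(model$offsets[[key]]^2))
    expect_true(any(abs(norms - 3) < 1e-9))
  }
  expect_null(model$offsets[["36-36"]])
})

test_that("offset collection is mirror-equivariant", {
  scan <- fix_scan()
  mirrored <- annotated_scan(
    scan$points * matrix(c(-1, 1, 1), nrow(scan$points), 3L, byrow = TRUE),
    scan$faces, scan$vertex_instance,
    ifelse(scan$vertex_fdi == 0L, 0L, mirror_fdi(pmax(scan$vertex_fdi, 11L))),
    scan$arch
  )
  a <- collect_offsets(list(scan))$offsets
  b <- collect_offsets(list(mirrored))$offsets
  expect_setequal(names(a), names(b))
  for (key in names(a)) {
    labs <- as.integer(strsplit(key, "-")[[1]])
    mkey <- paste0(mirror_fdi(labs[1]), "-", mirror_fdi(labs[2]))
    am <- a[[key]]
    bm <- b[[mkey]] * matrix(c(-1, 1, 1), nrow(b[[mkey]]), 3L, byrow = TRUE)
    expect_equal(
      am[do.call(order, as.data.frame(am)), ],
      bm[do.call(order, as.data.frame(bm)), ],
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("the Gaussian fit recovers mean, covariance and flags unseen pairs", {
  m0 <- collect_offsets(list(make_point_scan(list(
    "11" = cluster_at(c(-5, -20, 0)), "21" = cluster_at(c(5, -20, 0))
  ))))
  m0$offsets <- list("11-21" = rbind(c(1, 0, 0), c(3, 0, 0)))
  fit <- fit_offset_model(m0, ridge = 0.01)
  expect_equal(fit$pairs[["11-21"]]$mu, c(2, 0, 0), ignore_attr = TRUE)
  expect_null(fit$pairs[["31-32"]])
  expect_error(fit_offset_model(m0, ridge = -1), "nonnegative")

  # parameter recovery from 500 draws of a known Gaussian
  mu0 <- c(4, -2, 1)
  sigma0 <- matrix(c(1, 0.4, 0, 0.4, 0.8, 0.2, 0, 0.2, 0.5), 3L)
  ch <- chol(sigma0)
  draws <- with_seed_t(11, {
    matrix(stats::rnorm(1500), 500L) %*% ch +
      matrix(mu0, 500L, 3L, byrow = TRUE)
  })
  m1 <- m0
  m1$offsets <- list("14-15" = draws)
  fit1 <- fit_offset_model(m1, ridge = 0.01)
  expect_lt(sqrt(sum((fit1$pairs[["14-15"]]$mu - mu0)^2)), 0.2)
  expect_lt(
    norm(fit1$pairs[["14-15"]]$sigma - sigma0, "F"), 0.5
  )
})

test_that("pair costs match the closed-form Gaussian density", {
  model <- structure(
    list(
      offsets = list(), fitted = TRUE, ridge = 0,
      fallback_cost = 50,
      pairs = list("18-17" = list(mu = c(10, 0, 0), sigma = diag(3), k = 5)),
      pooled = NULL
    ),
    class = "offset_model"
  )
  ord <- structure(list(order = 1:2, direction = "unknown"),
    class = "tooth_ordering"
  )
  cent <- rbind(c(0, 10, 0), c(10, 10, 0)) # delta = (10, 0, 0)
  pc <- pair_costs(cent, ord, model, "upper")
  expect_equal(dim(pc), c(1L, 16L, 16L))
  expect_equal(pc[1, "18", "17"], 1.5 * log(2 * pi), tolerance = 1e-6)
  cent2 <- rbind(c(0, 10, 0), c(11, 10, 0)) # delta = (11, 0, 0)
  pc2 <- pair_costs(cent2, ord, model, "upper")
  expect_equal(pc2[1, "18", "17"], 1.5 * log(2 * pi) + 0.5, tolerance = 1e-6)
  # unobserved pairs use the floored fallback
  expect_equal(pc[1, "11", "12"], 50)
  # independent density oracle
  skip_if_not_installed("mclust")
  expect_equal(
    pc2[1, "18", "17"],
    -log(mclust::dmvnorm(matrix(c(11, 0, 0), 1L), c(10, 0, 0), diag(3))),
    tolerance = 1e-9
  )
})

test_that("exp(-pair cost) integrates to one over a grid around the mean", {
  model <- fix_model()
  fit <- model$pairs[["16-15"]]
  expect_false(is.null(fit))
  h <- 0.25
  gr <- seq(-4, 4, by = h)
  grid <- as.matrix(expand.grid(gr, gr, gr))
  sd3 <- sqrt(diag(fit$sigma))
  pts <- sweep(grid %*% diag(sd3), 2L, fit$mu, "+")
  dens <- apply(pts, 1L, function(x) {
    exp(-dentalarch:::neg_log_dmvnorm(x, fit$mu, fit$sigma))
  })
  integral <- sum(dens) * prod(h * sd3)
  expect_lt(abs(integral - 1), 0.1)
})

test_that("dynamic programming equals exhaustive search for short sequences", {
  # T = 1 reduces to the unary argmin
  ct1 <- random_cost_tables(1L, seed = 1)
  a1 <- optimal_fdi_sequence(ct1)
  expect_equal(a1$labels, ct1$labels[which.min(ct1$unary[1, ])])
  expect_equal(a1$total_cost, min(ct1$unary[1, ]))

  for (tn in 2:4) {
    for (s in 1:30) {
      ct <- random_cost_tables(tn, seed = 1000 * tn + s)
      dp <- optimal_fdi_sequence(ct)
      bf <- brute_force_sequence(ct)
      expect_equal(dp$total_cost, bf$total_cost, tolerance = 1e-10)
      expect_equal(dp$labels, bf$labels)
    }
  }
})

test_that("the DP solution dominates random label sequences", {
  with_seed_t(12, {
    for (s in 1:20) {
      ct <- random_cost_tables(5L, seed = 500 + s)
      dp <- optimal_fdi_sequence(ct)
      for (r in 1:50) {
        states <- sample.int(16L, 5L, replace = TRUE)
        cost <- sum(ct$unary[cbind(1:5, states)]) +
          sum(ct$pairwise[cbind(1:4, states[1:4], states[2:5])])
        expect_gte(cost + 1e-9, dp$total_cost)
      }
    }
  })
})

test_that("DP cost is recomputable from the chosen labels", {
  ct <- random_cost_tables(6L, seed = 77)
  dp <- optimal_fdi_sequence(ct)
  st <- dp$states
  recomputed <- sum(ct$unary[cbind(seq_along(st), st)]) +
    sum(ct$pairwise[cbind(seq_len(5L), st[1:5], st[2:6])])
  expect_equal(dp$total_cost, recomputed, tolerance = 1e-10)
})

test_that("relabeling restores ground truth and fixes neighbour confusions", {
  scan <- fix_scan()
  model <- fix_model()
  truth <- scan_labels(scan)
  pred <- perturb_predictions(scan, noise_config(seed = 3))
  expect_equal(relabel(pred, model)$labels, truth)

  # adversarial: swap the peak logits of two neighbouring teeth
  swapped <- pred
  i <- 5L
  tmp <- swapped$instances[[i]]$logits
  swapped$instances[[i]]$logits <- swapped$instances[[i + 1L]]$logits
  swapped$instances[[i + 1L]]$logits <- tmp
  expect_false(all(argmax_labels(swapped) == truth))
  expect_equal(relabel(swapped, model)$labels, truth)

  # single instance reduces to the arch-restricted argmax
  single <- predicted_instances(
    list(pred$instances[[4]]), nrow(scan$points)
  )
  expect_equal(relabel(single, model)$labels, argmax_labels(single))
})

test_that("relabeling never scores below the per-tooth argmax baseline", {
  model <- fix_model()
  for (s in 1:10) {
    sc <- generate_arch(generator_config(seed = 600 + s))
    pr <- perturb_predictions(sc, noise_config(
      centroid_sigma_mm = 0.5, label_confusion_rate = 0.15, seed = 700 + s
    ))
    truth <- scan_labels(sc)
    acc_dp <- mean(relabel(pr, model)$labels == truth)
    acc_argmax <- mean(argmax_labels(pr) == truth)
    expect_gte(acc_dp, acc_argmax)
  }
})
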