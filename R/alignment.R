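#' Pose parameters
#'
#' The alignment stage describes a scan's orientation by a forward
#' direction (anterior, `(0, -1, 0)` in the standard frame), an up
#' direction (coronal/occlusal, `(0, 0, 1)` in the standard frame) and a
#' translation (mm). Ground-truth poses carry unit, mutually orthogonal
#' directions; predicted poses may violate both, which the losses and
#' [apply_standardization()] tolerate.
#'
#' @param forward,up Numeric length-3 direction vectors.
#' @param translation Numeric length-3 vector (mm), default zero.
#' @return A `pose_params` object.
#' @export
pose_params <- function(forward, up, translation = c(0, 0, 0)) {
  forward <- as.numeric(forward)
  up <- as.numeric(up)
  translation <- as.numeric(translation)
  stopifnot(
    length(forward) == 3L, length(up) == 3L, length(translation) == 3L
  )
  if (sum(forward^2) < 1e-24 || sum(up^2) < 1e-24) {
    stop("pose directions must be nonzero", call. = FALSE)
  }
  structure(
    list(forward = forward, up = up, translation = translation),
    class = "pose_params"
  )
}

#' The canonical standard pose
#'
#' @return [pose_params()] with forward `(0, -1, 0)`, up `(0, 0, 1)` and
#'   zero translation.
#' @export
standard_pose <- function() {
  pose_params(c(0, -1, 0), c(0, 0, 1), c(0, 0, 0))
}

#' Standard-pose transform from dental landmarks
#'
#' Constructs the rigid transform taking a scan into the standard frame
#' using the occlusal plane defined by the two first-molar centroids and
#' the mean centroid of the central incisors: the scan is centred on the
#' origin (vertex mean), the first-molar centroid line is aligned with the
#' x-axis, the occlusal-plane normal on the coronal side is aligned with
#' +z, and the anterior-posterior axis follows y with the anterior side at
#' -y. Upper and lower arches end up oriented the same way.
#'
#' @param scan An [annotated_scan()] containing both first molars (16/26 or
#'   36/46) and both central incisors (11/21 or 31/41).
#' @return A [rigid_transform()] mapping the scan into the standard frame.
#' @export
standard_pose_from_landmarks <- function(scan) {
  stopifnot(inherits(scan, "annotated_scan"))
  lm <- landmark_labels(scan$arch)
  present <- scan_labels(scan)
  if (!all(lm %in% present)) {
    stop(
      "landmark teeth missing: need both first molars and both central ",
      "incisors (", paste(lm, collapse = ", "), ")",
      call. = FALSE
    )
  }
  cent <- scan_tooth_centroids(scan)
  # molar on the patient-right side of the canonical sequence first
  m1 <- cent[as.character(lm[1]), ]
  m2 <- cent[as.character(lm[2]), ]
  ci <- (cent[as.character(lm[3]), ] + cent[as.character(lm[4]), ]) / 2

  normal <- unit3(cross3(m2 - m1, ci - m1))
  # coronal side: crowns lie opposite the gingiva relative to the surface
  tooth_mean <- colMeans(scan$points[scan$vertex_fdi != 0L, , drop = FALSE])
  all_mean <- colMeans(scan$points)
  coronal <- tooth_mean - all_mean
  s <- sum(normal * coronal)
  if (abs(s) < 1e-9) {
    s <- sum(normal * c(0, 0, 1)) # degenerate: no gingiva to disambiguate
  }
  if (s < 0) normal <- -normal

  zax <- normal
  x0 <- m1 - m2
  xax <- unit3(x0 - sum(x0 * zax) * zax)
  yax <- cross3(zax, xax)
  # anterior (incisors) at -y
  if (sum(yax * (ci - (m1 + m2) / 2)) > 0) {
    xax <- -xax
    yax <- -yax
  }
  rot <- rbind(xax, yax, zax)
  dimnames(rot) <- NULL
  rigid_transform(rot, as.numeric(-rot %*% all_mean))
}

#' Rough pose normalization by principal component analysis
#'
#' Rotates the principal axes of a point set (descending variance) onto
#' x, y, z. Axis signs are fixed deterministically: each axis is flipped so
#' the coordinate skewness along it is nonnegative, then the third axis is
#' flipped if needed to make the rotation proper.
#'
#' @param points N x 3 matrix (mm), at least 3 non-collinear points.
#' @return A [rigid_transform()] centring the points and diagonalizing
#'   their covariance.
#' @export
pca_rough_align <- function(points) {
  points <- as_points_matrix(points)
  if (nrow(points) < 3L) {
    stop("need at least 3 points", call. = FALSE)
  }
  ctr <- colMeans(points)
  xc <- sweep(points, 2L, ctr, "-")
  cv <- crossprod(xc) / nrow(xc)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1)) {
    stop("degenerate covariance: points are (near-)collinear", call. = FALSE)
  }
  axes <- eg$vectors # columns, descending variance
  proj <- xc %*% axes
  for (j in 1:3) {
    sk <- mean(proj[, j]^3)
    if (sk < 0) axes[, j] <- -axes[, j]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  rot <- t(axes)
  rigid_transform(rot, as.numeric(-rot %*% ctr))
}

#' Orientation loss between a ground-truth and a predicted pose
#'
#' `2 - cos(f', fhat) - cos(u', uhat) + |cos(fhat, uhat)|`: the two cosine
#' terms pull the predicted forward/up directions toward the truth, the
#' last term penalizes non-orthogonal predictions. Ground-truth directions
#' enter unnormalized (they are unit by precondition); the loss is
#' invariant to positive rescaling of the predictions.
#'
#' @param truth [pose_params()] with unit, mutually orthogonal directions.
#' @param pred [pose_params()] with nonzero directions.
#' @return Nonnegative scalar; 0 iff the predictions are parallel to the
#'   truth and mutually orthogonal.
#' @export
orient_loss <- function(truth, pred) {
  stopifnot(inherits(truth, "pose_params"), inherits(pred, "pose_params"))
  if (abs(sum(truth$forward^2) - 1) > 1e-6 ||
    abs(sum(truth$up^2) - 1) > 1e-6 ||
    abs(sum(truth$forward * truth$up)) > 1e-6) {
    stop("ground-truth directions must be unit and orthogonal", call. = FALSE)
  }
  nf <- sqrt(sum(pred$forward^2))
  nu <- sqrt(sum(pred$up^2))
  if (nf < 1e-12 || nu < 1e-12) {
    stop("predicted directions must be nonzero", call. = FALSE)
  }
  2 -
    sum(truth$forward * pred$forward) / nf -
    sum(truth$up * pred$up) / nu +
    abs(sum(pred$forward * pred$up)) / (nf * nu)
}

# Smooth-L1 (Huber, beta = 1), elementwise, mean reduction.
smooth_l1 <- function(truth, pred, beta = 1) {
  d <- abs(as.numeric(truth) - as.numeric(pred))
  mean(ifelse(d < beta, 0.5 * d^2 / beta, d - 0.5 * beta))
}

# Binary cross-entropy, mean over elements, scores clamped at eps.
bce_loss <- function(truth, scores, eps = 1e-7) {
  s <- pmin(pmax(as.numeric(scores), eps), 1 - eps)
  y <- as.numeric(truth)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

# Soft-Dice loss with additive smoothing.
dice_loss <- function(truth, scores, smooth = 1e-6) {
  y <- as.numeric(truth)
  s <- as.numeric(scores)
  1 - (2 * sum(y * s) + smooth) / (sum(y) + sum(s) + smooth)
}

#' Full alignment loss
#'
#' `L_align = L_orient + SmoothL1(c', chat) + BCE(s', shat) + Dice(s', shat)`
#' combining the orientation loss, a smooth-L1 translation loss (beta = 1,
#' mean over the 3 coordinates), and binary cross-entropy plus soft-Dice
#' loss on the auxiliary point-level tooth/background segmentation.
#'
#' @param truth,pred [pose_params()] (truth orthonormal).
#' @param seg_truth Per-vertex ground-truth tooth indicator in \{0, 1\}.
#' @param seg_pred Per-vertex predicted tooth score in \[0, 1\] (clamped at
#'   1e-7 for the BCE term).
#' @return List with `total` and the per-term breakdown `orient`,
#'   `smooth_l1`, `bce`, `dice`.
#' @export
align_loss <- function(truth, pred, seg_truth, seg_pred) {
  if (length(seg_truth) != length(seg_pred)) {
    stop("segmentation vectors must have equal length", call. = FALSE)
  }
  lo <- orient_loss(truth, pred)
  l1 <- smooth_l1(truth$translation, pred$translation)
  lb <- bce_loss(seg_truth, seg_pred)
  ld <- dice_loss(seg_truth, seg_pred)
  list(total = lo + l1 + lb + ld, orient = lo, smooth_l1 = l1, bce = lb,
    dice = ld)
}

#' Standardize a point set from predicted pose parameters
#'
#' Applies the predicted translation in reverse, orthogonalizes the forward
#' direction against the up direction (Gram-Schmidt, up kept), completes a
#' right-handed orthonormal basis with the left-right axis
#' `cross(forward, up)`, and rotates the points so forward maps to
#' `(0, -1, 0)` and up to `(0, 0, 1)`.
#'
#' @param points N x 3 matrix (mm).
#' @param pred [pose_params()]; forward and up must not be parallel.
#' @return The standardized N x 3 point matrix.
#' @export
apply_standardization <- function(points, pred) {
  stopifnot(inherits(pred, "pose_params"))
  points <- as_points_matrix(points)
  u <- unit3(pred$up)
  f0 <- pred$forward
  f <- f0 - sum(f0 * u) * u
  if (sqrt(sum(f^2)) < 1e-9 * sqrt(sum(f0^2))) {
    stop("forward and up directions are (near-)parallel", call. = FALSE)
  }
  f <- unit3(f)
  r <- cross3(f, u)
  w <- cbind(r, f, u) # orthonormal, det = +1
  s <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1)) # standard-frame images
  rot <- s %*% t(w)
  shifted <- sweep(points, 2L, pred$translation, "-")
  shifted %*% t(rot)
}
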