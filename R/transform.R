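#' Rigid transforms in 3D
#'
#' Minimal proper rigid motion container used by the pose-standardization and
#' crop modules: `p' = R p + t` with `R` a 3x3 rotation (det = +1) and `t` a
#' translation in mm.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3 vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det = +1)", call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = translation),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to a point matrix
#'
#' @param points N x 3 numeric matrix (mm).
#' @param transform A [rigid_transform()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  points <- as_points_matrix(points)
  sweep(points %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Compose two rigid transforms (`first` applied before `second`)
#'
#' @param first,second [rigid_transform()] objects.
#' @return Their composition as a `rigid_transform`.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(
    second$rotation %*% first$rotation,
    as.numeric(second$rotation %*% first$translation) + second$translation
  )
}

#' Uniform random rotation
#'
#' Samples a rotation uniformly over SO(3) via a normalized Gaussian
#' quaternion.
#'
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [rigid_transform()] with zero translation.
#' @export
random_rotation <- function(seed = NULL) {
  q <- with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
  rigid_transform(rot, c(0, 0, 0))
}

# --- internal helpers -------------------------------------------------------

# Coerce to an N x 3 double matrix; accepts vectors of length 3.
as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    points <- matrix(as.numeric(points), ncol = 3L, byrow = TRUE)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop("points must be an N x 3 matrix", call. = FALSE)
  }
  storage.mode(points) <- "double"
  points
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
# seed = NULL evaluates under the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    stop("zero-length direction vector", call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}
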