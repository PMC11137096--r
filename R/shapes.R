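#' Coerce and validate a shape
#'
#' A *shape* is an ordered set of P corresponding 3-D points, stored as a
#' numeric P x 3 matrix in millimetres. Correspondence across a family is by
#' row index: row i of every shape is the same anatomical point.
#'
#' @param x numeric P x 3 matrix (or something coercible to one).
#' @return a validated P x 3 numeric matrix.
#' @export
as_shape <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L)
    stop("a shape must have 3 columns (x, y, z), got ", ncol(x))
  if (nrow(x) < 1L)
    stop("a shape must contain at least one point")
  if (!all(is.finite(x)))
    stop("shape coordinates must all be finite")
  dimnames(x) <- NULL
  x
}

#' Flatten a shape to a 3P-vector / restore it
#'
#' Column-major layout: all x coordinates, then all y, then all z. All model
#' vectors (means, modes, deformation fields) use this layout.
#'
#' @param x P x 3 matrix.
#' @return `shape_to_vector`: numeric vector of length 3P.
#' @export
shape_to_vector <- function(x) as.vector(as_shape(x))

#' @rdname shape_to_vector
#' @param v numeric 3P-vector.
#' @return `vector_to_shape`: P x 3 matrix.
#' @export
vector_to_shape <- function(v) {
  if (length(v) %% 3L != 0L) stop("length of v must be a multiple of 3")
  matrix(v, ncol = 3L)
}

#' Construct a triangulated surface
#'
#' @param points P x 3 matrix of vertex coordinates (mm).
#' @param faces T x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `tri_surface` with elements `points` and
#'   `faces`.
#' @export
tri_surface <- function(points, faces) {
  points <- as_shape(points)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L) stop("a surface needs at least one face")
  if (any(faces < 1L) || any(faces > nrow(points)))
    stop("face indices out of range [1, ", nrow(points), "]")
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  if (any(degen))
    stop("degenerate faces (repeated vertex) at rows: ",
         paste(which(degen), collapse = ", "))
  structure(list(points = points, faces = faces), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("tri_surface:", nrow(x$points), "points,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Elementary rotation matrices (degrees)
#'
#' @param deg angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate a synthetic planted-mode shape family
#'
#' Draws `n` corresponding shapes from a low-rank linear model
#' `mean + sum_j sqrt(var_j) z_ij mode_j + noise`, with `z ~ N(0,1)` and
#' isotropic Gaussian noise of standard deviation `noise_sd` per coordinate.
#' The planted mean, modes and variances are attached as attributes so tests
#' can check parameter recovery. Optional rigid nuisance transforms (rotations
#' uniform within +/-30 degrees per axis plus translations) emulate the pose
#' variation removed by generalized Procrustes alignment.
#'
#' Mode vectors are drawn once (orthonormalized Gaussian directions in 3P
#' space) unless supplied. With `noise_sd = 0` the family covariance has
#' exactly `k` nonzero eigenvalues.
#'
#' @param P number of points per shape.
#' @param n number of shapes (must exceed `k + 1`).
#' @param variances planted mode variances, positive and descending; its
#'   length is the planted rank k.
#' @param noise_sd isotropic noise standard deviation (mm).
#' @param seed integer seed; the family is a deterministic function of it.
#' @param base_shape optional P x 3 mean shape; default is a smooth open
#'   curve-like point cloud spanning ~100 mm.
#' @param modes optional 3P x k matrix of orthonormal planted modes.
#' @param rigid_nuisance if TRUE, each shape is additionally rotated
#'   (uniform within +/-30 degrees per axis) and translated (+/-20 mm).
#' @return list of n shapes (P x 3 matrices) with attributes
#'   `planted_mean`, `planted_modes`, `planted_variances`, `scores`.
#' @export
make_fixture_family <- function(P, n, variances, noise_sd = 0, seed = 1,
                                base_shape = NULL, modes = NULL,
                                rigid_nuisance = FALSE) {
  k <- length(variances)
  if (k >= n - 1L)
    stop("planted rank k = ", k, " must be < n - 1 = ", n - 1L,
         " for the rank to be recoverable")
  if (any(variances <= 0)) stop("variances must be positive")
  if (is.unsorted(rev(variances))) stop("variances must be descending")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(base_shape)) {
    t <- seq(0, 1, length.out = P)
    base_shape <- cbind(10 * sin(2 * pi * t), 15 * cos(3 * pi * t), 100 * t)
  }
  base_shape <- as_shape(base_shape)
  if (nrow(base_shape) != P) stop("base_shape must have P rows")
  if (is.null(modes)) {
    M <- matrix(rnorm(3 * P * k), 3 * P, k)
    modes <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
  } else {
    modes <- as.matrix(modes)
    if (nrow(modes) != 3 * P || ncol(modes) != k)
      stop("modes must be 3P x k")
  }
  mu <- shape_to_vector(base_shape)
  z <- matrix(rnorm(n * k), n, k)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    v <- mu + modes %*% (sqrt(variances) * z[i, ])
    if (noise_sd > 0) v <- v + rnorm(3 * P, sd = noise_sd)
    sh <- vector_to_shape(v)
    if (rigid_nuisance) {
      R <- rotation_x(runif(1, -30, 30)) %*%
        rotation_y(runif(1, -30, 30)) %*% rotation_z(runif(1, -30, 30))
      sh <- sh %*% t(R) + matrix(runif(3, -20, 20), P, 3, byrow = TRUE)
    }
    shapes[[i]] <- sh
  }
  attr(shapes, "planted_mean") <- base_shape
  attr(shapes, "planted_modes") <- modes
  attr(shapes, "planted_variances") <- variances
  attr(shapes, "scores") <- z
  shapes
}

# Save/restore .Random.seed so fixture generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
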