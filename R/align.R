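#' Optimal rigid alignment of two corresponding point sets
#'
#' Solves `argmin_{R,t} sum_i || R y_i + t - x_i ||^2` over proper rotations
#' (no scaling, no reflection) via the SVD of the cross-covariance with sign
#' correction so `det(R) = +1`. Optionally a similarity transform (uniform
#' scale) can be requested; rigid is the default, matching the alignment used
#' for pose removal in shape families.
#'
#' @param X target shape, P x 3 matrix.
#' @param Y source shape, P x 3 matrix (same P, corresponding rows).
#' @param allow_scale if TRUE also estimate a uniform scale factor.
#' @param weights optional non-negative per-point weights.
#' @return list of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `scale`, and `rmsd` after alignment (mm).
#' @export
procrustes_pair <- function(X, Y, allow_scale = FALSE, weights = NULL) {
  X <- as_shape(X); Y <- as_shape(Y)
  if (nrow(X) != nrow(Y)) stop("point counts differ")
  if (nrow(X) < 3) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("all weights zero")
  mx <- colSums(X * w) / sw
  my <- colSums(Y * w) / sw
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  A <- t(Xc * w) %*% Yc
  sv <- svd(A)
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300) && sum(sv$d > 1e-12 * max(sv$d)) < 2)
    stop("degenerate (collinear or coincident) point configuration")
  C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% C %*% t(sv$v)
  s <- 1
  if (allow_scale) {
    s <- sum(diag(C) * sv$d) / sum(w * rowSums(Yc^2))
  }
  t <- mx - s * as.vector(R %*% my)
  res <- sweep(s * Y %*% t(R), 2, t, "+") - X
  structure(list(rotation = R, translation = t, scale = s,
                 rmsd = sqrt(sum(w * rowSums(res^2)) / sw)),
            class = "rigid_transform")
}

#' Apply a rigid (or similarity) transform to points
#'
#' @param points P x 3 matrix.
#' @param tf a `rigid_transform` from [procrustes_pair()].
#' @return transformed P x 3 matrix.
#' @export
apply_rigid <- function(points, tf) {
  sweep(tf$scale * as.matrix(points) %*% t(tf$rotation), 2,
        tf$translation, "+")
}

#' Root-mean-square distance between two corresponding shapes
#' @param X,Y P x 3 matrices.
#' @return RMS of per-point Euclidean distances (mm).
#' @export
shape_rmsd <- function(X, Y) sqrt(mean(rowSums((as.matrix(X) - as.matrix(Y))^2)))

#' Procrustes distance (RMSD after optimal rigid alignment)
#' @param X,Y P x 3 matrices.
#' @export
procrustes_distance <- function(X, Y) procrustes_pair(X, Y)$rmsd

#' Generalized Procrustes Alignment of a shape family
#'
#' Iteratively aligns every shape rigidly to a reference and recomputes the
#' mean until the mean stops moving. The iteration-0 reference is the first
#' shape in input order (an arbitrary choice); thereafter the reference is
#' the current mean, re-centred at the origin each iteration to fix the
#' translational gauge.
#'
#' @param shapes list of P x 3 matrices with corresponding rows.
#' @param tol convergence tolerance on the RMS movement of the mean (mm).
#' @param max_iter maximum number of iterations.
#' @return list: `aligned` (list of aligned shapes), `mean` (P x 3),
#'   `iterations`, `converged`.
#' @export
gpa <- function(shapes, tol = 1e-6, max_iter = 100) {
  if (length(shapes) < 2) stop("need at least 2 shapes")
  shapes <- lapply(shapes, as_shape)
  P <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, 1L) == P))
    stop("all shapes must have the same point count")
  ref <- sweep(shapes[[1]], 2, colMeans(shapes[[1]]))
  aligned <- shapes
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    aligned <- lapply(shapes, function(sh) apply_rigid(sh, procrustes_pair(ref, sh)))
    newmean <- Reduce(`+`, aligned) / length(aligned)
    newmean <- sweep(newmean, 2, colMeans(newmean))
    if (shape_rmsd(newmean, ref) < tol) {
      ref <- newmean
      converged <- TRUE
      break
    }
    ref <- newmean
  }
  if (!converged)
    warning("GPA did not converge within ", max_iter, " iterations")
  list(aligned = aligned, mean = ref, iterations = it, converged = converged)
}

#' Nearest-neighbour indices between point sets
#'
#' For each query point, the index of the closest reference point
#' (Euclidean). Ties are broken to the lowest reference index. Computation is
#' blocked dense distance evaluation, contractually identical to an
#' exhaustive scan.
#'
#' @param query Q x 3 matrix.
#' @param ref N x 3 matrix.
#' @param block query rows processed per distance block.
#' @return list: `index` (length Q), `distance` (length Q, mm).
#' @export
nearest_neighbor <- function(query, ref, block = 2048L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  nq <- nrow(query)
  r2 <- rowSums(ref^2)
  idx <- integer(nq); dst <- numeric(nq)
  for (s in seq(1L, nq, by = block)) {
    e <- min(s + block - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), r2, "+") - 2 * q %*% t(ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, distance = dst)
}

#' Iterative Closest Point correspondence
#'
#' Alternates nearest-neighbour assignment and rigid Procrustes alignment of
#' the source onto its assigned targets until the assignment is fixed or
#' `max_iter` is reached. The returned map is the nearest-neighbour map under
#' the final transform.
#'
#' @param source P x 3 matrix (moved set).
#' @param target N x 3 matrix (fixed set).
#' @param max_iter maximum alternations.
#' @return list: `transform` (a `rigid_transform`), `map` with `index` and
#'   `distance` per source point, `iterations`, `converged`.
#' @export
icp_correspondence <- function(source, target, max_iter = 50) {
  source <- as_shape(source); target <- as_shape(target)
  tf <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                       scale = 1, rmsd = NA_real_),
                  class = "rigid_transform")
  cur <- source
  prev_idx <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    nn <- nearest_neighbor(cur, target)
    if (!is.null(prev_idx) && identical(nn$index, prev_idx)) {
      converged <- TRUE
      break
    }
    prev_idx <- nn$index
    tf <- procrustes_pair(target[nn$index, , drop = FALSE], source)
    cur <- apply_rigid(source, tf)
  }
  nn <- nearest_neighbor(cur, target)
  list(transform = tf, map = nn, iterations = it, converged = converged)
}
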