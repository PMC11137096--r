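#' Mean shape of an aligned family
#'
#' Arithmetic per-coordinate mean of the family.
#'
#' @param shapes list of aligned P x 3 matrices.
#' @return P x 3 matrix.
#' @export
compute_mean_shape <- function(shapes) {
  if (!length(shapes)) stop("empty shape list")
  shapes <- lapply(shapes, as_shape)
  Reduce(`+`, shapes) / length(shapes)
}

# n x 3P matrix of flattened shapes
.shape_matrix <- function(shapes) {
  t(vapply(shapes, shape_to_vector, numeric(3 * nrow(shapes[[1]]))))
}

#' Shape covariance in dual (Gram) form
#'
#' The sample covariance `(1/(n-1)) sum (X_i - mu)(X_i - mu)^T` of flattened
#' shapes is realized through its n x n dual: with D the n x 3P matrix of
#' deviations, the Gram matrix `D D^T / (n-1)` has the same nonzero spectrum
#' as the full 3P x 3P covariance, which is intractable to form when 3P is
#' large. The trace equals the total variance.
#'
#' @param shapes list of aligned P x 3 matrices, n >= 2.
#' @return list: `gram` (n x n), `deviations` (n x 3P), `mean` (3P vector),
#'   `trace` (total variance, mm^2).
#' @export
compute_covariance <- function(shapes) {
  n <- length(shapes)
  if (n < 2) stop("need at least 2 shapes")
  Xm <- .shape_matrix(shapes)
  mu <- colMeans(Xm)
  D <- sweep(Xm, 2, mu)
  G <- D %*% t(D) / (n - 1)
  list(gram = G, deviations = D, mean = mu, trace = sum(diag(G)))
}

#' Fit a PCA statistical shape model
#'
#' Principal modes are obtained from the eigendecomposition of the dual Gram
#' matrix and lifted to 3P space (mathematically identical to decomposing the
#' dense covariance, tractable when 3P >> n). Eigenvalues are the variances
#' along each mode, sorted descending; mode columns are orthonormal.
#'
#' @param shapes list of aligned, corresponding P x 3 matrices.
#' @param n_modes number of retained modes m, at most n - 1.
#' @return object of class `shape_model`: `mean` (3P), `modes` (3P x m,
#'   orthonormal columns), `eigenvalues` (m, descending), `n_train`,
#'   `total_variance`, `point_count`.
#' @export
fit_shape_model <- function(shapes, n_modes) {
  n <- length(shapes)
  if (n_modes > n - 1)
    stop("n_modes = ", n_modes, " exceeds n - 1 = ", n - 1)
  if (n_modes < 1) stop("n_modes must be >= 1")
  cv <- compute_covariance(shapes)
  eg <- eigen(cv$gram, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  m <- n_modes
  modes <- matrix(0, ncol(cv$deviations), m)
  for (j in seq_len(m)) {
    u <- as.vector(t(cv$deviations) %*% eg$vectors[, j])
    nu <- sqrt(sum(u^2))
    modes[, j] <- if (nu > 0) u / nu else 0
  }
  structure(list(mean = cv$mean, modes = modes,
                 eigenvalues = lam[seq_len(m)], n_train = n,
                 total_variance = cv$trace,
                 point_count = nrow(shapes[[1]])),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("shape_model:", x$point_count, "points,", length(x$eigenvalues),
      "modes fitted on", x$n_train, "shapes\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n  total variance:", signif(x$total_variance, 6), "mm^2\n")
  invisible(x)
}

#' Generate a shape from mode weights
#'
#' `shape = mean + sum_i sqrt(d_i) * phi_i * w_i`, where `w_i` are
#' standard-deviation multiples along each mode.
#'
#' @param model a [fit_shape_model()] result.
#' @param w numeric vector of SD weights, one per retained mode.
#' @return P x 3 matrix.
#' @export
sample_shape <- function(model, w) {
  m <- length(model$eigenvalues)
  if (length(w) != m)
    stop("w has length ", length(w), ", model has ", m, " modes")
  v <- model$mean + as.vector(model$modes %*% (sqrt(model$eigenvalues) * w))
  vector_to_shape(v)
}

#' Project a shape onto a model's mode weights
#'
#' Inverse of [sample_shape()] for shapes in the model span:
#' `w_i = phi_i^T (x - mean) / sqrt(d_i)`.
#'
#' @param model a `shape_model`.
#' @param shape P x 3 matrix.
#' @return numeric vector of SD weights.
#' @export
project_shape <- function(model, shape) {
  d <- shape_to_vector(shape) - model$mean
  raw <- as.vector(t(model$modes) %*% d)
  sd <- sqrt(model$eigenvalues)
  ifelse(sd > 0, raw / sd, 0)
}

#' Compactness: cumulative variance fraction of the first m modes
#'
#' @param model a `shape_model` (fit with at least `m` modes).
#' @param m number of leading modes.
#' @return fraction in `[0, 1]` of total variance captured.
#' @export
compactness <- function(model, m) {
  if (m <= 0) stop("m must be positive")
  if (m > length(model$eigenvalues))
    stop("m exceeds the ", length(model$eigenvalues), " retained modes")
  sum(model$eigenvalues[seq_len(m)]) / model$total_variance
}

# RMS or mean per-point distance between corresponding shapes
.reconstruction_error <- function(X, Y, metric = c("rmse", "mean")) {
  metric <- match.arg(metric)
  d <- sqrt(rowSums((X - Y)^2))
  if (metric == "rmse") sqrt(mean(d^2)) else mean(d)
}

#' Generalization: leave-one-out reconstruction error
#'
#' Each shape in turn is excluded, a model with `n_modes` modes is fitted on
#' the rest, and the excluded shape is reconstructed as
#' `mean + modes modes^T (x - mean)`. The per-fold error is the
#' root-mean-square (or mean) per-point distance between the shape and its
#' reconstruction.
#'
#' @param shapes list of aligned P x 3 matrices, n >= 3.
#' @param n_modes modes m, at most n - 2.
#' @param metric `"rmse"` (default) or `"mean"` per-point distance.
#' @param n_train optional number of randomly selected training shapes per
#'   fold (learning-curve variant); default all remaining shapes.
#' @param seed seed for the learning-curve subsampling.
#' @return list: `mean` and `sd` of the fold errors (mm), `per_fold`.
#' @export
generalization_loo <- function(shapes, n_modes, metric = "rmse",
                               n_train = NULL, seed = 1) {
  n <- length(shapes)
  if (n < 3) stop("need at least 3 shapes")
  if (n_modes > n - 2)
    stop("n_modes must be <= n - 2 for leave-one-out")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  errs <- vapply(seq_len(n), function(i) {
    rest <- shapes[-i]
    if (!is.null(n_train)) {
      if (n_train < n_modes + 1 || n_train > length(rest))
        stop("n_train out of range")
      rest <- rest[sample.int(length(rest), n_train)]
    }
    mod <- fit_shape_model(rest, n_modes)
    x <- shape_to_vector(shapes[[i]]) - mod$mean
    rec <- mod$mean + as.vector(mod$modes %*% (t(mod$modes) %*% x))
    .reconstruction_error(vector_to_shape(rec), shapes[[i]], metric)
  }, numeric(1))
  list(mean = mean(errs), sd = stats::sd(errs), per_fold = errs)
}

#' Specificity: realism of randomly generated shapes
#'
#' Draws `N` weight vectors with each component standard normal truncated to
#' `[-3, 3]`, generates the corresponding shapes, and measures each one's
#' distance (RMSE or mean per-point) to its most similar training shape.
#'
#' @param model a `shape_model`.
#' @param training list of aligned training shapes.
#' @param N number of random samples (default 1000).
#' @param seed integer seed.
#' @param metric `"rmse"` or `"mean"`.
#' @return list: `mean`, `sd` (mm), `per_sample`.
#' @export
specificity <- function(model, training, N = 1000, seed = 1,
                        metric = "rmse") {
  if (!length(training)) stop("empty training set")
  if (N < 1) stop("N must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- length(model$eigenvalues)
  lo <- stats::pnorm(-3); hi <- stats::pnorm(3)
  tr <- lapply(training, as_shape)
  per <- vapply(seq_len(N), function(i) {
    w <- stats::qnorm(stats::runif(m, lo, hi))
    g <- sample_shape(model, w)
    min(vapply(tr, function(s) .reconstruction_error(g, s, metric),
               numeric(1)))
  }, numeric(1))
  list(mean = mean(per), sd = stats::sd(per), per_sample = per)
}

#' Define a cohort sampling grid
#'
#' The virtual-cohort convention: the first `n_modes` principal modes are
#' swept over a fixed list of SD levels (default -3..3 in unit steps, seven
#' levels), enumerated in odometer order with the first mode slowest.
#'
#' @param n_modes number of swept modes (default 5).
#' @param levels ordered SD levels (default `-3:3`).
#' @return object of class `cohort_grid` with `n_modes`, `levels`, `size`.
#' @export
cohort_grid <- function(n_modes = 5, levels = -3:3) {
  structure(list(n_modes = as.integer(n_modes), levels = as.numeric(levels),
                 size = length(levels)^n_modes),
            class = "cohort_grid")
}

#' Mode weights for one cohort member
#'
#' Maps a 1-based model ID to its SD weight vector under the odometer
#' convention (first mode is the most significant digit).
#'
#' @param grid a [cohort_grid()].
#' @param model_id integer in `[1, grid$size]` (vectorized).
#' @return matrix with one row per ID and `n_modes` columns.
#' @export
cohort_weights <- function(grid, model_id) {
  L <- length(grid$levels)
  m <- grid$n_modes
  if (any(model_id < 1 | model_id > grid$size))
    stop("model_id out of range [1, ", grid$size, "]")
  id0 <- as.numeric(model_id) - 1
  W <- matrix(0, length(model_id), m)
  for (j in seq_len(m)) {
    digit <- (id0 %/% L^(m - j)) %% L
    W[, j] <- grid$levels[digit + 1]
  }
  W
}

#' Enumerate the virtual cohort of a shape model
#'
#' Yields the full SD-level grid over the leading modes in odometer order.
#' By default only the weight table is materialized; pass a callback to
#' receive each generated shape (memory-friendly for large grids).
#'
#' @param model a `shape_model`.
#' @param grid a [cohort_grid()]; `grid$n_modes` must not exceed the model's
#'   retained modes.
#' @param callback optional `function(model_id, w, shape)` called per member.
#' @return data.frame with `model_id` and weight columns `w1..wm`
#'   (invisibly if a callback is given).
#' @export
enumerate_cohort <- function(model, grid, callback = NULL) {
  if (grid$n_modes > length(model$eigenvalues))
    stop("grid sweeps more modes than the model retains")
  ids <- seq_len(grid$size)
  W <- cohort_weights(grid, ids)
  df <- data.frame(model_id = ids, W)
  names(df) <- c("model_id", paste0("w", seq_len(grid$n_modes)))
  if (!is.null(callback)) {
    mfull <- length(model$eigenvalues)
    for (i in ids) {
      w <- c(W[i, ], rep(0, mfull - grid$n_modes))
      callback(i, W[i, ], sample_shape(model, w))
    }
    return(invisible(df))
  }
  df
}
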