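test_that("mean and covariance match direct summation oracles", {
  set.seed(1)
  shapes <- lapply(1:7, function(i) matrix(rnorm(15), 5, 3))
  mu <- compute_mean_shape(shapes)
  expect_equal(mu, Reduce(`+`, shapes) / 7)
  expect_equal(compute_mean_shape(shapes[c(1, 1, 1)]), shapes[[1]])
  expect_equal(compute_mean_shape(shapes[1:2]),
               (shapes[[1]] + shapes[[2]]) / 2)
  # trace equals the dense 3P x 3P covariance trace
  cv <- compute_covariance(shapes)
  X <- t(sapply(shapes, as.vector))
  dense <- stats::cov(X)
  expect_equal(cv$trace, sum(diag(dense)), tolerance = 1e-10)
  # identical shapes: zero operator
  cv0 <- compute_covariance(shapes[c(2, 2, 2)])
  expect_equal(cv0$trace, 0, tolerance = 1e-20)
  # n = 2 closed form: single eigenvalue |v|^2 / 2
  v <- rnorm(15)
  cv2 <- compute_covariance(list(shapes[[1]],
                                 shapes[[1]] + matrix(v, 5, 3)))
  expect_equal(cv2$trace, sum(v^2) / 2)
  expect_error(compute_covariance(shapes[1]), "at least 2")
})

test_that("dual-form PCA equals the dense covariance decomposition", {
  set.seed(2)
  shapes <- lapply(1:12, function(i) matrix(rnorm(60), 20, 3))
  m <- fit_shape_model(shapes, 8)
  X <- t(sapply(shapes, as.vector))
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(m$eigenvalues, eg$values[1:8], tolerance = 1e-8)
  # same subspace (principal angles ~ 0), orthonormal columns
  sv <- svd(t(eg$vectors[, 1:8]) %*% m$modes)$d
  expect_equal(sv, rep(1, 8), tolerance = 1e-8)
  expect_equal(crossprod(m$modes), diag(8), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  # eigenvalue sum = trace of covariance (PCA identity at full rank)
  m_full <- fit_shape_model(shapes, 11)
  expect_equal(sum(m_full$eigenvalues), m_full$total_variance,
               tolerance = 1e-8)
  expect_error(fit_shape_model(shapes, 12), "n - 1")
})

test_that("single-direction family yields its direction and variance", {
  set.seed(3)
  u <- rnorm(30); u <- u / sqrt(sum(u^2))
  base <- matrix(rnorm(30), 10, 3)
  z <- rnorm(20, sd = 2)
  shapes <- lapply(z, function(s) base + matrix(s * u, 10, 3))
  m <- fit_shape_model(shapes, 1)
  expect_equal(m$eigenvalues[1], stats::var(z), tolerance = 1e-8)
  expect_equal(abs(sum(m$modes[, 1] * u)), 1, tolerance = 1e-8)
})

test_that("planted modes are recovered at Monte-Carlo scale", {
  fam <- make_fixture_family(P = 30, n = 200, variances = c(9, 4, 1),
                             noise_sd = 0, seed = 11)
  m <- fit_shape_model(fam, 3)
  expect_true(all(abs(m$eigenvalues - c(9, 4, 1)) / c(9, 4, 1) < 0.15))
  sv <- svd(t(attr(fam, "planted_modes")) %*% m$modes)$d
  expect_lt(acos(min(pmin(sv, 1))), 1e-6)   # subspace angle -> 0, noise-free
})

test_that("sample_shape and project_shape are mutually inverse and linear", {
  fam <- make_fixture_family(P = 15, n = 12, variances = c(4, 1),
                             noise_sd = 0.1, seed = 4)
  m <- fit_shape_model(fam, 2)
  expect_equal(sample_shape(m, c(0, 0)), vector_to_shape(m$mean))
  s1 <- sample_shape(m, c(1, 0))
  expect_equal(shape_to_vector(s1),
               m$mean + sqrt(m$eigenvalues[1]) * m$modes[, 1])
  w <- c(1.3, -2.1)
  expect_equal(project_shape(m, sample_shape(m, w)), w, tolerance = 1e-10)
  # superposition
  a <- sample_shape(m, c(1, 0.5)); b <- sample_shape(m, c(-2, 1))
  ab <- sample_shape(m, c(-1, 1.5))
  expect_equal(a + b - vector_to_shape(m$mean), ab, tolerance = 1e-10)
  expect_error(sample_shape(m, c(1, 2, 3)), "length")
})

test_that("compactness follows the eigenvalue arithmetic", {
  m <- structure(list(eigenvalues = c(4, 3, 2, 1), total_variance = 10,
                      mean = numeric(3), modes = diag(4)[, 1:4],
                      n_train = 5, point_count = 1),
                 class = "shape_model")
  expect_equal(compactness(m, 2), 0.7)
  expect_error(compactness(m, 0), "positive")
  # noise-free planted family at full rank -> 1; non-decreasing in m
  fam <- make_fixture_family(P = 20, n = 10, variances = c(4, 2, 1),
                             noise_sd = 0, seed = 6)
  mf <- fit_shape_model(fam, 9)
  cc <- sapply(1:9, compactness, model = mf)
  expect_true(all(diff(cc) >= -1e-12))
  expect_equal(cc[9], 1, tolerance = 1e-8)
  expect_equal(cc[3], 1, tolerance = 1e-8)   # rank 3 planted
})

test_that("generalization matches the planted noise scale", {
  # a shape in the span of the others reconstructs exactly
  fam0 <- make_fixture_family(P = 15, n = 10, variances = c(4, 1),
                              noise_sd = 0, seed = 7)
  g0 <- generalization_loo(fam0, 2)
  expect_lt(g0$mean, 1e-8)
  # with per-coordinate noise sigma, the left-out residual keeps the noise
  # component orthogonal to the m-dimensional mode subspace; the per-point
  # Euclidean RMSE is therefore ~ sigma * sqrt(3 (3P - m) / (3P))
  sigma <- 0.3
  P <- 25; n <- 40; m <- 3
  fam <- make_fixture_family(P = P, n = n, variances = c(9, 4, 1),
                             noise_sd = sigma, seed = 8)
  g <- generalization_loo(fam, m)
  expected <- sigma * sqrt(3 * (3 * P - m) / (3 * P))
  expect_gt(g$mean, 0.8 * expected)
  expect_lt(g$mean, 1.2 * expected)
  # non-increasing in m on a noise-free planted family
  fam2 <- make_fixture_family(P = 15, n = 12, variances = c(4, 2, 1),
                              noise_sd = 0, seed = 9)
  errs <- sapply(1:3, function(m) generalization_loo(fam2, m)$mean)
  expect_true(all(diff(errs) <= 1e-10))
  expect_error(generalization_loo(fam2, 11), "n - 2")
})

test_that("specificity measures distance to the nearest training shape", {
  fam <- make_fixture_family(P = 10, n = 8, variances = c(1, 0.5),
                             noise_sd = 0.05, seed = 10)
  m <- fit_shape_model(fam, 2)
  # degenerate model: all samples equal the mean
  md <- m; md$eigenvalues <- c(0, 0)
  sp <- specificity(md, fam, N = 5, seed = 1)
  mean_shape <- vector_to_shape(m$mean)
  nearest <- min(sapply(fam, function(s) sqrt(mean(rowSums((mean_shape - s)^2)))))
  expect_equal(sp$mean, nearest, tolerance = 1e-10)
  expect_equal(sp$sd, 0)
  # dense sampling of a 1-mode family bounds specificity by grid spacing
  u <- rnorm(30); u <- u / sqrt(sum(u^2))
  base <- matrix(0, 10, 3)
  grid_z <- seq(-3, 3, by = 0.05)
  training <- lapply(grid_z, function(s) base + matrix(s * u, 10, 3))
  m1 <- fit_shape_model(training, 1)
  sp1 <- specificity(m1, training, N = 200, seed = 2)
  spacing <- 0.05 * sqrt(m1$eigenvalues[1]) / sqrt(10)
  expect_lt(sp1$mean, spacing)
  expect_identical(specificity(m1, training, N = 50, seed = 3)$per_sample,
                   specificity(m1, training, N = 50, seed = 3)$per_sample)
})

test_that("cohort enumeration follows the odometer convention", {
  g <- cohort_grid(1, -3:3)
  fam <- make_fixture_family(P = 6, n = 8, variances = c(1, 0.5),
                             noise_sd = 0, seed = 12)
  m <- fit_shape_model(fam, 2)
  df <- enumerate_cohort(m, g)
  expect_equal(nrow(df), 7)
  expect_equal(df$w1, -3:3)
  g0 <- cohort_grid(2, 0)
  df0 <- enumerate_cohort(m, g0)
  expect_equal(nrow(df0), 1)
  shapes <- list()
  enumerate_cohort(m, g0, function(id, w, s) shapes[[id]] <<- s)
  expect_equal(shapes[[1]], vector_to_shape(m$mean))
  # first mode slowest
  g2 <- cohort_grid(2, c(-3, 3))
  W <- cohort_weights(g2, 1:4)
  expect_equal(W, rbind(c(-3, -3), c(-3, 3), c(3, -3), c(3, 3)))
  expect_equal(cohort_grid(5, -3:3)$size, 16807)
  expect_error(enumerate_cohort(m, cohort_grid(5, -3:3)), "more modes")
})
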