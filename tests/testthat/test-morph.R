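test_that("gmm_density matches the closed form and brute-force summation", {
  st <- gmm_state(matrix(0, 1, 3), sigma2 = 1)
  expect_equal(gmm_density(c(0, 0, 0), st), (2 * pi)^(-3 / 2))
  # two equal components, point equidistant: twice the single-component value
  st2 <- gmm_state(rbind(c(-1, 0, 0), c(1, 0, 0)), sigma2 = 0.5)
  single <- 0.5 * exp(-1 / (2 * 0.5)) / (2 * pi * 0.5)^(3 / 2)
  expect_equal(gmm_density(c(0, 0, 0), st2), 2 * single)
  # K = 5 random state vs term-by-term summation
  set.seed(1)
  mu <- matrix(rnorm(15), 5, 3)
  w <- runif(5); w <- 0.9 * w / sum(w)
  st5 <- gmm_state(mu, sigma2 = 0.7, weights = w, outlier_mass = 0.1,
                   volume = 50)
  x <- rnorm(3)
  brute <- sum(w * exp(-colSums((t(mu) - x)^2) / (2 * 0.7)) /
                 (2 * pi * 0.7)^(3 / 2)) + 0.1 / 50
  expect_equal(gmm_density(x, st5), brute, tolerance = 1e-12)
})

test_that("E-step responsibilities are row-stochastic and match Bayes rule", {
  set.seed(2)
  tmpl <- matrix(rnorm(9), 3, 3)
  tgt <- matrix(rnorm(12), 4, 3)
  P <- correspondence_posterior(tmpl, tgt, sigma2 = 0.8,
                                outlier_ratio = 0.1, volume = 100)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  # brute-force normalized posterior
  brute <- t(apply(tgt, 1, function(x) {
    g <- (0.9 / 3) * exp(-colSums((t(tmpl) - x)^2) / (2 * 0.8)) /
      (2 * pi * 0.8)^(3 / 2)
    c(g, 0.1 / 100) / (sum(g) + 0.1 / 100)
  }))
  expect_equal(unname(P), unname(brute), tolerance = 1e-10)
  # coincident point dominates; symmetric case splits responsibilities
  Pc <- correspondence_posterior(rbind(c(0, 0, 0), c(100, 0, 0)),
                                 matrix(c(0, 0, 0), 1), sigma2 = 1)
  expect_gt(Pc[1, 1], 0.999)
  Ps <- correspondence_posterior(rbind(c(-1, 0, 0), c(1, 0, 0)),
                                 matrix(0, 1, 3), sigma2 = 1)
  expect_equal(Ps[1, 1], Ps[1, 2])
  # extreme sigma2 never yields NaN
  Pu <- correspondence_posterior(tmpl, tgt * 1e4, sigma2 = 1e-12,
                                 outlier_ratio = 0)
  expect_false(anyNA(Pu))
})

test_that("rigid registration recovers constructed transforms", {
  set.seed(3)
  Y <- matrix(rnorm(150), 50, 3) * 10
  expect_equal(register_rigid(Y, Y)$result$max_euclid_to_target, 0,
               tolerance = 1e-6)
  R <- rotation_z(25) %*% rotation_x(10); tv <- c(5, -3, 2)
  X <- Y %*% t(R) + matrix(tv, 50, 3, byrow = TRUE)
  rr <- register_rigid(Y, X, registration_params(max_iter = 200))
  expect_lt(rr$result$max_euclid_to_target, 1e-6)
  expect_equal(rr$transform$rotation, R, tolerance = 1e-6)
  # 10 % appended outliers with omega = 0.10: rotation within 1 degree
  Xo <- rbind(X, matrix(runif(15, -60, 60), 5, 3))
  ro <- register_rigid(Y, Xo, registration_params(outlier_ratio = 0.10,
                                                  max_iter = 300))
  ca <- (sum(diag(t(ro$transform$rotation) %*% R)) - 1) / 2
  ang <- acos(pmin(pmax(ca, -1), 1)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("non-rigid registration recovers a planted smooth warp", {
  fx <- grid_surface_fixture(amplitude = 2)
  res <- register_nonrigid(fx$template, fx$target,
                           registration_params(max_iter = 500))
  rms <- sqrt(mean(rowSums((res$displacement - fx$warp)^2)))
  expect_lt(rms, 0.2)          # < 10 % of the 2 mm amplitude
  # identity target: displacement ~ 0
  r0 <- register_nonrigid(fx$template, fx$template,
                          registration_params(max_iter = 200))
  expect_lt(max(abs(r0$displacement)), 1e-6)
  # determinism
  res2 <- register_nonrigid(fx$template, fx$target,
                            registration_params(max_iter = 500))
  expect_identical(res$deformed_template, res2$deformed_template)
})

test_that("the penalized objective is non-increasing across EM iterations", {
  fx <- grid_surface_fixture(amplitude = 2)
  res <- register_nonrigid(fx$template, fx$target,
                           registration_params(max_iter = 300))
  tr <- res$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("infinite-stiffness non-rigid registration equals rigid", {
  set.seed(5)
  Y <- matrix(rnorm(120), 40, 3) * 12
  X <- Y %*% t(rotation_y(18)) + matrix(c(2, -1, 4), 40, 3, byrow = TRUE)
  pr <- registration_params(lambda_deform = 1e9, max_iter = 200)
  nl <- register_nonrigid(Y, X, pr)
  rg <- register_rigid(Y, X, registration_params(max_iter = 200))
  expect_lt(max(abs(nl$deformed_template - rg$result$deformed_template)),
            1e-4)
})

test_that("registration is equivariant under common rigid transforms", {
  fx <- grid_surface_fixture(amplitude = 1.5)
  res <- register_nonrigid(fx$template, fx$target,
                           registration_params(max_iter = 300))
  R <- rotation_z(40); tv <- c(10, -5, 3)
  mv <- function(m) sweep(m %*% t(R), 2, tv, "+")
  res2 <- register_nonrigid(mv(fx$template), mv(fx$target),
                            registration_params(max_iter = 300))
  expect_lt(max(abs(res2$deformed_template - mv(res$deformed_template))),
            1e-3)
})

test_that("multilayer morph refines below the distance threshold", {
  fx <- grid_surface_fixture(amplitude = 2)
  # identity: one layer, zero distance
  ml0 <- multilayer_morph(fx$template, fx$template, rotate_y90 = FALSE)
  expect_equal(ml0$layers_used, 1)
  expect_lt(ml0$distance_trace[1], 1e-6)
  # smooth synthetic target: terminates below 0.04 mm
  ml <- multilayer_morph(fx$template, fx$target,
                         registration_params(max_iter = 500),
                         rotate_y90 = FALSE)
  expect_true(ml$converged)
  expect_lt(ml$result$max_euclid_to_target, 0.04)
  # the published 90-degree pre-rotation start also converges
  ml90 <- multilayer_morph(fx$template, fx$target,
                           registration_params(max_iter = 500),
                           rotate_y90 = TRUE)
  expect_true(ml90$converged)
  # exhausted layer budget: flagged, no exception
  mlb <- multilayer_morph(fx$template, fx$target,
                          registration_params(max_iter = 3),
                          max_layers = 1, rotate_y90 = FALSE)
  expect_false(mlb$converged)
  expect_equal(mlb$layers_used, 1)
  expect_error(multilayer_morph(fx$template, fx$target, threshold = -1),
               "positive")
})

test_that("transport_points reproduces registered points and carries others", {
  fx <- grid_surface_fixture(amplitude = 2)
  res <- register_nonrigid(fx$template, fx$target,
                           registration_params(max_iter = 300))
  moved <- transport_points(fx$template, res)
  expect_equal(moved, unname(res$deformed_template), tolerance = 1e-10)
})
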