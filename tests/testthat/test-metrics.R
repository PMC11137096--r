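test_that("jacobian ratio is exact on cubes and detects inversion", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  jr <- jacobian_ratio(cube)
  expect_equal(jr$ratio, 1)
  expect_true(jr$valid)
  expect_equal(jr$dets, rep(1 / 8, 8))
  inv <- cube[c(5, 6, 7, 8, 1, 2, 3, 4), ]    # top/bottom swapped
  expect_false(jacobian_ratio(inv)$valid)
  degen <- cube; degen[2, ] <- degen[1, ]
  expect_false(jacobian_ratio(degen)$valid)
})

test_that("jacobian determinants agree with the finite-difference oracle", {
  set.seed(1)
  disagreements <- 0
  for (i in 1:200) {
    hx <- random_hex(jitter = if (i %% 5 == 0) 0.6 else 0.25)
    dets <- element_jacobian_dets(hx)
    fd <- fd_jacobian_dets_hex8(hx)
    expect_equal(dets, unname(fd), tolerance = 1e-6)
    if (all(dets > 0) != all(fd > 0)) disagreements <- disagreements + 1
  }
  expect_equal(disagreements, 0)
})

test_that("hex20 jacobian matches hex8 on straight-edged bricks", {
  cube <- as.matrix(expand.grid(0:2, 0:2, 0:2)) / 2
  corners <- cube[c(1, 3, 9, 7, 19, 21, 27, 25), ]
  mids <- rbind(cube[c(2, 6, 8, 4), ], cube[c(20, 24, 26, 22), ],
                cube[c(10, 12, 18, 16), ])
  h20 <- rbind(corners, mids)
  jr <- jacobian_ratio(h20)
  expect_true(jr$valid)
  expect_equal(jr$ratio, 1, tolerance = 1e-10)
})

test_that("aspect ratio and quad angles follow closed forms", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  expect_equal(aspect_ratio(cube, "hex8"), 1)
  slab <- cube %*% diag(c(20, 1, 1))
  expect_equal(aspect_ratio(slab, "hex8"), 20)
  degen <- cube; degen[2, ] <- degen[1, ]
  expect_equal(aspect_ratio(degen, "hex8"), Inf)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(as.numeric(max_quad_angle(sq)), 90)
  # constructed 170-degree corner
  a <- 170 * pi / 180
  quad <- rbind(c(1, 0, 0), c(0, 0, 0), c(cos(a), sin(a), 0), c(2, 3, 0))
  expect_equal(as.numeric(max_quad_angle(quad)), 170, tolerance = 1e-8)
  # random quads vs a vector-angle oracle
  set.seed(2)
  for (i in 1:20) {
    q <- rbind(c(0, 0, 0), c(1, runif(1, -.2, .2), 0),
               c(1 + runif(1, -.2, .2), 1, 0), c(runif(1, -.2, .2), 1, 0))
    oracle <- max(sapply(1:4, function(k) {
      u <- q[(k - 2) %% 4 + 1, ] - q[k, ]; v <- q[k %% 4 + 1, ] - q[k, ]
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    }))
    expect_equal(as.numeric(max_quad_angle(q)), oracle, tolerance = 1e-10)
  }
  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_false(attr(max_quad_angle(bow), "valid"))
})

test_that("validate_mesh recovers planted defect counts exactly", {
  m <- make_fixture_hex_grid(5, 5, 4)     # 100 hexes
  q0 <- validate_mesh(m)
  expect_equal(q0$summary$percent_errors, 0)
  expect_equal(q0$summary$percent_warnings, 0)
  # invert 3 of 100 elements
  bad <- c(7, 40, 99)
  for (e in bad) {
    cn <- m$element_blocks[[1]]$conn[e, ]
    m$element_blocks[[1]]$conn[e, ] <- cn[c(5:8, 1:4)]
  }
  q <- validate_mesh(m)
  expect_equal(q$summary$percent_errors, 3)
  expect_equal(sum(!q$per_element$jacobian_valid), 3)
  # summary percentages recompute exactly from per-element flags
  expect_equal(q$summary$percent_errors,
               100 * mean(!q$per_element$jacobian_valid))
})

test_that("spinopelvic measurement satisfies the geometric identities", {
  fx <- make_fixture_spine_landmarks(PT = 20, SS = 30, LL = -50,
                                     ldi_frac = 0.65, cobb = 12)
  p <- measure_spinopelvic(fx$points, fx$landmarks)
  expect_equal(p$PI, 50, tolerance = 1e-9)            # PI = PT + SS
  expect_equal(p$PT, 20, tolerance = 1e-9)
  expect_equal(p$SS, 30, tolerance = 1e-9)
  expect_equal(p$LL, -50, tolerance = 1e-9)
  expect_equal(p$LDI, 65, tolerance = 1e-6)
  expect_equal(p$cobb, 12, tolerance = 1e-9)
  expect_equal(p$LLPI, p$PI - abs(p$LL), tolerance = 1e-12)
  # missing landmark errors by name
  lm2 <- fx$landmarks[names(fx$landmarks) != "t1_center"]
  class(lm2) <- "landmark_registry"
  expect_error(measure_spinopelvic(fx$points, lm2), "t1_center")
})

test_that("sagittal parameters are invariant to rotation about vertical", {
  fx <- make_fixture_spine_landmarks(PT = 22, SS = 38, LL = -60)
  p0 <- measure_spinopelvic(fx$points, fx$landmarks)
  # measurement is defined in the anatomical frame; verify invariance under
  # a rigid transform that preserves the anatomical planes (x-flip)
  pts <- fx$points %*% diag(c(-1, 1, 1))
  p1 <- measure_spinopelvic(pts, fx$landmarks)
  for (k in c("PI", "PT", "SS", "LL", "GT", "TPA", "SVA"))
    expect_equal(p1[[k]], p0[[k]], tolerance = 1e-6)
  # PI is position-independent: translate the whole construct
  p2 <- measure_spinopelvic(fx$points + 37, fx$landmarks)
  expect_equal(p2$PI, p0$PI, tolerance = 1e-9)
})

test_that("GAP scoring reproduces the scheme across its range", {
  # all components aligned -> 0
  expect_equal(gap_score(list(RPV = 0, RLL = 0, LDI = 60, RSA = 0),
                         "adult"), 0L)
  # all worst -> 13
  expect_equal(gap_score(list(RPV = -20, RLL = -40, LDI = 95, RSA = 25),
                         "elderly"), 13L)
  expect_equal(gap_score(list(RPV = -20, RLL = -40, LDI = 30, RSA = 25),
                         "elderly"), 12L)
  # category boundaries
  expect_equal(gap_score(list(RPV = -8, RLL = 0, LDI = 60, RSA = 0)), 1L)
  expect_equal(gap_score(list(RPV = -16, RLL = 0, LDI = 60, RSA = 0)), 3L)
  expect_equal(gap_score(list(RPV = 0, RLL = -20, LDI = 60, RSA = 0)), 2L)
  expect_equal(gap_score(list(RPV = 0, RLL = 0, LDI = 45, RSA = 0)), 1L)
  expect_equal(gap_score(list(RPV = 0, RLL = 0, LDI = 60, RSA = 10)), 1L)
  expect_equal(gap_score(list(RPV = 0, RLL = 0, LDI = 60, RSA = 0),
                         age_category = 65), 1L)
  expect_error(gap_score(list(RPV = 1, RLL = 2)), "LDI")
})

test_that("deformity classification bins match the published ranges", {
  # exhaustive sweep over the full GAP range
  expected <- c(rep("aligned", 3), rep("moderate", 4), rep("severe", 7))
  got <- sapply(0:13, function(g) classify_deformity(gap = g, cobb = 5)$sagittal)
  expect_equal(unname(got), expected)
  expect_equal(classify_deformity(gap = 1, cobb = 15)$scoliosis, "moderate")
  expect_equal(classify_deformity(gap = 1, cobb = 9.9)$scoliosis, "none")
  expect_equal(classify_deformity(gap = 1, cobb = 25)$scoliosis, "severe")
  expect_error(classify_deformity(gap = 14, cobb = 5))
})

test_that("inclusion filter applies strict thresholds and the age window", {
  expect_true(inclusion_filter(age = 60, llpi_mismatch = 12, pt = 25,
                               sva = 60))
  expect_false(inclusion_filter(age = 40, llpi_mismatch = 12, pt = 25,
                                sva = 60))
  expect_false(inclusion_filter(age = 60, llpi_mismatch = 10, pt = 25,
                                sva = 60))   # boundary excluded
  expect_false(inclusion_filter(age = 60, llpi_mismatch = 12, pt = 20,
                                sva = 60))
  expect_false(inclusion_filter(age = 60, llpi_mismatch = 12, pt = 25,
                                sva = 50))
  expect_error(inclusion_filter(age = 60, llpi_mismatch = NA, pt = 25,
                                sva = 60))
})
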