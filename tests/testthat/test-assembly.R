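test_that("hollow IVD surface has the exact wall combinatorics", {
  lo <- make_fixture_endplate_patch(nx = 4, ny = 4, width = 40, depth = 30,
                                    z = 0)
  up <- make_fixture_endplate_patch(nx = 4, ny = 4, width = 40, depth = 30,
                                    z = 10)
  s <- build_ivd_surface(lo, up, n_layers = 8)
  expect_equal(length(lo$boundary), 12)
  expect_equal(s$wall_quad_count, 12 * 8)          # boundary x layers
  # default ring count: 8 layers of wall quads
  expect_equal(s$wall_quad_count / length(lo$boundary), 8)
  # coincident endplates are degenerate
  expect_error(build_ivd_surface(lo, lo, n_layers = 8), "degenerate")
  # mismatched boundary counts are named in the error
  up2 <- make_fixture_endplate_patch(nx = 5, ny = 4, z = 10)
  expect_error(build_ivd_surface(lo, up2, n_layers = 8), "14")
})

test_that("nucleus volume fraction matches closed-form two-box geometry", {
  # inner 2 x 2 x 1 box inside an outer 10 x 10 x 1 plate: 4/100 = 0.04
  outer_m <- make_fixture_hex_grid(5, 5, 1, dx = 2, dy = 2, dz = 1)
  centre <- 13                       # the single central 2 x 2 x 1 element
  esets <- list(NP = centre,
                AF = setdiff(seq_len(25), centre),
                CEP_CRANIAL = integer(0), CEP_CAUDAL = integer(0))
  m <- fe_model(outer_m$node_ids, outer_m$node_coords,
                outer_m$element_blocks, esets)
  fr <- nucleus_volume_fraction(m, tissue_sets())
  expect_equal(fr, 0.04)
  # uniform scaling leaves the fraction unchanged
  m2 <- replace_coordinates(m, m$node_coords * 2)
  expect_equal(nucleus_volume_fraction(m2, tissue_sets()), fr)
  # rigid transform too
  m3 <- replace_coordinates(m, m$node_coords %*% t(rotation_x(30)) + 5)
  expect_equal(nucleus_volume_fraction(m3, tissue_sets()), fr,
               tolerance = 1e-12)
})

test_that("hex volumes are exact for affine bricks", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  expect_equal(hex_volume(cube), 1)
  A <- matrix(c(2, 0.3, 0, 0.1, 1.5, 0, 0, 0.2, 3), 3, 3)
  expect_equal(hex_volume(cube %*% t(A)), abs(det(A)), tolerance = 1e-12)
})

test_that("transverse area fraction matches concentric prisms", {
  # concentric square prisms, inner half-width 1, outer 2: area ratio 0.25
  outer_m <- make_fixture_hex_grid(4, 4, 2, dx = 1, dy = 1, dz = 1)
  centre <- c(6, 7, 10, 11, 22, 23, 26, 27)
  esets <- list(NP = centre, AF = setdiff(seq_len(32), centre),
                CEP_CRANIAL = integer(0), CEP_CAUDAL = integer(0))
  m <- fe_model(outer_m$node_ids, outer_m$node_coords,
                outer_m$element_blocks, esets)
  expect_equal(nucleus_area_fraction(m, tissue_sets()), 4 / 16)
  expect_error(nucleus_area_fraction(m, tissue_sets(), z = 100), "intersect")
})

test_that("CEP thickness of a flat slab is exact", {
  m <- make_fixture_hex_grid(3, 3, 2, dx = 5, dy = 5, dz = 0.45)
  esets <- list(NP = integer(0), AF = integer(0),
                CEP_CRANIAL = 10:18, CEP_CAUDAL = 1:9)
  m <- fe_model(m$node_ids, m$node_coords, m$element_blocks, esets)
  ct <- cep_thickness(m, tissue_sets())
  expect_equal(ct$mean, 0.45)
  expect_equal(ct$sd, 0)
  expect_true(ct$in_range)
  # a 1.0 mm slab lies outside the 0.62 +/- 0.29 mm range
  m2 <- replace_coordinates(m, m$node_coords %*% diag(c(1, 1, 1 / 0.45)))
  expect_false(cep_thickness(m2, tissue_sets())$in_range)
})

test_that("the synthetic IVD template hits its anatomy targets", {
  tpl <- build_ivd_template()
  sets <- tpl$sets
  expect_equal(nucleus_volume_fraction(tpl$model, sets), 0.40,
               tolerance = 1e-6)
  expect_equal(nucleus_area_fraction(tpl$model, sets), 0.25,
               tolerance = 1e-9)
  ct <- cep_thickness(tpl$model, sets)
  expect_lt(abs(ct$mean - 0.7), 0.014)
  expect_true(ct$in_range)
  expect_equal(validate_mesh(tpl$model)$summary$percent_errors, 0)
  # tissue sets partition the element set
  all_ids <- unname(unlist(tpl$model$element_sets[unlist(sets)]))
  expect_equal(sort(all_ids), seq_along(all_ids))
})

test_that("IVD morphing preserves structure and restores proportions", {
  tpl <- build_ivd_template()
  skin <- sort(unique(as.vector(boundary_faces(tpl$model))))
  rows <- match(skin, tpl$model$node_ids)
  # identity target: structure untouched, fraction unchanged
  ident <- morph_ivd(tpl, tpl$model$node_coords[rows, ],
                     registration_params(max_iter = 200), max_layers = 2)
  expect_true(ident$valid)
  expect_equal(ident$fraction, 0.40, tolerance = 5e-3)
  expect_identical(ident$model$element_blocks, tpl$model$element_blocks)
  # anisotropic target
  target <- tpl$model$node_coords[rows, ] %*% diag(c(1.2, 0.9, 1.1))
  mv <- morph_ivd(tpl, target, registration_params(max_iter = 400),
                  max_layers = 4)
  expect_true(mv$morph$converged)
  expect_lt(abs(mv$fraction - 0.40), 0.005)
  expect_equal(mv$quality$summary$percent_errors, 0)
  # connectivity, numbering and sets are bitwise identical to the template
  expect_identical(mv$model$element_blocks, tpl$model$element_blocks)
  expect_identical(mv$model$element_sets, tpl$model$element_sets)
  expect_identical(mv$model$node_ids, tpl$model$node_ids)
})

test_that("ligament attachment builds one line element per row", {
  m <- make_fixture_hex_grid(2, 2, 2)
  expect_identical(attach_ligaments(m, ligament_table(character(0),
                                                      character(0),
                                                      integer(0),
                                                      integer(0))), m)
  tab <- ligament_table(group = c("ISL", "SSL", "LF", "CL", "ITL", "PLL",
                                  "ALL"),
                        level = rep("L1-L2", 7),
                        node_a = 1:7, node_b = 11:17)
  m2 <- attach_ligaments(m, tab)
  line_blocks <- Filter(function(b) b$kind == "line2", m2$element_blocks)
  expect_equal(length(line_blocks), 7)
  expect_equal(sum(sapply(line_blocks, function(b) length(b$elem_ids))), 7)
  expect_true(all(c("ISL", "SSL", "LF", "CL", "ITL", "PLL", "ALL") %in%
                    names(m2$element_sets)))
  expect_error(ligament_table("XXX", "L1", 1, 2), "unknown")
  tab2 <- rbind(tab, tab[1, ])
  expect_error(attach_ligaments(m, tab2), "duplicate")
})

test_that("model integration renumbers disjointly and keeps ties", {
  a <- make_fixture_hex_grid(1, 1, 1)
  b <- make_fixture_hex_grid(1, 1, 1, origin = c(10, 0, 0))
  one <- integrate_model(list(a))
  expect_equal(one$node_coords, a$node_coords)
  m <- integrate_model(list(a, b), ties = list(c("BLOCK", "P2_BLOCK")))
  expect_equal(length(m$node_ids), 16)
  expect_equal(sum(sapply(m$element_blocks, function(x) length(x$elem_ids))),
               2)
  expect_equal(length(m$ties), 1)
  expect_error(integrate_model(list(a, b), ties = list(c("NOPE", "BLOCK"))),
               "NOPE")
  # round-trip through INP preserves ties and sets
  f <- tempfile(fileext = ".inp")
  write_inp(m, f)
  m2 <- read_inp(f)
  expect_identical(m2$ties, m$ties)
  expect_identical(m2$element_sets[order(names(m2$element_sets))],
                   m$element_sets[order(names(m$element_sets))])
})
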