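# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Rectangular surface grid (points on a gently inclined plane) plus a smooth
# low-frequency warp of the given amplitude (mm). Normal-dominant, so
# point-set registration has a well-posed correspondence.
grid_surface_fixture <- function(amplitude = 2, spacing = 2.5) {
  g <- expand.grid(x = seq(0, 40, by = spacing), y = seq(0, 30, by = spacing))
  base <- cbind(g$x, g$y, 0.05 * g$x + 0.02 * g$y)
  warp <- cbind(0.15 * amplitude * sin(pi * g$x / 40),
                0.15 * amplitude * cos(pi * g$y / 30),
                amplitude * sin(pi * g$x / 40) * sin(pi * g$y / 30))
  list(template = base, target = base + warp, warp = warp)
}

# Random single hex8 element: unit cube with bounded corner perturbation
# (keeps the element valid for jitter < ~0.3).
random_hex <- function(jitter = 0.25) {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  cube + matrix(runif(24, -jitter, jitter), 8, 3)
}

# Independent finite-difference oracle for the isoparametric Jacobian
# determinant: maps F(xi) = sum_i N_i(xi) x_i with trilinear N written out
# directly, differentiated by central differences.
fd_jacobian_dets_hex8 <- function(coords, h = 1e-6) {
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  corners <- corners[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  Fmap <- function(xi) {
    N <- (1 + corners[, 1] * xi[1]) * (1 + corners[, 2] * xi[2]) *
      (1 + corners[, 3] * xi[3]) / 8
    colSums(coords * N)
  }
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  apply(gp, 1, function(xi) {
    J <- sapply(1:3, function(k) {
      e <- numeric(3); e[k] <- h
      (Fmap(xi + e) - Fmap(xi - e)) / (2 * h)
    })
    det(J)
  })
}

# Compare two tri_surfaces as unordered sets of facet coordinate triples
# (geometry equality irrespective of vertex indexing).
same_geometry <- function(a, b, tol = 1e-5) {
  facet_key <- function(s) {
    keys <- apply(s$faces, 1, function(f) {
      tri <- s$points[f, , drop = FALSE]
      paste(sort(sprintf("%.4f_%.4f_%.4f", tri[, 1], tri[, 2], tri[, 3])),
            collapse = "|")
    })
    sort(keys)
  }
  identical(facet_key(a), facet_key(b))
}

# Hex block plus a smooth planted-mode triangulated family sharing its
# nodes; used for deformation-field transfer and cohort-quality sweeps.
hex_ssm_fixture <- function(n = 30, seed = 7, noise_sd = 0.01,
                            variances = c(9, 4, 1)) {
  blk <- make_fixture_hex_grid(nx = 4, ny = 4, nz = 10, dx = 5, dy = 5,
                               dz = 5)
  pts <- blk$node_coords
  raw <- sapply(seq_along(variances), function(j) {
    a <- 0.2
    as.vector(cbind(a * sin(2 * pi * pts[, 3] / 50 + j),
                    a * cos(2 * pi * pts[, 1] / 40 + 2 * j),
                    a * sin(2 * pi * pts[, 3] / 50) *
                      cos(2 * pi * pts[, 2] / 40 + j)))
  })
  modes <- qr.Q(qr(raw))
  fam <- make_fixture_family(nrow(pts), n, variances, noise_sd = noise_sd,
                             seed = seed, base_shape = pts, modes = modes)
  model <- fit_shape_model(fam, length(variances))
  # hex nodes placed exactly on the fitted triangulated mean, so the
  # transfer map is the identity and mode rows copy over exactly
  blk <- replace_coordinates(blk, vector_to_shape(model$mean))
  fields <- transfer_fields(model, blk)
  list(block = blk, family = fam, model = model,
       hex_model = hex_shape_model(blk, fields))
}
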