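#' Synthetic intervertebral-disc hexahedral template
#'
#' Builds an idealized box-section disc with the anatomy targets of a
#' healthy template: the nucleus pulposus (NP) is the central quarter of the
#' transverse footprint (so its mid-plane area share is exactly 25 %), the
#' annulus fibrosus (AF) half-height tapers linearly towards the rim so
#' that the NP occupies 40 % of the disc (AF+NP) volume — the taper slope is
#' calibrated once at build time by bisection against the meshed volumes —
#' and two cartilage endplate (CEP) hex layers of constant thickness are
#' extruded along the local endplate normals. This is a synthetic stand-in
#' template, not a patient geometry.
#'
#' @param nx,ny transverse element counts (multiples of 4 so the NP border
#'   lies on grid lines).
#' @param nz_core vertical element count of the AF/NP core.
#' @param half_width,half_depth transverse half-extents (mm).
#' @param core_height central disc height (mm).
#' @param cep_thickness CEP layer thickness along the surface normal (mm).
#' @param np_volume_fraction target NP share of the AF+NP volume.
#' @return list: `model` (an [fe_model()] with element sets NP, AF,
#'   CEP_CRANIAL, CEP_CAUDAL), `sets` (a [tissue_sets()]), `taper` (the
#'   calibrated slope), `node_u` (per-node normalized radial parameter used
#'   for proportion control).
#' @export
build_ivd_template <- function(nx = 8, ny = 8, nz_core = 4,
                               half_width = 25, half_depth = 17.5,
                               core_height = 10, cep_thickness = 0.7,
                               np_volume_fraction = 0.40) {
  if (nx %% 4 || ny %% 4) stop("nx and ny must be multiples of 4")
  build <- function(beta) .build_ivd_mesh(nx, ny, nz_core, half_width,
                                          half_depth, core_height,
                                          cep_thickness, beta)
  sets <- tissue_sets()
  frac <- function(beta) nucleus_volume_fraction(build(beta)$model, sets)
  lo <- 0.05; hi <- 0.98
  if (frac(lo) > np_volume_fraction || frac(hi) < np_volume_fraction)
    stop("target NP volume fraction unattainable with this footprint")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac(mid) < np_volume_fraction) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  beta <- (lo + hi) / 2
  out <- build(beta)
  out$taper <- beta
  out$sets <- sets
  out
}

# structured box-disc mesh for a given taper slope beta
.build_ivd_mesh <- function(nx, ny, nz_core, A, B, h, cep, beta) {
  gx <- nx + 1L; gy <- ny + 1L
  xs <- seq(-A, A, length.out = gx)
  ys <- seq(-B, B, length.out = gy)
  col_of <- function(i, j) i + gx * (j - 1L)
  ncol_ <- gx * gy
  u <- outer(abs(xs) / A, abs(ys) / B, pmax)       # gx x gy max-norm fraction
  H <- (h / 2) * (1 - beta * pmax(0, (u - 0.5) / 0.5))
  dim(H) <- dim(u)
  # per-column vertex normal of the top surface z = H(x,y): area-weighted
  # average of adjacent discrete face normals (exact on planar patches)
  acc <- array(0, c(gx, gy, 3))
  for (j in seq_len(gy - 1L)) for (i in seq_len(gx - 1L)) {
    p00 <- c(xs[i], ys[j], H[i, j]); p10 <- c(xs[i + 1], ys[j], H[i + 1, j])
    p11 <- c(xs[i + 1], ys[j + 1], H[i + 1, j + 1])
    p01 <- c(xs[i], ys[j + 1], H[i, j + 1])
    d1 <- p11 - p00; d2 <- p01 - p10
    fn <- c(d1[2] * d2[3] - d1[3] * d2[2], d1[3] * d2[1] - d1[1] * d2[3],
            d1[1] * d2[2] - d1[2] * d2[1])
    if (fn[3] < 0) fn <- -fn
    for (ii in i:(i + 1L)) for (jj in j:(j + 1L))
      acc[ii, jj, ] <- acc[ii, jj, ] + fn
  }
  nz_tot <- nz_core + 2L                            # + one CEP layer each side
  nlay <- nz_tot + 1L
  coords <- matrix(0, ncol_ * nlay, 3)
  lid <- function(col, l) col + ncol_ * (l - 1L)    # l = 1..nlay bottom->top
  for (j in seq_len(gy)) for (i in seq_len(gx)) {
    col <- col_of(i, j)
    nrm_top <- acc[i, j, ] / sqrt(sum(acc[i, j, ]^2))
    zc <- H[i, j] * seq(-1, 1, length.out = nz_core + 1L)
    base <- cbind(xs[i], ys[j], zc)
    bot <- base[1, ] + cep * c(nrm_top[1], nrm_top[2], -nrm_top[3])
    top <- base[nz_core + 1L, ] + cep * nrm_top
    stack <- rbind(bot, base, top)
    for (l in seq_len(nlay)) coords[lid(col, l), ] <- stack[l, ]
  }
  conn <- NULL; tags <- character(0)
  np_cells <- function(i, j) {
    # cell (i, j) spans xs[i]..xs[i+1]; NP iff fully inside the central half
    xin <- xs[i] >= -A / 2 - 1e-9 && xs[i + 1] <= A / 2 + 1e-9
    yin <- ys[j] >= -B / 2 - 1e-9 && ys[j + 1] <= B / 2 + 1e-9
    xin && yin
  }
  for (l in seq_len(nz_tot)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    c00 <- col_of(i, j); c10 <- col_of(i + 1L, j)
    c11 <- col_of(i + 1L, j + 1L); c01 <- col_of(i, j + 1L)
    conn <- rbind(conn, c(lid(c00, l), lid(c10, l), lid(c11, l), lid(c01, l),
                          lid(c00, l + 1L), lid(c10, l + 1L),
                          lid(c11, l + 1L), lid(c01, l + 1L)))
    tags <- c(tags, if (l == 1L) "CEP_CAUDAL"
              else if (l == nz_tot) "CEP_CRANIAL"
              else if (np_cells(i, j)) "NP" else "AF")
  }
  eids <- seq_len(nrow(conn))
  blocks <- list(list(name = "IVD", kind = "hex8", elem_ids = eids,
                      conn = conn))
  esets <- split(eids, tags)
  model <- fe_model(seq_len(nrow(coords)), coords, blocks, esets)
  node_u <- numeric(nrow(coords))
  for (j in seq_len(gy)) for (i in seq_len(gx))
    node_u[lid(col_of(i, j), seq_len(nlay))] <- u[i, j]
  list(model = model, node_u = node_u)
}

#' Boundary (skin) quadrilateral faces of the hex blocks of a model
#'
#' Faces that occur exactly once across all hex elements.
#'
#' @param model an [fe_model()].
#' @return matrix of node-ID quadruples (one row per skin face).
#' @export
boundary_faces <- function(model) {
  faces <- NULL
  for (b in model$element_blocks) {
    if (!b$kind %in% c("hex8", "hex20")) next
    for (f in seq_len(6))
      faces <- rbind(faces, b$conn[, .hex_faces[f, ], drop = FALSE])
  }
  if (is.null(faces)) stop("model has no hex elements")
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "_"))
  faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

#' Morph an IVD hexahedral template onto a target surface
#'
#' Registers the template's outer skin nodes non-rigidly onto the target
#' point cloud with multi-layer refinement; interior nodes are carried
#' through the same smooth kernel displacement field. Node and element
#' numbering, connectivity and set membership are untouched. Afterwards the
#' nucleus volume proportion is restored to the target fraction by radial
#' scaling of the AF/NP interface (see [ivd_proportion_control()]) and the
#' morphed mesh is checked for inverted elements.
#'
#' @param template result of [build_ivd_template()] (or a list with
#'   `model`, `sets`, `node_u`).
#' @param target_points N x 3 matrix sampling the target outer surface.
#' @param params a [registration_params()].
#' @param threshold multilayer morph distance criterion (mm).
#' @param rotate_y90 forward the 90-degree pre-rotation to
#'   [multilayer_morph()] (default FALSE: the template is built in the
#'   target frame).
#' @param np_fraction target NP volume fraction (default 0.40) with
#'   tolerance `np_tol` (default 0.005).
#' @param max_layers layer budget.
#' @param np_tol acceptance half-width on the fraction.
#' @return list: `model` (morphed [fe_model()]), `fraction` (achieved NP
#'   volume fraction), `scale` (interface scale applied), `morph`
#'   (the [multilayer_morph()] report), `quality` (a `quality_report`),
#'   `valid` (no inverted elements and fraction within tolerance).
#' @export
morph_ivd <- function(template, target_points,
                      params = registration_params(), threshold = 0.04,
                      rotate_y90 = FALSE, np_fraction = 0.40,
                      np_tol = 0.005, max_layers = 5) {
  model <- template$model
  sets <- template$sets
  skin <- sort(unique(as.vector(boundary_faces(model))))
  rows <- match(skin, model$node_ids)
  skin_xyz <- model$node_coords[rows, , drop = FALSE]
  ml <- multilayer_morph(skin_xyz, target_points, params,
                         threshold = threshold, max_layers = max_layers,
                         rotate_y90 = rotate_y90)
  newc <- model$node_coords
  if (rotate_y90) newc <- newc %*% t(rotation_y(90))
  for (lay in ml$layers) newc <- transport_points(newc, lay)
  morphed <- replace_coordinates(model, newc)
  pc <- ivd_proportion_control(morphed, sets, template$node_u,
                               target = np_fraction, tol = np_tol / 25)
  quality <- validate_mesh(pc$model)
  list(model = pc$model, fraction = pc$fraction, scale = pc$scale,
       morph = ml, quality = quality,
       valid = quality$summary$percent_errors == 0 &&
         abs(pc$fraction - np_fraction) <= np_tol)
}

#' Radial AF/NP proportion control
#'
#' Rescales each node's distance from the nucleus centroid axis in the
#' transverse plane by a piecewise-linear map of its reference radial
#' parameter `u` (NP interior scaled by `s`, annulus re-distributed so the
#' outer boundary stays fixed), and solves for `s` by bisection so the
#' nucleus volume fraction reaches `target`.
#'
#' @param model the (morphed) disc [fe_model()].
#' @param sets a [tissue_sets()].
#' @param node_u per-node reference radial parameter in `[0, 1]` (0.5 at
#'   the AF/NP interface), as produced by [build_ivd_template()].
#' @param target NP volume fraction to reach.
#' @param tol bisection tolerance on the fraction.
#' @param u_interface reference interface parameter (default 0.5).
#' @return list: `model`, `scale`, `fraction`, `converged`.
#' @export
ivd_proportion_control <- function(model, sets, node_u, target = 0.40,
                                   tol = 1e-3, u_interface = 0.5) {
  np_rows <- .set_node_rows(model, sets$np)
  cxy <- colMeans(model$node_coords[np_rows, 1:2, drop = FALSE])
  base <- model$node_coords
  remap <- function(s) {
    g <- ifelse(node_u <= u_interface, s * node_u,
                s * u_interface + (node_u - u_interface) *
                  (1 - s * u_interface) / (1 - u_interface))
    fac <- ifelse(node_u > 0, g / node_u, 1)
    xy <- sweep(base[, 1:2, drop = FALSE], 2, cxy)
    cbind(sweep(xy * fac, 2, cxy, "+"), base[, 3])
  }
  frac_at <- function(s)
    nucleus_volume_fraction(replace_coordinates(model, remap(s)), sets)
  lo <- 0.55; hi <- 1.55
  flo <- frac_at(lo); fhi <- frac_at(hi)
  if (target < flo || target > fhi) {
    # out of bracket: return the closest endpoint, flagged
    s <- if (abs(flo - target) < abs(fhi - target)) lo else hi
    mm <- replace_coordinates(model, remap(s))
    return(list(model = mm, scale = s, fraction = frac_at(s),
                converged = FALSE))
  }
  for (i in 1:60) {
    s <- (lo + hi) / 2
    f <- frac_at(s)
    if (abs(f - target) <= tol) break
    if (f < target) lo <- s else hi <- s
  }
  list(model = replace_coordinates(model, remap(s)), scale = s,
       fraction = f, converged = abs(f - target) <= tol)
}

# node rows belonging to the hex elements of one element set
.set_node_rows <- function(model, set_name) {
  ids <- model$element_sets[[set_name]]
  nids <- integer(0)
  for (b in model$element_blocks) {
    sel <- b$elem_ids %in% ids
    if (any(sel)) nids <- c(nids, as.vector(b$conn[sel, , drop = FALSE]))
  }
  match(sort(unique(nids)), model$node_ids)
}
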