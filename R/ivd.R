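#' Tissue set names of an intervertebral disc model
#'
#' @param af,np element-set names of the annulus fibrosus and nucleus
#'   pulposus.
#' @param cep_cranial,cep_caudal element-set names of the two cartilage
#'   endplate layers.
#' @return named list of class `tissue_sets`.
#' @export
tissue_sets <- function(af = "AF", np = "NP", cep_cranial = "CEP_CRANIAL",
                        cep_caudal = "CEP_CAUDAL") {
  structure(list(af = af, np = np, cep_cranial = cep_cranial,
                 cep_caudal = cep_caudal), class = "tissue_sets")
}

.tet5 <- matrix(c(1, 2, 3, 6,  1, 3, 4, 8,  1, 6, 8, 5,  3, 8, 6, 7,
                  1, 3, 8, 6), ncol = 4, byrow = TRUE)

#' Volume of a hexahedral element
#'
#' Five-tetrahedron decomposition with a fixed diagonal convention (exact
#' for affinely mapped bricks, reproducible for warped ones). hex20 elements
#' are measured through their corner nodes.
#'
#' @param coords 8 x 3 (or 20 x 3) node coordinates in element order.
#' @return volume (mm^3).
#' @export
hex_volume <- function(coords) {
  coords <- as.matrix(coords)[1:8, , drop = FALSE]
  v <- 0
  for (r in seq_len(nrow(.tet5))) {
    a <- coords[.tet5[r, 1], ]
    v <- v + abs(det(rbind(coords[.tet5[r, 2], ] - a,
                           coords[.tet5[r, 3], ] - a,
                           coords[.tet5[r, 4], ] - a))) / 6
  }
  v
}

# volumes of all hex elements whose IDs lie in `ids`
.set_volume <- function(model, ids) {
  id2row <- match(seq_len(max(model$node_ids)), model$node_ids)
  tot <- 0
  for (b in model$element_blocks) {
    if (!b$kind %in% c("hex8", "hex20")) next
    sel <- which(b$elem_ids %in% ids)
    for (e in sel) {
      rows <- id2row[b$conn[e, 1:8]]
      tot <- tot + hex_volume(model$node_coords[rows, , drop = FALSE])
    }
  }
  tot
}

#' Nucleus pulposus volume fraction
#'
#' NP solid volume divided by the disc solid volume (annulus plus nucleus;
#' the thin cartilage endplates are vertebral-interface tissue and are not
#' part of the disc-proper denominator). Hex volumes via tetrahedral
#' decomposition, so the fraction is invariant under rigid transforms and
#' uniform scaling.
#'
#' @param model an [fe_model()] whose elements are hex8/hex20.
#' @param sets a [tissue_sets()].
#' @return fraction in `[0, 1]`.
#' @export
nucleus_volume_fraction <- function(model, sets) {
  np_ids <- model$element_sets[[sets$np]]
  af_ids <- model$element_sets[[sets$af]]
  if (!length(np_ids) || !length(af_ids))
    stop("empty AF or NP element set")
  v_np <- .set_volume(model, np_ids)
  v_af <- .set_volume(model, af_ids)
  v_np / (v_np + v_af)
}

# area of the cross-section of one hex element with the plane z = z0
.hex_plane_area <- function(coords, z0) {
  e <- .edges_of("hex8")
  pts <- NULL
  for (r in seq_len(nrow(e))) {
    a <- coords[e[r, 1], ]; b <- coords[e[r, 2], ]
    za <- a[3] - z0; zb <- b[3] - z0
    if (za == 0 && zb == 0) { pts <- rbind(pts, a[1:2], b[1:2]); next }
    if ((za > 0 && zb > 0) || (za < 0 && zb < 0)) next
    t <- za / (za - zb)
    if (is.finite(t) && t >= 0 && t <= 1)
      pts <- rbind(pts, (a + t * (b - a))[1:2])
  }
  if (is.null(pts) || nrow(pts) < 3) return(0)
  pts <- unique(round(pts, 9))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  n <- nrow(poly)
  abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
            poly[c(2:n, 1), 1] * poly[, 2])) / 2
}

#' Nucleus pulposus transverse area fraction
#'
#' NP cross-sectional area divided by the total disc cross-sectional area on
#' a transverse plane (default: mid-height of the AF+NP node bounding box).
#' Per-element cross sections are plane-element intersection polygons.
#'
#' @param model an [fe_model()].
#' @param sets a [tissue_sets()].
#' @param z plane height (mm); default mid-height.
#' @return fraction in `[0, 1]`.
#' @export
nucleus_area_fraction <- function(model, sets, z = NULL) {
  id2row <- match(seq_len(max(model$node_ids)), model$node_ids)
  ids <- c(model$element_sets[[sets$np]], model$element_sets[[sets$af]])
  if (!length(ids)) stop("empty AF/NP sets")
  if (is.null(z)) {
    zr <- range(unlist(lapply(model$element_blocks, function(b) {
      sel <- b$elem_ids %in% ids
      if (!any(sel)) return(NULL)
      model$node_coords[id2row[b$conn[sel, , drop = FALSE]], 3]
    })))
    z <- mean(zr)
  }
  area_of <- function(set_ids) {
    tot <- 0
    for (b in model$element_blocks) {
      if (!b$kind %in% c("hex8", "hex20")) next
      sel <- which(b$elem_ids %in% set_ids)
      for (e in sel) {
        rows <- id2row[b$conn[e, 1:8]]
        tot <- tot + .hex_plane_area(model$node_coords[rows, , drop = FALSE], z)
      }
    }
    tot
  }
  a_np <- area_of(model$element_sets[[sets$np]])
  a_tot <- a_np + area_of(model$element_sets[[sets$af]])
  if (a_tot == 0) stop("plane z = ", z, " does not intersect the disc")
  a_np / a_tot
}

#' Cartilage endplate thickness
#'
#' Per-element distance between the inner and outer CEP faces measured along
#' the local endplate normal (normal of the inner face, from the cross
#' product of its diagonals), averaged over both CEP layers. Models whose
#' mean lies outside the acceptable range 0.62 +/- 0.29 mm are flagged.
#'
#' @param model an [fe_model()].
#' @param sets a [tissue_sets()].
#' @return list: `mean`, `sd` (mm), `per_element`, `in_range`.
#' @export
cep_thickness <- function(model, sets) {
  ids <- c(model$element_sets[[sets$cep_cranial]],
           model$element_sets[[sets$cep_caudal]])
  if (!length(ids)) stop("empty CEP sets")
  id2row <- match(seq_len(max(model$node_ids)), model$node_ids)
  th <- numeric(0)
  for (b in model$element_blocks) {
    if (!b$kind %in% c("hex8", "hex20")) next
    sel <- which(b$elem_ids %in% ids)
    for (e in sel) {
      xyz <- model$node_coords[id2row[b$conn[e, 1:8]], , drop = FALSE]
      f1 <- xyz[1:4, ]; f2 <- xyz[5:8, ]
      d1 <- f1[3, ] - f1[1, ]; d2 <- f1[4, ] - f1[2, ]
      n <- c(d1[2] * d2[3] - d1[3] * d2[2], d1[3] * d2[1] - d1[1] * d2[3],
             d1[1] * d2[2] - d1[2] * d2[1])
      nn <- sqrt(sum(n^2))
      if (nn == 0) stop("degenerate CEP face in element ", b$elem_ids[e])
      th <- c(th, abs(sum((colMeans(f2) - colMeans(f1)) * n / nn)))
    }
  }
  m <- mean(th)
  list(mean = m, sd = stats::sd(th), per_element = th,
       in_range = m >= 0.62 - 0.29 && m <= 0.62 + 0.29)
}

#' Build a hollow intervertebral-disc target surface
#'
#' Connects two endplate quad patches by a lateral wall of `n_layers` rings
#' of quadrilaterals joining corresponding boundary vertices, producing the
#' closed-sided hollow surface used as a non-rigid morphing target. The wall
#' quad count is exactly `boundary_count * n_layers`.
#'
#' @param lower_endplate,upper_endplate lists with `points` (n x 3),
#'   `quads` (q x 4 point indices) and `boundary` (ordered loop of point
#'   indices); see [make_fixture_endplate_patch()]. Boundary loops must have
#'   equal vertex counts and correspond in order.
#' @param n_layers number of wall rings (default 8).
#' @return list of class `quad_surface`: `points`, `quads`,
#'   `wall_quad_count`.
#' @export
build_ivd_surface <- function(lower_endplate, upper_endplate, n_layers = 8) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  nb_l <- length(lower_endplate$boundary)
  nb_u <- length(upper_endplate$boundary)
  if (nb_l != nb_u)
    stop("endplate boundary loops differ: lower ", nb_l, " vs upper ", nb_u)
  lo_b <- lower_endplate$points[lower_endplate$boundary, , drop = FALSE]
  up_b <- upper_endplate$points[upper_endplate$boundary, , drop = FALSE]
  if (max(abs(up_b - lo_b)) < 1e-9)
    stop("degenerate spec: endplates coincide (zero disc height)")
  pts <- rbind(lower_endplate$points, upper_endplate$points)
  off <- nrow(lower_endplate$points)
  quads <- rbind(lower_endplate$quads, upper_endplate$quads + off)
  ring_idx <- list(lower_endplate$boundary)
  for (k in seq_len(n_layers - 1)) {
    t <- k / n_layers
    ring <- lo_b + t * (up_b - lo_b)
    ring_idx[[k + 1]] <- nrow(pts) + seq_len(nb_l)
    pts <- rbind(pts, ring)
  }
  ring_idx[[n_layers + 1]] <- upper_endplate$boundary + off
  wall <- NULL
  for (k in seq_len(n_layers)) {
    a <- ring_idx[[k]]; b <- ring_idx[[k + 1]]
    nxt <- c(2:nb_l, 1)
    wall <- rbind(wall, cbind(a, a[nxt], b[nxt], b))
  }
  structure(list(points = pts, quads = rbind(quads, wall),
                 wall_quad_count = nrow(wall)),
            class = "quad_surface")
}

#' Rectangular endplate patch fixture
#'
#' Regular grid patch with its boundary loop ordered counter-clockwise,
#' suitable for [build_ivd_surface()].
#'
#' @param nx,ny node counts along x and y.
#' @param width,depth physical extents (mm).
#' @param z patch height (mm); may also be a function `f(x, y)`.
#' @param center xy centre.
#' @return list: `points`, `quads`, `boundary`.
#' @export
make_fixture_endplate_patch <- function(nx = 5, ny = 5, width = 40,
                                        depth = 30, z = 0,
                                        center = c(0, 0)) {
  xs <- seq(-width / 2, width / 2, length.out = nx) + center[1]
  ys <- seq(-depth / 2, depth / 2, length.out = ny) + center[2]
  g <- expand.grid(x = xs, y = ys)
  zz <- if (is.function(z)) mapply(z, g$x, g$y) else rep(z, nrow(g))
  pts <- cbind(g$x, g$y, zz)
  gid <- function(i, j) i + nx * (j - 1)
  quads <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1))
    quads <- rbind(quads, c(gid(i, j), gid(i + 1, j), gid(i + 1, j + 1),
                            gid(i, j + 1)))
  boundary <- c(gid(seq_len(nx - 1), 1), gid(nx, seq_len(ny - 1)),
                gid(seq(nx, 2), ny), gid(1, seq(ny, 2)))
  list(points = pts, quads = quads, boundary = boundary)
}
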