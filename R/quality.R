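#' Isoparametric shape-function derivatives for brick elements
#'
#' Returns the derivative matrix dN (nodes x 3) of the trilinear (hex8) or
#' serendipity quadratic (hex20) shape functions at a reference point
#' `(xi, eta, zeta)`. Node ordering follows the Abaqus C3D8/C3D20
#' convention: corners 1-4 on the bottom face counter-clockwise, 5-8 on the
#' top; hex20 adds bottom-edge, top-edge, then vertical-edge midside nodes.
#'
#' @param xi,eta,zeta reference coordinates in `[-1, 1]`.
#' @param kind `"hex8"` or `"hex20"`.
#' @return nodes x 3 matrix of partial derivatives.
#' @export
shape_derivatives <- function(xi, eta, zeta, kind = c("hex8", "hex20")) {
  kind <- match.arg(kind)
  corners <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                      -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                    8, 3, byrow = TRUE)
  if (kind == "hex8") {
    dN <- matrix(0, 8, 3)
    for (i in 1:8) {
      a <- corners[i, 1]; b <- corners[i, 2]; c <- corners[i, 3]
      dN[i, ] <- c(a * (1 + b * eta) * (1 + c * zeta),
                   b * (1 + a * xi) * (1 + c * zeta),
                   c * (1 + a * xi) * (1 + b * eta)) / 8
    }
    return(dN)
  }
  mids <- matrix(c(0, -1, -1,  1, 0, -1,  0, 1, -1,  -1, 0, -1,
                   0, -1,  1,  1, 0,  1,  0, 1,  1,  -1, 0,  1,
                   -1, -1, 0,  1, -1, 0,  1, 1, 0,  -1, 1, 0),
                 12, 3, byrow = TRUE)
  dN <- matrix(0, 20, 3)
  for (i in 1:8) {
    a <- corners[i, 1]; b <- corners[i, 2]; c <- corners[i, 3]
    s <- a * xi + b * eta + c * zeta
    dN[i, ] <- c(a * (1 + b * eta) * (1 + c * zeta) * (2 * a * xi + b * eta + c * zeta - 1),
                 b * (1 + a * xi) * (1 + c * zeta) * (a * xi + 2 * b * eta + c * zeta - 1),
                 c * (1 + a * xi) * (1 + b * eta) * (a * xi + b * eta + 2 * c * zeta - 1)) / 8
  }
  for (k in 1:12) {
    a <- mids[k, 1]; b <- mids[k, 2]; c <- mids[k, 3]
    i <- 8 + k
    if (a == 0) {
      dN[i, ] <- c(-2 * xi * (1 + b * eta) * (1 + c * zeta),
                   b * (1 - xi^2) * (1 + c * zeta),
                   c * (1 - xi^2) * (1 + b * eta)) / 4
    } else if (b == 0) {
      dN[i, ] <- c(a * (1 - eta^2) * (1 + c * zeta),
                   -2 * eta * (1 + a * xi) * (1 + c * zeta),
                   c * (1 - eta^2) * (1 + a * xi)) / 4
    } else {
      dN[i, ] <- c(a * (1 - zeta^2) * (1 + b * eta),
                   b * (1 - zeta^2) * (1 + a * xi),
                   -2 * zeta * (1 + a * xi) * (1 + b * eta)) / 4
    }
  }
  dN
}

# Gauss-point reference coordinates used for Jacobian evaluation
.gauss_points <- function(kind) {
  if (kind == "hex8") {
    g <- 1 / sqrt(3)
    as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  } else {
    g <- sqrt(3 / 5)
    as.matrix(expand.grid(xi = c(-g, 0, g), eta = c(-g, 0, g),
                          zeta = c(-g, 0, g)))
  }
}

#' Jacobian determinants of a brick element at its Gauss points
#'
#' @param coords nodes x 3 matrix of element node coordinates (8 or 20
#'   rows, Abaqus ordering).
#' @return numeric vector of determinants (8 for hex8, 27 for hex20).
#' @export
element_jacobian_dets <- function(coords) {
  coords <- as.matrix(coords)
  kind <- switch(as.character(nrow(coords)), "8" = "hex8", "20" = "hex20",
                 stop("element must have 8 or 20 nodes"))
  gp <- .gauss_points(kind)
  vapply(seq_len(nrow(gp)), function(g) {
    dN <- shape_derivatives(gp[g, 1], gp[g, 2], gp[g, 3], kind)
    det(t(coords) %*% dN)
  }, numeric(1))
}

#' Jacobian ratio and validity of a hexahedral element
#'
#' Evaluates the Jacobian determinant of the isoparametric mapping at the
#' Gauss points (8 for hex8, 27 for hex20). The ratio is
#' `min|det| / max|det|`; the element is invalid (unusable for FE analysis)
#' if any determinant is non-positive, including the degenerate
#' coincident-node case.
#'
#' @param coords nodes x 3 coordinate matrix.
#' @return list: `ratio`, `valid`, `min_det`, `dets`.
#' @export
jacobian_ratio <- function(coords) {
  coords <- as.matrix(coords)
  dets <- element_jacobian_dets(coords)
  reason <- NULL
  valid <- all(dets > 0)
  if (anyDuplicated(round(coords, 9))) {
    valid <- FALSE
    reason <- "coincident element nodes"
  }
  mx <- max(abs(dets))
  ratio <- if (mx == 0) 0 else min(abs(dets)) / mx
  list(ratio = ratio, valid = valid, min_det = min(dets), dets = dets,
       reason = reason)
}

.edges_of <- function(kind) {
  switch(kind,
         hex8 = ,
         hex20 = matrix(c(1, 2, 2, 3, 3, 4, 4, 1, 5, 6, 6, 7, 7, 8, 8, 5,
                          1, 5, 2, 6, 3, 7, 4, 8), ncol = 2, byrow = TRUE),
         quad4 = matrix(c(1, 2, 2, 3, 3, 4, 4, 1), ncol = 2, byrow = TRUE),
         tri3 = matrix(c(1, 2, 2, 3, 3, 1), ncol = 2, byrow = TRUE),
         stop("no edges for kind ", kind))
}

.hex_faces <- matrix(c(1, 2, 3, 4,  5, 8, 7, 6,  1, 5, 6, 2,
                       2, 6, 7, 3,  3, 7, 8, 4,  4, 8, 5, 1),
                     ncol = 4, byrow = TRUE)

#' Aspect ratio of an element
#'
#' Longest edge length over shortest edge length (corner nodes only for
#' hex20). A zero-length edge yields `Inf`.
#'
#' @param coords nodes x 3 coordinate matrix.
#' @param kind element kind (`"hex8"`, `"hex20"`, `"quad4"`, `"tri3"`).
#' @return scalar aspect ratio.
#' @export
aspect_ratio <- function(coords, kind = c("hex8", "hex20", "quad4", "tri3")) {
  kind <- match.arg(kind)
  e <- .edges_of(kind)
  len <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                         coords[e[, 2], , drop = FALSE])^2))
  if (min(len) == 0) return(Inf)
  max(len) / min(len)
}

#' Maximum interior angle of a quadrilateral face (degrees)
#'
#' Interior corner angles from the vectors to the adjacent corners. A
#' self-intersecting (bowtie) vertex ordering is flagged via the `valid`
#' attribute.
#'
#' @param coords 4 x 3 matrix of corner coordinates in cyclic order.
#' @return maximum interior angle in degrees, with attribute `valid`.
#' @export
max_quad_angle <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 4) stop("a quad has 4 corners")
  angs <- numeric(4)
  for (i in 1:4) {
    p <- coords[(i - 2) %% 4 + 1, ]
    q <- coords[i, ]
    r <- coords[i %% 4 + 1, ]
    u <- p - q; v <- r - q
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) { angs[i] <- NA; next }
    angs[i] <- acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
  }
  out <- max(angs, na.rm = TRUE)
  attr(out, "valid") <- !.quad_self_intersects(coords)
  out
}

# Self-intersection (bowtie) test: project onto the Newell-normal plane and
# check whether either pair of opposite edges properly intersects.
.quad_self_intersects <- function(coords) {
  nxt <- c(2, 3, 4, 1)
  n <- colSums(cbind(
    (coords[, 2] - coords[nxt, 2]) * (coords[, 3] + coords[nxt, 3]),
    (coords[, 3] - coords[nxt, 3]) * (coords[, 1] + coords[nxt, 1]),
    (coords[, 1] - coords[nxt, 1]) * (coords[, 2] + coords[nxt, 2])))
  if (all(n == 0)) return(TRUE)
  n <- n / sqrt(sum(n^2))
  e1 <- diag(3)[, which.min(abs(n))]
  u <- e1 - sum(e1 * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  pts2 <- cbind(coords %*% u, coords %*% v)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-10 && t < 1 - 1e-10 && s > 1e-10 && s < 1 - 1e-10
  }
  seg_int(pts2[1, ], pts2[2, ], pts2[3, ], pts2[4, ]) ||
    seg_int(pts2[2, ], pts2[3, ], pts2[4, ], pts2[1, ])
}

# Vectorized Gauss-point determinants for all elements of a hex block.
# conn: E x nodes matrix of row indices into coords.
.block_jacobian_dets <- function(coords, conn, kind) {
  gp <- .gauss_points(kind)
  E <- nrow(conn)
  Xm <- matrix(coords[conn, 1], E); Ym <- matrix(coords[conn, 2], E)
  Zm <- matrix(coords[conn, 3], E)
  dets <- matrix(0, E, nrow(gp))
  for (g in seq_len(nrow(gp))) {
    dN <- shape_derivatives(gp[g, 1], gp[g, 2], gp[g, 3], kind)
    Jx <- Xm %*% dN; Jy <- Ym %*% dN; Jz <- Zm %*% dN
    dets[, g] <- Jx[, 1] * (Jy[, 2] * Jz[, 3] - Jy[, 3] * Jz[, 2]) -
      Jx[, 2] * (Jy[, 1] * Jz[, 3] - Jy[, 3] * Jz[, 1]) +
      Jx[, 3] * (Jy[, 1] * Jz[, 2] - Jy[, 2] * Jz[, 1])
  }
  dets
}

#' Mesh-quality report for a finite-element model
#'
#' Per-element Jacobian ratio and validity (hex blocks), aspect ratio (hex
#' and quad blocks) and maximum quad-face angle (quad elements and the six
#' faces of each hex), summarized as percentages in the style of a
#' mesh-qualification table: `percent_errors` (hexes with any non-positive
#' Gauss-point Jacobian determinant), `percent_warnings` (elements with
#' Jacobian ratio < 0.3, aspect ratio > 10 or a quad angle > 160 degrees),
#' `percent_aspect_gt_10` and `percent_quad_angle_gt_160`.
#'
#' @param model an [fe_model()].
#' @return object of class `quality_report`: `per_element` data.frame and
#'   `summary` named list of percentages.
#' @export
validate_mesh <- function(model) {
  rows <- list()
  id2row <- match(seq_len(max(model$node_ids)), model$node_ids)
  for (b in model$element_blocks) {
    if (!b$kind %in% c("hex8", "hex20", "quad4")) next
    conn <- matrix(id2row[b$conn], nrow(b$conn))
    n_el <- nrow(conn)
    jr <- rep(NA_real_, n_el); jv <- rep(NA, n_el)
    ar <- rep(NA_real_, n_el); qa <- rep(NA_real_, n_el)
    if (b$kind %in% c("hex8", "hex20")) {
      dets <- .block_jacobian_dets(model$node_coords, conn, b$kind)
      jv <- apply(dets, 1, function(d) all(d > 0))
      jr <- apply(dets, 1, function(d) {
        mx <- max(abs(d)); if (mx == 0) 0 else min(abs(d)) / mx
      })
      for (e in seq_len(n_el)) {
        xyz <- model$node_coords[conn[e, ], , drop = FALSE]
        ar[e] <- aspect_ratio(xyz[seq_len(min(8, nrow(xyz))), , drop = FALSE],
                              "hex8")
        qa[e] <- max(vapply(seq_len(6), function(f)
          as.numeric(max_quad_angle(xyz[.hex_faces[f, ], ])), numeric(1)))
      }
    } else {
      for (e in seq_len(n_el)) {
        xyz <- model$node_coords[conn[e, ], , drop = FALSE]
        ar[e] <- aspect_ratio(xyz, "quad4")
        qa[e] <- as.numeric(max_quad_angle(xyz))
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(block = b$name, kind = b$kind, elem_id = b$elem_ids,
                 jacobian_ratio = jr, jacobian_valid = jv,
                 aspect_ratio = ar, max_quad_angle = qa)
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = character(), kind = character(),
               elem_id = integer(), jacobian_ratio = numeric(),
               jacobian_valid = logical(), aspect_ratio = numeric(),
               max_quad_angle = numeric())
  ishex <- per$kind %in% c("hex8", "hex20")
  pct <- function(flag, base) {
    if (!sum(base)) return(0)
    100 * sum(flag & base, na.rm = TRUE) / sum(base)
  }
  warnflag <- (!is.na(per$jacobian_ratio) & per$jacobian_ratio < 0.3) |
    (!is.na(per$aspect_ratio) & per$aspect_ratio > 10) |
    (!is.na(per$max_quad_angle) & per$max_quad_angle > 160)
  summary <- list(
    percent_errors = pct(!per$jacobian_valid, ishex),
    percent_warnings = pct(warnflag, rep(TRUE, nrow(per))),
    percent_aspect_gt_10 = pct(per$aspect_ratio > 10, rep(TRUE, nrow(per))),
    percent_quad_angle_gt_160 = pct(per$max_quad_angle > 160,
                                    rep(TRUE, nrow(per))),
    n_elements = nrow(per), n_hex = sum(ishex))
  structure(list(per_element = per, summary = summary),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("quality_report: %d elements (%d hex) | errors %.2f%%",
                     " | warnings %.2f%% | aspect>10 %.2f%%",
                     " | quad angle>160 %.2f%%\n"),
              s$n_elements, s$n_hex, s$percent_errors, s$percent_warnings,
              s$percent_aspect_gt_10, s$percent_quad_angle_gt_160))
  invisible(x)
}

#' Structured hexahedral block fixture
#'
#' Regular nx x ny x nz grid of hex8 elements, used as a well-conditioned
#' synthetic template for morphing and quality tests.
#'
#' @param nx,ny,nz element counts along each axis.
#' @param dx,dy,dz element edge lengths (mm).
#' @param origin length-3 lower corner.
#' @param block_name element block / set name.
#' @return an [fe_model()] with one hex8 block.
#' @export
make_fixture_hex_grid <- function(nx = 4, ny = 4, nz = 8, dx = 5, dy = 5,
                                  dz = 5, origin = c(0, 0, 0),
                                  block_name = "BLOCK") {
  gx <- nx + 1L; gy <- ny + 1L; gz <- nz + 1L
  gid <- function(i, j, k) i + gx * (j - 1L) + gx * gy * (k - 1L)
  grid <- expand.grid(i = seq_len(gx), j = seq_len(gy), k = seq_len(gz))
  coords <- cbind(origin[1] + (grid$i - 1) * dx,
                  origin[2] + (grid$j - 1) * dy,
                  origin[3] + (grid$k - 1) * dz)
  el <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  conn <- t(apply(el, 1, function(e) {
    i <- e[1]; j <- e[2]; k <- e[3]
    c(gid(i, j, k), gid(i + 1, j, k), gid(i + 1, j + 1, k), gid(i, j + 1, k),
      gid(i, j, k + 1), gid(i + 1, j, k + 1), gid(i + 1, j + 1, k + 1),
      gid(i, j + 1, k + 1))
  }))
  eids <- seq_len(nrow(conn))
  fe_model(node_ids = seq_len(nrow(coords)), node_coords = coords,
           element_blocks = list(list(name = block_name, kind = "hex8",
                                      elem_ids = eids, conn = conn)),
           element_sets = stats::setNames(list(eids), block_name))
}
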