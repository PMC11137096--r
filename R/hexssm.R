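#' Transfer triangulated-SSM deformation fields to a hexahedral mean model
#'
#' The hexahedral mean model is rigidly aligned onto the triangulated mean
#' shape (GMM rigid registration), closest corresponding points are found by
#' ICP nearest-neighbour assignment, and each hexahedral node inherits the
#' `sqrt(eigenvalue)`-scaled mode rows of its closest triangulated point
#' (rotated back into the hexahedral model's own frame). The result is the
#' deformation-field matrix `DF` of the hexahedral shape relation
#' `shape = hex_mean + DF b`.
#'
#' @param tri_model a [fit_shape_model()] result on the triangulated family.
#' @param hex_mean an [fe_model()] (the morphed mean hexahedral model).
#' @param params a [registration_params()] for the rigid pre-alignment.
#' @return object of class `deformation_fields`: `DF` (3Q x m), `map`
#'   (per-hex-node index of the closest triangulated point), `distances`,
#'   `rigid` (the hex-to-tri `rigid_transform`), `n_modes`.
#' @export
transfer_fields <- function(tri_model, hex_mean,
                            params = registration_params()) {
  if (!length(hex_mean$node_ids)) stop("empty hexahedral model")
  tri_mean <- vector_to_shape(tri_model$mean)
  hx <- hex_mean$node_coords
  rr <- register_rigid(hx, tri_mean, params)
  icp <- icp_correspondence(rr$result$deformed_template, tri_mean,
                            max_iter = 30)
  nn <- icp$map
  R_total <- icp$transform$rotation %*% rr$transform$rotation
  m <- length(tri_model$eigenvalues)
  Q <- nrow(hx)
  DF <- matrix(0, 3 * Q, m)
  for (i in seq_len(m)) {
    Mi <- vector_to_shape(sqrt(tri_model$eigenvalues[i]) *
                            tri_model$modes[, i])
    DF[, i] <- as.vector(Mi[nn$index, , drop = FALSE] %*% R_total)
  }
  structure(list(DF = DF, map = nn$index, distances = nn$distance,
                 rigid = rr$transform, n_modes = m),
            class = "deformation_fields")
}

#' Hexahedral statistical shape model
#'
#' @param hex_mean an [fe_model()], the mean hexahedral template.
#' @param fields a [transfer_fields()] result; its `DF` row count must be
#'   three times the node count of `hex_mean`.
#' @return object of class `hex_shape_model`.
#' @export
hex_shape_model <- function(hex_mean, fields) {
  if (nrow(fields$DF) != 3 * length(hex_mean$node_ids))
    stop("DF rows (", nrow(fields$DF), ") != 3 x node count (",
         3 * length(hex_mean$node_ids), ")")
  structure(list(hex_mean = hex_mean, fields = fields,
                 n_modes = fields$n_modes),
            class = "hex_shape_model")
}

#' Sample a hexahedral model at given mode weights
#'
#' `shape = hex_mean + DF b`; connectivity, sets and ties are untouched
#' (pure coordinate replacement). `b = 0` returns the mean template's
#' coordinates bit-exactly.
#'
#' @param model a [hex_shape_model()].
#' @param b numeric SD-weight vector of length `n_modes`.
#' @return an [fe_model()].
#' @export
sample_hex <- function(model, b) {
  if (length(b) != model$n_modes)
    stop("b has length ", length(b), ", model has ", model$n_modes, " modes")
  if (all(b == 0)) return(model$hex_mean)
  disp <- vector_to_shape(as.vector(model$fields$DF %*% b))
  replace_coordinates(model$hex_mean, model$hex_mean$node_coords + disp)
}

#' Enumerate and write a hexahedral virtual cohort
#'
#' Writes a single template INP plus one plain-text coordinate file per
#' cohort member (`node_id x y z` rows in template *NODE order), the
#' size-saving convention for sharing large cohorts: any member's full input
#' file is recovered by coordinate replacement into the template.
#'
#' @param model a [hex_shape_model()].
#' @param grid a [cohort_grid()].
#' @param out_dir output directory (created if missing).
#' @param template_name filename for the template INP.
#' @return manifest data.frame: `model_id`, weight columns, `file`, and an
#'   `annotation` placeholder column (NA, filled by downstream measurement).
#' @export
enumerate_hex_cohort <- function(model, grid, out_dir,
                                 template_name = "mean_template.inp") {
  if (grid$n_modes > model$n_modes)
    stop("grid sweeps more modes than the model carries")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  write_inp(model$hex_mean, file.path(out_dir, template_name))
  ids <- seq_len(grid$size)
  W <- cohort_weights(grid, ids)
  files <- character(grid$size)
  for (i in ids) {
    b <- c(W[i, ], rep(0, model$n_modes - grid$n_modes))
    fm <- sample_hex(model, b)
    files[i] <- file.path(out_dir, sprintf("model_%05d.txt", i))
    write_coordinate_table(fm$node_ids, fm$node_coords, files[i])
  }
  df <- data.frame(model_id = ids, W, file = files,
                   annotation = NA_character_)
  names(df)[2:(1 + grid$n_modes)] <- paste0("w", seq_len(grid$n_modes))
  df
}

#' Personalize mode weights from sagittal-balance targets
#'
#' Finds the bounded weight vector `b` whose sampled hexahedral model best
#' reproduces target sagittal parameters (any subset of PI, PT, SS, LL),
#' minimizing the sum of squared normalized parameter errors. Each error is
#' normalized by that parameter's range over a seven-level sweep of mode 1,
#' balancing degrees of different magnitude. The search is deterministic: a
#' coarse grid (full factorial for up to three modes, cyclic coordinate
#' sweeps otherwise) followed by bounded local refinement. Out-of-reach
#' targets return the best-effort weights with a positive residual rather
#' than an error.
#'
#' @param model a [hex_shape_model()].
#' @param landmarks a [landmark_registry()] on the hexahedral template.
#' @param target named list/vector with any of `PI`, `PT`, `SS`, `LL`
#'   (degrees; LL signed).
#' @param bounds length-2 weight bounds per mode (default `c(-3, 3)`).
#' @param coarse_levels coarse search levels (default seven levels spanning
#'   the bounds).
#' @return list: `b`, `achieved` (a `spinopelvic_params`), `residual`
#'   (root of the normalized objective), `objective`, `scales`.
#' @export
personalize <- function(model, landmarks, target, bounds = c(-3, 3),
                        coarse_levels = NULL) {
  target <- target[!vapply(target, is.null, logical(1))]
  keys <- intersect(c("PI", "PT", "SS", "LL"), names(target))
  if (!length(keys)) stop("target must name at least one of PI, PT, SS, LL")
  if (!all(is.finite(unlist(target[keys])))) stop("targets must be finite")
  if (is.null(coarse_levels))
    coarse_levels <- seq(bounds[1], bounds[2], length.out = 7)
  m <- model$n_modes
  meas <- function(b) {
    p <- suppressWarnings(measure_spinopelvic(sample_hex(model, b),
                                              landmarks))
    unlist(p[keys])
  }
  sweep1 <- vapply(coarse_levels, function(l) meas(c(l, rep(0, m - 1))),
                   numeric(length(keys)))
  sweep1 <- matrix(sweep1, nrow = length(keys))
  scales <- apply(sweep1, 1, function(r) max(diff(range(r)), 1e-3))
  names(scales) <- keys
  obj <- function(b) {
    v <- (meas(b) - unlist(target[keys])) / scales
    sum(v^2)
  }
  best_b <- rep(0, m); best_o <- obj(best_b)
  if (m <= 3) {
    G <- as.matrix(do.call(expand.grid, rep(list(coarse_levels), m)))
    for (r in seq_len(nrow(G))) {
      o <- obj(G[r, ])
      if (o < best_o) { best_o <- o; best_b <- as.numeric(G[r, ]) }
    }
  } else {
    for (pass in 1:2) for (j in seq_len(m)) for (l in coarse_levels) {
      b <- best_b; b[j] <- l
      o <- obj(b)
      if (o < best_o) { best_o <- o; best_b <- b }
    }
  }
  opt <- stats::optim(best_b, obj, method = "L-BFGS-B",
                      lower = rep(bounds[1], m), upper = rep(bounds[2], m),
                      control = list(factr = 1e4))
  b <- if (opt$value <= best_o) opt$par else best_b
  objective <- min(opt$value, best_o)
  achieved <- suppressWarnings(measure_spinopelvic(sample_hex(model, b),
                                                   landmarks))
  list(b = b, achieved = achieved, residual = sqrt(objective),
       objective = objective, scales = scales)
}

#' Synthetic spine shape family with landmark registry
#'
#' Generates a family of spinopelvic landmark constellations whose pelvic
#' tilt, sacral slope, lordosis and lumbar distribution vary across
#' individuals (Gaussian around a centre), the synthetic analogue of a
#' patient family for the full tri-SSM to hex-SSM chain.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @param center named list of centre values (`PT`, `SS`, `LL`,
#'   `ldi_frac`).
#' @param sds named list of standard deviations for the same parameters.
#' @return list: `shapes` (list of P x 3 matrices), `landmarks`, `truth`
#'   (data.frame of constructed parameters per individual).
#' @export
make_fixture_spine_family <- function(n = 16, seed = 1,
                                      center = list(PT = 20, SS = 35,
                                                    LL = -55,
                                                    ldi_frac = 0.6),
                                      sds = list(PT = 5, SS = 5, LL = 8,
                                                 ldi_frac = 0.05)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  truth <- data.frame(PT = rnorm(n, center$PT, sds$PT),
                      SS = rnorm(n, center$SS, sds$SS),
                      LL = rnorm(n, center$LL, sds$LL),
                      ldi_frac = rnorm(n, center$ldi_frac, sds$ldi_frac))
  shapes <- lapply(seq_len(n), function(i)
    make_fixture_spine_landmarks(PT = truth$PT[i], SS = truth$SS[i],
                                 LL = truth$LL[i],
                                 ldi_frac = truth$ldi_frac[i])$points)
  lm <- make_fixture_spine_landmarks()$landmarks
  list(shapes = shapes, landmarks = lm, truth = truth)
}
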