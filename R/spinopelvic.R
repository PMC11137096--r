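#' Landmark registry
#'
#' Maps anatomical landmark names to node IDs on a reference mesh. Required
#' names for the sagittal parameter set are the femoral head centres
#' (`fem_head_l`, `fem_head_r`), the anterior/posterior points of the S1
#' superior endplate (`s1_ant`, `s1_post`), the L1 and L4 superior endplate
#' points (`l1_sup_ant`, `l1_sup_post`, `l4_sup_ant`, `l4_sup_post`) and the
#' T1 vertebral body centre (`t1_center`). Optional: `c7_center` (plumb
#' line; falls back to `t1_center`) and per-level coronal endplate pairs
#' `<lvl>_sup_left` / `<lvl>_sup_right` for the scoliosis cobb angle.
#'
#' @param names character vector of landmark names.
#' @param node_ids integer node IDs, same length.
#' @return named integer vector of class `landmark_registry`.
#' @export
landmark_registry <- function(names, node_ids) {
  if (length(names) != length(node_ids)) stop("names/node_ids length mismatch")
  if (anyDuplicated(names)) stop("duplicate landmark names")
  structure(stats::setNames(as.integer(node_ids), names),
            class = "landmark_registry")
}

.required_landmarks <- c("fem_head_l", "fem_head_r", "s1_ant", "s1_post",
                         "l1_sup_ant", "l1_sup_post", "l4_sup_ant",
                         "l4_sup_post", "t1_center")

# landmark coordinates from an fe_model or bare coordinate matrix
.landmark_coords <- function(model, landmarks) {
  if (inherits(model, "fe_model")) {
    ids <- model$node_ids; xyz <- model$node_coords
  } else {
    xyz <- as.matrix(model); ids <- seq_len(nrow(xyz))
  }
  rows <- match(as.integer(landmarks), ids)
  if (anyNA(rows))
    stop("landmark node IDs missing from model: ",
         paste(names(landmarks)[is.na(rows)], collapse = ", "))
  out <- xyz[rows, , drop = FALSE]
  rownames(out) <- names(landmarks)
  out
}

# signed angle (degrees) of a sagittal-plane (y, z) vector from an axis
.ang_from_horizontal <- function(v) atan2(v[2], v[1]) * 180 / pi
.ang_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Measure spinopelvic sagittal-balance parameters
#'
#' All angular parameters are computed on the sagittal (y-z) projection
#' under the package convention x lateral, +y anterior, z cranial:
#' * `SS` — sacral slope: S1 superior endplate line versus horizontal.
#' * `PT` — pelvic tilt: line from the bicoxofemoral axis midpoint to the
#'   sacral plate midpoint versus vertical (positive with the plate
#'   posterior to the femoral heads).
#' * `PI` — pelvic incidence: angle at the sacral plate midpoint between the
#'   cranial plate normal and the line to the bicoxofemoral midpoint;
#'   satisfies `PI = PT + SS` up to sign conventions.
#' * `LL` — lumbar lordosis: signed angle from the S1 to the L1 superior
#'   endplate line, negative in lordosis.
#' * `LLPI` — lordosis/incidence mismatch, `PI - |LL|`.
#' * `GT` / `TPA` — global tilt (angle at the sacral midpoint between the
#'   lines to the C7 centre and to the bicoxofemoral midpoint) and T1 pelvic
#'   angle (same construction at the femoral heads towards T1).
#' * `SVA` — sagittal vertical axis: anterior offset (mm) of the C7 plumb
#'   line from the posterosuperior S1 corner.
#' * `cobb` — scoliosis cobb angle from the coronal (x-z) projection,
#'   maximizing the inter-endplate angle over levels carrying
#'   `<lvl>_sup_left`/`_right` pairs (NA when fewer than two such levels).
#' * GAP components `RPV`, `RLL`, `LDI`, `RSA` via [gap_components()].
#'
#' @param model an [fe_model()] or a P x 3 coordinate matrix (node IDs then
#'   being row numbers).
#' @param landmarks a [landmark_registry()].
#' @return object of class `spinopelvic_params` (named list, degrees; SVA in
#'   mm). A warning is issued if `|PI - (PT + SS)| > 3` degrees.
#' @export
measure_spinopelvic <- function(model, landmarks) {
  missing <- setdiff(.required_landmarks, names(landmarks))
  if (length(missing))
    stop("missing required landmarks: ", paste(missing, collapse = ", "))
  lm <- .landmark_coords(model, landmarks)
  sag <- lm[, c(2, 3), drop = FALSE]   # (y, z): anterior, cranial
  H <- (sag["fem_head_l", ] + sag["fem_head_r", ]) / 2
  M <- (sag["s1_ant", ] + sag["s1_post", ]) / 2
  plate <- sag["s1_ant", ] - sag["s1_post", ]       # anterior-pointing
  th_s1 <- .ang_from_horizontal(plate)
  SS <- -th_s1                     # positive when sloping down anteriorly
  w <- M - H
  PT <- atan2(-w[1], w[2]) * 180 / pi
  nrm <- c(plate[2], -plate[1])                     # caudal plate normal
  if (nrm[2] > 0) nrm <- -nrm
  PI <- .ang_between(nrm, H - M)
  l1 <- sag["l1_sup_ant", ] - sag["l1_sup_post", ]
  l4 <- sag["l4_sup_ant", ] - sag["l4_sup_post", ]
  wrap <- function(a) ((a + 180) %% 360) - 180
  LL <- wrap(th_s1 - .ang_from_horizontal(l1))     # lordosis negative
  L4S1 <- wrap(th_s1 - .ang_from_horizontal(l4))
  c7 <- if ("c7_center" %in% names(landmarks)) sag["c7_center", ]
        else sag["t1_center", ]
  t1 <- sag["t1_center", ]
  GT <- .ang_between(M - c7, H - M)
  TPA <- .ang_between(t1 - H, M - H)
  SVA <- c7[1] - sag["s1_post", 1]
  cobb <- .coronal_cobb(lm, landmarks)
  gapc <- gap_components(PI = PI, SS = SS, LL = LL, GT = GT,
                         LDI = 100 * L4S1 / LL)
  out <- structure(list(PI = PI, PT = PT, SS = SS, LL = LL,
                        LLPI = PI - abs(LL), GT = GT,
                        RPV = gapc$RPV, RLL = gapc$RLL, LDI = gapc$LDI,
                        RSA = gapc$RSA, TPA = TPA, SVA = SVA, cobb = cobb,
                        L4S1 = L4S1),
                   class = "spinopelvic_params")
  if (abs(PI - (PT + SS)) > 3)
    warning(sprintf("PI (%.2f) deviates from PT + SS (%.2f) by > 3 degrees",
                    PI, PT + SS))
  out
}

.coronal_cobb <- function(lm, landmarks) {
  nms <- names(landmarks)
  lv <- unique(sub("_sup_(left|right)$", "",
                   grep("_sup_(left|right)$", nms, value = TRUE)))
  lv <- lv[paste0(lv, "_sup_left") %in% nms & paste0(lv, "_sup_right") %in% nms]
  if (length(lv) < 2) return(NA_real_)
  ang <- vapply(lv, function(l) {
    v <- lm[paste0(l, "_sup_right"), c(1, 3)] - lm[paste0(l, "_sup_left"), c(1, 3)]
    atan2(v[2], v[1]) * 180 / pi
  }, numeric(1))
  max(abs(outer(ang, ang, "-")))
}

#' @export
print.spinopelvic_params <- function(x, ...) {
  cat(sprintf(paste0("PI %.2f  PT %.2f  SS %.2f  LL %.2f  LL-PI %.2f  ",
                     "GT %.2f\nRPV %.2f  RLL %.2f  LDI %.2f  RSA %.2f  ",
                     "TPA %.2f  SVA %.1f mm  cobb %s\n"),
              x$PI, x$PT, x$SS, x$LL, x$LLPI, x$GT, x$RPV, x$RLL, x$LDI,
              x$RSA, x$TPA, x$SVA,
              if (is.na(x$cobb)) "NA" else sprintf("%.2f", x$cobb)))
  invisible(x)
}

#' Global Alignment and Proportion components
#'
#' Pelvic-incidence-proportioned alignment components of the GAP scheme:
#' relative pelvic version `RPV = SS - (0.59 PI + 9)`, relative lumbar
#' lordosis `RLL = |LL| - (0.62 PI + 29)`, lumbar distribution index
#' `LDI = 100 * L4-S1 lordosis / L1-S1 lordosis` (passed through when
#' supplied directly), and relative spinopelvic alignment
#' `RSA = GT - (0.48 PI - 15)`.
#'
#' @param PI,SS,LL,GT measured parameters (degrees); `LL` may be signed
#'   (lordosis negative) — its magnitude enters RLL.
#' @param LDI lumbar distribution index in percent.
#' @return list with `RPV`, `RLL`, `LDI`, `RSA`.
#' @export
gap_components <- function(PI, SS, LL, GT, LDI) {
  list(RPV = SS - (0.59 * PI + 9),
       RLL = abs(LL) - (0.62 * PI + 29),
       LDI = LDI,
       RSA = GT - (0.48 * PI - 15))
}

#' GAP category point configuration
#'
#' The category thresholds and points of the Global Alignment and Proportion
#' scheme, shipped as an editable table so numeric discrepancies with other
#' implementations are auditable. Points: relative pelvic version 0/1/3
#' (aligned / moderate / severe retroversion), relative lumbar lordosis
#' 0/2/3, lumbar distribution index 0 (50-80 %), 1 (40-50 %), 2 (< 40 %),
#' 3 (> 80 %, hyperlordotic maldistribution), relative spinopelvic alignment
#' 0/1/3, and an age factor of 1 point for the older ("elderly", >= 60 y)
#' category. Maximum total 13.
#'
#' @return named list of threshold/point vectors.
#' @export
gap_config <- function() {
  list(
    rpv = list(breaks = c(-15, -7), points = c(3, 1, 0)),
    rll = list(breaks = c(-33, -14), points = c(3, 2, 0)),
    ldi = list(low_breaks = c(40, 50), low_points = c(2, 1, 0),
               high_break = 80, high_points = 3),
    rsa = list(breaks = c(7, 18), points = c(0, 1, 3)),
    age = list(adult = 0, elderly = 1)
  )
}

#' GAP score (0-13)
#'
#' Sums the category points of the four proportioned alignment components
#' plus the age factor.
#'
#' @param params a `spinopelvic_params` object, or any list carrying `RPV`,
#'   `RLL`, `LDI`, `RSA` (degrees / percent).
#' @param age_category `"adult"` (< 60 years) or `"elderly"` (>= 60), or a
#'   numeric age.
#' @param config scheme configuration, see [gap_config()].
#' @return integer GAP score in `[0, 13]`.
#' @export
gap_score <- function(params, age_category = "adult", config = gap_config()) {
  need <- c("RPV", "RLL", "LDI", "RSA")
  miss <- need[!need %in% names(params)]
  miss <- c(miss, need[vapply(need, function(k)
    is.null(params[[k]]) || is.na(params[[k]]), logical(1))])
  if (length(miss))
    stop("missing GAP components: ", paste(unique(miss), collapse = ", "))
  if (is.numeric(age_category))
    age_category <- if (age_category >= 60) "elderly" else "adult"
  age_category <- match.arg(age_category, c("adult", "elderly"))
  binpts <- function(x, breaks, points)
    points[findInterval(x, breaks, left.open = TRUE) + 1]
  p_rpv <- binpts(params$RPV, config$rpv$breaks, config$rpv$points)
  p_rll <- binpts(params$RLL, config$rll$breaks, config$rll$points)
  p_ldi <- if (params$LDI > config$ldi$high_break) config$ldi$high_points
           else binpts(params$LDI, config$ldi$low_breaks, config$ldi$low_points)
  p_rsa <- binpts(params$RSA, config$rsa$breaks, config$rsa$points)
  p_age <- config$age[[age_category]]
  as.integer(p_rpv + p_rll + p_ldi + p_rsa + p_age)
}

#' Classify sagittal and scoliosis deformity
#'
#' Sagittal bins by GAP score: 0-2 aligned, 3-6 moderate, 7-13 severe.
#' Scoliosis bins by cobb angle: < 10 degrees none, 10-20 moderate,
#' > 20 severe.
#'
#' @param params list carrying `gap` (integer) and `cobb` (degrees); either
#'   may be passed directly as `gap =` / `cobb =` arguments.
#' @param gap,cobb optional overrides.
#' @return list with `sagittal` and `scoliosis` class labels.
#' @export
classify_deformity <- function(params = NULL, gap = NULL, cobb = NULL) {
  if (is.null(gap)) gap <- params$gap
  if (is.null(cobb)) cobb <- params$cobb
  if (is.null(gap) || is.na(gap)) stop("gap score required")
  if (gap < 0 || gap > 13) stop("gap must be in [0, 13]")
  sagittal <- if (gap <= 2) "aligned" else if (gap <= 6) "moderate" else "severe"
  scoliosis <- if (is.null(cobb) || is.na(cobb)) NA_character_
    else if (cobb < 10) "none" else if (cobb <= 20) "moderate" else "severe"
  list(sagittal = sagittal, scoliosis = scoliosis)
}

#' Deformity-cohort inclusion filter
#'
#' Inclusion requires age within 50-75 years and all three deformity
#' thresholds strictly exceeded: lordosis-incidence mismatch
#' `|LL - PI| > 10` degrees, pelvic tilt `> 20` degrees and sagittal
#' vertical axis `> 50` mm (5 cm). Boundary values are excluded.
#'
#' @param age years.
#' @param llpi_mismatch lordosis/incidence mismatch magnitude (degrees).
#' @param pt pelvic tilt (degrees).
#' @param sva sagittal vertical axis (mm).
#' @return logical.
#' @export
inclusion_filter <- function(age, llpi_mismatch, pt, sva) {
  if (anyNA(c(age, llpi_mismatch, pt, sva)))
    stop("all inclusion fields must be present")
  age >= 50 && age <= 75 && abs(llpi_mismatch) > 10 && pt > 20 && sva > 50
}

#' Synthetic spinopelvic landmark constellation
#'
#' Builds a landmark point set with prescribed pelvic tilt, sacral slope,
#' lumbar lordosis, lumbar distribution and coronal cobb angle, under the
#' package coordinate convention. Pelvic incidence follows from the
#' geometric identity `PI = PT + SS`. Used as the synthetic stand-in for
#' measurement and personalization tests.
#'
#' @param PT pelvic tilt (degrees).
#' @param SS sacral slope (degrees).
#' @param LL signed lumbar lordosis (degrees, negative lordotic).
#' @param ldi_frac L4-S1 share of total lordosis (0-1).
#' @param cobb coronal cobb angle (degrees).
#' @return list: `points` (P x 3 matrix), `landmarks` (a
#'   [landmark_registry()] with node IDs = row numbers), `truth` (the
#'   constructed parameter values).
#' @export
make_fixture_spine_landmarks <- function(PT = 20, SS = 35, LL = -55,
                                         ldi_frac = 0.6, cobb = 0) {
  d2r <- pi / 180
  H <- c(0, 0)                                    # bicoxofemoral midpoint (y,z)
  M <- H + 60 * c(-sin(PT * d2r), cos(PT * d2r))  # sacral plate midpoint
  plate <- c(cos(SS * d2r), -sin(SS * d2r))       # slopes down anteriorly
  s1a <- M + 17.5 * plate
  s1p <- M - 17.5 * plate
  ang_l1 <- (-SS - LL) * d2r
  ang_l4 <- (-SS - ldi_frac * LL) * d2r
  l1c <- M + c(-10, 160)
  l4c <- M + c(5, 60)
  l1a <- l1c + 15 * c(cos(ang_l1), sin(ang_l1))
  l1p <- l1c - 15 * c(cos(ang_l1), sin(ang_l1))
  l4a <- l4c + 16 * c(cos(ang_l4), sin(ang_l4))
  l4p <- l4c - 16 * c(cos(ang_l4), sin(ang_l4))
  t1c <- M + c(-25, 360)
  c7c <- M + c(-28, 395)
  sag <- rbind(fem_head_l = H, fem_head_r = H, s1_ant = s1a, s1_post = s1p,
               l1_sup_ant = l1a, l1_sup_post = l1p, l4_sup_ant = l4a,
               l4_sup_post = l4p, t1_center = t1c, c7_center = c7c)
  x <- c(-44, 44, rep(0, 8))
  pts <- cbind(x, sag)
  # coronal endplate pairs for the cobb angle, tilted +/- cobb/2
  half <- cobb / 2 * d2r
  t5c <- c(0, M[1] - 20, M[2] + 250)
  t12c <- c(0, M[1] - 5, M[2] + 170)
  pts <- rbind(pts,
               t5_sup_left = t5c + 14 * c(-cos(half), 0, -sin(half)),
               t5_sup_right = t5c + 14 * c(cos(half), 0, sin(half)),
               t12_sup_left = t12c + 14 * c(-cos(half), 0, sin(half)),
               t12_sup_right = t12c + 14 * c(cos(half), 0, -sin(half)))
  dimnames(pts) <- NULL
  reg <- landmark_registry(
    c("fem_head_l", "fem_head_r", "s1_ant", "s1_post", "l1_sup_ant",
      "l1_sup_post", "l4_sup_ant", "l4_sup_post", "t1_center", "c7_center",
      "t5_sup_left", "t5_sup_right", "t12_sup_left", "t12_sup_right"),
    seq_len(nrow(pts)))
  list(points = pts, landmarks = reg,
       truth = list(PT = PT, SS = SS, PI = PT + SS, LL = LL,
                    LDI = 100 * ldi_frac, cobb = cobb))
}
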