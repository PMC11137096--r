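#' Read an STL surface (ASCII or binary)
#'
#' Vertices are welded into an indexed point list with a fixed tolerance of
#' 1e-6 mm, in first-occurrence order, so families of corresponding STL files
#' written with the same vertex stream yield identically ordered point sets.
#'
#' @param path path to an STL file.
#' @param weld_tol welding tolerance in mm (default 1e-6).
#' @return a [tri_surface()].
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is_binary_stl(path)) read_stl_binary(path, weld_tol)
  else read_stl_ascii(path, weld_tol)
}

# A file is taken as binary STL when its size matches 84 + 50 * facet_count.
is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nfac <- readBin(con, "integer", 1, size = 4, endian = "little")
  !is.na(nfac) && nfac >= 0 && sz == 84 + 50 * as.numeric(nfac)
}

read_stl_binary <- function(path, weld_tol) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nfac <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (nfac < 1) stop("binary STL declares no facets: ", path)
  verts <- matrix(NA_real_, 3 * nfac, 3)
  for (i in seq_len(nfac)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12)
      stop("malformed binary STL: truncated facet record ", i)
    verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  weld_vertices(verts, weld_tol)
}

read_stl_ascii <- function(path, weld_tol) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0) stop("no vertex records in ASCII STL: ", path)
  if (length(vl) %% 3 != 0)
    stop("malformed ASCII STL: vertex count ", length(vl),
         " is not a multiple of 3 (facet ", length(vl) %/% 3 + 1, ")")
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad))
    stop("malformed facet record at facet ", (bad[1] - 1) %/% 3 + 1)
  verts <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(!is.finite(verts)))
    stop("non-numeric vertex coordinate near facet ",
         (which(!is.finite(verts[, 1]))[1] - 1) %/% 3 + 1)
  weld_vertices(verts, weld_tol)
}

# First-occurrence welding on a tolerance grid; ties resolved to the earliest
# vertex in file order so correspondence is positional across files.
weld_vertices <- function(verts, tol) {
  key <- paste(round(verts[, 1] / tol), round(verts[, 2] / tol),
               round(verts[, 3] / tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  points <- verts[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_surface(points, faces)
}

#' Write an STL surface
#'
#' Facet normals are recomputed from vertex winding (right-hand rule).
#' Binary output is bit-stable for identical input.
#'
#' @param surface a [tri_surface()].
#' @param path output path.
#' @param mode `"ascii"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, mode = c("ascii", "binary")) {
  mode <- match.arg(mode)
  if (!inherits(surface, "tri_surface")) stop("surface must be a tri_surface")
  if (nrow(surface$faces) == 0) stop("cannot write an empty surface")
  p <- surface$points
  f <- surface$faces
  v1 <- p[f[, 1], , drop = FALSE]
  v2 <- p[f[, 2], , drop = FALSE]
  v3 <- p[f[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (mode == "ascii") {
    fmt <- function(m) apply(m, 1, function(r) sprintf("%.9e %.9e %.9e",
                                                       r[1], r[2], r[3]))
    out <- c("solid vertemorph",
             as.vector(rbind(paste("facet normal", fmt(nrm)),
                             "  outer loop",
                             paste("    vertex", fmt(v1)),
                             paste("    vertex", fmt(v2)),
                             paste("    vertex", fmt(v3)),
                             "  endloop",
                             "endfacet")),
             "endsolid vertemorph")
    writeLines(out, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "vertemorph binary stl"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(nrm[i, ], v1[i, ], v2[i, ], v3[i, ]), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Number of facets declared in a binary STL header
#'
#' @param path path to a binary STL file.
#' @return integer facet count from the 4-byte header field.
#' @export
stl_facet_count <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  readBin(con, "integer", 1, size = 4, endian = "little")
}
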