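#' Construct a finite-element model
#'
#' A lightweight container mirroring the Abaqus INP dialect subset used for
#' the spine templates: nodes, typed element blocks, named element/node sets,
#' tie-constraint metadata, and any unparsed keyword sections carried as
#' opaque text for round-trip fidelity.
#'
#' @param node_ids integer vector of 1-based node IDs (preserved verbatim).
#' @param node_coords Q x 3 numeric matrix (mm), rows matching `node_ids`.
#' @param element_blocks list of blocks, each a list with `name`,
#'   `kind` (one of `"hex8"`, `"hex20"`, `"quad4"`, `"tri3"`, `"line2"`),
#'   `elem_ids` (integer) and `conn` (matrix of node IDs, one row per
#'   element).
#' @param element_sets named list of integer element-ID vectors.
#' @param node_sets named list of integer node-ID vectors.
#' @param ties list of 2-element character vectors
#'   `c(secondary_set, primary_set)`.
#' @param extra character vector of opaque INP lines re-emitted on write.
#' @return an object of class `fe_model`.
#' @export
fe_model <- function(node_ids, node_coords, element_blocks = list(),
                     element_sets = list(), node_sets = list(),
                     ties = list(), extra = character()) {
  node_ids <- as.integer(node_ids)
  node_coords <- as.matrix(node_coords)
  storage.mode(node_coords) <- "double"
  if (nrow(node_coords) != length(node_ids))
    stop("node_coords rows (", nrow(node_coords),
         ") != node_ids length (", length(node_ids), ")")
  if (anyDuplicated(node_ids)) stop("duplicate node IDs")
  dimnames(node_coords) <- NULL
  element_blocks <- lapply(element_blocks, function(b) {
    b$elem_ids <- as.integer(b$elem_ids)
    b$conn <- as.matrix(b$conn)
    storage.mode(b$conn) <- "integer"
    dimnames(b$conn) <- NULL
    b
  })
  element_sets <- lapply(element_sets, function(x) as.integer(sort(x)))
  node_sets <- lapply(node_sets, function(x) as.integer(sort(x)))
  m <- structure(list(node_ids = node_ids, node_coords = node_coords,
                      element_blocks = element_blocks,
                      element_sets = element_sets, node_sets = node_sets,
                      ties = ties, extra = extra),
                 class = "fe_model")
  validate_fe_model(m)
  m
}

.element_arity <- c(hex8 = 8L, hex20 = 20L, quad4 = 4L, tri3 = 3L, line2 = 2L)

#' Validate an fe_model's referential integrity
#'
#' Checks element arity, that every connectivity entry references an existing
#' node ID, and that set members reference existing elements/nodes.
#'
#' @param model an [fe_model()].
#' @return `model`, invisibly; errors describe offending IDs.
#' @export
validate_fe_model <- function(model) {
  all_eids <- integer()
  for (b in model$element_blocks) {
    if (!b$kind %in% names(.element_arity))
      stop("unknown element kind: ", b$kind)
    want <- .element_arity[[b$kind]]
    if (ncol(b$conn) != want)
      stop("block '", b$name, "' kind ", b$kind, " needs arity ", want,
           ", got ", ncol(b$conn))
    if (nrow(b$conn) != length(b$elem_ids))
      stop("block '", b$name, "': elem_ids/connectivity length mismatch")
    missing <- setdiff(unique(as.vector(b$conn)), model$node_ids)
    if (length(missing))
      stop("block '", b$name, "' references missing node IDs: ",
           paste(utils::head(missing, 10), collapse = ", "))
    all_eids <- c(all_eids, b$elem_ids)
  }
  if (anyDuplicated(all_eids)) stop("duplicate element IDs across blocks")
  for (nm in names(model$element_sets)) {
    missing <- setdiff(model$element_sets[[nm]], all_eids)
    if (length(missing))
      stop("element set '", nm, "' references missing elements: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  for (nm in names(model$node_sets)) {
    missing <- setdiff(model$node_sets[[nm]], model$node_ids)
    if (length(missing))
      stop("node set '", nm, "' references missing nodes: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  invisible(model)
}

#' @export
print.fe_model <- function(x, ...) {
  ne <- sum(vapply(x$element_blocks, function(b) length(b$elem_ids), 1L))
  cat("fe_model:", length(x$node_ids), "nodes,", ne, "elements in",
      length(x$element_blocks), "blocks,", length(x$element_sets),
      "element sets,", length(x$node_sets), "node sets,",
      length(x$ties), "ties\n")
  invisible(x)
}

# INP element TYPE= -> internal kind
.inp_kind <- function(type) {
  t <- toupper(type)
  if (grepl("^C3D8", t)) return("hex8")
  if (grepl("^C3D20", t)) return("hex20")
  if (grepl("^(S4|CPS4|M3D4)", t)) return("quad4")
  if (grepl("^(S3|STRI3|CPS3|M3D3)", t)) return("tri3")
  if (grepl("^(T3D2|T2D2|B31|CONN3D2|SPRINGA)", t)) return("line2")
  NA_character_
}

.kind_inp_type <- c(hex8 = "C3D8", hex20 = "C3D20", quad4 = "S4",
                    tri3 = "S3", line2 = "T3D2")

#' Read an Abaqus INP file (dialect subset)
#'
#' Interprets `*NODE`, `*ELEMENT` (with `TYPE=` and optional `ELSET=`),
#' `*ELSET`, `*NSET` (plain or `GENERATE`) and `*TIE` keyword sections plus
#' `**` comments. Any other keyword section is preserved verbatim in
#' `$extra` so the surrounding template text survives a read/write
#' round-trip.
#'
#' @param path path to an `.inp` file.
#' @return an [fe_model()].
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*\\*\\*", lines)]
  lines <- lines[nzchar(trimws(lines))]
  # join continuation lines (trailing comma) within data sections
  iskw <- grepl("^\\s*\\*", lines)
  node_ids <- integer(); coords <- list()
  blocks <- list(); esets <- list(); nsets <- list(); ties <- list()
  extra <- character()
  i <- 1L
  n <- length(lines)
  section_data <- function(start) {
    j <- start
    while (j <= n && !iskw[j]) j <- j + 1L
    j - 1L
  }
  kw_param <- function(header, key) {
    m <- regmatches(header,
                    regexec(paste0("(?i)", key, "\\s*=\\s*([^,]+)"),
                            header, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  parse_int_lines <- function(dat) {
    if (!length(dat)) return(integer())
    as.integer(unlist(strsplit(gsub("\\s", "", paste(dat, collapse = ",")),
                               ",+")))
  }
  while (i <= n) {
    if (!iskw[i]) { i <- i + 1L; next }
    header <- trimws(lines[i])
    kw <- toupper(sub("^\\*([A-Za-z ]+).*", "\\1", header))
    kw <- trimws(kw)
    dend <- section_data(i + 1L)
    dat <- if (dend >= i + 1L) lines[(i + 1L):dend] else character()
    if (kw == "NODE") {
      for (ln in dat) {
        parts <- strsplit(trimws(ln), "\\s*,\\s*")[[1]]
        node_ids <- c(node_ids, as.integer(parts[1]))
        coords[[length(coords) + 1L]] <- as.numeric(parts[2:4])
      }
    } else if (kw == "ELEMENT") {
      type <- kw_param(header, "TYPE")
      kind <- .inp_kind(type)
      if (is.na(kind)) {
        extra <- c(extra, lines[i:dend])
      } else {
        elset <- kw_param(header, "ELSET")
        # merge wrapped connectivity lines
        merged <- character(); buf <- ""
        for (ln in dat) {
          buf <- paste0(buf, trimws(ln))
          if (!grepl(",$", buf)) { merged <- c(merged, buf); buf <- "" }
        }
        if (nzchar(buf)) merged <- c(merged, buf)
        arity <- .element_arity[[kind]]
        ids <- integer(length(merged))
        conn <- matrix(0L, length(merged), arity)
        for (r in seq_along(merged)) {
          v <- as.integer(strsplit(merged[r], "\\s*,\\s*")[[1]])
          if (length(v) != arity + 1L)
            stop("element line has ", length(v) - 1L,
                 " nodes, expected ", arity, ": ", merged[r])
          ids[r] <- v[1]
          conn[r, ] <- v[-1]
        }
        name <- if (is.na(elset)) paste0("EB_", length(blocks) + 1L) else elset
        blocks[[length(blocks) + 1L]] <-
          list(name = name, kind = kind, elem_ids = ids, conn = conn)
        if (!is.na(elset))
          esets[[elset]] <- c(esets[[elset]], ids)
      }
    } else if (kw == "ELSET" || kw == "NSET") {
      setname <- kw_param(header, if (kw == "ELSET") "ELSET" else "NSET")
      gen <- grepl("(?i)GENERATE", header, perl = TRUE)
      members <- if (gen) {
        unlist(lapply(dat, function(ln) {
          v <- as.integer(strsplit(trimws(ln), "\\s*,\\s*")[[1]])
          step <- if (length(v) >= 3 && !is.na(v[3])) v[3] else 1L
          seq(v[1], v[2], by = step)
        }))
      } else parse_int_lines(dat)
      if (kw == "ELSET") esets[[setname]] <- unique(c(esets[[setname]], members))
      else nsets[[setname]] <- unique(c(nsets[[setname]], members))
    } else if (kw == "TIE") {
      for (ln in dat) {
        parts <- trimws(strsplit(ln, ",")[[1]])
        if (length(parts) >= 2)
          ties[[length(ties) + 1L]] <- c(parts[1], parts[2])
      }
    } else {
      extra <- c(extra, lines[i:dend])
    }
    i <- dend + 1L
  }
  if (!length(node_ids)) stop("no *NODE section found in ", path)
  fe_model(node_ids, do.call(rbind, coords), blocks, esets, nsets, ties, extra)
}

#' Write an fe_model as an Abaqus INP file
#'
#' Emits the interpreted dialect subset (`*NODE`, `*ELEMENT`, `*ELSET`,
#' `*NSET`, `*TIE`) followed by any opaque carried-over text.
#'
#' @param model an [fe_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(model, path) {
  out <- character()
  out <- c(out, "*NODE",
           sprintf("%d, %.9g, %.9g, %.9g", model$node_ids,
                   model$node_coords[, 1], model$node_coords[, 2],
                   model$node_coords[, 3]))
  # element IDs contributed per named elset by its defining *ELEMENT block
  block_sets <- list()
  for (b in model$element_blocks) {
    out <- c(out, sprintf("*ELEMENT, TYPE=%s, ELSET=%s",
                          .kind_inp_type[[b$kind]], b$name),
             vapply(seq_along(b$elem_ids), function(r)
               paste(c(b$elem_ids[r], b$conn[r, ]), collapse = ", "),
               character(1)))
    block_sets[[b$name]] <- c(block_sets[[b$name]], b$elem_ids)
  }
  emit_set <- function(kw, name, ids) {
    c(sprintf("*%s, %s=%s", kw, kw, name),
      vapply(split(ids, ceiling(seq_along(ids) / 10)),
             function(ch) paste(ch, collapse = ", "), character(1)))
  }
  for (nm in names(model$element_sets)) {
    ids <- setdiff(model$element_sets[[nm]], block_sets[[nm]])
    if (length(ids)) out <- c(out, emit_set("ELSET", nm, ids))
  }
  for (nm in names(model$node_sets))
    out <- c(out, emit_set("NSET", nm, model$node_sets[[nm]]))
  for (ti in seq_along(model$ties))
    out <- c(out, sprintf("*TIE, NAME=T%d", ti),
             paste(model$ties[[ti]][1], model$ties[[ti]][2], sep = ", "))
  out <- c(out, model$extra)
  writeLines(out, path)
  invisible(path)
}

#' Replace node coordinates of a template model
#'
#' Returns a model sharing all connectivity, sets and ties with the template;
#' only the node coordinates differ. This is the coordinate-replacement
#' workflow used to expand per-instance coordinate files against a single
#' mean template.
#'
#' @param template an [fe_model()].
#' @param coords Q x 3 matrix with one row per template node, in the
#'   template's node order.
#' @return an [fe_model()].
#' @export
replace_coordinates <- function(template, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(template$node_ids))
    stop("coordinate rows (", nrow(coords), ") != template node count (",
         length(template$node_ids), ")")
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  out <- template
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  out$node_coords <- coords
  out
}

#' Read/write plain node-coordinate tables
#'
#' Whitespace-separated `node_id x y z` rows matching the template's *NODE
#' ordering, so [replace_coordinates()] is a pure substitution.
#'
#' @param path file path.
#' @return `read_coordinate_table`: list with `node_ids` and `coords`.
#' @export
read_coordinate_table <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("id", "x", "y", "z"))
  list(node_ids = as.integer(d$id),
       coords = unname(as.matrix(d[, c("x", "y", "z")])))
}

#' @rdname read_coordinate_table
#' @param node_ids integer node IDs.
#' @param coords Q x 3 matrix.
#' @export
write_coordinate_table <- function(node_ids, coords, path) {
  writeLines(sprintf("%d %.9g %.9g %.9g", node_ids,
                     coords[, 1], coords[, 2], coords[, 3]), path)
  invisible(path)
}
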