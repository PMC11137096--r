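.ligament_groups <- c("ISL", "SSL", "LF", "CL", "ITL", "PLL", "ALL")

#' Ligament attachment table
#'
#' @param group character, one of the seven spinal ligament groups: ISL
#'   (interspinous), SSL (supraspinous), LF (ligamentum flavum), CL
#'   (capsular), ITL (intertransverse), PLL (posterior longitudinal), ALL
#'   (anterior longitudinal).
#' @param level text label of the spinal level (e.g. `"L4-L5"`).
#' @param node_a,node_b attachment node IDs.
#' @return data.frame of class `ligament_table`.
#' @export
ligament_table <- function(group, level, node_a, node_b) {
  df <- data.frame(group = as.character(group), level = as.character(level),
                   node_a = as.integer(node_a), node_b = as.integer(node_b),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$group), .ligament_groups)
  if (length(bad))
    stop("unknown ligament group(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(.ligament_groups, collapse = ", "), ")")
  class(df) <- c("ligament_table", "data.frame")
  df
}

#' Attach ligaments to a model as line elements
#'
#' Adds one two-node line element per table row, grouped into element sets
#' named by ligament group. Duplicate rows (same group, level and node pair)
#' are rejected.
#'
#' @param model an [fe_model()].
#' @param table a [ligament_table()] (may be empty: model returned
#'   unchanged).
#' @return the augmented [fe_model()].
#' @export
attach_ligaments <- function(model, table) {
  if (nrow(table) == 0) return(model)
  key <- paste(table$group, table$level, pmin(table$node_a, table$node_b),
               pmax(table$node_a, table$node_b))
  if (anyDuplicated(key))
    stop("duplicate ligament rows at indices: ",
         paste(which(duplicated(key)), collapse = ", "))
  missing <- setdiff(unique(c(table$node_a, table$node_b)), model$node_ids)
  if (length(missing))
    stop("ligament attachment nodes missing from model: ",
         paste(utils::head(missing, 10), collapse = ", "))
  next_id <- max(0L, unlist(lapply(model$element_blocks,
                                   function(b) b$elem_ids))) + 1L
  out <- model
  for (g in intersect(.ligament_groups, unique(table$group))) {
    rows <- table[table$group == g, , drop = FALSE]
    ids <- seq(next_id, length.out = nrow(rows))
    next_id <- next_id + nrow(rows)
    out$element_blocks[[length(out$element_blocks) + 1L]] <-
      list(name = g, kind = "line2", elem_ids = ids,
           conn = cbind(rows$node_a, rows$node_b))
    out$element_sets[[g]] <- ids
  }
  validate_fe_model(out)
  out
}

#' Integrate part models into one osteo-ligamentous model
#'
#' Renumbers node and element IDs of each part with disjoint offsets, merges
#' blocks and named sets (prefixing a part index on name collisions), and
#' records tie-constraint metadata between named sets of the merged model.
#'
#' @param parts list of [fe_model()] objects.
#' @param ties list of 2-element character vectors
#'   `c(secondary_set, primary_set)` referring to merged set names.
#' @return an [fe_model()] with a `provenance` attribute mapping each part
#'   to its node-ID range.
#' @export
integrate_model <- function(parts, ties = list()) {
  if (!length(parts)) stop("no parts to integrate")
  node_ids <- integer(0); coords <- NULL
  blocks <- list(); esets <- list(); nsets <- list()
  prov <- list()
  node_off <- 0L; elem_off <- 0L
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    ids <- p$node_ids + node_off
    node_ids <- c(node_ids, ids)
    coords <- rbind(coords, p$node_coords)
    prov[[k]] <- range(ids)
    for (b in p$element_blocks) {
      nm <- b$name
      if (nm %in% vapply(blocks, `[[`, "", "name"))
        nm <- sprintf("P%d_%s", k, nm)
      blocks[[length(blocks) + 1L]] <-
        list(name = nm, kind = b$kind, elem_ids = b$elem_ids + elem_off,
             conn = b$conn + node_off)
    }
    for (nm in names(p$element_sets)) {
      nm2 <- if (nm %in% names(esets)) sprintf("P%d_%s", k, nm) else nm
      esets[[nm2]] <- p$element_sets[[nm]] + elem_off
    }
    for (nm in names(p$node_sets)) {
      nm2 <- if (nm %in% names(nsets)) sprintf("P%d_%s", k, nm) else nm
      nsets[[nm2]] <- p$node_sets[[nm]] + node_off
    }
    node_off <- max(ids)
    eids <- unlist(lapply(p$element_blocks, `[[`, "elem_ids"))
    if (length(eids)) elem_off <- elem_off + max(eids)
  }
  for (tie in ties) {
    known <- c(names(esets), names(nsets),
               vapply(blocks, `[[`, "", "name"))
    bad <- setdiff(tie, known)
    if (length(bad))
      stop("tie references unknown set(s): ", paste(bad, collapse = ", "))
  }
  out <- fe_model(node_ids, coords, blocks, esets, nsets, ties)
  attr(out, "provenance") <- prov
  out
}
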