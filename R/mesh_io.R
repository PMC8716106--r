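# Mesh JSON I/O.
#
# The dialect is a plain-text stand-in for segmented-mesh exports
# (cells as typed polygons over shared vertices, walls with per-side
# membrane state); the schema is documented in
# inst/extdata/mesh-schema.json.

MESH_FORMAT_VERSION <- 1L

#' Save a cell complex to JSON
#'
#' Writes geometry and the full biochemical state; [load_mesh()] restores
#' it bit-exactly (numbers are serialized at full precision).
#'
#' @param cc a [cell_complex]
#' @param path output file
#' @return `path` invisibly
#' @export
save_mesh <- function(cc, path) {
  # keep only border vertices (centroid/fan vertices are derived state)
  used <- sort(unique(unlist(cc$rings, use.names = FALSE)))
  vmap <- integer(nrow(cc$V))
  vmap[used] <- seq_along(used)
  cc$rings <- lapply(cc$rings, function(r) vmap[r])
  cc$wall_v1 <- vmap[cc$wall_v1]; cc$wall_v2 <- vmap[cc$wall_v2]
  keepV <- cc$V[used, , drop = FALSE]
  keepP <- cc$pinned[used]
  cc$V <- keepV; cc$pinned <- keepP
  cells <- lapply(seq_along(cc$rings), function(ci) {
    list(id = cc$cells$id[ci],
         type = cc$cells$type[ci],
         vertex_ring = cc$rings[[ci]],
         state = list(IAA = cc$cells$IAA[ci], PIN = cc$cells$PIN[ci],
                      AUX1 = cc$cells$AUX1[ci], REG = cc$cells$REG[ci],
                      POL = cc$cells$POL[ci],
                      af = c(cc$cells$afx[ci], cc$cells$afy[ci]),
                      A_max = cc$cells$A_max[ci],
                      parity = cc$cells$parity[ci],
                      row = cc$cells$row[ci]))
  })
  walls <- lapply(seq_len(cc$nw), function(w) {
    sidx <- which(cc$side_wall == w)
    list(id = w,
         vertices = c(cc$wall_v1[w], cc$wall_v2[w]),
         cells = cc$cells$id[stats::na.omit(c(cc$wall_ca[w], cc$wall_cb[w]))],
         IAA = cc$wall_IAA[w],
         rest_length = cc$wall_rest[w],
         sides = lapply(sidx, function(s) {
           list(cell = cc$cells$id[cc$side_cell[s]],
                PIN = cc$side_PIN[s], AUX1 = cc$side_AUX1[s],
                REG = cc$side_REG[s], POL = cc$side_POL[s])
         }))
  })
  obj <- list(version = MESH_FORMAT_VERSION,
              vertices = unname(as.matrix(cc$V)),
              pinned = which(cc$pinned),
              cells = cells, walls = walls)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' Load a cell complex from JSON
#'
#' Validates the schema (every cell needs an id, a known `type` and a
#' `vertex_ring`; walls may adjoin at most two cells) and rebuilds the
#' complex including all biochemical state.
#'
#' @param path JSON file written by [save_mesh()] or conforming to the
#'   documented dialect
#' @return a [cell_complex]
#' @export
load_mesh <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$vertices) || is.null(obj$cells))
    stop("mesh parse error: missing 'vertices' or 'cells'")
  V <- do.call(rbind, lapply(obj$vertices, function(v) as.numeric(unlist(v))))
  ncell <- length(obj$cells)
  rings <- vector("list", ncell)
  types <- character(ncell)
  ids <- integer(ncell)
  st <- vector("list", ncell)
  for (k in seq_len(ncell)) {
    cl <- obj$cells[[k]]
    id <- cl$id %||% k
    if (is.null(cl$type))
      stop("mesh parse error: cell ", id, ": missing cell_type")
    if (!cl$type %in% CELL_TYPES)
      stop("mesh parse error: cell ", id, ": unknown cell_type '", cl$type, "'")
    if (is.null(cl$vertex_ring) || length(cl$vertex_ring) < 3)
      stop("mesh parse error: cell ", id, ": vertex_ring must have >= 3 vertices")
    rings[[k]] <- as.integer(unlist(cl$vertex_ring))
    types[k] <- cl$type
    ids[k] <- as.integer(id)
    st[[k]] <- cl$state
  }
  for (w in obj$walls %||% list()) {
    if (length(w$cells) > 2)
      stop("mesh validation error: wall ", w$id %||% "?", " shared by ",
           length(w$cells), " cells")
  }
  pinned <- rep(FALSE, nrow(V))
  pv <- as.integer(unlist(obj$pinned %||% list()))
  pinned[pv] <- TRUE
  cc <- new_cell_complex(V, rings, types, pinned = pinned)
  cc$cells$id <- ids
  cc$next_id <- max(ids) + 1L
  for (k in seq_len(ncell)) {
    s <- st[[k]]
    if (is.null(s)) next
    num <- function(x, d = 0) if (is.null(x)) d else as.numeric(x)
    cc$cells$IAA[k] <- num(s$IAA); cc$cells$PIN[k] <- num(s$PIN)
    cc$cells$AUX1[k] <- num(s$AUX1); cc$cells$REG[k] <- num(s$REG)
    cc$cells$POL[k] <- num(s$POL)
    if (!is.null(s$af)) {
      af <- as.numeric(unlist(s$af))
      cc$cells$afx[k] <- af[1]; cc$cells$afy[k] <- af[2]
    }
    cc$cells$A_max[k] <- num(s$A_max, Inf)
    cc$cells$parity[k] <- as.integer(num(s$parity))
    cc$cells$row[k] <- as.integer(num(s$row, NA))
  }
  id2idx <- match(seq_len(max(ids)), ids)
  for (w in obj$walls %||% list()) {
    vv <- as.integer(unlist(w$vertices))
    wi <- which(pmin(cc$wall_v1, cc$wall_v2) == min(vv) &
                  pmax(cc$wall_v1, cc$wall_v2) == max(vv))
    if (length(wi) != 1)
      stop("mesh validation error: wall ", w$id %||% "?",
           " references edge not present in any cell ring")
    cc$wall_IAA[wi] <- as.numeric(w$IAA %||% 0)
    cc$wall_rest[wi] <- as.numeric(w$rest_length %||% cc$wall_rest[wi])
    for (sd in w$sides %||% list()) {
      cix <- id2idx[as.integer(sd$cell)]
      si <- which(cc$side_wall == wi & cc$side_cell == cix)
      if (length(si) != 1)
        stop("mesh validation error: wall ", w$id %||% "?",
             ": side references cell ", sd$cell, " not adjoining the wall")
      cc$side_PIN[si] <- as.numeric(sd$PIN %||% 0)
      cc$side_AUX1[si] <- as.numeric(sd$AUX1 %||% 0)
      cc$side_REG[si] <- as.numeric(sd$REG %||% 0)
      cc$side_POL[si] <- as.numeric(sd$POL %||% 0)
    }
  }
  validate_complex(cc)
  cc
}
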