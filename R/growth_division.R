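# Auxin-dependent wall mechanics and cell division.
#
# Auxin relaxes wall stiffness in a biphasic (band-pass) manner: walls are
# stiff at negligible auxin, maximally relaxed at low-to-intermediate
# auxin and stiff again at high auxin (growth arrest). Division triggers
# on a per-type area threshold; the division plane passes through the
# centroid parallel to the AF vector, with the documented cell-type
# exceptions for the stem-cell niche.

#' Auxin-dependent cell wall extension stiffness
#'
#' `kE = kE_Max * (K1^4 / (IAA^4 + K1^4) + IAA^4 / (IAA^4 + K2^4))`: near
#' 1 (stiff) at IAA = 0 and IAA -> Inf, with a relaxed valley between
#' `K_1auxin` and `K_2auxin` where turgor-driven growth proceeds.
#'
#' @param IAA auxin concentration(s), nM
#' @param params parameter list (block `growth`)
#' @return stiffness value(s) in (0, kE_Max]
#' @export
wall_stiffness <- function(IAA, params) {
  pg <- params$growth
  I4 <- IAA^4
  pg$kE_Max * (pg$K_1auxin^4 / (I4 + pg$K_1auxin^4) + I4 / (I4 + pg$K_2auxin^4))
}

division_direction <- function(cc, ci, geom, parity_orth = FALSE) {
  afx <- cc$cells$afx[ci]; afy <- cc$cells$afy[ci]
  if (sqrt(afx^2 + afy^2) > 1e-9) {
    u <- c(afx, afy) / sqrt(afx^2 + afy^2)
  } else {
    # pre-polarity fallback: divide anticlinally w.r.t. the cell geometry
    u <- c(-geom$ax_y[ci], geom$ax_x[ci])   # axisMin direction
  }
  if (parity_orth) u <- c(-u[2], u[1])
  u
}

#' Decide whether (and how) a cell divides
#'
#' Checks the area threshold and the cell-type rule table and returns a
#' division event (or `NULL`): the division line passes through the
#' centroid, parallel to the AF vector by default (anticlinal), with the
#' stem-cell niche exceptions: CEI produces CEI + CEID; CEID divides
#' periclinally into Endodermis + Cortex; epidermis/LRC initials alternate
#' orthogonal/parallel divisions producing LRC or Epidermis; columella and
#' vascular initials divide asymmetrically, renewing themselves; QC and
#' columella never divide.
#'
#' @param cc a [cell_complex]
#' @param ci cell index
#' @param geom optional precomputed geometry
#' @return `NULL` or a list event: `cell`, `p0`, `u` (line), `types`
#'   (daughter types: first = rootward/inner daughter), `parity_used`
#' @export
check_and_divide <- function(cc, ci, geom = NULL) {
  type <- cc$cells$type[ci]
  if (type %in% NON_DIVIDING_TYPES) return(NULL)
  if (is.null(geom)) geom <- cc_geometry(cc)
  if (geom$cell_A[ci] < cc$cells$A_max[ci]) return(NULL)
  p0 <- c(geom$cell_cx[ci], geom$cell_cy[ci])
  parity_orth <- FALSE
  if (type == "EpidermisLRCInitial")
    parity_orth <- cc$cells$parity[ci] %% 2L == 0L
  u <- division_direction(cc, ci, geom, parity_orth)
  types <- switch(type,
    CEI = c("CEI", "CEID"),              # shootward daughter is the CEID
    CEID = c("Endodermis", "Cortex"),    # inner / outer (periclinal)
    EpidermisLRCInitial =
      if (parity_orth) c("EpidermisLRCInitial", "LRC")   # outer daughter LRC
      else c("EpidermisLRCInitial", "Epidermis"),        # shootward daughter
    ColumellaInitial = c("Columella", "ColumellaInitial"), # rootward columella
    VascularInitial = c("VascularInitial", "Vascular"),  # shootward vascular
    c(type, type))
  if (type == "CEID") u <- c(0, 1)   # periclinal: division line along the organ axis
  list(cell = ci, p0 = p0, u = u / sqrt(sum(u^2)), types = types,
       parity_used = parity_orth)
}

# order daughters for type assignment: returns TRUE if daughter A is the
# "first" daughter given the rule (rootward = smaller y; inner = smaller |x|)
daughter_is_first <- function(type, cA, cB, parity_orth = FALSE) {
  switch(type,
    CEI = cA[2] < cB[2],                          # first = rootward (CEI)
    CEID = abs(cA[1]) < abs(cB[1]),               # first = inner (Endodermis)
    EpidermisLRCInitial =
      if (parity_orth) abs(cA[1]) < abs(cB[1])    # first = inner (stays initial)
      else cA[2] < cB[2],                         # first = rootward (stays initial)
    ColumellaInitial = cA[2] < cB[2],             # first = rootward (Columella)
    VascularInitial = cA[2] < cB[2],              # first = rootward (stays initial)
    TRUE)
}

#' Apply a division event to the complex
#'
#' Inserts the two cut vertices on the parent boundary (splitting the cut
#' walls and the neighbours' rings so the mesh stays conforming), adds the
#' new wall with empty membranes and apoplast, splits the parent ring into
#' two CCW daughter polygons, retriangulates, and inherits state:
#' cytoplasmic concentrations and the AF vector are copied (amounts split
#' with area, concentrations preserved), membrane species stay on their
#' wall segments, `division_parity` is toggled, and rest quantities of the
#' daughters start from the current configuration.
#'
#' @param cc a [cell_complex]
#' @param event event from [check_and_divide()]
#' @param min_frac reject divisions where a daughter would hold less than
#'   this fraction of the parent area
#' @return list(cc, ok, daughters); on failure `ok = FALSE` with the
#'   unmodified complex
#' @export
apply_division <- function(cc, event, min_frac = 0.2) {
  ci <- event$cell
  ring <- cc$rings[[ci]]
  xy <- cc$V[ring, , drop = FALSE]
  hits <- line_polygon_intersections(xy, event$p0, event$u)
  if (nrow(hits) != 2) {
    # retry with a slightly perturbed angle
    th <- 10 * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    u2 <- as.vector(R %*% event$u)
    hits <- line_polygon_intersections(xy, event$p0, u2)
    if (nrow(hits) != 2) return(list(cc = cc, ok = FALSE))
  }
  m <- length(ring)
  nxt <- c(2:m, 1)
  snap_tol <- 0.05
  cc <- species_to_maps(cc)
  cut_vertex <- integer(2)
  # process higher edge index first so earlier indices stay valid
  ord <- order(hits$edge, decreasing = TRUE)
  ring2 <- ring
  for (h in ord) {
    e <- hits$edge[h]; t <- hits$t[h]
    a <- ring[e]; b <- ring[nxt[e]]
    if (t < snap_tol || t > 1 - snap_tol) {
      cut_vertex[h] <- if (t < snap_tol) a else b
      next
    }
    p <- cc$V[a, ] + t * (cc$V[b, ] - cc$V[a, ])
    cc$V <- rbind(cc$V, p)
    cc$pinned <- c(cc$pinned, FALSE)
    vnew <- nrow(cc$V)
    cut_vertex[h] <- vnew
    cc <- split_wall_maps(cc, a, b, vnew, t)
    # insert into the parent's ring
    ring2 <- append(ring2, vnew, after = which(ring2 == a &
      c(ring2[-1], ring2[1]) == b))
    # insert into the neighbour's ring (appears there as b -> a)
    w <- which(pmin(cc$wall_v1_saved, cc$wall_v2_saved) == pmin(a, b) &
                 pmax(cc$wall_v1_saved, cc$wall_v2_saved) == pmax(a, b))
    nb <- setdiff(c(cc$wall_ca_saved[w], cc$wall_cb_saved[w]), ci)
    nb <- nb[!is.na(nb)]
    if (length(nb)) {
      rn <- cc$rings[[nb]]
      pos <- which(rn == b & c(rn[-1], rn[1]) == a)
      cc$rings[[nb]] <- append(rn, vnew, after = pos)
    }
  }
  if (cut_vertex[1] == cut_vertex[2]) return(list(cc = restore_cc(cc), ok = FALSE))
  # split ring2 at the two cut vertices
  i1 <- which(ring2 == cut_vertex[1]); i2 <- which(ring2 == cut_vertex[2])
  if (length(i1) != 1 || length(i2) != 1) return(list(cc = restore_cc(cc), ok = FALSE))
  if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
  ringA <- ring2[i1:i2]
  ringB <- if (i1 == 1) ring2[i2:length(ring2)]
           else ring2[c(i2:length(ring2), 1:i1)]
  aA <- polygon_area(cc$V[ringA, , drop = FALSE])
  aB <- polygon_area(cc$V[ringB, , drop = FALSE])
  aP <- aA + aB
  if (length(ringA) < 3 || length(ringB) < 3 || aA <= 0 || aB <= 0 ||
      min(aA, aB) < min_frac * aP)
    return(list(cc = restore_cc(cc), ok = FALSE))
  cA <- polygon_centroid(cc$V[ringA, , drop = FALSE])
  cB <- polygon_centroid(cc$V[ringB, , drop = FALSE])

  type <- cc$cells$type[ci]
  first_is_A <- daughter_is_first(type, cA, cB, event$parity_used)
  tA <- if (first_is_A) event$types[1] else event$types[2]
  tB <- if (first_is_A) event$types[2] else event$types[1]

  # daughter A reuses the parent slot; daughter B is appended
  cl <- cc$cells
  ncell_old <- length(cc$rings)
  nb_id <- ncell_old + 1L
  cc$rings[[ci]] <- ringA
  cc$rings[[nb_id]] <- ringB
  for (f in names(cl)) cl[[f]] <- c(cl[[f]], cl[[f]][ci])
  cl$id[nb_id] <- cc$next_id
  cc$next_id <- cc$next_id + 1L
  cl$type[ci] <- tA; cl$type[nb_id] <- tB
  cl$parity[ci] <- cl$parity[ci] + 1L
  cl$parity[nb_id] <- cl$parity[nb_id] + 1L
  if (!is.null(cc$A_max_table)) {
    for (k in c(ci, nb_id)) {
      am <- cc$A_max_table[cl$type[k]]
      if (!is.na(am)) cl$A_max[k] <- as.numeric(am)
      if (cl$type[k] %in% NON_DIVIDING_TYPES) cl$A_max[k] <- Inf
    }
  }
  cl$A_rest[ci] <- aA; cl$A_rest[nb_id] <- aB
  # move the parent's center vertex to daughter A's centroid; new center for B
  cc$V[cl$center[ci], ] <- cA
  cc$V <- rbind(cc$V, cB)
  cc$pinned <- c(cc$pinned, FALSE)
  cl$center[nb_id] <- nrow(cc$V)
  cc$cells <- cl
  # new wall between the daughters: empty apoplast and membranes
  k <- wall_key(cut_vertex[1], cut_vertex[2])
  assign(k, c(0, sqrt(sum((cc$V[cut_vertex[1], ] - cc$V[cut_vertex[2], ])^2))),
         envir = cc$wall_map)
  # re-key side species of the parent's edges that went to daughter B
  remap_side_cells(cc$side_map, ci, nb_id, ringB)
  cc <- drop_saved(cc)
  cc <- index_complex(cc)
  list(cc = cc, ok = TRUE, daughters = c(ci, nb_id))
}

# split the stored wall/side state of edge (a,b) at new vertex v (parameter t)
split_wall_maps <- function(cc, a, b, v, t) {
  if (is.null(cc$wall_v1_saved)) {
    cc$wall_v1_saved <- cc$wall_v1; cc$wall_v2_saved <- cc$wall_v2
    cc$wall_ca_saved <- cc$wall_ca; cc$wall_cb_saved <- cc$wall_cb
  }
  wk <- wall_key(a, b)
  wv <- cc$wall_map[[wk]]
  if (!is.null(wv)) {
    rm(list = wk, envir = cc$wall_map)
    assign(wall_key(a, v), c(wv[1], wv[2] * t), envir = cc$wall_map)
    assign(wall_key(v, b), c(wv[1], wv[2] * (1 - t)), envir = cc$wall_map)
  }
  w <- which(pmin(cc$wall_v1_saved, cc$wall_v2_saved) == pmin(a, b) &
               pmax(cc$wall_v1_saved, cc$wall_v2_saved) == pmax(a, b))
  for (cell in c(cc$wall_ca_saved[w], cc$wall_cb_saved[w])) {
    if (is.na(cell)) next
    sk <- side_key(cell, a, b)
    sv <- cc$side_map[[sk]]
    if (!is.null(sv)) {
      rm(list = sk, envir = cc$side_map)
      assign(side_key(cell, a, v), sv, envir = cc$side_map)
      assign(side_key(cell, v, b), sv, envir = cc$side_map)
    }
  }
  cc
}

# change the owning-cell part of side keys for edges now in daughter B
remap_side_cells <- function(side_map, old_cell, new_cell, ringB) {
  m <- length(ringB)
  nxt <- c(2:m, 1)
  for (e in seq_len(m)) {
    a <- ringB[e]; b <- ringB[nxt[e]]
    sk <- side_key(old_cell, a, b)
    sv <- side_map[[sk]]
    if (!is.null(sv)) {
      rm(list = sk, envir = side_map)
      assign(side_key(new_cell, a, b), sv, envir = side_map)
    }
  }
  invisible(side_map)
}

drop_saved <- function(cc) {
  cc$wall_v1_saved <- cc$wall_v2_saved <- NULL
  cc$wall_ca_saved <- cc$wall_cb_saved <- NULL
  cc
}

restore_cc <- function(cc) {
  # a failed division may have inserted vertices/split walls; reindex to a
  # consistent state (inserted vertices are harmless collinear ring points)
  cc <- drop_saved(cc)
  index_complex(cc)
}

#' Remove cells from the complex (ablation)
#'
#' Deletes the given cells; their walls become organ surface (or vanish
#' when both sides are removed) and the remaining mesh is revalidated.
#' Used by the QC-ablation, LRC-removal and tip-excision scenarios.
#'
#' @param cc a [cell_complex]
#' @param cells integer indices of cells to remove
#' @return updated complex
#' @export
remove_cells <- function(cc, cells) {
  if (length(cells) == 0) return(cc)
  keep <- setdiff(seq_along(cc$rings), cells)
  cc <- species_to_maps(cc)
  # side keys of removed cells simply become unused; cell indices shift, so
  # re-key surviving sides to the new indices
  old_new <- match(seq_along(cc$rings), keep)
  sm <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ls(cc$side_map)) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    oc <- as.integer(parts[1])
    nc <- old_new[oc]
    if (!is.na(nc))
      assign(paste(c(nc, parts[-1]), collapse = "_"), cc$side_map[[k]], envir = sm)
  }
  cc$side_map <- sm
  km <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ls(cc$spoke_map)) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    nc <- old_new[as.integer(parts[1])]
    if (!is.na(nc))
      assign(paste(c(nc, parts[-1]), collapse = "_"), cc$spoke_map[[k]], envir = km)
  }
  cc$spoke_map <- km
  cc$rings <- cc$rings[keep]
  cc$cells <- lapply(cc$cells, function(x) x[keep])
  index_complex(cc)
}
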