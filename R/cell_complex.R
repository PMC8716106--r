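#' @importFrom stats runif setNames
NULL

#' Cell types of the root meristem model
#' @export
CELL_TYPES <- c("QC", "ColumellaInitial", "Columella", "EpidermisLRCInitial",
                "CEI", "CEID", "LRC", "Epidermis", "Endodermis", "Cortex",
                "Pericycle", "Vascular", "VascularInitial", "Source", "Sink")

# Types that never grow or divide
NON_GROWING_TYPES <- c("QC", "Columella", "Source", "Sink")
NON_DIVIDING_TYPES <- c("QC", "Columella", "Source", "Sink")
# Columella-lineage cells traffic PIN uniformly (PIN3-like)
UNIFORM_PIN_TYPES <- c("Columella", "ColumellaInitial")
VASCULAR_TYPES <- c("Vascular", "VascularInitial", "Pericycle", "Source")

wall_key <- function(v1, v2) paste0(pmin(v1, v2), "_", pmax(v1, v2))
side_key <- function(cell, v1, v2) paste0(cell, "_", wall_key(v1, v2))
spoke_key <- function(cell, v) paste0(cell, "_", v)

#' Construct a cell complex from polygons
#'
#' Low-level constructor: takes shared vertices and one counter-clockwise
#' vertex ring per cell, adds a centroid vertex per cell (fan
#' triangulation), initializes all biochemical state to zero and builds the
#' wall/membrane-side index.
#'
#' @param vertices numeric matrix (n x 2), positions in micrometres
#' @param rings list of integer vectors, one CCW ring per cell
#' @param types character vector of cell types (see [CELL_TYPES])
#' @param pinned optional logical vector marking immobile vertices
#' @return object of class `cell_complex`
#' @export
new_cell_complex <- function(vertices, rings, types, pinned = NULL) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  ncell <- length(rings)
  if (length(types) != ncell) stop("one type per ring required")
  bad <- setdiff(unique(types), CELL_TYPES)
  if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  nV0 <- nrow(vertices)
  centers <- matrix(0, ncell, 2)
  for (i in seq_len(ncell)) {
    xy <- vertices[rings[[i]], , drop = FALSE]
    a <- polygon_area(xy)
    if (a <= 0) stop("cell ", i, ": ring must be counter-clockwise with positive area")
    centers[i, ] <- polygon_centroid(xy)
  }
  V <- rbind(vertices, centers)
  if (is.null(pinned)) pinned <- rep(FALSE, nV0)
  pinned <- c(pinned, rep(FALSE, ncell))
  cc <- list(
    V = V,
    pinned = pinned,
    rings = rings,
    cells = list(
      id = seq_len(ncell),
      type = as.character(types),
      IAA = numeric(ncell), PIN = numeric(ncell), AUX1 = numeric(ncell),
      REG = numeric(ncell), POL = numeric(ncell),
      afx = numeric(ncell), afy = numeric(ncell),
      A_max = rep(Inf, ncell), parity = integer(ncell),
      kd_PIN = rep(1, ncell), kd_AUX1 = rep(1, ncell),
      b_IAA = numeric(ncell),
      center = nV0 + seq_len(ncell),
      row = rep(NA_integer_, ncell),
      growth_factor = rep(1, ncell),
      kE = rep(1, ncell),
      A_rest = numeric(ncell)
    ),
    next_id = ncell + 1L,
    wall_map = NULL, side_map = NULL, spoke_map = NULL,
    meta = list()
  )
  class(cc) <- "cell_complex"
  cc <- index_complex(cc)
  g <- cc_geometry(cc)
  cc$cells$A_rest <- g$cell_A
  cc
}

#' @export
print.cell_complex <- function(x, ...) {
  cat("<cell_complex>", length(x$rings), "cells,", x$nw, "walls,",
      nrow(x$V), "vertices\n")
  print(table(x$cells$type))
  invisible(x)
}

# Save all per-wall / per-side / per-spoke state into lookup maps keyed by
# vertex identity, so that a topology edit followed by index_complex()
# carries the biochemical state over.
species_to_maps <- function(cc) {
  wm <- new.env(hash = TRUE, parent = emptyenv())
  sm <- new.env(hash = TRUE, parent = emptyenv())
  km <- new.env(hash = TRUE, parent = emptyenv())
  wk <- wall_key(cc$wall_v1, cc$wall_v2)
  for (w in seq_len(cc$nw))
    assign(wk[w], c(cc$wall_IAA[w], cc$wall_rest[w]), envir = wm)
  sk <- side_key(cc$side_cell, cc$side_from, cc$side_to)
  for (s in seq_len(cc$ns))
    assign(sk[s], c(cc$side_PIN[s], cc$side_AUX1[s], cc$side_REG[s], cc$side_POL[s]),
           envir = sm)
  kk <- spoke_key(cc$spoke_cell, cc$spoke_v)
  for (k in seq_along(cc$spoke_cell))
    assign(kk[k], cc$spoke_rest[k], envir = km)
  cc$wall_map <- wm; cc$side_map <- sm; cc$spoke_map <- km
  cc
}

# Rebuild every derived structure from (V, rings, cells): walls, membrane
# sides in ring order, spokes, apoplast adjacency, constraint scatter
# matrices. Per-wall and per-side state is restored from the maps written
# by species_to_maps(), or initialized fresh.
index_complex <- function(cc) {
  ncell <- length(cc$rings)
  nvert <- nrow(cc$V)
  nedge <- sum(lengths(cc$rings))

  wenv <- new.env(hash = TRUE, parent = emptyenv())
  wall_v1 <- integer(nedge); wall_v2 <- integer(nedge)
  wall_ca <- integer(nedge); wall_cb <- rep(NA_integer_, nedge)
  nw <- 0L
  side_wall <- integer(nedge); side_cell <- integer(nedge)
  side_from <- integer(nedge); side_to <- integer(nedge)
  ns <- 0L
  for (ci in seq_len(ncell)) {
    r <- cc$rings[[ci]]
    m <- length(r)
    nx <- c(r[-1], r[1])
    for (e in seq_len(m)) {
      a <- r[e]; b <- nx[e]
      key <- wall_key(a, b)
      w <- wenv[[key]]
      if (is.null(w)) {
        nw <- nw + 1L; w <- nw
        wall_v1[w] <- a; wall_v2[w] <- b; wall_ca[w] <- ci
        assign(key, w, envir = wenv)
      } else {
        if (!is.na(wall_cb[w]))
          stop("mesh invalid: wall ", key, " shared by more than 2 cells")
        wall_cb[w] <- ci
      }
      ns <- ns + 1L
      side_wall[ns] <- w; side_cell[ns] <- ci
      side_from[ns] <- a; side_to[ns] <- b
    }
  }
  length(wall_v1) <- nw; length(wall_v2) <- nw
  length(wall_ca) <- nw; length(wall_cb) <- nw

  cc$nw <- nw; cc$ns <- ns
  cc$wall_v1 <- wall_v1; cc$wall_v2 <- wall_v2
  cc$wall_ca <- wall_ca; cc$wall_cb <- wall_cb
  cc$side_wall <- side_wall[seq_len(ns)]; cc$side_cell <- side_cell[seq_len(ns)]
  cc$side_from <- side_from[seq_len(ns)]; cc$side_to <- side_to[seq_len(ns)]

  # per-cell CSR over sides (sides are emitted cell by cell, in ring order)
  cnt <- lengths(cc$rings)
  cc$cell_side_ptr <- c(1L, 1L + cumsum(cnt))
  # ring neighbours of each side within its cell
  off <- rep(cc$cell_side_ptr[-length(cc$cell_side_ptr)], cnt)
  pos <- seq_len(ns) - off            # 0-based position in ring
  cc$side_next <- off + (pos + 1L) %% rep(cnt, cnt)
  cc$side_prev <- off + (pos - 1L) %% rep(cnt, cnt)

  # wall / side state from maps
  wlen <- sqrt(rowSums((cc$V[cc$wall_v2, , drop = FALSE] -
                          cc$V[cc$wall_v1, , drop = FALSE])^2))
  cc$wall_IAA <- numeric(nw); cc$wall_rest <- wlen
  if (!is.null(cc$wall_map)) {
    wk <- wall_key(cc$wall_v1, cc$wall_v2)
    for (w in seq_len(nw)) {
      v <- cc$wall_map[[wk[w]]]
      if (!is.null(v)) { cc$wall_IAA[w] <- v[1]; cc$wall_rest[w] <- v[2] }
    }
  }
  cc$side_PIN <- numeric(ns); cc$side_AUX1 <- numeric(ns)
  cc$side_REG <- numeric(ns); cc$side_POL <- numeric(ns)
  if (!is.null(cc$side_map)) {
    sk <- side_key(cc$side_cell, cc$side_from, cc$side_to)
    for (s in seq_len(ns)) {
      v <- cc$side_map[[sk[s]]]
      if (!is.null(v)) {
        cc$side_PIN[s] <- v[1]; cc$side_AUX1[s] <- v[2]
        cc$side_REG[s] <- v[3]; cc$side_POL[s] <- v[4]
      }
    }
  }

  # spokes: cell center to each ring vertex
  cc$spoke_cell <- rep(seq_len(ncell), cnt)
  cc$spoke_v <- unlist(cc$rings, use.names = FALSE)
  cc$spoke_center <- cc$cells$center[cc$spoke_cell]
  sp_len <- sqrt(rowSums((cc$V[cc$spoke_v, , drop = FALSE] -
                            cc$V[cc$spoke_center, , drop = FALSE])^2))
  cc$spoke_rest <- sp_len
  if (!is.null(cc$spoke_map)) {
    kk <- spoke_key(cc$spoke_cell, cc$spoke_v)
    for (k in seq_along(kk)) {
      v <- cc$spoke_map[[kk[k]]]
      if (!is.null(v)) cc$spoke_rest[k] <- v
    }
  }
  cc$wall_map <- cc$side_map <- cc$spoke_map <- NULL

  # ring CSR arrays (identical ordering to sides): vertex, its prev/next
  rv <- cc$spoke_v
  rc <- cc$spoke_cell
  nxt <- cc$side_to                       # next ring vertex of entry
  prv <- rv[cc$side_prev]                 # ring entries align with sides
  cc$ring_vertex <- rv; cc$ring_cell <- rc
  cc$ring_next_v <- nxt; cc$ring_prev_v <- prv

  # shape-matching groups: ring vertices + center, per cell
  gv <- integer(ns + ncell); gc <- integer(ns + ncell)
  k <- 1L
  for (ci in seq_len(ncell)) {
    r <- cc$rings[[ci]]
    m <- length(r)
    gv[k:(k + m - 1L)] <- r
    gc[k:(k + m - 1L)] <- ci
    gv[k + m] <- cc$cells$center[ci]
    gc[k + m] <- ci
    k <- k + m + 1L
  }
  cc$grp_vertex <- gv; cc$grp_cell <- gc
  gcnt <- cnt + 1L
  mu <- rowsum_by(cc$V[gv, 1], gc, ncell) / gcnt
  mv <- rowsum_by(cc$V[gv, 2], gc, ncell) / gcnt
  cc$shape_qx <- cc$V[gv, 1] - mu[gc]
  cc$shape_qy <- cc$V[gv, 2] - mv[gc]

  # bending triples = (prev, v, next) around each ring vertex
  cc$bend_a <- prv; cc$bend_b <- rv; cc$bend_c <- nxt
  cc$bend_rest <- signed_angle(cc$V, cc$bend_a, cc$bend_b, cc$bend_c)

  # apoplast diffusion pairs: walls sharing a vertex
  vw_i <- c(cc$wall_v1, cc$wall_v2)
  vw_w <- c(seq_len(nw), seq_len(nw))
  o <- order(vw_i)
  vw_i <- vw_i[o]; vw_w <- vw_w[o]
  pi <- integer(0); pj <- integer(0)
  if (nw > 0) {
    grp_start <- which(!duplicated(vw_i))
    grp_end <- c(grp_start[-1] - 1L, length(vw_i))
    npairs <- sum(choose(grp_end - grp_start + 1L, 2))
    pi <- integer(npairs); pj <- integer(npairs)
    k <- 1L
    for (g in seq_along(grp_start)) {
      ws <- vw_w[grp_start[g]:grp_end[g]]
      m <- length(ws)
      if (m >= 2) {
        cb <- utils::combn(ws, 2)
        nn <- ncol(cb)
        pi[k:(k + nn - 1L)] <- cb[1, ]
        pj[k:(k + nn - 1L)] <- cb[2, ]
        k <- k + nn
      }
    }
    length(pi) <- k - 1L; length(pj) <- k - 1L
  }
  cc$pair_i <- pi; cc$pair_j <- pj

  # shape group CSR pointer (ring + center per cell)
  cc$grp_ptr <- c(1L, 1L + cumsum(cnt + 1L))

  # per-wall gather of its 1-2 side indices (pad index ns+1 reads a 0)
  ws1 <- integer(nw); ws2 <- rep(ns + 1L, nw)
  for (s in seq_len(ns)) {
    w <- cc$side_wall[s]
    if (ws1[w] == 0L) ws1[w] <- s else ws2[w] <- s
  }
  cc$wall_side1 <- ws1; cc$wall_side2 <- ws2

  # scatter-add structures for vertex accumulation (Jacobi averaging by
  # the per-vertex constraint counts, floored at 1)
  cc$sc_wall <- make_scatter(c(cc$wall_v1, cc$wall_v2), nvert)
  cc$sc_spoke <- make_scatter(c(cc$spoke_center, cc$spoke_v), nvert)
  cc$sc_ring <- make_scatter(rv, nvert)
  cc$sc_grp <- make_scatter(gv, nvert)
  cc$sc_bend <- make_scatter(c(cc$bend_a, cc$bend_c), nvert)
  # borders use softened averaging (sqrt of the constraint count): the
  # wall family must be able to override the un-averaged XPBD pressure
  # when auxin stiffens the walls
  cc$cnt_dist <- sqrt(pmax(cc$sc_wall$cnt, 1))
  cc$cnt_sp <- pmax(cc$sc_spoke$cnt, 1)
  cc$cnt_grp <- pmax(cc$sc_grp$cnt, 1)
  cc$cnt_bend <- pmax(cc$sc_bend$cnt, 1)
  # symmetric apoplast-diffusion pair arrays, CSR-sorted by the first wall
  first <- c(pi, pj); other <- c(pj, pi)
  if (length(first)) {
    o <- order(first)
    fs <- first[o]
    starts <- which(!duplicated(fs))
    cc$pairw_first <- fs
    cc$pairw_other <- other[o]
    cc$pairw_wall <- fs[starts]
    cc$pairw_ptr <- c(starts, length(fs) + 1L)
  } else {
    cc$pairw_first <- cc$pairw_other <- cc$pairw_wall <- integer(0)
    cc$pairw_ptr <- 1L
  }
  cc$inv_mass <- as.numeric(!cc$pinned)
  # cached type masks (types only change together with the topology)
  ty <- cc$cells$type
  cc$is_source <- ty == "Source"
  cc$is_sink <- ty == "Sink"
  cc$is_nongrowing <- ty %in% NON_GROWING_TYPES
  cc$is_uniform_pin <- ty %in% UNIFORM_PIN_TYPES
  cc <- build_side_pairs(cc)
  cc
}

# rowsum over groups 1..ng (groups need not all be present)
rowsum_by <- function(x, g, ng) {
  out <- numeric(ng)
  s <- rowsum(x, g, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# CSR pointer over a vector of contiguous ascending group ids
group_ptr <- function(g) {
  c(which(!duplicated(g)), length(g) + 1L)
}

# group sums over a CSR partition: ptr has length ngroups+1, entries of x
# for group i occupy ptr[i]..(ptr[i+1]-1)
csr_sum <- function(x, ptr) {
  cs <- c(0, cumsum(x))
  cs[ptr[-1]] - cs[ptr[-length(ptr)]]
}

# index (into x) of the per-group maximum for a CSR partition
csr_which_max <- function(x, ptr, grp) {
  o <- order(grp, x)
  og <- grp[o]
  o[which(!duplicated(og, fromLast = TRUE))]  # one index per present group
}

# scatter-add structure: accumulate per-constraint values onto their target
# vertices without sparse matrices. ord sorts entries by target; vert lists
# the distinct targets; ptr is the CSR pointer over vert.
make_scatter <- function(targets, nvert) {
  o <- order(targets)
  ts <- targets[o]
  starts <- which(!duplicated(ts))
  list(ord = o, vert = ts[starts], ptr = c(starts, length(ts) + 1L),
       cnt = tabulate(targets, nvert))
}

# V[vert, ] += (sum of cx, cy per target) / div[vert]
scatter_add <- function(V, sc, cx, cy, div = NULL) {
  sx <- csr_sum(cx[sc$ord], sc$ptr)
  sy <- csr_sum(cy[sc$ord], sc$ptr)
  if (!is.null(div)) {
    d <- div[sc$vert]
    sx <- sx / d; sy <- sy / d
  }
  V[sc$vert, 1] <- V[sc$vert, 1] + sx
  V[sc$vert, 2] <- V[sc$vert, 2] + sy
  V
}

signed_angle <- function(V, a, b, c) {
  ux <- V[a, 1] - V[b, 1]; uy <- V[a, 2] - V[b, 2]
  vx <- V[c, 1] - V[b, 1]; vy <- V[c, 2] - V[b, 2]
  atan2(ux * vy - uy * vx, ux * vx + uy * vy)
}

# Per-step geometry of the whole complex (vectorized).
cc_geometry <- function(cc) {
  V <- cc$V
  ncell <- length(cc$rings)
  dx <- V[cc$wall_v2, 1] - V[cc$wall_v1, 1]
  dy <- V[cc$wall_v2, 2] - V[cc$wall_v1, 2]
  wall_L <- sqrt(dx^2 + dy^2)
  wL0 <- wall_L
  wL0[wL0 == 0] <- 1
  wall_ux <- dx / wL0; wall_uy <- dy / wL0

  sdx <- V[cc$side_to, 1] - V[cc$side_from, 1]
  sdy <- V[cc$side_to, 2] - V[cc$side_from, 2]
  sL <- sqrt(sdx^2 + sdy^2)
  sL0 <- sL
  sL0[sL0 == 0] <- 1
  side_nx <- sdy / sL0; side_ny <- -sdx / sL0   # outward for a CCW ring
  side_mx <- (V[cc$side_to, 1] + V[cc$side_from, 1]) / 2
  side_my <- (V[cc$side_to, 2] + V[cc$side_from, 2]) / 2

  rv <- cc$ring_vertex; nv <- cc$ring_next_v
  ptr <- cc$cell_side_ptr       # ring entries align with sides (CSR by cell)
  x <- V[rv, 1]; y <- V[rv, 2]; xn <- V[nv, 1]; yn <- V[nv, 2]
  cr <- x * yn - xn * y
  A <- 0.5 * csr_sum(cr, ptr)
  A_safe <- A
  A_safe[abs(A_safe) <= 1e-12] <- 1e-12
  cx <- csr_sum((x + xn) * cr, ptr) / (6 * A_safe)
  cy <- csr_sum((y + yn) * cr, ptr) / (6 * A_safe)
  sxx <- csr_sum((x^2 + x * xn + xn^2) * cr, ptr) / 12
  syy <- csr_sum((y^2 + y * yn + yn^2) * cr, ptr) / 12
  sxy <- csr_sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr, ptr) / 24
  cxx <- sxx / A_safe - cx^2
  cyy <- syy / A_safe - cy^2
  cxy <- sxy / A_safe - cx * cy
  tr2 <- (cxx + cyy) / 2
  dd <- sqrt(pmax(0, (cxx - cyy)^2 / 4 + cxy^2))
  l1 <- pmax(tr2 + dd, 0); l2 <- pmax(tr2 - dd, 0)
  v1x <- ifelse(abs(cxy) > 1e-14, l1 - cyy, ifelse(cxx >= cyy, 1, 0))
  v1y <- ifelse(abs(cxy) > 1e-14, cxy, ifelse(cxx >= cyy, 0, 1))
  nrm <- sqrt(v1x^2 + v1y^2); nrm[nrm == 0] <- 1
  v1x <- v1x / nrm; v1y <- v1y / nrm

  sumL <- csr_sum(sL, ptr)
  list(
    wall_L = wall_L, wall_ux = wall_ux, wall_uy = wall_uy,
    side_L = sL, side_nx = side_nx, side_ny = side_ny,
    side_mx = side_mx, side_my = side_my,
    cell_A = A, cell_cx = cx, cell_cy = cy, cell_sumL = sumL,
    ax_x = v1x, ax_y = v1y,
    ax_len_max = 2 * sqrt(l1), ax_len_min = 2 * sqrt(l2),
    ax_ratio = ifelse(l1 > 0, sqrt(l2 / l1), 1)
  )
}

#' Geometric descriptors of one cell
#'
#' Area (shoelace), polygon centroid, principal axes from the polygon's
#' second area moments, and the ordered membrane sections with their
#' lengths, outward unit normals and midpoints.
#'
#' @param cc a [cell_complex]
#' @param cell cell index
#' @return list with `area`, `centroid`, `axisMax`, `axisMin` (vectors whose
#'   lengths are the principal extents), `sections` (data.frame with
#'   `L_mem`, `nx`, `ny`, `mx`, `my`, `wall`)
#' @export
cell_geometry <- function(cc, cell) {
  r <- cc$rings[[cell]]
  xy <- cc$V[r, , drop = FALSE]
  a <- polygon_area(xy)
  if (abs(a) < 1e-12) stop("cell ", cell, ": degenerate (zero-area) polygon")
  ax <- polygon_principal_axes(xy)
  idx <- which(cc$side_cell == cell)
  g <- cc_geometry(cc)
  list(
    area = a,
    centroid = polygon_centroid(xy),
    axisMax = ax$dir[1, ] * ax$len[1],
    axisMin = ax$dir[2, ] * ax$len[2],
    sections = data.frame(
      L_mem = g$side_L[idx], nx = g$side_nx[idx], ny = g$side_ny[idx],
      mx = g$side_mx[idx], my = g$side_my[idx], wall = cc$side_wall[idx]
    )
  )
}

#' Validate the structural invariants of a cell complex
#'
#' Checks that every cell ring is a simple CCW polygon, that each wall
#' adjoins one or two cells with symmetric adjacency, that the centroid fan
#' triangulation tiles each polygon, and that all state is within bounds.
#'
#' @param cc a [cell_complex]
#' @param tol relative tolerance for the triangulation area check
#' @return `TRUE` invisibly; stops with a message on violation
#' @export
validate_complex <- function(cc, tol = 1e-9) {
  ncell <- length(cc$rings)
  g <- cc_geometry(cc)
  for (ci in seq_len(ncell)) {
    xy <- cc$V[cc$rings[[ci]], , drop = FALSE]
    a <- polygon_area(xy)
    if (a <= 0) stop("cell ", ci, ": ring not counter-clockwise")
    if (!polygon_is_simple(xy)) stop("cell ", ci, ": polygon not simple")
    # fan triangulation from the center vertex must tile the polygon
    cen <- cc$V[cc$cells$center[ci], ]
    r <- cc$rings[[ci]]; nx <- c(r[-1], r[1])
    tri <- 0.5 * abs((cc$V[r, 1] - cen[1]) * (cc$V[nx, 2] - cen[2]) -
                       (cc$V[nx, 1] - cen[1]) * (cc$V[r, 2] - cen[2]))
    if (abs(sum(tri) - a) > tol * a + 1e-12)
      stop("cell ", ci, ": fan triangulation does not tile polygon (center outside?)")
  }
  # adjacency symmetry: every side's wall lists the side's cell
  ok <- cc$wall_ca[cc$side_wall] == cc$side_cell |
    (!is.na(cc$wall_cb[cc$side_wall]) & cc$wall_cb[cc$side_wall] == cc$side_cell)
  if (!all(ok)) stop("wall adjacency not symmetric")
  with(cc$cells, {
    if (any(IAA < 0) || any(PIN < 0) || any(AUX1 < 0) || any(REG < 0) || any(POL < 0))
      stop("negative cytoplasmic concentration")
    if (any(sqrt(afx^2 + afy^2) > 1 + 1e-9)) stop("|af| exceeds 1")
  })
  if (any(cc$wall_IAA < 0)) stop("negative apoplastic auxin")
  if (any(cc$side_PIN < 0) || any(cc$side_AUX1 < 0))
    stop("negative membrane carrier amount")
  invisible(TRUE)
}

af_matrix <- function(cc) cbind(cc$cells$afx, cc$cells$afy)

#' Configuration of the synthetic heart-stage root template
#'
#' The generator produces an idealized rectangular-file layout tapering
#' toward the tip: `n_files` tissue files per side of the midline
#' (inside-out: vascular, pericycle, endodermis, cortex, epidermis),
#' `cells_per_file` body cells per file, and a fixed five-row tip housing a
#' stem-cell niche with exactly two QC cells, columella initials and
#' columella below them, CEI/CEID and epidermis/LRC initials flanking, and
#' an LRC sheath. The topmost central cells are auxin Sources and the
#' topmost outer epidermal cells auxin Sinks.
#'
#' @param n_files tissue files per side (default 5)
#' @param cells_per_file body cells per file above the niche (default 8)
#' @param widths file widths in um, innermost first, recycled to `n_files`
#' @param body_height body cell height (um)
#' @param tip_height tip-row cell height (um)
#' @param taper fractional narrowing of the organ at the tip (0..0.9)
#' @return list of class `root_template_config`
#' @export
root_template_config <- function(n_files = 5L, cells_per_file = 8L,
                                 widths = c(3, 3, 5, 7, 7),
                                 body_height = 8, tip_height = 4,
                                 taper = 0.3) {
  if (n_files < 1) stop("template configuration error: n_files must be >= 1")
  if (cells_per_file < 1) stop("template configuration error: cells_per_file must be >= 1")
  structure(list(n_files = as.integer(n_files),
                 cells_per_file = as.integer(cells_per_file),
                 widths = rep_len(widths, n_files),
                 body_height = body_height, tip_height = tip_height,
                 taper = taper),
            class = "root_template_config")
}

N_TIP_ROWS <- 5L

# type of body column k (1 = innermost) for n files per side
body_tissue <- function(k, n_files) {
  tiss <- c("Vascular", "Pericycle", "Endodermis", "Cortex", "Epidermis")
  if (n_files <= 5) {
    # innermost stays vascular, outermost epidermis; middle from the list
    idx <- round(seq(1, 5, length.out = n_files))
    tiss[idx[k]]
  } else {
    if (k <= n_files - 4) "Vascular" else tiss[k - (n_files - 5)]
  }
}

# tip rows, counted from the bottom (1..5); k = column distance from
# midline (1 = innermost)
tip_type <- function(rowk, k) {
  switch(rowk,
    `1` = if (k <= 2) "Columella" else "LRC",
    `2` = if (k <= 2) "Columella" else "LRC",
    `3` = if (k <= 2) "ColumellaInitial" else "LRC",
    `4` = if (k == 1) "QC" else if (k == 2) "ColumellaInitial"
          else if (k == 3) "CEI" else "LRC",
    `5` = if (k <= 2) "VascularInitial" else if (k == 3) "CEI"
          else if (k == 4) "CEID" else "EpidermisLRCInitial"
  )
}

#' Generate the synthetic heart-stage root template
#'
#' Builds a valid [cell_complex] with the embryonic root layout described
#' in [root_template_config()]: bilaterally symmetric cell files converging
#' on a stem-cell niche with exactly two QC cells, a columella below the
#' niche, an LRC sheath around the tip, Source cells (shoot-derived auxin
#' influx) at the top of the stele and Sink cells at the top of the
#' epidermis. All anisotropy-factor vectors start at zero (non-polar
#' embryo) and the top vertex row is pinned (attachment to the rest of the
#' embryo). Construction is deterministic.
#'
#' @param config a [root_template_config()]
#' @param A_max_factor division threshold as a multiple of the type's
#'   template mean area
#' @return a [cell_complex]
#' @export
#' @examples
#' cc <- build_synthetic_root_template(root_template_config(cells_per_file = 4))
#' sum(cc$cells$type == "QC")  # exactly 2
build_synthetic_root_template <- function(config = root_template_config(),
                                          A_max_factor = 1.5) {
  if (!inherits(config, "root_template_config"))
    config <- do.call(root_template_config, config)
  nf <- config$n_files
  ncols <- 2L * nf
  nrows <- config$cells_per_file + N_TIP_ROWS
  # column x breaks, mirrored about 0
  halfw <- cumsum(config$widths)
  xb <- c(-rev(halfw), 0, halfw)             # length ncols + 1
  yb <- c(0, cumsum(c(rep(config$tip_height, N_TIP_ROWS),
                      rep(config$body_height, config$cells_per_file))))
  H <- max(yb)
  # taper: narrow toward the tip (y = 0)
  taperf <- function(y) 1 - config$taper * ((H - y) / H)^2
  vid <- function(i, j) (j - 1L) * (ncols + 1L) + i   # i col node, j row node
  V <- matrix(0, (ncols + 1L) * (nrows + 1L), 2)
  for (j in seq_len(nrows + 1L)) {
    f <- taperf(yb[j])
    V[vid(seq_len(ncols + 1L), j), 1] <- xb * f
    V[vid(seq_len(ncols + 1L), j), 2] <- yb[j]
  }
  rings <- vector("list", ncols * nrows)
  types <- character(ncols * nrows)
  rowi <- integer(ncols * nrows); coli <- integer(ncols * nrows)
  ci <- 0L
  for (j in seq_len(nrows)) {
    for (i in seq_len(ncols)) {
      ci <- ci + 1L
      rings[[ci]] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      k <- if (i <= nf) nf + 1L - i else i - nf   # distance from midline
      if (j <= N_TIP_ROWS) {
        types[ci] <- tip_type(as.character(j), min(k, 5L))
        if (nf < 3 && j >= 3 && k > 2) types[ci] <- "LRC"
      } else {
        types[ci] <- body_tissue(k, nf)
      }
      if (j == nrows) {                     # boundary row: every top cell is
        # either an auxin source (central files, shoot-derived influx) or a
        # sink (auxin recycled back to the embryo)
        types[ci] <- if (k == 1) "Source" else "Sink"
      }
      rowi[ci] <- j; coli[ci] <- i
    }
  }
  pinned <- rep(FALSE, nrow(V))
  pinned[vid(seq_len(ncols + 1L), nrows + 1L)] <- TRUE
  cc <- new_cell_complex(V, rings, types, pinned = pinned)
  cc$cells$row <- rowi
  cc$meta <- list(template = config, nrows = nrows, ncols = ncols)
  # division thresholds: per-type multiples of the template mean area
  g <- cc_geometry(cc)
  tab <- tapply(g$cell_A, cc$cells$type, mean) * A_max_factor
  cc$A_max_table <- tab
  cc$cells$A_max <- as.numeric(tab[cc$cells$type])
  cc$cells$A_max[cc$cells$type %in% NON_DIVIDING_TYPES] <- Inf
  init_basal_carriers(cc)
}

# start carriers at their zero-auxin steady state (the embryo expresses
# basal AUX/LAX and PIN before any auxin arrives)
init_basal_carriers <- function(cc, params = default_params()) {
  pt <- params$transport
  a0 <- pt$b_AUX1 / (pt$AUX1_tr + pt$d_AUX1)
  p0 <- pt$b_PIN / (pt$PIN_tr + pt$d_PIN)
  cc$cells$AUX1 <- rep(a0, length(cc$rings))
  cc$cells$PIN <- rep(p0, length(cc$rings))
  g <- cc_geometry(cc)
  frac <- g$side_L / pmax(g$cell_sumL[cc$side_cell], 1e-12)
  cc$side_AUX1 <- pmin(a0 * pt$AUX1_tr * frac / pt$d_AUX1, pt$AUX1_MaxMem)
  d_mem0 <- pt$d_PINmax
  cc$side_PIN <- pmin(p0 * pt$PIN_tr / (cc$side_m * d_mem0), pt$PIN_MaxMem)
  cc
}
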