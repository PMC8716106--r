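# Position-Based Dynamics solver.
#
# The tissue is a triangulated polygon mesh; each solver step predicts
# vertex positions from external forces and then iteratively projects a
# set of constraints (distance, strain, shape, bending, XPBD pressure)
# directly onto positions. Constraint corrections are weighted by inverse
# masses (w = 0 pins a vertex) and by the iteration-corrected stiffness
# k' = 1 - (1 - k)^(1/n).

#' Iteration-corrected constraint stiffness
#'
#' A constraint with stiffness `k` projected once removes a fraction `k` of
#' the violation. Projected over `n` solver iterations the same `k` would
#' overshoot, so each pass uses `k' = 1 - (1 - k)^(1/n)`, which makes the
#' cumulative correction independent of the iteration count.
#'
#' @param k stiffness in \[0, 1\]
#' @param n number of solver iterations (>= 1)
#' @return the per-iteration stiffness `k'`
#' @export
#' @examples
#' effective_stiffness(0.75, 2) # 0.5
effective_stiffness <- function(k, n) {
  stopifnot(all(k >= 0 & k <= 1), all(n >= 1))
  1 - (1 - k)^(1 / n)
}

#' Project distance constraints
#'
#' For each constraint `C(p1, p2) = |p1 - p2| - d`, computes the
#' inverse-mass-weighted position corrections along the connecting
#' direction. Extension and compression may use different stiffnesses
#' (cell walls are near-incompressible but can be relaxed in extension).
#' Coincident endpoints are skipped with a warning (direction undefined).
#'
#' @param pos vertex positions (n x 2)
#' @param i,j endpoint vertex indices (vectors, one entry per constraint)
#' @param rest rest lengths
#' @param stiffness extension stiffness in \[0,1\] (recycled)
#' @param compress_stiffness compression stiffness (default: same)
#' @param inv_mass per-vertex inverse masses (default all 1)
#' @param n_iter solver iteration count for the k' correction
#' @return list with matrices `d_i`, `d_j` (one correction row per constraint)
#' @export
project_distance <- function(pos, i, j, rest, stiffness = 1,
                             compress_stiffness = stiffness,
                             inv_mass = NULL, n_iter = 1) {
  if (is.null(inv_mass)) inv_mass <- rep(1, nrow(pos))
  dx <- pos[i, 1] - pos[j, 1]
  dy <- pos[i, 2] - pos[j, 2]
  L <- sqrt(dx^2 + dy^2)
  bad <- L < 1e-12
  if (any(bad)) {
    warning("skipping ", sum(bad), " distance constraint(s) with coincident points")
    L[bad] <- 1
  }
  C <- L - rest
  ke <- rep_len(stiffness, length(C))
  k <- rep_len(compress_stiffness, length(C))
  ext <- C > 0
  k[ext] <- ke[ext]
  kp <- effective_stiffness(k, n_iter)
  wi <- inv_mass[i]; wj <- inv_mass[j]
  ws <- wi + wj
  scale <- kp * C / (L * ws)
  scale[ws <= 0 | bad] <- 0
  list(d_i = cbind(-wi * scale * dx, -wi * scale * dy),
       d_j = cbind(wj * scale * dx, wj * scale * dy))
}

#' Project the anisotropic strain constraint
#'
#' Restricts expansion along the cell's anisotropy-factor vector: each mesh
#' edge resists extension beyond its rest length with stiffness
#' `strength * |af| * (u_edge . u_af)^2`, so edges aligned with the AF are
#' stiffened while edges orthogonal to it are unconstrained. Compression is
#' not opposed (the constraint restricts growth, not shrinkage).
#'
#' @inheritParams project_distance
#' @param afx,afy AF vector assigned to each edge (from the owning cell)
#' @param strength overall scale of the constraint
#' @return list with matrices `d_i`, `d_j`
#' @export
project_strain <- function(pos, i, j, rest, afx, afy, strength = 1,
                           inv_mass = NULL, n_iter = 1) {
  dx <- pos[i, 1] - pos[j, 1]
  dy <- pos[i, 2] - pos[j, 2]
  L <- sqrt(dx^2 + dy^2)
  L[L < 1e-12] <- 1
  afm <- sqrt(afx^2 + afy^2)
  ux <- ifelse(afm > 0, afx / pmax(afm, 1e-12), 0)
  uy <- ifelse(afm > 0, afy / pmax(afm, 1e-12), 0)
  align2 <- ((dx * ux + dy * uy) / L)^2
  k <- pmin(1, strength * afm * align2)
  project_distance(pos, i, j, rest, stiffness = k, compress_stiffness = 0,
                   inv_mass = inv_mass, n_iter = n_iter)
}

#' Project shape-matching constraints
#'
#' Finds, per cell, the least-squares rigid transform (rotation +
#' translation) of the stored rest shape onto the current vertex group and
#' pulls each vertex toward its goal position. Prevents cell collapse and
#' preserves the cytoskeleton's resting arrangement while allowing growth
#' (rest shapes yield plastically elsewhere).
#'
#' @inheritParams project_distance
#' @param group_vertex vertex index per group entry
#' @param group_cell group (cell) id per entry; entries must be grouped
#' @param qx,qy rest-shape offsets per entry (centered per group)
#' @param stiffness shape stiffness in \[0,1\]
#' @return matrix of corrections, one row per group entry
#' @export
project_shape <- function(pos, group_vertex, group_cell, qx, qy,
                          stiffness = 1, inv_mass = NULL, n_iter = 1,
                          ptr = NULL) {
  if (is.null(inv_mass)) inv_mass <- rep(1, nrow(pos))
  if (is.null(ptr)) ptr <- group_ptr(group_cell)
  cnt <- diff(ptr)
  px <- pos[group_vertex, 1]; py <- pos[group_vertex, 2]
  mx <- csr_sum(px, ptr) / cnt
  my <- csr_sum(py, ptr) / cnt
  rx <- px - mx[group_cell]; ry <- py - my[group_cell]
  a <- csr_sum(rx * qx + ry * qy, ptr)
  b <- csr_sum(ry * qx - rx * qy, ptr)
  th <- atan2(b, a)
  co <- cos(th)[group_cell]; si <- sin(th)[group_cell]
  gx <- mx[group_cell] + co * qx - si * qy
  gy <- my[group_cell] + si * qx + co * qy
  kp <- effective_stiffness(rep_len(stiffness, 1), n_iter)
  w <- inv_mass[group_vertex]
  cbind(kp * w * (gx - px), kp * w * (gy - py))
}

#' Project bending constraints
#'
#' Restores the rest angle at each wall vertex `b` between the adjacent
#' border edges `(b,a)` and `(b,c)`, preventing wall angles from drifting
#' and cells from collapsing at the resting state.
#'
#' @inheritParams project_distance
#' @param a,b,c vertex index triples (angle measured at `b`)
#' @param rest_angle signed rest angles (radians)
#' @param stiffness bending stiffness in \[0,1\]
#' @return list with matrices `d_a`, `d_c` (vertex `b` is left in place)
#' @export
project_bending <- function(pos, a, b, c, rest_angle, stiffness = 1,
                            inv_mass = NULL, n_iter = 1) {
  if (is.null(inv_mass)) inv_mass <- rep(1, nrow(pos))
  ux <- pos[a, 1] - pos[b, 1]; uy <- pos[a, 2] - pos[b, 2]
  vx <- pos[c, 1] - pos[b, 1]; vy <- pos[c, 2] - pos[b, 2]
  th <- atan2(ux * vy - uy * vx, ux * vx + uy * vy)
  dth <- (rest_angle - th + pi) %% (2 * pi) - pi
  kp <- effective_stiffness(rep_len(stiffness, 1), n_iter)
  half <- kp * dth / 2
  wa <- as.numeric(inv_mass[a] > 0); wc <- as.numeric(inv_mass[c] > 0)
  # rotate v by +half (opens the angle), u by -half
  cu <- cos(-half); su <- sin(-half)
  cv <- cos(half); sv <- sin(half)
  list(d_a = cbind(wa * (cu * ux - su * uy - ux), wa * (su * ux + cu * uy - uy)),
       d_c = cbind(wc * (cv * vx - sv * vy - vx), wc * (sv * vx + cv * vy - vy)))
}

#' Project XPBD pressure (area) constraints
#'
#' Drives each cell polygon's area toward a target area (rest area times
#' the turgor overpressure) through the compliant XPBD formulation: the
#' Lagrange multiplier `lambda` accumulates across iterations and the
#' compliance `alpha-tilde = alpha / dt^2` sets how strongly turgor
#' competes with wall stiffness.
#'
#' @inheritParams project_distance
#' @param ring_vertex,ring_cell,ring_prev,ring_next ring CSR arrays
#' @param target target areas per cell
#' @param compliance XPBD compliance (alpha / dt^2)
#' @param lambda accumulated multipliers per cell (start each step at 0)
#' @return list with `dP` (corrections per ring entry) and updated `lambda`
#' @export
project_pressure <- function(pos, ring_vertex, ring_cell, ring_prev, ring_next,
                             target, compliance, lambda, inv_mass = NULL,
                             ptr = NULL) {
  if (is.null(inv_mass)) inv_mass <- rep(1, nrow(pos))
  if (is.null(ptr)) ptr <- group_ptr(ring_cell)
  x <- pos[ring_vertex, 1]; y <- pos[ring_vertex, 2]
  xn <- pos[ring_next, 1]; yn <- pos[ring_next, 2]
  A <- 0.5 * csr_sum(x * yn - xn * y, ptr)
  C <- A - target
  gx <- 0.5 * (pos[ring_next, 2] - pos[ring_prev, 2])
  gy <- 0.5 * (pos[ring_prev, 1] - pos[ring_next, 1])
  w <- inv_mass[ring_vertex]
  denom <- csr_sum(w * (gx^2 + gy^2), ptr) + compliance
  dl <- (-C - compliance * lambda) / denom
  list(dP = cbind(w * dl[ring_cell] * gx, w * dl[ring_cell] * gy),
       lambda = lambda + dl)
}

#' One generic PBD step over an explicit constraint list
#'
#' Reference implementation of the solver loop: velocities are updated
#' from external forces, positions predicted, the constraint list is
#' projected for `iterations` passes, and velocities are recomputed from
#' the positional change. Intended for small systems and testing; the
#' simulation engine uses the same projection kernels on indexed arrays.
#'
#' @param state list with `pos` (n x 2), `vel` (n x 2), `inv_mass` (n)
#' @param constraints list of constraints; each a list with `kind` in
#'   `c("distance", "strain", "shape", "bending", "pressure")` plus the
#'   fields the corresponding projector needs (see the `project_*`
#'   functions)
#' @param forces external force matrix (n x 2), default zero
#' @param dt time step
#' @param iterations solver iterations
#' @return updated state
#' @export
pbd_step <- function(state, constraints, forces = NULL, dt = 1, iterations = 1) {
  pos <- state$pos
  n <- nrow(pos)
  if (is.null(state$vel)) state$vel <- matrix(0, n, 2)
  if (is.null(state$inv_mass)) state$inv_mass <- rep(1, n)
  if (is.null(forces)) forces <- matrix(0, n, 2)
  prev <- pos
  vel <- state$vel + dt * forces * state$inv_mass
  pos <- pos + dt * vel
  lambda <- list()
  for (it in seq_len(iterations)) {
    for (ki in seq_along(constraints)) {
      cn <- constraints[[ki]]
      pos <- switch(cn$kind,
        distance = {
          pr <- project_distance(pos, cn$i, cn$j, cn$rest,
                                 stiffness = cn$k %||% 1,
                                 compress_stiffness = cn$k_compress %||% (cn$k %||% 1),
                                 inv_mass = state$inv_mass, n_iter = iterations)
          pos[cn$i, ] <- pos[cn$i, ] + pr$d_i
          pos[cn$j, ] <- pos[cn$j, ] + pr$d_j
          pos
        },
        strain = {
          pr <- project_strain(pos, cn$i, cn$j, cn$rest, cn$afx, cn$afy,
                               strength = cn$strength %||% 1,
                               inv_mass = state$inv_mass, n_iter = iterations)
          pos[cn$i, ] <- pos[cn$i, ] + pr$d_i
          pos[cn$j, ] <- pos[cn$j, ] + pr$d_j
          pos
        },
        shape = {
          d <- project_shape(pos, cn$group_vertex, cn$group_cell, cn$qx, cn$qy,
                             stiffness = cn$k %||% 1,
                             inv_mass = state$inv_mass, n_iter = iterations)
          pos[cn$group_vertex, ] <- pos[cn$group_vertex, ] + d
          pos
        },
        bending = {
          pr <- project_bending(pos, cn$a, cn$b, cn$c, cn$rest_angle,
                                stiffness = cn$k %||% 1,
                                inv_mass = state$inv_mass, n_iter = iterations)
          pos[cn$a, ] <- pos[cn$a, ] + pr$d_a
          pos[cn$c, ] <- pos[cn$c, ] + pr$d_c
          pos
        },
        pressure = {
          lam <- lambda[[as.character(ki)]] %||% numeric(length(cn$target))
          pr <- project_pressure(pos, cn$ring_vertex, cn$ring_cell,
                                 cn$ring_prev, cn$ring_next, cn$target,
                                 compliance = cn$compliance %||% 0, lambda = lam,
                                 inv_mass = state$inv_mass)
          lambda[[as.character(ki)]] <- pr$lambda
          pos[cn$ring_vertex, ] <- pos[cn$ring_vertex, ] + pr$dP
          pos
        },
        stop("unknown constraint kind: ", cn$kind))
    }
    if (any(!is.finite(pos)))
      stop("PBD solver divergence: non-finite position at iteration ", it)
  }
  state$vel <- (pos - prev) / dt
  state$pos <- pos
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- engine-side mechanics ---------------------------------------------

# Extension stiffness of each wall: most-relaxed adjoining cell governs.
wall_kE <- function(cc) {
  kE <- cc$cells$kE
  ka <- kE[cc$wall_ca]
  kb <- ifelse(is.na(cc$wall_cb), ka, kE[pmax(cc$wall_cb, 1L)])
  pmin(ka, kb)
}

# One full mechanics step on the complex: quasi-static PBD (growth is far
# slower than elastic relaxation, so predicted velocities are zero and the
# projected displacement is the step's motion).
mech_step <- function(cc, params) {
  pm <- params$mechanics
  n_it <- pm$iterations
  V <- cc$V
  w <- cc$inv_mass
  ncell <- length(cc$rings)
  gf <- cc$cells$growth_factor
  if (!identical(pm$all_cells_grow, TRUE))
    gf[cc$is_nongrowing %||% (cc$cells$type %in% NON_GROWING_TYPES)] <- 0
  target <- cc$cells$A_rest * (1 + pm$overpressure * gf)
  kE <- wall_kE(cc)
  af_w <- edge_af(cc)     # af per wall then per spoke
  lambda <- numeric(ncell)
  for (it in seq_len(n_it)) {
    # pressure (XPBD)
    pr <- project_pressure(V, cc$ring_vertex, cc$ring_cell, cc$ring_prev_v,
                           cc$ring_next_v, target, pm$pressure_compliance,
                           lambda, inv_mass = w, ptr = cc$cell_side_ptr)
    lambda <- pr$lambda
    V <- scatter_add(V, cc$sc_ring, pr$dP[, 1], pr$dP[, 2])
    # walls: auxin-dependent extension stiffness composed with the AF
    # strain stiffening (sequential projections with stiffness k1, k2 act
    # like one projection with 1 - (1-k1)(1-k2))
    ks <- strain_edge_k(V, cc$wall_v1, cc$wall_v2, cc$wall_rest,
                        af_w$wx, af_w$wy, pm$strain_stiffness)
    d <- project_distance(V, cc$wall_v1, cc$wall_v2, cc$wall_rest,
                          stiffness = 1 - (1 - kE) * (1 - ks),
                          compress_stiffness = pm$k_compress,
                          inv_mass = w, n_iter = n_it)
    V <- scatter_add(V, cc$sc_wall, c(d$d_i[, 1], d$d_j[, 1]),
                     c(d$d_i[, 2], d$d_j[, 2]), cc$cnt_dist)
    # spokes (pectin matrix, viscoelastic) + AF strain stiffening
    ks2 <- strain_edge_k(V, cc$spoke_center, cc$spoke_v, cc$spoke_rest,
                         af_w$sx, af_w$sy, pm$strain_stiffness)
    d2 <- project_distance(V, cc$spoke_center, cc$spoke_v, cc$spoke_rest,
                           stiffness = 1 - (1 - pm$k_internal) * (1 - ks2),
                           compress_stiffness = pm$k_internal,
                           inv_mass = w, n_iter = n_it)
    V <- scatter_add(V, cc$sc_spoke, c(d2$d_i[, 1], d2$d_j[, 1]),
                     c(d2$d_i[, 2], d2$d_j[, 2]), cc$cnt_sp)
    # shape matching
    ds <- project_shape(V, cc$grp_vertex, cc$grp_cell, cc$shape_qx, cc$shape_qy,
                        stiffness = pm$k_shape, inv_mass = w, n_iter = n_it,
                        ptr = cc$grp_ptr)
    V <- scatter_add(V, cc$sc_grp, ds[, 1], ds[, 2], cc$cnt_grp)
    # bending
    db <- project_bending(V, cc$bend_a, cc$bend_b, cc$bend_c, cc$bend_rest,
                          stiffness = pm$k_bend, inv_mass = w, n_iter = n_it)
    V <- scatter_add(V, cc$sc_bend, c(db$d_a[, 1], db$d_c[, 1]),
                     c(db$d_a[, 2], db$d_c[, 2]), cc$cnt_bend)
  }
  if (any(!is.finite(V)))
    stop("PBD solver divergence: non-finite vertex position")
  cc$V <- V
  cc
}

# extension-only stiffness of the AF strain constraint on an edge set:
# strength * |af| * cos^2(angle between edge and af)
strain_edge_k <- function(V, i, j, rest, afx, afy, strength) {
  dx <- V[i, 1] - V[j, 1]; dy <- V[i, 2] - V[j, 2]
  L2 <- pmax(dx^2 + dy^2, 1e-24)
  afm <- sqrt(afx^2 + afy^2)
  am <- afm
  am[am == 0] <- 1
  a2 <- (dx * afx / am + dy * afy / am)^2 / L2
  ext <- sqrt(L2) > rest
  pmin(1, strength * afm * a2) * ext
}

# AF vector assigned to each wall (max-|af| adjoining cell) and spoke.
edge_af <- function(cc) {
  afx <- cc$cells$afx; afy <- cc$cells$afy
  m2 <- afx^2 + afy^2
  ca <- cc$wall_ca; cb <- cc$wall_cb
  use_b <- !is.na(cb) & m2[pmax(cb, 1L)] > m2[ca]
  pick <- ifelse(use_b, cb, ca)
  list(wx = afx[pick], wy = afy[pick],
       sx = afx[cc$spoke_cell], sy = afy[cc$spoke_cell])
}

#' Measure wall strain
#'
#' Engineering strain of every wall segment relative to its stored rest
#' length: `eps = (L - L_rest) / L_rest`. Strains feed the anisotropy
#' factor; rest lengths themselves yield plastically toward the current
#' configuration in [plastic_update()] (viscoelastic walls).
#'
#' @param cc a [cell_complex]
#' @return numeric vector of strains, one per wall segment
#' @export
measure_strain <- function(cc) {
  if (any(cc$wall_rest <= 0)) stop("wall with non-positive rest length")
  L <- sqrt((cc$V[cc$wall_v2, 1] - cc$V[cc$wall_v1, 1])^2 +
              (cc$V[cc$wall_v2, 2] - cc$V[cc$wall_v1, 2])^2)
  (L - cc$wall_rest) / cc$wall_rest
}

#' Plastic (viscoelastic) yield of rest quantities
#'
#' Rest lengths of walls and spokes, rest areas, rest angles and rest
#' shapes relax toward the current configuration at `plastic_rate` (per
#' hour), converting sustained elastic strain into permanent growth.
#'
#' @param cc a [cell_complex]
#' @param params parameter list
#' @param dt elapsed model time (hours)
#' @return updated complex
#' @export
plastic_update <- function(cc, params, dt) {
  # plastic flow scales with wall extensibility: an auxin-stiffened wall
  # (kE near 1) creeps essentially not at all, a relaxed wall yields at
  # the full plastic rate
  soft_cell <- 1 - (cc$cells$kE %||% rep(0, length(cc$rings)))
  soft_wall <- 1 - wall_kE(cc)
  f <- 1 - exp(-params$mechanics$plastic_rate * dt)
  g <- cc_geometry(cc)
  cc$wall_rest <- cc$wall_rest + f * soft_wall * (g$wall_L - cc$wall_rest)
  spL <- sqrt(rowSums((cc$V[cc$spoke_v, , drop = FALSE] -
                         cc$V[cc$spoke_center, , drop = FALSE])^2))
  fs <- f * soft_cell[cc$spoke_cell]
  cc$spoke_rest <- cc$spoke_rest + fs * (spL - cc$spoke_rest)
  cc$cells$A_rest <- cc$cells$A_rest + f * soft_cell * (g$cell_A - cc$cells$A_rest)
  cur <- signed_angle(cc$V, cc$bend_a, cc$bend_b, cc$bend_c)
  dth <- (cur - cc$bend_rest + pi) %% (2 * pi) - pi
  fb <- f * soft_cell[cc$ring_cell]
  cc$bend_rest <- cc$bend_rest + fb * dth
  gcnt <- diff(cc$grp_ptr)
  mx <- csr_sum(cc$V[cc$grp_vertex, 1], cc$grp_ptr) / gcnt
  my <- csr_sum(cc$V[cc$grp_vertex, 2], cc$grp_ptr) / gcnt
  fg <- f * soft_cell[cc$grp_cell]
  cc$shape_qx <- cc$shape_qx + fg * (cc$V[cc$grp_vertex, 1] - mx[cc$grp_cell] - cc$shape_qx)
  cc$shape_qy <- cc$shape_qy + fg * (cc$V[cc$grp_vertex, 2] - my[cc$grp_cell] - cc$shape_qy)
  cc
}
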