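# Anisotropy factor (AF) dynamics.
#
# The AF is a per-cell vector (|af| in [0, 1]) abstracting the combined
# action of cortical microtubules, actin and cellulose microfibrils: it
# reorients in response to wall strain, stabilizing orthogonal to the
# dominant deformation, and in turn restricts growth along itself (the
# PBD strain constraint) and gates polar PIN delivery.

#' Update the anisotropy factors of all cells
#'
#' The AF stabilizes orthogonal to the dominant wall deformation and
#' self-reinforces while deformation persists. Per cell: the
#' strain-weighted orientation tensor of wall normals,
#' `M = sum_i |eps_i| n_i n_i^T`, defines the target axis (the normal of
#' the dominant strained walls, i.e. orthogonal to the deformation). The
#' AF rotates toward that axis at rate `af_reorient` and its magnitude
#' follows
#' `m' = m + dt * (gate * (m + R_AF * sum_i |(u(af) . n_i) * eps_i|) - d_AF * m)`:
#' autocatalytic growth plus strain reinforcement while the maximal wall
#' strain exceeds `strain_threshold` (`gate = 1`), pure decay below it.
#' A non-polar cell (`|af| < af_seed`) under threshold strain is seeded
#' along the target axis at magnitude `af_seed`. `|af'|` is clamped to 1.
#'
#' @param cc a [cell_complex]
#' @param eps wall strains from [measure_strain()]
#' @param params parameter list (block `anisotropy`)
#' @param dt elapsed time (hours)
#' @return matrix (ncell x 2) of updated AF vectors
#' @export
update_af <- function(cc, eps, params, dt) {
  pa <- params$anisotropy
  ncell <- length(cc$rings)
  g <- cc_geometry(cc)
  afx <- cc$cells$afx; afy <- cc$cells$afy
  afm <- sqrt(afx^2 + afy^2)

  eps_side <- eps[cc$side_wall]
  nx <- g$side_nx; ny <- g$side_ny
  ae <- abs(eps_side)
  # strain-weighted orientation tensor of wall normals
  Mxx <- csr_sum(ae * nx * nx, cc$cell_side_ptr)
  Mxy <- csr_sum(ae * nx * ny, cc$cell_side_ptr)
  Myy <- csr_sum(ae * ny * ny, cc$cell_side_ptr)
  tr2 <- (Mxx + Myy) / 2
  dd <- sqrt(pmax(0, (Mxx - Myy)^2 / 4 + Mxy^2))
  l1 <- tr2 + dd
  vx <- ifelse(abs(Mxy) > 1e-14, l1 - Myy, ifelse(Mxx >= Myy, 1, 0))
  vy <- ifelse(abs(Mxy) > 1e-14, Mxy, ifelse(Mxx >= Myy, 0, 1))
  vn <- sqrt(vx^2 + vy^2); vn[vn == 0] <- 1
  vx <- vx / vn; vy <- vy / vn

  max_eps <- rep(-Inf, ncell)
  top <- csr_which_max(eps_side, cc$cell_side_ptr, cc$side_cell)
  max_eps[cc$side_cell[top]] <- eps_side[top]
  gate <- max_eps >= pa$strain_threshold

  # seed non-polar cells experiencing threshold strain
  seed <- afm < pa$af_seed & gate
  if (any(seed)) {
    afx[seed] <- vx[seed] * pa$af_seed
    afy[seed] <- vy[seed] * pa$af_seed
    afm[seed] <- pa$af_seed
  }

  ux <- ifelse(afm > 0, afx / pmax(afm, 1e-300), 0)
  uy <- ifelse(afm > 0, afy / pmax(afm, 1e-300), 0)
  # reinforcement: alignment of the AF with strained-wall normals
  S <- csr_sum(abs((ux[cc$side_cell] * nx + uy[cc$side_cell] * ny) * eps_side),
               cc$cell_side_ptr)
  m2 <- afm + dt * (gate * (afm + pa$R_AF * S) - pa$d_AF * afm)
  m2 <- pmin(pmax(m2, 0), 1)
  # rotation toward the target axis (axis is sign-free: pick the closer
  # of v and -v)
  th <- atan2(uy, ux)
  tv <- atan2(vy, vx)
  dth <- (tv - th + pi / 2) %% pi - pi / 2
  th2 <- th + pmin(1, dt * pa$af_reorient) * dth * gate
  keep <- afm > 0
  gx <- ifelse(keep, m2 * cos(th2), 0)
  gy <- ifelse(keep, m2 * sin(th2), 0)
  matrix(c(gx, gy), ncol = 2)
}

#' AF contribution to PIN sensitivity
#'
#' `U = u(af) . n_mem`; `IAF = |af| * U^4 / (U^4 + Kaf^4)` per membrane
#' section: sections whose outward normal aligns with the AF axis are
#' sensitized, with quartic (switch-like) sharpness.
#'
#' @param cc a [cell_complex]
#' @param params parameter list
#' @param geom optional precomputed [cc_geometry()] result
#' @return numeric vector, one value in \[0, 1) per membrane side
#' @export
af_contribution <- function(cc, params, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pa <- params$anisotropy
  afx <- cc$cells$afx; afy <- cc$cells$afy
  afm <- sqrt(afx^2 + afy^2)
  ux <- ifelse(afm > 0, afx / pmax(afm, 1e-300), 0)
  uy <- ifelse(afm > 0, afy / pmax(afm, 1e-300), 0)
  U <- ux[cc$side_cell] * geom$side_nx + uy[cc$side_cell] * geom$side_ny
  U4 <- U^4
  afm[cc$side_cell] * U4 / (U4 + pa$Kaf^4)
}

#' Cell-geometry contribution to PIN sensitivity
#'
#' `r = |axisMin| / |axisMax|`;
#' `IG = |u(axisMax) . n_mem| * (1-r)^4 / ((1-r)^4 + Kgeom^4)`:
#' elongated cells bias PIN delivery toward the faces at the ends of their
#' long axis; isotropic cells (r = 1) contribute nothing.
#'
#' @inheritParams af_contribution
#' @return numeric vector, one value in \[0, 1) per membrane side
#' @export
geometry_contribution <- function(cc, params, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pa <- params$anisotropy
  r <- geom$ax_ratio
  h <- (1 - r)^4
  hill <- h / (h + pa$Kgeom^4)
  align <- abs(geom$ax_x[cc$side_cell] * geom$side_nx +
                 geom$ax_y[cc$side_cell] * geom$side_ny)
  align * hill[cc$side_cell]
}
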