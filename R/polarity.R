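# PIN polarization: per-membrane-section PIN sensitivity (softmax over raw
# contributions) and the two interchangeable auxin-feedback mechanisms
# that supply the auxin-flow term IP_mem:
#   "flux"                -- cells sense their net auxin flux vector
#   "regulator_polarizer" -- a mechanistic realization of flux sensing: an
#       auxin-activated membrane regulator displaces a PIN-recruiting
#       polarizer to the opposite side of the cell.

#' PIN sensitivity of every membrane section
#'
#' Raw sensitivity `PinSR = kAF*IAF + kP*IP + kAFP*(IAF + IP) + kG*IG` is
#' normalized by a softmax over each cell's sections, so the sensitivities
#' are positive and sum to 1 per cell. Columella-lineage cells bypass the
#' feedback and traffic PIN uniformly (`1/m` per section), mirroring the
#' apolar PIN3 distribution.
#'
#' @param cc a [cell_complex]
#' @param IP auxin-flow contribution per side (mechanism dependent)
#' @param IAF AF contribution per side ([af_contribution()])
#' @param IG geometry contribution per side ([geometry_contribution()])
#' @param params parameter list (block `polarity`)
#' @return numeric vector of sensitivities per side (sums to 1 per cell)
#' @export
pin_sensitivity <- function(cc, IP, IAF, IG, params) {
  pp <- params$polarity
  inter <- if (identical(pp$interaction, "product")) IAF * IP else IAF + IP
  raw <- pp$kAF * IAF + pp$kP * IP + pp$kAFP * inter + pp$kG * IG
  ncell <- length(cc$rings)
  # softmax per cell (stabilized by the per-cell max)
  mx <- rep(-Inf, ncell)
  top <- csr_which_max(raw, cc$cell_side_ptr, cc$side_cell)
  mx[cc$side_cell[top]] <- raw[top]
  e <- exp(raw - mx[cc$side_cell])
  s <- csr_sum(e, cc$cell_side_ptr)
  out <- e / s[cc$side_cell]
  unif <- cc$is_uniform_pin %||% (cc$cells$type %in% UNIFORM_PIN_TYPES)
  if (any(unif)) {
    usel <- unif[cc$side_cell]
    out[usel] <- 1 / cc$side_m[usel]
  }
  out
}

#' Net auxin-flux vector of each cell
#'
#' `FLUX_cell = sum_i u(centroid -> midpoint_i) * (E_i - I_i)`: unit
#' vectors from the cell centroid to each membrane midpoint, weighted by
#' the net efflux through that section (nM um / h). The vector points in
#' the direction auxin traverses the cell (from the influx face toward
#' the efflux face), so with-the-flux PIN allocation reinforces the
#' existing flow (canalization).
#'
#' @param cc a [cell_complex]
#' @param fluxes carrier fluxes from [carrier_fluxes()]
#' @param geom optional precomputed geometry
#' @return matrix (ncell x 2)
#' @export
flux_vector <- function(cc, fluxes, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  ncell <- length(cc$rings)
  dx <- geom$side_mx - geom$cell_cx[cc$side_cell]
  dy <- geom$side_my - geom$cell_cy[cc$side_cell]
  L <- sqrt(dx^2 + dy^2)
  L[L < 1e-12] <- 1
  net <- fluxes$E - fluxes$I
  cbind(csr_sum(dx / L * net, cc$cell_side_ptr),
        csr_sum(dy / L * net, cc$cell_side_ptr))
}

#' Auxin-flux contribution to PIN sensitivity
#'
#' `F_mem = (FLUX_cell . n_mem) * L_mem`; `IP = F^4 / (F^4 + Kflux^4)`.
#' By default only outward-aligned flux polarizes (negative `F_mem` is
#' clamped to 0 before the sign-blind quartic), so PIN accumulates on the
#' downstream face of the flux.
#'
#' @param cc a [cell_complex]
#' @param FLUX flux vectors from [flux_vector()]
#' @param params parameter list
#' @param geom optional precomputed geometry
#' @return numeric vector per side, values in \[0, 1)
#' @export
flux_contribution <- function(cc, FLUX, params, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pp <- params$polarity
  f <- (FLUX[cc$side_cell, 1] * geom$side_nx +
          FLUX[cc$side_cell, 2] * geom$side_ny) * geom$side_L
  if (isTRUE(pp$clamp_negative_flux)) f <- pmax(f, 0)
  f4 <- f^4
  ifelse(f4 > 0, f4 / (f4 + pp$Kflux^4), 0)
}

#' Auxin influx-efflux gradient metric (regulator-polarizer mechanism)
#'
#' `Grad_mem = [ (I-E)_mem + sum_i (I-E)_i / distance(mem, mem_i) ] *
#' amplification / A_cell`, with distances between section midpoints
#' (floored at `eps_dist`) and the net fluxes taken per unit cell area
#' (nM/h), which puts the metric on the nM scale of its half-max constant
#' `Kreg_GradK`. The metric localizes where auxin enters the cell and
#' drives regulator trafficking there.
#'
#' @inheritParams flux_vector
#' @param params parameter list
#' @return numeric vector per side
#' @export
grad_mem <- function(cc, fluxes, params, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pp <- params$polarity
  A <- pmax(geom$cell_A[cc$side_cell], 1)
  net <- (fluxes$I - fluxes$E) / A        # nM/h entering through the section
  if (is.null(cc$side_pair_i)) cc <- build_side_pairs(cc)
  acc <- numeric(cc$ns)
  if (length(cc$side_pair_i)) {
    i <- cc$side_pair_i; j <- cc$side_pair_j
    d <- sqrt((geom$side_mx[i] - geom$side_mx[j])^2 +
                (geom$side_my[i] - geom$side_my[j])^2)
    d <- pmax(d, pp$eps_dist)
    acc <- csr_sum(net[j] / d, cc$side_pair_ptr)
  }
  (net + acc) * pp$grad_amplification / A
}

# ordered pairs (i, j) of distinct sides within the same cell; pairs are
# contiguous in i, with CSR pointer side_pair_ptr over sides
build_side_pairs <- function(cc) {
  ptr <- cc$cell_side_ptr
  ncell <- length(cc$rings)
  pi <- vector("list", ncell); pj <- vector("list", ncell)
  m_of_side <- integer(cc$ns)
  for (ci in seq_len(ncell)) {
    s <- ptr[ci]:(ptr[ci + 1L] - 1L)
    m <- length(s)
    m_of_side[s] <- m
    if (m >= 2) {
      pi[[ci]] <- rep(s, each = m - 1L)
      pj[[ci]] <- unlist(lapply(seq_len(m), function(k) s[-k]), use.names = FALSE)
    }
  }
  cc$side_pair_i <- unlist(pi, use.names = FALSE)
  cc$side_pair_j <- unlist(pj, use.names = FALSE)
  cc$side_pair_ptr <- c(1L, 1L + cumsum(pmax(m_of_side - 1L, 0L)))
  cc$side_m <- m_of_side
  cc
}

#' Euler + stochastic update of the regulator-polarizer system
#'
#' Cytoplasmic pools: regulator and polarizer are produced at constant
#' rates and lost to auxin-gated trafficking and degradation. Membrane
#' pools: trafficking is distributed over sections (regulator additionally
#' weighted by the gradient metric), both species diffuse laterally along
#' the ordered ring of sections, and the polarizer is displaced
#' stochastically: per section a batch `Kdisp_POL * POL_mem * dt` is
#' reserved, a random ring neighbour (+1 or -1) is drawn, and the batch
#' moves iff that neighbour holds strictly less regulator. Displacement
#' conserves total polarizer exactly; draws come from the session RNG.
#'
#' @param cc a [cell_complex]
#' @param grad gradient metric from [grad_mem()]
#' @param params parameter list
#' @param dt time step (h)
#' @param geom optional precomputed geometry
#' @return list with `REG`, `POL` (cytoplasm) and `REG_mem`, `POL_mem`
#' @export
step_regulator_polarizer <- function(cc, grad, params, dt, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pp <- params$polarity
  ncell <- length(cc$rings)
  IAA <- cc$cells$IAA
  I2 <- IAA^2
  hr <- I2 / (I2 + pp$Kreg_IAA^2)
  hp <- I2 / (I2 + pp$Kpol_IAA^2)
  g4 <- pmax(grad, 0)^4
  gh <- g4 / (g4 + pp$Kreg_GradK^4)          # per side
  # gradient-driven trafficking targets sections in proportion to their
  # gate value (the influx face), the baseline part by section length
  gh_sum <- csr_sum(gh, cc$cell_side_ptr)
  gh_cell <- pmin(gh_sum, 1)
  gh_frac <- gh / pmax(gh_sum[cc$side_cell], 1e-12)
  gh_frac[gh_sum[cc$side_cell] <= 0] <- 0
  REG <- cc$cells$REG; POL <- cc$cells$POL
  dREG <- pp$b_REG - REG * (pp$Kreg_tr + pp$Kreg_GradT * gh_cell) * hr - pp$d_REG * REG
  dPOL <- pp$b_POL - POL * pp$Kpol_tr * hp - pp$d_POL * POL
  REG2 <- pmax(REG + dt * dREG, 0)
  POL2 <- pmax(POL + dt * dPOL, 0)
  # membrane binding
  frac <- geom$side_L / pmax(geom$cell_sumL[cc$side_cell], 1e-12)
  Rm <- cc$side_REG; Pm <- cc$side_POL
  gainR <- REG[cc$side_cell] * hr[cc$side_cell] *
    (pp$Kreg_tr * frac + pp$Kreg_GradT * gh_cell[cc$side_cell] * gh_frac)
  gainP <- POL[cc$side_cell] * pp$Kpol_tr * frac * hp[cc$side_cell]
  # lateral diffusion along the section ring: D is a diffusion
  # coefficient (um^2/h), discretized over midpoint distances
  dn <- pmax(sqrt((geom$side_mx[cc$side_next] - geom$side_mx)^2 +
                    (geom$side_my[cc$side_next] - geom$side_my)^2), 0.5)
  dp <- pmax(sqrt((geom$side_mx[cc$side_prev] - geom$side_mx)^2 +
                    (geom$side_my[cc$side_prev] - geom$side_my)^2), 0.5)
  diffR <- pp$D_reg * ((Rm[cc$side_next] - Rm) / dn^2 + (Rm[cc$side_prev] - Rm) / dp^2)
  diffP <- pp$D_pol * ((Pm[cc$side_next] - Pm) / dn^2 + (Pm[cc$side_prev] - Pm) / dp^2)
  Rm2 <- pmax(Rm + dt * (gainR + diffR - pp$d_REG * Rm), 0)
  Pm2 <- pmax(Pm + dt * (gainP + diffP - pp$d_POL * Pm), 0)
  # stochastic displacement of the polarizer away from the regulator
  batch <- pmin(pp$Kdisp_POL * dt, 1) * Pm2
  dir <- sample(c(-1L, 1L), cc$ns, replace = TRUE)
  nb <- ifelse(dir == 1L, cc$side_next, cc$side_prev)
  move <- Rm2[nb] < Rm2
  if (any(move)) {
    delta <- numeric(cc$ns)
    mv <- which(move)
    delta[mv] <- delta[mv] - batch[mv]
    add <- rowsum_by(batch[mv], nb[mv], cc$ns)
    Pm2 <- Pm2 + delta + add
  }
  list(REG = REG2, POL = POL2, REG_mem = Rm2, POL_mem = Pm2)
}

#' Polarizer contribution to PIN sensitivity
#'
#' `IP = POL_mem^4 / (POL_mem^4 + Kpol_IP^4)` (regulator-polarizer
#' mechanism).
#'
#' @param POL_mem membrane polarizer amounts
#' @param params parameter list
#' @return numeric vector per side, values in \[0, 1)
#' @export
polarizer_contribution <- function(POL_mem, params) {
  k4 <- params$polarity$Kpol_IP^4
  p4 <- POL_mem^4
  ifelse(p4 > 0, p4 / (p4 + k4), 0)
}
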