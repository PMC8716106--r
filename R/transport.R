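# Polar auxin transport: carrier-mediated fluxes between cells and the
# shared apoplast pools on their walls, passive membrane diffusion,
# saturable degradation, auxin-induced carrier expression and carrier
# trafficking with membrane saturation caps.
#
# Amounts are concentrations (nM = molecules / compartment area); flux
# terms carry units nM*um/h and are divided by the receiving compartment's
# area (cell polygon area, or wall length x apoplast thickness).

#' Carrier-mediated auxin fluxes across every membrane side
#'
#' `I_mem = K_AUX1 * AUX1_mem * IAA_mem * L_mem` (import, apoplast to
#' cell) and `E_mem = K_PIN * PIN_mem * IAA_cell * L_mem` (export), in
#' nM um / h.
#'
#' @param cc a [cell_complex]
#' @param params parameter list
#' @param geom optional precomputed geometry
#' @param flux_mask optional logical per side; `FALSE` zeroes both fluxes
#'   (used by the no-reflux scenario)
#' @return list with numeric vectors `I` and `E`, one entry per side
#' @export
carrier_fluxes <- function(cc, params, geom = NULL, flux_mask = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pt <- params$transport
  L <- geom$side_L
  I <- pt$K_AUX1 * cc$side_AUX1 * cc$wall_IAA[cc$side_wall] * L
  E <- pt$K_PIN * cc$side_PIN * cc$cells$IAA[cc$side_cell] * L
  if (!is.null(flux_mask)) {
    I[!flux_mask] <- 0
    E[!flux_mask] <- 0
  }
  list(I = I, E = E)
}

#' Saturable auxin degradation rate
#'
#' `d(IAA) = d_IAAb + (d_IAAMax - d_IAAb) * IAA^4 / (K_IAAMax^4 + IAA^4)`:
#' basal turnover that steepens at high auxin to preclude runaway
#' accumulation.
#'
#' @param IAA auxin concentration(s), nM
#' @param params parameter list
#' @return degradation rate(s), 1/h
#' @export
auxin_degradation <- function(IAA, params) {
  pt <- params$transport
  I4 <- IAA^4
  pt$d_IAAb + (pt$d_IAAMax - pt$d_IAAb) * I4 / (pt$K_IAAMax^4 + I4)
}

#' Euler update of the apoplastic (wall) auxin pools
#'
#' Each wall segment holds one shared apoplast pool. Per unit time it
#' gains the net carrier exchange of all adjoining cells, diffuses to
#' adjacent wall segments (rate `DI_IAA / (L + L_i)` between segment
#' midcompartments), exchanges passively with the adjoining cells'
#' cytoplasm (permeability `P_IAA`), and degrades saturably. Flux terms
#' are normalized by the apoplast area `L * wall_thickness`.
#'
#' @param cc a [cell_complex]
#' @param fluxes carrier fluxes from [carrier_fluxes()]
#' @param params parameter list
#' @param dt time step (h)
#' @param geom optional precomputed geometry
#' @return updated wall auxin vector (nM), clamped at 0
#' @export
step_apoplast <- function(cc, fluxes, params, dt, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pt <- params$transport
  nw <- cc$nw
  A_apo <- geom$wall_L * pt$wall_thickness
  W <- cc$wall_IAA
  xp <- c(fluxes$E - fluxes$I, 0)                      # sum sides per wall
  net <- xp[cc$wall_side1] + xp[cc$wall_side2]         # nM um / h
  # passive exchange with adjoining cells (leaves wall when positive)
  xp <- c(pt$P_IAA * (W[cc$side_wall] - cc$cells$IAA[cc$side_cell]) *
            geom$side_L, 0)
  pas <- xp[cc$wall_side1] + xp[cc$wall_side2]
  dW <- (net - pas) / pmax(A_apo, 0.1) - auxin_degradation(W, params) * W
  # apoplastic diffusion between wall segments sharing a junction
  if (length(cc$pairw_first)) {
    f <- pt$DI_IAA * (W[cc$pairw_first] - W[cc$pairw_other]) /
      (geom$wall_L[cc$pairw_first] + geom$wall_L[cc$pairw_other]) # nM um / h
    out <- csr_sum(f, cc$pairw_ptr)                    # net outflow per wall
    dW[cc$pairw_wall] <- dW[cc$pairw_wall] -
      out / pmax(A_apo[cc$pairw_wall], 0.1)
  }
  if (pt$surface_permeability > 0) {
    surf <- is.na(cc$wall_cb)
    dW[surf] <- dW[surf] - pt$surface_permeability * W[surf] / pt$wall_thickness
  }
  pmax(W + dt * dW, 0)
}

#' Euler update of cytoplasmic auxin
#'
#' `dIAA_cell/dt = b_IAA + [sum(I - E) + sum P_IAA (IAA_mem - IAA_cell) L] /
#' A_cell - d(IAA) IAA`, plus the boundary terms: Source cells receive a
#' constant total influx (shoot-derived auxin, not growing with the organ)
#' and Sink cells export to a virtual shoot pool at a first-order rate.
#'
#' @inheritParams step_apoplast
#' @return updated cell auxin vector (nM), clamped at 0
#' @export
step_cell_auxin <- function(cc, fluxes, params, dt, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pt <- params$transport
  C <- cc$cells$IAA
  net <- csr_sum(fluxes$I - fluxes$E, cc$cell_side_ptr)
  pas <- csr_sum(pt$P_IAA * (cc$wall_IAA[cc$side_wall] - C[cc$side_cell]) *
                   geom$side_L, cc$cell_side_ptr)
  dC <- cc$cells$b_IAA + (net + pas) / pmax(geom$cell_A, 1) -
    auxin_degradation(C, params) * C
  src <- cc$is_source %||% (cc$cells$type == "Source")
  dC[src] <- dC[src] + params$boundary$source_influx / pmax(geom$cell_A[src], 1)
  snk <- cc$is_sink %||% (cc$cells$type == "Sink")
  dC[snk] <- dC[snk] - params$boundary$sink_rate * C[snk]
  pmax(C + dt * dC, 0)
}

#' Growth dilution of all concentrations
#'
#' Concentrations are molecules per compartment area, so expansion of a
#' cell (or elongation of a wall) dilutes every species it carries while
#' shrinkage concentrates them. Non-growing tip cells (QC, columella)
#' therefore accumulate auxin relative to the expanding shaft.
#'
#' @param cc a [cell_complex]
#' @param geom_prev geometry before the mechanics step
#' @param geom_new geometry after the mechanics step
#' @return updated complex
#' @export
dilute_by_growth <- function(cc, geom_prev, geom_new) {
  rA <- pmin(pmax(geom_prev$cell_A / pmax(geom_new$cell_A, 1e-12), 0.5), 2)
  for (f in c("IAA", "PIN", "AUX1", "REG", "POL"))
    cc$cells[[f]] <- cc$cells[[f]] * rA
  rL <- pmin(pmax(geom_prev$wall_L / pmax(geom_new$wall_L, 1e-12), 0.5), 2)
  cc$wall_IAA <- cc$wall_IAA * rL
  rS <- rL[cc$side_wall]
  cc$side_PIN <- cc$side_PIN * rS
  cc$side_AUX1 <- cc$side_AUX1 * rS
  cc$side_REG <- cc$side_REG * rS
  cc$side_POL <- cc$side_POL * rS
  cc
}

#' Euler update of cytoplasmic carrier pools
#'
#' Auxin induces both carriers through Hill(2) kinetics on top of basal
#' expression; pools lose material to trafficking and degradation and are
#' capped at `AUX1_Max` / `PIN_Max`. Per-cell knockdown multipliers
#' (`kd_AUX1`, `kd_PIN`) scale the expression terms.
#'
#' @param cc a [cell_complex]
#' @param params parameter list
#' @param dt time step (h)
#' @return list with updated vectors `AUX1` and `PIN`
#' @export
step_carrier_expression <- function(cc, params, dt) {
  pt <- params$transport
  IAA <- cc$cells$IAA
  I2 <- IAA^2
  a <- cc$cells$AUX1
  p <- cc$cells$PIN
  da <- cc$cells$kd_AUX1 * (pt$b_AUX1 + pt$AUX1_expr * I2 / (pt$AUX1_K^2 + I2)) -
    a * pt$AUX1_tr - pt$d_AUX1 * a
  dp <- cc$cells$kd_PIN * (pt$b_PIN + pt$PIN_expr * I2 / (pt$PIN_K^2 + I2)) -
    p * pt$PIN_tr - pt$d_PIN * p
  list(AUX1 = pmin(pmax(a + dt * da, 0), pt$AUX1_Max),
       PIN = pmin(pmax(p + dt * dp, 0), pt$PIN_Max))
}

#' Euler update of membrane AUX/LAX
#'
#' AUX/LAX is trafficked uniformly: each membrane section receives the
#' fraction `L_mem / sum(L)` of the cytoplasmic trafficking flux
#' `AUX1_cell * AUX1_tr`, unless the section is saturated at
#' `AUX1_MaxMem`, and decays at `d_AUX1`.
#'
#' @inheritParams step_apoplast
#' @return updated per-side membrane AUX/LAX vector
#' @export
traffic_aux1 <- function(cc, params, dt, geom = NULL) {
  if (is.null(geom)) geom <- cc_geometry(cc)
  pt <- params$transport
  frac <- geom$side_L / pmax(geom$cell_sumL[cc$side_cell], 1e-12)
  gain <- cc$cells$AUX1[cc$side_cell] * pt$AUX1_tr * frac
  gain[cc$side_AUX1 >= pt$AUX1_MaxMem] <- 0
  pmin(pmax(cc$side_AUX1 + dt * (gain - pt$d_AUX1 * cc$side_AUX1), 0), pt$AUX1_MaxMem)
}

#' Euler update of membrane PIN
#'
#' Each section receives `PIN_cell * PIN_tr * PinS_mem` (zero when
#' saturated at `PIN_MaxMem`) and decays at
#' `d_PINmem = d_PIN + (d_PINmax - d_PIN) / (1 + IAA_cell)`: PIN turnover
#' on the membrane is enhanced when cellular auxin is low, enabling rapid
#' repolarization.
#'
#' @inheritParams step_apoplast
#' @param sens per-side PIN sensitivities from [pin_sensitivity()]; must
#'   sum to 1 within each cell
#' @return updated per-side membrane PIN vector
#' @export
traffic_pin <- function(cc, sens, params, dt, geom = NULL) {
  pt <- params$transport
  ssum <- csr_sum(sens, cc$cell_side_ptr)
  if (any(abs(ssum - 1) > 1e-6))
    stop("PIN sensitivities must be normalized per cell (softmax)")
  d_mem <- pt$d_PIN + (pt$d_PINmax - pt$d_PIN) / (1 + cc$cells$IAA)
  gain <- cc$cells$PIN[cc$side_cell] * pt$PIN_tr * sens
  gain[cc$side_PIN >= pt$PIN_MaxMem] <- 0
  pmin(pmax(cc$side_PIN + dt * (gain - d_mem[cc$side_cell] * cc$side_PIN), 0),
       pt$PIN_MaxMem)
}
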