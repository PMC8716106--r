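# Simulation driver and the in-silico experiment library: wild-type runs,
# mechanics-only runs, perturbations (ablations, knockdowns, auxin
# pulses), parameter sweeps and derived output metrics.

#' Scenario configuration
#'
#' @param template a [root_template_config()], a ready [cell_complex], or
#'   a path to a mesh JSON file
#' @param mechanism PIN polarization mechanism: `"flux"` or
#'   `"regulator_polarizer"`
#' @param steps number of simulation steps (each `params$mechanics$dt`
#'   hours of model time)
#' @param seed RNG seed (the regulator-polarizer displacement draws are
#'   the only stochastic element of the default model)
#' @param record_every snapshot cadence in steps (first and last steps are
#'   always recorded)
#' @param params parameter list from [default_params()]
#' @param perturbations list of timed actions, each
#'   `list(type = ..., step = ..., ...)`; see [perturb()]
#' @return list of class `scenario_config`
#' @export
scenario_config <- function(template = root_template_config(),
                            mechanism = c("flux", "regulator_polarizer"),
                            steps = 1500L, seed = 1L, record_every = 10L,
                            params = default_params(),
                            perturbations = list()) {
  mechanism <- match.arg(mechanism)
  if (steps < 0) stop("steps must be >= 0")
  for (a in perturbations) {
    if (is.null(a$type) || is.null(a$step))
      stop("each perturbation needs 'type' and 'step'")
    if (a$step > steps)
      stop("perturbation '", a$type, "' scheduled at step ", a$step,
           " beyond run end (", steps, ")")
  }
  structure(list(template = template, mechanism = mechanism,
                 steps = as.integer(steps), seed = as.integer(seed),
                 record_every = as.integer(record_every), params = params,
                 perturbations = perturbations),
            class = "scenario_config")
}

resolve_template <- function(template) {
  if (inherits(template, "cell_complex")) template
  else if (is.character(template)) load_mesh(template)
  else build_synthetic_root_template(template)
}

# mutable per-run scenario state (flags set by perturbations)
new_run_state <- function() {
  list(no_reflux = FALSE, pulse_rate = 0, pulse_end = -1L,
       oryzalin_factor = 1, events = list(),
       ledger = c(production = 0, degradation = 0, boundary = 0))
}

#' Apply one perturbation action
#'
#' Supported actions (fields beyond `type`/`step` in parentheses):
#' `qc_ablation`, `lrc_removal`, `tip_excision` (`height`: um above the QC
#' top to cut), `pin2_knockdown` (`factor`, default 0.1; LRC, epidermis
#' and cortex), `vascular_pin_knockdown` (`factor`), `aux1_knockdown`
#' (`factor`, default 0.1, all cells), `oryzalin` (`factor`, default 50;
#' multiplies the AF decay rate), `auxin_pulse` (`rate` nM/h, `duration`
#' steps), `no_reflux`, `source_removal`, `qc_synthesis` (`rate`, default
#' 10 nM/h).
#'
#' @param sim list with elements `cc`, `params`, `state` (see
#'   [new_run_state()]); this is the mutable simulation state
#' @param action list with `type` and action-specific fields
#' @param step current step (for pulse bookkeeping)
#' @return updated `sim` list
#' @export
perturb <- function(sim, action, step = action$step %||% 0L) {
  cc <- sim$cc; params <- sim$params; state <- sim$state
  ty <- action$type
  if (ty == "qc_ablation") {
    sel <- which(cc$cells$type == "QC")
    if (!length(sel)) warning("qc_ablation: no QC cells left (no-op)")
    else cc <- remove_cells(cc, sel)
  } else if (ty == "lrc_removal") {
    sel <- which(cc$cells$type == "LRC")
    if (!length(sel)) warning("lrc_removal: no LRC cells left (no-op)")
    else cc <- remove_cells(cc, sel)
  } else if (ty == "tip_excision") {
    g <- cc_geometry(cc)
    qc <- cc$cells$type == "QC"
    ycut <- if (any(qc)) max(g$cell_cy[qc]) + (action$height %||% 3)
            else min(g$cell_cy) + (action$height %||% 15)
    sel <- which(g$cell_cy <= ycut)
    if (!length(sel)) warning("tip_excision: nothing below the cut (no-op)")
    else cc <- remove_cells(cc, sel)
  } else if (ty == "pin2_knockdown") {
    sel <- cc$cells$type %in% c("LRC", "Epidermis", "Cortex")
    cc$cells$kd_PIN[sel] <- action$factor %||% 0.1
  } else if (ty == "vascular_pin_knockdown") {
    sel <- cc$cells$type %in% c("Vascular", "VascularInitial")
    cc$cells$kd_PIN[sel] <- action$factor %||% 0.1
  } else if (ty == "aux1_knockdown") {
    cc$cells$kd_AUX1[] <- action$factor %||% 0.1
  } else if (ty == "oryzalin") {
    state$oryzalin_factor <- action$factor %||% 200
  } else if (ty == "auxin_pulse") {
    state$pulse_rate <- action$rate %||% 50
    state$pulse_end <- step + (action$duration %||% 300L)
  } else if (ty == "no_reflux") {
    state$no_reflux <- TRUE
  } else if (ty == "source_removal") {
    params$boundary$source_influx <- 0
  } else if (ty == "qc_synthesis") {
    cc$cells$b_IAA[cc$cells$type == "QC"] <- action$rate %||% 10
  } else stop("unknown perturbation type: ", ty)
  list(cc = cc, params = params, state = state)
}

# per-side mask for the no-reflux scenario: FALSE across epidermis<->cortex
# walls (lateral auxin path from the outer tissues inward)
reflux_mask <- function(cc, state) {
  if (!state$no_reflux) return(NULL)
  ty <- cc$cells$type
  other <- ifelse(cc$wall_ca[cc$side_wall] == cc$side_cell,
                  cc$wall_cb[cc$side_wall], cc$wall_ca[cc$side_wall])
  a <- ty[cc$side_cell]
  b <- ifelse(is.na(other), NA, ty[pmax(other, 1L)])
  # outer sheath cells may not hand auxin back to the inner ground
  # tissues (the reflux path); the columella-to-LRC handoff at the very
  # tip and transport within the sheath stay open
  outer <- c("Epidermis", "LRC", "Sink")
  blocked <- c("Cortex", "Endodermis", "CEI", "CEID", "EpidermisLRCInitial")
  lateral <- (a %in% outer & b %in% blocked) | (a %in% blocked & b %in% outer)
  !ifelse(is.na(lateral), FALSE, lateral)
}

# one full chemistry phase (substepped Euler) incl. PIN sensitivity and
# trafficking; also accumulates the auxin mass ledger
chem_phase <- function(cc, params, state, dt) {
  pt <- params$transport
  nsub <- pt$n_substeps
  dtc <- dt / nsub
  geom <- cc_geometry(cc)
  mask <- reflux_mask(cc, state)
  led <- state$ledger
  pulse_on <- state$pulse_rate > 0
  b_extra <- if (pulse_on) {
    ifelse(cc$cells$type %in% c("Source", "Sink"), 0, state$pulse_rate)
  } else 0
  b_save <- cc$cells$b_IAA
  if (pulse_on) cc$cells$b_IAA <- b_save + b_extra
  A_apo <- geom$wall_L * pt$wall_thickness
  src <- cc$cells$type == "Source"
  snk <- cc$cells$type == "Sink"
  for (s in seq_len(nsub)) {
    fl <- carrier_fluxes(cc, params, geom, flux_mask = mask)
    # ledger terms computed from the pre-update state
    led["production"] <- led["production"] +
      dtc * (sum(cc$cells$b_IAA * geom$cell_A) +
               sum(src) * params$boundary$source_influx)
    led["degradation"] <- led["degradation"] +
      dtc * (sum(auxin_degradation(cc$cells$IAA, params) * cc$cells$IAA * geom$cell_A) +
               sum(auxin_degradation(cc$wall_IAA, params) * cc$wall_IAA * A_apo))
    led["boundary"] <- led["boundary"] +
      dtc * sum(params$boundary$sink_rate * cc$cells$IAA[snk] * geom$cell_A[snk])
    W2 <- step_apoplast(cc, fl, params, dtc, geom)
    C2 <- step_cell_auxin(cc, fl, params, dtc, geom)
    cc$wall_IAA <- W2
    cc$cells$IAA <- C2
    ex <- step_carrier_expression(cc, params, dtc)
    cc$cells$AUX1 <- ex$AUX1
    cc$cells$PIN <- ex$PIN
    cc$side_AUX1 <- traffic_aux1(cc, params, dtc, geom)
  }
  if (pulse_on) cc$cells$b_IAA <- b_save
  state$ledger <- led
  # PIN sensitivity from the current fluxes, then PIN trafficking
  fl <- carrier_fluxes(cc, params, geom, flux_mask = mask)
  IAF <- if (isTRUE(params$polarity$use_af))
    af_contribution(cc, params, geom) else numeric(cc$ns)
  IG <- geometry_contribution(cc, params, geom)
  if (identical(params$polarity$mechanism, "flux")) {
    FLUX <- flux_vector(cc, fl, geom)
    IP <- flux_contribution(cc, FLUX, params, geom)
  } else {
    gr <- grad_mem(cc, fl, params, geom)
    rp <- step_regulator_polarizer(cc, gr, params, dt, geom)
    cc$cells$REG <- rp$REG; cc$cells$POL <- rp$POL
    cc$side_REG <- rp$REG_mem; cc$side_POL <- rp$POL_mem
    IP <- polarizer_contribution(cc$side_POL, params)
  }
  sens <- pin_sensitivity(cc, IP, IAF, IG, params)
  cc$side_PIN <- traffic_pin(cc, sens, params, dt, geom)
  list(cc = cc, state = state, sens = sens)
}

# per-cell RMS extents along the organ axes (sqrt of the central second
# area moments): growth anisotropy compares their relative change
cell_extents <- function(cc, g) {
  rv <- cc$ring_vertex; nv <- cc$ring_next_v
  ptr <- cc$cell_side_ptr
  x <- cc$V[rv, 1]; y <- cc$V[rv, 2]
  xn <- cc$V[nv, 1]; yn <- cc$V[nv, 2]
  cr <- x * yn - xn * y
  A <- pmax(abs(g$cell_A), 1e-9)
  sxx <- csr_sum((x^2 + x * xn + xn^2) * cr, ptr) / 12
  syy <- csr_sum((y^2 + y * yn + yn^2) * cr, ptr) / 12
  cxx <- pmax(sxx / A - g$cell_cx^2, 1e-12)
  cyy <- pmax(syy / A - g$cell_cy^2, 1e-12)
  list(x = sqrt(cxx), y = sqrt(cyy))
}

#' Growth-anisotropy index of a mechanics run
#'
#' Per-cell ratio of relative axial to relative radial expansion between
#' two snapshots, `(ext_y1/ext_y0) / (ext_x1/ext_x0)`, summarized as a
#' geometric mean over the selected cells. 1 = isotropic growth, > 1 =
#' anisotropic elongation along the organ axis.
#'
#' @param trace a `simulation_trace`
#' @param from,to snapshot indices (default: first and last)
#' @param tissue optional tissue label filter (`"BPE"`/`"RSI"` for
#'   mechanics-only runs)
#' @return scalar index
#' @export
growth_anisotropy_index <- function(trace, from = 1L,
                                    to = length(trace$snapshots),
                                    tissue = "BPE") {
  s0 <- trace$snapshots[[from]]$cells
  s1 <- trace$snapshots[[to]]$cells
  m <- match(s1$id, s0$id)
  keep <- !is.na(m)
  if (!is.null(tissue) && !is.null(s1$tissue)) keep <- keep & s1$tissue == tissue
  r <- (s1$ext_y[keep] / s0$ext_y[m[keep]]) / (s1$ext_x[keep] / s0$ext_x[m[keep]])
  exp(mean(log(pmax(r, 1e-9))))
}

# per-cell PIN distribution metrics from membrane amounts
pin_metrics <- function(cc, geom) {
  ncell <- length(cc$rings)
  amt <- cc$side_PIN * geom$side_L
  tot <- rowsum_by(amt, cc$side_cell, ncell)
  tot0 <- pmax(tot, 1e-12)
  p <- amt / tot0[cc$side_cell]
  ent <- -rowsum_by(ifelse(p > 0, p * log(p), 0), cc$side_cell, ncell)
  # dominant face
  dom_frac <- numeric(ncell); dom_ny <- numeric(ncell)
  o <- order(cc$side_cell, amt)
  oc <- cc$side_cell[o]
  last <- which(!duplicated(oc, fromLast = TRUE))
  dom_frac[oc[last]] <- p[o[last]]
  dom_ny[oc[last]] <- geom$side_ny[o[last]]
  root_frac <- rowsum_by(amt * (geom$side_ny < -0.7), cc$side_cell, ncell) / tot0
  shoot_frac <- rowsum_by(amt * (geom$side_ny > 0.7), cc$side_cell, ncell) / tot0
  list(entropy = ent, dom_frac = dom_frac, dom_ny = dom_ny,
       rootward = root_frac, shootward = shoot_frac, total = tot)
}

take_snapshot <- function(cc, step, time_h, state) {
  g <- cc_geometry(cc)
  pm <- pin_metrics(cc, g)
  ext <- cell_extents(cc, g)
  A_apo_tot <- sum(cc$wall_IAA * g$wall_L) # thickness applied by caller if needed
  cells <- data.frame(
    id = cc$cells$id, type = cc$cells$type,
    x = g$cell_cx, y = g$cell_cy, area = g$cell_A,
    IAA = cc$cells$IAA, PIN_cell = cc$cells$PIN, AUX1_cell = cc$cells$AUX1,
    afx = cc$cells$afx, afy = cc$cells$afy,
    af_mag = sqrt(cc$cells$afx^2 + cc$cells$afy^2),
    aspect = ifelse(g$ax_len_min > 1e-9, g$ax_len_max / g$ax_len_min, 1),
    ax_x = g$ax_x, ax_y = g$ax_y,
    ext_x = ext$x, ext_y = ext$y,
    pin_entropy = pm$entropy, pin_dom_frac = pm$dom_frac, pin_dom_ny = pm$dom_ny,
    pin_rootward = pm$rootward, pin_shootward = pm$shootward,
    pin_mem_total = pm$total,
    stringsAsFactors = FALSE)
  list(step = step, time = time_h, cells = cells,
       root_length = max(cc$V[unlist(cc$rings), 2]) - min(cc$V[unlist(cc$rings), 2]),
       width = diff(range(cc$V[unlist(cc$rings), 1])),
       mean_IAA = mean(cc$cells$IAA),
       total_auxin_cells = sum(cc$cells$IAA * g$cell_A),
       total_auxin_walls = sum(cc$wall_IAA * g$wall_L),
       ledger = state$ledger,
       ncell = length(cc$rings))
}

#' Run a coupled simulation
#'
#' Executes, per step: (1) PBD mechanics, (2) strain measurement, AF
#' update and plastic yield, (3) substepped Euler chemistry (transport,
#' expression, AUX/LAX trafficking), (4) mechanism-specific IP, PIN
#' sensitivity and PIN trafficking, (5) auxin-dependent stiffness refresh,
#' (6) division check/apply, (7) scheduled perturbations, (8) recording.
#' Runs are reproducible for a fixed seed.
#'
#' @param config a [scenario_config()]
#' @return object of class `simulation_trace`: list with `config`,
#'   `snapshots` (list; see source for fields), `events` (division log),
#'   and `final` (the final [cell_complex])
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cc <- resolve_template(config$template)
  params <- config$params
  params$polarity$mechanism <- config$mechanism
  state <- new_run_state()
  dt <- params$mechanics$dt
  pert <- config$perturbations
  pert_steps <- vapply(pert, function(a) as.integer(a$step), integer(1))
  snapshots <- list()
  events <- list()
  cc$cells$kE <- wall_stiffness(cc$cells$IAA, params)
  snapshots[[1]] <- take_snapshot(cc, 0L, 0, state)
  if (config$steps >= 1) for (step in seq_len(config$steps)) {
    st <- engine_step(cc, params, state, dt, step)
    cc <- st$cc; state <- st$state
    events <- c(events, st$events)
    # (7) perturbations
    for (k in which(pert_steps == step)) {
      sim <- perturb(list(cc = cc, params = params, state = state),
                     pert[[k]], step = step)
      cc <- sim$cc; params <- sim$params; state <- sim$state
    }
    # (8) recording
    if (step %% config$record_every == 0 || step == config$steps)
      snapshots[[length(snapshots) + 1]] <- take_snapshot(cc, step, step * dt, state)
  }
  structure(list(config = config, snapshots = snapshots, events = events,
                 final = cc, params = params, state = state),
            class = "simulation_trace")
}

# One coupled engine step: (1) mechanics + growth dilution, (2) strain ->
# AF -> plastic yield, (3)+(4) chemistry and PIN polarity, (5) stiffness
# refresh, (6) divisions (optional).
engine_step <- function(cc, params, state, dt, step = 0L, divide = TRUE) {
  g_prev <- cc_geometry(cc)
  cc <- mech_step(cc, params)
  g_new <- cc_geometry(cc)
  cc <- dilute_by_growth(cc, g_prev, g_new)
  eps <- measure_strain(cc)
  p_af <- params
  p_af$anisotropy$d_AF <- p_af$anisotropy$d_AF * state$oryzalin_factor
  af2 <- update_af(cc, eps, p_af, dt)
  cc$cells$afx <- af2[, 1]; cc$cells$afy <- af2[, 2]
  cc <- plastic_update(cc, params, dt)
  if (step > state$pulse_end) state$pulse_rate <- 0
  ch <- chem_phase(cc, params, state, dt)
  cc <- ch$cc; state <- ch$state
  cc$cells$kE <- wall_stiffness(cc$cells$IAA, params)
  cc$cells$kE[cc$cells$type %in% NON_GROWING_TYPES] <- params$growth$kE_Max
  events <- list()
  if (divide) {
    g <- cc_geometry(cc)
    ready <- which(g$cell_A >= cc$cells$A_max)
    for (ci in ready) {
      ev <- check_and_divide(cc, ci, g)
      if (is.null(ev)) next
      res <- apply_division(cc, ev, min_frac = params$growth$min_daughter_frac)
      if (res$ok) {
        cc <- res$cc
        events[[length(events) + 1]] <- list(
          step = step, parent = cc$cells$id[res$daughters[1]],
          daughters = cc$cells$id[res$daughters],
          types = cc$cells$type[res$daughters],
          y = mean(cc$V[cc$rings[[res$daughters[1]]], 2]))
        g <- cc_geometry(cc)   # indices changed; refresh before next event
      }
    }
  }
  list(cc = cc, state = state, events = events)
}

#' PIN re-localization kinetics after cell division
#'
#' Runs a wild-type simulation until a polar PIN field is established,
#' force-divides the cell that is closest to its division threshold
#' (among the growing lineages), and follows the membrane PIN on the new
#' cross wall while the rest of the simulation continues (further
#' divisions suppressed so the tracked wall stays intact). Reported is
#' the time for the new wall's polar face to reach 95% of its final
#' (plateau) PIN level, the model analogue of time-lapse measurements of
#' PIN reappearance on new cell plates.
#'
#' @param template template config (small meshes suffice)
#' @param prep_steps steps run before the forced division
#' @param follow_steps steps tracked after the division
#' @param params parameter list
#' @param seed RNG seed
#' @return list: `t95_h` (hours to 95% of plateau), `plateau` (nM),
#'   `series` (data.frame time/PIN), `cell_type` of the divided cell
#' @export
pin_relocalization_experiment <- function(template = root_template_config(cells_per_file = 6),
                                          prep_steps = 600L, follow_steps = 600L,
                                          params = default_params(), seed = 1L) {
  set.seed(seed)
  cc <- resolve_template(template)
  state <- new_run_state()
  dt <- params$mechanics$dt
  cc$cells$kE <- wall_stiffness(cc$cells$IAA, params)
  for (step in seq_len(prep_steps)) {
    st <- engine_step(cc, params, state, dt, step, divide = FALSE)
    cc <- st$cc; state <- st$state
  }
  # the cell nearest its division threshold among dividing lineages with
  # an established polar PIN field and auxin throughput
  g <- cc_geometry(cc)
  pm <- pin_metrics(cc, g)
  # a polarized meristematic cell at the auxin level typical of the
  # dividing outer tissues (~0.5 nM, the regime of the epidermal
  # time-lapse measurements the trafficking parameters reproduce);
  # PIN recovery is auxin-dependent (membrane turnover slows with auxin)
  eligible <- which(!(cc$cells$type %in% NON_DIVIDING_TYPES) &
                      is.finite(cc$cells$A_max) & pm$dom_frac >= 0.4 &
                      cc$cells$IAA >= 0.1)
  if (!length(eligible))
    stop("no polarized dividing cell found; increase prep_steps")
  ci <- eligible[which.min(abs(cc$cells$IAA[eligible] - 0.5))]
  ctype <- cc$cells$type[ci]
  # transverse (anticlinal) cut through the centroid: the new cross wall
  # is the polar face of the shootward daughter
  ev <- list(cell = ci, p0 = c(g$cell_cx[ci], g$cell_cy[ci]),
             u = c(1, 0), types = rep(ctype, 2), parity_used = FALSE)
  res <- apply_division(cc, ev)
  if (!res$ok) stop("forced division failed")
  cc <- res$cc
  ids <- cc$cells$id[res$daughters]
  track <- function(cc) {
    da <- match(ids, cc$cells$id)
    w <- which((cc$wall_ca %in% da) &
                 !is.na(cc$wall_cb) & (cc$wall_cb %in% da))
    sides <- which(cc$side_wall %in% w)
    if (!length(sides)) return(c(NA, NA))
    cc$side_PIN[sides][order(-cc$side_PIN[sides])[1:2]]
  }
  times <- numeric(follow_steps)
  pin_hi <- numeric(follow_steps)
  for (step in seq_len(follow_steps)) {
    st <- engine_step(cc, params, state, dt, prep_steps + step, divide = FALSE)
    cc <- st$cc; state <- st$state
    times[step] <- step * dt
    pin_hi[step] <- track(cc)[1]
  }
  plateau <- stats::median(pin_hi[max(1, follow_steps - 19):follow_steps],
                           na.rm = TRUE)
  hit <- which(pin_hi >= 0.95 * plateau)
  t95 <- if (length(hit)) times[hit[1]] else NA_real_
  list(t95_h = t95, plateau = plateau,
       series = data.frame(time = times, PIN = pin_hi),
       cell_type = ctype)
}

#' @export
print.simulation_trace <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat("<simulation_trace>", length(x$snapshots), "snapshots,",
      length(x$events), "divisions,", last$ncell, "cells at step",
      last$step, "\n")
  invisible(x)
}

#' Run a mechanics-only simulation
#'
#' Pure growth mechanics without biochemistry: all walls share one relaxed
#' stiffness and each cell's pressure target is scaled by its tissue
#' growth factor. The template's top `rsi_rows` cell rows form the
#' root-shoot interface (RSI); the remainder is the basal part of the
#' embryo (BPE). `differential = 4` grows the BPE four times faster than
#' the RSI; `1` is uniform growth. `switch_step` optionally abolishes the
#' differential mid-run (growth factors equalized) to probe whether
#' established anisotropy persists.
#'
#' @param template a [root_template_config()] or [cell_complex]
#' @param steps number of steps
#' @param differential BPE/RSI growth-rate ratio (1 = uniform)
#' @param rsi_rows number of top cell rows forming the RSI
#' @param switch_step step at which growth is made uniform (NULL = never)
#' @param params parameter list; mechanics-only runs default to a coarser
#'   `dt` (0.1 h/step) matching the slower embryonic time scale
#' @param record_every snapshot cadence
#' @param wall_k relaxed wall stiffness used for every wall
#' @param seed RNG seed (the run itself is deterministic)
#' @return a `simulation_trace`
#' @export
mechanics_only <- function(template = root_template_config(), steps = 300L,
                           differential = 4, rsi_rows = 3L,
                           switch_step = NULL,
                           params = default_params(dt = 0.1),
                           record_every = 10L, wall_k = 0.02,
                           rsi_wall_k = 0.9, seed = 1L) {
  set.seed(seed)
  params$mechanics$all_cells_grow <- TRUE
  cc <- resolve_template(template)
  if (all(is.na(cc$cells$row)))
    stop("mechanics_only needs row annotations (template-built meshes have them)")
  nrows <- max(cc$cells$row, na.rm = TRUE)
  rsi <- cc$cells$row > nrows - rsi_rows
  # slow growth goes with low wall extensibility: in the differential
  # scenario the RSI both grows slower and keeps stiff walls
  set_tissues <- function(cc, diff_on) {
    cc$cells$growth_factor <- if (diff_on) ifelse(rsi, 1 / differential, 1) else rep(1, length(cc$rings))
    cc$cells$kE <- if (diff_on) ifelse(rsi, rsi_wall_k, wall_k) else rep(wall_k, length(cc$rings))
    cc
  }
  cc <- set_tissues(cc, differential > 1)
  dt <- params$mechanics$dt
  state <- new_run_state()
  snapshots <- list(take_snapshot(cc, 0L, 0, state))
  for (step in seq_len(steps)) {
    if (!is.null(switch_step) && step == switch_step)
      cc <- set_tissues(cc, FALSE)
    cc <- mech_step(cc, params)
    eps <- measure_strain(cc)
    af2 <- update_af(cc, eps, params, dt)
    cc$cells$afx <- af2[, 1]; cc$cells$afy <- af2[, 2]
    cc <- plastic_update(cc, params, dt)
    if (step %% record_every == 0 || step == steps)
      snapshots[[length(snapshots) + 1]] <- take_snapshot(cc, step, step * dt, state)
  }
  # tag tissues in every snapshot for downstream metrics
  for (k in seq_along(snapshots)) {
    snapshots[[k]]$cells$tissue <- ifelse(rsi[
      match(snapshots[[k]]$cells$id, cc$cells$id)], "RSI", "BPE")
  }
  structure(list(config = list(steps = steps, differential = differential,
                               rsi_rows = rsi_rows, switch_step = switch_step),
                 snapshots = snapshots, events = list(), final = cc),
            class = "simulation_trace")
}

#' Derived metric tables of a simulation trace
#'
#' Computes (a) longitudinal profiles binned along the root axis at the
#' final snapshot: mean relative area growth rate (vs the previous
#' snapshot), division counts, vascular and non-vascular auxin; (b) root
#' growth rate and mean auxin over time; (c) per-snapshot mean anisotropy
#' (cell aspect ratio, |af|) and PIN polarity (dominant-face fraction,
#' membrane entropy); (d) the auxin mass ledger closure
#' `production - degradation - boundary - storage change`.
#'
#' @param trace a `simulation_trace`
#' @param nbins number of longitudinal bins
#' @return list of data.frames: `profile`, `timeseries`, `ledger`
#' @export
simulation_metrics <- function(trace, nbins = 20L) {
  snaps <- trace$snapshots
  ns <- length(snaps)
  last <- snaps[[ns]]
  cells <- last$cells
  rng <- range(cells$y)
  br <- seq(rng[1], rng[2] + 1e-9, length.out = nbins + 1L)
  bin <- pmin(findInterval(cells$y, br, rightmost.closed = TRUE), nbins)
  # per-cell growth rate averaged over the last few recorded intervals
  # (cells that divided in an interval keep the parent id but halve in
  # area; such intervals are excluded from the estimate)
  gr <- rep(NA_real_, nrow(cells))
  if (ns > 1) {
    kfrom <- max(1L, ns - 5L)
    acc <- matrix(NA_real_, nrow(cells), ns - kfrom)
    for (k in seq_len(ns - kfrom)) {
      s0 <- snaps[[kfrom + k - 1L]]; s1 <- snaps[[kfrom + k]]
      m0 <- match(cells$id, s0$cells$id)
      m1 <- match(cells$id, s1$cells$id)
      ratio <- s1$cells$area[m1] / s0$cells$area[m0]
      ratio[is.na(ratio) | ratio < 0.75] <- NA
      acc[, k] <- log(ratio) / (s1$time - s0$time)
    }
    gr <- rowMeans(acc, na.rm = TRUE)
    gr[is.nan(gr)] <- NA
  }
  vasc <- cells$type %in% VASCULAR_TYPES
  prof <- data.frame(bin = seq_len(nbins),
                     y_mid = (br[-1] + br[-(nbins + 1)]) / 2)
  agg <- function(v, sel = rep(TRUE, length(v))) {
    out <- rep(NA_real_, nbins)
    t <- tapply(v[sel], bin[sel], mean, na.rm = TRUE)
    out[as.integer(names(t))] <- t
    out
  }
  prof$growth_rate <- agg(gr)
  prof$auxin_vascular <- agg(cells$IAA, vasc)
  prof$auxin_nonvascular <- agg(cells$IAA, !vasc)
  prof$auxin <- agg(cells$IAA)
  prof$divisions <- 0
  if (length(trace$events)) {
    ey <- vapply(trace$events, function(e) e$y, numeric(1))
    eb <- pmin(pmax(findInterval(ey, br, rightmost.closed = TRUE), 1L), nbins)
    tb <- table(eb)
    prof$divisions[as.integer(names(tb))] <- as.integer(tb)
  }
  ts <- data.frame(
    step = vapply(snaps, `[[`, integer(1), "step"),
    time = vapply(snaps, `[[`, numeric(1), "time"),
    root_length = vapply(snaps, `[[`, numeric(1), "root_length"),
    width = vapply(snaps, `[[`, numeric(1), "width"),
    mean_IAA = vapply(snaps, `[[`, numeric(1), "mean_IAA"),
    ncell = vapply(snaps, `[[`, numeric(1), "ncell"),
    mean_aspect = vapply(snaps, function(s) mean(s$cells$aspect), numeric(1)),
    mean_af = vapply(snaps, function(s) mean(s$cells$af_mag), numeric(1)),
    mean_pin_entropy = vapply(snaps, function(s)
      mean(s$cells$pin_entropy[s$cells$pin_mem_total > 1e-9]), numeric(1)),
    total_area = vapply(snaps, function(s) sum(s$cells$area), numeric(1)),
    total_auxin = vapply(snaps, function(s)
      s$total_auxin_cells + s$total_auxin_walls, numeric(1)))
  ts$growth_rate <- c(NA, diff(ts$root_length) / pmax(diff(ts$time), 1e-12))
  ts$area_growth <- c(NA, diff(log(ts$total_area)) / pmax(diff(ts$time), 1e-12))
  led <- last$ledger
  storage0 <- snaps[[1]]$total_auxin_cells + snaps[[1]]$total_auxin_walls
  storage1 <- last$total_auxin_cells + last$total_auxin_walls
  ledger <- data.frame(production = led["production"],
                       degradation = led["degradation"],
                       boundary = led["boundary"],
                       storage_change = storage1 - storage0,
                       row.names = NULL)
  ledger$residual <- ledger$production - ledger$degradation -
    ledger$boundary - ledger$storage_change
  list(profile = prof, timeseries = ts, ledger = ledger)
}

#' Sweep one parameter over a set of values
#'
#' Runs one simulation per value (shared seed and template) and returns
#' the per-value metric tables for comparison.
#'
#' @param config a [scenario_config()]
#' @param parameter dotted parameter path, e.g. `"polarity.kP"`
#' @param values numeric vector of values (empty gives an empty result)
#' @param nbins bins for [simulation_metrics()]
#' @return named list (one entry per value) of metric lists
#' @export
sweep_parameter <- function(config, parameter, values, nbins = 20L) {
  out <- list()
  for (v in values) {
    cf <- config
    cf$params <- set_param(cf$params, parameter, v)
    tr <- run_simulation(cf)
    out[[as.character(v)]] <- simulation_metrics(tr, nbins)
  }
  out
}
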