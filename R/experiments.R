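# Canned in-silico experiments and their summary statistics. These are the
# study conditions used throughout the package's tests and by
# scripts/acceptance.R; sizes are chosen so a full panel runs on a desktop
# in minutes (see the methods vignette for the problem sizes).

#' Standard wild-type scenario
#'
#' @param mechanism PIN polarization mechanism
#' @param steps simulation steps
#' @param cells_per_file body cells per file in the template
#' @param seed RNG seed
#' @param record_every snapshot cadence
#' @param perturbations optional timed actions
#' @param params parameter list
#' @return a [scenario_config()]
#' @export
wildtype_config <- function(mechanism = "flux", steps = 1500L,
                            cells_per_file = 6L, seed = 1L,
                            record_every = 50L, perturbations = list(),
                            params = default_params()) {
  scenario_config(template = root_template_config(cells_per_file = cells_per_file),
                  mechanism = mechanism, steps = steps, seed = seed,
                  record_every = record_every, params = params,
                  perturbations = perturbations)
}

#' Spatial pattern summary of a trace
#'
#' Condenses a run into the patterning statistics the root model is
#' judged by: position of the auxin maximum relative to the QC, the
#' growth-rate peak, polar PIN fractions per tissue and zone, bipolar
#' cortex cells near the LRC termination, and organ shape.
#'
#' @param trace a `simulation_trace`
#' @param nbins longitudinal bins
#' @return list of scalar summaries
#' @export
pattern_summary <- function(trace, nbins = 20L) {
  m <- simulation_metrics(trace, nbins)
  prof <- m$profile
  s <- trace$snapshots[[length(trace$snapshots)]]$cells
  qc_y <- if (any(s$type == "QC")) mean(s$y[s$type == "QC"]) else NA_real_
  bin_of <- function(y) {
    if (is.na(y)) return(NA_integer_)
    which.min(abs(prof$y_mid - y))
  }
  qc_bin <- bin_of(qc_y)
  aux_nv <- prof$auxin_nonvascular
  max_bin_nonvasc <- if (all(is.na(aux_nv))) NA_integer_ else which.max(aux_nv)
  gr <- prof$growth_rate
  growth_peak_bin <- if (all(is.na(gr))) NA_integer_ else which.max(gr)
  # zone means: apical meristem (QC level to 40% of the root length) vs
  # the basal root (top 30%)
  ylo <- min(s$y); yspan <- diff(range(s$y))
  apical <- prof$y_mid >= ylo + 0.05 * yspan & prof$y_mid <= ylo + 0.4 * yspan
  basal <- prof$y_mid >= ylo + 0.7 * yspan
  growth_apical <- mean(gr[apical], na.rm = TRUE)
  growth_basal <- mean(gr[basal], na.rm = TRUE)
  vas <- s$type == "Vascular"
  lrc_top <- if (any(s$type == "LRC")) max(s$y[s$type == "LRC"]) else min(s$y)
  epi_zone <- s$type == "Epidermis" & s$y > lrc_top & s$y < lrc_top + 20
  cor_zone <- s$type == "Cortex" & s$y > lrc_top & s$y < lrc_top + 30
  bipolar <- cor_zone & pmin(s$pin_rootward, s$pin_shootward) >= 0.1
  # tip auxin contrast: QC-adjacent bin vs the shaft (middle two quartiles)
  shaft <- setdiff(seq_len(nbins) [prof$y_mid > stats::quantile(s$y, 0.3) &
                                     prof$y_mid < stats::quantile(s$y, 0.8)], NA)
  tip_contrast <- if (is.na(qc_bin)) NA_real_ else {
    tipv <- mean(aux_nv[pmax(qc_bin - 1, 1):pmin(qc_bin + 1, nbins)], na.rm = TRUE)
    tipv / pmax(mean(aux_nv[shaft], na.rm = TRUE), 1e-9)
  }
  list(
    qc_bin = qc_bin,
    auxin_max_bin_nonvascular = max_bin_nonvasc,
    auxin_max_at_qc = !is.na(qc_y) && !is.na(max_bin_nonvasc) &&
      abs(prof$y_mid[max_bin_nonvasc] - qc_y) <= 15,
    tip_auxin_contrast = tip_contrast,
    growth_peak_bin = growth_peak_bin,
    growth_apical = growth_apical,
    growth_basal = growth_basal,
    vascular_rootward = mean(s$pin_rootward[vas]),
    vascular_shootward = mean(s$pin_shootward[vas]),
    epidermis_shootward_above_lrc = mean(s$pin_shootward[epi_zone]),
    epidermis_rootward_above_lrc = mean(s$pin_rootward[epi_zone]),
    n_bipolar_cortex = sum(bipolar),
    lrc_auxin = mean(s$IAA[s$type == "LRC"]),
    vascular_auxin = mean(s$IAA[vas]),
    mean_af = mean(s$af_mag),
    mean_pin_entropy = mean(s$pin_entropy[s$pin_mem_total > 1e-9]),
    width_length_ratio = trace$snapshots[[length(trace$snapshots)]]$width /
      trace$snapshots[[length(trace$snapshots)]]$root_length,
    mean_auxin = mean(s$IAA),
    ncell = nrow(s)
  )
}

#' Auxin reflux and source-removal experiment
#'
#' Four paired runs on a shared template and seed: with or without the
#' lateral reflux path (epidermis/LRC to cortex carrier transport), each
#' with or without local auxin synthesis in the QC, and with the
#' shoot-derived source removed mid-run. Probes whether the reflux loop
#' and local production can sustain root growth without the shoot.
#'
#' @param steps total steps; the source is removed at `removal_step`
#' @param removal_step step at which the shoot source is cut
#' @param cells_per_file template size
#' @param seed shared RNG seed
#' @param record_every snapshot cadence
#' @return named list of four `simulation_trace`s:
#'   `noreflux`, `noreflux_qc`, `reflux`, `reflux_qc`
#' @export
reflux_experiment <- function(steps = 1400L, removal_step = 400L,
                              cells_per_file = 6L, seed = 1L,
                              record_every = 25L) {
  base <- list(list(type = "source_removal", step = removal_step))
  no_reflux <- list(list(type = "no_reflux", step = 1L))
  qc_syn <- list(list(type = "qc_synthesis", step = 1L, rate = 10))
  mk <- function(pert) wildtype_config(steps = steps,
                                       cells_per_file = cells_per_file,
                                       seed = seed, record_every = record_every,
                                       perturbations = pert)
  list(
    noreflux    = run_simulation(mk(c(no_reflux, base))),
    noreflux_qc = run_simulation(mk(c(no_reflux, qc_syn, base))),
    reflux      = run_simulation(mk(base)),
    reflux_qc   = run_simulation(mk(c(qc_syn, base)))
  )
}

# mean auxin and mean growth rate over the last fraction of a run
late_stats <- function(trace, tail_frac = 0.25) {
  m <- simulation_metrics(trace)
  ts <- m$timeseries
  n <- nrow(ts)
  sel <- ts$step >= (1 - tail_frac) * max(ts$step)
  list(auxin = mean(ts$mean_IAA[sel]),
       growth = mean(ts$growth_rate[sel], na.rm = TRUE),
       length_gain = ts$root_length[n] - ts$root_length[1])
}

#' Cyclic external-auxin application experiment
#'
#' Runs a wild-type scenario with repeated episodes of ectopic auxin
#' synthesis in every root cell (the model analogue of external auxin
#' application); each pulse floods the root above the wall-stiffening
#' threshold, arresting growth, and growth resumes after withdrawal.
#'
#' @param steps total steps
#' @param pulse_steps start steps of the pulses
#' @param duration pulse length in steps
#' @param rate ectopic synthesis rate (nM/h)
#' @param cells_per_file template size
#' @param seed RNG seed
#' @return list: `trace`, and per-pulse growth statistics `before`,
#'   `during`, `after` (root growth rate, um/h) plus `recovery` ratios
#' @export
pulse_experiment <- function(steps = 1800L, pulse_steps = c(700L, 1250L),
                             duration = 250L, rate = 30,
                             cells_per_file = 6L, seed = 1L) {
  pert <- lapply(pulse_steps, function(s)
    list(type = "auxin_pulse", step = s, duration = duration, rate = rate))
  tr <- run_simulation(wildtype_config(steps = steps,
                                       cells_per_file = cells_per_file,
                                       seed = seed, record_every = 25L,
                                       perturbations = pert))
  ts <- simulation_metrics(tr)$timeseries
  # tissue-area expansion rate: smoother than the organ-length derivative
  win <- function(lo, hi) {
    sel <- ts$step > lo & ts$step <= hi
    mean(ts$area_growth[sel], na.rm = TRUE)
  }
  before <- during <- after <- recovery <- numeric(length(pulse_steps))
  for (k in seq_along(pulse_steps)) {
    s0 <- pulse_steps[k]
    before[k] <- win(s0 - 200L, s0)
    during[k] <- win(s0 + 50L, s0 + duration)
    post_end <- min(s0 + duration + 300L, steps)
    after[k] <- win(s0 + duration + 100L, post_end)
    recovery[k] <- after[k] / pmax(before[k], 1e-9)
  }
  list(trace = tr, before = before, during = during, after = after,
       recovery = recovery)
}

#' Paired contrasts of the perturbation panel
#'
#' Computes the ordinal comparisons each in-silico perturbation is judged
#' by, always against the panel's shared wild-type reference: LRC auxin
#' under the pin2-like knockdown, vascular auxin near the cut after tip
#' excision, loss of the tip maximum and accumulation above the wound
#' after QC ablation, AF collapse/PIN-entropy rise/radial swelling under
#' simulated microtubule disruption, and the tip-contrast drop when the
#' AF input to PIN sensitivity is removed.
#'
#' @param panel result of [perturbation_panel()]
#' @return named list of scalar contrasts (ratios/differences vs wild type)
#' @export
perturbation_contrasts <- function(panel) {
  wt <- panel$wildtype
  s_wt <- wt$snapshots[[length(wt$snapshots)]]$cells
  ps_wt <- pattern_summary(wt)
  out <- list(wildtype = ps_wt)
  zone_mean <- function(s, ylo, yhi, types = NULL) {
    sel <- s$y >= ylo & s$y <= yhi
    if (!is.null(types)) sel <- sel & s$type %in% types
    if (!any(sel)) return(NA_real_)
    mean(s$IAA[sel])
  }
  if (!is.null(panel$pin2)) {
    s <- panel$pin2$snapshots[[length(panel$pin2$snapshots)]]$cells
    out$pin2_lrc_ratio <- mean(s$IAA[s$type == "LRC"]) /
      mean(s_wt$IAA[s_wt$type == "LRC"])
  }
  if (!is.null(panel$tip_excision)) {
    s <- panel$tip_excision$snapshots[[length(panel$tip_excision$snapshots)]]$cells
    cut_y <- min(s$y)
    vt <- c("Vascular", "VascularInitial")
    out$tip_excision_vascular_ratio <-
      zone_mean(s, cut_y, cut_y + 20, vt) / zone_mean(s_wt, cut_y, cut_y + 20, vt)
  }
  if (!is.null(panel$qc_ablation)) {
    tr <- panel$qc_ablation
    # position of the niche before the ablation
    qc_y <- NA_real_
    for (sn in tr$snapshots) {
      if (any(sn$cells$type == "QC")) qc_y <- mean(sn$cells$y[sn$cells$type == "QC"])
    }
    s <- tr$snapshots[[length(tr$snapshots)]]$cells
    # the tip below the wound (columella lineage) loses its supply
    colty <- c("Columella", "ColumellaInitial")
    out$qc_ablation_tip_ratio <- mean(s$IAA[s$type %in% colty]) /
      mean(s_wt$IAA[s_wt$type %in% colty])
    # the severed canal pools auxin in the stele directly above the wound
    vt <- c("Vascular", "VascularInitial", "CEI", "CEID")
    out$qc_ablation_above_wound_ratio <-
      zone_mean(s, qc_y, qc_y + 15, vt) / zone_mean(s_wt, qc_y, qc_y + 15, vt)
  }
  if (!is.null(panel$oryzalin)) {
    ps <- pattern_summary(panel$oryzalin)
    out$oryzalin_af_ratio <- ps$mean_af / ps_wt$mean_af
    out$oryzalin_entropy_diff <- ps$mean_pin_entropy - ps_wt$mean_pin_entropy
    out$oryzalin_swelling <- ps$width_length_ratio / ps_wt$width_length_ratio
  }
  if (!is.null(panel$af_removal)) {
    ps <- pattern_summary(panel$af_removal)
    out$af_removal_contrast_ratio <- ps$tip_auxin_contrast / ps_wt$tip_auxin_contrast
    out$af_removal_entropy_diff <- ps$mean_pin_entropy - ps_wt$mean_pin_entropy
  }
  out
}

#' Perturbation panel
#'
#' Runs the library of in-silico perturbations against a shared wild-type
#' reference: pin2-like knockdown, root-tip excision, QC ablation,
#' simulated cortical-microtubule disruption (fast AF decay) and removal
#' of the AF input to PIN sensitivity. Each run shares the template, seed
#' and duration with the reference so comparisons are paired.
#'
#' @param steps total steps; structural perturbations act at `pert_step`
#' @param pert_step step at which ablations/knockdowns are applied
#' @param cells_per_file template size
#' @param seed shared RNG seed
#' @param which character vector selecting scenarios (default all)
#' @return named list of `simulation_trace`s including `wildtype`
#' @export
perturbation_panel <- function(steps = 1200L, pert_step = 500L,
                               cells_per_file = 6L, seed = 1L,
                               which = c("pin2", "tip_excision",
                                         "qc_ablation", "oryzalin",
                                         "af_removal")) {
  mk <- function(pert = list(), params = default_params())
    wildtype_config(steps = steps, cells_per_file = cells_per_file,
                    seed = seed, record_every = 50L,
                    perturbations = pert, params = params)
  out <- list(wildtype = run_simulation(mk()))
  if ("pin2" %in% which)   # knockdown mutants run mutant from the start
    out$pin2 <- run_simulation(mk(list(list(type = "pin2_knockdown",
                                            step = 1L))))
  if ("tip_excision" %in% which)
    out$tip_excision <- run_simulation(mk(list(list(type = "tip_excision",
                                                    step = pert_step))))
  if ("qc_ablation" %in% which)
    out$qc_ablation <- run_simulation(mk(list(list(type = "qc_ablation",
                                                   step = pert_step))))
  if ("oryzalin" %in% which)
    out$oryzalin <- run_simulation(mk(list(list(type = "oryzalin",
                                                step = pert_step))))
  if ("af_removal" %in% which)
    out$af_removal <- run_simulation(mk(params = default_params(use_af = FALSE)))
  out
}
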