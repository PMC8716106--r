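#' Default model parameters
#'
#' Returns the full parameter set of the coupled root model, grouped by
#' module. Biochemical rate constants follow the published reference
#' parameterization of polar auxin transport in the root meristem (units in
#' nM, micrometres and hours); solver and boundary settings that the
#' biological literature leaves open are exposed here with documented
#' defaults (see the methods vignette).
#'
#' @param ... named overrides, either flat (`kP = 5`) or nested
#'   (`transport = list(K_PIN = 2)`). Flat names are looked up in every
#'   block and replaced where found.
#' @return A nested list of class `rootsim_params` with blocks
#'   `mechanics`, `anisotropy`, `transport`, `polarity`, `growth`,
#'   `boundary`.
#' @export
#' @examples
#' p <- default_params(kP = 5)
#' p$polarity$kP
default_params <- function(...) {
  p <- list(
    mechanics = list(
      dt          = 0.02,  # hours of model time per simulation step
      iterations  = 10L,   # PBD solver passes per step
      # wall (border edge) compression stiffness: cells are incompressible
      k_compress  = 1,
      # internal (centroid spoke) edge stiffness, extension == compression
      k_internal  = 0.15,
      k_shape     = 0.1,   # shape-matching stiffness
      k_bend      = 0.05,  # bending (wall angle) stiffness
      # XPBD pressure compliance alpha-tilde = alpha/dt^2 (solver units)
      pressure_compliance = 300,
      # relative turgor overpressure: area target = rest area * (1 + overpressure)
      overpressure = 0.15,
      # plastic yield: rest lengths/shapes/areas relax toward the current
      # configuration at this rate (per hour) -- viscoelastic walls
      plastic_rate = 0.3,
      strain_stiffness = 1,  # scale of the AF-aligned strain constraint
      all_cells_grow = FALSE # mechanics-only runs lift the QC/columella growth arrest
    ),
    anisotropy = list(
      R_AF = 0.02,            # AF reorientation rate (1/h)
      d_AF = 0.01,            # AF decay rate (1/h)
      strain_threshold = 0.01,# minimum wall strain that triggers reorientation
      af_seed = 0.01,         # |af| below this counts as non-polar (reseeded)
      af_reorient = 1,        # AF rotation rate toward the strain axis (1/h)
      Kaf   = 0.5,            # half-max of AF contribution to PIN sensitivity
      Kgeom = 0.5             # half-max of geometry contribution
    ),
    transport = list(
      b_IAA     = 0,      # basal auxin production (nM/h); 10 in QC-synthesis runs
      DI_IAA    = 1,      # apoplastic auxin diffusion (um^2/h)
      d_IAAb    = 0.0125, # basal auxin degradation (nM/h as printed; used as rate)
      d_IAAMax  = 0.125,  # maximum auxin degradation rate (1/h)
      K_IAAMax  = 5,      # half-max auxin degradation (nM)
      K_AUX1    = 1,      # AUX/LAX import rate coefficient (um/h)
      K_PIN     = 1.4,    # PIN export rate coefficient (um/h)
      b_AUX1    = 1,      # AUX/LAX basal expression (nM/h)
      AUX1_expr = 30,     # auxin-induced AUX/LAX maximal expression (nM/h)
      AUX1_K    = 0.01,   # auxin half-max for AUX/LAX induction (nM)
      AUX1_tr   = 1,      # AUX/LAX trafficking rate (1/h)
      AUX1_Max  = 2,      # cap on cytoplasmic AUX/LAX (nM)
      AUX1_MaxMem = 15,   # cap on membrane AUX/LAX (nM)
      d_AUX1    = 0.08,   # AUX/LAX degradation rate (1/h)
      b_PIN     = 0.2,    # PIN basal expression (nM/h)
      PIN_expr  = 50,     # auxin-induced PIN maximal expression (nM/h)
      PIN_K     = 0.05,   # auxin half-max for PIN induction (nM)
      PIN_tr    = 1,      # PIN trafficking rate (1/h)
      PIN_Max   = 2,      # cap on cytoplasmic PIN (nM)
      PIN_MaxMem = 15,    # cap on membrane PIN (nM)
      d_PIN     = 0.08,   # PIN degradation rate (1/h)
      d_PINmax  = 0.8,    # maximum PIN degradation on membranes (1/h)
      P_IAA     = 0.02,   # passive membrane permeability (um/h); no published value
      wall_thickness = 1, # apoplast thickness (um): apoplast area = L * thickness
      surface_permeability = 0, # exchange with the organ exterior (cuticle: 0)
      n_substeps = 10L    # Euler substeps per mechanics step for chemistry
    ),
    polarity = list(
      mechanism = "flux", # "flux" or "regulator_polarizer"
      use_af = TRUE,      # FALSE removes the AF input to PIN sensitivity
      kAF  = 0,           # AF-only weight (0 in the default model)
      kP   = 3,           # auxin-flow weight
      kAFP = 3,           # AF + auxin-flow interaction weight
      kG   = 3,           # geometry weight
      interaction = "sum",# kAFP term: kAFP*(IAF+IP) as printed; "product" optional
      Kflux = 0.1,        # half-max of flux contribution (nM um)
      clamp_negative_flux = TRUE, # only outward-aligned flux polarizes
      # regulator-polarizer constants
      b_REG = 10, b_POL = 10, d_REG = 0.08, d_POL = 0.08,
      Kreg_tr = 1, Kpol_tr = 0.01,
      D_reg = 1, D_pol = 0.1,
      Kdisp_POL = 10,
      Kreg_IAA = 0.01, Kpol_IAA = 0.01,
      Kreg_GradT = 1, Kreg_GradK = 1,
      Kpol_IP = 0.1,
      grad_amplification = 50,
      eps_dist = 1e-6     # floor for midpoint distances in the gradient metric
    ),
    growth = list(
      kE_Max   = 1,     # maximum wall extension stiffness
      K_1auxin = 0.05,  # auxin-induced wall relaxation coefficient (nM)
      K_2auxin = 3,     # auxin-induced wall stiffening coefficient (nM)
      A_max_factor = 1.5, # division threshold = factor * template area of the type
      min_daughter_frac = 0.2 # reject divisions producing slivers below this
    ),
    boundary = list(
      source_influx = 250, # total auxin influx per Source cell (nM um^2 / h)
      sink_rate     = 1    # first-order auxin export rate of Sink cells (1/h)
    )
  )
  structure(modify_params(p, list(...)), class = "rootsim_params")
}

#' Merge overrides into a parameter list
#'
#' @param p parameter list from [default_params()]
#' @param overrides named list; block names merge recursively, flat names are
#'   searched across blocks.
#' @return modified parameter list
#' @export
modify_params <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == ""))
    stop("parameter overrides must be named")
  for (nm in nms) {
    val <- overrides[[nm]]
    if (nm %in% names(p) && is.list(p[[nm]]) && is.list(val)) {
      p[[nm]][names(val)] <- val
    } else {
      hit <- FALSE
      for (blk in names(p)) {
        if (nm %in% names(p[[blk]])) {
          p[[blk]][[nm]] <- val
          hit <- TRUE
        }
      }
      if (!hit) stop("unknown parameter: ", nm)
    }
  }
  p
}

#' Set a parameter by path
#'
#' Used by [sweep_parameter()] to address one scalar, e.g.
#' `"polarity.kP"` or `"growth.K_1auxin"`.
#'
#' @param p parameter list
#' @param path dotted path `"block.name"` (a bare name is searched in all
#'   blocks)
#' @param value replacement value
#' @return modified parameter list
#' @export
set_param <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    if (!parts[1] %in% names(p) || !parts[2] %in% names(p[[parts[1]]]))
      stop("unknown parameter path: ", path)
    p[[parts[1]]][[parts[2]]] <- value
    p
  } else if (length(parts) == 1) {
    ov <- list(value); names(ov) <- parts
    modify_params(p, ov)
  } else stop("parameter path must be 'block.name': ", path)
}
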