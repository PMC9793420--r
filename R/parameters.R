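#' Default model parameter set
#'
#' Returns the full parameter set of the root-tip model: auxin transport and
#' production rates, per-gene production/degradation rates and half-saturation
#' constants, chromatin-state (EpiO) rates, TOLS2 lateral-inhibition rates,
#' growth rates and zonation boundaries.
#'
#' Units: time in seconds, space in micrometres, concentrations and expression
#' levels in arbitrary units (a.u.). All expression levels follow a 1:100
#' degradation:maximum-production convention giving a maximum level of 100,
#' except ARF (maximum 300, baseline 10) and the TOLS2 production:degradation
#' ratio (1000, compensating for production in few cells and diffusion into
#' many).
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `root_params`.
#' @examples
#' p <- default_parameters()
#' p$p_AUX1 / p$d_AUX1   # maximum AUX1 expression level: 100
#' @export
default_parameters <- function(...) {
  p <- list(
    ## numerics
    dt = 0.4,               # s, PDE and ODE integration step
    dx = 2,                 # um, grid spacing

    ## auxin transport and turnover (grid level)
    p_auxin_baseline = 0.03,  # a.u. s^-1 per grid point, before celltypefactor
    d_auxin  = 1e-4,          # s^-1
    D_cell   = 600,           # um^2 s^-1, cytoplasmic diffusion
    D_wall   = 300,           # um^2 s^-1, apoplastic diffusion
    eff_basal = 0.5,          # s^-1, basal ABCB-mediated efflux
    inf_pas   = 0.5,          # s^-1, passive influx
    p_PIN     = 0.1,          # s^-1 per unit membrane PIN (prepattern x expression)
    p_AUXLAX  = 0.1,          # s^-1 per unit membrane AUX1+LAX3
    PIN_expression = 100,     # constant cellular PIN expression level
    yucca4factor = 0.1525,    # per YUCCA4 unit; 1 + 100*0.1525 = 16.25-fold
    auxin_ext = 0.15,         # a.u., external auxin for shootward boundary inflow
    boundary_outflux_frac = 0.10, # epidermis/cortex top outflow = 10% of influx capacity
    D_rad = 2,                # um s^-1, radial (3D-emulating) exchange rate
    k_homeostasis = 2,        # ARF-dependent extra auxin degradation (homeostasis variant)

    ## baseline gene expression (Eq 6-7 style)
    p_AUX1 = 0.01,  Km_AUX1 = 75,  d_AUX1 = 1e-4,
    p_Diff = 0.01,  d_Diff  = 1e-4, Th_Diff = 85, diff_gate = 80,

    ## direct/epio feedback expression
    LAX3_constant = 40,          # baseline-model constant LAX3 level
    p_LAX3_basal = 4e-3,         # basal LAX3 production (level 40)
    p_LAX3_auxin = 6e-3,         # maximum auxin-dependent extra production
    Km_LAX3 = 20, d_LAX3 = 1e-4,
    p_vasc = 4e-3,               # epio model: ungated vascular LAX3 production
    p_priming = 6e-3,            # epio model: EpiO-gated priming LAX3 production
    p_YUCCA4 = 1.2e-3 * 10, Km_YUCCA4 = 20, d_YUCCA4 = 1.2e-4,

    ## ARF / AUX-IAA signalling
    bind = 1e-3,        # per a.u. s^-1, ARF-AUX/IAA association
    unbind = 1e-3,      # s^-1, complex dissociation
    pIAA = 0.01,        # a.u. s^-1, AUX/IAA production
    d_IAAbasal = 1e-4,  # s^-1
    dIAATIR1 = 2e-4,    # s^-1 per a.u. auxin, TIR1/AFB-mediated IAA degradation
    p_ARFbasal = 1.5e-3,   # baseline ARF production (level 10)
    p_ARFauxin = 4.35e-2,  # auxin-dependent ARF production (level 300 max)
    Km_ARF = 30, d_ARF = 1.5e-4,

    ## EpiO chromatin integrator
    open_EpiO = 1e-2,    # a.u. s^-1, maximum chromatin opening rate
    close_EpiO = 1e-2,   # s^-1, maximum chromatin closing rate
    frac_min = 0.01,     # minimum effective fraction of the closing rate
    Km_EpiO_1 = 210,     # signalling half-max of opening function F1
    n_EpiO_1 = 6,
    Km_EpiO_2 = 1,       # EpiO half-max of closing-inhibition function F2
    n_EpiO_2 = 4,
    Km_trans = 10,       # EpiO half-max of the transcription gate F3
    n_trans = 6,

    ## TOLS2 lateral inhibition
    p_TOLS2 = 0.15, Km_TOLS2 = 100, d_TOLS2 = 1.5e-4,
    D_TOLS2 = 2e-4,      # s^-1, cell-to-cell exchange rate (decay length ~1 cell)
    p_IAA_TOLS2 = 4, Km_IAA_1 = 50, Km_IAA_2 = 25,

    ## growth
    cellcycle = 9,            # h, division cell cycle (doubling time)
    expansion_duration = 7,   # h, EZ expansion timescale
    tz_growth_rate = NA_real_, # per-um rate for TZ growth; NA = same as MZ
    noise_amplitude = 0.05,   # deterministic +/-5% division-rate staggering

    ## zonation (um from the root tip, lower-boundary convention)
    mz_end = 514, tz_start = 364, lrcap_mz_end = 314,

    ## reference cell height for production normalization
    reference_height_rows = 4
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  structure(p, class = "root_params")
}

#' Scenario configuration
#'
#' Bundles a parameter set with the experiment toggles that define a model
#' variant: feedback mode, lateral inhibition, transporter asymmetry, growth,
#' radial coupling, PIN-prepattern variant, dosage perturbations and an
#' optional imposed auxin pulse.
#'
#' @param params a `root_params` list, see [default_parameters()].
#' @param feedback_mode `"none"` (baseline: LAX3 constant, no induced
#'   YUCCA4/ARF), `"direct"` (auxin-dependent LAX3/YUCCA4/ARF gated only by
#'   differentiation), or `"epio"` (additionally gated by the chromatin open
#'   state).
#' @param tols2_enabled enable TOLS2 peptide lateral inhibition.
#' @param aux1_asymmetry fractional reduction of AUX1 expression on the left
#'   side's pericycle and vasculature files (symmetry-breaking experiments).
#' @param aux1_Km_override half-saturation constant for AUX1 induction
#'   (default `params$Km_AUX1`; the symmetry-breaking preset uses 85).
#' @param growth_enabled enable growth/division/culling dynamics.
#' @param radial_mode `"walls-only"` (default), `"walls+cells"`, `"off"`, or
#'   `"enhanced"` (walls-only at 4x rate).
#' @param dz_pin_variant `"default"` (more apolar endodermal/cortical PIN in
#'   the DZ) or `"apolar-equal"` (DZ PIN identical to EZ).
#' @param auxin_content_scale multiplies all auxin production and external
#'   boundary auxin (dosage experiments; 0.9 = 10% reduction).
#' @param boundary_influx_scale multiplies shootward boundary inflow.
#' @param arf_max_scale multiplies the auxin-dependent ARF production rate.
#' @param homeostasis_enabled enable ARF-dependent auxin degradation.
#' @param epio_blocked_early_ez block chromatin opening over the stationary
#'   auxin-loading pool at the start of the elongation zone (no-growth
#'   scenarios, where the pool would otherwise self-activate the feedback).
#' @param feedback_start_h hold the feedback genes and chromatin state
#'   inactive (baseline behaviour) until this simulated time; used to let
#'   growth-on runs equilibrate before the competition for stable sites
#'   starts (0 = active from the start).
#' @param pulse `NULL` or `list(amplitude, duration_h, start_h)`: auxin is
#'   clamped up to `amplitude` in a distal pericycle band for `duration_h`
#'   hours starting at `start_h` (default 0).
#' @param geometry `"fixture"` (small test tissue), `"small"`, or `"full"`
#'   (141 x 1516 grid); or a list from [geometry_spec()].
#' @param duration_h simulated duration in hours.
#' @param sampling_interval sampling interval in seconds (default 100).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(params = default_parameters(),
                            feedback_mode = c("none", "direct", "epio"),
                            tols2_enabled = FALSE,
                            aux1_asymmetry = 0,
                            aux1_Km_override = NULL,
                            growth_enabled = TRUE,
                            radial_mode = c("walls-only", "walls+cells", "off", "enhanced"),
                            dz_pin_variant = c("default", "apolar-equal"),
                            auxin_content_scale = 1,
                            boundary_influx_scale = 1,
                            arf_max_scale = 1,
                            homeostasis_enabled = FALSE,
                            epio_blocked_early_ez = FALSE,
                            feedback_start_h = 0,
                            pulse = NULL,
                            geometry = "fixture",
                            duration_h = 24,
                            sampling_interval = 100) {
  feedback_mode <- match.arg(feedback_mode)
  radial_mode <- match.arg(radial_mode)
  dz_pin_variant <- match.arg(dz_pin_variant)
  stopifnot(inherits(params, "root_params"),
            auxin_content_scale > 0, boundary_influx_scale > 0,
            arf_max_scale > 0, aux1_asymmetry >= 0, aux1_asymmetry < 1)
  if (!is.null(pulse)) {
    stopifnot(is.list(pulse), !is.null(pulse$amplitude), !is.null(pulse$duration_h))
    pulse$region <- pulse$region %||% "shootward_ez"
    pulse$start_h <- pulse$start_h %||% 0
  }
  if (is.character(geometry)) geometry <- geometry_spec(geometry)
  structure(list(
    params = params, feedback_mode = feedback_mode,
    tols2_enabled = tols2_enabled, aux1_asymmetry = aux1_asymmetry,
    aux1_Km = aux1_Km_override %||% params$Km_AUX1,
    growth_enabled = growth_enabled, radial_mode = radial_mode,
    dz_pin_variant = dz_pin_variant,
    auxin_content_scale = auxin_content_scale,
    boundary_influx_scale = boundary_influx_scale,
    arf_max_scale = arf_max_scale,
    homeostasis_enabled = homeostasis_enabled,
    epio_blocked_early_ez = epio_blocked_early_ez,
    feedback_start_h = feedback_start_h,
    pulse = pulse, geometry = geometry,
    duration_h = duration_h, sampling_interval = sampling_interval
  ), class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometry specification
#'
#' Named tissue geometries. `"full"` is the 141 x 1516-point (282 x 3032 um)
#' domain; `"small"` and `"fixture"` are proportionally shrunken domains for
#' desk-scale runs, with developmental-zone boundaries scaled by the same
#' factor so the zonal anatomy is preserved.
#'
#' @param name `"fixture"`, `"small"`, or `"full"`.
#' @return list with `n_cols`, `n_rows`, `cell_height_rows`, `zone_scale`,
#'   and per-file widths (grid points).
#' @export
geometry_spec <- function(name = c("fixture", "small", "full")) {
  name <- match.arg(name)
  ## widths in grid points per file, outside-in; full-scale totals 141 columns:
  ## 14 wall columns + 2*(lrcap 8 + epi 12 + cortex 14 + endo 8 + peri 8 + vasc 8) + centre 11
  switch(name,
    full = list(
      name = "full", n_cols = 141, n_rows = 1516,
      widths = c(lrcap = 8, epidermis = 12, cortex = 14, endodermis = 8,
                 pericycle = 8, vasculature = 8, centre = 11),
      cell_height_rows = 4,    # 8 um initial height, uniform
      zone_scale = 1, cap_rows = 40
    ),
    small = list(
      name = "small", n_cols = 61, n_rows = 400,
      widths = c(lrcap = 3, epidermis = 4, cortex = 5, endodermis = 3,
                 pericycle = 3, vasculature = 3, centre = 5),
      cell_height_rows = 4,
      zone_scale = 0.5, cap_rows = 20
    ),
    fixture = list(
      name = "fixture", n_cols = 61, n_rows = 220,
      widths = c(lrcap = 3, epidermis = 4, cortex = 5, endodermis = 3,
                 pericycle = 3, vasculature = 3, centre = 5),
      cell_height_rows = 4,
      zone_scale = 0.25, cap_rows = 12
    ))
}

#' Named scenario presets
#'
#' Each preset is the configuration of one in-silico experiment: the model
#' variant plus only the perturbations that experiment states.
#'
#' * `baseline`: no feedback (LAX3 constant at 40, no induced YUCCA4/ARF).
#' * `direct_feedback`: auxin-dependent LAX3 + YUCCA4 + ARF (max 300, Km 30),
#'   gated by differentiation only.
#' * `epio`: time-integrated feedback; LAX3/YUCCA4/ARF induction gated by the
#'   chromatin open state.
#' * `tols2`: `epio` plus TOLS2 lateral inhibition.
#' * `symmetry_breaking`: `tols2` plus 10% AUX1 asymmetry and AUX1 Km 85.
#' * `low_auxin`: `epio` with root-tip auxin content scaled by 0.9.
#' * `potent_arf7`: `epio` with ARF maximum halved and boundary influx x1.4.
#' * `homeostasis`: `epio` with influx x1.4 plus ARF-dependent auxin
#'   degradation.
#' * `apolar_dz_pin`: `epio` with endodermal/cortical DZ PIN equal to the EZ
#'   pattern.
#' * `nogrowth_pulse`: `epio` with growth off, chromatin opening blocked in
#'   the first 100 um of the EZ, and a 250 a.u. x 3 h auxin pulse in the
#'   shootward EZ.
#'
#' @param name preset name, see Details.
#' @param geometry geometry name or a list from [geometry_spec()], passed to [scenario_config()].
#' @param duration_h simulated hours.
#' @param ... further overrides forwarded to [scenario_config()].
#' @return A `scenario_config`.
#' @export
preset <- function(name, geometry = "fixture", duration_h = 24, ...) {
  known <- c("baseline", "direct_feedback", "epio", "tols2",
             "symmetry_breaking", "low_auxin", "potent_arf7", "homeostasis",
             "apolar_dz_pin", "nogrowth_pulse")
  if (!name %in% known)
    stop("unknown preset '", name, "'; known: ", paste(known, collapse = ", "))
  base <- list(geometry = geometry, duration_h = duration_h)
  args <- switch(name,
    baseline        = list(feedback_mode = "none"),
    direct_feedback = list(feedback_mode = "direct"),
    epio            = list(feedback_mode = "epio"),
    tols2           = list(feedback_mode = "epio", tols2_enabled = TRUE),
    symmetry_breaking = list(feedback_mode = "epio", tols2_enabled = TRUE,
                             aux1_asymmetry = 0.10, aux1_Km_override = 85),
    low_auxin       = list(feedback_mode = "epio", auxin_content_scale = 0.9),
    potent_arf7     = list(feedback_mode = "epio", arf_max_scale = 0.5,
                           boundary_influx_scale = 1.4),
    homeostasis     = list(feedback_mode = "epio", boundary_influx_scale = 1.4,
                           homeostasis_enabled = TRUE),
    apolar_dz_pin   = list(feedback_mode = "epio", dz_pin_variant = "apolar-equal"),
    nogrowth_pulse  = list(feedback_mode = "epio", growth_enabled = FALSE,
                           epio_blocked_early_ez = TRUE,
                           pulse = list(amplitude = 250, duration_h = 3,
                                        region = "shootward_ez",
                                        start_h = 12))
  )
  do.call(scenario_config, utils::modifyList(c(base, args), list(...)))
}

#' List the named presets
#' @return character vector of preset names.
#' @export
list_presets <- function() {
  c("baseline", "direct_feedback", "epio", "tols2", "symmetry_breaking",
    "low_auxin", "potent_arf7", "homeostasis", "apolar_dz_pin",
    "nogrowth_pulse")
}
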