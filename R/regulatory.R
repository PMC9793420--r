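## Per-cell gene regulation: auxin signalling with AUX/IAA quasi-steady-state,
## baseline and feedback gene expression, the EpiO chromatin integrator, and
## TOLS2 lateral inhibition. All functions are vectorized over cells and
## advance state with forward Euler at the PDE time step.

hill <- function(x, Km, n = 1) {
  x <- pmax(x, 0)
  xn <- x^n
  xn / (xn + Km^n)
}

#' Quasi-steady-state free ARF level
#'
#' Free ARF follows from the equilibrium of ARF-AUX/IAA association and
#' dissociation, with AUX/IAA itself at a quasi-steady state set by its
#' production (`pIAA * IAAreg`) and its basal plus auxin-dependent
#' (TIR1/AFB-mediated) degradation. Higher auxin degrades AUX/IAA faster,
#' lowering the sequestered fraction and freeing ARF.
#'
#' @param auxin cellular auxin level (a.u.), vectorized.
#' @param ARFtotal total expressed ARF (a.u.), vectorized.
#' @param params `root_params`.
#' @param IAAreg dimensionless AUX/IAA production multiplier (1 = wild type;
#'   raised by TOLS2 signalling, see [iaareg()]).
#' @return free ARF (a.u.), same length as inputs.
#' @export
free_arf_qss <- function(auxin, ARFtotal, params, IAAreg = 1) {
  stopifnot(all(auxin >= 0))
  IAA <- (params$pIAA * IAAreg) / (params$d_IAAbasal + params$dIAATIR1 * auxin)
  if (params$bind == 0) return(ARFtotal)
  ARFtotal * params$unbind / (params$unbind + params$bind * IAA)
}

#' Overall auxin signalling level
#'
#' Baseline signalling equals the cellular auxin level (ubiquitously expressed
#' response factors are not modelled explicitly). Cells expressing the
#' inducible generic ARF add signalling equal to the added capacity
#' (`ARFtotal`) times the fraction of that capacity in use (free over total
#' ARF), i.e. the free ARF level.
#'
#' @param auxin cellular auxin (a.u.).
#' @param ARFtotal total inducible ARF (a.u.).
#' @param ARFfree free inducible ARF (a.u.), `0 <= ARFfree <= ARFtotal`.
#' @return signalling level (a.u.).
#' @export
auxin_signalling <- function(auxin, ARFtotal, ARFfree) {
  stopifnot(all(ARFfree >= -1e-9), all(ARFfree <= ARFtotal + 1e-9))
  frac <- ifelse(ARFtotal > 0, ARFfree / ARFtotal, 0)
  auxin + ARFtotal * frac
}

#' Chromatin-opening input function F1
#'
#' Saturating (Hill) function of auxin signalling; half-maximal at
#' `Km_EpiO_1`.
#' @param signalling auxin signalling (a.u.).
#' @param params `root_params`.
#' @return value in \[0, 1\].
#' @export
epio_f1 <- function(signalling, params) {
  hill(signalling, params$Km_EpiO_1, params$n_EpiO_1)
}

#' Transcription-permissive chromatin gate F3
#'
#' Sigmoidal gate on the chromatin open state: auxin-dependent transcription
#' of the feedback genes is half-maximal at `EpiO = Km_trans` and requires a
#' sufficiently open state to proceed at all.
#' @param EpiO chromatin open state (a.u.).
#' @param params `root_params`.
#' @return value in \[0, 1\].
#' @export
epio_gate <- function(EpiO, params) {
  hill(EpiO, params$Km_trans, params$n_trans)
}

#' Advance the chromatin open state (EpiO)
#'
#' `dEpiO/dt = open_EpiO * F1(S) - close_EpiO * max(frac_min,
#' (1 - F1(S)) * (1 - F2(EpiO))) * EpiO`. Opening saturates with auxin
#' signalling (F1); closing is inhibited both by signalling (1 - F1) and by
#' the open state itself (1 - F2), representing transcriptional activity
#' counteracting chromatin closing, but never drops below `frac_min` of the
#' maximum closing rate. With maximum opening and minimum closing the steady
#' state is `open_EpiO / (close_EpiO * frac_min) = 100`.
#'
#' @param EpiO current open state (a.u.), vectorized.
#' @param signalling auxin signalling (a.u.).
#' @param dt time step (s).
#' @param params `root_params`.
#' @param open_blocked logical vector; where TRUE the opening term is zeroed
#'   (used by the no-growth scenario to block activation at the EZ start).
#' @return updated EpiO.
#' @export
step_epio <- function(EpiO, signalling, dt, params, open_blocked = FALSE) {
  f1 <- epio_f1(signalling, params)
  f2 <- hill(EpiO, params$Km_EpiO_2, params$n_EpiO_2)
  closing_frac <- pmax(params$frac_min, (1 - f1) * (1 - f2))
  opening <- params$open_EpiO * f1
  if (any(open_blocked)) opening <- opening * (!open_blocked)
  pmax(0, EpiO + dt * (opening - params$close_EpiO * closing_frac * EpiO))
}

#' Advance baseline expression (AUX1 and the differentiation factor)
#'
#' AUX1 production saturates with auxin (half-max `Km`), first-order decay.
#' The differentiation factor accumulates at a constant rate outside the
#' meristem and decays everywhere, permitting dedifferentiation.
#'
#' @param AUX1,Diff current levels (a.u.), vectorized over cells.
#' @param auxin cellular auxin (a.u.).
#' @param in_mz logical; TRUE for meristematic (MZ or TZ) cells, where the
#'   differentiation production term is zero.
#' @param dt time step (s).
#' @param params `root_params`.
#' @param Km AUX1 half-saturation (default `params$Km_AUX1`; the
#'   symmetry-breaking experiments override it).
#' @param aux1_production_scale per-cell multiplier on AUX1 production
#'   (asymmetry experiments), default 1.
#' @return list with updated `AUX1` and `Diff`.
#' @export
step_baseline_expression <- function(AUX1, Diff, auxin, in_mz, dt, params,
                                     Km = params$Km_AUX1,
                                     aux1_production_scale = 1) {
  AUX1 <- AUX1 + dt * (aux1_production_scale * params$p_AUX1 *
                         hill(auxin, Km) - params$d_AUX1 * AUX1)
  Diff <- Diff + dt * (params$p_Diff * (!in_mz) - params$d_Diff * Diff)
  list(AUX1 = pmax(AUX1, 0), Diff = pmax(Diff, 0))
}

#' Advance feedback gene expression (LAX3, YUCCA4, ARF)
#'
#' Behaviour depends on the feedback mode:
#' * `"none"`: LAX3 held constant at 40; no YUCCA4 or ARF induction.
#' * `"direct"`: auxin-signalling-dependent production terms, active only
#'   once the differentiation factor exceeds the gate (Diff > 80).
#' * `"epio"`: as `"direct"` but with each induced term additionally
#'   multiplied by the chromatin gate F3(EpiO); LAX3 production splits into
#'   an ungated vascular part (`p_vasc`) and a gated priming part
#'   (`p_priming`).
#'
#' YUCCA4 induction is restricted to vasculature and pericycle; YUCCA4 and
#' ARF induction are restricted to cells outside the meristem (EZ and DZ).
#'
#' @param LAX3,YUCCA4,ARFtotal current levels, vectorized over cells.
#' @param signalling auxin signalling (a.u.).
#' @param Diff differentiation factor (a.u.).
#' @param EpiO chromatin open state (a.u.; ignored unless mode `"epio"`).
#' @param is_stele logical, TRUE for vasculature/pericycle cells.
#' @param in_mz logical, TRUE for MZ/TZ cells.
#' @param dt time step (s).
#' @param params `root_params`.
#' @param mode `"none"`, `"direct"`, or `"epio"`.
#' @param arf_max_scale multiplier on auxin-dependent ARF production.
#' @return list with updated `LAX3`, `YUCCA4`, `ARFtotal`.
#' @export
step_feedback_expression <- function(LAX3, YUCCA4, ARFtotal, signalling, Diff,
                                     EpiO, is_stele, in_mz, dt, params,
                                     mode = c("none", "direct", "epio"),
                                     arf_max_scale = 1) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(list(LAX3 = rep_len(params$LAX3_constant, length(LAX3)),
                YUCCA4 = YUCCA4 + dt * (-params$d_YUCCA4 * YUCCA4),
                ARFtotal = ARFtotal + dt * (-params$d_ARF * ARFtotal)))
  }
  gate_diff <- as.numeric(Diff > params$diff_gate)
  gate_zone <- as.numeric(!in_mz)
  f3 <- if (mode == "epio") epio_gate(EpiO, params) else 1

  if (mode == "direct") {
    p_lax3 <- params$p_LAX3_basal +
      gate_diff * params$p_LAX3_auxin * hill(signalling, params$Km_LAX3)
  } else {
    p_lax3 <- params$p_vasc * hill(signalling, params$Km_LAX3) +
      gate_diff * f3 * params$p_priming * hill(signalling, params$Km_LAX3)
  }
  LAX3 <- LAX3 + dt * (p_lax3 - params$d_LAX3 * LAX3)

  p_y <- gate_diff * gate_zone * as.numeric(is_stele) * f3 *
    params$p_YUCCA4 * hill(signalling, params$Km_YUCCA4)
  YUCCA4 <- YUCCA4 + dt * (p_y - params$d_YUCCA4 * YUCCA4)

  p_arf <- params$p_ARFbasal + gate_diff * gate_zone * f3 *
    arf_max_scale * params$p_ARFauxin * hill(signalling, params$Km_ARF)
  ARFtotal <- ARFtotal + dt * (p_arf - params$d_ARF * ARFtotal)

  list(LAX3 = pmax(LAX3, 0), YUCCA4 = pmax(YUCCA4, 0),
       ARFtotal = pmax(ARFtotal, 0))
}

#' AUX/IAA production multiplier from TOLS2 signalling
#'
#' Lateral inhibition: TOLS2 raises AUX/IAA production (saturating at
#' `Km_IAA_1`), but a cell's own free ARF protects it (repression saturating
#' at `Km_IAA_2`), so inhibition lands on neighbours with low free ARF.
#' Without TOLS2 the multiplier is the wild-type constant 1.
#'
#' @param TOLS2 local TOLS2 level (a.u.).
#' @param ARFfree free ARF (a.u.).
#' @param params `root_params`.
#' @return multiplier `>= 1`.
#' @export
iaareg <- function(TOLS2, ARFfree, params) {
  1 + params$p_IAA_TOLS2 * hill(TOLS2, params$Km_IAA_1) *
    (params$Km_IAA_2 / (pmax(ARFfree, 0) + params$Km_IAA_2))
}

#' Advance TOLS2 peptide levels
#'
#' Per-cell production saturating in free ARF, first-order decay, and simple
#' cell-to-cell diffusion along the compartment graph (exchange rate
#' `D_TOLS2` per neighbour pair).
#'
#' @param TOLS2 current per-cell levels.
#' @param ARFfree free ARF per cell.
#' @param neighbours list (per cell) of integer indices of adjacent cells.
#' @param dt time step (s).
#' @param params `root_params`.
#' @return updated TOLS2 vector.
#' @export
step_tols2 <- function(TOLS2, ARFfree, neighbours, dt, params) {
  prod <- params$p_TOLS2 * hill(ARFfree, params$Km_TOLS2)
  diff_term <- vapply(seq_along(TOLS2), function(i) {
    nb <- neighbours[[i]]
    if (!length(nb)) return(0)
    sum(TOLS2[nb] - TOLS2[i])
  }, numeric(1))
  pmax(0, TOLS2 + dt * (prod - params$d_TOLS2 * TOLS2 +
                          params$D_TOLS2 * diff_term))
}
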