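## Grid-level auxin dynamics: production, degradation, diffusion, polar
## membrane transport, shootward boundary exchange and radial (3D-emulating)
## coupling, advanced by an alternating direction semi-implicit scheme
## (compiled core in src/adi.cpp).

#' Per-point auxin production rate of a cell
#'
#' Baseline rate times the cell-type factor (100 for QC, top columella and
#' vascular initials, 50 for lower columella, 30 for the lateral-root cap, 1
#' otherwise) plus the YUCCA4-dependent term (calibrated so YUCCA4 = 100
#' raises production 16.25-fold at factor 1), normalized by cell height so a
#' cell's total production does not depend on its height.
#'
#' @param celltypefactor cell-type production factor.
#' @param YUCCA4 cellular YUCCA4 expression (a.u.).
#' @param height_rows integer cell height in grid rows.
#' @param params `root_params`.
#' @param content_scale dosage multiplier (auxin-content experiments).
#' @return production rate per grid point (a.u. s^-1), vectorized.
#' @export
production_rate_at <- function(celltypefactor, YUCCA4, height_rows,
                               params = default_parameters(),
                               content_scale = 1) {
  params$p_auxin_baseline * content_scale *
    (celltypefactor + params$yucca4factor * YUCCA4) *
    (params$reference_height_rows / height_rows)
}

## per-cell production-rate vector for the solver
production_rates <- function(tissue, config) {
  cs <- tissue$cells
  n <- tissue$n_cells
  h <- pmax(cs$row1[1:n] - cs$row0[1:n] + 1L, 1L)
  production_rate_at(cs$ctf[1:n], tissue$state$YUCCA4[1:n], h, config$params,
                     config$auxin_content_scale)
}

#' Membrane fluxes across one membrane/wall point pair
#'
#' Efflux (cell to wall) is basal ABCB efflux plus PIN-mediated efflux, with
#' membrane PIN equal to the prepattern weight times the (constant) cellular
#' PIN expression; influx (wall to cell) is passive influx plus AUX1/LAX3-
#' mediated influx, with membrane carrier levels equal to prepattern weight
#' times cellular expression.
#'
#' @param auxin_cell auxin at the membrane grid point (a.u.).
#' @param auxin_wall auxin at the adjacent wall point (a.u.).
#' @param wPIN,wAUX1,wLAX3 prepattern weights at the membrane point.
#' @param AUX1,LAX3 cellular expression levels (a.u.).
#' @param params `root_params`.
#' @return list with `efflux` and `influx` (a.u. s^-1).
#' @export
membrane_flux <- function(auxin_cell, auxin_wall, wPIN, wAUX1, wLAX3,
                          AUX1, LAX3, params = default_parameters()) {
  eff <- (params$eff_basal + params$p_PIN * wPIN * params$PIN_expression) *
    auxin_cell
  inf <- (params$inf_pas + params$p_AUXLAX * (wAUX1 * AUX1 + wLAX3 * LAX3)) *
    auxin_wall
  list(efflux = eff, influx = inf)
}

#' Shootward boundary exchange terms
#'
#' The rest of the plant is not modelled explicitly: the walls above the
#' topmost vascular, pericycle and endodermal cells receive an auxin inflow
#' equal to a constant external auxin concentration times the (basal + PIN)
#' efflux capacity of the topmost simulated cell of that file, and the walls
#' above the topmost epidermal and cortical cells lose wall auxin at 10% of
#' the (passive + AUX1/LAX3) influx capacity of the topmost simulated cell.
#'
#' @param tissue tissue environment.
#' @param config `scenario_config`.
#' @return list with `src_idx`/`src_rate` (inflow points, a.u. s^-1) and
#'   `sink_idx`/`sink_rate` (outflow points, s^-1); indices are linear into
#'   the grid matrices.
#' @export
boundary_exchange <- function(tissue, config) {
  params <- config$params
  nr <- tissue$n_rows
  src_idx <- integer(0); src_rate <- numeric(0)
  sink_idx <- integer(0); sink_rate <- numeric(0)
  for (f in seq_len(nrow(tissue$files))) {
    ty <- tissue$files$type[f]
    if (!ty %in% c("vasculature", "pericycle", "endodermis", "epidermis",
                   "cortex")) next
    top <- file_top_cell(tissue, f)
    if (is.na(top)) next
    r1 <- tissue$cells$row1[top]
    if (r1 + 1L > nr) next
    cols <- tissue$cells$col0[top]:tissue$cells$col1[top]
    wall_lin <- (cols - 1L) * nr + (r1 + 1L)
    if (ty %in% c("vasculature", "pericycle", "endodermis")) {
      eff <- params$eff_basal +
        params$p_PIN * tissue$wPIN[r1, cols] * params$PIN_expression
      src_idx <- c(src_idx, wall_lin)
      src_rate <- c(src_rate, params$auxin_ext * config$auxin_content_scale *
                      config$boundary_influx_scale * eff)
    } else {
      infl <- params$inf_pas + params$p_AUXLAX *
        (tissue$wAUX1[r1, cols] * tissue$state$AUX1[top] +
           tissue$wLAX3[r1, cols] * tissue$state$LAX3[top])
      sink_idx <- c(sink_idx, wall_lin)
      sink_rate <- c(sink_rate, params$boundary_outflux_frac * infl)
    }
  }
  list(src_idx = src_idx, src_rate = src_rate,
       sink_idx = sink_idx, sink_rate = sink_rate)
}

#' Radial (3D-emulating) coupling terms
#'
#' The model is a 2-D longitudinal cross-section; to emulate radial auxin
#' flows of the 3-D root it exchanges auxin between laterally symmetric
#' positions, at a rate inversely scaled with the radial distance between
#' the pair. The default couples only wall points (passive, antisymmetric
#' exchange); `"walls+cells"` additionally exchanges between non-wall points
#' weighted by each point's efflux:(efflux+influx) ratio; `"off"` returns
#' zeros; `"enhanced"` is the wall coupling at four times the rate.
#'
#' @param field auxin concentration matrix.
#' @param tissue tissue environment.
#' @param config `scenario_config` (provides mode and parameters).
#' @return matrix of added time derivatives (a.u. s^-1) per grid point.
#' @export
radial_coupling_terms <- function(field, tissue, config) {
  params <- config$params
  mode <- config$radial_mode
  nr <- tissue$n_rows; nc <- tissue$n_cols
  out <- matrix(0, nr, nc)
  if (mode == "off") return(out)
  D_rad <- params$D_rad * if (mode == "enhanced") 4 else 1
  mc <- (nc + 1L) %/% 2L
  if (2L * mc - 1L != nc) stop("radial coupling requires symmetric (odd) column count")
  for (jl in seq_len(mc - 1L)) {
    jr <- nc + 1L - jl
    raddist <- (jr - jl) * tissue$dx
    wl <- tissue$kind[, jl] == KIND_WALL & tissue$kind[, jr] == KIND_WALL
    ex <- D_rad * (field[wl, jr] - field[wl, jl]) / raddist
    out[wl, jl] <- out[wl, jl] + ex
    out[wl, jr] <- out[wl, jr] - ex
    if (mode == "walls+cells") {
      cl <- tissue$kind[, jl] %in% c(KIND_INTERIOR, KIND_MEMBRANE) &
        tissue$kind[, jr] %in% c(KIND_INTERIOR, KIND_MEMBRANE)
      if (any(cl)) {
        ratio <- function(j, rows) {
          eff <- rep(params$eff_basal, sum(rows))
          inf <- rep(params$inf_pas, sum(rows))
          mem <- tissue$kind[rows, j] == KIND_MEMBRANE
          id <- tissue$cell_id[rows, j]
          eff[mem] <- eff[mem] + params$p_PIN * tissue$wPIN[rows, j][mem] *
            params$PIN_expression
          inf[mem] <- inf[mem] + params$p_AUXLAX *
            (tissue$wAUX1[rows, j][mem] * tissue$state$AUX1[id[mem]] +
               tissue$wLAX3[rows, j][mem] * tissue$state$LAX3[id[mem]])
          eff / (eff + inf)
        }
        rl <- ratio(jl, cl); rr <- ratio(jr, cl)
        ex <- D_rad * (rr * field[cl, jr] - rl * field[cl, jl]) / raddist
        out[cl, jl] <- out[cl, jl] + ex
        out[cl, jr] <- out[cl, jr] - ex
      }
    }
  }
  out
}

#' Advance the auxin field by one time step
#'
#' Applies production, radial coupling and boundary exchange explicitly, then
#' two backward-Euler sweeps, implicit along rows and then along columns;
#' diffusion and membrane transport terms are assigned to the sweep of their
#' direction and degradation to the column sweep. The flux-form
#' discretization conserves mass exactly in a closed system.
#'
#' @param tissue tissue environment (the `auxin` matrix is updated in place).
#' @param config `scenario_config`.
#' @param dt time step (s), default `params$dt`.
#' @param decay_mult per-cell degradation multiplier (homeostasis variant).
#' @return list with `cell_mean` (per-cell mean auxin), mass-balance
#'   diagnostics (`prod_added`, `boundary_net`, `decay_removed`), and the
#'   clipping counter.
#' @export
step_auxin <- function(tissue, config, dt = config$params$dt,
                       decay_mult = NULL) {
  params <- config$params
  n <- tissue$n_cells
  if (is.null(decay_mult)) decay_mult <- rep(1, n)
  ## boundary terms depend on geometry and (slowly varying) carrier levels:
  ## refresh on geometry change or every 25 steps
  cnt <- tissue$be_count %||% 25L
  if (is.null(tissue$be_cache) ||
      !identical(tissue$be_stamp, tissue$geom_stamp) || cnt >= 25L) {
    tissue$be_cache <- boundary_exchange(tissue, config)
    tissue$be_stamp <- tissue$geom_stamp
    tissue$be_count <- 0L
  } else {
    tissue$be_count <- cnt + 1L
  }
  be <- tissue$be_cache
  mode_code <- switch(config$radial_mode, off = 0L, `walls-only` = 1L,
                      `walls+cells` = 2L, enhanced = 3L)
  D_rad <- params$D_rad * if (config$radial_mode == "enhanced") 4 else 1
  res <- step_auxin_cpp(
    tissue$auxin, tissue$kind, tissue$cell_id,
    tissue$wPIN, tissue$wAUX1, tissue$wLAX3,
    tissue$state$AUX1[1:n], tissue$state$LAX3[1:n],
    rep(params$PIN_expression, n), production_rates(tissue, config),
    decay_mult, dt, params$dx, params$D_cell, params$D_wall,
    params$eff_basal, params$inf_pas, params$p_PIN, params$p_AUXLAX,
    params$d_auxin, mode_code, D_rad,
    be$src_idx, be$src_rate, be$sink_idx, be$sink_rate)
  if (!res$finite)
    stop("auxin solver produced non-finite values (diverged); ",
         "last good total auxin: ", sum(tissue$auxin))
  tissue$auxin <- res$field
  res
}

#' Per-cell net auxin flux vectors
#'
#' Sums the directed membrane fluxes (efflux outward positive) over each
#' cell's membrane points into a net flux vector, reported as components,
#' angle and magnitude. `fx` is positive toward higher columns (left to
#' right), `fy` positive shootward.
#'
#' @param tissue tissue environment.
#' @param config `scenario_config`.
#' @return tibble with one row per living cell: `id`, `fx`, `fy`, `angle`
#'   (radians, atan2(fy, fx)) and `magnitude`.
#' @export
compute_flux_vectors <- function(tissue, config) {
  params <- config$params
  n <- tissue$n_cells
  res <- flux_vectors_cpp(tissue$auxin, tissue$kind, tissue$cell_id,
                          tissue$wPIN, tissue$wAUX1, tissue$wLAX3,
                          tissue$state$AUX1[1:n], tissue$state$LAX3[1:n],
                          rep(params$PIN_expression, n),
                          params$eff_basal, params$inf_pas, params$p_PIN,
                          params$p_AUXLAX)
  out <- tibble::tibble(
    id = seq_len(n), fx = res$fx, fy = res$fy,
    angle = atan2(res$fy, res$fx),
    magnitude = sqrt(res$fx^2 + res$fy^2)
  )
  out[tissue$cells$alive[1:n], ]
}
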