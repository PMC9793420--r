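## Shared fixtures: a minimal tissue geometry and parameter sets sized for
## fast tests; the explicit finite-difference oracle for the auxin solver.

tiny_geometry <- function(n_rows = 48) {
  list(name = "tiny", n_cols = 27, n_rows = n_rows,
       widths = c(lrcap = 1, epidermis = 1, cortex = 1, endodermis = 1,
                  pericycle = 1, vasculature = 1, centre = 1),
       cell_height_rows = 4, zone_scale = 0.1, cap_rows = 12)
}

## parameters with gentle rates so an explicit reference integration is
## stable at small substeps (algebra checks, not the default conditions)
mild_params <- function(...) {
  default_parameters(D_cell = 6, D_wall = 4, eff_basal = 0.3, inf_pas = 0.3,
                     p_PIN = 0.004, p_AUXLAX = 0.004, p_auxin_baseline = 1e-3,
                     d_auxin = 1e-4, dt = 0.01, ...)
}

## closed-system parameters: no production, decay, boundary or radial terms
closed_params <- function(...) {
  default_parameters(p_auxin_baseline = 0, d_auxin = 0, auxin_ext = 0,
                     boundary_outflux_frac = 0, ...)
}

## Explicit finite-difference reference for the auxin field: computes the
## time derivative of every grid point directly from the model's transport
## rules (independent of the ADI implementation) and advances with forward
## Euler substeps.
oracle_rate_matrix <- function(tissue, config) {
  params <- config$params
  nr <- tissue$n_rows; nc <- tissue$n_cols
  n <- tissue$n_cells
  k <- tissue$kind; id <- tissue$cell_id
  ## directional rate from p to its neighbour q
  rate <- function(ip, jp, iq, jq) {
    kp <- k[ip, jp]; kq <- k[iq, jq]
    if (kp == 0L || kq == 0L) return(0)
    cellp <- kp %in% c(1L, 2L); cellq <- kq %in% c(1L, 2L)
    if (cellp && cellq)
      return(if (id[ip, jp] == id[iq, jq]) params$D_cell / params$dx^2 else 0)
    if (kp == 3L && kq == 3L) return(params$D_wall / params$dx^2)
    if (kp == 2L && kq == 3L)
      return(params$eff_basal + params$p_PIN * tissue$wPIN[ip, jp] *
               params$PIN_expression)
    if (kp == 3L && kq == 2L)
      return(params$inf_pas + params$p_AUXLAX *
               (tissue$wAUX1[iq, jq] * tissue$state$AUX1[id[iq, jq]] +
                  tissue$wLAX3[iq, jq] * tissue$state$LAX3[id[iq, jq]]))
    0
  }
  ## rate matrices per direction (toward +row, -row, +col, -col)
  R <- list(up = matrix(0, nr, nc), down = matrix(0, nr, nc),
            right = matrix(0, nr, nc), left = matrix(0, nr, nc))
  for (j in seq_len(nc))
    for (i in seq_len(nr)) {
      if (i < nr) R$up[i, j] <- rate(i, j, i + 1L, j)
      if (i > 1) R$down[i, j] <- rate(i, j, i - 1L, j)
      if (j < nc) R$right[i, j] <- rate(i, j, i, j + 1L)
      if (j > 1) R$left[i, j] <- rate(i, j, i, j - 1L)
    }
  R
}

oracle_derivative <- function(field, tissue, config, R,
                              prod_per_cell = NULL) {
  params <- config$params
  nr <- tissue$n_rows; nc <- tissue$n_cols
  out_flux <- field * (R$up + R$down + R$right + R$left)
  shift <- function(M, di, dj) {
    Z <- matrix(0, nr, nc)
    ri <- seq_len(nr) - di; rj <- seq_len(nc) - dj
    ok_i <- ri >= 1 & ri <= nr; ok_j <- rj >= 1 & rj <= nc
    Z[ok_i, ok_j] <- M[ri[ok_i], rj[ok_j]]
    Z
  }
  in_flux <- shift(field * R$up, 1, 0) + shift(field * R$down, -1, 0) +
    shift(field * R$right, 0, 1) + shift(field * R$left, 0, -1)
  d <- in_flux - out_flux
  cellpt <- tissue$kind == 1L | tissue$kind == 2L
  d[cellpt] <- d[cellpt] - params$d_auxin * field[cellpt]
  if (!is.null(prod_per_cell)) {
    idm <- tissue$cell_id
    d[cellpt] <- d[cellpt] + prod_per_cell[idm[cellpt]]
  }
  d + radial_coupling_terms(field, tissue, config)
}

oracle_step <- function(tissue, config, dt, n_sub, field = tissue$auxin,
                        with_production = TRUE) {
  R <- oracle_rate_matrix(tissue, config)
  prod <- if (with_production) production_rates(tissue, config) else NULL
  be <- boundary_exchange(tissue, config)
  h <- dt / n_sub
  for (s in seq_len(n_sub)) {
    d <- oracle_derivative(field, tissue, config, R, prod)
    d[be$src_idx] <- d[be$src_idx] + be$src_rate
    d[be$sink_idx] <- d[be$sink_idx] - be$sink_rate * field[be$sink_idx]
    field <- field + h * d
  }
  field
}

## small tissue with some auxin already in it
seeded_tissue <- function(config, level = 5) {
  tis <- build_root_tissue(config)
  tis$auxin[tis$kind != 0L] <- level
  tis
}
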