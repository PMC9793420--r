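test_that("auxin production follows cell-type factors, YUCCA4 and height normalization", {
  p <- default_parameters()
  base <- production_rate_at(1, 0, p$reference_height_rows, p)
  ## QC 100x, LR cap 30x baseline
  expect_equal(production_rate_at(100, 0, p$reference_height_rows, p),
               100 * base)
  expect_equal(production_rate_at(30, 0, p$reference_height_rows, p),
               30 * base)
  ## YUCCA4 at its maximum of 100 raises production 16.25-fold
  expect_equal(production_rate_at(1, 100, p$reference_height_rows, p) / base,
               16.25)
  ## doubling cell height halves the per-point rate, keeping the cell total
  h <- p$reference_height_rows
  expect_equal(production_rate_at(1, 0, 2 * h, p), base / 2)
  expect_equal(2 * h * production_rate_at(1, 0, 2 * h, p),
               h * production_rate_at(1, 0, h, p))
})

test_that("membrane fluxes separate carrier-mediated and passive components", {
  p <- default_parameters()
  ## zero PIN prepattern: efflux reduces to the basal term
  fl <- membrane_flux(10, 5, wPIN = 0, wAUX1 = 1, wLAX3 = 1,
                      AUX1 = 100, LAX3 = 100, p)
  expect_equal(fl$efflux, p$eff_basal * 10)
  ## zero wall auxin: all influx terms vanish
  fl <- membrane_flux(10, 0, 1, 1, 1, 100, 100, p)
  expect_equal(fl$influx, 0)
  ## constant PIN expression of 100 with weight g
  g <- 0.37
  fl <- membrane_flux(2, 0, g, 0, 0, 0, 0, p)
  expect_equal(fl$efflux, (p$eff_basal + p$p_PIN * 100 * g) * 2)
})

test_that("a closed system conserves auxin mass to machine precision", {
  cfg <- scenario_config(params = closed_params(), geometry = tiny_geometry(),
                         radial_mode = "off", growth_enabled = FALSE)
  tis <- seeded_tissue(cfg, level = 5)
  tis$auxin[20, 10] <- 80   # asymmetric blob
  total0 <- sum(tis$auxin)
  for (i in 1:50) step_auxin(tis, cfg, dt = 0.4)
  expect_lt(abs(sum(tis$auxin) - total0) / total0, 1e-8)
})

test_that("a uniform field with uniform kinetics relaxes to production/decay", {
  ## no transport, no diffusion contrasts: every cell point obeys
  ## dc/dt = p - d c exactly, fixed point c = p/d
  p <- default_parameters(eff_basal = 0, inf_pas = 0, p_PIN = 0, p_AUXLAX = 0,
                          auxin_ext = 0, boundary_outflux_frac = 0,
                          p_auxin_baseline = 2e-3, d_auxin = 1e-4)
  g <- tiny_geometry()
  cfg <- scenario_config(params = p, geometry = g, radial_mode = "off",
                         growth_enabled = FALSE)
  tis <- build_root_tissue(cfg)
  ## make production uniform: neutralize cell-type factors and heights
  tis$cells$ctf[] <- 1
  n <- tis$n_cells
  hts <- tis$cells$row1[1:n] - tis$cells$row0[1:n] + 1L
  target <- p$p_auxin_baseline * (p$reference_height_rows / hts) / p$d_auxin
  for (i in 1:12000) step_auxin(tis, cfg, dt = 20)
  cells <- as_cells_tibble(tis)
  got <- vapply(cells$id, function(i) {
    mean(tis$auxin[cells$row0[cells$id == i]:cells$row1[cells$id == i],
                   cells$col0[cells$id == i]:cells$col1[cells$id == i]])
  }, numeric(1))
  expect_equal(got, target[cells$id], tolerance = 1e-6)
})

test_that("the ADI step agrees with an explicit finite-difference reference", {
  cfg <- scenario_config(params = mild_params(), geometry = tiny_geometry(),
                         radial_mode = "walls-only", growth_enabled = FALSE)
  tis <- seeded_tissue(cfg, level = 2)
  tis$auxin[15:25, 8:14] <- 10
  ref_tis <- seeded_tissue(cfg, level = 2)
  ref_tis$auxin[15:25, 8:14] <- 10
  dt <- cfg$params$dt
  ## one ADI step vs explicit Euler at dt/100
  ref <- oracle_step(ref_tis, cfg, dt, n_sub = 100)
  step_auxin(tis, cfg, dt = dt)
  scale <- max(ref)
  expect_lt(max(abs(tis$auxin - ref)) / scale, 1e-3)
})

test_that("boundary exchange matches the stated in/outflow structure", {
  cfg <- scenario_config(geometry = tiny_geometry(), growth_enabled = FALSE)
  tis <- build_root_tissue(cfg)
  p <- cfg$params
  be <- boundary_exchange(tis, cfg)
  expect_true(length(be$src_idx) > 0)
  expect_true(length(be$sink_idx) > 0)
  ## zero external auxin: no inflow anywhere
  cfg0 <- scenario_config(params = default_parameters(auxin_ext = 0),
                          geometry = tiny_geometry())
  be0 <- boundary_exchange(build_root_tissue(cfg0), cfg0)
  expect_true(all(be0$src_rate == 0))
  ## inflow is linear in the topmost cell's PIN efflux: doubling p_PIN
  ## (hence efflux capacity) scales the PIN part of the inflow
  cfg2 <- scenario_config(params = default_parameters(eff_basal = 0,
                                                      p_PIN = 2 * p$p_PIN),
                          geometry = tiny_geometry())
  tis2 <- build_root_tissue(cfg2)
  be_a <- boundary_exchange(tis2, cfg2)
  cfg1 <- scenario_config(params = default_parameters(eff_basal = 0),
                          geometry = tiny_geometry())
  be_b <- boundary_exchange(build_root_tissue(cfg1), cfg1)
  expect_equal(be_a$src_rate, 2 * be_b$src_rate)
  ## epidermal/cortical outflow rate is exactly 10% of the influx capacity
  tis_k <- build_root_tissue(cfg)
  files <- tis_k$files
  f_epi <- which(files$type == "epidermis" & files$side == -1L)
  top <- rootpriming:::file_top_cell(tis_k, f_epi)
  r1 <- tis_k$cells$row1[top]
  cols <- tis_k$cells$col0[top]:tis_k$cells$col1[top]
  infl <- p$inf_pas + p$p_AUXLAX *
    (tis_k$wAUX1[r1, cols] * tis_k$state$AUX1[top] +
       tis_k$wLAX3[r1, cols] * tis_k$state$LAX3[top])
  lin <- (cols - 1L) * tis_k$n_rows + (r1 + 1L)
  got <- be$sink_rate[match(lin, be$sink_idx)]
  expect_equal(got, 0.10 * infl)
})

test_that("radial coupling is antisymmetric, distance-scaled and removable", {
  cfg <- scenario_config(geometry = tiny_geometry())
  tis <- seeded_tissue(cfg, level = 3)
  ## symmetric field: zero net term everywhere
  terms <- radial_coupling_terms(tis$auxin, tis, cfg)
  expect_true(all(abs(terms) < 1e-12))
  ## asymmetric wall concentrations: term scales inversely with pair distance
  f <- tis$auxin
  wl <- which(tis$kind == 3L, arr.ind = TRUE)
  f[wl[1, 1], wl[1, 2]] <- f[wl[1, 1], wl[1, 2]] + 10
  t1 <- radial_coupling_terms(f, tis, cfg)
  i <- wl[1, 1]; jl <- wl[1, 2]; jr <- tis$n_cols + 1 - jl
  raddist <- abs(jr - jl) * tis$dx
  expect_equal(t1[i, jl],
               unname(cfg$params$D_rad * (f[i, jr] - f[i, jl]) / raddist))
  expect_equal(t1[i, jr], -t1[i, jl])   # antisymmetric exchange
  ## off mode: zeros
  cfg_off <- scenario_config(geometry = tiny_geometry(), radial_mode = "off")
  expect_true(all(radial_coupling_terms(f, tis, cfg_off) == 0))
  ## enhanced mode: four times the default wall exchange
  cfg_e <- scenario_config(geometry = tiny_geometry(),
                           radial_mode = "enhanced")
  te <- radial_coupling_terms(f, tis, cfg_e)
  expect_equal(te[i, jl], 4 * t1[i, jl])
})

test_that("radial coupling off makes severed halves evolve independently", {
  ## cut the tissue along its centre column so no contiguous transport path
  ## joins the halves; only the radial coupling can then link them
  run_mode <- function(mode, perturb) {
    cfg <- scenario_config(params = closed_params(), radial_mode = mode,
                           geometry = tiny_geometry(), growth_enabled = FALSE)
    tis <- seeded_tissue(cfg, level = 1)
    mid <- (tis$n_cols + 1L) %/% 2L
    tis$kind[, mid] <- 0L
    tis$cell_id[, mid] <- 0L
    tis$auxin[, mid] <- 0
    if (perturb)
      tis$auxin[, (mid + 1L):tis$n_cols] <-
        tis$auxin[, (mid + 1L):tis$n_cols] + 50
    for (i in 1:5) step_auxin(tis, cfg, dt = 0.4)
    tis$auxin[, 1:(mid - 1L)]
  }
  base <- run_mode("off", perturb = FALSE)
  off_left <- run_mode("off", perturb = TRUE)
  on_left <- run_mode("walls-only", perturb = TRUE)
  expect_equal(off_left, base, tolerance = 1e-12)
  expect_gt(max(abs(on_left - base)), 1e-2)
})

test_that("per-cell net flux vectors reflect membrane polarity", {
  cfg <- scenario_config(params = closed_params(), radial_mode = "off",
                         geometry = tiny_geometry())
  tis <- seeded_tissue(cfg, level = 4)
  fv <- compute_flux_vectors(tis, cfg)
  cells <- as_cells_tibble(tis)
  ## a vasculature MZ cell with rootward PIN has a rootward (negative y) net
  ## flux under a uniform field
  i <- cells$id[cells$type == "vasculature" & cells$zone == "MZ"][2]
  expect_lt(fv$fy[fv$id == i], 0)
  ## an epidermis cell with shootward PIN points shootward
  j <- cells$id[cells$type == "epidermis" & cells$zone == "MZ"][2]
  expect_gt(fv$fy[fv$id == j], 0)
})

test_that("halving the time step changes the field only slightly (convergence)", {
  ## membrane-transport rates are stiff (rate x dt >> 1 at practical steps),
  ## so the split scheme's error shrinks slowly with dt; the stated
  ## convergence bounds are 10% in mean relative terms and 15% at the single
  ## worst grid point
  cfg <- scenario_config(geometry = tiny_geometry(), growth_enabled = FALSE)
  tis1 <- seeded_tissue(cfg, level = 2)
  tis2 <- seeded_tissue(cfg, level = 2)
  for (i in 1:3000) step_auxin(tis1, cfg, dt = 0.2)
  for (i in 1:6000) step_auxin(tis2, cfg, dt = 0.1)
  inside <- tis2$kind != 0L
  expect_lt(mean(abs(tis1$auxin[inside] - tis2$auxin[inside])) /
              mean(tis2$auxin[inside]), 0.10)
  expect_lt(max(abs(tis1$auxin - tis2$auxin)) / max(tis2$auxin), 0.15)
})
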