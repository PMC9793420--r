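## Orchestration: couples the auxin PDE, the per-cell regulatory ODEs and the
## growth engine into a deterministic time-stepped simulation with periodic
## sampling of fields, per-cell traces and events.

## per-cell signalling and free ARF given current auxin means
evaluate_signalling <- function(tissue, config, auxin_cell) {
  n <- tissue$n_cells
  st <- tissue$state
  reg <- if (config$tols2_enabled)
    iaareg(st$TOLS2[1:n], st$ARFfree[1:n], config$params) else rep(1, n)
  ARFfree <- free_arf_qss(auxin_cell, st$ARFtotal[1:n], config$params, reg)
  list(ARFfree = ARFfree,
       signalling = auxin_signalling(auxin_cell, st$ARFtotal[1:n], ARFfree),
       IAAreg = reg)
}

## cell adjacency graph (shared walls): consecutive cells in a file plus
## laterally overlapping cells in adjacent files; recomputed when geometry
## changes
cell_neighbours <- function(tissue) {
  cs <- tissue$cells
  n <- tissue$n_cells
  alive <- which(cs$alive)
  nb <- vector("list", n)
  for (i in alive) {
    cand <- alive[cs$row0[alive] <= cs$row1[i] + 2L &
                    cs$row1[alive] >= cs$row0[i] - 2L &
                    cs$col0[alive] <= cs$col1[i] + 2L &
                    cs$col1[alive] >= cs$col0[i] - 2L]
    nb[[i]] <- setdiff(cand, i)
  }
  nb
}

## stele cells in the shootward half of the (positional) elongation zone;
## the band is defined by position, not differentiation state, so it remains
## meaningful in no-growth runs where resident cells differentiate in place
pulse_target_cells <- function(tissue, config) {
  params <- config$params
  zs <- tissue$zone_scale
  ez0 <- params$mz_end * zs
  ## band in the shootward, differentiated part of the domain where the
  ## no-growth baseline sits below the chromatin-opening threshold, so only
  ## the imposed signal can trigger a response
  lo <- ez0 + 950 * zs
  hi <- ez0 + 1050 * zs
  cs <- tissue$cells
  n <- tissue$n_cells
  d <- (cs$row0[1:n] - 1L) * tissue$dx
  which(cs$alive[1:n] & cs$type[1:n] == "pericycle" &
          d >= lo & d <= hi)
}

#' Run a scenario simulation
#'
#' Advances the coupled model from a freshly built tissue: each step performs
#' signalling evaluation (AUX/IAA quasi-steady state, lateral-inhibition
#' multiplier), one auxin PDE step, forward-Euler updates of the gene,
#' chromatin-state and peptide ODEs, and a growth/division/zonation/culling
#' pass; fields and per-cell states are sampled every `sampling_interval`
#' seconds. Fully deterministic: no random number generator is used anywhere.
#'
#' @param config a `scenario_config`, e.g. from [preset()].
#' @param progress print a progress line every simulated hour.
#' @return An object of class `root_sim`: config, sampled per-cell traces,
#'   kymograph matrices (auxin and signalling along the left pericycle
#'   mid-line), event log, mass-balance diagnostics, the final field and the
#'   tissue environment.
#' @export
run_scenario <- function(config, progress = FALSE) {
  params <- config$params
  tis <- build_root_tissue(config)
  ## note: differentiation rates are not rescaled for shrunken geometries --
  ## growth-driven displacement speeds scale with the growing tissue below a
  ## cell, so zone proportions are preserved automatically
  dt <- params$dt
  n_steps <- max(1L, round(config$duration_h * 3600 / dt))
  sample_every <- max(1L, round(config$sampling_interval / dt))

  ## left pericycle mid-column for the kymograph line
  fL <- which(tis$files$type == "pericycle" & tis$files$side == -1L)
  kymo_col <- (tis$files$col0[fL] + tis$files$col1[fL]) %/% 2L

  ## AUX1 asymmetry: production reduced on the left stele files
  asym_scale_of <- function() {
    n <- tis$n_cells
    s <- rep(1, n)
    if (config$aux1_asymmetry > 0) {
      cs <- tis$cells
      s[cs$side[1:n] == -1L & cs$type[1:n] %in% c("pericycle", "vasculature")] <-
        1 - config$aux1_asymmetry
    }
    s
  }

  nb <- if (config$tols2_enabled) cell_neighbours(tis) else NULL
  auxin_cell <- rep(0, tis$n_cells)
  samples <- vector("list", n_steps %/% sample_every + 1L)
  kymo_aux <- kymo_sig <- vector("list", length(samples))
  diag_rows <- vector("list", length(samples))
  s_i <- 0L
  events <- list()
  pulse_on_prev <- FALSE

  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    n <- tis$n_cells
    st <- tis$state
    alive <- tis$cells$alive[1:n]

    ## signalling from the current field
    sg <- evaluate_signalling(tis, config, auxin_cell)
    tis$state$ARFfree <- sg$ARFfree

    ## homeostasis variant: ARF-dependent extra auxin degradation in cells
    ## with induced ARF expression
    decay_mult <- NULL
    if (config$homeostasis_enabled)
      decay_mult <- 1 + params$k_homeostasis *
        pmax(0, st$ARFtotal[1:n] - 10) / 300

    ## auxin PDE step
    res <- step_auxin(tis, config, dt, decay_mult)
    auxin_cell <- res$cell_mean

    ## imposed auxin pulse (no-growth scenarios)
    if (!is.null(config$pulse)) {
      p <- config$pulse
      on <- t_now >= p$start_h * 3600 && t_now < (p$start_h + p$duration_h) * 3600
      if (on) {
        tgt <- pulse_target_cells(tis, config)
        for (i in tgt) {
          rr <- tis$cells$row0[i]:tis$cells$row1[i]
          cc <- tis$cells$col0[i]:tis$cells$col1[i]
          tis$auxin[rr, cc] <- pmax(tis$auxin[rr, cc], p$amplitude)
          auxin_cell[i] <- max(auxin_cell[i], p$amplitude)
        }
      }
      pulse_on_prev <- on
    }

    ## gene expression (forward Euler, same clock as the PDE); before
    ## feedback_start_h the feedback tier runs in baseline mode and the
    ## chromatin state is held closed (equilibration burn-in)
    fb_active <- t_now >= config$feedback_start_h * 3600
    mode_eff <- if (fb_active) config$feedback_mode else "none"
    in_mz <- tis$cells$zone[1:n] %in% c("MZ", "TZ")
    bl <- step_baseline_expression(st$AUX1[1:n], st$Diff[1:n], auxin_cell,
                                   in_mz, dt, params, Km = config$aux1_Km,
                                   aux1_production_scale = asym_scale_of())
    tis$state$AUX1 <- bl$AUX1
    tis$state$Diff <- bl$Diff
    is_stele <- tis$cells$type[1:n] %in% c("pericycle", "vasculature")
    fb <- step_feedback_expression(st$LAX3[1:n], st$YUCCA4[1:n],
                                   st$ARFtotal[1:n], sg$signalling,
                                   bl$Diff, st$EpiO[1:n], is_stele, in_mz,
                                   dt, params, mode = mode_eff,
                                   arf_max_scale = config$arf_max_scale)
    tis$state$LAX3 <- fb$LAX3
    tis$state$YUCCA4 <- fb$YUCCA4
    tis$state$ARFtotal <- fb$ARFtotal

    blocked <- !fb_active
    if (config$epio_blocked_early_ez) {
      ## cover the stationary auxin-loading pool of the non-growing root,
      ## which extends well past the elongation-zone start, up to the distal
      ## band used for imposed-signal experiments
      d <- (tis$cells$row0[1:n] - 1L) * tis$dx
      ez0 <- params$mz_end * tis$zone_scale
      blocked <- blocked | (d > ez0 & d <= ez0 + 940 * tis$zone_scale)
    }
    tis$state$EpiO <- step_epio(st$EpiO[1:n], sg$signalling, dt, params,
                                open_blocked = blocked)
    if (config$tols2_enabled)
      tis$state$TOLS2 <- step_tols2(st$TOLS2[1:n], tis$state$ARFfree[1:n],
                                    nb, dt, params)

    ## growth, zonation, culling
    if (config$growth_enabled) {
      stamp0 <- tis$geom_stamp
      ev <- grow_cells(tis, dt, config, t_now)
      moved <- tis$geom_stamp != stamp0
      ev <- c(ev, advance_differentiation(tis, config, dt = NULL,
                                          time = t_now, full = moved))
      if (moved) ev <- c(ev, cull_and_shed(tis, config, t_now))
      if (length(ev)) {
        events <- c(events, ev)
        if (moved || tis$n_cells > length(auxin_cell)) {
          if (config$tols2_enabled) nb <- cell_neighbours(tis)
          if (tis$n_cells > length(auxin_cell))
            auxin_cell <- c(auxin_cell,
                            rep(0, tis$n_cells - length(auxin_cell)))
        }
      }
    } else {
      ev <- advance_differentiation(tis, config, dt = NULL, time = t_now,
                                    full = FALSE)
      if (length(ev)) events <- c(events, ev)
    }

    ## sampling
    if (step %% sample_every == 0L) {
      s_i <- s_i + 1L
      tab <- as_cells_tibble(tis)
      n2 <- tis$n_cells
      sg2 <- evaluate_signalling(tis, config,
                                 c(auxin_cell, rep(0, n2 - length(auxin_cell))))
      tab$auxin <- c(auxin_cell, rep(0, n2 - length(auxin_cell)))[tab$id]
      tab$signalling <- sg2$signalling[tab$id]
      tab$time_h <- t_now / 3600
      samples[[s_i]] <- tab
      line <- tis$auxin[, kymo_col]
      kymo_aux[[s_i]] <- line
      extra <- sg2$signalling - c(auxin_cell, rep(0, n2 - length(auxin_cell)))
      ids <- tis$cell_id[, kymo_col]
      sig_line <- line + ifelse(ids > 0, extra[pmax(ids, 1L)], 0)
      kymo_sig[[s_i]] <- sig_line
      diag_rows[[s_i]] <- c(time_h = t_now / 3600,
                            total_auxin = sum(tis$auxin),
                            prod = res$prod_added / dt,
                            boundary = res$boundary_net / dt,
                            decay = res$decay_removed / dt,
                            n_cells = sum(tis$cells$alive))
      if (progress && s_i %% 36L == 0L)
        message(sprintf("t = %.1f h, cells = %d, total auxin = %.1f",
                        t_now / 3600, sum(tis$cells$alive), sum(tis$auxin)))
    }
  }

  samples <- samples[seq_len(s_i)]
  traces <- dplyr::bind_rows(samples)
  ev_tab <- if (length(events))
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  else tibble::tibble(time = numeric(0), event = character(0),
                      id = integer(0), row = integer(0))
  structure(list(
    config = config,
    traces = traces,
    kymograph_auxin = do.call(rbind, kymo_aux[seq_len(s_i)]),
    kymograph_signalling = do.call(rbind, kymo_sig[seq_len(s_i)]),
    kymo_col = kymo_col,
    times_h = vapply(diag_rows[seq_len(s_i)], `[[`, numeric(1), "time_h"),
    events = ev_tab,
    diagnostics = dplyr::bind_rows(lapply(diag_rows[seq_len(s_i)],
                                          function(x) tibble::as_tibble(as.list(x)))),
    final_field = tis$auxin,
    tissue = tis
  ), class = "root_sim")
}

#' @export
print.root_sim <- function(x, ...) {
  cat("<root_sim> ", x$config$feedback_mode, " feedback, ",
      max(x$times_h), " h simulated, ",
      sum(x$tissue$cells$alive), " cells, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Tidy per-cell traces of a simulation
#'
#' @param x a `root_sim`.
#' @param ... unused.
#' @return tibble of sampled per-cell states over time (one row per cell and
#'   sampling time).
#' @export
tidy.root_sim <- function(x, ...) x$traces

#' One-row summary of a simulation
#'
#' @param x a `root_sim`.
#' @param ... unused.
#' @return tibble with duration, cell/event counts, and final total auxin.
#' @export
glance.root_sim <- function(x, ...) {
  tibble::tibble(
    duration_h = max(x$times_h),
    n_cells = sum(x$tissue$cells$alive),
    n_events = nrow(x$events),
    n_divisions = sum(x$events$event == "divide"),
    total_auxin = sum(x$final_field),
    max_signalling = max(x$traces$signalling)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
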