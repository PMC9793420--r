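## Long fixture-scale scenario runs shared across acceptance tests: computed
## once per test session, on demand. Durations are sized so the full suite
## runs on one CPU in well under half an hour (see the methods vignette for
## the problem sizes used).

.run_cache <- new.env(parent = emptyenv())

acceptance_run <- function(name) {
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  p <- default_parameters(dt = 2)
  cfg <- switch(name,
    baseline = scenario_config(params = p, geometry = "fixture",
                               duration_h = 50, feedback_mode = "none",
                               sampling_interval = 200),
    epio = scenario_config(params = p, geometry = "fixture",
                           duration_h = 58, feedback_mode = "epio",
                           feedback_start_h = 24, sampling_interval = 200),
    low_auxin = scenario_config(params = p, geometry = "fixture",
                                duration_h = 46, feedback_mode = "epio",
                                feedback_start_h = 24,
                                auxin_content_scale = 0.9,
                                sampling_interval = 200),
    tols2 = scenario_config(params = p, geometry = "fixture",
                            duration_h = 58, feedback_mode = "epio",
                            feedback_start_h = 24, tols2_enabled = TRUE,
                            sampling_interval = 200),
    pulse_strong = pulse_cfg(p, list(amplitude = 250, duration_h = 3,
                                     start_h = 8)),
    pulse_weak = pulse_cfg(p, list(amplitude = 150, duration_h = 3,
                                   start_h = 8)),
    pulse_short = pulse_cfg(p, list(amplitude = 250, duration_h = 0.25,
                                    start_h = 8)),
    stop("unknown cached run: ", name))
  sim <- run_scenario(cfg)
  .run_cache[[name]] <- sim
  sim
}

pulse_cfg <- function(p, pulse) {
  scenario_config(params = p, geometry = "fixture", duration_h = 20,
                  feedback_mode = "epio", growth_enabled = FALSE,
                  epio_blocked_early_ez = TRUE, pulse = pulse,
                  sampling_interval = 200)
}

## traced steady-state pericycle cells (past the equilibration transient)
steady_traces <- function(sim, min_cross = 26) {
  tr <- trace_cells(sim)
  tr[tr$cross_time > min_cross, ]
}

## per-cell summary of the secondary response
response_summary <- function(tr) {
  tr |>
    dplyr::group_by(.data$id, .data$crossing_order) |>
    dplyr::summarise(peak = max(.data$signalling),
                     final = dplyr::last(.data$signalling),
                     epio_max = max(.data$EpiO),
                     arf_max = max(.data$ARFtotal),
                     .groups = "drop") |>
    dplyr::arrange(.data$crossing_order)
}
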