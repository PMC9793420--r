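## Growth, division, differentiation-driven zone transitions, culling and
## shedding. Cells carry a continuous length updated from per-micrometre
## exponential growth; when it exceeds the integer grid length by one, a grid
## row is inserted at the cell's mid-height (duplicating local auxin, so
## insertion neither creates nor dilutes concentration). Cells in the meristem
## proper divide upon doubling their birth length, with a new wall row
## inserted between the daughters. The simulation domain is constant-sized:
## cells reaching the top are culled, lateral-root cap cells are shed beyond
## the cap's meristem end.

#' Effective division/growth rate of a meristematic cell
#'
#' All meristematic cells share one average division rate (doubling time =
#' `cellcycle`), staggered deterministically by the cell's longitudinal birth
#' coordinate to avoid artificial whole-meristem synchrony: `mean_j %% 3`
#' equal to 0, 1, 2 gives the average rate, +5% and -5% respectively.
#'
#' @param mean_j 0-based longitudinal coordinate of the cell centre at birth.
#' @param params `root_params`.
#' @return growth rate (s^-1, per unit length).
#' @export
division_rate_of <- function(mean_j, params = default_parameters()) {
  r <- log(2) / (params$cellcycle * 3600)
  s <- mean_j %% 3
  r * (1 + params$noise_amplitude * ((s == 1) - (s == 2)))
}

## shift a file's interior-column strip up by one row starting at `at_row`;
## the new row at `at_row` duplicates the previous content of that row
## (auxin, kinds, weights) unless overwritten by the caller afterwards
shift_strip_up <- function(tis, cols, at_row) {
  nr <- tis$n_rows
  tis$geom_stamp <- tis$geom_stamp + 1L
  for (nm in c("kind", "cell_id", "wPIN", "wAUX1", "wLAX3", "auxin")) {
    M <- tis[[nm]]
    M[(at_row + 1L):nr, cols] <- M[at_row:(nr - 1L), cols]
    tis[[nm]] <- M
  }
  invisible(tis)
}

file_top_cell <- function(tis, f) {
  idx <- which(tis$cells$alive & !is.na(tis$cells$file) & tis$cells$file == f)
  if (!length(idx)) return(NA_integer_)
  idx[which.max(tis$cells$row1[idx])]
}

## remove one cell from the grid (points and its apical wall become outside)
remove_cell <- function(tis, i) {
  cs <- tis$cells
  tis$geom_stamp <- tis$geom_stamp + 1L
  rr <- cs$row0[i]:min(cs$row1[i] + 1L, tis$n_rows)
  cc <- cs$col0[i]:cs$col1[i]
  tis$kind[rr, cc] <- KIND_OUTSIDE
  tis$cell_id[rr, cc] <- 0L
  tis$auxin[rr, cc] <- 0
  tis$wPIN[rr, cc] <- 0; tis$wAUX1[rr, cc] <- 0; tis$wLAX3[rr, cc] <- 0
  tis$cells$alive[i] <- FALSE
  invisible(tis)
}

append_state_copy <- function(tis, from) {
  for (nm in names(tis$state)) tis$state[[nm]] <- c(tis$state[[nm]],
                                                    tis$state[[nm]][from])
  invisible(tis)
}

## ensure the file has headroom for inserting one row; culls the topmost cell
## if its apical wall would pass the domain top. Returns event rows.
ensure_headroom <- function(tis, f, time) {
  ev <- NULL
  top <- file_top_cell(tis, f)
  if (is.na(top)) return(ev)
  if (tis$cells$row1[top] + 1L >= tis$n_rows) {
    ev <- list(time = time, event = "cull", id = top,
               row = tis$cells$row0[top])
    remove_cell(tis, top)
  }
  ev
}

## insert one grid row at the mid-height of cell i (growth row addition)
insert_row <- function(tis, i, config, time) {
  cs <- tis$cells
  f <- cs$file[i]
  ev <- ensure_headroom(tis, f, time)
  if (!tis$cells$alive[i]) return(list(ev))  # the growing cell was culled
  cs <- tis$cells
  m <- as.integer(floor((cs$row0[i] + cs$row1[i]) / 2))
  cols <- cs$col0[i]:cs$col1[i]
  shift_strip_up(tis, cols, m)   # new row m duplicates the old mid row
  tis$cells$row1[i] <- cs$row1[i] + 1L
  above <- which(tis$cells$alive & !is.na(tis$cells$file) &
                   tis$cells$file == f & tis$cells$row0 > m &
                   seq_len(tis$n_cells) != i)
  tis$cells$row0[above] <- tis$cells$row0[above] + 1L
  tis$cells$row1[above] <- tis$cells$row1[above] + 1L
  c(list(list(time = time, event = "insert", id = i, row = m)), list(ev))
}

#' Divide a meristematic cell
#'
#' Splits the mother's rows between two daughters (the rootward daughter
#' receives the extra row when the count is odd) and inserts a new wall row
#' between them. Daughters inherit the mother's expression state, cell-type
#' production factor (the vascular-initial factor stays with the rootward
#' daughter) and transporter prepattern; their `mean_j` is fixed at their own
#' centre at creation and their division clocks reset (birth length = own
#' length).
#'
#' @param tissue tissue environment.
#' @param i index of the mother cell (must be in the meristem proper).
#' @param config `scenario_config`.
#' @param time simulation time (s), for the event log.
#' @return list of event records.
#' @export
divide_cell <- function(tissue, i, config, time = 0) {
  tis <- tissue
  cs <- tis$cells
  if (cs$zone[i] != "MZ" || cs$static[i])
    stop("division attempted outside the meristem proper")
  f <- cs$file[i]
  ev <- ensure_headroom(tis, f, time)
  if (!tis$cells$alive[i]) return(list(ev))
  cs <- tis$cells
  r0 <- cs$row0[i]; r1 <- cs$row1[i]
  h <- r1 - r0 + 1L
  hr <- as.integer(ceiling(h / 2))
  cols <- cs$col0[i]:cs$col1[i]
  split_row <- r0 + hr
  shift_strip_up(tis, cols, split_row)
  tis$kind[split_row, cols] <- KIND_WALL
  tis$cell_id[split_row, cols] <- 0L
  tis$auxin[split_row, cols] <- tis$auxin[split_row + 1L, cols]
  tis$wPIN[split_row, cols] <- 0; tis$wAUX1[split_row, cols] <- 0
  tis$wLAX3[split_row, cols] <- 0
  above <- which(tis$cells$alive & !is.na(tis$cells$file) &
                   tis$cells$file == f & tis$cells$row0 > r0 &
                   seq_len(tis$n_cells) != i)
  tis$cells$row0[above] <- tis$cells$row0[above] + 1L
  tis$cells$row1[above] <- tis$cells$row1[above] + 1L

  ctf_root <- cs$ctf[i]
  ctf_shoot <- if (cs$type[i] == "vasculature" && cs$ctf[i] == 100) 1 else cs$ctf[i]
  cont <- cs$length_cont[i]
  id_root <- add_cell(tis, cs$type[i], cs$side[i], cs$col0[i], cs$col1[i],
                      r0, r0 + hr - 1L, ctf = ctf_root)
  tis$cells$file[id_root] <- f
  tis$cells$length_cont[id_root] <- cont * hr / h
  append_state_copy(tis, i)
  id_shoot <- add_cell(tis, cs$type[i], cs$side[i], cs$col0[i], cs$col1[i],
                       split_row + 1L, r1 + 1L, ctf = ctf_shoot)
  tis$cells$file[id_shoot] <- f
  tis$cells$length_cont[id_shoot] <- cont * (h - hr) / h
  append_state_copy(tis, i)
  tis$cells$alive[i] <- FALSE
  apply_prepattern(tis, id_root, config)
  apply_prepattern(tis, id_shoot, config)
  c(list(list(time = time, event = "divide", id = i, row = r0)), list(ev))
}

#' Advance growth for all cells over one time step
#'
#' Meristematic cells (and transition-zone cells, at the same per-micrometre
#' rate unless `tz_growth_rate` overrides it) grow exponentially at the
#' staggered division rate; elongation-zone cells expand at the expansion
#' rate (1/expansion timescale); differentiated and static cells do not grow.
#' Row insertions and divisions are triggered where thresholds are crossed.
#'
#' @param tissue tissue environment.
#' @param dt time step (s).
#' @param config `scenario_config`.
#' @param time simulation time (s).
#' @return list of event records (possibly empty).
#' @export
grow_cells <- function(tissue, dt, config, time = 0) {
  tis <- tissue; params <- config$params
  cs <- tis$cells
  n <- tis$n_cells
  idx <- seq_len(n)
  live <- cs$alive & !cs$static
  zone <- cs$zone
  r <- numeric(n)
  r_mz <- division_rate_of(cs$mean_j[1:n], params)
  r_tz <- if (is.na(params$tz_growth_rate)) log(2) / (params$cellcycle * 3600)
          else params$tz_growth_rate
  r_ez <- 1 / (params$expansion_duration * 3600)
  r[zone == "MZ"] <- r_mz[zone == "MZ"]
  r[zone == "TZ"] <- r_tz
  r[zone == "EZ"] <- r_ez
  r[!live] <- 0
  tis$cells$length_cont <- cs$length_cont + dt * r * cs$length_cont

  events <- list()
  ## row insertions (continuous length exceeds integer length by >= 1)
  repeat {
    cs <- tis$cells
    lint <- cs$row1 - cs$row0 + 1L
    need <- which(cs$alive & !cs$static & (cs$length_cont - lint >= 1))
    if (!length(need)) break
    events <- c(events, insert_row(tis, need[1], config, time))
  }
  ## divisions at size doubling, meristem proper only
  repeat {
    cs <- tis$cells
    ready <- which(cs$alive & !cs$static & cs$zone == "MZ" &
                     cs$length_cont >= 2 * cs$birth_length)
    if (!length(ready)) break
    events <- c(events, divide_cell(tis, ready[1], config, time))
  }
  events[!vapply(events, is.null, logical(1))]
}

#' Differentiation-driven zone transitions
#'
#' Optionally integrates the differentiation factor (constant production
#' outside the meristem, first-order decay everywhere, permitting
#' dedifferentiation), then re-evaluates every cell's zone from its position
#' and differentiation level, reassigning the transporter prepattern on each
#' transition. Crossing the differentiation threshold moves a cell to the DZ
#' and ends its elongation.
#'
#' @param tissue tissue environment.
#' @param config `scenario_config`.
#' @param dt time step (s) to integrate the differentiation factor, or
#'   `NULL` to only apply transitions.
#' @param time simulation time (s).
#' @param full re-evaluate every cell's zone (needed after cells moved);
#'   otherwise only differentiation-threshold crossings (EZ to DZ) are
#'   checked, which is the only transition possible without movement.
#' @return list of zone-change event records.
#' @export
advance_differentiation <- function(tissue, config, dt = NULL, time = 0,
                                    full = TRUE) {
  tis <- tissue; params <- config$params
  n <- tis$n_cells
  cs <- tis$cells
  if (!is.null(dt)) {
    in_mz <- cs$zone %in% c("MZ", "TZ")
    D <- tis$state$Diff
    D <- D + dt * (params$p_Diff * (!in_mz) - params$d_Diff * D)
    tis$state$Diff <- pmax(D, 0)
  }
  events <- list()
  if (full) {
    live <- which(cs$alive & !cs$static)
    dist <- (cs$row0 - 1L) * tis$dx
    newzone <- zone_of(dist[live], cs$type[live], tis$state$Diff[live],
                       params, tis$zone_scale)
    changed <- live[newzone != cs$zone[live]]
    nz <- newzone[newzone != cs$zone[live]]
  } else {
    changed <- which(cs$alive & !cs$static & cs$zone == "EZ" &
                       tis$state$Diff > params$Th_Diff)
    nz <- rep("DZ", length(changed))
  }
  for (k in seq_along(changed)) {
    i <- changed[k]
    tis$cells$zone[i] <- nz[k]
    apply_prepattern(tis, i, config)
    events <- c(events, list(list(time = time, event = "zone-change", id = i,
                                  row = cs$row0[i])))
  }
  events
}

#' Cull cells at the domain top and shed lateral-root cap cells
#'
#' A cell whose wall above its apical membrane reaches the topmost grid row
#' is removed; a lateral-root cap cell whose basal membrane passes the cap
#' meristem end (314 um, zone-scaled) is shed. No other removals occur.
#'
#' @param tissue tissue environment.
#' @param config `scenario_config`.
#' @param time simulation time (s).
#' @return list of removal event records.
#' @export
cull_and_shed <- function(tissue, config, time = 0) {
  tis <- tissue; params <- config$params
  events <- list()
  for (f in seq_len(nrow(tis$files))) {
    repeat {
      top <- file_top_cell(tis, f)
      if (is.na(top) || tis$cells$row1[top] + 1L < tis$n_rows) break
      events <- c(events, list(list(time = time, event = "cull", id = top,
                                    row = tis$cells$row0[top])))
      remove_cell(tis, top)
    }
  }
  cs <- tis$cells
  shed_at <- params$lrcap_mz_end * tis$zone_scale
  shed <- which(cs$alive & !cs$static & cs$type == "lrcap" &
                  (cs$row0 - 1L) * tis$dx > shed_at)
  for (i in shed) {
    events <- c(events, list(list(time = time, event = "shed", id = i,
                                  row = cs$row0[i])))
    remove_cell(tis, i)
  }
  events
}
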