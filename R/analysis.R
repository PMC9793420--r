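## Derived observables: kymographs (standard and experimental style), traced
## pericycle cells, priming-event detection, stable prebranch-site detection,
## normalized peak-difference metrics and narrowing summaries.

#' Build a kymograph
#'
#' The kymograph samples the one-grid-point-wide vertical line through the
#' middle of the left pericycle file every sampling interval and concatenates
#' the lines over time. The `"experimental"` style skews the matrix so a
#' differentiated cell stays at a constant horizontal position (as in
#' live-imaging kymographs, where the root tip moves): each line is shifted
#' by the displacement of an anchor cell in the differentiation zone and the
#' domain is padded as the root "grows".
#'
#' @param sim a `root_sim`.
#' @param style `"standard"` or `"experimental"`.
#' @param quantity `"signalling"` or `"auxin"`.
#' @return object of class `root_kymograph`: a `time x position` matrix plus
#'   sampling times and spacing.
#' @export
build_kymograph <- function(sim, style = c("standard", "experimental"),
                            quantity = c("signalling", "auxin")) {
  style <- match.arg(style)
  quantity <- match.arg(quantity)
  M <- if (quantity == "signalling") sim$kymograph_signalling
       else sim$kymograph_auxin
  times <- sim$times_h
  dx <- sim$tissue$dx
  if (style == "experimental") {
    ## anchor: the left pericycle cell furthest shootward at the first sample
    tr <- sim$traces
    peri <- tr[tr$type == "pericycle" & tr$side == -1L, ]
    t0 <- min(peri$time_h)
    first <- peri[peri$time_h == t0, ]
    anchor <- first$id[which.max(first$row0)]
    arows <- peri[peri$id == anchor, c("time_h", "row0")]
    off <- round(approx(arows$time_h, arows$row0, xout = times,
                        rule = 2)$y) - arows$row0[1]
    maxoff <- max(off, 0)
    out <- matrix(NA_real_, nrow(M), ncol(M) + maxoff)
    for (k in seq_len(nrow(M)))
      out[k, seq_len(ncol(M)) + (maxoff - off[k])] <- M[k, ]
    M <- out
  }
  structure(list(matrix = M, times_h = times, dx = dx, style = style,
                 quantity = quantity), class = "root_kymograph")
}

#' Trace pericycle cells from a start distance
#'
#' Returns per-cell time series for left-side pericycle cells, starting when
#' each cell's distance from the tip first reaches `start_distance`
#' (zone-scaled), ordered by crossing time; ids persist across divisions of
#' cells below, so traces are contiguous.
#'
#' @param sim a `root_sim`.
#' @param start_distance distance threshold in full-scale micrometres
#'   (default 500; multiplied by the geometry's zone scale).
#' @param side -1 (left, default), 1 (right) or NULL (both).
#' @return tibble of trace rows with a `crossing_order` column.
#' @export
trace_cells <- function(sim, start_distance = 500, side = -1L) {
  zs <- sim$tissue$zone_scale
  thr <- start_distance * zs
  tr <- sim$traces
  tr <- tr[tr$type == "pericycle", ]
  if (!is.null(side)) tr <- tr[tr$side == side, ]
  if (!nrow(tr)) return(tr)
  crossed <- tr |> dplyr::filter(.data$distance_um >= thr)
  if (!nrow(crossed)) return(tr[0, ])
  cross <- crossed |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(cross_time = min(.data$time_h), .groups = "drop")
  cross <- cross[order(cross$cross_time), ]
  cross$crossing_order <- seq_len(nrow(cross))
  tr |>
    dplyr::inner_join(cross, by = "id") |>
    dplyr::filter(.data$time_h >= .data$cross_time) |>
    dplyr::arrange(.data$crossing_order, .data$time_h)
}

#' Detect priming events in cell traces
#'
#' Works on the sequence of per-cell peak signalling values in crossing
#' order: local maxima separated by minima deeper than `prominence` define
#' events; each event's member cells are the consecutive cells between the
#' flanking minima.
#'
#' @param traces tibble from [trace_cells()] (needs `crossing_order`,
#'   `time_h`, and the value column).
#' @param prominence minimum drop (a.u.) between consecutive events.
#' @param value column to analyse (default `"signalling"`).
#' @return tibble with one row per event: `event`, `n_cells`,
#'   `peak_value`, `peak_time_h`, `first_cell`, `last_cell`.
#' @export
detect_priming_events <- function(traces, prominence = 10,
                                  value = "signalling") {
  stopifnot(nrow(traces) > 0)
  pk <- traces |>
    dplyr::group_by(.data$crossing_order, .data$id) |>
    dplyr::summarise(peak = max(.data[[value]]),
                     peak_time = .data$time_h[which.max(.data[[value]])],
                     .groups = "drop") |>
    dplyr::arrange(.data$crossing_order)
  v <- pk$peak
  m <- length(v)
  if (m < 3) return(tibble::tibble(event = integer(0), n_cells = integer(0),
                                   peak_value = numeric(0),
                                   peak_time_h = numeric(0),
                                   first_cell = integer(0),
                                   last_cell = integer(0)))
  is_max <- which(v > c(-Inf, v[-m]) & v >= c(v[-1], -Inf))
  ## keep maxima exceeding the lower of the two flanking minima by prominence
  keep <- vapply(is_max, function(i) {
    left <- if (i > 1) min(v[1:i]) else v[1]
    right <- if (i < m) min(v[i:m]) else v[m]
    (v[i] - max(left, right)) >= prominence
  }, logical(1))
  mx <- is_max[keep]
  if (!length(mx)) return(tibble::tibble(event = integer(0),
                                         n_cells = integer(0),
                                         peak_value = numeric(0),
                                         peak_time_h = numeric(0),
                                         first_cell = integer(0),
                                         last_cell = integer(0)))
  ## event boundaries at the minima between consecutive maxima
  bounds <- c(0, vapply(seq_len(length(mx) - 1), function(k) {
    seg <- mx[k]:mx[k + 1]
    seg[which.min(v[seg])]
  }, numeric(1)), m)
  tibble::tibble(
    event = seq_along(mx),
    n_cells = as.integer(diff(bounds)),
    peak_value = v[mx],
    peak_time_h = pk$peak_time[mx],
    first_cell = pk$id[bounds[-length(bounds)] + 1],
    last_cell = pk$id[bounds[-1]]
  )
}

#' Detect stable prebranch-site cells
#'
#' Operational criterion: a traced cell is a stable prebranch site if its
#' signalling is non-decreasing over the final `window_h` hours of its trace
#' and its final signalling exceeds its own priming peak. The priming peak
#' is the maximum while the cell's differentiation factor is still below the
#' feedback gate (80) when a `Diff` column is available, and the first-half
#' maximum otherwise. This operationalizes the "stably maintained,
#' continuous rising" behaviour; per-side results are returned.
#'
#' @param traces trace tibble (needs `id`, `side`, `time_h`, `signalling`,
#'   and optionally `Diff`).
#' @param window_h length of the final window (h).
#' @param tol relative tolerance for "non-decreasing" between hourly means.
#' @return tibble with `id`, `side`, `final_signalling`, `priming_peak`,
#'   `secondary_max`, `stable` (logical); one row per traced cell.
#' @export
detect_stable_pbs <- function(traces, window_h = 10, tol = 0.01) {
  stopifnot(nrow(traces) > 0)
  has_diff <- "Diff" %in% names(traces)
  traces |>
    dplyr::group_by(.data$id, .data$side) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      final_signalling = dplyr::last(.data$signalling),
      priming_peak = {
        pre <- if (has_diff) .data$Diff <= 80 else
          .data$time_h <= min(.data$time_h) +
            (max(.data$time_h) - min(.data$time_h)) / 2
        if (any(pre)) max(.data$signalling[pre]) else Inf
      },
      secondary_max = {
        pre <- if (has_diff) .data$Diff <= 80 else
          .data$time_h <= min(.data$time_h) +
            (max(.data$time_h) - min(.data$time_h)) / 2
        if (any(!pre)) max(.data$signalling[!pre]) else -Inf
      },
      nondecreasing = {
        ## discrete growth events impose a sawtooth on the signal; compare
        ## hourly block means over the final window instead of raw samples
        sel <- .data$time_h >= max(.data$time_h) - window_h
        w <- .data$signalling[sel]
        hb <- floor(.data$time_h[sel] - min(.data$time_h[sel]))
        m <- tapply(w, hb, mean)
        length(m) >= 2 && all(diff(m) >= -tol * max(abs(m)))
      },
      .groups = "drop") |>
    dplyr::mutate(stable = .data$nondecreasing &
                    .data$final_signalling > .data$priming_peak) |>
    dplyr::select(-"nondecreasing")
}

#' Normalized peak and at-distance differences between two traces
#'
#' Both traces are normalized together so the larger one peaks at 100; the
#' peak difference and the difference when the cells are at `at_distance`
#' are returned on that 0-100 scale.
#'
#' @param trace_a,trace_b tibbles with `time_h`, `distance_um` and the value
#'   column.
#' @param at_distance query distance (um, in the run's own scale).
#' @param value column to compare (e.g. `"signalling"` or `"EpiO"`).
#' @return named numeric: `peak_difference`, `at_distance_difference`.
#' @export
normalized_difference_metrics <- function(trace_a, trace_b, at_distance,
                                          value = "signalling") {
  va <- trace_a[[value]]; vb <- trace_b[[value]]
  mx <- max(va, vb)
  if (mx <= 0) return(c(peak_difference = 0, at_distance_difference = 0))
  va <- va / mx * 100; vb <- vb / mx * 100
  at_val <- function(tr, v) {
    i <- which(tr$distance_um >= at_distance)
    if (!length(i)) stop("queried distance ", at_distance, " not reached")
    v[i[1]]
  }
  c(peak_difference = abs(max(va) - max(vb)),
    at_distance_difference = abs(at_val(trace_a, va) - at_val(trace_b, vb)))
}

#' Narrowing of a high-signalling domain over time
#'
#' Counts, per sampling time, how many cells (for traces) or contiguous
#' above-threshold runs (for a kymograph matrix) exceed a threshold,
#' reporting how an initially broad signalling domain narrows to the final
#' prebranch site.
#'
#' @param x trace tibble (with `time_h`, `id`, `signalling`) or a numeric
#'   matrix (time in rows).
#' @param threshold signalling threshold (a.u.).
#' @param ... unused.
#' @return tibble with `time_h` (or row index) and `n_above`.
#' @export
narrowing_summary <- function(x, threshold, ...) UseMethod("narrowing_summary")

#' @export
narrowing_summary.matrix <- function(x, threshold, ...) {
  runs <- apply(x >= threshold, 1, function(r) {
    r[is.na(r)] <- FALSE
    sum(diff(c(FALSE, r)) == 1)
  })
  tibble::tibble(time_index = seq_len(nrow(x)), n_above = as.integer(runs))
}

#' @export
narrowing_summary.data.frame <- function(x, threshold, ...) {
  x |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(n_above = sum(.data$signalling >= threshold),
                     .groups = "drop")
}

#' @importFrom rlang .data
NULL
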