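## ggplot2 views of simulation results. Colour maps are cosmetic; the numeric
## matrices and tibbles are the tested artifacts.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kymograph heat map
#'
#' @param object a `root_kymograph`.
#' @param ... unused.
#' @return a ggplot: time (h) vs distance from the tip (um), colour = value.
#' @export
autoplot.root_kymograph <- function(object, ...) {
  M <- object$matrix
  df <- expand.grid(time_h = object$times_h,
                    position_um = (seq_len(ncol(M)) - 1) * object$dx)
  df$value <- as.vector(M)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_um, y = .data$time_h,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "distance from tip (µm)", y = "time (h)",
                  fill = object$quantity) +
    ggplot2::theme_minimal()
}

#' Kymograph view of a simulation
#'
#' @param object a `root_sim`.
#' @param quantity `"signalling"` or `"auxin"`.
#' @param style `"standard"` or `"experimental"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.root_sim <- function(object, quantity = "signalling",
                              style = "standard", ...) {
  autoplot(build_kymograph(object, style = style, quantity = quantity))
}

#' Per-cell signalling traces
#'
#' @param sim a `root_sim`.
#' @param value column of the trace table to plot.
#' @param start_distance passed to [trace_cells()].
#' @return a ggplot of the traced pericycle cells over time.
#' @export
plot_traces <- function(sim, value = "signalling", start_distance = 500) {
  tr <- trace_cells(sim, start_distance = start_distance)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_h, y = .data[[value]],
                                   group = .data$id,
                                   colour = factor(.data$crossing_order))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time (h)", y = value) +
    ggplot2::theme_minimal()
}

#' Tissue snapshot
#'
#' @param sim a `root_sim`.
#' @param what `"auxin"` (field) or `"zone"` (cell zones).
#' @return a ggplot of the final state.
#' @export
plot_snapshot <- function(sim, what = c("auxin", "zone")) {
  what <- match.arg(what)
  tis <- sim$tissue
  if (what == "auxin") {
    df <- expand.grid(row = seq_len(tis$n_rows), col = seq_len(tis$n_cols))
    df$value <- as.vector(tis$auxin)
    df$value[as.vector(tis$kind) == KIND_OUTSIDE] <- NA
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white") +
      ggplot2::labs(fill = "auxin") + ggplot2::theme_void()
  } else {
    cells <- as_cells_tibble(tis)
    ggplot2::ggplot(cells, ggplot2::aes(xmin = .data$col0, xmax = .data$col1,
                                        ymin = .data$row0, ymax = .data$row1,
                                        fill = .data$zone)) +
      ggplot2::geom_rect(colour = "grey30", linewidth = 0.1) +
      ggplot2::theme_void()
  }
}
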