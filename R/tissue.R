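## Tissue construction: a 2-D grid of labelled points (cell interior,
## membrane, wall, outside) hosting a bilaterally symmetric set of cell files
## (epidermis, cortex, endodermis, pericycle, vasculature, flanking LR cap)
## above a static curved cap template (columella, QC, lower LR cap) at the
## root tip. Row 1 is the rootward (tip) end; the distance of a cell from the
## tip is the 0-based row index of its lower boundary times dx.

KIND_OUTSIDE <- 0L; KIND_INTERIOR <- 1L; KIND_MEMBRANE <- 2L; KIND_WALL <- 3L

CELL_TYPES <- c("epidermis", "cortex", "endodermis", "pericycle",
                "vasculature", "lrcap", "columella", "qc")

#' Developmental zone of a cell
#'
#' Zonation is superimposed by distance from the root tip: cells whose lower
#' boundary lies at 514 um or less are meristematic (the 364-514 um band is
#' the transition zone, which grows but no longer divides); beyond that cells
#' are elongating until their differentiation factor exceeds `Th_Diff` (85),
#' after which they belong to the differentiation zone. For the faster
#' maturing lateral-root cap the meristem ends at 314 um.
#'
#' @param distance_um distance of the cell's lower (rootward) boundary from
#'   the tip (um).
#' @param cell_type one of the tissue's cell types (`"lrcap"` has its own
#'   meristem boundary).
#' @param diff_level differentiation factor (a.u.).
#' @param params `root_params`.
#' @param zone_scale scale factor applied to the zone boundaries (shrunken
#'   test geometries scale their zones proportionally).
#' @return `"MZ"`, `"TZ"`, `"EZ"` or `"DZ"` (vectorized).
#' @export
zone_of <- function(distance_um, cell_type, diff_level = 0,
                    params = default_parameters(), zone_scale = 1) {
  stopifnot(all(distance_um >= 0))
  n <- max(length(distance_um), length(cell_type), length(diff_level))
  d <- rep_len(distance_um, n)
  ty <- rep_len(cell_type, n)
  df <- rep_len(diff_level, n)
  mz_end <- ifelse(ty == "lrcap", params$lrcap_mz_end, params$mz_end) * zone_scale
  tz_start <- params$tz_start * zone_scale
  zone <- ifelse(d <= mz_end,
                 ifelse(d > tz_start & ty != "lrcap", "TZ", "MZ"),
                 ifelse(df > params$Th_Diff, "DZ", "EZ"))
  zone
}

#' Transporter prepattern table
#'
#' Relative membrane placement weights for PIN, AUX1 and LAX3 per cell type,
#' developmental zone and membrane face (rootward, shootward, inner, outer),
#' following the qualitative polarities of root-tip reflux models: rootward
#' PIN in the stele, shootward PIN in epidermis and lateral-root cap, inward
#' PIN transitions in the elongation zone of endodermis and cortex, and (in
#' the default table) more apolar endodermal/cortical PIN in the
#' differentiation zone. The `"apolar-equal"` variant keeps the DZ
#' endodermis/cortex PIN pattern identical to the EZ pattern.
#'
#' @param variant `"default"` or `"apolar-equal"`.
#' @return nested list: `table[[cell_type]][[zone]]` is a list of numeric
#'   `c(root, shoot, inner, outer)` weights named `PIN`, `AUX1`, `LAX3`.
#' @export
prepattern_table <- function(variant = c("default", "apolar-equal")) {
  variant <- match.arg(variant)
  if (!is.null(.prepattern_cache[[variant]]))
    return(.prepattern_cache[[variant]])
  f <- function(root, shoot, inner, outer) c(root = root, shoot = shoot,
                                             inner = inner, outer = outer)
  uni <- function(w) f(w, w, w, w)
  zones <- c("MZ", "TZ", "EZ", "DZ")
  mk <- function(PIN, AUX1, LAX3) list(PIN = PIN, AUX1 = AUX1, LAX3 = LAX3)
  tab <- list()
  for (z in zones) {
    tab$vasculature[[z]] <- mk(f(1, 0, 0, 0.1), uni(0.8), uni(1))
    tab$pericycle[[z]]   <- mk(f(1, 0, 0, 0.1), uni(0.5), uni(1))
    tab$endodermis[[z]]  <- mk(f(1, 0, 0, 0),   uni(0.2), uni(0))
    tab$cortex[[z]]      <- mk(f(0, 1, 0, 0),   uni(0.2), uni(0))
    tab$epidermis[[z]]   <- mk(f(0, 1, 0, 0.1), uni(1),   uni(0))
    tab$lrcap[[z]]       <- mk(f(0, 1, 0.5, 0), uni(1),   uni(0))
    tab$columella[[z]]   <- mk(uni(0.5),        uni(1),   uni(0))
    tab$qc[[z]]          <- mk(f(0.1, 0.1, 0.1, 0.1), uni(0.5), uni(0))
  }
  ## strong inward transitions in the elongation zone return auxin to the
  ## stele while stele rootward transport weakens there, so the returned
  ## auxin pools into the loading zone at the elongation-zone start instead
  ## of being flushed back into the meristem
  tab$endodermis$EZ$PIN <- f(0.2, 0, 0.8, 0)
  tab$cortex$EZ$PIN     <- f(0, 0.3, 0.7, 0)
  tab$epidermis$EZ$PIN  <- f(0, 0.6, 0.4, 0)
  tab$pericycle$EZ$PIN  <- f(0.3, 0, 0.1, 0.1)
  tab$vasculature$EZ$PIN <- f(0.3, 0, 0, 0.2)
  ## DZ: vasculature hands auxin to the pericycle; pericycle and endodermis
  ## orient toward one another (recycling); endodermis/cortex more apolar.
  ## Rootward components keep the distal DZ draining so non-primed auxin
  ## declines with distance.
  tab$vasculature$DZ$PIN <- f(0.3, 0, 0, 0.6)
  tab$pericycle$DZ$PIN   <- f(0.15, 0, 0.1, 0.4)
  if (variant == "default") {
    tab$endodermis$DZ$PIN <- f(0.3, 0.2, 0.4, 0.2)
    tab$cortex$DZ$PIN     <- f(0.25, 0.3, 0.25, 0.2)
  } else {
    tab$endodermis$DZ$PIN <- tab$endodermis$EZ$PIN
    tab$cortex$DZ$PIN     <- tab$cortex$EZ$PIN
  }
  .prepattern_cache[[variant]] <- tab
  tab
}

.prepattern_cache <- new.env(parent = emptyenv())

## file layout left to right, with sides (-1 left, 0 centre, 1 right)
file_layout <- function(widths) {
  types <- c("lrcap", "epidermis", "cortex", "endodermis", "pericycle",
             "vasculature")
  data.frame(
    type = c(types, "vasculature", rev(types)),
    side = c(rep(-1L, 6), 0L, rep(1L, 6)),
    width = unname(c(widths[types], widths["centre"], rev(widths[types]))),
    stringsAsFactors = FALSE
  )
}

new_tissue_env <- function(n_rows, n_cols, dx, zone_scale) {
  tis <- new.env(parent = emptyenv())
  tis$n_rows <- n_rows; tis$n_cols <- n_cols
  tis$dx <- dx; tis$zone_scale <- zone_scale
  tis$kind <- matrix(KIND_OUTSIDE, n_rows, n_cols)
  tis$cell_id <- matrix(0L, n_rows, n_cols)
  tis$wPIN <- matrix(0, n_rows, n_cols)
  tis$wAUX1 <- matrix(0, n_rows, n_cols)
  tis$wLAX3 <- matrix(0, n_rows, n_cols)
  tis$auxin <- matrix(0, n_rows, n_cols)
  tis$cells <- list()   # parallel vectors, filled by add_cell
  tis$n_cells <- 0L
  tis$geom_stamp <- 0L  # incremented on any geometry change (cache key)
  for (fld in c("type", "zone")) tis$cells[[fld]] <- character(0)
  for (fld in c("side", "col0", "col1", "row0", "row1", "mean_j", "file"))
    tis$cells[[fld]] <- integer(0)
  for (fld in c("length_cont", "birth_length", "ctf"))
    tis$cells[[fld]] <- numeric(0)
  for (fld in c("static", "alive")) tis$cells[[fld]] <- logical(0)
  tis
}

add_cell <- function(tis, type, side, col0, col1, row0, row1, ctf = 1,
                     static = FALSE, zone = "MZ") {
  id <- tis$n_cells + 1L
  tis$n_cells <- id
  cs <- tis$cells
  cs$type[id] <- type; cs$side[id] <- as.integer(side)
  cs$col0[id] <- col0; cs$col1[id] <- col1
  cs$row0[id] <- row0; cs$row1[id] <- row1
  cs$length_cont[id] <- row1 - row0 + 1
  cs$birth_length[id] <- row1 - row0 + 1
  cs$mean_j[id] <- as.integer(floor((row0 + row1) / 2) - 1L)  # 0-based centre
  cs$ctf[id] <- ctf; cs$static[id] <- static; cs$alive[id] <- TRUE
  cs$zone[id] <- zone; cs$file[id] <- NA_integer_
  tis$cells <- cs
  ## paint the rectangle: perimeter membrane, inside interior
  rr <- row0:row1; cc <- col0:col1
  tis$kind[rr, cc] <- KIND_MEMBRANE
  if (length(rr) > 2 && length(cc) > 2)
    tis$kind[(row0 + 1):(row1 - 1), (col0 + 1):(col1 - 1)] <- KIND_INTERIOR
  tis$cell_id[rr, cc] <- id
  ## surrounding walls (shared walls are idempotent)
  wr <- c(row0 - 1L, row1 + 1L); wc <- c(col0 - 1L, col1 + 1L)
  tis$kind[wr[wr >= 1 & wr <= tis$n_rows], (col0 - 1L):(col1 + 1L)] <- KIND_WALL
  tis$kind[(row0 - 1L):(row1 + 1L), wc[wc >= 1 & wc <= tis$n_cols]] <- KIND_WALL
  id
}

#' Build the root-tip tissue
#'
#' Constructs the labelled grid and cell set for a scenario: bilaterally
#' symmetric cell files (outside-in: lateral-root cap, epidermis, cortex,
#' endodermis, pericycle, vasculature, with a centre vasculature file), a
#' static cap template of columella, QC and lower lateral-root cap cells at
#' the tip, cell-type-specific widths, uniform initial cell heights, zone
#' assignment and zone-specific transporter prepatterns, and cell-type
#' auxin-production factors (100 for QC, top columella and vascular initials,
#' 50 for lower columella, 30 for the lateral-root cap, 1 otherwise).
#'
#' @param config a `scenario_config`.
#' @return A tissue environment holding the grid matrices (`kind`,
#'   `cell_id`, transporter weight matrices, `auxin`) and the cell table;
#'   inspect with [as_cells_tibble()].
#' @export
build_root_tissue <- function(config) {
  geom <- config$geometry; params <- config$params
  widths <- geom$widths
  if (any(widths < 1)) stop("geometry cannot host all cell types: zero width")
  lay <- file_layout(widths)
  n_cols_needed <- sum(lay$width) + nrow(lay) + 1L
  if (geom$n_cols != n_cols_needed)
    stop("n_cols (", geom$n_cols, ") does not match file widths (need ",
         n_cols_needed, ")")
  bh <- max(2L, as.integer(geom$cap_rows) %/% 6L)  # cap band cell height
  cap_top_wall <- 1L + 4L * (bh + 1L)
  min_rows <- cap_top_wall + 3L * (geom$cell_height_rows + 1L)
  if (geom$n_rows < min_rows)
    stop("geometry cannot host the tissue: need at least ", min_rows, " rows")

  tis <- new_tissue_env(geom$n_rows, geom$n_cols, params$dx, geom$zone_scale)
  tis$cell_height_rows <- geom$cell_height_rows

  ## file column extents
  cur <- 1L  # column 1 is the outer left wall
  lay$col0 <- lay$col1 <- NA_integer_
  for (f in seq_len(nrow(lay))) {
    lay$col0[f] <- cur + 1L
    lay$col1[f] <- cur + lay$width[f]
    cur <- lay$col1[f] + 1L
  }
  tis$files <- lay

  ## --- static cap template (staircase approximation of the curved tip) ---
  stele <- range(lay$col0[lay$type %in% c("endodermis", "pericycle",
                                          "vasculature")],
                 lay$col1[lay$type %in% c("endodermis", "pericycle",
                                          "vasculature")])
  flankL <- c(min(lay$col0), lay$col1[lay$type == "cortex" & lay$side == -1L])
  flankR <- c(lay$col0[lay$type == "cortex" & lay$side == 1L], max(lay$col1))
  band_rows <- function(k) {
    r0 <- 2L + (k - 1L) * (bh + 1L)
    c(r0, r0 + bh - 1L)
  }
  for (k in 1:2) {  # lower columella
    br <- band_rows(k)
    add_cell(tis, "columella", 0L, stele[1], stele[2], br[1], br[2],
             ctf = 50, static = TRUE)
  }
  br <- band_rows(3)  # top columella layer
  add_cell(tis, "columella", 0L, stele[1], stele[2], br[1], br[2],
           ctf = 100, static = TRUE)
  br <- band_rows(4)  # quiescent centre
  add_cell(tis, "qc", 0L, stele[1], stele[2], br[1], br[2],
           ctf = 100, static = TRUE)
  for (k in 2:4) {    # flanking lower LR cap; band 1 left open (curved tip)
    br <- band_rows(k)
    add_cell(tis, "lrcap", -1L, flankL[1], flankL[2], br[1], br[2],
             ctf = 30, static = TRUE)
    add_cell(tis, "lrcap", 1L, flankR[1], flankR[2], br[1], br[2],
             ctf = 30, static = TRUE)
  }

  ## --- rectangular files above the cap ---
  h <- geom$cell_height_rows
  lrcap_top_um <- params$lrcap_mz_end * geom$zone_scale
  for (f in seq_len(nrow(lay))) {
    ty <- lay$type[f]
    first_vasc <- TRUE
    r0 <- cap_top_wall + 1L
    while (r0 + h <= geom$n_rows) {
      dist <- (r0 - 1L) * params$dx
      if (ty == "lrcap" && dist >= lrcap_top_um) break
      ctf <- if (ty == "lrcap") 30 else if (ty == "vasculature" && first_vasc) 100 else 1
      first_vasc <- FALSE
      id <- add_cell(tis, ty, lay$side[f], lay$col0[f], lay$col1[f],
                     r0, r0 + h - 1L, ctf = ctf)
      tis$cells$file[id] <- f
      r0 <- r0 + h + 1L
    }
    ## continuous vertical wall columns over the file's extent above the cap
    ## (cap-template walls are painted by the cap cells themselves)
    top <- max(tis$cells$row1[tis$cells$file %in% f &
                                tis$cells$alive], cap_top_wall - 1L) + 1L
    tis$kind[cap_top_wall:top, c(lay$col0[f] - 1L, lay$col1[f] + 1L)] <- KIND_WALL
  }

  ## initial differentiation heuristic and zone assignment
  init_state(tis, config)
  for (i in seq_len(tis$n_cells)) apply_prepattern(tis, i, config)
  tis
}

## initial regulatory state: plausible pre-burn-in levels; differentiation
## ramps with distance beyond the elongation-zone start so distal cells start
## differentiated instead of re-running their full history
init_state <- function(tis, config) {
  params <- config$params; zs <- tis$zone_scale
  n <- tis$n_cells
  dist <- (tis$cells$row0 - 1L) * params$dx
  ez_start <- params$mz_end * zs
  ramp <- 460 * zs
  Diff <- ifelse(dist > ez_start, pmin(100, (dist - ez_start) / ramp * 100), 0)
  Diff[tis$cells$static] <- 0
  tis$cells$zone <- zone_of(dist, tis$cells$type, Diff, params, zs)
  tis$cells$zone[tis$cells$static] <- "MZ"
  tis$state <- list(
    AUX1 = rep(50, n), LAX3 = rep(params$LAX3_constant, n),
    YUCCA4 = rep(0, n), Diff = Diff,
    ARFtotal = rep(10, n), ARFfree = rep(0, n),
    EpiO = rep(0, n), TOLS2 = rep(0, n)
  )
  invisible(tis)
}

#' Assign membrane transporter weights to one cell
#'
#' Writes the (PIN, AUX1, LAX3) prepattern weights of the cell's type and
#' current zone onto its membrane grid points, face by face: the bottom row
#' of the cell rectangle is the rootward face, the top row the shootward
#' face, and the side columns the lateral faces (mapped to inner/outer by
#' the cell's side; the centre file uses the outer weight on both sides).
#' Re-invoked on every zone transition; daughters keep the mother's weights
#' until their next transition.
#'
#' @param tissue tissue environment from [build_root_tissue()].
#' @param i cell index.
#' @param config `scenario_config` (selects the DZ PIN variant).
#' @return the tissue, invisibly.
#' @export
apply_prepattern <- function(tissue, i, config) {
  cs <- tissue$cells
  tab <- prepattern_table(config$dz_pin_variant)
  ent <- tab[[cs$type[i]]][[cs$zone[i]]]
  if (is.null(ent)) stop("no prepattern entry for ", cs$type[i], "/", cs$zone[i])
  r0 <- cs$row0[i]; r1 <- cs$row1[i]; c0 <- cs$col0[i]; c1 <- cs$col1[i]
  side <- cs$side[i]
  ## lateral faces: left column and right column of the rectangle
  left_face <- if (side == -1L) "outer" else if (side == 1L) "inner" else "outer"
  right_face <- if (side == -1L) "inner" else if (side == 1L) "outer" else "outer"
  for (nm in c("PIN", "AUX1", "LAX3")) {
    W <- tissue[[paste0("w", if (nm == "PIN") "PIN" else nm)]]
    w <- ent[[nm]]
    if (r1 - r0 >= 2) {
      if (c1 > c0) {
        W[(r0 + 1):(r1 - 1), c0] <- w[[left_face]]
        W[(r0 + 1):(r1 - 1), c1] <- w[[right_face]]
      } else {
        ## single-column cell: both lateral faces share the column; use the
        ## mean so construction stays mirror-symmetric
        W[(r0 + 1):(r1 - 1), c0] <- (w[[left_face]] + w[[right_face]]) / 2
      }
    }
    W[r0, c0:c1] <- w[["root"]]
    W[r1, c0:c1] <- w[["shoot"]]
    tissue[[paste0("w", if (nm == "PIN") "PIN" else nm)]] <- W
  }
  invisible(tissue)
}

#' Cell table as a tibble
#'
#' @param tissue tissue environment.
#' @param alive_only drop removed cells.
#' @return tibble with one row per cell: id, type, side, zone, extent,
#'   lengths, distance from the tip, and regulatory state.
#' @export
as_cells_tibble <- function(tissue, alive_only = TRUE) {
  cs <- tissue$cells; st <- tissue$state
  n <- tissue$n_cells
  out <- tibble::tibble(
    id = seq_len(n), type = cs$type[1:n], side = cs$side[1:n],
    zone = cs$zone[1:n], col0 = cs$col0[1:n], col1 = cs$col1[1:n],
    row0 = cs$row0[1:n], row1 = cs$row1[1:n],
    length_int = cs$row1[1:n] - cs$row0[1:n] + 1L,
    length_cont = cs$length_cont[1:n], birth_length = cs$birth_length[1:n],
    mean_j = cs$mean_j[1:n], ctf = cs$ctf[1:n],
    distance_um = (cs$row0[1:n] - 1L) * tissue$dx,
    static = cs$static[1:n], alive = cs$alive[1:n],
    AUX1 = st$AUX1[1:n], LAX3 = st$LAX3[1:n], YUCCA4 = st$YUCCA4[1:n],
    Diff = st$Diff[1:n], ARFtotal = st$ARFtotal[1:n],
    ARFfree = st$ARFfree[1:n], EpiO = st$EpiO[1:n], TOLS2 = st$TOLS2[1:n]
  )
  if (alive_only) out <- out[out$alive, ]
  out
}
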