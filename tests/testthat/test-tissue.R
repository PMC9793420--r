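test_that("zonation boundaries follow distance, cell type and differentiation", {
  p <- default_parameters()
  expect_equal(zone_of(400, "vasculature", 0, p), "TZ")
  expect_equal(zone_of(320, "lrcap", 0, p), "EZ")     # LR cap meristem ends at 314
  expect_equal(zone_of(600, "pericycle", 90, p), "DZ")
  expect_equal(zone_of(600, "pericycle", 50, p), "EZ")
  expect_equal(zone_of(200, "pericycle", 0, p), "MZ")
  expect_equal(zone_of(514, "pericycle", 0, p), "TZ")
  expect_equal(zone_of(515, "pericycle", 0, p), "EZ")
  ## monotone MZ -> TZ -> EZ ordering in distance below the threshold
  z <- zone_of(seq(0, 1000, by = 2), "vasculature", 0, p)
  ord <- match(z, c("MZ", "TZ", "EZ"))
  expect_true(all(diff(ord) >= 0))
  ## zone boundaries scale with the geometry
  expect_equal(zone_of(400 * 0.25, "vasculature", 0, p, zone_scale = 0.25),
               "TZ")
})

test_that("the fixture tissue satisfies the grid invariants", {
  cfg <- scenario_config(geometry = "fixture")
  tis <- build_root_tissue(cfg)
  ## labelling is a partition over the four kinds
  expect_true(all(tis$kind %in% 0:3))
  ## every membrane point belongs to exactly one cell and touches >= 1 wall
  ## point and >= 1 point of its own cell, and no other cell (vectorized
  ## over all membrane points)
  mem <- which(tis$kind == 2L, arr.ind = TRUE)
  expect_true(all(tis$cell_id[mem] > 0))
  n_wall <- n_own <- n_other <- integer(nrow(mem))
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    ii <- mem[, 1] + d[1]; jj <- mem[, 2] + d[2]
    ok <- ii >= 1 & ii <= tis$n_rows & jj >= 1 & jj <= tis$n_cols
    lin <- cbind(ii[ok], jj[ok])
    kinds <- tis$kind[lin]; ids <- tis$cell_id[lin]
    own_id <- tis$cell_id[mem][ok]
    n_wall[ok] <- n_wall[ok] + (kinds == 3L)
    n_own[ok] <- n_own[ok] + (kinds %in% c(1L, 2L) & ids == own_id)
    n_other[ok] <- n_other[ok] + (kinds %in% c(1L, 2L) & ids != own_id)
  }
  expect_true(all(n_wall >= 1))    # touches a wall
  expect_true(all(n_own >= 1))     # touches its own cell region
  expect_true(all(n_other == 0))   # adjacent to exactly one cell region
  ## walls and outside points carry no cell id
  expect_true(all(tis$cell_id[tis$kind == 3L] == 0L))
  expect_true(all(tis$cell_id[tis$kind == 0L] == 0L))
  ## all eight cell types are present
  expect_setequal(unique(tis$cells$type),
                  c("epidermis", "cortex", "endodermis", "pericycle",
                    "vasculature", "lrcap", "columella", "qc"))
})

test_that("construction is bilaterally symmetric", {
  cfg <- scenario_config(geometry = "fixture")
  tis <- build_root_tissue(cfg)
  mirror <- function(M) M[, ncol(M):1]
  expect_identical(tis$kind, mirror(tis$kind))
  expect_identical(tis$wPIN, mirror(tis$wPIN))
  expect_identical(tis$wAUX1, mirror(tis$wAUX1))
  expect_identical(tis$wLAX3, mirror(tis$wLAX3))
  ## cell sets mirror: types at mirrored columns agree
  cells <- as_cells_tibble(tis)
  left <- cells[cells$side == -1L, ]
  right <- cells[cells$side == 1L, ]
  expect_equal(nrow(left), nrow(right))
})

test_that("the default full-scale geometry has the stated dimensions", {
  g <- geometry_spec("full")
  expect_equal(g$n_cols, 141)
  expect_equal(g$n_rows, 1516)
  p <- default_parameters()
  expect_equal(g$n_cols * p$dx, 282)   # 282 x 3032 um
  expect_equal(g$n_rows * p$dx, 3032)
  cfg <- scenario_config(geometry = "full")
  tis <- build_root_tissue(cfg)
  expect_equal(dim(tis$kind), c(1516, 141))
  expect_identical(tis$kind, tis$kind[, 141:1])  # symmetric at full scale too
})

test_that("invalid geometries are rejected", {
  g <- geometry_spec("fixture")
  g$widths["cortex"] <- 0
  expect_error(scenario_config(geometry = g) |> build_root_tissue(),
               "cannot host")
  g2 <- geometry_spec("fixture")
  g2$n_rows <- 10
  expect_error(scenario_config(geometry = g2) |> build_root_tissue(),
               "rows")
})

test_that("cell-type production factors follow the prescribed values", {
  cfg <- scenario_config(geometry = "fixture")
  tis <- build_root_tissue(cfg)
  cells <- as_cells_tibble(tis)
  expect_equal(unique(cells$ctf[cells$type == "qc"]), 100)
  expect_equal(unique(cells$ctf[cells$type == "lrcap"]), 30)
  col_ctf <- sort(unique(cells$ctf[cells$type == "columella"]))
  expect_equal(col_ctf, c(50, 100))     # lower layers 50, top layer 100
  ## vascular initials (bottom vasculature cells) are 100, the rest 1
  vasc <- cells[cells$type == "vasculature", ]
  expect_setequal(unique(vasc$ctf), c(1, 100))
  expect_true(all(cells$ctf[cells$type %in%
                              c("epidermis", "cortex", "endodermis",
                                "pericycle")] == 1))
})

test_that("prepatterns are zone-specific and the apolar-DZ variant equates EZ and DZ", {
  tab <- prepattern_table("default")
  ## stated polarities: rootward stele PIN, shootward epidermis/LR cap
  expect_gt(tab$vasculature$MZ$PIN[["root"]], tab$vasculature$MZ$PIN[["shoot"]])
  expect_gt(tab$epidermis$MZ$PIN[["shoot"]], tab$epidermis$MZ$PIN[["root"]])
  expect_gt(tab$lrcap$MZ$PIN[["shoot"]], tab$lrcap$MZ$PIN[["root"]])
  ## EZ inward transitions
  expect_gt(tab$endodermis$EZ$PIN[["inner"]], tab$endodermis$MZ$PIN[["inner"]])
  ## default DZ endodermis/cortex more apolar than EZ (smaller spread)
  spread <- function(w) max(w) - min(w)
  expect_lt(spread(tab$cortex$DZ$PIN), spread(tab$cortex$EZ$PIN))
  expect_lt(spread(tab$endodermis$DZ$PIN), spread(tab$endodermis$EZ$PIN))
  ## variant: DZ equals EZ
  tab2 <- prepattern_table("apolar-equal")
  expect_identical(tab2$endodermis$DZ$PIN, tab2$endodermis$EZ$PIN)
  expect_identical(tab2$cortex$DZ$PIN, tab2$cortex$EZ$PIN)
})

test_that("apply_prepattern writes face weights onto membrane points only", {
  cfg <- scenario_config(geometry = "fixture")
  tis <- build_root_tissue(cfg)
  cells <- as_cells_tibble(tis)
  i <- cells$id[cells$type == "vasculature" & cells$zone == "MZ"][2]
  tab <- prepattern_table("default")
  r0 <- cells$row0[cells$id == i]; r1 <- cells$row1[cells$id == i]
  c0 <- cells$col0[cells$id == i]; c1 <- cells$col1[cells$id == i]
  ## rootward face carries the rootward weight (polarized rootward)
  expect_true(all(tis$wPIN[r0, c0:c1] == tab$vasculature$MZ$PIN[["root"]]))
  expect_true(all(tis$wPIN[r1, c0:c1] == tab$vasculature$MZ$PIN[["shoot"]]))
  ## interior points carry no weights
  if (r1 - r0 >= 2 && c1 - c0 >= 2)
    expect_true(all(tis$wPIN[(r0 + 1):(r1 - 1), (c0 + 1):(c1 - 1)] == 0))
})
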