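test_that("gene steady states follow the production:degradation convention", {
  p <- default_parameters()
  ## saturating auxin: AUX1 climbs to p/d = 100; at auxin = Km it reaches 50
  AUX1 <- 0; Diff <- 0
  for (i in 1:150000) {
    st <- step_baseline_expression(AUX1, Diff, auxin = 1e6, in_mz = TRUE,
                                   dt = 5, p)
    AUX1 <- st$AUX1; Diff <- st$Diff
  }
  expect_equal(AUX1, 100, tolerance = 1e-3)
  expect_equal(Diff, 0)
  AUX1 <- 0
  for (i in 1:150000)
    AUX1 <- step_baseline_expression(AUX1, 0, auxin = p$Km_AUX1,
                                     in_mz = TRUE, dt = 5, p)$AUX1
  expect_equal(AUX1, 50, tolerance = 1e-3)
})

test_that("differentiation factor integrates outside the meristem and decays inside", {
  p <- default_parameters()
  Diff <- 0
  for (i in 1:150000)
    Diff <- step_baseline_expression(0, Diff, 0, in_mz = FALSE, dt = 5, p)$Diff
  expect_equal(Diff, 100, tolerance = 1e-3)  # asymptote p_Diff/d_Diff
  Diff <- 20
  for (i in 1:20000)
    Diff <- step_baseline_expression(0, Diff, 0, in_mz = TRUE, dt = 5, p)$Diff
  expect_lt(Diff, 0.2)  # dedifferentiation toward 0
})

test_that("quasi-steady-state free ARF matches the full binding ODE system", {
  p <- default_parameters()
  ## independent oracle: integrate free IAA and ARF-IAA complex to
  ## equilibrium at fixed auxin and fixed total ARF
  full_ode_arf <- function(auxin, ARFtotal, p, IAAreg = 1) {
    IAA <- 0; C <- 0
    for (i in 1:400000) {
      ARFfree <- ARFtotal - C
      dIAA <- p$pIAA * IAAreg - (p$d_IAAbasal + p$dIAATIR1 * auxin) * IAA -
        p$bind * ARFfree * IAA + p$unbind * C
      dC <- p$bind * ARFfree * IAA - p$unbind * C
      IAA <- IAA + 0.5 * dIAA; C <- C + 0.5 * dC
    }
    ARFtotal - C
  }
  for (auxin in c(0, 1, 10, 100, 500)) {
    qss <- free_arf_qss(auxin, 300, p)
    ode <- full_ode_arf(auxin, 300, p)
    expect_lt(abs(qss - ode) / max(ode, 1e-6), 0.01)
  }
  ## monotone increasing in auxin: more TIR1-mediated IAA degradation
  ## liberates ARF
  a <- exp(seq(log(0.1), log(500), length.out = 40))
  fr <- free_arf_qss(a, 300, p)
  expect_true(all(diff(fr) > 0))
  ## no sequestration without binding
  p0 <- default_parameters(bind = 0)
  expect_equal(free_arf_qss(5, 123, p0), 123)
})

test_that("auxin signalling combines auxin with utilised ARF capacity", {
  p <- default_parameters()
  expect_equal(auxin_signalling(42, 0, 0), 42)        # no added capacity
  af <- free_arf_qss(0, 10, p)
  expect_lt(auxin_signalling(0, 10, af), 0.2)          # ~0 at zero auxin
  ## non-decreasing in ARFtotal at fixed bound fraction
  for (bound_frac in c(0.2, 0.5, 0.8)) {
    tot <- seq(0, 300, by = 30)
    s <- auxin_signalling(10, tot, (1 - bound_frac) * tot)
    expect_true(all(diff(s) >= 0))
  }
})

test_that("chromatin opening F1 is half-maximal at its Km and EpiO saturates at 100", {
  p <- default_parameters()
  expect_equal(epio_f1(p$Km_EpiO_1, p), 0.5)
  ## saturating signalling: steady state open/(close * frac_min) = 100
  E <- 0
  for (i in 1:80000) E <- step_epio(E, 1e6, dt = 2, p)
  expect_equal(E, 100, tolerance = 1e-3)
  ## nothing to open or close at the origin
  expect_equal(step_epio(0, 0, dt = 1, p), 0)
})

test_that("EpiO temporally integrates its input: longer pulses leave more EpiO", {
  p <- default_parameters()
  run_pulse <- function(amp, dur_s, total_s = 6 * 3600, dt = 10) {
    E <- 0
    for (t in seq(dt, total_s, by = dt))
      E <- step_epio(E, if (t <= dur_s) amp else 0, dt, p)
    E
  }
  e1 <- run_pulse(100, 3600)
  e2 <- run_pulse(100, 7200)
  expect_gt(e2, e1)
  ## monotone in duration across a range
  es <- vapply(c(0.5, 1, 2, 3) * 3600, function(d) run_pulse(100, d),
               numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("EpiO amplifies normalized input differences (temporal integration)", {
  p <- default_parameters()
  ## two priming-like pulses, the weaker at 75% of the stronger
  tgrid <- seq(10, 12 * 3600, by = 10)
  shape <- function(t) 110 * exp(-((t - 2.5 * 3600) / 4500)^2)
  EA <- EB <- 0; mA <- mB <- 0
  for (t in tgrid) {
    EA <- step_epio(EA, shape(t), 10, p)
    EB <- step_epio(EB, 0.75 * shape(t), 10, p)
    mA <- max(mA, EA); mB <- max(mB, EB)
  }
  input_diff <- 25                      # 100 vs 75 on the normalized scale
  epio_diff <- (1 - mB / mA) * 100
  expect_gt(epio_diff, input_diff)
})

test_that("the transcription gate F3 is sigmoidal with half-max at Km_trans", {
  p <- default_parameters()
  expect_lt(epio_gate(0, p), 1e-6)
  expect_equal(epio_gate(p$Km_trans, p), 0.5)
  e <- seq(0, 100, by = 1)
  expect_true(all(diff(epio_gate(e, p)) >= 0))
})

test_that("feedback expression respects mode, gates and restrictions", {
  p <- default_parameters()
  dt <- 1
  ## below the differentiation gate every induced term is zero in all modes
  for (mode in c("direct", "epio")) {
    st <- step_feedback_expression(LAX3 = 0, YUCCA4 = 0, ARFtotal = 0,
                                   signalling = 1e6, Diff = 50, EpiO = 100,
                                   is_stele = TRUE, in_mz = FALSE, dt, p,
                                   mode = mode)
    ## only basal/vascular production remains
    expect_equal(st$YUCCA4, 0)
    expect_lte(st$ARFtotal, dt * p$p_ARFbasal + 1e-12)
  }
  ## mode none: LAX3 pinned at its constant level
  st <- step_feedback_expression(77, 5, 5, 1e6, 100, 100, TRUE, FALSE, dt, p,
                                 mode = "none")
  expect_equal(st$LAX3, p$LAX3_constant)
  ## epio mode with closed chromatin: only the vascular LAX3 term remains
  st <- step_feedback_expression(0, 0, 0, 1e6, 100, EpiO = 0,
                                 is_stele = TRUE, in_mz = FALSE, dt, p,
                                 mode = "epio")
  expect_equal(st$LAX3, dt * p$p_vasc, tolerance = 1e-4)
  expect_equal(st$YUCCA4, 0, tolerance = 1e-9)
  ## saturating signalling with the differentiation gate open: ARF climbs to
  ## its designed maximum of 300 (direct mode; the chromatin gate in epio
  ## mode reaches the same maximum as F3 -> 1)
  A <- 0
  for (i in 1:120000)
    A <- step_feedback_expression(0, 0, A, 1e6, 100, 100, TRUE, FALSE,
                                  dt = 5, p, mode = "direct")$ARFtotal
  expect_equal(A, 300, tolerance = 1e-2)
  ## epio mode at the EpiO ceiling comes within F3(100) of the maximum
  A <- 0
  for (i in 1:120000)
    A <- step_feedback_expression(0, 0, A, 1e6, 100, 100, TRUE, FALSE,
                                  dt = 5, p, mode = "epio")$ARFtotal
  f3max <- epio_gate(100, p)
  expect_equal(A, (p$p_ARFbasal + f3max * p$p_ARFauxin) / p$d_ARF,
               tolerance = 1e-2)
  ## YUCCA4 induction restricted to the stele
  st <- step_feedback_expression(0, 0, 0, 1e6, 100, 100, is_stele = FALSE,
                                 in_mz = FALSE, dt, p, mode = "direct")
  expect_equal(st$YUCCA4, 0)
})

test_that("TOLS2 production, diffusion and the IAA multiplier behave as specified", {
  p <- default_parameters()
  ## wild-type baseline: no TOLS2 means multiplier 1
  expect_equal(iaareg(0, 50, p), 1)
  ## high TOLS2 with low free ARF raises the multiplier above 1, which
  ## lowers free ARF on re-evaluation
  m <- iaareg(500, 5, p)
  expect_gt(m, 1)
  expect_lt(free_arf_qss(50, 300, p, IAAreg = m), free_arf_qss(50, 300, p))
  ## own free ARF protects: multiplier decreases with ARFfree
  expect_gt(iaareg(500, 5, p), iaareg(500, 500, p))
  ## no production without free ARF
  t2 <- step_tols2(c(0, 0, 0), ARFfree = c(0, 0, 0),
                   neighbours = list(2L, c(1L, 3L), 2L), dt = 10, p)
  expect_equal(t2, c(0, 0, 0))
  ## pure diffusion conserves total TOLS2
  p0 <- default_parameters(p_TOLS2 = 0, d_TOLS2 = 0)
  x <- c(100, 0, 0)
  for (i in 1:1000)
    x <- step_tols2(x, c(0, 0, 0), list(2L, c(1L, 3L), 2L), dt = 10, p0)
  expect_equal(sum(x), 100, tolerance = 1e-9)
  expect_true(all(x > 0))
})

test_that("regulatory states remain finite and non-negative at the default step", {
  p <- default_parameters()
  ## stiffness check: extreme inputs at dt = 0.4 s stay bounded
  AUX1 <- LAX3 <- YUCCA4 <- ARF <- EpiO <- 0; Diff <- 0
  for (i in 1:10000) {
    bl <- step_baseline_expression(AUX1, Diff, auxin = 1e4, in_mz = FALSE,
                                   dt = 0.4, p)
    AUX1 <- bl$AUX1; Diff <- bl$Diff
    fb <- step_feedback_expression(LAX3, YUCCA4, ARF, signalling = 1e4,
                                   Diff, EpiO, TRUE, FALSE, 0.4, p, "epio")
    LAX3 <- fb$LAX3; YUCCA4 <- fb$YUCCA4; ARF <- fb$ARFtotal
    EpiO <- step_epio(EpiO, 1e4, 0.4, p)
  }
  vals <- c(AUX1, LAX3, YUCCA4, ARF, EpiO, Diff)
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= 0))
  expect_lte(max(AUX1, LAX3, YUCCA4, Diff), 100 + 1e-6)
  expect_lte(ARF, 300 + 1e-6)
  expect_lte(EpiO, 100 + 1e-6)
})
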