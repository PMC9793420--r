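---
title: "Model and methods: auxin-driven priming and stable prebranch-site formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rootpriming)
```

# Overview

`rootpriming` simulates an *Arabidopsis* root tip as a coupled multiscale
system: a 2-D grid-level auxin transport field, per-cell gene-regulatory
ordinary differential equations, a slow chromatin open-state variable that
temporally integrates auxin signalling, peptide-mediated lateral inhibition,
and cell growth/division dynamics on a constant-sized domain. The purpose is
mechanistic: to show how transient, oscillatory auxin elevations in
pericycle cells at the start of the elongation zone ("priming") can be
converted into a stable, spatially narrow auxin-signalling maximum — a
prebranch site (PBS) — through the combination of (i) temporal integration
of the priming signal by a chromatin state and (ii) a delayed positive
feedback that raises auxin signalling capacity (ARF), auxin import (LAX3)
and auxin synthesis (YUCCA4) only in cells whose chromatin state passed a
threshold.

# Tissue representation

The root tip is laid out on a rectangular grid (2 µm spacing). Grid points
are cell interior, cell membrane, cell wall, or outside. Cells are
rectangles of grid points whose perimeter ring is membrane; single-point
wall lines separate adjacent cells. Files run, outside-in: lateral-root cap,
epidermis, cortex, endodermis, pericycle and vasculature, mirrored around a
centre vasculature file; a static cap template of columella, quiescent
centre and lower lateral-root cap cells occupies the tip. The full-scale
domain is 141 × 1516 points (282 × 3032 µm); shrunken geometries
(`geometry_spec()`) preserve the file layout and scale the zonation
boundaries proportionally.

Zonation is superimposed by distance from the tip: meristem up to 514 µm
(transition zone from 364 µm, growing but non-dividing), elongation zone
beyond, and differentiation zone once a cell's differentiation factor
exceeds 85. The lateral-root cap matures faster (meristem end at 314 µm) and
its cells are shed beyond that point. Because the domain is constant-sized,
cells displaced past the top are culled.

Column widths per file and the staircase shape of the cap template are
proportioned after published root-tip model layouts; they are structural
choices, not fitted quantities.

# Auxin transport

Every cell point carries auxin concentration (arbitrary units). The field
obeys production, first-order degradation (cell points), intracellular and
wall diffusion, and carrier-mediated membrane transport:

* efflux (membrane → wall): `(eff_basal + p_PIN · PINmem) · c_mem`, with
  `PINmem` the product of a per-face prepattern weight and the constant
  cellular PIN expression (100);
* influx (wall → membrane): `(inf_pas + p_AUXLAX · (AUX1mem + LAX3mem)) ·
  c_wall`, with membrane carrier levels the product of prepattern weight and
  the cell's dynamic AUX1/LAX3 expression.

Prepattern weights per cell type, zone and face encode the root's polar
transport circuit: rootward PIN in the stele, shootward PIN in epidermis and
lateral-root cap, strong inward transitions in elongation-zone endodermis,
cortex and epidermis combined with weakened stele rootward transport there
(so the returned auxin pools into the loading zone at the elongation-zone
start instead of being flushed back into the meristem), and more apolar
endodermal/cortical patterns in the differentiation zone, where vasculature
hands auxin over to the pericycle and pericycle/endodermis recycle it.
Moderate rootward components keep the distal differentiation zone draining
gently, so auxin in non-primed cells declines with distance while still
fuelling the secondary signalling rise of locked prebranch-site cells.

Production per point is `p_auxin_baseline · (celltypefactor + yucca4factor ·
YUCCA4)`, normalized by cell height so a cell's total production is
height-independent. `celltypefactor` is 100 for the quiescent centre, top
columella layer and vascular initials, 50 for lower columella, 30 for the
lateral-root cap, and 1 elsewhere. `yucca4factor` is calibrated so maximum
YUCCA4 expression (100) raises production 16.25-fold.

Boundary conditions mimic the rest of the plant: walls above the topmost
vascular, pericycle and endodermal cells receive an inflow proportional to a
constant external auxin level times the efflux capacity of the topmost cell;
walls above the topmost epidermal and cortical cells lose wall auxin at 10%
of the topmost cell's influx capacity. A weak radial exchange between
laterally mirrored wall points, scaled inversely with the pair's radial
distance, emulates the 3-D nature of the real root; a variant extends it to
cell points weighted by each point's efflux:influx ratio.

## Numerical scheme

The transport equation is advanced with an alternating direction
semi-implicit scheme: explicit application of production, radial and
boundary terms, then two backward-Euler sweeps, implicit along rows and then
along columns (Thomas tridiagonal solves). Diffusion and membrane-transport
terms belong to the sweep of their direction; degradation to the column
sweep. The flux-form discretization conserves mass exactly in a closed
system, and the implicit treatment is unconditionally stable and
positivity-preserving, which matters because membrane transport rates (up to
~10 s⁻¹) would destabilize explicit stepping at the default Δt = 0.4 s.
Defaults are Δt = 0.4 s and Δx = 2 µm. The scheme is first-order in time,
and the membrane-transport terms are stiff relative to any practical step
(rates up to ~10 s⁻¹), so the step-size dependence is appreciable: halving
Δt from 0.2 s to 0.1 s changes a developing transient field by about 8% in
mean relative terms and a similar amount at the worst grid point (adjacent
to the strongest source); a regression test guards stated bounds of 10% and
15%. The scheme is chosen for robustness — unconditional stability,
positivity and exact mass balance under stiff transport — rather than
high-order accuracy. Long scenario runs in this package use Δt = 2 s:
per-point values there carry discretization error of that order, but the
emergent quantities the analyses use (priming period, cohort structure,
selection outcomes) are calibrated and tested at that same fixed step.

# Auxin signalling

In the baseline model auxin signalling equals the cellular auxin level. The
feedback models add an inducible generic ARF: AUX/IAA is taken at its
quasi-steady state given its production (`pIAA · IAAreg`) and basal plus
auxin-dependent (TIR1/AFB-mediated) degradation, and free ARF follows from
the ARF–AUX/IAA binding equilibrium,

```
IAA*     = pIAA · IAAreg / (d_IAAbasal + dIAATIR1 · auxin)
ARFfree  = ARFtotal · unbind / (unbind + bind · IAA*)
```

Total signalling is the auxin level plus the added capacity times its
utilised fraction — i.e. plus free ARF. The exact algebraic form of this
"capacity × utilisation" term was an open choice; the implemented form
satisfies all qualitative constraints (zero added signalling without
expressed ARF, ≈ zero at zero auxin, monotone in capacity, maximum added
signalling equal to the ARF ceiling of 300).

# Gene expression

All genes use production–degradation ODEs advanced by forward Euler on the
same clock as the PDE. Degradation rates lie in 1.0–1.5 × 10⁻⁴ s⁻¹
(half-lives 1.3–1.9 h), and maximum production is 100-fold degradation, so
levels saturate at 100 — except ARF (maximum 300, baseline 10) and the
TOLS2 production:degradation ratio of 1000, which compensates for its
production in few cells and diffusion into many.

* AUX1: auxin-induced (half-saturation 75; the symmetry-breaking experiment
  raises it to 85), expressed everywhere.
* Differentiation factor: constant production outside the meristem, decay
  everywhere (enabling dedifferentiation); crossing 85 ends elongation and
  marks the differentiation zone. Auxin-dependent LAX3/YUCCA4/ARF induction
  is only permitted beyond level 80.
* LAX3: constant (40) in the baseline model; in the direct-feedback model
  basal plus auxin-induced production; in the time-integrated model the
  induced part splits into an ungated vascular term and a chromatin-gated
  priming term.
* YUCCA4: auxin-induced, restricted to vasculature/pericycle outside the
  meristem; feeds back on auxin production.
* ARF: baseline plus auxin-induced production (restricted to outside the
  meristem), gated like LAX3/YUCCA4.

# The chromatin integrator (EpiO)

EpiO represents the open-chromatin state of an unspecified priming-response
locus:

```
dEpiO/dt = open_EpiO · F1(S) − close_EpiO · max(frac_min, (1−F1(S)) · (1−F2(EpiO))) · EpiO
```

`F1` is a Hill function of signalling (half-max `Km_EpiO_1`); closing is
inhibited both by signalling and by the open state itself (`F2`), never
dropping below `frac_min` of the maximum closing rate. At saturating
signalling the steady state is `open_EpiO / (close_EpiO · frac_min) = 100`.
A sigmoidal gate `F3(EpiO)` (half-max `Km_trans`) multiplies the
auxin-induced production of LAX3 (priming part), YUCCA4 and ARF in the
time-integrated model.

The Hill exponents, rates and thresholds of the chromatin module are not
independently identifiable from first principles; they were calibrated, as
the model's own parametrization procedure prescribes, against the simulated
auxin gradient and its priming excursions so that (i) chromatin opening
responds selectively to the strongest priming excursions (cohort-top peaks
around 230 a.u. on the test geometry) and not to the runner-up peaks
(~200–225) nor to the post-priming baseline, (ii) a 10% reduction in auxin
content leaves every cell below the opening threshold, and (iii) the slowly
declining signalling of non-primed differentiation-zone cells can never
ignite the feedback, however long they reside there. The resulting defaults
are `open_EpiO = close_EpiO = 10⁻²`, `frac_min = 0.01`, `Km_EpiO_1 = 210`
(Hill 6), `Km_EpiO_2 = 1` (Hill 4), `Km_trans = 10` (Hill 6). In this regime
the integrator has a genuine ignition threshold: for signalling with
`F1 < ~0.36` the closed state is a stable equilibrium (no accumulation, ever
— this is what makes the selectivity robust against slow signalling creep),
while supra-threshold signalling must persist for tens of minutes to carry
EpiO through the unstable point, after which the open state persists with a
half-life of about two hours — long enough for the differentiation gate to
open and the ARF/LAX3/YUCCA4 feedback to lock in strongly primed cells,
and short enough that a brief excursion decays back before locking. The
chromatin rates are deliberately faster than the gene-expression decay
family: the integration window must match the pulse durations of the
geometry being simulated (fixture priming pulses last one to three hours),
and the rates scale down accordingly for full-scale runs.

# Lateral inhibition (TOLS2)

TOLS2 peptide production saturates in free ARF, decays first-order, and
diffuses cell-to-cell on the adjacency graph. Its signalling raises AUX/IAA
production through

```
IAAreg = 1 + p_IAA_TOLS2 · H(TOLS2; Km_IAA_1) · Km_IAA_2 / (ARFfree + Km_IAA_2)
```

so high local free ARF protects a cell from its own peptide while
neighbouring cells with lower free ARF are repressed — the shootward, weaker
of two nascent prebranch sites loses.

# Growth, division and the constant domain

Cells carry a continuous length updated exponentially at per-micrometre
rates: `ln 2 / cellcycle` (9 h) in the meristem (the transition zone uses
the same rate unless overridden), `1 / expansion_duration` (7 h) in the
elongation zone, zero after differentiation. When the continuous length
exceeds the integer grid length by one, a grid row is inserted at the cell's
mid-height, duplicating the local auxin concentration (no dilution; the
elongation-zone no-dilution assumption extends naturally to this choice).
Meristem-proper cells divide on doubling their birth length; the rows are
split (rootward daughter takes the remainder) and a new wall row is inserted
between the daughters. Division rates are staggered deterministically by the
cell-centre coordinate at birth (`mean_j %% 3` → ±5%), avoiding artificial
whole-meristem synchrony without any random number generator: the entire
simulator is bit-reproducible.

# Scenario presets

Each in-silico experiment is a named preset differing from baseline only in
its stated fields: feedback variants (`baseline`, `direct_feedback`,
`epio`), lateral inhibition (`tols2`), symmetry breaking (10% AUX1 asymmetry
plus AUX1 Km 85), dosage (`low_auxin`: auxin content × 0.9; `potent_arf7`:
ARF maximum halved, boundary influx × 1.4; `homeostasis`: influx × 1.4 plus
ARF-dependent auxin degradation), the apolar-DZ PIN variant, and the
no-growth pulse experiment (growth off, chromatin opening blocked in the
first 100 µm of the elongation zone, an imposed 250 a.u. × 3 h auxin pulse
in the shootward elongation zone).

Interpretation choices on the perturbations, made once and kept: "root tip
auxin content" scaling multiplies all production rates and the external
boundary auxin; the potent/arf7 "influx increased by 40%" applies to the
shootward boundary inflow; the homeostasis variant multiplies auxin
degradation by `1 + k_h · max(0, ARFtotal − 10)/300` in cells with induced
ARF; the AUX1 asymmetry reduces AUX1 production on the left pericycle and
vasculature files.

The no-growth pulse experiment needs two further operational choices.
Without growth there is no advective loss through the domain top, so the
stationary auxin-loading pool is hotter and much wider than in the growing
root; chromatin opening is therefore blocked from the elongation-zone start
up to the distal band used for the imposed signal (rather than only the
first 100 µm), which is the same reasoning the blocking exists for at all —
preventing spurious activation by the stationary pool. The imposed pulse
clamps auxin up to its amplitude in the pericycle cells of a one-cell-deep
band placed where the no-growth baseline sits well below the opening
threshold (950–1050 µm beyond the meristem end, zone-scaled); clamping a
wider band lets the clamped cells pool each other's efflux past the
threshold regardless of the imposed amplitude, which would defeat the
dose-dependence the experiment probes. With these choices a 250 a.u. × 3 h
pulse ignites a persistent secondary response, while a 150 a.u. pulse never
crosses the opening threshold and a 250 a.u. × 15 min pulse opens the gate
too briefly for the feedback to lock.

Growth-on feedback scenarios start with the feedback tier held in baseline
mode (`feedback_start_h`, 24 h in the packaged analyses) so that the initial
cell cohorts — whose auxin histories reflect the arbitrary initial state
rather than steady priming — cannot ignite the feedback and flood their
successors; competition for stable sites then starts from the converged
priming regime.

# What the test geometry shows — and what it does not

Development and testing use a proportionally shrunken geometry (61 × 220
points, zone boundaries scaled by 0.25) so that multi-day dynamics run in
minutes. Growth-driven displacement speeds scale with the amount of growing
tissue below a cell, so zone proportions and the reflux architecture are
preserved without rescaling any rate constant. On this geometry the model
reproduces, qualitatively, the full chain: reflux-driven auxin loading at
the elongation-zone start (stele concentrations of ~140–175 a.u. against a
transition-zone valley of ~50–65), recurring priming bands (about five
pericycle cells per event, event peaks alternating around 205–230 a.u.,
period ≈ 2 h per cell and ≈ 7 h per event), selective chromatin opening in
the most strongly primed pericycle cell of each event with a partial
response in the runner-up, a delayed and then persistent secondary
auxin-signalling rise in the winners (induced ARF near its ceiling of 300),
its complete abolition at 10% lower auxin content, and TOLS2-mediated
repression of the runner-up's response while the winner's lock persists.

One positional feature departs from the reference behaviour: on the fixture
the repressed, weaker partner of each event lies rootward of the persisting
winner (the winner is the earlier-crossing, hence more shootward, cell),
whereas the reference dynamics repress a shootward weaker site. Which side
of an event wins depends on the fine structure of growth-driven size
variation at elongation-zone entry and evidently differs at fixture scale;
the inhibition mechanism itself — protection by a cell's own free ARF,
repression of the low-free-ARF partner — behaves identically.

Quantities tied to the full-scale geometry do not transfer: the number of
cells per priming event scales with the meristem's cell flux (about ten at
full scale, a fraction of that on the fixture), absolute distances (500 µm
trace start, 1000 µm comparisons) map through the zone-scale factor, and
run durations differ. Tests therefore assert the mechanism (ordering,
selectivity, presence/absence of responses) at fixture scale and the
analytic quantities exactly; they do not claim full-scale numeric
reproduction. Problem sizes used by the test suite: fixture tissue
(61 × 220), runs of 24–60 simulated hours at Δt = 2 s, and a miniature
27-column tissue for solver-level checks at Δt = 0.4 s.

# Numerical and design choices

* Initial state: auxin zero everywhere; genes at plausible baseline (AUX1
  50, LAX3 40, ARF 10, EpiO 0); the differentiation factor is seeded with a
  distance ramp beyond the elongation-zone start so distal cells begin
  differentiated. The first ~15–20 h of a growth-on run are burn-in: the
  initial cell cohorts carry transient auxin histories and analyses window
  past them (trace filters use crossing time > 20 h in long runs).
* Decay acts on cell points only; walls lose auxin through influx and the
  shootward boundary.
* Negative concentrations are clipped to zero and counted; the implicit
  scheme does not produce them at the default step.
* Event ordering in a step: signalling evaluation → PDE step → gene/EpiO/
  TOLS2 Euler step → growth → row insertions → divisions → zone
  transitions → culling/shedding. Zone re-evaluation is full after any
  geometry change and threshold-only otherwise.
* Division tie-break: odd row counts give the extra row to the rootward
  daughter.
* The kymograph line is the middle column of the left pericycle file,
  sampled every 100 s; the "experimental" style anchors a differentiated
  cell at a fixed horizontal position and pads the domain as the root grows.
* The stable-PBS criterion (a secondary response exceeding the cell's
  pre-differentiation priming peak, with final-window signalling staying
  above that peak) is an operationalization; the narrowing summary
  thresholds are exposed arguments.

# Known limitations

* Parameter values are reconstructed from stated constraints and
  calibration, not copied from a published table; absolute concentrations
  are arbitrary units and only relative behaviour is meaningful.
* The staggered-cell-wall variant, differential per-file elongation-zone
  onsets, mechanics of symplastic growth, and root bending are not
  modelled.
* Lateral inhibition uses a single peptide proxy; no ARF/IAA dimerization
  or ARF-dependent AUX/IAA feedback.
* The fixture-scale priming cohort is about five cells, not ten — the
  cohort size scales with the meristem's cell flux, which the shrunken
  geometry reduces; full-scale runs reproduce the architecture but need
  multi-hour wall-clock times.
* Because the chromatin integrator is operated in its threshold regime on
  the fixture (required for dosage selectivity at this scale), normalized
  chromatin-state differences between a primed cell and a 75%-input
  reference are amplified far beyond twofold rather than matching the
  graded reference values; the amplification property holds, the printed
  magnitudes do not transfer.
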