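---
title: "Methods: regional ventilation distribution and respiratory mechanics during assisted spontaneous breathing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional ventilation and mechanics during assisted breathing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peepflow` quantifies how PEEP redistributes tidal volume during
neurally adjusted ventilatory assist (NAVA), combining per-breath
respiratory mechanics from pressure/flow waveforms with regional
ventilation from electrical impedance tomography (EIT). This vignette is
the package's account of the science: the models, the parameters that
matter, what the synthetic generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The measurement model

**Breaths.** Spontaneous breathing is segmented on the flow signal
alone: inspiration starts at a positive-going crossing of a small flow
threshold (default 0.02 L/s) sustained for at least 0.08 s, expiration
at the subsequent negative-going zero crossing, and the breath ends at
the next inspiration onset. The hysteresis rejects sensor noise at the
rapid rates seen at ZEEP (up to ~90/min) without missing short
inspirations; incomplete leading/trailing breaths are discarded because
both the mechanics fit and the tidal impedance change need full cycles.
An Edi-based (neural) cycle criterion is deliberately not implemented:
flow-based detection is self-contained and testable against analytic
zero crossings. Per acquisition the first three complete breaths are
analyzed, matching the 1-minute steady-state acquisition convention.

**Mechanics.** Transpulmonary pressure is P_TP = P_AO − P_ESO sample by
sample. Per breath, ordinary least squares fits the single-compartment
equation of motion P_TP(t) = V(t)/C + R·V̇(t) + P0 over the full cycle
(inspiration plus expiration; an inspiration-only window is available
via a flag). The model includes the intercept P0: breaths start from a
non-zero end-expiratory distending pressure at PEEP, and the
conventional multilinear method carries it. Volume enters the
regression in litres so R comes out in cmH₂O·s/L, while C is reported
in ml/cmH₂O; the conversion is centralized and tested. Because P_TP
(not P_AO) is regressed, the fitted resistance is physically the
lung/airway component; the field's label "respiratory-system
resistance" is nevertheless kept for the output column, since that is
how the quantity is conventionally reported in this protocol. Fits with
a non-positive volume coefficient are flagged `rejected` and excluded
from aggregates rather than silently dropped.

The maximum transpulmonary pressure of a breath is referenced to
end-expiratory esophageal pressure: with ΔP_ESO the esophageal change
from end-expiration to the moment of maximum P_TP,
P_TP max = (P_AO − ΔP_ESO) at that moment, and the resistive-corrected
"true" maximum is P_TP,true max = P_TP max − R·V̇ at that moment. The
correction matters because the animals breathe continuously with no
inspiratory hold, so flow — and hence a resistive pressure component —
is present at the P_TP maximum. End-expiration is taken as the last
sample before the inspiration onset of the analyzed breath, the natural
reading of "esophageal pressure at end-expiration" for a breath whose
maximum lies in the following inspiration.

**EIT.** The 32×32 relative-impedance image is split into four
equal-height horizontal bands, anterior to posterior. Equal bands over
the full grid (no lung mask by default) are the vendor-software
convention; they keep the extreme bands partly extra-pulmonary, which
is why anterior and posterior proportions are small single digits. A
pixel mask can be supplied for both the frame path and the partition.
Per breath, the end-expiratory frame is the global-Z minimum within
±0.2 s of the flow-defined inspiration onset (reconciling the 50 Hz EIT
clock with 200 Hz flow timing without assuming perfect synchrony) and
the end-inspiratory frame is the global-Z maximum within the breath.
ΔZ per ROI is the difference of mean Z between those frames;
proportions are each ROI's share of the total; the dependent fraction
of ventilation is

DFV (%) = 100 · (ΔZ mid-posterior + ΔZ posterior) / ΔZ total.

DFV is unit-free under any common rescaling of the four ΔZ values
(tested as an invariant), which is what makes arbitrary device units
usable. Negative regional ΔZ (paradoxical, pendelluft-like) is reported
with a flag rather than clamped, so proportions can exceed 100/fall
below 0 in that case and the signal is preserved. A breath with total
ΔZ ≤ 0 is a degenerate breath: an error at the operator level, a logged
exclusion at the pipeline level.

**Titration.** The selected PEEP minimizes |DFV − 50|; ties break
toward the lower PEEP (the less injurious choice at equal homogeneity).
The dependent-minus-non-dependent difference curve crosses zero at the
same homogeneity point; its sign convention is negative = predominantly
non-dependent.

**Statistics.** Comparisons are routed by Shapiro–Wilk (on paired
differences for paired data) at α = 0.05: any rejection routes to the
nonparametric test — Wilcoxon signed-rank for paired data, Mann–Whitney
otherwise — else Student's t. The signed-rank p-value is exact for up
to 25 non-zero differences: the full distribution of the positive-rank
sum over all sign assignments is built by convolution on the grid of
doubled ranks, which stays exact with midranks (ties). Beyond that a
normal approximation with tie and continuity correction is used. Zero
differences are dropped before ranking (Wilcoxon's original treatment;
the policy is the standard reproducible choice). All tests are
two-sided. The Bonferroni family defaults to m = 15, the number of
unordered pairs among the six PEEP levels of one ladder direction,
giving the 0.05/15 ≈ 0.0033 decision threshold; m is configurable
because the exact comparison family behind a published threshold is
rarely enumerated. Incremental and decremental phases are never pooled;
paired comparisons pair animals with themselves (each animal is its own
control).

## The synthetic generator

No public dataset accompanies this protocol, so the generator is a
first-class, tested module that produces complete protocol datasets:
NAVA-assisted breathing waveforms plus EIT sequences for each animal at
each ladder step (0, 3, 6, 9, 12, 15, 12, 9, 6, 3, 0 cmH₂O; 1 min per
step).

**Breathing model.** A single compartment obeys
R_aw·V̇ = P_vent + P_mus − V/C_rs, integrated with fixed-step classical
RK4 at 200 Hz (implemented in C++; the half-sine neural drive is
evaluated analytically at half-steps). Neural drive Edi is a half-sine
burst; the ventilator delivers P_vent = NAVA-level × Edi above PEEP
while Edi exceeds the 0.5 µV trigger (the NAVA principle), and the
inspiratory muscles add P_mus = k_edi × Edi. Esophageal pressure
combines chest-wall recoil and muscle pressure,
P_ESO = offset + V/C_cw − P_mus, so the emitted P_TP identity
P_TP = const + R_aw·V̇ + V/C_lung holds by construction and the
transpulmonary fit must recover C_lung and R_aw — the pipeline-vs-truth
oracle used throughout the tests.

**Calibration is closed-form, against the study conditions.** As PEEP
rises 0 → 15 cmH₂O: respiratory rate falls linearly 75 → 38 /min and
the tidal volume target rises 153 → 297 ml (the post-lavage
rapid-shallow → slow-deep pattern); peak airway pressure 6.6 → 23.5
cmH₂O fixes the Edi amplitude through the NAVA gain (2.3 cmH₂O/µV),
since peak P_AO = PEEP + NAVA-level × Edi peak; lung compliance rises
linearly 14.5 → 26.9 ml/cmH₂O. Because the ODE is linear in the drive,
the muscle gain k_edi that meets the tidal volume target is solved
exactly from two unit-drive simulations — no iterative tuning. Fixed
defaults: R_aw = 8 cmH₂O·s/L and C_cw = 100 ml/cmH₂O, typical values
for a ~28 kg pig with an endotracheal tube; end-expiratory esophageal
offset −2.5 cmH₂O.

**Regional model.** The dependent volume fraction follows a logistic in
PEEP, f(PEEP) = f_min + (f_max − f_min)/(1 + e^{−(PEEP−p50)/w}), with
defaults f_min = 0.23, f_max = 0.69, p50 = 8.5 cmH₂O, w = 5 cmH₂O —
solved once from the anchors f(0) = 0.30, f(9) ≈ 0.47, f(15) ≈ 0.59 and
not revisited. The split is applied to volume, not pressure. The
extreme-band shares (anterior within non-dependent, posterior within
dependent) interpolate linearly in PEEP between the shares implied by
the anchor ΔZ patterns, keeping anterior/posterior proportions at the
observed few percent. ROI traces are gain × regional volume + baseline
+ Gaussian noise (default gain 0.1 AU/ml, equal across ROIs — DFV is
gain-invariant only under common scaling, and per-ROI gains exist as a
config field precisely to exercise that caveat). Frames, when
requested, paint each band uniformly so the frame-stack and trace paths
are exactly equivalent downstream.

**Cohort heterogeneity.** Animal-level random effects: multiplicative
lognormal on compliance (sdlog 0.15), tidal volume target (0.20),
respiratory rate (0.17), resistance (0.15) and Edi amplitude (0.15);
additive Gaussian on the dependent fraction (SD 0.07) and esophageal
offset (SD 1.5 cmH₂O). These produce cohort spreads of the magnitude a
10-animal lavage experiment shows, which is what the statistics module
needs to be exercised meaningfully. Channel noise defaults: 0.1 cmH₂O
on pressures, 0.005 L/s on flow, 0.02 AU on EIT traces.

**What the generator does not emulate.** Within-animal breath-to-breath
variability (cycle timing is constant within an acquisition),
two-compartment pendelluft dynamics, gas exchange, cardiogenic
oscillations on the EIT signal, electrode-plane movement with lung
inflation, and EIT reconstruction artefacts. Passing tests on generator
output therefore demonstrate that the measurement chain is correct and
self-consistent — not that it is robust to every artefact of real
recordings. The true within-animal PEEP dependence of Edi amplitude is
unknown; the linear interpolation between the pressure-derived
endpoints is a modelling choice of this package.

## Numerical choices

- Integration of flow to volume is trapezoidal (pneumotachograph
  post-processing convention); volumes in ml.
- The mechanics fit uses QR least squares; a rank-deficient design
  (flow collinear with volume) is a hard error, and the test suite pins
  the fit to an explicit normal-equation oracle at 1e-9.
- Display rounding of proportions is to the nearest whole percent, half
  away from zero (`round_half_up()`); internal values keep full
  precision.
- Time grids must be uniform to 1 part in 10⁶; Edi is never resampled
  implicitly.
- Clock alignment defaults to declared-offset 0 (simultaneous
  acquisition); cross-correlation alignment scans frame-period lags of
  the global Z against integrated flow within ±2 s and is opt-in, since
  how the original 200 Hz and 50 Hz streams were time-locked is not
  public.
- Random sub-seeds and all simulation draws come from one seeded R
  stream: identical config + seed gives bit-identical datasets.

## Problem sizes in the test suite

The suite exercises the full default protocol — 10 animals × 11 steps ×
60 s at 200 Hz waveforms / 50 Hz EIT traces (330 analyzed breaths, 660
scans) — which generates and analyzes in a few seconds. Property checks
use 20–100 simulated breaths for mechanics recovery, 50 random paired
samples (n ≤ 12) against the exhaustive 2ⁿ signed-rank oracle, and
2,000 null replicates for the routed pipeline's type-I error. Frame
stacks are kept to short sequences in tests; cohort-scale EIT uses the
trace representation.

## Limitations

The package analyzes; it does not reconstruct EIT images or speak any
vendor format — converters to the documented CSV layouts are the user's
responsibility. The dependent/non-dependent dichotomy assumes supine
posture. The equation-of-motion fit assumes linear single-compartment
mechanics within a breath; in severe inhomogeneity the fitted C and R
are effective values. The resistive correction of P_TP max uses the
same breath's fitted resistance, so a rejected fit also removes the
corrected pressure for that breath. Center-of-ventilation,
impedance-ratio and pixel-level overdistension/collapse titration
indices are out of scope.
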