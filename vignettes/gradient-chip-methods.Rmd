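---
title: "Models and methods behind gradchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gradchip models a two-inlet hydrogel microfluidic chip that screens a pair
of drugs against 3D tumour spheroids. Seven parallel culture channels
(microwell columns A–G, left to right) connect two inlet reservoirs to one
outlet; a thin *laminar flow distribution layer* (the "gap") between the
glass lid and the hydrogel admits single cells and drugs but retains grown
spheroids. Dosing the left inlet with temozolomide (TMZ, 600 µM) and the
right inlet with the NF-κB inhibitor BAY 11-7082 (10 µM) creates opposed
concentration gradients, so each column receives a different dose *pair*
from a single experiment. This vignette records the models, the
calibrations, and the design decisions taken where the platform leaves
choices open.

## 1. Hydraulics: perfusion and gap-depth estimation

The chip is modelled as a resistance network: two wide, hydraulically
negligible feed ports from the inlets to a common manifold; seven
rectangular culture channels in parallel from the manifold to the outlet;
and the gap layer as one wide slit spanning the footprint, in parallel with
the channels (it overlies the whole hydrogel — the simplest topology
consistent with the chip cross-section). Every segment uses the wide-duct
approximation

$$R = \frac{12\,\mu L}{w h^{3}\,(1 - 0.63\,h/w)},$$

accurate to a few percent at the relevant aspect ratios and exact in the
slit limit. Flows solve Kirchhoff's node balance with $Q = \Delta P / R$
per edge; pressures are solved internally as offsets from the inlet head so
that the tiny pressure drop across the feed ports is not lost to floating-
point cancellation (interior node imbalance stays below $10^{-12}$ of the
inflow).

The driving pressure during the perfusion measurement is the hydrostatic
head of the chip tilted at 45° with a 30 mm in-plane inlet–outlet
separation, $\Delta P = \rho g \,\Delta\ell \sin\theta \approx 208$ Pa;
reservoir draw-down is neglected (quasi-static).

Two calibration anchors pin the free dimensions:

* **Channel depth, 87 µm.** The channel cross-sections are not published.
  The depth is calibrated once so that the channel-only network (gap fully
  crosslinked, i.e. depth 0) reproduces the measured 0.12 mL/min perfusion
  at the 45° head. Width (500 µm), length (20 mm), pitch (1.5 mm) and well
  dimensions (400 µm diameter, 300 µm deep, six per column) are plausible
  stand-ins exposed in the configuration.
* **UV irradiance, 20 mW/cm².** Forced by the published 32 s ↔ 640 mJ/cm²
  equivalence.

`estimate_gap_depth()` inverts the strictly monotone forward model
`predict_perfusion()` by bracketing on $[0, 500]$ µm to $10^{-3}$ µm. The
published depths (57.3/92.6/106.6/162.1 µm) serve as *probe points* for
round-trip validation only: the original device's exact geometry and
inversion model are unpublished, so blind reproduction of those depths is
not a meaningful target, and the forward model indeed predicts different
absolute rates at those depths than were measured. The exposure-time to
depth relation itself is purely empirical: a Hyman-filtered monotone cubic
through the measured pairs, refusing extrapolation, with no
photopolymerisation kinetics.

## 2. Transport: the two-drug column gradient

The gradient forms in the gap layer, which is thin (≈93 µm) relative to
its lateral extent (10.5 × 20 mm), so transport is modelled depth-averaged
in 2D. The domain is the chip footprint; the inlet edge is split at the
centreline between the two drug streams, the opposite edge is the outlet,
and the side walls are no-flux. For this rectangle with uniform depth the
exact Hele-Shaw flow is uniform plug flow down the axis, and the face-flux
field is constructed directly (exactly divergence-free; each column-pitch
strip carries exactly 1/7 of the flow, matching the network's equal channel
flows). Unequal inlet flows are outside this construction and are rejected.

Each drug's steady fraction field solves
$\nabla\!\cdot\!(\mathbf{u}c) = D\nabla^2 c$ by a finite-volume scheme:
first-order upwind advection with central diffusion, one sparse direct
solve per drug. Upwinding is monotone, so the discrete maximum principle
holds and fractions stay in $[0,1]$ to round-off — a property worth more
here than formal order, because the downstream consumer is a bounded dose
map. Upwind numerical diffusion acts only *along* the flow (where gradients
are negligible); the lateral gradient that sets the column doses is
resolved by the second-order central operator, which is why column
fractions move by well under one percentage point when the grid is halved
from the default 50 µm to 25 µm cells.

Microwells are dead-ended: at steady state they equilibrate diffusively
with the channel above, so a column's fraction is the mean over its well
cells. Doses are fractions times the inlet concentrations.

**Péclet calibration.** Inlet flow rate and diffusivities of the original
finite-element simulation are unpublished. Both drugs get the generic
small-molecule diffusivity $5\times10^{-10}$ m²/s, and the dosing flow is
calibrated *once, in closed form*: a step profile advected a distance $L$
at speed $v$ spreads laterally as
$c = \tfrac12\,\mathrm{erfc}\!\big(x / (2\sqrt{D L / v})\big)$, and
matching the published 82% fraction at the third column (1.5 mm off-centre,
wells centred 10 mm downstream) gives a spread of 1.15 mm, i.e.
$v = 3.77\ \mu$m/s and a dosing flow of $2.198\times10^{-4}$ mL/min
(column-pitch Péclet ≈ 11, length Péclet ≈ 150). This one number is stored
in the default configuration; no per-column tuning exists anywhere. The
solved gradient then lands within 0.6 points of all seven published
fractions, and mirror symmetry forces the central column to exactly 50%
and mirror pairs to sum to 100%.

```{r}
library(gradchip)
sol <- solve_gradient(chip_geometry())   # 210 x 400 cells of 50 um
sol$dose_map
```

## 3. Dose–response, Bliss independence, and the column-wise statistics

Viability follows the four-parameter Hill model
$V(d) = V_0\,(1 - E_{\max}\, d^{n}/(d^{n} + EC_{50}^{n}))$.
`fit_hill()` performs bounded Levenberg–Marquardt least squares
($E_{\max}\in[0,1]$, $EC_{50}$ within a decade of the tested range,
$n\in[0.3,6]$), initialised from the dose-0 mean and the dose nearest
half-maximal response, with an `L-BFGS-B` fallback and a
`non_identifiable` flag for flat responses.

The synergy null is **Bliss independence**,
$e_{AB} = e_A + e_B - e_A e_B$ — chosen over Loewe additivity because the
two drugs act through different mechanisms and share no common dose scale.
Per column, the observed effect is $e = 1 - V/V_{\text{ctrl}}$ against the
pooled same-day untreated control mean; the Bliss expectation evaluates
the two single-drug Hill curves at that column's simulated doses; their
difference is the excess. The edge columns are treated as near-monotherapy
anchors (cross-contamination below 0.5% of the opposite inlet dose is
ignored).

Published reports of this assay mark significance with stars from
unspecified t tests.
The package adopts the safest default for $n=5$ with unequal variances:
the **unpaired two-sided Welch test**, computed directly from summary
statistics ($t = \Delta\bar x / \sqrt{s_A^2+s_B^2}$ with
Welch–Satterthwaite df on the squared SEMs), which is algebraically
identical to the replicate-level test. Raw p-values are reported alongside
Holm-adjusted flags per comparison family (vs column A, vs column G, vs
control). Published summary statistics need not reproduce the original
stars under this choice, and no agreement is forced.

## 4. The synthetic experiment generator

`simulate_viability_experiment()` emulates the 7-column × {day 4, day 7} ×
$n=5$ design. Per day and column: single-drug effects are Hill effects at
the column doses scaled by a day factor (0.5 at day 4, 1.0 at day 7 —
drug effectiveness grows over the week); the combined truth is
$e = e_{\text{Bliss}} + \kappa\, e_A e_B (1 - e_{\text{Bliss}})$, where
$\kappa$ is an invented interaction knob ($0$ = exact Bliss consistency);
replicates are Gaussian with SD 0.10 viability fraction, truncated to
$[0,1]$ — bounded proportions with mean ± SEM reporting, giving column
SEMs around 4.5 points, inside the 2–7 point range typical of this assay.
Default Hill curves are anchored to the published single-agent behaviour:
TMZ $E_{\max}=0.4$, $EC_{50}=250$ µM, $n=1.5$ (≈32% effect at 600 µM);
BAY $E_{\max}=0.28$, $EC_{50}=0.1$ µM, $n=0.8$ (≈27% at 10 µM, nearly
flat across columns D–G as observed). Control viability is 0.92.

What the generator does *not* emulate: spheroid growth and death kinetics,
within-spheroid drug gradients, imaging noise structure, day-to-day
correlation within a chip, or patient heterogeneity. Passing recovery
tests therefore demonstrates that the *analysis chain* is unbiased and
correctly calibrated under its own assumptions — not that real chips obey
those assumptions.

Two quantitative properties of this design are worth stating plainly,
because both are dictated by arithmetic rather than implementation:

* **EC50 identifiability depends on the curve, not just the noise.** The
  fitter-validation study (7 column doses + control, $n=5$, 5-point noise,
  200 seeds) uses a reference curve with $EC_{50}=300$ µM — inside the
  tested range — and near-complete maximal effect ($E_{\max}=0.9$, $n=2$);
  there the EC50 is recovered within 20% in well over 90% of runs. The
  TMZ-anchored default curve, with only 40% maximal effect, is *structurally*
  weakly identified at the same noise (the $E_{\max}$–$EC_{50}$ ridge has
  correlation ≈ 0.96 and recovery drops to ≈ a third of runs). That is a
  genuine property of shallow dose–response data from this assay.
* **The $\kappa$ interaction is bounded.** The synergy increment
  $\kappa\,e_A e_B(1-e_{\text{Bliss}}) = \kappa\,e_A(1-e_A)\,e_B(1-e_B)$
  can never exceed $\kappa/16$ (≈0.019 at $\kappa=0.3$; ≈0.010 at the
  central columns for the anchored effect sizes), while the per-column
  excess estimate carries an SEM of ≈0.05 at the design noise. Per-seed
  significance of the excess in individual columns is therefore
  underpowered by roughly an order of magnitude at $\kappa=0.3$; the
  package reports the excess and its test honestly rather than inflating
  either the interaction model or the noise floor. Null calibration, by
  contrast, is sharp: at $\kappa=0$ the per-column mean excess stays
  within ±0.05 over 200 seeds.

## 5. Numerical choices and problem sizes

* Grid: default 50 µm cells (210 × 400 = 84 000 unknowns per drug; direct
  sparse LU), chosen as the resolution at which halving the spacing moves
  every column fraction by far less than one percentage point. The test
  suite uses 100 µm cells where only structure is under test.
* Transport residual gate $10^{-10}$, tracer-flux conservation gate
  $10^{-3}$ (measured imbalance is at round-off, ~$10^{-14}$).
* Root tolerance of the depth inversion: $10^{-3}$ µm; network imbalance
  gate $10^{-12}$ of inflow.
* Degenerate inputs are errors, not warnings: non-positive dimensions,
  even channel counts under mirror symmetry, non-monotone exposure–depth
  records, extrapolation requests, doses outside $[0,1]$ effect bounds,
  fewer than four dose levels, unknown configuration keys.
* All stochastic paths take explicit seeds; identical configuration and
  seed give byte-identical CSV output (fixed row order and float
  formatting).

## 6. Known limitations

* The chip dimensions not present in the published text are stand-ins;
  absolute hydraulic predictions away from the 0.12 mL/min anchor carry
  that uncertainty (the measured 1.18 mL/min at a 92.6 µm gap vs 0.60
  predicted shows its size). Column *fractions* are robust to this because
  they depend on the advection–diffusion balance, not on absolute
  resistance.
* Transport is steady-state and depth-averaged: no wash-in transients, no
  vertical stratification, no drug uptake or degradation.
* The plug-flow field cannot represent unequal inlet flows or asymmetric
  layouts; symmetric operation is asserted, not simulated around.
* Bliss scoring needs external single-drug reference curves; in the
  pipeline they come from the generator's ground truth (in a real screen,
  from separate monotherapy runs). Fitting both Hill curves from a single
  combination chip is not attempted — the edge columns provide only one
  dose each.
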