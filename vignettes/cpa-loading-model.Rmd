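---
title: "Modelling CPA perfusion loading of whole organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CPA perfusion loading of whole organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kroghcpa)
```

Vitrifying a whole organ requires loading 8–9 M of cryoprotective agent
(CPA) through the vasculature without destroying it on the way: too fast
and osmotic excursions tear the tissue, too slow and the chemical toxicity
of the CPA accumulates. This vignette documents the model this package
uses to navigate that trade-off, the choices made where the underlying
physics or the available data leave the design open, and what the
package's tests do and do not demonstrate.

## The Krogh unit and its observable

The organ is idealised as a large number of identical hexagonal-prism
units in parallel, each a capillary of radius $r_c$ and length $l_c$
surrounded by tissue out to the hexagon apothem $r_k$ (half the
intercapillary distance). Mass exchange happens at the capillary wall —
capillaries dominate the surface-area budget of the vasculature — and the
unit's outer boundary is a symmetry plane, hence fixed. Two geometric
consequences do a lot of work:

* Only part of the tissue participates in osmosis. The osmotically active
  volume is modelled as a smaller hexagonal prism of apothem $r_a$, with
  initial volume $V_0 = l_c(2\sqrt{3}r_a^2 - \pi r_{c0}^2)$. The
  inactive fraction $V_b$ follows from $r_a$.
* Because the outer boundary is fixed, any change in tissue volume is
  taken up by the capillary lumen:
  $r_c(V) = \sqrt{(2\sqrt{3}r_a^2 - V/l_c)/\pi}$. With laminar flow the
  organ's structural resistance scales as $r_c^{-4}$, so *vascular
  resistance is a live readout of tissue volume*. Every resistance the
  package reports is normalised to the stabilised carrier-flush baseline,
  which cancels both the unknown number of units and the capillary
  length.

Transport across the wall follows the Kedem–Katchalsky flux pair (positive
into the tissue), with state variables $(V, n_{cpa})$ and conserved
impermeant amount $n_{is}$:

$$J_v = S L_p\left[(P_f - P_t) - R_g T\left(\Delta C_{is} +
  \sigma \Delta C_{cpa}\right)\right], \qquad
J_{cpa} = S\,\omega R_g T\,\Delta C_{cpa} +
  J_v(1-\sigma)\bar{C}_{cpa},$$

where $\bar{C}_{cpa}$ is the arithmetic mean of the two CPA
concentrations, $S = 2\pi r_c l_c$ the exchange area, and concentrations
are derived as amount over active volume. The capillary fluid is assigned
the arterial inlet composition throughout (no axial depletion), following
the dimensionless-analysis argument that concentration gradients along and
across the capillary relax much faster than the loading dynamics.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| $r_{c0}$ | isotonic capillary radius | 3e-6 | m |
| $r_k$ | Krogh unit apothem | 7.5e-6 | m |
| $l_c$ | capillary length | 55e-6 | m |
| $r_a$ | active-volume apothem | 3.86e-6 | m |
| $L_p$ | hydraulic conductivity | 1.5e-14 | m³/(N·s) |
| $\omega$ | CPA permeability | 7.0e-13 | mol/(N·s) |
| $\sigma$ | reflection coefficient | 0.10 | — |
| $\alpha$ | toxicity exponent | 3.12 | — |
| $\beta$ | toxicity prefactor | 9.39e-6 | min⁻¹·M⁻ᵅ |
| $T$ | temperature | 277.15 | K |
| $M_{iso}$ | isotonic osmolarity | 290 | mol/m³ |

Geometry defaults are rat-kidney capillary morphometry; $r_a$, $L_p$,
$\omega$, $\sigma$ are perfusion-derived estimates and $\alpha$, $\beta$
slice-assay calibrations for the 8.4 M VMP cocktail at 4 °C, treated
throughout as a single permeant species with osmotic coefficient 1.
Internally everything is SI; protocol-facing interfaces use the
experimental conventions (minutes, mol/L, mmHg, mOsm) and convert at the
boundary (1 mmHg = 133.322 Pa, 1 M = 1000 mol/m³). The toxicity integral
is evaluated in minutes and mol/L, the units in which $\beta$'s magnitude
is meaningful.

## Design choices in the transport model

**Membrane area.** Whether $S$ should track the instantaneous lumen
radius is genuinely open: the resistance readout certainly tracks
$r_c(t)$, but the exchange area is endothelial membrane, a material
surface whose area is set by the cells themselves rather than by how far
the lumen happens to be dilated. The package defaults to evaluating $S$
at the isotonic radius (`surface_mode = "fixed"`) on that physical
argument; `"instantaneous"` is available, and the choice moves loading
endpoints by only a few percent (the instantaneous area is larger
whenever the tissue has shrunk, so it loads slightly faster).

**Hydraulic term.** $(P_f - P_t)$ defaults to zero. Perfusion pressure
(40–60 mmHg ≈ 5.3–8 kPa) is three orders of magnitude below the osmotic
pressure scale of molar CPA gradients ($R_g T \cdot 1000\,\mathrm{mol/m^3}
\approx 2.3$ MPa), and the interstitial pressure is unobservable from
perfusion data. The protocol object still records its pressure schedule
(40 mmHg, raised to 60 mmHg at the full-strength step to maintain flow
against the viscous solution) because it is part of the experimental
protocol, but by default it does not enter the fluxes.

**Baseline and volume fractions.** Loading starts from the isotonic state
($V = V_0$, $C_{is,t} = 290$ mol/m³) and the first 20 min are a CPA-free
flush with the carrier (330 mOsm), whose end state defines the
normalisation baseline for resistance *and* for the osmotic-constraint
volume fractions. The carrier being mildly hyperosmotic, the baseline
volume is $290/330 \approx 0.88\,V_0$. Constraint floors are taken
relative to this baseline rather than to $V_0$: the baseline is the state
the experiment can actually observe (it is where resistance is
normalised), and under this model the reference loading protocol then
respects the 45% hard floor — taking floors relative to $V_0$ would
paradoxically disqualify the protocol that is known to work.

**Integration.** The ODE system is stiff in places (water relaxes in
~1–2 min, CPA in ~10 min, and the full-strength step is a discontinuity),
so each protocol segment — flush, ramp, plateau, hold — is integrated
separately with `deSolve`'s `lsoda` at `rtol = 1e-8` and scale-aware
absolute tolerances, with dense output (1 s by default; 5 s inside the
grid search, which changes endpoints by well under 0.01%). Auto-terminated
holds use `lsodar` root-finding on $C_{cpa,t} = $ target, so hold
durations are event-accurate, not grid-quantised. The capillary radius is
clamped inside the derivative against solver trial steps that overshoot
the geometric range; a genuine collapse ($V \le 0$) is an error. The
toxicity cost is a trapezoidal cumulative integral of
$\beta C_{cpa,t}^\alpha$ on the output grid.

## Parameter estimation

Estimation is staged exactly as the experiments are: each stage fixes
what the previous one measured.

1. **$r_a$** from stepped-osmolarity plateaus: $1/\sqrt{R}$ regressed on
   $M_{iso}/M$ (the organ Boyle van't Hoff line). Only the
   slope/intercept ratio is used — it is invariant to how $R$ was
   normalised, and inverting it for $r_a$ needs no knowledge of the unit
   count. Steady plateaus are extracted as the mean over a terminal
   window (default 3 min) behind a drift guard.
2. **$L_p$** from the resistance transient after an impermeant challenge
   (carrier + 300 mM lactose, 15 min): with no CPA in play the transient
   shape depends on $L_p$ alone. One-dimensional bounded minimisation on
   $\log_{10} L_p \in [-16, -12]$.
3. **$\omega, \sigma$** from the shrink–swell transient after a 25% VMP
   (2.1 M) challenge: $\sigma$ sets the overshoot depth, $\omega$ the
   recovery rate. Bounded quasi-Newton minimisation from three
   deterministic starts with $\omega$ log-spaced across its range.
   A $\sigma = 0$ CPA leaves no imprint on resistance at all (no volume
   response, impermeants balanced), so such fits are flagged
   non-identifiable rather than reported; monotone traces are flagged
   likewise. Post-switch viscosity enters as a constant ratio
   (default 1.3 for 25% VMP); being constant it rescales but does not
   reshape the transient, so a mis-specified ratio does not bias the
   kinetics.
4. **$\alpha, \beta$** from slice viabilities: per concentration, a
   zero-intercept least-squares fit of $\ln(\text{viability})$ against
   exposure time (controls pin viability 1 at $t = 0$; replicates
   pooled; non-positive viabilities excluded with a warning), then a
   regression of $\ln k$ on $\ln C$. The second regression is
   precision-weighted by default: at low concentrations the true decay
   over the assay window is a few percent, comparable to assay noise, so
   the fitted rate there can carry a relative error above 100% and — on
   the log scale — can swing the exponent arbitrarily. Weighting by the
   inverse variance of $\ln k$ (propagated from each rate fit) lets the
   informative concentrations dominate; with exact data the weights are
   equal and the fit is the ordinary one. Whether the original assay
   analysis constrained the intercept is not documented; the
   zero-intercept form is the stated choice here, with a nonlinear
   exponential fit available as an option.

## Protocol optimization

Candidates are ramp–hold–step schedules over ramp rate 40–70 mM/min, ramp
duration 70–120 min, plateau duration 4–20 min (defaults step 1 mM/min ×
5 min × 1 min ≈ 5.8k simulations, about two minutes on one CPU at the
5 s output grid). For each candidate the full-strength hold is terminated
when the tissue reaches the vitrifiable target; the target defaults to the
simulated endpoint of the existing validated protocol rather than a
hard-coded constant, so the criterion stays self-consistent if the model
or parameters change. Candidates are rejected when the plateau
concentration leaves [3, 7] M, the volume drops below 45% of baseline,
more than 25 min are spent below 73% ("extended duration" is read as a
*cumulative* budget; a contiguous-excursion mode is provided), or the
target is unreachable within the hold cap (60 min). Ties in the toxicity
cost break toward the shortest total protocol, then the lowest ramp rate;
the sweep is exhaustive and deterministic, so re-runs are bit-identical.

Under the default parameters the feasible per-ramp-rate minimum curve is
shallow: the toxicity cost declines by only a few percent from 40 to
~60 mM/min and is then flat to within a few tenths of a percent, with the
binding structure set by the 45% hard floor (the best candidates sit just
above it). The package therefore reports the full per-rate curve alongside
the argmin — with a surface this flat, the argmin's exact location is less
informative than the curve itself, and small changes in the transport
formulation shift it along the plateau.

## Synthetic data: what it does and does not show

The generators replay the package's own forward models at chosen "true"
parameters and overlay seeded noise: multiplicative Gaussian (CV 2%) on
resistances, as instrument noise on a ratio quantity, and multiplicative
Gaussian (sd 0.05) on viability fractions, clipped at zero. Designs mirror
the experiments: switch challenges of 15/30 min, stepped-osmolarity
plateau sets, and a 4-concentration × 6-time × 4-replicate slice grid.
All generators are pure functions of (config, seed).

Passing recovery tests on these data shows that the estimation pipeline
is *consistent* — it inverts the forward model correctly, and degrades
gracefully under the assumed noise. It does not show that the forward
model is the right description of a real kidney, nor that real
measurement error looks like the assumed noise: real traces carry pump
lag, tubing compliance, slow drifts and occasional steps, none of which
are simulated, and real replicate variance in slice assays is unknown.
The noise magnitudes are stated assumptions, exposed in
`synth_config()`, not estimates.

## Known limitations

* Single effective permeant: the VMP components (DMSO, formamide, EG)
  have different permeabilities in reality; their separation is out of
  scope, as are the polymeric ice blockers beyond their osmotic
  contribution to the carrier.
* Parameters are fixed at 4 °C; no temperature dependence, so cooling or
  warming phases cannot be modelled.
* No axial discretisation of the capillary and no regional (cortex vs
  medulla) heterogeneity: one Krogh unit stands for the whole organ.
* Loading only; unloading (deglycerolisation-style) protocols involve the
  reverse osmotic problem and are not treated.
* The toxicity model is a lumped power law; it carries no mechanism and
  should not be extrapolated far outside the calibrated 1–8.4 M,
  15–120 min window.
* Perfusion-resistance predictions assume the viscosity ratio supplied by
  the user; the package ships no viscosity model for CPA mixtures.
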