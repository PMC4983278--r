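---
title: "Modelling soil recovery from acid deposition with stemflow micro-heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil recovery from acid deposition with stemflow micro-heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemflowS)
```

## The problem

Beech stemflow funnels precipitation — and with it dissolved sulfur — onto
a small infiltration zone at the stem base. During the acid-deposition peak
of the early 1980s, soil columns close to the trunk therefore received far
higher sulfur loads than the between-trees area; at the same time the extra
water flux flushes them faster, so after deposition collapsed (Austrian
SO₂ emissions fell by about 95 % between 1980 and 2013) they approach the
new, lower sulfate steady state sooner. Distance from the stem thus acts as
a *false chronosequence*: the near-stem column shows today what the
between-trees column will show years from now. `stemflowS` implements both
halves of that argument — a phenomenological input–output budget model per
column, and the micro-spatial soil-chemistry analysis used to evaluate it.

## The budget model and its assumptions

Each column's annual sulfur **input** is throughfall plus its routed share
of stemflow, concentrated from the crown projection area $A$ onto the
column's infiltration area $a$:

$$I = \mathrm{TF}_S + f \cdot \mathrm{SF}_S \cdot A / a .$$

The model is annual-resolution and phenomenological: no sulfate
adsorption/desorption isotherms, no organic-S mineralization kinetics, no
canopy or storm-event hydrology. Its assumptions are:

* **Linearity.** Inputs decline linearly from the 1983 peak (the historic
  load) to the 2013 input. Outputs decline linearly from the end of their
  plateau to the 2013 output.
* **Initial steady state.** Maximal outputs equal maximal inputs: after a
  decade of roughly constant emissions before 1983, each column is assumed
  at short-term input–output equilibrium.
* **Delayed response.** The output holds its 1983 plateau for a
  column-specific delay before declining — the soil keeps releasing stored
  sulfur. The delay scales inversely with the water time factor
  $F = (\mathrm{TF}+\mathrm{SF})/\mathrm{TF}$:
  `delay = round_half_up(base_delay / F)`, with a 12-year base delay for
  the throughfall-only column. Half-up rounding is the only simple rule
  that maps the factor sequence $(3, 2, 12/7, 4/3, 1)$ exactly onto the
  published delays $(4, 6, 7, 9, 12)$ years. Explicitly supplied delays
  take precedence, and the default stand uses them.
* **Recovery criterion.** Recovery is the first calendar year strictly
  after the output plateau with $O \le I$; exact equality counts as
  recovered. A column whose output never exceeds its input is
  *always-balanced*; one with no qualifying year up to the horizon (2050 by
  default) is *not-recovered*.

### Post-2013 behaviour (an open design choice)

What the two series do after the 2013 anchor cannot be observed. The
default continues the input at its 2013 value (emissions had largely
stabilized) and extrapolates the output along its 1995→2013 slope, floored
at zero. Both rules are switchable (`post_anchor` arguments:
both-constant, both-extrapolated) because nothing in the data constrains
them. One consequence worth knowing: with the 2013 endpoints fixed, the
direction of the load–recovery relationship depends on the sign of
$O_{2013} - I_{2013}$. If the column is already a net sink in 2013
($O_{2013} \le I_{2013}$), the crossing happens on the 1983–2013 segment
and a higher historic load always recovers *later* (the monotonicity the
false chronosequence needs, and the regime the property tests use). If the
column is still a net source in 2013, the crossing happens on the
extrapolated segment, whose slope steepens with the load, and the relation
reverses. Scenario sweeps should therefore fix endpoints that describe the
regime they intend to probe.

### Endpoint fixtures

The original 1983 throughfall/stemflow sulfur fluxes and the 2013
input/output anchors were measured in companion field studies and are not
available as published data. The defaults here
(`default_flux_table()`: TF 15 → 10, SF 3 → 0.6 kg S ha⁻¹ yr⁻¹;
between-trees seepage output 8 kg S ha⁻¹ yr⁻¹ in 2013) are synthetic
fixtures of realistic magnitude, chosen once and documented as such. All
recovery years computed from them demonstrate the method's behaviour, not
the study sites'. Two endpoint rules are structural, not fixtures: the
near-stem (27 cm) column's 2013 output is set equal to its 2013
stemflow-derived input, and intermediate columns scale the between-trees
output in proportion to their 2013 input (a smooth interpolation between
the two stated anchor rules).

### Routing geometry

Infiltration areas are not published. The default assigns each downhill
column the annulus between the midpoints to its neighbouring sampled
distances, starting at the stem surface (radius 25 cm) and ending at the
crown-projection radius $\sqrt{A/\pi}$; the annuli tile the crown circle
outside the stem. Uphill columns get the annulus of their absolute
distance, but a routing fraction of 0 — stemflow runs downhill. Any area
can be overridden per column (`infiltration_area`, via code or the YAML
stand config). The published routing fractions sum to 1.02; whether that
2 % excess is overlap or rounding is unknown, so the package keeps the
fractions exactly as given, reports the sum, warns, and only rejects sums
above 1.05 in strict mode. Routing fractions are applied identically to
sulfur mass and to stemflow water so that loads and time factors stay
mutually consistent.

## The soil-gradient analysis

* **Stores.** `element_store()` is the dimensional identity
  concentration × bulk density × thickness × 0.1 (mg g⁻¹ · g cm⁻³ · cm →
  t ha⁻¹), computed per half-open horizon `[top, bottom)` over the canonical
  set 0–3, 3–10, 10–20, 20–30, 30–50 cm; no coarse-fragment correction is
  applied unless a `stone_fraction` column is present (then ×(1 − fraction)).
  A forest-floor layer can be carried as an extra horizon record.
* **Gradients.** Verdicts use non-strict monotonicity with an absolute tie
  tolerance of 1e-9 in the variable's units; an all-tied sequence is
  reported explicitly as "non-monotone: flat" rather than resolved to
  either direction. Uphill samples are reported separately from the
  downhill sequence.
* **Deltas.** Survey pairs are aligned on (site, distance, horizon) cells,
  replicates averaged within a cell, differenced late − early. Missing
  values are excluded with a logged count, never imputed; unmatched cells
  are an error naming the offenders.
* **Acidification front.** With deltas ordered by depth, the front is the
  boundary between the deepest non-negative delta and the first negative
  one, provided all deeper deltas are also negative. All-positive profiles
  have no front (`NA`); a profile negative throughout places the front at
  the surface (0 cm — no recovered layer yet), which keeps the
  front-depth comparison defined at the between-trees column where the
  topsoil itself still acidifies. Non-monotone sign patterns are flagged,
  not guessed.
* **pH maps.** Plain inverse-distance weighting, default power 2, all
  samples, exact-hit threshold 1e-9 cm. IDW was chosen for determinism and
  because it cannot overshoot the sample value range; the original mapping
  method is unnamed, and variogram-based kriging is deliberately out of
  scope.

## The synthetic-data generator

`generate_survey()` emulates the qualitative structure the analysis
assumes, with all expectations deterministic given the configuration and
all noise seeded:

* 1983 topsoil pH rises from 3.5 at 27 cm to 6.5 at 300 cm — an amplitude
  of exactly 3 units, the configured bound. The distance response is
  saturating (logarithmic, capped at the outermost distance) because the
  change is steepest near the stem; a linear shape is switchable.
* 2010 topsoil pH runs 5.5 → 5.0: the gradient flattened and inverted.
* Below a distance-dependent front depth, 2010 pH sits 0.4 units *below*
  1983 (front migration); the front is deepest at 27 cm and at the surface
  at 150–300 cm, where the topsoil delta is already negative.
* Exchangeable Ca and Mg profile stores increase downhill (defaults 8 and
  1.5 t ha⁻¹ at 3 m, 60 % depleted at the stem), with the depletion
  weighted towards the deep soil.
* Total-S profile stores are distance-flat at 0.85 t ha⁻¹, inside the
  observed 0.7–1.0 t ha⁻¹ range; C and N stores (90 and 7 t ha⁻¹) are
  likewise flat.
* Noise is independent Gaussian per cell — additive for pH (sd 0.1) and
  bulk density (sd 0.03), multiplicative for concentrations (relative sd
  0.05) — with values clipped into physical ranges (pH 2–9, bulk density
  0.1–2.5, concentrations ≥ 0) and the clipping logged. There is no
  spatial autocorrelation model and no attempt to reproduce the real
  sites' values: passing tests show the *method* recovers the configured
  structure, not that it would behave identically on field data, which has
  correlated noise, gaps and unknown replicate structure (the generator
  exposes `replicates`, default one core per cell).
* The 2010 pH anchors, store levels and noise sds are invented fixtures —
  the historic surveys are published only as figures — and live only in
  config defaults.

`generate_grid()` reuses the topsoil profile radially around the stem;
`generate_deposition_history()` wraps the deterministic trajectories,
optionally with clipped annual Gaussian noise.

## Numerical choices

Trajectories are exact lines between breakpoints (second differences below
1e-9 within segments); the cumulative net-S balance is a trapezoidal
integral, exact for piecewise-linear series with breakpoints on integer
years. Negative fluxes are clipped to zero with a logged notice. All CSV
output is plain comma/point-decimal UTF-8 with a mandatory header, written
deterministically so a fixed seed and config give byte-identical files;
inputs must not use thousands separators (in the Austrian notation
"385.000 t", the tables here would mean 385000). Unknown config keys are
rejected outright.

## Problem sizes

The test-suite checks run at sizes chosen to exercise the properties while
staying quick: 100 random scenarios against the interpolation and
scan oracles, a 50-point historic-load grid for monotonicity, 20 scenarios
against a 0.001-year Riemann sum (tolerance 1e-9), 200 seeded trials for
pH-amplitude recovery (noise sd 0.2, 20 replicates, 3-standard-error
criterion at ≥ 95 %), and 1000 noisy deposition replicates for the
recovery-year stability check, which uses a steep-decline scenario
(115 → 0 kg S ha⁻¹ yr⁻¹) because first-crossing detection under
independent annual noise is biased early when the gap declines slowly
relative to the noise.

## Known limitations

The model has no process chemistry, so it cannot attribute the delayed
output to desorption versus mineralization; it only encodes their combined
phenomenology. Recovery years computed from fixture endpoints are
illustrative. The false-chronosequence reading assumes columns differ only
in load and flushing rate, not in soil properties — the analysis half of
the package exists precisely to check how far that holds. Uphill columns
are treated by absolute distance in the synthetic expectations, which
ignores that they never received stemflow historically; their generated
chemistry should be read as "throughfall-dominated" rather than as a
mechanistic uphill model.
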