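---
title: "A substrate-inclusive fuzzy-logic model of riverine spawning habitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A substrate-inclusive fuzzy-logic model of riverine spawning habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spawnhab)
```

## The problem

*Coreius guichenoti* is a drifting-egg cyprinid of the upper Yangtze basin
whose spawning grounds have been fragmented by cascade hydropower
development. Its eggs are semi-buoyant: they must stay suspended in flowing
water while they develop, which ties successful spawning to a narrow joint
window of water temperature, flow velocity and water depth — and, as field
surveys repeatedly show, to the character of the river bed, since the fish
favour gravel/cobble substrates and avoid sand and boulder beds.

`spawnhab` implements a reach-scale assessment of this spawning habitat. It
scores every cell of a two-dimensional hydraulic field with a fuzzy-logic
habitat model over four factors — bed grain size, water temperature,
depth-averaged velocity and water depth — and aggregates the per-cell scores
into reach-level indices. A parallel substrate-free three-factor model allows
the effect of including substrate to be isolated. Because the hydrodynamic
and bathymetric inputs of a real reach are rarely shareable, the package
also ships a calibrated synthetic reach generator so the whole pipeline is
reproducible from a seed.

## The fuzzy habitat model

Each input factor is described by five linguistic grades (`VL`, `L`, `M`,
`H`, `VH`) with piecewise-linear membership functions; a value can belong to
several grades at once (at 18 °C a cell is half `VL`, half `L`). A rule base
maps grade combinations to an output suitability grade; inference is the
standard Mamdani scheme:

* **AND** within a rule: minimum over the four factor terms, where each
  factor term is the maximum membership over the grades the rule allows for
  that factor (so the `AC` wildcard contributes the factor's maximal
  membership);
* **implication**: the rule's output set is clipped at the rule strength;
* **aggregation**: pointwise maximum of all clipped output sets;
* **defuzzification**: centroid,
  `HSI = ∫ z · μ(z) dz / ∫ μ(z) dz` on the unit interval,

yielding a crisp habitat suitability index `HSI ∈ [0, 1]` per cell.

### Membership breakpoints

Published sources state suitability *thresholds*, not curve shapes: spawning
is unsuitable below 18 °C and above 27 °C and optimal at 20–25 °C; velocity
is optimal at 0.2–1.3 m/s and unsuitable above 1.5 m/s; depth is optimal at
1.2–11.5 m and unsuitable above 15 m; beds finer than 2 mm (sand) or coarser
than 40 cm (boulders) are unsuitable while 2–25 cm gravel/cobble is
favourable. The packaged defaults place every one of these thresholds at a
0.5/0.5 crossover between adjacent grades and use linear transitions whose
widths are scaled to each factor (2 °C for temperature, 0.1–0.2 m/s for
velocity, 0.4–2 m for depth, 2 mm–10 cm for grain size). Transition widths
are the genuinely open part of this design: they must be narrow enough not
to overlap neighbouring thresholds (the 0.1 and 0.2 m/s velocity crossovers
are only 0.1 m/s apart), and the temperature width is pinned by the worked
17 °C/18 °C example above. All breakpoints live in
`inst/extdata/fuzzy_variables.yaml` and can be replaced wholesale via
`read_fuzzy_variables()`.

The five output sets are triangles on `[0, 1]`: `VL` (0, 0, 0.2),
`L` (0, 0.2, 0.4), `M` (0.3, 0.5, 0.7), `H` (0.6, 0.8, 1) and
`VH` (0.8, 1, 1). The `L` centroid of 0.2 sits below the 0.3 class cutoff,
so a reach blocked by a single factor (e.g. March water temperatures) is
classified 100 % low-suitability, as it should be. One known consequence:
a fully blocked reach has OSI exactly 0.2 under this geometry, so reported
reach OSI values below ~0.1 for blocked periods cannot be reproduced with
any normal output sets of this form; the geometry is configurable rather
than guessed.

### The rule base

The four-factor rule table is shipped as plain text
(`inst/extdata/rules_4factor.txt`), one rule per line with `/` alternatives
and the `AC` wildcard. Thirteen rows encode the published expert knowledge;
two completion rows are added and flagged as such in the file:

* `VH AC AC AC -> L` — boulder beds block spawning, mirroring the printed
  sand-blocking row (`VL AC AC AC -> L`);
* `L/M/H L/H L/H L/H -> L` — when temperature, velocity and depth are all
  merely marginal (`L` or `H`) no printed row matches; every such
  combination is assigned low suitability.

With these completions an exhaustive enumeration shows every one of the
5⁴ grade combinations matches at least one rule, so the aggregated output
can never be empty under covering membership functions (the centroid
fallback for an identically-zero aggregate exists only as a guard). Rules
with identical expanded antecedents but different consequents are rejected
at load time.

### The substrate-free baseline

`build_baseline()` reconstructs the three-factor model the four-factor table
was developed from: substrate-blocking rows are dropped, remaining substrate
antecedents become `AC`, and where deleting the substrate clause makes two
expanded rules disagree the **lower** consequent is kept. The table upgrades
hydraulic combinations when substrate is favourable (`M` substrate turns
`(L/H temperature, velocity, M depth)` combinations one grade up), so
removing the substrate clause must recover the pre-upgrade grade; keeping
the higher grade instead would make the baseline dominate the four-factor
model cell by cell and the substrate comparison could never be positive.
Under the lower-consequent rule the comparison reproduces the expected
seasonal sign structure: no effect while temperature blocks everything,
a strictly positive usable-area gain when the bed is gravel/cobble and the
temperature is marginal (May-like conditions), and small negative effects
once the bed coarsens into boulders (flood-season conditions).

## Estimating bed grain size from the flow

Where no substrate map is supplied, the bed-surface grain diameter is
estimated by inverting an incipient-motion threshold-velocity formula

```
Ue = (h/d)^0.14 * sqrt(17.6 * (rho_s - rho)/rho * d
                       + 6.05e-7 * (10 + h) / d^0.72)
```

with `rho_s = 2.65`, `rho = 1` g/cm³ (only the ratio enters). `Ue` is
U-shaped in `d`: the second term (cohesion/viscosity) diverges for fine
grains while the first (gravity) grows for coarse ones. The inversion
targets gravel-to-boulder beds, so it works on the coarse, monotonically
increasing branch only: `ue_minimum()` brackets the branch point by
golden-section search on `log d` (relative tolerance 1e-8) and
`invert_grain_size()` bisects on `[d_min, 2 m]` to a relative tolerance of
1e-6, clamping (with a flag) velocities below the attainable minimum or
beyond the 2 m bracket.

A physical caveat documented here deliberately: at gentle velocities
(0.4–0.6 m/s in ~10 m of water) this formula attributes the flow to
sub-millimetre sand — `Ue(10 m, 25 cm)` is about 4.5 m/s — so per-cell
inversion of a low-flow field yields a sand bed, which the habitat model
rightly blocks. Reported gravel/cobble beds under exactly such flows imply a
different (undocumented) hydraulics-to-substrate mapping; reconciling the
two is not possible from the published material. The pipeline therefore
prefers a supplied `grain_d_m` column and the synthetic generator produces
one (next section); the inversion remains available as the fallback and as
a tool in its own right.

## The synthetic reach

`generate_field()` emulates the fields a 2-D hydrodynamic model would
provide, without claiming hydrodynamic fidelity:

* a 6 km prismatic reach with a parabolic channel cross-section
  (bankfull depth 18 m) flanked by low floodplain strips; channel cells on
  a 20 m lattice, floodplain cells on a 50 m lattice;
* per period, the uniform-flow stage is solved with `stats::uniroot()` so
  that the Manning conveyance of the cross-section carries the period's
  discharge with the period's roughness; cell velocity follows the local
  Manning relation `u = h^(2/3) sqrt(S) / n`. The per-period roughness from
  the operating schedule is essential: with a single `n`, uniform flow
  scales velocity only like `Q^0.4` and no geometry can be simultaneously
  slow at ~1 840 m³/s and mostly faster than 1.5 m/s at ~9 600 m³/s;
* independent mean-one lognormal noise (s.d. 0.15) multiplies depth and
  velocity, clipped to physical bounds; dry lattice cells are kept with
  `NA` hydraulics so total area is conserved exactly;
* the bed grain size follows a velocity-competence relation
  `d = 0.1 m * (u / 0.5 m/s)^2.4` with mean-one lognormal noise
  (s.d. 0.3). The reference point and exponent are fixed once from the
  documented regimes — a predominantly sub-25 cm gravel/cobble bed at low
  discharge and a boulder-dominated (>40 cm) bed under flood flows, finer
  near the banks than in the thalweg — and are not tuned further.

`calibrate_reach_spec()` fixes the two free geometric parameters (channel
width, slope) by a deterministic coarse grid search on the noise-free
profile so that the ~1 840 m³/s semi-month gives mean wetted depth within
9–10 m and mean velocity within 0.4–0.6 m/s, and the ~9 596 m³/s flood puts
more than half the wetted area above 1.5 m/s (the flood band is evaluated as
its analytic expectation under the velocity noise). Among feasible grid
points the one with the largest minimum band margin is kept, which makes
calibration deterministic, independent of the seed and idempotent. On this
image the calibrated defaults are a 270 m channel at slope 5.1e-4.

What the generator does *not* emulate: real bathymetry, backwater from the
downstream dam, unsteady flood routing, longitudinal variation (the reach is
prismatic, so all cross-sections share one noise-free profile), and any
spatial autocorrelation of the noise. Tests passing on these fields
demonstrate correctness of the pipeline under a realistic joint
depth/velocity/substrate structure; they do not validate the model against
the real river.

## Reach-level metrics

With `A_i` the cell areas and `HSI_i` the per-cell scores over wetted cells
(dry cells are excluded with a logged count):

* `WUA = Σ A_i HSI_i` (m²), the weighted usable area;
* `OSI = WUA / Σ A_i`, the area-weighted mean suitability;
* `ISP`, `MSP`, `LSP`: the area percentages with `HSI ≥ 0.7`,
  `0.3 ≤ HSI < 0.7` and `HSI < 0.3` — half-open exactly as printed, so a
  cell at 0.7 is ideal and a cell at 0.3 is moderate.

The three proportions sum to 100 % by construction and `OSI · Σ A_i = WUA`
to machine precision; both identities are enforced property-style in the
test suite. Display rounding (two decimals, WUA also in 10⁵ m²) happens only
in the table writers.

## Numerical choices

* Defuzzification grid: step 0.001 on `[0, 1]` (trapezoidal quadrature;
  agreement with a 1e-5-step oracle is within 1e-3 over random clip
  vectors, tested).
* Inputs outside a variable's universe are clamped to its bounds — the
  membership shoulders are flat there, so clamping only formalises the
  extension; a count is logged when verbose.
* Zero aggregated membership returns the configured fallback (default 0)
  with a warning; with the completed rule base this guard is unreachable.
* The whole-field evaluator is vectorised and processes cells in chunks of
  ~4 000 grid-rows to bound memory; results are bit-identical to the
  scalar `infer()` + `defuzzify_centroid()` path (tested).
* All randomness flows from a single integer seed; the generator restores
  the caller's RNG state.

## Problem sizes

The packaged defaults produce ~4 400 lattice cells per period (~3 600
wetted at low flow). A full ten-period, two-model comparison therefore
evaluates ~70 000 cell-periods and runs in well under a minute on one core;
these sizes were chosen as the smallest that exercise every regime of the
schedule (blocked, marginal-temperature, flood) with stable area fractions.

## Known limitations

* Transition widths of the membership functions and the output-set geometry
  are expert defaults, not fitted quantities; reach-level magnitudes (WUA,
  OSI) move with them, while threshold-anchored qualitative behaviour
  (blocked periods, sign of the substrate effect) is robust.
* The incipient-motion inversion and the documented gravel/cobble regimes
  are mutually inconsistent at low velocities (see above); magnitudes of
  the substrate comparison on synthetic fields are therefore indicative
  only.
* The baseline is a reconstruction from the four-factor table under the
  lower-consequent rule, not a verbatim copy of the earlier three-factor
  model, whose full rule table is not available here.
* Temperature is spatially uniform within a period, as the schedule
  provides one measured value per semi-month.
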