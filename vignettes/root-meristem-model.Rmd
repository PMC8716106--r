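---
title: "A coupled mechano-biochemical model of root meristem growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled mechano-biochemical model of root meristem growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootsim)
```

## The model

`rootsim` simulates the growing *Arabidopsis* root meristem as a 2D cell
complex: cells are triangulated polygons sharing vertices, edges and
walls. Each wall segment carries a shared apoplastic auxin pool and, per
adjoining cell, membrane-bound carrier amounts (PIN efflux and AUX/LAX
influx carriers, and in one model variant a regulator/polarizer pair).
Three coupled layers evolve together:

1. **Tissue mechanics (PBD).** Instead of integrating forces, a
   Position-Based Dynamics solver projects constraints directly onto
   vertex positions each step: distance constraints on walls (stiff in
   compression, auxin-dependent in extension) and on centroid spokes
   (the pectin/cytoskeleton matrix), shape matching per cell, bending at
   wall vertices, a strain constraint that stiffens edges aligned with
   the cell's anisotropy factor, and an XPBD pressure constraint driving
   each polygon toward its turgor target area. Rest lengths, shapes and
   areas yield plastically toward the current configuration, converting
   sustained elastic strain into permanent growth (viscoelastic walls).
2. **Polar auxin transport.** Carrier-mediated import/export
   (`I = K_AUX1 * AUX1_mem * IAA_wall * L`,
   `E = K_PIN * PIN_mem * IAA_cell * L`), apoplastic diffusion between
   wall segments, passive membrane permeability, saturable degradation
   (Hill exponent 4), auxin-induced carrier expression (Hill exponent 2,
   capped pools) and carrier trafficking with membrane saturation. PIN
   is delivered to membrane sections in proportion to a softmax over
   per-section sensitivities combining the auxin-flow feedback, the
   anisotropy factor and cell geometry; columella-lineage cells traffic
   PIN uniformly. Growth dilutes every concentration (amounts are
   conserved when compartments expand), so the non-growing tip
   concentrates auxin relative to the expanding shaft.
3. **Growth control.** Auxin sets wall extension stiffness through a
   biphasic response: stiff near zero auxin, maximally relaxed between
   `K_1auxin` = 0.05 nM and `K_2auxin` = 3 nM, stiff again at high
   auxin (growth arrest). Cells divide when they exceed a per-type area
   threshold, by default through the centroid parallel to the
   anisotropy factor (anticlinal), with the stem-cell niche exceptions
   (CEI, CEID, epidermis/LRC initials, columella and vascular
   initials); QC and columella never grow or divide.

Two interchangeable PIN polarization mechanisms supply the auxin-flow
term: the **flux mechanism** senses the cell's net auxin flux vector and
sensitizes the downstream faces (canalization), and the
**regulator-polarizer mechanism** realizes flux sensing molecularly: an
auxin-activated regulator binds preferentially where auxin enters the
cell and displaces a PIN-recruiting polarizer toward the opposite
membrane, where it recruits PIN. The polarizer displacement is the only
stochastic element of the model.

## Units and time

Lengths are micrometres, concentrations nM (molecules per compartment
area), rates per hour. One simulation step advances 0.02 h of model
time by default; chemistry is sub-stepped 10x within each mechanics
step (explicit Euler, stable for all default rates). Mechanics-only
embryo simulations use a coarser 0.1 h step, matching the slower
embryonic time scale.

## Parameters

All biochemical rate constants take the reference values of the
published root auxin-transport parameterization (see `default_params()`
for the complete annotated list). Settings that the literature leaves
open are package choices, fixed once:

* **Solver**: 10 projection passes per step; XPBD pressure compliance
  300 (solver units); turgor overpressure 0.15 (area target = rest area
  x 1.15); spoke stiffness 0.15, shape 0.1, bending 0.05. These were
  calibrated jointly so an isolated relaxed cell grows a few percent
  per hour and a tissue meristem cell cycles on the scale of a day,
  while auxin-stiffened walls arrest growth by more than an order of
  magnitude. Border walls use softened (square-root) Jacobi averaging
  and plastic yield scales with wall extensibility `1 - kE`; without
  these, the un-averaged XPBD pressure out-muscles stiffened walls and
  high-auxin growth arrest never materializes.
* **Plastic yield rate** 0.3 per hour: walls are viscoelastic; the rate
  sets how fast elastic strain consolidates into growth and how long
  strains persist to feed the anisotropy factor.
* **Anisotropy factor**: reorientation toward the strain axis at about
  1 per hour (cortical-microtubule time scale), strain-gated
  autocatalytic magnitude growth, decay 0.01 per hour, gating threshold
  at 1% wall strain, seed magnitude 0.01. The published form of the AF
  equation is reinterpreted in two ways, both forced by its stated
  phenomenology: the bare AF term inside the derivative is read as
  strain-gated self-reinforcement (otherwise the AF can never reach
  functional magnitudes within a simulation), and the direction term
  uses wall normals so the AF aligns orthogonal to the dominant
  deformation, as described, rather than parallel to it; a
  strain-weighted orientation tensor supplies the target axis so the AF
  can also reorient when the deformation axis changes.
* **Boundary**: each of the two Source cells receives a constant total
  influx of 250 nM um^2/h (constant in time, so concentrations dilute
  as the organ grows); every other top-row cell is a Sink exporting at
  1/h to the shoot. The influx was chosen within the carrying capacity
  of a single vascular file (`K_PIN * PIN_MaxMem * wall width`), so the
  canal, not the boundary cell, limits throughput.
* **Passive permeability** 0.02 um/h (no published value): small enough
  that the polar canal, not passive leak, dominates patterning.
* **Regulator-polarizer**: membrane diffusion treats the published
  coefficients as true diffusion coefficients (um^2/h) over section
  midpoint distances, and the gradient metric uses per-area fluxes with
  amplification 50, placing the influx face near the gate's half-max
  constant while spillover faces stay below it. With the published
  length-weighted regulator delivery on quadrilateral cells, the
  regulator otherwise fails to mark the influx face and PIN stays
  bipolar.
* **Division thresholds**: 1.5x the type's template mean area;
  daughters inherit the threshold of their (possibly new) type.

## The synthetic template

`build_synthetic_root_template()` generates an idealized heart-stage
layout: five tissue files per side (vascular, pericycle, endodermis,
cortex, epidermis; widths 3/3/5/7/7 um, body cells 8 um tall), a
five-row tip with exactly two QC cells, columella initials and columella
below them, CEI/CEID and epidermis/LRC initials flanking, an LRC sheath,
and a tapered outline. The vasculature is deliberately narrow: the
geometry term of PIN sensitivity then confines transport axially, as in
real roots, which is essential for the canal to reach the tip before
leaking laterally. The top vertex row is pinned (attachment to the rest
of the embryo); all anisotropy factors start at zero. The generator is
deterministic; alternative meshes can be supplied through the JSON
dialect read by `load_mesh()` (schema in `inst/extdata/`).

What the template does *not* emulate: curved cell walls, the full
rounded outline of a real embryo, multiple columella layers per file,
or segmentation noise. Passing tests on this template show the
mechanisms operate and interact as described; they do not certify
quantitative agreement with any particular imaged root.

## Study conditions and problem sizes

The standard runs used by the test-suite and by
`scripts/acceptance.R`:

* wild-type: 6 body cells per file (110 cells), 1500 steps (30 h),
  both mechanisms;
* mechanics-only symmetry breaking: 2 body cells per file (70 cells),
  300 steps of 0.1 h, uniform vs 4x differential growth at the RSI,
  with an optional mid-run switch to uniform;
* reflux/source-removal: four paired 1400-step runs, source removed at
  step 400;
* auxin pulses: 1800 steps with two 5 h applications;
* perturbation panel: paired 1200-step runs (pin2-like knockdown, tip
  excision, QC ablation, simulated microtubule disruption, AF removal).

These sizes keep the full panel within minutes on one core while
leaving enough cells per longitudinal bin for the profile statistics.

## Numerical choices and degenerate inputs

Chemistry compartment areas are floored (1 um^2 for cells, 0.1 um^2
for walls) so transient sliver geometries cannot produce unbounded
rates; divisions that would create a daughter below 20% of the parent
area are rejected and retried once with a perturbed angle; intersection
points within 5% of an existing vertex are snapped to it. The softmax
is computed with the per-cell maximum subtracted. Polarizer
displacement moves `min(Kdisp_POL * dt, 1)` of each section's pool and
conserves the total exactly. Ties in the orientation tensor fall back
to the x axis. Growth dilution ratios are clamped to [0.5, 2] per step
against remeshing artifacts.

## Design choices where the design was open

* The division plane "parallel to the AF" uses the AF direction; a
  non-polar cell falls back to its short principal axis (anticlinal
  with respect to the cell geometry).
* "Periclinal" for the CEID is implemented as a division line along
  the organ axis, producing inner (endodermis) and outer (cortex)
  daughters.
* A shared wall takes the minimum extension stiffness of its two
  cells: the relaxed cell governs.
* The no-reflux intervention zeroes carrier fluxes on walls between the
  outer sheath (epidermis, LRC) and the inner ground tissues; the
  columella-to-LRC handoff at the very tip stays open.
* Membrane caps are intensive (concentrations), so daughters keep their
  parents' caps.
* Both `kAFP * (IAF + IP)` (as published) and a product form of the
  interaction term are available (`polarity$interaction`).
* Negative projected flux is clamped before the sign-blind quartic of
  the flux contribution: only outward-aligned flux polarizes, which is
  required for a directional canal.

## Known limitations

* The epidermal/LRC return stream ("reverse fountain") emerges, but its
  lateral re-entry into the ground tissues is weak on quadrilateral
  cells: the winner-take-all softmax leaves little PIN on lateral
  faces. Consequently the no-reflux intervention changes where growth
  happens more than how much auxin the organ retains, and bipolar
  cortex cells near the LRC termination appear reliably only under the
  regulator-polarizer mechanism.
* Rapid elongation-zone growth, cell differentiation, tropisms and
  plasmodesmatal transport are outside the model's scope.
* The PIN re-localization time after division is auxin-dependent
  (membrane turnover slows with cellular auxin), so the reported
  kinetics refer to the moderate-auxin outer tissues where such
  measurements are made; high-auxin cells near the niche repolarize
  more slowly.
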