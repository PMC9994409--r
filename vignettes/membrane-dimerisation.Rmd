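---
title: "Simulating receptor confinement and dimerisation on a crowded membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating receptor confinement and dimerisation on a crowded membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(raftsim)
```

## The model

raftsim simulates lateral diffusion and reversible dimerisation of a
membrane receptor — parameterised for the platelet collagen receptor
GPVI — as an agent-based model on a small square patch of plasma
membrane. The patch is a periodic box (a flat torus), so a single tile
stands in for an effectively infinite membrane. Three ingredients define
the dynamics:

* **Hard-disc agents.** Receptor monomers, receptor dimers and inert
  crowder proteins are circular discs that never overlap. A proposed
  move that would create an overlap is rejected and the agent stays in
  place for that tick. Tangency (centre distance exactly equal to the
  radius sum) is not an overlap; dissociation relies on this to place
  two tangent daughters.
* **Position-dependent Brownian steps.** Each tick, every agent is
  visited once in a fresh uniform random order. An agent at position
  $x$ draws a step of length $\ell = \sqrt{D(x)}\,|z|$, $z \sim N(0,1)$,
  in a uniformly random direction. $D(x) = D_{in}$ when the agent centre
  lies inside any confined domain (closed disc, minimal-image test) and
  $D_{out}$ otherwise, evaluated at the *start* of the step. Confined
  domains are static circles of reduced diffusivity, the model's proxy
  for lipid rafts. Dimers step with scale $\ell / 2^{1/4}$ (the
  Stokes–Einstein consequence of doubling the disc area at conserved
  total area), and inert crowders at half the receptor step scale.
* **Stochastic reactions.** After its move, a monomer dimerises with
  probability $k_b$ per tick provided another monomer lies within the
  capture threshold — an edge-to-edge gap of at most 10% of the monomer
  diameter. The pair is replaced by one dimer of radius
  $\sqrt{2}R_{monomer}$ (total disc area exactly conserved) at the
  minimal-image midpoint; if that disc would overlap anything the event
  is abandoned. A dimer dissociates with probability $k_d$ per tick into
  two tangent monomers placed symmetrically about its centre along a
  uniformly random axis, retried up to 20 times against overlaps and
  deferred if no axis fits. Molecule count $n_{mono} + 2\,n_{dimer}$ and
  total receptor disc area are exact invariants; the engine aborts if
  either is violated.

The observables recorded each tick are the dimeric fraction of molecules,
$2 n_{dimer} / (n_{mono} + 2 n_{dimer})$, and the fraction of receptor
molecules whose agent centre lies inside a confined domain.

## From physical constants to simulation units

`scale_parameters()` maps measured platelet constants onto the
dimensionless units the engine uses, treating the platelet as a perfect
sphere tiled into raft-containing boxes:

```{r}
scale_parameters(real_world_params())          # human: 7.4 fl, 9600 copies
scale_parameters(real_world_params(preset = "mouse"))
```

For the human defaults (volume 7.4 fl, 9600 GPVI copies, lateral
diffusivity 0.091 um^2/s, 200 nm rafts covering 35% of the membrane,
114 angstrom projected receptor diameter) the chain gives a membrane area
of 1.8e-11 m^2, about 205 boxes per platelet of side 0.3 um (30
simulation units), 47 receptors per box with scaled diameter 3.8% of the
box, an expected per-tick step of 12.5 nm and a tick duration of 0.43 ms.
All intermediates are carried unrounded; rounding happens only for
display and for the integer receptor count (half away from zero, which is
what makes 9600 copies over 204.6 boxes come out at 47). Alternative
published area estimates for a discoid platelet with an exposed open
canalicular system (2.4e-11 and 3.2e-11 m^2) are larger than the
spherical value used here; they are documented for context and not used
downstream.

## Defaults and the conditions they encode

The default `sim_config()` is the standard experimental setup: 47
receptor monomers (no dimers) placed uniformly at random without overlap
in a 30-unit periodic box, one central confined domain covering 35% of
the box, $D_{out} = D_{in} = 1$, $k_b = 0.05$ per molecule per tick,
$k_d = 0.01$ per tick, 200,000 ticks with observables averaged over the
final 50,000, and three replicates (seeds `seed`, `seed + 1`, ...).
Inert crowders default to a diameter of 5% of the box and half receptor
speed. The ten `preset()` sweeps vary one or two of these parameters at
a time: diffusivity contrast (presets 1–2), confined area crossed with
contrast (3), domain merging at fixed total area (4), crowder count (5),
crowder disintegration at conserved total area (6), global diffusivity
(7), the confined-area estimation design (8), receptor density (9), and
the $k_b \times k_d$ ligand-binding proxy grid (10).

Two interpretation choices deserve note. "Fold merging" in preset 4 is
implemented against a reference of 8 equal domains at 35% total area, so
fold $f$ uses $\mathrm{round}(8/f)$ domains: fold 8 is one merged circle,
fold 0.5 is 16 fragments. The merging-invariance property makes results
insensitive to this convention, which is the experiment's own conclusion.
In preset 3 the single domain circle may exceed half the box at the top
of the swept range; membership tests are minimal-image aware, so the
sweep runs unchanged at the cost of the nominal area fraction slightly
overstating the truly covered area there.

## Numerical choices

* **Capture threshold geometry.** The 10%-of-diameter threshold is
  measured edge-to-edge. Centre-to-centre would be geometrically
  impossible for non-overlapping discs of that diameter.
* **One binding draw per focal monomer per tick**, applied to the
  nearest candidate (ties broken uniformly). The Bernoulli draw is made
  before the neighbour scan — the two commute, and this keeps the scan
  off the hot path at small $k_b$.
* **Start-evaluated diffusivity.** The step scale uses $D$ at the
  agent's pre-move position; boundary crossings within a step are not
  sub-resolved. For such jump processes the stationary density scales
  like $1/\sqrt{D}$ (inverse step length) rather than the $1/D$ of the
  continuum Ito limit, which materially affects how strongly receptors
  localise at a given contrast.
* **Rejected moves are skipped, not re-drawn.** Re-drawing until
  acceptance would inflate effective diffusivity in crowds.
* **Tangent dissociation.** Daughters are placed exactly tangent
  (centre $\pm R_{monomer}$). They therefore start inside each other's
  capture shell (gap 0) but escape it after a relative displacement of
  only 10% of a diameter; re-capture amplification consequently requires
  step lengths well below the capture gap ($D \lesssim 10^{-3}$ in box
  units). This is the main regime difference from implementations that
  respawn daughters coincident at the dimer centre, which lengthens pair
  contact times by roughly two orders of magnitude.
* **Scheduling.** Agents created mid-tick act from the next tick,
  preventing double updates. The engine records every `thin` ticks
  (default 10) to bound memory; window means are taken over retained
  records.
* **Randomness.** Initial placement uses R's RNG; the compiled tick
  loop uses an internal xoshiro256++ stream seeded from R's RNG, so a
  run is bit-reproducible given `set.seed()` while keeping per-draw cost
  a few nanoseconds. Normal deviates use the polar method.
* **Neighbour search.** A uniform cell grid (cell size at least the
  largest radius sum and the capture distance) restricts overlap and
  capture queries to a 3x3 neighbourhood; configurations whose discs are
  large relative to the box fall back to exact all-pairs. The grid is
  required to agree with the all-pairs rule and is tested against it on
  random configurations.

## What the generator emulates, and what it does not

Initial states (and the named test fixtures built by `make_fixture()`)
emulate a uniformly mixed resting membrane: receptors start monomeric
and uniformly placed, domains are static, and crowders are featureless
discs. Real membranes violate most of this in detail — rafts are
transient and mobile, the actin cytoskeleton fences diffusion, receptor
copy number varies more than tenfold between platelets, and GPVI
interacts with specific partners rather than generic crowders. Passing
tests therefore validate the simulator's internal physics (excluded
volume, conservation laws, diffusion scaling, reaction kinetics), not
quantitative predictions about platelet biology.

## Problem sizes used by the test suite

The acceptance-style checks run the presets at the standard setup
(200,000 ticks, 3 replicates) where a single point is asserted, and at
reduced sizes (50,000–60,000 ticks, final 20,000-tick windows) where a
trend across many sweep points is asserted; the confined-area estimation
design is run at 60,000 ticks, which its regression tolerates well.
Property tests use boxes of 1–4,000 agents and 2,000–100,000 ticks.
These sizes were chosen so the full suite exercises every preset while
each assertion retains a comfortable Monte Carlo margin.

## Known limitations

* No higher-order clusters: reactions stop at dimers, and ligand effects
  enter only through the $k_b/k_d$ grid.
* Domains neither move, split nor merge within a run; merging is studied
  across runs at fixed total area.
* Whether inert crowders slow down inside confined domains is not
  specified by the underlying study; here they experience the same
  $D_{in}/D_{out}$ field as receptors (scaled by their speed factor). In
  the shipped crowder experiments the domain area is zero, so nothing
  depends on this choice.
* In contact-time-amplified regimes (very low diffusivity, or extreme
  contrast inside domains) equilibrium dimer levels are sensitive to the
  dissociation placement convention discussed above; the tangent
  convention used here is the conservative, overlap-free reading.
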