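# raftsim

Agent-based simulation of receptor diffusion, confinement and
dimerisation on the platelet plasma membrane.

The platelet collagen receptor GPVI signals far more strongly as a dimer
than as a monomer, and how often dimers form depends on membrane
physics: how fast receptors diffuse, whether raft-like "confined
domains" slow them down locally, and how crowded the membrane is with
other proteins. raftsim models a 0.3 um x 0.3 um membrane tile as a
periodic 2-D box of hard discs. Each tick, every agent takes a Brownian
step of length sqrt(D(x)) |N(0,1)| in a random direction (rejected if it
would overlap another disc; D is reduced inside static circular confined
domains), then a monomer whose edge-to-edge gap to another monomer is at
most 10% of its diameter dimerises with probability k_b per tick, and a
dimer dissociates with probability k_d per tick into two tangent
monomers. Dimers have radius sqrt(2) R_monomer (area-conserving) and
step slower by 2^(1/4) (Stokes-Einstein). The package is aimed at
quantitative membrane biologists who want a fast, reproducible sandbox
for diffusion-limited receptor oligomerisation.

It provides:

* `scale_parameters()` — the deterministic calculator from measured
  platelet constants (volume 7.4 fl, 9600 GPVI copies, D = 0.091 um^2/s,
  200 nm rafts covering 35% of the membrane, 114 angstrom receptor) to
  simulation units: a 30-unit box (0.3 um), 47 receptors per box of
  scaled diameter 3.8%, an expected step of 12.5 nm and a tick of
  0.43 ms; human and mouse presets.
* `sim_config()` / `run_sim()` / `run_replicates()` — a compiled,
  seed-reproducible tick engine with excluded volume, confined domains,
  reaction events, equilibrium-window averaging and replicate summaries.
* `preset(1:10)` / `run_sweep()` — the ten study designs (diffusivity
  contrast, confined-domain area, domain merging, inert crowding,
  crowder disintegration, global diffusivity, confined-area estimation,
  receptor density, k_b x k_d grid), plus `pearson()` and
  `estimate_area_at_half_inside()` for the derived statistics.
* config/result I/O (`load_config()`, `write_results()`, manifests with
  seeds and checksums), deterministic test fixtures, and a thin CLI at
  `inst/cli/raftsim` (subcommands `scale`, `run`, `sweep`, `plot`,
  `fixtures`).

## Worked example

Equilibrium dimerisation with one 35% confined domain at a 10:1
diffusivity contrast (a 50,000-tick run, averaging the final 20,000
ticks, three replicates):

```r
library(raftsim)
cfg <- sim_config(d_in = 0.1, n_steps = 50000, window = 20000)
run_replicates(cfg, seed = 1)
#> Equilibrium summary over 3 replicate(s), master seed 1
#>        observable    mean        sd n_replicates
#>        n_monomers 31.6163 0.0191398            3
#>          n_dimers  7.6918 0.0095699            3
#>  fraction_dimeric  0.3273 0.0004072            3
#>   fraction_inside  0.7491 0.0075071            3
```

Of the 47 receptor molecules, on average 31.6 remain monomeric and 7.7
are dimers, so 32.7% of molecules are in dimeric form and 74.9% sit
inside the confined domain (which covers only 35% of the tile — the
slow-diffusion domain concentrates receptors about fivefold in density
terms). The `sd` column is the spread across the three replicate seeds.

The scaling calculator reproduces the real-world-to-simulation mapping:

```r
as.data.frame(scale_parameters(real_world_params()))
# platelet area 1.84e-11 m^2, 205 boxes/platelet, box length 3.0e-7 m,
# 47 receptors/box, scaled diameter 3.8%, step 12.5 nm, tick 0.43 ms
```

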