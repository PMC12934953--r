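# nucleomech

Coupled mechanochemical simulation of nuclear deformation on nanopillar
substrates, in R.

When a cell spreads on a bed of nanopillars, its perinuclear actin cap
presses the nucleus onto the pillar array; the nuclear envelope (NE)
stretches, lamin A/C redistributes, nuclear pore complexes (NPCs) open, and
YAP/TAZ moves into the nucleus. `nucleomech` implements a quantitative model
of this axis for researchers in nuclear mechanotransduction: a finite-element
model of the NE as an incompressible Mooney–Rivlin hyperelastic shell

  W = E_scale [E1 (Ī₁ − 3) + E2 (Ī₂ − 3)] − p (J − 1),

inflated by an osmotic pressure ΔP, compressed by a cap stress
σ_cap(t) = σ_max (1 − e^(−t/t₀)) e^((Z − Z_apex)/Z₀), with pillar steric
repulsion and rigid floor contact, bidirectionally coupled to surface/volume
reaction–transport of lamin A/C, NPCs and YAP/TAZ on the deforming geometry
(implicit diffusion–reaction plus multiplicative dilution by the local area
ratio α or volume ratio J). Deformation gates YAP/TAZ import through the
local NE stretch and the active-NPC density; lamin density scales the NE
stiffness back, via E_scale = (1 − φ_L) + φ_L [L]/[L]_ref. The force per
lamin subunit, F_L = |σ_NE|/[L], serves as a rupture-propensity proxy.

The methods vignette (`vignettes/nucleomech-methods.Rmd`) describes the
model, its numerical treatment, and the design decisions in detail.

## Worked example

A short flat-substrate compression at test-scale resolution:

```r
library(nucleomech)

fx  <- make_coarse_fixture("flat_coarse", hedge = 0.8, t_end = 300)
cfg <- fx$config
cfg$schedule$sigma_max <- 400          # Pa, actin-cap plateau
run <- run_simulation(cfg, mesh = fx$mesh)
run$metrics[, c("t", "sigma_cap_Pa", "dP_Pa", "vol_nuc", "yap_nc", "npcA_mean")]
#>     t sigma_cap_Pa    dP_Pa  vol_nuc    yap_nc npcA_mean
#> 1   0      0.00000 820.0000 144.0769 0.4356953 0.1602305
#> 2  50     19.50823 823.4182 139.2772 0.4501320 0.1653349
#> 3 100     38.06503 826.8136 134.7035 0.4666477 0.1711773
#> 4 150     55.71681 830.4052 130.0333 0.4842466 0.1788466
#> 5 200     72.50770 833.6551 125.9403 0.5002239 0.1866390
#> 6 250     88.47969 836.4992 122.4575 0.5141314 0.1939288
#> 7 300    103.67271 838.9607 119.5156 0.5260403 0.2005289
```

As the cap assembles (column `sigma_cap_Pa`), the nucleoplasm volume
(`vol_nuc`, µm³) falls and the osmotic pressure (`dP_Pa`) rises to resist
it; NPC activation (`npcA_mean`, µm⁻²) and the YAP/TAZ nuclear-to-cytosolic
ratio (`yap_nc`) climb — compression drives nuclear YAP/TAZ import.

Key entry points:

- `build_reference_mesh()`, `shell_geometry()`, `nanopillar_array()` —
  quarter-domain shell + nucleoplasm meshes and substrate layouts;
- `inflate_shell()`, `ramp_cap()`, `solve_equilibrium()` — the mechanics;
- `run_simulation()` — the full coupled loop;
- `run_pitch_sweep()`, `critical_pitch()`, `mean_lower_stretch()`,
  `max_tension()`, `integrated_force()` — the pitch-sweep analyses;
- `balloon_oracle()` — independent closed-form thick-sphere inflation, used
  to validate the finite-element mechanics.

A thin command-line wrapper is provided in `inst/cli/nucleomech.R`
(`inflate`, `simulate`, `sweep` subcommands over a YAML configuration).

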