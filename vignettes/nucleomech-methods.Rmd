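---
title: "Modeling nuclear envelope deformation and remodeling on nanopillar substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nuclear envelope deformation and remodeling on nanopillar substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`nucleomech` simulates how a cell nucleus deforms when the cell spreads on a
flat substrate or on a square array of nanopillars, and how that deformation
feeds back on the molecular state of the nuclear envelope (NE). It couples
two components on a shared quarter-domain tetrahedral mesh:

**Mechanics.** The NE (double bilayer plus lamina, lumped) is a spherical
hyperelastic shell of stress-free outer radius $R_0 = 4.1$ um and thickness
$\Delta T = 0.2$ um. The material is incompressible Mooney-Rivlin,

$$W = E_{scale}\,[E_1(\bar I_1 - 3) + E_2(\bar I_2 - 3)] - p\,(J-1),$$

with $E_1 = 5000$ Pa, $E_2 = 1000$ Pa, a pressure-like multiplier $p$, and a
projection equation $\phi_0 (J-1) + p = 0$ with $\phi_0 = 10^8$ Pa that
enforces incompressibility to a relative volume deviation of order
$|p|/\phi_0 \sim 10^{-4}$. We use the *isochoric* invariants
$\bar I_k = J^{-2k/3} I_k$: the plain two-invariant form has a nonzero
hydrostatic stress $2(E_1+2E_2)$ at $F = I$, which combined with the
pressure projection would contract the reference state by a spurious
$|J-1| \approx 1.4\times10^{-4}$ and leave the reference weakly pre-stressed.
At incompressibility both forms describe identical material behavior; the
isochoric split simply makes the reference state exactly stress-free, as the
parameter table assumes.

Loads: an osmotic pressure difference $\Delta P$ (820 Pa after inflation)
acts on the inner surface along the deformed normal (a follower load,
applied with Nanson's relation $\alpha n = J F^{-T} N$); the perinuclear
actin cap acts downward on the outer surface with magnitude
$\sigma_{cap}(t)\, e^{(Z - Z_{apex})/Z_0}$ and the saturating schedule
$\sigma_{cap}(t) = \sigma_{max}(1 - e^{-t/t_{0,cap}})$; nanopillars repel
the NE with $\sigma_{contact,0}\, e^{-(z - d_{steric})/d_{steric}}$ applied
along the inward deformed normal, localized laterally by a smooth
super-Gaussian lattice indicator; the substrate floor at $z = -h_{NP}$ is a
rigid contact enforced as an active-set Dirichlet condition re-evaluated
every Newton iteration (released when the reaction becomes adhesive).
The nucleoplasm enters the mechanics only through the pressure feedback
$\Delta P \leftarrow \Delta P - \phi_{inner}(vol - vol_{prev})/vol$
($\phi_{inner} = 100$ Pa), iterated with the equilibrium solve until the
pressure changes by less than 1%.

**Reaction-transport.** NE-bound lamin A/C (surface density on the inner
NE, tracked on the outer surface via the concentric radial map),
inactive/active nuclear pore complexes (NPCs, outer surface), phosphorylated
lamin and nuclear YAP/TAZ (volume concentrations) evolve by
diffusion-reaction on the deforming geometry. Advection is handled by the
splitting used throughout: implicit-Euler diffusion-reaction on the domain
frozen at the new time, followed by a multiplicative dilution correction by
the ratio of old to new local measure (volume Jacobian $J$ for volume
species, areal stretch $\alpha$ for surface species). Lamin cycles between
the NE-bound pool (phosphorylation $k_{rl}[L]$) and the nucleoplasmic pool
(dephosphorylation $k_{fl}\,h([F])\,[L]_{phos}$ with the Hill factor
$h([F]) = p_{cyto}[F]^{2.6}/(C_L + p_{cyto}[F]^{2.6})$). NPC activation is
mass-action in F-actin, lamin and (fixed) active myosin. YAP/TAZ import is
stretch-gated,
$k_{in,tot} = \phi_{scale}(k_{in,b} + k_{in}[NPC]_A)\,
 e^{(\alpha - \alpha_{init})/\alpha_0}$,
against first-order efflux; the cytosol is well-mixed with a pseudo-steady
sequestration balance and closes the YAP/TAZ budget by global conservation.
F-actin at the NE is the analytic cylinder-PM model:
$[F] = [F]_0 + [F]_1 e^{-d_{NE\text{-}PM}/d_F} e^{H_{PM}/H_0}$, with the
curvature term active only on pillar sides.

**Coupling.** Deformation feeds transport through the dilution maps, the
local stretch in the import rate, and the F-actin field evaluated on the
deformed surface. Transport feeds back through the lamin-dependent
stiffness multiplier applied to both elastic constants,

$$E_{scale} = (1 - \phi_L) + \phi_L\,[L]/[L]_{ref},$$

which is 1 at the reference (wild-type) density and keeps the membrane
contribution $(1-\phi_L)$ at zero lamin. (The alternative sign,
$(\phi_L - 1) + \phi_L [L]/[L]_{ref}$, would zero the NE stiffness at the
reference density with $\phi_L = 1/2$, which cannot be intended.) The
rupture proxy is the force per lamin subunit $F_L = |\sigma_{NE}|/[L]$
(1 Pa um$^2$ = 1 pN) with the NE traction from the stress field at the
inner surface.

# Discretization and numerics

*Mesh.* The quarter domain ($X,Y \ge 0$) is meshed by an "octasphere"
triangulation (two subdivided octant spherical triangles sharing the
equator arc — no degenerate pole cells), replicated on radial levels and
connected by prisms split into tetrahedra with the minimal-global-vertex
diagonal rule (always conforming). The radial structure makes the
concentric inner-outer surface map exact at vertices: the projection of an
outer vertex onto the inner sphere *is* an inner-level vertex, so the
lamin bookkeeping needs no interpolation. Displacements are quadratic
(10-node tets, mid-edge nodes projected radially so spherical surfaces are
curved to second order); pressure is linear on vertices (the standard
stable mixed pair). Transport fields are linear on vertices.

*Mechanics solver.* Newton with analytic volume tangents
(directional-derivative form), finite-difference tangents for the follower
surface loads, backtracking line search, and a chord variant that reuses
the sparse LU factorization while the contraction rate stays good. Load
increments (pressure during inflation; cap stress at
$\min(2\,\text{kPa}, \sigma_{max}/10)$ per step) are halved on failure.
Dirichlet jumps (floor projection, symmetry) are imposed in sub-steps of at
most 0.05 um so constraint changes cannot invert elements. The apex "roof"
stabilization ties the z-displacement of the apex patch to the
area-weighted mean of the surrounding annulus as a simultaneous multi-point
constraint (the converged limit of pinning it to the previous step's
annulus average, without the lag that otherwise builds an apex spike on
coarse meshes); a weak z-spring on the apex patch (a few pN in total,
orders of magnitude below the loads) removes the rigid vertical mode
before floor contact forms. Symmetry is the mirror condition: the *normal*
displacement component vanishes on each cut plane ($u_x = 0$ on $X = 0$,
$u_y = 0$ on $Y = 0$).

*Quadrature.* Degree-5 collapsed Gauss-Jacobi (27 points) in cells,
degree-4 (6-point) rules on facets.

*Nucleoplasm extension.* The displacement is extended into the nucleoplasm
by minimizing a compressible neo-Hookean energy
($E_{1,nuc} = 5$ kPa, $\phi_{nuc} = 10^5$ Pa) with the shell displacement
as Dirichlet data (ramped in sub-steps for large squashes). It is used
only to advect the volume species; the nucleoplasm volume in the pressure
loop comes from a divergence-theorem integral over the deformed inner
surface, which is independent of the extension.

*Transport.* Mass matrices are lumped, so both splitting sub-steps conserve
the same (lumped) totals: pure advection conserves species numbers to
machine precision, and exchange reactions are either solved jointly
(the NPC pair, one implicit block system, conserving the pointwise sum
exactly) or applied with matched explicit fluxes (lamin cycling across the
surface/volume pools). YAP/TAZ conservation is enforced identically through
the cytosolic-pool closure. Implicit Euler handles the stiff NPC
deactivation ($k_{rNPC} = 8.7\,s^{-1}$) at any step size; tiny negative
concentrations (below $10^{-10}$ in magnitude) are clipped.

*Time stepping.* The step is bounded by [0.5, 50] s and by the cap-stress
increment rule; it is halved when the mechanics fails to converge and
doubled back gently on success. The splitting is first-order in $\Delta t$
(verified by a step-halving test on a prescribed sinusoidal dilation).

# Initialization and the tabulated steady state

The run begins by inflating the shell to $P_{max}$, then setting all
species to the uniform steady state of the well-mixed kinetics at the
computed post-inflation measures (inner/outer areas, nucleoplasm volume).
Two details deserve note:

- The tabulated closed-form initial conditions use the bare maximum
  dephosphorylation rate $k_{fl}$; evaluated with the tabulated reference
  measures they give $[L]_{init} \approx 2980$ um$^{-2}$, the tabulated
  reference density. But the *dynamics* dephosphorylate at the
  Hill-modulated effective rate, so that state is not a fixed point: it
  relaxes by about 6% over the first few hundred seconds. By default the
  package initializes at the self-consistent (Hill-rate) balance, which is
  stationary to well under 1% over 1000 s; `kinetic_params(ss_hill = FALSE)`
  reproduces the literal tabulated expressions instead.
- The lamin stiffness reference `L_ref` defaults to the wild-type initial
  density *at the run's own measures*, so $E_{scale} = 1$ at initialization
  and a low-lamin run (half the lamin total) starts at
  $E_{scale} = 0.75$, as the stiffness-fraction parameter intends.

One consequence of the printed constants deserves emphasis: the inflation
pressure (820 Pa) sits only about 5% below the free shell's limit-pressure
plateau (~865 Pa for this Mooney-Rivlin wall). A uniformly softened shell
(e.g. the half-lamin condition, $E_{scale} = 0.75$) therefore has *no
stable equilibrium* at that fixed pressure — the balloon runs away. The
initialization handles this by the exact invariance of hyperelastic
equilibria under joint scaling of moduli and loads: a uniform stiffness
rescaling rescales the osmotic pressure multiplier
($\Delta P \to E_{scale}\,\Delta P$) and keeps the inflated geometry,
which is the physically meaningful initial condition — the osmotic
pressure is whatever holds the inflated volume. During the subsequent cap
loop the stiffness field changes only fractions of a percent per step and
ordinary incremental solves apply, with the pressure-update loop providing
the volume feedback.

Two kinetic constants are used by the equations but not tabulated in the
source model: the fixed active-myosin level ($[M]_A$, default 1.5 uM) and
the YAP/TAZ efflux rate ($k_{out}$, default 1 s$^{-1}$), both taken from
the prior whole-cell model lineage and exposed as ordinary parameters.
Quantities that depend on their magnitudes (absolute N/C ratios, absolute
NPC activation levels) should be read as calibrated rather than predicted;
the package's validation targets avoid them.

# What the solver reproduces, and known gaps

On the printed material parameters, free inflation at 820 Pa yields an
outer radius of 5.27-5.28 um and a deformed thickness of 0.117 um; the
finite-element solution agrees with an independent closed-form thick-sphere
quadrature (`balloon_oracle()`) to well under 1%. The parameter table's
footnotes quote 5.0 um / 0.13 um for the same pressure; those three numbers
are mutually inconsistent with the printed $E_1, E_2$ (the exact 1-D
solution gives $P(5.0\,\mu m) = 757$ Pa), so the package reports the
computed values and documents the discrepancy rather than retuning
constants. Similarly, the incompressibility deviation at full inflation is
0.012% — set by $|p|/\phi_0$ with the tabulated $\phi_0 = 10^8$ Pa, and so
not reducible below 0.01% at this load for any formulation with that
penalty. Under flat-substrate compression to $\sigma_{max} = 800$ Pa with
the pressure-update loop, the nucleoplasm loses 49-50% of its inflated
volume, matching the stated $\phi_{inner}$ calibration, and the bilayer
tension stays of order 1 mN/m.

The tabulated "initial" measures (107.5 / 118.4 um$^2$, 152 um$^3$) do not
match any spherical quarter-domain state of the printed geometry (their
area-to-volume ratios are not mutually consistent with a sphere either);
the package computes its own quarter-domain measures (about 84 / 88
um$^2$ and 144 um$^3$ post-inflation) and accepts the tabulated values as
explicit inputs where a test calls for them.

# Problem sizes and the synthetic test fixtures

Production-quality runs use edge lengths of 0.1-0.15 um near the substrate.
The package's own test and validation runs use deliberately coarse
quarter-domain meshes (edge lengths 0.6-1.2 um, roughly 700-2500
tetrahedra): at these sizes an inflation solve takes seconds to a minute
and a full flat-substrate compression a few minutes, while the inflation
benchmark stays within a fraction of a percent of the closed-form oracle.
Pillar indentation at 0.2-um pillar radius is geometrically under-resolved
at these edge lengths; pitch-sweep outputs at test scale are therefore
read as orderings and windows rather than converged values. The
prescribed-deformation fixtures (uniform dilation, uniaxial squash)
exercise the transport splitting exactly, independently of the mechanics.

The synthetic fixtures emulate the study's geometry and load program, not
real microscopy data: there is no stochasticity, no wrinkling or local
bilayer detachment, no chromatin mechanics and no viscoelasticity, so
passing tests demonstrate the solver reproduces *this model's* physics,
not that the model captures every feature of real nuclei.

# Worked example

```{r}
library(nucleomech)

fx <- make_coarse_fixture("flat_coarse", hedge = 0.8, t_end = 300)
cfg <- fx$config
cfg$schedule$sigma_max <- 400
run <- run_simulation(cfg, mesh = fx$mesh)
run$metrics[, c("t", "sigma_cap_Pa", "dP_Pa", "vol_nuc", "yap_nc",
                "npcA_mean", "max_tension")]
```

The volume falls and the osmotic pressure rises as the cap assembles, NPC
activation and the YAP/TAZ N/C ratio climb — the compression-activates-
import axis the model encodes. `run_pitch_sweep()` repeats this over
nanopillar pitches; `critical_pitch()` extracts the stretch-maximizing
pitch.
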