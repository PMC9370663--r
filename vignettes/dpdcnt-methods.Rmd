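---
title: "Coarse-grained DPD simulation of lipid self-assembly on carbon nanotubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained DPD simulation of lipid self-assembly on carbon nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdcnt)
```

## The physical problem

Phospholipids dispersed in water adsorb onto carbon nanotubes (CNTs):
hydrophobic tails seek the graphitic surface, hydrophilic head groups
seek water. Depending on how much lipid is available per unit tube
surface, the adsorbed layer ranges from a sparse submonolayer of
flat-lying molecules through disordered hemimicellar patches to an
organized monolayer in which chains stand perpendicular to the surface.
`dpdcnt` simulates this process with dissipative particle dynamics (DPD)
for dipalmitoylphosphatidylcholine (DPPC) on armchair tubes of four
diameters, and computes the observables that characterize it: adsorption
kinetics, aggregate clustering, cylindrical density profiles, tail
orientation order, and the saturation surface density as a function of
tube curvature.

## Model

### Beads and mapping

Six bead species are used (`bead_types()`): three head beads (`h1`
choline-like, `h2` phosphate-like, `h3` glycerol-like), the hydrocarbon
tail bead `t`, water `w`, and the tube bead `cnt`. One water bead lumps
four water molecules (0.12 nm^3^); one tube bead lumps eight carbon
atoms. A DPPC molecule is twelve beads: the `h1-h2-h3a` backbone, a
linked `h3b`, and two four-bead `t` chains, one per glycerol bead
(`build_dppc_topology()`).

Reduced units are used throughout: lengths in the cutoff $r_C$, energies
in $k_BT$, masses 1. With the reduced bead density $\rho = 3$ the
physical cutoff is $r_C = (\rho \cdot 0.12\,\mathrm{nm^3})^{1/3}$, which
rounds to 0.71 nm (`derive_rc_nm()`). The value is stored at full
precision; printed surface densities in nm^-2^ are obtained by dividing
by $r_C^2$ (`convert_surface_density()`).

### Forces

Between all non-bonded bead pairs within $r_C$ three forces act:

* conservative soft repulsion
  $F^C_{ij} = a_{ij}(1 - r_{ij}/r_C)\,\hat r_{ij}$,
* a random force
  $F^R_{ij} = \sigma (1 - r_{ij}/r_C)\,\theta_{ij}\,\Delta t^{-1/2}\hat r_{ij}$
  with $\theta_{ij}$ a unit-variance Gaussian shared by both members of
  the pair, and
* a dissipative force
  $F^D_{ij} = -\gamma (1 - r_{ij}/r_C)^2 (\hat r_{ij}\cdot v_{ij})\,\hat r_{ij}$.

The random/dissipative pair is the DPD thermostat; it conserves momentum
pair by pair, and the fluctuation-dissipation relation
$\sigma^2 = 2\gamma k_BT$ fixes $\sigma$ once $\gamma$ is chosen. The
repulsion matrix $a_{ij}$ (`default_interaction_model()`) uses 100 for
like beads, 110 for the charged head beads `h1`, `h2` (a mean-field
stand-in for electrostatic repulsion, so no explicit electrostatics are
needed), 130 for the strongly hydrophobic contacts (tail-water,
head-tail, head-tube), and intermediate values for the glycerol bead.
Notably $a_{t,cnt} = 100 < a_{t,w} = 130$: tails prefer the tube over
water, which is the thermodynamic driving force for adsorption.

Bonds are harmonic, $u = \tfrac12 k_{bond}(r - r_0)^2$ with
$k_{bond} = 512\,k_BT/r_C^2$ and $r_0 \in \{0.47, 0.31, 0.59\}$
(`bond_terms()`). Angles use
$u = \tfrac12 k_{angle}(1 - \cos(\theta - \theta_0))$ with
$k_{angle} = 6\,k_BT$; the `h2-h3-h3` kink prefers 120 degrees, all
chain triples 180 degrees (`angle_terms()`). Angle terms are
instantiated only for the tabulated type patterns; consecutive triples
with no tabulated pattern (e.g. `h1-h2-h3`) carry none.

### Bonded-pair exclusion

Directly bonded (1-2) pairs are excluded from the non-bonded forces.
Without this exclusion the soft repulsion displaces the sampled bond
minima far from $r_0$ (the short 0.31 glycerol-glycerol bond would sit
near 0.41). With it, the chain bonds of an isolated molecule sample
their $r_0$ to better than 0.02 $r_C$. Two residual shifts remain and
are physics, not artifacts: 1-3 neighbors still repel (stretching the
crowded head-region bonds by up to ~0.08 $r_C$ in vacuum), and in the
$\rho = 3$ fluid the surrounding pressure compresses all springs by a
few hundredths of $r_C$ (a potential-of-mean-force effect). The test
suite asserts the bare-spring behavior on the chain bonds and bounds the
residual shifts.

## System construction

`system_spec()` describes a system: one tube (diameter from the armchair
chirality: 1.97, 2.67, 3.94 or 6.2 $r_C$ for (10,10) through (34,34);
length 15.5 $r_C$ at full scale), a lipid count, a water-bead count
(20,000 at full scale), and the fixed box length $L_y = 22.5$ along the
tube axis. The perpendicular box lengths are derived at build time so
that mobile beads fill the accessible volume (box minus tube interior)
at $\rho = 3$.

Tube beads are placed on a triangular lattice wrapped onto the cylinder
at one eighth of graphene's atom areal density (38.2/8 ≈ 4.77 nm^-2^,
converted to $r_C^{-2}$); the lattice detail is a free choice — only the
diameter, length and areal density enter the physics. The printed
reduced diameters are used verbatim rather than recomputed from the
chirality, because the four printed values are not mutually consistent
with a single carbon-carbon geometry. Tube beads are frozen: excluded
from integration and from thermostat pairs, while their conservative
repulsion still acts on mobile beads.

Lipids are inserted as rigid copies of an extended reference
conformation with random position and orientation, then water beads, by
grid-accelerated rejection sampling with a minimum inter-bead distance
of 0.5 $r_C$ (an initialization nicety — the potentials are soft) and a
hard exclusion of the tube interior over its axial extent. Beads may
diffuse into wide tubes during dynamics; only the initial state excludes
them. Velocities are drawn from the Maxwell distribution at $k_BT = 1$
with the net momentum removed. Builds are bit-reproducible given the
seed.

`table2_catalog()` enumerates the 44 studied systems (4 tubes x 11
lipid loadings from 10 to 500), carrying the reported equilibrium box
sizes as metadata. `scaled_preset()` shrinks a cataloged system to a
desk-scale miniature: box volume scaled by $s$, bead counts by $s$, tube
length and $L_y$ by $s^{1/3}$, tube diameter kept (it is intensive).

What the generator emulates: composition, density, geometry and the
random dispersed initial state of the study systems. What it does not:
atomistic chemistry (bead-level resolution only), explicit charges
(folded into $a_{ij}$), tube flexibility, and — in scaled presets — the
full separation between tube length and box length, so end effects are
relatively larger at small scale. Passing tests on scaled systems
therefore demonstrate correct mechanics and qualitative phase behavior,
not quantitative agreement with full-scale runs.

## Integration

The engine uses the modified velocity-Verlet scheme standard in DPD with
prediction parameter $\lambda = 0.65$: positions advance with the
current force; velocities are predicted as
$\tilde v = v + \lambda\,\Delta t\,f$ before the new force (whose
dissipative part needs velocities) is evaluated; the corrector is the
trapezoidal mean of old and new forces. The default time step is
$\Delta t = 0.02$: the stiff $k_{bond} = 512$ bonds make the common DPD
choice of 0.04 marginal, and at 0.02 the measured kinetic temperature
stays within about 1% of the target across $\gamma \in \{2, 4.5, 9\}$.
The default $\gamma = 4.5$ is standard DPD practice; $\sigma$ is always
derived from it. Any integrator that passes the determinism, momentum
and thermostat tests is conformant.

Pair search uses linked cells with a half stencil, falling back to an
exhaustive minimum-image loop for boxes under three cells per dimension;
the cell path is tested pair-for-pair against the exhaustive oracle. The
thermostat noise stream comes from a seeded generator; one Gaussian is
drawn per interacting mobile pair per step, shared by both pair members,
so runs are exactly reproducible. Coincident beads (a measure-zero event
under soft potentials) receive a deterministic fallback direction along
x and are counted in a warning.

## Pressure coupling

The study protocol fixes $L_y$ and lets $L_x$, $L_z$ respond
independently to keep the perpendicular pressure components at a
set-point. The set-point is not a free parameter of the physics: it must
be the pressure of the model's own water at $\rho = 3$, so that the
barostat reproduces the correct density. `calibrate_pressure()` measures
it from a short pure-water NVT run; the result is within 10% of the
literature excess-pressure estimate
$\rho k_BT + 0.101\,a\rho^2 \approx 94$ for $a = 100$, $\rho = 3$.

Coupling is Berendsen-style per axis:
$\mu_\alpha = [1 - \kappa\,(\Delta t/\tau_p)(P_0 - P_{\alpha\alpha})]^{1/3}$
with relaxation constant $\tau_p = 10$ reduced time units and an
effective compressibility prefactor $\kappa = 0.016$ (the DPD-water
value at this state point, $1/(\rho\,\partial P/\partial\rho)$). Scale
factors are clamped to $[0.99, 1.01]$ per step for robustness. Mobile
positions rescale affinely; the frozen tube translates rigidly with the
scaled box center so its diameter is never distorted. Under this scheme
a pure-water NPT run holds the density at 3 to well within 2%.

## Observables

All distances are measured to the cylinder through the tube bead
centers; the 1.06 $r_C$ adsorption cutoff is of the order of the
non-bonded range, consistent with that convention, and is exposed as a
parameter everywhere.

* **Adsorption** (`adsorbed_fraction()`): a lipid is adsorbed when any
  of its twelve beads is within the cutoff of the surface in absolute
  distance; inner-surface contacts (relevant for the wide (34,34) tube)
  count too and are flagged separately. Beads beyond the tube ends use
  the distance to the nearest rim circle.
* **Clustering** (`cluster_lipids()`): union-find over the graph whose
  edges join lipids with any tail-bead pair closer than 1.0 $r_C$;
  verified against a breadth-first oracle.
* **Density profiles** (`radial_density_profile()`): histogram of
  surface distance restricted to the tube's axial extent, normalized by
  cylindrical shell volumes (default bin 0.1 $r_C$); density times shell
  volume reconstructs the mean counted beads exactly.
* **Orientation** (`orientation_distribution()`): per chain, the vector
  from the first to the terminal tail bead against the outward radial
  normal at the chain midpoint; folded to [0, 90] degrees (0 = radial,
  90 = tangent), the two chains of a lipid averaged, histogrammed in 5
  degree bins as plain normalized frequency *without* a $\sin\theta$
  correction — an isotropic sample therefore shows the sine baseline,
  which the tests document.
* **Equilibration** (`detect_equilibration()`): earliest frame from
  which consecutive sliding-window means (window 10% of the series)
  differ by less than a relative tolerance; default $10^{-3}$. The
  saturation estimator passes 0.05 instead, because the adsorbed *count*
  fluctuates by a few lipids even at saturation as molecules exchange
  with the solution, and the stricter tolerance misreads that as drift.
* **Saturation density** (`saturation_density()`): post-plateau mean
  adsorbed count divided by the bead-center cylinder area $\pi D L$. Two
  conventions are reported: `rho_s` counts outer-surface lipids only;
  `rho_s_total` also counts inner-surface adsorbates over the same outer
  area. The materials-balance reading of a saturation density (how much
  lipid the tube takes up per unit surface) cannot distinguish the two
  for wide tubes, so both are kept; narrow tubes admit no interior
  lipids and the conventions coincide. Estimates are refused when no
  plateau exists. Because the adsorbed count keeps creeping slowly
  toward full saturation long after the noise-level plateau test first
  passes, the auto-detected estimate averages the final third of the
  trajectory — the most-converged segment — rather than everything after
  the first detection; an explicitly supplied window is used verbatim.

## Numerical choices and degenerate inputs

* Angle forces regularize $\sin\theta$ away from zero (bound $10^{-8}$)
  for colinear geometries.
* Coincident beads get a fixed fallback direction with a warning.
* Non-finite coordinates abort the run with the step and bead index.
* On-axis chain midpoints (undefined radial normal) are assigned the
  tangent angle by convention.
* Zero-length tail vectors are an error (they cannot arise from bonded
  dynamics).
* Histogram outputs carry their normalization so raw counts are
  recoverable.

## Problem sizes

The full study scale (about 26,500 beads for 1.3x10^5 steps, 44
systems) is a batch-compute workload. The package's own test and
demonstration workloads are chosen at desk scale: water boxes of a few
hundred to a thousand beads for thermostat and pressure checks, and
1/8-volume scaled systems (tube length 7.75, two to four thousand water
beads) with lipid loads of 1.1-1.4 times the tube's capacity for the
adsorption and saturation studies, integrating for (2-9)x10^4 steps.
The excess is kept moderate and the reservoir dilute on purpose: with a
large surplus in a small box, the excess lipids assemble into a
box-spanning bilayer that docks onto the tube and strips monolayer
coverage — the same monolayer/bilayer coexistence the full-scale systems
show, but destructive at small box sizes. At these sizes
the saturation density is an intensive quantity and lands near its
full-scale value, though rim effects of the shorter tube and the smaller
reservoir bias it low by of order 10-20%; the curvature *ordering*
across tube diameters is robust to the scaling. The orientational
ordering *transition* itself — the second, reorientation step of the
two-step mechanism — is not reliably reachable at these scales: it
requires coverage above roughly 0.9 of saturation, and in the small box
the competing spanning-bilayer phase (which at full scale forms at the
tube ends without disturbing the monolayer) can consume monolayer lipids
first. The orientation observable's response to ordering is therefore
exercised on geometric archetype fixtures, and the dynamical transition
is a full-scale computation.

## Limitations

* No electrostatics beyond the mean-field $a_{ij}$ adjustment.
* Rigid, frozen, single-walled, uncapped tubes only; single lipid
  species.
* Berendsen-style coupling does not sample the rigorous NPT ensemble
  (box fluctuations are damped); it is used for its robustness, as only
  mean densities enter the analysis.
* No physical-time mapping is claimed: outputs use reduced time only.
* Helical wrapping order, free-energy profiles and bilayer validation
  are out of scope.
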