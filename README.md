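# dpdcnt

Coarse-grained dissipative particle dynamics (DPD) simulation and
analysis of dipalmitoylphosphatidylcholine (DPPC) self-assembly on
carbon nanotubes (CNTs).

Amphiphilic lipids dispersed in water coat carbon nanotubes: hydrophobic
tails adsorb on the graphitic surface, hydrophilic heads face the water.
As the available lipid per unit tube surface grows, the adsorbed layer
passes from a sparse submonolayer of flat-lying molecules through
disordered hemimicellar patches to an organized monolayer with chains
standing perpendicular to the surface — a two-step process in which
densification precedes orientational ordering. The saturation surface
density depends on tube curvature. `dpdcnt` is for computational
biophysicists and soft-matter modelers who want to simulate and quantify
this process at desk scale in R.

## What is inside

* **Model**: the 12-bead DPPC bead-spring model (beads `h1, h2, h3, t`),
  four-to-one water mapping, eight-to-one CNT mapping, the full symmetric
  repulsion matrix `a_ij`, harmonic bonds (`k = 512 kBT/rC^2`) and cosine
  angle bending (`k = 6 kBT`), all in reduced units with
  `rC = (3 x 0.12 nm^3)^(1/3) ~ 0.71 nm`.
* **Forces**: soft conservative repulsion
  `F^C = a_ij (1 - r/rC) r_hat`, plus the momentum-conserving DPD
  thermostat pair — random force
  `F^R = sigma (1 - r/rC) theta dt^(-1/2) r_hat` and dissipative force
  `F^D = -gamma (1 - r/rC)^2 (r_hat . v) r_hat` with
  `sigma^2 = 2 gamma kBT`.
* **Engine** (C++ core): cell-list pair search, modified velocity-Verlet
  integration (`lambda = 0.65`, `dt = 0.02`), frozen tube beads, and
  Berendsen-style anisotropic pressure coupling on the two box axes
  perpendicular to the tube, with the set-point calibrated from the
  model's own water (`calibrate_pressure()`).
* **Builder**: the 44-system study catalog (`table2_catalog()`: four
  armchair tubes of reduced diameter 1.97-6.2, lipid loads 10-500,
  20,000 water beads) and reproducible scaled-down presets
  (`scaled_preset()`).
* **Observables**: adsorbed fraction at the 1.06 rC surface cutoff,
  union-find aggregate clustering, cylindrical-shell density profiles,
  tail orientation histograms (0 deg = perpendicular to the surface),
  equilibration detection, and the saturation surface density `rho_s`.
* **IO/CLI**: extended-XYZ plus a lossless full-precision archival text
  format, YAML configs and run manifests, CSV observables, and a
  `dpdcnt` command-line pipeline (`catalog`, `build`, `run`, `analyze`,
  `demo`) in `inst/cli/`.

## Worked example

A 1/8-volume miniature of the CNT(20,20) system with a high lipid load,
run for 20,000 steps under NPT, shows the adsorption kinetics and the
resulting coverage:

```r
library(dpdcnt)

spec <- scaled_preset("cnt2020_500", scale = 0.125, seed = 11)
cfg  <- build_system(spec)
cfg
#> DPD configuration: 3496 beads (252 frozen), 62 lipids, 2500 water
#>   box 10.22 x 11.25 x 10.22 rC
#>   tube: radius 1.970, length 7.78 rC, 252 beads

p0 <- calibrate_pressure(seed = 11)        # ~ 89 (reduced units)
st <- integrator_settings(n_steps = 20000, seed = 11)
traj <- dpd_run(cfg, st, barostat = barostat_settings(p0),
                sample_every = 500)

ads <- adsorbed_fraction(traj)
round(ads$fraction_adsorbed[c(1, 5, 10, 20, 41)], 3)
#> [1] 0.258 0.500 0.726 0.758 0.742
```

The fraction of the 62 lipids touching the tube surface climbs from 0.26
at insertion to a plateau around 0.74: the surface fills by one-by-one
attachment and aggregate docking, then exchanges molecules with the
solution. `cluster_lipids(traj)` reports the surface-attached aggregate
and the remaining micelles, and `orientation_distribution(traj)` gives
the tail-angle histogram of the adsorbed layer (at this sub-saturation
coverage, mostly tangent angles near 90 degrees).

On an oversupplied tube the post-plateau saturation density follows:

```r
sat <- saturation_density(traj_oversupplied)   # refuses unequilibrated runs
sat$rho_s        # lipids per rC^2 on the outer surface
sat$rho_s_total  # including inner-surface adsorbates (wide tubes)
```

Saturation densities rise with tube curvature; converted with
`convert_surface_density()`, a reduced density of 1.05 is about
2.07 nm^-2.

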