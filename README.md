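# poregate

Post-processing toolkit for molecular-simulation studies of **hydrophobic
gating** in ion channels — in particular channels (such as the
large-conductance Ca²⁺-activated K⁺ channel) whose pore closes not by steric
occlusion but by spontaneous dewetting of a hydrophobic segment below the
selectivity filter, a process in which lipid acyl tails entering the pore
through lateral fenestrations can take an active part.

The package is aimed at simulators who have trajectories (or toy-sampler
output) in hand and want the standard analysis battery for this problem:

* **Pore radius profiles** r(z) by the inscribed-sphere construction,
  `r(z) = max_c min_i (|c − x_i| − vdw_i)`, computed deterministically
  (coarse-to-fine grid search + local refinement) with or without lipid atoms
  in the include set, with block-analysis errors over frames.
* **Deep-pore occupancy**: water and lipid-tail-carbon counts in a cylindrical
  deep-pore volume (DPV: radius 0.7 nm, height 0.5 nm, top face 1.2 nm below
  the selectivity-filter center of mass), sharp or Fermi-smoothed
  (`f(d) = 1/(1 + e^{d/λ})`, λ = 3 Å by convention), wet/dry state
  classification, joint −log density maps, waters in contact with the
  innermost filter ion, and annular-lipid contact records.
* **Helix tilt**: S6 (pore-lining) helix axes by SVD of the Cα trace and tilt
  distributions θ = arccos|a·ẑ| pooled over frames and subunits.
* **Hydration free energies**: restrained-sampling mean forces
  `−k⟨Ñ − N⟩` (harmonic restraint `k/2 (N − Ñ)²` on the smoothed water
  count), block-average standard errors, thermodynamic integration (Euler or
  trapezoid) into F(N) with propagated errors, and metadynamics reweighting
  (`w ∝ e^{+V(s)/k_BT}`) of a lipid-density collective variable.
* **Synthetic data with exact ground truth**: channel-like fixtures with
  scripted wetting/dewetting events, Metropolis samplers on declared
  free-energy landscapes, Langevin metadynamics traces with recorded hill
  lists, and ideal helices at prescribed tilts — so every estimator can be
  validated end to end without any simulation engine.

Structures are read from PDB/GRO, trajectories from multi-model PDB or DCD;
atoms are addressed with a small selection language
(`"resname TIP3 and name OH2"`, `"name C2* C3*"`, `"resid 305:320"`).

## Worked example

A 25-frame synthetic channel starts wet (14 waters in the DPV); at frame 13
three lipid tail carbons breach the pore and 13 waters leave:

```r
library(poregate)

fx <- build_channel_fixture(
  n_frames = 25, n_water_dpv = 14,
  lipid_entry = list(frame = 13, lipid = 1, tail = "unsaturated", n_carbons = 3),
  water_exit  = list(frame = 13, n = 13), seed = 1)

m   <- fx$manifest
occ <- occupancy_series(fx$series, m$selections$water, m$selections$lipid_tails,
                        m$selections$sf, reference = m$selections$reference)
head(occ[occ$time >= 0.22, ], 3)
#>    time n_water n_lipid
#> 12 0.22      14       0
#> 13 0.24       1       3
#> 14 0.26       1       3

st <- occupancy_stats(occ)
#> mean n_water = 7.24 (sd 6.63), mean n_lipid = 1.56, r = -1.00
attr(wet_dry_classify(occ), "switches")
#> [1] 13
```

The counts jump exactly at the scripted frame, water and lipid occupancy are
perfectly anticorrelated, and the wet→dry classifier reports the switch at
frame 13.

Free energies from restrained sampling of a known quadratic landscape
F(N) = 0.25 (N − 10)²:

```r
ws <- sample_restrained_series(function(N) 0.25 * (N - 10)^2, k = 1,
        targets = seq(0, 20, length.out = 40), n_samples = 22000, seed = 1)
prof <- integrate_profile(lapply(ws, mean_force), method = "trapezoid",
                          abscissa = "mean_position")
profile_features(prof)$global_min
#> global minimum at N = 10.18, F = -11.113 kcal/mol
```

The recovered vertex sits at the true minimum (N = 10) to within the window
spacing, and the profile matches the parabola with RMSE ≈ 0.01 kcal/mol.

A YAML-configured pipeline driver (`run_subcommand()`, stages `fixture`,
`radius`, `occupancy`, `tilt`, `rmd-fe`, `metad-fe`, `contacts`, `report`)
writes TSV/JSON artifacts per stage; `inst/scripts/poregate` is a thin
command-line wrapper around it.

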