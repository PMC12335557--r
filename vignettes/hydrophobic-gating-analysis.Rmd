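---
title: "Methods: pore hydration, lipid penetration, and hydration free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore hydration, lipid penetration, and hydration free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

# The problem

In several K⁺ channels the closed state shows no steric occlusion of the
pore: the pore-lining helices leave a lumen wide enough for water and ions,
yet conduction stops. The accepted explanation is *hydrophobic gating* —
spontaneous, reversible dewetting of a hydrophobic stretch of the pore — and,
in channels with lateral fenestrations between the pore-lining (S6) helices,
lipid acyl tails that breach the lumen and actively displace water.
`poregate` implements the analysis battery for this picture: where is the
pore narrow (and how much narrower when intruding lipid atoms are counted as
part of the wall), how many waters and lipid carbons occupy the deep pore,
when does the pore switch between wet and dry, how tilted are the S6 helices
(tilt controls fenestration size), and what is the free-energy profile of
pore hydration.

# Data model and conventions

A configuration (`atom_frame`) is an n×3 coordinate matrix in **angstrom**
plus per-atom metadata (name, residue name/number, segment, element, vdW
radius); a trajectory (`frame_series`) stacks frames of constant topology
with strictly increasing times in **ns**. Energies are in **kcal/mol**,
temperatures in kelvin (k_B = 0.0019872041 kcal/mol/K). Coordinates are used
in a frame-local orthonormal basis; periodic images are **not** unwrapped —
all counting regions are assumed to sit well inside the box, which holds for
a channel centered in a membrane patch but not for analyses near the box
boundary (a documented limitation).

vdW radii come from a bundled Bondi-type element table (`vdw_radii()`);
unknown elements get a declared default (1.7 Å) with a warning, and the
table is swappable per call. Water is counted by its oxygen position; "lipid
carbon atoms" means acyl-tail carbons only, selected by atom-name template
(`C2*` = sn-2 oleoyl, unsaturated; `C3*` = sn-1 palmitoyl, saturated, in
CHARMM-style naming), configurable for other lipid types. All counting
regions are closed sets: an atom exactly on a boundary counts as inside.
This is a measure-zero convention that only matters for hand-built inputs,
but it is fixed so that fixtures are reproducible.

Supported formats are PDB and GRO for structures, multi-model PDB and DCD
for trajectories (read via `bio3d`; multi-model PDB written by the package).

# Pore axis and radius profile

The pore axis is anchored at the selectivity-filter (SF) center of mass
(z = 0 there, z negative toward the cytosol) and directed along the dominant
principal axis of the SF atom stack. The sign is fixed by a reference
selection on the cytosolic side (axis points from reference toward SF); with
no reference, the laboratory +z convention is used. The axis estimate
assumes the SF selection is taller than it is wide — true for the stacked
coordination rings of a K⁺-channel filter; for a flat selection the dominant
principal axis would lie in-plane.

The radius at an axial slice z is the inscribed-sphere clearance

r(z) = max_c min_i ( |c − x_i| − vdw_i ),

maximized over in-plane centers c. Atoms with |z_atom − z| ≤ vdw + dz
contribute through the full 3D point-to-sphere distance (a sphere cut by the
slice plane), not a 2D projection. The classic implementation maximizes by
simulated annealing; we replace that with a deterministic search —
coarse grid (1 Å) over the search disc, fine grid (`grid_spacing`, default
0.2 Å) around the best coarse point, Nelder–Mead polish
(`reltol = 1e-12`), each slice seeded with the previous slice's maximizer —
trading annealing's stochasticity for bit-reproducibility. On ≤200-atom
fixtures the result agrees with an exhaustive 0.02 Å dense-grid search to
within 0.05 Å (asserted in the tests), which is the accuracy claim of the
profiler.

Two radius-like parameters are deliberately distinct:

* `search_radius` (default 5 Å) — the in-plane search disc around the axis.
  It must be pore-sized: with an unbounded disc the maximizer of an *open*
  wall (and any real channel has lateral fenestrations) escapes past the
  wall into bulk, where clearance grows without meaning.
* `cap` (default 12 Å, beyond pore scale) — the largest radius ever
  reported; slices with no atoms in the slab report the cap with a flag,
  meaning "no pore constriction here".

Because the maximum of a min-distance field sits at a non-smooth point
(equidistant from several atom spheres), derivative-free polish localizes it
to a few 10⁻³ Å, not machine precision; rigid-transform equivariance of the
profile is therefore asserted at 5·10⁻³ Å — two orders below the 0.05 Å
accuracy claim. Enlarging the include set (protein → protein + lipids) can
only shrink the profile, which the tests assert pointwise.

Per-frame profiles are averaged with standard errors from non-overlapping
block means (see below), the standard guard against serial correlation in
trajectory averages.

# Occupancy, smoothed counting, and wet/dry states

The deep pore volume (DPV) is a cylinder coaxial with the pore: radius
0.7 nm, height 0.5 nm, top face 1.2 nm below the SF center of mass
(`dpv_region()`, all overridable). It is recomputed per frame from that
frame's SF selection, so the counting region tracks the protein.

The restrained-sampling collective variable needs a *continuous* count, so
`smooth_count()` implements a separable product of per-axis Fermi factors
f(d) = 1/(1 + e^{d/λ}) at signed distance d outside each box face, with
λ = 3 Å the conventional smoothing. The exact kernel used by
volumetric-map implementations in MD engines is not standardized; the
product form is our choice because it reproduces the sharp indicator exactly
at λ = 0 and the stated λ-semantics (half weight on a face, ~1 deep
inside). The counting box is meant to be set from the min/max extent of the
two residue rings flanking the hydrophobic cavity, somewhat larger than the
cavity itself to keep the boundary smoothing away from the region of
interest.

Equilibrium statistics (`occupancy_stats()`) discard frames before `t_min`
(in production-scale trajectories the convention is to discard the first
200 ns; for short synthetic series the cutoff is rescaled through the
pipeline configuration). 1D and 2D kernel density estimates use Scott's
bandwidth by default; the joint water/lipid map is reported as
−log(density) shifted so its global minimum is zero, the conventional way of
displaying wet/dry basins. Frames are classified wet when
n_water ≥ 5 — the default threshold sits in the gap between the dewetted
(~0–1 waters) and hydrated (~14–16 waters) regimes and is configurable.

`sf_contact_waters()` counts water oxygens within 3.6 Å (inclusive) of the
innermost filter ion — a proxy for whether the filter remains in contact
with cavity water. `annular_lipid_contacts()` records lipids simultaneously
within 6 Å (heavy-atom minimum distance) of the S6 helices, the R329 side
chains and the K392 side chains, with head-group distances, a
tail-saturation label, a DPV-penetration flag and tail-atom xy projections
in the axis frame. When no tail penetrates, the record is labelled by the
tail closest to the pore axis — a tie-break that keeps the label
well-defined for two-tailed lipids.

The lipid-density collective variable (`lipid_density_cv()`) is the
(optionally Fermi-smoothed) count of tail carbons in a 0.7 nm sphere at the
pore-facing phenylalanine ring; because it is ambiguous whether such a CV
should be reported as a raw count or per volume, both are exposed
(`normalize = TRUE` divides by the sphere volume in nm³).

# Helix tilt

The helix axis is the dominant right singular vector of the centered Cα
trace, oriented from first to last residue; for regular helices this agrees
with local-axis averaging schemes to within about a degree, and is simpler
and deterministic. Finite helices with a fractional number of turns have an
intrinsically anisotropic in-plane point distribution, which biases the SVD
axis by up to ~0.4° at 30 residues — the reason tilt-recovery tolerances are
0.5°, not zero. Tilt is θ = arccos|a·v| ∈ [0°, 90°]: the absolute dot
product makes θ invariant under axis sign flips. S6 helices are kinked in
the channels of interest, so the axis can be fit over a residue sub-window
(`residue_window`) to analyze the segment below the kink; the default is the
full selection because no canonical window is established. Distributions are
pooled over frames and subunits with a Scott-bandwidth KDE and make no
unimodality assumption (per-subunit heterogeneity shows up as bimodality).

# Restrained-sampling free energies

Restrained MD adds k/2 (N − Ñ(r))² to the Hamiltonian, with Ñ the smoothed
count and N the target filling level. Per window, the free-energy gradient
is estimated as −k⟨Ñ − N⟩ over samples past the burn-in, its error as
k · block SE. Defaults mirror standard practice for this protocol: k = 1
kcal/mol per count², samples every 1 ps, 4 ns windows with the first 2 ns
discarded, 100 ps blocks, 40 windows per profile. The block SE is the
standard deviation of non-overlapping block means over √(number of blocks),
discarding a trailing partial block; it is calibrated on iid data and
conservative (larger) under serial correlation, both asserted in tests.

**Integration abscissa — a deliberate design choice.** Integrating the mean
forces over the *target* grid reconstructs the spring-smoothed profile
G(N) = −k_BT ln ∫ e^{−β[F(x) + k/2 (x−N)²]} dx, which converges to F only
as the spring stiffens; at k = 1 and soft landscapes the distortion is
substantial (for F = a/2 (x−N0)², G has curvature ak/(a+k)). But the same
estimator satisfies an exact identity for locally quadratic F:
−k⟨Ñ − N⟩ = F′(⟨Ñ⟩). Evaluating each window's force at its *mean sampled
position* and integrating over that (non-uniform) grid — umbrella
integration, in effect — recovers F itself at any k. `integrate_profile()`
exposes both (`abscissa = "target"` or `"mean_position"`); the default is
the target grid (the literal protocol), while landscape-recovery validation
uses mean positions. The integrator is Euler (left Riemann, the named
method) by default with the trapezoid as an option; the trapezoid is exact
for linear forces and is used wherever quantitative recovery is asserted.
Errors propagate in quadrature, √Σ(se_i ΔN_i)², so they grow monotonically
with distance from the integration origin. Duplicate targets are an error;
unsorted windows are sorted with a warning; the profile is shifted to zero
at a reference grid point (first point by default).

# Metadynamics reweighting

Given a CV trace and its deposited Gaussian bias (a hill list or a
precomputed evaluator), each sample is weighted by e^{+V_final(s_i)/k_BT}
with V_final the total bias at the end of the run — the *last-bias
approximation*, the simplest defensible reweighting estimator; the exact
estimator used by any given study is rarely stated, so the choice is made
explicitly here rather than inferred. A weighted histogram on the requested
grid gives p̂(s) and F = −k_BT ln p̂, shifted so the global minimum is zero
(the plotted convention for reweighted profiles). With zero bias the
estimator reduces *exactly* to the plain histogram — asserted as an identity
in the tests. A histogram (not a KDE) is used precisely so that this
degenerate case is exact. Errors come from block analysis over contiguous
time blocks (default 5). Well-tempered and standard metadynamics bias
records are both accepted since only the final bias enters. The default
temperature is 300 K and configurable, since production temperatures vary
and the trace rarely records it.

`profile_features()` reports local minima, saddle points and barrier heights
(saddle minus the shallower minimum). Minima separated by barriers below
`min_barrier` are merged into the deeper partner — statistical roughness of
histogram estimates otherwise fragments a well into spurious minima; 0.5
kcal/mol (below k_BT·ln anything interesting at 300 K ≈ 0.6) is used in
validation.

# What the synthetic generators emulate — and what they do not

`build_channel_fixture()` produces a channel-shaped point set: an SF marker
stack (tall and narrow, so its principal axis is the pore axis), a cytosolic
reference marker, a cylindrical shell of carbon rings as "protein", an
innermost-ion marker, single-site waters, coarse two-tailed lipids with
phosphate/head markers, contact-site markers (R329/K392/S6), and S6 helices
at prescribed tilts. Scripted events relocate waters out of, and lipid tail
carbons into, the deep pore volume at declared frames. Placements are
deterministic given the seed, margins keep every placed atom at least 0.5 Å
from region boundaries, and the returned manifest describes the emitted
frames *exactly* — that exactness is the module's entire contract and is
what the counting tests assert. The fixtures emulate the *geometry and
bookkeeping* of a gating trajectory (counts, events, contacts, tilts), not
its physics: no thermal motion (coordinates are rigid between events), no
real lipid conformations, no solvent structure, no force field. Passing
counting tests therefore demonstrates correctness of the estimators, not
realism of the data.

`sample_restrained_series()` draws Metropolis samples from
exp(−β[F(N) + k/2 (N−N*)²]) on the continuous N line (continuous because
the restraint acts on a smoothed count), with proposal width 2√(k_BT/k) and
recorded acceptance. `sample_metad_trace()` integrates an overdamped
Langevin walker (Euler–Maruyama, numerical landscape gradient, analytic
hill gradient) with periodic Gaussian deposition and optional reflecting
bounds; zero hill height degenerates to unbiased sampling. Both are
bit-reproducible given a seed. These samplers are exact for their stated
distributions but carry none of the kinetics of molecular dynamics — window
autocorrelation times, for instance, are set by the proposal width, not by
water dynamics.

Validation problem sizes, chosen to make statistical tolerances comfortable
while keeping the whole suite fast: 40 windows × 2×10⁴ post-burn-in samples
for quadratic-landscape recovery (RMSE < 0.15 kcal/mol asserted); 40
windows × 5×10³ samples at k = 10 for the double well (wells at 2 and 14
within 0.5, 3 kcal/mol barrier within 0.3); 6×10⁴ samples for reweighting
(wells within 0.5 kcal/mol); 10⁴ samples for block-SE calibration (within
30% of σ/√n). The double-well restraint k = 10 kcal/mol per count² is a
deliberate condition: stiff restraints keep the window distribution narrow
relative to the landscape's curvature, where the mean-position identity is
most accurate.

# Pipeline

`run_subcommand()` drives the stages (`fixture`, `radius`, `occupancy`,
`tilt`, `rmd-fe`, `metad-fe`, `contacts`, `report`) from a YAML
configuration merged over documented defaults (`default_config()`); every
stage writes TSV artifacts with parameter-recording header comments plus
JSON summaries, logs to stderr, and removes partial outputs on failure.
`report` collates whatever stage outputs exist into one versioned JSON
summary. The same configuration and seed give byte-identical numerical
outputs. A thin command-line wrapper lives at `inst/scripts/poregate`.

# Known limitations

* Straight pore axis: no curved centerlines; meandering pores would need a
  different profiler.
* No PBC unwrapping; regions must not straddle the box boundary.
* XTC trajectories are not read (no R reader available); use DCD or
  multi-model PDB.
* The SVD helix axis is a whole-segment estimate; strongly kinked helices
  should be analyzed per segment via `residue_window`.
* The last-bias reweighting estimator ignores the time dependence of the
  bias offset c(t); for quickly converged bias this is second-order, but a
  time-dependent estimator would be the next refinement.
* Momenta are never represented: every analysis here is configurational.
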