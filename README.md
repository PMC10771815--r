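# polydroplet

Coarse-grained simulation and analysis of polymer conformations at the
interface of phase-separated droplets.

Biomolecular condensates formed by liquid–liquid phase separation are
bounded by an interface between a polymer-rich dense phase and a dilute
phase, and the chains crossing that interface adopt conformations that
differ from the droplet interior: they become more compact, their ends are
enriched at the surface, and most segments lie tangential to it. This
package is for researchers who want to quantify those effects in
coarse-grained simulations — of hydrophobic homopolymers as minimal models
of prion-like low-complexity domains, or of their own bead-level
trajectories read from standard text formats.

## What it provides

- **Simulator** (`run_langevin`, `run_bulk_p0`, `droplet_study`,
  `bulk_study`): BAOAB Langevin dynamics for implicit-solvent bead-spring
  chains with hydropathy-scaled Lennard-Jones (Ashbaugh–Hatch) pair
  interactions, harmonic bonds `U = k (r − r0)²`, and optional
  Debye–Hückel electrostatics; a constant-pressure (P = 0) bulk ensemble
  via Monte Carlo volume moves provides the interface-free reference.
- **Interface geometry** (`find_largest_cluster`, `droplet_center`,
  `radial_concentration_profile`, `fit_tanh_profile`, `asphericity`):
  periodicity-safe droplet detection and the four-parameter interface fit

  c(d_COM) = (c_dense + c_dilute)/2 − (c_dense − c_dilute)/2 · tanh((d_COM − d_MID)/δ),

  where d_COM is the distance from the droplet's centre of mass, c_dense
  and c_dilute the phase concentrations, d_MID the interface midpoint, and
  δ its width; the interface region defaults to the central 80 % traversal,
  d_MID ± 1.0986 δ.
- **Conformation analysis** (`chain_records`, `rg_distribution_by_bin`,
  `segment_records`, `segment_occupancy`, `segmental_rg_profile`,
  `contact_profile`): radius of gyration `Rg² = N⁻¹ Σᵢ |rᵢ − r_com|²` and
  end-to-end distances for chains and for every contiguous segment of
  length `n_seg` (indexed by its middle bead), occupancy of segment indices
  by region, and inter-/intrachain contact profiles.
- **Orientation analysis** (`orientation_records`, `angle_profile`,
  `folded_angle`, `isotropic_mean_angle`, `theta_min`): the angle θ between
  the segment-to-centre vector and the segment end-to-end vector, folded
  into [π/2, π] (π/2 = tangential, π = perpendicular), with the isotropic
  reference π − 1 ≈ 2.1416 rad and the chord-geometry bound
  θ_min = π/2 + arcsin(Re / 2R).
- **Synthetic droplets** (`synthetic_droplet_spec`,
  `generate_synthetic_droplet`, `generate_noisy_profile`): configurations
  with planted density, compactness, end-enrichment and orientation
  structure, so every analysis stage has a parameter-recovery test.
- **Pipeline** (`run_pipeline`): simulate/generate/read → interface →
  conformations → orientation from one config, with CSV/JSON outputs and a
  hashed run manifest.

## Worked example

A synthetic droplet with a planted interface at d_MID = 60 (reduced length
units), width δ = 12, dense phase 2000 mM and end-segment enrichment:

```r
library(polydroplet)

sp <- synthetic_droplet_spec(chain_length = 20, b = 1.5, c_dense = 2000,
                             c_dilute = 0, d_mid = 60, delta = 12,
                             end_enrichment = 3, seed = 7)
traj <- generate_synthetic_droplet(sp, n_frames = 20)
traj
#> md_trajectory: 20 frames, 1200 beads (60 chains), units=reduced

prof <- radial_concentration_profile(traj, bin_width = 4)
fit <- fit_tanh_profile(prof)
#> Warning: fitted c_dilute < 0; clipped to 0
fit
#> interface_fit: c_dense=2073  c_dilute=0  d_mid=58.4  delta=12.64
#>   interface region [44.51, 72.28] (coverage 0.80)  [c_dilute clipped to 0]
```

The fit recovers the planted parameters: the dense phase within ~4 %, the
midpoint within one chain radius of gyration and the width within its
Rg-broadened tolerance (the generator plants the tanh law at the chain-COM
level, so the bead-level profile is that law smeared by the chain form
factor). The empty dilute phase comes back as a slightly negative
least-squares estimate, clipped to 0 and flagged — the fit's documented
rule. Orientation statistics against the isotropic reference:

```r
orc <- orientation_records(traj, n_seg = 20)
ap <- angle_profile(orc, seq(0, 90, 15), min_count = 30)
round(ap$mean_theta, 3)
#> [1] 2.140 2.211 2.182 2.162 2.180
isotropic_mean_angle()
#> [1] 2.141593
```

The innermost bin sits at the isotropic reference π − 1; the outer bins
cover the shell feeding the planted end enrichment, where chain ends turn
radially outward and the mean angle rises above π − 1. With
`end_enrichment = 0` every bin sits at the reference (one of the package's
acceptance checks).

For a real molecular-dynamics droplet, `droplet_study(seed = 1)` runs the
packaged desk-scale protocol (20 strongly cohesive chains of 20 beads,
reduced units) and returns the trajectory, profile and interface fit in one
call; about 1.5 minutes on one CPU.

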