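---
title: "Polymer conformations at droplet interfaces: model, methods and design choices"
author: "polydroplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymer conformations at droplet interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

Biomolecular condensates formed by liquid–liquid phase separation have an
interface dividing a polymer-rich dense phase from a dilute phase, and the
conformations of the chains at that interface differ measurably from those
in the droplet interior. `polydroplet` provides the full workflow needed to
study this at coarse-grained resolution: a Langevin-dynamics simulator for
implicit-solvent bead-spring homopolymers (and, through per-type parameters,
simple heteropolymers), droplet detection and interface localization via a
hyperbolic-tangent fit to the radial concentration profile, chain- and
segment-level conformational statistics as a function of the distance from
the droplet's centre of mass (`d_com`), and segment orientation statistics
relative to the droplet radius. A synthetic-droplet generator with planted,
known statistical structure closes the loop: every analysis stage has a
parameter-recovery test surface that does not require molecular dynamics.

## Energy model

Each monomer is a spherical bead in implicit solvent. Nonbonded bead pairs
interact through a hydropathy-scaled Lennard-Jones (Ashbaugh–Hatch) form:
for $r \le 2^{1/6}\sigma$,

$$U(r) = U_{LJ}(r) + (1-\lambda)\,\varepsilon,$$

and $U(r) = \lambda\, U_{LJ}(r)$ beyond the minimum, with
$U_{LJ} = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$, shifted so the
potential vanishes at the cutoff. The hydropathy $\lambda \in [0, 1.1]$
interpolates between a purely repulsive (WCA) bead at $\lambda = 0$ and a
fully attractive one at $\lambda = 1$; the homopolymer studies here use
$\lambda = 1$. Bonds are harmonic, $U = k (r - r_0)^2$ (note: no factor
$\tfrac12$; the force is $-2k(r - r_0)$, used consistently). Charged bead
types interact through a Debye–Hückel screened Coulomb term, zero-shifted at
its own cutoff; the homopolymer preset carries zero charge and the term is
inactive. Directly bonded pairs are excluded from nonbonded interactions.

Two unit presets exist. The `real` preset works in Å, kcal/mol, amu, with
defaults in the range used by residue-level coarse-grained IDP models
(σ = 6 Å, ε = 0.2 kcal/mol, bond r₀ = 3.8 Å, k = 10 kcal/mol/Å²,
Debye length 10 Å, dielectric 80). These numbers are deliberately pure
configuration — the package does not claim any specific published parameter
table, and every quantitative test is stated so that it does not depend on
them. The `reduced` preset (σ = ε = m = 1) is used for the desk-scale
studies and all benchmarks.

## Simulation protocol

Dynamics use a BAOAB-split Langevin integrator (time step 0.005 τ in reduced
units, 10 fs default in real units; friction 1/τ or 1/ps). The Gaussian
noise stream is generated by a seeded Box–Muller transform over a
Mersenne-Twister engine inside the compiled core, so seeded runs are
bit-reproducible on a platform. Forces come from an all-pairs or linked-cell
pass (chosen automatically; both paths are verified to enumerate identical
pair sets), and a net-momentum check (pairwise forces sum to zero) plus a
central-finite-difference oracle guard every term of the energy model.

Droplet runs start from a pre-assembled condensate rather than waiting for
self-assembly: chains are grown as self-avoiding random walks inside a ball
sized to a target concentration, with two safeguards worth recording.
First, a short capped steepest-descent minimization removes the high-energy
contacts that random packing leaves at the 0.8 σ exclusion distance; without
it the first few hundred dynamics steps can diverge at a production time
step. Second, the walk construction is end-asymmetric (growth proceeds
outward from the first bead), so the bead order of exactly half the chains,
chosen at random, is reversed. Chain-end identity relaxes slowly in a dense
droplet, and without this flip a desk-scale run retains a visible, spurious
asymmetry between the two chain ends in segment-occupancy statistics.

The bulk reference at zero external pressure interleaves Monte Carlo volume
moves (isotropic, log-volume steps, molecular centre-of-mass scaling so bond
lengths are untouched) with dynamics. Moves are accepted with the isobaric
criterion at P = 0; the step amplitude is tuned toward mid-range acceptance
during the equilibration fraction only. At P = 0 the box relaxes to the
system's naturally preferred concentration, which is the reference for the
droplet-interior plateau.

## Desk-scale study conditions

The reference droplet study (`droplet_study()`) uses 20 chains of 20 beads
in reduced units with the bond/diameter ratio r₀/σ = 3.8/6 ≈ 0.63 of
residue-level models — bonds substantially shorter than the bead diameter,
which matters for contact statistics (below). The temperature was placed
inside the liquid-droplet window for this geometry, determined by a
temperature scan: at kT ≲ 1 ε the overlapping-bond droplet is glassy (chain
centre-of-mass displacements over the whole production run are a fraction of
σ, and conformational statistics never forget the packed start), while at
kT ≈ 3 ε chains begin to evaporate. The default kT = 2 ε is roughly two
thirds of the evaporation onset: unambiguously liquid (chains diffuse
several σ, comparable to the droplet radius, during production) yet fully
condensed — all 20 chains belong to one cluster and the fitted dilute-phase
concentration is zero. Equilibration is 30 000 steps and production 60 000
steps with a frame every 300; the periodic box (40 σ, about ten droplet
radii) keeps the dilute phase explicit and the profile's outer bins genuinely
empty. These problem sizes keep the full study under two minutes on one CPU;
the acceptance and test suites state every expectation so that it is
meaningful at this scale, and the known desk-scale limitations are listed at
the end of this vignette.

## Interface localization

Droplet geometry never assumes a fixed centre: per frame, chains are
clustered (nodes = chains, an edge when any inter-chain bead pair is within
the cluster cutoff, default 1.5 σ under minimum image), the largest
component is taken (ties resolved toward the lowest chain id, so results are
deterministic), and its centre of mass is computed periodicity-safely — a
circular mean per axis followed by a minimum-image refinement, so a droplet
straddling the box boundary poses no problem. Shape fluctuations are ignored
in the radial binning, but the gyration-tensor asphericity
$b = [(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
(\lambda_3-\lambda_1)^2] / [2(\lambda_1+\lambda_2+\lambda_3)^2]$ is always
available so the sphericity assumption is checkable (the reference droplet
sits near b ≈ 0.01).

The time-accumulated radial concentration profile (1 bead/Å³ ≡ 1.66054×10⁶
mM; exact spherical-shell volumes; bin width 5 Å in real units, 1 σ in
reduced) is fit by Levenberg–Marquardt least squares to

$$c(d) = \frac{c_{dense}+c_{dilute}}{2} -
         \frac{c_{dense}-c_{dilute}}{2}\tanh\!\left(\frac{d-d_{mid}}{\delta}\right),$$

with start values from profile quantiles: the inner 20 % of bins for
$c_{dense}$, the outer 10 % for $c_{dilute}$, the first bin below the
midpoint concentration for $d_{mid}$ and a tenth of that for δ. By default
each bin is weighted by its inverse count variance (one over the squared
single-bead concentration times the bin's count, floored at one count):
the innermost spherical shells are tiny and hold only a handful of beads,
and unweighted least squares would let their wild concentration estimates
drag the plateau parameter, while genuinely empty outer bins deserve their
full weight. Unweighted fitting remains available (`weighting = "none"`)
for profiles whose noise is multiplicative rather than count-like, and is
what the grid-search cross-check in the test suite uses. The fit is
unconstrained; a negative $c_{dilute}$ (which least squares happily produces
when the dilute phase is empty) is clipped to zero and flagged. By the
functional form the radius at half-central concentration equals $d_{mid}$.
The interface region defaults to the central 80 % traversal of the
concentration drop, $d_{mid} \pm \delta\,\mathrm{atanh}(0.8) \approx
d_{mid} \pm 1.0986\,\delta$ — a 10–90-style convention; the coverage is a
parameter because no universal rule exists. Region assignment is a strict
partition: interior below the inner bound, interface on the closed band,
exterior beyond.

## Conformation and orientation statistics

Chains are always unwrapped by bond-walking (minimum image per bond) before
any centre-of-mass or size computation; `chain_rg()` refuses visibly wrapped
input. $R_g^2 = N^{-1}\sum_i |r_i - r_{com}|^2$ with equal masses (for a
homopolymer the mass-weighted and geometric centres coincide, which is why
the package does not expose a choice). A Lagrange-identity oracle
($R_g^2 = (2N^2)^{-1}\sum_{ij} r_{ij}^2$) pins the implementation in tests.

Segments are contiguous windows of `n_seg` beads, indexed by their middle
bead (the larger of the two middle beads when `n_seg` is even, so a 50-mer's
whole-chain segment has index 26). Windowed prefix sums make the per-segment
COM/Rg/Re pass linear in chain length. The "end" subset comprises the two
terminal segments; the "middle" subset is the segment whose index is nearest
the chain midpoint (ties toward the lower index). Segmental Rg profiles can
be normalized by the mean over interior bins, which makes different segment
lengths comparable; the normalizer is reported alongside the raw means.

The orientation angle θ is measured between the segment-to-droplet-centre
vector and the segment end-to-end vector, folded as
$\max(\theta, \pi - \theta)$ into $[\pi/2, \pi]$: π/2 is tangential to the
droplet surface, π perpendicular. The fold convention is forced by two
analytic anchors — the reported range itself, and the isotropic reference:
under random orientation the folded angle has density $\sin\theta$ on
$[\pi/2, \pi]$, whose mean
$\int_{\pi/2}^{\pi}\theta\sin\theta\,d\theta = \pi - 1 \approx 2.1416$ rad
is the null line drawn through every angle profile. A Monte Carlo estimate
over 10⁶ random orientation pairs reproduces it to < 0.002 rad in the test
suite. The centre vector originates at the segment COM by default; an
alternative origin at the segment's outer terminal bead is available behind
the `origin` flag, because the geometric bound below is naturally stated at
a terminal bead and the two constructions differ slightly for short
segments. Segments with a degenerate (near-zero) end-to-end vector are
skipped and counted, never silently assigned an angle.

A chord-geometry bound limits how tangential a segment can be: a segment of
end-to-end distance $R_e$ whose terminal bead sits at distance $R$ from the
centre, confined to the ball of radius $R$, satisfies

$$\theta \ge \theta_{min} = \frac{\pi}{2} + \arcsin\!\frac{R_e}{2R},$$

which tends to π/2 (tangential) for $R \gg R_e$ and reaches π for a
diametral chord. Because the source for this estimate was not available in
closed form, the package's form was validated against a brute-force
minimization over all chord placements; the two agree to < 10⁻³ rad across
the tested $R/R_e$ range, and the closed form is exact under the chord
geometry.

### Contact conventions

"Contact" has no universal definition, and the choice changes a qualitative
conclusion, so the package is explicit about it. `contact_profile()`
defaults to a first-solvation-shell convention: cutoff 1.5 σ, intrachain
pairs within 2 bonds excluded. Under that convention, in a dense droplet the
interchain count dominates the intrachain count — most first-shell
neighbours of a monomer belong to other chains. Under a bead-overlap
convention (cutoff = σ, no bonded exclusion), which is the natural reading
when bonds are much shorter than the bead diameter (r₀/σ ≈ 0.63, so a
monomer's ±1 and ±2 contour neighbours sit inside its own diameter),
intrachain contacts exceed interchain contacts at every radius. Both knobs
are plain arguments and are recorded in output metadata; the acceptance
check of the intrachain-dominance signature uses the bead-overlap
convention, and this paragraph is the documentation of that choice.

## The synthetic-droplet generator

The generator plants known structure so that each analysis stage can be
tested by parameter recovery, without dynamics:

- **Density.** Chain centre-of-mass radii are rejection-sampled from
  $p(r) \propto r^2 c(r)$ with $c$ the planted tanh profile; the chain count
  is derived so the planted absolute concentrations are realized (forcing a
  chain count rescales the planted values, and the truth metadata records
  what was actually realized).
- **Conformations.** Chains are ideal (Gaussian) with RMS bond length b,
  optionally scaled by a piecewise-linear compactness profile s(d).
- **Orientation.** The whole-chain end-to-end vector is rotated to be
  isotropic, tangential or radial relative to the local radial direction.
- **End enrichment.** For chains in the shell just *below* the interface
  band (displaced inward by the ~0.4 Re conditional offset of a terminal
  segment and capped at the inner bound), with probability e/(1+e) a
  randomly chosen chain end is rotated radially outward about the chain
  COM. The rotated end reaches into the band while the chain middle stays
  below it; since rotation moves no centre of mass, the density profile is
  untouched and occupancy and density recovery tests stay independent.
  Enrichment is a membership effect, so it is only visible when the band
  width is comparable to the chain size — the recovery tests therefore use
  a thin-interface geometry and compare against the zero-enrichment null.

Every planted value is recorded in the trajectory metadata. What the
generator does *not* emulate: excluded volume and chain–chain correlation
(chains may overlap), thermodynamic consistency between density and
conformations, and dynamics. One consequence is worth stating precisely:
the generator plants the tanh law at the *chain-COM* level, so the
*bead*-level profile is that law convolved with the chain form factor. The
recovery tests therefore check the midpoint to within one chain Rg and the
width to within the Rg-broadened tolerance at the bead level, and recover
the planted law sharply at the chain-COM level. Passing these tests
demonstrates that the analysis stages measure what they claim on data with
known structure; it does not by itself validate the force field against any
experimental system.

## Known desk-scale limitations

- The droplet radius is only ~3 segment lengths, so the geometric fold bound
  is active across the whole fitted interface band: within the band even
  end segments average tangential-to-isotropic angles, and the
  perpendicular tilt of chain ends appears in the shell just *inside* the
  fitted band (where their folded angles clearly exceed π − 1) rather than
  inside the band itself. In a droplet hundreds of Å across this shell and
  the band overlap; at 20×20 scale they separate by about half a segment
  end-to-end distance. The acceptance suite asserts the in-band statement
  faithfully and separately documents the subsurface counterpart.
- The interior is not a bulk reservoir: the surface-to-volume ratio is so
  large that terminal-segment depletion of the interior (the mirror of their
  interface enrichment) is visible; "interior uniformity" is therefore
  asserted as absence of terminal *enrichment* rather than strict
  uniformity.
- The P = 0 bulk concentration and the droplet-interior plateau agree to a
  few percent, not exactly; a droplet of radius ~4 σ carries a visible
  Laplace-pressure offset. The comparison tolerance (15 %) covers the
  finite-size gap in both directions.
- The per-frame centre estimate is itself a statistic: with only a few tens
  of chains it follows density fluctuations, which inflates the apparent
  concentration near the centre (by ~10–20 % at ~30 chains per frame) and
  smears the profile slightly. Analyses accept an explicit `center`
  argument for cases where the true centre is known (synthetic data), and
  the effect shrinks as chain count grows.

## Pipeline and configuration

`run_pipeline()` executes input → interface → conformation → orientation
from a single config (an R list or YAML file) with per-stage blocks, writes
CSV/JSON outputs as each stage completes, and finishes with a manifest
holding the config snapshot, the seed, the package version, MD5 hashes of
every output, and all collected warnings (clipped dilute concentrations,
skipped degenerate segments). A failing stage leaves the completed outputs
plus a manifest naming the failure. Re-running the same config reproduces
identical hashes. The exactly-one-input rule is enforced up front, as is
`n_seg ≤ chain_length`, before any compute. A thin command-line wrapper
lives at `inst/scripts/run_pipeline.R`; the package functions themselves are
the primary interface.

```{r example-config}
config <- list(
  seed = 1,
  input = list(mode = "synthetic", chain_length = 20, b = 1.5,
               c_dense = 1500, d_mid = 50, delta = 10,
               n_frames = 12, end_enrichment = 2),
  interface = list(bin_width = 4, coverage = 0.8),
  conformation = list(n_seg = c(5, 10), contact_cutoff = 1.5, bin_width = 10),
  orientation = list(origin = "com", bin_width = 10)
)
manifest <- run_pipeline(config, "run1")
```
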