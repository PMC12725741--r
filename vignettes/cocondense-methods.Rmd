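---
title: "Modeling sequence-dependent protein-DNA co-condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sequence-dependent protein-DNA co-condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cocondense)
```

## The physical model

`cocondense` simulates the co-condensation of DNA-binding, phase-separating
proteins with a single end-tethered DNA molecule, the geometry of
coverslip- and optical-tweezer-based single-molecule assays. DNA is a
semiflexible bead-spring polymer in which one bead ("monomer") stands for
10 bp, roughly the footprint of a bacterial transcription factor, giving a
5 kb molecule 500 monomers. Proteins are single spherical beads of the
same diameter. Everything is expressed in reduced units: bead diameter
sigma = 1 (3.4 nm at 0.34 nm/bp), thermal energy kBT = 1, bead mass m = 1,
time tau = sigma * sqrt(m/kBT).

The force field is the standard bead-spring set:

* harmonic bonds, U = kb/2 (l - 1)^2 with kb = 100 kBT/sigma^2;
* bending, U = kappa (1 - cos theta) over consecutive bonds with
  kappa = 15 kBT, which gives the chain a persistence length of about 15
  monomers (150 bp);
* excluded volume between monomers through the WCA potential (Lennard-Jones
  with epsilon = 1 kBT truncated at 2^(1/6) sigma and shifted);
* attraction for protein-protein pairs (depth eps_PP, default 2.0 kBT) and
  monomer-protein pairs (depth eps_MP(i), set per monomer by the affinity
  profile) through the 12-6 Lennard-Jones potential truncated at 2.5 sigma
  and shifted to zero at the cutoff.

Directly bonded monomer pairs are excluded from nonbonded interactions, the
usual convention for harmonic (non-FENE) bead-spring chains; with the stiff
default bond this keeps the bond-length distribution governed by the
harmonic term alone (variance approximately kBT/kb, which the test suite
verifies by equipartition).

Sequence enters exclusively through the per-monomer binding energies. Four
profiles are built by `build_block_profile()` / `sequence_to_profile()`:

* **homogeneous** — every monomer 2.0 kBT;
* **het1** — an ABA block copolymer: central 50% of the chain at 2.25 kBT,
  two 25% flanks at 1.75 kBT, so the chain-average affinity stays exactly
  2.0 kBT;
* **het2** — two high-affinity blocks (2.25 kBT) separated and flanked by
  low-affinity blocks (0.1 kBT). The full-chain layout is the symmetric
  five-block pattern L-H-L-H-L with equal block lengths, which keeps both
  high-affinity blocks away from the tethers;
* **sequence-mapped** — a real nucleotide sequence (e.g. the last 5 kb of
  lambda-phage DNA) partitioned into non-overlapping 10-bp windows from the
  5' end (trailing remainder dropped), each window mapped to one of eleven
  affinity classes by its AT count. The class-to-energy map is linear
  between the range endpoints: 0.1 kBT at 0 AT bases, 4.0 kBT at 10,
  i.e. 0.1 + 0.39 per AT base. `N` counts as non-AT.

Block layouts scale proportionally with chain length (het1 stays 25/50/25,
het2 stays five equal blocks), so desk-scale chains keep the same sequence
architecture.

The control parameters mirror the experiments: the normalized end-to-end
distance Re' = Re/s (tether separation over contour length) and the bulk
protein concentration rho_p in micromolar, converted to a bead count
through the box volume and Avogadro's number (`concentration_to_count()`;
84.5 uM in the reference 80 x 80 x 600 sigma^3 box is ~7680 proteins).

## Dynamics

The equations of motion are integrated with the BAOAB splitting of
underdamped Langevin dynamics: velocity-Verlet half-kicks and half-drifts
around an exact Ornstein-Uhlenbeck update of the velocities. Defaults are
T = 1 kBT, damping gamma = 0.1/tau and dt = 0.01 tau. The tethered first
and last monomers are simply excluded from integration. An overdamped
Euler-Maruyama mode is available for comparison
(`integrate_system(..., overdamped = TRUE)`).

Boundaries are periodic in all three axes with the tether anchors as fixed
points; anchors sit on the box long axis, symmetric about the center. The
initial chain is a discrete helix of exact unit bonds between the anchors
— each bond advances Re/(Nm-1) along the axis while the transverse
component completes a whole number of turns at a radius below a quarter of
the box cross-section — so arbitrary slack is taken up without the path
ever leaving the box or overlapping its own periodic images. Proteins are
inserted uniformly with overlap rejection (minimum 0.9 sigma). Nonbonded forces run over a cell
list rebuilt every step; for small or extremely dilute systems the code
falls back to an all-pairs loop, so the force field is exact within the
cutoff in either path.

The experiment protocol (`run_experiment()`) follows the single-molecule
workflow: equilibrate the bare tethered chain, insert proteins, equilibrate
again, then record production frames. Protein-phase equilibration runs in
ten windows of the step budget and stops early once both the
window-averaged potential energy and the largest-cluster size change by
less than 2% over two consecutive windows. For replicates, independently
seeded bare-DNA equilibrations feed the protein runs, and thermostat,
placement and initialization draw from separate seed offsets so each
ingredient is independently reproducible.

## Condensate detection

Condensates are detected per frame with DBSCAN (MinPts = 6, twice the data
dimensionality) on the joint set of proteins and monomers, under the
periodic minimum-image metric. The radius epsilon is chosen per frame from
the sorted 5-NN distance curve (k = MinPts - 1): the curve is smoothed
with a degree-3 Savitzky-Golay filter and the knee — the point of maximum
discrete curvature |y''|/(1 + y'^2)^(3/2) after rescaling both axes to
[0, 1] — gives epsilon.

Two numerical choices matter at desk scale and are worth stating
explicitly:

* **Window scaling.** The default window of 199 points operates on
  full-scale frames of ~8000 particles, i.e. about 2% of the curve. Applied
  to a 200-point desk-scale frame it would degenerate into a single global
  cubic, whose edge oscillations corrupt the knee. For curves shorter than
  ten windows the window therefore shrinks to about sqrt(n) (odd, at least
  degree + 2), which keeps the dense-to-dilute jump from being smeared
  across the knee. Because the sorted curve is non-decreasing by
  construction, the smoothed estimate is projected back onto the monotone
  cone (isotonic regression) — polynomial filters ring around sharp jumps,
  and the spurious dip just below a jump otherwise carries the largest
  curvature — and clamped to the raw curve's range. Knee candidates
  exclude the filter's half-window startup regions at either end.
* **First prominent knee.** On frames where a sizable fraction of points is
  bare chain (inevitable when the chain is shortened but its tethered
  geometry retained), the sorted curve can carry two elbows: dense
  condensate to chain, and chain to dilute gas. The strict curvature
  argmax flips between them from frame to frame, which makes per-frame
  epsilon — and with it every downstream count — flicker. `knee_epsilon()`
  therefore returns the smallest index whose curvature reaches at least
  half the global maximum. On single-elbow curves this is exactly the
  argmax with ties broken toward smaller epsilon; on two-elbow curves it
  consistently selects the dense-phase knee.

Clusters below 20 particles are discarded as transient oligomers.
Per-cluster records carry members, centroid, per-axis radii (half the
maximum extent along each axis, after minimum-image unwrapping about a
member) and the ellipsoidal volume Vc = 4/3 pi rx ry rz.

Condensate identity across frames is greedy maximum-Jaccard matching
(threshold 0.3) against a registry of each track's last-seen members.
Overlap is computed on the DNA monomers of a cluster when available: the
chain segment a condensate holds is far more persistent than its protein
complement, which exchanges with the dilute phase on the frame timescale.
Larger clusters match first, so a fission fragment cannot steal the parent
identity. The number of condensates "at equilibrium" is the number of
tracks present in at least 80% of the analysis window.

## Observables

* **Occupancy** P_m: fraction of analysis frames in which monomer m is a
  condensate member (Eq.-level identity `sum(P_m) * frames = total inside
  events` is tested exactly).
* **Capillary force**: from bond stretching. F_DNA = kb (mean tethered
  bond - mean free-ends bond) is the bare tether force;
  F_DNA,protein = kb (mean bond outside condensates - mean tethered bond)
  with "outside" meaning both endpoint monomers outside every detected
  condensate of that frame; the capillary force is their difference,
  reported in kBT/sigma and in pN (1 kBT/sigma = 4.11 pN nm / 3.4 nm =
  1.209 pN). Replicates aggregate as mean +/- sd. Capillary forces are
  physically meaningful only in runs that hold at least one equilibrium
  condensate, and force-affinity comparisons restrict to those replicates.
* **Interfacial affinity** I_a: occupancy-weighted mean binding energy over
  interface monomers, where the interface is the closed band
  0.1 < P_m <= 1 (an open alternative 0.1 < P_m < 0.9 is switchable; the
  closed band, which includes fully interior monomers, is the default, as
  the occupancy weighting makes their contribution dominate only when the
  condensate itself is small). The interface is split into left and right
  sides about the condensate core — the longest contiguous run with
  P_m >= 0.9, or the occupancy peak if no run saturates — and the two
  sides' values are averaged.
* **Kymograph**: monomer x time membership matrix.
* **Coarsening**: per-frame effective radius R = (3 Vc / 4 pi)^(1/3) of
  each track, normalized by the final largest radius; the growth exponent
  is the log-log slope over frames where the largest radius is between 20%
  and 80% of its final value, which excludes both nucleation noise and the
  arrested plateau.
* **Persistence length**: exponential fit to the mean bond-tangent
  correlation; after a first pass up to 30 bonds the fit is repeated over
  separations up to twice the estimate, limiting the upward bias from
  excluded-volume swelling at long contour separations.

The force pipeline subtracts the bare-DNA baseline exactly as the two-step
difference described above; on synthetic bond-length series with prescribed
mean shifts the pipeline returns kb times the shifts to machine precision,
which the tests exercise.

## What the synthetic fixtures emulate

The `fixtures` module builds Gaussian blobs with uniform background
scatter, drifting blobs, exact 0/1 membership matrices, and bond-length
series with prescribed means. These give the detection and observables
stacks unambiguous ground truth: blob separation must exceed five spreads,
and background density stays below the MinPts = 6 noise regime. They do
not emulate the fuzzy interfaces, protein exchange, or chain connectivity
of real condensates — tests passing on fixtures demonstrate the analysis
machinery, while the engine-level acceptance experiments (condensate
counts, force-extension switch, coarsening exponent) probe the physics.

## Desk-scale experiment sizes

Full-scale runs (500 monomers, thousands of proteins, 1.5e7 production
steps, 3000 frames) are cluster-scale. The package's own experiments run
at a documented desk scale chosen once: chains of 50-100 monomers in a
20 x 20 x (1.25 s) sigma box, 4e5 equilibration and 6e5 production steps,
100-300 frames, with concentrations expressed in uM and converted through
the same Avogadro relation (so 84.5 uM means ~96 proteins in the
100-monomer box). The block layouts, interaction strengths, thermostat
and time step are identical to the full-scale conditions. At this scale a
co-condensate nucleates and wets the chain within the equilibration
budget, and a 7-point Re' scan with 3 replicates per point completes in
tens of minutes on one core.

Two desk-scale caveats follow from the shortened chain: the bare-chain
fraction of each frame is larger, which is why the knee selection needs
the robustness choices above, and absolute forces carry larger replicate
spread because fewer bonds enter the outside-condensate average.

Two phenomena do **not** survive the reduction to desk scale, and the
corresponding acceptance-style tests document this honestly rather than
papering over it:

* **Stable condensate pairs on the two-block chain.** When protein-protein
  attraction is much weaker than the 2.25-kBT block affinity, both
  high-affinity blocks carry a protein coat (direct minimum-image counts
  of proteins within 1.5 sigma of block monomers show both blocks loaded
  and the low-affinity middle block empty), which is the two-condensate
  regime in substance. But a coat of 5-15 proteins threaded on a
  30-monomer block is not a dense droplet: at no epsilon does DBSCAN with
  MinPts = 6 resolve the two coats as two clusters without also chaining
  along the bare backbone. Raising protein-protein attraction to 2 kBT
  produces genuine droplets, but then the desk-scale system coarsens to a
  single droplet within the run: the arrest of ripening that stabilizes
  the pair operates on timescales around 1e7 tau, orders of magnitude
  beyond a minutes-scale run.
* **The diffusive growth exponent.** In a desk-scale box the largest
  droplet absorbs most of the protein reservoir while growing from
  MinPts-size to its final size in under one decade of time, and much of
  that growth happens in discrete coalescence jumps. A log-log fit over
  such a window does not measure the diffusion-limited R ~ t^(1/2) law,
  and measured exponents scatter widely across seeds. The estimator is
  implemented and tested as specified; recovering the exponent cleanly
  needs a reservoir (and therefore runtimes) well beyond a desk-scale
  budget.

## Degenerate inputs and numerical edges

* A straight-line k-distance curve (e.g. a periodic lattice) has no knee:
  `knee_epsilon()` raises a degenerate-curve error, and
  `detect_condensates()` falls back to `fallback_epsilon` when configured.
* Bond lengths of exactly zero abort the force evaluation (singularity).
* Non-finite coordinates abort integration with the step number.
* At T = 0 the thermostat noise vanishes and the integrator is purely
  dissipative; total energy decays monotonically, which is tested.
* Attractive pairs with eps <= 0 do not interact at all, which provides
  exact free-particle reference dynamics for the diffusion checks.

## Known limitations

The model does not alter DNA mechanics upon protein binding, has no
hydrodynamic interactions, treats proteins as isotropic single beads, and
the box is periodic rather than walled. Desk-scale condensate counts and
force curves reproduce the qualitative regime structure (single condensate
for homogeneous DNA, stable pairs for strongly bound het2, the het1 force
switch near Re' = 0.5) but not the absolute magnitudes of cluster-scale
runs. The AT-to-affinity map is the linear stand-in described above; any
monotone 11-level map on [0.1, 4.0] kBT can be substituted through
`affinity_profile()`.
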