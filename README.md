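# cocondense

Coarse-grained Brownian-dynamics simulation and analysis of
sequence-dependent protein–DNA co-condensation on end-tethered DNA.

Phase-separating DNA-binding proteins (transcription factors such as Sox2
and FoxA1, heterochromatin protein HP1, nucleoid-associated proteins like
Dps) form droplets together with the DNA they bind. On a DNA molecule
tethered at both ends — the geometry of coverslip and optical-tweezer
assays — such a co-condensate reels in slack DNA and pulls on the bare
DNA outside it with a *capillary force* of order a piconewton. This
package provides a complete desk-scale framework for asking how the DNA
*sequence* shapes that process: where condensates form, how many coexist,
how they coarsen, and how strongly they pull.

It is intended for biophysicists and quantitative biologists who want to
explore sequence/affinity designs or reanalyze single-molecule
co-condensation experiments with a mechanistic polymer model.

## Model in brief

DNA is a semiflexible bead-spring chain (one bead = 10 bp, persistence
length 15 beads = 150 bp), tethered at both ends at a chosen normalized
extension Re′ = Re/s inside a periodic box; proteins are single attractive
beads at bulk concentration ρp (μM). Nonbonded interactions are
Lennard-Jones (attraction, cutoff 2.5 σ) and WCA (DNA excluded volume);
bonds are harmonic (kb = 100 kBT/σ²) with κ(1 − cos θ) bending
(κ = 15 kBT). Dynamics are underdamped Langevin (BAOAB; T = 1 kBT,
γ = 0.1 τ⁻¹, Δt = 0.01 τ). Sequence enters through per-monomer binding
energies ε_MP ∈ [0.1, 4] kBT: homogeneous (2 kBT), block-heterogeneous
(`het1`: 1.75/2.25/1.75, `het2`: two 2.25-kBT blocks in a 0.1-kBT
background), or mapped from a nucleotide sequence by the AT content of
each 10-bp window.

The analysis stack implements:

* per-frame condensate detection with DBSCAN (MinPts = 6), the radius ε
  chosen per frame from the knee of the Savitzky–Golay-smoothed sorted
  5-NN distance curve;
* condensate volumes `Vc = 4/3 π rx ry rz` from half-max extents;
* capillary force from bond stretching:
  `F_DNA = kb(l̄t − l̄0)`, `F_DNA,protein = kb(l̄t,p − l̄t)` over bonds
  outside condensates, `F = F_DNA,protein − F_DNA` (reported in kBT/σ and
  pN, 1 kBT/σ ≈ 1.209 pN);
* per-monomer occupancy `P_m`, potential-energy profiles along the
  contour, kymographs, coarsening kinetics with a growth-exponent fit, and
  the occupancy-weighted interfacial affinity
  `Ia = Σ ε_mp P_m / Σ P_m` over interface monomers (0.1 < P_m ≤ 1);
* persistence-length recovery from tangent–tangent correlations;
* grid scans over Re′ and ρp with replicate aggregation, plus synthetic
  fixture generators for testing the analysis without dynamics.

## Worked example

A desk-scale homogeneous-DNA experiment (60 monomers, Re′ = 0.6,
ρp = 109.9 μM ≈ 77 proteins in the scaled box) runs in about a minute:

```r
library(cocondense)

cfg  <- scaled_config("homogeneous", n_monomers = 60L, re_prime = 0.6,
                      rho_uM = 109.9, equil_steps = 4e5,
                      prod_steps = 6e5, n_frames = 100L)
traj <- run_experiment(cfg, seed = 21)
det  <- detect_trajectory(traj, detection_params())

count_equilibrium_condensates(det)
#> [1] 1

occ <- occupancy(det, frames = 51:100)
range(occ$p_m)
#> [1] 0 1
interfacial_affinity(occ, build_block_profile("homogeneous", 60L))
#> Interface: 36 monomers (band closed), Ia left=2.000 right=2.000 avg=2.000 kBT
```

One protein–DNA condensate wets the chain (the single persistent cluster),
holding a block of monomers at full occupancy with a 36-monomer interface
band; since every monomer binds at 2 kBT, the interfacial affinity is
exactly 2 kBT. Swapping
`"homogeneous"` for `"het2"` with `eps_pp = 1.5` yields two stable
condensates pinned at the two high-affinity blocks; a `run_scan()` over
Re′ for `"het1"` shows the capillary-force jump near Re′ ≈ 0.5 as the
high-affinity central block reaches the condensate interface.

A thin CLI over the same functions is installed with the package
(`system.file("scripts/cocondense", package = "cocondense")`) with
subcommands `simulate`, `detect`, `observe`, `scan`, `fixtures`.

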