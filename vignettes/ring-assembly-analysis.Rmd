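---
title: "Ring-oligomer geometry, interface energetics and sedimentation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-oligomer geometry, interface energetics and sedimentation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoring)
```

`oligoring` analyses closed circular protein oligomers — the motivating
system is C-phycocyanin (CPC), whose (αβ) heterodimer protomer can close
into a D₃ hexamer or, with a slightly different protomer bend, a wider D₄
octamer. This vignette documents the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Coordinate model and superposition

Atoms are held in a plain data frame with author chain ids and author
residue numbers, because the residues practitioners talk about (αArg30,
βPro69, αCys84) are named in author numbering. Alternate locations other
than blank/'A' are dropped on reading; hydrogens are excluded from all
geometry and surface-area work, since deposited models of these assemblies
are heavy-atom. Both PDB and PDBx/mmCIF are read and written; mmCIF is the
canonical format for large deposited assemblies and the PDB writer exists
mainly for compact fixtures.

Superposition is the Kabsch SVD solution with the determinant correction
applied unconditionally: biological assemblies are chiral, so a reflection
is never an acceptable fit even when it has lower residual. Cα pairing for
superposition offers both residue-number matching and global sequence
alignment (match +1, mismatch 0, gap −1); which pairing a published rmsd
used is usually unstated, so both are exposed and give identical results
whenever numbering is consistent.

## Protomer grouping and ring symmetry

Chains are paired into (αβ) protomers either in file order or by contacts
(most inter-chain atom pairs within 5 Å); contact pairing refuses to guess
when the two best candidates are within 5% of each other. Protomer indices
follow angular position about the assembly axis.

Symmetry detection scores, for each candidate order *n*, the hypothesis
that the protomer centroids of each layer sit at 360/*n* spacing about a
principal axis. Two axis candidates are tried — the smallest-eigenvalue
eigenvector of the centroid covariance (right for oblate single rings and
stacked double rings) and the largest (right for prolate stacks) — and the
one with the lower residual wins. The score is the mean absolute deviation
of consecutive azimuth gaps from 360/*n* **plus a radial-consistency
penalty** (the relative standard deviation of the centroid radii, in
degree-equivalents): a genuine ring axis sees all centroids at one radius,
while a spurious in-plane axis can fake perfect 2-fold azimuth spacing but
never a common radius. Without the penalty a C₄ ring viewed down an
in-plane axis scores as C₂; with it the correct order wins by orders of
magnitude. Layers are split at the largest axial gap, accepted only when it
exceeds both 5 Å and 60% of the axial range — so coordinate jitter cannot
split a flat ring. Ties between candidate orders within 10⁻³ deg go to the
larger *n* (the more specific hypothesis). The type is Dₙ when the two
layers map onto each other under some perpendicular 2-fold axis (tested on
centroid azimuths with a 10 deg tolerance), otherwise Cₙ.

## Angle measurements

The protomer bend is measured as the **planar vertex angle** at the middle
anchor Cα (defaults αGln70, vertex αArg30, βGly70): three points define no
torsion, and the conventional printed values (≈110° for the hexamer
protomer, ≈123° for the octamer protomer) are only reproducible as a planar
angle. The adjacent-monomer angle (αGln70, vertex βPro69, next protomer's
βPro69; ≈52° hexamer, ≈90° octamer) needs a convention for "next": the two
layers of a Dₙ assembly wind in opposite azimuthal senses, so the package
takes, of the two azimuthal neighbours in the same layer, the one whose
third-anchor atom lies nearer the first anchor — an orientation-free rule
that picks the structural interface partner in both layers. All angle
functions report per-copy values and the mean over symmetry-equivalent
copies, since deposited assemblies deviate slightly from ideal symmetry.

Inter-protomer rotations come from the Kabsch transform between matched Cα
sets, θ = arccos((tr R − 1)/2); for an ideal ring adjacent protomers give
exactly 360/*n*, and the ideal difference between two ring orders is
Δθ = (360/n − 360/m)° — 30° between orders 3 and 4, which is why a
hexamer/octamer switch is a large structural change. The pore diameter is
2·min(radial distance − van der Waals radius) over heavy atoms, reported
beside the raw centre-to-atom diameter because printed "inner diameters"
rarely state whether atom radii were subtracted.

## Chromophore networks

Phycocyanobilins are open-chain tetrapyrroles thioether-bonded to conserved
cysteines (α84, β82, β153). Sites are detected as hetero residues from a
configurable name set (CYC, PCB, BLA by default — deposited CPC structures
vary), anchored to the nearest cysteine Sγ within 2.5 Å of a chromophore
carbon. Distances are **centroid-to-centroid over heavy atoms**; published
pair distances rarely state their metric, which is why accession-based
comparisons should carry a ±1 Å allowance. Named pairs (e.g. α84PCB–β82PCB)
report the minimum over symmetry-equivalent copies, matching how single
representative values are quoted for symmetric assemblies. No Förster or
excitonic calculation is attempted — the networks support proximity
arguments only.

## Surface areas and assembly energetics

Solvent accessibility uses Shrake–Rupley sampling: Bondi radii, 1.4 Å
probe, 960 deterministic Fibonacci points per atom (all configurable),
spatial binning for neighbours. An isolated atom is exact by construction;
two-sphere overlaps agree with the analytic spherical-cap area to better
than 1% at the default sampling, and doubling the point count moves totals
by under 0.3%. Interface burial is (ASA_A + ASA_B − ASA_complex)/2 per
part, and contact% = BSA/(ASA + BSA) uses the part's own isolated area as
the denominator. The solvation estimate Σ ASP(element) × buried area is an
element-level atomic-solvation-parameter model (C and S favourable to bury,
N/O/P not); it is an order-of-magnitude tool, deliberately not calibrated
against any particular interface-analysis program, whose entropy terms are
not public.

The assembly model therefore treats the dissociation free energies
ΔG⁰_diss as *input data*. The shipped defaults (4.8, 20.9, 16.0, 54.6,
20.9 kcal/mol for n = 2, 3, 4, 6, 8) are the values for the thermophilic
CPC this package was built around; they are overridable. Formation steps
use ΔG⁰_f = −(ΔG⁰_diss(product) − Σ ΔG⁰_diss(parts)), negative =
favourable — so tetramers→octamer is +11.1 kcal/mol (blocked) while the
dimer route stays downhill. Each step carries its multiplicity along a
route, and Σ count·ΔG⁰_f from monomers to a product telescopes to
−ΔG⁰_diss(product) exactly; `route_totals()` checks this identity.

## Sedimentation velocity

Units are CGS: radii in cm, s in seconds (1 S = 10⁻¹³ s), D in cm²/s,
viscosity in poise. The Lamm equation is solved on a uniform finite-volume
grid (defaults: 400 cells, meniscus 6.0 cm, bottom 7.2 cm, 60,000 rpm,
293.15 K) with zero total flux at both ends — a closed cell — using
Crank–Nicolson in time and exponentially fitted (Scharfetter–Gummel) face
fluxes. The conservative form makes the discrete sector mass ∫c·r dr exact
to machine precision regardless of step sizes; Crank–Nicolson keeps
second-order accuracy in time. Exponential fitting remains stable and
non-oscillatory at moderate cell Péclet numbers sω²r·h/D, but a grid that
is genuinely too coarse for the requested diffusion smears the boundary, so
the solver refuses inputs with Péclet above 20 and advises a finer grid.
The default internal step resolves the fastest species to about one cell
per step. Against the non-diffusing limit, boundary midpoints track
r_m·exp(sω²t) to about 0.1%.

The c(s) model ties D to s through one shared frictional ratio,
D(s) = (√2/18π)·kT·s^(−1/2)·(η·f/f₀)^(−3/2)·((1−v̄ρ)/v̄)^(1/2), the same
scaling the Svedberg mass solution uses, so the two are mutually consistent
by construction. Kernels are forward Lamm solutions on the data's own grid
(no interpolation when the radii are uniform); the inversion is
non-negative least squares with second-difference Tikhonov rows. The
regularization weight is expressed relative to the data block (scaled by
√(n_obs/n_penalty) and the mean kernel magnitude) so one default, λ = 0.05,
behaves consistently across scan counts; it was set so that the residual
rmsd of a fit at the generator's reference noise (σ = 0.005 absorbance)
stays at the noise level, comfortably below 0.01. Heavier smoothing is a
user decision. `f_ratio = "fit"` runs a golden-section scan over
[1.0, 2.5] on a coarsened grid (every second s-point, every second radius)
and refits at full resolution; on synthetic data generated at f/f₀ = 1.195
the scan lands within a few 10⁻³ of the truth. Peaks above 5% of the
distribution maximum become species: weighted-centroid s over the peak
support, s₂₀,w (standard-water constants ρ = 0.998234 g/mL,
η = 0.010020 P), Svedberg mass, and the loading integral; species within
15% of k× a supplied monomer mass are labelled (αβ)_k. Single-scan
datasets are rejected — the time dimension carries the signal.

Default solution parameters are the dilute-phosphate CPC conditions
(ρ = 1.00980 g/mL, η = 0.01029 P, v̄ = 0.73149 mL/g); with the standard
water constants these reproduce the four reference s₂₀,w values to 0.01 S,
and with f/f₀ = 1.195 the Svedberg masses to well under 1%.

## The synthetic-data generator

`build_ring()` constructs the anchor geometry *exactly*: the bend and
adjacent angles of the unjittered ring equal the requested values to
machine precision, protomer copies are exact rotations, and a second layer
is the image of the first under a perpendicular 2-fold axis (layer
half-offset 15 Å). The toy protomer is deliberately minimal — a Cα trace
(~56 + 31 residues per chain, including the anchor residues at their
conventional author numbers), one cysteine per chain, and one five-atom
pseudo-chromophore thioether-bonded 1.81 Å from each Sγ. The two
chromophores of a protomer are spaced so the nearest α84PCB–β82PCB
centroid distance is 20.0 Å, emulating the intra-ring PCB spacing of
phycocyanin; default ring radius 45 Å (55.1 Å is the matching octamer
radius at equal protomer spacing, scaling by sin(60°)/sin(45°)). Jitter is
seeded i.i.d. Gaussian noise on every coordinate, with the RNG state
restored afterwards.

What the generator does **not** emulate: real secondary structure and
side chains (so absolute surface areas and pore diameters are toy-scale
and only *comparisons* are meaningful), asymmetric deviations of deposited
models, crystal contacts, or chromophore conformational detail. Passing
geometry tests on these rings demonstrates correct recovery of constructed
geometry, not agreement with any deposited structure; the surrogate
hexamer/octamer checks therefore build rings *at* the published angle
values (110°/52° D₃ and 123°/90° D₄) and verify the pipeline reads them
back through the same code path a deposited file would take.

`simulate_auc()` emulates the solution experiment: a four-species mixture
at 3.15, 5.24, 7.97 and 11.32 S dominated by the 5.24 S dimer (loadings
0.15/0.60/0.10/0.15 of a total signal near one absorbance unit, the
regime of a ~1 mg/mL sample), one shared f/f₀ = 1.195, scans every 300 s to
9000 s, and i.i.d. Gaussian noise of σ = 0.005. It does not model optical
baselines, time-invariant noise, meniscus artifacts, or multi-speed
protocols.

## Problem sizes and runtime

The test suite and the acceptance script run at desk scale by choice:
rings of 2–16 protomers (hundreds of atoms), 30-scan × 400-radius
sedimentation datasets, 100-point s-grids, 960-point SASA sampling. The
full suite completes in well under a minute; the complete c(s) analysis
with frictional-ratio fitting takes ~30 s on one CPU.

## Interface and reporting

This package is used from R; the pipeline stages are exposed as the
`report_*()` functions (geometry, chromophores, energetics, AUC), driven
by a validated `run_config()` that rejects unknown keys, loadable from
YAML/JSON. Reports write JSON (full precision) and CSV (4 significant
digits) without absolute paths or embedded timestamps, so identical inputs
give byte-identical outputs; the parameters actually used go to a separate
log file. `scripts/acceptance.R` is the batch entry point that recomputes
the headline numbers.

## Known limitations

* Symmetry detection assumes protomer centroids actually form rings; it
  will not diagnose helical or open assemblies.
* contact% and the solvation estimate depend on the sampling parameters at
  the 1% level; cross-program comparisons of interface energies need wide
  tolerances because solvation parameterizations differ.
* The c(s) inversion shares one f/f₀ across all species; strongly
  non-globular mixtures violate that, as they do in any single-f/f₀
  analysis.
* The Lamm solver handles a single speed and a closed cell only; no
  meniscus-position fitting, no equilibrium analysis.
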