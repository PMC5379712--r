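---
title: "Methods: nucleosome trajectory analysis with planted-dynamics validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome trajectory analysis with planted-dynamics validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

## Scope and data model

`nucdyn` analyses nucleosome core particle (NCP) trajectories: ~146 bp of
DNA wound around a histone octamer, here with the centromeric H3 variant
CENP-A. The package does not run molecular dynamics; it consumes
coordinate trajectories (from any source) and computes the standard
observables used to compare a modified and an unmodified system —
contact occupancy, RMSF, dimer COM distances, DNA unwrapping, groove
widths, helix scissoring, essential-dynamics PCA and free-energy
landscapes — plus the fragment-ion arithmetic and cell-scoring rules used
on the experimental side of such studies.

Units are fixed throughout: Ångström for coordinates, nanoseconds for
time, degrees for angles, Dalton for masses, kT for free energies. Frames
are 1-indexed; residue indices are preserved exactly as given by the
input and never renumbered, so residue labels like K124 keep their
meaning. The native trajectory format (`.trj`) is deliberately plain
text — a header with atom/frame counts and metadata, then one coordinate
triple per atom per frame — so fixtures are human-diffable and no binary
dependency is required. PDB reading attaches per-element average masses
at parse time because PDB files carry none; pseudo-atoms from the
generator carry explicit bead masses (330 Da per nucleotide bead, 110 Da
per residue bead) since COM observables need them.

## Analysis window and blocked statistics

Long production runs continue to equilibrate; by default the leading 60%
of frames are discarded (`equilibration_fraction = 0.6`), so a 1 µs run
is analysed on its final 400 ns. Blocked statistics split that window
into `block_count = 3` contiguous thirds: RMSF is computed per block
about each block's own mean, and the standard deviation of the three
block values is reported as the error bar. For DNA, a per-base-pair
variant averages the two strands' P-bead values.

## Contacts

Occupancy uses one representative atom per residue — Cα for protein, P
for DNA — and a cutoff of 8 Å. A distance exactly equal to the cutoff
counts as a contact (the boundary has to fall on one side; this choice is
documented and tested). A pair with occupancy ≥ 0.5 is called a "stable
contact" by default; the threshold is exposed because the literature's
phrasing is loose. Comparing two maps over identical residue axes yields
retained / lost / gained pair sets, which is how interface loss (e.g. the
CENP-C docking surface upon acetylation) is quantified. The vectorized
distance path is tested for exact equality against an O(n²) per-frame
brute force on random fixtures.

## Geometry observables

* **Superposition** removes rigid-body motion by a mass-unweighted
  Kabsch fit of each frame onto the *time-average* of the reference
  selection — standard essential-dynamics practice, preferred over
  fitting to frame 1 which privileges an arbitrary snapshot. The average
  is reached by aligning to frame 1 first and re-fitting once onto the
  resulting mean. Collinear references are rejected (the rotation would
  be underdetermined).
* **COM distances** are mass-weighted using the attached masses. Which
  atoms enter a dimer group is a `selection()` choice rather than a
  hard-wired rule, because analyses differ on whether tails are included.
* **DNA end-to-dyad distance** is measured between the COM of the
  terminal base pair's two P beads and the COM of the pseudo-dyad base
  pair's P beads. The *entry* end is the strand-I 5′ terminus side by
  default; the assignment is recorded in the topology and overridable.
  The terminal base pair (not a terminal segment COM) is used — the
  simplest defensible convention.
* **Groove widths** have no universally agreed trajectory-level
  algorithm; the package uses a documented P–P convention: the distance
  between P of strand-I residue *i* and P of strand-J residue
  `basepair(i) + k` (k = 3 minor, k = 7 major, in strand-J numbering),
  minus a 5.8 Å phosphate-exclusion diameter, floored at 0. Conclusions
  about grooves are statements relative to this convention, not to any
  curvilinear (Curves-style) definition.
* **Scissoring** is the angle between the dominant principal axes of the
  α2 and α3 Cα sets of CENP-A. Axis signs are fixed at frame 1 by the
  largest-component-positive rule and propagated by continuity, so the
  series is smooth and its sign is reproducible.
* **Coherence** between series is the Pearson correlation of the raw
  per-frame values — no smoothing, detrending or lag, which keeps the
  estimator unambiguous.
* **Harmonic amplitude recovery** (for breathing) locates the
  periodogram peak and then maximizes the DFT magnitude over a continuous
  frequency neighbourhood. This avoids the up-to-36% scalloping loss of a
  bare FFT bin when the oscillation period does not divide the window,
  and is insensitive to the white-noise floor.

## Essential dynamics

PCA is the eigendecomposition of the mass-unweighted 3N × 3N covariance
of superposed coordinates. `scope = "core"` uses the eight histone
chains' Cα beads; `scope = "nuc"` adds DNA P beads with ten base pairs
truncated from each end — DNA ends have high RMSF and would otherwise
dominate the leading modes. Eigenvector signs are fixed by making the
largest-magnitude component positive, so projections are reproducible
across platforms. Superposition for the whole-nucleosome scope fits on
the full PCA selection (protein-only fitting is an alternative; fitting
on what you decompose is the more common default and is used here).

Free-energy landscapes are Boltzmann inversions of the 2D projection
histogram, `F = −kT ln(P/P_max)`: the most populated bin is exactly 0 and
*unsampled bins are flagged, never assigned 0*, because an unvisited bin
is missing data, not a minimum. kT defaults to 1 so landscapes are in
thermal units without needing a temperature.

Mode animations displace the mean structure along one eigenvector by
`animation_scale × sqrt(eigenvalue) × cos(phase)` over one cycle
(default five-fold amplification for visual clarity, even frame counts
hit the exact ±extremes) and are written as multi-MODEL PDB.

## The synthetic generator: what it is and is not

The generator is a statistical fixture with analytically known ground
truth, not a physics simulator. It emulates, geometrically and
statistically: a 146-bp duplex on a 1.7-turn superhelix (radius 41.8 Å,
pitch 25.9 Å, 10.5 bp/turn local twist, P beads at 9.3 Å from the helical
axis); eight 60-bead histone chains laid out as four dimers with the two
CENP-A α2 helices facing each other 6 Å apart as an idealized 4-helix
bundle; and four planted dynamic components:

1. i.i.d. isotropic Gaussian jitter, SD `core_sigma` (default 0.5 Å;
   0.35 Å under the compacted "acetyl" regime) — so per-bead RMSF has the
   closed form √3·σ;
2. sinusoidal rigid displacement of the terminal 10 bp of each end along
   the dyad→end direction (defaults 5 Å entry, 1 Å exit, periods 40 and
   27 ns) — displacement along that line makes the end-to-dyad distance
   modulation exactly sinusoidal with the planted amplitude;
3. a latent bivariate-Gaussian oscillation driving the α2–α3 scissoring
   angle (SD 5° about a 20° rest angle) and the minor-groove width at a
   probe base pair (SD 1.5 Å), with correlation `scissor_groove_rho`
   (default 0.82) constructed by Gaussian mixing
   (`g = ρ·s + sqrt(1−ρ²)·ε`);
4. under the acetyl regime, a constant rigid offset (default 2 Å) moving
   the CENP-A′/H4′ dimer toward CENP-A/H4, so the difference in mean
   dimer-COM distance between regimes equals the offset exactly.

The beads that carry planted signals (CENP-A α2/α3, the groove probe
pair) receive their deterministic signal *without* jitter. This is a
deliberate fixture-design choice: it gives the planted correlation and
amplitudes closed-form expectations, so recovery tests are sharp rather
than attenuation-corrected. The `"unmodified"` preset has symmetric 2 Å
breathing and zero scissor–groove coupling; the `"acetyl"` preset has the
compacted core, the dimer offset, asymmetric breathing and the 0.82
coupling — mirroring the qualitative contrast such studies report.

What the generator does **not** emulate: solvent, sequence-dependent DNA
mechanics, force-field energetics, anharmonic or multi-state kinetics,
correlated (non-white) thermal noise, and realistic histone fold
geometry. Passing the recovery tests therefore demonstrates that the
*estimators* are correct and unbiased under known conditions; it does not
certify behaviour on real all-atom trajectories, whose contact maps, COM
shifts and landscape ruggedness require the original microsecond runs.

## Numerical choices

* Contact distances are compared squared with a 10⁻⁹ Ų slack to make the
  ≤-cutoff decision robust to floating-point cancellation.
* Kabsch uses SVD with a determinant correction, so reflections are never
  returned even for degenerate-looking inputs.
* Eigenvalues are clipped at 0 (they can come out at −10⁻¹⁴ numerically);
  the eigenvalue sum equals the total positional variance to 10⁻⁸
  relative error by the trace identity, which is asserted in tests.
* Fragment-ion constants: proton 1.007276 Da, water 18.010565 Da,
  monoisotopic residue masses to five decimals — this reproduces
  published 5-decimal theoretical columns to within 10⁻³ m/z. Neutral
  losses and a/c/z series are deliberately excluded; the default 0.4 Da
  match tolerance suits ion-trap CID spectra.
* Fiber scoring defaults to the inclusive comparison (fraction ≥ 0.5
  counts as positive) since "at least 50%" is the operational phrasing;
  a strict mode is exposed. Replication fractions pool foci counts
  across cells (Σ double-positive / Σ total), not means of per-cell
  ratios; the two differ and the pooled convention matches how foci
  totals are reported.
* Theoretical precursor m/z values are reported as computed; published
  spectra sometimes print *observed* precursor values that differ in the
  second decimal, and the package does not force agreement with them.

## Problem sizes

The validation suite uses sizes chosen to make sampling error small
relative to the asserted tolerances: 6000 frames for the RMSF closed-form
check (3% band ≈ 3.8 standard errors per atom), 5000 frames for the
coherence and breathing recoveries (the Fisher-z 95% interval around
ρ = 0.82 at n = 5000 is ≈ [0.78, 0.86]), 10⁵ samples for Boltzmann
curvature inversion (15% band), 2000 frames for planted-mode PCA, and 20
random 50-residue/20-frame fixtures for brute-force contact equality.

## Known limitations

Groove widths and scissoring are convention-bound (above); the PDB parser
handles the ATOM/HETATM subset only; trajectories are held in memory as a
frames × 3N matrix, which is comfortable for coarse-grained beads and
Cα/P subsets but not for full atomistic systems at long lengths; and the
free-energy landscape is a histogram estimator — no kernel smoothing or
reweighting — so its ruggedness at fixed sampling depends on bin count.
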