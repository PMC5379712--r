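# nucdyn

Analysis toolkit for nucleosome core particle (NCP) dynamics, built around
the question of how histone post-translational modifications — in
particular acetylation and methylation of lysine 124 in the centromeric
histone variant CENP-A — reshape nucleosome structure, DNA accessibility
and CENP-C recruitment.

The package has three parts:

1. **Trajectory analysis** for molecular-dynamics-style coordinate data:
   residue–residue contact occupancy maps and interface-retention scoring,
   RMSF with blocked error bars, mass-weighted center-of-mass (COM)
   distance distributions between histone dimers, DNA end-to-pseudo-dyad
   unwrapping distances, groove-width and α2–α3 helix-scissoring time
   series with Pearson coherence, essential-dynamics PCA (histone core or
   whole nucleosome with DNA-end truncation), free-energy landscapes and
   amplified mode animations.
2. **A synthetic nucleosome generator**: an idealized 146-bp duplex wound
   ~1.7 superhelical turns around eight pseudo-histone chains, simulated
   with *planted*, analytically known dynamics (isotropic jitter,
   asymmetric sinusoidal end breathing, a correlated scissoring/groove
   latent oscillation, a dimer compaction offset). Every analysis stage is
   validated by recovering the planted parameters.
3. **Mass-spectrometry and cell-scoring calculators**: monoisotopic b/y
   fragment-ion series and spectrum annotation for modified peptides
   (e.g. VTLFPK(acetyl)DVQLAR), and explicit counting rules for
   chromatin-fiber CENP-C co-localization, centromeric replication timing
   and four-category mitotic defect binning.

## The core quantities

* **Contact occupancy** between residues *i*, *j* over *T* analyzed frames,
  using one representative atom per residue (Cα for protein, P for DNA):
  `O_ij = #{t : ||x_i(t) − x_j(t)|| ≤ c} / T` with cutoff `c = 8 Å` by
  default. `O_ij = 1` means the contact is formed in every frame.
* **RMSF** of atom *i* about its time average:
  `RMSF_i = sqrt(⟨||x_i(t) − ⟨x_i⟩||²⟩)`, reported with the standard
  deviation over blocked thirds of the analysis window.
* **Essential dynamics**: eigendecomposition of the 3N × 3N positional
  covariance of the superposed trajectory; free-energy landscapes by
  Boltzmann inversion of the projection histogram,
  `F(q1, q2) = −kT ln(P / P_max)`, so the most populated bin is at 0 kT.
* **Fragment ions**: `b_i = Σ_{k≤i} m_k + proton`,
  `y_i = Σ_{k>n−i} m_k + water + proton`, with modification mass deltas
  (acetyl +42.010565 Da, methyl +14.015650 Da) folded into the residue
  masses; multi-charge m/z = (neutral + z·proton)/z.

## Worked example

```r
library(nucdyn)

params <- simulation_params(n_frames = 2000, seed = 42)
sys  <- build_nucleosome_model(params)
traj <- simulate_trajectory(sys$model, sys$topo, params)
traj
#> <ncp_trajectory> 2000 frames x 772 atoms, t = [0, 199.9] ns

# coherence between 4-helix-bundle scissoring and minor-groove modulation
sc <- scissoring_series(traj, sys$topo)
gw <- groove_width_series(traj, sys$topo, "minor", position = 73)
series_correlation(sc, gw)
#> [1] 0.8033061

# asymmetric DNA end breathing, recovered from end-to-dyad series
entry <- dna_end_to_dyad_series(traj, sys$topo, "entry")
exit  <- dna_end_to_dyad_series(traj, sys$topo, "exit")
round(c(entry = harmonic_amplitude(entry$series)$amplitude,
        exit  = harmonic_amplitude(exit$series)$amplitude), 2)
#> entry  exit
#>  5.00  0.98

# CENP-A / CENP-A' interface occupancy on the post-equilibration window
bundle <- contact_occupancy(traj, sys$topo,
                            selection(roles = "CENP-A",  atom_names = "CA"),
                            selection(roles = "CENP-A'", atom_names = "CA"),
                            analysis_config(equilibration_fraction = 0.6))
bundle
#> <ncp_contact_map> 60 x 60 residues, cutoff 8 A, 800 frames; mean occupancy 0.037

# fragment ions of the K124-acetylated tryptic peptide
pep <- peptide("VTLFPKDVQLAR", mods = c("6" = "acetyl"))
pep
#> <ncp_peptide> VTLFPK(acetyl)DVQLAR, M = 1427.81362 Da
head(render_ion_table(pep), 3)
#>   b_index       b1        b2 seq       y1       y2 y_index
#> 1       1 100.0757  50.54148   V       NA       NA      NA
#> 2       2 201.1234 101.06532   T 1329.752 665.3799      11
#> 3       3 314.2074 157.60735   L 1228.705 614.8560      10
```

The planted correlation (0.82) and breathing amplitudes (5 Å entry, 1 Å
exit) are generator ground truth; the numbers above are their estimates
from the measured series. The ion table rows pair each residue's b index
with the complementary y index, the usual published layout.

A command-line wrapper over the same functions ships in
`inst/scripts/nucdyn` (subcommands `simulate`, `contacts`, `geometry`,
`pca`, `fel`, `animate`, `ions`, `score`; every run writes a
`manifest.json` with its configuration hash and seed).

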