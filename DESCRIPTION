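Package: nucdyn
Title: Nucleosome Trajectory Dynamics, Fragment-Ion and Foci-Scoring Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained and all-atom nucleosome
    trajectories: residue-residue contact occupancy maps and interface
    retention, RMSF with blocked error estimates, mass-weighted
    center-of-mass distance series, DNA end-to-dyad unwrapping distances,
    groove-width and helix-scissoring time series with Pearson coherence,
    essential-dynamics PCA with free-energy landscapes and amplified mode
    animations. Includes a synthetic nucleosome generator that plants
    analytically known dynamics (breathing, scissoring-groove coupling,
    dimer compaction) for end-to-end validation, a monoisotopic b/y
    peptide fragment-ion calculator with spectrum annotation for histone
    modification analysis, and counting rules for chromatin-fiber
    co-localization, centromere replication timing, and mitotic defect
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
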