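Package: ConPathDMS
Title: Consensus Pathogenicity Scoring and Dimer-Interface Trajectory
    Analysis for hRPE65 Missense Variants
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-track assessment of missense variants of uncertain
    significance in the dimerisation region of human RPE65. A consensus
    pathogenicity score (ConPath) aggregates binary calls from a benchmarked
    panel of variant-effect predictors, with tools selected by recall and
    specificity on a labelled benchmark set. A trajectory post-processing
    layer computes RMSD series, per-residue RMSF profiles and direct or
    water-mediated hydrogen-bond occupancies from multi-model coordinate
    ensembles of wild-type and mutant dimers, and derives structural and
    pairwise-interaction alerts by wild-type versus mutant comparison. The
    three alerts per variant are combined into a four-level
    pathogenic-potential classification. Synthetic benchmark and ensemble
    generators with known ground truth support end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
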