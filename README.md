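# ConPathDMS

Two-track assessment of missense variants of uncertain significance (VUS)
in the dimer-mediating region of human RPE65, the retinoid isomerase whose
biallelic loss causes gene-therapy-treatable retinal dystrophy.

**Who it is for.** Computational biologists and variant curators who have
(a) a matrix of per-variant calls or raw scores from variant-effect
predictors, and/or (b) coordinate ensembles (multi-model PDB snapshots from
molecular-dynamics production runs) of a wild-type dimer and of mutant
dimers, and want a reproducible, threshold-explicit classification of each
variant's pathogenic potential.

**The model.** Each variant gets three binary alerts:

- **ConPath alert** — the ConPath score is the number of tools in a
  benchmarked predictor panel calling the variant Pathogenic; with the
  19-tool panel, score ≥ 10 fires the alert (≤ 9 is a neutral consensus).
  Panel tools are those with Recall ≥ 0.78 and Specificity ≥ 0.67 on a
  labelled benchmark (27 pathogenic : 3 benign known RPE65 variants), with
  Precision = TP/(TP+FP), Specificity = TN/(TN+FP), Recall = TP/(TP+FN),
  Accuracy = (TP+TN)/N.
- **Interaction alert** — a native wild-type hydrogen bond (occupancy
  ≥ 0.5 of frames) involving the mutated residue is lost in the mutant:
  no contact over that residue pair reaches max(0.50, wt − 0.20).
- **Structural alert** — second-half mean RMSD of the interface alpha
  carbons ≥ 1.5 Å, or a ≥ 3-residue run with mutant RMSF ≥ 2.0 Å where the
  wild type stays < 1.0 Å.

The number of alerts (3/2/1/0) maps to the class HPPV / MHPPV / MLPPV /
LPPV (high → low pathogenic potential); variants with 0 or 3 alerts are the
high-confidence subset.

The package also ships a synthetic-data module (`makeBenchmark()`,
`makeEnsemble()`, `buildToyDimer()`) generating benchmarks with controlled
per-tool error rates and coordinate ensembles with controlled per-residue
RMSF and hydrogen-bond occupancies, so the whole pipeline is testable
without any external download, plus transcriptions of the published
19-tool × 13-variant call matrices, benchmark statistics, occupancy table
and alert annotations (`hrpe65DmsData()`).

## Worked example

```r
library(ConPathDMS)

d <- hrpe65DmsData()                      # bundled study data
rbind(conPath(d$matrix1), conPath(d$matrix2))
#>    variant votes panel_size       call
#> 1    K303N    13         19 Pathogenic
#> 2    N373S     0         19    Neutral
#> 3    D375N     3         19    Neutral
#> 4    D375H     6         19    Neutral
#> 5    E399K     9         19    Neutral
#> 6    T390I    17         19 Pathogenic
#> 7    V407A    14         19 Pathogenic
#> 8    T400S     6         19    Neutral
#> 9    W402S    15         19 Pathogenic
#> 10   N301S     1         19    Neutral
#> 11   S307F    17         19 Pathogenic
#> 12   V384F    13         19 Pathogenic
#> 13   T306I    18         19 Pathogenic
```

Each row is one VUS: `votes` is its ConPath score (Pathogenic calls among
the 19 panel tools) and `call` applies the ≥ 10 threshold — e.g. E399K sits
at the borderline score 9 and is called Neutral by consensus.

```r
rep <- cohortReport(d$alerts)             # the 13 three-alert profiles
rep$classCounts
#>  LPPV MLPPV MHPPV  HPPV
#>     4     3     4     2
rep$highConfidence
#> [1] "N373S" "D375N" "D375H" "T400S" "S307F" "T306I"
```

Four variants show no alert (confidently neutral), two show all three
(confidently pathogenic: S307F, T306I); the six together are the
high-confidence subset.

The trajectory side works the same way from coordinates: read ensembles
with `readPdbEnsemble()`, compute `rmsdSeries()` / `rmsfProfile()` /
`hbondOccupancy()` / `waterBridgeOccupancy()`, derive alerts with
`structuralAlert()` and `interactionAlert()`, or let
`runFullEvaluation()` drive everything from a config (YAML or list) and
write the intermediate and final tables.

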