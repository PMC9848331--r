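---
title: "Methods: consensus pathogenicity scoring and dimer-interface trajectory alerts"
author: "ConPathDMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus pathogenicity scoring and dimer-interface trajectory alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConPathDMS)
```

## The problem

Human RPE65 is the retinoid-isomerase of the visual cycle; biallelic
loss-of-function variants cause retinal dystrophies that are now treatable
by gene therapy, which makes the classification of missense variants of
uncertain significance (VUS) in this gene clinically consequential. Variants
falling in the dimer-mediating sequence (DMS) — the region through which the
two RPE65 monomers associate — can be pathogenic through destabilisation of
local folding or of the dimer interface rather than through direct catalytic
damage, so sequence-only predictors and structure-based evidence are
complementary there.

ConPathDMS implements a two-track assessment of such variants:

1. a **consensus track**: binary pathogenicity calls from a panel of
   variant-effect predictors, benchmarked on labelled RPE65 variants and
   aggregated into a vote count (the *ConPath score*);
2. a **structural track**: post-processing of coordinate ensembles (e.g.
   snapshots from molecular-dynamics production runs, stored as multi-model
   PDB) of a wild-type dimer and of one mutant dimer per variant, yielding a
   *structural alert* (conformational deviation) and a *pairwise-interaction
   alert* (loss of native hydrogen bonds).

The two tracks meet in a three-flag profile per variant — structural,
interaction, and ConPath (score at or above threshold) — and the number of
flags that fire maps to a four-level class:

| alerts | class | reading |
|---|---|---|
| 3 | HPPV | high pathogenic potential |
| 2 | MHPPV | moderate/high |
| 1 | MLPPV | moderate/low |
| 0 | LPPV | low |

Variants with 0 or 3 alerts form the *high-confidence* subset: all lines of
evidence agree.

## Consensus track

### Binarisation

Tools that emit raw scores are converted to Pathogenic/Neutral calls with
the convention *score ≥ cutoff ⇒ Pathogenic*. `defaultCutoffs()` carries the
conventional per-tool cutoffs (0 for Eigen/Eigen-PC raw coding scores,
SNPs3D, INPS-sequence, PROST; 0.4 for Integrated FitCons; 0.5 for REVEL,
VEST4, DANN, MutPred2, PON-P2; 0.75 for MVP; 20 for CADD/CADD_hg19; 50 for
SuSPect). Whether a score exactly at the cutoff is pathogenic is a
convention, not a fact of the tools; we adopt ≥ (matching the common "CADD ≥
20" usage) and expose a per-tool strict-inequality override
(`binarizeCalls(strict = )`). Missing cells stay missing; binarisation is
idempotent and monotone (raising a score never turns a Pathogenic call
Neutral), properties the test suite asserts on random matrices.

### Benchmarking and tool selection

Performance on a labelled benchmark (27 pathogenic : 3 benign in the
bundled study data — the real imbalance of the public record for this gene)
is summarised by the four standard fractions

$$\mathrm{Precision}=\frac{TP}{TP+FP},\quad
\mathrm{Specificity}=\frac{TN}{TN+FP},\quad
\mathrm{Recall}=\frac{TP}{TP+FN},\quad
\mathrm{Accuracy}=\frac{TP+TN}{TP+TN+FP+FN}.$$

Metrics are computed in full precision and rounded (half-up, 2 decimals)
only for reporting; a zero denominator yields `NA` plus an `undefined` flag,
never a silent 0. On a benchmark of known class sizes the printed recall and
specificity determine the whole confusion table
(`impliedConfusionCounts()`), which is how the bundled per-tool statistics
are expanded to counts.

Tool selection keeps tools with recall ≥ 0.78 **and** specificity ≥ 0.67.
These thresholds are quoted on the reported 2-decimal scale and are applied
there: a tool recovering 21 of 27 pathogenic variants (21/27 = 0.777…,
reported 0.78) passes, as does 2 of 3 benign (2/3 → 0.67). Applying them to
raw fractions instead would silently drop almost the entire published
19-tool panel — a subtle trap we document because it is invisible on any
benchmark whose class sizes divide the thresholds evenly.

### ConPath score

The ConPath score of a variant is the number of panel tools calling it
Pathogenic. With the 19-tool panel, a score ≥ 10 is a pathogenic consensus
call and ≤ 9 neutral; for any other panel size the default threshold is the
strict majority `floor(n/2) + 1` (which reproduces 10 at n = 19), and every
report carries the panel size. Missing panel predictions are an error by
default; an opt-in policy counts them as Neutral with a warning —
conservative toward non-pathogenicity, so an incomplete panel can only
lower, never raise, a score.

```{r}
d <- hrpe65DmsData()
conPath(d$matrix1)
```

## Structural track

### Superposition, RMSD, RMSF

Rigid-body superposition is a least-squares (Kabsch) fit with the
reflection branch excluded; fits with fewer than 3 atoms or collinear
geometry are rejected. The RMSD series superposes each frame on a *fit*
selection and measures a second selection without refitting — mirroring the
production-run setup in which the alpha carbons of the external residues
are restrained (they define the frame of reference) while the interface
region moves freely. The "second half" summary statistic is the mean over
the last `ceiling(N/2)` frames. RMSF is the per-atom root-mean-square
deviation about the window-mean position after superposition (or without
any fit, `fit = NULL`, for ensembles already sharing a frame of reference —
the standard "nofit" analysis). Selections use a compact mini-language,
e.g. `"A:70-125:CA"`; reports can renumber residues into hRPE65 numbering
via a constant offset (`toHrpe65()`, default 277: model residue 98 is
hRPE65 375).

### Hydrogen bonds and occupancies

The geometric criteria are configurable because no universal convention
exists; the defaults are donor–acceptor heavy-atom distance ≤ 3.5 Å and
donor–H–acceptor angle ≥ 135°, conventional values for trajectory analysis.
When a topology carries no hydrogens, a heavy-atom-only fallback (≤ 3.3 Å)
is available behind a warning. Occupancy is the fraction of frames in which
*any* qualifying atom pair connects the two residues — a bidentate contact
counts once per frame, so residue-level occupancies never double-count.
Contacts whose atoms on both ends belong to charged side-chain groups are
tagged salt bridges; the alert logic treats them like any other direct
bond, because a lost ionic anchor is at least as destabilising as a lost
neutral bond. A water bridge requires a *single* water oxygen within the
distance criterion of a polar atom of each residue in the same frame; two
waters each serving one side do not bridge. Side-chain packing contacts
(`contactOccupancy()`, 4.5 Å) are reported for completeness but never feed
the interaction alert, which is hydrogen-bond based.

### The two structural alerts

**Interaction alert.** Native interactions are the wild-type direct
contacts with occupancy ≥ 0.5 (present for at least half the trajectory).
A native contact is *maintained* in a mutant when some direct contact over
the same residue pair has occupancy ≥ max(0.50, wt − 0.20): a bond may
weaken by up to 20 occupancy points but never below half-time presence.
This calibration is the loosest rule that cleanly separates the quantified
wild-type→mutant transitions in the bundled study data (0.55 → 0.52
maintained; 1.00 → 0.75 lost; 0.90 → 0.60 lost). The alert fires when at
least one native pair involving the mutated residue is lost; pairs
elsewhere in the network are reported as context but do not trigger, since
downstream rearrangements are consequences, not independent evidence.

**Structural alert.** Fires when the mutant's second-half mean RMSD of the
interface selection reaches 1.5 Å (wild-type baseline in the bundled data:
about 1.0 Å), **or** when a run of ≥ 3 consecutive residues shows mutant
RMSF ≥ 2.0 Å where the wild type stays below 1.0 Å — a localised
flexibility peak absent from the wild type. The OR combination is a design
choice: in the bundled data the two signatures co-occur in all four flagged
variants, so OR and AND are indistinguishable there; OR is kept because
either signature alone is already a reproducible deviation from the
wild-type baseline.

## Synthetic data: what it emulates, and what it does not

`makeBenchmark()` draws per-tool calls independently with the configured
sensitivity/specificity at the study's 27:3 imbalance — it emulates
calibrated-but-imperfect predictors, not correlated ones (real predictor
panels share training data and features, so real consensus scores are more
correlated than simulated ones; tests on generated benchmarks validate the
*bookkeeping*, not panel redundancy).

`makeEnsemble()` produces frames as the reference structure (a schematic
~60-residue two-chain dimer, `buildToyDimer()`, with backbone and polar
side-chain atoms) plus independent rigid per-residue Gaussian displacements
whose per-coordinate scale σ/√3 makes the expected 3-D RMSF equal the
per-residue target σ. Prescribed bonds place the acceptor (or bridging
water) inside the geometric criteria with probability equal to the target
occupancy — bonded frames draw distance from U(2.7, 3.3) Å and angle from
U(150°, 180°), non-bonded frames distance from U(4.5, 6.0) Å, so the ground
truth is unambiguous with respect to the default criteria. Frames are
independent: there is no autocorrelation, no physical force field, no
solvent beyond the prescribed bridging waters. Passing recovery tests
therefore demonstrate estimator correctness (occupancy counting, RMSF
estimation, alert thresholds), not the ability of short simulations to
sample real conformational ensembles.

Problem sizes in the tests were chosen so the sampling oracles are sharp at
desk scale: 2000 frames for occupancy recovery (binomial 99% CI half-width
≈ 0.023 at p = 0.5), 1000 frames for RMSF recovery (3 SE ≈ 4% of σ), a few
hundred replicate benchmarks for rate recovery. The published trajectory
analyses behind the bundled summaries come from 3 µs production runs that
are not reproducible at this scale; the bundled occupancy and RMSD/RMSF
summary tables transcribe their *reported outcomes* and the recovery tests
substitute for re-simulation.

## Numerical choices and degenerate inputs

- Rounding of reported metrics is half-up (`roundHalfUp()`), not
  round-half-even, to match how the reference values were printed.
- Superposition refuses < 3 or collinear fit atoms rather than returning an
  ill-conditioned transform; the SVD branch excludes reflections.
- Occupancies are frame-order invariant and stable under trajectory
  self-concatenation (asserted as properties).
- Undefined metrics (zero denominators) propagate as `NA` + flag; variants
  with incomplete alert profiles are reported but never classified.
- Ties: score = cutoff is Pathogenic (overridable per tool); occupancy
  exactly at a threshold passes (≥ conventions throughout).
- PDB I/O (via bio3d) preserves coordinates to the format's 3 decimals;
  files with insertion codes or inconsistent per-MODEL atom counts are
  rejected with the offending model named.

## Known limitations

- The interaction alert keys contacts by residue pair, not by atom pair: a
  contact that migrates between atoms of the same pair counts as
  maintained. This matches how the reference judgments were made but can
  mask a chemically meaningful rearrangement.
- The maintenance rule's floor/drop calibration is anchored on one protein
  system; other systems may need different values (both are arguments).
- The heavy-atom hydrogen-bond fallback cannot check angles and is
  correspondingly permissive.
- `classifyVariant()` weights the three alerts equally; a borderline
  ConPath score (e.g. 9/19) counts fully as "no alert", surfaced only in
  the evidence text.
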