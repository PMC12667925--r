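---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind each stage of
`lmsproteo`, the parameters that matter, what the synthetic cohort does and
does not emulate, and the design choices made where the underlying
methodology left the details open.

## TMT preprocessing

The preprocessing chain runs in a fixed order: missingness filter → KNN
imputation → sample-loading normalization → internal reference scaling →
TMM. The order matters: imputation needs the filter first (a feature with no
observations cannot be imputed), and IRS needs complete per-plex reference
means.

* **Missingness filter** (`min_valid_frac`, default 0.30): features observed
  in fewer than 30% of channels are removed. The boundary is inclusive — 30
  of 100 valid stays, 29 is dropped.
* **KNN imputation** (`k`, default 10): a missing cell is the mean of the
  `k` nearest features (Euclidean distance on jointly observed samples,
  scaled by the number of shared observations) that are observed at that
  sample. The underlying method does not fix `k`, the metric, or the scale;
  we declare `k = 10`, the scaled metric above, and log2-scale imputation.
  Imputed values are absolute neighbor values (the standard KNN-imputation
  semantics), so an imputed cell carries its neighbors' plex batch factors
  rather than its own; with 20% missingness and 0.3 log2 batch SD this
  leaves a small plex-structured residual after IRS. It is visible in very
  clean simulations (see *Limitations*) and negligible relative to a 1.0
  log2 subtype signature.
* **Sample loading** rescales every channel to the grand-mean column total —
  the assumption that equal protein amounts were labeled per channel.
* **IRS**: per feature, each plex is scaled by `g / r_p` (`r_p` = plex
  reference mean, `g` = geometric mean of the `r_p`). After correction the
  reference means agree exactly across plexes. If a feature has no reference
  measurement in some plex, that plex's values become missing rather than
  guessed — conservative, and consistent with filtering before imputation.
* **TMM** (`logratio_trim = 0.30`, `sum_trim = 0.05`): scale factors against
  the column whose total is closest to the mean, trimmed on both tails of M
  and A, rescaled to geometric mean 1. Running after SL and IRS, it is a
  final median-centering touch; factors are near 1.
* **Differential abundance**: Welch *t* with BH correction on log2
  intensities. Count-based models designed for sequencing reads do not
  transfer to TMT log intensities; the Welch substitute preserves the two
  roles the stage plays here — ranking features and thresholding at an FDR.

## Consensus NMF subtyping

The top `top_n = 500` rows of the merged proteome + phosphoproteome matrix
by **mean absolute deviation** (about the mean — not the median-based
`stats::mad`) are median-centered and split into positive and negative
parts, giving a non-negative matrix with `2 * top_n` rows on which
`V ≈ WH` is meaningful. This split is the established convention for
NMF on signed log-ratio data; `(pos − neg)` reconstructs the centered input
exactly.

Factorization uses Lee–Seung multiplicative updates for the Frobenius
objective (compiled in C++), which never increase the objective. Full
factorizations (`nmf_factorize()`) run to `tol = 1e-6` within
`max_iter = 2000`. Consensus restarts only need a stable argmax assignment,
not full convergence, so `consensus_cluster()` defaults to `max_iter = 200`,
`tol = 1e-4` per restart; "iterations" in the consensus sense are random
restarts (1000 by default, 200 in the bundled analyses), each contributing
one co-clustering indicator.

Rank selection surveys k = 2..7 with two reproducibility metrics computed
from the consensus matrix: the cophenetic correlation of the average-linkage
dendrogram against the `1 − consensus` distances, and the mean silhouette on
the same distances. The default choice rule takes the k's whose cophenetic
value is within `drop_tol = 0.05` of the maximum and whose smallest class
has ≥ `min_class = 5` samples, discards those whose silhouette falls more
than `sil_tol = 0.1` below the candidates' best, and picks the largest
survivor. The silhouette condition exists because the cophenetic curve can
plateau above the true rank (see *Limitations*); both metrics backing the
choice mirrors how such cluster numbers are chosen in practice, and
`k_override` reproduces a fixed published choice exactly.

## Allele-specific instability scores

All scores work on merged segments (adjacent, touching, same-state) and
autosomes only; profiles are expected to be purity/ploidy-resolved integer
copy numbers (total = major + minor).

* **Ploidy** is the length-weighted mean total copy number; **WGD** is
  called when more than 50% of the autosomal genome (denominator: the
  build's autosomal length) has major copy number ≥ 2. A coverage fraction
  below 50% triggers a warning.
* **CIN** counts merged segments per category — gain (total > 2), loss
  (total < 2), LOH (minor = 0, total ≥ 1) — and sums them. A segment counts
  in every category it satisfies (a single-copy LOH segment adds 2);
  `exclusive = TRUE` switches to one-category counting.
* **HRD-LOH**: maximal LOH runs strictly longer than 15 Mb that do not span
  an entire chromosome.
* **LST**: per chromosome arm, after removing runs shorter than 3 Mb and
  re-merging equal flanks, junctions between runs of *different total copy
  number* where both flanks are ≥ 10 Mb and the gap is ≤ 3 Mb. Using total
  copy number as the LST state means copy-neutral LOH does not create a
  junction — it changes alleles, not dosage.
* **TAI**: maximal allelic-imbalance runs (major ≠ minor) touching a
  telomere (position 0 or the chromosome end), not spanning the whole
  chromosome, and not crossing the centromere. "Crossing" means spanning
  the whole centromere interval; a run ending inside it, or exactly at its
  edge, counts as non-crossing. No minimum length by default
  (`min_len = 0`, configurable).
* **HRD = HRD-LOH + LST + TAI**, exactly.

Every scorer is checked against an independent naive implementation (direct
scans of runs and junctions) on 1,000 random profiles in the test suite.

## Enrichment and kinase activity

`ssgsea_scores()` ranks each sample's features by (log-transformed)
abundance and walks the ranked list: in-set steps add `|value|^weight`
(normalized to sum 1), out-of-set steps subtract `1/(N − n_set)`. The score
is the *area* under this running curve (its signed sum over all ranks), with
`weight = 0.75`, `min_overlap = 3`, and per-set z-scoring across samples as
the normalized enrichment score. The same engine scores pathway collections,
immune/stemness/cell-cycle signatures, and — after `expand_sites()` turns
multi-site phosphopeptides into one entity per site — site-centric PTM
signatures. Permutation p-values are deliberately omitted for single-sample
scores (the scores are consumed as continuous variables); `preranked_gsea()`
provides the classic max-deviation ES with feature-label permutations where
significance is needed.

`kinase_scores()` is a substrate-set z-score: for a kinase with `m ≥ 3`
annotated sites present, `z = (mean substrate FC − mean FC) · √m / SD(FC)`
against the global site fold-change distribution, two-sided normal p, BH
across kinases. Network-propagation refinements exist in the field; the
plain z-score keeps the statistic transparent and testable (negating all
fold changes negates every z exactly), and the substrate aggregation is
exposed for extension.

## Integration stages

Cis/trans mapping uses Spearman correlation (rank t approximation for p, as
`cor.test`) between gene-level copy number and the gene's own mRNA/protein
abundance; BH runs within the cis family, and within each copy-number
gene's trans family when trans targets are requested (all-pairs trans at
cohort scale is quadratic and rarely wanted). The transfer experiment
filters features at FDR < 0.01 and linear |FC| > 2 (one-vs-rest contrasts),
then trains a random forest with a stratified 70/30 split and `mtry` chosen
by stratified 10-fold cross-validation on the training portion; performance
is macro-averaged F1 on the held-out samples. Survival stratification is
standard Kaplan–Meier with the log-rank test.

## The synthetic cohort

`simulate_cohort()` emulates the *structure* such studies rest on: three
balanced subtypes (n = 60 by default) with 1.0 log2 signatures on 50
proteins/phosphosites each; 16-channel plexes whose pooled-reference channel
equals, before noise, the arithmetic mean of its plex's tumor channels on
the intensity scale — precisely the premise IRS corrects against;
multiplicative per-plex, per-feature batch effects (0.3 log2 SD); 20%
missingness, at random or with logistic intensity-dependent dropout;
per-subtype segment profiles whose lesions are planted so each contributes
to exactly one score (copy-neutral 2+0 LOH; 8 Mb telomeric 2+1 imbalance,
below the LST flank minimum; balanced 12 Mb 2+2 insertions for LST junction
pairs; 5 Mb filler gains/losses below every threshold); cis genes whose
mRNA/protein track their copy number; kinases whose substrate sites shift in
their active subtype; exponential survival with per-subtype hazards (0.02,
0.12, 0.06 events/month) under uniform censoring.

Two deliberate simplifications are worth knowing. First, tumor channels
carry `noise_sd = 0.5` log2 noise — biological plus technical variation
between samples — while pooled-reference channels carry only
`ref_noise_sd = 0.1` log2: the pool is the same aliquot in every plex, so it
has no biological variation, and 0.1 log2 is a typical within-plex technical
CV. Giving references the full sample-level noise would make IRS propagate
one channel's noise to its whole plex, which misrepresents how pooled
references behave. Second, the gene-level copy-number matrix used for
cis/trans mapping jitters independently of subtype; the subtype-linked
instability lives in the segment profiles. The two inputs serve different
consumers, and coupling them would plant additional sample structure beyond
the intended subtypes.

What the generator does **not** emulate: feature-feature correlation
(co-regulation), peptide-level structure and rollup, realistic mutation or
copy-number landscapes, non-proportional hazards, or cohort imbalance.
Passing tests on this cohort therefore demonstrate the correctness of the
computations and the recoverability of planted structure under controlled
noise — not performance on the full messiness of real data.

## Problem sizes

The bundled analyses and tests use a 60-sample, 1,500-protein,
1,000-phosphosite cohort for the end-to-end clustering checks (rank survey
k = 2..7 at 200 restarts, five replicate cohorts), 1,000 random segment
profiles for scorer/oracle equivalence, and 1,000-feature matrices for the
statistical-calibration checks. These sizes give stable medians while
keeping a full run in minutes on one CPU.

## Limitations

* On cleanly separated synthetic clusters the cophenetic correlation does
  not drop above the true rank: at k = 4 every restart re-finds the same
  best sub-split of one cluster (a fixed noise direction in the data), so
  the consensus matrix stays near-ultrametric and cophenetic stays ≈ 1 for
  all k. Real cohorts, with many weak competing substructures, produce the
  restart disagreement that makes the cophenetic curve informative. This is
  why rank selection here also leans on the silhouette, which does fall
  sharply past the true rank (≈ 1.0 at k = 3 vs ≈ 0.75 at k = 4 under the
  default simulation), and on minimum class size.
* IRS leaves the small KNN-related plex residual described above; with
  realistic co-regulated features the imputation error would be dominated by
  shared biology instead.
* The LST smoothing iteration removes short runs greedily (first-shortest);
  pathological tie arrangements could in principle merge differently than
  other implementations, though random-profile testing against the naive
  oracle has not produced a discrepancy.
* `segment_profiles` requires non-overlapping segments per chromosome and
  integer allele-specific states; subclonal (fractional) copy numbers are
  out of scope.
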