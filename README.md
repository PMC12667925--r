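# lmsproteo

Proteogenomic subtyping and genomic-instability scoring for multi-omic tumor
cohorts, built around the analysis design of TMT-based soft-tissue
leiomyosarcoma (STLMS) studies: multiplexed proteome + phosphoproteome
quantification with pooled-reference channels, targeted-panel allele-specific
copy-number segments, and survival follow-up. The package is aimed at
computational biologists who want the full chain — from raw TMT intensities
to proteome subtypes, HRD scores, kinase activities, and survival strata — as
tested, reusable R functions, exercised end-to-end on a synthetic cohort with
planted ground truth.

## What it implements

**TMT preprocessing** (`normalize_tmt()` and its stages): features observed
in <30% of samples are removed; remaining gaps are filled by K-nearest-
neighbor imputation on the log2 scale; sample-loading normalization equalizes
channel totals; internal reference scaling (IRS) rescales each plex per
feature by `g / r_p`, where `r_p` is the plex's pooled-reference mean and `g`
the geometric mean of all `r_p`, removing plex batch effects; trimmed mean of
M-values (TMM, trim 0.30 on M / 0.05 on A) centers the channels. A Welch
*t* + Benjamini-Hochberg stage (`differential_abundance()`) provides
two-group comparisons on the log2 intensities.

**Consensus NMF subtyping** (`prepare_nmf_input()`, `consensus_cluster()`,
`rank_survey()`, `assign_subtypes()`): the top-500 features of the merged
proteome + phosphoproteome matrix by mean absolute deviation are
median-centered and split into positive/negative parts; `V ≈ WH` is
factorized by multiplicative updates (compiled core) from many random
restarts; co-clustering frequencies form the consensus matrix, and rank
k = 2..7 is surveyed by cophenetic correlation and mean silhouette.

**Allele-specific instability scores** (`score_instability()`): ploidy
(length-weighted mean total copy number), whole-genome doubling (>50% of the
autosomal genome at major copy number ≥ 2), CIN (count of gains CN > 2,
losses CN < 2, and LOH segments), and the HRD scar components — HRD-LOH
(LOH runs > 15 Mb not spanning a whole chromosome), LST (junctions between
≥ 10 Mb regions of different total copy number, ≤ 3 Mb apart, after 3 Mb
smoothing, per arm), TAI (telomeric allelic-imbalance runs not crossing the
centromere) — with `hrd = hrd_loh + lst + tai`.

**Enrichment and kinase activity** (`ssgsea_scores()`, `preranked_gsea()`,
`ora_test()`, `expand_sites()`, `kinase_scores()`): single-sample GSEA with
weight 0.75, the area-under-running-sum statistic, min overlap 3, and per-set
z-scoring; classic preranked GSEA with permutation p-values; hypergeometric
over-representation with BH correction; site-centric expansion of multi-site
phosphopeptides; KSEA-style kinase z-scores
`z = (mean substrate FC − mean FC) · √m / SD(FC)`.

**Integration** (`cis_trans_map()`, `alteration_frequencies()`,
`cooccurrence_fisher()`, `select_transfer_features()`,
`fit_subtype_classifier()`, `km_logrank()`): Spearman cis/trans
copy-number-expression mapping with per-family BH; oncoprint frequencies and
Fisher co-occurrence; the FDR < 0.01, |FC| > 2 feature filter feeding a
random-forest subtype-transfer classifier scored by macro-F1; Kaplan-Meier
curves with log-rank tests.

**Synthetic cohort** (`simulate_cohort()`, `simulate_segments()`): generates
every input above with planted subtype signatures, TMT batch structure with
pooled references, MS-style missingness, per-subtype instability targets
(exact in deterministic mode), cis effects, kinase-driven phosphosite shifts,
and subtype-dependent exponential survival — so the whole chain is testable
offline.

## Worked example

```r
library(lmsproteo)

coh <- simulate_cohort(simulation_config(seed = 7))
res <- run_pipeline(coh, out_dir = "run1", n_init = 200, seed = 7)

res$survey$table
#>   k cophenetic mean_silhouette min_class_size degenerate
#> 1 2  0.9882591       0.7008090             20      FALSE
#> 2 3  1.0000000       1.0000000             20      FALSE
#> 3 4  0.9985549       0.7646965              9      FALSE
#> 4 5  0.9933889       0.6176626              4      FALSE
#> 5 6  0.9845279       0.5089685              4      FALSE
#> 6 7  0.9756492       0.4916858              4      FALSE

res$report$chosen_k        # 3   (cophenetic + silhouette + min class size)
res$report$ari_vs_truth    # 1   (recovered labels match the planted subtypes)

head(res$instability, 3)
#>   sample_id   ploidy   wgd n_gain n_loss n_loh_segments cin hrd_loh lst tai hrd
#> 1      S001 4.023603  TRUE     64      3              8  75       8   4   3  15
#> 2      S002 4.058312  TRUE     78      4              8  90       8  14   6  28
#> 3      S003 2.022908 FALSE      5      1              1   7       1   4   1   6

res$survival_os$p          # 7.1e-05: subtypes stratify overall survival
```

The survey shows both reproducibility metrics peaking at k = 3 with every
class ≥ 20 samples; the instability table separates the genomically stable
subtype (ploidy ≈ 2, HRD ≈ 5) from the whole-genome-doubled, HRD-high
subtypes, mirroring the low/high instability split such cohorts show.

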