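---
title: "Methods: salivary proteomics and metaproteomics of a T2D case-control cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salivary proteomics and metaproteomics of a T2D case-control cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`salivamp` re-implements, as a tested and reusable pipeline, the analysis of
a salivary proteomics/metaproteomics case-control study of screen-detected
type-2 diabetes (15 healthy controls vs 15 T2D participants): 16S-guided
reduction of the bacterial protein search space, preprocessing and
imputation of peptide/protein quantification matrices, lowest-common-
ancestor (LCA) taxonomic profiling, differential-abundance and enrichment
statistics, and covariate-adjusted peptide-trait association. The mass-
spectrometry search itself is out of scope: the pipeline starts from a
post-search quantification report. All stages are exercised end to end on
synthetic cohorts with planted effects, so every statistical claim made by
the test suite is about quantities the package itself computes.

## The synthetic cohort generator

The generator (`sim_config()`, `make_taxonomy()`, `make_reference_bundle()`,
`simulate_cohort()`) emulates the structure of such a study's inputs:

* **Design.** Two groups of 15 participants (`n_per_group = 15`).
* **Taxonomy.** 7 phyla x 5 genera x 3 species (35 genera), mirroring the
  scale of an oral microbiome profile (tens of genera across ~7 phyla).
* **Reference bundle.** One V4-like 250-nt 16S reference per species,
  generated by hierarchical block mutation (about 25% of positions
  substituted per phylum, 8% per genus, 2% per species) so that 16S identity
  is ordered species < genus < phylum, plus 20 protein records per species
  with `SEQFxxxx_yyyyy` identifiers.
* **Peptides.** 600 human and 450 bacterial peptides — a desk-scale stand-in
  for the ~11,500/~7,500 of a deep experiment, chosen so the full pipeline
  runs in minutes; percentages and error rates, not absolute counts, are
  what the tests assert. Human peptides are proteotypic (about 3 per
  protein). Bacterial peptides map to 1–3 proteins within one species
  (70%), across species of one genus (20%), or across phyla (10%), so the
  LCA stage sees the full range of resolutions.
* **Intensities.** Per-feature mean log2 intensities are uniform over
  `dynamic_range_log10 = 4.5` decades (between the ~5 decades of human and
  ~4 of bacterial signal in deep salivary data), with per-feature biological
  SD of 0.5 log2 units. Planted protein and genus log2 fold changes are
  added to the T2D samples; defaults plant 12 human up / 3 down and 3
  bacterial up / 2 down at |log2FC| = 2, and one genus up / one down at
  |log2FC| = 1.5, echoing the asymmetry (mostly human, mostly up) of the
  motivating study.
* **Missingness.** Left-censored MNAR: `P(missing) = plogis(-k z + b)` with
  `z` the global z-score of the latent log2 intensity,
  `k = censoring_strength = 1.5`, and the intercept `b` solved numerically
  (`uniroot`) so the overall missing fraction equals `missing_rate = 0.25`.
  This is the mechanism the downshift imputation presumes; `k = 0` gives
  MCAR for comparison. The study itself does not report its missingness
  mechanism or rate, so these two values are configurable conditions, not
  calibrated ones.
* **16S data.** Per-participant ASV FASTA (species references with 0.5%
  per-base substitution error; each species present in a participant with
  probability 0.85) and a genus x sample count table drawn from a
  Dirichlet-multinomial (concentration 50, 30,000 reads) whose proportions
  track the simulated per-sample bacterial biomass — which is what makes the
  metaproteomics-vs-16S concordance stage meaningful.
* **Traits.** Age, sex, smoking (three categories), BMI, fasting glucose and
  HbA1c are drawn to match the published cohort's group summaries; insulin
  at 30 min, waist and fat% are log-normal with planted peptide slopes on
  the ln scale (default: two peptides of the up-shifted genus with slope
  -0.5 on insulin, echoing the reported negative associations).

All randomness flows from one seed through named sub-streams
(`stage_seed()`), so a fixed `sim_config()` reproduces the cohort
byte for byte, and the `truth` record lists exactly the planted non-null
features for downstream power/FDR checks.

**What the generator does not emulate:** spectrum-level effects (retention
time, ion mobility, fragmentation), realistic protein homology between
taxa, correlated peptide noise within a protein, batch structure, and
compositional coupling between human and bacterial signal. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to everything real data can do.

## Database reduction

`merge_dedupe()` concatenates participants' ASV FASTA and removes exact
(case-normalised) duplicates — deliberately literal, no clustering.
`align_16s()` computes optimal Smith–Waterman local alignment scores with
affine gaps via `Biostrings::pairwiseAlignment()`; the scoring scheme
defaults to the classic nucleotide-BLAST values (match +2, mismatch -3, gap
open 5, extend 2) because a raw-score threshold is only interpretable under
a concrete scheme: a perfect 250-nt match scores 500, and the default
retention rule — per query, score strictly greater than 450, then the top
200 by score — admits only near-full-length, high-identity hits. `N` scores
as a mismatch against everything, including itself. Ties at the top-k cutoff
break by subject identifier (strict top-k). `build_reduced_db()` emits the
union of all proteins of the retained taxa once each, with provenance. A
tabular adapter (`read_tabular_hits()`) ingests outfmt-6-like TSVs for users
who align externally.

The reduction is monotone (raising `min_score` or lowering `top_k` never
adds proteins) and idempotent, and the internal aligner is pinned to an
independent quadratic dynamic-programming oracle in the tests.

## Quantification preprocessing

`read_quant_report()` pivots the long report into peptide and protein
matrices; protein values are rolled up **from proteotypic peptides only**
(sum by default; median and top-3 mean available), since shared peptides
cannot be attributed unambiguously. `filter_valid()` keeps features with at
least 70% present values across **all** samples (the boundary is kept; the
filter is not per group, which the source procedure does not request).

`impute_downshift()` draws missing cells of feature *f* i.i.d. from
Normal(mu_f - 1.8 sigma_f, (0.3 sigma_f)^2) where mu_f, sigma_f are the
observed mean/SD of *f* across all samples. Note the distribution is
**per feature**, not per sample — the common Perseus convention is per
sample, but the procedure modelled here is explicitly relative to "the
corresponding protein across all samples", and that reading wins. A
zero-variance feature imputes at its mean with a warning.

`impute_iterative()` is a chained nonparametric imputer in the style of
forest-based imputation: initialise missing cells at feature means, then
re-predict each incomplete feature from all others (samples as
observations) with a random forest (`ranger`, single-threaded, seeded),
sweeping features by ascending missingness until the relative Frobenius
change of the imputed cells falls below 1e-3 (default cap 10 sweeps). The
regressor is a parameter (`num_trees`); the tests verify planted linear
structure is recovered with R^2 > 0.9 and that observed cells are bit-exact
untouched.

## Differential statistics

`two_sample_t()` is the pooled-variance Student test by default (Welch
available); `t_from_summary()` applies the identical formula to printed
means/SDs/ns, which is how the package recomputes published cohort
characteristic p-values (BMI 0.68, age 0.93, HbA1c 0.01, fasting glucose
< 0.001 at n = 15/15). Degenerate inputs are defined, not errors: equal
constant groups give t = 0, p = 1; unequal constant groups give the p -> 0
limit with a warning. `bh_adjust()` is the Benjamini–Hochberg step-up
(validated input, `stats::p.adjust` underneath, pinned to a brute-force
"min over the tail" oracle in tests). `differential_table()` combines
per-feature pooled tests, BH across all features, and a direction call at
q < 0.05; fold changes are computed after imputation, matching the
workflow order. `pca_quant()` is SVD PCA of centred (unscaled) log2 data —
the proteomics convention — reporting percent variance per component and
per-feature contributions (squared loadings normalised to 100 per
component) from which `pca_drivers()` lists separation drivers.

## Enrichment

`enrich_1d()` scores each annotation term by a two-sided Mann–Whitney
comparison of member vs non-member values, reported as the rank-biserial
score `s = 2 U_in/(n_in n_out) - 1` (ties counted half), so s = +1 exactly
when members occupy all top ranks, and s is invariant under monotone
transforms of the values. `enrich_2d()` computes s per dimension and refers
`z_x^2 + z_y^2` (tie-corrected normal approximations of U) to chi-square
with 2 df for joint significance — an approximation, documented and
swappable for a permutation p, whose tail the tests check against
Monte-Carlo. The per-group value fed to 2D enrichment is the per-group mean
log2 peptide intensity (the exact quantity is not specified by the source
procedure; this is the assumption made here). Minimum term size is 2,
matching the smallest term one would report. Thresholds default to BH FDR
< 0.02 for enrichment (the source also mentions 0.04 in one place for the
Fisher step; `alpha` is a parameter and 0.02 is the default).

`hcluster()` z-scores rows, then agglomerates on Euclidean distance with
average linkage by default (linkage is a flag; the source names only the
metric). `fisher_cluster()` tests each (cluster, term) 2x2 table with the
two-sided Fisher exact test (point-probability method) and BH within each
cluster.

## Taxonomic profiling

`lca()` returns the deepest node on all lineages; it operates on node
identity, not rank, and callers project with `ancestor_at_rank()` — so
ranks between phylum and genus may be present or absent (Unipept-style
behaviour without a complete rank ladder). Peptides resolving **below**
genus count as their genus in mapping summaries; without that rule
genus-mapping percentages are ill-defined. `relative_abundance()` sums raw
(back-transformed) intensities per taxon within each sample, keeps an
explicit `unassigned` bin, and normalises per sample — the compositional
convention, and required for per-sample t-tests on relative abundances.
`genus_intensity_diff()` follows the stated four steps literally:
back-transform, sum per genus over genus-specific peptides only,
re-log2, pooled t-test with BH. No compositional transform (CLR etc.) is
applied before the t-tests, matching the modelled procedure.
`concordance()` is the Pearson correlation of per-genus totals (summed raw
peptide intensity vs summed 16S reads, across all samples), with union-fill
of missing genera at 0 — "total intensity of all bacterial genera" is read
as the grand total per genus, an assumption documented here.

## Association models

`fit_trait_model()` regresses the ln-transformed, z-scaled trait on peptide
log2 abundance plus covariates (age, sex as an indicator, smoking as
current/ex vs never — two indicators for the three categories — and
glycemic status). Natural log is used for the trait: the base only rescales
the coefficient and the z-scaling absorbs it, which the tests verify as
exact invariance under positive rescaling of the trait.
`fit_interaction()` adds peptide x group and reports that coefficient.
`associate_all()` fits every peptide x trait pair, controls BH FDR jointly
across all pairs (per-trait family available — the source does not state
the family), and flags q < 0.05 as significant, p < 0.05 as suggestive.
Rank-deficient designs are an error naming the collinear columns in the
single-fit functions; `associate_all()` first drops constant or redundant
covariate indicators with a warning, which small cohorts can produce (for
example, a smoking category absent from the sample).

## Numerical choices and degenerate inputs

* Missingness intercept solved by `uniroot` on [-50, 50] to 1e-10.
* Iterative imputer convergence: relative Frobenius change < 1e-3.
* hclust ties follow `stats::hclust`'s deterministic behaviour for a fixed
  input order; the generator emits features in a fixed order, so the whole
  pipeline is seed-deterministic (two runs produce identical output MD5s).
* Strict boundaries: alignment score 450 is excluded; the 70% valid-value
  boundary is included; top-k is strict (ties beyond k dropped).
* A quantification report row with non-positive or missing intensity is a
  schema error: absent measurements are absent rows.

## Problem sizes used by the checks

The shipped analysis (`analysis/01...07`) runs the default 1050-peptide,
30-sample cohort; the test suite uses smaller cohorts (4–12 species,
60–120 peptides) and targeted matrices chosen so each statistical check has
the sample size it needs — e.g. >= 10^4 imputed cells for recovering the
downshift parameters (pooled standardized shift 1.8 and width ratio 0.3
within four standard errors), 200 simulation replicates for power (> 90% at
planted log2FC = 2, n = 15/15) and for FDR control under the global null.
These sizes are the package's own choices for tight, fast checks.

## Known limitations

* The taxonomy generator produces only phylum/genus/species ranks; the tree
  model supports intermediate ranks but the generator does not exercise
  them.
* The 2D joint test's chi-square approximation assumes the two dimensions'
  rank statistics are independent under the null, which correlated value
  maps violate; use the score signs/magnitudes, or a permutation p, when
  the two dimensions share structure.
* Protein rollup from proteotypic peptide sums is one convention among
  several; search engines may emit LFQ-style protein values instead, and
  `read_quant_matrix()` accepts such precomputed matrices.
* Dataset-scale headline counts of the motivating study (thousands of
  proteins, specific genus names) depend on its deposited raw data and a
  commercial search engine; they are qualitative anchors for the synthetic
  defaults, not quantities this package reproduces.
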