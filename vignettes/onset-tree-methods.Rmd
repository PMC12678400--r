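---
title: "Decision-tree subtyping of Parkinson's disease by age of onset: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree subtyping of Parkinson's disease by age of onset: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsettree)
```

## The problem and the approach

Parkinson's disease (PD) is clinically heterogeneous, and data-driven
subtyping by cluster analysis has proven sensitive to study design and hard
to validate across cohorts. `onsettree` implements an alternative,
interpretable route: train a binary CART classifier to predict whether a
patient has early onset PD (EOPD, age of onset strictly between 21 and 50
years, label 0) or late onset PD (LOPD, onset above 50, label 1) from
clinical rating-scale items, then read each leaf of the fitted tree off as a
*candidate subtype* — a conjunction of `(feature, ≤/>, threshold)`
conditions. Candidates are filtered through three criteria against an
independent validation cohort and the survivors are characterized
post hoc. The age of onset guides the partition without ever entering the
feature set, so the resulting subtypes are onset-related but defined purely
by clinical features.

The clinical substrate is the MDS-UPDRS rating scale (ordinal items scored
0 Normal to 4 Severe, across four parts), the 15-item Geriatric Depression
Scale (0–15), and gender. Patients with onset at exactly 50 years
(the class boundary) or at 21 or below (juvenile onset) are excluded from
labeling.

## The classifier

`fit_tree()` is a from-scratch binary CART with the Gini criterion
(`gini_impurity(counts) = 1 − Σ p²`, 0 for a pure node and 0.5 for a
balanced one). At every node each feature is scanned over all midpoints
between consecutive distinct sorted values; the split maximizing the
decrease in count-weighted impurity wins. Growth stops when a node is pure,
the depth limit is reached, or no split leaves both children with at least
`min_samples_leaf` rows. Three determinism rules make refits reproducible:

* among equal impurity decreases, the lowest feature index wins, then the
  smallest threshold;
* ordinal items are treated as numeric, so thresholds like "≤ 1.5" read as
  "at most Slight";
* a leaf with exactly tied class counts is labelled late onset (the
  dataset-majority class) and logged in `tie_leaves`.

Leaf-size limits are enforced on *row* counts, duplicates from oversampling
included; unique-patient accounting happens downstream in the subtype-size
criterion. Feature relevance is summarized by normalized Gini importance:
for each feature, the sum over its internal nodes of the node's count
fraction times its impurity decrease, normalized to sum to one.

Hyperparameters (`cv_grid()`: minimum samples per leaf in
{10, 12, 14, 16, 18, 20}, maximum depth in {4, 8, 12, 16, 20}) are selected
by 10-fold cross-validation. Folds partition *unique patients*, never rows,
so oversampling duplicates of one patient cannot straddle a fold boundary.
Whether oversampling happens before or inside cross-validation is not
determined by the study narrative; the default applies it inside each
fold's training portion only (no duplicate leakage into validation folds),
and `oversample_before_cv = TRUE` reproduces the literal
oversample-then-split reading. Neither mode is asserted against any
published accuracy: those numbers depend on access-controlled data. Grid
ties break to the smaller depth, then the larger minimum leaf — the simpler
tree.

Evaluation reports accuracy, precision and recall for the late onset class,
and AUROC obtained by ranking patients by their leaf's class-1 training
fraction with midrank tie handling; a one-class test set reports AUROC as
missing.

## Preprocessing

`assign_onset_labels()` applies the onset definition and reports juvenile
and boundary exclusions separately. `select_features()` makes three passes:
features with more than 15% missing data are dropped; onset-derived
features (onset age, assessment age, disease duration) are blocklisted
because the label is computed from them; and a multicollinearity check
drops, for any pair with |Pearson r| ≥ 0.999 on complete cases (exact
duplicates included), the later column. The correlation cutoff is a
deliberate near-1 value: the check exists to remove linearly dependent
copies (ages recorded at different assessments and the like), not to prune
merely correlated symptoms.

Missing values are imputed with *normative values* — training-split median
for numeric scales (ages, the depression total) and mode for ordinal/binary
items, mode ties breaking to the smallest (most normal) score. Normative
values are fitted on the training split only and applied everywhere, so no
held-out information leaks; a property test permutes held-out values and
asserts the fitted values are unchanged. External validation cohorts are
imputed with their *own* normative values before rule matching, since
nothing in the study design says how missing external values should meet
rule conditions; propagating them would silently fail conjunctions.

The train/test split is a plain seeded random 80–20 split (no
stratification is claimed anywhere), sized `floor(0.8 n)` — 381 patients
give 304 and 77. Class imbalance (late onset outnumbers early onset roughly
2:1) is handled by random oversampling: minority rows are resampled with
replacement to the majority count, keeping original patient ids so that
restricting to unique patients recovers the original table.

## From leaves to subtypes, and the three criteria

`extract_candidate_subtypes()` walks the tree depth-first; along each
root-to-leaf path only the tightest bound per feature is kept (smallest
upper bound, largest lower bound), so `x ≤ 3` followed by `x ≤ 1`
simplifies to `x ≤ 1`. All leaves are extracted: the published candidate
set contains early, late and mixed leaves alike. Members are the unique
training patients routed to the leaf, and the reported class counts and
Gini impurity are computed over unique patients — row counts would let
oversampling duplicates bias the skew (a flag restores the row-count
variant). Categories follow the impurity of the member composition: at most
0.4 means a clear majority and the candidate is *primarily early* or
*primarily late*; above 0.4 it is *mixed*. Names are the category initial
plus an ordinal in left-to-right leaf order; the published numbering origin
is unstated, so leaf order is the package's convention.

The filter applies three criteria in order:

1. **Size.** At least 10 unique training patients.
   `oversampled_min_leaf()` translates this into the row threshold the
   oversampled table implies: with a 197:107 imbalance, 10 unique minority
   patients correspond to 197/107 × 10 = 18.4 rows, so 19 rows.
2. **External matches.** An early (late) candidate must match at least
   `ceiling(5%)` of the validation cohort's early (late) onset patients — 4
   and 17 at external class sizes 68 and 321. Mixed candidates, being
   onset-independent, are matched against the *full* external cohort
   including patients excluded from labeling (threshold 21 at 402).
3. **Precision.** For early/late candidates only, the precision
   (own-class matches over all matches) must strictly exceed the external
   class prior — 68/389 = 0.175 for early, 321/389 = 0.825 for late. The
   alternative reading of precision as own-class matches over the whole
   external cohort contradicts the published precision values, so the
   tabulated arithmetic is authoritative here. Mixed candidates are exempt.

`filter_from_counts()` runs the same criteria from already-tabulated match
counts; replaying the published counts through it reproduces the six
surviving subtypes (E4, L1, L2, L4, M3, M7) and every pass/fail flag.

## Characterization

`summarize_subtype()` reports means and sample (n−1) standard deviations of
assessment and onset age, gender counts, and disease duration as the
difference of the two reported means. `checksheet_ratios()` covers binary
diagnostic check-sheet items: features with 30% or more missing data are
excluded, and the ratio's denominator is the subtype's full patient count
with missing member values counted as non-positive — the published ratios
(e.g. 11/25 = 0.44) are consistent with exactly this convention. A
*distinguishable feature* for a subtype deviates from the overall cohort
mean by more than 0.1; a set-level distinguisher does so for at least half
the subtypes. The "overall" reference is the whole cohort passed in, not
the union of final subtypes.

Agreement with external clusterings uses the unadjusted 1971 Rand index
(fraction of patient pairs placed together in both partitions or apart in
both) — the adjusted variant is a different statistic and is not what the
comparison cites. Cluster labels arrive as two-column files
(`patient_id`, `label`); clusters with fewer than 10 patients are dropped
before comparison, unassigned/noise labels form their own group, and
`cluster_overlap()` lists (subtype, cluster) pairs sharing at least 10
patients. The clustering algorithms themselves are consumed as external
label providers; the analysis scripts use a k-means run as a stand-in
producer of such labels.

## The synthetic cohort generator

The real training and validation cohorts are access-controlled, so
`generate_paired_cohorts()` provides synthetic stand-ins with the
statistical shape the analysis assumes. **No generative model of the real
data exists; every distributional choice below is a stand-in, chosen once
for plausibility, and is labelled as such.**

* **Schema.** 70 ordinal 0–4 items organised like the four MDS-UPDRS parts,
  a 0–15 depression score, binary gender (P(male) = 0.54, near the
  published cohort's 214:183). Baseline ordinal distributions are truncated
  geometric with decay 0.45 — mass concentrated on Normal/Slight, as in
  mildly affected cohorts — which keeps background rule-match rates low.
  The depression score decays at 0.75 (mean about 3).
* **Onset ages.** A 2:1 late:early mix. EOPD ages draw from Normal(42.6,
  10.5) truncated to (21.5, 49.5), LOPD from Normal(58, 10.5) truncated to
  (50.5, 90), both rounded half-up to whole years — the published subtype
  means motivate the centres. Truncation keeps the juvenile and boundary
  exclusion zones empty unless a demographic shift is configured.
* **Assessment age** adds a nonnegative Normal(8, 5) disease-duration
  offset, matching the ~8-year published mean duration.
* **The paired validation cohort** draws from independent substreams and
  adds 5 years to onset (and hence assessment) ages — the published
  validation cohort is about 5 years older. The shift can push early onset
  ages across the 50-year boundary, so the validation cohort has
  proportionally fewer EOPD patients and a few excluded boundary cases,
  as in the real data.
* **Planted subtypes** are ground-truth rules: members are drawn first (by
  prevalence), their onset class from the subtype's skew, and with
  probability `adherence` their condition features are redrawn from the
  baseline truncated to the satisfying range. Default: two subtypes at 10%
  prevalence, skew 0.9/0.1, adherence 0.95. Infeasible conditions (no
  satisfiable category) are rejected by name.
* **Missingness** is injected independently per cell at a per-feature rate
  (default 2%, never on ids or ages; at most 30%).
* **Seeding.** One user seed expands into per-cohort, per-stage substreams,
  so adding a generation stage never perturbs earlier draws and equal
  configs are byte-identical.
* **Not modelled:** longitudinal progression, genetics, and inter-feature
  correlation (the study gives no correlation structure; an explicit
  decision to keep the background independent). Tests passing on this
  generator therefore show the pipeline's mechanics are correct, not that
  real PD cohorts contain recoverable subtypes.

### What the recovery test shows

The parameter-recovery property plants two fully adherent subtypes
(prevalence 0.10, onset skew at the extremes 1.0/0.0) in cohorts of 1500
and asks the full pipeline — generation, preprocessing, oversampling,
fitting, extraction, filtering — to return a surviving rule whose matches
on the training cohort have Jaccard overlap ≥ 0.8 with the ground-truth
member set, for at least one of the two subtypes, in at least 8 of 10
seeds. The planted rules use three conditions each, matching the path depth
of the published subtype rules (3–8 conditions). This matters: with
two-condition rules the background match rate at the baseline distribution
(~0.5%) contaminates the planted leaf, the leaf stays impure, and the
unpruned greedy partitioner carves spurious trailing splits that each shed
~7% of the members. Three-condition conjunctions drop background matches
to ~0.04%, the leaf is essentially pure, and splitting stops on its own —
an instructive illustration of why the method's published rules are
several conditions deep. The recovery run uses a single-cell grid
(depth 8, minimum leaf 10); the end-to-end test exercises the 10-fold grid
search once at a reduced 2×2 grid to keep the default suite fast.

## Numerical and degenerate-input choices

* Split decreases must exceed 1e-12 — every accepted split strictly
  decreases weighted impurity; exact zero-gain splits are refused.
* `stat_mode()` ties break to the smallest value; medians use the standard
  even-count midpoint.
* Half-up rounding for generated ages avoids the round-half-to-even
  artefact at the 50-year class boundary.
* Empty-node impurity, empty training input, one-class oversampling, an
  entirely missing training feature, fewer than two surviving features, and
  more folds than unique patients all raise immediate errors rather than
  propagating damaged state.
* A tree with no splits yields an all-zero importance vector flagged
  `no_splits`; a test set with one class reports AUROC as missing; a
  subtype with no external matches fails the precision criterion with an
  explicit reason.

## Feature harmonization

Rules learned on one cohort's names are evaluated on another's through a
feature map (TSV: `source`, `target`, `kind`, `derivation`). Exact entries
are renames — case-sensitive after whitespace trimming, because clinical
dictionaries use exact codes — and are invertible (`direction =
"reverse"`). Derived entries carry a row-wise arithmetic derivation
evaluated over the columns of the cohort being transformed; they are
one-way (an arithmetic derivation has no defined inverse), missing inputs
propagate to missing outputs, and a derivation referencing an absent column
errors by default (`missing_inputs = "skip"` accommodates maps that bundle
derivations oriented toward the other schema, as the packaged cross-study
map does for the Epworth product). Duplicate sources are rejected by
default; `on_duplicate = "first"` keeps the first occurrence with a
warning — the packaged map lists the Hoehn & Yahr stage under two
validation codes, and which one the original exercise used is not
recorded. Unmapped features are dropped from the harmonized view but kept
in an `auxiliary` attribute.

## Scale of the shipped analyses

The `analysis/` scripts and the end-to-end test run at 1500 patients per
cohort with a reduced 2×2 hyperparameter grid (depth 4/8, minimum leaf
10/20) under 10-fold cross-validation, and the recovery property uses ten
seeded replicates — sizes chosen to keep a full run in the minutes range
on a single core while preserving the study's class-imbalance and
leaf-size regimes. The full published grid is available through
`cv_grid()`'s defaults.

## Known limitations

* The generator's independence assumption means synthetic cohorts are
  easier than real ones: no correlated symptom clusters compete with
  planted rules.
* Published model-performance numbers (validation/test accuracy, AUROC)
  are tied to the restricted data and are deliberately not asserted.
* Greedy unpruned CART fragments weakly separated subgroups; the package
  intentionally implements no pruning, surrogate splits, or multiway
  splits, matching the method it reproduces.
* The Table-style "tree depth" reported for a rule is the raw path length
  before per-feature simplification.
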