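# onsettree

Interpretable Parkinson's disease (PD) subtyping from clinical
rating-scale data, for biostatisticians and clinical-data scientists who
need subtype definitions that can be read, audited and re-applied to a new
cohort.

Cluster-based PD subtyping is sensitive to study design and rarely
validates across cohorts. `onsettree` implements a decision-tree
alternative: a binary CART classifier (Gini criterion) is trained to
separate early onset PD (EOPD: age of onset AO with 21 < AO < 50, label 0)
from late onset PD (LOPD: AO > 50, label 1) using MDS-UPDRS items, the
Geriatric Depression Scale and gender — the onset age itself never enters
the feature set. Each leaf of the fitted tree is a *candidate subtype*: a
conjunction of conditions

```
feature₁ ≤ t₁  AND  feature₂ > t₂  AND … 
```

over ordinal 0–4 severity codes. Candidates are categorized by the Gini
impurity of their member composition (g = 1 − p₀² − p₁² ≤ 0.4 → primarily
early/late; g > 0.4 → mixed) and filtered against an independent
validation cohort by three criteria:

1. **size** — at least 10 unique training patients (oversampling-adjusted:
   a 197:107 class imbalance turns 10 unique minority patients into
   ⌈197/107 × 10⌉ = 19 rows);
2. **external matches** — at least ⌈5%⌉ of the corresponding external
   onset class (mixed candidates match against the full cohort);
3. **precision** — own-class matches / all matches must exceed the
   external class prior (mixed candidates exempt).

Survivors are characterized (demographics, binary check-sheet ratios,
distinguishable features, Rand-index agreement with external
clusterings). Because the original cohorts are access-controlled, the
package ships a synthetic paired-cohort generator with *planted*
rule-defined subtypes, so the whole pipeline is testable against a known
ground truth; see `vignette("onset-tree-methods")` for the model, every
tunable parameter, and the generator's assumptions.

## Worked example

Simulate a paired cohort with two planted three-condition subtypes, run
the full pipeline, and inspect a recovered rule:

```r
library(onsettree)

late_rule <- tibble::tibble(feature = c("updrs3_10", "updrs2_12", "updrs1_11"),
                            op = ">", threshold = 2)
early_rule <- tibble::tibble(feature = c("updrs1_13", "updrs3_17", "updrs2_05"),
                             op = ">", threshold = 2)
cfg <- generator_config(
  n_patients = 1500, seed = 7,
  planted_subtypes = list(
    planted_subtype(late_rule,  prevalence = 0.10, onset_skew = 1.0, adherence = 1.0),
    planted_subtype(early_rule, prevalence = 0.10, onset_skew = 0.0, adherence = 1.0)
  )
)
pair <- generate_paired_cohorts(cfg)

res <- run_subtyping_pipeline(
  pair$training, pair$validation,
  grid = cv_grid(min_samples_leaf = c(10L, 20L), max_depth = c(4L, 8L),
                 k = 10L, seed = 7),
  config = preprocess_config(seed = 7)
)
round(unlist(res$test_metrics), 3)
#>  accuracy precision    recall     auroc 
#>     0.673     0.738     0.783     0.692
subset(res$filter$report, final_pass,
       select = c(name, category, n_unique, c2_matches, c2_threshold, precision))
#> # A tibble: 5 × 6
#>   name  category n_unique c2_matches c2_threshold precision
#> 1 M1    mixed         153        210           75    NA
#> 2 M2    mixed         141        155           75    NA
#> 3 M4    mixed         244        290           75    NA
#> 4 L8    late           88        116           53     0.975
#> 5 E2    early         102         99           22     0.832
```

The test metrics are modest by design: most of the cohort is onset-noise
background, and only the planted fifth is predictable. `L8` is the
recovered late-skewed planted subtype — 88 unique members, pure
composition, surviving every criterion:

```r
res$rules[[which(vapply(res$rules, `[[`, "", "name") == "L8")]]
#> <subtype_rule> L8 (late), 88 unique members, gini 0.000
#>   updrs2_05 <= 2.5
#>   updrs1_11 > 2.5
#>   updrs2_12 > 1.5
#>   updrs3_18 <= 1.5
```

Matching this rule against the full training cohort and comparing with the
planted ground-truth member set gives a Jaccard overlap of 0.72 for this
seed; the dedicated recovery property in the test suite quantifies this
across ten seeds.

## The analysis workflow

`analysis/` holds the staged pipeline, each script a thin driver over the
package that prints what it found and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # paired cohorts + feature map
Rscript analysis/02_harmonize.R          # map validation onto training schema
Rscript analysis/03_preprocess.R         # labels, selection, split, imputation
Rscript analysis/04_fit_tree.R           # CV grid search, final tree, importances
Rscript analysis/05_subtype.R            # rules, three-criteria filter, replay
Rscript analysis/06_characterize.R       # demographics, distinguishers, Rand index
```

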