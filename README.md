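# tnbcsubtyper

Histopathology-based subtype classification of triple-negative breast
cancer (TNBC), for pathologists and translational researchers who need an
mRNA-free surrogate for molecular subtyping, and for methodologists who
want the full evaluation pipeline (threshold derivation, concordance,
survival, enrichment and genomic-alteration statistics) as tested,
reusable code.

## The classification

Two routine slide readings drive the rule:

* **AR Allred score** `A` = proportion score (0–5 points for 0%, ≤1%,
  1–10%, 11–33%, 34–66%, ≥67% AR-positive nuclei) + intensity score (0–3
  for negative/weak/intermediate/strong), so `A ∈ {0,…,8}`;
* **stromal TILs** `T` ∈ [0, 100]%, scored in 10% increments.

```
A ≥ 6             → LAR  (luminal androgen receptor; matches molecular LAR)
A < 6, T ≥ 60     → LP   (lymphocyte-predominant;   matches IM)
A < 6, 20 ≤ T <60 → LI   (lymphocyte-intermediate;  matches BL1)
A < 6, T < 20     → LD   (lymphocyte-depleted;      matches M)
```

The cut-offs 6 / 20 / 60 are re-derivable from labeled data with the
in-house CART trainer (`cart_fit()`, greedy Gini partitioning, max depth 5,
complexity 0.0001) under a smallest-right-side-value threshold-reporting
convention (`report_thresholds()`). The package also provides:

* `normalize_expression()` / `call_molecular_subtype()` — centroid-
  correlation molecular calls with the p ≥ 0.05 unclassified (UNC) rule;
* `crosstab()`, `overall_accuracy()` (Wilson CI), `cohen_kappa()`,
  `per_class_metrics()` — concordance against molecular truth;
* `km_curve()`, `logrank_test()`, `cox_fit()` (Efron ties, LP reference) —
  survival by subtype;
* `signature_scores()` (ssGSEA-style or mean-z), `group_anova_fdr()`,
  `posthoc_pairwise_t()`, `alteration_tests()` (Fisher + BH),
  `hrd_compare()` (Kruskal–Wallis + rank-sum post hoc);
* `build_table1_fixture()` and `generate_cohort()` /
  `generate_expression()` / `generate_alterations()` — a deterministic
  reconstruction of the published 317-case cross-tabulation and synthetic
  cohorts calibrated to it;
* `run_all()` and a CLI (`inst/cli/tnbcsubtyper.R`) — the end-to-end
  pipeline with a checksummed manifest.

## Worked example

```r
library(tnbcsubtyper)

cls <- classify_table(build_table1_fixture())   # 317 reconstructed cases
ct  <- crosstab(cls$classified, cls$molecular_truth)
column_percentages(ct)["LAR", "LAR"]            # 47.9 — printed Table value
acc <- overall_accuracy(ct)
sprintf("accuracy %.3f (95%% CI %.3f-%.3f), kappa %.3f",
        acc$accuracy, acc$lower, acc$upper, cohen_kappa(ct))
#> "accuracy 0.606 (95% CI 0.545-0.665), kappa 0.469"
per_class_metrics(ct)
#>   subtype precision recall    f1 balanced_accuracy
#> 1     LAR     0.586  0.756 0.660             0.819
#> 2      LP     0.667  0.613 0.639             0.756
#> 3      LI     0.523  0.371 0.434             0.629
#> 4      LD     0.622  0.700 0.659             0.749
```

Accuracy/kappa exclude the 68 UNC-truth cases (which cannot match any
classified label); the LI group scores lowest on every per-class metric,
the behavior this classification is known for. On a synthetic cohort the
survival machinery recovers the configured subtype effects:

```r
cohort <- classify_table(generate_cohort(cohort_config(400, seed = 1)))
sv <- survival_by_subtype(cohort, "rfs")
sv$logrank
#> chisq 37.56, df 3, p 3.5e-08
as.data.frame(sv$cox)       # hazard ratios vs the LP reference group
#>         term   hr lower upper        p
#> 1 subtypeLAR 1.93  1.19  3.15 8.19e-03
#> 2  subtypeLI 1.78  1.09  2.91 2.03e-02
#> 3  subtypeLD 3.47  2.25  5.34 1.78e-08
```

The LD-vs-LP estimate (3.47, CI 2.25–5.34) brackets the generator's
configured true relapse-free-survival hazard ratio of 3.68.

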