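# sepsipanel

Multi-biomarker panel selection and severity scoring for pediatric sepsis.

Severe sepsis in critically ill children is hard to classify from any single
biomarker. This package implements a complete, testable methodology for
building multi-biomarker severity classifiers on longitudinal pediatric
intensive-care cohorts — for biostatisticians reproducing or auditing the
approach, and for methodologists stress-testing it on synthetic data:

* **Exhaustive canonical-correlation panel search.** For every panel size
  *k*, the biomarker subset maximizing the canonical correlation with the
  binary severity label, found by enumerating all subsets (all 2¹⁹ − 1 of
  them for the 19-variable panel). With a one-dimensional label this is the
  multiple correlation √R². Greedy forward selection is included for
  comparison, and stepwise traces report what enters and leaves at each *k*.
* **Sparse linear SVM.** A class-weighted 1-norm soft-margin SVM
  (min ‖w‖₁ + C₊Σξᵢ + C₋Σξᵢ s.t. yᵢ(w·xᵢ + b) ≥ 1 − ξᵢ), solved exactly as a
  linear program; the L1 penalty zeroes irrelevant weights. `l1svm()` is the
  central fitting function, with `predict`, `coef`, `print`, and `summary`
  methods.
* **Bagged evaluation.** Ensembles of bootstrap-refitted SVMs (mean decision
  function), scored by sensitivity, specificity, PPV, and NPV over repeated
  random one-third test splits (`l1svm_bag()`, `repeated_evaluation()`,
  `subset_size_curve()`).
* **Random-forest importance.** Out-of-bag permutation importance (mean
  decrease in accuracy) computed by direct tree traversal over a 1000-tree
  forest (`panel_forest()`, `mda_importance()`).
* **The published three-marker severity score.** Angiopoietin-2,
  angiopoietin-1 and bicarbonate with standardized weights
  (+1.994, −1.396, −1.340), shipped as an immutable model
  (`published_severity_model()`), plus longitudinal score trajectories
  (`score_cohort()`).
* **A seeded synthetic cohort generator** (`sample_cohort()`) emulating the
  study's structure: 45 patients in two severity groups, group-specific
  correlation blocks, planted Ang-2↑ / Ang-1↓ / HCO3↓ severe-group effects
  that decay after day 2, a twice-daily-then-daily sampling schedule capped
  at 10 draws, and two pure-noise control columns.

## Worked example

```r
library(sepsipanel)

cfg    <- cohort_config(dropout_prob = 0, seed = 7)  # 45 patients x 10 draws
cohort <- sample_cohort(cfg)
feats  <- cohort_features(cohort)
xn     <- normalize_features(feats$x)$x

stepwise_trace(xn, feats$y, k_max = 5)
#> Stepwise best-subset selection (canonical correlation with outcome)
#>  dim      corr entering leaving
#>    1 0.4883993    Ang-2
#>    2 0.5322401     HCO3
#>    3 0.5574321    PIM-2
#>    4 0.5765371    Ang-1
#>    5 0.5900524      Wgt
```

The planted Ang-2 marker leads the search (correlation 0.49 alone), and each
additional biomarker raises the panel's canonical correlation — the `corr`
column is non-decreasing by construction. Fitting the sparse SVM on the
three-marker panel:

```r
l1svm(feats$x[, c("Ang-2", "Ang-1", "HCO3")], feats$y)
#> Sparse (1-norm) linear SVM severity model
#>   3 features, 3 nonzero weights, bias -0.1556
#>     Ang-2          +1.2584
#>     Ang-1          -0.4440
#>     HCO3           -0.3544
#>   penalties: C_pos = 1.5, C_neg = 1 (pos = N_neg/N_pos, neg = 1)
```

The weight signs carry the clinical direction — high Ang-2 with low Ang-1
and low bicarbonate drives the severity score positive. Evaluating that
panel over repeated random splits:

```r
repeated_evaluation(feats$x, feats$y, subset = c("Ang-2", "Ang-1", "HCO3"),
                    B = 20, R = 25, seed = 7)
#> Repeated-split evaluation (R = 25, B = 20) of {Ang-2, Ang-1, HCO3}
#>  measure  mean     se
#>      TPR 0.578 0.0124
#>      TNR 0.857 0.0066
#>      PPV 0.722 0.0121
#>      NPV 0.759 0.0082
```

So on this synthetic cohort the three-marker panel detects 58 % of severe
draws while keeping specificity at 86 %, and roughly three of four
positive/negative calls are correct. The published decision function scores
raw biomarker values directly; a one-SD angiopoietin-2 excursion above the
published mean isolates its weight:

```r
pub <- published_severity_model()
predict(pub, c("Ang-2" = 8518.1 + 13264, "Ang-1" = 2649.2, "HCO3" = 27.270))
#> [1] 1.994
```

`run_pipeline(pipeline_config(...))` executes every stage end-to-end and
writes a seeded, provenance-stamped report bundle (cohort, correlation
heatmap tables, selection traces, measure-vs-panel-size curves, fitted model
JSON, importance ranking, trajectories).

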