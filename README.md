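# predvote

Consensus voting and benchmarking of in silico missense-variant
pathogenicity predictors.

## The problem

Clinical genetics laboratories routinely run several missense prediction
tools — SIFT, PolyPhen-2, PROVEAN, SNPs&GO, SNAP — or metaservers
(Meta-SNP, PredictSNP) on variants of uncertain significance, then combine
the verdicts informally. For genes such as the long QT syndrome trio
*KCNQ1*, *KCNH2* and *SCN5A*, which combination of tools actually
classifies best is an empirical question, and the answer turns out to be
gene-dependent. `predvote` implements the full evaluation pipeline for
answering it on any panel of variants with trusted truth labels:

1. **Harmonization** — each tool's native vocabulary ("Probably/Possibly
   damaging", "Deleterious", "Non-neutral", "Disease", …) is collapsed
   onto binary `damaging`/`tolerated` calls; unknown labels are errors,
   never silent coercions. Truth labels are screened by an evidence filter
   (pathogenic: in vitro functional characterisation or family
   co-segregation; benign: functional characterisation or allele frequency
   strictly above 1%).
2. **Consensus voting** — for every committee of tools, the consensus is
   `damaging` when at least half the committee votes damaging
   (2·n_damaging ≥ n_tools). Ties are deliberately called damaging, so a
   split committee escalates rather than dismisses a possibly pathogenic
   variant. Metaservers are scored as single columns, never mixed into
   committees.
3. **Metric battery** — per committee and per stratum (gene, pooled,
   protein region): accuracy, sensitivity TP/(TP+FN)×100, specificity
   TN/(TN+FP)×100, and the Matthews correlation coefficient

   MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

   the balanced statistic used to rank combinations, since raw accuracy is
   inflated by the strong pathogenic/benign imbalance of clinical panels.
4. **ROC analysis** — per-tool ROC curves from the continuous scores
   (with each tool's polarity: a low SIFT score is damaging, a high
   PolyPhen-2 probability is damaging), tie-corrected Mann–Whitney AUC,
   and DeLong placement-value 95% confidence intervals.
5. **Comparative statistics** — pairwise phi association between tool
   calls (are committees redundant?) and Kruskal–Wallis comparison of
   per-combination accuracies.
6. **Synthetic panels** — a seeded Gaussian-copula generator produces
   correlated predictor panels with exact marginal sensitivity/specificity
   control, so every stage is testable without querying any web service.

## Worked example

```r
library(predvote)

panel <- generate_panel(lqts_replica_config(seed = 101))
panel
#> prediction_panel: 312 variants (282 pathogenic / 30 benign), 7 tools
#>   genes: KCNH2 (90), KCNQ1 (109), SCN5A (113)
#>   tools: PolyPhen-2, SIFT, PROVEAN, SNPs&GO, SNAP
#>   metaservers: Meta-SNP, PredictSNP
#>   missing calls: 41 / 2184 cells

ev <- evaluate_all(panel)                       # 132 (combination, stratum) rows
head(rank_by_mcc(ev, "KCNQ1")[, c("combination", "accuracy",
                                  "sensitivity", "specificity", "mcc")], 3)
#>                 combination accuracy sensitivity specificity   mcc
#> 1 PROVEAN+SIFT+SNAP+SNPs&GO     96.0        98.9        57.1 0.656
#> 2   PolyPhen-2+SIFT+SNPs&GO     91.3        91.6        87.5 0.600
#> 3              SIFT+SNPs&GO     94.3        96.9        62.5 0.594
```

The ranking is by MCC: the top committee is the one that classifies *both*
pathogenic and benign KCNQ1 variants well on this simulated panel, even
though other committees reach higher raw accuracy.

Metrics can also be evaluated directly on counts. The best published
KCNQ1 committee (PROVEAN+SNPs&GO+SIFT on 101 pathogenic / 8 benign
variants) corresponds to the confusion matrix TP=94, FP=0, TN=8, FN=7:

```r
metric_set(confusion_matrix(tp = 94, fp = 0, tn = 8, fn = 7))
#> accuracy 93.6%, sensitivity 93.1%, specificity 100.0%, MCC 0.70
```

Per-tool ROC with DeLong intervals, pooled across genes:

```r
roc_summary(panel, strata = "pooled")[, c("tool", "auc", "ci_low", "ci_high")]
#>         tool   auc ci_low ci_high
#> 1 PolyPhen-2 0.698  0.578   0.818
#> 2       SIFT 0.765  0.668   0.863
#> 3    PROVEAN 0.794  0.702   0.886
#> ...
```

A full run (`run_report()`) writes `combo_evaluations.tsv`,
`roc_summary.tsv`, `association_matrix.tsv` and a JSON manifest; the thin
CLI in `exec/predvote` exposes the same as `simulate` / `evaluate` /
`roc` / `report` subcommands.

## Vignette

`vignettes/benchmarking-consensus-predictors.Rmd` documents the model and
its assumptions, the voting rule and tie policy, the zero-denominator and
missing-call conventions, the synthetic-panel generator and what it does
and does not emulate, and known limitations.
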