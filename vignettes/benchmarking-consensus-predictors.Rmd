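---
title: "Benchmarking consensus committees of missense pathogenicity predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking consensus committees of missense pathogenicity predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predvote)
```

## The evaluation problem

A diagnostic laboratory confronted with a missense variant of uncertain
significance in a long QT syndrome gene (*KCNQ1*, *KCNH2*, *SCN5A*) will
typically consult several in silico predictors. Each tool answers in its
own vocabulary and with its own error profile, and the tools are
positively correlated — they tend to fail on the same hard variants.
`predvote` treats the practice itself as the object of study: given a
panel of variants whose pathogenicity is independently established, which
single tool, committee of tools, or metaserver classifies best, per gene
and pooled?

The pipeline has five stages: vocabulary harmonization, evidence-based
inclusion filtering, committee voting, a confusion-matrix metric battery,
and score-based ROC analysis, with phi association and Kruskal–Wallis
comparison as supporting statistics.

## Truth labels and the inclusion filter

A variant's truth label is only as good as its evidence. The filter keeps
a pathogenic variant when it is functionally characterised in vitro or
supported by family co-segregation, and a benign variant when it is
functionally characterised or common in the population. The
allele-frequency cut is *strictly* greater than 0.01 — "greater than 1%"
is read literally, so a variant at exactly 1% is rejected. Filtering
partitions its input: every record is kept or rejected with a
machine-readable reason, and nothing is silently dropped.

## Harmonization

Tool vocabularies are declared per tool as label maps
(`default_vocabularies()` ships maps for PolyPhen-2, SIFT, PROVEAN,
SNPs&GO, SNAP, Meta-SNP and PredictSNP). Matching is case- and
whitespace-insensitive; both PolyPhen-2 damaging grades ("Probably
damaging", "Possibly damaging") collapse to `damaging`. Everything
outside a tool's declared vocabulary raises an error naming the tool and
the label, because an out-of-vocabulary label almost always means
mislabelled columns, not a new category.

## The voting rule and the tie policy

For a committee of $k$ tools with $d$ damaging votes the consensus is

$$\text{damaging} \iff 2d \ge k.$$

For odd $k$ this is a strict majority; for even $k$ it is a majority with
ties called damaging. The closed form was chosen because it reproduces
every row of the enumerated per-size rule table (sizes 2–5) that defines
the procedure, including the five-tool "three tolerated → tolerated" row,
and it extends the table coherently to committees of any size, so single
tools and metaservers flow through the identical code path. The tie
policy is a clinical stance, not a numerical accident: in a cascade
screening context the cost of dismissing a truly pathogenic variant
exceeds the cost of over-calling, so a split committee escalates.
Over-calling on even committees is the predictable price; the test suite
checks the rule exhaustively against a literal transcription of the rule
table.

## Missing predictions

Tools occasionally return nothing for a variant. Missing calls are
retained as `NA` through parsing and simulation; the policy is decided at
evaluation time:

* `exclude` (default) — a variant missing any committee member's call is
  dropped from that committee's confusion matrix. Metrics stay
  well-defined and comparable, at the cost of slightly different
  denominators per committee.
* `reduce` — the vote runs on the non-missing subset under the same tie
  rule.

The default is `exclude` because it keeps each committee's evaluation a
pure function of complete data. Note that per-committee denominators then
vary, which is also the most plausible explanation for small
inconsistencies one finds in published benchmark tables between printed
accuracies and the accuracy implied by the printed sensitivity,
specificity and class sizes (see *Reconstructed matrices* below).

## The metric battery

All metrics derive from TP/FP/TN/FN counts. Sensitivity
$[TP/(TP+FN)]\times 100$ and specificity $[TN/(TN+FP)]\times 100$ are
reported as percentages; accuracy is $(TP+TN)/n \times 100$; and

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} \in [-1, 1].$$

Committees are ranked by MCC, which equals the Pearson correlation of the
binary prediction and truth vectors and is therefore robust to the severe
class imbalance of clinical panels (benign variants are scarce). An MCC
above 0.5 is a reasonable bar for an acceptable committee. Ties in the
ranking break toward fewer tools (cheaper, and less prone to tie-driven
over-calling), then higher specificity (the clinically safer error
profile), then name.

Numerical conventions, chosen so rankings are total and degenerate strata
are survivable:

* zero-denominator sensitivity/specificity/accuracy → `NA`
  (undefined-sentinel, printed as "NA" in reports), never an exception;
* MCC with any zero marginal sum → 0 with a `degenerate` attribute (the
  common convention for constant predictions);
* full double precision is kept internally and in machine-readable
  output; the one-decimal-percent / two-decimal-MCC / three-decimal-AUC
  precision appears only at presentation time. (The occasionally seen
  typeset form "(TP×TN) − (FP×FN)/√(...)" of the MCC is read as the
  standard formula above; the code comments say so.)

## ROC curves and DeLong intervals

Continuous scores are oriented so higher means more damaging
(`low_is_damaging` tools such as SIFT and PROVEAN are negated).
Thresholds are placed at every distinct oriented score plus ±∞, with "≥
threshold is damaging", so curves are bit-reproducible. The trapezoidal
area equals the tie-corrected Mann–Whitney statistic
$U/(n_{pos}n_{neg})$ with ties scoring ½ — an identity the tests verify
on a thousand random instances at $10^{-12}$.

The AUC variance uses DeLong's placement-value estimator in its fast
midrank form: each pathogenic score's placement is the fraction of benign
scores it outranks and vice versa, and
$\widehat{var} = S_{10}/n_{pos} + S_{01}/n_{neg}$. The 95% (configurable)
interval is the normal approximation clipped to $[0,1]$; perfect
separation collapses the variance and returns a flagged zero-width
interval. Monte-Carlo coverage of the interval is tested at a true
binormal AUC of 0.8 with 200 variants per class over 2,000 replicates and
must land in $[0.93, 0.97]$.

Polarity is a declared per-tool constant by default. An `auto` mode
(choose the orientation with AUC ≥ 0.5, record the choice) exists, but
fixed polarity is the replication default: auto-orientation can never
report an AUC below 0.5, and genuinely anti-predictive tools on hard
genes do occur and should be visible as such.

## Supporting statistics

Inter-tool association is the phi coefficient of the harmonized binary
calls, from the closed 2×2 form — the question being answered is whether
the *calls* entering a committee are redundant, not whether raw scores
co-vary (a Spearman mode on scores is available). Constant vectors yield
`NA`.

The Kruskal–Wallis comparison of combination accuracies delegates the
rank test (mid-rank tie correction, chi-squared approximation) to
`stats::kruskal.test`. The sampling unit is a design choice the source
procedure leaves open: the default feeds per-variant 0/1 correctness
indicators grouped by combination, the only reading that gives the test
non-trivial group sizes; a per-gene-accuracy mode is provided as the
conservative alternative. All-identical observations return $H = 0$,
$p = 1$ rather than an error.

## The synthetic panel generator

`generate_panel()` draws panels from a Gaussian-copula latent-difficulty
model. Each variant has a shared difficulty $z \sim N(0,1)$; tool $t$
errs iff

$$\sqrt{\rho}\, z + \sqrt{1-\rho}\, \epsilon_t > \Phi^{-1}(p_t),$$

with $p_t$ the tool's sensitivity (pathogenic variants) or specificity
(benign), and $\epsilon_t \sim N(0,1)$ tool-specific. The left side is
standard normal for every $\rho$, so marginal correctness rates equal the
configured $p_t$ exactly — the generator is analytically testable at
$\rho = 0$ and parameter recovery is verified at $n = 2{,}000$ per class
within 3σ binomial bounds — while $\rho > 0$ makes tools err together,
producing the positive pairwise phi observed between real predictors
(monotonicity in $\rho$ is tested over 50 replicate panels).

Scores are drawn conditional on the emitted call — damaging calls from
Beta(2 + s, 2), tolerated from Beta(2, 2 + s) on the damagingness scale,
with per-tool separation $s \ge 0$ — then flipped to $1 - \text{score}$
for `low_is_damaging` tools. Conditioning on the call guarantees
call/score consistency (a tool never says "tolerated" while scoring the
variant as confidently damaging) and makes the score AUC strictly
increasing in $s$. Evidence annotations are generated consistent with the
inclusion filter (pathogenic: 70% functional / 30% co-segregation;
benign: 50% functional / 50% allele-frequency with AF drawn uniformly on
(0.011, 0.20)), and regions with proportions 0.15 / 0.35 / 0.15 / 0.35
over N-terminus / transmembrane / C-terminus / loop — round figures for a
multi-pass membrane protein. Missing cells are masked uniformly at
random. All randomness flows from the mandatory config seed and the
caller's RNG state is restored afterwards.

### The shipped benchmark configuration

`lqts_replica_config()` fixes the panel structure to the canonical LQTS
benchmark: KCNQ1 101 pathogenic / 8 benign, KCNH2 82/8, SCN5A 99/14 —
312 variants. (Published summaries of this benchmark disagree internally
about the pooled split — an abstract says 283/29 where the per-gene table
sums to 282/30; the table is followed here, and the matrices below use
282/30.) The per-tool operating characteristics are free parameters of
the emulation, chosen once as field-plausible: sensitivities 0.85–0.92
(missense predictors are tuned sensitive), specificities 0.45–0.78 with
SNAP weakest and metaservers best-calibrated, $\rho = 0.3$ (moderate
shared difficulty, below the "strongly correlated" regime that would make
committees pointless), separations 1.5–3.5 echoing the same ordering, and
a 2% missing rate. These values shape simulated metric levels but none of
the pipeline's correctness properties depend on them.

### What the generator does not emulate

Real predictor scores are not Beta-distributed, real inter-tool
dependence is not exchangeable single-$\rho$, real missingness is not
uniform (web services fail systematically on specific isoforms), and real
per-gene difficulty differences (SCN5A being notoriously harder than the
potassium-channel genes) are not built in unless configured per gene.
Passing tests therefore certify the pipeline's arithmetic and invariants,
not any claim about how real tools perform on real genes.

## Reconstructed confusion matrices

Desk-scale verification uses the integer confusion matrices implied by
the published class sizes and one-decimal rates for each best committee:
KCNQ1 (94, 0, 8, 7), KCNH2 (75, 1, 7, 7), SCN5A (86, 7, 7, 13), pooled
(234, 6, 24, 48), each the unique integer solution on its class split.
The internally consistent published values (KCNQ1 MCC 0.70; KCNH2
accuracy 91.1% and MCC 0.62; SCN5A MCC 0.32; pooled accuracy 82.7% and
MCC 0.44) are reproduced exactly. Two published accuracies (KCNQ1 92.7%,
SCN5A 81.4%) conflict with their own printed sensitivity/specificity and
class sizes, which imply 93.6% and 82.3%; shrunken denominators from
variants with missing predictions are the likely cause. These are
documented, not targeted.

```{r matrices}
metric_set(confusion_matrix(tp = 94, fp = 0, tn = 8, fn = 7))
metric_set(confusion_matrix(tp = 234, fp = 6, tn = 24, fn = 48))
```

## Problem sizes used by the test suite

The suite runs desk-scale checks instantly and keeps the stochastic
checks at sizes where the distributional guarantees are sharp but cheap:
exhaustive vote enumeration to committee size 5; 1,000 random ROC
instances of ≤ 30 points; 2,000 DeLong coverage replicates at 200 + 200;
10,000 random confusion matrices for the MCC–Pearson identity; 1,000
null Kruskal–Wallis simulations (3 × 10); parameter recovery at 2,000 per
class and dependence monotonicity over 50 replicate 300-variant panels.
These sizes are the package's own choices for tight Monte-Carlo bounds at
interactive run times.

## Known limitations

* Committees are unweighted votes; no score averaging, stacking or
  retraining of metaservers is attempted, by design.
* The benign strata of realistic panels are tiny (8–14 variants), so
  specificity and the benign side of MCC carry wide sampling error —
  rankings on such strata are indicative, not definitive.
* The DeLong interval is a normal approximation; with a handful of
  variants per class, or AUC at the boundary, it degrades (flagged where
  detectable).
* Protein-region stratification is a label collapse supplied with the
  panel; no structural annotation is computed.
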