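---
title: "Relative simplicity: scoring, ranking and direct classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative simplicity: scoring, ranking and direct classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsdc)
```

## The model

Every quantity in this package is a function of a 2 × r contingency table
crossing the class of each sample (+ or −, after one-vs-rest
binarization) with a discretized view of expression. Three views are used:

* **vertical individual** (2 × 2): gene j above/below its *endpoint*
  `EP_j = (mean over negatives + mean over positives) / 2`, the midpoint
  of the two class means;
* **horizontal pair** (2 × 2): the within-sample order `X_ij > X_iq`
  versus `X_ij < X_iq` for a gene pair — because both values come from the
  same sample, any per-sample background shift cancels;
* **vertical pair** (2 × 4): the joint endpoint split of the two genes,
  columns (>,>), (>,<), (<,>), (<,<).

A value exactly on a threshold (or a within-sample tie) splits the
sample's unit mass 0.5/0.5 across the two consistent columns, so counts
may be half-integers and every table's grand total equals the number of
samples.

The score of a table is its **relative simplicity**. With complexity
`C = C_row + C_column`, where each row and each column contributes
`−Σ nᵢ log₂(nᵢ/N)` with its own total as N, and `C_max` the complexity of
the table with identical class margins but the counts of each class spread
evenly over the r columns (`C_row_max = n log₂ r`,
`C_column_max = −f₊ log₂(f₊/n) − f₋ log₂(f₋/n)`):

$$RS = \frac{C_{\max} - C}{C_{\max}} \in [0, 1].$$

Dividing by `C_max` makes 2 × 2 and 2 × 4 tables comparable. Complexity is
the frequency-weighted relative of Shannon entropy: it sees not only the
proportions but the absolute counts, so evidence from 40 samples counts
for more than the same proportions in 8. This is the stated reason for
preferring it (and the chi-square, which shares the property) over plain
entropy as a selection score.

A gene pair's score pools the horizontal and vertical views before
normalizing:

$$RS_{jq} = \frac{(C^{hor}_{\max} + C^{ver}_{\max}) - (C^{hor} + C^{ver})}
                 {C^{hor}_{\max} + C^{ver}_{\max}},$$

and a gene's **integrated score** adds its weighted share of every pair:

$$IRS_j = RS_j + \sum_{q \ne j} \frac{RS_j}{RS_j + RS_q}\, RS_{jq}.$$

The sum runs over all p − 1 partners, exactly as defined — ranking is
O(p²) pair evaluations, computed by vectorized kernels
(`integrated_rank()` is verified bit-for-bit against a literal double loop
in the test suite).

Selection and classification are *transductive*: to classify a sample,
assign it each candidate label in turn, merge it into the training data,
recompute endpoints and all tables on the merged data, and keep the label
with the higher score — the individual RS for a single gene, otherwise the
network score `RS\text{-}net = Σ_{j≠q} RS_{jq}` over the gene subset.
`forward_select()` introduces genes in rank order and keeps a candidate
only if it strictly improves the leave-one-out MCC of this classifier
(the first gene is always kept and sets the benchmark). Multi-class
prediction fits one subset per class one-vs-rest and then runs a
paired-votes tournament: class 1 meets class 2 on the union of their
subsets and only their own training samples; the winner meets class 3,
and so on — m − 1 contests, balanced two-class comparisons throughout.

### Assumptions

* Expression is continuous with no missing values; classes are known and
  each has at least two training samples.
* The endpoint split assumes the two class means are a meaningful
  per-gene threshold (a Fisher-discriminant-style midpoint); heavily
  multimodal within-class expression weakens the vertical views (that is
  exactly the situation the horizontal view is designed to survive).
* Outliers are assumed rare and roughly Gaussian-correctable: values
  outside `mean ± u_α · sd` of their gene are pulled to the corresponding
  leave-one-out band edge before any scoring. Adjustment is applied once
  to the training set only — never to test samples, and never re-run on
  transductively merged data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` / `u_alpha` | 0.05 / 1.96 | outlier band half-width in gene sd units. 1.96 is the conventional two-sided 5% normal quantile; other `alpha` values use `qnorm(1 − α/2)`. |
| `sd_estimator` | `"sample"` | sd used by the outlier band. The n−1 estimator is the statistical default for estimated dispersion; the population variant is exposed because the definition does not specify one. |
| `B` | 100 | forward-selection scan bound (number of top-ranked genes examined). |
| `backend` | `"rs"` | scoring backend: `rs`, `entropy`, `chi2`. |
| `chi2_correction` | `"yates_nofloor"` | 2 × 2 continuity-correction variant (see below). |
| `class_order` | first appearance | one-vs-rest order and tournament sequence. |

## Score backends

`entropy` and `chi2` are drop-in comparators sharing the whole pipeline.

* The **chi-square backend** scores 2 × 2 tables with
  `χ² = n(|ad − bc| − n/2)² / (f₊ f₋ f₁ f₂)` and 2 × 4 tables with the
  plain Pearson statistic. The 2 × 2 correction term is *not* floored at
  zero before squaring: this single convention reproduces simultaneously
  the fixture values 4.5 (pure table) and 0.5 (balanced all-tie table) and
  both published 2 × 2 worked examples (p = 0.0027 and p = 0.7806 — the
  latter has `|ad − bc| − n/2 = −16`, so a floored Yates statistic would
  be 0). The floored and uncorrected variants remain available via
  `chi2_correction`. Any zero margin gives χ² = 0. One observation worth
  recording: the fixture's printed chi-squares for vertical *pair* tables
  whose patterns occupy only two of the four columns correspond to
  dropping the zero-total columns and applying the corrected 2 × 2
  formula to what remains (4.5 rather than Pearson's 8); the package keeps
  the plain 2 × r Pearson statistic as the module contract and the test
  suite applies the collapse explicitly where it checks those printed
  values.
* The **entropy backend** is the same `(max − observed)/max` construction
  with each row's and column's Shannon entropy in place of its complexity
  — i.e. RS with the frequency weighting dropped. The reference
  description never prints this formula; this analog was chosen so that
  the two backends differ in exactly one property (count sensitivity),
  which is the property under study.

## The synthetic generator

`generate_dataset()` plants gene *pairs* following six joint-effect
templates: consistent reversal of expression (I) or of relative expression
(II), consistent expression (III) or relative expression (IV),
heterogeneous per-sample background (V: the class signal lives entirely in
the within-sample order; both genes look balanced to any per-gene
threshold), and interaction (VI: only the joint endpoint split is
informative). Samples of the target class receive the pattern's positive
template (alternating between its two row variants for V and VI), all
others the negative template. Choices made once:

* **jitter**: additive Gaussian, default sd = 5% of the pattern's own
  template value range — large enough that detection is a statistical
  question, small enough that high-contrast genes stay separable;
* **noise genes**: i.i.d. uniform on [5, 110], spanning the template
  values, so noise and signal live on the same scale;
* determinism: the spec's seed fully determines the output and the
  caller's RNG state is restored afterwards.

What the generator does *not* emulate: probe saturation, batch effects,
correlated noise between genes, heavy-tailed platform noise. Passing the
recovery tests therefore demonstrates the scores' behavior under clean
planted signal, not performance on any real platform.

`pattern_fixture()` returns the exact noise-free 8 × 12 reference dataset
(one pair per pattern) used throughout the tests; every printed
contingency table and chi-square value for it is asserted in the suite.

## Numerical conventions

* Base-2 logarithms everywhere; every `0 · log(0/x)` term is 0.
* `RS := 0` when `C_max = 0` (degenerate tables); a pair weight `0/0`
  (both genes individually uninformative) contributes nothing to either
  partner.
* Prediction ties (`score(+) = score(−)`) go to the negative class — the
  pseudo-decision's else-branch; in a tournament contest, to the later
  class of the pair.
* MCC with a zero marginal factor is 0.
* Ranking ties keep the original gene order (stable sort).
* Scalar and vectorized scoring paths accumulate complexity terms in the
  same left-to-right double-precision order, so they agree bit-for-bit;
  mathematical invariances that reorder additions (e.g. column
  permutation) hold to ~1 ulp and are tested at tolerance 1e-12.
* Written datasets print each value with the fewest significant digits
  (15–17) that re-read to the identical double.

## Open design points, resolved

* The outlier rule's prose condition for the upper branch contains an
  obvious sign typo; the displayed two-branch form (below lower bound /
  above upper bound) is implemented.
* Whether the outlier sd is the sample or population estimator is not
  specified; sample sd is the default and both are exposed.
* The forward-selection pseudo-code would, read literally, delete the
  first gene immediately after setting the benchmark to its own MCC; the
  accompanying step-wise description (introduce gene 1, set the benchmark,
  keep it) is followed instead.
* The leave-one-out scheme scores the *relabeled* left-out sample merged
  back into the data — intentionally different from conventional LOOCV,
  where the sample would be excluded from the training statistics. This
  is implemented as described; `dc_predict_binary()` on the sample with
  its row removed from the task reproduces the internal decision exactly
  (asserted in the suite).
* Whether the paired-votes result depends on the tournament order is not
  addressed by the method's description; the order is fixed (first
  appearance, configurable) and exposed rather than silently permuted.

## Problem sizes used by the test suite

Bulk score properties run on 10,000 random tables; ranking/oracle
equivalence on p ≤ 30 datasets; pattern recovery on 20 replicates of
n = 40, p = 512 (12 planted genes + 500 noise); the end-to-end classifier
on 3-class datasets of 8 samples per class, 20 genes, with 20
label-permuted replicates for the chance-level control. These sizes were
chosen to exercise every code path at meaningful statistical power while
keeping the default suite fast.

## Known limitations

* **Zero individual score suppresses pair credit.** The integrated score
  weights each pair term by `RS_j / (RS_j + RS_q)`. If a gene's individual
  vertical RS is *exactly* zero — which is the defining situation of
  patterns V and VI, whose individual tables are perfectly balanced — the
  weight is zero against every informative partner and the gene's IRS
  collapses to (near) zero regardless of how strong its pair signal is.
  On the noise-free fixture the pattern V/VI genes therefore rank *below*
  random noise genes, and in the planted-recovery experiment they sit far
  outside the top 5% in every replicate, even though their pair scores
  alone (horizontal for V, vertical 2 × 4 for VI) identify them reliably.
  The corresponding recovery assertion in the acceptance tests documents
  this honestly as a failing expectation rather than altering the formula.
  In real data individual RS is rarely exactly zero, which softens but
  does not remove the effect: the weight remains proportional to a small
  individual score. A practitioner who cares about purely interaction- or
  background-driven pairs should inspect `rs_pair()` scores (or the
  pair-score matrix) directly rather than relying on the integrated
  ranking alone.
* Forward selection is greedy with no backward elimination; the first
  ranked gene is always kept.
* Transductive prediction is O(n · |genes|²) per sample and label — cheap
  for the intended n of tens to low hundreds, not designed for thousands
  of samples.
* The 2 × r chi-square p-values use the asymptotic distribution; at the
  small counts typical here they are reference values, not calibrated
  test levels.
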