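---
title: "Methods: n-gram encoding, separation-statistic feature selection, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: n-gram encoding, separation-statistic feature selection, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerselect)
```

## The model

`kmerselect` classifies protein sequences into superfamilies without
alignment. Each sequence over the 20-letter amino-acid alphabet is
represented by the frequencies of its n-grams (contiguous substrings) of
lengths 1, 2 and 3. The descriptor universe is fixed and ordered — all
20 single residues, the 400 2-mers and the 8000 3-mers, giving
N_total = 8420 coordinates — so feature indices are stable across
datasets, runs and machines (length-ascending, then lexicographic).

For descriptor length k the frequency of k-mer g in a sequence of
length L is count(g) / (L − k + 1), counting every overlapping window
(stride 1). The denominator is per-block, not global: each k-block of a
clean sequence sums to exactly 1, so a sequence is three stacked
probability distributions. Windows that overlap a non-standard residue
(B, J, O, U, X, Z, stops, gaps) are excluded from both the count and the
denominator under the default `drop_ngrams` policy; see below.

## The selection statistic

Let X̄ᵢ(j) and Sᵢ²(j) be the mean and sample variance (divisor Nᵢ − 1) of
feature j over the Nᵢ sequences of superfamily i. For every unordered
pair of classes (p, q) the per-feature separation is

vd₍p,q₎(j) = |X̄ₚ(j) − X̄_q(j)| / (Sₚ²(j)/N_total + S_q²(j)/N_total),

and the final metric is the minimum over all C(C−1)/2 pairs:
vd(j) = min₍p≠q₎ vd₍p,q₎(j). The minimum is the essential step: a
feature scores high only if it discriminates *every* pair of
superfamilies simultaneously. Features are ranked by vd descending and
the top k kept (default k = 50, at the upper end of the "a few tens"
regime this family of methods targets; an absolute threshold mode
`min_metric` is available as an alternative stopping rule).

Two details of the denominator deserve comment.

* **`as_printed` vs `welch`.** The default `as_printed` form divides the
  variances by N_total (the universe size, 8420) and takes no square
  root. It is implemented verbatim because it is the statistic that
  defines the method. It is, however, dimensionally unusual — the
  natural two-sample statistic scales each variance by its own class
  size under a square root — so the `welch` variant,
  |X̄ₚ − X̄_q| / √(Sₚ²/Nₚ + S_q²/N_q), is provided as a first-class
  alternative. The two variants can rank differently: `as_printed`
  strongly favours low-variance features, so rare descriptors with small
  but consistent class differences can outrank a high-rate marker whose
  within-class count fluctuates. Every result records which variant
  produced it.
* **Degenerate denominators.** A zero denominator with a zero numerator
  scores 0 (the feature is identical in both classes). A zero
  denominator with a positive numerator scores +Inf: a zero-variance
  feature whose class means differ separates the pair perfectly and is
  ranked above every finite score. Ties — including ties among
  infinities and among the all-zero tail — break by ascending feature
  index, which makes the selected set deterministic.

Per-class variance is computed by a sparsity-aware two-pass formula: for
a feature with m nonzero values x₁…x_m in a class of N sequences,
SS = Σ(xᵢ − x̄)² + (N − m)·x̄², avoiding both a dense materialisation of
the 8420-column matrix and the cancellation-prone one-pass formula. A
naive nested-loop implementation of the whole chain lives in the test
suite and the vectorized path is required to agree with it to 1e-10
relative on randomized instances.

## Experimental protocol

`run_experiment()` repeats (default 10 times): draw a stratified
train/test split (default 70/30; per class, round(N·f) training rows
clamped so both sides keep at least one row), fit the class statistics
and feature selection **on the training partition only**, restrict both
partitions to the selected descriptors, train the classifier, evaluate
on the held-out partition. Fitting selection on the training rows only
is fixed by design: selecting on all data would leak test information
into the feature set, and the suite asserts that deleting any test row
leaves a run's selected set unchanged. A conventional stratified k-fold
cross-validation mode (`cv_folds`) is provided as an alternative
protocol for the same machinery.

Classifier back-ends are standard implementations used with their
ecosystem defaults: e1071 naive Bayes and SVM, rpart decision trees,
randomForest, and an nnet single-hidden-layer network with 10 hidden
units, softmax outputs (one unit per class) and at most 500 epochs.
One non-default choice applies to all of them: feature columns that are
constant on the training partition are dropped before fitting. Such
columns carry no information, and a Gaussian class-conditional density
with zero standard deviation is undefined, so keeping them would make
naive Bayes degenerate. Run r of an experiment derives its split and
its classifier initialisation from `seed + r − 1`, making every run
individually reproducible.

## Evaluation panel

A C×C confusion matrix (rows actual, columns predicted) is reduced
one-vs-rest: per class, TP is the diagonal cell, FN the rest of the row,
FP the rest of the column, TN everything else. The panel reports TPR
(= sensitivity = recall), FPR, specificity, precision, F-measure and
MCC per class, plus unweighted macro and count-weighted averages —
both, because a single plotted value per metric is ambiguous between
the two reductions. Accuracy is trace over total. Any 0/0 cell (a class
never predicted, an empty F-measure denominator, a zero MCC
denominator) is defined as 0 and flagged rather than raised, so
degenerate runs still aggregate.

## The synthetic generator

`generate_sequences()` draws residues i.i.d. from a background
distribution (uniform by default) with lengths uniform on a range, then
overwrites uniformly chosen non-overlapping windows with each planted
descriptor until the expected occurrence rate (count per k-window)
matches the class's target; the fractional part of the target count is
resolved by a Bernoulli draw. Collisions are handled by sampling only
among currently free positions, and a configuration whose expected
injected residues exceed the shortest sequence is rejected outright.
Background can create incidental copies of a planted descriptor
(expected 20⁻ᵏ per window), and adjacent injections create overlap
n-grams (two abutting MKV copies contain KVM and VMK), so the
generation report's *realized* per-class frequencies — not the nominal
rates — are the ground truth recovery experiments should use.

What the generator emulates is exactly one thing: multi-class sequence
sets whose class signal lives in n-gram occurrence rates. It makes no
attempt to mimic real superfamily composition biases, length
distributions, phylogenetic correlation between sequences, or
position-dependent motif placement. Passing tests on this data
therefore show that the selector recovers n-gram-level signal and that
the harness measures it without leakage — not that any particular
accuracy will be attained on real UniProt superfamilies.

The three presets reproduce the shapes of the benchmark superfamily
selections this method family is usually evaluated on — 750/520/560
(total 1830), 250/250/250 (750) and 190/150/140 (480) — each with one
class-specific 3-mer planted at a 5% window rate, a signal strong
enough that a well-calibrated classifier should approach perfect
accuracy.

## Study conditions used by the tests and the acceptance script

All empirical checks run at sizes chosen to make their effects robust
rather than marginal:

* *Planted-descriptor recovery*: 2 classes × 300 sequences, lengths
  80–120, one 3-mer at rate 0.05 vs 0, twenty generator seeds; the
  planted descriptor is required in the selector's top 10 in at least
  18 of 20 seeds.
* *Selection benefit*: 3 classes × 80 sequences, lengths 60–100, one
  marker per class at rate 0.015 — a deliberately weak signal, because
  that is the regime in which the thousands of uninformative
  descriptors measurably dilute a full-feature Gaussian naive Bayes
  while the top-50 selection retains the markers. Ten 70/30 runs per
  arm.
* *Chance level*: the same shape with nothing planted must put ten-run
  mean accuracy within three standard deviations of 1/3.

## Known limitations

* The `as_printed` statistic is not scale-equivariant and its N_total
  scaling has no sampling-theory interpretation; when in doubt about
  ranking behaviour, run both variants and compare the selected sets.
* Frequencies from short sequences are coarse (a length-8 sequence
  quantises 2-mer frequencies to multiples of 1/7); neither the
  encoder nor the statistic models this extra variance explicitly.
* One-vs-rest MCC on strongly unbalanced confusion matrices can be
  dominated by the majority class; the per-class table is always
  emitted so this is visible.
* The CLI's dense CSV hand-off is convenient but large (one column per
  descriptor); use the MatrixMarket writer for big datasets.
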