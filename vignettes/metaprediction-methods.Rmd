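---
title: "Methods: random-forest metaprediction of variant pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest metaprediction of variant pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Large clinical archives such as ClinVar hold hundreds of thousands of
variants whose assertions are either confident (benign / likely benign,
pathogenic / likely pathogenic) or unresolved: variants of uncertain
significance (VUS) and variants with conflicting interpretations (CI).
Independently of the clinical record, most nonsynonymous variants carry
categorical functional-impact calls from established predictors, distributed
through dbNSFP and copied into VCF INFO fields by SnpSift. `pathometa` builds
a *metapredictor*: a classifier whose features are the categorical calls of
eight such tools — FATHMM (D/T), SIFT (D/T), PolyPhen-2 HDIV and HVAR
(D/P/B), PROVEAN (D/N), MutationAssessor (H/M/L/N), MutationTaster (A/D/N/P)
and LRT (D/N/U) — 8 variables with 23 categories in total.

The model is a random forest: an ensemble of classification trees, each
grown on a bootstrap sample of the training variants with `mtry` candidate
features per split. The pathogenic probability of a variant (RFprob) is the
fraction of trees voting pathogenic — deliberately an uncalibrated vote
fraction, because the downstream reclassification rule "RFprob ≥ 0.9" is
defined on that scale. The label is the majority vote, with the 0.5 boundary
assigned to pathogenic. Training uses confidently-labelled variants only
(benign = 0, pathogenic = 1); the fitted model is then applied to the VUS/CI
set, and predictions with RFprob at or above a threshold in (0.5, 1] (default
0.9, boundary retained) form the high-confidence pathogenic set.

Two evaluation measures drive model selection: the out-of-bag (OOB) error,
computed from the votes of trees that did not see a sample in their
bootstrap — a built-in cross-validation surrogate — and the area under the
ROC curve (AUC) from stratified 10-fold cross-validation, computed by
sweeping the vote-fraction threshold and integrating by trapezoid (equal to
the Mann–Whitney concordance probability with ties counted 1/2).

## Label grouping and complete cases

Raw `CLNSIG` strings are grouped into four analysis labels: benign
(`Benign`, `Likely_benign`, `Benign/Likely_benign`), pathogenic (the three
pathogenic counterparts), `vus`, and `conflicting`. Compound strings with
comma-joined qualifiers (`"Pathogenic,_risk_factor"`) map by their leading
term — ClinVar's primary assertion; anything else (e.g. `drug_response`)
is excluded and counted in the exclusion report. Because the feature space
is the complete set of eight calls, only complete cases are retained;
exclusions are reported per missing-call pattern, and duplicate genomic keys
keep their first occurrence to avoid leakage between training folds.
Multi-transcript calls (`"T,D"` or `"T&D"`) collapse to the most severe
category under each tool's severity order — the conservative reading for a
pathogenicity screen; how the original training data handled transcript
multiplicity is not documented, so this is a package choice.

## The four feature representations

* **Label encoding** (n × 8): categories mapped to 0..k−1 in lexicographic
  order per predictor. Compact but imposes an artificial ordinal scale.
* **One-hot** (n × 23): the indicator matrix, one binary column per
  category; every row sums to 8, one 1 per predictor block.
* **MCA** (n × 2): correspondence analysis of the indicator matrix Z.
  With correspondence matrix P = Z/(nQ), row masses r = 1/n, column masses
  c, the standardized residual matrix is
  S = D_r^(−1/2) (P − r c′) D_c^(−1/2); its singular value decomposition
  gives row principal coordinates D_r^(−1/2) U Σ, of which the first two
  are retained. Total inertia is (J − Q)/Q — 15/8 = 1.875 for the full
  vocabularies — and no Benzécri/Greenacre eigenvalue correction is
  applied, the simplest standard variant. Internally the package
  eigendecomposes the J × J matrix S′S and maps rows through the transition
  formula f = (z/Q − c)′ D_c^(−1/2) V, which handles new rows identically;
  the test suite verifies this route against a literal dense-SVD oracle to
  1e−8. Axis signs are fixed by forcing the largest-magnitude category
  loading positive, so results are deterministic. The encoder is fitted on
  the training rows only and new (reclassification) rows are projected
  through the transition formula — fitting on train+reclass jointly would
  also be defensible, but projection keeps the training representation
  independent of the prediction set.
* **Autoencoder** (n × 2): a symmetric bottleneck network
  23 → h → 2 → h → 23 with h ∈ {10, 20, 30}, hidden activations rectifier,
  rectifier-with-dropout (rate 0.2, inverted dropout, hidden layers only)
  or tanh, and a linear bottleneck and output. A single hidden layer of
  10–30 units cannot by itself emit a two-dimensional code, so the two-unit
  bottleneck is interposed; the bottleneck activations are the learned
  representation. Training minimizes mean squared reconstruction error by
  minibatch SGD (default batch 16, learning rate 1e−3) over 10–30 full
  shuffled passes, with Glorot-uniform initialization under a fixed seed,
  so fitted weights are reproducible. The optimizer is intentionally plain:
  any scheme that reliably decreases the reconstruction loss serves, and
  the loss-decrease property is asserted in the tests for all three
  activations.

## Tuning, selection and importance

`grid_search()` evaluates every combination of representation, autoencoder
hyperparameters, number of trees (default grid 50–1000 in steps of 50) and
`mtry` (default {2, ⌊√d⌋, ⌊d/2⌋, d}, clipped and deduplicated; {2, 4, 11,
23} for one-hot). Each cell reports the stratified 10-fold CV AUC and the
OOB error of a forest grown on all training rows; the winner maximizes AUC
with ties broken by lower OOB error, then fewer trees, then smaller `mtry`.
Every cell derives a fixed sub-seed from the master seed, so the whole
search is bit-reproducible. Unsupervised encoders are fitted once on the
full training table before the forest is cross-validated; since labels play
no part in the encoders, no label information crosses fold boundaries.

Feature importance is the mean decrease in Gini impurity, summed over trees
and normalized to 1; for one-hot models the per-category columns are also
aggregated to their source predictor so importance is comparable across
representations. Naive Bayes and linear/RBF SVM baselines (with Platt's
monotone probability calibration, which leaves AUC unchanged) are evaluated
under the same CV harness for the comparison table.

Class imbalance is left uncorrected: the intended training sets are only
mildly unbalanced, and vote fractions remain interpretable.

## What the synthetic generator emulates — and what it does not

`simulate_variants()` draws, per variant with pathogenic ground truth, each
predictor's *most severe* category with probability `concordance` and
otherwise a uniform draw over the remaining categories; benign truth mirrors
this with the *least severe* category. VUS/CI strata carry the ClinVar
`CLNSIG` strings but a hidden 50:50 ground truth, so recovery can be scored.
Calls are independently masked with probability `missing_rate`; positions
are collision-free per contig and ref ≠ alt, since only key uniqueness
matters downstream. A `concordance` vector (one value per predictor) can
plant a single informative predictor among uniform-noise ones
(`concordance = 1/k`), which is how the importance-recovery experiments are
built.

The generator's class-conditional calls are *independent across predictors*
given the truth — real predictors are highly correlated (they share
conservation signals); categories other than the class-consistent one are
uniform, and missingness is completely at random, whereas real missingness
tracks gene coverage in dbNSFP. Passing tests therefore demonstrate correct
mechanics and statistical behaviour under a known signal, not real-data
performance: with eight independent informative predictors at concordance
0.9 the classes are nearly separable (CV AUC ≈ 1), which is *stronger*
separation than real ClinVar features provide.

## Default study conditions and problem sizes

The packaged experiments use balanced training sets (1000 + 1000 variants)
at concordance 0.9 with 5% missingness — a realistic per-tool agreement
rate for confidently-labelled ClinVar variants — plus VUS/CI strata for
reclassification; OOB-vs-CV agreement is checked at n = 5000 and
importance recovery over 100 seeded replicates of n = 1000. These sizes
give stable estimates (CV AUC standard deviations below 0.01) while keeping
a full run in minutes on one core; the conclusions are unchanged at larger
n.

## Numerical choices and degenerate inputs

* MCA requires ≥ 3 distinct rows and ≥ 2 positive singular values; columns
  for never-observed categories are dropped with a warning (lowering the
  total inertia accordingly).
* Encoding rejects rows with missing calls rather than imputing.
* CV folds that degenerate to a single class are skipped with a warning;
  AUC is undefined (error) when a score set has only one class.
* The simulator and every fitting function save and restore the caller's
  RNG state, so library calls do not perturb user-level reproducibility.
* Thresholds: predicted label uses RFprob ≥ 0.5; high confidence uses
  RFprob ≥ threshold, boundary retained in both cases.

## Known limitations

* LRT's category set includes "D" as defined by dbNSFP; some summaries list
  only N/U. `predictor_vocabularies(lrt_d = FALSE)` switches it off.
* The autoencoder is a faithful small MLP, not a tuned representation
  learner; its purpose is the representation benchmark, not state-of-the-art
  reconstruction.
* Published reclassification percentages for archives of this kind are
  sensitive to the denominator (per-stratum vs overall);
  `summarize_reclassification()` reports both.
* The pipeline neither runs the eight predictors nor re-derives ClinVar
  review status; it consumes `_pred` categories as given.
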