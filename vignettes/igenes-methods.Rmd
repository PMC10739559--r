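---
title: "Methods: selection, ensemble prediction, and I-Gene scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection, ensemble prediction, and I-Gene scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igenes)
```

This vignette documents the statistical model behind `igenes`, the
decisions taken where more than one defensible formulation exists, and
what the package's validation on simulated cohorts does and does not
demonstrate about real data.

## The data model

A CIGT table is a patients-by-features table: a unique patient identifier,
a binary diagnosis (0 = control, 1 = case), and numeric features that mix
processed gene expression with demographic attributes. The package assumes
expression values are already normalized upstream (e.g. log-scale
abundances); it performs no library-size or batch correction. Categorical
demographics are integer-encoded by lexicographic category order rather
than one-hot expanded, deliberately: every input column stays a single
feature, so selection provenance, attributions, and I-Gene scores refer to
the biomarker or attribute a clinician recognizes. The encoding is
deterministic, so cohorts written and re-read reproduce codes exactly.

Missing values are rejected at validation by default. Silent imputation
hides data problems; when imputation is wanted, `impute_cigt()` computes
per-feature medians — on the training part only, with the medians reusable
for the test part — so no information leaks across the split.

## Feature selection

Four selectors run independently; each reports a per-feature statistic,
p value (where defined), rank, and a selected set at significance level
`alpha` (default 0.05, a conventional choice; a Benjamini–Hochberg option
is available but off by default since the base method is defined on raw
p values).

* **Point-biserial correlation** — Pearson correlation `r` between the
  feature and the 0/1 label, with the two-sided p value from
  `t = r√((n−2)/(1−r²))` on `n − 2` degrees of freedom.
* **Chi-square** — each feature is dichotomized at its own mean (a
  label-free, monotone reduction) and the resulting 2×2 class-by-level
  table is tested with the classical Pearson chi-square statistic
  (margin-based expected counts, no continuity correction, 1 df). A
  count-style chi-square score applied directly to continuous expression
  values has no chi-square null and is severely miscalibrated, while the
  mean-split contingency test holds its nominal type-I rate — the package
  asserts a 0.05 ± 0.02 null selection rate over 1000 simulated null
  genes for each of the three statistical selectors. A mean threshold is
  preferred over a median threshold because the median forces fixed 50/50
  level margins, whose discrete (hypergeometric) null makes the
  uncorrected test measurably liberal.
* **ANOVA** — the one-way F statistic between cases and controls; with
  two groups `F = t²` for the pooled-variance t, an identity the test
  suite asserts to 1e-9.
* **RFE** — backward elimination with a random-forest importance backend
  (mean Gini decrease), removing exactly one feature per iteration until
  `n_keep` remain. The default `n_keep` is the top 10 % of features
  (at least one). Kept features have rank 1; eliminated features count
  upward in reverse elimination order.

Zero-variance features cannot be tested and are excluded with a warning in
every selector rather than raising — a single flat probe should not abort
a cohort analysis. Selected sets combine by union (default),
intersection, or at-least-k vote; the union default reflects that the
intersection of four heterogeneous selectors is frequently empty on small
cohorts. An empty combined set is an explicit error with advice, never a
silent empty continuation. Demographics compete like any feature;
`force_demographics = TRUE` appends them regardless.

## The prediction ensemble

Five base classifiers — random forest (100 trees), RBF-kernel SVM
(cost 1, γ = 1/p), XGBoost (100 rounds, depth 6, η = 0.3), k-NN (k = 5),
and a perceptron with one hidden layer of 100 units (≤ 500 iterations,
decay 1e-4) — are fitted on the selected features. None of these
hyperparameters are tuned; all are exposed in `ensemble_control()`. One
z-score standardization, fitted on training rows only, is shared by every
member: the scale-sensitive members (SVM, k-NN, MLP) require it, and tree
models are scale-invariant, so a single matrix keeps the pipeline simple.
The test suite asserts that the stored scaler equals the training-column
moments and inverts to machine precision.

SVM case probabilities come from Platt scaling — a logistic regression of
the training labels on the SVM decision values. This is a deliberate
choice over the SVM library's built-in cross-validated calibration, whose
internal randomness is not controlled by R's RNG and would break the
package's guarantee that one seed reproduces every output byte for byte.

Two voters aggregate the enabled members: the soft voter averages case
probabilities (unweighted) and calls a case when the mean is **≥ 0.5**;
the hard voter takes the majority label and resolves exact ties — possible
when users disable members, leaving an even count — to **control**,
signalling an `igenes_tie` condition. The asymmetry is intentional and
unit-tested: a patient whose probability evidence is exactly balanced is
flagged as a case for follow-up, whereas a tied discrete vote defaults to
the less alarming call rather than silently flipping.

Evaluation uses a stratified 70/30 split (largest-remainder allocation per
class, ties broken by ascending class label) and reports accuracy, F1
(positive class = case), and ROC AUC per classifier. The hard voter has no
probability, so its AUC is computed from its 0/1 labels; a single-class
evaluation set yields `NA` AUC with a warning.

## Attributions and the I-Gene score

Per-classifier feature attributions are interventional Shapley values of
the **case probability** (not the decision label, so signs carry magnitude
information). The value of a coalition is the model output with
in-coalition features taken from the explained patient and the remainder
marginalized over a background set — the training cohort, subsampled to at
most 100 rows with the run seed. Two estimators:

* **exact** (≤ 8 features by default): full enumeration of the `2^M`
  coalitions with the Shapley subset weights. The test suite checks it
  against an independent brute-force enumeration over feature orderings on
  small tree models, to 1e-6.
* **sampling** (default above 8 features): marginal contributions averaged
  over 8 random feature orderings. Contributions telescope within an
  ordering, so additivity (`baseline + Σφ = f(x)`) is exact for any number
  of orderings; only the split of credit between correlated features is
  estimated. Eight orderings, averaged over all explained patients, is
  enough to stabilize the global mean-|φ| ranking the I-Gene score uses;
  it is a speed/precision default, overridable via `n_perm`.

A member whose explainer fails is excluded from scoring with a warning —
never zero-filled, which would masquerade as "no importance". The two
voters are not explained: hard voting has no probabilistic output to
attribute, and the soft voter is a fixed average of members already
explained individually.

The aggregation chain is then:

1. shares `s_{c,f} = mean|φ_{c,f}| / Σ_g mean|φ_{c,g}|` (mean absolute
   attribution is the conventional global importance; an all-zero
   classifier is flagged degenerate and excluded);
2. concentration `HHI_c = Σ_f s_{c,f}²` on the unit scale (not the
   ×10 000 economics convention — unit-interval weights compose cleanly);
3. weights `w_c = HHI_c / Σ HHI` — proportional to concentration, the
   simplest monotone scheme: classifiers relying on few high-impact
   biomarkers count for more;
4. raw scores `I_f = Σ_c w_c s_{c,f}`, which sum to 1 by construction
   (asserted to 1e-9), displayed as `100 · I_f / max I`.

**Directionality.** For each feature and classifier the Pearson
correlation between feature values and per-patient attributions is
computed and averaged across classifiers with the HHI weights. A weighted
correlation above `tau` (default 0.1) labels the feature `overexpressed`
(high values push toward a case call), below `−tau` `underexpressed`,
otherwise `neutral`. The correlation rule treats both polarities
symmetrically and the `tau` band keeps noise-level features from getting a
confident label. An alternative reading — comparing case/control means
among positively attributed patients only — conditions on the model's
output and breaks symmetry between polarities, so the correlation rule is
the default. Zero-variance features are `neutral` with a warning. HHI
weights are computed over the full selected-feature set, not a top slice,
so the concentration a classifier is rewarded for is measured on
everything it saw.

## The synthetic cohort generator

`simulate_cigt()` draws uninformative genes i.i.d. Normal(8, 1) in both
classes (log2-expression-like location and scale) and shifts the case mean
of informative genes by ±`effect_size`·SD, alternating the sign by gene
index so directionality is exercised in both polarities from one cohort.
Optional demographics are generated independently of the label. The
defaults — 100 cases/100 controls, 50 genes, 5 informative at d = 2 —
are the package's reference study conditions: large enough that selection
power is essentially 1 and ensemble accuracy is high, small enough that
the full validation suite runs in minutes on one CPU.

What the generator does **not** emulate: count-level noise
(negative-binomial dispersion), library-size effects, batch structure,
gene–gene correlation, or label-confounded demographics. Passing tests
therefore demonstrate the pipeline's correctness and calibration under
clean Gaussian signal, not its power on real RNA-seq cohorts; on real
data, correlated genes will share Shapley credit and effect sizes are
rarely d = 2.

## Determinism and numerical choices

Every stochastic stage derives its own substream seed from the single run
seed plus a stage name, so stages are reproducible independently of
execution order, and the test suite asserts that two pipeline runs with
one seed produce byte-identical CSVs. XGBoost runs single-threaded for the
same reason. Scaling uses population-style `sd` with zero-SD features
scaled by 1 (they contribute nothing after centring). Share/weight sums
are validated to 1e-9; HHI rejects share vectors that do not sum to 1.
Ranks break ties by first occurrence (column order), documented and
stable.

## Validation scale

The test suite validates at these problem sizes, chosen as the package's
reference conditions: calibration on 1000 null genes (n = 100);
planted-signal recovery over 10 seeded replicates of the default cohort
(selection recall, held-out soft-vote accuracy, top-10 I-Gene placement of
all five planted genes); direction agreement at 200/200 samples; Shapley
oracle equivalence on 2-feature trees with 8 samples; and byte-level
determinism of the full pipeline.

## Known limitations

Binary diagnosis only — multiclass labels are rejected at validation.
Attribution cost grows as `n_perm × M × background × patients`
predictions per member; for very wide selected sets, lower
`background_size` or `n_perm`, or explain a subsample. Shapley credit
splits across correlated biomarkers, so a true driver gene can share its
I-Gene score with a correlated passenger; the score ranks predictive
reliance, not causality.
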