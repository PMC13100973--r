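---
title: "Deficit-accumulation frailty and its brain correlates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deficit-accumulation frailty and its brain correlates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraildex)
```

## The scientific problem

Frailty, understood as the accumulation of health deficits across
physiological systems, is increasingly studied as a marker — and possible
driver — of dementia. `fraildex` implements a complete analysis chain for
this question in a three-group clinical design (cognitively unimpaired, CU;
Alzheimer's disease, AD; frontotemporal lobar degeneration, FTLD):

1. construction of a deficit-accumulation **frailty index** from ~32 binary
   health items, with screening and completeness rules;
2. **class-weighted gradient-boosted classification** of diagnostic pairs
   from the index (or the item set), with cross-validated AUC and additive
   (SHAP) attributions;
3. **mass-univariate OLS association** of frailty with regional gray-matter
   volumes and with ROI-to-ROI functional connectivity, per group, with
   FDR control;
4. **subsampling contrasts** of the frailty–brain association strength
   between groups;
5. **image-quality covariates** (spatial SNR, segmented temporal SNR) for
   sensitivity re-runs.

Because patient-level data cannot ship with the package, a first-class
**synthetic cohort generator** reproduces the statistical structure each
stage assumes, with ground-truth parameters emitted alongside the data so
that recovery is testable.

## The frailty index

For participant $i$ with $k_i$ observed binary items, the index is

$$\mathrm{FI}_i = \frac{\#\{\text{deficits present}\}}{k_i},$$

i.e. missing items shrink the denominator rather than being imputed.
Participants observing fewer than 80% of the item set receive no index
(`included = FALSE`). Items pass four screens before entering the index, in
this order: missingness $\le$ 15%; deficit prevalence within $[1\%, 80\%]$;
pairwise Pearson $|r| < 0.8$ on the binarized values (pairwise-complete);
iterative variance-inflation-factor pruning at VIF $< 10$ on complete
cases. Each decision is recorded in a ledger (`screen_items()`), so the
screening is reproducible from its recorded statistics, and re-screening
the retained set is a no-op.

Choices the index definition leaves open, fixed here once:

* **Binarization cut points** are not part of the index definition; the
  package ships a declarative default map (`default_item_specs()`: BMI
  deficit outside $[18.5, 30)$, SBP $\ge 140$, DBP $\ge 90$, resting HR
  outside 60–100, GDS-SF $\ge 5$, GAD-7 $\ge 5$, MMSE $< 24$, PFAQ
  $\ge 6$, per-domain NPI-Q positivity, current smoking, …) but every
  analysis must state its own rule set; a raw column without a rule is a
  schema error.
* **Boundary convention**: thresholds are closed on the deficit side — a
  value equal to the cut point is a deficit. Stated once, applied
  everywhere.
* **Correlated-pair tie-break**: the member with more missing values is
  dropped; ties drop the later item in spec order. Deterministic, hence a
  reproducible ledger.
* **Sensitivity variants** (`variant_index()`) recompute the index without
  the CDR block, without CDR+MMSE, and without CDR+MMSE+GAD-7+GDS-SF — the
  standard guard against circularity when the index classifies diagnoses
  that are themselves defined partly through those instruments. The 80%
  completeness gate applies to the reduced denominator.

## The synthetic cohort generator

`cohort_config()` defaults encode the emulated study design:

* group frailty distributions: CU $\mathcal N(0.14, 0.065^2)$, $n = 1924$;
  AD $\mathcal N(0.24, 0.075^2)$, $n = 1126$; FTLD
  $\mathcal N(0.27, 0.10^2)$, $n = 411$ — **truncated to $[0,1]$ by
  rejection sampling**, not clipping. For these parameters the truncation
  boundary sits $\ge 2$ SD from every mean, so rejection keeps the realized
  moments within a fraction of a percent of the configured ones, whereas
  clipping would pile mass at 0 and bias downstream AUCs.
* 32 binary items across the six deficit domains, with per-group deficit
  probability equal to the group's mean frailty, so the computed index has
  the configured group means in expectation. Item draws are independent
  given group by default; an opt-in logistic coupling
  (`item_coupling = "logistic"`) shifts each item's logit by the
  participant's standardized latent frailty for end-to-end tests that need
  index–truth correlation. The joint distribution of items within person is
  a modelling choice — no published fact constrains it — so the simplest
  structure is the default.
* missingness is completely at random at rate 0.02 (no published
  missingness mechanism exists to emulate; 2% is typical of curated
  clinical batteries).
* ROI volumes: $v = 5.0 + \beta_g \, \mathrm{FI} + s_{\text{scanner}} +
  \varepsilon$, $\varepsilon \sim \mathcal N(0, 0.5^2)$ in arbitrary
  TIV-adjusted units, with default group slopes CU $-1$, AD $-2$, FTLD
  $-3$ per unit frailty (disease groups couple more strongly), and three
  scanners at offsets $0, +0.2, -0.2$.
* connectivity edges on the Fisher-z scale: baseline $0.3$, group slopes
  $-0.1/-0.2/-0.3$, residual SD $0.2$; matrices are symmetric by
  construction and the diagonal is excluded from analysis.

What the generator does **not** emulate: inter-regional covariance beyond
the shared frailty signal, non-Gaussian item batteries, informative
missingness, scanner-by-region interactions, and any voxel-level structure.
Tests passing on this cohort therefore validate the statistical machinery
and its calibration, not claims about real MRI data.

## Classification stage

`fit_evaluate()` follows the boosted-logistic design: a stratified 80%
train / 10% test / 10% reserve split (the stated fractions leave 10%
unassigned; the package holds it in reserve rather than silently enlarging
either partition); hyperparameters chosen by a Bayesian search — Gaussian
process surrogate (`kernlab::gausspr`) with expected-improvement
acquisition over a Latin-hypercube-initialized design — scored by 10-fold
stratified cross-validated AUC on the training partition; class imbalance
handled by `scale_pos_weight` = (negatives/positives), recomputed on each
fold's training part; a single refit on the full training partition; SHAP
attributions computed once on that partition.

Defaults the source design leaves unstated, fixed here: search space
`max_depth` 2–8, `learning_rate` 0.01–0.3 (log), `n_estimators` 50–500,
`min_child_weight` 1–10, `subsample` 0.6–1.0; budget 25 evaluations;
decision threshold 0.5 for confusion matrices.

Two reporting decisions deserve emphasis:

* **Fold AUCs are recomputed after selection** on a fresh stratified fold
  split. Reusing the winning candidate's own search scores would inherit
  the optimism of a maximum over noisy CV estimates (~+0.02 at budget 10 in
  our measurements). This matters most for the hardest pair (AD vs FTLD),
  where the distributions overlap heavily.
* Threshold metrics (accuracy, balanced accuracy, sensitivity, specificity,
  precision, F1, Brier) are reported **both** for the held-out 10% test
  partition and for the pooled CV predictions, labelled `metrics_test` and
  `metrics_cv`, because a report of this kind can come from either and the
  two can differ noticeably at these sample sizes.

For a single monotone feature the model's AUC must match the Mann–Whitney
`rank_auc()` of the raw feature — that identity (and the binormal closed
form $\Phi(\Delta\mu / \sqrt{\sigma_1^2 + \sigma_2^2})$) is the analytic
oracle used by the test suite. One subtlety the synthetic design exposes:
with unequal group variances the likelihood-ratio-optimal score is
non-monotone in the feature, so a flexible classifier can legitimately
exceed the binormal AUC by a few points on the AD/FTLD pair (the
Gaussian LR bound is ≈ 0.64 against a binormal 0.595 at those parameters).

## Mass-univariate association models

One OLS per region (or edge): outcome on frailty plus dummy-coded scanner
covariates, most frequent scanner as reference (maximal stability of the
reference column). Per model we extract the frailty $t$ and $p$, the model
$F$ $p$ and adjusted $R^2$. Model $p$ values are Benjamini–Hochberg
corrected **across the region (edge) family within one group's analysis**;
families are never pooled across groups. A unit is significant when its
FDR-corrected model $p$ and its raw frailty $p$ are both below .05 — the
FDR-corrected frailty $p$ is also emitted so users can apply the stricter
reading. Constant-outcome units are flagged degenerate and excluded from
the FDR family with a message.

A caveat the null simulations make visible: when scanner (or any covariate)
truly affects the outcome, the *model* $p$ is significant everywhere, and
the dual criterion degenerates to the uncorrected frailty $p < .05$ —
expected false-positive fraction ≈ 5% rather than FDR-controlled. The
calibration tests therefore use a fully null generative model (zero slopes
*and* zero scanner offsets); under it the significant fraction is ≈ 0 and
the raw frailty $p$ values are uniform. Users wanting strict control over
the frailty claim itself should gate on `frailty_q`.

On fixtures of ≤ 5 regions and ≤ 30 participants the implementation matches
a naive normal-equations oracle to 10⁻⁸ (shared-design QR vs explicit
$(X'X)^{-1}X'y$).

## Subsampling contrasts

Within each group, `subsample_t_distribution()` redraws a fraction
(default 0.8, without replacement — the fraction is not part of the
published design and is recorded in the output) of the group's
participants `n_draws` times (design value 1000), refits every unit's OLS
on each draw, and records the frailty $t$. Draw-level seeds derive from the
master seed by draw index, so distributed and serial execution agree
exactly; a brute-force loop oracle reproduces the matrix bit-for-bit under
a shared seed. Degenerate draws (constant outcome, vanishing scanner
level) are redrawn up to a retry cap.

`contrast_groups()` compares two groups' empirical $t$ distributions per
unit with a Welch two-sample test, BH-corrected across the restricted unit
family — restricted, per the published procedure, to units significantly
associated with frailty in at least one group's full-sample analysis. The
group with the larger absolute mean $t$ is labelled dominant.

**Calibration property, and its limits.** The draws within a group overlap
heavily (fraction 0.8), so the empirical $t$ values concentrate around the
group's *full-sample* $t$, whose own sampling variability does not shrink
with `n_draws`. The Welch statistic divides by SDs scaled with
$1/\sqrt{n_{\text{draws}}}$, so between-group contrast $t$ values are very
large whenever the two groups' full-sample $t$'s differ at all — including
by chance. For equal **nonzero** slopes in independent cohorts the
unrestricted contrast flags most units (measured ~90% at slope $-2$ in
both groups); this anti-conservativeness is a property of the published
procedure (its very large printed contrast $t$ values arise the same way),
not an implementation artifact, and the package surfaces `n_draws`
alongside every contrast so magnitudes stay interpretable. What keeps the
procedure's false-positive surface in check is the **restriction rule**:
under the equal-slope *null* (no frailty–brain association in either
group), the restriction set is empty with high probability and ≈ 0
contrasts are flagged — the property the calibration tests assert.
Contrast results should be read as "the association profiles differ", not
as calibrated tests of slope equality.

## Quality metrics

Spatial SNR is the mean of (already-masked) voxel intensities divided by
their SD — scale-invariant, undefined for constant input. Temporal SNR
splits a series into consecutive non-overlapping 20-point segments
anchored at the first time point (anchoring/overlap is a package choice;
the formula's source states neither), averages each complete segment's
mean/SD ratio, and discards the trailing remainder; the segment count is
exactly $\lfloor T/20 \rfloor$. The package computes tSNR per series;
averaging over voxels, if desired, happens upstream.

**Known estimator bias.** At segment length 20 the ratio
$\bar x_{\text{seg}} / s_{\text{seg}}$ is biased upward: $E[s] = c_4(20)\,
\sigma$ with $c_4(20) \approx 0.987$, and Jensen's inequality on $1/s$
adds a further $O(1/n)$ term, so the segmented estimator converges to
$\approx 1.04\,\mu/\sigma$ rather than $\mu/\sigma$ (measured 10.40 for
$\mathcal N(100, 10^2)$ over 2000 replicate segments). The package applies
no correction, because the formula it implements specifies none; the bias
is irrelevant for the metric's use as a *covariate* (it is a fixed
multiplicative factor at fixed segment length) but matters if tSNR values
are compared across different segment lengths. The corresponding
convergence check in the acceptance tests is expected to fail at a ±2%
band and is left failing by design.

## Group statistics

Continuous cohort-table variables use classic one-way ANOVA with Tukey HSD
post hocs; categorical variables use uncorrected Pearson $\chi^2$ (the
printed statistics of the emulated study match the uncorrected form on its
printed counts). ANCOVA (group + age, sex, education) reports the partial
group $F$ with Tukey HSD on covariate-adjusted means via `multcomp::glht`;
Cohen's $d$ is the pooled-SD form on raw values and is reported for
reference only, since covariate-adjusted $d$ values depend on an
adjustment structure that cannot be recovered from a printed table.
Complete cases are used per variable, with the analysis $n$ recorded.

## Problem sizes and seeds

All stochastic behavior flows from integer seeds; every stage re-derives
sub-seeds by fixed offsets, so any stage is reproducible in isolation. The
test suite runs the classifier at full published sample sizes with a
search budget of 10 (the single-feature AUC is insensitive to the boosting
hyperparameters — the suite asserts the rank-AUC identity), the
mass-univariate null calibration at 200 replicates × 116 regions ×
$n = 200$, and the subsampling stages at `n_draws` = 200 on ≤ 10-region
parcellations; these sizes were chosen to keep the full suite under a
minute while leaving every assertion's Monte-Carlo error an order of
magnitude below its tolerance.

## Limitations

* Real-data mode expects upstream preprocessing (TIV adjustment,
  normalization, masking, motion correction) to be complete; the package
  starts at ROI tables.
* The dual significance criterion follows the published wording; see the
  caveat above about covariate-driven model significance.
* The subsampling contrast is descriptive, not a calibrated test of slope
  equality.
* No imputation, no multiclass models, no cross-site harmonization beyond
  scanner dummies, no network-based statistics.
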