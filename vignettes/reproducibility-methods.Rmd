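---
title: "Assessing the reproducibility of connectivity group contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the reproducibility of connectivity group contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcrepro)
```

## The problem

Edgewise case–control differences in resting-state functional connectivity
are notoriously unstable across cohorts. `fcrepro` provides the statistical
machinery to ask *whether* a group contrast reproduces — across independent
datasets, and across random splits of a single dataset — and to attribute
failures to disease heterogeneity rather than technical variation.

This vignette documents the model, the tunable parameters, the numerical
conventions, and the design decisions that were genuinely open, together
with what the synthetic-data tests do and do not establish about real data.

## Connectivity and the group contrast

Each scan is a $T \times R$ matrix of mean region timecourses. Connectivity
for an unordered region pair $(a, b)$ is the Fisher z-transform of the
Pearson correlation, $z = \operatorname{atanh}(r)$, the variance-stabilising
scale on which group effects are modelled as additive. All $P = R(R-1)/2$
pairs are stored in one canonical order (lexicographic in $(i, j)$, $i<j$,
1-based), the single source of truth for every downstream vector.

Numerical conventions:

* correlations are clipped to $|r| \le 1 - 10^{-12}$ before `atanh`, so a
  perfectly correlated pair yields a large finite $|z| > 13$ rather than an
  infinity; a *constant* timecourse is an error naming the region — silent
  `NaN`s would poison the whole vector;
* the NC-vs-PD contrast is an unequal-variance (Welch) two-sample t-test per
  pair, computed with a two-pass variance formula; the sign convention is
  $t > 0 \iff \overline{FC}(\mathrm{NC}) > \overline{FC}(\mathrm{PD})$, so
  positive $t$ reads "connectivity decreased in disease";
* a pair with zero variance in both groups gets $t = 0$, $p = 1$;
* samples are *scans* by default. Cohorts with replicate scans typically
  report scan counts per group, implying pooled replicates; because
  replicates of one subject are not independent, a
  `sample_unit = "subject_mean"` switch averages each subject's FC vectors
  first. The default is the pooled (scan-level) analysis.
* No per-edge multiple-testing correction is applied inside the contrast:
  inference happens at the level of aggregate permutation statistics, not
  individual edges.

## The reproducibility statistic and its permutation null

For datasets $i, j$ with contrast t-vectors $T_i, T_j$, reproducibility is
$R_{ij} = \operatorname{corr}(T_i, T_j)$. Its significance comes from
permuting the group labels *independently in each dataset* and recomputing
both contrasts:
$$p_{ij} = \#\{\sigma : R_{ij}^{(\sigma)} \ge R_{ij}\} / N .$$

Decisions worth recording:

* the formula is implemented verbatim — no add-one correction — so $p = 0$
  is attainable; the conservative companion $(Np + 1)/(N + 1)$ is carried in
  the result object;
* ties $R^{(\sigma)} = R$ count toward the numerator ("$\ge$" as written);
* labels are permuted at **subject** level by default (all scans of a
  subject move together): the subject is the exchangeable unit when
  replicate scans exist. A `perm_unit = "scan"` switch provides the laxer
  alternative; on cohorts without replicates the two coincide.
* $N = 1000$ permutations by default.

## Random splits: the heterogeneity probe

A dataset with $\ge 2$ replicate scans per subject supports two split
geometries:

* **split subjects** (heterogeneous): within each group, subjects are
  randomly partitioned into halves (side 1 takes the extra subject when the
  count is odd), all scans of a subject on one side;
* **split replicates** (homogeneous): every subject appears on both sides
  through disjoint replicate scans, with the assignment randomised per
  subject and balanced when there are more than two replicates.

Both halves are then compared exactly as two datasets would be. Replicate
splits share their subject sample, so only scan-level noise separates them;
subject splits additionally resample the population. Consistent
reproducibility across replicate splits together with frequent
non-reproducibility across subject splits therefore indicates that the
*population* is heterogeneous — subpopulations carry different connectivity
alterations — rather than that the measurement is unstable. `split_batch()`
aggregates the per-split $(R, p)$ values into the median $R$ and the
fraction of splits non-reproducible at each $\alpha$ (defaults 0.01, 0.05),
plus empirical CDFs via `autoplot()`.

## Edge-level consistency: min(max(p))

Even a globally non-reproducible contrast may contain a few edges that
replicate. For a direction $+$ (or $-$), every pair whose $t$ is positive
(negative) in *all* datasets receives $\max(p)$, the worst of its
per-dataset two-sided p-values; pairs failing the sign condition anywhere
are excluded. The ranked table ascends in $\max(p)$ with ties broken by
pair index, and the scalar summary is $\min(\max(p))$. Because that minimum
runs over thousands of edges it is not a p-value; its significance is the
fraction of joint label permutations achieving a smaller-or-equal statistic
("$\le$", ties counting). Per-dataset p-values entering $\max(p)$ are the
two-sided Welch p-values restricted by sign — the reading consistent with
published tables of this statistic. An empty retained set yields
$\min(\max(p)) := 1$, the most conservative convention. Pairs with $t$
exactly 0 (a measure-zero event) belong to neither direction.

## Classifier transfer

`select_features()` ranks pairs by $|t|$ on training data only (ties broken
by ascending pair index). Two classifiers are deliberately simple, since the
evaluation protocol, not the model, is the point:

* a linear-kernel SVM at fixed cost $C = 1$, features standardised by
  training means/SDs (no tuning: tuning would silently change the
  contract);
* Gaussian naive Bayes with per-class means and variances, the variances
  floored at $10^{-9} \times$ the largest feature variance for numerical
  safety.

Performance is the balanced average accuracy
$A_{acc} = (acc_{NC} + acc_{PD})/2$, insensitive to class imbalance: any
constant prediction scores exactly 0.5. `evaluate()` refuses overlapping
train/test scan sets unless resubstitution is explicitly requested.
`split_half_batch()` repeats stratified half-splits at subject level by
default so replicate scans never straddle the train/test boundary (identity
leakage); `split_unit = "scan"` reproduces the laxer policy. With
`permute_labels = TRUE` the group labels are freshly permuted before every
repeat — the chance-level null. A *single* fixed permutation is not used
for that purpose: it retains chance alignment with the true labels, and the
mean accuracy over splits then converges to that alignment's accuracy, not
to 0.5.

## The synthetic cohort generator

No real multi-site patient data ships with the package; the generator
emulates the *structure* those analyses exploit:

1. a baseline correlation matrix $C_0$ = low-rank-plus-diagonal
   ($WW' + \operatorname{diag}(u)$, rescaled to unit diagonal), giving the
   block-like structure of parcellated connectomes; its own seed
   (`base_seed`) lets several simulated "sites" share one underlying
   connectome;
2. disease subtypes: each PD subject draws a subtype by the configured
   proportions; the subtype shifts its edge set by $\Delta z$ in Fisher-z
   space (`apply_effect_in_z()`), with repair to the nearest valid
   correlation matrix;
3. subject- and scan-level Gaussian jitter on off-diagonal z-entries
   (`sigma_subject`, `sigma_scan`), each followed by repair — the variance
   components that make split-subjects and split-replicates genuinely
   different;
4. per scan, a $T \times R$ draw from $\mathcal N(0, C_{scan})$, optionally
   passed through an AR(1) recursion
   $x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\,\varepsilon_t$ whose innovations
   are already cross-correlated, so the stationary lag-0 correlation equals
   the target exactly.

Matrix repair is alternating projections with Dykstra's correction
(eigenvalue clipping at 0, unit-diagonal restoration; at most 100
iterations, Frobenius tolerance $10^{-8}$), finished by a congruence step
that restores the unit diagonal without leaving the PSD cone.

Defaults, chosen once as a plausible modest clinical cohort: $T = 150$
timepoints at TR = 2 s (a five-minute scan), 15 + 15 subjects with 2
replicates, $\Delta z = 0.35$ on 20 edges (the middle of the 0.2–0.5 range
that spans weak-to-strong reported connectivity effects; no published
effect-size scale exists for this contrast, so this is a calibration choice,
not an empirical claim), `sigma_subject` = 0.1 and `sigma_scan` = 0.05 —
between-subject variability about twice the scan-to-scan test-retest
variability, in line with the common finding that individual connectomes are
stable relative to group differences.

What the generator does **not** emulate: hemodynamics, physiological and
motion artifacts, scanner-specific spectra, non-Gaussian tails, spatial
autocorrelation of parcels, and site covariate shifts other than sampling
variability. Passing tests therefore establish the *statistical machinery*
(calibration, invariances, oracle agreement, qualitative split behaviour)
— not that real cohorts will show any particular effect.

## Temporal operations

Lightweight per-scan operations mirror common preprocessing variants whose
influence on reproducibility one may want to probe:

* **global signal regression** — least-squares removal of the cross-region
  mean (with intercept); a constant global signal degenerates to demeaning;
* **ideal bandpass** — DFT coefficients strictly below `low_hz` or strictly
  above `high_hz` are zeroed (DC removed whenever `low_hz > 0`). Band edges
  exactly on a DFT bin are kept; the filter is idempotent. This is an
  idealised stand-in for the non-ideal highpass filters of standard fMRI
  toolchains — flagged here, not claimed equivalent;
* **double-TR decimation** — keep the 1st, 3rd, 5th, … timepoints and
  double `tr_seconds`; which phase is kept is a free choice, fixed to the
  first sample for determinism.

## Pipeline and seeds

`run_pipeline()` executes a declarative stage list (R list or YAML) and
writes a JSON manifest of every artifact with its stage, parameters and
seed. Each stage draws its seed as a stable hash of the global seed and the
stage *name*, so inserting a stage never shifts another stage's randomness.
All stochastic functions accept an explicit `seed` and restore the caller's
RNG state.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep the full suite within
a few minutes while leaving each check statistically meaningful: chance
calibration of the classifier on a 30 + 30-scan cohort at $R = 90$ over 500
half-splits; exhaustive-enumeration agreement on 3 + 3-subject cohorts
($\binom{6}{3}^2 = 400$ label assignments) against 1000 Monte-Carlo
permutations; null calibration over 200 simulated dataset pairs with
$N = 1000$; split-geometry patterns on 10 + 10-subject cohorts at $R = 16$
with 100 splits × 300 permutations; generator consistency at
$T = 5 \times 10^4$. Production analyses would scale $N_s$ and $N$ up via
the corresponding arguments (the package defaults are $N = 1000$
permutations, and split counts are explicit everywhere).

## Known limitations

* Welch p-values assume approximate normality of Fisher-z connectivity
  within groups; with very short scans ($T \lesssim 30$) the z-values are
  noticeably non-normal and the permutation tests, not the parametric
  p-values, should carry the inference.
* The min(max(p)) table inherits the per-dataset two-sided p-values; it
  ranks edges but makes no per-edge error-rate claim — only the joint
  permutation p of the minimum is calibrated.
* Subject-level permutation assumes subjects are exchangeable under the
  null within a dataset; covariate-driven structure (age, sex, site within
  a dataset) is not modelled.
* `extract_roi_timecourses()` performs no motion estimation or voxel-level
  preprocessing; inputs are assumed registered to the atlas grid, and
  low-motion subsetting is a metadata flag supplied by the user.
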