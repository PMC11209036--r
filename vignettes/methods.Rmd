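---
title: "Methods: causal-forest feature selection for parcellated rs-fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal-forest feature selection for parcellated rs-fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Resting-state fMRI fluctuations in the 0.01–0.15 Hz band differ between
Parkinson's disease (PD) patients and healthy controls, but the raw data —
hundreds of regional BOLD time courses per scan — are far too
high-dimensional for direct case-control modeling. `fmriCF` implements a
complete analysis chain for atlas-parcellated ROI time series:

1. **Featurization**: 58 descriptors per region (11,600 over a 200-region
   Schaefer-style parcellation), in three families.
2. **Causal-forest ranking**: an honest causal forest whose
   split-frequency importance, stabilized over ten independently seeded
   runs, reduces the feature set by 96–99.9%.
3. **Wrapper refinement**: greedy forward subset selection tailoring the
   reduced pool to a specific classifier.
4. **Evaluation**: patient-grouped nested cross-validation of logistic
   and gradient-boosted classifiers.
5. **Association mapping**: correspondence analysis projecting
   sex-by-diagnosis (or sex-by-severity) groups and their top brain
   regions onto two dimensions.

A synthetic cohort generator with planted, severity-scaled regional
effects provides the ground truth against which every stage is validated.

# Feature extraction

Each region's series is z-scored before analysis, because scanner units
are arbitrary and acquisitions are heterogeneous; the intensity *mean*
and *variance* are computed on the raw series so they retain the
intensity scale, while the remaining descriptors are scale-free. The
families are:

* **Intensity (6)** — mean, population variance, skewness, excess
  kurtosis, average normalized autocorrelation over lags
  `1..min(20, N-2)`, and maximum wave height (crest-to-trough range). A
  constant series yields 0 for everything but the mean.
* **Frequency (42)** — the analyzed band 0.01–0.15 Hz is tiled by ten
  contiguous 0.014 Hz bands (`buildFilterBank()`). Per band: spectral
  energy (sum of one-sided squared DFT moduli over in-band bins),
  dominant frequency (maximal-power bin, ties to the lower frequency),
  variance of the band-limited signal, and its average autocorrelation.
  Two global descriptors complete the family: the dominant frequency over
  the whole band and the fraction of analyzed-range power in that bin.
* **Connectivity (10)** — per band, the Pearson correlation between the
  band-limited signal and a unit sinusoid at the band's center frequency,
  maximized over a 64-point phase grid spanning one period.

Numerical choices, fixed so that every descriptor is reproducible against
a direct-summation oracle: series are linearly detrended (closed form)
before the DFT; no window function is applied; band-limiting uses an
ideal rectangular DFT mask (zero out-of-band bins, inverse transform);
band membership is half-open `[low, high)` with the top band including
the upper edge; a band containing no DFT bin contributes zeros with a
warning; a zero-variance band signal has overlap 0.

Two consequences of these definitions are worth knowing. First, band
*energy* scales with the frame count, so cohorts with heterogeneous
acquisition lengths (175–265 frames here) see extra variance on that
descriptor; the band-signal *variance* descriptor is length-free. Second,
band-limited noise is itself sinusoid-like, so connectivity overlaps are
sizable (~0.4–0.7) even for pure noise; the descriptor is informative
through its modulation, not its absolute level.

# The causal forest

`fitCausalForest()` grows honest causal trees. Each tree draws a
subsample without replacement (fraction 0.5 by default), splits it into a
*structure* half and an *estimation* half (an even split by default), and
recursively chooses, among `mtry` randomly drawn features (default
`floor(sqrt(p))`), the split maximizing the treatment-effect
heterogeneity criterion

$$\frac{n_L\,n_R}{(n_L+n_R)^2}\,\bigl(\hat\tau_L-\hat\tau_R\bigr)^2,
\qquad \hat\tau = \bar Y_{T=1}-\bar Y_{T=0},$$

computed on the structure half, subject to a minimum of 5 treated and 5
control samples per child. Leaf effects are re-estimated on the held-out
estimation half (honesty); a leaf predicts only if that half contains the
per-arm minima, and `predictCate()` averages valid leaves across trees.
A constant outcome admits no positive criterion, so the forest degrades
to stumps and the importance ranking is uniform (with a warning).

**Feature importance** is the raw split frequency: the number of internal
splits on each feature across the forest, normalized to sum to one, with
ties broken by feature name. Depth weighting is deliberately not applied
— the quoted definition of the ranking is frequency-based.

**Treatment/outcome convention.** For case-control ranking the package's
*detection preset* uses treatment = diagnosis (PD = 1) and outcome =
severity score (0 for controls), so heterogeneity splits track features
that modulate the diagnosis–severity contrast; the *severity preset*
restricts to patients with treatment = (score above threshold). This is a
documented package choice — a case-control label admits several
causal-forest formulations, and the convention chosen here is the one
that makes every reported ranking well-posed.

**A structural caveat** discovered during validation and worth stating
plainly: with per-arm leaf minimums, *no* valid split exists on a feature
that (nearly) separates the treatment arms — both children would need
both arms. A causal forest therefore cannot rank the very strongest
diagnosis markers; it ranks features whose group difference is graded and
overlapping. Region-level aggregation absorbs this in practice because an
affected region carries several partially overlapping descriptors, but
single deterministic separators are invisible to the criterion. This is
inherent to honest effect-heterogeneity splitting, not an implementation
artifact.

# Stability selection and region scores

The forest is refit ten times with independently derived seeds
(`stabilitySelect()`). Each run marks its top 4% of features (the
complement of a 96% reduction; the sweep values 99.9, 99.5, 99, 98, 96
are all expressible via `stabilityConfig(reductionPercent = )`),
restricted to features the run actually split on — a feature with zero
splits is not "highly ranked" no matter how the alphabet orders ties.
Features marked in at least 4 of 10 runs are kept, ordered by mean
importance, capped at the top-cut size. `regionAverageRanking()` then
aggregates selected features by region (mean importance and count),
omitting regions with none — the data behind region bubble plots.

# Wrapper forward selection

`wfss()` starts from the empty set and greedily adds the candidate whose
addition maximizes patient-grouped cross-validated accuracy of the
configured classifier, stopping when no candidate improves strictly
(tolerance 0) or a size cap is reached. The fold assignment is drawn once
and reused across all candidate evaluations; the starting score is the
majority-class accuracy, making the acceptance trace non-decreasing by
construction. Plain sequential forward selection is used — no floating
steps. Note that pure greedy search cannot seed a perfectly balanced
two-feature interaction (neither feature moves the score alone); it
reliably completes interactions once any marginal signal seeds them.

# Classifiers and nested cross-validation

The logistic classifier maximizes the Bernoulli log-likelihood of
$P(y=1\mid x,\omega) = 1/(1+e^{-\omega^Tx})$ with a small ridge penalty
($\lambda = 10^{-4}$, intercept unpenalized) by Newton iterations with
step halving; the ridge guarantees a finite optimum under complete
separation. Features are z-scored with training-fold statistics only.
Gradient boosting is delegated to the xgboost backend (binary logistic
objective, single-threaded and seeded for determinism).

`nestedCv()` evaluates the full pipeline with ℓ outer folds (default 5)
and k inner folds (default 5; 3 in the smaller validation runs).
Fold assignment is at the participant level, stratified by class, so
**all sessions of one participant share a fold** — the leakage guard
asserts train/test participant disjointness on every split. Feature
selection (forest + wrapper) is refit inside each outer training fold;
sessions are scored as independent test items; metrics (accuracy, F1,
precision, recall) are averaged over outer folds.

# Correspondence analysis

`fitMca()` performs classical CA of the groups-by-regions count table
(cell = number of a region's stability-selected features in a group):
with correspondence matrix $P = N/n$, row/column masses $r, c$, the SVD
of $S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ yields principal inertias
$\sigma_i^2$, inertia shares, and principal coordinates
$D_r^{-1/2}U\Sigma$, $D_c^{-1/2}V\Sigma$. The two leading dimensions are
retained (rank-1 tables return one dimension with a warning); axis signs
are fixed by making each axis's largest-magnitude coordinate positive; no
Benzécri/Greenacre inertia correction is applied. CA of the small
aggregate table is used rather than observation-level MCA because the
published object of interest *is* the four-groups-by-regions table;
observation-level indicators are not recoverable from aggregates.
Severity groups split patients strictly above a motor-score threshold of
23.7 (UPDRS-III, approximately Hoehn–Yahr stage 2); a score exactly at
the threshold is "below".

Group attribution of features is sign-based: within each sex the
detection-preset forest is fit, and a stable feature goes to the patient
group if its mean is higher in patients, otherwise to the control group
(analogously above/below for the severity variant). A within-group-only
forest formulation cannot produce per-population rankings for a
case-control label; the sign split is the package's documented analogue.

# The synthetic cohort generator

`generateCohort()` emulates the study conditions the feature extractor
must tolerate: a four-cell cohort (sex × diagnosis), 175–265 frames at TR
2–2.4 s drawn uniformly per session, multi-session patients, and a
200-region default parcellation. Every draw comes from a per-entity RNG
substream derived from (root seed, participant id, session index), so
enlarging a cohort never reshuffles existing data.

The background process per region is Gaussian noise band-limited to
0.008–0.2 Hz plus one random-phase sinusoid at each filter-bank band
center (fixed amplitude 0.5 relative to unit-sd noise). This gives every
feature family non-degenerate, session-stable values: band energies are
phase-free, so a planted band-power change expresses consistently rather
than being drowned by random oscillator placement. The fluctuation
process rides on a per-region baseline (uniform 700–900) at 2–3%
amplitude, BOLD-like.

Patients receive two optional perturbations in the configured affected
regions, both scaled by severity relative to the severity median
(`sevScale = severity / 23.7`):

* an amplitude multiplier `1 + amplitudeEffect * sevScale` on the whole
  fluctuation (visible in the raw-variance descriptor);
* a band-power multiplier `1 + (factor - 1) * sevScale` applied by
  scaling the in-band DFT coefficients.

Severity is log-normal with median 23.7 — the UPDRS-III threshold — and
`sdlog = 0.6`, a wide, realistic motor-score spread. The width matters
twice: it populates both severity subgroups around the threshold, and it
makes planted effects *severity-graded with overlapping arms* — early
(low-severity) patients resemble controls, which is both clinically
realistic and, per the structural caveat above, the regime in which an
honest causal forest can rank the planted features at all.

What the generator does **not** emulate: volumetric images, head motion,
physiological noise regressors, spatial correlation between regions, and
site effects. Passing tests therefore demonstrate the correctness and
calibration of the algorithms on planted structure, not clinical
performance on real PD cohorts.

# Problem sizes used in validation

The packaged validation runs use desk-scale sizes chosen to make the
planted structure statistically recoverable: effect-modifier ranking at
n = 1000 samples × 50 features; region recovery and detection on cohorts
of 300 participants (75 per cell, one session, 6 regions, effects
amplitude 0.5 and band factor 2.5 in two regions — region recovery is
power-limited below roughly 200 participants under these effect sizes,
so the cohort is sized comparably to real case-control rs-fMRI studies
of this kind); null calibration on an
effect-free 100-session cohort with 20 label permutations. Region-level
ranking at these sizes uses 800 shallow trees (`maxDepth = 2`,
subsample 0.8): shallow trees concentrate split counts on root-level
heterogeneity, which stabilizes the frequency ranking when samples per
node are few; the package default (unlimited depth, 500 trees) suits
CATE estimation at larger n. All empirical numbers quoted anywhere in
the package documentation are computed by the test suite or by
`scripts/acceptance.R` at run time.

# Known limitations

* Split-frequency importance is a relative, forest-size-dependent score;
  it is reported normalized and should not be compared across cohorts.
* The detection preset's outcome (severity, zero for controls) makes the
  split criterion sensitive to heavy severity tails; the log-normal
  generator keeps these moderate, but real severity distributions with
  extreme outliers would warrant a transformed outcome.
* Greedy forward selection is order-dependent and offers no optimality
  guarantee; it is the spec'd search and is validated for interaction
  completion, not global subset optimality.
* No confidence intervals for CATE, no orthogonalization/DML
  residualization, no multi-class staging.
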