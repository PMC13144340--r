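---
title: "Inter-subject correlation analysis of framed naturalistic fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject correlation analysis of framed naturalistic fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscpipe)
```

# The model

## Inter-subject correlation

For participants $i$ and $j$ watching the same stimulus segment $s$, the ISC
map is the voxel-wise Pearson correlation of their time series over the
segment's volumes, Fisher transformed:

$$ z_{ij}^{(s)}(v) = \operatorname{atanh}\, r\!\left(y_i(v,\cdot),\, y_j(v,\cdot)\right). $$

The Fisher transform stabilizes the variance so maps can be averaged and
modelled linearly. Maps are computed for **all** unordered pairs — $n(n-1)/2$
per segment — then averaged within frame (or frame-by-topic) conditions.
Because the statistic is the correlation of two observed time courses, no
model of the hemodynamic response to a long, complex stimulus is needed;
that is the point of using ISC for naturalistic designs.

Two preprocessing steps precede the correlation. First, nuisance regression:
every voxel's series is replaced by its residual from a projection onto an
intercept, the six motion parameters, and (by default) linear and quadratic
detrending columns; Pearson correlation is mean-invariant, so the residual
centering is harmless, and the polynomial columns remove slow scanner drift
that would otherwise inflate all correlations. Second, segment extraction:
volumes are assigned to a segment when their acquisition onset falls in
$[\text{onset}, \text{onset}+\text{duration})$ (half-open, so no volume can
belong to two segments), and the first 8 volumes of each segment (12 s at
TR = 1.5 s) are dropped to skip the initial hemodynamic transient. The
exclusion is counted in volumes, not seconds, so it remains well-defined at
any TR. Segments that retain fewer than 10 volumes are rejected — a Pearson
correlation on fewer points is too unstable to analyse.

## Baseline correction

Even with no shared stimulus processing, two participants' series correlate
slightly: scanner artefacts, residual drift, shared physiological rhythms.
The correction estimates this floor from *unmatched* pairings — participant
$i$'s segment $A$ against participant $j$'s segment $B \ne A$, truncated to
the shorter length — Fisher-transforms each, averages them into one baseline
map per pair, and subtracts it from that pair's stimulus-specific maps. All
ordered unmatched combinations are used when there are at most 200 per pair,
otherwise a seeded uniform subsample of 200 (the combinatorial count grows
as $S(S-1)$ with $S$ segments, and the estimate has long stopped improving
by 200). The corrected maps are required by the dyadic regression stage;
condition contrasts may use them optionally, since the pair-mean regressors
in the contrast GLM already absorb pair-level offsets.

## Condition contrasts with block-restricted permutation

Condition-averaged pair maps are stacked into a samples-by-voxels response
(one sample per pair per condition) and fitted voxel-wise with OLS on
condition indicators plus one mean-effect regressor per pair. The pair
regressors absorb the repeated-measures dependence; with two conditions the
contrast t is algebraically the paired t-test (a property the test suite
asserts against `t.test`). Contrast t maps are enhanced with TFCE:

$$ \mathrm{TFCE}(v) = \sum_{h = dh,\, 2dh,\, \dots \le t(v)} e_h(v)^{E}\, h^{H}\, dh, $$

with $e_h(v)$ the voxel count of the connected component containing $v$ at
threshold $h$. Defaults are the method's standard settings, $E = 0.5$,
$H = 2$, 6-connectivity, and $dh = \max|t|/100$ per map; negative values are
enhanced on the negated map and re-signed. The summation is a compiled
routine because it sits inside the permutation loop.

The null distribution comes from relabeling the condition labels
**independently within each participant pair** — samples from different
pairs are never exchangeable, samples of one pair across conditions are.
FWE-corrected p-values use the max-TFCE statistic over the mask
(within-contrast) or over mask × contrasts (across-contrast):

$$ p_{\mathrm{FWE}}(v) = \frac{1 + \#\{\text{perm max} \ge \mathrm{TFCE}_{\mathrm{obs}}(v)\}}{n_{\mathrm{perm}} + 1}, $$

where the unpermuted labeling contributes the "+1" as permutation 1, so the
smallest attainable p is $1/(n_{\mathrm{perm}}+1)$. When fewer distinct
within-block relabelings than `n_perm` exist (e.g. $2^B$ for two conditions
and $B$ pairs), all of them are enumerated — with a warning — and the test is
exact.

## Generalized Pareto tail refinement

With 1 000 permutations the smallest reportable p is about $10^{-3}$.
`gpd_tail_pvalue()` refines p-values below the activation gate $p < .10$ by
fitting a generalized Pareto distribution (maximum likelihood) to the null
exceedances above the 90th percentile; the refined p is the tail mass times
the GPD survival at the observed statistic. The fit must pass an
Anderson–Darling screen implemented by parametric bootstrap (self-contained
and exact up to Monte-Carlo error, rather than a transcribed critical-value
table); if the fit fails at the 90th percentile the threshold is raised
(92.5th, 95th) and the fit retried — the standard remedy in the tail
approximation literature — before falling back to the empirical p.
Degenerate nulls (all values equal) always fall back, with a warning.

## Dyadic proximity regression

The proximity regressor for covariate $x$ is $-|x_i - x_j|$ per pair: zero
for identical scores, increasingly negative for dissimilar pairs, so a
*positive* coefficient on baseline-corrected ISC means similar pairs are
more synchronized. Covariates are z-scored across participants before the
distance is taken, making 21-point attitude scales and composite scores
comparable; the proximity columns themselves are left unscaled to keep their
sign and zero interpretable. Each regressor is tested with the other design
columns as nuisance covariates via Freedman–Lane residualization (response
and tested regressor both residualized against the nuisance columns; the
resulting t with the full-model degrees of freedom equals the full-model t).

Permutation for dyadic data needs care: the 45 pairs of 10 participants are
not independent — pairs sharing a participant are correlated. Shuffling pair
rows directly ignores this. The default scheme is therefore
**subject-level**: the tested covariate's participant scores are permuted
and all pairwise proximities rebuilt, which preserves the dyadic dependence
structure under the null; direct pair-level shuffling remains available
behind `scheme = "pair"` for sensitivity analysis. The test suite verifies
the calibration empirically (the family-wise false-positive rate of the
subject-level scheme on null cohorts stays near the nominal 5%).
Between-condition differences in the proximity effect (`condition_moderation()`)
regress the per-pair difference map on the same design, so the coefficient is
exactly the between-condition coefficient difference and the machinery is
unchanged.

## Behavioral stage

`composite_scores()` averages item sets into negative-affect, positive-affect,
fear and anger composites; the item mapping is configuration, not code,
because subscale composition is instrument-specific. `fit_framing_model()`
is OLS of an outcome on frame (neutral reference) plus covariates; the
within-subject variant absorbs a participant fixed effect, the
dependency-light equivalent of participant demeaning, which the tests verify
against an explicit demeaned-OLS oracle. `interaction_model()` enforces
marginality: a three-way interaction cannot be requested without its two-way
margins and main effects.

# The synthetic cohort generator

`simulate_cohort()` emulates a within-subject framed-video design at desk
scale: every participant sees `n_stimuli` clips once per frame condition
(default 12 × 3, mirroring the 36-clip design the package targets; default
N = 27, TR 1.5 s, 8×8×8 grid with an ellipsoidal "brain" mask). During the
segment for stimulus $k$ under frame $f$, signal voxels of participant $i$
carry

$$ \kappa_f \left( \cos\theta_i \, s^A(t) + \sin\theta_i \, s^B(t) \right), $$

where $s^A, s^B$ are latent time courses shared across participants —
smoothed white noise (moving average, width 5 volumes, band-limited like
hemodynamics), standardized and exactly orthonormalized per segment — and
the first `transient_s` seconds of every segment (default 12 s, the window
the preprocessing stage excludes) carry no stimulus-locked signal, emulating
the unsettled hemodynamic response at stimulus onset. Standardizing the
latents on the post-transient window also matters statistically: if the
shared streams were normalized over one window but correlated over another,
their sample variance on the analysis window would fluctuate segment by
segment *identically for every pair*, inducing cross-pair correlation that a
within-pair permutation scheme cannot represent and inflating the test —
with matched windows the latent sample variance is exactly one and the
calibration Monte-Carlo confirms nominal error rates. Furthermore,
$\theta_i$ maps the participant's coupling covariate affinely onto
$[0, \gamma\pi/2]$. Consequences, and the reasons for these choices:

* pairwise signal covariance is exactly $\kappa_f^2 \cos(\theta_i-\theta_j)$,
  so the expected signal-voxel ISC has the closed form
  $\kappa_f^2 \cos(\theta_i-\theta_j) / (\kappa_f^2 + \sigma^2)$
  (`expected_pair_isc()`), an analytic oracle for the whole pipeline;
* $\gamma = 0$ makes synchrony independent of the covariate (the null for the
  proximity regression), $\gamma > 0$ makes it decay monotonically with
  covariate distance;
* each stimulus × frame combination gets its *own* latent pair. Clips in
  different frames are different recordings in the target design, and the
  unmatched-segment baseline relies on different segments carrying
  independent stimulus-locked signal — shared streams across frames would
  contaminate it.

Noise is AR(1) with marginal standard deviation fixed at $\sigma$ regardless
of the autocorrelation $\phi$ (innovation variance $\sigma^2(1-\phi^2)$), so
the closed form above stays valid for any $\phi$. Each participant also
receives a random quadratic drift (standard deviation `drift_amplitude`,
global across voxels) and a linear leak of their six simulated motion
regressors (`motion_amplitude`), giving `regress_out_nuisance()` something
real to remove: both confounds lie exactly in the span of the default
nuisance design (motion columns plus quadratic detrend), so preprocessing
restores the analytic model. The default amplitudes (0.3 and 0.5 in units of
the noise SD) are moderate relative to realistic fMRI confound magnitudes.

Default coupling amplitudes are κ = 0.8 / 0.6 / 0.4 for neutral / threat /
blame — monotonically decreasing synchrony with emotional framing, the
structure the contrast stage is designed to detect — with σ = 1, φ = 0.3,
γ = 0.5, and 10% of mask voxels carrying signal. The stimulus schedule is
one shared events table (sequential segments, 4.5 s gaps, 12 s initial
rest); clip order in the target design is counterbalanced per participant,
but segment-wise ISC is order-invariant, so a shared schedule loses nothing
while keeping one events file. The inter-stimulus gap is exposed as a
parameter rather than fixed, since scanner-side inter-trial intervals are
design-specific.

What the generator does **not** emulate: hemodynamic response convolution
(latent streams are band-limited but not HRF-convolved), spatial
autocorrelation of noise, realistic anatomy (signal voxels are a random
scatter within the ellipsoid), physiological rhythms, or per-participant
stimulus timing. Passing tests therefore demonstrate the statistical
machinery — estimator consistency, calibration, FWE control, power at known
SNR — not robustness to the full complexity of real BOLD data.

`simulate_survey()` is the behavioral counterpart: one clip per respondent
(25/50/25% neutral/threat/blame, as in a threat-weighted between-subject
design), twelve 0–20 emotion items with a latent negativity trait, injected
additive frame effects on named composites, and a sharing count. Because the
anger and fear items are subsets of the negative items, an injected
negative-affect effect propagates into those composites; the generator
records the *implied* composite-level coefficients in `attr(, "truth")` so
recovery is tested against the right numbers.

# Numerical choices

* **Fisher clamp.** $|r|$ is clamped to $1 - 10^{-7}$ before `atanh`, so a
  perfect correlation maps to ≈ 8.41 rather than infinity; values below
  $1 - 10^{-6}$ are shifted by less than $5\times10^{-8}$.
* **Zero-variance voxels** get $r = 0$ and a logged count instead of NaN,
  keeping map algebra total.
* **Degenerate fits.** Zero-residual GLM contrasts are capped at
  $|t| \le 10^6$ (totality without affecting ranks); a voxel whose
  residualized response is numerically zero (e.g. a constant map) reports
  $t = 0$ rather than 0/0 rounding noise.
* **TFCE step.** $dh = \max|t|/100$ per map bounds the discretization error
  of the threshold sum at about 1%; the closed-form tests run at
  $dh = v/1000$ where the error is ≈ 0.15%.
* **Unequal segment lengths** are handled by correlating at native length
  and truncating unmatched baseline pairs to the shorter segment — no
  interpolation.
* **Determinism.** Every stochastic routine takes a seed; identical
  configurations give bit-identical cohorts, permutation results and
  pipeline reports. The pipeline derives per-stage sub-seeds from one global
  seed. Datasets round-trip exactly: NIfTI runs are written as doubles and
  table numerics at 17 significant digits.

# Validation scales

The test suite validates the statistical properties at deliberately small
problem sizes chosen so the whole suite runs on one CPU in minutes while the
Monte-Carlo error stays far below the tolerances being asserted: 6×6×6
grids (136 mask voxels), 4–10 participants, 250 permutations per test, 200
null datasets for type-I calibration (the 95% binomial band around a nominal
5% is then 2–9%), 50 runs for power, and ≥ 100 segments for the analytic
ISC recovery. `scripts/acceptance.R` recomputes the same quantities from
scratch at comparable sizes.

# Known limitations

* **Dyadic dependence in condition contrasts.** The pair-blocked permutation
  test is exact when samples from different pairs are independent — the
  regime the type-I calibration Monte-Carlo verifies (no stimulus-locked
  signal, where the family-wise error rate is nominal). When all
  participants carry a *shared* stimulus-locked signal of equal strength in
  every condition, the pair maps of different pairs co-fluctuate through
  participant-level signal-noise cross terms, a dependence that independent
  within-pair relabeling cannot represent; in that regime the family-wise
  error at signal voxels is inflated (measurably so for coupling amplitudes
  κ ≳ 0.3 at desk scale). This is a property of the pair-blocked
  exchangeability scheme itself — the standard construction for
  repeated-measures ISC designs — not of its implementation here; the
  pair-mean regressors absorb pair-level offsets but not
  participant-by-condition fluctuations. Contrast conclusions should
  therefore rest on the max-statistic FWE over the whole mask (which is
  dominated by the far more numerous independent non-signal voxels) and, for
  dyadic covariate questions, on the subject-level permutation scheme of the
  proximity stage, which does respect this dependence.
* TFCE trades voxel-level localization for cluster-level sensitivity: a
  non-signal voxel adjacent to a strong true cluster inherits enhancement up
  to its own height and is occasionally flagged. In the localization
  Monte-Carlo this spillover affects a minority of runs and every such voxel
  touches a true signal voxel; interpretation of TFCE maps should be at
  cluster, not voxel, resolution.
* Permutation p-values for dyadic regressors rely on subject-level
  relabeling; with very few participants (< 8) the number of distinct
  relabelings limits resolution.
* The within-subject behavioral model uses participant fixed effects, not a
  random-intercept mixed model; a mixed-model backend can be swapped in
  where shrinkage across participants matters.
* The univariate GLM t is the only statistic offered for condition
  contrasts; multivariate statistics are out of scope.
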