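# iscpipe

Inter-subject correlation (ISC) analysis for naturalistic fMRI experiments
with framed stimuli, with permutation inference and a fully synthetic
validation cohort.

## The problem

When different people watch the same video clip, stimulus-driven brain
regions produce similar hemodynamic time courses across viewers. ISC
quantifies this: for every pair of participants and every stimulus segment,
the voxel-wise Pearson correlation of their BOLD time series, Fisher
r-to-z transformed,

&nbsp;&nbsp;&nbsp;&nbsp;z<sub>ij</sub>(v) = atanh( corr( y<sub>i</sub>(v, t), y<sub>j</sub>(v, t) ) ).

High z means a voxel tracks the shared stimulus the same way in both brains.
Experiments that manipulate the *framing* of otherwise identical content
(neutral wording vs. threat or blame rhetoric) can then ask two questions
this package is built to answer:

1. **Condition contrasts** — is neural synchrony lower when content is
   framed emotionally? Per-pair condition-averaged z-maps are compared with a
   voxel-wise GLM (t contrasts with per-pair mean regressors for the repeated
   measures), inference by permutation restricted to exchangeability blocks —
   condition labels may only be shuffled *within* a participant pair — with
   threshold-free cluster enhancement (TFCE) and family-wise error (FWE)
   control via the max-statistic null, within and across contrasts, plus
   generalized Pareto tail refinement of small permutation p-values.
2. **Dyadic proximity regression** — do politically similar pairs stay more
   synchronized than dissimilar pairs? Pair-level z-maps (after subtracting a
   baseline built from *unmatched* segment pairings, which removes
   stimulus-nonspecific correlation such as scanner noise and shared drift)
   are regressed on proximity regressors, −|x<sub>i</sub> − x<sub>j</sub>|,
   the negative distance between the pair's covariate scores. Permutation
   inference is subject-level: covariate scores are permuted across
   participants and the dyadic design rebuilt, respecting the dependence of
   pairs that share a participant.

Because raw study data are rarely redistributable, the package ships a
synthetic BOLD cohort generator (`simulate_cohort()`) with known ground
truth: stimulus-locked shared signals whose coupling κ depends on the frame
condition and whose pairwise correlation decays with covariate distance,
plus AR(1) noise, polynomial drift, and motion confounds that genuinely leak
into the data. Under this model the expected signal-voxel ISC has the closed
form κ²·cos(θ<sub>i</sub> − θ<sub>j</sub>) / (κ² + σ²), which anchors the
test suite. A light behavioral stage (`simulate_survey()`,
`fit_framing_model()`) covers composite emotion scoring and the framing-
effect linear models that accompany such designs.

## Worked example

```r
library(iscpipe)

cfg <- sim_config(n_participants = 6, grid_dims = c(6, 6, 6), n_stimuli = 4,
                  segment_duration_s = 60,
                  kappa_by_frame = c(neutral = 0.9, threat = 0.6, blame = 0.4),
                  gamma_proximity = 0.5, seed = 42)
cohort <- simulate_cohort(cfg)
pre    <- preprocess_cohort(cohort)     # motion + drift regression, segments
pm     <- average_by_condition(all_pair_maps(pre$series_by_participant,
                                             pre$segments, pre$voxel_ids))
res <- permute_and_correct(condition_samples(pm), cohort$mask,
                           list("neutral>blame"  = c(neutral = 1, blame = -1),
                                "neutral>threat" = c(neutral = 1, threat = -1)),
                           n_perm = 500, seed = 1)
res
```

```
Permutation test: 2 contrasts, 500 permutations, seed 1
Permutation result 'neutral>blame': 136 voxels, 500 permutations
  max |t| 14.18, max TFCE 1.15e+03, min FWE p 0.001996, 15 voxels with p <= 0.05
Permutation result 'neutral>threat': 136 voxels, 500 permutations
  max |t| 9.07, max TFCE 257, min FWE p 0.001996, 13 voxels with p <= 0.05
```

The generator placed 14 signal voxels with stronger coupling for neutral
(κ = 0.9) than blame (κ = 0.4) framing; the neutral>blame contrast flags 15
voxels at FWE p ≤ .05 — all 14 true signal voxels plus one neighbour picked
up by TFCE's cluster enhancement (cluster-level, not voxel-level,
localization). The minimum attainable p with 500 permutations is
1/501 ≈ 0.002.

`run_pipeline()` drives the same stages (plus baseline correction, proximity
regression, and the behavioral models) end to end from one YAML/JSON config
with a JSON report, and `inst/cli/iscpipe.R` is a thin command-line wrapper
around it.

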