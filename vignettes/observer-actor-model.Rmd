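---
title: "An observer-actor model of reach compensation under skewed visuomotor noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An observer-actor model of reach compensation under skewed visuomotor noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachloss)
```

## The problem

During repeated reaching, the mapping between hand and visual feedback can be
perturbed by noise. When that noise is *skewed*, different objectives
prescribe different places to aim: minimizing squared error tracks the
*mean* of the perturbation distribution, minimizing absolute error tracks
the *median*, and maximizing the probability of hitting the target tracks
the *mode*. A skewed perturbation distribution therefore dissociates
error-based (model-based) learning from reinforcement-based (model-free)
learning purely by where people end up aiming.

`reachloss` implements the complete computational pipeline for this design:
the skewed lateral-shift distributions and trial schedules, the Bayesian
observer that integrates a learned prior with cue-dependent visual evidence,
the actor policies that turn a posterior (or a predicted cursor density)
into an aim point, the four-parameter model fit that recovers a
participant's loss exponent and sensory uncertainties, descriptive trial-log
analyses, and the resampling statistics used for group comparisons. A
synthetic-participant generator supplies trial logs with the statistical
structure the analyses assume, so every stage runs and is testable without
any behavioral data.

## The shift distributions

Two designs are built in. The 2000-trial cue-uncertainty design draws a
lateral shift each trial, with replacement, from seven equally spaced values
at 5 mm intervals; the modal shift sits at one end of the range with
relative frequency 9/21 (about 42.9%) and the six others carry 2/21 each.
The right-skew variant spans 0-30 mm (mean 10, median 5, mode 0 mm); the
left-skew variant is its mirror image about 10 mm. The probabilities are
stored as exact rationals, treating the printed percentages (42.8% / 9.5%)
as rounded, so the printed moments are reproduced exactly. The 5 mm spacing
is the unique equally-spaced seven-point reconstruction consistent with the
printed range, moments and frequencies; the tests validate the
reconstruction against those moments rather than hard-coding them.

The 500-trial target-feedback design uses three shifts at -14, 0 and +14 mm
(the spacing equals the 14 mm target diameter), presented exactly 300 / 100
/ 100 times in a seeded random order ("sampled until depletion"), so every
schedule is a permutation of a fixed multiset. Right skew puts the mode at
-14 mm (mean -5.6 mm).

```{r}
distribution_stats(make_exp1_prior("right"))[1:3]
distribution_stats(make_exp2_prior("right"))[1:3]
```

## The observer: posterior over shifts

On cue-uncertainty trials the observer senses the (shifted) cursor centroid
with Gaussian uncertainty whose SD depends on the cue: a single dot
(`sigma_sensed` small), a 15 mm or 30 mm dot cloud (larger), or withheld
feedback (infinite). The posterior over shifts is the point-wise product of
the discrete prior and this likelihood, renormalized. Two limits matter and
are handled explicitly: an infinite SD returns the prior unchanged, and a
zero SD puts all mass on the support atom nearest the sensed value.

The posterior is kept on the prior's discrete atoms by default, because the
experimental priors are discrete. A kernel-smoothed variant
(`method = "smoothed"`, Gaussian kernel, default bandwidth 2 mm) is also
provided for illustrating sensed values that fall off the support (e.g.
22.5 mm); the two representations give closely matching posterior means, and
all quantitative results in the package use the discrete form.

## The actor: loss functions and optimal aims

The power loss `|shift - x|^alpha` is averaged over the posterior and the
compensation is the *negated* minimizer (the movement counteracts the
estimated shift). `alpha = 2` yields minus the posterior mean, `alpha = 1`
minus the weighted median, and `alpha -> 0` approaches minus the mode.
Minimization is a dense scan over the support range (step 0.005 mm, atoms
always included as candidates) with bounded scalar refinement for smooth
losses (`alpha > 1`). For `alpha <= 1` the expected loss is kinked at the
atoms, where its minimizers sit, so the scan result is kept as-is; plateau
ties (possible at `alpha <= 1`) resolve to the minimizer nearest the
posterior mean and are flagged.

```{r}
post <- posterior(make_exp1_prior("right"), x_sensed = 0, sigma_sensed = Inf)
optimal_compensation(post, alpha = 2)$aim_mm  # minus the prior mean
optimal_compensation(post, alpha = 1)$aim_mm  # minus the prior median
```

For the target-feedback design the relevant object is the predicted cursor
density: the convolution of the Gaussian hand density (SD `sigma_mv`, the
participant's movement variability) with the discrete shift distribution --
a Gaussian mixture evaluated on a uniform grid (default -80 to 80 mm at
0.02 mm, covering the built-in shifts plus 5 SD of the largest noise level
considered; the density constructor raises an error if 0.1% or more of the
mass falls outside the grid, and wider grids can be passed for wider
problems). Two optimal aims follow:

* **Mean-seeking** (`aim_min_sq_error`): minimizes expected squared cursor
  error about the target. Closed form `-(mean(d) - target)`, independent of
  movement variability. For the right-skew three-point distribution this is
  +5.6 mm. (The figure caption of the source design prints 5.4 mm; the
  stated computation -- the negated mean of the cursor density, whose
  distribution mean is -5.6 mm -- gives 5.6 mm, and this package follows the
  computation. The 0.2 mm gap is documented, not reproduced.)
* **Mode-seeking**: two readings are implemented, because the published aim
  values fall between them and the exact computation behind those numbers is
  not stated. `aim_max_hits_mode` aligns the argmax of the cursor density
  with the target (the verbatim 0-1-loss reading; mode located by grid
  argmax with parabolic refinement, plateau ties resolved to the centre of
  the leftmost plateau run). `aim_max_hits_width` maximizes the closed-form
  probability of landing within the finite 14 mm target. At the three group
  movement variabilities (10.6, 9.2, 8.8 mm) the finite-width reading gives
  10.79 / 11.56 / 11.76 mm and the mode reading 11.29 / 12.11 / 12.33 mm;
  both preserve the ordering (lower variability, larger compensation) and
  both exceed the mean-seeking 5.6 mm, which is the dissociation the design
  tests.

```{r}
d <- make_exp2_prior("right")
c(sq = aim_min_sq_error(d, 10.6)$aim_mm,
  mode = aim_max_hits_mode(d, 10.6)$aim_mm,
  width = aim_max_hits_width(d, 10.6)$aim_mm)
```

## The four-parameter fit

A participant's 2000-trial log is condition-averaged over its last 1000
trials into a 7 x 4 table of mean compensation per (shift, cue) cell; the
fit then minimizes the weighted least absolute error between these 28 cell
means and the model-optimal compensation surface over `alpha` and the three
sensory SDs, with the withheld-feedback SD fixed at infinity. Weights give
each cue condition equal total influence while weighting shifts within a
cue by their prior frequency -- the stated reading of "equally weight the
conditions with proportional emphasis by frequency". The withheld column's
prediction depends only on `alpha`, which anchors the exponent.

Numerics: parameters are log-transformed for positivity; Nelder-Mead runs
from eight start points (`alpha` in 1, 1.5, 2, 2.5 crossed with two sigma
scalings); inside the objective, all 28 cell optima are obtained in one
vectorized sweep (0.02 mm scan plus clamped parabolic refinement). A cyclic
coordinate-descent polish (three sweeps of bounded 1-D refinement per
log-parameter) follows the best start: when a sensory SD is small relative
to the 5 mm atom spacing the posterior is nearly a delta and the objective
is nearly flat in that parameter, which plain simplex steps resolve poorly;
because the objective is deterministic, the 1-D polish recovers such
parameters precisely. On noiseless synthetic tables the fit returns the
generating parameters to within 0.1%, and on noisy simulants (2 mm motor
noise) cohort-mean exponents recover to within 0.1.

## The synthetic participants

A simulated participant is the observer-actor above plus Gaussian execution
noise on the final hand position; the cursor is the hand position plus the
scheduled shift, exactly, and a trial is rewarded when the cursor lands
within 7 mm of the target centre (half the 14 mm target diameter; groups
whose name contains `Reinf` carry the reward flag). The sensed centroid
equals the true shift by default, matching the model's assumption; optional
Gaussian sensing noise is available for robustness studies. Defaults mirror
the study conditions: 2000 trials with cue odds 3:1:1:1 and groups of 10
(cue-uncertainty design); 500 trials, groups of 30 split equally between
skews, group movement variabilities 10.6 / 9.2 / 8.8 mm (target-feedback
design).

The 500-trial design's learning dynamics are not specified by the source
analyses, which use only the asymptotic window; the simulator optionally
approaches the asymptotic aim along a single exponential (time constant 25
trials, so the asymptote is reached well before trial 100) purely so binned
series have a realistic acquisition phase. Simulated trial logs are i.i.d.
given the aim: they contain no trial-by-trial learning, no online
within-reach corrections, no drifts or outliers. Passing tests therefore
demonstrate that the pipeline's estimators and tests behave correctly under
the model's own assumptions, not that real reaching data satisfy them.

## Descriptive analyses and statistics

Binned series use a 3-trial head bin (bin 0) followed by consecutive
10-trial bins; note bin 0 *overlaps* bin 1, mirroring the figure convention
of plotting immediate post-perturbation behavior alongside the full series.
Asymptote means and movement variability use the last 400 of 500 trials;
variability is the sample SD (n-1), a choice the source leaves unstated.
Left-skew data are pooled with right-skew data by reflecting about the
alignment point of the two distributions (10 mm in the cue-uncertainty
design, 0 mm in the target-feedback design).

Group comparisons use nonparametric bootstrap tests on means (default 1e6
resamples), Holm-Bonferroni adjustment, percentile CIs, and the
common-language effect size (pairwise win percentage, ties counted half).
The null construction for the bootstrap is not uniquely determined by
"make no parameter assumptions": the default recenters each sample on the
null (pooled mean for two samples) and scales the recentred residuals by
sqrt(n/(n-1)) so the bootstrap variance of the mean is unbiased -- without
that scaling the test rejects true nulls at about 0.073 instead of 0.05 at
n = 20. A label-permutation null is provided as an alternative. At the
study's per-group size (n = 30) the default test's measured type-I error is
about 0.06 at a nominal 0.05.

## Reproducing the pipeline end to end

`run_pipeline()` chains simulate, analyze and fit (cue-uncertainty design)
or simulate, analyze, aims and group statistics (target-feedback design),
writing trial logs, per-participant results and a manifest (config hash,
master seed, per-participant seeds) from which a run is exactly
reproducible. The package's own acceptance checks simulate cohorts at the
study sizes (30 fits of 2000-trial logs; 90 simulants of 500 trials) and
verify the qualitative dissociation: mode-seeking simulants compensate
significantly further than mean-seeking ones, while error-only and
error-plus-reinforcement simulants -- both mean-seeking, per the study's
conclusion -- are statistically indistinguishable.

## Known limitations

* Only Gaussian likelihoods and power / 0-1 losses are implemented (no
  inverted-Gaussian loss family), and only 1-D lateral behavior is modeled.
* The fit assumes the 28-cell design; sparser designs raise errors rather
  than fitting partial tables.
* The mean-based bootstrap remains mildly anticonservative below n of about
  20 even with the variance correction; for very small groups the
  permutation variant is preferable.
* Simulated learning curves are a convenience, not a model of trial-by-trial
  adaptation; learning-rate inference is out of scope.
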