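# reachloss

Loss-function dissociation in sensorimotor reaching: a Bayesian
observer–actor pipeline for reach compensation under skewed visuomotor
noise.

## The scientific problem

In a reaching task, visual feedback of the hand (a cursor) can be laterally
shifted on every trial by an amount drawn from a **skewed** discrete
distribution. Because the distribution is skewed, its mean, median and mode
are separated — and so are the optimal aim points of different loss
functions:

- minimizing expected squared error, `|error|²`, aims at minus the **mean**
  of the shifts (error-based, model-based learning);
- minimizing absolute error, `|error|¹`, aims at minus the **median**;
- minimizing the 0–1 loss (maximizing target hits) aims so the **mode** of
  the predicted cursor distribution lands on the target (reinforcement-based,
  model-free learning).

Where a participant asymptotically aims therefore reveals which loss
function their sensorimotor system is minimizing. This package implements
the full computational analysis for that design, for researchers in
sensorimotor learning:

- **Observer** (Bayesian integration): posterior over shifts from a discrete
  prior `p(x_shift)` and a Gaussian likelihood
  `p(x_sensed | x_shift, σ_sensed)` with cue-dependent uncertainty (single
  dot, 15 mm cloud, 30 mm cloud, withheld = ∞).
- **Actor** (expected-loss minimization): compensation
  `comp = −argmin_x E[|x_shift − x|^α]` under the posterior; and, for the
  target-feedback design, the cursor density
  `p(x_cursor | x_aim, σ_mv) = Normal(x_aim, σ_mv) * p(x_shift)`
  (convolution) with mean-seeking `x_aim^min(err²)` and mode-seeking
  `x_aim^max(hits)` optima.
- **Model fit**: the four parameters `(α, σ_sensed(1..3))` recovered per
  participant by weighted least-absolute-error Nelder–Mead over 28
  condition-averaged cells.
- **Synthetic cohorts, descriptive analyses and bootstrap statistics**, so
  the whole pipeline runs with no external data.

## Worked example

```r
library(reachloss)

pri <- make_exp1_prior("right")
pri
#> Lateral-shift distribution 'exp1_SR' (skew: right)
#>  shift_mm     prob
#>         0 0.428571
#>         5 0.095238
#>        ...
#> mean = 10 mm, median = 5 mm, mode = 0 mm

# A 22.5 mm shift sensed through the 15 mm cloud: prior pulls the estimate
post <- posterior(pri, x_sensed = 22.5, sigma_sensed = 15)
optimal_compensation(post, alpha = 2)
#> Optimal aim: -14.613 mm  [criterion: min_power_error, alpha = 2, ...]

# With feedback withheld the posterior is the prior itself:
post_inf <- posterior(pri, x_sensed = 0, sigma_sensed = Inf)
optimal_compensation(post_inf, alpha = 2)$aim_mm  # -10 (minus the mean)
optimal_compensation(post_inf, alpha = 1)$aim_mm  # -5  (minus the median)

# Target-feedback design: mean-seeking vs mode-seeking aims dissociate
d <- make_exp2_prior("right")   # shifts -14/0/+14 mm at 60/20/20%
aim_min_sq_error(d, sigma_mv = 10.6)
#> Optimal aim: 5.600 mm  [criterion: min_power_error, alpha = 2, ...]
aim_max_hits_width(d, sigma_mv = 10.6)
#> Optimal aim: 10.793 mm  [criterion: max_hits_width, target width = 14 mm,
#>  objective 0.35496]

# Simulate a squared-error participant and recover their loss exponent
p <- sim_participant("demo", "Error_SR", alpha = 2, motor_sd = 2, seed = 42)
rec <- simulate_exp1_participant(p, pri)   # 2000 trials
fit_bayes_model(condition_averages(rec), pri)
#> Observer fit: alpha = 2.028; sigma (dot, cloud15, cloud30) =
#>   (1.62, 14.16, 26.03) mm
#> weighted |error| objective = 1.0556 (8 starts, converged: TRUE)
```

The fitted exponent near 2 says the simulated participant minimized
approximately squared error; a mode-seeking (reinforcement-driven)
participant would fit with a much lower exponent and a larger asymptotic
compensation (10.8 mm rather than 5.6 mm in the target-feedback design).

`run_pipeline(default_exp2_config(), out_dir)` chains
simulate → analyze → aims → group statistics and writes trial logs, a
per-participant summary, per-group optimal aims, Holm-adjusted bootstrap
comparisons and a manifest from which the run is exactly reproducible.

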