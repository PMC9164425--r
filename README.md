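# bayesmr

Random-effect Bayesian Mendelian randomization for two heterogeneous
studies, one of which has the exposures completely missing, with a
divide-and-combine scheme for large samples.

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data.  Two practical complications motivate this package:

* the instrument–exposure and instrument–outcome associations often come
  from **two different studies** that are not homogeneous — locations of
  the modelled variables shift between populations and protocols; and
* one of the studies frequently records **no exposure data at all**
  (genotypes and outcomes only), so conventional two-sample analysis
  discards its outcome information or the other study's.

`bayesmr` fits a linear structural-equation model for two exposures
(X₁, X₂) and two outcomes (Y₁, Y₂) instrumented by three blocks of
independent dosages — Z₁ (L variants, X₁ only), Z₂ (K variants, X₂ only)
and Z₃ (M variants, shared) — with a latent scalar confounder
U ~ N(0, 1).  For Study A (fully observed):

    X₁ | Z,U ~ N(α₁'Z₁ + α₃₁'Z₃ + δ_X₁ U,  σ²_X₁A)
    X₂ | Z,U ~ N(α₂'Z₂ + α₃₂'Z₃ + δ_X₂ U,  σ²_X₂A)
    Y₁ | X₁,U ~ N(β₁X₁ + δ_Y₁ U,  σ²_Y₁A)
    Y₂ | X₂,U ~ N(β₂X₂ + δ_Y₂ U,  σ²_Y₂A)

Study B (exposures missing) adds a random-effect intercept V to each
equation and has its own residual scales.  The causal estimands are β₁
and β₂.  Priors: α ~ N(0, 0.3²) per component, β ~ N(0, 10²),
σ ~ Inv-Gamma(3, 2) on each residual *standard deviation*, V ~ N(0, 1),
δ ~ N(0, 1).

Inference is by a data-augmentation Gibbs sampler (RcppArmadillo): every
sweep imputes Study B's missing exposures from their conditional normals
and updates all parameters and latent confounders from their full
conditionals, so imputation and estimation happen simultaneously in one
Markov chain.  Convergence is monitored by split-chain R̂.  A two-sample
inverse-variance weighted (IVW) estimator is included as the
conventional comparator, and `partition_combined()` /
`aggregate_fits()` implement the recentred subset-posterior
divide-and-combine scheme (with 2-D Gaussian KDE of the joint
(β₁, β₂) posterior) for samples too large for a single MCMC run.
The methods vignette (`vignettes/bayesian-mr-heterogeneity.Rmd`)
documents the model, the sampler's group moves, and every numerical
choice.

## Worked example

Simulate one combined dataset under the package's standard evaluation
conditions (n = 400, 50% missing exposures, instrument strength 0.3,
true β₁ = β₂ = 0.3), fit the Bayesian model, and compare with IVW:

```r
library(bayesmr)
cfg <- sim_config(n_total = 400, missing_rate = 0.5,
                  alpha_level = 0.3, beta_level = 0.3, seed = 1)
d <- simulate_combined(cfg, replicate = 1)
fit <- bmr(d, settings = mcmc_settings(seed = 1))
fit
#> Random-effect Bayesian Mendelian randomization fit
#>   data: nA = 200, nB = 200 (missing rate 50.0%)
#>   sampler: 4 chains, 1000 warmup + 2000 kept iterations
#>
#> Causal effects (posterior):
#>        mean     sd median  lower  upper   rhat
#> beta1 0.295 0.0053 0.2950 0.2846 0.3054 1.0061
#> beta2 0.294 0.0055 0.2941 0.2832 0.3047 1.0053
#>
#> Max split-Rhat over structural parameters: 1.0066

ivw(d, pair = 1)
#> Two-sample IVW estimate (20 instruments)
#>   beta_hat = 0.2408 (se 0.1190), 95% CI [0.0076, 0.4740]
```

Both causal effects are recovered: the Bayesian posterior concentrates
tightly around the true 0.3 (posterior sd ≈ 0.005, all R̂ < 1.01), while
IVW — which uses only Study A for stage 1 and Study B for stage 2 — is
attenuated toward zero (0.24) with a ~20× wider interval, the expected
weak-instrument behaviour at this sample size.  `summary(fit)` tabulates
every structural parameter; `plot(fit)` draws the joint (β₁, β₂)
posterior density; `coef()`, `confint()` and `as.matrix()` expose point
estimates, equal-tailed intervals and raw draws.

Replicate experiments over the full configuration grid (missing rate ×
instrument strength × effect size, four metrics per cell) run through
`run_small_study()`; the large-sample divide-and-combine experiment
(full-data fit vs J subset fits, aggregated by recentring) through
`run_large_study()`.

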