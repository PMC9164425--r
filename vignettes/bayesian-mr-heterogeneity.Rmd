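---
title: "Random-effect Bayesian Mendelian randomization with missing exposures"
author: "bayesmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-effect Bayesian Mendelian randomization with missing exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmr)
```

## The problem

Mendelian randomization (MR) estimates the causal effect of an exposure on
an outcome by using genetic variants as instrumental variables: a valid
instrument is associated with the exposure, independent of the unmeasured
confounders, and affects the outcome only through the exposure.  In
practice the two association analyses often come from two different
studies, and those studies are rarely exchangeable — different populations,
protocols and measurement conventions shift locations of the modelled
variables between studies.  A second practical obstacle is that one of the
studies frequently measures only genotypes and outcomes: all exposure
values are missing for its participants.

`bayesmr` implements a Bayesian solution for exactly this two-study
pattern, with two exposures and two outcomes observed jointly:

* **Study A** observes instruments, exposures and outcomes;
* **Study B** observes instruments and outcomes only — both exposures are
  completely missing by design;
* Study B's equations receive **study-level random-effect intercepts**
  that absorb between-study heterogeneity;
* the missing exposures are treated as unknowns and **imputed inside the
  MCMC** while the causal effects are estimated, so no observed data are
  discarded.

## The model

For individual $i$, let $Z_1 \in \{0,1,2\}^L$, $Z_2 \in \{0,1,2\}^K$ and
$Z_3 \in \{0,1,2\}^M$ be three blocks of mutually independent genotype
dosages: $Z_1$ instruments the first exposure $X_1$ only, $Z_2$ the second
exposure $X_2$ only, and $Z_3$ is shared by both.  A latent scalar $U
\sim N(0,1)$ summarises the unmeasured confounders.  For Study A,

$$
\begin{aligned}
X_1 \mid Z, U &\sim N(\alpha_1' Z_1 + \alpha_{31}' Z_3 + \delta_{X_1} U,\ \sigma_{X_1A}^2),\\
X_2 \mid Z, U &\sim N(\alpha_2' Z_2 + \alpha_{32}' Z_3 + \delta_{X_2} U,\ \sigma_{X_2A}^2),\\
Y_1 \mid X_1, U &\sim N(\beta_1 X_1 + \delta_{Y_1} U,\ \sigma_{Y_1A}^2),\\
Y_2 \mid X_2, U &\sim N(\beta_2 X_2 + \delta_{Y_2} U,\ \sigma_{Y_2A}^2),
\end{aligned}
$$

and Study B adds a random-effect intercept to each equation
($V_{X_1}, V_{X_2}, V_{Y_1}, V_{Y_2}$) and uses its own residual scales
$\sigma_{\cdot B}$.  The causal estimands are $\beta_1$ ($X_1$ on $Y_1$)
and $\beta_2$ ($X_2$ on $Y_2$).  Genotypes are treated as fixed
covariates.  There are no direct $Z \to Y$ (pleiotropy) paths; the model
assumes linear, additive, homoscedastic relations with a single scalar
confounder summary.

Priors: $\alpha_{\cdot j} \sim N(0, 0.3^2)$ on every instrument-strength
component (instruments individually explain little exposure variance),
$\beta_{1,2} \sim N(0, 10^2)$, every residual *standard deviation*
$\sigma \sim \text{Inv-Gamma}(3, 2)$ (on the sd, not the variance), and
$V_\cdot \sim N(0, 1)$.  The confounder loadings $\delta$ carry no
published default; we use $N(0, 1)$, on the scale of the simulation
ground truth, configurable through `prior_spec(delta_sd = )`.

The model is stated for standardised observed variables.  We treat that
as a modelling assumption rather than a preprocessing step: the simulator
generates on the raw scale of the stated parameter values and the fitter
does not rescale by default, because the replicate metrics recover
$\beta$ on the generative scale.  `bmr(standardise = TRUE)` opts into
centring/scaling when analysing raw data whose scales are arbitrary.

## Inference: data augmentation in one Markov chain

The unknowns are the structural parameters, one latent $U_i$ per
individual in both studies, and the imputed Study-B exposures $X_1^*,
X_2^*$.  All full conditionals are tractable, so `bmr()` runs a
systematic-scan Gibbs sampler (compiled with RcppArmadillo):

1. draw $X_1^*, X_2^*$ from their conditional normals given the current
   parameters and $U$ (the imputation step);
2. draw the coefficient block of each structural equation — e.g.
   $(\alpha_1, \alpha_{31}, \delta_{X_1}, V_{X_1})$ — from its conjugate
   multivariate normal, pooling both studies with their own residual
   variances;
3. draw each residual sd by a slice step on $\log\sigma$ (the
   inverse-gamma prior on the sd is not conjugate);
4. draw each $U_i$ from its conditional normal.

A scheme that alternates imputation and estimation and one that samples
everything "simultaneously" coincide here: a Gibbs sweep *is* both, with
the same stationary distribution.  For that reason the package ships a
single sampler rather than two selectable ones.

### Mixing: exact group moves on the flat directions

Three near-flat directions of this posterior make naive conditional
updates random-walk with tiny steps, and we resolve each with an exact
group move (a generalized-Gibbs update along an invariance direction of
the likelihood):

* **Imputation ridge** $(X^*_1 + c,\ V_{X_1} + c,\ V_{Y_1} - \beta_1 c)$:
  the likelihood is invariant; only the $V$ priors pin $c$, which is
  refreshed from its exact Gaussian conditional (same for the second
  pair).
* **Confounder scale** $(U \to sU,\ \delta \to \delta/s)$: constrained
  only by the $U$ and $\delta$ priors; $s$ is drawn by a slice step under
  the Haar measure of the scale group.
* **Residual scale of the imputed exposures** $(\sigma_{X_kB} \to
  s\sigma_{X_kB},\ X_k^* \to m + s(X_k^* - m))$: when $\beta_k \approx 0$
  the outcome carries no information about $\sigma_{X_kB}$ and a naive
  update self-reinforces; the joint rescale samples the reachable
  direction in one step.
* **Study-B location** $(U_B + c,\ V_k - \delta_k c)$: pinned by the $U$
  prior across $n_B$ individuals and the $V$ priors.

The likelihood is also invariant under jointly flipping the signs of all
four $\delta$ and of $U$, so the $\delta$ signs are labels, not
estimands.  Chains are initialised with positive $\delta$ and each chain
is sign-aligned afterwards (all $\delta$ and $U$ flipped if the chain's
mean $\delta_{X_1}$ is negative) so that the convergence diagnostic
measures mixing rather than label switching; $\beta$, $V$ and $X^*$ are
unaffected by the relabelling.

With these moves, 4 chains of 1000 warmup + 2000 kept iterations (the
defaults) keep split-$\hat R$ below 1.1 for every structural parameter
in almost every simulated dataset across the full grid, and the
simulation harness refits the rare straggler once with doubled
iterations (which has sufficed in practice); a fit takes about 1–2 s at
$n = 400$.  Initial values are drawn from the priors shrunk by
`init_scale` (default 0.1), with the latent exposures started at their
instrument-based linear predictions.  Intervals are equal-tailed, the
point summary is the posterior mean, and $\hat R$ is the plain split-chain
statistic (not rank-normalised), matching the convention under which
"below 1.1" is the usual gate.  The sampler was validated against an
independent JAGS implementation of the identical model (see
`test-inference.R`); JAGS serves only as a cross-check, never as the
implementation.

## The IVW comparator

The benchmark is two-sample inverse-variance weighted estimation using
Study A for instrument–exposure associations and Study B for
instrument–outcome associations.  Pair 1 uses $Z_1 \cup Z_3$, pair 2
$Z_2 \cup Z_3$ (the shared block is a valid instrument for both).  Because
individual-level data are in hand, both stages regress on all of the
pair's instruments *jointly* by default, which removes the variance
explained by the other instruments from each residual; per-instrument
marginal regressions remain available (`assoc = "marginal"`).  The point
estimate uses the classical first-order weights
$w_i = se(\Gamma_i)^{-2}$:

$$\hat\beta_{IVW} = \frac{\sum_i w_i \hat\gamma_i \hat\Gamma_i}
                         {\sum_i w_i \hat\gamma_i^2}.$$

The reported standard error propagates the stage-1 sampling uncertainty
through the ratio by the delta method,

$$se^2 = \frac{1}{\sum_i w_i\hat\gamma_i^2} +
  \frac{\sum_i \{w_i(\hat\Gamma_i - 2\hat\gamma_i\hat\beta)\}^2\,
        se(\hat\gamma_i)^2}{(\sum_i w_i \hat\gamma_i^2)^2},$$

which reduces to the familiar first-order form when stage-1 noise is
negligible and widens the interval exactly where instruments are weak —
without it, weak-instrument coverage collapses far below what the
replicate experiments show.  Confidence intervals are
$\hat\beta \pm 1.96\,se$.

## Divide and combine for large studies

MCMC cost grows with $n$, so for large studies the data are split into
$J$ subsets — **stratified by study**, so every subset keeps the full
data's missing rate — and fitted independently (embarrassingly parallel).
With subset posterior means $\hat\mu_j$ and their average $\hat\mu$,
every draw of subset $j$ is recentred by $\hat\mu - \hat\mu_j$ and the
draws are pooled with equal weight.  The pooled mean then equals
$\hat\mu$ *exactly* (an algebraic identity the tests assert to $10^{-10}$),
and the aggregation error of the mean vanishes at rate $1/q$ in the
subset size $q = n/J$.

Each subset sees only $q$ observations, so a single subset posterior is
about $J$ times wider in variance than the full-data posterior.  Pooling
plainly recentred draws therefore overstates the aggregated uncertainty
by a factor of about $J$, whereas the theory this scheme appeals to —
and the observed behaviour of full-data versus aggregated contours —
has the aggregated variance tracking the full-data posterior variance
(difference vanishing faster than $1/n$).  `aggregate_fits()` therefore
also shrinks each subset's draws about its own mean by $1/\sqrt{J}$ by
default (`scale_correct = TRUE`), which matches the second moment
without touching the grand mean; `scale_correct = FALSE` yields the
plain recentred mixture for comparison.  Latent per-individual
quantities are never aggregated — they are subset-specific by
construction — and each subset estimates its own random effects $V$.

Joint posteriors of $(\beta_1, \beta_2)$ are visualised with a 2-D
Gaussian product-kernel density estimate (`posterior_kde2d()`), with a
Scott-type per-dimension bandwidth $sd \cdot N^{-1/6}$ (overridable), a
grid padded by three bandwidths so the trapezoid integral is $\approx 1$,
and kernel evaluation delegated to `MASS::kde2d()`.

## The synthetic-data generator

`sim_config()` / `simulate_combined()` emulate the evaluation conditions
of the replicate experiments; the defaults *are* those conditions and are
not meant to be tuned per run:

| quantity | default | meaning |
|---|---|---|
| $L, K, M$ | 15, 15, 5 | instruments per block |
| genotype law | Binomial(2, 0.3) | i.i.d. dosages |
| $\alpha$ | 0.1 or 0.3 | one common magnitude, all positive |
| $\beta_1 = \beta_2$ | 0 or 0.3 | causal effects |
| $\delta$ | 1 | confounder loadings |
| $\sigma$ | 0.1 | residual sds, all equations and studies |
| $V$ | Uniform($-0.5, 0.5$) | redrawn per replicate (4 components) |
| $n$ | 400 (small) / 50,000 (large) | $n_B = $ round($n\cdot$missing rate) |
| missing rate | 20%, 50% or 80% | Study-B share |

Replicate $r$ of a configuration runs on a substream derived
deterministically from `(seed, r)`, so replicates are reproducible
individually and independent of generation order; a fresh $V$ vector is
drawn for every replicate ("different degrees of heterogeneity in
different datasets").  Signs of $\alpha$ are not published; all-positive
is used.  Study-B sizes round half up, and configurations where rounding
moves the realised missing rate by more than one percentage point are
rejected.

What the generator does *not* emulate: linkage disequilibrium between
variants, realistic allele-frequency spectra, direct pleiotropy,
non-linear or binary outcomes, case-control ascertainment.  Passing
tests on these data show correctness of the machinery under the stated
generative model, not robustness to violations of it.

## Evaluation metrics and problem sizes

`run_small_study()` evaluates estimators over replicate datasets by four
metrics per configuration, method and effect: mean and standard deviation
of the point estimates (posterior mean for the Bayesian method), coverage
of the 95% intervals at the true effect, and power (share of intervals
excluding zero; reported only for non-zero truth).  Intervals are treated
as closed — ties have probability zero under continuous posteriors.  A
replicate whose structural $\hat R$ exceeds 1.1 is refit once with
doubled iterations, then excluded with a count if still non-convergent.

The test-suite problem sizes are deliberate reductions chosen to keep
the checks sharp but fast: the IVW table comparison runs 1000 replicates
per configuration (more than the published 200, so our own Monte-Carlo
error is small relative to the comparison bands); the Bayesian headline
cells run 25 replicates; the divide-and-combine consistency check uses
$n = 2000$ with $J \in \{2, 10\}$ over 5 seeds; and the large-study
concordance check uses $n = 5000$ with $J \in \{1, 5, 50\}$, preserving
the published subset-size ratios.  The full-scale experiments remain
available through the same functions by passing the published sizes.

## Known limitations

* $V_{X_1}$ and $V_{X_2}$ are barely identified when Study B lacks
  exposures — their posteriors stay close to the $N(0,1)$ prior; the
  outcome-equation intercepts $V_{Y}$ are data-identified.  This mirrors
  the model as stated; the causal effects are unaffected.
* $\sigma_{X_1B}, \sigma_{X_2B}$ are likewise weakly identified (only
  through the outcome equations), and their posteriors lean on the prior.
* The delta-method IVW standard error is first-order; at extremely weak
  instruments no closed-form se fully captures the ratio's sampling law.
* The sampler exploits conjugacy of the linear-Gaussian model; extending
  to binary outcomes or non-linear links would require replacing the
  coefficient updates.
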