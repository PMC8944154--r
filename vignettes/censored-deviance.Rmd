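---
title: "Exact deviance for Bayesian censored-data models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact deviance for Bayesian censored-data models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censdev)
```

## The problem

A censored observation is known only to lie in a region: below a cutoff
(left), above one (right), or inside a semi-closed interval $(l, u]$. Its
likelihood contribution is the probability of that region,

$$
L_i(\theta) =
\begin{cases}
f(y_i \mid \theta) & \text{observed} \\
F(u_i \mid \theta) & \text{left-censored} \\
1 - F(l_i \mid \theta) & \text{right-censored} \\
F(u_i \mid \theta) - F(l_i \mid \theta) & \text{interval-censored,}
\end{cases}
$$

and the deviance is $D(\theta) = -2 \sum_i \log L_i(\theta)$, which splits
into an observed part (block $O$) and a censored part (blocks $C$, the
one-sided records, and $I$, the interval records).

General-purpose Gibbs samplers commonly handle censoring through a degenerate
interval-indicator distribution. That device produces the correct posterior,
but the indicator's own likelihood is identically 1, so the automatic
deviance monitor silently assigns every censored observation a deviance of
zero. Posterior summaries look fine; DIC-style model comparison is computed
from the wrong function — it has the *wrong focus*, the censoring indicator
rather than the outcome. `censdev` builds the exact censored likelihood, the
equivalent Bernoulli-indicator factorization of it, and deviance-based model
selection on top, plus a labeled diagnostic (`observed_only_deviance()`)
that reproduces the biased observed-only deviance for demonstration. The
diagnostic is never an input to a comparison report.

## The Bernoulli-indicator factorization

The alternative route partitions records into $O$, $C$ and $I$
(`partition_blocks()`), and rewrites every censored contribution as a
Bernoulli likelihood with fixed data (`bernoulli_augment()`):

* each one-sided record carries $Z_1 = 1$ (left) or $Z_1 = 0$ (right) with
  success probability $p = F(\text{cut})$, so left records contribute
  $\log p$ and right records $\log(1 - p)$;
* each interval record carries $Z_2 = 1$ with success probability
  $F(u) - F(l)$.

The indicators are deterministic functions of the censoring pattern — data,
not latent variables — so the factorization equals the exact likelihood term
by term. The two implementations (`exact_log_likelihood()`,
`augmented_log_likelihood()`) deliberately travel different numerical paths
(the exact route uses a dedicated stable survivor form, the augmented route
the distribution function on the probability scale), and their agreement to
$10^{-10}$ is enforced as a property test over randomized datasets spanning
every family and censoring mix, and lifted to the per-draw deviance monitor.

```{r equivalence}
d <- censored_data(value = c(1.2, NA, NA),
                   status = c("observed", "right", "interval"),
                   lower = c(NA, 2, 0.5), upper = c(NA, NA, 1.5))
sp <- family_spec("weibull", shape = 1.5, scale = 2)
c(exact = as.numeric(exact_log_likelihood(d, sp)),
  augmented = as.numeric(augmented_log_likelihood(bernoulli_augment(d), sp)))
```

## Families and conventions

`family_spec()` covers exponential, Weibull, normal, log-normal,
log-logistic, binomial and beta-binomial outcomes, all evaluated in log
space. Two parameterizations had to be fixed by convention:

* **Weibull**: shape $k$ and scale $s$ with $S(y) = \exp\{-(y/s)^k\}$ —
  the `stats::pweibull()` parameterization;
* **log-logistic**: shape $k$ and scale $s$ with
  $F(y) = 1/(1 + (y/s)^{-k})$.

For count families the distribution function is a step function, so the
meaning of a cutoff needs a convention. `censdev` reads censoring statements
strictly by default (`count_strict = TRUE`): "censored below $u$" means
$Y < u$ and contributes $P(Y \le u - 1)$, "censored above $l$" means
$Y > l$ and contributes $P(Y > l)$. The non-strict reading is available as
an option; continuous families are insensitive to the choice. Intervals are
semi-closed $(l, u]$ with probability $F(u) - F(l)$ for every support, and a
degenerate interval ($l \ge u$) is a validation error rather than a silent
zero. The synthetic adverse-event generator masks counts *strictly below*
the study cutoff, so generator and likelihood use the same convention.

Every probability term is floored at $10^{-12}$ before the log; floored
terms are counted and surfaced in the `n_clipped` attribute so a deviance
sum can never be poisoned by a single $-\infty$ while the clipping stays
visible.

## The sampler

`run_mcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler:
one Gaussian proposal per parameter per iteration on an unconstrained scale
(log for positive parameters, scaled logit for bounded ones), with the
transform's Jacobian in the target. The choice is deliberate: the models
here are low-dimensional (at most a hundred-odd parameters in the saturated
meta-analysis model), and a fixed, dependency-free kernel keeps runs exactly
reproducible — chain $c$ is seeded with `seed + c` and identical inputs give
bit-identical draws.

Step sizes adapt toward an acceptance rate of 0.44 (the scalar-update
optimum) by a Robbins–Monro recursion with gain $\min(0.5, t^{-0.6})$,
during burn-in only; afterwards the kernel is frozen so the saved draws come
from a fixed Markov chain. Initial values default to prior medians.
Hierarchical models supply a joint `log_prior` (and, for many-parameter
models, a per-coordinate prior delta and a parameter-to-observation
dependency map so each update touches only the likelihood terms it can
change).

The default protocol (`mcmc_config()`) is 3 chains, 30,000 burn-in
iterations, 10,000 saved draws per chain with thinning by 3 — the protocol
used for the survival application below. Unit tests use shorter, explicitly
configured runs.

## Deviance statistics

`monitor_deviance()` evaluates each observation's exact deviance at every
saved draw. From it:

* $\bar D$ is the posterior mean deviance;
* $p_D$ (effective number of parameters) defaults to the **plug-in**
  estimator $\bar D - D(\hat\theta)$, where $\hat\theta$ is the posterior
  mean taken on the *unconstrained* scale and mapped back
  (`posterior_plugin_estimate()`), which makes $p_D$ invariant to how
  constrained parameters are parameterized. A **variance** estimator
  ($\mathrm{Var}(D)/2$) is available as a labeled alternative; a negative
  plug-in $p_D$ is reported with a flag, never clipped;
* $\mathrm{DIC} = \bar D + p_D$;
* the optimism $p_{\mathrm{opt}}$ of the penalized expected deviance
  defaults to the **asymptotic** form $2 \sum_i p_{D,i}$ built from the
  per-observation plug-in split. The alternative **importance** estimator
  reweights draws per observation by $w_t \propto 1/f(y_i \mid \theta_t) =
  \exp\{d_i(\theta_t)/2\}$ (self-normalized), i.e. it targets the
  leave-one-out posterior and estimates the optimism as the reweighted minus
  the plain posterior mean of $d_i$; observations whose weights collapse
  (effective sample size below 5% of draws) fall back to the asymptotic
  penalty with a warning;
* $\mathrm{PED} = \bar D + p_{\mathrm{opt}}$.

Both identities are asserted to $10^{-8}$, every report row carries its
estimator labels, and `compare_models()` refuses fits made on different
datasets.

## The survival application

The package ships an accessor for the classical acute myeloid leukemia
maintenance table (23 subjects, 18 observed deaths, 5 right-censored;
time in weeks, covariate 1 if chemotherapy was maintained). The preset
`fit_exponential_survival()` models subject hazards as
$\lambda_i = \exp(\beta_0 + \beta_1 x_i)$ — $\beta_0$ the log baseline
hazard, $\beta_1$ the log hazard ratio — with vague normal(0, sd 100)
priors on both coefficients (the analysis is likelihood-dominated, so the
posterior deviance is insensitive to any reasonably vague choice). Observed
times contribute $\log \lambda_i - \lambda_i t_i$, censored times
$-\lambda_i t_i$. The acceptance suite reproduces the published posterior
mean deviances for this model (exact $\approx 164.6$ versus observed-only
$\approx 154.9$) under the full sampling protocol; the gap *is* the censored
part of the deviance, which is what the wrong-focus monitor discards. The
covariate coding ($x = 1$ for maintained) fixes the sign of $\beta_1$ but
cancels from the deviance.

## The meta-analysis application

`fit_ae_model()` implements seven models for study-level adverse-event
counts in which a study either reports its count or is censored below a
study-specific reporting cutoff (left-censoring of a count, strict by the
convention above). Where the model structure left prior choices open, the
defaults are:

* Models **B** and **C** put independent Beta(1, 1) priors on the group- or
  drug-level incidences directly on the probability scale — "drug effects
  without a link function" reads most naturally as independent incidences,
  and a uniform beta prior keeps them exchangeable;
* Models **D/E/F** use $g(p_s) = \mu + \theta_{d(s)}$ with logit, cloglog
  and probit links respectively, $\theta_d \sim N(0, \sigma)$,
  $\sigma \sim$ half-Cauchy(1) (the conventional weakly informative scale
  for a hierarchical standard deviation) and $\mu \sim N(0, 10)$, which is
  diffuse on all three link scales;
* Models **A** and **G** (complete pooling and saturated) give their beta
  shape parameters Uniform(0.01, 100) hyperpriors — wide enough to be
  vague, bounded away from the degenerate origin.

The drug-class mapping is standard pharmacology: nivolumab and
pembrolizumab are PD-1 inhibitors; atezolizumab, avelumab and durvalumab
are PD-L1 inhibitors.

The published study-level pneumonitis table this model family was designed
around is distributed through an external repository and is not bundled
here; the corresponding reproduction test runs only when a user supplies
that table (`inst/extdata/pneumonitis_ae.csv`). Everything else about the
seven models is exercised on synthetic tables: the drug-effect models
(C–F) beat complete pooling by DIC, the DIC spread across the three links
stays small when effects are moderate, the saturated model attains the
lowest mean deviance but the worst PED, and $p_{\mathrm{opt}} \ge p_D$ on
every fit.

## Synthetic data: what it does and does not emulate

`simulate_censored_survival()` draws exponential event times under the
regression model with a binary covariate and applies administrative or
random-exponential censoring; `simulate_ae_meta()` draws binomial counts
across the five drugs and masks counts below the cutoff. Defaults for the
meta-analysis generator (125 studies, incidences of a few percent, study
sizes 20–500, cutoff 2) are sized so the resulting tables have the *shape*
of a realistic rare-event meta-analysis; they are labeled synthetic study
conditions, not a reproduction of any published dataset.

The generators share the likelihood's censoring conventions and are
noninformative by construction (the masking rule depends on the realized
count only through the cutoff comparison, and censoring times are
independent of event times). Passing tests on these data therefore show
correctness of the likelihood, sampler and selection statistics under
noninformative censoring with a correctly specified outcome family; they do
not probe informative censoring, model misspecification, or the
selection-mechanism sensitivity questions that arise with real reporting
practices.

`recovery_harness()` refits a model on independently seeded replicates and
reports bias and credible-interval coverage; the acceptance suite requires
at least 85% empirical coverage of nominal 95% intervals for the survival
coefficients over 40 replicates of $n = 300$ with roughly 30%
administrative censoring.

## Problem sizes and numerical choices

Test runs use 2 chains with hundreds to a few thousand saved draws — enough
for the Monte-Carlo tolerances asserted — while the survival reproduction
and the acceptance script use the full 3 × 30,000/10,000/thin-3 protocol.
The conjugate oracles (beta-binomial; normal mean with known variance) are
checked within 3 standard errors under a conservative effective-sample-size
deflation. Ties and degenerate inputs are handled explicitly: constant
chains report $\hat R = 1$ with a degeneracy flag, kernel densities refuse
constant or undersized draws, and the empty dataset has log-likelihood 0.

## Known limitations

* Truncation is out of scope: it changes the normalizing constant rather
  than contributing a region probability, and the likelihood here assumes
  noninformative censoring throughout.
* The sampler is a random-walk method; for strongly correlated
  high-dimensional posteriors it mixes slowly, and the saturated model G is
  the practical ceiling of what the package is intended for.
* WAIC, BPIC and cross-validation scores are natural extensions of the
  per-observation deviance matrix but are not implemented.
* The importance-sampling optimism estimator inherits the usual fragility
  of unbounded likelihood-ratio weights; its ESS guard and asymptotic
  fallback are blunt instruments by design.
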