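---
title: "Methods: Bayesian latent class analysis for rTBI surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian latent class analysis for rTBI surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtbisurv)
```

## The estimation problem

Recurrent traumatic brain injury (rTBI) — a new TBI within a year of an
index TBI — must be monitored from administrative claims, but no perfect
reference diagnosis exists against which a claims-based case definition
could be validated. Treating any one definition as truth would bias both
the incidence and the accuracy estimates. The package therefore treats
true recurrence status as a latent class: four imperfect case definitions
are applied simultaneously, and their joint response patterns identify the
prevalence of the latent class and each definition's sensitivity and
specificity at once.

## Model and assumptions

For index patient $i$, let $y_{ij} \in \{0,1\}$ be the result of case
definition $j$, $j = 1,\dots,4$ (outpatient claim, ER claim, hospital
discharge abstract, head radiology paired with a trauma diagnosis), over
the window 7–365 days post-index. With latent status
$C_i \in \{\text{no rTBI}, \text{rTBI}\}$, prevalence
$\pi = P(C_i = 1)$, sensitivities $Se_j$ and specificities $Sp_j$, and
**conditional independence of the definitions given $C_i$**, the pattern
probability is

$$P(y) = \pi \prod_j Se_j^{y_j}(1-Se_j)^{1-y_j}
       + (1-\pi)\prod_j (1-Sp_j)^{y_j} Sp_j^{1-y_j}.$$

The $2^4 = 16$ patterns carry 15 degrees of freedom against 9 parameters,
so the two-class model is identified; the analogous three-class model
needs 13 parameters (`model_dimensions(4, 3)`) and is out of scope here —
only its counting arithmetic is implemented, because sparse response
patterns leave it unidentifiable in practice without informative priors.
The parameter count follows the published scheme of one incidence
parameter plus one response probability per definition per class
($1 + KJ$), which reproduces both printed counts (9 and 13); note this
differs by one from the textbook $(K-1) + KJ$ count at $K = 3$, since the
class-membership structure is described by the single incidence parameter.

Conditional independence is an assumption, not a theorem; it is checked by
posterior predictive checks (below).

## Sampler

`fit_two_class()` is a Gibbs sampler with data augmentation, written for
the aggregated pattern counts (the sufficient statistic):

1. given parameters, the latent class-1 count of each pattern cell is
   Binomial with the Bayes posterior probability of membership;
2. given latent counts, $\pi$, $Se_j$, $Sp_j$ have conjugate Beta
   full conditionals, sampled by inverse-CDF under their truncation
   bounds.

**Priors as constraints.** All priors are Beta(1, 1) truncated:
$\pi \in (0, 0.25)$, every $Sp_j \in (0.7, 1)$, and the ER and DAD
sensitivities $\in (0.02, 0.9)$. The published analysis states that
non-informative prior information was placed on exactly this parameter
set (incidence, all specificities, ER and DAD sensitivities) but not its
numeric ranges, so these bounds are reconstructions, fully overridable via
`lcm_priors()`, and the prior-sensitivity harness varies them. Label
switching is prevented structurally rather than by post-hoc relabelling:
updates of the constrained definitions are rejected (through the
truncation bounds) whenever they would violate $Se_j + Sp_j > 1$.

**Sex covariate.** With covariates active, $\pi$ is replaced per subject
by $\mathrm{logit}^{-1}(\beta_0 + \beta_{sex}\,male_i)$; counts are
aggregated by pattern × sex and $(\beta_0, \beta_{sex})$ are updated by a
random-walk Metropolis step with a flat prior. The proposal scale adapts
toward ~35% acceptance during burn-in only, so the post-burn-in chain is a
valid fixed-kernel sampler. A draw is rejected if any stratum prevalence
reaches 0.5 (the logistic-layer analogue of the label guard). Only the
prevalence carries the covariate; letting sex shift Se/Sp as well would
cost 8 more parameters against the same 15 degrees of freedom.

**Settings.** Defaults are 3 chains × 20,000 iterations with 5,000
burn-in, the published configuration. Convergence is monitored by the
Gelman–Rubin statistic (implemented as the classic potential scale
reduction factor and cross-checked against `coda::gelman.diag` in the test
suite) with the conventional < 1.1 criterion; non-convergence always
raises a warning and is flagged in the returned object, never silent.

**Validation oracle.** `brute_force_posterior()` integrates the exact
posterior on a lattice for instances with at most two definitions
(refusing anything larger than $2\times10^7$ lattice points). The test
suite requires MCMC marginal means to match the grid means within 0.02 on
toy data — an end-to-end check of the sampler that is independent of the
sampler itself.

## Propagating incident-cohort uncertainty

The index cohort is itself an estimate from an upstream incident-TBI
latent class model, represented here by a per-patient membership
probability. `draw_incident_cohorts()` predicts cohorts by independent
Bernoulli draws from these probabilities; the model is refitted on each
predicted cohort (`run_multi_cohort()`, deterministic per-cohort seeds,
per-cohort failures recorded but not fatal) and `pool_draws()` stacks an
equal post-burn-in draw budget per cohort — the multiple-imputation-style
mixture of posteriors. Whether the original analysis pooled equal budgets
or all retained draws is not stated; equal budgets are the default because
they weight every predicted cohort equally. Age strata are then combined
by `pool_across_strata()` as a mixture weighted by mean predicted cohort
size, and every scalar is summarised as the median and shortest 95%
highest-density interval computed on sorted draws (`hdi()`), which matches
the highest-posterior-density summaries reported without assuming
unimodality machinery.

The published analysis predicted 1,000 cohorts per age group; the bundled
`analysis/` drivers use 50 cohorts of a 20,000-patient synthetic
population with 2 chains × 1,500 iterations per fit. These desk-scale
sizes keep a complete run in the low minutes while leaving every Monte
Carlo error small relative to the intervals being reported; all of them
are arguments, not constants.

## Model checking

`pairwise_agreement()` computes raw concordance $P(y_j = y_k)$ for the six
definition pairs. Raw concordance is used rather than kappa because the
posterior predictive check compares the same statistic on observed and
replicated data, so any chance-correction would cancel.
`posterior_predictive_check()` simulates replicate datasets of the
observed size from retained draws and reports, per pair, the probability
that observed agreement exceeds predicted agreement. Values outside
(0.05, 0.95) are flagged; the cutoff is a convention (the source analysis
states the check's direction but no threshold). Under data generated from
the fitted model the six p-values are calibrated; strong conditional
dependence injected between two definitions drives at least one pair's
p-value extreme — both properties are exercised in the test suite.

`prior_sensitivity()` refits under alternative truncation ranges and
flags any parameter whose 95% interval no longer overlaps the primary
analysis interval.

## Derived quantities

* `ppv()` / `npv()` — Bayes identities; computed draw-wise by default and
  summarised with HDIs, since plugging point estimates into a nonlinear
  identity does not commute with posterior summarising (the draw-wise
  route is also why two published predictive-value cells differ slightly
  from the plug-in arithmetic).
* `adjust_crude_incidence()` — the Rogan–Gladen estimator
  $(p + Sp - 1)/(Se + Sp - 1)$, the standard crude-rate correction using
  only Se and Sp, clamped to $[0,1]$ with a flag. Rates per 100
  person-years are divided by 100 before adjustment (small-rate
  approximation, exact at the 1-year-risk scale the generator uses).
* `adjusted_median_time()` — each suspected event is weighted by
  $P(\text{true index}) \times P(\text{true rTBI} \mid \text{pattern})$;
  the weighted median is the smallest day whose cumulative weight reaches
  half the total (with unit weights this coincides with the lower-median
  convention of `crude_median_time()`). Early false positives carry small
  weights, so the adjusted median sits later than the crude one whenever
  early noise is present.

## The synthetic cohort generator

No claims data can be shared, so `sim_config()` defines the study
conditions the analysis is exercised under, and those defaults *are* the
published setting wherever a value is printed:

* age-specific 1-year recurrence risks 0.0169 / 0.0357 / 0.0903
  (children / adults / elderly), with most-severe-index multipliers from
  the published severity ratios (1.685 / 3.219 / 1.051);
* male log-odds ratio log(1.4) on recurrence (the adults' published M:F
  ratio 1.409);
* definition sensitivities (0.19, 0.42, 0.14, 0.79) and specificities
  (0.9516, 0.9898, 0.9876, 0.9874) — the adults' published accuracy row;
* recurrence-time medians 120 / 75 / 109 days, drawn from a discretised
  exponential on [7, 365] (the source reports only medians; the
  exponential is the maximum-entropy waiting-time choice);
* incident-TBI probabilities (0.12, 0.04, 0.09) chosen so the three
  index-cohort sizes fall in the published proportions (0.361 / 0.395 /
  0.243); membership probabilities Beta(18, 2) for true cases and
  Beta(2, 18) for the 3% of non-cases with spurious index signals,
  emulating a well-separated upstream classifier;
* `followup_noise_rate = 0.002`/day with geometric decay (factor 0.85)
  over days 7–30 — visible early false-positive clustering without
  dominating the crude rate; `censor_prob = 0.15` — the source does not
  state its censoring fraction, and this default is acknowledged as
  arbitrary.

The generator is calibrated so that, with the noise rate at zero and no
censoring, the empirical Se/Sp of each definition measured against latent
truth equals the configured values (a tested invariant). What it does
*not* emulate: multiple recurrences per patient (the analysis handles
single events only), external causes of injury, hospital length of stay,
seasonal claim patterns, or correlated false positives across definitions
— so passing tests demonstrate correctness of the machinery under the
stated model, not robustness to every real-data pathology. Conversely the
conditional-dependence PPC test injects exactly such a violation to show
the diagnostics can detect it.

## Numerical choices and degenerate inputs

* Truncated Beta draws use the inverse-CDF; when the truncation mass
  underflows, the draw pins to the nearer bound rather than producing NaN.
* Pattern indices encode flags with the outpatient definition as the most
  significant bit; the index → flags → index round trip is tested for all
  16 values.
* Person-time uses 365-day years exactly, matching the day-based window.
* Empty claim streams, empty pattern counts, all-zero weights, single
  chains passed to the Gelman–Rubin statistic, and person-time with exit
  before index all raise explicit errors.
* `derive_seed()` fans a master seed into per-stage and per-cohort seeds
  below $2^{31}$, making every pipeline stage reproducible bit-for-bit.

## Known limitations

The specificity constraints matter when patterns are sparse: with a few
hundred subjects the posterior leans on the truncation bounds, which is
why the prior-sensitivity harness exists. The Rogan–Gladen adjustment can
clamp at 0 when the apparent rate falls below $1 - Sp$; the clamp is
flagged rather than hidden. The Metropolis step for the sex covariate
assumes the two sex strata share Se/Sp. And the generator's independence
of false positives across definitions is the very assumption the fitted
model makes — real claims may violate it, which is what the posterior
predictive checks are for.
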