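---
title: "A Bayesian bivariate model for diagnostic test accuracy meta-analysis"
author: "dtameta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian bivariate model for diagnostic test accuracy meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtameta)
```

## The problem

A diagnostic test accuracy (DTA) study evaluates an index test against a
reference standard and reports a 2x2 table: true positives (TP), false
positives (FP), true negatives (TN), false negatives (FN). Sensitivity
(TP/(TP+FN)) and specificity (TN/(TN+FP)) are estimated jointly because
they are negatively correlated across studies through implicit threshold
differences. The package implements the full analysis chain for a
meta-analysis of such studies, exercised on a packaged study-level table of
four noninvasive cardiac stress tests (exercise ECG, stress
echocardiography, stress SPECT, and stress CMR) evaluated against
angiographically confirmed obstructive coronary artery disease, and on
synthetic cohorts.

## Reconstructing counts from printed percentages

Published summary tables often print only the total `n` and the
sensitivity/specificity/accuracy percentages. The binomial likelihood
needs integer counts, so `reconstruct_counts()` recovers them by a
constrained integer search over the unprinted diseased-stratum size
`D = TP + FN`:

* for each `D` in `1, ..., n-1`, imply `TP = round(sen * D / 100)` and
  `TN = round(spe * (n - D) / 100)` with halves rounded away from zero;
* score the candidate by the summed squared percentage-point mismatch of
  the implied sensitivity, specificity, and accuracy against the printed
  values;
* return the minimizer, breaking exact ties by the most balanced design
  (smallest `|2D - n|`), then the smaller `D`.

The tie-break matters only for symmetric inputs (for example
`n = 100, sen = spe = acc = 50`, where several `D` fit exactly); on real
rows the optimum is unique in practice. The procedure is checked in the
test suite against full enumeration of all `(D, TP, TN)` triples on every
packaged row small enough to enumerate. A minimal residual above 25
squared percentage points flags the row as internally inconsistent — a
handful of published rows cannot be produced exactly by any integer table,
presumably because the printed accuracy was computed on a different
denominator; flagged rows are listed, never silently altered.

## The bivariate binomial-normal model

For study `i` with diseased stratum size `n_Di` and non-diseased `n_NDi`:

* `TP_i ~ Binomial(n_Di, logit^-1(mu_se + phi_se,i))`
* `TN_i ~ Binomial(n_NDi, logit^-1(mu_sp + phi_sp,i))`
* `(phi_se,i, phi_sp,i) ~ N2(0, Sigma)` with SDs `(sigma_se, sigma_sp)`
  and correlation `rho`.

Priors: `mu_se, mu_sp ~ N(0, sd = 10)` on the logit scale; penalized
complexity priors `PC(3, 0.05)` on both SDs, i.e. exponential with rate
`-log(0.05)/3` so that `P(sigma > 3) = 0.05`, shrinking toward the
no-heterogeneity base model; and `atanh(rho) ~ N(0, sd = 5)` on the
Fisher-z scale. The "large variance" choices (10 and 5) are the package's
own concretization of deliberately weak priors: both are effectively flat
over the plausible logit range (|logit| < 6 covers probabilities from
0.25% to 99.75%) while keeping the posterior proper; both are
configurable through `prior_spec()`.

Pooled sensitivity and specificity are `logit^-1(mu_se)` and
`logit^-1(mu_sp)`, computed draw-wise and then summarized (medians and
equal-tailed 95% credible intervals); quantiles commute with the monotone
inverse logit, means do not, so transforming a summary is never done.

## The sampler

`fit_bivariate()` runs an adaptive random-walk Metropolis-within-Gibbs
sampler on the unconstrained scale (log SDs, Fisher-z correlation), with
the study-level deviations sampled explicitly — no marginalization or
quadrature; at the study counts involved here (at most a few dozen per
fit) exactness is cheap. Each sweep applies:

1. a joint random-walk update of `(mu_se, mu_sp)`;
2. a *translation* move shifting the means while counter-shifting all
   deviations, which leaves the likelihood invariant and decouples the
   means from the random effects (the centered parameterization alone
   mixes poorly under the strong heterogeneity seen in this dataset);
3. vectorized per-study updates of the deviation pairs (valid as parallel
   accept/reject because the deviations are conditionally independent
   given the hyperparameters);
4. per-margin *scale* moves rescaling a SD together with its deviations —
   the non-centered direction, which keeps the SDs mixing when the
   posterior approaches the no-heterogeneity boundary (the random-effect
   density change cancels the proposal Jacobian exactly, leaving only the
   likelihood and the SD prior in the ratio);
5. scalar random-walk updates of `log sigma_se`, `log sigma_sp`, `z`;
6. a joint `(z, phi_sp)` move that rebuilds the specificity deviations
   from their standardized innovations under the proposed correlation —
   the move that crosses between a boundary-correlation mode and the
   interior; and
7. an independence refresh of `z` from its prior, whose proposal density
   cancels the prior in the acceptance ratio, jumping freely across the
   flat region when few studies leave the correlation weakly identified.

Proposal scales adapt in batches of 50 iterations during burn-in
(diminishing adaptation, targets ~30% for pair updates and ~44% for
scalar ones) and freeze afterwards. The default budget is 4 chains of
10,000 iterations with the first half discarded — 40,000 total sweeps,
20,000 retained draws. Convergence is monitored by split-chain R-hat on
every hyperparameter with a 1.05 threshold; a fit exceeding it is flagged,
carries a full diagnostics dump, and warns rather than reporting silently.
With one study the correlation is unidentifiable and is fixed at zero.

Degenerate inputs: out-of-support states (non-positive SDs, |rho| >= 1)
get log density `-Inf` and are rejected rather than raised; proposals that
would push `tanh(z)` to exactly +/-1 in floating point are rejected the
same way.

## Summary ROC curve and AUC

The summary curve is the conditional-expectation line of the fitted
bivariate normal mapped to ROC space,
`Se(f) = logit^-1(mu_se + rho (sigma_se/sigma_sp)(logit(1-f) - mu_sp))`,
the standard mapping when no hierarchical HSROC reparameterization is
requested. The AUC integrates `Se(f)` by the trapezoid rule on a 1999-point
grid over the *full* false-positive-rate range, with endpoint values taken
from the curve's analytic limits. Restricting integration to the observed
FPR range is a common alternative convention and gives different numbers;
published AUC values whose convention is unstated are therefore treated as
soft checks only (the test suite allows a 0.10 band). The reported AUC is
the posterior median of draw-wise AUCs with its equal-tailed 95% interval;
the draw-wise computation is thinned to at most 2000 draws, which changes
the median by far less than its Monte Carlo error.

## Heterogeneity and small-study asymmetry

I2 is computed per margin on the logit scale with fixed-effect
inverse-variance weights: `Q = sum(w_i (theta_i - theta_bar)^2)`,
`I2 = max(0, (Q - df)/Q)`. This is a deliberately conventional choice —
Bayesian hierarchical fits have no native I2, and the computing convention
behind published I2 values is typically unstated — so printed I2 values
are order-of-magnitude checks only. The 0.5 continuity correction is
applied to all four cells of a table only when some cell is zero.

The asymmetry test runs the classical Egger precision regression
(`theta/sqrt(v)` on `1/sqrt(v)`; a nonzero intercept indicates small-study
effects) separately per margin, then combines the margins by stacking the
two regressions, estimating the joint intercept covariance with a
study-clustered CR1 sandwich (each study contributes both margins), and
referring the 2-df Wald statistic to `F(2, k-2)` — the asymptotic
chi-square reference is visibly liberal at meta-analytic cluster counts.
Simulation in the test suite confirms near-nominal size under the
regression's own null (homogeneous effects, large strata) and high power
against a size-dependent selection mechanism. Two caveats are inherited
from the statistic itself, not the implementation: between-study
heterogeneity inflates rejection, and on a logit margin the estimated
variance shares counts with the effect, which biases the intercept when
strata are small. Both are documented rather than patched, because the
per-margin intercepts remain the standard descriptive quantity.

## Descriptive pooling and robustness

`simple_pool()` reproduces the descriptive "Overall" rows of the packaged
table: sums of sample sizes and *unweighted* arithmetic means of the
printed percentages, rounded to one decimal. Verification against the
packaged table shows the unweighted convention reproduces 11 of its 13
Overall rows exactly; a size-weighted variant is also provided since both
conventions circulate, and neither is chosen silently — the output labels
which was used. Two published Overall rows are internally inconsistent
with their own study rows (one is recovered exactly when that section's
last study is dropped, suggesting the row predates a late addition); the
test suite checks those two to a 1-point band and names them.

Leave-one-out analysis refits the model k times with a derived seed per
exclusion (`seed + index`), reporting per-exclusion posterior summaries
and their min/max envelope. Subgroup analysis fits each group
independently under a shared prior and iteration budget; schemes cover
modality, stressor-within-modality, female-only vs mixed cohorts,
region (documented country-to-continent map, with transcontinental Turkey
grouped with Europe), publication period (through 2004 vs 2005 onward),
and design. Single-study groups are fitted with the correlation fixed at
zero and flagged.

## The synthetic-cohort generator

`simulate_studies()` forward-simulates exactly the model the fit assumes:
latent `(logit Se, logit Sp)` pairs from the bivariate normal, stratum
sizes from a prevalence knob (default 0.5 — the model conditions on
stratum sizes and the source analyses never model prevalence), binomial
counts within strata. Each study draws from its own seeded substream, so
enlarging a cohort never reshuffles earlier studies. A truth table of the
latent values supports parameter-recovery tests.

What passing synthetic tests do *not* show: real study collections
violate the generative model in ways the generator deliberately omits —
threshold drift over time, verification bias, non-binomial
overdispersion within studies, and publication selection (a size-dependent
inclusion filter is simulated only for the asymmetry-test power check).
Parameter recovery on synthetic cohorts validates the sampler, not the
model's adequacy for any particular dataset.

## Problem sizes and reproducibility

The default analysis budget (4 x 10,000 iterations) fits any modality
subset of the packaged table in seconds on one core; the test suite runs
reduced budgets (2 chains, 800-5,000 iterations) for fits whose role is
structural rather than numerical, and the full budget where published
values are compared. All randomness flows from explicit integer seeds:
chain `c` of a fit uses `seed + c - 1`, leave-one-out refit `i` uses
`seed + i`, and simulated study `i` uses an affine substream of the cohort
seed. The headline pooled estimates are stable to the third decimal across
seeds under the default budget.

## Known limitations

* Reconstructed counts are best-fit integers, not the original study
  counts; rows flagged by the residual threshold show that some published
  percentage triples are mutually inconsistent. Pooled estimates computed
  from reconstructed counts can differ from estimates computed from the
  original extracted counts by a few hundredths.
* The correlation is weakly identified in small subgroups; its posterior
  can be nearly flat, and the split R-hat on `z` is then the binding
  convergence constraint.
* The Egger-type combined test should be read descriptively under strong
  heterogeneity (see above).
* No meta-regression on continuous moderators, no trim-and-fill or
  selection-model adjustment, and no INLA-style deterministic
  approximation are provided.
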