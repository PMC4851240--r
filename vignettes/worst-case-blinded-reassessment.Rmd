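---
title: "Worst-case sample size reassessment after a blinded interim analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worst-case sample size reassessment after a blinded interim analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindsr)
```

## The problem

Blinded interim looks are widely regarded as harmless: if nobody sees the
treatment labels, changing the second-stage sample size should not bias the
final test. That intuition fails as soon as the blinded data contain a
*secondary* endpoint with a real treatment effect — a lab parameter, a
safety marker, a pharmacodynamic readout. Such an endpoint partially
reveals each subject's allocation, and a sample size "reassessment" that
exploits this leakage can inflate the one-sided type I error rate of the
primary z-test well above its nominal level. `blindsr` computes how bad
this can get: the *maximum* type I error rate over all second-stage sample
size rules that depend only on blinded first-stage data.

This is an upper bound by construction. No real sponsor follows the
worst-case rule; the bound is the right object precisely when no binding,
pre-specified reassessment algorithm exists, because then nothing rules the
worst case out.

## Model and assumptions

Each subject contributes a primary response $X$ and a secondary response
$Y$ with

$$(X, Y) \mid G = g \;\sim\; N\!\left(\,(\mu_g, \nu_g),\;
\sigma^2 \begin{pmatrix} 1 & \rho \\ \rho & 1\end{pmatrix}\right),
\qquad g \in \{0, 1\},$$

where $G$ is the hidden allocation. The primary hypothesis is
$H_0\colon \mu_1 \le \mu_0$, tested one-sided at level $\alpha$ with the
known-$\sigma$ z-statistic $Z_N = \sum_i (2G_i - 1)X_i / (\sigma\sqrt N)$
after $N = n_1 + n_2$ subjects. Key simplifications, shared by all
computations here: common variance in both arms and endpoints, 1:1
allocation, a single interim look, and secondary-endpoint distribution
known to the (adversarial) analyst. Under $H_0$ we set
$\mu_0 = \mu_1 = 0$ without loss of generality — the z-statistic is
location-anchored by the known $\sigma$.

## The worst-case machinery

**Posterior allocation.** Under simple randomization, Bayes' theorem gives
per-subject posterior treatment probabilities
$q_j = \varphi_1(x_j, y_j)\,/\,\{\varphi_0(x_j, y_j) +
\varphi_1(x_j, y_j)\}$ (`allocation_posterior()`). Identical arms give
$q_j \equiv 1/2$; a large standardised secondary effect
$|\nu_1 - \nu_0|/\sigma$ pushes every $q_j$ to 0 or 1 even at $\rho = 0$.

**Conditional law of $Z_1$.** Given the blinded stage-1 data, $Z_1$ is
asymptotically normal with mean
$m_1 = \sum_i (2q_i - 1)x_i / (\sigma\sqrt{n_1})$ and variance
$V_1 = 4\sum_i x_i^2 q_i(1 - q_i) / (\sigma^2 n_1)$
(`conditional_moments()`). The same asymptotics apply under balanced
random allocation, for $n_1$ as large as the studies here use; for small
$n_1$ the package offers exact enumeration
(`exact_allocation_posterior()`) and a balance-preserving Metropolis
sampler (`mcmc_sample_allocations()`) whose proposal swaps one treated
with one untreated subject, accepted on the likelihood ratio of the two
swapped subjects only.

**Worst-case $n_2$.** The blinded conditional rejection probability is
$1 - \Phi\{(z_{1-\alpha} - \sqrt{n_1/N}\,m_1)/\sqrt{(n_1 V_1 + n_2)/N}\}$.
Substituting $u = \sqrt{n_1/N}$ makes it a smooth function of
$u \in (0, 1]$ whose derivative has the sign of $z_{1-\alpha}(1-V_1)u -
m_1$; it therefore has at most one interior stationary point,
$\tilde n_2 = \{(z_{1-\alpha}(1 - V_1)/m_1)^2 - 1\}\,n_1$, and that point
is a *maximum* of the conditional error exactly when $V_1 < 1$ and
$m_1 > 0$. `worst_case_n2()` evaluates the conditional error at
$\{n_{2\min}, \tilde n_2$ clamped$, n_{2\max}\}$ and returns the argmax,
which is the exact continuous-in-$n_2$ maximizer in every branch; for
$V_1 > 1$ the interior point is a minimum, so the maximizer is always an
endpoint of the allowed range. An unrestricted design is encoded as
$n_{2\max} = \infty$, whose conditional error is the limit $\alpha$; the
equivalent threshold formulation uses
$z_* = z_{1-\alpha}(1 - V_1)/\sqrt{1 + n_{2\max}/n_1}$ and
$z^* = z_{1-\alpha}(1 - V_1)/\sqrt{1 + n_{2\min}/n_1}$. The candidate-set
form was chosen over a literal three-branch transcription because it is
algebraically equivalent where the branches are unambiguous and remains
exact in the edge cases ($m_1 = 0$, $V_1 = 1$, unbounded $n_{2\max}$);
the test suite holds it to within $10^{-6}$ of a refined
$10^4$-point grid search over 200 random configurations.

**Block randomization.** With balanced blocks of length $\tau$ there are
$K = \binom{\tau}{\tau/2}$ equally likely sequences per block; the block
posterior weighs the product densities of all $\tau$ members
(`block_posterior()`, log-scale accumulation), and the blocked moments
$m_{Z_1}, v_{Z_1}$ sum independent per-block score means and variances
(`block_conditional_moments()`). Smaller blocks unblind more: a $\tau = 2$
block pins each pair down to two hypotheses. The indicator convention is
$1$ = treatment throughout; swapping the arm labels negates $m_{Z_1}$,
which the tests assert. Blocks are fixed, consecutive and full — partial
blocks are rejected rather than guessed. Whether the *second* stage is
also blocked does not enter the conditional-error formula (stage-2 is
simulated as balanced allocation in the full-trial drivers).

## Monte Carlo drivers and their defaults

`estimate_max_type1()` simulates stage-1 data under the null, applies the
worst-case rule per run, and either averages the attained blinded
conditional error (`method = "analytic"`) or completes each trial and
counts rejections (`method = "montecarlo"`). The study conditions are the
package defaults: $n_1 = 144$, $\sigma = 1$, one-sided
$\alpha = 0.025$, secondary effects in $[0, 2]$, 200{,}000 runs, the
restricted variant using $n_2 \in [n_1/2, 4n_1]$; the case studies use
$n_1 = 400$ with lymphocyte ($\nu_0 = 1.8$, $\nu_1 = 0.55$,
$\sigma = 0.31$) and WBC ($\nu_0 = 6.5$, $\nu_1 = 3.8$, $\sigma = 1.57$)
parameterizations, a 10-point $\rho$ grid on $[0, 0.9]$ (the grid spacing
is the package's choice; only the interval is given by the setting), and
optionally $n_2 \in [200, 1600]$.

Numerical and implementation choices worth knowing:

* $n_2$ is continuous in the rule; only the full-trial simulator rounds
  it to the nearest even integer and clamps to the bounds.
* Under random allocation the vectorised engines fix the balanced
  allocation vector instead of permuting it: every statistic computed
  (posteriors, $m_1$, $V_1$, $Z_1$) is symmetric in the subject index, so
  the joint law is unchanged and a per-run permutation would only cost
  time. `simulate_stage1()` itself permutes genuinely.
* In the full-trial z-test driver the second-stage statistic $Z_2$ is
  drawn directly from its exact null distribution, $N(0, 1)$; the t-test
  driver simulates both groups' exact sufficient statistics (means and
  within-group sums of squares, the latter as scaled $\chi^2$ draws) and
  forms the pooled two-sample t with $N - 2$ degrees of freedom. The
  reassessment rule itself always uses the known-$\sigma$ closed form —
  there is no t-specific worst-case rule.
* The t-test driver needs a finite $n_{2\max}$; the unrestricted rule can
  demand unbounded second stages, which have no finite-sample t-test.
* At $|\rho| = 1$ the joint density is singular; the posterior becomes
  the indicator of which arm's deterministic residual $y - \rho x$
  matches, with ties at 1/2.
* Monte Carlo standard errors: standard deviation of per-run conditional
  errors over $\sqrt{n_{\text{runs}}}$ for the analytic estimator,
  binomial for the rejection-counting one.
* Seeding: each driver call consumes a single R random stream, chunked,
  so results are identical for identical `(seed, n_runs)`; grid drivers
  give each grid point its own offset seed, making per-point results
  independent of which other points are requested. Per-run substreams
  were considered and dropped — they only pay off under parallel
  execution, which the package does not use.

The acceptance script (`scripts/acceptance.R`) recomputes the headline
numbers at 200{,}000 runs for the single-configuration estimate, 100{,}000
runs per $\rho$ grid point for the case studies and 50{,}000 datasets per
point for the unblinding correlations; the test suite uses 4{,}000 to
120{,}000 runs per check. These sizes were chosen so every reported
quantity carries a Monte Carlo standard error at least an order of
magnitude below the effects being measured.

## What the generator does and does not emulate

`simulate_stage1()` draws exactly the model above: bivariate normal
responses, exact balance (or blocks, or iid coins), known parameters. It
does not emulate unequal variances, non-normal or discrete endpoints
(the case-study primary endpoint is a relapse *count* in reality; it is
modelled here as normal with the secondary endpoint's $\sigma$, following
the same normal-model computation the bound is derived under), dropout,
staggered entry, or estimation of $(\nu_0, \nu_1, \sigma, \rho)$ from
blinded data. Passing tests therefore certify the computations under the
stated model, not robustness of the bound to departures from it. The
known-distribution assumption makes the bound conservative in the right
way: it is what an adversary with perfect historical information could
achieve.

## A known artifact, and limitations

With $\sigma$ known and *no* secondary effect, the rule still inflates
the z-test: $V_1$ is then the lumped second moment, and stopping early
exactly when the blinded data show excess variance ($V_1 > 1$) buys
rejection probability. Performing a t-test at the final analysis removes
this artifact (the same excess variance inflates the t denominator) and
makes the procedure slightly conservative at zero secondary effect —
both behaviours are asserted in the test suite.

Known limitations: the normal approximation to the conditional law of
$Z_1$ degrades for large standardised secondary effects and very high
$\rho$ (for $n_1 = 144$ it is adequate up to effect 2 and
$\rho \le 0.8$, which the tests check against the MCMC integration);
enumeration is capped at $n_1 \le 14$ and block enumeration at
$\tau \le 12$; and the unblinding correlation $r$ is defined here as the
across-trials Pearson correlation of the unblinded and blinded effect
estimates under the null, computed by simulation.

## A worked example

```{r example, eval = FALSE}
library(blindsr)

params <- fingolimod_params("wbc", rho = 0.5)
design <- trial_design(n1 = 400, n2min = 200, n2max = 1600)

fit <- estimate_max_type1(params, design, n_runs = 5e4, seed = 1)
tidy(fit)

cs <- run_case_study("wbc", n_runs = 5e4, seed = 1)
autoplot(cs)

run_unblinding_study("wbc", n_runs = 2e4, seed = 1)
```
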