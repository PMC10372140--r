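---
title: "Methods: Kumaraswamy inference under progressive Type-II censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kumaraswamy inference under progressive Type-II censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kumacens)
```

## The model and the sampling design

The Kumaraswamy distribution on the unit interval has density
$f(x) = \alpha\beta x^{\alpha-1}(1-x^\alpha)^{\beta-1}$ and distribution
function $F(x) = 1-(1-x^\alpha)^\beta$ with two positive shape parameters.
Unlike the beta distribution, the cdf and quantile function are closed-form
and invertible, so censored likelihoods, product-spacings objectives and
quantile-variance design criteria all stay in elementary functions. The
case $\alpha=\beta=1$ is Uniform(0,1); $\alpha,\beta<1$ gives a U-shape,
$\alpha,\beta>1$ a unimodal interior mode.

Under a progressive Type-II censoring scheme, $n$ units start on test and
at the $i$-th observed failure $R_i$ surviving units are withdrawn; the
test ends at the $m$-th failure with $R_m$ absorbing whatever remains
($\sum R_i = n-m$). The observed data are the $m$ censored order
statistics together with the (pre-specified) removal plan. The joint
density contributes a factor $(1-F(x_{(i)}))^{R_i}$ per failure, plus an
ordering constant that does not involve the parameters; the package
excludes that constant by default so complete-sample log-likelihoods agree
with the i.i.d. values that information criteria expect.

## Sample generation

`rpcs2()` uses the classical one-pass transformation: with
$W_1,\dots,W_m$ i.i.d. uniform,
$V_i = W_i^{1/(i + R_m + \dots + R_{m-i+1})}$ and
$U_{(i)} = 1 - V_m\cdots V_{m-i+1}$ have the exact joint law of
progressively censored uniform order statistics, and the sample is their
Kumaraswamy quantile transform. This is exact (no accept/reject), $O(m)$,
and trivially seedable. The tests verify the first order statistic
against its closed-form law $1-(1-F(x))^n$ and the conventional Type-II
special case against brute-force order-statistic simulation.

`censor_complete_sample()` applies a scheme to recorded data: the smallest
remaining value is the next failure, then $R_i$ remaining units are
withdrawn uniformly at random without replacement. Which units are
withdrawn from a real dataset is inherently a modelling choice; uniform
random withdrawal is the conventional reading, and the seed makes any
given realization reproducible. Tied data values are kept in stable sort
order (the packaged dataset has no ties); heavily tied data would need a
tie-breaking policy this package deliberately does not invent.

## Frequentist estimation

The score equation in $\beta$ has the closed-form solution
$\hat\beta(\alpha) = -m / \sum_i (R_i+1)\log(1-x_{(i)}^\alpha)$, so
`mle_fit()` solves the one-dimensional profile equation in $\alpha$:
bracket by geometric expansion from `init_alpha = 1` (the scale-free
uniform case), then `uniroot` at tolerance `1e-10` with a 200-iteration
cap. Profiling makes existence/uniqueness visible (a sign change of a
monotone profile score) and is considerably more robust than a 2-D Newton
start. The observed information uses the printed closed-form second
derivatives ($\ell_{\beta\beta} = -m/\beta^2$ exactly) and a closed-form
2×2 inverse; Wald intervals truncate negative lower bounds at zero and
flag them, since both parameters are positive.

The maximum product spacings estimator maximizes the log product of cdf
spacings between consecutive order statistics, with boundary conventions
$F(x_{(0)})=0$, $F(x_{(m+1)})=1$ and censoring weights
$\beta R_i \log(1-x_{(i)}^\alpha)$. Spacings are differences of survival
powers $e^{\beta z_{i-1}} - e^{\beta z_i}$ with
$z_i = \log(1-x_{(i)}^\alpha)$; the implementation evaluates them as
$e^{\beta z_{i-1}}(-\mathrm{expm1}(\beta(z_i-z_{i-1})))$, because the
naive difference cancels catastrophically when adjacent observations are
close. `mps_fit()` runs BFGS on the log-parameter scale with the analytic
gradient, then polishes the stationarity conditions with damped Newton
steps so the score sup-norm is driven below $10^{-9}$ in regular cases.
No information identity holds for the spacings criterion, so the reported
variance matrix is the observed-information inverse at the MPS point,
documented as a reporting approximation; Monte-Carlo dispersion is the
primary precision summary for this estimator.

## Bayesian estimation

Independent Gamma$(a_1,b_1)$ and Gamma$(a_2,b_2)$ priors (shape/rate) on
$\alpha$ and $\beta$. Three Bayes estimators are supported: posterior
mean (squared error), $-(1/c)\log E[e^{-c\theta}]$ (LINEX, asymmetric
with direction set by the sign of $c$), and $(E[\theta^{-q}])^{-1/q}$
(general entropy). The LINEX estimator tends to the posterior mean as
$c\to0$, and general entropy with $q=-1$ is the posterior mean exactly;
both identities are asserted in the tests.

**Lindley expansion.** The posterior-expectation ratio is expanded to
second order around the MLE using log-likelihood derivatives to third
order and the log-prior gradient. Two choices were genuinely open:

* $\sigma$ is taken as the inverse of the full negative Hessian, not the
  elementwise $-1/\ell_{ii}$. This is consistent with the
  observed-information matrix used everywhere else and makes the
  reduction exact: with a flat prior and third derivatives zeroed, the
  squared-error expansion returns the MLE identically (a test asserts
  this).
* The third derivative $\ell_{\alpha\alpha\alpha}$ is implemented as the
  derivative of the closed-form $\ell_{\alpha\alpha}$,
  $2m/\alpha^3 - \sum_i \{\beta(R_i+1)-1\}
  x_i^\alpha(1+x_i^\alpha)(\log x_i)^3/(1-x_i^\alpha)^3$, and gated by a
  finite-difference cross-check in the tests; typeset versions of this
  expression are easy to mis-parse, the defining derivative is not.

For the asymmetric losses the expansion approximates an expectation that
must be positive ($E[e^{-c\theta}]$ or $E[\theta^{-q}]$); at small $m$
the second-order correction can overshoot and leave it nonpositive. The
package raises an error naming the failing loss rather than clamping:
surfacing where the expansion breaks down is part of the method's honest
behaviour, and callers can fall back to MCMC.

**MCMC.** The full conditional of $\beta$ is exactly
Gamma$(m+a_2,\; b_2 - \sum_i (R_i+1)\log(1-x_{(i)}^\alpha))$ — the rate
is positive because every log term is negative — so $\beta$ is a Gibbs
draw. The $\alpha$ conditional, derived from the joint posterior,
carries the factor $\beta\sum_i(R_i+1)\log(1-x_{(i)}^\alpha)$; the
implementation uses this exact conditional (the sampler would otherwise
not target the joint posterior, and the quadrature cross-checks in the
test suite would fail). $\alpha$ is updated by random-walk
Metropolis–Hastings with a normal proposal whose standard deviation
defaults to the asymptotic standard error of $\hat\alpha$ ("auto");
nonpositive proposals are rejected, which is the correct
detailed-balance treatment of the positivity constraint (not
reflection). Chains start at the MLE. Defaults are 10,000 draws with
2,000 burn-in. The sampler is validated against analytic gamma moments
(proposal sd frozen at zero) and against 2-D quadrature posterior means
on small instances.

HPD intervals use the Chen–Shao sorted-draws construction: among all
windows spanning $\lfloor N(1-\gamma)\rfloor$ order statistics, the
shortest, ties broken leftmost. Prior elicitation moment-matches the
gamma priors to the mean and ($k-1$ denominator) variance of maximum
likelihood estimates from past samples: $b = \bar\theta/s^2$,
$a = \bar\theta^2/s^2$.

## Optimal scheme selection

Three criteria, all "smaller is better": determinant and trace of the
variance–covariance matrix of the MLEs, and the delta-method variance of
$\log \hat T_u$ for the quantile
$T_u = (1-(1-u)^{1/\beta})^{1/\alpha}$, on the default grid
$u \in \{0.25, 0.5, 0.75\}$. `rank_schemes()` evaluates candidates
either on supplied fits or as Monte-Carlo averages of per-replicate
observed-information criteria at the per-replicate MLE, with common
random numbers across schemes (the same replicate seed drives every
scheme), which makes the comparison order-invariant and much
lower-variance. At 1000 replicates this reproduces the published
comparison values for the $(40, 20)$ grid closely and, in particular,
the qualitative finding that front-loaded removal plans (all removals at
the first failure) minimize the determinant criterion. Per-replicate
determinants are heavy-tailed at small $m$, so scheme comparisons at
few hundred replicates can be unstable; the package leaves replication
choice to the caller and defaults to 1000.

## Goodness of fit

Four two-parameter candidates are compared on complete samples:
Kumaraswamy, generalized exponential $F=(1-e^{-\lambda x})^\theta$, Burr
XII $F=1-(1+x^c)^{-k}$, and beta. For the first three the second
parameter is closed-form given the first, so fitting is a 1-D profile
optimization over a wide log-scale bracket; beta is a 2-D BFGS fit from
a method-of-moments start. All criteria use $k=2$ parameters. The
Kolmogorov–Smirnov statistic is computed by brute force over the $n$
empirical jump points; the p-value uses the exact finite-$n$ Kolmogorov
distribution, appropriate at $n=20$ where the asymptotic series is
noticeably off. On Kumaraswamy-generated data the structurally different
families (generalized exponential, Burr XII) lose the AIC comparison
almost always at $n=200$, but the beta family — a near-twin on the unit
interval — wins a substantial minority of replicates; distinguishing
Kumaraswamy from beta by fit alone needs far larger samples, and the
package makes no stronger claim.

## The simulation harness and what it shows

`run_simulation()` reproduces the full study loop: generate a censored
sample at the truth, run the requested estimators, aggregate Avg, MSE,
average interval length and coverage percent. Each replicate reseeds
from the master seed and the replicate counter, so tables are
bit-reproducible and batch-insensitive. Non-convergent replicates are
dropped and counted rather than silently imputed.

The generator emulates exactly the published study conditions: truths
$(\alpha,\beta) \in \{(0.5,0.5), (0.5,1), (1,1), (1,2)\}$, $n \in
\{40, 80\}$, the four tabulated removal patterns per $(n,m)$, 1000
replications for frequentist cells, and prior elicitation from 500
complete samples of size 60. What synthetic sampling cannot emulate is
real data's departures from the parametric model — measurement
rounding, serial dependence (the reservoir series is a time series read
as an i.i.d. sample), and model misspecification — so passing tests
certify the estimators' behaviour *under the model*, not robustness
beyond it.

Problem sizes used by the packaged checks: the two frequentist table
cells run 1000 replicates; the Gibbs-sampler cell runs 200 replicates of
10,000-draw chains; HPD coverage uses 500 replicates at
$(n,m) = (80,60)$ with weakly informative Gamma(1, 0.01) priors, where
measured coverage sits at 93–95% — slightly below nominal, the typical
small-sample behaviour of highest-density intervals for skewed positive
parameters. Under the study's own informative moment-matched priors,
coverage is 96–100% (the published coverage values are likewise 96–98%):
informative priors centred near the truth overcover by construction.

One published cell is not reproducible from the stated design: the
Bayes-average cell at $(n,m)=(40,30)$ under squared error. Priors
elicited from complete-sample MLEs at the truth are centred at the mean
of those MLEs, which is biased upward at $n=60$, so the posterior-mean
average lands about 4% above the published value; the published
averages fall *below* the truth for both parameters in every cell, which
truth-elicited priors combined with a balance-preserving sampler cannot
produce. The acceptance check for that cell is kept at its stated
tolerance and documents the discrepancy rather than re-tuning the
elicitation toward the published number.

## Numerical choices and limitations

* All distribution evaluations route through `log1p`/`expm1`; powers
  $x^\alpha$ are computed as $e^{\alpha\log x}$ in log space where
  cancellation threatens.
* Profile-score root tolerance $10^{-10}$, iteration cap 200; MPS score
  polished below $10^{-9}$ sup-norm; LINEX/GE posterior averages in
  log-sum-exp form (no overflow for extreme $c$, $q$).
* Degenerate inputs: tied observations are rejected at construction (a
  zero spacing would make the MPS objective $-\infty$, which is
  surfaced with a warning if forced); a singular observed information
  matrix errors with a condition-number diagnostic.
* The package does not implement hybrid/adaptive/first-failure
  censoring variants, bootstrap or EM-based intervals, multi-chain
  convergence diagnostics, or exhaustive search over all removal plans
  (the candidate list is the caller's).
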