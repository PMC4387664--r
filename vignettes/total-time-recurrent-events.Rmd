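---
title: "Simulating and analysing recurrent events on a total time scale"
author: "ttrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing recurrent events on a total time scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttrec)
```

## The model

Recurrent medical events — falls in elderly people, episodes of otitis
media, seizures, relapses — are often driven by a hazard that depends on
*total* time: time since a fixed origin such as disease onset, treatment
start or birth.  The risk process does not reset when an event occurs.
Writing $T_i$ for the time of the $i$-th event and $N(t)$ for the number
of events before $t$, we assume the intensity of $N$ is
$$ Y(t)\,\lambda_0(t)\,z\,e^{\beta^\top x}, $$
the Andersen–Gill counting-process model: $\lambda_0$ is an arbitrary
baseline hazard of total time, $x$ are fixed covariates with log hazard
ratios $\beta$, $z$ is an optional gamma frailty with mean 1 and variance
$\theta$ capturing unobserved inter-patient heterogeneity, and $Y(t)$ is
the at-risk indicator.  Increments are independent of event history; only
for a constant baseline hazard does this coincide with a gap-time
(renewal) model.

## The simulation algorithm

Because the hazard depends on total time, the distribution of the gap
$U_i = T_i - T_{i-1}$ depends on when the previous event happened.  Its
conditional cumulative hazard is
$$ \tilde\Lambda_t(u) = \Lambda(u + t) - \Lambda(t), $$
with $\Lambda(t) = \int_0^t \lambda(s)\,ds$, and
$\exp(-\tilde\Lambda_t(U_i))$ is uniform on $(0,1)$ given $T_{i-1} = t$.
Inverting therefore gives the recursion implemented by
`simulate_subject()`:
$$ t_1 = \Lambda^{-1}(-\log a_1), \qquad
   t_{i+1} = t_i + \tilde\Lambda_{t_i}^{-1}(-\log a_{i+1}), $$
with independent uniforms $a_i$.  Two practical extensions:

* **Risk-free intervals.**  If an event is followed (with probability
  $p$) by a period of length $d$ in which the subject cannot relapse —
  hospitalisation after a fall, treatment courses — the hazard is zero on
  $[t_i, t_i + d]$ and the next recursion starts from $t_i + d$.  In the
  counting-process output the subject simply has no at-risk record over
  the gap.
* **Covariates and frailty.**  A subject with factor
  $c = z e^{\beta^\top x}$ needs no separate derivation:
  $\tilde\Lambda_t^{-1}(u) = \tilde\Lambda_{0,t}^{-1}(u / c)$, so one
  baseline inversion (`scaled_inv_cond_cum_hazard()`) serves every
  subject.

Closed forms are implemented for three families:

| family | $\Lambda(t)$ | $\tilde\Lambda_t^{-1}(u)$ |
|---|---|---|
| Weibull ($\lambda, \nu$) | $\lambda t^\nu$ | $((u + \lambda t^\nu)/\lambda)^{1/\nu} - t$ |
| Gompertz ($\lambda, \alpha$) | $\frac{\lambda}{\alpha}(e^{\alpha t} - 1)$ | $\frac{1}{\alpha}\log(\frac{\alpha}{\lambda}u + e^{\alpha t}) - t$ |
| log-normal ($\mu, \sigma$) | $-\log(1 - \Phi(\frac{\log t - \mu}{\sigma}))$ | via $\Phi^{-1}$ on the log-survival scale |

Any other baseline can be supplied as a `custom` cumulative hazard
function; its inverse is found by geometric bracket expansion from
$[0, 1]$ followed by derivative-free root refinement.

## Numerical choices

* **Inversion tolerance.**  No canonical tolerance exists for the custom
  inversion; we use an absolute gap tolerance of $10^{-10}$ with at most
  200 iterations, tight enough that round-trip errors stay below the
  $10^{-9}$ the closed forms achieve.
* **Gompertz at $\alpha = 0$.**  The printed formula divides by
  $\alpha$; we treat $|\alpha| < 10^{-12}$ as the exponential limit
  $\Lambda(t) = \lambda t$ for continuity.
* **Bounded cumulative hazards.**  For $\alpha < 0$ the Gompertz
  cumulative hazard is bounded by $\lambda/(-\alpha)$; the uniform
  inversion argument only produces an event when $-\log a$ does not
  exceed the remaining mass.  Inversion past the bound returns `Inf`
  ("beyond horizon"), which the simulator maps to censoring.
* **Log-normal tails.**  The textbook inverse evaluates
  $\Phi^{-1}(\exp(\cdot))$ and underflows once the cumulative hazard
  exceeds roughly 30; we work with `pnorm`/`qnorm` on the log scale
  throughout, which is exact at $t = 0$ and stable arbitrarily far out.
* **Events at the censoring time.**  A candidate exactly at $C$ (a
  probability-zero event, but reachable through serialised data) counts
  as an event.

## The synthetic-data generator

`simulate_recurrent()` emulates a cohort of `n` independent subjects:
covariates drawn per subject (Bernoulli, Gaussian, constant, or
balanced-binary assignment of exactly $\lfloor n/2 \rfloor$ ones via a
seeded permutation, mirroring trial randomisation), a gamma frailty,
a censoring time (administrative at $\tau$, or uniform on $[0, \tau]$
for an independent dropout fraction $q$), then the event recursion.
Risk-free decisions are independent Bernoulli draws per event,
independent of covariates and frailty — the minimal model absent any
reason for dependence.  One seeded RNG stream per dataset is consumed in
a documented order (permutation, then per subject: covariates, frailty,
dropout, event uniforms), so a dataset is bit-reproducible from its seed.

The generator intentionally omits several features of real registries:
staggered entry and left truncation, terminal events competing with the
recurrent process, time-varying covariates, and hazards that depend on
the number of previous events.  Passing tests therefore demonstrate
correctness of the stated model, not robustness to those violations.

## Analysis components

`agfit()` maximises the start/stop partial likelihood with Breslow tie
handling (simulated times are continuous, so ties have measure zero and
Breslow keeps reference comparisons simple).  The risk set at an event
time $t$ contains records with $start < t \le stop$ — exactly the
convention the simulator's record writer uses, so risk-free gaps drop
out of the denominator.  Newton–Raphson starts at $\beta = 0$, declares
convergence when the log partial likelihood moves by less than
$10^{-9}$, halves steps that decrease the likelihood, and flags monotone
likelihoods (a coefficient walking past $\pm 20$, or 25 iterations)
instead of returning silently.  The naive variance is the inverse
observed information; the robust variance is the clustered sandwich
$I^{-1}(\sum_g s_g s_g^\top)I^{-1}$ over per-subject summed score
residuals, the standard choice when frailty-induced intra-patient
correlation is ignored by the fitted model.  `nelson_aalen()` estimates
the cumulative hazard with the same at-risk convention.

When the data carry unobserved heterogeneity, the Andersen–Gill
coefficient remains unbiased but the naive variance is too small;
robust standard errors restore the test's level at the cost of wider
intervals.  The acceptance suite checks both halves of that statement by
simulation.

## Power and sample size

`estimate_power()` simulates trials, fits each, applies the design's
Wald test and reports the rejection fraction with its binomial
Monte-Carlo standard error $\sqrt{p(1-p)/n_{sim}}$.  Replicates whose
fit does not converge are dropped and counted, so power denominators are
honest.  `find_sample_size()` doubles $n$ from a lower bound until the
target power is bracketed, bisects on an even grid (default step 4),
then refines to step 2, breaking ties toward smaller $n$; per-replicate
seeds are shared across evaluated $n$ (common random numbers), which
keeps the estimated power curve monotone enough to bisect.

The default `trial_design()` encodes a falls-prevention trial: assumed
two-year incidences of 3.72 (control) and 2.74 (intervention) events per
subject with a Weibull shape of 2 give scales $3.72/2^2 = 0.93$ and
$2.74/2^2 = 0.69$ and a hazard ratio of $0.69/0.93 = 0.74$; follow-up is
two years with 50% uniform dropout, and the robust two-sided Wald test
is taken at the 5% level.  Risk-free durations quoted in weeks convert
to study years as $d/52$ (so 8 weeks is $0.1538$ years); the follow-up
and hazard scales are all on the year scale, so no other conversion
arises.  The intervention arm is simulated through
$\beta = \log(0.74)$ on the balanced indicator, equivalent to
simulating the two scales separately up to rounding of the printed
ratio.

```{r}
trial_design()
```

Problem sizes: the packaged checks run the law checks at $10^4$
subjects, the estimator studies at 200–300 datasets of 100 subjects,
and the sample-size searches at 1000 simulated trials per evaluated
$n$ — large enough that binomial Monte-Carlo error (about 1.3 power
points at 80% power) is small relative to the acceptance tolerances,
and small enough to run on a laptop in minutes.  Production sample-size
calculations should use `nsim = 10000`, which scales linearly.

## Known limitations

* Only time-invariant covariates; effects act proportionally on the
  baseline hazard.
* The frailty is gamma; other mixing distributions change the marginal
  count law.
* `find_sample_size()` assumes power is (stochastically) monotone in
  $n$; exotic designs violating that would need a grid scan instead.
* The Andersen–Gill fit offers Breslow ties only — adequate for
  continuous simulated times, a deliberate non-goal for heavily tied
  registry data.
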