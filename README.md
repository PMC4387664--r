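# ttrec — recurrent events on a total time scale

`ttrec` simulates recurrent-event data whose hazard is defined on a
*total* time scale — time since a fixed origin, with no reset at events —
and provides the analysis machinery needed to design trials with such
data.  It is aimed at biostatisticians planning or evaluating studies
with recurrent endpoints (falls, infections, relapses) analysed with the
Andersen–Gill counting-process model.

## The method

Under the Andersen–Gill model the intensity of the event count $N(t)$ is
$Y(t)\,\lambda_0(t)\,z\,e^{\beta^\top x}$ with baseline hazard
$\lambda_0$ of total time, fixed covariates $x$, and optional gamma
frailty $z$ (mean 1, variance $\theta$).  The gap to the next event,
given the previous event at total time $t$, has conditional cumulative
hazard
$$\tilde\Lambda_t(u) = \Lambda(u+t) - \Lambda(t),$$
and $\exp(-\tilde\Lambda_t(U))$ is standard uniform, so event times can
be generated recursively by inversion:
$t_1 = \Lambda^{-1}(-\log a_1)$,
$t_{i+1} = t_i + \tilde\Lambda_{t_i}^{-1}(-\log a_{i+1})$ with
independent uniforms $a_i$.  Closed-form inverses are implemented for
Weibull, log-normal and Gompertz baselines (numeric inversion for any
custom cumulative hazard), covariates and frailty enter through a single
scaling $\tilde\Lambda_t^{-1}(u/c)$ with $c = z e^{\beta^\top x}$, and
events may be followed by *risk-free intervals* of length $d$ (with
probability $p$) during which the subject leaves the risk set.  Output
is a counting-process `(id, start, stop, status, x...)` table.

On the analysis side the package fits the Andersen–Gill model by
Newton–Raphson on the start/stop partial likelihood (Breslow ties) with
naive and robust (clustered sandwich) standard errors, estimates
cumulative hazards by Nelson–Aalen with discontinuous risk sets, and
estimates power / required sample size for two-arm balanced trials by
simulation.

## Worked example

Simulate 100 subjects over two years from a Weibull baseline
(scale $4/\sqrt2$, shape $0.5$), a Bernoulli(0.5) covariate with log
hazard ratio $\beta = 1$, frailty variance $\theta = 0.3$, and a
three-month risk-free interval after every event; then fit the model:

```r
library(ttrec)
hm  <- hazard_model("weibull", scale = 4 / sqrt(2), shape = 0.5)
eff <- effect_spec(beta = 1, covariates = list(cov_bernoulli(0.5)),
                   frailty_variance = 0.3)
d <- simulate_recurrent(hm, eff, riskfree = riskfree_spec(0.25, 1),
                        censoring = censoring_spec(2), n = 100, seed = 42)
head(d, 3)
#>   id     start         stop status x1
#> 1  1 0.0000000 0.0001804934      1  1
#> 2  1 0.2501805 0.2998577507      1  1
#> 3  1 0.5498578 0.7858912866      1  1

summary(agfit(d))
#> Andersen-Gill fit (Breslow ties, clustered sandwich variance)
#>   100 subjects, 361 records, 296 events; logPL = -1197.9233
#>       coef naive_se robust_se p_robust
#> x1 1.09251  0.11951   0.15207        0
#> Hazard ratios with robust 95% CIs:
#>        HR lower .95 upper .95
#> x1 2.9817    2.2132    4.0171
```

The record gaps (e.g. `0.2998 → 0.5499`) are the risk-free holes: the
subject is off the risk set for 0.25 years after each event, which the
fit's risk sets and the Nelson–Aalen denominators both honour.  The
coefficient recovers $\beta = 1$ within its robust standard error; the
robust SE exceeds the naive one because ignored frailty correlates
events within subjects.

Power for a falls-prevention trial (control two-year incidence 3.72,
hazard ratio 0.74, shape 2, 50% uniform dropout — the packaged default
`trial_design()`):

```r
estimate_power(trial_design(), n = 160, nsim = 1000, seed = 1)
#> Power 0.7890 (MC SE 0.0129) at N = 160 [1000/1000 converged replicates]

find_sample_size(trial_design(), target_power = 0.8, nsim = 1000, seed = 42)$n0
#> [1] 162
```

A command-line wrapper with `simulate` / `analyze` / `power` /
`samplesize` subcommands is installed at `inst/cli/ttrec`.

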