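# lpaa: stage-structured dynamics of cannibalistic flour beetle populations

Flour beetles (*Tribolium*) are a classic laboratory system for nonlinear
population dynamics: their life stages interact through cannibalism, and
manipulating those interactions has famously driven laboratory cultures
into cycles and chaos. This package implements and analyses a
four-stage discrete-time map — the **LPAA model** — in which the adult
population is split into newly emerged (`A1`) and mature (`A2`) cohorts to
account for the sharply reduced fecundity of callow adults, alongside the
classical three-stage **LPA model** for comparison.

On a two-week time step,

```
L(t+1)  = b A2(t) exp(-c1 A2(t))
P(t+1)  = (1 - mu_l) L(t)
A1(t+1) = (1 - mu_p) P(t)
A2(t+1) = A1(t) exp(-c2 A2(t)) + (1 - mu_a) A2(t)
```

with recruitment `b`, stage mortalities `mu_l, mu_p, mu_a`, and
per-mature-adult cannibalism intensities `c1` (on eggs) and `c2` (on newly
emerged adults). The net reproductive number `R0 = b(1-mu_l)(1-mu_p)/mu_a`
separates extinction (`R0 < 1`, globally stable) from persistence
(`R0 > 1`, unique positive steady state with `A2* = ln(R0)/(c1+c2)`).

The package is for ecologists and modellers who want to:

* simulate either map, with projection matrices, Jacobians, steady states,
  invariant-region bounds and primitivity checks (`project_population`,
  `steady_states`, `state_bounds`, `primitivity_index`);
* classify stability — extinction threshold, proved local and global
  bounds on `R0`, the scalar delay-equation reduction of the mature-adult
  dynamics, and `(mu_a, ln b)` stability-region maps (`stability_assessment`,
  `delay_simulate`, `stability_region`);
* run chaos diagnostics: renormalised Lyapunov-exponent computation and
  bifurcation scans with transient removal (`lyapunov_exponent`,
  `bifurcation_scan`, `orbit_period`);
* fit either model to biweekly census data by one-step-forecast weighted
  least squares, with direct larval-mortality estimation and
  adult-cohort reconstruction from total counts (`lpaa_fit`,
  `compare_models`, `qq_residuals`);
* generate synthetic multi-group census experiments with controlled noise
  for end-to-end testing and recovery scoring (`generate_census`,
  `generate_experiment`, `recovery_error`).

## Worked example

```r
library(lpaa)

p <- lpaa_medians()        # median fitted parameters of the 8-group experiment
net_reproductive_number(p)
#> [1] 70.81668
steady_states(p)$E_star
#>         L         P        A1        A2
#>  77.82790  30.71867  30.71867 335.44051
stability_assessment(p)
#> R0 = 70.82; extinction state: unstable
#> positive steady state: outside_proved_region (proved global bound 2.718, local bound 3.607)
primitivity_index(projection_matrix(p))
#> [1] 6
```

`R0` is far above the proved sufficient bounds, yet the dynamics still
settle: the Lyapunov exponent along the orbit is clearly negative,

```r
lyapunov_exponent(p, c(10, 10, 10, 10), n_transient = 5000, n_steps = 2000)
#> Lyapunov exponent: -0.350538 per step (2000 steps, spectral norm)
```

and bifurcation scans in `b`, `c1` and `c2` around these values collapse to
point attractors everywhere — chaos is not intrinsic to this
parameterisation. Fitting a synthetic 8-group experiment (5% observation
noise) recovers the generating parameters:

```r
truth <- lpaa_params(b = 6.4232, mu_l = 0.6053, mu_p = 0.05,
                     mu_a = 0.0358, c1 = 0.0099, c2 = 0.0028)
ex <- generate_experiment(truth, state0 = c(L = 250, P = 5, A1 = 0, A2 = 100),
                          n_groups = 8, seed = 11, noise = "lognormal",
                          cv = 0.05, anchor_adults = TRUE)
fit <- lpaa_fit(ex$censuses, n_starts = 50, seed = 11)
fit
#> LPAA model fitted to 8 census series by one-step forecast SSE
#>        b     mu_l     mu_p     mu_a       c1       c2
#> 6.407890 0.600936 0.106009 0.038546 0.010002 0.002083
#> objective (weighted SSE): 28830
summary(fit)
#> ...
#> forecasts: 64; per-stage SSE: L 5823, P 1350, A 2.166e+04
#> QQ straightness (residual normal-quantile correlation): 0.9675
```

Recruitment and egg cannibalism come back within a few percent; `mu_l` is
estimated directly from the pupae/larvae ratios. See the methods vignette
(`vignettes/lpaa-methods.Rmd`) for the model theory, the numerical choices
behind the Lyapunov and fitting machinery, and what the synthetic
experiments do and do not demonstrate.

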