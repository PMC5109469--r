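# torpormeter

Bayesian detection of daily torpor and estimation of thermoregulatory
parameters from multi-day recordings of core body temperature (T_B, °C) and
mass-specific oxygen consumption (VO2, ml O2/g/hr) in small mammals.

## What it does, and for whom

Daily torpor — a minutes-to-hours bout of actively suppressed metabolism —
is usually scored against fixed T_B thresholds that ignore how much baseline
metabolism varies between individuals. torpormeter is for physiologists and
chronobiologists who want an individualized, fully automated definition
instead, plus estimates of what the thermoregulatory system actually changed
during torpor. The pipeline:

1. **Baseline model.** Each animal's 24-h baseline `alpha` (one value per
   time-of-day bin, K bins per day) follows a *circular second-order trend*
   prior — circular second differences
   `eta_k = alpha_k − 2 alpha_{k−1} + alpha_{k−2} ~ N(0, sigma2²)` — with
   observations `Y_t ~ N(alpha_{t mod K}, sigma1²)`. `fit_sigma2()`
   calibrates `sigma2` hierarchically from a few multi-day recordings of
   non-torpid animals; `fit_baseline()` then fits `alpha` from a *single
   day*. Given the scales the model is linear-Gaussian, so the package
   marginalizes `alpha` exactly (circulant FFT algebra) and runs MCMC only
   over the noise scales.
2. **Torpor detection.** `detect_torpor()` flags a time point as torpor
   when both T_B and VO2 fall strictly below the lower edge of the 99.9%
   posterior predictive interval of the day-1 baseline.
   `torpor_episodes()` / `torpor_stats()` summarize bouts.
3. **Thermoregulatory parameters.** From minimal metabolic points across
   ambient temperatures T_A, Bayesian regressions
   `min T_B = a1·T_A + b1`, `min VO2 = −a2·T_A + b2` and the no-intercept
   conduction law `VO2 = G·(T_B − T_A)` yield, by eliminating T_A, the
   thermogenesis line `VO2 = H·(T_R − T_B)` with feedback gain
   `H = a2/a1` and set-point `T_R = b1 + a1·b2/a2`, summarized as
   posterior means with 89% HPDIs; plus Q10 and an out-of-range predictive
   check at the coldest probe temperature.
4. **Simulation.** A mechanistic generator (heat-balance ODE
   `C dT_B/dt = H(T_R − T_B) − G(T_B − T_A)` with normal/torpid regime
   switching) produces cohorts with known ground truth for end-to-end
   recovery testing, orchestrated by `run_torpor_pipeline()`.

## Worked example

```r
library(torpormeter)
cfg <- pipeline_config(
  seed = 11,
  synthetic = list(n_animals = 3, ta_grid = c(12, 16, 20, 24), bin_width = 30),
  trend = list(n_chains = 2, n_warmup = 300, n_samples = 500))
report <- run_torpor_pipeline(cfg)
report_render(report)
```

prints (true generating values: normal `(G, H, T_R) = (0.228, 5.1, 36.6)`,
torpid `(0.144, 0.437, 32.8)`):

```
torpormeter report (seed 11, config 618424c7)
animals: 12; pooled held-out coverage: tb 0.890, vo2 0.970
induction rate (%):
  ta_12: 100
  ta_16: 100
  ta_20: 100
  ta_24: 100
Q10 by ambient temperature:
  ta_12: 3.231
  ta_16: 4.088
  ta_20: 5.622
  ta_24: 6.978
normal state:
  a1 0.04764  b1 34.86  a2 0.2181  b2 8.058  G 0.2329
  H 5.152 [2.318, 7.663]  T_R 36.62 [36.11, 37.07] (89% HPDI)
torpid state:
  a1 0.2258  b1 25.12  a2 0.1023  b2 3.391  G 0.1381
  H 0.4543 [0.3729, 0.5302]  T_R 32.64 [32.01, 33.25] (89% HPDI)
state shift: G reduction 41%; H reduction 91.2%; T_R drop 3.98 degC; G/H 0.045 -> 0.304
```

Reading it: every simulated animal entered torpor; the Q10 of the normal-to-torpid
VO2 drop climbs from ~3 at 12 °C to ~7
at 24 °C — far above the 2–3 of passive temperature dependence, i.e. the
metabolism is actively suppressed. The fitted state shift recovers the
generating truth: the feedback gain H collapses by ~91% while the set-point
T_R drops only ~4 °C, and the G/H balance moves from set-point-dominated
(0.045) toward ambient-dominated (0.304). The held-out band coverage is the
fraction of non-torpid day-2/3 points inside each animal's 99.9% day-1 band
(T_B coverage sits below nominal here because the generator's slow
set-point wander is fresh on each day — deliberate, mildly out-of-model
realism).

A thin CLI over the same functions lives at `inst/scripts/torpormeter.R`
(`simulate`, `fit-sigma2`, `fit-baseline`, `detect`, `thermo-fit`, `q10`,
`run`).

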