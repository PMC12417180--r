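# psmcea

Treatment-cycle-resolved cost-effectiveness analysis for two-arm oncology
trials, built on a three-state partitioned survival model (PSM).

Published oncology trials report Kaplan–Meier (KM) curves for
progression-free survival (PFS) and overall survival (OS), but rarely the
individual patient data (IPD) behind them — and oncology cost structures are
anything but flat: induction chemotherapy gives way to cheaper maintenance,
drug costs stop at progression, and imaging recurs on its own calendar.
Health-economic tools that price an "average cycle" miss all of this.
`psmcea` is for health-economics analysts and outcomes researchers who need
to go from digitized KM coordinates and per-cycle cost tables to a full
probabilistic cost-effectiveness analysis.

## What the package does

1. **IPD reconstruction.** Digitized curve coordinates plus the published
   number-at-risk table are inverted back to per-patient `(time, event)`
   records with an iterative KM-inversion (Guyot-type) algorithm. Quality is
   scored as RMSE, mean and maximum absolute error of the reconstructed KM
   against the digitized clicks, gated at the conventional thresholds
   (RMSE ≤ 0.05, mean ≤ 0.02, max ≤ 0.05).
2. **Survival modelling.** Log-rank test and Cox hazard ratio validate the
   reconstruction; six accelerated-failure-time families (exponential,
   Weibull, log-normal, log-logistic, Gompertz, generalized gamma) are fit
   by right-censored maximum likelihood, ℓ = Σ_events log f(tᵢ) +
   Σ_censored log S(tᵢ), and the family with minimal AIC = 2k − 2ℓ is
   selected per arm and endpoint for extrapolation.
3. **Partitioned survival model.** At each cycle boundary t_c the cohort is
   split into stable disease, progressed disease and death:
   p_SD = S_PFS(t_c), p_PD = S_OS(t_c) − S_PFS(t_c), p_death = 1 − S_OS(t_c),
   with half-cycle-corrected occupancy (trapezoid of adjacent boundaries).
4. **Cycle-resolved costing.** State-dependent drug costs and state-
   independent care costs are supplied *per treatment cycle*, sampled from
   gamma distributions (mean μ, SD μ·cv), weighted by state occupancy and
   discounted at the cycle midpoint.
5. **Decision analysis.** QALYs from beta-sampled utilities, ICER as the
   ratio of mean increments, net monetary benefit NMB = λ·QALY − cost,
   cost-effectiveness acceptability curves and the expected value of
   perfect information EVPI(λ) = E[maxₐ NMBₐ] − maxₐ E[NMBₐ].

A synthetic-trial generator (`trial_scenario()`, `write_demo_bundle()`)
produces complete, internally consistent input bundles — true IPD from known
laws, digitizer-style curve exports, risk tables and treatment-schedule
cost tables — so the whole pipeline can be exercised with a known ground
truth.

## Worked example

```r
library(psmcea)

sc  <- trial_scenario(seed = 42, n_sims = 1000)  # 300 vs 150 subjects, Q3W cycles
cfg <- write_demo_bundle(sc, "demo")             # curves, risk tables, costs, config
psa <- run_pipeline(cfg, "demo_out", plots = FALSE)
print(psa)
print(attr(psa, "quality"))
```

```
PSA over 1000 simulations (WTP = 268,200/QALY)
  incremental cost: 56832.24 (95% CI 51037.15 to 62970.04)
  incremental QALY: 0.8306 (95% CI 0.6981 to 0.9398)
  ICER: 68422.77 per QALY
  P(cost-effective at reference WTP): 1.000
  endpoint          arm n_points        rmse mean_abs_error max_abs_error pass
1      PFS experimental       60 0.001482010    0.001153849   0.003047740 TRUE
2      PFS      control       60 0.002917464    0.002520554   0.006933375 TRUE
3       OS experimental       60 0.001200734    0.000931305   0.002294842 TRUE
4       OS      control       60 0.001518992    0.000852212   0.007137539 TRUE
```

Reading this: all four digitized curves reconstruct with RMSE well under the
0.05 adequacy gate; the experimental arm gains 0.83 discounted QALYs at an
extra cost of 56,832 currency units, an ICER of ~68,400 per QALY — far below
the 268,200 reference threshold, so the experimental arm is cost-effective
in essentially every simulation. `demo_out/` also receives per-stage CSVs
(reconstructed IPD, fit report, per-cycle traces and costs, CEAC/EVPI
tables) and, with `plots = TRUE`, the standard figures (KM overlays, AIC
bars, state occupancy, per-cycle cost, CE plane, CEAC, EVPI).

The same pipeline runs from a shell:

```sh
inst/cli/psmcea simulate-demo --out demo --seed 42
inst/cli/psmcea run --config demo/config.yaml --out demo_out
```

For real analyses, point the config at your own digitized-curve CSVs
(`time,survival`), risk tables (`time,n_risk`) and cost tables
(`cycle,arm,state,cost` and `cycle,arm,<category...>`);
`config_template("config.yaml")` writes a fully commented starting point.

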