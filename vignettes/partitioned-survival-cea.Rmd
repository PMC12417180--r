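---
title: "Methods: from digitized KM curves to a cycle-resolved cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from digitized KM curves to a cycle-resolved cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

`psmcea` chains five stages: reconstruction of individual patient data (IPD)
from digitized Kaplan–Meier (KM) coordinates, parametric survival modelling,
a three-state partitioned survival model (PSM), treatment-cycle-resolved
costing, and probabilistic decision analysis. This vignette records the
model in each stage, the conventions adopted where the methodology is
genuinely open, and what the package's tests do and do not establish.

## Reconstructing IPD from digitized curves

A digitized curve is a sequence of clicks $(t_k, S_k)$ read off a published
KM plot, plus (ideally) the number-at-risk row printed beneath it. The
inversion follows the iterative KM-inversion approach of Guyot et al.
(2012): the click sequence is partitioned by the risk-table rows; within
each interval the published at-risk drop that the survival ratios cannot
explain is attributed to censoring, assumed uniformly spread over the
interval; event counts at each click are
$d_k = n_k\,(1 - S_k / \hat S_{k-1})$, rounded by largest remainder so each
interval's total is an integer; and the interval's censor count is adjusted
in unit steps (cap 10,000, with a short local scan to step over rounding
plateaus) until the implied at-risk count matches the published one or the
discrepancy cannot be reduced further.

Conventions that required a decision:

* **At-risk comparison point.** Published at-risk counts at time $T$ include
  patients who fail *at* $T$. Each risk row is therefore mapped to the first
  click at or after $T$, and the published count is compared with the
  running count just before that click's events. Events the curve only
  reveals at that click (they truly occurred just before $T$ but between
  clicks) land after the comparison — the one place the time-discretized
  model can put them.
* **Running-estimate anchoring.** Survival ratios are anchored on the
  reconstructed KM value at interval entry rather than the digitized value,
  so integer-rounding drift self-corrects across intervals.
* **Ties and placement.** Events precede censorings at tied times (the
  standard KM convention); censor times sit strictly inside click gaps.
* **Irreducible mismatch.** When no censor count can reconcile the curve
  with the published count (the curve is authoritative), the residual is
  recorded per risk row in the `residual_at_risk` attribute rather than
  forced to zero by discarding events.
* **No risk table.** Censoring is assumed absent before the last click, all
  survivors are censored there, and the cohort size defaults to 100 unless
  a total event count pins it down. The error metrics are scale-dependent,
  so an explicit default is preferable to silent inference.

Quality is scored by evaluating the KM estimator of the reconstruction at
every click: RMSE, mean and maximum absolute error, gated at RMSE ≤ 0.05,
mean ≤ 0.02, max ≤ 0.05. Two properties of this gate are worth
understanding. First, it measures *self-consistency* of the inversion, not
fidelity to the unobserved truth: a monotone but biased digitization (e.g.
a mis-calibrated axis) reconstructs "well" by this measure, which is why
non-monotonicity beyond a small tolerance (0.005 survival units, half the
strictest gate) is refused at read time instead of silently repaired.
Second, in the deep tail — one to four patients at risk — moving a single
subject between event and censoring is unidentifiable from the curve, so a
denser risk table does not always reduce RMSE; the package's tests check
exactness in the censoring-free integer regime and no *systematic*
degradation under refinement, not per-seed monotonicity.

## Parametric survival models

Six accelerated-failure-time families are fit per arm and endpoint by
maximizing the right-censored log-likelihood
$\ell = \sum_{\text{events}} \log f(t_i) + \sum_{\text{censored}} \log S(t_i)$.
Parameterizations are fixed to the forms standard in survival
extrapolation: exponential $S = e^{-\lambda t}$; Weibull
$S = e^{-(t/b)^a}$; log-normal $S = 1 - \Phi((\log t - \mu)/\sigma)$;
log-logistic $S = 1/(1 + (t/\alpha)^\beta)$; Gompertz
$S = \exp(-\tfrac{b}{a}(e^{at}-1))$ with shape $a \in \mathbb{R}$ (a
negative shape plateaus at $e^{b/a} > 0$, the documented exception to
$S \to 0$); generalized gamma in the Prentice $(\mu, \sigma, Q)$ form with
$Q = 0$ reducing to the log-normal. The exponential rate is closed-form
($d / \sum t_i$); the others are maximized by BFGS with numerical gradients
on log-transformed positive parameters, from three deterministic
moment-style starts, with a Nelder–Mead polish; a family whose optimizer
fails is reported and skipped, not fatal. AIC $= 2k - 2\ell$ selects the
extrapolation family; ties break toward fewer parameters, then a fixed
family order. The test suite cross-checks the maximized likelihoods against
an independent AFT implementation (`flexsurv`) to $10^{-4}$.

Between-arm validation statistics — the log-rank test and the Cox hazard
ratio (Breslow ties, Wald 95% CI) — are delegated to the `survival`
package; digitized-data granularity does not warrant anything beyond
Breslow's tie handling.

## The partitioned survival model

At cycle boundaries $t_c = c\Delta$ (default $\Delta$ = 3 weeks, the Q3W
oncology convention; horizon = number of cost-table cycles × $\Delta$):
$p_{SD} = S_{PFS}(t_c)$, $p_{PD} = S_{OS}(t_c) - S_{PFS}(t_c)$,
$p_{death} = 1 - S_{OS}(t_c)$. Because the two curves are fit
independently, extrapolations can cross; crossings are clamped
($p_{PD} = 0$, $p_{SD} = S_{OS}$) and counted rather than prevented by
constrained fitting. Per-cycle occupancy is the mean of adjacent boundary
values — the trapezoid reading of the half-cycle correction — and both
QALYs and costs discount at the cycle midpoint with annual compounding,
$(1+r)^{-t_{mid}}$, consistent with that trapezoid.

Two survival curves do not identify how deaths split between the alive
states. The default convention applies the same per-cycle death probability
in SD and PD: $p_{sd.d} = p_{pd.d} = 1 - S_{OS}(t+\Delta)/S_{OS}(t)$ and
$p_{sd.pd} = \max(0,\, p_{exit\,SD} - p_{death})$ — the only symmetric
assumption derivable from the curves alone. A `pd_first` mode (deaths drawn
from PD occupancy first) is available for sensitivity analysis. Once a
curve reaches zero the corresponding transitions are fixed at 1.

## Costs and utilities

Costs are split into state-dependent drug costs (per arm, state and
treatment cycle) and state-independent care costs (imaging, labs,
supportive care, summed per cycle). Each positive cell with mean $\mu$ is
sampled from a gamma with shape $1/cv^2$ and scale $\mu\,cv^2$; zero-mean
cells stay exactly zero, and $cv = 0$ is the degenerate deterministic path
(used by the exactness tests). The default $cv = 0.20$ mirrors the utility
range below; the distribution family is standard for costs, its spread is
an input. Cycle cost is
$occ_{SD}\,c_{SD} + occ_{PD}\,c_{PD} + (occ_{SD}+occ_{PD})\,c_{indep}$:
state-independent costs are charged to *alive* occupancy by default (dead
patients are not imaged), with a `full`-cohort switch since the convention
is not universal. Costs beyond the table's last cycle are zero — the table
defines the horizon. Utilities are beta-distributed by method of moments
with mean $u$ and SD $= u \times range/2$; the "±20% range" is read as ±2
standard deviations, keeping ~95% of draws inside the stated range. A
requested spread infeasible for a beta mean (SD² ≥ u(1−u)) is refused with
guidance rather than silently truncated.

## Decision analysis

The PSA redraws utilities and the cost cube under one seeded stream
(utilities first, then costs by arm); survival parameters stay at their
maximum-likelihood estimates — uncertainty propagation covers the two
quantities the cost model contributes, and the reconstruction/fit stages
carry their own quality gates. The ICER is the ratio of mean increments
(per-simulation ratios are unstable near zero QALY gain), with dominance
flagged instead of reported as a ratio when signs disagree, and "undefined"
below $10^{-9}$ mean QALY gain. CEAC ties split evenly so the two arms'
curves sum to one; EVPI is computed on the same per-simulation NMB matrix.
The default WTP grid spans 0 to twice the reference threshold in 101
points, wide enough to show the CEAC crossover and the EVPI peak on either
side of the threshold. Reference thresholds (for example 1× and 3× GDP per
capita where that guideline applies) are user inputs; no lookup table is
bundled. Intervals are 2.5/97.5 empirical percentiles throughout. Memory
scales with cycles × arms × simulations for the cost cube only (a few MB at
172 cycles × 1000 simulations); per-cycle intermediates are accumulated,
not stored per simulation.

## The synthetic-trial generator

`trial_scenario()` encodes the study conditions the package is tested
under: a 2:1 trial (300/150) shaped like a contemporary first-line advanced
NSCLC immunotherapy study — 3-week cycles over a 170-cycle (~9.8-year)
horizon, 4 induction cycles then maintenance through cycle 35 (two years of
treatment), no post-progression drug cost, imaging 6-weekly through month
12 then 9-weekly, constant lab/supportive costs, utilities 0.80/0.65,
5% annual discounting, 1000 simulations. Default survival laws are
exponential (PFS medians 0.9/0.5 years; OS built per subject as progression
time plus an independent post-progression time with medians 1.1/1.0 years),
with uniform administrative censoring at 2.5–3.5 years of follow-up.
OS-as-sum guarantees $S_{PFS} \le S_{OS}$ by construction — independent
laws can cross, which is an error mode, not a fixture. Where the literature
motivated a shape but not a number (censoring window, cost magnitudes,
utilities), values were chosen once as field-typical and are not tuned.

The generator emulates exact digitization (clicks sampled from the true KM
step function, optional Gaussian jitter) and truth-consistent risk tables.
It does **not** emulate systematic digitization bias, axis miscalibration,
interval censoring, competing risks, or cost inflation — so a passing
pipeline demonstrates correctness of the *inversion and accounting*, not
robustness to every real-world extraction pathology.

## Numerical choices and problem sizes

Monotonicity repair tolerance 0.005 survival units; time constants fixed at
1 year = 12 months = 365.25/7 weeks; occupancy conservation and transition
clamps enforced to $10^{-9}$; likelihood optimizer reltol $10^{-10}$ with
$10^{-12}$ polish; censor-iteration cap 10,000 per interval. The test suite
runs the statistical checks at sizes chosen to make the assertions sharp on
one CPU in well under a minute each: 2000/arm for hazard-ratio recovery,
1000 null replicates (250/arm) for log-rank size, 50 replicates at n = 500
for AIC family recovery, 30 replicates for the end-to-end
digitize–reconstruct–Cox coverage check, and a full-pipeline run at 1000
simulations for Monte-Carlo consistency of the PSA means with the
deterministic ($cv = 0$, zero utility range) evaluation.

## Known limitations

* Two arms only; no frontier analysis across three or more strategies, no
  EVPPI, and no one-way deterministic sensitivity analysis (cycle-varying
  costs do not reduce to a single parameter to vary).
* PFS/OS crossing is handled by clamping, not by jointly constrained
  fitting; heavy clamping (reported in `n_crossings`) signals that the
  selected families extrapolate incompatibly.
* No cure/spline models, background-mortality tables, tunnel states,
  age-dependent utilities, or currency/inflation handling.
* The reconstruction quality gate certifies self-consistency of the
  inversion, not agreement with the unpublished source data; at-risk
  residuals (`residual_at_risk`) should be inspected when tables and curves
  disagree.
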