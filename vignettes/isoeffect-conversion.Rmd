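---
title: "LQ survival fitting and isoeffect dose conversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LQ survival fitting and isoeffect dose conversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqconvert)
```

## The model

Clonogenic survival after a single dose $d$ (Gy) is described by the
linear-quadratic (LQ) model

$$ S(d) = e^{-\alpha d - \beta d^2}, $$

where $\alpha$ (Gy$^{-1}$) captures single-hit, irreparable lethal damage
and $\beta$ (Gy$^{-2}$) two-hit, repairable sublethal damage. The ratio
$\alpha/\beta$ (Gy) is the dose at which the two contributions are equal;
it is small (≈ 1–4 Gy) for late-responding tissues such as prostate.

A schedule of $n$ fractions of $d$ Gy with complete sublethal-damage
repair between fractions survives as $S(d)^n$ — the assumption is
justified for inter-fraction intervals of 6 h or more, by which time
sublethal repair is complete. `predict_sf()` implements exactly this;
no incomplete-repair or treatment-time factor is modelled.

Two routes convert a fractionated schedule $(n_1, d_1)$ to an equivalent
single dose:

* **Calculated** — the biologically effective dose
  $\mathrm{BED} = n\,d\,(1 + d/(\alpha/\beta))$ is equated between
  schedules, $n_1 d_1 (1 + d_1/(\alpha/\beta)) =
  n_2 d_2 (1 + d_2/(\alpha/\beta))$, and the quadratic solved for $d_2$
  (`equivalent_dose_per_fraction()`). The non-negative root is
  $d_2 = \tfrac{\alpha/\beta}{2}\left(-1 +
  \sqrt{1 + 4\,\mathrm{BED}/(n_2\,\alpha/\beta)}\right)$.
* **Measured** — the observed fractionated surviving fraction is mapped
  through the fitted single-dose curve: the unique non-negative root of
  $\beta d^2 + \alpha d + \ln S = 0$ (`invert_single_dose()`; the
  "$+\sqrt{}$" root is the only non-negative one because the product of
  the roots, $\ln S/\beta$, is negative for $S < 1$).

Under an exactly-LQ world the two routes solve the same equation and
agree to machine precision. The discrepancy statistic
$\mathrm{C/M} = 100\,\times$ calculated/measured (`cm_percent()`)
therefore isolates departures from LQ behaviour: C/M < 100 means the BED
conversion promises more effect from a single hypofractionated dose than
the survival curve actually delivers.

`eqd2()` gives the equivalent total dose in conventional 2 Gy fractions,
$\mathrm{EQD2} = \mathrm{BED}/(1 + 2/(\alpha/\beta))$; a schedule already
at 2 Gy/fraction has EQD2 equal to its physical total dose, which the
tests assert exactly.

## Fitting

Taking logs makes the LQ model linear in the regressors $(-d, -d^2)$
with zero intercept (the curve is forced through $S(0)=1$), so
`fit_lq()` is ordinary least squares via `stats::lm()` — closed-form,
deterministic, no starting values. Choices that matter:

* **Zero-dose points** are accepted but dropped from the regression: in
  a through-origin model they have zero regressors and zero residual, so
  they would only inflate the residual degrees of freedom.
* **Weighting** is off by default. Optionally each point is weighted by
  the delta-method variance of $\ln \mathrm{SF}$,
  $\mathrm{se}_{\ln} = \mathrm{se}/\mathrm{SF}$; weighted and unweighted
  fits coincide when all log-scale errors are equal (tested).
* **Identifiability** requires at least 3 distinct doses overall and 2
  distinct positive doses (two parameters); designs concentrated on one
  dose raise a singular-design error.
* **Nonnegativity**: $\alpha, \beta \ge 0$ physically. Negative
  estimates (possible under extreme noise) are clipped to zero with a
  warning rather than re-fit under constraints — for realistic LQ data
  this triggers only in degenerate cases, and transparency about it was
  preferred over a constrained optimiser.
* **$R^2$** uses the through-origin convention
  $1 - \mathrm{SSR}/\sum y_i^2$ on the log scale; through-origin $R^2$
  conventions differ between packages, so the definition is fixed here.
* **CIs** are asymptotic $t$ intervals from the regression covariance.
  A Monte-Carlo study at the default assay design (below) puts the
  realised coverage of the 95% $\alpha$ interval at ~92%.

Surviving fractions are computed per replicate against the *same
replicate's* control plating efficiency (pooled control as fallback),
cancelling replicate-level plating effects; the aggregation rule is a
package choice since colony-assay protocols rarely state one. Surviving
fractions of exactly 0 cannot enter a log-domain fit; wholly-dead
schedules are dropped with a warning, while zero wells within a schedule
still contribute to that schedule's mean.

## Rounding conventions

Printed radiotherapy tables round half away from zero
(`round_half_away()`): equivalent doses to 2 decimals, BED/EQD2 to 1
decimal, C/M to integer percent. C/M is computed from the 2-decimal
calculated dose — the convention under which every published-style table
cell, including edge cases that differ in the third decimal, reproduces
integer-for-integer. JSON reports keep full-precision values alongside
the rounded ones.

## The synthetic generator

`sim_config()` emulates the colony-formation experiment the analysis
assumes: single doses 0, 1, 2, 4, 6, 8, 12 Gy plus fractionated arms
4 Gy × 2 and 6 Gy × 2, three replicate wells of 2000 cells, baseline
plating efficiency 0.3 (a typical clonogenic value for these prostate
lines). Colony counts are binomial with success probability
$\mathrm{PE}_0 \times S$ — binomial rather than Poisson so counts can
never exceed seeded cells, though at these plating efficiencies the two
are indistinguishable. Everything is reproducible bit-for-bit given
`(seed, config)`.

What the generator does *not* emulate: plate-position and edge effects,
counting error in colony scoring, day-to-day plating-efficiency drift,
and cell-cycle redistribution between fractions. Passing tests therefore
validate the arithmetic pipeline under idealised sampling noise, not the
full error budget of a wet-lab assay.

At this design the 12 Gy wells are almost always empty (expected
survival ~10⁻⁶ at 2000 cells/well) and 8 Gy wells hold 0–3 colonies, so
a *single* simulated assay estimates $\alpha$ with a relative RMSE near
50% — matching the wide $\alpha$ CIs real fits report. The
parameter-recovery study (`parameter_recovery_study()`, 500 simulations;
~15 s) shows the pipeline is nonetheless nearly unbiased: relative bias
−8% for $\alpha$ and +3% for $\beta$, with 92% coverage of the 95%
$\alpha$ interval. The small residual bias comes from averaging
log-transformed noisy survival at the highest informative doses
(Jensen's inequality) and from dropping all-zero schedules.

## The high-dose tail and the overestimation mechanism

`sim_config(tail = ...)` switches the truth model to LQ-with-linear
tail: per fraction, $\ln S$ follows the LQ curve up to a transition dose
$d_T$ and continues linearly with slope $-s$, continuous at $d_T$. This
is a minimal two-parameter stand-in for universal-survival-curve /
linear-quadratic-linear behaviour, in which survival falls nearly
linearly (in log) at high dose; `default_tail()` uses $d_T = 6$ Gy and
$s = 0.8$ Gy$^{-1}$ (final slope $D_0 = 1.25$ Gy), both typical of
published high-dose survival data.

`overestimation_demo()` runs noise-free by design: the exact single-dose
surviving fractions of the truth model are fitted with the LQ model, and
each fractionated arm is converted both ways. Under pure LQ truth C/M is
exactly 100 — deviations elsewhere are thus attributable to model
misspecification alone, which is the mechanism the demonstration
isolates. Under tail truth, C/M < 100 is equivalent to the fitted curve
*under-killing* at the per-fraction dose $d_1$. An unweighted
log-domain fit over 0–12 Gy is dominated by the large 12 Gy deviation
from LQ, which lowers $\hat\beta$ and raises $\hat\alpha$; the fitted
curve consequently over-kills at low doses and under-kills near the
transition. The overestimation therefore appears for the 6 Gy × 2 arm
(whose equivalent single dose, ~10 Gy, lies well into the tail):
C/M = 95 at the fitted ratio, rising toward 100 when the conversion is
recomputed at an inflated $\alpha/\beta$ — whereas the 4 Gy × 2 arm,
whose equivalent dose sits at the transition itself, can show C/M ≥ 100.
This asymmetry is a genuine property of the procedure, not a defect:
which arms exhibit the effect depends on where the fitted curve crosses
the truth, and with real (noisy, tail-bearing) data the crossing point
is not controlled.

## The toy growth simulator

`simulate_growth()` is deliberately minimal: deterministic exponential
regrowth $V(t) = V_0 e^{gt}$ with an instantaneous multiplicative kill
(the LQ per-fraction surviving fraction) on each irradiation day, one
fraction per day from day 0, lognormal measurement noise of a given CV
(mean-one, so measurements are unbiased), and truncation when the true
volume reaches the sacrifice endpoint. Defaults — 0.09 cm³ at
randomisation (short diameter ≈ 0.5 cm under the caliper formula
$V = L W^2/2$, `ellipsoid_volume()`), doubling time ≈ 5 days, 2 cm³
endpoint, measurements every 3 days — are declared assumptions, since
xenograft irradiation calendars are rarely printed. The simulator
supports ordering checks only (equal-BED schedules suppress growth
comparably; total log-kill is $\alpha \times \mathrm{BED}$ at the exact
fitted ratio): no immune, hypoxic or repopulation-rate effects are
modelled, so absolute growth delays are not meaningful.

## Problem sizes and reproducibility

The test suite and the analysis scripts use the sizes quoted above: 500
simulations for the recovery study, 5000 wells for binomial-law checks,
grids of ≤ 100 ratios for monotonicity sweeps — all chosen as the
smallest sizes at which the Monte-Carlo standard errors are comfortably
inside the asserted tolerances. Every stochastic step takes an explicit
seed.

The `analysis/` directory holds the numbered drivers that reproduce the
full analysis (simulate → fit → tables → sensitivity → recovery →
mechanism demo) and write their tables under `results/`; together with
the exported functions they are the package's interface — the workflow
is a sequence of analyses, not a shell tool, so no separate command-line
wrapper is provided.

## Known limitations

* The BED/EQD2 algebra excludes overall-treatment-time and repopulation
  corrections throughout.
* Dose-dependent $\alpha/\beta$ values are *inputs* (per-schedule ratio
  configuration); no dose→ratio law is fitted or assumed.
* The linear-tail truth model is qualitative: it reproduces the
  direction and ratio-dependence of the C/M discrepancy, not any
  particular published magnitude.
* C/M carries no uncertainty statement, because measured equivalent
  doses enter as point values.
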