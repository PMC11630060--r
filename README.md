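# lqconvert

Radiobiology tooling for a question that matters in hypofractionated
radiotherapy planning: **when you convert a fractionated regimen into an
"equivalent" single high dose with the BED formula, how far off are
you?**

The linear-quadratic (LQ) model describes clonogenic survival after a
single dose *d* as

    S(d) = exp(−α·d − β·d²)

with α (Gy⁻¹) the irreparable single-hit kill, β (Gy⁻²) the repairable
two-hit kill, and α/β (Gy) the dose at which the two contribute equally.
With complete sublethal-damage repair between fractions, *n* fractions
of *d* Gy survive as S(d)ⁿ, and isoeffect between schedules is expressed
through the biologically effective dose

    BED = n·d·(1 + d / (α/β)),      EQD2 = BED / (1 + 2 / (α/β)).

`lqconvert` implements both routes from a fractionated schedule to an
equivalent single dose — **calculated** (solve the BED quadratic) and
**measured** (invert the fitted survival curve at the observed
fractionated survival) — and the discrepancy statistic
**C/M = 100 × calculated / measured**. C/M < 100 means the BED
conversion overestimates what a single hypofractionated dose achieves,
the signature of an α/β ratio that rises with dose per fraction. The
package is aimed at radiobiologists and medical physicists analysing
colony-formation assays or stress-testing fractionation conversions.

It covers, end to end:

* clonogenic-assay arithmetic: plating efficiency, surviving fraction,
  replicate aggregation, CSV I/O (`plating_efficiency()`,
  `surviving_fraction()`, `aggregate_replicates()`,
  `read_assay_table()`);
* LQ fitting in the log domain (through-origin least squares) with
  asymptotic CIs and through-origin R² (`fit_lq()`), prediction and
  analytic curve inversion (`predict_sf()`, `invert_single_dose()`);
* isoeffect algebra: `bed()`, `eqd2()`,
  `equivalent_dose_per_fraction()`, `cm_percent()`, conversion and
  BED/EQD2 tables, α/β sensitivity sweeps (`conversion_table()`,
  `schedule_comparison_table()`, `cm_sensitivity()`);
* a synthetic-data module: binomial colony-count assays under LQ or
  LQ-with-linear-tail truth (`sim_config()`, `simulate_assay()`),
  Monte-Carlo parameter recovery (`parameter_recovery_study()`), the
  noise-free overestimation mechanism demo (`overestimation_demo()`),
  and a toy xenograft growth simulator (`simulate_growth()`).

## Worked example

Convert the 4 Gy × 2 and 6 Gy × 2 fractionated arms of a prostate line
(fitted α/β = 1.75 Gy, measured equivalent single doses 7.19 and
9.16 Gy) at the fitted and two elevated α/β ratios:

```r
library(lqconvert)

rows <- tibble::tibble(cell_line = "PC3", n_fractions = 2,
                       dose_per_fraction_gy = c(4, 6),
                       measured_gy = c(7.19, 9.16))
tab <- conversion_table(rows, ratios = c(1.75, 3.46, 4.24))
tab[, c("cell_line", "dose_per_fraction_gy", "ratio",
        "calculated", "measured", "cm")]
#> # A tibble: 6 × 6
#>   cell_line dose_per_fraction_gy ratio calculated measured    cm
#>   <chr>                    <dbl> <dbl>      <dbl>    <dbl> <int>
#> 1 PC3                          4  1.75       5.96     7.19    83
#> 2 PC3                          4  3.46       6.19     7.19    86
#> 3 PC3                          4  4.24       6.27     7.19    87
#> 4 PC3                          6  1.75       8.81     9.16    96
#> 5 PC3                          6  3.46       9.06     9.16    99
#> 6 PC3                          6  4.24       9.17     9.16   100
```

Reading: at the fitted ratio the BED formula claims 5.96 Gy matches
4 Gy × 2, but the survival curve says 7.19 Gy is needed — the single
dose's effectiveness is overestimated by 17 points (C/M = 83). Raising
α/β toward the values fitted at higher doses per fraction closes the
gap (83 → 86 → 87; the 6 Gy arm reaches 100).

The numbered scripts in `analysis/` run the whole workflow — simulate
assays, fit survival curves, rebuild the conversion/discrepancy and
BED/EQD2 tables, sweep C/M over α/β = 1–10 Gy, run the 500-simulation
parameter-recovery study, and demonstrate on synthetic tail-model data
that the overestimation arises from LQ misspecification at high dose —
writing tables to `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

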