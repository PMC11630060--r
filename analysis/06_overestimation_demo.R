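#!/usr/bin/env Rscript
# The mechanism study, noise-free. Under pure LQ truth the BED conversion
# and survival-curve inversion agree exactly (C/M = 100 everywhere), so
# any deviation observed elsewhere is model misspecification, not noise.
# Under an LQ-linear-tail truth - survival falling off more slowly beyond
# ~6 Gy, as universal-survival-curve-type models describe - the fitted LQ
# curve under-kills near the transition, the 6 Gy x 2 arm's measured
# equivalent dose exceeds the calculated one (C/M < 100), and inflating
# the alpha/beta ratio moves C/M back toward 100.

library(lqconvert)

dir.create("results", showWarnings = FALSE)

lq_demo <- overestimation_demo(sim_config())
cat("Pure LQ truth: C/M =", lq_demo$rows$cm, "(exact agreement)\n\n")

cfg <- sim_config(tail = default_tail())
fitted_ratio <- overestimation_demo(cfg)$fit$ratio
demo <- overestimation_demo(cfg, inflated_ratios = 2 * fitted_ratio)
cat("Tail truth (transition 6 Gy, slope 0.8/Gy); LQ fit to its single-dose data:\n")
print(demo$fit)
r6 <- demo$rows[demo$rows$dose_per_fraction_gy == 6, ]
cat(sprintf("\n6 Gy x 2 arm: measured %.2f Gy vs calculated %.2f Gy -> C/M = %d%%\n",
            r6$measured[1], r6$calculated[r6$ratio_source == "fitted"],
            r6$cm[r6$ratio_source == "fitted"]))
cat(sprintf("at doubled alpha/beta (%.1f Gy): C/M = %d%%\n",
            r6$ratio[r6$ratio_source == "supplied"],
            r6$cm[r6$ratio_source == "supplied"]))
write_report(demo$rows, "results/overestimation_demo")

# Toy xenograft comparison: arms with nearly equal log kill track each
# other; the single 8 Gy arm is the first suppressed but regrows on the
# same exponential slope.
traj <- simulate_growth(growth_config(noise_cv = 0), seed = 1)
write_report(traj, "results/growth_trajectories")
endpoints <- dplyr::summarise(dplyr::group_by(traj, group),
                              days_to_endpoint = max(day))
print(endpoints)
cat("Schedules ordered by BED are ordered by time to the 2 cm^3 endpoint.\n")
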