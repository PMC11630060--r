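#!/usr/bin/env Rscript
# Reproduce the discrepancy tables from the published inputs: fitted
# alpha/beta ratios (1.75 Gy PC3, 3.78 Gy DU145), elevated ratios (3.46,
# 4.24 Gy and 6, 10 Gy), and the measured equivalent single doses read
# off the fitted survival curves (7.19/9.16 and 7.93/10.83 Gy).

library(lqconvert)

dir.create("results", showWarnings = FALSE)

pc3_rows <- tibble::tibble(cell_line = "PC3", n_fractions = 2,
                           dose_per_fraction_gy = c(4, 6),
                           measured_gy = c(7.19, 9.16))
du145_rows <- tibble::tibble(cell_line = "DU145", n_fractions = 2,
                             dose_per_fraction_gy = c(4, 6),
                             measured_gy = c(7.93, 10.83))

# Baseline conversion at each line's own fitted ratio, then the same
# conversions at elevated alpha/beta values.
tab1 <- dplyr::bind_rows(conversion_table(pc3_rows, 1.75),
                         conversion_table(du145_rows, 3.78))
tab2 <- conversion_table(pc3_rows, c(1.75, 3.46, 4.24))
tab3 <- conversion_table(du145_rows, c(3.78, 6, 10))
write_report(tab1, "results/table_conversion_baseline")
write_report(tab2, "results/table_conversion_pc3_ratios")
write_report(tab3, "results/table_conversion_du145_ratios")

cat("Baseline C/M (%):", tab1$cm, "\n")
cat("  every value is below 100: the BED conversion overestimates what a\n",
    " single hypofractionated dose achieves.\n")
cat("PC3 at ratios 1.75/3.46/4.24:", tab2$cm[order(tab2$dose_per_fraction_gy)],
    "\nDU145 at ratios 3.78/6/10: ", tab3$cm[order(tab3$dose_per_fraction_gy)],
    "\n  C/M climbs toward 100 as the ratio is raised.\n")

# BED / EQD2 across the xenograft fractionation arms, pairing each
# schedule with the conventional ratio and (for 3 and 8 Gy/F) the
# elevated dose-specific ratios taken as external inputs.
sched <- tibble::tibble(n_fractions = c(10, 5, 6, 1, 2),
                        dose_per_fraction_gy = c(2, 3, 3, 8, 8))
ratios <- list(1.75, c(1.75, 3.46), c(1.75, 3.46), c(1.75, 4.24),
               c(1.75, 4.24))
tab5 <- schedule_comparison_table(sched, ratios)
write_report(tab5, "results/table_bed_eqd2")
cat("\nBED/EQD2 grid written; at 1.75 Gy, 10 x 2 Gy (BED 42.9) pairs with\n",
    "5 x 3 Gy and 1 x 8 Gy, but at the elevated ratios it pairs with\n",
    "6 x 3 Gy (33.6) and 2 x 8 Gy (46.2) - one extra fraction each.\n")
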