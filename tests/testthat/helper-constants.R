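# Published survival-curve parameters and printed table values used as
# golden references across the test files.

pc3 <- list(alpha = 0.1461, beta = 0.08366, ratio = 1.75,
            measured = c(d4x2 = 7.19, d6x2 = 9.16))
du145 <- list(alpha = 0.1981, beta = 0.05237, ratio = 3.78,
              measured = c(d4x2 = 7.93, d6x2 = 10.83))

# Conversion/discrepancy tables: equivalent single doses and C/M by
# cell line, fractionated arm and alpha/beta ratio.
golden_conversions <- tibble::tribble(
  ~cell_line, ~n_fractions, ~dose_per_fraction_gy, ~ratio, ~calculated, ~measured, ~cm,
  "PC3",   2, 4, 1.75, 5.96,  7.19,  83L,
  "PC3",   2, 4, 3.46, 6.19,  7.19,  86L,
  "PC3",   2, 4, 4.24, 6.27,  7.19,  87L,
  "PC3",   2, 6, 1.75, 8.81,  9.16,  96L,
  "PC3",   2, 6, 3.46, 9.06,  9.16,  99L,
  "PC3",   2, 6, 4.24, 9.17,  9.16, 100L,
  "DU145", 2, 4, 3.78, 6.22,  7.93,  78L,
  "DU145", 2, 4, 6.00, 6.43,  7.93,  81L,
  "DU145", 2, 4, 10.0, 6.70,  7.93,  84L,
  "DU145", 2, 6, 3.78, 9.11, 10.83,  84L,
  "DU145", 2, 6, 6.00, 9.37, 10.83,  87L,
  "DU145", 2, 6, 10.0, 9.73, 10.83,  90L
)

# BED/EQD2 schedule table (Gy); ratio paired with schedule as published.
golden_bed_eqd2 <- tibble::tribble(
  ~n_fractions, ~dose_per_fraction_gy, ~ratio, ~bed, ~eqd2,
  10, 2, 1.75, 42.9, 20.0,
   5, 3, 1.75, 40.7, 19.0,
   5, 3, 3.46, 28.0, 17.7,
   6, 3, 1.75, 48.9, 22.8,
   6, 3, 3.46, 33.6, 21.3,
   1, 8, 1.75, 44.6, 20.8,
   1, 8, 4.24, 23.1, 15.7,
   2, 8, 1.75, 89.1, 41.6,
   2, 8, 4.24, 46.2, 31.4
)

# Small deterministic assay: 3 replicates whose surviving fractions at
# the single 4 Gy arm are exactly 0.4, 0.5, 0.6 against per-replicate
# control plating efficiency 0.1.
toy_assay <- function() {
  tibble::tibble(
    cell_line = "TOY",
    n_fractions = 1,
    dose_per_fraction_gy = rep(c(0, 4), each = 3),
    cells_seeded = 1000,
    colonies = c(100, 100, 100, 40, 50, 60),
    replicate = rep(c("R1", "R2", "R3"), 2)
  )
}
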