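#!/usr/bin/env Rscript
# Simulation study: how much does each reference scheme (REST, average,
# linked mastoids, vertex) distort the positive center of mass of scalp
# potentials generated by single dipoles?
#
# 1994 dipoles on a cubic grid (spacing 0.0905, r <= 0.86, z >= 0) are each
# activated along x, y and z with a damped Gaussian burst, projected through
# the three-shell head model onto the 61 scalp electrodes, re-referenced four
# ways, and compared - per dipole, orientation and reference - with the
# infinity-reference CM standard.
#
# Outputs under results/simulation/: error_table.csv, summary.csv, tukey.csv

suppressPackageStartupMessages(library(restcm))
dir.create("results/simulation", recursive = TRUE, showWarnings = FALSE)

mont <- easycap63_montage()
mont <- mont[mont$scalp, ]
class(mont) <- c("eeg_montage", "data.frame")
grid <- build_dipole_grid()
message("lead field: ", nrow(mont), " electrodes x 3 x ",
        nrow(grid$positions), " dipoles")
lf <- leadfield_infinity(head_model(), mont, grid)

res <- run_reference_comparison(head_model(), mont, grid, lf = lf)
print(res)

write.csv(res$error_table, "results/simulation/error_table.csv",
          row.names = FALSE)
write.csv(res$summary, "results/simulation/summary.csv", row.names = FALSE)

tuk <- do.call(rbind, lapply(c("x", "y", "z"), function(o) {
  d <- as.data.frame(res$stats[[o]])
  d$orientation <- o
  d$anova_F <- attr(res$stats[[o]], "anova")$F
  d
}))
write.csv(tuk, "results/simulation/tukey.csv", row.names = FALSE)

overall <- sapply(c("REST", "AR", "LM", "CZ"), function(r)
  mean(res$error_table$err[res$error_table$reference == r]))
message("overall mean CM error by reference:")
print(round(overall, 4))
message("REST is ", ifelse(which.min(overall) == 1, "", "NOT "),
        "the smallest overall.")
message("Note: with this ideally left-right symmetric montage the average ",
        "reference is nearly unbiased for x-oriented dipoles and undercuts ",
        "REST there; see the methods vignette.")
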