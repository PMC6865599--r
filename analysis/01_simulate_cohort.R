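#!/usr/bin/env Rscript
# Simulate a demonstration cohort of phase-coupled "BOLD-like" signals.
#
# Two groups (16 vs 12 subjects, two conditions each) of 210-frame, 90-area
# scans at TR = 2 s. Four planted FC states drive the pairwise phase
# relations through a hidden Markov sequence; state 4's stationary occupancy
# is planted at 0.08 in group A vs 0.05 in group B, the kind of deficit the
# downstream inference should flag. Scan TSVs and ground truth go to
# scratch/ (inputs for the next scripts); the planted-occupancy summary goes
# to results/.

suppressPackageStartupMessages(library(leidar))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

spec <- synthetic_spec(n_group_a = 16, n_group_b = 12, n_conditions = 2,
                       seed = 20260901L)
cohort_dir <- "scratch/demo_cohort"
manifest <- simulate_cohort(spec, cohort_dir)
cat("cohort written:", manifest, "\n")

truth <- jsonlite::read_json(file.path(cohort_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
occ <- as.matrix(truth$planted_occupancy)
man <- data.table::fread(manifest)
stopifnot(nrow(man) == 28 * 2)

summ <- do.call(rbind, lapply(seq_len(ncol(occ)), function(s) {
  data.frame(state = s,
             mean_occupancy_A = mean(occ[man$group == "A", s]),
             mean_occupancy_B = mean(occ[man$group == "B", s]))
}))
summ$planted_difference <- summ$mean_occupancy_A - summ$mean_occupancy_B
data.table::fwrite(summ, "results/01_planted_occupancy.csv")
print(summ, digits = 3)
cat("\nstate 4 carries the planted occupancy deficit (A - B ~ 0.03)\n")
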