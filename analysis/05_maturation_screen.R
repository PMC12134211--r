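#!/usr/bin/env Rscript
# End-to-end maturation screen on synthetic data: six strains spanning
# fast/slow maturation and one bleaching protein, three replicate
# chloramphenicol-chase experiments, decoding-informed genotype labels, and
# per-FP maturation time summaries with recovery against ground truth.

suppressMessages(library(optipool))
dir.create("results", showWarnings = FALSE)

strains <- data.frame(
  strain = c("fastA", "fastB", "midA", "midB", "slowA", "bleachA"),
  c      = c(120,     90,      60,     70,     40,      80),
  alpha  = c(2,       1.5,     1.5,    2,      2.5,     3),
  tau_m  = c(10,      20,      45,     75,     150,     40),
  tau_b  = c(NA,      NA,      NA,     NA,     NA,      250),
  stringsAsFactors = FALSE
)

res <- run_full(strains, n_replicates = 3L, n_lineages_per_strain = 10L,
                p_round_error = 0.038, noise_sd = 0.5, seed = 20260924L)

write.csv(res$fits$per_replicate, "results/fp_fits_per_replicate.csv",
          row.names = FALSE)
write.csv(res$fits$summary, "results/fp_summary.csv", row.names = FALSE)
write.csv(res$recovery, "results/tau_recovery.csv", row.names = FALSE)

cat("per-FP maturation summary (3 replicates):\n")
print(res$fits$summary[, c("fp", "mean_tau_m", "sem", "n_replicates",
                           "reported")], row.names = FALSE)
cat("\nrecovery against generator ground truth:\n")
print(res$recovery[, c("fp", "true_tau_m", "est_tau_m", "rel_error")],
      row.names = FALSE)
cat("\njoin diagnostics:\n")
print(res$join_diagnostics, row.names = FALSE)
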