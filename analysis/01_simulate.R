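#!/usr/bin/env Rscript
# Stage 1: simulate synthetic cohorts for both orientation-judgment
# experiments and write the trial tables plus a cohort manifest.
#
#   Rscript analysis/01_simulate.R [--seed 1] [--reps 30] [--out-dir results]
#
# Cohort: three symmetric-range subjects (generated with the resampling
# variant, the best-supported account) and one asymmetric-range subject
# (plain self-consistent generator).

suppressPackageStartupMessages(library(condobs))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
reps <- as.integer(get_arg("--reps", "30"))
out_dir <- file.path(get_arg("--out-dir", "results"), "synthetic")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

truth1 <- observer_params(4, 16, 4, alpha_cw = 22, beta = 8, sigma_0 = 2.5)
truth2 <- observer_params(6, 18, 4, alpha_cw = 30, alpha_ccw = 12, beta = 8,
                          p_cw = 0.5, sigma_0 = 2.5, experiment = "exp2")

manifest <- list()
simulate_one <- function(id, params, experiment, generator, s) {
  des <- build_design(experiment, reps, seed = seed * 100 + s)
  tab <- simulate_subject(params, des, generator, seed = seed * 1000 + s,
                          subject_id = id)
  path <- file.path(out_dir, paste0(id, ".csv"))
  write_trials(tab, path)
  sp <- split_and_filter(tab)
  message(sprintf(
    "%s: %d trials (%d correct, %d incorrect, %.2f%% excluded) -> %s",
    id, nrow(tab), nrow(sp$correct), nrow(sp$incorrect),
    100 * sp$report$excluded_fraction, path))
  data.frame(subject_id = id, experiment_id = experiment,
             generator = generator, sigma_0 = params$sigma_0,
             seed = seed * 1000 + s, table_file = basename(path))
}

manifest <- rbind(
  simulate_one("S1", truth1, "exp1", "2b-resampled", 1),
  simulate_one("S2", truth1, "exp1", "2b-resampled", 2),
  simulate_one("S3", truth1, "exp1", "2b-resampled", 3),
  simulate_one("A1", truth2, "exp2", "selfconsistent", 4)
)
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
message("manifest -> ", file.path(out_dir, "manifest.csv"))
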