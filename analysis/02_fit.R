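#!/usr/bin/env Rscript
# Stage 2: joint maximum-likelihood fit of the self-consistent observer to
# each subject's correct trials (decision data from all trials).
#
#   Rscript analysis/02_fit.R [--seed 1] [--restarts 10] [--out-dir results]

suppressPackageStartupMessages(library(condobs))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
restarts <- as.integer(get_arg("--restarts", "10"))
out_dir <- get_arg("--out-dir", "results")
syn_dir <- file.path(out_dir, "synthetic")
fit_dir <- file.path(out_dir, "fits")
dir.create(fit_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read.csv(file.path(syn_dir, "manifest.csv"),
                     stringsAsFactors = FALSE)
for (i in seq_len(nrow(manifest))) {
  row <- manifest[i, ]
  tab <- read_trials(file.path(syn_dir, row$table_file))
  sp <- split_and_filter(tab)
  cfg <- fit_config(n_restarts = restarts, seed = seed * 10 + i,
                    experiment = row$experiment_id)
  t0 <- Sys.time()
  fit <- fit_correct_trials(sp$correct, tab, cfg, sigma_0 = row$sigma_0)
  el <- round(as.numeric(Sys.time() - t0, units = "secs"))
  bp <- fit$best_params
  message(sprintf(
    "%s: nll %.1f in %ds; sigma_s (%.2f, %.2f), sigma_m %.2f, alpha (%.1f, %.1f), beta %.1f, p_cw %.3f",
    row$subject_id, fit$nll, el, bp$sigma_s_low, bp$sigma_s_high, bp$sigma_m,
    bp$alpha_cw, bp$alpha_ccw, bp$beta, bp$p_cw))
  out <- list(subject_id = row$subject_id, experiment = row$experiment_id,
              nll = fit$nll, params = unclass(bp),
              restarts = fit$restarts,
              config = list(n_restarts = restarts, seed = cfg$seed,
                            grid_step = cfg$grid_step))
  jsonlite::write_json(out, file.path(fit_dir,
                                      paste0(row$subject_id, "_fit.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
message("fits -> ", fit_dir)
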