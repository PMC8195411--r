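#!/usr/bin/env Rscript
# Stage 3: parameter-free prediction of incorrect-trial estimate
# distributions for every model variant, from the correct-trial fits.
# Writes one CSV per subject with the predicted mean estimate per condition
# and variant next to the observed mean.
#
#   Rscript analysis/03_predict.R [--out-dir results] [--grid-step 0.5]

suppressPackageStartupMessages(library(condobs))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
out_dir <- get_arg("--out-dir", "results")
grid_step <- as.numeric(get_arg("--grid-step", "0.5"))
syn_dir <- file.path(out_dir, "synthetic")
fit_dir <- file.path(out_dir, "fits")
pred_dir <- file.path(out_dir, "predictions")
dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read.csv(file.path(syn_dir, "manifest.csv"),
                     stringsAsFactors = FALSE)
models <- c("1a", "1b", "2a", "2b", "2c")
for (i in seq_len(nrow(manifest))) {
  row <- manifest[i, ]
  tab <- read_trials(file.path(syn_dir, row$table_file))
  inc <- split_and_filter(tab)$incorrect
  fj <- jsonlite::read_json(file.path(fit_dir,
                                      paste0(row$subject_id, "_fit.json")),
                            simplifyVector = TRUE)
  pars <- do.call(observer_params, fj$params[
    c("sigma_s_low", "sigma_s_high", "sigma_m", "alpha_cw", "alpha_ccw",
      "beta", "p_cw", "sigma_0", "lapse", "experiment")])
  dsets <- lapply(models, function(mid)
    predict_incorrect(pars, inc, mid, grid_step = grid_step))
  names(dsets) <- models
  summ <- mean_estimate_summary(inc, dsets)
  path <- file.path(pred_dir, paste0(row$subject_id, "_means.csv"))
  write.csv(summ$per_condition, path, row.names = FALSE)
  message(sprintf("%s: %d incorrect-trial conditions -> %s",
                  row$subject_id, nrow(summ$per_condition), path))
}
message("predictions -> ", pred_dir)
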