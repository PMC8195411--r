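# Parameter-free prediction, the omniscient bound, normalization, bootstrap
# and the summary statistics.

sim_incorrect <- function(params, generating_model = "selfconsistent",
                          seed = 50, reps = 70, experiment = "exp1") {
  d <- build_design(experiment, reps, seed = seed)
  tab <- simulate_subject(params, d, generating_model, seed = seed + 1)
  split_and_filter(tab)$incorrect
}

test_that("prior-only predictions ignore the noise level and the
           uncertainty heuristic tracks it", {
  p <- exp1_params()
  inc <- sim_incorrect(p)
  d1a <- predict_incorrect(p, inc, "1a", grid_step = 0.5)
  d1b <- predict_incorrect(p, inc, "1b", grid_step = 0.5)
  k_lo <- names(d1a)[grepl("\\|low\\|cw", names(d1a))][1]
  th <- d1a[[k_lo]]$theta
  k_hi <- sub("low", "high", k_lo)
  expect_lt(max(abs(d1a[[k_lo]]$bin_probs - d1a[[k_hi]]$bin_probs)), 1e-9)
  expect_equal(predictive_mean(d1b[[k_lo]]), 3, tolerance = 0.01)
  expect_equal(predictive_mean(d1b[[k_hi]]), 18, tolerance = 0.01)
})

test_that("table log likelihood counts bin surprisals and ignores trial
           order", {
  p <- exp1_params()
  inc <- sim_incorrect(p)
  dset <- predict_incorrect(p, inc, "2a", grid_step = 0.5)
  ll <- table_loglik(dset, inc)
  expect_true(is.finite(ll) && ll < 0)
  shuf <- inc[sample.int(nrow(inc)), ]
  expect_equal(table_loglik(dset, shuf), ll, tolerance = 1e-9)
  # one-trial check against the bin probability
  one <- inc[1, ]
  pd <- dset[[condobs:::.condition_key(one$theta_deg, one$noise_level,
                                       one$true_category)]]
  b <- findInterval(one$estimate_deg, pd$bin_edges)
  expect_equal(table_loglik(dset, one),
               log(max(pd$bin_probs[b], 1e-6)), tolerance = 1e-12)
})

test_that("omniscient likelihood is counting-exact and bounds every model", {
  tiny <- data.frame(theta_deg = c(3, 3, 6), noise_level = "low",
                     true_category = "cw", estimate_deg = c(4.1, 4.2, 2))
  # condition theta=6: single trial -> 0; theta=3: both in [4, 4.5) -> 0
  expect_equal(omniscient_loglik(tiny), 0)
  tiny$estimate_deg <- c(4.1, 5.3, 2)
  expect_equal(omniscient_loglik(tiny), 2 * log(0.5))
  p <- exp1_params()
  inc <- sim_incorrect(p)
  for (mid in c("1a", "1b", "2a")) {
    dset <- predict_incorrect(p, inc, mid, grid_step = 0.5)
    expect_gte(omniscient_loglik(inc), table_loglik(dset, inc))
  }
})

test_that("normalized scores anchor Model 1a at 0 and the bound at 1", {
  expect_equal(normalized_loglik(-500, -500, -100), 0)
  expect_equal(normalized_loglik(-100, -500, -100), 1)
  expect_equal(normalized_loglik(-300, -500, -100), 0.5)
  expect_error(normalized_loglik(-1, -1, -1), "degenerate")
})

test_that("stratified bootstrap is deterministic, honest about constants,
           and calibrated for a mean", {
  tab <- data.frame(theta_deg = 0, noise_level = "low",
                    true_category = "cw")
  set.seed(99)
  tab <- tab[rep(1, 10000), ]
  tab$estimate_deg <- rnorm(10000)
  ci <- bootstrap_ci(function(t) mean(t$estimate_deg), tab, n_boot = 200,
                     seed = 3)
  ci2 <- bootstrap_ci(function(t) mean(t$estimate_deg), tab, n_boot = 200,
                      seed = 3)
  expect_identical(ci, ci2)
  half <- (ci[["hi"]] - ci[["lo"]]) / 2
  expect_lt(abs(half - 1.96 / 100) / (1.96 / 100), 0.3)
  cst <- bootstrap_ci(function(t) 7, tab, n_boot = 50, seed = 1)
  expect_identical(unname(cst), c(7, 7, 7))
})

test_that("mean-estimate summary recovers perfect predictions and flags the
           flip model's underestimation of resampled data", {
  p <- exp1_params()
  inc <- sim_incorrect(p, "2b-resampled", seed = 60)
  d2a <- predict_incorrect(p, inc, "2a", grid_step = 0.5)
  summ <- mean_estimate_summary(inc, list(`2a` = d2a))
  # data generated with resampling is more repulsed than the flip model
  sgn <- condobs:::category_sign(summ$per_condition$true_category)
  expect_gt(mean(sgn * (summ$per_condition$data_mean -
                          summ$per_condition$mean_2a)), 0)
  # scoring a table whose estimates sit at the predicted means is perfect
  fake <- inc
  keys <- condobs:::.condition_key(inc$theta_deg, inc$noise_level,
                                   inc$true_category)
  mus <- vapply(d2a[keys], predictive_mean, numeric(1))
  fake$estimate_deg <- unname(mus)
  s2 <- mean_estimate_summary(fake, list(`2a` = d2a))
  expect_lt(s2$metrics$mse, 1e-12)
  expect_gt(s2$metrics$r, 0.999)
})

test_that("asymmetric priors produce the cw/ccw estimate asymmetry and
           symmetric ones do not", {
  p2 <- exp2_params()
  inc2 <- sim_incorrect(p2, seed = 70, experiment = "exp2")
  asym <- asymmetry_statistic(inc2, n_boot = 100, seed = 1)
  expect_gt(asym$cw_mean, asym$ccw_mean)
  expect_gt(asym$difference[["lo"]], 0)
  p1 <- exp1_params()
  inc1 <- sim_incorrect(p1, seed = 71)
  asym1 <- asymmetry_statistic(inc1, n_boot = 100, seed = 1)
  expect_lt(asym1$difference[["lo"]], 0)
  expect_gt(asym1$difference[["hi"]], 0)
})

test_that("resampled-generator cohorts rank the variants as expected over
           seeds", {
  p <- exp1_params()
  d <- build_design("exp1", 70, seed = 80)
  # predictions are parameter-free and shared across seeds
  all_cells <- expand.grid(theta_deg = d$orientations,
                           noise_level = c("low", "high"),
                           stringsAsFactors = FALSE)
  all_cells$true_category <- ifelse(all_cells$theta_deg >= 0, "cw", "ccw")
  zero <- all_cells[all_cells$theta_deg == 0, ]
  zero$true_category <- "ccw"
  all_cells <- rbind(all_cells, zero)
  # +/-21 deg at low noise: incorrect choices essentially never happen there
  all_cells <- all_cells[!(abs(all_cells$theta_deg) == 21 &
                             all_cells$noise_level == "low"), ]
  dsets <- lapply(c("1a", "2a", "2b"), function(mid)
    predict_incorrect(p, all_cells, mid, grid_step = 0.5))
  names(dsets) <- c("1a", "2a", "2b")
  ranks <- vapply(1:10, function(s) {
    tab <- simulate_subject(p, d, "2b-resampled", seed = 300 + s)
    inc <- split_and_filter(tab)$incorrect
    inc <- inc[!(abs(inc$theta_deg) == 21 & inc$noise_level == "low"), ]
    ll <- vapply(dsets, table_loglik, numeric(1), incorrect_table = inc)
    omni <- omniscient_loglik(inc)
    nl <- vapply(ll, normalized_loglik, numeric(1), ll_1a = ll[["1a"]],
                 ll_omni = omni)
    c(nl[["2a"]] > 0, nl[["2b"]] >= nl[["2a"]], nl[["2b"]] > 0)
  }, logical(3))
  expect_gte(sum(ranks[1, ]), 6)   # flip model above the prior-only anchor
  expect_equal(sum(ranks[2, ]), 10) # resampling at least matches the flip
  expect_equal(sum(ranks[3, ]), 10) # the generating variant scores best
})

test_that("omniscient bound exceeds the prior-only anchor and bootstrap CIs
           of the normalized scores cover their point estimates", {
  p <- exp1_params()
  inc <- sim_incorrect(p, "2b-resampled", seed = 90)
  d1a <- predict_incorrect(p, inc, "1a", grid_step = 0.5)
  expect_gt(omniscient_loglik(inc), table_loglik(d1a, inc))
  rep <- compare_models(p, inc, models = c("1a", "2a"), n_boot = 100,
                        seed = 4, grid_step = 0.5)
  expect_true(all(rep$normalized_ci$lo <= rep$normalized_ci$point + 1e-12))
  expect_true(all(rep$normalized_ci$hi >= rep$normalized_ci$point - 1e-12))
})
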