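# Designs, the forward simulator, trial IO and filtering.

test_that("designs reproduce the two experiments' trial counts and balance", {
  d1 <- build_design("exp1", 70, seed = 1)
  expect_equal(nrow(d1$trials), 2100)
  expect_length(d1$orientations, 15)
  expect_equal(d1$noise_sigmas, c(low = 3, high = 18))
  d2 <- build_design("exp2", 70)
  expect_equal(nrow(d2$trials), 1820)
  expect_length(d2$orientations, 13)
  expect_equal(d2$noise_sigmas, c(low = 6, high = 18))
  counts <- table(d2$trials$theta_deg, d2$trials$noise_level)
  expect_true(all(counts == 70))
  expect_error(build_design("exp3"))
})

test_that("simulation is a deterministic function of the seed", {
  p <- exp1_params()
  d <- build_design("exp1", 5, seed = 2)
  a <- simulate_subject(p, d, seed = 10)
  b <- simulate_subject(p, d, seed = 10)
  c <- simulate_subject(p, d, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$estimate_deg, c$estimate_deg))
})

test_that("reference-orientation trials get a fair a-priori category", {
  p <- exp1_params()
  d <- build_design("exp1", 500, seed = 3)
  tab <- simulate_subject(p, d, seed = 12)
  z <- tab[tab$theta_deg == 0, ]
  expect_gte(nrow(z), 1000)
  expect_lt(abs(mean(z$choice_correct) - 0.5), 0.03)
  expect_true(all(tab$choice_correct == (tab$choice == tab$true_category)))
})

test_that("noise-free chain reproduces the posterior-mean estimate exactly", {
  p <- observer_params(3, 18, sigma_m = 0, alpha_cw = 21, beta = 8,
                       sigma_0 = 0)
  d <- build_design("exp1", 3, seed = 4)
  tab <- simulate_subject(p, d, seed = 13)
  mod <- observer_model(p)
  corr <- tab[tab$choice_correct, ][1:20, ]
  expected <- vapply(seq_len(nrow(corr)), function(i)
    estimate_posterior_mean(corr$m[i], corr$choice[i],
                            condobs::sigma_s_for(p, corr$noise_level[i]),
                            mod$priors[[corr$choice[i]]], mod$grid),
    numeric(1))
  expect_equal(corr$estimate_deg, expected, tolerance = 1e-9)
  # and nothing is excluded without motor noise or lapses
  expect_equal(split_and_filter(tab)$report$excluded_fraction, 0)
})

test_that("choice frequencies agree with the psychometric function
           (chi-squared over 20 seeds)", {
  p <- exp1_params()
  mod <- observer_model(p)
  d <- build_design("exp1", 70, seed = 5)
  pvals <- vapply(1:20, function(s) {
    tab <- simulate_subject(p, d, seed = 100 + s)
    ag <- aggregate(cbind(ncw = tab$choice == "cw", n = rep(1, nrow(tab))),
                    by = list(theta = tab$theta_deg,
                              noise = tab$noise_level), FUN = sum)
    pr <- condobs:::psychometric_by_row(mod, ag$theta, ag$noise)
    pr[ag$theta == 0] <- 0.5
    chi <- sum((ag$ncw - ag$n * pr)^2 / pmax(ag$n * pr * (1 - pr), 1e-9))
    pchisq(chi, df = nrow(ag), lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("incorrect-trial rates track the psychometric within binomial
           error", {
  p <- exp1_params()
  mod <- observer_model(p)
  d <- build_design("exp1", 70, seed = 6)
  tab <- simulate_subject(p, d, seed = 14)
  ag <- aggregate(cbind(ninc = !tab$choice_correct, n = rep(1, nrow(tab))),
                  by = list(theta = tab$theta_deg, noise = tab$noise_level),
                  FUN = sum)
  pr <- condobs:::psychometric_by_row(mod, ag$theta, ag$noise)
  p_inc <- ifelse(ag$theta > 0, 1 - pr, ifelse(ag$theta < 0, pr, 0.5))
  lo <- qbinom(0.025, ag$n, p_inc)
  hi <- qbinom(0.975, ag$n, p_inc)
  inside <- ag$ninc >= lo & ag$ninc <= hi
  expect_gte(sum(inside), nrow(ag) - 4)
})

test_that("trial tables round-trip through CSV losslessly", {
  p <- exp1_params()
  tab <- simulate_subject(p, build_design("exp1", 2, seed = 7), seed = 15,
                          subject_id = "RT1")
  path <- tempfile(fileext = ".csv")
  write_trials(tab, path)
  back <- read_trials(path)
  for (cl in names(back)) {
    if (is.numeric(tab[[cl]])) {
      expect_equal(back[[cl]], as.numeric(tab[[cl]]), tolerance = 1e-12)
    } else {
      expect_equal(as.character(back[[cl]]), as.character(tab[[cl]]))
    }
  }
  # schema violations are named
  df <- utils::read.csv(path)
  df$estimate_deg <- NULL
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_trials(path2), "estimate_deg")
  # a real-data file without generator columns loads with NA
  df2 <- utils::read.csv(path)
  df2$m <- df2$m_m <- df2$n_draws <- NULL
  path3 <- tempfile(fileext = ".csv")
  write_trials(df2, path3)
  real <- read_trials(path3)
  expect_true(all(is.na(real$m)))
})

test_that("inconsistent estimates are excluded by the feedback-corrected
           sign rule", {
  base <- data.frame(
    subject_id = "X", experiment_id = "exp1", trial_index = 1:6,
    theta_deg = c(4, 4, -4, -4, 4, 4), noise_level = "low",
    sigma_s_deg = 3,
    true_category = c("cw", "cw", "ccw", "ccw", "cw", "cw"),
    choice = c("cw", "cw", "ccw", "cw", "ccw", "ccw"),
    choice_correct = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    estimate_deg = c(4, -6, -3, -5, 6, -2), consistent = TRUE,
    stringsAsFactors = FALSE)
  sp <- split_and_filter(base)
  # row 2: correct cw choice but negative estimate -> excluded
  # row 6: feedback says cw but estimate negative -> excluded
  expect_equal(sp$report$n_excluded, 2)
  expect_equal(sp$report$excluded_fraction, 2 / 6)
  expect_equal(nrow(sp$correct), 2)
  expect_equal(nrow(sp$incorrect), 2)
  # estimate exactly 0 is never flagged
  base$estimate_deg[2] <- 0
  expect_equal(split_and_filter(base)$report$n_excluded, 1)
})

test_that("lapses inject excludable trials at roughly the lapse rate", {
  p <- observer_params(3, 18, 4, alpha_cw = 21, beta = 8, sigma_0 = 0,
                       lapse = 0.2)
  tab <- simulate_subject(p, build_design("exp1", 20, seed = 8), seed = 16)
  frac <- split_and_filter(tab)$report$excluded_fraction
  # a uniform lapse lands on the wrong side roughly half the time
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.2)
})
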