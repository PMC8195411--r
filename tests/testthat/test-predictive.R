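# Binned predictive estimate distributions: normalization, closed forms,
# mirror symmetry, repulsion and noise orderings, grid stability, and a
# Monte-Carlo spot check (the full oracle sweep lives in the acceptance
# tests).

test_that("all variants produce normalized distributions", {
  mod <- observer_model(exp1_params())
  for (mid in c("1a", "1b", "2a", "2b", "2c", "selfconsistent")) {
    for (cc in c("correct", "incorrect")) {
      pd <- predictive_distribution(mod, 6, "high", mid, cc)
      expect_lt(abs(sum(pd$bin_probs) - 1), 1e-6)
      expect_true(all(pd$bin_probs >= 0))
      expect_equal(pd$bin_edges[2] - pd$bin_edges[1], 0.5)
    }
  }
})

test_that("prior-only incorrect-trial distribution is the motor-noise
           Gaussian around the prior mean, for both noise levels", {
  mod <- observer_model(exp1_params())
  mu <- prior_mean(mod$priors$cw, mod$grid)
  for (nl in c("low", "high")) {
    pd <- predictive_distribution(mod, 6, nl, "1a", "incorrect")
    exact <- pnorm((pd$bin_edges[-1] - mu) / 2) -
      pnorm((pd$bin_edges[-length(pd$bin_edges)] - mu) / 2)
    expect_lt(max(abs(pd$bin_probs - exact)), 1e-6)
  }
})

test_that("uncertainty-only distribution has mean sigma_s and SD sigma_0", {
  mod <- observer_model(exp1_params(sigma_0 = 2.5))
  pd_lo <- predictive_distribution(mod, 6, "low", "1b", "incorrect")
  pd_hi <- predictive_distribution(mod, 6, "high", "1b", "incorrect")
  expect_equal(predictive_mean(pd_lo), 3, tolerance = 0.01)
  expect_equal(predictive_mean(pd_hi), 18, tolerance = 0.01)
  expect_lt(abs(predictive_sd(pd_hi) / 2.5 - 1), 0.01)
})

test_that("mirrored conditions give mirrored distributions under symmetric
           parameters", {
  mod <- observer_model(exp1_params())
  for (mid in c("2a", "2b", "selfconsistent")) {
    for (cc in c("correct", "incorrect")) {
      a <- predictive_distribution(mod, 9, "low", mid, cc)
      b <- predictive_distribution(mod, -9, "low", mid, cc)
      expect_lt(max(abs(a$bin_probs - rev(b$bin_probs))), 1e-6)
    }
  }
})

test_that("resampling and reweighting repulse estimates at least as much as
           the plain decision flip, and high noise more than low", {
  mod <- observer_model(exp1_params())
  for (nl in c("low", "high")) {
    for (th in c(0, 3, 9, 15)) {
      m2a <- predictive_mean(predictive_distribution(mod, th, nl, "2a",
                                                     "incorrect",
                                                     category = "cw"))
      m2b <- predictive_mean(predictive_distribution(mod, th, nl, "2b",
                                                     "incorrect",
                                                     category = "cw"))
      m2c <- predictive_mean(predictive_distribution(mod, th, nl, "2c",
                                                     "incorrect",
                                                     category = "cw"))
      expect_gte(m2b, m2a - 1e-9)
      expect_gte(m2c, m2a - 1e-9)
    }
  }
  for (mid in c("1b", "2a", "2b", "2c")) {
    lo <- predictive_mean(predictive_distribution(mod, 6, "low", mid,
                                                  "incorrect"))
    hi <- predictive_mean(predictive_distribution(mod, 6, "high", mid,
                                                  "incorrect"))
    expect_gt(abs(hi), abs(lo))
  }
})

test_that("decision-flip incorrect-trial means are approximately constant
           across stimulus orientation", {
  mod <- observer_model(exp1_params())
  for (nl in c("low", "high")) {
    means <- vapply(c(0, 3, 6, 9, 12), function(th)
      predictive_mean(predictive_distribution(mod, th, nl, "2a", "incorrect",
                                              category = "cw")), numeric(1))
    expect_lt(diff(range(means)) / mean(means), 0.15)
  }
})

test_that("marginal distribution is the psychometric mixture of the
           conditional ones", {
  mod <- observer_model(exp1_params())
  th <- 6; nl <- "high"
  p_corr <- psychometric(mod, th, nl)
  pc <- predictive_distribution(mod, th, nl, "2a", "correct")
  pi <- predictive_distribution(mod, th, nl, "2a", "incorrect")
  pm <- predictive_distribution(mod, th, nl, "2a", "marginal")
  mix <- p_corr * pc$bin_probs + (1 - p_corr) * pi$bin_probs
  expect_lt(max(abs(pm$bin_probs - mix / sum(mix))), 1e-9)
})

test_that("a condition that essentially never occurs raises an error", {
  mod <- observer_model(exp1_params())
  expect_error(predictive_distribution(mod, 30, "low", "2a", "incorrect"),
               "empty condition")
  expect_error(predictive_distribution(mod, 0, "low", "2a", "incorrect"),
               "a-priori category")
})

test_that("halving the grid step moves predicted means by less than
           0.05 deg", {
  p <- exp1_params()
  m1 <- observer_model(p, default_grid(p, step = 0.2))
  m2 <- observer_model(p, default_grid(p, step = 0.1))
  for (spec in list(c("2a", "incorrect"), c("selfconsistent", "correct"),
                    c("2b", "incorrect"))) {
    a <- predictive_mean(predictive_distribution(m1, 6, "high", spec[1],
                                                 spec[2]))
    b <- predictive_mean(predictive_distribution(m2, 6, "high", spec[1],
                                                 spec[2]))
    expect_lt(abs(a - b), 0.05)
  }
})

test_that("grid predictions match forward simulation (spot check)", {
  p <- exp1_params()
  mod <- observer_model(p)
  for (spec in list(list("2a", "incorrect"), list("2b", "incorrect"),
                    list("selfconsistent", "correct"))) {
    pd <- predictive_distribution(mod, 6, "low", spec[[1]], spec[[2]])
    emp <- oracle_histogram(p, 6, "low", spec[[1]], spec[[2]],
                            pd$bin_edges, n = 1e5, seed = 3)
    expect_lt(total_variation(pd$bin_probs, emp), 0.02)
  }
})
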