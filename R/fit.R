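# Joint maximum-likelihood fit of the self-consistent observer.
#
# The likelihood (one term per categorical choice over all trials, one term
# per estimate over correct trials) is evaluated on a coarser fitting grid
# with all conditions of a (category, noise) group batched through shared
# Toeplitz kernels and a shared bin matrix, which brings one evaluation down
# to tens of milliseconds so that multi-restart Nelder-Mead is feasible.

#' Fit configuration
#'
#' @param n_restarts Number of random Nelder-Mead restarts (default 30).
#' @param seed Integer seed controlling the random initial values.
#' @param experiment `"exp1"` (fixes `p_cw = 0.5` and a shared prior width)
#'   or `"exp2"` (asymmetric widths, free `p_cw`).
#' @param bounds Named list of `c(lo, hi)` bounds on the natural scale for
#'   `sigma_s`, `sigma_m`, `alpha`, `beta`, `p_cw`.
#' @param maxit Maximum simplex iterations of the polish stage; exploration
#'   restarts are additionally capped at 250 iterations.
#' @param reltol Relative function tolerance of each restart.
#' @param polish If `TRUE`, the best restart is re-optimized at the full
#'   iteration budget and a tighter tolerance (`reltol / 100`).
#' @param grid_step Grid spacing (deg) used during optimization; the final
#'   model can be re-evaluated on a finer grid.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_restarts = 30, seed = 1,
                       experiment = c("exp1", "exp2"),
                       bounds = list(sigma_s = c(0.5, 40),
                                     sigma_m = c(0.01, 20),
                                     alpha = c(5, 60),
                                     beta = c(0.5, 40),
                                     p_cw = c(0.05, 0.95)),
                       maxit = 2000, reltol = 1e-7, polish = TRUE,
                       grid_step = 0.5) {
  experiment <- match.arg(experiment)
  stopifnot(n_restarts >= 1, all(vapply(bounds, function(b)
    b[1] > 0 || identical(b, bounds$p_cw), logical(1))))
  structure(list(n_restarts = n_restarts, seed = seed,
                 experiment = experiment, bounds = bounds, maxit = maxit,
                 reltol = reltol, polish = polish, grid_step = grid_step),
            class = "fit_config")
}

# fitting grid: adaptive to the parameter set but capped so wild restart
# values cannot blow up the node count
.fit_grid <- function(params, step) {
  smax <- max(sqrt(params$sigma_s_high^2 + params$sigma_m^2),
              params$sigma_s_low)
  reach <- max(params$alpha_cw, params$alpha_ccw) + params$beta + 4 * smax
  half <- min(max(90, ceiling(reach / step) * step + step), 180)
  orientation_grid(-half, half, step)
}

FIT_BINS <- seq(-180, 180, by = 0.5)
PROB_FLOOR <- 1e-6

# precomputed sufficient statistics of the data for fast likelihood evals
.fit_data <- function(correct_table, all_trials_table) {
  dec <- stats::aggregate(
    cbind(n_cw = all_trials_table$choice == "cw",
          n_tot = rep(1, nrow(all_trials_table))),
    by = list(theta = all_trials_table$theta_deg,
              noise = all_trials_table$noise_level), FUN = sum)
  groups <- list()
  if (nrow(correct_table) > 0) {
    bin_idx <- findInterval(correct_table$estimate_deg, FIT_BINS,
                            rightmost.closed = TRUE)
    bin_idx <- pmin(pmax(bin_idx, 1L), length(FIT_BINS) - 1L)
    for (cat in CATEGORIES) {
      for (nl in c("low", "high")) {
        sel <- correct_table$choice == cat & correct_table$noise_level == nl
        if (!any(sel)) next
        tab <- table(theta = correct_table$theta_deg[sel], bin = bin_idx[sel])
        df <- as.data.frame(tab, stringsAsFactors = FALSE)
        df <- df[df$Freq > 0, ]
        groups[[paste(cat, nl, sep = "_")]] <- list(
          cat = cat, nl = nl,
          theta = as.numeric(df$theta), bin = as.integer(df$bin),
          count = df$Freq,
          thetas = sort(unique(as.numeric(df$theta))),
          bins = sort(unique(as.integer(df$bin))))
      }
    }
  }
  list(dec = dec, groups = groups)
}

# negative joint log likelihood from the precomputed statistics
.nll_from_data <- function(params, data, grid_step) {
  grid <- .fit_grid(params, grid_step)
  model <- observer_model(params, grid)
  # decision term
  p <- psychometric_by_row(model, data$dec$theta, data$dec$noise)
  ll <- sum(data$dec$n_cw * log(pmax(p, 1e-12)) +
            (data$dec$n_tot - data$dec$n_cw) * log(pmax(1 - p, 1e-12)))
  # estimate term, batched per (category, noise) group: all orientations of a
  # group share the memory kernel, the estimation curve and the bin matrix
  sigma_0 <- params$sigma_0
  sigma_m <- params$sigma_m
  g <- model$grid
  for (gr in data$groups) {
    curve <- model$curves[[paste(gr$cat, gr$nl, sep = "_")]]
    edges_lo <- FIT_BINS[gr$bins]
    edges_hi <- FIT_BINS[gr$bins + 1L]
    nth <- length(gr$thetas)
    Won <- matrix(0, g$n, nth)      # on-grid measurement weights per theta
    extras <- vector("list", nth)   # off-grid criterion node (x, weight)
    for (j in seq_len(nth)) {
      rn <- .region_nodes(model, gr$thetas[j], gr$nl, gr$cat)
      sp <- .split_nodes(rn$x, g)
      Won[sp$idx, j] <- rn$w[sp$w_on]
      if (length(sp$off) > 0)
        extras[[j]] <- list(x = rn$x[sp$off], w = rn$w[sp$off])
    }
    if (sigma_m > 0) {
      K <- .gauss_kernel(model, sigma_m)
      M <- K %*% Won
      for (j in seq_len(nth))
        if (!is.null(extras[[j]]))
          M[, j] <- M[, j] + as.vector(
            stats::dnorm(outer(g$theta, extras[[j]]$x, "-"), 0, sigma_m) %*%
              extras[[j]]$w)
      M <- M * model$trapw
      M <- sweep(M, 2, colSums(M), "/")
      extras <- vector("list", nth)           # all mass now on grid nodes
    } else {
      M <- Won                                 # weights already sum with extras
    }
    if (sigma_0 > 0) {
      ue <- sort(unique(c(edges_lo, edges_hi)))  # adjacent bins share edges
      C <- .fast_pnorm(outer(ue, curve, "-") / sigma_0)
      B <- C[match(edges_hi, ue), , drop = FALSE] -
           C[match(edges_lo, ue), , drop = FALSE]
      P <- B %*% M                             # n_used_bins x n_theta
      for (j in seq_len(nth)) {
        ex <- extras[[j]]
        if (is.null(ex)) next
        v <- vapply(ex$x, .posterior_mean_scalar, numeric(1),
                    sigma_like = model$sigma_like[[gr$nl]],
                    prior = model$priors[[gr$cat]], grid = g)
        P[, j] <- P[, j] + as.vector(
          (.fast_pnorm(outer(edges_hi, v, "-") / sigma_0) -
           .fast_pnorm(outer(edges_lo, v, "-") / sigma_0)) %*% ex$w)
      }
    } else {
      P <- matrix(0, length(gr$bins), nth)
      for (j in seq_len(nth)) {
        v <- curve
        mass <- M[, j]
        ex <- extras[[j]]
        if (!is.null(ex)) {
          v <- c(v, vapply(ex$x, .posterior_mean_scalar, numeric(1),
                           sigma_like = model$sigma_like[[gr$nl]],
                           prior = model$priors[[gr$cat]], grid = g))
          mass <- c(mass, ex$w)
        }
        idx <- findInterval(v, FIT_BINS, rightmost.closed = TRUE)
        P[, j] <- vapply(gr$bins, function(b) sum(mass[idx == b]), numeric(1))
      }
    }
    jpos <- match(gr$theta, gr$thetas)
    bpos <- match(gr$bin, gr$bins)
    pv <- P[cbind(bpos, jpos)]
    ll <- ll + sum(gr$count * log(pmax(pv, PROB_FLOOR)))
  }
  -ll
}

# psychometric for paired (theta, noise) vectors
psychometric_by_row <- function(model, theta, noise) {
  out <- numeric(length(theta))
  for (nl in c("low", "high")) {
    sel <- noise == nl
    if (any(sel)) out[sel] <- psychometric(model, theta[sel], nl)
  }
  out
}

#' Joint negative log likelihood
#'
#' The fitted objective: minus the sum of the log probability of every
#' categorical choice (all trials, from the psychometric function) and the
#' log probability of the 0.5-deg bin of every estimate on correct trials
#' (from the self-consistent predictive distribution conditioned on the
#' choice), with a floor of 1e-6 on bin probabilities.
#'
#' @param params An [observer_params()] with the subject's `sigma_0`.
#' @param correct_table Correct, consistent trials (estimate term).
#' @param all_trials_table All trials (choice term).
#' @param grid_step Quadrature grid spacing in deg.
#' @return The negative log likelihood (finite for in-bounds parameters).
#' @export
joint_nll <- function(params, correct_table, all_trials_table,
                      grid_step = 0.2) {
  if (any(!all_trials_table$noise_level %in% c("low", "high")))
    stop("configuration error: unknown noise level in trial table")
  data <- .fit_data(correct_table, all_trials_table)
  .nll_from_data(params, data, grid_step)
}

# parameter vector <-> observer_params transforms (log scale; logit for p_cw)
.par_to_params <- function(par, experiment, sigma_0) {
  if (experiment == "exp1") {
    observer_params(sigma_s_low = exp(par[1]), sigma_s_high = exp(par[2]),
                    sigma_m = exp(par[3]), alpha_cw = exp(par[4]),
                    alpha_ccw = exp(par[4]), beta = exp(par[5]),
                    p_cw = 0.5, sigma_0 = sigma_0, experiment = "exp1")
  } else {
    observer_params(sigma_s_low = exp(par[1]), sigma_s_high = exp(par[2]),
                    sigma_m = exp(par[3]), alpha_cw = exp(par[4]),
                    alpha_ccw = exp(par[5]), beta = exp(par[6]),
                    p_cw = stats::plogis(par[7]), sigma_0 = sigma_0,
                    experiment = "exp2")
  }
}

.bounds_penalty <- function(params, bounds) {
  excess <- 0
  chk <- function(x, b) max(0, b[1] - x) + max(0, x - b[2])
  excess <- excess + chk(params$sigma_s_low, bounds$sigma_s) +
    chk(params$sigma_s_high, bounds$sigma_s) +
    chk(params$sigma_m, bounds$sigma_m) +
    chk(params$alpha_cw, bounds$alpha) + chk(params$alpha_ccw, bounds$alpha) +
    chk(params$beta, bounds$beta) + chk(params$p_cw, bounds$p_cw)
  excess
}

#' Fit the self-consistent observer to correct-trial data
#'
#' Joint maximum-likelihood fit: Nelder-Mead simplex on log-transformed
#' parameters (logit for `p_cw`), restarted from `n_restarts` random initial
#' values drawn log-uniformly inside the bounds; the lowest negative log
#' likelihood wins. Deterministic given the config seed. `sigma_0` is fixed,
#' never fitted; experiment-1 mode fixes `p_cw = 0.5` and a shared prior
#' width.
#'
#' @param correct_table Correct, consistent trials.
#' @param all_trials_table All trials (choice term).
#' @param config A [fit_config()].
#' @param sigma_0 The subject's motor noise SD in deg.
#' @return Object of class `fit_result`: `best_params`, `nll`, `restarts`
#'   (one row per restart: initial values, final nll, convergence code,
#'   evaluations) and `config`.
#' @export
fit_correct_trials <- function(correct_table, all_trials_table, config,
                               sigma_0) {
  stopifnot(inherits(config, "fit_config"), nrow(correct_table) > 0,
            nrow(all_trials_table) > 0, sigma_0 >= 0)
  data <- .fit_data(correct_table, all_trials_table)
  bounds <- config$bounds
  obj <- function(par) {
    params <- try(.par_to_params(par, config$experiment, sigma_0),
                  silent = TRUE)
    if (inherits(params, "try-error")) return(1e10)
    pen <- .bounds_penalty(params, bounds)
    if (pen > 0) return(1e10 * (1 + pen))
    .nll_from_data(params, data, config$grid_step)
  }
  n_par <- if (config$experiment == "exp1") 5L else 7L
  set.seed(config$seed)
  runif_log <- function(b) exp(stats::runif(config$n_restarts,
                                            log(b[1]), log(b[2])))
  inits <- cbind(log(runif_log(bounds$sigma_s)),
                 log(runif_log(bounds$sigma_s)),
                 log(runif_log(bounds$sigma_m)),
                 log(runif_log(bounds$alpha)))
  if (config$experiment == "exp2")
    inits <- cbind(inits, log(runif_log(bounds$alpha)))
  inits <- cbind(inits, log(runif_log(bounds$beta)))
  if (config$experiment == "exp2")
    inits <- cbind(inits, stats::qlogis(stats::runif(config$n_restarts,
                                                     0.2, 0.8)))
  restarts <- vector("list", config$n_restarts)
  fits <- vector("list", config$n_restarts)
  # exploration restarts are iteration-capped; the winner is polished at the
  # full iteration budget and a tighter tolerance below
  explore_maxit <- min(config$maxit, 250)
  for (r in seq_len(config$n_restarts)) {
    fit <- try(stats::optim(inits[r, ], obj, method = "Nelder-Mead",
                            control = list(maxit = explore_maxit,
                                           reltol = config$reltol)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      restarts[[r]] <- data.frame(restart = r, nll = NA_real_,
                                  converged = FALSE, evals = NA_integer_)
      next
    }
    fits[[r]] <- fit
    restarts[[r]] <- data.frame(restart = r, nll = fit$value,
                                converged = fit$convergence == 0,
                                evals = fit$counts[["function"]])
  }
  restarts <- do.call(rbind, restarts)
  init_df <- as.data.frame(inits)
  names(init_df) <- paste0("init_", seq_len(n_par))
  restarts <- cbind(restarts, init_df)
  ok <- which(!is.na(restarts$nll) & restarts$nll < 1e9)
  if (length(ok) == 0)
    stop("fit failure: no restart converged; restart table attached",
         call. = FALSE)
  best <- ok[which.min(restarts$nll[ok])]
  best_par <- fits[[best]]$par
  best_nll <- fits[[best]]$value
  if (config$polish) {
    pol <- stats::optim(best_par, obj, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = config$reltol / 100))
    if (pol$value <= best_nll) {
      best_par <- pol$par
      best_nll <- pol$value
    }
  }
  structure(list(
    best_params = .par_to_params(best_par, config$experiment, sigma_0),
    nll = best_nll, restarts = restarts, config = config),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Observer fit: nll %.3f over %d restarts (%d converged)\n",
              x$nll, nrow(x$restarts), sum(x$restarts$converged, na.rm = TRUE)))
  print(x$best_params)
  invisible(x)
}
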