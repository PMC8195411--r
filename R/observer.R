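# Observer-model primitives: decision, memory, estimation.
#
# All integrals are trapezoid sums on a shared uniform orientation grid.
# Gaussian transition kernels between on-grid variables are Toeplitz, so a
# kernel matrix is assembled from a single vector of density values; this is
# what keeps the joint likelihood cheap enough for simplex fitting.

# --- fast standard-normal CDF ----------------------------------------------
# Linear interpolation in a precomputed table. Absolute error < 1e-8, which
# is far below every tolerance used on binned probabilities.
.pnorm_env <- new.env(parent = emptyenv())

.fast_pnorm <- function(z) {
  if (is.null(.pnorm_env$tab)) {
    .pnorm_env$h <- 5e-4
    .pnorm_env$zmax <- 8.4
    .pnorm_env$zs <- seq(-.pnorm_env$zmax, .pnorm_env$zmax, by = .pnorm_env$h)
    .pnorm_env$tab <- stats::pnorm(.pnorm_env$zs)
  }
  h <- .pnorm_env$h; zmax <- .pnorm_env$zmax; tab <- .pnorm_env$tab
  z <- pmin(pmax(z, -zmax), zmax)
  pos <- (z + zmax) / h
  i <- pmin(floor(pos), length(tab) - 2L)
  frac <- pos - i
  lo <- tab[i + 1L]
  lo + frac * (tab[i + 2L] - lo)
}

# --- Toeplitz Gaussian kernel ----------------------------------------------
# K[i, j] = dnorm(theta_i - theta_j, 0, sigma), built by indexing a vector of
# n distinct values. Cached per observer model.
.gauss_kernel <- function(model, sigma) {
  key <- sprintf("K_%.12g", sigma)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  n <- model$grid$n
  if (is.null(model$cache$idx))
    model$cache$idx <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
  kv <- stats::dnorm((0:(n - 1)) * model$grid$step, 0, sigma)
  K <- matrix(kv[model$cache$idx], n, n)
  model$cache[[key]] <- K
  K
}

# --- observer model object -------------------------------------------------

#' Build a self-consistent observer model
#'
#' Precomputes, for a parameter set on a grid: the two conditioned priors,
#' the decision criterion \eqn{m^*} for each noise level (the measurement at
#' which the category posterior is 0.5), and the posterior-mean estimation
#' curves \eqn{\hat\theta(m_m)} for each category and noise level. All other
#' operations take this object.
#'
#' @param params An [observer_params()] object.
#' @param grid An [orientation_grid()]; defaults to [default_grid()] for the
#'   parameter set.
#' @return An object of class `observer_model`.
#' @examples
#' p <- observer_params(3, 18, 4, alpha_cw = 21, beta = 8, sigma_0 = 2)
#' mod <- observer_model(p)
#' psychometric(mod, theta = 3, noise_level = "low")
#' @export
observer_model <- function(params, grid = default_grid(params)) {
  stopifnot(inherits(params, "observer_params"),
            inherits(grid, "orientation_grid"))
  model <- list(params = params, grid = grid,
                trapw = trapezoid_weights(grid),
                priors = conditioned_priors(params, grid),
                cache = new.env(parent = emptyenv()))
  class(model) <- "observer_model"
  model$sigma_like <- c(low  = sqrt(params$sigma_s_low^2  + params$sigma_m^2),
                        high = sqrt(params$sigma_s_high^2 + params$sigma_m^2))
  model$criteria <- c(low  = .decision_criterion(model, "low"),
                      high = .decision_criterion(model, "high"))
  # estimation curves f[cat, noise]: posterior mean at every grid node
  model$curves <- list()
  for (cat in CATEGORIES)
    for (nl in c("low", "high"))
      model$curves[[paste(cat, nl, sep = "_")]] <-
        .estimate_curve(model, cat, model$sigma_like[[nl]])
  model
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Self-consistent observer model\n")
  cat(sprintf("  grid: [%g, %g] deg, step %g (%d nodes)\n",
              x$grid$lo, x$grid$hi, x$grid$step, x$grid$n))
  cat(sprintf("  decision criterion m*: %.4f (low) / %.4f (high) deg\n",
              x$criteria[["low"]], x$criteria[["high"]]))
  print(x$params)
  invisible(x)
}

# posterior-mean estimate at every grid node, for one conditioned prior and
# likelihood width; dense Gaussian weights over the prior's support columns
# with a log-domain fallback where they underflow
.estimate_curve <- function(model, category, sigma_like) {
  g <- model$grid
  pw <- model$priors[[category]]$density * model$trapw
  nz <- which(pw > 0)
  D <- stats::dnorm(outer(g$theta, g$theta[nz], "-"), 0, sigma_like)
  den <- as.vector(D %*% pw[nz])
  num <- as.vector(D %*% (g$theta[nz] * pw[nz]))
  f <- num / den
  bad <- !is.finite(f) | den < 1e-290
  if (any(bad))
    f[bad] <- vapply(g$theta[bad], .posterior_mean_scalar, numeric(1),
                     sigma_like = sigma_like,
                     prior = model$priors[[category]], grid = g)
  f
}

# vectorized posterior means (chunked dense weights, scalar log-domain
# fallback where the unshifted weights underflow)
.posterior_mean_batch <- function(m_m, sigma_like, prior, grid) {
  pw <- prior$density * trapezoid_weights(grid)
  nz <- which(pw > 0)
  thnz <- grid$theta[nz]
  pwnz <- pw[nz]
  out <- numeric(length(m_m))
  for (ix in split(seq_along(m_m), ceiling(seq_along(m_m) / 1000))) {
    W <- exp(-(outer(m_m[ix], thnz, "-"))^2 / (2 * sigma_like^2))
    W <- W * rep(pwnz, each = length(ix))
    den <- rowSums(W)
    out[ix] <- as.vector(W %*% thnz) / den
  }
  bad <- !is.finite(out)
  if (any(bad))
    out[bad] <- vapply(m_m[bad], .posterior_mean_scalar, numeric(1),
                       sigma_like = sigma_like, prior = prior, grid = grid)
  out
}

# log-domain posterior mean for a single memory sample (never NaN)
.posterior_mean_scalar <- function(m_m, sigma_like, prior, grid) {
  lp <- ifelse(prior$density > 0, log(prior$density), -Inf)
  lw <- -(m_m - grid$theta)^2 / (2 * sigma_like^2) + lp
  mx <- max(lw)
  if (!is.finite(mx)) return(grid$theta[which.max(prior$density)])
  w <- exp(lw - mx) * trapezoid_weights(grid)
  sum(w * grid$theta) / sum(w)
}

# --- decision stage --------------------------------------------------------

#' Category likelihood of a measurement
#'
#' \eqn{p(m|C) = \int N(m; \theta, \sigma_s)\, p(\theta|C)\, d\theta},
#' evaluated by grid quadrature.
#'
#' @param m Sensory measurement(s) in deg (vectorized).
#' @param sigma_s Sensory noise SD in deg (> 0).
#' @param prior_cw,prior_ccw The two conditioned priors.
#' @param grid The grid the priors live on.
#' @return A list with vectors `cw` and `ccw` of likelihood densities.
#' @export
category_likelihood <- function(m, sigma_s, prior_cw, prior_ccw, grid) {
  stopifnot(sigma_s > 0)
  w <- trapezoid_weights(grid)
  D <- stats::dnorm(outer(m, grid$theta, "-"), 0, sigma_s)
  list(cw  = as.vector(D %*% (prior_cw$density * w)),
       ccw = as.vector(D %*% (prior_ccw$density * w)))
}

#' Posterior probability of the clockwise category
#'
#' \eqn{p(C = cw | m)} by Bayes' rule over the two conditioned priors with
#' category prior `p_cw`.
#'
#' @param model An [observer_model()].
#' @param m Measurement(s) in deg.
#' @param noise_level `"low"` or `"high"`.
#' @return Probability vector in \[0, 1\].
#' @export
decision_posterior <- function(model, m, noise_level) {
  sigma_s <- sigma_s_for(model$params, noise_level)
  lik <- category_likelihood(m, sigma_s, model$priors$cw, model$priors$ccw,
                             model$grid)
  num <- lik$cw * model$params$p_cw
  den <- num + lik$ccw * (1 - model$params$p_cw)
  if (any(den == 0))
    stop("degenerate measurement: zero likelihood under both categories")
  num / den
}

#' Categorical decision
#'
#' Chooses the category with higher posterior; an exact tie (posterior 0.5)
#' is broken uniformly at random.
#'
#' @inheritParams decision_posterior
#' @return Character vector of `"cw"` / `"ccw"`.
#' @export
decide <- function(model, m, noise_level) {
  p <- decision_posterior(model, m, noise_level)
  out <- ifelse(p > 0.5, "cw", "ccw")
  tie <- abs(p - 0.5) < 1e-12     # numerically exact tie
  if (any(tie))
    out[tie] <- sample(CATEGORIES, sum(tie), replace = TRUE)
  out
}

# root of the posterior log-ratio in m; -Inf / +Inf if the ratio never
# changes sign because one category dominates everywhere
.decision_criterion <- function(model, noise_level) {
  p <- model$params
  sigma_s <- sigma_s_for(p, noise_level)
  if (p$p_cw == 1) return(-Inf)
  if (p$p_cw == 0) return(Inf)
  g <- model$grid
  pw_cw <- model$priors$cw$density * model$trapw
  pw_ccw <- model$priors$ccw$density * model$trapw
  lr_at <- function(m) {
    D <- stats::dnorm(m - g$theta, 0, sigma_s)
    lcw <- sum(D * pw_cw); lccw <- sum(D * pw_ccw)
    log(lcw) - log(lccw) + log(p$p_cw) - log(1 - p$p_cw)
  }
  K <- .gauss_kernel(model, sigma_s)
  lcw <- as.vector(K %*% pw_cw)
  lccw <- as.vector(K %*% pw_ccw)
  ok <- lcw > 1e-290 & lccw > 1e-290
  lr <- log(lcw[ok]) - log(lccw[ok]) + log(p$p_cw) - log(1 - p$p_cw)
  th <- g$theta[ok]
  # the log posterior ratio is nondecreasing in m; bracket the sign change,
  # treating |lr| below a tiny tolerance as numerically zero (exact symmetry)
  tol <- 1e-9
  neg <- lr < -tol
  pos <- lr > tol
  if (!any(pos) && !any(neg)) return(0)
  if (!any(pos)) return(Inf)
  if (!any(neg)) return(-Inf)
  a <- max(th[neg])
  b <- min(th[pos])
  if (a >= b)
    stop("criterion not found: posterior ratio does not change sign on the grid")
  stats::uniroot(lr_at, c(a, b), extendInt = "upX", tol = 1e-11)$root
}

#' Psychometric function
#'
#' Probability of choosing the cw category as a function of true stimulus
#' orientation, \eqn{p(\hat C = cw|\theta)}, obtained by marginalizing the
#' threshold decision rule over the measurement distribution:
#' \eqn{1 - \Phi((m^* - \theta)/\sigma_s)}.
#'
#' @param model An [observer_model()].
#' @param theta Stimulus orientation(s) in deg.
#' @param noise_level `"low"` or `"high"`.
#' @return Probability vector.
#' @export
psychometric <- function(model, theta, noise_level) {
  mstar <- model$criteria[[match.arg(noise_level, c("low", "high"))]]
  if (mstar == -Inf) return(rep(1, length(theta)))
  if (mstar == Inf) return(rep(0, length(theta)))
  sigma_s <- sigma_s_for(model$params, noise_level)
  1 - stats::pnorm((mstar - theta) / sigma_s)
}

# --- memory stage ----------------------------------------------------------

#' Marginal density of the memory sample given the stimulus
#'
#' The recalled sample is the measurement plus Gaussian memory noise, so its
#' marginal given \eqn{\theta} is Gaussian with SD
#' \eqn{\sqrt{\sigma_s^2 + \sigma_m^2}}.
#'
#' @param theta Stimulus orientation in deg.
#' @param sigma_s,sigma_m Sensory and memory noise SDs in deg.
#' @param grid An [orientation_grid()].
#' @return Density vector over `grid$theta`.
#' @export
memory_sample_density <- function(theta, sigma_s, sigma_m, grid) {
  stopifnot(sigma_s > 0, sigma_m >= 0)
  stats::dnorm(grid$theta, theta, sqrt(sigma_s^2 + sigma_m^2))
}

#' Feedback-consistent memory resampling
#'
#' Memory recall under the resampling model: proposals are drawn from a
#' Gaussian centered on the original measurement `m` with the combined SD
#' \eqn{\sqrt{\sigma_s^2 + \sigma_m^2}} until one falls on the side of the
#' reference consistent with the feedback-corrected category. The number of
#' proposals consumed is returned as a response-time proxy.
#'
#' @param m Original measurement in deg (scalar).
#' @param sigma_s,sigma_m Sensory and memory noise SDs in deg.
#' @param category_f Feedback-corrected category (`"cw"` or `"ccw"`).
#' @param max_draws Proposal cap; past it the sample is drawn from the
#'   analytic truncated Gaussian instead and `fallback` is set.
#' @return List with `m_m` (accepted sample), `n_draws` (proposals used) and
#'   `fallback` (logical).
#' @export
resample_memory <- function(m, sigma_s, sigma_m, category_f,
                            max_draws = 10000) {
  stopifnot(length(m) == 1, sigma_s > 0, sigma_m >= 0)
  category_f <- match.arg(category_f, CATEGORIES)
  s <- category_sign(category_f)
  sig <- sqrt(sigma_s^2 + sigma_m^2)
  batch <- 64L
  used <- 0L
  while (used < max_draws) {
    nb <- min(batch, max_draws - used)
    x <- stats::rnorm(nb, m, sig)
    hit <- which(s * x > 0)
    if (length(hit) > 0)
      return(list(m_m = x[hit[1]], n_draws = used + hit[1], fallback = FALSE))
    used <- used + nb
  }
  # analytic truncated draw via inverse CDF
  if (s > 0) {
    plo <- stats::pnorm(0, m, sig)
    u <- stats::runif(1, plo, 1)
  } else {
    phi <- stats::pnorm(0, m, sig)
    u <- stats::runif(1, 0, phi)
  }
  list(m_m = stats::qnorm(u, m, sig), n_draws = max_draws, fallback = TRUE)
}

# --- estimation stage ------------------------------------------------------

#' Posterior-mean orientation estimate
#'
#' The conditioned Bayesian estimate: mean of the posterior proportional to
#' \eqn{N(m_m; \theta, \sigma_{like})\, p(\theta|C)} under squared-error
#' loss. Computed in the log domain; never returns `NaN`.
#'
#' @param m_m Memory sample(s) in deg (vectorized).
#' @param category Conditioning category, `"cw"` or `"ccw"`.
#' @param sigma_like Likelihood width in deg; the generative chain gives
#'   \eqn{\sqrt{\sigma_s^2 + \sigma_m^2}}, the reweighted model a wider value.
#' @param prior The matching [make_conditioned_prior()] object.
#' @param grid The grid the prior lives on.
#' @return Estimate(s) in deg, sign-consistent with `category`.
#' @export
estimate_posterior_mean <- function(m_m, category, sigma_like, prior, grid) {
  stopifnot(sigma_like > 0)
  category <- match.arg(category, CATEGORIES)
  stopifnot(prior$category == category)
  vapply(m_m, .posterior_mean_scalar, numeric(1),
         sigma_like = sigma_like, prior = prior, grid = grid)
}

#' Prior-only estimate (Model 1a)
#'
#' If the categorical judgment erased all sensory evidence inconsistent with
#' it, the post-feedback posterior collapses to the conditioned prior of the
#' feedback-corrected category; the optimal estimate is that prior's mean,
#' independent of the measurement and of both noise levels.
#'
#' @param category_f Feedback-corrected category.
#' @param prior The matching conditioned prior.
#' @param grid Grid the prior lives on.
#' @return Estimate in deg.
#' @export
model1a_estimate <- function(category_f, prior, grid) {
  stopifnot(prior$category == category_f)
  prior_mean(prior, grid)
}

#' Uncertainty-only heuristic estimate (Model 1b)
#'
#' The observer retains only the trial's sensory uncertainty and places the
#' estimate one sensory SD away from the reference on the feedback side.
#'
#' @param category_f Feedback-corrected category.
#' @param sigma_s Sensory noise SD in deg.
#' @return \eqn{+\sigma_s} for cw, \eqn{-\sigma_s} for ccw.
#' @export
model1b_estimate <- function(category_f, sigma_s) {
  stopifnot(sigma_s > 0)
  category_sign(category_f) * sigma_s
}

#' Bayesian surprise of negative feedback
#'
#' KL divergence between the decision posterior and its flipped counterpart,
#' \eqn{q \ln\frac{q}{1-q} + (1-q)\ln\frac{1-q}{q} = (2q-1)\ln\frac{q}{1-q}},
#' where `q` is the posterior probability of the chosen category. Symmetric
#' in \eqn{q \leftrightarrow 1-q} and zero at \eqn{q = 0.5}.
#'
#' @param p_choice Posterior probability of the chosen category (vectorized).
#' @return Surprise in nats.
#' @export
kl_surprise <- function(p_choice) {
  eps <- 1e-12
  if (any(p_choice <= 0 | p_choice >= 1)) {
    warning("p_choice clamped away from {0, 1}")
    p_choice <- pmin(pmax(p_choice, eps), 1 - eps)
  }
  (2 * p_choice - 1) * log(p_choice / (1 - p_choice))
}

#' Surprise-reweighted sensory uncertainty
#'
#' Model 2c scales the sensory likelihood width by one plus the Bayesian
#' surprise: \eqn{\sigma_s' = (1 + KL)\,\sigma_s}.
#'
#' @param sigma_s Sensory noise SD in deg.
#' @param kl Surprise in nats (>= 0).
#' @return Reweighted SD in deg.
#' @export
reweighted_sigma <- function(sigma_s, kl) {
  stopifnot(all(kl >= 0))
  (1 + kl) * sigma_s
}
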