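# Binned predictive estimate distributions.
#
# A predictive distribution for a condition (stimulus orientation, noise
# level, model variant, trial correctness) is computed by (1) restricting the
# measurement integral to the decision region that produces the required
# choice, (2) pushing the measurement through the variant's memory-recall
# rule to a marginal over memory samples, (3) mapping memory samples through
# the conditioned posterior-mean estimate, and (4) convolving with Gaussian
# motor noise while integrating over 0.5-deg estimate bins. Steps (2)-(3)
# produce a discrete set of support points (estimate values) with masses;
# step (4) is exact per support point via the Gaussian CDF.

MODEL_IDS <- c("1a", "1b", "2a", "2b", "2c", "selfconsistent")

# estimate bin edges: integer multiples of `width` covering the grid
default_bins <- function(grid, width = 0.5) {
  lo <- floor(grid$lo / width) * width
  hi <- ceiling(grid$hi / width) * width
  seq(lo, hi, by = width)
}

# measurement quadrature nodes over the decision region of `chosen`:
# grid nodes inside the region plus the off-grid criterion node, with
# composite trapezoid weights times the truncated Gaussian density,
# normalized to sum 1
.region_nodes <- function(model, theta, noise_level, chosen) {
  g <- model$grid
  sigma_s <- sigma_s_for(model$params, noise_level)
  mstar <- model$criteria[[noise_level]]
  s <- category_sign(chosen)
  if (is.infinite(mstar)) {   # one category chosen for every measurement
    x <- g$theta
    wq <- model$trapw
  } else if (s > 0) {
    keep <- g$theta > mstar + 1e-12
    x <- c(mstar, g$theta[keep])
    wq <- .trap_weights_nonuniform(x)
  } else {
    keep <- g$theta < mstar - 1e-12
    x <- c(g$theta[keep], mstar)
    wq <- .trap_weights_nonuniform(x)
  }
  w <- wq * stats::dnorm(x, theta, sigma_s)
  list(x = x, w = w / sum(w))
}

.trap_weights_nonuniform <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  d <- diff(x)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

# split measurement nodes into on-grid indices and off-grid extras
.split_nodes <- function(x, grid) {
  pos <- (x - grid$lo) / grid$step
  ongrid <- abs(pos - round(pos)) < 1e-9
  list(idx = round(pos[ongrid]) + 1L, w_on = which(ongrid),
       off = which(!ongrid))
}

# marginal mass of the memory sample over grid nodes:
# q_i = sum_k w_k N(theta_i; x_k, sigma), times trapezoid weights
.memory_marginal <- function(model, x, w, sigma) {
  g <- model$grid
  sp <- .split_nodes(x, g)
  q <- numeric(g$n)
  if (length(sp$idx) > 0) {
    K <- .gauss_kernel(model, sigma)
    wpad <- numeric(g$n)
    wpad[sp$idx] <- w[sp$w_on]
    q <- as.vector(K %*% wpad)
  }
  for (k in sp$off)
    q <- q + w[k] * stats::dnorm(g$theta, x[k], sigma)
  mass <- q * model$trapw
  mass / sum(mass)
}

# marginal mass of the resampled memory sample (Model 2b): proposals from
# N(x_k, sigma_c) truncated to the side of `category_f`, one-sided trapezoid
# on that side of the reference
.resampled_marginal <- function(model, x, w, sigma_c, category_f) {
  g <- model$grid
  s <- category_sign(category_f)
  # acceptance probability P(sample on the category side), computed from the
  # accurate lower tail so far-side components cannot underflow to zero
  accept <- stats::pnorm(s * x / sigma_c)
  w_adj <- w / pmax(accept, 1e-300)
  sp <- .split_nodes(x, g)
  q <- numeric(g$n)
  if (length(sp$idx) > 0) {
    K <- .gauss_kernel(model, sigma_c)
    wpad <- numeric(g$n)
    wpad[sp$idx] <- w_adj[sp$w_on]
    q <- as.vector(K %*% wpad)
  }
  for (k in sp$off)
    q <- q + w_adj[k] * stats::dnorm(g$theta, x[k], sigma_c)
  side <- if (s > 0) g$theta >= 0 else g$theta <= 0
  q[!side] <- 0
  wq <- numeric(g$n)           # one-sided trapezoid weights on the side
  wq[side] <- g$step
  edge <- range(which(side))
  wq[edge] <- g$step / 2
  mass <- q * wq
  mass / sum(mass)
}

# decision posterior p(cw|m) at measurement nodes, reusing Toeplitz kernels
.posterior_at_nodes <- function(model, x, noise_level) {
  g <- model$grid
  sigma_s <- sigma_s_for(model$params, noise_level)
  sp <- .split_nodes(x, g)
  p <- numeric(length(x))
  pw_cw <- model$priors$cw$density * model$trapw
  pw_ccw <- model$priors$ccw$density * model$trapw
  if (length(sp$idx) > 0) {
    K <- .gauss_kernel(model, sigma_s)
    lcw <- as.vector(K[sp$idx, , drop = FALSE] %*% pw_cw)
    lccw <- as.vector(K[sp$idx, , drop = FALSE] %*% pw_ccw)
    num <- lcw * model$params$p_cw
    p[sp$w_on] <- num / (num + lccw * (1 - model$params$p_cw))
  }
  if (length(sp$off) > 0)
    p[sp$off] <- decision_posterior(model, x[sp$off], noise_level)
  p
}

# posterior-mean curve for an arbitrary likelihood width (Model 2c levels)
.curve_for_width <- function(model, category, width) {
  key <- sprintf("curve_%s_%.10g", category, width)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  cv <- .estimate_curve(model, category, width)
  model$cache[[key]] <- cv
  cv
}

# support points (estimate values before motor noise) and masses for one
# condition; the heart of every model variant
.predictive_support <- function(model, theta, noise_level, model_id,
                                correctness, category) {
  p <- model$params
  g <- model$grid
  sigma_s <- sigma_s_for(p, noise_level)
  chosen <- if (correctness == "correct") category else flip_category(category)
  # estimation prior: the feedback-corrected category for the post-feedback
  # variants, the observer's own choice for the plain self-consistent rule
  est_cat <- if (correctness == "correct") category
             else if (model_id == "selfconsistent") chosen else category
  if (model_id == "1a" && correctness == "incorrect")
    return(list(v = prior_mean(model$priors[[category]], g), mass = 1))
  if (model_id == "1b" && correctness == "incorrect")
    return(list(v = model1b_estimate(category, sigma_s), mass = 1))
  rn <- .region_nodes(model, theta, noise_level, chosen)
  curve_key <- paste(est_cat, noise_level, sep = "_")
  if (model_id == "2b" && correctness == "incorrect") {
    sigma_c <- model$sigma_like[[noise_level]]
    mass <- .resampled_marginal(model, rn$x, rn$w, sigma_c, category)
    keep <- mass > 0
    return(list(v = model$curves[[curve_key]][keep], mass = mass[keep]))
  }
  if (model_id == "2c" && correctness == "incorrect") {
    q <- .posterior_at_nodes(model, rn$x, noise_level)
    kl <- kl_surprise(pmin(pmax(q, 1e-12), 1 - 1e-12))
    widths <- sqrt(reweighted_sigma(sigma_s, kl)^2 + p$sigma_m^2)
    n_lev <- 41L
    rng <- range(widths)
    if (diff(rng) < 1e-9) {
      lev_of <- rep(1L, length(widths)); lev_w <- mean(widths); n_lev <- 1L
    } else {
      lev_w <- seq(rng[1], rng[2], length.out = n_lev)
      lev_of <- pmin(pmax(round((widths - rng[1]) / diff(rng) * (n_lev - 1)) + 1,
                          1L), n_lev)
    }
    v_all <- numeric(0); m_all <- numeric(0)
    for (l in seq_len(n_lev)) {
      sel <- lev_of == l
      if (!any(sel)) next
      wl <- sum(rn$w[sel])
      cv <- .curve_for_width(model, est_cat, lev_w[l])
      if (p$sigma_m > 0) {
        mass <- .memory_marginal(model, rn$x[sel], rn$w[sel], p$sigma_m) * wl
        keep <- mass > 1e-16
        v_all <- c(v_all, cv[keep]); m_all <- c(m_all, mass[keep])
      } else {
        xs <- rn$x[sel]
        sp <- .split_nodes(xs, g)
        v <- numeric(length(xs))
        v[sp$w_on] <- cv[sp$idx]
        for (k in sp$off)
          v[k] <- .posterior_mean_scalar(xs[k], lev_w[l],
                                         model$priors[[est_cat]], g)
        v_all <- c(v_all, v); m_all <- c(m_all, rn$w[sel])
      }
    }
    return(list(v = v_all, mass = m_all / sum(m_all)))
  }
  # plain recall: self-consistent rule and Model 2a
  if (p$sigma_m > 0) {
    mass <- .memory_marginal(model, rn$x, rn$w, p$sigma_m)
    keep <- mass > 1e-16
    return(list(v = model$curves[[curve_key]][keep],
                mass = mass[keep] / sum(mass[keep])))
  }
  sp <- .split_nodes(rn$x, g)
  v <- numeric(length(rn$x))
  v[sp$w_on] <- model$curves[[curve_key]][sp$idx]
  for (k in sp$off)
    v[k] <- .posterior_mean_scalar(rn$x[k], model$sigma_like[[noise_level]],
                                   model$priors[[est_cat]], g)
  list(v = v, mass = rn$w)
}

# motor convolution + 0.5-deg binning of a support/mass set
.bin_support <- function(v, mass, sigma_0, edges) {
  nb <- length(edges) - 1L
  if (sigma_0 == 0) {
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    if (any(idx < 1 | idx > nb)) stop("estimate support outside bin range")
    probs <- numeric(nb)
    agg <- tapply(mass, idx, sum)
    probs[as.integer(names(agg))] <- agg
    return(probs)
  }
  probs <- numeric(nb)
  chunk <- 4000L
  for (st in seq(1, length(v), by = chunk)) {
    en <- min(st + chunk - 1L, length(v))
    Z <- outer(edges, v[st:en], "-") / sigma_0   # (nb+1) x chunk
    C <- .fast_pnorm(Z)
    probs <- probs + as.vector((C[-1, , drop = FALSE] -
                                C[-nrow(C), , drop = FALSE]) %*% mass[st:en])
  }
  probs
}

#' Predictive distribution of orientation estimates
#'
#' Computes the binned distribution \eqn{p(\hat\theta | \theta, noise)} for a
#' model variant, conditioned on the trial outcome: `"correct"` restricts the
#' measurement integral to the decision region matching the true category
#' (self-consistent estimation on the chosen side), `"incorrect"` restricts
#' it to the opposing region and applies the variant's post-feedback rule
#' with the feedback-corrected category, and `"marginal"` mixes the two with
#' the psychometric weights. The final distribution is convolved with
#' Gaussian motor noise and integrated over estimate bins of width 0.5 deg.
#'
#' @param model An [observer_model()].
#' @param theta True stimulus orientation in deg.
#' @param noise_level `"low"` or `"high"`.
#' @param model_id One of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"2c"`,
#'   `"selfconsistent"`. Variants differ only on incorrect trials; correct
#'   trials always follow the self-consistent rule.
#' @param correctness `"correct"`, `"incorrect"` or `"marginal"`.
#' @param category True (feedback-corrected) category; defaults to the sign
#'   of `theta`, must be given explicitly for `theta == 0`.
#' @param bins Bin edges in deg (width 0.5); default covers the grid.
#' @return Object of class `predictive_distribution` with `bin_edges`,
#'   `bin_probs` (sums to 1) and the conditioning fields.
#' @examples
#' p <- observer_params(3, 18, 4, alpha_cw = 21, beta = 8, sigma_0 = 2)
#' mod <- observer_model(p)
#' pd <- predictive_distribution(mod, theta = 6, noise_level = "low",
#'                               model_id = "2a", correctness = "incorrect")
#' predictive_mean(pd)
#' @export
predictive_distribution <- function(model, theta, noise_level, model_id,
                                    correctness = c("correct", "incorrect",
                                                    "marginal"),
                                    category = NULL,
                                    bins = default_bins(model$grid)) {
  correctness <- match.arg(correctness)
  model_id <- match.arg(model_id, MODEL_IDS)
  noise_level <- match.arg(noise_level, c("low", "high"))
  if (is.null(category)) {
    category <- sign_category(theta)
    if (is.na(category))
      stop("theta = 0: the a-priori category must be given explicitly")
  }
  category <- match.arg(category, CATEGORIES)
  stopifnot(abs(diff(range(diff(bins))) ) < 1e-9,
            abs(bins[2] - bins[1] - 0.5) < 1e-9)
  p_cw <- psychometric(model, theta, noise_level)
  p_corr <- if (category == "cw") p_cw else 1 - p_cw
  if (correctness == "marginal") {
    parts <- list()
    wts <- c(correct = p_corr, incorrect = 1 - p_corr)
    probs <- numeric(length(bins) - 1L)
    for (cc in names(wts)) {
      if (wts[[cc]] < 1e-12) next
      pd <- predictive_distribution(model, theta, noise_level, model_id,
                                    cc, category, bins)
      probs <- probs + wts[[cc]] * pd$bin_probs
    }
    probs <- probs / sum(probs)
    return(structure(list(model_id = model_id, theta = theta,
                          noise_level = noise_level, correctness = "marginal",
                          category = category, bin_edges = bins,
                          bin_probs = probs),
                     class = "predictive_distribution"))
  }
  p_cond <- if (correctness == "correct") p_corr else 1 - p_corr
  if (p_cond < 1e-12)
    stop("empty condition: outcome probability ", signif(p_cond, 3),
         " at theta = ", theta)
  sup <- .predictive_support(model, theta, noise_level, model_id,
                             correctness, category)
  if (length(sup$v) > 5000) {     # merge near-identical support points
    key <- round(sup$v / 0.02)
    agg <- rowsum(sup$mass, key)
    sup <- list(v = as.numeric(rownames(agg)) * 0.02, mass = as.vector(agg))
  }
  probs <- .bin_support(sup$v, sup$mass, model$params$sigma_0, bins)
  s <- sum(probs)
  if (abs(1 - s) > 1e-3)
    stop("bin coverage loss: binned mass ", signif(s, 6))
  probs <- probs / s
  structure(list(model_id = model_id, theta = theta,
                 noise_level = noise_level, correctness = correctness,
                 category = category, bin_edges = bins, bin_probs = probs),
            class = "predictive_distribution")
}

#' Mean of a binned predictive distribution
#'
#' @param pd A [predictive_distribution()] object.
#' @return Mean estimate in deg (sum of bin centers times probabilities).
#' @export
predictive_mean <- function(pd) {
  centers <- (pd$bin_edges[-1] + pd$bin_edges[-length(pd$bin_edges)]) / 2
  sum(centers * pd$bin_probs)
}

#' Standard deviation of a binned predictive distribution
#'
#' @param pd A [predictive_distribution()] object.
#' @return SD of the binned estimate in deg.
#' @export
predictive_sd <- function(pd) {
  centers <- (pd$bin_edges[-1] + pd$bin_edges[-length(pd$bin_edges)]) / 2
  mu <- sum(centers * pd$bin_probs)
  sqrt(sum((centers - mu)^2 * pd$bin_probs))
}

#' @export
print.predictive_distribution <- function(x, ...) {
  cat(sprintf(
    "Predictive distribution: model %s, theta %g deg, %s noise, %s trials\n",
    x$model_id, x$theta, x$noise_level, x$correctness))
  cat(sprintf("  %d bins of 0.5 deg; mean %.3f deg, sd %.3f deg\n",
              length(x$bin_probs), predictive_mean(x), predictive_sd(x)))
  invisible(x)
}
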