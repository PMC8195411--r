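# Shared fixtures and an independent Monte-Carlo oracle.
#
# The oracle simulates the generative rules forward with its own numerics
# (its own fine grid, its own raised-cosine prior construction, inverse-CDF
# sampling of truncated Gaussians) so that it shares no quadrature code with
# the grid-based predictive distributions it is used to check. It assumes
# symmetric priors with p_cw = 0.5, for which the decision criterion is 0 by
# symmetry.

exp1_params <- function(sigma_0 = 2, sigma_m = 4) {
  observer_params(sigma_s_low = 3, sigma_s_high = 18, sigma_m = sigma_m,
                  alpha_cw = 21, beta = 8, sigma_0 = sigma_0)
}

exp2_params <- function(sigma_0 = 2.5) {
  observer_params(sigma_s_low = 6, sigma_s_high = 18, sigma_m = 4,
                  alpha_cw = 30, alpha_ccw = 12, beta = 8, p_cw = 0.5,
                  sigma_0 = sigma_0, experiment = "exp2")
}

# --- oracle internals ------------------------------------------------------

oracle_env <- new.env(parent = emptyenv())

# raised-cosine prior on the oracle's own grid (cw side)
.oracle_setup <- function(params, step = 0.05, half = 110) {
  key <- sprintf("%.6g_%.6g_%.6g_%.6g", params$alpha_cw, params$beta,
                 params$sigma_m, step)
  if (!is.null(oracle_env[[key]])) return(oracle_env[[key]])
  th <- seq(-half, half, by = step)
  a <- params$alpha_cw; b <- params$beta
  dens <- numeric(length(th))
  dens[th >= 0 & th <= a] <- 1
  if (b > 0) {
    roll <- th > a & th <= a + b
    dens[roll] <- 0.5 * (1 + cos(pi * (th[roll] - a) / b))
  }
  dens <- dens / (sum(dens) * step)
  st <- list(theta = th, step = step, prior_cw = dens)
  oracle_env[[key]] <- st
  st
}

# posterior-mean curve over memory samples, by direct Riemann sums on the
# oracle grid (chunked); cw prior, arbitrary likelihood width
.oracle_curve <- function(st, width) {
  nz <- which(st$prior_cw > 0)
  thnz <- st$theta[nz]
  pnz <- st$prior_cw[nz]
  f <- numeric(length(st$theta))
  for (ix in split(seq_along(st$theta),
                   ceiling(seq_along(st$theta) / 2000))) {
    W <- exp(-(outer(st$theta[ix], thnz, "-"))^2 / (2 * width^2))
    W <- W * rep(pnz, each = length(ix))
    den <- rowSums(W)
    num <- as.vector(W %*% thnz)
    f[ix] <- ifelse(den > 0, num / den, thnz[which.max(pnz)])
  }
  f
}

# Monte-Carlo estimate histogram for one condition with symmetric exp1-style
# parameters (criterion at 0). Returns bin probabilities on `edges`.
oracle_histogram <- function(params, theta, noise_level, model_id,
                             correctness, edges, n = 1e5, seed = 1,
                             category = "cw") {
  stopifnot(params$alpha_cw == params$alpha_ccw, params$p_cw == 0.5)
  st <- .oracle_setup(params)
  sigma_s <- if (noise_level == "low") params$sigma_s_low else
    params$sigma_s_high
  sigma_m <- params$sigma_m
  sig_c <- sqrt(sigma_s^2 + sigma_m^2)
  s <- if (category == "cw") 1 else -1
  set.seed(seed)
  # measurement restricted to the decision region via inverse CDF
  on_cat_side <- correctness == "correct"
  p0 <- pnorm((0 - theta) / sigma_s)
  u <- if (xor(on_cat_side, s < 0)) runif(n, p0, 1) else runif(n, 0, p0)
  m <- theta + sigma_s * qnorm(u)
  est_cat_sign <- s    # feedback-corrected category on both branches here
  if (model_id == "1a") {
    v <- est_cat_sign * sum(st$theta * st$prior_cw) * st$step
  } else if (model_id == "1b") {
    v <- est_cat_sign * sigma_s
  } else {
    if (model_id == "2b" && correctness == "incorrect") {
      lo <- pnorm(est_cat_sign * m / sig_c)   # P(wrong side) if s>0 -> lower
      ulo <- pnorm((0 - m) / sig_c)
      mm <- if (est_cat_sign > 0) m + sig_c * qnorm(runif(n, ulo, 1))
            else m + sig_c * qnorm(runif(n, 0, ulo))
    } else {
      mm <- m + rnorm(n, 0, sigma_m)
    }
    if (model_id == "2c" && correctness == "incorrect") {
      # decision posterior from the oracle's own likelihoods
      mg <- seq(-110, 110, by = 0.1)
      nz <- which(st$prior_cw > 0)
      Lcw <- vapply(mg, function(mi)
        sum(dnorm(mi, st$theta[nz], sigma_s) * st$prior_cw[nz]) * st$step,
        numeric(1))
      Lccw <- rev(Lcw)                        # mirror symmetry
      q <- Lcw / (Lcw + Lccw)
      qi <- approx(mg, q, xout = pmin(pmax(m, -110), 110))$y
      qi <- pmin(pmax(qi, 1e-12), 1 - 1e-12)
      kl <- (2 * qi - 1) * log(qi / (1 - qi))
      w <- sqrt(((1 + kl) * sigma_s)^2 + sigma_m^2)
      v <- numeric(n)
      thnz <- st$theta[nz]; pnz <- st$prior_cw[nz]
      smm <- est_cat_sign * mm                # fold onto the cw prior
      for (ix in split(seq_len(n), ceiling(seq_len(n) / 2000))) {
        W <- exp(-(outer(smm[ix], thnz, "-"))^2 / (2 * w[ix]^2))
        W <- W * rep(pnz, each = length(ix))
        den <- rowSums(W)
        v[ix] <- ifelse(den > 0, as.vector(W %*% thnz) / den,
                        thnz[which.max(pnz)])
      }
      v <- est_cat_sign * v
    } else {
      cv <- .oracle_curve(st, sig_c)
      v <- est_cat_sign *
        approx(st$theta, cv, xout = pmin(pmax(est_cat_sign * mm, -110), 110))$y
    }
  }
  est <- v + rnorm(n, 0, params$sigma_0)
  est <- pmin(pmax(est, edges[1] + 1e-9), edges[length(edges)] - 1e-9)
  h <- hist(est, breaks = edges, plot = FALSE)
  h$counts / n
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
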