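#' Conditioned stimulus prior
#'
#' The observer's prior over stimulus orientation given the category,
#' \eqn{p(\theta|C)}: zero on the opposite side of the reference, constant on
#' a plateau of width `alpha` on the category's side, then a raised-cosine
#' roll-off of width `beta`,
#' \deqn{p(\theta|C) \propto \frac{1}{2}\Big(1 + \cos\frac{\pi(|\theta| - \alpha)}{\beta}\Big),
#'   \quad \alpha < |\theta| \le \alpha + \beta,}
#' reaching exactly zero at \eqn{|\theta| = \alpha + \beta}. Before
#' discretization the plateau height is \eqn{1/(\alpha + \beta/2)} (the
#' raised cosine halves the area of the roll-off band). The discretized
#' density is renormalized so its trapezoid integral on the grid is exactly 1.
#'
#' @param category `"cw"` (support on positive orientations) or `"ccw"`.
#' @param alpha Plateau width in deg (> 0).
#' @param beta Roll-off width in deg (>= 0; 0 gives a box prior).
#' @param grid An [orientation_grid()]. Must cover `[-(alpha+beta), alpha+beta]`.
#' @return An object of class `conditioned_prior`: list with `density` (on
#'   `grid$theta`), `category`, `alpha`, `beta`.
#' @examples
#' g <- orientation_grid(-40, 40, 0.2)
#' p <- make_conditioned_prior("cw", alpha = 21, beta = 10, g)
#' @export
make_conditioned_prior <- function(category, alpha, beta, grid) {
  category <- match.arg(category, CATEGORIES)
  stopifnot(alpha > 0, beta >= 0)
  if (grid$lo > -(alpha + beta) || grid$hi < alpha + beta)
    stop("grid too narrow: prior support [", -(alpha + beta), ", ",
         alpha + beta, "] exceeds grid bounds")
  s <- category_sign(category)
  x <- s * grid$theta                       # category-signed coordinate
  dens <- numeric(grid$n)
  dens[x >= 0 & x <= alpha] <- 1
  if (beta > 0) {
    roll <- x > alpha & x <= alpha + beta
    dens[roll] <- 0.5 * (1 + cos(pi * (x[roll] - alpha) / beta))
  } else {
    dens[x == alpha] <- 0.5                 # midpoint value at the jump
  }
  dens[x == 0] <- 0.5                       # jump at the reference
  dens <- dens / (alpha + beta / 2)         # continuous normalization
  dens <- dens / grid_integral(dens, grid)  # exact on the grid
  structure(
    list(density = dens, category = category, alpha = alpha, beta = beta),
    class = "conditioned_prior"
  )
}

#' Mean of a conditioned prior
#'
#' The optimal estimate of the prior-only observer (mean of
#' \eqn{p(\theta|C)} under squared-error loss).
#'
#' @param prior A [make_conditioned_prior()] object.
#' @param grid The grid the prior was built on.
#' @return Mean orientation in degrees (signed).
#' @export
prior_mean <- function(prior, grid) {
  grid_integral(grid$theta * prior$density, grid)
}

# both conditioned priors for a parameter set
conditioned_priors <- function(params, grid) {
  list(cw  = make_conditioned_prior("cw",  params$alpha_cw,  params$beta, grid),
       ccw = make_conditioned_prior("ccw", params$alpha_ccw, params$beta, grid))
}
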