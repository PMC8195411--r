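#' Uniform orientation grid
#'
#' All densities and integrals in the observer model are evaluated by
#' trapezoid quadrature on a uniform grid of orientations (degrees relative to
#' the reference). The same grid is shared by the stimulus orientation
#' \eqn{\theta}, the sensory measurement \eqn{m} and the memory sample
#' \eqn{m_m}, so Gaussian transition kernels between them are Toeplitz and can
#' be assembled cheaply.
#'
#' @param lo,hi Grid bounds in degrees. Must bracket 0.
#' @param step Grid spacing in degrees (> 0).
#' @return An object of class `orientation_grid`: a list with elements
#'   `theta` (node vector), `step`, `lo`, `hi` and `n`.
#' @examples
#' g <- orientation_grid(-90, 90, 0.2)
#' length(g$theta)
#' @export
orientation_grid <- function(lo = -90, hi = 90, step = 0.2) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step),
            length(lo) == 1, length(hi) == 1, length(step) == 1,
            step > 0, lo < 0, hi > 0)
  n_lo <- round(-lo / step)
  n_hi <- round(hi / step)
  theta <- seq(-n_lo, n_hi) * step  # exact multiples of step; contains 0
  structure(
    list(theta = theta, step = step, lo = theta[1], hi = theta[length(theta)],
         n = length(theta)),
    class = "orientation_grid"
  )
}

#' Grid wide enough for a parameter set
#'
#' Builds a symmetric grid covering every conditioned prior's support plus at
#' least four times the largest sensory noise standard deviation beyond each
#' edge, with a floor at +/- 90 deg.
#'
#' @param params An [observer_params()] object.
#' @param step Grid spacing in degrees.
#' @return An `orientation_grid`.
#' @export
default_grid <- function(params, step = 0.2) {
  smax <- max(params$sigma_s_low, params$sigma_s_high,
              sqrt(params$sigma_s_high^2 + params$sigma_m^2))
  reach <- max(params$alpha_cw, params$alpha_ccw) + params$beta + 4 * smax
  half <- max(90, ceiling(reach / step) * step + step)
  orientation_grid(-half, half, step)
}

# trapezoid quadrature weights for a uniform grid
trapezoid_weights <- function(grid) {
  w <- rep(grid$step, grid$n)
  w[c(1, grid$n)] <- grid$step / 2
  w
}

# integral of `values` on the grid
grid_integral <- function(values, grid) {
  sum(values * trapezoid_weights(grid))
}

# index of the grid node equal to x (error if off-grid beyond tolerance)
grid_index <- function(x, grid, tol = 1e-8) {
  i <- round((x - grid$lo) / grid$step) + 1
  stopifnot(all(abs(grid$theta[i] - x) < tol))
  i
}
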