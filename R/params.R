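#' Observer parameters
#'
#' Bundles every generative / fitted parameter of the self-consistent
#' observer:
#' \describe{
#'   \item{sigma_s_low, sigma_s_high}{sensory noise SD (deg) for the low- and
#'     high-noise stimulus condition; the width of the Gaussian measurement
#'     distribution \eqn{p(m|\theta)}.}
#'   \item{sigma_m}{memory noise SD (deg); the recalled sample is
#'     \eqn{m_m \sim N(m, \sigma_m)}.}
#'   \item{alpha_cw, alpha_ccw}{width (deg) of the uniform plateau of the
#'     conditioned stimulus prior on the cw / ccw side of the reference.}
#'   \item{beta}{smoothness (deg) of the raised-cosine roll-off of the prior,
#'     shared by both sides.}
#'   \item{p_cw}{prior probability of the cw category. Fixed at 0.5 in
#'     experiment-1 (symmetric) mode; free in experiment-2 mode.}
#'   \item{sigma_0}{motor (response) noise SD in deg. Measured independently
#'     per subject and never fitted.}
#'   \item{lapse}{simulator-only probability that an estimate is replaced by a
#'     uniform random draw; used to inject inconsistent trials. Default 0.}
#' }
#'
#' @param sigma_s_low,sigma_s_high Sensory noise SDs in deg (> 0).
#' @param sigma_m Memory noise SD in deg (>= 0).
#' @param alpha_cw,alpha_ccw Prior plateau widths in deg (> 0).
#' @param beta Prior roll-off width in deg (>= 0).
#' @param p_cw Category prior probability in \[0, 1\].
#' @param sigma_0 Motor noise SD in deg (>= 0).
#' @param lapse Lapse probability in \[0, 1\] (simulator only).
#' @param experiment `"exp1"` (symmetric: requires `alpha_cw == alpha_ccw`
#'   and `p_cw == 0.5`) or `"exp2"` (asymmetric).
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(sigma_s_low = 3, sigma_s_high = 18, sigma_m = 4,
#'                 alpha_cw = 21, alpha_ccw = 21, beta = 8, sigma_0 = 2)
#' @export
observer_params <- function(sigma_s_low, sigma_s_high, sigma_m,
                            alpha_cw, alpha_ccw = alpha_cw, beta,
                            p_cw = 0.5, sigma_0 = 0, lapse = 0,
                            experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  vals <- c(sigma_s_low = sigma_s_low, sigma_s_high = sigma_s_high,
            sigma_m = sigma_m, alpha_cw = alpha_cw, alpha_ccw = alpha_ccw,
            beta = beta, p_cw = p_cw, sigma_0 = sigma_0, lapse = lapse)
  if (!all(is.finite(vals)))
    stop("observer_params: all parameters must be finite")
  stopifnot(sigma_s_low > 0, sigma_s_high > 0, sigma_m >= 0,
            alpha_cw > 0, alpha_ccw > 0, beta >= 0,
            p_cw >= 0, p_cw <= 1, sigma_0 >= 0, lapse >= 0, lapse <= 1)
  if (experiment == "exp1") {
    if (alpha_cw != alpha_ccw)
      stop("experiment-1 mode requires alpha_cw == alpha_ccw")
    if (p_cw != 0.5)
      stop("experiment-1 mode requires p_cw == 0.5")
  }
  structure(
    list(sigma_s_low = sigma_s_low, sigma_s_high = sigma_s_high,
         sigma_m = sigma_m, alpha_cw = alpha_cw, alpha_ccw = alpha_ccw,
         beta = beta, p_cw = p_cw, sigma_0 = sigma_0, lapse = lapse,
         experiment = experiment),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer parameters (", x$experiment, " mode)\n", sep = "")
  cat(sprintf("  sigma_s: %.3f (low) / %.3f (high) deg\n",
              x$sigma_s_low, x$sigma_s_high))
  cat(sprintf("  sigma_m: %.3f deg   sigma_0: %.3f deg\n",
              x$sigma_m, x$sigma_0))
  cat(sprintf("  prior:   alpha_cw %.3f, alpha_ccw %.3f, beta %.3f deg\n",
              x$alpha_cw, x$alpha_ccw, x$beta))
  cat(sprintf("  p_cw:    %.3f   lapse: %.3f\n", x$p_cw, x$lapse))
  invisible(x)
}

#' Sensory noise SD for a noise level
#'
#' @param params An [observer_params()] object.
#' @param noise_level `"low"` or `"high"`.
#' @return Sensory noise SD in degrees.
#' @export
sigma_s_for <- function(params, noise_level) {
  switch(match.arg(noise_level, c("low", "high")),
         low = params$sigma_s_low, high = params$sigma_s_high)
}

# --- category labels -------------------------------------------------------

CATEGORIES <- c("cw", "ccw")

#' Flip a category label
#'
#' `"cw"` (clockwise, positive orientations) maps to `"ccw"` and vice versa.
#'
#' @param category `"cw"` or `"ccw"` (vectorized).
#' @return The opposite label(s).
#' @examples
#' flip_category(c("cw", "ccw"))
#' @export
flip_category <- function(category) {
  stopifnot(all(category %in% CATEGORIES))
  ifelse(category == "cw", "ccw", "cw")
}

# sign convention: cw <-> +1, ccw <-> -1
category_sign <- function(category) {
  stopifnot(all(category %in% CATEGORIES))
  ifelse(category == "cw", 1, -1)
}

# category of an orientation; theta == 0 maps to NA (assigned a priori)
sign_category <- function(theta) {
  ifelse(theta > 0, "cw", ifelse(theta < 0, "ccw", NA_character_))
}
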