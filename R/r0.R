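#' Basic reproductive number of an aggregate
#'
#' `R0` is the expected number of new heritable aggregates produced per
#' aggregate lifetime.  Linearizing the aggregate moments around the
#' aggregate-free state `s = alpha/mu` gives
#' \deqn{R_0 = \frac{k_e \beta \gamma\, \alpha/\mu}
#'                  {\mu^2 + \mu\gamma(2 n_0 - 1) + \gamma^2 n_0 (n_0 - 1)}}
#' Aggregates invade exactly when `R0 > 1`, and at coexistence
#' `R0 = (alpha/mu) / s*`, i.e. the inverse of the steady-state soluble
#' fraction.  With `gamma = 0` no new templates are ever made and `R0 = 0`.
#'
#' @inheritParams moment_derivatives
#' @return Dimensionless reproduction number (>= 0).
#' @examples
#' p <- npm_params(alpha = 100, beta = 2e-4, gamma = 1e-3, mu = 7e-3, n0 = 4)
#' r0_from_params(p)            # ~51.95
#' 1 / steady_state_coexistence(p)$s * (100 / 7e-3) # identical
#' @export
r0_from_params <- function(params) {
  params <- as_npm_params(params)
  with(params, {
    if (gamma == 0) return(0)
    ke_beta <- elongation_ends * beta
    ke_beta * gamma * (alpha / mu) /
      (mu^2 + mu * gamma * (2 * n0 - 1) + gamma^2 * n0 * (n0 - 1))
  })
}

#' R0 from a measured steady-state soluble fraction
#'
#' At the coexistence steady state total protein is `alpha/mu`, so the
#' soluble fraction is `f = s*/(alpha/mu)` and `R0 = 1/f`.  A fully
#' soluble strain (`f = 1`) sits exactly at the persistence threshold.
#'
#' @param f Soluble fraction(s) in (0, 1]; vectorized.
#' @return `R0 = 1/f` (>= 1).
#' @export
r0_from_soluble_fraction <- function(f) {
  check_fraction(f)
  1 / f
}

check_fraction <- function(f, open_upper = FALSE) {
  ok <- is.numeric(f) & is.finite(f) & f > 0 & (if (open_upper) f < 1 else f <= 1)
  if (!is.numeric(f) || any(!ok))
    abort(sprintf("soluble fractions must lie in (0, 1%s)",
                  if (open_upper) "" else "]"),
          class = "propagon_domain_error")
  invisible(f)
}

#' Invert the steady state for the fragmentation rate
#'
#' Given a steady-state soluble fraction `f` and the remaining rates, solves
#' `s*(gamma) = f * alpha/mu` for `gamma`.  The steady state gives a
#' quadratic
#' \deqn{n_0(n_0-1)\gamma^2 + (\mu(2n_0-1) - k_e\beta s^*)\gamma + \mu^2 = 0}
#' which has zero or two positive roots.  The smaller (slow-fragmentation)
#' root continues smoothly to the persistence boundary as `f -> 1` and is
#' returned; both roots are attached as the `"roots"` attribute.  When no
#' positive root exists the requested `R0 = 1/f` exceeds the maximum
#' attainable over `gamma` and an error reports the attainable range.
#'
#' @param f Target steady-state soluble fraction, in (0, 1).
#' @param alpha,beta,mu,n0,elongation_ends Remaining model parameters, as in
#'   [npm_params()].
#' @param root `"small"` (default) or `"large"`: which branch to return.
#' @return Fragmentation rate `gamma` (/min) with attribute `roots`.
#' @examples
#' g <- gamma_from_soluble_fraction(0.01925, alpha = 100, beta = 2e-4,
#'                                  mu = 7e-3, n0 = 4)
#' @export
gamma_from_soluble_fraction <- function(f, alpha, beta, mu, n0,
                                        elongation_ends = 2,
                                        root = c("small", "large")) {
  root <- match.arg(root)
  if (length(f) != 1) abort("`f` must be scalar", class = "propagon_domain_error")
  check_fraction(f, open_upper = TRUE)
  params0 <- npm_params(alpha, beta, 1e-6, mu, n0, elongation_ends) # validate
  ke_beta <- elongation_ends * beta
  s_star <- f * alpha / mu
  a <- n0 * (n0 - 1)
  b <- mu * (2 * n0 - 1) - ke_beta * s_star
  cc <- mu^2
  disc <- b^2 - 4 * a * cc
  if (b >= 0 || disc < 0) {
    # s* is minimized (R0 maximized) at gamma = mu / sqrt(a)
    s_min <- mu * (2 * sqrt(a) + 2 * n0 - 1) / ke_beta
    f_min <- s_min / (alpha / mu)
    abort(sprintf(paste0(
      "no fragmentation rate reaches soluble fraction %.4g: attainable ",
      "fractions are [%.4g, 1) (R0 at most %.4g)"), f, f_min, 1 / f_min),
      class = "propagon_infeasible", attainable_f_min = f_min)
  }
  roots <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  g <- if (root == "small") roots[1] else roots[2]
  structure(g, roots = roots)
}
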