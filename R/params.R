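#' Kinetic parameters of the nucleated polymerization model
#'
#' Bundles the five rate constants of the aggregate-dynamics model together
#' with the elongation-end convention.  Protein amounts are in arbitrary
#' "monomer units" and time is in minutes; only dimensionless observables
#' (the soluble fraction and R0) are compared across strains.
#'
#' @param alpha Monomer synthesis rate (monomer units / min).  Zero is
#'   accepted so individual processes can be switched off in simulations.
#' @param beta Conversion (elongation) rate constant per fiber end
#'   (per monomer unit / min); zero switches conversion off.
#' @param gamma Fragmentation rate per internal bond (/min), >= 0.
#'   Guanidine treatment corresponds to `gamma = 0`.
#' @param mu Dilution rate from cell growth (/min), > 0; see
#'   [mu_from_doubling_time()].
#' @param n0 Minimum stable aggregate (nucleus) size in monomers; fragments
#'   smaller than `n0` dissolve instantly.  Integer >= 2.
#' @param elongation_ends Number of growing fiber ends (1 or 2).  The
#'   effective elongation propensity per fiber is
#'   `elongation_ends * beta * s`.  Two-ended growth is the default.
#'
#' @return An object of class `npm_params`.
#' @examples
#' p <- npm_params(alpha = 100, beta = 2e-4, gamma = 1e-3, mu = 7e-3, n0 = 4)
#' r0_from_params(p)
#' @export
npm_params <- function(alpha, beta, gamma, mu, n0, elongation_ends = 2) {
  stop_if_not_scalar(alpha, "alpha")
  stop_if_not_scalar(beta, "beta")
  stop_if_not_scalar(gamma, "gamma")
  stop_if_not_scalar(mu, "mu")
  stop_if_not_scalar(n0, "n0")
  if (alpha < 0) abort("`alpha` must be >= 0", class = "propagon_bad_params")
  if (beta < 0) abort("`beta` must be >= 0", class = "propagon_bad_params")
  if (gamma < 0) abort("`gamma` must be >= 0", class = "propagon_bad_params")
  if (mu <= 0) abort("`mu` must be > 0", class = "propagon_bad_params")
  if (n0 < 2 || n0 != round(n0))
    abort("`n0` must be an integer >= 2", class = "propagon_bad_params")
  if (!elongation_ends %in% c(1, 2))
    abort("`elongation_ends` must be 1 or 2", class = "propagon_bad_params")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
         n0 = as.integer(n0), elongation_ends = elongation_ends),
    class = "npm_params"
  )
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(paste0("`", name, "` must be a finite numeric scalar"),
          class = "propagon_bad_params")
  invisible(x)
}

#' @export
print.npm_params <- function(x, ...) {
  cat("<npm_params>\n")
  cat(sprintf("  alpha = %g  beta = %g  gamma = %g  mu = %g  n0 = %d\n",
              x$alpha, x$beta, x$gamma, x$mu, x$n0))
  cat(sprintf("  elongation ends: %d   R0 = %.4g\n",
              x$elongation_ends, r0_from_params(x)))
  invisible(x)
}

# effective elongation rate constant (per fiber, per monomer unit of s)
beta_eff <- function(params) params$elongation_ends * params$beta

is_npm_params <- function(x) inherits(x, "npm_params")

as_npm_params <- function(x) {
  if (is_npm_params(x)) return(x)
  if (is.list(x) || is.data.frame(x)) {
    need <- c("alpha", "beta", "gamma", "mu", "n0")
    if (all(need %in% names(x))) {
      ee <- if ("elongation_ends" %in% names(x)) x[["elongation_ends"]][1] else 2
      return(npm_params(x[["alpha"]][1], x[["beta"]][1], x[["gamma"]][1],
                        x[["mu"]][1], x[["n0"]][1], ee))
    }
  }
  abort("cannot interpret `params`: supply npm_params() or a list/row with alpha, beta, gamma, mu, n0",
        class = "propagon_bad_params")
}

#' Dilution rate from a culture doubling time
#'
#' Exponentially growing cells dilute every intracellular species at rate
#' `mu = ln(2) / t_d`.
#'
#' @param t_d Doubling time in minutes (> 0); vectorized.
#' @return Dilution rate(s) in /min satisfying `mu * t_d = log(2)`.
#' @examples
#' mu_from_doubling_time(97.7) # wildtype-like strain
#' @export
mu_from_doubling_time <- function(t_d) {
  if (!is.numeric(t_d) || any(!is.finite(t_d)) || any(t_d <= 0))
    abort("`t_d` must be positive and finite (minutes)",
          class = "propagon_bad_params")
  log(2) / t_d
}
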