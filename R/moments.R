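#' Time derivatives of the closed moment system
#'
#' The size-resolved model closes exactly in the first three moments
#' (soluble monomer `s`, fiber number `U`, aggregated mass `M`) as long as
#' every fiber has at least `n0` monomers:
#'
#' \deqn{ds/dt = \alpha - \mu s - k_e \beta s U + \gamma n_0 (n_0-1) U}
#' \deqn{dU/dt = \gamma (M - (2 n_0 - 1) U) - \mu U}
#' \deqn{dM/dt = k_e \beta s U - \gamma n_0 (n_0-1) U - \mu M}
#'
#' with \eqn{k_e} the number of growing ends.  Total protein `T = s + M`
#' obeys `dT/dt = alpha - mu * T` exactly.
#'
#' @param params An [npm_params()] object.
#' @param state Named numeric vector (or 1-row data frame) with components
#'   `s`, `U`, `M`; all finite and non-negative.
#' @return Named numeric vector `c(s = ds/dt, U = dU/dt, M = dM/dt)`.
#' @export
moment_derivatives <- function(params, state) {
  params <- as_npm_params(params)
  state <- as_moment_state(state)
  with(c(params, as.list(state)), {
    ke_beta <- elongation_ends * beta
    c(s = alpha - mu * s - ke_beta * s * U + gamma * n0 * (n0 - 1) * U,
      U = gamma * (M - (2 * n0 - 1) * U) - mu * U,
      M = ke_beta * s * U - gamma * n0 * (n0 - 1) * U - mu * M)
  })
}

as_moment_state <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, c("s", "U", "M")])
  if (is.list(state)) state <- unlist(state[c("s", "U", "M")])
  if (!all(c("s", "U", "M") %in% names(state)))
    abort("state needs named components s, U, M",
          class = "propagon_invalid_state")
  state <- state[c("s", "U", "M")]
  if (any(!is.finite(state)) || any(state < 0))
    abort("state components must be finite and non-negative",
          class = "propagon_invalid_state")
  state
}

#' Aggregate-free steady state
#'
#' Without aggregates, synthesis balances dilution at `s = alpha / mu`.
#'
#' @inheritParams moment_derivatives
#' @return A 1-row tibble with columns `s`, `U`, `M`.
#' @export
steady_state_prion_free <- function(params) {
  params <- as_npm_params(params)
  tibble(s = params$alpha / params$mu, U = 0, M = 0)
}

#' Coexistence (prion-carrying) steady state
#'
#' Closed form of the non-trivial equilibrium of the moment system:
#' \deqn{s^* = \frac{\gamma^2 n_0(n_0-1) + \mu(\gamma(2n_0-1)+\mu)}
#'                  {k_e \beta \gamma}}
#' with `M* = alpha/mu - s*` and `U* = gamma M* / (gamma (2 n0 - 1) + mu)`.
#' The state exists only when `s* < alpha/mu`, i.e. exactly when
#' [r0_from_params()] exceeds 1; otherwise (including `gamma = 0`, where
#' fragmentation-driven replication is impossible) `NULL` is returned.
#'
#' @inheritParams moment_derivatives
#' @return A 1-row tibble with columns `s`, `U`, `M`, or `NULL` when no
#'   coexistence state exists.
#' @examples
#' p <- npm_params(alpha = 100, beta = 2e-4, gamma = 1e-3, mu = 7e-3, n0 = 4)
#' steady_state_coexistence(p)
#' @export
steady_state_coexistence <- function(params) {
  params <- as_npm_params(params)
  with(params, {
    if (gamma == 0) return(NULL)
    ke_beta <- elongation_ends * beta
    D <- gamma * (2 * n0 - 1) + mu
    s_star <- (gamma^2 * n0 * (n0 - 1) + mu * D) / (ke_beta * gamma)
    if (s_star >= alpha / mu) return(NULL)
    M_star <- alpha / mu - s_star
    tibble(s = s_star, U = gamma * M_star / D, M = M_star)
  })
}

#' Integrate the moment system
#'
#' Solves the closed (s, U, M) system with a stiff-capable solver
#' (`deSolve::lsoda`).  Small negative undershoots (within the absolute
#' tolerance) are clipped to zero for reporting; anything more negative
#' raises an error, since it indicates solver misuse rather than roundoff.
#'
#' @inheritParams moment_derivatives
#' @param init Initial state: named vector or 1-row data frame with
#'   `s`, `U`, `M`.
#' @param times Strictly increasing numeric vector of output times
#'   (minutes); the first element is the initial time.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A tibble of class `npm_trajectory` with columns `t`, `s`, `U`,
#'   `M`, `total` (= s + M), carrying `params` as an attribute.
#' @examples
#' p <- npm_params(alpha = 100, beta = 2e-4, gamma = 1e-3, mu = 7e-3, n0 = 4)
#' traj <- integrate_moments(p, c(s = 100 / 7e-3, U = 1, M = 4),
#'                           times = seq(0, 5000, by = 100))
#' tail(traj)
#' @export
integrate_moments <- function(params, init, times, rtol = 1e-8,
                              atol = 1e-10) {
  params <- as_npm_params(params)
  init <- as_moment_state(init)
  check_time_grid(times)
  if (rtol <= 0 || atol <= 0)
    abort("tolerances must be positive", class = "propagon_bad_params")

  deriv <- function(t, y, p) list(moment_derivatives_raw(params, y))
  sol <- deSolve::lsoda(y = init, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    abort("moment integration failed; last good state attached",
          class = "propagon_integration_error",
          last_state = sol[nrow(sol), ])
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "t"
  out <- clip_negative(out, c("s", "U", "M"), atol)
  out$total <- out$s + out$M
  attr(out, "params") <- params
  class(out) <- c("npm_trajectory", class(out))
  out
}

# unchecked fast path used inside integrators
moment_derivatives_raw <- function(params, y) {
  s <- y[[1]]; U <- y[[2]]; M <- y[[3]]
  ke_beta <- params$elongation_ends * params$beta
  g <- params$gamma; n0 <- params$n0; mu <- params$mu
  c(params$alpha - mu * s - ke_beta * s * U + g * n0 * (n0 - 1) * U,
    g * (M - (2 * n0 - 1) * U) - mu * U,
    ke_beta * s * U - g * n0 * (n0 - 1) * U - mu * M)
}

check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2 || any(diff(times) <= 0) ||
      any(!is.finite(times)))
    abort("`times` must be a strictly increasing numeric vector",
          class = "propagon_bad_params")
  invisible(times)
}

clip_negative <- function(df, cols, atol, factor = 10) {
  for (cl in cols) {
    v <- df[[cl]]
    bad <- v < -factor * atol
    if (any(bad))
      abort(sprintf("column %s went below -%g*atol during integration (min %g)",
                    cl, factor, min(v)),
            class = "propagon_integration_error")
    df[[cl]] <- pmax(v, 0)
  }
  df
}

#' Closed-form total protein along a trajectory
#'
#' `T(t) = T(0) exp(-mu t) + (alpha/mu)(1 - exp(-mu t))`; used as the
#' conservation oracle for every integrator in the package.
#'
#' @inheritParams moment_derivatives
#' @param total0 Initial total protein `s(0) + M(0)`.
#' @param times Numeric vector of times (minutes, relative to the start).
#' @return Numeric vector of total protein values.
#' @export
total_protein_closed_form <- function(params, total0, times) {
  params <- as_npm_params(params)
  with(params, total0 * exp(-mu * times) + (alpha / mu) * (1 - exp(-mu * times)))
}
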