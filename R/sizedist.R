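#' Truncated fiber-size distribution
#'
#' Abundances `u_i` for fiber sizes `i = n0 ... i_max`.  The size-resolved
#' system is the ground truth against which the moment closure is checked;
#' fibers elongate one monomer at a time, every internal bond breaks at the
#' same rate, and break products below `n0` dissolve instantly.
#'
#' @param n0 Minimum stable size (monomers), integer >= 2.
#' @param counts Non-negative abundances for sizes `n0, n0+1, ..., i_max`.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(n0, counts) {
  if (n0 < 2 || n0 != round(n0))
    abort("`n0` must be an integer >= 2", class = "propagon_bad_params")
  if (!is.numeric(counts) || length(counts) < 1 || any(!is.finite(counts)) ||
      any(counts < 0))
    abort("`counts` must be finite non-negative abundances",
          class = "propagon_bad_params")
  structure(list(n0 = as.integer(n0), counts = as.numeric(counts),
                 i_max = as.integer(n0 + length(counts) - 1L)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> sizes %d..%d  U = %g  M = %g\n",
              x$n0, x$i_max, dist_moments(x)["U"], dist_moments(x)["M"]))
  invisible(x)
}

dist_moments <- function(dist) {
  sizes <- seq.int(dist$n0, dist$i_max)
  c(U = sum(dist$counts), M = sum(sizes * dist$counts))
}

#' Time derivatives of the size-resolved system
#'
#' For fiber size `i` (with `u_{n0 - 1} = 0`):
#' \deqn{du_i/dt = k_e\beta s (u_{i-1} - u_i) - \gamma (i-1) u_i - \mu u_i
#'                + 2\gamma \sum_{j > i} u_j}
#' Every break of a size-`j` fiber yields two pieces; a piece of size
#' `i < j` is produced at rate `2 gamma u_j`, and pieces below `n0` return
#' their mass to the monomer pool (rate `gamma n0 (n0-1)` per fiber).
#' Elongation out of the top class `i_max` leaves the system; the caller is
#' responsible for choosing `i_max` so this flux is negligible (monitored
#' by [integrate_full()]).
#'
#' @inheritParams moment_derivatives
#' @param dist A [size_distribution()].
#' @param s Soluble monomer amount (>= 0).
#' @return List with `ds` (scalar), `du` (vector over sizes), and
#'   `mass_outflux` (monomer units/min leaving through the truncation
#'   boundary).
#' @export
full_derivatives <- function(params, dist, s) {
  params <- as_npm_params(params)
  if (!inherits(dist, "size_distribution"))
    abort("`dist` must be a size_distribution", class = "propagon_bad_params")
  if (dist$n0 != params$n0)
    abort("distribution and params disagree on n0",
          class = "propagon_bad_params")
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 0)
    abort("`s` must be a finite non-negative scalar",
          class = "propagon_invalid_state")
  u <- dist$counts
  n <- length(u)
  n0 <- dist$n0
  sizes <- seq.int(n0, dist$i_max)
  keb <- beta_eff(params)
  g <- params$gamma
  mu <- params$mu
  U <- sum(u)

  # tail sums S_i = sum_{j >= i} u_j, needed as S_{i+1}
  tail_above <- rev(cumsum(rev(u))) - u
  inflow <- c(0, u[-n]) # elongation from the class below
  du <- keb * s * (inflow - u) - g * (sizes - 1) * u - mu * u +
    2 * g * tail_above
  ds <- params$alpha - mu * s - keb * s * U + g * n0 * (n0 - 1) * U
  list(ds = ds, du = du,
       mass_outflux = keb * s * u[n] * (dist$i_max + 1))
}

#' Integrate the size-resolved system
#'
#' Oracle integrator for the moment closure.  When `i_max` is `NULL` it is
#' chosen adaptively: starting from the smallest power of two at least
#' `4 * n0` (and at least three times the expected steady-state mean size
#' when a coexistence state exists), the truncation is doubled until the
#' cumulative mass lost through the boundary stays below `max_loss` of
#' total protein.  The realized loss is always reported.
#'
#' @inheritParams integrate_moments
#' @param init A [size_distribution()] (padded with zeros up to `i_max` as
#'   needed).
#' @param s0 Initial soluble monomer amount.
#' @param i_max Truncation size, or `NULL` for adaptive choice.
#' @param max_loss Acceptable truncation mass loss as a fraction of mean
#'   total protein (default 0.1%).
#' @return A tibble of class `npm_full_trajectory` with columns `t`, `s`,
#'   `U`, `M`, `total`; attributes `i_max`, `truncation_loss` (monomer
#'   units lost), `truncation_frac`, and `final_dist`.
#' @export
integrate_full <- function(params, init, s0, times, i_max = NULL,
                           rtol = 1e-8, atol = 1e-10, max_loss = 1e-3) {
  params <- as_npm_params(params)
  if (!inherits(init, "size_distribution"))
    abort("`init` must be a size_distribution", class = "propagon_bad_params")
  check_time_grid(times)
  adaptive <- is.null(i_max)
  if (adaptive) {
    guess <- 4 * params$n0
    ss <- steady_state_coexistence(params)
    if (!is.null(ss)) guess <- max(guess, 3 * ss$M / ss$U)
    i_max <- 2^ceiling(log2(max(guess, init$i_max)))
  }
  if (i_max < init$i_max)
    abort("i_max smaller than the initial distribution",
          class = "propagon_config_error")

  repeat {
    out <- integrate_full_fixed(params, init, s0, times, i_max, rtol, atol)
    if (!adaptive || attr(out, "truncation_frac") < max_loss ||
        i_max >= 2^13)
      break
    i_max <- i_max * 2
  }
  if (attr(out, "truncation_frac") >= max_loss)
    warn(sprintf("truncation loss %.3g%% exceeds %.3g%% at i_max = %d",
                 100 * attr(out, "truncation_frac"), 100 * max_loss, i_max),
         class = "propagon_truncation_warning")
  out
}

integrate_full_fixed <- function(params, init, s0, times, i_max, rtol, atol) {
  n0 <- params$n0
  sizes <- seq.int(n0, i_max)
  n <- length(sizes)
  u0 <- numeric(n)
  u0[seq_along(init$counts)] <- init$counts
  keb <- beta_eff(params)
  g <- params$gamma
  mu <- params$mu
  alpha <- params$alpha
  szm1 <- sizes - 1

  deriv <- function(t, y, p) {
    s <- y[1]
    u <- y[2:(n + 1)]
    U <- sum(u)
    tail_above <- rev(cumsum(rev(u))) - u
    inflow <- c(0, u[-n])
    du <- keb * s * (inflow - u) - g * szm1 * u - mu * u + 2 * g * tail_above
    ds <- alpha - mu * s - keb * s * U + g * n0 * (n0 - 1) * U
    dlost <- keb * s * u[n] * (i_max + 1)
    list(c(ds, du, dlost))
  }
  sol <- deSolve::lsoda(y = c(s0, u0, 0), times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    abort("size-distribution integration failed",
          class = "propagon_integration_error",
          last_state = sol[nrow(sol), ])
  y <- unname(as.matrix(sol))
  s <- pmax(y[, 2], 0)
  umat <- y[, 3:(n + 2), drop = FALSE]
  umat[umat < 0] <- 0
  U <- rowSums(umat)
  M <- as.numeric(umat %*% sizes)
  lost <- y[, n + 3]
  out <- tibble(t = y[, 1], s = s, U = U, M = M, total = s + M)
  attr(out, "params") <- params
  attr(out, "i_max") <- i_max
  attr(out, "truncation_loss") <- lost[length(lost)]
  attr(out, "truncation_frac") <-
    lost[length(lost)] / max(mean(out$total), .Machine$double.eps)
  attr(out, "final_dist") <- size_distribution(n0, umat[nrow(umat), ])
  class(out) <- c("npm_full_trajectory", class(out))
  out
}
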