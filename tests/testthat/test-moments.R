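# Reference parameter set used throughout: alpha = 100, beta = 2e-4,
# gamma = 1e-3, mu = 7e-3, n0 = 4.  Its coexistence state was frozen from
# an independent long-time integration of the moment ODEs (deSolve, rtol
# 1e-10, t = 2e5 min): s* = 275.0, U* = 1000.7653..., M* = 14010.714...
ref_params <- npm_params(alpha = 100, beta = 2e-4, gamma = 1e-3,
                         mu = 7e-3, n0 = 4)

test_that("the aggregate-free state is an exact equilibrium", {
  ss <- steady_state_prion_free(ref_params)
  expect_equal(ss$s, 100 / 7e-3)
  expect_equal(ss[, c("U", "M")], tibble::tibble(U = 0, M = 0))
  expect_equal(unname(moment_derivatives(ref_params, ss)), c(0, 0, 0))
  p1 <- npm_params(0.004, 1e-4, 1e-4, 0.004, 4) # alpha == mu
  expect_equal(steady_state_prion_free(p1)$s, 1)
})

test_that("total protein obeys dT/dt = alpha - mu T for any valid state", {
  set.seed(101)
  for (i in 1:50) {
    p <- rand_params(c(0.3, 8))
    st <- rand_state(p)
    d <- moment_derivatives(p, st)
    expect_equal(d[["s"]] + d[["M"]], p$alpha - p$mu * (st[["s"]] + st[["M"]]),
                 tolerance = 1e-12)
  }
})

test_that("invalid states are rejected", {
  expect_error(moment_derivatives(ref_params, c(s = -1, U = 0, M = 0)),
               class = "propagon_invalid_state")
  expect_error(moment_derivatives(ref_params, c(s = 1, U = NaN, M = 0)),
               class = "propagon_invalid_state")
  expect_error(moment_derivatives(ref_params, c(s = 1, U = Inf, M = 0)),
               class = "propagon_invalid_state")
})

test_that("coexistence closed form matches the long-time integration", {
  ss <- steady_state_coexistence(ref_params)
  expect_equal(ss$s, 275.0, tolerance = 1e-12)
  expect_equal(ss$U, 1000.7653061224491, tolerance = 1e-12)
  expect_equal(ss$s + ss$M, 100 / 7e-3, tolerance = 1e-14)
  # all three derivatives vanish (relative to the state scale)
  d <- moment_derivatives(ref_params, ss)
  expect_true(all(abs(d) <= 1e-10 * unlist(ss[c("s", "U", "M")])))
  # and the trajectory actually converges there
  traj <- integrate_moments(ref_params,
                            c(s = 100 / 7e-3, U = 1, M = 4),
                            times = c(0, 10^(2:5)))
  final <- unlist(traj[nrow(traj), c("s", "U", "M")])
  expect_rel_equal(final, unlist(ss[c("s", "U", "M")]), 1e-3)
})

test_that("coexistence exists exactly when R0 exceeds one", {
  expect_null(steady_state_coexistence(
    npm_params(100, 2e-4, 0, 7e-3, 4)))
  set.seed(202)
  for (i in 1:100) {
    p <- rand_params(c(0.2, 5))
    ss <- steady_state_coexistence(p)
    if (r0_from_params(p) > 1) {
      expect_false(is.null(ss))
      expect_true(all(unlist(ss) > 0))
    } else {
      expect_null(ss)
    }
  }
})

test_that("moment trajectories conserve total protein", {
  set.seed(303)
  times <- seq(0, 2000, by = 250)
  for (i in 1:10) {
    p <- rand_params(c(0.5, 8))
    st <- rand_state(p)
    traj <- integrate_moments(p, st, times, rtol = 1e-8, atol = 1e-10)
    expect_rel_equal(traj$total,
                     total_protein_closed_form(p, sum(st[c("s", "M")]), times),
                     1e-7)
  }
})

test_that("an aggregate-free trajectory relaxes exponentially to alpha/mu", {
  p <- ref_params
  times <- seq(0, 1000, by = 100)
  traj <- integrate_moments(p, c(s = 1000, U = 0, M = 0), times)
  expect_rel_equal(traj$s, total_protein_closed_form(p, 1000, times), 1e-7)
  expect_equal(traj$U, rep(0, length(times)))
})

test_that("a trajectory started at coexistence stays there", {
  ss <- steady_state_coexistence(ref_params)
  traj <- integrate_moments(ref_params, ss, times = seq(0, 5000, by = 1000))
  for (cl in c("s", "U", "M"))
    expect_rel_equal(traj[[cl]], rep(ss[[cl]], nrow(traj)), 1e-6)
})

test_that("time grids must be strictly increasing", {
  expect_error(integrate_moments(ref_params, c(s = 1, U = 0, M = 0),
                                 c(0, 0, 1)),
               class = "propagon_bad_params")
})

test_that("R0 is proportional to gamma in the dilution-dominated regime", {
  # gamma (2 n0 - 1) <= mu/100 and gamma n0 (n0 - 1) <= mu/100
  mu <- 7e-3
  n0 <- 4
  gammas <- 10^seq(log10(5.8e-7), log10(5.8e-6), length.out = 7)
  stopifnot(max(gammas) * (2 * n0 - 1) <= mu / 100,
            max(gammas) * n0 * (n0 - 1) <= mu / 100)
  ratio <- vapply(gammas, function(g)
    r0_from_params(npm_params(100, 2e-4, g, mu, n0)) / g, 0)
  expect_lt(max(ratio) / min(ratio) - 1, 0.02)
})
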