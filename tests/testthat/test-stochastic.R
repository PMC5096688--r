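test_that("protocol construction is validated", {
  expect_error(protocol(c(100, -5), c(0, 1)), class = "propagon_config_error")
  expect_error(protocol(100, 1.5), class = "propagon_config_error")
  expect_error(protocol(100, 1, sample_times = 200),
               class = "propagon_config_error")
  pr <- recovery_protocol(curing = 600, recovery = 600, sample_every = 200)
  expect_equal(nrow(pr$phases), 2)
  expect_equal(pr$phases$gamma_scale, c(0, 1))
  expect_equal(pr$sample_times, c(600, 800, 1000, 1200))
})

test_that("identical seeds give identical trajectories", {
  p <- npm_params(7, 3e-4, 1e-3, 7e-3, 4)
  init <- cell_state(1000, rep(10L, 20))
  a <- simulate_well_mixed(p, init, 200, seed = 31)
  b <- simulate_well_mixed(p, init, 200, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  pr <- recovery_protocol(curing = 200, recovery = 200, sample_every = 100)
  la <- simulate_lineage(p, pr, init = init, t_d = 95, seed = 13)
  lb <- simulate_lineage(p, pr, init = init, t_d = 95, seed = 13)
  expect_identical(as.data.frame(la), as.data.frame(lb))
})

test_that("with all reactions off, fibers are a pure death process", {
  # each fiber survives dilution for time t with probability exp(-mu t)
  p <- npm_params(0, 0, 0, 0.01, 4)
  init <- cell_state(0, rep(4L, 200))
  set.seed(77)
  finals <- vapply(1:600, function(i) {
    sim <- simulate_well_mixed(p, init, 100, sample_times = c(0, 100))
    sim$U[2]
  }, 0)
  expected <- 200 * exp(-1)
  se <- sqrt(200 * exp(-1) * (1 - exp(-1))) / sqrt(600)
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("ensemble means track the moment ODEs", {
  pan <- default_panel()
  p <- panel_params(pan[1, ])
  init <- cell_state(round(p$alpha / p$mu), rep(10L, 20))
  times <- c(0, 150, 300)
  set.seed(88)
  runs <- lapply(1:300, function(i)
    as.matrix(simulate_well_mixed(p, init, 300,
                                  sample_times = times)[, c("s", "U", "M")]))
  arr <- simplify2array(runs)
  mn <- apply(arr, 1:2, mean)
  se <- apply(arr, 1:2, sd) / sqrt(length(runs))
  ode <- integrate_moments(p, c(s = round(p$alpha / p$mu), U = 20, M = 200),
                           times)
  z <- (mn[-1, ] - as.matrix(ode[-1, c("s", "U", "M")])) / se[-1, ]
  expect_lt(max(abs(z)), 3)
})

test_that("a nucleus-sized fiber is destroyed by its first fragmentation", {
  # both pieces of any break of a size-n0 fiber dissolve, so U can only
  # step from 1 to 0
  p <- npm_params(0, 0, 0.05, 1e-9, 4)
  set.seed(99)
  for (i in 1:20) {
    sim <- simulate_well_mixed(p, cell_state(0, 4L), 500,
                               sample_times = seq(0, 500, by = 5),
                               audit = TRUE)
    expect_true(all(sim$U %in% c(0, 1)))
    expect_true(all(diff(sim$U) <= 0))
    expect_equal(sim$U[length(sim$U)], 0) # mean waiting time 1/(3 gamma)
    # dissolved fiber mass returned to the monomer pool
    expect_equal(sim$s + sim$M, rep(4, nrow(sim)))
  }
})

test_that("division partitions fibers binomially", {
  p <- npm_params(0, 0, 0, 7e-3, 4)
  pr <- protocol(100, 0, sample_times = c(0, 100))
  N <- 1000
  init <- cell_state(0, rep(4L, N))
  set.seed(111)
  finals <- vapply(1:400, function(i) {
    rec <- simulate_lineage(p, pr, init = init, t_d = 60, p_keep = 0.5)
    rec$propagons[2]
  }, 0)
  expect_lt(abs(mean(finals) - N / 2), 3 * sqrt(N * 0.25 / 400))
  v <- var(finals)
  se_var <- sqrt(2 / 399) * N * 0.25
  expect_lt(abs(v - N * 0.25), 3 * se_var)
})

test_that("curing halves propagons every generation", {
  # fragmentation off, 5 divisions: mean count 1000 / 2^5
  p <- npm_params(0, 0, 1e-3, 7e-3, 4)
  pr <- protocol(500, 0, labels = "GdnHCl", sample_times = c(0, 500))
  init <- cell_state(0, rep(4L, 1000))
  set.seed(222)
  finals <- vapply(1:200, function(i) {
    rec <- simulate_lineage(p, pr, init = init, t_d = 99, p_keep = 0.5)
    rec$propagons[2]
  }, 0)
  expected <- 1000 / 2^5
  se <- sqrt(1000 * (1 / 32) * (1 - 1 / 32)) / sqrt(200)
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("division alone conserves total propagons across the population", {
  p <- npm_params(0, 0, 1e-3, 7e-3, 4)
  pr <- protocol(400, 0, sample_times = seq(0, 400, by = 100))
  init <- cell_state(0, rep(5L, 137))
  pop <- simulate_population(p, pr, init = init, t_d = 80, seed = 17)
  totals <- tapply(pop$propagons, pop$time_min, sum)
  expect_true(all(totals == 137))
  # per-cell mean halves each generation
  means <- tapply(pop$propagons, pop$time_min, mean)
  expect_equal(as.numeric(means[c("80", "160")]),
               c(137 / 2, 137 / 4))
})

test_that("the event audit passes on a supercritical run", {
  pan <- default_panel()
  p <- panel_params(pan[5, ]) # R2E1
  expect_no_error(
    simulate_well_mixed(p, steady_state_cell(p), 120, seed = 3,
                        audit = TRUE))
})

test_that("amplification rate recovers an exact exponential", {
  tbl <- tibble::tibble(time_min = rep(c(0, 60, 120, 180), each = 2),
                        propagons = rep(round(50 * exp(0.004 * c(0, 60, 120, 180))),
                                        each = 2))
  r <- amplification_rate(tbl)
  agg <- round(50 * exp(0.004 * c(0, 60, 120, 180)))
  fit <- stats::lm(log(agg) ~ c(0, 60, 120, 180))
  expect_equal(r$rate_per_min, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_error(amplification_rate(tbl, window = c(0, 60)),
               class = "propagon_window_error")
  tbl0 <- tibble::tibble(time_min = c(0, 60, 120), propagons = c(2, 0, 3))
  expect_error(amplification_rate(tbl0), class = "propagon_window_error")
})

test_that("faster fragmentation gives a faster fitted recovery", {
  pan <- default_panel()
  two <- pan[pan$strain %in% c("dRPR", "R2E1"), ]
  pr <- recovery_protocol()
  tbl <- generate_propagon_timecourse(two, pr, n_cells = 16, seed = 314)
  rates <- amplification_rate(tbl)
  expect_gt(rates$rate_per_min[rates$strain == "R2E1"],
            rates$rate_per_min[rates$strain == "dRPR"])
})

test_that("the plating assay is binomial with the stated efficiency", {
  expect_identical(propagon_assay(137), 137L)
  expect_identical(propagon_assay(0, 0.5, seed = 1), 0L)
  set.seed(5)
  obs <- propagon_assay(rep(1000L, 1000), 0.5)
  expect_lt(abs(mean(obs) - 500), 3 * sqrt(1000 * 0.25) / sqrt(1000))
  expect_error(propagon_assay(-1), class = "propagon_domain_error")
  expect_error(propagon_assay(10, 0), class = "propagon_domain_error")
})
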