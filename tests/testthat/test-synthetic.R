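test_that("the default panel encodes the expected strain structure", {
  pan <- default_panel()
  expect_equal(pan$strain,
               c("RWT", "R1-5", "dRPR", "R1-5dRPR", "R2E1", "R2E2"))
  g <- setNames(pan$gamma, pan$strain)
  # strict fragmentation ordering across the panel
  expect_true(g[["R2E2"]] > g[["R2E1"]])
  expect_true(g[["R2E1"]] > g[["RWT"]])
  expect_true(g[["RWT"]] > g[["R1-5"]])
  expect_true(g[["R1-5"]] > g[["dRPR"]])
  expect_true(g[["dRPR"]] > g[["R1-5dRPR"]])
  # shared alpha, beta, n0; per-strain dilution from the doubling times
  expect_equal(length(unique(pan$alpha)), 1)
  expect_equal(length(unique(pan$beta)), 1)
  expect_equal(pan$mu, unname(mu_from_doubling_time(pan$t_d)))
  truth <- ground_truth(pan)
  expect_true(all(truth$r0 > 1))
  r0 <- setNames(truth$r0, truth$strain)
  expect_gt(r0[["RWT"]], r0[["dRPR"]])
  expect_gt(r0[["R2E2"]], r0[["RWT"]])
  # wildtype and R1-5 are built to be experimentally indistinguishable
  f <- setNames(truth$soluble_fraction, truth$strain)
  expect_equal(f[["RWT"]], f[["R1-5"]], tolerance = 1e-8)
  # panel construction is deterministic
  expect_identical(default_panel(), pan)
})

test_that("ground truth satisfies the model identities", {
  truth <- ground_truth(default_panel())
  expect_equal(truth$r0, 1 / truth$soluble_fraction)
  pan <- default_panel()
  for (i in seq_len(nrow(pan))) {
    g <- gamma_from_soluble_fraction(truth$soluble_fraction[i],
                                     pan$alpha[i], pan$beta[i],
                                     pan$mu[i], pan$n0[i])
    expect_equal(as.numeric(g), truth$gamma[i], tolerance = 1e-8)
  }
})

test_that("soluble tables are exact at zero noise and unbiased otherwise", {
  pan <- default_panel(noise_sd = 0)
  tbl <- generate_soluble_table(pan, seed = 1)
  truth <- ground_truth(pan)
  expect_equal(tbl$soluble_fraction,
               rep(truth$soluble_fraction, each = 6))
  # large-replicate mean converges on the truth
  pan1 <- default_panel(n_reps = 10000)[1, ]
  tbl1 <- generate_soluble_table(pan1, seed = 2)
  se <- 0.01 / sqrt(10000)
  expect_lt(abs(mean(tbl1$soluble_fraction) -
                  ground_truth(pan1)$soluble_fraction), 3 * se)
})

test_that("subcritical strains are rejected by the soluble generator", {
  pan <- default_panel()[1, ]
  pan$gamma <- 1e-9 # effectively no fragmentation: R0 < 1
  expect_lt(ground_truth(pan)$r0, 1)
  expect_error(generate_soluble_table(pan, seed = 1),
               class = "propagon_generator_error")
})

test_that("study generation is bit-identical under the master seed", {
  pan <- default_panel()[c(1, 5), ]
  s1 <- synthetic_study(pan, master_seed = 11, n_cells = 3,
                        protocol = recovery_protocol(curing = 300,
                                                     recovery = 300,
                                                     sample_every = 150))
  s2 <- synthetic_study(pan, master_seed = 11, n_cells = 3,
                        protocol = recovery_protocol(curing = 300,
                                                     recovery = 300,
                                                     sample_every = 150))
  expect_identical(s1$soluble, s2$soluble)
  expect_identical(s1$propagons, s2$propagons)
  s3 <- synthetic_study(pan, master_seed = 12, n_cells = 3,
                        protocol = recovery_protocol(curing = 300,
                                                     recovery = 300,
                                                     sample_every = 150))
  expect_false(identical(s1$soluble, s3$soluble))
})

test_that("propagon tables show the curing decay then recovery", {
  pan <- default_panel()[6, ] # R2E2: slow growth keeps counts high
  # pure curing: per-generation halving on the table
  cure <- protocol(pan$t_d * 3, 0, sample_times = pan$t_d * (0:3))
  tbl <- generate_propagon_timecourse(pan, cure, n_cells = 40, seed = 21)
  m <- tapply(tbl$propagons, tbl$time_min, mean)
  u0 <- m[[1]]
  expect_rel_equal(unname(m), u0 / 2^(0:3), 0.2)
  # default protocol: mean counts rise during recovery
  tbl2 <- generate_propagon_timecourse(pan, recovery_protocol(),
                                       n_cells = 24, seed = 22)
  m2 <- tapply(tbl2$propagons, tbl2$time_min, mean)
  expect_gt(m2[[length(m2)]], m2[[1]])
})
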