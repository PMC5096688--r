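#' Measured doubling times of the strain panel
#'
#' Doubling times (minutes, rich medium) of the prion-propagating repeat
#' and RPR sequence-variant strains.  `R1-5dRPR` is not separately
#' tabulated and is assigned the `dRPR` value, its closest construct.
#'
#' @return Named numeric vector of doubling times in minutes.
#' @export
strain_doubling_times <- function() {
  c(RWT = 97.7, `R1-5` = 99.1, dRPR = 99.5, `R1-5dRPR` = 99.5,
    R2E1 = 112.3, R2E2 = 166.0)
}

# gamma defaults (per internal bond, /min) for the panel.  R1-5 is solved at
# construction so that its steady-state soluble fraction matches RWT exactly
# (the two strains are experimentally indistinguishable) despite their
# different growth rates.
panel_gamma <- c(RWT = 1.70e-4, `R1-5` = NA, dRPR = 1.45e-4,
                 `R1-5dRPR` = 1.25e-4, R2E1 = 1.95e-4, R2E2 = 2.20e-4)

#' Default six-strain synthetic panel
#'
#' Ground-truth parameterization of the six prion-propagating strains
#' (RWT, R1-5, dRPR, R1-5dRPR, R2E1, R2E2).  All strains share the
#' synthesis rate, conversion rate and nucleus size; fragmentation rates
#' are strictly ordered `R2E2 > R2E1 > RWT > R1-5 > dRPR > R1-5dRPR`
#' (with R1-5 within 2% of RWT), and each strain uses its own measured
#' doubling time.  The conversion rate is calibrated once so that the
#' fastest-fragmenting strain (R2E2) has `R0 = 10`; the panel then spans
#' `R0` of roughly 1.5 to 10, a range in which the soluble-fraction
#' measurement (replicate noise sd 0.01) still constrains `gamma` well.
#'
#' @param alpha Shared synthesis rate (monomer units/min).
#' @param n0 Shared nucleus size.
#' @param n_reps Replicates per strain for the soluble-fraction generator.
#' @param noise_sd Measurement noise sd on soluble fractions.
#' @return Tibble with one row per strain: `strain`, `alpha`, `beta`,
#'   `gamma`, `mu`, `n0`, `elongation_ends`, `t_d`, `n_reps`, `noise_sd`.
#' @examples
#' default_panel()
#' @export
default_panel <- function(alpha = 100, n0 = 4, n_reps = 6, noise_sd = 0.01) {
  t_d <- strain_doubling_times()
  mu <- mu_from_doubling_time(t_d)
  # calibrate beta: R0 is linear in beta, target R0(R2E2) = 10
  r0_unit <- r0_from_params(npm_params(alpha, 1, panel_gamma[["R2E2"]],
                                       mu[["R2E2"]], n0))
  beta <- 10 / r0_unit
  gamma <- panel_gamma
  f_rwt <- 1 / r0_from_params(npm_params(alpha, beta, gamma[["RWT"]],
                                         mu[["RWT"]], n0))
  gamma[["R1-5"]] <- as.numeric(
    gamma_from_soluble_fraction(f_rwt, alpha, beta, mu[["R1-5"]], n0))
  tibble(strain = names(t_d), alpha = alpha, beta = beta,
         gamma = unname(gamma[names(t_d)]), mu = unname(mu),
         n0 = as.integer(n0), elongation_ends = 2, t_d = unname(t_d),
         n_reps = as.integer(n_reps), noise_sd = noise_sd)
}

panel_params <- function(row) {
  npm_params(row$alpha, row$beta, row$gamma, row$mu, row$n0,
             row$elongation_ends)
}

#' Ground truth for a strain panel
#'
#' Exact per-strain fragmentation rate, steady-state soluble fraction and
#' R0 from the closed forms; the answer key for parameter-recovery tests.
#'
#' @param panel A panel tibble as from [default_panel()].
#' @return Tibble: `strain`, `gamma`, `mu`, `t_d`, `soluble_fraction`,
#'   `r0`.
#' @export
ground_truth <- function(panel) {
  check_columns(panel, c("strain", "alpha", "beta", "gamma", "mu", "n0"),
                "panel")
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    r0 <- r0_from_params(panel_params(row))
    tibble(strain = row$strain, gamma = row$gamma, mu = row$mu,
           t_d = if ("t_d" %in% names(row)) row$t_d else log(2) / row$mu,
           soluble_fraction = 1 / r0, r0 = r0)
  })
}

#' Generate a replicate soluble-fraction table
#'
#' Emulates the thermal-solubility measurement: per strain, `n_reps`
#' replicate soluble fractions equal to the exact steady-state fraction
#' plus additive Gaussian noise (`noise_sd`), clamped into (0, 1].
#' Subcritical strains (no coexistence state, hence no prion-carrying
#' soluble level) are rejected.
#'
#' @param panel Panel tibble (one or more strain rows), as from
#'   [default_panel()].
#' @param seed Optional integer; generation is deterministic given the
#'   seed.
#' @return Tibble with columns `strain`, `replicate`, `soluble_fraction`.
#' @export
generate_soluble_table <- function(panel, seed = NULL) {
  check_columns(panel, c("strain", "alpha", "beta", "gamma", "mu", "n0",
                         "n_reps", "noise_sd"), "panel")
  truth <- ground_truth(panel)
  sub <- truth$r0 <= 1
  if (any(sub))
    abort(paste0("subcritical strain(s) cannot be measured: ",
                 paste(truth$strain[sub], collapse = ", ")),
          class = "propagon_generator_error")
  with_optional_seed(seed, {
    purrr::map_dfr(seq_len(nrow(panel)), function(i) {
      f <- truth$soluble_fraction[i] +
        rnorm(panel$n_reps[i], 0, panel$noise_sd[i])
      tibble(strain = panel$strain[i], replicate = seq_len(panel$n_reps[i]),
             soluble_fraction = pmin(pmax(f, 1e-6), 1))
    })
  })
}

#' Generate per-cell propagon time courses
#'
#' Emulates the curing / recovery assay: for each strain, `n_cells`
#' independent cell lineages are simulated through the protocol with
#' [simulate_lineage()], all drawing from one RNG stream seeded by `seed`,
#' and the propagon count of every cell is recorded at each sample time.
#'
#' @inheritParams generate_soluble_table
#' @param protocol A [protocol()]; default [recovery_protocol()].
#' @param n_cells Lineages per strain.
#' @param p_keep Fiber retention probability at division.
#' @return Tibble with columns `strain`, `time_min`, `cell_id`,
#'   `propagons`.
#' @export
generate_propagon_timecourse <- function(panel,
                                         protocol = recovery_protocol(),
                                         n_cells = 64, p_keep = 0.5,
                                         seed = NULL) {
  check_columns(panel, c("strain", "alpha", "beta", "gamma", "mu", "n0",
                         "t_d"), "panel")
  if (n_cells < 1)
    abort("`n_cells` must be >= 1", class = "propagon_bad_params")
  # one seeded RNG scope for the whole table: cells draw from a common
  # stream, so tables from different seeds are independent
  with_optional_seed(seed, {
    purrr::map_dfr(seq_len(nrow(panel)), function(i) {
      row <- panel[i, ]
      params <- panel_params(row)
      init <- steady_state_cell(params)
      purrr::map_dfr(seq_len(n_cells), function(cell) {
        rec <- simulate_lineage(params, protocol, init = init,
                                t_d = row$t_d, p_keep = p_keep)
        tibble(strain = row$strain, time_min = rec$time_min,
               cell_id = cell, propagons = as.integer(rec$propagons))
      })
    })
  })
}

#' Generate a complete synthetic study
#'
#' Bundles the panel ground truth, a soluble-fraction table and a propagon
#' time-course table, all derived deterministically from one master seed.
#'
#' @param panel Panel tibble; default [default_panel()].
#' @param master_seed Integer seed; the soluble and propagon generators use
#'   offsets of it.
#' @param protocol Protocol for the propagon assay.
#' @param n_cells Lineages per strain (set to 0 to skip the propagon
#'   table).
#' @return Object of class `synthetic_study`: list with `panel`, `truth`,
#'   `soluble`, `propagons`, `master_seed`.
#' @export
synthetic_study <- function(panel = default_panel(), master_seed = 1,
                            protocol = recovery_protocol(), n_cells = 64) {
  study <- list(
    panel = panel,
    truth = ground_truth(panel),
    soluble = generate_soluble_table(panel, seed = master_seed),
    propagons = if (n_cells > 0)
      generate_propagon_timecourse(panel, protocol, n_cells = n_cells,
                                   seed = master_seed + 500000L)
    else NULL,
    master_seed = master_seed)
  class(study) <- "synthetic_study"
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d strains, seed %d\n", nrow(x$panel),
              x$master_seed))
  cat(sprintf("  soluble: %d rows; propagons: %s rows\n", nrow(x$soluble),
              if (is.null(x$propagons)) "no" else nrow(x$propagons)))
  invisible(x)
}
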