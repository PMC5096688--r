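#' Define a curing / recovery protocol
#'
#' A protocol is an ordered list of phases, each with a duration and a
#' fragmentation multiplier, plus the times at which per-cell propagon
#' counts are sampled.  `gamma_scale = 0` encodes guanidine treatment,
#' which inhibits Hsp104 and blocks fragmentation while synthesis and
#' conversion continue.
#'
#' @param durations Phase durations in minutes (> 0).
#' @param gamma_scales Fragmentation multipliers in \[0, 1\], one per phase.
#' @param labels Optional phase labels.
#' @param sample_times Times (minutes from protocol start, within the total
#'   duration) at which propagon counts are recorded.
#' @return An object of class `propagon_protocol`.
#' @seealso [recovery_protocol()] for the standard curing-then-recovery
#'   assay.
#' @export
protocol <- function(durations, gamma_scales, labels = NULL,
                     sample_times = numeric()) {
  if (length(durations) != length(gamma_scales) || length(durations) == 0)
    abort("durations and gamma_scales must have equal positive length",
          class = "propagon_config_error")
  if (any(!is.finite(durations)) || any(durations <= 0))
    abort("phase durations must be positive", class = "propagon_config_error")
  if (any(!is.finite(gamma_scales)) || any(gamma_scales < 0) ||
      any(gamma_scales > 1))
    abort("gamma_scales must lie in [0, 1]", class = "propagon_config_error")
  total <- sum(durations)
  if (any(sample_times < 0) || any(sample_times > total))
    abort("sample_times must lie within the protocol duration",
          class = "propagon_config_error")
  if (is.null(labels))
    labels <- paste0("phase", seq_along(durations))
  structure(list(
    phases = tibble(duration = as.numeric(durations),
                    gamma_scale = as.numeric(gamma_scales),
                    label = as.character(labels)),
    sample_times = sort(as.numeric(sample_times)),
    total = total), class = "propagon_protocol")
}

#' Standard guanidine curing / recovery protocol
#'
#' Cells are grown in GdnHCl (fragmentation blocked) for `curing` minutes,
#' then released into rich medium for `recovery` minutes; propagon counts
#' are sampled every `sample_every` minutes during recovery, starting at
#' release.
#'
#' @param curing Curing-phase duration in minutes (default 720, i.e. 12 h).
#' @param recovery Recovery duration in minutes (default 720).
#' @param sample_every Sampling interval during recovery (minutes).
#' @return A [protocol()].
#' @export
recovery_protocol <- function(curing = 720, recovery = 720,
                              sample_every = 120) {
  protocol(durations = c(curing, recovery), gamma_scales = c(0, 1),
           labels = c("GdnHCl", "recovery"),
           sample_times = curing + seq(0, recovery, by = sample_every))
}

#' @export
print.propagon_protocol <- function(x, ...) {
  cat(sprintf("<propagon_protocol> %d phase(s), %g min, %d sample times\n",
              nrow(x$phases), x$total, length(x$sample_times)))
  print(x$phases)
  invisible(x)
}

#' Construct a single-cell state
#'
#' @param s Soluble monomer count (non-negative integer).
#' @param aggregates Integer vector of fiber sizes, all >= `n0` of the model
#'   in use.
#' @return An object of class `cell_state`; the propagon count of a cell is
#'   simply `length(aggregates)`.
#' @export
cell_state <- function(s, aggregates = integer()) {
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 0 ||
      s != round(s))
    abort("`s` must be a non-negative integer", class = "propagon_bad_params")
  if (length(aggregates) > 0 &&
      (any(!is.finite(aggregates)) || any(aggregates != round(aggregates)) ||
       any(aggregates < 2)))
    abort("aggregate sizes must be integers >= 2",
          class = "propagon_bad_params")
  structure(list(s = as.numeric(s), aggregates = as.integer(aggregates)),
            class = "cell_state")
}

#' Steady-state cell for a parameter set
#'
#' Rounds the coexistence steady state to an integer-valued cell: `U*`
#' fibers whose sizes split `M*` as evenly as possible.
#'
#' @inheritParams moment_derivatives
#' @return A [cell_state()].
#' @export
steady_state_cell <- function(params) {
  params <- as_npm_params(params)
  ss <- steady_state_coexistence(params)
  if (is.null(ss))
    abort("no coexistence steady state for these parameters (R0 <= 1)",
          class = "propagon_config_error")
  U <- max(1L, round(ss$U))
  base <- floor(ss$M / U)
  extra <- round(ss$M - base * U)
  sizes <- rep(base, U) + c(rep(1L, extra), rep(0L, U - extra))
  cell_state(round(ss$s), pmax(sizes, params$n0))
}

#' Exact stochastic simulation of a well-mixed compartment
#'
#' Gillespie simulation of the molecule-level model (synthesis, dilution of
#' monomer and fibers, two-ended elongation, per-bond fragmentation with
#' instant dissolution of sub-`n0` pieces).  This is the brute-force
#' oracle for [integrate_moments()]: ensemble means of (s, U, M) track the
#' moment ODEs.
#'
#' @inheritParams moment_derivatives
#' @param init A [cell_state()].
#' @param t_max End time (minutes).
#' @param sample_times Times at which (s, U, M) are recorded; defaults to
#'   51 evenly spaced points.
#' @param seed Optional integer for a reproducible local RNG scope.
#' @param audit When `TRUE`, every event is checked for mass balance and
#'   fragmentation bookkeeping (slower; used by tests).
#' @param max_events Abort guard against unbounded-growth configurations.
#' @return Tibble with columns `t`, `s`, `U`, `M` and attribute
#'   `final_state` (a `cell_state`).
#' @examples
#' p <- npm_params(alpha = 7, beta = 3e-4, gamma = 1e-3, mu = 7e-3, n0 = 4)
#' sim <- simulate_well_mixed(p, cell_state(1000, rep(10, 20)), 500, seed = 1)
#' @export
simulate_well_mixed <- function(params, init, t_max, sample_times = NULL,
                                seed = NULL, audit = FALSE,
                                max_events = 5e7) {
  params <- as_npm_params(params)
  if (!inherits(init, "cell_state"))
    abort("`init` must be a cell_state", class = "propagon_bad_params")
  if (length(init$aggregates) > 0 && any(init$aggregates < params$n0))
    abort("initial fiber sizes must be >= n0", class = "propagon_bad_params")
  if (!is.finite(t_max) || t_max <= 0)
    abort("`t_max` must be positive and finite", class = "propagon_bad_params")
  if (is.null(sample_times)) sample_times <- seq(0, t_max, length.out = 51)
  sample_times <- sort(sample_times)

  res <- with_optional_seed(seed,
    ssa_segment(init$s, init$aggregates, params$alpha, beta_eff(params),
                params$gamma, params$mu, params$n0, 0, t_max, sample_times,
                dilution = TRUE, audit = audit, max_events = max_events))
  out <- tibble(t = res$samples[, 1], s = res$samples[, 2],
                U = res$samples[, 3], M = res$samples[, 4])
  attr(out, "final_state") <- cell_state(res$s, res$sizes)
  attr(out, "params") <- params
  out
}

#' Simulate one cell lineage through a curing / recovery protocol
#'
#' Follows a single (focal) cell through the phases of a [protocol()].
#' Within a phase the cell evolves as in [simulate_well_mixed()] with the
#' fragmentation rate scaled by the phase's `gamma_scale`, but with no
#' continuous dilution: dilution is implemented by division.  Every `t_d`
#' minutes the cell divides; each fiber stays with the focal cell
#' independently with probability `p_keep` and the monomer count is halved
#' binomially.  Propagon counts (number of fibers) are recorded at the
#' protocol's sample times.
#'
#' @inheritParams simulate_well_mixed
#' @param protocol A [protocol()].
#' @param t_d Division interval in minutes (> 0).
#' @param p_keep Probability that the focal cell retains a given fiber at
#'   division (in (0, 1); 0.5 is a symmetric partition).
#' @param init A [cell_state()], or `NULL` for [steady_state_cell()].
#' @return Tibble with columns `time_min`, `propagons`, `s`, `M`;
#'   attributes `division_times` and `seed`.
#' @export
simulate_lineage <- function(params, protocol, init = NULL, t_d,
                             p_keep = 0.5, seed = NULL, audit = FALSE,
                             max_events = 5e7) {
  params <- as_npm_params(params)
  if (!inherits(protocol, "propagon_protocol"))
    abort("`protocol` must be a propagon_protocol",
          class = "propagon_config_error")
  if (!is.finite(t_d) || t_d <= 0)
    abort("`t_d` must be positive", class = "propagon_bad_params")
  if (!is.finite(p_keep) || p_keep <= 0 || p_keep >= 1)
    abort("`p_keep` must be in (0, 1)", class = "propagon_bad_params")
  if (is.null(init)) init <- steady_state_cell(params)
  if (!inherits(init, "cell_state"))
    abort("`init` must be a cell_state", class = "propagon_bad_params")

  with_optional_seed(seed, {
    run_lineage(params, protocol, init, t_d, p_keep, audit, max_events,
                seed_label = seed)
  })
}

run_lineage <- function(params, protocol, init, t_d, p_keep, audit,
                        max_events, seed_label = NULL) {
  division_times <- seq(t_d, protocol$total, by = t_d)
  phase_ends <- cumsum(protocol$phases$duration)
  breaks <- sort(unique(c(protocol$sample_times, division_times, phase_ends,
                          protocol$total)))
  breaks <- breaks[breaks > 0]

  s <- init$s
  sizes <- init$aggregates
  t_now <- 0
  samp <- matrix(NA_real_, nrow = length(protocol$sample_times), ncol = 3)
  record <- function(tm) {
    idx <- which(abs(protocol$sample_times - tm) < 1e-9)
    for (i in idx) samp[i, ] <<- c(length(sizes), s, sum(sizes))
  }
  record(0)

  for (b in breaks) {
    phase_idx <- findInterval(b - 1e-9, c(0, phase_ends),
                              rightmost.closed = FALSE)
    gsc <- protocol$phases$gamma_scale[min(phase_idx, nrow(protocol$phases))]
    res <- ssa_segment(s, sizes, params$alpha, beta_eff(params),
                       params$gamma * gsc, params$mu, params$n0,
                       t_now, b, numeric(), dilution = FALSE, audit = audit,
                       max_events = max_events)
    s <- res$s
    sizes <- res$sizes
    t_now <- b
    if (any(abs(division_times - b) < 1e-9)) {
      keep <- stats::runif(length(sizes)) < p_keep
      sizes <- sizes[keep]
      s <- rbinom(1, s, 0.5)
    }
    record(b)
  }
  out <- tibble(time_min = protocol$sample_times, propagons = samp[, 1],
                s = samp[, 2], M = samp[, 3])
  attr(out, "division_times") <- division_times
  attr(out, "seed") <- seed_label
  out
}

#' Simulate the whole descending cell population
#'
#' Like [simulate_lineage()] but every daughter cell is kept and simulated,
#' so conservation laws over the full population can be checked (e.g. with
#' fragmentation blocked the total propagon count across all cells is
#' exactly constant).  The population doubles at each division, so this is
#' only practical for a handful of generations.
#'
#' @inheritParams simulate_lineage
#' @return Tibble with columns `time_min`, `cell_id`, `propagons`.
#' @export
simulate_population <- function(params, protocol, init = NULL, t_d,
                                p_keep = 0.5, seed = NULL,
                                max_events = 5e7) {
  params <- as_npm_params(params)
  if (!inherits(protocol, "propagon_protocol"))
    abort("`protocol` must be a propagon_protocol",
          class = "propagon_config_error")
  if (is.null(init)) init <- steady_state_cell(params)
  n_div <- floor(protocol$total / t_d)
  if (2^n_div > 4096)
    abort("population tracking limited to 12 divisions",
          class = "propagon_config_error")
  phase_ends <- cumsum(protocol$phases$duration)

  with_optional_seed(seed, {
    cells <- list(list(s = init$s, sizes = init$aggregates))
    t_now <- 0
    division_times <- seq(t_d, protocol$total, by = t_d)
    boundaries <- sort(unique(c(division_times, protocol$total, phase_ends)))
    records <- list()
    snap <- function(tm) {
      tibble(time_min = tm, cell_id = seq_along(cells),
             propagons = vapply(cells, function(cl) length(cl$sizes), 0L))
    }
    records[[1]] <- snap(0)
    for (b in boundaries) {
      phase_idx <- findInterval(b - 1e-9, c(0, phase_ends))
      gsc <- protocol$phases$gamma_scale[min(phase_idx,
                                             nrow(protocol$phases))]
      cells <- lapply(cells, function(cl) {
        res <- ssa_segment(cl$s, cl$sizes, params$alpha, beta_eff(params),
                           params$gamma * gsc, params$mu, params$n0,
                           t_now, b, numeric(), dilution = FALSE,
                           audit = FALSE, max_events = max_events)
        list(s = res$s, sizes = res$sizes)
      })
      t_now <- b
      if (any(abs(division_times - b) < 1e-9)) {
        cells <- unlist(lapply(cells, function(cl) {
          keep <- stats::runif(length(cl$sizes)) < p_keep
          s_keep <- rbinom(1, cl$s, 0.5)
          list(list(s = s_keep, sizes = cl$sizes[keep]),
               list(s = cl$s - s_keep, sizes = cl$sizes[!keep]))
        }), recursive = FALSE)
      }
      records[[length(records) + 1]] <- snap(b)
    }
    dplyr::bind_rows(records)
  })
}

#' Fit the propagon re-amplification rate
#'
#' The early-recovery growth of propagon counts is approximately
#' exponential, so the rate is estimated as the least-squares slope of
#' `log(summary propagon count)` against time over the chosen window.
#' The recovery rate rises with the fragmentation rate (at matched
#' conversion), which is what makes the assay a fragmentation read-out.
#'
#' @param data Propagon table with columns `time_min` and `propagons`
#'   (optionally `strain`, in which case one rate per strain is returned).
#' @param window Optional vector of sample times to use (default: all).
#' @param summary `"mean"` (default) or `"median"` of per-cell counts at
#'   each time.
#' @return Tibble with columns `strain` (if present), `rate_per_min`,
#'   `se`, `n_times`.
#' @export
amplification_rate <- function(data, window = NULL,
                               summary = c("mean", "median")) {
  summary <- match.arg(summary)
  check_columns(data, c("time_min", "propagons"), "propagon table")
  fit_one <- function(df, label) {
    agg <- dplyr::summarise(
      dplyr::group_by(df, .data$time_min),
      value = if (summary == "mean") mean(.data$propagons) else
        stats::median(.data$propagons),
      .groups = "drop")
    if (!is.null(window)) agg <- agg[agg$time_min %in% window, ]
    if (nrow(agg) < 3)
      abort("need at least 3 sample times in the window",
            class = "propagon_window_error")
    if (any(agg$value <= 0))
      abort(sprintf("zero %s propagon count at t = %g: shrink the window",
                    summary, agg$time_min[which(agg$value <= 0)[1]]),
            class = "propagon_window_error")
    fit <- lm(log(value) ~ time_min, data = agg)
    tibble(strain = label, rate_per_min = unname(coef(fit)[2]),
           se = summary(fit)$coefficients[2, 2], n_times = nrow(agg))
  }
  if ("strain" %in% names(data)) {
    out <- purrr::imap_dfr(split(data, data$strain), fit_one)
  } else {
    out <- fit_one(data, NA_character_)
    out$strain <- NULL
  }
  out
}

#' Colony-based propagon counting assay
#'
#' The in-vivo dilution assay detects each propagon as one prion-positive
#' colony; with imperfect plating each propagon is detected independently
#' with probability `plating_efficiency`.
#'
#' @param true_count Non-negative integer propagon count(s).
#' @param plating_efficiency Detection probability in (0, 1].
#' @param seed Optional integer for reproducibility.
#' @return Observed count(s); `Binomial(true_count, plating_efficiency)`.
#' @export
propagon_assay <- function(true_count, plating_efficiency = 1, seed = NULL) {
  if (any(!is.finite(true_count)) || any(true_count < 0) ||
      any(true_count != round(true_count)))
    abort("`true_count` must be non-negative integer(s)",
          class = "propagon_domain_error")
  if (plating_efficiency <= 0 || plating_efficiency > 1)
    abort("`plating_efficiency` must be in (0, 1]",
          class = "propagon_domain_error")
  if (plating_efficiency == 1) return(as.integer(true_count))
  with_optional_seed(seed,
    rbinom(length(true_count), as.integer(true_count), plating_efficiency))
}
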