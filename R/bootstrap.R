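#' Bootstrap estimate of R0 for one strain
#'
#' The point estimate is the plug-in `R0 = 1 / mean(f)` (the soluble
#' fraction `f` is the directly measured quantity; `point = "mean_inv"`
#' gives `mean(1/f)` instead).  Confidence intervals come from resampling
#' replicates with replacement:
#'
#' * `"robust"` (default): the wider of the `"student"` and `"expanded"`
#'   intervals below, guarding against the known small-sample failure
#'   modes of each;
#' * `"student"`: equal-tailed studentized (bootstrap-t) interval for
#'   `mean(f)`, mapped through `1/x`;
#' * `"expanded"`: percentile interval with Hesterberg's small-sample
#'   expanded quantile levels;
#' * `"percentile"`: the plain percentile interval of `1/mean`.
#'
#' With fewer than two distinct replicate values the interval degenerates
#' to the point estimate.
#'
#' @param replicates Numeric vector of soluble fractions in (0, 1]
#'   (>= 2 values for a meaningful interval).
#' @param strain Optional strain label carried into the result.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Optional integer; when supplied the resampling is done in a
#'   local RNG scope so results are reproducible and the caller's RNG
#'   state is untouched.
#' @param method Interval method, see above.
#' @param point `"inv_mean"` (default) or `"mean_inv"`.
#' @return A 1-row tibble: `strain`, `r0`, `ci_low`, `ci_high`, `n`,
#'   `n_boot`, `method`.
#' @examples
#' bootstrap_r0(c(0.04, 0.05, 0.06), strain = "RWT", seed = 1)
#' @export
bootstrap_r0 <- function(replicates, strain = NA_character_, n_boot = 10000,
                         ci_level = 0.95, seed = NULL,
                         method = c("robust", "student", "expanded",
                                    "percentile"),
                         point = c("inv_mean", "mean_inv")) {
  method <- match.arg(method)
  point <- match.arg(point)
  check_replicates(replicates, strain)
  if (n_boot < 1000)
    abort("`n_boot` must be >= 1000", class = "propagon_bad_params")
  if (ci_level <= 0 || ci_level >= 1)
    abort("`ci_level` must be in (0, 1)", class = "propagon_bad_params")

  est <- if (point == "inv_mean") 1 / mean(replicates) else
    mean(1 / replicates)
  ci <- with_optional_seed(seed,
    boot_ci_r0(replicates, n_boot, ci_level, method, point))
  tibble(strain = strain, r0 = est,
         ci_low = min(ci[1], est), ci_high = max(ci[2], est),
         n = length(replicates), n_boot = as.integer(n_boot),
         method = method)
}

check_replicates <- function(x, strain = NA_character_) {
  if (!is.numeric(x) || length(x) < 1)
    abort("replicates must be a numeric vector",
          class = "propagon_data_error")
  bad <- which(!is.finite(x) | x <= 0 | x > 1)
  if (length(bad) > 0)
    abort(sprintf("replicate %d%s is outside (0, 1]: %s", bad[1],
                  if (is.na(strain)) "" else paste0(" of strain ", strain),
                  format(x[bad[1]])),
          class = "propagon_data_error")
  invisible(x)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# expanded-percentile tail probability (Hesterberg 2015): the percentile
# interval of a mean at small n is too narrow by roughly the t/normal and
# n/(n-1) factors; widen the quantile levels accordingly.
expanded_alpha <- function(n, ci_level) {
  alpha <- (1 - ci_level) / 2
  if (n < 2) return(alpha)
  pnorm(-qt(1 - alpha, n - 1) * sqrt(n / (n - 1)))
}

boot_means <- function(x, n_boot) {
  m <- matrix(sample(x, length(x) * n_boot, replace = TRUE), nrow = n_boot)
  n <- ncol(m)
  list(mean = rowMeans(m),
       var = (rowMeans(m^2) - rowMeans(m)^2) * n / (n - 1))
}

boot_ci_r0 <- function(x, n_boot, ci_level, method, point) {
  n <- length(x)
  if (length(unique(x)) < 2) {
    est <- if (point == "inv_mean") 1 / mean(x) else mean(1 / x)
    return(c(est, est))
  }
  alpha <- (1 - ci_level) / 2
  if (point == "mean_inv") { # bootstrap the mean of 1/f directly
    bs <- boot_means(1 / x, n_boot)
    return(unname(quantile(bs$mean, c(alpha, 1 - alpha))))
  }
  bs <- boot_means(x, n_boot)
  m <- mean(x)
  se <- sd(x) / sqrt(n)
  ci_from_mean_interval <- function(ci_m) {
    ci_m <- pmin(pmax(ci_m, .Machine$double.eps), 1)
    sort(1 / ci_m)
  }
  student <- function() {
    tq <- quantile((bs$mean - m) / sqrt(bs$var / n), c(alpha, 1 - alpha),
                   names = FALSE, na.rm = TRUE)
    ci_from_mean_interval(c(m - tq[2] * se, m - tq[1] * se))
  }
  expanded <- function() {
    a <- expanded_alpha(n, ci_level)
    ci_from_mean_interval(quantile(bs$mean, c(a, 1 - a), names = FALSE))
  }
  switch(method,
    percentile = unname(quantile(1 / bs$mean, c(alpha, 1 - alpha))),
    expanded = expanded(),
    student = student(),
    robust = {
      ci_s <- student(); ci_e <- expanded()
      c(min(ci_s[1], ci_e[1]), max(ci_s[2], ci_e[2]))
    })
}

#' Compare R0 between two strains
#'
#' Estimates `delta = R0(a) - R0(b)` with a confidence interval from
#' independent resampling of the two replicate sets, and flags the pair as
#' significantly different exactly when the interval excludes zero.  The
#' default interval is a symmetric studentized bootstrap (resample SEs are
#' floored at half the plug-in SE to avoid degenerate studentized
#' statistics at small n) at `ci_level = 0.99`; the conservative default
#' reflects that pairs are reported without any multiplicity correction.
#'
#' @param a,b Numeric vectors of soluble fractions for the two strains.
#' @param strain_a,strain_b Labels.
#' @param n_boot,seed As in [bootstrap_r0()].
#' @param ci_level Confidence level for the difference (default 0.99).
#' @param method `"student_sym"` (default), `"expanded"` or `"percentile"`.
#' @return A 1-row tibble: `strain_a`, `strain_b`, `delta`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
compare_r0 <- function(a, b, strain_a = "a", strain_b = "b", n_boot = 10000,
                       ci_level = 0.99, seed = NULL,
                       method = c("student_sym", "expanded", "percentile")) {
  method <- match.arg(method)
  check_replicates(a, strain_a)
  check_replicates(b, strain_b)
  if (n_boot < 1000)
    abort("`n_boot` must be >= 1000", class = "propagon_bad_params")
  d <- 1 / mean(a) - 1 / mean(b)
  ci <- with_optional_seed(seed, boot_ci_delta(a, b, n_boot, ci_level, method))
  tibble(strain_a = strain_a, strain_b = strain_b, delta = d,
         ci_low = ci[1], ci_high = ci[2],
         significant = ci[1] > 0 || ci[2] < 0)
}

boot_ci_delta <- function(a, b, n_boot, ci_level, method) {
  na <- length(a); nb <- length(b)
  d <- 1 / mean(a) - 1 / mean(b)
  if (length(unique(a)) < 2 && length(unique(b)) < 2) return(c(d, d))
  bsa <- boot_means(a, n_boot)
  bsb <- boot_means(b, n_boot)
  dd <- 1 / bsa$mean - 1 / bsb$mean
  alpha <- (1 - ci_level) / 2
  switch(method,
    percentile = unname(quantile(dd, c(alpha, 1 - alpha))),
    expanded = {
      aa <- expanded_alpha(min(na, nb), ci_level)
      unname(quantile(dd, c(aa, 1 - aa)))
    },
    student_sym = {
      # delta-method SEs for 1/mean(a) - 1/mean(b)
      sed <- sqrt(var(a) / na / mean(a)^4 + var(b) / nb / mean(b)^4)
      if (sed == 0) return(c(d, d))
      sedd <- sqrt(bsa$var / na / bsa$mean^4 + bsb$var / nb / bsb$mean^4)
      sedd <- pmax(sedd, 0.5 * sed)
      q <- quantile(abs(dd - d) / sedd, ci_level, names = FALSE)
      c(d - q * sed, d + q * sed)
    })
}

#' Infer R0 per strain from a replicate soluble-fraction table
#'
#' Data-frame-first wrapper around [bootstrap_r0()]: groups the table by
#' strain and returns a fitted object with [tidy()]/[glance()] methods and
#' an [autoplot()].
#'
#' @param data Data frame with columns `strain` and `soluble_fraction`
#'   (such as the output of [generate_soluble_table()] or
#'   [read_soluble_table()]).
#' @inheritParams bootstrap_r0
#' @return An object of class `r0_fit`.
#' @examples
#' panel <- default_panel()
#' tbl <- generate_soluble_table(panel, seed = 42)
#' fit <- infer_r0(tbl, seed = 1)
#' tidy(fit)
#' @export
infer_r0 <- function(data, n_boot = 10000, ci_level = 0.95, seed = NULL,
                     method = c("robust", "student", "expanded",
                                "percentile"),
                     point = c("inv_mean", "mean_inv")) {
  method <- match.arg(method)
  point <- match.arg(point)
  check_columns(data, c("strain", "soluble_fraction"), "soluble table")
  groups <- split(data$soluble_fraction, data$strain)
  seeds <- derive_seeds(seed, groups)
  est <- purrr::imap(groups, function(x, nm) {
    bootstrap_r0(x, strain = nm, n_boot = n_boot, ci_level = ci_level,
                 seed = seeds[[nm]], method = method, point = point)
  })
  structure(
    list(estimates = dplyr::bind_rows(est), data = as_tibble(data),
         settings = list(n_boot = n_boot, ci_level = ci_level, seed = seed,
                         method = method, point = point)),
    class = "r0_fit")
}

derive_seeds <- function(seed, n) {
  nms <- NULL
  if (is.list(n)) { nms <- names(n); n <- length(n) }
  if (is.null(seed)) return(setNames(rep(list(NULL), n), nms))
  setNames(as.list(seed + seq_len(n) - 1L), nms)
}

#' @export
print.r0_fit <- function(x, ...) {
  cat(sprintf("<r0_fit> %d strain(s), %d replicates, %s bootstrap (B = %d)\n",
              nrow(x$estimates), nrow(x$data), x$settings$method,
              x$settings$n_boot))
  print(x$estimates)
  invisible(x)
}

#' @rdname infer_r0
#' @param x An `r0_fit` object.
#' @param ... Unused.
#' @export
tidy.r0_fit <- function(x, ...) x$estimates

#' @rdname infer_r0
#' @export
glance.r0_fit <- function(x, ...) {
  tibble(n_strains = nrow(x$estimates), n_obs = nrow(x$data),
         n_boot = x$settings$n_boot, ci_level = x$settings$ci_level,
         method = x$settings$method)
}

#' Pairwise strain comparisons of R0
#'
#' Runs [compare_r0()] for the requested strain pairs of a replicate table
#' (or of the data inside an [infer_r0()] fit).
#'
#' @param data Data frame with `strain` and `soluble_fraction` columns, or
#'   an `r0_fit`.
#' @param pairs Two-column character matrix / data frame of (strain_a,
#'   strain_b) pairs, or `NULL` for all unordered pairs.
#' @inheritParams compare_r0
#' @return Tibble with one row per comparison.
#' @export
compare_strains <- function(data, pairs = NULL, n_boot = 10000,
                            ci_level = 0.99, seed = NULL,
                            method = c("student_sym", "expanded",
                                       "percentile")) {
  method <- match.arg(method)
  if (inherits(data, "r0_fit")) data <- data$data
  check_columns(data, c("strain", "soluble_fraction"), "soluble table")
  groups <- split(data$soluble_fraction, data$strain)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(groups), 2))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2)
    abort("`pairs` must have two columns", class = "propagon_bad_params")
  missing <- setdiff(unique(as.vector(pairs)), names(groups))
  if (length(missing) > 0)
    abort(paste0("strain(s) not in the table: ",
                 paste(missing, collapse = ", ")),
          class = "propagon_data_error")
  seeds <- derive_seeds(seed, nrow(pairs))
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    compare_r0(groups[[pairs[i, 1]]], groups[[pairs[i, 2]]],
               strain_a = pairs[i, 1], strain_b = pairs[i, 2],
               n_boot = n_boot, ci_level = ci_level, seed = seeds[[i]],
               method = method)
  })
}

check_columns <- function(data, cols, what) {
  if (!is.data.frame(data))
    abort(paste0(what, " must be a data frame"),
          class = "propagon_data_error")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0)
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "propagon_data_error")
  invisible(data)
}
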