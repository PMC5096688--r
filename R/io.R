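delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, what) {
  if (!file.exists(path))
    abort(paste0(what, " file not found: ", path),
          class = "propagon_parse_error")
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    progress = FALSE)
}

parse_stop <- function(path, line, msg) {
  abort(sprintf("%s:%d: %s", path, line, msg),
        class = "propagon_parse_error")
}

#' Read a replicate soluble-fraction table
#'
#' Reads a delimited text file (TSV by default, CSV by extension) with
#' columns `strain`, `replicate` and `soluble_fraction` (fractions in
#' (0, 1]).  A `soluble_percent` column is accepted instead and converted
#' to fractions with an explicit message — percentages are never guessed
#' silently.  Malformed rows are rejected with the file name and line
#' number (header is line 1).
#'
#' @param path File path.
#' @return Tibble with columns `strain`, `replicate`, `soluble_fraction`.
#' @export
read_soluble_table <- function(path) {
  df <- read_table_checked(path, "soluble table")
  if ("soluble_percent" %in% names(df) &&
      !"soluble_fraction" %in% names(df)) {
    message("read_soluble_table: converting soluble_percent to fractions ",
            "(divided by 100)")
    df$soluble_fraction <- suppressWarnings(as.numeric(df$soluble_percent)) / 100
    df$soluble_percent <- NULL
  }
  need <- c("strain", "replicate", "soluble_fraction")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    abort(paste0(path, ": missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "propagon_parse_error")
  f <- suppressWarnings(as.numeric(df$soluble_fraction))
  for (i in seq_along(f)) {
    if (is.na(f[i]))
      parse_stop(path, i + 1L, "non-numeric soluble_fraction")
    if (f[i] <= 0 || f[i] > 1)
      parse_stop(path, i + 1L,
                 sprintf("soluble_fraction %g outside (0, 1]", f[i]))
  }
  tibble(strain = as.character(df$strain),
         replicate = as.integer(df$replicate), soluble_fraction = f)
}

#' Write a soluble-fraction table
#'
#' @param x Tibble with columns `strain`, `replicate`, `soluble_fraction`.
#' @param path Output path (`.tsv` default, `.csv` by extension).
#' @return `x`, invisibly.
#' @export
write_soluble_table <- function(x, path) {
  check_columns(x, c("strain", "replicate", "soluble_fraction"),
                "soluble table")
  check_fraction(x$soluble_fraction)
  readr::write_delim(x[, c("strain", "replicate", "soluble_fraction")],
                     path, delim = delim_for(path))
  invisible(x)
}

#' Read a per-cell propagon table
#'
#' Columns `strain`, `time_min`, `cell_id`, `propagons` (non-negative
#' integers).  Rows are validated and returned sorted by strain, time and
#' cell; malformed values are rejected with file and line.
#'
#' @param path File path.
#' @return Sorted tibble.
#' @export
read_propagon_table <- function(path) {
  df <- read_table_checked(path, "propagon table")
  need <- c("strain", "time_min", "cell_id", "propagons")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    abort(paste0(path, ": missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "propagon_parse_error")
  p <- suppressWarnings(as.numeric(df$propagons))
  tm <- suppressWarnings(as.numeric(df$time_min))
  for (i in seq_along(p)) {
    if (is.na(p[i]) || p[i] < 0 || p[i] != round(p[i]))
      parse_stop(path, i + 1L,
                 sprintf("propagons must be a non-negative integer (got %s)",
                         as.character(df$propagons[i])))
    if (is.na(tm[i]))
      parse_stop(path, i + 1L, "non-numeric time_min")
  }
  out <- tibble(strain = as.character(df$strain), time_min = tm,
                cell_id = as.integer(df$cell_id),
                propagons = as.integer(p))
  dplyr::arrange(out, .data$strain, .data$time_min, .data$cell_id)
}

#' Write a per-cell propagon table
#'
#' @param x Tibble with columns `strain`, `time_min`, `cell_id`,
#'   `propagons`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_propagon_table <- function(x, path) {
  check_columns(x, c("strain", "time_min", "cell_id", "propagons"),
                "propagon table")
  if (any(x$propagons < 0) || any(x$propagons != round(x$propagons)))
    abort("propagons must be non-negative integers",
          class = "propagon_data_error")
  readr::write_delim(x[, c("strain", "time_min", "cell_id", "propagons")],
                     path, delim = delim_for(path))
  invisible(x)
}

run_config_defaults <- function() {
  list(alpha = 100, beta = NULL, n0 = 4, elongation_ends = 2,
       n_boot = 10000, ci_level = 0.95, comparison_ci_level = 0.99,
       root = "small", p_keep = 0.5, n_cells = 64, curing = 720,
       recovery = 720, sample_every = 120, seed = 1,
       n_reps = 6, noise_sd = 0.01)
}

#' Read a run configuration file
#'
#' YAML (or JSON read as YAML) configuration for the command-line
#' pipeline.  Unknown keys are rejected rather than ignored; known keys
#' override the documented defaults, which are returned when `path` is
#' `NULL`.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for defaults.
#' @return Named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    abort(paste0(path, ": unknown config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "propagon_parse_error")
  utils::modifyList(defaults, cfg)
}
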