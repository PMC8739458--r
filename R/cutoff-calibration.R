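# Re-deriving QC cutoffs from historical distributions: percentile borders
# (default: the value excluding the bottom 2% of data), predicted
# below-cutoff / outside-window fractions, and rule-set comparison by flag
# deltas.

.calib_parameters <- c("is_peak_area", "peak_area", "sn", "rrt",
                       "concentration", "confirming_ion_area")

# Pull one parameter's values out of a results selection; "rrt" is computed.
parameter_values <- function(results, parameter) {
  parameter <- match.arg(parameter, .calib_parameters)
  if (parameter == "rrt") {
    compute_rrt(results$rt, results$is_rt)
  } else {
    results[[parameter]]
  }
}

#' Empirical percentile border
#'
#' The value below which a given fraction of the historical distribution
#' falls — the candidate cutoff that excludes, by default, the bottom 2% of
#' data. Uses linear interpolation between order statistics (the "type 7"
#' quantile definition), so the estimate is deterministic and convergent.
#'
#' @param values Numeric vector; `NA`s are dropped before computation.
#' @param level Fraction in (0, 1); default 0.02.
#' @return The empirical quantile at `level`.
#' @examples
#' empirical_border(1:100, 0.02)
#' @export
empirical_border <- function(values, level = 0.02) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("level must be a single fraction in (0, 1)")
  }
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no non-missing values to compute a border from")
  unname(quantile(values, probs = level, type = 7, names = FALSE))
}

#' Fraction of values below a cutoff
#'
#' Strict inequality, mirroring the flag engine's pass-at-equality
#' convention, so a predicted fail fraction matches the realised flag rate
#' exactly.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param cutoff The cutoff value.
#' @return `count(value < cutoff) / count(non-missing)`.
#' @export
fraction_below <- function(values, cutoff) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no non-missing values")
  mean(values < cutoff)
}

#' Fraction of values outside a window
#'
#' Inclusive bounds count as inside, matching the RRT rule.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param window Length-2 numeric `(low, high)`, `low < high`.
#' @return `count(value < low or value > high) / count(non-missing)`.
#' @export
fraction_outside_window <- function(values, window) {
  stopifnot(length(window) == 2)
  low <- window[[1]]; high <- window[[2]]
  if (!(low < high)) abort("window must satisfy low < high")
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no non-missing values")
  mean(values < low | values > high)
}

#' Derive percentile-based cutoffs per compound and instrument
#'
#' Groups the filtered historical results by (compound, instrument) and
#' computes the [empirical_border()] of one parameter for each group —
#' between-instrument signal differences make per-instrument borders
#' essential. Groups smaller than `min_n` are skipped with a warning.
#'
#' Restricting `filter` to calibrator + QC rows evaluates cutoffs against
#' controlled material; including patient rows adds matrix effects to the
#' picture. Both are one configuration of the same code path.
#'
#' @param con Connection from [init_schema()].
#' @param filter A [result_filter()].
#' @param parameter One of `"is_peak_area"`, `"peak_area"`, `"sn"`, `"rrt"`,
#'   `"concentration"`, `"confirming_ion_area"`.
#' @param level Percentile level in (0, 1); default 0.02.
#' @param min_n Minimum non-missing group size (default 50).
#' @return A tibble of cutoff estimates: `compound`, `instrument_id`,
#'   `parameter`, `level`, `border`, `n`, `date_start`, `date_end`,
#'   `sample_types`.
#' @export
derive_cutoffs <- function(con, filter = result_filter(),
                           parameter = "is_peak_area", level = 0.02,
                           min_n = 50) {
  parameter <- match.arg(parameter, .calib_parameters)
  rows <- query_results(con, filter)
  if (nrow(rows) == 0) abort("filter selects no results")
  rows$.value <- parameter_values(rows, parameter)
  st <- paste(sort(unique(rows$sample_type)), collapse = ",")
  out <- rows |>
    group_by(.data$compound, .data$instrument_id) |>
    summarise(
      n = sum(!is.na(.data$.value)),
      border = if (sum(!is.na(.data$.value)) > 0)
        empirical_border(.data$.value, level) else NA_real_,
      date_start = min(.data$injection_time, na.rm = TRUE),
      date_end = max(.data$injection_time, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(parameter = parameter, level = level, sample_types = st) |>
    select("compound", "instrument_id", "parameter", "level", "border",
           "n", "date_start", "date_end", "sample_types")
  small <- out$n < min_n
  if (any(small)) {
    warn(paste0("skipping ", sum(small), " group(s) with fewer than ", min_n,
                " values: ",
                paste(out$compound[small], "@", out$instrument_id[small],
                      collapse = "; ")))
    out <- out[!small, ]
  }
  out
}

#' Compare two rule sets by their flag deltas
#'
#' Evaluates both rule sets on the identical set of (result, rule)
#' observation pairs from the filtered selection and counts transitions:
#' a *new* flag fails under the new rules but passed under the old; a
#' *removed* flag is the converse. Observations are the pairs evaluable
#' (pass or fail) under both rule sets over their shared rules.
#'
#' @param con Connection from [init_schema()].
#' @param filter A [result_filter()] selecting the evaluation rows.
#' @param old,new `qc_ruleset` objects.
#' @return A `ruleset_comparison`: `n_observations`, `n_new_flags`,
#'   `n_removed_flags`, `pct_increase` (= 100 * new/observations),
#'   `pct_decrease`, and `per_rule_breakdown`. `glance()` gives the one-row
#'   summary.
#' @export
compare_rulesets <- function(con, filter = result_filter(), old, new) {
  stopifnot(inherits(old, "qc_ruleset"), inherits(new, "qc_ruleset"))
  rows <- query_results(con, filter)
  if (nrow(rows) == 0) abort("filter selects no results")
  # calibrator context for ion-ratio expectations, regardless of filter
  ctx <- query_results(con, result_filter(
    batches = unique(rows$xml_file_name), sample_types = "calibrator"))
  ctx <- bind_rows(ctx, rows[rows$sample_type == "calibrator", ]) |>
    distinct(.data$result_key, .keep_all = TRUE)

  f_old <- evaluate_results(rows, old, context = ctx)
  f_new <- evaluate_results(rows, new, context = ctx)

  joined <- dplyr::inner_join(
    f_old |> select("result_key", "rule", old_status = "status"),
    f_new |> select("result_key", "rule", new_status = "status"),
    by = c("result_key", "rule")
  ) |>
    filter(.data$old_status != "not_evaluable",
           .data$new_status != "not_evaluable")

  joined <- joined |>
    mutate(transition = dplyr::case_when(
      .data$new_status == "fail" & .data$old_status == "pass" ~ "new",
      .data$new_status == "pass" & .data$old_status == "fail" ~ "removed",
      TRUE ~ "unchanged"
    ))
  n_obs <- nrow(joined)
  n_new <- sum(joined$transition == "new")
  n_removed <- sum(joined$transition == "removed")
  breakdown <- joined |>
    group_by(.data$rule) |>
    summarise(n_observations = n(),
              n_new = sum(.data$transition == "new"),
              n_removed = sum(.data$transition == "removed"),
              .groups = "drop")
  structure(list(
    old_name = old$name, new_name = new$name,
    n_observations = n_obs, n_new_flags = n_new, n_removed_flags = n_removed,
    pct_increase = 100 * n_new / n_obs,
    pct_decrease = 100 * n_removed / n_obs,
    per_rule_breakdown = breakdown
  ), class = "ruleset_comparison")
}

#' @export
print.ruleset_comparison <- function(x, ...) {
  cat(sprintf(
    "<ruleset_comparison> '%s' -> '%s' on %d observations\n  new flags: %d (%.2f%%)  removed flags: %d (%.2f%%)\n",
    x$old_name, x$new_name, x$n_observations, x$n_new_flags, x$pct_increase,
    x$n_removed_flags, x$pct_decrease))
  print(x$per_rule_breakdown)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ruleset_comparison <- function(x, ...) {
  tibble(old_name = x$old_name, new_name = x$new_name,
         n_observations = x$n_observations, n_new_flags = x$n_new_flags,
         n_removed_flags = x$n_removed_flags, pct_increase = x$pct_increase,
         pct_decrease = x$pct_decrease)
}

#' @exportS3Method generics::tidy
tidy.ruleset_comparison <- function(x, ...) x$per_rule_breakdown
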