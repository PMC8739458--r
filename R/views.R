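# The computations behind the five dashboard views: histogram, plotted
# average (trend), plotted batch, plotted Std-A signal, and absolute RT vs
# monthly average — plus the statistical summary table each view carries.
# The view layer adds no arithmetic beyond grouping; overlays and pass/fail
# markers delegate to the rule engine and the calibration module so the
# dashboard and the flags can never disagree.

#' Statistical summary of a value selection
#'
#' The summary table shown beside every dashboard view. Missing values are
#' counted (`n_null`) and excluded from all statistics.
#'
#' @param values Numeric vector.
#' @param cutoff Optional minimum cutoff; adds `pct_below_cutoff` via
#'   [fraction_below()].
#' @param window Optional `(low, high)` window; adds `pct_outside_window`
#'   via [fraction_outside_window()].
#' @param quantile_levels Quantile levels to report (default 0.02, 0.25,
#'   0.75, reported as `q02`, `q25`, `q75`).
#' @return A one-row tibble: `n`, `n_null`, `mean`, `median`, `sd`, `min`,
#'   `max`, one column per quantile level, `pct_below_cutoff`,
#'   `pct_outside_window`.
#' @export
summarize_values <- function(values, cutoff = NULL, window = NULL,
                             quantile_levels = c(0.02, 0.25, 0.75)) {
  n_null <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0) abort("no non-missing values to summarise")
  qs <- quantile(v, probs = quantile_levels, type = 7, names = FALSE)
  qcols <- setNames(as.list(qs),
                    paste0("q", sub("^0\\.", "", sprintf("%02.0f", quantile_levels * 100))))
  out <- tibble(
    n = length(v), n_null = n_null, mean = mean(v), median = median(v),
    sd = if (length(v) > 1) sd(v) else 0, min = min(v), max = max(v)
  )
  out <- dplyr::bind_cols(out, as_tibble(qcols))
  out$pct_below_cutoff <- if (is.null(cutoff)) NA_real_ else
    100 * fraction_below(v, cutoff)
  out$pct_outside_window <- if (is.null(window)) NA_real_ else
    100 * fraction_outside_window(v, window)
  out
}

# Resolve the configured cutoff overlay for a selection, when a ruleset is
# supplied and the selection is a single compound x instrument.
.overlay_cutoff <- function(rows, rs, parameter) {
  if (is.null(rs)) return(NA_real_)
  combos <- distinct(rows[, c("compound", "instrument_id")])
  if (nrow(combos) != 1) return(NA_real_)
  cut <- resolve_cutoffs(rs, combos$compound[[1]], combos$instrument_id[[1]])
  switch(parameter,
         is_peak_area = cut$is_peak_area_min,
         peak_area = cut$std_a_peak_area_min,
         sn = cut$sn_min,
         NA_real_)
}

#' Histogram view
#'
#' Distribution of one QC parameter over a filtered historical selection,
#' with the configured cutoff and the bottom-percentile border overlaid —
#' the view used to judge whether a validation-era cutoff still fits the
#' instrument's current behaviour.
#'
#' @param con Connection from [init_schema()].
#' @param filter A [result_filter()].
#' @param parameter Parameter name (see [derive_cutoffs()]).
#' @param ruleset Optional `qc_ruleset` supplying the cutoff overlay (used
#'   when the filter isolates one compound x instrument).
#' @param n_bins Number of equal-width bins (default 50).
#' @param level Percentile level for the border overlay (default 0.02).
#' @return A `histogram_view`: `bins` (tibble `left`, `right`, `count`;
#'   half-open `[left, right)` with the last bin closed), `border`,
#'   `cutoff`, `summary`, plus the request fields. Has an `autoplot()`
#'   method.
#' @export
histogram_view <- function(con, filter = result_filter(),
                           parameter = "is_peak_area", ruleset = NULL,
                           n_bins = 50, level = 0.02) {
  rows <- query_results(con, filter)
  if (nrow(rows) == 0) abort("filter selects no results")
  values <- parameter_values(rows, parameter)
  v <- values[!is.na(values)]
  if (length(v) == 0) abort("no non-missing values for parameter")
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  if (min(v) == max(v)) edges <- seq(min(v) - 0.5, max(v) + 0.5, length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  cutoff <- .overlay_cutoff(rows, ruleset, parameter)
  border <- empirical_border(v, level)
  structure(list(
    filter = filter, parameter = parameter, level = level,
    bins = tibble(left = edges[-length(edges)], right = edges[-1],
                  count = counts),
    border = border,
    cutoff = cutoff,
    summary = summarize_values(values,
                               cutoff = if (is.na(cutoff)) NULL else cutoff)
  ), class = "histogram_view")
}

# Calendar month (UTC) label for grouping, e.g. "2021-03".
month_label <- function(time) format(time, "%Y-%m", tz = "UTC")

#' Plotted-average (trend) view
#'
#' Per-period summary statistics of one parameter: by calendar month (UTC)
#' or by batch in injection order. Each selected row contributes to exactly
#' one group.
#'
#' @inheritParams histogram_view
#' @param grouping `"by_month"` or `"by_batch"`.
#' @return A `trend_view` with `points`: one row per group (`group`,
#'   ordered chronologically) bound to its [summarize_values()] columns.
#' @export
average_trend_view <- function(con, filter = result_filter(),
                               parameter = "is_peak_area",
                               grouping = c("by_month", "by_batch")) {
  grouping <- match.arg(grouping)
  rows <- query_results(con, filter)
  if (nrow(rows) == 0) abort("filter selects no results")
  rows$.value <- parameter_values(rows, parameter)
  rows$.group <- switch(grouping,
                        by_month = month_label(rows$injection_time),
                        by_batch = rows$xml_file_name)
  ord <- rows |>
    group_by(.data$.group) |>
    summarise(first_time = min(.data$injection_time), .groups = "drop") |>
    arrange(.data$first_time)
  points <- purrr::map_dfr(ord$.group, function(gr) {
    vals <- rows$.value[rows$.group == gr]
    dplyr::bind_cols(tibble(group = gr), summarize_values(vals))
  })
  structure(list(filter = filter, parameter = parameter,
                 grouping = grouping, points = points),
            class = "trend_view")
}

#' Plotted-batch view
#'
#' One batch's parameter values in injection order, with the configured
#' cutoff overlay — instrument performance within a single run.
#'
#' @inheritParams histogram_view
#' @param batch_name The batch's `xml_file_name`.
#' @return A `trend_view` (grouping `"by_injection_order"`) whose `points`
#'   are the individual injections (`sample_id`, `compound`,
#'   `injection_time`, `value`), plus `cutoff`, and `summary`.
#' @export
batch_view <- function(con, batch_name, parameter = "is_peak_area",
                       ruleset = NULL) {
  rows <- query_results(con, result_filter(batches = batch_name))
  if (nrow(rows) == 0) abort(paste0("unknown batch: ", batch_name))
  rows$.value <- parameter_values(rows, parameter)
  rows <- arrange(rows, .data$injection_time, .data$result_key)
  structure(list(
    batch_name = batch_name, parameter = parameter,
    grouping = "by_injection_order",
    points = tibble(sample_id = rows$sample_id, compound = rows$compound,
                    sample_type = rows$sample_type,
                    injection_time = rows$injection_time,
                    value = rows$.value),
    cutoff = .overlay_cutoff(rows, ruleset, parameter),
    summary = summarize_values(rows$.value)
  ), class = "trend_view")
}

#' Std-A signal view
#'
#' The first calibrator's quantifying peak area per batch and compound, with
#' pass/fail status against the configured Std-A minimum — batch-to-batch
#' sensitivity monitoring. Status is computed by the rule engine itself
#' ([check_std_a()]), so the view can never disagree with the flags.
#'
#' @inheritParams histogram_view
#' @param ruleset A `qc_ruleset` (required: supplies `std_a_peak_area_min`).
#' @return A `std_a_signal_view`: `points` (one row per batch x compound
#'   with a Std-A row: `xml_file_name`, `compound`, `peak_area`, `status`)
#'   and `color_code` (per batch: `"all_pass"` / `"any_fail"` /
#'   `"not_evaluable"`).
#' @export
std_a_signal_view <- function(con, filter = result_filter(), ruleset) {
  stopifnot(inherits(ruleset, "qc_ruleset"))
  f <- filter
  f$sample_types <- "calibrator"
  rows <- query_results(con, f)
  if (nrow(rows) == 0) abort("selection contains no calibrator rows")
  points <- rows |>
    group_by(.data$xml_file_name, .data$compound) |>
    dplyr::group_map(function(g, key) {
      g$xml_file_name <- key$xml_file_name
      g$compound <- key$compound
      cutoffs <- resolve_cutoffs(ruleset, key$compound, g$instrument_id[[1]])
      flag <- check_std_a(g, cutoffs)
      tibble(xml_file_name = key$xml_file_name, compound = key$compound,
             instrument_id = g$instrument_id[[1]],
             peak_area = flag$measured, status = flag$status)
    }) |>
    bind_rows() |>
    arrange(.data$xml_file_name, .data$compound)
  color_code <- points |>
    group_by(.data$xml_file_name) |>
    summarise(status = if (any(.data$status == "fail")) "any_fail"
              else if (all(.data$status == "not_evaluable")) "not_evaluable"
              else "all_pass",
              .groups = "drop")
  structure(list(filter = filter, points = points, color_code = color_code),
            class = "std_a_signal_view")
}

#' Absolute retention time vs monthly average
#'
#' Per-batch mean retention time for each compound against its calendar
#' month's average (equal-weight mean over rows), with the exact deviation
#' of each batch from its month — chromatography drift from batch to batch.
#'
#' @inheritParams histogram_view
#' @return An `rt_view`: `per_batch` (`xml_file_name`, `compound`, `month`,
#'   `mean_rt`, `n`), `monthly` (`month`, `compound`, `mean_rt`, `n`), and
#'   `deviations` (`per_batch` joined with `deviation = batch mean - month
#'   mean`).
#' @export
absolute_rt_view <- function(con, filter = result_filter()) {
  rows <- query_results(con, filter)
  rows <- rows[!is.na(rows$rt), ]
  if (nrow(rows) == 0) abort("selection contains no retention times")
  rows$month <- month_label(rows$injection_time)
  per_batch <- rows |>
    group_by(.data$xml_file_name, .data$compound, .data$month) |>
    summarise(mean_rt = mean(.data$rt), n = n(), .groups = "drop") |>
    arrange(.data$month, .data$xml_file_name, .data$compound)
  monthly <- rows |>
    group_by(.data$month, .data$compound) |>
    summarise(mean_rt = mean(.data$rt), n = n(), .groups = "drop")
  deviations <- per_batch |>
    left_join(monthly |> rename(month_mean_rt = "mean_rt", month_n = "n"),
              by = c("month", "compound")) |>
    mutate(deviation = .data$mean_rt - .data$month_mean_rt)
  structure(list(filter = filter, per_batch = per_batch, monthly = monthly,
                 deviations = deviations),
            class = "rt_view")
}
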