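# The QC rule engine: five rules per result/batch, re-implementing the
# semantics of an automated review tool for a multiplexed opioid
# confirmation assay. Boundary convention throughout: minima pass at
# equality, the RRT window is inclusive at both bounds; a null measured
# value is never a failure (status "not_evaluable"); a null threshold
# disables the rule (status "pass", threshold "disabled").

.rules <- c("rrt", "is_peak_area", "std_a", "sn", "ion_ratio")

.flag_tbl <- function(result_key, rule, status, measured, threshold_repr,
                      compound, xml_file_name) {
  tibble(result_key = as.integer(result_key), rule = rule, status = status,
         measured = as.numeric(measured), threshold_repr = threshold_repr,
         compound = compound, xml_file_name = xml_file_name)
}

empty_flags <- function() {
  .flag_tbl(integer(), character(), character(), double(), character(),
            character(), character())
}

# Attach surrogate keys to results that never went through the datastore.
ensure_result_keys <- function(results) {
  if (!"result_key" %in% names(results)) {
    results$result_key <- seq_len(nrow(results))
  }
  results
}

#' Relative retention time
#'
#' The analyte retention time divided by its paired internal standard's
#' retention time; co-eluting pairs give values near 1.0.
#'
#' @param rt,is_rt Retention times in minutes (vectorised).
#' @return `rt / is_rt`, `NA` where either input is missing or `is_rt` is
#'   not positive.
#' @examples
#' compute_rrt(2.5, 2.0)   # 1.25
#' @export
compute_rrt <- function(rt, is_rt) {
  out <- rt / is_rt
  out[is.na(rt) | is.na(is_rt) | is_rt <= 0] <- NA_real_
  out
}

#' Ion ratio
#'
#' Confirming-ion peak area divided by quantifying-ion peak area, the
#' identity check of a targeted MS/MS assay.
#'
#' @param confirming_area,quantifying_area Peak areas (vectorised).
#' @return The ratio, `NA` where either input is missing or the quantifying
#'   area is not positive.
#' @export
compute_ion_ratio <- function(confirming_area, quantifying_area) {
  out <- confirming_area / quantifying_area
  out[is.na(confirming_area) | is.na(quantifying_area) | quantifying_area <= 0] <- NA_real_
  out
}

# Shared minimum-threshold rule: pass at equality, fail strictly below.
.check_min <- function(results, measured, threshold, rule) {
  n <- nrow(results)
  if (is.na(threshold)) {
    return(.flag_tbl(results$result_key, rule, rep("pass", n), measured,
                     rep("disabled", n), results$compound,
                     results$xml_file_name))
  }
  status <- ifelse(is.na(measured), "not_evaluable",
                   ifelse(measured < threshold, "fail", "pass"))
  .flag_tbl(results$result_key, rule, status, measured,
            rep(paste0(">= ", format(threshold)), n),
            results$compound, results$xml_file_name)
}

#' Single-rule checks
#'
#' Each `check_*()` evaluates one QC rule on result rows against one
#' resolved [compound_cutoffs()] row and returns flag rows (`result_key`,
#' `rule`, `status`, `measured`, `threshold_repr`, plus `compound` and
#' `xml_file_name` for reporting). `status` is `"pass"`, `"fail"`, or
#' `"not_evaluable"` when a required input is missing.
#'
#' * `check_rrt()`: fail iff rt/is_rt lies strictly outside the inclusive
#'   window `[rrt_low, rrt_high]`.
#' * `check_is_peak_area()`, `check_sn()`: fail iff the measured value is
#'   strictly below the minimum; equality passes.
#' * `check_ion_ratio()`: the expected ratio is `expected_ion_ratio` when
#'   configured, otherwise the mean ion ratio of the batch's calibrator rows;
#'   fail iff `|measured/expected - 1| > ion_ratio_tolerance`.
#' * `check_std_a()`: batch-level rule on the first (lowest) calibrator —
#'   identified by ascending level label, ties broken by nominal
#'   concentration — failing iff its quantifying peak area is below
#'   `std_a_peak_area_min`.
#'
#' @param results Result rows (one compound) as returned by
#'   [parse_quant_xml()] or [query_results()].
#' @param cutoffs A one-row cutoffs tibble from [resolve_cutoffs()].
#' @param batch_results Same-batch, same-compound rows providing the
#'   calibrator context for the ion-ratio expectation.
#' @return A tibble of flag rows.
#' @name qc-checks
NULL

#' @rdname qc-checks
#' @export
check_rrt <- function(results, cutoffs) {
  results <- ensure_result_keys(results)
  n <- nrow(results)
  if (is.na(cutoffs$rrt_low) || is.na(cutoffs$rrt_high)) {
    return(.flag_tbl(results$result_key, "rrt", rep("pass", n),
                     compute_rrt(results$rt, results$is_rt),
                     rep("disabled", n), results$compound,
                     results$xml_file_name))
  }
  rrt <- compute_rrt(results$rt, results$is_rt)
  status <- ifelse(is.na(rrt), "not_evaluable",
                   ifelse(rrt < cutoffs$rrt_low | rrt > cutoffs$rrt_high,
                          "fail", "pass"))
  .flag_tbl(results$result_key, "rrt", status, rrt,
            rep(sprintf("[%s, %s]", format(cutoffs$rrt_low),
                        format(cutoffs$rrt_high)), n),
            results$compound, results$xml_file_name)
}

#' @rdname qc-checks
#' @export
check_is_peak_area <- function(results, cutoffs) {
  results <- ensure_result_keys(results)
  .check_min(results, results$is_peak_area, cutoffs$is_peak_area_min,
             "is_peak_area")
}

#' @rdname qc-checks
#' @export
check_sn <- function(results, cutoffs) {
  results <- ensure_result_keys(results)
  .check_min(results, results$sn, cutoffs$sn_min, "sn")
}

# Expected ion ratio for a batch x compound: configured value, else the mean
# over calibrator rows with usable areas; NA when underivable.
expected_ion_ratio_for <- function(cutoffs, batch_results) {
  if (!is.na(cutoffs$expected_ion_ratio)) return(cutoffs$expected_ion_ratio)
  cal <- batch_results[batch_results$sample_type == "calibrator", ]
  ratios <- compute_ion_ratio(cal$confirming_ion_area, cal$peak_area)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) return(NA_real_)
  mean(ratios)
}

#' @rdname qc-checks
#' @export
check_ion_ratio <- function(results, cutoffs, batch_results = results) {
  results <- ensure_result_keys(results)
  n <- nrow(results)
  tol <- cutoffs$ion_ratio_tolerance
  measured <- compute_ion_ratio(results$confirming_ion_area, results$peak_area)
  if (is.na(tol)) {
    return(.flag_tbl(results$result_key, "ion_ratio", rep("pass", n),
                     measured, rep("disabled", n), results$compound,
                     results$xml_file_name))
  }
  expected <- expected_ion_ratio_for(cutoffs, batch_results)
  if (is.na(expected) || expected <= 0) {
    return(.flag_tbl(results$result_key, "ion_ratio",
                     rep("not_evaluable", n), measured,
                     rep("expected ratio underivable", n), results$compound,
                     results$xml_file_name))
  }
  status <- ifelse(is.na(measured), "not_evaluable",
                   ifelse(abs(measured / expected - 1) > tol, "fail", "pass"))
  .flag_tbl(results$result_key, "ion_ratio", status, measured,
            rep(sprintf("%s +/- %d%%", format(expected), round(tol * 100)), n),
            results$compound, results$xml_file_name)
}

# Order calibrator rows "first" to last: ascending level label (Std-A <
# Std-B < ...), ties broken by ascending nominal concentration.
std_a_row <- function(cal_rows) {
  ord <- order(cal_rows$sample_id, cal_rows$concentration,
               method = "radix", na.last = TRUE)
  cal_rows[ord[1], ]
}

#' @rdname qc-checks
#' @export
check_std_a <- function(batch_results, cutoffs) {
  batch_results <- ensure_result_keys(batch_results)
  cal <- batch_results[batch_results$sample_type == "calibrator", ]
  compound <- if (nrow(batch_results)) batch_results$compound[[1]] else NA_character_
  fname <- if (nrow(batch_results)) batch_results$xml_file_name[[1]] else NA_character_
  if (nrow(cal) == 0) {
    return(.flag_tbl(NA_integer_, "std_a", "not_evaluable", NA_real_,
                     "no calibrator rows", compound, fname))
  }
  first <- std_a_row(cal)
  .check_min(first, first$peak_area, cutoffs$std_a_peak_area_min, "std_a")
}

#' Adjust an internal-standard cutoff for a new IS lot
#'
#' Internal-standard solutions prepared in-lab vary between lots. A bias of
#' up to 10% between the lot mean and the reference mean is accepted as-is;
#' beyond that the cutoff is rescaled multiplicatively by the lot/reference
#' ratio so the rule keeps its sensitivity to per-sample ion suppression.
#'
#' @param reference_mean Reference lot mean IS peak area (positive).
#' @param current_lot_mean Current lot mean IS peak area (positive).
#' @param cutoff The configured IS peak-area cutoff (positive).
#' @param tolerance Accepted relative bias, inclusive (default 0.10).
#' @return The adjusted cutoff.
#' @examples
#' adjust_is_cutoff_for_lot(100000, 130000, 20000)  # 26000
#' @export
adjust_is_cutoff_for_lot <- function(reference_mean, current_lot_mean, cutoff,
                                     tolerance = 0.10) {
  if (!is.numeric(reference_mean) || is.na(reference_mean) || reference_mean <= 0) {
    abort("reference_mean must be positive")
  }
  if (!is.numeric(current_lot_mean) || is.na(current_lot_mean) || current_lot_mean <= 0) {
    abort("current_lot_mean must be positive")
  }
  bias <- (current_lot_mean - reference_mean) / reference_mean
  if (abs(bias) <= tolerance) cutoff else cutoff * (1 + bias)
}

# Evaluate every applicable rule over a results tibble. Per-row rules (rrt,
# is_peak_area, sn, ion_ratio) apply to qc and patient rows; the Std-A rule
# applies once per (batch, compound) to its calibrator rows. `context`
# supplies same-batch calibrator rows when `results` is a filtered
# selection.
evaluate_results <- function(results, rs, context = results) {
  stopifnot(inherits(rs, "qc_ruleset"))
  results <- ensure_result_keys(results)
  context <- ensure_result_keys(context)

  combos <- distinct(results[, c("compound", "instrument_id")])
  missing <- character()
  for (i in seq_len(nrow(combos))) {
    ok <- tryCatch({
      resolve_cutoffs(rs, combos$compound[[i]], combos$instrument_id[[i]])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) missing <- c(missing, sprintf("%s @ %s", combos$compound[[i]],
                                           combos$instrument_id[[i]]))
  }
  if (length(missing)) {
    abort(paste0("ruleset '", rs$name, "' has no entry for: ",
                 paste(missing, collapse = "; ")))
  }

  flags <- list()
  groups <- results |>
    group_by(.data$xml_file_name, .data$compound, .data$instrument_id) |>
    dplyr::group_split()
  for (g in groups) {
    cutoffs <- resolve_cutoffs(rs, g$compound[[1]], g$instrument_id[[1]])
    ctx <- context[context$xml_file_name == g$xml_file_name[[1]] &
                     context$compound == g$compound[[1]], ]
    per_row <- g[g$sample_type %in% c("qc", "patient"), ]
    if (nrow(per_row) > 0) {
      flags[[length(flags) + 1L]] <- check_rrt(per_row, cutoffs)
      flags[[length(flags) + 1L]] <- check_is_peak_area(per_row, cutoffs)
      flags[[length(flags) + 1L]] <- check_sn(per_row, cutoffs)
      flags[[length(flags) + 1L]] <- check_ion_ratio(per_row, cutoffs, ctx)
    }
    if (any(g$sample_type == "calibrator")) {
      flags[[length(flags) + 1L]] <- check_std_a(g, cutoffs)
    }
  }
  if (length(flags) == 0) return(empty_flags())
  out <- bind_rows(flags)
  out[order(out$result_key, match(out$rule, .rules)), ]
}

#' Evaluate a batch against a rule set
#'
#' Applies all five QC rules to a parsed batch: rrt, is_peak_area, sn and
#' ion_ratio to every QC and patient row, and the batch-level Std-A rule
#' once per compound. Failing flags are what a reviewing technologist would
#' triage.
#'
#' @param pb A `parsed_batch`.
#' @param rs A `qc_ruleset`; lookup must resolve for every compound present.
#' @return A `qc_flag_report`: list with `ruleset_name`, `flags` (tibble of
#'   flag rows) and `totals` (per-rule pass/fail/not_evaluable counts).
#'   `tidy()` returns the flags, `glance()` a one-row summary.
#' @export
evaluate_batch <- function(pb, rs) {
  stopifnot(inherits(pb, "parsed_batch"))
  flags <- evaluate_results(pb$results, rs)
  new_flag_report(flags, rs)
}

new_flag_report <- function(flags, rs) {
  totals <- flags |>
    count(.data$rule, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("pass", "fail", "not_evaluable")) {
    if (!col %in% names(totals)) totals[[col]] <- 0L
  }
  structure(list(ruleset_name = rs$name, flags = flags,
                 totals = totals[, c("rule", "pass", "fail", "not_evaluable")]),
            class = "qc_flag_report")
}

#' @export
print.qc_flag_report <- function(x, ...) {
  cat(sprintf("<qc_flag_report> ruleset '%s': %d flags (%d fail, %d not evaluable)\n",
              x$ruleset_name, nrow(x$flags), sum(x$flags$status == "fail"),
              sum(x$flags$status == "not_evaluable")))
  print(x$totals)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qc_flag_report <- function(x, ...) x$flags

#' @exportS3Method generics::glance
glance.qc_flag_report <- function(x, ...) {
  tibble(ruleset_name = x$ruleset_name,
         n_flags = nrow(x$flags),
         n_pass = sum(x$flags$status == "pass"),
         n_fail = sum(x$flags$status == "fail"),
         n_not_evaluable = sum(x$flags$status == "not_evaluable"))
}

#' Export a flag report to CSV
#'
#' @param report A `qc_flag_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_flags_csv <- function(report, path) {
  readr::write_csv(report$flags, path)
  invisible(path)
}
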