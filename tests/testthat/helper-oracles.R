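# Independent brute-force oracles. These deliberately re-derive every rule
# and statistic with plain loops and base subsetting, sharing no code with
# the package's vectorised implementations.

# Type-7 quantile by hand: linear interpolation between order statistics.
quantile_oracle <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# In-memory re-implementation of the result filter (AND semantics,
# half-open date interval) for comparison with SQL-backed query_results().
filter_oracle <- function(rows, filter) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(filter$instruments)) keep <- keep & rows$instrument_id %in% filter$instruments
  if (!is.null(filter$compounds)) keep <- keep & rows$compound %in% filter$compounds
  if (!is.null(filter$sample_types)) keep <- keep & rows$sample_type %in% filter$sample_types
  if (!is.null(filter$batches)) keep <- keep & rows$xml_file_name %in% filter$batches
  if (!is.null(filter$date_range)) {
    keep <- keep & !is.na(rows$injection_time) &
      rows$injection_time > filter$date_range[[1]] &
      rows$injection_time <= filter$date_range[[2]]
  }
  out <- rows[keep, ]
  out[order(out$injection_time, out$result_key), ]
}

oracle_resolve <- function(rs, compound, instrument) {
  e <- rs$entries
  i <- which(e$compound == compound & e$instrument_id == instrument)
  if (!length(i)) i <- which(e$compound == compound & e$instrument_id == "*")
  as.list(e[i[1], ])
}

# Brute-force evaluation of all five rules on a results tibble, row by row.
# Returns a data frame (result_key, rule, status) sorted for comparison.
oracle_flags <- function(results, rs) {
  df <- as.data.frame(results)
  if (is.null(df$result_key)) df$result_key <- seq_len(nrow(df))
  key <- function(f, c) paste(f, c, sep = "\r")

  # expected ion ratios per (file, compound), from calibrator rows
  expected_map <- new.env(parent = emptyenv())
  combos <- unique(df[, c("xml_file_name", "compound")])
  for (j in seq_len(nrow(combos))) {
    f <- combos$xml_file_name[j]; cmp <- combos$compound[j]
    cal <- df[df$xml_file_name == f & df$compound == cmp &
                df$sample_type == "calibrator", ]
    ok <- !is.na(cal$confirming_ion_area) & !is.na(cal$peak_area) &
      cal$peak_area > 0
    assign(key(f, cmp),
           if (any(ok)) mean(cal$confirming_ion_area[ok] / cal$peak_area[ok])
           else NA_real_,
           envir = expected_map)
  }

  cap <- 5L * nrow(df) + nrow(combos)
  out_key <- integer(cap); out_rule <- character(cap); out_status <- character(cap)
  n_out <- 0L
  emit <- function(k, rule, status) {
    n_out <<- n_out + 1L
    out_key[[n_out]] <<- k
    out_rule[[n_out]] <<- rule
    out_status[[n_out]] <<- status
  }

  for (i in seq_len(nrow(df))) {
    if (!(df$sample_type[i] %in% c("qc", "patient"))) next
    cut <- oracle_resolve(rs, df$compound[i], df$instrument_id[i])

    if (is.na(cut$rrt_low) || is.na(cut$rrt_high)) {
      st <- "pass"
    } else if (is.na(df$rt[i]) || is.na(df$is_rt[i]) || df$is_rt[i] <= 0) {
      st <- "not_evaluable"
    } else {
      v <- df$rt[i] / df$is_rt[i]
      st <- if (v >= cut$rrt_low && v <= cut$rrt_high) "pass" else "fail"
    }
    emit(df$result_key[i], "rrt", st)

    st <- if (is.na(cut$is_peak_area_min)) "pass"
      else if (is.na(df$is_peak_area[i])) "not_evaluable"
      else if (df$is_peak_area[i] >= cut$is_peak_area_min) "pass" else "fail"
    emit(df$result_key[i], "is_peak_area", st)

    st <- if (is.na(cut$sn_min)) "pass"
      else if (is.na(df$sn[i])) "not_evaluable"
      else if (df$sn[i] >= cut$sn_min) "pass" else "fail"
    emit(df$result_key[i], "sn", st)

    if (is.na(cut$ion_ratio_tolerance)) {
      st <- "pass"
    } else {
      expected <- cut$expected_ion_ratio
      if (is.na(expected)) {
        expected <- get(key(df$xml_file_name[i], df$compound[i]),
                        envir = expected_map)
      }
      m <- if (is.na(df$confirming_ion_area[i]) || is.na(df$peak_area[i]) ||
               df$peak_area[i] <= 0) NA_real_
        else df$confirming_ion_area[i] / df$peak_area[i]
      st <- if (is.na(expected) || expected <= 0) "not_evaluable"
        else if (is.na(m)) "not_evaluable"
        else if (abs(m / expected - 1) > cut$ion_ratio_tolerance) "fail"
        else "pass"
    }
    emit(df$result_key[i], "ion_ratio", st)
  }

  for (j in seq_len(nrow(combos))) {
    f <- combos$xml_file_name[j]; cmp <- combos$compound[j]
    sub <- df[df$xml_file_name == f & df$compound == cmp, ]
    cal <- sub[sub$sample_type == "calibrator", ]
    if (nrow(cal) == 0) next
    first <- cal[order(cal$sample_id, cal$concentration)[1], ]
    cut <- oracle_resolve(rs, cmp, first$instrument_id)
    st <- if (is.na(cut$std_a_peak_area_min)) "pass"
      else if (is.na(first$peak_area)) "not_evaluable"
      else if (first$peak_area >= cut$std_a_peak_area_min) "pass" else "fail"
    emit(first$result_key, "std_a", st)
  }

  out <- data.frame(result_key = out_key[seq_len(n_out)],
                    rule = out_rule[seq_len(n_out)],
                    status = out_status[seq_len(n_out)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$result_key, out$rule), ]
  rownames(out) <- NULL
  out
}

# Engine flags reduced to the oracle's comparable shape.
engine_flags_comparable <- function(flags) {
  out <- as.data.frame(flags[, c("result_key", "rule", "status")])
  out <- out[order(out$result_key, out$rule), ]
  rownames(out) <- NULL
  out
}
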