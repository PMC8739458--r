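# Rule sets: per compound x instrument QC thresholds with an instrument
# wildcard fallback ("*"). A null (NA) threshold disables the rule for that
# compound: the flag passes with threshold "disabled", which allows partial
# rule sets during migration.

.cutoff_cols <- c("compound", "instrument_id", "rrt_low", "rrt_high",
                  "is_peak_area_min", "std_a_peak_area_min", "sn_min",
                  "ion_ratio_tolerance", "expected_ion_ratio", "lloq")

#' Per-compound QC thresholds
#'
#' One rule-set entry: the thresholds applied to a compound on one
#' instrument (or on any instrument, `instrument_id = "*"`).
#'
#' @param compound Compound name.
#' @param instrument_id Instrument identifier, or `"*"` as wildcard.
#' @param rrt_low,rrt_high Relative-retention-time acceptance window
#'   (dimensionless, inclusive at both bounds). `rrt_low < rrt_high`, both
#'   positive.
#' @param is_peak_area_min Minimum internal-standard peak area (area counts),
#'   or `NA` to disable.
#' @param std_a_peak_area_min Minimum peak area of the first (lowest)
#'   calibrator, or `NA`.
#' @param sn_min Minimum signal-to-noise ratio, or `NA`.
#' @param ion_ratio_tolerance Relative tolerance on the ion ratio (e.g. 0.2
#'   = +/-20%), in (0, 1), or `NA` to disable.
#' @param expected_ion_ratio Expected confirming/quantifying ion ratio; `NA`
#'   means derive it from the batch's calibrators.
#' @param lloq Lower limit of quantification (ng/mL), carried for filtering,
#'   not flagged.
#' @return A one-row tibble of thresholds.
#' @export
compound_cutoffs <- function(compound, instrument_id = "*",
                             rrt_low = 0.984, rrt_high = 1.024,
                             is_peak_area_min = NA_real_,
                             std_a_peak_area_min = NA_real_,
                             sn_min = NA_real_,
                             ion_ratio_tolerance = 0.2,
                             expected_ion_ratio = NA_real_,
                             lloq = NA_real_) {
  if (!is.na(rrt_low) && !is.na(rrt_high) &&
      (rrt_low <= 0 || rrt_low >= rrt_high)) {
    abort("rrt window must satisfy 0 < rrt_low < rrt_high")
  }
  if (!is.na(ion_ratio_tolerance) &&
      (ion_ratio_tolerance <= 0 || ion_ratio_tolerance >= 1)) {
    abort("ion_ratio_tolerance must lie in (0, 1)")
  }
  tibble(compound = compound, instrument_id = instrument_id,
         rrt_low = as.numeric(rrt_low), rrt_high = as.numeric(rrt_high),
         is_peak_area_min = as.numeric(is_peak_area_min),
         std_a_peak_area_min = as.numeric(std_a_peak_area_min),
         sn_min = as.numeric(sn_min),
         ion_ratio_tolerance = as.numeric(ion_ratio_tolerance),
         expected_ion_ratio = as.numeric(expected_ion_ratio),
         lloq = as.numeric(lloq))
}

#' Build a QC rule set
#'
#' @param entries A tibble of [compound_cutoffs()] rows (bind several with
#'   [dplyr::bind_rows()]). `(compound, instrument_id)` must be unique.
#' @param name,version Labels carried into reports.
#' @return A `qc_ruleset` object.
#' @export
ruleset <- function(entries, name = "ruleset", version = "1") {
  entries <- as_tibble(entries)
  missing_cols <- setdiff(.cutoff_cols, names(entries))
  if (length(missing_cols)) {
    abort(paste0("ruleset entries missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(entries[, c("compound", "instrument_id")])) {
    abort("duplicate (compound, instrument_id) entries in ruleset")
  }
  structure(list(name = name, version = version,
                 entries = entries[, .cutoff_cols]),
            class = "qc_ruleset")
}

#' @export
print.qc_ruleset <- function(x, ...) {
  cat(sprintf("<qc_ruleset> %s v%s: %d entries (%d compounds)\n",
              x$name, x$version, nrow(x$entries),
              length(unique(x$entries$compound))))
  invisible(x)
}

#' Resolve the thresholds for one compound on one instrument
#'
#' An instrument-specific entry beats the `"*"` wildcard; a compound with
#' neither is an error, so lookup is total over configured compounds.
#'
#' @param rs A `qc_ruleset`.
#' @param compound Compound name.
#' @param instrument_id Instrument identifier.
#' @return A one-row cutoffs tibble.
#' @export
resolve_cutoffs <- function(rs, compound, instrument_id) {
  stopifnot(inherits(rs, "qc_ruleset"))
  e <- rs$entries
  hit <- e[e$compound == compound & e$instrument_id == instrument_id, ]
  if (nrow(hit) == 0) hit <- e[e$compound == compound & e$instrument_id == "*", ]
  if (nrow(hit) == 0) {
    abort(paste0("no rule entry for compound '", compound,
                 "' on instrument '", instrument_id, "'"))
  }
  hit[1, ]
}

#' Read / write a rule set as YAML
#'
#' The config schema is a mapping with `name`, `version` and a list
#' `entries`, each entry holding the [compound_cutoffs()] fields (absent
#' fields are `NA` = rule disabled).
#'
#' @param path YAML file path.
#' @return `read_ruleset()` returns a `qc_ruleset`; `write_ruleset()`
#'   returns `path` invisibly.
#' @export
read_ruleset <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- purrr::map_dfr(doc$entries, function(e) {
    do.call(compound_cutoffs, e)
  })
  ruleset(entries, name = doc$name %na% "ruleset", version = as.character(doc$version %na% "1"))
}

#' @rdname read_ruleset
#' @param rs A `qc_ruleset`.
#' @export
write_ruleset <- function(rs, path) {
  stopifnot(inherits(rs, "qc_ruleset"))
  entries <- purrr::pmap(rs$entries, function(...) {
    e <- list(...)
    e[!vapply(e, function(v) length(v) == 1 && is.na(v), logical(1))]
  })
  yaml::write_yaml(list(name = rs$name, version = rs$version,
                        entries = entries), path)
  invisible(path)
}
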