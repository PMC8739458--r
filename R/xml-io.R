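#' Batch quantification XML dialect
#'
#' Vendor middleware exports one XML file per analytical batch. The package
#' reads and writes a minimal, documented dialect that carries the same
#' information as a TargetLynx-style export:
#'
#' ```
#' <QUANTBATCH file_name="..." timestamp="2021-01-04T08:00:00Z"
#'             instrument_id="LCMS-1" lc_batch_name="...">
#'   <CALIBRATIONS>
#'     <CALIBRATION compound="Morphine" internal_standard="Morphine-d3"
#'                  weighting="1/x" slope="1052.1" r_squared="0.998"
#'                  curve_type="linear" origin="exclude"/>
#'     ...
#'   </CALIBRATIONS>
#'   <SAMPLES>
#'     <SAMPLE sample_id="Std-A" sample_type="Standard" vial="1:A,1"
#'             injection_time="2021-01-04T08:02:00Z">
#'       <COMPOUND name="Morphine" compound_id="cmp01"
#'                 internal_standard="Morphine-d3" is_id="is01" cc="true">
#'         <PEAK area="61234.5" confirming_ion_area="30617.2" rt="2.41"
#'               sn="351.2" concentration="1.0"/>
#'         <ISPEAK area="59871.0" confirming_ion_area="29935.5" rt="2.40"
#'                 sn="812.3"/>
#'       </COMPOUND>
#'       ...
#'     </SAMPLE>
#'     ...
#'   </SAMPLES>
#' </QUANTBATCH>
#' ```
#'
#' Every numeric quantity is an attribute; a missing or non-numeric attribute
#' parses to `NA` (never zero) and is recorded as a parse warning. Sample
#' types are free text in the file and normalised to the controlled
#' vocabulary `calibrator` / `qc` / `patient` / `blank` at parse time
#' (`Standard` and `Calibrator` map to `calibrator`, `Analyte` and `Patient`
#' to `patient`). Timestamps are ISO-8601; offsets are converted to UTC.
#'
#' @name quant-xml-dialect
NULL

# free-text sample type -> controlled vocabulary
.sample_type_map <- c(
  standard = "calibrator", calibrator = "calibrator",
  qc = "qc", "quality control" = "qc",
  patient = "patient", analyte = "patient", unknown = "patient",
  blank = "blank"
)

# controlled vocabulary -> dialect spelling used on write
.sample_type_out <- c(
  calibrator = "Standard", qc = "QC", patient = "Patient", blank = "Blank"
)

.result_num_cols <- c(
  "peak_area", "confirming_ion_area", "rt", "sn", "concentration",
  "is_peak_area", "is_rt", "is_sn", "is_confirming_ion_area"
)

result_cols <- function() {
  c("xml_file_name", "lc_batch_name", "sample_type", "sample_id", "vial",
    "injection_time", "compound", "compound_id", "peak_area",
    "confirming_ion_area", "rt", "sn", "concentration", "cc",
    "internal_standard", "is_id", "is_peak_area", "is_rt", "is_sn",
    "is_confirming_ion_area", "instrument_id")
}

new_parsed_batch <- function(batch, calibrations, results, warnings) {
  structure(
    list(batch = batch, calibrations = calibrations, results = results,
         parse_warnings = warnings),
    class = "parsed_batch"
  )
}

#' @export
print.parsed_batch <- function(x, ...) {
  cat(sprintf(
    "<parsed_batch> %s  instrument %s\n  %d samples, %d calibrations, %d results, %d parse warnings\n",
    x$batch$xml_file_name, x$batch$instrument_id, x$batch$sample_count,
    nrow(x$calibrations), nrow(x$results), nrow(x$parse_warnings)
  ))
  invisible(x)
}

# Validate the cross-record invariants of a parsed batch.
validate_parsed_batch <- function(pb) {
  stopifnot(inherits(pb, "parsed_batch"))
  if (nrow(pb$results) > 0 &&
      !all(pb$results$xml_file_name == pb$batch$xml_file_name)) {
    abort("results reference a different xml_file_name than the batch record")
  }
  cal_compounds <- unique(pb$results$compound[pb$results$sample_type == "calibrator"])
  missing <- setdiff(cal_compounds, pb$calibrations$compound)
  if (length(missing) > 0) {
    abort(paste0("calibrator results without a calibration record: ",
                 paste(missing, collapse = ", ")))
  }
  n_samples <- length(unique(pb$results$sample_id))
  if (pb$batch$sample_count != n_samples) {
    abort("batch sample_count does not match the number of distinct samples")
  }
  invisible(pb)
}

# -- parsing -----------------------------------------------------------------

# Read a numeric attribute; missing or non-numeric values become NA and a
# warning row is appended to the collector environment.
.num_attr <- function(node, attr, path, wc) {
  raw <- xml2::xml_attr(node, attr)
  if (is.na(raw)) {
    wc$rows[[length(wc$rows) + 1L]] <-
      list(field_path = paste0(path, "@", attr), reason = "missing")
    return(NA_real_)
  }
  val <- as_num_strict(raw)
  if (is.na(val)) {
    wc$rows[[length(wc$rows) + 1L]] <-
      list(field_path = paste0(path, "@", attr),
           reason = paste0("non-numeric value '", raw, "'"))
  }
  val
}

.chr_attr <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) NA_character_ else v
}

.require_attr <- function(node, attr, path) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    abort(paste0("structural error: mandatory attribute '", attr,
                 "' missing on ", path))
  }
  v
}

#' Parse one batch quantification XML file
#'
#' Reads a file in the [quant-xml-dialect] and returns the batch record, the
#' per-compound calibration records and one result row per (sample, compound)
#' pair. Missing or non-numeric numeric fields become `NA` and are listed in
#' `parse_warnings`; no record is dropped.
#'
#' @param path Path to an XML file.
#' @return A `parsed_batch` object: a list with tibbles `batch` (one row),
#'   `calibrations`, `results` and `parse_warnings` (`field_path`, `reason`).
#' @examples
#' cfg <- generator_config(seed = 1, n_batches = 1, samples_per_batch = 4)
#' dir <- tempfile(); dir.create(dir)
#' man <- generate_corpus(cfg, dir)
#' pb <- parse_quant_xml(man$files[[1]])
#' pb$batch
#' @seealso [write_quant_xml()], [parse_folder()]
#' @export
parse_quant_xml <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      abort(paste0("malformed XML in '", basename(path), "': ",
                   conditionMessage(e)))
    }
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "QUANTBATCH") {
    abort(paste0("structural error: root element is <", xml2::xml_name(root),
                 ">, expected <QUANTBATCH>"))
  }
  wc <- new.env(parent = emptyenv()); wc$rows <- list()

  file_name <- .require_attr(root, "file_name", "QUANTBATCH")
  instrument_id <- .require_attr(root, "instrument_id", "QUANTBATCH")
  ts <- parse_iso_dt(.require_attr(root, "timestamp", "QUANTBATCH"))
  lc_batch_name <- .chr_attr(root, "lc_batch_name")

  kids <- xml2::xml_children(root)
  kid_names <- xml2::xml_name(kids)
  for (extra in setdiff(kid_names, c("CALIBRATIONS", "SAMPLES"))) {
    wc$rows[[length(wc$rows) + 1L]] <-
      list(field_path = paste0("QUANTBATCH/", extra),
           reason = "unknown element ignored")
  }
  cal_node <- kids[kid_names == "CALIBRATIONS"]
  smp_node <- kids[kid_names == "SAMPLES"]
  if (length(cal_node) == 0) abort("structural error: missing <CALIBRATIONS> element")
  if (length(smp_node) == 0) abort("structural error: missing <SAMPLES> element")

  cal_children <- xml2::xml_find_all(cal_node[[1]], "./CALIBRATION")
  calibrations <- purrr::map_dfr(cal_children, function(cn) {
    cpath <- paste0("CALIBRATION[", .require_attr(cn, "compound", "CALIBRATION"), "]")
    tibble(
      xml_file_name = file_name,
      timestamp = ts,
      compound = xml2::xml_attr(cn, "compound"),
      internal_standard = .chr_attr(cn, "internal_standard"),
      weighting = .chr_attr(cn, "weighting"),
      slope = .num_attr(cn, "slope", cpath, wc),
      r_squared = .num_attr(cn, "r_squared", cpath, wc),
      curve_type = .chr_attr(cn, "curve_type"),
      origin = .chr_attr(cn, "origin")
    )
  })
  if (nrow(calibrations) == 0) calibrations <- empty_calibrations()

  samples <- xml2::xml_find_all(smp_node[[1]], "./SAMPLE")
  results <- purrr::map_dfr(samples, function(sn) {
    sid <- .require_attr(sn, "sample_id", "SAMPLE")
    spath <- paste0("SAMPLE[", sid, "]")
    raw_type <- .require_attr(sn, "sample_type", spath)
    stype <- unname(.sample_type_map[tolower(raw_type)])
    if (is.na(stype)) {
      abort(paste0("structural error: unknown sample_type '", raw_type,
                   "' on ", spath))
    }
    vial <- .chr_attr(sn, "vial")
    inj <- parse_iso_dt(.chr_attr(sn, "injection_time"))
    compounds <- xml2::xml_find_all(sn, "./COMPOUND")
    purrr::map_dfr(compounds, function(cn) {
      cname <- .require_attr(cn, "name", paste0(spath, "/COMPOUND"))
      cpath <- paste0(spath, "/COMPOUND[", cname, "]")
      peak <- xml2::xml_find_first(cn, "./PEAK")
      ispk <- xml2::xml_find_first(cn, "./ISPEAK")
      cc_raw <- .chr_attr(cn, "cc")
      num <- function(node, attr, sub) {
        if (inherits(node, "xml_missing")) NA_real_
        else .num_attr(node, attr, paste0(cpath, "/", sub), wc)
      }
      tibble(
        xml_file_name = file_name,
        lc_batch_name = lc_batch_name,
        sample_type = stype,
        sample_id = sid,
        vial = vial,
        injection_time = inj,
        compound = cname,
        compound_id = .chr_attr(cn, "compound_id"),
        peak_area = num(peak, "area", "PEAK"),
        confirming_ion_area = num(peak, "confirming_ion_area", "PEAK"),
        rt = num(peak, "rt", "PEAK"),
        sn = num(peak, "sn", "PEAK"),
        concentration = num(peak, "concentration", "PEAK"),
        cc = if (is.na(cc_raw)) NA else identical(tolower(cc_raw), "true"),
        internal_standard = .chr_attr(cn, "internal_standard"),
        is_id = .chr_attr(cn, "is_id"),
        is_peak_area = num(ispk, "area", "ISPEAK"),
        is_rt = num(ispk, "rt", "ISPEAK"),
        is_sn = num(ispk, "sn", "ISPEAK"),
        is_confirming_ion_area = num(ispk, "confirming_ion_area", "ISPEAK"),
        instrument_id = instrument_id
      )
    })
  })
  if (nrow(results) == 0) results <- empty_results()
  results <- results[, result_cols()]

  inj_times <- results$injection_time[!is.na(results$injection_time)]
  batch <- tibble(
    xml_file_name = file_name,
    timestamp = ts,
    instrument_id = instrument_id,
    injection_first = if (length(inj_times)) min(inj_times) else as.POSIXct(NA, tz = "UTC"),
    injection_last = if (length(inj_times)) max(inj_times) else as.POSIXct(NA, tz = "UTC"),
    sample_count = length(samples)
  )
  warnings <- if (length(wc$rows)) {
    dplyr::bind_rows(lapply(wc$rows, as_tibble))
  } else {
    tibble(field_path = character(), reason = character())
  }
  pb <- new_parsed_batch(batch, calibrations, results, warnings)
  validate_parsed_batch(pb)
  pb
}

empty_results <- function() {
  tibble(
    xml_file_name = character(), lc_batch_name = character(),
    sample_type = character(), sample_id = character(), vial = character(),
    injection_time = as.POSIXct(character(), tz = "UTC"),
    compound = character(), compound_id = character(),
    peak_area = double(), confirming_ion_area = double(), rt = double(),
    sn = double(), concentration = double(), cc = logical(),
    internal_standard = character(), is_id = character(),
    is_peak_area = double(), is_rt = double(), is_sn = double(),
    is_confirming_ion_area = double(), instrument_id = character()
  )
}

empty_calibrations <- function() {
  tibble(
    xml_file_name = character(0), timestamp = as.POSIXct(character(), tz = "UTC"),
    compound = character(), internal_standard = character(),
    weighting = character(), slope = double(), r_squared = double(),
    curve_type = character(), origin = character()
  )
}

#' Parse a folder of batch XML files
#'
#' Parses every `.xml` file in a directory in lexicographic order. A file
#' that fails to parse does not abort the folder: its error is collected in
#' the `failures` attribute.
#'
#' @param dir Directory containing batch XML files.
#' @param pattern Regular expression selecting dialect files.
#' @return A list of `parsed_batch` objects (one per successfully parsed
#'   file, in sorted file-name order) with attribute `failures`, a tibble of
#'   (`file`, `error`).
#' @export
parse_folder <- function(dir, pattern = "\\.xml$") {
  if (!dir.exists(dir)) abort(paste0("directory not found: ", dir))
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  failures <- list()
  batches <- list()
  for (f in files) {
    pb <- tryCatch(parse_quant_xml(f), error = function(e) e)
    if (inherits(pb, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(file = f, error = conditionMessage(pb))
    } else {
      batches[[length(batches) + 1L]] <- pb
    }
  }
  fail_tbl <- if (length(failures)) bind_rows(failures) else
    tibble(file = character(), error = character())
  structure(batches, failures = fail_tbl)
}

# -- writing -----------------------------------------------------------------

.set_attr_if <- function(node, attr, value) {
  if (length(value) == 1 && !is.na(value)) xml2::xml_set_attr(node, attr, value)
  invisible(node)
}

#' Write a parsed batch back to dialect XML
#'
#' Serialises a `parsed_batch` to the [quant-xml-dialect]. `NA` numeric
#' fields are emitted as absent attributes (and re-parse as `NA`), so
#' `parse_quant_xml(write_quant_xml(pb, f))` reproduces every record
#' field-by-field.
#'
#' @param pb A `parsed_batch`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_xml <- function(pb, path) {
  validate_parsed_batch(pb)
  b <- pb$batch
  root <- xml2::xml_new_root("QUANTBATCH")
  xml2::xml_set_attr(root, "file_name", b$xml_file_name)
  xml2::xml_set_attr(root, "timestamp", format_iso_dt(b$timestamp))
  xml2::xml_set_attr(root, "instrument_id", b$instrument_id)
  lc <- if (nrow(pb$results) > 0) pb$results$lc_batch_name[[1]] else NA_character_
  .set_attr_if(root, "lc_batch_name", lc)

  cals <- xml2::xml_add_child(root, "CALIBRATIONS")
  if (nrow(pb$calibrations) > 0) {
    for (i in seq_len(nrow(pb$calibrations))) {
      cr <- pb$calibrations[i, ]
      cn <- xml2::xml_add_child(cals, "CALIBRATION")
      xml2::xml_set_attr(cn, "compound", cr$compound)
      .set_attr_if(cn, "internal_standard", cr$internal_standard)
      .set_attr_if(cn, "weighting", cr$weighting)
      .set_attr_if(cn, "slope", format_num(cr$slope))
      .set_attr_if(cn, "r_squared", format_num(cr$r_squared))
      .set_attr_if(cn, "curve_type", cr$curve_type)
      .set_attr_if(cn, "origin", cr$origin)
    }
  }

  smps <- xml2::xml_add_child(root, "SAMPLES")
  res <- pb$results
  if (nrow(res) > 0) {
    sample_ids <- unique(res$sample_id)
    for (sid in sample_ids) {
      rows <- res[res$sample_id == sid, ]
      first <- rows[1, ]
      sn <- xml2::xml_add_child(smps, "SAMPLE")
      xml2::xml_set_attr(sn, "sample_id", sid)
      xml2::xml_set_attr(sn, "sample_type",
                         unname(.sample_type_out[first$sample_type]))
      .set_attr_if(sn, "vial", first$vial)
      .set_attr_if(sn, "injection_time", format_iso_dt(first$injection_time))
      for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        cn <- xml2::xml_add_child(sn, "COMPOUND")
        xml2::xml_set_attr(cn, "name", r$compound)
        .set_attr_if(cn, "compound_id", r$compound_id)
        .set_attr_if(cn, "internal_standard", r$internal_standard)
        .set_attr_if(cn, "is_id", r$is_id)
        if (!is.na(r$cc)) {
          xml2::xml_set_attr(cn, "cc", if (r$cc) "true" else "false")
        }
        peak_vals <- c(area = r$peak_area,
                       confirming_ion_area = r$confirming_ion_area,
                       rt = r$rt, sn = r$sn, concentration = r$concentration)
        if (any(!is.na(peak_vals))) {
          pk <- xml2::xml_add_child(cn, "PEAK")
          for (a in names(peak_vals)) .set_attr_if(pk, a, format_num(peak_vals[[a]]))
        }
        is_vals <- c(area = r$is_peak_area,
                     confirming_ion_area = r$is_confirming_ion_area,
                     rt = r$is_rt, sn = r$is_sn)
        if (any(!is.na(is_vals))) {
          ip <- xml2::xml_add_child(cn, "ISPEAK")
          for (a in names(is_vals)) .set_attr_if(ip, a, format_num(is_vals[[a]]))
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
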