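# Relational persistence of the three-table model: batch, calibration,
# results. Timestamps are stored as ISO-8601 UTC text (lexicographically
# ordered); numeric columns carry CHECK constraints so text values are
# rejected on insert despite SQLite's type affinity.

.ddl <- list(
  batch = "
    CREATE TABLE IF NOT EXISTS batch (
      batch_key       INTEGER PRIMARY KEY,
      xml_file_name   TEXT NOT NULL UNIQUE,
      timestamp       TEXT,
      instrument_id   TEXT,
      injection_first TEXT,
      injection_last  TEXT,
      sample_count    INTEGER CHECK (sample_count >= 0)
    )",
  calibration = "
    CREATE TABLE IF NOT EXISTS calibration (
      calibration_key INTEGER PRIMARY KEY,
      xml_file_name   TEXT NOT NULL,
      timestamp       TEXT,
      compound        TEXT NOT NULL,
      internal_standard TEXT,
      weighting       TEXT,
      slope           REAL CHECK (slope IS NULL OR typeof(slope) IN ('integer','real')),
      r_squared       REAL CHECK (r_squared IS NULL OR
                        (typeof(r_squared) IN ('integer','real')
                         AND r_squared >= 0 AND r_squared <= 1)),
      curve_type      TEXT,
      origin          TEXT,
      UNIQUE (xml_file_name, compound)
    )",
  results = "
    CREATE TABLE IF NOT EXISTS results (
      result_key      INTEGER PRIMARY KEY,
      xml_file_name   TEXT NOT NULL,
      lc_batch_name   TEXT,
      sample_type     TEXT NOT NULL CHECK
                        (sample_type IN ('calibrator','qc','patient','blank')),
      sample_id       TEXT,
      vial            TEXT,
      injection_time  TEXT,
      compound        TEXT NOT NULL,
      compound_id     TEXT,
      peak_area       REAL CHECK (peak_area IS NULL OR
                        (typeof(peak_area) IN ('integer','real') AND peak_area >= 0)),
      confirming_ion_area REAL CHECK (confirming_ion_area IS NULL OR
                        (typeof(confirming_ion_area) IN ('integer','real')
                         AND confirming_ion_area >= 0)),
      rt              REAL CHECK (rt IS NULL OR
                        (typeof(rt) IN ('integer','real') AND rt > 0)),
      sn              REAL CHECK (sn IS NULL OR
                        (typeof(sn) IN ('integer','real') AND sn >= 0)),
      concentration   REAL CHECK (concentration IS NULL OR
                        (typeof(concentration) IN ('integer','real')
                         AND concentration >= 0)),
      cc              INTEGER CHECK (cc IS NULL OR cc IN (0, 1)),
      internal_standard TEXT,
      is_id           TEXT,
      is_peak_area    REAL CHECK (is_peak_area IS NULL OR
                        (typeof(is_peak_area) IN ('integer','real')
                         AND is_peak_area >= 0)),
      is_rt           REAL CHECK (is_rt IS NULL OR
                        (typeof(is_rt) IN ('integer','real') AND is_rt > 0)),
      is_sn           REAL CHECK (is_sn IS NULL OR
                        (typeof(is_sn) IN ('integer','real') AND is_sn >= 0)),
      is_confirming_ion_area REAL CHECK (is_confirming_ion_area IS NULL OR
                        (typeof(is_confirming_ion_area) IN ('integer','real')
                         AND is_confirming_ion_area >= 0)),
      instrument_id   TEXT
    )"
)

#' Initialise (or open) a QC datastore
#'
#' Creates the three-table schema — `batch`, `calibration`, `results` — in an
#' embedded SQLite database. Each table carries a surrogate integer primary
#' key; `xml_file_name` is unique at batch level so re-ingesting a file is
#' detected. Calling twice on the same target is a no-op.
#'
#' `instrument_id` is denormalised onto `results` so per-instrument
#' distribution queries stay single-table; every historical evaluation splits
#' by instrument.
#'
#' @param target Database locator: a file path or `":memory:"`.
#' @return An open `DBIConnection` with the schema in place. Close it with
#'   [DBI::dbDisconnect()].
#' @export
init_schema <- function(target = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), target)
  for (tab in names(.ddl)) {
    if (DBI::dbExistsTable(con, tab)) {
      have <- DBI::dbListFields(con, tab)
      want <- .schema_fields(tab)
      if (!setequal(have, want)) {
        DBI::dbDisconnect(con)
        abort(paste0("existing table '", tab,
                     "' has incompatible columns; refusing to migrate"))
      }
    } else {
      DBI::dbExecute(con, .ddl[[tab]])
    }
  }
  con
}

.schema_fields <- function(tab) {
  switch(tab,
    batch = c("batch_key", "xml_file_name", "timestamp", "instrument_id",
              "injection_first", "injection_last", "sample_count"),
    calibration = c("calibration_key", "xml_file_name", "timestamp",
                    "compound", "internal_standard", "weighting", "slope",
                    "r_squared", "curve_type", "origin"),
    results = c("result_key", result_cols())
  )
}

#' Load a parsed batch into the datastore
#'
#' Inserts the batch, calibration and result records atomically. A file
#' already present (same `xml_file_name`) inserts nothing and is reported as
#' a duplicate; a constraint violation rolls back the whole batch.
#'
#' @param pb A `parsed_batch` from [parse_quant_xml()].
#' @param con Connection from [init_schema()].
#' @return A one-row tibble: `batch_key`, `n_calibrations`, `n_results`,
#'   `duplicate`.
#' @export
load_batch <- function(pb, con) {
  validate_parsed_batch(pb)
  fname <- pb$batch$xml_file_name
  dup <- DBI::dbGetQuery(
    con, "SELECT batch_key FROM batch WHERE xml_file_name = ?",
    params = list(fname))
  if (nrow(dup) > 0) {
    return(tibble(batch_key = dup$batch_key[[1]], n_calibrations = 0L,
                  n_results = 0L, duplicate = TRUE))
  }
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) DBI::dbExecute(con, "ROLLBACK"), add = TRUE)

  b <- pb$batch
  DBI::dbExecute(con,
    "INSERT INTO batch (xml_file_name, timestamp, instrument_id,
                        injection_first, injection_last, sample_count)
     VALUES (?, ?, ?, ?, ?, ?)",
    params = list(b$xml_file_name, format_iso_dt(b$timestamp),
                  b$instrument_id, format_iso_dt(b$injection_first),
                  format_iso_dt(b$injection_last), b$sample_count))
  batch_key <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS k")$k[[1]]

  if (nrow(pb$calibrations) > 0) {
    cal <- pb$calibrations
    cal$timestamp <- format_iso_dt(cal$timestamp)
    DBI::dbExecute(con,
      "INSERT INTO calibration (xml_file_name, timestamp, compound,
         internal_standard, weighting, slope, r_squared, curve_type, origin)
       VALUES (:xml_file_name, :timestamp, :compound, :internal_standard,
               :weighting, :slope, :r_squared, :curve_type, :origin)",
      params = as.list(cal))
  }
  if (nrow(pb$results) > 0) {
    res <- pb$results
    res$injection_time <- format_iso_dt(res$injection_time)
    res$cc <- as.integer(res$cc)
    DBI::dbExecute(con,
      paste0("INSERT INTO results (", paste(result_cols(), collapse = ", "),
             ") VALUES (", paste0(":", result_cols(), collapse = ", "), ")"),
      params = as.list(res))
  }
  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  tibble(batch_key = batch_key, n_calibrations = nrow(pb$calibrations),
         n_results = nrow(pb$results), duplicate = FALSE)
}

#' Describe a result selection
#'
#' Builds a filter over the `results` table. Absent fields impose no
#' restriction; present fields conjoin (AND). The date range is half-open,
#' `(start, end]`, on `injection_time`, so month-partitioned views never
#' double-count boundary injections.
#'
#' @param instruments,compounds,sample_types,batches Optional character
#'   vectors restricting the corresponding column.
#' @param date_range Optional length-2 `POSIXct` (or coercible) vector
#'   `(start, end]`.
#' @return A `result_filter` object.
#' @export
result_filter <- function(instruments = NULL, compounds = NULL,
                          sample_types = NULL, date_range = NULL,
                          batches = NULL) {
  if (!is.null(sample_types)) {
    bad <- setdiff(sample_types, c("calibrator", "qc", "patient", "blank"))
    if (length(bad)) abort(paste0("unknown sample_type: ", paste(bad, collapse = ", ")))
  }
  if (!is.null(date_range)) {
    stopifnot(length(date_range) == 2)
    date_range <- as.POSIXct(date_range, tz = "UTC")
  }
  structure(list(instruments = instruments, compounds = compounds,
                 sample_types = sample_types, date_range = date_range,
                 batches = batches),
            class = "result_filter")
}

.filter_sql <- function(filter) {
  stopifnot(inherits(filter, "result_filter"))
  clauses <- character()
  params <- list()
  add_in <- function(col, vals) {
    if (is.null(vals)) return()
    clauses <<- c(clauses, paste0(col, " IN (",
                                  paste(rep("?", length(vals)), collapse = ", "), ")"))
    params <<- c(params, as.list(vals))
  }
  add_in("instrument_id", filter$instruments)
  add_in("compound", filter$compounds)
  add_in("sample_type", filter$sample_types)
  add_in("xml_file_name", filter$batches)
  if (!is.null(filter$date_range)) {
    clauses <- c(clauses, "injection_time > ?", "injection_time <= ?")
    params <- c(params, as.list(format_iso_dt(filter$date_range)))
  }
  list(where = if (length(clauses)) paste(" WHERE", paste(clauses, collapse = " AND ")) else "",
       params = params)
}

#' Query result records
#'
#' Returns exactly the rows satisfying the conjunction of the filter's
#' present fields, in deterministic order (`injection_time`, then
#' `result_key`). Read-only: no mutation path is exposed.
#'
#' @param con Connection from [init_schema()].
#' @param filter A [result_filter()]; the default selects everything.
#' @return A tibble of result records (with `result_key`), timestamps as
#'   UTC `POSIXct`, `cc` as logical.
#' @export
query_results <- function(con, filter = result_filter()) {
  fs <- .filter_sql(filter)
  sql <- paste0("SELECT * FROM results", fs$where,
                " ORDER BY injection_time, result_key")
  df <- if (length(fs$params)) {
    DBI::dbGetQuery(con, sql, params = fs$params)
  } else {
    DBI::dbGetQuery(con, sql)
  }
  out <- as_tibble(df)
  out$injection_time <- parse_iso_dt(out$injection_time)
  out$cc <- as.logical(out$cc)
  out
}

#' Read the batch and calibration tables
#'
#' @param con Connection from [init_schema()].
#' @return A tibble of the full table, timestamps parsed to UTC `POSIXct`.
#' @export
query_batches <- function(con) {
  out <- as_tibble(DBI::dbGetQuery(con, "SELECT * FROM batch ORDER BY timestamp, batch_key"))
  out$timestamp <- parse_iso_dt(out$timestamp)
  out$injection_first <- parse_iso_dt(out$injection_first)
  out$injection_last <- parse_iso_dt(out$injection_last)
  out
}

#' @rdname query_batches
#' @export
query_calibrations <- function(con) {
  out <- as_tibble(DBI::dbGetQuery(
    con, "SELECT * FROM calibration ORDER BY xml_file_name, compound"))
  out$timestamp <- parse_iso_dt(out$timestamp)
  out
}

#' Export a datastore table to CSV
#'
#' @param con Connection from [init_schema()].
#' @param table One of `"batch"`, `"calibration"`, `"results"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_table_csv <- function(con, table = c("results", "batch", "calibration"),
                             path) {
  table <- match.arg(table)
  tbl <- switch(table,
                results = query_results(con),
                batch = query_batches(con),
                calibration = query_calibrations(con))
  readr::write_csv(tbl, path)
  invisible(path)
}
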