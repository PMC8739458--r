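# Synthetic batch generator: dialect-conformant corpora with controllable
# statistical structure, so every other module is testable without any
# clinical data. Signal intensities follow a lognormal law (positive,
# right-skewed, matching real peak-area distributions); per-instrument
# scale factors emulate differences in ion optics and detector gain; an
# optional second lognormal mode emulates the bimodal internal-standard
# distributions seen in historical data; patient rows can be randomly
# ion-suppressed to mimic matrix effects of dilute-and-shoot preparation.

#' Default compound panel for the generator
#'
#' A small panel of opioids with isotope-labelled internal standards,
#' nominal retention times (minutes) and expected confirming/quantifying
#' ion ratios.
#'
#' @return A tibble with columns `name`, `is_name`, `nominal_rt`,
#'   `expected_ion_ratio`.
#' @export
default_compounds <- function() {
  tibble(
    name = c("Morphine", "Codeine", "6-Monoacetylmorphine", "Oxycodone",
             "Fentanyl", "Methadone"),
    is_name = c("Morphine-d3", "Codeine-d6", "6-Monoacetylmorphine-d6",
                "Oxycodone-d6", "Fentanyl-d5", "Methadone-d9"),
    nominal_rt = c(1.10, 1.35, 1.85, 1.60, 2.95, 3.40),
    expected_ion_ratio = c(0.45, 0.52, 0.38, 0.61, 0.55, 0.47)
  )
}

#' Configure the synthetic-batch generator
#'
#' Defines the statistical conditions of a generated corpus. Defaults model
#' a two-instrument targeted opioid confirmation assay: six calibrator
#' levels (Std-A lowest), two QC samples and patient samples per batch;
#' lognormal internal-standard peak areas scaled per instrument; analyte
#' retention times co-eluting with their internal standards (RRT centred on
#' 1.0 with small multiplicative noise).
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the corpus
#'   byte-for-byte.
#' @param n_batches Number of batches (one XML file each).
#' @param samples_per_batch Samples per batch, including calibrators and QC.
#' @param instruments Tibble `(instrument_id, is_area_scale)`; batches are
#'   assigned round-robin. Scale factors multiply IS peak areas, emulating
#'   between-instrument signal differences.
#' @param compounds Tibble as [default_compounds()].
#' @param calibrator_levels Ordered tibble `(label, concentration)`; the
#'   first row is the lowest calibrator ("Std-A").
#' @param n_qc Number of QC samples per batch.
#' @param qc_concentrations Nominal QC concentrations (ng/mL), recycled.
#' @param is_area_meanlog,is_area_sdlog Lognormal law of IS peak areas
#'   (area counts) before instrument scaling.
#' @param bimodal_fraction Fraction of IS areas routed to a second lognormal
#'   mode (default 0 = unimodal).
#' @param bimodal_meanlog_shift Meanlog offset of the second mode.
#' @param rrt_sd Relative SD of the analyte RT around its internal
#'   standard's RT (IS RT stays at the nominal value, so RRT centres on 1).
#' @param response_factor Quantifying peak area per ng/mL.
#' @param peak_area_sdlog Multiplicative (lognormal) noise on analyte areas.
#' @param sn_meanlog,sn_sdlog Lognormal law of analyte signal-to-noise.
#' @param ion_ratio_sd Relative noise on the confirming/quantifying ratio.
#' @param patient_suppression Length-2 numeric `(probability, multiplier)`:
#'   each patient row is ion-suppressed (both analyte and IS areas
#'   multiplied) with this probability.
#' @param missing_field_rate Probability that any one numeric field of a row
#'   is missing from the emitted XML (accepted as null downstream).
#' @param start_date First batch timestamp (UTC).
#' @param batch_interval_hours Hours between consecutive batch timestamps.
#' @param plants List of planted-violation directives; see
#'   [plant_failures()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L,
                             n_batches = 10,
                             samples_per_batch = 20,
                             instruments = tibble(
                               instrument_id = c("LCMS-1", "LCMS-2"),
                               is_area_scale = c(1.0, 0.7)),
                             compounds = default_compounds(),
                             calibrator_levels = tibble(
                               label = paste0("Std-", LETTERS[1:6]),
                               concentration = c(1, 5, 10, 50, 100, 500)),
                             n_qc = 2,
                             qc_concentrations = c(30, 300),
                             is_area_meanlog = 11,
                             is_area_sdlog = 0.4,
                             bimodal_fraction = 0,
                             bimodal_meanlog_shift = -1,
                             rrt_sd = 0.005,
                             response_factor = 1000,
                             peak_area_sdlog = 0.25,
                             sn_meanlog = log(300),
                             sn_sdlog = 0.6,
                             ion_ratio_sd = 0.02,
                             patient_suppression = c(0.02, 0.3),
                             missing_field_rate = 0,
                             start_date = "2021-01-04T08:00:00Z",
                             batch_interval_hours = 84,
                             plants = list()) {
  n_cal <- nrow(calibrator_levels)
  if (samples_per_batch < n_cal + n_qc) {
    abort("samples_per_batch must cover calibrators and QC samples")
  }
  rates <- c(bimodal_fraction, missing_field_rate, patient_suppression[[1]])
  if (any(rates < 0 | rates > 1)) abort("rates/fractions must lie in [0, 1]")
  if (any(instruments$is_area_scale <= 0)) abort("is_area_scale must be positive")
  if (anyDuplicated(calibrator_levels$label)) abort("calibrator labels must be unique")
  structure(list(
    seed = as.integer(seed), n_batches = n_batches,
    samples_per_batch = samples_per_batch, instruments = instruments,
    compounds = compounds, calibrator_levels = calibrator_levels,
    n_qc = n_qc, qc_concentrations = qc_concentrations,
    is_area_meanlog = is_area_meanlog, is_area_sdlog = is_area_sdlog,
    bimodal_fraction = bimodal_fraction,
    bimodal_meanlog_shift = bimodal_meanlog_shift,
    rrt_sd = rrt_sd, response_factor = response_factor,
    peak_area_sdlog = peak_area_sdlog,
    sn_meanlog = sn_meanlog, sn_sdlog = sn_sdlog,
    ion_ratio_sd = ion_ratio_sd,
    patient_suppression = patient_suppression,
    missing_field_rate = missing_field_rate,
    start_date = start_date, batch_interval_hours = batch_interval_hours,
    plants = plants
  ), class = "generator_config")
}

#' Planted-violation directives
#'
#' Directives modify generated rows *after* the random draws so a corpus
#' contains an exact, known number of rule violations; every touched row is
#' recorded in the ground-truth table. Each directive restricts its eligible
#' rows by `compound`, `sample_type` and/or `instrument_id` (NULL = no
#' restriction); eligible rows are taken in deterministic generation order.
#'
#' * `plant_below_cutoff()` forces exactly `n` eligible rows of `parameter`
#'   to `value` (which must be `< cutoff`) and reflects any other eligible
#'   row that falls below `cutoff` to above it, so exactly `n` rows sit
#'   below the cutoff.
#' * `plant_rrt_outside()` sets `rt = is_rt * factor` on exactly `n`
#'   eligible rows (choose `factor` outside the window) and pulls every
#'   other eligible row's RT to co-elution so exactly `n` RRTs fall outside
#'   `window`.
#' * `plant_std_a()` sets the Std-A (first calibrator) quantifying peak area
#'   of `compound` to `value` in the first `n_batches` eligible batches; if
#'   `ensure_above` is given, other batches' Std-A areas are reflected above
#'   it.
#'
#' @param parameter Numeric result field to modify.
#' @param cutoff,window The threshold the violation is defined against.
#' @param value,factor The planted value / RRT factor.
#' @param n,n_batches Exact number of planted rows / batches.
#' @param compound,sample_type,instrument_id Optional eligibility
#'   restrictions.
#' @param ensure_above Optional floor applied to non-planted Std-A rows.
#' @return A directive, to be passed to [plant_failures()].
#' @name plant-directives
#' @export
plant_below_cutoff <- function(parameter, cutoff, n, value = cutoff / 2,
                               compound = NULL, sample_type = NULL,
                               instrument_id = NULL) {
  if (!(value < cutoff)) abort("planted value must lie below the cutoff")
  structure(list(type = "below_cutoff", parameter = parameter,
                 cutoff = cutoff, value = value, n = n, compound = compound,
                 sample_type = sample_type, instrument_id = instrument_id),
            class = "plant_directive")
}

#' @rdname plant-directives
#' @export
plant_rrt_outside <- function(factor, n, window = c(0.984, 1.024),
                              compound = NULL, sample_type = NULL,
                              instrument_id = NULL) {
  if (factor >= window[[1]] && factor <= window[[2]]) {
    abort("factor must lie outside the window")
  }
  structure(list(type = "rrt_outside", factor = factor, n = n,
                 window = window, compound = compound,
                 sample_type = sample_type, instrument_id = instrument_id),
            class = "plant_directive")
}

#' @rdname plant-directives
#' @export
plant_std_a <- function(value, n_batches, compound, ensure_above = NULL) {
  structure(list(type = "std_a", value = value, n_batches = n_batches,
                 compound = compound, ensure_above = ensure_above),
            class = "plant_directive")
}

#' Add planted violations to a generator configuration
#'
#' @param config A `generator_config`.
#' @param plants A list of [plant-directives].
#' @return The configuration with the directives appended.
#' @export
plant_failures <- function(config, plants) {
  stopifnot(inherits(config, "generator_config"))
  if (inherits(plants, "plant_directive")) plants <- list(plants)
  ok <- vapply(plants, inherits, logical(1), "plant_directive")
  if (!all(ok)) abort("plants must be plant_directive objects")
  config$plants <- c(config$plants, plants)
  config
}

# Eligible row indices for a directive, in generation order.
.eligible_rows <- function(res, d) {
  keep <- rep(TRUE, nrow(res))
  if (!is.null(d$compound)) keep <- keep & res$compound %in% d$compound
  if (!is.null(d$sample_type)) keep <- keep & res$sample_type %in% d$sample_type
  if (!is.null(d$instrument_id)) keep <- keep & res$instrument_id %in% d$instrument_id
  which(keep)
}

.apply_plant <- function(res, d, id) {
  if (d$type == "below_cutoff") {
    elig <- .eligible_rows(res, d)
    if (length(elig) < d$n) {
      abort(sprintf("infeasible plant %s: %d eligible rows, %d requested",
                    id, length(elig), d$n))
    }
    target <- elig[seq_len(d$n)]
    res[[d$parameter]][target] <- d$value
    res$planted[target] <- id
    rest <- setdiff(elig, target)
    low <- rest[!is.na(res[[d$parameter]][rest]) &
                  res[[d$parameter]][rest] < d$cutoff]
    if (length(low)) {
      res[[d$parameter]][low] <- 2 * d$cutoff - res[[d$parameter]][low]
      res$planted[low] <- paste0(id, ":reflected")
    }
  } else if (d$type == "rrt_outside") {
    elig <- .eligible_rows(res, d)
    elig <- elig[!is.na(res$is_rt[elig])]
    if (length(elig) < d$n) {
      abort(sprintf("infeasible plant %s: %d eligible rows, %d requested",
                    id, length(elig), d$n))
    }
    target <- elig[seq_len(d$n)]
    res$rt[target] <- res$is_rt[target] * d$factor
    res$planted[target] <- id
    rest <- setdiff(elig, target)
    rrt <- res$rt[rest] / res$is_rt[rest]
    out <- rest[!is.na(rrt) & (rrt < d$window[[1]] | rrt > d$window[[2]])]
    if (length(out)) {
      res$rt[out] <- res$is_rt[out]
      res$planted[out] <- paste0(id, ":recentred")
    }
  } else if (d$type == "std_a") {
    # first calibrator = lowest sample_id among calibrators (Std-A < Std-B)
    cal_idx <- which(res$sample_type == "calibrator" & res$compound == d$compound)
    if (length(cal_idx) == 0) abort(sprintf("plant %s: no calibrator rows", id))
    first_label <- min(res$sample_id[cal_idx])
    idx <- cal_idx[res$sample_id[cal_idx] == first_label]
    batches <- unique(res$xml_file_name[idx])
    if (length(batches) < d$n_batches) {
      abort(sprintf("infeasible plant %s: %d batches, %d requested",
                    id, length(batches), d$n_batches))
    }
    hit <- idx[res$xml_file_name[idx] %in% batches[seq_len(d$n_batches)]]
    res$peak_area[hit] <- d$value
    res$planted[hit] <- id
    if (!is.null(d$ensure_above)) {
      rest <- setdiff(idx, hit)
      low <- rest[!is.na(res$peak_area[rest]) & res$peak_area[rest] < d$ensure_above]
      if (length(low)) {
        res$peak_area[low] <- 2 * d$ensure_above - res$peak_area[low]
        res$planted[low] <- paste0(id, ":reflected")
      }
    }
  } else {
    abort(paste0("unknown plant directive type: ", d$type))
  }
  res
}

#' Generate synthetic batches in memory
#'
#' Draws the whole corpus (deterministically for a fixed seed), applies any
#' planted violations, then applies field dropout. Use [generate_corpus()]
#' to additionally serialise the batches to dialect XML.
#'
#' @param config A `generator_config`.
#' @return A list: `batches` (list of `parsed_batch`), `ground_truth`
#'   (tibble of true per-row values with `suppressed`, `planted` and
#'   `missing_fields` columns), `instruments` (the per-instrument scale
#'   table).
#' @export
generate_batches <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, .generate_batches_impl(config))
}

.generate_batches_impl <- function(cfg) {
  n_cal <- nrow(cfg$calibrator_levels)
  n_pat <- cfg$samples_per_batch - n_cal - cfg$n_qc
  cmp <- cfg$compounds
  t0 <- parse_iso_dt(cfg$start_date)

  sample_plan <- bind_rows(
    tibble(sample_id = cfg$calibrator_levels$label, sample_type = "calibrator",
           nominal_conc = cfg$calibrator_levels$concentration),
    if (cfg$n_qc > 0) tibble(
      sample_id = sprintf("QC-%d", seq_len(cfg$n_qc)), sample_type = "qc",
      nominal_conc = rep_len(cfg$qc_concentrations, cfg$n_qc)),
    if (n_pat > 0) tibble(
      sample_id = sprintf("Pat-%03d", seq_len(n_pat)), sample_type = "patient",
      nominal_conc = NA_real_)
  )

  all_res <- list()
  all_cal <- list()
  batch_meta <- list()
  for (b in seq_len(cfg$n_batches)) {
    inst <- cfg$instruments[((b - 1) %% nrow(cfg$instruments)) + 1, ]
    ts <- t0 + (b - 1) * cfg$batch_interval_hours * 3600
    fname <- sprintf("batch_%03d.xml", b)
    lc_name <- sprintf("OPI-%03d", b)

    plan <- sample_plan
    plan$vial <- sprintf("1:%d", seq_len(nrow(plan)))
    plan$injection_time <- ts + (seq_len(nrow(plan)) - 1) * 120
    # patient concentrations: right-skewed, occasionally high
    pat <- plan$sample_type == "patient"
    plan$conc <- plan$nominal_conc
    plan$conc[pat] <- rlnorm(sum(pat), meanlog = log(50), sdlog = 1)
    qc <- plan$sample_type == "qc"
    plan$conc[qc] <- plan$nominal_conc[qc] * exp(rnorm(sum(qc), 0, 0.05))

    grid <- tidyr::expand_grid(si = seq_len(nrow(plan)), ci = seq_len(nrow(cmp)))
    n <- nrow(grid)
    s <- plan[grid$si, ]
    co <- cmp[grid$ci, ]

    mode2 <- runif(n) < cfg$bimodal_fraction
    meanlog <- cfg$is_area_meanlog + ifelse(mode2, cfg$bimodal_meanlog_shift, 0)
    is_area <- rlnorm(n, meanlog, cfg$is_area_sdlog) * inst$is_area_scale
    peak_area <- cfg$response_factor * s$conc *
      exp(rnorm(n, 0, cfg$peak_area_sdlog))
    suppressed <- s$sample_type == "patient" &
      runif(n) < cfg$patient_suppression[[1]]
    is_area[suppressed] <- is_area[suppressed] * cfg$patient_suppression[[2]]
    peak_area[suppressed] <- peak_area[suppressed] * cfg$patient_suppression[[2]]

    is_rt <- co$nominal_rt
    rt <- co$nominal_rt * (1 + rnorm(n, 0, cfg$rrt_sd))
    sn <- rlnorm(n, cfg$sn_meanlog, cfg$sn_sdlog)
    is_sn <- rlnorm(n, cfg$sn_meanlog + 1, cfg$sn_sdlog / 2)
    conf <- peak_area * co$expected_ion_ratio *
      (1 + rnorm(n, 0, cfg$ion_ratio_sd))
    is_conf <- is_area * 0.5 * (1 + rnorm(n, 0, cfg$ion_ratio_sd))

    all_res[[b]] <- tibble(
      xml_file_name = fname, lc_batch_name = lc_name,
      sample_type = s$sample_type, sample_id = s$sample_id, vial = s$vial,
      injection_time = s$injection_time,
      compound = co$name, compound_id = sprintf("cmp%02d", grid$ci),
      peak_area = peak_area, confirming_ion_area = conf, rt = rt, sn = sn,
      concentration = s$conc, cc = s$sample_type == "calibrator",
      internal_standard = co$is_name, is_id = sprintf("is%02d", grid$ci),
      is_peak_area = is_area, is_rt = is_rt, is_sn = is_sn,
      is_confirming_ion_area = is_conf, instrument_id = inst$instrument_id,
      suppressed = suppressed
    )
    all_cal[[b]] <- tibble(
      xml_file_name = fname, timestamp = ts, compound = cmp$name,
      internal_standard = cmp$is_name, weighting = "1/x",
      slope = cfg$response_factor * exp(rnorm(nrow(cmp), 0, 0.02)),
      r_squared = runif(nrow(cmp), 0.995, 0.9999),
      curve_type = "linear", origin = "exclude"
    )
    batch_meta[[b]] <- tibble(xml_file_name = fname, timestamp = ts,
                              instrument_id = inst$instrument_id,
                              sample_count = nrow(plan))
  }

  res <- bind_rows(all_res)
  res$planted <- NA_character_
  for (i in seq_along(cfg$plants)) {
    res <- .apply_plant(res, cfg$plants[[i]], paste0("plant_", i))
  }

  truth <- res
  # field dropout (never on planted rows, so planted counts stay exact)
  res$missing_fields <- ""
  if (cfg$missing_field_rate > 0) {
    droppable <- is.na(res$planted)
    for (f in .result_num_cols) {
      drop <- droppable & runif(nrow(res)) < cfg$missing_field_rate
      res[[f]][drop] <- NA_real_
      res$missing_fields[drop] <- trimws(paste(res$missing_fields[drop], f), "left")
    }
  }
  truth$missing_fields <- res$missing_fields

  batches <- vector("list", cfg$n_batches)
  for (b in seq_len(cfg$n_batches)) {
    bm <- batch_meta[[b]]
    rows <- res[res$xml_file_name == bm$xml_file_name, ]
    inj <- rows$injection_time
    batch <- tibble(
      xml_file_name = bm$xml_file_name, timestamp = bm$timestamp,
      instrument_id = bm$instrument_id,
      injection_first = min(inj), injection_last = max(inj),
      sample_count = bm$sample_count
    )
    pb <- new_parsed_batch(
      batch, all_cal[[b]],
      rows[, result_cols()],
      tibble(field_path = character(), reason = character())
    )
    validate_parsed_batch(pb)
    batches[[b]] <- pb
  }
  list(batches = batches,
       ground_truth = truth[, c("xml_file_name", "sample_id", "sample_type",
                                "compound", "instrument_id", .result_num_cols,
                                "suppressed", "planted", "missing_fields")],
       instruments = cfg$instruments)
}

#' Generate a synthetic corpus on disk
#'
#' Runs [generate_batches()] and serialises every batch to dialect XML in
#' `out_dir`, plus a `ground_truth/` sidecar (plain CSV, test-only: true
#' per-row draws, suppression, planted violations, dropped fields,
#' per-instrument scale factors). Deterministic for a fixed seed.
#'
#' @param config A `generator_config`.
#' @param out_dir Output directory (created if missing).
#' @return A manifest list: `files` (XML paths in batch order),
#'   `ground_truth`, `instruments`, `batches` (the in-memory
#'   `parsed_batch` objects), `config`.
#' @export
generate_corpus <- function(config, out_dir) {
  gen <- generate_batches(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- vapply(gen$batches, function(pb) {
    path <- file.path(out_dir, pb$batch$xml_file_name)
    write_quant_xml(pb, path)
    path
  }, character(1))
  gt_dir <- file.path(out_dir, "ground_truth")
  if (!dir.exists(gt_dir)) dir.create(gt_dir)
  readr::write_csv(gen$ground_truth, file.path(gt_dir, "results.csv"))
  readr::write_csv(gen$instruments, file.path(gt_dir, "instruments.csv"))
  list(files = files, ground_truth = gen$ground_truth,
       instruments = gen$instruments, batches = gen$batches, config = config)
}
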