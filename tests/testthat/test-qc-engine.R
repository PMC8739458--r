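test_that("compute_rrt and compute_ion_ratio obey their algebra and null rules", {
  expect_equal(compute_rrt(2.40, 2.40), 1.0)
  expect_equal(compute_rrt(2.50, 2.00), 1.25)
  expect_equal(compute_ion_ratio(5, 5), 1.0)
  expect_equal(compute_ion_ratio(0, 5), 0.0)

  set.seed(7)
  rt <- runif(200, 0.5, 5); is_rt <- runif(200, 0.5, 5)
  expect_equal(compute_rrt(rt, is_rt) * is_rt, rt)
  conf <- runif(200, 0, 1e5); quant <- runif(200, 1, 1e5)
  expect_equal(compute_ion_ratio(conf, quant) * quant, conf)

  expect_true(is.na(compute_rrt(2.4, NA)))
  expect_true(is.na(compute_rrt(NA, 2.4)))
  expect_true(is.na(compute_rrt(2.4, 0)))
  expect_true(is.na(compute_ion_ratio(100, 0)))
})

make_rows <- function(n = 1, ...) {
  defaults <- list(
    xml_file_name = "b.xml", lc_batch_name = "B", sample_type = "patient",
    sample_id = sprintf("Pat-%03d", seq_len(n)), vial = "1:1",
    injection_time = as.POSIXct("2021-01-04 08:00:00", tz = "UTC"),
    compound = "Morphine", compound_id = "c1", peak_area = 50000,
    confirming_ion_area = 25000, rt = 1.10, sn = 200, concentration = 50,
    cc = FALSE, internal_standard = "Morphine-d3", is_id = "i1",
    is_peak_area = 60000, is_rt = 1.10, is_sn = 500,
    is_confirming_ion_area = 30000, instrument_id = "LCMS-1"
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(lapply(defaults, function(v) rep(v, length.out = n)))
}

test_that("RRT window is inclusive at both bounds and null-safe", {
  cut <- compound_cutoffs("Morphine", rrt_low = 0.984, rrt_high = 1.024)
  rrt_flag <- function(rt, is_rt = 1.0) {
    check_rrt(make_rows(rt = rt, is_rt = is_rt), cut)$status
  }
  expect_equal(rrt_flag(1.000), "pass")
  expect_equal(rrt_flag(0.984), "pass")   # exact boundary passes
  expect_equal(rrt_flag(1.024), "pass")
  expect_equal(rrt_flag(0.9839), "fail")
  expect_equal(rrt_flag(1.0241), "fail")
  expect_equal(rrt_flag(NA_real_), "not_evaluable")
  expect_equal(rrt_flag(1.0, NA_real_), "not_evaluable")

  # brute-force sweep
  set.seed(8)
  vals <- runif(1000, 0.9, 1.1)
  flags <- check_rrt(make_rows(n = 1000, rt = vals, is_rt = 1.0), cut)
  expect_equal(flags$status == "fail", vals < 0.984 | vals > 1.024)
})

test_that("minimum-threshold rules pass at equality and disable on null cutoffs", {
  cut <- compound_cutoffs("Morphine", is_peak_area_min = 20000, sn_min = 100)
  expect_equal(check_is_peak_area(make_rows(is_peak_area = 20000), cut)$status, "pass")
  expect_equal(check_is_peak_area(make_rows(is_peak_area = 0), cut)$status, "fail")
  expect_equal(check_is_peak_area(make_rows(is_peak_area = NA_real_), cut)$status,
               "not_evaluable")
  expect_equal(check_sn(make_rows(sn = 100), cut)$status, "pass")
  expect_equal(check_sn(make_rows(sn = 99.999), cut)$status, "fail")

  disabled <- compound_cutoffs("Morphine", sn_min = NA_real_)
  f <- check_sn(make_rows(sn = 1), disabled)
  expect_equal(f$status, "pass")
  expect_equal(f$threshold_repr, "disabled")
})

test_that("ion ratio uses configured expectation or in-batch calibrator mean", {
  cut <- compound_cutoffs("Morphine", expected_ion_ratio = 0.50,
                          ion_ratio_tolerance = 0.2)
  # |0.61/0.50 - 1| = 0.22 > 0.2 -> fail
  f <- check_ion_ratio(make_rows(confirming_ion_area = 0.61, peak_area = 1), cut)
  expect_equal(f$status, "fail")
  expect_equal(check_ion_ratio(
    make_rows(confirming_ion_area = 0.599, peak_area = 1), cut)$status, "pass")
  expect_equal(check_ion_ratio(
    make_rows(confirming_ion_area = 0.50, peak_area = 1), cut)$status, "pass")

  # derived expectation: calibrators share ratio r, patient at r passes
  derive_cut <- compound_cutoffs("Morphine", ion_ratio_tolerance = 0.2)
  cal <- make_rows(n = 3, sample_type = "calibrator",
                   sample_id = paste0("Std-", LETTERS[1:3]),
                   peak_area = c(1000, 5000, 10000),
                   confirming_ion_area = 0.37 * c(1000, 5000, 10000))
  pat <- make_rows(peak_area = 2000, confirming_ion_area = 0.37 * 2000)
  expect_equal(check_ion_ratio(pat, derive_cut, bind_rows(cal, pat))$status, "pass")
  off <- make_rows(peak_area = 2000, confirming_ion_area = 0.37 * 2000 * 1.25)
  expect_equal(check_ion_ratio(off, derive_cut, bind_rows(cal, off))$status, "fail")

  # no usable calibrators and no configured expectation -> not evaluable
  expect_equal(check_ion_ratio(pat, derive_cut, pat)$status, "not_evaluable")
})

test_that("the Std-A rule flags the first calibrator by level order", {
  cut <- compound_cutoffs("Morphine", std_a_peak_area_min = 900)
  cal <- make_rows(n = 3, sample_type = "calibrator",
                   sample_id = c("Std-C", "Std-A", "Std-B"),
                   peak_area = c(10000, 1000, 5000),
                   concentration = c(10, 1, 5))
  f <- check_std_a(cal, cut)
  expect_equal(f$status, "pass")           # Std-A at 1000 >= 900
  expect_equal(f$measured, 1000)           # picked Std-A, not Std-C
  expect_equal(f$result_key, 2L)

  expect_equal(check_std_a(cal, compound_cutoffs("Morphine",
    std_a_peak_area_min = 1000))$status, "pass")  # equality passes
  expect_equal(check_std_a(cal, compound_cutoffs("Morphine",
    std_a_peak_area_min = 1001))$status, "fail")

  cal$peak_area[2] <- NA_real_
  expect_equal(check_std_a(cal, cut)$status, "not_evaluable")
  expect_equal(check_std_a(make_rows(sample_type = "patient"), cut)$status,
               "not_evaluable")
})

test_that("planted sub-cutoff Std-A batches are counted exactly", {
  cfg <- plant_failures(
    small_config(seed = 31, n_batches = 10),
    plant_std_a(value = 100, n_batches = 3, compound = "Codeine",
                ensure_above = 400))
  gen <- generate_batches(cfg)
  rs <- basic_ruleset(std_a_peak_area_min = 400)
  fails <- vapply(gen$batches, function(pb) {
    fl <- tidy(evaluate_batch(pb, rs))
    sum(fl$rule == "std_a" & fl$status == "fail" & fl$compound == "Codeine")
  }, numeric(1))
  expect_equal(sum(fails), 3)
  planted <- gen$ground_truth[!is.na(gen$ground_truth$planted) &
                                gen$ground_truth$planted == "plant_1", ]
  expect_equal(sort(unique(planted$xml_file_name)),
               sprintf("batch_%03d.xml", 1:3))
})

test_that("internal-standard lot bias within 10% leaves the cutoff unchanged", {
  expect_equal(adjust_is_cutoff_for_lot(100000, 100000, 20000), 20000)
  expect_equal(adjust_is_cutoff_for_lot(100000, 110000, 20000), 20000)  # +10% inclusive
  expect_equal(adjust_is_cutoff_for_lot(100000, 90000, 20000), 20000)   # -10% inclusive
  expect_equal(adjust_is_cutoff_for_lot(100000, 130000, 20000), 26000)
  expect_equal(adjust_is_cutoff_for_lot(100000, 50000, 20000), 10000)
  expect_error(adjust_is_cutoff_for_lot(0, 100000, 20000), "positive")
})

test_that("rule-set lookup prefers the instrument-specific entry over the wildcard", {
  rs <- ruleset(bind_rows(
    compound_cutoffs("Morphine", instrument_id = "*", is_peak_area_min = 100),
    compound_cutoffs("Morphine", instrument_id = "LCMS-2", is_peak_area_min = 999)
  ))
  expect_equal(resolve_cutoffs(rs, "Morphine", "LCMS-2")$is_peak_area_min, 999)
  expect_equal(resolve_cutoffs(rs, "Morphine", "LCMS-1")$is_peak_area_min, 100)
  expect_error(resolve_cutoffs(rs, "Ketamine", "LCMS-1"), "no rule entry")
})

test_that("evaluate_batch matches the brute-force oracle and conserves totals", {
  cfg <- small_config(seed = 32, n_batches = 2, samples_per_batch = 14,
                      missing_field_rate = 0.08)
  gen <- generate_batches(cfg)
  rs <- basic_ruleset(is_peak_area_min = 35000, sn_min = 150,
                      std_a_peak_area_min = 700)
  for (pb in gen$batches) {
    rep <- evaluate_batch(pb, rs)
    expect_equal(engine_flags_comparable(rep$flags),
                 oracle_flags(pb$results, rs))
    # totals conservation
    expect_equal(sum(rep$totals$pass) + sum(rep$totals$fail) +
                   sum(rep$totals$not_evaluable), nrow(rep$flags))
    # null safety: no fail has a missing measured value for per-row rules
    bad <- rep$flags[rep$flags$status == "fail" & is.na(rep$flags$measured), ]
    expect_equal(nrow(bad), 0)
  }
})

test_that("an all-null batch produces no failures, only not-evaluable flags", {
  cfg <- small_config(seed = 33, n_batches = 1, samples_per_batch = 8)
  gen <- generate_batches(cfg)
  pb <- gen$batches[[1]]
  for (f in c("peak_area", "confirming_ion_area", "rt", "sn",
              "is_peak_area", "is_rt", "is_sn")) {
    pb$results[[f]] <- NA_real_
  }
  rs <- basic_ruleset(is_peak_area_min = 35000, sn_min = 150,
                      std_a_peak_area_min = 700)
  rep <- evaluate_batch(pb, rs)
  expect_equal(sum(rep$flags$status == "fail"), 0)
  expect_true(all(rep$flags$status == "not_evaluable"))
})

test_that("raising a cutoff never decreases fails; widening the window never increases them", {
  cfg <- small_config(seed = 34, n_batches = 3, samples_per_batch = 12)
  gen <- generate_batches(cfg)
  pb <- gen$batches[[1]]
  fails <- function(rs) sum(tidy(evaluate_batch(pb, rs))$status == "fail")
  cuts <- seq(10000, 80000, by = 10000)
  f_by_cut <- vapply(cuts, function(k) fails(basic_ruleset(is_peak_area_min = k)),
                     numeric(1))
  expect_true(all(diff(f_by_cut) >= 0))
  narrow <- fails(basic_ruleset(rrt_low = 0.995, rrt_high = 1.005))
  wide <- fails(basic_ruleset(rrt_low = 0.95, rrt_high = 1.05))
  expect_true(wide <= narrow)
})

test_that("an unresolvable compound aborts with the missing entries listed", {
  cfg <- small_config(seed = 35, n_batches = 1)
  gen <- generate_batches(cfg)
  rs <- basic_ruleset(compounds = "Morphine")
  expect_error(evaluate_batch(gen$batches[[1]], rs), "Codeine")
})

test_that("rule sets round-trip through YAML config files", {
  rs <- ruleset(bind_rows(
    compound_cutoffs("Morphine", is_peak_area_min = 20000, sn_min = 50,
                     expected_ion_ratio = 0.45),
    compound_cutoffs("Fentanyl", instrument_id = "LCMS-2",
                     std_a_peak_area_min = 800)
  ), name = "prod", version = "3")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset(rs, path)
  back <- read_ruleset(path)
  expect_equal(back$entries, rs$entries)
  expect_equal(back$name, "prod")
  expect_equal(back$version, "3")
})
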