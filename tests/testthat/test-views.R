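test_that("summarize_values equals independent brute-force recomputation", {
  expect_equal(summarize_values(c(1, 2, 3))$mean, 2)
  expect_equal(summarize_values(c(1, 2, 3))$median, 2)
  s0 <- summarize_values(rep(4, 9))
  expect_equal(s0$sd, 0)
  expect_equal(s0$q02, 4)
  expect_equal(s0$q75, 4)

  set.seed(51)
  v <- c(rlnorm(500, 11, 0.4), NA, NA)
  s <- summarize_values(v, cutoff = 40000, window = c(30000, 120000))
  w <- v[!is.na(v)]
  expect_equal(s$n, 500)
  expect_equal(s$n_null, 2)
  expect_equal(s$mean, sum(w) / length(w))
  expect_equal(s$median, sort(w)[c(250, 251)] |> mean())
  expect_equal(s$sd, sqrt(sum((w - mean(w))^2) / (length(w) - 1)))
  expect_equal(s$min, min(w))
  expect_equal(s$max, max(w))
  expect_equal(s$q25, quantile_oracle(w, 0.25))
  expect_equal(s$pct_below_cutoff, 100 * sum(w < 40000) / length(w))
  expect_equal(s$pct_outside_window,
               100 * sum(w < 30000 | w > 120000) / length(w))
  # ordering invariant
  expect_true(s$min <= s$q25 && s$q25 <= s$median &&
                s$median <= s$q75 && s$q75 <= s$max)
})

test_that("histogram bins partition the selection and overlays match the modules", {
  cfg <- small_config(seed = 52, n_batches = 4, samples_per_batch = 12)
  st <- loaded_store(cfg)
  withr::defer(DBI::dbDisconnect(st$con))
  rs <- basic_ruleset(is_peak_area_min = 30000)
  f <- result_filter(compounds = "Morphine", instruments = "LCMS-1")
  hv <- histogram_view(st$con, f, "is_peak_area", ruleset = rs, n_bins = 12)

  expect_equal(sum(hv$bins$count), hv$summary$n)
  expect_equal(hv$bins$left[-1], hv$bins$right[-nrow(hv$bins)])  # contiguous
  vals <- query_results(st$con, f)$is_peak_area
  expect_equal(hv$border, empirical_border(vals, 0.02))
  expect_equal(hv$cutoff, 30000)
  expect_equal(hv$summary$pct_below_cutoff, 100 * fraction_below(vals, 30000))
  # brute-force bin counts
  edges <- seq(min(vals), max(vals), length.out = 13)
  manual <- vapply(seq_len(12), function(i) {
    if (i < 12) sum(vals >= edges[i] & vals < edges[i + 1])
    else sum(vals >= edges[i] & vals <= edges[i + 1])
  }, numeric(1))
  expect_equal(hv$bins$count, manual)
})

test_that("a uniform plant fills equal-width bins evenly", {
  cfg <- small_config(seed = 53, n_batches = 1, samples_per_batch = 10,
                      compounds = default_compounds()[1, ])
  gen <- generate_batches(cfg)
  pb <- gen$batches[[1]]
  # plant a uniform grid over [0, 10): 10 values per bin across 10 bins
  pb$results$sn <- seq(0, 9.9, length.out = 10)
  con <- init_schema(":memory:")
  withr::defer(DBI::dbDisconnect(con))
  load_batch(pb, con)
  hv <- histogram_view(con, result_filter(), "sn", n_bins = 5)
  expect_equal(hv$bins$count, rep(2, 5))
})

test_that("a bimodal internal-standard mixture shows two histogram modes", {
  cfg <- small_config(seed = 54, n_batches = 10, samples_per_batch = 20,
                      compounds = default_compounds()[1, ],
                      instruments = tibble::tibble(instrument_id = "LCMS-1",
                                                   is_area_scale = 1),
                      bimodal_fraction = 0.45, bimodal_meanlog_shift = -1.6,
                      is_area_sdlog = 0.25)
  st <- loaded_store(cfg)
  withr::defer(DBI::dbDisconnect(st$con))
  hv <- histogram_view(st$con, result_filter(), "is_peak_area", n_bins = 30)
  counts <- hv$bins$count
  # smooth, then count strict local maxima above a noise floor
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm <- as.numeric(sm); sm[is.na(sm)] <- 0
  peaks <- sum(diff(sign(diff(sm))) == -2 & sm[2:(length(sm) - 1)] > max(sm) / 8)
  expect_gte(peaks, 2)
})

test_that("trend views partition rows into chronologically ordered groups", {
  cfg <- small_config(seed = 55, n_batches = 10, samples_per_batch = 10,
                      batch_interval_hours = 24 * 7)  # spans > 2 months
  st <- loaded_store(cfg)
  withr::defer(DBI::dbDisconnect(st$con))
  f <- result_filter(compounds = "Codeine")
  tv <- average_trend_view(st$con, f, "is_peak_area", "by_month")
  rows <- query_results(st$con, f)
  expect_gte(nrow(tv$points), 3)
  expect_equal(tv$points$group, sort(tv$points$group))
  expect_equal(sum(tv$points$n), sum(!is.na(rows$is_peak_area)))
  # per-group means equal a brute-force split
  months <- format(rows$injection_time, "%Y-%m", tz = "UTC")
  for (i in seq_len(nrow(tv$points))) {
    expect_equal(tv$points$mean[i],
                 mean(rows$is_peak_area[months == tv$points$group[i]]))
  }

  bv <- average_trend_view(st$con, f, "is_peak_area", "by_batch")
  expect_equal(nrow(bv$points), 10)
  expect_equal(sum(bv$points$n), sum(!is.na(rows$is_peak_area)))
})

test_that("batch_view orders points by injection time regardless of storage order", {
  cfg <- small_config(seed = 56, n_batches = 1, samples_per_batch = 10)
  gen <- generate_batches(cfg)
  pb <- gen$batches[[1]]
  shuffle <- withr::with_seed(1, sample(nrow(pb$results)))
  pb$results <- pb$results[shuffle, ]
  con <- init_schema(":memory:")
  withr::defer(DBI::dbDisconnect(con))
  load_batch(pb, con)
  bv <- batch_view(con, pb$batch$xml_file_name, "is_peak_area")
  expect_equal(nrow(bv$points), nrow(pb$results))
  expect_true(!is.unsorted(bv$points$injection_time))
  expect_error(batch_view(con, "nope.xml"), "unknown batch")
})

test_that("Std-A view agrees with the rule engine and colour-codes batches", {
  cfg <- plant_failures(
    small_config(seed = 57, n_batches = 10),
    plant_std_a(value = 100, n_batches = 3, compound = "Morphine",
                ensure_above = 400))
  st <- loaded_store(cfg)
  withr::defer(DBI::dbDisconnect(st$con))
  rs <- basic_ruleset(std_a_peak_area_min = 400)
  sv <- std_a_signal_view(st$con, result_filter(), rs)

  n_cmp <- nrow(default_compounds())
  expect_equal(nrow(sv$points), 10 * n_cmp)  # one point per batch x compound
  expect_equal(sum(sv$color_code$status == "any_fail"), 3)

  # cross-module equivalence with check_std_a on the same stored rows
  rows <- query_results(st$con, result_filter(sample_types = "calibrator"))
  for (i in seq_len(nrow(sv$points))) {
    sub <- rows[rows$xml_file_name == sv$points$xml_file_name[i] &
                  rows$compound == sv$points$compound[i], ]
    cut <- resolve_cutoffs(rs, sv$points$compound[i], sub$instrument_id[[1]])
    expect_equal(sv$points$status[i], check_std_a(sub, cut)$status)
  }
})

test_that("absolute RT view computes exact deviations from monthly means", {
  cfg <- small_config(seed = 58, n_batches = 6, samples_per_batch = 10,
                      rrt_sd = 0)
  gen <- generate_batches(cfg)
  # shift one batch's RTs by +0.05 min for one compound
  shift_batch <- gen$batches[[2]]$batch$xml_file_name
  for (b in seq_along(gen$batches)) {
    if (gen$batches[[b]]$batch$xml_file_name == shift_batch) {
      sel <- gen$batches[[b]]$results$compound == "Fentanyl"
      gen$batches[[b]]$results$rt[sel] <- gen$batches[[b]]$results$rt[sel] + 0.05
    }
  }
  con <- init_schema(":memory:")
  withr::defer(DBI::dbDisconnect(con))
  for (pb in gen$batches) load_batch(pb, con)

  rv <- absolute_rt_view(con, result_filter(compounds = "Fentanyl"))
  rows <- query_results(con, result_filter(compounds = "Fentanyl"))
  rows$month <- format(rows$injection_time, "%Y-%m", tz = "UTC")
  # internal consistency: deviations recompute exactly from the two tables
  for (i in seq_len(nrow(rv$deviations))) {
    d <- rv$deviations[i, ]
    expect_equal(d$deviation, d$mean_rt - d$month_mean_rt)
    manual_batch <- mean(rows$rt[rows$xml_file_name == d$xml_file_name])
    manual_month <- mean(rows$rt[rows$month == d$month])
    expect_equal(d$mean_rt, manual_batch)
    expect_equal(d$month_mean_rt, manual_month)
  }
  # the shifted batch deviates by +0.05 * (1 - batch_n / month_n)
  d <- rv$deviations[rv$deviations$xml_file_name == shift_batch, ]
  frac <- d$n / d$month_n
  expect_equal(d$deviation, 0.05 * (1 - frac))
  # with rrt_sd = 0 all other batches share their month means exactly
  others <- rv$deviations[rv$deviations$xml_file_name != shift_batch &
                            rv$deviations$month != d$month, ]
  expect_true(all(abs(others$deviation) < 1e-12))
})

test_that("view autoplot methods return ggplot objects", {
  cfg <- small_config(seed = 59, n_batches = 3, samples_per_batch = 8)
  st <- loaded_store(cfg)
  withr::defer(DBI::dbDisconnect(st$con))
  rs <- basic_ruleset(is_peak_area_min = 30000, std_a_peak_area_min = 400)
  f <- result_filter(compounds = "Morphine")
  expect_s3_class(ggplot2::autoplot(histogram_view(st$con, f, "is_peak_area")), "ggplot")
  expect_s3_class(ggplot2::autoplot(average_trend_view(st$con, f, "is_peak_area", "by_batch")), "ggplot")
  expect_s3_class(ggplot2::autoplot(batch_view(st$con, "batch_001.xml", "is_peak_area", rs)), "ggplot")
  expect_s3_class(ggplot2::autoplot(std_a_signal_view(st$con, f, rs)), "ggplot")
  expect_s3_class(ggplot2::autoplot(absolute_rt_view(st$con, f)), "ggplot")
})
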