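test_that("registry honors stratum counts and NYC county labels", {
  cfg <- sim_config(n_rural = 2, n_urban_non_nyc = 2, n_nyc = 1, seed = 1)
  reg <- make_pol_registry(cfg)
  expect_equal(nrow(reg), 5L)
  expect_equal(sum(reg$county %in% NYC_COUNTIES), 1L)
  expect_equal(as.vector(table(reg$urbanicity_truth)[c("rural", "urban_non_nyc", "nyc")]),
               c(2L, 2L, 1L))
  expect_false(anyDuplicated(reg$pol_id) > 0)
  expect_true(all(reg$customers_served >= 1))
  expect_true(all(reg$xmax > reg$xmin & reg$ymax > reg$ymin))
  expect_error(make_pol_registry(sim_config(n_rural = 0, n_urban_non_nyc = 0,
                                            n_nyc = 0)), "empty registry")
  # the study registry's NYC share: 76 of 1,764 POLs is 4.3%
  expect_equal(round(100 * 76 / (985 + 703 + 76), 1), 4.3)
})

test_that("generation is deterministic under a fixed seed, including written files", {
  cfg <- sim_config(n_rural = 1, n_urban_non_nyc = 1, n_nyc = 1,
                    period_start = "2019-01-01", period_end = "2019-02-28",
                    seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$registry, s2$registry)
  expect_identical(s1$outages, s2$outages)
  expect_identical(s1$admissions, s2$admissions)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim_tables(s1, d1); write_sim_tables(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  rt <- read_sim_tables(d1)
  expect_equal(nrow(rt$admissions), nrow(s1$admissions))
  expect_equal(rt$outages$customers_out, s1$outages$customers_out)
})

test_that("outage series respects rates, bounds and the 30-minute calendar", {
  cfg0 <- sim_config(n_rural = 1, n_urban_non_nyc = 0, n_nyc = 0,
                     period_start = "2019-06-02", period_end = "2019-06-02",
                     window_true = 0.5, outage_onset_rate = 0,
                     missingness_rate = 0.1, seed = 3)
  reg <- make_pol_registry(cfg0)
  ser <- qc0 <- simulate_outage_series(reg, cfg0)
  expect_true(all(ser$customers_out == 0))        # no events, no outages
  expect_lte(nrow(ser), 48 + 1)                   # one day plus burn-in slot
  expect_true(all(as.POSIXlt(ser$interval_start)$min %in% c(0L, 30L)))
  # degenerate affected fraction: every in-outage interval at 60% exactly
  cfg6 <- sim_config(n_rural = 1, n_urban_non_nyc = 0, n_nyc = 0,
                     period_start = "2019-06-01", period_end = "2019-06-30",
                     outage_onset_rate = 0.5, affected_fixed = 0.6,
                     missingness_rate = 0, seed = 4)
  reg6 <- make_pol_registry(cfg6)
  ser6 <- simulate_outage_series(reg6, cfg6)
  on <- ser6$customers_out > 0
  expect_true(any(on))
  expect_true(all(ser6$customers_out[on] ==
                    round(0.6 * ser6$customers_served[on])))
  expect_true(all(ser6$customers_out <= ser6$customers_served))
  # larger study: the bound holds everywhere
  sim <- small_sim()
  expect_true(all(sim$outages$customers_out <= sim$outages$customers_served))
})

test_that("block groups are nested, counted and rural where their host is rural", {
  cfg <- sim_config(n_rural = 2, n_urban_non_nyc = 2, n_nyc = 1,
                    n_bg_per_pol = 3, seed = 5)
  reg <- make_pol_registry(cfg)
  bg <- make_block_groups(reg, cfg)
  expect_equal(nrow(bg), 15L)   # 3 per POL, 5 POLs
  # centroid strictly inside the host POL rectangle
  host <- reg[match(bg$pol_id, reg$pol_id), ]
  expect_true(all(bg$centroid_x > host$xmin & bg$centroid_x < host$xmax &
                    bg$centroid_y > host$ymin & bg$centroid_y < host$ymax))
  expect_true(all(bg$rural_population <= bg$population))
  # rural POLs: aggregated rural share above one half
  for (p in reg$pol_id[reg$urbanicity_truth == "rural"]) {
    sub <- bg[bg$pol_id == p, ]
    expect_gt(sum(sub$rural_population) / sum(sub$population), 0.5)
  }
})

test_that("weather is seasonal, nonnegative in precipitation, and reproducible", {
  cfg <- sim_config(n_rural = 1, n_urban_non_nyc = 0, n_nyc = 0,
                    period_start = "2017-01-01", period_end = "2020-12-31",
                    seed = 6)
  reg <- make_pol_registry(cfg)
  bg <- make_block_groups(reg, cfg)
  wx0 <- simulate_weather(bg, cfg, tmean_sd = 0)
  one <- wx0[wx0$bg_id == bg$bg_id[1], ]
  # with zero noise the sinusoid repeats exactly after 4 years = 1461 days
  shift <- match(one$day[1] + 1461, one$day)
  expect_equal(one$tmean[shift], one$tmean[1], tolerance = 1e-10)
  expect_true(all(wx0$ppt >= 0))
  expect_identical(simulate_weather(bg, cfg), simulate_weather(bg, cfg))
})

test_that("hospitalization generator enforces burn-in and baseline contracts", {
  cfg <- sim_config(n_rural = 1, n_urban_non_nyc = 1, n_nyc = 0,
                    period_start = "2019-03-01", period_end = "2019-04-30",
                    seed = 7)
  reg <- make_pol_registry(cfg)
  bg <- make_block_groups(reg, cfg)
  ser <- simulate_outage_series(reg, cfg)
  wx <- simulate_weather(bg, cfg)
  # truncating the burn-in raises the history error
  trunc <- ser[ser$interval_start >= as.POSIXct("2019-03-01 00:00:00", tz = tz), ]
  expect_error(simulate_hospitalizations(bg, trunc, wx, cfg),
               "insufficient exposure history")
  # zero baseline: no records
  cfg0 <- cfg; cfg0$baseline_admission_rate <- 0
  expect_equal(nrow(simulate_hospitalizations(bg, ser, wx, cfg0)), 0L)
  # records carry hour-resolution timestamps, pediatric ages, resolvable codes
  recs <- simulate_hospitalizations(bg, ser, wx, cfg)
  expect_true(all(as.POSIXlt(recs$admission_ts)$min == 0))
  expect_true(all(recs$age >= 0 & recs$age <= 17))
  m <- load_injury_matrix()
  spec <- recs[recs$true_category != "unspecified", ]
  for (i in seq_len(min(nrow(spec), 50))) {
    codes <- unlist(spec[i, c("dx1", "dx2", "dx3", "dx4")])
    expect_gt(length(extract_categories(codes, m)), 0)
  }
})

test_that("admission rate is flat in exposure under a null effect", {
  # aggregate many short null replicates; regress hourly counts on exposure
  slopes <- numeric(10)
  for (r in 1:10) {
    cfg <- sim_config(n_rural = 1, n_urban_non_nyc = 1, n_nyc = 0,
                      period_start = "2019-01-01", period_end = "2019-06-30",
                      true_log_or = 0, outage_onset_rate = 0.2,
                      baseline_admission_rate = 0.6, seed = 100 + r)
    sim <- simulate_study(cfg)
    hours <- seq(as.POSIXct("2019-01-01 00:00:00", tz = tz),
                 as.POSIXct("2019-06-30 23:00:00", tz = tz), by = 3600)
    counts <- table(factor(format(sim$admissions$admission_ts, "%Y-%m-%d %H"),
                           levels = format(hours, "%Y-%m-%d %H")))
    pol <- sim$block_groups$pol_id[1]
    ex <- exposure_series(sim$outages, rep(pol, length(hours)), hours,
                          cfg$window_true, cfg$threshold_true)
    slopes[r] <- coef(lm(as.vector(counts) ~ ex))[2]
  }
  # mean slope within Monte-Carlo error of zero
  expect_lt(abs(mean(slopes)) / (sd(slopes) / sqrt(length(slopes))), 4)
})
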