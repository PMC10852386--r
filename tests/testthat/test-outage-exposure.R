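test_that("QC drops small and gappy POLs with strict boundaries", {
  n <- 48 * 10  # ten days
  ok <- make_series("A", customers = 30, n_intervals = n)
  small <- make_series("B", customers = 25, n_intervals = n)
  gappy <- make_series("C", customers = 100, n_intervals = n)
  gappy <- gappy[-seq_len(ceiling(0.06 * n)), ]          # 6% missing
  edge <- make_series("D", customers = 100, n_intervals = n)
  edge <- edge[-seq_len(0.05 * n), ]                     # exactly 5% missing
  tab <- rbind(ok, small, gappy, edge)
  res <- qc_filter_pols(tab, period = range(ok$interval_start))
  kept <- unique(res$filtered$pol_id)
  expect_setequal(kept, c("A", "D"))   # 30 customers and 5.0% missing retained
  expect_equal(res$report$n_excluded_small, 1L)
  expect_equal(res$report$n_excluded_missing, 1L)
  expect_equal(res$report$n_retained, 2L)
})

test_that("a POL failing both rules is counted once in the retention arithmetic", {
  n <- 48 * 5
  a <- make_series("A", customers = 100, n_intervals = n)
  both <- make_series("B", customers = 10, n_intervals = n)
  both <- both[-seq_len(ceiling(0.2 * n)), ]
  res <- qc_filter_pols(rbind(a, both), period = range(a$interval_start))
  expect_equal(res$report$n_retained,
               res$report$n_input_pols - res$report$n_excluded)
  expect_equal(res$report$n_excluded, 1L)
})

test_that("outage indicator threshold is inclusive", {
  expect_true(outage_indicator(50, 100, 0.50))
  expect_false(outage_indicator(49, 100, 0.50))
  expect_true(outage_indicator(1, 100, 0.01))
  expect_error(outage_indicator(0, 0, 0.1), "no customers")
})

test_that("windowed exposure counts intervals and tallies gaps", {
  # 36-hour window = 72 intervals; plant 5 above threshold
  out <- rep(0L, 48 * 4)
  out[10:14] <- 60L
  s <- make_series("P", start = "2018-03-01 00:00:00", n_intervals = 48 * 4,
                   customers = 100, out = out)
  end <- as.POSIXct("2018-03-02 12:00:00", tz = tz)  # window covers slots 1-72
  ev <- cumulative_outage_hours(s, end, 36, 0.5)
  expect_equal(ev$outage_hours, 2.5)
  expect_equal(ev$n_missing_intervals, 0L)
  # all below threshold
  expect_equal(cumulative_outage_hours(s, end, 36, 0.7)$outage_hours, 0)
  # missing intervals are tallied and treated as non-outage
  s2 <- s[-(10:14), ]
  ev2 <- cumulative_outage_hours(s2, end, 36, 0.5)
  expect_equal(ev2$outage_hours, 0)
  expect_equal(ev2$n_missing_intervals, 5L)
  # window entirely outside the series errors
  expect_error(cumulative_outage_hours(s, as.POSIXct("2019-01-01", tz = tz),
                                       36, 0.5), "no exposure history")
})

test_that("windowed metric equals the brute-force recount on random series", {
  set.seed(31)
  for (r in 1:25) {
    n <- 48 * 6
    out <- ifelse(runif(n) < 0.1, sample(0:100, n, replace = TRUE), 0L)
    s <- make_series("P", start = "2018-03-01 00:00:00", n_intervals = n,
                     customers = 100, out = out)
    s <- s[runif(n) > 0.05, ]   # random gaps
    end <- as.POSIXct("2018-03-01 00:00:00", tz = tz) +
      3600 * sample(37:(6 * 24 - 1), 1)
    w <- sample(c(12, 24, 36), 1)
    th <- sample(c(0.01, 0.1, 0.2, 0.5), 1)
    ev <- cumulative_outage_hours(s, end, w, th)
    expect_equal(ev$outage_hours, naive_outage_hours(s, end, w, th))
  }
})

test_that("bulk exposure equals per-timestamp computation and flags missing POLs", {
  sim <- small_sim()
  qc <- qc_filter_pols(sim$outages)
  set.seed(32)
  pols <- sample(unique(qc$filtered$pol_id), 40, replace = TRUE)
  times <- as.POSIXct("2018-02-01 00:00:00", tz = tz) +
    3600 * sample.int(300 * 24, 40)
  bulk <- exposure_series(qc$filtered, pols, times, 36, 0.2)
  for (i in 1:40) {
    ser <- qc$filtered[qc$filtered$pol_id == pols[i], ]
    expect_equal(bulk[i], cumulative_outage_hours(ser, times[i], 36,
                                                  0.2)$outage_hours)
  }
  expect_true(is.na(exposure_series(qc$filtered, "NOPE", times[1], 36, 0.2)))
  expect_true(is.na(exposure_series(qc$filtered, NA_character_, times[1],
                                    36, 0.2)))
})

test_that("exposure is monotone in threshold and window", {
  sim <- small_sim()
  qc <- qc_filter_pols(sim$outages)
  set.seed(33)
  pols <- sample(unique(qc$filtered$pol_id), 100, replace = TRUE)
  times <- as.POSIXct("2018-03-01 00:00:00", tz = tz) +
    3600 * sample.int(250 * 24, 100)
  e <- sapply(c(0.01, 0.1, 0.2, 0.5), function(th)
    exposure_series(qc$filtered, pols, times, 36, th))
  expect_true(all(e[, 4] <= e[, 3] & e[, 3] <= e[, 2] & e[, 2] <= e[, 1]))
  w <- sapply(c(12, 24, 36), function(wh)
    exposure_series(qc$filtered, pols, times, wh, 0.1))
  expect_true(all(w[, 1] <= w[, 2] & w[, 2] <= w[, 3]))
})

test_that("block groups map to containing POLs with deterministic tie-breaks", {
  pols <- data.frame(pol_id = c("P1", "P2"), xmin = c(0, 1), xmax = c(1, 2),
                     ymin = 0, ymax = 1)
  bgs <- data.frame(bg_id = c("in1", "in2", "border", "outside"),
                    centroid_x = c(0.5, 1.5, 1.0, 5.0),
                    centroid_y = c(0.5, 0.5, 0.5, 0.5))
  expect_warning(map <- assign_blockgroup_to_pol(bgs, pols), "boundary")
  expect_equal(map$pol_id[map$bg_id == "in1"], "P1")
  expect_equal(map$pol_id[map$bg_id == "in2"], "P2")
  expect_equal(map$pol_id[map$bg_id == "border"], "P1")  # lowest pol_id
  expect_true(is.na(map$pol_id[map$bg_id == "outside"]))
  # delegation: unmapped block group yields the missing-exposure signal
  sim <- small_sim()
  qc <- qc_filter_pols(sim$outages)
  expect_null(exposure_for_timestamp("outside", Sys.time(), map,
                                     qc$filtered, 36, 0.5))
})

test_that("outage summaries reproduce ratio arithmetic and are additive", {
  # one POL per stratum, constructed to fixed customer-hour totals
  mk <- function(pol, served, out, n) {
    grid <- seq(as.POSIXct("2018-01-01 00:00:00", tz = tz), by = 1800,
                length.out = n)
    data.frame(pol_id = pol, interval_start = grid, customers_served = served,
               customers_out = out)
  }
  tab <- rbind(mk("U", 100, 40, 100),   # 2000 customer-hours
               mk("R", 50, 20, 100),    # 1000
               mk("N", 200, 0, 100))    # 0
  umap <- data.frame(pol_id = c("U", "R", "N"),
                     class = c("urban_non_nyc", "rural", "nyc"))
  s <- summarize_outages(tab, umap, thresholds = 0.1)
  st <- s$strata
  expect_equal(st$customer_hours_out[st$class == "urban_non_nyc"], 2000)
  expect_equal(st$avg_hours_per_customer[st$class == "urban_non_nyc"], 20)
  expect_equal(st$customer_hours_share_pct[st$class == "rural"], 100 / 3,
               tolerance = 1e-10)
  # additivity: stratum customer-hours sum to the statewide total exactly
  expect_equal(sum(st$customer_hours_out[st$class != "all"]),
               st$customer_hours_out[st$class == "all"])
  # empty stratum: zeros, no crash
  umap2 <- rbind(umap, data.frame(pol_id = "ZZ", class = "empty_class"))
  s2 <- summarize_outages(tab, umap2, thresholds = 0.1)
  row <- s2$strata[s2$strata$class == "empty_class", ]
  expect_equal(row$customers, 0)
  expect_equal(row$avg_hours_per_customer, 0)
})
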