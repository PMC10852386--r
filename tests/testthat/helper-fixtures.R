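# Shared fixtures and independent oracles, built in code.

tz <- OUTAGECC_TZ

# a single-POL outage series on the full 30-minute grid
make_series <- function(pol_id = "P1", start = "2018-06-01 00:00:00",
                        n_intervals = 48 * 7, customers = 100,
                        out = rep(0L, n_intervals)) {
  grid <- seq(as.POSIXct(start, tz = tz), by = 1800,
              length.out = n_intervals)
  data.frame(pol_id = pol_id, interval_start = grid,
             customers_served = customers, customers_out = out)
}

# naive per-interval recount oracle for the windowed exposure metric
naive_outage_hours <- function(series, end_time, window_hours, threshold) {
  t0 <- end_time - window_hours * 3600
  hits <- 0
  for (i in seq_len(nrow(series))) {
    s <- series$interval_start[i]
    if (s >= t0 && s < end_time &&
        series$customers_out[i] / series$customers_served[i] >= threshold)
      hits <- hits + 1
  }
  0.5 * hits
}

# naive (unguarded) conditional log-likelihood oracle
naive_clogit_loglik <- function(x, case, strata, beta) {
  x <- as.matrix(x)
  sum(vapply(split(seq_len(nrow(x)), strata), function(i) {
    num <- exp(sum(x[i[case[i]], ] * beta))
    den <- sum(exp(x[i, , drop = FALSE] %*% beta))
    log(num / den)
  }, numeric(1)))
}

# random single-covariate matched design: n strata of size m
random_design_1d <- function(n = 20, m = 4, beta = 0.5) {
  strat <- rep(seq_len(n), each = m)
  x <- stats::rnorm(n * m)
  eta <- exp(x * beta)
  case <- unlist(lapply(split(eta, strat), function(e) {
    k <- sample.int(length(e), 1, prob = e)
    seq_along(e) == k
  }), use.names = FALSE)
  list(x = matrix(x, ncol = 1), case = case, strata = strat)
}

# small simulated study reused across tests (one year, modest size)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_rural = 2, n_urban_non_nyc = 2, n_nyc = 1,
                        period_start = "2018-01-01", period_end = "2018-12-31",
                        baseline_admission_rate = 0.15, seed = 42)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})
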