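#' Synthetic study generator
#'
#' Generates POL registries, 30-minute outage series, block groups, daily
#' weather and hospitalization records with the statistical structure the
#' case-crossover analysis assumes — including a known true exposure effect —
#' so every downstream stage is testable without restricted data.
#'
#' Admissions are drawn from an hourly Poisson process whose intensity
#' multiplies a baseline with hour-of-day, day-of-week and seasonal structure
#' (so that referent matching is load-bearing) by
#' `exp(true_log_or * E(t)/scale_hours + f(tmean) + gamma * ppt)`, where
#' `E(t)` is the cumulative outage-hours at `threshold_true` over
#' `window_true` hours preceding `t` in the record's block group's POL.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Defaults describe the test-scale study: a small registry observed over
#' 2017-2020 producing roughly 2,000 admissions, with outage events frequent
#' enough that matched strata are informative about the exposure effect at
#' the severe (50%) threshold. Outage durations are log-normal and affected
#' fractions Beta-distributed, giving the right-skewed outage-hour
#' distributions seen in real feeds.
#'
#' @param n_rural,n_urban_non_nyc,n_nyc POLs per urbanicity stratum.
#' @param n_bg_per_pol block groups per POL.
#' @param period_start,period_end study period (dates, inclusive).
#' @param outage_onset_rate outage events per POL-day.
#' @param duration_meanlog,duration_sdlog log-normal outage duration (hours).
#' @param affected_shape1,affected_shape2 Beta parameters of the affected
#'   customer fraction.
#' @param affected_fixed if non-NULL, use this constant affected fraction
#'   instead of the Beta draw (degenerate distribution).
#' @param missingness_rate fraction of 30-minute intervals dropped at random.
#' @param baseline_admission_rate cases per block-group-day before modifiers.
#' @param true_log_or true log odds ratio per `scale_hours` of exposure.
#' @param scale_hours hours of exposure per odds-ratio unit.
#' @param threshold_true,window_true exposure definition used by the
#'   generating model (customer fraction; hours).
#' @param temp_coef,ppt_coef weather effects on log admission intensity:
#'   `temp_coef * (tmean - 12)^2` and `ppt_coef * ppt`.
#' @param p_unspecified probability a record carries only an unmatched
#'   ("unspecified") diagnosis code.
#' @param p_extra_other probability a specific-cause record carries an
#'   additional unspecific "other" code (exercises the most-specific rule).
#' @param p_poisoning_smoke probability a fire/burn record also carries a
#'   poisoning code (exercises the smoke-inhalation tie-break).
#' @param seed integer; fixes all randomness (sub-generators derive their
#'   streams from it deterministically).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rural = 3L, n_urban_non_nyc = 3L, n_nyc = 1L,
                       n_bg_per_pol = 2L,
                       period_start = "2017-01-01", period_end = "2020-12-31",
                       outage_onset_rate = 0.08,
                       duration_meanlog = log(4), duration_sdlog = 0.8,
                       affected_shape1 = 2, affected_shape2 = 1.2,
                       affected_fixed = NULL,
                       missingness_rate = 0.01,
                       baseline_admission_rate = 0.098,
                       true_log_or = log(1.30), scale_hours = 4,
                       threshold_true = 0.5, window_true = 36,
                       temp_coef = 0.0008, ppt_coef = 0.003,
                       p_unspecified = 0.186, p_extra_other = 0.10,
                       p_poisoning_smoke = 0.5,
                       seed = 1L) {
  cfg <- list(n_rural = n_rural, n_urban_non_nyc = n_urban_non_nyc,
              n_nyc = n_nyc, n_bg_per_pol = n_bg_per_pol,
              period_start = as.Date(period_start),
              period_end = as.Date(period_end),
              outage_onset_rate = outage_onset_rate,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              affected_shape1 = affected_shape1,
              affected_shape2 = affected_shape2,
              affected_fixed = affected_fixed,
              missingness_rate = missingness_rate,
              baseline_admission_rate = baseline_admission_rate,
              true_log_or = true_log_or, scale_hours = scale_hours,
              threshold_true = threshold_true, window_true = window_true,
              temp_coef = temp_coef, ppt_coef = ppt_coef,
              p_unspecified = p_unspecified, p_extra_other = p_extra_other,
              p_poisoning_smoke = p_poisoning_smoke,
              seed = as.integer(seed))
  if (any(c(outage_onset_rate, missingness_rate, baseline_admission_rate) < 0))
    stop("rates must be nonnegative")
  if (threshold_true <= 0 || threshold_true > 1)
    stop("threshold_true must be in (0, 1]")
  if (window_true <= 0) stop("window_true must be positive")
  if (cfg$period_end < cfg$period_start) stop("period must span >= 1 day")
  class(cfg) <- "sim_config"
  cfg
}

UPSTATE_COUNTIES <- c("Albany", "Erie", "Monroe", "Onondaga", "Suffolk",
                      "Westchester", "Dutchess", "Broome")

#' Generate a POL registry with toy rectangular geometries
#'
#' POLs are laid out as non-overlapping unit rectangles along the x axis.
#' Customer counts scale with the urbanicity stratum (rural POLs small, NYC
#' POLs large); NYC POLs carry one of the five NYC county labels.
#'
#' @param config a [sim_config()].
#' @return data.frame: `pol_id`, `customers_served`, `county`,
#'   `urbanicity_truth`, and rectangle bounds `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
make_pol_registry <- function(config) {
  n <- config$n_rural + config$n_urban_non_nyc + config$n_nyc
  if (n == 0L) stop("empty registry")
  set.seed(config$seed + 1L)
  truth <- c(rep("rural", config$n_rural),
             rep("urban_non_nyc", config$n_urban_non_nyc),
             rep("nyc", config$n_nyc))
  customers <- integer(n)
  customers[truth == "rural"] <- round(stats::runif(sum(truth == "rural"), 100, 1000))
  customers[truth == "urban_non_nyc"] <- round(stats::runif(sum(truth == "urban_non_nyc"), 2000, 8000))
  customers[truth == "nyc"] <- round(stats::runif(sum(truth == "nyc"), 20000, 60000))
  county <- character(n)
  county[truth != "nyc"] <- sample(UPSTATE_COUNTIES, sum(truth != "nyc"),
                                   replace = TRUE)
  county[truth == "nyc"] <- sample(NYC_COUNTIES, sum(truth == "nyc"),
                                   replace = TRUE)
  data.frame(pol_id = sprintf("POL%04d", seq_len(n)),
             customers_served = customers, county = county,
             urbanicity_truth = truth,
             xmin = seq_len(n) - 1, xmax = seq_len(n),
             ymin = 0, ymax = 1)
}

#' Generate block groups nested in POLs
#'
#' Each POL rectangle is divided into vertical strips, one block group per
#' strip, with the population centroid at the strip center (strictly inside
#' the host POL). Rural POLs get block groups whose rural population share
#' exceeds one half in aggregate; urban POLs get low rural shares; NYC POLs
#' none.
#'
#' @param registry from [make_pol_registry()].
#' @param config a [sim_config()].
#' @return data.frame: `bg_id`, `pol_id` (host), `county`, `population`,
#'   `rural_population`, rectangle bounds, `centroid_x`, `centroid_y`.
#' @export
make_block_groups <- function(registry, config) {
  if (nrow(registry) == 0L) stop("empty registry")
  set.seed(config$seed + 2L)
  k <- config$n_bg_per_pol
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    p <- registry[i, ]
    x0 <- p$xmin + (seq_len(k) - 1) / k
    x1 <- p$xmin + seq_len(k) / k
    pop <- round(stats::runif(k, 500, 3000))
    share <- switch(p$urbanicity_truth,
                    rural = stats::runif(k, 0.6, 0.95),
                    urban_non_nyc = stats::runif(k, 0.02, 0.3),
                    nyc = rep(0, k))
    data.frame(pol_id = p$pol_id, county = p$county,
               population = pop, rural_population = round(share * pop),
               xmin = x0, xmax = x1, ymin = p$ymin, ymax = p$ymax,
               centroid_x = (x0 + x1) / 2, centroid_y = (p$ymin + p$ymax) / 2)
  })
  out <- do.call(rbind, rows)
  out <- cbind(bg_id = sprintf("BG%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

## full 30-minute grid from (period_start - burn-in) through period_end 23:30
interval_grid <- function(config) {
  start <- as.POSIXct(paste(config$period_start, "00:00:00"),
                      tz = OUTAGECC_TZ) - config$window_true * 3600
  end <- as.POSIXct(paste(config$period_end, "23:30:00"), tz = OUTAGECC_TZ)
  seq(start, end, by = 1800)
}

#' Simulate 30-minute outage series for a registry
#'
#' Outage events per POL arrive as a Poisson process at `outage_onset_rate`
#' per POL-day; each event has a log-normal duration and a Beta-distributed
#' affected customer fraction (overlapping events take the larger fraction).
#' The series starts `window_true` hours before the study period so that
#' exposure look-backs are covered at the first admission hour, and a
#' `missingness_rate` fraction of intervals is removed at random.
#'
#' @param registry from [make_pol_registry()].
#' @param config a [sim_config()].
#' @return data.frame: `pol_id`, `interval_start` (POSIXct), `customers_served`,
#'   `customers_out`.
#' @export
simulate_outage_series <- function(registry, config) {
  if (config$outage_onset_rate < 0) stop("rates must be nonnegative")
  set.seed(config$seed + 3L)
  grid <- interval_grid(config)
  nslot <- length(grid)
  n_days <- nslot / 48
  out <- vector("list", nrow(registry))
  for (i in seq_len(nrow(registry))) {
    served <- registry$customers_served[i]
    n_ev <- stats::rpois(1L, config$outage_onset_rate * n_days)
    frac_out <- numeric(nslot)
    if (n_ev > 0L) {
      onset <- sample.int(nslot, n_ev, replace = TRUE)
      dur_slots <- pmax(1L, ceiling(2 * stats::rlnorm(n_ev,
                                                      config$duration_meanlog,
                                                      config$duration_sdlog)))
      frac <- if (is.null(config$affected_fixed))
        stats::rbeta(n_ev, config$affected_shape1, config$affected_shape2)
      else rep(config$affected_fixed, n_ev)
      for (e in seq_len(n_ev)) {
        idx <- onset[e]:min(nslot, onset[e] + dur_slots[e] - 1L)
        frac_out[idx] <- pmax(frac_out[idx], frac[e])
      }
    }
    customers_out <- pmin(served, round(frac_out * served))
    keep <- stats::runif(nslot) >= config$missingness_rate
    out[[i]] <- data.frame(pol_id = registry$pol_id[i],
                           interval_start = grid[keep],
                           customers_served = served,
                           customers_out = customers_out[keep])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate daily block-group weather on PRISM days
#'
#' Mean temperature is a seasonal sinusoid plus a block-group offset and
#' Gaussian noise; precipitation is zero on dry days and Gamma-distributed on
#' wet days (always nonnegative). Days extend a few days beyond the study
#' period so that referent look-backs are always covered.
#'
#' @param block_groups from [make_block_groups()].
#' @param config a [sim_config()].
#' @param tmean_sd set 0 for an exactly sinusoidal series.
#' @return data.frame: `bg_id`, `day` (Date, PRISM label), `tmean` (degrees
#'   C), `ppt` (mm).
#' @export
simulate_weather <- function(block_groups, config, tmean_sd = 2) {
  set.seed(config$seed + 4L)
  days <- seq(config$period_start - 3, config$period_end + 3, by = "day")
  doy <- as.numeric(days - as.Date(paste0(format(days[1], "%Y"), "-01-01")))
  nb <- nrow(block_groups)
  offset <- stats::rnorm(nb, 0, 0.5)
  rows <- lapply(seq_len(nb), function(i) {
    tmean <- 10 - 13 * cos(2 * pi * (doy - 14) / 365.25) + offset[i] +
      stats::rnorm(length(days), 0, tmean_sd)
    wet <- stats::runif(length(days)) < 0.35
    ppt <- ifelse(wet, stats::rgamma(length(days), shape = 0.7, scale = 9), 0)
    data.frame(bg_id = block_groups$bg_id[i], day = days,
               tmean = tmean, ppt = pmax(ppt, 0))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## sample one ICD-10 code (prefix + trailing digit) for a base category
sample_code <- function(base_category, matrix) {
  pats <- matrix$pattern[matrix$category == base_category]
  paste0(pats[sample.int(length(pats), 1L)], sample(0:9, 1L))
}

## codes for a resolved category, planting the tie-breaking combinations
codes_for_category <- function(category, matrix, config) {
  extra_other <- stats::runif(1) < config$p_extra_other
  codes <- switch(category,
    transport = sample_code(sample(c("motor_vehicle_traffic",
                                     "transportation_other"), 1L), matrix),
    poisoning = sample_code(sample(c("poisoning_drug", "poisoning_nondrug"), 1L),
                            matrix),
    fire_burn = {
      c(sample_code("fire_burn", matrix),
        if (stats::runif(1) < config$p_poisoning_smoke)
          sample_code(sample(c("poisoning_drug", "poisoning_nondrug"), 1L),
                      matrix))
    },
    multiple = {
      pool <- c("cut_pierce", "drowning", "fall", "environmental",
                "struck_by_against", "suffocation", "transport", "poisoning")
      two <- sample(pool, 2L)
      vapply(two, function(cc) codes_for_base_pair(cc, matrix), character(1))
    },
    other_specified = sample_code("other", matrix),
    sample_code(category, matrix))
  if (extra_other && category != "other_specified")
    codes <- c(codes, sample_code("other", matrix))
  codes
}

codes_for_base_pair <- function(cc, matrix) {
  if (cc == "transport")
    sample_code(sample(c("motor_vehicle_traffic", "transportation_other"), 1L),
                matrix)
  else if (cc == "poisoning")
    sample_code(sample(c("poisoning_drug", "poisoning_nondrug"), 1L), matrix)
  else sample_code(cc, matrix)
}

#' Simulate hospitalization records
#'
#' Draws hourly admission counts per block group from a Poisson process with
#' the intensity described in [synthetic_data], attaches ages from a
#' four-band pediatric marginal and diagnosis codes from a category-frequency
#' mixture (both bundled as editable fixtures). The code mixture deliberately
#' plants the tie-breaking combinations the resolution rules must handle:
#' specific + "other", fire/burn + poisoning, two specific categories, and
#' unspecified-only records. `true_category` records the planted truth.
#'
#' @param block_groups from [make_block_groups()].
#' @param outage_series from [simulate_outage_series()]; must cover
#'   `window_true` hours of burn-in before the period.
#' @param weather from [simulate_weather()].
#' @param config a [sim_config()].
#' @return data.frame: `record_id`, `admission_ts` (POSIXct, hour
#'   resolution), `bg_id`, `age`, `dx1`..`dx4`, `true_category`.
#' @export
simulate_hospitalizations <- function(block_groups, outage_series, weather,
                                      config) {
  period_start <- as.POSIXct(paste(config$period_start, "00:00:00"),
                             tz = OUTAGECC_TZ)
  if (min(outage_series$interval_start) > period_start - config$window_true * 3600)
    stop("insufficient exposure history")
  set.seed(config$seed + 5L)

  hours <- seq(period_start,
               as.POSIXct(paste(config$period_end, "23:00:00"),
                          tz = OUTAGECC_TZ), by = 3600)
  nh <- length(hours)
  hod <- as.POSIXlt(hours)$hour
  dow <- as.POSIXlt(hours)$wday
  mon <- as.POSIXlt(hours)$mon + 1L

  ## multiplicative baseline structure, each factor normalized to mean one
  hmult <- exp(0.4 * sin(2 * pi * (hod - 15) / 24))
  hmult <- hmult / mean(exp(0.4 * sin(2 * pi * (0:23 - 15) / 24)))
  mmult <- exp(0.25 * cos(2 * pi * (mon - 7) / 12))
  mmult <- mmult / mean(exp(0.25 * cos(2 * pi * (1:12 - 7) / 12)))
  dmult <- c(1.15, 0.95, 0.95, 0.95, 0.95, 1.0, 1.15)[dow + 1L]
  dmult <- dmult / mean(c(1.15, 0.95, 0.95, 0.95, 0.95, 1.0, 1.15))

  pday <- prism_day(hours)
  day0 <- min(weather$day)
  day_idx <- as.integer(pday - day0) + 1L
  n_days_wx <- as.integer(max(weather$day) - day0) + 1L

  pols <- unique(block_groups$pol_id)
  expo <- matrix(NA_real_, nh, length(pols), dimnames = list(NULL, pols))
  for (p in pols)
    expo[, p] <- exposure_series(outage_series, rep(p, nh), hours,
                                 config$window_true, config$threshold_true)
  if (anyNA(expo)) stop("insufficient exposure history")

  recs <- vector("list", nrow(block_groups))
  for (i in seq_len(nrow(block_groups))) {
    bg <- block_groups$bg_id[i]
    wx <- weather[weather$bg_id == bg, ]
    tm <- pp <- rep(NA_real_, n_days_wx)
    tm[as.integer(wx$day - day0) + 1L] <- wx$tmean
    pp[as.integer(wx$day - day0) + 1L] <- wx$ppt
    loglin <- config$true_log_or * expo[, block_groups$pol_id[i]] /
      config$scale_hours +
      config$temp_coef * (tm[day_idx] - 12)^2 + config$ppt_coef * pp[day_idx]
    lambda <- (config$baseline_admission_rate / 24) * hmult * mmult * dmult *
      exp(loglin)
    counts <- stats::rpois(nh, lambda)
    hit <- which(counts > 0L)
    if (length(hit) == 0L) next
    recs[[i]] <- data.frame(admission_ts = rep(hours[hit], counts[hit]),
                            bg_id = bg)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    return(data.frame(record_id = character(0),
                      admission_ts = as.POSIXct(character(0), tz = OUTAGECC_TZ),
                      bg_id = character(0), age = integer(0),
                      dx1 = character(0), dx2 = character(0),
                      dx3 = character(0), dx4 = character(0),
                      true_category = character(0)))
  }
  df <- do.call(rbind, recs)
  df <- df[order(df$admission_ts, df$bg_id), , drop = FALSE]
  n <- nrow(df)
  df$record_id <- sprintf("R%06d", seq_len(n))

  bands <- utils::read.csv(system.file("extdata", "age_band_frequencies.csv",
                                       package = "outagecc"))
  bi <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$count)
  df$age <- bands$age_min[bi] +
    floor(stats::runif(n) * (bands$age_max[bi] - bands$age_min[bi] + 1L))

  freq <- utils::read.csv(system.file("extdata", "category_frequencies.csv",
                                      package = "outagecc"))
  imatrix <- load_injury_matrix()
  cat_i <- sample.int(nrow(freq), n, replace = TRUE, prob = freq$count)
  truecat <- freq$category[cat_i]
  unspec <- stats::runif(n) < config$p_unspecified
  truecat[unspec] <- "unspecified"
  dxm <- t(vapply(seq_len(n), function(j) {
    codes <- if (unspec[j]) paste0("X59", sample(0:9, 1L))
             else codes_for_category(truecat[j], imatrix, config)
    length(codes) <- 4L
    ifelse(is.na(codes), "", codes)
  }, character(4)))
  df$dx1 <- dxm[, 1]; df$dx2 <- dxm[, 2]; df$dx3 <- dxm[, 3]; df$dx4 <- dxm[, 4]
  df$true_category <- truecat
  rownames(df) <- NULL
  df[, c("record_id", "admission_ts", "bg_id", "age",
         "dx1", "dx2", "dx3", "dx4", "true_category")]
}

#' Simulate a complete synthetic study
#'
#' Runs all generators in order under the configuration's single seed.
#'
#' @param config a [sim_config()].
#' @return list: `registry`, `block_groups`, `outages`, `weather`,
#'   `admissions`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  registry <- make_pol_registry(config)
  block_groups <- make_block_groups(registry, config)
  outages <- simulate_outage_series(registry, config)
  weather <- simulate_weather(block_groups, config)
  admissions <- simulate_hospitalizations(block_groups, outages, weather,
                                          config)
  list(registry = registry, block_groups = block_groups, outages = outages,
       weather = weather, admissions = admissions, config = config)
}
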