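#' Time-stratified case-crossover machinery
#'
#' Referent selection, weather-day alignment, spline confounder basis, and
#' assembly of matched strata for conditional logistic regression.
#'
#' All timestamps are kept in a fixed-offset local zone (default UTC-5, no
#' daylight saving) so that "hour of admission" is unambiguous year-round.
#'
#' @name case_crossover
#' @keywords internal
NULL

#' Fixed local timezone used throughout
#'
#' "Etc/GMT+5" is POSIX sign convention for UTC-5 with no daylight saving.
#' @export
OUTAGECC_TZ <- "Etc/GMT+5"

#' Referent timestamps for a case admission
#'
#' Time-stratified referent selection: every other timestamp in the same
#' calendar month and year that shares the case's day of week and hour of
#' day. Calendar months contain four or five of any weekday, so the list has
#' three or four entries and never includes the case time itself.
#'
#' @param admission_ts a `POSIXct` timestamp at hour resolution.
#' @return `POSIXct` vector of referent timestamps, in the input's timezone.
#' @examples
#' ts <- as.POSIXct("2018-07-10 14:00", tz = OUTAGECC_TZ)
#' referent_times(ts)  # the four other July 2018 Tuesdays at 14:00
#' @export
referent_times <- function(admission_ts) {
  if (length(admission_ts) != 1L) stop("one timestamp at a time")
  lt <- as.POSIXlt(admission_ts)
  dom <- lt$mday
  ## same weekday days in this month: dom mod 7 congruent, 1..month length
  first_same <- ((dom - 1L) %% 7L) + 1L
  ndays <- month_length(lt$year + 1900L, lt$mon + 1L)
  days <- seq(first_same, ndays, by = 7L)
  days <- setdiff(days, dom)
  out <- admission_ts + (days - dom) * 86400
  out
}

## days in a calendar month (vectorized)
month_length <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  base + as.integer(month == 2L & leap)
}

#' Map a timestamp to its PRISM weather day
#'
#' PRISM daily grids aggregate the 24 hours ending at noon UTC of the labelled
#' day: day `D` covers `[noon UTC of D-1, noon UTC of D)`. Hourly admission
#' and outage timestamps are aligned to that convention before joining daily
#' weather.
#'
#' @param ts `POSIXct` timestamp(s).
#' @return `Date` vector of PRISM day labels.
#' @examples
#' prism_day(as.POSIXct("2018-01-15 06:00", tz = OUTAGECC_TZ))  # 2018-01-15
#' prism_day(as.POSIXct("2018-01-15 08:00", tz = OUTAGECC_TZ))  # 2018-01-16
#' @export
prism_day <- function(ts) {
  hour_utc <- as.integer(format(ts, "%H", tz = "UTC"))
  as.Date(ts, tz = "UTC") + (hour_utc >= 12L)
}

#' Natural cubic spline basis with three knots
#'
#' Truncated-power construction of the natural cubic spline: with knots
#' \eqn{\xi_1 < \xi_2 < \xi_3} and
#' \eqn{d_k(t) = [(t-\xi_k)_+^3 - (t-\xi_3)_+^3] / (\xi_3 - \xi_k)},
#' the basis (beyond the stratum-absorbed intercept) is
#' \eqn{\{t,\; d_1(t) - d_2(t)\}}: two free columns, continuous second
#' derivative at the knots, exactly linear outside the boundary knots.
#'
#' @param values numeric vector (temperatures, degrees C).
#' @param knots three strictly increasing knot locations.
#' @return numeric matrix with columns `ns1` (linear) and `ns2` (curvature).
#' @export
natural_spline_basis <- function(values, knots) {
  if (length(knots) != 3L || any(diff(knots) <= 0))
    stop("knots must be three strictly increasing values")
  pos3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pos3(values - knots[k]) - pos3(values - knots[3])) /
    (knots[3] - knots[k])
  cbind(ns1 = values, ns2 = d(1) - d(2))
}

#' Default knot placement for the temperature spline
#'
#' 10th, 50th and 90th percentiles of the supplied (case-row) temperatures.
#' @param tmean numeric temperatures.
#' @return numeric vector of three knots.
#' @export
temperature_knots <- function(tmean) {
  k <- unname(stats::quantile(tmean, c(0.1, 0.5, 0.9), names = FALSE))
  if (any(diff(k) <= 0)) {
    ## degenerate spread: fall back to equally spaced knots over the range
    r <- range(tmean)
    if (diff(r) <= 0) r <- r + c(-1, 1)
    k <- seq(r[1], r[2], length.out = 3)
  }
  k
}

#' Build matched case-crossover strata with exposure and weather attached
#'
#' One stratum per admission record: the case row plus its three or four
#' referent rows (same hour of day, day of week, calendar month and year).
#' Exposure is the windowed cumulative outage-hour metric of the record's
#' block group's host POL evaluated at each row's timestamp; weather is the
#' block group's PRISM-day mean temperature and cumulative precipitation.
#' Strata with missing exposure (unmapped block group, QC-excluded POL, or no
#' exposure history) or missing weather at any row are dropped and tallied.
#'
#' @param records data.frame with `record_id`, `admission_ts` (POSIXct),
#'   `bg_id`.
#' @param outage_table QC-passed outage intervals (see [qc_filter_pols()]).
#' @param mapping block-group-to-POL mapping from [assign_blockgroup_to_pol()].
#' @param weather daily weather with `bg_id`, `day` (Date), `tmean`, `ppt`.
#' @param window_hours exposure look-back window (hours).
#' @param threshold outage customer-fraction threshold.
#' @return list: `strata` data.frame (`stratum_id`, `record_id`, `bg_id`,
#'   `ts`, `is_case`, `exposure_hours`, `tmean`, `ppt`), `n_dropped_exposure`,
#'   `n_dropped_weather`.
#' @export
build_strata <- function(records, outage_table, mapping, weather,
                         window_hours = 36, threshold = 0.5) {
  if (nrow(records) == 0L)
    return(list(strata = NULL, n_dropped_exposure = 0L, n_dropped_weather = 0L))
  n <- nrow(records)
  lt <- as.POSIXlt(records$admission_ts)
  dom <- lt$mday
  ndays <- month_length(lt$year + 1900L, lt$mon + 1L)
  first_same <- ((dom - 1L) %% 7L) + 1L
  cand <- outer(first_same, 7L * (0:4), `+`)      # n x 5 candidate days
  valid <- cand <= ndays & cand != dom
  ri <- which(valid)                              # column-major
  rec_i <- ((ri - 1L) %% n) + 1L
  ref_ts <- records$admission_ts[rec_i] +
    (cand[ri] - dom[rec_i]) * 86400
  df <- data.frame(stratum_id = c(seq_len(n), rec_i),
                   record_id = c(records$record_id, records$record_id[rec_i]),
                   bg_id = c(records$bg_id, records$bg_id[rec_i]),
                   ts = c(records$admission_ts, ref_ts),
                   is_case = c(rep(TRUE, n), rep(FALSE, length(rec_i))))
  df <- df[order(df$stratum_id, !df$is_case, df$ts), , drop = FALSE]

  pol <- mapping$pol_id[match(df$bg_id, mapping$bg_id)]
  df$exposure_hours <- exposure_series(outage_table, pol, df$ts,
                                       window_hours, threshold)
  day <- prism_day(df$ts)
  wi <- match(paste(df$bg_id, day), paste(weather$bg_id, weather$day))
  df$tmean <- weather$tmean[wi]
  df$ppt <- weather$ppt[wi]

  bad_exp <- unique(df$stratum_id[is.na(df$exposure_hours)])
  bad_wx <- setdiff(unique(df$stratum_id[is.na(df$tmean) | is.na(df$ppt)]),
                    bad_exp)
  keep <- !(df$stratum_id %in% c(bad_exp, bad_wx))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(strata = out,
       n_dropped_exposure = length(bad_exp),
       n_dropped_weather = length(bad_wx))
}

#' Assemble the regression design from built strata
#'
#' Covariates: exposure in hours divided by `scale_hours` (so the exposure
#' coefficient is per `scale_hours` outage-hours), the two natural-spline
#' temperature columns, and linear precipitation. Alternatively the exposure
#' can be dichotomized at `dichotomize_at` hours.
#'
#' @param strata data.frame from [build_strata()].
#' @param scale_hours hours per unit of the exposure covariate (default 4).
#' @param knots temperature knots; default from case-row temperatures.
#' @param dichotomize_at if non-NULL, replace the continuous exposure with
#'   `1(exposure_hours >= dichotomize_at)` (and ignore `scale_hours`).
#' @return list: `x` covariate matrix, `case`, `strata_id`, `knots`.
#' @export
strata_design <- function(strata, scale_hours = 4, knots = NULL,
                          dichotomize_at = NULL) {
  if (is.null(knots)) knots <- temperature_knots(strata$tmean[strata$is_case])
  ns <- natural_spline_basis(strata$tmean, knots)
  expo <- if (is.null(dichotomize_at)) strata$exposure_hours / scale_hours
          else as.numeric(strata$exposure_hours >= dichotomize_at)
  x <- cbind(exposure = expo, tmean_ns1 = ns[, 1], tmean_ns2 = ns[, 2],
             ppt = strata$ppt)
  list(x = x, case = strata$is_case, strata_id = strata$stratum_id,
       knots = knots)
}
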