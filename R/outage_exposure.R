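#' Outage exposure metrics
#'
#' Quality filtering of power-operating-locality (POL) outage feeds,
#' thresholded outage indicators, windowed cumulative outage-hour exposure,
#' block-group-to-POL linkage, and descriptive outage summaries.
#'
#' An outage feed is a data.frame of 30-minute intervals with columns
#' `pol_id`, `interval_start` (POSIXct on the half-hour grid),
#' `customers_served`, `customers_out`.
#'
#' @name outage_exposure
#' @keywords internal
NULL

## modal value of an integer vector (ties: first-seen)
modal_value <- function(v) {
  u <- unique(v)
  u[which.max(tabulate(match(v, u)))]
}

#' Quality-filter POLs by size and temporal completeness
#'
#' Drops POLs whose modal number of customers served is below `min_customers`
#' or whose fraction of missing 30-minute intervals over the study period
#' exceeds `max_missing`. Both inequalities are strict: a POL with exactly
#' `min_customers` customers, or exactly `max_missing` missingness, is
#' retained. The modal customer count is used because metered customer counts
#' drift over time in real feeds.
#'
#' @param outage_table outage intervals (see [outage_exposure]).
#' @param min_customers exclusion threshold on customers served (default 30).
#' @param max_missing exclusion threshold on the missing-interval fraction
#'   (default 0.05).
#' @param period optional `POSIXct` length-2 vector giving the study period;
#'   defaults to the range of `interval_start` in the table. The expected
#'   interval count per POL is the number of 30-minute slots in the period.
#' @return list: `filtered` (the retained rows), `report` (a `qc_report`:
#'   `n_input_pols`, `n_excluded_small`, `n_excluded_missing`, `n_retained`,
#'   and a per-POL table with modal customers and missingness fraction).
#' @export
qc_filter_pols <- function(outage_table, min_customers = 30,
                           max_missing = 0.05, period = NULL) {
  if (nrow(outage_table) == 0L) stop("empty outage table")
  if (!inherits(outage_table$interval_start, "POSIXct"))
    stop("interval_start must be POSIXct")
  if (is.null(period)) period <- range(outage_table$interval_start)
  n_expected <- floor(as.numeric(difftime(period[2], period[1],
                                          units = "secs")) / 1800) + 1
  per <- split(seq_len(nrow(outage_table)), outage_table$pol_id)
  pol_ids <- names(per)
  modal <- vapply(per, function(i) modal_value(outage_table$customers_served[i]), 0)
  n_present <- lengths(per)
  miss_frac <- 1 - n_present / n_expected
  small <- modal < min_customers
  ## strict inequality with a guard against floating-point residue so that a
  ## POL with exactly max_missing missingness is retained
  gappy <- miss_frac > max_missing + 1e-9
  drop <- small | gappy
  report <- structure(list(
    n_input_pols = length(pol_ids),
    n_excluded_small = sum(small),
    n_excluded_missing = sum(gappy),
    n_excluded = sum(drop),
    n_retained = sum(!drop),
    retention = sum(!drop) / length(pol_ids),
    per_pol = data.frame(pol_id = pol_ids, modal_customers = modal,
                         missing_fraction = miss_frac, excluded = drop,
                         row.names = NULL)
  ), class = "qc_report")
  keep_rows <- outage_table$pol_id %in% pol_ids[!drop]
  list(filtered = outage_table[keep_rows, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "POL quality control: %d input, %d excluded (%d small, %d gappy), %d retained (%.1f%%)\n",
    x$n_input_pols, x$n_excluded, x$n_excluded_small, x$n_excluded_missing,
    x$n_retained, 100 * x$retention))
  invisible(x)
}

#' Thresholded outage indicator
#'
#' TRUE when at least a fraction `threshold` of customers are without power;
#' the comparison is inclusive (>=).
#'
#' @param customers_out,customers_served nonnegative integer vectors.
#' @param threshold fraction in (0, 1].
#' @return logical vector.
#' @export
outage_indicator <- function(customers_out, customers_served, threshold) {
  if (any(customers_served == 0)) stop("no customers")
  customers_out / customers_served >= threshold
}

#' Windowed cumulative outage-hours before a timestamp
#'
#' Counts the 30-minute intervals whose start falls in the half-open window
#' `[end_time - window_hours, end_time)` and whose outage indicator exceeds
#' the threshold; each counted interval contributes half an hour. The window
#' excludes the admission hour itself ("immediately preceding"). Intervals
#' absent from the feed are treated as non-outage and tallied in
#' `n_missing_intervals`.
#'
#' @param pol_series outage intervals for a single POL.
#' @param end_time `POSIXct` end of the look-back window.
#' @param window_hours window length W in hours.
#' @param threshold outage fraction threshold.
#' @return list of class `exposure_value`: `outage_hours` (in `[0, W]`, a
#'   multiple of 0.5), `n_missing_intervals`, `window_hours`, `threshold`.
#' @export
cumulative_outage_hours <- function(pol_series, end_time, window_hours,
                                    threshold) {
  if (length(unique(pol_series$pol_id)) > 1L)
    stop("pol_series must contain a single POL")
  t0 <- end_time - window_hours * 3600
  smin <- min(pol_series$interval_start)
  smax <- max(pol_series$interval_start)
  if (end_time <= smin || t0 > smax) stop("no exposure history")
  inwin <- pol_series$interval_start >= t0 & pol_series$interval_start < end_time
  sub <- pol_series[inwin, , drop = FALSE]
  ind <- outage_indicator(sub$customers_out, sub$customers_served, threshold)
  expected <- as.integer(window_hours * 2)
  structure(list(outage_hours = 0.5 * sum(ind),
                 n_missing_intervals = expected - nrow(sub),
                 window_hours = window_hours, threshold = threshold),
            class = "exposure_value")
}

#' Vectorized windowed exposure over many (POL, timestamp) queries
#'
#' Same metric as [cumulative_outage_hours()], computed via per-POL
#' cumulative sums so that thousands of matched-set rows evaluate in one
#' pass. Returns `NA` where the POL is `NA` (unmapped block group), absent
#' from the table (QC-excluded), or has no interval overlapping the window.
#'
#' @param outage_table outage intervals for all POLs.
#' @param pol POL id per query (may contain `NA`).
#' @param times `POSIXct` end-of-window per query.
#' @param window_hours,threshold as in [cumulative_outage_hours()].
#' @return numeric vector of outage-hours, `NA` = missing exposure.
#' @export
exposure_series <- function(outage_table, pol, times, window_hours, threshold) {
  res <- rep(NA_real_, length(times))
  tnum <- as.numeric(times)
  W <- window_hours * 3600
  tab_pol <- outage_table$pol_id
  for (p in unique(pol[!is.na(pol)])) {
    sel <- which(pol == p)
    rows <- which(tab_pol == p)
    if (length(rows) == 0L) next
    s <- as.numeric(outage_table$interval_start[rows])
    g0 <- min(s)
    g1 <- max(s)
    n <- as.integer(round((g1 - g0) / 1800)) + 1L
    ind <- numeric(n)
    idx <- as.integer(round((s - g0) / 1800)) + 1L
    ind[idx] <- as.numeric(outage_table$customers_out[rows] /
                             outage_table$customers_served[rows] >= threshold)
    cs <- c(0, cumsum(ind))
    t <- tnum[sel]
    hi <- pmin(pmax(ceiling((t - g0) / 1800), 0), n)
    lo <- pmin(pmax(ceiling((t - W - g0) / 1800), 0), n)
    val <- 0.5 * (cs[hi + 1L] - cs[lo + 1L])
    val[t <= g0 | (t - W) > g1] <- NA_real_
    res[sel] <- val
  }
  res
}

#' Map block groups to the POL containing their population centroid
#'
#' Toy geometries are axis-aligned rectangles, so containment is a direct
#' coordinate comparison. A centroid on a shared boundary is assigned
#' deterministically to the lowest `pol_id` with a warning; a centroid
#' outside every POL is left unmapped (`NA`) and its records are dropped
#' downstream.
#'
#' @param block_groups data.frame with `bg_id`, `centroid_x`, `centroid_y`.
#' @param pol_geometries data.frame with `pol_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @return data.frame `bg_id`, `pol_id` (`NA` when unmapped).
#' @export
assign_blockgroup_to_pol <- function(block_groups, pol_geometries) {
  g <- pol_geometries[order(pol_geometries$pol_id), , drop = FALSE]
  ties <- character(0)
  pol <- vapply(seq_len(nrow(block_groups)), function(i) {
    x <- block_groups$centroid_x[i]
    y <- block_groups$centroid_y[i]
    hit <- which(x >= g$xmin & x <= g$xmax & y >= g$ymin & y <= g$ymax)
    if (length(hit) == 0L) return(NA_character_)
    if (length(hit) > 1L) ties <<- c(ties, block_groups$bg_id[i])
    as.character(g$pol_id[hit[1L]])
  }, character(1))
  if (length(ties) > 0L)
    warning("centroid on shared POL boundary, assigned to lowest pol_id: ",
            paste(ties, collapse = ", "))
  data.frame(bg_id = block_groups$bg_id, pol_id = pol, row.names = NULL)
}

#' Exposure for one block group and timestamp
#'
#' Delegates to [cumulative_outage_hours()] on the block group's mapped POL.
#' Returns `NULL` (missing-exposure signal) when the block group is unmapped
#' or its POL was excluded by quality control.
#'
#' @param bg_id block-group id.
#' @param timestamp `POSIXct` admission (or referent) time.
#' @param mapping output of [assign_blockgroup_to_pol()].
#' @param outage_table QC-passed outage intervals.
#' @param window_hours,threshold as in [cumulative_outage_hours()].
#' @return an `exposure_value`, or `NULL` when exposure is unavailable.
#' @export
exposure_for_timestamp <- function(bg_id, timestamp, mapping, outage_table,
                                   window_hours, threshold) {
  pol <- mapping$pol_id[match(bg_id, mapping$bg_id)]
  if (is.na(pol)) return(NULL)
  series <- outage_table[outage_table$pol_id == pol, , drop = FALSE]
  if (nrow(series) == 0L) return(NULL)
  cumulative_outage_hours(series, timestamp, window_hours, threshold)
}

#' Descriptive outage summaries by urbanicity stratum
#'
#' Per stratum: total customers (sum of per-POL modal customers served),
#' customer-hours without power (sum of customers out times half an hour),
#' their percentage shares, and average outage-hours per customer
#' (customer-hours divided by customers). Per stratum and threshold:
#' POL-hours above threshold and the median / IQR / maximum of yearly
#' outage-hours per POL. A statewide `all` row aggregates the strata; shares
#' are additive by construction.
#'
#' @param outage_table QC-passed outage intervals.
#' @param urbanicity_map data.frame `pol_id`, `class`.
#' @param thresholds numeric vector of outage fraction thresholds.
#' @return list: `strata` (one row per class plus `all`), `by_threshold`
#'   (one row per class x threshold).
#' @export
summarize_outages <- function(outage_table, urbanicity_map,
                              thresholds = c(0.1, 0.2, 0.5)) {
  cls <- urbanicity_map$class[match(outage_table$pol_id, urbanicity_map$pol_id)]
  classes <- sort(unique(urbanicity_map$class))
  per_pol <- split(seq_len(nrow(outage_table)), outage_table$pol_id)
  pol_modal <- vapply(per_pol, function(i) modal_value(outage_table$customers_served[i]), 0)
  pol_class <- urbanicity_map$class[match(names(per_pol), urbanicity_map$pol_id)]

  strata <- do.call(rbind, lapply(classes, function(cl) {
    rows <- which(cls == cl)
    customers <- sum(pol_modal[pol_class == cl], na.rm = TRUE)
    ch <- 0.5 * sum(as.numeric(outage_table$customers_out[rows]))
    data.frame(class = cl, n_pols = sum(pol_class == cl, na.rm = TRUE),
               customers = customers, customer_hours_out = ch,
               avg_hours_per_customer = if (customers > 0) ch / customers else 0)
  }))
  tot_cust <- sum(strata$customers)
  tot_ch <- sum(strata$customer_hours_out)
  strata$customers_share_pct <-
    if (tot_cust > 0) 100 * strata$customers / tot_cust else 0
  strata$customer_hours_share_pct <-
    if (tot_ch > 0) 100 * strata$customer_hours_out / tot_ch else 0
  all_row <- data.frame(class = "all", n_pols = sum(strata$n_pols),
                        customers = tot_cust, customer_hours_out = tot_ch,
                        avg_hours_per_customer =
                          if (tot_cust > 0) tot_ch / tot_cust else 0,
                        customers_share_pct = if (tot_cust > 0) 100 else 0,
                        customer_hours_share_pct = if (tot_ch > 0) 100 else 0)
  strata <- rbind(strata, all_row)

  year <- as.integer(format(outage_table$interval_start, "%Y"))
  by_threshold <- do.call(rbind, lapply(thresholds, function(th) {
    ind <- outage_table$customers_out / outage_table$customers_served >= th
    do.call(rbind, lapply(classes, function(cl) {
      rows <- which(cls == cl)
      if (length(rows) == 0L) {
        return(data.frame(class = cl, threshold = th, pol_hours_above = 0,
                          yearly_hours_median = 0, yearly_hours_q1 = 0,
                          yearly_hours_q3 = 0, yearly_hours_max = 0))
      }
      yh <- tapply(0.5 * ind[rows],
                   list(outage_table$pol_id[rows], year[rows]), sum)
      yh <- as.numeric(yh[!is.na(yh)])
      q <- stats::quantile(yh, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = cl, threshold = th,
                 pol_hours_above = 0.5 * sum(ind[rows]),
                 yearly_hours_median = q[2], yearly_hours_q1 = q[1],
                 yearly_hours_q3 = q[3], yearly_hours_max = max(yh))
    }))
  }))
  rownames(strata) <- rownames(by_threshold) <- NULL
  list(strata = strata, by_threshold = by_threshold)
}
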