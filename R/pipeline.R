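#' Full analysis pipeline
#'
#' Orchestrates quality control, urbanicity classification, injury coding,
#' matched-stratum construction and conditional-logistic fitting across the
#' analysis grid: urbanicity strata (plus pooled) by outage threshold by
#' exposure window, with optional pooled injury-subgroup models.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Analysis run configuration
#'
#' @param thresholds outage customer-fraction thresholds (the 1% entry is the
#'   small-outage sensitivity axis).
#' @param windows exposure look-back windows in hours; `primary_window` must
#'   be among them.
#' @param primary_window the main-analysis window (hours).
#' @param scale_hours report odds ratios per this many outage-hours.
#' @param exclude_years integer years to drop (e.g. `2020` for the pandemic
#'   sensitivity analysis).
#' @param stratify_by_urbanicity fit all-cause models per urbanicity class
#'   (a pooled all-cause model is always fitted).
#' @param pooled_subgroups fit per-injury-category models pooled across
#'   urbanicity.
#' @param min_informative minimum informative strata required to fit a cell;
#'   below it the cell reports "insufficient data".
#' @param dichotomize_at optional hours cutoff: replace the continuous
#'   exposure with an at-least-this-many-hours indicator.
#' @param descriptive compute the descriptive outage summary (skippable in
#'   replicated simulation studies where only the fit matters).
#' @return a `run_config` list.
#' @export
run_config <- function(thresholds = c(0.01, 0.10, 0.20, 0.50),
                       windows = c(12, 24, 36, 48), primary_window = 36,
                       scale_hours = 4, exclude_years = integer(0),
                       stratify_by_urbanicity = TRUE,
                       pooled_subgroups = FALSE, min_informative = 10L,
                       dichotomize_at = NULL, descriptive = TRUE) {
  if (any(thresholds <= 0 | thresholds > 1)) stop("thresholds must be in (0,1]")
  if (any(windows <= 0)) stop("windows must be positive")
  if (!primary_window %in% windows) stop("primary window must be in windows")
  structure(list(thresholds = thresholds, windows = windows,
                 primary_window = primary_window, scale_hours = scale_hours,
                 exclude_years = as.integer(exclude_years),
                 stratify_by_urbanicity = stratify_by_urbanicity,
                 pooled_subgroups = pooled_subgroups,
                 min_informative = as.integer(min_informative),
                 dichotomize_at = dichotomize_at,
                 descriptive = isTRUE(descriptive)),
            class = "run_config")
}

## fit one analysis cell from a strata table whose exposure column is set
fit_cell <- function(strata, rconfig) {
  if (is.null(strata) || nrow(strata) == 0L)
    return(list(status = "insufficient data", n_strata = 0L,
                n_informative = 0L))
  des <- strata_design(strata, scale_hours = rconfig$scale_hours,
                       dichotomize_at = rconfig$dichotomize_at)
  info <- sum(informative_strata(des$x[, "exposure", drop = FALSE],
                                 des$strata_id))
  if (info < rconfig$min_informative)
    return(list(status = "insufficient data",
                n_strata = length(unique(des$strata_id)),
                n_informative = info))
  fit <- tryCatch(fit_clogit(des$x, des$case, des$strata_id),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(list(status = paste("error:", conditionMessage(fit)),
                n_strata = length(unique(des$strata_id)),
                n_informative = info))
  if (fit$separation || !fit$converged)
    return(list(status = if (fit$separation) "separation" else "no convergence",
                n_strata = fit$n_strata, n_informative = info))
  or <- odds_ratio(fit, index = 1L, scale = 1)  # exposure already scaled
  list(status = "ok", fit = fit, or = or[["or"]], ci_low = or[["ci_low"]],
       ci_high = or[["ci_high"]], n_strata = fit$n_strata,
       n_informative = info)
}

#' Run the full case-crossover analysis
#'
#' @param data list with `registry`, `block_groups`, `outages`, `weather`,
#'   `admissions` (as produced by [simulate_study()] or [read_sim_tables()]).
#' @param rconfig a [run_config()].
#' @param injury_matrix_path optional path to a full injury matrix; defaults
#'   to the bundled subset.
#' @return list of class `outagecc_results`: `grid` (one row per fitted
#'   cell), `qc` report, `urbanicity`, `outage_summary`, `retention` tally,
#'   `strata_drops`, `rconfig`.
#' @export
run_pipeline <- function(data, rconfig = run_config(),
                         injury_matrix_path = NULL) {
  qc <- qc_filter_pols(data$outages)
  outages <- qc$filtered

  crosswalk <- compute_crosswalk(data$block_groups, data$registry)
  urbanicity <- classify_pols(data$registry, data$block_groups, crosswalk)
  mapping <- assign_blockgroup_to_pol(data$block_groups, data$registry)

  imatrix <- if (is.null(injury_matrix_path)) load_injury_matrix()
             else load_injury_matrix(injury_matrix_path)
  records <- resolve_records(data$admissions, imatrix)
  retained_pols <- qc$report$per_pol$pol_id[!qc$report$per_pol$excluded]
  flt <- filter_analyzable(records, mapping, retained_pols)
  records <- flt$retained

  if (length(rconfig$exclude_years) > 0L) {
    yr <- as.integer(format(records$admission_ts, "%Y"))
    records <- records[!(yr %in% rconfig$exclude_years), , drop = FALSE]
  }
  pol_of <- mapping$pol_id[match(records$bg_id, mapping$bg_id)]
  records$urbanicity <- urbanicity$class[match(pol_of, urbanicity$pol_id)]

  outage_summary <- if (rconfig$descriptive)
    summarize_outages(outages, urbanicity, thresholds = rconfig$thresholds)
  else NULL

  ## build the stratum skeleton once (referents + weather), then swap the
  ## exposure column per (threshold, window) cell
  skel <- build_strata(records, outages, mapping, data$weather,
                       window_hours = rconfig$primary_window,
                       threshold = max(rconfig$thresholds))
  strata <- skel$strata
  if (!is.null(strata)) {
    strata$urbanicity <-
      records$urbanicity[match(strata$record_id, records$record_id)]
    strata$category <-
      records$category[match(strata$record_id, records$record_id)]
    pol_row <- mapping$pol_id[match(strata$bg_id, mapping$bg_id)]
  }

  grid <- list()
  add_cell <- function(label, axis, threshold, window, cell) {
    grid[[length(grid) + 1L]] <<- data.frame(
      analysis = axis, stratum = label, threshold = threshold,
      window_hours = window, status = cell$status,
      or = if (cell$status == "ok") cell$or else NA_real_,
      ci_low = if (cell$status == "ok") cell$ci_low else NA_real_,
      ci_high = if (cell$status == "ok") cell$ci_high else NA_real_,
      n_strata = cell$n_strata, n_informative = cell$n_informative)
  }

  for (th in rconfig$thresholds) {
    for (w in rconfig$windows) {
      if (is.null(strata)) {
        sub0 <- NULL
      } else {
        sub0 <- strata
        sub0$exposure_hours <- exposure_series(outages, pol_row, strata$ts,
                                               w, th)
        bad <- unique(sub0$stratum_id[is.na(sub0$exposure_hours)])
        sub0 <- sub0[!(sub0$stratum_id %in% bad), , drop = FALSE]
      }
      add_cell("pooled", "all_cause", th, w, fit_cell(sub0, rconfig))
      if (rconfig$stratify_by_urbanicity && !is.null(sub0)) {
        for (cl in sort(unique(stats::na.omit(sub0$urbanicity)))) {
          sub <- sub0[sub0$urbanicity == cl, , drop = FALSE]
          add_cell(cl, "all_cause", th, w, fit_cell(sub, rconfig))
        }
      }
      if (rconfig$pooled_subgroups && !is.null(sub0)) {
        for (cat in sort(unique(sub0$category))) {
          sub <- sub0[sub0$category == cat, , drop = FALSE]
          add_cell(cat, "subgroup", th, w, fit_cell(sub, rconfig))
        }
      }
    }
  }
  structure(list(grid = do.call(rbind, grid), qc = qc$report,
                 urbanicity = urbanicity, outage_summary = outage_summary,
                 retention = flt$tally,
                 strata_drops = list(exposure = skel$n_dropped_exposure,
                                     weather = skel$n_dropped_weather),
                 rconfig = rconfig),
            class = "outagecc_results")
}

#' Human-readable and tabular report of pipeline results
#'
#' @param results an `outagecc_results` bundle from [run_pipeline()].
#' @return list: `table` (the OR grid), `text` (character lines).
#' @export
report_results <- function(results) {
  if (is.null(results$grid)) stop("empty results bundle")
  g <- results$grid
  lines <- c("Case-crossover analysis report", "",
             sprintf("POL QC: %d input, %d excluded small, %d excluded gappy, %d retained (%.1f%%)",
                     results$qc$n_input_pols, results$qc$n_excluded_small,
                     results$qc$n_excluded_missing, results$qc$n_retained,
                     100 * results$qc$retention),
             sprintf("Records: %d input, %d specified (%.1f%%), %d analyzable (%.1f%%)",
                     results$retention$n_input, results$retention$n_specified,
                     results$retention$pct_specified,
                     results$retention$n_complete,
                     results$retention$pct_complete),
             "",
             sprintf("Odds ratios per %g exposure-hours:", results$rconfig$scale_hours))
  ok <- g$status == "ok"
  lines <- c(lines, vapply(which(ok), function(i) {
    sprintf("  %-10s %-16s thr %.2f win %2.0fh  OR %.3f (%.3f, %.3f)  strata %d (%d informative)",
            g$analysis[i], g$stratum[i], g$threshold[i], g$window_hours[i],
            g$or[i], g$ci_low[i], g$ci_high[i], g$n_strata[i],
            g$n_informative[i])
  }, character(1)))
  if (any(!ok)) {
    lines <- c(lines, "", "Cells without estimates:")
    lines <- c(lines, vapply(which(!ok), function(i) {
      sprintf("  %-10s %-16s thr %.2f win %2.0fh  %s",
              g$analysis[i], g$stratum[i], g$threshold[i], g$window_hours[i],
              g$status[i])
    }, character(1)))
  }
  list(table = g, text = lines)
}

#' Write a results bundle to disk
#'
#' @param results an `outagecc_results` bundle.
#' @param dir output directory; writes `or_grid.csv`, `report.txt`,
#'   `fit_summary.json`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- report_results(results)
  utils::write.csv(rep$table, file.path(dir, "or_grid.csv"), row.names = FALSE)
  writeLines(rep$text, file.path(dir, "report.txt"))
  jsonlite::write_json(
    list(qc = results$qc[c("n_input_pols", "n_excluded_small",
                           "n_excluded_missing", "n_retained")],
         retention = results$retention,
         strata_drops = results$strata_drops),
    file.path(dir, "fit_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
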