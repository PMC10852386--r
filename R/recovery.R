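#' Simulation studies: parameter recovery and type-I error
#'
#' Replicates the full pipeline — generation, quality control, linkage,
#' injury coding, matched-stratum construction and conditional-logistic
#' fitting — on synthetic data with a known true exposure effect, and
#' summarizes estimate bias, confidence-interval coverage and test size.
#'
#' @name recovery
#' @keywords internal
NULL

#' One simulate-and-fit replicate
#'
#' Simulates a study under `config`, runs the pipeline at the generating
#' threshold and window only (pooled across urbanicity), and returns the
#' exposure estimate.
#'
#' @param config a [sim_config()]; its `seed` drives the replicate.
#' @param min_informative forwarded to [run_config()].
#' @return one-row data.frame: `beta` (log OR per `scale_hours`), `se`, `or`,
#'   `ci_low`, `ci_high`, `covered` (CI contains the configured truth),
#'   `p_value` (Wald, two-sided, of the null of no exposure effect),
#'   `n_strata`, `n_informative`, `status`.
#' @export
recovery_replicate <- function(config, min_informative = 10L) {
  sim <- simulate_study(config)
  rconfig <- run_config(thresholds = config$threshold_true,
                        windows = config$window_true,
                        primary_window = config$window_true,
                        scale_hours = config$scale_hours,
                        stratify_by_urbanicity = FALSE,
                        pooled_subgroups = FALSE,
                        min_informative = min_informative,
                        descriptive = FALSE)
  res <- run_pipeline(sim, rconfig)
  g <- res$grid[res$grid$stratum == "pooled", , drop = FALSE][1, ]
  if (g$status != "ok") {
    return(data.frame(beta = NA_real_, se = NA_real_, or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, covered = NA,
                      p_value = NA_real_, n_strata = g$n_strata,
                      n_informative = g$n_informative, status = g$status))
  }
  beta <- log(g$or)
  se <- (log(g$ci_high) - log(g$ci_low)) / (2 * stats::qnorm(0.975))
  true_or <- exp(config$true_log_or)
  data.frame(beta = beta, se = se, or = g$or,
             ci_low = g$ci_low, ci_high = g$ci_high,
             covered = g$ci_low <= true_or & true_or <= g$ci_high,
             p_value = 2 * stats::pnorm(-abs(beta / se)),
             n_strata = g$n_strata, n_informative = g$n_informative,
             status = "ok")
}

#' Run a replicated simulation study
#'
#' @param n_reps number of replicates.
#' @param config base [sim_config()]; replicate `r` runs with seed
#'   `config$seed + 1000 * r`.
#' @param min_informative forwarded to [recovery_replicate()].
#' @return data.frame with one [recovery_replicate()] row per replicate plus
#'   a `rep` column.
#' @export
run_recovery <- function(n_reps, config = sim_config(),
                         min_informative = 10L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 1000 * r) %% .Machine$integer.max)
    cbind(rep = r, recovery_replicate(cfg, min_informative))
  })
  do.call(rbind, rows)
}

#' Summarize a replicated study
#'
#' @param reps output of [run_recovery()].
#' @param alpha test level for the rejection rate.
#' @return list: `n_ok`, `mean_or` (mean of estimated ORs), `mean_beta`,
#'   `coverage` (fraction of CIs containing the truth), `rejection_rate`
#'   (fraction of Wald p-values below `alpha`).
#' @export
summarize_recovery <- function(reps, alpha = 0.05) {
  ok <- reps[reps$status == "ok", , drop = FALSE]
  list(n_ok = nrow(ok),
       mean_or = mean(ok$or),
       mean_beta = mean(ok$beta),
       coverage = mean(ok$covered),
       rejection_rate = mean(ok$p_value < alpha))
}
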