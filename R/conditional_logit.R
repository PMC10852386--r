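#' Conditional logistic regression for matched case-crossover sets
#'
#' Maximum-likelihood estimation for matched sets with exactly one case per
#' stratum. The conditional likelihood of stratum \eqn{s} with rows
#' \eqn{x_1, \dots, x_m} and case row \eqn{c} is
#' \deqn{L_s(\beta) = \exp(x_c^T \beta) / \sum_j \exp(x_j^T \beta),}
#' the probability that, among the matched times, the admission fell on the
#' one with the case's covariates. Strata whose rows all share identical
#' covariates (concordant strata) contribute a constant and carry no
#' information about \eqn{\beta}.
#'
#' @name conditional_logit
#' @keywords internal
NULL

## Log-likelihood, score and observed information in one vectorized pass.
## x: n x p matrix; case: logical n; strata: vector of stratum ids.
clogit_parts <- function(x, case, strata, beta) {
  eta <- drop(x %*% beta)
  sid <- as.integer(factor(strata))
  ## max-subtraction per stratum for overflow safety
  m_s <- as.vector(tapply(eta, sid, max))
  m <- m_s[sid]
  w <- exp(eta - m)
  denom_s <- rowsum(w, sid)[, 1L]
  denom <- denom_s[sid]
  p <- as.vector(w / denom)
  loglik <- sum(eta[case]) - sum(log(denom_s)) - sum(m_s)
  px <- p * x
  score <- colSums(x[case, , drop = FALSE]) - colSums(px)
  mu <- rowsum(px, sid)                      # per-stratum weighted mean of x
  hess <- -(crossprod(x, px) - crossprod(mu))
  list(loglik = loglik, score = score, hessian = hess)
}

#' Conditional log-likelihood of a single matched stratum
#'
#' @param x numeric matrix of covariates, one row per stratum member.
#' @param case logical vector marking the single case row.
#' @param beta numeric coefficient vector.
#' @return The stratum's conditional log-likelihood (always <= 0), computed
#'   with max-subtraction so large linear predictors do not overflow.
#' @examples
#' x <- matrix(c(1, 0, 0, 0, 0), ncol = 1)
#' stratum_loglik(x, c(TRUE, rep(FALSE, 4)), beta = 0)  # -log(5)
#' @export
stratum_loglik <- function(x, case, beta) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite covariates in stratum")
  if (sum(case) != 1L) stop("stratum must contain exactly one case")
  eta <- drop(x %*% beta)
  m <- max(eta)
  eta[case] - m - log(sum(exp(eta - m)))
}

#' Which strata are informative?
#'
#' A stratum is informative when at least one covariate varies within it;
#' concordant strata contribute nothing to the conditional likelihood.
#' @param x covariate matrix.
#' @param strata stratum id vector.
#' @return logical, one entry per unique stratum (in factor-level order).
#' @export
informative_strata <- function(x, strata) {
  x <- as.matrix(x)
  sid <- factor(strata)
  vapply(split(seq_len(nrow(x)), sid), function(i) {
    xi <- x[i, , drop = FALSE]
    any(apply(xi, 2L, function(col) max(col) - min(col) > 0))
  }, logical(1))
}

#' Fit a conditional logistic regression by Newton-Raphson
#'
#' Maximizes the summed conditional log-likelihood over matched sets with one
#' case each, using analytic score and observed information, step-halving to
#' enforce monotone log-likelihood ascent, and a Levenberg-style ridge on the
#' information matrix if it is numerically singular near a flat direction.
#'
#' Estimates are declared non-identified (separation) when any coefficient
#' exceeds `separation_bound` in absolute value during iteration; the fit is
#' then flagged and no estimates are returned, rather than silently reporting
#' an enormous odds ratio.
#'
#' @param x numeric matrix (or data.frame) of covariates.
#' @param case logical vector, exactly one `TRUE` per stratum.
#' @param strata stratum identifiers.
#' @param init starting coefficient vector (default all zero).
#' @param tol convergence tolerance on the maximum absolute score component.
#' @param max_iter maximum Newton iterations.
#' @param separation_bound coefficient magnitude that triggers the separation
#'   flag (on the scale of the supplied covariates).
#' @return An object of class `clogit_fit`: list with `beta`, `se`,
#'   `covariance` (inverse observed information), `loglik`, `n_strata`,
#'   `n_informative_strata`, `converged`, `separation`, `n_iter`.
#' @seealso [odds_ratio()], [brute_force_mle_1d()]
#' @export
fit_clogit <- function(x, case, strata, init = NULL, tol = 1e-8,
                       max_iter = 50L, separation_bound = 10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite covariates")
  case <- as.logical(case)
  sid <- factor(strata)
  cases_per <- tapply(case, sid, sum)
  if (any(cases_per != 1L)) stop("every stratum must contain exactly one case")

  info <- informative_strata(x, sid)
  n_informative <- sum(info)
  if (n_informative == 0L) stop("flat likelihood: no informative strata")

  ## drop concordant strata: they shift the loglik by a constant, never the
  ## score, so estimates are unchanged (reported loglik includes them)
  keep <- info[as.integer(sid)]
  sizes <- tabulate(as.integer(sid))
  const_ll <- sum(-log(sizes[!info]))
  xk <- x[keep, , drop = FALSE]
  ck <- case[keep]
  sk <- droplevels(sid[keep])

  p <- ncol(x)
  beta <- if (is.null(init)) rep(0, p) else rep_len(as.numeric(init), p)
  parts <- clogit_parts(xk, ck, sk, beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(parts$score)) < tol) { converged <- TRUE; break }
    H <- -parts$hessian
    step <- tryCatch(solve(H, parts$score), error = function(e) NULL)
    if (is.null(step)) {
      ridge <- 1e-8 * max(diag(H), 1)
      step <- solve(H + diag(ridge, p), parts$score)
    }
    ## step-halving: the conditional log-likelihood is concave, so a short
    ## enough Newton step always increases it
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      cand_parts <- clogit_parts(xk, ck, sk, cand)
      if (cand_parts$loglik >= parts$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- beta; cand_parts <- parts; break }
    }
    beta <- cand
    parts <- cand_parts
    if (any(abs(beta) > separation_bound)) { separation <- TRUE; break }
  }
  if (max(abs(parts$score)) < tol) converged <- TRUE
  if (separation) {
    return(structure(list(beta = NULL, se = NULL, covariance = NULL,
                          loglik = NA_real_, n_strata = nlevels(sid),
                          n_informative_strata = n_informative,
                          converged = FALSE, separation = TRUE, n_iter = iter),
                     class = "clogit_fit"))
  }
  covariance <- solve(-parts$hessian)
  covariance <- (covariance + t(covariance)) / 2
  structure(list(beta = drop(beta), se = sqrt(diag(covariance)),
                 covariance = covariance,
                 loglik = parts$loglik + const_ll,
                 n_strata = nlevels(sid),
                 n_informative_strata = n_informative,
                 converged = converged, separation = FALSE, n_iter = iter),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("Conditional logistic regression fit\n")
  if (isTRUE(x$separation)) {
    cat("  separation detected: no finite maximizer, no estimates reported\n")
    return(invisible(x))
  }
  est <- cbind(beta = x$beta, se = x$se, z = x$beta / x$se)
  print(round(est, 5))
  cat(sprintf("  loglik %.4f  strata %d (informative %d)  %s in %d iter\n",
              x$loglik, x$n_strata, x$n_informative_strata,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Odds ratio and Wald confidence interval from a fitted model
#'
#' @param fit a converged [fit_clogit()] result.
#' @param index coefficient index (default 1, the exposure term).
#' @param scale multiply the coefficient by this before exponentiating; with
#'   exposure in hours, `scale = 4` reports the OR per 4 outage-hours.
#' @param level confidence level.
#' @return named numeric: `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(fit, index = 1L, scale = 1, level = 0.95) {
  if (!inherits(fit, "clogit_fit")) stop("fit must be a clogit_fit")
  if (!isTRUE(fit$converged)) stop("fit did not converge; no odds ratio")
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- unname(fit$beta[index])
  se <- unname(fit$se[index])
  c(or = exp(scale * b),
    ci_low = exp(scale * (b - z * se)),
    ci_high = exp(scale * (b + z * se)))
}

#' Brute-force one-dimensional conditional MLE (testing oracle)
#'
#' Grid search over the summed conditional log-likelihood for a single
#' covariate, refined by bisection on the analytic score. Independent of the
#' Newton path in [fit_clogit()]; used to validate it.
#'
#' @param x single-column covariate matrix or vector.
#' @param case logical case indicator.
#' @param strata stratum ids.
#' @param grid numeric `c(lo, hi, step)`.
#' @return list with `beta` (the argmax), `loglik`, and `flat` (TRUE when the
#'   likelihood carries no information, i.e. all strata concordant).
#' @export
brute_force_mle_1d <- function(x, case, strata, grid = c(-5, 5, 0.01)) {
  x <- as.matrix(x)
  if (ncol(x) != 1L) stop("oracle requires a single covariate")
  if (!any(informative_strata(x, strata))) {
    return(list(beta = NA_real_, loglik = clogit_parts(x, case, strata, 0)$loglik,
                flat = TRUE))
  }
  bs <- seq(grid[1], grid[2], by = grid[3])
  ll <- vapply(bs, function(b) clogit_parts(x, case, strata, b)$loglik, 0)
  i <- which.max(ll)
  if (i == 1L || i == length(bs)) stop("widen grid: argmax at grid edge")
  ## bisection on the score within the bracketing grid cells
  lo <- bs[i - 1L]; hi <- bs[i + 1L]
  sc <- function(b) clogit_parts(x, case, strata, b)$score
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sc(mid) > 0) lo <- mid else hi <- mid
  }
  b <- (lo + hi) / 2
  list(beta = b, loglik = clogit_parts(x, case, strata, b)$loglik, flat = FALSE)
}
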