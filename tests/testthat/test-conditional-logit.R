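test_that("stratum log-likelihood has the closed-form uniform and concordant values", {
  x <- matrix(c(1, 0, 0, 0, 0), ncol = 1)
  case <- c(TRUE, rep(FALSE, 4))
  expect_equal(stratum_loglik(x, case, 0), -log(5))
  # concordant stratum: -log(m) for any beta
  xc <- matrix(rep(2.5, 4), ncol = 1)
  for (b in c(-3, 0, 1.7))
    expect_equal(stratum_loglik(xc, c(TRUE, FALSE, FALSE, FALSE), b), -log(4))
  expect_error(stratum_loglik(matrix(c(1, NA), ncol = 1), c(TRUE, FALSE), 0),
               "non-finite")
})

test_that("guarded likelihood matches the naive formula and survives huge predictors", {
  set.seed(101)
  for (r in 1:20) {
    m <- sample(3:5, 1)
    x <- matrix(rnorm(m * 2), ncol = 2)
    case <- seq_len(m) == sample.int(m, 1)
    beta <- rnorm(2)
    expect_equal(stratum_loglik(x, case, beta),
                 naive_clogit_loglik(x, case, rep(1, m), beta),
                 tolerance = 1e-12)
  }
  # max-subtraction: linear predictors around 1e4 do not overflow
  x <- matrix(c(10000, 9999, 9998), ncol = 1)
  ll <- stratum_loglik(x, c(TRUE, FALSE, FALSE), 1)
  expect_true(is.finite(ll) && ll < 0)
})

test_that("symmetric paired design yields a zero estimate", {
  # case-referent exposure differences +c and -c in equal numbers
  strat <- rep(1:10, each = 2)
  x <- matrix(0, 20, 1)
  x[seq(1, 20, 2), 1] <- rep(c(1, -1), 5)  # case rows alternate +1 / -1
  case <- rep(c(TRUE, FALSE), 10)
  fit <- fit_clogit(x, case, strat)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
})

test_that("Newton estimates agree with the brute-force 1-D oracle", {
  set.seed(202)
  for (r in 1:5) {
    d <- random_design_1d(n = 20, m = 4, beta = 0.7)
    fit <- fit_clogit(d$x, d$case, d$strata)
    oracle <- brute_force_mle_1d(d$x, d$case, d$strata)
    expect_true(fit$converged)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-4)
    # argmax property: oracle loglik beats any grid point
    for (b in seq(-2, 2, by = 0.5))
      expect_lte(naive_clogit_loglik(d$x, d$case, d$strata, b),
                 oracle$loglik + 1e-10)
  }
})

test_that("1:1 strata reduce to intercept-free paired logistic regression", {
  set.seed(303)
  n <- 60
  strat <- rep(seq_len(n), each = 2)
  x <- matrix(rnorm(2 * n), ncol = 1)
  case <- rep(c(TRUE, FALSE), n)
  fit <- fit_clogit(x, case, strat)
  d <- x[case, 1] - x[!case, 1]
  ref <- suppressWarnings(
    glm(rep(1, n) ~ d - 1, family = binomial()))
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("estimates match survival::clogit on a multi-covariate design", {
  skip_if_not_installed("survival")
  set.seed(404)
  n <- 50
  strat <- rep(seq_len(n), each = 4)
  x <- cbind(e = rnorm(4 * n), t1 = rnorm(4 * n), t2 = rnorm(4 * n),
             pp = rnorm(4 * n))
  case <- rep(c(TRUE, FALSE, FALSE, FALSE), n)
  fit <- fit_clogit(x, case, strat)
  df <- data.frame(case = case, x, strat = strat)
  ref <- survival::coxph(survival::Surv(rep(1, nrow(df)), case) ~
                           e + t1 + t2 + pp + survival::strata(strat),
                         data = df, method = "exact")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("likelihood properties: stratum-constant shifts and concordant strata are inert", {
  set.seed(505)
  d <- random_design_1d(n = 15, m = 4, beta = 0.4)
  fit <- fit_clogit(d$x, d$case, d$strata)
  # add a stratum-constant to the covariate
  shift <- rnorm(15)[d$strata]
  fit2 <- fit_clogit(d$x + shift, d$case, d$strata)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-7)
  # append concordant strata: estimates unchanged, loglik drops by log(4) each
  xc <- rbind(d$x, matrix(1, 8, 1))
  cc <- c(d$case, rep(c(TRUE, FALSE, FALSE, FALSE), 2))
  sc <- c(d$strata, rep(16:17, each = 4))
  fit3 <- fit_clogit(xc, cc, sc)
  expect_equal(fit$beta, fit3$beta, tolerance = 1e-7)
  expect_equal(fit3$loglik, fit$loglik - 2 * log(4), tolerance = 1e-8)
  expect_equal(fit3$n_strata, 17L)
  expect_equal(fit3$n_informative_strata, 15L)
  # covariance is symmetric positive definite
  ev <- eigen(fit$covariance, symmetric = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("separation is flagged instead of reporting a huge estimate", {
  # case strictly more exposed than every referent in every stratum
  strat <- rep(1:10, each = 3)
  x <- matrix(rep(c(1, 0, 0), 10), ncol = 1)
  case <- rep(c(TRUE, FALSE, FALSE), 10)
  fit <- fit_clogit(x, case, strat)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_null(fit$beta)
  expect_error(odds_ratio(fit), "converge")
})

test_that("degenerate inputs raise errors", {
  x <- matrix(rep(1, 8), ncol = 1)
  case <- rep(c(TRUE, FALSE), 4)
  strat <- rep(1:4, each = 2)
  expect_error(fit_clogit(x, case, strat), "flat likelihood")
  expect_error(fit_clogit(x, rep(TRUE, 8), strat), "exactly one case")
  d <- random_design_1d(5, 3, 0)
  expect_error(brute_force_mle_1d(cbind(d$x, d$x), d$case, d$strata),
               "single covariate")
  flat <- brute_force_mle_1d(x, case, strat)
  expect_true(flat$flat)
})

test_that("odds-ratio scaling follows the exp/log identity", {
  d <- list()
  set.seed(606)
  d <- random_design_1d(n = 40, m = 4, beta = log(1.30) / 4)
  fit <- fit_clogit(d$x, d$case, d$strata)
  or4 <- odds_ratio(fit, scale = 4)
  expect_equal(unname(or4["or"]), exp(4 * fit$beta[1]))
  expect_true(or4["ci_low"] < or4["or"] && or4["or"] < or4["ci_high"])
  # beta = 0 -> OR 1 with CI containing 1
  fit0 <- fit
  fit0$beta[1] <- 0
  or0 <- odds_ratio(fit0, scale = 4)
  expect_equal(unname(or0["or"]), 1)
  expect_true(or0["ci_low"] <= 1 && 1 <= or0["ci_high"])
})

test_that("confidence-interval width shrinks at the root-n rate", {
  set.seed(707)
  width <- function(n) {
    d <- random_design_1d(n = n, m = 4, beta = 0.3)
    fit <- fit_clogit(d$x, d$case, d$strata)
    o <- odds_ratio(fit)
    log(o[["ci_high"]]) - log(o[["ci_low"]])
  }
  w1 <- mean(replicate(30, width(50)))
  w2 <- mean(replicate(30, width(200)))
  expect_gt(w1 / w2, 1.7)   # sqrt(4) = 2 within Monte-Carlo slack
  expect_lt(w1 / w2, 2.4)
})
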