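test_that("composite log-likelihood matches hand computations", {
  # single Poisson cell: obs 3, expected 2 -> -2 + 3 ln 2 - ln 3!
  sim <- list(control_incidence = c(`1` = 2), n_base = 1, replication = 1)
  obs <- list(control_incidence = c(`1` = 3), n_base = 1)
  expect_equal(composite_loglik(sim, obs), -2 + 3 * log(2) - log(6))
  # additivity across independent blocks
  sim2 <- list(control_incidence = c(`1` = 2),
               interval_cancers = matrix(4, 1, 1), n_base = 1,
               replication = 1)
  obs_a <- list(control_incidence = c(`1` = 3), n_base = 1)
  obs_b <- list(interval_cancers = matrix(5, 1, 1), n_base = 1)
  obs_ab <- list(control_incidence = c(`1` = 3),
                 interval_cancers = matrix(5, 1, 1), n_base = 1)
  expect_equal(composite_loglik(sim2, obs_ab),
               composite_loglik(sim2, obs_a) + composite_loglik(sim2, obs_b))
  # expected zero with observed positive: sentinel for -Inf
  sim0 <- list(control_incidence = c(`1` = 0), n_base = 1, replication = 1)
  expect_equal(composite_loglik(sim0, obs), lcscreen:::LOGLIK_SENTINEL)
})

test_that("each Poisson block is maximized where expectation meets count", {
  obs <- list(control_incidence = c(`1` = 7), n_base = 1)
  ll <- vapply(seq(3, 12, by = 0.25), function(lam)
    composite_loglik(list(control_incidence = c(`1` = lam), n_base = 1,
                          replication = 1), obs), numeric(1))
  lam_grid <- seq(3, 12, by = 0.25)
  expect_equal(lam_grid[which.max(ll)], 7)
})

test_that("differential evolution solves standard benchmarks", {
  sphere <- function(x) sum(x^2)
  o <- de_optimize(sphere, rep(-5, 5), rep(5, 5),
                   control = list(generations = 200, early_stop = 200),
                   seed = 1)
  expect_lt(o$value, 1e-6)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  o2 <- de_optimize(rosen, c(-2, -2), c(2, 2),
                    control = list(NP = 40, generations = 500,
                                   early_stop = 500), seed = 2)
  expect_lt(o2$value, 1e-3)
  # best value is monotone non-increasing along the trace
  expect_true(all(diff(o$trace) <= 0))
  expect_true(all(diff(o2$trace) <= 0))
})

test_that("differential evolution is reproducible and respects bounds", {
  f <- function(x) sum((x - 0.3)^2) + sin(10 * x[1])
  a <- de_optimize(f, c(-1, -1), c(1, 1),
                   control = list(generations = 30), seed = 7)
  b <- de_optimize(f, c(-1, -1), c(1, 1),
                   control = list(generations = 30), seed = 7)
  expect_identical(a$trace, b$trace)
  expect_identical(a$par, b$par)
  expect_true(all(a$population >= -1 & a$population <= 1))
  expect_error(de_optimize(f, c(-1, -1), c(1, 1),
                           control = list(NP = 3), seed = 1),
               class = "lcscreen_config_error")
  expect_error(de_optimize(f, c(2, 2), c(1, 1)),
               class = "lcscreen_validation_error")
})

test_that("free-parameter declarations validate and patch the bundle", {
  expect_error(free_parameter("cure:IA", 0.9, 0.1),
               class = "lcscreen_validation_error")
  p <- default_params()
  p2 <- lcscreen:::apply_free(p, c("sensitivity:IA:adenocarcinoma:baseline",
                                   "cure:IB", "sojourn:IA:squamous:male:mean"),
                              c(0.5, 0.7, 2.5))
  expect_equal(sensitivity(p2$sensitivity, "IA", "adenocarcinoma", FALSE),
               0.5)
  expect_equal(unname(unclass(p2$cure)["IB"]), 0.7)
  expect_equal(lcscreen:::sojourn_lookup(p2$sojourn, "IA", "squamous",
                                         "male")$mean, 2.5)
  expect_error(lcscreen:::apply_free(p, "nonsense:IA", 1),
               class = "lcscreen_config_error")
})

test_that("zero free parameters return a single evaluation", {
  coh <- small_cohort(seed = 30)
  truth <- run_trial(coh, seed = 31)
  targets <- calibration_targets(truth)
  fit <- calibrate(coh, screening_protocol(), list(), targets, seed = 32)
  expect_length(coef(fit), 0)
  expect_true(is.finite(fit$loglik))
  expect_equal(fit$nfev, 1L)
})

test_that("profile matches the closed-form Poisson interval and scales", {
  thr <- qchisq(0.975, 1)
  toy <- function(k) {
    obj <- function(lt) -stats::dpois(k, exp(lt), log = TRUE)
    pr <- profile_loglik(obj, log(k), 1, lower = log(k) - 2,
                         upper = log(k) + 2, step = 0.005)
    # closed-form likelihood-ratio bounds
    lr <- function(lam) 2 * (stats::dpois(k, k, log = TRUE) -
                               stats::dpois(k, lam, log = TRUE)) - thr
    lo <- uniroot(lr, c(k / 4, k))$root
    hi <- uniroot(lr, c(k, 4 * k))$root
    c(got_lo = exp(pr$lower), got_hi = exp(pr$upper), lo = lo, hi = hi)
  }
  t100 <- toy(100)
  expect_lt(abs(t100["got_lo"] / t100["lo"] - 1), 0.01)
  expect_lt(abs(t100["got_hi"] / t100["hi"] - 1), 0.01)
  # 100x the counts: interval width shrinks about tenfold
  t1e4 <- toy(10000)
  w1 <- t100["got_hi"] - t100["got_lo"]
  expect_equal(unname(w1 / (t1e4["got_hi"] - t1e4["got_lo"]) * 100), 10,
               tolerance = 0.1)
  # the range always contains the point estimate
  expect_lte(t100["got_lo"], 100)
  expect_gte(t100["got_hi"], 100)
})

test_that("one-sided profiles are flagged when no crossing exists", {
  obj <- function(x) 0 # flat likelihood
  pr <- profile_loglik(obj, 0, 1, lower = -1, upper = 1, step = 0.1)
  expect_true(pr$lower_open)
  expect_true(pr$upper_open)
  expect_equal(pr$lower, -1)
  expect_equal(pr$upper, 1)
})
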