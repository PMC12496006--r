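test_that("weibull scale reproduces the target mean", {
  # exponential case: Gamma(2) = 1
  expect_equal(weibull_scale_from_mean(5, 1), 5)
  # fitted IA adenocarcinoma cell: quadrature of the Weibull mean
  sc <- weibull_scale_from_mean(3.56, 0.35)
  m <- stats::integrate(function(x) x * stats::dweibull(x, 0.35, sc), 0, Inf,
                        rel.tol = 1e-10)$value
  expect_equal(m, 3.56, tolerance = 1e-6)
  expect_error(weibull_scale_from_mean(3, 0),
               class = "lcscreen_validation_error")
  expect_error(weibull_scale_from_mean(-1, 1),
               class = "lcscreen_validation_error")
})

test_that("sojourn draws recover the configured means for every cell", {
  sp <- sojourn_params()
  tab <- sp$table
  set.seed(20)
  for (i in seq_len(nrow(tab))) {
    n <- 1e5
    x <- sample_sojourn(tab$stage[i], tab$histology[i], tab$sex[i], sp,
                        n = n)
    expect_lt(abs(mean(x) - tab$mean[i]), 3 * stats::sd(x) / sqrt(n))
  }
  # heavy tail at shape < 1: median below mean
  x <- sample_sojourn("IA", "adenocarcinoma", "male", sp, seed = 21, n = 1e5)
  expect_lt(stats::median(x), mean(x))
  expect_error(sample_sojourn("IA", "carcinoid", "male", sp),
               class = "lcscreen_config_error")
})

test_that("disease-course stage at diagnosis follows sequential Bernoulli", {
  det <- clinical_detection_probs(c(IA = 0.2, IB = 0.3, II = 0.5,
                                    IIIA = 0.5, IIIB = 0.5, IV = 1))
  n <- 1e5
  course <- simulate_disease_course(rep(50, n), "adenocarcinoma", "male",
                                    det = det, seed = 31)
  # closed-form product oracle
  p <- unclass(det)
  want <- numeric(6)
  remain <- 1
  for (k in 1:6) {
    want[k] <- remain * p[k]
    remain <- remain * (1 - p[k])
  }
  want[6] <- want[6] + remain # stage IV always diagnoses
  emp <- tabulate(course$dx_stage, 6) / n
  for (k in 1:6) expect_lt(abs(emp[k] - want[k]), 3 * mc_se(want[k], n))
  # degenerate vectors
  d1 <- clinical_detection_probs(c(IA = 1, IB = 0, II = 0, IIIA = 0,
                                   IIIB = 0, IV = 1))
  c1 <- simulate_disease_course(rep(50, 500), "squamous", "female",
                                det = d1, seed = 32)
  expect_true(all(c1$dx_stage == 1))
  expect_true(all(c1$dx_age > c1$entry_IA)) # dx at end of the IA sojourn
  d0 <- clinical_detection_probs(c(IA = 0, IB = 0, II = 0, IIIA = 0,
                                   IIIB = 0, IV = 1))
  c0 <- simulate_disease_course(rep(50, 500), "squamous", "female",
                                det = d0, seed = 33)
  expect_true(all(c0$dx_stage == 6))
  # stage IV must carry probability one
  expect_error(clinical_detection_probs(c(IA = 0, IB = 0, II = 0, IIIA = 0,
                                          IIIB = 0, IV = 0.5)),
               class = "lcscreen_validation_error")
})

test_that("stage entries are ordered and stage lookup is half-open", {
  course <- simulate_disease_course(rep(50, 1000), "adenocarcinoma", "male",
                                    seed = 34)
  ent <- as.matrix(course[paste0("entry_", c("IA", "IB", "II", "IIIA",
                                             "IIIB", "IV"))])
  expect_true(all(diff(t(ent)) >= 0))
  expect_true(all(lcscreen:::stage_at_age(course, course$entry_IA) == 1))
  expect_true(all(lcscreen:::stage_at_age(course, course$entry_IA - 1e-9)
                  == 0))
})

test_that("mixture-cure survival behaves at its extremes", {
  tab <- default_survival_table()
  tab$cure[] <- 1
  always <- sample_survival(rep(1L, 200), "adenocarcinoma", rep(60, 200),
                            survival_params(tab), seed = 1)
  expect_true(all(is.infinite(always)))
  tab$cure[] <- 0
  tab$rate[] <- 0.5
  n <- 1e5
  d <- sample_survival(rep(1L, n), "adenocarcinoma", rep(60, n),
                       survival_params(tab), seed = 2)
  expect_lt(abs(mean(d - 60) - 2), 3 * 2 / sqrt(n)) # Exp(0.5) mean 2
})

test_that("life histories compose the components consistently", {
  coh <- generate_cohort(400, 100, seed = 8)
  lh <- build_life_histories(coh, seed = 9)
  expect_identical(build_life_histories(coh, seed = 9), lh) # reproducible
  no_onset <- !is.finite(lh$onset_age)
  expect_true(all(is.na(lh$histology[no_onset])))
  expect_true(all(is.finite(lh$oc_death_age)))
  # a latent cancer (onset after other-cause death) is never observed
  latent <- is.finite(lh$onset_age) & lh$onset_age > lh$oc_death_age
  expect_true(all(lh$dx_age[latent] > lh$oc_death_age[latent]))
  # death invariant: nothing observed after min(lc, oc) death
  obs_death <- pmin(ifelse(lh$dx_age < lh$oc_death_age, lh$lc_death_age,
                           Inf), lh$oc_death_age)
  expect_true(all(obs_death <= lh$oc_death_age))
  # histology draw follows the configured per-sex distribution
  coh2 <- generate_cohort(4e4, 0, seed = 10)
  lh2 <- build_life_histories(coh2, seed = 11)
  onset <- is.finite(lh2$onset_age)
  hd <- histology_distribution()$male
  emp <- table(factor(lh2$histology[onset], names(hd))) / sum(onset)
  for (h in names(hd))
    expect_lt(abs(emp[[h]] - hd[[h]]), 3 * mc_se(hd[[h]], sum(onset)))
})
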