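test_that("sensitivity lookup honors table and parametric modes", {
  sens <- nelson_ct_sensitivity()
  expect_equal(sensitivity(sens, "IA", "adenocarcinoma", FALSE), 0.410)
  expect_equal(sensitivity(sens, "IA", "adenocarcinoma", TRUE), 0.709)
  expect_equal(sensitivity(sens, "IB", "other_nsclc", FALSE), 0.264)
  # zero repeat boost: repeat equals baseline exactly
  expect_equal(sensitivity(sens, "II", "squamous", TRUE),
               sensitivity(sens, "II", "squamous", FALSE))
  expect_error(sensitivity(sens, "IA", "carcinoid"),
               class = "lcscreen_config_error")
  base <- data.frame(stage = "IA", histology = "adenocarcinoma",
                     baseline = 0.41)
  par0 <- sensitivity_params("parametric", base = base,
                             beta_repeat = c(adenocarcinoma = 0))
  expect_identical(sensitivity(par0, "IA", "adenocarcinoma", TRUE),
                   sensitivity(par0, "IA", "adenocarcinoma", FALSE))
  # repeat sensitivity is monotone in the boost and saturates at 1
  betas <- c(0.5, 1, 2, 5, 20)
  vals <- vapply(betas, function(b)
    sensitivity(sensitivity_params("parametric", base = base,
                                   beta_repeat = c(adenocarcinoma = b)),
                "IA", "adenocarcinoma", TRUE), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[5], 1, tolerance = 1e-6)
  expect_error(sensitivity_params("parametric", base = base,
                                  beta_repeat = c(adenocarcinoma = -1)),
               class = "lcscreen_validation_error")
})

test_that("screen_person detects only prevalent preclinical cancers", {
  sens <- nelson_ct_sensitivity()
  prot <- screening_protocol()
  # no onset yet at the screen: never detected even at sensitivity 1
  lh_late <- make_prevalent_lh(100, onset_t = 4)
  expect_true(all(is.na(screen_person(lh_late, 2, prot, flat_sensitivity(1),
                                      seed = 1))))
  # already clinically diagnosed before the round: not screened
  lh_dx <- make_prevalent_lh(100, dx_t = 0.5)
  expect_true(all(is.na(screen_person(lh_dx, 2, prot, flat_sensitivity(1),
                                      seed = 1))))
  # prevalent IA adenocarcinoma at a repeat screen: detection near 70.9%
  n <- 2e4
  lh <- make_prevalent_lh(n)
  det <- screen_person(lh, 2, prot, sens, seed = 2)
  expect_lt(abs(mean(!is.na(det)) - 0.709), 3 * mc_se(0.709, n))
  expect_true(all(det[!is.na(det)] == 1L))
  # same cancer at baseline screen: 41%
  det1 <- screen_person(lh, 1, prot, sens, seed = 3)
  expect_lt(abs(mean(!is.na(det1)) - 0.410), 3 * mc_se(0.410, n))
  # sensitivity one: every prevalent cancer detected
  expect_true(all(!is.na(screen_person(lh, 2, prot, flat_sensitivity(1),
                                       seed = 4))))
})

test_that("mortality prevention cancels scheduled deaths at rate d", {
  n <- 2e4
  lh <- make_prevalent_lh(n, dx_t = 2, oc_t = 30, lc_death_age = 60 + 6)
  lh$det_stage <- 1L
  out <- apply_mortality_prevention(lh, cure = cure_probs(), seed = 5)
  expect_lt(abs(mean(out$prevented) - 0.83), 3 * mc_se(0.83, n))
  expect_true(all(out$death_age[out$prevented] == out$oc_death_age[1]))
  expect_true(all(out$death_age[!out$prevented] == 66))
  # d = 0 reproduces the counterfactual exactly
  out0 <- apply_mortality_prevention(lh, cure = cure_probs(
    c(IA = 0, IB = 0, II = 0, IIIA = 0, IIIB = 0, IV = 0)), seed = 6)
  expect_true(all(!out0$prevented))
  expect_equal(out0$death_age,
               pmin(lh$lc_death_age, lh$oc_death_age))
  # d = 1: every scheduled death among detected is prevented
  out1 <- apply_mortality_prevention(lh, cure = cure_probs(
    c(IA = 1, IB = 1, II = 1, IIIA = 1, IIIB = 1, IV = 1)), seed = 7)
  expect_true(all(out1$prevented))
  # counterfactual survivor (no scheduled LC death): never "prevented"
  lh2 <- make_prevalent_lh(100, dx_t = 50, oc_t = 30) # latent: dx after oc
  lh2$det_stage <- 1L
  o2 <- apply_mortality_prevention(lh2, cure = cure_probs(), seed = 8)
  expect_true(all(!o2$prevented))
  expect_true(all(o2$overdiagnosed))
  expect_equal(o2$death_age, lh2$oc_death_age)
})

test_that("a toy trial reproduces hand-enumerated detections", {
  stages <- c("IA", "IB", "II", "IIIA", "IIIB", "IV")
  mk <- function(id, arm, onset_t, ib_t, dx_t) {
    e <- c(60 + onset_t, 60 + ib_t, Inf, Inf, Inf, Inf)
    data.frame(id = id, sex = "male", arm = arm,
               age_at_randomization = 60, oc_death_age = 95,
               onset_age = 60 + onset_t, histology = "adenocarcinoma",
               setNames(as.data.frame(as.list(e)),
                        paste0("entry_", stages)),
               dx_age = 60 + dx_t, dx_stage = 2L, lc_death_age = Inf)
  }
  # p1: IA from t=-1, dx far out -> detected round 1 in IA
  # p2: onset t=2 (after round 2), IB from t=2.8 -> detected round 3 in IB
  # p3: onset t=1.5, clinical dx t=2.5 -> interval cancer in window (1,3]
  # p4: control arm, dx t=4 -> control incidence year 4
  lh <- rbind(mk(1, "screen", -1, 50, 60), mk(2, "screen", 2, 2.8, 50),
              mk(3, "screen", 1.5, 40, 2.5), mk(4, "control", 0.5, 30, 4))
  class(lh) <- c("lc_life_histories", "data.frame")
  coh <- lh[, c("id", "sex", "arm", "age_at_randomization")]
  attr(coh, "n_base") <- 4
  params <- default_params(sensitivity = flat_sensitivity(1))
  prot <- screening_protocol(attendance = attendance_model(c(1, 1, 1, 1)))
  res <- run_trial(coh, prot, params, seed = 1, life_histories = lh)
  expect_equal(res$screen_detected[1, 1, 1], 1L) # round 1, IA, adeno
  expect_equal(res$screen_detected[3, 2, 1], 1L) # round 3, IB, adeno
  expect_equal(sum(res$screen_detected), 2L)
  expect_equal(sum(res$interval_cancers["1-3", ]), 1L)
  expect_equal(unname(res$control_incidence["4"]), 1L)
  expect_equal(sum(res$control_incidence), 1L)
  # p1 leaves the pool after detection; p3 exits at clinical diagnosis;
  # p2 is detected at round 3: rounds screen 3, 2, 1, 0 persons
  expect_equal(unname(res$n_screens), c(3L, 2L, 1L, 0L))
})

test_that("every screen-arm cancer falls in exactly one outcome class", {
  coh <- generate_cohort(2000, 500, seed = 12)
  res <- run_trial(coh, seed = 13)
  lh <- res$life_histories
  scr <- lh$arm == "screen" & is.finite(lh$onset_age)
  fend <- res$protocol$followup_end
  t_dx <- lh$dx_age - lh$age_at_randomization
  detected <- !is.na(lh$det_round)
  clinical_fu <- !detected & lh$dx_age < lh$oc_death_age & t_dx > 0 &
    t_dx <= fend
  after_fu <- !detected & lh$dx_age < lh$oc_death_age &
    (t_dx > fend | t_dx <= 0)
  never <- !detected & lh$dx_age >= lh$oc_death_age
  expect_equal(sum(scr),
               sum(scr & detected) + sum(scr & clinical_fu) +
                 sum(scr & after_fu) + sum(scr & never))
  expect_true(all(detected[scr] + clinical_fu[scr] + after_fu[scr] +
                    never[scr] == 1))
  # overdiagnosis bookkeeping
  expect_gte(res$overdiagnosed, 0)
  expect_equal(res$overdiagnosed,
               sum(detected & lh$dx_age >= lh$oc_death_age))
})

test_that("null screening detects nothing and zero attendance screens no one", {
  coh <- generate_cohort(1500, 300, seed = 14)
  res0 <- run_trial(coh, params = default_params(
    sensitivity = flat_sensitivity(0)), seed = 15)
  expect_equal(sum(res0$screen_detected), 0L)
  expect_equal(res0$overdiagnosed, 0L)
  prot0 <- screening_protocol(attendance = attendance_model(c(0, 0, 0, 0)))
  resa <- run_trial(coh, prot0, seed = 15)
  expect_equal(unname(resa$n_screens), rep(0L, 4))
  expect_equal(sum(resa$screen_detected), 0L)
})

test_that("screening shifts detection toward earlier stages", {
  coh <- generate_cohort(12474, 2382, seed = 16)
  res <- run_trial(coh, seed = 17)
  lh <- res$life_histories
  scr_stage <- c(lh$det_stage[!is.na(lh$det_stage)],
                 lh$dx_stage[lh$arm == "screen" & is.na(lh$det_stage) &
                               lh$dx_age < lh$oc_death_age])
  ctl_stage <- lh$dx_stage[lh$arm == "control" &
                             lh$dx_age < lh$oc_death_age]
  expect_gt(mean(scr_stage <= 2), mean(ctl_stage <= 2))
})

test_that("zero cure probabilities leave arm mortality equal in expectation", {
  coh <- generate_cohort(12474, 2382, seed = 18)
  params <- default_params(cure = cure_probs(
    c(IA = 0, IB = 0, II = 0, IIIA = 0, IIIB = 0, IV = 0)))
  res <- run_trial(coh, params = params, seed = 19)
  d <- res$lc_deaths
  n <- res$n_arm
  p <- suppressWarnings(stats::chisq.test(
    matrix(c(d["screen"], n["screen"] - d["screen"],
             d["control"], n["control"] - d["control"]), 2)))$p.value
  expect_gt(p, 0.01)
  # and per-person death ages equal the no-screening counterfactual
  lh <- res$life_histories
  cf <- ifelse(lh$dx_age < lh$oc_death_age & is.finite(lh$lc_death_age) &
                 lh$lc_death_age < lh$oc_death_age,
               pmin(lh$lc_death_age, lh$oc_death_age), lh$oc_death_age)
  expect_equal(lh$death_age, cf)
})

test_that("person-years after detection match a per-person brute force", {
  coh <- generate_cohort(6000, 1500, seed = 20)
  res <- run_trial(coh, seed = 21)
  lh <- res$life_histories
  fend <- res$protocol$followup_end
  det <- which(!is.na(lh$det_round))
  py <- setNames(numeric(6), c("IA", "IB", "II", "IIIA", "IIIB", "IV"))
  for (i in det) {
    t_det <- lh$det_age[i] - lh$age_at_randomization[i]
    t_end <- min(lh$death_age[i] - lh$age_at_randomization[i], fend)
    py[lh$det_stage[i]] <- py[lh$det_stage[i]] + max(0, t_end - t_det)
  }
  expect_equal(res$py_after_detection, py, tolerance = 1e-10)
})

test_that("all-screen average equals the detected/detectable ratio", {
  # deterministic ratio arithmetic: (41+71+71+71)/(4x100) = 63.5%
  res <- list(screen_detected = array(0, c(4, 6, 4)),
              detectable = array(0, c(4, 6, 4)))
  res$screen_detected[, 1, 1] <- c(41, 71, 71, 71)
  res$detectable[, 1, 1] <- 100
  expect_equal(all_screen_average_sensitivity(res)[1, 1], 63.5)
  # equal baseline and repeat s: average is s for any pool sizes
  res$screen_detected[, 2, 2] <- c(30, 60, 15, 3) * 0.5
  res$detectable[, 2, 2] <- c(30, 60, 15, 3)
  expect_equal(all_screen_average_sensitivity(res)[2, 2], 50)
  # empty pool reported as absent
  expect_true(is.na(all_screen_average_sensitivity(res)[3, 3]))
})
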