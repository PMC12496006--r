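#' Stage-specific mortality-prevention (cure) probabilities
#'
#' Probability that a lung-cancer death scheduled in the no-screening
#' counterfactual is prevented when the cancer is screen-detected in the
#' given stage. The default stage IA/IB value of 0.83 is the fitted estimate
#' for the NELSON protocol; values for later stages are synthetic stand-ins
#' declining with stage.
#'
#' @param probs Named vector over stages IA..IV, each in `[0, 1]`.
#' @return Named numeric vector of class `cure_probs`.
#' @export
cure_probs <- function(probs = c(IA = 0.83, IB = 0.83, II = 0.60,
                                 IIIA = 0.35, IIIB = 0.15, IV = 0.05)) {
  if (!identical(names(probs), STAGES))
    stop_validation("probs must be named IA, IB, II, IIIA, IIIB, IV")
  check_prob(probs, "cure probabilities")
  structure(probs, class = "cure_probs")
}

#' Four-round CT screening protocol
#'
#' @param round_times Years from randomization of the four screens (default
#'   0, 1, 3, 5.5: baseline then 1-, 2- and 2.5-year intervals).
#' @param attendance An [attendance_model()].
#' @param followup_end Years of follow-up after randomization.
#' @return A list of class `screening_protocol`.
#' @export
screening_protocol <- function(round_times = c(0, 1, 3, 5.5),
                               attendance = attendance_model(),
                               followup_end = 10) {
  if (length(round_times) != 4L || any(diff(round_times) <= 0))
    stop_validation("round_times must be 4 strictly increasing times")
  if (followup_end <= round_times[4L])
    stop_validation("followup_end must exceed the last round")
  structure(list(round_times = round_times, attendance = attendance,
                 followup_end = followup_end),
            class = "screening_protocol")
}

#' Screen life histories at one round
#'
#' Applies one CT round to (vectorized) life histories: a person contributes
#' a screen only if attending, alive, and not yet clinically diagnosed; a
#' detection requires a preclinical cancer (onset at or before the screen,
#' clinical diagnosis after it) and a Bernoulli success at the CT sensitivity
#' of the stage occupied at the screen instant.
#'
#' @param lh An `lc_life_histories` data frame.
#' @param round_index Round number 1..4.
#' @param protocol A [screening_protocol()].
#' @param sens A [sensitivity_params()].
#' @param attendance Logical attendance matrix from [sample_attendance()]
#'   (defaults to full attendance).
#' @param is_repeat Logical vector: whether this is a repeat screen for each
#'   person (after their first attended screen). Default: repeat for every
#'   round after the first.
#' @param seed Integer seed.
#' @return Integer vector: detected stage index (1 = IA .. 6 = IV) or `NA`
#'   when no detection occurred.
#' @export
screen_person <- function(lh, round_index, protocol = screening_protocol(),
                          sens = nelson_ct_sensitivity(), attendance = NULL,
                          is_repeat = round_index > 1L, seed = NULL) {
  n <- nrow(lh)
  t_r <- protocol$round_times[round_index]
  age_r <- lh$age_at_randomization + t_r
  attending <- if (is.null(attendance)) rep(TRUE, n)
               else attendance[, round_index]
  alive <- age_r < pmin(lh$oc_death_age,
                        ifelse(lh$dx_age < lh$oc_death_age,
                               lh$lc_death_age, Inf))
  undiagnosed <- age_r < lh$dx_age
  detectable <- attending & alive & undiagnosed &
    lh$onset_age <= age_r
  stage_idx <- stage_at_age(lh, age_r)
  out <- rep(NA_integer_, n)
  with_seed(seed, {
    u <- runif(n) # fixed draw count irrespective of detectability
    i <- which(detectable)
    if (length(i)) {
      p <- sensitivity(sens, stage_idx[i], lh$histology[i],
                       rep_len(is_repeat, n)[i])
      hit <- u[i] < p
      out[i[hit]] <- as.integer(stage_idx[i][hit])
    }
    out
  })
}

#' Apply the mortality-prevention mechanism to screen-detected cancers
#'
#' For each screen-detected cancer with a lung-cancer death scheduled in the
#' no-screening counterfactual (clinical diagnosis and LC death both before
#' the other-cause death), the death is cancelled with the stage-specific
#' cure probability, in which case the person dies of other causes at the
#' scheduled other-cause age. Unsuccessful prevention leaves the life history
#' exactly as without screening. Detections whose counterfactual had no LC
#' diagnosis before death (overdiagnosis) or no LC death are bookkept but
#' unchanged.
#'
#' @param lh An `lc_life_histories` data frame with columns `det_stage` (and
#'   the natural-history columns).
#' @param detected_stage Integer stage indices of the screen detections
#'   (`NA` = not screen-detected); defaults to `lh$det_stage`.
#' @param cure A [cure_probs()].
#' @param seed Integer seed.
#' @return `lh` with logical columns `prevented` and `overdiagnosed` and a
#'   `death_age` column holding the realized death age.
#' @export
apply_mortality_prevention <- function(lh, detected_stage = lh$det_stage,
                                       cure = cure_probs(), seed = NULL) {
  n <- nrow(lh)
  scheduled <- is.finite(lh$lc_death_age) &
    lh$dx_age < lh$oc_death_age & lh$lc_death_age < lh$oc_death_age
  detected <- !is.na(detected_stage)
  with_seed(seed, {
    u <- runif(n)
    d <- rep(0, n)
    d[detected] <- unclass(cure)[detected_stage[detected]]
    prevented <- detected & scheduled & (u < d)
    overdx <- detected & lh$dx_age >= lh$oc_death_age
    lh$prevented <- prevented
    lh$overdiagnosed <- overdx
    lh$death_age <- ifelse(scheduled & !prevented,
                           pmin(lh$lc_death_age, lh$oc_death_age),
                           lh$oc_death_age)
    lh
  })
}

#' Run a complete screening trial
#'
#' Simulates the full trial: life histories for both arms, four CT rounds in
#' time order for the screen arm (a cancer detected at one round leaves the
#' screening pool), the mortality-prevention draw at detection, interval and
#' control-arm clinical incidence, and mortality follow-up after screen
#' detection. All random streams are pre-committed from the seed with fixed
#' draw counts, so the result is a smooth quasi-deterministic function of
#' the model parameters given the seed (common random numbers for
#' calibration).
#'
#' @param cohort An `lc_cohort` with both arms.
#' @param protocol A [screening_protocol()].
#' @param params A [default_params()] bundle.
#' @param seed Integer seed.
#' @param life_histories Optional pre-built `lc_life_histories` (bypasses
#'   natural-history simulation; used for common-random-number calibration
#'   of screening-layer parameters).
#' @return A list of class `lc_trial_result`: `screen_detected` and
#'   `detectable` (round x stage x histology counts), `n_screens` and
#'   `n_negative` per round, `interval_cancers` (window x stage),
#'   `control_incidence` and `screened_arm_clinical` (counts per year since
#'   randomization), `py_after_detection` / `lc_deaths_after_detection` (by
#'   stage at detection), `lc_deaths` per arm within follow-up,
#'   `overdiagnosed`, `n_base`, `replication`, and the augmented
#'   `life_histories`.
#' @export
run_trial <- function(cohort, protocol = screening_protocol(),
                      params = default_params(), seed = NULL,
                      life_histories = NULL) {
  if (!all(c("screen", "control") %in% cohort$arm) && nrow(cohort) > 1L)
    warning("cohort does not contain both arms")
  lh <- if (is.null(life_histories))
    build_life_histories(cohort, params, seed = sub_seed(seed, 101L))
  else life_histories
  n <- nrow(lh)
  att <- sample_attendance(cohort, protocol$attendance,
                           seed = sub_seed(seed, 102L))
  screen_u <- with_seed(sub_seed(seed, 103L), matrix(runif(n * 4L), n, 4L))
  cure_u <- with_seed(sub_seed(seed, 104L), runif(n))

  fend <- protocol$followup_end
  in_screen <- lh$arm == "screen"
  # counterfactual (no-screening) observed events
  cf_dx <- lh$dx_age < lh$oc_death_age            # clinically diagnosed
  cf_lc_death <- cf_dx & is.finite(lh$lc_death_age) &
    lh$lc_death_age < lh$oc_death_age
  t_dx <- lh$dx_age - lh$age_at_randomization

  det_round <- rep(NA_integer_, n)
  det_stage <- rep(NA_integer_, n)
  det_age <- rep(NA_real_, n)
  screened_before <- rep(FALSE, n)
  dims <- c(4L, 6L, 4L)
  dn <- list(round = paste0("round", 1:4), stage = STAGES,
             histology = HISTOLOGIES)
  screen_detected <- array(0L, dims, dn)
  detectable_ct <- array(0L, dims, dn)
  n_screens <- n_negative <- integer(4L)

  hist_idx <- match(lh$histology, HISTOLOGIES)
  for (r in 1:4) {
    t_r <- protocol$round_times[r]
    age_r <- lh$age_at_randomization + t_r
    alive <- age_r < pmin(lh$oc_death_age,
                          ifelse(cf_dx, lh$lc_death_age, Inf))
    screened <- in_screen & att[, r] & alive & age_r < lh$dx_age &
      is.na(det_round)
    n_screens[r] <- sum(screened)
    stage_idx <- stage_at_age(lh, age_r)
    pool <- screened & lh$onset_age <= age_r
    ip <- which(pool)
    if (length(ip)) {
      p <- sensitivity(params$sensitivity, stage_idx[ip],
                       lh$histology[ip], screened_before[ip])
      hit <- screen_u[ip, r] < p
      ih <- ip[hit]
      det_round[ih] <- r
      det_stage[ih] <- as.integer(stage_idx[ih])
      det_age[ih] <- age_r[ih]
      tab_pool <- table(factor(stage_idx[ip], 1:6),
                        factor(hist_idx[ip], 1:4))
      detectable_ct[r, , ] <- detectable_ct[r, , ] + unclass(tab_pool)
      if (length(ih)) {
        tab_det <- table(factor(stage_idx[ih], 1:6),
                         factor(hist_idx[ih], 1:4))
        screen_detected[r, , ] <- screen_detected[r, , ] + unclass(tab_det)
      }
    }
    n_negative[r] <- n_screens[r] -
      sum(det_round == r, na.rm = TRUE)
    screened_before <- screened_before | screened
  }

  lh$det_round <- det_round
  lh$det_stage <- det_stage
  lh$det_age <- det_age
  # prevention draw with the pre-committed uniforms (fixed stream)
  scheduled <- is.finite(lh$lc_death_age) & cf_dx &
    lh$lc_death_age < lh$oc_death_age
  detected <- !is.na(det_stage)
  d <- rep(0, n)
  d[detected] <- unclass(params$cure)[det_stage[detected]]
  lh$prevented <- detected & scheduled & (cure_u < d)
  lh$overdiagnosed <- detected & !cf_dx
  lh$death_age <- ifelse(scheduled & !lh$prevented,
                         pmin(lh$lc_death_age, lh$oc_death_age),
                         lh$oc_death_age)

  t_death <- lh$death_age - lh$age_at_randomization
  lc_death_obs <- scheduled & !lh$prevented

  years <- seq_len(ceiling(fend))
  year_of <- function(t) pmin(ceiling(pmax(t, 1e-9)), max(years))
  count_by_year <- function(sel, t) {
    tabulate(year_of(t[sel]), nbins = max(years))
  }
  in_fu <- function(t) t > 0 & t <= fend

  ctrl <- !in_screen
  ctrl_inc <- count_by_year(ctrl & cf_dx & in_fu(t_dx), t_dx)
  # screen-arm clinical diagnoses: scheduled dx observed only if the person
  # was not screen-detected first and the dx precedes death
  scr_clin <- in_screen & cf_dx & in_fu(t_dx) &
    (is.na(det_age) | det_age > lh$dx_age)
  scr_inc <- count_by_year(scr_clin, t_dx)

  # half-open trial-time windows between consecutive rounds / follow-up end
  wnd_breaks <- c(0, protocol$round_times[-1L], fend)
  wnd_labels <- sprintf("%g-%g", head2(wnd_breaks), wnd_breaks[-1L])
  iv_sel <- which(scr_clin)
  iv_wnd <- findInterval(t_dx[iv_sel], wnd_breaks, left.open = FALSE,
                         rightmost.closed = TRUE)
  iv_wnd <- pmin(pmax(iv_wnd, 1L), length(wnd_labels))
  interval_cancers <- matrix(0L, length(wnd_labels), 6L,
                             dimnames = list(window = wnd_labels,
                                             stage = STAGES))
  if (length(iv_sel)) {
    tb <- table(factor(iv_wnd, seq_along(wnd_labels)),
                factor(lh$dx_stage[iv_sel], 1:6))
    interval_cancers <- interval_cancers + unclass(tb)
  }

  det_i <- which(detected)
  py <- deaths <- setNames(numeric(6L), STAGES)
  if (length(det_i)) {
    t_det <- det_age[det_i] - lh$age_at_randomization[det_i]
    t_end <- pmin(t_death[det_i], fend)
    py_i <- pmax(0, t_end - t_det)
    died <- lc_death_obs[det_i] & t_death[det_i] <= fend
    for (k in 1:6) {
      sk <- det_stage[det_i] == k
      py[k] <- sum(py_i[sk])
      deaths[k] <- sum(died[sk])
    }
  }

  res <- list(
    screen_detected = screen_detected,
    detectable = detectable_ct,
    n_screens = setNames(n_screens, dn$round),
    n_negative = setNames(n_negative, dn$round),
    interval_cancers = interval_cancers,
    control_incidence = setNames(ctrl_inc, years),
    screened_arm_clinical = setNames(scr_inc, years),
    py_after_detection = py,
    lc_deaths_after_detection = deaths,
    lc_deaths = c(
      screen = sum(lc_death_obs & in_screen & in_fu(t_death)),
      control = sum(lc_death_obs & ctrl & in_fu(t_death))),
    overdiagnosed = sum(lh$overdiagnosed),
    n_arm = c(screen = sum(in_screen), control = sum(ctrl)),
    n_base = attr(cohort, "n_base") %||% nrow(cohort),
    replication = attr(cohort, "replication") %||% 1L,
    protocol = protocol,
    attendance = att,
    life_histories = lh)
  class(res) <- "lc_trial_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
head2 <- function(x) x[-length(x)]

#' @export
print.lc_trial_result <- function(x, ...) {
  cat("Screening trial simulation\n")
  cat(sprintf("  persons: %d screen / %d control (replication %d)\n",
              x$n_arm["screen"], x$n_arm["control"], x$replication))
  cat(sprintf("  screens: %s\n", paste(x$n_screens, collapse = ", ")))
  cat(sprintf("  screen-detected cancers: %d (overdiagnosed %d)\n",
              sum(x$screen_detected), x$overdiagnosed))
  cat(sprintf("  interval/clinical cancers in screen arm: %d\n",
              sum(x$interval_cancers)))
  cat(sprintf("  control-arm cancers in follow-up: %d\n",
              sum(x$control_incidence)))
  cat(sprintf("  LC deaths in follow-up: %d screen / %d control\n",
              x$lc_deaths["screen"], x$lc_deaths["control"]))
  invisible(x)
}

#' All-screen average sensitivity
#'
#' The detected-to-detectable ratio across all four rounds per (stage,
#' histology): the total number of screen-detected cancers divided by the
#' total detectable pool (persons screened with a preclinical cancer of that
#' stage at the screen instant, counted at every round at which they are
#' screened). Lies between the baseline and repeat sensitivities whenever
#' both contribute.
#'
#' @param result An `lc_trial_result` from [run_trial()].
#' @return Matrix (stage x histology) of percentages; `NA` where the
#'   detectable pool is empty.
#' @export
all_screen_average_sensitivity <- function(result) {
  det <- apply(result$screen_detected, c(2, 3), sum)
  pool <- apply(result$detectable, c(2, 3), sum)
  out <- 100 * det / pool
  out[pool == 0] <- NA_real_
  out
}
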