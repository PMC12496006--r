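#' Histology distribution of incident lung cancers
#'
#' Per-sex probabilities over the four modelled histologies. Defaults are
#' synthetic stand-ins resembling western-European case mixes, with a higher
#' adenocarcinoma share among women.
#'
#' @param male,female Named probability vectors over
#'   `adenocarcinoma, squamous, other_nsclc, sclc`, each summing to 1.
#' @return A list of class `histology_distribution`.
#' @export
histology_distribution <- function(
    male = c(adenocarcinoma = 0.42, squamous = 0.24, other_nsclc = 0.15,
             sclc = 0.19),
    female = c(adenocarcinoma = 0.55, squamous = 0.12, other_nsclc = 0.14,
               sclc = 0.19)) {
  for (p in list(male, female)) {
    if (!identical(sort(names(p)), sort(HISTOLOGIES)))
      stop_validation("histology probabilities must cover exactly: ",
                      paste(HISTOLOGIES, collapse = ", "))
    check_prob(p, "histology probabilities")
    if (abs(sum(p) - 1) > 1e-9)
      stop_validation("histology probabilities must sum to 1")
  }
  structure(list(male = male[HISTOLOGIES], female = female[HISTOLOGIES]),
            class = "histology_distribution")
}

#' Stage-specific clinical (symptomatic) detection probabilities
#'
#' Probability that a cancer is diagnosed symptomatically at the end of each
#' stage's sojourn rather than progressing undetected; stage IV always ends
#' in clinical diagnosis. Defaults are synthetic stand-ins rising with stage.
#'
#' @param probs Named vector over stages IA..IV with `IV = 1`.
#' @return A named numeric vector of class `clinical_detection_probs`.
#' @export
clinical_detection_probs <- function(
    probs = c(IA = 0.10, IB = 0.25, II = 0.45, IIIA = 0.65, IIIB = 0.85,
              IV = 1)) {
  if (!identical(names(probs), STAGES))
    stop_validation("probs must be named IA, IB, II, IIIA, IIIB, IV")
  check_prob(probs, "clinical detection probabilities")
  if (probs[["IV"]] != 1)
    stop_validation("stage IV clinical detection probability must be 1")
  structure(probs, class = "clinical_detection_probs")
}

#' Post-diagnosis survival parameters
#'
#' Mixture-cure exponential survival after clinical diagnosis: with the
#' stage/histology cure fraction no lung-cancer death is scheduled; otherwise
#' the time from diagnosis to lung-cancer death is exponential with the given
#' event rate. Defaults are synthetic stand-ins with survival worsening by
#' stage and poorer outcomes for small-cell cancers.
#'
#' @param table Data frame with columns `stage`, `histology`, `cure`
#'   (fraction in `[0,1]`) and `rate` (/year, > 0).
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(table = default_survival_table()) {
  need <- c("stage", "histology", "cure", "rate")
  if (!all(need %in% names(table)))
    stop_config("survival table needs columns ", paste(need, collapse = ", "))
  check_prob(table$cure, "cure fraction")
  if (any(table$rate <= 0)) stop_validation("event rate must be > 0")
  table$key <- paste(table$stage, table$histology, sep = "|")
  structure(list(table = table), class = "survival_params")
}

#' @rdname survival_params
#' @export
default_survival_table <- function() {
  cure <- c(IA = 0.55, IB = 0.45, II = 0.35, IIIA = 0.18, IIIB = 0.08,
            IV = 0.02)
  rate <- c(IA = 0.25, IB = 0.30, II = 0.40, IIIA = 0.55, IIIB = 0.70,
            IV = 1.20)
  rows <- expand.grid(stage = STAGES, histology = HISTOLOGIES,
                      stringsAsFactors = FALSE)
  sc <- rows$histology == "sclc"
  data.frame(rows,
             cure = unname(cure[rows$stage]) * ifelse(sc, 0.5, 1),
             rate = unname(rate[rows$stage]) * ifelse(sc, 1.5, 1))
}

#' Simulate the preclinical disease course
#'
#' From onset the cancer enters stage IA and progresses IA -> IB -> II ->
#' IIIA -> IIIB -> IV, spending a Weibull sojourn time in each stage. At the
#' end of each stage's sojourn a Bernoulli draw with the stage's clinical
#' detection probability decides between symptomatic diagnosis (at that age,
#' in that stage) and progression; stage IV always ends in diagnosis. Very
#' short sojourn draws effectively skip stages.
#'
#' All arguments are vectorized over persons; the number of random draws per
#' person is fixed (6 sojourns + 6 detection deviates) regardless of outcome,
#' so parameter changes never shift the random stream.
#'
#' @param onset_age Ages at stage IA entry (`Inf` = no cancer).
#' @param histology,sex Character vectors (recycled).
#' @param sojourns A [sojourn_params()].
#' @param det A [clinical_detection_probs()].
#' @param seed Integer seed.
#' @return Data frame with stage entry ages `entry_IA` .. `entry_IV`, the
#'   clinical diagnosis age `dx_age` and stage index `dx_stage` (1 = IA .. 6
#'   = IV).
#' @export
simulate_disease_course <- function(onset_age, histology, sex,
                                    sojourns = sojourn_params(),
                                    det = clinical_detection_probs(),
                                    seed = NULL) {
  n <- length(onset_age)
  histology <- rep_len(histology, n)
  sex <- rep_len(sex, n)
  with_seed(seed, {
    soj <- matrix(0, n, 6L)
    u <- matrix(runif(n * 6L), n, 6L)
    for (k in 1:6) {
      ms <- sojourn_lookup(sojourns, STAGES[k], histology, sex)
      scale <- weibull_scale_from_mean(ms$mean, ms$shape)
      soj[, k] <- rweibull(n, shape = ms$shape, scale = scale)
    }
    entries <- matrix(onset_age, n, 6L)
    for (k in 2:6) entries[, k] <- entries[, k - 1L] + soj[, k - 1L]
    detected <- sweep(u, 2L, unclass(det)[STAGES], `<`)
    detected[, 6L] <- TRUE
    dx_stage <- max.col(detected, ties.method = "first")
    dx_age <- entries[cbind(seq_len(n), dx_stage)] +
      soj[cbind(seq_len(n), dx_stage)]
    out <- as.data.frame(entries)
    names(out) <- paste0("entry_", STAGES)
    out$dx_age <- dx_age
    out$dx_stage <- dx_stage
    out
  })
}

# stage index occupied at (absolute) age `at`; 0 before onset, entries are
# half-open [entry_k, entry_{k+1}); only valid while at < dx_age
stage_at_age <- function(course, at) {
  entries <- as.matrix(course[paste0("entry_", STAGES)])
  rowSums(entries <= at)
}

#' Sample post-diagnosis lung-cancer death ages
#'
#' With probability equal to the cure fraction no lung-cancer death is
#' scheduled (`Inf`); otherwise the death age is the diagnosis age plus an
#' exponential survival draw. The observed cause of death downstream is the
#' earlier of the lung-cancer and other-cause death ages.
#'
#' @param stage Stage indices (1..6) or labels at diagnosis.
#' @param histology Histology labels.
#' @param age_at_dx Ages at clinical diagnosis.
#' @param surv A [survival_params()].
#' @param oc_death_age Other-cause death ages (carried through, not used in
#'   the draw).
#' @param seed Integer seed.
#' @return Lung-cancer death ages (`Inf` when cured).
#' @export
sample_survival <- function(stage, histology, age_at_dx,
                            surv = survival_params(), oc_death_age = NULL,
                            seed = NULL) {
  n <- length(age_at_dx)
  if (is.numeric(stage)) stage <- STAGES[stage]
  key <- paste(stage, rep_len(histology, n), sep = "|")
  i <- match(key, surv$table$key)
  if (anyNA(i)) stop_config("survival parameters missing for: ",
                            paste(unique(key[is.na(i)]), collapse = ", "))
  cure <- surv$table$cure[i]
  rate <- surv$table$rate[i]
  with_seed(seed, {
    cured <- runif(n) < cure
    delay <- rexp(n, rate = rate)
    ifelse(cured, Inf, age_at_dx + delay)
  })
}

#' Simulate complete life histories
#'
#' Composes the natural-history components for every person in a cohort:
#' other-cause death from the smoking-adjusted life table, TSCE lung-cancer
#' onset, a histology draw, the staged preclinical disease course, and
#' mixture-cure survival from clinical diagnosis. Each component draws from
#' an independently sub-seeded stream, so the whole pipeline is reproducible
#' from one seed.
#'
#' @param cohort An `lc_cohort`.
#' @param params A [default_params()] bundle.
#' @param seed Integer seed.
#' @return A data frame of class `lc_life_histories`, one row per person:
#'   cohort columns plus `oc_death_age`, `onset_age` (`Inf` = never),
#'   `histology` (`NA` without onset), stage entry ages, `dx_age`/`dx_stage`
#'   (the *scheduled* clinical diagnosis, which is observed only if it
#'   precedes death), and `lc_death_age` (`Inf` = cured). The observed death
#'   age is `pmin(lc_death_age, oc_death_age)` with events after it ignored.
#' @examples
#' coh <- generate_cohort(n_male = 50, n_female = 10, seed = 1)
#' lh <- build_life_histories(coh, seed = 2)
#' mean(is.finite(lh$onset_age))
#' @export
build_life_histories <- function(cohort, params = default_params(),
                                 seed = NULL) {
  n <- nrow(cohort)
  oc <- sample_other_cause_death(cohort, params$life_tables,
                                 seed = sub_seed(seed, 1L))
  onset <- sample_onset_age(cohort, params$tsce, seed = sub_seed(seed, 2L))
  hist <- with_seed(sub_seed(seed, 3L), {
    u <- runif(n)
    out <- character(n)
    for (s in SEXES) {
      i <- cohort$sex == s
      out[i] <- HISTOLOGIES[1L + findInterval(u[i],
                  cumsum(params$histology[[s]]), left.open = TRUE)]
    }
    out
  })
  course <- simulate_disease_course(onset, hist, cohort$sex,
                                    params$sojourn,
                                    params$clinical_detection,
                                    seed = sub_seed(seed, 4L))
  lc_death <- sample_survival(course$dx_stage, hist, course$dx_age,
                              params$survival, oc,
                              seed = sub_seed(seed, 5L))
  hist[!is.finite(onset)] <- NA_character_
  lh <- data.frame(cohort, oc_death_age = oc, onset_age = onset,
                   histology = hist, course, lc_death_age = lc_death)
  attr(lh, "replication") <- attr(cohort, "replication")
  attr(lh, "n_base") <- attr(cohort, "n_base")
  class(lh) <- c("lc_life_histories", "data.frame")
  lh
}

#' @rdname build_life_histories
#' @param i Row index of the person to simulate.
#' @export
build_life_history <- function(cohort, i, params = default_params(),
                               seed = NULL) {
  build_life_histories(cohort[i, , drop = FALSE], params, seed)
}
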