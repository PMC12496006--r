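#' Cohort generator configuration
#'
#' Distribution settings for the synthetic high-risk cohort. Defaults describe
#' a plausible screening-eligible population: ages 50-74 centred near 58,
#' smoking initiation in adolescence, moderate-to-heavy intensities, and a
#' 55:45 current:former smoker split with quit times within the last 10 years
#' (so that eligibility remains satisfiable).
#'
#' @param age_mean,age_sd Mean/SD of age at randomization (years), truncated
#'   to `age_range`.
#' @param age_range Allowed age-at-randomization interval.
#' @param start_age_mean,start_age_sd Mean/SD of (integer) smoking start age,
#'   truncated to `start_age_range`.
#' @param start_age_range Allowed start-age interval.
#' @param cpd_values,cpd_weights Support and weights of the cigarettes/day
#'   mixture.
#' @param current_prob Probability of being a current (vs former) smoker.
#' @param quit_years_max Former smokers quit `Uniform(0, quit_years_max)`
#'   years before randomization.
#' @param trial_start_year Calendar year of randomization (fixes birth year).
#' @param max_rejections Per-person cap on eligibility rejection sampling;
#'   exceeding it signals an infeasible configuration.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(age_mean = 58, age_sd = 5.5, age_range = c(50, 74),
                          start_age_mean = 17, start_age_sd = 3,
                          start_age_range = c(10, 30),
                          cpd_values = c(10, 15, 20, 25, 30),
                          cpd_weights = c(0.05, 0.20, 0.35, 0.25, 0.15),
                          current_prob = 0.55, quit_years_max = 10,
                          trial_start_year = 2003, max_rejections = 1000) {
  if (length(cpd_values) != length(cpd_weights) || any(cpd_weights < 0) ||
      sum(cpd_weights) <= 0)
    stop_config("cpd_values/cpd_weights mismatch or degenerate weights")
  check_prob(current_prob, "current_prob")
  if (quit_years_max > 10)
    stop_config("quit_years_max > 10 would generate ineligible former smokers")
  structure(as.list(environment()), class = "cohort_config")
}

# vectorized truncated-normal draw by rejection
rtnorm <- function(n, mean, sd, lo, hi) {
  if (hi <= lo) return(rep(lo, n)) # degenerate interval
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# vectorized eligibility for generator rows (single-segment histories)
row_eligible <- function(age, start_age, quit_years, cpd) {
  dur <- pmax(0, (age - quit_years) - start_age)
  expo <- (cpd > 15 & dur > 25) | (cpd > 10 & dur > 30)
  expo & quit_years < 10 & (age - quit_years) >= start_age
}

#' Generate a synthetic screening-trial cohort
#'
#' Draws a cohort of high-risk current and recent-former smokers, every one of
#' whom satisfies [eligibility_check()] (enforced by per-person rejection
#' sampling). Each person carries a single-segment smoking history from their
#' start age to their quit age (or ongoing). Persons are assigned 1:1 to the
#' screen and control arms by deterministic alternation on id, which removes
#' arm-imbalance noise from arm contrasts; the whole cohort can be replicated
#' to reduce Monte-Carlo noise in trial-level aggregates.
#'
#' @param n_male,n_female Number of distinct male/female persons (defaults are
#'   the Dutch NELSON participant counts).
#' @param replication Positive integer; each person is copied this many times
#'   (fresh ids, same covariates are *not* reused -- replicates are drawn
#'   independently from the same distributions).
#' @param seed Integer seed; identical seed and config give an identical
#'   cohort.
#' @param config A [cohort_config()].
#' @return A data frame of class `lc_cohort` with columns `id`, `sex`,
#'   `birth_year`, `age_at_randomization`, `start_age`, `quit_age` (`NA` for
#'   current smokers), `cpd`, `arm`, and attributes `replication` and
#'   `n_base`.
#' @examples
#' coh <- generate_cohort(n_male = 40, n_female = 10, seed = 1)
#' table(coh$sex, coh$arm)
#' @export
generate_cohort <- function(n_male = 12474, n_female = 2382, replication = 1,
                            seed = NULL, config = cohort_config()) {
  stopifnot(n_male >= 0, n_female >= 0, replication >= 1)
  n <- (n_male + n_female) * replication
  cfg <- config
  if (max(cfg$cpd_values[cfg$cpd_weights > 0]) <= 10)
    stop_config("no cpd value in the mixture can satisfy eligibility")
  with_seed(seed, {
    sex <- rep(c("male", "female"), c(n_male * replication,
                                      n_female * replication))
    if (n == 0L) {
      coh <- data.frame(id = integer(), sex = character(),
                        birth_year = numeric(),
                        age_at_randomization = numeric(),
                        start_age = numeric(), quit_age = numeric(),
                        cpd = numeric(), arm = character())
    } else {
      age <- rtnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                    cfg$age_range[2])
      draw <- function(k) {
        start <- pmin(pmax(round(stats::rnorm(k, cfg$start_age_mean,
                                              cfg$start_age_sd)),
                           cfg$start_age_range[1]), cfg$start_age_range[2])
        cpd <- sample(cfg$cpd_values, k, replace = TRUE,
                      prob = cfg$cpd_weights)
        current <- runif(k) < cfg$current_prob
        quit_years <- ifelse(current, 0, runif(k, 0, cfg$quit_years_max))
        list(start = start, cpd = cpd, current = current,
             quit_years = quit_years)
      }
      d <- draw(n)
      bad <- which(!row_eligible(age, d$start, d$quit_years, d$cpd))
      tries <- 0L
      while (length(bad)) {
        tries <- tries + 1L
        if (tries > cfg$max_rejections)
          stop_config("eligibility rejection cap reached; ",
                      "distribution settings appear infeasible")
        r <- draw(length(bad))
        for (f in names(r)) d[[f]][bad] <- r[[f]]
        bad <- bad[!row_eligible(age[bad], d$start[bad], d$quit_years[bad],
                                 d$cpd[bad])]
      }
      coh <- data.frame(
        id = seq_len(n), sex = sex,
        birth_year = round(cfg$trial_start_year - age),
        age_at_randomization = age,
        start_age = d$start,
        quit_age = ifelse(d$current, NA_real_, age - d$quit_years),
        cpd = d$cpd,
        arm = ifelse(seq_len(n) %% 2L == 1L, "screen", "control"))
    }
    attr(coh, "replication") <- replication
    attr(coh, "n_base") <- n_male + n_female
    class(coh) <- c("lc_cohort", "data.frame")
    coh
  })
}

#' Smoking history of one cohort row
#'
#' @param cohort An `lc_cohort`.
#' @param i Row index.
#' @return A [smoking_history()].
#' @export
cohort_smoking <- function(cohort, i) {
  r <- cohort[i, ]
  end <- if (is.na(r$quit_age)) 110 else r$quit_age
  smoking_history(r$start_age,
                  data.frame(age_from = r$start_age, age_to = end,
                             cpd = r$cpd),
                  quit_age = r$quit_age)
}

#' Write / read a cohort CSV
#'
#' The on-disk format stores smoking as a semicolon-delimited list of
#' `from:to:cpd` triples in the `cpd_segments` column, so multi-segment
#' histories round-trip even though the generator emits single segments.
#'
#' @param cohort An `lc_cohort`.
#' @param path File path.
#' @return `read_cohort` returns the `lc_cohort`; `write_cohort` its path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  end <- ifelse(is.na(cohort$quit_age), 110, cohort$quit_age)
  out <- data.frame(id = cohort$id, sex = cohort$sex,
                    birth_year = cohort$birth_year,
                    age_at_randomization = cohort$age_at_randomization,
                    start_age = cohort$start_age, quit_age = cohort$quit_age,
                    cpd_segments = sprintf("%g:%g:%g", cohort$start_age, end,
                                           cohort$cpd),
                    arm = cohort$arm)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  first <- vapply(strsplit(x$cpd_segments, ";", fixed = TRUE), `[`,
                  character(1), 1L)
  parts <- do.call(rbind, strsplit(first, ":", fixed = TRUE))
  x$cpd <- as.numeric(parts[, 3L])
  x$cpd_segments <- NULL
  attr(x, "replication") <- 1L
  attr(x, "n_base") <- nrow(x)
  class(x) <- c("lc_cohort", "data.frame")
  x
}

#' Screening attendance model
#'
#' Round-specific attendance probabilities, optionally shifted on the logit
#' scale by sex and by age (per decade above 60). Defaults are the published
#' adherence rates of the four CT rounds: 96.1, 94.5, 91.9 and 70.5 percent.
#'
#' @param round_rates Four probabilities in `[0, 1]`.
#' @param sex_logit Named logit offsets per sex (default none).
#' @param age_logit_per_decade Logit offset per decade of age above 60
#'   (default 0).
#' @return A list of class `attendance_model`.
#' @export
attendance_model <- function(round_rates = c(0.961, 0.945, 0.919, 0.705),
                             sex_logit = c(male = 0, female = 0),
                             age_logit_per_decade = 0) {
  if (length(round_rates) != 4L)
    stop_validation("round_rates must have length 4")
  check_prob(round_rates, "round_rates")
  structure(list(round_rates = round_rates, sex_logit = sex_logit,
                 age_logit_per_decade = age_logit_per_decade),
            class = "attendance_model")
}

#' Sample per-person, per-round attendance
#'
#' @param cohort An `lc_cohort` (or any data frame with `sex` and
#'   `age_at_randomization` columns).
#' @param model An [attendance_model()].
#' @param seed Integer seed.
#' @return Logical matrix, one row per person, one column per round; the
#'   marginal attended fraction per round converges to the configured rates.
#' @export
sample_attendance <- function(cohort, model = attendance_model(),
                              seed = NULL) {
  n <- nrow(cohort)
  with_seed(seed, {
    off <- model$sex_logit[cohort$sex] +
      model$age_logit_per_decade * (cohort$age_at_randomization - 60) / 10
    off[is.na(off)] <- 0
    out <- matrix(FALSE, n, 4L)
    for (r in 1:4) {
      p <- model$round_rates[r]
      pr <- if (all(off == 0)) rep(p, n)
            else if (p %in% c(0, 1)) rep(p, n) else expit(logit(p) + off)
      out[, r] <- runif(n) < pr
    }
    colnames(out) <- paste0("round", 1:4)
    out
  })
}
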