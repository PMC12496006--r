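#' Baseline other-cause mortality life table
#'
#' Annual other-cause death probabilities by single year of age, generated
#' from a Gompertz-Makeham hazard \eqn{h(a) = A + B e^{Ca}} as a configurable
#' stand-in for national statistics rates. The table closes at `max_age`
#' where the death probability is forced to 1. A person-level smoking
#' multiplier \eqn{\exp(\gamma \cdot \mathrm{packyears} / 40)} scales the
#' annual probabilities (on the hazard-like scale, capped at 1); the default
#' \eqn{\gamma = \log 2} doubles other-cause mortality at 40 pack-years.
#'
#' @param sex `"male"` or `"female"` (label only; defaults differ by sex).
#' @param makeham Age-independent hazard component A (per year).
#' @param gompertz_b,gompertz_c Gompertz coefficients B and C.
#' @param gamma Log-linear smoking effect per 40 pack-years.
#' @param max_age Closing age of the table.
#' @return A list of class `life_table` with fields `sex`, `ages` (0..max),
#'   `q` (annual death probabilities, q[max] = 1) and `gamma`.
#' @export
life_table <- function(sex = c("male", "female"), makeham = 2e-4,
                       gompertz_b = if (match.arg(sex) == "male") 3.3e-5
                                    else 1.9e-5,
                       gompertz_c = 0.094, gamma = log(2), max_age = 110) {
  sex <- match.arg(sex)
  ages <- 0:max_age
  h <- makeham + gompertz_b * exp(gompertz_c * ages)
  q <- 1 - exp(-h)
  q[length(q)] <- 1
  check_prob(q, "life-table q")
  structure(list(sex = sex, ages = ages, q = q, gamma = gamma),
            class = "life_table")
}

#' Smoking multiplier on other-cause mortality
#'
#' @param table A [life_table()].
#' @param packyears Pack-years smoked.
#' @return Positive hazard multipliers.
#' @export
smoking_multiplier <- function(table, packyears) {
  exp(table$gamma * packyears / 40)
}

#' Sample ages at death from other causes
#'
#' Vectorized sequential sampling from the multiplier-adjusted annual death
#' probabilities, conditional on being alive at the age at randomization.
#' Death is placed uniformly within the death year; the returned age always
#' exceeds the age at randomization.
#'
#' @param cohort An `lc_cohort` (needs `age_at_randomization`; pack-years are
#'   derived from `start_age`, `quit_age`, `cpd` unless `multiplier` is
#'   given).
#' @param table A [life_table()], or a named list of tables per sex.
#' @param seed Integer seed.
#' @param multiplier Optional explicit per-person hazard multipliers
#'   (overrides the smoking adjustment).
#' @return Numeric vector of death ages (years).
#' @export
sample_other_cause_death <- function(cohort, table, seed = NULL,
                                     multiplier = NULL) {
  n <- nrow(cohort)
  tabs <- if (inherits(table, "life_table")) {
    list(male = table, female = table)
  } else {
    if (!all(SEXES %in% names(table)))
      stop_validation("need a life table per sex")
    table
  }
  for (tb in tabs) {
    if (length(tb$q) != length(tb$ages) || any(is.na(tb$q)))
      stop_validation("life table has missing ages")
    if (tb$q[length(tb$q)] != 1)
      stop_validation("life table must close with q = 1 at the cap")
  }
  if (is.null(multiplier)) {
    a <- cohort$age_at_randomization
    upper <- pmin(a, ifelse(is.na(cohort$quit_age), a, cohort$quit_age))
    py <- pmax(0, upper - cohort$start_age) * cohort$cpd / 20
    multiplier <- smoking_multiplier(tabs$male, py)
  }
  stopifnot(all(multiplier > 0), length(multiplier) == n)
  max_age <- max(tabs$male$ages)
  with_seed(seed, {
    a0 <- floor(cohort$age_at_randomization)
    death_year <- rep(NA_integer_, n)
    alive <- rep(TRUE, n)
    qmat <- cbind(male = tabs$male$q, female = tabs$female$q)
    sexcol <- ifelse(cohort$sex == "female", 2L, 1L)
    for (age in 0:max_age) {
      at_risk <- alive & a0 <= age
      if (!any(at_risk)) next
      p <- pmin(1, qmat[age + 1L, sexcol] * multiplier)
      dies <- at_risk & (runif(n) < p)
      death_year[dies] <- age
      alive[dies] <- FALSE
    }
    out <- death_year + runif(n)
    pmax(out, cohort$age_at_randomization + 1e-9)
  })
}
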