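#' Construct a smoking history
#'
#' A smoking history is a piecewise-constant cigarettes-per-day (CPD) exposure
#' over a lifetime: contiguous, non-overlapping age segments each with a
#' positive smoking intensity, plus an optional quit age after which exposure
#' is zero. It drives both the carcinogenesis dose-response
#' ([tsce_hazard()]) and the smoking adjustment of other-cause mortality.
#'
#' @param start_age Age (years) smoking began; must equal the start of the
#'   first segment.
#' @param segments Data frame with columns `age_from`, `age_to`, `cpd`:
#'   contiguous half-open age intervals `[age_from, age_to)` and the
#'   cigarettes/day smoked in each.
#' @param quit_age Age smoking stopped, or `NA` for a current smoker. When
#'   present it must equal the end of the last segment and be at least
#'   `start_age`.
#' @return An object of class `smoking_history`.
#' @examples
#' sh <- smoking_history(17, data.frame(age_from = 17, age_to = 60, cpd = 20))
#' pack_years(sh, 60)
#' @export
smoking_history <- function(start_age, segments, quit_age = NA_real_) {
  if (!is.data.frame(segments) ||
      !all(c("age_from", "age_to", "cpd") %in% names(segments)))
    stop_validation("segments must have columns age_from, age_to, cpd")
  segments <- segments[order(segments$age_from), , drop = FALSE]
  if (nrow(segments) == 0L)
    stop_validation("at least one smoking segment is required")
  if (any(segments$cpd <= 0))
    stop_validation("cpd must be > 0 within segments")
  if (any(segments$age_to <= segments$age_from))
    stop_validation("segments must have age_to > age_from")
  if (nrow(segments) > 1L) {
    gaps <- segments$age_from[-1L] - segments$age_to[-nrow(segments)]
    if (any(abs(gaps) > 1e-9))
      stop_validation("segments must be contiguous and non-overlapping")
  }
  if (abs(segments$age_from[1L] - start_age) > 1e-9)
    stop_validation("start_age must match the first segment")
  if (!is.na(quit_age)) {
    if (quit_age < start_age)
      stop_validation("quit_age must be >= start_age")
    if (abs(segments$age_to[nrow(segments)] - quit_age) > 1e-9)
      stop_validation("quit_age must match the end of the last segment")
  }
  structure(list(start_age = start_age, segments = segments,
                 quit_age = quit_age),
            class = "smoking_history")
}

#' @export
print.smoking_history <- function(x, ...) {
  status <- if (is.na(x$quit_age)) "current smoker"
            else sprintf("quit at age %.3g", x$quit_age)
  cat(sprintf("Smoking history: started age %.3g, %s\n", x$start_age, status))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Cigarettes per day at a given age
#'
#' @param smoking A [smoking_history()].
#' @param age Age(s) in years.
#' @return Numeric vector of CPD (0 outside smoking segments or after
#'   quitting).
#' @export
cpd_at <- function(smoking, age) {
  seg <- smoking$segments
  out <- numeric(length(age))
  for (i in seq_len(nrow(seg))) {
    inside <- age >= seg$age_from[i] & age < seg$age_to[i]
    out[inside] <- seg$cpd[i]
  }
  if (!is.na(smoking$quit_age)) out[age >= smoking$quit_age] <- 0
  out
}

#' Cumulative pack-years smoked by a given age
#'
#' One pack-year is 20 cigarettes/day for one year.
#'
#' @inheritParams cpd_at
#' @return Pack-years accumulated up to `age`.
#' @export
pack_years <- function(smoking, age) {
  seg <- smoking$segments
  vapply(age, function(a) {
    dur <- pmax(0, pmin(seg$age_to, a) - seg$age_from)
    sum(dur * seg$cpd) / 20
  }, numeric(1))
}

#' Trial smoking-eligibility rule
#'
#' High-risk eligibility as used for trial entry: a minimum exposure of
#' either more than 15 CPD smoked for more than 25 years, or more than 10 CPD
#' for more than 30 years; and the person must be a current smoker or have
#' quit less than 10 years before `age`.
#'
#' @param smoking A [smoking_history()].
#' @param age Age at assessment (years); must be at least the start age.
#' @return `TRUE` if eligible.
#' @examples
#' sh <- smoking_history(30, data.frame(age_from = 30, age_to = 60, cpd = 20))
#' eligibility_check(sh, 60)   # 30 years at 20 CPD, current smoker
#' @export
eligibility_check <- function(smoking, age) {
  if (!inherits(smoking, "smoking_history"))
    stop_validation("smoking must be a smoking_history")
  if (age < smoking$start_age)
    stop_validation("age must be >= start_age")
  seg <- smoking$segments
  upper <- if (is.na(smoking$quit_age)) age else min(age, smoking$quit_age)
  dur <- pmax(0, pmin(seg$age_to, upper) - seg$age_from)
  yrs_gt15 <- sum(dur[seg$cpd > 15])
  yrs_gt10 <- sum(dur[seg$cpd > 10])
  exposure_ok <- (yrs_gt15 > 25) || (yrs_gt10 > 30)
  recency_ok <- is.na(smoking$quit_age) || (age - smoking$quit_age < 10)
  exposure_ok && recency_ok
}
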