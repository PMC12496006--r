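#' Extract calibration targets from a trial result
#'
#' Converts an `lc_trial_result` into observed-style count targets at the
#' base-trial scale (counts divided by the replication factor and rounded):
#' yearly control-arm incidence, interval cancers, per-round screen
#' composition (negatives plus stage-specific positives), and lung-cancer
#' deaths with person-years after screen detection.
#'
#' @param result An `lc_trial_result`.
#' @param scale `"base"` (default) divides counts by the replication factor,
#'   giving targets at the size of the underlying trial; `"replicated"`
#'   keeps the replicated counts, treating the whole replicated population
#'   as the observed trial (useful for parameter-recovery experiments that
#'   need more information than one trial's worth).
#' @return A list of class `lc_targets`.
#' @export
calibration_targets <- function(result, scale = c("base", "replicated")) {
  scale <- match.arg(scale)
  r <- if (scale == "base") result$replication else 1L
  screens <- lapply(1:4, function(k) {
    pos <- apply(result$screen_detected[k, , , drop = FALSE], 2, sum)
    round(c(negative = unname(result$n_negative[k]),
            setNames(pos, STAGES)) / r)
  })
  tg <- list(
    control_incidence = round(result$control_incidence / r),
    interval_cancers = round(result$interval_cancers / r),
    screens = screens,
    deaths = data.frame(stage = STAGES,
                        deaths = round(unname(
                          result$lc_deaths_after_detection) / r),
                        py = unname(result$py_after_detection) / r),
    n_base = if (scale == "base") result$n_base
             else result$n_base * result$replication)
  class(tg) <- "lc_targets"
  tg
}

LOGLIK_SENTINEL <- -1e10

#' Composite log-likelihood of simulated versus observed trial outcomes
#'
#' Sums three likelihood blocks, equally weighted: (a) Poisson terms for the
#' yearly control-arm incidence and for interval cancers, with the simulated
#' counts scaled to expected counts at the observed scale; (b) a multinomial
#' term per screening round over \{negative screen, positive by stage\},
#' using the simulated composition as cell probabilities; (c) Poisson terms
#' for lung-cancer deaths after screen detection with simulated death rates
#' applied to the observed person-years. A simulated expectation of zero
#' where a positive count was observed yields a large negative sentinel
#' value standing in for \eqn{-\infty}. Any target block set to `NULL` is
#' skipped.
#'
#' @param sim An `lc_trial_result` (its `replication` scales counts to
#'   expectations).
#' @param obs An [calibration_targets()] object.
#' @return Scalar log-likelihood (higher is better).
#' @export
composite_loglik <- function(sim, obs) {
  scale <- obs$n_base / (sim$n_base * sim$replication)
  ll <- 0
  pois_block <- function(k, lambda) {
    if (any(k > 0 & lambda <= 0)) return(NA_real_)
    i <- k > 0 | lambda > 0
    sum(dpois(k[i], lambda[i], log = TRUE))
  }
  if (!is.null(obs$control_incidence)) {
    lam <- as.numeric(sim$control_incidence) * scale
    b <- pois_block(as.numeric(obs$control_incidence), lam)
    if (is.na(b)) return(LOGLIK_SENTINEL)
    ll <- ll + b
  }
  if (!is.null(obs$interval_cancers)) {
    lam <- as.numeric(sim$interval_cancers) * scale
    b <- pois_block(as.numeric(obs$interval_cancers), lam)
    if (is.na(b)) return(LOGLIK_SENTINEL)
    ll <- ll + b
  }
  if (!is.null(obs$screens)) {
    for (k in 1:4) {
      pos <- apply(sim$screen_detected[k, , , drop = FALSE], 2, sum)
      cells <- c(negative = unname(sim$n_negative[k]), setNames(pos, STAGES))
      tot <- sum(cells)
      o <- as.numeric(obs$screens[[k]])
      if (sum(o) == 0) next
      if (tot == 0 || any(o > 0 & cells == 0)) return(LOGLIK_SENTINEL)
      p <- cells / tot
      ll <- ll + stats::dmultinom(o, prob = p, log = TRUE)
    }
  }
  if (!is.null(obs$deaths)) {
    sim_rate <- ifelse(sim$py_after_detection > 0,
                       sim$lc_deaths_after_detection /
                         sim$py_after_detection, 0)
    lam <- sim_rate * obs$deaths$py
    b <- pois_block(obs$deaths$deaths, lam)
    if (is.na(b)) return(LOGLIK_SENTINEL)
    ll <- ll + b
  }
  ll
}
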