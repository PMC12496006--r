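#' Two-stage clonal expansion carcinogenesis parameters
#'
#' The TSCE model describes lung carcinogenesis as initiation of normal cells
#' (rate \eqn{\nu}), clonal expansion of initiated cells (division rate
#' \eqn{\alpha}, death rate \eqn{\beta}), and malignant conversion (rate
#' \eqn{\mu}). Smoking acts on the effective initiation rate and on the net
#' proliferation rate \eqn{g = \alpha - \beta - \mu} through
#' \eqn{x = x_0 (1 + c \cdot \mathrm{cpd}^p)}. Only rate combinations are
#' identifiable, so \eqn{\alpha} is held fixed and \eqn{\beta} is derived as
#' \eqn{\alpha - g - \mu}. Preclinical onset (entry into stage IA) follows
#' malignant conversion after a fixed `lag`.
#'
#' Defaults are synthetic but field-plausible: they give a never-smoker
#' lifetime lung-cancer risk below one percent, a several-fold risk increase
#' for multi-decade heavy smokers, and roughly the share of trial
#' participants (about 6 percent) developing lung cancer within follow-up.
#'
#' @param nu0 Background effective initiation rate (events/year).
#' @param alpha Cell division rate (/year), held fixed.
#' @param g0 Background net proliferation rate (/year).
#' @param mu0 Malignant conversion rate (/year).
#' @param c_nu,p_nu Dose coefficient and exponent on initiation.
#' @param c_g,p_g Dose coefficient and exponent on promotion.
#' @param lag Years between malignant conversion and stage IA onset.
#' @param risk_scale Named per-sex multipliers on the initiation rate (the
#'   country-level risk-scaling knob).
#' @return A list of class `tsce_params`.
#' @export
tsce_params <- function(nu0 = 0.14, alpha = 7, g0 = 0.09, mu0 = 5e-7,
                        c_nu = 0.6, p_nu = 1, c_g = 0.16, p_g = 0.5,
                        lag = 0, risk_scale = c(male = 1, female = 1)) {
  vals <- c(nu0 = nu0, alpha = alpha, g0 = g0, mu0 = mu0, c_nu = c_nu,
            p_nu = p_nu, c_g = c_g, p_g = p_g, lag = lag)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_validation("all TSCE parameters must be finite and non-negative")
  if (alpha <= 0) stop_validation("alpha must be > 0")
  structure(c(as.list(vals), list(risk_scale = risk_scale)),
            class = "tsce_params")
}

# piecewise-constant (from, to, nu, a, b, m) segments for one smoking history
tsce_segments <- function(params, smoking, sex = "male", max_age = 110) {
  seg <- smoking$segments
  doses <- c(0, seg$cpd)
  breaks <- c(0, seg$age_from[1L], seg$age_to)
  if (!is.na(smoking$quit_age)) {
    doses <- c(doses, 0)
    breaks <- c(breaks, max_age)
  } else breaks[length(breaks)] <- max_age
  keep <- breaks[-1L] > breaks[-length(breaks)]
  from <- breaks[-length(breaks)][keep]
  to <- breaks[-1L][keep]
  d <- doses[keep]
  scale <- params$risk_scale[[sex]]
  nu <- params$nu0 * (1 + params$c_nu * d^params$p_nu) * scale
  g <- params$g0 * (1 + params$c_g * d^params$p_g)
  m <- rep(params$mu0, length(d))
  b <- params$alpha - g - m
  if (any(b < 0))
    stop_validation("alpha too small: derived cell death rate is negative")
  cbind(from = from, to = to, nu = nu, a = params$alpha, b = b, m = m)
}

#' TSCE cumulative hazard and hazard of lung-cancer onset
#'
#' `tsce_cumhaz` evaluates the cumulative hazard \eqn{\Lambda(t)} of first
#' malignant conversion for one smoking history, using the exact
#' piecewise-constant closed form of the two-stage clonal expansion survival
#' function. `tsce_hazard` is its derivative (central finite difference).
#'
#' @param params A [tsce_params()].
#' @param smoking A [smoking_history()], or `NULL` for a never-smoker.
#' @param age Ages (years) at which to evaluate.
#' @param sex Sex for the risk-scale multiplier.
#' @return Cumulative hazard (dimensionless) or hazard rate (/year) at each
#'   age.
#' @examples
#' p <- tsce_params()
#' tsce_hazard(p, NULL, 65)  # never-smoker background hazard at 65
#' @export
tsce_cumhaz <- function(params, smoking, age, sex = "male") {
  if (is.null(smoking)) {
    smoking <- smoking_history(0, data.frame(age_from = 0, age_to = 1e-9 + 0,
                                             cpd = 1e-12))
    smoking$segments$cpd <- 1e-300 # effectively zero dose
  }
  sg <- tsce_segments(params, smoking, sex)
  .tsce_cumhaz_cpp(age, sg[, "from"], sg[, "to"], sg[, "nu"], sg[, "a"],
                   sg[, "b"], sg[, "m"])
}

#' @rdname tsce_cumhaz
#' @export
tsce_hazard <- function(params, smoking, age, sex = "male") {
  eps <- 5e-4
  lo <- pmax(age - eps, 0)
  hi <- age + eps
  (tsce_cumhaz(params, smoking, hi, sex) -
     tsce_cumhaz(params, smoking, lo, sex)) / (hi - lo)
}

#' Sample ages at preclinical lung-cancer onset
#'
#' Inverse-CDF sampling on the TSCE cumulative hazard: for each person a
#' target exponential deviate \eqn{E = -\log U} is drawn and the onset age
#' solves \eqn{\Lambda(a) = E} (plus the configured lag); persons whose
#' cumulative hazard never reaches the target have no onset.
#'
#' @param cohort An `lc_cohort`.
#' @param params A [tsce_params()].
#' @param seed Integer seed.
#' @param hazard Optional override: a vectorized function of age giving the
#'   onset hazard (/year) used for every person instead of the TSCE model
#'   (intended for testing and idealized scenarios).
#' @param grid_step Age-grid resolution (years) for hazard inversion.
#' @return Numeric vector of onset ages; `Inf` when no onset occurs by the
#'   end of the modelled lifespan (age 110).
#' @export
sample_onset_age <- function(cohort, params = tsce_params(), seed = NULL,
                             hazard = NULL, grid_step = 0.5) {
  n <- nrow(cohort)
  grid <- seq(0, 110, by = grid_step)
  with_seed(seed, {
    target <- -log(runif(n))
    if (!is.null(hazard)) {
      h <- hazard(grid)
      H <- c(0, cumsum((h[-1L] + h[-length(h)]) / 2 * diff(grid)))
      idx <- findInterval(target, H)
      onset <- rep(Inf, n)
      ok <- idx < length(H) & target > 0
      i <- idx[ok]
      dl <- H[i + 1L] - H[i]
      onset[ok] <- grid[i] + ifelse(dl > 0, (target[ok] - H[i]) / dl, 0) *
        (grid[i + 1L] - grid[i])
      return(onset + params$lag)
    }
    # vectorized flat segment assembly: [0,start) unexposed, [start,end)
    # smoking, and for former smokers [quit,110) unexposed again
    start <- cohort$start_age
    former <- !is.na(cohort$quit_age)
    end <- ifelse(former, cohort$quit_age, 110)
    nseg <- ifelse(former, 3L, 2L)
    off <- c(0L, cumsum(nseg))
    N <- off[n + 1L]
    from <- to <- d <- numeric(N)
    p1 <- off[seq_len(n)] + 1L
    from[p1] <- 0; to[p1] <- start; d[p1] <- 0
    from[p1 + 1L] <- start; to[p1 + 1L] <- end; d[p1 + 1L] <- cohort$cpd
    p3 <- (p1 + 2L)[former]
    from[p3] <- end[former]; to[p3] <- 110; d[p3] <- 0
    scale <- unname(params$risk_scale[cohort$sex])
    nu <- params$nu0 * (1 + params$c_nu * d^params$p_nu) *
      rep(scale, times = nseg)
    g <- params$g0 * (1 + params$c_g * d^params$p_g)
    m <- rep(params$mu0, N)
    b <- params$alpha - g - m
    if (any(b < 0))
      stop_validation("alpha too small: derived cell death rate is negative")
    onset <- .tsce_onset_cpp(grid, off, from, to, nu,
                             rep(params$alpha, N), b, m, target)
    onset + params$lag
  })
}
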