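#' Declare a free calibration parameter
#'
#' Parameters are addressed by colon-separated ids:
#' `sensitivity:<stage>:<histology>:<baseline|repeat>`, `cure:<stage>`,
#' `sojourn:<stage>:<histology>:<sex>:<mean|shape>`,
#' `clinical_detection:<stage>`, or `tsce:<field>`. Probabilities are
#' searched on the logit scale and positive quantities on the log scale.
#'
#' @param id Parameter id string.
#' @param lower,upper Bounds on the natural scale.
#' @return A list of class `free_parameter`.
#' @export
free_parameter <- function(id, lower, upper) {
  if (lower > upper) stop_validation("lower bound exceeds upper bound")
  structure(list(id = id, lower = lower, upper = upper),
            class = "free_parameter")
}

param_transform <- function(id) {
  kind <- strsplit(id, ":", fixed = TRUE)[[1L]][1L]
  if (kind %in% c("sensitivity", "cure", "clinical_detection"))
    list(to = logit, from = expit)
  else
    list(to = log, from = exp)
}

# patch a parameter bundle with natural-scale values for the given ids
apply_free <- function(params, ids, values) {
  for (j in seq_along(ids)) {
    parts <- strsplit(ids[j], ":", fixed = TRUE)[[1L]]
    v <- values[j]
    switch(parts[1L],
      sensitivity = {
        tab <- params$sensitivity$table
        i <- which(tab$stage == parts[2L] & tab$histology == parts[3L])
        if (!length(i)) stop_config("unknown sensitivity cell: ", ids[j])
        col <- if (parts[4L] == "baseline") "baseline" else "repeat."
        params$sensitivity$table[i, col] <- v
      },
      cure = {
        if (!parts[2L] %in% STAGES) stop_config("unknown stage: ", ids[j])
        params$cure[parts[2L]] <- v
      },
      sojourn = {
        tab <- params$sojourn$table
        i <- which(tab$stage == parts[2L] & tab$histology == parts[3L] &
                     tab$sex == parts[4L])
        if (!length(i)) stop_config("unknown sojourn cell: ", ids[j])
        params$sojourn$table[i, parts[5L]] <- v
      },
      clinical_detection = {
        if (!parts[2L] %in% STAGES) stop_config("unknown stage: ", ids[j])
        params$clinical_detection[parts[2L]] <- v
      },
      tsce = {
        if (!parts[2L] %in% names(params$tsce))
          stop_config("unknown tsce field: ", ids[j])
        params$tsce[[parts[2L]]] <- v
      },
      stop_config("unknown parameter id: ", ids[j]))
  }
  params
}

#' Calibrate model parameters to trial targets
#'
#' Wraps [de_optimize()] around [run_trial()] and [composite_loglik()]: the
#' free parameters are searched on their transformed scales, each candidate
#' is evaluated by simulating the trial with a fixed simulation seed (common
#' random numbers, making the objective quasi-deterministic), and the
#' negative composite log-likelihood is minimized. When every free parameter
#' belongs to the screening layer (sensitivity or cure), the natural
#' histories are simulated once and reused across evaluations.
#'
#' @param cohort An `lc_cohort`.
#' @param protocol A [screening_protocol()].
#' @param free List of [free_parameter()] declarations (empty list: the
#'   bundle is evaluated once and returned unchanged).
#' @param targets An [calibration_targets()] object.
#' @param params Starting [default_params()] bundle.
#' @param settings [de_optimize()] control list.
#' @param seed Integer seed (drives both the optimizer and the fixed
#'   simulation stream).
#' @return An object of class `lc_calibration` with the fitted natural-scale
#'   values (`coef()`), achieved log-likelihood (`logLik()`), optimizer
#'   trace, and the frozen objective used for profiling.
#' @export
calibrate <- function(cohort, protocol = screening_protocol(), free,
                      targets, params = default_params(),
                      settings = list(), seed = NULL) {
  ids <- vapply(free, function(f) f$id, character(1))
  trans <- lapply(ids, param_transform)
  sim_seed <- sub_seed(seed, 7L) %||% 1L
  screening_only <- length(ids) > 0L &&
    all(grepl("^(sensitivity|cure):", ids))
  lh <- if (screening_only)
    build_life_histories(cohort, params, seed = sub_seed(sim_seed, 101L))
  objective <- function(v_t) {
    nat <- vapply(seq_along(v_t), function(j) trans[[j]]$from(v_t[j]),
                  numeric(1))
    p2 <- apply_free(params, ids, nat)
    sim <- run_trial(cohort, protocol, p2, seed = sim_seed,
                     life_histories = lh)
    -composite_loglik(sim, targets)
  }
  if (length(ids) == 0L) {
    sim <- run_trial(cohort, protocol, params, seed = sim_seed)
    fit <- list(par = numeric(0), transformed = numeric(0),
                loglik = composite_loglik(sim, targets),
                trace = numeric(0), free = free, ids = character(0),
                objective = function(v) -composite_loglik(sim, targets),
                params = params, nfev = 1L, seed = seed)
    class(fit) <- "lc_calibration"
    return(fit)
  }
  lower_t <- vapply(seq_along(free), function(j)
    trans[[j]]$to(free[[j]]$lower), numeric(1))
  upper_t <- vapply(seq_along(free), function(j)
    trans[[j]]$to(free[[j]]$upper), numeric(1))
  opt <- de_optimize(objective, lower_t, upper_t, control = settings,
                     seed = sub_seed(seed, 8L))
  nat <- vapply(seq_along(opt$par), function(j)
    trans[[j]]$from(opt$par[j]), numeric(1))
  fit <- list(par = setNames(nat, ids), transformed = opt$par,
              loglik = -opt$value, trace = opt$trace, free = free,
              ids = ids, lower_t = lower_t, upper_t = upper_t,
              objective = objective,
              params = apply_free(params, ids, nat),
              nfev = opt$nfev, generations = opt$generations, seed = seed)
  class(fit) <- "lc_calibration"
  fit
}

#' @export
print.lc_calibration <- function(x, ...) {
  cat("Calibrated screening-model parameters\n")
  cat(sprintf("  log-likelihood: %.3f (%d objective evaluations)\n",
              x$loglik, x$nfev))
  if (length(x$par)) {
    for (i in seq_along(x$par))
      cat(sprintf("  %-45s %.4f\n", x$ids[i], x$par[i]))
  } else cat("  (no free parameters)\n")
  invisible(x)
}

#' @export
summary.lc_calibration <- function(object, ...) {
  tab <- data.frame(
    id = object$ids,
    estimate = unname(object$par),
    lower = vapply(object$free, `[[`, numeric(1), "lower"),
    upper = vapply(object$free, `[[`, numeric(1), "upper"))
  structure(list(table = tab, loglik = object$loglik, nfev = object$nfev),
            class = "summary.lc_calibration")
}

#' @export
print.summary.lc_calibration <- function(x, ...) {
  cat(sprintf("Composite log-likelihood %.3f after %d evaluations\n",
              x$loglik, x$nfev))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.lc_calibration <- function(object, ...) object$par

#' @export
logLik.lc_calibration <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' Profile-likelihood feasible range on a generic objective
#'
#' Walks one coordinate of a (negative log-likelihood) objective up and down
#' from its point estimate on the given scale, holding all other coordinates
#' fixed, until the likelihood-ratio statistic \eqn{2(\hat\ell - \ell)}
#' crosses the 97.5th percentile of the \eqn{\chi^2_1} distribution
#' (5.024); the crossing point is linearly interpolated between bracketing
#' grid points. If a bound is reached without a crossing the range is
#' one-sided and flagged.
#'
#' @param objective Function returning the negative log-likelihood.
#' @param par Point-estimate parameter vector (objective's scale).
#' @param index Coordinate to profile.
#' @param lower,upper Walk limits for that coordinate.
#' @param step Grid step on the objective's scale.
#' @param threshold Likelihood-ratio cutoff (default
#'   `qchisq(0.975, df = 1)`).
#' @param max_steps Cap on grid points per direction.
#' @return List with `lower`, `upper`, `point`, `threshold` and logical
#'   `lower_open`/`upper_open` flags (TRUE when no crossing was found before
#'   the walk limit).
#' @export
profile_loglik <- function(objective, par, index, lower = -Inf,
                           upper = Inf, step = 0.02,
                           threshold = qchisq(0.975, 1), max_steps = 2000L) {
  ll_hat <- -objective(par)
  walk <- function(dir, limit) {
    x0 <- par[index]
    d0 <- 0
    for (s in seq_len(max_steps)) {
      x1 <- par[index] + dir * s * step
      hit_limit <- (dir > 0 && x1 > limit) || (dir < 0 && x1 < limit)
      if (hit_limit) x1 <- limit
      p <- par
      p[index] <- x1
      d1 <- 2 * (ll_hat - (-objective(p)))
      if (is.na(d1)) d1 <- Inf
      if (d1 >= threshold) {
        x <- if (d1 > d0) x0 + (threshold - d0) / (d1 - d0) * (x1 - x0)
             else x1
        return(list(bound = x, open = FALSE))
      }
      if (hit_limit) return(list(bound = x1, open = TRUE))
      x0 <- x1
      d0 <- d1
    }
    list(bound = x0, open = TRUE)
  }
  up <- walk(1, upper)
  dn <- walk(-1, lower)
  list(lower = dn$bound, upper = up$bound, point = par[index],
       threshold = threshold, lower_open = dn$open, upper_open = up$open)
}

#' Profile-likelihood feasible range of a calibrated parameter
#'
#' @param fit An `lc_calibration`.
#' @param id Free-parameter id to profile.
#' @param step Grid step on the transformed scale.
#' @param ... Passed to [profile_loglik()].
#' @return A list of class `lc_feasible_range` with natural-scale `lower`,
#'   `point`, `upper`, the threshold used, and one-sidedness flags.
#' @export
profile_parameter <- function(fit, id, step = 0.02, ...) {
  index <- match(id, fit$ids)
  if (is.na(index)) stop_config("not a free parameter of this fit: ", id)
  tr <- param_transform(id)
  pr <- profile_loglik(fit$objective, fit$transformed, index,
                       lower = fit$lower_t[index],
                       upper = fit$upper_t[index], step = step, ...)
  structure(list(param = id, lower = tr$from(pr$lower),
                 point = tr$from(pr$point), upper = tr$from(pr$upper),
                 threshold = pr$threshold, lower_open = pr$lower_open,
                 upper_open = pr$upper_open),
            class = "lc_feasible_range")
}

#' @export
print.lc_feasible_range <- function(x, ...) {
  cat(sprintf("Feasible range for %s: %.4f (%s%.4f, %.4f%s)\n",
              x$param, x$point,
              if (x$lower_open) "<" else "", x$lower, x$upper,
              if (x$upper_open) ">" else ""))
  invisible(x)
}
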