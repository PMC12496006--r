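#' Differential evolution optimizer (DE/rand/1/bin)
#'
#' Minimizes an objective over a box by the classic differential evolution
#' scheme: for each target vector a mutant \eqn{x_{r1} + F (x_{r2} -
#' x_{r3})} is built from three distinct random population members, combined
#' by binomial crossover with rate CR (one coordinate always taken from the
#' mutant), clipped to the bounds, and kept if it does not increase the
#' objective. The best objective value is therefore non-increasing across
#' generations, and the whole trajectory is reproducible from the seed.
#'
#' @param fn Objective function of a numeric vector; smaller is better.
#' @param lower,upper Finite bound vectors.
#' @param control List: `NP` (population size, default `10 * dim`, minimum
#'   4), `F` (differential weight, 0.5), `CR` (crossover rate, 0.9),
#'   `generations` (300), `early_stop` (stop after this many stagnant
#'   generations, 50), `trace` (record per-generation best, TRUE).
#' @param seed Integer seed.
#' @return List with `par`, `value`, `trace` (best value per generation,
#'   starting with the initial population), `generations` run, `nfev`, and
#'   the final `population`.
#' @examples
#' sph <- function(x) sum(x^2)
#' de_optimize(sph, rep(-5, 2), rep(5, 2),
#'             control = list(generations = 50), seed = 1)$value
#' @export
de_optimize <- function(fn, lower, upper, control = list(), seed = NULL) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(c(lower, upper))))
    stop_validation("bounds must be finite and of equal length")
  if (any(lower > upper)) stop_validation("lower bound exceeds upper bound")
  ctl <- modifyList(list(NP = 10L * d, F = 0.5, CR = 0.9,
                         generations = 300L, early_stop = 50L,
                         trace = TRUE), control)
  NP <- as.integer(ctl$NP)
  if (NP < 4L) stop_config("NP must be at least 4")
  with_seed(seed, {
    pop <- matrix(runif(NP * d, rep(lower, each = NP),
                        rep(upper, each = NP)), NP, d)
    val <- apply(pop, 1L, fn)
    nfev <- NP
    trace <- min(val)
    stagnant <- 0L
    gen <- 0L
    while (gen < ctl$generations && stagnant < ctl$early_stop) {
      gen <- gen + 1L
      best_before <- min(val)
      for (i in seq_len(NP)) {
        r <- sample(seq_len(NP)[-i], 3L)
        mutant <- pop[r[1L], ] + ctl$F * (pop[r[2L], ] - pop[r[3L], ])
        cross <- runif(d) < ctl$CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        fv <- fn(trial)
        nfev <- nfev + 1L
        if (fv <= val[i]) {
          pop[i, ] <- trial
          val[i] <- fv
        }
      }
      if (ctl$trace) trace <- c(trace, min(val))
      stagnant <- if (min(val) < best_before - 1e-12) 0L else stagnant + 1L
    }
    b <- which.min(val)
    list(par = pop[b, ], value = val[b], trace = trace,
         generations = gen, nfev = nfev, population = pop)
  })
}
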