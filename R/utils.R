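# internal helpers

#' @useDynLib lcscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dpois qchisq rbinom rexp runif rweibull setNames uniroot
#' @importFrom utils read.csv write.csv modifyList
NULL

STAGES <- c("IA", "IB", "II", "IIIA", "IIIB", "IV")
HISTOLOGIES <- c("adenocarcinoma", "squamous", "other_nsclc", "sclc")
SEXES <- c("male", "female")

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL leaves the active stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed so independent stages of a pipeline driven by one
# user seed draw from distinct streams (kept below 2^31)
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271 + 7919 * as.integer(k)) %% 2147483587L
}

stop_config <- function(...) {
  stop(structure(class = c("lcscreen_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("lcscreen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_validation(what, " must lie in [0, 1]")
  invisible(x)
}
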