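#' Weibull scale from a target mean
#'
#' Sojourn distributions are parameterized by their mean and shape; the
#' corresponding Weibull scale is \eqn{\lambda = m / \Gamma(1 + 1/k)}.
#'
#' @param mean Target expectation (> 0).
#' @param shape Weibull shape (> 0).
#' @return Weibull scale such that `rweibull(n, shape, scale)` has the given
#'   expectation.
#' @examples
#' weibull_scale_from_mean(5, 1)  # exponential case: scale 5
#' @export
weibull_scale_from_mean <- function(mean, shape) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop_validation("mean must be positive")
  if (any(!is.finite(shape)) || any(shape <= 0))
    stop_validation("shape must be positive")
  mean / gamma(1 + 1 / shape)
}

#' Preclinical sojourn-time parameters
#'
#' Mean and Weibull shape of the time a cancer spends in each TNM stage,
#' by histology and sex. [default_sojourn_table()] bundles the fitted stage
#' IA adenocarcinoma values (mean 3.56 y men / 4.77 y women, shape 0.35 --
#' a heavy-tailed distribution whose short draws emulate stage-skipping)
#' with synthetic stand-in values for all other cells, where no published
#' table is available.
#'
#' @param table Data frame with columns `stage`, `histology`, `sex`, `mean`,
#'   `shape` covering every combination that will be simulated.
#' @return An object of class `sojourn_params`.
#' @export
sojourn_params <- function(table = default_sojourn_table()) {
  need <- c("stage", "histology", "sex", "mean", "shape")
  if (!all(need %in% names(table)))
    stop_config("sojourn table needs columns ", paste(need, collapse = ", "))
  if (any(table$mean <= 0) || any(table$shape <= 0))
    stop_validation("sojourn mean and shape must be positive")
  table$key <- paste(table$stage, table$histology, table$sex, sep = "|")
  if (anyDuplicated(table$key))
    stop_config("duplicate (stage, histology, sex) rows in sojourn table")
  structure(list(table = table), class = "sojourn_params")
}

#' @rdname sojourn_params
#' @export
default_sojourn_table <- function() {
  base_mean <- c(
    adenocarcinoma = NA, squamous = 1.5, other_nsclc = 1.5, sclc = 0.4)
  rows <- expand.grid(stage = STAGES, histology = HISTOLOGIES,
                      sex = SEXES, stringsAsFactors = FALSE)
  later <- c(IA = NA, IB = 1.0, II = 0.8, IIIA = 0.7, IIIB = 0.6, IV = 0.5)
  mean <- ifelse(rows$stage == "IA",
                 ifelse(rows$histology == "adenocarcinoma",
                        ifelse(rows$sex == "male", 3.56, 4.77),
                        base_mean[rows$histology]),
                 later[rows$stage])
  mean[rows$stage != "IA" & rows$histology == "sclc"] <- 0.3
  shape <- ifelse(rows$stage == "IA" & rows$histology == "adenocarcinoma",
                  0.35, 1.44)
  cbind(rows, mean = unname(mean), shape = shape)
}

# vectorized (mean, shape) lookup
sojourn_lookup <- function(params, stage, histology, sex) {
  key <- paste(stage, histology, sex, sep = "|")
  i <- match(key, params$table$key)
  if (anyNA(i))
    stop_config("sojourn parameters missing for: ",
                paste(unique(key[is.na(i)]), collapse = ", "))
  params$table[i, c("mean", "shape")]
}

#' Draw preclinical sojourn times
#'
#' @param stage,histology,sex Scalars identifying the parameter cell.
#' @param params A [sojourn_params()].
#' @param seed Integer seed.
#' @param n Number of draws.
#' @return Weibull sojourn durations (years) whose expectation equals the
#'   configured mean.
#' @export
sample_sojourn <- function(stage, histology, sex, params = sojourn_params(),
                           seed = NULL, n = 1) {
  ms <- sojourn_lookup(params, stage, histology, sex)
  scale <- weibull_scale_from_mean(ms$mean, ms$shape)
  with_seed(seed, rweibull(n, shape = ms$shape, scale = scale))
}
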