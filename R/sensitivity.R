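#' CT screening sensitivity parameters
#'
#' Two parameterizations of the probability that a CT screen detects a
#' preclinical cancer of a given stage and histology:
#' \describe{
#'   \item{table mode}{explicit baseline-screen and repeat-screen
#'     probabilities per (stage, histology), as in a fitted sensitivity
#'     table;}
#'   \item{parametric mode}{a baseline probability per (stage, histology)
#'     plus a per-histology logit-scale repeat-screen boost
#'     \eqn{\beta_h \ge 0}: repeat sensitivity =
#'     \eqn{\mathrm{expit}(\mathrm{logit}(base) + \beta_h)}. The boost
#'     reflects nodule-growth (volume doubling time) information that is
#'     only available once a prior scan exists; \eqn{\beta_h = 0} makes
#'     repeat and baseline screens exactly equal.}
#' }
#'
#' @param mode `"table"` or `"parametric"`.
#' @param table Table mode: data frame with columns `stage`, `histology`,
#'   `baseline`, `repeat.` (probabilities in `[0, 1]`).
#' @param base Parametric mode: data frame `stage`, `histology`, `baseline`.
#' @param beta_repeat Parametric mode: named non-negative logit boosts per
#'   histology.
#' @return An object of class `sensitivity_params`.
#' @seealso [nelson_ct_sensitivity()] for the bundled fitted table.
#' @export
sensitivity_params <- function(mode = c("table", "parametric"), table = NULL,
                               base = NULL, beta_repeat = NULL) {
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(table)) stop_config("table mode requires a table")
    rep_col <- intersect(c("repeat.", "repeat"), names(table))[1L]
    if (is.na(rep_col) || !all(c("stage", "histology", "baseline") %in%
                               names(table)))
      stop_config("table needs columns stage, histology, baseline, repeat")
    check_prob(table$baseline, "baseline sensitivity")
    check_prob(table[[rep_col]], "repeat sensitivity")
    tab <- data.frame(stage = table$stage, histology = table$histology,
                      baseline = table$baseline,
                      repeat. = table[[rep_col]])
  } else {
    if (is.null(base) || is.null(beta_repeat))
      stop_config("parametric mode requires base and beta_repeat")
    check_prob(base$baseline, "baseline sensitivity")
    if (any(beta_repeat < 0)) stop_validation("beta_repeat must be >= 0")
    tab <- data.frame(stage = base$stage, histology = base$histology,
                      baseline = base$baseline,
                      repeat. = expit(logit(base$baseline) +
                                        unname(beta_repeat[base$histology])))
    # logit(1) is Inf; beta 0 must reproduce baseline exactly
    exact <- base$baseline %in% c(0, 1) |
      unname(beta_repeat[base$histology]) == 0
    tab$repeat.[exact] <- tab$baseline[exact]
  }
  tab$key <- paste(tab$stage, tab$histology, sep = "|")
  if (anyDuplicated(tab$key))
    stop_config("duplicate (stage, histology) rows in sensitivity table")
  structure(list(mode = mode, table = tab,
                 beta_repeat = if (mode == "parametric") beta_repeat),
            class = "sensitivity_params")
}

#' Bundled fitted CT sensitivity table
#'
#' Loads the packaged stage x histology CT sensitivity estimates for the
#' NELSON protocol (percent, converted to probabilities), e.g. 41.0 percent
#' for a stage IA adenocarcinoma at the baseline screen and 70.9 percent at
#' repeat screens. For squamous, small-cell and other-NSCLC cancers the
#' fitted repeat boost was zero, so baseline and repeat values coincide.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A table-mode [sensitivity_params()] with the all-screen averages
#'   kept in `attr(, "all_screen_average")` (percent) and reference values
#'   in `attr(, "nlst")`.
#' @export
nelson_ct_sensitivity <- function(path = system.file(
    "extdata", "ct_sensitivity_nelson.csv", package = "lcscreen")) {
  if (!file.exists(path)) stop_config("sensitivity table not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("all_screen_average", "baseline", "repeat.",
                          "nlst"), names(x)))
    if (any(x[[col]] < 0 | x[[col]] > 100))
      stop_validation(col, " must lie in [0, 100] percent")
  sp <- sensitivity_params("table",
                           table = data.frame(stage = x$stage,
                                              histology = x$histology,
                                              baseline = x$baseline / 100,
                                              repeat. = x$repeat. / 100))
  attr(sp, "all_screen_average") <- setNames(x$all_screen_average,
                                             paste(x$stage, x$histology,
                                                   sep = "|"))
  if ("nlst" %in% names(x))
    attr(sp, "nlst") <- setNames(x$nlst, paste(x$stage, x$histology,
                                               sep = "|"))
  sp
}

#' Evaluate CT sensitivity
#'
#' @param params A [sensitivity_params()].
#' @param stage Stage labels (or indices 1..6).
#' @param histology Histology labels.
#' @param is_repeat Logical; `TRUE` for any screen after the person's first
#'   attended screen.
#' @return Detection probabilities in `[0, 1]` (vectorized).
#' @examples
#' sens <- nelson_ct_sensitivity()
#' sensitivity(sens, "IA", "adenocarcinoma", is_repeat = FALSE)  # 0.41
#' @export
sensitivity <- function(params, stage, histology, is_repeat = FALSE) {
  if (is.numeric(stage)) stage <- STAGES[stage]
  n <- max(length(stage), length(histology), length(is_repeat))
  key <- paste(rep_len(stage, n), rep_len(histology, n), sep = "|")
  i <- match(key, params$table$key)
  if (anyNA(i))
    stop_config("sensitivity missing for: ",
                paste(unique(key[is.na(i)]), collapse = ", "))
  ifelse(rep_len(is_repeat, n), params$table$repeat.[i],
         params$table$baseline[i])
}
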