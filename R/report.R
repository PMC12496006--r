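#' Write / read a sensitivity table file
#'
#' Writes the stage x histology CT sensitivities in percent to one decimal,
#' with columns `all_screen_average`, `baseline`, `repeat` (mirroring the
#' fitted-table layout). Writing, reading and re-writing produces identical
#' bytes.
#'
#' @param params A table-mode [sensitivity_params()].
#' @param averages Optional all-screen averages (percent) as a stage x
#'   histology matrix from [all_screen_average_sensitivity()] or a named
#'   vector keyed `stage|histology`; defaults to the values stored on
#'   `params`, else blank.
#' @param path Output CSV path.
#' @return `write_sensitivity_table` returns `path` invisibly;
#'   `read_sensitivity_table` a table-mode [sensitivity_params()].
#' @export
write_sensitivity_table <- function(params, averages = NULL, path) {
  tab <- params$table
  key <- paste(tab$stage, tab$histology, sep = "|")
  avg <- rep(NA_real_, nrow(tab))
  if (is.null(averages)) averages <- attr(params, "all_screen_average")
  if (is.matrix(averages)) {
    averages <- setNames(as.vector(averages),
                         as.vector(outer(rownames(averages),
                                         colnames(averages), paste,
                                         sep = "|")))
  }
  if (!is.null(averages)) avg <- unname(averages[key])
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  lines <- c("stage,histology,all_screen_average,baseline,repeat",
             sprintf("%s,%s,%s,%s,%s", tab$stage, tab$histology, fmt(avg),
                     fmt(100 * tab$baseline), fmt(100 * tab$repeat.)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sensitivity_table
#' @export
read_sensitivity_table <- function(path) {
  if (!file.exists(path)) stop_config("sensitivity table not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("baseline", "repeat."))
    if (any(x[[col]] < 0 | x[[col]] > 100, na.rm = TRUE))
      stop_validation(col, " must lie in [0, 100] percent")
  sp <- sensitivity_params("table",
                           table = data.frame(stage = x$stage,
                                              histology = x$histology,
                                              baseline = x$baseline / 100,
                                              repeat. = x$repeat. / 100))
  if ("all_screen_average" %in% names(x))
    attr(sp, "all_screen_average") <- setNames(x$all_screen_average,
                                               paste(x$stage, x$histology,
                                                     sep = "|"))
  sp
}

#' Export tidy trial-result series
#'
#' Writes the aggregate trial outcomes as tidy CSV files:
#' `incidence_by_year.csv` (year, arm, count; clinical diagnoses),
#' `yield_by_round_stage.csv` (round, stage, histology, count of
#' screen-detected cancers), `interval_cancers.csv` (window, stage, count),
#' `screens_by_round.csv` (round, screens, negatives) and
#' `mortality_followup.csv` (stage at detection, person-years, LC deaths).
#' Sums across exported rows equal the corresponding trial-result totals.
#'
#' @param result An `lc_trial_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_yield_series <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  years <- as.integer(names(result$control_incidence))
  inc <- rbind(
    data.frame(year = years, arm = "control",
               count = as.integer(result$control_incidence)),
    data.frame(year = years, arm = "screen",
               count = as.integer(result$screened_arm_clinical)))
  write.csv(inc, fp("incidence_by_year.csv"), row.names = FALSE,
            quote = FALSE)
  g <- expand.grid(round = 1:4, stage = STAGES, histology = HISTOLOGIES,
                   stringsAsFactors = FALSE)
  g$count <- as.integer(result$screen_detected[cbind(
    g$round, match(g$stage, STAGES), match(g$histology, HISTOLOGIES))])
  write.csv(g, fp("yield_by_round_stage.csv"), row.names = FALSE,
            quote = FALSE)
  iv <- expand.grid(window = rownames(result$interval_cancers),
                    stage = STAGES, stringsAsFactors = FALSE)
  iv$count <- as.integer(result$interval_cancers[cbind(
    match(iv$window, rownames(result$interval_cancers)),
    match(iv$stage, STAGES))])
  write.csv(iv, fp("interval_cancers.csv"), row.names = FALSE, quote = FALSE)
  sc <- data.frame(round = 1:4, screens = as.integer(result$n_screens),
                   negatives = as.integer(result$n_negative))
  write.csv(sc, fp("screens_by_round.csv"), row.names = FALSE, quote = FALSE)
  mf <- data.frame(stage = STAGES,
                   person_years = unname(result$py_after_detection),
                   lc_deaths = as.integer(
                     result$lc_deaths_after_detection))
  write.csv(mf, fp("mortality_followup.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(vapply(c("incidence_by_year.csv", "yield_by_round_stage.csv",
                     "interval_cancers.csv", "screens_by_round.csv",
                     "mortality_followup.csv"), fp, character(1)))
}
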