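#' Default natural-history and screening parameter bundle
#'
#' Collects every model component with its default configuration: TSCE
#' carcinogenesis, per-sex life tables, histology distribution, sojourn
#' times, clinical detection, mixture-cure survival, the fitted CT
#' sensitivity table and the stage-specific cure probabilities.
#'
#' @param tsce,life_tables,histology,sojourn,clinical_detection,survival,sensitivity,cure
#'   Component overrides; see the respective constructors.
#' @return A list of class `lc_params`.
#' @export
default_params <- function(tsce = tsce_params(),
                           life_tables = list(male = life_table("male"),
                                              female = life_table("female")),
                           histology = histology_distribution(),
                           sojourn = sojourn_params(),
                           clinical_detection = clinical_detection_probs(),
                           survival = survival_params(),
                           sensitivity = nelson_ct_sensitivity(),
                           cure = cure_probs()) {
  structure(list(tsce = tsce, life_tables = life_tables,
                 histology = histology, sojourn = sojourn,
                 clinical_detection = clinical_detection,
                 survival = survival, sensitivity = sensitivity,
                 cure = cure),
            class = "lc_params")
}

#' Write / read a parameter bundle as YAML
#'
#' Serializes every component of an `lc_params` bundle (tables as row
#' lists); `read_params(write_params(p, f))` reproduces the bundle.
#'
#' @param params An [default_params()] bundle.
#' @param path YAML file path.
#' @return `read_params` returns the bundle; `write_params` the path,
#'   invisibly.
#' @export
write_params <- function(params, path) {
  ser <- list(
    tsce = params$tsce[setdiff(names(params$tsce), "risk_scale")],
    tsce_risk_scale = as.list(params$tsce$risk_scale),
    life_tables = lapply(params$life_tables, function(tb)
      list(sex = tb$sex, gamma = tb$gamma, q = tb$q)),
    histology = lapply(unclass(params$histology), as.list),
    sojourn = unname(split(params$sojourn$table[
      c("stage", "histology", "sex", "mean", "shape")],
      seq_len(nrow(params$sojourn$table)))),
    clinical_detection = as.list(unclass(params$clinical_detection)),
    survival = unname(split(params$survival$table[
      c("stage", "histology", "cure", "rate")],
      seq_len(nrow(params$survival$table)))),
    sensitivity = unname(split(params$sensitivity$table[
      c("stage", "histology", "baseline", "repeat.")],
      seq_len(nrow(params$sensitivity$table)))),
    cure = as.list(unclass(params$cure)))
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_config("parameter file not found: ", path)
  y <- yaml::read_yaml(path)
  rowbind <- function(rows) do.call(rbind, lapply(rows, as.data.frame))
  lt <- lapply(y$life_tables, function(tb) {
    out <- life_table(tb$sex, gamma = tb$gamma)
    out$q <- as.numeric(tb$q)
    out$ages <- seq_along(out$q) - 1L
    out
  })
  default_params(
    tsce = do.call(tsce_params, c(y$tsce,
      list(risk_scale = unlist(y$tsce_risk_scale)))),
    life_tables = lt,
    histology = histology_distribution(unlist(y$histology$male),
                                       unlist(y$histology$female)),
    sojourn = sojourn_params(rowbind(y$sojourn)),
    clinical_detection = clinical_detection_probs(
      unlist(y$clinical_detection)[STAGES]),
    survival = survival_params(rowbind(y$survival)),
    sensitivity = sensitivity_params("table", table = rowbind(y$sensitivity)),
    cure = cure_probs(unlist(y$cure)[STAGES]))
}
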