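# shared fixtures, built in code

# a life-history table of n persons who all carry a preclinical cancer of
# `stage` from onset_t (years from randomization, may be negative) until a
# scheduled clinical diagnosis at dx_t; death ages far out unless given
make_prevalent_lh <- function(n, stage = "IA",
                              histology = "adenocarcinoma",
                              age_rand = 60, onset_t = -0.5, dx_t = 50,
                              oc_t = 40, lc_death_age = Inf, arm = "screen",
                              sex = "male") {
  stages <- c("IA", "IB", "II", "IIIA", "IIIB", "IV")
  k <- match(stage, stages)
  entries <- matrix(Inf, n, 6, dimnames = list(NULL, paste0("entry_",
                                                            stages)))
  onset <- age_rand + onset_t
  entries[, seq_len(k)] <- matrix(rep(onset - (k - seq_len(k)) * 1e-3,
                                      each = n), n)
  lh <- data.frame(id = seq_len(n), sex = sex, arm = arm,
                   age_at_randomization = age_rand,
                   oc_death_age = age_rand + oc_t,
                   onset_age = onset, histology = histology,
                   entries,
                   dx_age = age_rand + dx_t, dx_stage = 6L,
                   lc_death_age = lc_death_age)
  class(lh) <- c("lc_life_histories", "data.frame")
  lh
}

# sensitivity table with one constant value everywhere
flat_sensitivity <- function(p) {
  g <- expand.grid(stage = c("IA", "IB", "II", "IIIA", "IIIB", "IV"),
                   histology = c("adenocarcinoma", "squamous",
                                 "other_nsclc", "sclc"),
                   stringsAsFactors = FALSE)
  sensitivity_params("table",
                     table = data.frame(g, baseline = p, repeat. = p))
}

# small two-arm cohort wrapper
small_cohort <- function(n_male = 60, n_female = 20, seed = 1, ...) {
  generate_cohort(n_male, n_female, seed = seed, ...)
}

mc_se <- function(p, n) sqrt(p * (1 - p) / n)
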