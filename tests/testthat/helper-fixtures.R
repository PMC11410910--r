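# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal cohort for phenome/trajectory unit tests: ids P1..Pn, a common
# assessment date, simple covariates.
toy_cohort <- function(n, assessment = as.Date("2010-01-01")) {
  data.frame(person_id = paste0("P", seq_len(n)),
             sex = rep_len(c(0, 1), n),
             age = 50 + (seq_len(n) %% 20),
             bmi = 27 + (seq_len(n) %% 5),
             townsend = rep_len(c(-2, 0, 2), n),
             smoking = factor(rep_len(c("never", "former", "current"), n)),
             alcohol = factor(rep_len(c("current", "never"), n)),
             physical_activity = factor(rep_len(c("light", "medium", "heavy"), n)),
             urate = 4 + (seq_len(n) %% 7) * 0.5,
             assessment_date = assessment,
             death_date = as.Date(NA),
             stringsAsFactors = FALSE)
}

toy_events <- function(person, phecode, day,
                       origin = as.Date("2010-01-01"), source = "registry") {
  data.frame(person_id = person, phecode = phecode,
             date = origin + day, source = source, stringsAsFactors = FALSE)
}

# Small simulated study used by several scan tests (built once per file run).
small_config <- function(seed = 11, n = 4000, ...) {
  sim_config(n_individuals = n, n_variants = 60, seed = seed, ...)
}

# A one-disease config for parameter-recovery style checks: a single
# urate-driven phenotype plus mortality, no covariate effects.
recovery_config <- function(seed, n = 20000, log_or = log(1.5),
                            baseline = 0.10) {
  sim_config(
    n_individuals = n, n_variants = 60, seed = seed,
    disease_models = list(
      disease_model("008.0", baseline, log_or, onset_rate = 0.15,
                    label = "Target phenotype"),
      disease_model("death", 0.04, 0, onset_rate = 0.08)),
    trajectory_links = list())
}
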