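#' Simulation configuration for a synthetic biobank cohort
#'
#' Collects every knob of the synthetic-data generator: cohort size, variant
#' panel, the genetic architecture of serum urate, covariate moments matching
#' a UK-Biobank-like population, logistic disease models, and directed
#' disease-progression links. All downstream modules are exercised on data
#' from this generator, so its defaults encode the study conditions: urate
#' 5.2 (SD 1.4) mg/dL with 6.06% of variance explained by the variant panel,
#' age 56.7 (8.0) years, BMI 27.4 (4.8), Townsend index -1.5 (3.0), 54%
#' female.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of urate-associated variants simulated.
#' @param allele_freqs effect-allele frequencies, strictly inside (0,1);
#'   default evenly spaced on 0.05..0.5.
#' @param urate_effects per-allele urate effects in mg/dL; default: the first
#'   30% of variants carry equal positive effects, the rest are null.
#' @param target_variance_explained fraction of urate variance attributable
#'   to the variant panel, in `[0, 1)`; `NULL` keeps `urate_effects` on their
#'   literal mg/dL scale and only adds noise up to the target SD.
#' @param covariate_moments named list of moments; see
#'   [default_covariate_moments()].
#' @param disease_models list of [disease_model()] objects; must include a
#'   model with phecode `"death"` for mortality to be simulated.
#' @param trajectory_links list of `list(source=, target=, multiplier=)`
#'   entries: after the source's onset the target's onset hazard is
#'   multiplied by `multiplier`, forcing source-before-target ordering in
#'   expectation when the multiplier exceeds 1. Chained links should be
#'   listed in causal order.
#' @param followup_years length of post-assessment follow-up; onset times are
#'   truncated to this window.
#' @param n_centers number of assessment centres (categorical covariate).
#' @param n_pcs number of genetic principal-component columns (standard
#'   normal stand-ins preserving the adjustment structure).
#' @param n_bp_variants variants in the dedicated blood-pressure score block.
#' @param egfr_urate_cor correlation between eGFR and urate (renal excretion
#'   makes it negative in real data).
#' @param ld_blocks optional list of `list(indices=, rho=)` giving blocks of
#'   variants made mutually correlated (Gaussian-copula factor model) so that
#'   LD clumping has something to prune.
#' @param seed integer master seed; every sub-generator derives its own
#'   stream from it. Mandatory: a seedless simulation refuses to start.
#' @return an object of class `ua_sim_config` (validated list).
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 100,
                       allele_freqs = NULL,
                       urate_effects = NULL,
                       target_variance_explained = 0.0606,
                       covariate_moments = default_covariate_moments(),
                       disease_models = default_disease_models(),
                       trajectory_links = default_trajectory_links(),
                       followup_years = 12,
                       n_centers = 10,
                       n_pcs = 10,
                       n_bp_variants = 10,
                       egfr_urate_cor = -0.3,
                       ld_blocks = NULL,
                       seed = NULL) {
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("a seed is required; a seedless simulation refuses to start")
  }
  seed <- as.integer(seed)
  if (is.null(allele_freqs)) {
    allele_freqs <- seq(0.05, 0.5, length.out = n_variants)
  }
  if (is.null(urate_effects)) {
    urate_effects <- numeric(n_variants)
    urate_effects[seq_len(max(1L, floor(0.3 * n_variants)))] <- 0.1
  }
  if (length(allele_freqs) != n_variants ||
      length(urate_effects) != n_variants) {
    stop("allele_freqs and urate_effects must have length n_variants")
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  if (!is.null(target_variance_explained)) {
    if (target_variance_explained < 0 || target_variance_explained >= 1) {
      stop("target_variance_explained must lie in [0, 1)")
    }
  }
  if (followup_years <= 0) stop("followup_years must be positive")
  for (nm in c("smoking", "alcohol", "physical_activity")) {
    pr <- covariate_moments[[nm]]
    if (abs(sum(pr) - 1) > 1e-6) {
      stop("category probabilities for ", nm, " must sum to 1")
    }
  }
  phecodes <- vapply(disease_models, `[[`, character(1), "phecode")
  if (anyDuplicated(phecodes)) stop("duplicate phecodes in disease_models")
  for (lk in trajectory_links) {
    if (!all(c(lk$source, lk$target) %in% phecodes)) {
      stop("trajectory link references unknown phecode: ",
           lk$source, " -> ", lk$target)
    }
    if (lk$multiplier <= 0) stop("hazard multipliers must be positive")
  }
  tgts <- vapply(trajectory_links, `[[`, character(1), "target")
  tgts <- tgts[vapply(trajectory_links, `[[`, numeric(1), "multiplier") != 1]
  if (anyDuplicated(tgts)) {
    stop("multiple trajectory links into one target are not supported")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 allele_freqs = allele_freqs,
                 urate_effects = urate_effects,
                 target_variance_explained = target_variance_explained,
                 covariate_moments = covariate_moments,
                 disease_models = disease_models,
                 trajectory_links = trajectory_links,
                 followup_years = followup_years,
                 n_centers = as.integer(n_centers),
                 n_pcs = as.integer(n_pcs),
                 n_bp_variants = as.integer(n_bp_variants),
                 egfr_urate_cor = egfr_urate_cor,
                 ld_blocks = ld_blocks,
                 seed = seed),
            class = "ua_sim_config")
}

#' Default covariate moments (UK-Biobank-like population)
#'
#' Means/SDs for continuous covariates and category probabilities for the
#' lifestyle factors. Category probabilities are renormalized over the known
#' levels (the small "unknown" fractions in the source population are folded
#' in proportionally).
#' @return named list of moment vectors.
#' @export
default_covariate_moments <- function() {
  norm1 <- function(x) x / sum(x)
  list(urate = c(mean = 5.2, sd = 1.4),
       age = c(mean = 56.7, sd = 8.0),
       bmi = c(mean = 27.4, sd = 4.8),
       townsend = c(mean = -1.5, sd = 3.0),
       egfr = c(mean = 90, sd = 15),
       sex = c(female = 0.54, male = 0.46),
       smoking = norm1(c(current = 0.104, former = 0.354, never = 0.537)),
       alcohol = norm1(c(current = 0.931, former = 0.035, never = 0.032)),
       physical_activity = norm1(c(light = 0.339, medium = 0.380,
                                   heavy = 0.232)))
}

#' Logistic disease model for the generator
#'
#' Each disease occurs with probability
#' `plogis(qlogis(baseline_prevalence) + log_or_per_sd_urate * z_urate +
#' covariate terms)`; affected persons then receive an onset time from a
#' truncated-exponential waiting-time distribution. Continuous covariates
#' named in `covariate_log_ors` enter as z-scores; `sex` enters as the
#' female indicator.
#'
#' @param phecode phenotype identifier (the sentinel `"death"` marks the
#'   mortality outcome; it also sets the cohort death date and censors later
#'   diagnoses).
#' @param baseline_prevalence probability at covariate means, in (0,1).
#' @param log_or_per_sd_urate log odds ratio per SD of urate.
#' @param covariate_log_ors named list/vector of log-ORs for covariates.
#' @param onset_rate exponential hazard (per year) for the waiting time from
#'   assessment to diagnosis, truncated at the follow-up horizon. Ignored
#'   for the target of an active trajectory link, whose timing comes from
#'   the prevalence-matched hazard process (see [simulate_diagnoses()]).
#' @param prevalent_fraction fraction of affected persons whose first onset
#'   predates assessment (uniform over the five prior years); forced to 0 for
#'   death.
#' @param label human-readable phenotype label.
#' @return an object of class `ua_disease_model`.
#' @export
disease_model <- function(phecode, baseline_prevalence,
                          log_or_per_sd_urate = 0,
                          covariate_log_ors = NULL,
                          onset_rate = 0.15,
                          prevalent_fraction = 0,
                          label = phecode) {
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    stop("baseline_prevalence must lie in (0, 1)")
  }
  if (onset_rate <= 0) stop("onset_rate must be positive")
  if (prevalent_fraction < 0 || prevalent_fraction >= 1) {
    stop("prevalent_fraction must lie in [0, 1)")
  }
  if (identical(phecode, "death")) prevalent_fraction <- 0
  structure(list(phecode = as.character(phecode),
                 label = label,
                 baseline_prevalence = baseline_prevalence,
                 log_or_per_sd_urate = log_or_per_sd_urate,
                 covariate_log_ors = covariate_log_ors,
                 onset_rate = onset_rate,
                 prevalent_fraction = prevalent_fraction),
            class = "ua_disease_model")
}

#' Default disease panel for demonstrations and tests
#'
#' A small panel mixing urate-driven cardiometabolic phenotypes (gout,
#' hypertension, type 2 diabetes, renal failure, heart failure), null
#' phenotypes, and overall mortality, with a planted progression chain
#' hypertension -> heart failure -> death.
#' @return list of [disease_model()] objects.
#' @export
default_disease_models <- function() {
  list(
    disease_model("274.1", 0.05, log(2.0), c(bmi = 0.2, sex = -0.5),
                  onset_rate = 0.2, prevalent_fraction = 0.10,
                  label = "Gout"),
    disease_model("401.1", 0.25, log(1.4), c(age = 0.3, bmi = 0.3),
                  onset_rate = 0.25, prevalent_fraction = 0.15,
                  label = "Essential hypertension"),
    disease_model("250.2", 0.08, log(1.3), c(bmi = 0.4),
                  onset_rate = 0.2, prevalent_fraction = 0.10,
                  label = "Type 2 diabetes"),
    disease_model("585.3", 0.03, log(1.5), c(age = 0.3),
                  onset_rate = 0.12, prevalent_fraction = 0.05,
                  label = "Chronic renal failure"),
    disease_model("428.2", 0.04, log(1.3), c(age = 0.4),
                  onset_rate = 0.12, prevalent_fraction = 0.05,
                  label = "Congestive heart failure"),
    disease_model("244.0", 0.05, 0, NULL, onset_rate = 0.15,
                  prevalent_fraction = 0.10, label = "Hypothyroidism"),
    disease_model("495.0", 0.06, 0, NULL, onset_rate = 0.15,
                  prevalent_fraction = 0.10, label = "Asthma"),
    disease_model("death", 0.06, log(1.15), c(age = 0.6),
                  onset_rate = 0.10, label = "Death")
  )
}

#' @rdname default_disease_models
#' @export
default_trajectory_links <- function() {
  list(list(source = "401.1", target = "428.2", multiplier = 4),
       list(source = "428.2", target = "death", multiplier = 4))
}

# Independent reproducible RNG stream per sub-generator.
derive_seed <- function(seed, label) {
  offsets <- c(genotypes = 1L, urate = 2L, covariates = 3L, diagnoses = 4L,
               sumstats = 5L, bp = 6L, egfr = 7L, matching = 8L)
  off <- offsets[[label]]
  (abs(as.integer(seed)) %% 100000000L) + off * 1000003L
}

#' Simulate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Each variant's dosage is Binomial(2, allele frequency), independent across
#' people. Optional `ld_blocks` in the config induce within-block correlation
#' through a single-factor Gaussian copula (dosages remain marginal
#' Binomial(2, f) hard calls). Variant positions are laid out every 100 kb
#' along one synthetic chromosome so that window-based instrument selection
#' has real coordinates to work with.
#'
#' @param config a [sim_config()].
#' @return integer matrix persons x variants with a `variant_info` attribute
#'   (data.frame: variant_id, chrom, pos, effect_allele, other_allele, eaf).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "ua_sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  m <- config$n_variants
  f <- config$allele_freqs
  g <- matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), nrow = n)
  if (!is.null(config$ld_blocks)) {
    for (bl in config$ld_blocks) {
      idx <- bl$indices
      rho <- bl$rho
      u <- stats::rnorm(n)
      for (j in idx) {
        z <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
        g[, j] <- stats::qbinom(stats::pnorm(z), 2L, f[j])
      }
    }
  }
  ids <- sprintf("v%04d", seq_len(m))
  rownames(g) <- sprintf("P%06d", seq_len(n))
  colnames(g) <- ids
  attr(g, "variant_info") <- data.frame(
    variant_id = ids, chrom = "1", pos = 100000L * seq_len(m),
    effect_allele = "A", other_allele = "G", eaf = f,
    stringsAsFactors = FALSE)
  g
}

#' Simulate serum urate with a controlled genetic component
#'
#' The genetic value is the dosage-weighted sum of `urate_effects`. With a
#' `target_variance_explained` set, genetic value and residual noise are both
#' standardized and mixed so the population mean/SD match the configured
#' moments (default 5.2/1.4 mg/dL) and the realized genetic variance fraction
#' equals the target up to sampling error. With the target `NULL`, effects
#' keep their literal mg/dL scale and noise is added up to the target SD
#' (requiring the genetic variance not to exceed the total). Values are
#' floored at 0.1 mg/dL (urate is positive).
#'
#' @param genotypes matrix from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return numeric urate vector (mg/dL) with attribute `genetic_value`.
#' @export
simulate_urate <- function(genotypes, config) {
  stopifnot(inherits(config, "ua_sim_config"))
  if (ncol(genotypes) != length(config$urate_effects)) {
    stop("genotype matrix not conformable with urate_effects")
  }
  set.seed(derive_seed(config$seed, "urate"))
  mom <- config$covariate_moments$urate
  n <- nrow(genotypes)
  gval <- drop(genotypes %*% config$urate_effects)
  tve <- config$target_variance_explained
  eps <- stats::rnorm(n)
  if (is.null(tve)) {
    vg <- stats::var(gval)
    if (vg > mom[["sd"]]^2) {
      stop("genetic variance exceeds the target urate variance; ",
           "set target_variance_explained to rescale")
    }
    urate <- mom[["mean"]] + (gval - mean(gval)) +
      eps * sqrt(mom[["sd"]]^2 - vg)
  } else if (all(config$urate_effects == 0) || stats::var(gval) == 0) {
    urate <- mom[["mean"]] + mom[["sd"]] * (eps - mean(eps)) / stats::sd(eps)
  } else {
    gz <- (gval - mean(gval)) / stats::sd(gval)
    ez <- (eps - mean(eps)) / stats::sd(eps)
    # orthogonalize noise against the genetic value so the realized variance
    # split is exact rather than approximate
    ez <- ez - gz * sum(ez * gz) / sum(gz * gz)
    ez <- ez / stats::sd(ez)
    urate <- mom[["mean"]] +
      mom[["sd"]] * (sqrt(tve) * gz + sqrt(1 - tve) * ez)
  }
  urate <- pmax(urate, 0.1)
  attr(urate, "genetic_value") <- gval
  urate
}

#' Simulate covariates matching the configured moments
#'
#' Continuous covariates are Gaussian at the configured mean/SD; lifestyle
#' factors are categorical at the configured probabilities; assessment centre
#' is uniform over `n_centers` levels; `n_pcs` standard-normal columns stand
#' in for genetic principal components; assessment dates are uniform over a
#' four-year recruitment window starting 2006-01-01.
#'
#' @param config a [sim_config()].
#' @return data.frame keyed by `person_id`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "ua_sim_config"))
  set.seed(derive_seed(config$seed, "covariates"))
  n <- config$n_individuals
  mom <- config$covariate_moments
  rcont <- function(m) stats::rnorm(n, m[["mean"]], m[["sd"]])
  rcat <- function(pr) factor(sample(names(pr), n, TRUE, prob = pr),
                              levels = names(pr))
  out <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    sex = stats::rbinom(n, 1L, mom$sex[["female"]]),  # 1 = female
    age = rcont(mom$age),
    bmi = rcont(mom$bmi),
    townsend = rcont(mom$townsend),
    smoking = rcat(mom$smoking),
    alcohol = rcat(mom$alcohol),
    physical_activity = rcat(mom$physical_activity),
    assessment_center = factor(sample(seq_len(config$n_centers), n, TRUE)),
    assessment_date = as.Date("2006-01-01") + sample.int(1461L, n, TRUE) - 1L,
    stringsAsFactors = FALSE)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n)
  colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
  cbind(out, as.data.frame(pcs))
}

# Inverse-CDF draw from an exponential truncated to (0, horizon],
# with a hazard change-point at `ts` where the rate is multiplied by `mult`.
truncated_onset <- function(u, rate, horizon, ts = NULL, mult = 1) {
  if (is.null(ts) || mult == 1) {
    h_total <- rate * horizon
    h <- -log1p(-u * (1 - exp(-h_total)))
    return(h / rate)
  }
  ts <- pmin(ts, horizon)
  h_total <- rate * ts + mult * rate * (horizon - ts)
  h <- -log1p(-u * (1 - exp(-h_total)))
  ifelse(h <= rate * ts, h / rate, ts + (h - rate * ts) / (mult * rate))
}

#' Simulate dated diagnoses, progression links and death
#'
#' Disease status is Bernoulli under each model's logistic liability (urate
#' entering per SD). Affected persons receive an onset drawn from an
#' exponential waiting time truncated at the follow-up horizon; a configured
#' `prevalent_fraction` of them instead get a pre-assessment onset so that
#' washout and prior-history logic have work to do. The target of a
#' trajectory link is instead generated from a per-person hazard process
#' whose baseline rate reproduces the logistic probability over follow-up
#' and which is multiplied by the link factor after the source's onset: a
#' unit multiplier is exactly the logistic model, larger multipliers raise
#' both the post-source target risk and the source-before-target ordering.
#' The `"death"` phecode sets the death date and censors any later
#' diagnoses.
#'
#' @param cohort data.frame with `person_id`, `urate`, `assessment_date` and
#'   the covariates named by the disease models.
#' @param config a [sim_config()].
#' @return EventTable data.frame: `person_id`, `phecode`, `date`, `source`,
#'   ISO dates; attribute `death_date` (named Date vector, NA if alive).
#' @export
simulate_diagnoses <- function(cohort, config) {
  stopifnot(inherits(config, "ua_sim_config"))
  set.seed(derive_seed(config$seed, "diagnoses"))
  n <- nrow(cohort)
  zu <- (cohort$urate - mean(cohort$urate)) / stats::sd(cohort$urate)
  horizon <- config$followup_years

  zcov <- function(nm) {
    v <- cohort[[nm]]
    if (is.null(v)) stop("cohort lacks covariate ", nm)
    if (nm == "sex") return(as.numeric(v))
    (v - mean(v)) / stats::sd(v)
  }

  phecodes <- vapply(config$disease_models, `[[`, character(1), "phecode")
  affected <- matrix(FALSE, n, length(phecodes),
                     dimnames = list(NULL, phecodes))
  onset <- matrix(NA_real_, n, length(phecodes),
                  dimnames = list(NULL, phecodes))  # years from assessment

  for (k in seq_along(config$disease_models)) {
    dm <- config$disease_models[[k]]
    lp <- stats::qlogis(dm$baseline_prevalence) + dm$log_or_per_sd_urate * zu
    if (length(dm$covariate_log_ors)) {
      for (nm in names(dm$covariate_log_ors)) {
        lp <- lp + dm$covariate_log_ors[[nm]] * zcov(nm)
      }
    }
    aff <- stats::runif(n) < stats::plogis(lp)
    affected[, k] <- aff
    na <- sum(aff)
    if (na > 0L) {
      t0 <- truncated_onset(stats::runif(na), dm$onset_rate, horizon)
      if (dm$prevalent_fraction > 0) {
        prev <- stats::runif(na) < dm$prevalent_fraction
        t0[prev] <- -stats::runif(sum(prev), 1 / 365.25, 5)
      }
      onset[aff, k] <- t0
    }
  }

  # Progression links: the target of a link is re-simulated as a per-person
  # hazard process whose baseline rate solves 1 - exp(-r T) = p (the logistic
  # probability), multiplied by the link factor after the source's onset, the
  # person being affected iff the onset lands inside follow-up. With no
  # source onset this reproduces the logistic margin exactly, so a unit
  # multiplier is a no-op (and is skipped); above 1 it raises both the
  # post-source risk of the target and the source-before-target ordering.
  # Links are processed in the given order so causally listed chains
  # propagate.
  lp_store <- list()
  for (k in seq_along(config$disease_models)) {
    dm <- config$disease_models[[k]]
    lp <- stats::qlogis(dm$baseline_prevalence) + dm$log_or_per_sd_urate * zu
    if (length(dm$covariate_log_ors)) {
      for (nm in names(dm$covariate_log_ors)) {
        lp <- lp + dm$covariate_log_ors[[nm]] * zcov(nm)
      }
    }
    lp_store[[phecodes[k]]] <- lp
  }
  for (lk in config$trajectory_links) {
    if (lk$multiplier == 1) next
    src <- lk$source; tgt <- lk$target
    dm <- config$disease_models[[match(tgt, phecodes)]]
    p_i <- stats::plogis(lp_store[[tgt]])
    r_i <- -log1p(-p_i) / horizon
    h <- -log1p(-stats::runif(n))  # unit-exponential cumulative hazard draw
    ts <- ifelse(affected[, src] & !is.na(onset[, src]) & onset[, src] > 0,
                 onset[, src], Inf)
    t_new <- ifelse(h <= r_i * pmin(ts, horizon) | !is.finite(ts),
                    h / r_i,
                    ts + (h - r_i * ts) / (lk$multiplier * r_i))
    aff <- t_new <= horizon
    onset[, tgt] <- ifelse(aff, t_new, NA_real_)
    affected[, tgt] <- aff
    if (dm$prevalent_fraction > 0) {
      ia <- which(aff)
      prev <- ia[stats::runif(length(ia)) < dm$prevalent_fraction]
      onset[prev, tgt] <- -stats::runif(length(prev), 1 / 365.25, 5)
    }
  }

  # death censors everything after it
  death_years <- if ("death" %in% phecodes) onset[, "death"] else rep(NA_real_, n)
  if ("death" %in% phecodes) {
    for (k in which(phecodes != "death")) {
      late <- !is.na(onset[, k]) & !is.na(death_years) & onset[, k] > death_years
      onset[late, k] <- NA_real_
      affected[late, k] <- FALSE
    }
  }

  keep <- which(!is.na(onset), arr.ind = TRUE)
  events <- data.frame(
    person_id = cohort$person_id[keep[, 1L]],
    phecode = phecodes[keep[, 2L]],
    date = cohort$assessment_date[keep[, 1L]] +
      round(onset[keep] * 365.25),
    source = "registry",
    stringsAsFactors = FALSE)
  events <- events[order(events$person_id, events$phecode), , drop = FALSE]
  rownames(events) <- NULL
  dd <- cohort$assessment_date + round(death_years * 365.25)
  names(dd) <- cohort$person_id
  attr(events, "death_date") <- dd
  events
}

#' Per-variant summary statistics (GWAS stand-in)
#'
#' Simple linear regression of urate on each variant's dosage, unadjusted:
#' slope, standard error, and the two-sided normal p-value of beta/SE. This
#' is the summary-statistics table instrument selection consumes.
#' Monomorphic variants have no defined SE; they are excluded and listed in
#' the `excluded` attribute.
#'
#' @param genotypes matrix from [simulate_genotypes()].
#' @param urate numeric urate vector.
#' @return VariantTable data.frame: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `eaf`, `beta`, `se`, `pvalue`.
#' @export
emit_summary_stats <- function(genotypes, urate) {
  n <- nrow(genotypes)
  info <- attr(genotypes, "variant_info")
  if (is.null(info)) {
    info <- data.frame(variant_id = colnames(genotypes), chrom = "1",
                       pos = seq_len(ncol(genotypes)), effect_allele = "A",
                       eaf = colMeans(genotypes) / 2,
                       stringsAsFactors = FALSE)
  }
  y <- as.numeric(urate) - mean(urate)
  gc <- sweep(genotypes, 2, colMeans(genotypes))
  sxx <- colSums(gc^2)
  mono <- sxx == 0
  sxy <- drop(crossprod(gc, y))
  beta <- sxy / sxx
  rss <- sum(y^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  p <- pmin(2 * stats::pnorm(-abs(beta / se)), 1)
  out <- data.frame(variant_id = info$variant_id, chrom = info$chrom,
                    pos = info$pos, effect_allele = info$effect_allele,
                    eaf = colMeans(genotypes) / 2,
                    beta = beta, se = se, pvalue = p,
                    stringsAsFactors = FALSE)
  excluded <- out$variant_id[mono]
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Simulate a complete synthetic study
#'
#' Runs every sub-generator under its own seed stream and assembles the
#' pieces: cohort table (covariates, urate, eGFR correlated with urate,
#' death date), genotype matrix, variant summary statistics, diagnosis
#' events, and a dedicated blood-pressure genetic score built from its own
#' variant block (equal weights, frequency 0.3) for the factorial design.
#'
#' @param config a [sim_config()].
#' @return object of class `ua_study`: list with `config`, `cohort`,
#'   `genotypes`, `variant_info`, `events`, `summary_stats`, `bp_score`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "ua_sim_config"))
  genotypes <- simulate_genotypes(config)
  urate <- simulate_urate(genotypes, config)
  cohort <- simulate_covariates(config)
  cohort$urate <- as.numeric(urate)

  set.seed(derive_seed(config$seed, "egfr"))
  mom <- config$covariate_moments$egfr
  rho <- config$egfr_urate_cor
  zu <- (cohort$urate - mean(cohort$urate)) / stats::sd(cohort$urate)
  cohort$egfr <- mom[["mean"]] +
    mom[["sd"]] * (rho * zu + sqrt(1 - rho^2) * stats::rnorm(nrow(cohort)))

  events <- simulate_diagnoses(cohort, config)
  cohort$death_date <- as.Date(attr(events, "death_date")[cohort$person_id])

  set.seed(derive_seed(config$seed, "bp"))
  nb <- config$n_bp_variants
  bp_g <- matrix(stats::rbinom(nrow(cohort) * nb, 2L, 0.3), ncol = nb)
  bp_score <- drop(bp_g %*% rep(1, nb))

  structure(list(config = config,
                 cohort = cohort,
                 genotypes = genotypes,
                 variant_info = attr(genotypes, "variant_info"),
                 events = events,
                 summary_stats = emit_summary_stats(genotypes, urate),
                 bp_score = bp_score),
            class = "ua_study")
}

#' @export
print.ua_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d persons, %d variants, %d diagnosis events, %d deaths\n",
              nrow(x$cohort), ncol(x$genotypes), nrow(x$events),
              sum(!is.na(x$cohort$death_date))))
  invisible(x)
}
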