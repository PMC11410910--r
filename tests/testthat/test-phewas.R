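make_summary <- function(p, pos = NULL, beta = NULL, chrom = "1") {
  n <- length(p)
  data.frame(variant_id = paste0("v", seq_len(n)),
             chrom = rep_len(chrom, n),
             pos = if (is.null(pos)) 100000 * seq_len(n) else pos,
             effect_allele = "A", eaf = 0.3,
             beta = if (is.null(beta)) rep(0.1, n) else beta,
             se = 0.01, pvalue = p, stringsAsFactors = FALSE)
}

r2_matrix <- function(n, pairs = list()) {
  m <- diag(n)
  dimnames(m) <- list(paste0("v", 1:n), paste0("v", 1:n))
  for (p in pairs) m[p$i, p$j] <- m[p$j, p$i] <- p$r2
  m
}

test_that("greedy clumping keeps the strongest of each linked set", {
  ss <- make_summary(c(1e-10, 1e-9, 1e-8 * 0.99))
  ld <- r2_matrix(3, list(list(i = 1, j = 2, r2 = 0.5)))
  def <- select_instruments(ss, ld, p_threshold = 5e-8, r2_threshold = 0.01)
  expect_setequal(def$variant_ids, c("v1", "v3"))

  # independent pairs: everything significant is kept
  def2 <- select_instruments(ss, r2_matrix(3), r2_threshold = 0.01)
  expect_setequal(def2$variant_ids, c("v1", "v2", "v3"))
  expect_error(select_instruments(make_summary(c(0.5, 0.2)), r2_matrix(2)),
               "threshold")
})

test_that("clumping satisfies the keep/drop property on random instances", {
  set.seed(501)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    ss <- make_summary(runif(n, 1e-12, 1e-8))
    m <- diag(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- sample(c(0, runif(1)), 1, prob = c(0.6, 0.4))
    }
    dimnames(m) <- list(ss$variant_id, ss$variant_id)
    thr <- 0.1
    def <- select_instruments(ss, m, r2_threshold = thr)
    kept <- def$variant_ids
    dropped <- setdiff(ss$variant_id, kept)
    # no kept pair violates the threshold
    if (length(kept) > 1) {
      expect_true(all(m[kept, kept][upper.tri(diag(length(kept)))] < thr))
    }
    # every dropped variant conflicts with a kept, more significant variant
    for (d in dropped) {
      conf <- kept[m[d, kept] >= thr]
      expect_true(any(ss$pvalue[match(conf, ss$variant_id)] <=
                        ss$pvalue[match(d, ss$variant_id)]))
    }
  }
})

test_that("score computation is a plain weighted dosage sum", {
  g <- matrix(c(0, 1, 2, 2, 1, 0), ncol = 2,
              dimnames = list(paste0("P", 1:3), c("v1", "v2")))
  def1 <- structure(list(variant_ids = "v1", weights = 1,
                         standardize = FALSE), class = "ua_prs_def")
  expect_equal(unname(compute_prs(g, def1)), c(0, 1, 2))
  def2 <- structure(list(variant_ids = c("v1", "v2"),
                         weights = c(0.3, -0.2), standardize = FALSE),
                    class = "ua_prs_def")
  expect_equal(unname(compute_prs(g, def2)), c(-0.4, 0.1, 0.6))
  def0 <- structure(list(variant_ids = c("v1", "v2"), weights = c(0, 0),
                         standardize = TRUE), class = "ua_prs_def")
  expect_error(compute_prs(g, def0), "zero variance")
  def3 <- structure(list(variant_ids = "v9", weights = 1,
                         standardize = FALSE), class = "ua_prs_def")
  expect_error(compute_prs(g, def3), "v9")
})

test_that("the observational scan recovers a planted effect and drops small phenotypes", {
  cfg <- recovery_config(seed = 51, n = 12000)
  st <- simulate_study(cfg)
  map <- phecode_identity_map(c("008.0", "death"))
  mapped <- map_events(st$events, map)
  filt <- incident_filter(mapped, st$cohort)
  phen <- define_case_control(filt, map, st$cohort, min_cases = 200)
  res <- run_obs_phewas(st$cohort, phen)
  row <- res[res$phecode == "008.0", ]
  expect_equal(nrow(res), length(phen))
  expect_lt(abs(row$beta - log(1.5)), 3 * row$se)
  expect_true(row$ci_low <= row$or && row$or <= row$ci_high)

  # a phenotype under the case floor is absent
  phen_high <- define_case_control(filt, map, st$cohort,
                                   min_cases = nrow(st$cohort))
  res2 <- run_obs_phewas(st$cohort, phen_high)
  expect_equal(nrow(res2), 0L)
})

test_that("the exposure coefficient ignores covariate column order", {
  cfg <- small_config(seed = 52)
  st <- simulate_study(cfg)
  map <- phecode_identity_map(
    vapply(cfg$disease_models, `[[`, character(1), "phecode"))
  phen <- define_case_control(map_events(st$events, map), map, st$cohort,
                              min_cases = 100)
  a <- run_obs_phewas(st$cohort, phen,
                      covariates = c("age", "sex", "bmi", "townsend"))
  b <- run_obs_phewas(st$cohort, phen,
                      covariates = c("townsend", "bmi", "sex", "age"))
  expect_equal(a$beta, b$beta, tolerance = 1e-8)
})

test_that("PRS scan runs on the all-case phenome and matches the obs direction", {
  cfg <- recovery_config(seed = 53, n = 15000)
  st <- simulate_study(cfg)
  map <- phecode_identity_map(c("008.0", "death"))
  mapped <- map_events(st$events, map)
  phen_all <- define_case_control(mapped, map, st$cohort, min_cases = 200)
  def <- select_instruments(st$summary_stats, st$genotypes,
                            p_threshold = 1e-4)
  prs <- compute_prs(st$genotypes, def)
  res <- run_prs_phewas(st$cohort, phen_all, prs)
  filt <- incident_filter(mapped, st$cohort)
  phen_obs <- define_case_control(filt, map, st$cohort, min_cases = 200)
  obs <- run_obs_phewas(st$cohort, phen_obs)
  expect_equal(sign(res$beta[res$phecode == "008.0"]),
               sign(obs$beta[obs$phecode == "008.0"]))
})

test_that("overlap keeps only both-significant, direction-consistent phenotypes", {
  mk <- function(phecode, beta, fdr) {
    data.frame(phecode = phecode, label = phecode, beta = beta,
               fdr_p = fdr, stringsAsFactors = FALSE)
  }
  obs <- mk(c("a", "b", "c", "d", "e"), c(0.3, 0.2, -0.4, 0.5, 0.1),
            c(0.01, 0.01, 0.01, 0.30, 0.01))
  prs <- mk(c("a", "b", "c", "d", "e"), c(0.1, -0.2, -0.1, 0.4, 0.2),
            c(0.01, 0.01, 0.01, 0.01, 0.30))
  out <- overlap_consistent(obs, prs)
  expect_setequal(out$phecode, c("a", "c"))  # b flips sign, d/e miss FDR
  expect_equal(nrow(overlap_consistent(mk("a", 1, 0.5), mk("a", 1, 0.01))), 0L)
})

test_that("stratified scan skips small strata and flags planted heterogeneity", {
  set.seed(54)
  n <- 20000
  cohort <- data.frame(person_id = sprintf("P%05d", 1:n),
                       sex = rbinom(n, 1, 0.5),
                       age = rnorm(n, 56, 8),
                       bmi = rnorm(n, 27, 4),
                       townsend = rnorm(n, -1.5, 3),
                       smoking = factor(sample(c("never", "ever"), n, TRUE)),
                       alcohol = factor(sample(c("current", "never"), n, TRUE)),
                       physical_activity = factor(sample(c("low", "high"), n, TRUE)),
                       urate = rnorm(n, 5.2, 1.4),
                       assessment_date = as.Date("2008-06-01"),
                       stringsAsFactors = FALSE)
  zu <- scale(cohort$urate)[, 1]
  # effect in women only (log OR 0.35/SD), none in men
  p <- plogis(qlogis(0.08) + 0.35 * zu * (cohort$sex == 1))
  carriers <- cohort$person_id[runif(n) < p]
  map <- phecode_identity_map("433.0", "Cerebral occlusion")
  ev <- toy_events(carriers, rep("433.0", length(carriers)), 500,
                   origin = as.Date("2008-06-01"))
  phen <- define_case_control(map_events(ev, map), map, cohort,
                              min_cases = 200)
  st <- stratified_scan(cohort, phen, "sex", exposure = "urate",
                        min_cases = 200)
  expect_equal(nrow(st$heterogeneity), 1L)
  expect_lt(st$heterogeneity$p, 0.05)
  expect_error(stratified_scan(cohort, phen, rep(1, n)), "constant")
  # raise the floor beyond one stratum's cases: phenotype leaves the comparison
  st2 <- stratified_scan(cohort, phen, "sex", exposure = "urate",
                         min_cases = n)
  expect_equal(NROW(st2$heterogeneity), 0L)
})

test_that("non-linearity follow-up returns one LR test per phenotype", {
  cfg <- recovery_config(seed = 55, n = 8000)
  st <- simulate_study(cfg)
  map <- phecode_identity_map(c("008.0", "death"))
  phen <- define_case_control(map_events(st$events, map), map, st$cohort,
                              min_cases = 100)
  def <- select_instruments(st$summary_stats, st$genotypes,
                            p_threshold = 1e-3)
  prs <- compute_prs(st$genotypes, def)
  nl <- nonlinearity_followup(st$cohort, phen, prs, c("008.0", "unknown"))
  expect_equal(nl$phecode, "008.0")
  expect_equal(nl$df, 3L)
  expect_true(nl$p > 0 && nl$p <= 1)
  expect_true("unknown" %in% attr(nl, "skipped"))
})
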