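test_that("configuration invariants are enforced", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(n_variants = 3, allele_freqs = c(0, 0.2, 0.3),
                          urate_effects = c(0, 0, 0), seed = 1),
               "strictly inside")
  expect_error(sim_config(target_variance_explained = 1, seed = 1), "0, 1")
  expect_error(sim_config(trajectory_links = list(
    list(source = "nope", target = "death", multiplier = 2)), seed = 1),
    "unknown phecode")
  expect_error(disease_model("x", 0), "0, 1")
})

test_that("genotypes are reproducible, integer dosages, with correct frequency", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 5,
                    allele_freqs = rep(0.5, 5), urate_effects = rep(0, 5),
                    seed = 21)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% 0:2))
  # Binomial(2, 0.5): mean dosage 1 with SE sqrt(0.5/10000)
  expect_true(all(abs(colMeans(g1) - 1) < 0.03))
})

test_that("genotype frequencies satisfy Hardy-Weinberg", {
  cfg <- sim_config(n_individuals = 5000, n_variants = 60, seed = 22)
  g <- simulate_genotypes(cfg)
  rejections <- 0L
  for (j in seq_len(ncol(g))) {
    obs <- tabulate(g[, j] + 1L, 3L)
    f <- (obs[2] + 2 * obs[3]) / (2 * sum(obs))
    expected <- sum(obs) * c((1 - f)^2, 2 * f * (1 - f), f^2)
    chi2 <- sum((obs - expected)^2 / pmax(expected, 1e-12))
    if (pchisq(chi2, 1, lower.tail = FALSE) < 0.001) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)  # 60 null tests at alpha 0.001
})

test_that("LD blocks induce correlation without breaking the margins", {
  cfg <- sim_config(n_individuals = 8000, n_variants = 10,
                    allele_freqs = rep(0.3, 10), urate_effects = rep(0, 10),
                    ld_blocks = list(list(indices = 1:4, rho = 0.8)),
                    seed = 23)
  g <- simulate_genotypes(cfg)
  r2_in <- cor(g[, 1], g[, 2])^2
  r2_out <- cor(g[, 1], g[, 9])^2
  expect_gt(r2_in, 0.3)
  expect_lt(r2_out, 0.01)
  expect_true(all(abs(colMeans(g) / 2 - 0.3) < 0.02))
})

test_that("urate hits the target moments and variance explained", {
  cfg <- sim_config(n_individuals = 50000, seed = 24)
  g <- simulate_genotypes(cfg)
  u <- simulate_urate(g, cfg)
  expect_lt(abs(mean(u) - 5.2), 0.05)
  expect_lt(abs(sd(u) - 1.4), 0.05)
  r2 <- summary(lm(u ~ attr(u, "genetic_value")))$r.squared
  expect_gt(r2, 0.05)
  expect_lt(r2, 0.07)
})

test_that("null genetics give zero variance explained; raw-effect mode keeps the mg/dL scale", {
  cfg0 <- sim_config(n_individuals = 5000, n_variants = 10,
                     allele_freqs = rep(0.3, 10), urate_effects = rep(0, 10),
                     seed = 25)
  u0 <- simulate_urate(simulate_genotypes(cfg0), cfg0)
  expect_equal(var(attr(u0, "genetic_value")), 0)
  expect_lt(abs(sd(u0) - 1.4), 0.05)

  cfg1 <- sim_config(n_individuals = 50000, n_variants = 10,
                     allele_freqs = rep(0.3, 10),
                     urate_effects = c(0.2, rep(0, 9)),
                     target_variance_explained = NULL, seed = 26)
  g1 <- simulate_genotypes(cfg1)
  u1 <- simulate_urate(g1, cfg1)
  ss <- emit_summary_stats(g1, u1)
  expect_lt(abs(ss$beta[1] - 0.2), 0.02)
})

test_that("summary statistics agree with lm and their own normal p-values", {
  cfg <- sim_config(n_individuals = 3000, n_variants = 20, seed = 27)
  g <- simulate_genotypes(cfg)
  u <- simulate_urate(g, cfg)
  ss <- emit_summary_stats(g, u)
  for (j in c(1, 7, 15)) {
    o <- summary(lm(u ~ g[, j]))$coefficients
    expect_equal(ss$beta[j], o[2, 1], tolerance = 1e-8)
    expect_equal(ss$se[j], o[2, 2], tolerance = 1e-8)
  }
  expect_equal(ss$pvalue, pmin(2 * pnorm(-abs(ss$beta / ss$se)), 1),
               tolerance = 1e-10)
})

test_that("monomorphic variants are excluded and flagged", {
  g <- cbind(v1 = rbinom(200, 2, 0.4), v2 = rep(2L, 200))
  ss <- emit_summary_stats(g, rnorm(200, 5.2, 1.4))
  expect_identical(attr(ss, "excluded"), "v2")
  expect_false("v2" %in% ss$variant_id)
})

test_that("diagnosis generation is reproducible and respects death censoring", {
  cfg <- small_config(seed = 28)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$cohort, s2$cohort)

  ev <- s1$events
  dd <- s1$cohort$death_date[match(ev$person_id, s1$cohort$person_id)]
  expect_true(all(is.na(dd) | ev$date <= dd))
  # death events are never prevalent
  death_ev <- ev[ev$phecode == "death", ]
  ad <- s1$cohort$assessment_date[match(death_ev$person_id,
                                        s1$cohort$person_id)]
  expect_true(all(death_ev$date > ad))
})

test_that("urate log odds ratio is recovered by a logistic refit", {
  cfg <- recovery_config(seed = 29)
  st <- simulate_study(cfg)
  co <- st$cohort
  zu <- (co$urate - mean(co$urate)) / sd(co$urate)
  y <- as.integer(co$person_id %in%
                    st$events$person_id[st$events$phecode == "008.0"])
  fit <- fit_logistic(cbind(intercept = 1, zu = zu), y)
  expect_lt(abs(fit$coefficients[["zu"]] - log(1.5)),
            3 * fit$standard_errors[["zu"]])
})

test_that("a unit hazard multiplier leaves the ordering exchangeable; a strong one forces it", {
  null_models <- list(  # equal onset rates: ordering exchangeable under m = 1
    disease_model("100.0", 0.12, 0, onset_rate = 0.2),
    disease_model("200.0", 0.12, 0, onset_rate = 0.2))
  strong_models <- list(  # slow target hazard leaves room for the boost
    disease_model("100.0", 0.12, 0, onset_rate = 0.2),
    disease_model("200.0", 0.12, 0, onset_rate = 0.08))
  cfg_null <- sim_config(n_individuals = 8000, n_variants = 10,
                         allele_freqs = rep(0.3, 10),
                         urate_effects = rep(0, 10),
                         disease_models = null_models,
                         trajectory_links = list(
                           list(source = "100.0", target = "200.0",
                                multiplier = 1)),
                         seed = 30)
  st <- simulate_study(cfg_null)
  ev <- st$events
  w <- reshape(ev[, c("person_id", "phecode", "date")],
               idvar = "person_id", timevar = "phecode", direction = "wide")
  both <- w[!is.na(w$date.100.0) & !is.na(w$date.200.0), ]
  fwd <- sum(both$date.100.0 < both$date.200.0)
  rev_ <- sum(both$date.200.0 < both$date.100.0)
  expect_gt(binom.test(fwd, fwd + rev_, 0.5)$p.value, 1e-3)

  cfg_str <- sim_config(n_individuals = 20000, n_variants = 10,
                        allele_freqs = rep(0.3, 10),
                        urate_effects = rep(0, 10),
                        disease_models = strong_models,
                        trajectory_links = list(
                          list(source = "100.0", target = "200.0",
                               multiplier = 5)),
                        seed = 31)
  st2 <- simulate_study(cfg_str)
  ev2 <- st2$events
  w2 <- reshape(ev2[, c("person_id", "phecode", "date")],
                idvar = "person_id", timevar = "phecode", direction = "wide")
  both2 <- w2[!is.na(w2$date.100.0) & !is.na(w2$date.200.0), ]
  fwd2 <- sum(both2$date.100.0 < both2$date.200.0)
  rev2 <- sum(both2$date.200.0 < both2$date.100.0)
  expect_gt(fwd2 / (fwd2 + rev2), 0.5)
  expect_lt(binom.test(fwd2, fwd2 + rev2, 0.5)$p.value, 0.05)
})
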