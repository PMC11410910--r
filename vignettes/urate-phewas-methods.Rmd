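---
title: "Methods: phenome-wide association, disease trajectories and factorial MR for serum urate"
author: "uratephewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide association, disease trajectories and factorial MR for serum urate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uratephewas)
```

# What the package does

`uratephewas` implements a complete analysis chain for asking what elevated
serum uric acid does to human health in a biobank-scale cohort, and whether
urate-lowering drugs could be repurposed:

1. **Phenome construction.** Dated diagnosis codes are grouped into
   phecodes; each phenotype's controls exclude carriers of clinically
   neighbouring codes (the exclusion range); phenotypes with fewer than 200
   cases are dropped; and the observational analysis keeps only incident
   cases diagnosed more than six months after the urate measurement.
2. **Two phenome-wide scans.** An observational scan (measured urate,
   adjusted for age, sex, BMI, Townsend deprivation, smoking, physical
   activity and alcohol) and a genetic scan (a weighted polygenic score of
   urate-associated variants, adjusted for age, sex, assessment centre and
   10 genetic principal components), each with Benjamini–Hochberg control.
   Phenotypes significant in both scans with the same effect direction form
   the replicated "overlap" set.
3. **Stratified scans and non-linearity.** Sex- (or kidney-function-)
   stratified refits with a two-sample z-test on the log odds ratios, and a
   five-knot restricted-cubic-spline likelihood-ratio test for departures
   from log-linearity in the genetic score.
4. **Disease trajectories.** Among persons with urate above the cohort
   median, every unordered pair of replicated phenotypes (plus death) is
   screened in three steps: co-occurrence in at least 1% of the subset, an
   exact binomial test on the temporal ordering, and a matched conditional
   logistic regression for the risk of D2 after D1. Surviving directed
   pairs form a progression network whose weak components are reported as
   clusters.
5. **Drug repurposing and factorial MR.** Variants within 500 kb of a
   drug-target gene, urate-associated at P < 0.05 and LD-pruned at
   r² < 0.2, proxy each urate-lowering drug class; the score is oriented so
   higher means lower genetically predicted urate, so OR < 1 reads as
   protection. A 2×2 median split of the urate and blood-pressure genetic
   scores emulates a factorial trial of the two interventions.

Because individual-level biobank data cannot be redistributed, the package
ships a synthetic-cohort generator with the same statistical structure, and
every stage is validated against it.

# The statistical kernel

The scans rest on a small self-contained kernel, written for the package
because its behaviour is asserted against closed forms in the test suite:

* `fit_logistic()` — maximum likelihood by iteratively reweighted least
  squares with step-halving; convergence when the largest score component
  falls below 1e-8, at most 50 iterations. Wald standard errors come from
  the inverse observed information. Perfect or quasi-separation surfaces as
  non-convergence (additionally flagged when any coefficient exceeds 15 in
  absolute value, i.e. odds ratios beyond e¹⁵); affected phenotypes are
  skipped with a log entry rather than penalized, mirroring common PheWAS
  practice. Rank-deficient designs raise an error naming the collinear
  columns.
* `fit_conditional_logistic()` — Newton–Raphson on the conditional
  likelihood for matched sets with exactly one case
  (\(\prod_s e^{x_{case}\beta} / \sum_j e^{x_j\beta}\)); strata without
  exactly one case and one comparison subject are dropped and counted. The
  general multi-case conditional likelihood is exponential in the case
  count and is not needed by the 1:k matching the trajectory step uses.
* `binomial_direction_test()` — exact two-sided binomial p at null 0.5,
  minlike convention (sum of outcome probabilities not exceeding the
  observed one), capped at 1.
* `bh_fdr()` — the step-up adjustment
  \(\tilde p_{(i)} = \min_{j \ge i} m\,p_{(j)}/j\), discoveries at
  adjusted p < q.
* `heterogeneity_z()` — \(z = (\beta_1-\beta_2)/\sqrt{se_1^2+se_2^2}\);
  used for sex and eGFR comparisons. The criterion for calling an effect
  sex-specific is left to the caller; the package only reports the test.
* `rcs_basis()` — the restricted truncated-power cubic spline basis
  (linear beyond the boundary knots), scaled by \((t_k-t_1)^2\) for
  conditioning; with five knots this adds three non-linear columns, so the
  likelihood-ratio test for non-linearity has 3 degrees of freedom.

`glm()`, `survival::clogit()`, `binom.test()` and `p.adjust()` are used in
the test suite as independent oracles for these routines, never as the
implementation.

# The synthetic cohort: what it emulates

`sim_config()` fixes the study conditions; its defaults are the conditions
under which all packaged results are produced.

* **Genotypes** are Binomial(2, f) hard calls under Hardy–Weinberg
  equilibrium, frequencies evenly spaced over 0.05–0.5, laid out every
  100 kb along one synthetic chromosome so window-based instrument
  selection is meaningful. An optional single-factor Gaussian copula
  creates LD blocks for the clumping logic to prune; no attempt is made at
  realistic LD decay, imputation artefacts or relatedness.
* **Urate** mixes a standardized genetic value with orthogonalized Gaussian
  noise so the population mean/SD are 5.2/1.4 mg/dL and the realized
  variance explained equals the 6.06% target essentially exactly. Setting
  `target_variance_explained = NULL` instead keeps the literal mg/dL
  per-allele effects and fills the remaining variance with noise, which is
  the mode used when per-variant effect recovery is tested.
* **Covariates** match the intended population moments: age 56.7 (8.0)
  years, BMI 27.4 (4.8) kg/m², Townsend −1.5 (3.0), 54% female; smoking,
  alcohol and physical activity are categorical with probabilities
  renormalized over the known levels; assessment centre (10 levels) and 10
  standard-normal "principal components" preserve the genetic adjustment
  structure without a genotype PCA. eGFR is Gaussian (90, 15) with a −0.3
  correlation with urate, reflecting renal urate excretion, which gives the
  kidney-function-stratified scan a realistic stratifier.
* **Diseases** follow logistic liabilities: affection probability
  `plogis(qlogis(prevalence) + β·z_urate + covariate terms)`. Logistic
  (rather than probit) liability was chosen deliberately so that the
  generative coefficient is exactly the estimand of the analysis model and
  parameter-recovery tests are unbiased in expectation. Onsets are
  truncated-exponential waiting times after assessment (rates ~0.1–0.25 per
  year over a 12-year follow-up); a configurable fraction of affected
  persons gets a pre-assessment onset so washout and prior-history logic
  are exercised.
* **Progression links.** The target of a link is generated from a
  per-person hazard process whose baseline rate solves
  \(1-e^{-rT} = p\) for the logistic probability \(p\), multiplied by the
  link factor after the source's onset, the person being affected iff the
  onset lands inside follow-up. A unit multiplier reproduces the logistic
  margin exactly (and is treated as a no-op), so the null-ordering case is
  exchangeable; multipliers above 1 raise both the post-source risk of the
  target and the source-before-target ordering, which is precisely what
  trajectory steps 2 and 3 are built to detect. An earlier design that only
  re-drew the onset time conditional on a fixed affection status was
  rejected: with an appreciable baseline cumulative hazard it barely moves
  the ordering and creates no risk elevation for the conditional
  regression to find. One active link per target is supported; chains are
  listed in causal order.
* **Death** is an ordinary disease model with the sentinel phecode
  `"death"`; it sets the death date, censors later diagnoses, and can be
  the target (never the source) of a link.
* **Summary statistics** are per-variant unadjusted linear regressions of
  urate on dosage with normal-theory p-values — the stand-in for an
  external GWAS. Monomorphic variants are excluded and flagged.

What passing tests on this generator do **not** show: robustness to
real-data features it omits — linkage disequilibrium with megabase-scale
structure, population stratification actually confounding the score,
miscoded or missing diagnoses, informative censoring, and covariate
measurement error. The package validates the machinery, not the
epidemiology of any particular dataset.

# Design choices on points the analysis description leaves open

* **"Six months"** is fixed at 183 days, boundary excluded: an onset
  exactly 183 days after assessment is removed, 184 retained. Determinism
  across platforms was preferred over calendar arithmetic.
* **Washout scope.** The incident-case washout applies to the
  observational scan only. The genetic scan uses all (prevalent plus
  incident) cases, since the genetic exposure precedes every onset. Washout
  and prevalent removals are per-phenotype; they do not touch the person's
  standing in other phenotypes.
* **Observational exposure unit** defaults to per SD of measured urate so
  both scans read "per SD"; per-mg/dL is a flag.
* **FDR families** are per scan (observational, genetic, each stratum,
  each drug), not pooled. Phenotypes whose fit failed contribute no
  p-value and are excluded from the family size m.
* **Trajectory matching.** The conditional regression uses risk-set
  sampling: each D2 case is matched 1:1 (configurable) on sex and 5-year
  age band to persons D2-free and alive at the case's onset date; exposure
  is a D1 diagnosis strictly before that date; remaining covariates enter
  the model, not the matching. Sex is absorbed by the matching and is
  therefore not a model covariate. Same-day D1/D2 diagnoses are ties:
  counted in the co-occurrence, excluded from the direction test.
* **"Above the median"** is strict; persons exactly at the median are
  excluded from the high-urate subset. The subset is defined on measured
  urate, not the score.
* **Factorial split.** The two-stage wording is followed: urate score
  split at the whole-population median, blood-pressure score at the median
  within each urate subgroup; ties go to the "high" side. A global-split
  mode exists behind a flag because the two differ when the scores are
  correlated. The reference group is high-urate/high-BP, so protective
  combination effects appear as OR < 1.
* **Drug-score orientation.** Weights are applied with the sign that makes
  a higher score mean lower genetically predicted urate, inferred from the
  goal of proxying urate-lowering treatment; gout is the built-in positive
  control (its OR should fall below 1 whenever the simulation encodes a
  urate-to-gout effect).
* **Command-line interface.** The pipeline is exposed as R functions
  (`run_pipeline()` and the per-stage functions) plus YAML/TSV readers and
  writers; no shell dispatcher is shipped. All randomness flows from the
  config seed — a seedless config refuses to simulate — and each
  sub-generator derives its own stream, so module outputs are reproducible
  independently of execution order.

# Numerical choices

* IRLS convergence at max |score| < 1e-8, 50 iterations; likelihood-based
  step-halving (12 halvings max) guards difficult designs.
* Wald (not profile) confidence intervals throughout, matching standard
  PheWAS reporting: symmetric on the log-OR scale.
* The spline basis rescaling by \((t_k-t_1)^2\) changes the basis span not
  at all and the likelihood-ratio test not at all; it keeps the information
  matrix well-conditioned when the score has long tails.
* Likelihood-ratio statistics are clamped at 0; a statistic below −1e-6 is
  surfaced as a convergence error rather than silently truncated.
* Greedy LD clumping breaks p-value ties by (chromosome, position, variant
  id), making instrument sets reproducible under permutation of the input
  table.

# Problem sizes used in the packaged checks

The packaged tests run the scans at cohort sizes of 10,000–20,000 with
8–10 phenotypes, 100-replicate calibration and recovery loops, and a
50,000-person draw for the urate moment checks; the demonstration pipeline
in `scripts/acceptance.R` uses the default 20,000-person configuration.
These sizes were chosen so each check's Monte-Carlo error is comfortably
inside its assertion margin while the whole suite stays quick to run;
coverage-style assertions (≥ 90 of 100 replicates covering the truth) are
standard small-sample tolerances for nominal 95% intervals.

# Known limitations

* The conditional likelihood covers 1-case strata only — sufficient for
  the package's matching design, not for general highly-stratified data.
* No Firth correction: separated phenotypes are reported as skipped, not
  estimated.
* Two-sample MR estimators (IVW, MR-Egger) and pleiotropy sensitivity
  analyses are out of scope; the design is one-sample score regression.
* The synthetic ICD layer is thin by design: the generator emits phecodes
  directly, and raw-code mapping is exercised through small toy maps. No
  primary-care (Read code) mapping logic is included.
* Trajectory reporting is pairwise; multi-step paths are visible in the
  network but not separately enumerated or tested.

# A worked example

```{r example, eval = FALSE}
library(uratephewas)
cfg <- sim_config(seed = 7)          # 20,000 persons, default disease panel
run <- run_pipeline(cfg, out_dir = "demo_out")
print(run)
run$overlap                          # replicated phenotypes
run$network                          # retained progression edges
```

The run report carries every funnel count (phenotypes tested, significant
per scan, overlap, pair funnel, per-drug instrument counts, factorial group
sizes), and the written TSVs carry a config-hash header line so any output
file can be traced to the exact configuration that produced it.
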