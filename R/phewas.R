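# Pairwise r-squared lookup: `ld` is either a symmetric r^2 matrix with
# variant ids on both dimnames, or a genotype panel (persons x variants)
# from which r^2 is computed as squared Pearson correlation of dosages.
ld_r2 <- function(ld, ids) {
  ld <- as.matrix(ld)
  if (nrow(ld) == ncol(ld) && !is.null(rownames(ld)) &&
      identical(rownames(ld), colnames(ld)) && all(ids %in% rownames(ld))) {
    return(ld[ids, ids, drop = FALSE])
  }
  miss <- setdiff(ids, colnames(ld))
  if (length(miss)) stop("no LD source for variants: ", paste(miss, collapse = ", "))
  suppressWarnings(stats::cor(ld[, ids, drop = FALSE]))^2
}

# Greedy clumping: repeatedly keep the smallest-P remaining variant and
# discard all remaining variants with r^2 >= threshold to it. Ties on P
# broken by (chrom, pos, variant_id).
greedy_clump <- function(cand, r2, r2_threshold) {
  ord <- order(cand$pvalue, cand$chrom, cand$pos, cand$variant_id)
  remaining <- cand$variant_id[ord]
  kept <- character(0)
  while (length(remaining)) {
    head_id <- remaining[1]
    kept <- c(kept, head_id)
    remaining <- remaining[-1]
    if (length(remaining)) {
      drop <- r2[head_id, remaining] >= r2_threshold
      drop[is.na(drop)] <- FALSE
      remaining <- remaining[!drop]
    }
  }
  kept
}

#' Select approximately independent urate instruments
#'
#' Genome-wide instrument selection for the urate polygenic score: keep
#' variants associated with urate at `p_threshold` (default genome-wide
#' significance, 5e-8) and prune them by greedy LD clumping at
#' `r2_threshold` (default 0.01): the most significant remaining variant is
#' kept and every remaining variant in LD with it at or above the threshold
#' is discarded, until none remain.
#'
#' @param summary VariantTable (`variant_id`, `chrom`, `pos`, `beta`, `se`,
#'   `pvalue`).
#' @param ld pairwise r^2 matrix, or a genotype panel to compute it from.
#' @param p_threshold significance threshold for candidacy.
#' @param r2_threshold LD threshold; pairs at or above it conflict.
#' @return object of class `ua_prs_def`: list with `variant_ids`, `weights`
#'   (urate-increasing mg/dL betas), `standardize = TRUE`.
#' @export
select_instruments <- function(summary, ld, p_threshold = 5e-8,
                               r2_threshold = 0.01) {
  cand <- summary[summary$pvalue < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no variant passes the significance threshold ", p_threshold)
  }
  kept <- greedy_clump(cand, ld_r2(ld, cand$variant_id), r2_threshold)
  structure(list(variant_ids = kept,
                 weights = cand$beta[match(kept, cand$variant_id)],
                 standardize = TRUE),
            class = "ua_prs_def")
}

#' @export
print.ua_prs_def <- function(x, ...) {
  cat(sprintf("genetic score: %d variants%s\n", length(x$variant_ids),
              if (isTRUE(x$standardize)) " (standardized)" else ""))
  invisible(x)
}

#' Compute a weighted polygenic score
#'
#' Score = sum over instruments of dosage x weight; with `standardize` the
#' score is z-scored in the cohort so downstream odds ratios read per one SD
#' of genetically predicted exposure.
#'
#' @param genotypes dosage matrix (persons x variants, named columns).
#' @param prs_def a `ua_prs_def` (or list with `variant_ids`, `weights`,
#'   `standardize`).
#' @return named numeric vector of per-person scores.
#' @export
compute_prs <- function(genotypes, prs_def) {
  miss <- setdiff(prs_def$variant_ids, colnames(genotypes))
  if (length(miss)) {
    stop("variants missing from genotype matrix: ", paste(miss, collapse = ", "))
  }
  sc <- drop(genotypes[, prs_def$variant_ids, drop = FALSE] %*% prs_def$weights)
  if (isTRUE(prs_def$standardize)) {
    s <- stats::sd(sc)
    if (!is.finite(s) || s == 0) {
      stop("score has zero variance; cannot standardize")
    }
    sc <- (sc - mean(sc)) / s
  }
  names(sc) <- rownames(genotypes)
  sc
}

# Covariate design matrix (treatment-coded factors), intercept first.
build_design <- function(cohort, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(1, nrow(cohort), 1, dimnames = list(NULL, "intercept")))
  }
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(f, data = cohort)
  colnames(mm)[1] <- "intercept"
  mm
}

# Shared scan engine: one logistic fit per phenotype with the given exposure,
# BH-FDR across converged fits.
scan_engine <- function(cohort, phenome, exposure, covariates,
                        exposure_kind, q = 0.05, stratum = NA_character_) {
  if (is.null(names(exposure))) names(exposure) <- cohort$person_id
  rows <- list()
  skipped <- character(0)
  for (ph in phenome) {
    ids <- c(ph$case_ids, ph$control_ids)
    ids <- ids[ids %in% cohort$person_id & ids %in% names(exposure)]
    sub <- droplevels(cohort[match(ids, cohort$person_id), , drop = FALSE])
    y <- as.integer(ids %in% ph$case_ids)
    mm <- build_design(sub, covariates)
    x <- cbind(mm[, 1, drop = FALSE], exposure = exposure[ids],
               mm[, -1, drop = FALSE])
    fit <- tryCatch(fit_logistic(x, y), error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      skipped <- c(skipped, ph$phecode)
      next
    }
    b <- fit$coefficients[["exposure"]]
    se <- fit$standard_errors[["exposure"]]
    rows[[ph$phecode]] <- data.frame(
      phecode = ph$phecode, label = ph$label,
      exposure_kind = exposure_kind, stratum = stratum,
      n_cases = sum(y), n_controls = sum(1 - y),
      beta = b, se = se, or = exp(b),
      ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
      p = fit$p_values[["exposure"]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phecode = character(0), label = character(0),
                      exposure_kind = character(0), stratum = character(0),
                      n_cases = integer(0), n_controls = integer(0),
                      beta = numeric(0), se = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p = numeric(0))
    out$fdr_p <- numeric(0)
    out$significant <- logical(0)
  } else {
    fdr <- bh_fdr(out$p, q = q)
    out$fdr_p <- fdr$adjusted_p
    out$significant <- fdr$significant
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "q") <- q
  class(out) <- c("ua_phewas", "data.frame")
  out
}

#' Observational phenome-wide scan of measured urate
#'
#' One multivariable logistic regression per retained phenotype: case status
#' on measured urate plus lifestyle/socioeconomic covariates, with BH-FDR
#' across the scan. The phenome is expected to be incident-filtered (six
#' month washout) before this scan. The exposure is measured urate per
#' cohort SD by default; `per_sd = FALSE` reports per mg/dL.
#'
#' @param cohort cohort table.
#' @param phenome a `ua_phenome`.
#' @param covariates adjustment set (column names in `cohort`).
#' @param per_sd report odds ratios per SD of urate (default) or per mg/dL.
#' @param q FDR level.
#' @return `ua_phewas` data.frame (one AssociationResult row per phenotype);
#'   attribute `skipped` lists phenotypes whose fit did not converge (these
#'   do not count towards the FDR family).
#' @export
run_obs_phewas <- function(cohort, phenome,
                           covariates = c("age", "sex", "bmi", "townsend",
                                          "smoking", "physical_activity",
                                          "alcohol"),
                           per_sd = TRUE, q = 0.05) {
  expo <- cohort$urate
  if (per_sd) expo <- (expo - mean(expo)) / stats::sd(expo)
  names(expo) <- cohort$person_id
  scan_engine(cohort, phenome, expo, covariates,
              exposure_kind = "measured_urate", q = q)
}

#' PRS-based phenome-wide scan
#'
#' As [run_obs_phewas()] but with the standardized urate polygenic score as
#' the exposure (odds ratios per SD of genetically predicted urate) and the
#' genetic adjustment set (age, sex, assessment centre, 10 PCs). Because the
#' genetic exposure precedes every diagnosis, the phenome here uses all
#' (prevalent plus incident) cases, not the washout-filtered set.
#'
#' @param cohort cohort table.
#' @param phenome a `ua_phenome` built without the incident filter.
#' @param prs named per-person score (standardized internally if needed).
#' @param covariates adjustment set.
#' @param q FDR level.
#' @return `ua_phewas` data.frame.
#' @export
run_prs_phewas <- function(cohort, phenome, prs,
                           covariates = c("age", "sex", "assessment_center",
                                          paste0("PC", 1:10)),
                           q = 0.05) {
  if (is.null(names(prs))) names(prs) <- cohort$person_id
  s <- stats::sd(prs)
  if (!is.finite(s) || s == 0) stop("score has zero variance; cannot standardize")
  prs <- (prs - mean(prs)) / s
  scan_engine(cohort, phenome, prs, covariates, exposure_kind = "prs", q = q)
}

subset_phenome <- function(phenome, ids, min_cases = 1) {
  out <- list()
  for (ph in phenome) {
    d <- ph
    d$case_ids <- intersect(ph$case_ids, ids)
    d$control_ids <- intersect(ph$control_ids, ids)
    d$excluded_ids <- intersect(ph$excluded_ids, ids)
    d$n_cases <- length(d$case_ids)
    if (d$n_cases >= min_cases && length(d$control_ids) > 0) out[[ph$phecode]] <- d
  }
  structure(out, class = "ua_phenome", n_dropped = length(phenome) - length(out))
}

#' Stratified scan with heterogeneity testing
#'
#' Runs the chosen scan separately in the two levels of a binary stratifier
#' (sex, or an eGFR dichotomy) and tests per-phenotype heterogeneity of the
#' log odds ratios with the two-sample z-test. Phenotypes failing the case
#' floor in either stratum are skipped from the comparison. The exposure is
#' standardized on the full cohort so per-stratum effects share a scale.
#'
#' @param cohort cohort table.
#' @param phenome a `ua_phenome`.
#' @param stratifier name of a binary column in `cohort`, or a vector with
#'   exactly two distinct values aligned with `cohort` rows.
#' @param exposure `"urate"` or `"prs"`.
#' @param prs per-person score, required when `exposure = "prs"`.
#' @param covariates adjustment set; defaults to the scan's convention minus
#'   the stratifier itself.
#' @param min_cases per-stratum case floor.
#' @param q FDR level (applied within each stratum's scan separately).
#' @return list of class `ua_strat_scan`: `results` (stacked per-stratum
#'   `ua_phewas` rows) and `heterogeneity` (phecode, per-stratum betas/SEs,
#'   z, p).
#' @export
stratified_scan <- function(cohort, phenome, stratifier, exposure = "urate",
                            prs = NULL, covariates = NULL, min_cases = 200,
                            q = 0.05) {
  strat <- if (is.character(stratifier) && length(stratifier) == 1L) {
    cohort[[stratifier]]
  } else stratifier
  lev <- sort(unique(strat))
  if (length(lev) < 2L) stop("stratifier is constant")
  if (length(lev) > 2L) stop("stratifier must be binary")
  strat_name <- if (is.character(stratifier) && length(stratifier) == 1L) {
    stratifier
  } else "stratum"

  if (is.null(covariates)) {
    covariates <- if (exposure == "prs") {
      c("age", "sex", "assessment_center", paste0("PC", 1:10))
    } else {
      c("age", "sex", "bmi", "townsend", "smoking", "physical_activity",
        "alcohol")
    }
  }
  covariates <- setdiff(covariates, strat_name)

  expo <- if (exposure == "prs") {
    if (is.null(prs)) stop("prs required for a PRS-stratified scan")
    (prs - mean(prs)) / stats::sd(prs)
  } else {
    (cohort$urate - mean(cohort$urate)) / stats::sd(cohort$urate)
  }
  names(expo) <- cohort$person_id

  kind <- if (exposure == "prs") "prs" else "measured_urate"
  res <- list()
  for (lv in lev) {
    ids <- cohort$person_id[strat == lv]
    ph_sub <- subset_phenome(phenome, ids, min_cases = min_cases)
    res[[as.character(lv)]] <- scan_engine(
      cohort[strat == lv, , drop = FALSE], ph_sub, expo[ids], covariates,
      exposure_kind = kind, q = q,
      stratum = paste0(strat_name, "=", lv))
  }
  shared <- intersect(res[[1]]$phecode, res[[2]]$phecode)
  het <- NULL
  if (length(shared)) {
    i1 <- match(shared, res[[1]]$phecode)
    i2 <- match(shared, res[[2]]$phecode)
    hz <- heterogeneity_z(res[[1]]$beta[i1], res[[1]]$se[i1],
                          res[[2]]$beta[i2], res[[2]]$se[i2])
    het <- data.frame(phecode = shared,
                      beta_1 = res[[1]]$beta[i1], se_1 = res[[1]]$se[i1],
                      beta_2 = res[[2]]$beta[i2], se_2 = res[[2]]$se[i2],
                      z = hz$z, p = hz$p, stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, res), heterogeneity = het,
                 levels = lev, stratifier = strat_name),
            class = "ua_strat_scan")
}

#' @export
print.ua_strat_scan <- function(x, ...) {
  cat(sprintf("stratified scan by %s (%s vs %s): %d shared phenotypes, %d with heterogeneity p < 0.05\n",
              x$stratifier, x$levels[1], x$levels[2],
              NROW(x$heterogeneity),
              if (is.null(x$heterogeneity)) 0L else sum(x$heterogeneity$p < 0.05)))
  invisible(x)
}

#' Overlap of observational and PRS scans with consistent direction
#'
#' The replication rule of the two-pronged design: a phenotype counts as
#' robustly urate-associated when it is FDR-significant in both the
#' observational and the PRS scan and the log odds ratios agree in sign.
#'
#' @param obs_results,prs_results `ua_phewas` tables over a shared phenome.
#' @param q FDR level applied to both scans' adjusted p-values.
#' @return data.frame `phecode`, `label`, `beta_obs`, `beta_prs` (zero rows
#'   when the significant sets are disjoint or conflict in direction).
#' @export
overlap_consistent <- function(obs_results, prs_results, q = 0.05) {
  m <- merge(obs_results[, c("phecode", "label", "beta", "fdr_p")],
             prs_results[, c("phecode", "beta", "fdr_p")],
             by = "phecode", suffixes = c("_obs", "_prs"))
  keep <- m$fdr_p_obs < q & m$fdr_p_prs < q &
    sign(m$beta_obs) == sign(m$beta_prs) & m$beta_obs != 0
  out <- data.frame(phecode = m$phecode[keep], label = m$label[keep],
                    beta_obs = m$beta_obs[keep], beta_prs = m$beta_prs[keep],
                    stringsAsFactors = FALSE)
  out[order(out$phecode), , drop = FALSE]
}

#' Restricted-cubic-spline non-linearity follow-up
#'
#' For each requested phenotype (normally the overlap set), compares the
#' linear-in-score logistic fit against a five-knot restricted cubic spline
#' fit of the same score, knots at the 5th/25th/50th/75th/95th percentiles
#' of the genetically predicted exposure in the full cohort, by likelihood
#' ratio on 3 df.
#'
#' @param cohort cohort table.
#' @param phenome a `ua_phenome`.
#' @param prs named standardized score.
#' @param phecodes phenotypes to test.
#' @param covariates adjustment set.
#' @return data.frame `phecode`, `lr`, `df`, `p` (phenotypes whose fits fail
#'   or whose knots collapse are skipped, listed in attribute `skipped`).
#' @export
nonlinearity_followup <- function(cohort, phenome, prs, phecodes,
                                  covariates = c("age", "sex",
                                                 "assessment_center",
                                                 paste0("PC", 1:10))) {
  if (is.null(names(prs))) names(prs) <- cohort$person_id
  knots <- stats::quantile(prs, c(0.05, 0.25, 0.50, 0.75, 0.95), names = FALSE)
  if (length(unique(knots)) < 5L) {
    warning("fewer than 5 distinct knot percentiles; nothing tested")
    return(structure(data.frame(phecode = character(0), lr = numeric(0),
                                df = integer(0), p = numeric(0)),
                     skipped = phecodes))
  }
  rows <- list()
  skipped <- character(0)
  for (pc in phecodes) {
    ph <- phenome[[pc]]
    if (is.null(ph)) { skipped <- c(skipped, pc); next }
    ids <- c(ph$case_ids, ph$control_ids)
    ids <- ids[ids %in% cohort$person_id]
    sub <- droplevels(cohort[match(ids, cohort$person_id), , drop = FALSE])
    y <- as.integer(ids %in% ph$case_ids)
    covm <- build_design(sub, covariates)
    basis <- rcs_basis(prs[ids], knots)
    lin <- tryCatch(fit_logistic(cbind(covm[, 1, drop = FALSE],
                                       exposure = basis[, 1],
                                       covm[, -1, drop = FALSE]), y),
                    error = function(e) e)
    spl <- tryCatch(fit_logistic(cbind(covm[, 1, drop = FALSE], basis,
                                       covm[, -1, drop = FALSE]), y),
                    error = function(e) e)
    if (inherits(lin, "error") || inherits(spl, "error") ||
        !lin$converged || !spl$converged) {
      skipped <- c(skipped, pc); next
    }
    nt <- tryCatch(nonlinearity_test(lin, spl), error = function(e) e)
    if (inherits(nt, "error")) { skipped <- c(skipped, pc); next }
    rows[[pc]] <- data.frame(phecode = pc, lr = nt$lr, df = nt$df, p = nt$p,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(phecode = character(0), lr = numeric(0),
                                      df = integer(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
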