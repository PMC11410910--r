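#' Define a drug-target gene region
#'
#' A urate-lowering drug class is proxied by variants around its target gene
#' (cis instruments): e.g. xanthine oxidase inhibitors via XDH, uricosurics
#' via SLC22A12, purine nucleoside phosphorylase inhibitors via PNP.
#'
#' @param drug_class label for the drug class.
#' @param gene target gene symbol.
#' @param chrom chromosome of the gene.
#' @param gene_start,gene_end gene coordinates in base pairs.
#' @param window flanking window in base pairs (default 500 kb each side).
#' @return object of class `ua_drug_target`.
#' @export
drug_target <- function(drug_class, gene, chrom, gene_start, gene_end,
                        window = 500000) {
  if (gene_start >= gene_end) stop("gene_start must be < gene_end")
  if (window < 0) stop("window must be non-negative")
  structure(list(drug_class = drug_class, gene = gene,
                 chrom = as.character(chrom),
                 gene_start = as.numeric(gene_start),
                 gene_end = as.numeric(gene_end),
                 window = as.numeric(window)),
            class = "ua_drug_target")
}

#' Read a drug-target table
#'
#' @param path TSV with columns `gene, chrom, start, end, drug_class` and
#'   optional `window`.
#' @return list of [drug_target()] objects.
#' @export
read_drug_targets <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("gene", "chrom", "start", "end", "drug_class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("targets table lacks columns: ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    drug_target(tab$drug_class[i], tab$gene[i], tab$chrom[i],
                as.numeric(tab$start[i]), as.numeric(tab$end[i]),
                window = if ("window" %in% names(tab)) {
                  as.numeric(tab$window[i])
                } else 500000)
  })
}

#' Select cis instruments for a urate-lowering drug target
#'
#' Drug-proxy instrument selection uses the deliberately relaxed regional
#' criteria: variants (i) within `window` base pairs of the target gene,
#' (ii) associated with urate at `p_threshold` (default 0.05) and (iii)
#' mutually pruned by greedy LD clumping at `r2_threshold` (default 0.2).
#' Weights are oriented so that a higher score means lower genetically
#' proxied urate (the urate-increasing betas are applied with flipped sign),
#' hence an odds ratio below 1 reads as a protective drug effect.
#'
#' @param target a [drug_target()].
#' @param summary VariantTable with positions.
#' @param ld r^2 matrix or genotype panel.
#' @param p_threshold,r2_threshold regional selection thresholds.
#' @return `ua_prs_def` with urate-lowering orientation (attribute
#'   `drug_class`).
#' @export
select_drug_instruments <- function(target, summary, ld,
                                    p_threshold = 0.05, r2_threshold = 0.2) {
  stopifnot(inherits(target, "ua_drug_target"))
  lo <- target$gene_start - target$window
  hi <- target$gene_end + target$window
  cand <- summary[summary$chrom == target$chrom &
                    summary$pos >= lo & summary$pos <= hi &
                    summary$pvalue < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no instrument survives selection for target ", target$gene,
         " (", target$drug_class, ")")
  }
  kept <- greedy_clump(cand, ld_r2(ld, cand$variant_id), r2_threshold)
  def <- structure(list(variant_ids = kept,
                        weights = -cand$beta[match(kept, cand$variant_id)],
                        standardize = TRUE),
                   class = "ua_prs_def")
  attr(def, "drug_class") <- target$drug_class
  attr(def, "gene") <- target$gene
  def
}

#' Drug-repurposing scan over the replicated phenotypes
#'
#' For each drug target: build the urate-lowering genetic score, standardize
#' it, and fit one multivariable logistic regression per phenotype in the
#' supplied (overlap-consistent) set with the genetic adjustment covariates.
#' Gout acts as the positive control: when the simulation encodes a
#' urate-to-gout effect, the urate-lowering score should show OR < 1 there.
#'
#' @param cohort cohort table.
#' @param phenome a `ua_phenome` (all-case, not washout-filtered).
#' @param genotypes dosage matrix.
#' @param summary VariantTable.
#' @param ld r^2 matrix or genotype panel.
#' @param targets list of [drug_target()] objects.
#' @param phecodes phenotypes to test (normally the overlap set; phenotypes
#'   not in it are absent from the output).
#' @param covariates adjustment set.
#' @param q FDR level, applied within each drug's scan.
#' @return data.frame of AssociationResult rows with a `drug_class` column.
#' @export
run_drug_repurposing <- function(cohort, phenome, genotypes, summary, ld,
                                 targets, phecodes,
                                 covariates = c("age", "sex",
                                                "assessment_center",
                                                paste0("PC", 1:10)),
                                 q = 0.05) {
  ph_use <- phenome[names(phenome) %in% phecodes]
  class(ph_use) <- "ua_phenome"
  out <- list()
  for (tg in targets) {
    def <- select_drug_instruments(tg, summary, ld)
    score <- compute_prs(genotypes, def)
    res <- scan_engine(cohort, ph_use, score, covariates,
                       exposure_kind = "drug_score", q = q)
    if (nrow(res)) {
      res$drug_class <- tg$drug_class
      res$gene <- tg$gene
      res$n_instruments <- length(def$variant_ids)
    }
    out[[tg$drug_class]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign the 2x2 factorial groups
#'
#' Two-stage median split emulating a factorial trial of urate lowering and
#' blood-pressure lowering: the population is first split at the overall
#' median of the urate genetic score, then each urate subgroup is split at
#' its own median of the blood-pressure score (`split = "global"` uses the
#' whole-population BP median instead; the two differ when the scores are
#' correlated). Persons exactly at a median go to the "high" side. The
#' reference group is high-urate/high-BP.
#'
#' @param urate_score,bp_score per-person genetic scores (higher = higher
#'   genetically predicted urate / blood pressure), equal length.
#' @param split `"two-stage"` (default) or `"global"`.
#' @return factor of class labels `high_urate_high_bp` (reference),
#'   `low_urate_high_bp`, `high_urate_low_bp`, `low_urate_low_bp`.
#' @export
assign_factorial_groups <- function(urate_score, bp_score,
                                    split = c("two-stage", "global")) {
  split <- match.arg(split)
  if (length(urate_score) != length(bp_score)) stop("score lengths differ")
  if (stats::sd(urate_score) == 0 || stats::sd(bp_score) == 0) {
    stop("constant score cannot be median-split")
  }
  high_u <- urate_score >= stats::median(urate_score)
  high_b <- logical(length(bp_score))
  if (split == "global") {
    high_b <- bp_score >= stats::median(bp_score)
  } else {
    for (side in c(TRUE, FALSE)) {
      idx <- which(high_u == side)
      high_b[idx] <- bp_score[idx] >= stats::median(bp_score[idx])
    }
  }
  lab <- ifelse(high_u,
                ifelse(high_b, "high_urate_high_bp", "high_urate_low_bp"),
                ifelse(high_b, "low_urate_high_bp", "low_urate_low_bp"))
  factor(lab, levels = c("high_urate_high_bp", "low_urate_high_bp",
                         "high_urate_low_bp", "low_urate_low_bp"))
}

#' Estimate factorial group effects on cardiovascular outcomes
#'
#' One logistic regression per outcome with three group indicators (the
#' high-urate/high-BP group is the reference) plus covariates. An additivity
#' diagnostic compares the low/low log-OR against the sum of the two
#' single-exposure log-ORs, with a Wald z from the fitted covariance.
#'
#' @param groups factor from [assign_factorial_groups()], aligned with
#'   `cohort` rows.
#' @param cohort cohort table.
#' @param phenome a `ua_phenome`.
#' @param phecodes outcomes to test (typically cardiovascular).
#' @param covariates adjustment set.
#' @return data.frame with one row per (outcome, non-reference group):
#'   `phecode`, `group`, `n`, `or`, `ci_low`, `ci_high`, `p`; attribute
#'   `additivity` holds the per-outcome diagnostic.
#' @export
estimate_factorial_effects <- function(groups, cohort, phenome, phecodes,
                                       covariates = c("age", "sex",
                                                      "assessment_center",
                                                      paste0("PC", 1:10))) {
  if (any(table(groups) == 0)) stop("empty factorial group")
  names(groups) <- cohort$person_id
  rows <- list()
  addv <- list()
  glev <- levels(groups)[-1]
  for (pc in phecodes) {
    ph <- phenome[[pc]]
    if (is.null(ph)) next
    ids <- c(ph$case_ids, ph$control_ids)
    ids <- ids[ids %in% cohort$person_id]
    sub <- droplevels(cohort[match(ids, cohort$person_id), , drop = FALSE])
    y <- as.integer(ids %in% ph$case_ids)
    gind <- sapply(glev, function(g) as.numeric(groups[ids] == g))
    colnames(gind) <- glev
    mm <- build_design(sub, covariates)
    x <- cbind(mm[, 1, drop = FALSE], gind, mm[, -1, drop = FALSE])
    fit <- tryCatch(fit_logistic(x, y), error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) next
    for (g in glev) {
      b <- fit$coefficients[[g]]
      se <- fit$standard_errors[[g]]
      rows[[paste(pc, g)]] <- data.frame(
        phecode = pc, group = g, n = sum(groups[ids] == g),
        beta = b, or = exp(b),
        ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
        p = fit$p_values[[g]], stringsAsFactors = FALSE)
    }
    # additivity: beta(low/low) vs beta(low/high) + beta(high/low)
    cvec <- stats::setNames(numeric(length(fit$coefficients)),
                            names(fit$coefficients))
    cvec["low_urate_low_bp"] <- 1
    cvec["low_urate_high_bp"] <- -1
    cvec["high_urate_low_bp"] <- -1
    dif <- sum(cvec * fit$coefficients)
    vdif <- drop(t(cvec) %*% fit$covariance %*% cvec)
    addv[[pc]] <- data.frame(
      phecode = pc, deviation = dif, se = sqrt(vdif),
      z = dif / sqrt(vdif),
      p = 2 * stats::pnorm(-abs(dif / sqrt(vdif))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phecode = character(0), group = character(0),
                      n = integer(0), beta = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "additivity") <- do.call(rbind, addv)
  out
}
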