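# 32-bit FNV-1a hash of the deparsed config; stamped into every output
# header so a result file can be traced to the run that produced it.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # multiply mod 2^32 in two 16-bit halves (doubles cannot hold the product)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

ua_schemas <- list(
  cohort = list(required = c("person_id", "sex", "age", "bmi", "townsend",
                             "urate", "assessment_date"),
                dates = c("assessment_date", "death_date"),
                factors = c("smoking", "alcohol", "physical_activity",
                            "assessment_center")),
  events = list(required = c("person_id", "phecode", "date", "source"),
                dates = "date", factors = character(0)),
  summary_stats = list(required = c("variant_id", "chrom", "pos",
                                    "effect_allele", "eaf", "beta", "se",
                                    "pvalue"),
                       dates = character(0), factors = character(0)),
  genotypes = list(required = "person_id", dates = character(0),
                   factors = character(0)))

#' Write a pipeline table as TSV
#'
#' Tab-delimited, UTF-8, ISO-8601 dates, header row, plus a leading comment
#' line carrying the config hash so outputs are traceable to their run.
#'
#' @param x data.frame.
#' @param path output path.
#' @param config optional config whose hash is stamped in the header.
#' @return invisibly, `path`.
#' @export
write_ua_table <- function(x, path, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s",
                     if (is.null(config)) "none" else config_hash(config)),
             con)
  for (cl in names(x)) if (inherits(x[[cl]], "Date")) {
    x[[cl]] <- format(x[[cl]], "%Y-%m-%d")
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a pipeline table with schema validation
#'
#' Checks required columns (error names the first missing one), parses date
#' columns with a per-line error on malformed dates, and converts the
#' schema's categorical columns to factors. Write-then-read is an identity
#' on the tables the pipeline emits.
#'
#' @param path TSV written by [write_ua_table()] (or compatible).
#' @param schema one of `"cohort"`, `"events"`, `"summary_stats"`,
#'   `"genotypes"`, or NULL for no validation.
#' @return data.frame.
#' @export
read_ua_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "")
  if (!is.null(schema)) {
    sc <- ua_schemas[[schema]]
    if (is.null(sc)) stop("unknown schema: ", schema)
    miss <- setdiff(sc$required, names(x))
    if (length(miss)) {
      stop("table ", path, " lacks required column: ", miss[1])
    }
    for (cl in intersect(sc$dates, names(x))) {
      raw <- x[[cl]]
      parsed <- as.Date(raw, format = "%Y-%m-%d")
      bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
      if (length(bad)) {
        stop("malformed date in column ", cl, " at line ", bad[1] + 2L,
             " of ", path)
      }
      x[[cl]] <- parsed
    }
    for (cl in intersect(sc$factors, names(x))) x[[cl]] <- factor(x[[cl]])
  }
  x
}

#' Export hard-call genotypes as VCF
#'
#' Minimal VCFv4.2 writer: one ALT allele per variant (the effect allele),
#' GT-only FORMAT, dosages 0/1/2 written as 0/0, 0/1, 1/1. The matching
#' [read_vcf_dosages()] restores the dosage matrix.
#'
#' @param genotypes dosage matrix with a `variant_info` attribute (as from
#'   [simulate_genotypes()]).
#' @param path output `.vcf` path (uncompressed).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  info <- attr(genotypes, "variant_info")
  if (is.null(info)) stop("genotype matrix lacks variant_info")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    writeLines(paste(c(info$chrom[j], info$pos[j], info$variant_id[j],
                       info$other_allele[j], info$effect_allele[j], ".",
                       "PASS", ".", "GT",
                       gt_code[genotypes[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @return for `read_vcf_dosages`: integer dosage matrix (persons x
#'   variants, ALT-allele counts) with a `variant_info` attribute.
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("not a VCF: missing #CHROM header in ", path)
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  persons <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  dos <- vapply(fields, function(f) {
    gt <- substr(f[-(1:9)], 1, 3)
    as.integer(substr(gt, 1, 1) != "0") + as.integer(substr(gt, 3, 3) != "0")
  }, integer(length(persons)))
  dos <- matrix(dos, nrow = length(persons))
  rownames(dos) <- persons
  colnames(dos) <- vapply(fields, `[[`, character(1), 3L)
  attr(dos, "variant_info") <- data.frame(
    variant_id = colnames(dos),
    chrom = vapply(fields, `[[`, character(1), 1L),
    pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
    effect_allele = vapply(fields, `[[`, character(1), 5L),
    other_allele = vapply(fields, `[[`, character(1), 4L),
    eaf = colMeans(dos) / 2, stringsAsFactors = FALSE)
  dos
}

#' Synthetic drug-target panel matching the simulated variant layout
#'
#' Three gene regions named after the urate-lowering drug-target genes (XDH
#' for xanthine oxidase inhibitors, SLC22A12 for uricosurics, PNP for purine
#' nucleoside phosphorylase inhibitors), placed along the simulated
#' chromosome so their 500 kb windows cover part of the causal variant
#' block. Synthetic stand-ins: coordinates bear no relation to the real
#' genes.
#' @return list of [drug_target()] objects.
#' @export
synthetic_drug_targets <- function() {
  list(drug_target("XOI", "XDH", "1", 250000, 350000),
       drug_target("uricosuric", "SLC22A12", "1", 1150000, 1250000),
       drug_target("PNP-inhibitor", "PNP", "1", 2150000, 2250000))
}

#' Run the full analysis chain on a synthetic study
#'
#' Executes simulate -> phenome -> observational and PRS scans ->
#' sex-stratified scan -> overlap -> non-linearity follow-up -> disease
#' trajectories in the high-urate subset -> drug repurposing -> factorial
#' MR, and collects a machine-readable run report with the funnel counts at
#' every stage. All randomness flows from `config$seed`.
#'
#' @param config a [sim_config()] (its seed drives everything, including
#'   risk-set matching).
#' @param out_dir optional directory; when given, every table is written as
#'   TSV (config-hash header), the network as GraphML and DOT, and the
#'   report as YAML.
#' @param q FDR level used throughout.
#' @param min_cases minimum case count per phenotype.
#' @param washout_days incident washout for the observational scan.
#' @param min_cooccurrence trajectory step-1 threshold.
#' @param match_ratio controls per case in trajectory step 3.
#' @param prs_p_threshold,prs_r2_threshold genome-wide instrument selection.
#' @param targets drug-target list; default [synthetic_drug_targets()].
#' @param split factorial split mode, `"two-stage"` or `"global"`.
#' @return object of class `ua_run`: all intermediate results plus `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, q = 0.05, min_cases = 200,
                         washout_days = 183, min_cooccurrence = 0.01,
                         match_ratio = 1, prs_p_threshold = 5e-8,
                         prs_r2_threshold = 0.01,
                         targets = synthetic_drug_targets(),
                         split = "two-stage") {
  stopifnot(inherits(config, "ua_sim_config"))
  study <- simulate_study(config)
  cohort <- study$cohort

  phecodes <- vapply(config$disease_models, `[[`, character(1), "phecode")
  labels <- vapply(config$disease_models, `[[`, character(1), "label")
  map <- phecode_identity_map(phecodes, labels)

  mapped <- map_events(study$events, map)
  inc <- incident_filter(mapped, cohort, washout_days = washout_days)
  phenome_obs <- define_case_control(inc, map, cohort, min_cases = min_cases)
  phenome_all <- define_case_control(mapped, map, cohort,
                                     min_cases = min_cases)

  obs <- run_obs_phewas(cohort, phenome_obs, q = q)
  prs_def <- select_instruments(study$summary_stats, ld = study$genotypes,
                                p_threshold = prs_p_threshold,
                                r2_threshold = prs_r2_threshold)
  prs <- compute_prs(study$genotypes, prs_def)
  prs_scan <- run_prs_phewas(cohort, phenome_all, prs, q = q)
  strat <- stratified_scan(cohort, phenome_obs, "sex", exposure = "urate",
                           min_cases = min_cases, q = q)
  overlap <- overlap_consistent(obs, prs_scan, q = q)
  nl <- nonlinearity_followup(cohort, phenome_all, prs, overlap$phecode)

  subset_ids <- select_high_urate(cohort)
  traj_codes <- setdiff(union(overlap$phecode, "death"), character(0))
  if (length(traj_codes) >= 2L) {
    pairs <- enumerate_pairs(mapped, cohort, subset_ids, traj_codes,
                             min_cooccurrence = min_cooccurrence)
    pairs <- test_directions(pairs, q = q)
    pairs <- estimate_pair_effects(pairs, mapped, cohort, subset_ids,
                                   match_ratio = match_ratio, q = q,
                                   seed = config$seed)
    network <- build_network(pairs)
  } else {
    pairs <- NULL
    network <- NULL
  }

  drug <- if (nrow(overlap)) {
    tryCatch(run_drug_repurposing(cohort, phenome_all, study$genotypes,
                                  study$summary_stats, study$genotypes,
                                  targets, overlap$phecode, q = q),
             error = function(e) { message("drug scan skipped: ",
                                           conditionMessage(e)); NULL })
  } else NULL

  # factorial MR: split on genetically predicted urate and the BP score
  groups <- assign_factorial_groups(prs, study$bp_score, split = split)
  cardio <- intersect(overlap$phecode, names(phenome_all))
  num <- suppressWarnings(as.numeric(cardio))
  is_circ <- !is.na(num) & num >= 394 & num < 460
  cardio <- if (any(is_circ)) cardio[is_circ] else cardio
  factorial <- if (length(cardio)) {
    estimate_factorial_effects(groups, cohort, phenome_all, cardio)
  } else NULL

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_individuals = nrow(cohort),
    n_variants = ncol(study$genotypes),
    n_events = nrow(study$events),
    n_phenotypes_obs = length(phenome_obs),
    n_phenotypes_prs = length(phenome_all),
    n_instruments = length(prs_def$variant_ids),
    n_sig_obs = sum(obs$significant),
    n_sig_prs = sum(prs_scan$significant),
    n_overlap = nrow(overlap),
    n_nonlinear = sum(nl$p < 0.05),
    n_high_urate = length(subset_ids),
    pair_funnel = if (is.null(pairs)) c(evaluated = 0L, cooccurrence = 0L,
                                        direction = 0L, retained = 0L) else c(
      evaluated = nrow(pairs),
      cooccurrence = sum(pairs$stage %in% c("cooccurrence", "direction",
                                            "retained")),
      direction = sum(pairs$stage %in% c("direction", "retained")),
      retained = sum(pairs$stage == "retained")),
    drug_instruments = if (is.null(drug)) integer(0) else
      tapply(drug$n_instruments, drug$drug_class, max),
    factorial_group_sizes = as.list(table(groups)),
    versions = list(r = as.character(getRversion()),
                    package = as.character(utils::packageVersion("uratephewas"))))

  run <- structure(list(config = config, study = study, map = map,
                        phenome_obs = phenome_obs, phenome_all = phenome_all,
                        obs = obs, prs_def = prs_def, prs = prs,
                        prs_scan = prs_scan, stratified = strat,
                        overlap = overlap, nonlinearity = nl,
                        pairs = pairs, network = network, drug = drug,
                        groups = groups, factorial = factorial,
                        report = report),
                   class = "ua_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cf <- run$config
  p <- function(f) file.path(out_dir, f)
  write_ua_table(run$study$cohort, p("cohort.tsv"), cf)
  write_ua_table(run$study$events, p("events.tsv"), cf)
  write_ua_table(run$study$summary_stats, p("summary_stats.tsv"), cf)
  write_ua_table(run$obs, p("obs_phewas.tsv"), cf)
  write_ua_table(run$prs_scan, p("prs_phewas.tsv"), cf)
  if (!is.null(run$stratified$heterogeneity)) {
    write_ua_table(run$stratified$heterogeneity, p("heterogeneity.tsv"), cf)
  }
  write_ua_table(run$overlap, p("overlap.tsv"), cf)
  if (!is.null(run$pairs)) write_ua_table(run$pairs, p("pairs.tsv"), cf)
  if (!is.null(run$network)) {
    export_network(run$network, graphml = p("network.graphml"),
                   dot = p("network.dot"),
                   clusters_tsv = p("clusters.tsv"))
  }
  if (!is.null(run$drug)) write_ua_table(run$drug, p("drug_repurposing.tsv"), cf)
  if (!is.null(run$factorial)) {
    write_ua_table(run$factorial, p("factorial.tsv"), cf)
  }
  rep <- run$report
  rep$pair_funnel <- as.list(rep$pair_funnel)
  rep$drug_instruments <- as.list(rep$drug_instruments)
  yaml::write_yaml(rep, p("report.yaml"))
  invisible(out_dir)
}

#' @export
print.ua_run <- function(x, ...) {
  r <- x$report
  cat("urate phenome pipeline run\n")
  cat(sprintf("  cohort: %d persons, %d variants, seed %d (config %s)\n",
              r$n_individuals, r$n_variants, r$seed, r$config_hash))
  cat(sprintf("  phenome: %d phenotypes (obs) / %d (prs), %d instruments\n",
              r$n_phenotypes_obs, r$n_phenotypes_prs, r$n_instruments))
  cat(sprintf("  significant: %d obs, %d prs, %d overlapping (consistent)\n",
              r$n_sig_obs, r$n_sig_prs, r$n_overlap))
  cat(sprintf("  trajectory funnel: %d evaluated -> %d co-occurring -> %d directed -> %d retained\n",
              r$pair_funnel[["evaluated"]], r$pair_funnel[["cooccurrence"]],
              r$pair_funnel[["direction"]], r$pair_funnel[["retained"]]))
  if (length(r$drug_instruments)) {
    cat("  drug instruments:",
        paste(names(r$drug_instruments), unlist(r$drug_instruments),
              sep = "=", collapse = ", "), "\n")
  }
  cat("  factorial groups:",
      paste(names(r$factorial_group_sizes),
            unlist(r$factorial_group_sizes), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Load a simulation config from YAML
#'
#' The YAML document mirrors the [sim_config()] arguments; disease models
#' are given as a list of mappings with the [disease_model()] fields, and
#' trajectory links as `{source, target, multiplier}` mappings.
#'
#' @param path YAML file.
#' @return a `ua_sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$disease_models)) {
    y$disease_models <- lapply(y$disease_models, function(d) {
      do.call(disease_model, d)
    })
  }
  if (!is.null(y$covariate_moments)) {
    y$covariate_moments <- utils::modifyList(default_covariate_moments(),
                                             lapply(y$covariate_moments, unlist))
  }
  do.call(sim_config, y)
}
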