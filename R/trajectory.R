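#' Select the high-urate subset
#'
#' Disease trajectories are explored among persons with measured urate
#' strictly above the cohort median (persons exactly at the median are
#' excluded, which makes the subset deterministic).
#'
#' @param cohort cohort table with `urate`.
#' @return character vector of person ids.
#' @export
select_high_urate <- function(cohort) {
  med <- stats::median(cohort$urate)
  ids <- cohort$person_id[cohort$urate > med]
  if (length(ids) == 0L) warning("no person strictly above the median urate")
  ids
}

# Precompute, for the subset, each phecode's post-assessment first-onset
# dates and pre-assessment (prior-history) carriers.
pair_onsets <- function(mapped_events, cohort, subset_ids) {
  ev <- mapped_events[mapped_events$person_id %in% subset_ids, , drop = FALSE]
  ad <- cohort$assessment_date[match(ev$person_id, cohort$person_id)]
  post <- ev$first_date > ad
  list(
    post = split(data.frame(person_id = ev$person_id[post],
                            date = ev$first_date[post],
                            stringsAsFactors = FALSE),
                 ev$phecode[post]),
    prior = split(ev$person_id[!post], ev$phecode[!post]))
}

#' Enumerate candidate disease pairs (trajectory step 1)
#'
#' Evaluates every unordered pair from `phecode_list` — k(k-1)/2 pairs — in
#' the high-urate subset, restricted to first onsets after recruitment.
#' Persons with a prior (pre-assessment) history of either member are
#' excluded from that pair's analysis set. A pair survives when its
#' co-occurrence count reaches `min_cooccurrence` of the subset. Forward,
#' reverse and same-day (tie) ordering counts are recorded for the direction
#' test.
#'
#' @param mapped_events output of [map_events()] (all onsets, including
#'   pre-assessment ones, so prior history is visible).
#' @param cohort cohort table (`assessment_date` per person).
#' @param subset_ids persons in the high-urate subset.
#' @param phecode_list phenotypes to pair (may include `"death"`).
#' @param min_cooccurrence minimum fraction of the subset with both diseases.
#' @return data.frame of class `ua_pairs`, one row per evaluated pair:
#'   `d1`, `d2`, `n_both`, `n_d1_first`, `n_d2_first`, `n_ties`,
#'   `n_eligible`, `stage` (`"evaluated"` or `"cooccurrence"`); attribute
#'   `n_subset`.
#' @export
enumerate_pairs <- function(mapped_events, cohort, subset_ids, phecode_list,
                            min_cooccurrence = 0.01) {
  phecode_list <- unique(as.character(phecode_list))
  if (length(phecode_list) == 0L) stop("empty phecode list")
  on <- pair_onsets(mapped_events, cohort, subset_ids)
  n_subset <- length(subset_ids)

  k <- length(phecode_list)
  rows <- vector("list", k * (k - 1L) / 2L)
  r <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      d1 <- phecode_list[i]; d2 <- phecode_list[j]
      p1 <- on$post[[d1]]; p2 <- on$post[[d2]]
      prior <- unique(c(on$prior[[d1]], on$prior[[d2]]))
      eligible_n <- n_subset - sum(subset_ids %in% prior)
      both <- if (is.null(p1) || is.null(p2)) character(0) else {
        intersect(p1$person_id, p2$person_id)
      }
      t1 <- p1$date[match(both, p1$person_id)]
      t2 <- p2$date[match(both, p2$person_id)]
      r <- r + 1L
      rows[[r]] <- data.frame(
        d1 = d1, d2 = d2, n_both = length(both),
        n_d1_first = sum(t1 < t2), n_d2_first = sum(t2 < t1),
        n_ties = sum(t1 == t2), n_eligible = eligible_n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$stage <- ifelse(out$n_both / n_subset >= min_cooccurrence,
                      "cooccurrence", "evaluated")
  rownames(out) <- NULL
  attr(out, "n_subset") <- n_subset
  class(out) <- c("ua_pairs", "data.frame")
  out
}

#' Binomial direction test per disease pair (trajectory step 2)
#'
#' For each pair surviving step 1, orients the pair along its majority
#' temporal direction (ties excluded) and tests the ordering counts against
#' a fair-coin null with the exact binomial test, BH-FDR across tested
#' pairs. Pairs whose FDR-adjusted p-value clears `q` advance with a fixed
#' D1 -> D2 orientation. Death can never be a D1: a pair whose majority
#' direction would put death first is dropped.
#'
#' @param pairs a `ua_pairs` table from [enumerate_pairs()].
#' @param q FDR level.
#' @return the table with `direction_p`, `direction_fdr_p` filled in and
#'   `stage` advanced to `"direction"` for significant pairs (orientation
#'   swapped in place so `d1` precedes `d2`).
#' @export
test_directions <- function(pairs, q = 0.05) {
  pairs$direction_p <- NA_real_
  pairs$direction_fdr_p <- NA_real_
  idx <- which(pairs$stage == "cooccurrence")
  for (i in idx) {
    if (pairs$n_d2_first[i] > pairs$n_d1_first[i]) {
      pairs[i, c("d1", "d2")] <- pairs[i, c("d2", "d1")]
      pairs[i, c("n_d1_first", "n_d2_first")] <-
        pairs[i, c("n_d2_first", "n_d1_first")]
    }
    if (pairs$d1[i] == "death") next  # death is terminal, never a source
    informative <- pairs$n_d1_first[i] + pairs$n_d2_first[i]
    if (informative == 0L) next  # all ties
    pairs$direction_p[i] <- binomial_direction_test(pairs$n_d1_first[i],
                                                    pairs$n_d2_first[i])
  }
  tested <- which(!is.na(pairs$direction_p))
  if (length(tested)) {
    fdr <- bh_fdr(pairs$direction_p[tested], q = q)
    pairs$direction_fdr_p[tested] <- fdr$adjusted_p
    pairs$stage[tested][fdr$significant] <- "direction"
  }
  pairs
}

#' Matched conditional-logistic pair effects (trajectory step 3)
#'
#' For each directed pair D1 -> D2 from step 2, estimates the odds of
#' developing D2 after a D1 diagnosis with a matched risk-set design: every
#' incident D2 case is matched (default 1:1) to persons of the same sex and
#' 5-year age band who are D2-free and alive at the case's D2 onset, the
#' exposure is a D1 diagnosis before that index date, and a conditional
#' logistic regression adjusts for the remaining covariates (sex and age
#' band are absorbed by the matching). BH-FDR across pairs; a pair is
#' retained when OR > 1 and the adjusted p-value clears `q`.
#'
#' @param pairs table from [test_directions()].
#' @param mapped_events,cohort,subset_ids as in [enumerate_pairs()].
#' @param covariates model covariates (must vary within matched sets, so sex
#'   is excluded by default; age enters continuously within its band).
#' @param match_ratio controls per case.
#' @param q FDR level.
#' @param seed seed for the control sampling (risk sets are drawn at
#'   random); required so the funnel is reproducible.
#' @return the table with `pair_or`, `pair_ci_low`, `pair_ci_high`,
#'   `pair_p`, `pair_fdr_p`, `n_strata_used` filled and `stage` advanced to
#'   `"retained"` for pairs with OR > 1 and FDR < `q`.
#' @export
estimate_pair_effects <- function(pairs, mapped_events, cohort, subset_ids,
                                  covariates = c("age", "bmi", "townsend",
                                                 "smoking",
                                                 "physical_activity",
                                                 "alcohol"),
                                  match_ratio = 1, q = 0.05, seed = 1) {
  set.seed(derive_seed(seed, "matching"))
  on <- pair_onsets(mapped_events, cohort, subset_ids)
  sub <- cohort[match(subset_ids, cohort$person_id), , drop = FALSE]
  band <- paste(sub$sex, floor(sub$age / 5), sep = ":")
  names(band) <- subset_ids
  covm <- NULL
  if (length(covariates)) {
    covm <- build_design(droplevels(sub), covariates)[, -1, drop = FALSE]
    rownames(covm) <- subset_ids
  }
  death_date <- sub$death_date
  names(death_date) <- subset_ids

  for (col in c("pair_or", "pair_ci_low", "pair_ci_high", "pair_p",
                "pair_fdr_p")) pairs[[col]] <- NA_real_
  pairs$n_strata_used <- NA_integer_

  idx <- which(pairs$stage == "direction")
  for (i in idx) {
    d1 <- pairs$d1[i]; d2 <- pairs$d2[i]
    prior <- unique(c(on$prior[[d1]], on$prior[[d2]]))
    eligible <- setdiff(subset_ids, prior)
    p1 <- on$post[[d1]]; p2 <- on$post[[d2]]
    d2_date <- p2$date[match(eligible, p2$person_id)]
    names(d2_date) <- eligible
    d1_date <- p1$date[match(eligible, p1$person_id)]
    names(d1_date) <- eligible
    cases <- eligible[!is.na(d2_date)]
    if (length(cases) == 0L) next

    by_band <- split(eligible, band[eligible])
    st_id <- character(0); st_lab <- character(0)
    st_y <- integer(0); st_exp <- numeric(0)
    s <- 0L
    for (cs in cases) {
      t_index <- d2_date[[cs]]
      cand <- setdiff(by_band[[band[[cs]]]], cs)
      if (length(cand)) {
        dd <- d2_date[cand]
        alive <- is.na(death_date[cand]) | death_date[cand] > t_index
        free <- is.na(dd) | dd > t_index
        cand <- cand[alive & free]
      }
      if (length(cand) == 0L) next
      ctrl <- if (length(cand) <= match_ratio) cand else {
        sample(cand, match_ratio)
      }
      s <- s + 1L
      members <- c(cs, ctrl)
      st_id <- c(st_id, members)
      st_lab <- c(st_lab, rep(sprintf("s%06d", s), length(members)))
      st_y <- c(st_y, c(1L, rep(0L, length(ctrl))))
      st_exp <- c(st_exp, as.integer(!is.na(d1_date[members]) &
                                       d1_date[members] < t_index))
    }
    if (s == 0L) next
    fit <- tryCatch(
      fit_conditional_logistic(st_lab, st_exp, st_y,
                               covariates = if (is.null(covm)) NULL else
                                 covm[st_id, , drop = FALSE]),
      error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) next
    b <- fit$coefficients[["exposure"]]
    se <- fit$standard_errors[["exposure"]]
    pairs$pair_or[i] <- exp(b)
    pairs$pair_ci_low[i] <- exp(b - 1.959964 * se)
    pairs$pair_ci_high[i] <- exp(b + 1.959964 * se)
    pairs$pair_p[i] <- fit$p_values[["exposure"]]
    pairs$n_strata_used[i] <- fit$n_strata_used
  }

  est <- which(!is.na(pairs$pair_p))
  if (length(est)) {
    fdr <- bh_fdr(pairs$pair_p[est], q = q)
    pairs$pair_fdr_p[est] <- fdr$adjusted_p
    keep <- fdr$significant & pairs$pair_or[est] > 1
    pairs$stage[est][keep] <- "retained"
  }
  pairs
}

#' Build the directed disease-trajectory network
#'
#' Assembles retained D1 -> D2 pairs into a directed graph whose nodes are
#' phecodes plus the death sentinel; weakly connected components are
#' reported as clusters. Edge attributes carry the full pair statistics.
#'
#' @param pairs table from [estimate_pair_effects()] (rows at stage
#'   `"retained"` become edges; an empty network is allowed).
#' @return object of class `ua_trajnet`: list with `graph` (igraph),
#'   `edges` (data.frame) and `clusters` (membership data.frame).
#' @export
build_network <- function(pairs) {
  edges <- pairs[pairs$stage == "retained", , drop = FALSE]
  if (any(edges$d1 == "death")) stop("death cannot be a trajectory source")
  g <- igraph::graph_from_data_frame(
    edges[, c("d1", "d2", "n_both", "n_d1_first", "n_d2_first",
              "direction_fdr_p", "pair_or", "pair_fdr_p")],
    directed = TRUE)
  cl <- if (igraph::vcount(g) > 0) {
    mem <- igraph::components(g, mode = "weak")$membership
    data.frame(phecode = names(mem), cluster = as.integer(mem),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(phecode = character(0), cluster = integer(0))
  structure(list(graph = g, edges = edges, clusters = cl),
            class = "ua_trajnet")
}

#' @export
print.ua_trajnet <- function(x, ...) {
  cat(sprintf("trajectory network: %d nodes, %d edges, %d cluster(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (nrow(x$clusters)) max(x$clusters$cluster) else 0L))
  if (nrow(x$edges)) {
    print(x$edges[, c("d1", "d2", "n_both", "pair_or", "pair_fdr_p")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Export a trajectory network
#'
#' Writes the directed graph as GraphML (via igraph) or Graphviz DOT, and
#' the cluster membership as TSV.
#'
#' @param net a `ua_trajnet`.
#' @param graphml,dot,clusters_tsv output paths (NULL skips that format).
#' @return invisibly, the paths written.
#' @export
export_network <- function(net, graphml = NULL, dot = NULL,
                           clusters_tsv = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(net$graph, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(dot)) {
    igraph::write_graph(net$graph, dot, format = "dot")
    written <- c(written, dot)
  }
  if (!is.null(clusters_tsv)) {
    utils::write.table(net$clusters, clusters_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, clusters_tsv)
  }
  invisible(written)
}
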