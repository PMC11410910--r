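test_that("the high-urate subset is strictly above the median", {
  co <- toy_cohort(5)
  co$urate <- 1:5
  expect_setequal(select_high_urate(co), c("P4", "P5"))
  co$urate <- rep(4, 5)
  expect_warning(ids <- select_high_urate(co), "median")
  expect_length(ids, 0L)
  co2 <- toy_cohort(10)
  co2$urate <- (1:10) / 2
  expect_length(select_high_urate(co2), 5L)  # even n, distinct values
})

test_that("pair enumeration counts co-occurrence and temporal order on a toy table", {
  co <- toy_cohort(8)
  # A/B co-occur in 4 of 8 persons: A first in 3, B first in 1; C rare
  ev <- toy_events(
    c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4", "P5", "P6", "P7"),
    c("A", "B", "A", "B", "A", "B", "B", "A", "A", "B", "C"),
    c(200, 300, 210, 400, 220, 500, 230, 600, 240, 250, 260))
  map <- phecode_identity_map(c("A", "B", "C"))
  mapped <- map_events(ev, map)
  pairs <- enumerate_pairs(mapped, co, co$person_id, c("A", "B", "C"),
                           min_cooccurrence = 0.25)
  expect_equal(nrow(pairs), 3L)  # 3 phecodes -> 3 unordered pairs
  ab <- pairs[pairs$d1 == "A" & pairs$d2 == "B", ]
  expect_equal(ab$n_both, 4L)
  expect_equal(ab$n_d1_first, 3L)
  expect_equal(ab$n_d2_first, 1L)
  expect_equal(ab$stage, "cooccurrence")
  expect_true(all(pairs$stage[pairs$d2 == "C" | pairs$d1 == "C"] ==
                    "evaluated"))
  expect_error(enumerate_pairs(mapped, co, co$person_id, character(0)),
               "empty")
})

test_that("prior history of either disease removes a person from the pair's analysis set", {
  co <- toy_cohort(6)
  # P1 has A before assessment -> excluded from the (A,B) analysis set
  ev <- toy_events(c("P1", "P1", "P2", "P2"),
                   c("A", "B", "A", "B"),
                   c(-100, 300, 200, 310))
  map <- phecode_identity_map(c("A", "B"))
  pairs <- enumerate_pairs(map_events(ev, map), co, co$person_id, c("A", "B"),
                           min_cooccurrence = 0)
  expect_equal(pairs$n_eligible, 5L)
  expect_equal(pairs$n_both, 1L)  # only P2: P1's B onset lacks a post A onset
})

test_that("direction testing orients pairs and applies exact binomial FDR", {
  base <- data.frame(d1 = c("A", "A"), d2 = c("B", "C"),
                     n_both = c(10, 11), n_d1_first = c(0, 6),
                     n_d2_first = c(10, 5), n_ties = c(0, 0),
                     n_eligible = c(100, 100),
                     stage = "cooccurrence", stringsAsFactors = FALSE)
  class(base) <- c("ua_pairs", "data.frame")
  out <- test_directions(base)
  # first pair flips to B -> A and is significant at the exact 2*0.5^10
  expect_equal(out$d1[1], "B")
  expect_equal(out$direction_p[1], 2 * 0.5^10)
  expect_equal(out$stage[1], "direction")
  # 6 vs 5 is compatible with a fair coin
  expect_gt(out$direction_p[2], 0.05)
  expect_equal(out$stage[2], "cooccurrence")
})

test_that("death is never oriented as a trajectory source", {
  base <- data.frame(d1 = "A", d2 = "death", n_both = 12, n_d1_first = 0,
                     n_d2_first = 12, n_ties = 0, n_eligible = 100,
                     stage = "cooccurrence", stringsAsFactors = FALSE)
  class(base) <- c("ua_pairs", "data.frame")
  out <- test_directions(base)
  expect_equal(out$d1, "death")
  expect_true(is.na(out$direction_p))
  expect_equal(out$stage, "cooccurrence")
})

test_that("a planted progression is recovered as a directed edge with adjusted effect", {
  cfg <- sim_config(
    n_individuals = 20000, n_variants = 10, allele_freqs = rep(0.3, 10),
    urate_effects = rep(0, 10),
    disease_models = list(
      disease_model("100.0", 0.15, 0, onset_rate = 0.25),
      disease_model("200.0", 0.10, 0, onset_rate = 0.10),
      disease_model("death", 0.03, 0, onset_rate = 0.08)),
    trajectory_links = list(list(source = "100.0", target = "200.0",
                                 multiplier = 5)),
    seed = 61)
  st <- simulate_study(cfg)
  map <- phecode_identity_map(c("100.0", "200.0", "death"))
  mapped <- map_events(st$events, map)
  subset_ids <- select_high_urate(st$cohort)
  pairs <- enumerate_pairs(mapped, st$cohort, subset_ids,
                           c("100.0", "200.0", "death"))
  pairs <- test_directions(pairs)
  pairs <- estimate_pair_effects(pairs, mapped, st$cohort, subset_ids,
                                 seed = cfg$seed)
  net <- build_network(pairs)
  edges <- paste(net$edges$d1, net$edges$d2, sep = ">")
  expect_true("100.0>200.0" %in% edges)
  expect_false("200.0>100.0" %in% edges)
  tgt <- net$edges[net$edges$d1 == "100.0" & net$edges$d2 == "200.0", ]
  expect_gt(tgt$pair_or, 1)
  expect_lt(tgt$pair_fdr_p, 0.05)
  # funnel monotonicity
  n_eval <- nrow(pairs)
  n_co <- sum(pairs$stage %in% c("cooccurrence", "direction", "retained"))
  n_dir <- sum(pairs$stage %in% c("direction", "retained"))
  n_ret <- sum(pairs$stage == "retained")
  expect_true(n_eval >= n_co && n_co >= n_dir && n_dir >= n_ret)
  # death terminal
  if (igraph::vcount(net$graph) > 0 && "death" %in% igraph::V(net$graph)$name) {
    expect_equal(igraph::degree(net$graph, "death", mode = "out"),
                 c(death = 0))
  }
})

test_that("network construction reports components and survives emptiness", {
  pairs <- data.frame(
    d1 = c("A", "B", "B"), d2 = c("B", "C", "death"),
    n_both = 10, n_d1_first = 9, n_d2_first = 1, n_ties = 0,
    n_eligible = 100, stage = "retained", direction_p = 0.01,
    direction_fdr_p = 0.01, pair_or = 2, pair_ci_low = 1.2,
    pair_ci_high = 3.1, pair_p = 0.001, pair_fdr_p = 0.003,
    n_strata_used = 9, stringsAsFactors = FALSE)
  net <- build_network(pairs)
  expect_equal(igraph::vcount(net$graph), 4L)
  expect_equal(max(net$clusters$cluster), 1L)
  expect_equal(unname(igraph::degree(net$graph, "death", mode = "out")), 0)

  empty <- build_network(transform(pairs, stage = "evaluated"))
  expect_equal(igraph::ecount(empty$graph), 0L)

  bad <- transform(pairs, d1 = c("death", "B", "B"))
  expect_error(build_network(bad), "terminal|source")

  # serialization round trip preserves the edge list
  tmp <- tempfile(fileext = ".graphml")
  export_network(net, graphml = tmp)
  back <- igraph::read_graph(tmp, format = "graphml")
  el_out <- apply(igraph::as_edgelist(net$graph), 1, paste, collapse = ">")
  el_in <- apply(igraph::as_edgelist(back), 1, paste, collapse = ">")
  expect_setequal(el_in, el_out)
})
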