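edge_df <- function(...) {
  df <- data.frame(...)
  for (col in c("textmining", "experimental", "database", "coexpression")) {
    if (is.null(df[[col]])) df[[col]] <- 0
  }
  if (is.null(df$combined_score)) {
    df$combined_score <- 1 - (1 - df$textmining) * (1 - df$experimental) *
      (1 - df$database) * (1 - df$coexpression)
  }
  df
}

test_that("graph loading filters, deduplicates, and validates the schema", {
  df <- edge_df(protein1 = c("A", "B", "A"), protein2 = c("B", "A", "C"),
                experimental = c(0.69, 0.80, 0.95))
  g <- load_interaction_graph(df, combined_min = 0.7)
  # A-B duplicate collapsed to the max (0.80 >= 0.7, kept); 0.69 alone would go
  expect_equal(igraph::ecount(g), 2)
  ab <- igraph::E(g, P = c("A", "B"))
  expect_equal(igraph::E(g)$combined_score[as.integer(ab)], 0.80)

  df <- edge_df(protein1 = "A", protein2 = "B", experimental = 0.69)
  expect_error(load_interaction_graph(df, combined_min = 0.7), "no edges")

  expect_error(load_interaction_graph(data.frame(x = 1), 0.7),
               "protein1, protein2")
})

test_that("down-weighting the text-mining channel prunes text-only edges", {
  df <- edge_df(protein1 = c("A", "B"), protein2 = c("B", "C"),
                textmining = c(0.9, 0.1), experimental = c(0, 0.9))
  g <- load_interaction_graph(df, combined_min = 0.5, textmining_weight = 0)
  # the text-mining-only A-B edge collapses to combined 0 and is pruned
  expect_equal(igraph::ecount(g), 1)
  expect_false("A" %in% igraph::V(g)$name)
})

test_that("kernels implement the two degree normalizations", {
  df <- edge_df(protein1 = "A", protein2 = "B", experimental = 1)
  g <- load_interaction_graph(df, combined_min = 0.5)
  ks <- build_kernel(g, "symmetric")
  expect_equal(unname(ks$K[1, 2]), 1)  # 1/sqrt(1*1)
  expect_equal(unname(ks$K[2, 1]), 1)

  set.seed(20)
  g <- random_test_graph(25)
  kst <- build_kernel(g, "stochastic")
  expect_equal(unname(rowSums(kst$K)), rep(1, nrow(kst$K)), tolerance = 1e-12)

  # regular unit-weight graph: kernels are scalar multiples
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("R", 1:6)
  igraph::E(ring)$weight <- 1
  k1 <- build_kernel(ring, "symmetric")$K
  k2 <- build_kernel(ring, "stochastic")$K
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("propagation limit cases and the path-graph closed form hold", {
  solo <- igraph::make_graph(c(), n = 1)
  igraph::V(solo)$name <- "A"
  expect_equal(as.numeric(propagate(solo, "A")), 1)

  path <- igraph::make_graph(~ A - B, B - C)
  igraph::E(path)$weight <- 1
  # alpha = 1: pure restart, scores equal the seed vector
  p <- propagate(path, "A", alpha = 1)
  expect_equal(as.numeric(p), c(1, 0, 0))

  # 3-node path seeded at one end: matches the direct linear solve
  p <- propagate(path, "A", alpha = 0.75, kernel = "stochastic", tol = 1e-12)
  oracle <- propagate_solve(path, "A", alpha = 0.75, kernel = "stochastic")
  expect_equal(unname(p[names(oracle)]), unname(oracle), tolerance = 1e-10)

  expect_error(propagate(path, "Z"), "no seed")
  expect_message(propagate(path, c("A", "Z")), "reallocated")
})

test_that("scores are a probability vector and match igraph's PageRank", {
  set.seed(31)
  g <- random_test_graph(40)
  seeds <- igraph::V(g)$name[1:3]
  p <- propagate(g, seeds, alpha = 0.75, kernel = "stochastic")
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  s <- numeric(igraph::vcount(g))
  s[match(seeds, igraph::V(g)$name)] <- 1 / 3
  pr <- igraph::page_rank(g, personalized = s, damping = 0.25,
                          weights = igraph::E(g)$weight)$vector
  expect_equal(unname(p[names(pr)]), unname(pr), tolerance = 1e-8)
})

test_that("degree-matched null obeys the add-one rule and ranks planted nodes", {
  set.seed(5)
  g <- random_test_graph(40)
  seeds <- igraph::V(g)$name[1:2]
  null <- degree_matched_null(g, seeds, n_perm = 19, rng_seed = 99)
  expect_true(all(null$empirical_p >= 1 / 20))
  expect_true(all(null$empirical_p <= 1))

  cfg <- small_config()
  net <- simulate_interaction_network(cfg)
  gg <- load_interaction_graph(mtorwalk:::string_edge_frame(net$graph), 0.7)
  planted <- intersect(net$ground_truth$planted_community,
                       igraph::V(gg)$name)
  null <- degree_matched_null(gg, cfg$network$seed_genes, n_perm = 99,
                              rng_seed = 7)
  p_planted <- null$empirical_p[null$gene %in% planted]
  p_bg <- null$empirical_p[!null$gene %in% planted]
  expect_lt(median(p_planted), median(p_bg))
})

test_that("the non-mutated filter removes prevalent genes and breaks ties deterministically", {
  scores <- c(A = 0.3, B = 0.3, C = 0.25, D = 0.15)
  pct <- c(A = 0.5, B = 0.5, C = 3.5, D = NA)
  deg <- c(A = 5, B = 2, C = 1, D = 1)
  expect_warning(
    out <- filter_nonmutated(scores, pct, degree = deg, cutoff_pct = 3),
    "lack alteration data")
  # C at 3.5% removed; tie between A and B broken by lower degree
  expect_equal(out$nominations$Gene_Symbol, c("B", "A", "D"))
  expect_equal(out$nominations$Filtered_Rank, 1:3)
  expect_true(out$nominations$Missing_Pct[3])
  expect_false("C" %in% out$nominations$Gene_Symbol)
  expect_true("C" %in% out$unfiltered$Gene_Symbol)

  # hotspot carriers move to the side table
  out <- suppressWarnings(
    filter_nonmutated(scores, pct, hotspot_genes = "A", degree = deg))
  expect_false("A" %in% out$nominations$Gene_Symbol)
  expect_equal(out$hotspot_excluded$Gene_Symbol, "A")
})
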