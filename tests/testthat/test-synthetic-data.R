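test_that("degenerate and calibrated mutation rates are honored", {
  cfg <- small_config()
  cfg$mutation_prevalence["EIF4E", ] <- 0
  sim <- simulate_alteration_cohorts(cfg)
  expect_equal(sum(sim$alterations$mutation[, "EIF4E"]), 0L)

  # large single cohort: observed prevalence within 3 binomial SDs of 10%
  genes <- c("G1", "G2")
  big <- simulation_config(
    cohorts = "C1", n_samples_per_cohort = 10000L, genes = genes,
    mutation_prevalence = matrix(0.10, 2, 1, dimnames = list(genes, "C1")),
    cna_amp_rates = matrix(0, 2, 1, dimnames = list(genes, "C1")),
    cna_del_rates = matrix(0, 2, 1, dimnames = list(genes, "C1")),
    rng_seed = 4L
  )
  sim <- simulate_alteration_cohorts(big)
  obs <- colMeans(sim$alterations$mutation)
  sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(obs - 0.10) < sd3))
})

test_that("CNA calls follow the 5-category split with the 70/30 level rule", {
  cfg <- small_config()
  sim <- simulate_alteration_cohorts(cfg)
  cna <- sim$alterations$cna
  expect_true(all(cna %in% -2:2))
  # amplification rate 0.10, deletion 0.05 everywhere; check pooled marginals
  n <- length(cna)
  expect_lt(abs(mean(cna > 0) - 0.10), 4 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(mean(cna < 0) - 0.05), 4 * sqrt(0.05 * 0.95 / n))
  # high-level fraction within amplified cells near 0.3
  expect_lt(abs(mean(cna[cna > 0] == 2) - 0.3), 0.08)
})

test_that("planted exclusivity pair reaches its target odds ratio", {
  cfg <- pair_config(5000, odds_ratio = 0.2, marginal = 0.3, rng_seed = 21L)
  sim <- simulate_alteration_cohorts(cfg)
  a <- sim$alterations$mutation[, "PTEN"]
  b <- sim$alterations$mutation[, "PIK3CA"]
  or <- (sum(a & b) * sum(!a & !b)) / (sum(a & !b) * sum(!a & b))
  expect_gt(or, 0.1)
  expect_lt(or, 0.4)
  # marginals held fixed
  expect_equal(mean(a), 0.3, tolerance = 0.03)
  expect_equal(mean(b), 0.3, tolerance = 0.03)
})

test_that("the 2x2 joint construction hits its target exactly and rejects degenerate marginals", {
  for (pA in c(0.1, 0.3, 0.6)) {
    for (pB in c(0.2, 0.5)) {
      for (or in c(0.2, 1, 3)) {
        p <- solve_joint_2x2(pA, pB, or)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_equal(unname(p["p11"] + p["p10"]), pA, tolerance = 1e-10)
        expect_equal(unname(p["p11"] + p["p01"]), pB, tolerance = 1e-10)
        expect_equal(unname(p["p11"] * p["p00"] / (p["p10"] * p["p01"])), or,
                     tolerance = 1e-8)
      }
    }
  }
  expect_error(solve_joint_2x2(0, 0.3, 2))
  expect_error(solve_joint_2x2(0.3, 1, 2))
})

test_that("expression planting recovers the configured effect size", {
  # null: no planted effect -> group means differ by < 4 SE at n = 1000
  cfg0 <- effect_config(250, delta = 0, rng_seed = 8L)
  sim <- simulate_alteration_cohorts(cfg0)
  ex <- simulate_expression(sim$alterations, cfg0)
  act <- colMeans(ex$expression[cfg0$modules$translational, ])
  lab <- ex$genotype$PTEN_loss
  d <- mean(act[lab == 1]) - mean(act[lab == 0])
  se <- sqrt(1 / 4) * sqrt(1 / sum(lab == 1) + 1 / sum(lab == 0))
  expect_lt(abs(d), 4 * se)

  # planted delta = 0.5 on a 4-gene module, n = 2000
  cfg <- effect_config(500, delta = 0.5, rng_seed = 9L)
  sim <- simulate_alteration_cohorts(cfg)
  ex <- simulate_expression(sim$alterations, cfg)
  act <- colMeans(ex$expression[cfg$modules$translational, ])
  lab <- ex$genotype$PTEN_loss
  d <- mean(act[lab == 1]) - mean(act[lab == 0])
  expect_gt(d, 0.4)
  expect_lt(d, 0.6)
})

test_that("a fixed seed reproduces every artifact byte-for-byte", {
  cfg <- small_config(rng_seed = 33L)
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  p1 <- write_synthetic_fixtures(cfg, d1)
  p2 <- write_synthetic_fixtures(cfg, d2)
  h1 <- unname(tools::md5sum(p1))
  h2 <- unname(tools::md5sum(p2))
  expect_identical(h1, h2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted network community is a connected, enriched, high-confidence clique", {
  cfg <- small_config()
  net <- simulate_interaction_network(cfg)
  g <- net$graph
  planted <- net$ground_truth$planted_community

  sub <- igraph::induced_subgraph(g, planted)
  expect_true(igraph::is_connected(sub))

  deg <- igraph::degree(g)
  expect_gt(mean(deg[planted]), mean(deg[setdiff(names(deg), planted)]))

  # channel scores within [0,1]; combined is the noisy-or of the channels
  comb <- igraph::E(g)$combined_score
  chans <- cbind(igraph::E(g)$textmining, igraph::E(g)$experimental,
                 igraph::E(g)$database, igraph::E(g)$coexpression)
  expect_true(all(chans >= 0 & chans <= 1))
  expect_equal(comb, 1 - apply(1 - chans, 1, prod), tolerance = 1e-12)

  # combined-score filter removes exactly the sub-cutoff edges
  filtered <- load_interaction_graph(mtorwalk:::string_edge_frame(g),
                                     combined_min = 0.7)
  expect_equal(igraph::ecount(filtered), sum(comb >= 0.7))
})

test_that("fixtures round-trip through the package readers without loss", {
  cfg <- small_config(rng_seed = 12L)
  d <- file.path(tempdir(), "roundtrip")
  paths <- write_synthetic_fixtures(cfg, d)
  sim <- simulate_alteration_cohorts(cfg)

  suppressMessages({
    back <- read_alterations(paths["maf"], paths["gistic"], paths["cohorts"])
  })
  expect_identical(back$mutation[sim$alterations$samples, sim$alterations$genes],
                   sim$alterations$mutation)
  expect_identical(back$cna[sim$alterations$samples, sim$alterations$genes],
                   sim$alterations$cna)
  expect_identical(unname(back$cohort), unname(sim$alterations$cohort))

  mods <- read_gmt(paths["gmt"])
  expect_identical(mods, cfg$modules)

  edges <- read_string_edges(paths["string"])
  net <- simulate_interaction_network(cfg)
  expect_equal(nrow(edges), igraph::ecount(net$graph))
  expect_equal(sort(unique(c(edges$protein1, edges$protein2))),
               sort(igraph::V(net$graph)$name))
  unlink(d, recursive = TRUE)
})

test_that("symbol harmonization collapses known aliases", {
  expect_equal(harmonize_symbols(c("PRAS40", "PTEN", "FRAP1")),
               c("AKT1S1", "PTEN", "MTOR"))
  expect_equal(harmonize_symbols("XYZ", extra = c(XYZ = "ABC")), "ABC")
})
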