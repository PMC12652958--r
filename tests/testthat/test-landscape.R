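make_alt <- function(mut, cna, cohort) {
  cohort_alterations(mut, cna, cohort)
}

test_that("prevalence counts altered samples once per mode", {
  genes <- c("ONC", "TSG")
  samples <- paste0("S", 1:20)
  mut <- matrix(FALSE, 20, 2, dimnames = list(samples, genes))
  cna <- matrix(0L, 20, 2, dimnames = list(samples, genes))
  mut[1:2, "ONC"] <- TRUE          # 2/20 mutated
  cna[1, "ONC"] <- 2L              # sample 1 also amplified: counted once
  cna[3, "ONC"] <- 1L
  cna[4, "ONC"] <- -2L             # deletion ignored for an oncogene
  roles <- gene_roles(genes, c("oncogene", "tumor_suppressor"))
  alt <- make_alt(mut, cna, rep("C1", 20))

  pm <- compute_prevalence(alt, "mutation", roles)
  expect_equal(unname(pm$pct["ONC", "C1"]), 10)
  pu <- compute_prevalence(alt, "union", roles)
  expect_equal(unname(pu$pct["ONC", "C1"]), 15)  # S1,S2 mutated + S3 amplified
  expect_equal(unname(pu$pct["TSG", "C1"]), 0)
})

test_that("pan prevalence is the sample-weighted mean of cohort prevalences", {
  cfg <- small_config()
  cfg$n_samples_per_cohort <- c(30L, 60L, 90L, 60L, 30L)
  sim <- simulate_alteration_cohorts(cfg)
  pu <- compute_prevalence(sim$alterations, "union")
  weighted <- drop(pu$pct %*% pu$n) / sum(pu$n)
  expect_equal(unname(pu$pan_pct[names(weighted)]), unname(weighted),
               tolerance = 1e-12)
})

test_that("normalized entropy hits its closed forms", {
  for (k in c(2, 3, 7)) {
    expect_equal(as.numeric(normalized_entropy(rep(4, k))), 1, tolerance = 1e-12)
    expect_equal(as.numeric(normalized_entropy(c(9, rep(0, k - 1)))), 0)
  }
  expect_equal(as.numeric(normalized_entropy(c(0.5, 0.5, 0))),
               log(2) / log(3), tolerance = 1e-12)
  z <- normalized_entropy(c(0, 0, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(normalized_entropy(5), ">= 2")
})

test_that("tau index hits its closed forms", {
  expect_equal(as.numeric(tau_index(c(7, 0, 0))), 1)
  expect_equal(as.numeric(tau_index(rep(3, 6))), 0)
  expect_equal(as.numeric(tau_index(c(10, 5, 0))), 0.75)
  z <- tau_index(c(0, 0))
  expect_true(is.na(z))
  expect_true(attr(z, "degenerate"))
})

test_that("entropy decreases and tau increases as mass concentrates", {
  k <- 6
  base <- rep(10, k)
  shifts <- seq(0, 9, length.out = 10)
  H <- sapply(shifts, function(s) {
    v <- base; v[-1] <- v[-1] - s; v[1] <- v[1] + s * (k - 1)
    as.numeric(normalized_entropy(v))
  })
  tau <- sapply(shifts, function(s) {
    v <- base; v[-1] <- v[-1] - s; v[1] <- v[1] + s * (k - 1)
    as.numeric(tau_index(v))
  })
  expect_true(all(diff(H) < 0))
  expect_true(all(diff(tau) > 0))
})

test_that("classification applies Shared precedence and the diff rule", {
  n <- setNames(rep(100L, 6), paste0("C", 1:6))
  # both rules satisfied -> Shared wins
  v <- setNames(c(22, 11, 8, 7, 6, 5), names(n))
  expect_equal(classify_gene(v, n)$class, "Shared")

  v <- setNames(c(25, 4, 3, 2, 1, 1), names(n))
  cls <- classify_gene(v, n)
  expect_equal(cls$class, "Tumor-specific")
  expect_equal(cls$top, "C1")
  expect_equal(cls$top_vs_second_diff, 21)

  v <- setNames(rep(1, 6), names(n))
  expect_equal(classify_gene(v, n)$class, "Ambiguous")

  # invariant under cohort relabeling
  perm <- c(4, 2, 6, 1, 3, 5)
  v <- setNames(c(25, 4, 3, 2, 1, 1), names(n))
  expect_equal(classify_gene(v[perm], n[perm])$class, classify_gene(v, n)$class)

  expect_warning(out <- classify_gene(setNames(c(30, 1), c("A", "B")),
                                      setNames(c(10L, 10L), c("A", "B"))),
                 "fewer cohorts")
  expect_equal(out$class, "Ambiguous")
})

test_that("heterogeneity test reproduces the hand-computed Pearson statistic", {
  r <- heterogeneity_test(c(10, 10), c(100, 100))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- heterogeneity_test(c(30, 10), c(100, 100))
  expect_equal(r$statistic, 12.5, tolerance = 1e-10)
  expect_equal(r$test_name, "chi2_pearson")

  expect_warning(heterogeneity_test(c(5, 5, 0), c(50, 50, 0)), "zero evaluable")
})

test_that("count reconstruction rounds half away from zero", {
  expect_equal(reconstruct_counts(2.5, 100), 3L)   # 2.5 -> 3
  expect_equal(reconstruct_counts(10, 35), 4L)     # 3.5 -> 4
  expect_equal(reconstruct_counts(0, 100), 0L)
})

test_that("landscape table composes the stage outputs coherently", {
  empty <- cohort_alterations(
    matrix(FALSE, 3, 0, dimnames = list(paste0("S", 1:3), NULL)),
    matrix(0L, 3, 0, dimnames = list(paste0("S", 1:3), NULL)),
    rep("C1", 3))
  tbl <- landscape_table(empty)
  expect_equal(nrow(tbl), 0)

  cfg <- small_config()
  # plant a lineage-restricted gene: 20% in one cohort, 0.5% elsewhere
  cfg$mutation_prevalence["RICTOR", ] <- 0.005
  cfg$mutation_prevalence["RICTOR", "C3"] <- 0.20
  cfg$cna_amp_rates["RICTOR", ] <- 0
  cfg$cna_del_rates["RICTOR", ] <- 0
  sim <- simulate_alteration_cohorts(cfg)
  tbl <- landscape_table(sim$alterations)

  expect_equal(nrow(tbl), length(cfg$genes))
  expect_identical(names(tbl)[1:11],
                   c("Gene", "Mutated_Pct_Pan", "Amplified_Pct_Pan", "Entropy",
                     "Tau", "Class", "Top_Cancer", "Second_Cancer",
                     "Top_vs_Second_Diff", "Chi2_p", "BH_FDR_q"))
  # q consistent with BH over the table's p column
  expect_equal(tbl$BH_FDR_q, bh_fdr(tbl$Chi2_p))
  expect_true(all(tbl$BH_FDR_q >= tbl$Chi2_p - 1e-15))

  rictor <- tbl[tbl$Gene == "RICTOR", ]
  expect_equal(rictor$Class, "Tumor-specific")
  expect_gt(rictor$Tau, 0.9)
  expect_equal(rictor$Top_Cancer, "C3")
})
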