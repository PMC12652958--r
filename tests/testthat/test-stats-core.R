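test_that("BH step-up adjustment matches hand computation and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("Fisher exact test follows the probability-mass convention", {
  r <- fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$effect, 1)
  expect_equal(r$p_value, 1)
  expect_false(r$corrected)

  r <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(r$effect, 121)  # Haldane +0.5 on all cells
  expect_true(r$corrected)

  r <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))
  expect_equal(r$effect, 9)

  # zero margin carries no information
  r <- fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$effect))
  expect_false(r$evaluable)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-squared test reproduces hand computation and the Yates shrinkage", {
  r <- chi2_test(matrix(c(25, 75, 25, 75), 2, byrow = TRUE))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  tab <- matrix(c(20, 80, 40, 60), 2, byrow = TRUE)
  pearson <- chi2_test(tab, yates = FALSE)
  expect_equal(pearson$statistic, 200 / 21, tolerance = 1e-10) # 9.5238...
  yates <- chi2_test(tab, yates = TRUE)
  expect_lt(yates$statistic, pearson$statistic)
  expect_equal(dim(pearson$expected), c(2L, 2L))

  expect_error(chi2_test(matrix(1:6, 3), yates = TRUE), "2x2")
})

test_that("the small-count rule switches between Fisher and Yates chi-squared", {
  sparse <- matrix(c(2, 8, 1, 9), 2, byrow = TRUE)   # expected < 5
  expect_equal(association_test_2x2(sparse)$test_name, "fisher_exact")
  dense <- matrix(c(30, 70, 40, 60), 2, byrow = TRUE)
  expect_equal(association_test_2x2(dense)$test_name, "chi2_yates")
})

test_that("Mann-Whitney U: exact enumeration, convention, and power", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 9)  # all 9 cross-pairs won by group1
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_true(r$exact)
  expect_equal(r$effect, 1)

  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r$p_value, 0.99)
  expect_equal(r$effect, 0)

  set.seed(1)
  r <- mann_whitney(rnorm(200), rnorm(200, mean = 1))
  expect_lt(r$p_value, 1e-10)
  expect_false(r$exact)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Cliff's delta matches the cross-pair definition", {
  expect_equal(cliffs_delta(c(1, 2), c(2, 3)), 0.75)
  expect_equal(cliffs_delta(1:5, 1:5), 0)
  expect_equal(cliffs_delta(1:3, 4:6), 1)
  expect_equal(cliffs_delta(4:6, 1:3), -1)

  brute <- function(g0, g1) {
    (sum(outer(g1, g0, ">")) - sum(outer(g1, g0, "<"))) /
      (length(g0) * length(g1))
  }
  set.seed(3)
  for (i in 1:20) {
    g0 <- sample(1:8, 7, replace = TRUE)
    g1 <- sample(1:8, 5, replace = TRUE)
    expect_equal(cliffs_delta(g0, g1), brute(g0, g1))
    # antisymmetry under group swap
    expect_equal(cliffs_delta(g1, g0), -cliffs_delta(g0, g1))
  }
})

test_that("robust linear model recovers exact fits and flags rank deficiency", {
  g <- rep(c(0, 1), each = 20)
  fit <- suppressWarnings(linear_model_robust(g, data.frame(genotype = g)))
  est <- fit$estimate[fit$term == "genotype"]
  expect_equal(est, 1, tolerance = 1e-12)
  expect_lt(attr(fit, "sigma"), 1e-10)

  set.seed(5)
  d <- data.frame(genotype = g, copy = g)  # perfectly collinear
  expect_error(linear_model_robust(rnorm(40), d), "rank deficient")
})

test_that("robust model genotype CI covers zero under label permutation", {
  set.seed(9)
  y <- rnorm(200)
  cohort <- factor(rep(c("A", "B"), each = 100))
  cover <- 0L
  for (i in 1:100) {
    g <- sample(rep(c(0, 1), each = 100))
    fit <- linear_model_robust(y, data.frame(genotype = g, cohort = cohort))
    row <- fit[fit$term == "genotype", ]
    cover <- cover + (row$conf_low <= 0 && row$conf_high >= 0)
  }
  expect_gte(cover, 90L)
})
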