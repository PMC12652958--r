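#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment of a vector of p-values, returned in input order.
#' q-values are monotone along the sorted p-values and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`. Ties and zeros are allowed.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric, non-missing, and lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Construct a test-result record
#'
#' Light container used by all stage-level tests so that downstream tables
#' can record which decision rule fired.
#'
#' @param statistic Test statistic (may be `NA`).
#' @param p_value Two-sided p-value in `[0, 1]`.
#' @param test_name One of `"fisher_exact"`, `"chi2_yates"`, `"chi2_pearson"`,
#'   `"chi2_mc"`, `"mann_whitney"`.
#' @param effect Optional effect size (odds ratio or Cliff's delta).
#' @param n_evaluable Number of observations entering the test.
#' @param ... Additional named fields (e.g. `expected`, `conf_int`,
#'   `corrected`, `evaluable`).
#' @return A list of class `mtor_test`.
#' @keywords internal
test_result <- function(statistic, p_value, test_name, effect = NA_real_,
                        n_evaluable = NA_integer_, ...) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    c(list(statistic = unname(statistic), p_value = min(unname(p_value), 1),
           test_name = test_name, effect = unname(effect),
           n_evaluable = as.integer(n_evaluable)),
      list(...)),
    class = "mtor_test"
  )
}

#' @export
print.mtor_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %s, p = %s, effect = %s, n = %d\n",
              x$test_name, format(x$statistic), format(x$p_value),
              format(x$effect), x$n_evaluable))
  invisible(x)
}

check_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  counts
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table are summed. The point odds ratio is the
#' sample cross-product `(ad)/(bc)`; when any cell is zero the reported
#' estimate applies the Haldane-Anscombe +0.5 correction to every cell and is
#' flagged via `corrected`. The 95% CI on the log odds ratio uses the normal
#' (Woolf) approximation with the same correction.
#'
#' A table with a zero row or column margin carries no information about
#' association: the result is marked non-evaluable with `p = 1` and a missing
#' odds ratio.
#'
#' @param counts 2x2 matrix of non-negative integer counts; rows index one
#'   binary variable, columns the other.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return An `mtor_test` with fields `effect` (odds ratio), `conf_int`,
#'   `corrected`, `evaluable`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_2x2 <- function(counts, conf_level = 0.95) {
  counts <- check_2x2(counts)
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d

  if (any(c(r1, r2, c1, c2) == 0)) {
    return(test_result(NA_real_, 1, "fisher_exact", effect = NA_real_,
                       n_evaluable = n, conf_int = c(NA_real_, NA_real_),
                       corrected = FALSE, evaluable = FALSE))
  }

  # X = count in cell (1,1) ~ Hypergeometric(c1 successes, c2 failures, r1 draws)
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  corrected <- any(counts == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    se <- sqrt(sum(1 / (counts + 0.5)))
  } else {
    or <- (a * d) / (b * c)
    se <- sqrt(sum(1 / counts))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)

  test_result(NA_real_, p, "fisher_exact", effect = or, n_evaluable = n,
              conf_int = ci, corrected = corrected, evaluable = TRUE)
}

#' Chi-squared test of independence
#'
#' Pearson's chi-squared on an `r x 2` table, with the Yates continuity
#' correction available for 2x2 tables only. The expected-count matrix is
#' returned so callers can apply the small-count decision rule.
#'
#' @param counts Non-negative integer matrix, 2x2 or Kx2.
#' @param yates Apply the Yates continuity correction (2x2 tables only).
#' @return An `mtor_test` with fields `df` and `expected`.
#' @examples
#' chi2_test(matrix(c(20, 40, 80, 60), 2), yates = FALSE)
#' @export
chi2_test <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L || nrow(counts) < 2L) stop("expected a Kx2 table, K >= 2")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (yates && nrow(counts) > 2L) {
    stop("the Yates correction is defined for 2x2 tables only")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  test_result(ct$statistic, ct$p.value,
              if (yates) "chi2_yates" else "chi2_pearson",
              n_evaluable = sum(counts),
              df = unname(ct$parameter), expected = ct$expected)
}

#' 2x2 association test with automatic exact/asymptotic selection
#'
#' Applies the small-count rule used throughout the pipeline: Fisher's exact
#' test when any expected cell count is below 5, otherwise the Yates-corrected
#' chi-squared test.
#'
#' @inheritParams fisher_exact_2x2
#' @return An `mtor_test`; `test_name` records which rule fired.
#' @export
association_test_2x2 <- function(counts) {
  counts <- check_2x2(counts)
  n <- sum(counts)
  if (n == 0 || any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(fisher_exact_2x2(counts))
  }
  expected <- outer(rowSums(counts), colSums(counts)) / n
  if (any(expected < 5)) fisher_exact_2x2(counts) else chi2_test(counts, yates = TRUE)
}

#' Mann-Whitney U test
#'
#' Compares two independent samples. The reported statistic is
#' `U1 = #\{x1 > x0\} + 0.5 #\{x1 = x0\}` over all cross-pairs (wins of
#' `group1`). The p-value is exact (enumeration) when `n0 + n1 <= 20` with no
#' ties, otherwise a tie-corrected normal approximation with continuity
#' correction is used. Cliff's delta is attached as the effect size.
#'
#' @param group0,group1 Non-empty numeric vectors.
#' @return An `mtor_test` with `effect` = Cliff's delta and field `exact`.
#' @export
mann_whitney <- function(group0, group1) {
  if (length(group0) == 0L || length(group1) == 0L) {
    stop("both groups must be non-empty")
  }
  n0 <- length(group0); n1 <- length(group1)
  ties <- anyDuplicated(c(group0, group1)) > 0L
  exact <- (n0 + n1 <= 20L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group1, group0, exact = exact, correct = TRUE)
  )
  test_result(unname(wt$statistic), wt$p.value, "mann_whitney",
              effect = cliffs_delta(group0, group1),
              n_evaluable = n0 + n1, exact = exact)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x1 > x0\} - #\{x1 < x0\}) / (n0 * n1)` over all cross-pairs.
#' Positive values mean `group1` is stochastically larger. Computed from
#' midranks, so it scales to large samples.
#'
#' @param group0,group1 Non-empty numeric vectors.
#' @return A number in `[-1, 1]`.
#' @examples
#' cliffs_delta(c(1, 2), c(2, 3)) # 0.75
#' @export
cliffs_delta <- function(group0, group1) {
  if (length(group0) == 0L || length(group1) == 0L) {
    stop("both groups must be non-empty")
  }
  n0 <- length(group0); n1 <- length(group1)
  r <- rank(c(group0, group1))
  u1 <- sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u1 / (n0 * n1) - 1
}

#' Linear model with heteroskedasticity-robust standard errors
#'
#' Ordinary least squares with an HC1 sandwich covariance, Wald confidence
#' intervals and p-values. Categorical covariates (e.g. cancer cohort) are
#' dummy-encoded against a reference level by the standard model-matrix
#' machinery.
#'
#' @param response Numeric response vector.
#' @param design Data frame of predictors (e.g. a binary genotype indicator
#'   and a factor-valued cohort column).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A data frame with one row per coefficient: `term`, `estimate`,
#'   `se`, `statistic`, `p_value`, `conf_low`, `conf_high`. The residual
#'   standard deviation is attached as attribute `sigma`.
#' @export
linear_model_robust <- function(response, design, conf_level = 0.95) {
  design <- as.data.frame(design)
  if (length(response) != nrow(design)) stop("response/design length mismatch")
  if (length(response) <= ncol(design) + 1L) {
    stop("need more observations than parameters")
  }
  dat <- cbind(data.frame(.response = response), design)
  fit <- stats::lm(.response ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("design is rank deficient; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = "HC1")
  ct <- suppressWarnings(lmtest::coeftest(fit, vcov. = vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = rownames(ct),
    estimate = ct[, 1],
    se = ct[, 2],
    statistic = ct[, 3],
    p_value = ct[, 4],
    conf_low = ct[, 1] - z * ct[, 2],
    conf_high = ct[, 1] + z * ct[, 2],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "sigma") <- stats::sigma(fit)
  out
}
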