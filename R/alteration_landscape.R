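#' Gene role table
#'
#' Maps each panel gene to a functional role used by the role-aware
#' alteration encodings: oncogenes count amplifications as altered, tumor
#' suppressors count deletions, unspecified genes count any non-zero
#' copy-number call. A logical hotspot flag marks genes carrying recurrent
#' activating hotspot variants (excluded from non-mutated nominations).
#'
#' @param genes Character vector of gene symbols.
#' @param role Character vector (recycled) drawn from `"oncogene"`,
#'   `"tumor_suppressor"`, `"unspecified"`.
#' @param hotspot Logical vector (recycled).
#' @return Data frame with columns `gene`, `role`, `hotspot`.
#' @export
gene_roles <- function(genes, role = "unspecified", hotspot = FALSE) {
  role <- rep(role, length.out = length(genes))
  if (!all(role %in% c("oncogene", "tumor_suppressor", "unspecified"))) {
    stop("role must be oncogene, tumor_suppressor or unspecified")
  }
  data.frame(gene = genes, role = role,
             hotspot = rep(as.logical(hotspot), length.out = length(genes)),
             stringsAsFactors = FALSE)
}

#' Default roles for the mTOR-axis panel
#'
#' PTEN, TSC1 and TSC2 are tumor suppressors; the kinases, adaptors and
#' translational effectors are treated as oncogenic candidates; genes outside
#' the known panel default to unspecified.
#'
#' @param genes Character vector of gene symbols.
#' @return A [gene_roles()] data frame.
#' @export
default_gene_roles <- function(genes) {
  tsg <- c("PTEN", "TSC1", "TSC2")
  onc <- c("PIK3CA", "MTOR", "RPTOR", "RICTOR", "MLST8", "RPS6KB1",
           "EIF4EBP1", "RPS6", "AKT1", "EIF4E", "RHEB", "AKT1S1")
  role <- ifelse(genes %in% tsg, "tumor_suppressor",
                 ifelse(genes %in% onc, "oncogene", "unspecified"))
  gene_roles(genes, role)
}

role_lookup <- function(roles, genes) {
  r <- stats::setNames(roles$role, roles$gene)[genes]
  r[is.na(r)] <- "unspecified"
  r
}

#' Per-sample altered indicator under a given alteration mode
#'
#' @param alterations A [cohort_alterations()].
#' @param mode One of `"mutation"`, `"amplification"`, `"deletion"`,
#'   `"union"` (mutation OR the role-appropriate copy-number event).
#' @param roles A [gene_roles()] data frame (required for `"union"`).
#' @return Logical samples x genes matrix; a gene whose copy-number calls are
#'   entirely missing yields `NA` under the CNA-dependent modes.
#' @export
altered_matrix <- function(alterations,
                           mode = c("union", "mutation", "amplification", "deletion"),
                           roles = NULL) {
  mode <- match.arg(mode)
  mut <- alterations$mutation
  cna <- alterations$cna
  amp <- !is.na(cna) & cna > 0
  del <- !is.na(cna) & cna < 0
  any_cna <- !is.na(cna) & cna != 0
  out <- switch(mode,
    mutation = mut,
    amplification = amp,
    deletion = del,
    union = {
      if (is.null(roles)) roles <- default_gene_roles(alterations$genes)
      r <- role_lookup(roles, alterations$genes)
      cna_part <- any_cna
      cna_part[, r == "oncogene"] <- amp[, r == "oncogene"]
      cna_part[, r == "tumor_suppressor"] <- del[, r == "tumor_suppressor"]
      mut | cna_part
    }
  )
  if (mode != "mutation") {
    all_missing <- colSums(!is.na(cna)) == 0L
    if (any(all_missing)) {
      message("genes with no copy-number data: ",
              paste(alterations$genes[all_missing], collapse = ", "))
      out[, all_missing] <- NA
    }
  }
  out
}

#' Per-cohort alteration prevalence
#'
#' Percentage of evaluable samples altered within each cohort, under the
#' requested encoding, plus the pooled pan-cohort percentage.
#'
#' @inheritParams altered_matrix
#' @return A list of class `prevalence_matrix` with `pct` (genes x cohorts,
#'   percent), `pan_pct` (named vector over the pooled samples), `n` (samples
#'   per cohort) and `mode`.
#' @export
compute_prevalence <- function(alterations,
                               mode = c("union", "mutation", "amplification", "deletion"),
                               roles = NULL) {
  mode <- match.arg(mode)
  alt <- altered_matrix(alterations, mode, roles)
  cohorts <- sort(unique(alterations$cohort))
  pct <- sapply(cohorts, function(co) {
    100 * colMeans(alt[alterations$cohort == co, , drop = FALSE])
  })
  pct <- matrix(pct, nrow = length(alterations$genes),
                dimnames = list(alterations$genes, cohorts))
  structure(list(
    pct = pct,
    pan_pct = 100 * colMeans(alt),
    n = stats::setNames(as.integer(table(alterations$cohort)[cohorts]), cohorts),
    mode = mode
  ), class = "prevalence_matrix")
}

#' Normalized Shannon entropy of a prevalence vector
#'
#' `H = -sum(p_i log p_i) / log K` on the normalized vector, natural log
#' (normalization makes the base irrelevant); `0 log 0 = 0`. Uniform vectors
#' give 1, one-hot vectors 0. An all-zero vector returns 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param x Non-negative prevalence vector over `K >= 2` cohorts.
#' @return A number in `[0, 1]`.
#' @export
normalized_entropy <- function(x) {
  k <- length(x)
  if (k < 2L) stop("entropy requires >= 2 cohorts")
  if (anyNA(x) || any(x < 0)) stop("prevalences must be non-negative")
  s <- sum(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  p <- x / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(k)
}

#' Tau specificity index of a prevalence vector
#'
#' `tau = sum(1 - x_i / max(x)) / (K - 1)`: 0 for uniform vectors, 1 for
#' one-hot vectors. An all-zero vector returns `NA` with attribute
#' `degenerate = TRUE`.
#'
#' @inheritParams normalized_entropy
#' @return A number in `[0, 1]`.
#' @export
tau_index <- function(x) {
  k <- length(x)
  if (k < 2L) stop("tau requires >= 2 cohorts")
  if (anyNA(x) || any(x < 0)) stop("prevalences must be non-negative")
  m <- max(x)
  if (m == 0) return(structure(NA_real_, degenerate = TRUE))
  sum(1 - x / m) / (k - 1)
}

#' Classification cutoffs for the shared / tumor-specific rule
#' @param shared_min_pct Minimum per-cohort prevalence (percent) counting
#'   toward the Shared rule.
#' @param shared_min_studies Minimum number of cohorts at or above
#'   `shared_min_pct` for a Shared call.
#' @param specific_diff_pp Minimum top-minus-second difference (percentage
#'   points) for a Tumor-specific call.
#' @return Named list of cutoffs.
#' @export
landscape_cutoffs <- function(shared_min_pct = 5, shared_min_studies = 5,
                              specific_diff_pp = 10) {
  list(shared_min_pct = shared_min_pct,
       shared_min_studies = shared_min_studies,
       specific_diff_pp = specific_diff_pp)
}

#' Classify a gene as Shared, Tumor-specific or Ambiguous
#'
#' Shared (>= `shared_min_pct`% in >= `shared_min_studies` cohorts) is
#' evaluated first and takes precedence even when the top-minus-second
#' difference also exceeds the Tumor-specific cutoff; otherwise
#' Tumor-specific when top - second >= `specific_diff_pp` percentage points;
#' otherwise Ambiguous. Top/second cohorts are ranked by prevalence with ties
#' broken by larger cohort size, then lexicographic label.
#'
#' @param prevalences Named numeric vector of per-cohort percentages.
#' @param n Optional named vector of cohort sizes (tie-break only).
#' @param cutoffs A [landscape_cutoffs()] list.
#' @return List with `class`, `top`, `second`, `top_vs_second_diff`.
#' @export
classify_gene <- function(prevalences, n = NULL, cutoffs = landscape_cutoffs()) {
  k <- length(prevalences)
  labels <- names(prevalences)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  if (is.null(n)) n <- stats::setNames(rep(1L, k), labels)
  ord <- order(-prevalences, -n[labels], labels)
  top <- labels[ord[1]]
  second <- if (k >= 2L) labels[ord[2]] else NA_character_
  diff <- if (k >= 2L) prevalences[ord[1]] - prevalences[ord[2]] else NA_real_

  if (k < cutoffs$shared_min_studies) {
    warning("fewer cohorts than shared_min_studies; classification is Ambiguous")
    cls <- "Ambiguous"
  } else if (sum(prevalences >= cutoffs$shared_min_pct) >= cutoffs$shared_min_studies) {
    cls <- "Shared"
  } else if (!is.na(diff) && diff >= cutoffs$specific_diff_pp) {
    cls <- "Tumor-specific"
  } else {
    cls <- "Ambiguous"
  }
  list(class = cls, top = top, second = second,
       top_vs_second_diff = unname(diff))
}

#' Reconstruct integer counts from prevalence and cohort size
#'
#' Rounds half away from zero so the reconstruction is stable across
#' platforms.
#' @param pct Prevalence in percent.
#' @param n Cohort size.
#' @return Integer vector of altered counts.
#' @export
reconstruct_counts <- function(pct, n) {
  x <- pct * n / 100
  as.integer(trunc(x + 0.5 * sign(x)))
}

#' Between-cohort heterogeneity test for one gene
#'
#' Pearson's chi-squared on the K x 2 (altered, not altered) table; when any
#' expected count falls below 5 an exact test is substituted (full
#' enumeration for 2 cohorts, Monte-Carlo otherwise). Cohorts with zero
#' evaluable samples are dropped with a warning.
#'
#' @param altered Integer vector of altered counts per cohort.
#' @param n Integer vector of evaluable samples per cohort.
#' @return An `mtor_test`.
#' @export
heterogeneity_test <- function(altered, n) {
  stopifnot(length(altered) == length(n), all(altered <= n))
  keep <- n > 0
  if (!all(keep)) {
    warning("dropping cohorts with zero evaluable samples")
    altered <- altered[keep]; n <- n[keep]
  }
  if (length(n) < 2L) stop("heterogeneity requires >= 2 cohorts")
  tab <- cbind(altered = altered, not_altered = n - altered)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    if (nrow(tab) == 2L) return(fisher_exact_2x2(tab))
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 2000)
    return(test_result(NA_real_, ft$p.value, "chi2_mc", n_evaluable = sum(n)))
  }
  chi2_test(tab, yates = FALSE)
}

#' Pan-cancer specificity landscape table
#'
#' One row per gene: pooled mutated/amplified percentages, normalized
#' entropy and tau on the per-cohort union prevalences, the
#' Shared/Tumor-specific/Ambiguous class with top and second cohorts,
#' the between-cohort heterogeneity test and its BH-FDR q over the gene
#' panel, plus mutation-only and amplification-only sensitivity metrics.
#'
#' @param alterations A [cohort_alterations()].
#' @param roles A [gene_roles()] data frame.
#' @param cutoffs A [landscape_cutoffs()] list.
#' @return Data frame (one row per gene) with attribute `meta` recording the
#'   cutoffs, encoding mode and BH family size.
#' @export
landscape_table <- function(alterations, roles = default_gene_roles(alterations$genes),
                            cutoffs = landscape_cutoffs()) {
  genes <- alterations$genes
  if (length(genes) == 0L) {
    out <- data.frame(Gene = character(0))
    attr(out, "meta") <- list(cutoffs = cutoffs, mode = "union", bh_family = 0L)
    return(out)
  }
  prev_u <- compute_prevalence(alterations, "union", roles)
  prev_m <- compute_prevalence(alterations, "mutation", roles)
  prev_a <- compute_prevalence(alterations, "amplification", roles)
  n <- prev_u$n

  rows <- lapply(genes, function(g) {
    v <- prev_u$pct[g, ]
    cls <- classify_gene(v, n, cutoffs)
    het <- heterogeneity_test(reconstruct_counts(v, n), n)
    data.frame(
      Gene = g,
      Mutated_Pct_Pan = round(prev_m$pan_pct[[g]], 3),
      Amplified_Pct_Pan = round(prev_a$pan_pct[[g]], 3),
      Entropy = round(as.numeric(normalized_entropy(v)), 4),
      Tau = round(as.numeric(tau_index(v)), 4),
      Class = cls$class,
      Top_Cancer = cls$top,
      Second_Cancer = cls$second,
      Top_vs_Second_Diff = round(cls$top_vs_second_diff, 3),
      Chi2_p = het$p_value,
      Entropy_Mutation = round(as.numeric(normalized_entropy(prev_m$pct[g, ])), 4),
      Tau_Mutation = round(as.numeric(tau_index(prev_m$pct[g, ])), 4),
      Entropy_Amplification = round(as.numeric(normalized_entropy(prev_a$pct[g, ])), 4),
      Tau_Amplification = round(as.numeric(tau_index(prev_a$pct[g, ])), 4),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$BH_FDR_q <- bh_fdr(out$Chi2_p)
  front <- c("Gene", "Mutated_Pct_Pan", "Amplified_Pct_Pan", "Entropy", "Tau",
             "Class", "Top_Cancer", "Second_Cancer", "Top_vs_Second_Diff",
             "Chi2_p", "BH_FDR_q")
  out <- out[, c(front, setdiff(names(out), front))]
  rownames(out) <- NULL
  attr(out, "meta") <- list(cutoffs = cutoffs, mode = "union",
                            bh_family = nrow(out),
                            n_per_cohort = as.list(n))
  out
}

#' Write the landscape table and its metadata
#' @param table Output of [landscape_table()].
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_landscape <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "landscape.tsv"),
             meta = file.path(dir, "landscape_meta.json"))
  write_tsv(table, paths["table"])
  write_json_meta(attr(table, "meta"), paths["meta"])
  invisible(paths)
}
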