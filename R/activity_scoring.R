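#' Pooled gene-wise z-scores
#'
#' Centers and scales each gene across the pooled sample set (sample SD,
#' denominator `n - 1`). Genes with zero variance carry no contrast and are
#' dropped with a warning.
#'
#' @param expression Genes x samples numeric matrix.
#' @return Genes x samples matrix of z-scores.
#' @export
pooled_zscores <- function(expression) {
  if (ncol(expression) < 2L) stop("z-scoring requires >= 2 samples")
  sds <- apply(expression, 1, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warning("dropping zero-variance genes: ",
            paste(rownames(expression)[flat], collapse = ", "))
    expression <- expression[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  (expression - rowMeans(expression)) / sds
}

#' Module activity as mean member z-score
#'
#' Arithmetic mean of the constituent genes' z-scores, per sample. Members
#' absent from the matrix are skipped with a message; a module with no
#' measured member is an error.
#'
#' @param z Genes x samples z-score matrix.
#' @param members Character vector of module member genes.
#' @return Named per-sample numeric vector.
#' @export
module_activity <- function(z, members) {
  present <- intersect(members, rownames(z))
  if (length(present) == 0L) stop("no module member present in the z matrix")
  absent <- setdiff(members, present)
  if (length(absent)) {
    message("module members absent from expression: ",
            paste(absent, collapse = ", "))
  }
  colMeans(z[present, , drop = FALSE])
}

#' Binary genotype groups for a contrast
#'
#' Encodes carrier (1) versus comparator (0) status per sample:
#' * `loss`: mutation OR copy-number deletion (-1/-2); comparator = everyone
#'   else (the tumor-suppressor encoding).
#' * `mutation`: mutation flag only.
#' * `amplification`: copy-number gain (+1/+2) versus diploid; samples with a
#'   deletion are excluded (`NA`) so the comparator is genuinely diploid.
#'
#' @param alterations A [cohort_alterations()].
#' @param gene Contrast gene.
#' @param event One of `"loss"`, `"mutation"`, `"amplification"`.
#' @return Integer vector (1 carrier, 0 comparator, `NA` excluded), named by
#'   sample.
#' @export
genotype_groups <- function(alterations, gene,
                            event = c("loss", "mutation", "amplification")) {
  event <- match.arg(event)
  if (!gene %in% alterations$genes) stop("gene not present: ", gene)
  mut <- alterations$mutation[, gene]
  cna <- alterations$cna[, gene]
  out <- switch(event,
    loss = as.integer(mut | (!is.na(cna) & cna < 0)),
    mutation = as.integer(mut),
    amplification = {
      lab <- ifelse(!is.na(cna) & cna > 0, 1L,
                    ifelse(!is.na(cna) & cna < 0, NA_integer_, 0L))
      as.integer(lab)
    })
  stats::setNames(out, alterations$samples)
}

#' Genotype-module association tests
#'
#' For every contrast x module combination: a Mann-Whitney comparison of
#' module activity between carriers and comparators with Cliff's delta,
#' group medians/IQRs and the median difference (carrier minus comparator),
#' plus a cohort-adjusted linear model with HC1 robust standard errors whose
#' genotype coefficient is the adjusted activity shift. BH-FDR is applied
#' over all emitted rows (the table is the correction family).
#'
#' @param z Genes x samples z-score matrix (see [pooled_zscores()]).
#' @param modules Named list of member-gene vectors.
#' @param alterations A [cohort_alterations()] covering the same samples.
#' @param contrasts Named list; each element `list(gene, event)` as in
#'   [genotype_groups()].
#' @return A list of class `activity_associations`: `table` (one row per
#'   contrast x module), `delta_matrix` (modules x contrasts matrix of
#'   adjusted coefficients), `scores` (per-sample module scores with cohort
#'   and genotype labels), `meta` (BH family size, skipped contrasts).
#' @export
association_tests <- function(z, modules, alterations, contrasts) {
  samples <- intersect(colnames(z), alterations$samples)
  dropped <- length(alterations$samples) - length(samples)
  if (dropped > 0) {
    message(dropped, " samples lack expression and are dropped from activity scoring")
  }
  if (length(samples) == 0L) stop("no overlap between expression and alteration samples")
  z <- z[, samples, drop = FALSE]
  cohort <- alterations$cohort[samples]

  scores <- data.frame(sample = samples, cohort = unname(cohort),
                       stringsAsFactors = FALSE)
  for (m in names(modules)) scores[[m]] <- module_activity(z, modules[[m]])

  multi_cohort <- length(unique(cohort)) > 1L
  skipped <- character(0)
  rows <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    labels <- genotype_groups(alterations, ct$gene, ct$event)[samples]
    scores[[paste0("genotype_", cn)]] <- labels
    keep <- !is.na(labels)
    if (sum(labels[keep] == 1L) == 0L || sum(labels[keep] == 0L) == 0L) {
      skipped <- c(skipped, cn)
      next
    }
    for (m in names(modules)) {
      act <- scores[[m]]
      g0 <- act[keep & labels == 0L]
      g1 <- act[keep & labels == 1L]
      mw <- mann_whitney(g0, g1)

      design <- data.frame(genotype = labels[keep])
      if (multi_cohort) design$cohort <- factor(cohort[keep])
      lmfit <- tryCatch(linear_model_robust(act[keep], design),
                        error = function(e) NULL)
      if (is.null(lmfit)) {
        model <- rep(NA_real_, 4)
      } else {
        gi <- lmfit[lmfit$term == "genotype", ]
        model <- c(gi$estimate, gi$conf_low, gi$conf_high, gi$p_value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        Contrast = cn, Module = m, Method = "Mann-Whitney (Cliff's delta)",
        p = mw$p_value, q = NA_real_, Cliffs_delta = mw$effect,
        Median_Diff = stats::median(g1) - stats::median(g0),
        N0 = length(g0), N1 = length(g1),
        Median0 = stats::median(g0), Median1 = stats::median(g1),
        IQR0 = stats::IQR(g0), IQR1 = stats::IQR(g1),
        Model_Delta = model[1], Model_CI_low = model[2],
        Model_CI_high = model[3], Model_p = model[4],
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Contrast = character(0))
  if (nrow(tab)) tab$q <- bh_fdr(tab$p)
  rownames(tab) <- NULL

  delta <- matrix(NA_real_, length(modules), length(contrasts),
                  dimnames = list(names(modules), names(contrasts)))
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      delta[tab$Module[i], tab$Contrast[i]] <- tab$Model_Delta[i]
    }
  }
  structure(list(table = tab, delta_matrix = delta, scores = scores,
                 meta = list(bh_family = nrow(tab), skipped = skipped,
                             cohort_adjusted = multi_cohort)),
            class = "activity_associations")
}

#' Write activity associations
#' @param assoc Output of [association_tests()].
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_activity <- function(assoc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "activity.tsv"),
             delta = file.path(dir, "delta_matrix.tsv"),
             meta = file.path(dir, "activity_meta.json"))
  write_tsv(assoc$table, paths["table"])
  dm <- data.frame(Module = rownames(assoc$delta_matrix), assoc$delta_matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(dm, paths["delta"])
  write_json_meta(assoc$meta, paths["meta"])
  invisible(paths)
}
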