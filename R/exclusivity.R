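#' Role-aware binary alteration matrix
#'
#' One boolean per sample x gene under the role rule: oncogenes are altered
#' by mutation or amplification, tumor suppressors by mutation or deletion,
#' unspecified genes by mutation or any non-zero copy-number call (flagged).
#' Restricted encodings (`"mutation"`, `"scna"`) support the sensitivity
#' reruns on mutation-only or copy-number-only matrices.
#'
#' @param alterations A [cohort_alterations()].
#' @param roles A [gene_roles()] data frame.
#' @param encoding `"role"` (default), `"mutation"`, or `"scna"` (the
#'   role-appropriate copy-number event alone).
#' @return Logical samples x genes matrix with attribute `encoding` (a named
#'   character vector recording each gene's rule).
#' @export
binarize_alterations <- function(alterations,
                                 roles = default_gene_roles(alterations$genes),
                                 encoding = c("role", "mutation", "scna")) {
  encoding <- match.arg(encoding)
  r <- role_lookup(roles, alterations$genes)
  cna <- alterations$cna
  amp <- !is.na(cna) & cna > 0
  del <- !is.na(cna) & cna < 0
  any_cna <- !is.na(cna) & cna != 0
  cna_part <- any_cna
  cna_part[, r == "oncogene"] <- amp[, r == "oncogene"]
  cna_part[, r == "tumor_suppressor"] <- del[, r == "tumor_suppressor"]
  # samples with no CNA measurement fall back to the mutation flag
  out <- switch(encoding,
    role = alterations$mutation | cna_part,
    mutation = alterations$mutation,
    scna = cna_part
  )
  prov <- ifelse(r == "oncogene", "mutation|amplification",
                 ifelse(r == "tumor_suppressor", "mutation|deletion",
                        "mutation|any_cna"))
  if (encoding == "mutation") prov[] <- "mutation"
  if (encoding == "scna") prov <- sub("mutation\\|", "", prov)
  attr(out, "encoding") <- stats::setNames(prov, alterations$genes)
  out
}

#' All-pairs mutual exclusivity / co-occurrence tests
#'
#' For every unordered gene pair, builds the 2x2 co-alteration table over the
#' jointly evaluable samples and applies the small-count rule (Fisher's exact
#' test when any expected count < 5, Yates-corrected chi-squared otherwise).
#' The odds ratio is the sample cross-product with the Haldane-Anscombe +0.5
#' estimate when a cell is zero (flagged); negative `log2_odds_ratio` means
#' mutual exclusivity, positive co-occurrence. BH-FDR is applied over all
#' emitted pairs in the run. Pairs with a degenerate margin (a gene never or
#' always altered) are emitted as non-evaluable.
#'
#' @param binary Logical samples x genes matrix from
#'   [binarize_alterations()].
#' @return Data frame with one row per pair: `geneA`, `geneB`, 2x2 counts
#'   `n11`, `n10`, `n01`, `n00`, `odds_ratio`, `log2_odds_ratio`,
#'   `test_name`, `statistic`, `p`, `q`, `n_evaluable`, `corrected`,
#'   `evaluable`, `direction`.
#' @export
pairwise_association <- function(binary) {
  genes <- colnames(binary)
  if (length(genes) < 2L) stop("need >= 2 genes")
  pairs <- utils::combn(genes, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    a <- binary[, ga]; b <- binary[, gb]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    counts <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                     2, 2, byrow = TRUE)
    res <- association_test_2x2(counts)
    evaluable <- !identical(res$evaluable, FALSE)
    or <- if (res$test_name == "fisher_exact") res$effect else {
      if (any(counts == 0)) {
        ((counts[1, 1] + 0.5) * (counts[2, 2] + 0.5)) /
          ((counts[1, 2] + 0.5) * (counts[2, 1] + 0.5))
      } else {
        (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
      }
    }
    l2 <- if (is.na(or)) NA_real_ else log2(or)
    data.frame(
      geneA = ga, geneB = gb,
      n11 = counts[1, 1], n10 = counts[1, 2],
      n01 = counts[2, 1], n00 = counts[2, 2],
      odds_ratio = or, log2_odds_ratio = l2,
      test_name = res$test_name,
      statistic = if (is.null(res$statistic)) NA_real_ else res$statistic,
      p = res$p_value,
      n_evaluable = sum(keep),
      corrected = isTRUE(res$corrected) || (evaluable && any(counts == 0)),
      evaluable = evaluable,
      direction = if (is.na(l2)) NA_character_ else
        if (l2 < 0) "mutual_exclusivity" else
          if (l2 > 0) "co_occurrence" else "independent",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- out$evaluable
  out$q[ok] <- bh_fdr(out$p[ok])
  cols <- c("geneA", "geneB", "n11", "n10", "n01", "n00", "odds_ratio",
            "log2_odds_ratio", "test_name", "statistic", "p", "q",
            "n_evaluable", "corrected", "evaluable", "direction")
  rownames(out) <- NULL
  out[, cols]
}

#' Signed association matrix with clustering order
#'
#' Symmetric matrix of log2 odds ratios clipped to `[-clip, +clip]` for
#' display (the unclipped values are kept alongside); the diagonal and
#' non-evaluable cells are `NA`, and cells with `q >= q_threshold` are
#' flagged for desaturation. Row/column order comes from average-linkage
#' hierarchical clustering of the Euclidean distances between signed
#' association profiles (missing entries treated as 0 for clustering only).
#'
#' @param records Output of [pairwise_association()].
#' @param clip Display clip magnitude (default 1.6).
#' @param q_threshold Significance threshold for desaturation (default 0.10).
#' @return List of class `association_matrix`: `display` (clipped), `raw`,
#'   `desaturate` (logical matrix), `order` (gene order), `hclust`.
#' @export
association_matrix <- function(records, clip = 1.6, q_threshold = 0.10) {
  genes <- sort(unique(c(records$geneA, records$geneB)))
  raw <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  desat <- matrix(FALSE, length(genes), length(genes),
                  dimnames = list(genes, genes))
  for (i in seq_len(nrow(records))) {
    if (!isTRUE(records$evaluable[i])) next
    a <- records$geneA[i]; b <- records$geneB[i]
    raw[a, b] <- raw[b, a] <- records$log2_odds_ratio[i]
    ns <- is.na(records$q[i]) || records$q[i] >= q_threshold
    desat[a, b] <- desat[b, a] <- ns
  }
  display <- pmin(pmax(raw, -clip), clip)
  prof <- raw
  prof[is.na(prof)] <- 0
  hc <- if (length(genes) > 2L) {
    stats::hclust(stats::dist(prof, method = "euclidean"), method = "average")
  } else NULL
  ord <- if (is.null(hc)) genes else genes[hc$order]
  structure(list(display = display, raw = raw, desaturate = desat,
                 order = ord, hclust = hc, clip = clip,
                 q_threshold = q_threshold),
            class = "association_matrix")
}

#' Plot the signed association heatmap
#'
#' Diverging heatmap of the clipped log2 odds-ratio matrix in clustering
#' order (requires the pheatmap package).
#'
#' @param x An [association_matrix()].
#' @param filename Optional output file passed to pheatmap.
#' @param ... Further arguments to `pheatmap::pheatmap`.
#' @export
plot_association_heatmap <- function(x, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("the pheatmap package is required for plotting")
  }
  m <- x$display[x$order, x$order]
  m[is.na(m)] <- 0
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = seq(-x$clip, x$clip, length.out = 101),
                     color = grDevices::colorRampPalette(
                       c("#2166AC", "white", "#B2182B"))(100),
                     filename = filename, ...)
}

#' Write exclusivity outputs
#' @param records Output of [pairwise_association()].
#' @param assoc_matrix Output of [association_matrix()].
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_exclusivity <- function(records, assoc_matrix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pairs = file.path(dir, "pairs.tsv"),
             matrix = file.path(dir, "log2or_matrix.tsv"),
             order = file.path(dir, "clustering_order.txt"))
  write_tsv(records, paths["pairs"])
  m <- data.frame(Gene = rownames(assoc_matrix$raw), assoc_matrix$raw,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(m, paths["matrix"])
  writeLines(assoc_matrix$order, paths["order"])
  invisible(paths)
}
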