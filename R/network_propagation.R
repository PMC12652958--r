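#' Load and confidence-filter a STRING-style interaction graph
#'
#' Parses a weighted edge list (path or data frame as returned by
#' [read_string_edges()]), optionally down-weights the text-mining channel
#' and recombines the per-channel scores as `1 - prod(1 - s_c)`, collapses
#' duplicate A-B/B-A rows keeping the highest-confidence record, removes
#' self-loops, and drops every edge whose combined score falls below the
#' cutoff.
#'
#' @param edges Path to a STRING-style TSV or an equivalent data frame with
#'   `protein1`, `protein2`, per-channel scores and `combined_score`
#'   (0-1000 integers or 0-1 floats; auto-detected).
#' @param combined_min Combined-score cutoff; edges strictly below it are
#'   removed (primary setting 0.7, sensitivity 0.4).
#' @param textmining_weight Factor in `[0, 1]` applied to the text-mining
#'   score before recombination; 1 leaves the supplied combined score
#'   untouched.
#' @return An undirected `igraph` with per-channel edge attributes,
#'   `combined_score`, and `weight = combined_score`.
#' @export
load_interaction_graph <- function(edges, combined_min = 0.7,
                                   textmining_weight = 1) {
  stopifnot(combined_min >= 0, combined_min <= 1,
            textmining_weight >= 0, textmining_weight <= 1)
  df <- if (is.character(edges)) read_string_edges(edges) else as.data.frame(edges)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df))) {
    stop("expected columns protein1, protein2, <channel scores>, combined_score")
  }
  channels <- setdiff(names(df), need)
  if (max(unlist(df[c(channels, "combined_score")]), na.rm = TRUE) > 1) {
    df[c(channels, "combined_score")] <-
      lapply(df[c(channels, "combined_score")], function(x) x / 1000)
  }
  if (textmining_weight < 1 && "textmining" %in% channels) {
    df$textmining <- df$textmining * textmining_weight
    df$combined_score <- 1 - Reduce(`*`, lapply(df[channels], function(s) 1 - s))
  }
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  key <- ifelse(df$protein1 < df$protein2,
                paste(df$protein1, df$protein2, sep = "\r"),
                paste(df$protein2, df$protein1, sep = "\r"))
  ord <- order(key, -df$combined_score)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[df$combined_score >= combined_min, , drop = FALSE]
  if (nrow(df) == 0L) stop("no edges survive the combined-score cutoff")
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::E(g)$weight <- igraph::E(g)$combined_score
  g
}

#' Build the degree-normalized propagation kernel
#'
#' Weighted degrees (sums of combined scores) populate the diagonal degree
#' matrix `D`. The `symmetric` kernel is `D^-1/2 A D^-1/2` (the primary,
#' hub-corrected operator); the `stochastic` kernel is the row-stochastic
#' walk matrix `D^-1 A`, under which propagation is exactly personalized
#' PageRank with damping `1 - alpha`. Zero-degree nodes are dropped with a
#' warning.
#'
#' @param graph Weighted undirected `igraph` (edge attribute `weight`).
#' @param kernel `"symmetric"` or `"stochastic"`.
#' @return List of class `propagation_kernel`: `K` (the matrix), `nodes`,
#'   `kernel`.
#' @export
build_kernel <- function(graph, kernel = c("symmetric", "stochastic")) {
  kernel <- match.arg(kernel)
  deg <- igraph::strength(graph)
  if (any(deg == 0)) {
    warning("dropping zero-degree nodes: ",
            paste(names(deg)[deg == 0], collapse = ", "))
    graph <- igraph::delete_vertices(graph, which(deg == 0))
    deg <- igraph::strength(graph)
  }
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  K <- if (kernel == "symmetric") {
    dinv <- 1 / sqrt(deg)
    A * outer(dinv, dinv)
  } else {
    A / deg
  }
  structure(list(K = K, nodes = igraph::V(graph)$name, kernel = kernel),
            class = "propagation_kernel")
}

#' Random walk with restart / personalized PageRank
#'
#' Iterates the restart recursion `u <- (1 - alpha) M u + alpha s` from
#' `u = s`, where `M` is the propagation operator (the symmetric kernel
#' itself, or the column-stochastic transpose of the row-stochastic kernel)
#' and `s` assigns equal mass to the seed nodes present in the graph. The
#' reported scores are the L1-normalized state, monitored for convergence in
#' L1 norm; at the fixed point they equal the renormalized direct solve
#' `alpha (I - (1 - alpha) K)^-1 s`. Seeds absent from the graph reallocate
#' their mass to the remaining seeds (message); no seed in the graph is an
#' error.
#'
#' @param graph Weighted undirected `igraph`, typically from
#'   [load_interaction_graph()] or [simulate_interaction_network()].
#' @param seeds Character vector of seed node names.
#' @param alpha Restart probability in `(0, 1]` (primary setting 0.75;
#'   sensitivity 0.5 and 0.9).
#' @param kernel `"symmetric"` (default) or `"stochastic"`.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return Named numeric vector of non-negative node scores summing to 1
#'   over all graph nodes (dropped zero-degree nodes score 0), with
#'   attribute `diagnostics` (iterations, residual, alpha, kernel, seeds
#'   used).
#' @export
propagate <- function(graph, seeds, alpha = 0.75,
                      kernel = c("symmetric", "stochastic"),
                      tol = 1e-10, max_iter = 1000L) {
  kernel <- match.arg(kernel)
  stopifnot(alpha > 0, alpha <= 1)
  all_nodes <- igraph::V(graph)$name
  if (igraph::vcount(graph) == 1L) {
    if (!all_nodes %in% seeds) stop("no seed node present in the graph")
    out <- stats::setNames(1, all_nodes)
    attr(out, "diagnostics") <- list(iterations = 0L, residual = 0,
                                     alpha = alpha, kernel = kernel,
                                     seeds_used = all_nodes)
    return(out)
  }
  kern <- build_kernel(graph, kernel)
  nodes <- kern$nodes
  seeds_in <- intersect(seeds, nodes)
  if (length(seeds_in) == 0L) stop("no seed node present in the graph")
  if (length(seeds_in) < length(seeds)) {
    message("seeds absent from graph, mass reallocated: ",
            paste(setdiff(seeds, seeds_in), collapse = ", "))
  }
  s <- stats::setNames(numeric(length(nodes)), nodes)
  s[seeds_in] <- 1 / length(seeds_in)

  M <- if (kernel == "symmetric") kern$K else t(kern$K)
  u <- s
  p_prev <- s
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    u <- (1 - alpha) * drop(M %*% u) + alpha * s
    p <- u / sum(u)
    residual <- sum(abs(p - p_prev))
    p_prev <- p
    if (residual < tol) break
  }
  if (residual >= tol) {
    stop(sprintf("propagation did not converge in %d iterations (residual %.3e)",
                 max_iter, residual))
  }
  out <- stats::setNames(numeric(length(all_nodes)), all_nodes)
  out[nodes] <- p_prev
  attr(out, "diagnostics") <- list(iterations = iter, residual = residual,
                                   alpha = alpha, kernel = kernel,
                                   seeds_used = seeds_in)
  out
}

#' Direct linear-solve reference for the propagation fixed point
#'
#' `p = alpha (I - (1 - alpha) K)^-1 s`, renormalized to sum 1. Exposed for
#' diagnostics; the iterative [propagate()] must agree with it.
#'
#' @inheritParams propagate
#' @return Named numeric vector over the kernel's nodes.
#' @export
propagate_solve <- function(graph, seeds, alpha = 0.75,
                            kernel = c("symmetric", "stochastic")) {
  kernel <- match.arg(kernel)
  kern <- build_kernel(graph, kernel)
  nodes <- kern$nodes
  seeds_in <- intersect(seeds, nodes)
  if (length(seeds_in) == 0L) stop("no seed node present in the graph")
  s <- stats::setNames(numeric(length(nodes)), nodes)
  s[seeds_in] <- 1 / length(seeds_in)
  M <- if (kernel == "symmetric") kern$K else t(kern$K)
  p <- alpha * solve(diag(length(nodes)) - (1 - alpha) * M, s)
  stats::setNames(p / sum(p), nodes)
}

#' Degree-matched permutation null for propagation scores
#'
#' Replaces each seed with a uniform draw from its weighted-degree quantile
#' bin (default 10 bins; bins with fewer than 2 candidates are widened to
#' their neighbors with a warning), re-propagates, and reports per-node
#' empirical p-values with the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams propagate
#' @param n_perm Number of permutations.
#' @param n_bins Number of degree quantile bins.
#' @param rng_seed Optional integer seed for the permutation draws.
#' @return Data frame `gene`, `score`, `null_mean`, `empirical_p`.
#' @export
degree_matched_null <- function(graph, seeds, alpha = 0.75,
                                kernel = c("symmetric", "stochastic"),
                                n_perm = 200L, n_bins = 10L,
                                rng_seed = NULL) {
  kernel <- match.arg(kernel)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  observed <- propagate(graph, seeds, alpha = alpha, kernel = kernel)
  deg <- igraph::strength(graph)
  nodes <- names(deg)
  breaks <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  names(bin) <- nodes

  seeds_in <- intersect(seeds, nodes)
  pools <- lapply(seeds_in, function(sd) {
    b <- bin[sd]
    pool <- nodes[bin == b]
    width <- 0L
    while (length(pool) < 2L && width < max(bin)) {
      width <- width + 1L
      pool <- nodes[abs(bin - b) <= width]
      warning("degree bin too small for seed ", sd, "; widened")
    }
    pool
  })

  null_ge <- numeric(length(observed))
  names(null_ge) <- names(observed)
  null_sum <- null_ge
  for (i in seq_len(n_perm)) {
    perm_seeds <- character(length(pools))
    taken <- character(0)
    for (j in seq_along(pools)) {
      cand <- setdiff(pools[[j]], taken)
      if (length(cand) == 0L) cand <- pools[[j]]
      perm_seeds[j] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      taken <- c(taken, perm_seeds[j])
    }
    null_p <- propagate(graph, perm_seeds, alpha = alpha, kernel = kernel)
    null_ge <- null_ge + (null_p >= observed)
    null_sum <- null_sum + null_p
  }
  data.frame(
    gene = names(observed),
    score = as.numeric(observed),
    null_mean = as.numeric(null_sum / n_perm),
    empirical_p = as.numeric((1 + null_ge) / (n_perm + 1)),
    stringsAsFactors = FALSE
  )
}

#' Filter propagation scores down to non-mutated nominations
#'
#' Ranks nodes by propagation score (ties broken by lower degree, then
#' symbol), annotates each with its pan-cancer alteration prevalence, and
#' removes genes altered in more than `cutoff_pct` percent of samples as
#' well as seeds and hotspot-flagged genes. Hotspot exclusions are emitted
#' to a side table; genes lacking alteration data are retained with a
#' missing-prevalence flag and a warning.
#'
#' @param scores Named score vector from [propagate()].
#' @param alteration_pct Named vector, percent of pooled samples altered
#'   (non-synonymous mutation or focal amplification).
#' @param hotspot_genes Genes carrying recurrent activating hotspot variants.
#' @param cutoff_pct Maximum prevalence (percent) for a "non-mutated" call.
#' @param degree Optional named degree vector (defaults to 0 where unknown).
#' @param source_support Optional named integer vector of supporting-source
#'   counts (user-supplied annotation; `NA` when absent).
#' @param seeds Seed genes (flagged and excluded from nominations).
#' @return List of class `nomination_set`: `nominations` (Filtered_Rank,
#'   Gene_Symbol, Page_Rank_Score, Pan_Cancer_Alteration_Pct, Degree,
#'   Source_Support_Count, Missing_Pct), `unfiltered` (full ranking with
#'   flags), `hotspot_excluded`.
#' @export
filter_nonmutated <- function(scores, alteration_pct,
                              hotspot_genes = character(0), cutoff_pct = 3,
                              degree = NULL, source_support = NULL,
                              seeds = character(0)) {
  genes <- names(scores)
  pct <- unname(alteration_pct[genes])
  missing_pct <- is.na(pct) | !(genes %in% names(alteration_pct))
  if (any(missing_pct)) {
    warning(sum(missing_pct), " genes lack alteration data; retained with flag")
  }
  deg <- if (is.null(degree)) rep(NA_integer_, length(genes)) else
    as.integer(degree[genes])
  supp <- if (is.null(source_support)) rep(NA_integer_, length(genes)) else
    as.integer(source_support[genes])

  full <- data.frame(
    Gene_Symbol = genes,
    Page_Rank_Score = as.numeric(scores),
    Pan_Cancer_Alteration_Pct = pct,
    Degree = deg,
    Source_Support_Count = supp,
    Missing_Pct = missing_pct,
    Seed = genes %in% seeds,
    Hotspot = genes %in% hotspot_genes,
    stringsAsFactors = FALSE
  )
  ord <- order(-full$Page_Rank_Score, full$Degree, full$Gene_Symbol)
  full <- full[ord, , drop = FALSE]
  full$Rank <- seq_len(nrow(full))
  rownames(full) <- NULL

  high <- !full$Missing_Pct & full$Pan_Cancer_Alteration_Pct > cutoff_pct
  keep <- !high & !full$Hotspot & !full$Seed
  nominations <- full[keep, c("Gene_Symbol", "Page_Rank_Score",
                              "Pan_Cancer_Alteration_Pct", "Degree",
                              "Source_Support_Count", "Missing_Pct")]
  nominations <- cbind(Filtered_Rank = seq_len(nrow(nominations)), nominations)
  rownames(nominations) <- NULL

  structure(list(
    nominations = nominations,
    unfiltered = full,
    hotspot_excluded = full[full$Hotspot, , drop = FALSE],
    cutoff_pct = cutoff_pct
  ), class = "nomination_set")
}

#' Write propagation outputs
#' @param nomination_set Output of [filter_nonmutated()].
#' @param diagnostics Diagnostics attribute of [propagate()] output.
#' @param dir Output directory.
#' @param null_pvalues Optional output of [degree_matched_null()].
#' @return Invisibly, the file paths.
#' @export
write_propagation <- function(nomination_set, diagnostics, dir,
                              null_pvalues = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(full = file.path(dir, "propagation_full.tsv"),
             nominations = file.path(dir, "nominations.tsv"),
             diagnostics = file.path(dir, "propagation_diagnostics.json"))
  write_tsv(nomination_set$unfiltered, paths["full"])
  write_tsv(nomination_set$nominations, paths["nominations"])
  write_json_meta(c(diagnostics, list(cutoff_pct = nomination_set$cutoff_pct)),
                  paths["diagnostics"])
  if (!is.null(null_pvalues)) {
    paths["null"] <- file.path(dir, "null_pvalues.tsv")
    write_tsv(null_pvalues, paths["null"])
  }
  invisible(paths)
}
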