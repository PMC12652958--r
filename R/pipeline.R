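#' Run the full prioritization pipeline on a configuration
#'
#' Orchestrates every stage end-to-end from a [simulation_config()] (or from
#' files previously written with [write_synthetic_fixtures()]): alteration
#' simulation, the specificity landscape, pooled z-scoring and
#' genotype-module association tests, confidence-filtered network
#' propagation with the non-mutated filter, and all-pairs exclusivity
#' testing. When `out_dir` is given every stage table is written along with
#' a run manifest (package version, effective parameters, seeds, input
#' digests).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @param alpha Restart probability for propagation.
#' @param combined_min Combined-score cutoff for the interaction graph.
#' @param kernel Propagation kernel.
#' @param nonmutated_cutoff_pct Alteration-prevalence cutoff (percent) for
#'   the non-mutated filter.
#' @param cutoffs Landscape classification cutoffs.
#' @param hotspot_genes Genes excluded from nominations as hotspot carriers.
#' @param n_perm Permutations for the degree-matched null (0 skips it).
#' @return A list of class `mtor_run` with elements `landscape`, `activity`,
#'   `propagation` (scores, nomination_set, null), `exclusivity` (records,
#'   matrix), `alterations`, `manifest`.
#' @export
run_mtor_pipeline <- function(config = default_simulation_config(),
                              out_dir = NULL, alpha = 0.75,
                              combined_min = 0.7,
                              kernel = c("symmetric", "stochastic"),
                              nonmutated_cutoff_pct = 3,
                              cutoffs = landscape_cutoffs(),
                              hotspot_genes = character(0),
                              n_perm = 0L) {
  kernel <- match.arg(kernel)
  roles <- default_gene_roles(config$genes)

  sim <- simulate_alteration_cohorts(config)
  alterations <- sim$alterations
  landscape <- landscape_table(alterations, roles, cutoffs)

  ex <- simulate_expression(alterations, config)
  z <- pooled_zscores(ex$expression)
  contrasts <- lapply(config$module_effects, function(e) {
    list(gene = e$gene, event = e$event)
  })
  activity <- association_tests(z, config$modules, alterations, contrasts)

  propagation <- NULL
  if (!is.null(config$network)) {
    net <- simulate_interaction_network(config)
    edges <- string_edge_frame(net$graph)
    graph <- load_interaction_graph(edges, combined_min = combined_min)
    seeds <- config$network$seed_genes
    scores <- propagate(graph, seeds, alpha = alpha, kernel = kernel)
    alt_pct <- stats::setNames(net$node_table$alteration_pct,
                               net$node_table$gene)
    deg <- igraph::degree(graph)
    noms <- filter_nonmutated(scores, alt_pct,
                              hotspot_genes = hotspot_genes,
                              cutoff_pct = nonmutated_cutoff_pct,
                              degree = deg, seeds = seeds)
    null <- if (n_perm > 0L) {
      degree_matched_null(graph, seeds, alpha = alpha, kernel = kernel,
                          n_perm = n_perm, rng_seed = config$rng_seed + 4L)
    } else NULL
    propagation <- list(scores = scores, graph = graph,
                        nomination_set = noms, null = null,
                        ground_truth = net$ground_truth)
  }

  binary <- binarize_alterations(alterations, roles)
  records <- pairwise_association(binary)
  ex_matrix <- association_matrix(records)

  manifest <- list(
    package = "mtorwalk",
    version = as.character(utils::packageVersion("mtorwalk")),
    rng_seed = config$rng_seed,
    parameters = list(alpha = alpha, combined_min = combined_min,
                      kernel = kernel,
                      nonmutated_cutoff_pct = nonmutated_cutoff_pct,
                      cutoffs = cutoffs),
    cohorts = stats::setNames(as.list(config$n_samples_per_cohort),
                              config$cohorts),
    n_genes = length(config$genes),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  run <- structure(list(
    landscape = landscape, activity = activity, propagation = propagation,
    exclusivity = list(records = records, matrix = ex_matrix),
    alterations = alterations, ground_truth = sim$ground_truth,
    expression_truth = ex$ground_truth, manifest = manifest
  ), class = "mtor_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_landscape(landscape, out_dir)
    write_activity(activity, out_dir)
    if (!is.null(propagation)) {
      write_propagation(propagation$nomination_set,
                        attr(propagation$scores, "diagnostics"), out_dir,
                        null_pvalues = propagation$null)
    }
    write_exclusivity(records, ex_matrix, out_dir)
    written <- list.files(out_dir, full.names = TRUE)
    written <- written[!grepl("manifest\\.json$", written)]
    manifest$output_digests <- as.list(tools::md5sum(written))
    run$manifest <- manifest
    write_json_meta(manifest, file.path(out_dir, "manifest.json"))
  }
  run
}

# igraph -> STRING-style data frame on the 0-1 scale (internal)
string_edge_frame <- function(graph) {
  el <- igraph::as_edgelist(graph)
  data.frame(
    protein1 = el[, 1], protein2 = el[, 2],
    textmining = igraph::E(graph)$textmining,
    experimental = igraph::E(graph)$experimental,
    database = igraph::E(graph)$database,
    coexpression = igraph::E(graph)$coexpression,
    combined_score = igraph::E(graph)$combined_score,
    stringsAsFactors = FALSE
  )
}

#' @export
print.mtor_run <- function(x, ...) {
  cat("<mtor_run>\n")
  cat(sprintf("  landscape: %d genes\n", nrow(x$landscape)))
  cat(sprintf("  activity: %d association rows\n", nrow(x$activity$table)))
  if (!is.null(x$propagation)) {
    cat(sprintf("  propagation: %d nodes, %d nominations\n",
                length(x$propagation$scores),
                nrow(x$propagation$nomination_set$nominations)))
  }
  cat(sprintf("  exclusivity: %d pairs\n", nrow(x$exclusivity$records)))
  invisible(x)
}

#' Robustness grid over diffusion and filtering parameters
#'
#' Reruns the propagation stage over the cartesian grid of restart
#' probabilities, combined-score cutoffs and FDR thresholds, and summarizes
#' stability as the fraction of the primary setting's top-k nominations
#' recovered under each alternative (and the count of exclusivity pairs
#' significant at each FDR threshold).
#'
#' @param config A [simulation_config()] with a network entry.
#' @param alphas Restart probabilities to scan.
#' @param combined_mins Combined-score cutoffs to scan.
#' @param fdr_thresholds BH-FDR thresholds applied to the exclusivity table.
#' @param top_k Size of the nomination head compared across settings.
#' @param primary Named list giving the primary setting (defaults
#'   `alpha = 0.75`, `combined_min = 0.7`).
#' @return Long-format data frame: one row per grid point with
#'   `top_k_overlap` (shared fraction with the primary nominations) and
#'   `n_significant_pairs`.
#' @export
robustness_grid <- function(config = default_simulation_config(),
                            alphas = c(0.5, 0.75, 0.9),
                            combined_mins = c(0.4, 0.7),
                            fdr_thresholds = c(0.01, 0.05, 0.10),
                            top_k = 10L,
                            primary = list(alpha = 0.75, combined_min = 0.7)) {
  if (is.null(config$network)) stop("robustness grid requires a network configuration")
  net <- simulate_interaction_network(config)
  edges <- string_edge_frame(net$graph)
  alt_pct <- stats::setNames(net$node_table$alteration_pct,
                             net$node_table$gene)
  seeds <- config$network$seed_genes

  sim <- simulate_alteration_cohorts(config)
  records <- pairwise_association(
    binarize_alterations(sim$alterations, default_gene_roles(config$genes)))

  top_for <- function(alpha, combined_min) {
    graph <- load_interaction_graph(edges, combined_min = combined_min)
    scores <- propagate(graph, seeds, alpha = alpha)
    noms <- filter_nonmutated(scores, alt_pct, seeds = seeds,
                              degree = igraph::degree(graph))
    utils::head(noms$nominations$Gene_Symbol, top_k)
  }
  primary_top <- top_for(primary$alpha, primary$combined_min)

  grid <- expand.grid(alpha = alphas, combined_min = combined_mins,
                      fdr = fdr_thresholds, KEEP.OUT.ATTRS = FALSE)
  cache <- new.env()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    key <- paste(grid$alpha[i], grid$combined_min[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- tryCatch(top_for(grid$alpha[i], grid$combined_min[i]),
                               error = function(e) NA_character_)
    }
    top <- cache[[key]]
    data.frame(
      alpha = grid$alpha[i], combined_min = grid$combined_min[i],
      fdr = grid$fdr[i],
      top_k_overlap = if (anyNA(top)) NA_real_ else
        length(intersect(top, primary_top)) / length(primary_top),
      n_significant_pairs = sum(records$q < grid$fdr[i], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "primary_top") <- primary_top
  out
}
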