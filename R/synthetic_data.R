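#' Simulation configuration for TCGA-style synthetic cohorts
#'
#' Bundles every parameter of the synthetic-data generator: cohort layout,
#' per-gene/per-cohort mutation and copy-number rates, planted expression
#' effects, planted mutual-exclusivity pairs, and the interaction-network
#' recipe. All downstream stages are driven off objects produced under a
#' configuration, so a fixed `rng_seed` reproduces every artifact exactly.
#'
#' @param cohorts Character vector of unique cohort labels.
#' @param n_samples_per_cohort Positive integer, recycled across cohorts, or
#'   a vector of the same length as `cohorts`.
#' @param genes Character vector of gene symbols.
#' @param mutation_prevalence Genes x cohorts matrix of mutation
#'   probabilities in `[0, 1]`.
#' @param cna_amp_rates,cna_del_rates Genes x cohorts matrices of
#'   amplification / deletion probabilities; within each the high-level call
#'   (+2 or -2) receives `high_level_fraction` of the mass and the low-level
#'   call (+1 or -1) the remainder.
#' @param modules Named list of character vectors: expression modules.
#' @param module_effects Named list of planted genotype-expression effects;
#'   each element is `list(gene, event, module, delta)` with `event` one of
#'   `"loss"`, `"mutation"`, `"amplification"` and `delta` in z-units.
#' @param exclusivity_pairs List of `list(gene_a, gene_b, odds_ratio)`
#'   elements; the mutation flags of each pair are drawn from the exact 2x2
#'   joint distribution with the target odds ratio at the configured
#'   marginals.
#' @param network List with `n_nodes`, `attachment` (preferential-attachment
#'   edges per new node), `community_size` (planted seed-proximal community,
#'   includes the seeds), `seed_genes`, and `high_alteration_fraction`
#'   (fraction of background nodes assigned an alteration prevalence above
#'   the non-mutated cutoff).
#' @param high_level_fraction Fraction of CNA mass on the +/-2 call
#'   (default 0.3, i.e. 70% low-level / 30% high-level).
#' @param rng_seed Integer seed; each artifact type (alterations,
#'   expression, network) derives its own stream from it.
#' @return A list of class `simulation_config`.
#' @seealso [default_simulation_config()]
#' @export
simulation_config <- function(cohorts, n_samples_per_cohort, genes,
                              mutation_prevalence, cna_amp_rates,
                              cna_del_rates, modules = list(),
                              module_effects = list(),
                              exclusivity_pairs = list(),
                              network = NULL,
                              high_level_fraction = 0.3,
                              rng_seed = 1L) {
  if (anyDuplicated(cohorts)) stop("cohort labels must be unique")
  if (length(cohorts) < 1L || length(genes) < 1L) stop("need >= 1 cohort and gene")
  n <- as.integer(rep(n_samples_per_cohort, length.out = length(cohorts)))
  if (any(n <= 0L)) stop("n_samples_per_cohort must be positive")

  as_rate_matrix <- function(m, what) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(length(genes), length(cohorts)))) {
      stop(what, " must be a genes x cohorts matrix")
    }
    if (anyNA(m) || any(m < 0 | m > 1)) stop(what, " must lie in [0, 1]")
    dimnames(m) <- list(genes, cohorts)
    m
  }
  mutation_prevalence <- as_rate_matrix(mutation_prevalence, "mutation_prevalence")
  cna_amp_rates <- as_rate_matrix(cna_amp_rates, "cna_amp_rates")
  cna_del_rates <- as_rate_matrix(cna_del_rates, "cna_del_rates")
  if (any(cna_amp_rates + cna_del_rates > 1)) {
    stop("amplification + deletion rate exceeds 1 for some gene/cohort")
  }
  for (nm in names(modules)) {
    if (length(modules[[nm]]) == 0L) stop("module '", nm, "' has zero genes")
    if (!all(modules[[nm]] %in% genes)) {
      stop("module '", nm, "' references genes outside the panel")
    }
  }
  for (eff in module_effects) {
    stopifnot(eff$gene %in% genes, eff$module %in% names(modules),
              eff$event %in% c("loss", "mutation", "amplification"))
  }
  for (pr in exclusivity_pairs) {
    stopifnot(pr$gene_a %in% genes, pr$gene_b %in% genes, pr$odds_ratio > 0)
  }
  if (!is.null(network)) {
    stopifnot(network$n_nodes >= network$community_size,
              network$community_size >= length(network$seed_genes),
              length(network$seed_genes) >= 1L)
  }
  structure(list(
    cohorts = as.character(cohorts), n_samples_per_cohort = n,
    genes = as.character(genes), mutation_prevalence = mutation_prevalence,
    cna_amp_rates = cna_amp_rates, cna_del_rates = cna_del_rates,
    modules = modules, module_effects = module_effects,
    exclusivity_pairs = exclusivity_pairs, network = network,
    high_level_fraction = high_level_fraction,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Default synthetic study conditions
#'
#' Ten TCGA-style cohorts of 200 tumors each over a 16-gene mTOR-axis panel
#' (the 12 core genes plus EIF4E, RHEB, LAMTOR1 and PRKAA1 for the
#' expression modules). Marginal mutation and amplification rates follow the
#' pan-cancer scale typical of this panel (PTEN ~10% mutated, PIK3CA ~13%
#' mutated / ~29% amplified, RICTOR ~27% amplified, ...), with the top
#' cohort enriched 2.5-fold for mutations (UCEC for PTEN/PIK3CA, GBM
#' otherwise) and GBM enriched for amplifications. A translational-module
#' effect of 0.5 z-units is planted on PTEN-loss carriers, smaller effects on
#' PIK3CA-mutant and RICTOR-amplified tumors, and a PTEN--PIK3CA mutation
#' pair is planted at odds ratio 0.2 (mutual exclusivity). The network
#' recipe plants a 15-node seed-proximal community (the 5 core seeds plus 10
#' neighbors) on a 200-node preferential-attachment backbone.
#'
#' @param rng_seed Integer seed.
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(rng_seed = 1L) {
  cohorts <- c("UCEC", "GBM", "KIRC", "BRCA", "LUAD",
               "COAD", "HNSC", "LGG", "OV", "STAD")
  mut_pan <- c(PTEN = 0.097, PIK3CA = 0.127, MTOR = 0.061, RPTOR = 0.048,
               RICTOR = 0.051, MLST8 = 0.038, RPS6KB1 = 0.039,
               EIF4EBP1 = 0.036, RPS6 = 0.038, AKT1 = 0.041, TSC1 = 0.051,
               TSC2 = 0.054, EIF4E = 0.020, RHEB = 0.015, LAMTOR1 = 0.010,
               PRKAA1 = 0.020)
  amp_pan <- c(PTEN = 0.078, PIK3CA = 0.291, MTOR = 0.098, RPTOR = 0.236,
               RICTOR = 0.265, MLST8 = 0.184, RPS6KB1 = 0.226,
               EIF4EBP1 = 0.228, RPS6 = 0.100, AKT1 = 0.140, TSC1 = 0.123,
               TSC2 = 0.184, EIF4E = 0.030, RHEB = 0.020, LAMTOR1 = 0.020,
               PRKAA1 = 0.030)
  del_pan <- c(PTEN = 0.100, PIK3CA = 0.020, MTOR = 0.020, RPTOR = 0.020,
               RICTOR = 0.020, MLST8 = 0.020, RPS6KB1 = 0.020,
               EIF4EBP1 = 0.020, RPS6 = 0.020, AKT1 = 0.020, TSC1 = 0.050,
               TSC2 = 0.050, EIF4E = 0.010, RHEB = 0.010, LAMTOR1 = 0.010,
               PRKAA1 = 0.010)
  genes <- names(mut_pan)

  mut <- matrix(mut_pan, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  top <- ifelse(genes %in% c("PTEN", "PIK3CA"), "UCEC", "GBM")
  mut[cbind(genes, top)] <- pmin(1, 2.5 * mut_pan)
  amp <- matrix(amp_pan, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  amp[, "GBM"] <- pmin(0.9, 1.8 * amp_pan)
  del <- matrix(del_pan, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))

  simulation_config(
    cohorts = cohorts, n_samples_per_cohort = 200L, genes = genes,
    mutation_prevalence = mut, cna_amp_rates = amp, cna_del_rates = del,
    modules = list(
      translational = c("EIF4E", "EIF4EBP1", "RPS6", "RPS6KB1"),
      nutrient_sensing = c("LAMTOR1", "PRKAA1", "RHEB")
    ),
    module_effects = list(
      PTEN_loss = list(gene = "PTEN", event = "loss",
                       module = "translational", delta = 0.5),
      PIK3CA_mut = list(gene = "PIK3CA", event = "mutation",
                        module = "translational", delta = 0.3),
      RICTOR_amp = list(gene = "RICTOR", event = "amplification",
                        module = "nutrient_sensing", delta = 0.3)
    ),
    exclusivity_pairs = list(
      list(gene_a = "PTEN", gene_b = "PIK3CA", odds_ratio = 0.2)
    ),
    network = list(
      n_nodes = 200L, attachment = 3L, community_size = 15L,
      seed_genes = c("MTOR", "RPTOR", "RICTOR", "EIF4EBP1", "RPS6KB1"),
      high_alteration_fraction = 0.25
    ),
    rng_seed = rng_seed
  )
}

#' Solve the 2x2 joint distribution with a target odds ratio
#'
#' Given marginal probabilities `p_a`, `p_b` and a target odds ratio, returns
#' the unique joint cell probabilities `(p11, p10, p01, p00)` with those
#' marginals and `p11 p00 / (p10 p01)` equal to the target (the quadratic-root
#' construction). Errors if the target is infeasible at the given marginals.
#'
#' @param p_a,p_b Marginal probabilities in `(0, 1)`.
#' @param odds_ratio Target odds ratio, > 0.
#' @return Named numeric vector `c(p11, p10, p01, p00)`.
#' @export
solve_joint_2x2 <- function(p_a, p_b, odds_ratio) {
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1, odds_ratio > 0)
  if (abs(odds_ratio - 1) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    a <- odds_ratio - 1
    b <- 1 + (p_a + p_b) * (odds_ratio - 1)
    disc <- b^2 - 4 * a * odds_ratio * p_a * p_b
    if (disc < 0) stop("odds ratio infeasible at the given marginals")
    roots <- (b + c(-1, 1) * sqrt(disc)) / (2 * a)
    lo <- max(0, p_a + p_b - 1)
    hi <- min(p_a, p_b)
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop("odds ratio infeasible at the given marginals")
    p11 <- roots[ok][1]
  }
  p <- c(p11 = p11, p10 = p_a - p11, p01 = p_b - p11,
         p00 = 1 - p_a - p_b + p11)
  if (any(p < -1e-12)) stop("odds ratio infeasible at the given marginals")
  pmax(p, 0)
}

#' Construct a cohort alteration table
#'
#' Container for per-sample somatic calls: a logical mutation matrix, an
#' integer GISTIC-style copy-number matrix on the `{-2,-1,0,+1,+2}` scale,
#' and the sample-to-cohort assignment.
#'
#' @param mutation Logical samples x genes matrix.
#' @param cna Integer samples x genes matrix with values in `-2..2` (`NA`
#'   allowed for genes absent from the copy-number input).
#' @param cohort Character/factor vector of cohort labels, one per sample.
#' @return A list of class `cohort_alterations` with elements `mutation`,
#'   `cna`, `cohort`, `samples`, `genes`.
#' @export
cohort_alterations <- function(mutation, cna, cohort) {
  mutation <- as.matrix(mutation)
  cna <- as.matrix(cna)
  if (!identical(dim(mutation), dim(cna))) stop("mutation/cna dimension mismatch")
  if (length(cohort) != nrow(mutation)) stop("one cohort label per sample required")
  if (is.null(rownames(mutation)) ||
      (ncol(mutation) > 0L && is.null(colnames(mutation)))) {
    stop("mutation matrix needs sample rownames and gene colnames")
  }
  if (is.null(colnames(mutation))) colnames(mutation) <- character(0)
  if (any(abs(cna) > 2, na.rm = TRUE) || any(cna != round(cna), na.rm = TRUE)) {
    stop("cna calls must be integers in -2..2")
  }
  structure(list(
    mutation = mutation == TRUE,
    cna = cna,
    cohort = stats::setNames(as.character(cohort), rownames(mutation)),
    samples = rownames(mutation),
    genes = colnames(mutation)
  ), class = "cohort_alterations")
}

#' @export
print.cohort_alterations <- function(x, ...) {
  cat(sprintf("<cohort_alterations> %d samples x %d genes, %d cohorts\n",
              length(x$samples), length(x$genes),
              length(unique(x$cohort))))
  invisible(x)
}

#' Simulate per-cohort somatic alterations
#'
#' Draws, per cohort, independent Bernoulli mutation flags at the configured
#' prevalences and copy-number calls from the 5-category distribution over
#' `{-2,-1,0,+1,+2}` (amplification/deletion mass split 70% low-level, 30%
#' high-level by default). Planted exclusivity pairs override the two genes'
#' mutation flags with draws from the exact 2x2 joint distribution at the
#' target odds ratio and configured marginals.
#'
#' @param config A [simulation_config()].
#' @return List with `alterations` (a [cohort_alterations()]) and
#'   `ground_truth` (configured prevalences and planted structure).
#' @export
simulate_alteration_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 1L)
  genes <- config$genes
  cohorts <- config$cohorts
  n_tot <- sum(config$n_samples_per_cohort)
  samples <- sprintf("S%05d", seq_len(n_tot))
  cohort <- rep(cohorts, config$n_samples_per_cohort)

  mut <- matrix(FALSE, n_tot, length(genes),
                dimnames = list(samples, genes))
  cna <- matrix(0L, n_tot, length(genes),
                dimnames = list(samples, genes))
  hf <- config$high_level_fraction

  # pre-solve planted joints per cohort (errors surface before any sampling)
  joints <- lapply(config$exclusivity_pairs, function(pr) {
    lapply(cohorts, function(co) {
      solve_joint_2x2(config$mutation_prevalence[pr$gene_a, co],
                      config$mutation_prevalence[pr$gene_b, co],
                      pr$odds_ratio)
    })
  })
  planted_genes <- unlist(lapply(config$exclusivity_pairs,
                                 function(pr) c(pr$gene_a, pr$gene_b)))

  for (ci in seq_along(cohorts)) {
    rows <- which(cohort == cohorts[ci])
    for (g in genes) {
      if (!(g %in% planted_genes)) {
        mut[rows, g] <- stats::runif(length(rows)) < config$mutation_prevalence[g, cohorts[ci]]
      }
      a <- config$cna_amp_rates[g, cohorts[ci]]
      d <- config$cna_del_rates[g, cohorts[ci]]
      cna[rows, g] <- sample(c(-2L, -1L, 0L, 1L, 2L), length(rows),
                             replace = TRUE,
                             prob = c(d * hf, d * (1 - hf), 1 - a - d,
                                      a * (1 - hf), a * hf))
    }
    for (pi in seq_along(config$exclusivity_pairs)) {
      pr <- config$exclusivity_pairs[[pi]]
      cell <- sample(4L, length(rows), replace = TRUE, prob = joints[[pi]][[ci]])
      mut[rows, pr$gene_a] <- cell %in% c(1L, 2L)
      mut[rows, pr$gene_b] <- cell %in% c(1L, 3L)
    }
  }

  list(
    alterations = cohort_alterations(mut, cna, cohort),
    ground_truth = list(
      true_mutation_prevalence = config$mutation_prevalence,
      true_amp_rates = config$cna_amp_rates,
      true_del_rates = config$cna_del_rates,
      planted_exclusive_pairs = config$exclusivity_pairs
    )
  )
}

#' Simulate expression with planted genotype-linked module shifts
#'
#' Expression is unit-variance Gaussian noise per gene and sample; for each
#' configured effect, `delta` z-units are added to the member genes of the
#' effect's module in samples carrying the altered genotype (carriers defined
#' exactly as in [genotype_groups()]).
#'
#' @param alterations A [cohort_alterations()].
#' @param config The [simulation_config()] that produced `alterations`.
#' @return List with `expression` (genes x samples matrix), `genotype` (data
#'   frame of per-sample carrier labels per contrast, `NA` = excluded), and
#'   `ground_truth` (planted effects).
#' @export
simulate_expression <- function(alterations, config) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(alterations, "cohort_alterations"))
  set.seed(config$rng_seed + 2L)
  genes <- config$genes
  samples <- alterations$samples
  expr <- matrix(stats::rnorm(length(genes) * length(samples)),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
  genotype <- data.frame(sample = samples,
                         cohort = unname(alterations$cohort),
                         stringsAsFactors = FALSE)
  for (nm in names(config$module_effects)) {
    eff <- config$module_effects[[nm]]
    members <- config$modules[[eff$module]]
    labels <- genotype_groups(alterations, eff$gene, eff$event)
    carriers <- which(!is.na(labels) & labels == 1L)
    if (length(carriers)) {
      expr[members, carriers] <- expr[members, carriers] + eff$delta
    }
    genotype[[nm]] <- labels
  }
  list(expression = expr, genotype = genotype,
       ground_truth = list(planted_effects = config$module_effects))
}

#' Simulate a STRING-like weighted interaction network
#'
#' A preferential-attachment backbone with heavy-tailed degrees, on which a
#' seed-proximal community (the seed genes plus extra neighbors) is planted as
#' a clique of high-confidence edges. Every edge carries per-channel evidence
#' scores in `[0, 1]` (textmining, experimental, database, coexpression) and a
#' combined score `1 - prod(1 - s_c)`. Each node is assigned a pan-cancer
#' alteration prevalence: planted non-seed nodes are rarely altered (the
#' candidates the non-mutated filter should retain), seeds and a configured
#' fraction of background nodes exceed the 3% cutoff.
#'
#' @param config A [simulation_config()] with a non-`NULL` `network` entry.
#' @return List with `graph` (an undirected `igraph` with edge attributes
#'   `textmining`, `experimental`, `database`, `coexpression`,
#'   `combined_score`), `node_table` (data frame `gene`, `alteration_pct`,
#'   `hotspot`), and `ground_truth` (`planted_community`, `seed_genes`,
#'   `high_alteration_genes`).
#' @export
simulate_interaction_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"), !is.null(config$network))
  set.seed(config$rng_seed + 3L)
  net <- config$network
  n <- net$n_nodes
  seeds <- net$seed_genes
  k <- net$community_size

  g <- igraph::sample_pa(n, power = 1, m = net$attachment, directed = FALSE)
  planted_idx <- sample(n, k)
  nodes <- sprintf("BG%03d", seq_len(n))
  nodes[planted_idx[seq_along(seeds)]] <- seeds
  nodes[planted_idx[-seq_along(seeds)]] <- sprintf("PROX%02d", seq_len(k - length(seeds)))
  igraph::V(g)$name <- nodes

  planted <- nodes[planted_idx]
  clique_edges <- t(utils::combn(planted, 2))
  have <- igraph::get_edge_ids(g, clique_edges, error = FALSE)
  if (any(have == 0)) {
    g <- igraph::add_edges(g, t(clique_edges[have == 0, , drop = FALSE]))
  }
  g <- igraph::simplify(g)

  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  planted_edge <- el[, 1] %in% planted & el[, 2] %in% planted
  tm <- stats::rbeta(m, 1.5, 2.5)
  ex <- ifelse(planted_edge, stats::rbeta(m, 6, 1.5), stats::rbeta(m, 1, 4))
  db <- ifelse(planted_edge, stats::rbeta(m, 5, 2),
               stats::rbinom(m, 1, 0.2) * stats::rbeta(m, 2, 2))
  cx <- stats::rbeta(m, 1, 5)
  combined <- 1 - (1 - tm) * (1 - ex) * (1 - db) * (1 - cx)
  igraph::E(g)$textmining <- tm
  igraph::E(g)$experimental <- ex
  igraph::E(g)$database <- db
  igraph::E(g)$coexpression <- cx
  igraph::E(g)$combined_score <- combined

  alt_pct <- numeric(n)
  names(alt_pct) <- nodes
  is_seed <- nodes %in% seeds
  is_planted <- nodes %in% planted
  bg <- !is_planted
  high_bg <- bg & stats::runif(n) < net$high_alteration_fraction
  alt_pct[bg] <- stats::runif(sum(bg), 0, 2.5)
  alt_pct[high_bg] <- stats::runif(sum(high_bg), 3.5, 40)
  alt_pct[is_planted & !is_seed] <- stats::runif(sum(is_planted & !is_seed), 0, 2.5)
  alt_pct[is_seed] <- stats::runif(sum(is_seed), 8, 35)

  node_table <- data.frame(gene = nodes, alteration_pct = unname(alt_pct),
                           hotspot = FALSE, stringsAsFactors = FALSE)
  seeds_present <- seeds[seeds %in% nodes]
  if (length(seeds_present) < length(seeds)) {
    warning("some seed genes absent from the generated graph")
  }
  list(
    graph = g,
    node_table = node_table,
    ground_truth = list(
      planted_community = planted,
      seed_genes = seeds,
      high_alteration_genes = node_table$gene[node_table$alteration_pct > 3]
    )
  )
}
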