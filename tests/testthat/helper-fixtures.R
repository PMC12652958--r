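# Shared synthetic fixtures, built in code at test time.

# Compact study: 5 cohorts x 60 samples, 6-gene panel, small planted network.
small_config <- function(rng_seed = 11L) {
  genes <- c("PTEN", "PIK3CA", "RICTOR", "EIF4E", "EIF4EBP1", "RPS6KB1")
  cohorts <- paste0("C", 1:5)
  mut <- matrix(0.08, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  mut["PTEN", "C1"] <- 0.25
  amp <- matrix(0.10, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  del <- matrix(0.05, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  simulation_config(
    cohorts = cohorts, n_samples_per_cohort = 60L, genes = genes,
    mutation_prevalence = mut, cna_amp_rates = amp, cna_del_rates = del,
    modules = list(translational = c("EIF4E", "EIF4EBP1", "RPS6KB1")),
    module_effects = list(
      PTEN_loss = list(gene = "PTEN", event = "loss",
                       module = "translational", delta = 0.5)
    ),
    network = list(n_nodes = 80L, attachment = 3L, community_size = 10L,
                   seed_genes = c("MTOR", "RPTOR", "RICTOR"),
                   high_alteration_fraction = 0.25),
    rng_seed = rng_seed
  )
}

# Single-contrast expression-recovery config: k cohorts pooled, planted delta
# on a 4-gene translational module, no copy-number noise on the contrast gene.
effect_config <- function(n_per_cohort, delta = 0.5, rng_seed = 1L,
                          n_cohorts = 4L) {
  genes <- c("PTEN", "EIF4E", "EIF4EBP1", "RPS6", "RPS6KB1")
  cohorts <- paste0("C", seq_len(n_cohorts))
  mut <- matrix(0.15, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  zero <- matrix(0, length(genes), length(cohorts),
                 dimnames = list(genes, cohorts))
  amp <- zero; del <- zero
  del["PTEN", ] <- 0.10
  simulation_config(
    cohorts = cohorts, n_samples_per_cohort = n_per_cohort, genes = genes,
    mutation_prevalence = mut, cna_amp_rates = amp, cna_del_rates = del,
    modules = list(translational = c("EIF4E", "EIF4EBP1", "RPS6", "RPS6KB1")),
    module_effects = list(
      PTEN_loss = list(gene = "PTEN", event = "loss",
                       module = "translational", delta = delta)
    ),
    rng_seed = rng_seed
  )
}

# Mutation-only panel with one planted exclusive pair at the given OR and
# marginals (no copy-number events, so role binarization equals mutation).
pair_config <- function(n_total, odds_ratio = 0.2, marginal = 0.3,
                        rng_seed = 1L, extra_genes = c("AKT1", "TSC1")) {
  genes <- c("PTEN", "PIK3CA", extra_genes)
  cohorts <- c("C1", "C2")
  mut <- matrix(marginal, length(genes), length(cohorts),
                dimnames = list(genes, cohorts))
  zero <- matrix(0, length(genes), length(cohorts),
                 dimnames = list(genes, cohorts))
  simulation_config(
    cohorts = cohorts, n_samples_per_cohort = n_total / 2, genes = genes,
    mutation_prevalence = mut, cna_amp_rates = zero, cna_del_rates = zero,
    exclusivity_pairs = list(
      list(gene_a = "PTEN", gene_b = "PIK3CA", odds_ratio = odds_ratio)
    ),
    rng_seed = rng_seed
  )
}

# Random connected weighted graph for propagation oracle tests.
random_test_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- min(1, 3 / n)
  repeat {
    g <- igraph::sample_gnp(n, p)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    if (igraph::vcount(g) >= 3 && igraph::ecount(g) >= 2) break
  }
  igraph::V(g)$name <- paste0("N", seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.4, 1)
  igraph::E(g)$combined_score <- igraph::E(g)$weight
  g
}

# Independent Fisher oracle: explicit hypergeometric enumeration via choose().
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- sum(tab)
  support <- max(0, r1 - c2):min(r1, c1)
  prob <- choose(c1, support) * choose(c2, r1 - support) / choose(n, r1)
  p_obs <- choose(c1, a) * choose(c2, b) / choose(n, r1)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
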