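# mtorwalk

Network-aware prioritization of mTOR-axis genes across cancer cohorts.

The mTOR serine/threonine kinase integrates growth-factor, nutrient and
energy signals, and its axis (PI3K–AKT–mTORC1/2 with the translational
effectors EIF4E/EIF4EBP1/RPS6/RPS6KB1) is recurrently altered across tumor
types. `mtorwalk` implements a reproducible pan-cancer framework for this
axis, aimed at computational biologists who want falsifiable, ranked
candidate lists rather than database compilations:

1. **Alteration landscape** — per-cohort prevalences of mutation,
   amplification, deletion, or the role-aware union; tissue-specificity via
   normalized Shannon entropy `H = −Σ pᵢ log pᵢ / log K` and the tau index
   `τ = Σ(1 − xᵢ/x_max)/(K−1)`; Shared / Tumor-specific / Ambiguous
   classification; between-cohort heterogeneity tests with BH-FDR.
2. **Module activity** — pooled gene-wise z-scores, module activity as the
   arithmetic mean of member z-scores, genotype contrasts (e.g. PTEN loss,
   PIK3CA mutation, RICTOR amplification vs. diploid), Mann–Whitney tests
   with Cliff's δ, and cohort-adjusted linear models with HC1 robust
   standard errors.
3. **Network propagation** — random walk with restart / personalized
   PageRank (`p ← (1−α)·K·p + α·s`, restart α = 0.75 by default) on a
   STRING-style interaction graph filtered at combined score ≥ 0.7, with
   symmetric (`D^−1/2 A D^−1/2`) or row-stochastic degree normalization,
   degree-matched permutation nulls, and a non-mutated filter that removes
   genes altered in > 3% of samples to surface "guilty-by-association"
   candidates.
4. **Mutual exclusivity / co-occurrence** — role-aware binary alteration
   matrices (oncogene: mutation ∪ amplification; tumor suppressor:
   mutation ∪ deletion), all-pairs Fisher / Yates-χ² tests with automatic
   small-count selection, odds ratios with Haldane correction, and the
   signed log₂OR heatmap matrix clipped to ±1.6 for display.

A synthetic-data generator emulates TCGA-style cohorts (MAF-like mutation
calls, GISTIC thresholded copy numbers, expression with planted
genotype-linked module shifts) and STRING-like confidence-weighted networks
with a planted seed-proximal community, so every stage is tested against
known ground truth without any data download.

## Worked example

```r
library(mtorwalk)
run <- run_mtor_pipeline(default_simulation_config(rng_seed = 1))
run
#> <mtor_run>
#>   landscape: 16 genes
#>   activity: 6 association rows
#>   propagation: 181 nodes, 139 nominations
#>   exclusivity: 120 pairs

head(run$landscape[, c("Gene", "Entropy", "Tau", "Class", "BH_FDR_q")], 3)
#>     Gene Entropy    Tau  Class     BH_FDR_q
#> 1   PTEN  0.9851 0.4618 Shared 3.325749e-06
#> 2 PIK3CA  0.9935 0.3545 Shared 4.993583e-07
#> 3   MTOR  0.9873 0.4335 Shared 1.071230e-03
```

Entropy near 1 with moderate τ says these genes are altered broadly rather
than in one lineage (hence `Shared`); the q-values show the between-cohort
heterogeneity that remains is still highly significant.

```r
head(run$propagation$nomination_set$nominations[, 1:5], 3)
#>   Filtered_Rank Gene_Symbol Page_Rank_Score Pan_Cancer_Alteration_Pct Degree
#> 1             1      PROX05      0.01523613                 0.7382707     14
#> 2             2      PROX08      0.01521007                 1.9937302     15
#> 3             3      PROX07      0.01512773                 0.7482283     15
```

The top non-mutated nominations are exactly the planted seed-proximal
community nodes (`PROX*`): rarely altered (< 3%) yet topologically adjacent
to the mTOR core — the "guilty-by-association" signature the diffusion is
designed to surface.

```r
subset(run$activity$table, Contrast == "PTEN_loss" & Module == "translational",
       c(p, Cliffs_delta, Model_Delta))
#>              p Cliffs_delta Model_Delta
#> 1 4.783236e-61    0.5097462   0.4678214
```

The cohort-adjusted model recovers the planted 0.5 z-unit translational
shift in PTEN-loss tumors (estimate 0.468), with a concordant Cliff's δ.

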