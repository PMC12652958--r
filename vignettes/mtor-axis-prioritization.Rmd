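---
title: "Methods: network-aware prioritization of mTOR-axis genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-aware prioritization of mTOR-axis genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtorwalk)
```

## The problem

Catalogues of mTOR-pathway genes abound; ranked, testable hypotheses do
not. `mtorwalk` turns alteration calls, expression and an interaction
network into three kinds of falsifiable statements about the mTOR axis:
which genes are altered broadly versus in specific lineages, which
expression modules shift with which genotypes, and which rarely-altered
genes are nonetheless topologically proximal to the recurrently altered
core ("guilty by association"). Because the matched tumor data are
controlled-access, the package ships a synthetic generator that emulates
their structure with planted ground truth; every empirical claim in this
vignette is one the test suite or the acceptance script computes.

## Stage 1: alteration landscape

Per cohort, a gene's prevalence is the percentage of evaluable samples
altered. Four encodings are supported: mutation only, amplification
(GISTIC call +1/+2), deletion (−1/−2), and the role-aware union (oncogene:
mutation ∪ amplification; tumor suppressor: mutation ∪ deletion;
unspecified: mutation ∪ any non-zero call). The specificity metrics are
computed on the vector of per-cohort union prevalences — the union is the
most complete notion of "altered", and the mutation-only and
amplification-only metrics are emitted alongside as sensitivity columns:

* normalized Shannon entropy `H = −Σ pᵢ log pᵢ / log K` (natural log; the
  normalization cancels the base), 1 = uniform across cohorts, 0 =
  concentrated;
* tau index `τ = Σ(1 − xᵢ/x_max)/(K−1)`, the complementary convention
  (0 = uniform, 1 = restricted to one cohort).

Classification applies Shared (≥ 5% prevalence in ≥ 5 cohorts) **before**
Tumor-specific (top − second ≥ 10 percentage points): a gene can satisfy
both, and broad prevalence is the stronger statement, so Shared takes
precedence. With fewer cohorts than `shared_min_studies` the class is
reported Ambiguous with a warning rather than guessed from a rule the
data cannot support. Ties for the top cohort are broken by larger cohort,
then lexicographic label, so output is deterministic under relabeling.

Between-cohort heterogeneity uses Pearson's χ² on the K×2
(altered / not-altered) table; when any expected count is below 5 an exact
test is substituted (full hypergeometric enumeration for two cohorts,
Monte-Carlo otherwise — the network exact algorithm is fragile for K×2
tables at these sample sizes). Counts reconstructed from printed
prevalences use round-half-away-from-zero, which is stable across
platforms. q-values are BH-FDR over the gene panel (the table is the
family; its size is recorded in the output metadata).

## Stage 2: module activity

Gene-wise z-scores are computed across the pooled cohort (sample SD,
`n−1`); zero-variance genes carry no contrast and are dropped with a
warning. Module activity is the arithmetic mean of member z-scores — a
deliberately transparent score whose linearity (a concatenated module is
the member-count-weighted mean of its parts) is property-tested.
Enrichment-style scorers are out of scope; the mean-z score is the
contract.

Genotype contrasts follow the role encodings: "loss" is mutation or
deletion (the tumor-suppressor rule — "loss" is never defined more
narrowly here, for consistency with the exclusivity stage), "mutation" is
the flag alone, and "amplification vs. diploid" excludes deleted samples
from the comparator so the baseline is genuinely diploid. Each
contrast × module cell gets a Mann–Whitney test with Cliff's δ, group
medians/IQRs, and a linear model of activity on the genotype indicator
with cancer type as a categorical covariate (when more than one cohort is
pooled) and HC1 sandwich standard errors — heteroskedasticity across
cohorts is expected, and HC1 is the conventional default among the
sandwich variants. BH-FDR is applied per emitted table.

## Stage 3: network propagation

Edges below the combined-score cutoff (primary 0.7, sensitivity 0.4) are
removed after optional down-weighting of the text-mining channel, in which
case the combined score is recomputed as the noisy-OR
`1 − Π(1 − s_c)` of the retained channels. Weighted degrees (sums of
combined scores) define `D`; two kernels are exposed:

* `symmetric` (default): `D^−1/2 A D^−1/2`, the hub-corrected operator;
* `stochastic`: the row-stochastic walk matrix `D^−1 A`, applied through
  its transpose so the iteration is exactly personalized PageRank with
  damping `1 − α` — this equivalence is verified against an independent
  PageRank implementation in the tests (for the stochastic kernel only;
  the symmetric kernel is a different operator and no equivalence is
  claimed for it).

Propagation iterates `u ← (1−α) M u + α s` from the seed distribution
(equal mass over seeds present in the graph; absent seeds reallocate their
mass). A numerical subtlety: the symmetric kernel does not preserve
probability mass, so renormalizing the *state* each step would shift the
fixed point away from the resolvent. The implementation therefore iterates
the affine map unnormalized — it converges geometrically since the
spectral radius of `(1−α)M` is below 1 — while reporting and monitoring
the L1-normalized sequence. The returned scores are non-negative, sum to
1 at every iteration, and at convergence (L1 tolerance 1e−10, cap 1,000
iterations, non-convergence is an error) equal the renormalized direct
solve `α(I − (1−α)K)^−1 s`, which `propagate_solve()` exposes as an
oracle.

Empirical enrichment uses degree-matched seed permutations: each seed is
replaced by a uniform draw from its weighted-degree decile (bins with
fewer than two candidates are widened with a warning), and per-node
p-values use the add-one rule `(1 + #{null ≥ obs})/(n_perm + 1)`.

The non-mutated filter annotates every node with its pan-cancer alteration
prevalence (mutation or amplification over pooled samples), removes genes
above 3%, flags hotspot carriers into a side table, and excludes the seeds
themselves. Score ties are broken by lower degree (the less-connected gene
is the more surprising nominee), then symbol. The whole filtered graph is
propagated by default; restricting to a seed neighborhood is a
presentation choice, not a different method. The default hotspot list is
empty — hotspot annotation is a curated input the user supplies. The
`source_support_count` column is likewise carried through as user-supplied
annotation (`NA` by default); it derives from database census work outside
this package's scope.

## Stage 4: mutual exclusivity / co-occurrence

Role-aware binarization (above) yields a samples × genes boolean matrix;
samples without a copy-number measurement fall back to the mutation flag
and the per-gene encoding provenance is recorded. For each unordered pair
the 2×2 co-alteration table is tested with Fisher's exact test when any
expected count is below 5, otherwise Yates-corrected χ². The two-sided
Fisher p sums hypergeometric probabilities no larger than the observed
table's (the probability-mass convention). The odds ratio is the sample
cross-product `(ad)/(bc)`; with a zero cell the Haldane–Anscombe +0.5
correction is applied to the *estimate only*, never to the exact p, and
flagged. Negative log₂OR is labeled mutual exclusivity, positive
co-occurrence. BH-FDR runs over all emitted pairs in one run. The display
matrix clips log₂OR to ±1.6 (the unclipped values are retained), blanks
the diagonal and non-evaluable cells, desaturates q ≥ 0.10 cells, and
orders genes by average-linkage hierarchical clustering of Euclidean
distances between signed association profiles (missing entries treated as
0 for clustering only) — linkage and distance are conventional choices
where any reasonable pair would do. Mutation-only and copy-number-only
sensitivity matrices come from an encoding flag, not separate code paths.

## Statistical kernel conventions

* BH-FDR is the standard step-up adjustment (delegated to `p.adjust`),
  returned in input order; permutation equivariance, `q ≥ p` and `q ≤ 1`
  are property-tested.
* Mann–Whitney uses exact enumeration when `n0 + n1 ≤ 20` with no ties,
  otherwise the tie-corrected, continuity-corrected normal approximation.
  The reported statistic is the wins of group 1, matching the sign
  convention of Cliff's δ and the median-difference column (carrier −
  comparator).
* Cliff's δ is computed from midranks, `δ = 2U₁/(n0·n1) − 1`, which
  matches the cross-pair definition exactly (brute-force-verified) and
  scales to pooled-cohort sizes.
* The Yates correction is applied to 2×2 tables only; K×2 heterogeneity
  tables use uncorrected Pearson (the correction is not defined there).

## The synthetic generator as study conditions

Defaults (chosen once, not tuned): 10 TCGA-style cohorts × 200 samples; a
16-gene panel (the 12 core mTOR-axis genes plus EIF4E, RHEB, LAMTOR1,
PRKAA1); marginal mutation and amplification rates on the pan-cancer scale
typical of this panel (PTEN ~10% mutated, PIK3CA ~13% mutated / ~29%
amplified, RICTOR ~27% amplified), with a 2.5-fold mutation enrichment in
the top cohort; copy-number mass split 70% low-level / 30% high-level
within amplification and deletion; a planted translational-module shift of
0.5 z-units in PTEN-loss carriers (with smaller PIK3CA and RICTOR
effects); a planted PTEN–PIK3CA mutation pair at odds ratio 0.2, drawn
from the exact 2×2 joint solved from (OR, marginals) via the quadratic in
the concordant cell; and a 200-node preferential-attachment network with a
15-node planted seed-proximal clique carrying high experimental/database
channel scores. Expression noise is unit-variance Gaussian — downstream
z-scoring makes the marginal distribution immaterial to the contracts.
Each artifact type draws from its own RNG stream derived from the single
configuration seed, so fixtures regenerate byte-identically and
independently.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real tumors: mutational signatures and subclonality,
batch and purity effects, correlated copy-number segments, dependence
between events beyond the pairwise OR targets, and the literature biases
baked into real interaction networks. Recovery of planted structure shows
the estimators are correct, not that real data satisfy their assumptions.

## Problem sizes and numerical choices

Test and acceptance runs use the default 2,000-sample cohorts, the
200-node graph, replicate counts of 100 for recovery checks and 1,000 for
type-I calibration, and 5,000 samples for the planted-pair screen — sizes
at which binomial and normal-theory error bands are tight enough for the
assertions while the full suite stays fast. Propagation oracle agreement
is checked to 1e−8 on random graphs of up to 50 nodes across
α ∈ {0.5, 0.75, 0.9} and both kernels; Fisher p-values agree with full
fixed-margin enumeration to 1e−10 for margins up to 30.

## Known limitations

Heterogeneity p-values from the Monte-Carlo exact branch depend on the
caller's RNG state; the pipeline seeds it, but direct callers should too.
The degree-matched null re-propagates per permutation and is O(n_perm)
full diffusions — acceptable at hundreds of nodes, slow at tens of
thousands. The alteration-prevalence annotation used by the non-mutated
filter is an input; when it comes from a different source than the
landscape stage the two can disagree, and the filter deliberately trusts
its own input rather than silently reconciling them. Gene-symbol
harmonization uses a small static alias map, not a live registry.
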