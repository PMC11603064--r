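---
title: "Gene-dose differential expression and trajectory timing: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-dose differential expression and trajectory timing: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Many neurodevelopmental disorders are caused by losing one functional copy of
a transcription factor. A single-nucleus RNA-seq experiment across an allelic
series — knockout (dose 0), heterozygote (dose 1), wild type (dose 2) — asks
three statistical questions that this package answers as a tested pipeline:

1. **Which genes respond to gene dose, and how?** Pairwise comparisons
   between wild type and heterozygote are often underpowered (the effect of
   losing one allele is subtle), so dose is modeled ordinally across all
   three genotypes.
2. **Which cell types carry the burden of dysregulation**, once their very
   different sizes are equalized?
3. **Is differentiation itself delayed?** Mutant nuclei may occupy earlier
   positions along the differentiation trajectory, and individual genes may
   peak at the wrong pseudotime.

`doseDE` implements the full chain — QC, normalization, pseudobulk NB
differential expression, composition tests, trajectory statistics, gene-set
enrichment and regulon scoring — together with a synthetic-data generator
that plants every effect the chain is supposed to find, so each stage is
validated by parameter recovery rather than by eye.

# Pseudobulk differential expression

Single-cell counts within each (cluster, sample) combination are summed into
pseudobulk columns and analyzed with a bulk-style negative-binomial GLM
(variance $\mu + \alpha\mu^2$, log link, offset $\log s_j$):

* **Size factors** $s_j$ are the median-of-ratios over genes with nonzero
  counts in every column, rescaled to geometric mean 1.
* **Dispersions** are estimated in three stages: method-of-moments
  initialisation; profile-likelihood maximisation in $\alpha$ alone with
  fitted means held at $\bar{y}_g s_j$ (a 48-point log-spaced grid with
  quadratic interpolation at the optimum — accurate to a few percent, which
  the next stage dominates); then shrinkage of $\log\alpha$ halfway toward a
  trend that is log-linear in $1/\text{mean}$. The half-weight convex
  combination is a deliberately simple, testable stand-in for full
  empirical-Bayes machinery; the floor is $10^{-8}$ and all-zero genes are
  excluded from testing.
* **Pairwise contrasts** use a Wald test on the log2-scale coefficient;
  **dose responses** use a likelihood-ratio test of `~ dose` (the allele
  count 0/1/2 entering as a numeric covariate, so the test has 1 df and the
  reported fold change is a per-allele slope) against the intercept-only
  model. Interaction LRTs (`~ covariate * dose` vs additive) use the same
  engine. LFCs are unshrunk maximum-likelihood estimates; the conventional
  calling rule (BH $q < 0.05$ and $|\log_2 FC| \ge 0.2$) is applied to them
  directly, a documented deviation from pipelines that shrink LFCs first.

Among dose-significant genes, a gene is classified **repressed** if its
normalized mean peaks at dose 0 (de-repressed on loss) and **activated** if
it peaks at dose 2; genes peaking at the heterozygote are non-monotone in
dose and are deliberately excluded from both classes rather than
force-classified.

**DEG burden.** DE sensitivity grows with cluster size, so clusters are
compared after repeated fixed-size downsampling: a balanced draw of
`n_cells` nuclei (default 700, half per genotype arm, without replacement),
the full pseudobulk DE on the subsample, a DEG count — repeated 10 times.
Clusters that cannot supply the draw are reported `N/A`, never zero. Each
cluster's replicate counts are compared to the pooled counts of all other
eligible clusters by a two-sided Mann–Whitney U test with BH correction;
the versus-pooled-others grouping is this package's choice (the convention
is not standardized), as is the per-cluster PRNG stream keyed by
`(seed, cluster)` that makes draws independent of cluster enumeration order.

# QC, normalization and per-cell scores

Cells are kept when UMIs ∈ [800, 6000], detected genes ∈ [300, 3000],
mitochondrial reads (genes with the reserved `mt-` prefix) ≤ 1%, and
$\log(\text{genes})/\log(\text{UMIs}) \ge 0.9$ (base-invariant; equality is
kept). Violated rules are enumerated per cell; zero-depth cells are dropped
with their own reason rather than crashing the ratio. Normalization is
$\log_2(1 + 10^4 \cdot c/\text{total})$; log base 2 is recorded in the
matrix attributes.

**LISI** (local inverse Simpson's index) quantifies genotype mixing: the
3×perplexity nearest neighbours are weighted by a Gaussian kernel whose
bandwidth is calibrated per cell by bisection to entropy $\log(30)$
(tolerance $10^{-5}$), and the inverse Simpson index of the neighbourhood's
label probabilities is the effective number of genotypes present (1 =
segregated, 3 = perfectly mixed for three genotypes).

**Cell-cycle scores** are signature means minus expression-matched control
means (25 average-expression bins, 50 seeded controls per signature gene,
expression ties broken lexicographically); the phase is the argmax of the
S and G2M scores when either is positive, else G1/G0.

**Markers** are one-vs-rest Wilcoxon rank-sum tests (normal approximation
with tie correction) restricted to genes with log2 mean difference ≥ 0.5 and
detection fraction ≥ 0.25 in either group, BH-adjusted within cluster.

# Composition

Per-sample cluster proportions are arcsin-square-root transformed, fitted
per cluster across samples, and the residual variances are shrunk by an
empirical-Bayes scaled-inverse-chi-square prior fit by moments across
clusters (`limma::squeezeVar` supplies exactly this), giving a moderated t
(two groups) or moderated F (three or more). The transform is standard
practice for proportion data even though the source convention names only
"moderated" tests; cell-cycle-phase proportions reuse the same operation
with phase labels in place of clusters.

# Trajectory statistics

Pseudotime is the shortest-path geodesic distance from an analyst-chosen
root cell on a symmetric kNN graph (k = 15, Euclidean edge weights) over a
supplied embedding, min–max scaled to [0, 1]; principal-graph learning is
intentionally out of scope, and an externally computed pseudotime can be
passed to every downstream test.

* **Dynamic genes**: Moran's I on the neighbour graph with the
  randomization-assumption normal approximation, one-sided toward positive
  autocorrelation (trajectory-variable genes are positively autocorrelated
  by construction), BH with $q < 0.05$.
* **Distribution shifts**: per-cluster two-sided two-sample KS tests of
  pseudotime between genotype pairs, plus relative density-difference
  curves $(f_{mut} - f_{WT})/f_{WT}$ over equal-width bins.
* **Expression timing**: per gene,
  $D_{KL}(P_{WT}\,\|\,Q_{mut}) = \sum_b p_b \ln(p_b/q_b)$ between binned
  mean-expression profiles (20 quantile bins computed on the pooled WT
  pseudotime so the WT profile is near-uniformly supported; pseudocount
  $10^{-6}$; nats). The null shuffles genotype labels across cells — one
  shared permutation set for all genes so gene-wise p-values are comparable
  — with $p = (1 + \#\{D_{null} \ge D_{obs}\})/(1 + n_{perm})$ and BH.

The KL direction (WT as reference), log base, bin count, pseudocount and
permutation count are configuration with stated defaults — the source
convention pins none of them.

**Common-support trimming.** With a real maturation lag, mutants never reach
the latest pseudotime, so genotype labels of late cells are not exchangeable
and a global-shuffle permutation null flags *every* late-peaked gene as a
timing positive — on the planted world roughly 14% of unshifted dynamic
genes, almost all peaking beyond the mutants' reach. `kl_timing_test`
therefore trims both arms to the overlap of their pseudotime ranges before
binning (default `trim_common_support = TRUE`); the range shift itself is
precisely what the KS tests measure. After trimming, the false-positive rate
on unshifted genes drops to the nominal level while power on genuinely
peak-shifted genes remains high. Bins left empty in one arm after trimming
are merged into their neighbour and logged.

# Enrichment and regulons

Over-representation uses the upper hypergeometric tail (identical to the
one-sided Fisher exact test on a 2×2 table) within a caller-supplied
universe — all genes expressed in the relevant cluster — with BH across
sets. For targets with expression bias there is a resampling null: B = 1000
draws of the query's size from the top 50% of expression-ranked genes (mean
normalized expression, ties by label); fold enrichment is observed over the
*median* null overlap, matching the convention of reporting e.g. a 4.7-fold
enrichment from an observed 123 against a median 26. Yates-corrected
chi-square (with the exact clamped formula) and Fisher's exact test cover
2×2 association questions.

Regulon activity is a rank-based AUC: genes ranked per cell by descending
count (ties broken by seeded jitter below $10^{-9}$ of the count scale), and
each regulon scored by the area under its recovery curve within the top-5%
window, normalized so a fully-contained set scores 1. The Regulon
Specificity Score is $1 - JSD$ (log base 2) between the regulon's normalized
cell-activity distribution and the normalized cluster indicator. Regulons
are called differential between genotypes by a Wilcoxon test on per-cell
AUCs with an effect floor of 0.01 mean-AUC difference — the "differentially
expressed regulon" notion is not standardized, so both pieces are explicit
conventions, as is the "specific regulon" denominator rule (max RSS more
than 2 MADs above the across-regulon median).

# The synthetic world

`simulate_dataset()` draws nuclei with uniform latent pseudotime, log-normal
library sizes (median 3,000 UMIs, sdlog 0.3 — the scale of the motivating
experiments) and gene-wise NB dispersions (log-normal, median 0.1, sdlog
0.5), and genes from archetypes: repressed genes follow a decreasing
logistic "progenitor program", activated genes an increasing "maturation
program", dynamic genes Gaussian bumps at random peaks, cell-cycle S/G2M
programs active in early-pseudotime cycling cells, flat mitochondrial genes
pinned at ~0.5% of reads, and flat nulls. Counts are
$NB(\text{libsize} \times p_{gc}, \alpha_g)$ with $p$ normalized per cell.

The planted effects are the validation contract: repressed genes shift
$+0.5\,\log_2$ per lost allele (visible already in Hets), activated genes
$-1.0\,\log_2$ in KO but only 20% of that in Hets (threshold-like), mutants
read all pseudotime-dependent programs at an effective pseudotime
`maturation_lag × (2 − dose)` earlier (truncated at 0), and 200 dynamic
genes peak +0.2 later in mutants. Cell types are fixed quantile segments of
true pseudotime (5 by default) so cluster labels exist without a clusterer,
and the emitted 2-D embedding is a noisy 1-D manifold in *effective*
pseudotime — what an expression-derived embedding would recover.

Two design points deserve emphasis. First, dose-class genes ride *true*
pseudotime: if their logistic programs also shifted with the lag, the lag
would leak into their planted fold changes and the generative log2FC would
no longer be the quantity the DE stage is supposed to recover; the lag is
expressed through cell positions and the dynamic program instead. Second,
the heterozygote lag size is a free choice (0.1 per lost allele) — the
motivating literature does not quantify it — so recovery tests establish
sensitivity at that lag, not the lag itself.

What a green suite does **not** establish: robustness to ambient RNA,
doublets, batch effects beyond sample identity, non-uniform cell capture
along the trajectory, or misassigned cluster labels — none of which the
generator emulates. Pseudobulk columns within a genotype are exchangeable
replicates here; real biological replicates are more dispersed, so real
type-I behaviour depends on the dispersion estimation absorbing that extra
variance.

# Numerical choices

IRLS converges at max coefficient update $<10^{-8}$ (natural-log scale, 100
iterations, linear predictor clamped at 30); non-converged genes carry
missing statistics. The LRT clamps $\lambda$ at 0 and treats identical
designs as a 0-df degenerate case ($p = 1$ at $\lambda = 0$). BH is applied
within the family stated by each operation (per cluster for markers and DE
tables; across all tests performed for KS, regulons and timing). The QC
ratio rule keeps equality; zero-margin 2×2 tables return $p = 1$; a
resampling fold with median-null 0 is flagged undefined rather than
infinite.

# Limitations

No LFC shrinkage, no outlier detection (Cook's distance), no independent
filtering, no compositional log-ratio models, no mixed-effects terms for
litter, and no network inference — regulons and embeddings are inputs. The
DEG-burden grouping (each cluster versus pooled others) and all KL-test
conventions are package decisions that should be held fixed across
comparisons rather than treated as estimates of any external pipeline's
behaviour.
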