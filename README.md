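# GeneSetInvariance

Are curated oncogene sets statistically special, or do they behave like any
random set of genes of the same size? `GeneSetInvariance` is an R package
for answering that question on bulk and single-cell expression data. It is
aimed at computational biologists who have a genes-by-samples abundance
matrix with tumor/normal labels (TPM or proteomic units), a focal gene set
(for example the Cancer Gene Census), and optionally a protein–protein
interaction network and clustered single-cell counts.

## The method

The central object is the **size-matched resampling null**. For a
statistic *T* computed on a gene set, the package draws *B* (default 100)
uniform random sets of the focal set's size from the expressed-gene
universe, evaluates *T* on each, and locates the focal set by its mid-rank
percentile

&nbsp;&nbsp;*p* = (#{T_b < T_focal} + ½·#{T_b = T_focal}) / B.

Under exchangeability *p* is uniform; "invariance" of a focal set is the
observation that *p* is unremarkable for every statistic examined.
Statistics supported for each sample pair (averaged over all
normal–normal, tumor–tumor and normal×tumor pairs):

- Pearson correlation *r* and Spearman correlation (Pearson on mid-ranks);
- mutual information in nats, from rank-transformed values cut into
  equal-count bins with the bin count from Doane's rule
  k = ⌈1 + log₂ n + log₂(1 + |g₁|/σ_g₁)⌉;
- expression noise η² = σ²/μ² per gene (squared coefficient of variation,
  population variance), averaged over genes.

Around the core sit the supporting stages: per-sample distribution fitting
(log-normal, loglogistic, Weibull, Pareto, Burr XII) with minimum-AIC
selection driving a tail-quantile low-expression filter; PCA embeddings
with mean normal–tumor Euclidean distances; neighbor-joining sample trees
and average-linkage clustering with an adjusted-Rand separation score;
interaction-network degree reports with a discrete power-law MLE
(P(k) ∝ k^−α); and a single-cell stage (QC, LogNormalize, per-cluster
two-sided Wilcoxon DE with BH adjustment, focal fraction among DE genes).
Synthetic-data generators with planted, recoverable structure (bulk
log-normal TPM, erased-configuration-model scale-free networks, clustered
negative-binomial counts) make every stage testable end to end. See the
vignette in `vignettes/gene-set-invariance.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(GeneSetInvariance)

sim <- simulateBulk(bulkSimConfig(seed = 1))   # 2000 genes, 10+10 samples
pairStatReport(sim$matrix, sim$focal)
#>   gene_subset group         r       rho        mi       eta2 n_pairs
#> 1       focal  NvsN 0.9338590 0.9557958 1.1142668 0.01926410      45
#> 2       focal  TvsT 0.8009142 0.8741442 0.8178746 0.06473186      45
#> 3       focal  NvsT 0.8702040 0.9149272 0.9323060 0.04290649     100
```

Normal samples correlate more strongly (r ≈ 0.93) and are less noisy
(η² ≈ 0.019) than tumor samples (r ≈ 0.80, η² ≈ 0.065) — the generator's
condition-dependent dispersion at work. Is the focal set special?

```r
buildNull(sim$matrix, sim$focal, "eta2", "NvsT", nReps = 100, seed = 2)
#> ResamplingNull of 'eta2:NvsT' (set size 100, 100 replicates)
#>   focal value: 0.0429065; null mean: 0.044175; percentile: 0.2
```

Percentile 0.20: the focal set's normal-vs-tumor noise is typical of
random same-size sets — invariant. A planted contrast is flagged cleanly;
with a 3-fold degree boost on focal nodes in a simulated interaction
network:

```r
net <- simulateNetwork(networkSimConfig(focalDegreeBoost = 3, seed = 1))
degreeNull(net$network, net$focal, nReps = 100, seed = 2)
#> ResamplingNull of 'meanDegree' (set size 100, 100 replicates)
#>   focal value: 5.67; null mean: 2.1007; percentile: 1
```

The focal set averages 5.67 interactions per gene against a null mean of
2.10 — percentile 1, decisively non-invariant.

`runInvarianceReport(list(seed = 1, outDir = "report"))` runs every stage
from one config (YAML accepted) and writes TSV/Newick/JSON outputs.

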