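---
title: "Single-sample coexpression networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample coexpression networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnets)
```

## The problem

Coexpression networks are usually estimated from many samples at once, which
yields one *aggregate* network per cohort and erases the heterogeneity that
precision oncology cares about. Single-sample (sample-specific) network
inference attributes a network to each individual sample, typically by
measuring how that sample perturbs, or contributes to, the cohort-level
correlation structure. ssnets implements six such methods on a common
Pearson-correlation (PCC) backbone, with the whole cohort itself as the
reference (no normal-tissue samples), plus the evaluation machinery needed to
compare them: preprocessing, background-network pruning, top-k edge
selection, node strength, hubs and their subtype specificity, driver
enrichment, empirical-Bayes differential node strength, and correlation of
node strengths with matched proteomics and copy-number data.

## The six methods

Throughout, $e^{\alpha}_{ij}$ is the PCC of genes $i,j$ over all $N$
samples, and $e^{\alpha-q}_{ij}$ the PCC with sample $q$ removed.

* **SSN** — correlation perturbation. The reference is the cohort without
  $q$, the perturbed network adds $q$ back, so
  $w_{ij}^q = e^{\alpha}_{ij} - e^{\alpha-q}_{ij}$. No edge significance
  test is applied; edges are filtered later by background pruning and
  top-k selection, identically for all methods.
* **LIONESS** — linear interpolation,
  $w_{ij}^q = N(e^{\alpha}_{ij} - e^{\alpha-q}_{ij}) + e^{\alpha-q}_{ij}$.
  The multiplier is the sample count $N$: it is what makes the all-sample
  network the average of the single-sample networks (the reconstruction
  identity $N e^{\alpha} = w^q + (N-1)e^{\alpha-q}$, tested to 1e-10).
  SSN and LIONESS share both correlation matrices, so
  $w^q_{\text{LIONESS}} = N\,w^q_{\text{SSN}} + e^{\alpha-q}$ exactly.
* **SWEET** — weighted interpolation. The perturbed network appends a
  duplicate of column $q$ ($N+1$ columns); the genome-wide sample weight
  $W_q = (\mu_q - \min\mu + x)/(\max\mu - \min\mu + x)$ with $x = 0.01$
  rescales the perturbation, where $\mu_q$ is the mean correlation of
  sample $q$'s profile with every other profile. Then
  $w^q = W_q \cdot N \cdot K (e^{\alpha+q} - e^{\alpha}) + e^{\alpha}$ with
  balance $K = 0.1$. The original z-test edge filter is replaced by the
  shared top-k selection.
* **iENA** — single-sample correlation from reference moments. With
  per-gene mean $\mu_i$ and *population* variance (denominator $N$) over
  the cohort, $w_{ij}^q = z_{iq} z_{jq}$ where
  $z_{iq} = (x_{iq}-\mu_i)/\sigma_i$. The sample mean of these weights is
  exactly the aggregate PCC. Only the first-order node networks are
  implemented; the higher-order edge networks are out of scope.
* **CSN** — a binary network per sample from a statistical-independence
  test. For gene $g$ and sample $s$, the neighborhood $N_g(s)$ holds the
  $k = \mathrm{round}(0.1 n)$ *other* samples nearest to $x_{gs}$ in that
  gene's expression. Under independence the overlap
  $n_{ij} = |N_i(s)\cap N_j(s)|$ is exactly hypergeometric with mean
  $k^2/n$; the statistic $\rho = n_{ij}/n - (k/n)^2$ standardized by the
  hypergeometric null sd is compared to the upper-$\alpha$ normal quantile
  ($\alpha = 0.01$). Excluding the sample itself from its own neighborhood
  is what makes the null exact: with self-inclusion the two neighborhoods
  share one member surely, the overlap becomes $1 + $ a hypergeometric on
  $n-1$, and the realized null edge rate at $n=100$ is 0.034 instead of
  0.009 at $\alpha = 0.01$. Distance ties are broken by smaller sample
  index, so results are deterministic.
* **SSPGI** — rank-based edge perturbation against a background network.
  Genes are ranked within each sample (ascending, average ties);
  $\delta_{es} = r_{is} - r_{js}$ for each background edge $e=(i,j)$,
  and the weight is the perturbation
  $\Delta_{es} = \delta_{es} - \bar\delta_e$ against the cohort mean. The
  per-edge mean of $\Delta$ is zero by construction. The original tool's
  7800-gene ceiling is not inherited; `emulate_cap = TRUE` reproduces it
  for comparability studies.

All six return the same container: a tibble with canonical `gene_a <
gene_b` pairs and one weight column per sample, so pruning
(`prune_to_background()`), per-sample top-k selection by absolute weight
with lexicographic tie-breaks (`select_top_edges()`), and within-sample
max-abs scaling into $[-1,1]$ (`scale_weights_unit()`) apply uniformly.
Max-abs rather than min-max scaling preserves the sign of negative edges
and maps absent (zero) edges to zero.

## Preprocessing

`filter_low_counts()` keeps genes with CPM above 1 in at least one sample,
with library sizes fixed before filtering. `normalize_log_cpm()` uses
$\log_2(\mathrm{cpm} + 0.5)$; the pseudocount of 0.5 is configurable and
recorded here because conventions differ. `select_hvg()` keeps genes whose
cross-sample variance (denominator $n-1$) strictly exceeds a threshold
(2.75 by default, the scale appropriate for cohort log-CPM data), with an
optional hard cap on gene count. `scale_genes()` z-scores each gene.
`remove_outlier_samples()` clusters samples by average-linkage on
$1 - $ Spearman correlation, cuts the tree at 95% of its maximum merge
height and drops clusters of fewer than 3 samples. Note that cutting below
the maximum height always separates the top merge, so the no-removal case
is a cohort whose clusters are all big enough to keep, not literally a
single cluster.

## Statistics

The two-group differential machinery (`moderated_t_engine()`, used both for
expression and for node strengths) is a moderated t-test: per-feature pooled
variances $s_g^2$ on $d$ degrees of freedom are shrunk toward a prior,
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by the method of moments on $\log s_g^2$ via digamma/trigamma
inversion; the moderated t is referred to $d_0 + d$ degrees of freedom.
When the trigamma inversion has no positive solution the prior degrees of
freedom are infinite (complete shrinkage), and forcing $d_0 = 0$ recovers
the ordinary pooled t-test exactly — both limits are tested, and the whole
engine is cross-checked against an independent reference implementation.
Significance flags combine BH-adjusted p ≤ 0.05 with an absolute effect
cutoff of 1; for node strengths the "LFC" effect is the raw group-mean
strength difference, reproducing the convention of feeding strengths to the
linear model directly. Enrichment uses the exact hypergeometric upper tail
with the network's gene universe as background; group comparisons of
concordance use Kruskal-Wallis with a tie-corrected Dunn post hoc and BH
adjustment across pairs (the adjustment method is recorded in the result).

Node strength is the sum of absolute weights of a gene's retained edges.
Topology metrics (density without loops, average local clustering with
zeros for degree < 2, mean node/edge betweenness, diameter of the largest
component, component count over the declared universe) are computed on the
unweighted graph of nonzero edges, because negative correlations cannot act
as distances. Hubs are the `hub_n` most connected nodes per network
(degree, ties by strength then gene id); regularly recurring hubs occur in
at least 75% of a group's networks; subtype-specific hubs are regular in
one group and in no other.

## The synthetic cohort generator

`generate_cohort()` produces the benchmark substrate: an unbalanced
two-subtype cohort (40 vs 8 samples), 300 genes, six shared coexpression
modules plus two subtype programs per group (15 genes each), negative
binomial counts (dispersion 0.1) with lognormal library-size factors
(sd 0.2), and linked proteomics and copy-number matrices.

* **Latent structure.** Each module has a latent activity per sample;
  module genes load on it with $\lambda = 1.2$ on the log2 scale over a
  per-gene noise sd of 0.5. Shared modules fluctuate around zero. A
  group-specific module is a subtype *program*: within its own group its
  activity has mean $\pm 2$ (signs alternate across a group's programs,
  mirroring the roughly even up/down split of real subtype DE genes);
  outside its group the shared activity is replaced by independent per-gene
  noise of the same variance, so within-module correlation exists only in
  the matching subtype and the HVG step cannot tell the gene classes apart
  by variance alone. Zero-mean "rewiring" without the activation mean was
  rejected: a module then deviates strongly in only about half of its own
  group's samples, no gene recurs as a hub in 75% of any group's networks,
  and the cohort has no differential expression and no PCA separation —
  none of the subtype behaviors the evaluation is supposed to probe.
* **Background network.** Modules are hub-centered: each module's
  designated hub gene is wired to every member, and the remaining member
  pairs are included with probability 0.3 (within-pathway densities of
  integrated functional networks are of this order). The hubs of the
  specific modules are the planted drivers, so "driver" has a topological
  meaning. An equal number of uniformly random non-module decoy pairs is
  added.
* **Copy number.** States 1-4 are drawn per gene and sample with an
  amplification-biased marginal (5/80/10/5%), drivers are amplified with
  probability 0.6 in their own subtype's samples, and dosage scales both a
  gene's level ($\log_2(\mathrm{cnv}/2)$) and its co-variation amplitude —
  an amplified gene transcribes more per unit of regulatory input. Dosage
  is the generator's channel linking node strength to measured omics at
  the per-sample level.
* **Proteomics** is the per-sample log2 expression mean plus Gaussian
  noise (sd 0.7). Baselines are uniform on log2 3-8 and independent of the
  network structure.

### What the generator does and does not emulate

It emulates subtype-separable coexpression with unbalanced groups, planted
rewiring, driver hubs, overdispersed counts, and omics linked to
expression. It deliberately does not emulate expression-participation
coupling — in real tissue, abundantly expressed genes produce detectable
co-variation while silent genes do not, which ties a gene's network
strength to its abundance. Deviation-based single-sample weights track
|z-score| and are blind to absolute level once genes are standardized, so
on this generator the strength-versus-proteomics comparison between
single-sample and aggregate networks is driven almost entirely by the CNV
dosage channel. Passing tests therefore demonstrate the algebra, the
calibration, and the subtype-recovery behavior of the methods; they do not
demonstrate that proteomics concordance on real cohorts would rank the
methods the same way.

### Benchmark protocol sizes

`benchmark_cohort()` runs the whole pipeline at desk scale: 300 genes, 48
samples, HVG variance threshold 0 (the generator's genes are the designed
universe), top-k = 60% of the background edges (retaining roughly the edges
of the modules active in a sample while forcing genuine selection among
the rest; the real-data convention of matching the average CSN network
size does not transfer, because CSN at $n = 48$ with $k = 5$ neighborhoods
yields ~50-edge networks), and 20 hubs per network (about twice the number
of structural module hubs, so every active module's hub fits with margin).
Group-size bias is summarized on raw top-k strengths, since the bias lives
in the weight magnitudes that within-sample unit scaling removes by
design; unit-scaled strengths feed the differential analysis, as in the
evaluation protocol.

## Worked example

```{r example, eval = FALSE}
library(ssnets)

cohort <- generate_cohort(synthetic_config(seed = 1))
scaled <- cohort$counts |>
  filter_low_counts() |>
  normalize_log_cpm() |>
  select_hvg(threshold = 0) |>
  scale_genes()

panel <- scaled |>
  lioness_panel() |>
  prune_to_background(cohort$background) |>
  select_top_edges(k = 500)

strengths <- node_strength(scale_weights_unit(panel))
res <- differential_node_strength(strengths, cohort$groups)
plot_volcano(res)

pc <- pca_node_strength(strengths, cohort$groups)
autoplot(pc)
```

## Known limitations

* All leave-one-out quantities are recomputed per sample rather than
  rank-one-updated; fine at cohort scale here, quadratic-times-$N$ in
  general.
* The generator's two-group design does not exercise the >2-group
  generalization of subtype-specific hubs beyond unit tests.
* CSN at small cohort sizes ($n \lesssim 50$) is underpowered by
  construction (neighborhoods of ~5 samples); its sparse binary networks
  are faithful to the method, not an artifact of this implementation.
* The spec of the Dunn post hoc adjustment (BH) and of the top-k ranking
  (absolute weights) are conventions recorded in the outputs; alternatives
  exist in the literature.
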