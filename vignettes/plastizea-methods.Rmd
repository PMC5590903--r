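---
title: "Models and methods behind plastizea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastizea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plastizea compares gene-expression plasticity between a domesticate (maize)
and its wild ancestor (teosinte) across two environments, Early Holocene
(EH: low temperature and CO₂) and Modern Ambient (MA), and screens for
genetic assimilation: genes whose environmental response in the ancestor has
been lost in the crop. This vignette documents the statistical models, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the design
was genuinely open.

# Differential expression

## Model

Counts for gene $g$ in sample $j$ are modeled as negative binomial,
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$, and

$$\log \mu_{gj} = \log s_j + \beta_{0g} + \beta_{\text{group}(j),g}
  + \beta_{\text{env},g}\, x_j,$$

where $s_j$ is a per-sample size factor, group is the teosinte population or
maize inbred line of origin, and $x_j = 1$ for EH samples (MA is the
reference level, so a positive fold change means higher expression under
EH). The two taxa are always fitted separately: teosinte is outbred, so each
plant enters as its own sample with population as a covariate; maize inbred
replicates are biological replicates with line as the covariate. Both
reduce to the same model matrix.

This is an intentionally *simplified* NB engine:

* **Size factors** are plain median-of-ratios: the per-sample median of
  $K_{gj} / (\prod_{j'} K_{gj'})^{1/n}$ over genes with no zero count,
  rescaled to geometric mean 1. A `pseudo_reference = TRUE` flag computes
  the per-gene geometric mean over positive counts only, for sparse
  matrices where no gene is everywhere nonzero.
* **Dispersions** are method-of-moments on normalized counts:
  $\hat\alpha_g = \max\{(s^2_g - \bar m_g)/\bar m_g^2,\ 10^{-8}\}$, with the
  variance pooled within group × condition cells and $\bar m_g$ the grand
  mean. There is no shrinkage by default; an optional log-linear
  mean–dispersion trend (50/50 shrinkage in log space) exists but is off.
* **Testing** is a Wald test on $\beta_{\text{env}}$ from a Fisher-scoring
  IRLS fit with the dispersion held fixed (at most 100 iterations,
  convergence when no coefficient moves by more than $10^{-8}$), with a
  two-sided normal p-value. Genes with all-zero counts, or non-converging
  fits, are reported with missing p.

Numeric parity with full-featured DE tools (fold-change shrinkage,
independent filtering, outlier replacement) is an explicit non-goal; the
engine is validated instead against known generators: type-I error within
[0.03, 0.07] and approximately uniform null p-values at 2,000 null genes,
and recovery of a planted $\mathrm{lfc} = 2$ within ±15%.

**Small-sample caveat.** The Wald p-value is asymptotic. At the real
experiment's replication (6–12 samples per condition) it is mildly
anti-conservative (empirically ~7–8% rejections at nominal 5% with 2 × 6
samples); the calibration suite therefore uses 2 × 12 samples, where the
approximation holds. Users analyzing very small designs should prefer the
stricter FDR threshold (0.01) the pipeline exposes — the same mitigation
the original study used against its pseudo-replication.

## Multiple testing

`adjust_pvalues()` implements the BH and BY step-up rules directly (rather
than wrapping `p.adjust`) because missing p-values must be excluded from the
number of tests $m$ and returned missing. BY multiplies the BH adjustment by
$c(m) = \sum_{i=1}^m 1/i$.

## Flowering-gene filter

`remove_flagged_genes()` removes a user-supplied list of
developmental-stage markers from both DE tables and reports how many of
them were significant in only maize, only teosinte, or both — the two taxa
differ in developmental timing, so stage-sensitive genes would otherwise
masquerade as plasticity differences.

# Classification

The gene universe is the **intersection** of genes testable (non-missing
adjusted p) in both taxa. The union would let a gene be called
"taxon-specific" merely because it was never tested in the other taxon;
"specific" here must mean *tested and null* in the other taxon. At FDR
threshold $\alpha$ (default 0.05):

| category | rule |
|---|---|
| `non_DE` | significant in neither taxon |
| `maize_specific` / `teosinte_specific` | significant in exactly that taxon |
| `shared_same` | significant in both, $\mathrm{sign}(\text{lfc}_m)\cdot\mathrm{sign}(\text{lfc}_t) > 0$ |
| `shared_opposite` | significant in both, sign product $< 0$ |

A shared gene with a fold change of exactly zero in one taxon (a
measure-zero event possible only with degenerate inputs) is assigned
`shared_same` with a warning. Teosinte-specific genes are the assimilation
candidates; `refine_assimilation_candidates()` intersects them with a
selection-candidate set and then with a fixed-regulatory-difference set,
mirroring the candidate-refinement logic used on real evidence lists.

# Set statistics

`resample_enrichment()` draws `n_resamples` (default 10,000) uniform
subsets of the background matched to the candidate-set size and reports
empirical tail probabilities with the +1 pseudocount,
$p = (1 + \#\{\text{null} \ge k\})/(R + 1)$, so the smallest reportable p is
$1/(R+1) < 10^{-4}$ at the default — a permutation p of exactly zero is
never printed. The analytic counterpart `hypergeometric_overlap_p()` is kept
as an independent oracle; the suite checks agreement within ±0.02 at 10,000
resamples. The "independence" test between the two taxa's DE sets is
realized as resampling the maize DE set against the teosinte DE set over the
shared tested universe — the null construction the resampling machinery
implies.

`term_enrichment()` runs a two-sided Fisher exact test (the conditional
minimum-likelihood rule of `fisher.test`, which is oracle-checkable by
enumeration over the hypergeometric support) per annotation term, after
removing genes without terms from both the set and the background and
skipping terms with fewer than 5 background genes; adjustment is BY, chosen
for its validity under the strong dependence among overlapping terms. A term
annotating every background gene is reported with odds ratio 1 and p 1.

# Co-expression networks

Networks are built per taxon on the **EH samples** (the reference
environment) and preservation is scored on the MA samples. Steps and
defaults:

1. **Filter**: keep genes with ≥ 1 nonzero count in every taxon × condition
   group.
2. **Transform**: $\log_2(K_{gj}/s_j + 1)$ — monotone, zero-preserving, and
   variance-flattening; a pragmatic stand-in for a full variance-stabilizing
   transform, adequate for correlation-based networks.
3. **Adjacency**: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (unsigned
   default — the convention of the standard tooling when not stated
   otherwise; a signed option $((1+\mathrm{cor})/2)^\beta$ exists).
   `pick_soft_power()` chooses the smallest $\beta$ whose connectivity
   distribution satisfies the scale-free criterion ($R^2 \ge 0.8$ of
   $\log_{10}$ frequency vs $\log_{10}$ binned connectivity, 10 equal-width
   bins), falling back to the largest candidate with a warning.
4. **TOM**: $\mathrm{TOM}_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) /
   (\min(k_i, k_j) + 1 - a_{ij})$, unit diagonal; clustering dissimilarity
   is $1 - \mathrm{TOM}$.
5. **Modules**: average-linkage hierarchical clustering with a **static cut
   at the 0.99 quantile of merge heights** plus a minimum module size
   (default 30). This deliberately simplifies the dynamic-hybrid tree cut;
   module *counts* on real data are therefore not reproduction targets.
   Eigengenes are the first principal component of the standardized module
   expression, unit norm, sign-oriented to correlate positively with the
   module mean. Modules whose eigengenes are closer than 0.25 in
   correlation dissimilarity merge iteratively, closest pair first.
6. **Preservation**: per module, a density statistic (mean intramodular
   adjacency in the test network) and a connectivity statistic (correlation
   between reference and test intramodular connectivity, paired by gene),
   each standardized against `n_permutations` (default 200) random gene
   sets of matched size; for a random set the connectivity pairing is
   arbitrary, which makes the null a label-permutation null with mean ≈ 0.
   $Z_{\text{summary}}$ is the mean of the two Z's, classed by the
   conventional bands: $< 2$ none, $2$–$10$ moderate, $> 10$ high. The
   published method reports a larger battery of statistics; this two-part
   composite is an interpretation, flagged as such, and is validated by the
   planted contrast (noisy copy $\Rightarrow Z > 10$; gene labels permuted
   $\Rightarrow Z < 2$, across five seeds).
7. **Hubs**: genes ranked by intramodular connectivity, ties broken
   lexicographically for determinism.

# Variability comparisons

`gene_cv()` uses the sample (n−1) standard deviation over panel lines
(convention not dictated by any source; recorded here). Zero-mean genes
are returned missing and dropped from comparisons. `mann_whitney_u()`
computes U with midranks; for $n_1 + n_2 \le 10$ the two-sided p comes from
exact enumeration over all $\binom{n}{n_1}$ rank assignments, otherwise from
the normal approximation with tie-corrected variance and continuity
correction (the two branches agree within 0.02 at the boundary).
`compare_categories()` reports medians, IQRs and the figure-style
significance codes (** < 0.01, *** < 0.001); no multiple-testing correction
is applied across the handful of category pairs, matching the starred
box-plot presentation it emulates.

# Synthetic data: the stated world

`simulate_experiment()` draws
$K_{gj} \sim \mathrm{NB}\!\left(\ell_j\, m_g\, 2^{x_j \lambda_g + \pi_{g,\text{group}(j)}},\ \alpha_g\right)$
with library-size factors $\ell_j \sim U(0.7, 1.3)$, log-normal baselines
$m_g$ (meanlog $\log 200$, sdlog 1), log-normal dispersions $\alpha_g$
(meanlog $\log 0.1$, sdlog 0.5), i.i.d. normal gene × group offsets
$\pi$ (sd 0.1 log₂ units), and planted responses $\lambda_g$ whose absolute
value is $|N(1.5, 0.5)|$ with random sign for responsive genes.

* **Design default** mirrors the real experiment: 4 teosinte populations ×
  3 plants and 4 maize inbreds × 2 replicates, 2 environments, one teosinte
  MA sample missing — 39 samples. Every dimension is configurable because
  recovery tests need more replication than the real n provides.
* **Category proportions** are anchored to the published counts — 1,021
  shared and 3,953 / 3,355 total DE genes — over the 29,611 genes expressed
  in both taxa (the only both-taxa universe the source text prints). The
  shared set splits 80/20 into same/opposite direction; the source states
  only that the majority move in the same direction, so the 80% is a free
  parameter of this package, not a published claim. Effect-size magnitudes
  are likewise free parameters (the source reports none).
* **Annotations** (`simulate_annotations()`): named gene sets drawn without
  replacement with per-category odds weights; a term map with
  Poisson-distributed terms per gene; per-gene diversity for both taxa as
  log-normals with a taxon-wide median reduction (default 0.7 for maize,
  emulating the domestication bottleneck).
* **Panel** (`simulate_panel()`): per-gene log-normal expression over lines
  with category-dependent log-sd, so the coefficient of variation has the
  closed form $\sqrt{e^{\sigma^2} - 1}$. Defaults order the categories
  teosinte-specific < maize-specific < non-DE in variability, the direction
  the comparison layer is expected to recover.

**What a green test establishes — and what it does not.** The generator
produces exactly the distributional family the DE model assumes (NB with
per-gene dispersion, multiplicative library sizes, additive log-scale group
effects). Green recovery tests therefore establish internal correctness of
the machinery, not robustness to the ways real RNA-seq violates the model:
no GC or length bias, no correlated genes outside planted modules, no
outlier samples, no batch structure confounded with environment, no
mapping ambiguity. Published genome-scale numbers (DE totals, module counts
35/52, soft powers 24/10, preservation fractions, specific enrichment
p-values, the 83/6 candidate counts) depend on raw reads and external
evidence lists and are out of reach of this synthetic world; tests that
reference such counts (e.g. the 5/7/3 flowering-filter split or the 83/6
refinement) do so on constructed fixtures that plant those intersections.

**Seeding.** Every top-level operation takes one seed and splits it into
per-subtask child seeds via a seeded draw from the integer range, so whole
runs are byte-reproducible from one integer while stages stay independent;
callers' RNG state is always restored.

# Numerical and degenerate-input choices

* IRLS linear predictors are clamped to ±30 to avoid overflow before
  convergence; dispersions are floored at $10^{-8}$.
* Zero-variance genes are dropped from networks with a warning; an
  all-constant expression matrix is an error.
* A module smaller than 3 genes is skipped in preservation with a warning;
  fewer genes than `min_module_size` leaves everything unassigned.
* An annotation set equal to the background yields a forced overlap and
  `p_enrich = 1`; a null sd of zero reports a missing z-score.
* Empty gene-set files warn and yield empty sets; genes outside the
  background are dropped from candidates with a warning.
* Pipeline configs are JSON — the one nested plain-text format with a
  parser in the package's dependency footprint.

# Known limitations

* The dynamic tree cut is approximated by a static quantile cut; module
  granularity on real data will differ from the full algorithm.
* The preservation composite uses two statistics, not the published
  battery of seven; band placement at the 2/10 thresholds is nonetheless
  the standard convention.
* Wald inference is anti-conservative below ~10 samples per condition (see
  above).
* The Fisher/BY term enrichment treats the term map as flat; no ontology
  graph propagation is performed.
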