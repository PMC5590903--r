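# plastizea

Tools for asking whether gene-expression **plasticity** in a wild ancestor
became **genetically assimilated** (canalized) in its domesticate. The
motivating system is maize (*Zea mays* ssp. *mays*) and its wild ancestor
teosinte (*Zea mays* ssp. *parviglumis*) grown under two controlled
environments — an Early Holocene (EH) chamber (low temperature and CO₂) and a
Modern Ambient (MA) control. Genes that respond to the environment in
teosinte but not in maize are the assimilation candidates: plastic in the
ancestor, invariant in the crop.

The package implements the full comparative pipeline downstream of the
count matrices:

- **Differential expression** per taxon between EH and MA with a
  negative-binomial log-link GLM (`~ group + condition`), median-of-ratios
  size factors, method-of-moments dispersions, Wald tests, and BH/BY FDR
  control. The model for gene *g*, sample *j* is
  `K_gj ~ NB(mu_gj, alpha_g)` with
  `log mu_gj = log s_j + beta_0 + beta_group(j) + beta_env * x_j`,
  where `x_j = 1` under EH; the reported `lfc` is `beta_env / log 2`.
- **Cross-taxon classification** of every gene testable in both taxa into
  {non_DE, maize_specific, teosinte_specific, shared_same, shared_opposite},
  plus refinement of assimilation candidates against external evidence sets
  (selection scans, fixed regulatory differences).
- **Set statistics**: Monte-Carlo resampling overlap enrichment
  (`p = (1 + #{null ≥ k}) / (R + 1)`, default R = 10,000) with an exact
  hypergeometric oracle, and Fisher-exact term enrichment with the
  Benjamini–Yekutieli correction.
- **Co-expression networks**: soft-power adjacency `|cor|^β`, topological
  overlap (TOM), average-linkage module detection with eigengene merging at
  dissimilarity 0.25, permutation-based cross-environment module
  preservation (`Zsummary` with the standard <2 / 2–10 / >10 bands), and
  hub-gene ranking.
- **Variability**: per-gene coefficient of variation across an inbred-line
  panel and Mann-Whitney comparisons of any per-gene statistic across
  response categories (codes ** < 0.01, *** < 0.001).
- **A synthetic-data generator** that plants known response categories in NB
  counts for the two-taxon, two-environment design (plus annotation sets,
  a line panel, and diversity tables), so every stage can be tested against
  ground truth.

## Worked example

```r
library(plastizea)

sim <- simulate_experiment(sim_config(n_genes = 2000, seed = 42))
de <- lapply(c("maize", "teosinte"), function(taxon) {
  counts <- sim$counts[[taxon]]; design <- sim$designs[[taxon]]
  sf   <- estimate_size_factors(counts, pseudo_reference = TRUE)
  disp <- estimate_dispersions(counts, design, sf)
  add_adjusted_pvalues(test_condition_effect(counts, design, sf, disp))
})
cats <- classify_genes(de[[1]], de[[2]], alpha = 0.05)
category_counts(cats)
#>            non_DE    maize_specific teosinte_specific       shared_same
#>              1546               212               172                55
#>   shared_opposite
#>                15

ts  <- cats$gene_id[cats$category == "teosinte_specific"]
ann <- simulate_annotations(sim$truth,
  enrichment_spec = list(selection = list(size = 100,
                                          odds = c(teosinte_specific = 3))),
  seed = 43)
resample_enrichment(ts, ann$sets$sets$selection, cats$gene_id,
                    n_resamples = 10000, seed = 44)
#> overlap k = 23 (candidate 172, annotation 100, background 2000)
#> null: mean 8.55, sd 2.71 over 10000 resamples; z = 5.32
#> p_enrich = 9.999e-05, p_deplete = 1
```

The classification recovers the planted structure (the generator planted
~10% maize-responsive and ~8% teosinte-responsive genes), and the
teosinte-specific candidates are correctly detected as enriched (z = 5.3) in
the "selection" set that was simulated with 3:1 odds in their favor; the
empirical p bottoms out at its floor `1/(R+1) < 1e-4`.

The whole pipeline can also be driven from one configuration:

```r
cfg <- pipeline_config(simulate = list(n_genes = 1000),
                       output_dir = "run1", seed = 1)
report <- run_pipeline(cfg)        # writes TSVs + report.json under run1/
```

or from the command line via `inst/cli/plastizea.R`
(`Rscript plastizea.R run-all --config cfg.json --seed 1 --out run1`).

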