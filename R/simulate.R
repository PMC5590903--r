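# Synthetic-data generator: NB count matrices for two taxa x two environments
# with planted condition-response categories, plus annotation sets, a
# many-line panel matrix and per-gene diversity tables, all with ground truth.

#' Build a simulation configuration
#'
#' Defaults emulate the real experimental design: four teosinte populations
#' with three plants each and four maize inbreds with two replicates each,
#' grown in two environments (Early Holocene, EH, and Modern Ambient, MA),
#' with one teosinte MA sample missing (39 samples total). Category default
#' proportions are anchored to the published counts (1,021 shared, 3,953
#' maize, 3,355 teosinte DE genes out of 29,611 genes expressed in both taxa)
#' and rescaled to `n_genes`.
#'
#' @param n_genes number of genes to simulate.
#' @param category_proportions named fractions for the five response
#'   categories; must sum to at most 1 + 1e-8 (any shortfall goes to
#'   `non_DE`).
#' @param lfc_distribution list(mean, sd) of the absolute log2 fold change of
#'   responsive genes (log2 units).
#' @param baseline_mean_distribution list(meanlog, sdlog) of the log-normal
#'   baseline mean count.
#' @param dispersion_distribution list(meanlog, sdlog) of the log-normal NB
#'   dispersion alpha (variance = mu + alpha * mu^2).
#' @param population_effect_sd sd of i.i.d. normal gene x group offsets, in
#'   log2 units.
#' @param design_spec per-taxon list with `n_groups`, `n_reps`,
#'   `environments`, and `drop_samples` (sample ids absent from the design).
#' @param library_size_range range of uniform multiplicative library-size
#'   factors.
#' @param seed integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       category_proportions = NULL,
                       lfc_distribution = list(mean = 1.5, sd = 0.5),
                       baseline_mean_distribution = list(meanlog = log(200),
                                                         sdlog = 1),
                       dispersion_distribution = list(meanlog = log(0.1),
                                                      sdlog = 0.5),
                       population_effect_sd = 0.1,
                       design_spec = default_design_spec(),
                       library_size_range = c(0.7, 1.3),
                       seed = 1L) {
  if (is.null(category_proportions)) {
    category_proportions <- default_category_proportions()
  }
  cp <- category_proportions
  if (!all(names(cp) %in% GENE_CATEGORIES)) {
    stop_pz("unknown category in proportions: %s",
            paste(setdiff(names(cp), GENE_CATEGORIES), collapse = ", "))
  }
  full <- setNames(numeric(length(GENE_CATEGORIES)), GENE_CATEGORIES)
  full[names(cp)] <- cp
  de_sum <- sum(full[setdiff(GENE_CATEGORIES, "non_DE")])
  if (any(full < 0) || de_sum > 1 + 1e-8) {
    stop_pz("category proportions must be nonnegative and sum to <= 1")
  }
  full["non_DE"] <- 1 - de_sum
  if (n_genes < 1) stop_pz("n_genes must be positive")
  sds <- c(lfc_distribution$sd, baseline_mean_distribution$sdlog,
           dispersion_distribution$sdlog, population_effect_sd)
  if (any(sds < 0)) stop_pz("all sds must be >= 0")
  if (length(design_spec) == 0) stop_pz("design_spec must name >= 1 taxon")
  cfg <- list(n_genes = as.integer(n_genes),
              category_proportions = full,
              lfc_distribution = lfc_distribution,
              baseline_mean_distribution = baseline_mean_distribution,
              dispersion_distribution = dispersion_distribution,
              population_effect_sd = population_effect_sd,
              design_spec = design_spec,
              library_size_range = library_size_range,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default response-category proportions
#'
#' Derived from the published counts: 1,021 shared and 3,953 / 3,355 total DE
#' genes in maize / teosinte, over the 29,611 genes expressed in both taxa.
#' The shared set is split 80/20 into same/opposite direction (the source
#' reports only that the majority of shared genes move in the same direction).
#' @export
default_category_proportions <- function() {
  universe <- 29611
  shared <- 1021 / universe
  c(maize_specific = (3953 - 1021) / universe,
    teosinte_specific = (3355 - 1021) / universe,
    shared_same = 0.8 * shared,
    shared_opposite = 0.2 * shared)
}

#' Default two-taxon design: 4 teosinte populations x 3 plants, 4 maize
#' inbreds x 2 replicates, 2 environments, one teosinte MA sample missing.
#' @export
default_design_spec <- function() {
  list(teosinte = list(n_groups = 4, n_reps = 3,
                       environments = c("EH", "MA"),
                       drop_samples = "teosinte_g4_r3_MA"),
       maize = list(n_groups = 4, n_reps = 2,
                    environments = c("EH", "MA"),
                    drop_samples = character(0)))
}

build_design <- function(taxon, spec) {
  grid <- expand.grid(rep = seq_len(spec$n_reps),
                      group = seq_len(spec$n_groups),
                      condition = spec$environments,
                      stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("%s_g%d_r%d_%s", taxon, grid$group, grid$rep,
                        grid$condition),
    taxon = taxon,
    group = sprintf("%s_g%d", taxon, grid$group),
    condition = grid$condition,
    stringsAsFactors = FALSE)
  design <- design[!design$sample_id %in% (spec$drop_samples %||% character(0)), ]
  rownames(design) <- NULL
  for (cond in spec$environments) {
    tab <- table(design$group[design$condition == cond])
    # >= 2 samples per taxon per environment overall; per-group cells may be 1
    if (sum(design$condition == cond) < 2) {
      stop_pz("design for %s has < 2 samples in condition %s", taxon, cond)
    }
    if (length(tab) == 0) stop_pz("empty design cell for %s/%s", taxon, cond)
  }
  design
}

draw_signed_lfc <- function(n, dist) {
  mag <- abs(stats::rnorm(n, dist$mean, dist$sd))
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate a two-taxon count experiment with planted response categories
#'
#' Counts are drawn NB with mean
#' `libsize_j * base_mean_g * 2^(x_j * lfc + pop_effect)` where `x_j` is 1
#' for EH samples and 0 for MA, and dispersion `alpha_g` (variance
#' `mu + alpha * mu^2`). Category semantics: `maize_specific` genes respond
#' only in maize, `teosinte_specific` only in teosinte, `shared_same` in both
#' with the same sign, `shared_opposite` with opposite signs, `non_DE` in
#' neither.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (named list of gene x sample integer matrices,
#'   one per taxon), `designs` (matching sample-design data.frames), and
#'   `truth` (data.frame: gene_id, category, lfc_maize, lfc_teosinte,
#'   base_mean, dispersion).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) stop_pz("config must be a sim_config")
  seeds <- derive_seeds(config$seed, 2L + length(config$design_spec))
  n <- config$n_genes

  truth <- with_seed(seeds[1], {
    counts_per_cat <- floor(config$category_proportions * n)
    counts_per_cat["non_DE"] <- n - sum(counts_per_cat[names(counts_per_cat)
                                                       != "non_DE"])
    category <- rep(names(counts_per_cat), counts_per_cat)
    category <- sample(category)          # shuffle gene order
    lfc_maize <- numeric(n)
    lfc_teosinte <- numeric(n)
    ld <- config$lfc_distribution
    i <- category == "maize_specific"
    lfc_maize[i] <- draw_signed_lfc(sum(i), ld)
    i <- category == "teosinte_specific"
    lfc_teosinte[i] <- draw_signed_lfc(sum(i), ld)
    i <- category == "shared_same"
    lfc_maize[i] <- draw_signed_lfc(sum(i), ld)
    lfc_teosinte[i] <- sign(lfc_maize[i]) * abs(stats::rnorm(sum(i), ld$mean, ld$sd))
    i <- category == "shared_opposite"
    lfc_maize[i] <- draw_signed_lfc(sum(i), ld)
    lfc_teosinte[i] <- -sign(lfc_maize[i]) * abs(stats::rnorm(sum(i), ld$mean, ld$sd))
    bd <- config$baseline_mean_distribution
    dd <- config$dispersion_distribution
    data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
               category = category,
               lfc_maize = lfc_maize,
               lfc_teosinte = lfc_teosinte,
               base_mean = stats::rlnorm(n, bd$meanlog, bd$sdlog),
               dispersion = stats::rlnorm(n, dd$meanlog, dd$sdlog),
               stringsAsFactors = FALSE)
  })

  counts <- list()
  designs <- list()
  taxa <- names(config$design_spec)
  for (t in seq_along(taxa)) {
    taxon <- taxa[t]
    design <- build_design(taxon, config$design_spec[[taxon]])
    lfc <- switch(taxon, maize = truth$lfc_maize,
                  teosinte = truth$lfc_teosinte,
                  truth[[paste0("lfc_", taxon)]] %||% numeric(n))
    mat <- with_seed(seeds[2L + t], {
      nsamp <- nrow(design)
      libsize <- stats::runif(nsamp, config$library_size_range[1],
                              config$library_size_range[2])
      groups <- unique(design$group)
      pop_eff <- matrix(stats::rnorm(n * length(groups), 0,
                                     config$population_effect_sd),
                        nrow = n, dimnames = list(NULL, groups))
      x <- as.numeric(design$condition == "EH")
      m <- matrix(0L, nrow = n, ncol = nsamp,
                  dimnames = list(truth$gene_id, design$sample_id))
      for (j in seq_len(nsamp)) {
        mu <- libsize[j] * truth$base_mean *
          2^(x[j] * lfc + pop_eff[, design$group[j]])
        size <- 1 / pmax(truth$dispersion, 1e-12)
        m[, j] <- stats::rnbinom(n, mu = mu, size = size)
      }
      m
    })
    counts[[taxon]] <- mat
    designs[[taxon]] <- design
  }
  list(counts = counts, designs = designs, truth = truth)
}

#' Simulate annotation sets, a gene-to-term map and per-gene diversity
#'
#' Stands in for external evidence resources: selection-candidate and
#' regulatory-divergence gene lists (with configurable enrichment in given
#' response categories), a term annotation map, and a per-gene nucleotide
#' diversity table for both taxa with a taxon-wide reduction (emulating the
#' maize domestication bottleneck).
#'
#' @param truth truth table from [simulate_experiment()].
#' @param enrichment_spec named list; each element is
#'   `list(size = n, odds = c(category = odds, ...))`. Genes are sampled
#'   without replacement with weight `odds[category]` (default 1).
#' @param seed integer seed.
#' @param n_terms number of distinct annotation terms.
#' @param terms_per_gene Poisson mean of terms assigned per gene.
#' @param diversity_reduction multiplicative factor applied to the reduced
#'   taxon's diversity scale (median maize / median teosinte).
#' @param reduced_taxon taxon whose diversity is reduced.
#' @return list with `sets` (a gene-set collection), `term_map`
#'   (data.frame gene_id, term), and `diversity` (data.frame gene_id,
#'   maize, teosinte).
#' @export
simulate_annotations <- function(truth, enrichment_spec, seed = 1L,
                                 n_terms = 50, terms_per_gene = 2,
                                 diversity_reduction = 0.7,
                                 reduced_taxon = "maize") {
  seeds <- derive_seeds(seed, 3L)
  genes <- truth$gene_id
  n <- length(genes)

  sets <- with_seed(seeds[1], {
    out <- list()
    for (name in names(enrichment_spec)) {
      spec <- enrichment_spec[[name]]
      if (spec$size > n) {
        stop_pz("set '%s' of size %d exceeds the %d-gene pool",
                name, spec$size, n)
      }
      odds <- setNames(rep(1, length(GENE_CATEGORIES)), GENE_CATEGORIES)
      if (!is.null(spec$odds)) odds[names(spec$odds)] <- spec$odds
      w <- odds[truth$category]
      eligible <- sum(w > 0)
      if (spec$size > eligible) {
        stop_pz("set '%s' of size %d exceeds the eligible pool of %d genes",
                name, spec$size, eligible)
      }
      out[[name]] <- sample(genes, spec$size, prob = w)
    }
    out
  })

  term_map <- with_seed(seeds[2], {
    terms <- sprintf("TERM:%04d", seq_len(n_terms))
    k <- stats::rpois(n, terms_per_gene)
    gene_rep <- rep(genes, k)
    data.frame(gene_id = gene_rep,
               term = sample(terms, length(gene_rep), replace = TRUE),
               stringsAsFactors = FALSE)
  })

  diversity <- with_seed(seeds[3], {
    base_meanlog <- log(0.01)   # typical per-gene pairwise diversity scale
    sdlog <- 0.5
    teo <- stats::rlnorm(n, base_meanlog, sdlog)
    red <- stats::rlnorm(n, base_meanlog + log(diversity_reduction), sdlog)
    d <- data.frame(gene_id = genes, maize = teo, teosinte = teo,
                    stringsAsFactors = FALSE)
    d[[reduced_taxon]] <- red
    other <- setdiff(c("maize", "teosinte"), reduced_taxon)
    d[[other]] <- teo
    d
  })

  list(sets = gene_set_collection(sets, background = genes),
       term_map = term_map, diversity = diversity)
}

#' Simulate a gene x inbred-line expression panel
#'
#' Per-gene expression across a large panel of lines is log-normal around the
#' gene's baseline mean, with a category-dependent log-scale sd controlling
#' the coefficient of variation (CV of a log-normal with log-sd sigma is
#' `sqrt(exp(sigma^2) - 1)`). Defaults make taxon-specific DE genes less
#' variable than non-DE genes, with teosinte-specific the least variable.
#'
#' @param truth truth table from [simulate_experiment()].
#' @param n_lines number of panel lines (default mirrors the 503-line panel).
#' @param variance_spec named numeric: per-category log-scale sd.
#' @param seed integer seed.
#' @return numeric matrix genes x lines, strictly positive (unless a
#'   category's scale is 0, in which case its genes are constant).
#' @export
simulate_panel <- function(truth, n_lines = 503,
                           variance_spec = c(non_DE = 0.6,
                                             maize_specific = 0.45,
                                             teosinte_specific = 0.35,
                                             shared_same = 0.5,
                                             shared_opposite = 0.5),
                           seed = 1L) {
  if (n_lines < 2) stop_pz("n_lines must be >= 2")
  miss <- setdiff(unique(truth$category), names(variance_spec))
  if (length(miss)) stop_pz("variance_spec missing categories: %s",
                            paste(miss, collapse = ", "))
  with_seed(seed, {
    n <- nrow(truth)
    sigma <- variance_spec[truth$category]
    m <- matrix(stats::rlnorm(n * n_lines,
                              meanlog = rep(log(truth$base_mean), n_lines),
                              sdlog = rep(sigma, n_lines)),
                nrow = n,
                dimnames = list(truth$gene_id,
                                sprintf("line%04d", seq_len(n_lines))))
    m
  })
}
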