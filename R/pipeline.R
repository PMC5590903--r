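# End-to-end orchestration: simulate (or load) -> differential expression ->
# classification -> set statistics -> co-expression -> variability, from one
# configuration with a single master seed and a machine-readable JSON report.

#' Build a pipeline configuration
#'
#' Either a `simulate` block (arguments to [sim_config()], plus annotation
#' and panel settings) or an `inputs` block (paths to count/design tables and
#' optional gene sets, term map, panel and diversity tables) must be present.
#'
#' @param simulate list of [sim_config()] arguments, or `NULL`.
#' @param inputs named list of file paths (`counts_maize`, `design_maize`,
#'   `counts_teosinte`, `design_teosinte`, optional `gene_sets`, `term_map`,
#'   `flag_genes`, `panel`, `diversity`), or `NULL`.
#' @param alpha_fdr FDR threshold for DE and classification (0.05 default,
#'   0.01 as the stringent alternative).
#' @param adjust_method "BH" or "BY" for the DE adjustment.
#' @param n_resamples Monte-Carlo resamples for overlap enrichment.
#' @param network a [network_params()].
#' @param stages named logicals enabling `de`, `classify`, `enrich`,
#'   `coexpress`, `variability`.
#' @param output_dir where tables and the report are written.
#' @param seed master seed; mandatory, split deterministically per stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            alpha_fdr = 0.05, adjust_method = "BH",
                            n_resamples = 10000,
                            network = network_params(),
                            stages = c(de = TRUE, classify = TRUE,
                                       enrich = TRUE, coexpress = TRUE,
                                       variability = TRUE),
                            output_dir = tempfile("plastizea_run_"),
                            seed = 1L) {
  if (is.null(simulate) && is.null(inputs)) {
    stop_pz("either a simulate block or an inputs block is required")
  }
  if (is.null(seed)) stop_pz("seed is mandatory")
  defaults <- c(de = TRUE, classify = TRUE, enrich = TRUE, coexpress = TRUE,
                variability = TRUE)
  defaults[names(stages)] <- stages
  structure(list(simulate = simulate, inputs = inputs,
                 alpha_fdr = alpha_fdr, adjust_method = adjust_method,
                 n_resamples = n_resamples, network = network,
                 stages = defaults, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Nested key/value text: top-level keys mirror the arguments of
#' [pipeline_config()]; the `network` block holds [network_params()]
#' arguments and `simulate` holds [sim_config()] arguments.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- do.call(network_params, as.list(raw$network %||% list()))
  stages <- unlist(raw$stages %||% list())
  if (is.null(stages)) stages <- c(de = TRUE)
  pipeline_config(simulate = raw$simulate,
                  inputs = raw$inputs,
                  alpha_fdr = raw$alpha_fdr %||% 0.05,
                  adjust_method = raw$adjust_method %||% "BH",
                  n_resamples = raw$n_resamples %||% 10000,
                  network = net,
                  stages = stages,
                  output_dir = raw$output_dir %||% tempfile("plastizea_run_"),
                  seed = raw$seed %||% stop_pz("config must set a seed"))
}

log_info <- function(verbose, ...) {
  if (verbose) message(sprintf("[plastizea] %s", sprintf(...)))
}

load_pipeline_inputs <- function(config, seeds, verbose) {
  if (!is.null(config$inputs)) {
    ip <- config$inputs
    counts <- list(maize = read_count_table(ip$counts_maize),
                   teosinte = read_count_table(ip$counts_teosinte))
    designs <- list(maize = read_sample_design(ip$design_maize),
                    teosinte = read_sample_design(ip$design_teosinte))
    truth <- NULL
    background <- intersect(rownames(counts$maize), rownames(counts$teosinte))
    sets <- if (!is.null(ip$gene_sets)) {
      read_gene_sets(ip$gene_sets, background)
    } else {
      NULL
    }
    term_map <- if (!is.null(ip$term_map)) read_term_map(ip$term_map)
    flag_genes <- if (!is.null(ip$flag_genes)) {
      readLines(ip$flag_genes, warn = FALSE)
    } else {
      character(0)
    }
    panel <- if (!is.null(ip$panel)) {
      p <- read_count_table(ip$panel)    # integer panel accepted
      storage.mode(p) <- "double"
      p
    }
    diversity <- if (!is.null(ip$diversity)) {
      utils::read.table(ip$diversity, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
    list(counts = counts, designs = designs, truth = truth, sets = sets,
         term_map = term_map, flag_genes = flag_genes, panel = panel,
         diversity = diversity)
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- seeds["simulate"]
    cfg <- do.call(sim_config, sim_args)
    log_info(verbose, "simulating %d genes", cfg$n_genes)
    sim <- simulate_experiment(cfg)
    n <- cfg$n_genes
    ann <- simulate_annotations(
      sim$truth,
      enrichment_spec = list(
        selection = list(size = max(20L, round(0.05 * n)),
                         odds = c(teosinte_specific = 3)),
        fixed_regulatory = list(size = max(10L, round(0.01 * n)),
                                odds = c(teosinte_specific = 3))),
      seed = seeds["annotations"])
    panel <- simulate_panel(sim$truth, n_lines = 200, seed = seeds["panel"])
    list(counts = sim$counts, designs = sim$designs, truth = sim$truth,
         sets = ann$sets, term_map = ann$term_map, flag_genes = character(0),
         panel = panel, diversity = ann$diversity)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (classification needs DE;
#' enrichment needs classification), writes every table as TSV under the
#' configured output directory, and writes a JSON run report that, together
#' with the config and seed, fully determines the run.
#'
#' @param config a [pipeline_config()] or a path to a JSON config file.
#' @param verbose emit per-stage progress messages.
#' @return the run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_pz("config must be a pipeline_config or a path to one")
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- setNames(derive_seeds(config$seed, 6),
                    c("simulate", "annotations", "panel", "enrich",
                      "preservation", "spare"))
  report <- list(tool = "plastizea",
                 version = as.character(utils::packageVersion("plastizea")),
                 seed = config$seed,
                 alpha_fdr = config$alpha_fdr,
                 n_resamples = config$n_resamples,
                 stages = as.list(config$stages))

  stage <- "load"
  res <- tryCatch({
    dat <- load_pipeline_inputs(config, seeds, verbose)
    report$inputs <- list(
      fingerprints = lapply(dat$counts, fingerprint),
      n_genes = nrow(dat$counts[[1]]),
      n_samples = vapply(dat$counts, ncol, integer(1)))
    if (!is.null(dat$truth)) {
      utils::write.table(dat$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    de <- NULL
    if (config$stages[["de"]]) {
      stage <- "de"
      de <- list()
      for (taxon in names(dat$counts)) {
        log_info(verbose, "differential expression: %s", taxon)
        counts <- dat$counts[[taxon]]
        design <- dat$designs[[taxon]]
        sf <- estimate_size_factors(counts, pseudo_reference = TRUE)
        disp <- estimate_dispersions(counts, design, sf)
        tab <- test_condition_effect(counts, design, sf, disp)
        tab <- add_adjusted_pvalues(tab, config$adjust_method)
        de[[taxon]] <- tab
      }
      if (length(dat$flag_genes) > 0) {
        filt <- remove_flagged_genes(de$maize, de$teosinte, dat$flag_genes,
                                     config$alpha_fdr)
        de$maize <- filt$de_maize
        de$teosinte <- filt$de_teosinte
        report$flagged_gene_removal <- as.list(filt$removed)
      }
      for (taxon in names(de)) {
        write_de_table(de[[taxon]],
                       file.path(out_dir, sprintf("de_%s.tsv", taxon)))
      }
      report$de <- lapply(de, function(tab) {
        list(n_tested = sum(!is.na(tab$p_adj)),
             n_significant = sum(tab$p_adj < config$alpha_fdr, na.rm = TRUE))
      })
    }

    categories <- NULL
    if (config$stages[["classify"]] && !is.null(de)) {
      stage <- "classify"
      categories <- classify_genes(de$maize, de$teosinte, config$alpha_fdr)
      utils::write.table(categories, file.path(out_dir, "categories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$category_counts <- as.list(category_counts(categories))
      if (!is.null(dat$sets) &&
          all(c("selection", "fixed_regulatory") %in% names(dat$sets$sets))) {
        cand <- refine_assimilation_candidates(
          categories, dat$sets$sets$selection,
          dat$sets$sets$fixed_regulatory)
        report$assimilation_candidates <-
          list(n_selected = cand$n_selected,
               n_selected_fixed = cand$n_selected_fixed)
      }
    }

    if (config$stages[["enrich"]] && !is.null(categories)) {
      stage <- "enrich"
      background <- categories$gene_id
      enrich_seeds <- derive_seeds(seeds["enrich"],
                                   (length(dat$sets$sets) %||% 0) * 4 + 1)
      rows <- list()
      si <- 0
      cats <- c("maize_specific", "teosinte_specific", "shared_same",
                "shared_opposite")
      for (set_name in names(dat$sets$sets)) {
        for (catg in cats) {
          cand <- categories$gene_id[categories$category == catg]
          if (length(cand) == 0) next
          si <- si + 1
          er <- resample_enrichment(cand, dat$sets$sets[[set_name]],
                                    background,
                                    n_resamples = config$n_resamples,
                                    seed = enrich_seeds[si])
          rows[[length(rows) + 1]] <- data.frame(
            candidate = catg, annotation = set_name, k = er$k,
            candidate_size = er$candidate_size,
            annotation_size = er$annotation_size,
            null_mean = er$null_mean, null_sd = er$null_sd,
            z_score = er$z_score, p_enrich = er$p_enrich,
            p_deplete = er$p_deplete, stringsAsFactors = FALSE)
        }
      }
      # cross-taxon DE independence test: maize DE overlap with teosinte DE
      de_m <- categories$gene_id[categories$category %in%
                                   c("maize_specific", "shared_same",
                                     "shared_opposite")]
      de_t <- categories$gene_id[categories$category %in%
                                   c("teosinte_specific", "shared_same",
                                     "shared_opposite")]
      if (length(de_m) > 0 && length(de_t) > 0) {
        er <- resample_enrichment(de_m, de_t, background,
                                  n_resamples = config$n_resamples,
                                  seed = enrich_seeds[length(enrich_seeds)])
        rows[[length(rows) + 1]] <- data.frame(
          candidate = "maize_DE", annotation = "teosinte_DE", k = er$k,
          candidate_size = er$candidate_size,
          annotation_size = er$annotation_size,
          null_mean = er$null_mean, null_sd = er$null_sd,
          z_score = er$z_score, p_enrich = er$p_enrich,
          p_deplete = er$p_deplete, stringsAsFactors = FALSE)
        report$de_overlap_independence <- list(k = er$k,
                                               p_enrich = er$p_enrich)
      }
      enrichment <- do.call(rbind, rows)
      if (!is.null(enrichment)) {
        utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$enrichment <- lapply(seq_len(nrow(enrichment)), function(i) {
          as.list(enrichment[i, c("candidate", "annotation", "k",
                                  "z_score", "p_enrich", "p_deplete")])
        })
      }
      if (!is.null(dat$term_map)) {
        ts <- categories$gene_id[categories$category == "teosinte_specific"]
        if (length(ts) > 0) {
          terms <- term_enrichment(ts, background, dat$term_map,
                                   alpha = config$alpha_fdr)
          utils::write.table(terms,
                             file.path(out_dir, "term_enrichment.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          report$term_enrichment <- list(n_terms_tested = nrow(terms),
                                         n_significant = sum(terms$significant))
        }
      }
    }

    if (config$stages[["coexpress"]]) {
      stage <- "coexpress"
      keep <- filter_coexpression_genes(dat$counts$maize, dat$counts$teosinte,
                                        dat$designs$maize,
                                        dat$designs$teosinte)
      report$coexpression <- list(n_filtered_genes = length(keep))
      pres_seeds <- derive_seeds(seeds["preservation"],
                                 length(dat$counts))
      for (ti in seq_along(dat$counts)) {
        taxon <- names(dat$counts)[ti]
        log_info(verbose, "co-expression network: %s", taxon)
        counts <- dat$counts[[taxon]][keep, , drop = FALSE]
        design <- dat$designs[[taxon]]
        sf <- estimate_size_factors(counts, pseudo_reference = TRUE)
        expr <- transform_counts(counts, sf)
        eh <- design$sample_id[design$condition == "EH"]
        ma <- design$sample_id[design$condition == "MA"]
        params <- config$network
        params$seed <- pres_seeds[ti]
        net <- build_tom(expr[, eh, drop = FALSE], params)
        mods <- detect_modules(net$dissimilarity,
                               expr[rownames(net$tom), eh, drop = FALSE],
                               params)
        utils::write.table(
          data.frame(gene_id = names(mods$modules), module = mods$modules),
          file.path(out_dir, sprintf("modules_%s.tsv", taxon)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        pres <- module_preservation(expr[rownames(net$tom), eh, drop = FALSE],
                                    expr[rownames(net$tom), ma, drop = FALSE],
                                    mods, params)
        utils::write.table(pres,
                           file.path(out_dir,
                                     sprintf("preservation_%s.tsv", taxon)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        hubs <- hub_genes(net$adjacency, mods)
        utils::write.table(hubs,
                           file.path(out_dir, sprintf("hubs_%s.tsv", taxon)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$coexpression[[taxon]] <- list(
          n_modules = length(unique(mods$modules[mods$modules > 0])),
          preservation = lapply(seq_len(nrow(pres)), function(i) {
            as.list(pres[i, c("module", "size", "Zsummary", "preservation")])
          }))
      }
    }

    if (config$stages[["variability"]] && !is.null(categories) &&
        !is.null(dat$panel)) {
      stage <- "variability"
      cv <- gene_cv(dat$panel)
      utils::write.table(
        data.frame(gene_id = names(cv), cv = cv),
        file.path(out_dir, "cv.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pairs <- list(c("non_DE", "maize_specific"),
                    c("non_DE", "teosinte_specific"),
                    c("maize_specific", "teosinte_specific"))
      cmp <- compare_categories(cv, categories, pairs,
                                statistic_name = "CV")
      utils::write.table(cmp$comparisons,
                         file.path(out_dir, "cv_comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$variability <- list(
        cv = lapply(seq_len(nrow(cmp$comparisons)), function(i) {
          as.list(cmp$comparisons[i, c("category_a", "category_b",
                                       "p_value", "code")])
        }))
      if (!is.null(dat$diversity)) {
        for (taxon in intersect(c("maize", "teosinte"),
                                names(dat$diversity))) {
          dv <- setNames(dat$diversity[[taxon]], dat$diversity$gene_id)
          dcmp <- compare_categories(dv, categories, pairs,
                                     statistic_name =
                                       paste0("diversity_", taxon))
          utils::write.table(
            dcmp$comparisons,
            file.path(out_dir, sprintf("diversity_comparisons_%s.tsv",
                                       taxon)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
        report$variability$diversity_median_ratio <-
          stats::median(dat$diversity$maize) /
          stats::median(dat$diversity$teosinte)
      }
    }

    report
  }, error = function(e) {
    stop_pz("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  write_run_report(res, file.path(out_dir, "report.json"))
  invisible(res)
}
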