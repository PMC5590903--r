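# Cross-taxon response-category classification: each gene tested in both
# taxa is assigned to non_DE / maize_specific / teosinte_specific /
# shared_same / shared_opposite, and teosinte-specific genes (the genetic
# assimilation candidates: plastic in the wild ancestor, invariant in the
# crop) can be refined against external evidence sets.

#' Classify genes into cross-taxon response categories
#'
#' The gene universe is the intersection of genes testable (non-missing
#' adjusted p) in both taxa; genes missing in either taxon are excluded and
#' counted. A gene significant in both taxa is `shared_same` if its log2 fold
#' changes agree in sign and `shared_opposite` otherwise; a zero fold change
#' in one taxon (sign product 0) falls to `shared_same` with a warning.
#'
#' @param de_maize,de_teosinte DE results with `p_adj` filled in.
#' @param alpha FDR threshold in (0, 1).
#' @return data.frame (gene_id, category, lfc_maize, lfc_teosinte,
#'   p_adj_maize, p_adj_teosinte) with attributes `alpha` and `n_excluded`.
#' @export
classify_genes <- function(de_maize, de_teosinte, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop_pz("alpha must be in (0, 1)")
  m <- de_maize[!is.na(de_maize$p_adj), c("gene_id", "lfc", "p_adj")]
  t <- de_teosinte[!is.na(de_teosinte$p_adj), c("gene_id", "lfc", "p_adj")]
  universe <- intersect(m$gene_id, t$gene_id)
  if (length(universe) == 0) stop_pz("no gene testable in both taxa")
  n_excluded <- length(union(de_maize$gene_id, de_teosinte$gene_id)) -
    length(universe)
  mi <- m[match(universe, m$gene_id), ]
  ti <- t[match(universe, t$gene_id), ]
  sig_m <- mi$p_adj < alpha
  sig_t <- ti$p_adj < alpha
  category <- rep("non_DE", length(universe))
  category[sig_m & !sig_t] <- "maize_specific"
  category[!sig_m & sig_t] <- "teosinte_specific"
  shared <- sig_m & sig_t
  sprod <- sign(mi$lfc) * sign(ti$lfc)
  if (any(shared & sprod == 0)) {
    warn_pz("%d shared gene(s) with a zero fold change assigned shared_same",
            sum(shared & sprod == 0))
  }
  category[shared & sprod >= 0] <- "shared_same"
  category[shared & sprod < 0] <- "shared_opposite"
  out <- data.frame(gene_id = universe,
                    category = factor(category, levels = GENE_CATEGORIES),
                    lfc_maize = mi$lfc, lfc_teosinte = ti$lfc,
                    p_adj_maize = mi$p_adj, p_adj_teosinte = ti$p_adj,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("gene_category_table", "data.frame")
  out
}

#' Count genes per response category
#' @param categories a table from [classify_genes()].
#' @return named integer vector over the five categories.
#' @export
category_counts <- function(categories) {
  table(factor(categories$category, levels = GENE_CATEGORIES))
}

#' Refine genetic-assimilation candidates against external evidence
#'
#' Intersects the teosinte-specific DE genes with a set of selection
#' candidates, and that intersection further with a set of genes carrying a
#' fixed regulatory difference, mirroring the candidate-refinement logic used
#' on real evidence lists (selection scans, allele-specific expression).
#'
#' @param categories a table from [classify_genes()].
#' @param selection_set gene ids with evidence of selection.
#' @param fixed_regulatory_set gene ids with a fixed regulatory difference.
#' @return list: `selected` (teosinte-specific and selected), `selected_fixed`
#'   (additionally fixed-regulatory), and their sizes `n_selected`,
#'   `n_selected_fixed`.
#' @export
refine_assimilation_candidates <- function(categories, selection_set,
                                           fixed_regulatory_set) {
  ts <- categories$gene_id[categories$category == "teosinte_specific"]
  selected <- intersect(ts, selection_set)
  selected_fixed <- intersect(selected, fixed_regulatory_set)
  list(selected = selected, selected_fixed = selected_fixed,
       n_selected = length(selected),
       n_selected_fixed = length(selected_fixed))
}
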