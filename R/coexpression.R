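# Weighted co-expression networks: expression filtering, a
# variance-flattening transform, scale-free soft-power selection, adjacency
# and topological overlap matrices, average-linkage module detection with
# eigengene merging, permutation-based cross-environment module preservation
# (Zsummary with the 2/10 bands), and hub-gene ranking. Networks are built on
# the reference environment (EH) and tested on the other (MA).

#' Network construction parameters
#'
#' @param beta soft power (positive integer) applied to correlations.
#' @param network_type "unsigned" (`|cor|^beta`) or "signed"
#'   (`((1 + cor)/2)^beta`).
#' @param min_module_size smallest cluster kept as a module.
#' @param merge_cutoff eigengene-dissimilarity threshold below which modules
#'   are merged (0.25 means modules with eigengene correlation above 0.75
#'   merge).
#' @param cut_height_quantile static dendrogram cut: quantile of merge
#'   heights.
#' @param n_permutations permutations for module preservation.
#' @param seed integer seed (preservation permutations only; detection is
#'   deterministic).
#' @return list of class `network_params`.
#' @export
network_params <- function(beta = 6, network_type = c("unsigned", "signed"),
                           min_module_size = 30, merge_cutoff = 0.25,
                           cut_height_quantile = 0.99, n_permutations = 200,
                           seed = 1L) {
  network_type <- match.arg(network_type)
  if (beta < 1) stop_pz("beta must be >= 1")
  if (!(merge_cutoff > 0 && merge_cutoff < 1)) {
    stop_pz("merge_cutoff must be in (0, 1)")
  }
  structure(list(beta = beta, network_type = network_type,
                 min_module_size = as.integer(min_module_size),
                 merge_cutoff = merge_cutoff,
                 cut_height_quantile = cut_height_quantile,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "network_params")
}

#' Filter to genes expressed in both taxa across both environments
#'
#' A gene is retained iff it has at least one nonzero count in every
#' taxon x condition group; genes silent in any of the four groups are
#' dropped.
#'
#' @param counts_maize,counts_teosinte gene x sample count matrices sharing a
#'   gene-id namespace.
#' @param design_maize,design_teosinte matching sample designs.
#' @return character vector of retained gene ids.
#' @export
filter_coexpression_genes <- function(counts_maize, counts_teosinte,
                                      design_maize, design_teosinte) {
  validate_sample_design(design_maize, counts_maize)
  validate_sample_design(design_teosinte, counts_teosinte)
  genes <- intersect(rownames(counts_maize), rownames(counts_teosinte))
  if (length(genes) == 0) stop_pz("no shared genes between taxa")
  keep <- rep(TRUE, length(genes))
  for (input in list(list(counts_maize, design_maize),
                     list(counts_teosinte, design_teosinte))) {
    counts <- input[[1]][genes, , drop = FALSE]
    design <- input[[2]]
    for (cond in c("EH", "MA")) {
      samp <- design$sample_id[design$condition == cond]
      if (length(samp) == 0) stop_pz("missing condition group %s", cond)
      keep <- keep & rowSums(counts[, samp, drop = FALSE] > 0) >= 1
    }
  }
  genes[keep]
}

#' Variance-flattening count transform
#'
#' `log2(count / size_factor + 1)`: strictly monotone per sample, maps zeros
#' to zero, and flattens the NB mean-variance relationship enough for
#' correlation-based network construction.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors positive per-sample factors.
#' @return numeric matrix, same shape.
#' @export
transform_counts <- function(counts, size_factors) {
  if (any(size_factors <= 0)) stop_pz("size factors must be positive")
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

adjacency_matrix <- function(expr, beta, network_type) {
  v <- apply(expr, 1, stats::var)
  if (all(v == 0)) stop_pz("all genes have constant expression")
  if (any(v == 0)) {
    warn_pz("%d zero-variance gene(s) dropped from the network", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(expr))
  a <- if (network_type == "signed") ((1 + cc) / 2)^beta else abs(cc)^beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  a
}

#' Pick the soft power by the scale-free topology criterion
#'
#' For each candidate power the connectivity distribution is binned
#' (equal-width on k), and `log10(frequency)` is regressed on `log10(mean
#' binned connectivity)`; the model R-squared is the scale-free fit index.
#' Returns the smallest power reaching `r2_threshold`, or the largest
#' candidate with a warning if none does.
#'
#' @param expr gene x sample expression matrix.
#' @param candidate_betas integer powers to evaluate.
#' @param r2_threshold scale-free fit threshold.
#' @param n_bins connectivity histogram bins.
#' @param network_type "unsigned" or "signed".
#' @return list: `beta`, and `fit_table` (beta, r_squared, slope,
#'   mean_connectivity).
#' @export
pick_soft_power <- function(expr, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                            r2_threshold = 0.8, n_bins = 10,
                            network_type = "unsigned") {
  if (length(candidate_betas) < 1) stop_pz("need >= 1 candidate power")
  if (nrow(expr) < n_bins) stop_pz("fewer genes than connectivity bins")
  fits <- lapply(candidate_betas, function(beta) {
    a <- adjacency_matrix(expr, beta, network_type)
    diag(a) <- 0
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins)
    data.frame(beta = beta, r_squared = fit$r_squared, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  fit_table <- do.call(rbind, fits)
  ok <- which(fit_table$r_squared >= r2_threshold)
  if (length(ok) > 0) {
    beta <- fit_table$beta[ok[1]]
  } else {
    beta <- max(candidate_betas)
    warn_pz("no candidate power reached R^2 >= %.2f; using the maximum (%d)",
            r2_threshold, beta)
  }
  list(beta = beta, fit_table = fit_table)
}

# R^2 and slope of log10(freq) ~ log10(mean k) over equal-width bins of k.
scale_free_fit <- function(k, n_bins) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(use) < 3) return(list(r_squared = 0, slope = NA_real_))
  fit <- stats::lm(log10(freq[use]) ~ log10(kmean[use]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}

#' Build adjacency and topological overlap matrices
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (signed:
#' `((1 + cor)/2)^beta`); connectivity `k_i = sum_{j != i} a_ij`; topological
#' overlap
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with unit diagonal. The clustering dissimilarity is `1 - TOM`.
#'
#' @param expr gene x sample expression matrix (>= 3 samples); zero-variance
#'   genes are dropped with a warning.
#' @param params a [network_params()].
#' @return list: `adjacency` (unit diagonal), `tom`, `dissimilarity`.
#' @export
build_tom <- function(expr, params = network_params()) {
  if (ncol(expr) < 3) stop_pz("need >= 3 samples to build a network")
  a <- adjacency_matrix(expr, params$beta, params$network_type)
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  list(adjacency = a, tom = tom, dissimilarity = 1 - tom)
}

module_eigengene <- function(expr_mod) {
  # expr_mod: genes x samples; eigengene = first PC over standardized genes,
  # unit norm, sign-oriented to correlate positively with the module mean.
  z <- t(scale(t(expr_mod)))
  z[is.na(z)] <- 0
  sv <- svd(t(z), nu = 1, nv = 0)
  e <- sv$u[, 1]
  ref <- colMeans(z)
  if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
  e
}

#' Detect co-expression modules by average-linkage clustering
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' static cut at a quantile of the merge heights (a simplification of the
#' dynamic tree cut); clusters below `min_module_size` become unassigned
#' (module 0). Modules whose eigengenes are closer than `merge_cutoff` in
#' correlation dissimilarity are merged iteratively, closest pair first.
#' Detection is fully deterministic.
#'
#' @param dissimilarity square symmetric TOM dissimilarity.
#' @param expr gene x sample expression matrix (same genes), used for
#'   eigengenes.
#' @param params a [network_params()].
#' @return list of class `module_assignment`: `modules` (named integer, 0 =
#'   unassigned), `eigengenes` (samples x modules), `sizes`, `tree`.
#' @export
detect_modules <- function(dissimilarity, expr, params = network_params()) {
  n <- nrow(dissimilarity)
  if (n != nrow(expr)) stop_pz("dissimilarity and expr disagree on genes")
  genes <- rownames(expr) %||% sprintf("g%d", seq_len(n))
  if (n < params$min_module_size) {
    warn_pz("fewer genes (%d) than min_module_size (%d): all unassigned",
            n, params$min_module_size)
    return(structure(list(modules = setNames(rep(0L, n), genes),
                          eigengenes = NULL, sizes = integer(0), tree = NULL),
                     class = "module_assignment"))
  }
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  h <- stats::quantile(tree$height, params$cut_height_quantile)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= params$min_module_size]
  modules <- setNames(rep(0L, n), genes)
  # label modules 1..K by decreasing size
  big <- big[order(-sizes[big])]
  for (i in seq_along(big)) modules[raw == as.integer(big[i])] <- i
  if (all(modules == 0)) {
    warn_pz("no cluster reached min_module_size: all genes unassigned")
    return(structure(list(modules = modules, eigengenes = NULL,
                          sizes = integer(0), tree = tree),
                     class = "module_assignment"))
  }
  merged <- merge_close_modules(modules, expr, params$merge_cutoff)
  eig <- compute_eigengenes(merged, expr)
  structure(list(modules = merged,
                 eigengenes = eig,
                 sizes = table(merged[merged > 0]),
                 tree = tree),
            class = "module_assignment")
}

compute_eigengenes <- function(modules, expr) {
  labs <- sort(unique(modules[modules > 0]))
  if (length(labs) == 0) return(NULL)
  eig <- vapply(labs, function(m) {
    module_eigengene(expr[modules == m, , drop = FALSE])
  }, numeric(ncol(expr)))
  colnames(eig) <- paste0("ME", labs)
  rownames(eig) <- colnames(expr)
  eig
}

merge_close_modules <- function(modules, expr, merge_cutoff) {
  repeat {
    labs <- sort(unique(modules[modules > 0]))
    if (length(labs) < 2) break
    eig <- compute_eigengenes(modules, expr)
    d <- 1 - stats::cor(eig)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (min(d) >= merge_cutoff) break
    keep <- labs[min(idx)]
    drop <- labs[max(idx)]
    modules[modules == drop] <- keep
  }
  # relabel 1..K by decreasing size
  labs <- sort(unique(modules[modules > 0]))
  sizes <- vapply(labs, function(m) sum(modules == m), integer(1))
  remap <- setNames(seq_along(labs), labs[order(-sizes)])
  out <- modules
  for (m in labs) out[modules == m] <- remap[as.character(m)]
  out
}

#' Permutation-based cross-environment module preservation
#'
#' For each reference-defined module: the density statistic is the mean
#' intramodular adjacency in the test network; the connectivity statistic is
#' the correlation of intramodular connectivity vectors between reference and
#' test, paired by gene. Both are standardized against `n_permutations`
#' size-matched random test-side gene sets (a label-permutation null: a
#' random set's connectivity is unpaired with the module's reference
#' connectivity), giving Zdensity and Zconnectivity; `Zsummary` is their
#' mean. Bands: below 2 no preservation, 2-10 moderate, above 10 high.
#'
#' @param expr_ref,expr_test gene x sample expression matrices over the same
#'   genes (reference environment and test environment).
#' @param modules module assignment from the reference network (named integer
#'   vector or a `module_assignment`).
#' @param params a [network_params()]; `n_permutations` and `seed` control
#'   the null.
#' @return data.frame: module, size, Zdensity, Zconnectivity, Zsummary,
#'   preservation class.
#' @export
module_preservation <- function(expr_ref, expr_test, modules,
                                params = network_params()) {
  if (inherits(modules, "module_assignment")) modules <- modules$modules
  genes <- intersect(rownames(expr_ref), rownames(expr_test))
  if (length(genes) < 3) stop_pz("reference and test share too few genes")
  modules <- modules[genes]
  expr_ref <- expr_ref[genes, , drop = FALSE]
  expr_test <- expr_test[genes, , drop = FALSE]
  a_ref <- adjacency_matrix(expr_ref, params$beta, params$network_type)
  a_test <- adjacency_matrix(expr_test, params$beta, params$network_type)
  diag(a_ref) <- 0
  diag(a_test) <- 0
  n <- length(genes)
  safe_cor <- function(x, y) {
    if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else 0
  }
  test_stats <- function(kr, idx) {
    # density and connectivity of a test-side gene set, scored against the
    # module's reference connectivity vector kr (pairing by position; for a
    # random set both orderings are arbitrary, giving a no-association null)
    st <- a_test[idx, idx, drop = FALSE]
    c(mean(st[upper.tri(st)]), safe_cor(kr, rowSums(st)))
  }
  labs <- sort(unique(modules[modules > 0]))
  seeds <- derive_seeds(params$seed, max(length(labs), 1))
  rows <- list()
  for (i in seq_along(labs)) {
    m <- labs[i]
    idx <- which(modules == m)
    if (length(idx) < 3) {
      warn_pz("module %d has < 3 genes; skipped", m)
      next
    }
    kr <- rowSums(a_ref[idx, idx, drop = FALSE])
    obs <- test_stats(kr, idx)
    null <- with_seed(seeds[i], {
      vapply(seq_len(params$n_permutations),
             function(p) test_stats(kr, sample.int(n, length(idx))),
             numeric(2))
    })
    mu <- rowMeans(null)
    sdev <- apply(null, 1, stats::sd)
    z <- ifelse(sdev > 0, (obs - mu) / sdev, 0)
    zsum <- mean(z)
    rows[[length(rows) + 1]] <- data.frame(
      module = m, size = length(idx),
      Zdensity = z[1], Zconnectivity = z[2], Zsummary = zsum,
      preservation = if (zsum < 2) "none" else if (zsum <= 10) "moderate"
                     else "high",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(module = integer(0), size = integer(0), Zdensity = numeric(0),
               Zconnectivity = numeric(0), Zsummary = numeric(0),
               preservation = character(0))
  rownames(out) <- NULL
  out
}

#' Rank hub genes by intramodular connectivity
#'
#' Genes within each module ranked by the row sum of the adjacency restricted
#' to the module (excluding self-adjacency); ties broken lexicographically by
#' gene id.
#'
#' @param adjacency symmetric adjacency matrix with gene ids.
#' @param modules named module assignment (0 = unassigned, skipped).
#' @param top_n genes reported per module (whole module if larger).
#' @return data.frame: module, gene_id, connectivity, rank.
#' @export
hub_genes <- function(adjacency, modules, top_n = 10) {
  if (inherits(modules, "module_assignment")) modules <- modules$modules
  genes <- rownames(adjacency)
  modules <- modules[genes]
  labs <- sort(unique(modules[modules > 0]))
  rows <- lapply(labs, function(m) {
    idx <- which(modules == m)
    sub <- adjacency[idx, idx, drop = FALSE]
    k <- rowSums(sub) - diag(sub)
    ord <- order(-k, names(k))
    keep <- seq_len(min(top_n, length(idx)))
    data.frame(module = m, gene_id = names(k)[ord][keep],
               connectivity = unname(k[ord][keep]), rank = keep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(module = integer(0), gene_id = character(0),
               connectivity = numeric(0), rank = integer(0))
  rownames(out) <- NULL
  out
}
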