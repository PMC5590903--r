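# Gene-set overlap statistics: Monte-Carlo resampling enrichment with the
# +1 pseudocount empirical p (10,000 resamples by default, so the smallest
# reportable p is 1/10,001 < 1e-4), an exact hypergeometric tail as the
# analytic oracle, and Fisher-exact term enrichment with the
# Benjamini-Yekutieli correction.

#' Exact hypergeometric overlap tail probability
#'
#' Tail of `Hypergeometric(N, K, n)`: the overlap of a fixed size-`K`
#' annotation with a uniformly drawn size-`n` subset of an `N`-gene
#' background. Computed in log space.
#'
#' @param k observed overlap.
#' @param K annotation-set size within the background.
#' @param n candidate-set size.
#' @param N background size.
#' @param tail "upper" for `P(X >= k)` (enrichment) or "lower" for
#'   `P(X <= k)` (depletion).
#' @return probability.
#' @export
hypergeometric_overlap_p <- function(k, K, n, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (K > N || n > N || K < 0 || n < 0 || N < 0) {
    stop_pz("need 0 <= K, n <= N")
  }
  if (k < 0 || k > min(n, K)) stop_pz("need 0 <= k <= min(n, K)")
  if (tail == "upper") {
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  } else {
    exp(stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
  }
}

#' Monte-Carlo resampling overlap enrichment
#'
#' Compares the observed overlap of a candidate gene set with an annotation
#' set against the overlaps of `n_resamples` equal-sized sets drawn uniformly
#' without replacement from the background. Empirical p-values use the +1
#' pseudocount (`p = (1 + #{null >= k}) / (n_resamples + 1)`), so a p of
#' exactly 0 is never reported.
#'
#' @param candidate_set,annotation_set,background character vectors of gene
#'   ids; candidate and annotation are intersected with the background (with
#'   a warning if genes fall outside it).
#' @param n_resamples number of null sets (>= 100).
#' @param seed integer seed; resampling is bit-reproducible.
#' @return list of class `enrichment_result`: sizes, observed overlap `k`,
#'   null mean/sd, `z_score`, `p_enrich`, `p_deplete`, `seed`.
#' @export
resample_enrichment <- function(candidate_set, annotation_set, background,
                                n_resamples = 10000, seed = 1L) {
  if (n_resamples < 100) stop_pz("n_resamples must be >= 100")
  background <- unique(background)
  candidate_set <- unique(candidate_set)
  annotation_set <- unique(annotation_set)
  out_cand <- setdiff(candidate_set, background)
  if (length(out_cand) > 0) {
    warn_pz("%d candidate gene(s) outside the background were dropped",
            length(out_cand))
    candidate_set <- intersect(candidate_set, background)
  }
  annotation_set <- intersect(annotation_set, background)
  N <- length(background)
  n <- length(candidate_set)
  if (n > N) stop_pz("candidate set larger than background")
  if (n == 0) stop_pz("empty candidate set after background intersection")
  member <- background %in% annotation_set
  K <- sum(member)
  k <- sum(candidate_set %in% annotation_set)
  null <- with_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) sum(member[sample.int(N, n)]), numeric(1))
  })
  mu <- mean(null)
  sdev <- stats::sd(null)
  structure(list(candidate_size = n, annotation_size = K,
                 background_size = N, k = k,
                 n_resamples = as.integer(n_resamples),
                 null_mean = mu, null_sd = sdev,
                 z_score = if (sdev > 0) (k - mu) / sdev else NA_real_,
                 p_enrich = (1 + sum(null >= k)) / (n_resamples + 1),
                 p_deplete = (1 + sum(null <= k)) / (n_resamples + 1),
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "overlap k = %d (candidate %d, annotation %d, background %d)\n",
    x$k, x$candidate_size, x$annotation_size, x$background_size))
  cat(sprintf("null: mean %.2f, sd %.2f over %d resamples; z = %.2f\n",
              x$null_mean, x$null_sd, x$n_resamples,
              x$z_score %||% NA_real_))
  cat(sprintf("p_enrich = %.4g, p_deplete = %.4g\n", x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Fisher-exact term enrichment with Benjamini-Yekutieli correction
#'
#' Per annotation term, a two-sided Fisher exact test (conditional
#' minimum-likelihood rule) on the 2x2 table of set membership vs term
#' membership over the background. Genes without any term are removed from
#' both the set and the background; terms annotating fewer than
#' `min_term_size` background genes are skipped.
#'
#' @param gene_set candidate gene ids.
#' @param background background gene ids.
#' @param term_map data.frame (gene_id, term).
#' @param alpha significance threshold on the BY-adjusted p.
#' @param min_term_size minimum background genes per tested term.
#' @return data.frame: term, set_in_term, set_total, bg_in_term, bg_total,
#'   odds_ratio, p_value, p_adj, significant.
#' @export
term_enrichment <- function(gene_set, background, term_map, alpha = 0.05,
                            min_term_size = 5) {
  annotated <- unique(term_map$gene_id)
  background <- intersect(unique(background), annotated)
  if (length(background) == 0) stop_pz("no background gene has a term")
  gene_set <- intersect(unique(gene_set), background)
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  term_genes <- split(tm$gene_id, tm$term)
  term_genes <- lapply(term_genes, unique)
  sizes <- lengths(term_genes)
  term_genes <- term_genes[sizes >= min_term_size]
  if (length(term_genes) == 0) {
    return(data.frame(term = character(0), set_in_term = integer(0),
                      set_total = integer(0), bg_in_term = integer(0),
                      bg_total = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  n_set <- length(gene_set)
  N <- length(background)
  rows <- lapply(names(term_genes), function(term) {
    tg <- term_genes[[term]]
    a <- length(intersect(gene_set, tg))        # in set, in term
    b <- n_set - a                              # in set, not in term
    c0 <- length(tg) - a                        # not in set, in term
    d <- N - n_set - c0
    tab <- matrix(c(a, c0, b, d), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    r1 <- if (a + b > 0) a / (a + b) else NA_real_
    r2 <- if (c0 + d > 0) c0 / (c0 + d) else NA_real_
    or <- if (!is.na(r1) && !is.na(r2) && isTRUE(all.equal(r1, r2))) {
      1   # non-informative term (e.g. annotates every background gene)
    } else if (b == 0 || c0 == 0) {
      Inf
    } else if (a == 0 || d == 0) {
      0
    } else {
      (a * d) / (b * c0)
    }
    data.frame(term = term, set_in_term = a, set_total = n_set,
               bg_in_term = length(tg), bg_total = N, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p_value, "BY")
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
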