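# Expression-variability statistics: per-gene coefficient of variation
# across an inbred-line panel, a Mann-Whitney U test (exact for small
# samples, tie-corrected normal approximation otherwise), and nonparametric
# comparison of any per-gene statistic across response categories with the
# starred significance codes (** < 0.01, *** < 0.001).

#' Per-gene coefficient of variation across a panel
#'
#' `CV_g = sd_g / mean_g` with the sample (n - 1) standard deviation. Genes
#' with zero mean are returned missing and excluded downstream.
#'
#' @param panel gene x line numeric matrix with >= 2 lines.
#' @return named numeric vector of CVs (NA for zero-mean genes).
#' @export
gene_cv <- function(panel) {
  if (ncol(panel) < 2) stop_pz("panel needs >= 2 lines to compute a CV")
  m <- rowMeans(panel)
  s <- apply(panel, 1, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  names(cv) <- rownames(panel)
  cv
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. For combined sample
#' sizes of at most 10 the two-sided p is computed by exact enumeration over
#' all assignments of the pooled ranks; otherwise the normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y non-empty numeric samples (NAs dropped).
#' @return list: `U` (statistic for `x`), `p_value` (two-sided), `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_pz("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  if (length(unique(pooled)) == 1L) {
    warn_pz("all values identical across both samples")
    return(list(U = U, p_value = 1, method = "degenerate"))
  }
  if (n1 + n2 <= 10) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mid) >= abs(U - mid) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  cc <- 0.5 * sign(U - mid)
  z <- (U - mid - cc) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approximation")
}

significance_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ""))
}

#' Compare a per-gene statistic across response categories
#'
#' Pairwise two-sided Mann-Whitney tests over the requested category pairs,
#' with per-category summaries (n, median, IQR) and the starred significance
#' codes used in box-plot figures (** below 0.01, *** below 0.001). No
#' multiple-testing correction is applied across the handful of pairs.
#'
#' @param stat named per-gene numeric vector (e.g. CV or diversity); missing
#'   values and genes outside the category table are dropped.
#' @param categories a table from [classify_genes()] or any data.frame with
#'   `gene_id` and `category`.
#' @param pairs list of 2-vectors of category names; default: all pairs among
#'   categories present with >= 2 genes.
#' @param statistic_name label stored in the output.
#' @return list of class `category_comparison`: `summary` (per category) and
#'   `comparisons` (category_a, category_b, n_a, n_b, U, p_value, code).
#' @export
compare_categories <- function(stat, categories, pairs = NULL,
                               statistic_name = "statistic") {
  stat <- stat[!is.na(stat)]
  idx <- match(names(stat), categories$gene_id)
  keep <- !is.na(idx)
  stat <- stat[keep]
  cat_of <- as.character(categories$category[idx[keep]])
  groups <- split(stat, cat_of)
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    q <- stats::quantile(groups[[g]], c(0.25, 0.5, 0.75))
    data.frame(category = g, n = length(groups[[g]]), median = q[[2]],
               iqr = q[[3]] - q[[1]], stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  if (is.null(pairs)) {
    present <- names(groups)[lengths(groups) >= 2]
    pairs <- if (length(present) >= 2) {
      asplit(utils::combn(present, 2), 2)
    } else {
      list()
    }
  }
  rows <- list()
  for (pr in pairs) {
    a <- groups[[pr[1]]] %||% numeric(0)
    b <- groups[[pr[2]]] %||% numeric(0)
    if (length(a) < 2 || length(b) < 2) {
      warn_pz("pair (%s, %s) skipped: category with < 2 genes", pr[1], pr[2])
      next
    }
    mw <- mann_whitney_u(a, b)
    rows[[length(rows) + 1]] <- data.frame(
      category_a = pr[1], category_b = pr[2],
      n_a = length(a), n_b = length(b),
      U = mw$U, p_value = mw$p_value,
      code = significance_code(mw$p_value),
      stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, rows) %||%
    data.frame(category_a = character(0), category_b = character(0),
               n_a = integer(0), n_b = integer(0), U = numeric(0),
               p_value = numeric(0), code = character(0))
  rownames(comparisons) <- NULL
  structure(list(statistic = statistic_name, summary = summary,
                 comparisons = comparisons),
            class = "category_comparison")
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf("Category comparison of %s\n", x$statistic))
  print(x$summary, row.names = FALSE)
  cat("\nPairwise Mann-Whitney (** < 0.01, *** < 0.001):\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
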