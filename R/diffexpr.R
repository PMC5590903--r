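# Negative-binomial differential expression between EH and MA with group
# covariates: median-of-ratios size factors, method-of-moments dispersions,
# per-gene NB log-link GLM with Wald test, BH/BY adjustment, and the
# flowering-gene filter. Deliberately simplified relative to full DE tools:
# no fold-change shrinkage, no independent filtering, no outlier replacement.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g(count_gj / geomean_g)` over reference-eligible genes
#' (those with no zero count in any sample), rescaled so the factors have
#' geometric mean 1. With `pseudo_reference = TRUE` the per-gene geometric
#' mean is computed over positive counts only, allowing matrices where every
#' gene has some zero.
#'
#' @param counts gene x sample count matrix.
#' @param pseudo_reference fall back to a positive-count pseudo reference.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- validate_count_matrix(counts)
  if (any(colSums(counts) == 0)) stop_pz("sample with all-zero counts")
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    if (!pseudo_reference) {
      stop_pz(paste("no gene has nonzero counts in every sample;",
                    "retry with pseudo_reference = TRUE"))
    }
    loggeo <- apply(counts, 1, function(x) {
      pos <- x > 0
      if (sum(pos) < 2) NA_real_ else mean(log(x[pos]))
    })
    ok <- !is.na(loggeo)
    if (!any(ok)) stop_pz("no reference-eligible genes")
  } else {
    loggeo <- rowMeans(log(counts + (counts == 0)))  # zeros never used when ok
    loggeo[!ok] <- NA_real_
  }
  logratios <- log(counts[ok, , drop = FALSE] + (counts[ok, , drop = FALSE] == 0)) -
    loggeo[ok]
  sf <- exp(apply(logratios, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Method-of-moments NB dispersion estimates
#'
#' On size-factor-normalized counts, the within-cell variance (pooled across
#' all group x condition design cells) and the grand mean give
#' `alpha_g = max((s2_g - m_g) / m_g^2, 1e-8)`. An optional log-linear
#' mean-dispersion trend shrinkage (50/50 in log space) is off by default.
#'
#' @param counts gene x sample count matrix.
#' @param design sample design with `group` and `condition`.
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param trend apply trend shrinkage.
#' @return named per-gene dispersion vector (alpha, variance = mu + alpha mu^2).
#' @export
estimate_dispersions <- function(counts, design, size_factors, trend = FALSE) {
  validate_sample_design(design, counts)
  design <- design[match(colnames(counts), design$sample_id), ]
  cell <- paste(design$group, design$condition, sep = ":")
  sizes <- table(cell)
  if (all(sizes < 2)) stop_pz("no design cell has replication (>= 2 samples)")
  norm <- sweep(counts, 2, size_factors, "/")
  ss <- 0
  df <- 0
  for (c0 in names(sizes)) {
    j <- cell == c0
    if (sum(j) < 2) next
    sub <- norm[, j, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + sum(j) - 1
  }
  s2 <- ss / df
  m <- rowMeans(norm)
  alpha <- pmax((s2 - m) / m^2, 1e-8)
  alpha[m == 0] <- 1e-8
  if (trend) {
    use <- alpha > 1e-8 & m > 0
    if (sum(use) > 10) {
      fit <- stats::lm(log(alpha[use]) ~ log(m[use]))
      trend_alpha <- exp(cbind(1, log(pmax(m, 1e-8))) %*% stats::coef(fit))[, 1]
      alpha <- pmax(exp(0.5 * log(alpha) + 0.5 * log(pmax(trend_alpha, 1e-8))),
                    1e-8)
    }
  }
  names(alpha) <- rownames(counts)
  alpha
}

# One NB log-link GLM fit with fixed dispersion via Fisher-scoring IRLS.
# Returns coefficients, their covariance, and a convergence flag.
fit_nb_glm <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-8) {
  # init from the linearized model on log counts
  beta <- tryCatch(
    stats::lm.fit(X, log(y + 0.5) - offset)$coefficients,
    error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)                # Fisher weights, NB variance
    z <- (eta - offset) + (y - mu) / mu       # working response
    XtWX <- crossprod(X, X * W)
    upd <- tryCatch(solve(XtWX, crossprod(X, W * z)),
                    error = function(e) NULL)
    if (is.null(upd)) return(list(converged = FALSE))
    delta <- drop(upd) - beta
    beta <- drop(upd)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE))
  list(beta = beta, cov = cov, converged = converged)
}

#' Per-gene Wald test of the environment effect
#'
#' Fits, per gene, a negative-binomial log-link GLM with model matrix
#' `~ group + condition` (MA as the reference environment, so positive log2
#' fold changes mean higher expression under EH), with log size factors as
#' offset and the supplied dispersions held fixed. The Wald statistic is the
#' condition coefficient over its standard error with a two-sided normal
#' p-value. Genes with all-zero counts, or whose fit does not converge in 100
#' iterations, get a missing p-value.
#'
#' @param counts gene x sample count matrix.
#' @param design sample design (`group`, `condition` with both EH and MA).
#' @param size_factors per-sample factors.
#' @param dispersions per-gene alpha.
#' @return data.frame (gene_id, base_mean, lfc, lfc_se, wald_stat, p_value,
#'   p_adj = NA placeholder, converged), with size factors and dispersions in
#'   attributes. `lfc` is in log2 units, EH relative to MA.
#' @export
test_condition_effect <- function(counts, design, size_factors, dispersions) {
  validate_sample_design(design, counts)
  design <- design[match(colnames(counts), design$sample_id), ]
  if (!all(c("EH", "MA") %in% design$condition)) {
    stop_pz("design must contain both EH and MA samples")
  }
  condition <- factor(design$condition, levels = c("MA", "EH"))
  group <- factor(design$group)
  X <- if (nlevels(group) > 1) {
    stats::model.matrix(~ group + condition)
  } else {
    stats::model.matrix(~ condition)
  }
  if (qr(X)$rank < ncol(X)) stop_pz("model matrix is not full rank")
  cond_col <- ncol(X)
  offset <- log(size_factors)
  norm <- sweep(counts, 2, size_factors, "/")
  n_genes <- nrow(counts)
  lfc <- lfc_se <- wald <- p <- rep(NA_real_, n_genes)
  converged <- rep(FALSE, n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    fit <- fit_nb_glm(y, X, offset, dispersions[g])
    if (!isTRUE(fit$converged)) next
    converged[g] <- TRUE
    b <- fit$beta[cond_col]
    se <- sqrt(fit$cov[cond_col, cond_col])
    lfc[g] <- b / log(2)
    lfc_se[g] <- se / log(2)
    wald[g] <- b / se
    p[g] <- 2 * stats::pnorm(-abs(wald[g]))
  }
  out <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    lfc = lfc, lfc_se = lfc_se, wald_stat = wald,
                    p_value = p, p_adj = NA_real_,
                    converged = converged,
                    stringsAsFactors = FALSE)
  attr(out, "size_factors") <- size_factors
  attr(out, "dispersions") <- dispersions
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg / Benjamini-Yekutieli step-up adjustment
#'
#' Missing p-values are excluded from the number of tests m and returned
#' missing. BY multiplies the BH adjustment by `c(m) = sum_{i=1..m} 1/i`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param method "BH" or "BY".
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_pz("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  adj <- pmin(1, cummin(cm * m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Apply an adjusted-p column to a DE result
#' @param de a DE result from [test_condition_effect()].
#' @param method adjustment method.
#' @return the DE result with `p_adj` filled in.
#' @export
add_adjusted_pvalues <- function(de, method = "BH") {
  de$p_adj <- adjust_pvalues(de$p_value, method)
  de
}

#' Remove flagged genes (e.g. flowering-stage markers) from DE results
#'
#' Flagged genes are removed from both tables; the removal counts report how
#' many of the flagged genes were significant in only the maize table, only
#' the teosinte table, or both, at the given FDR threshold.
#'
#' @param de_maize,de_teosinte DE results with `p_adj` filled in.
#' @param flag_set character vector of gene ids to remove.
#' @param alpha FDR threshold defining "significant".
#' @return list with filtered `de_maize`, `de_teosinte`, and `removed` counts
#'   (maize_only, teosinte_only, both, total).
#' @export
remove_flagged_genes <- function(de_maize, de_teosinte, flag_set,
                                 alpha = 0.05) {
  flag_set <- unique(flag_set)
  sig_m <- de_maize$gene_id[!is.na(de_maize$p_adj) & de_maize$p_adj < alpha]
  sig_t <- de_teosinte$gene_id[!is.na(de_teosinte$p_adj) &
                                 de_teosinte$p_adj < alpha]
  both <- intersect(intersect(flag_set, sig_m), sig_t)
  m_only <- setdiff(intersect(flag_set, sig_m), sig_t)
  t_only <- setdiff(intersect(flag_set, sig_t), sig_m)
  removed <- c(maize_only = length(m_only), teosinte_only = length(t_only),
               both = length(both),
               total = length(m_only) + length(t_only) + length(both))
  list(de_maize = de_maize[!de_maize$gene_id %in% flag_set, , drop = FALSE],
       de_teosinte = de_teosinte[!de_teosinte$gene_id %in% flag_set, ,
                                 drop = FALSE],
       removed = removed)
}
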