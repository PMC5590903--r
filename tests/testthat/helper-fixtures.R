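# Shared fixtures: all built in code at test time.

# Random count matrix with ids.
random_counts <- function(n_genes = 20, n_samples = 6, mu = 50, seed = 1) {
  withr_seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 10), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

withr_seed <- function(seed) set.seed(seed)

# Single-group two-condition design for a count matrix.
flat_design <- function(counts, n_eh = ncol(counts) %/% 2,
                        taxon = "maize", group = "g1") {
  n <- ncol(counts)
  data.frame(sample_id = colnames(counts), taxon = taxon, group = group,
             condition = c(rep("EH", n_eh), rep("MA", n - n_eh)),
             stringsAsFactors = FALSE)
}

# Null NB counts plus DE genes at a fixed lfc, with matching design.
nb_dataset <- function(n_null, n_de = 0, lfc = 0, mu0 = 100, alpha = 0.1,
                       n_per_cond = 6, seed = 1) {
  withr_seed(seed)
  n <- n_null + n_de
  lfc_vec <- c(rep(lfc, n_de), rep(0, n_null))
  x <- rep(c(1, 0), each = n_per_cond)
  mu <- mu0 * 2^outer(lfc_vec, x)
  counts <- matrix(rnbinom(n * 2 * n_per_cond, mu = mu, size = 1 / alpha), n,
                   dimnames = list(sprintf("g%05d", seq_len(n)),
                                   sprintf("s%03d", seq_len(2 * n_per_cond))))
  list(counts = counts, design = flat_design(counts, n_eh = n_per_cond),
       de_idx = seq_len(n_de))
}

# Planted-block expression: n_blocks of block_size genes each driven by its
# own latent factor with per-gene loadings drawn from weight_range, plus
# i.i.d. noise. Heterogeneous loadings make intramodular connectivity an
# identifiable per-gene property (needed for connectivity-preservation
# statistics); the default keeps loadings constant. Returns genes x samples.
block_expr <- function(block_size = 100, n_samples = 20, n_blocks = 2,
                       noise_sd = 0.3, weight_range = c(1, 1), seed = 1) {
  withr_seed(seed)
  drivers <- matrix(rnorm(n_blocks * n_samples), n_blocks)
  expr <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    w <- runif(block_size, weight_range[1], weight_range[2])
    w * matrix(rep(drivers[b, ], each = block_size), block_size) +
      matrix(rnorm(block_size * n_samples, sd = noise_sd), block_size)
  }))
  rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
  colnames(expr) <- sprintf("s%03d", seq_len(n_samples))
  expr
}

# Adjusted Rand index between two labelings (independent oracle for
# planted-partition recovery).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Tiny DE table pair with prescribed adjusted p-values for classification
# tests.
de_stub <- function(gene_id, lfc, p_adj) {
  data.frame(gene_id = gene_id, base_mean = 100, lfc = lfc, lfc_se = 0.1,
             wald_stat = lfc / 0.1, p_value = p_adj, p_adj = p_adj,
             stringsAsFactors = FALSE)
}
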