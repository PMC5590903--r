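# coexpression: expression filter, transform, soft power, TOM, module
# detection, preservation, hubs.

test_that("expression filter requires signal in all four taxon x condition groups", {
  m_m <- random_counts(6, 8, seed = 1) + 1
  m_t <- random_counts(6, 8, seed = 2) + 1
  d_m <- flat_design(m_m, taxon = "maize")
  d_t <- flat_design(m_t, taxon = "teosinte")
  eh_m <- d_m$sample_id[d_m$condition == "EH"]
  m_m["g001", eh_m] <- 0                     # silent in all maize-EH samples
  keep <- filter_coexpression_genes(m_m, m_t, d_m, d_t)
  expect_false("g001" %in% keep)
  expect_true("g002" %in% keep)

  # brute-force recount oracle on a random sparse pair
  set.seed(3)
  a <- matrix(rbinom(30 * 8, 1, 0.35) * rpois(30 * 8, 5), 30,
              dimnames = list(sprintf("g%03d", 1:30), colnames(m_m)))
  b <- matrix(rbinom(30 * 8, 1, 0.35) * rpois(30 * 8, 5), 30,
              dimnames = list(sprintf("g%03d", 1:30), colnames(m_t)))
  keep2 <- filter_coexpression_genes(a, b, d_m, d_t)
  brute <- rownames(a)[vapply(seq_len(30), function(g) {
    all(vapply(list(list(a, d_m), list(b, d_t)), function(x) {
      all(vapply(c("EH", "MA"), function(cond) {
        any(x[[1]][g, x[[2]]$sample_id[x[[2]]$condition == cond]] > 0)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))]
  expect_equal(keep2, brute)
})

test_that("count transform maps zeros to zero, preserves ranks, flattens variance", {
  m <- random_counts(10, 4, seed = 5)
  m[1, 1] <- 0
  tr <- transform_counts(m, rep(1, 4))
  expect_equal(tr[1, 1], 0)
  for (j in 1:4) {
    expect_equal(order(tr[, j]), order(m[, j]))
  }
  # variance flattening on NB data with moderate dispersion
  set.seed(6)
  mus <- exp(runif(300, log(5), log(5000)))
  nb <- matrix(rnbinom(300 * 20, mu = mus, size = 1 / 0.3), 300,
               dimnames = list(sprintf("g%03d", 1:300),
                               sprintf("s%02d", 1:20)))
  slope_raw <- coef(lm(apply(nb, 1, sd) ~ rowMeans(nb)))[2]
  tnb <- transform_counts(nb, rep(1, 20))
  slope_tr <- coef(lm(apply(tnb, 1, sd) ~ rowMeans(tnb)))[2]
  expect_lt(abs(slope_tr), abs(slope_raw))
})

test_that("soft-power pick reaches the scale-free criterion on heavy-tailed networks", {
  # hub-structured expression: gene g follows a few latent drivers with
  # weights decaying as a power law, giving a heavy-tailed connectivity
  set.seed(7)
  n <- 150; nsamp <- 30
  drivers <- matrix(rnorm(5 * nsamp), 5)
  w <- (1:n)^-0.8
  expr <- t(vapply(1:n, function(g) {
    w[g] * drivers[1 + g %% 5, ] + rnorm(nsamp, sd = 0.6)
  }, numeric(nsamp)))
  dimnames(expr) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:nsamp))
  res <- pick_soft_power(expr, candidate_betas = 1:30, r2_threshold = 0.8)
  chosen <- res$fit_table[res$fit_table$beta == res$beta, ]
  expect_gte(chosen$r_squared, 0.8)
  expect_equal(res$beta, min(res$fit_table$beta[res$fit_table$r_squared >= 0.8]))

  # brute-force recomputation of the reported fit for the chosen power
  a <- abs(cor(t(expr)))^res$beta
  diag(a) <- 0
  k <- rowSums(a)
  breaks <- seq(min(k), max(k), length.out = 11)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  km <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0 & km > 0
  r2 <- summary(lm(log10(freq[use]) ~ log10(km[use])))$r.squared
  expect_equal(chosen$r_squared, r2, tolerance = 1e-10)
})

test_that("soft-power fallback and degenerate candidate list", {
  expr <- block_expr(30, 12, n_blocks = 2, seed = 8)
  expect_warning(res <- pick_soft_power(expr, candidate_betas = c(1, 2)),
                 "maximum")
  expect_equal(res$beta, 2)
  one <- suppressWarnings(pick_soft_power(expr, candidate_betas = 3))
  expect_equal(one$beta, 3)
  expect_equal(nrow(one$fit_table), 1)
  expect_error(pick_soft_power(expr[1:5, ], candidate_betas = 1:2),
               "fewer genes")
})

test_that("TOM: two-node closure, bounds, brute-force formula oracle", {
  # two perfectly correlated genes
  expr2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(expr2) <- paste0("s", 1:4)
  net2 <- build_tom(expr2, network_params(beta = 3))
  expect_equal(net2$tom["g1", "g2"], 1)

  expr <- block_expr(3, 10, n_blocks = 2, noise_sd = 1, seed = 9)
  params <- network_params(beta = 4)
  net <- build_tom(expr, params)
  expect_true(all(net$tom >= 0 & net$tom <= 1))
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_equal(net$tom, t(net$tom))
  expect_equal(unname(diag(net$tom)), rep(1, 6))
  expect_equal(unname(diag(net$adjacency)), rep(1, 6))
  # beta = 1 unsigned adjacency equals |correlation|
  net1 <- build_tom(expr, network_params(beta = 1))
  a1 <- net1$adjacency; diag(a1) <- 0
  cc <- abs(cor(t(expr))); diag(cc) <- 0
  expect_equal(a1, cc, tolerance = 1e-12)

  # element-wise brute-force evaluation of the TOM formula on 6 genes
  a <- net$adjacency
  diag(a) <- 0
  k <- rowSums(a)
  brute <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) { brute[i, j] <- 1; next }
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    brute[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(brute) <- dimnames(net$tom)
  expect_equal(net$tom, brute, tolerance = 1e-12)

  expect_error(build_tom(expr[, 1:2], params), ">= 3 samples")
  expect_error(build_tom(matrix(1, 4, 5,
                                dimnames = list(paste0("g", 1:4),
                                                paste0("s", 1:5))),
                         params), "constant")
})

test_that("planted two-block structure is recovered as two modules", {
  for (seed in c(1, 2, 3)) {
    expr <- block_expr(100, 20, n_blocks = 2, noise_sd = 0.3, seed = seed)
    params <- network_params(beta = 6, min_module_size = 30)
    net <- build_tom(expr, params)
    mods <- detect_modules(net$dissimilarity, expr, params)
    truth <- rep(1:2, each = 100)
    ari <- adjusted_rand_index(mods$modules, truth)
    expect_gte(ari, 0.9)
    expect_lte(length(unique(mods$modules[mods$modules > 0])), 3)
  }
})

test_that("modules with correlated eigengenes are merged at the 0.25 cutoff", {
  # two planted blocks driven by latent factors correlated at ~0.9:
  # eigengene dissimilarity ~0.1 < 0.25, so they must merge
  set.seed(13)
  nsamp <- 30
  d1 <- rnorm(nsamp)
  d2 <- 0.9 * d1 + sqrt(1 - 0.9^2) * rnorm(nsamp)
  mk <- function(driver, n) {
    t(vapply(1:n, function(i) driver + rnorm(nsamp, sd = 0.2),
             numeric(nsamp)))
  }
  expr <- rbind(mk(d1, 60), mk(d2, 60))
  dimnames(expr) <- list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:nsamp))
  params <- network_params(beta = 6, min_module_size = 30,
                           merge_cutoff = 0.25)
  net <- build_tom(expr, params)
  mods <- detect_modules(net$dissimilarity, expr, params)
  expect_equal(length(unique(mods$modules[mods$modules > 0])), 1)
  # with a tiny cutoff they stay separate
  params2 <- network_params(beta = 6, min_module_size = 30,
                            merge_cutoff = 0.01)
  mods2 <- detect_modules(net$dissimilarity, expr, params2)
  expect_equal(length(unique(mods2$modules[mods2$modules > 0])), 2)
})

test_that("min_module_size larger than n leaves every gene unassigned", {
  expr <- block_expr(10, 10, n_blocks = 2, seed = 14)
  params <- network_params(beta = 2, min_module_size = 50)
  net <- build_tom(expr, params)
  expect_warning(mods <- detect_modules(net$dissimilarity, expr, params),
                 "unassigned")
  expect_true(all(mods$modules == 0))
})

test_that("module detection is deterministic and eigengenes well oriented", {
  expr <- block_expr(50, 16, n_blocks = 2, seed = 15)
  params <- network_params(beta = 6, min_module_size = 20)
  net <- build_tom(expr, params)
  a <- detect_modules(net$dissimilarity, expr, params)
  b <- detect_modules(net$dissimilarity, expr, params)
  expect_identical(a$modules, b$modules)
  expect_identical(a$eigengenes, b$eigengenes)
  for (m in colnames(a$eigengenes)) {
    e <- a$eigengenes[, m]
    expect_equal(sum(e^2), 1, tolerance = 1e-8)
    lab <- as.integer(sub("ME", "", m))
    msub <- t(scale(t(expr[a$modules == lab, , drop = FALSE])))
    expect_gte(cor(e, colMeans(msub)), 0)
  }
})

test_that("preservation contrasts noisy copies against destroyed structure across seeds", {
  for (seed in 1:5) {
    expr <- block_expr(60, 20, n_blocks = 4, noise_sd = 0.3,
                       weight_range = c(0.5, 1.5), seed = 300 + seed)
    params <- network_params(beta = 6, min_module_size = 30,
                             n_permutations = 100, seed = 400 + seed)
    net <- build_tom(expr, params)
    mods <- detect_modules(net$dissimilarity, expr, params)
    set.seed(500 + seed)
    noisy <- expr + matrix(rnorm(length(expr), sd = 0.1), nrow(expr))
    pres_hi <- module_preservation(expr, noisy, mods, params)
    expect_true(all(pres_hi$Zsummary > 10))
    expect_true(all(pres_hi$preservation == "high"))

    permuted <- expr[sample(nrow(expr)), ]
    rownames(permuted) <- rownames(expr)
    pres_lo <- module_preservation(expr, permuted, mods, params)
    expect_true(all(pres_lo$Zsummary < 2))
    expect_true(all(pres_lo$preservation == "none"))

    if (seed == 1) {
      # permutation null is seed-reproducible
      again <- module_preservation(expr, noisy, mods, params)
      expect_identical(pres_hi, again)
    }
  }
})

test_that("preservation classes follow the 2/10 bands at the boundaries", {
  classify_band <- function(z) if (z < 2) "none" else if (z <= 10) "moderate" else "high"
  expect_equal(classify_band(1.999), "none")
  expect_equal(classify_band(2), "moderate")
  expect_equal(classify_band(10), "moderate")
  expect_equal(classify_band(10.001), "high")
  # and the implementation agrees on real output
  expr <- block_expr(40, 14, n_blocks = 1, seed = 19)
  params <- network_params(beta = 4, min_module_size = 20,
                           n_permutations = 50, seed = 20)
  net <- build_tom(expr, params)
  mods <- detect_modules(net$dissimilarity, expr, params)
  pres <- module_preservation(expr, expr, mods, params)
  expect_equal(pres$preservation,
               vapply(pres$Zsummary, classify_band, character(1)))
})

test_that("hub ranking equals brute force with lexicographic ties", {
  expr <- block_expr(20, 15, n_blocks = 1, noise_sd = 0.5, seed = 21)
  net <- build_tom(expr, network_params(beta = 4))
  modules <- setNames(rep(1L, 20), rownames(expr))
  hubs <- hub_genes(net$adjacency, modules, top_n = 20)
  a <- net$adjacency
  k <- rowSums(a) - diag(a)
  brute <- names(k)[order(-k, names(k))]
  expect_equal(hubs$gene_id, brute)
  # top_n beyond the module size returns the whole module
  expect_equal(nrow(hub_genes(net$adjacency, modules, top_n = 100)), 20)
  # argmax sanity on a 3-gene module
  sub <- net$adjacency[1:3, 1:3]
  h3 <- hub_genes(sub, setNames(rep(1L, 3), rownames(sub)), top_n = 1)
  ksub <- rowSums(sub) - diag(sub)
  expect_equal(h3$gene_id, names(which.max(ksub)))
})
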