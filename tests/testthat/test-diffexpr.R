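# diffexpr: size factors, dispersions, NB Wald GLM, BH/BY, flagged-gene
# removal.

test_that("size factors: symmetry, hand case, zero-row invariance", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(estimate_size_factors(m), c(s1 = 1, s2 = 1))

  m2 <- cbind(s1 = c(a = 10, b = 20, c = 30), s2 = c(20, 40, 60))
  expect_equal(estimate_size_factors(m2),
               c(s1 = 1 / sqrt(2), s2 = sqrt(2)))

  m3 <- rbind(m2, zero1 = c(0, 0), zero2 = c(0, 0))
  expect_equal(estimate_size_factors(m3), estimate_size_factors(m2))
})

test_that("size factors have geometric mean 1 and are scale-equivariant", {
  m <- random_counts(50, 6, seed = 7) + 1
  sf <- estimate_size_factors(m)
  expect_equal(exp(mean(log(sf))), 1)
  m2 <- m
  m2[, 3] <- m[, 3] * 3
  sf2 <- estimate_size_factors(m2)
  # ratio form: tripling sample 3 triples its factor relative to the others
  expect_equal(sf2[3] / sf2[1], 3 * sf[3] / sf[1], tolerance = 1e-6)
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  m <- random_counts(100, 8, mu = 80, seed = 8) + 1
  sf <- estimate_size_factors(m)
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m)
  oracle <- oracle / exp(mean(log(oracle)))   # same geometric-mean-1 scale
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-8)
})

test_that("no reference gene errors with a pointer to the fallback flag", {
  m <- rbind(a = c(0, 5, 5), b = c(5, 0, 5), c = c(5, 5, 0))
  colnames(m) <- paste0("s", 1:3)
  expect_error(estimate_size_factors(m), "pseudo_reference")
  expect_silent(estimate_size_factors(m, pseudo_reference = TRUE))
})

test_that("dispersions: floor for constant genes, recovery from generators", {
  const <- matrix(7, 4, 12,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  d <- flat_design(const)
  a <- estimate_dispersions(const, d, rep(1, 12))
  expect_true(all(a == 1e-8))

  # Poisson generator (alpha = 0): most estimates near the floor
  set.seed(31)
  pois <- matrix(rpois(500 * 50, 100), 500,
                 dimnames = list(sprintf("g%03d", 1:500),
                                 sprintf("s%03d", 1:50)))
  dp <- flat_design(pois, n_eh = 25)
  ap <- estimate_dispersions(pois, dp, rep(1, 50))
  expect_gte(mean(ap < 0.05), 0.8)

  # NB generator with alpha = 0.5 at 200 samples
  set.seed(32)
  nb <- matrix(rnbinom(300 * 200, mu = 100, size = 2), 300,
               dimnames = list(sprintf("g%03d", 1:300),
                               sprintf("s%03d", 1:200)))
  dn <- flat_design(nb, n_eh = 100)
  an <- estimate_dispersions(nb, dn, rep(1, 200))
  expect_gte(median(an), 0.4)
  expect_lte(median(an), 0.6)
})

test_that("unreplicated designs are rejected", {
  m <- random_counts(5, 2, seed = 1)
  d <- data.frame(sample_id = colnames(m), taxon = "maize",
                  group = c("g1", "g2"), condition = c("EH", "MA"))
  expect_error(estimate_dispersions(m, d, c(1, 1)), "replication")
})

test_that("constant counts across conditions give lfc 0 and p near 1", {
  m <- matrix(50, 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  d <- flat_design(m)
  de <- test_condition_effect(m, d, rep(1, 10), rep(0.1, 6))
  expect_equal(de$lfc, rep(0, 6), tolerance = 1e-8)
  expect_true(all(de$p_value > 0.99))
})

test_that("all-zero genes get missing p and group covariates are honored", {
  dat <- nb_dataset(40, seed = 41)
  counts <- dat$counts
  counts[1, ] <- 0
  design <- dat$design
  design$group <- rep_len(c("p1", "p2"), nrow(design))  # two populations
  sf <- estimate_size_factors(counts, pseudo_reference = TRUE)
  disp <- estimate_dispersions(counts, design, sf)
  de <- test_condition_effect(counts, design, sf, disp)
  expect_true(is.na(de$p_value[1]))
  expect_false(anyNA(de$p_value[-1]))
})

test_that("relabeling conditions flips lfc and keeps p-values", {
  dat <- nb_dataset(30, n_de = 10, lfc = 1.5, seed = 43)
  sf <- estimate_size_factors(dat$counts)
  disp <- estimate_dispersions(dat$counts, dat$design, sf)
  de <- test_condition_effect(dat$counts, dat$design, sf, disp)
  flipped <- dat$design
  flipped$condition <- ifelse(flipped$condition == "EH", "MA", "EH")
  de2 <- test_condition_effect(dat$counts, flipped, sf, disp)
  expect_equal(de2$lfc, -de$lfc, tolerance = 1e-8)
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-10)
})

test_that("BH and BY match hand step-up computations", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "BH"), rep(0.04, 4))
  expect_equal(adjust_pvalues(p, "BY"), rep(0.04 * 25 / 12, 4))
  expect_equal(adjust_pvalues(rep(1, 5), "BH"), rep(1, 5))
  # missing p excluded from m, returned missing
  pm <- c(0.01, NA, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(pm, "BH"), c(0.04, NA, 0.04, 0.04, 0.04))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # p_adj >= p per gene, and agreement with p.adjust when nothing is missing
  set.seed(9)
  pr <- runif(100)
  expect_true(all(adjust_pvalues(pr, "BH") >= pr))
  expect_equal(adjust_pvalues(pr, "BH"), p.adjust(pr, "BH"))
  expect_equal(adjust_pvalues(pr, "BY"), p.adjust(pr, "BY"))
})

test_that("BH controls empirical FDR on simulated mixtures", {
  set.seed(77)
  fdrs <- replicate(20, {
    p <- c(runif(800), rbeta(200, 0.05, 1))
    truth_null <- rep(c(TRUE, FALSE), c(800, 200))
    called <- adjust_pvalues(p, "BH") < 0.05
    if (any(called)) sum(called & truth_null) / sum(called) else 0
  })
  expect_lte(mean(fdrs), 0.07)
})

test_that("flagged-gene removal reports (maize-only, teosinte-only, both)", {
  de_m <- de_stub(paste0("g", 1:10), lfc = 1,
                  p_adj = c(rep(0.001, 6), rep(0.5, 4)))
  de_t <- de_stub(paste0("g", 1:10), lfc = 1,
                  p_adj = c(rep(0.5, 2), rep(0.001, 6), rep(0.5, 2)))
  # flag g1 (maize-only sig), g3 (both sig), g7 (teosinte-only sig), g10 (ns)
  res <- remove_flagged_genes(de_m, de_t, c("g1", "g3", "g7", "g10"))
  expect_equal(res$removed,
               c(maize_only = 1, teosinte_only = 1, both = 1, total = 3))
  expect_false(any(c("g1", "g3", "g7", "g10") %in% res$de_maize$gene_id))

  # constructed counts mirroring the real flowering-gene filter: 5 maize-only,
  # 7 teosinte-only, 3 both
  genes <- sprintf("f%02d", 1:40)
  pm <- rep(0.5, 40); pt <- rep(0.5, 40)
  pm[1:5] <- 0.001                  # maize-only
  pt[6:12] <- 0.001                 # teosinte-only
  pm[13:15] <- 0.001; pt[13:15] <- 0.001   # both
  res2 <- remove_flagged_genes(de_stub(genes, 1, pm), de_stub(genes, 1, pt),
                               genes[1:15])
  expect_equal(unname(res2$removed), c(5, 7, 3, 15))

  # no-ops
  res3 <- remove_flagged_genes(de_m, de_t, character(0))
  expect_equal(unname(res3$removed), c(0, 0, 0, 0))
  expect_equal(nrow(res3$de_maize), 10)
  res4 <- remove_flagged_genes(de_m, de_t, c("zzz1", "zzz2"))
  expect_equal(unname(res4$removed), c(0, 0, 0, 0))
})
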