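test_that("basic statistics match Nei's formulas on worked examples", {
  # one population, genotypes {AA, Aa, Aa, aa}
  gm <- make_gm(matrix(c(0L, 1L, 1L, 2L), ncol = 1), pops = rep("p1", 4))
  bs <- basic_stats(gm)
  expect_equal(unname(bs$Ho), 0.5)
  expect_equal(unname(bs$Hs), 7 / 12, tolerance = 1e-12)  # 0.58333
  expect_equal(unname(bs$fis), 1 / 7, tolerance = 1e-12)  # 0.142857
  # all heterozygotes: Ho = 1, FIS < 0
  gm2 <- make_gm(matrix(rep(1L, 6), ncol = 1), pops = rep("p1", 6))
  bs2 <- basic_stats(gm2)
  expect_equal(unname(bs2$Ho), 1)
  expect_lt(bs2$fis, 0)
  # a monomorphic locus contributes Ho = Hs = 0 and leaves FIS unchanged
  gm3 <- make_gm(cbind(c(0L, 1L, 1L, 2L), rep(0L, 4)), pops = rep("p1", 4))
  bs3 <- basic_stats(gm3)
  expect_equal(unname(bs3$hs_loc[2, 1]), 0)
  expect_equal(unname(bs3$fis), 1 / 7, tolerance = 1e-12)
  # single-individual populations are rejected
  gm4 <- make_gm(matrix(c(0L, 1L), ncol = 1), pops = c("a", "b"))
  expect_error(basic_stats(gm4), "at least 2")
})

test_that("Weir-Cockerham theta hits the boundary cases", {
  # fixed for opposite alleles: theta = 1
  gm <- make_gm(matrix(c(rep(0L, 4), rep(2L, 4)), ncol = 1),
                pops = rep(c("p1", "p2"), each = 4))
  expect_equal(wc_pairwise_fst(gm)$theta, 1)
  # identical genotype samples in both populations: theta <= 0
  g <- c(0L, 1L, 1L, 2L, 0L)
  gm2 <- make_gm(matrix(c(g, g), ncol = 1), pops = rep(c("p1", "p2"), each = 5))
  expect_lte(wc_pairwise_fst(gm2)$theta, 0)
  # monomorphic everywhere: undefined
  gm3 <- make_gm(matrix(rep(0L, 8), ncol = 2), pops = rep(c("p1", "p2"), each = 2))
  expect_error(wc_pairwise_fst(gm3), "monomorphic|variance")
})

test_that("multi-locus theta is the ratio of sums and matches the oracle", {
  set.seed(42)
  n1 <- 8; n2 <- 6
  dos <- matrix(rbinom((n1 + n2) * 10, 2,
                       rep(runif(10, 0.2, 0.8), each = n1 + n2)),
                nrow = n1 + n2)
  dos[sample(length(dos), 12)] <- NA  # missing calls included
  pop <- rep(c("p1", "p2"), c(n1, n2))
  gm <- make_gm(dos, pops = pop)
  fst <- wc_pairwise_fst(gm)
  expect_equal(fst$theta, oracle_wc_theta(dos, pop), tolerance = 1e-12)
  # component-level agreement
  for (j in c(1, 5, 10)) {
    ora <- oracle_wc_locus(dos[, j], pop)
    expect_equal(fst$components$a[j], unname(ora["a"]), tolerance = 1e-12)
    expect_equal(fst$components$abc[j], unname(ora["abc"]), tolerance = 1e-12)
  }
  # ratio of sums, not mean of per-locus ratios
  mean_of_ratios <- mean(fst$theta_by_locus, na.rm = TRUE)
  expect_gt(abs(fst$theta - mean_of_ratios), 1e-6)
})

test_that("multi-allelic theta matches the per-allele oracle", {
  cfg <- genotype_sim_config(n_loci = 10, n_per_pop = c(15, 10),
                             theta_background = 0.1, seed = 31,
                             missing_rate = 0.05)
  ms <- sim_microsat_genotypes(cfg, n_alleles = 5)
  gm <- ms$genotypes
  expect_equal(wc_pairwise_fst(gm)$theta,
               oracle_wc_theta_msat(gm$a1, gm$a2, gm$individuals$pop),
               tolerance = 1e-12)
})

test_that("theta is invariant to allele relabeling and individual order", {
  sg <- sim_snp_genotypes(genotype_sim_config(n_loci = 100, n_per_pop = 10,
                                              seed = 19))
  gm <- sg$genotypes
  t0 <- wc_pairwise_fst(gm)$theta
  # swap reference/alternate at a random subset of loci
  gm2 <- gm
  set.seed(1)
  flip <- sample(100, 40)
  gm2$dosage[, flip] <- 2L - gm2$dosage[, flip]
  expect_equal(wc_pairwise_fst(gm2)$theta, t0, tolerance = 1e-12)
  # permute individuals
  gm3 <- gm
  perm <- sample(dim(gm)[1])
  gm3$dosage <- gm3$dosage[perm, ]
  gm3$individuals <- gm3$individuals[perm, ]
  expect_equal(wc_pairwise_fst(gm3)$theta, t0, tolerance = 1e-12)
})

test_that("allele-matching betas behave on extreme and null cases", {
  # fixed opposite alleles: beta = 1 in both populations
  gm <- make_gm(matrix(c(rep(0L, 4), rep(2L, 4)), ncol = 1),
                pops = rep(c("p1", "p2"), each = 4))
  b <- population_specific_fst(gm)
  expect_equal(unname(b$beta), c(1, 1))
  # two samples from one panmictic population: betas near zero
  sg <- sim_snp_genotypes(genotype_sim_config(n_loci = 2000, n_per_pop = 20,
                                              theta_background = 0, seed = 3))
  b2 <- population_specific_fst(sg$genotypes)
  expect_lt(max(abs(b2$beta)), 0.02)
  # overall beta is the unweighted mean
  expect_equal(b2$beta_overall, mean(b2$beta))
})

test_that("locus bootstrap is deterministic and degenerates correctly", {
  sg <- sim_snp_genotypes(genotype_sim_config(n_loci = 150, n_per_pop = 10,
                                              seed = 37))
  fst <- wc_pairwise_fst(sg$genotypes)
  ci1 <- bootstrap_ci(fst, n_boot = 300, seed = 9)
  ci2 <- bootstrap_ci(fst, n_boot = 300, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$ci_high)
  # constant per-locus statistic: zero-width interval
  one <- make_gm(matrix(c(rep(0L, 4), rep(2L, 4)), ncol = 1),
                 pops = rep(c("p1", "p2"), each = 4))
  dup <- make_gm(matrix(c(rep(0L, 4), rep(2L, 4)), nrow = 8, ncol = 5),
                 pops = rep(c("p1", "p2"), each = 4))
  fst_dup <- wc_pairwise_fst(dup)
  ci3 <- bootstrap_ci(fst_dup, n_boot = 100, seed = 2)
  expect_equal(ci3$ci_low, ci3$ci_high)
  expect_equal(ci3$ci_low, wc_pairwise_fst(one)$theta)
  # per-population statistics get one CI row each
  bs <- basic_stats(sg$genotypes)
  cib <- bootstrap_ci(bs, n_boot = 200, seed = 4)
  expect_identical(nrow(cib), 6L)  # Ho, Hs, FIS x 2 populations
  expect_true(all(cib$ci_low <= cib$ci_high))
})

test_that("PCA separates diverged populations and orders variance", {
  sg <- sim_snp_genotypes(genotype_sim_config(n_loci = 300, n_per_pop = 12,
                                              theta_background = 0.3,
                                              seed = 41))
  pc <- pca_genotypes(sg$genotypes)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  pop <- sg$genotypes$individuals$pop
  s1 <- pc$scores[, 1]
  expect_true(max(s1[pop == "pop1"]) < min(s1[pop == "pop2"]) ||
                min(s1[pop == "pop1"]) > max(s1[pop == "pop2"]))
  # duplicated individual gets identical scores
  gm <- sg$genotypes
  gm$dosage <- rbind(gm$dosage, gm$dosage[1, ])
  gm$individuals <- rbind(gm$individuals, gm$individuals[1, ])
  pc2 <- pca_genotypes(gm)
  expect_equal(pc2$scores[1, ], pc2$scores[nrow(pc2$scores), ],
               tolerance = 1e-8)
  # zero-variance input is rejected
  flat <- make_gm(matrix(1L, 4, 3))
  expect_error(pca_genotypes(flat), "zero-variance")
})

test_that("k-means reassignment recovers simulated populations", {
  sg <- sim_snp_genotypes(genotype_sim_config(n_loci = 800, n_per_pop = c(14, 10),
                                              theta_background = 0.3,
                                              seed = 43))
  pc <- pca_genotypes(sg$genotypes)
  expect_warning(assign_clusters(pc, k = 2, n_pcs = 75, seed = 1), "clamped")
  labels <- suppressWarnings(assign_clusters(pc, k = 2, n_pcs = 75, seed = 1))
  pop <- sg$genotypes$individuals$pop
  # perfect agreement up to label permutation; cluster 1 is the larger
  expect_identical(length(unique(labels[pop == "pop1"])), 1L)
  expect_identical(length(unique(labels[pop == "pop2"])), 1L)
  expect_identical(unique(labels[pop == "pop1"]), 1L)
  expect_identical(assign_clusters(pc, k = 1, n_pcs = 5), rep(1L, 24))
  expect_error(assign_clusters(pc, k = 30, n_pcs = 5), "clusters")
})
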