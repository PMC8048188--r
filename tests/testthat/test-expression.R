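test_that("TMM factors normalize composition with geometric mean one", {
  design <- data.frame(sample = paste0("s", 1:3),
                       population = "CV", timepoint = 0)
  base <- matrix(rpois(600, 50), ncol = 3)
  rownames(base) <- paste0("g", 1:200)
  # identical columns: all factors 1
  same <- count_matrix(cbind(base[, 1], base[, 1], base[, 1]), design)
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-10)
  # a column that is a pure 2x scaling of another: M-values all zero,
  # so factors stay 1 and CPM-normalized abundances already match
  scaled <- count_matrix(cbind(base[, 1], 2L * base[, 1], base[, 3]), design)
  f <- tmm_factors(scaled)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  lib <- colSums(scaled$counts)
  norm <- t(t(scaled$counts) / (lib * f))
  expect_equal(norm[, 1], norm[, 2], tolerance = 1e-8)
  # all-zero sample is rejected
  zero <- count_matrix(cbind(base[, 1], 0L * base[, 1]), design[1:2, ])
  expect_error(tmm_factors(zero), "all-zero")
})

test_that("the expression filter requires full detection in one cell", {
  design <- data.frame(sample = paste0("s", 1:6),
                       population = rep(c("CV", "SP"), each = 3),
                       timepoint = rep(0, 6))
  counts <- rbind(
    g1 = c(5L, 3L, 8L, 0L, 0L, 0L),  # complete in CV:0 -> kept
    g2 = c(5L, 0L, 8L, 4L, 0L, 2L),  # a zero in every cell -> dropped
    g3 = c(0L, 0L, 0L, 0L, 0L, 0L))  # all zero -> dropped
  cm <- count_matrix(counts, design)
  kept <- filter_expressed(cm)
  expect_identical(rownames(kept$counts), "g1")
})

test_that("DGE log2 fold changes match an unshrunk NB maximum-likelihood fit", {
  cfg <- expression_sim_config(n_genes = 60, seed = 15,
                               baseline_logmean_dist = c(7, 0.5),
                               planted_dge = data.frame(gene = 1:10,
                                                        cell = "SP:168",
                                                        log2fc = 1.5))
  se <- sim_expression(cfg)
  cm <- filter_expressed(se$counts)
  dge <- dge_fit_test(cm, contrasts = "between_168")
  cells <- design_cells(cm$design)
  nf <- tmm_factors(cm)
  off <- log(colSums(cm$counts) * nf)
  for (g in c(sprintf("gene%05d", 1:10), sprintf("gene%05d", 30:34))) {
    y <- cm$counts[g, ]
    fit <- suppressWarnings(
      MASS::glm.nb(y ~ 0 + cells + offset(off)))
    ml_lfc <- (coef(fit)["cellsSP:168"] - coef(fit)["cellsCV:168"]) / log(2)
    expect_lt(abs(dge$log2fc[dge$gene == g] - ml_lfc), 0.05)
  }
})

test_that("DGE contrasts are antisymmetric under population relabeling", {
  se <- sim_expression(expression_sim_config(
    n_genes = 100, seed = 16,
    planted_dge = data.frame(gene = 1:5, cell = "SP:168", log2fc = 2)))
  cm <- filter_expressed(se$counts)
  dge <- dge_fit_test(cm, contrasts = "between_168")
  swapped <- cm
  swapped$design$population <- ifelse(cm$design$population == "CV", "SP", "CV")
  dge_sw <- dge_fit_test(swapped, contrasts = "between_168")
  m <- match(dge$gene, dge_sw$gene)
  expect_equal(dge$log2fc, -dge_sw$log2fc[m], tolerance = 1e-8)
  expect_equal(dge$p, dge_sw$p[m], tolerance = 1e-8)
})

test_that("DGE is calibrated on null data and powered on planted effects", {
  null_se <- sim_expression(expression_sim_config(n_genes = 800, seed = 18))
  dge0 <- dge_fit_test(filter_expressed(null_se$counts),
                       contrasts = "between_72")
  expect_gte(mean(dge0$p < 0.05), 0.02)
  expect_lte(mean(dge0$p < 0.05), 0.08)
  se <- sim_expression(expression_sim_config(
    n_genes = 500, seed = 45,
    planted_dge = data.frame(gene = 1:25, cell = "SP:168", log2fc = 2)))
  dge <- dge_fit_test(filter_expressed(se$counts), contrasts = "between_168")
  planted <- dge$gene %in% sprintf("gene%05d", 1:25)
  expect_gte(mean(dge$q[planted] < 0.05), 0.8)
  expect_error(dge_fit_test(filter_expressed(se$counts), contrasts = "nope"),
               "unknown contrast")
})

test_that("DEU flags usage shifts but not pure abundance changes", {
  se <- sim_expression(expression_sim_config(
    n_genes = 250, seed = 46,
    planted_dge = data.frame(gene = 21:28, cell = "SP:168", log2fc = 2),
    planted_deu = data.frame(gene = 1:15, cell = "SP:168", exon = 1,
                             usage_ref = 0.5, usage_alt = 0.1)))
  deu <- deu_fit_test(se$exon_counts, contrasts = "between_168")
  deu_genes <- sprintf("gene%05d", 1:15)
  dge_genes <- sprintf("gene%05d", 21:28)
  expect_gte(mean(deu$q[deu$gene %in% deu_genes] < 0.05), 0.6)
  # scaling all exons together is not differential usage
  expect_true(all(deu$q[deu$gene %in% dge_genes] > 0.05))
})

test_that("gene-level DEU p-values are the Simes combination of exon p-values", {
  # Simes over the E-1 smallest exon p-values: because the per-exon
  # relative contrasts sum to zero within a gene, only E-1 of them are
  # free, and the largest p-value carries no extra information
  simes <- function(p) {
    E <- length(p)
    ps <- sort(p)[seq_len(E - 1)]
    min(pmin(ps * (E - 1) / seq_len(E - 1), 1))
  }
  se <- sim_expression(expression_sim_config(n_genes = 150, seed = 20))
  ecm <- se$exon_counts
  cells <- design_cells(ecm$design)
  mm <- stats::model.matrix(~ 0 + cells)
  colnames(mm) <- levels(cells)
  y <- edgeR::DGEList(ecm$counts)
  y <- edgeR::calcNormFactors(y)
  v <- limma::voom(y, mm)
  fit <- limma::lmFit(v, mm)
  cons <- plasticity_contrasts(ecm$design)["between_168"]
  cfit <- limma::contrasts.fit(fit, do.call(cbind, cons))
  sp <- limma::diffSplice(cfit, geneid = ecm$gene, exonid = ecm$exon,
                          verbose = FALSE)
  exon_tab <- limma::topSplice(sp, coef = 1, test = "t", number = Inf)
  manual <- vapply(split(exon_tab$P.Value, exon_tab$GeneID), simes, 0)
  deu <- deu_fit_test(ecm, contrasts = "between_168")
  m <- match(deu$gene, names(manual))
  expect_equal(deu$p, unname(manual[m]), tolerance = 1e-10)
})

test_that("the DEU null controls type-I error at the 0.05 level", {
  se <- sim_expression(expression_sim_config(n_genes = 800, seed = 24))
  deu <- deu_fit_test(se$exon_counts, contrasts = "between_0")
  # conservative by construction (shared gene-level noise cancels in the
  # exon contrast but inflates the exon variance estimate): never above
  # nominal, and no false discoveries after BH
  expect_lte(mean(deu$p < 0.05), 0.07)
  expect_identical(sum(deu$q < 0.05), 0L)
})

test_that("single-exon genes are excluded from DEU with a message", {
  design <- default_design_cells()
  design <- data.frame(sample = paste0("s", 1:32),
                       population = rep(c("CV", "SP"), each = 16),
                       timepoint = rep(rep(c(0, 72, 168), times = c(6, 5, 5)), 2))
  set.seed(9)
  counts <- matrix(rpois(3 * 32, 60), nrow = 3)
  rownames(counts) <- c("gA:1", "gA:2", "gB:1")
  ecm <- exon_count_matrix(counts, design)
  expect_message(res <- deu_fit_test(ecm, contrasts = "between_0"),
                 "single-exon")
  expect_false("gB" %in% res$gene)
})

test_that("the GEV dispersion test is calibrated, filters CV, and has power", {
  cells <- data.frame(population = c("CV", "SP"), timepoint = 0, n = 16)
  null_se <- sim_expression(expression_sim_config(n_genes = 500,
                                                  groups = cells, seed = 43))
  gev0 <- gev_fit_test(null_se$counts,
                       groups = null_se$counts$design$population)
  expect_gte(mean(gev0$p < 0.05), 0.025)
  expect_lte(mean(gev0$p < 0.05), 0.085)
  se <- sim_expression(expression_sim_config(
    n_genes = 300, groups = cells, seed = 101,
    planted_gev = data.frame(gene = 1:20, cell = "SP:0", ratio = 4)))
  gev <- gev_fit_test(se$counts, groups = se$counts$design$population)
  planted <- gev$gene %in% sprintf("gene%05d", 1:20)
  expect_gte(mean(gev$p[planted] < 0.05), 0.5)
  expect_lte(mean(gev$p[!planted] < 0.05), 0.12)
  expect_gte(sum(gev$q[planted] < 0.05), 1)
})

test_that("the GEV CV window removes inflated-variability genes", {
  design <- data.frame(sample = paste0("s", 1:32),
                       population = rep(c("CV", "SP"), each = 16),
                       timepoint = 0)
  set.seed(12)
  ordinary <- rnbinom(32, mu = 100, size = 1 / 0.1)  # CV ~ 0.33
  inflated <- rnbinom(32, mu = 100, size = 1 / 25)   # CV ~ 5
  cm <- count_matrix(rbind(gA = ordinary, gB = inflated,
                           gC = rnbinom(32, mu = 80, size = 1 / 0.1)),
                     design)
  gev <- gev_fit_test(cm, groups = design$population)
  expect_true("gA" %in% gev$gene)
  expect_false("gB" %in% gev$gene)
  expect_gte(attr(gev, "n_cv_filtered"), 1L)
})

test_that("DGE results are invariant to gene and sample order", {
  se <- sim_expression(expression_sim_config(n_genes = 80, seed = 26))
  cm <- filter_expressed(se$counts)
  dge <- dge_fit_test(cm, contrasts = "between_168")
  set.seed(1)
  gperm <- sample(nrow(cm$counts))
  sperm <- sample(ncol(cm$counts))
  cm2 <- cm
  cm2$counts <- cm$counts[gperm, sperm]
  cm2$design <- cm$design[sperm, ]
  dge2 <- dge_fit_test(cm2, contrasts = "between_168")
  m <- match(dge$gene, dge2$gene)
  expect_equal(dge$p, dge2$p[m], tolerance = 1e-8)
  expect_equal(dge$log2fc, dge2$log2fc[m], tolerance = 1e-8)
})
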