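# Per-population allele summaries.
#
# SNP path (vectorized): for each locus and population, the number of
# genotyped individuals, the alternate-allele frequency and the observed
# heterozygote frequency. Microsatellite path (per-locus): population x
# allele count matrices plus per-allele heterozygote-carrier counts.
.snp_pop_stats <- function(dosage, pop) {
  lev <- levels(pop)
  lapply(lev, function(k) {
    d <- dosage[pop == k, , drop = FALSE]
    n <- colSums(!is.na(d))
    list(n = n,
         p = ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_))
  })
}

.msat_locus_stats <- function(gm, pop, j) {
  lev <- levels(pop)
  K <- max(c(gm$a1[, j], gm$a2[, j]), na.rm = TRUE)
  counts <- matrix(0, length(lev), K)
  hets <- matrix(0, length(lev), K)
  n <- numeric(length(lev))
  for (i in seq_along(lev)) {
    sel <- pop == lev[i] & !is.na(gm$a1[, j])
    a1 <- gm$a1[sel, j]; a2 <- gm$a2[sel, j]
    n[i] <- sum(sel)
    counts[i, ] <- tabulate(a1, K) + tabulate(a2, K)
    het <- a1 != a2
    for (k in seq_len(K))
      hets[i, k] <- sum(het & (a1 == k | a2 == k))
  }
  list(n = n, counts = counts, hets = hets)
}

#' Observed heterozygosity, gene diversity and FIS
#'
#' Per locus and population: `Ho` is the heterozygote fraction among
#' genotyped individuals and `Hs` is Nei's (1987) unbiased gene
#' diversity `n/(n-1) * (1 - sum p_k^2 - Ho/(2n))`. Population FIS is
#' `1 - mean(Ho)/mean(Hs)` over loci (multi-locus means; loci with
#' undefined `Hs` are excluded). Works for biallelic dosages and
#' multi-allelic allele pairs.
#'
#' @param gm a [genotype_matrix()].
#' @param pops optional population labels (defaults to
#'   `gm$individuals$pop`).
#' @return An object of class `popgen_basic`: per-population `Ho`, `Hs`,
#'   `fis` (multi-locus), and per-locus matrices `ho_loc`, `hs_loc`
#'   (loci x populations) retained for bootstrapping.
#' @export
basic_stats <- function(gm, pops = NULL) {
  pop <- .pop_factor(gm, pops)
  if (any(table(pop) < 2))
    stop("each population needs at least 2 individuals (Hs undefined)")
  L <- dim(gm)[2]
  lev <- levels(pop)
  ho <- matrix(NA_real_, L, length(lev), dimnames = list(NULL, lev))
  hs <- ho
  if (gm$type == "snp") {
    st <- .snp_pop_stats(gm$dosage, pop)
    for (i in seq_along(lev)) {
      n <- st[[i]]$n; p <- st[[i]]$p; h <- st[[i]]$h
      ok <- n > 1
      ho[ok, i] <- h[ok]
      hs[ok, i] <- n[ok] / (n[ok] - 1) *
        (1 - p[ok]^2 - (1 - p[ok])^2 - h[ok] / (2 * n[ok]))
    }
  } else {
    for (j in seq_len(L)) {
      st <- .msat_locus_stats(gm, pop, j)
      for (i in seq_along(lev)) {
        n <- st$n[i]
        if (n > 1) {
          p <- st$counts[i, ] / (2 * n)
          hobs <- sum(st$hets[i, ]) / (2 * n)  # each het carries 2 alleles
          ho[j, i] <- hobs
          hs[j, i] <- n / (n - 1) * (1 - sum(p^2) - hobs / (2 * n))
        }
      }
    }
  }
  mean_ho <- colMeans(ho, na.rm = TRUE)
  # Hs undefined (NA) loci excluded from both means for FIS consistency
  mean_hs <- colMeans(hs, na.rm = TRUE)
  fis <- 1 - mean_ho / mean_hs
  structure(list(Ho = mean_ho, Hs = mean_hs, fis = fis,
                 ho_loc = ho, hs_loc = hs, populations = lev),
            class = "popgen_basic")
}

#' @export
print.popgen_basic <- function(x, ...) {
  cat("Per-population diversity (multi-locus means):\n")
  print(data.frame(population = x$populations, Ho = x$Ho, Hs = x$Hs,
                   FIS = x$fis, row.names = NULL))
  invisible(x)
}

# Weir & Cockerham (1984) variance components for one allele across r
# populations; all arguments are locus-vectors (or matrices with one
# column per population).
.wc_components <- function(n, p, h) {
  # n, p, h: matrices loci x r
  r <- ncol(n)
  nbar <- rowMeans(n)
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham FST
#'
#' Weir & Cockerham's (1984) theta for two populations. Variance
#' components `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals) are computed per allele and
#' locus from sample sizes, allele frequencies and heterozygote
#' frequencies; the multi-locus estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)` over all alleles and loci. Multi-allelic
#' loci contribute one term per allele. Per-locus components are
#' retained for bootstrapping.
#'
#' @param gm a [genotype_matrix()].
#' @param pops optional population labels; exactly two populations, each
#'   with at least two individuals.
#' @return An object of class `wc_fst`: `theta`, per-locus data frame
#'   `components` (`a`, `abc` summed over alleles), `theta_by_locus`.
#' @export
wc_pairwise_fst <- function(gm, pops = NULL) {
  pop <- .pop_factor(gm, pops)
  if (nlevels(pop) != 2) stop("pairwise FST needs exactly 2 populations")
  if (any(table(pop) < 2)) stop("each population needs >= 2 individuals")
  L <- dim(gm)[2]
  a_loc <- numeric(L); abc_loc <- numeric(L)
  if (gm$type == "snp") {
    st <- .snp_pop_stats(gm$dosage, pop)
    n <- cbind(st[[1]]$n, st[[2]]$n)
    p <- cbind(st[[1]]$p, st[[2]]$p)
    h <- cbind(st[[1]]$h, st[[2]]$h)
    ok <- rowSums(n > 0) == 2 & rowMeans(n) > 1
    comp <- .wc_components(n[ok, , drop = FALSE], p[ok, , drop = FALSE],
                           h[ok, , drop = FALSE])
    # the two alleles of a biallelic locus contribute equal components
    a_loc[ok] <- 2 * comp$a
    abc_loc[ok] <- 2 * (comp$a + comp$b + comp$c)
    a_loc[!ok] <- NA; abc_loc[!ok] <- NA
  } else {
    for (j in seq_len(L)) {
      st <- .msat_locus_stats(gm, pop, j)
      if (any(st$n < 1) || mean(st$n) <= 1) { a_loc[j] <- NA; abc_loc[j] <- NA; next }
      K <- ncol(st$counts)
      p <- st$counts / (2 * st$n)
      h <- st$hets / st$n
      aa <- 0; ss <- 0
      for (k in seq_len(K)) {
        comp <- .wc_components(matrix(st$n, 1), matrix(p[, k], 1),
                               matrix(h[, k], 1))
        aa <- aa + comp$a
        ss <- ss + comp$a + comp$b + comp$c
      }
      a_loc[j] <- aa; abc_loc[j] <- ss
    }
  }
  num <- sum(a_loc, na.rm = TRUE); den <- sum(abc_loc, na.rm = TRUE)
  if (!is.finite(den) || den == 0)
    stop("FST undefined: zero total variance (monomorphic data?)")
  structure(list(theta = num / den,
                 components = data.frame(a = a_loc, abc = abc_loc),
                 theta_by_locus = a_loc / abc_loc,
                 populations = levels(pop)),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham pairwise FST (%s vs %s): %.5f\n",
              x$populations[1], x$populations[2], x$theta))
  invisible(x)
}

#' Population-specific FST (allele-matching betas)
#'
#' Coalescent-flavoured population-specific FST via allele-matching
#' proportions: `M_i` is the sample-size-corrected probability that two
#' distinct alleles drawn within population i match,
#' `M_B` the mean matching probability between population pairs, and
#' `beta_i = (M_i - M_B) / (1 - M_B)` with matching proportions averaged
#' over loci before taking the ratio. The overall beta is the unweighted
#' mean of the `beta_i`.
#'
#' @param gm a [genotype_matrix()].
#' @param pops optional population labels; at least two populations.
#' @return An object of class `beta_fst`: `beta` (per population),
#'   `beta_overall`, and per-locus matrices `m_within` (loci x pops),
#'   `m_between` (loci) for bootstrapping.
#' @export
population_specific_fst <- function(gm, pops = NULL) {
  pop <- .pop_factor(gm, pops)
  r <- nlevels(pop)
  if (r < 2) stop("need at least 2 populations")
  L <- dim(gm)[2]
  lev <- levels(pop)
  mw <- matrix(NA_real_, L, r, dimnames = list(NULL, lev))
  mb <- rep(NA_real_, L)
  if (gm$type == "snp") {
    st <- .snp_pop_stats(gm$dosage, pop)
    pmat <- do.call(cbind, lapply(st, `[[`, "p"))
    nmat <- do.call(cbind, lapply(st, `[[`, "n"))
    for (i in seq_len(r)) {
      N <- 2 * nmat[, i]
      cA <- pmat[, i] * N
      ok <- nmat[, i] > 1
      mw[ok, i] <- (cA[ok] * (cA[ok] - 1) +
                      (N[ok] - cA[ok]) * (N[ok] - cA[ok] - 1)) /
        (N[ok] * (N[ok] - 1))
    }
    pairs <- utils::combn(r, 2)
    mb_mat <- sapply(seq_len(ncol(pairs)), function(q) {
      i <- pairs[1, q]; j <- pairs[2, q]
      pmat[, i] * pmat[, j] + (1 - pmat[, i]) * (1 - pmat[, j])
    })
    mb <- rowMeans(as.matrix(mb_mat))
  } else {
    pairs <- utils::combn(r, 2)
    for (l in seq_len(L)) {
      st <- .msat_locus_stats(gm, pop, l)
      N <- 2 * st$n
      for (i in seq_len(r))
        if (st$n[i] > 1)
          mw[l, i] <- sum(st$counts[i, ] * (st$counts[i, ] - 1)) /
            (N[i] * (N[i] - 1))
      pv <- st$counts / pmax(N, 1)
      mb[l] <- mean(sapply(seq_len(ncol(pairs)), function(q)
        sum(pv[pairs[1, q], ] * pv[pairs[2, q], ])))
    }
  }
  mb_bar <- mean(mb, na.rm = TRUE)
  if (mb_bar >= 1) stop("between-population matching is 1: beta undefined")
  beta <- (colMeans(mw, na.rm = TRUE) - mb_bar) / (1 - mb_bar)
  structure(list(beta = beta, beta_overall = mean(beta),
                 m_within = mw, m_between = mb, populations = lev),
            class = "beta_fst")
}

#' @export
print.beta_fst <- function(x, ...) {
  cat("Population-specific FST (allele-matching beta):\n")
  print(data.frame(population = x$populations, beta = x$beta,
                   row.names = NULL))
  cat(sprintf("overall beta: %.5f\n", x$beta_overall))
  invisible(x)
}

#' Bootstrap confidence intervals over loci
#'
#' Percentile bootstrap resampling loci with replacement and
#' re-aggregating the stored per-locus components of an estimate
#' (variance components for FST, per-locus Ho/Hs for FIS, matching
#' proportions for beta). Replicates on which the statistic is undefined
#' are skipped and counted; more than 10% skipped is an error.
#'
#' @param x a `wc_fst`, `popgen_basic` or `beta_fst` object.
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed (required; resampling is deterministic
#'   under it).
#' @param ... unused.
#' @return A data frame with one row per statistic: `statistic`,
#'   `population` (or `NA`), `estimate`, `ci_low`, `ci_high`, plus
#'   attributes `n_boot`, `level`, `seed`, `n_skipped`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000, level = 0.95, seed, ...) {
  UseMethod("bootstrap_ci")
}

.boot_engine <- function(L, n_boot, level, seed, stat_fun, est, labels,
                         statistic, populations) {
  if (L < 2) stop("bootstrap needs >= 2 loci")
  set.seed(seed)
  idx <- matrix(sample.int(L, L * n_boot, replace = TRUE), ncol = n_boot)
  reps <- apply(idx, 2, stat_fun)
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  bad <- apply(reps, 2, function(z) any(!is.finite(z)))
  if (mean(bad) > 0.10)
    stop(sprintf("statistic undefined on %.0f%% of bootstrap replicates",
                 100 * mean(bad)))
  reps <- reps[, !bad, drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- t(apply(reps, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  out <- data.frame(statistic = statistic, population = populations,
                    estimate = est, ci_low = ci[, 1], ci_high = ci[, 2],
                    row.names = NULL)
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  attr(out, "seed") <- seed
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.wc_fst <- function(x, n_boot = 1000, level = 0.95, seed, ...) {
  comp <- x$components
  .boot_engine(nrow(comp), n_boot, level, seed,
               stat_fun = function(i) {
                 den <- sum(comp$abc[i], na.rm = TRUE)
                 if (den == 0) NA_real_ else sum(comp$a[i], na.rm = TRUE) / den
               },
               est = x$theta, labels = NULL,
               statistic = "fst_wc_pairwise", populations = NA_character_)
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.popgen_basic <- function(x, n_boot = 1000, level = 0.95, seed, ...) {
  r <- length(x$populations)
  .boot_engine(nrow(x$ho_loc), n_boot, level, seed,
               stat_fun = function(i) {
                 ho <- colMeans(x$ho_loc[i, , drop = FALSE], na.rm = TRUE)
                 hs <- colMeans(x$hs_loc[i, , drop = FALSE], na.rm = TRUE)
                 c(ho, hs, 1 - ho / hs)
               },
               est = c(x$Ho, x$Hs, x$fis), labels = NULL,
               statistic = rep(c("Ho", "Hs", "FIS"), each = r),
               populations = rep(x$populations, 3))
}

#' @rdname bootstrap_ci
#' @export
bootstrap_ci.beta_fst <- function(x, n_boot = 1000, level = 0.95, seed, ...) {
  .boot_engine(nrow(x$m_within), n_boot, level, seed,
               stat_fun = function(i) {
                 mbb <- mean(x$m_between[i], na.rm = TRUE)
                 if (mbb >= 1) return(rep(NA_real_, ncol(x$m_within)))
                 (colMeans(x$m_within[i, , drop = FALSE], na.rm = TRUE) - mbb) /
                   (1 - mbb)
               },
               est = x$beta, labels = NULL,
               statistic = "fst_pop_specific", populations = x$populations)
}

#' Principal components of a genotype matrix
#'
#' Dosages are mean-imputed at missing entries and column-centered (no
#' variance scaling) before decomposition.
#'
#' @param gm a SNP-encoded [genotype_matrix()] with at least 2
#'   individuals and 2 loci.
#' @return An object of class `pca_result`: `scores` (individuals x
#'   components), `variance_explained`, `loadings`.
#' @export
pca_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "snp")
  d <- dim(gm)
  if (d[1] < 2 || d[2] < 2) stop("need >= 2 individuals and >= 2 loci")
  x <- gm$dosage
  storage.mode(x) <- "double"
  cm <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- cm[nas[, 2]]
  x <- sweep(x, 2, colMeans(x))
  if (all(abs(x) < 1e-12)) stop("zero-variance genotype matrix")
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, variance_explained = ve,
                 loadings = pc$rotation),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d individuals, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_explained[1],
              100 * (x$variance_explained[2] %||% NA)))
  invisible(x)
}

#' K-means cluster reassignment on PCA scores
#'
#' K-means with multiple restarts on the first `n_pcs` score columns;
#' labels are renumbered so cluster 1 is the largest.
#'
#' @param pca a [pca_genotypes()] result.
#' @param k number of clusters.
#' @param n_pcs number of leading components to use (clamped, with a
#'   warning, to those available).
#' @param seed integer seed.
#' @return Integer cluster labels, one per individual.
#' @export
assign_clusters <- function(pca, k = 2, n_pcs = 75, seed = 1L) {
  n <- nrow(pca$scores)
  if (k > n) stop("more clusters than individuals")
  if (n_pcs > ncol(pca$scores)) {
    warning(sprintf("n_pcs clamped from %d to %d available components",
                    n_pcs, ncol(pca$scores)))
    n_pcs <- ncol(pca$scores)
  }
  if (k == 1) return(rep(1L, n))
  set.seed(seed)
  km <- kmeans(pca$scores[, seq_len(n_pcs), drop = FALSE], centers = k,
               nstart = 25)
  sizes <- table(km$cluster)
  relab <- order(sizes, decreasing = TRUE)
  match(km$cluster, relab)
}
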