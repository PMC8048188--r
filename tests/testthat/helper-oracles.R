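# Independent brute-force oracles used to verify the package's
# estimators. These deliberately re-derive everything from first
# principles (scalar loops, explicit enumeration) rather than sharing
# code with the implementation.

# Exact HWE p-value by full enumeration of genotype tables compatible
# with the observed allele counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  weights <- c()
  hets <- c()
  for (h in 0:n) {
    aa <- (nA - h) / 2
    bb <- (2 * n - nA - h) / 2
    if (aa >= 0 && bb >= 0 && aa == round(aa) && bb == round(bb)) {
      weights <- c(weights, 2^h * factorial(n) /
                     (factorial(aa) * factorial(h) * factorial(bb)))
      hets <- c(hets, h)
    }
  }
  pr <- weights / sum(weights)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs + 1e-12])
}

# Literal BH step-up: q_(k) = min_{j >= k} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m))
    q[k] <- min(1, min(ps[k:m] * m / (k:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Weir-Cockerham (1984) per-locus variance components for a biallelic
# locus, written as explicit scalar loops over both alleles.
oracle_wc_locus <- function(dos, pop) {
  lev <- unique(pop)
  r <- length(lev)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    d <- dos[pop == lev[i]]
    d <- d[!is.na(d)]
    n[i] <- length(d)
    p[i] <- sum(d) / (2 * length(d))
    h[i] <- mean(d == 1)
  }
  total_a <- 0; total_abc <- 0
  for (allele in 1:2) {
    pa <- if (allele == 1) p else 1 - p
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * pa) / (r * nbar)
    s2 <- sum(n * (pa - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) * s2 / r -
                                (2 * nbar - 1) * hbar / (4 * nbar))
    cc <- hbar / 2
    total_a <- total_a + a
    total_abc <- total_abc + a + b + cc
  }
  c(a = total_a, abc = total_abc)
}

oracle_wc_theta <- function(dosage, pop) {
  comp <- sapply(seq_len(ncol(dosage)), function(j)
    oracle_wc_locus(dosage[, j], pop))
  sum(comp["a", ]) / sum(comp["abc", ])
}

# Multi-allelic WC theta from explicit allele-pair matrices.
oracle_wc_theta_msat <- function(a1, a2, pop) {
  lev <- unique(pop)
  r <- length(lev)
  tot_a <- 0; tot_abc <- 0
  for (j in seq_len(ncol(a1))) {
    K <- max(c(a1[, j], a2[, j]), na.rm = TRUE)
    n <- numeric(r)
    pk <- matrix(0, r, K); hk <- matrix(0, r, K)
    for (i in seq_len(r)) {
      sel <- pop == lev[i] & !is.na(a1[, j])
      x1 <- a1[sel, j]; x2 <- a2[sel, j]
      n[i] <- length(x1)
      for (k in 1:K) {
        pk[i, k] <- (sum(x1 == k) + sum(x2 == k)) / (2 * n[i])
        hk[i, k] <- mean(x1 != x2 & (x1 == k | x2 == k))
      }
    }
    for (k in 1:K) {
      nbar <- mean(n)
      nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
      pbar <- sum(n * pk[, k]) / (r * nbar)
      s2 <- sum(n * (pk[, k] - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * hk[, k]) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) * s2 / r -
                                  (2 * nbar - 1) * hbar / (4 * nbar))
      cc <- hbar / 2
      tot_a <- tot_a + a
      tot_abc <- tot_abc + a + b + cc
    }
  }
  tot_a / tot_abc
}

# Chi-square from expected counts.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Convenience constructor for small SNP genotype matrices.
make_gm <- function(dosage, pops = NULL, cluster = NULL, qual = NULL,
                    biallelic = NULL, gq = NULL) {
  L <- ncol(dosage)
  loci <- data.frame(id = paste0("L", seq_len(L)),
                     cluster = cluster %||% rep("c1", L),
                     qual = qual %||% rep(60, L),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  if (!is.null(biallelic)) loci$biallelic <- biallelic
  individuals <- data.frame(id = paste0("i", seq_len(nrow(dosage))),
                            stringsAsFactors = FALSE)
  if (!is.null(pops)) individuals$pop <- pops
  genotype_matrix(dosage = dosage, loci = loci, individuals = individuals,
                  gq = gq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
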