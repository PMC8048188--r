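#' Configuration for genotype simulation
#'
#' Parameters of the Balding-Nichols two-level model used to simulate
#' population samples of biallelic SNPs or multi-allelic microsatellites.
#' Each locus draws an ancestral allele frequency; each population then
#' draws its own frequency from a Beta (or Dirichlet) distribution whose
#' concentration is governed by a divergence parameter `theta` on the FST
#' scale, and genotypes are drawn with a within-population inbreeding
#' coefficient `f_is` deflating (or, if negative, inflating) the
#' heterozygote probability.
#'
#' Defaults mirror the study conditions the package's validation targets:
#' two populations of 16 individuals, 5000 loci, background divergence
#' 0.023 and no inbreeding.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (recycled to `n_pops`).
#' @param n_loci number of loci.
#' @param theta_background per-locus divergence parameter in `[0, 1)`;
#'   a scalar, or a vector of length `n_pops` for population-specific
#'   drift.
#' @param theta_selected divergence used for planted outlier loci
#'   (must be >= max of `theta_background`).
#' @param n_selected number of planted outlier loci.
#' @param f_is within-population inbreeding coefficient in `(-1, 1)`.
#' @param ancestral_maf_range interval within `(0, 1)` from which the
#'   ancestral allele frequency is drawn uniformly.
#' @param missing_rate fraction of calls set to missing, in `[0, 1)`.
#' @param cluster_size loci per transcript cluster (SNP loci are laid
#'   out in consecutive blocks of this size).
#' @param seed integer seed; all randomness in the simulator derives
#'   from it.
#'
#' @return A list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_pops = 2, n_per_pop = 16, n_loci = 5000,
                                theta_background = 0.023,
                                theta_selected = 0.4, n_selected = 0,
                                f_is = 0, ancestral_maf_range = c(0.1, 0.9),
                                missing_rate = 0, cluster_size = 5,
                                seed = 1L) {
  n_per_pop <- rep_len(n_per_pop, n_pops)
  theta_background <- rep_len(theta_background, n_pops)
  if (any(theta_background < 0) || any(theta_background >= 1))
    stop("theta_background must lie in [0, 1)")
  if (theta_selected < 0 || theta_selected >= 1)
    stop("theta_selected must lie in [0, 1)")
  if (n_selected > 0 && theta_selected < max(theta_background))
    stop("theta_selected must be >= theta_background")
  if (n_selected > n_loci) stop("n_selected must be <= n_loci")
  if (f_is <= -1 || f_is >= 1) stop("f_is must lie in (-1, 1)")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] >= ancestral_maf_range[2] ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] >= 1)
    stop("ancestral_maf_range must be an ordered interval within (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (any(n_per_pop < 1)) stop("populations must be non-empty")
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 theta_background = theta_background,
                 theta_selected = theta_selected, n_selected = n_selected,
                 f_is = f_is, ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate, cluster_size = cluster_size,
                 seed = as.integer(seed)),
            class = "genotype_sim_config")
}

# Balding-Nichols population frequency draw; theta = 0 returns the
# ancestral frequency exactly.
.bn_freq <- function(p, theta) {
  out <- p
  pos <- theta > 0
  if (length(theta) == 1L) pos <- rep(pos, length(p))
  th <- rep_len(theta, length(p))
  i <- which(pos)
  if (length(i))
    out[i] <- rbeta(length(i), p[i] * (1 - th[i]) / th[i],
                    (1 - p[i]) * (1 - th[i]) / th[i])
  out
}

# genotype draws with inbreeding: P(het) = 2p(1-p)(1-F),
# P(hom alt) = p^2 + F p(1-p).
.draw_dosage <- function(pk, n, f_is) {
  L <- length(pk)
  p_hom_alt <- pk^2 + f_is * pk * (1 - pk)
  p_het <- 2 * pk * (1 - pk) * (1 - f_is)
  u <- matrix(runif(n * L), nrow = n)
  g <- matrix(0L, n, L)
  PA <- matrix(rep(p_hom_alt, each = n), nrow = n)
  PH <- matrix(rep(p_het, each = n), nrow = n)
  g[u < PA + PH] <- 1L
  g[u < PA] <- 2L
  g
}

#' Simulate biallelic SNP genotypes under the Balding-Nichols model
#'
#' Draws, per locus, an ancestral allele frequency uniform on
#' `ancestral_maf_range`; per population, a frequency from
#' `Beta(p(1-theta)/theta, (1-p)(1-theta)/theta)`; then Hardy-Weinberg
#' genotypes adjusted for inbreeding `f_is`. The first `n_selected`
#' randomly chosen loci are planted at `theta_selected` and labelled
#' `"selected"` in the truth table. Loci are assigned to transcript
#' clusters in consecutive blocks of `cluster_size`.
#'
#' @param cfg a [genotype_sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()] of
#'   dosages with population labels, site qualities and genotype
#'   qualities) and `truth` (data frame: `locus`, `class`, `theta`,
#'   `ancestral_p`).
#' @export
sim_snp_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "genotype_sim_config"))
  seeds <- derive_seeds(cfg$seed, 3L, salt = 101L)
  L <- cfg$n_loci
  n_tot <- sum(cfg$n_per_pop)

  set.seed(seeds[1])
  p_anc <- runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  sel <- if (cfg$n_selected > 0) sort(sample.int(L, cfg$n_selected)) else integer(0)

  set.seed(seeds[2])
  dosage <- matrix(NA_integer_, n_tot, L)
  pop_lab <- rep(paste0("pop", seq_len(cfg$n_pops)), cfg$n_per_pop)
  theta_used <- matrix(rep(cfg$theta_background, each = L), nrow = L)
  if (length(sel)) theta_used[sel, ] <- cfg$theta_selected
  row0 <- 0L
  for (k in seq_len(cfg$n_pops)) {
    pk <- .bn_freq(p_anc, theta_used[, k])
    nk <- cfg$n_per_pop[k]
    dosage[row0 + seq_len(nk), ] <- .draw_dosage(pk, nk, cfg$f_is)
    row0 <- row0 + nk
  }

  set.seed(seeds[3])
  if (cfg$missing_rate > 0)
    dosage[matrix(runif(length(dosage)) < cfg$missing_rate,
                  nrow = n_tot)] <- NA_integer_
  qual <- round(runif(L, 45, 99), 1)
  gq <- matrix(sample(60:99, n_tot * L, replace = TRUE), n_tot, L)

  cluster <- paste0("cl", (seq_len(L) - 1L) %/% cfg$cluster_size + 1L)
  loci <- data.frame(id = sprintf("snp%06d", seq_len(L)), cluster = cluster,
                     qual = qual, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  individuals <- data.frame(id = sprintf("ind%03d", seq_len(n_tot)),
                            pop = pop_lab, stringsAsFactors = FALSE)
  truth <- data.frame(locus = loci$id,
                      class = ifelse(seq_len(L) %in% sel, "selected", "neutral"),
                      theta = theta_used[, 1],
                      ancestral_p = p_anc, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage = dosage, loci = loci,
                                   individuals = individuals, gq = gq),
       truth = truth)
}

#' Simulate multi-allelic microsatellite genotypes
#'
#' Multi-allelic Balding-Nichols: per locus, ancestral allele frequencies
#' from a symmetric Dirichlet(1); per population, frequencies from
#' `Dirichlet(ancestral * (1-theta)/theta)`; genotypes are unordered
#' allele pairs. Missing calls are inserted per call at
#' `cfg$missing_rate`.
#'
#' @param cfg a [genotype_sim_config()].
#' @param n_alleles number of alleles per locus (>= 2).
#' @return As [sim_snp_genotypes()], with a microsatellite-encoded
#'   [genotype_matrix()].
#' @export
sim_microsat_genotypes <- function(cfg, n_alleles = 8) {
  stopifnot(inherits(cfg, "genotype_sim_config"))
  if (n_alleles < 2) stop("n_alleles must be >= 2")
  seeds <- derive_seeds(cfg$seed, 2L, salt = 202L)
  L <- cfg$n_loci
  K <- n_alleles
  n_tot <- sum(cfg$n_per_pop)
  pop_lab <- rep(paste0("pop", seq_len(cfg$n_pops)), cfg$n_per_pop)

  set.seed(seeds[1])
  a1 <- matrix(NA_integer_, n_tot, L)
  a2 <- matrix(NA_integer_, n_tot, L)
  theta <- rep_len(cfg$theta_background, cfg$n_pops)
  for (l in seq_len(L)) {
    anc <- rgamma(K, 1); anc <- anc / sum(anc)
    row0 <- 0L
    for (k in seq_len(cfg$n_pops)) {
      fk <- if (theta[k] > 0) {
        g <- rgamma(K, anc * (1 - theta[k]) / theta[k]); g / sum(g)
      } else anc
      nk <- cfg$n_per_pop[k]
      a1[row0 + seq_len(nk), l] <- sample.int(K, nk, TRUE, fk)
      a2[row0 + seq_len(nk), l] <- sample.int(K, nk, TRUE, fk)
      row0 <- row0 + nk
    }
  }

  set.seed(seeds[2])
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n_tot * L) < cfg$missing_rate, n_tot, L)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }

  loci <- data.frame(id = sprintf("msat%02d", seq_len(L)),
                     cluster = sprintf("msat%02d", seq_len(L)),
                     qual = NA_real_, stringsAsFactors = FALSE)
  individuals <- data.frame(id = sprintf("ind%04d", seq_len(n_tot)),
                            pop = pop_lab, stringsAsFactors = FALSE)
  truth <- data.frame(locus = loci$id, class = "neutral",
                      theta = theta[1], stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(a1 = a1, a2 = a2, loci = loci,
                                   individuals = individuals),
       truth = truth)
}
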