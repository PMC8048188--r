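#' Genotype filter specification
#'
#' Thresholds of the SNP quality-control cascade. Defaults reproduce the
#' "overall" panel rules: site and genotype qualities strictly above 30,
#' minor allele frequency at least 0.05 (inclusive), at most 20% missing
#' calls per site, biallelic sites only. The Hardy-Weinberg and LD
#' thresholds are off (`NULL`) by default; set them (and
#' `max_site_missing = 0`) to obtain the "neutral" panel.
#'
#' @param min_site_quality retain sites with QUAL strictly greater.
#' @param min_genotype_quality calls with GQ below this are masked to
#'   missing before MAF/missingness are computed.
#' @param biallelic_only drop non-biallelic sites.
#' @param min_maf minimum minor allele frequency (inclusive), computed on
#'   non-missing calls after GQ masking.
#' @param max_site_missing maximum fraction of missing calls per site.
#' @param hwe_p_threshold loci with exact-test p below this are removed
#'   (`NULL` = no HWE filter).
#' @param ld_r2_threshold within-cluster LD pruning threshold in
#'   `(0, 1]` (`NULL` = no pruning).
#' @param max_individual_missing remove individuals with at least this
#'   many missing loci (`NULL` = keep all).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_site_quality = 30, min_genotype_quality = 30,
                        biallelic_only = TRUE, min_maf = 0.05,
                        max_site_missing = 0.20, hwe_p_threshold = NULL,
                        ld_r2_threshold = NULL,
                        max_individual_missing = NULL) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_site_missing >= 0, max_site_missing <= 1)
  if (!is.null(hwe_p_threshold))
    stopifnot(hwe_p_threshold >= 0, hwe_p_threshold <= 1)
  if (!is.null(ld_r2_threshold))
    stopifnot(ld_r2_threshold > 0, ld_r2_threshold <= 1)
  structure(list(min_site_quality = min_site_quality,
                 min_genotype_quality = min_genotype_quality,
                 biallelic_only = biallelic_only, min_maf = min_maf,
                 max_site_missing = max_site_missing,
                 hwe_p_threshold = hwe_p_threshold,
                 ld_r2_threshold = ld_r2_threshold,
                 max_individual_missing = max_individual_missing),
            class = "filter_spec")
}

#' Apply the site-level filter cascade
#'
#' Stages, in order: genotype-quality masking, site quality (strict
#' `>`), biallelic, minor allele frequency (inclusive `>=`), per-site
#' missingness (`<=`), and - when enabled in the spec - the
#' Hardy-Weinberg exact-test filter (pooled across populations) and
#' within-cluster LD pruning. Each stage keeps a subset of the previous
#' stage's loci and preserves their order; the cascade is idempotent.
#'
#' @param gm a SNP-encoded [genotype_matrix()].
#' @param spec a [filter_spec()].
#' @return The filtered [genotype_matrix()] (with low-GQ calls masked).
#' @export
apply_site_filters <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "snp",
            inherits(spec, "filter_spec"))
  if (dim(gm)[2] == 0) stop("empty genotype matrix")
  # 1. genotype-quality masking
  if (!is.null(gm$gq) && !is.null(spec$min_genotype_quality)) {
    mask <- !is.na(gm$gq) & gm$gq <= spec$min_genotype_quality
    gm$dosage[mask] <- NA_integer_
  }
  keep <- rep(TRUE, dim(gm)[2])
  # 2. site quality (strictly greater than)
  if (!is.null(spec$min_site_quality) && !is.null(gm$loci$qual))
    keep <- keep & (is.na(gm$loci$qual) | gm$loci$qual > spec$min_site_quality)
  # 3. biallelic
  if (isTRUE(spec$biallelic_only) && !is.null(gm$loci$biallelic))
    keep <- keep & gm$loci$biallelic
  # 4. MAF (inclusive) on non-missing calls
  n_ok <- colSums(!is.na(gm$dosage))
  p <- colSums(gm$dosage, na.rm = TRUE) / (2 * pmax(n_ok, 1))
  maf <- pmin(p, 1 - p)
  keep <- keep & n_ok > 0 & maf >= spec$min_maf
  # 5. missingness
  keep <- keep & .missing_by_locus(gm) <= spec$max_site_missing
  gm2 <- subset_loci(gm, keep)
  # 6. HWE (pooled)
  if (!is.null(spec$hwe_p_threshold) && dim(gm2)[2] > 0) {
    d <- gm2$dosage
    pvals <- vapply(seq_len(ncol(d)), function(j) {
      hwe_exact_test(sum(d[, j] == 0, na.rm = TRUE),
                     sum(d[, j] == 1, na.rm = TRUE),
                     sum(d[, j] == 2, na.rm = TRUE))
    }, 0)
    gm2 <- subset_loci(gm2, pvals >= spec$hwe_p_threshold)
  }
  # 7. LD pruning
  if (!is.null(spec$ld_r2_threshold) && dim(gm2)[2] > 0)
    gm2 <- prune_ld(gm2, spec$ld_r2_threshold)
  if (dim(gm2)[2] == 0) warning("all loci removed by site filters")
  gm2
}

#' Exact Hardy-Weinberg test
#'
#' Exact conditional test on the genotype counts of a biallelic locus:
#' conditioning on the allele counts, the probability of a heterozygote
#' count `h` is proportional to `2^h * n! / (nAA! h! naa!)`; the p-value
#' sums the probabilities of all heterozygote counts (of the same parity
#' as the minor-allele count) whose probability does not exceed the
#' observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, summing to at
#'   least 1).
#' @return The exact p-value; monomorphic samples give 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("empty genotype sample")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  n_minor <- min(nA, na)
  if (n_minor == 0) return(1)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  log_w <- hs * log(2) + lfactorial(n) -
    lfactorial((nA - hs) / 2) - lfactorial(hs) - lfactorial((na - hs) / 2)
  pr <- exp(log_w - max(log_w))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Within-cluster LD pruning
#'
#' Greedy left-to-right pass within each transcript cluster: a locus is
#' removed when its squared Pearson correlation of dosages
#' (pairwise-complete) with any already-retained locus of the same
#' cluster is strictly greater than `r2_threshold`. Loci in different
#' clusters are never compared. Zero-variance comparisons count as
#' r-squared 0.
#'
#' @param gm a SNP-encoded [genotype_matrix()] with cluster ids.
#' @param r2_threshold pruning threshold in `(0, 1]`.
#' @return The pruned [genotype_matrix()].
#' @export
prune_ld <- function(gm, r2_threshold = 0.20) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "snp")
  cl <- gm$loci$cluster
  if (is.null(cl)) stop("loci carry no cluster ids")
  keep <- logical(dim(gm)[2])
  for (c_id in unique(cl)) {
    idx <- which(cl == c_id)
    kept <- integer(0)
    for (j in idx) {
      ok <- TRUE
      for (k in kept) {
        r <- suppressWarnings(
          cor(gm$dosage[, j], gm$dosage[, k],
              use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_threshold) { ok <- FALSE; break }
      }
      if (ok) { kept <- c(kept, j); keep[j] <- TRUE }
    }
  }
  subset_loci(gm, keep)
}

#' Remove individuals by missingness and exclusion list
#'
#' Individuals missing at least `max_missing_loci` loci, or named on the
#' exclusion list (e.g. full-siblings identified upstream), are removed.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_loci remove individuals with `>=` this many
#'   missing loci (`NULL` = no missingness rule).
#' @param exclusion_list character vector of individual ids to drop.
#' @return The filtered [genotype_matrix()]; removing everyone is an
#'   error.
#' @export
filter_individuals <- function(gm, max_missing_loci = NULL,
                               exclusion_list = character(0)) {
  keep <- rep(TRUE, dim(gm)[1])
  if (!is.null(max_missing_loci))
    keep <- keep & .missing_by_individual(gm) < max_missing_loci
  keep <- keep & !(gm$individuals$id %in% exclusion_list)
  if (!any(keep)) stop("all individuals removed")
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message(sprintf("filter_individuals: removed %d of %d individuals",
                    n_rm, length(keep)))
  subset_individuals(gm, keep)
}

#' Build the overall and neutral SNP panels
#'
#' `overall`: quality / biallelic / MAF / missingness filters only.
#' `neutral`: additionally no missing data, Hardy-Weinberg exact-test
#' p >= `hwe_p` kept, and within-cluster LD pruning at `ld_r2`.
#'
#' @param gm a SNP-encoded [genotype_matrix()].
#' @param hwe_p HWE p-value threshold (default 0.005).
#' @param ld_r2 LD r-squared threshold (default 0.20).
#' @return A list with elements `overall` and `neutral`.
#' @export
snp_panels <- function(gm, hwe_p = 0.005, ld_r2 = 0.20) {
  overall <- apply_site_filters(gm, filter_spec())
  neutral <- apply_site_filters(gm, filter_spec(max_site_missing = 0,
                                                hwe_p_threshold = hwe_p,
                                                ld_r2_threshold = ld_r2))
  list(overall = overall, neutral = neutral)
}
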