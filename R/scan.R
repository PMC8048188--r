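#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; the input order is preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Principal-component outlier scan
#'
#' Detects SNPs whose allele frequencies are unusually structured along
#' the leading axes of genetic variation. Each centered, scaled dosage
#' vector is regressed on the first `K` principal-component score
#' vectors, giving `K` z-statistics per SNP; their squared Mahalanobis
#' distance (robust covariance) is divided by the genomic inflation
#' factor `lambda = median(D^2) / qchisq(0.5, K)` and referred to a
#' chi-square distribution with `K` degrees of freedom. A SNP is
#' flagged when its BH q-value is below `alpha` AND its largest squared
#' z-statistic lies on component 1 (variation along the
#' population-structure axis).
#'
#' @param gm a SNP-encoded [genotype_matrix()].
#' @param K number of principal components (default 2).
#' @param alpha flagging threshold on the q-value.
#' @param robust use a minimum-covariance-determinant estimate of the
#'   z covariance (falls back to the classical covariance on failure or
#'   tiny panels).
#' @return An object of class `outlier_scan`: data frame with per-SNP
#'   `locus`, `stat` (D^2), `p`, `q`, `component`, `flagged`; plus
#'   `lambda`, `method`.
#' @export
pc_outlier_scan <- function(gm, K = 2, alpha = 0.05, robust = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "snp")
  n <- dim(gm)[1]; L <- dim(gm)[2]
  if (n <= 2 * K) stop("need more than 2K individuals")
  x <- gm$dosage
  storage.mode(x) <- "double"
  cm <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- cm[nas[, 2]]
  x <- sweep(x, 2, colMeans(x))
  csd <- apply(x, 2, sd)
  informative <- csd > 0
  xs <- x
  xs[, informative] <- sweep(x[, informative, drop = FALSE], 2,
                             csd[informative], "/")
  sv <- svd(xs[, informative, drop = FALSE], nu = K, nv = 0)
  U <- sv$u  # orthonormal score directions
  # per-SNP regression of scaled dosage on the K orthonormal scores
  B <- crossprod(U, xs)                      # K x L coefficients
  rss <- colSums(xs^2) - colSums(B^2)
  df <- n - K - 1
  sigma2 <- pmax(rss / df, .Machine$double.eps)
  z <- t(B) / sqrt(sigma2)                   # L x K
  z[!informative, ] <- 0
  zin <- z[informative, , drop = FALSE]
  covz <- NULL
  if (robust && sum(informative) > 5 * K)
    covz <- tryCatch(MASS::cov.rob(zin, method = "mcd"),
                     error = function(e) NULL)
  if (is.null(covz))
    covz <- list(center = colMeans(zin), cov = stats::cov(zin))
  d2 <- mahalanobis(z, covz$center, covz$cov)
  lambda <- median(d2[informative]) / qchisq(0.5, K)
  p <- pchisq(d2 / lambda, df = K, lower.tail = FALSE)
  p[!informative] <- 1
  q <- bh_fdr(p)
  comp <- max.col(z^2, ties.method = "first")
  res <- data.frame(locus = gm$loci$id, stat = d2, p = p, q = q,
                    component = comp, flagged = q < alpha & comp == 1L,
                    stringsAsFactors = FALSE)
  structure(list(result = res, lambda = lambda, K = K, alpha = alpha,
                 method = "pc_mahalanobis"),
            class = "outlier_scan")
}

#' Permutation FST outlier scan
#'
#' Per-locus Weir-Cockerham theta compared with its null distribution
#' under `n_perm` random permutations of the population labels.
#' Empirical p-values use the `(1 + b) / (1 + n_perm)` convention, so p
#' is never zero. Loci whose theta is undefined (monomorphic) get p = 1.
#'
#' @param gm a SNP-encoded [genotype_matrix()].
#' @param pops optional population labels (two populations).
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed.
#' @param alpha flagging threshold on the q-value.
#' @return An object of class `outlier_scan` with per-SNP `stat`
#'   (per-locus theta), `p`, `q`, `flagged`.
#' @export
fst_permutation_scan <- function(gm, pops = NULL, n_perm = 999, seed = 1L,
                                 alpha = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "snp")
  if (n_perm < 99) stop("n_perm must be >= 99")
  pop <- .pop_factor(gm, pops)
  if (nlevels(pop) != 2) stop("permutation scan needs exactly 2 populations")
  theta_locus <- function(pp) {
    st <- .snp_pop_stats(gm$dosage, pp)
    n <- cbind(st[[1]]$n, st[[2]]$n)
    p <- cbind(st[[1]]$p, st[[2]]$p)
    h <- cbind(st[[1]]$h, st[[2]]$h)
    comp <- .wc_components(n, p, h)
    th <- comp$a / (comp$a + comp$b + comp$c)
    th[!is.finite(th)] <- NA_real_
    th[rowSums(n > 0) < 2 | rowMeans(n) <= 1] <- NA_real_
    th
  }
  obs <- theta_locus(pop)
  set.seed(seed)
  exceed <- integer(dim(gm)[2])
  valid <- !is.na(obs)
  for (b in seq_len(n_perm)) {
    perm <- factor(sample(as.character(pop)), levels = levels(pop))
    null_th <- theta_locus(perm)
    exceed <- exceed + (!is.na(null_th) & !is.na(obs) & null_th >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[!valid] <- 1
  q <- bh_fdr(p)
  res <- data.frame(locus = gm$loci$id, stat = obs, p = p, q = q,
                    component = NA_integer_, flagged = q < alpha & valid,
                    stringsAsFactors = FALSE)
  structure(list(result = res, n_perm = n_perm, seed = seed, alpha = alpha,
                 method = "fst_permutation"),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("outlier_scan (%s): %d SNPs, %d flagged at q < %.2g\n",
              x$method, nrow(x$result), sum(x$result$flagged), x$alpha))
  if (!is.null(x$lambda))
    cat(sprintf("  genomic inflation lambda = %.3f\n", x$lambda))
  invisible(x)
}

#' Intersect two outlier scans and map to genes
#'
#' A SNP is a joint outlier when its q-value is below `alpha` in BOTH
#' scans. A gene is selection-flagged when it contains at least one
#' joint-outlier SNP; the gene-level retained value is the minimum
#' `-log10 q` among the gene's significant q-values across both methods
#' and all its joint-outlier SNPs (the least significant of the
#' significant).
#'
#' @param scan_a,scan_b `outlier_scan` objects over the same loci.
#' @param locus_to_gene data frame `locus`, `gene`.
#' @param alpha significance threshold.
#' @return A data frame, one row per selection-flagged gene: `gene`,
#'   `n_joint_snps`, `sel_neglog10q`. Attribute `joint_loci` lists the
#'   joint-outlier SNPs.
#' @export
intersect_to_genes <- function(scan_a, scan_b, locus_to_gene, alpha = 0.05) {
  ra <- scan_a$result; rb <- scan_b$result
  if (!setequal(ra$locus, rb$locus))
    stop("the two scans cover different loci")
  rb <- rb[match(ra$locus, rb$locus), ]
  # joint outlier: q < alpha in both scans, and each scan's own
  # component restriction (PC1 for the PC scan) satisfied
  on_axis <- function(r) is.na(r$component) | r$component == 1L
  joint <- ra$q < alpha & rb$q < alpha & on_axis(ra) & on_axis(rb)
  df <- data.frame(locus = ra$locus[joint], qa = ra$q[joint],
                   qb = rb$q[joint], stringsAsFactors = FALSE)
  m <- match(df$locus, locus_to_gene$locus)
  if (anyNA(m)) {
    message(sprintf("intersect_to_genes: %d joint loci missing from the map, excluded",
                    sum(is.na(m))))
    df <- df[!is.na(m), ]; m <- m[!is.na(m)]
  }
  df$gene <- locus_to_gene$gene[m]
  if (!nrow(df)) {
    out <- data.frame(gene = character(0), n_joint_snps = integer(0),
                      sel_neglog10q = numeric(0))
    attr(out, "joint_loci") <- character(0)
    return(out)
  }
  # per SNP both q's are significant; retain the least significant
  # -log10 q across methods, then the minimum across the gene's SNPs
  df$neglog <- pmin(-log10(df$qa), -log10(df$qb))
  byg <- split(df$neglog, df$gene)
  out <- data.frame(gene = names(byg),
                    n_joint_snps = as.integer(lengths(byg)),
                    sel_neglog10q = vapply(byg, min, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "joint_loci") <- df$locus
  out
}
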