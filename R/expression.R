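#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (edgeR), rescaled to geometric mean
#' one, so that the effective library size of sample j is
#' `lib.size_j * factor_j`.
#'
#' @param cm a [count_matrix()].
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(colSums(cm$counts) == 0)) stop("sample with all-zero counts")
  y <- edgeR::DGEList(cm$counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  setNames(y$samples$norm.factors, colnames(cm$counts))
}

#' Expression filter: full detection in at least one design cell
#'
#' A gene is retained if and only if there is at least one
#' population-by-timepoint cell in which every sample has a nonzero
#' count for it.
#'
#' @param cm a [count_matrix()].
#' @param groups optional grouping factor over samples (defaults to the
#'   six design cells).
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(cm, groups = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  g <- groups %||% design_cells(cm$design)
  g <- droplevels(factor(g))
  keep <- rep(FALSE, nrow(cm$counts))
  for (lev in levels(g)) {
    cols <- which(g == lev)
    keep <- keep | rowSums(cm$counts[, cols, drop = FALSE] > 0) == length(cols)
  }
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}

#' The nine study contrasts
#'
#' Between-population contrasts at each timepoint, and within-population
#' contrasts between successive (and outer) timepoints, expressed over
#' the `population:timepoint` cell means.
#'
#' @param design a sample design data frame (two populations, three
#'   timepoints).
#' @return A named list of contrast vectors over the cell levels.
#' @export
plasticity_contrasts <- function(design) {
  cells <- design_cells(design)
  lev <- levels(cells)
  pops <- sort(unique(as.character(design$population)))
  tps <- sort(unique(design$timepoint))
  if (length(pops) != 2 || length(tps) != 3)
    stop("expected two populations and three timepoints")
  cvec <- function(plus, minus) {
    v <- setNames(numeric(length(lev)), lev)
    v[plus] <- 1; v[minus] <- -1
    v
  }
  cl <- function(p, t) paste(p, t, sep = ":")
  out <- list()
  for (t in tps)
    out[[paste0("between_", t)]] <- cvec(cl(pops[2], t), cl(pops[1], t))
  for (p in pops) {
    out[[paste0(p, "_", tps[2], "v", tps[1])]] <- cvec(cl(p, tps[2]), cl(p, tps[1]))
    out[[paste0(p, "_", tps[3], "v", tps[2])]] <- cvec(cl(p, tps[3]), cl(p, tps[2]))
    out[[paste0(p, "_", tps[3], "v", tps[1])]] <- cvec(cl(p, tps[3]), cl(p, tps[1]))
  }
  out
}

.as_plasticity_result <- function(df) {
  class(df) <- c("plasticity_result", "data.frame")
  df
}

#' Differential gene expression (NB quasi-likelihood GLM)
#'
#' Negative-binomial log-linear models with TMM offsets are fit per gene
#' over the six design cells (edgeR quasi-likelihood pipeline); each
#' requested contrast is tested with the QL F-test and adjusted by BH
#' within the contrast family.
#'
#' @param cm an expression-filtered [count_matrix()].
#' @param contrasts `"all"` or a character vector naming a subset of
#'   [plasticity_contrasts()].
#' @return A `plasticity_result` data frame: `gene`, `contrast`,
#'   `test = "DGE"`, `stat` (F), `log2fc`, `p`, `q`.
#' @export
dge_fit_test <- function(cm, contrasts = "all") {
  stopifnot(inherits(cm, "count_matrix"))
  cons <- plasticity_contrasts(cm$design)
  if (!identical(contrasts, "all")) {
    missing <- setdiff(contrasts, names(cons))
    if (length(missing))
      stop("unknown contrast(s): ", paste(missing, collapse = ", "))
    cons <- cons[contrasts]
  }
  cells <- design_cells(cm$design)
  used <- lapply(cons, function(v) names(v)[v != 0])
  need <- unique(unlist(used))
  absent <- setdiff(need, levels(droplevels(cells)))
  if (length(absent))
    stop("contrast not estimable; missing design cells: ",
         paste(absent, collapse = ", "))
  mm <- stats::model.matrix(~ 0 + cells)
  colnames(mm) <- levels(cells)
  y <- edgeR::DGEList(cm$counts, group = cells)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateDisp(y, mm)
  fit <- edgeR::glmQLFit(y, mm)
  out <- lapply(names(cons), function(cn) {
    tt <- edgeR::glmQLFTest(fit, contrast = cons[[cn]])
    tab <- edgeR::topTags(tt, n = Inf, sort.by = "none")$table
    data.frame(gene = rownames(tab), contrast = cn, test = "DGE",
               stat = tab$F, log2fc = tab$logFC, p = tab$PValue,
               q = bh_fdr(tab$PValue), stringsAsFactors = FALSE)
  })
  .as_plasticity_result(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Differential exon usage (voom + exon linear models + Simes)
#'
#' Exon-level log-CPM values with voom precision weights are fit with
#' weighted linear models; for each exon the contrast coefficient is
#' compared against the precision-weighted average of the gene's other
#' exons (limma's `diffSplice`), and per-gene p-values are obtained by
#' the Simes procedure over the gene's exons, then BH-adjusted across
#' genes. Single-exon genes are excluded.
#'
#' @param ecm an [exon_count_matrix()].
#' @param contrasts as in [dge_fit_test()].
#' @return A `plasticity_result` data frame (`test = "DEU"`, `stat` and
#'   `log2fc` are `NA`; the evidence is the Simes-aggregated p).
#' @export
deu_fit_test <- function(ecm, contrasts = "all") {
  stopifnot(inherits(ecm, "exon_count_matrix"))
  cons <- plasticity_contrasts(ecm$design)
  if (!identical(contrasts, "all")) cons <- cons[contrasts]
  multi <- ecm$gene %in% names(which(table(ecm$gene) >= 2))
  n_single <- length(unique(ecm$gene[!multi]))
  if (n_single > 0)
    message(sprintf("deu_fit_test: %d single-exon genes excluded", n_single))
  counts <- ecm$counts[multi, , drop = FALSE]
  gene <- ecm$gene[multi]; exon <- ecm$exon[multi]
  cells <- design_cells(ecm$design)
  mm <- stats::model.matrix(~ 0 + cells)
  colnames(mm) <- levels(cells)
  y <- edgeR::DGEList(counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  v <- limma::voom(y, mm)
  fit <- limma::lmFit(v, mm)
  cmat <- do.call(cbind, cons)
  cfit <- limma::contrasts.fit(fit, cmat)
  sp <- limma::diffSplice(cfit, geneid = gene, exonid = exon,
                          verbose = FALSE)
  out <- lapply(seq_along(cons), function(i) {
    ts <- limma::topSplice(sp, coef = i, test = "simes", number = Inf)
    data.frame(gene = ts$GeneID, contrast = names(cons)[i], test = "DEU",
               stat = NA_real_, log2fc = NA_real_, p = ts$P.Value,
               q = bh_fdr(ts$P.Value), stringsAsFactors = FALSE)
  })
  .as_plasticity_result(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

# NB log-likelihood with offsets; phi on the log scale for stability
.nb_ll <- function(y, off, eta, log_phi) {
  sum(dnbinom(y, size = exp(-log_phi), mu = exp(eta + off), log = TRUE))
}

# fit one group: (eta, log phi) by bounded quasi-Newton from moment starts
.nb_fit_group <- function(y, off) {
  m <- mean(y / exp(off))
  if (m <= 0) m <- 1e-8
  v <- var(y / exp(off))
  phi0 <- max((v - m) / m^2, 1e-4)
  if (!is.finite(phi0)) phi0 <- 0.1
  o <- suppressWarnings(
    optim(c(log(m), log(phi0)),
          function(par) -.nb_ll(y, off, par[1], par[2]),
          method = "L-BFGS-B", lower = c(-40, -12), upper = c(40, 6),
          control = list(maxit = 200)))
  list(ll = -o$value, eta = o$par[1], log_phi = o$par[2],
       converged = o$convergence == 0)
}

# reduced model: group-specific means, common dispersion
.nb_fit_common_phi <- function(y, off, g) {
  lev <- levels(g)
  eta0 <- vapply(lev, function(k) {
    m <- mean(y[g == k] / exp(off[g == k])); log(max(m, 1e-8))
  }, 0)
  m_all <- mean(y / exp(off))
  v <- var(y / exp(off))
  phi0 <- max((v - m_all) / max(m_all^2, 1e-12), 1e-4)
  if (!is.finite(phi0)) phi0 <- 0.1
  nll <- function(par) {
    eta <- par[seq_along(lev)][as.integer(g)]
    -sum(dnbinom(y, size = exp(-par[length(lev) + 1]),
                 mu = exp(eta + off), log = TRUE))
  }
  o <- suppressWarnings(
    optim(c(eta0, log(phi0)), nll, method = "L-BFGS-B",
          lower = c(rep(-40, length(lev)), -12),
          upper = c(rep(40, length(lev)), 6),
          control = list(maxit = 300)))
  list(ll = -o$value, phi = exp(o$par[length(lev) + 1]),
       eta = o$par[seq_along(lev)], converged = o$convergence == 0)
}

#' Gene expression variability (NB dispersion likelihood-ratio test)
#'
#' For each gene, two maximum-likelihood negative-binomial fits with a
#' log(library size x TMM factor) offset on the mean: a full model with
#' group factors on both the log-mean and the log-dispersion, and a
#' reduced model with group on the mean only (common dispersion). The
#' statistic `2 * (ll_full - ll_reduced)` is referred to chi-square with
#' `nlevels(groups) - 1` degrees of freedom. Genes must pass a
#' mean-CPM > `cpm_min` inclusion rule, and genes whose fitted
#' coefficient of variation `sqrt(phi + 1/mu)` falls outside `cv_bounds`
#' (near-Poisson or inflated) are removed before testing. Non-convergent
#' fits are excluded and counted.
#'
#' @param cm a [count_matrix()].
#' @param groups factor over samples defining the comparison (typically
#'   two levels: population at a timepoint, or two timepoints within a
#'   population).
#' @param cpm_min counts-per-million inclusion threshold.
#' @param cv_bounds open interval of admissible fitted CV values.
#' @return A `plasticity_result` data frame (`test = "GEV"`, `stat` is
#'   the LRT statistic). Attributes `n_cpm_filtered`, `n_cv_filtered`,
#'   `n_nonconverged` record the exclusions.
#' @export
gev_fit_test <- function(cm, groups, cpm_min = 1, cv_bounds = c(1e-3, 3)) {
  stopifnot(inherits(cm, "count_matrix"))
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least two groups")
  if (length(g) != ncol(cm$counts)) stop("groups must match samples")
  counts <- cm$counts
  lib <- colSums(counts)
  nf <- tmm_factors(cm)
  off <- log(lib * nf)
  cpm <- t(t(counts) / (lib / 1e6))
  keep <- rowMeans(cpm) > cpm_min
  n_cpm <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  G <- nlevels(g)
  res <- vector("list", nrow(counts))
  n_cv <- 0L; n_fail <- 0L
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    red <- tryCatch(.nb_fit_common_phi(y, off, g), error = function(e) NULL)
    if (is.null(red) || !red$converged) { n_fail <- n_fail + 1L; next }
    # CV of copy number: CV^2 = Var/mean^2 = phi + 1/mu at the mean count
    mu_bar <- mean(y)
    cv <- sqrt(red$phi + 1 / max(mu_bar, 1e-12))
    if (cv <= cv_bounds[1] || cv >= cv_bounds[2]) { n_cv <- n_cv + 1L; next }
    full_ll <- 0; ok <- TRUE
    for (k in levels(g)) {
      f <- tryCatch(.nb_fit_group(y[g == k], off[g == k]),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) { ok <- FALSE; break }
      full_ll <- full_ll + f$ll
    }
    if (!ok) { n_fail <- n_fail + 1L; next }
    lrt <- max(2 * (full_ll - red$ll), 0)
    res[[i]] <- data.frame(gene = rownames(counts)[i], stat = lrt,
                           p = pchisq(lrt, df = G - 1, lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0)
    res <- data.frame(gene = character(0), stat = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  out <- data.frame(gene = res$gene,
                    contrast = rep(paste(levels(g), collapse = "v"), nrow(res)),
                    test = rep("GEV", nrow(res)), stat = res$stat,
                    log2fc = rep(NA_real_, nrow(res)), p = res$p,
                    q = if (nrow(res)) bh_fdr(res$p) else numeric(0),
                    stringsAsFactors = FALSE)
  out <- .as_plasticity_result(out)
  attr(out, "n_cpm_filtered") <- n_cpm
  attr(out, "n_cv_filtered") <- n_cv
  attr(out, "n_nonconverged") <- n_fail
  out
}
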