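#' Classify genes by plasticity and selection evidence
#'
#' A gene is plastic when any DGE/DEU/GEV q-value in any contrast is
#' below `alpha`; its retained plasticity value is the LOWEST `-log10 q`
#' among the significant ones (the least significant of the
#' significant). Selection flags and values are passed through from
#' [intersect_to_genes()]. Genes in the universe absent from every
#' result table are "neither".
#'
#' @param plasticity a `plasticity_result` data frame (rows from any mix
#'   of tests and contrasts).
#' @param selection the [intersect_to_genes()] output.
#' @param gene_universe character vector of all genes under study.
#' @param alpha significance threshold.
#' @param retain `"min"` (default: lowest significant `-log10 q`, as
#'   used for the plots) or `"max"` (most significant; sensitivity
#'   analysis).
#' @return A `gene_evidence` data frame, one row per universe gene:
#'   `gene`, `plastic`, `selected`, `plast_neglog10q`, `sel_neglog10q`,
#'   `plast_tests`.
#' @export
classify_genes <- function(plasticity, selection, gene_universe,
                           alpha = 0.05, retain = c("min", "max")) {
  retain <- match.arg(retain)
  extra <- setdiff(unique(c(plasticity$gene, selection$gene)), gene_universe)
  if (length(extra))
    stop("genes in results but not in the universe: ",
         paste(head(extra, 5), collapse = ", "))
  sig <- plasticity[plasticity$q < alpha, , drop = FALSE]
  byg <- split(sig, sig$gene)
  plast_val <- vapply(byg, function(d) {
    v <- -log10(d$q)
    if (retain == "min") min(v) else max(v)
  }, 0)
  plast_tests <- vapply(byg, function(d)
    paste(sort(unique(d$test)), collapse = ","), "")
  out <- data.frame(gene = gene_universe,
                    plastic = gene_universe %in% names(byg),
                    selected = gene_universe %in% selection$gene,
                    plast_neglog10q = NA_real_, sel_neglog10q = NA_real_,
                    plast_tests = NA_character_, stringsAsFactors = FALSE)
  m <- match(out$gene, names(byg))
  out$plast_neglog10q[!is.na(m)] <- plast_val[m[!is.na(m)]]
  out$plast_tests[!is.na(m)] <- plast_tests[m[!is.na(m)]]
  m2 <- match(out$gene, selection$gene)
  out$sel_neglog10q[!is.na(m2)] <- selection$sel_neglog10q[m2[!is.na(m2)]]
  class(out) <- c("gene_evidence", "data.frame")
  out
}

#' 2x2 contingency counts from gene evidence
#'
#' @param evidence a [classify_genes()] result.
#' @return Named integer vector: `both`, `selection_only`,
#'   `plasticity_only`, `neither`.
#' @export
contingency_counts <- function(evidence) {
  c(both = sum(evidence$plastic & evidence$selected),
    selection_only = sum(!evidence$plastic & evidence$selected),
    plasticity_only = sum(evidence$plastic & !evidence$selected),
    neither = sum(!evidence$plastic & !evidence$selected))
}

#' Chi-square test of independence on a 2x2 table
#'
#' Closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally with
#' the Yates continuity correction, referred to chi-square with one
#' degree of freedom.
#'
#' @param table 2x2 matrix of counts, or a named vector as returned by
#'   [contingency_counts()] (rows: selection yes/no; columns: plasticity
#'   yes/no).
#' @param yates apply the continuity correction.
#' @return An object of class `contingency_summary`: `counts`, `total`,
#'   `statistic`, `df`, `p_value`, `yates`.
#' @export
chisq_independence <- function(table, yates = FALSE) {
  if (!is.matrix(table))
    table <- matrix(table[c("both", "selection_only",
                            "plasticity_only", "neither")],
                    2, 2, byrow = TRUE)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  storage.mode(table) <- "double"
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (any(c(a + b, c + d, a + c, b + d) == 0))
    stop("test undefined: zero row or column margin")
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(delta - n / 2, 0)
  stat <- n * delta^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  structure(list(counts = table, total = n, statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 yates = yates),
            class = "contingency_summary")
}

#' @export
print.contingency_summary <- function(x, ...) {
  cat("2x2 selection x plasticity contingency:\n")
  tab <- x$counts
  dimnames(tab) <- list(selection = c("yes", "no"),
                        plasticity = c("yes", "no"))
  print(tab)
  cat(sprintf("chi-square(1, n = %d) = %.4g%s, p = %.3g\n",
              x$total, x$statistic,
              if (x$yates) " (Yates-corrected)" else "", x$p_value))
  invisible(x)
}

#' Scatter of selection versus plasticity evidence
#'
#' Per-gene `-log10 q` retained values; genes with only one kind of
#' evidence are drawn on their axis.
#'
#' @param x a `gene_evidence` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gene_evidence <- function(x, ...) {
  px <- ifelse(is.na(x$sel_neglog10q), 0, x$sel_neglog10q)
  py <- ifelse(is.na(x$plast_neglog10q), 0, x$plast_neglog10q)
  show <- x$plastic | x$selected
  col <- ifelse(x$plastic & x$selected, "purple",
                ifelse(x$plastic, "steelblue", "firebrick"))
  plot(px[show], py[show], col = col[show], pch = 19, cex = 0.7,
       xlab = expression(-log[10] ~ q ~ "(selection)"),
       ylab = expression(-log[10] ~ q ~ "(plasticity)"), ...)
  legend("topright", pch = 19, col = c("purple", "steelblue", "firebrick"),
         legend = c("both", "plasticity only", "selection only"),
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Run the full simulate-to-contingency pipeline
#'
#' Simulates genotypes and counts (or accepts pre-built objects),
#' applies the SNP filter cascade, computes the population-genetic
#' report, runs both outlier scans, runs the DGE/DEU/GEV tests over all
#' nine contrasts, classifies genes and tests selection-plasticity
#' independence. All result tables, a JSON run summary and a
#' selection-versus-plasticity scatter are written to `outdir`.
#'
#' @param geno_cfg a [genotype_sim_config()]; ignored when `genotypes`
#'   is supplied.
#' @param expr_cfg an [expression_sim_config()]; ignored when
#'   `expression` is supplied.
#' @param genotypes optional pre-built result of [sim_snp_genotypes()].
#' @param expression optional pre-built result of [sim_expression()].
#' @param locus_to_gene optional data frame `locus`, `gene`; by default
#'   SNP clusters are mapped onto the simulated genes cyclically so that
#'   the two data types share a gene universe.
#' @param outdir output directory (created if needed); `NULL` = no
#'   files written.
#' @param alpha significance threshold used throughout.
#' @param n_boot,n_perm bootstrap / permutation replicates.
#' @param seed integer master seed for the stochastic stages.
#' @return A list bundle: `panels`, `popgen` (basic stats, pairwise FST,
#'   betas, with CIs), `scans`, `plasticity`, `evidence`, `contingency`,
#'   `log`.
#' @export
run_pipeline <- function(geno_cfg = genotype_sim_config(),
                         expr_cfg = expression_sim_config(),
                         genotypes = NULL, expression = NULL,
                         locus_to_gene = NULL, outdir = NULL,
                         alpha = 0.05, n_boot = 1000, n_perm = 999,
                         seed = 1L) {
  seeds <- derive_seeds(seed, 4L, salt = 404L)
  log <- list(seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim_g <- genotypes %||% stage("simulate_genotypes", sim_snp_genotypes(geno_cfg))
  sim_e <- expression %||% stage("simulate_expression", sim_expression(expr_cfg))
  log$n_loci_simulated <- dim(sim_g$genotypes)[2]
  log$n_genes_simulated <- nrow(sim_e$counts$counts)

  panels <- stage("filter", snp_panels(sim_g$genotypes))
  log$n_loci_overall <- dim(panels$overall)[2]
  log$n_loci_neutral <- dim(panels$neutral)[2]
  if (log$n_loci_overall == 0) stop("pipeline stage 'filter': no loci retained")

  popgen <- stage("popgen", {
    bs <- basic_stats(panels$overall)
    fst <- wc_pairwise_fst(panels$overall)
    beta <- population_specific_fst(panels$overall)
    list(basic = bs, fst = fst, beta = beta,
         ci = rbind(bootstrap_ci(bs, n_boot, seed = seeds[1]),
                    bootstrap_ci(fst, n_boot, seed = seeds[1]),
                    bootstrap_ci(beta, n_boot, seed = seeds[1])))
  })

  scans <- stage("scan", {
    a <- pc_outlier_scan(panels$overall, K = 2, alpha = alpha)
    b <- fst_permutation_scan(panels$overall, n_perm = n_perm,
                              seed = seeds[2], alpha = alpha)
    list(pc = a, fst_perm = b)
  })

  genes <- rownames(sim_e$counts$counts)
  if (is.null(locus_to_gene)) {
    cl <- panels$overall$loci$cluster
    gene_of_cluster <- setNames(genes[(seq_along(unique(cl)) - 1L) %%
                                        length(genes) + 1L], unique(cl))
    locus_to_gene <- data.frame(locus = panels$overall$loci$id,
                                gene = gene_of_cluster[cl],
                                stringsAsFactors = FALSE)
  }
  selection <- stage("intersect",
                     intersect_to_genes(scans$pc, scans$fst_perm,
                                        locus_to_gene, alpha = alpha))
  log$n_joint_outlier_snps <- length(attr(selection, "joint_loci"))
  log$n_selection_genes <- nrow(selection)

  plast <- stage("plasticity", {
    kept <- filter_expressed(sim_e$counts)
    log$n_genes_expressed <- nrow(kept$counts)
    dge <- dge_fit_test(kept)
    ecm <- sim_e$exon_counts
    ecm$counts <- ecm$counts[ecm$gene %in% rownames(kept$counts), , drop = FALSE]
    sel_e <- ecm$gene %in% rownames(kept$counts)
    ecm$gene <- ecm$gene[sel_e]; ecm$exon <- ecm$exon[sel_e]
    deu <- deu_fit_test(ecm)
    gev <- do.call(rbind, lapply(gev_comparisons(kept$design), function(cp) {
      sub <- kept
      sub$counts <- sub$counts[, cp$samples, drop = FALSE]
      sub$design <- sub$design[cp$samples, , drop = FALSE]
      g <- gev_fit_test(sub, groups = cp$groups)
      g$contrast <- cp$name
      g
    }))
    .as_plasticity_result(rbind(dge, deu, gev))
  })

  universe <- unique(c(genes, locus_to_gene$gene))
  evidence <- stage("classify",
                    classify_genes(plast, selection, universe, alpha = alpha))
  counts4 <- contingency_counts(evidence)
  contingency <- if (all(c(counts4["both"] + counts4["selection_only"],
                           counts4["plasticity_only"] + counts4["neither"],
                           counts4["both"] + counts4["plasticity_only"],
                           counts4["selection_only"] + counts4["neither"]) > 0))
    chisq_independence(counts4) else NULL
  log$contingency <- as.list(counts4)

  bundle <- list(panels = panels, popgen = popgen, scans = scans,
                 selection = selection, plasticity = plast,
                 evidence = evidence, contingency = contingency, log = log)
  if (!is.null(outdir)) write_pipeline_outputs(bundle, outdir)
  bundle
}

# the nine pairwise comparisons for the variability test
gev_comparisons <- function(design) {
  pops <- sort(unique(as.character(design$population)))
  tps <- sort(unique(design$timepoint))
  out <- list()
  for (t in tps) {
    s <- which(design$timepoint == t)
    out[[paste0("between_", t)]] <-
      list(name = paste0("between_", t), samples = s,
           groups = design$population[s])
  }
  for (p in pops) for (pair in list(tps[c(1, 2)], tps[c(2, 3)], tps[c(1, 3)])) {
    s <- which(design$population == p & design$timepoint %in% pair)
    nm <- paste0(p, "_", pair[2], "v", pair[1])
    out[[nm]] <- list(name = nm, samples = s,
                      groups = design$timepoint[s])
  }
  out
}

#' @rdname run_pipeline
#' @param bundle a [run_pipeline()] result.
#' @export
write_pipeline_outputs <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(bundle$popgen$ci, "popgen_report.tsv")
  tsv(bundle$scans$pc$result, "scan_pc.tsv")
  tsv(bundle$scans$fst_perm$result, "scan_fst_perm.tsv")
  tsv(bundle$plasticity, "plasticity_results.tsv")
  tsv(bundle$evidence, "gene_evidence.tsv")
  summary <- list(log = bundle$log,
                  contingency = if (!is.null(bundle$contingency))
                    list(counts = as.list(as.vector(bundle$contingency$counts)),
                         statistic = bundle$contingency$statistic,
                         p_value = bundle$contingency$p_value))
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  png(file.path(outdir, "selection_vs_plasticity.png"), width = 800,
      height = 600)
  plot(bundle$evidence,
       main = "Selection vs plasticity evidence per gene")
  dev.off()
  invisible(outdir)
}
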