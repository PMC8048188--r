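#' Configuration for expression-count simulation
#'
#' Negative-binomial gene counts over a `population x timepoint` design,
#' with exon counts drawn conditionally on gene totals by multinomial
#' split so that differential exon usage can be planted without changing
#' gene-level abundance. Effects are planted per design cell
#' (`"<population>:<timepoint>"`).
#'
#' Defaults emulate the salinity-challenge study design: two populations
#' (`CV`, `SP`), timepoints 0/72/168 h, and 16 fish per population split
#' 6/5/5 over the timepoints.
#'
#' @param n_genes number of genes.
#' @param groups data frame of design cells: `population`, `timepoint`,
#'   `n` (samples per cell).
#' @param baseline_logmean_dist length-2 vector `(meanlog, sdlog)` of the
#'   per-gene natural-log baseline mean count.
#' @param dispersion baseline NB dispersion (variance = mu + phi mu^2).
#' @param lib_size_range interval of relative library-size factors,
#'   strictly positive.
#' @param planted_dge data frame `gene` (index), `cell`, `log2fc`: the
#'   cell's log2 mean is shifted by `log2fc`.
#' @param planted_deu data frame `gene`, `cell`, `exon`, `usage_ref`,
#'   `usage_alt`: the named exon's usage proportion is `usage_ref` in all
#'   cells except `cell`, where it is `usage_alt`.
#' @param planted_gev data frame `gene`, `cell`, `ratio`: the NB
#'   dispersion in `cell` is multiplied by `ratio`.
#' @param exons_per_gene length-2 integer range of exons per gene.
#' @param seed integer seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  groups = default_design_cells(),
                                  baseline_logmean_dist = c(4.5, 1.2),
                                  dispersion = 0.1,
                                  lib_size_range = c(0.7, 1.3),
                                  planted_dge = NULL, planted_deu = NULL,
                                  planted_gev = NULL,
                                  exons_per_gene = c(3L, 8L),
                                  seed = 1L) {
  stopifnot(all(c("population", "timepoint", "n") %in% names(groups)))
  if (any(lib_size_range <= 0)) stop("library sizes must be positive")
  if (dispersion <= 0) stop("dispersion must be > 0")
  for (nm in c("planted_dge", "planted_deu", "planted_gev")) {
    pl <- get(nm)
    if (!is.null(pl) && anyDuplicated(pl$gene))
      stop(nm, ": planted genes must be distinct within a type")
  }
  if (!is.null(planted_dge) && any(!is.finite(planted_dge$log2fc)))
    stop("planted log2 fold changes must be finite")
  exons_per_gene <- rep_len(as.integer(exons_per_gene), 2L)
  structure(list(n_genes = n_genes, groups = as.data.frame(groups),
                 baseline_logmean_dist = baseline_logmean_dist,
                 dispersion = dispersion, lib_size_range = lib_size_range,
                 planted_dge = planted_dge, planted_deu = planted_deu,
                 planted_gev = planted_gev, exons_per_gene = exons_per_gene,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' @rdname expression_sim_config
#' @export
default_design_cells <- function() {
  data.frame(population = rep(c("CV", "SP"), each = 3),
             timepoint = rep(c(0, 72, 168), 2),
             n = rep(c(6, 5, 5), 2))
}

#' Simulate gene and exon counts with planted effects
#'
#' Gene counts are NB with mean
#' `exp(baseline + cell effects) * lib_size_factor` and per-gene (and,
#' for planted variability genes, per-cell) dispersion. Exon counts are
#' a multinomial split of each gene count using per-cell exon-usage
#' proportions, so planted usage shifts leave gene totals untouched.
#'
#' @param cfg an [expression_sim_config()].
#' @return A list: `counts` ([count_matrix()]), `exon_counts`
#'   ([exon_count_matrix()]), `truth` (one row per gene: `gene`,
#'   `class` in `null/DGE/DEU/GEV` (comma-joined when several),
#'   `param`), and `lib_factors`.
#' @export
sim_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  seeds <- derive_seeds(cfg$seed, 3L, salt = 303L)
  G <- cfg$n_genes
  cells <- cfg$groups
  cell_id <- paste(cells$population, cells$timepoint, sep = ":")
  design <- data.frame(
    sample = unlist(lapply(seq_len(nrow(cells)), function(i)
      sprintf("%s_%s_r%d", cells$population[i], cells$timepoint[i],
              seq_len(cells$n[i])))),
    population = rep(cells$population, cells$n),
    timepoint = rep(cells$timepoint, cells$n),
    stringsAsFactors = FALSE)
  S <- nrow(design)
  samp_cell <- rep(cell_id, cells$n)
  genes <- sprintf("gene%05d", seq_len(G))

  set.seed(seeds[1])
  base_log <- rnorm(G, cfg$baseline_logmean_dist[1], cfg$baseline_logmean_dist[2])
  sf <- runif(S, cfg$lib_size_range[1], cfg$lib_size_range[2])
  n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), G, TRUE)

  # per-gene x per-sample log-mean shifts and dispersions
  shift <- matrix(0, G, S)
  if (!is.null(cfg$planted_dge))
    for (i in seq_len(nrow(cfg$planted_dge))) {
      r <- cfg$planted_dge[i, ]
      shift[r$gene, samp_cell == r$cell] <- log(2) * r$log2fc
    }
  phi <- matrix(cfg$dispersion, G, S)
  if (!is.null(cfg$planted_gev))
    for (i in seq_len(nrow(cfg$planted_gev))) {
      r <- cfg$planted_gev[i, ]
      phi[r$gene, samp_cell == r$cell] <- cfg$dispersion * r$ratio
    }

  set.seed(seeds[2])
  mu <- exp(base_log + shift) * rep(sf, each = G)
  counts <- matrix(rnbinom(G * S, mu = mu, size = 1 / phi), G, S)
  rownames(counts) <- genes

  # exon usage proportions: baseline per gene, per-cell override for DEU
  set.seed(seeds[3])
  usage_base <- lapply(seq_len(G), function(g) {
    u <- rgamma(n_ex[g], 5); u / sum(u)
  })
  deu <- cfg$planted_deu
  if (!is.null(deu))
    for (i in seq_len(nrow(deu))) {
      r <- deu[i, ]
      u <- usage_base[[r$gene]]
      if (r$exon > length(u)) stop("planted DEU exon index out of range")
      u[-r$exon] <- u[-r$exon] * (1 - r$usage_ref) / sum(u[-r$exon])
      u[r$exon] <- r$usage_ref
      usage_base[[r$gene]] <- u
    }
  exon_rows <- sum(n_ex)
  ecounts <- matrix(0L, exon_rows, S)
  egene <- rep(genes, n_ex)
  eidx <- unlist(lapply(n_ex, seq_len))
  rstart <- c(0L, cumsum(n_ex))
  for (g in seq_len(G)) {
    rows <- rstart[g] + seq_len(n_ex[g])
    u_by_cell <- matrix(rep(usage_base[[g]], S), ncol = S)
    if (!is.null(deu) && g %in% deu$gene) {
      r <- deu[deu$gene == g, ]
      alt <- usage_base[[g]]
      alt[-r$exon] <- alt[-r$exon] * (1 - r$usage_alt) / sum(alt[-r$exon])
      alt[r$exon] <- r$usage_alt
      u_by_cell[, samp_cell == r$cell] <- alt
    }
    for (s in seq_len(S))
      if (counts[g, s] > 0)
        ecounts[rows, s] <- rmultinom(1, counts[g, s], u_by_cell[, s])[, 1]
  }
  rownames(ecounts) <- paste(egene, eidx, sep = ":")

  cls <- rep("", G)
  addc <- function(cls, g, lab) {
    cls[g] <- ifelse(cls[g] == "", lab, paste(cls[g], lab, sep = ","))
    cls
  }
  par <- rep(NA_real_, G)
  if (!is.null(cfg$planted_dge)) {
    cls <- addc(cls, cfg$planted_dge$gene, "DGE")
    par[cfg$planted_dge$gene] <- cfg$planted_dge$log2fc
  }
  if (!is.null(deu)) {
    cls <- addc(cls, deu$gene, "DEU")
    par[deu$gene] <- deu$usage_alt - deu$usage_ref
  }
  if (!is.null(cfg$planted_gev)) {
    cls <- addc(cls, cfg$planted_gev$gene, "GEV")
    par[cfg$planted_gev$gene] <- cfg$planted_gev$ratio
  }
  cls[cls == ""] <- "null"
  truth <- data.frame(gene = genes, class = cls, param = par,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, design),
       exon_counts = exon_count_matrix(ecounts, design,
                                       gene = egene, exon = eidx),
       truth = truth, lib_factors = sf)
}
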