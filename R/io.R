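#' Write a SNP genotype matrix as VCF v4.2
#'
#' The transcript-cluster label goes in the CHROM column (clusters coded
#' as chromosomes), positions number loci within their cluster, site
#' quality goes in QUAL, and each call is written as `GT:GQ`.
#'
#' @param gm a SNP-encoded [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "snp")
  n <- dim(gm)[1]; L <- dim(gm)[2]
  gt <- matrix("./.", n, L)
  gt[which(gm$dosage == 0L)] <- "0/0"
  gt[which(gm$dosage == 1L)] <- "0/1"
  gt[which(gm$dosage == 2L)] <- "1/1"
  gq <- if (!is.null(gm$gq)) gm$gq else matrix(99L, n, L)
  cell <- matrix(paste(gt, gq, sep = ":"), n, L)
  cell[is.na(gm$dosage)] <- "./.:."
  pos <- stats::ave(seq_len(L), gm$loci$cluster, FUN = seq_along)
  qual <- ifelse(is.na(gm$loci$qual), ".", sprintf("%g", gm$loci$qual))
  body <- paste(gm$loci$cluster, pos, gm$loci$id,
                gm$loci$ref %||% "A", gm$loci$alt %||% "T",
                qual, "PASS", ".", "GT:GQ",
                apply(cell, 2, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=plastisel",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$individuals$id), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Loads all records; biallelic records become alternate-allele dosages.
#' Genotype qualities are stored alongside the calls so that low-GQ
#' masking can be applied at filter time, not at read time. The CHROM
#' column is used as the transcript-cluster id unless `cluster_map`
#' supplies one.
#'
#' @param path VCF v4.2 file.
#' @param cluster_map optional data frame `locus`, `cluster` overriding
#'   the CHROM-derived cluster ids.
#' @param pops optional per-individual population labels (in VCF sample
#'   order), or a data frame `id`, `pop`.
#' @return A SNP-encoded [genotype_matrix()]. Multi-allelic records are
#'   kept (flagged by `loci$biallelic = FALSE`) with `NA` dosage beyond
#'   the first alternate allele masked; non-diploid genotypes are an
#'   error.
#' @export
read_vcf <- function(path, cluster_map = NULL, pops = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("^[0-9.]+$", gt_raw[!is.na(gt_raw)])) ||
      any(grepl("[/|].*[/|]", gt_raw[!is.na(gt_raw)])))
    stop("non-diploid genotype encountered in ", path)
  alt <- fix$ALT
  biallelic <- !grepl(",", alt) & !is.na(alt) & alt != "."
  # dosage = count of first alternate allele; others treated as missing
  g <- gsub("|", "/", gt_raw, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = ncol(gt_raw), ncol = nrow(gt_raw))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dosage[] <- t(matrix(map[g], nrow = nrow(gt_raw)))
  gq_raw <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                     error = function(e) NULL)
  gq <- if (!is.null(gq_raw)) t(gq_raw) else NULL
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  cluster <- fix$CHROM
  if (!is.null(cluster_map)) {
    m <- match(ids, cluster_map$locus)
    cluster[!is.na(m)] <- cluster_map$cluster[m[!is.na(m)]]
  }
  loci <- data.frame(id = ids, cluster = cluster,
                     qual = suppressWarnings(as.numeric(fix$QUAL)),
                     ref = fix$REF, alt = alt, biallelic = biallelic,
                     stringsAsFactors = FALSE)
  samp <- colnames(gt_raw)
  if (is.data.frame(pops)) pops <- pops$pop[match(samp, pops$id)]
  individuals <- data.frame(id = samp, stringsAsFactors = FALSE)
  if (!is.null(pops)) individuals$pop <- pops
  rownames(dosage) <- samp
  genotype_matrix(dosage = dosage, loci = loci, individuals = individuals,
                  gq = gq)
}

#' Write / read a microsatellite genotype table
#'
#' Plain-text dialect: a header row, then one row per individual with
#' `id`, `site` (population label), and two integer allele columns per
#' locus. Missing calls are coded `0 0`.
#'
#' @param gm a microsatellite-encoded [genotype_matrix()].
#' @param path file path.
#' @return `path` (writer) or a [genotype_matrix()] (reader).
#' @export
write_msat_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"), gm$type == "msat")
  L <- dim(gm)[2]
  a1 <- gm$a1; a2 <- gm$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  out <- matrix(0L, nrow = dim(gm)[1], ncol = 2 * L)
  out[, seq(1, 2 * L, 2)] <- a1
  out[, seq(2, 2 * L, 2)] <- a2
  hdr <- c("id", "site",
           paste(rep(gm$loci$id, each = 2), c("a", "b"), sep = "_"))
  df <- data.frame(gm$individuals$id,
                   gm$individuals$pop %||% rep("NA", dim(gm)[1]), out)
  names(df) <- hdr
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msat_table
#' @export
read_msat_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  acols <- df[, -(1:2), drop = FALSE]
  if (ncol(acols) %% 2 != 0)
    stop("expected two allele columns per locus in ", path)
  L <- ncol(acols) / 2
  a1 <- as.matrix(acols[, seq(1, 2 * L, 2), drop = FALSE])
  a2 <- as.matrix(acols[, seq(2, 2 * L, 2), drop = FALSE])
  a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
  # half-missing calls are fully masked
  half <- is.na(a1) != is.na(a2)
  a1[half] <- NA; a2[half] <- NA
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  ids <- sub("_a$", "", names(acols)[seq(1, 2 * L, 2)])
  dimnames(a1) <- dimnames(a2) <- NULL
  genotype_matrix(a1 = a1, a2 = a2,
                  loci = data.frame(id = ids, cluster = ids,
                                    stringsAsFactors = FALSE),
                  individuals = data.frame(id = as.character(df[[1]]),
                                           pop = as.character(df[[2]]),
                                           stringsAsFactors = FALSE))
}

#' Write / read count matrices and design tables as TSV
#'
#' Gene tables have a `gene` key column; exon tables a `gene:exonIndex`
#' key column named `exon`.
#'
#' @param cm a [count_matrix()] or [exon_count_matrix()].
#' @param path file path.
#' @return `path` (writers); a [count_matrix()] /
#'   [exon_count_matrix()] / design data frame (readers).
#' @export
write_counts <- function(cm, path) {
  key <- if (inherits(cm, "exon_count_matrix")) "exon" else "gene"
  df <- data.frame(rownames(cm$counts), cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param design_path path of the design TSV (`sample`, `population`,
#'   `timepoint`).
#' @export
read_counts <- function(path, design_path) {
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- m[, design$sample, drop = FALSE]
  if (names(df)[1] == "exon") exon_count_matrix(m, design)
  else count_matrix(m, design)
}

#' @rdname write_counts
#' @export
write_design <- function(cm, path) {
  write.table(cm$design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
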