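#' Count matrix with sample design
#'
#' Gene-level integer counts with a `population x timepoint` sample
#' design, as produced by transcript-cluster ("gene") quantification.
#'
#' @param counts non-negative integer matrix, genes x samples, with row
#'   and column names.
#' @param design data frame with one row per sample: `sample`,
#'   `population`, `timepoint` (order must match the columns of
#'   `counts`).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design) {
  stopifnot(is.matrix(counts), ncol(counts) == nrow(design))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  design <- as.data.frame(design)
  stopifnot(all(c("sample", "population", "timepoint") %in% names(design)))
  colnames(counts) <- design$sample
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' Exon-level count matrix
#'
#' Exon counts keyed `gene:exonIndex`, sharing the gene-level sample
#' design. Every exon maps to exactly one gene.
#'
#' @param counts non-negative integer matrix, exons x samples, row names
#'   `"<gene>:<exon index>"`.
#' @param design as in [count_matrix()].
#' @param gene,exon optional explicit gene ids / exon indices per row;
#'   parsed from the row names when omitted.
#' @return An object of class `exon_count_matrix`.
#' @export
exon_count_matrix <- function(counts, design, gene = NULL, exon = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) == nrow(design))
  storage.mode(counts) <- "integer"
  if (is.null(gene)) {
    parts <- strsplit(rownames(counts), ":", fixed = TRUE)
    gene <- vapply(parts, `[`, "", 1L)
    exon <- as.integer(vapply(parts, `[`, "", 2L))
  }
  design <- as.data.frame(design)
  colnames(counts) <- design$sample
  structure(list(counts = counts, design = design,
                 gene = gene, exon = exon),
            class = "exon_count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  cells:", paste(levels(design_cells(x$design)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.exon_count_matrix <- function(x, ...) {
  cat(sprintf("exon_count_matrix: %d exons in %d genes x %d samples\n",
              nrow(x$counts), length(unique(x$gene)), ncol(x$counts)))
  invisible(x)
}

#' Population-by-timepoint cell factor for a sample design
#'
#' @param design a design data frame (`sample`, `population`,
#'   `timepoint`).
#' @return A factor with levels `"<population>:<timepoint>"`, timepoint
#'   varying slowest.
#' @export
design_cells <- function(design) {
  tp <- sort(unique(design$timepoint))
  pop <- sort(unique(as.character(design$population)))
  lev <- as.vector(outer(pop, tp, function(p, t) paste(p, t, sep = ":")))
  factor(paste(design$population, design$timepoint, sep = ":"), levels = lev)
}
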