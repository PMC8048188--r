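#' Genotype matrix container
#'
#' A light container for individual-by-locus genotype calls. Two call
#' encodings are supported: biallelic SNP dosages (counts of the alternate
#' allele, `0/1/2`, `NA` = missing) and unordered multi-allelic allele
#' pairs (microsatellites), stored as two integer allele-index matrices.
#'
#' @param dosage integer matrix, individuals x loci, entries in
#'   `{0, 1, 2, NA}` (SNP encoding). Exactly one of `dosage` or
#'   `a1`/`a2` must be given.
#' @param a1,a2 integer matrices, individuals x loci, allele indices
#'   (>= 1) of the two allele copies; `NA` in both = missing call
#'   (microsatellite encoding).
#' @param loci data frame with one row per locus: `id`, `cluster`
#'   (transcript-cluster / chromosome label), optional `qual` (site
#'   quality), `ref`, `alt`.
#' @param individuals data frame with one row per individual: `id`,
#'   optional `pop` (population label).
#' @param gq optional numeric matrix of per-call genotype qualities,
#'   same shape as the call matrices.
#'
#' @return An object of class `genotype_matrix` with elements `type`
#'   (`"snp"` or `"msat"`), the call matrices, `loci`, `individuals`
#'   and `gq`.
#' @export
genotype_matrix <- function(dosage = NULL, a1 = NULL, a2 = NULL,
                            loci, individuals, gq = NULL) {
  if (!is.null(dosage) && (!is.null(a1) || !is.null(a2)))
    stop("give either 'dosage' or 'a1'/'a2', not both")
  if (is.null(dosage) && (is.null(a1) || is.null(a2)))
    stop("give 'dosage' (SNP) or both 'a1' and 'a2' (microsatellite)")
  type <- if (!is.null(dosage)) "snp" else "msat"
  calls <- if (type == "snp") dosage else a1
  stopifnot(is.matrix(calls), nrow(loci) == ncol(calls),
            nrow(individuals) == nrow(calls))
  if (type == "snp") {
    bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
    if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
    storage.mode(dosage) <- "integer"
  } else {
    stopifnot(identical(dim(a1), dim(a2)))
    if (any(is.na(a1) != is.na(a2)))
      stop("half-missing allele pairs are not supported")
    storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  }
  if (!is.null(gq)) stopifnot(identical(dim(gq), dim(calls)))
  loci <- as.data.frame(loci); individuals <- as.data.frame(individuals)
  if (is.null(loci$id)) stop("'loci' needs an 'id' column")
  if (is.null(individuals$id)) stop("'individuals' needs an 'id' column")
  structure(list(type = type, dosage = dosage, a1 = a1, a2 = a2,
                 loci = loci, individuals = individuals, gq = gq),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) {
  m <- if (x$type == "snp") x$dosage else x$a1
  dim(m)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("genotype_matrix (%s): %d individuals x %d loci\n",
              x$type, d[1], d[2]))
  miss <- if (x$type == "snp") mean(is.na(x$dosage)) else mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.2f%%", 100 * miss))
  if (!is.null(x$individuals$pop))
    cat(sprintf("; populations: %s",
                paste(names(table(x$individuals$pop)), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# number of missing calls per individual / per locus
.missing_by_individual <- function(gm) {
  m <- if (gm$type == "snp") gm$dosage else gm$a1
  rowSums(is.na(m))
}
.missing_by_locus <- function(gm) {
  m <- if (gm$type == "snp") gm$dosage else gm$a1
  colMeans(is.na(m))
}

# subset helpers preserving metadata
subset_loci <- function(gm, keep) {
  if (is.logical(keep)) keep <- which(keep)
  gm$loci <- gm$loci[keep, , drop = FALSE]
  for (f in c("dosage", "a1", "a2", "gq"))
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][, keep, drop = FALSE]
  gm
}

subset_individuals <- function(gm, keep) {
  if (is.logical(keep)) keep <- which(keep)
  gm$individuals <- gm$individuals[keep, , drop = FALSE]
  for (f in c("dosage", "a1", "a2", "gq"))
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][keep, , drop = FALSE]
  gm
}

# population factor from gm or explicit labels
.pop_factor <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- gm$individuals$pop
  if (is.null(pops)) stop("no population labels available")
  if (length(pops) != dim(gm)[1])
    stop("population labels do not match the number of individuals")
  factor(pops)
}
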