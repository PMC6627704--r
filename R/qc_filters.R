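#' Quality-control filters for genotype tables
#'
#' `filter_autosomes()` drops every marker whose chromosome label is not a
#' plain autosome number (in particular the X chromosome).
#' `filter_snp_call_rate()` removes SNPs whose call rate falls below
#' `min_rate` (strictly below: a SNP at exactly the threshold is kept).
#' Both filters are idempotent and commute with each other.
#'
#' @param table A [genotype_table()].
#' @param min_rate Minimum fraction of non-missing calls a SNP needs to be
#'   retained (default 0.90).
#' @return A filtered [genotype_table()]; the sample set is never changed.
#' @export
filter_autosomes <- function(table) {
  validate_genotype_table(table)
  keep <- is_autosome_label(table$markers$chrom)
  subset_markers(table, which(keep))
}

#' @rdname filter_autosomes
#' @export
filter_snp_call_rate <- function(table, min_rate = 0.90) {
  validate_genotype_table(table)
  stopifnot(min_rate >= 0, min_rate <= 1)
  n <- nrow(table$samples)
  if (n == 0L) return(table)
  rate <- colSums(!is.na(table$calls)) / n
  subset_markers(table, which(rate >= min_rate))
}

#' Intersect two genotyping panels
#'
#' Restricts two tables to the SNPs present in both (in the first table's
#' marker order) and reconciles counted alleles: where the two panels count
#' different alleles of the same SNP, the second table's calls are flipped
#' (0 <-> 2) so that dosages refer to the same allele. SNPs carrying
#' incompatible (disjoint) allele pairs raise an error.
#'
#' @param a,b Two [genotype_table()] objects.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   panel.
#' @export
intersect_panels <- function(a, b) {
  validate_genotype_table(a); validate_genotype_table(b)
  shared <- intersect(a$markers$snp_id, b$markers$snp_id)
  ia <- which(a$markers$snp_id %in% shared)
  a2 <- subset_markers(a, ia)
  ib <- match(a2$markers$snp_id, b$markers$snp_id)
  b2 <- subset_markers(b, ib)

  for (j in seq_len(nrow(a2$markers))) {
    ca <- a2$markers$allele1[j]
    cb <- b2$markers$allele1[j]
    if (is.na(ca) || is.na(cb) || identical(ca, cb)) next
    set_a <- stats::na.omit(c(a2$markers$allele1[j], a2$markers$allele2[j]))
    set_b <- stats::na.omit(c(b2$markers$allele1[j], b2$markers$allele2[j]))
    if (length(intersect(set_a, set_b)) == 0L)
      stop("incompatible alleles for SNP ", a2$markers$snp_id[j],
           ": ", paste(set_a, collapse = "/"), " vs ", paste(set_b, collapse = "/"))
    if (identical(b2$markers$allele2[j], ca)) {
      ## flip dosages in b so both panels count the same allele
      b2$calls[, j] <- 2L - b2$calls[, j]
      tmp <- b2$markers$allele1[j]
      b2$markers$allele1[j] <- b2$markers$allele2[j]
      b2$markers$allele2[j] <- tmp
    } else {
      stop("cannot reconcile counted allele for SNP ", a2$markers$snp_id[j])
    }
  }
  list(a = a2, b = b2)
}

#' Per-sample genotyping call rates
#'
#' @param table A [genotype_table()] with at least one marker.
#' @return Numeric vector (sample order) of the fraction of non-missing calls.
#' @export
sample_call_rates <- function(table) {
  validate_genotype_table(table)
  if (nrow(table$markers) == 0L)
    stop("call rates are undefined for a table with zero markers")
  rates <- rowMeans(!is.na(table$calls))
  names(rates) <- table$samples$sample_id
  rates
}
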