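#' Expected homozygous SNP count under Hardy-Weinberg
#'
#' For an individual genotyped at a set of loci with reference allele
#' frequencies `p_j`, the expected number of homozygous SNPs is
#' `sum_j (1 - 2 p_j (1 - p_j))`. The expression is symmetric in
#' `p_j <-> 1 - p_j`, so the counted-allele frequency can be used in place of
#' the major-allele frequency.
#'
#' @param freqs Per-SNP allele-frequency vector.
#' @param loci Index set of the loci to sum over (default: all).
#' @return The expected homozygote count (a single number).
#' @export
expected_homozygosity <- function(freqs, loci = seq_along(freqs)) {
  if (length(loci) == 0L) stop("empty locus set")
  p <- freqs[loci]
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  sum(1 - 2 * p * (1 - p))
}

#' Heterozygosity-based inbreeding coefficient
#'
#' The classical excess-homozygosity estimator
#' `f_i = (O_i - E_i) / (L_i - E_i)`, where `O_i` is the observed number of
#' homozygous SNPs for individual `i`, `E_i` the Hardy-Weinberg expectation
#' given allele frequencies estimated from all samples pooled, and `L_i` the
#' number of non-missing genotyped SNPs for that individual. `E_i` sums only
#' over the individual's non-missing loci, so missingness does not bias the
#' contrast. The estimate may be negative (excess heterozygosity); no
#' small-sample correction is applied to `E_i`.
#'
#' @param table A [genotype_table()].
#' @param freqs Optional allele-frequency vector; by default frequencies are
#'   pooled over all samples in the table.
#' @return Data frame with one row per individual: `sample_id`, `population`,
#'   `O`, `E`, `L`, `f`. Where `L_i = E_i` the estimate is undefined and
#'   reported as `NA` with a warning.
#' @export
inbreeding_het <- function(table, freqs = NULL) {
  validate_genotype_table(table)
  if (is.null(freqs)) freqs <- allele_freqs(table)
  n <- nrow(table$samples)
  O <- E <- L <- f <- numeric(n)
  hom_contrib <- 1 - 2 * freqs * (1 - freqs)
  for (i in seq_len(n)) {
    g <- table$calls[i, ]
    ok <- !is.na(g) & !is.na(freqs)
    L[i] <- sum(ok)
    if (L[i] == 0L) stop("individual ", table$samples$sample_id[i],
                         " has no genotyped SNPs")
    O[i] <- sum(g[ok] != 1L)
    E[i] <- sum(hom_contrib[ok])
    f[i] <- if (abs(L[i] - E[i]) < .Machine$double.eps * L[i]) NA_real_
            else (O[i] - E[i]) / (L[i] - E[i])
  }
  if (anyNA(f)) warning("f is undefined (L = E) for ", sum(is.na(f)), " individual(s)")
  data.frame(sample_id = table$samples$sample_id,
             population = table$samples$population,
             O = O, E = E, L = L, f = f, stringsAsFactors = FALSE)
}

#' ROH-based inbreeding coefficient
#'
#' Fraction of the autosomal genome covered by an individual's runs of
#' homozygosity: the summed ROH length divided by the autosome length. The
#' default denominator, 2,242,939,370 bp, is the autosomal equine genome
#' length covered by the medium-density SNP array this pipeline was built
#' around.
#'
#' @param rohs Data frame of one individual's ROH segments with columns
#'   `chrom`, `start_bp`, `end_bp` (non-overlapping within a chromosome).
#' @param autosome_length Denominator in bp.
#' @return The genome fraction covered (single number).
#' @export
froh <- function(rohs, autosome_length = 2242939370) {
  stopifnot(autosome_length > 0)
  if (nrow(rohs) == 0L) return(0)
  for (ch in unique(rohs$chrom)) {
    seg <- rohs[rohs$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start_bp), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start_bp[-1L] <= seg$end_bp[-nrow(seg)]))
      stop("overlapping ROH segments on chromosome ", ch,
           " (detector invariant violated)")
  }
  sum(rohs$end_bp - rohs$start_bp + 1) / autosome_length
}
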