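## internal: vectorized Weir-Cockerham (1984) two-population variance
## components. Inputs are per-SNP sample sizes (diploid individuals), counted-
## allele frequencies and observed heterozygote proportions for each
## population. Returns the among-population component `a` and the total
## `a + b + c`.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, total = a + b + cc)
}

#' Weir-Cockerham F_ST for one SNP between two populations
#'
#' Computes the Weir-Cockerham (1984) variance components from the two
#' populations' genotype counts: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), and the
#' per-SNP estimate `a / (a + b + c)`. The estimator is unbiased around 0,
#' so per-SNP values may be slightly negative.
#'
#' @param counts_a,counts_b Length-3 vectors of genotype counts
#'   `(n0, n1, n2)` -- individuals carrying 0, 1 or 2 copies of the counted
#'   allele -- in each population.
#' @return A list: `numerator` (`a`), `denominator` (`a + b + c`), `ratio`
#'   (`NA` when the denominator is 0).
#' @export
wc_fst_snp <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 3L, length(counts_b) == 3L)
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  if (n1 < 1 || n2 < 1) stop("both populations need at least one non-missing call")
  p1 <- (2 * counts_a[3] + counts_a[2]) / (2 * n1)
  p2 <- (2 * counts_b[3] + counts_b[2]) / (2 * n2)
  h1 <- counts_a[2] / n1
  h2 <- counts_b[2] / n2
  wc <- wc_components(n1, p1, h1, n2, p2, h2)
  ratio <- if (is.na(wc$total) || wc$total == 0) NA_real_ else wc$a / wc$total
  list(numerator = unname(wc$a), denominator = unname(wc$total),
       ratio = unname(ratio))
}

#' Weighted Weir-Cockerham F_ST between two populations
#'
#' Ratio-of-sums combination across SNPs: the summed among-population
#' components divided by the summed totals, the standard multi-locus
#' Weir-Cockerham weighting. SNPs with a zero or undefined denominator (e.g.
#' monomorphic in both populations) are excluded from both sums; negative
#' per-SNP components are retained unclamped. Intended for an LD-pruned
#' panel.
#'
#' @param table A [genotype_table()].
#' @param popA,popB Population labels present in the table.
#' @return A list: `weighted_fst`, `n_snps_used`, and the per-SNP data frame
#'   `per_snp` (`snp_id`, `numerator`, `denominator`, `ratio`).
#' @export
fst_weighted <- function(table, popA, popB) {
  validate_genotype_table(table)
  ia <- table$samples$population == popA
  ib <- table$samples$population == popB
  if (!any(ia)) stop("no samples in population ", popA)
  if (!any(ib)) stop("no samples in population ", popB)
  GA <- table$calls[ia, , drop = FALSE]
  GB <- table$calls[ib, , drop = FALSE]
  n1 <- colSums(!is.na(GA)); n2 <- colSums(!is.na(GB))
  s1 <- colSums(GA, na.rm = TRUE); s2c <- colSums(GB, na.rm = TRUE)
  het1 <- colSums(GA == 1L, na.rm = TRUE); het2 <- colSums(GB == 1L, na.rm = TRUE)
  usable <- n1 >= 1 & n2 >= 1
  p1 <- ifelse(n1 > 0, s1 / (2 * n1), NA)
  p2 <- ifelse(n2 > 0, s2c / (2 * n2), NA)
  h1 <- ifelse(n1 > 0, het1 / n1, NA)
  h2 <- ifelse(n2 > 0, het2 / n2, NA)
  wc <- wc_components(n1, p1, h1, n2, p2, h2)
  ok <- usable & !is.na(wc$total) & wc$total != 0
  if (!any(ok)) stop("no usable SNPs between ", popA, " and ", popB)
  per_snp <- data.frame(snp_id = table$markers$snp_id,
                        numerator = wc$a, denominator = wc$total,
                        ratio = ifelse(ok, wc$a / wc$total, NA_real_),
                        stringsAsFactors = FALSE)
  list(weighted_fst = sum(wc$a[ok]) / sum(wc$total[ok]),
       n_snps_used = sum(ok), per_snp = per_snp)
}

#' Pairwise F_ST matrix over all populations
#'
#' Weighted Weir-Cockerham F_ST for every unordered pair of population
#' labels, plus the number of SNPs each estimate used.
#'
#' @param table A [genotype_table()] with at least 2 population labels.
#' @return A list: `fst` (symmetric matrix, zero diagonal) and `n_snps`
#'   (matrix of per-pair SNP counts).
#' @export
fst_matrix <- function(table) {
  validate_genotype_table(table)
  pops <- unique(table$samples$population)
  if (length(pops) < 2L) stop("need at least 2 population labels")
  sizes <- table(table$samples$population)
  if (any(sizes < 2)) warning("population(s) with fewer than 2 samples: ",
                              paste(names(sizes)[sizes < 2], collapse = ", "))
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  nsnp <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    res <- fst_weighted(table, pops[i], pops[j])
    fst[i, j] <- fst[j, i] <- res$weighted_fst
    nsnp[i, j] <- nsnp[j, i] <- res$n_snps_used
  }
  list(fst = fst, n_snps = nsnp)
}
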