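#' Pairwise linkage disequilibrium r-squared from unphased genotypes
#'
#' `r2_matrix()` returns the matrix of squared haplotype-frequency
#' correlations between every pair of markers in `X`, estimated by maximum
#' likelihood over the two-locus haplotype frequencies with an EM step to
#' resolve the phase of double heterozygotes (the only ambiguous class).
#' Haplotype counts are accumulated from pairwise-complete samples; EM starts
#' at linkage-equilibrium product frequencies and iterates to a `1e-8`
#' haplotype-frequency tolerance (at most 200 iterations). Monomorphic loci
#' yield `NA`. `r2_pair()` is the two-vector convenience wrapper.
#'
#' The computation is fully vectorized: all 3x3 genotype-pair counts for all
#' marker pairs are obtained as cross-products of indicator matrices, and the
#' EM update runs elementwise on those count matrices.
#'
#' @param X Genotype matrix (samples x markers, dosages 0/1/2, NA allowed).
#' @param Y Optional second genotype matrix; the result is then
#'   `ncol(X) x ncol(Y)`.
#' @return Matrix of r-squared values (`NA` where undefined).
#' @export
r2_matrix <- function(X, Y = NULL) {
  X <- as.matrix(X)
  sym <- is.null(Y)
  if (sym) Y <- X else Y <- as.matrix(Y)
  IX <- lapply(0:2, function(v) { M <- (X == v); M[is.na(M)] <- FALSE; M * 1 })
  IY <- lapply(0:2, function(v) { M <- (Y == v); M[is.na(M)] <- FALSE; M * 1 })
  N <- list()
  for (a in 1:3) for (b in 1:3)
    N[[paste(a, b)]] <- crossprod(IX[[a]], IY[[b]])

  ## known haplotype counts from unambiguous genotype pairs (dosages count
  ## allele "A" at both loci)
  K_AB <- 2 * N[["3 3"]] + N[["3 2"]] + N[["2 3"]]
  K_Ab <- 2 * N[["3 1"]] + N[["3 2"]] + N[["2 1"]]
  K_aB <- 2 * N[["1 3"]] + N[["1 2"]] + N[["2 3"]]
  K_ab <- 2 * N[["1 1"]] + N[["1 2"]] + N[["2 1"]]
  C <- N[["2 2"]]                       # double heterozygotes
  H <- K_AB + K_Ab + K_aB + K_ab + 2 * C # total haplotypes = 2 * n pairs

  pA <- (K_AB + K_Ab + C) / H
  pB <- (K_AB + K_aB + C) / H
  ## EM for the AB haplotype frequency; allele frequencies are invariant
  ## under the update, so hAB alone parameterizes the fit
  hAB <- pA * pB
  for (it in 1:200) {
    hAb <- pA - hAB
    haB <- pB - hAB
    hab <- 1 - pA - pB + hAB
    num <- hAB * hab
    den <- num + hAb * haB
    w <- ifelse(den > 0, num / den, 0.5)
    hAB_new <- (K_AB + C * w) / H
    delta <- max(abs(hAB_new - hAB), na.rm = TRUE)
    hAB <- hAB_new
    if (!is.finite(delta) || delta < 1e-8) break
  }
  D <- hAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D * D / denom, NA_real_)
  r2[H == 0] <- NA_real_
  if (sym) diag(r2) <- ifelse(diag(denom) > 0, 1, NA_real_)
  r2
}

#' @rdname r2_matrix
#' @param calls_a,calls_b Genotype vectors at the two loci (same samples).
#' @export
r2_pair <- function(calls_a, calls_b) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (sum(ok) < 2L) stop("need at least 2 samples with both calls non-missing")
  r2_matrix(matrix(calls_a[ok], ncol = 1), matrix(calls_b[ok], ncol = 1))[1, 1]
}

#' Linkage-disequilibrium decay along a chromosome
#'
#' Computes r-squared for every within-chromosome pair of polymorphic SNPs,
#' assigns each pair to a non-overlapping distance bin `[k*w, (k+1)*w)` by
#' intermarker distance, and reports the mean r-squared and mean distance per
#' bin. Bins without pairs are omitted.
#'
#' @param table A [genotype_table()].
#' @param chrom Chromosome label.
#' @param bin_width Bin width in bp (default 10 kb).
#' @return Data frame: `bin_start`, `bin_end`, `mean_r2`, `mean_distance`,
#'   `n_pairs`.
#' @export
ld_decay <- function(table, chrom, bin_width = 10000) {
  validate_genotype_table(table)
  idx <- which(table$markers$chrom == as.character(chrom))
  if (length(idx) < 2L) stop("chromosome ", chrom, " has fewer than 2 SNPs")
  X <- table$calls[, idx, drop = FALSE]
  bp <- table$markers$bp[idx]
  R2 <- r2_matrix(X)
  m <- length(idx)
  iu <- which(upper.tri(R2))
  r2 <- R2[iu]
  dist <- abs(outer(bp, bp, "-"))[iu]
  keep <- !is.na(r2)
  if (!any(keep)) return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                                    mean_r2 = numeric(0), mean_distance = numeric(0),
                                    n_pairs = integer(0)))
  r2 <- r2[keep]; dist <- dist[keep]
  bin <- floor(dist / bin_width)
  out <- data.frame(
    bin_start = as.numeric(names(tapply(r2, bin, mean))) * bin_width,
    mean_r2 = as.numeric(tapply(r2, bin, mean)),
    mean_distance = as.numeric(tapply(dist, bin, mean)),
    n_pairs = as.integer(tapply(r2, bin, length))
  )
  out$bin_end <- out$bin_start + bin_width
  out[order(out$bin_start), c("bin_start", "bin_end", "mean_r2",
                              "mean_distance", "n_pairs")]
}

#' Greedy sliding-window LD pruning
#'
#' Scans windows of `window` SNPs advancing `step` SNPs at a time within each
#' chromosome. Inside a window, marker pairs are examined in marker order;
#' when a pair's r-squared reaches `r2_max` the *later* SNP of the pair is
#' removed, and removed SNPs stay removed in all later windows. Windows never
#' cross chromosome boundaries. These are the settings used to decorrelate a
#' panel before inbreeding, IBD, F_ST, MDS, admixture and tree estimation.
#'
#' @param table A [genotype_table()] with markers sorted by chromosome and bp.
#' @param window Window size in SNPs (default 100).
#' @param step Window shift in SNPs (default 25).
#' @param r2_max Removal threshold: pairs with `r2 >= r2_max` trigger removal
#'   (default 0.1).
#' @return Character vector of the SNP ids kept.
#' @export
ld_prune <- function(table, window = 100, step = 25, r2_max = 0.1) {
  validate_genotype_table(table)
  if (step > window) stop("step must not exceed the window size")
  kept_ids <- character(0)
  for (ch in unique(table$markers$chrom)) {
    idx <- which(table$markers$chrom == ch)
    m <- length(idx)
    keep <- rep(TRUE, m)
    starts <- seq(1L, max(1L, m), by = step)
    starts <- starts[starts <= m]
    for (s in starts) {
      w_idx <- s:min(s + window - 1L, m)
      live <- w_idx[keep[w_idx]]
      if (length(live) < 2L) next
      R2 <- r2_matrix(table$calls[, idx[live], drop = FALSE])
      for (ii in seq_len(length(live) - 1L)) {
        if (!keep[live[ii]]) next
        for (jj in (ii + 1L):length(live)) {
          if (!keep[live[jj]]) next
          r2 <- R2[ii, jj]
          if (!is.na(r2) && r2 >= r2_max) keep[live[jj]] <- FALSE
        }
      }
    }
    kept_ids <- c(kept_ids, table$markers$snp_id[idx[keep]])
  }
  kept_ids
}

#' Restrict a table to a set of SNP ids
#'
#' @param table A [genotype_table()].
#' @param snp_ids Ids to keep (order of the table is preserved).
#' @return A [genotype_table()].
#' @export
keep_snps <- function(table, snp_ids) {
  subset_markers(table, which(table$markers$snp_id %in% snp_ids))
}
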