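#' Genome-wide identity-by-state matrix
#'
#' For each pair of individuals the IBS proportion is the mean, over loci
#' non-missing in both, of the shared allele count divided by 2 (0, 0.5 or 1
#' per locus). The genetic distance is `1 - IBS`. Computed by indicator
#' cross-products, so it scales to tens of thousands of markers.
#'
#' @param table A [genotype_table()] with at least 2 samples.
#' @return A list: `distance` (symmetric, zero diagonal), `ibs` (similarity),
#'   `n_loci` (pairwise complete locus counts), `metric_name`.
#' @export
ibs_matrix <- function(table) {
  validate_genotype_table(table)
  n <- nrow(table$samples)
  if (n < 2L) stop("need at least 2 samples")
  G <- table$calls
  I <- lapply(0:2, function(v) { M <- (G == v); M[is.na(M)] <- FALSE; M * 1 })
  counts <- matrix(0, n, n)
  shared <- matrix(0, n, n)
  for (a in 1:3) for (b in 1:3) {
    M <- tcrossprod(I[[a]], I[[b]])
    counts <- counts + M
    shared <- shared + M * (2 - abs(a - b)) / 2
  }
  if (any(counts[upper.tri(counts)] == 0)) {
    bad <- which(counts == 0 & upper.tri(counts), arr.ind = TRUE)[1L, ]
    stop("samples ", table$samples$sample_id[bad[1]], " and ",
         table$samples$sample_id[bad[2]], " share no non-missing loci")
  }
  ibs <- shared / counts
  ids <- table$samples$sample_id
  dimnames(ibs) <- dimnames(counts) <- list(ids, ids)
  dist <- 1 - ibs
  diag(dist) <- 0
  list(distance = dist, ibs = ibs, n_loci = counts,
       metric_name = "one_minus_ibs_proportion")
}

#' Method-of-moments identity-by-descent estimation
#'
#' PLINK-style moment estimator of the pairwise IBD-state distribution. For
#' each pair the observed counts of IBS states 0/1/2 (over loci non-missing
#' in both and polymorphic in the reference frequencies) are equated with
#' their expectations given the IBD state: `P(IBD=0)` from the IBS-0 count,
#' then `P(IBD=1)` and `P(IBD=2)` by sequential subtraction. Negative
#' solutions are truncated to 0 and the triple renormalized; the relatedness
#' summary is `pihat = P(IBD=2) + P(IBD=1)/2`. No small-sample bias
#' correction is applied to the expected state probabilities. This estimator
#' is intended for an LD-pruned panel.
#'
#' @param table A [genotype_table()].
#' @param freqs Reference allele frequencies (default: pooled over all
#'   samples in the table).
#' Truncation keeps the state probabilities in the simplex but makes the
#' null expectation of `pihat` slightly positive at moderate marker counts;
#' the untruncated `pihat_raw` is returned alongside as the unbiased signed
#' estimate.
#'
#' @return Data frame with one row per unordered pair: `id1`, `id2`,
#'   `p_ibd0`, `p_ibd1`, `p_ibd2`, `pihat`, `pihat_raw`, `n_loci_used`.
#' @export
mom_ibd <- function(table, freqs = NULL) {
  validate_genotype_table(table)
  if (is.null(freqs)) freqs <- allele_freqs(table)
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  p <- freqs
  q <- 1 - p
  ## per-locus expected IBS-state probabilities by IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd0 <- 1 - e0_ibd0 - e2_ibd0
  e2_ibd1 <- p^2 + q^2
  e1_ibd1 <- 2 * p * q

  n <- nrow(table$samples)
  ids <- table$samples$sample_id
  G <- table$calls
  pairs <- utils::combn(n, 2)
  out <- vector("list", ncol(pairs))
  warned <- FALSE
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    gi <- G[i, ]; gj <- G[j, ]
    ok <- poly & !is.na(gi) & !is.na(gj)
    L <- sum(ok)
    if (L < 50L && !warned) {
      warning("fewer than 50 usable loci for at least one pair")
      warned <- TRUE
    }
    d <- abs(gi[ok] - gj[ok])
    N0 <- sum(d == 2L)
    N2 <- sum(d == 0L)
    N1 <- L - N0 - N2
    E0 <- sum(e0_ibd0[ok])
    P0 <- if (E0 > 0) N0 / E0 else 0
    E1_1 <- sum(e1_ibd1[ok])
    P1 <- if (E1_1 > 0) (N1 - P0 * sum(e1_ibd0[ok])) / E1_1 else 0
    P2 <- if (L > 0) (N2 - P0 * sum(e2_ibd0[ok]) - P1 * sum(e2_ibd1[ok])) / L else 0
    Pv <- pmax(c(P0, P1, P2), 0)
    if (sum(Pv) == 0) Pv <- c(1, 0, 0)
    Pv <- Pv / sum(Pv)
    out[[k]] <- data.frame(id1 = ids[i], id2 = ids[j],
                           p_ibd0 = Pv[1], p_ibd1 = Pv[2], p_ibd2 = Pv[3],
                           pihat = Pv[3] + 0.5 * Pv[2],
                           pihat_raw = P2 + 0.5 * P1, n_loci_used = L,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared-distance matrix, eigendecomposes it, and scales
#' the top eigenvectors by the square roots of their eigenvalues. The
#' variance explained by component `k` is its eigenvalue divided by the sum
#' of the positive eigenvalues (negative eigenvalues are discarded from the
#' accounting).
#'
#' @param d Symmetric distance matrix (e.g. `ibs_matrix(x)$distance`).
#' @param n_components Number of components to return (at most samples - 1).
#' @return A list: `coordinates` (samples x components),
#'   `variance_explained` (fraction per component, non-increasing),
#'   `eigenvalues`.
#' @export
classical_mds <- function(d, n_components = 2) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 samples")
  if (n_components > nrow(d) - 1L) stop("n_components must be <= samples - 1")
  if (all(d == 0)) stop("all-zero distance matrix: variance undefined")
  fit <- stats::cmdscale(stats::as.dist(d), k = n_components, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  ve <- fit$eig[seq_len(n_components)] / sum(pos)
  ve <- pmax(ve, 0)
  coords <- fit$points
  if (ncol(coords) < n_components) {
    ## cmdscale drops dimensions with non-positive eigenvalues
    coords <- cbind(coords, matrix(0, nrow(coords), n_components - ncol(coords)))
  }
  rownames(coords) <- rownames(d)
  list(coordinates = coords, variance_explained = ve, eigenvalues = fit$eig)
}
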