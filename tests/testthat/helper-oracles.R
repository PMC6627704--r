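# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles with plain loops, sharing no code path with the
# package implementations they check.

# --- ROH: exhaustive naive scanner ------------------------------------------
# Enumerates every window explicitly, computes per-SNP homozygous-window
# fractions by direct counting, then walks candidate runs with a loop.
naive_roh_scan <- function(calls, markers, params) {
  m <- length(calls)
  w <- params$window_snp
  cand <- logical(m)
  if (m >= w) {
    n_win <- m - w + 1
    win_hom <- logical(n_win)
    for (s in seq_len(n_win)) {
      win <- calls[s:(s + w - 1)]
      win_hom[s] <- sum(is.na(win)) <= params$window_missing &&
        sum(win == 1, na.rm = TRUE) <= params$window_het
    }
    for (j in seq_len(m)) {
      in_win <- max(1, j - w + 1):min(n_win, j)
      frac <- sum(win_hom[in_win]) / length(in_win)
      cand[j] <- frac >= params$hit_threshold &&
        !is.na(calls[j]) && calls[j] != 1
    }
  }
  segs <- list()
  j <- 1
  while (j <= m) {
    if (!cand[j]) { j <- j + 1; next }
    run <- j
    while (j + 1 <= m && cand[j + 1] &&
           markers$bp[j + 1] - markers$bp[j] <= params$max_gap) {
      j <- j + 1
      run <- c(run, j)
    }
    len <- markers$bp[run[length(run)]] - markers$bp[run[1]] + 1
    if (length(run) >= params$min_snp && len >= params$min_length &&
        len / length(run) <= params$min_density) {
      segs[[length(segs) + 1]] <- data.frame(
        chrom = markers$chrom[run[1]], start_bp = markers$bp[run[1]],
        end_bp = markers$bp[run[length(run)]], n_snps = length(run),
        length = len, stringsAsFactors = FALSE)
    }
    j <- j + 1
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      length = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# --- LD r2: grid-search ML over the haplotype-frequency simplex -------------
# The two-locus haplotype likelihood profiled over D: allele frequencies are
# invariant under the EM update, so the ML solution has the sample allele
# frequencies and the search is over D alone (coarse grid then refinement).
grid_r2 <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  cells <- table(factor(ga, 0:2), factor(gb, 0:2))
  loglik <- function(D) {
    hAB <- pA * pB + D; hAb <- pA * (1 - pB) - D
    haB <- (1 - pA) * pB - D; hab <- (1 - pA) * (1 - pB) + D
    h <- cbind(hAB, hAb, haB, hab)
    if (any(h < -1e-12)) return(rep(-Inf, length(D)))
    h <- pmax(h, 0)
    P <- cbind(
      `0 0` = h[, 4]^2,           `0 1` = 2 * h[, 3] * h[, 4],
      `0 2` = h[, 3]^2,           `1 0` = 2 * h[, 2] * h[, 4],
      `1 1` = 2 * h[, 1] * h[, 4] + 2 * h[, 2] * h[, 3],
      `1 2` = 2 * h[, 1] * h[, 3], `2 0` = h[, 2]^2,
      `2 1` = 2 * h[, 1] * h[, 2], `2 2` = h[, 1]^2)
    n <- c(cells["0", "0"], cells["0", "1"], cells["0", "2"],
           cells["1", "0"], cells["1", "1"], cells["1", "2"],
           cells["2", "0"], cells["2", "1"], cells["2", "2"])
    as.vector(log(pmax(P, 1e-300)) %*% n)
  }
  lo <- max(-pA * pB, -(1 - pA) * (1 - pB))
  hi <- min(pA * (1 - pB), (1 - pA) * pB)
  grid <- seq(lo, hi, length.out = 4001)
  best <- grid[which.max(loglik(grid))]
  stepw <- (hi - lo) / 4000
  fine <- seq(max(lo, best - stepw), min(hi, best + stepw), length.out = 4001)
  D <- fine[which.max(loglik(fine))]
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# --- Weir-Cockerham per-SNP components, direct transcription ----------------
# Works from genotype count triples, writing each 1984 quantity out longhand.
wc_oracle <- function(cA, cB) {
  n1 <- cA[1] + cA[2] + cA[3]
  n2 <- cB[1] + cB[2] + cB[3]
  p1 <- (cA[2] + 2 * cA[3]) / (2 * n1)
  p2 <- (cB[2] + 2 * cB[3]) / (2 * n2)
  h1 <- cA[2] / n1
  h2 <- cB[2] / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  CV2 <- ((n1 - nbar)^2 + (n2 - nbar)^2) / (r - 1) / nbar^2  # squared CV of sizes
  nc <- nbar * (1 - CV2 / r)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, total = a + b + cc)
}

# --- greedy LD pruning, naive re-implementation -----------------------------
naive_prune <- function(table, window, step, r2_max) {
  kept <- character(0)
  for (ch in unique(table$markers$chrom)) {
    idx <- which(table$markers$chrom == ch)
    keep <- rep(TRUE, length(idx))
    s <- 1
    while (s <= length(idx)) {
      win <- s:min(s + window - 1, length(idx))
      for (i in win) for (j in win) {
        if (j <= i || !keep[i] || !keep[j]) next
        r2 <- tryCatch(r2_pair(table$calls[, idx[i]], table$calls[, idx[j]]),
                       error = function(e) NA)
        if (!is.na(r2) && r2 >= r2_max) keep[j] <- FALSE
      }
      s <- s + step
    }
    kept <- c(kept, table$markers$snp_id[idx[keep]])
  }
  kept
}
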