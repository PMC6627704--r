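test_that("expected homozygosity sums 1 - 2p(1-p) over the locus set", {
  expect_equal(expected_homozygosity(0.5), 0.5)
  expect_equal(expected_homozygosity(1.0), 1.0)
  # direct arithmetic: 0.5 + 0.82 + 0.58
  expect_equal(expected_homozygosity(c(0.5, 0.9, 0.7)), 1.90)
  # symmetric under p <-> 1-p, so counted vs major allele is immaterial
  expect_equal(expected_homozygosity(c(0.1, 0.3)),
               expected_homozygosity(c(0.9, 0.7)))
  expect_error(expected_homozygosity(numeric(0)), "empty")
  expect_error(expected_homozygosity(c(0.5, 0.2), integer(0)), "empty")
})

test_that("heterozygosity-based inbreeding has its analytic endpoints", {
  # fully homozygous individual: O = L -> f = 1 regardless of E
  calls <- rbind(c(0L, 2L, 2L, 0L, 2L),
                 c(1L, 1L, 0L, 1L, 2L),
                 c(0L, 1L, 2L, 1L, 1L))
  tab <- tiny_table(calls)
  res <- inbreeding_het(tab)
  expect_equal(res$f[1], 1)
  expect_equal(res$O[1], 5)
  expect_equal(res$L, c(5, 5, 5))
  # internal consistency with the defining identity
  expect_equal(res$f, (res$O - res$E) / (res$L - res$E))
  # E from pooled frequencies: p = colMeans/2
  p <- colMeans(calls) / 2
  expect_equal(res$E, rep(sum(1 - 2 * p * (1 - p)), 3))

  # missing loci are excluded from O, E and L for that individual
  calls2 <- calls; calls2[2, 1:2] <- NA
  res2 <- inbreeding_het(tiny_table(calls2))
  expect_equal(res2$L[2], 3)

  # all-homozygous panel: L = E at every individual -> undefined with warning
  mono <- tiny_table(matrix(2L, 3, 4))
  expect_warning(resm <- inbreeding_het(mono), "undefined")
  expect_true(all(is.na(resm$f)))
})

test_that("population mean of f is near zero for unrelated HW individuals", {
  m <- population_model(n_pops = 1, fst = 1e-4, n_snps = 1500)
  fr <- draw_balding_nichols(m, seed = 21)
  tab <- simulate_unrelated(fr, n_per_pop = 100, missing_rate = 0, seed = 22)
  res <- inbreeding_het(tab)
  se <- sd(res$f) / sqrt(nrow(res))
  expect_lt(abs(mean(res$f)), 3 * se + 1e-3)
})

test_that("ROH-based inbreeding divides summed lengths by the genome constant", {
  expect_equal(froh(data.frame(chrom = character(0), start_bp = numeric(0),
                               end_bp = numeric(0))), 0)
  segs <- data.frame(chrom = c("1", "2"), start_bp = c(1, 1),
                     end_bp = c(112146969, 112146968))
  # 224,293,937 bp over the array-covered autosome -> 0.1
  expect_equal(froh(segs), 0.1)
  full <- data.frame(chrom = "1", start_bp = 1, end_bp = 2242939370)
  expect_equal(froh(full), 1)
  overlap <- data.frame(chrom = c("1", "1"), start_bp = c(1, 50),
                        end_bp = c(100, 120))
  expect_error(froh(overlap), "overlapping")
})

test_that("EM r2 equals the grid-search ML oracle and is invariant to coding", {
  set.seed(31)
  # identical polymorphic vectors -> 1
  g <- rbinom(40, 2, 0.4)
  expect_equal(r2_pair(g, g), 1)

  # null: independent loci at n = 1000 stay below 0.01
  a <- rbinom(1000, 2, 0.3); b <- rbinom(1000, 2, 0.6)
  expect_lt(r2_pair(a, b), 0.01)

  # monomorphic locus -> undefined
  expect_true(is.na(r2_pair(rep(2L, 30), rbinom(30, 2, 0.5))))

  # oracle equality + symmetry + allele-flip invariance on random pairs
  for (k in 1:25) {
    set.seed(300 + k)
    n <- sample(30:80, 1)
    h <- rbinom(2 * n, 1, runif(1, 0.2, 0.8))
    g1 <- h[1:n] + h[(n + 1):(2 * n)]
    mix <- rbinom(2 * n, 1, runif(1))
    h2 <- ifelse(mix == 1, h, rbinom(2 * n, 1, runif(1, 0.2, 0.8)))
    g2 <- h2[1:n] + h2[(n + 1):(2 * n)]
    if (length(unique(g1)) == 1 || length(unique(g2)) == 1) next
    r <- r2_pair(g1, g2)
    expect_lt(abs(r - grid_r2(g1, g2)), 1e-6)
    expect_lt(abs(r - r2_pair(g2, g1)), 1e-12)
    expect_lt(abs(r - r2_pair(2L - g1, g2)), 1e-12)
    expect_lt(abs(r - r2_pair(g1, 2L - g2)), 1e-12)
  }
})

test_that("LD decay bins pairs by intermarker distance", {
  # three SNPs at 1, 4 and 13 kb: pairs at 3, 9 and 12 kb
  calls <- matrix(rbinom(60, 2, 0.5), nrow = 20)
  tab <- tiny_table(calls, bp = c(1000, 4000, 13000))
  bins <- ld_decay(tab, "1", bin_width = 10000)
  expect_equal(bins$bin_start, c(0, 10000))
  expect_equal(bins$n_pairs, c(2L, 1L))
  # a single-pair bin's mean is that pair's r2
  expect_equal(bins$mean_r2[2], r2_pair(calls[, 1], calls[, 3]))
  expect_equal(bins$mean_distance[2], 12000)

  # Wright-Fisher fixture: decreasing trend over the first bins
  H <- wright_fisher_haplotypes(Ne = 30, generations = 40, n_snps = 120,
                                length_bp = 5e7, seed = 41)
  wf <- haplotypes_to_table(H)
  dec <- ld_decay(wf, "1", bin_width = 5e6)
  first <- head(dec, 10)
  expect_lt(cor(first$bin_start, first$mean_r2, method = "spearman"), 0)
})

test_that("greedy LD pruning matches a naive oracle and its postcondition", {
  set.seed(51)
  # duplicated SNP column: exactly one of the pair survives
  base <- matrix(rbinom(200, 2, 0.5), nrow = 20)
  dup <- cbind(base[, 1], base)
  tabd <- tiny_table(dup)
  kept <- ld_prune(tabd, window = 5, step = 2, r2_max = 0.1)
  expect_true(xor("snp1" %in% kept, "snp2" %in% kept))

  # mutually independent SNPs: identity
  indep <- tiny_table(matrix(rbinom(2000 * 3, 2, 0.5), nrow = 2000)[1:500, ])
  expect_equal(ld_prune(indep, 100, 25, 0.1), indep$markers$snp_id)

  # 12-SNP constructed fixture with planted correlation blocks vs the oracle
  for (s in 1:5) {
    set.seed(500 + s)
    h <- matrix(rbinom(12 * 40, 1, 0.5), ncol = 12)
    h[, 2] <- h[, 1]; h[, 7] <- ifelse(rbinom(40, 1, 0.9) == 1, h[, 6], h[, 7])
    g <- h[seq(1, 39, 2), ] + h[seq(2, 40, 2), ]
    tab <- tiny_table(g, chrom = rep(c("1", "2"), each = 6))
    kept <- ld_prune(tab, window = 4, step = 2, r2_max = 0.1)
    expect_identical(kept, naive_prune(tab, 4, 2, 0.1))
  }

  # postcondition: no surviving within-window pair at or above the threshold
  wfH <- wright_fisher_haplotypes(Ne = 25, generations = 30, n_snps = 60,
                                  length_bp = 2e7, seed = 52)
  wf <- haplotypes_to_table(wfH)
  kept <- ld_prune(wf, window = 10, step = 5, r2_max = 0.2)
  # windows are defined on the original marker sequence: every surviving
  # pair that shared a window must be below the threshold
  m <- ncol(wf$calls)
  for (s in seq(1, m, by = 5)) {
    win <- s:min(s + 9, m)
    surv <- win[wf$markers$snp_id[win] %in% kept]
    if (length(surv) < 2) next
    R <- r2_matrix(wf$calls[, surv, drop = FALSE])
    expect_true(all(R[upper.tri(R)] < 0.2, na.rm = TRUE))
  }

  expect_error(ld_prune(wf, window = 10, step = 11), "step")
})
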