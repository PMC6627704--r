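test_that("per-SNP Weir-Cockerham matches the direct formula transcription", {
  # fixed for opposite alleles: complete differentiation
  fixed <- wc_fst_snp(c(20, 0, 0), c(0, 0, 20))
  expect_equal(fixed$ratio, 1)

  # identical large samples from one frequency: estimate near 0
  set.seed(91)
  g <- rmultinom(2, 500, c(0.36, 0.48, 0.16))
  near0 <- wc_fst_snp(g[, 1], g[, 2])
  expect_lt(abs(near0$ratio), 0.05)

  # random genotype-count tables vs the longhand oracle
  for (k in 1:50) {
    set.seed(9100 + k)
    cA <- rmultinom(1, sample(8:40, 1), runif(3, 0.05, 1))[, 1]
    cB <- rmultinom(1, sample(8:40, 1), runif(3, 0.05, 1))[, 1]
    got <- wc_fst_snp(cA, cB)
    want <- wc_oracle(cA, cB)
    expect_lt(abs(got$numerator - want$a), 1e-10)
    expect_lt(abs(got$denominator - want$total), 1e-10)
  }

  # monomorphic in both populations: undefined ratio
  mono <- wc_fst_snp(c(10, 0, 0), c(12, 0, 0))
  expect_true(is.na(mono$ratio))
})

test_that("weighted F_ST recovers the simulated differentiation", {
  # identical populations (same frequencies) -> near 0
  model0 <- population_model(n_pops = 1, fst = 0.05, n_snps = 1000)
  fr0 <- draw_balding_nichols(model0, seed = 93)
  fr0 <- rbind(popA = fr0[1, ], popB = fr0[1, ])
  attr(fr0, "markers") <- attr(draw_balding_nichols(model0, seed = 93), "markers")
  tab0 <- simulate_unrelated(fr0, 30, 0, seed = 94)
  res0 <- fst_weighted(tab0, "popA", "popB")
  expect_lt(abs(res0$weighted_fst), 0.02)

  # Balding-Nichols F = 0.10 recovered within +/- 0.01 (3 seeds)
  for (s in c(11, 22, 33)) {
    model <- population_model(n_pops = 2, fst = 0.10, n_snps = 5000,
                              chrom_plan = data.frame(chrom = "1", n_snps = 5000,
                                                      length_bp = 2e8))
    fr <- draw_balding_nichols(model, seed = s)
    tab <- simulate_unrelated(fr, 50, 0, seed = s + 1)
    res <- fst_weighted(tab, "pop1", "pop2")
    expect_lt(abs(res$weighted_fst - 0.10), 0.01)
    expect_gt(res$n_snps_used, 4500)
  }

  # all SNPs monomorphic -> error
  mono <- tiny_table(matrix(2L, 6, 4), pop = rep(c("A", "B"), each = 3))
  mono$samples$population <- rep(c("A", "B"), each = 3)
  expect_error(fst_weighted(mono, "A", "B"), "no usable SNPs")
})

test_that("the F_ST matrix is symmetric and ranks simulated divergence", {
  # three populations at increasing divergence from the shared ancestor
  model <- population_model(n_pops = 3, fst = c(0.01, 0.10, 0.30), n_snps = 3000)
  fr <- draw_balding_nichols(model, seed = 95)
  tab <- simulate_unrelated(fr, 30, 0, seed = 96)
  res <- fst_matrix(tab)
  expect_true(isSymmetric(res$fst))
  expect_equal(unname(diag(res$fst)), rep(0, 3))
  # pairs involving the most drifted population are the most differentiated
  expect_gt(res$fst["pop1", "pop3"], res$fst["pop1", "pop2"])
  expect_gt(res$fst["pop2", "pop3"], res$fst["pop1", "pop2"])

  # two populations: a single off-diagonal value
  two <- simulate_unrelated(fr[1:2, ], 20, 0, seed = 97,
                            markers = attr(fr, "markers"))
  res2 <- fst_matrix(two)
  expect_equal(dim(res2$fst), c(2L, 2L))
  expect_equal(res2$fst[1, 2], res2$fst[2, 1])
})

test_that("admixture EM maximizes the likelihood with simplex constraints", {
  model <- population_model(n_pops = 2, fst = 0.2, n_snps = 300)
  fr <- draw_balding_nichols(model, seed = 101)
  tab <- simulate_unrelated(fr, 20, 0.02, seed = 102)

  # K = 1 is the analytic fixed point: Q all ones, P = pooled frequencies
  fit1 <- admixture_em(tab, 1, seed = 103)
  expect_equal(unname(fit1$Q[, 1]), rep(1, 40))
  expect_equal(as.vector(fit1$P), unname(allele_freqs(tab)), tolerance = 1e-6)

  fit2 <- admixture_em(tab, 2, seed = 104)
  # monotone log-likelihood, Q rows on the simplex at convergence
  expect_true(all(diff(fit2$loglik_trace) > -1e-6))
  expect_equal(unname(rowSums(fit2$Q)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(fit2$P >= 0 & fit2$P <= 1))

  # well-separated pops: individuals assign cleanly to their cluster
  expect_gt(mean(apply(fit2$Q, 1, max)), 0.9)
  # and the assignment matches the population labels after label matching
  lab <- apply(fit2$Q, 1, which.max)
  expect_true(all(lab[1:20] == lab[1]) && all(lab[21:40] == lab[21]) &&
                lab[1] != lab[21])

  expect_error(admixture_em(tab, 50, seed = 1), "K must not exceed")
})

test_that("cross-validation prefers the generating number of clusters", {
  model <- population_model(n_pops = 2, fst = 0.25, n_snps = 200)
  fr <- draw_balding_nichols(model, seed = 111)
  tab <- simulate_unrelated(fr, 15, 0, seed = 112)
  cv <- admixture_cv(tab, K_range = 1:3, folds = 3, seed = 113,
                     tol = 1e-5, max_iter = 150)
  expect_equal(nrow(cv), 3L)
  expect_lt(cv$cv_error[cv$K == 2], cv$cv_error[cv$K == 1])
  # robust to the number of folds on strongly structured data
  cv5 <- admixture_cv(tab, K_range = 1:3, folds = 5, seed = 114,
                      tol = 1e-5, max_iter = 150)
  expect_equal(cv$K[which.min(cv$cv_error)] == 1,
               cv5$K[which.min(cv5$cv_error)] == 1)
  expect_error(admixture_cv(tab, 1:2, folds = 1, seed = 1), "folds")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3-taxon closed form: terminal branches (d12+d13-d23)/2 etc.
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0, 2, 4))

  # additive 5-taxon matrix: exact topology and path-length recovery
  set.seed(121)
  for (k in 1:5) {
    true <- ape::rtree(5, br = function(n) runif(n, 0.2, 1.5))
    true <- ape::unroot(true)
    dmat <- ape::cophenetic.phylo(true)
    rec <- nj_tree(dmat)
    expect_equal(ape::dist.topo(ape::unroot(rec), true), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(dmat), colnames(dmat)] -
                        dmat)), 1e-9)
  }

  # two identical rows join with zero-length terminal branches
  d5 <- as.matrix(dist(c(0, 0, 3, 7)))
  rownames(d5) <- colnames(d5) <- paste0("t", 1:4)
  tr5 <- nj_tree(d5)
  twin_edges <- tr5$edge.length[match(1:2, tr5$edge[, 2])]
  expect_equal(unname(twin_edges), c(0, 0))

  # leaf-permutation invariance of the unrooted topology
  perm <- c(3, 1, 5, 2, 4)
  true <- ape::unroot(ape::rtree(5))
  dmat <- ape::cophenetic.phylo(true)
  t1 <- nj_tree(dmat)
  t2 <- nj_tree(dmat[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)

  expect_error(nj_tree(matrix(1:9, 3, 3)), "symmetric")
})

test_that("Newick output round-trips topology and branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  txt <- readLines(path)
  # one parenthesized cluster holding all three labelled, lengthed leaves
  expect_match(txt, "^\\(.*\\);$")
  for (tip in c("A:", "B:", "C:")) expect_match(txt, tip, fixed = TRUE)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))

  # 5-taxon additive tree: re-read pairwise distances equal the original
  set.seed(123)
  true <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.3, 1)))
  dmat <- ape::cophenetic.phylo(true)
  rec <- nj_tree(dmat)
  write_newick(rec, path)
  back5 <- ape::read.tree(path)
  expect_lt(max(abs(ape::cophenetic.phylo(back5)[rownames(dmat), colnames(dmat)] -
                      dmat)), 1e-8)

  bad <- tr; bad$tip.label[2] <- ""
  expect_error(write_newick(bad, path), "label")
})
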