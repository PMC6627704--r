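test_that("PED/MAP decoding matches a hand-decoded fixture", {
  # marker m1: alleles A/G, counted = A (lexicographically smaller)
  # marker m2: alleles C/T, counted = C; marker m3: missing for sample 2
  f <- write_pedmap_lines(
    c("fam1 ind1 0 0 1 -9 A A C T G G",
      "fam2 ind2 0 0 2 -9 A G T T 0 0"),
    c("1 m1 0 100", "1 m2 0 200", "2 m3 0 50"))
  tab <- read_plink_text(f$ped, f$map)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(tab$samples$population, c("fam1", "fam2"))
  expect_equal(tab$samples$sample_id, c("ind1", "ind2"))
  expect_identical(tab$calls, matrix(c(2L, 1L, 1L, 0L, 2L, NA), nrow = 2,
                                     dimnames = NULL))
  expect_equal(tab$markers$allele1, c("A", "C", "G"))
  expect_equal(tab$markers$bp, c(100, 200, 50))
})

test_that("all-missing PED rows and malformed inputs are handled", {
  f <- write_pedmap_lines(
    c("p i1 0 0 0 -9 0 0 0 0", "p i2 0 0 0 -9 0 0 0 0"),
    c("1 m1 0 10", "1 m2 0 20"))
  tab <- read_plink_text(f$ped, f$map)
  expect_true(all(is.na(tab$calls)))

  # half-missing genotype becomes missing with a warning
  f2 <- write_pedmap_lines(c("p i1 0 0 0 -9 A 0"), c("1 m1 0 10"))
  expect_warning(tab2 <- read_plink_text(f2$ped, f2$map), "half-missing")
  expect_true(is.na(tab2$calls[1, 1]))

  # MAP rows not matching PED marker count
  f3 <- write_pedmap_lines(c("p i1 0 0 0 -9 A A C C"),
                           c("1 m1 0 10", "1 m2 0 20", "1 m3 0 30"))
  expect_error(read_plink_text(f3$ped, f3$map), "dimension mismatch")

  # ragged PED
  f4 <- write_pedmap_lines(c("p i1 0 0 0 -9 A A", "p i2 0 0 0 -9 A A C C"),
                           c("1 m1 0 10"))
  expect_error(read_plink_text(f4$ped, f4$map), "ragged PED.*line 2")
})

test_that("PED/MAP round-trip preserves calls, order and labels exactly", {
  set.seed(11)
  raw <- random_table(6, 15, seed = 11, miss = 0.15)
  raw$samples$population <- rep(c("breedA", "breedB"), each = 3)
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "rt.ped"); map <- file.path(dir, "rt.map")
  # first pass normalizes the counted allele to the lexicographic rule
  # (a monomorphic column can be re-counted); thereafter identity holds
  write_plink_text(raw, ped, map)
  tab <- read_plink_text(ped, map)
  write_plink_text(tab, ped, map)
  back <- read_plink_text(ped, map)
  expect_identical(back$calls, tab$calls)
  expect_equal(back$markers$snp_id, tab$markers$snp_id)
  expect_equal(back$markers$bp, tab$markers$bp)
  expect_equal(back$samples, tab$samples)

  # empty table writes valid (empty) files
  empty <- tab; empty$calls <- tab$calls[0, , drop = FALSE]
  empty$samples <- tab$samples[0, , drop = FALSE]
  write_plink_text(empty, ped, map)
  back0 <- read_plink_text(ped, map)
  expect_equal(nrow(back0$samples), 0L)
  expect_equal(nrow(back0$markers), 15L)
})

test_that("internal TSV dialect round-trips", {
  tab <- random_table(4, 6, seed = 3, miss = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(tab, path)
  back <- read_genotype_tsv(path, map = tab$markers)
  expect_identical(back$calls, tab$calls)
  expect_equal(back$samples, tab$samples)
})

test_that("autosome and call-rate filters follow the QC rules", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L, 0L), each = 4), nrow = 4)
  tab <- tiny_table(calls, chrom = c("1", "X", "2", "X", "31"))
  aut <- filter_autosomes(tab)
  expect_equal(aut$markers$chrom, c("1", "2", "31"))
  expect_equal(nrow(aut$samples), 4L)
  # idempotent
  expect_identical(filter_autosomes(aut)$markers, aut$markers)
  # all-X leaves samples intact
  allx <- tiny_table(calls, chrom = rep("X", 5))
  expect_equal(ncol(filter_autosomes(allx)$calls), 0L)
  expect_equal(nrow(filter_autosomes(allx)$samples), 4L)

  # call-rate boundary: exactly 90% kept, below removed (10 samples)
  cr <- matrix(1L, nrow = 10, ncol = 3)
  cr[1, 2] <- NA          # snp2: 9/10 = 0.90 -> kept
  cr[1:2, 3] <- NA        # snp3: 8/10 = 0.80 -> removed
  tcr <- tiny_table(cr)
  kept <- filter_snp_call_rate(tcr, 0.90)
  expect_equal(kept$markers$snp_id, c("snp1", "snp2"))
  # no missing data -> identity
  expect_equal(ncol(filter_snp_call_rate(tiny_table(cr[3:10, ]))$calls), 3L)
  # idempotence and order invariance with the autosome filter
  mixed <- tiny_table(cbind(cr, cr), chrom = rep(c("1", "X"), each = 3))
  a_then_c <- filter_snp_call_rate(filter_autosomes(mixed), 0.9)
  c_then_a <- filter_autosomes(filter_snp_call_rate(mixed, 0.9))
  expect_identical(a_then_c$markers, c_then_a$markers)
  expect_identical(a_then_c$calls, c_then_a$calls)
})

test_that("planted missingness survivor list matches a hand count", {
  set.seed(9)
  calls <- matrix(1L, nrow = 10, ncol = 20)
  n_miss <- c(0, 1, 2, 0, 3, 1, 0, 2, 1, 0, 4, 0, 1, 2, 0, 1, 5, 0, 1, 2)
  for (j in seq_len(20)) if (n_miss[j] > 0) calls[seq_len(n_miss[j]), j] <- NA
  tab <- tiny_table(calls)
  kept <- filter_snp_call_rate(tab, 0.90)
  expect_equal(kept$markers$snp_id, paste0("snp", which(n_miss <= 1)))
})

test_that("sample call rates are per-sample fractions of non-missing calls", {
  calls <- matrix(1L, nrow = 3, ncol = 10)
  calls[2, 1:5] <- NA
  calls[3, 1:2] <- NA
  tab <- tiny_table(calls)
  expect_equal(unname(sample_call_rates(tab)), c(1, 0.5, 0.8))
  empty <- tiny_table(matrix(integer(0), nrow = 3, ncol = 0))
  expect_error(sample_call_rates(empty), "zero markers")
})

test_that("panel intersection keeps shared SNPs and reconciles counted alleles", {
  a <- tiny_table(matrix(c(0L, 1L, 2L, 2L, 1L, 0L, 1L, 1L, 0L, 2L), nrow = 2))
  b <- tiny_table(matrix(c(2L, 1L, 0L, 0L, 1L, 2L, 2L, 0L), nrow = 2))
  b$markers$snp_id <- c("snp2", "snp3", "snp9", "snp5")
  res <- intersect_panels(a, b)
  expect_equal(res$a$markers$snp_id, c("snp2", "snp3", "snp5"))
  expect_equal(res$b$markers$snp_id, c("snp2", "snp3", "snp5"))

  # swapped counted allele in b gets flipped
  b2 <- b
  b2$markers$allele1 <- c("B", "A", "A", "A")
  b2$markers$allele2 <- c("A", "B", "B", "B")
  res2 <- intersect_panels(a, b2)
  expect_equal(res2$b$calls[, 1], 2L - b$calls[, 1])
  expect_equal(res2$b$markers$allele1[1], "A")
  # other shared markers untouched
  expect_equal(res2$b$calls[, 2], b$calls[, 2])

  # identical panels -> identity
  resid <- intersect_panels(a, a)
  expect_identical(resid$a$calls, a$calls)
  expect_identical(resid$b$calls, a$calls)

  # disjoint allele pairs -> incompatibility error
  b3 <- b
  b3$markers$allele1 <- c("C", "A", "A", "A")
  b3$markers$allele2 <- c("T", "B", "B", "B")
  expect_error(intersect_panels(a, b3), "incompatible alleles")
})
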