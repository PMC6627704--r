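# Shared fixture builders for the suite. Everything is generated in code.

# quick genotype_table from a call matrix; markers default to one autosome
# with 1-Mb spacing
tiny_table <- function(calls, chrom = NULL, bp = NULL, pop = "popA",
                       sample_id = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  n <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) {
    # per-chromosome ascending 1-Mb spaced positions
    bp <- if (m == 0) numeric(0) else
      stats::ave(seq_len(m), rep_len(chrom, m), FUN = seq_along) * 1e6
  }
  if (is.null(sample_id)) sample_id <- sprintf("s%02d", seq_len(n))
  genotype_table(
    calls,
    data.frame(snp_id = sprintf("snp%d", seq_len(m)),
               chrom = as.character(rep_len(chrom, m)),
               bp = bp, allele1 = rep_len("A", m), allele2 = rep_len("B", m),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, population = rep_len(pop, n),
               stringsAsFactors = FALSE))
}

# write a small PED/MAP pair into a temp dir and return the two paths
write_pedmap_lines <- function(ped_lines, map_lines) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ped <- file.path(dir, "x.ped"); map <- file.path(dir, "x.map")
  writeLines(ped_lines, ped); writeLines(map_lines, map)
  list(ped = ped, map = map)
}

# random genotype table for property-style loops
random_table <- function(n, m, seed, miss = 0, maf_range = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
  if (miss > 0) calls[runif(n * m) < miss] <- NA
  tiny_table(calls)
}

# random genotype vector with homozygous stretches planted for the
# detector-vs-oracle comparisons
random_roh_chromosome <- function(seed, m = 200) {
  set.seed(seed)
  bp <- sort(sample.int(6e7, m))
  calls <- rbinom(m, 2, 0.5)
  # plant 0-2 homozygous stretches of random extent
  for (k in seq_len(sample(0:2, 1))) {
    a <- sample.int(m - 20, 1)
    b <- min(m, a + sample(20:120, 1))
    calls[a:b] <- sample(c(0L, 2L), b - a + 1, replace = TRUE)
  }
  # sprinkle missingness
  calls[runif(m) < 0.03] <- NA
  list(calls = calls,
       markers = data.frame(snp_id = sprintf("s%d", 1:m), chrom = "1", bp = bp,
                            stringsAsFactors = FALSE))
}

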