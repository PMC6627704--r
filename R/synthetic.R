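#' Population model for synthetic genotype generation
#'
#' Describes the structured populations the generators emulate: the number of
#' populations, their Balding-Nichols differentiation from a shared ancestral
#' gene pool, the number of SNPs and the chromosome layout. Defaults are a
#' desk-scale stand-in for a multi-breed medium-density array study: a few
#' populations of ~20 individuals with moderate differentiation and an
#' ancestral allele-frequency law bounded away from fixation.
#'
#' @param n_pops Number of populations.
#' @param fst Balding-Nichols differentiation per population (recycled);
#'   `0 <= fst < 1`.
#' @param n_snps Total number of SNPs across all chromosomes.
#' @param chrom_plan Data frame with columns `chrom`, `n_snps`, `length_bp`;
#'   defaults to two 100-Mb autosomes splitting `n_snps` evenly.
#' @param freq_range Lower/upper bound of the Uniform ancestral allele
#'   frequency law (default `c(0.05, 0.95)`, avoiding monomorphic loci).
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_pops = 3, fst = 0.1, n_snps = 2000,
                             chrom_plan = NULL, freq_range = c(0.05, 0.95)) {
  fst <- rep_len(fst, n_pops)
  stopifnot(all(fst >= 0), all(fst < 1), n_snps >= 1)
  if (is.null(chrom_plan)) {
    n1 <- ceiling(n_snps / 2)
    chrom_plan <- data.frame(chrom = c("1", "2"),
                             n_snps = c(n1, n_snps - n1),
                             length_bp = c(1e8, 1e8),
                             stringsAsFactors = FALSE)
  }
  chrom_plan$chrom <- as.character(chrom_plan$chrom)
  if (sum(chrom_plan$n_snps) != n_snps)
    stop("chromosome plan SNP counts must sum to n_snps")
  if (any(chrom_plan$length_bp <= 0)) stop("chromosome lengths must be positive")
  structure(list(n_pops = n_pops, fst = fst, n_snps = n_snps,
                 chrom_plan = chrom_plan, freq_range = freq_range),
            class = "population_model")
}

## internal: draw a sorted marker map from a chromosome plan
make_marker_map <- function(chrom_plan, prefix = "snp") {
  maps <- lapply(seq_len(nrow(chrom_plan)), function(i) {
    n <- chrom_plan$n_snps[i]
    if (n == 0L) return(NULL)
    bp <- sort(sample.int(chrom_plan$length_bp[i], n))
    data.frame(chrom = chrom_plan$chrom[i], bp = bp, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$snp_id <- sprintf("%s_%s_%d", prefix, map$chrom, seq_len(nrow(map)))
  map$allele1 <- "A"
  map$allele2 <- "B"
  map[, c("snp_id", "chrom", "bp", "allele1", "allele2")]
}

#' Balding-Nichols population allele frequencies
#'
#' For each SNP an ancestral frequency `p` is drawn from the model's Uniform
#' law; each population's frequency is then drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is `p` and whose variance is
#' `F p (1-p)` -- the classical Balding-Nichols model, so the Weir-Cockerham
#' estimator applied to the resulting genotypes recovers `F`. Populations with
#' `F = 0` copy the ancestral frequency.
#'
#' @param model A [population_model()].
#' @param seed Integer seed; the draw is bit-reproducible.
#' @return Matrix (`n_pops` x `n_snps`) of population allele frequencies with
#'   attributes `ancestral` (the ancestral frequencies) and `markers`
#'   (a marker map drawn from the chromosome plan).
#' @export
draw_balding_nichols <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  set.seed(as.integer(seed))
  m <- model$n_snps
  p <- stats::runif(m, model$freq_range[1], model$freq_range[2])
  freqs <- matrix(NA_real_, nrow = model$n_pops, ncol = m)
  for (k in seq_len(model$n_pops)) {
    f <- model$fst[k]
    if (f == 0) {
      freqs[k, ] <- p
    } else {
      freqs[k, ] <- stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
  }
  rownames(freqs) <- paste0("pop", seq_len(model$n_pops))
  attr(freqs, "ancestral") <- p
  attr(freqs, "markers") <- make_marker_map(model$chrom_plan)
  freqs
}

#' Simulate unrelated diploid individuals from population frequencies
#'
#' Genotypes are Binomial(2, p) draws, independent across loci (no LD), with
#' optional Bernoulli missingness -- the Hardy-Weinberg baseline against which
#' the inbreeding and relatedness estimators should read zero.
#'
#' @param freqs Population x SNP frequency matrix, e.g. from
#'   [draw_balding_nichols()]; its `markers` attribute (or the `markers`
#'   argument) supplies the map.
#' @param n_per_pop Individuals per population (recycled).
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed.
#' @param markers Optional marker map overriding `attr(freqs, "markers")`.
#' @return A [genotype_table()] with populations labelled by the rownames of
#'   `freqs`.
#' @export
simulate_unrelated <- function(freqs, n_per_pop, missing_rate = 0, seed,
                               markers = NULL) {
  if (is.null(markers)) markers <- attr(freqs, "markers")
  if (is.null(markers)) stop("no marker map: supply `markers`")
  stopifnot(all(freqs >= 0 & freqs <= 1), missing_rate >= 0, missing_rate < 1)
  set.seed(as.integer(seed))
  n_pops <- nrow(freqs)
  m <- ncol(freqs)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  pops <- rownames(freqs)
  if (is.null(pops)) pops <- paste0("pop", seq_len(n_pops))

  blocks <- vector("list", n_pops)
  for (k in seq_len(n_pops)) {
    n <- n_per_pop[k]
    g <- matrix(stats::rbinom(n * m, 2L, rep(freqs[k, ], each = n)), nrow = n)
    blocks[[k]] <- g
  }
  calls <- do.call(rbind, blocks)
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }
  samples <- data.frame(
    sample_id = unlist(lapply(seq_len(n_pops), function(k)
      sprintf("%s_%02d", pops[k], seq_len(n_per_pop[k])))),
    population = rep(pops, n_per_pop),
    stringsAsFactors = FALSE
  )
  genotype_table(calls, markers, samples)
}

#' Pedigree specification
#'
#' A data frame of individuals with optional sire and dam (`NA` for founders).
#' Parents must precede offspring, both parents are given or neither, selfing
#' is rejected, and parent links must be acyclic.
#'
#' @param id Character vector of individual ids (unique).
#' @param sire,dam Parent ids or `NA` for founders.
#' @param pop Population label per individual.
#' @return A validated data frame of class `pedigree_spec`.
#' @export
pedigree_spec <- function(id, sire, dam, pop = "ped") {
  ped <- data.frame(id = as.character(id), sire = as.character(sire),
                    dam = as.character(dam),
                    pop = rep_len(as.character(pop), length(id)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  if (any(xor(is.na(ped$sire), is.na(ped$dam))))
    stop("individuals must have both parents or neither")
  nonf <- !is.na(ped$sire)
  if (any(ped$sire[nonf] == ped$dam[nonf])) stop("selfing is not allowed")
  for (i in which(nonf)) {
    ps <- match(ped$sire[i], ped$id)
    pd <- match(ped$dam[i], ped$id)
    if (is.na(ps) || is.na(pd)) stop("unknown parent for ", ped$id[i])
    if (ps >= i || pd >= i)
      stop("pedigree cycle or ordering violation: parents of ", ped$id[i],
           " must precede it")
  }
  class(ped) <- c("pedigree_spec", "data.frame")
  ped
}

#' The five-member full-sib mating pedigree
#'
#' Two unrelated, non-inbred founders; their two offspring mated; one
#' grand-offspring. The grand-offspring's expected inbreeding coefficient by
#' Wright's path counting is exactly 1/4.
#'
#' @param pop Population label.
#' @return A [pedigree_spec()].
#' @export
fullsib_pedigree <- function(pop = "fullsib") {
  pedigree_spec(id   = c("F1", "F2", "S1", "S2", "O1"),
                sire = c(NA, NA, "F1", "F1", "S1"),
                dam  = c(NA, NA, "F2", "F2", "S2"),
                pop  = pop)
}

#' Pedigree kinship and inbreeding by exact recursion
#'
#' `kinship_matrix()` computes the kinship (coancestry) matrix by the tabular
#' method: for founders `phi(i,i) = 1/2`; for an individual with parents `s`
#' and `d`, `phi(i,i) = (1 + phi(s,d)) / 2` and
#' `phi(i,j) = (phi(s,j) + phi(d,j)) / 2` for any `j` preceding `i`. This
#' recursion evaluates Wright's path-counting coefficients exactly.
#' `pedigree_inbreeding()` returns `F_i = phi(sire_i, dam_i)` (0 for
#' founders).
#'
#' @param ped A [pedigree_spec()].
#' @return `kinship_matrix`: a symmetric matrix; `pedigree_inbreeding`: a
#'   named numeric vector of inbreeding coefficients.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_spec"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- match(ped$sire[i], ped$id)
    d <- match(ped$dam[i], ped$id)
    if (is.na(s)) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[s, d])
      for (j in seq_len(i - 1L)) {
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[s, j] + phi[d, j])
      }
    }
  }
  phi
}

#' @rdname kinship_matrix
#' @export
pedigree_inbreeding <- function(ped) {
  phi <- kinship_matrix(ped)
  f <- vapply(seq_len(nrow(ped)), function(i) {
    s <- match(ped$sire[i], ped$id)
    if (is.na(s)) return(0)
    phi[s, match(ped$dam[i], ped$id)]
  }, numeric(1))
  names(f) <- ped$id
  f
}

## --- haplotype segment machinery -------------------------------------------
## a haplotype on one chromosome is a run-length list: `ends` (bp, cumulative
## segment end positions, last == chromosome length) and `labels` (founder-
## haplotype ancestry labels)

new_hap <- function(length_bp, label) list(ends = length_bp, labels = label)

## take the piece of haplotype `h` covering (from, to] and return its segments
slice_hap <- function(h, from, to) {
  i1 <- which(h$ends > from)[1L]
  i2 <- which(h$ends >= to)[1L]
  ends <- pmin(h$ends[i1:i2], to)
  list(ends = ends, labels = h$labels[i1:i2])
}

## merge adjacent equal-label segments
compact_hap <- function(h) {
  if (length(h$labels) <= 1L) return(h)
  keep <- c(h$labels[-1L] != h$labels[-length(h$labels)], TRUE)
  list(ends = h$ends[keep], labels = h$labels[keep])
}

## one meiosis: recombine the two parental haplotypes with Poisson crossovers
recombine_hap <- function(h1, h2, length_bp, cM_per_Mb) {
  length_cM <- length_bp / 1e6 * cM_per_Mb
  n_xo <- stats::rpois(1L, length_cM / 100)
  if (n_xo == 0L) {
    return(if (stats::runif(1) < 0.5) h1 else h2)
  }
  xo <- sort(ceiling(stats::runif(n_xo) * (length_bp - 1)))
  xo <- unique(xo)
  bounds <- c(0, xo, length_bp)
  src <- if (stats::runif(1) < 0.5) 1L else 2L
  pieces_ends <- list(); pieces_labels <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    h <- if (src == 1L) h1 else h2
    sl <- slice_hap(h, bounds[k], bounds[k + 1L])
    pieces_ends[[k]] <- sl$ends
    pieces_labels[[k]] <- sl$labels
    src <- 3L - src
  }
  compact_hap(list(ends = unlist(pieces_ends), labels = unlist(pieces_labels)))
}

## label of the founder haplotype carried at each bp position
hap_labels_at <- function(h, pos) {
  h$labels[findInterval(pos, c(0, h$ends), left.open = TRUE)]
}

## autozygous tracts: maximal regions where the two haplotypes carry the same
## founder-haplotype label
autozygous_tracts <- function(h1, h2) {
  ends <- sort(unique(c(h1$ends, h2$ends)))
  l1 <- hap_labels_at(h1, ends)
  l2 <- hap_labels_at(h2, ends)
  auto <- l1 == l2
  starts <- c(1, ends[-length(ends)] + 1)
  if (!any(auto)) return(NULL)
  ## merge adjacent autozygous pieces
  out_start <- numeric(0); out_end <- numeric(0)
  open <- FALSE
  for (k in seq_along(ends)) {
    if (auto[k] && !open) { out_start <- c(out_start, starts[k]); open <- TRUE }
    if (open && (!auto[k])) { out_end <- c(out_end, ends[k - 1L]); open <- FALSE }
  }
  if (open) out_end <- c(out_end, ends[length(ends)])
  data.frame(start_bp = out_start, end_bp = out_end)
}

#' Gene dropping through a pedigree with recombination
#'
#' Founders receive two whole-chromosome haplotypes with unique ancestry
#' labels; transmission follows Mendelian segregation with Poisson (Haldane)
#' crossovers at `cM_per_Mb`. Genotypes are read off the transmitted
#' haplotypes at the marker positions (founder-haplotype alleles are Bernoulli
#' draws from `founder_freqs`), and the true autozygous tracts -- maximal
#' regions where an individual's two haplotypes descend from the same founder
#' haplotype -- are returned alongside. These tracts are the ground-truth
#' counterpart of detected runs of homozygosity.
#'
#' @param ped A [pedigree_spec()].
#' @param founder_freqs Per-SNP allele frequency vector for founder
#'   haplotypes (length = total SNPs in `chrom_plan`), or a single number.
#' @param chrom_plan Data frame (`chrom`, `n_snps`, `length_bp`).
#' @param cM_per_Mb Genetic map density (default 1 cM/Mb).
#' @param seed Integer seed.
#' @param markers Optional pre-drawn marker map (as from an earlier call);
#'   positions must respect `chrom_plan`.
#' @return A list: `table` (a [genotype_table()]), `tracts` (data frame
#'   `sample_id`, `chrom`, `start_bp`, `end_bp`), `markers`, and
#'   `founder_freqs`.
#' @export
gene_drop <- function(ped, founder_freqs, chrom_plan, cM_per_Mb = 1.0, seed,
                      markers = NULL) {
  stopifnot(inherits(ped, "pedigree_spec"))
  set.seed(as.integer(seed))
  chrom_plan$chrom <- as.character(chrom_plan$chrom)
  if (is.null(markers)) markers <- make_marker_map(chrom_plan)
  m <- nrow(markers)
  founder_freqs <- rep_len(founder_freqs, m)
  stopifnot(all(founder_freqs >= 0 & founder_freqs <= 1))

  n <- nrow(ped)
  founders <- which(is.na(ped$sire))
  n_fhap <- 2L * length(founders)
  ## founder-haplotype alleles: rows = ancestry labels, cols = SNPs
  fh_alleles <- matrix(stats::rbinom(n_fhap * m, 1L, rep(founder_freqs, each = n_fhap)),
                       nrow = n_fhap)

  n_chrom <- nrow(chrom_plan)
  ## haps[[i]][[c]] = list(h1, h2)
  haps <- vector("list", n)
  next_label <- 1L
  for (i in seq_len(n)) {
    s <- match(ped$sire[i], ped$id)
    haps[[i]] <- vector("list", n_chrom)
    if (is.na(s)) {
      lab1 <- next_label; lab2 <- next_label + 1L
      next_label <- next_label + 2L
      for (cc in seq_len(n_chrom)) {
        L <- chrom_plan$length_bp[cc]
        haps[[i]][[cc]] <- list(new_hap(L, lab1), new_hap(L, lab2))
      }
    } else {
      d <- match(ped$dam[i], ped$id)
      for (cc in seq_len(n_chrom)) {
        L <- chrom_plan$length_bp[cc]
        hp <- recombine_hap(haps[[s]][[cc]][[1]], haps[[s]][[cc]][[2]], L, cM_per_Mb)
        hm <- recombine_hap(haps[[d]][[cc]][[1]], haps[[d]][[cc]][[2]], L, cM_per_Mb)
        haps[[i]][[cc]] <- list(hp, hm)
      }
    }
  }

  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  tract_list <- list()
  for (i in seq_len(n)) {
    for (cc in seq_len(n_chrom)) {
      ch <- chrom_plan$chrom[cc]
      idx <- which(markers$chrom == ch)
      if (length(idx)) {
        pos <- markers$bp[idx]
        lab1 <- hap_labels_at(haps[[i]][[cc]][[1]], pos)
        lab2 <- hap_labels_at(haps[[i]][[cc]][[2]], pos)
        a1 <- fh_alleles[cbind(lab1, idx)]
        a2 <- fh_alleles[cbind(lab2, idx)]
        calls[i, idx] <- a1 + a2
      }
      tr <- autozygous_tracts(haps[[i]][[cc]][[1]], haps[[i]][[cc]][[2]])
      if (!is.null(tr)) {
        tr$sample_id <- ped$id[i]
        tr$chrom <- ch
        tract_list[[length(tract_list) + 1L]] <- tr
      }
    }
  }
  tracts <- if (length(tract_list)) {
    do.call(rbind, tract_list)[, c("sample_id", "chrom", "start_bp", "end_bp")]
  } else {
    data.frame(sample_id = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0))
  }

  table <- genotype_table(calls, markers,
                          data.frame(sample_id = ped$id, population = ped$pop,
                                     stringsAsFactors = FALSE))
  list(table = table, tracts = tracts, markers = markers,
       founder_freqs = founder_freqs)
}

#' True autozygosity fraction from ground-truth tracts
#'
#' Sum of tract lengths divided by the autosome length, per individual --
#' the ground-truth counterpart of the ROH-based inbreeding coefficient.
#'
#' @param tracts Tract data frame as produced by [gene_drop()].
#' @param autosome_length Total autosomal length in bp.
#' @param sample_ids Optional ids to report (so individuals without tracts
#'   appear with 0).
#' @return Named numeric vector of autozygous genome fractions.
#' @export
true_froh <- function(tracts, autosome_length, sample_ids = NULL) {
  stopifnot(autosome_length > 0)
  if (nrow(tracts)) {
    if (any(tracts$end_bp < tracts$start_bp) || any(tracts$start_bp < 1))
      stop("malformed tract coordinates")
    if (any(tracts$end_bp - tracts$start_bp + 1 > autosome_length))
      stop("tract longer than the stated autosome length")
  }
  len <- tapply(tracts$end_bp - tracts$start_bp + 1, tracts$sample_id, sum)
  if (is.null(sample_ids)) sample_ids <- names(len)
  out <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
  out[names(len)] <- len / autosome_length
  if (any(out > 1)) stop("tracts exceed the autosome length")
  out
}

#' Wright-Fisher haplotype pool with recombination
#'
#' Discrete-generation random union of gametes in a population of `Ne`
#' diploids: each offspring haplotype is a recombinant copy (Poisson
#' crossovers at `cM_per_Mb`) of a random parent's two haplotypes. Drift over
#' the stated generations builds linkage disequilibrium that decays with
#' distance, which is what the LD-decay machinery is tested against.
#'
#' @param Ne Diploid population size (>= 2).
#' @param generations Number of generations of drift (0 returns the initial
#'   independent-locus pool).
#' @param n_snps Number of SNPs on the single simulated chromosome.
#' @param length_bp Chromosome length.
#' @param cM_per_Mb Genetic map density.
#' @param seed Integer seed.
#' @param freq_range Initial allele-frequency law (Uniform bounds).
#' @return A `2*Ne` x `n_snps` 0/1 haplotype matrix with attribute `markers`.
#' @export
wright_fisher_haplotypes <- function(Ne, generations, n_snps, length_bp,
                                     cM_per_Mb = 1.0, seed,
                                     freq_range = c(0.05, 0.95)) {
  stopifnot(Ne >= 2)
  set.seed(as.integer(seed))
  plan <- data.frame(chrom = "1", n_snps = n_snps, length_bp = length_bp,
                     stringsAsFactors = FALSE)
  markers <- make_marker_map(plan)
  pos_cM <- markers$bp / 1e6 * cM_per_Mb
  length_cM <- length_bp / 1e6 * cM_per_Mb

  p0 <- stats::runif(n_snps, freq_range[1], freq_range[2])
  H <- matrix(stats::rbinom(2L * Ne * n_snps, 1L, rep(p0, each = 2L * Ne)),
              nrow = 2L * Ne)

  gamete <- function(h1, h2) {
    n_xo <- stats::rpois(1L, length_cM / 100)
    if (n_xo == 0L) return(if (stats::runif(1) < 0.5) h1 else h2)
    xo <- sort(stats::runif(n_xo) * length_cM)
    seg <- findInterval(pos_cM, xo)
    start <- stats::rbinom(1L, 1L, 0.5)
    ifelse((seg + start) %% 2L == 0L, h1, h2)
  }

  for (g in seq_len(generations)) {
    H_new <- matrix(0L, nrow = 2L * Ne, ncol = n_snps)
    for (i in seq_len(Ne)) {
      par <- sample.int(Ne, 2L, replace = FALSE)
      H_new[2L * i - 1L, ] <- gamete(H[2L * par[1L] - 1L, ], H[2L * par[1L], ])
      H_new[2L * i, ]      <- gamete(H[2L * par[2L] - 1L, ], H[2L * par[2L], ])
    }
    H <- H_new
  }
  attr(H, "markers") <- markers
  H
}

#' Fold a haplotype pool into a genotype table
#'
#' Pairs consecutive haplotypes into diploid individuals.
#'
#' @param H Haplotype matrix from [wright_fisher_haplotypes()].
#' @param population Population label.
#' @return A [genotype_table()].
#' @export
haplotypes_to_table <- function(H, population = "wf") {
  markers <- attr(H, "markers")
  n <- nrow(H) / 2L
  calls <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_table(calls, markers,
                 data.frame(sample_id = sprintf("%s_%02d", population, seq_len(n)),
                            population = population, stringsAsFactors = FALSE))
}
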