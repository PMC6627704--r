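#' Parameters of the sliding-window ROH caller
#'
#' Defaults follow the medium-density equine array protocol: 50-SNP windows
#' slid one SNP at a time, each window allowed at most 2 missing calls and no
#' heterozygotes; a SNP belongs to a homozygous segment when at least 5% of
#' the windows containing it are homozygous; a called run must contain at
#' least 50 SNPs, span at least 1 Mb, average at least one SNP per 5000 kb,
#' and adjacent SNPs in a run may be at most 5000 kb apart.
#'
#' @param window_snp Window size in SNPs.
#' @param window_missing Maximum missing calls per homozygous window.
#' @param window_het Maximum heterozygous calls per homozygous window.
#' @param hit_threshold Minimum fraction of homozygous windows containing a
#'   SNP for it to be a segment candidate.
#' @param min_snp Minimum SNPs per called segment.
#' @param min_length Minimum segment length in bp.
#' @param min_density Maximum bp per SNP within a segment.
#' @param max_gap Maximum bp between adjacent SNPs within a segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50, window_missing = 2, window_het = 0,
                       hit_threshold = 0.05, min_snp = 50,
                       min_length = 1e6, min_density = 5e6, max_gap = 5e6) {
  p <- list(window_snp = window_snp, window_missing = window_missing,
            window_het = window_het, hit_threshold = hit_threshold,
            min_snp = min_snp, min_length = min_length,
            min_density = min_density, max_gap = max_gap)
  stopifnot(window_snp >= 1, window_missing >= 0, window_het >= 0,
            hit_threshold > 0, hit_threshold <= 1,
            min_snp >= 1, min_length > 0, min_density > 0, max_gap > 0)
  class(p) <- "roh_params"
  p
}

#' Fraction of homozygous windows containing each SNP
#'
#' Enumerates every contiguous window of `window_snp` SNPs along one
#' chromosome of one individual. A window is homozygous when it contains at
#' most `window_missing` missing calls and at most `window_het` heterozygous
#' calls. For each SNP the returned value is the number of homozygous windows
#' containing it divided by the number of windows containing it (interior
#' SNPs sit in `window_snp` windows; SNPs near the chromosome ends in fewer).
#'
#' @param calls One individual's dosage vector along one chromosome (marker
#'   order = bp order).
#' @param params A [roh_params()].
#' @return Numeric vector of per-SNP fractions with attribute `n_windows`
#'   (the per-SNP denominator). If the chromosome has fewer SNPs than the
#'   window size, all fractions are 0 with a warning.
#' @export
window_hit_fraction <- function(calls, params = roh_params()) {
  m <- length(calls)
  w <- params$window_snp
  if (m < w) {
    warning("chromosome has ", m, " SNPs, fewer than the window size ", w)
    out <- rep(0, m)
    attr(out, "n_windows") <- rep(0L, m)
    return(out)
  }
  miss <- as.integer(is.na(calls))
  het <- as.integer(!is.na(calls) & calls == 1L)
  cm <- c(0L, cumsum(miss))
  chh <- c(0L, cumsum(het))
  n_win <- m - w + 1L
  win_miss <- cm[(w + 1L):(m + 1L)] - cm[1L:n_win]
  win_het <- chh[(w + 1L):(m + 1L)] - chh[1L:n_win]
  hom_win <- as.integer(win_miss <= params$window_missing &
                          win_het <= params$window_het)
  chw <- c(0L, cumsum(hom_win))
  s <- seq_len(m)
  lo <- pmax(1L, s - w + 1L)   # first window containing SNP s
  hi <- pmin(n_win, s)         # last window containing SNP s
  n_containing <- hi - lo + 1L
  n_hom <- chw[hi + 1L] - chw[lo]
  out <- n_hom / n_containing
  attr(out, "n_windows") <- n_containing
  out
}

#' Call runs of homozygosity on one chromosome of one individual
#'
#' Candidate SNPs are those whose homozygous-window fraction reaches
#' `hit_threshold` *and* whose own call is homozygous and non-missing (so a
#' called segment never contains a heterozygote). Maximal runs of
#' consecutive candidate SNPs are split wherever adjacent candidates are more
#' than `max_gap` apart, and each run is kept only if it contains at least
#' `min_snp` SNPs, spans at least `min_length` bp, and averages at most
#' `min_density` bp per SNP. Segment bounds are the bp positions of the first
#' and last candidate SNP; lengths are 1-based inclusive.
#'
#' @param calls Dosage vector for one individual along one chromosome.
#' @param markers Marker map rows for that chromosome (`chrom`, `bp`).
#' @param params A [roh_params()].
#' @return Data frame of segments: `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length`.
#' @export
call_rohs <- function(calls, markers, params = roh_params()) {
  stopifnot(length(calls) == nrow(markers))
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      length = numeric(0), stringsAsFactors = FALSE)
  if (length(calls) == 0L) return(empty)
  frac <- suppressWarnings(window_hit_fraction(calls, params))
  cand <- frac >= params$hit_threshold & !is.na(calls) & calls != 1L
  if (!any(cand)) return(empty)

  idx <- which(cand)
  ## break runs at non-consecutive indices or at bp gaps > max_gap
  brk <- c(TRUE, diff(idx) != 1L | diff(markers$bp[idx]) > params$max_gap)
  run_id <- cumsum(brk)
  segs <- lapply(split(idx, run_id), function(ii) {
    n <- length(ii)
    start <- markers$bp[ii[1L]]
    end <- markers$bp[ii[n]]
    len <- end - start + 1
    if (n >= params$min_snp && len >= params$min_length &&
        len / n <= params$min_density) {
      data.frame(chrom = markers$chrom[ii[1L]], start_bp = start, end_bp = end,
                 n_snps = n, length = len, stringsAsFactors = FALSE)
    } else NULL
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Call ROHs for every individual in a genotype table
#'
#' Runs [call_rohs()] per individual and chromosome (on the unpruned marker
#' set, by convention) and classifies each segment by size.
#'
#' @param table A [genotype_table()].
#' @param params A [roh_params()].
#' @param short_max,long_min Size-class bounds passed to [classify_roh()].
#' @return Data frame: `sample_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length`, `size_class`.
#' @export
detect_rohs <- function(table, params = roh_params(),
                        short_max = 5e6, long_min = 1e7) {
  validate_genotype_table(table)
  out <- list()
  chroms <- unique(table$markers$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(table$markers$chrom == ch))
  for (i in seq_len(nrow(table$samples))) {
    for (k in seq_along(chroms)) {
      idx <- chrom_idx[[k]]
      segs <- call_rohs(table$calls[i, idx],
                        table$markers[idx, , drop = FALSE], params)
      if (nrow(segs)) {
        segs$sample_id <- table$samples$sample_id[i]
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length = numeric(0),
                      size_class = character(0), stringsAsFactors = FALSE))
  rohs <- do.call(rbind, out)
  rohs$size_class <- classify_roh(rohs$length, short_max, long_min)
  rohs[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps", "length",
           "size_class")]
}

#' Size class of an ROH segment
#'
#' Long runs (by default > 10 Mb) reflect recent common ancestry of the two
#' haplotypes; short runs (<= 5 Mb) older inbreeding. Lengths in between are
#' classed medium.
#'
#' @param length Segment length(s) in bp.
#' @param short_max Upper bound of the short class (inclusive).
#' @param long_min Lower bound of the long class (exclusive).
#' @return Character vector: `"short"`, `"medium"` or `"long"`.
#' @export
classify_roh <- function(length, short_max = 5e6, long_min = 1e7) {
  stopifnot(short_max < long_min)
  ifelse(length > long_min, "long", ifelse(length <= short_max, "short", "medium"))
}

#' Per-population ROH summary
#'
#' Summarizes detected ROHs the way multi-breed diversity studies tabulate
#' them: total segment count per population; mean/SD/min/max segment count
#' per individual; mean/SD/min/max segment length (Mb); mean/SD/min/max
#' ROH-based inbreeding coefficient; and the mean Mb covered per individual
#' by short, medium and long segments. Individuals without any ROH enter the
#' statistics with count 0 and froh 0.
#'
#' @param rohs Segment data frame from [detect_rohs()].
#' @param samples Data frame `sample_id`, `population` covering every
#'   genotyped individual (populations without individuals are omitted with a
#'   warning).
#' @param autosome_length Denominator for [froh()].
#' @return Data frame with one row per population.
#' @export
roh_summary <- function(rohs, samples, autosome_length = 2242939370) {
  pops <- unique(samples$population)
  rows <- list()
  for (p in pops) {
    ids <- samples$sample_id[samples$population == p]
    if (length(ids) == 0L) { warning("population ", p, " has no individuals; omitted"); next }
    seg <- rohs[rohs$sample_id %in% ids, , drop = FALSE]
    counts <- stats::setNames(rep(0L, length(ids)), ids)
    if (nrow(seg)) {
      tab <- table(seg$sample_id)
      counts[names(tab)] <- as.integer(tab)
    }
    fr <- vapply(ids, function(id)
      froh(seg[seg$sample_id == id, , drop = FALSE], autosome_length), numeric(1))
    len_mb <- seg$length / 1e6
    class_mb <- vapply(c("short", "medium", "long"), function(cl) {
      per_ind <- vapply(ids, function(id)
        sum(seg$length[seg$sample_id == id & seg$size_class == cl]) / 1e6,
        numeric(1))
      mean(per_ind)
    }, numeric(1))
    rows[[p]] <- data.frame(
      population = p, n_individuals = length(ids), total_rohs = nrow(seg),
      count_mean = mean(counts), count_sd = stats::sd(counts),
      count_min = min(counts), count_max = max(counts),
      length_mb_mean = if (nrow(seg)) mean(len_mb) else 0,
      length_mb_sd = if (nrow(seg) > 1) stats::sd(len_mb) else 0,
      length_mb_min = if (nrow(seg)) min(len_mb) else 0,
      length_mb_max = if (nrow(seg)) max(len_mb) else 0,
      froh_mean = mean(fr), froh_sd = stats::sd(fr),
      froh_min = min(fr), froh_max = max(fr),
      short_mb_mean = class_mb[["short"]],
      medium_mb_mean = class_mb[["medium"]],
      long_mb_mean = class_mb[["long"]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generations to the common ancestor of an IBD segment
#'
#' The expected length of an identity-by-descent segment whose common
#' ancestor lived `g` generations ago is `100 / (2g)` centimorgans; inverting
#' gives `g = 100 / (2 L)` for a segment of `L` cM. At a 1 cM/Mb map the
#' 10-Mb long-ROH threshold thus dates to about 5 generations.
#'
#' @param roh_length_cM Segment length(s) in centimorgans (> 0).
#' @return Number of generations back to the common ancestor.
#' @export
generations_from_length <- function(roh_length_cM) {
  if (any(roh_length_cM <= 0)) stop("segment length must be positive")
  100 / (2 * roh_length_cM)
}
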