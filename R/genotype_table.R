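#' Diploid SNP genotype table
#'
#' The central container of the package: an individuals x markers matrix of
#' diploid biallelic genotype calls together with a marker map and population
#' labels. Calls count copies of the marker's *counted* allele (0, 1, 2) with
#' `NA` for missing genotypes.
#'
#' @param calls Integer matrix, samples in rows, markers in columns, entries
#'   in `{0, 1, 2, NA}`.
#' @param markers Data frame with columns `snp_id` (unique), `chrom`
#'   (character label; autosome number or `"X"`), `bp` (1-based position,
#'   strictly increasing within a chromosome), and optionally `allele1`
#'   (the counted allele) and `allele2`.
#' @param samples Data frame with columns `sample_id` and `population`
#'   (non-empty label).
#'
#' @return An object of class `genotype_table` with elements `calls`,
#'   `markers`, `samples`.
#' @export
genotype_table <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- NULL
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chrom", "bp") %in% names(markers)))
    stop("markers must have columns snp_id, chrom, bp")
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id, population")
  if (is.null(markers$allele1)) markers$allele1 <- rep(NA_character_, nrow(markers))
  if (is.null(markers$allele2)) markers$allele2 <- rep(NA_character_, nrow(markers))
  markers$chrom <- as.character(markers$chrom)
  markers$bp <- as.numeric(markers$bp)
  obj <- structure(list(calls = calls, markers = markers, samples = samples),
                   class = "genotype_table")
  validate_genotype_table(obj)
  obj
}

#' @rdname genotype_table
#' @param x A `genotype_table`.
#' @export
validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (nrow(x$calls) != nrow(x$samples))
    stop("call matrix has ", nrow(x$calls), " rows but ", nrow(x$samples), " samples")
  if (ncol(x$calls) != nrow(x$markers))
    stop("call matrix has ", ncol(x$calls), " columns but ", nrow(x$markers), " markers")
  vals <- x$calls[!is.na(x$calls)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (anyDuplicated(x$markers$snp_id))
    stop("duplicated snp_id in marker map")
  if (any(x$markers$bp < 1))
    stop("marker bp positions must be >= 1")
  for (ch in unique(x$markers$chrom)) {
    bp <- x$markers$bp[x$markers$chrom == ch]
    if (length(bp) > 1L && any(diff(bp) <= 0))
      stop("markers on chromosome ", ch, " are not strictly ascending by bp")
  }
  if (any(is.na(x$samples$population)) || any(!nzchar(x$samples$population)))
    stop("population labels must be non-empty")
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$samples), "samples x", nrow(x$markers), "markers\n")
  cat("  populations:", paste(unique(x$samples$population), collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

## internal: subset helpers keep the class invariants intact
subset_markers <- function(x, idx) {
  genotype_table(x$calls[, idx, drop = FALSE], x$markers[idx, , drop = FALSE], x$samples)
}

subset_samples <- function(x, idx) {
  genotype_table(x$calls[idx, , drop = FALSE], x$markers, x$samples[idx, , drop = FALSE])
}

#' Counted-allele frequencies pooled over all samples
#'
#' Frequency of the counted allele at each marker, estimated from all
#' non-missing calls pooled across every sample (the whole-panel reference
#' used by the heterozygosity-based inbreeding estimator and the
#' method-of-moments IBD machinery).
#'
#' @param table A [genotype_table()].
#' @return Numeric vector of frequencies named by `snp_id`; `NaN` where a
#'   marker has no non-missing calls.
#' @export
allele_freqs <- function(table) {
  p <- colMeans(table$calls, na.rm = TRUE) / 2
  names(p) <- table$markers$snp_id
  p
}

## internal: TRUE for chromosome labels that are plain autosome numbers
is_autosome_label <- function(chrom) grepl("^[0-9]+$", chrom)
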