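#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses whitespace-delimited PLINK text files into a [genotype_table()].
#' Each PED row holds six leading columns (family, individual, father, mother,
#' sex, phenotype) followed by two allele columns per marker; the MAP file
#' holds chromosome, SNP id, genetic position and bp position. The family-ID
#' column is used as the population label. Per marker the counted allele is
#' the lexicographically smaller observed allele, so allele counting is
#' deterministic regardless of file order. `0 0` encodes a missing genotype;
#' half-missing genotypes (e.g. `A 0`) are treated as missing with a warning.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @return A [genotype_table()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (length(map_fields) && any(lengths(map_fields) < 4))
    stop("MAP rows must have 4 columns (chrom, snp_id, cM, bp)")
  markers <- data.frame(
    snp_id = vapply(map_fields, `[`, "", 2L),
    chrom  = vapply(map_fields, `[`, "", 1L),
    bp     = as.numeric(vapply(map_fields, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  n_mark <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  if (length(fields)) {
    len <- lengths(fields)
    if (any(len != len[1L]))
      stop("ragged PED file: line ", which(len != len[1L])[1L],
           " has ", len[which(len != len[1L])[1L]], " fields, expected ", len[1L])
    if ((len[1L] - 6L) %% 2L != 0L)
      stop("PED rows must have 6 leading columns plus 2 allele columns per marker")
    n_ped_mark <- (len[1L] - 6L) %/% 2L
    if (n_ped_mark != n_mark)
      stop("dimension mismatch: PED implies ", n_ped_mark,
           " markers but MAP lists ", n_mark)
    m <- do.call(rbind, fields)
  } else {
    m <- matrix(character(0), nrow = 0, ncol = 6 + 2 * n_mark)
  }

  n_samp <- nrow(m)
  samples <- data.frame(
    population = if (n_samp) m[, 1L] else character(0),
    sample_id  = if (n_samp) m[, 2L] else character(0),
    stringsAsFactors = FALSE
  )[, c("sample_id", "population")]

  calls <- matrix(NA_integer_, nrow = n_samp, ncol = n_mark)
  allele1 <- rep(NA_character_, n_mark)
  allele2 <- rep(NA_character_, n_mark)
  half_missing <- 0L
  for (j in seq_len(n_mark)) {
    a <- m[, 5L + 2L * j]
    b <- m[, 6L + 2L * j]
    half <- xor(a == "0", b == "0")
    half_missing <- half_missing + sum(half)
    miss <- (a == "0") | (b == "0")
    obs <- sort(unique(c(a[!miss], b[!miss])))
    if (length(obs) > 2L)
      stop("marker ", markers$snp_id[j], " has more than two alleles")
    if (length(obs) >= 1L) allele1[j] <- obs[1L]
    if (length(obs) == 2L) allele2[j] <- obs[2L]
    if (n_samp) {
      cj <- (a == allele1[j]) + (b == allele1[j])
      cj[miss] <- NA_integer_
      calls[, j] <- as.integer(cj)
    }
  }
  if (half_missing > 0L)
    warning(half_missing, " half-missing genotype(s) treated as missing")

  markers$allele1 <- allele1
  markers$allele2 <- allele2
  genotype_table(calls, markers, samples)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_plink_text()]: re-reading the written files reproduces the
#' calls, marker order and population labels exactly. Missing genotypes are
#' written as `0 0`.
#'
#' @param table A [genotype_table()].
#' @param ped_path,map_path Output paths.
#' @export
write_plink_text <- function(table, ped_path, map_path) {
  validate_genotype_table(table)
  mk <- table$markers
  a1 <- mk$allele1
  a2 <- mk$allele2
  ## fall back to abstract allele codes where a table was built without them
  a1[is.na(a1)] <- "A"
  a2[is.na(a2)] <- "B"

  map_out <- paste(mk$chrom, mk$snp_id, 0, format(mk$bp, scientific = FALSE, trim = TRUE))
  con <- tryCatch(file(map_path, "w"), error = function(e)
    stop("cannot open MAP path for writing: ", map_path))
  writeLines(map_out, con); close(con)

  n_samp <- nrow(table$samples)
  n_mark <- nrow(mk)
  geno_strings <- matrix("0 0", nrow = n_samp, ncol = n_mark)
  for (j in seq_len(n_mark)) {
    g <- table$calls[, j]
    s <- geno_strings[, j]
    s[!is.na(g) & g == 2L] <- paste(a1[j], a1[j])
    s[!is.na(g) & g == 1L] <- paste(a1[j], a2[j])
    s[!is.na(g) & g == 0L] <- paste(a2[j], a2[j])
    geno_strings[, j] <- s
  }
  rows <- if (n_samp == 0L) character(0) else {
    lead <- cbind(table$samples$population, table$samples$sample_id,
                  "0", "0", "0", "-9")
    apply(cbind(lead, geno_strings), 1L, paste, collapse = " ")
  }
  con <- tryCatch(file(ped_path, "w"), error = function(e)
    stop("cannot open PED path for writing: ", ped_path))
  writeLines(rows, con); close(con)
  invisible(NULL)
}

#' Read/write the internal tabular genotype dialect
#'
#' A simple TSV with header `sample_id`, `population`, then one column per
#' `snp_id` holding counted-allele dosages in `{0, 1, 2, NA}`. The marker map
#' is not carried by the format; supply one on reading, or positions default
#' to consecutive 1-kb spacing on chromosome 1.
#'
#' @param table A [genotype_table()].
#' @param path Output (or input) path.
#' @param map Optional marker data frame (`snp_id`, `chrom`, `bp`) matched by
#'   `snp_id` on reading.
#' @return `read_genotype_tsv` returns a [genotype_table()].
#' @export
write_genotype_tsv <- function(table, path) {
  validate_genotype_table(table)
  df <- data.frame(sample_id = table$samples$sample_id,
                   population = table$samples$population,
                   stringsAsFactors = FALSE)
  geno <- as.data.frame(table$calls)
  names(geno) <- table$markers$snp_id
  utils::write.table(cbind(df, geno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path, map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  snp_ids <- setdiff(names(df), c("sample_id", "population"))
  calls <- as.matrix(df[, snp_ids, drop = FALSE])
  if (is.null(map)) {
    map <- data.frame(snp_id = snp_ids, chrom = "1",
                      bp = seq_along(snp_ids) * 1000, stringsAsFactors = FALSE)
  } else {
    map <- map[match(snp_ids, map$snp_id), , drop = FALSE]
    if (anyNA(map$snp_id)) stop("map is missing some snp_ids present in the TSV")
  }
  genotype_table(calls, map,
                 data.frame(sample_id = df$sample_id, population = df$population,
                            stringsAsFactors = FALSE))
}
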