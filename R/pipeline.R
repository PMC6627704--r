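#' Pipeline configuration
#'
#' Assembles every setting of the end-to-end analysis with the protocol
#' defaults: SNP call-rate filter at 0.90 on autosomes only; LD pruning with
#' a 100-SNP window shifting 25 SNPs at r2 >= 0.1; the 50-SNP sliding-window
#' ROH caller with its segment criteria; 10-kb LD-decay bins; 4 MDS
#' components; admixture over K = 1..15 with 5-fold cross-validation; and
#' the 2,242,939,370-bp autosome length. A config round-trips losslessly
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param input Either `list(ped =, map =)` (optionally `ped2`, `map2` for a
#'   second panel to intersect) or `list(synthetic = <list>)` describing a
#'   [population_model()] (fields `n_pops`, `fst`, `n_snps`, `n_per_pop`,
#'   `missing_rate`, optionally `pedigree = "fullsib"`).
#' @param min_call_rate SNP call-rate threshold.
#' @param autosomes_only Drop non-autosomal markers first.
#' @param prune_window,prune_step,prune_r2 LD-pruning settings.
#' @param roh [roh_params()] list.
#' @param ld_chrom Chromosome for the LD-decay curve.
#' @param ld_bin_width LD-decay bin width (bp).
#' @param mds_components Number of MDS components.
#' @param admixture_k Integer vector of K values.
#' @param admixture_folds Cross-validation folds.
#' @param autosome_length Denominator of the ROH-based inbreeding
#'   coefficient.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            min_call_rate = 0.90,
                            autosomes_only = TRUE,
                            prune_window = 100, prune_step = 25, prune_r2 = 0.1,
                            roh = roh_params(),
                            ld_chrom = "2", ld_bin_width = 10000,
                            mds_components = 4,
                            admixture_k = 1:15, admixture_folds = 5,
                            autosome_length = 2242939370,
                            seed = 1) {
  cfg <- list(input = input, min_call_rate = min_call_rate,
              autosomes_only = autosomes_only,
              prune_window = prune_window, prune_step = prune_step,
              prune_r2 = prune_r2, roh = unclass(roh),
              ld_chrom = as.character(ld_chrom), ld_bin_width = ld_bin_width,
              mds_components = mds_components,
              admixture_k = as.integer(admixture_k),
              admixture_folds = admixture_folds,
              autosome_length = autosome_length, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(NULL)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    input = raw$input,
    min_call_rate = raw$min_call_rate,
    autosomes_only = raw$autosomes_only,
    prune_window = raw$prune_window, prune_step = raw$prune_step,
    prune_r2 = raw$prune_r2,
    roh = do.call(roh_params, raw$roh),
    ld_chrom = raw$ld_chrom, ld_bin_width = raw$ld_bin_width,
    mds_components = raw$mds_components,
    admixture_k = raw$admixture_k, admixture_folds = raw$admixture_folds,
    autosome_length = raw$autosome_length, seed = raw$seed)
  cfg
}

## internal: build a genotype table from a config's synthetic block
synthesize_input <- function(spec, seed) {
  model <- population_model(
    n_pops = spec$n_pops %||% 3,
    fst = spec$fst %||% 0.1,
    n_snps = spec$n_snps %||% 2000)
  freqs <- draw_balding_nichols(model, seed = seed)
  table <- simulate_unrelated(freqs, n_per_pop = spec$n_per_pop %||% 20,
                              missing_rate = spec$missing_rate %||% 0.02,
                              seed = seed + 1L)
  if (identical(spec$pedigree, "fullsib")) {
    drop <- gene_drop(fullsib_pedigree(), founder_freqs = attr(freqs, "ancestral"),
                      chrom_plan = model$chrom_plan, seed = seed + 2L,
                      markers = table$markers)
    table <- genotype_table(rbind(table$calls, drop$table$calls),
                            table$markers,
                            rbind(table$samples, drop$table$samples))
  }
  table
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full diversity analysis
#'
#' Orchestrates the stages in their fixed order: load (intersecting two
#' panels if given), autosome filter, SNP call-rate filter; then two
#' branches. The *pruned* branch (LD pruning at the configured settings)
#' feeds the heterozygosity-based inbreeding coefficients, method-of-moments
#' IBD, IBS distances with MDS, the pairwise F_ST matrix, admixture with
#' cross-validation, and the neighbor-joining tree (on the same 1 - IBS
#' distances). The *unpruned* branch feeds ROH detection (with per-individual
#' ROH-based inbreeding and the per-population summary) and the LD-decay
#' curve. The run is deterministic under the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   TSV (plus the Newick tree and a provenance log).
#' @return A list of class `run_report`: `fi`, `ibd`, `mds`, `fst`,
#'   `admixture` (fits per K + `cv`), `tree`, `rohs`, `roh_summary`,
#'   `ld_decay`, and `provenance` (settings, seed, SNP/sample counts per
#'   stage).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  counts <- list()
  table <- stage("load", {
    inp <- config$input
    if (!is.null(inp$synthetic)) {
      synthesize_input(inp$synthetic, seed)
    } else {
      t1 <- read_plink_text(inp$ped, inp$map)
      if (!is.null(inp$ped2)) {
        t2 <- read_plink_text(inp$ped2, inp$map2)
        both <- intersect_panels(t1, t2)
        genotype_table(rbind(both$a$calls, both$b$calls), both$a$markers,
                       rbind(both$a$samples, both$b$samples))
      } else t1
    }
  })
  counts$input <- ncol(table$calls)

  if (isTRUE(config$autosomes_only))
    table <- stage("autosome_filter", filter_autosomes(table))
  counts$after_autosome_filter <- ncol(table$calls)
  table <- stage("call_rate_filter",
                 filter_snp_call_rate(table, config$min_call_rate))
  counts$after_call_rate_filter <- ncol(table$calls)

  kept <- stage("ld_prune",
                ld_prune(table, config$prune_window, config$prune_step,
                         config$prune_r2))
  pruned <- keep_snps(table, kept)
  counts$after_pruning <- ncol(pruned$calls)

  fi <- stage("inbreeding_het", inbreeding_het(pruned))
  ibd <- stage("mom_ibd", mom_ibd(pruned))
  ibs <- stage("ibs", ibs_matrix(pruned))
  mds <- stage("mds", classical_mds(ibs$distance, config$mds_components))
  fst <- stage("fst", fst_matrix(pruned))
  admix <- stage("admixture", {
    fits <- lapply(config$admixture_k, function(K)
      admixture_em(pruned, K, seed = seed + 100L + K))
    names(fits) <- paste0("K", config$admixture_k)
    cv <- admixture_cv(pruned, config$admixture_k, config$admixture_folds,
                       seed = seed + 200L)
    list(fits = fits, cv = cv)
  })
  tree <- stage("nj_tree", nj_tree(ibs$distance))

  params <- do.call(roh_params, config$roh)
  rohs <- stage("roh_detection", detect_rohs(table, params))
  fr <- vapply(table$samples$sample_id, function(id)
    froh(rohs[rohs$sample_id == id, , drop = FALSE], config$autosome_length),
    numeric(1))
  rsum <- stage("roh_summary",
                roh_summary(rohs, table$samples, config$autosome_length))
  ld <- stage("ld_decay", {
    if (config$ld_chrom %in% table$markers$chrom)
      ld_decay(table, config$ld_chrom, config$ld_bin_width)
    else ld_decay(table, table$markers$chrom[1], config$ld_bin_width)
  })

  report <- list(
    fi = fi, ibd = ibd, ibs = ibs, mds = mds, fst = fst,
    admixture = admix, tree = tree,
    rohs = rohs, froh = fr, roh_summary = rsum, ld_decay = ld,
    provenance = list(settings = unclass(config), seed = seed,
                      snp_counts = counts,
                      n_samples = nrow(table$samples))
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write a run report as plain-text tables
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Directory (created if absent).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name, rn = FALSE)
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  wt(report$fi, "inbreeding_het.tsv")
  wt(report$ibd, "ibd_pairs.tsv")
  coords <- as.data.frame(report$mds$coordinates)
  names(coords) <- paste0("C", seq_len(ncol(coords)))
  ve_line <- paste0("# variance_explained\t",
                    paste(format(report$mds$variance_explained, digits = 10),
                          collapse = "\t"))
  mds_path <- file.path(out_dir, "mds_coordinates.tsv")
  writeLines(ve_line, mds_path)
  suppressWarnings(utils::write.table(coords, mds_path, sep = "\t", quote = FALSE,
                                      row.names = TRUE, col.names = NA, append = TRUE))
  wt(report$fst$fst, "fst_matrix.tsv", rn = TRUE)
  wt(report$fst$n_snps, "fst_n_snps.tsv", rn = TRUE)
  for (nm in names(report$admixture$fits))
    wt(round(report$admixture$fits[[nm]]$Q, 8), paste0("admixture_Q_", nm, ".tsv"))
  wt(report$admixture$cv, "admixture_cv.tsv")
  write_newick(report$tree, file.path(out_dir, "nj_tree.nwk"))
  wt(report$rohs, "roh_segments.tsv")
  wt(data.frame(sample_id = names(report$froh), froh = report$froh), "froh.tsv")
  if (!is.null(report$roh_summary)) wt(report$roh_summary, "roh_summary.tsv")
  wt(report$ld_decay, "ld_decay.tsv")
  prov <- report$provenance
  log_lines <- c(
    "equidiv run log",
    paste0("seed: ", prov$seed),
    paste0("samples: ", prov$n_samples),
    paste0("snps_", names(prov$snp_counts), ": ", unlist(prov$snp_counts)),
    paste0("settings: ", paste(utils::capture.output(utils::str(prov$settings)),
                               collapse = " | "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}

#' Write a synthetic fixture to disk
#'
#' Generates a synthetic dataset (Balding-Nichols populations, optionally a
#' gene-dropped pedigree appended) and writes PED/MAP files plus
#' ground-truth sidecars (population allele frequencies, true autozygous
#' tracts, the pedigree).
#'
#' @param model A [population_model()].
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_per_pop Individuals per population.
#' @param missing_rate Per-call missingness.
#' @param pedigree Optional [pedigree_spec()] to gene-drop and append.
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, the list of files written.
#' @export
make_fixture <- function(model, out_dir, seed, n_per_pop = 20,
                         missing_rate = 0.02, pedigree = NULL, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- draw_balding_nichols(model, seed = seed)
  table <- simulate_unrelated(freqs, n_per_pop, missing_rate, seed = seed + 1L)
  files <- c(ped = file.path(out_dir, "fixture.ped"),
             map = file.path(out_dir, "fixture.map"),
             freqs = file.path(out_dir, "truth_frequencies.tsv"))
  tracts <- NULL
  if (!is.null(pedigree)) {
    drop <- gene_drop(pedigree, founder_freqs = attr(freqs, "ancestral"),
                      chrom_plan = model$chrom_plan, seed = seed + 2L,
                      markers = table$markers)
    table <- genotype_table(rbind(table$calls, drop$table$calls), table$markers,
                            rbind(table$samples, drop$table$samples))
    tracts <- drop$tracts
    files <- c(files, tracts = file.path(out_dir, "truth_tracts.tsv"),
               pedigree = file.path(out_dir, "pedigree.tsv"))
  }
  write_plink_text(table, files[["ped"]], files[["map"]])
  fq <- data.frame(snp_id = table$markers$snp_id, t(freqs))
  utils::write.table(fq, files[["freqs"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tracts)) {
    utils::write.table(tracts, files[["tracts"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(pedigree), files[["pedigree"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(files)
}
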