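# End-to-end pipeline commands wiring the modules together. Each cmd_*
# returns a status code (0 success, 2 empty-result warning) plus its outputs;
# the `rarebin` executable script maps these onto process exit codes.

meta_header <- function(kv) {
  sprintf("# %s=%s", names(kv), vapply(kv, as.character, ""))
}

#' Build a knowledge store file from region and group tables
#'
#' @param region_files Character vector of region table files.
#' @param region_types Region type per file (recycled if length 1).
#' @param group_files Optional character vector of GMT files.
#' @param out Output SQLite store path.
#' @param formats Dialect per region file, `"tsv"` or `"bed"` (recycled).
#' @param force Overwrite an existing store.
#' @param genome_build Build tag recorded in the store.
#' @return Invisibly, list with `status` (0), `store` path, and counts.
#' @export
cmd_build_knowledge <- function(region_files, region_types = "gene",
                                group_files = character(), out,
                                formats = "tsv", force = FALSE,
                                genome_build = "synthetic") {
  if (!length(region_files)) stop("at least one region file is required")
  region_types <- rep_len(region_types, length(region_files))
  formats <- rep_len(formats, length(region_files))
  kb <- kb_new(genome_build = genome_build)
  n_regions <- 0L
  for (i in seq_along(region_files)) {
    n_regions <- n_regions +
      kb_load_regions(kb, region_files[i], region_type = region_types[i],
                      format = formats[i])
  }
  if (n_regions == 0L) stop("zero regions loaded: refusing to write an empty store")
  n_groups <- 0L
  for (f in group_files) n_groups <- n_groups + kb_load_groups(kb, f)
  kb_save(kb, out, force = force)
  message(sprintf("knowledge-store regions=%d groups=%d sources=%s out=%s",
                  n_regions, n_groups, paste(kb_sources(kb), collapse = ","), out))
  invisible(list(status = 0L, store = out, n_regions = n_regions,
                 n_groups = n_groups))
}

#' Run the binning pipeline end to end
#'
#' Frequencies -> rarity calls -> feature bins (optional exon/intron or
#' prediction splits) -> per-individual burden matrix, written as a bin
#' summary TSV and a bin matrix CSV. Run metadata is embedded as commented
#' header lines; outputs are byte-identical for identical inputs and
#' configuration (no timestamps unless requested).
#'
#' @param vcf,phenotypes,store Input file paths (store from
#'   [cmd_build_knowledge()]; may be NULL for intergenic-only runs).
#' @param out_dir Output directory.
#' @param config A [binning_config()].
#' @param predictions Optional prediction table file (required when
#'   `config$prediction_split`).
#' @param timestamps Embed a timestamp header line.
#' @return Invisibly, list with `status` (0, or 2 when no rare loci exist at
#'   the threshold), output paths, and the in-memory results.
#' @export
cmd_bin <- function(vcf, phenotypes, store = NULL, out_dir,
                    config = binning_config(), predictions = NULL,
                    timestamps = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- read_vcf(vcf)
  phen <- read_phenotypes(phenotypes)
  kb <- if (!is.null(store)) kb_open(store) else NULL
  gft <- group_allele_frequencies(gm, phen)
  rarity <- rarity_calls(gft, config$maf_threshold)
  meta <- c(tool = "rarebin", version = as.character(utils::packageVersion("rarebin")),
            maf_threshold = config$maf_threshold,
            feature_types = paste(config$feature_types, collapse = "+"),
            intergenic_window = config$intergenic_window,
            subfeature_filter = config$subfeature_filter,
            prediction_split = config$prediction_split,
            n_loci = nrow(rarity), n_rare_loci = sum(rarity$rare))
  if (timestamps) meta <- c(meta, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  summary_path <- file.path(out_dir, "bins.tsv")
  matrix_path <- file.path(out_dir, "bin_matrix.csv")
  if (!any(rarity$rare)) {
    warning(sprintf("no rare loci at threshold %g: empty outputs written",
                    config$maf_threshold))
    writeLines(c(meta_header(meta),
                 "bin_id\tfeature_type\tchrom\tspan_start\tspan_stop\tn_loci\ttotal_variants_case\ttotal_variants_control"),
               summary_path)
    writeLines(c(meta_header(meta), "sample_id"), matrix_path)
    return(invisible(list(status = 2L, summary = summary_path,
                          matrix = matrix_path, bins = list())))
  }
  bins <- build_feature_bins(rarity, kb, config)
  if (config$subfeature_filter != "none") {
    bins <- apply_subfeature_filter(bins, kb, config$subfeature_filter)
  }
  if (config$prediction_split) {
    if (is.null(predictions)) stop("prediction_split enabled but no prediction table given")
    bins <- apply_prediction_split(bins, read_predictions(predictions))
  }
  if (!length(bins)) {
    warning("no bins produced: empty outputs written")
    writeLines(c(meta_header(meta),
                 "bin_id\tfeature_type\tchrom\tspan_start\tspan_stop\tn_loci\ttotal_variants_case\ttotal_variants_control"),
               summary_path)
    writeLines(c(meta_header(meta), "sample_id"), matrix_path)
    return(invisible(list(status = 2L, summary = summary_path,
                          matrix = matrix_path, bins = list())))
  }
  bmat <- build_bin_matrix(bins, gm, rarity)
  phen_al <- align_phenotypes(gm, phen)
  case_cols <- names(phen_al)[phen_al == "case"]
  control_cols <- names(phen_al)[phen_al == "control"]
  span <- t(vapply(bins, function(b)
    c(min(b$coords$pos), max(b$coords$pos)), numeric(2)))
  sumtab <- data.frame(
    bin_id = bmat$summary$bin_id,
    feature_type = bmat$summary$feature_type,
    chrom = vapply(bins, function(b) b$coords$chrom[1], ""),
    span_start = as.integer(span[, 1]), span_stop = as.integer(span[, 2]),
    n_loci = bmat$summary$n_loci,
    total_variants_case = as.integer(rowSums(bmat$matrix[, case_cols, drop = FALSE])),
    total_variants_control = as.integer(rowSums(bmat$matrix[, control_cols, drop = FALSE])),
    stringsAsFactors = FALSE)
  con <- file(summary_path, "w")
  writeLines(meta_header(meta), con)
  utils::write.table(sumtab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  out <- data.frame(sample_id = colnames(bmat$matrix),
                    t(bmat$matrix), check.names = FALSE)
  con <- file(matrix_path, "w")
  writeLines(meta_header(meta), con)
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  close(con)
  message(sprintf("bin n_bins=%d n_rare_loci=%d out=%s",
                  length(bins), sum(rarity$rare), out_dir))
  invisible(list(status = 0L, summary = summary_path, matrix = matrix_path,
                 bins = bins, bin_matrix = bmat, rarity = rarity))
}

read_bin_matrix_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!nrow(tab) || names(tab)[1] != "sample_id") {
    stop(sprintf("'%s' is not a bin matrix CSV (or is empty)", path))
  }
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- tab$sample_id
  m
}

#' Test bins from a bin matrix file
#'
#' @param matrix_file Bin matrix CSV written by [cmd_bin()].
#' @param phenotypes Phenotype table path.
#' @param alpha Significance level on the adjusted p-value.
#' @param out Output results TSV path.
#' @return Invisibly, list with `status`, `out`, and the results table.
#' @export
cmd_test <- function(matrix_file, phenotypes, alpha = 0.05, out) {
  m <- read_bin_matrix_csv(matrix_file)
  phen <- read_phenotypes(phenotypes)
  res <- test_all_bins(m, phen, alpha = alpha)
  con <- file(out, "w")
  writeLines(meta_header(c(tool = "rarebin", alpha = alpha, m = nrow(m))), con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message(sprintf("test n_bins=%d n_significant=%d out=%s",
                  nrow(res), sum(res$significant), out))
  invisible(list(status = 0L, out = out, results = res))
}

#' Run a simulation study and write its tables
#'
#' @param mode `"null"` (type I error) or `"power"`.
#' @param n_samples Cohort size per replicate.
#' @param replicates Number of replicates (>= 1).
#' @param out_dir Output directory for replicate and summary TSVs.
#' @param seed Master seed.
#' @param threshold MAF binning threshold.
#' @param scale Demography rescaling factor.
#' @param n_pools Haplotype pools rotated over.
#' @param config,model Optional explicit [demography_config()] /
#'   [effect_model()] overriding `mode`/`scale`.
#' @return Invisibly, list with `status`, output paths, and the study result.
#' @export
cmd_simulate <- function(mode = c("null", "power"), n_samples = 1000,
                         replicates = 1000, out_dir, seed = 1,
                         threshold = 0.05, scale = 100, n_pools = 25,
                         config = NULL, model = NULL) {
  mode <- match.arg(mode)
  if (replicates < 1) stop("replicates must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- demography_config(scale = scale)
  if (is.null(model)) model <- if (mode == "null") null_model() else effect_model()
  study <- run_error_power_study(config, model, n_samples, replicates,
                                 threshold = threshold, seed = seed,
                                 n_pools = n_pools)
  rep_path <- file.path(out_dir, "replicates.tsv")
  sum_path <- file.path(out_dir, "summary.tsv")
  meta <- c(tool = "rarebin", mode = mode, n_samples = n_samples,
            replicates = replicates, threshold = threshold, seed = seed,
            scale = config$scale, n_pools = n_pools,
            or_detrimental = model$or_detrimental,
            or_protective = model$or_protective,
            fraction_detrimental = model$fraction_detrimental,
            epochs = paste(sprintf("%g@%g", config$epochs$size,
                                   config$epochs$generations), collapse = ";"))
  con <- file(rep_path, "w")
  writeLines(meta_header(meta), con)
  utils::write.table(study$results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(sum_path, "w")
  writeLines(meta_header(meta), con)
  utils::write.table(
    data.frame(mode = mode, n_samples = n_samples, replicates = replicates,
               rejection_fraction = study$rejection,
               mean_rare_loci = mean(study$results$n_rare_loci)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message(sprintf("simulate mode=%s n=%d reps=%d rejection=%.4f out=%s",
                  mode, n_samples, replicates, study$rejection, out_dir))
  invisible(list(status = 0L, replicates = rep_path, summary = sum_path,
                 study = study))
}

#' Write a toy fixture dataset from the command pipeline
#'
#' Thin wrapper over [generate_toy_dataset()] for the `make-fixture`
#' subcommand.
#'
#' @inheritParams generate_toy_dataset
#' @return Invisibly, list with `status` and the generator's output.
#' @export
cmd_make_fixture <- function(dir, n_genes = 3, n_pathways = 1, n_samples = 20,
                             n_loci = 30, seed = 1) {
  res <- generate_toy_dataset(dir, n_genes = n_genes, n_pathways = n_pathways,
                              n_samples = n_samples, n_loci = n_loci, seed = seed)
  message(sprintf("make-fixture genes=%d pathways=%d samples=%d loci=%d dir=%s",
                  n_genes, n_pathways, n_samples, n_loci, dir))
  invisible(list(status = 0L, fixture = res))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Used by the command-line interface, where explicit flags override file
#' values.
#'
#' @param path Configuration file.
#' @return Named character vector.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop(sprintf("config line not key=value: '%s'", lines[bad][1]))
  stats::setNames(trimws(vapply(kv, `[[`, "", 3L)),
                  trimws(vapply(kv, `[[`, "", 2L)))
}
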