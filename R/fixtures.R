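# Deterministic plain-text writers for synthetic fixtures. The VCF writer
# emits minimal v4.2 records (GT only) that round-trip through read_vcf().

write_simple_vcf <- function(gm, path) {
  n <- n_loci(gm)
  gt <- matrix("", nrow = n, ncol = n_samples(gm))
  code <- function(a) ifelse(is.na(a), ".", as.character(a - 1L))
  gt[] <- paste(code(gm$a1), code(gm$a2), sep = "/")
  ref <- vapply(gm$loci$alleles, `[[`, "", 1L)
  alt <- vapply(gm$loci$alleles, function(a)
    if (length(a) > 1L) paste(a[-1L], collapse = ",") else ".", "")
  rows <- paste(gm$loci$chrom, gm$loci$pos, ".", ref, alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rarebin-fixture",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"),
    rows), path)
  invisible(path)
}

write_phenotype_table <- function(phen, path) {
  writeLines(c("sample_id\tstatus",
               paste(names(phen), as.character(phen), sep = "\t")), path)
  invisible(path)
}

write_region_table <- function(regions, path) {
  writeLines(paste(regions$chromosome, regions$start, regions$stop,
                   regions$label, sep = "\t"), path)
  invisible(path)
}

write_gmt <- function(pathways, path) {
  writeLines(vapply(names(pathways), function(p)
    paste(c(p, "synthetic pathway", pathways[[p]]), collapse = "\t"), ""),
    path)
  invisible(path)
}

#' Generate a fully synthetic toy dataset on disk
#'
#' Writes a self-consistent fixture — VCF genotypes, phenotype table, gene
#' and exon region tables (1-based TSV dialect), and a GMT pathway file —
#' together with the generating truth, so files parsed back through
#' [read_vcf()], [read_phenotypes()], [kb_load_regions()] and
#' [kb_load_groups()] can be checked against what was generated.
#'
#' Genes are laid head to tail on chromosome "1" (4 kb each, 6 kb apart),
#' each with two 1 kb exons at its ends. Each pathway draws two member genes
#' (with wrap-around, so every pathway has at least one member). Genic loci
#' are placed uniformly inside random genes, intergenic loci in the gaps;
#' every locus is biallelic with per-group alternate-allele probabilities
#' drawn from `maf_range`, and genotypes are binomial draws per sample.
#' Output is byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes,n_pathways,n_samples,n_loci Fixture dimensions (positive;
#'   `n_pathways` may be 0).
#' @param frac_intergenic Fraction of loci placed between genes.
#' @param maf_range Range the per-group alternate-allele probability is
#'   drawn from (keep below the intended binning threshold for "all rare"
#'   fixtures).
#' @param seed Integer seed.
#' @return List with file `paths` (vcf, phenotypes, genes, exons, gmt) and
#'   `truth` (genes, exons, pathways, loci table with per-group allele
#'   probabilities, genotype matrix, phenotypes).
#' @export
generate_toy_dataset <- function(dir, n_genes = 3, n_pathways = 1,
                                 n_samples = 20, n_loci = 30,
                                 frac_intergenic = 0.2,
                                 maf_range = c(0.005, 0.04), seed = 1) {
  stopifnot(n_genes >= 1, n_pathways >= 0, n_samples >= 2, n_loci >= 1)
  set.seed(as.integer(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_len <- 4000L; gap <- 2000L
  starts <- 1000L + (seq_len(n_genes) - 1L) * (gene_len + gap)
  genes <- data.frame(label = sprintf("GENE_%d", seq_len(n_genes)),
                      chromosome = "1", start = starts,
                      stop = starts + gene_len - 1L, stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(label = genes$label, chromosome = "1", start = genes$start,
               stop = genes$start + 999L),
    data.frame(label = genes$label, chromosome = "1",
               start = genes$stop - 999L, stop = genes$stop))
  exons <- exons[order(exons$start), ]
  pathways <- list()
  if (n_pathways > 0) {
    for (p in seq_len(n_pathways)) {
      idx <- unique(((p - 1L) * 2L + 0:1) %% n_genes + 1L)
      pathways[[sprintf("PATH_%d", p)]] <- genes$label[idx]
    }
  }
  n_inter <- round(frac_intergenic * n_loci)
  n_genic <- n_loci - n_inter
  genic_pos <- integer(0); genic_gene <- character(0)
  if (n_genic > 0) {
    g <- sort(sample.int(n_genes, n_genic, replace = TRUE))
    offset <- sample.int(gene_len, n_genic, replace = TRUE) - 1L
    genic_pos <- genes$start[g] + offset
    genic_gene <- genes$label[g]
  }
  inter_pos <- integer(0)
  if (n_inter > 0) {
    pool <- c(1:999, as.vector(outer(1:gap - 1L, genes$stop, `+`) + 1L))
    pool <- setdiff(pool, genic_pos)
    if (length(pool) < n_inter) stop("requested more intergenic loci than available positions")
    inter_pos <- sample(pool, n_inter)
  }
  pos <- c(genic_pos, inter_pos)
  in_gene <- c(genic_gene, rep(NA_character_, n_inter))
  dup <- duplicated(pos)
  if (any(dup)) { # resolve collisions by nudging within the region
    for (i in which(dup)) {
      while (pos[i] %in% pos[-i]) pos[i] <- pos[i] + 1L
    }
  }
  ord <- order(pos)
  pos <- pos[ord]; in_gene <- in_gene[ord]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  p_case <- stats::runif(n_loci, maf_range[1], maf_range[2])
  p_control <- stats::runif(n_loci, maf_range[1], maf_range[2])
  samples <- sprintf("S%03d", seq_len(n_samples))
  n_case <- n_samples %/% 2L
  lab <- sample(c(rep("case", n_case), rep("control", n_samples - n_case)))
  phen <- phenotype_assignment(stats::setNames(lab, samples))
  pmat <- ifelse(matrix(lab == "case", nrow = n_loci, ncol = n_samples, byrow = TRUE),
                 p_case[row(matrix(0, n_loci, n_samples))],
                 p_control[row(matrix(0, n_loci, n_samples))])
  altc1 <- matrix(stats::rbinom(n_loci * n_samples, 1L, pmat), n_loci)
  altc2 <- matrix(stats::rbinom(n_loci * n_samples, 1L, pmat), n_loci)
  loci <- data.frame(chrom = "1", pos = pos, stringsAsFactors = FALSE)
  loci$alleles <- Map(c, ref, alt)
  gm <- new_genotype_matrix(samples, loci, altc1 + 1L, altc2 + 1L)
  paths <- list(vcf = file.path(dir, "toy.vcf"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                genes = file.path(dir, "regions_gene.tsv"),
                exons = file.path(dir, "regions_exon.tsv"),
                gmt = file.path(dir, "pathways.gmt"))
  write_simple_vcf(gm, paths$vcf)
  write_phenotype_table(phen, paths$phenotypes)
  write_region_table(genes, paths$genes)
  write_region_table(exons, paths$exons)
  if (length(pathways)) write_gmt(pathways, paths$gmt) else paths$gmt <- NULL
  truth <- list(genes = genes, exons = exons, pathways = pathways,
                loci = data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                                  p_case = p_case, p_control = p_control,
                                  in_gene = in_gene, stringsAsFactors = FALSE),
                genotypes = gm, phenotypes = phen)
  list(paths = paths, truth = truth)
}
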