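# Spike-in cohort builder: 87 samples split 43/44, many background gene bins,
# one target gene whose locus count is controlled, a fully penetrant
# heterozygous spike inside it. Background alternate alleles are rare
# binomial draws so every background locus stays below the binning threshold
# in expectation.
build_spike_fixture <- function(target_loci, n_noise_genes = 120,
                                loci_per_noise_gene = 5, alt_p = 0.01,
                                seed = 1) {
  set.seed(seed)
  n_samples <- 87L
  samples <- sprintf("S%03d", seq_len(n_samples))
  lab <- sample(c(rep("case", 43L), rep("control", 44L)))
  phen <- phenotype_assignment(stats::setNames(lab, samples))
  gene_len <- 50000L
  n_genes <- n_noise_genes + 1L
  starts <- 1000L + (seq_len(n_genes) - 1L) * (gene_len + 10000L)
  genes <- data.frame(label = c(sprintf("NOISE_%03d", seq_len(n_noise_genes)), "TARGET"),
                      chromosome = "7", start = starts,
                      stop = starts + gene_len - 1L, stringsAsFactors = FALSE)
  counts <- c(rep(loci_per_noise_gene, n_noise_genes), target_loci)
  gene_of <- rep(seq_len(n_genes), counts)
  pos <- genes$start[gene_of] +
    unlist(lapply(counts, function(k) sort(sample.int(gene_len - 100L, k))))
  n_loci <- length(pos)
  a_extra <- matrix(stats::rbinom(2L * n_loci * n_samples, 1L, alt_p),
                    nrow = 2L * n_loci)
  loci <- data.frame(chrom = "7", pos = pos, stringsAsFactors = FALSE)
  loci$alleles <- rep(list(c("A", "G")), n_loci)
  gm <- rarebin:::new_genotype_matrix(
    samples, loci,
    a_extra[seq_len(n_loci), , drop = FALSE] + 1L,
    a_extra[n_loci + seq_len(n_loci), , drop = FALSE] + 1L)
  spike_pos <- genes$start[n_genes] + gene_len - 50L
  kb <- kb_new()
  tf <- tempfile()
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chromosome, genes$start,
                     genes$stop, genes$label), tf)
  kb_load_regions(kb, tf, "gene")
  unlink(tf)
  gm <- spike_in_variant(gm, phen, "7", spike_pos, "TARGET", kb)
  list(gm = gm, phen = phen, kb = kb, genes = genes, spike_pos = spike_pos)
}

spike_fixture_results <- function(fx, threshold = 0.05) {
  gft <- group_allele_frequencies(fx$gm, fx$phen)
  rar <- rarity_calls(gft, threshold)
  bins <- build_feature_bins(rar, fx$kb,
                             binning_config(threshold, feature_types = "gene"))
  bm <- build_bin_matrix(bins, fx$gm, rar)
  test_all_bins(bm, fx$phen, alpha = 0.05)
}
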