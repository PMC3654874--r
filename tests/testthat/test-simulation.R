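# small, fast demography used where the full default schedule is not needed
tiny_config <- function(...) {
  demography_config(epochs = data.frame(size = 4000, generations = 40,
                                        growth = FALSE),
                    scale = 40, selection = "neutral", burnin_factor = 4, ...)
}

test_that("the simulator is deterministic and silent at mutation rate zero", {
  cfg <- tiny_config()
  p1 <- simulate_region(cfg, seed = 11)
  p2 <- simulate_region(cfg, seed = 11)
  expect_identical(p1$positions, p2$positions)
  expect_identical(p1$s, p2$s)
  expect_identical(as.matrix(p1$mat), as.matrix(p2$mat))
  expect_gt(length(p1$positions), 0)
  p3 <- simulate_region(cfg, seed = 12)
  expect_false(identical(p1$positions, p3$positions))
  cfg0 <- tiny_config(mutation_rate = 0)
  expect_length(simulate_region(cfg0, seed = 1)$positions, 0)
})

test_that("neutral constant-size diversity matches the 4*N*mu*L expectation", {
  cfg <- tiny_config()
  # scaled: N = 100 diploids, mu' = 40 * 1.8e-8, burn-in 400 generations
  expectation <- 4 * 100 * (1.8e-8 * 40) * 5000
  dv <- vapply(1:40, function(s) pool_diversity(simulate_region(cfg, s)), numeric(1))
  se <- sd(dv) / sqrt(length(dv))
  expect_lt(abs(mean(dv) - expectation), 3 * se)
})

test_that("rescaling below the drift floor is rejected", {
  expect_error(simulate_region(demography_config(scale = 500), seed = 1), "< 50")
})

test_that("null cohorts get balanced labels independent of genotype", {
  cfg <- tiny_config()
  pool <- simulate_region(cfg, seed = 3)
  cc <- sample_case_control(pool, 250, null_model(), seed = 5)
  expect_equal(sum(cc$phenotypes == "case"), 125)
  expect_equal(sum(cc$phenotypes == "control"), 125)
  expect_equal(n_samples(cc$genotypes), 250)
  expect_s3_class(cc$genotypes, "genotype_matrix")
  # derived-allele counts agree between the matrix and the sparse counts
  der <- (cc$genotypes$a1 == 2L) + (cc$genotypes$a2 == 2L)
  expect_equal(unname(der), unname(as.matrix(cc$counts)))
})

test_that("an overwhelming detrimental model makes cases carry more variants", {
  cfg <- tiny_config()
  pools <- lapply(1:5, function(s) simulate_region(cfg, s))
  mp <- merge_pools(pools)
  m <- effect_model(or_detrimental = 100, or_protective = 0.9,
                    fraction_detrimental = 1)
  wins <- 0L
  for (s in 1:20) {
    cc <- sample_case_control(mp, 200, m, seed = s, genotypes = FALSE)
    B <- Matrix::colSums(cc$counts)
    if (mean(B[cc$phenotypes == "case"]) > mean(B[cc$phenotypes == "control"])) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 19L)
})

test_that("merged pools concatenate sites and haplotypes", {
  cfg <- tiny_config()
  pools <- lapply(1:3, function(s) simulate_region(cfg, s))
  mp <- merge_pools(pools)
  expect_equal(mp$n_hap, sum(vapply(pools, `[[`, integer(1), "n_hap")))
  expect_equal(length(mp$positions), sum(lengths(lapply(pools, `[[`, "positions"))))
  # positions offset per subpool stay distinct
  expect_false(any(duplicated(mp$positions)))
  expect_equal(sum(mp$mat), sum(vapply(pools, function(p) sum(p$mat), numeric(1))))
})

test_that("spike-in adds one heterozygous variant per case and nothing else", {
  set.seed(77)
  gm <- random_genotype_matrix(n_samples = 87, n_loci = 10, chroms = "7")
  lab <- c(rep("case", 43), rep("control", 44))
  phen <- phenotype_assignment(stats::setNames(lab, gm$samples))
  gm2 <- spike_in_variant(gm, phen, "7", 116140000L)
  expect_equal(n_loci(gm2), 11L)
  i <- n_loci(gm2)
  carriers <- (gm2$a1[i, ] == 2L) + (gm2$a2[i, ] == 2L)
  expect_equal(sum(carriers), 43) # total added variants = number of cases
  expect_true(all(carriers[lab == "case"] == 1))
  expect_true(all(carriers[lab == "control"] == 0))
  # spiked-locus MAF among cases = 0.5 by construction
  gft <- group_allele_frequencies(gm2, phen)
  expect_equal(unname(minor_allele_frequency(locus_freqs(gft, i, "case"))), 0.5)
  expect_equal(unname(minor_allele_frequency(locus_freqs(gft, i, "control"))), 0)
  # collisions and case-free cohorts are rejected
  expect_error(spike_in_variant(gm2, phen, "7", 116140000L), "collides")
  allctl <- phenotype_assignment(stats::setNames(rep("control", 87), gm$samples))
  expect_error(suppressWarnings(spike_in_variant(gm, allctl, "7", 1L)),
               "zero cases|non-empty")
  # knowledge-base guard
  kb <- kb_new()
  tf <- withr::local_tempfile()
  writeLines("7\t116139654\t116148595\tCAV_LIKE", tf)
  kb_load_regions(kb, tf, "gene")
  expect_error(spike_in_variant(gm, phen, "7", 999L, "CAV_LIKE", kb), "not inside")
  expect_s3_class(spike_in_variant(gm, phen, "7", 116140001L, "CAV_LIKE", kb),
                  "genotype_matrix")
})

test_that("the fast study burden matches the full binning pipeline", {
  cfg <- tiny_config()
  pools <- lapply(1:4, function(s) simulate_region(cfg, s))
  mp <- merge_pools(pools)
  for (seed in 1:3) {
    cc <- sample_case_control(mp, 80, null_model(), seed = seed)
    fast <- rarebin:::region_burden(cc$counts, cc$phenotypes, 0.05)
    gft <- group_allele_frequencies(cc$genotypes, cc$phenotypes)
    rar <- rarity_calls(gft, 0.05)
    kb <- kb_new()
    tf <- tempfile()
    writeLines(sprintf("1\t1\t%d\tREGION", 4L * cfg$region_length), tf)
    kb_load_regions(kb, tf, "gene")
    unlink(tf)
    if (!any(rar$rare)) next
    bins <- build_feature_bins(rar, kb, binning_config(0.05, feature_types = "gene"))
    bm <- build_bin_matrix(bins, cc$genotypes, rar)
    expect_equal(unname(bm$matrix["REGION", ]), unname(fast$burden))
  }
})

test_that("study results are reproducible and degenerate cases behave", {
  cfg <- tiny_config()
  s1 <- run_error_power_study(cfg, null_model(), 100, 20, seed = 9, n_pools = 3)
  s2 <- run_error_power_study(cfg, null_model(), 100, 20, seed = 9, n_pools = 3)
  expect_identical(s1$results, s2$results)
  expect_true(all(s1$results$p >= 0 & s1$results$p <= 1))
  one <- run_error_power_study(cfg, null_model(), 100, 1, seed = 2, n_pools = 2)
  expect_true(one$rejection %in% c(0, 1))
  expect_error(run_error_power_study(cfg, null_model(), 100, 0, seed = 1),
               "replicates")
})

test_that("toy datasets round-trip through the parsers to the generating truth", {
  d <- withr::local_tempdir()
  fx <- generate_toy_dataset(file.path(d, "a"), n_genes = 3, n_pathways = 1,
                             n_samples = 20, n_loci = 30, seed = 5)
  gm <- read_vcf(fx$paths$vcf)
  expect_equal(gm$loci$pos, fx$truth$loci$pos)
  expect_equal(vapply(gm$loci$alleles, `[[`, "", 1L), fx$truth$loci$ref)
  expect_equal(unname(gm$a1), unname(fx$truth$genotypes$a1))
  phen <- read_phenotypes(fx$paths$phenotypes)
  expect_equal(as.character(phen), as.character(fx$truth$phenotypes),
               ignore_attr = TRUE)
  kb <- kb_new()
  expect_equal(kb_load_regions(kb, fx$paths$genes, "gene"), 3L, ignore_attr = TRUE)
  expect_equal(kb_load_regions(kb, fx$paths$exons, "exon"), 6L, ignore_attr = TRUE)
  expect_equal(kb_load_groups(kb, fx$paths$gmt), 1L, ignore_attr = TRUE)
  expect_equal(kb_regions(kb)$start[kb_regions(kb)$region_type == "gene"],
               fx$truth$genes$start)
  # all loci rare at a threshold above the generating allele probabilities:
  # bins match the generating gene memberships
  gft <- group_allele_frequencies(gm, phen)
  rar <- rarity_calls(gft, 0.49)
  cfg <- binning_config(0.49, feature_types = c("gene", "pathway", "intergenic"))
  bins <- build_feature_bins(rar, kb, cfg)
  types <- vapply(bins, `[[`, "", "feature_type")
  ids <- vapply(bins, `[[`, "", "bin_id")
  poly <- rar$rare
  for (g in unique(stats::na.omit(fx$truth$loci$in_gene))) {
    want <- which(fx$truth$loci$in_gene == g & poly)
    if (length(want)) {
      expect_equal(sort(bins[[which(ids == g)]]$loci), want, info = g)
    }
  }
  # byte-identical regeneration under the same seed
  fx2 <- generate_toy_dataset(file.path(d, "b"), n_genes = 3, n_pathways = 1,
                              n_samples = 20, n_loci = 30, seed = 5)
  for (nm in setdiff(names(fx$paths), "gmt")) {
    expect_identical(readLines(fx$paths[[nm]]), readLines(fx2$paths[[nm]]))
  }
  # no intergenic loci requested -> no intergenic bins
  fx0 <- generate_toy_dataset(file.path(d, "c"), n_genes = 2, n_pathways = 0,
                              n_samples = 10, n_loci = 10,
                              frac_intergenic = 0, seed = 3)
  gm0 <- read_vcf(fx0$paths$vcf)
  kb0 <- kb_new()
  kb_load_regions(kb0, fx0$paths$genes, "gene")
  gft0 <- group_allele_frequencies(gm0, read_phenotypes(fx0$paths$phenotypes))
  bins0 <- build_feature_bins(rarity_calls(gft0, 0.49), kb0,
                              binning_config(0.49, feature_types = c("gene", "intergenic")))
  expect_false(any(vapply(bins0, `[[`, "", "feature_type") == "intergenic"))
})
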