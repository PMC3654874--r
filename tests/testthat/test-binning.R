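toy_kb <- function() {
  kb <- kb_new()
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c("1\t1000\t2000\tGENE_A",
               "1\t5000\t9000\tGENE_B",
               "1\t8000\t12000\tGENE_C", # overlaps GENE_B
               "2\t100\t400\tGENE_D"), f)
  kb_load_regions(kb, f, "gene")
  g <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c("PATH_1\tdesc\tGENE_A\tGENE_B",
               "PATH_2\tdesc\tGENE_B\tGENE_C"), g)
  kb_load_groups(kb, g)
  kb
}

rarity_from <- function(loci, binned) {
  # loci: data.frame(chrom, pos); binned: list of allele sets ("" = common)
  out <- data.frame(locus = seq_len(nrow(loci)), chrom = loci$chrom,
                    pos = loci$pos, maf_case = NA_real_, maf_control = NA_real_,
                    rare = lengths(binned) > 0, stringsAsFactors = FALSE)
  out$binned <- binned
  class(out) <- c("rarity_calls", "data.frame")
  out
}

test_that("minor allele frequency is the second most frequent allele", {
  expect_equal(minor_allele_frequency(c(C = 0.97, T = 0.03)), 0.03)
  expect_equal(minor_allele_frequency(c(T = 0.80, A = 0.16, G = 0.04)), 0.16)
  expect_equal(minor_allele_frequency(c(A = 1.0)), 0)
  # tie at the top: the tied frequency is the MAF
  expect_equal(minor_allele_frequency(c(A = 0.5, C = 0.25, G = 0.25)), 0.25)
  expect_equal(minor_allele_frequency(c(A = 0.5, T = 0.5)), 0.5)
  expect_error(minor_allele_frequency(numeric(0)), "unobserved")
})

test_that("rarity uses strict inequality in either group", {
  f08 <- c(G = 0.92, A = 0.08)
  expect_false(classify_rarity(f08, f08, 0.05)$rare)
  f049 <- c(G = 0.951, A = 0.049)
  expect_true(classify_rarity(f049, f049, 0.05)$rare)
  # boundary: MAF exactly at threshold is not binned
  f05 <- c(G = 0.95, A = 0.05)
  expect_false(classify_rarity(f05, f05, 0.05)$rare)
  # either group suffices
  expect_true(classify_rarity(f08, f049, 0.05)$rare)
  # polyallelic: all non-major alleles binned together
  poly <- c(G = 0.95, C = 0.03, T = 0.02)
  cl <- classify_rarity(poly, poly, 0.05)
  expect_equal(cl$binned_alleles, c("C", "T"))
  expect_equal(cl$maf_case, 0.03)
})

test_that("binned sets union across triggering groups with per-group majors", {
  # allele common in controls but absent in cases: case side triggers and
  # bins it as a protective variant
  cl <- classify_rarity(c(C = 1, T = 0), c(C = 0.8, T = 0.2), 0.05)
  expect_true(cl$rare)
  expect_equal(cl$binned_alleles, "T")
  # majors differ: each triggering group contributes its own non-major set
  cl2 <- classify_rarity(c(C = 0.99, T = 0.01), c(C = 0.02, T = 0.98), 0.05)
  expect_setequal(cl2$binned_alleles, c("C", "T"))
})

test_that("monomorphic loci are dropped before binning at any threshold", {
  gm <- random_genotype_matrix(10, 5)
  gm$a1[1, ] <- 1L; gm$a2[1, ] <- 1L # monomorphic in everyone
  phen <- random_phenotypes(gm$samples)
  gft <- group_allele_frequencies(gm, phen)
  rar <- rarity_calls(gft, 1.0)
  expect_false(rar$rare[1])
  expect_length(rar$binned[[1]], 0)
  # threshold 0 -> nothing rare at all
  rar0 <- rarity_calls(gft, 0)
  expect_false(any(rar0$rare))
  # threshold 1 -> every polymorphic locus rare
  poly <- vapply(seq_len(n_loci(gm)), function(i) {
    a <- c(gm$a1[i, ], gm$a2[i, ])
    length(unique(a[!is.na(a)])) > 1
  }, logical(1))
  expect_equal(rar$rare, poly)
})

test_that("raising the threshold never removes a locus from rarity", {
  set.seed(11)
  gm <- random_genotype_matrix(40, 60)
  phen <- random_phenotypes(gm$samples)
  gft <- group_allele_frequencies(gm, phen)
  prev <- rep(FALSE, 60)
  for (t in c(0.02, 0.05, 0.1, 0.3, 1.0)) {
    cur <- rarity_calls(gft, t)$rare
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("gene, pathway, and intergenic bins assemble correctly", {
  kb <- toy_kb()
  loci <- data.frame(chrom = c("1", "1", "1", "1", "1", "2"),
                     pos = c(1500, 6000, 9000, 9500, 120000, 250))
  binned <- list("x", "x", "x", character(0), "x", "x")
  rar <- rarity_from(loci, binned)
  cfg <- binning_config(0.05, feature_types = c("gene", "pathway", "intergenic"))
  bins <- build_feature_bins(rar, kb, cfg)
  ids <- vapply(bins, `[[`, "", "bin_id")
  types <- vapply(bins, `[[`, "", "feature_type")
  # locus at 9000 is in both GENE_B and GENE_C (overlap tolerated)
  b <- function(id) bins[[which(ids == id)]]
  expect_setequal(ids[types == "gene"], c("GENE_A", "GENE_B", "GENE_C", "GENE_D"))
  expect_equal(b("GENE_B")$coords$pos, c(6000, 9000))
  expect_equal(b("GENE_C")$coords$pos, 9000)
  # pathway = deduplicated union of member gene loci
  expect_equal(b("PATH_1")$coords$pos, c(1500, 6000, 9000))
  expect_equal(b("PATH_2")$coords$pos, c(6000, 9000))
  # rare locus outside every gene falls into a 50 kb window: [100001, 150000];
  # the chr2 locus sits inside GENE_D, so no chr2 window appears
  expect_equal(ids[types == "intergenic"], "chr1:window_3")
  expect_equal(b("chr1:window_3")$coords$pos, 120000)
  # locus 4 not rare: appears nowhere
  expect_false(any(vapply(bins, function(b) 9500 %in% b$coords$pos, logical(1))))
  # every rare locus is caught when gene+intergenic are both enabled
  caught <- sort(unique(unlist(lapply(bins, function(b) b$loci))))
  expect_setequal(caught, which(rar$rare))
})

test_that("feature selection drives assignment: genic loci fall to windows when gene is off", {
  kb <- toy_kb()
  rar <- rarity_from(data.frame(chrom = "1", pos = 1500), list("x"))
  cfg <- binning_config(0.05, feature_types = "intergenic")
  bins <- build_feature_bins(rar, kb, cfg)
  expect_length(bins, 1L)
  expect_equal(bins[[1]]$bin_id, "chr1:window_1")
  expect_error(
    build_feature_bins(rar, kb_new(), binning_config(feature_types = "pathway")),
    "no groups")
})

test_that("exon/intron splitting partitions loci within their genes", {
  kb <- toy_kb()
  f <- withr::local_tempfile()
  writeLines(c("1\t1000\t1200\tGENE_A", "1\t5000\t5500\tGENE_B"), f)
  kb_load_regions(kb, f, "exon")
  rar <- rarity_from(data.frame(chrom = c("1", "1", "1"), pos = c(1100, 1500, 5200)),
                     list("x", "x", "x"))
  bins <- build_feature_bins(rar, kb, binning_config(feature_types = "gene"))
  split <- apply_subfeature_filter(bins, kb, "both")
  ids <- vapply(split, `[[`, "", "bin_id")
  expect_setequal(ids, c("GENE_A_exon", "GENE_A_intron", "GENE_B_exon"))
  expect_equal(split[[which(ids == "GENE_A_exon")]]$coords$pos, 1100)
  expect_equal(split[[which(ids == "GENE_A_intron")]]$coords$pos, 1500)
  only_ex <- apply_subfeature_filter(bins, kb, "exon")
  expect_setequal(vapply(only_ex, `[[`, "", "bin_id"),
                  c("GENE_A_exon", "GENE_B_exon"))
  expect_error(apply_subfeature_filter(bins, toy_kb(), "both"), "no exon regions")
})

test_that("prediction splits keep only predicted loci", {
  kb <- toy_kb()
  rar <- rarity_from(data.frame(chrom = c("1", "1", "1"), pos = c(1100, 1500, 6000)),
                     list("x", "x", "x"))
  bins <- build_feature_bins(rar, kb, binning_config(feature_types = "gene"))
  pred <- data.frame(chromosome = c("1", "1"), position = c(1100, 1500),
                     category = c("risk", "benign"))
  split <- apply_prediction_split(bins, pred)
  ids <- vapply(split, `[[`, "", "bin_id")
  expect_setequal(ids, c("GENE_A_benign", "GENE_A_risk"))
  # unpredicted locus 6000 is in no output bin
  expect_false(any(vapply(split, function(b) 6000 %in% b$coords$pos, logical(1))))
  # all loci unpredicted -> error advising to disable
  expect_error(apply_prediction_split(bins,
    data.frame(chromosome = "9", position = 1, category = "x")), "disable")
})

test_that("burden entries follow the additive count of binned alleles", {
  # three samples: het, hom-alt, compound het of two binned alleles
  loci <- data.frame(chrom = "1", pos = c(1100, 1200))
  loci$alleles <- list(c("C", "T"), c("G", "A", "T"))
  gm <- rarebin:::new_genotype_matrix(
    c("S1", "S2", "S3"), loci,
    a1 = matrix(c(1L, 2L, NA, 1L, 1L, 2L), nrow = 2, byrow = TRUE),
    a2 = matrix(c(2L, 2L, 1L, 1L, 1L, 3L), nrow = 2, byrow = TRUE))
  rar <- rarity_from(loci, list("T", c("A", "T")))
  kb <- toy_kb()
  bins <- build_feature_bins(rar, kb, binning_config(feature_types = "gene"))
  bm <- build_bin_matrix(bins, gm, rar)
  expect_equal(dim(bm$matrix), c(1L, 3L))
  # S1: het at locus1 (1) + hom ref at locus2 (0) = 1
  # S2: hom alt at locus1 (2) + hom ref (0) = 2
  # S3: half-missing locus1 (0) + A/T both binned (2) = 2
  expect_equal(bm$matrix["GENE_A", ], c(S1 = 1L, S2 = 2L, S3 = 2L))
  expect_equal(bm$summary$n_loci, 2L)
  expect_equal(bm$summary$total_variants, 5L)
  expect_true(all(bm$matrix <= 2 * bm$summary$n_loci))
})

test_that("full pipeline agrees with the brute-force reference on random data", {
  set.seed(2024)
  for (rep in 1:25) {
    n_samples <- sample(6:30, 1)
    n_loci <- sample(10:100, 1)
    gm <- random_genotype_matrix(n_samples, n_loci, chroms = "1", max_pos = 120000)
    phen <- random_phenotypes(gm$samples)
    n_genes <- sample(1:10, 1)
    st <- sort(sample.int(110000, n_genes))
    genes <- data.frame(label = sprintf("G%02d", seq_len(n_genes)),
                        chromosome = "1", start = st,
                        stop = st + sample(2000:20000, n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    n_path <- sample(0:3, 1)
    pathways <- list()
    if (n_path > 0) {
      for (p in seq_len(n_path)) {
        pathways[[sprintf("P%d", p)]] <-
          sample(genes$label, sample(seq_len(n_genes), 1))
      }
    }
    threshold <- sample(c(0.05, 0.1, 0.25), 1)
    ref <- oracle_binning_pipeline(gm, stats::setNames(as.character(phen), names(phen)),
                                   genes, pathways, threshold)
    kb <- kb_new()
    gf <- tempfile(); writeLines(sprintf("%s\t%d\t%d\t%s", genes$chromosome,
                                         genes$start, genes$stop, genes$label), gf)
    kb_load_regions(kb, gf, "gene")
    unlink(gf)
    if (length(pathways)) {
      pf <- tempfile()
      writeLines(vapply(names(pathways), function(p)
        paste(c(p, "d", pathways[[p]]), collapse = "\t"), ""), pf)
      kb_load_groups(kb, pf)
      unlink(pf)
    }
    gft <- group_allele_frequencies(gm, phen)
    rar <- rarity_calls(gft, threshold)
    expect_equal(which(rar$rare), ref$rare)
    feats <- if (length(pathways)) c("gene", "pathway", "intergenic") else
      c("gene", "intergenic")
    cfg <- binning_config(threshold, feature_types = feats)
    bins <- build_feature_bins(rar, kb, cfg)
    ids <- vapply(bins, `[[`, "", "bin_id")
    expect_setequal(ids, names(ref$bins))
    if (length(bins)) {
      bm <- build_bin_matrix(bins, gm, rar)
      for (id in ids) {
        expect_equal(sort(bins[[which(ids == id)]]$loci), ref$bins[[id]]$loci,
                     info = id)
        expect_equal(bm$matrix[id, ], ref$burden[id, ], info = id)
      }
      # column-sum consistency of recorded totals
      expect_equal(bm$summary$total_variants, as.integer(rowSums(bm$matrix)))
    } else {
      expect_length(ref$bins, 0)
    }
  }
})
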