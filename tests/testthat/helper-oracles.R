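# Independent brute-force oracles used across the test files. These are
# deliberately naive (nested loops, no indexing structures, no shared code
# with the package internals) so they can arbitrate the implementation.

# O(n) linear scan for regions containing a position.
oracle_regions_containing <- function(regions, chromosome, position, type = NULL) {
  hit <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    ok <- r$chromosome == chromosome && r$start <= position && position <= r$stop
    if (!is.null(type)) ok <- ok && r$region_type == type
    hit[i] <- ok
  }
  regions[hit, , drop = FALSE]
}

# Per-allele tally of observed alleles for one locus and a set of samples.
oracle_locus_freqs <- function(gm, locus, sample_ids) {
  al <- gm$loci$alleles[[locus]]
  counts <- stats::setNames(rep(0, length(al)), al)
  for (s in sample_ids) {
    j <- which(gm$samples == s)
    for (a in c(gm$a1[locus, j], gm$a2[locus, j])) {
      if (!is.na(a)) counts[al[a]] <- counts[al[a]] + 1
    }
  }
  if (sum(counts) == 0) return(stats::setNames(numeric(0), character(0)))
  counts / sum(counts)
}

# Exact two-sided permutation p-value for the rank-sum statistic, enumerated
# over every assignment of the pooled values into groups of sizes n1/n2.
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  # midranks computed by hand from sorted values
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v)[order(order(v))][i] == sort(v)))
    # positions of equal values share the average of their sorted indices
    sapply(seq_along(v), function(i) mean(which(sort(v) == v[i])))
  }
  r <- midrank(pooled)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  stat <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

# Full brute-force reference binning pipeline: per-group frequencies, rarity
# calls, gene/pathway/intergenic bins and the burden matrix, all with plain
# nested loops over a "truth" description (lists/data.frames, no kb object).
# genes: data.frame(label, chromosome, start, stop); pathways: named list of
# gene label vectors.
oracle_binning_pipeline <- function(gm, phen_named, genes, pathways, threshold,
                                    window = 50000, features = c("gene", "pathway", "intergenic")) {
  samples <- gm$samples
  grp <- phen_named[samples]
  freqs_of <- function(i, g) {
    ids <- samples[grp == g]
    al <- gm$loci$alleles[[i]]
    counts <- stats::setNames(rep(0, length(al)), al)
    for (s in ids) {
      j <- which(samples == s)
      for (a in c(gm$a1[i, j], gm$a2[i, j])) if (!is.na(a)) counts[al[a]] <- counts[al[a]] + 1
    }
    if (sum(counts) == 0) return(NULL)
    counts / sum(counts)
  }
  n <- nrow(gm$loci)
  binned_alleles <- vector("list", n)
  for (i in seq_len(n)) {
    fc <- freqs_of(i, "case"); fk <- freqs_of(i, "control")
    seen <- character()
    if (!is.null(fc)) seen <- union(seen, names(fc)[fc > 0])
    if (!is.null(fk)) seen <- union(seen, names(fk)[fk > 0])
    if (length(seen) <= 1) { binned_alleles[[i]] <- character(); next }
    binned <- character()
    for (f in list(fc, fk)) {
      if (is.null(f)) next
      srt <- sort(f, decreasing = TRUE)
      maf <- if (length(f) == 1) 0 else srt[[2]]
      if (maf < threshold) {
        top <- names(f)[f == max(f)]
        major <- sort(top)[1]
        binned <- union(binned, setdiff(names(f), major))
      }
    }
    binned_alleles[[i]] <- binned
  }
  rare <- which(lengths(binned_alleles) > 0)
  bins <- list() # name -> list(type, loci)
  add <- function(bins, id, type, loci) {
    bins[[id]] <- list(type = type, loci = sort(unique(loci)))
    bins
  }
  in_gene <- function(i, g) {
    gm$loci$chrom[i] == g$chromosome && g$start <= gm$loci$pos[i] &&
      gm$loci$pos[i] <= g$stop
  }
  assigned <- integer(0)
  if ("gene" %in% features) {
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      loci <- rare[sapply(rare, in_gene, g = g)]
      if (length(loci)) {
        bins <- add(bins, g$label, "gene", loci)
        assigned <- union(assigned, loci)
      }
    }
  }
  if ("pathway" %in% features && length(pathways)) {
    for (pname in names(pathways)) {
      loci <- integer(0)
      for (glabel in pathways[[pname]]) {
        g <- genes[genes$label == glabel, ]
        if (!nrow(g)) next
        loci <- union(loci, rare[sapply(rare, in_gene, g = g[1, ])])
      }
      if (length(loci)) {
        bins <- add(bins, pname, "pathway", loci)
        assigned <- union(assigned, loci)
      }
    }
  }
  if ("intergenic" %in% features) {
    for (i in setdiff(rare, assigned)) {
      k <- (gm$loci$pos[i] - 1) %/% window
      id <- sprintf("chr%s:window_%d", sub("^chr", "", gm$loci$chrom[i]), k + 1)
      old <- if (id %in% names(bins)) bins[[id]]$loci else integer(0)
      bins <- add(bins, id, "intergenic", c(old, i))
    }
  }
  burden <- matrix(0L, nrow = length(bins), ncol = length(samples),
                   dimnames = list(names(bins), samples))
  for (b in seq_along(bins)) {
    for (i in bins[[b]]$loci) {
      al <- gm$loci$alleles[[i]]
      for (j in seq_along(samples)) {
        for (a in c(gm$a1[i, j], gm$a2[i, j])) {
          if (!is.na(a) && al[a] %in% binned_alleles[[i]]) {
            burden[b, j] <- burden[b, j] + 1L
          }
        }
      }
    }
  }
  list(binned_alleles = binned_alleles, rare = rare, bins = bins, burden = burden)
}

# Random genotype matrix for property tests.
random_genotype_matrix <- function(n_samples, n_loci, chroms = c("1", "2"),
                                   max_pos = 200000, p_multi = 0.2,
                                   p_missing = 0.05) {
  samples <- sprintf("S%03d", seq_len(n_samples))
  chrom <- sample(chroms, n_loci, replace = TRUE)
  pos <- integer(n_loci)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sample.int(max_pos, length(idx))
  }
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  bases <- c("A", "C", "G", "T")
  alleles <- lapply(seq_len(n_loci), function(i) {
    k <- if (stats::runif(1) < p_multi) 3L else 2L
    sample(bases, k)
  })
  draw <- function() {
    m <- matrix(NA_integer_, n_loci, n_samples)
    for (i in seq_len(n_loci)) {
      k <- length(alleles[[i]])
      p <- c(0.9, rep(0.1 / (k - 1), k - 1))
      m[i, ] <- sample.int(k, n_samples, replace = TRUE, prob = p)
    }
    m[matrix(stats::runif(n_loci * n_samples) < p_missing, n_loci)] <- NA_integer_
    m
  }
  loci <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  loci$alleles <- alleles
  rarebin:::new_genotype_matrix(samples, loci, draw(), draw())
}

random_phenotypes <- function(samples) {
  n <- length(samples)
  lab <- sample(c(rep("case", n %/% 2), rep("control", n - n %/% 2)))
  phenotype_assignment(stats::setNames(lab, samples))
}
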