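#' Binning configuration
#'
#' @param maf_threshold Minor-allele-frequency threshold in \[0, 1\]. A locus
#'   is rare — and contributes to bins — iff its MAF is *strictly* below this
#'   value in the case group or the control group (either suffices). The
#'   strict inequality matters at the boundary: MAF exactly equal to the
#'   threshold is not binned.
#' @param feature_types Subset of `"gene"`, `"pathway"`, `"intergenic"`:
#'   which feature bins to construct.
#' @param intergenic_window Window size in bp for intergenic catch-all bins
#'   (default 50 kb). Each chromosome is tiled from position 1 in fixed,
#'   non-overlapping, inclusive windows.
#' @param subfeature_filter `"none"`, `"exon"` or `"intron"`: split bins by
#'   exon membership (see [apply_subfeature_filter()]).
#' @param prediction_split Logical: split bins by functional-prediction
#'   category (requires a prediction table at binning time).
#' @return A `binning_config` list.
#' @export
binning_config <- function(maf_threshold = 0.05,
                           feature_types = c("gene", "intergenic"),
                           intergenic_window = 50000L,
                           subfeature_filter = "none",
                           prediction_split = FALSE) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 1,
            intergenic_window >= 1,
            all(feature_types %in% c("gene", "pathway", "intergenic")),
            length(feature_types) >= 1)
  subfeature_filter <- match.arg(subfeature_filter, c("none", "exon", "intron"))
  structure(list(maf_threshold = maf_threshold,
                 feature_types = unique(feature_types),
                 intergenic_window = as.integer(intergenic_window),
                 subfeature_filter = subfeature_filter,
                 prediction_split = isTRUE(prediction_split)),
            class = "binning_config")
}

#' Minor allele frequency of one locus in one group
#'
#' The minor allele frequency is the frequency of the *second most frequent*
#' allele. For a biallelic locus this is the rarer allele; for a polyallelic
#' locus the third, fourth, ... alleles do not change the MAF. A monomorphic
#' locus (single allele) has MAF 0. When the two top frequencies tie (e.g.
#' 0.5/0.5), the tied frequency is the MAF regardless of which allele is
#' ranked second.
#'
#' @param freqs Named numeric vector of allele frequencies for one locus in
#'   one group (may include zero-frequency alleles).
#' @return The frequency of the second most frequent allele (0 for a
#'   monomorphic locus).
#' @export
#' @examples
#' minor_allele_frequency(c(C = 0.97, T = 0.03)) # 0.03
#' minor_allele_frequency(c(T = 0.80, A = 0.16, G = 0.04)) # 0.16
minor_allele_frequency <- function(freqs) {
  if (!length(freqs)) stop("locus unobserved in group: no allele frequencies")
  if (length(freqs) == 1L) return(0)
  sort(freqs, decreasing = TRUE)[[2]]
}

# Major allele of a group: most frequent; 50/50 ties broken lexicographically.
major_allele <- function(freqs) {
  top <- names(freqs)[freqs == max(freqs)]
  if (length(top) > 1L) top <- sort(top)[1]
  top
}

#' Classify one locus as rare/common and derive its binned alleles
#'
#' A locus is rare iff its MAF is strictly below `threshold` in the case
#' group *or* the control group. When a group triggers rarity, all of that
#' group's non-major alleles are binned identically (the rule does not
#' distinguish among minor alleles of a polyallelic locus); when both groups
#' trigger, the per-group non-major allele sets are unioned. A locus that is
#' monomorphic across both groups carries no non-major allele, contributes
#' nothing, and is reported as not binned.
#'
#' @param case_freqs,control_freqs Named allele-frequency vectors for the two
#'   groups (zero-frequency alleles may be included; a length-zero vector
#'   means the locus is unobserved in that group).
#' @param threshold MAF threshold (strict `<`).
#' @return List with `rare` (logical), `maf_case`, `maf_control` (NA when
#'   unobserved), and `binned_alleles` (character, empty when not rare).
#' @export
#' @examples
#' # MAF 0.03 < 0.05 in both groups: both non-major alleles binned
#' classify_rarity(c(G = 0.95, C = 0.03, T = 0.02),
#'                 c(G = 0.95, C = 0.03, T = 0.02), threshold = 0.05)
classify_rarity <- function(case_freqs, control_freqs, threshold) {
  if (!length(case_freqs) && !length(control_freqs)) {
    stop("locus unobserved in both groups")
  }
  maf_case <- if (length(case_freqs)) minor_allele_frequency(case_freqs) else NA_real_
  maf_control <- if (length(control_freqs)) minor_allele_frequency(control_freqs) else NA_real_
  binned <- character()
  if (length(case_freqs) && !is.na(maf_case) && maf_case < threshold) {
    binned <- c(binned, setdiff(names(case_freqs), major_allele(case_freqs)))
  }
  if (length(control_freqs) && !is.na(maf_control) && maf_control < threshold) {
    binned <- c(binned, setdiff(names(control_freqs), major_allele(control_freqs)))
  }
  binned <- sort(unique(binned))
  list(rare = length(binned) > 0L, maf_case = maf_case,
       maf_control = maf_control, binned_alleles = binned)
}

#' Rarity calls for every locus of a frequency table
#'
#' Applies [classify_rarity()] locus by locus. Loci monomorphic across both
#' groups combined (a single distinct observed allele) are excluded before
#' binning: they carry no minor allele to count.
#'
#' @param gft A `group_freq_table` from [group_allele_frequencies()].
#' @param threshold MAF threshold (strict `<`).
#' @return A `rarity_calls` data.frame: one row per locus with `locus`
#'   (index), `chrom`, `pos`, `maf_case`, `maf_control`, `rare`, and
#'   list-column `binned` of binned allele symbols.
#' @export
rarity_calls <- function(gft, threshold) {
  n <- nrow(gft$loci)
  maf_case <- maf_control <- rep(NA_real_, n)
  rare <- logical(n)
  binned <- vector("list", n)
  for (i in seq_len(n)) {
    fc <- locus_freqs(gft, i, "case")
    fk <- locus_freqs(gft, i, "control")
    binned[[i]] <- character()
    # distinct alleles observed anywhere (monomorphic-in-both exclusion)
    obs <- unique(c(names(fc)[fc > 0], names(fk)[fk > 0]))
    if (length(obs) <= 1L) {
      if (length(fc)) maf_case[i] <- minor_allele_frequency(fc)
      if (length(fk)) maf_control[i] <- minor_allele_frequency(fk)
      next
    }
    cl <- classify_rarity(fc, fk, threshold)
    maf_case[i] <- cl$maf_case
    maf_control[i] <- cl$maf_control
    rare[i] <- cl$rare
    binned[[i]] <- cl$binned_alleles
  }
  out <- data.frame(locus = seq_len(n), chrom = gft$loci$chrom,
                    pos = gft$loci$pos, maf_case = maf_case,
                    maf_control = maf_control, rare = rare,
                    stringsAsFactors = FALSE)
  out$binned <- binned
  class(out) <- c("rarity_calls", "data.frame")
  out
}

new_bin <- function(bin_id, feature_type, coords, provenance = integer()) {
  coords <- coords[order(coords$chrom, coords$pos), , drop = FALSE]
  coords <- coords[!duplicated(coords[c("chrom", "pos")]), , drop = FALSE]
  structure(list(bin_id = bin_id, feature_type = feature_type,
                 loci = coords$locus, coords = coords, provenance = provenance),
            class = "bin_definition")
}

#' @export
print.bin_definition <- function(x, ...) {
  cat(sprintf("<bin> %s [%s] %d loci\n", x$bin_id, x$feature_type, length(x$loci)))
  invisible(x)
}

intergenic_bin_id <- function(chrom, pos, window) {
  k <- (pos - 1) %/% window # 0-based window index
  pre <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  sprintf("%s:window_%d", pre, k + 1)
}

#' Build feature bins from rare loci and a knowledge base
#'
#' Constructs the requested feature bins:
#' * **gene**: one bin per gene region containing at least one rare locus
#'   within its (inclusive) boundaries. Overlapping genes each get the locus.
#' * **pathway**: one bin per knowledge-base group; its loci are the
#'   deduplicated union of the member genes' rare loci.
#' * **intergenic**: each chromosome is tiled from position 1 into fixed
#'   windows of `intergenic_window` bp; a window is emitted only when it
#'   holds a rare locus assigned to *no* emitted gene/pathway bin, so the
#'   tiling catches exactly the variants the requested features miss.
#'
#' Empty bins are never emitted. Bin order is deterministic: feature type
#' (gene, pathway, intergenic), then genomic position, then label.
#'
#' @param rarity A `rarity_calls` table.
#' @param kb A `knowledge_base` (required for gene/pathway features).
#' @param config A `binning_config`.
#' @return List of `bin_definition` objects.
#' @export
build_feature_bins <- function(rarity, kb, config) {
  stopifnot(inherits(config, "binning_config"))
  feats <- config$feature_types
  rl <- rarity[rarity$rare, , drop = FALSE]
  bins <- list()
  assigned <- rep(FALSE, nrow(rl))
  coords <- data.frame(locus = rl$locus, chrom = rl$chrom, pos = rl$pos,
                       stringsAsFactors = FALSE)
  gene_assign <- NULL
  if (any(c("gene", "pathway") %in% feats)) {
    if (is.null(kb)) stop("gene/pathway features require a knowledge base")
    gene_assign <- kb_assign_loci(kb, rl$chrom, rl$pos, "gene")
  }
  if ("gene" %in% feats && !is.null(gene_assign) && nrow(gene_assign)) {
    for (rid in unique(gene_assign$region_id)) {
      li <- gene_assign$locus_idx[gene_assign$region_id == rid]
      reg <- kb$regions[kb$regions$region_id == rid, ]
      bins[[length(bins) + 1L]] <-
        new_bin(reg$label, "gene", coords[li, , drop = FALSE], provenance = rid)
      assigned[li] <- TRUE
    }
  }
  if ("pathway" %in% feats) {
    if (!nrow(kb$groups)) stop("pathway feature requested but no groups loaded")
    for (gi in seq_len(nrow(kb$groups))) {
      gid <- kb$groups$group_id[gi]
      members <- kb$group_members$region_id[kb$group_members$group_id == gid]
      li <- unique(gene_assign$locus_idx[gene_assign$region_id %in% members])
      if (!length(li)) next
      bins[[length(bins) + 1L]] <-
        new_bin(kb$groups$label[gi], "pathway", coords[li, , drop = FALSE],
                provenance = gid)
      assigned[li] <- TRUE
    }
  }
  if ("intergenic" %in% feats) {
    left <- which(!assigned)
    if (length(left)) {
      wid <- intergenic_bin_id(rl$chrom[left], rl$pos[left], config$intergenic_window)
      for (w in unique(wid)) {
        li <- left[wid == w]
        bins[[length(bins) + 1L]] <-
          new_bin(w, "intergenic", coords[li, , drop = FALSE])
      }
    }
  }
  sort_bins(bins)
}

sort_bins <- function(bins) {
  if (!length(bins)) return(bins)
  ft <- match(vapply(bins, `[[`, "", "feature_type"),
              c("gene", "pathway", "intergenic"))
  chrom <- vapply(bins, function(b) b$coords$chrom[1], "")
  pos <- vapply(bins, function(b) b$coords$pos[1], numeric(1))
  id <- vapply(bins, `[[`, "", "bin_id")
  bins[order(ft, chrom, pos, id)]
}

#' Split bins into exon and intron sub-bins
#'
#' Replaces each gene or pathway bin by up to two bins suffixed `"_exon"`
#' and `"_intron"`. A locus is exonic iff it lies inside any exon region of
#' the bin's own gene(s) (exon regions are matched to genes by label); all
#' other loci of the bin are intronic. Empty halves are dropped.
#' `filter = "exon"` or `"intron"` retains only that half. Intergenic bins
#' have no parent gene and pass through unchanged.
#'
#' @param bins List of `bin_definition`s.
#' @param kb A `knowledge_base` holding exon regions.
#' @param filter `"exon"`, `"intron"` or `"both"`.
#' @return List of `bin_definition`s.
#' @export
apply_subfeature_filter <- function(bins, kb, filter = c("both", "exon", "intron")) {
  filter <- match.arg(filter)
  exons <- kb$regions[kb$regions$region_type == "exon", , drop = FALSE]
  if (!nrow(exons)) stop("sub-feature filter requested but no exon regions loaded")
  out <- list()
  for (b in bins) {
    if (b$feature_type == "intergenic") {
      out[[length(out) + 1L]] <- b
      next
    }
    genes <- kb$regions[kb$regions$region_id %in% b$provenance, , drop = FALSE]
    ex <- exons[exons$label %in% genes$label, , drop = FALSE]
    exonic <- rep(FALSE, nrow(b$coords))
    for (i in seq_len(nrow(ex))) {
      exonic <- exonic | (b$coords$chrom == ex$chromosome[i] &
                            b$coords$pos >= ex$start[i] &
                            b$coords$pos <= ex$stop[i])
    }
    halves <- list(exon = which(exonic), intron = which(!exonic))
    for (h in names(halves)) {
      if (filter != "both" && filter != h) next
      li <- halves[[h]]
      if (!length(li)) next
      out[[length(out) + 1L]] <- new_bin(
        paste0(b$bin_id, "_", h), b$feature_type,
        b$coords[li, , drop = FALSE], provenance = b$provenance)
    }
  }
  sort_bins(out)
}

#' Split bins by functional-prediction category
#'
#' Each bin is split into one bin per prediction category present among its
#' loci, suffixed `"_<category>"`. Loci without a prediction record are
#' excluded from all split bins: only predicted variants enter the analysis
#' when prediction-based binning is in force.
#'
#' @param bins List of `bin_definition`s.
#' @param predictions data.frame with columns `chromosome`, `position`,
#'   `category` (an optional `score` column is ignored). A locus is keyed by
#'   chromosome:position.
#' @return List of `bin_definition`s.
#' @export
apply_prediction_split <- function(bins, predictions) {
  stopifnot(all(c("chromosome", "position", "category") %in% names(predictions)))
  key <- paste(predictions$chromosome, predictions$position, sep = ":")
  out <- list()
  for (b in bins) {
    bkey <- paste(b$coords$chrom, b$coords$pos, sep = ":")
    cat_ <- predictions$category[match(bkey, key)]
    for (cg in sort(unique(stats::na.omit(cat_)))) {
      li <- which(!is.na(cat_) & cat_ == cg)
      out[[length(out) + 1L]] <- new_bin(
        paste0(b$bin_id, "_", cg), b$feature_type,
        b$coords[li, , drop = FALSE], provenance = b$provenance)
    }
  }
  if (length(bins) && !length(out)) {
    stop(paste("prediction split removed every locus from every bin",
               "(no loci have prediction records); disable the split"))
  }
  sort_bins(out)
}

#' Read a functional-prediction table
#'
#' TSV with header columns chromosome, position, category (free text); an
#' optional score column is read but only logged.
#'
#' @param path Prediction table file.
#' @return data.frame with columns `chromosome`, `position`, `category`.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chromosome", "position", "category")
  if (!all(need %in% names(tab))) {
    stop("prediction table needs columns: chromosome, position, category")
  }
  if ("score" %in% names(tab)) {
    message(sprintf("prediction scores present (range %s-%s); categories drive the split",
                    min(tab$score), max(tab$score)))
  }
  tab$position <- as.integer(tab$position)
  tab[need]
}

#' Per-individual bin burden matrix
#'
#' For every bin and sample, the summed count (0, 1 or 2 per locus) of
#' *binned* alleles over the bin's member loci. Under the additive model a
#' heterozygote for one binned allele contributes 1, a homozygote 2, and a
#' genotype carrying two different binned alleles also contributes 2. Missing
#' calls contribute 0.
#'
#' @param bins List of `bin_definition`s (non-empty).
#' @param gm The `genotype_matrix` the rarity calls were computed from.
#' @param rarity The matching `rarity_calls` table.
#' @return A `bin_matrix`: list with `matrix` (bins x samples, dimnames set),
#'   `bins`, and `summary` data.frame (bin_id, feature_type, n_loci,
#'   total_variants).
#' @export
build_bin_matrix <- function(bins, gm, rarity) {
  if (!length(bins)) stop("no bins to tally")
  if (nrow(rarity) != n_loci(gm)) {
    stop("rarity calls and genotype matrix disagree on locus count")
  }
  used <- sort(unique(unlist(lapply(bins, `[[`, "loci"))))
  contrib <- matrix(0L, nrow = n_loci(gm), ncol = n_samples(gm))
  for (i in used) {
    codes <- match(rarity$binned[[i]], gm$loci$alleles[[i]])
    codes <- codes[!is.na(codes)]
    if (!length(codes)) next
    contrib[i, ] <- (gm$a1[i, ] %in% codes) + (gm$a2[i, ] %in% codes)
  }
  m <- matrix(0L, nrow = length(bins), ncol = n_samples(gm),
              dimnames = list(vapply(bins, `[[`, "", "bin_id"), gm$samples))
  for (j in seq_along(bins)) {
    li <- bins[[j]]$loci
    m[j, ] <- if (length(li) == 1L) contrib[li, ] else colSums(contrib[li, , drop = FALSE])
  }
  summary <- data.frame(
    bin_id = rownames(m),
    feature_type = vapply(bins, `[[`, "", "feature_type"),
    n_loci = vapply(bins, function(b) length(b$loci), integer(1)),
    total_variants = as.integer(rowSums(m)),
    stringsAsFactors = FALSE
  )
  structure(list(matrix = m, bins = bins, summary = summary),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d bins x %d samples, %d total variants\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$summary$total_variants)))
  invisible(x)
}
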