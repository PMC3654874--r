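#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x file (optionally bgzipped) into a compact genotype
#' matrix. Each VCF record becomes one locus; multiallelic records are kept
#' as a single polyallelic locus rather than being split into biallelic
#' records, because the rarity rule operates on the full allele set of a
#' locus. Missing genotypes (`./.`) are preserved as missing and excluded
#' from allele-frequency denominators; half-calls (`./1`) contribute one
#' observed allele and one missing allele. Phase separators `|` and `/` are
#' treated identically: burden counting is phase-free.
#'
#' @param path VCF file with GT genotype fields.
#' @return A `genotype_matrix`: list with `samples` (character),
#'   `loci` (data.frame chrom, pos, and list-column `alleles`, reference
#'   first), and integer matrices `a1`, `a2` (loci x samples) holding 1-based
#'   allele codes into each locus' allele list, `NA` for missing.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, 1, drop = TRUE]
  if (ncol(v@gt) < 2L) stop("VCF contains no sample genotype columns")
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE), function(x) "GT" %in% x, logical(1)))) {
    stop("VCF records without a GT field are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  n_loci <- nrow(gt)
  alleles <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    alt <- fix[i, "ALT"]
    alts <- if (is.na(alt) || alt == ".") character() else strsplit(alt, ",", fixed = TRUE)[[1]]
    alleles[[i]] <- unname(c(fix[i, "REF"], alts))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("malformed VCF record at %s:%s (unparseable POS)",
                 fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  parse_haps <- function(gt, which_hap) {
    # genotype strings -> allele index (0-based in VCF), NA for '.'
    h <- sub("^([^/|]*)[/|]?.*$", "\\1", gt)
    if (which_hap == 2L) {
      h <- ifelse(grepl("[/|]", gt), sub("^[^/|]*[/|]", "", gt), NA_character_)
      h <- sub("[/|].*$", "", h) # guard against >diploid calls: keep first two
    }
    h[h == "." | h == "" | is.na(h)] <- NA_character_
    idx <- suppressWarnings(as.integer(h))
    matrix(idx + 1L, nrow = nrow(gt), ncol = ncol(gt))
  }
  gt[is.na(gt)] <- "."
  a1 <- parse_haps(gt, 1L)
  a2 <- parse_haps(gt, 2L)
  n_alleles <- lengths(alleles)
  bad <- which(a1 > n_alleles[row(a1)] | a2 > n_alleles[row(a2)])
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% n_loci) + 1L
    stop(sprintf("malformed VCF record at %s:%d (allele index out of range)",
                 fix[i, "CHROM"], pos[i]))
  }
  loci <- data.frame(chrom = fix[, "CHROM"], pos = pos, stringsAsFactors = FALSE)
  loci$alleles <- alleles
  new_genotype_matrix(samples, loci, a1, a2)
}

new_genotype_matrix <- function(samples, loci, a1, a2) {
  stopifnot(nrow(a1) == nrow(loci), ncol(a1) == length(samples),
            all(dim(a1) == dim(a2)), all(loci$pos >= 1))
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d loci x %d samples\n", nrow(x$loci), length(x$samples)))
  invisible(x)
}

#' Number of loci / samples in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' @rdname n_loci
#' @export
n_samples <- function(gm) length(gm$samples)

#' Read a case/control phenotype table
#'
#' Expects a two-column header table (TSV or CSV, detected from the header
#' line's separator) mapping sample id to status. Status vocabulary: `0` /
#' `control` are controls, `1` / `case` are cases (case-insensitive for the
#' words). Any other status is an error naming the offending row.
#'
#' @param path Phenotype table file.
#' @return A `phenotype_assignment`: named factor (levels control, case)
#'   indexed by sample id.
#' @export
read_phenotypes <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("phenotype table needs sample and status columns")
  status <- tolower(trimws(tab[[2]]))
  ok <- status %in% c("0", "1", "case", "control")
  if (any(!ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("row %d (sample '%s'): status '%s' not in {0,1,case,control}",
                 bad, tab[[1]][bad], tab[[2]][bad]))
  }
  grp <- ifelse(status %in% c("1", "case"), "case", "control")
  phenotype_assignment(stats::setNames(grp, tab[[1]]))
}

#' Construct a phenotype assignment
#'
#' @param x Named character vector (names = sample ids, values `"case"` or
#'   `"control"`).
#' @return A `phenotype_assignment` (named factor, levels control then case).
#' @export
phenotype_assignment <- function(x) {
  stopifnot(!is.null(names(x)), all(x %in% c("case", "control")))
  if (anyDuplicated(names(x))) stop("duplicate sample ids in phenotype assignment")
  structure(factor(x, levels = c("control", "case")),
            names = names(x), class = c("phenotype_assignment", "factor"))
}

# Align a phenotype assignment with a genotype matrix: VCF samples missing
# from the table are dropped with a warning; table samples missing from the
# VCF are reported and ignored. Both groups must stay non-empty.
align_phenotypes <- function(gm, phen) {
  extra <- setdiff(names(phen), gm$samples)
  if (length(extra)) {
    message(sprintf("%d phenotyped sample(s) absent from genotypes ignored: %s",
                    length(extra), paste(extra, collapse = ", ")))
  }
  missing <- setdiff(gm$samples, names(phen))
  if (length(missing)) {
    warning(sprintf("%d genotyped sample(s) without phenotype dropped: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  keep <- intersect(gm$samples, names(phen))
  out <- phen[keep]
  if (!all(c("case", "control") %in% out)) {
    stop("two-group analysis requires both a non-empty case and control group")
  }
  out
}

#' Per-group allele frequencies at every locus
#'
#' For each locus and phenotype group, the frequency of each allele among the
#' *observed* (non-missing) alleles of that group's samples. Missing calls do
#' not enter the denominator. A locus with no observed alleles in a group has
#' an all-`NA` frequency record for that group.
#'
#' @param gm A `genotype_matrix`.
#' @param phen A `phenotype_assignment`; samples are aligned with the
#'   genotype matrix (mismatches warned/dropped as described in
#'   [read_phenotypes()]).
#' @return A `group_freq_table`: list with `loci`, group names, and per group
#'   a count matrix and a frequency matrix (loci x max allele count; `NA`
#'   columns beyond a locus' allele list).
#' @export
group_allele_frequencies <- function(gm, phen) {
  phen <- align_phenotypes(gm, phen)
  kmax <- max(lengths(gm$loci$alleles))
  n_alleles <- lengths(gm$loci$alleles)
  res <- list(loci = gm$loci, groups = c("control", "case"),
              counts = list(), freqs = list())
  for (g in res$groups) {
    cols <- which(gm$samples %in% names(phen)[phen == g])
    cnt <- matrix(0L, nrow = nrow(gm$loci), ncol = kmax)
    for (a in seq_len(kmax)) {
      cnt[, a] <- rowSums(gm$a1[, cols, drop = FALSE] == a, na.rm = TRUE) +
        rowSums(gm$a2[, cols, drop = FALSE] == a, na.rm = TRUE)
    }
    cnt[col(cnt) > n_alleles] <- NA_integer_
    tot <- rowSums(cnt, na.rm = TRUE)
    frq <- cnt / ifelse(tot > 0, tot, NA_real_)
    res$counts[[g]] <- cnt
    res$freqs[[g]] <- frq
  }
  structure(res, class = "group_freq_table")
}

#' @export
print.group_freq_table <- function(x, ...) {
  cat(sprintf("<group_freq_table> %d loci, groups: %s\n",
              nrow(x$loci), paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Named allele-frequency vector for one locus and group
#'
#' @param gft A `group_freq_table`.
#' @param locus Locus index (row of the locus table).
#' @param group `"case"` or `"control"`.
#' @return Named numeric vector over the locus' full allele list (alleles
#'   with zero observed copies keep an explicit 0, so that an allele absent
#'   from one group but present in the other is still visible as non-major
#'   there); length zero if the locus is entirely unobserved in the group.
#' @export
locus_freqs <- function(gft, locus, group) {
  al <- gft$loci$alleles[[locus]]
  f <- gft$freqs[[group]][locus, seq_along(al)]
  names(f) <- al
  if (all(is.na(f))) return(stats::setNames(numeric(0), character(0)))
  f
}
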