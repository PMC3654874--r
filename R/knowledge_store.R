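#' Create an empty knowledge base
#'
#' A knowledge base standardizes biological knowledge into two concepts used
#' for bin construction: *regions* (genomic segments with a start and stop
#' position, e.g. genes or exons) and *groups* (named collections of regions,
#' e.g. pathways). The store lives in memory as plain tables and can be
#' persisted to / reopened from a single SQLite file with [kb_save()] and
#' [kb_open()], so no database server or network connection is ever needed.
#'
#' Coordinates are stored 1-based and inclusive on both ends. Strand is
#' ignored throughout: bin assignment is purely positional. Overlapping
#' regions are permitted; a position inside two genes belongs to both.
#'
#' @param genome_build Free-text genome build tag recorded with the store.
#' @return An object of class `knowledge_base` (an environment).
#' @export
#' @examples
#' kb <- kb_new()
#' tf <- tempfile()
#' writeLines(c("1\t1000\t2000\tGENE_A", "1\t5000\t9000\tGENE_B"), tf)
#' kb_load_regions(kb, tf, region_type = "gene")
#' kb_regions_containing(kb, "1", 1500)
kb_new <- function(genome_build = "synthetic") {
  kb <- new.env(parent = emptyenv())
  kb$regions <- data.frame(
    region_id = integer(), label = character(), chromosome = character(),
    start = integer(), stop = integer(), region_type = character(),
    source = character(), stringsAsFactors = FALSE
  )
  kb$groups <- data.frame(
    group_id = integer(), label = character(), source = character(),
    stringsAsFactors = FALSE
  )
  kb$group_members <- data.frame(
    group_id = integer(), region_id = integer(), stringsAsFactors = FALSE
  )
  kb$genome_build <- genome_build
  kb$next_region_id <- 1L
  kb$next_group_id <- 1L
  class(kb) <- "knowledge_base"
  kb
}

REGION_TYPES <- c("gene", "exon", "intron", "regulatory", "ECR", "other")

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(
    "<knowledge_base> build=%s | %d regions (%s) | %d groups | sources: %s\n",
    x$genome_build, nrow(x$regions),
    paste(names(table(x$regions$region_type)), collapse = ","),
    nrow(x$groups),
    paste(kb_sources(x), collapse = ",")
  ))
  invisible(x)
}

#' List knowledge sources present in a store
#' @param kb A `knowledge_base`.
#' @return Character vector of source names.
#' @export
kb_sources <- function(kb) {
  sort(unique(c(kb$regions$source, kb$groups$source)))
}

#' Region and group tables of a knowledge base
#'
#' @param kb A `knowledge_base`.
#' @return `kb_regions()`: the region table (one row per region);
#'   `kb_groups()`: the group table; `kb_group_members()`: the
#'   (group_id, region_id) membership table.
#' @export
kb_regions <- function(kb) kb$regions

#' @rdname kb_regions
#' @export
kb_groups <- function(kb) kb$groups

#' @rdname kb_regions
#' @export
kb_group_members <- function(kb) kb$group_members

#' Load a region table into the knowledge base
#'
#' Two dialects are supported and always chosen explicitly, never sniffed:
#' `"tsv"` is 1-based inclusive with columns chrom, start, stop, label
#' (tab-separated, no header); `"bed"` is standard BED (0-based half-open,
#' columns chrom, chromStart, chromEnd, name) and is converted to the 1-based
#' inclusive internal convention on load.
#'
#' Rows that cannot be parsed, or whose start exceeds their stop, are rejected
#' individually with a warning naming the line number; remaining rows still
#' load. Duplicate (label, type, coordinates) records collapse to one region,
#' so reloading the same file is idempotent.
#'
#' @param kb A `knowledge_base`.
#' @param path Region table file.
#' @param region_type One of `"gene"`, `"exon"`, `"intron"`, `"regulatory"`,
#'   `"ECR"`, `"other"`.
#' @param format `"tsv"` (1-based inclusive) or `"bed"` (0-based half-open).
#' @param source Source name recorded with each region.
#' @return Invisibly, the number of distinct new regions stored.
#' @export
kb_load_regions <- function(kb, path, region_type = "gene",
                            format = c("tsv", "bed"), source = "user") {
  stopifnot(inherits(kb, "knowledge_base"))
  format <- match.arg(format)
  region_type <- match.arg(region_type, REGION_TYPES)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  added <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      warning(sprintf("line %d: expected >= 4 tab-separated fields, got %d; row skipped",
                      i, length(f)))
      next
    }
    start <- suppressWarnings(as.integer(f[[2]]))
    stop_ <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(start) || is.na(stop_)) {
      warning(sprintf("line %d: non-integer coordinates '%s'/'%s'; row skipped",
                      i, f[[2]], f[[3]]))
      next
    }
    if (format == "bed") { # 0-based half-open -> 1-based inclusive
      start <- start + 1L
    }
    if (start > stop_) {
      warning(sprintf("line %d: start %d > stop %d; row skipped", i, start, stop_))
      next
    }
    if (start < 1L) {
      warning(sprintf("line %d: start %d < 1; row skipped", i, start))
      next
    }
    recs[[i]] <- data.frame(label = f[[4]], chromosome = f[[1]],
                            start = start, stop = stop_,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs)) {
    new <- do.call(rbind, recs)
    new <- unique(new)
    key <- function(d) paste(d$label, region_type, d$chromosome, d$start, d$stop)
    old <- kb$regions[kb$regions$region_type == region_type &
                        kb$regions$source == source, ]
    new <- new[!(key(new) %in% key(old)), , drop = FALSE]
    if (nrow(new)) {
      ids <- seq.int(kb$next_region_id, length.out = nrow(new))
      kb$next_region_id <- kb$next_region_id + nrow(new)
      kb$regions <- rbind(kb$regions, data.frame(
        region_id = ids, label = new$label, chromosome = new$chromosome,
        start = new$start, stop = new$stop, region_type = region_type,
        source = source, stringsAsFactors = FALSE
      ))
      added <- nrow(new)
    }
  }
  invisible(added)
}

#' Load a GMT gene-set file as groups
#'
#' GMT records are tab-separated: group label, description, then one or more
#' member labels. Member labels are resolved against stored gene regions by
#' exact label match; unresolvable members are skipped with a warning, and a
#' group whose members all fail to resolve is not stored. A duplicate group
#' label from the same source replaces the previous definition with a warning.
#'
#' @param kb A `knowledge_base`.
#' @param path GMT file.
#' @param source Source name recorded with each group.
#' @return Invisibly, the number of groups stored.
#' @export
kb_load_groups <- function(kb, path, source = "user") {
  stopifnot(inherits(kb, "knowledge_base"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty group file: no groups loaded")
    return(invisible(0L))
  }
  genes <- kb$regions[kb$regions$region_type == "gene", ]
  added <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      warning(sprintf("line %d: GMT record needs label, description and >= 1 member; skipped", i))
      next
    }
    label <- f[[1]]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    hit <- members %in% genes$label
    if (any(!hit)) {
      warning(sprintf("group '%s': unresolved member label(s) %s skipped",
                      label, paste(sQuote(members[!hit]), collapse = ", ")))
    }
    member_ids <- genes$region_id[genes$label %in% members[hit]]
    if (!length(member_ids)) next
    dup <- kb$groups$group_id[kb$groups$label == label & kb$groups$source == source]
    if (length(dup)) {
      warning(sprintf("group '%s' from source '%s' already present: replaced", label, source))
      kb$groups <- kb$groups[!kb$groups$group_id %in% dup, ]
      kb$group_members <- kb$group_members[!kb$group_members$group_id %in% dup, ]
      added <- added - 1L
    }
    gid <- kb$next_group_id
    kb$next_group_id <- kb$next_group_id + 1L
    kb$groups <- rbind(kb$groups, data.frame(
      group_id = gid, label = label, source = source, stringsAsFactors = FALSE))
    kb$group_members <- rbind(kb$group_members, data.frame(
      group_id = gid, region_id = sort(member_ids)))
    added <- added + 1L
  }
  invisible(added)
}

#' Regions containing a genomic position
#'
#' Returns exactly the stored regions whose closed interval \[start, stop\]
#' contains the query position on the same chromosome (both endpoints
#' inclusive), optionally restricted to one region type. An unknown
#' chromosome yields an empty table, not an error.
#'
#' @param kb A `knowledge_base`.
#' @param chromosome Chromosome name (exact string match).
#' @param position 1-based position.
#' @param region_type Optional type filter.
#' @return A region table subset (possibly empty).
#' @export
kb_regions_containing <- function(kb, chromosome, position, region_type = NULL) {
  stopifnot(inherits(kb, "knowledge_base"), position >= 1)
  r <- kb$regions
  if (!is.null(region_type)) r <- r[r$region_type == region_type, , drop = FALSE]
  r <- r[r$chromosome == chromosome, , drop = FALSE]
  if (!nrow(r)) return(r)
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(start = r$start, end = r$stop),
    IRanges::IRanges(start = as.integer(position), width = 1L)
  )
  r[hits, , drop = FALSE]
}

# Vectorized locus -> region assignment used by the binning engine.
# Returns a data.frame (locus_idx, region_id) for all containments.
kb_assign_loci <- function(kb, chrom, pos, region_type) {
  r <- kb$regions[kb$regions$region_type == region_type, , drop = FALSE]
  out <- data.frame(locus_idx = integer(), region_id = integer())
  if (!nrow(r) || !length(pos)) return(out)
  for (ch in unique(chrom)) {
    ri <- which(r$chromosome == ch)
    li <- which(chrom == ch)
    if (!length(ri) || !length(li)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = as.integer(pos[li]), width = 1L),
      IRanges::IRanges(start = r$start[ri], end = r$stop[ri])
    )
    if (length(ov)) {
      out <- rbind(out, data.frame(
        locus_idx = li[S4Vectors::queryHits(ov)],
        region_id = r$region_id[ri[S4Vectors::subjectHits(ov)]]
      ))
    }
  }
  out
}

#' Groups containing a region
#'
#' @param kb A `knowledge_base`.
#' @param region_id A stored region identifier.
#' @return Group table subset for all groups whose member set contains the
#'   region; empty when the region belongs to no group.
#' @export
kb_groups_of <- function(kb, region_id) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!region_id %in% kb$regions$region_id) {
    stop(sprintf("unknown region_id %s: no such knowledge record", region_id))
  }
  gids <- kb$group_members$group_id[kb$group_members$region_id == region_id]
  kb$groups[kb$groups$group_id %in% gids, , drop = FALSE]
}

KB_SCHEMA_VERSION <- "1"

#' Persist a knowledge base to a single SQLite file
#'
#' @param kb A `knowledge_base`.
#' @param path Output file; must not exist unless `force = TRUE`.
#' @param force Overwrite an existing store file.
#' @return Invisibly, `path`.
#' @export
kb_save <- function(kb, path, force = FALSE) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (file.exists(path) && !force) {
    stop(sprintf("store file '%s' already exists (use force = TRUE to overwrite)", path))
  }
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "meta", data.frame(
    key = c("schema_version", "genome_build"),
    value = c(KB_SCHEMA_VERSION, kb$genome_build)))
  DBI::dbWriteTable(con, "regions", kb$regions)
  DBI::dbWriteTable(con, "groups", kb$groups)
  DBI::dbWriteTable(con, "group_members", kb$group_members)
  invisible(path)
}

#' Reopen a knowledge base from a SQLite store file
#'
#' @param path File written by [kb_save()].
#' @return A `knowledge_base`.
#' @export
kb_open <- function(path) {
  if (!file.exists(path)) stop(sprintf("no store file at '%s'", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbReadTable(con, "meta")
  kb <- kb_new(genome_build = meta$value[meta$key == "genome_build"])
  kb$regions <- DBI::dbReadTable(con, "regions")
  kb$groups <- DBI::dbReadTable(con, "groups")
  kb$group_members <- DBI::dbReadTable(con, "group_members")
  kb$next_region_id <- if (nrow(kb$regions)) max(kb$regions$region_id) + 1L else 1L
  kb$next_group_id <- if (nrow(kb$groups)) max(kb$groups$group_id) + 1L else 1L
  kb_validate(kb)
  kb
}

# Referential integrity + coordinate invariants; stops on violation.
kb_validate <- function(kb) {
  if (nrow(kb$regions)) {
    stopifnot(all(kb$regions$start <= kb$regions$stop),
              all(nzchar(kb$regions$chromosome)))
  }
  if (nrow(kb$group_members)) {
    dangling <- setdiff(kb$group_members$region_id, kb$regions$region_id)
    if (length(dangling)) {
      stop(sprintf("knowledge store integrity violation: dangling region ids %s",
                   paste(dangling, collapse = ",")))
    }
  }
  invisible(TRUE)
}
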