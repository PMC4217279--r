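#' Read mappings from a SAM or BAM file
#'
#' Imports all mapped alignment records into a tibble, one row per mapping.
#' Unmapped records are skipped. The per-mapping edit distance is taken from
#' the standard NM tag when present; when absent and a reference genome is
#' supplied it is recomputed from CIGAR and sequence, otherwise it is left
#' `NA` (and [compute_read_stats()] will refuse to work with it).
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param genome optional [ref_genome()] used to recompute missing edit
#'   distances.
#' @return tibble with one row per mapping: `read_name`, `mate` (1 or 2),
#'   `flag`, `contig`, `start`, `stop`, `strand`, `cigar`, `seq`,
#'   `mismatches`, plus classification tags (`class`, `mapping_count`,
#'   `single_best_match`) when present in the file.
#' @export
read_mappings <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"),
      tag = c("NM", "Yc", "Yn", "Ys")))[[1]]
  keep <- !is.na(res$pos)
  if (!any(keep)) {
    return(tibble(read_name = character(), mate = integer(),
                  flag = integer(), contig = character(), start = integer(),
                  stop = integer(), strand = character(), cigar = character(),
                  seq = character(), mismatches = integer()))
  }
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  tag_or <- function(nm, default) {
    v <- res$tag[[nm]]
    if (is.null(v)) rep(default, sum(keep)) else v[keep]
  }
  out <- tibble(
    read_name = res$qname[keep],
    mate = ifelse(bitwAnd(res$flag[keep], 128L) > 0L, 2L, 1L),
    flag = res$flag[keep],
    contig = as.character(res$rname[keep]),
    start = res$pos[keep],
    stop = res$pos[keep] + width - 1L,
    strand = ifelse(as.character(res$strand[keep]) == "-", "-", "+"),
    cigar = res$cigar[keep],
    seq = as.character(res$seq[keep]),
    mismatches = as.integer(tag_or("NM", NA_integer_)))
  if (!is.null(res$tag$Yc)) {
    out$class <- factor(c(P = "PERFECT", B = "BEST", C = "COMMON")[
      tag_or("Yc", NA_character_)], levels = MAPPING_CLASSES)
    out$mapping_count <- as.integer(tag_or("Yn", NA_integer_))
    out$single_best_match <- as.integer(tag_or("Ys", 0L)) == 1L
  }
  if (any(is.na(out$mismatches)) && !is.null(genome)) {
    out <- recompute_edit_distance(out, genome)
  }
  out
}

recompute_edit_distance <- function(mappings, genome) {
  todo <- which(is.na(mappings$mismatches))
  if (length(todo) == 0) return(mappings)
  nm <- vapply(todo, function(i) {
    row <- mappings[i, ]
    if (is.na(row$seq) || row$seq == "*") return(NA_integer_)
    walk <- walk_alignment(row$seq, row$cigar, row$start,
                           ref_seq(genome, row$contig))
    walk$edit_distance
  }, integer(1))
  mappings$mismatches[todo] <- nm
  mappings
}

# Decompose one alignment against the reference. Returns the per-base
# substitutions, insertion events (anchored to the reference base preceding
# the inserted sequence), deletion events (keyed by first deleted base), the
# reference positions covered by aligned (M) bases, and the edit distance.
walk_alignment <- function(seq, cigar, start, refseq) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  rpos <- start
  qpos <- 1L
  subs_pos <- integer(); subs_ref <- character(); subs_alt <- character()
  ins <- list(); del <- list()
  m_start <- integer(); m_end <- integer()
  ed <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      rb <- strsplit(substring(refseq, rpos, rpos + len - 1L), "")[[1]]
      qb <- strsplit(substring(seq, qpos, qpos + len - 1L), "")[[1]]
      diff <- which(rb != qb)
      ed <- ed + length(diff)
      if (length(diff)) {
        subs_pos <- c(subs_pos, rpos + diff - 1L)
        subs_ref <- c(subs_ref, rb[diff])
        subs_alt <- c(subs_alt, qb[diff])
      }
      m_start <- c(m_start, rpos); m_end <- c(m_end, rpos + len - 1L)
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      ins[[length(ins) + 1L]] <- list(pos = rpos - 1L,
        alt = substring(seq, qpos, qpos + len - 1L))
      ed <- ed + len
      qpos <- qpos + len
    } else if (op == "D") {
      del[[length(del) + 1L]] <- list(pos = rpos,
        ref = substring(refseq, rpos, rpos + len - 1L))
      ed <- ed + len
      rpos <- rpos + len
    } else if (op == "N") {
      rpos <- rpos + len
    } else if (op %in% c("S")) {
      qpos <- qpos + len
    } # H/P consume nothing tracked here
  }
  list(substitutions = tibble(position = subs_pos, ref = subs_ref,
                              alt = subs_alt),
       insertions = ins, deletions = del,
       aligned = tibble(start = m_start, end = m_end),
       edit_distance = ed)
}

sam_header <- function(genome, sorted = TRUE) {
  c(sprintf("@HD\tVN:1.6\tSO:%s",
            if (sorted) "coordinate" else "unsorted"),
    sprintf("@SQ\tSN:%s\tLN:%d", genome$contigs$contig,
            genome$contigs$length))
}

#' Write a classified track as an indexed BAM
#'
#' Persists classified mappings to a coordinate-sorted, indexed BAM carrying
#' three custom tags so the classification round-trips without
#' recomputation: `Yc` (class, one character `P`/`B`/`C`), `Yn` (the read's
#' mapping count) and `Ys` (single-best-match flag, 0/1). The standard `NM`
#' tag carries the edit distance.
#'
#' @param classified tibble from [classify_mappings()].
#' @param path output BAM path (`.bam`).
#' @param genome [ref_genome()] supplying contig names and lengths for the
#'   header.
#' @return the BAM path, invisibly.
#' @export
write_track <- function(classified, path, genome) {
  stopifnot(all(c("class", "mapping_count", "single_best_match") %in%
                  names(classified)))
  m <- arrange(classified, .data$contig, .data$start)
  seqs <- ifelse(is.na(m$seq) | m$seq == "", "*", m$seq)
  lines <- paste(
    m$read_name, m$flag, m$contig, m$start, 255L, m$cigar, "*", 0L, 0L,
    seqs, "*",
    paste0("NM:i:", m$mismatches),
    paste0("Yc:A:", substr(as.character(m$class), 1, 1)),
    paste0("Yn:i:", m$mapping_count),
    paste0("Ys:i:", as.integer(m$single_best_match)),
    sep = "\t")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(sam_header(genome), lines), sam)
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::sortBam(tmp, dest)
  Rsamtools::indexBam(paste0(dest, ".bam"))
  invisible(paste0(dest, ".bam"))
}

#' Re-open a classified track
#'
#' Reads a BAM written by [write_track()] back into a classified mapping
#' tibble; the stored tags are used as-is, no reclassification happens.
#'
#' @param path BAM file with classification tags.
#' @return classified mapping tibble.
#' @export
read_track <- function(path) {
  out <- read_mappings(path)
  if (!"class" %in% names(out)) {
    stop(path, " carries no classification tags; run classify_mappings() ",
         "and write_track() first")
  }
  out
}
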