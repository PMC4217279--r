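# Features eligible for operon detection: protein-coding sequences or RNAs.
# When both a gene and a CDS cover the same locus, the gene rows are used.
operon_features <- function(genome, contig) {
  f <- genome$features[genome$features$contig == contig, , drop = FALSE]
  if (any(f$type == "gene")) f <- f[f$type == "gene", , drop = FALSE]
  else f <- f[f$type %in% c("CDS", "rRNA", "tRNA", "ncRNA", "misc_RNA"),
              , drop = FALSE]
  arrange(f, .data$start)
}

#' Detect operons from spanning reads
#'
#' Two neighbouring same-strand genes are assigned to an operon when the
#' number of uniquely mapped reads (mapping count 1) overlapping at least
#' one base of each gene is strictly higher than `min_spanning_reads`.
#' Qualifying adjacent pairs are chained transitively into maximal operons.
#' When the intergenic gap is too large to be spanned by single reads
#' (wider than the track's median read length) and `use_gap_coverage` is
#' on, a pair alternatively qualifies when the minimum coverage in the gap
#' is strictly higher than `min_gap_coverage`.
#'
#' @param track classified mapping tibble.
#' @param genome [ref_genome()].
#' @param min_spanning_reads spanning-read threshold (strict `>`).
#' @param use_gap_coverage enable the gap-coverage fallback.
#' @param min_gap_coverage gap-coverage threshold (strict `>`).
#' @param class_filter mapping-class filter (cumulative).
#' @return tibble with one row per operon: `contig`, `strand`, `operon_id`,
#'   `n_genes`, `feature_ids` (list), `spanning_reads` (list, per adjacent
#'   pair), `gap_min_coverage` (list, per adjacent pair), `start`, `stop`.
#' @export
detect_operons <- function(track, genome, min_spanning_reads = 5,
                           use_gap_coverage = FALSE, min_gap_coverage = 0,
                           class_filter = "COMMON") {
  m_all <- filter_class(track, class_filter)
  out <- purrr::map_dfr(
    intersect(genome$contigs$contig, unique(m_all$contig)),
    function(ctg) {
      f <- operon_features(genome, ctg)
      if (nrow(f) < 2) return(NULL)
      m <- m_all[m_all$contig == ctg, , drop = FALSE]
      uni <- m[!is.na(m$mapping_count) & m$mapping_count == 1L, ,
               drop = FALSE]
      med_len <- if (nrow(m) > 0) median(m$stop - m$start + 1) else 0
      len <- contig_length(genome, ctg)
      cov <- coverage_vector(m, ctg, len)
      rd <- IRanges::IRanges(uni$start, uni$stop)
      pairs <- tibble(a = seq_len(nrow(f) - 1), b = seq_len(nrow(f) - 1) + 1)
      pairs <- pairs[f$strand[pairs$a] == f$strand[pairs$b], , drop = FALSE]
      if (nrow(pairs) == 0) return(NULL)
      qual <- purrr::pmap_dfr(pairs, function(a, b) {
        ov_a <- IRanges::overlapsAny(rd, IRanges::IRanges(f$start[a],
                                                          f$stop[a]))
        ov_b <- IRanges::overlapsAny(rd, IRanges::IRanges(f$start[b],
                                                          f$stop[b]))
        spanning <- sum(ov_a & ov_b)
        gap <- if (f$start[b] > f$stop[a] + 1) {
          min(cov[(f$stop[a] + 1):(f$start[b] - 1)])
        } else NA_integer_
        gap_width <- max(f$start[b] - f$stop[a] - 1, 0)
        ok <- spanning > min_spanning_reads ||
          (use_gap_coverage && gap_width > med_len && !is.na(gap) &&
             gap > min_gap_coverage)
        tibble(a = a, b = b, spanning_reads = spanning,
               gap_min_coverage = gap, qualifies = ok)
      })
      qual <- qual[qual$qualifies, , drop = FALSE]
      if (nrow(qual) == 0) return(NULL)
      # chain transitively: qualifying pairs sharing a gene merge
      g <- igraph::graph_from_edgelist(
        cbind(as.character(qual$a), as.character(qual$b)), directed = FALSE)
      comp <- igraph::components(g)$membership
      purrr::map_dfr(seq_len(max(comp)), function(k) {
        members <- sort(as.integer(names(comp)[comp == k]))
        pp <- qual[qual$a %in% members & qual$b %in% members, ]
        tibble(contig = ctg, strand = f$strand[members[1]],
               n_genes = length(members),
               feature_ids = list(f$feature_id[members]),
               spanning_reads = list(pp$spanning_reads),
               gap_min_coverage = list(pp$gap_min_coverage),
               start = min(f$start[members]), stop = max(f$stop[members]))
      })
    })
  if (nrow(out) == 0) {
    return(tibble(contig = character(), strand = character(),
                  operon_id = character(), n_genes = integer(),
                  feature_ids = list(), spanning_reads = list(),
                  gap_min_coverage = list(), start = integer(),
                  stop = integer()))
  }
  out <- arrange(out, .data$contig, .data$start)
  out$operon_id <- paste0("operon_", seq_len(nrow(out)))
  out[, c("contig", "strand", "operon_id", "n_genes", "feature_ids",
          "spanning_reads", "gap_min_coverage", "start", "stop")]
}
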