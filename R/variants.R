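aligned_coverage <- function(m, len, ops = c("M", "=", "X")) {
  if (nrow(m) == 0) return(integer(len))
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    m$cigar, pos = m$start, ops = ops)
  as.integer(IRanges::coverage(unlist(rl), width = len))
}

# Collect variant evidence from every mapping whose alignment differs from
# the reference (edit distance > 0).
collect_events <- function(m, refseq) {
  carriers <- which(m$mismatches > 0L)
  if (length(carriers) == 0) {
    return(tibble(position = integer(), type = character(),
                  ref = character(), alt = character(), strand = character()))
  }
  purrr::map_dfr(carriers, function(i) {
    w <- walk_alignment(m$seq[i], m$cigar[i], m$start[i], refseq)
    bind_rows(
      if (nrow(w$substitutions)) mutate(w$substitutions,
                                        type = "substitution"),
      bind_rows(lapply(w$insertions, function(e)
        tibble(position = e$pos, ref = "-", alt = e$alt,
               type = "insertion"))),
      bind_rows(lapply(w$deletions, function(e)
        tibble(position = e$pos, ref = e$ref, alt = "-",
               type = "deletion")))) |>
      mutate(strand = m$strand[i])
  })
}

#' Detect SNPs and DIPs from a classified track
#'
#' Pileup-based variant caller: at every position, each alternative allele
#' (substituted base, inserted sequence anchored to the base it follows, or
#' deletion keyed by its first deleted base) is counted over the mappings
#' admitted by `class_filter` (cumulative class semantics). An allele is
#' reported when both thresholds pass: its frequency -- `100 * count /
#' total` with `total` the eligible aligned coverage at the position
#' (deletion-spanning coverage for deletions) -- reaches
#' `min_variation_percent`, and its supporting read count reaches
#' `min_mismatch_count`. Read bases of N are excluded from numerator and
#' denominator.
#'
#' @param track classified mapping tibble.
#' @param genome matching [ref_genome()].
#' @param min_variation_percent minimum percent variation, in (0, 100].
#' @param min_mismatch_count minimum supporting reads.
#' @param class_filter mapping class filter (cumulative).
#' @param count_main_base when `FALSE`, alleles that form the position's
#'   majority call are suppressed.
#' @param annotate annotate location and coding effect via
#'   [annotate_effects()].
#' @param code [genetic_code()] used for effect annotation.
#' @return tibble with one row per passing (position, allele): `contig`,
#'   `position`, `type`, `ref`, `alt`, `count`, `total`, `frequency`,
#'   `fwd_count`, `rev_count`, plus annotation columns when `annotate`.
#' @export
detect_variants <- function(track, genome, min_variation_percent = 90,
                            min_mismatch_count = 5,
                            class_filter = "COMMON",
                            count_main_base = TRUE, annotate = TRUE,
                            code = genetic_code(11)) {
  stopifnot(min_variation_percent > 0, min_mismatch_count >= 1)
  if (!all(unique(track$contig) %in% genome$contigs$contig)) {
    stop("track contigs not present in reference")
  }
  m_all <- filter_class(track, class_filter)
  out <- purrr::map_dfr(unique(m_all$contig), function(ctg) {
    m <- m_all[m_all$contig == ctg, ]
    refseq <- ref_seq(genome, ctg)
    len <- contig_length(genome, ctg)
    cov_m <- aligned_coverage(m, len)
    cov_span <- aligned_coverage(m, len, ops = c("M", "=", "X", "D"))
    ev <- collect_events(m, refseq)
    if (nrow(ev) == 0) return(NULL)
    # N read bases drop out of both sides of the frequency
    n_mask <- ev$alt == "N" | ev$ref == "N"
    n_excl <- dplyr::count(ev[n_mask & ev$type == "substitution", ],
                           .data$position, name = "n_reads")
    ev <- ev[!n_mask, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    calls <- ev |>
      group_by(.data$position, .data$type, .data$ref, .data$alt) |>
      summarise(count = dplyr::n(),
                fwd_count = sum(.data$strand == "+"),
                rev_count = sum(.data$strand == "-"), .groups = "drop") |>
      left_join(n_excl, by = "position") |>
      mutate(
        total = ifelse(.data$type == "deletion",
                       cov_span[.data$position], cov_m[.data$position]) -
          dplyr::coalesce(.data$n_reads, 0L),
        frequency = 100 * .data$count / pmax(.data$total, 1L)) |>
      select(-"n_reads")
    if (!count_main_base) {
      calls <- filter(calls, .data$count <= .data$total - .data$count)
    }
    calls |>
      filter(.data$frequency >= min_variation_percent,
             .data$count >= min_mismatch_count) |>
      mutate(contig = ctg, .before = 1)
  })
  if (nrow(out) == 0) {
    out <- tibble(contig = character(), position = integer(),
                  type = character(), ref = character(), alt = character(),
                  count = integer(), fwd_count = integer(),
                  rev_count = integer(), total = integer(),
                  frequency = double())
  }
  out <- arrange(out, .data$contig, .data$position, .data$type, .data$alt)
  out <- out[, c("contig", "position", "type", "ref", "alt", "count",
                 "total", "frequency", "fwd_count", "rev_count")]
  if (annotate) out <- annotate_effects(out, genome, code) else out
}

#' Annotate variant location and coding effect
#'
#' Classifies each variant as intragenic (inside at least one annotated
#' feature) or intergenic, and for substitutions inside a CDS computes the
#' reference and alternative codon in the CDS reading frame (on the reverse
#' complement for minus-strand CDS) together with the encoded amino acids.
#' CDS features whose length is not a multiple of 3 are skipped with a
#' warning.
#'
#' @param variants tibble from [detect_variants()].
#' @param genome [ref_genome()].
#' @param code [genetic_code()].
#' @return `variants` with `location`, `feature_id`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa` columns added.
#' @export
annotate_effects <- function(variants, genome, code = genetic_code(11)) {
  f <- genome$features
  ann <- purrr::pmap_dfr(
    variants[, c("contig", "position", "type", "ref", "alt")],
    function(contig, position, type, ref, alt) {
      hits <- f[f$contig == contig & f$start <= position &
                  f$stop >= position, , drop = FALSE]
      loc <- if (nrow(hits) > 0) "intragenic" else "intergenic"
      # prefer the gene-level id for reporting, the CDS for the frame
      fid <- if (nrow(hits) > 0) {
        hits$feature_id[order(match(hits$type, c("gene", "CDS")),
                              na.last = TRUE)][1]
      } else NA_character_
      res <- tibble(location = loc, feature_id = fid,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_)
      cds <- hits[hits$type == "CDS", , drop = FALSE]
      if (type != "substitution" || nrow(cds) == 0) return(res)
      cds <- cds[1, ]
      if ((cds$stop - cds$start + 1L) %% 3L != 0L) {
        warning("CDS ", cds$feature_id, " length not divisible by 3; ",
                "effect not annotated")
        return(res)
      }
      refseq <- ref_seq(genome, contig)
      if (cds$strand == "+") {
        offset <- position - cds$start
        cstart <- cds$start + 3L * (offset %/% 3L)
        codon <- substring(refseq, cstart, cstart + 2L)
        within <- offset %% 3L + 1L
        alt_codon <- codon
        substring(alt_codon, within, within) <- alt
      } else {
        offset <- cds$stop - position
        cend <- cds$stop - 3L * (offset %/% 3L)
        codon <- reverse_complement(substring(refseq, cend - 2L, cend))
        within <- offset %% 3L + 1L
        alt_codon <- codon
        substring(alt_codon, within, within) <- reverse_complement(alt)
      }
      res$ref_codon <- codon
      res$alt_codon <- alt_codon
      res$ref_aa <- translate_codons(codon, code)
      res$alt_aa <- translate_codons(alt_codon, code)
      res
    })
  bind_cols(variants, ann)
}

#' Export variants
#'
#' `write_variants()` writes the full result table as TSV;
#' `write_variants_vcf()` writes a minimal VCF 4.2 with indels converted to
#' the anchored reference/alternative representation.
#'
#' @param variants tibble from [detect_variants()].
#' @param path output path.
#' @param genome [ref_genome()] (needed for VCF anchor bases and contig
#'   headers).
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' @rdname write_variants
#' @export
write_variants_vcf <- function(variants, genome, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$contigs$contig,
            genome$contigs$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Eligible coverage\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- purrr::pmap_chr(
    variants[, c("contig", "position", "type", "ref", "alt", "count",
                 "total", "frequency")],
    function(contig, position, type, ref, alt, count, total, frequency) {
      refseq <- ref_seq(genome, contig)
      if (type == "substitution") {
        pos <- position; vref <- ref; valt <- alt
      } else if (type == "insertion") {
        pos <- position
        anchor <- substring(refseq, position, position)
        vref <- anchor; valt <- paste0(anchor, alt)
      } else {
        pos <- position - 1L
        anchor <- substring(refseq, pos, pos)
        vref <- paste0(anchor, ref); valt <- anchor
      }
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
              contig, pos, vref, valt, total, frequency / 100)
    })
  writeLines(c(header, rows), path)
  invisible(path)
}
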