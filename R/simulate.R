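# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Every simulator entry point routes its
# randomness through this, so a seed fully determines the output.
with_sim_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate an annotated reference genome
#'
#' Generates a random nucleotide sequence with non-overlapping gene + CDS
#' feature pairs laid out left to right. Genes grouped by
#' `operon_structure` share a strand and are separated by short
#' (`operon_gap`) intergenic gaps; other neighbours alternate strands and
#' are separated by `intergenic_gap`. Gene lengths are multiples of 3. The
#' output is fully determined by `seed`.
#'
#' @param genome_length total length, bp.
#' @param n_genes number of genes (0 gives a featureless genome).
#' @param gene_length gene length, bp (rounded down to a multiple of 3).
#' @param intergenic_gap,operon_gap gaps between neighbouring genes, bp.
#' @param operon_structure list of integer vectors of gene indices to place
#'   as co-oriented operon groups, e.g. `list(1:3)`.
#' @param contig contig name.
#' @param seed integer seed.
#' @return a [ref_genome()].
#' @export
simulate_reference <- function(genome_length = 10000, n_genes = 8,
                               gene_length = 750, intergenic_gap = 400,
                               operon_gap = 50, operon_structure = NULL,
                               contig = "chr", seed = 1) {
  with_sim_seed(seed, {
    gene_length <- (gene_length %/% 3L) * 3L
    seq <- paste(sample(c("A", "C", "G", "T"), genome_length,
                        replace = TRUE), collapse = "")
    if (n_genes == 0) return(ref_genome(setNames(seq, contig)))
    group_of <- rep(NA_integer_, n_genes)
    for (k in seq_along(operon_structure)) {
      group_of[operon_structure[[k]]] <- k
    }
    strand_of_group <- sample(c("+", "-"), max(1, length(operon_structure)),
                              replace = TRUE)
    cursor <- intergenic_gap
    rows <- vector("list", n_genes)
    strand_prev <- "-"
    for (i in seq_len(n_genes)) {
      same_group <- i > 1 && !is.na(group_of[i]) &&
        identical(group_of[i], group_of[i - 1])
      if (i > 1) {
        cursor <- cursor + if (same_group) operon_gap else intergenic_gap
      }
      strand <- if (!is.na(group_of[i])) {
        strand_of_group[group_of[i]]
      } else {
        strand_prev <- if (strand_prev == "+") "-" else "+"
        strand_prev
      }
      start <- cursor
      stop <- start + gene_length - 1L
      if (stop > genome_length - intergenic_gap) {
        stop("infeasible packing: ", n_genes, " genes of ", gene_length,
             " bp do not fit in ", genome_length, " bp")
      }
      rows[[i]] <- tibble(
        contig = contig,
        feature_id = c(sprintf("gene_%02d", i), sprintf("cds_%02d", i)),
        type = c("gene", "CDS"), start = start, stop = stop,
        strand = strand, locus_tag = sprintf("LOC_%02d", i),
        product = NA_character_)
      cursor <- stop + 1L
    }
    ref_genome(setNames(seq, contig), bind_rows(rows))
  })
}

mapping_skeleton <- function(read_name, mate, flag, contig, start, cigar,
                             seq, mismatches) {
  tibble(read_name = read_name, mate = as.integer(mate),
         flag = as.integer(flag), contig = contig,
         start = as.integer(start),
         stop = as.integer(start +
           GenomicAlignments::cigarWidthAlongReferenceSpace(cigar) - 1L),
         strand = ifelse(bitwAnd(as.integer(flag), 16L) > 0L, "-", "+"),
         cigar = cigar, seq = seq, mismatches = as.integer(mismatches))
}

#' Write alignments as a SAM file
#'
#' @param mappings mapping tibble (as produced by the simulators).
#' @param path output `.sam` path.
#' @param genome [ref_genome()] for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mappings, path, genome) {
  m <- mappings
  lines <- paste(m$read_name, m$flag, m$contig, m$start, 255L, m$cigar,
                 "*", 0L, 0L, ifelse(is.na(m$seq), "*", m$seq), "*",
                 paste0("NM:i:", m$mismatches), sep = "\t")
  writeLines(c(sam_header(genome, sorted = FALSE), lines), path)
  invisible(path)
}

read_window <- function(refseq, start, len) substring(refseq, start,
                                                      start + len - 1L)

#' Simulate a resequencing track with planted variants
#'
#' Emits error-free reads at uniformly random positions and plants the
#' requested variants: at each variant position, the given percentage of
#' the reads able to carry the event does so (with matching CIGAR, sequence
#' and edit distance). Planted variants must be at least one read length
#' apart so that no read carries two events.
#'
#' @param genome [ref_genome()].
#' @param variants tibble with `position`, `type` (substitution /
#'   insertion / deletion), `alt` (substituted base or inserted sequence;
#'   ignored for deletions), `size` (deletion length, default 1) and
#'   `frequency` (percent of carrying reads, default 100).
#' @param depth mean coverage.
#' @param read_length read length, bp.
#' @param seed integer seed.
#' @return list with `mappings` (tibble ready for [classify_mappings()])
#'   and `truth` (the planted variant table, normalized to the caller
#'   representation of [detect_variants()]).
#' @export
simulate_resequencing <- function(genome, variants = NULL, depth = 50,
                                  read_length = 50, seed = 1) {
  contig <- genome$contigs$contig[1]
  refseq <- ref_seq(genome, contig)
  len <- contig_length(genome, contig)
  if (is.null(variants)) {
    variants <- tibble(position = integer(), type = character(),
                       alt = character(), size = integer(),
                       frequency = double())
  }
  variants <- as_tibble(variants)
  if (!"size" %in% names(variants)) variants$size <- 1L
  if (!"frequency" %in% names(variants)) variants$frequency <- 100
  if (nrow(variants) > 1 &&
      min(diff(sort(variants$position))) < read_length) {
    stop("planted variants must be at least one read length apart")
  }
  with_sim_seed(seed, {
    n_reads <- as.integer(ceiling(depth * len / read_length))
    starts <- sample.int(len - read_length + 1L, n_reads, replace = TRUE)
    flags <- sample(c(0L, 16L), n_reads, replace = TRUE)
    cigars <- rep(paste0(read_length, "M"), n_reads)
    nms <- integer(n_reads)
    seqs <- rep(NA_character_, n_reads)
    # patch the (few) variant-carrying reads, one planted variant at a time
    for (vi in seq_len(nrow(variants))) {
      v <- variants[vi, ]
      over <- which(starts >= v$position - read_length + 1L &
                      starts <= v$position + max(v$size, 1L))
      if (length(over) == 0) next
      carry <- over[runif(length(over)) <= v$frequency / 100]
      for (i in carry) {
        s <- starts[i]
        if (v$type == "substitution" && v$position >= s &&
            v$position <= s + read_length - 1L) {
          seq <- read_window(refseq, s, read_length)
          k <- v$position - s + 1L
          substring(seq, k, k) <- v$alt
          seqs[i] <- seq; nms[i] <- 1L
        } else if (v$type == "insertion") {
          ins <- v$alt; ik <- nchar(ins)
          # needs aligned bases on both sides of the anchor
          if (v$position >= s && v$position <= s + read_length - 2L - ik) {
            left <- v$position - s + 1L
            right <- read_length - left - ik
            seqs[i] <- paste0(read_window(refseq, s, left), ins,
                              read_window(refseq, v$position + 1L, right))
            cigars[i] <- paste0(left, "M", ik, "I", right, "M")
            nms[i] <- ik
          } else if (v$position >= s && v$position <= s + read_length - 1L) {
            # too little room right of the anchor to align the insertion:
            # start the fragment past the anchor instead
            starts[i] <- v$position + 1L
          }
        } else if (v$type == "deletion") {
          k <- v$size
          if (v$position >= s + 1L && v$position <= s + read_length - 1L) {
            left <- v$position - s
            right <- read_length - left
            seqs[i] <- paste0(read_window(refseq, s, left),
                              read_window(refseq, v$position + k, right))
            cigars[i] <- paste0(left, "M", k, "D", right, "M")
            nms[i] <- k
          } else if (v$position <= s && s <= v$position + k - 1L) {
            # read would start inside the deleted bases: shift past them
            starts[i] <- v$position + k
          }
        }
      }
    }
    plain <- is.na(seqs)
    seqs[plain] <- read_window(refseq, starts[plain], read_length)
    rows <- mapping_skeleton(sprintf("r%06d", seq_len(n_reads)), 1L, flags,
                             contig, starts, cigars, seqs, nms)
    truth <- if (nrow(variants) == 0) {
      mutate(variants, ref = character())
    } else variants |>
      mutate(
        ref = dplyr::case_when(
          .data$type == "substitution" ~
            substring(refseq, .data$position, .data$position),
          .data$type == "deletion" ~
            substring(refseq, .data$position, .data$position + .data$size - 1L),
          TRUE ~ "-"),
        alt = ifelse(.data$type == "deletion", "-", .data$alt))
    list(mappings = bind_rows(rows), truth = truth)
  })
}

#' Simulate a 5'-enriched RNA-seq track with planted TSSs
#'
#' Plants a sharp pileup of `read_starts` reads whose 5' ends coincide at
#' each requested TSS position, over a smooth background of evenly tiled
#' transcript-body reads on both strands (tile spacing
#' `read_length / background_depth` per strand), so background positions
#' carry at most one read start each.
#'
#' @param genome [ref_genome()].
#' @param tss tibble with `position`, `strand`, `read_starts`.
#' @param background_depth per-strand background coverage.
#' @param read_length read length, bp.
#' @param seed integer seed.
#' @return list with `mappings` and `truth` (the planted TSS table).
#' @export
simulate_tss_track <- function(genome, tss, background_depth = 1,
                               read_length = 50, seed = 1) {
  contig <- genome$contigs$contig[1]
  refseq <- ref_seq(genome, contig)
  len <- contig_length(genome, contig)
  tss <- as_tibble(tss)
  with_sim_seed(seed, {
    spacing <- max(1L, as.integer(round(read_length / background_depth)))
    bg_starts <- seq.int(1L, len - read_length + 1L, by = spacing)
    rows <- list(
      mapping_skeleton(sprintf("bgf%06d", seq_along(bg_starts)), 1L, 0L,
                       contig, bg_starts, paste0(read_length, "M"),
                       read_window(refseq, bg_starts, read_length), 0L),
      mapping_skeleton(sprintf("bgr%06d", seq_along(bg_starts)), 1L, 16L,
                       contig, bg_starts, paste0(read_length, "M"),
                       read_window(refseq, bg_starts, read_length), 0L))
    for (k in seq_len(nrow(tss))) {
      p <- tss$position[k]; s5 <- tss$strand[k]; n <- tss$read_starts[k]
      start <- if (s5 == "+") p else p - read_length + 1L
      if (start < 1L || start + read_length - 1L > len) {
        stop("planted TSS too close to the contig edge: ", p)
      }
      rows[[length(rows) + 1L]] <- mapping_skeleton(
        sprintf("tss%02d_%04d", k, seq_len(n)), 1L,
        if (s5 == "+") 0L else 16L, contig, start,
        paste0(read_length, "M"),
        read_window(refseq, start, read_length), 0L)
    }
    list(mappings = bind_rows(rows), truth = tss)
  })
}

#' Simulate a paired-end track with planted distorted pairs
#'
#' Concordant pairs get forward-reverse orientation and an outer distance
#' drawn inside the perfect interval; a `distorted_fraction` of pairs is
#' planted as discordant, half by a too-small outer distance and half by
#' wrong (forward-forward) orientation.
#'
#' @param genome [ref_genome()].
#' @param n_pairs number of read pairs.
#' @param expected_distance,deviation perfect-distance interval
#'   specification.
#' @param distorted_fraction fraction of planted discordant pairs.
#' @param read_length read length, bp.
#' @param seed integer seed.
#' @return list with `mappings` and `truth` (`pair_id`, `planted` in
#'   perfect/distorted).
#' @export
simulate_paired <- function(genome, n_pairs = 1000, expected_distance = 250,
                            deviation = 0.1, distorted_fraction = 0.1,
                            read_length = 50, seed = 1) {
  contig <- genome$contigs$contig[1]
  refseq <- ref_seq(genome, contig)
  len <- contig_length(genome, contig)
  with_sim_seed(seed, {
    lo <- ceiling(expected_distance * (1 - deviation))
    hi <- floor(expected_distance * (1 + deviation))
    distorted <- runif(n_pairs) < distorted_fraction
    wrong_orient <- distorted & runif(n_pairs) < 0.5
    too_close <- distorted & !wrong_orient
    frag <- sample.int(hi - lo + 1L, n_pairs, replace = TRUE) + lo - 1L
    frag[too_close] <- sample.int(lo - 2L * read_length,
                                  sum(too_close), replace = TRUE) +
      2L * read_length - 1L
    fs <- vapply(frag, function(f) sample.int(len - f + 1L, 1L), integer(1))
    names <- sprintf("p%06d", seq_len(n_pairs))
    m2_start <- fs + frag - read_length
    m1 <- mapping_skeleton(names, 1L, 64L + 1L, contig, fs,
                           paste0(read_length, "M"),
                           read_window(refseq, fs, read_length), 0L)
    m2 <- mapping_skeleton(names, 2L,
                           ifelse(wrong_orient, 128L + 1L, 128L + 1L + 16L),
                           contig, m2_start, paste0(read_length, "M"),
                           read_window(refseq, m2_start, read_length), 0L)
    list(mappings = bind_rows(m1, m2),
         truth = tibble(pair_id = names,
                        planted = ifelse(distorted, "distorted",
                                         "perfect")))
  })
}

#' Simulate multi-mapped reads with asserted edit distances
#'
#' Each read receives several alignment records (one primary, the rest
#' flagged secondary) at random positions with edit distances drawn from
#' `mismatch_range`; at least one placement per read attains the minimum.
#' The reported edit-distance tag is authoritative for classification;
#' base-level sequence consistency is not maintained for the secondary
#' placements.
#'
#' @param genome [ref_genome()].
#' @param n_reads number of distinct reads.
#' @param placements number of mappings per read (recycled / sampled).
#' @param mismatch_range integer range to draw edit distances from.
#' @param read_length read length, bp.
#' @param seed integer seed.
#' @return list with `mappings` and `truth` (per-read `mapping_count` and
#'   `min_mismatches`).
#' @export
simulate_multimapped <- function(genome, n_reads = 1000,
                                 placements = 2:4, mismatch_range = 0:3,
                                 read_length = 50, seed = 1) {
  contig <- genome$contigs$contig[1]
  refseq <- ref_seq(genome, contig)
  len <- contig_length(genome, contig)
  with_sim_seed(seed, {
    ks <- if (length(placements) == 1) rep(placements, n_reads) else
      sample(placements, n_reads, replace = TRUE)
    total <- sum(ks)
    starts <- sample.int(len - read_length + 1L, total, replace = TRUE)
    nms <- sample(mismatch_range, total, replace = TRUE)
    first <- rep(FALSE, total)
    first[cumsum(c(1L, ks[-n_reads]))] <- TRUE
    mappings <- mapping_skeleton(
      rep(sprintf("m%06d", seq_len(n_reads)), ks), 1L,
      ifelse(first, 0L, 256L), contig, starts,
      paste0(read_length, "M"), read_window(refseq, starts, read_length),
      nms)
    truth <- mappings |>
      group_by(.data$read_name) |>
      summarise(mapping_count = dplyr::n(),
                min_mismatches = min(.data$mismatches), .groups = "drop")
    list(mappings = mappings, truth = truth)
  })
}

#' Simulate a two-condition count table
#'
#' Negative-binomial counts for `n_regions` regions over two conditions; a
#' `de_fraction` of regions gets its condition-B mean multiplied by `fold`.
#'
#' @param n_regions number of regions.
#' @param n_a,n_b replicates per condition.
#' @param base_mean mean count of non-differential regions.
#' @param fold fold change of planted differential regions.
#' @param de_fraction fraction of differential regions.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param seed integer seed.
#' @return list with `counts` (region + one column per sample `a1..`,
#'   `b1..`) and `truth` (`region`, `differential`).
#' @export
simulate_counts <- function(n_regions = 100, n_a = 3, n_b = 3,
                            base_mean = 100, fold = 4, de_fraction = 0.2,
                            dispersion = 0.05, seed = 1) {
  with_sim_seed(seed, {
    de <- runif(n_regions) < de_fraction
    mu_a <- rep(base_mean, n_regions)
    mu_b <- ifelse(de, base_mean * fold, base_mean)
    counts <- tibble(region = sprintf("R%04d", seq_len(n_regions)))
    for (j in seq_len(n_a)) {
      counts[[paste0("a", j)]] <- rnbinom(n_regions, mu = mu_a,
                                          size = 1 / dispersion)
    }
    for (j in seq_len(n_b)) {
      counts[[paste0("b", j)]] <- rnbinom(n_regions, mu = mu_b,
                                          size = 1 / dispersion)
    }
    list(counts = counts,
         truth = tibble(region = counts$region, differential = de))
  })
}
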