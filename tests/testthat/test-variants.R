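# pileup fixture: reads over a 60 bp contig, built base by base
variant_fixture <- function(n_total = 10, n_alt = 3, pos = 30L, seed = 1) {
  set.seed(seed)
  seq <- random_dna(60)
  g <- ref_genome(c(chr = seq))
  ref_base <- substring(seq, pos, pos)
  alt_base <- other_base(ref_base)
  reads <- lapply(seq_len(n_total), function(i) {
    start <- 21L
    s <- substring(seq, start, start + 29L)
    nm <- 0L
    if (i <= n_alt) {
      substring(s, pos - start + 1L, pos - start + 1L) <- alt_base
      nm <- 1L
    }
    mk_mapping(paste0("v", i), start, len = 30, nm = nm, seq = s)
  })
  list(genome = g, track = classify_mappings(dplyr::bind_rows(reads)),
       ref = ref_base, alt = alt_base, pos = pos)
}

test_that("substitutions pass when both thresholds hold, and only then", {
  fx <- variant_fixture()
  v <- detect_variants(fx$track, fx$genome, min_variation_percent = 25,
                       min_mismatch_count = 2, annotate = FALSE)
  expect_equal(nrow(v), 1)
  expect_equal(v$type, "substitution")
  expect_equal(v$position, fx$pos)
  expect_equal(v$ref, fx$ref)
  expect_equal(v$alt, fx$alt)
  expect_equal(v$count, 3L)
  expect_equal(v$total, 10L)
  expect_equal(v$frequency, 30)

  none <- detect_variants(fx$track, fx$genome, min_variation_percent = 25,
                          min_mismatch_count = 4, annotate = FALSE)
  expect_equal(nrow(none), 0)
})

test_that("a uniform 1-bp deletion is called at 100% frequency", {
  set.seed(2)
  seq <- random_dna(60)
  g <- ref_genome(c(chr = seq))
  reads <- lapply(1:5, function(i) {
    s <- paste0(substring(seq, 11, 29), substring(seq, 31, 41))
    mk_mapping(paste0("d", i), 11, cigar = "19M1D11M", nm = 1, seq = s)
  })
  v <- detect_variants(classify_mappings(dplyr::bind_rows(reads)), g,
                       min_variation_percent = 50, min_mismatch_count = 2,
                       annotate = FALSE)
  expect_equal(nrow(v), 1)
  expect_equal(v$type, "deletion")
  expect_equal(v$position, 30L)
  expect_equal(v$ref, substring(seq, 30, 30))
  expect_equal(v$alt, "-")
  expect_equal(v$frequency, 100)
})

test_that("insertions are anchored to the base they follow", {
  set.seed(3)
  seq <- random_dna(60)
  g <- ref_genome(c(chr = seq))
  reads <- lapply(1:4, function(i) {
    s <- paste0(substring(seq, 11, 30), "GG", substring(seq, 31, 38))
    mk_mapping(paste0("i", i), 11, cigar = "20M2I8M", nm = 2, seq = s)
  })
  v <- detect_variants(classify_mappings(dplyr::bind_rows(reads)), g,
                       min_variation_percent = 50, min_mismatch_count = 2,
                       annotate = FALSE)
  expect_equal(v$type, "insertion")
  expect_equal(v$position, 30L)
  expect_equal(v$alt, "GG")
})

test_that("N read bases drop out of numerator and denominator", {
  fx <- variant_fixture(n_total = 10, n_alt = 3)
  # add two reads carrying N at the variant position
  seqN <- fx$track$seq[1]
  substring(seqN, fx$pos - 21L + 1L, fx$pos - 21L + 1L) <- "N"
  withN <- dplyr::bind_rows(
    fx$track,
    classify_mappings(dplyr::bind_rows(
      mk_mapping("n1", 21, len = 30, nm = 1, seq = seqN),
      mk_mapping("n2", 21, len = 30, nm = 1, seq = seqN))))
  v <- detect_variants(withN, fx$genome, min_variation_percent = 25,
                       min_mismatch_count = 2, annotate = FALSE)
  v <- v[v$position == fx$pos & v$type == "substitution", ]
  expect_equal(v$count, 3L)
  expect_equal(v$total, 10L)  # 12 reads minus the 2 N carriers
})

test_that("raising either threshold never adds a variant", {
  g <- simulate_reference(genome_length = 3000, n_genes = 0, seed = 4)
  vars <- tibble::tibble(position = c(500L, 1500L, 2500L),
                         type = "substitution",
                         alt = vapply(c(500L, 1500L, 2500L), function(p)
                           other_base(substring(g$sequences[[1]], p, p)),
                           character(1)),
                         size = 1L, frequency = c(100, 60, 30))
  tr <- classify_mappings(simulate_resequencing(g, vars, depth = 20,
                                                seed = 5)$mappings)
  grid <- expand.grid(pct = c(10, 30, 60, 90), cnt = c(1, 3, 6, 12))
  calls <- lapply(seq_len(nrow(grid)), function(i) {
    v <- detect_variants(tr, g, grid$pct[i], grid$cnt[i], annotate = FALSE)
    paste(v$position, v$alt)
  })
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$pct[j] >= grid$pct[i] && grid$cnt[j] >= grid$cnt[i]) {
        expect_true(all(calls[[j]] %in% calls[[i]]))
      }
    }
  }
})

test_that("eligible-coverage totals grow with the class filter", {
  g <- simulate_reference(genome_length = 3000, n_genes = 0, seed = 6)
  mm <- simulate_multimapped(g, n_reads = 300, seed = 7)$mappings
  tr <- classify_mappings(mm)
  len <- 3000L
  covs <- lapply(c("PERFECT", "BEST", "COMMON"), function(f) {
    coverage_profile(tr, g, class_filter = f)$coverage
  })
  expect_true(all(covs[[1]] <= covs[[2]]) && all(covs[[2]] <= covs[[3]]))
})

test_that("codon and amino-acid effect is computed in the CDS frame", {
  seq <- "ATGGCTTAAGGG"
  g <- ref_genome(c(chr = seq),
                  tibble::tibble(contig = "chr", feature_id = "cds1",
                                 type = "CDS", start = 1L, stop = 9L,
                                 strand = "+"))
  reads <- lapply(1:6, function(i) {
    s <- seq
    substring(s, 5, 5) <- "T"
    mk_mapping(paste0("c", i), 1, cigar = "12M", nm = 1, seq = s)
  })
  v <- detect_variants(classify_mappings(dplyr::bind_rows(reads)), g,
                       min_variation_percent = 50, min_mismatch_count = 2)
  expect_equal(v$location, "intragenic")
  expect_equal(v$feature_id, "cds1")
  expect_equal(v$ref_codon, "GCT")
  expect_equal(v$alt_codon, "GTT")
  expect_equal(v$ref_aa, "A")
  expect_equal(v$alt_aa, "V")
})

test_that("minus-strand CDS effects use the reverse complement", {
  # reverse complement of ATGGCTTAA placed on the minus strand at 4..12
  seq <- paste0("CCC", "TTAAGCCAT", "CC")  # revcomp(ATGGCTTAA) = TTAAGCCAT
  g <- ref_genome(c(chr = seq),
                  tibble::tibble(contig = "chr", feature_id = "cdsm",
                                 type = "CDS", start = 4L, stop = 12L,
                                 strand = "-"))
  # codon 2 of the CDS is GCT (ref positions 7..9 = AGC on the fwd strand);
  # plant A->T in codon space: forward base at position 8 G->A gives
  # alt codon GTT on the minus strand
  reads <- lapply(1:6, function(i) {
    s <- substring(seq, 1, 14)
    substring(s, 8, 8) <- "A"
    mk_mapping(paste0("m", i), 1, cigar = "14M", nm = 1, seq = s)
  })
  v <- detect_variants(classify_mappings(dplyr::bind_rows(reads)), g,
                       min_variation_percent = 50, min_mismatch_count = 2)
  expect_equal(v$position, 8L)
  expect_equal(v$ref_codon, "GCT")
  expect_equal(v$alt_codon, "GTT")
  expect_equal(v$ref_aa, "A")
  expect_equal(v$alt_aa, "V")
})

test_that("intergenic variants carry no codon fields; odd CDS warns", {
  fx <- variant_fixture()
  v <- detect_variants(fx$track, fx$genome, 25, 2)
  expect_equal(v$location, "intergenic")
  expect_true(is.na(v$ref_codon))

  godd <- ref_genome(fx$genome$sequences,
                     tibble::tibble(contig = "chr", feature_id = "odd",
                                    type = "CDS", start = 25L, stop = 34L,
                                    strand = "+"))
  expect_warning(vo <- detect_variants(fx$track, godd, 25, 2),
                 "divisible by 3")
  expect_equal(vo$location, "intragenic")
  expect_true(is.na(vo$ref_codon))
})

test_that("variant TSV and VCF exports are written with anchored indels", {
  set.seed(8)
  seq <- random_dna(60)
  g <- ref_genome(c(chr = seq))
  reads <- lapply(1:5, function(i) {
    s <- paste0(substring(seq, 11, 29), substring(seq, 31, 41))
    mk_mapping(paste0("d", i), 11, cigar = "19M1D11M", nm = 1, seq = s)
  })
  v <- detect_variants(classify_mappings(dplyr::bind_rows(reads)), g, 50, 2,
                       annotate = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v, tsv)
  write_variants_vcf(v, g, vcf)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 1)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  rec <- strsplit(lines[!startsWith(lines, "#")], "\t")[[1]]
  expect_equal(as.integer(rec[2]), 29L)  # anchored one base upstream
  expect_equal(nchar(rec[4]), 2L)        # anchor + deleted base
  expect_equal(nchar(rec[5]), 1L)
})

test_that("planted variants are recovered exactly on an error-free track", {
  g <- simulate_reference(genome_length = 8000, n_genes = 4, seed = 9)
  pos <- c(700L, 1800L, 3100L, 4500L, 6200L)
  vars <- tibble::tibble(
    position = pos,
    type = c("substitution", "deletion", "substitution", "insertion",
             "substitution"),
    alt = c(other_base(substring(g$sequences[[1]], 700, 700)), "-",
            other_base(substring(g$sequences[[1]], 3100, 3100)), "CATG",
            other_base(substring(g$sequences[[1]], 6200, 6200))),
    size = c(1L, 3L, 1L, 4L, 1L), frequency = 100)
  sim <- simulate_resequencing(g, vars, depth = 30, seed = 10)
  v <- detect_variants(classify_mappings(sim$mappings), g,
                       min_variation_percent = 90, min_mismatch_count = 5,
                       annotate = FALSE)
  expect_equal(v$position, pos)
  expect_equal(v$type, vars$type)
  # zero false positives anywhere else
  expect_equal(nrow(v), length(pos))
})
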