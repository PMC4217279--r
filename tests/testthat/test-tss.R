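test_that("the quantile cutoff matches the rank construction on the spec example", {
  x <- c(rep(0, 997), 5, 8, 12)
  expect_equal(upper_quantile_cutoff(x, 0.0025), 5)
})

test_that("a constant vector admits no position", {
  x <- rep(7, 1000)
  cut <- upper_quantile_cutoff(x, 0.0025)
  expect_equal(cut, 8)
  expect_equal(sum(x >= cut), 0)
})

test_that("admissions never exceed the quantile mass plus none (tie-aware)", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rpois(2000, lambda = sample(c(0.05, 0.5, 2), 1))
    cut <- upper_quantile_cutoff(x, 0.0025)
    expect_lte(sum(x >= cut), ceiling(0.0025 * length(x)))
  }
})

test_that("parameter estimation needs a non-empty track", {
  g <- toy_genome(500)
  empty <- classify_mappings(mk_mapping("x", 1))[0, ]
  expect_error(estimate_tss_parameters(empty, g), "empty")
})

test_that("a sharp coverage increase with enough read starts is a TSS", {
  # coverage 2 upstream, 52 at position 100 where 50 reads start
  bg <- dplyr::bind_rows(mk_mapping("b1", 60, len = 90),
                         mk_mapping("b2", 60, len = 90))
  stack <- dplyr::bind_rows(lapply(1:50, function(i)
    mk_mapping(paste0("s", i), 100, len = 50)))
  tr <- classify_mappings(dplyr::bind_rows(bg, stack))
  g <- toy_genome(500)
  res <- detect_tss(tr, g, tss_parameters(10, 200))
  expect_equal(res$position, 100L)
  expect_equal(res$strand, "+")
  expect_equal(res$read_starts, 50L)
  expect_equal(res$percent_increase, 2500)
})

test_that("high-background positions are rejected by the increase criterion", {
  # staggered deep background: coverage ~1000 over 100..399, no position
  # with a qualifying relative increase
  bg <- dplyr::bind_rows(lapply(1:100, function(p) {
    dplyr::bind_rows(lapply(1:10, function(i)
      mk_mapping(paste0("b", p, "_", i), p, len = 300)))
  }))
  stack <- dplyr::bind_rows(lapply(1:50, function(i)
    mk_mapping(paste0("s", i), 150, len = 50)))
  tr <- classify_mappings(dplyr::bind_rows(bg, stack))
  res <- detect_tss(tr, toy_genome(500), tss_parameters(10, 200))
  expect_equal(nrow(res), 0)
})

test_that("only the best-scoring position in a 3 bp window is reported", {
  mk_stack <- function(pos, n) dplyr::bind_rows(lapply(seq_len(n),
    function(i) mk_mapping(paste0("p", pos, "_", i), pos, len = 50)))
  tr <- classify_mappings(dplyr::bind_rows(mk_stack(100, 20),
                                           mk_stack(102, 35)))
  res <- detect_tss(tr, toy_genome(500), tss_parameters(5, 100))
  expect_equal(res$position, 102L)
  # ties resolve toward the 5' end
  tr2 <- classify_mappings(dplyr::bind_rows(mk_stack(200, 20),
                                            mk_stack(202, 20)))
  res2 <- detect_tss(tr2, toy_genome(500), tss_parameters(5, 100))
  expect_equal(res2$position, 200L)
})

test_that("an antisense TSS inside an opposite-strand gene is categorised", {
  g <- ref_genome(c(chr = random_dna(2000)),
                  tibble::tibble(contig = "chr", feature_id = "minus_gene",
                                 type = "gene", start = 300L, stop = 900L,
                                 strand = "-"))
  stack <- dplyr::bind_rows(lapply(1:30, function(i)
    mk_mapping(paste0("a", i), 500, len = 50)))
  res <- detect_tss(classify_mappings(stack), g, tss_parameters(5, 100))
  expect_equal(res$category, "cis-antisense")
  expect_equal(res$position, 500L)
  # transcript extends while coverage stays at/above the end threshold
  expect_equal(res$novel_transcript_stop, 549L)
})

test_that("TSS near an annotated same-strand start is associated to it", {
  g <- ref_genome(c(chr = random_dna(2000)),
                  tibble::tibble(contig = "chr", feature_id = "geneA",
                                 type = "gene", start = 600L, stop = 1200L,
                                 strand = "+"))
  stack <- dplyr::bind_rows(lapply(1:30, function(i)
    mk_mapping(paste0("t", i), 570, len = 50)))
  res <- detect_tss(classify_mappings(stack), g, tss_parameters(5, 100))
  expect_equal(res$category, "annotated-start")
  expect_equal(res$associated_feature, "geneA")
  expect_true(is.na(res$novel_transcript_stop))
})

test_that("intergenic TSS without association is trans-encoded with a transcript", {
  g <- toy_genome(2000)
  stack <- dplyr::bind_rows(lapply(1:30, function(i)
    mk_mapping(paste0("t", i), 1000, len = 60)))
  res <- detect_tss(classify_mappings(stack), g, tss_parameters(5, 100))
  expect_equal(res$category, "trans-encoded")
  expect_equal(res$novel_transcript_stop, 1059L)
})

test_that("minus-strand detection runs in transcription direction", {
  stack <- dplyr::bind_rows(lapply(1:30, function(i)
    mk_mapping(paste0("m", i), 151, len = 50, strand = "-")))
  res <- detect_tss(classify_mappings(stack), toy_genome(500),
                    tss_parameters(5, 100))
  expect_equal(res$strand, "-")
  expect_equal(res$position, 200L)  # 5' end of a minus-strand read
})

test_that("detection equals the brute-force all-pairs oracle", {
  set.seed(13)
  g <- toy_genome(800, seed = 14)
  for (rep in 1:20) {
    n_stacks <- sample(2:5, 1)
    m <- dplyr::bind_rows(lapply(seq_len(n_stacks), function(k) {
      pos <- sample(60:700, 1)
      strand <- sample(c("+", "-"), 1)
      n <- sample(3:30, 1)
      dplyr::bind_rows(lapply(seq_len(n), function(i)
        mk_mapping(paste0("s", rep, "_", k, "_", i),
                   if (strand == "+") pos else pos - 49L,
                   len = 50, strand = strand)))
    }))
    bg <- dplyr::bind_rows(lapply(seq(1, 750, by = 37), function(p)
      mk_mapping(paste0("bg", rep, "_", p), p, len = 50,
                 strand = sample(c("+", "-"), 1))))
    tr <- classify_mappings(dplyr::bind_rows(m, bg))
    prm <- tss_parameters(sample(2:12, 1), sample(c(50, 150, 400), 1))
    got <- detect_tss(tr, g, prm)[, c("position", "strand")]
    exp <- oracle_tss_positions(tr, 800, prm$min_read_starts,
                                prm$min_percent_increase)
    expect_equal(as.data.frame(got), as.data.frame(exp))
  }
})

test_that("planted TSSs are recovered exactly with auto-estimated parameters", {
  g <- simulate_reference(genome_length = 12000, n_genes = 8, seed = 15)
  genes <- g$features[g$features$type == "gene", ]
  tss <- tibble::tibble(
    position = ifelse(genes$strand == "+", genes$start - 25L,
                      genes$stop + 25L),
    strand = genes$strand,
    read_starts = sample(c(30L, 50L, 80L), nrow(genes), replace = TRUE))
  sim <- simulate_tss_track(g, tss, seed = 16)
  tr <- classify_mappings(sim$mappings)
  params <- estimate_tss_parameters(tr, g)
  expect_true(params$auto_estimated)
  res <- detect_tss(tr, g, params)
  expect_equal(
    dplyr::arrange(res[, c("position", "strand")], position),
    dplyr::arrange(tibble::tibble(position = tss$position,
                                  strand = tss$strand), position))
  expect_true(all(res$category == "annotated-start"))
})
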