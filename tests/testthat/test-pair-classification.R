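cm <- function(read, start, len = 50, strand = "+", nm = 0, mate = 1) {
  classify_mappings(mk_mapping(read, start, len = len, strand = strand,
                               nm = nm, mate = mate))
}

PAIR_CLASSES_EXPECTED <- c("PERFECT_PAIR", "DISTORTED_PAIR",
                           "SINGLE_MAPPING")

ref_ids <- function(recs) {
  ids <- c(recs$m1_id, recs$m2_id)
  ids[!is.na(ids)]
}

test_that("one concordant combination is a Perfect pair with outer distance", {
  recs <- classify_mapping_pair(cm("r", 100), cm("r", 300, strand = "-",
                                                 mate = 2),
                                expected_distance = 250, deviation = 0.1)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$classification, "PERFECT_PAIR")
  expect_equal(recs$distance, 349L - 100L + 1L)
})

test_that("an unmapped partner yields a Single Mapping", {
  recs <- classify_mapping_pair(cm("r", 100), cm("r", 1, mate = 2)[0, ],
                                expected_distance = 250)
  expect_equal(recs$classification, "SINGLE_MAPPING")
  expect_true(is.na(recs$distance))
  expect_true(is.na(recs$m2_id))
})

test_that("perfect pairs are kept and leftovers become Single Mappings", {
  m2 <- dplyr::bind_rows(cm("r", 300, strand = "-", mate = 2),
                         cm("r", 800, strand = "-", mate = 2))
  recs <- classify_mapping_pair(cm("r", 100), m2, expected_distance = 250,
                                deviation = 0.1)
  expect_setequal(recs$classification, c("PERFECT_PAIR", "SINGLE_MAPPING"))
  pp <- recs[recs$classification == "PERFECT_PAIR", ]
  expect_equal(sort(c(pp$m1_start, pp$m2_start)), c(100L, 300L))
  single <- recs[recs$classification == "SINGLE_MAPPING", ]
  expect_equal(single$m1_start, 800L)
})

test_that("a lone too-close combination is a Distorted pair", {
  recs <- classify_mapping_pair(cm("r", 100), cm("r", 180, strand = "-",
                                                 mate = 2),
                                expected_distance = 250, deviation = 0.1)
  expect_equal(recs$classification, "DISTORTED_PAIR")
  expect_equal(recs$distance, 130L)
})

test_that("wrong orientation with one combination is a Distorted pair", {
  recs <- classify_mapping_pair(cm("r", 100), cm("r", 300, strand = "+",
                                                 mate = 2),
                                expected_distance = 250, deviation = 0.1)
  expect_equal(recs$classification, "DISTORTED_PAIR")
})

test_that("multi-mapping with only larger distances gives all Single Mappings", {
  m1 <- dplyr::bind_rows(cm("r", 100), cm("r", 5000))
  m2 <- cm("r", 2500, strand = "-", mate = 2)
  recs <- classify_mapping_pair(m1, m2, expected_distance = 250,
                                deviation = 0.1)
  expect_equal(recs$classification, rep("SINGLE_MAPPING", 3))
})

test_that("the largest smaller-distance pair per region is stored", {
  # two smaller-distance candidates in one neighbourhood: keep the wider one
  m1 <- dplyr::bind_rows(cm("r", 100), cm("r", 130))
  m2 <- cm("r", 230, strand = "-", mate = 2)
  recs <- classify_mapping_pair(m1, m2, expected_distance = 250,
                                deviation = 0.1)
  expect_equal(sum(recs$classification == "DISTORTED_PAIR"), 1)
  dp <- recs[recs$classification == "DISTORTED_PAIR", ]
  expect_equal(dp$m1_start, 100L)  # distance 180 beats distance 150
  expect_equal(sum(recs$classification == "SINGLE_MAPPING"), 1)
})

test_that("every mapping appears in exactly one record (random cases)", {
  set.seed(20)
  for (case in 1:40) {
    n1 <- sample(0:4, 1); n2 <- sample(0:4, 1)
    if (n1 + n2 == 0) next
    m1 <- if (n1 > 0) classify_mappings(dplyr::bind_rows(lapply(
      seq_len(n1), function(i) mk_mapping("r", sample(5000, 1),
                                          strand = sample(c("+", "-"), 1),
                                          nm = sample(0:2, 1))))) else
      mk_mapping("x", 1)[0, ]
    m2 <- if (n2 > 0) classify_mappings(dplyr::bind_rows(lapply(
      seq_len(n2), function(i) mk_mapping("r", sample(5000, 1),
                                          strand = sample(c("+", "-"), 1),
                                          nm = sample(0:2, 1),
                                          mate = 2)))) else
      mk_mapping("x", 1, mate = 2)[0, ]
    recs <- classify_mapping_pair(m1, m2, expected_distance = 250,
                                  deviation = 0.2)
    ids <- ref_ids(recs)
    expect_equal(length(ids), n1 + n2)
    expect_equal(anyDuplicated(ids), 0)
    expect_true(all(recs$classification %in% PAIR_CLASSES_EXPECTED))
  }
})

test_that("pair records are independent of input mapping order", {
  set.seed(30)
  m1 <- classify_mappings(dplyr::bind_rows(
    mk_mapping("r", 100), mk_mapping("r", 900), mk_mapping("r", 2000)))
  m2 <- classify_mappings(dplyr::bind_rows(
    mk_mapping("r", 300, strand = "-", mate = 2),
    mk_mapping("r", 1100, strand = "-", mate = 2)))
  a <- classify_mapping_pair(m1, m2, 250, 0.1)
  b <- classify_mapping_pair(m1[sample(3), ], m2[sample(2), ], 250, 0.1)
  key <- function(x) {
    as.data.frame(dplyr::arrange(
      x[, c("classification", "distance", "m1_start", "m2_start")],
      classification, m1_start))
  }
  expect_equal(key(a), key(b))
})

test_that("enlarging the deviation never loses Perfect pairs", {
  set.seed(40)
  for (case in 1:25) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    m1 <- classify_mappings(dplyr::bind_rows(lapply(seq_len(n1), function(i)
      mk_mapping("r", sample(3000, 1)))))
    m2 <- classify_mappings(dplyr::bind_rows(lapply(seq_len(n2), function(i)
      mk_mapping("r", sample(3000, 1), strand = "-", mate = 2))))
    n_perfect <- vapply(c(0.05, 0.15, 0.3, 0.45), function(dev) {
      recs <- classify_mapping_pair(m1, m2, 250, dev)
      sum(recs$classification == "PERFECT_PAIR")
    }, double(1))
    expect_true(all(diff(n_perfect) >= 0))
  }
})

test_that("whole-track pair classification recovers the planted mix", {
  g <- simulate_reference(genome_length = 20000, n_genes = 0, seed = 50)
  sim <- simulate_paired(g, n_pairs = 400, distorted_fraction = 0.15,
                         seed = 51)
  recs <- classify_pairs(classify_mappings(sim$mappings), 250, 0.1, "fr")
  expect_equal(nrow(recs), 400)
  joined <- dplyr::left_join(recs, sim$truth, by = "pair_id")
  expect_true(all(joined$classification[joined$planted == "perfect"] ==
                    "PERFECT_PAIR"))
  expect_true(all(joined$classification[joined$planted == "distorted"] ==
                    "DISTORTED_PAIR"))
})
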