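PAIR_CLASSES <- c("PERFECT_PAIR", "DISTORTED_PAIR", "SINGLE_MAPPING")

# Candidate pairings of mate-1 x mate-2 mappings with their outer distance
# (rightmost aligned base - leftmost aligned base + 1) and geometry calls.
pair_candidates <- function(m1, m2, expected_distance, deviation,
                            orientation) {
  if (nrow(m1) == 0 || nrow(m2) == 0) {
    return(tibble(i = integer(), j = integer(), distance = integer(),
                  orient_ok = logical(), geometry = character(),
                  min_rank = integer()))
  }
  grid <- expand.grid(i = seq_len(nrow(m1)), j = seq_len(nrow(m2)))
  a <- m1[grid$i, ]; b <- m2[grid$j, ]
  left_strand <- ifelse(a$start <= b$start, a$strand, b$strand)
  right_strand <- ifelse(a$start <= b$start, b$strand, a$strand)
  orient_ok <- switch(orientation,
    fr = left_strand == "+" & right_strand == "-",
    rf = left_strand == "-" & right_strand == "+",
    same = a$strand == b$strand)
  distance <- pmax(a$stop, b$stop) - pmin(a$start, b$start) + 1L
  lo <- expected_distance * (1 - deviation)
  hi <- expected_distance * (1 + deviation)
  geometry <- case_when(
    !orient_ok ~ "misoriented",
    distance < lo ~ "smaller",
    distance > hi ~ "larger",
    TRUE ~ "perfect")
  rank_of <- function(cl) {
    if (is.null(cl)) rep(3L, nrow(grid)) else as.integer(cl)
  }
  tibble(i = grid$i, j = grid$j, distance = distance,
         orient_ok = orient_ok, geometry = geometry,
         min_rank = pmin(rank_of(a$class), rank_of(b$class)),
         closeness = abs(distance - expected_distance))
}

# Maximum-cardinality bipartite matching over the perfect-geometry
# candidates; the weight encodes, below the cardinality term, the class
# preference (Perfect > Best > Common mappings) and distance closeness.
match_perfect_pairs <- function(cand, n1, n2) {
  pc <- cand[cand$geometry == "perfect", , drop = FALSE]
  if (nrow(pc) == 0) return(pc)
  pc <- arrange(pc, .data$min_rank, .data$closeness, .data$i, .data$j)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n1), rep(TRUE, n2)),
    edges = as.vector(rbind(pc$i, n1 + pc$j)))
  w <- 1e6 - 1e4 * pc$min_rank - pmin(pc$closeness, 9999)
  mt <- igraph::max_bipartite_match(g, weights = w)$matching
  sel <- !is.na(mt[seq_len(n1)]) & mt[seq_len(n1)] > n1
  picked <- tibble(i = which(sel), j = mt[which(sel)] - n1)
  dplyr::semi_join(pc, picked, by = c("i", "j"))
}

# Table-1 "largest smaller distance pair for each region": smaller-distance
# candidates are grouped into regions (connected components of candidates
# whose spans lie within the outer perfect-distance bound of each other, or
# that share a mapping) and the candidate with the greatest distance --
# closest to the perfect interval -- is kept per region.
pick_distorted <- function(cand, m1, m2, expected_distance, deviation) {
  sc <- cand[cand$geometry == "smaller", , drop = FALSE]
  if (nrow(sc) == 0) return(sc)
  span_start <- pmin(m1$start[sc$i], m2$start[sc$j])
  span_stop <- pmax(m1$stop[sc$i], m2$stop[sc$j])
  reach <- expected_distance * (1 + deviation)
  n <- nrow(sc)
  adj <- outer(seq_len(n), seq_len(n), function(a, b) {
    share <- sc$i[a] == sc$i[b] | sc$j[a] == sc$j[b]
    near <- pmax(span_start[a], span_start[b]) -
      pmin(span_stop[a], span_stop[b]) <= reach
    share | near
  })
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  sc$region <- comp
  sc |>
    arrange(.data$region, dplyr::desc(.data$distance), .data$min_rank,
            .data$closeness, .data$i, .data$j) |>
    group_by(.data$region) |>
    dplyr::slice(1) |>
    ungroup()
}

flatten_mapping <- function(m, idx, mate, prefix) {
  cols <- c("start", "stop", "strand", "class", "mapping_count")
  if (is.na(idx)) {
    out <- as.list(setNames(rep(NA, length(cols) + 2),
                            paste0(prefix, c("id", "mate", cols))))
    out[[paste0(prefix, "strand")]] <- NA_character_
    return(out)
  }
  row <- m[idx, ]
  out <- list(paste0(mate, ":", idx), mate, row$start, row$stop, row$strand,
              if ("class" %in% names(row)) as.character(row$class) else
                NA_character_,
              if ("mapping_count" %in% names(row)) row$mapping_count else
                NA_integer_)
  setNames(out, paste0(prefix, c("id", "mate", cols)))
}

pair_record <- function(classification, pair_id, m1, m2, i = NA, j = NA,
                        distance = NA_integer_) {
  # a single mapping from mate 2 is carried in the m1_* slot
  if (is.na(i) && !is.na(j)) {
    first <- flatten_mapping(m2, j, 2L, "m1_")
    second <- flatten_mapping(m1, NA, 1L, "m2_")
  } else {
    first <- flatten_mapping(m1, i, 1L, "m1_")
    second <- flatten_mapping(m2, j, 2L, "m2_")
  }
  as_tibble(c(list(pair_id = pair_id, classification = classification,
                   distance = as.integer(distance)), first, second))
}

#' Classify all mappings of one mapping pair
#'
#' Applies the read-pair classification to the full set of mappings of the
#' two reads of a sequenced pair (the "mapping pair"). A pairing with
#' correct orientation and outer distance within
#' `expected_distance * (1 +/- deviation)` is a Perfect read pair. With one
#' mapping per mate, a discordant combination is a Distorted pair. With more
#' than two mappings, all Perfect pairings (chosen by maximum matching with
#' Perfect > Best > Common mapping-class preference, never reusing a
#' mapping) are emitted; among correctly oriented pairings whose distance
#' falls below the perfect interval, the one with the greatest distance per
#' genomic region is emitted as a Distorted pair; every remaining mapping
#' becomes a Single Mapping. Pairings wider than the perfect interval never
#' form pairs in the multi-mapping case.
#'
#' @param mappings_read1,mappings_read2 classified mapping tibbles holding
#'   all mappings of mate 1 / mate 2 (either may have zero rows).
#' @param expected_distance expected outer distance (fragment length), bp.
#' @param deviation allowed fractional deviation, in `[0, 1)`.
#' @param orientation `"fr"` (forward-reverse, default), `"rf"`, or
#'   `"same"` for same-strand mate-pair libraries.
#' @param pair_id identifier shared by all emitted records.
#' @return tibble with one row per read-pair record: `pair_id`,
#'   `classification` (PERFECT_PAIR / DISTORTED_PAIR / SINGLE_MAPPING),
#'   `distance`, and flattened `m1_*` / `m2_*` mapping columns (`m2_*` is
#'   `NA` for Single Mappings). Every input mapping is referenced exactly
#'   once across the records.
#' @export
classify_mapping_pair <- function(mappings_read1, mappings_read2,
                                  expected_distance, deviation = 0.1,
                                  orientation = c("fr", "rf", "same"),
                                  pair_id = "pair") {
  orientation <- match.arg(orientation)
  m1 <- arrange(as_tibble(mappings_read1), .data$start, .data$strand)
  m2 <- arrange(as_tibble(mappings_read2), .data$start, .data$strand)
  n1 <- nrow(m1); n2 <- nrow(m2)
  total <- n1 + n2
  if (total == 0) {
    return(pair_record("SINGLE_MAPPING", pair_id, m1, m2)[0, ])
  }
  singles <- function(is1, is2) {
    bind_rows(
      lapply(is1, function(i) pair_record("SINGLE_MAPPING", pair_id,
                                          m1, m2, i = i)),
      lapply(is2, function(j) pair_record("SINGLE_MAPPING", pair_id,
                                          m1, m2, j = j)))
  }
  if (total == 1) return(singles(seq_len(n1), seq_len(n2)))
  cand <- pair_candidates(m1, m2, expected_distance, deviation, orientation)
  if (total == 2 && n1 == 1 && n2 == 1) {
    cls <- if (cand$geometry[1] == "perfect") "PERFECT_PAIR" else
      "DISTORTED_PAIR"
    return(pair_record(cls, pair_id, m1, m2, i = 1, j = 1,
                       distance = cand$distance[1]))
  }
  perfect <- match_perfect_pairs(cand, n1, n2)
  used1 <- perfect$i; used2 <- perfect$j
  rest <- cand[!(cand$i %in% used1) & !(cand$j %in% used2), , drop = FALSE]
  distorted <- pick_distorted(rest, m1, m2, expected_distance, deviation)
  used1 <- c(used1, distorted$i); used2 <- c(used2, distorted$j)
  recs <- bind_rows(
    purrr::pmap(perfect[, c("i", "j", "distance")], function(i, j, distance)
      pair_record("PERFECT_PAIR", pair_id, m1, m2, i, j, distance)),
    purrr::pmap(distorted[, c("i", "j", "distance")], function(i, j, distance)
      pair_record("DISTORTED_PAIR", pair_id, m1, m2, i, j, distance)),
    singles(setdiff(seq_len(n1), used1), setdiff(seq_len(n2), used2)))
  recs
}

#' Classify every mapping pair of a paired track
#'
#' Groups a classified track by read name and runs
#' [classify_mapping_pair()] on each mapping pair (mate-1 mappings against
#' mate-2 mappings).
#'
#' @param track classified mapping tibble with paired reads (`mate` column).
#' @inheritParams classify_mapping_pair
#' @return tibble of read-pair records with `pair_id` set to the read name.
#' @export
classify_pairs <- function(track, expected_distance, deviation = 0.1,
                           orientation = c("fr", "rf", "same")) {
  orientation <- match.arg(orientation)
  track |>
    dplyr::group_split(.data$read_name) |>
    purrr::map(function(g) {
      classify_mapping_pair(g[g$mate == 1L, ], g[g$mate == 2L, ],
                            expected_distance, deviation, orientation,
                            pair_id = g$read_name[1])
    }) |>
    bind_rows()
}
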