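MAPPING_CLASSES <- c("PERFECT", "BEST", "COMMON")

# Mapping classes are cumulative when used as filters: PERFECT is a subset
# of BEST, BEST of COMMON. class_members() expands a filter label to the
# class labels it admits.
class_members <- function(class_filter) {
  class_filter <- match.arg(class_filter, MAPPING_CLASSES)
  MAPPING_CLASSES[seq_len(match(class_filter, MAPPING_CLASSES))]
}

#' Per-read mapping statistics
#'
#' For every read (mates of a pair counted as distinct reads), counts its
#' mappings in the file and the lowest edit distance among them. These two
#' numbers drive the Perfect/Best/Common classification.
#'
#' @param mappings tibble from [read_mappings()]; input order is irrelevant.
#' @return tibble with `read_name`, `mate`, `mapping_count`,
#'   `min_mismatches`.
#' @export
compute_read_stats <- function(mappings) {
  if (any(is.na(mappings$mismatches))) {
    bad <- mappings$read_name[is.na(mappings$mismatches)][1]
    stop("mapping of read ", bad, " has no edit distance (NM) and no ",
         "reference was available to recompute it")
  }
  mappings |>
    group_by(.data$read_name, .data$mate) |>
    summarise(mapping_count = dplyr::n(),
              min_mismatches = min(.data$mismatches), .groups = "drop")
}

#' Classify mappings into Perfect, Best and Common Match
#'
#' A mapping with zero mismatches is a Perfect Match. A mapping whose edit
#' distance equals the minimum over all of its read's mappings (but is
#' nonzero) is a Best Match: the read cannot be placed anywhere else with
#' fewer mismatches. Everything else is a Common Match. As query sets the
#' classes nest: Perfect is a subset of Best is a subset of Common (all
#' mappings); the stored label is the smallest applicable class. A mapping
#' additionally carries the Single Best Match flag when it is the only
#' mapping of its read attaining the minimum edit distance.
#'
#' @param mappings tibble from [read_mappings()].
#' @param stats optional precomputed [compute_read_stats()] table covering
#'   every read in `mappings`.
#' @return `mappings` with `mapping_count`, `min_mismatches`, `class`
#'   (factor PERFECT/BEST/COMMON) and `single_best_match` columns added.
#' @export
classify_mappings <- function(mappings, stats = NULL) {
  if (is.null(stats)) stats <- compute_read_stats(mappings)
  out <- mappings |>
    select(-dplyr::any_of(c("mapping_count", "min_mismatches", "class",
                            "single_best_match"))) |>
    left_join(stats, by = c("read_name", "mate"))
  if (any(is.na(out$mapping_count))) {
    stop("stats table does not cover every read")
  }
  attainers <- out |>
    filter(.data$mismatches == .data$min_mismatches) |>
    dplyr::count(.data$read_name, .data$mate, name = ".n_attain")
  out |>
    left_join(attainers, by = c("read_name", "mate")) |>
    mutate(
      class = factor(
        case_when(.data$mismatches == 0L ~ "PERFECT",
                  .data$mismatches == .data$min_mismatches ~ "BEST",
                  TRUE ~ "COMMON"),
        levels = MAPPING_CLASSES),
      single_best_match =
        .data$mismatches == .data$min_mismatches & .data$.n_attain == 1L) |>
    select(-".n_attain")
}

filter_class <- function(track, class_filter = "COMMON") {
  if (!"class" %in% names(track)) stop("track is not classified")
  filter(track, .data$class %in% class_members(class_filter))
}

resolve_interval <- function(track, genome, contig, from, to) {
  if (is.null(contig)) {
    contig <- if (!is.null(genome)) genome$contigs$contig[1] else
      track$contig[1]
  }
  if (is.null(to)) {
    to <- if (!is.null(genome)) contig_length(genome, contig) else
      max(track$stop[track$contig == contig], 1L)
  }
  list(contig = contig, from = as.integer(from), to = as.integer(to))
}

coverage_vector <- function(track, contig, to) {
  m <- track[track$contig == contig, ]
  cov <- IRanges::coverage(IRanges::IRanges(m$start, m$stop), width = to)
  as.integer(cov)
}

#' Class-resolved coverage of a track
#'
#' Per-position mapping coverage under the cumulative class semantics: the
#' PERFECT filter counts only Perfect mappings, BEST counts Perfect + Best,
#' COMMON counts all. Consequently coverage is non-decreasing from PERFECT
#' to COMMON at every position.
#'
#' @param track classified mapping tibble.
#' @param genome optional [ref_genome()] (supplies contig bounds).
#' @param contig,from,to interval to profile (defaults: first contig, whole
#'   contig).
#' @param class_filter `"PERFECT"`, `"BEST"` or `"COMMON"` (cumulative).
#' @param strand_mode `"combined"` (one row per position) or `"separate"`
#'   (one row per position and strand).
#' @return tibble with `contig`, `pos`, `strand` (`"*"` when combined) and
#'   `coverage`.
#' @export
coverage_profile <- function(track, genome = NULL, contig = NULL, from = 1,
                             to = NULL, class_filter = "COMMON",
                             strand_mode = c("combined", "separate")) {
  strand_mode <- match.arg(strand_mode)
  iv <- resolve_interval(track, genome, contig, from, to)
  m <- filter_class(track, class_filter)
  pos <- seq.int(iv$from, iv$to)
  if (strand_mode == "combined") {
    cov <- coverage_vector(m, iv$contig, iv$to)[pos]
    return(tibble(contig = iv$contig, pos = pos, strand = "*",
                  coverage = cov))
  }
  bind_rows(lapply(c("+", "-"), function(s) {
    cov <- coverage_vector(m[m$strand == s, ], iv$contig, iv$to)[pos]
    tibble(contig = iv$contig, pos = pos, strand = s, coverage = cov)
  }))
}

#' Per-position read-start counts
#'
#' Counts, per position and strand, the mappings whose biological 5' end
#' lies there: the leftmost aligned base for plus-strand mappings, the
#' rightmost for minus-strand mappings. This is the primary TSS signal.
#'
#' @inheritParams coverage_profile
#' @return tibble with `contig`, `pos`, `strand`, `read_starts` (one row per
#'   position and strand).
#' @export
read_start_counts <- function(track, genome = NULL, contig = NULL, from = 1,
                              to = NULL, class_filter = "COMMON") {
  iv <- resolve_interval(track, genome, contig, from, to)
  m <- filter_class(track, class_filter)
  m <- m[m$contig == iv$contig, ]
  pos <- seq.int(iv$from, iv$to)
  starts5 <- ifelse(m$strand == "+", m$start, m$stop)
  bind_rows(lapply(c("+", "-"), function(s) {
    cnt <- tabulate(starts5[m$strand == s], nbins = iv$to)[pos]
    tibble(contig = iv$contig, pos = pos, strand = s, read_starts = cnt)
  }))
}

#' Combine the coverage of several tracks
#'
#' Superimposes tracks on the same reference: `sum` adds coverage position
#' by position over any number of tracks; `difference` (exactly two tracks)
#' returns the signed per-position difference `track1 - track2`.
#'
#' @param tracks list of classified mapping tibbles.
#' @param mode `"sum"` or `"difference"`.
#' @inheritParams coverage_profile
#' @return coverage tibble as from [coverage_profile()] (strand combined).
#' @export
combine_tracks <- function(tracks, mode = c("sum", "difference"),
                           genome = NULL, contig = NULL, from = 1, to = NULL,
                           class_filter = "COMMON") {
  mode <- match.arg(mode)
  stopifnot(is.list(tracks), length(tracks) >= 2)
  if (mode == "difference" && length(tracks) != 2) {
    stop("difference mode needs exactly 2 tracks")
  }
  contigs <- unique(unlist(lapply(tracks, function(t) unique(t$contig))))
  iv <- resolve_interval(tracks[[1]], genome, contig, from, to)
  if (!is.null(genome) && !all(contigs %in% genome$contigs$contig)) {
    stop("tracks refer to contigs absent from the reference")
  }
  profs <- lapply(tracks, coverage_profile, genome = genome,
                  contig = iv$contig, from = iv$from, to = iv$to,
                  class_filter = class_filter)
  cov <- profs[[1]]$coverage
  for (p in profs[-1]) {
    cov <- if (mode == "sum") cov + p$coverage else cov - p$coverage
  }
  tibble(contig = iv$contig, pos = profs[[1]]$pos, strand = "*",
         coverage = cov)
}
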