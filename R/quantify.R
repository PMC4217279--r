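#' RPKM and read-count quantification of reference features
#'
#' Counts, for every annotated feature, the reads (admitted by
#' `class_filter`) whose alignment overlaps the feature -- each read at most
#' once per feature -- and derives the RPKM value
#' `read_count * 1e9 / (total_mapped_reads * feature_length_bp)`, i.e.
#' total feature reads per million mapped reads per kilobase of feature.
#' Results can be filtered by closed RPKM and read-count intervals.
#'
#' @param track classified mapping tibble.
#' @param genome [ref_genome()].
#' @param class_filter mapping-class filter (cumulative).
#' @param min_rpkm,max_rpkm,min_count,max_count closed filter intervals.
#' @return tibble with `feature_id`, `contig`, `type`, `length`,
#'   `read_count`, `rpkm`.
#' @export
quantify_features <- function(track, genome, class_filter = "COMMON",
                              min_rpkm = 0, max_rpkm = Inf, min_count = 0,
                              max_count = Inf) {
  m <- filter_class(track, class_filter)
  total_mapped <- nrow(distinct(m, .data$read_name, .data$mate))
  if (total_mapped == 0) stop("no mapped reads in the chosen classes")
  f <- genome$features
  zero_len <- f$stop < f$start
  if (any(zero_len)) {
    warning("skipping zero-length features: ",
            paste(f$feature_id[zero_len], collapse = ", "))
    f <- f[!zero_len, , drop = FALSE]
  }
  counts <- purrr::map_dfr(unique(f$contig), function(ctg) {
    fc <- f[f$contig == ctg, , drop = FALSE]
    mc <- distinct(m[m$contig == ctg, ],
                   .data$read_name, .data$mate, .data$start, .data$stop)
    hits <- IRanges::findOverlaps(IRanges::IRanges(fc$start, fc$stop),
                                  IRanges::IRanges(mc$start, mc$stop))
    per_feat <- tibble(idx = S4Vectors::queryHits(hits),
                       read = paste(mc$read_name[S4Vectors::subjectHits(hits)],
                                    mc$mate[S4Vectors::subjectHits(hits)])) |>
      distinct() |>
      dplyr::count(.data$idx, name = "read_count")
    fc$read_count <- 0L
    fc$read_count[per_feat$idx] <- per_feat$read_count
    fc
  })
  counts |>
    mutate(length = .data$stop - .data$start + 1L,
           rpkm = .data$read_count * 1e9 / (total_mapped * .data$length)) |>
    filter(.data$rpkm >= min_rpkm, .data$rpkm <= max_rpkm,
           .data$read_count >= min_count, .data$read_count <= max_count) |>
    select("feature_id", "contig", "type", "length", "read_count", "rpkm")
}

#' Feature coverage analysis
#'
#' For every feature, computes the share of its bases covered by at least
#' `min_coverage` mappings and the mean coverage, then lists the features
#' whose covered share reaches `min_covered_percent` (mode `"covered"`) or
#' falls below it (mode `"uncovered"`). The two modes partition the feature
#' set.
#'
#' @param track classified mapping tibble.
#' @param genome [ref_genome()].
#' @param min_coverage per-base coverage needed for a base to count as
#'   covered.
#' @param min_covered_percent percent threshold on the covered share.
#' @param mode `"covered"` or `"uncovered"`.
#' @param class_filter mapping-class filter (cumulative).
#' @return tibble with `feature_id`, `contig`, `type`, `percent_covered`,
#'   `mean_coverage`.
#' @export
feature_coverage <- function(track, genome, min_coverage = 1,
                             min_covered_percent = 90,
                             mode = c("covered", "uncovered"),
                             class_filter = "COMMON") {
  mode <- match.arg(mode)
  m <- filter_class(track, class_filter)
  f <- genome$features
  out <- purrr::map_dfr(unique(f$contig), function(ctg) {
    fc <- f[f$contig == ctg, , drop = FALSE]
    cov <- coverage_vector(m[m$contig == ctg, ], ctg,
                           contig_length(genome, ctg))
    purrr::pmap_dfr(fc[, c("feature_id", "type", "start", "stop")],
                    function(feature_id, type, start, stop) {
      fcov <- cov[start:stop]
      tibble(feature_id = feature_id, contig = ctg, type = type,
             percent_covered = 100 * mean(fcov >= min_coverage),
             mean_coverage = mean(fcov))
    })
  })
  if (mode == "covered") {
    filter(out, .data$percent_covered >= min_covered_percent)
  } else {
    filter(out, .data$percent_covered < min_covered_percent)
  }
}

#' General coverage analysis
#'
#' Reports the maximal runs of consecutive positions whose coverage lies
#' below (`mode = "below"`, strict `<`) or at/above (`mode = "above"`,
#' `>=`) a threshold; for a fixed threshold the two modes partition each
#' contig. The threshold is either absolute or a multiple of the
#' genome-wide mean coverage (`threshold_mode = "mean-multiple"`).
#'
#' @param track classified mapping tibble.
#' @param genome [ref_genome()].
#' @param mode `"below"` or `"above"`.
#' @param threshold_mode `"absolute"` or `"mean-multiple"`.
#' @param threshold threshold value or mean multiplier.
#' @param class_filter mapping-class filter (cumulative).
#' @return tibble of disjoint sorted intervals: `contig`, `start`, `stop`,
#'   `width`, `mean_coverage`.
#' @export
coverage_regions <- function(track, genome, mode = c("below", "above"),
                             threshold_mode = c("absolute", "mean-multiple"),
                             threshold = 1, class_filter = "COMMON") {
  mode <- match.arg(mode)
  threshold_mode <- match.arg(threshold_mode)
  m <- filter_class(track, class_filter)
  covs <- lapply(genome$contigs$contig, function(ctg) {
    coverage_vector(m[m$contig == ctg, ], ctg, contig_length(genome, ctg))
  })
  names(covs) <- genome$contigs$contig
  resolved <- if (threshold_mode == "absolute") threshold else {
    threshold * mean(unlist(covs))
  }
  purrr::map_dfr(genome$contigs$contig, function(ctg) {
    cov <- covs[[ctg]]
    hit <- if (mode == "below") cov < resolved else cov >= resolved
    r <- rle(hit)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    tibble(contig = ctg, start = starts[keep], stop = stops[keep]) |>
      mutate(width = .data$stop - .data$start + 1L,
             mean_coverage = purrr::map2_dbl(.data$start, .data$stop,
                                             ~ mean(cov[.x:.y])))
  })
}
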