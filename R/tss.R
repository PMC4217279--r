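#' Tie-aware upper-quantile cutoff
#'
#' Returns the smallest observed value `v` such that at most
#' `ceiling(mass * length(x))` elements of `x` satisfy `x >= v`; when no
#' observed value qualifies (e.g. a constant vector), `max(x) + 1`. A
#' position is "in the upper `mass` quantile of all other values" exactly
#' when its value reaches this cutoff, so the number of admitted positions
#' is guaranteed to stay within the quantile mass even on heavily tied
#' discrete data.
#'
#' @param x numeric vector of per-position statistics.
#' @param mass upper-tail mass, e.g. 0.0025.
#' @return scalar cutoff.
#' @export
upper_quantile_cutoff <- function(x, mass) {
  stopifnot(length(x) > 0, mass > 0, mass < 1)
  bound <- ceiling(mass * length(x))
  ux <- sort(unique(x))
  freq <- tabulate(match(x, ux), nbins = length(ux))
  count_ge <- rev(cumsum(rev(freq)))
  ok <- which(count_ge <= bound)
  if (length(ok) > 0) ux[min(ok)] else max(x) + 1
}

#' TSS detection parameters
#'
#' Bundle of the two balancing detection thresholds and the windowing
#' parameters. A position is a TSS candidate only when both criteria hold:
#' its read-start count reaches `min_read_starts` and its percent coverage
#' increase over the upstream neighbour reaches `min_percent_increase`.
#'
#' @param min_read_starts minimum read starts at the position.
#' @param min_percent_increase minimum percent coverage increase from the
#'   upstream neighbour (100 * (cov2 - cov1) / max(cov1, 1)).
#' @param collapse_window bp window in which only the best-scoring position
#'   is reported (default 3).
#' @param association_window bp window around a TSS searched for an
#'   annotated feature start (default 1000).
#' @param transcript_end_coverage coverage below which a suggested novel
#'   transcript ends (default 1).
#' @param class_filter mapping-class filter used for coverage and read
#'   starts (default `"BEST"`, cumulative).
#' @param quantile_mass upper-tail mass used by the auto-estimator.
#' @param auto_estimated whether the thresholds came from
#'   [estimate_tss_parameters()].
#' @return object of class `tss_parameters`.
#' @export
tss_parameters <- function(min_read_starts, min_percent_increase,
                           collapse_window = 3, association_window = 1000,
                           transcript_end_coverage = 1,
                           class_filter = "BEST", quantile_mass = 0.0025,
                           auto_estimated = FALSE) {
  structure(list(min_read_starts = min_read_starts,
                 min_percent_increase = min_percent_increase,
                 collapse_window = collapse_window,
                 association_window = association_window,
                 transcript_end_coverage = transcript_end_coverage,
                 class_filter = class_filter,
                 quantile_mass = quantile_mass,
                 auto_estimated = auto_estimated),
            class = "tss_parameters")
}

#' @export
print.tss_parameters <- function(x, ...) {
  cat("<tss_parameters> min_read_starts=", x$min_read_starts,
      ", min_percent_increase=", round(x$min_percent_increase, 2),
      if (x$auto_estimated) paste0(" (auto, mass=", x$quantile_mass, ")"),
      "\n", sep = "")
  invisible(x)
}

# Per-strand coverage and detection statistics for one contig, oriented in
# the strand's transcription direction. The upstream neighbour of position
# p is p-1 on the plus strand and p+1 on the minus strand; the first
# position in transcription direction has no pair and gets NA increase.
strand_scan <- function(track, genome, contig, strand, class_filter) {
  len <- contig_length(genome, contig)
  m <- filter_class(track, class_filter)
  m <- m[m$contig == contig & m$strand == strand, , drop = FALSE]
  cov <- coverage_vector(m, contig, len)
  starts5 <- if (strand == "+") m$start else m$stop
  rs <- tabulate(starts5, nbins = len)
  upstream <- if (strand == "+") c(NA, cov[-len]) else c(cov[-1], NA)
  inc <- 100 * (cov - upstream) / pmax(upstream, 1)
  tibble(pos = seq_len(len), strand = strand, coverage = cov,
         read_starts = rs, upstream = upstream, percent_increase = inc)
}

#' Estimate TSS detection thresholds from the track itself
#'
#' Sets both thresholds to tie-aware upper-`quantile_mass` cutoffs of the
#' track-wide empirical distributions: `min_read_starts` from the
#' per-position read-start counts and `min_percent_increase` from the
#' per-position-pair percent coverage increases, each pooled over both
#' strands of all contigs. With the default mass of 0.0025 each criterion
#' admits at most 2.5 positions per kb of scanned positions.
#'
#' @param track classified mapping tibble (at least one mapped read).
#' @param genome [ref_genome()].
#' @param quantile_mass upper-tail mass (default 0.0025).
#' @inheritParams tss_parameters
#' @return a [tss_parameters()] object with `auto_estimated = TRUE`.
#' @export
estimate_tss_parameters <- function(track, genome, quantile_mass = 0.0025,
                                    class_filter = "BEST",
                                    collapse_window = 3,
                                    association_window = 1000,
                                    transcript_end_coverage = 1) {
  if (nrow(track) == 0) stop("cannot estimate parameters from an empty track")
  scans <- purrr::map_dfr(
    intersect(genome$contigs$contig, unique(track$contig)),
    function(ctg) bind_rows(
      strand_scan(track, genome, ctg, "+", class_filter),
      strand_scan(track, genome, ctg, "-", class_filter)))
  min_rs <- max(upper_quantile_cutoff(scans$read_starts, quantile_mass), 1)
  inc <- scans$percent_increase[!is.na(scans$percent_increase)]
  min_inc <- upper_quantile_cutoff(inc, quantile_mass)
  tss_parameters(min_read_starts = min_rs, min_percent_increase = min_inc,
                 collapse_window = collapse_window,
                 association_window = association_window,
                 transcript_end_coverage = transcript_end_coverage,
                 class_filter = class_filter, quantile_mass = quantile_mass,
                 auto_estimated = TRUE)
}

# Collapse qualifying positions: within each collapse_window run, keep the
# position with the most read starts, ties resolved toward the 5' end.
collapse_candidates <- function(cand, window, strand) {
  if (nrow(cand) == 0) return(cand)
  cand <- arrange(cand, .data$pos)
  grp <- cumsum(c(1, diff(cand$pos) > (window - 1)))
  cand$.grp <- grp
  five_first <- if (strand == "+") cand$pos else -cand$pos
  cand$.ord <- five_first
  cand |>
    group_by(.data$.grp) |>
    arrange(dplyr::desc(.data$read_starts), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".grp", -".ord") |>
    arrange(.data$pos)
}

categorize_tss <- function(pos, strand, contig, genome, scan_cov, params) {
  f <- genome$features[genome$features$contig == contig, , drop = FALSE]
  same <- f[f$strand == strand, , drop = FALSE]
  res <- list(category = "trans-encoded", associated_feature = NA_character_,
              novel_transcript_stop = NA_integer_)
  if (nrow(same) > 0) {
    five <- ifelse(same$strand == "+", same$start, same$stop)
    d <- abs(five - pos)
    hit <- which(d <= params$association_window)
    if (length(hit) > 0) {
      res$category <- "annotated-start"
      res$associated_feature <- same$feature_id[hit[which.min(d[hit])]]
      return(res)
    }
  }
  inside <- f[f$start <= pos & f$stop >= pos, , drop = FALSE]
  if (any(inside$strand == strand)) {
    res$category <- "novel"
  } else if (nrow(inside) > 0) {
    res$category <- "cis-antisense"
  }
  # suggest a transcript from the TSS to where coverage drops below the
  # user threshold
  len <- length(scan_cov)
  run <- pos
  step <- if (strand == "+") 1L else -1L
  while (run + step >= 1L && run + step <= len &&
         scan_cov[run + step] >= params$transcript_end_coverage) {
    run <- run + step
  }
  res$novel_transcript_stop <- if (scan_cov[pos] >= params$transcript_end_coverage) run else pos
  res
}

#' Detect transcription start sites
#'
#' Scans, per strand and in transcription direction, every pair of
#' neighbouring positions of a 5'-enriched track. A position is reported as
#' TSS when enough reads start there and the percent coverage increase from
#' its upstream neighbour is high enough (both thresholds from `params`);
#' the increase criterion rejects positions inside already highly covered
#' regions. Within each `collapse_window` only the position with the most
#' read starts is kept (ties toward the 5'-most position). Each TSS is then
#' associated with the nearest same-strand feature whose 5' end lies within
#' `association_window` (category `annotated-start`); unassociated TSS are
#' categorised `novel` (inside a same-strand feature), `cis-antisense`
#' (inside an opposite-strand feature) or `trans-encoded` (intergenic), and
#' a novel transcript is suggested from the TSS up to the last position
#' with coverage at or above `transcript_end_coverage`.
#'
#' @param track classified mapping tibble.
#' @param genome [ref_genome()].
#' @param params a [tss_parameters()] object; when `NULL`, parameters are
#'   auto-estimated with [estimate_tss_parameters()].
#' @param contig contig to scan (default: all contigs in the track).
#' @return tibble with `contig`, `position`, `strand`, `read_starts`,
#'   `percent_increase`, `category`, `associated_feature`,
#'   `novel_transcript_stop` (NA for annotated starts).
#' @export
detect_tss <- function(track, genome, params = NULL, contig = NULL) {
  if (is.null(params)) params <- estimate_tss_parameters(track, genome)
  contigs <- if (is.null(contig)) {
    intersect(genome$contigs$contig, unique(track$contig))
  } else contig
  out <- purrr::map_dfr(contigs, function(ctg) {
    purrr::map_dfr(c("+", "-"), function(s) {
      scan <- strand_scan(track, genome, ctg, s, params$class_filter)
      cand <- filter(scan, !is.na(.data$percent_increase),
                     .data$read_starts >= params$min_read_starts,
                     .data$percent_increase >= params$min_percent_increase)
      cand <- collapse_candidates(cand, params$collapse_window, s)
      if (nrow(cand) == 0) return(NULL)
      cats <- purrr::map_dfr(cand$pos, function(p) {
        as_tibble(categorize_tss(p, s, ctg, genome, scan$coverage, params))
      })
      tibble(contig = ctg, position = cand$pos, strand = s,
             read_starts = cand$read_starts,
             percent_increase = cand$percent_increase) |>
        bind_cols(cats) |>
        mutate(novel_transcript_stop = ifelse(
          .data$category == "annotated-start", NA_integer_,
          .data$novel_transcript_stop))
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(contig = character(), position = integer(),
                  strand = character(), read_starts = integer(),
                  percent_increase = double(), category = character(),
                  associated_feature = character(),
                  novel_transcript_stop = integer())
  }
  arrange(out, .data$contig, .data$position, .data$strand)
}
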