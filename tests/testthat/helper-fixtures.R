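# Hand-built fixtures and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (per-position loops, direct formula
# evaluation) and never call the code paths they check.

mk_mapping <- function(read_name, start, len = 50L, strand = "+", nm = 0L,
                       contig = "chr", mate = 1L, cigar = NULL, seq = NA,
                       flag = NULL) {
  cigar <- cigar %||% paste0(len, "M")
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  flag <- flag %||% (if (strand == "-") 16L else 0L)
  tibble::tibble(read_name = read_name, mate = as.integer(mate),
                 flag = as.integer(flag), contig = contig,
                 start = as.integer(start),
                 stop = as.integer(start + width - 1L), strand = strand,
                 cigar = cigar, seq = as.character(seq),
                 mismatches = as.integer(nm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

# --- codon oracle: enumerate every 3-mer on both strands --------------------

oracle_find_codons <- function(seq, code, kinds) {
  revcomp1 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  wanted <- switch(kinds,
                   start = code$start_codons,
                   stop = code$stop_codons,
                   both = union(code$start_codons, code$stop_codons))
  len <- nchar(seq)
  rows <- list()
  for (p in seq_len(len - 2L)) {
    fwd <- substring(seq, p, p + 2L)
    rev_chars <- rev(strsplit(fwd, "")[[1]])
    rev <- paste(revcomp1[rev_chars], collapse = "")
    if (fwd %in% wanted) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = p, strand = "+", frame = ((p - 1L) %% 3L) + 1L,
        codon = fwd,
        kind = if (fwd %in% code$stop_codons) "stop" else "start")
    }
    if (rev %in% wanted) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = p, strand = "-",
        frame = ((len - (p + 2L)) %% 3L) + 1L, codon = rev,
        kind = if (rev %in% code$stop_codons) "stop" else "start")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  if (kinds != "both") out <- out[out$kind == kinds, , drop = FALSE]
  dplyr::arrange(out, position, strand)
}

# --- express oracle: direct evaluation of the printed formulas --------------

oracle_express <- function(A, B) {
  k <- nrow(A)
  out <- data.frame(mean_a = double(k), mean_b = double(k),
                    var_a = double(k), var_b = double(k),
                    ratio_ab = double(k), ratio_ba = double(k),
                    confidence = double(k))
  for (i in seq_len(k)) {
    wa <- ncol(A); wb <- ncol(B)
    ma <- sum(A[i, ]) / wa
    mb <- sum(B[i, ]) / wb
    va <- if (wa > 1) sum((A[i, ] - ma)^2) / (wa - 1) else 0
    vb <- if (wb > 1) sum((B[i, ] - mb)^2) / (wb - 1) else 0
    out$mean_a[i] <- ma; out$mean_b[i] <- mb
    out$var_a[i] <- va; out$var_b[i] <- vb
    out$ratio_ab[i] <- ma / (if (mb == 0) 1 else mb)
    out$ratio_ba[i] <- mb / (if (ma == 0) 1 else ma)
    out$confidence[i] <- if (ma == 0 || mb == 0) -1 else {
      -log10(0.5 * (va / ma + vb / mb))
    }
  }
  out
}

# --- TSS oracle: per-position loops over every neighbouring pair ------------

oracle_tss_positions <- function(mappings, len, min_read_starts,
                                 min_percent_increase, collapse_window = 3) {
  out <- list()
  for (s in c("+", "-")) {
    mm <- mappings[mappings$strand == s, , drop = FALSE]
    cov <- integer(len); rs <- integer(len)
    for (p in seq_len(len)) {
      cov[p] <- sum(mm$start <= p & mm$stop >= p)
      five <- if (s == "+") mm$start else mm$stop
      rs[p] <- sum(five == p)
    }
    cand <- integer(0)
    for (p in seq_len(len)) {
      up <- if (s == "+") p - 1L else p + 1L
      if (up < 1L || up > len) next
      inc <- 100 * (cov[p] - cov[up]) / max(cov[up], 1)
      if (rs[p] >= min_read_starts && inc >= min_percent_increase) {
        cand <- c(cand, p)
      }
    }
    if (length(cand) > 0) {
      grp <- cumsum(c(1, diff(cand) > (collapse_window - 1)))
      kept <- vapply(split(cand, grp), function(ps) {
        best <- ps[rs[ps] == max(rs[ps])]
        if (s == "+") min(best) else max(best)
      }, double(1))
      out[[s]] <- tibble::tibble(position = as.integer(unname(kept)),
                                 strand = s)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(position = integer(), strand = character())
  }
  dplyr::arrange(res, position, strand)
}

# small annotated genome shared by several tests
toy_genome <- function(len = 2000, seed = 42) {
  tracktools::simulate_reference(genome_length = len, n_genes = 0,
                                 seed = seed)
}
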