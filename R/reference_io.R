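#' Reference genome container
#'
#' A `ref_genome` bundles one or more contig sequences with their annotated
#' features. Coordinates are 1-based, fully closed intervals on the forward
#' strand; the strand of a feature is carried separately, so `start <= stop`
#' always holds. Sequences are uppercase A/C/G/T/N; lowercase input is
#' uppercased and any other character becomes N with a warning.
#'
#' @param sequences named character vector of contig sequences.
#' @param features tibble with columns `contig`, `feature_id`, `type`,
#'   `start`, `stop`, `strand`, `locus_tag`, `product`. May have zero rows.
#' @return An object of class `ref_genome` with elements `contigs` (tibble of
#'   `contig`, `length`), `sequences`, and `features` (sorted by start).
#' @export
ref_genome <- function(sequences, features = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)))
  sequences <- vapply(sequences, sanitize_sequence, character(1))
  if (is.null(features)) features <- empty_features()
  features <- as_tibble(features)
  for (col in c("locus_tag", "product")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  if (!"contig" %in% names(features)) features$contig <- names(sequences)[1]
  features <- features[, c("contig", "feature_id", "type", "start", "stop",
                           "strand", "locus_tag", "product")]
  features$start <- as.integer(features$start)
  features$stop <- as.integer(features$stop)
  lens <- setNames(nchar(sequences), names(sequences))
  bad <- features$start < 1L | features$stop > lens[features$contig] |
    features$start > features$stop
  if (any(bad)) {
    stop("features outside sequence bounds: ",
         paste(features$feature_id[bad], collapse = ", "))
  }
  features <- arrange(features, .data$contig, .data$start, .data$stop)
  structure(
    list(contigs = tibble(contig = names(sequences), length = unname(lens)),
         sequences = sequences, features = features),
    class = "ref_genome")
}

empty_features <- function() {
  tibble(contig = character(), feature_id = character(), type = character(),
         start = integer(), stop = integer(), strand = character(),
         locus_tag = character(), product = character())
}

sanitize_sequence <- function(x) {
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    warning("non-ACGTN characters in sequence replaced by N")
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", nrow(x$contigs), " contig(s), ",
      sum(x$contigs$length), " bp, ", nrow(x$features), " feature(s)\n",
      sep = "")
  invisible(x)
}

#' @export
length.ref_genome <- function(x) sum(x$contigs$length)

ref_seq <- function(genome, contig = NULL) {
  if (is.null(contig)) contig <- genome$contigs$contig[1]
  s <- genome$sequences[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  s
}

contig_length <- function(genome, contig = NULL) {
  if (is.null(contig)) contig <- genome$contigs$contig[1]
  len <- genome$contigs$length[match(contig, genome$contigs$contig)]
  if (is.na(len)) stop("unknown contig: ", contig)
  len
}

FEATURE_TYPES <- c("gene", "CDS", "rRNA", "tRNA", "ncRNA", "misc_RNA")

normalize_feature_type <- function(type) {
  ifelse(type %in% FEATURE_TYPES, type, "other")
}

#' Load a reference genome
#'
#' Reads a reference sequence and its annotation from FASTA, GenBank or EMBL
#' flat files, or GFF2/GFF3. A GFF file needs its sequence from an embedded
#' `##FASTA` section, a sibling `.fa`/`.fasta` file, or the `fasta` argument.
#' Plain FASTA yields a featureless genome.
#'
#' @param path path to the reference file.
#' @param format one of `"auto"`, `"fasta"`, `"genbank"`, `"embl"`, `"gff3"`,
#'   `"gff2"`. `"auto"` sniffs the extension and first line.
#' @param fasta optional FASTA path supplying sequence for GFF input.
#' @return A [ref_genome()].
#' @export
load_reference <- function(path, format = c("auto", "fasta", "genbank",
                                            "embl", "gff3", "gff2"),
                           fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
    fasta = load_fasta(path),
    genbank = parse_flatfile(path, dialect = "genbank"),
    embl = parse_flatfile(path, dialect = "embl"),
    gff3 = load_gff(path, version = 3, fasta = fasta),
    gff2 = load_gff(path, version = 2, fasta = fasta))
}

sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) return("fasta")
  if (ext %in% c("gb", "gbk", "gbff", "genbank")) return("genbank")
  if (ext %in% c("embl", "ebl")) return("embl")
  if (ext %in% c("gff3")) return("gff3")
  if (ext %in% c("gff", "gff2")) {
    first <- readLines(path, n = 1)
    return(if (grepl("gff-version\\s+3", first)) "gff3" else
           if (grepl("gff-version", first)) "gff2" else "gff3")
  }
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) return("fasta")
  if (startsWith(first, "LOCUS")) return("genbank")
  if (startsWith(first, "ID")) return("embl")
  if (grepl("gff-version\\s+3", first)) return("gff3")
  if (grepl("gff-version", first)) return("gff2")
  stop("cannot determine reference format of ", path)
}

load_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ref_genome(seqs)
}

load_gff <- function(path, version = 3, fasta = NULL) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")[1]
  seqs <- NULL
  if (!is.na(fasta_at)) {
    fa_tmp <- tempfile(fileext = ".fa")
    writeLines(lines[(fasta_at + 1):length(lines)], fa_tmp)
    seqs <- load_fasta(fa_tmp)$sequences
    lines <- lines[seq_len(fasta_at - 1)]
  } else if (!is.null(fasta)) {
    seqs <- load_fasta(fasta)$sequences
  } else {
    sib <- c(paste0(tools::file_path_sans_ext(path), ".fa"),
             paste0(tools::file_path_sans_ext(path), ".fasta"))
    sib <- sib[file.exists(sib)]
    if (length(sib) == 0) {
      stop("GFF input needs sequence: embedded ##FASTA, sibling .fa/.fasta, ",
           "or the `fasta` argument")
    }
    seqs <- load_fasta(sib[1])$sequences
  }
  gff_tmp <- tempfile(fileext = if (version == 3) ".gff3" else ".gff")
  writeLines(lines, gff_tmp)
  gr <- if (version == 3) {
    rtracklayer::import(gff_tmp, format = "gff3")
  } else {
    rtracklayer::import(gff_tmp, format = "gff2")
  }
  md <- S4Vectors::mcols(gr)
  get_col <- function(nm) {
    if (nm %in% names(md)) as.character(md[[nm]]) else
      rep(NA_character_, length(gr))
  }
  ids <- get_col("ID")
  if (all(is.na(ids))) ids <- get_col("gene_id")
  ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
  features <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    feature_id = ids,
    type = normalize_feature_type(as.character(md$type)),
    start = GenomicRanges::start(gr),
    stop = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    locus_tag = get_col("locus_tag"),
    product = get_col("product"))
  features <- filter(features, !.data$type %in% "other" |
                       !as.character(md$type) %in% c("region", "chromosome"))
  ref_genome(seqs, features)
}

# Minimal GenBank/EMBL flat-file reader: header id, FEATURES table
# (single-range and complement() locations; join() collapsed to its span),
# ORIGIN/SQ sequence block. Qualifiers kept: locus_tag, gene, product.
parse_flatfile <- function(path, dialect = c("genbank", "embl")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "genbank") {
    id_line <- grep("^LOCUS", lines, value = TRUE)[1]
    if (is.na(id_line)) stop("not a GenBank flat file (no LOCUS): ", path)
    contig <- strsplit(trimws(sub("^LOCUS", "", id_line)), "\\s+")[[1]][1]
    feat_start <- grep("^FEATURES", lines)[1]
    seq_start <- grep("^ORIGIN", lines)[1]
    if (is.na(seq_start)) stop("no ORIGIN section in ", path)
    seq_lines <- lines[(seq_start + 1):length(lines)]
    feat_lines <- if (!is.na(feat_start)) {
      lines[(feat_start + 1):(seq_start - 1)]
    } else character()
    key_re <- "^ {5}(\\S+) +(.*)$"
  } else {
    id_line <- grep("^ID ", lines, value = TRUE)[1]
    if (is.na(id_line)) stop("not an EMBL flat file (no ID): ", path)
    contig <- strsplit(trimws(sub("^ID", "", id_line)), "[;\\s]+")[[1]][1]
    seq_start <- grep("^SQ", lines)[1]
    if (is.na(seq_start)) stop("no SQ section in ", path)
    seq_lines <- lines[(seq_start + 1):length(lines)]
    feat_lines <- sub("^FT", "  ", grep("^FT", lines, value = TRUE))
    key_re <- "^ {2} {3}(\\S+) +(.*)$"
  }
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  features <- parse_feature_table(feat_lines, contig, key_re)
  ref_genome(setNames(sequence, contig), features)
}

parse_feature_table <- function(feat_lines, contig, key_re) {
  if (length(feat_lines) == 0) return(empty_features())
  is_key <- grepl(key_re, feat_lines)
  idx <- cumsum(is_key)
  recs <- split(feat_lines[idx > 0], idx[idx > 0])
  rows <- purrr::imap(recs, function(block, i) {
    key <- sub(key_re, "\\1", block[1])
    rest <- paste(trimws(c(sub(key_re, "\\2", block[1]), block[-1])),
                  collapse = "")
    # location runs until the first qualifier
    loc <- sub("/.*$", "", rest)
    quals <- regmatches(rest, gregexpr('/[a-z_]+=(("[^"]*")|[^/ ]+)',
                                       rest))[[1]]
    qual <- function(nm) {
      hit <- grep(paste0("^/", nm, "="), quals, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      gsub('^"|"$', "", sub("^/[a-z_]+=", "", hit[1]))
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) == 0) return(NULL)
    if (grepl("join", loc) && length(nums) > 2) {
      warning("join() location collapsed to its span for feature ", key)
    }
    id <- qual("locus_tag")
    if (is.na(id)) id <- qual("gene")
    if (is.na(id)) id <- paste0(key, "_", i)
    tibble(contig = contig, feature_id = id,
           type = normalize_feature_type(key),
           start = min(nums), stop = max(nums), strand = strand,
           locus_tag = qual("locus_tag"), product = qual("product"))
  })
  rows <- purrr::compact(rows)
  feats <- if (length(rows)) bind_rows(rows) else empty_features()
  filter(feats, !.data$type == "other" |
           !grepl("^(source)", .data$feature_id))
}

#' Write a genome as normalized FASTA + GFF3
#'
#' @param genome a [ref_genome()].
#' @param fasta_path,gff_path output paths.
#' @return `genome`, invisibly.
#' @export
write_reference <- function(genome, fasta_path, gff_path) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, fasta_path)
  f <- genome$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     genome$contigs$contig, genome$contigs$length))
  if (nrow(f) > 0) {
    attrs <- paste0("ID=", f$feature_id,
                    ifelse(is.na(f$locus_tag), "",
                           paste0(";locus_tag=", f$locus_tag)),
                    ifelse(is.na(f$product), "",
                           paste0(";product=", f$product)))
    lines <- c(lines, paste(f$contig, "tracktools", f$type, f$start, f$stop,
                            ".", f$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, gff_path)
  invisible(genome)
}

#' NCBI genetic code tables
#'
#' Wraps the NCBI translation tables with explicit start- and stop-codon
#' sets. Start codons are ATG plus the table's alternative initiation codons.
#'
#' @param table_id NCBI translation table identifier (default 11, the
#'   bacterial/archaeal/plastid code).
#' @return An object of class `genetic_code` with `table_id`, `codons`
#'   (named character of length 64), `start_codons` and `stop_codons`.
#' @export
genetic_code <- function(table_id = 11) {
  codons <- Biostrings::getGeneticCode(as.character(table_id))
  structure(
    list(table_id = table_id,
         codons = setNames(as.character(codons), names(codons)),
         start_codons = union("ATG", attr(codons, "alt_init_codons")),
         stop_codons = names(codons)[codons == "*"]),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table ", x$table_id, "; starts: ",
      paste(x$start_codons, collapse = ","), "; stops: ",
      paste(x$stop_codons, collapse = ","), "\n", sep = "")
  invisible(x)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_codons <- function(codons, code) {
  aa <- code$codons[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Locate start and stop codons in all six reading frames
#'
#' Scans every 3-mer on both strands of a contig and reports those matching
#' the code's start and/or stop codons. `position` is the leftmost reference
#' base of the codon on both strands; on the minus strand the codon is read
#' from the reverse complement. Frames are numbered 1-3 per strand: on the
#' plus strand from the 5' end of the forward sequence, on the minus strand
#' from the 5' end of the reverse complement.
#'
#' @param genome a [ref_genome()].
#' @param code a [genetic_code()].
#' @param kinds `"start"`, `"stop"` or `"both"`.
#' @param contig contig to scan (default: first).
#' @return tibble with `contig`, `position`, `strand`, `frame`, `codon`,
#'   `kind`, sorted by position.
#' @export
find_codons <- function(genome, code = genetic_code(11),
                        kinds = c("both", "start", "stop"), contig = NULL) {
  kinds <- match.arg(kinds)
  if (is.null(contig)) contig <- genome$contigs$contig[1]
  seq <- ref_seq(genome, contig)
  len <- nchar(seq)
  if (len < 3) stop("contig shorter than one codon")
  wanted <- switch(kinds,
    start = code$start_codons,
    stop = code$stop_codons,
    both = union(code$start_codons, code$stop_codons))
  pos <- seq_len(len - 2L)
  fwd <- substring(seq, pos, pos + 2L)
  rev <- reverse_complement(fwd)
  hit_f <- fwd %in% wanted
  hit_r <- rev %in% wanted
  kind_of <- function(codon) {
    ifelse(codon %in% code$stop_codons, "stop", "start")
  }
  out <- bind_rows(
    tibble(contig = contig, position = pos[hit_f], strand = "+",
           frame = ((pos[hit_f] - 1L) %% 3L) + 1L, codon = fwd[hit_f]),
    tibble(contig = contig, position = pos[hit_r], strand = "-",
           frame = ((len - (pos[hit_r] + 2L)) %% 3L) + 1L,
           codon = rev[hit_r]))
  out$kind <- kind_of(out$codon)
  if (kinds != "both") out <- filter(out, .data$kind == kinds)
  arrange(out, .data$position, .data$strand)
}
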