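#' Filter thresholds for NUMT calls
#'
#' @param max_evalue maximum e-value (default 1e-4).
#' @param min_identity identity must be strictly greater than this
#'   percentage (default 63).
#' @param min_length minimum nuclear (subject) interval length in bases,
#'   inclusive (default 28).
#' @return a `FilterThresholds` list.
#' @export
filter_thresholds <- function(max_evalue = 1e-4, min_identity = 63,
                              min_length = 28L) {
  stopifnot(max_evalue > 0, min_identity >= 0, min_identity <= 100,
            min_length >= 1)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_length = as.integer(min_length)),
            class = "FilterThresholds")
}

#' Exact-match seeds between a query and a subject
#'
#' Enumerates maximal exact matches of length at least `word_size` between
#' the query and the subject (forward strand) and between the query and the
#' reverse complement of the subject (minus strand). Each maximal match is
#' reported once.
#'
#' @param query,subject DNA character strings (or `DNAString`s).
#' @param word_size minimum exact-match length (>= 4; default 11, the
#'   standard nucleotide word size).
#' @param both_strands search the minus strand as well (default TRUE).
#' @return data.frame with `qstart`, `sstart` (1-based, forward-strand
#'   leftmost coordinates), `length` and `strand`.
#' @export
seed_hits <- function(query, subject, word_size = 11L, both_strands = TRUE) {
  stopifnot(word_size >= 4L)
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  fwd <- cpp_seed_hits(query, subject, as.integer(word_size))
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (both_strands) {
    n <- nchar(subject)
    rev <- cpp_seed_hits(query, revcomp_chr(subject), as.integer(word_size))
    if (nrow(rev)) {
      # convert the reverse-complement coordinate to the forward-strand
      # leftmost base of the matched subject segment
      rev$sstart <- n - (rev$sstart + rev$length)
      rev$strand <- rep("-", nrow(rev))
      out <- rbind(fwd, rev)
    }
  }
  out$qstart <- out$qstart + 1L
  out$sstart <- out$sstart + 1L
  out[order(out$qstart, out$sstart), , drop = FALSE]
}

# shared X-drop default: score units the running optimum may be undercut by
# before an extension front is abandoned
.default_x_drop <- 20L

#' Extend a seed into a gapped local alignment
#'
#' Runs X-drop dynamic programming (Gotoh affine gaps; a gap of length g
#' costs `gap_open + gap_extend * g`) leftwards and rightwards from the seed,
#' which is scored as exact matches. On small inputs the returned score
#' equals the full Smith-Waterman-Gotoh optimum whenever that optimum passes
#' through the seed and never dips more than `x_drop` below its running
#' maximum.
#'
#' @param query,subject DNA character strings (plus-strand orientation; pass
#'   the reverse complement of the subject for minus-strand seeds).
#' @param qstart,sstart 1-based start of the seed on query and subject.
#' @param length seed length in bases (exact match).
#' @param scheme a [scoring_scheme()].
#' @param x_drop X-drop termination threshold in score units (default 20).
#' @return a one-row data.frame: `query_start`, `query_end` (1-based
#'   inclusive), `subject_start`, `subject_end` (0-based half-open), `score`,
#'   `matches`, `aligned_cols`, `gaps`, `identity`.
#' @export
extend_alignment <- function(query, subject, qstart, sstart, length,
                             scheme = scoring_scheme(),
                             x_drop = .default_x_drop) {
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  h <- cpp_extend_one(query, subject, as.integer(qstart) - 1L,
                      as.integer(sstart) - 1L, as.integer(length),
                      scheme$reward, scheme$penalty, scheme$gap_open,
                      scheme$gap_extend, as.integer(x_drop))
  data.frame(query_start = h$qstart + 1L, query_end = h$qend,
             subject_start = h$sstart, subject_end = h$send,
             score = h$score, matches = h$matches,
             aligned_cols = h$aligned_cols, gaps = h$gaps,
             identity = 100 * h$matches / h$aligned_cols)
}

#' Apply e-value, identity and length filters to a hit table
#'
#' Surviving hits satisfy `evalue <= max_evalue`, `identity > min_identity`
#' (strict) and subject-interval length `>= min_length` (inclusive). The
#' number of hits removed by each criterion (counted independently) is
#' attached as `attr(, "removed")`.
#'
#' @param hits hit table from [find_numts()] (or compatible data.frame with
#'   `evalue`, `identity`, `subject_start`, `subject_end`).
#' @param thresholds a [filter_thresholds()].
#' @return the filtered hit table.
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  len <- hits$subject_end - hits$subject_start
  pass_e <- hits$evalue <= thresholds$max_evalue
  pass_i <- hits$identity > thresholds$min_identity
  pass_l <- len >= thresholds$min_length
  out <- hits[pass_e & pass_i & pass_l, , drop = FALSE]
  attr(out, "removed") <- c(evalue = sum(!pass_e), identity = sum(!pass_i),
                            length = sum(!pass_l))
  out
}

#' Find NUMTs: align a pan-mitogenome pool against a nuclear genome
#'
#' Seeds every pool record against every genome sequence on both strands,
#' extends seeds into gapped local alignments, attaches Karlin-Altschul
#' e-values (search lengths are the raw query and total genome lengths; no
#' BLAST-style length adjustment, recorded in the result metadata), applies
#' the thresholds, wraps hits lying entirely within the circular pad back to
#' unpadded query coordinates, and merges the surviving nuclear intervals.
#'
#' @param pool a `PanMitogenome` from [assemble_panmito()].
#' @param genome nuclear genome: a named character vector, `DNAStringSet`,
#'   or FASTA path.
#' @param scheme a [scoring_scheme()].
#' @param thresholds a [filter_thresholds()].
#' @param word_size seed word size (default 11).
#' @param x_drop X-drop termination threshold (default 20).
#' @return a list of class `numt_result`: `numts` (merged [GenomicRanges]
#'   intervals), `hits` (the filtered per-hit table, with query coordinates
#'   1-based inclusive on the padded query and subject coordinates 0-based
#'   half-open), `removed` (per-criterion filter counts) and `meta`.
#' @export
find_numts <- function(pool, genome, scheme = scoring_scheme(),
                       thresholds = filter_thresholds(), word_size = 11L,
                       x_drop = .default_x_drop) {
  genome <- as_genome_charvec(genome)
  if (pool$total == 0L) stop("empty pool")
  if (length(genome) == 0L || sum(nchar(genome)) == 0L)
    stop("empty genome")
  qseqs <- as.character(pool$records)
  mc <- S4Vectors::mcols(pool$records)
  n_total <- sum(nchar(genome))
  all_hits <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") genome[[chrom]] else
        revcomp_chr(genome[[chrom]])
      df <- cpp_search(subj, qseqs, as.integer(word_size), scheme$reward,
                       scheme$penalty, scheme$gap_open, scheme$gap_extend,
                       as.integer(x_drop))
      if (nrow(df) == 0L) next
      slen <- nchar(genome[[chrom]])
      if (strand == "-") {
        ss <- slen - df$send
        se <- slen - df$sstart
        df$sstart <- ss
        df$send <- se
      }
      hits <- data.frame(
        query_id = names(pool$records)[df$query],
        query_start = df$qstart + 1L, query_end = df$qend,
        subject_chrom = chrom, subject_start = df$sstart,
        subject_end = df$send, strand = strand, score = df$score,
        aligned_cols = df$aligned_cols, matches = df$matches,
        gaps = df$gaps,
        identity = 100 * df$matches / df$aligned_cols,
        evalue = evalue(df$score, nchar(qseqs)[df$query], n_total, scheme),
        stringsAsFactors = FALSE)
      all_hits[[length(all_hits) + 1L]] <- hits
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    empty_hit_table()
  filtered <- filter_hits(hits, thresholds)
  removed <- attr(filtered, "removed")
  # hits entirely within the circular pad are images of the sequence start
  if (nrow(filtered)) {
    olen <- setNames(mc$original_length, names(pool$records))
    ol <- olen[filtered$query_id]
    wrap <- filtered$query_start > ol
    filtered$query_start[wrap] <- filtered$query_start[wrap] - ol[wrap]
    filtered$query_end[wrap] <- filtered$query_end[wrap] - ol[wrap]
  }
  rownames(filtered) <- NULL
  numts <- if (nrow(filtered)) {
    merge_intervals(GenomicRanges::GRanges(
      filtered$subject_chrom,
      IRanges::IRanges(start = filtered$subject_start + 1L,
                       end = filtered$subject_end)))
  } else GenomicRanges::GRanges()
  structure(list(numts = numts, hits = filtered, removed = removed,
                 meta = list(word_size = word_size, x_drop = x_drop,
                             scheme = scheme, thresholds = thresholds,
                             n_total = n_total,
                             length_adjustment = "none (raw lengths)")),
            class = "numt_result")
}

#' @export
print.numt_result <- function(x, ...) {
  cat("numt_result:", length(x$numts), "merged NUMT intervals from",
      nrow(x$hits), "filtered hits\n")
  invisible(x)
}

# accept DNAStringSet / named character / FASTA path
as_genome_charvec <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    nm <- vapply(strsplit(names(genome), "[ \t]+"), `[`, character(1), 1L)
    genome <- setNames(as.character(genome), nm)
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  toupper(genome)
}

empty_hit_table <- function() {
  data.frame(query_id = character(), query_start = integer(),
             query_end = integer(), subject_chrom = character(),
             subject_start = integer(), subject_end = integer(),
             strand = character(), score = integer(),
             aligned_cols = integer(), matches = integer(), gaps = integer(),
             identity = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in BLAST outfmt-6-like layout
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, score (raw score in place of the bit score).
#'
#' @param hits hit table from [find_numts()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_chrom,
    pident = sprintf("%.2f", hits$identity), length = hits$aligned_cols,
    mismatch = hits$aligned_cols - hits$matches - hits$gaps,
    gapopen = hits$gaps, qstart = hits$query_start, qend = hits$query_end,
    sstart = ifelse(hits$strand == "+", hits$subject_start + 1L,
                    hits$subject_end),
    send = ifelse(hits$strand == "+", hits$subject_end,
                  hits$subject_start + 1L),
    evalue = format(hits$evalue, digits = 3), score = hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
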