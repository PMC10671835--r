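#' Decompose a pool into a k-mer table
#'
#' Slides a window of length `k` base by base over every pool record and
#' counts each window. Windows containing `N` or any IUPAC ambiguity code
#' (R, Y, S, W, K, M, B, D, H, V) are discarded.
#'
#' @param pool a `PanMitogenome`, a record set, or a character vector of
#'   sequences.
#' @param k word length (default 20).
#' @return a `KmerTable`: list with `k`, `counts` (named integer vector,
#'   k-mer to occurrence count across the pool), `total_segments` and
#'   `unique_count`.
#' @export
kmer_decompose <- function(pool, k = 20L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  seqs <- if (inherits(pool, "PanMitogenome")) as.character(pool$records)
          else as.character(pool)
  words <- unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < k) return(character())
    ok <- strsplit(s, "")[[1]] %in% c("A", "C", "G", "T")
    # a window is clean iff all k of its positions are ACGT
    run <- cumsum(ok)
    starts <- seq_len(L - k + 1L)
    clean <- (run[starts + k - 1L] - c(0L, run)[starts]) == k
    substring(s, starts[clean], starts[clean] + k - 1L)
  }), use.names = FALSE)
  counts <- if (length(words)) table(words) else table(character())
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(k = k, counts = counts,
                 total_segments = sum(counts),
                 unique_count = length(counts)),
            class = "KmerTable")
}

#' @export
print.KmerTable <- function(x, ...) {
  cat(sprintf("KmerTable k=%d: %d windows, %d unique k-mers\n", x$k,
              x$total_segments, x$unique_count))
  invisible(x)
}

#' Map a k-mer table onto a nuclear genome
#'
#' Reports every genome position (both strands) matched by a table k-mer
#' with at most `max_mismatch` mismatches, once per distinct
#' (k-mer, position) pair; duplicate placements collapse. Exact matching
#' (the default) uses a preprocessed dictionary scan; mismatch-tolerant
#' matching (at most 3) scans per k-mer.
#'
#' @param table a `KmerTable`.
#' @param genome named character vector, `DNAStringSet` or FASTA path.
#' @param max_mismatch allowed mismatches per placement (0-3; default 0).
#' @return a `GRanges` of per-position hits (width `k`) with metadata
#'   columns `kmer` and `pool_count` (the k-mer's occurrence count in the
#'   pool).
#' @export
map_kmers <- function(table, genome, max_mismatch = 0L) {
  stopifnot(inherits(table, "KmerTable"))
  if (max_mismatch > 3L) stop("max_mismatch must be <= 3")
  genome <- as_genome_charvec(genome)
  if (sum(nchar(genome)) == 0L) stop("empty genome")
  kmers <- names(table$counts)
  if (!length(kmers)) return(GenomicRanges::GRanges())
  k <- table$k
  res <- list()
  kset <- Biostrings::DNAStringSet(kmers)
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    slen <- length(subj)
    for (strand in c("+", "-")) {
      if (max_mismatch == 0L) {
        pd <- Biostrings::PDict(if (strand == "+") kset else
          Biostrings::reverseComplement(kset))
        m <- Biostrings::matchPDict(pd, subj)
        starts <- Biostrings::startIndex(m)
        idx <- rep(seq_along(starts), lengths(starts))
        pos <- unlist(starts, use.names = FALSE)
      } else {
        probe <- if (strand == "+") kset else
          Biostrings::reverseComplement(kset)
        ml <- lapply(seq_along(probe), function(i)
          Biostrings::start(Biostrings::matchPattern(
            probe[[i]], subj, max.mismatch = max_mismatch)))
        idx <- rep(seq_along(ml), lengths(ml))
        pos <- unlist(ml, use.names = FALSE)
      }
      if (!length(pos)) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(pos), kmer_idx = idx,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, res)
  # one report per distinct (k-mer, position) pair
  df <- df[!duplicated(df[, c("chrom", "start", "kmer_idx")]), , drop = FALSE]
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start, width = k),
    strand = df$strand, kmer = kmers[df$kmer_idx],
    pool_count = unname(table$counts[df$kmer_idx]))
}

#' Merge per-position k-mer hits into mapped segments
#'
#' Overlapping or book-ended hit footprints are merged into maximal
#' segments; every segment has length at least `k`.
#'
#' @param hits `GRanges` from [map_kmers()].
#' @return `GRanges` of segments with metadata `supporting_kmers` (distinct
#'   k-mers mapping within the segment) and `depth_max` (maximum per-base
#'   hit coverage).
#' @export
merge_segments <- function(hits) {
  if (length(hits) == 0L) return(GenomicRanges::GRanges())
  segs <- merge_intervals(hits)
  ov <- GenomicRanges::findOverlaps(segs, hits, ignore.strand = TRUE)
  km <- S4Vectors::mcols(hits)$kmer
  support <- vapply(split(km[S4Vectors::subjectHits(ov)],
                          S4Vectors::queryHits(ov)),
                    function(v) length(unique(v)), integer(1))
  cov <- GenomicRanges::coverage(hits)
  depth <- vapply(seq_along(segs), function(i) {
    ch <- as.character(GenomicRanges::seqnames(segs))[i]
    max(S4Vectors::runValue(cov[[ch]][IRanges::IRanges(
      GenomicRanges::start(segs)[i], GenomicRanges::end(segs)[i])]))
  }, numeric(1))
  S4Vectors::mcols(segs)$supporting_kmers <-
    as.integer(support[as.character(seq_along(segs))])
  S4Vectors::mcols(segs)$depth_max <- as.integer(depth)
  segs
}

#' Histogram of mapped-segment lengths
#'
#' @param segments `GRanges` from [merge_segments()].
#' @return data.frame with `length`, `n_segments` and `n_kmers` (total
#'   supporting k-mers at that length), sorted by length. Segment counts are
#'   conserved: `sum(n_segments) == length(segments)`.
#' @export
length_histogram <- function(segments) {
  if (length(segments) == 0L)
    return(data.frame(length = integer(), n_segments = integer(),
                      n_kmers = integer()))
  w <- GenomicRanges::width(segments)
  sup <- S4Vectors::mcols(segments)$supporting_kmers
  if (is.null(sup)) sup <- rep(1L, length(segments))
  agg <- aggregate(cbind(n_segments = rep(1L, length(w)), n_kmers = sup),
                   by = list(length = w), FUN = sum)
  agg[order(agg$length), , drop = FALSE]
}

#' Knee of the segment-length distribution
#'
#' Operationalises the visual "turning point" of the length distribution as
#' the length L inside `search_range` with the largest drop of log-counts
#' between consecutive occupied lengths; ties break toward smaller L. If the
#' search range is unoccupied or the histogram is flat, the configured
#' default is returned with a warning.
#'
#' @param histogram data.frame from [length_histogram()] (the `n_kmers`
#'   column is used when present, else `n_segments`, else the second
#'   column).
#' @param k word length the histogram was built with (default 20).
#' @param search_range two-element length interval searched for the knee
#'   (default `c(k + 1, 3 * k)`).
#' @param default fallback cutoff (default 28).
#' @return the estimated minimum credible NUMT length, in bases.
#' @export
turning_point <- function(histogram, k = 20L,
                          search_range = c(k + 1L, 3L * k), default = 28L) {
  cnt_col <- if ("n_kmers" %in% names(histogram)) "n_kmers"
             else if ("n_segments" %in% names(histogram)) "n_segments"
             else names(histogram)[2]
  h <- histogram[histogram[[cnt_col]] > 0, , drop = FALSE]
  h <- h[order(h$length), , drop = FALSE]
  if (nrow(h) >= 2) {
    lg <- log(h[[cnt_col]])
    drop <- lg[-nrow(h)] - lg[-1]
    at <- h$length[-1]
    in_range <- at >= search_range[1] & at <= search_range[2]
    if (any(in_range) && max(drop[in_range]) > 0) {
      cand <- at[in_range]
      return(cand[which.max(drop[in_range])])
    }
  }
  warning("no knee found in search range; returning default ", default)
  as.integer(default)
}
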