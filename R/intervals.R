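#' Merge overlapping and book-ended intervals
#'
#' Thin wrapper over [GenomicRanges::reduce()]: intervals that overlap, are
#' book-ended, or are separated by fewer than `min_gap` bases are joined
#' (matching `bedtools merge` semantics with `-d min_gap`).
#'
#' @param x a `GRanges`.
#' @param min_gap gaps strictly smaller than this are closed (default 0:
#'   only overlapping/book-ended intervals merge).
#' @return a merged `GRanges` (pairwise disjoint, sorted).
#' @export
merge_intervals <- function(x, min_gap = 0L) {
  GenomicRanges::reduce(x, min.gapwidth = max(as.integer(min_gap), 1L),
                        ignore.strand = TRUE)
}

#' Summary statistics of a merged interval set
#'
#' @param x a merged `GRanges`.
#' @return data.frame with `count`, `total_length`, `min`, `median`, `mean`,
#'   `max` (lengths in bases; the median of an even count is the lower
#'   median). An empty set yields all zeros with a warning.
#' @export
interval_summary <- function(x) {
  if (length(x) == 0L) {
    warning("empty interval set")
    return(data.frame(count = 0L, total_length = 0L, min = 0L, median = 0L,
                      mean = 0, max = 0L))
  }
  w <- sort(GenomicRanges::width(x))
  lower_median <- w[floor((length(w) + 1) / 2)]
  data.frame(count = length(x), total_length = sum(w), min = w[1],
             median = lower_median, mean = mean(w), max = w[length(w)])
}

# error unless the genome labels (seqinfo genome, when set) agree
check_same_genome <- function(A, B) {
  ga <- unique(stats::na.omit(GenomeInfoDb::genome(A)))
  gb <- unique(stats::na.omit(GenomeInfoDb::genome(B)))
  if (length(ga) && length(gb) && !identical(sort(ga), sort(gb)))
    stop("genome label mismatch: ", paste(ga, collapse = ","), " vs ",
         paste(gb, collapse = ","))
  invisible(TRUE)
}

#' Overlap statistics between two merged interval sets
#'
#' @param A,B merged `GRanges` on the same genome (labels checked when set
#'   via `seqinfo`).
#' @return data.frame with `shared_length` (bases in the intersection),
#'   `frac_A_in_B`, `frac_B_in_A` and `frac_shared_of_union`.
#' @export
overlap_stats <- function(A, B) {
  check_same_genome(A, B)
  shared <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::intersect(A, B, ignore.strand = TRUE))))
  la <- sum(GenomicRanges::width(A))
  lb <- sum(GenomicRanges::width(B))
  lu <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::union(A, B, ignore.strand = TRUE))))
  data.frame(shared_length = shared,
             frac_A_in_B = if (la > 0) shared / la else NA_real_,
             frac_B_in_A = if (lb > 0) shared / lb else NA_real_,
             frac_shared_of_union = if (lu > 0) shared / lu else NA_real_)
}

#' Build the combined NUMTs-Blacklist exclusion set
#'
#' Merges the NUMT compilation, an external blacklist, and observed read
#' pile-up regions into one exclusion set. Each output interval carries a
#' `sources` label listing which inputs contributed to it.
#'
#' @param numts,external_blacklist,observed_pileups merged `GRanges`
#'   (empty sets allowed).
#' @return merged `GRanges` with a `sources` metadata column.
#' @export
blacklist_union <- function(numts,
                            external_blacklist = GenomicRanges::GRanges(),
                            observed_pileups = GenomicRanges::GRanges()) {
  check_same_genome(numts, external_blacklist)
  check_same_genome(numts, observed_pileups)
  inputs <- list(numts = numts, external = external_blacklist,
                 pileup = observed_pileups)
  combined <- suppressWarnings(do.call(c, unname(lapply(inputs, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  }))))
  out <- merge_intervals(combined)
  if (length(out)) {
    src <- vapply(seq_along(out), function(i) {
      hit <- vapply(inputs, function(g)
        length(suppressWarnings(GenomicRanges::findOverlaps(out[i], g))) > 0,
        logical(1))
      paste(names(inputs)[hit], collapse = ",")
    }, character(1))
    S4Vectors::mcols(out)$sources <- src
  }
  out
}

#' Read a BED file (3-6 columns, 0-based half-open)
#'
#' Track and browser lines are skipped with a warning; a line with
#' `start >= end` or negative coordinates is an error reporting the line
#' number. Name, score and strand columns are preserved when present.
#'
#' @param path BED path.
#' @param genome optional genome label to record in the `seqinfo`.
#' @return a `GRanges`.
#' @export
read_bed <- function(path, genome = NA_character_) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser)\\b", lines)
  if (any(skip)) warning("skipped ", sum(skip), " track/browser line(s)")
  keep <- which(!skip & nzchar(lines))
  if (!length(keep)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines[keep], "\t")
  ncol <- lengths(fields)
  if (any(ncol < 3)) stop("line ", keep[which(ncol < 3)[1]],
                          ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("line ", keep[bad[1]], ": invalid BED interval '",
         lines[keep[bad[1]]], "'")
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, end = end),
    strand = if (max(ncol) >= 6)
      ifelse(ncol >= 6, vapply(fields, function(f)
        if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*",
        character(1)), "*") else "*")
  if (max(ncol) >= 4)
    S4Vectors::mcols(gr)$name <- vapply(fields, function(f)
      if (length(f) >= 4) f[4] else NA_character_, character(1))
  if (max(ncol) >= 5)
    S4Vectors::mcols(gr)$score <- vapply(fields, function(f)
      if (length(f) >= 5) f[5] else NA_character_, character(1))
  if (!is.na(genome)) GenomeInfoDb::genome(gr) <- genome
  gr
}

#' Write a `GRanges` as BED (0-based half-open)
#'
#' Emits 3 columns, or 4-6 when `name`, `score` or strand information is
#' present, so that [read_bed()] round-trips bit-exactly.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  mc <- S4Vectors::mcols(x)
  has_name <- "name" %in% colnames(mc)
  has_score <- "score" %in% colnames(mc)
  has_strand <- length(x) > 0 &&
    any(as.character(GenomicRanges::strand(x)) != "*")
  cols <- list(as.character(GenomicRanges::seqnames(x)),
               GenomicRanges::start(x) - 1L, GenomicRanges::end(x))
  if (has_name || has_score || has_strand)
    cols <- c(cols, list(if (has_name) mc$name else rep(".", length(x))))
  if (has_score || has_strand)
    cols <- c(cols, list(if (has_score) mc$score else rep(".", length(x))))
  if (has_strand)
    cols <- c(cols, list(as.character(GenomicRanges::strand(x))))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Convert BED-style to 1-based inclusive mitogenome coordinates
#'
#' Internal coordinates are 0-based half-open (BED); mitochondrial positions
#' are reported 1-based inclusive. All conversion between the two conventions
#' goes through this pair of helpers.
#'
#' @param start0,end0 0-based half-open interval.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
bed_to_mt1 <- function(start0, end0) {
  data.frame(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' @rdname bed_to_mt1
#' @param start1,end1 1-based inclusive interval.
#' @return for `mt1_to_bed`: data.frame with 0-based half-open `start`,
#'   `end`.
#' @export
mt1_to_bed <- function(start1, end1) {
  data.frame(start = as.integer(start1) - 1L, end = as.integer(end1))
}
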