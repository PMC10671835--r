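#' Construct a set of mitochondrial records
#'
#' A record set is a [Biostrings::DNAStringSet] whose `mcols()` carry the
#' bookkeeping the pool needs: `kind` (one of `"full"`, `"control"`,
#' `"reference"`), `original_length` (bases before circular padding) and
#' `pad` (bases of circular extension applied, 0 until [circular_extend()]).
#'
#' @param sequences named character vector or `DNAStringSet` of DNA sequences
#'   (IUPAC alphabet); names are the record ids.
#' @param kind record kind, recycled to the number of sequences.
#' @return a `DNAStringSet` with `kind`, `original_length` and `pad` metadata
#'   columns.
#' @export
mito_records <- function(sequences, kind = c("full", "control", "reference")) {
  kind <- match.arg(kind)
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == ""))
      stop("all sequences must be named (record ids)")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  S4Vectors::mcols(sequences) <- S4Vectors::DataFrame(
    kind = rep(kind, length(sequences)),
    original_length = Biostrings::width(sequences),
    pad = integer(length(sequences)))
  sequences
}

#' Read mitochondrial sequences from a FASTA file
#'
#' Sequences are uppercased; the record id is the first whitespace-delimited
#' token of the header. Multi-line and single-line FASTA are both accepted.
#' A character outside the IUPAC DNA alphabet (ACGT, N and the ambiguity
#' codes) is an error naming the record and the offending position.
#'
#' @param path FASTA file path.
#' @param kind record kind to assign (`"full"`, `"control"` or
#'   `"reference"`).
#' @return a record set as from [mito_records()]; an empty file yields an
#'   empty set with a warning.
#' @export
read_mito_fasta <- function(path, kind = c("full", "control", "reference")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(raw) == 0L) {
    warning("empty FASTA: ", path)
    return(mito_records(Biostrings::DNAStringSet(), kind))
  }
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(raw))
  allowed <- c(strsplit("ACGTNRYSWKMBDHV", "")[[1]])
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad))
      stop(sprintf("record '%s': non-IUPAC character '%s' at position %d",
                   ids[i], chars[bad[1]], bad[1]))
  }
  names(seqs) <- ids
  mito_records(seqs, kind)
}

#' Remove byte-identical duplicate sequences
#'
#' For each group of records with identical sequence (after uppercasing,
#' which [read_mito_fasta()] already performs), the first record by input
#' order survives; input order is preserved. The ids of the removed records
#' are attached as `metadata(x)$removed_ids`.
#'
#' @param records an unpadded record set.
#' @return the deduplicated record set.
#' @export
dedup_exact <- function(records) {
  stopifnot(all(S4Vectors::mcols(records)$pad == 0L))
  dup <- duplicated(as.character(records))
  out <- records[!dup]
  S4Vectors::metadata(out)$removed_ids <- names(records)[dup]
  out
}

#' Keep only full-length mitogenome records
#'
#' @param records a record set of kind `"full"`.
#' @param min_len minimum unpadded length in bases (default 16530).
#' @return records with `original_length >= min_len`; the discard count is
#'   reported via `message()`.
#' @export
filter_full_length <- function(records, min_len = 16530L) {
  keep <- S4Vectors::mcols(records)$original_length >= min_len
  if (any(!keep))
    message(sum(!keep), " record(s) below ", min_len, " bp discarded")
  records[keep]
}

#' Circularly extend records by copying the leading bases to the end
#'
#' The mitogenome is circular; appending the first `pad` bases to the end of
#' each sequence lets local alignments cross the arbitrary linearisation
#' origin. Control-region fragments are linear sub-sequences and are never
#' padded.
#'
#' @param records a record set (kinds `"full"` or `"reference"`).
#' @param pad bases to append (default 100); 0 returns the input unchanged.
#' @return the padded record set (`pad` metadata updated, `original_length`
#'   unchanged).
#' @export
circular_extend <- function(records, pad = 100L) {
  pad <- as.integer(pad)
  stopifnot(pad >= 0L)
  if (pad == 0L || length(records) == 0L) return(records)
  mc <- S4Vectors::mcols(records)
  if (any(mc$kind == "control"))
    stop("control-region fragments are linear and must not be padded")
  if (any(mc$pad != 0L)) stop("records are already padded")
  short <- mc$original_length <= pad
  if (any(short))
    stop("record(s) not longer than the pad (", pad, " bp): ",
         paste(names(records)[short], collapse = ", "))
  out <- Biostrings::xscat(records, Biostrings::subseq(records, 1L, pad))
  names(out) <- names(records)
  mc$pad <- pad
  S4Vectors::mcols(out) <- mc
  out
}

#' Assemble the pan-mitogenome query pool
#'
#' Combines deduplicated, length-filtered full-length mitogenomes (circularly
#' padded), unpadded control-region fragments, and the padded reference
#' mitogenome into a single pool. Record ids must be unique across kinds.
#'
#' @param full full-length record set (already deduplicated and
#'   length-filtered; padded here if not yet padded).
#' @param control control-region record set (kept as-is: neither
#'   deduplicated nor padded).
#' @param reference single reference record (padded here if needed).
#' @param pad circular pad in bases (default 100).
#' @return a `PanMitogenome`: a list with `records` (the pooled record set),
#'   `counts` (per kind), `pad` and `total`.
#' @export
assemble_panmito <- function(full, control, reference, pad = 100L) {
  pad <- as.integer(pad)
  pad_if_needed <- function(x) {
    if (length(x) && pad > 0L && all(S4Vectors::mcols(x)$pad == 0L))
      circular_extend(x, pad) else x
  }
  full <- pad_if_needed(full)
  reference <- pad_if_needed(reference)
  ids <- c(names(full), names(control), names(reference))
  if (anyDuplicated(ids))
    stop("duplicate record ids across kinds: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- c(full, control, reference)
  counts <- c(full = length(full), control = length(control),
              reference = length(reference))
  structure(list(records = records, counts = counts, pad = pad,
                 total = length(records)),
            class = "PanMitogenome")
}

#' @export
print.PanMitogenome <- function(x, ...) {
  cat("PanMitogenome pool:", x$total, "records",
      sprintf("(%d full, %d control, %d reference), pad %d bp\n",
              x$counts[["full"]], x$counts[["control"]],
              x$counts[["reference"]], x$pad))
  invisible(x)
}

#' Write a pool to disk (FASTA + tab-separated manifest)
#'
#' @param pool a `PanMitogenome`.
#' @param dir output directory (created if missing); writes `pool.fasta` and
#'   `manifest.tsv` (columns id, kind, original_length, pad).
#' @return the directory, invisibly.
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(pool$records, file.path(dir, "pool.fasta"))
  mc <- S4Vectors::mcols(pool$records)
  manifest <- data.frame(id = names(pool$records), kind = mc$kind,
                         original_length = mc$original_length, pad = mc$pad)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a pool written by [write_pool()]
#'
#' @param dir directory containing `pool.fasta` and `manifest.tsv`.
#' @return a `PanMitogenome`.
#' @export
read_pool <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "pool.fasta"))
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  stopifnot(identical(names(seqs), manifest$id))
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    kind = manifest$kind, original_length = manifest$original_length,
    pad = manifest$pad)
  counts <- c(full = sum(manifest$kind == "full"),
              control = sum(manifest$kind == "control"),
              reference = sum(manifest$kind == "reference"))
  structure(list(records = seqs, counts = counts,
                 pad = max(manifest$pad), total = length(seqs)),
            class = "PanMitogenome")
}
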