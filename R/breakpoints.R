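#' Project filtered hits onto circular mitogenome coordinates
#'
#' Builds per-position coverage and endpoint (breakpoint) counts over the
#' circular mitogenome. Query positions beyond `mt_length` (images inside
#' the circular pad) wrap back to the sequence start; coverage is
#' incremented once per hit per covered position, and each hit's wrapped
#' start and end increment the endpoint counts.
#'
#' @param hits hit table from [find_numts()] (needs `query_start`,
#'   `query_end`, 1-based inclusive on the padded query).
#' @param mt_length mitogenome length (default 16569).
#' @param pad circular pad the queries carried (default 100).
#' @return an `MtCoverageProfile`: list with `mt_length`, `coverage`
#'   (integer vector of length `mt_length`, 1-based) and `endpoints`.
#' Which hits can be projected onto the canonical mitogenome?
#'
#' Hits are projectable when their query coordinates fit the canonical
#' padded coordinate system. Queries from molecules longer than `mt_length`
#' (lineages carrying net insertions) have no exact canonical coordinates
#' and are excluded.
#'
#' @inheritParams project_to_mt
#' @return logical vector over the hit rows.
#' @export
mt_projectable <- function(hits, mt_length = 16569L, pad = 100L) {
  hits$query_start >= 1L & hits$query_end <= mt_length + pad
}

#' @export
project_to_mt <- function(hits, mt_length = 16569L, pad = 100L) {
  mt_length <- as.integer(mt_length)
  coverage <- integer(mt_length)
  endpoints <- integer(mt_length)
  if (nrow(hits)) {
    if (any(hits$query_end > mt_length + pad) || any(hits$query_start < 1L))
      stop("corrupt hit: query interval outside padded mitogenome")
    # difference-array accumulation; a hit crossing the origin splits in two
    dif <- integer(mt_length + 1L)
    for (i in seq_len(nrow(hits))) {
      s <- mt_wrap(hits$query_start[i], mt_length)
      e <- mt_wrap(hits$query_end[i], mt_length)
      if (e >= s) {
        dif[s] <- dif[s] + 1L
        dif[e + 1L] <- dif[e + 1L] - 1L
      } else {
        dif[s] <- dif[s] + 1L
        dif[mt_length + 1L] <- dif[mt_length + 1L] - 1L
        dif[1L] <- dif[1L] + 1L
        dif[e + 1L] <- dif[e + 1L] - 1L
      }
      endpoints[s] <- endpoints[s] + 1L
      endpoints[e] <- endpoints[e] + 1L
    }
    coverage <- cumsum(dif[seq_len(mt_length)])
  }
  structure(list(mt_length = mt_length, coverage = as.integer(coverage),
                 endpoints = endpoints),
            class = "MtCoverageProfile")
}

#' @export
print.MtCoverageProfile <- function(x, ...) {
  cat(sprintf(
    "MtCoverageProfile over %d bp: coverage sum %d, %d endpoints\n",
    x$mt_length, sum(x$coverage), sum(x$endpoints)))
  invisible(x)
}

#' Low-coverage (candidate breakpoint) regions on the circular mitogenome
#'
#' Returns the maximal circular runs of at least `min_run` positions whose
#' coverage is at or below the given quantile of the coverage distribution.
#' A run may wrap the origin, in which case `start > end`. On a constant
#' positive profile the quantile equals the maximum and no region is
#' reported; an all-zero profile returns the full circle with a warning.
#'
#' @param profile an `MtCoverageProfile`.
#' @param quantile coverage quantile defining "low" (default 0.05).
#' @param min_run minimum run length in bases (default 20).
#' @return data.frame with 1-based inclusive `start`, `end` and `wraps`.
#' @export
low_coverage_regions <- function(profile, quantile = 0.05, min_run = 20L) {
  cov <- profile$coverage
  L <- profile$mt_length
  if (all(cov == 0L)) {
    warning("all-zero coverage profile: whole mitogenome is low-coverage")
    return(data.frame(start = 1L, end = L, wraps = FALSE))
  }
  thr <- as.numeric(stats::quantile(cov, quantile))
  if (thr >= max(cov))
    return(data.frame(start = integer(), end = integer(), wraps = logical()))
  low <- cov <= thr
  # rotate so the scan starts outside a run, making circular runs contiguous
  anchor <- which(!low)[1]
  rot <- c(anchor:L, seq_len(anchor - 1L))
  lr <- low[rot]
  r <- rle(lr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(), wraps = logical()))
  s <- mt_wrap(starts[keep] + anchor - 1L, L)
  e <- mt_wrap(ends[keep] + anchor - 1L, L)
  out <- data.frame(start = s, end = e, wraps = e < s)
  out[order(out$start), , drop = FALSE]
}

#' Read a mitogenome feature annotation table
#'
#' Tab-separated with columns `name`, `start`, `end`, `category`
#' (1-based inclusive; `start > end` denotes a feature wrapping the origin;
#' categories: control, tRNA, rRNA, CDS).
#'
#' @param path TSV path.
#' @param mt_length mitogenome length used for validation.
#' @return data.frame of features.
#' @export
read_mt_annotation <- function(path, mt_length = 16569L) {
  ann <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end", "category") %in% names(ann)),
            all(ann$start >= 1), all(ann$end >= 1),
            all(ann$start <= mt_length), all(ann$end <= mt_length))
  ann
}

#' Per-category overlap fractions of mitogenome regions
#'
#' For each region (1-based inclusive, circular; `start > end` wraps), the
#' fraction of its bases overlapping each annotation category, plus an
#' `unannotated` remainder. A base covered by features of several
#' categories is credited to each, so category fractions may individually
#' approach 1 while `unannotated` accounts only for bases touched by no
#' feature.
#'
#' @param regions data.frame with `start`, `end` (e.g. from
#'   [low_coverage_regions()]).
#' @param annotation data.frame as from [read_mt_annotation()].
#' @param mt_length mitogenome length (default 16569).
#' @return data.frame: one row per region with `start`, `end`, one column
#'   per category and `unannotated`.
#' @export
annotate_regions <- function(regions, annotation, mt_length = 16569L) {
  cats <- sort(unique(annotation$category))
  # per-base membership masks over the circle; coordinates past mt_length
  # wrap (a region given as 16000..18000 continues through the origin)
  circ_mask <- function(starts, ends) {
    m <- logical(mt_length)
    for (i in seq_along(starts)) {
      s <- mt_wrap(starts[i], mt_length); e <- mt_wrap(ends[i], mt_length)
      if (e >= s) m[s:e] <- TRUE else m[c(s:mt_length, 1:e)] <- TRUE
    }
    m
  }
  cat_masks <- lapply(cats, function(cc)
    circ_mask(annotation$start[annotation$category == cc],
              annotation$end[annotation$category == cc]))
  names(cat_masks) <- cats
  any_mask <- Reduce(`|`, cat_masks, logical(mt_length))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rm <- circ_mask(regions$start[i], regions$end[i])
    n <- sum(rm)
    fr <- vapply(cat_masks, function(m) sum(m & rm) / n, numeric(1))
    c(list(start = regions$start[i], end = regions$end[i]),
      as.list(fr), list(unannotated = sum(rm & !any_mask) / n))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
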