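#' Run configuration for the end-to-end discovery pipeline
#'
#' Collects every stage default in one validated object. Unknown keys are
#' rejected; every threshold is echoed into the output manifest so results
#' are self-describing.
#'
#' @param full,control,reference mitochondrial inputs: FASTA paths or record
#'   sets (see [read_mito_fasta()], [mito_records()]).
#' @param genome nuclear genome: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @param external_blacklist,pileups optional BED paths (or `GRanges`) fed
#'   into the exclusion-set union.
#' @param pad circular pad (default 100).
#' @param min_full_len minimum full-length mitogenome length (default
#'   16530).
#' @param reward,penalty,gap_open,gap_extend alignment scoring (defaults
#'   2, -3, 5, 2).
#' @param max_evalue,min_identity,min_length NUMT filters (defaults 1e-4,
#'   63, 28).
#' @param k k-mer length (default 20).
#' @param max_mismatch k-mer mapping mismatches (default 0).
#' @param word_size seed word size (default 11).
#' @param x_drop X-drop threshold (default 20).
#' @param mt_length mitogenome length (default 16569).
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic; default 1).
#' @return a `RunConfig` list.
#' @export
run_config <- function(full, control, reference, genome,
                       external_blacklist = NULL, pileups = NULL,
                       pad = 100L, min_full_len = 16530L, reward = 2L,
                       penalty = -3L, gap_open = 5L, gap_extend = 2L,
                       max_evalue = 1e-4, min_identity = 63,
                       min_length = 28L, k = 20L, max_mismatch = 0L,
                       word_size = 11L, x_drop = 20L, mt_length = 16569L,
                       seed = 1L) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Load a run configuration from a flat YAML file
#'
#' Unknown keys are an error.
#'
#' @param path YAML path with keys matching the arguments of
#'   [run_config()].
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

as_records <- function(x, kind) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    read_mito_fasta(x, kind) else x
}

as_bed_granges <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (is.character(x)) read_bed(x) else x
}

#' Run the whole NUMT discovery pipeline
#'
#' Chains pool assembly, alignment-based NUMT discovery, interval summary,
#' k-mer short-segment scanning, circular breakpoint profiling, and
#' exclusion-set construction; writes every result plus a provenance
#' manifest into `out_dir`. Identical config and inputs produce
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) a list with the in-memory results: `pool`, `result`
#'   ([find_numts()] output), `stats`, `segments`, `histogram`,
#'   `turning_point`, `profile`, `breakpoint_regions`, `blacklist`.
#' @export
numt_discover <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()

  pool <- stage("build-panmito", {
    full <- as_records(config$full, "full")
    control <- as_records(config$control, "control")
    reference <- as_records(config$reference, "reference")
    n_in <- length(full)
    full <- dedup_exact(full)
    n_dedup <- length(full)
    full <- filter_full_length(full, config$min_full_len)
    log_counts$panmito <- c(full_in = n_in, full_dedup = n_dedup,
                            full_kept = length(full),
                            control = length(control))
    assemble_panmito(full, control, reference, pad = config$pad)
  })
  write_pool(pool, file.path(out_dir, "pool"))

  scheme <- scoring_scheme(config$reward, config$penalty, config$gap_open,
                           config$gap_extend)
  thresholds <- filter_thresholds(config$max_evalue, config$min_identity,
                                  config$min_length)
  result <- stage("find-numts",
    find_numts(pool, config$genome, scheme, thresholds,
               word_size = config$word_size, x_drop = config$x_drop))
  log_counts$filters <- result$removed
  write_hit_table(result$hits, file.path(out_dir, "hits.tsv"))
  write_bed(result$numts, file.path(out_dir, "numts.bed"))

  stats <- stage("summary-stats",
    if (length(result$numts)) interval_summary(result$numts) else
      suppressWarnings(interval_summary(result$numts)))
  write.table(stats, file.path(out_dir, "numt_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  kmer <- stage("kmer-scan", {
    tab <- kmer_decompose(pool, k = config$k)
    hits <- map_kmers(tab, config$genome, max_mismatch = config$max_mismatch)
    segs <- merge_segments(hits)
    hist <- length_histogram(segs)
    tp <- suppressWarnings(turning_point(hist, k = config$k))
    list(segments = segs, histogram = hist, turning_point = tp)
  })
  write_bed(kmer$segments, file.path(out_dir, "segments.bed"))
  write.table(kmer$histogram, file.path(out_dir, "kmer_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  bp <- stage("breakpoints", {
    proj <- result$hits[mt_projectable(result$hits, config$mt_length,
                                       config$pad), , drop = FALSE]
    profile <- project_to_mt(proj, mt_length = config$mt_length,
                             pad = config$pad)
    regions <- suppressWarnings(low_coverage_regions(profile))
    list(profile = profile, regions = regions)
  })
  write.table(data.frame(position = seq_len(bp$profile$mt_length),
                         coverage = bp$profile$coverage,
                         endpoints = bp$profile$endpoints),
              file.path(out_dir, "mt_coverage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bp$regions, file.path(out_dir, "breakpoint_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  blacklist <- stage("blacklist-union",
    blacklist_union(result$numts, as_bed_granges(config$external_blacklist),
                    as_bed_granges(config$pileups)))
  write_bed(blacklist, file.path(out_dir, "blacklist.bed"))

  manifest <- list(
    package = as.character(utils::packageVersion("pannumt")),
    config = config_manifest(config),
    input_checksums = input_checksums(config),
    counts = log_counts,
    numts = length(result$numts),
    numts_total_length = sum(GenomicRanges::width(result$numts)),
    turning_point = kmer$turning_point,
    length_adjustment = result$meta$length_adjustment)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(pool = pool, result = result, stats = stats,
                 segments = kmer$segments, histogram = kmer$histogram,
                 turning_point = kmer$turning_point, profile = bp$profile,
                 breakpoint_regions = bp$regions, blacklist = blacklist))
}

config_manifest <- function(config) {
  keep <- !vapply(config, function(v)
    methods::is(v, "DNAStringSet") || methods::is(v, "GRanges") ||
      (is.character(v) && length(v) > 1) ||
      (is.character(v) && length(v) == 1 && nchar(v) > 200), logical(1))
  lapply(unclass(config)[keep], function(v)
    if (is.numeric(v) || is.character(v) || is.logical(v)) v else
      class(v)[1])
}

input_checksums <- function(config) {
  paths <- Filter(function(v) is.character(v) && length(v) == 1L &&
                    file.exists(v),
                  unclass(config)[c("full", "control", "reference",
                                    "genome", "external_blacklist",
                                    "pileups")])
  if (!length(paths)) return(list())
  sums <- tools::md5sum(unlist(paths))
  as.list(setNames(unname(sums), names(paths)))
}
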