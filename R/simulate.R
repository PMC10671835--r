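#' Simulation configuration
#'
#' Describes a complete synthetic study: a mitochondrial population with
#' realistic redundancy (exact duplicates) and diversity (substitutions and
#' small indels from a single random root), control-region fragments, and a
#' nuclear background with planted, divergence-controlled NUMT insertions.
#' All generators are deterministic under `seed` (sub-generators derive
#' seeds `seed + 1 .. seed + 4`).
#'
#' @param seed RNG seed (integer).
#' @param mt_length mitogenome length (default 16569).
#' @param n_full full-length population size.
#' @param dup_fraction fraction of the population that are byte-copies of
#'   earlier records.
#' @param sub_rate substitutions per site per lineage.
#' @param indel_rate indels per site per lineage.
#' @param n_control number of control-region fragments.
#' @param control_len_range fragment length range (default 400-1598).
#' @param background_len nuclear background length in bases.
#' @param background_gc GC fraction of the background.
#' @param numt_specs data.frame with one planted insertion per row:
#'   `source_start` (1-based on the circular root), `source_length`,
#'   `divergence` (fraction) and `insertion_point` (0-based offset in the
#'   pre-insertion background); `NULL` until filled (see
#'   [random_numt_specs()]).
#' @param k k-mer length for short-segment scans.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed, mt_length = 16569L, n_full = 60L,
                       dup_fraction = 0.25, sub_rate = 0.002,
                       indel_rate = 5e-5, n_control = 80L,
                       control_len_range = c(400L, 1598L),
                       background_len = 2e6, background_gc = 0.41,
                       numt_specs = NULL, k = 20L) {
  stopifnot(dup_fraction >= 0, dup_fraction < 1, sub_rate >= 0,
            sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            control_len_range[1] > 0, control_len_range[2] < mt_length)
  structure(list(seed = as.integer(seed), mt_length = as.integer(mt_length),
                 n_full = as.integer(n_full), dup_fraction = dup_fraction,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 n_control = as.integer(n_control),
                 control_len_range = as.integer(control_len_range),
                 background_len = as.integer(background_len),
                 background_gc = background_gc, numt_specs = numt_specs,
                 k = as.integer(k)),
            class = "SimConfig")
}

# the control region (D-loop) on root coordinates: 16,024-16,569 and 1-576
.control_region <- function(mt_length = 16569L)
  c(16024:mt_length, 1:576)

#' Random root mitogenome for a configuration
#'
#' @param config a [sim_config()].
#' @return character scalar of length `mt_length` (uniform ACGT).
#' @export
sim_root <- function(config) {
  set.seed(config$seed)
  paste(sample(c("A", "C", "G", "T"), config$mt_length, replace = TRUE),
        collapse = "")
}

# circular substring extraction on a 1-based sequence
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  idx <- mt_wrap(start:(start + len - 1L), L)
  if (start + len - 1L <= L) substr(seq, start, start + len - 1L)
  else paste0(substr(seq, start, L), substr(seq, 1L, idx[length(idx)]))
}

# apply n_sub substitutions (always to a different base) and n_indel indels
# (insert/delete 50/50, geometric(0.5) lengths capped at 10 bp)
mutate_seq <- function(seq, n_sub, n_indel) {
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0) {
    pos <- sample.int(length(chars), min(n_sub, length(chars)))
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  if (n_indel > 0) {
    for (i in seq_len(n_indel)) {
      len <- min(rgeom(1, 0.5) + 1L, 10L)
      at <- sample.int(length(chars), 1L)
      if (runif(1) < 0.5 && length(chars) > len + 1L) {
        chars <- chars[-(at:min(at + len - 1L, length(chars)))]
      } else {
        chars <- append(chars, sample(bases, len, replace = TRUE), after = at)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate the full-length mitochondrial population
#'
#' Draws each distinct lineage independently from the root (a star
#' phylogeny: i.i.d. substitutions and indels), resampling any lineage that
#' drops below 16,530 bp or collides byte-identically with an earlier
#' lineage, then appends `dup_fraction * n_full` byte-copies of randomly
#' chosen earlier records.
#'
#' @param config a [sim_config()].
#' @return a full-length record set (see [mito_records()]).
#' @export
simulate_population <- function(config) {
  root <- sim_root(config)
  set.seed(config$seed + 1L)
  n_dup <- round(config$dup_fraction * config$n_full)
  n_unique <- config$n_full - n_dup
  L <- config$mt_length
  degenerate <- config$sub_rate == 0 && config$indel_rate == 0
  seqs <- character(n_unique)
  for (i in seq_len(n_unique)) {
    for (try in 1:50) {
      s <- mutate_seq(root, rbinom(1, L, config$sub_rate),
                      rbinom(1, L, config$indel_rate))
      ok <- nchar(s) >= 16530L && (degenerate || !(s %in% seqs[seq_len(i - 1)]))
      if (ok) break
      if (try == 50) stop("could not generate a valid lineage (length or ",
                          "uniqueness constraint infeasible)")
    }
    seqs[i] <- s
  }
  if (n_dup > 0)
    seqs <- c(seqs, seqs[sample.int(n_unique, n_dup, replace = TRUE)])
  names(seqs) <- sprintf("sim_full_%04d", seq_along(seqs))
  mito_records(seqs, "full")
}

#' Simulate control-region fragments
#'
#' Fragments are drawn from the control-region coordinates of random
#' population members, with lengths uniform in `control_len_range`,
#' wrapping the origin as needed.
#'
#' @param population record set from [simulate_population()].
#' @param config a [sim_config()].
#' @return a control record set.
#' @export
simulate_control_fragments <- function(population, config) {
  stopifnot(length(population) > 0 || config$n_control == 0)
  set.seed(config$seed + 2L)
  if (config$n_control == 0L)
    return(mito_records(setNames(character(), character()), "control"))
  ctrl <- .control_region(config$mt_length)
  seqs <- vapply(seq_len(config$n_control), function(i) {
    member <- as.character(population[[sample.int(length(population), 1L)]])
    len <- sample(config$control_len_range[1]:config$control_len_range[2], 1L)
    start <- sample(ctrl, 1L)
    circ_substr(member, min(start, nchar(member)), len)
  }, character(1))
  names(seqs) <- sprintf("sim_ctrl_%04d", seq_len(config$n_control))
  mito_records(seqs, "control")
}

#' Draw a random set of planted-NUMT specifications
#'
#' Lengths log-uniform in `len_range`, divergences uniform in `div_range`,
#' source starts uniform on the circular root, insertion points uniform on
#' the background with at least `min_sep` bases between consecutive points.
#'
#' @param config a [sim_config()].
#' @param n number of insertions (default 50).
#' @param len_range source length range (default 35-14855).
#' @param div_range divergence range (default 0-0.20).
#' @param min_sep minimum separation between insertion points (default 500).
#' @return data.frame of specs suitable for `sim_config(numt_specs = )`.
#' @export
random_numt_specs <- function(config, n = 50L, len_range = c(35L, 14855L),
                              div_range = c(0, 0.20), min_sep = 500L) {
  set.seed(config$seed + 4L)
  lens <- round(exp(runif(n, log(len_range[1]), log(len_range[2]))))
  divs <- runif(n, div_range[1], div_range[2])
  starts <- sample.int(config$mt_length, n, replace = TRUE)
  for (try in 1:100) {
    pts <- sort(sample.int(config$background_len - 1L, n))
    if (all(diff(pts) >= min_sep)) break
    if (try == 100) stop("cannot place non-overlapping insertion points")
  }
  data.frame(source_start = starts, source_length = lens, divergence = divs,
             insertion_point = pts)
}

#' Plant NUMT insertions into a random nuclear background
#'
#' Generates an i.i.d. background at the configured GC content, copies each
#' spec's source segment from the circular root, mutates it to its
#' divergence (substitutions and small indels at a 10:1 ratio), inserts it,
#' and records the exact post-insertion coordinates as the truth set.
#'
#' @param config a [sim_config()] with `numt_specs` set.
#' @return a `TruthSet`: list with `genome` (named character vector, one
#'   sequence `chrS`), `truth` (`GRanges` with `source_start`,
#'   `source_length`, `divergence` metadata) and `config`.
#' @export
plant_numts <- function(config) {
  specs <- config$numt_specs
  if (is.null(specs)) stop("config$numt_specs is not set")
  if (anyDuplicated(specs$insertion_point))
    stop("overlapping (duplicate) insertion points")
  root <- sim_root(config)
  set.seed(config$seed + 3L)
  gc <- config$background_gc
  bg <- paste(sample(c("A", "C", "G", "T"), config$background_len,
                     replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
              collapse = "")
  specs <- specs[order(specs$insertion_point), , drop = FALSE]
  inserts <- vapply(seq_len(nrow(specs)), function(i) {
    src <- circ_substr(root, specs$source_start[i], specs$source_length[i])
    d <- specs$divergence[i]
    n_events <- round(d * nchar(src))
    n_indel <- round(n_events / 11)
    mutate_seq(src, n_events - n_indel, n_indel)
  }, character(1))
  pieces <- character(2L * nrow(specs) + 1L)
  starts <- integer(nrow(specs))
  ends <- integer(nrow(specs))
  prev <- 0L
  offset <- 0L
  for (i in seq_len(nrow(specs))) {
    pt <- specs$insertion_point[i]
    pieces[2L * i - 1L] <- substr(bg, prev + 1L, pt)
    starts[i] <- pt + offset                 # 0-based
    ends[i] <- starts[i] + nchar(inserts[i])
    pieces[2L * i] <- inserts[i]
    offset <- offset + nchar(inserts[i])
    prev <- pt
  }
  pieces[2L * nrow(specs) + 1L] <- substr(bg, prev + 1L, nchar(bg))
  genome <- c(chrS = paste(pieces, collapse = ""))
  truth <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = starts + 1L, end = ends),
    source_start = specs$source_start, source_length = specs$source_length,
    divergence = specs$divergence)
  structure(list(genome = genome, truth = truth, config = config),
            class = "TruthSet")
}

#' Score recovery of planted insertions
#'
#' A truth interval is recovered when some called interval overlaps it by at
#' least 50% reciprocally. Precision counts called intervals overlapping no
#' truth interval as false. Boundary error is the mean absolute start/end
#' offset of the best-matching called interval among recovered pairs;
#' `frac_within_slack` is the fraction of recovered boundaries within
#' `slack` bases of the truth.
#'
#' @param called merged `GRanges` of NUMT calls.
#' @param truth a `TruthSet` or its `truth` `GRanges`.
#' @param slack boundary tolerance in bases for `frac_within_slack`
#'   (default 5).
#' @return list with `recall`, `precision`, `boundary_error`,
#'   `frac_within_slack` and `per_truth` (data.frame with `recovered`,
#'   `divergence`, `boundary_err` per planted insertion).
#' @export
evaluate_recovery <- function(called, truth, slack = 5L) {
  tr <- if (inherits(truth, "TruthSet")) truth$truth else truth
  nt <- length(tr)
  recovered <- logical(nt)
  bnd <- rep(NA_real_, nt)
  if (length(called) && nt) {
    ov <- GenomicRanges::findOverlaps(tr, called, ignore.strand = TRUE)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        tr[qi], called[si], ignore.strand = TRUE))
      recip <- w >= 0.5 * GenomicRanges::width(tr)[qi] &
        w >= 0.5 * GenomicRanges::width(called)[si]
      for (t in unique(qi[recip])) {
        cand <- si[recip & qi == t]
        best <- cand[which.max(w[recip & qi == t])]
        recovered[t] <- TRUE
        bnd[t] <- mean(c(
          abs(GenomicRanges::start(called)[best] -
                GenomicRanges::start(tr)[t]),
          abs(GenomicRanges::end(called)[best] - GenomicRanges::end(tr)[t])))
      }
    }
  }
  n_called <- length(called)
  false_calls <- if (n_called) {
    sum(GenomicRanges::countOverlaps(called, tr, ignore.strand = TRUE) == 0)
  } else 0L
  div <- S4Vectors::mcols(tr)$divergence
  list(recall = if (nt) mean(recovered) else NA_real_,
       precision = if (n_called) 1 - false_calls / n_called else NA_real_,
       boundary_error = if (any(recovered)) mean(bnd[recovered]) else
         NA_real_,
       frac_within_slack = if (any(recovered))
         mean(bnd[recovered] <= slack) else NA_real_,
       per_truth = data.frame(recovered = recovered,
                              divergence = div %||% rep(NA_real_, nt),
                              boundary_err = bnd))
}

#' The standard simulated scene
#'
#' Convenience wrapper assembling the benchmark this package validates
#' itself on: a 2 Mb background with 50 planted insertions (lengths
#' log-uniform 35-14,855 bp, divergence uniform 0-20%), a simulated
#' mitochondrial population, control fragments, and a discovery pool of 8
#' full-length records, 12 control fragments and the root reference.
#'
#' @param seed RNG seed (default 7).
#' @param n_pool_full,n_pool_control pool sizes drawn from the simulated
#'   population (defaults 8 and 12).
#' @return list with `config`, `truthset`, `population`, `control`, `pool`.
#' @export
standard_scene <- function(seed = 7L, n_pool_full = 8L, n_pool_control = 12L) {
  config <- sim_config(seed = seed)
  config$numt_specs <- random_numt_specs(config)
  truthset <- plant_numts(config)
  population <- simulate_population(config)
  control <- simulate_control_fragments(population, config)
  uniq <- dedup_exact(population)
  full <- filter_full_length(uniq[seq_len(min(n_pool_full, length(uniq)))])
  ctrl <- control[seq_len(min(n_pool_control, length(control)))]
  ref <- mito_records(setNames(sim_root(config), "sim_ref"), "reference")
  pool <- assemble_panmito(full, ctrl, ref, pad = 100L)
  list(config = config, truthset = truthset, population = population,
       control = control, pool = pool)
}
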