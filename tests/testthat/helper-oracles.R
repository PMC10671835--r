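# Independent oracles used across the suite. These deliberately share no
# code with the package internals: full-matrix dynamic programming, boolean
# masks, naive string scans.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Full Smith-Waterman-Gotoh local alignment score (affine gaps: a gap of
# length g costs gap_open + gap_extend * g), complete O(nm) matrices.
gotoh_score <- function(q, s, reward = 2, penalty = -3, gap_open = 5,
                        gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEGI <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEGI, n + 1, m + 1)
  Iy <- matrix(NEGI, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (qc[i] == sc[j]) reward else penalty
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + sub)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

# Pure bisection root of the lambda equation, independent of solve_lambda.
lambda_bisect <- function(reward, penalty, tol = 1e-12) {
  f <- function(l) 0.25 * exp(l * reward) + 0.75 * exp(l * penalty) - 1
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Boolean-mask interval algebra over a single chromosome of length n.
mask_from_intervals <- function(start0, end0, n) {
  m <- logical(n)
  for (i in seq_along(start0)) {
    if (end0[i] > start0[i]) m[(start0[i] + 1):end0[i]] <- TRUE
  }
  m
}

mask_to_intervals <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start0 = starts[r$values] - 1L, end0 = ends[r$values])
}

# Naive sliding-window exact k-mer scan over both strands; returns the set
# of distinct (kmer, chrom, start) placements, 1-based starts.
naive_kmer_scan <- function(kmers, genome, k) {
  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < k) next
    wins <- substring(s, 1:(L - k + 1), k:L)
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") kmers else vapply(kmers, rc, character(1))
      hit <- which(wins %in% probe)
      if (length(hit)) {
        kid <- match(wins[hit],
                     if (strand == "+") kmers else
                       vapply(kmers, rc, character(1)))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = hit, kmer = kmers[kid],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      kmer = character()))
  df <- do.call(rbind, out)
  unique(df[order(df$chrom, df$start, df$kmer), , drop = FALSE])
}

# Brute-force circular run scan: maximal circular runs of positions with
# value <= thr and length >= min_run, on a doubled vector.
circular_low_runs <- function(cov, thr, min_run) {
  L <- length(cov)
  low <- cov <= thr
  if (all(low)) return(data.frame(start = 1L, end = L))
  dbl <- c(low, low)
  runs <- rle(dbl)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & starts <= L
  res <- list()
  for (i in which(keep)) {
    s <- starts[i]; e <- ends[i]
    if (e - s + 1L > L) e <- s + L - 1L
    if (e - s + 1L >= min_run) {
      e_wrapped <- ((e - 1L) %% L) + 1L
      res[[length(res) + 1L]] <- data.frame(start = s, end = e_wrapped)
    }
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer()))
  df <- do.call(rbind, res)
  df[order(df$start), , drop = FALSE]
}

# The standard scene is used by several files; build it once per run.
scene_cache <- new.env(parent = emptyenv())
get_standard_scene <- function() {
  if (is.null(scene_cache$scene))
    scene_cache$scene <- standard_scene(seed = 7)
  scene_cache$scene
}
get_standard_result <- function() {
  if (is.null(scene_cache$result)) {
    scene <- get_standard_scene()
    scene_cache$result <- find_numts(scene$pool, scene$truthset$genome)
  }
  scene_cache$result
}
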