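test_that("seeding finds exact matches on both strands and agrees with a
           brute-force word-intersection scan", {
  set.seed(101)
  q <- random_dna(50)
  sh <- seed_hits(q, q, word_size = 11)
  expect_true(any(sh$qstart == 1 & sh$sstart == 1 & sh$length == 50 &
                    sh$strand == "+"))

  sh_rc <- seed_hits(q, rc(q), word_size = 11)
  expect_true(all(sh_rc$strand == "-"))
  expect_true(any(sh_rc$length == 50))

  # random sequences: every maximal run >= w found by the naive diagonal scan
  naive_maximal_runs <- function(q, s, w) {
    qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
    runs <- 0L
    for (d in (-(length(qc) - w)):(length(sc) - w)) {
      i <- max(1L, 1L - d); len <- 0L
      while (i <= length(qc) && i + d <= length(sc)) {
        if (qc[i] == sc[i + d]) len <- len + 1L
        else { if (len >= w) runs <- runs + 1L; len <- 0L }
        i <- i + 1L
      }
      if (len >= w) runs <- runs + 1L
    }
    runs
  }
  set.seed(42)
  a <- random_dna(1000); b <- random_dna(1000)
  got <- seed_hits(a, b, word_size = 7, both_strands = FALSE)
  expect_equal(nrow(got), naive_maximal_runs(a, b, 7))
})

test_that("seed extension reproduces simple arithmetic scores", {
  h <- extend_alignment("ACGTACGT", "ACGTACGT", 1, 1, 8)
  expect_equal(h$score, 16)
  expect_equal(h$identity, 100)
  expect_equal(h$gaps, 0)

  # one mismatch among 10 aligned bases: 9 * 2 - 3
  h2 <- extend_alignment("ACGTACGTAC", "ACGTACCTAC", 1, 1, 6)
  expect_equal(h2$score, 15)
  expect_equal(h2$identity, 90)
  expect_equal(h2$aligned_cols, 10)
})

test_that("extension equals the full Smith-Waterman-Gotoh optimum on random
           pairs whenever a word seed exists", {
  set.seed(7)
  n_checked <- 0L
  for (r in 1:80) {
    core_len <- sample(20:60, 1)
    core <- random_dna(core_len)
    mut <- strsplit(core, "")[[1]]
    n_mut <- sample(0:floor(core_len / 8), 1)
    if (n_mut > 0) {
      at <- sample(core_len, n_mut)
      mut[at] <- vapply(mut[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    q <- paste0(random_dna(sample(5:50, 1)), core,
                random_dna(sample(5:50, 1)))
    s <- paste0(random_dna(sample(5:50, 1)), paste(mut, collapse = ""),
                random_dna(sample(5:50, 1)))
    sh <- seed_hits(q, s, word_size = 11, both_strands = FALSE)
    if (nrow(sh) == 0) next
    got <- max(vapply(seq_len(nrow(sh)), function(i)
      extend_alignment(q, s, sh$qstart[i], sh$sstart[i],
                       sh$length[i])$score, numeric(1)))
    expect_equal(got, gotoh_score(q, s))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 40)
})

test_that("hit filtering enforces strict identity, inclusive length, and
           the e-value ceiling", {
  hits <- data.frame(
    evalue = c(1e-6, 1e-6, 1e-3, 1e-6),
    identity = c(63.0, 90, 90, 90),
    subject_start = 0L, subject_end = c(100L, 28L, 100L, 27L))
  out <- filter_hits(hits, filter_thresholds())
  expect_equal(nrow(out), 1L)          # only the length-28, 90%-id survivor
  expect_equal(out$subject_end, 28L)
  removed <- attr(out, "removed")
  expect_equal(unname(removed["evalue"]), 1L)
  expect_equal(unname(removed["identity"]), 1L)
  expect_equal(unname(removed["length"]), 1L)
})

test_that("an exact planted copy is recovered as one full-identity NUMT and
           a 50%-identity copy is rejected", {
  set.seed(55)
  ref_seq <- random_dna(16569)
  ref <- mito_records(c(ref = ref_seq), "reference")
  no_full <- mito_records(setNames(character(), character()), "full")
  no_ctrl <- mito_records(setNames(character(), character()), "control")
  pool <- assemble_panmito(no_full, no_ctrl, ref, pad = 100)

  insert <- substr(ref_seq, 1001, 2000)
  genome <- c(chr1 = paste0(random_dna(5000), insert, random_dna(5000)))
  res <- find_numts(pool, genome)
  expect_equal(length(res$numts), 1L)
  # boundaries exact up to chance 1-2 bp matches in the flanking background
  expect_lte(abs(GenomicRanges::start(res$numts) - 5001L), 2L)
  expect_lte(abs(GenomicRanges::width(res$numts) - 1000L), 4L)
  expect_true(any(res$hits$identity == 100))

  # mutate every other base: ~50% identity, below the >63 filter
  chars <- strsplit(insert, "")[[1]]
  at <- seq(1, 1000, by = 2)
  chars[at] <- vapply(chars[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  genome50 <- c(chr1 = paste0(random_dna(5000), paste(chars, collapse = ""),
                              random_dna(5000)))
  res50 <- find_numts(pool, genome50)
  expect_equal(length(res50$numts), 0L)
})

test_that("discovery is strand-symmetric: a reverse-complemented genome
           yields the mirrored interval set", {
  set.seed(66)
  cfg <- sim_config(seed = 66, background_len = 150000,
                    numt_specs = data.frame(
                      source_start = c(2000, 9000),
                      source_length = c(400, 1500),
                      divergence = c(0.03, 0.12),
                      insertion_point = c(40000, 100000)))
  ts <- plant_numts(cfg)
  ref <- mito_records(setNames(sim_root(cfg), "ref"), "reference")
  pool <- assemble_panmito(
    mito_records(setNames(character(), character()), "full"),
    mito_records(setNames(character(), character()), "control"), ref)
  fwd <- find_numts(pool, ts$genome)
  L <- nchar(ts$genome[[1]])
  rev_genome <- setNames(rc(ts$genome[[1]]), names(ts$genome))
  bwd <- find_numts(pool, rev_genome)
  mirrored <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(bwd$numts),
    IRanges::IRanges(start = L - GenomicRanges::end(bwd$numts) + 1L,
                     end = L - GenomicRanges::start(bwd$numts) + 1L))
  expect_equal(as.data.frame(sort(mirrored))[, 1:3],
               as.data.frame(sort(fwd$numts))[, 1:3])
})

test_that("undiverged planted copies are recovered with boundaries within
           2 bp of the truth", {
  cfg <- sim_config(seed = 77, background_len = 120000,
                    numt_specs = data.frame(
                      source_start = c(500, 5000, 12000),
                      source_length = c(60, 300, 2000),
                      divergence = 0,
                      insertion_point = c(20000, 60000, 100000)))
  ts <- plant_numts(cfg)
  ref <- mito_records(setNames(sim_root(cfg), "ref"), "reference")
  pool <- assemble_panmito(
    mito_records(setNames(character(), character()), "full"),
    mito_records(setNames(character(), character()), "control"), ref)
  res <- find_numts(pool, ts$genome)
  ev <- evaluate_recovery(res$numts, ts)
  expect_equal(ev$recall, 1)
  expect_true(all(ev$per_truth$boundary_err <= 2))
})

test_that("hits landing entirely inside the circular pad are wrapped back
           to unpadded query coordinates", {
  set.seed(88)
  mt <- random_dna(16569)
  ref <- mito_records(c(ref = mt), "reference")
  pool <- assemble_panmito(
    mito_records(setNames(character(), character()), "full"),
    mito_records(setNames(character(), character()), "control"), ref,
    pad = 100)
  # plant a copy of mt positions 10..59: the pad images those as 16579..16628
  insert <- substr(mt, 10, 59)
  genome <- c(chr1 = paste0(random_dna(3000), insert, random_dna(3000)))
  res <- find_numts(pool, genome,
                    thresholds = filter_thresholds(min_length = 28))
  expect_true(all(res$hits$query_start <= 16569))
  expect_true(any(res$hits$query_start == 10))
})
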