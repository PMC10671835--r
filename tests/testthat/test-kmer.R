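test_that("k-mer decomposition counts every clean window and discards
           windows touching N or ambiguity codes", {
  set.seed(11)
  s <- random_dna(100)
  tab <- kmer_decompose(s, k = 20)
  expect_equal(tab$total_segments, 81L)

  tabN <- kmer_decompose("ACGTNACGTACG", k = 4)
  # windows overlapping the N (positions 2-5) are absent
  expect_false(any(grepl("N", names(tabN$counts))))
  expect_equal(tabN$total_segments, 5L)  # window 1 plus the 4 after the N

  tabA <- kmer_decompose(strrep("A", 30), k = 20)
  expect_equal(tabA$unique_count, 1L)
  expect_equal(tabA$total_segments, 11L)

  tabR <- kmer_decompose("ACGTRACGT", k = 4)
  expect_false(any(grepl("R", names(tabR$counts))))
})

test_that("k-mer mapping hits exact placements on both strands and
           collapses duplicate placements", {
  set.seed(12)
  km <- random_dna(20)
  tab <- kmer_decompose(km, k = 20)
  genome <- c(chr1 = paste0(random_dna(500), km, random_dna(500)))
  h <- map_kmers(tab, genome)
  expect_equal(length(h), 1L)
  expect_equal(GenomicRanges::start(h), 501L)
  expect_equal(as.character(GenomicRanges::strand(h)), "+")

  genome_rc <- c(chr1 = paste0(random_dna(300), rc(km), random_dna(300)))
  h2 <- map_kmers(tab, genome_rc)
  expect_equal(length(h2), 1L)
  expect_equal(as.character(GenomicRanges::strand(h2)), "-")

  expect_error(map_kmers(tab, genome, max_mismatch = 4), "<= 3")
})

test_that("exact mapping equals a naive sliding-window scan on a seeded
           genome and mismatch tolerance is monotone", {
  set.seed(13)
  genome <- c(chrA = random_dna(60000), chrB = random_dna(40000))
  # half genome-derived k-mers (guaranteed hits), half random
  pulls <- vapply(sample(1:59000, 250), function(p)
    substr(genome[["chrA"]], p, p + 19), character(1))
  tab <- kmer_decompose(c(pulls, vapply(1:250, function(i) random_dna(20),
                                        character(1))), k = 20)
  got <- map_kmers(tab, genome)
  oracle <- naive_kmer_scan(names(tab$counts), genome, 20)
  got_df <- unique(data.frame(
    chrom = as.character(GenomicRanges::seqnames(got)),
    start = GenomicRanges::start(got),
    kmer = S4Vectors::mcols(got)$kmer, stringsAsFactors = FALSE))
  got_df <- got_df[order(got_df$chrom, got_df$start, got_df$kmer), ]
  rownames(got_df) <- rownames(oracle) <- NULL
  expect_equal(got_df, oracle)

  # raising max_mismatch never loses a placement
  small_tab <- kmer_decompose(pulls[1:20], k = 20)
  g_small <- c(chrA = substr(genome[["chrA"]], 1, 20000))
  h0 <- map_kmers(small_tab, g_small, max_mismatch = 0)
  h1 <- map_kmers(small_tab, g_small, max_mismatch = 1)
  key <- function(h) paste(GenomicRanges::start(h),
                           S4Vectors::mcols(h)$kmer)
  expect_true(all(key(h0) %in% key(h1)))
})

test_that("segment merging unions hit footprints (mask oracle) and every
           segment is at least k long", {
  set.seed(14)
  km1 <- random_dna(20)
  km2 <- random_dna(20)
  # overlapping placements at offsets 0 and 5 -> one 25 bp segment
  genome <- c(chr1 = paste0(
    random_dna(100), substr(km1, 1, 5), km1, random_dna(100)))
  tab <- kmer_decompose(c(paste0(substr(km1, 1, 5), substr(km1, 1, 15)),
                          km1), k = 20)
  h <- map_kmers(tab, genome)
  segs <- merge_segments(h)
  expect_true(all(GenomicRanges::width(segs) >= 20))
  expect_true(any(GenomicRanges::width(segs) == 25L))

  # far-apart placements stay separate 20 bp segments
  genome2 <- c(chr1 = paste0(random_dna(100), km1, random_dna(100), km2,
                             random_dna(100)))
  tab2 <- kmer_decompose(c(km1, km2), k = 20)
  segs2 <- merge_segments(map_kmers(tab2, genome2))
  expect_equal(length(segs2), 2L)
  expect_true(all(GenomicRanges::width(segs2) == 20L))

  # seeded scene: footprint union equals the boolean-mask oracle
  genome3 <- c(chrA = random_dna(30000))
  pulls <- vapply(sample(1:29000, 120), function(p)
    substr(genome3[["chrA"]], p, p + 19), character(1))
  tab3 <- kmer_decompose(pulls, k = 20)
  hits3 <- map_kmers(tab3, genome3)
  segs3 <- merge_segments(hits3)
  mask <- mask_from_intervals(GenomicRanges::start(hits3) - 1L,
                              GenomicRanges::end(hits3), 30000)
  oracle <- mask_to_intervals(mask)
  expect_equal(GenomicRanges::start(segs3) - 1L, oracle$start0)
  expect_equal(GenomicRanges::end(segs3), oracle$end0)
})

test_that("the length histogram is exhaustive and conserves the segment
           count", {
  segs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 100, 200),
                             width = c(20, 20, 25)),
    supporting_kmers = c(1L, 3L, 6L))
  h <- length_histogram(segs)
  expect_equal(h$length, c(20L, 25L))
  expect_equal(h$n_segments, c(2L, 1L))
  expect_equal(h$n_kmers, c(4L, 6L))
  expect_equal(sum(h$n_segments), length(segs))
  expect_equal(nrow(length_histogram(GenomicRanges::GRanges())), 0L)
})

test_that("the knee detector finds a constructed turning point at 28,
           defaults on flat input, and matches an exhaustive search", {
  lens <- 20:60
  counts <- ifelse(lens <= 27, 1e5, 1e2)
  h <- data.frame(length = lens, count = counts)
  expect_equal(turning_point(h, k = 20), 28L)

  flat <- data.frame(length = 20:60, count = 500)
  expect_warning(tp <- turning_point(flat, k = 20), "default")
  expect_equal(tp, 28L)

  # random occupied histogram: exhaustive search over log-count drops
  set.seed(15)
  lens2 <- sort(sample(20:80, 30))
  counts2 <- sample(1:10000, 30)
  h2 <- data.frame(length = lens2, count = counts2)
  got <- suppressWarnings(turning_point(h2, k = 20))
  lg <- log(counts2)
  drops <- lg[-length(lg)] - lg[-1]
  at <- lens2[-1]
  in_r <- at >= 21 & at <= 60
  exhaustive <- if (any(in_r) && max(drops[in_r]) > 0)
    at[in_r][which.max(drops[in_r])] else 28L
  expect_equal(got, exhaustive)
})
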