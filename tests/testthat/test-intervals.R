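gr <- function(start0, end0, chrom = "chr1") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0))
}

test_that("merging joins overlapping and book-ended intervals and matches a
           boolean-mask oracle on random input", {
  m1 <- merge_intervals(gr(c(0, 5), c(10, 15)))
  expect_equal(GenomicRanges::start(m1), 1L)
  expect_equal(GenomicRanges::end(m1), 15L)

  m2 <- merge_intervals(gr(c(0, 10), c(10, 20)))
  expect_equal(length(m2), 1L)
  expect_equal(GenomicRanges::width(m2), 20L)

  set.seed(1234)
  n <- 1000L
  s <- sample(0:9950, n, replace = TRUE)
  e <- s + sample(1:50, n, replace = TRUE)
  merged <- merge_intervals(gr(s, e))
  oracle <- mask_to_intervals(mask_from_intervals(s, e, 10100))
  expect_equal(GenomicRanges::start(merged) - 1L, oracle$start0)
  expect_equal(GenomicRanges::end(merged), oracle$end0)

  # idempotent and order-independent
  expect_equal(as.data.frame(merge_intervals(merged)),
               as.data.frame(merged))
  perm <- sample(n)
  expect_equal(as.data.frame(merge_intervals(gr(s[perm], e[perm]))),
               as.data.frame(merged))

  # min_gap joins intervals separated by less than the gap
  g <- merge_intervals(gr(c(0, 15), c(10, 25)), min_gap = 6)
  expect_equal(length(g), 1L)
  g2 <- merge_intervals(gr(c(0, 15), c(10, 25)), min_gap = 5)
  expect_equal(length(g2), 2L)
})

test_that("summary statistics use base lengths with the lower median", {
  st <- interval_summary(gr(c(0, 20), c(10, 50)))
  expect_equal(st$count, 2L)
  expect_equal(st$total_length, 40L)
  expect_equal(st$min, 10L)
  expect_equal(st$max, 30L)
  expect_equal(st$mean, 20)
  expect_equal(st$median, 10L)  # lower median of {10, 30}

  one <- interval_summary(gr(5, 25))
  expect_true(all(unlist(one[c("min", "median", "max")]) == 20L) &&
                one$mean == 20)
  expect_warning(z <- interval_summary(GenomicRanges::GRanges()), "empty")
  expect_equal(z$count, 0L)
})

test_that("overlap statistics satisfy the identity cases, the published
           blacklist fraction arithmetic, and inclusion-exclusion", {
  A <- merge_intervals(gr(c(0, 100), c(50, 200)))
  expect_equal(overlap_stats(A, A)$frac_A_in_B, 1)
  expect_equal(overlap_stats(A, A)$frac_shared_of_union, 1)

  B <- merge_intervals(gr(1000, 2000))
  expect_equal(overlap_stats(A, B)$shared_length, 0L)

  # compilation B of total length 415,928 with 278,266 bases inside A
  A2 <- merge_intervals(gr(0, 500000))
  B2 <- merge_intervals(gr(c(221734, 500000),
                           c(500000, 500000 + 415928 - 278266)))
  ov <- overlap_stats(A2, B2)
  expect_equal(sum(GenomicRanges::width(B2)), 415928L)
  expect_equal(ov$shared_length, 278266L)
  expect_equal(ov$frac_B_in_A, 278266 / 415928, tolerance = 1e-12)

  # inclusion-exclusion on random merged sets
  set.seed(99)
  mk <- function() {
    s <- sample(0:5000, 200, replace = TRUE)
    merge_intervals(gr(s, s + sample(1:80, 200, replace = TRUE)))
  }
  X <- mk(); Y <- mk()
  ovxy <- overlap_stats(X, Y)
  lu <- sum(GenomicRanges::width(GenomicRanges::union(X, Y)))
  expect_equal(sum(GenomicRanges::width(X)) + sum(GenomicRanges::width(Y)),
               lu + ovxy$shared_length)
  # symmetry of the shared length
  expect_equal(overlap_stats(Y, X)$shared_length, ovxy$shared_length)

  GA <- X; GenomeInfoDb::genome(GA) <- "simA"
  GB <- Y; GenomeInfoDb::genome(GB) <- "simB"
  expect_error(overlap_stats(GA, GB), "genome label mismatch")
})

test_that("the exclusion-set union merges three sources, labels provenance,
           and matches the mask oracle", {
  numts <- merge_intervals(gr(c(0, 100), c(50, 150)))
  empty <- GenomicRanges::GRanges()
  u1 <- blacklist_union(numts, empty, empty)
  expect_equal(as.data.frame(u1)[, 1:3], as.data.frame(numts)[, 1:3])
  expect_true(all(S4Vectors::mcols(u1)$sources == "numts"))

  u2 <- blacklist_union(numts, numts, empty)
  expect_equal(sum(GenomicRanges::width(u2)),
               sum(GenomicRanges::width(numts)))

  set.seed(4321)
  mk <- function(n) {
    s <- sample(0:9000, n, replace = TRUE)
    merge_intervals(gr(s, s + sample(1:60, n, replace = TRUE)))
  }
  a <- mk(150); b <- mk(150); p <- mk(150)
  u3 <- blacklist_union(a, b, p)
  mask <- mask_from_intervals(GenomicRanges::start(a) - 1L,
                              GenomicRanges::end(a), 9100) |
    mask_from_intervals(GenomicRanges::start(b) - 1L,
                        GenomicRanges::end(b), 9100) |
    mask_from_intervals(GenomicRanges::start(p) - 1L,
                        GenomicRanges::end(p), 9100)
  expect_equal(sum(GenomicRanges::width(u3)), sum(mask))
})

test_that("BED io round-trips bit-exactly, reports bad lines, and keeps
           strand", {
  x <- gr(c(10, 200, 1000), c(90, 450, 1100))
  S4Vectors::mcols(x)$name <- c("n1", "n2", "n3")
  S4Vectors::mcols(x)$score <- c("0", "5", "9")
  GenomicRanges::strand(x) <- c("+", "-", "+")
  path <- tempfile(fileext = ".bed")
  write_bed(x, path)
  first <- readLines(path)
  y <- read_bed(path)
  write_bed(y, path)
  expect_identical(readLines(path), first)
  expect_equal(as.character(GenomicRanges::strand(y)),
               c("+", "-", "+"))
  expect_equal(S4Vectors::mcols(y)$name, c("n1", "n2", "n3"))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t100\t50"), bad)
  expect_error(read_bed(bad), "line 2")

  tracked <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t0\t10"), tracked)
  expect_warning(tr <- read_bed(tracked), "track")
  expect_equal(length(tr), 1L)
})

test_that("mitochondrial coordinate conversion is a clean inverse pair", {
  b <- mt1_to_bed(16024, 16569)
  expect_equal(b$start, 16023L)
  expect_equal(b$end, 16569L)
  back <- bed_to_mt1(b$start, b$end)
  expect_equal(back$start, 16024L)
  expect_equal(back$end, 16569L)
})
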