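bedpeHeader <- paste0("#", paste(c("chrom1", "start1", "end1", "chrom2",
                                   "start2", "end2", "observed", "expected"),
                                 collapse = "\t"))

bedpeRow <- function(chrom1, s1, chrom2, s2, o, e, bin = 1e4) {
  paste(chrom1, s1, s1 + bin, chrom2, s2, s2 + bin, o, e, sep = "\t")
}

test_that("readLoops parses BEDPE rows with counts, skipping headers", {
  path <- writeBedpeFixture(c(
    bedpeHeader,
    bedpeRow("chr1", 1000000, "chr1", 1350000, 159, 36),
    bedpeRow("chr2", 5000000, "chr2", 5200000, 80, 20),
    bedpeRow("chr3", 100000, "chr3", 400000, 25, 5)))
  lp <- readLoops(path)
  expect_s4_class(lp, "HiCLoops")
  expect_length(lp, 3)
  expect_equal(observedCounts(lp), c(159, 80, 25))
  expect_equal(expectedCounts(lp), c(36, 20, 5))
  # 0-based half-open on disk -> 1-based closed GRanges in memory
  expect_equal(GenomicRanges::start(firstAnchor(lp))[1], 1000001)
  expect_equal(GenomicRanges::end(firstAnchor(lp))[1], 1010000)
  expect_equal(loopSpans(lp), c(350000, 200000, 300000))
})

test_that("readLoops reports malformed and invalid rows by line number", {
  na_path <- writeBedpeFixture(c(
    bedpeHeader,
    bedpeRow("chr1", 1e6, "chr1", 1.35e6, 159, 36),
    bedpeRow("chr1", 2e6, "chr1", 2.35e6, "NA", 36)))
  expect_error(readLoops(na_path), "line 3.*observed")

  short_path <- writeBedpeFixture(c(
    bedpeHeader,
    bedpeRow("chr1", 1e6, "chr1", 1.35e6, 159, 36),
    "chr1\t100\t200\tchr1"))
  expect_error(readLoops(short_path), "line 3")

  neg_path <- writeBedpeFixture(c(
    bedpeHeader,
    bedpeRow("chr1", 1e6, "chr1", 1.35e6, -4, 36)))
  expect_error(readLoops(neg_path), "negative")

  expect_error(readLoops(file.path(tempdir(), "no-such-file.bedpe")),
               "not found")
})

test_that("readLoops orders anchors upstream-first and normalizes chroms", {
  path <- writeBedpeFixture(c(
    bedpeHeader,
    bedpeRow("1", 1350000, "1", 1000000, 100, 10)))  # reversed anchors
  lp <- readLoops(path)
  expect_equal(as.character(GenomicRanges::seqnames(firstAnchor(lp))),
               "chr1")
  expect_equal(GenomicRanges::start(firstAnchor(lp)), 1000001)
  expect_equal(loopSpans(lp), 350000)
})

test_that("write/read round-trips records exactly", {
  lp <- makeLoops(chrom = c("chr1", "chr7"), start1 = c(1e6, 2.5e6),
                  span = c(3.5e5, 1.2e6), observed = c(159, 42.5),
                  expected = c(36, 7.25))
  path <- file.path(withr::local_tempdir(), "rt.bedpe")
  writeLoops(lp, path)
  back <- readLoops(path)
  expect_equal(observedCounts(back), observedCounts(lp))
  expect_equal(expectedCounts(back), expectedCounts(lp))
  expect_equal(loopSpans(back), loopSpans(lp))
  expect_equal(as.character(GenomicRanges::seqnames(firstAnchor(back))),
               as.character(GenomicRanges::seqnames(firstAnchor(lp))))
  expect_equal(GenomicRanges::start(secondAnchor(back)),
               GenomicRanges::start(secondAnchor(lp)))
})

test_that("loopSpans is start-to-start and rejects inter-chromosomal pairs", {
  lp <- makeLoops("chr1", 1e6, 3.5e5, 159, 36)
  expect_equal(loopSpans(lp), 350000)
  same <- makeLoops("chr1", 1e6, 0, 10, 5)
  expect_equal(loopSpans(same), 0)
  trans <- HiCLoops(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e4)),
    GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1e4)), 10, 5)
  expect_error(loopSpans(trans), "inter-chromosomal")
})

test_that("binSpan floors to the bin grid and validates inputs", {
  expect_equal(binSpan(347500), 340000)
  expect_equal(binSpan(0), 0)
  expect_equal(binSpan(10000), 10000)
  expect_equal(binSpan(c(5000, 19999), binSize = 10000), c(0, 10000))
  expect_error(binSpan(100, binSize = 0), "positive")
  expect_error(binSpan(-1), "non-negative")
})

test_that("filterLoops applies the three rules, hand-enumerated", {
  res <- filterLoops(toyFilterLoops())
  expect_length(res$loops, 2)
  expect_equal(observedCounts(res$loops), c(50, 40))  # order preserved
  rep <- res$report
  expect_equal(rep$removed_count[rep$rule == "span"], 1)       # 2.5 Mb loop
  expect_equal(rep$removed_count[rep$rule == "autosome"], 1)   # chrX loop
  expect_equal(rep$removed_count[rep$rule == "obs_gt_exp"], 1) # o == e loop
})

test_that("filterLoops boundary: span exactly 2 Mb is removed (strict)", {
  lp <- makeLoops("chr1", c(1e6, 1e6), c(2e6, 1.99e6), c(50, 50), c(10, 10))
  res <- filterLoops(lp)
  expect_length(res$loops, 1)
  expect_equal(loopSpans(res$loops), 1.99e6)
})

test_that("filterLoops is idempotent and reconciles counts", {
  lp <- toyFilterLoops()
  first <- filterLoops(lp)
  second <- filterLoops(first$loops)
  expect_length(second$loops, length(first$loops))
  expect_true(all(second$report$removed_count == 0))
  # rules fail disjointly on this fixture: removals sum to the deficit
  expect_equal(length(lp) - length(first$loops),
               sum(first$report$removed_count))
})

test_that("filterLoops passes everything through when all rules hold", {
  lp <- makeLoops(c("chr1", "chr22"), c(1e6, 2e6), c(1e5, 1.5e6),
                  c(100, 50), c(20, 10))
  res <- filterLoops(lp)
  expect_length(res$loops, 2)
  expect_true(all(res$report$removed_count == 0))
  empty <- filterLoops(res$loops[0])
  expect_length(empty$loops, 0)
})

test_that("HiCLoops validity catches inconsistent slots", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e4))
  expect_error(HiCLoops(a, a, c(1, 2), 1), "one value per loop")
  expect_error(HiCLoops(a, a, -1, 0), "non-negative")
  expect_error(HiCLoops(a, a, 1, 0, referenceDepth = 0), "positive")
})
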