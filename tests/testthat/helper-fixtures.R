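# In-code fixtures shared across test files.

# Build a HiCLoops object from plain vectors (10 kb anchors, start-aligned).
makeLoops <- function(chrom, start1, span, observed, expected,
                      binSize = 1e4, referenceDepth = 5536073657) {
  a1 <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start1 + 1, start1 + binSize))
  a2 <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start1 + span + 1, start1 + span + binSize))
  HiCLoops(a1, a2, observed, expected, referenceDepth)
}

# The five-loop toy set exercising each filter rule once:
# spans 100 kb / 500 kb / 2.5 Mb, one loop on chrX, one with o == e.
toyFilterLoops <- function() {
  makeLoops(chrom = c("chr1", "chr2", "chr3", "chrX", "chr5"),
            start1 = rep(1e6, 5),
            span = c(1e5, 5e5, 2.5e6, 3e5, 3e5),
            observed = c(50, 40, 30, 20, 10),
            expected = c(10, 10, 10, 10, 10))
}

# Write a loop set as a BEDPE text fixture, returning the path.
writeBedpeFixture <- function(lines, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  path <- file.path(dir, "loops.bedpe")
  writeLines(lines, path)
  path
}

# Monte-Carlo oracle for the two-group power formula: difference of log
# group means, normalized by the model-based variance at the design mean
# (the quantity the closed form approximates), two-sided at level alpha.
mcRejectionRate <- function(mu, dispersion, effect, alpha, n, nsim, seed) {
  set.seed(seed)
  y1 <- matrix(stats::rnbinom(n * nsim, mu = mu, size = 1 / dispersion),
               nrow = n)
  y2 <- matrix(stats::rnbinom(n * nsim, mu = mu * effect,
                              size = 1 / dispersion), nrow = n)
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  ok <- m1 > 0 & m2 > 0
  z <- (log(m2) - log(m1)) / sqrt(2 * (1 / mu + dispersion) / n)
  mean(abs(z[ok]) > stats::qnorm(1 - alpha / 2))
}
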