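test_that("simulated loop sets are deterministic per seed", {
  a <- simulateLoopSet(loopSimSpec(nLoops = 500, seed = 99))
  b <- simulateLoopSet(loopSimSpec(nLoops = 500, seed = 99))
  expect_equal(observedCounts(a), observedCounts(b))
  expect_equal(loopSpans(a), loopSpans(b))
  expect_identical(as.character(GenomicRanges::seqnames(firstAnchor(a))),
                   as.character(GenomicRanges::seqnames(firstAnchor(b))))
  c <- simulateLoopSet(loopSimSpec(nLoops = 500, seed = 100))
  expect_false(identical(observedCounts(a), observedCounts(c)))
})

test_that("default calibration: median span 300 kb, spans on the bin grid", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 10000, seed = 1))
  sp <- loopSpans(lp)
  expect_lt(abs(median(sp) - 3e5), 3e4)
  expect_true(all(sp %% 1e4 == 0))
  expect_true(all(sp >= 2e4 - 1e4 & sp < 2e6))  # binning may floor minSpan
  # skewed short: mean above median is the long right tail
  expect_gt(mean(sp), median(sp))
})

test_that("every simulated record passes the loop filters", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 3000, seed = 33))
  res <- filterLoops(lp)
  expect_length(res$loops, 3000)
  expect_true(all(res$report$removed_count == 0))
  expect_true(all(observedCounts(lp) > expectedCounts(lp)))
})

test_that("constant looping fraction 0.5 makes observed ~ 2x expected", {
  spec <- loopSimSpec(nLoops = 4000, seed = 3,
                      loopingFractionRange = c(0.5, 0.5), noiseCV = 0)
  lp <- simulateLoopSet(spec)
  expect_equal(observedCounts(lp), 2 * expectedCounts(lp),
               tolerance = 1e-12)
})

test_that("generated sets reproduce their own decay and looping targets", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 8000, seed = 17))
  fit <- suppressWarnings(fitPowerLaw(loopSpans(lp), expectedCounts(lp)))
  expect_lt(abs(fit@exponent - (-1)) / 1, 0.10)
  frac <- loopingFraction(observedCounts(lp), expectedCounts(lp))
  bins <- binSpan(loopSpans(lp), 2e5)
  med <- vapply(split(frac, bins), median, numeric(1))
  expect_true(all(med > 0.4 & med < 0.9))
  # looping fraction rises with span
  expect_gt(med[length(med)], med[1])
})

test_that("replicate counts follow the negative-binomial moments", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 5000, seed = 21))
  # Poisson limit: variance/mean ~ 1 across loops with many replicates
  sim0 <- simulateReplicateCounts(lp, nReps = 20, dispersion = 0,
                                  seed = 5)
  cnt <- SummarizedExperiment::assay(sim0$condition1, "counts")
  ratio <- apply(cnt, 1, var) / pmax(rowMeans(cnt), 1e-9)
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # overdispersed: moment recovery of phi from (var - mean)/mean^2
  sim <- simulateReplicateCounts(lp, nReps = 20, dispersion = 0.04,
                                 seed = 6)
  cm <- SummarizedExperiment::assay(sim$condition1, "counts")
  mns <- rowMeans(cm); vrs <- apply(cm, 1, var)
  phiHat <- sum(vrs - mns) / sum(mns^2)
  expect_lt(abs(phiHat - 0.04) / 0.04, 0.25)
})

test_that("condition fold change enters through compression", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 2000, seed = 8))
  sim <- simulateReplicateCounts(lp, nReps = 50, dispersion = 0.001,
                                 fcLooping = 2, seed = 9)
  m1 <- rowMeans(SummarizedExperiment::assay(sim$condition1, "counts"))
  m2 <- rowMeans(SummarizedExperiment::assay(sim$condition2, "counts"))
  eff <- observedFC(observedCounts(lp), expectedCounts(lp), 2)
  expect_lt(median(abs(m2 / m1 - eff) / eff), 0.05)
  # null change: conditions exchangeable in distribution
  sim0 <- simulateReplicateCounts(lp, nReps = 50, dispersion = 0.001,
                                  fcLooping = 1, seed = 10)
  m1b <- rowMeans(SummarizedExperiment::assay(sim0$condition1, "counts"))
  m2b <- rowMeans(SummarizedExperiment::assay(sim0$condition2, "counts"))
  expect_lt(abs(mean(m2b / m1b) - 1), 0.01)
})

test_that("end-to-end: simulated replicates return the simulating phi", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 4000, seed = 30))
  sim <- simulateReplicateCounts(lp, nReps = 4, dispersion = 0.01,
                                 depthScale = 1, seed = 31)
  est <- estimateCommonDispersion(sim$condition1)
  expect_lt(abs(est - 0.01) / 0.01, 0.25)
})

test_that("simulated rejection rates track the power model end-to-end", {
  lp <- simulateLoopSet(loopSimSpec(nLoops = 400, seed = 41))
  lp <- lp[observedCounts(lp) > 30 & observedCounts(lp) < 400]
  n <- 4; phi <- 0.01; alpha <- 0.05
  o <- observedCounts(lp); e <- expectedCounts(lp)
  pred <- loopPower(lp, fcLooping = 2, dispersion = phi, alpha = alpha,
                    n = n)
  nsim <- 40
  rej <- matrix(0, length(lp), nsim)
  for (s in seq_len(nsim)) {
    sim <- simulateReplicateCounts(lp, nReps = n, dispersion = phi,
                                   fcLooping = 2, seed = 1000 + s)
    y1 <- SummarizedExperiment::assay(sim$condition1, "counts")
    y2 <- SummarizedExperiment::assay(sim$condition2, "counts")
    m1 <- rowMeans(y1); m2 <- rowMeans(y2)
    z <- (log(pmax(m2, 0.5)) - log(pmax(m1, 0.5))) /
      sqrt(2 * (1 / o + phi) / n)
    rej[, s] <- abs(z) > qnorm(1 - alpha / 2)
  }
  empirical <- rowMeans(rej)
  # mean absolute gap across loops within the oracle tolerance
  expect_lt(mean(abs(empirical - pred)), 0.10)
})

test_that("contact files are deterministic, sized, whitespace-delimited", {
  expect_length(simulateContactFile(0, seed = 1), 0)
  lines <- simulateContactFile(100, seed = 2)
  expect_length(lines, 100)
  expect_identical(lines, simulateContactFile(100, seed = 2))
  expect_true(all(lengths(strsplit(lines, " ")) == 8))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "c.txt")
  simulateContactFile(50, seed = 3, path = p)
  expect_identical(readLines(p), simulateContactFile(50, seed = 3))
})
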