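#' Specification for a synthetic loop set
#'
#' Bundles the calibration of \code{\link{simulateLoopSet}}. Defaults mimic
#' the structure of deeply sequenced human lymphoblastoid (GM12878) Hi-C
#' loop calls at 10 kb resolution: about 14.8 thousand loops; a log-normal
#' span distribution with median 300 kb, skewed short, truncated to
#' [20 kb, 2 Mb); background (expected) counts following a power-law decay
#' with distance; and a looping fraction — the share of observed counts
#' attributable to the loop rather than the polymer background — rising
#' log-linearly from about 0.5 at the shortest spans to about 0.8 at the
#' longest.
#'
#' @param nLoops number of loops (default 14849).
#' @param medianSpan median of the span distribution, bp (default 3e5).
#' @param sdLog log-scale SD of the span distribution (default 0.75).
#' @param minSpan,maxSpan truncation bounds in bp; spans are resampled into
#'   [minSpan, maxSpan) (defaults 2e4 and 2e6).
#' @param decay a \linkS4class{DecayModel} for expected counts at the
#'   reference depth (default \code{DecayModel(2e7, -1)}, giving ~57
#'   expected counts at 350 kb at the default reference depth).
#' @param loopingFractionRange fractions at \code{minSpan} and
#'   \code{maxSpan}, interpolated log-linearly in span (default
#'   \code{c(0.5, 0.8)}).
#' @param noiseCV coefficient of variation of the multiplicative log-normal
#'   noise on observed counts (default 0.3, i.e. an interquartile spread of
#'   roughly 1.5-fold at fixed distance). This is pixel-to-pixel
#'   variability of the loop set, distinct from replicate-level dispersion.
#' @param binSize working resolution, bp (default 10000).
#' @param referenceDepth total unique contacts of the emulated map (default
#'   5536073657).
#' @param seed integer RNG seed (required: generated sets are deterministic
#'   per seed).
#' @return a list of class \code{"LoopSimSpec"}.
#' @export
loopSimSpec <- function(nLoops = 14849, medianSpan = 3e5, sdLog = 0.75,
                        minSpan = 2e4, maxSpan = 2e6,
                        decay = DecayModel(2e7, -1),
                        loopingFractionRange = c(0.5, 0.8),
                        noiseCV = 0.3, binSize = 10000,
                        referenceDepth = 5536073657, seed) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  stopifnot(nLoops >= 1, minSpan > 0, maxSpan > minSpan,
            all(loopingFractionRange > 0), all(loopingFractionRange < 1),
            noiseCV >= 0)
  structure(list(nLoops = as.integer(nLoops), medianSpan = medianSpan,
                 sdLog = sdLog, minSpan = minSpan, maxSpan = maxSpan,
                 decay = decay, loopingFractionRange = loopingFractionRange,
                 noiseCV = noiseCV, binSize = binSize,
                 referenceDepth = referenceDepth, seed = as.integer(seed)),
            class = "LoopSimSpec")
}

.loopingFraction <- function(span, spec) {
  fr <- spec$loopingFractionRange
  w <- (log(span) - log(spec$minSpan)) /
    (log(spec$maxSpan) - log(spec$minSpan))
  fr[1] + (fr[2] - fr[1]) * pmin(pmax(w, 0), 1)
}

#' Simulate a calibrated synthetic loop set
#'
#' Draws loop spans from the truncated log-normal of the spec, bins them to
#' the working resolution, places anchors on random autosomes, sets expected
#' counts from the decay model at the span, and sets observed counts to
#' \code{expected / (1 - loopingFraction(span))} times multiplicative
#' log-normal noise. Every record passes \code{\link{filterLoops}} by
#' construction (spans in [20 kb, 2 Mb), autosomal, observed > expected);
#' rare noise draws that would push observed at or below expected are
#' redrawn (bounded retries).
#'
#' @param spec a \code{\link{loopSimSpec}}.
#' @return a \linkS4class{HiCLoops} object with \code{spec$nLoops} records,
#'   identical across calls with the same spec (seed included).
#' @examples
#' lp <- simulateLoopSet(loopSimSpec(nLoops = 1000, seed = 42))
#' median(loopSpans(lp))
#' @export
simulateLoopSet <- function(spec) {
  stopifnot(inherits(spec, "LoopSimSpec"))
  set.seed(spec$seed)
  n <- spec$nLoops
  meanlog <- log(spec$medianSpan)

  spans <- numeric(0)
  while (length(spans) < n) {
    draw <- stats::rlnorm(n, meanlog = meanlog, sdlog = spec$sdLog)
    draw <- draw[draw >= spec$minSpan & draw < spec$maxSpan]
    spans <- c(spans, draw)
  }
  spans <- binSpan(spans[seq_len(n)], spec$binSize)

  expected <- predictCounts(spec$decay, spans)
  frac <- .loopingFraction(spans, spec)
  sdlogNoise <- sqrt(log(1 + spec$noiseCV^2))
  base <- expected / (1 - frac)
  observed <- base * stats::rlnorm(n, meanlog = -sdlogNoise^2 / 2,
                                   sdlog = sdlogNoise)
  for (try_ in 1:100) {
    bad <- observed <= expected
    if (!any(bad)) break
    observed[bad] <- base[bad] *
      stats::rlnorm(sum(bad), meanlog = -sdlogNoise^2 / 2,
                    sdlog = sdlogNoise)
  }
  if (any(observed <= expected)) {
    stop("could not generate observed > expected within retry bound; ",
         "check loopingFractionRange and noiseCV")
  }

  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  start1 <- sample.int(1e4, n, replace = TRUE) * spec$binSize
  a1 <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start1 + 1, start1 + spec$binSize))
  a2 <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start1 + spans + 1, start1 + spans +
                              spec$binSize))
  HiCLoops(a1, a2, observed, expected, spec$referenceDepth)
}

#' Simulate replicate count matrices for two conditions
#'
#' Draws negative-binomial replicate counts around each loop's (depth-scaled)
#' observed counts: condition 1 at mean \code{mu = observed * depthScale},
#' condition 2 at \code{mu * observedFC(o, e, fcLooping)}, i.e. the looping
#' component changes by \code{fcLooping} while the background stays fixed.
#' Variance is \code{mu + dispersion * mu^2}; \code{dispersion = 0}
#' degenerates to Poisson. Library sizes are set to
#' \code{referenceDepth(loops) * depthScale} for every replicate.
#'
#' @param loops a \linkS4class{HiCLoops} object.
#' @param nReps replicates per condition.
#' @param dispersion \eqn{\phi \ge 0}.
#' @param fcLooping fold change of looping counts in condition 2 (default 1:
#'   the two conditions are exchangeable).
#' @param depthScale per-replicate depth as a fraction of the reference
#'   depth (default 1).
#' @param seed integer RNG seed.
#' @return list with \linkS4class{LoopCountMatrix} elements
#'   \code{condition1} and \code{condition2}.
#' @export
simulateReplicateCounts <- function(loops, nReps, dispersion, fcLooping = 1,
                                    depthScale = 1, seed) {
  stopifnot(dispersion >= 0, nReps >= 1, depthScale > 0)
  set.seed(as.integer(seed))
  o <- observedCounts(loops); e <- expectedCounts(loops)
  mu1 <- o * depthScale
  mu2 <- mu1 * observedFC(o, e, fcLooping)
  drawMat <- function(mu) {
    m <- if (dispersion == 0) {
      stats::rpois(length(mu) * nReps, lambda = rep(mu, nReps))
    } else {
      stats::rnbinom(length(mu) * nReps, mu = rep(mu, nReps),
                     size = 1 / dispersion)
    }
    matrix(m, nrow = length(mu), ncol = nReps)
  }
  lib <- rep(referenceDepth(loops) * depthScale, nReps)
  list(condition1 = LoopCountMatrix(drawMat(mu1), libSizes = lib),
       condition2 = LoopCountMatrix(drawMat(mu2), libSizes = lib))
}

#' Simulate a whitespace-delimited contact-record file
#'
#' Writes (or returns) dummy merged-contacts-style lines — strand, chromosome,
#' position, fragment for each read end — for exercising the thinning code.
#' Content is arbitrary but deterministic per seed.
#'
#' @param nRecords number of lines (>= 0).
#' @param seed integer RNG seed.
#' @param path optional output file; when given, lines are written there and
#'   the path returned invisibly.
#' @return character vector of lines, or (with \code{path}) the path.
#' @export
simulateContactFile <- function(nRecords, seed, path = NULL) {
  stopifnot(nRecords >= 0)
  set.seed(as.integer(seed))
  if (nRecords == 0) {
    lines <- character(0)
  } else {
    chr1 <- sample(1:22, nRecords, replace = TRUE)
    chr2 <- sample(1:22, nRecords, replace = TRUE)
    lines <- paste(sample(0:1, nRecords, TRUE), chr1,
                   sample.int(2e8, nRecords, TRUE),
                   sample.int(8e5, nRecords, TRUE),
                   sample(0:1, nRecords, TRUE), chr2,
                   sample.int(2e8, nRecords, TRUE),
                   sample.int(8e5, nRecords, TRUE))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
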