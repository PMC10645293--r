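#' Rescale counts between sequencing depths
#'
#' Bernoulli thinning of a contact map keeps each contact with probability
#' target/reference, so a pixel's counts scale linearly in expectation. This
#' models re-extraction of loop counts at a different depth without touching
#' contact files; the value is the expectation and is deliberately not
#' rounded.
#'
#' @param countAtRef counts at the reference depth. Vectorized.
#' @param referenceDepth depth (unique contacts) the counts come from, > 0.
#' @param targetDepth depth to rescale to, > 0.
#' @return \code{countAtRef * targetDepth / referenceDepth}.
#' @examples
#' scaleCounts(100, 5e9, 2e9)   # 40
#' @export
scaleCounts <- function(countAtRef, referenceDepth, targetDepth) {
  if (any(referenceDepth <= 0) || any(targetDepth <= 0)) {
    stop("depths must be positive")
  }
  countAtRef * targetDepth / referenceDepth
}

#' Percent of well-powered loops for one experimental design
#'
#' For one combination of replicates, per-replicate sequencing depth, and
#' dispersion, computes per-loop power to detect \code{fcLooping} (after
#' fold-change compression) and reports the percentage of loops whose power
#' strictly exceeds \code{threshold}. The per-test alpha is Bonferroni:
#' \code{alphaNominal / length(loops)}.
#'
#' @param loops a pre-filtered \linkS4class{HiCLoops} object.
#' @param fcLooping fold change of looping counts (default 2).
#' @param dispersion \eqn{\phi}, squared CV across replicates.
#' @param nReplicates replicates per condition.
#' @param depthPerReplicate unique contacts per replicate.
#' @param referenceDepth depth of the input counts; defaults to
#'   \code{referenceDepth(loops)}.
#' @param alphaNominal family-wise alpha before Bonferroni (default 0.05).
#' @param threshold power threshold defining "well-powered" (default 0.8;
#'   strict inequality).
#' @return percentage in [0, 100].
#' @seealso \code{\link{sweepPowerGrid}}, \code{\link{powerByDistance}}
#' @export
percentWellPowered <- function(loops, fcLooping = 2, dispersion,
                               nReplicates, depthPerReplicate,
                               referenceDepth = NULL,
                               alphaNominal = 0.05, threshold = 0.8) {
  if (length(loops) == 0) stop("empty loop set")
  if (is.null(referenceDepth)) referenceDepth <- referenceDepth(loops)
  alpha <- bonferroniAlpha(alphaNominal, length(loops))
  pw <- loopPower(loops, fcLooping = fcLooping, dispersion = dispersion,
                  alpha = alpha, n = nReplicates,
                  depthScale = depthPerReplicate / referenceDepth)
  100 * mean(pw > threshold)
}

#' Sweep a depth-by-replicates-by-dispersion design grid
#'
#' Evaluates \code{\link{percentWellPowered}} on every combination of
#' per-replicate sequencing depth, replicate number, and dispersion, the
#' planning sweep for differential-loop experiment design. Defaults follow
#' the canonical grid: per-replicate depths from 50 million to 5 billion
#' contacts, 2-10 replicates, dispersions 0.001, 0.01, and 0.04, a 2-fold
#' change in looping, and a 0.8 power threshold.
#'
#' @param loops a pre-filtered \linkS4class{HiCLoops} object.
#' @param depthsPerReplicate numeric vector of per-replicate depths.
#' @param replicates integer vector of replicates per condition.
#' @param dispersions numeric vector of \eqn{\phi} values.
#' @param fcLooping,threshold,alphaNominal,referenceDepth as in
#'   \code{\link{percentWellPowered}}.
#' @return data.frame with one row per grid cell: \code{depth_per_replicate},
#'   \code{replicates}, \code{dispersion}, \code{total_depth_per_condition}
#'   (their product), \code{percent_well_powered}, \code{n_loops}. The sweep
#'   is deterministic.
#' @examples
#' lp <- simulateLoopSet(loopSimSpec(nLoops = 500, seed = 1))
#' head(sweepPowerGrid(lp, depthsPerReplicate = c(5e8, 2e9),
#'                     replicates = 2, dispersions = 0.001))
#' @export
sweepPowerGrid <- function(loops,
                           depthsPerReplicate = c(5e7, 1e8, 2.5e8, 5e8,
                                                  7.5e8, 1e9, 2e9, 3e9,
                                                  4e9, 5e9),
                           replicates = 2:10,
                           dispersions = c(0.001, 0.01, 0.04),
                           fcLooping = 2, threshold = 0.8,
                           alphaNominal = 0.05, referenceDepth = NULL) {
  if (length(loops) == 0) stop("empty loop set")
  if (any(depthsPerReplicate <= 0)) stop("depths must be positive")
  if (any(replicates < 2)) stop("need at least 2 replicates per condition")
  grid <- expand.grid(depth_per_replicate = depthsPerReplicate,
                      replicates = replicates,
                      dispersion = dispersions,
                      KEEP.OUT.ATTRS = FALSE)
  grid$total_depth_per_condition <-
    grid$depth_per_replicate * grid$replicates
  grid$percent_well_powered <- mapply(function(d, n, phi) {
    percentWellPowered(loops, fcLooping = fcLooping, dispersion = phi,
                       nReplicates = n, depthPerReplicate = d,
                       referenceDepth = referenceDepth,
                       alphaNominal = alphaNominal, threshold = threshold)
  }, grid$depth_per_replicate, grid$replicates, grid$dispersion)
  grid$n_loops <- length(loops)
  grid
}

#' Well-powered loops per genomic-distance bin
#'
#' Splits loops into distance bins at the working resolution and reports the
#' percentage and number of well-powered loops per bin for one experimental
#' design, showing how detection power falls with loop size.
#'
#' @inheritParams percentWellPowered
#' @param binSize bin width in bp (default 10000).
#' @return data.frame with one row per non-empty bin, ordered by distance:
#'   \code{bin_start}, \code{percent_well_powered}, \code{n_well_powered},
#'   \code{n_loops}.
#' @export
powerByDistance <- function(loops, fcLooping = 2, dispersion,
                            nReplicates, depthPerReplicate,
                            referenceDepth = NULL, alphaNominal = 0.05,
                            binSize = 10000, threshold = 0.8) {
  if (length(loops) == 0) stop("empty loop set")
  if (is.null(referenceDepth)) referenceDepth <- referenceDepth(loops)
  alpha <- bonferroniAlpha(alphaNominal, length(loops))
  pw <- loopPower(loops, fcLooping = fcLooping, dispersion = dispersion,
                  alpha = alpha, n = nReplicates,
                  depthScale = depthPerReplicate / referenceDepth)
  bins <- binSpan(loopSpans(loops), binSize)
  well <- pw > threshold
  byBin <- split(well, bins)
  res <- data.frame(
    bin_start = as.numeric(names(byBin)),
    percent_well_powered = 100 * vapply(byBin, mean, numeric(1)),
    n_well_powered = vapply(byBin, sum, numeric(1)),
    n_loops = lengths(byBin)
  )
  rownames(res) <- NULL
  res[order(res$bin_start), , drop = FALSE]
}
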