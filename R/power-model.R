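#' Bonferroni-corrected per-test alpha
#'
#' @param nominal family-wise significance level (default 0.05).
#' @param nTests number of tests, e.g. the number of loops evaluated at a
#'   given sequencing depth.
#' @return \code{nominal / nTests}.
#' @examples
#' bonferroniAlpha(0.05, 14849)
#' @export
bonferroniAlpha <- function(nominal = 0.05, nTests) {
  if (nominal <= 0 || nominal >= 1) stop("nominal alpha must be in (0, 1)")
  if (any(nTests < 1)) stop("nTests must be at least 1")
  nominal / nTests
}

#' Closed-form power for a two-group comparison of overdispersed counts
#'
#' Normal-approximation power of a two-sided test comparing mean counts
#' between two conditions with \code{n} replicates each, under the negative
#' binomial variance model \eqn{var = \mu + \phi \mu^2} (so \eqn{\phi} is the
#' squared biological coefficient of variation). The form is the standard
#' sample-size identity for sequencing counts,
#' \deqn{n = (z_{1-\alpha/2} + z_{\beta})^2 \;
#'       \frac{2\,(1/\mu + \phi)}{(\ln \Delta)^2},}
#' solved for power:
#' \deqn{power = \Phi\!\left(\sqrt{\frac{n (\ln \Delta)^2}
#'       {2 (1/\mu + \phi)}} - z_{1-\alpha/2}\right),}
#' clipped to [0, 1]. The factor 2 reflects the two groups; \eqn{1/\mu} is
#' the Poisson (counting) part of the squared CV and \eqn{\phi} the
#' overdispersion part. This matches the conventions of the RNA-seq power
#' function the framework is parameterized after (its \code{cv} argument is
#' \eqn{\sqrt{\phi}}), verified against Monte-Carlo negative-binomial
#' rejection rates in the test suite.
#'
#' The test is two-sided, so the direction of the effect does not matter
#' (\eqn{|\ln \Delta|} is used) and a null effect \eqn{\Delta = 1} returns
#' exactly \eqn{\alpha/2}, the probability mass of one rejection tail.
#'
#' @param mu mean counts per replicate at the feature (> 0). Vectorized.
#' @param dispersion \eqn{\phi \ge 0}, squared CV across replicates.
#' @param effect fold change \eqn{\Delta > 0} on the observed-count scale.
#' @param alpha two-sided per-test significance level in (0, 1).
#' @param n replicates per condition (>= 1).
#' @return power in \eqn{[\alpha/2, 1)}, same length as the longest
#'   argument.
#' @seealso \code{\link{loopPower}}, \code{\link{solveMinCounts}}
#' @examples
#' powerTwoGroup(mu = 50, dispersion = 0.001, effect = 2, alpha = 0.05, n = 2)
#' @export
powerTwoGroup <- function(mu, dispersion, effect, alpha, n) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  if (any(effect <= 0)) stop("effect must be positive")
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must be in (0, 1)")
  if (any(n < 1)) stop("n must be at least 1")
  # upper-tail form keeps full precision at Bonferroni-scale alphas
  z <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  arg <- sqrt(n * log(effect)^2 / (2 * (1 / mu + dispersion))) - z
  pmin(pmax(stats::pnorm(arg), 0), 1)
}

#' Per-loop power at a given looping fold change
#'
#' Composes the fold-change compression model with the two-group power
#' formula: the effect size entering the test is the observed-count fold
#' change \code{observedFC(o, e, fcLooping)}, and the per-replicate mean is
#' the loop's observed counts rescaled by \code{depthScale} (the ratio of
#' the evaluated per-replicate depth to the reference depth of the counts).
#'
#' @param loops a \linkS4class{HiCLoops} object (pre-filtered: o > e).
#' @param fcLooping fold change of looping counts to detect.
#' @param dispersion \eqn{\phi}, squared CV across replicates.
#' @param alpha per-test two-sided significance level (already
#'   multiplicity-corrected; see \code{\link{bonferroniAlpha}}).
#' @param n replicates per condition.
#' @param depthScale per-replicate depth as a fraction of
#'   \code{referenceDepth(loops)} (default 1).
#' @return numeric vector of per-loop power.
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6 + 1, 1.01e6))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1.35e6 + 1, 1.36e6))
#' lp <- HiCLoops(a1, a2, observed = 159, expected = 36)
#' loopPower(lp, fcLooping = 2, dispersion = 0.001, alpha = 0.05, n = 2)
#' @export
loopPower <- function(loops, fcLooping, dispersion, alpha, n,
                      depthScale = 1) {
  if (depthScale <= 0) stop("depthScale must be positive")
  o <- observedCounts(loops); e <- expectedCounts(loops)
  eff <- observedFC(o, e, fcLooping)
  powerTwoGroup(mu = o * depthScale, dispersion = dispersion, effect = eff,
                alpha = alpha, n = n)
}

#' Smallest mean counts reaching a target power
#'
#' Inverts \code{\link{powerTwoGroup}} in \code{mu} by bisection: the
#' smallest per-replicate mean count at which the power reaches
#' \code{targetPower}. Because power saturates at
#' \eqn{\Phi(\sqrt{n (\ln \Delta)^2 / (2\phi)} - z_{1-\alpha/2})} as
#' \eqn{\mu \to \infty}, targets above that ceiling are unreachable at any
#' depth and \code{Inf} is returned.
#'
#' @param dispersion \eqn{\phi \ge 0}.
#' @param effect fold change \eqn{\Delta \ne 1}.
#' @param alpha per-test two-sided significance level.
#' @param n replicates per condition.
#' @param targetPower target in \eqn{(\alpha/2, 1)}.
#' @param tol relative bisection tolerance (default 1e-6).
#' @return the minimal \code{mu} (counts), or \code{Inf} when unreachable.
#' @examples
#' mu <- solveMinCounts(0.001, 2, 0.05, 2, 0.8)
#' powerTwoGroup(mu, 0.001, 2, 0.05, 2)   # ~0.8
#' @export
solveMinCounts <- function(dispersion, effect, alpha, n, targetPower,
                           tol = 1e-6) {
  if (effect == 1) stop("effect = 1: no mean count can reach the target")
  if (targetPower <= alpha / 2 || targetPower >= 1) {
    stop("targetPower must be in (alpha/2, 1)")
  }
  z <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  ceiling_ <- if (dispersion > 0) {
    stats::pnorm(sqrt(n * log(effect)^2 / (2 * dispersion)) - z)
  } else 1
  if (ceiling_ < targetPower) return(Inf)
  lo <- 1e-9; hi <- 1
  while (powerTwoGroup(hi, dispersion, effect, alpha, n) < targetPower) {
    hi <- hi * 10
    if (hi > 1e18) return(Inf)
  }
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (powerTwoGroup(mid, dispersion, effect, alpha, n) >= targetPower) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}
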