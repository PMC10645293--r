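#' Fold-change compression between looping and observed counts
#'
#' The counts observed at a loop pixel are the sum of a distance-dependent
#' polymer background (the expected counts \eqn{e}) and the counts due to
#' looping interactions (\eqn{o - e}). When looping changes by a factor
#' \eqn{FC_{looping}} the background stays put, so the fold change seen on
#' observed counts is compressed:
#' \deqn{FC_{observed} = \frac{(o - e)\,FC_{looping} + e}{o}.}
#' \code{observedFC} evaluates this; \code{invertObservedFC} solves it for
#' \eqn{FC_{looping}}; \code{loopingCounts} and \code{loopingFraction} return
#' \eqn{o - e} and \eqn{(o - e)/o}.
#'
#' All four are vectorized over loops. \eqn{FC_{looping} < 1} (loop loss) is
#' permitted: the same formula applies, and the observed fold change is then
#' bounded below by \eqn{e/o}, the point where the looping component
#' vanishes.
#'
#' @param o observed counts, > 0.
#' @param e expected counts, with 0 <= e <= o (e < o where an inverse is
#'   required).
#' @param fcLooping fold change of looping counts, > 0.
#' @param fcObserved fold change of observed counts, > e/o.
#' @return \code{observedFC} and \code{invertObservedFC} return fold changes;
#'   \code{loopingCounts} counts; \code{loopingFraction} a fraction in
#'   [0, 1].
#' @examples
#' observedFC(159, 36, 2)        # 1.7736...: a doubling of looping
#' loopingCounts(159, 36)        # 123
#' loopingFraction(159, 36)      # 0.7736..., i.e. 77% of observed counts
#' invertObservedFC(159, 36, observedFC(159, 36, 2))   # 2
#' @name fc-compression
NULL

#' @rdname fc-compression
#' @export
observedFC <- function(o, e, fcLooping) {
  if (any(o <= 0)) stop("observed counts must be positive")
  if (any(e < 0) || any(e > o)) {
    stop("expected counts must satisfy 0 <= e <= o (filter loops first)")
  }
  if (any(fcLooping <= 0)) stop("fcLooping must be positive")
  ((o - e) * fcLooping + e) / o
}

#' @rdname fc-compression
#' @export
loopingCounts <- function(o, e) {
  if (any(e > o)) stop("expected counts exceed observed (unfiltered input)")
  o - e
}

#' @rdname fc-compression
#' @export
loopingFraction <- function(o, e) {
  if (any(o <= 0)) stop("observed counts must be positive")
  if (any(e < 0) || any(e > o)) {
    stop("expected counts must satisfy 0 <= e <= o")
  }
  (o - e) / o
}

#' @rdname fc-compression
#' @export
invertObservedFC <- function(o, e, fcObserved) {
  if (any(o <= 0)) stop("observed counts must be positive")
  if (any(e < 0)) stop("expected counts must be non-negative")
  if (any(o == e)) {
    stop("no looping signal (o == e): inverse fold change undefined")
  }
  if (any(e > o)) stop("expected counts exceed observed (unfiltered input)")
  if (any(fcObserved <= e / o)) {
    stop("fcObserved at or below e/o has no positive looping fold change")
  }
  (fcObserved * o - e) / (o - e)
}
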