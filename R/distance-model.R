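#' Quantile profile of loop counts by genomic distance
#'
#' Bins loops at the working resolution and summarizes the chosen count field
#' per bin with its median, quartiles, and deciles, the summary used to
#' visualize distance decay. Quantiles use linear interpolation between order
#' statistics (\code{stats::quantile} type 7).
#'
#' @param loops a \linkS4class{HiCLoops} object.
#' @param binSize bin width in bp (default 10000).
#' @param field \code{"observed"} or \code{"expected"}.
#' @return A data.frame with columns \code{bin} (bin start, bp), \code{q10},
#'   \code{q25}, \code{median}, \code{q75}, \code{q90}, and \code{n}, one row
#'   per non-empty bin, bins strictly increasing. Empty input gives a
#'   zero-row frame.
#' @seealso \code{\link{fitPowerLaw}}
#' @export
profileByDistance <- function(loops, binSize = 10000,
                              field = c("observed", "expected")) {
  field <- match.arg(field)
  vals <- if (field == "observed") observedCounts(loops) else
    expectedCounts(loops)
  empty <- data.frame(bin = numeric(0), q10 = numeric(0), q25 = numeric(0),
                      median = numeric(0), q75 = numeric(0),
                      q90 = numeric(0), n = integer(0))
  if (length(loops) == 0) return(empty)
  bins <- binSpan(loopSpans(loops), binSize)
  out <- lapply(split(vals, bins), function(v) {
    q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
    data.frame(q10 = q[1], q25 = q[2], median = q[3], q75 = q[4], q90 = q[5],
               n = length(v))
  })
  res <- do.call(rbind, out)
  res <- cbind(bin = as.numeric(names(out)), res)
  rownames(res) <- NULL
  res[order(res$bin), , drop = FALSE]
}

#' Fit a power-law decay model to counts versus distance
#'
#' Fits \eqn{count = a \cdot d^{b}} by ordinary least squares in log-log
#' space: \eqn{\log(count) = \log a + b \log d}. The log-OLS fit is
#' closed-form and deterministic, which suits its smoothing role; set
#' \code{refine = TRUE} to follow it with a nonlinear least-squares
#' refinement on the original scale (initialized at the log-OLS solution).
#'
#' @param distances genomic distances in bp, all > 0.
#' @param counts counts, all > 0, same length.
#' @param refine run an \code{nls} refinement on the natural scale.
#' @return A \linkS4class{DecayModel} with the log-space R-squared in
#'   \code{r2Log}.
#' @examples
#' d <- 10^seq(4, 6, length.out = 20)
#' fitPowerLaw(d, 1000 * d^-1)
#' @export
fitPowerLaw <- function(distances, counts, refine = FALSE) {
  if (length(distances) != length(counts)) {
    stop("distances and counts must have the same length")
  }
  if (length(distances) < 3) stop("need at least 3 points to fit")
  if (any(distances <= 0)) stop("distances must be positive")
  if (any(counts <= 0)) stop("counts must be positive")
  if (length(unique(distances)) < 2) {
    stop("degenerate fit: all distances equal")
  }
  ld <- log(distances); lc <- log(counts)
  fit <- stats::lm(lc ~ ld)
  b <- unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  r2 <- summary(fit)$r.squared
  if (refine) {
    nl <- try(stats::nls(counts ~ a * distances^b,
                         start = list(a = a, b = b),
                         control = stats::nls.control(warnOnly = TRUE)),
              silent = TRUE)
    if (!inherits(nl, "try-error")) {
      cf <- stats::coef(nl)
      a <- unname(cf["a"]); b <- unname(cf["b"])
    }
  }
  DecayModel(coefficient = a, exponent = b, r2Log = r2)
}

#' Predict counts from a decay model
#'
#' @param model a \linkS4class{DecayModel}.
#' @param distance genomic distance(s) in bp, all > 0.
#' @return \code{coefficient * distance^exponent}, always positive.
#' @examples
#' predictCounts(DecayModel(1000, -1), 1e5)   # 10
#' @rdname predictCounts
#' @export
setMethod("predictCounts", "DecayModel", function(model, distance) {
  if (any(distance <= 0)) stop("distance must be positive")
  model@coefficient * distance^model@exponent
})

setMethod("show", "DecayModel", function(object) {
  cat("DecayModel: count =", signif(object@coefficient, 6), "* d^",
      signif(object@exponent, 6), "\n")
  if (!is.na(object@r2Log)) {
    cat("  log-space R-squared:", signif(object@r2Log, 4), "\n")
  }
  invisible(NULL)
})
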