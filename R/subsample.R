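#' Keep probability for thinning to a target depth
#'
#' The exact fraction of contact records to retain so that a map of
#' \code{parentDepth} unique contacts is thinned, in expectation, to
#' \code{targetDepth}.
#'
#' @param targetDepth desired number of unique contacts (0 <= target <=
#'   parent).
#' @param parentDepth unique contacts in the source map (> 0).
#' @return \code{targetDepth / parentDepth}.
#' @examples
#' keepProbability(2e9, 5536073657)
#' @export
keepProbability <- function(targetDepth, parentDepth) {
  if (parentDepth <= 0) stop("parentDepth must be positive")
  if (targetDepth < 0) stop("targetDepth must be non-negative")
  if (targetDepth > parentDepth) {
    stop("cannot upsample: targetDepth exceeds parentDepth")
  }
  targetDepth / parentDepth
}

#' Bernoulli-thin a contact-record text stream
#'
#' Streams a whitespace-delimited contact file (Juicer merged-contacts style,
#' but any line-oriented text works: lines are opaque) and keeps each line
#' independently with probability \code{keepProb}. Kept lines preserve order
#' and content byte-for-byte. Memory use is bounded by \code{chunkSize}
#' lines, not file size. The draw sequence is fixed by \code{seed}, so the
#' same seed and input reproduce the same kept set exactly.
#'
#' Because each line is an independent Bernoulli trial, the realized kept
#' count is Binomial(N, p): thinning to very deep targets lands within a
#' relative deviation of about \eqn{5\sqrt{(1-p)/(Np)}} of the whole-number
#' target (about 0.01\% or less once \eqn{Np \ge 10^9}). The realized count
#' is returned so callers can record it.
#'
#' @param inPath input text file.
#' @param outPath output file for the kept lines; \code{NULL} to count
#'   without writing.
#' @param keepProb per-line keep probability in [0, 1].
#' @param seed integer RNG seed.
#' @param chunkSize lines per read chunk (default 1e5).
#' @return A list: \code{keptCount}, \code{totalCount}, \code{keepProb},
#'   \code{seed}.
#' @seealso \code{\link{keepProbability}}, \code{\link{bernoulliKeptCount}}
#' @export
thinContacts <- function(inPath, outPath = NULL, keepProb, seed,
                         chunkSize = 1e5) {
  if (keepProb < 0 || keepProb > 1) stop("keepProb must be in [0, 1]")
  if (!file.exists(inPath)) stop("file not found: ", inPath)
  set.seed(as.integer(seed))
  con <- file(inPath, open = "r")
  on.exit(close(con), add = TRUE)
  out <- NULL
  if (!is.null(outPath)) {
    out <- file(outPath, open = "w")
    on.exit(close(out), add = TRUE)
  }
  kept <- 0; total <- 0
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (!length(lines)) break
    total <- total + length(lines)
    take <- stats::runif(length(lines)) < keepProb
    k <- lines[take]
    kept <- kept + length(k)
    if (!is.null(out) && length(k)) writeLines(k, out)
  }
  list(keptCount = kept, totalCount = total, keepProb = keepProb,
       seed = as.integer(seed))
}

#' Realized kept count of a large Bernoulli thinning run
#'
#' Simulates the per-record keep/drop decisions of \code{\link{thinContacts}}
#' for \code{nRecords} records without materializing any lines, in chunks, so
#' billions of records are feasible. Useful for verifying the realized-depth
#' accuracy of thinning at depths where writing a fixture file would be
#' impractical.
#'
#' @param nRecords number of records (non-negative; may exceed 2^31).
#' @param keepProb per-record keep probability in [0, 1].
#' @param seed integer RNG seed.
#' @param chunkSize records per chunk (default 1e7).
#' @return A list: \code{keptCount}, \code{target} (\code{nRecords *
#'   keepProb}), and \code{relDeviation} (\code{|kept - target| / target},
#'   \code{NA} when the target is 0).
#' @export
bernoulliKeptCount <- function(nRecords, keepProb, seed, chunkSize = 1e7) {
  if (keepProb < 0 || keepProb > 1) stop("keepProb must be in [0, 1]")
  if (nRecords < 0) stop("nRecords must be non-negative")
  set.seed(as.integer(seed))
  kept <- 0
  remaining <- nRecords
  while (remaining > 0) {
    m <- min(remaining, chunkSize)
    kept <- kept + sum(stats::runif(m) < keepProb)
    remaining <- remaining - m
  }
  target <- nRecords * keepProb
  list(keptCount = kept, target = target,
       relDeviation = if (target > 0) abs(kept - target) / target else
         NA_real_)
}
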