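#' @import methods
#' @importFrom GenomicRanges GRanges start end seqnames width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
NULL

#' HiCLoops: a set of chromatin-loop pixels with observed and expected counts
#'
#' Container for loop calls at a fixed bin resolution. Each loop is a pair of
#' genomic anchors together with the Hi-C contact counts observed at the loop
#' pixel and the counts expected from the distance-dependent polymer
#' background alone. Counts refer to a contact map of total depth
#' \code{referenceDepth} unique contacts; power calculations rescale them
#' linearly to other depths.
#'
#' Anchors are stored as \linkS4class{GRanges} (1-based, closed intervals, the
#' Bioconductor convention); the BEDPE reader converts from 0-based half-open
#' coordinates on the way in and back on the way out.
#'
#' @slot anchor1 \code{GRanges} of upstream anchors.
#' @slot anchor2 \code{GRanges} of downstream anchors (same length).
#' @slot observed numeric vector of observed counts per loop pixel.
#' @slot expected numeric vector of background-expected counts per loop pixel.
#' @slot referenceDepth single numeric, total unique contacts of the source
#'   contact map the counts were extracted from.
#'
#' @seealso \code{\link{HiCLoops}} (constructor), \code{\link{readLoops}},
#'   \code{\link{filterLoops}}, \code{\link{loopPower}}
#' @name HiCLoops-class
#' @rdname HiCLoops-class
#' @exportClass HiCLoops
setClass("HiCLoops",
  slots = c(
    anchor1 = "GRanges",
    anchor2 = "GRanges",
    observed = "numeric",
    expected = "numeric",
    referenceDepth = "numeric"
  )
)

setValidity("HiCLoops", function(object) {
  n <- length(object@anchor1)
  msgs <- character()
  if (length(object@anchor2) != n) {
    msgs <- c(msgs, "anchor1 and anchor2 must have the same length")
  }
  if (length(object@observed) != n || length(object@expected) != n) {
    msgs <- c(msgs, "observed and expected must have one value per loop")
  }
  if (any(!is.finite(object@observed)) || any(object@observed < 0)) {
    msgs <- c(msgs, "observed counts must be finite and non-negative")
  }
  if (any(!is.finite(object@expected)) || any(object@expected < 0)) {
    msgs <- c(msgs, "expected counts must be finite and non-negative")
  }
  if (length(object@referenceDepth) != 1 || !is.finite(object@referenceDepth) ||
      object@referenceDepth <= 0) {
    msgs <- c(msgs, "referenceDepth must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HiCLoops object
#'
#' @param anchor1,anchor2 \code{GRanges} of equal length, the two loop
#'   anchors. \code{anchor1} is conventionally the upstream anchor;
#'   intra-chromosomal pairs are reordered by the reader, not here.
#' @param observed,expected numeric vectors of per-pixel counts.
#' @param referenceDepth total unique contacts of the source map
#'   (default \code{5536073657}, the depth of the deeply sequenced GM12878
#'   map the default calibration mimics).
#'
#' @return A \linkS4class{HiCLoops} object.
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000001, 1010000))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1350001, 1360000))
#' HiCLoops(a1, a2, observed = 159, expected = 36)
#' @export
HiCLoops <- function(anchor1, anchor2, observed, expected,
                     referenceDepth = 5536073657) {
  new("HiCLoops",
      anchor1 = anchor1, anchor2 = anchor2,
      observed = as.numeric(observed), expected = as.numeric(expected),
      referenceDepth = as.numeric(referenceDepth))
}

#' DecayModel: power-law fit of counts versus genomic distance
#'
#' Represents the distance decay of Hi-C contact counts as
#' \eqn{count = a \cdot d^{b}} with coefficient \eqn{a > 0} and exponent
#' \eqn{b} (typically negative for polymer decay).
#'
#' @slot coefficient positive numeric, the scale \eqn{a} in counts.
#' @slot exponent numeric, the exponent \eqn{b} (dimensionless).
#' @slot r2Log numeric, coefficient of determination of the fit in log-log
#'   space (\code{NA} for models constructed directly).
#'
#' @seealso \code{\link{fitPowerLaw}}, \code{\link{predictCounts}}
#' @name DecayModel-class
#' @rdname DecayModel-class
#' @exportClass DecayModel
setClass("DecayModel",
  slots = c(coefficient = "numeric", exponent = "numeric", r2Log = "numeric"),
  prototype = prototype(r2Log = NA_real_)
)

setValidity("DecayModel", function(object) {
  msgs <- character()
  if (length(object@coefficient) != 1 || !is.finite(object@coefficient) ||
      object@coefficient <= 0) {
    msgs <- c(msgs, "coefficient must be a single positive number")
  }
  if (length(object@exponent) != 1 || !is.finite(object@exponent)) {
    msgs <- c(msgs, "exponent must be a single finite number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DecayModel
#'
#' @param coefficient positive scale \eqn{a} (counts).
#' @param exponent exponent \eqn{b}.
#' @param r2Log optional log-space R-squared diagnostic.
#' @return A \linkS4class{DecayModel}.
#' @examples
#' DecayModel(coefficient = 2e7, exponent = -1)
#' @export
DecayModel <- function(coefficient, exponent, r2Log = NA_real_) {
  new("DecayModel", coefficient = as.numeric(coefficient),
      exponent = as.numeric(exponent), r2Log = as.numeric(r2Log))
}

#' LoopCountMatrix: loops-by-replicates raw counts for dispersion estimation
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay
#' \code{"counts"} (loops in rows, replicates in columns) and a
#' \code{libSize} column in \code{colData} giving each replicate's total
#' unique contacts. Used by \code{\link{estimateCommonDispersion}}.
#'
#' @seealso \code{\link{LoopCountMatrix}} (constructor)
#' @name LoopCountMatrix-class
#' @rdname LoopCountMatrix-class
#' @exportClass LoopCountMatrix
setClass("LoopCountMatrix", contains = "SummarizedExperiment")

setValidity("LoopCountMatrix", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'counts' is required")
  }
  if (!"libSize" %in% colnames(SummarizedExperiment::colData(object))) {
    msgs <- c(msgs, "colData column 'libSize' is required")
  } else {
    ls <- object$libSize
    if (any(!is.finite(ls)) || any(ls <= 0)) {
      msgs <- c(msgs, "libSize values must be finite and positive")
    }
  }
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0)) {
      msgs <- c(msgs, "counts must be finite and non-negative")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a LoopCountMatrix
#'
#' @param counts numeric matrix, loops in rows and replicates in columns.
#' @param libSizes per-replicate library sizes (total unique contacts).
#'   Defaults to the column sums of \code{counts}.
#' @return A \linkS4class{LoopCountMatrix}.
#' @examples
#' m <- matrix(rpois(40, 20), ncol = 4)
#' LoopCountMatrix(m)
#' @export
LoopCountMatrix <- function(counts, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(libSizes) != ncol(counts)) {
    stop("need one library size per replicate column")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(libSize = as.numeric(libSizes))
  )
  new("LoopCountMatrix", se)
}
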