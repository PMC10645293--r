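#' @rdname HiCLoops-accessors
#' @export
setGeneric("firstAnchor", function(x) standardGeneric("firstAnchor"))

#' @rdname HiCLoops-accessors
#' @export
setGeneric("secondAnchor", function(x) standardGeneric("secondAnchor"))

#' @rdname HiCLoops-accessors
#' @export
setGeneric("observedCounts", function(x) standardGeneric("observedCounts"))

#' @rdname HiCLoops-accessors
#' @export
setGeneric("expectedCounts", function(x) standardGeneric("expectedCounts"))

#' @rdname HiCLoops-accessors
#' @export
setGeneric("referenceDepth", function(x) standardGeneric("referenceDepth"))

#' @rdname loopSpans
#' @export
setGeneric("loopSpans", function(x) standardGeneric("loopSpans"))

#' @rdname predictCounts
#' @export
setGeneric("predictCounts", function(model, distance) {
  standardGeneric("predictCounts")
})
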