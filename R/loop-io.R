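#' Accessors for HiCLoops
#'
#' @param x a \linkS4class{HiCLoops} object.
#' @return \code{firstAnchor}/\code{secondAnchor} return \code{GRanges};
#'   \code{observedCounts}/\code{expectedCounts} numeric vectors;
#'   \code{referenceDepth} a single numeric.
#' @name HiCLoops-accessors
NULL

#' @rdname HiCLoops-accessors
#' @export
setMethod("firstAnchor", "HiCLoops", function(x) x@anchor1)

#' @rdname HiCLoops-accessors
#' @export
setMethod("secondAnchor", "HiCLoops", function(x) x@anchor2)

#' @rdname HiCLoops-accessors
#' @export
setMethod("observedCounts", "HiCLoops", function(x) x@observed)

#' @rdname HiCLoops-accessors
#' @export
setMethod("expectedCounts", "HiCLoops", function(x) x@expected)

#' @rdname HiCLoops-accessors
#' @export
setMethod("referenceDepth", "HiCLoops", function(x) x@referenceDepth)

#' @export
setMethod("length", "HiCLoops", function(x) length(x@anchor1))

#' @export
setMethod("[", "HiCLoops", function(x, i, j, ..., drop = TRUE) {
  new("HiCLoops",
      anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
      observed = x@observed[i], expected = x@expected[i],
      referenceDepth = x@referenceDepth)
})

setMethod("show", "HiCLoops", function(object) {
  n <- length(object)
  cat("HiCLoops with", n, "loops\n")
  cat("  referenceDepth:", format(object@referenceDepth, big.mark = ","),
      "contacts\n")
  if (n > 0) {
    sp <- loopSpans(object)
    cat("  span: median", format(stats::median(sp), big.mark = ","),
        "bp, range", format(min(sp), big.mark = ","), "-",
        format(max(sp), big.mark = ","), "bp\n")
    cat("  observed counts: median", signif(stats::median(object@observed), 4),
        " expected: median", signif(stats::median(object@expected), 4), "\n")
  }
  invisible(NULL)
})

#' Genomic span of each loop
#'
#' Distance between the two anchors, defined start-to-start on the upstream
#' (anchor1) and downstream (anchor2) anchor in 0-based coordinates. For
#' anchors binned at the working resolution this makes the span an exact
#' multiple of the bin size.
#'
#' @param x a \linkS4class{HiCLoops} object.
#' @return integer-valued numeric vector of spans in bp.
#' @details Inter-chromosomal pairs have no genomic distance; they raise an
#'   error.
#' @examples
#' lp <- simulateLoopSet(loopSimSpec(nLoops = 5, seed = 1))
#' loopSpans(lp)
#' @rdname loopSpans
#' @export
setMethod("loopSpans", "HiCLoops", function(x) {
  if (length(x) == 0) return(numeric(0))
  c1 <- as.character(GenomicRanges::seqnames(x@anchor1))
  c2 <- as.character(GenomicRanges::seqnames(x@anchor2))
  if (any(c1 != c2)) {
    stop("span is undefined for inter-chromosomal loops")
  }
  abs(GenomicRanges::start(x@anchor2) - GenomicRanges::start(x@anchor1))
})

#' Bin a genomic distance to the working resolution
#'
#' Floors a span to the nearest multiple of \code{binSize} below it, the
#' convention used for per-distance summaries at 10 kb resolution.
#'
#' @param span numeric vector of distances in bp, all \code{>= 0}.
#' @param binSize bin width in bp (default 10000).
#' @return numeric vector, \code{floor(span / binSize) * binSize}.
#' @examples
#' binSpan(347500)            # 340000
#' binSpan(c(0, 10000))       # 0, 10000
#' @export
binSpan <- function(span, binSize = 10000) {
  if (length(binSize) != 1 || !is.finite(binSize) || binSize <= 0) {
    stop("binSize must be a single positive number")
  }
  if (any(span < 0)) stop("span must be non-negative")
  floor(span / binSize) * binSize
}

.normalizeChrom <- function(chrom) {
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Read loops from a BEDPE file with count columns
#'
#' Parses a tab- (or whitespace-) separated BEDPE dialect: the six standard
#' coordinate columns \code{chrom1 start1 end1 chrom2 start2 end2} followed by
#' further columns, two of which carry the observed and expected counts.
#' Coordinates are 0-based half-open on disk and converted to the 1-based
#' closed \code{GRanges} convention in memory. Lines starting with \code{#}
#' are treated as headers and skipped; if the last header line has one field
#' per column it is used to resolve column names.
#'
#' @param path path to the BEDPE file.
#' @param observedCol,expectedCol names (when a header is present) or 1-based
#'   indices of the observed- and expected-count columns. Defaults
#'   \code{"observed"} and \code{"expected"}.
#' @param referenceDepth total unique contacts of the source map recorded on
#'   the returned object.
#' @return A \linkS4class{HiCLoops} object, one record per data row, in file
#'   order. Anchors are sorted so anchor1 is upstream for intra-chromosomal
#'   pairs.
#' @details Malformed rows (wrong field count, non-numeric coordinates or
#'   counts) raise an error naming the offending line number; negative counts
#'   raise a validation error.
#' @seealso \code{\link{writeLoops}}, \code{\link{filterLoops}}
#' @export
readLoops <- function(path, observedCol = "observed",
                      expectedCol = "expected",
                      referenceDepth = 5536073657) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  isHeader <- grepl("^#", lines)
  dataIdx <- which(!isHeader & nzchar(trimws(lines)))
  headerNames <- NULL
  hdr <- which(isHeader)
  if (length(hdr)) {
    fields <- strsplit(sub("^#\\s*", "", lines[hdr[length(hdr)]]), "\\s+")[[1]]
    if (length(fields) >= 8) headerNames <- fields
  }
  if (!length(dataIdx)) {
    return(HiCLoops(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                    numeric(0), numeric(0), referenceDepth))
  }
  rows <- strsplit(lines[dataIdx], "\\s+")
  nf <- lengths(rows)
  if (length(unique(nf)) != 1) {
    bad <- dataIdx[which(nf != nf[1])[1]]
    stop("malformed row at line ", bad, ": inconsistent column count")
  }
  if (nf[1] < 8) {
    stop("malformed row at line ", dataIdx[1],
         ": need 6 BEDPE columns plus observed and expected counts")
  }
  mat <- do.call(rbind, rows)
  cols <- if (!is.null(headerNames) && length(headerNames) == ncol(mat)) {
    headerNames
  } else {
    c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
      paste0("V", seq_len(ncol(mat) - 6) + 6))
  }
  colnames(mat) <- cols
  resolveCol <- function(spec, fallback) {
    if (is.numeric(spec)) return(as.integer(spec))
    i <- match(spec, cols)
    if (!is.na(i)) return(i)
    if (!is.na(fallback)) return(fallback)
    stop("count column '", spec, "' not found and no header to resolve it")
  }
  # without a header, fall back to BEDPE cols 7 and 8 for observed/expected
  oIdx <- resolveCol(observedCol, if (is.null(headerNames)) 7L else NA)
  eIdx <- resolveCol(expectedCol, if (is.null(headerNames)) 8L else NA)

  numOrFail <- function(txt, what, colIdx) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("parse error at line ", dataIdx[bad[1]], ": non-numeric ", what,
           " value '", txt[bad[1]], "'")
    }
    v
  }
  s1 <- numOrFail(mat[, 2], "start1"); e1 <- numOrFail(mat[, 3], "end1")
  s2 <- numOrFail(mat[, 5], "start2"); e2 <- numOrFail(mat[, 6], "end2")
  obs <- numOrFail(mat[, oIdx], "observed count")
  exp_ <- numOrFail(mat[, eIdx], "expected count")
  if (any(obs < 0) || any(exp_ < 0)) {
    bad <- dataIdx[which(obs < 0 | exp_ < 0)[1]]
    stop("validation error at line ", bad, ": negative counts")
  }
  chrom1 <- .normalizeChrom(mat[, 1]); chrom2 <- .normalizeChrom(mat[, 4])
  # order anchors so anchor1 is upstream on intra-chromosomal pairs
  swap <- chrom1 == chrom2 & s2 < s1
  if (any(swap)) {
    tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
    tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  }
  a1 <- GenomicRanges::GRanges(chrom1, IRanges::IRanges(s1 + 1, e1))
  a2 <- GenomicRanges::GRanges(chrom2, IRanges::IRanges(s2 + 1, e2))
  HiCLoops(a1, a2, obs, exp_, referenceDepth)
}

#' Write loops to a BEDPE file with count columns
#'
#' Inverse of \code{\link{readLoops}}: writes a \code{#}-prefixed header line
#' naming the columns, then one tab-separated row per loop with 0-based
#' half-open coordinates and the observed/expected counts.
#'
#' @param loops a \linkS4class{HiCLoops} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLoops <- function(loops, path) {
  header <- paste0("#", paste(c("chrom1", "start1", "end1", "chrom2",
                                "start2", "end2", "observed", "expected"),
                              collapse = "\t"))
  fmtNum <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, scientific = FALSE, trim = TRUE, digits = 15))
  }
  rows <- if (length(loops) == 0) character(0) else paste(
    as.character(GenomicRanges::seqnames(loops@anchor1)),
    GenomicRanges::start(loops@anchor1) - 1,
    GenomicRanges::end(loops@anchor1),
    as.character(GenomicRanges::seqnames(loops@anchor2)),
    GenomicRanges::start(loops@anchor2) - 1,
    GenomicRanges::end(loops@anchor2),
    fmtNum(loops@observed), fmtNum(loops@expected),
    sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Filter loops by span, chromosome, and signal rules
#'
#' Applies the standard inclusion rules for loop power analysis: genomic span
#' strictly shorter than \code{maxSpan} (default 2 Mb), both anchors on an
#' autosome (chr1-chr22 after chromosome-name normalization), and observed
#' counts strictly greater than expected. A loop is kept only if it passes
#' every active rule; the report counts, per rule, how many input loops fail
#' it (a loop failing several rules is counted under each).
#'
#' @param loops a \linkS4class{HiCLoops} object.
#' @param maxSpan maximum span in bp, exclusive (default 2e6).
#' @param autosomes character vector of allowed chromosomes after
#'   normalization to the \code{"chr"} prefix. Default \code{chr1..chr22}.
#'   Set \code{NULL} to disable the rule.
#' @param requireObsGtExp keep only loops with observed > expected
#'   (default \code{TRUE}).
#' @return A list with elements \code{loops} (the kept \code{HiCLoops}, input
#'   order preserved) and \code{report} (data.frame with columns \code{rule}
#'   and \code{removed_count}).
#' @details Filtering is idempotent: applying it to its own output removes
#'   nothing.
#' @examples
#' lp <- simulateLoopSet(loopSimSpec(nLoops = 100, seed = 1))
#' filterLoops(lp)$report
#' @export
filterLoops <- function(loops, maxSpan = 2e6,
                        autosomes = paste0("chr", 1:22),
                        requireObsGtExp = TRUE) {
  n <- length(loops)
  if (n == 0) {
    report <- data.frame(rule = c("span", "autosome", "obs_gt_exp"),
                         removed_count = c(0L, 0L, 0L))
    return(list(loops = loops, report = report))
  }
  spans <- loopSpans(loops)
  failSpan <- spans >= maxSpan
  if (is.null(autosomes)) {
    failChrom <- rep(FALSE, n)
  } else {
    c1 <- .normalizeChrom(as.character(GenomicRanges::seqnames(loops@anchor1)))
    c2 <- .normalizeChrom(as.character(GenomicRanges::seqnames(loops@anchor2)))
    failChrom <- !(c1 %in% autosomes & c2 %in% autosomes)
  }
  failObs <- if (requireObsGtExp) loops@observed <= loops@expected else
    rep(FALSE, n)
  keep <- !(failSpan | failChrom | failObs)
  report <- data.frame(
    rule = c("span", "autosome", "obs_gt_exp"),
    removed_count = c(sum(failSpan), sum(failChrom), sum(failObs))
  )
  list(loops = loops[keep], report = report)
}
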