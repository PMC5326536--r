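#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @import GenomicRanges
#' @import IRanges
NULL

#' Chain: one gapped pairwise-alignment chain between two assemblies
#'
#' Represents a single UCSC chain: a score, the source (reference) and target
#' span, and an ordered set of ungapped alignment blocks. Block coordinates are
#' stored 0-based half-open, as in the chain format itself; negative-strand
#' target blocks are normalised to forward-strand coordinates at parse time
#' (`tStart` of each block is always a forward coordinate) with the strand flag
#' preserved in `tStrand`.
#'
#' Slots `tStartNative`/`tEndNative` keep the header's strand-frame span so
#' that [writeChainFile()] can round-trip files byte-compatibly.
#'
#' @slot score numeric chain score.
#' @slot id chain id (character, may be `NA`).
#' @slot sChrom,sSize,sStart,sEnd source (reference) sequence name, length and
#'   chain span (0-based half-open).
#' @slot tChrom,tSize,tStrand target sequence name, length and strand.
#' @slot tStartNative,tEndNative target chain span in the strand frame used by
#'   the file header.
#' @slot blocks `data.frame` with columns `sStart`, `width`, `tStart`
#'   (forward-frame target start), one row per ungapped block, sorted by
#'   `sStart`.
#' @export
setClass("AlignmentChain", representation(
  score = "numeric",
  id = "character",
  sChrom = "character", sSize = "integer", sStart = "integer", sEnd = "integer",
  tChrom = "character", tSize = "integer", tStrand = "character",
  tStartNative = "integer", tEndNative = "integer",
  blocks = "data.frame"
))

setValidity("AlignmentChain", function(object) {
  b <- object@blocks
  msg <- character(0)
  if (!all(c("sStart", "width", "tStart") %in% names(b)))
    msg <- c(msg, "blocks must have columns sStart, width, tStart")
  else if (nrow(b) > 0) {
    if (any(b$width <= 0)) msg <- c(msg, "block widths must be positive")
    if (is.unsorted(b$sStart, strictly = TRUE) && nrow(b) > 1)
      msg <- c(msg, "blocks must be sorted by source start")
    sEnds <- b$sStart + b$width
    if (nrow(b) > 1 && any(b$sStart[-1] < sEnds[-nrow(b)]))
      msg <- c(msg, "blocks overlap on the source")
    if (b$sStart[1] < object@sStart || sEnds[nrow(b)] > object@sEnd)
      msg <- c(msg, "blocks exceed the declared source span")
    if (any(b$tStart < 0) || any(b$tStart + b$width > object@tSize))
      msg <- c(msg, "target blocks exceed the target sequence")
  }
  if (!object@tStrand %in% c("+", "-"))
    msg <- c(msg, "tStrand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignmentChain", function(object) {
  cat(sprintf(
    "Chain %s: %s:[%d,%d) -> %s:[%d,%d)(%s)  score=%g  %d block(s), %d aligned bp\n",
    ifelse(is.na(object@id), "", object@id),
    object@sChrom, object@sStart, object@sEnd,
    object@tChrom, object@tStartNative, object@tEndNative, object@tStrand,
    object@score, nrow(object@blocks), sum(object@blocks$width)))
})

#' SyntenyMap: reference windows with their lifted spans and retention verdicts
#'
#' The central container of the synteny stage: a set of fixed-size reference
#' windows (as a [GenomicRanges::GRanges]) whose metadata columns record, per
#' window, the best lifted target run (`liftedChrom`, `liftedStart`,
#' `liftedEnd`, 1-based closed like all GRanges coordinates), the fraction of
#' reference bases remapped into that run (`remapFraction`), the total mapped
#' fraction over all runs (`mappedFraction`), the target span length
#' (`liftedLength`, first to last lifted base) and the retention `verdict`
#' (one of `retained`, `rejected_low_remap`, `rejected_size`,
#' `rejected_split`, `unmapped`).
#'
#' @slot windows `GRanges` of reference windows with the metadata columns
#'   described above.
#' @slot refMask `GRanges` of reference-side masked intervals (possibly empty).
#' @slot targetMask `GRanges` of target-side masked intervals.
#' @slot params named list of the thresholds used to build the map.
#' @export
setClass("SyntenyMap", representation(
  windows = "GRanges",
  refMask = "GRanges",
  targetMask = "GRanges",
  params = "list"
))

setValidity("SyntenyMap", function(object) {
  mc <- S4Vectors::mcols(object@windows)
  need <- c("windowId", "remapFraction", "mappedFraction", "liftedLength",
            "liftedChrom", "liftedStart", "liftedEnd", "verdict")
  if (!all(need %in% names(mc)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, names(mc)), collapse = ", ")))
  v <- mc$verdict
  ok <- v %in% c("retained", "rejected_low_remap", "rejected_size",
                 "rejected_split", "unmapped")
  if (!all(ok)) return("unknown verdict value")
  ret <- v == "retained"
  if (any(ret)) {
    p <- object@params
    minRemap <- if (is.null(p$minRemap)) 0.80 else p$minRemap
    minLen <- if (is.null(p$minLen)) 180000L else p$minLen
    maxLen <- if (is.null(p$maxLen)) 220000L else p$maxLen
    if (any(mc$remapFraction[ret] <= minRemap))
      return("retained window with remapFraction at or below the threshold")
    if (any(mc$liftedLength[ret] < minLen | mc$liftedLength[ret] > maxLen))
      return("retained window with liftedLength outside the size bounds")
    if (anyNA(mc$liftedChrom[ret]))
      return("retained window without a lifted span")
  }
  TRUE
})

setMethod("show", "SyntenyMap", function(object) {
  v <- S4Vectors::mcols(object@windows)$verdict
  cat(sprintf("SyntenyMap with %d reference windows\n", length(object@windows)))
  print(table(verdict = v))
  if (length(object@refMask))
    cat(sprintf("reference-side mask: %d intervals (%d bp)\n",
                length(object@refMask), sum(IRanges::width(object@refMask))))
  if (length(object@targetMask))
    cat(sprintf("target-side mask: %d intervals (%d bp)\n",
                length(object@targetMask), sum(IRanges::width(object@targetMask))))
})

#' RegressionSummary: a compact linear-model summary
#'
#' Thin S4 container for the quantities reported from ordinary least squares
#' fits: coefficient table (estimate, standard error, t, two-sided p), R^2,
#' adjusted R^2, overall F with its degrees of freedom, and n.
#'
#' @slot coefficients matrix with columns `estimate`, `se`, `t`, `p`.
#' @slot r2,adjR2 numeric scalars.
#' @slot fstat numeric overall F statistic.
#' @slot fdf numeric length-2 degrees of freedom (p, n - p - 1).
#' @slot n integer number of complete cases used.
#' @slot label character model label.
#' @export
setClass("RegressionSummary", representation(
  coefficients = "matrix",
  r2 = "numeric", adjR2 = "numeric",
  fstat = "numeric", fdf = "numeric",
  n = "integer", label = "character"
))

setMethod("show", "RegressionSummary", function(object) {
  cat(sprintf("Linear model%s: n = %d, R2 = %.4g, F(%d,%d) = %.4g\n",
              ifelse(nchar(object@label), paste0(" [", object@label, "]"), ""),
              object@n, object@r2, object@fdf[1], object@fdf[2], object@fstat))
  printCoefmat(object@coefficients, P.values = TRUE, has.Pvalue = TRUE)
})

#' PCRResult: principal-component regression decomposition
#'
#' Result of regressing a response on the principal components of standardised
#' predictors. Per PC: loadings on the original predictors (sign-fixed so the
#' largest-magnitude loading is positive), share of predictor variance,
#' share of response variance (per-PC R^2, additive because PCs are
#' orthogonal), and the sign of the association with the response.
#'
#' @slot loadings p x p matrix of predictor loadings (columns = PCs).
#' @slot varianceShare per-PC share of predictor variance.
#' @slot r2PerPC per-PC share of response variance.
#' @slot assocSign sign (+1/-1/0) of each PC's correlation with the response.
#' @slot totalR2 sum of `r2PerPC`; equals the full-OLS R^2 on the same data.
#' @slot retained logical, FALSE for numerically zero-variance PCs.
#' @slot n integer number of complete cases.
#' @export
setClass("PCRResult", representation(
  loadings = "matrix",
  varianceShare = "numeric",
  r2PerPC = "numeric",
  assocSign = "numeric",
  totalR2 = "numeric",
  retained = "logical",
  n = "integer"
))

setValidity("PCRResult", function(object) {
  if (any(object@r2PerPC < -1e-12 | object@r2PerPC > 1 + 1e-12))
    return("per-PC R2 outside [0,1]")
  if (object@totalR2 < -1e-12 || object@totalR2 > 1 + 1e-12)
    return("total R2 outside [0,1]")
  TRUE
})

setMethod("show", "PCRResult", function(object) {
  k <- length(object@r2PerPC)
  cat(sprintf("Principal-component regression: n = %d, total R2 = %.4g\n",
              object@n, object@totalR2))
  tab <- data.frame(
    varShare = round(object@varianceShare, 4),
    r2 = round(object@r2PerPC, 4),
    sign = c("-", "0", "+")[object@assocSign + 2],
    row.names = colnames(object@loadings))
  print(tab)
})

#' SharedPolyReport: trans-species polymorphism audit
#'
#' @slot nAlignableVariableA number of species-A variable sites that lift to
#'   species-B coordinates.
#' @slot nAlsoVariableB how many of those coincide with a species-B variable
#'   site.
#' @slot fraction `nAlsoVariableB / nAlignableVariableA` (`NA` when the
#'   denominator is zero).
#' @slot nVariableA total species-A variable sites before lifting.
#' @slot alleleAware logical, whether allele identity was required for a match.
#' @export
setClass("SharedPolyReport", representation(
  nAlignableVariableA = "integer",
  nAlsoVariableB = "integer",
  fraction = "numeric",
  nVariableA = "integer",
  alleleAware = "logical"
))

setValidity("SharedPolyReport", function(object) {
  if (object@nAlsoVariableB > object@nAlignableVariableA)
    return("numerator exceeds denominator")
  TRUE
})

setMethod("show", "SharedPolyReport", function(object) {
  cat(sprintf(
    "Shared polymorphism audit%s:\n  %d variable sites in A, %d alignable, %d also variable in B (fraction %.4g)\n",
    if (object@alleleAware) " (allele-aware)" else "",
    object@nVariableA, object@nAlignableVariableA, object@nAlsoVariableB,
    object@fraction))
})
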