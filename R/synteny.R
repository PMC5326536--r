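# Window tiling, chain lift-over and the collinearity retention filters.
#
# Retention rule: a reference window is kept when more than 80% of its bases
# remap into a single collinear target run and the run's span (first to last
# lifted base) lies within [180 kb, 220 kb]. The remap threshold is strict
# (">"), the size bounds inclusive.

#' Tile a genome into non-overlapping fixed-size windows
#'
#' @param chromSizes named integer vector of chromosome lengths, or a
#'   two-column data frame (name, length) as read by [readChromSizes()].
#' @param windowSize window width in bp (default 200 kb).
#' @return a `GRanges` of windows in genome order with a logical metadata
#'   column `partial` marking a trailing window shorter than `windowSize`.
#'   Partial windows are emitted but excluded from analysis by default
#'   downstream.
#' @export
tileWindows <- function(chromSizes, windowSize = 200000L) {
  if (is.data.frame(chromSizes))
    chromSizes <- stats::setNames(as.integer(chromSizes[[2]]), chromSizes[[1]])
  if (!length(chromSizes)) stop("empty chromosome set", call. = FALSE)
  if (is.null(names(chromSizes)) || anyNA(names(chromSizes)))
    stop("chromSizes must be named", call. = FALSE)
  windowSize <- as.integer(windowSize)
  if (is.na(windowSize) || windowSize <= 0L)
    stop("windowSize must be a positive integer", call. = FALSE)
  tiles <- GenomicRanges::tileGenome(chromSizes, tilewidth = windowSize,
                                     cut.last.tile.in.chrom = TRUE)
  S4Vectors::mcols(tiles)$partial <- IRanges::width(tiles) < windowSize
  tiles
}

# Core lift engine. Maps many windows through many chains at once.
# Overlapping chains are resolved per base by chain score (ties: input order);
# a "run" is the set of bases of one window lifted through one chain, which is
# collinear on a single target chromosome by construction.
#
# Returns a data.frame with one row per (window, chain) run:
# win (index into `windows`), tChrom, tStrand, tStart0, tEnd0 (forward,
# 0-based half-open span from first to last lifted base), count (lifted bases).
.liftRuns <- function(windows, chains) {
  ord <- order(-vapply(chains, function(c) c@score, numeric(1)))
  covered <- new.env(parent = emptyenv())
  win0 <- IRanges::IRanges(GenomicRanges::start(windows),
                           GenomicRanges::end(windows))
  winChrom <- as.character(GenomicRanges::seqnames(windows))
  out <- vector("list", length(chains))
  for (k in ord) {
    ch <- chains[[k]]
    b <- ch@blocks
    blocksIR <- IRanges::IRanges(b$sStart + 1L, width = b$width)
    cov <- if (!is.null(covered[[ch@sChrom]])) covered[[ch@sChrom]]
           else IRanges::IRanges()
    covFree <- IRanges::setdiff(
      IRanges::IRanges(ch@sStart + 1L, ch@sEnd), cov)
    covered[[ch@sChrom]] <- IRanges::reduce(IRanges::union(cov, blocksIR))
    if (!length(covFree)) next
    wsel <- which(winChrom == ch@sChrom)
    if (!length(wsel)) next
    h1 <- IRanges::findOverlaps(blocksIR, covFree)
    if (!length(h1)) next
    frag <- IRanges::pintersect(blocksIR[S4Vectors::queryHits(h1)],
                                covFree[S4Vectors::subjectHits(h1)])
    blkIdx <- S4Vectors::queryHits(h1)
    wir <- win0[wsel]
    h2 <- IRanges::findOverlaps(frag, wir)
    if (!length(h2)) next
    piece <- IRanges::pintersect(frag[S4Vectors::queryHits(h2)],
                                 wir[S4Vectors::subjectHits(h2)])
    blk <- blkIdx[S4Vectors::queryHits(h2)]
    off <- IRanges::start(piece) - 1L - b$sStart[blk]
    w <- IRanges::width(piece)
    if (ch@tStrand == "+") {
      t0 <- b$tStart[blk] + off
      t1 <- t0 + w
    } else {
      t1 <- b$tStart[blk] + b$width[blk] - off
      t0 <- t1 - w
    }
    out[[k]] <- data.frame(
      win = wsel[S4Vectors::subjectHits(h2)],
      chain = k, tChrom = ch@tChrom, tStrand = ch@tStrand,
      t0 = t0, t1 = t1, width = w)
  }
  pieces <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pieces) || !nrow(pieces))
    return(data.frame(win = integer(0), chain = integer(0),
                      tChrom = character(0), tStrand = character(0),
                      tStart0 = integer(0), tEnd0 = integer(0),
                      count = integer(0)))
  dt <- data.table::as.data.table(pieces)
  runs <- dt[, list(tChrom = tChrom[1L], tStrand = tStrand[1L],
                    tStart0 = min(t0), tEnd0 = max(t1),
                    count = sum(width)),
             by = c("win", "chain")]
  as.data.frame(runs)
}

#' Lift an interval into the other genome through alignment chains
#'
#' Maps every base of `interval` through the chain blocks (bases falling in
#' chain gaps are unlifted; bases covered by several chains go to the
#' highest-scoring one, ties broken by input order) and groups the lifted
#' bases into collinear runs, one per chain. For each run the returned range
#' is the target span from the first to the last lifted base; metadata column
#' `liftedBases` counts the reference bases mapped into it.
#'
#' @param interval a length-1 `GRanges`.
#' @param chains list of [AlignmentChain] objects (see [readChainFile()]).
#' @return a `GRanges` of target runs, sorted by decreasing `liftedBases`,
#'   with metadata columns `liftedBases` and `chainScore`. Empty when the
#'   interval is unmapped.
#' @export
liftInterval <- function(interval, chains) {
  stopifnot(is(interval, "GRanges"), length(interval) == 1L)
  runs <- .liftRuns(interval, chains)
  runs <- runs[order(-runs$count), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = runs$tChrom,
    ranges = IRanges::IRanges(runs$tStart0 + 1L, runs$tEnd0),
    strand = if (nrow(runs)) runs$tStrand else character(0),
    liftedBases = runs$count,
    chainScore = vapply(chains[runs$chain], function(c) c@score, numeric(1)))
}

#' Build the cross-species window map with retention filters
#'
#' For every full-size reference window, lifts its bases through the chains,
#' picks the single collinear target run with the largest lifted-base count,
#' and assigns a retention verdict:
#' \describe{
#'   \item{retained}{remap fraction strictly above `minRemap` into one run and
#'     target span length within `[minLen, maxLen]`.}
#'   \item{rejected_size}{single-run remap passes but the span is shorter than
#'     `minLen` or longer than `maxLen`.}
#'   \item{rejected_split}{no single run reaches `minRemap` but the total
#'     mapped fraction over all runs does.}
#'   \item{rejected_low_remap}{total mapped fraction at or below `minRemap`.}
#'   \item{unmapped}{no base lifts.}
#' }
#'
#' @param refWindows `GRanges` from [tileWindows()]; partial windows are
#'   dropped (with a message) unless `dropPartial = FALSE`, in which case they
#'   are an error.
#' @param chains list of [AlignmentChain] objects.
#' @param minRemap strict lower bound on the single-run remap fraction
#'   (default 0.80).
#' @param minLen,maxLen inclusive bounds on the lifted span length
#'   (defaults 180 kb and 220 kb).
#' @param dropPartial drop trailing sub-size windows (default TRUE).
#' @return a [SyntenyMap].
#' @export
buildWindowMap <- function(refWindows, chains, minRemap = 0.80,
                           minLen = 180000L, maxLen = 220000L,
                           dropPartial = TRUE) {
  partial <- S4Vectors::mcols(refWindows)$partial
  if (is.null(partial))
    partial <- IRanges::width(refWindows) < max(IRanges::width(refWindows))
  if (any(partial)) {
    if (!dropPartial)
      stop("refWindows contains partial (sub-size) windows", call. = FALSE)
    refWindows <- refWindows[!partial]
  }
  if (!length(refWindows)) stop("no full-size windows to map", call. = FALSE)

  runs <- .liftRuns(refWindows, chains)
  W <- IRanges::width(refWindows)
  nWin <- length(refWindows)

  best <- data.frame(win = seq_len(nWin), bestCount = 0L, total = 0L,
                     tChrom = NA_character_, tStrand = NA_character_,
                     tStart0 = NA_integer_, tEnd0 = NA_integer_)
  if (nrow(runs)) {
    dt <- data.table::as.data.table(runs)
    # per window: total mapped bases and the best run (max count; chains are
    # already in score-resolved base ownership, ties by chain order)
    agg <- dt[order(-count, chain),
              list(bestCount = count[1L], total = sum(count),
                   tChrom = tChrom[1L], tStrand = tStrand[1L],
                   tStart0 = tStart0[1L], tEnd0 = tEnd0[1L]),
              by = "win"]
    idx <- agg$win
    best$bestCount[idx] <- agg$bestCount
    best$total[idx] <- agg$total
    best$tChrom[idx] <- agg$tChrom
    best$tStrand[idx] <- agg$tStrand
    best$tStart0[idx] <- agg$tStart0
    best$tEnd0[idx] <- agg$tEnd0
  }

  remap <- best$bestCount / W
  mapped <- best$total / W
  liftedLen <- best$tEnd0 - best$tStart0
  verdict <- ifelse(
    best$total == 0L, "unmapped",
    ifelse(remap > minRemap,
           ifelse(liftedLen >= minLen & liftedLen <= maxLen,
                  "retained", "rejected_size"),
           ifelse(mapped > minRemap, "rejected_split", "rejected_low_remap")))

  gr <- refWindows
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    windowId = sprintf("%s:%d-%d",
                       as.character(GenomicRanges::seqnames(refWindows)),
                       GenomicRanges::start(refWindows) - 1L,
                       GenomicRanges::end(refWindows)),
    remapFraction = remap,
    mappedFraction = mapped,
    liftedLength = ifelse(is.na(liftedLen), 0L, liftedLen),
    liftedChrom = best$tChrom,
    liftedStart = best$tStart0 + 1L,
    liftedEnd = best$tEnd0,
    liftedStrand = best$tStrand,
    verdict = verdict)
  new("SyntenyMap", windows = gr,
      refMask = GenomicRanges::GRanges(),
      targetMask = GenomicRanges::GRanges(),
      params = list(minRemap = minRemap, minLen = minLen, maxLen = maxLen))
}

#' Attach a mask to a window map
#'
#' Registers intervals (e.g. coding sequence from a BED/GFF) to be excluded
#' from downstream site streams and qualifying-site counts, on the reference
#' or the target side. Masks accumulate: calling twice unions the intervals.
#' Per-window masked-base counts are recorded in the metadata columns
#' `refMaskedBases` / `targetMaskedBases` (the latter computed over the lifted
#' spans).
#'
#' @param map a [SyntenyMap].
#' @param mask a `GRanges` of intervals to exclude.
#' @param side `"ref"` or `"target"`: which genome's coordinates `mask` is in.
#' @return the updated [SyntenyMap].
#' @export
maskIntervals <- function(map, mask, side = c("ref", "target")) {
  side <- match.arg(side)
  stopifnot(is(map, "SyntenyMap"), is(mask, "GRanges"))
  mask <- GenomicRanges::reduce(mask)
  gr <- map@windows
  if (side == "ref") {
    map@refMask <- GenomicRanges::reduce(GenomicRanges::union(map@refMask, mask))
    S4Vectors::mcols(gr)$refMaskedBases <-
      .overlapBases(gr, map@refMask)
  } else {
    map@targetMask <- GenomicRanges::reduce(GenomicRanges::union(map@targetMask, mask))
    spans <- liftedSpans(map, retainedOnly = FALSE)
    masked <- rep(NA_integer_, length(gr))
    ok <- !is.na(S4Vectors::mcols(gr)$liftedChrom)
    if (any(ok)) masked[ok] <- .overlapBases(spans[ok], map@targetMask)
    S4Vectors::mcols(gr)$targetMaskedBases <- masked
  }
  map@windows <- gr
  map
}

# bases of each range in `gr` covered by the (reduced) mask
.overlapBases <- function(gr, mask) {
  out <- integer(length(gr))
  if (!length(mask) || !length(gr)) return(out)
  h <- GenomicRanges::findOverlaps(gr, mask)
  if (!length(h)) return(out)
  pi <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(h)],
                                  mask[S4Vectors::subjectHits(h)])
  tab <- rowsum(IRanges::width(pi), S4Vectors::queryHits(h))
  out[as.integer(rownames(tab))] <- as.integer(tab[, 1])
  out
}

#' Reference windows of a window map
#'
#' @param map a [SyntenyMap].
#' @return the reference-window `GRanges` with all verdict metadata columns.
#' @export
refWindows <- function(map) map@windows

#' Lifted target spans of a window map
#'
#' @param map a [SyntenyMap].
#' @param retainedOnly return only retained windows (default TRUE).
#' @return `GRanges` in target coordinates, carrying `windowId`.
#' @export
liftedSpans <- function(map, retainedOnly = TRUE) {
  mc <- S4Vectors::mcols(map@windows)
  keep <- if (retainedOnly) mc$verdict == "retained" else !is.na(mc$liftedChrom)
  GenomicRanges::GRanges(
    seqnames = mc$liftedChrom[keep],
    ranges = IRanges::IRanges(mc$liftedStart[keep], mc$liftedEnd[keep]),
    strand = mc$liftedStrand[keep],
    windowId = mc$windowId[keep])
}

#' @describeIn liftedSpans retention verdict per window, as a character vector
#'   named by window id.
#' @export
verdicts <- function(map) {
  mc <- S4Vectors::mcols(map@windows)
  stats::setNames(as.character(mc$verdict), mc$windowId)
}

#' Write a window map as a TSV (0-based half-open coordinates)
#'
#' @param map a [SyntenyMap].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWindowMap <- function(map, path) {
  gr <- map@windows
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    window_id = mc$windowId,
    remap_fraction = mc$remapFraction,
    mapped_fraction = mc$mappedFraction,
    lifted_chrom = mc$liftedChrom,
    lifted_start = mc$liftedStart - 1L,
    lifted_end = mc$liftedEnd,
    lifted_length = mc$liftedLength,
    verdict = mc$verdict)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
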