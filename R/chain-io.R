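# UCSC chain reading/writing. The chain format is the substrate of the whole
# synteny stage, so parsing is strict: block arithmetic must tile the declared
# chain spans exactly, and errors name the offending line.

.chainStop <- function(lineno, fmt, ...) {
  stop(sprintf(paste0("chain parse error at line %d: ", fmt), lineno, ...),
       call. = FALSE)
}

#' Read a UCSC chain file
#'
#' Parses a chain file (header lines `chain score tName tSize tStrand tStart
#' tEnd qName qSize qStrand qStart qEnd id` followed by `size dt dq` triples
#' and a terminal bare `size`). In this package's vocabulary the chain's
#' *target* side of the header (`t`) is the **source** (reference) genome of
#' the lift and the *query* side (`q`) is the lift **target**, matching how
#' UCSC `over.chain` files are oriented for liftOver.
#'
#' Negative-strand targets are normalised to forward coordinates per the UCSC
#' convention (reverse-complement frame in the file); the strand flag is kept
#' on the returned [AlignmentChain].
#'
#' @param path path to a chain file.
#' @return a list of [AlignmentChain] objects, in file order.
#' @examples
#' tf <- tempfile(fileext = ".chain")
#' writeLines(c("chain 100 chr1 1000 + 0 100 chrA 1000 + 0 100 1", "100", ""), tf)
#' readChainFile(tf)[[1]]
#' @export
readChainFile <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^chain\\b", ln))
      .chainStop(i, "expected a 'chain' header, got '%s'", substr(ln, 1, 40))
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < 12L)
      .chainStop(i, "header has %d fields, expected at least 12", length(f))
    hline <- i
    score <- suppressWarnings(as.numeric(f[2]))
    sSize <- suppressWarnings(as.integer(f[4]))
    sStart <- suppressWarnings(as.integer(f[6]))
    sEnd <- suppressWarnings(as.integer(f[7]))
    tSize <- suppressWarnings(as.integer(f[9]))
    tStart <- suppressWarnings(as.integer(f[11]))
    tEnd <- suppressWarnings(as.integer(f[12]))
    if (anyNA(c(score, sSize, sStart, sEnd, tSize, tStart, tEnd)))
      .chainStop(i, "non-numeric field in header")
    if (f[5] != "+")
      .chainStop(i, "reference (tName side) strand must be '+', got '%s'", f[5])
    if (!f[10] %in% c("+", "-"))
      .chainStop(i, "query strand must be '+' or '-', got '%s'", f[10])
    if (sStart >= sEnd || tStart >= tEnd)
      .chainStop(i, "chain span is empty or inverted")

    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    lastLine <- i
    repeat {
      i <- i + 1L
      if (i > n)
        .chainStop(hline, "chain has no terminating single-size block line")
      bl <- trimws(lines[[i]])
      if (bl == "")
        .chainStop(i, "blank line before the terminating block line")
      bf <- suppressWarnings(as.integer(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(bf))
        .chainStop(i, "non-numeric alignment block line")
      if (length(bf) == 1L) {
        sizes <- c(sizes, bf); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        lastLine <- i
        i <- i + 1L
        break
      }
      if (length(bf) != 3L)
        .chainStop(i, "alignment line has %d fields, expected 3 (size dt dq)", length(bf))
      if (bf[1] <= 0L || bf[2] < 0L || bf[3] < 0L)
        .chainStop(i, "block size must be positive and gaps non-negative")
      sizes <- c(sizes, bf[1]); dts <- c(dts, bf[2]); dqs <- c(dqs, bf[3])
    }

    nb <- length(sizes)
    sStarts <- sStart + cumsum(c(0L, (sizes + dts)[-nb]))
    tNative <- tStart + cumsum(c(0L, (sizes + dqs)[-nb]))
    if (sStarts[nb] + sizes[nb] != sEnd)
      .chainStop(lastLine,
                 "block arithmetic ends at %d on the reference, header declares tEnd %d",
                 sStarts[nb] + sizes[nb], sEnd)
    if (tNative[nb] + sizes[nb] != tEnd)
      .chainStop(lastLine,
                 "block arithmetic ends at %d on the query, header declares qEnd %d",
                 tNative[nb] + sizes[nb], tEnd)
    if (tEnd > tSize || sEnd > sSize)
      .chainStop(hline, "chain span exceeds the declared sequence size")

    tForward <- if (f[10] == "+") tNative else tSize - (tNative + sizes)
    ch <- new("AlignmentChain",
              score = score, id = if (length(f) >= 13L) f[13] else NA_character_,
              sChrom = f[3], sSize = sSize, sStart = sStart, sEnd = sEnd,
              tChrom = f[8], tSize = tSize, tStrand = f[10],
              tStartNative = tStart, tEndNative = tEnd,
              blocks = data.frame(sStart = sStarts, width = sizes,
                                  tStart = as.integer(tForward)))
    validObject(ch)
    chains[[length(chains) + 1L]] <- ch
  }
  if (!length(chains)) stop("no chains found in ", path, call. = FALSE)
  chains
}

#' Write chains to a UCSC chain file
#'
#' Inverse of [readChainFile()]: reconstructs the `size dt dq` triples from the
#' stored blocks (converting forward-frame target coordinates back to the
#' strand frame) and preserves scores and ids, so that
#' `writeChainFile(readChainFile(x))` reproduces the block structure exactly.
#'
#' @param chains a list of [AlignmentChain] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChainFile <- function(chains, path) {
  if (is(chains, "AlignmentChain")) chains <- list(chains)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    b <- ch@blocks
    nb <- nrow(b)
    tNative <- if (ch@tStrand == "+") b$tStart else ch@tSize - (b$tStart + b$width)
    hdr <- paste("chain",
                 format(ch@score, scientific = FALSE, trim = TRUE),
                 ch@sChrom, ch@sSize, "+", ch@sStart, ch@sEnd,
                 ch@tChrom, ch@tSize, ch@tStrand,
                 ch@tStartNative, ch@tEndNative,
                 if (is.na(ch@id)) "" else ch@id)
    writeLines(trimws(hdr), con)
    if (nb > 1L) {
      dt <- b$sStart[-1L] - (b$sStart + b$width)[-nb]
      dq <- tNative[-1L] - (tNative + b$width)[-nb]
      writeLines(paste(b$width[-nb], dt, dq), con)
    }
    writeLines(as.character(b$width[nb]), con)
    writeLines("", con)
  }
  invisible(path)
}
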