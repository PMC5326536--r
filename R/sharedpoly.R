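# Trans-species polymorphism audit: after complete lineage sorting no shared
# ancestral variants are expected, so sites variable in both species should
# be no more frequent than coincidental double hits.

#' Lift single positions through alignment chains
#'
#' Per-base lift: each position goes to the highest-scoring chain whose
#' blocks cover it (ties by chain order); positions in chain gaps are
#' unlifted (`NA`).
#'
#' @param chrom,pos parallel vectors of source chromosome and 1-based
#'   position.
#' @param chains list of [AlignmentChain] objects.
#' @return data.frame with `tChrom`, `tPos` (1-based, forward strand),
#'   `tStrand`; `NA` rows for unlifted positions.
#' @export
liftSitePositions <- function(chrom, pos, chains) {
  stopifnot(length(chrom) == length(pos))
  if (!length(chains)) stop("no chains supplied", call. = FALSE)
  ord <- order(-vapply(chains, function(c) c@score, numeric(1)))
  blocks <- do.call(rbind, lapply(seq_along(ord), function(i) {
    ch <- chains[[ord[i]]]
    b <- ch@blocks
    data.frame(prec = i, sChrom = ch@sChrom, sStart = b$sStart,
               width = b$width, tStart = b$tStart, tChrom = ch@tChrom,
               tStrand = ch@tStrand)
  }))
  bgr <- GenomicRanges::GRanges(blocks$sChrom,
                                IRanges::IRanges(blocks$sStart + 1L,
                                                 blocks$sStart + blocks$width))
  pgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  h <- GenomicRanges::findOverlaps(pgr, bgr)
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  o <- order(qh, blocks$prec[sh])
  qh <- qh[o]; sh <- sh[o]
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]

  out <- data.frame(tChrom = rep(NA_character_, length(pos)),
                    tPos = rep(NA_integer_, length(pos)),
                    tStrand = rep(NA_character_, length(pos)))
  off <- pos[qh] - 1L - blocks$sStart[sh]
  plus <- blocks$tStrand[sh] == "+"
  t0 <- integer(length(sh))
  t0[plus] <- blocks$tStart[sh][plus] + off[plus]
  t0[!plus] <- blocks$tStart[sh][!plus] + blocks$width[sh][!plus] - 1L - off[!plus]
  out$tChrom[qh] <- blocks$tChrom[sh]
  out$tPos[qh] <- t0 + 1L
  out$tStrand[qh] <- blocks$tStrand[sh]
  out
}

#' Collect sites variable in at least one population of a species
#'
#' A site counts as variable when it is a coverage-passing, polymorphic
#' bi-allelic SNP (0 < alternate copies < called copies) in one or more of
#' the populations' VCFs.
#'
#' @param vcfPaths character vector of per-population VCF paths.
#' @param minDp coverage threshold; set `applyCoverage = FALSE` to count
#'   variable sites regardless of coverage.
#' @param applyCoverage apply the all-individuals depth filter (default TRUE).
#' @return data.frame of unique variable sites: `chrom`, `pos`, `ref`, `alt`.
#' @export
collectVariableSites <- function(vcfPaths, minDp = 4, applyCoverage = TRUE) {
  .variableSiteTable(lapply(vcfPaths, function(p) readSites(p)$sites),
                     minDp = minDp, applyCoverage = applyCoverage)
}

# same reduction, starting from already-parsed site tables
.variableSiteTable <- function(siteDfs, minDp = 4, applyCoverage = TRUE) {
  parts <- lapply(siteDfs, function(s) {
    v <- s$isVariant & s$altCopies > 0L & s$altCopies < s$nCalled
    if (applyCoverage) v <- v & s$minDepth >= minDp
    s[v, c("chrom", "pos", "ref", "alt")]
  })
  all <- do.call(rbind, parts)
  all[!duplicated(all[, c("chrom", "pos")]), , drop = FALSE]
}

.revcomp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Audit shared (trans-species) polymorphism
#'
#' Lifts species-A variable sites per base through the chains and counts how
#' many coincide with species-B variable sites. Sites that fail to lift are
#' excluded from the denominator. By default matching is by coordinate only
#' ("variable at the homologous position"); with `alleleAware = TRUE` the
#' unordered allele pair must also agree (reverse-complemented across
#' negative-strand chains).
#'
#' @param sitesA,sitesB data.frames of variable sites from
#'   [collectVariableSites()], in species-A and species-B coordinates.
#' @param chains list of [AlignmentChain] mapping A coordinates to B.
#' @param alleleAware require allele identity for a match (default FALSE).
#' @return a [SharedPolyReport].
#' @export
auditSharedPolymorphism <- function(sitesA, sitesB, chains,
                                    alleleAware = FALSE) {
  if (!length(chains)) stop("no chains supplied", call. = FALSE)
  lifted <- liftSitePositions(sitesA$chrom, sitesA$pos, chains)
  ok <- !is.na(lifted$tPos)
  keyB <- paste(sitesB$chrom, sitesB$pos)
  keyA <- paste(lifted$tChrom[ok], lifted$tPos[ok])
  hit <- match(keyA, keyB)
  matched <- !is.na(hit)
  if (alleleAware && any(matched)) {
    ia <- which(ok)[matched]
    ib <- hit[matched]
    aRef <- sitesA$ref[ia]; aAlt <- sitesA$alt[ia]
    neg <- lifted$tStrand[ia] == "-"
    aRef[neg] <- .revcomp(aRef[neg])
    aAlt[neg] <- .revcomp(aAlt[neg])
    sameSet <- (aRef == sitesB$ref[ib] & aAlt == sitesB$alt[ib]) |
      (aRef == sitesB$alt[ib] & aAlt == sitesB$ref[ib])
    matched[matched] <- sameSet
  }
  nDen <- sum(ok)
  nNum <- sum(matched)
  new("SharedPolyReport",
      nAlignableVariableA = as.integer(nDen),
      nAlsoVariableB = as.integer(nNum),
      fraction = if (nDen > 0) nNum / nDen else NA_real_,
      nVariableA = nrow(sitesA),
      alleleAware = alleleAware)
}
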