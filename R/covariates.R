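# Per-window genomic covariates: coding-sequence density, intergenic GC,
# repeat density, gene-length-weighted dS with exclusions, recombination
# rate, chromosome length; plus the skew-reducing transforms
# (sqrt for CDS density and dS, log10(x+1) for recombination rate).

#' Coding-sequence density per window
#'
#' Fraction of window bases covered by the union of CDS features
#' (strand-agnostic; overlapping CDS counted once).
#'
#' @param windows `GRanges` of windows.
#' @param gff `GRanges` of annotation features; rows with `type == "CDS"` are
#'   used when a `type` column is present, otherwise all rows.
#' @return numeric vector in `[0, 1]`, one value per window.
#' @export
cdsDensity <- function(windows, gff) {
  feats <- gff
  tp <- S4Vectors::mcols(gff)$type
  if (!is.null(tp)) feats <- gff[as.character(tp) == "CDS"]
  .overlapBases(windows, GenomicRanges::reduce(feats)) /
    IRanges::width(windows)
}

#' Repeat density per window (union coverage of a repeat BED)
#'
#' @param windows `GRanges` of windows.
#' @param repeats `GRanges` of repeat intervals.
#' @return numeric vector in `[0, 1]`.
#' @export
repeatDensity <- function(windows, repeats) {
  .overlapBases(windows, GenomicRanges::reduce(repeats)) /
    IRanges::width(windows)
}

#' Intergenic GC content per window
#'
#' GC fraction over intergenic, non-N bases of each window. "Intergenic" is
#' the complement of annotated gene spans (rows with `type == "gene"` when a
#' type column is present, otherwise all annotation rows reduced).
#'
#' @param windows `GRanges` of windows.
#' @param seqs a named `DNAStringSet` (one sequence per chromosome).
#' @param genes `GRanges` of gene annotations to exclude.
#' @param minBases windows with fewer intergenic non-N bases than this are
#'   returned as `NA` (default 1000).
#' @return numeric vector in `[0, 1]`, `NA` where insufficient sequence.
#' @export
windowedGC <- function(windows, seqs, genes, minBases = 1000) {
  stopifnot(is(seqs, "DNAStringSet"))
  gspan <- GenomicRanges::reduce(if (!is.null(S4Vectors::mcols(genes)$type))
    genes[as.character(S4Vectors::mcols(genes)$type) == "gene"] else genes)
  out <- rep(NA_real_, length(windows))
  for (i in seq_along(windows)) {
    w <- windows[i]
    chrom <- as.character(GenomicRanges::seqnames(w))
    if (!chrom %in% names(seqs)) next
    inter <- GenomicRanges::setdiff(w, gspan, ignore.strand = TRUE)
    if (!length(inter)) next
    r <- IRanges::restrict(IRanges::ranges(inter), start = 1L,
                           end = length(seqs[[chrom]]))
    if (!sum(IRanges::width(r))) next
    seq <- unlist(Biostrings::extractAt(seqs[[chrom]], r))
    f <- Biostrings::letterFrequency(seq, c("G", "C", "A", "T"))
    tot <- sum(f)
    if (tot < minBases) next
    out[i] <- sum(f[c("G", "C")]) / tot
  }
  out
}

#' Gene-length-weighted dS per window
#'
#' Average synonymous substitution rate of the genes overlapping each window,
#' weighted by overlap length, after excluding genes with `ds == 0` or
#' `ds > 2`. A window average above 0.3 is set to missing, as is a window
#' with no remaining genes.
#'
#' @param windows `GRanges` of windows.
#' @param genes `GRanges` of genes with a numeric `ds` metadata column.
#' @param dsMax window-average ceiling above which dS is set missing
#'   (default 0.3).
#' @param excludeZero,excludeAbove per-gene exclusion rules (defaults 0 and 2).
#' @return numeric vector, `NA` where missing.
#' @export
weightedDS <- function(windows, genes, dsMax = 0.3,
                       excludeZero = TRUE, excludeAbove = 2) {
  ds <- S4Vectors::mcols(genes)$ds
  if (is.null(ds)) stop("genes must carry a 'ds' metadata column", call. = FALSE)
  if (any(ds < 0, na.rm = TRUE)) stop("negative dS in input", call. = FALSE)
  keep <- !is.na(ds) & ds <= excludeAbove
  if (excludeZero) keep <- keep & ds > 0
  genes <- genes[keep]
  ds <- ds[keep]
  out <- rep(NA_real_, length(windows))
  if (!length(genes)) return(out)
  h <- GenomicRanges::findOverlaps(windows, genes, ignore.strand = TRUE)
  if (!length(h)) return(out)
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  w <- IRanges::width(GenomicRanges::pintersect(windows[qh], genes[sh],
                                                ignore.strand = TRUE))
  num <- rowsum(w * ds[sh], qh)
  den <- rowsum(w, qh)
  idx <- as.integer(rownames(num))
  val <- num[, 1] / den[, 1]
  val[val > dsMax] <- NA_real_
  out[idx] <- val
  out
}

#' Skew-reducing predictor transforms
#'
#' Adds transformed columns: square root for CDS density and dS,
#' `log10(x + 1)` for recombination rate. GC and repeat density are left
#' untransformed. Missing values propagate.
#'
#' @param tab data.frame with columns `cdsDensity`, `ds`, `recRate`.
#' @return `tab` with added columns `cdsDensityT`, `dsT`, `recRateT`.
#' @export
transformPredictors <- function(tab) {
  stopifnot(all(c("cdsDensity", "ds", "recRate") %in% names(tab)))
  tab$cdsDensityT <- sqrt(tab$cdsDensity)
  tab$dsT <- sqrt(tab$ds)
  tab$recRateT <- log10(tab$recRate + 1)
  tab
}

#' Assemble the per-window covariate table
#'
#' @param windows `GRanges` with a `windowId` column (typically the retained
#'   reference windows of a [SyntenyMap]).
#' @param gff `GRanges` gene annotation (CDS rows used for density, gene rows
#'   for the intergenic mask).
#' @param repeats `GRanges` repeat intervals.
#' @param gc either a named numeric vector of precomputed per-window
#'   intergenic GC (indexed by window id) or a `DNAStringSet` to compute it
#'   from.
#' @param dsGenes `GRanges` of genes with a `ds` column (see [weightedDS()]).
#' @param rec named numeric vector of per-window recombination rates (cM/Mb).
#' @param chromSizes named vector of chromosome lengths (for the
#'   chromosome-length covariate).
#' @return data.frame with raw and transformed predictors plus `chromLength`.
#' @export
buildCovariateTable <- function(windows, gff, repeats, gc, dsGenes, rec,
                                chromSizes) {
  ids <- S4Vectors::mcols(windows)$windowId
  if (is.null(ids)) stop("windows must carry a windowId column", call. = FALSE)
  gcv <- if (is(gc, "DNAStringSet")) windowedGC(windows, gc, gff)
         else as.numeric(gc[ids])
  tab <- data.frame(
    windowId = ids,
    cdsDensity = cdsDensity(windows, gff),
    gc = gcv,
    repeatDensity = repeatDensity(windows, repeats),
    ds = weightedDS(windows, dsGenes),
    recRate = as.numeric(rec[ids]),
    chromLength = as.numeric(
      chromSizes[as.character(GenomicRanges::seqnames(windows))]),
    row.names = NULL)
  transformPredictors(tab)
}
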