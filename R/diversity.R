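# Coverage-filtered per-window nucleotide diversity.
#
# The estimator is the standard windowed pi: for each variable site passing
# the coverage filter, the unbiased per-site heterozygosity
# 2*p*(1-p) * n/(n-1) (p = alternate-allele frequency among the n called
# copies), summed over variable sites and divided by the number of qualifying
# sites (all sites passing coverage, monomorphic included). It equals the
# mean pairwise difference per site over all haplotype pairs and is therefore
# free of phasing.

#' Does a site pass the per-population coverage filter?
#'
#' A site qualifies when every individual in the population has read depth at
#' least `minDp` (inclusive).
#'
#' @param depths per-sample read depths at the site.
#' @param minDp minimum depth (default 4).
#' @return logical scalar. `NA` depths fail the filter.
#' @export
sitePassesCoverage <- function(depths, minDp = 4) {
  if (!length(depths)) stop("empty depth vector", call. = FALSE)
  depths[is.na(depths)] <- -1
  all(depths >= minDp)
}

#' Per-window nucleotide diversity from site allele counts
#'
#' @param altCopies alternate-allele copies at each coverage-passing site.
#' @param nCalled called allele copies at each site (per-site, may vary with
#'   missing genotypes).
#' @param nQualifyingSites total sites passing coverage in the window
#'   (variable plus monomorphic); the denominator of pi.
#' @param unbiased apply the n/(n-1) sample-size correction (default TRUE).
#' @return list with `pi` (per-site; `NA` when `nQualifyingSites` is 0, never
#'   0 in that case), `nQualifyingSites`, `nVariableSites`.
#' @export
windowPi <- function(altCopies, nCalled, nQualifyingSites, unbiased = TRUE) {
  stopifnot(length(altCopies) == length(nCalled))
  if (any(nCalled < altCopies)) stop("altCopies exceeds nCalled", call. = FALSE)
  variable <- altCopies > 0L & altCopies < nCalled
  nVar <- sum(variable)
  if (nQualifyingSites <= 0)
    return(list(pi = NA_real_, nQualifyingSites = 0L, nVariableSites = nVar))
  num <- 0
  if (nVar) {
    n <- nCalled[variable]
    if (any(n < 2L)) stop("variable site with fewer than 2 called copies",
                          call. = FALSE)
    p <- altCopies[variable] / n
    corr <- if (unbiased) n / (n - 1) else 1
    num <- sum(2 * p * (1 - p) * corr)
  }
  list(pi = num / nQualifyingSites,
       nQualifyingSites = as.integer(nQualifyingSites),
       nVariableSites = as.integer(nVar))
}

#' Windowed diversity for one population from a site table
#'
#' Vectorised engine behind [diversityFromVcf()]: assigns sites to windows,
#' applies the coverage filter and optional mask, and computes per-window pi
#' with qualifying-site bookkeeping.
#'
#' The qualifying-site denominator per window is
#' `accessible - maskedBases - nVariableFailingCoverage`: `accessible` is the
#' externally supplied count of coverage-accessible sites (all-sites notion),
#' masked bases are removed from it, and variant records that fail the
#' coverage filter are subtracted since they were counted as accessible.
#'
#' @param sites data.frame as in the `sites` element of [readSites()]
#'   (columns `chrom`, `pos`, `altCopies`, `nCalled`, `minDepth`).
#' @param windows `GRanges` with a `windowId` metadata column.
#' @param accessible named numeric vector of accessible-site counts, indexed
#'   by window id. Defaults to the window widths.
#' @param minDp coverage threshold (default 4).
#' @param mask optional `GRanges`; sites inside it are excluded and its
#'   per-window base count is removed from the denominator.
#' @param unbiased see [windowPi()].
#' @return a data.frame: `windowId`, `pi`, `nQualifyingSites`,
#'   `nVariableSites`. `pi` is `NA` where no site qualifies.
#' @export
diversityFromSites <- function(sites, windows, accessible = NULL,
                               minDp = 4, mask = NULL, unbiased = TRUE) {
  ids <- S4Vectors::mcols(windows)$windowId
  if (is.null(ids)) stop("windows must carry a windowId column", call. = FALSE)
  if (is.null(accessible))
    accessible <- stats::setNames(as.numeric(IRanges::width(windows)), ids)
  acc <- as.numeric(accessible[ids])
  if (anyNA(acc))
    stop("accessible-site counts missing for some windows", call. = FALSE)

  maskedBases <- numeric(length(windows))
  if (!is.null(mask) && length(mask)) {
    mask <- GenomicRanges::reduce(mask)
    maskedBases <- .overlapBases(windows, mask)
  }

  n <- nrow(sites)
  win <- rep(NA_integer_, n)
  if (n) {
    if (!is.null(sites$windowId) && is.null(mask)) {
      # pre-assigned sites (e.g. from the in-memory generator)
      win <- match(sites$windowId, ids)
    } else {
      gr <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos, sites$pos))
      win <- GenomicRanges::findOverlaps(gr, windows, select = "first")
      if (!is.null(mask) && length(mask)) {
        inMask <- IRanges::overlapsAny(gr, mask)
        win[inMask] <- NA_integer_  # masked sites leave the stream entirely
      }
    }
  }

  nw <- length(windows)
  num <- numeric(nw)
  failVar <- integer(nw)
  nVar <- integer(nw)
  if (n) {
    dt <- data.table::data.table(win = win, altc = sites$altCopies,
                                 ncal = sites$nCalled,
                                 mdp = sites$minDepth)
    dt <- dt[!is.na(win)]
    dt[, pass := mdp >= minDp & ncal >= 2L]
    dt[, variable := pass & altc > 0L & altc < ncal]
    agg <- dt[, list(
      num = {
        v <- variable
        p <- altc[v] / ncal[v]
        sum(2 * p * (1 - p) * (if (unbiased) ncal[v] / (ncal[v] - 1) else 1))
      },
      fail = sum(!pass),
      nvar = sum(variable)), by = "win"]
    num[agg$win] <- agg$num
    failVar[agg$win] <- agg$fail
    nVar[agg$win] <- agg$nvar
  }

  qual <- pmax(acc - maskedBases - failVar, 0)
  data.frame(windowId = ids,
             pi = ifelse(qual > 0, num / qual, NA_real_),
             nQualifyingSites = as.integer(round(qual)),
             nVariableSites = nVar,
             row.names = NULL)
}

#' Windowed diversity for one population from a VCF
#'
#' @param vcfPath population VCF with per-sample GT and DP.
#' @param windows `GRanges` with `windowId` (reference windows for the focal
#'   species, or lifted spans for the other species).
#' @param accessible,minDp,mask,unbiased see [diversityFromSites()].
#' @return a data.frame as in [diversityFromSites()] plus skip counters as
#'   attributes `nMultiallelicSkipped` and `nIndelSkipped`.
#' @export
diversityFromVcf <- function(vcfPath, windows, accessible = NULL,
                             minDp = 4, mask = NULL, unbiased = TRUE) {
  rs <- readSites(vcfPath)
  out <- diversityFromSites(rs$sites, windows, accessible = accessible,
                            minDp = minDp, mask = mask, unbiased = unbiased)
  attr(out, "nMultiallelicSkipped") <- rs$nMultiallelicSkipped
  attr(out, "nIndelSkipped") <- rs$nIndelSkipped
  out
}

#' Window-level QC and the species average of two population estimates
#'
#' Drops windows with fewer than `minSites` qualifying sites in either
#' population, averages the two population pi values, and flags outlier
#' windows whose species pi exceeds `Q3 + outlierK * IQR` of the kept
#' distribution. Outliers are flagged but kept unless `removeOutliers = TRUE`
#' (removal mirrors an ad hoc manual exclusion and therefore requires an
#' explicit opt-in).
#'
#' @param div long data.frame with columns `windowId`, `pop`, `pi`,
#'   `nQualifyingSites`, exactly two populations.
#' @param minSites qualifying-site threshold (default 10 000; "fewer than" is
#'   strict, so a window with exactly `minSites` is kept).
#' @param outlierK IQR multiplier for the outlier bound (default 10).
#' @param removeOutliers drop flagged windows (default FALSE).
#' @return a data.frame: `windowId`, `piSpecies`, `qcVerdict` (`kept`,
#'   `dropped_low_sites`, `dropped_outlier`), `outlier` (logical),
#'   `minQualifyingSites`.
#' @export
applyWindowQC <- function(div, minSites = 10000, outlierK = 10,
                          removeOutliers = FALSE) {
  pops <- unique(div$pop)
  if (length(pops) != 2L)
    stop("expected exactly two populations, got ",
         paste(pops, collapse = ", "), call. = FALSE)
  a <- div[div$pop == pops[1L], ]
  b <- div[div$pop == pops[2L], ]
  m <- match(a$windowId, b$windowId)
  if (anyNA(m)) stop("populations cover different window sets", call. = FALSE)
  b <- b[m, ]
  minQual <- pmin(a$nQualifyingSites, b$nQualifyingSites)
  low <- minQual < minSites | is.na(a$pi) | is.na(b$pi)
  piSpecies <- (a$pi + b$pi) / 2
  verdict <- ifelse(low, "dropped_low_sites", "kept")

  outlier <- rep(FALSE, nrow(a))
  keptPi <- piSpecies[!low]
  if (length(keptPi) >= 4L) {
    q <- stats::quantile(keptPi, c(0.25, 0.75), names = FALSE)
    bound <- q[2] + outlierK * (q[2] - q[1])
    outlier <- !low & piSpecies > bound
    if (removeOutliers) verdict[outlier] <- "dropped_outlier"
  }
  data.frame(windowId = a$windowId,
             piSpecies = piSpecies,
             qcVerdict = verdict,
             outlier = outlier,
             minQualifyingSites = minQual,
             row.names = NULL)
}
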