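# Readers for the external formats around the pipeline: VCF site streams,
# chromosome sizes, and strict keyed covariate TSVs. GFF3 and BED go through
# rtracklayer at the call sites that need them.

# genotype strings -> per-site alternate-allele copies and called copies.
# Handles unphased/phased diploid calls; anything containing '.' is missing.
.gtToCounts <- function(gt) {
  u <- unique(as.vector(gt))
  alt <- integer(length(u)); called <- integer(length(u))
  for (i in seq_along(u)) {
    g <- u[i]
    if (is.na(g) || grepl("\\.", g)) { alt[i] <- 0L; called[i] <- 0L; next }
    al <- strsplit(g, "[/|]")[[1]]
    called[i] <- length(al)
    alt[i] <- sum(al == "1")
    if (any(!al %in% c("0", "1")))
      stop("non bi-allelic genotype '", g, "' after filtering", call. = FALSE)
  }
  m <- match(as.vector(gt), u)
  list(alt = matrix(alt[m], nrow = nrow(gt)),
       called = matrix(called[m], nrow = nrow(gt)))
}

#' Read bi-allelic SNP site records from a VCF
#'
#' Loads per-sample genotypes and read depths for one population's VCF and
#' reduces them to the per-site quantities the diversity estimator needs:
#' alternate-allele copies among called copies, number of called copies, and
#' the minimum per-sample depth (the coverage filter requires every sample to
#' reach the threshold, so the minimum is sufficient). Multi-allelic records
#' and indels are excluded and counted; monomorphic records (ALT = ".") are
#' kept with zero alternate copies so all-sites VCFs can be used for the
#' qualifying-site denominator.
#'
#' VCF positions are 1-based; a `region` given as a `GRanges` restricts the
#' stream to records inside it.
#'
#' @param vcfPath path to a VCF (plain or bgzipped).
#' @param region optional `GRanges` restricting the records returned.
#' @param keepDepths keep the full per-sample depth matrix in the result
#'   (default FALSE; the `minDepth` column is always present).
#' @return a list with elements `sites` (data.frame: `chrom`, `pos`, `ref`,
#'   `alt`, `altCopies`, `nCalled`, `minDepth`, `isVariant`), `nSamples`,
#'   `nMultiallelicSkipped`, `nIndelSkipped`, and (optionally) `depths`.
#' @export
readSites <- function(vcfPath, region = NULL, keepDepths = FALSE) {
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos)) stop("non-numeric POS in ", vcfPath, call. = FALSE)
  for (cc in unique(chrom)) {
    if (is.unsorted(pos[chrom == cc]))
      stop("VCF ", vcfPath, " is not sorted by position within ", cc,
           call. = FALSE)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."

  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L |
                       (alt != "." & nchar(alt) != 1L) | alt == "*")
  keep <- !multi & !indel

  if (!is.null(region)) {
    stopifnot(is(region, "GRanges"))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    keep <- keep & IRanges::overlapsAny(gr, region)
  }

  fmt <- v@gt[, 1]
  if (!any(grepl("\\bDP\\b", fmt)))
    stop("VCF ", vcfPath, " has no per-sample DP field; a per-sample read ",
         "depth (FORMAT field DP) is required for the coverage filter",
         call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  dp[is.na(dp)] <- 0
  nSamples <- ncol(gt)

  gt <- gt[keep, , drop = FALSE]
  dp <- dp[keep, , drop = FALSE]
  counts <- .gtToCounts(gt)
  minDepth <- if (nrow(dp)) do.call(pmin, as.data.frame(dp)) else numeric(0)

  sites <- data.frame(
    chrom = chrom[keep], pos = pos[keep],
    ref = ref[keep], alt = alt[keep],
    altCopies = as.integer(rowSums(counts$alt)),
    nCalled = as.integer(rowSums(counts$called)),
    minDepth = as.numeric(minDepth),
    isVariant = alt[keep] != ".",
    row.names = NULL)
  out <- list(sites = sites, nSamples = nSamples,
              nMultiallelicSkipped = sum(multi),
              nIndelSkipped = sum(indel))
  if (keepDepths) out$depths <- dp
  out
}

#' Read a two-column chromosome-sizes TSV
#'
#' @param path TSV with columns name, length (no header).
#' @return a named integer vector of sequence lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome in ", path,
                                    call. = FALSE)
  stats::setNames(df$size, df$chrom)
}

#' Read a keyed covariate TSV
#'
#' Strictly validated reader for per-window (or per-gene) covariate tables:
#' the named key and value columns must exist, duplicate keys are an error,
#' and literal `NA` values propagate as missing (never as 0).
#'
#' @param path TSV path (header row required).
#' @param keyColumn name of the key column.
#' @param valueColumn name of the numeric value column.
#' @return a named numeric vector, `NA` for missing values.
#' @export
readCovariateTsv <- function(path, keyColumn, valueColumn) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(keyColumn, valueColumn)) {
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")",
           call. = FALSE)
  }
  if (anyDuplicated(df[[keyColumn]]))
    stop("duplicated key(s) in ", path, ": ",
         paste(unique(df[[keyColumn]][duplicated(df[[keyColumn]])]),
               collapse = ", "), call. = FALSE)
  stats::setNames(as.numeric(df[[valueColumn]]), df[[keyColumn]])
}
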