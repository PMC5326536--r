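# End-to-end orchestration: synteny -> diversity (with and without CDS
# masking) -> shared polymorphism -> covariates -> correlation/regression/PCR.
# Stages communicate through files and plain tables so each is independently
# testable; any stage failure aborts naming the stage.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full cross-species diversity pipeline
#'
#' @param inputs named list of input paths: `chain`, `aSizes`, `bSizes`,
#'   `vcfA` (character vector, one per population), `vcfB`, `genesA`,
#'   `genesB`, `repeatsA`, `rec`, `gc`, `ds`, `accessible` (TSV with columns
#'   `window_id`, `accessible_a`, `accessible_b`). This is the file set
#'   written by [simulateDataset()]; real data in the same formats work
#'   identically.
#' @param windowSize,minRemap,minLen,maxLen synteny thresholds (defaults:
#'   200 kb windows, remap > 0.80, span within 180-220 kb).
#' @param minDp,minSites diversity thresholds (defaults: depth >= 4 in every
#'   individual, >= 10 000 qualifying sites).
#' @param removeOutliers drop flagged outlier windows (default FALSE).
#' @param outDir optional directory for per-stage TSVs and a JSON summary.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents the provenance of simulated inputs).
#' @return a list with elements `map` ([SyntenyMap]), `diversity` (merged
#'   per-window species table), `sharedPoly` ([SharedPolyReport] list:
#'   coverage-filtered and unfiltered), `covariates`, `models` (correlations,
#'   OLS fits, PCR, decile fits) and `summary` (flat named list of headline
#'   numbers).
#' @export
runPipeline <- function(inputs,
                        windowSize = 200000L, minRemap = 0.80,
                        minLen = 180000L, maxLen = 220000L,
                        minDp = 4, minSites = 10000,
                        removeOutliers = FALSE,
                        outDir = NULL, seed = NA_integer_) {
  need <- c("chain", "aSizes", "vcfA", "vcfB", "genesA", "genesB",
            "repeatsA", "rec", "gc", "ds", "accessible")
  for (nm in need) {
    if (is.null(inputs[[nm]]))
      stop("pipeline input '", nm, "' is missing", call. = FALSE)
    for (f in inputs[[nm]]) if (!file.exists(f))
      stop("pipeline input '", nm, "' not found: ", f, call. = FALSE)
  }

  chains <- .stage("synteny", readChainFile(inputs$chain))
  map <- .stage("synteny", {
    aSizes <- readChromSizes(inputs$aSizes)
    windows <- tileWindows(aSizes, windowSize)
    buildWindowMap(windows, chains, minRemap = minRemap,
                   minLen = minLen, maxLen = maxLen)
  })
  winA <- refWindows(map)
  retained <- S4Vectors::mcols(winA)$verdict == "retained"
  winAr <- winA[retained]
  spansB <- liftedSpans(map)

  acc <- .stage("diversity", {
    accA <- readCovariateTsv(inputs$accessible, "window_id", "accessible_a")
    accB <- readCovariateTsv(inputs$accessible, "window_id", "accessible_b")
    list(a = accA, b = accB)
  })

  gffA <- .stage("covariates", rtracklayer::import(inputs$genesA))
  gffB <- .stage("covariates", rtracklayer::import(inputs$genesB))
  cdsMaskA <- gffA[as.character(S4Vectors::mcols(gffA)$type) == "CDS"]
  cdsMaskB <- gffB[as.character(S4Vectors::mcols(gffB)$type) == "CDS"]

  siteTabs <- .stage("diversity", {
    list(A = lapply(inputs$vcfA, function(p) readSites(p)$sites),
         B = lapply(inputs$vcfB, function(p) readSites(p)$sites))
  })

  runSpecies <- function(tabs, windows, accv, mask) {
    div <- do.call(rbind, lapply(seq_along(tabs), function(p) {
      d <- diversityFromSites(tabs[[p]], windows, accessible = accv,
                              minDp = minDp, mask = mask)
      d$pop <- sprintf("pop%d", p)
      d
    }))
    applyWindowQC(div, minSites = minSites, removeOutliers = removeOutliers)
  }

  div <- .stage("diversity", {
    sppA <- runSpecies(siteTabs$A, winAr, acc$a, mask = NULL)
    sppB <- runSpecies(siteTabs$B, spansB, acc$b, mask = NULL)
    sppAm <- runSpecies(siteTabs$A, winAr, acc$a, mask = cdsMaskA)
    sppBm <- runSpecies(siteTabs$B, spansB, acc$b, mask = cdsMaskB)
    m <- match(sppA$windowId, sppB$windowId)
    data.frame(windowId = sppA$windowId,
               piA = sppA$piSpecies, piB = sppB$piSpecies[m],
               qcA = sppA$qcVerdict, qcB = sppB$qcVerdict[m],
               piAMasked = sppAm$piSpecies,
               piBMasked = sppBm$piSpecies[m],
               kept = sppA$qcVerdict == "kept" & sppB$qcVerdict[m] == "kept",
               row.names = NULL)
  })

  shared <- .stage("shared_poly", {
    sitesA <- .variableSiteTable(siteTabs$A, minDp = minDp)
    sitesB <- .variableSiteTable(siteTabs$B, minDp = minDp)
    sitesAu <- .variableSiteTable(siteTabs$A, applyCoverage = FALSE)
    sitesBu <- .variableSiteTable(siteTabs$B, applyCoverage = FALSE)
    list(filtered = auditSharedPolymorphism(sitesA, sitesB, chains),
         unfiltered = auditSharedPolymorphism(sitesAu, sitesBu, chains))
  })

  covar <- .stage("covariates", {
    aSizes <- readChromSizes(inputs$aSizes)
    gc <- readCovariateTsv(inputs$gc, "window_id", "gc")
    rec <- readCovariateTsv(inputs$rec, "window_id", "rec")
    dsDf <- utils::read.table(inputs$ds, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    dsGenes <- GenomicRanges::GRanges(
      dsDf$chrom, IRanges::IRanges(dsDf$start + 1L, dsDf$end),
      ds = dsDf$ds)
    repeats <- rtracklayer::import(inputs$repeatsA)
    buildCovariateTable(winAr, gffA, repeats, gc, dsGenes, rec, aSizes)
  })

  models <- .stage("regress", {
    kept <- div$kept
    d <- div[kept, ]
    cv <- covar[match(d$windowId, covar$windowId), ]
    rhoAll <- spearmanCor(d$piA, d$piB)
    rhoMasked <- spearmanCor(d$piAMasked, d$piBMasked)
    table1 <- chromosomeCovariateModel(d$piB, d$piA, cv$chromLength)
    X5 <- data.frame(recRate = cv$recRateT, cdsDensity = cv$cdsDensityT,
                     ds = cv$dsT, gc = cv$gc,
                     repeatDensity = cv$repeatDensity)
    table2 <- olsFit(d$piA, X5, label = "five-predictor model")
    pcr <- pcRegression(d$piA, X5)
    deciles <- list(
      cdsHigh = decileRegression(d$piA, cv$recRateT, cv$cdsDensityT, "highest"),
      cdsLow = decileRegression(d$piA, cv$recRateT, cv$cdsDensityT, "lowest"),
      gcHigh = decileRegression(d$piA, cv$recRateT, cv$gc, "highest"),
      gcLow = decileRegression(d$piA, cv$recRateT, cv$gc, "lowest"))
    list(rhoAll = rhoAll, rhoMasked = rhoMasked, table1 = table1,
         table2 = table2, pcr = pcr, deciles = deciles)
  })

  summary <- list(
    nWindows = length(winA),
    nRetained = sum(retained),
    retainedFraction = mean(retained),
    nAnalysed = sum(div$kept),
    piMeanA = mean(div$piA[div$kept]),
    piMeanB = mean(div$piB[div$kept]),
    rho = models$rhoAll$rho,
    rhoMasked = models$rhoMasked$rho,
    sharedPolyFraction = shared$filtered@fraction,
    sharedPolyNumerator = shared$filtered@nAlsoVariableB,
    sharedPolyDenominator = shared$filtered@nAlignableVariableA,
    table1R2 = models$table1@r2,
    table2R2 = models$table2@r2,
    pcrR2PerPC = models$pcr@r2PerPC,
    manifest = list(package = "syntpi",
                    version = as.character(utils::packageVersion("syntpi")),
                    seed = seed,
                    thresholds = list(windowSize = windowSize,
                                      minRemap = minRemap, minLen = minLen,
                                      maxLen = maxLen, minDp = minDp,
                                      minSites = minSites)))

  res <- list(map = map, diversity = div, sharedPoly = shared,
              covariates = covar, models = models, summary = summary)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeWindowMap(map, file.path(outDir, "windows.tsv"))
    utils::write.table(div, file.path(outDir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(covar, file.path(outDir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
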