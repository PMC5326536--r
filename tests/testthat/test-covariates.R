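# Per-window covariates and transforms.

.win200k <- function() {
  w <- gr("chr1", 1, 200000)
  S4Vectors::mcols(w)$windowId <- "w1"
  w
}

test_that("CDS density is union coverage over the window", {
  w <- .win200k()
  expect_equal(cdsDensity(w, GenomicRanges::GRanges()), 0)

  # two overlapping CDS merging to 4000 bp -> 0.02
  cds <- gr("chr1", c(1001, 3001), c(4000, 5000), type = "CDS")
  expect_equal(cdsDensity(w, cds), 0.02)

  tile <- gr("chr1", 1, 200000, type = "CDS")
  expect_equal(cdsDensity(w, tile), 1)

  # clipping: features hanging over the window edge stay bounded
  over <- gr("chr1", 199001, 300000, type = "CDS")
  expect_equal(cdsDensity(w, over), 1000 / 200000)
})

test_that("repeat density is bounded for any interval input", {
  set.seed(6)
  w <- .win200k()
  st <- sample.int(400000, 50)
  rep <- gr("chr1", st, st + sample.int(5000, 50))
  d <- repeatDensity(w, rep)
  expect_gte(d, 0); expect_lte(d, 1)
})

test_that("intergenic GC is computed over non-genic non-N bases", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("GCGCATAT", 25)))
  w <- gr("chr1", 1, 200)
  S4Vectors::mcols(w)$windowId <- "w1"
  empty <- GenomicRanges::GRanges()
  expect_equal(windowedGC(w, seqs, empty, minBases = 10), 0.5)

  at <- Biostrings::DNAStringSet(c(chr1 = strrep("ATTA", 50)))
  expect_equal(windowedGC(w, at, empty, minBases = 10), 0)

  # fully genic window -> missing
  gene <- gr("chr1", 1, 200, type = "gene")
  expect_true(is.na(windowedGC(w, seqs, gene, minBases = 10)))

  # Ns are excluded from the denominator
  withN <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("N", 100),
                                                    strrep("GC", 50))))
  expect_equal(windowedGC(w, withN, empty, minBases = 10), 1)
})

test_that("weighted dS applies exclusions and the window ceiling", {
  w <- .win200k()
  g <- gr("chr1", c(1001, 5001), c(1300, 5900))  # lengths 300 and 900
  S4Vectors::mcols(g)$ds <- c(0.1, 0.2)
  expect_equal(weightedDS(w, g), (300 * 0.1 + 900 * 0.2) / 1200)

  gz <- gr("chr1", 1001, 1300, ds = 0)
  expect_true(is.na(weightedDS(w, gz)))          # dS = 0 excluded

  gs <- gr("chr1", 1001, 1300, ds = 2.5)
  expect_true(is.na(weightedDS(w, gs)))          # dS > 2 excluded

  gh <- gr("chr1", c(1001, 5001), c(1300, 5300), ds = c(0.35, 0.35))
  expect_true(is.na(weightedDS(w, gh)))          # window mean above 0.3

  gneg <- gr("chr1", 1001, 1300, ds = -0.1)
  expect_error(weightedDS(w, gneg), "negative")
})

test_that("weighted dS is invariant to splitting a gene", {
  w <- .win200k()
  whole <- gr("chr1", c(1001, 9001), c(2000, 9900), ds = c(0.12, 0.3))
  split <- gr("chr1", c(1001, 1501, 9001), c(1500, 2000, 9900),
              ds = c(0.12, 0.12, 0.3))
  expect_equal(weightedDS(w, whole), weightedDS(w, split), tolerance = 1e-12)
})

test_that("transforms are the documented maps and preserve rank order", {
  tab <- data.frame(cdsDensity = c(0.04, 0.01), ds = c(0.25, 0.09),
                    recRate = c(0, 9))
  tt <- transformPredictors(tab)
  expect_equal(tt$cdsDensityT, c(0.2, 0.1))
  expect_equal(tt$dsT, c(0.5, 0.3))
  expect_equal(tt$recRateT, c(0, 1))

  set.seed(2)
  x <- data.frame(cdsDensity = runif(50), ds = runif(50, 0, 2),
                  recRate = rexp(50, 1 / 3))
  tx <- transformPredictors(x)
  expect_equal(order(tx$cdsDensityT), order(x$cdsDensity))
  expect_equal(order(tx$dsT), order(x$ds))
  expect_equal(order(tx$recRateT), order(x$recRate))

  # missing propagates
  expect_true(is.na(transformPredictors(
    data.frame(cdsDensity = 0.1, ds = NA_real_, recRate = 1))$dsT))
})

test_that("the assembled covariate table has bounded densities", {
  cfg <- simulationConfig(seed = 21, chromLengths = c(3e6, 2e6))
  sim <- simulateDataset(cfg, dir = tempfile("covsim"))
  win <- tileWindows(readChromSizes(sim$files$aSizes), cfg$windowSize)
  map <- buildWindowMap(win, sim$chains)
  winAr <- refWindows(map)[S4Vectors::mcols(refWindows(map))$verdict ==
                             "retained"]
  tab <- buildCovariateTable(
    winAr,
    rtracklayer::import(sim$files$genesA),
    rtracklayer::import(sim$files$repeatsA),
    readCovariateTsv(sim$files$gc, "window_id", "gc"),
    local({
      d <- read.delim(sim$files$ds)
      GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                             ds = d$ds)
    }),
    readCovariateTsv(sim$files$rec, "window_id", "rec"),
    readChromSizes(sim$files$aSizes))
  expect_true(all(tab$cdsDensity >= 0 & tab$cdsDensity <= 1))
  expect_true(all(tab$repeatDensity >= 0 & tab$repeatDensity <= 1))
  expect_true(all(tab$gc >= 0 & tab$gc <= 1, na.rm = TRUE))
  # generator truth: realised CDS density matches the drawn landscape
  m <- match(tab$windowId, sim$truth$windowId)
  expect_lt(max(abs(tab$cdsDensity - sim$truth$cdsA[m])), 1e-4)
  expect_equal(tab$recRate, sim$truth$recA[m], tolerance = 1e-6)
})
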