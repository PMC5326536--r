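# Window tiling, lift-over and retention filters.

test_that("tileWindows tiles chromosomes with partial-window flags", {
  w <- tileWindows(c(chr1 = 1000000L), 200000L)
  expect_length(w, 5)
  expect_false(any(S4Vectors::mcols(w)$partial))

  w2 <- tileWindows(c(chr1 = 450000L), 200000L)
  expect_length(w2, 3)
  expect_equal(IRanges::width(w2), c(200000L, 200000L, 50000L))
  expect_equal(S4Vectors::mcols(w2)$partial, c(FALSE, FALSE, TRUE))

  expect_error(tileWindows(c(chr1 = 1000L), 0), "positive")
  expect_error(tileWindows(integer(0)), "empty")
})

test_that("liftInterval maps an interval inside one identity block", {
  ch <- chainFromText(c("chain 10 chr1 500000 + 0 400000 t1 500000 + 50000 450000 1",
                        "400000"))
  hit <- liftInterval(gr("chr1", 1001, 3000), ch)
  expect_length(hit, 1)
  expect_equal(S4Vectors::mcols(hit)$liftedBases, 2000L)
  expect_equal(GenomicRanges::start(hit), 51001L)
  expect_equal(GenomicRanges::end(hit), 53000L)
})

test_that("a reference-side deletion removes bases but keeps one run", {
  # 200 kb window over a chain with a 10 kb dt gap: 190 kb lift, 190 kb span
  ch <- chainFromText(c("chain 10 chr1 500000 + 0 200000 t1 500000 + 0 190000 1",
                        "100000 10000 0", "90000"))
  hit <- liftInterval(gr("chr1", 1, 200000), ch)
  expect_length(hit, 1)
  expect_equal(S4Vectors::mcols(hit)$liftedBases, 190000L)
  expect_equal(IRanges::width(hit), 190000L)
  # brute-force check on a scaled-down copy of the same structure
  ch2 <- chainFromText(c("chain 10 chr1 5000 + 0 2000 t1 5000 + 0 1900 1",
                         "1000 100 0", "900"))
  bf <- bruteLiftInterval(ch2, "chr1", 0L, 2000L)
  expect_equal(bf$count, 1900L)
  expect_equal(bf$tEnd0 - bf$tStart0, 1900L)
})

test_that("an interval spanning chains on two target chromosomes gives two runs", {
  chains <- c(
    chainFromText(c("chain 10 chr1 10000 + 0 1000 t1 10000 + 0 1000 1", "1000")),
    chainFromText(c("chain 9 chr1 10000 + 1000 2000 t2 10000 + 0 1000 2", "1000")))
  hit <- liftInterval(gr("chr1", 1, 2000), chains)
  expect_length(hit, 2)
  expect_setequal(as.character(GenomicRanges::seqnames(hit)), c("t1", "t2"))
})

test_that("lift runs agree exactly with per-base brute force on random chains", {
  set.seed(99)
  for (rep in 1:6) {
    chains <- makeRandomChains(6)
    for (i in 1:10) {
      s0 <- sample.int(9000, 1) - 1L
      e0 <- s0 + sample.int(1000, 1)
      chrom <- sample(c("chr1", "chr2"), 1)
      mine <- liftInterval(gr(chrom, s0 + 1L, e0), chains)
      bf <- bruteLiftInterval(chains, chrom, s0, e0)
      expect_equal(length(mine), nrow(bf))
      if (nrow(bf)) {
        expect_equal(S4Vectors::mcols(mine)$liftedBases, bf$count)
        expect_equal(as.character(GenomicRanges::seqnames(mine)), bf$tChrom)
        expect_equal(GenomicRanges::start(mine), bf$tStart0 + 1L)
        expect_equal(GenomicRanges::end(mine), bf$tEnd0)
      }
    }
  }
})

.oneWindowMap <- function(chains, W = 200000L, ...) {
  win <- tileWindows(c(chr1 = W), W)
  buildWindowMap(win, chains, ...)
}

test_that("retention verdicts follow the remap and size rules", {
  # remap 1.0, span 200 kb -> retained
  ident <- chainFromText(c("chain 10 chr1 200000 + 0 200000 t1 300000 + 0 200000 1",
                           "200000"))
  expect_equal(unname(verdicts(.oneWindowMap(ident))), "retained")

  # remap exactly 0.80 is NOT retained ("more than 80%" is strict)
  m80 <- chainFromText(c("chain 10 chr1 200000 + 0 160000 t1 300000 + 0 160000 1",
                         "160000"))
  expect_equal(unname(verdicts(.oneWindowMap(m80))), "rejected_low_remap")

  # remap 0.85 with span 190 kb -> retained
  m85 <- chainFromText(c("chain 10 chr1 200000 + 0 180000 t1 300000 + 0 190000 1",
                         "85000 10000 20000", "85000"))
  expect_equal(unname(verdicts(.oneWindowMap(m85))), "retained")

  # remap 0.95 but target span inflated to 230 kb -> rejected_size
  infl <- chainFromText(c("chain 10 chr1 200000 + 0 190000 t1 300000 + 0 230000 1",
                          "95000 0 40000", "95000"))
  expect_equal(unname(verdicts(.oneWindowMap(infl))), "rejected_size")

  # two half-window runs on different chromosomes -> rejected_split
  spl <- c(
    chainFromText(c("chain 10 chr1 200000 + 0 100000 t1 300000 + 0 100000 1",
                    "100000")),
    chainFromText(c("chain 9 chr1 200000 + 100000 200000 t2 300000 + 0 100000 2",
                    "100000")))
  expect_equal(unname(verdicts(.oneWindowMap(spl))), "rejected_split")

  # no chain at all -> unmapped
  off <- chainFromText(c("chain 10 chr9 200000 + 0 1000 t1 300000 + 0 1000 1",
                         "1000"))
  expect_equal(unname(verdicts(.oneWindowMap(off))), "unmapped")
})

test_that("tightening thresholds never increases the retained count", {
  cfg <- simulationConfig(seed = 5, chromLengths = c(6e6, 4e6),
                          rearrangementRate = 0.2, smallIndelRate = 0.6)
  sim <- simulateDataset(cfg, annotations = FALSE, positions = FALSE)
  win <- tileWindows(stats::setNames(cfg$chromLengths, c("chrA1", "chrA2")),
                     cfg$windowSize)
  nRet <- function(...) sum(verdicts(buildWindowMap(win, sim$chains, ...)) ==
                              "retained")
  base <- nRet()
  expect_lte(nRet(minRemap = 0.9), base)
  expect_lte(nRet(minLen = 195000L, maxLen = 205000L), base)
  expect_lte(nRet(minRemap = 0.99, minLen = 199000L, maxLen = 201000L),
             nRet(minRemap = 0.9))
})

test_that("a self-chain genome retains every full window with remap 1", {
  cfg <- simulationConfig(seed = 8, chromLengths = c(4e6, 2e6),
                          rearrangementRate = 0, smallIndelRate = 0,
                          lowSiteRate = 0)
  sim <- simulateDataset(cfg, annotations = FALSE, positions = FALSE)
  win <- tileWindows(stats::setNames(cfg$chromLengths, c("chrA1", "chrA2")),
                     cfg$windowSize)
  map <- buildWindowMap(win, sim$chains)
  mc <- S4Vectors::mcols(refWindows(map))
  expect_true(all(mc$verdict == "retained"))
  expect_true(all(mc$remapFraction == 1))
})

test_that("masks register per-window masked base counts on either side", {
  ident <- chainFromText(c("chain 10 chr1 200000 + 0 200000 t1 300000 + 0 200000 1",
                           "200000"))
  map <- .oneWindowMap(ident)
  m0 <- maskIntervals(map, GenomicRanges::GRanges(), "ref")
  expect_equal(S4Vectors::mcols(refWindows(m0))$refMaskedBases, 0L)

  # one 1000 bp exon -> exactly 1000 bases flagged
  m1 <- maskIntervals(map, gr("chr1", 5001, 6000), "ref")
  expect_equal(S4Vectors::mcols(refWindows(m1))$refMaskedBases, 1000L)

  m2 <- maskIntervals(map, gr("t1", 1, 200000), "target")
  expect_equal(S4Vectors::mcols(refWindows(m2))$targetMaskedBases, 200000L)
})
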