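# The generator: determinism, landscape sharing, expected-pi arithmetic,
# Watterson correspondence, truth bookkeeping.

test_that("identical seeds give identical datasets, files included", {
  cfg <- simulationConfig(seed = 33, chromLengths = c(2e6, 1e6))
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  s1 <- simulateDataset(cfg, dir = d1)
  s2 <- simulateDataset(cfg, dir = d2)
  expect_equal(s1$truth, s2$truth)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
  s3 <- simulateDataset(simulationConfig(seed = 34,
                                         chromLengths = c(2e6, 1e6)))
  expect_false(identical(s3$truth$expPiA, s1$truth$expPiA))
  expect_error(simulationConfig(), "seed")
})

test_that("the sharing coefficient tunes cross-species landscape similarity", {
  cfg1 <- simulationConfig(seed = 1, chromLengths = 6e8, share = 1)
  set.seed(cfg1$seed)
  l1 <- drawLandscapes(cfg1)
  expect_equal(rank(l1$recA), rank(l1$recB))
  expect_equal(rank(l1$cdsA), rank(l1$cdsB))

  cfg0 <- simulationConfig(seed = 2, chromLengths = 6e8, share = 0)
  set.seed(cfg0$seed)
  l0 <- drawLandscapes(cfg0)  # 3000 windows
  expect_lt(abs(cor(l0$recA, l0$recB, method = "spearman")), 0.1)
  expect_lt(abs(cor(l0$cdsA, l0$cdsB, method = "spearman")), 0.1)

  set.seed(cfg1$seed)
  expect_equal(drawLandscapes(cfg1), l1)  # bit-identical under the seed
})

test_that("the diversity-reduction factor follows the closed form", {
  cfg <- simulationConfig(seed = 3, chromLengths = 2e6, k = 2,
                          noiseSd = 0)
  land <- data.frame(chrom = "chrA1", start = 0, end = 2e5,
                     windowId = "w", recA = 0.9, recB = 0.9,
                     cdsA = 0.1, cdsB = 0, muScaleA = 1, muScaleB = 1,
                     gcA = 0.4, gcB = 0.4, repA = 0.1, repB = 0.1)
  ep <- expectedPi(cfg, land)
  expect_equal(ep$bA, exp(-0.2), tolerance = 1e-12)  # d/(r+eps) = 0.1
  expect_equal(ep$bB, 1)                             # no targets, no reduction
  expect_equal(ep$expPiA, 4 * cfg$neA * cfg$muA * exp(-0.2),
               tolerance = 1e-12)

  cfg0 <- simulationConfig(seed = 3, chromLengths = 2e6, k = 0, noiseSd = 0)
  ep0 <- expectedPi(cfg0, land)
  expect_equal(ep0$bA, 1)  # k = 0: expected pi tracks mutation input only
  expect_equal(ep0$expPiA, 4 * cfg0$neA * cfg0$muA)
})

test_that("realised window pi is unbiased for the designed expectation", {
  cfg <- simulationConfig(seed = 44, chromLengths = 2e6)
  set.seed(1)
  nRep <- 100
  win <- data.frame(chrom = "chrA1", start = (seq_len(nRep) - 1) * 2e5,
                    acc = 2e5, expPi = 0.004)
  em <- emitVariants(cfg, win, positions = FALSE)[[1]]$sites
  nHap <- 2 * cfg$samplesPerPop
  term <- with(em, {
    p <- altCopies / nCalled
    2 * p * (1 - p) * nCalled / (nCalled - 1)
  })
  piHat <- as.numeric(rowsum(term, em$win)) / 2e5
  se <- sd(piHat) / sqrt(nRep)
  expect_lt(abs(mean(piHat) - 0.004), 3 * se)

  # E[pi] = 0 emits nothing
  none <- emitVariants(cfg, transform(win, expPi = 0), positions = FALSE)
  expect_equal(nrow(none[[1]]$sites), 0)
})

test_that("depth draws pass the coverage filter at the designed rate", {
  cfg <- simulationConfig(seed = 45, chromLengths = 2e6)
  set.seed(2)
  win <- data.frame(chrom = "chrA1", start = 0, acc = 2e5, expPi = 0.01)
  em <- emitVariants(cfg, win, positions = FALSE)[[1]]$sites
  # Poisson(20) tail: P(all 15 individuals >= 4) > 99.9%
  expect_gt(mean(em$minDepth >= 4), 0.99)
  pTheory <- (1 - ppois(3, cfg$meanDepth))^cfg$samplesPerPop
  expect_lt(abs(mean(em$minDepth >= 4) - pTheory), 0.005)
})

test_that("per-sample VCF output reproduces the site allele counts", {
  cfg <- simulationConfig(seed = 46, chromLengths = 1e6)
  sim <- simulateDataset(cfg, dir = tempfile("vcfsim"))
  rs <- readSites(sim$files$vcfA1)
  # every record bi-allelic SNP, copies consistent with 15 diploids
  expect_true(all(rs$sites$nCalled == 30L))
  expect_true(all(rs$sites$altCopies >= 1 & rs$sites$altCopies <= 29))
  expect_equal(rs$nMultiallelicSkipped + rs$nIndelSkipped, 0)
  # neutral SFS: singletons are the modal class
  tab <- tabulate(rs$sites$altCopies, 29)
  expect_equal(which.max(tab), 1L)
})

test_that("truth flags map to the constructed chain defects", {
  cfg <- simulationConfig(seed = 47, chromLengths = c(4e6, 4e6),
                          rearrangementRate = 0.3, lowSiteRate = 0.1)
  sim <- simulateDataset(cfg, annotations = FALSE, positions = FALSE)
  truth <- sim$truth
  expect_true(all(table(truth$flag) > 0))  # all defect classes drawn
  map <- buildWindowMap(
    tileWindows(stats::setNames(cfg$chromLengths, c("chrA1", "chrA2")),
                cfg$windowSize),
    sim$chains)
  v <- verdicts(map)
  expect_equal(unname(v[truth$windowId]), truth$expectedVerdict)
  # low-site windows keep their synteny verdict but carry a small budget
  expect_true(all(truth$accA[truth$flag == "low_site"] < 10000))
  expect_true(all(truth$accA[truth$flag == "none"] == cfg$windowSize))
})
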