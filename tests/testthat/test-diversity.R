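# Windowed pi: estimator, coverage filter, QC.

test_that("the coverage filter requires every individual at the threshold", {
  expect_true(sitePassesCoverage(c(4, 4, 4)))       # inclusive "at least 4"
  expect_false(sitePassesCoverage(c(4, 3, 9)))
  expect_false(sitePassesCoverage(c(10, NA, 10)))
  expect_true(sitePassesCoverage(c(2, 2), minDp = 2))
  expect_error(sitePassesCoverage(numeric(0)), "empty")
})

test_that("windowPi matches hand-computed per-site heterozygosity", {
  # one site, p = 0.5 among n = 8 copies: 2*0.25*(8/7) = 4/7 per site
  r <- windowPi(4L, 8L, 1000L)
  expect_equal(r$pi, (4 / 7) / 1000, tolerance = 1e-12)
  # equals mean pairwise difference over all C(8,2)=28 haplotype pairs: 16/28
  expect_equal(4 / 7, 16 / 28)

  # no variable sites but qualifying sites -> exactly zero
  expect_equal(windowPi(integer(0), integer(0), 150000L)$pi, 0)
  # no qualifying sites -> missing, never zero
  expect_true(is.na(windowPi(integer(0), integer(0), 0L)$pi))
})

test_that("windowPi equals brute-force pair enumeration on small fixtures", {
  # spec-style fixture: allele counts 1/8, 4/8, 7/8 over 10 000 sites
  geno <- rbind(c(1, 2, 2), c(0, 1, 2), c(0, 1, 2), c(0, 0, 1))
  cnt <- genoToCounts(geno)
  expect_equal(cnt$altCopies, c(1L, 4L, 7L))
  r <- windowPi(cnt$altCopies, cnt$nCalled, 10000L)
  expect_equal(r$pi, brutePi(geno, 10000L), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    L <- sample(5:50, 1)
    geno <- randomGeno(m, L)
    cnt <- genoToCounts(geno)
    r <- windowPi(cnt$altCopies, cnt$nCalled, L)
    expect_equal(r$pi, brutePi(geno, L), tolerance = 1e-12)
  }
})

test_that("pi is free of phasing", {
  set.seed(13)
  for (i in 1:5) {
    geno <- randomGeno(sample(2:8, 1), sample(4:12, 1))
    L <- ncol(geno)
    ref <- brutePi(geno, L, phase = "ref_first")
    for (j in 1:4)
      expect_equal(brutePi(geno, L, phase = "random"), ref,
                   tolerance = 1e-12)
  }
})

.toyWindows <- function() {
  w <- gr("chr1", c(1, 101), c(100, 200))
  S4Vectors::mcols(w)$windowId <- c("w1", "w2")
  w
}

test_that("diversityFromSites books qualifying sites and masks correctly", {
  w <- .toyWindows()
  sites <- data.frame(chrom = "chr1", pos = c(10L, 50L, 150L, 160L),
                      altCopies = c(2L, 1L, 3L, 4L),
                      nCalled = 8L, minDepth = c(9, 2, 9, 9))
  d <- diversityFromSites(sites, w, minDp = 4)
  # w1: one passing variable site (2/8), one failing -> qual 99
  expect_equal(d$nQualifyingSites, c(99L, 100L))
  expect_equal(d$nVariableSites, c(1L, 2L))
  p <- 2 / 8
  expect_equal(d$pi[1], 2 * p * (1 - p) * (8 / 7) / 99, tolerance = 1e-12)

  # masking an interval with no variable sites: denominator shrinks,
  # numerator untouched
  dm <- diversityFromSites(sites, w, minDp = 4, mask = gr("chr1", 61, 80))
  expect_equal(dm$pi[1] * dm$nQualifyingSites[1],
               d$pi[1] * d$nQualifyingSites[1], tolerance = 1e-12)
  expect_equal(dm$nQualifyingSites[1], 79L)

  # masking the whole window removes all qualifying sites -> missing pi
  dall <- diversityFromSites(sites, w, minDp = 4, mask = gr("chr1", 1, 100))
  expect_equal(dall$nQualifyingSites[1], 0L)
  expect_true(is.na(dall$pi[1]))
})

test_that("window QC drops low-site windows and flags outliers", {
  div <- data.frame(
    windowId = rep(c("w1", "w2", "w3"), 2),
    pop = rep(c("p1", "p2"), each = 3),
    pi = c(0.004, 0.0041, 0.004, 0.0039, 0.0042, 0.004),
    nQualifyingSites = c(150000L, 9999L, 10000L, 150000L, 150000L, 12000L))
  qc <- applyWindowQC(div)
  expect_equal(qc$qcVerdict,
               c("kept", "dropped_low_sites", "kept"))  # 10 000 exactly kept
  expect_equal(qc$piSpecies[1], mean(c(0.004, 0.0039)))

  # an extreme window is flagged, and dropped only on request
  n <- 40
  div2 <- data.frame(
    windowId = rep(sprintf("w%02d", 1:n), 2),
    pop = rep(c("p1", "p2"), each = n),
    pi = rep(c(seq(0.001, 0.002, length.out = n - 1), 0.042), 2),
    nQualifyingSites = 150000L)
  qc2 <- applyWindowQC(div2)
  expect_true(qc2$outlier[n])
  expect_equal(qc2$qcVerdict[n], "kept")
  qc3 <- applyWindowQC(div2, removeOutliers = TRUE)
  expect_equal(qc3$qcVerdict[n], "dropped_outlier")
  expect_false(any(qc3$outlier[-n]))
})

test_that("population diversity is consistent between VCF and site paths", {
  set.seed(77)
  tf <- tempfile(fileext = ".vcf")
  pos <- sort(sample.int(200, 20))
  gt <- matrix(sample(c("0/0", "0/1", "1/1"), 60, replace = TRUE), 20, 3)
  dp <- matrix(sample(2:20, 60, replace = TRUE), 20, 3)
  writeVcfFixture(tf, rep("chr1", 20), pos, rep("A", 20), rep("G", 20),
                  gt, dp)
  w <- gr("chr1", 1, 200)
  S4Vectors::mcols(w)$windowId <- "w1"
  d <- diversityFromVcf(tf, w, accessible = c(w1 = 200))
  rs <- readSites(tf)
  d2 <- diversityFromSites(rs$sites, w, accessible = c(w1 = 200))
  expect_equal(d$pi, d2$pi)
  # cross-check against brute-force enumeration restricted to passing sites
  dosage <- matrix(c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt], 20, 3)
  pass <- apply(dp, 1, function(x) all(x >= 4))
  bf <- brutePi(t(dosage[pass, , drop = FALSE]), 200 - sum(!pass))
  expect_equal(d$pi, bf, tolerance = 1e-12)
})
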