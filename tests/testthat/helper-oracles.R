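# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results from first principles (per-base loops, pair enumeration,
# normal equations) and stay independent of the package's vectorised paths.

# --- chain fixtures ---------------------------------------------------------

chainFromText <- function(lines) {
  tf <- tempfile(fileext = ".chain")
  writeLines(c(lines, ""), tf)
  readChainFile(tf)
}

# random chains on a small source genome; overlapping sources, mixed strands
makeRandomChains <- function(nChains = 6, sLen = 10000L, tLen = 20000L) {
  chains <- list()
  for (k in seq_len(nChains)) {
    sChrom <- sample(c("chr1", "chr2"), 1)
    tChrom <- sample(c("t1", "t2", "t3"), 1)
    strand <- sample(c("+", "-"), 1)
    nb <- sample(3:7, 1)
    sizes <- sample(40:300, nb, replace = TRUE)
    dts <- sample(0:120, nb - 1, replace = TRUE)
    dqs <- sample(0:120, nb - 1, replace = TRUE)
    sSpan <- sum(sizes) + sum(dts)
    tSpan <- sum(sizes) + sum(dqs)
    sStart <- sample.int(sLen - sSpan, 1) - 1L
    tStartNat <- sample.int(tLen - tSpan, 1) - 1L
    sStarts <- sStart + cumsum(c(0L, (sizes + c(dts, 0L))[-nb]))
    tNat <- tStartNat + cumsum(c(0L, (sizes + c(dqs, 0L))[-nb]))
    tFwd <- if (strand == "+") tNat else tLen - (tNat + sizes)
    chains[[k]] <- new("AlignmentChain",
      score = as.numeric(sample.int(1e6, 1)), id = as.character(k),
      sChrom = sChrom, sSize = sLen,
      sStart = sStarts[1], sEnd = sStarts[nb] + sizes[nb],
      tChrom = tChrom, tSize = tLen, tStrand = strand,
      tStartNative = tStartNat, tEndNative = tNat[nb] + sizes[nb],
      blocks = data.frame(sStart = as.integer(sStarts),
                          width = as.integer(sizes),
                          tStart = as.integer(tFwd)))
  }
  chains
}

# lift one 0-based source position through the chains, per-base rules:
# highest score wins, ties by input order; gap bases unlifted
bruteLiftBase <- function(chains, chrom, pos0) {
  ord <- order(-vapply(chains, function(c) c@score, numeric(1)))
  for (k in ord) {
    ch <- chains[[k]]
    if (ch@sChrom != chrom) next
    b <- ch@blocks
    for (j in seq_len(nrow(b))) {
      if (pos0 >= b$sStart[j] && pos0 < b$sStart[j] + b$width[j]) {
        off <- pos0 - b$sStart[j]
        t0 <- if (ch@tStrand == "+") b$tStart[j] + off
              else b$tStart[j] + b$width[j] - 1L - off
        return(list(chain = k, tChrom = ch@tChrom, t0 = t0))
      }
    }
  }
  NULL
}

# per-base ownership arrays: for every source base, which chain claims it
# (highest score first, ties by input order) and which target base it maps
# to. Same per-base rules as bruteLiftBase, built once per chain set.
bruteOwnership <- function(chains, sLen = 10000L) {
  ord <- order(-vapply(chains, function(c) c@score, numeric(1)))
  own <- list()
  for (k in ord) {
    ch <- chains[[k]]
    if (is.null(own[[ch@sChrom]]))
      own[[ch@sChrom]] <- list(chain = rep(NA_integer_, sLen),
                               t0 = rep(NA_integer_, sLen))
    arr <- own[[ch@sChrom]]
    b <- ch@blocks
    for (j in seq_len(nrow(b))) {
      idx <- (b$sStart[j] + 1L):(b$sStart[j] + b$width[j])  # 1-based
      off <- idx - 1L - b$sStart[j]
      t0 <- if (ch@tStrand == "+") b$tStart[j] + off
            else b$tStart[j] + b$width[j] - 1L - off
      free <- is.na(arr$chain[idx])
      arr$chain[idx[free]] <- k
      arr$t0[idx[free]] <- t0[free]
    }
    own[[ch@sChrom]] <- arr
  }
  own
}

# per-base brute-force lift of an interval, grouped into per-chain runs
bruteLiftInterval <- function(chains, chrom, s0, e0, own = NULL) {
  if (is.null(own)) own <- bruteOwnership(chains)
  arr <- own[[chrom]]
  empty <- data.frame(chain = integer(0), tChrom = character(0),
                      tStart0 = integer(0), tEnd0 = integer(0),
                      count = integer(0))
  if (is.null(arr)) return(empty)
  idx <- (s0 + 1L):e0
  ch <- arr$chain[idx]
  t0 <- arr$t0[idx]
  lifted <- !is.na(ch)
  if (!any(lifted)) return(empty)
  df <- data.frame(chain = ch[lifted], t0 = t0[lifted])
  out <- do.call(rbind, lapply(split(df, df$chain), function(g) {
    data.frame(chain = g$chain[1],
               tChrom = chains[[g$chain[1]]]@tChrom,
               tStart0 = min(g$t0), tEnd0 = max(g$t0) + 1L,
               count = nrow(g))
  }))
  out[order(-out$count), , drop = FALSE]
}

# --- diversity oracle -------------------------------------------------------

# mean pairwise difference per site by explicit haplotype-pair enumeration.
# geno: samples x sites matrix of alt-allele dosages (0/1/2). Any phasing of
# heterozygotes is valid because pi is phase-free; `phase` picks one.
brutePi <- function(geno, nQualifying, phase = c("ref_first", "random")) {
  phase <- match.arg(phase)
  m <- nrow(geno); L <- ncol(geno)
  hap <- matrix(0L, nrow = 2L * m, ncol = L)
  for (i in seq_len(m)) for (j in seq_len(L)) {
    g <- geno[i, j]
    al <- if (g == 0L) c(0L, 0L) else if (g == 2L) c(1L, 1L)
          else if (phase == "ref_first") c(0L, 1L) else sample(c(0L, 1L))
    hap[2L * i - 1L, j] <- al[1]
    hap[2L * i, j] <- al[2]
  }
  nh <- nrow(hap)
  tot <- 0
  npairs <- 0
  for (a in seq_len(nh - 1L)) for (b in (a + 1L):nh) {
    tot <- tot + sum(hap[a, ] != hap[b, ])
    npairs <- npairs + 1
  }
  (tot / npairs) / nQualifying
}

# random genotype matrix for m diploids at L sites
randomGeno <- function(m, L) {
  matrix(sample(0:2, m * L, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
         nrow = m)
}

genoToCounts <- function(geno) {
  list(altCopies = as.integer(colSums(geno)),
       nCalled = rep(2L * nrow(geno), ncol(geno)))
}

# union of coverage-passing polymorphic sites over populations (in-memory
# site tables from the generator)
variableUnion <- function(siteList, minDp = 4) {
  parts <- lapply(siteList, function(s) {
    v <- s$altCopies > 0L & s$altCopies < s$nCalled & s$minDepth >= minDp
    s[v, c("chrom", "pos")]
  })
  all <- do.call(rbind, parts)
  all[!duplicated(all), , drop = FALSE]
}

# --- regression oracle ------------------------------------------------------

normalEquationsOls <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  fitted <- Xm %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(coef = as.numeric(beta), r2 = r2)
}

# --- VCF fixture writer -----------------------------------------------------

writeVcfFixture <- function(path, chrom, pos, ref, alt, gt, dp,
                            samples = sprintf("s%d", seq_len(ncol(gt)))) {
  stopifnot(length(pos) == nrow(gt), all(dim(gt) == dim(dp)))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            "GT:DP", paste0(gt[i, ], ":", dp[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# small GRanges constructor (1-based closed, as GRanges convention)
gr <- function(chrom, start1, end1, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), ...)
}
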