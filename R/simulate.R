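# Two-species synthetic data with a shared linked-selection landscape and
# known ground truth for every pipeline stage.
#
# The generator works at the level of windowed sufficient statistics rather
# than a full coalescent: per window the segregating-site count is Poisson
# with the Watterson correspondence S ~ Pois(E[pi] * L * a_n), site
# frequencies follow the neutral SFS P(i) proportional to 1/i, and genotypes
# are random assortments of the allele copies. Realised window pi is then an
# unbiased estimate of the designed E[pi], which is what the analysis
# consumes.

#' Watterson's correction factor
#'
#' `a_n = sum_{i=1}^{n-1} 1/i` for `n` sampled haplotypes; relates the
#' expected segregating-site count to theta (`E[S] = theta * L * a_n`).
#'
#' @param n number of haplotypes (>= 2).
#' @return numeric scalar.
#' @export
wattersonA <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

# draw site frequencies i in 1..n-1 from the neutral SFS (P(i) ~ 1/i)
.sampleSfs <- function(nSites, nHap) {
  if (!nSites) return(integer(0))
  p <- 1 / seq_len(nHap - 1L)
  findInterval(stats::runif(nSites) * sum(p), cumsum(p)) + 1L
}

#' Configuration of the two-species simulator
#'
#' Defaults are calibrated to the study system the pipeline is designed for:
#' two songbird-like genomes analysed in 200 kb windows, species A with
#' theta = 4*Ne*mu = 0.004 per site and species B with 0.0012 (the observed
#' genome-wide window-pi scale of a flycatcher-like and a crow-like
#' population), 15 diploids per population and two populations per species,
#' mean read depth 20, CDS density averaging 0.02 per site, and a
#' recombination landscape spanning roughly 0.1-10 cM/Mb.
#'
#' @param seed mandatory integer seed; every downstream draw is a
#'   deterministic function of it.
#' @param chromLengths,windowSize genome shape: chromosome lengths in bp and
#'   the window width. The default is five chromosomes with the strong size
#'   skew typical of avian karyotypes (60/36/24/18/12 Mb), tiled into 200 kb
#'   windows (750 windows), so the chromosome-length covariate varies as it
#'   does in real genomes.
#' @param neA,neB,muA,muB per-species effective population size and mutation
#'   rate (theta = 4*Ne*mu).
#' @param recMeanlog,recSdlog log-normal recombination-rate marginal (cM/Mb).
#' @param cdsBeta,repBeta Beta parameters of the CDS-density and
#'   repeat-density marginals.
#' @param gcBase,gcCdsCoupling,gcNoiseSd intergenic GC model: base level plus
#'   a linear coupling to CDS density plus Gaussian noise (clamped to
#'   `[0.25, 0.70]`).
#' @param muSdlog log-normal sd of the per-window mutation-rate landscape
#'   (mean 1); the per-gene dS track is proportional to it.
#' @param k linked-selection strength in the diversity-reduction factor
#'   `B = exp(-k * cds / (rec + epsilon))`.
#' @param share landscape-sharing coefficient `s` in `[0, 1]`: each species'
#'   landscape latent is `s * z + (1 - s) * independent`.
#' @param noiseSd per-species log-normal noise sd on expected pi.
#' @param samplesPerPop,nPops diploid individuals per population, populations
#'   per species.
#' @param meanDepth Poisson mean of per-sample read depth.
#' @param rearrangementRate probability that a window's chain is perturbed
#'   (split across target chromosomes, indel-inflated beyond the size bound,
#'   or gap-deleted below the remap bound, in equal shares).
#' @param lowSiteRate probability that a window is given a sub-threshold
#'   accessible-site count (exercises the 10 000-site filter).
#' @param smallIndelRate probability of a small (50-500 bp) benign indel in
#'   an unperturbed window's chain.
#' @param epsilon recombination floor in the B factor (cM/Mb).
#' @return a classed list of validated parameters.
#' @export
simulationConfig <- function(seed,
                             chromLengths = c(6e7L, 3.6e7L, 2.4e7L,
                                              1.8e7L, 1.2e7L),
                             windowSize = 2e5L,
                             neA = 5e5, neB = 1.5e5,
                             muA = 2e-9, muB = 2e-9,
                             recMeanlog = log(1.2), recSdlog = 1.0,
                             cdsBeta = c(0.8, 39.2),
                             repBeta = c(1.5, 16.5),
                             gcBase = 0.42, gcCdsCoupling = 0.4,
                             gcNoiseSd = 0.025,
                             muSdlog = 0.2,
                             k = 2, share = 0.8, noiseSd = 0.3,
                             samplesPerPop = 15L, nPops = 2L,
                             meanDepth = 20,
                             rearrangementRate = 0.02,
                             lowSiteRate = 0.01,
                             smallIndelRate = 0.3,
                             epsilon = 0.1) {
  if (missing(seed) || is.na(seed))
    stop("a seed is mandatory: the generator must be deterministic",
         call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              chromLengths = as.integer(chromLengths),
              nChrom = length(chromLengths),
              windowSize = as.integer(windowSize),
              neA = neA, neB = neB, muA = muA, muB = muB,
              recMeanlog = recMeanlog, recSdlog = recSdlog,
              cdsBeta = cdsBeta, repBeta = repBeta,
              gcBase = gcBase, gcCdsCoupling = gcCdsCoupling,
              gcNoiseSd = gcNoiseSd, muSdlog = muSdlog,
              k = k, share = share, noiseSd = noiseSd,
              samplesPerPop = as.integer(samplesPerPop),
              nPops = as.integer(nPops), meanDepth = meanDepth,
              rearrangementRate = rearrangementRate,
              lowSiteRate = lowSiteRate,
              smallIndelRate = smallIndelRate, epsilon = epsilon)
  with(cfg, {
    stopifnot(nChrom >= 1L, all(chromLengths >= windowSize), windowSize > 0L,
              neA > 0, neB > 0, muA > 0, muB > 0,
              k >= 0, share >= 0, share <= 1, noiseSd >= 0,
              samplesPerPop >= 2L, nPops >= 1L, meanDepth > 0,
              rearrangementRate >= 0, rearrangementRate <= 1,
              lowSiteRate >= 0, lowSiteRate <= 1, epsilon > 0)
  })
  class(cfg) <- "syntpiSimConfig"
  cfg
}

# shared-landscape copula draw: latent s*z + (1-s)*e standardised, pushed
# through the marginal's quantile function
.copulaDraw <- function(z, s, qfun) {
  x <- s * z + (1 - s) * stats::rnorm(length(z))
  qfun(stats::pnorm(x / sqrt(s^2 + (1 - s)^2)))
}

#' Draw the per-window genomic landscapes of both species
#'
#' For each landscape (recombination rate, CDS density, repeat density,
#' mutation scale) one shared standard-normal component is drawn per window;
#' each species' value is `s * z + (1 - s) * independent`, mapped through the
#' landscape's marginal distribution (Gaussian copula), so the sharing
#' coefficient tunes the cross-species landscape correlation. Intergenic GC
#' is derived from each species' CDS density with independent noise.
#'
#' Uses the current RNG state; [simulateDataset()] seeds it from the config.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with window coordinates (0-based half-open, species A)
#'   and per-species landscape columns.
#' @export
drawLandscapes <- function(config) {
  W <- config$windowSize
  perChrom <- config$chromLengths %/% W
  nWin <- sum(perChrom)
  chrom <- rep(sprintf("chrA%d", seq_len(config$nChrom)), times = perChrom)
  start0 <- unlist(lapply(perChrom, function(k) (seq_len(k) - 1L) * W),
                   use.names = FALSE)
  s <- config$share
  draw2 <- function(qfun) {
    z <- stats::rnorm(nWin)
    list(a = .copulaDraw(z, s, qfun), b = .copulaDraw(z, s, qfun))
  }
  rec <- draw2(function(u) stats::qlnorm(u, config$recMeanlog, config$recSdlog))
  cds <- draw2(function(u) stats::qbeta(u, config$cdsBeta[1], config$cdsBeta[2]))
  rep_ <- draw2(function(u) stats::qbeta(u, config$repBeta[1], config$repBeta[2]))
  mu <- draw2(function(u) stats::qlnorm(u, 0, config$muSdlog))
  cdsMean <- config$cdsBeta[1] / sum(config$cdsBeta)
  gc <- function(d) pmin(pmax(
    config$gcBase + config$gcCdsCoupling * (d - cdsMean) +
      stats::rnorm(nWin, 0, config$gcNoiseSd), 0.25), 0.70)
  data.frame(
    windowId = sprintf("%s:%d-%d", chrom, start0, start0 + W),
    chrom = chrom, start = start0, end = start0 + W,
    recA = rec$a, recB = rec$b,
    cdsA = cds$a, cdsB = cds$b,
    repA = rep_$a, repB = rep_$b,
    muScaleA = mu$a, muScaleB = mu$b,
    gcA = gc(cds$a), gcB = gc(cds$b),
    row.names = NULL)
}

#' Expected per-window diversity under linked selection
#'
#' Background-selection-style reduction
#' `B = exp(-k * d / (r + epsilon))` with `d` the CDS density and `r` the
#' recombination rate; expected diversity
#' `E[pi] = 4 * Ne * mu * muScale * B * exp(eta)` with per-species,
#' per-window log-normal noise `eta ~ N(0, noiseSd^2)`.
#'
#' @param config a [simulationConfig()].
#' @param land landscapes from [drawLandscapes()].
#' @return `land` with added columns `bA`, `bB`, `expPiA`, `expPiB`.
#' @export
expectedPi <- function(config, land) {
  n <- nrow(land)
  land$bA <- exp(-config$k * land$cdsA / (land$recA + config$epsilon))
  land$bB <- exp(-config$k * land$cdsB / (land$recB + config$epsilon))
  land$expPiA <- 4 * config$neA * config$muA * land$muScaleA * land$bA *
    exp(stats::rnorm(n, 0, config$noiseSd))
  land$expPiB <- 4 * config$neB * config$muB * land$muScaleB * land$bB *
    exp(stats::rnorm(n, 0, config$noiseSd))
  land
}

# per-window perturbation flags; drawn once, recorded in the truth table
.drawFlags <- function(config, nWin) {
  u <- stats::runif(nWin)
  flag <- rep("none", nWin)
  pert <- u < config$rearrangementRate
  flag[pert] <- sample(c("split", "inflate", "low_remap"),
                       sum(pert), replace = TRUE)
  ls <- stats::runif(nWin) < config$lowSiteRate & flag == "none"
  flag[ls] <- "low_site"
  flag
}

#' Build the chain file and annotations realising the drawn landscapes
#'
#' Chains are block-identity between species A chromosomes `chrA*` and
#' species B chromosomes `chrB*`, with small benign indels in unperturbed
#' windows. Perturbed windows realise, by construction, the synteny failures
#' the retention filters must catch: `split` windows map half each to two
#' spare target chromosomes, `inflate` windows get a 30 kb target-side
#' insertion (span 230 kb > 220 kb), `low_remap` windows lose 50 kb of
#' reference bases to a chain gap (remap 0.75), and `low_site` windows get a
#' sub-threshold accessible-site count. The truth table records which window
#' must fail which filter.
#'
#' @param config a [simulationConfig()].
#' @param land landscapes (with expected pi) from [expectedPi()].
#' @param annotations also realise GFF3/BED/dS annotation objects (default
#'   TRUE; large replicate studies that only consume the chain/variant layer
#'   can skip them).
#' @return list with `chains` (list of [AlignmentChain]), `truth` (per-window
#'   data.frame incl. target spans, accessible counts, flags and expected
#'   verdicts), `genesA`/`genesB` (`GRanges` gene/CDS annotation),
#'   `repeatsA` (`GRanges`), `dsGenes` (`GRanges` with `ds`), `aSizes`,
#'   `bSizes` (named vectors).
#' @export
emitChainsAndAnnotations <- function(config, land, annotations = TRUE) {
  W <- config$windowSize
  nWin <- nrow(land)
  flag <- .drawFlags(config, nWin)

  chains <- list()
  tChrom <- rep(NA_character_, nWin)
  tStart0 <- rep(NA_integer_, nWin)
  tEnd0 <- rep(NA_integer_, nWin)
  lifted <- integer(nWin)
  accA <- rep(as.numeric(W), nWin)
  splCursor <- c(0L, 0L)
  splUsed <- c(FALSE, FALSE)

  chromNames <- sprintf("chrA%d", seq_len(config$nChrom))
  for (cc in unique(land$chrom)) {
    idx <- which(land$chrom == cc)
    sLen <- config$chromLengths[match(cc, chromNames)]
    tName <- sub("^chrA", "chrB", cc)
    tCursor <- 0L
    blocks <- list()
    flush <- function(blocks) {
      if (!length(blocks)) return(NULL)
      b <- as.data.frame(data.table::rbindlist(blocks))
      new("AlignmentChain", score = as.numeric(sum(b$width)) * 10,
          id = as.character(length(chains) + 1L),
          sChrom = cc, sSize = sLen,
          sStart = b$sStart[1L], sEnd = b$sStart[nrow(b)] + b$width[nrow(b)],
          tChrom = tName, tSize = .Machine$integer.max, tStrand = "+",
          tStartNative = b$tStart[1L],
          tEndNative = b$tStart[nrow(b)] + b$width[nrow(b)],
          blocks = b)
    }
    for (i in idx) {
      s0 <- land$start[i]
      f <- flag[i]
      if (f == "split") {
        ch <- flush(blocks); if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
        blocks <- list()
        half <- W %/% 2L
        for (h in 1:2) {
          sp <- splCursor[h]
          chains[[length(chains) + 1L]] <- new(
            "AlignmentChain", score = as.numeric(half),
            id = as.character(length(chains) + 1L),
            sChrom = cc, sSize = sLen,
            sStart = s0 + (h - 1L) * half, sEnd = s0 + h * half,
            tChrom = sprintf("chrB_spl%d", h), tSize = .Machine$integer.max,
            tStrand = "+",
            tStartNative = sp, tEndNative = sp + half,
            blocks = data.frame(sStart = s0 + (h - 1L) * half,
                                width = half, tStart = sp))
          splCursor[h] <- sp + half + 1000L
          splUsed[h] <- TRUE
        }
        lifted[i] <- W
        tChrom[i] <- NA_character_  # no single run; split across spares
        next
      }
      if (f == "low_remap") {
        g <- 50000L; x <- 75000L
        blocks <- c(blocks, list(
          data.frame(sStart = s0, width = x, tStart = tCursor),
          data.frame(sStart = s0 + x + g, width = W - x - g,
                     tStart = tCursor + x)))
        tChrom[i] <- tName; tStart0[i] <- tCursor
        tEnd0[i] <- tCursor + W - g
        lifted[i] <- W - g
        tCursor <- tCursor + W - g
      } else if (f == "inflate") {
        g <- 30000L; x <- 100000L
        blocks <- c(blocks, list(
          data.frame(sStart = s0, width = x, tStart = tCursor),
          data.frame(sStart = s0 + x, width = W - x,
                     tStart = tCursor + x + g)))
        tChrom[i] <- tName; tStart0[i] <- tCursor
        tEnd0[i] <- tCursor + W + g
        lifted[i] <- W
        tCursor <- tCursor + W + g
      } else {
        if (f == "low_site")
          accA[i] <- sample(4000:9000, 1L)
        if (stats::runif(1) < config$smallIndelRate) {
          g <- sample(50:500, 1L)
          x <- as.integer(round(stats::runif(1, 0.2, 0.8) * W))
          if (stats::runif(1) < 0.5) {  # reference-side gap (dt)
            blocks <- c(blocks, list(
              data.frame(sStart = s0, width = x, tStart = tCursor),
              data.frame(sStart = s0 + x + g, width = W - x - g,
                         tStart = tCursor + x)))
            tChrom[i] <- tName; tStart0[i] <- tCursor
            tEnd0[i] <- tCursor + W - g
            lifted[i] <- W - g
            tCursor <- tCursor + W - g
          } else {  # target-side gap (dq)
            blocks <- c(blocks, list(
              data.frame(sStart = s0, width = x, tStart = tCursor),
              data.frame(sStart = s0 + x, width = W - x,
                         tStart = tCursor + x + g)))
            tChrom[i] <- tName; tStart0[i] <- tCursor
            tEnd0[i] <- tCursor + W + g
            lifted[i] <- W
            tCursor <- tCursor + W + g
          }
        } else {
          blocks <- c(blocks, list(
            data.frame(sStart = s0, width = W, tStart = tCursor)))
          tChrom[i] <- tName; tStart0[i] <- tCursor
          tEnd0[i] <- tCursor + W
          lifted[i] <- W
          tCursor <- tCursor + W
        }
      }
    }
    ch <- flush(blocks); if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
  }

  # declare target sizes now that the cursors are final
  bSizes <- stats::setNames(
    rep(0L, config$nChrom), sprintf("chrB%d", seq_len(config$nChrom)))
  for (ch in chains) {
    if (ch@tChrom %in% names(bSizes))
      bSizes[ch@tChrom] <- max(bSizes[ch@tChrom], ch@tEndNative)
  }
  for (h in 1:2) if (splUsed[h])
    bSizes[sprintf("chrB_spl%d", h)] <- splCursor[h]
  bSizes <- bSizes + 1000L
  chains <- lapply(chains, function(ch) {
    ch@tSize <- as.integer(bSizes[ch@tChrom])
    validObject(ch)
    ch
  })
  aSizes <- stats::setNames(config$chromLengths, chromNames)

  expectedVerdict <- c(none = "retained", low_site = "retained",
                       split = "rejected_split", inflate = "rejected_size",
                       low_remap = "rejected_low_remap")[flag]
  accB <- ifelse(is.na(tChrom), NA_real_, pmin(accA, lifted))

  ann <- if (annotations) .realiseAnnotations(config, land, tChrom, tStart0)
         else list(genesA = NULL, genesB = NULL, repeatsA = NULL,
                   dsGenes = NULL)
  truth <- cbind(land,
                 data.frame(flag = flag, expectedVerdict = expectedVerdict,
                            tChrom = tChrom, tStart = tStart0, tEnd = tEnd0,
                            liftedBases = lifted, accA = accA, accB = accB))
  list(chains = chains, truth = truth,
       genesA = ann$genesA, genesB = ann$genesB,
       repeatsA = ann$repeatsA, dsGenes = ann$dsGenes,
       aSizes = aSizes, bSizes = bSizes)
}

# gene/CDS/repeat annotations realising the drawn densities, plus per-gene dS
.realiseAnnotations <- function(config, land, tChrom, tStart0) {
  W <- config$windowSize
  nWin <- nrow(land)
  geneRows <- list(); cdsRows <- list(); repRows <- list()
  geneRowsB <- list(); dsRows <- list()
  for (i in seq_len(nWin)) {
    s0 <- land$start[i]
    chrom <- land$chrom[i]
    cdsBases <- max(3L, as.integer(round(land$cdsA[i] * W)))
    exw <- c(cdsBases %/% 3L, cdsBases %/% 3L,
             cdsBases - 2L * (cdsBases %/% 3L))
    exStart <- s0 + as.integer(round(c(0.2, 0.5, 0.8) * W)) - exw %/% 2L
    gid <- sprintf("g%05d", i)
    geneRows[[i]] <- data.frame(chrom = chrom, start = min(exStart),
                                end = max(exStart + exw), id = gid)
    cdsRows[[i]] <- data.frame(chrom = chrom, start = exStart,
                               end = exStart + exw, id = gid)
    ds <- 0.1 * land$muScaleA[i] * exp(stats::rnorm(1, 0, 0.1))
    dsRows[[i]] <- data.frame(chrom = chrom, start = min(exStart),
                              end = max(exStart + exw), id = gid, ds = ds)
    u <- stats::runif(1)
    if (u < 0.02) {  # gene with dS = 0, excluded by rule
      dsRows[[i]] <- rbind(dsRows[[i]], data.frame(
        chrom = chrom, start = s0 + 1000L, end = s0 + 1300L,
        id = paste0(gid, "z"), ds = 0))
    } else if (u < 0.03) {  # saturated gene, dS > 2, excluded by rule
      dsRows[[i]] <- rbind(dsRows[[i]], data.frame(
        chrom = chrom, start = s0 + 2000L, end = s0 + 2300L,
        id = paste0(gid, "s"), ds = 2.5))
    }
    repBases <- as.integer(round(land$repA[i] * W))
    if (repBases >= 2L) {
      rw <- c(repBases %/% 2L, repBases - repBases %/% 2L)
      rs <- s0 + as.integer(round(c(0.1, 0.6) * W))
      repRows[[i]] <- data.frame(chrom = chrom, start = rs, end = rs + rw)
    }
    # B-side CDS for target-side masking: same offsets inside the lifted span
    if (!is.na(tChrom[i])) {
      offB <- tStart0[i] + (exStart - s0)
      geneRowsB[[i]] <- data.frame(chrom = tChrom[i], start = offB,
                                   end = offB + exw, id = gid)
    }
  }
  toGR <- function(rows, type, withId = TRUE) {
    df <- as.data.frame(data.table::rbindlist(rows))
    if (!nrow(df)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end))
    if (!is.null(type)) S4Vectors::mcols(gr)$type <- type
    if (identical(type, "CDS")) S4Vectors::mcols(gr)$phase <- 0L
    if (withId && !is.null(df$id)) S4Vectors::mcols(gr)$ID <- df$id
    if (!is.null(df$ds)) S4Vectors::mcols(gr)$ds <- df$ds
    gr
  }
  genesA <- c(toGR(geneRows, "gene"), toGR(cdsRows, "CDS"))
  genesB <- c(toGR(geneRowsB, "gene"),
              toGR(geneRowsB, "CDS"))  # single-exon approximation per exon set
  list(genesA = sort(genesA), genesB = sort(genesB),
       repeatsA = toGR(repRows, NULL, withId = FALSE),
       dsGenes = toGR(dsRows, NULL))
}

# minimum-depth distribution over m independent Poisson(lambda) samples:
# P(min = x) = (1 - F(x-1))^m - (1 - F(x))^m
.sampleMinDepth <- function(nSites, lambda, m) {
  if (!nSites) return(integer(0))
  hi <- as.integer(stats::qpois(1 - 1e-12, lambda)) + 2L
  surv <- (1 - stats::ppois(0:hi - 1, lambda))^m
  pmf <- surv - c(surv[-1], 0)
  findInterval(stats::runif(nSites) * sum(pmf), cumsum(pmf)) + 0L
}

#' Generate variant sites for one species
#'
#' Per window and population: `S ~ Poisson(E[pi] * accessible * a_n)`
#' segregating sites at uniform distinct positions inside the accessible
#' span, frequencies from the neutral SFS, genotypes by random assortment of
#' the allele copies, per-sample depths Poisson. Both populations of a
#' species share the same expected pi (panmixia), which reproduces the high
#' within-species between-population window correlation.
#'
#' With `perSample = TRUE` the full per-sample genotype/depth draw is
#' returned (needed to write VCFs); otherwise the per-site sufficient
#' statistics are returned (`altCopies`, `nCalled`, `minDepth`), whose
#' marginal distribution is identical, which is what large replicate studies
#' consume.
#'
#' @param config a [simulationConfig()].
#' @param windows data.frame with `chrom`, `start` (0-based), `acc`
#'   (accessible bases) and `expPi` for the species being emitted.
#' @param perSample also return genotype and depth matrices (default FALSE).
#' @param positions draw per-site genomic positions (default TRUE; window
#'   summaries do not need them and replicate studies can skip the draw).
#' @return a list with one element per population: data.frame of sites
#'   (`win` row index into `windows`, `altCopies`, `nCalled`, `minDepth`;
#'   `chrom` and `pos` (1-based) when `positions = TRUE`; plus `gt` and `dp`
#'   matrices when `perSample = TRUE`).
#' @export
emitVariants <- function(config, windows, perSample = FALSE,
                         positions = TRUE) {
  if (perSample && !positions)
    stop("per-sample output requires positions", call. = FALSE)
  nHap <- 2L * config$samplesPerPop
  aN <- wattersonA(nHap)
  out <- vector("list", config$nPops)
  for (p in seq_len(config$nPops)) {
    S <- stats::rpois(nrow(windows), windows$expPi * windows$acc * aN)
    S <- pmin(S, windows$acc)  # infinite-sites cap: distinct positions
    win <- rep(seq_len(nrow(windows)), S)
    if (positions) {
      pos <- unlist(lapply(seq_len(nrow(windows)), function(i) {
        if (!S[i]) return(integer(0))
        sample.int(windows$acc[i], S[i],
                   useHash = S[i] <= windows$acc[i] %/% 2L)
      }), use.names = FALSE)
      if (is.null(pos)) pos <- integer(0)
      pos <- windows$start[win] + pos  # 1-based: start 0-based, offsets 1-based
    } else {
      pos <- NULL
    }
    nSites <- length(win)
    alt <- .sampleSfs(nSites, nHap)
    # quick data.frame: columns are guaranteed equal-length vectors.
    # chrom/pos are omitted when positions are not drawn, keeping large
    # replicate studies lean; window assignment travels in `win`.
    cols <- if (positions) list(chrom = windows$chrom[win], pos = pos)
            else list()
    sites <- structure(
      c(cols, list(win = win, altCopies = alt,
                   nCalled = rep(nHap, nSites),
                   minDepth = rep(NA_integer_, nSites))),
      class = "data.frame", row.names = c(NA_integer_, -nSites))
    if (perSample) {
      m <- config$samplesPerPop
      g <- matrix(0L, nrow = nSites, ncol = m)
      altRem <- alt
      totRem <- rep(nHap, nSites)
      for (j in seq_len(m)) {
        gj <- if (nSites) stats::rhyper(nSites, altRem, totRem - altRem, 2L)
              else integer(0)
        g[, j] <- gj
        altRem <- altRem - gj
        totRem <- totRem - 2L
      }
      dp <- matrix(stats::rpois(nSites * m, config$meanDepth),
                   nrow = nSites, ncol = m)
      sites$minDepth <- if (nSites) do.call(pmin, as.data.frame(dp))
                        else integer(0)
      out[[p]] <- list(sites = sites, gt = g, dp = dp)
    } else {
      sites$minDepth <- .sampleMinDepth(nSites, config$meanDepth,
                                        config$samplesPerPop)
      out[[p]] <- list(sites = sites)
    }
  }
  out
}

# write one population's sites as a sorted VCF with GT:DP
.writeVcf <- function(sites, gt, dp, chromSizes, path, samplePrefix) {
  nSites <- nrow(sites)
  m <- ncol(gt)
  bases <- c("A", "C", "G", "T")
  refIdx <- sample.int(4L, nSites, replace = TRUE)
  altIdx <- 1L + (refIdx - 1L + sample.int(3L, nSites, replace = TRUE)) %% 4L
  gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nSites)
  cells <- matrix(paste0(gtStr, ":", dp), nrow = nSites)
  body <- data.table::data.table(
    CHROM = sites$chrom, POS = sites$pos, ID = ".",
    REF = bases[refIdx], ALT = bases[altIdx],
    QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT:DP")
  for (j in seq_len(m))
    body[[sprintf("%s%02d", samplePrefix, j)]] <- cells[, j]
  data.table::setorder(body, CHROM, POS)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chromSizes),
                   chromSizes),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   sprintf("%s%02d", samplePrefix, seq_len(m))),
                 collapse = "\t"))
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a full two-species dataset
#'
#' Seeds the RNG from the config and produces, in order: landscapes,
#' expected diversity, chains + annotations + truth table, and variant
#' sites. With an output directory all external files consumed by the
#' pipeline are written (`a2b.chain`, per-population VCFs, GFF3/BED
#' annotation, covariate and accessible-site TSVs, chromosome sizes,
#' `truth.tsv`); identical seeds give byte-identical files.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed); `NULL` for an in-memory
#'   dataset (site tables instead of VCFs).
#' @param annotations realise and write annotation objects (default TRUE;
#'   must be TRUE when `dir` is given).
#' @return list with `config`, `truth`, `chains`, annotation objects, file
#'   paths (when `dir` is given) and in-memory `sites` (when it is not:
#'   `sites$A`/`sites$B`, one entry per population).
#' @export
simulateDataset <- function(config, dir = NULL, annotations = TRUE,
                            positions = TRUE) {
  if (!is.null(dir) && (!annotations || !positions))
    stop("file output requires annotations and positions", call. = FALSE)
  set.seed(config$seed)
  land <- drawLandscapes(config)
  land <- expectedPi(config, land)
  scaf <- emitChainsAndAnnotations(config, land, annotations = annotations)
  truth <- scaf$truth

  winA <- data.frame(chrom = truth$chrom, start = truth$start,
                     acc = truth$accA, expPi = truth$expPiA)
  okB <- !is.na(truth$tChrom)
  winB <- data.frame(chrom = truth$tChrom[okB], start = truth$tStart[okB],
                     acc = truth$accB[okB], expPi = truth$expPiB[okB])

  perSample <- !is.null(dir)
  sitesA <- emitVariants(config, winA, perSample = perSample,
                         positions = positions)
  sitesB <- emitVariants(config, winB, perSample = perSample,
                         positions = positions)

  out <- list(config = config, truth = truth, chains = scaf$chains,
              genesA = scaf$genesA, genesB = scaf$genesB,
              repeatsA = scaf$repeatsA, dsGenes = scaf$dsGenes,
              aSizes = scaf$aSizes, bSizes = scaf$bSizes)

  if (is.null(dir)) {
    # map window row indices back to window ids
    for (p in seq_along(sitesA))
      sitesA[[p]]$sites$windowId <- truth$windowId[sitesA[[p]]$sites$win]
    for (p in seq_along(sitesB))
      sitesB[[p]]$sites$windowId <- truth$windowId[okB][sitesB[[p]]$sites$win]
    out$sites <- list(A = lapply(sitesA, `[[`, "sites"),
                      B = lapply(sitesB, `[[`, "sites"))
    return(out)
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  writeChainFile(scaf$chains, fp("a2b.chain"))

  writeSizes <- function(sz, path)
    utils::write.table(data.frame(names(sz), unname(sz)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeSizes(scaf$aSizes, fp("a.sizes"))
  writeSizes(scaf$bSizes, fp("b.sizes"))

  rtracklayer::export(scaf$genesA, fp("genes_a.gff3"), format = "gff3")
  rtracklayer::export(scaf$genesB, fp("genes_b.gff3"), format = "gff3")
  repBed <- scaf$repeatsA
  rtracklayer::export(repBed, fp("repeats_a.bed"), format = "bed")

  utils::write.table(
    data.frame(window_id = truth$windowId, rec = truth$recA),
    fp("rec.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(window_id = truth$windowId, gc = truth$gcA),
    fp("gc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  dsDf <- data.frame(
    gene_id = S4Vectors::mcols(scaf$dsGenes)$ID,
    chrom = as.character(GenomicRanges::seqnames(scaf$dsGenes)),
    start = GenomicRanges::start(scaf$dsGenes) - 1L,
    end = GenomicRanges::end(scaf$dsGenes),
    ds = S4Vectors::mcols(scaf$dsGenes)$ds)
  utils::write.table(dsDf, fp("ds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(window_id = truth$windowId,
               accessible_a = truth$accA, accessible_b = truth$accB),
    fp("accessible.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files <- list(chain = fp("a2b.chain"), aSizes = fp("a.sizes"),
                bSizes = fp("b.sizes"), genesA = fp("genes_a.gff3"),
                genesB = fp("genes_b.gff3"), repeatsA = fp("repeats_a.bed"),
                rec = fp("rec.tsv"), gc = fp("gc.tsv"), ds = fp("ds.tsv"),
                accessible = fp("accessible.tsv"), truth = fp("truth.tsv"))
  for (p in seq_along(sitesA)) {
    path <- fp(sprintf("a.pop%d.vcf", p))
    .writeVcf(sitesA[[p]]$sites, sitesA[[p]]$gt, sitesA[[p]]$dp,
              scaf$aSizes, path, sprintf("A%d_", p))
    files[[sprintf("vcfA%d", p)]] <- path
  }
  for (p in seq_along(sitesB)) {
    path <- fp(sprintf("b.pop%d.vcf", p))
    .writeVcf(sitesB[[p]]$sites, sitesB[[p]]$gt, sitesB[[p]]$dp,
              scaf$bSizes, path, sprintf("B%d_", p))
    files[[sprintf("vcfB%d", p)]] <- path
  }
  out$files <- files
  out
}
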