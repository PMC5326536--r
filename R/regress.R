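# The statistics layer: Spearman correlation between species, ordinary least
# squares (five-predictor model and the chromosome-length covariate model),
# principal-component regression, and decile-stratified diversity ~
# recombination fits. Model fitting is delegated to stats::lm / prcomp /
# cor.test; this layer owns the model definitions and the PCR decomposition.

#' Spearman rank correlation
#'
#' Mid-ranks for ties; p-value from [stats::cor.test()] (exact where it
#' chooses to be for small tie-free samples, AS89/t approximation otherwise).
#'
#' @param x,y paired observations; incomplete pairs are dropped.
#' @return list with `rho`, `n`, `p`.
#' @export
spearmanCor <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Ordinary least squares with classical inference
#'
#' Intercept always included. Rank-deficient designs are an error naming the
#' collinear columns rather than silently dropping them.
#'
#' @param y response vector.
#' @param X data.frame of predictors; incomplete cases are dropped.
#' @param label optional model label carried into the result.
#' @return a [RegressionSummary].
#' @export
olsFit <- function(y, X, label = "") {
  X <- as.data.frame(X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop("need more observations than parameters", call. = FALSE)
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)
  co <- s$coefficients
  colnames(co) <- c("estimate", "se", "t", "p")
  new("RegressionSummary",
      coefficients = co,
      r2 = unname(s$r.squared), adjR2 = unname(s$adj.r.squared),
      fstat = unname(s$fstatistic[1]),
      fdf = unname(s$fstatistic[2:3]),
      n = as.integer(n), label = label)
}

#' Principal-component regression
#'
#' Standardises the predictors on complete cases (correlation-matrix PCA),
#' orients each PC so its largest-magnitude loading is positive, and
#' decomposes the response variance over the orthogonal PC scores: the per-PC
#' R-squared values are squared correlations with the response and sum
#' exactly to the full-OLS R-squared on the same cases. The sign of each
#' PC's association with the response is reported separately from the
#' loading orientation.
#'
#' PCs with numerically zero variance (e.g. duplicated predictors) are kept
#' in the output with zero response share and `retained = FALSE`.
#'
#' @param y response vector.
#' @param X data.frame of predictors.
#' @return a [PCRResult].
#' @export
pcRegression <- function(y, X) {
  X <- as.data.frame(X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("need more observations than predictors",
                              call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor(s): ",
         paste(names(X)[sds == 0], collapse = ", "), call. = FALSE)
  Xs <- scale(as.matrix(X))
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  # sign convention: largest-magnitude loading positive
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- Xs %*% rot
  sdev <- pc$sdev
  retained <- sdev > 1e-8 * max(sdev)
  r2 <- numeric(length(sdev))
  sgn <- numeric(length(sdev))
  for (k in which(retained)) {
    r <- stats::cor(y, scores[, k])
    r2[k] <- r^2
    sgn[k] <- sign(r)
  }
  new("PCRResult",
      loadings = rot,
      varianceShare = sdev^2 / sum(sdev^2),
      r2PerPC = r2,
      assocSign = sgn,
      totalR2 = sum(r2),
      retained = retained,
      n = as.integer(n))
}

#' Chromosome length as a covariate of cross-species diversity
#'
#' Regresses one species' window diversity on the other species' diversity
#' plus the window's chromosome length, to ask whether chromosome size
#' explains cross-species covariation beyond the homologous diversity itself.
#'
#' @param piB response: window diversity of the predicted species.
#' @param piA window diversity of the predictor species (same windows).
#' @param chromLength chromosome length per window.
#' @param logLength log10-transform the length covariate (default FALSE,
#'   i.e. raw length).
#' @return a [RegressionSummary].
#' @export
chromosomeCovariateModel <- function(piB, piA, chromLength,
                                     logLength = FALSE) {
  cc <- stats::complete.cases(piB, piA, chromLength)
  if (sum(cc) < 4L) stop("need at least 4 complete cases", call. = FALSE)
  len <- if (logLength) log10(chromLength) else chromLength
  olsFit(piB, data.frame(piOther = piA, chromLength = len),
         label = "chromosome-length covariate model")
}

#' Diversity ~ recombination within a stratifier decile
#'
#' Selects the highest or lowest `fraction` (default 10%) of complete-case
#' windows by the stratifying variable (`floor(fraction * n)` windows, ties
#' broken by input order, i.e. genome coordinate) and fits diversity against
#' transformed recombination rate within the stratum.
#'
#' @param pi window diversity.
#' @param rec transformed recombination rate.
#' @param stratifier variable defining the strata (e.g. CDS density or GC).
#' @param decile `"highest"` or `"lowest"`.
#' @param fraction stratum size as a fraction of complete cases (default 0.1).
#' @return a [RegressionSummary].
#' @export
decileRegression <- function(pi, rec, stratifier,
                             decile = c("highest", "lowest"),
                             fraction = 0.1) {
  decile <- match.arg(decile)
  cc <- stats::complete.cases(pi, rec, stratifier)
  pi <- pi[cc]; rec <- rec[cc]; stratifier <- stratifier[cc]
  n <- length(pi)
  if (length(unique(stratifier)) < 2L)
    stop("stratifier is constant; deciles are undefined", call. = FALSE)
  m <- floor(fraction * n)
  if (m < 3L) stop("stratum too small (", m, " windows)", call. = FALSE)
  ord <- order(stratifier)  # stable: ties keep input (coordinate) order
  sel <- if (decile == "lowest") ord[seq_len(m)] else ord[seq(n - m + 1L, n)]
  olsFit(pi[sel], data.frame(recRate = rec[sel]),
         label = sprintf("%s %d%% by stratifier (n=%d)", decile,
                         round(fraction * 100), m))
}
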