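#' Leave-one-chromosome-out kinship matrices
#'
#' K[i, j] is the mean over included markers of
#' \code{P_i(B) P_j(B) + P_i(D) P_j(D)}; for the LOCO matrix of chromosome
#' c the mean excludes c's markers, so the scan on c is not contaminated by
#' the tested locus.
#'
#' @param prob genotype probabilities from \code{\link{founderGenoProb}}.
#' @return list: \code{loco} (named list of strains x strains matrices, one
#'   per chromosome), \code{overall} (all-marker kinship).
#' @export
calcKinshipLoco <- function(prob) {
  pB <- prob$pB
  if (nrow(pB) < 2L) stop("kinship requires at least 2 strains")
  pD <- 1 - pB
  Sall <- tcrossprod(pB) + tcrossprod(pD)
  nAll <- ncol(pB)
  chroms <- unique(prob$chrom)
  overall <- Sall / nAll
  loco <- list()
  if (length(chroms) < 2L) {
    warning("single-chromosome genome: LOCO impossible, using all-marker kinship")
    for (ch in chroms) loco[[ch]] <- overall
  } else {
    for (ch in chroms) {
      j <- prob$chrom == ch
      Sc <- tcrossprod(pB[, j, drop = FALSE]) + tcrossprod(pD[, j, drop = FALSE])
      loco[[ch]] <- (Sall - Sc) / (nAll - sum(j))
    }
  }
  list(loco = loco, overall = overall)
}

# profiled ML log-likelihood of the variance-ratio parameter h2 given the
# eigenvalues of 2K and rotated response/design
.profileLogLik <- function(h2, lambda, yr, Xr) {
  w <- 1 / (h2 * lambda + (1 - h2))
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  rss <- max(sum(fit$residuals^2), 1e-12)
  -length(yr) / 2 * log(rss) + 0.5 * sum(log(w))
}

#' Fit the null linear mixed model
#'
#' Model: y = X beta + u + e with var(u) = s2g * 2K and var(e) = s2e.
#' 2K is eigendecomposed once and the profiled ML log-likelihood is
#' maximised over h2 = s2g / (s2g + s2e) on [0, 0.99] by scalar search
#' (tolerance 1e-6).  A likelihood flat in h2 (e.g. identity kinship) is
#' resolved to h2 = 0.
#'
#' @param y numeric phenotype vector.
#' @param covariates covariate matrix (an intercept column is added).
#' @param K kinship matrix for these strains.
#' @return list: \code{h2}, \code{lambda}, \code{U} (eigenvectors),
#'   \code{weights}, \code{logLik}, \code{rss0} (weighted null residual sum
#'   of squares).
#' @export
fitNullLMM <- function(y, covariates = NULL, K = NULL) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  keep <- is.finite(y) & stats::complete.cases(X)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " strains with non-finite phenotype/covariates")
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    if (!is.null(K)) K <- K[keep, keep]
  }
  if (is.null(K)) K <- diag(length(y)) / 2
  ed <- eigen(2 * K, symmetric = TRUE)
  yr <- crossprod(ed$vectors, y)
  Xr <- crossprod(ed$vectors, X)
  h2 <- .estimateH2(ed$values, yr, Xr)
  w <- 1 / (h2 * ed$values + (1 - h2))
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  rss0 <- max(sum(fit$residuals^2), 1e-12)
  list(h2 = h2, lambda = ed$values, U = ed$vectors, weights = w,
       logLik = .profileLogLik(h2, ed$values, yr, Xr), rss0 = rss0)
}

.estimateH2 <- function(lambda, yr, Xr) {
  opt <- stats::optimize(.profileLogLik, c(0, 0.99), maximum = TRUE,
                         tol = 1e-6, lambda = lambda, yr = yr, Xr = Xr)
  l0 <- .profileLogLik(0, lambda, yr, Xr)
  if (opt$objective <= l0 + 1e-8) 0 else opt$maximum
}

# per-chromosome scan pieces shared between the observed scan and
# permutations: eigendecompositions and rotated marker probabilities
.prepScan <- function(prob, kinship, markerKeep) {
  chroms <- unique(prob$chrom)
  prep <- list()
  for (ch in chroms) {
    j <- which(prob$chrom == ch & markerKeep)
    K <- kinship$loco[[ch]]
    ed <- eigen(2 * K, symmetric = TRUE)
    prep[[ch]] <- list(
      lambda = ed$values, U = ed$vectors,
      rotPB = crossprod(ed$vectors, prob$pB[, j, drop = FALSE]),
      marker = prob$marker[j], posBp = prob$posBp[j])
  }
  prep
}

# LOD curve for one (possibly permuted) phenotype/covariate alignment:
# GLS in the rotated space, LOD = (n/2) log10(RSS0 / RSS1)
.scanAll <- function(prep, y, X) {
  n <- length(y)
  lods <- list(); h2 <- numeric(length(prep))
  names(h2) <- names(prep)
  for (ch in names(prep)) {
    p <- prep[[ch]]
    yr <- crossprod(p$U, y)
    Xr <- crossprod(p$U, X)
    h2c <- .estimateH2(p$lambda, yr, Xr)
    h2[ch] <- h2c
    sw <- sqrt(1 / (h2c * p$lambda + (1 - h2c)))
    yw <- yr * sw; Xw <- Xr * sw
    qx <- qr(Xw)
    ry <- qr.resid(qx, yw)
    rss0 <- max(sum(ry^2), 1e-12)
    M <- qr.resid(qx, p$rotPB * sw)
    mm <- colSums(M^2)
    my <- as.numeric(crossprod(M, ry))
    rss1 <- rss0 - ifelse(mm > 1e-10, my^2 / mm, 0)
    rss1 <- pmax(rss1, 1e-12)
    lods[[ch]] <- n / 2 * log10(rss0 / rss1)
  }
  list(lod = lods, h2 = h2)
}

#' Single-locus genome scan with a LOCO linear mixed model
#'
#' For each phenotype and marker, fits generalised least squares in the
#' rotated space of the chromosome's LOCO kinship eigendecomposition with
#' design \code{[intercept | covariates | P(B)]}; the null heritability is
#' re-estimated per chromosome under the covariates-only model.  LOD is
#' \code{(n/2) log10(RSS0/RSS1)}.  Markers monomorphic for the founder
#' label within the analysed strains are removed before scanning.  With
#' \code{nPerm > 0}, genome-wide significance thresholds are computed by
#' permuting phenotype and covariate rows jointly against the genotypes and
#' taking empirical quantiles (type 7) of the per-permutation genome-wide
#' maximum LOD.
#'
#' @param prob genotype probabilities (\code{\link{founderGenoProb}}),
#'   possibly row-subset to the analysed strains.
#' @param y named numeric phenotype vector (names = strains; must be a
#'   subset of \code{rownames(prob$pB)}).
#' @param covariates optional matrix/data.frame of covariates (e.g. the
#'   number of inbreeding generations), rows aligned to \code{y}.
#' @param kinship optional precomputed \code{\link{calcKinshipLoco}} result.
#' @param nPerm number of permutations (0 = none; the conventional design
#'   uses 100).
#' @param alphas significance levels for thresholds.
#' @param seed seed for the permutation draws.
#' @param lodDrop LOD-support-interval drop for the peak table.
#' @return a \code{\linkS4class{QTLScan}}.
#' @export
scanQTL <- function(prob, y, covariates = NULL, kinship = NULL,
                    nPerm = 0L, alphas = 0.05, seed = 1, lodDrop = 1.5) {
  strains <- rownames(prob$pB)
  if (!is.null(names(y))) {
    if (!all(names(y) %in% strains))
      stop("phenotype strains absent from genotype probabilities: ",
           paste(utils::head(setdiff(names(y), strains), 3), collapse = ", "))
    strains <- names(y)
  } else names(y) <- strains
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(y))
  }
  keep <- is.finite(y) & (if (is.null(covariates)) TRUE else
    stats::complete.cases(covariates))
  if (!all(keep))
    message("dropping ", sum(!keep), " strains with non-finite values")
  y <- y[keep]
  covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  strains <- strains[keep]
  pB <- prob$pB[strains, , drop = FALSE]
  prob <- list(pB = pB, marker = prob$marker, chrom = prob$chrom,
               posBp = prob$posBp, cM = prob$cM)
  if (is.null(kinship)) kinship <- calcKinshipLoco(prob)
  else kinship <- list(loco = lapply(kinship$loco, function(K)
    K[strains, strains, drop = FALSE]),
    overall = kinship$overall[strains, strains, drop = FALSE])
  nB <- colSums(pB > 0.5); nD <- colSums(pB < 0.5)
  markerKeep <- nB > 0L & nD > 0L
  prep <- .prepScan(prob, kinship, markerKeep)
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  obs <- .scanAll(prep, y, X)
  lodDf <- do.call(rbind, lapply(names(prep), function(ch)
    data.frame(marker = prep[[ch]]$marker, chrom = ch,
               posBp = prep[[ch]]$posBp, lod = pmax(obs$lod[[ch]], 0))))
  rownames(lodDf) <- NULL
  thr <- numeric(0); permMax <- numeric(0)
  if (nPerm > 0L) {
    pt <- permutationThreshold(prob, y, covariates, kinship, nPerm = nPerm,
                               alphas = alphas, seed = seed, .prep = prep)
    thr <- pt$thresholds; permMax <- pt$maxima
  }
  scan <- methods::new("QTLScan", lod = lodDf, h2 = obs$h2,
                       nStrains = length(y),
                       covariateNames = colnames(covariates) %||% character(),
                       thresholds = thr, permMax = permMax,
                       peaks = data.frame())
  pk <- lapply(unique(lodDf$chrom), function(ch) {
    d <- lodDf[lodDf$chrom == ch, ]
    i <- which.max(d$lod)
    ci <- lodSupportInterval(scan, ch, drop = lodDrop)
    data.frame(chrom = ch, marker = d$marker[i], posBp = d$posBp[i],
               lod = d$lod[i], intervalStartBp = ci[1], intervalEndBp = ci[2])
  })
  scan@peaks <- do.call(rbind, pk)
  rownames(scan@peaks) <- NULL
  scan
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation-based genome-wide significance thresholds
#'
#' Permutes the rows of (phenotype, covariates) jointly against the
#' genotypes/kinship, records the genome-wide maximum LOD of each
#' permutation (the null heritability is re-estimated per chromosome for
#' every permutation), and returns empirical (1 - alpha) quantiles with
#' linear interpolation (quantile type 7).  Deterministic given the seed.
#'
#' @inheritParams scanQTL
#' @param .prep internal: precomputed scan pieces.
#' @return list: \code{thresholds} (named by alpha), \code{maxima}.
#' @export
permutationThreshold <- function(prob, y, covariates = NULL, kinship = NULL,
                                 nPerm = 100L, alphas = 0.05, seed = 1,
                                 .prep = NULL) {
  stopifnot(nPerm >= 1L)
  if (nPerm < 20L && any(alphas <= 0.05))
    warning("fewer than 20 permutations poorly resolve alpha <= 0.05")
  if (is.null(.prep)) {
    if (is.null(kinship)) kinship <- calcKinshipLoco(prob)
    nB <- colSums(prob$pB > 0.5); nD <- colSums(prob$pB < 0.5)
    .prep <- .prepScan(prob, kinship, nB > 0L & nD > 0L)
  }
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  set.seed(seed)
  maxima <- vapply(seq_len(nPerm), function(p) {
    pi <- sample.int(length(y))
    max(unlist(.scanAll(.prep, y[pi], X[pi, , drop = FALSE])$lod))
  }, numeric(1))
  thr <- stats::quantile(maxima, 1 - alphas, type = 7, names = FALSE)
  list(thresholds = stats::setNames(thr, as.character(alphas)),
       maxima = maxima)
}

#' LOD support interval around a chromosome's peak
#'
#' The interval spans the contiguous run of markers containing the peak
#' whose LOD stays within \code{drop} of the maximum, extended outward by
#' one flanking marker on each side where present.
#'
#' @param scan a \code{\linkS4class{QTLScan}}.
#' @param chromosome chromosome identifier.
#' @param drop LOD drop defining the support region (default 1.5).
#' @return numeric \code{c(startBp, endBp)}.
#' @export
lodSupportInterval <- function(scan, chromosome, drop = 1.5) {
  d <- scan@lod[scan@lod$chrom == chromosome, , drop = FALSE]
  if (!nrow(d)) stop("no markers on chromosome ", chromosome)
  d <- d[order(d$posBp), ]
  peak <- which.max(d$lod)
  thrLod <- d$lod[peak] - drop
  lo <- peak
  while (lo > 1L && d$lod[lo - 1L] >= thrLod) lo <- lo - 1L
  hi <- peak
  while (hi < nrow(d) && d$lod[hi + 1L] >= thrLod) hi <- hi + 1L
  lo <- max(1L, lo - 1L)
  hi <- min(nrow(d), hi + 1L)
  c(startBp = d$posBp[lo], endBp = d$posBp[hi])
}
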