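#' Per-strain mutator phenotypes
#'
#' Computes the three mutator phenotypes for each strain from its retained
#' mutation calls: \emph{mutation count} (fraction of genotyped STRs with a
#' new mutation: retained calls divided by non-missing genotyped loci),
#' \emph{mutation size} (mean signed RU change, separately for expansions
#' and contractions) and \emph{expansion propensity} (fraction of new
#' mutations whose allele is longer than the founder allele; undefined for
#' strains with zero mutations, and contraction propensity is its
#' complement).
#'
#' @param calls mutation call data.frame (already filtered as desired; rows
#'   with \code{strainIncluded == FALSE} are ignored when present).
#' @param strSE STR genotype experiment (denominator of mutation count).
#' @param strains strains to report (default: all columns of \code{strSE}).
#' @return data.frame with one row per strain: \code{strainId},
#'   \code{nGenotyped}, \code{nMutations}, \code{mutationCount},
#'   \code{expansionPropensity}, \code{meanExpansionSize},
#'   \code{meanContractionSize}, plus \code{epoch} / \code{nGenerations}
#'   when present in the experiment's column data.
#' @export
mutatorPhenotypes <- function(calls, strSE, strains = colnames(strSE)) {
  if ("strainIncluded" %in% names(calls))
    calls <- calls[calls$strainIncluded, , drop = FALSE]
  a1 <- SummarizedExperiment::assay(strSE, "a1")
  a2 <- SummarizedExperiment::assay(strSE, "a2")
  nGeno <- colSums(!is.na(a1) & !is.na(a2))
  res <- lapply(strains, function(s) {
    d <- calls$deltaRu[calls$strainId == s]
    n <- length(d)
    ng <- if (s %in% names(nGeno)) nGeno[[s]] else 0L
    data.frame(
      strainId = s, nGenotyped = ng, nMutations = n,
      mutationCount = if (ng > 0) n / ng else NA_real_,
      expansionPropensity = if (n > 0) mean(d > 0) else NA_real_,
      meanExpansionSize = if (any(d > 0)) mean(d[d > 0]) else NA_real_,
      meanContractionSize = if (any(d < 0)) mean(d[d < 0]) else NA_real_)
  })
  out <- do.call(rbind, res)
  cd <- SummarizedExperiment::colData(strSE)
  for (col in intersect(c("epoch", "nGenerations"), names(cd)))
    out[[col]] <- cd[out$strainId, col]
  rownames(out) <- out$strainId
  out
}

#' @rdname mutatorPhenotypes
#' @param strain a single strain id.
#' @return \code{mutationCount}: the fraction of genotyped STRs with a new
#'   mutation in the strain (\code{NA} if no genotyped loci).
#' @export
mutationCount <- function(calls, strSE, strain) {
  mutatorPhenotypes(calls, strSE, strains = strain)$mutationCount
}

#' @rdname mutatorPhenotypes
#' @param direction \code{"expansion"} or \code{"contraction"}.
#' @param absolute report absolute instead of signed mean size.
#' @return \code{mutationSize}: mean signed RU change of the strain's calls
#'   in the given direction (\code{NA} if none).
#' @export
mutationSize <- function(calls, strain,
                         direction = c("expansion", "contraction"),
                         absolute = FALSE) {
  direction <- match.arg(direction)
  d <- calls$deltaRu[calls$strainId == strain]
  d <- if (direction == "expansion") d[d > 0] else d[d < 0]
  if (!length(d)) return(NA_real_)
  if (absolute) mean(abs(d)) else mean(d)
}

#' @rdname mutatorPhenotypes
#' @return \code{expansionPropensity}: fraction of the strain's mutations
#'   with a positive RU change (\code{NA} if no mutations).
#' @export
expansionPropensity <- function(calls, strain) {
  d <- calls$deltaRu[calls$strainId == strain]
  if (!length(d)) return(NA_real_)
  mean(d > 0)
}

#' Mutation-sharing principal component analysis
#'
#' Builds the strain-by-mutation indicator matrix (one column per distinct
#' (locus, new allele) pair, 1 when the strain carries that new allele),
#' column-centres it without scaling, and extracts principal components by
#' singular value decomposition.  Component signs are fixed so that the
#' loading of largest magnitude is positive.
#'
#' @param calls mutation call data.frame.
#' @param strains strains forming the rows (default: strains present in
#'   \code{calls}); strains without calls get all-zero indicator rows.
#' @param nComponents number of components to return.
#' @return list: \code{scores} (strains x components), \code{loadings},
#'   \code{sdev} (component standard deviations), \code{keys} (column
#'   identities \code{locusId:newAllele}).
#' @export
mutationPCA <- function(calls, strains = NULL, nComponents = 2L) {
  if (is.null(strains)) strains <- sort(unique(calls$strainId))
  if (length(strains) < 2L) stop("need at least 2 strains")
  key <- paste(calls$locusId, calls$observedRu, sep = ":")
  keys <- sort(unique(key))
  if (length(keys) < 2L) stop("need at least 2 distinct mutations")
  M <- matrix(0, length(strains), length(keys),
              dimnames = list(strains, keys))
  M[cbind(match(calls$strainId, strains), match(key, keys))] <- 1
  M <- M[, , drop = FALSE]
  Mc <- sweep(M, 2L, colMeans(M))
  k <- min(nComponents, dim(Mc) - 1L)
  if (all(abs(Mc) < 1e-12)) {
    scores <- matrix(0, length(strains), max(k, 1L),
                     dimnames = list(strains, paste0("PC", seq_len(max(k, 1L)))))
    return(list(scores = scores, loadings = NULL, sdev = rep(0, max(k, 1L)),
                keys = keys))
  }
  sv <- svd(Mc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  load <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(scores) <- list(strains, paste0("PC", seq_len(k)))
  dimnames(load) <- list(keys, paste0("PC", seq_len(k)))
  list(scores = scores, loadings = load,
       sdev = sv$d / sqrt(max(1, nrow(M) - 1L)), keys = keys)
}
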