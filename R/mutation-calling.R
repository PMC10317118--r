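#' Call new STR mutations against the local founder haplotype
#'
#' A candidate mutation is a non-missing homozygous strain genotype that
#' matches neither founder allele (under the default rule; set
#' \code{rule = "local-founder"} to call any genotype differing from the
#' local haplotype's founder allele, including ones equal to the other
#' founder's).  Each candidate is assigned to the haplotype block containing
#' the locus; loci in gaps between blocks attach to the nearest block edge
#' in bp, and exact midpoint ties drop the locus for that strain.
#' Heterozygous strain calls are excluded, as are loci whose founder alleles
#' are unresolved or dropped.
#'
#' @param strSE STR genotype experiment (assays \code{a1}, \code{a2}).
#' @param founders a \code{\linkS4class{FounderPanel}} with resolved founder
#'   alleles (after \code{\link{inferMissingFounderStr}} where needed).
#' @param blocks haplotype blocks (\code{\link{buildHaplotypeBlocks}}).
#' @param droppedLoci locus ids to exclude (e.g. modal-rule drops).
#' @param rule candidate definition; \code{"either-founder"} (default)
#'   requires the genotype to match neither founder.
#' @return data.frame of mutation calls: \code{strainId}, \code{locusId},
#'   \code{chrom}, \code{posBp}, \code{motif}, \code{motifLen},
#'   \code{canonicalMotif}, \code{founderLabel}, \code{founderRu},
#'   \code{observedRu}, \code{deltaRu}, \code{direction}.
#' @export
callNewMutations <- function(strSE, founders, blocks,
                             droppedLoci = character(),
                             rule = c("either-founder", "local-founder")) {
  rule <- match.arg(rule)
  st <- founders@strLoci
  a1 <- SummarizedExperiment::assay(strSE, "a1")
  a2 <- SummarizedExperiment::assay(strSE, "a2")
  if (!identical(rownames(a1), st$locusId))
    stop("STR experiment rows must match founder panel loci")
  chrom <- as.character(GenomeInfoDb::seqnames(st))
  if (!all(chrom %in% GenomeInfoDb::seqlevels(founders@markers)))
    stop("STR loci on chromosomes absent from the marker map: ",
         paste(utils::head(setdiff(chrom, GenomeInfoDb::seqlevels(founders@markers)), 3),
               collapse = ", "))
  pos <- GenomicRanges::start(st)
  resolved <- !is.na(st$ruB) & !is.na(st$ruD) & !(st$locusId %in% droppedLoci)
  out <- list()
  for (s in colnames(a1)) {
    hom <- resolved & !is.na(a1[, s]) & !is.na(a2[, s]) & a1[, s] == a2[, s]
    idx <- which(hom)
    if (!length(idx)) next
    lab <- .blockLabelsAt(blocks, s, chrom[idx], pos[idx])
    keep <- !is.na(lab)
    idx <- idx[keep]; lab <- lab[keep]
    if (!length(idx)) next
    fRu <- ifelse(lab == "B", st$ruB[idx], st$ruD[idx])
    oRu <- ifelse(lab == "B", st$ruD[idx], st$ruB[idx])
    obs <- a1[idx, s]
    isMut <- obs != fRu
    if (rule == "either-founder") isMut <- isMut & obs != oRu
    if (!any(isMut)) next
    i <- idx[isMut]
    out[[s]] <- data.frame(
      strainId = s, locusId = st$locusId[i], chrom = chrom[i],
      posBp = pos[i], motif = st$motif[i], motifLen = st$motifLen[i],
      canonicalMotif = st$canonicalMotif[i],
      founderLabel = lab[isMut], founderRu = as.integer(fRu[isMut]),
      observedRu = as.integer(obs[isMut]),
      deltaRu = as.integer(obs[isMut] - fRu[isMut]))
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(strainId = character(), locusId = character(),
               chrom = character(), posBp = integer(), motif = character(),
               motifLen = integer(), canonicalMotif = character(),
               founderLabel = character(), founderRu = integer(),
               observedRu = integer(), deltaRu = integer())
  calls$direction <- ifelse(calls$deltaRu > 0, "expansion", "contraction")
  rownames(calls) <- NULL
  calls
}

#' Remove recurrent mutations shared by many strains
#'
#' Drops every call at a locus where the identical new allele is carried by
#' more than \code{maxStrains} strains; such common alleles have likely been
#' segregating on multiple backgrounds (or reflect founder genotyping
#' error) rather than representing independent new mutations.
#'
#' @param calls mutation call data.frame.
#' @param maxStrains threshold (default 10; an allele in exactly
#'   \code{maxStrains} strains is retained).
#' @return filtered calls.
#' @export
filterRecurrent <- function(calls, maxStrains = 10L) {
  if (!nrow(calls)) return(calls)
  key <- paste(calls$locusId, calls$observedRu, sep = "\r")
  nStr <- vapply(split(calls$strainId, key),
                 function(s) length(unique(s)), integer(1))
  calls[nStr[key] <= maxStrains, , drop = FALSE]
}

#' Flag strains with too few mutations for reliable phenotypes
#'
#' Strains with fewer than \code{minMutations} retained calls are excluded
#' from phenotype computation; their calls stay in the table, flagged via
#' the added \code{strainIncluded} column.
#'
#' @param calls mutation call data.frame (post recurrence filter).
#' @param minMutations minimum call count for inclusion (default 10;
#'   exactly 10 is included).
#' @return list: \code{calls} (with \code{strainIncluded}),
#'   \code{includedStrains}, \code{excludedStrains}.
#' @export
filterStrains <- function(calls, minMutations = 10L) {
  cnt <- table(calls$strainId)
  included <- names(cnt)[cnt >= minMutations]
  excluded <- names(cnt)[cnt < minMutations]
  calls$strainIncluded <- calls$strainId %in% included
  list(calls = calls, includedStrains = included, excludedStrains = excluded)
}

#' Flag strains with an outlier mutation burden within their epoch
#'
#' A strain is flagged when its call count exceeds \code{fold} times the
#' median count of the other strains in the same epoch (strictly greater);
#' single-strain epochs never flag.
#'
#' @param calls mutation call data.frame.
#' @param metadata data.frame with \code{strainId} and \code{epoch} (strains
#'   absent from \code{calls} count zero).
#' @param fold multiplier (default 2).
#' @return character vector of flagged strain ids.
#' @export
flagOutlierStrains <- function(calls, metadata, fold = 2.0) {
  stopifnot(all(c("strainId", "epoch") %in% names(metadata)))
  cnt <- table(factor(calls$strainId, levels = metadata$strainId))
  flagged <- character()
  for (ep in unique(metadata$epoch)) {
    s <- metadata$strainId[metadata$epoch == ep]
    if (length(s) < 2L) next
    for (x in s) {
      med <- stats::median(cnt[setdiff(s, x)])
      if (cnt[x] > fold * med) flagged <- c(flagged, x)
    }
  }
  flagged
}

#' Benchmark mutation calls against a simulation truth table
#'
#' Precision and recall on (strain, locus) pairs, optionally restricted to
#' a set of resolvable loci (loci whose founder alleles could be resolved).
#'
#' @param calls mutation call data.frame.
#' @param truth truth table (\code{strainId}, \code{locusId} columns).
#' @param loci optional locus ids to restrict both sets to.
#' @return list: \code{precision}, \code{recall}, \code{nCalls},
#'   \code{nTruth}, \code{nHit}.
#' @export
benchmarkCalls <- function(calls, truth, loci = NULL) {
  if (!is.null(loci)) {
    calls <- calls[calls$locusId %in% loci, , drop = FALSE]
    truth <- truth[truth$locusId %in% loci, , drop = FALSE]
  }
  ck <- paste(calls$strainId, calls$locusId)
  tk <- paste(truth$strainId, truth$locusId)
  hit <- sum(ck %in% tk)
  list(precision = if (length(ck)) hit / length(ck) else NA_real_,
       recall = if (length(tk)) sum(tk %in% ck) / length(tk) else NA_real_,
       nCalls = length(ck), nTruth = length(tk), nHit = hit)
}
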