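#' Two-sided z-proportion test
#'
#' Pooled two-proportion z test: \code{z = (p1 - p2) / sqrt(p(1-p)(1/n1 +
#' 1/n2))} with the pooled estimate \code{p = (x1+x2)/(n1+n2)} and normal
#' two-sided p-value.  Degenerate pooled proportions (0 or 1) give z = 0,
#' p = 1.  The normal approximation is used regardless of counts; a warning
#' is raised when any expected cell is below 5.
#'
#' @param x1,n1,x2,n2 successes and totals of the two groups.
#' @return list: \code{z}, \code{p}, \code{p1}, \code{p2}, \code{pooled}.
#' @export
zProportionTest <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("group totals must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("successes must lie in [0, n]")
  pool <- (x1 + x2) / (n1 + n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  if (pool <= 0 || pool >= 1)
    return(list(z = 0, p = 1, p1 = p1, p2 = p2, pooled = pool))
  if (min(n1 * pool, n1 * (1 - pool), n2 * pool, n2 * (1 - pool)) < 5)
    warning("expected cell count below 5: normal approximation is poor")
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2, pooled = pool)
}

# per-(strain, locus) genotyped-call table with parent haplotype, parent
# length in bp, and mutation/expansion status; the workhorse behind the
# binned-rate and contrast analyses
.callContext <- function(calls, strSE, founders, blocks,
                         droppedLoci = character()) {
  st <- founders@strLoci
  a1 <- SummarizedExperiment::assay(strSE, "a1")
  a2 <- SummarizedExperiment::assay(strSE, "a2")
  resolved <- which(!is.na(st$ruB) & !is.na(st$ruD) &
                      !(st$locusId %in% droppedLoci))
  chrom <- as.character(GenomeInfoDb::seqnames(st))[resolved]
  pos <- GenomicRanges::start(st)[resolved]
  mutKey <- paste(calls$strainId, calls$locusId)
  expKey <- mutKey[calls$deltaRu > 0]
  parts <- lapply(colnames(a1), function(s) {
    nm <- which(!is.na(a1[resolved, s]))
    if (!length(nm)) return(NULL)
    i <- resolved[nm]
    lab <- .blockLabelsAt(blocks, s, chrom[nm], pos[nm])
    ok <- !is.na(lab)
    i <- i[ok]; lab <- lab[ok]
    fRu <- ifelse(lab == "B", st$ruB[i], st$ruD[i])
    key <- paste(s, st$locusId[i])
    data.table::data.table(
      strainId = s, locusId = st$locusId[i], chrom = chrom[nm][ok],
      motifLen = st$motifLen[i], canonicalMotif = st$canonicalMotif[i],
      haplotype = lab, parentRu = as.integer(fRu),
      parentBp = as.integer(fRu * st$motifLen[i]),
      isMut = key %in% mutKey, isExp = key %in% expKey)
  })
  data.table::rbindlist(parts)
}

#' Binned relative mutation rate and expansion fraction
#'
#' Every non-missing genotyped call is assigned to a parent-length bin
#' (founder allele of the strain's local haplotype, in bp = RU x motif
#' length, or in RU with \code{binByRu}); per bin the relative mutation
#' rate is mutations / genotyped calls and the expansion fraction is
#' expansions / mutations (missing when the bin has no mutations).
#'
#' @param calls mutation call data.frame (retained calls).
#' @param strSE STR genotype experiment.
#' @param founders resolved \code{\linkS4class{FounderPanel}}.
#' @param blocks haplotype blocks.
#' @param binWidthBp bin width (bp by default, RU when \code{binByRu}).
#' @param groupBy stratification: \code{"none"}, \code{"motifLen"},
#'   \code{"canonicalMotif"}, \code{"haplotype"} (B vs D at
#'   \code{focalMarker}) or \code{"chromClass"} (autosome / X / Y).
#' @param focalMarker marker id for \code{groupBy = "haplotype"}.
#' @param fls \code{\linkS4class{FounderLabelSet}} (labels at
#'   \code{focalMarker}) for \code{groupBy = "haplotype"}.
#' @param droppedLoci locus ids to exclude.
#' @param binByRu bin by repeat-unit count instead of bp.
#' @return data.frame: \code{group}, \code{binStart}, \code{binMid},
#'   \code{nCalls}, \code{nMutations}, \code{relativeRate},
#'   \code{nExpansions}, \code{expansionFraction}.
#' @export
binnedMutationRate <- function(calls, strSE, founders, blocks,
                               binWidthBp = 4,
                               groupBy = c("none", "motifLen",
                                           "canonicalMotif", "haplotype",
                                           "chromClass"),
                               focalMarker = NULL, fls = NULL,
                               droppedLoci = character(), binByRu = FALSE) {
  groupBy <- match.arg(groupBy)
  if (binWidthBp <= 0) stop("binWidthBp must be positive")
  ctx <- .callContext(calls, strSE, founders, blocks, droppedLoci)
  if (!nrow(ctx)) stop("no genotyped calls with resolvable haplotype")
  len <- if (binByRu) ctx$parentRu else ctx$parentBp
  ctx$bin <- floor(len / binWidthBp) * binWidthBp
  ctx$group <- switch(groupBy,
    none = "all",
    motifLen = as.character(ctx$motifLen),
    canonicalMotif = ctx$canonicalMotif,
    chromClass = ifelse(ctx$chrom %in% c("chrX", "X"), "X",
                        ifelse(ctx$chrom %in% c("chrY", "Y"), "Y", "autosome")),
    haplotype = {
      if (is.null(focalMarker) || is.null(fls))
        stop("groupBy = 'haplotype' needs focalMarker and fls")
      lab <- SummarizedExperiment::assay(fls, "label")[focalMarker, ]
      unname(lab[ctx$strainId])
    })
  ctx <- ctx[!is.na(ctx$group), ]
  isMut <- isExp <- bin <- NULL # data.table NSE
  agg <- ctx[, list(nCalls = .N, nMutations = sum(isMut),
                    nExpansions = sum(isExp)),
             by = c("group", "bin")]
  agg <- agg[order(agg$group, agg$bin), ]
  out <- data.table::setDF(agg)
  names(out)[names(out) == "bin"] <- "binStart"
  out$binMid <- out$binStart + binWidthBp / 2
  out$relativeRate <- out$nMutations / out$nCalls
  out$expansionFraction <- ifelse(out$nMutations > 0,
                                  out$nExpansions / out$nMutations, NA_real_)
  out[, c("group", "binStart", "binMid", "nCalls", "nMutations",
          "relativeRate", "nExpansions", "expansionFraction")]
}

#' Pearson trend of a binned rate with repeat length
#'
#' Correlates bin midpoints with the binned relative mutation rate (or
#' expansion fraction) and reports the t-distribution two-sided p-value.
#' Bins with undefined values are skipped; fewer than 3 usable bins, or a
#' zero-variance rate vector, give a missing result.
#'
#' @param table output of \code{\link{binnedMutationRate}} (one group).
#' @param value \code{"relativeRate"} or \code{"expansionFraction"}.
#' @return list: \code{r}, \code{p}, \code{n} (bins used).
#' @export
lengthTrendCorrelation <- function(table,
                                   value = c("relativeRate",
                                             "expansionFraction")) {
  value <- match.arg(value)
  v <- table[[value]]
  ok <- is.finite(v) & is.finite(table$binMid)
  if (sum(ok) < 3L) return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  x <- table$binMid[ok]; y <- v[ok]
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Haplotype contrast of mutation spectra at a focal locus
#'
#' Splits strains by their founder label at \code{focalMarker} and compares
#' the two groups' pooled expansion fraction (expansions / mutations) and
#' pooled relative mutation rate (mutations / genotyped calls) with the
#' two-sided z-proportion test, overall and within strata (motif length
#' class, canonical motif, chromosome class).  Strains with a missing label
#' at the focal marker are excluded; their number is reported.
#'
#' @param calls mutation call data.frame (retained calls).
#' @param focalMarker marker identifier.
#' @param fls \code{\linkS4class{FounderLabelSet}} with imputed labels.
#' @param strSE STR genotype experiment.
#' @param founders resolved founder panel.
#' @param blocks haplotype blocks.
#' @param strata which stratifications to include beyond \code{"all"}.
#' @param droppedLoci locus ids to exclude.
#' @return data.frame with one row per (measure, stratum): pooled counts
#'   per group, \code{z}, \code{p}; attribute \code{"excludedStrains"}
#'   gives the strains without a focal label.
#' @export
haplotypeContrast <- function(calls, focalMarker, fls, strSE, founders,
                              blocks,
                              strata = c("motifLen", "canonicalMotif",
                                         "chromClass"),
                              droppedLoci = character()) {
  lab <- SummarizedExperiment::assay(fls, "label")[focalMarker, ]
  excluded <- names(lab)[is.na(lab)]
  ctx <- .callContext(calls, strSE, founders, blocks, droppedLoci)
  ctx$focal <- unname(lab[ctx$strainId])
  ctx <- ctx[!is.na(ctx$focal), ]
  ctx$chromClass <- ifelse(ctx$chrom %in% c("chrX", "X"), "X",
                           ifelse(ctx$chrom %in% c("chrY", "Y"), "Y",
                                  "autosome"))
  one <- function(d, stratum, level) {
    gB <- d[d$focal == "B", ]; gD <- d[d$focal == "D", ]
    if (!nrow(gB) || !nrow(gD))
      return(data.frame(measure = c("expansionPropensity", "mutationRate"),
                        stratum = stratum, level = level,
                        xB = NA, nB = NA, xD = NA, nD = NA,
                        z = NA_real_, p = NA_real_,
                        comparable = FALSE))
    rows <- list()
    mB <- sum(gB$isMut); mD <- sum(gD$isMut)
    if (mB >= 1 && mD >= 1) {
      t1 <- zProportionTest(sum(gB$isExp), mB, sum(gD$isExp), mD)
      rows[[1]] <- data.frame(measure = "expansionPropensity",
                              stratum = stratum, level = level,
                              xB = sum(gB$isExp), nB = mB,
                              xD = sum(gD$isExp), nD = mD,
                              z = t1$z, p = t1$p, comparable = TRUE)
    }
    t2 <- zProportionTest(mB, nrow(gB), mD, nrow(gD))
    rows[[length(rows) + 1L]] <- data.frame(
      measure = "mutationRate", stratum = stratum, level = level,
      xB = mB, nB = nrow(gB), xD = mD, nD = nrow(gD),
      z = t2$z, p = t2$p, comparable = TRUE)
    do.call(rbind, rows)
  }
  out <- list(one(ctx, "all", "all"))
  for (s in strata) {
    col <- switch(s, motifLen = "motifLen", canonicalMotif = "canonicalMotif",
                  chromClass = "chromClass")
    for (lev in sort(unique(as.character(ctx[[col]]))))
      out[[length(out) + 1L]] <-
        one(ctx[as.character(ctx[[col]]) == lev, ], s, lev)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excludedStrains") <- excluded
  res
}
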