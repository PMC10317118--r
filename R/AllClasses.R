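#' FounderPanel: founder SNP alleles and STR reference on a shared marker map
#'
#' Container for the two-founder reference of an RI panel: SNP marker
#' positions with founder alleles and genetic-map coordinates, and STR loci
#' with motif and founder repeat-unit (RU) lengths.  Founder RU lengths may
#' be \code{NA} (ungenotyped founder); \code{\link{inferMissingFounderStr}}
#' resolves or drops such loci.  Panels produced by
#' \code{\link{generateFounders}} additionally carry \code{trueRuB} /
#' \code{trueRuD} metadata columns holding the complete simulated founder
#' alleles for benchmarking; real panels do not have them.
#'
#' @slot markers \code{GRanges} of SNP markers (width 1) with metadata
#'   columns \code{alleleB}, \code{alleleD} (founder bases) and \code{cM}
#'   (genetic-map position, non-decreasing with bp within a chromosome).
#' @slot strLoci \code{GRanges} of STR loci with metadata columns
#'   \code{locusId}, \code{motif}, \code{motifLen} (2-6), \code{canonicalMotif},
#'   \code{ruB}, \code{ruD} (integer RU counts, \code{NA} = missing founder).
#'
#' @export
setClass("FounderPanel",
  representation(markers = "GRanges", strLoci = "GRanges"))

setValidity("FounderPanel", function(object) {
  msg <- character()
  mk <- object@markers
  st <- object@strLoci
  need <- c("alleleB", "alleleD", "cM")
  if (!all(need %in% names(S4Vectors::mcols(mk))))
    msg <- c(msg, "markers must have mcols alleleB, alleleD, cM")
  needs <- c("locusId", "motif", "motifLen", "canonicalMotif", "ruB", "ruD")
  if (!all(needs %in% names(S4Vectors::mcols(st))))
    msg <- c(msg, "strLoci must have mcols locusId, motif, motifLen, canonicalMotif, ruB, ruD")
  if (!length(msg)) {
    ml <- st$motifLen
    if (any(ml < 2L | ml > 6L)) msg <- c(msg, "motifLen must be in [2, 6]")
    if (any(st$ruB < 1L, na.rm = TRUE) || any(st$ruD < 1L, na.rm = TRUE))
      msg <- c(msg, "founder RU lengths must be >= 1 where present")
    if (!S4Vectors::isSorted(mk))
      msg <- c(msg, "markers must be sorted by (chromosome, position)")
    # cM non-decreasing with bp within each chromosome
    sp <- split(mk$cM, as.character(GenomeInfoDb::seqnames(mk)))
    if (any(vapply(sp, is.unsorted, logical(1))))
      msg <- c(msg, "cM positions must be non-decreasing within a chromosome")
    if (anyDuplicated(st$locusId)) msg <- c(msg, "locusId must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FounderPanel marker \code{GRanges} accessor
#' @param x,object a \code{FounderPanel}
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname FounderPanel
#' @export
setMethod("markers", "FounderPanel", function(x) x@markers)

#' @describeIn FounderPanel STR locus \code{GRanges} accessor
#' @export
setGeneric("strLoci", function(x) standardGeneric("strLoci"))

#' @rdname FounderPanel
#' @export
setMethod("strLoci", "FounderPanel", function(x) x@strLoci)

setMethod("show", "FounderPanel", function(object) {
  cat("FounderPanel with", length(object@markers), "SNP markers and",
      length(object@strLoci), "STR loci on",
      length(GenomeInfoDb::seqlevels(object@markers)), "chromosomes\n")
  nm <- sum(is.na(object@strLoci$ruB)) + sum(is.na(object@strLoci$ruD))
  cat("  informative SNPs:",
      sum(object@markers$alleleB != object@markers$alleleD),
      "| polymorphic STRs:",
      sum(!is.na(object@strLoci$ruB) & !is.na(object@strLoci$ruD) &
            object@strLoci$ruB != object@strLoci$ruD),
      "| missing founder alleles:", nm, "\n")
})

#' RIPanelSim: a simulated RI panel with full ground truth
#'
#' Result of \code{\link{simulatePanel}}: noise-free diploid genotypes for
#' every strain, plus the simulation truth (final founder mosaics and the
#' table of STR mutations that drifted to fixation) used for benchmarking.
#'
#' @slot founders the \code{\linkS4class{FounderPanel}} used (released view,
#'   i.e. with any masked founder alleles set to \code{NA}).
#' @slot snp \code{RangedSummarizedExperiment}; assay \code{"geno"} is a
#'   marker x strain character matrix with values \code{"B"}, \code{"H"},
#'   \code{"D"} or \code{NA} (uninformative markers are \code{NA}).
#' @slot str \code{RangedSummarizedExperiment}; assays \code{"a1"},
#'   \code{"a2"} are locus x strain integer RU counts (noise free).
#' @slot truth \code{data.frame} of fixed mutations: \code{strainId},
#'   \code{locusId}, \code{founderLabel}, \code{founderRu} (the transmitted
#'   ancestral-stock allele), \code{finalRu}.  Only loci homozygous for both
#'   sequence and founder label are recorded: unfixed loci have no single
#'   final allele and are excluded from the pipeline's observable by the
#'   heterozygote rule.
#' @slot trueMarkerLabels marker x strain character matrix of true diploid
#'   founder labels (\code{"B"}, \code{"H"}, \code{"D"}).
#' @slot trueStrLabels STR-locus x strain character matrix of true labels.
#' @slot params list: the breeding plan, mutation model, seed, and the
#'   per-epoch ancestral-stock founder alleles.
#'
#' @export
setClass("RIPanelSim",
  representation(founders = "FounderPanel", snp = "RangedSummarizedExperiment",
                 str = "RangedSummarizedExperiment", truth = "data.frame",
                 trueMarkerLabels = "matrix", trueStrLabels = "matrix",
                 params = "list"))

setValidity("RIPanelSim", function(object) {
  msg <- character()
  if (!identical(colnames(object@snp), colnames(object@str)))
    msg <- c(msg, "snp and str experiments must share strain columns")
  if (nrow(object@snp) != length(object@founders@markers))
    msg <- c(msg, "snp rows must match founder markers")
  if (nrow(object@str) != length(object@founders@strLoci))
    msg <- c(msg, "str rows must match founder STR loci")
  if (length(msg)) msg else TRUE
})

#' @describeIn RIPanelSim founder panel accessor
#' @param x,object an \code{RIPanelSim}
#' @export
setGeneric("founderPanel", function(x) standardGeneric("founderPanel"))

#' @rdname RIPanelSim
#' @export
setMethod("founderPanel", "RIPanelSim", function(x) x@founders)

#' @describeIn RIPanelSim SNP genotype \code{SummarizedExperiment} accessor
#' @export
setGeneric("snpGeno", function(x) standardGeneric("snpGeno"))

#' @rdname RIPanelSim
#' @export
setMethod("snpGeno", "RIPanelSim", function(x) x@snp)

#' @describeIn RIPanelSim STR genotype \code{RangedSummarizedExperiment} accessor
#' @export
setGeneric("strGeno", function(x) standardGeneric("strGeno"))

#' @rdname RIPanelSim
#' @export
setMethod("strGeno", "RIPanelSim", function(x) x@str)

#' @describeIn RIPanelSim truth-table accessor
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname RIPanelSim
#' @export
setMethod("truthTable", "RIPanelSim", function(x) x@truth)

setMethod("show", "RIPanelSim", function(object) {
  cd <- SummarizedExperiment::colData(object@str)
  cat("RIPanelSim:", ncol(object@snp), "strains,",
      nrow(object@snp), "SNP markers,", nrow(object@str), "STR loci\n")
  cat("  epochs:", paste(unique(as.character(cd$epoch)), collapse = ", "),
      "| fixed mutations in truth table:", nrow(object@truth), "\n")
})

#' FounderLabelSet: per-strain founder labels with HMM posteriors
#'
#' A \code{RangedSummarizedExperiment} (markers x strains) holding the
#' founder-label track of an RI panel.  Assay \code{"label"} is a character
#' matrix with values \code{"B"}, \code{"D"} or \code{NA} (missing);
#' after \code{\link{imputeFounderLabels}} an assay \code{"probB"} holds the
#' marginal posterior probability of the B state from the two-state HMM.
#'
#' @export
setClass("FounderLabelSet", contains = "RangedSummarizedExperiment")

setValidity("FounderLabelSet", function(object) {
  msg <- character()
  if (!"label" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'label' required")
  else {
    lab <- SummarizedExperiment::assay(object, "label")
    bad <- !is.na(lab) & !(lab %in% c("B", "D"))
    if (any(bad)) msg <- c(msg, "labels must be 'B', 'D' or NA")
  }
  if (!"cM" %in% names(S4Vectors::mcols(SummarizedExperiment::rowRanges(object))))
    msg <- c(msg, "rowRanges must carry a cM column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FounderLabelSet", function(object) {
  lab <- SummarizedExperiment::assay(object, "label")
  cat("FounderLabelSet:", nrow(object), "markers x", ncol(object), "strains;",
      sprintf("%.1f%% labels missing", 100 * mean(is.na(lab))), "\n")
  if ("probB" %in% SummarizedExperiment::assayNames(object))
    cat("  HMM posteriors present (assay 'probB')\n")
})

#' QTLScan: a single-locus genome scan result
#'
#' @slot lod \code{data.frame} with columns \code{marker}, \code{chrom},
#'   \code{posBp}, \code{lod} for every scanned marker.
#' @slot h2 named numeric: null-model heritability per chromosome (under the
#'   chromosome's LOCO kinship).
#' @slot nStrains number of strains analysed.
#' @slot covariateNames covariate column names (intercept excluded).
#' @slot thresholds named numeric: genome-wide LOD thresholds per alpha
#'   (empty when no permutations were run).
#' @slot permMax numeric: genome-wide maximum LOD of each permutation.
#' @slot peaks \code{data.frame}: per-chromosome peak marker, LOD and the
#'   1.5-LOD support interval.
#'
#' @export
setClass("QTLScan",
  representation(lod = "data.frame", h2 = "numeric", nStrains = "integer",
                 covariateNames = "character", thresholds = "numeric",
                 permMax = "numeric", peaks = "data.frame"))

setValidity("QTLScan", function(object) {
  msg <- character()
  if (!all(c("marker", "chrom", "posBp", "lod") %in% names(object@lod)))
    msg <- c(msg, "lod must have columns marker, chrom, posBp, lod")
  if (any(object@lod$lod < -1e-8, na.rm = TRUE))
    msg <- c(msg, "LOD scores must be non-negative (up to tolerance)")
  if (length(object@thresholds) > 1L) {
    a <- as.numeric(names(object@thresholds))
    if (is.unsorted(rev(object@thresholds[order(a)])))
      msg <- c(msg, "thresholds must be decreasing in alpha")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn QTLScan LOD curve accessor
#' @param x,object a \code{QTLScan}
#' @export
setGeneric("lodCurve", function(x) standardGeneric("lodCurve"))

#' @rdname QTLScan
#' @export
setMethod("lodCurve", "QTLScan", function(x) x@lod)

#' @describeIn QTLScan permutation threshold accessor (named by alpha)
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname QTLScan
#' @export
setMethod("thresholds", "QTLScan", function(x) x@thresholds)

#' @describeIn QTLScan per-chromosome peak table accessor
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname QTLScan
#' @export
setMethod("peaks", "QTLScan", function(x) x@peaks)

setMethod("show", "QTLScan", function(object) {
  i <- which.max(object@lod$lod)
  cat("QTLScan:", nrow(object@lod), "markers,", object@nStrains, "strains\n")
  cat(sprintf("  max LOD %.2f at %s (%s:%d)\n", object@lod$lod[i],
              object@lod$marker[i], object@lod$chrom[i], object@lod$posBp[i]))
  if (length(object@thresholds))
    cat("  thresholds:", paste(sprintf("alpha=%s: %.2f",
        names(object@thresholds), object@thresholds), collapse = "; "), "\n")
})
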