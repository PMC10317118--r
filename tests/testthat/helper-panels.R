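# shared fixture builders: everything is generated in code at test time

tinyPanel <- function(seed = 42, ...) {
  generateFounders(nChromosomes = 2L, nMarkersPerChrom = 40L,
                   nStrsPerChrom = 150L, chromLengthBp = 5e7,
                   chromLengthCM = 50, seed = seed, ...)
}

tinySim <- function(fp = tinyPanel(), gens = c(20L, 40L), nStrains = 6L,
                    model = mutationModel(baseRate = 5e-4), seed = 5, ...) {
  plan <- breedingPlan(data.frame(epochId = paste0("e", seq_along(gens)),
                                  nStrains = nStrains,
                                  nGenerations = gens))
  simulatePanel(fp, plan, model, seed = seed, ...)
}

runInference <- function(r, fp, errorRate = 0.002) {
  fls <- imputeFounderLabels(assignFounderLabels(r$snp, fp),
                             errorRate = errorRate)
  blocks <- buildHaplotypeBlocks(fls)
  inf <- inferMissingFounderStr(fp, r$str, blocks)
  list(fls = fls, blocks = blocks, inf = inf)
}

# a hand-specified founder panel on one chromosome
manualPanel <- function(markerPos, strPos, ruB, ruD, motif = "AT",
                        chrom = "chr1", cMPerMb = 0.5) {
  mk <- GenomicRanges::GRanges(chrom, IRanges::IRanges(markerPos, width = 1L),
                               alleleB = "A", alleleD = "G",
                               cM = markerPos / 1e6 * cMPerMb)
  names(mk) <- sprintf("M%03d", seq_along(markerPos))
  motif <- rep_len(motif, length(strPos))
  id <- sprintf("S%03d", seq_along(strPos))
  st <- GenomicRanges::GRanges(chrom, IRanges::IRanges(strPos, width = 1L),
                               locusId = id, motif = motif,
                               motifLen = nchar(motif),
                               canonicalMotif = canonicalMotif(motif),
                               ruB = as.integer(ruB), ruD = as.integer(ruD),
                               trueRuB = as.integer(ruB),
                               trueRuD = as.integer(ruD))
  names(st) <- id
  methods::new("FounderPanel", markers = mk, strLoci = st)
}

# STR experiment from allele matrices (loci x strains)
manualStrSE <- function(fp, a1, a2 = a1) {
  st <- strLoci(fp)
  strains <- colnames(a1)
  dimnames(a1) <- dimnames(a2) <- list(st$locusId, strains)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(a1 = a1, a2 = a2), rowRanges = st,
    colData = S4Vectors::DataFrame(strainId = strains, row.names = strains))
}

# label set from a markers x strains character matrix
manualLabelSet <- function(fp, lab) {
  mk <- markers(fp)
  dimnames(lab) <- list(names(mk), colnames(lab))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(label = lab), rowRanges = mk,
    colData = S4Vectors::DataFrame(strainId = colnames(lab),
                                   row.names = colnames(lab)))
  methods::new("FounderLabelSet", se)
}

manualBlocks <- function(chrom, start, end, strain, label) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strain = strain, label = label)
}

# simple mutation-call table builder for filter tests
manualCalls <- function(strainId, locusId, deltaRu = 1L,
                        observedRu = 10L + deltaRu, founderRu = 10L,
                        motifLen = 4L, chrom = "chr1") {
  n <- max(length(strainId), length(locusId))
  data.frame(strainId = rep_len(strainId, n),
             locusId = rep_len(locusId, n), chrom = rep_len(chrom, n),
             posBp = rep_len(1000L, n), motif = rep_len("AGAT", n),
             motifLen = rep_len(motifLen, n),
             canonicalMotif = rep_len("AAGT", n),
             founderLabel = rep_len("B", n),
             founderRu = rep_len(as.integer(founderRu), n),
             observedRu = rep_len(as.integer(observedRu), n),
             deltaRu = rep_len(as.integer(deltaRu), n),
             direction = ifelse(rep_len(deltaRu, n) > 0, "expansion",
                                "contraction"))
}
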