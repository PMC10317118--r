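# one full-scale end-to-end replicate of the study design: 150 strains in
# five epochs (20-100 generations), 5 chromosomes x 200 markers, 5000 STR
# loci, expansion bias controlled by the mutator locus genotype
runEndToEnd <- function(seed, expansionProbB = 0.6, expansionProbD = 0.4,
                        missingCallRate = 0.02, hetErrorRate = 0.005,
                        nPerm = 100L) {
  fp <- generateFounders(seed = seed)
  model <- mutationModel(expansionProbB = expansionProbB,
                         expansionProbD = expansionProbD)
  sim <- simulatePanel(fp, breedingPlan(), model, seed = seed + 1L)
  r <- renderPanel(sim, missingCallRate = missingCallRate,
                   hetErrorRate = hetErrorRate, seed = seed + 2L)
  fls <- imputeFounderLabels(assignFounderLabels(r$snp, fp))
  blocks <- buildHaplotypeBlocks(fls)
  inf <- inferMissingFounderStr(fp, r$str, blocks)
  calls <- callNewMutations(r$str, inf$founders, blocks,
                            droppedLoci = inf$droppedLoci)
  calls <- filterRecurrent(calls, 10L)
  outliers <- flagOutlierStrains(calls, r$metadata, 2.0)
  calls <- calls[!(calls$strainId %in% outliers), , drop = FALSE]
  fs <- filterStrains(calls, 10L)
  retained <- fs$calls[fs$calls$strainIncluded, , drop = FALSE]
  pheno <- mutatorPhenotypes(retained, r$str, strains = fs$includedStrains)
  prob <- founderGenoProb(fls)
  kinship <- calcKinshipLoco(prob)
  y <- stats::setNames(pheno$expansionPropensity, pheno$strainId)
  covar <- as.matrix(pheno[, "nGenerations", drop = FALSE])
  scan <- if (nPerm > 0L)
    scanQTL(prob, y, covariates = covar, kinship = kinship,
            nPerm = nPerm, alphas = 0.05, seed = seed + 3L) else NULL
  trueMarker <- strpanel:::.resolveMutatorLocus(model, fp)$mutatorLocus
  mk <- markers(fp)[trueMarker]
  list(sim = sim, render = r, founders = inf$founders, fls = fls,
       blocks = blocks, inf = inf, calls = retained, pheno = pheno,
       scan = scan, trueMarker = trueMarker,
       trueChrom = as.character(GenomeInfoDb::seqnames(mk)),
       truePos = GenomicRanges::start(mk))
}

# detection summary for one replicate: genome-wide peak, threshold,
# whether the peak is significant on the true chromosome, and whether the
# 1.5-LOD interval there covers the true position
detectQTL <- function(rep) {
  lod <- lodCurve(rep$scan)
  thr <- thresholds(rep$scan)[["0.05"]]
  peak <- lod[which.max(lod$lod), ]
  pk <- peaks(rep$scan)
  onTrue <- pk[pk$chrom == rep$trueChrom, ]
  list(maxLod = peak$lod, threshold = thr,
       detectedAnywhere = peak$lod > thr,
       detectedOnTrueChrom = peak$lod > thr && peak$chrom == rep$trueChrom,
       covered = onTrue$intervalStartBp <= rep$truePos &&
         onTrue$intervalEndBp >= rep$truePos)
}
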