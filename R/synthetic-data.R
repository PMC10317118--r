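#' Stepwise STR mutation model parameters
#'
#' Parameters of the per-transmission STR mutation process used by the
#' simulator.  A transmission mutates a locus with probability
#' \code{min(rateCap, baseRate * exp(lengthSlope * len_bp))} where
#' \code{len_bp} is the transmitting parent's current allele length in base
#' pairs (RU count x motif length); the step size is \code{1 + Geometric(p)}
#' repeat units and the step is an expansion with probability
#' \code{expansionProbB} or \code{expansionProbD} according to the
#' transmitting parent's genotype at \code{mutatorLocus} (heterozygous
#' parents use the mean of the two).  Results are floored at 1 RU.
#'
#' @param baseRate per-transmission mutation probability at length 0 bp.
#' @param lengthSlope rate multiplier exponent per bp of parent length.
#' @param rateCap upper clip for the per-transmission rate.
#' @param stepGeometricP geometric parameter of the step-size law.
#' @param expansionProbB,expansionProbD expansion probability for
#'   transmissions from parents carrying the B (resp. D) haplotype at the
#'   mutator locus; in (0, 1).
#' @param mutatorLocus marker identifier of the mutator locus, or \code{NULL}
#'   to place it at the central marker of the middle chromosome when the
#'   model is first used with a panel.
#' @return a list of class \code{"MutationModel"}.
#' @export
mutationModel <- function(baseRate = 1e-4, lengthSlope = 0.04,
                          rateCap = 0.01, stepGeometricP = 0.8,
                          expansionProbB = 0.6, expansionProbD = 0.4,
                          mutatorLocus = NULL) {
  stopifnot(baseRate >= 0, baseRate < 1, rateCap > 0, rateCap <= 1,
            stepGeometricP > 0, stepGeometricP <= 1,
            expansionProbB > 0, expansionProbB < 1,
            expansionProbD > 0, expansionProbD < 1)
  structure(list(baseRate = baseRate, lengthSlope = lengthSlope,
                 rateCap = rateCap, stepGeometricP = stepGeometricP,
                 expansionProbB = expansionProbB,
                 expansionProbD = expansionProbD,
                 mutatorLocus = mutatorLocus),
            class = "MutationModel")
}

#' Breeding plan for a multi-epoch RI panel
#'
#' @param epochs data.frame with columns \code{epochId}, \code{nStrains},
#'   \code{nGenerations} (generation 1 is the F1 cross; subsequent
#'   generations are sib-mating rounds).  The default emulates a five-epoch
#'   panel with inbreeding depths spanning 20-100 generations.
#' @return the validated data.frame.
#' @export
breedingPlan <- function(epochs = data.frame(
    epochId = paste0("epoch", 1:5), nStrains = 30L,
    nGenerations = c(20L, 40L, 60L, 80L, 100L))) {
  stopifnot(all(c("epochId", "nStrains", "nGenerations") %in% names(epochs)),
            all(epochs$nGenerations >= 1L), all(epochs$nStrains >= 1L),
            !anyDuplicated(epochs$epochId))
  epochs
}

#' Canonical form of an STR motif
#'
#' The lexicographically smallest string among all rotations of the motif
#' and of its reverse complement, so that e.g. TCTA, AGAT and ATCT share one
#' canonical key.
#'
#' @param motif character vector of DNA motifs.
#' @return character vector of canonical motifs.
#' @export
canonicalMotif <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(motif, function(m) {
    ch <- strsplit(m, "")[[1]]
    rc <- rev(unname(comp[ch]))
    rots <- function(x) vapply(seq_along(x), function(i)
      paste(x[c(i:length(x), seq_len(i - 1L))], collapse = ""), character(1))
    min(c(rots(ch), rots(rc)))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a two-founder reference panel
#'
#' Draws SNP markers and STR loci on a shared marker map.  Genetic positions
#' are linear in bp (constant recombination rate), so cM is non-decreasing
#' with bp by construction.  A fraction of STR loci has one founder allele
#' masked to \code{NA} in the released \code{ruB}/\code{ruD} columns; the
#' complete simulated alleles are kept in \code{trueRuB}/\code{trueRuD} for
#' benchmarking and as the simulator's transmission source.
#'
#' @param nChromosomes,nMarkersPerChrom,nStrsPerChrom positive counts.
#' @param fracSnpInformative fraction of SNPs with distinct founder alleles.
#' @param fracStrPolymorphic fraction of STRs whose founder alleles differ
#'   (offset 3-5 RU, random sign).
#' @param fracFounderMissing fraction of STR loci with one founder allele
#'   masked in the released panel.
#' @param chromLengthBp,chromLengthCM physical and genetic chromosome length.
#' @param seed integer seed (\code{NULL} = use current RNG state).
#' @return a \code{\linkS4class{FounderPanel}}.
#' @export
generateFounders <- function(nChromosomes = 5L, nMarkersPerChrom = 200L,
                             nStrsPerChrom = 1000L,
                             fracSnpInformative = 0.9,
                             fracStrPolymorphic = 0.3,
                             fracFounderMissing = 0.05,
                             chromLengthBp = 1e8, chromLengthCM = 60,
                             seed = NULL) {
  if (nChromosomes < 1L || nMarkersPerChrom < 1L || nStrsPerChrom < 1L)
    stop("counts must be positive")
  stopifnot(fracSnpInformative >= 0, fracSnpInformative <= 1,
            fracStrPolymorphic >= 0, fracStrPolymorphic <= 1,
            fracFounderMissing >= 0, fracFounderMissing <= 1)
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", seq_len(nChromosomes))
  bases <- c("A", "C", "G", "T")

  mk <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(as.integer(chromLengthBp) - 2000L, nMarkersPerChrom))
    data.frame(chrom = ch, pos = pos)
  }))
  nM <- nrow(mk)
  mk$cM <- mk$pos / chromLengthBp * chromLengthCM
  nInf <- round(fracSnpInformative * nM)
  informative <- rep(FALSE, nM)
  if (nInf > 0) informative[sample.int(nM, nInf)] <- TRUE
  aB <- sample(bases, nM, replace = TRUE)
  aD <- aB
  aD[informative] <- vapply(aB[informative],
                            function(b) sample(setdiff(bases, b), 1L),
                            character(1))
  markers <- GenomicRanges::GRanges(mk$chrom,
                                    IRanges::IRanges(mk$pos, width = 1L),
                                    alleleB = aB, alleleD = aD, cM = mk$cM)
  names(markers) <- sprintf("M_%s_%04d", mk$chrom,
                            rep(seq_len(nMarkersPerChrom), nChromosomes))

  st <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(as.integer(chromLengthBp) - 2000L, nStrsPerChrom))
    data.frame(chrom = ch, pos = pos)
  }))
  nS <- nrow(st)
  mlen <- sample(c(2L, 3L, 4L), nS, replace = TRUE, prob = c(0.25, 0.2, 0.55))
  motif <- vapply(mlen, function(k) {
    repeat {
      m <- paste(sample(bases, k, replace = TRUE), collapse = "")
      if (length(unique(strsplit(m, "")[[1]])) > 1L) return(m)
    }
  }, character(1))
  ruB <- sample(6:20, nS, replace = TRUE)
  ruD <- ruB
  poly <- rep(FALSE, nS)
  nPoly <- round(fracStrPolymorphic * nS)
  if (nPoly > 0) poly[sample.int(nS, nPoly)] <- TRUE
  offs <- sample(3:5, nS, replace = TRUE) * sample(c(-1L, 1L), nS, replace = TRUE)
  ruD[poly] <- pmax(1L, ruB[poly] + offs[poly])
  relB <- ruB; relD <- ruD
  nMiss <- round(fracFounderMissing * nS)
  miss <- rep(FALSE, nS)
  if (nMiss > 0) miss[sample.int(nS, nMiss)] <- TRUE
  whichF <- runif(nS) < 0.5
  relB[miss & whichF] <- NA_integer_
  relD[miss & !whichF] <- NA_integer_
  locusId <- sprintf("STR_%s_%d", st$chrom, st$pos)
  strLoci <- GenomicRanges::GRanges(
    st$chrom, IRanges::IRanges(st$pos, width = 1L),
    locusId = locusId, motif = motif, motifLen = mlen,
    canonicalMotif = canonicalMotif(motif),
    ruB = relB, ruD = relD, trueRuB = ruB, trueRuD = ruD)
  names(strLoci) <- locusId
  sl <- stats::setNames(rep(chromLengthBp, nChromosomes), chroms)
  GenomeInfoDb::seqlengths(markers) <- sl
  GenomeInfoDb::seqlengths(strLoci) <- sl
  methods::new("FounderPanel", markers = markers, strLoci = strLoci)
}

# Combined (chromosome, position)-ordered layout of markers + STR loci with
# 0-based indices for the compiled breeding core.  STR cM positions are
# interpolated from the marker map.
.panelLayout <- function(founders) {
  mk <- founders@markers; st <- founders@strLoci
  chroms <- GenomeInfoDb::seqlevels(mk)
  chrM <- as.character(GenomeInfoDb::seqnames(mk))
  chrS <- as.character(GenomeInfoDb::seqnames(st))
  posM <- GenomicRanges::start(mk); posS <- GenomicRanges::start(st)
  cmS <- numeric(length(st))
  for (ch in chroms) {
    im <- chrM == ch; is <- chrS == ch
    if (!any(is)) next
    if (sum(im) >= 2L) {
      cmS[is] <- stats::approx(posM[im], mk$cM[im], xout = posS[is],
                               rule = 2, ties = "ordered")$y
    } else cmS[is] <- if (any(im)) mk$cM[im][1] else 0
  }
  df <- data.frame(chrom = c(chrM, chrS), pos = c(posM, posS),
                   cM = c(mk$cM, cmS),
                   isStr = rep(c(FALSE, TRUE), c(length(mk), length(st))),
                   srcIdx = c(seq_along(mk), seq_along(st)))
  o <- order(match(df$chrom, chroms), df$pos)
  df <- df[o, ]
  offsets <- c(0L, cumsum(tabulate(match(df$chrom, chroms), length(chroms))))
  list(chroms = chroms, chromOffsets = as.integer(offsets),
       cmPos = df$cM, strIdx = as.integer(ifelse(df$isStr, df$srcIdx - 1L, -1L)),
       rowIsStr = df$isStr, srcIdx = df$srcIdx)
}

.resolveMutatorLocus <- function(model, founders) {
  if (is.null(model$mutatorLocus)) {
    mk <- founders@markers
    lev <- GenomeInfoDb::seqlevels(mk)
    midChrom <- lev[ceiling(length(lev) / 2)]
    onC <- which(as.character(GenomeInfoDb::seqnames(mk)) == midChrom)
    mid <- onC[which.min(abs(GenomicRanges::start(mk)[onC] -
                               stats::median(GenomicRanges::start(mk)[onC])))]
    model$mutatorLocus <- names(mk)[mid]
  }
  model
}

.mutatorLocusIndex <- function(model, founders, layout) {
  if (is.null(model$mutatorLocus)) return(-1L)
  mIdx <- match(model$mutatorLocus, names(founders@markers))
  if (is.na(mIdx)) stop("mutatorLocus '", model$mutatorLocus,
                        "' is not a marker in the panel")
  as.integer(which(!layout$rowIsStr & layout$srcIdx == mIdx) - 1L)
}

#' Apply the stepwise mutation model to parental STR alleles
#'
#' Reference R implementation of the per-transmission mutation law (the
#' breeding simulator applies the identical law in compiled code).
#'
#' @param parentRu integer vector of parental repeat-unit counts (>= 1).
#' @param motifLen motif length(s) in bp (recycled).
#' @param mutatorGenotype \code{"B"}, \code{"D"} or \code{"H"}: the
#'   transmitting parent's genotype at the mutator locus.
#' @param model a \code{\link{mutationModel}}.
#' @return integer vector of transmitted repeat-unit counts.
#' @export
mutateStr <- function(parentRu, motifLen, mutatorGenotype = "H",
                      model = mutationModel()) {
  if (any(parentRu < 1L)) stop("parentRu must be >= 1")
  n <- length(parentRu)
  motifLen <- rep_len(motifLen, n)
  pExp <- switch(mutatorGenotype,
                 B = model$expansionProbB, D = model$expansionProbD,
                 H = (model$expansionProbB + model$expansionProbD) / 2,
                 stop("mutatorGenotype must be 'B', 'D' or 'H'"))
  rate <- pmin(model$rateCap,
               model$baseRate * exp(model$lengthSlope * parentRu * motifLen))
  hit <- stats::runif(n) < rate
  out <- as.integer(parentRu)
  if (!any(hit)) return(out)
  k <- sum(hit)
  step <- 1L + stats::rgeom(k, model$stepGeometricP)
  sgn <- ifelse(stats::runif(k) < pExp, 1L, -1L)
  out[hit] <- pmax(1L, out[hit] + sgn * step)
  out
}

#' Simulate one RI strain genome
#'
#' F1 (B x D) cross followed by \code{nGenerations - 1} rounds of sib-mating
#' on an explicit two-line pedigree.  Meiosis places crossovers as a Poisson
#' process on the cM scale (Haldane, no interference); every parent-to-gamete
#' transmission may mutate each STR under the stepwise model, with the
#' expansion bias read from the transmitting parent's genotype at the
#' mutator locus.
#'
#' @param founders a \code{\linkS4class{FounderPanel}}.
#' @param nGenerations total generations (1 = the F1 itself).
#' @param model a \code{\link{mutationModel}}.
#' @param seed optional integer seed.
#' @param stockB,stockD founder-stock STR alleles to transmit (defaults:
#'   the panel's complete simulated alleles).
#' @return list with \code{markerLabels} / \code{strLabels} (character
#'   vectors of diploid founder labels \code{"B"}/\code{"H"}/\code{"D"}, in
#'   panel order) and \code{strLen} (STR x 2 integer matrix of repeat
#'   lengths, haplotype-phased with the labels).
#' @export
simulateStrain <- function(founders, nGenerations, model = mutationModel(),
                           seed = NULL, stockB = NULL, stockD = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nGenerations >= 1L)
  layout <- .panelLayout(founders)
  model <- .resolveMutatorLocus(model, founders)
  st <- founders@strLoci
  if (is.null(stockB)) stockB <- st$trueRuB
  if (is.null(stockD)) stockD <- st$trueRuD
  if (is.null(stockB) || is.null(stockD) || anyNA(stockB) || anyNA(stockD))
    stop("complete founder stock alleles required for simulation")
  mutIdx <- .mutatorLocusIndex(model, founders, layout)
  res <- .simulate_strain_cpp(layout$chromOffsets, layout$cmPos,
                              layout$strIdx, as.integer(st$motifLen),
                              as.integer(stockB), as.integer(stockD),
                              as.integer(nGenerations), mutIdx,
                              model$baseRate, model$lengthSlope,
                              model$rateCap, model$stepGeometricP,
                              model$expansionProbB, model$expansionProbD)
  code <- c("B", "H", "D")[res$label[, 1] + res$label[, 2] + 1L]
  isS <- layout$rowIsStr
  list(markerLabels = code[!isS][order(layout$srcIdx[!isS])],
       strLabels = code[isS][order(layout$srcIdx[isS])],
       strLen = res$strLen)
}

#' Simulate a complete multi-epoch RI panel
#'
#' Breeds every strain of the plan independently from the founder cross and
#' assembles noise-free genotype tables plus the simulation truth.  Epoch
#' sharing of mutations can be emulated by letting the ancestral founder
#' stocks drift between epochs: before each epoch,
#' \code{stockTransmissionsPerEpoch} rounds of the mutation process are
#' applied cumulatively to each founder stock haplotype, so successive
#' epochs inherit (and share) earlier stock mutations.
#'
#' @param founders a \code{\linkS4class{FounderPanel}} (from
#'   \code{\link{generateFounders}}).
#' @param plan a \code{\link{breedingPlan}}.
#' @param model a \code{\link{mutationModel}}.
#' @param seed integer seed; the whole panel is deterministic given it.
#' @param stockTransmissionsPerEpoch non-negative integer (default 0: all
#'   epochs transmit the reference founder alleles).
#' @return an \code{\linkS4class{RIPanelSim}}.
#' @export
simulatePanel <- function(founders, plan = breedingPlan(),
                          model = mutationModel(), seed = 1,
                          stockTransmissionsPerEpoch = 0L) {
  set.seed(seed)
  layout <- .panelLayout(founders)
  model <- .resolveMutatorLocus(model, founders)
  mutIdx <- .mutatorLocusIndex(model, founders, layout)
  st <- founders@strLoci
  mk <- founders@markers
  nS <- length(st); nM <- length(mk)
  stockB <- as.integer(st$trueRuB); stockD <- as.integer(st$trueRuD)
  if (anyNA(stockB) || anyNA(stockD))
    stop("founder panel lacks complete trueRuB/trueRuD alleles")
  nStrains <- sum(plan$nStrains)
  strainId <- sprintf("RIS%03d", seq_len(nStrains))
  mlab <- matrix(NA_character_, nM, nStrains, dimnames = list(names(mk), strainId))
  slab <- matrix(NA_character_, nS, nStrains, dimnames = list(st$locusId, strainId))
  a1 <- matrix(NA_integer_, nS, nStrains, dimnames = list(st$locusId, strainId))
  a2 <- a1
  epoch <- character(nStrains); nGen <- integer(nStrains)
  stocks <- list()
  isS <- layout$rowIsStr
  oM <- order(layout$srcIdx[!isS]); oS <- order(layout$srcIdx[isS])
  k <- 0L
  for (e in seq_len(nrow(plan))) {
    if (stockTransmissionsPerEpoch > 0L) {
      stockB <- .stock_transmissions_cpp(stockB, as.integer(st$motifLen),
        as.integer(stockTransmissionsPerEpoch), model$baseRate,
        model$lengthSlope, model$rateCap, model$stepGeometricP,
        model$expansionProbB)
      stockD <- .stock_transmissions_cpp(stockD, as.integer(st$motifLen),
        as.integer(stockTransmissionsPerEpoch), model$baseRate,
        model$lengthSlope, model$rateCap, model$stepGeometricP,
        model$expansionProbD)
    }
    stocks[[as.character(plan$epochId[e])]] <- list(B = stockB, D = stockD)
    for (j in seq_len(plan$nStrains[e])) {
      k <- k + 1L
      res <- .simulate_strain_cpp(layout$chromOffsets, layout$cmPos,
                                  layout$strIdx, as.integer(st$motifLen),
                                  stockB, stockD,
                                  as.integer(plan$nGenerations[e]), mutIdx,
                                  model$baseRate, model$lengthSlope,
                                  model$rateCap, model$stepGeometricP,
                                  model$expansionProbB, model$expansionProbD)
      code <- c("B", "H", "D")[res$label[, 1] + res$label[, 2] + 1L]
      mlab[, k] <- code[!isS][oM]
      slab[, k] <- code[isS][oS]
      a1[, k] <- res$strLen[, 1]
      a2[, k] <- res$strLen[, 2]
      epoch[k] <- as.character(plan$epochId[e])
      nGen[k] <- plan$nGenerations[e]
    }
  }
  # SNP genotype table: founder-coded calls at informative markers only
  geno <- mlab
  geno[mk$alleleB == mk$alleleD, ] <- NA_character_
  cd <- S4Vectors::DataFrame(strainId = strainId, epoch = epoch,
                             nGenerations = nGen, row.names = strainId)
  snp <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno), rowRanges = mk, colData = cd)
  strSE <- SummarizedExperiment::SummarizedExperiment(
    assays = list(a1 = a1, a2 = a2), rowRanges = st, colData = cd)
  # truth: loci fixed for sequence and founder label whose allele differs
  # from the transmitted (epoch-stock) founder allele
  rows <- vector("list", nStrains)
  for (k in seq_len(nStrains)) {
    stk <- stocks[[epoch[k]]]
    fRu <- ifelse(slab[, k] == "B", stk$B, ifelse(slab[, k] == "D", stk$D, NA))
    mut <- which(!is.na(fRu) & a1[, k] == a2[, k] & a1[, k] != fRu)
    if (length(mut))
      rows[[k]] <- data.frame(strainId = strainId[k],
                              locusId = st$locusId[mut],
                              founderLabel = slab[mut, k],
                              founderRu = as.integer(fRu[mut]),
                              finalRu = a1[mut, k])
  }
  truth <- if (any(!vapply(rows, is.null, logical(1))))
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  else data.frame(strainId = character(), locusId = character(),
                  founderLabel = character(), founderRu = integer(),
                  finalRu = integer())
  rownames(truth) <- NULL
  methods::new("RIPanelSim", founders = founders, snp = snp, str = strSE,
               truth = truth, trueMarkerLabels = mlab, trueStrLabels = slab,
               params = list(plan = plan, model = model, seed = seed,
                             stockTransmissionsPerEpoch = stockTransmissionsPerEpoch,
                             stocks = stocks))
}

#' Render a simulated panel into noisy genotype calls (and files)
#'
#' Injects missing calls and spurious heterozygous STR calls at the stated
#' rates, emulating genotyping dropout and stutter-like errors.  With a
#' non-\code{NULL} \code{dir}, writes the file set the analysis pipeline
#' consumes: SNP genotype TSV, marker map TSV, STR genotype VCF, strain
#' metadata TSV and the mutation truth table TSV.
#'
#' @param sim an \code{\linkS4class{RIPanelSim}}.
#' @param missingCallRate probability in [0, 1) that a SNP or STR call is
#'   set to missing.
#' @param hetErrorRate probability in [0, 1) that a non-missing STR call is
#'   replaced by a spurious heterozygous call (second allele one RU longer).
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return (invisibly) a list with the noisy \code{snp} and \code{str}
#'   experiments, \code{metadata}, \code{truth} and, when written, the file
#'   \code{paths}.
#' @export
renderPanel <- function(sim, missingCallRate = 0.02, hetErrorRate = 0.005,
                        seed = 1, dir = NULL) {
  stopifnot(missingCallRate >= 0, missingCallRate < 1,
            hetErrorRate >= 0, hetErrorRate < 1)
  set.seed(seed)
  snp <- sim@snp; strSE <- sim@str
  geno <- SummarizedExperiment::assay(snp, "geno")
  a1 <- SummarizedExperiment::assay(strSE, "a1")
  a2 <- SummarizedExperiment::assay(strSE, "a2")
  if (hetErrorRate > 0) {
    flip <- matrix(runif(length(a1)) < hetErrorRate, nrow(a1))
    flip <- flip & !is.na(a1)
    a2[flip] <- a1[flip] + 1L
  }
  if (missingCallRate > 0) {
    dropS <- matrix(runif(length(geno)) < missingCallRate, nrow(geno))
    geno[dropS] <- NA_character_
    dropT <- matrix(runif(length(a1)) < missingCallRate, nrow(a1))
    a1[dropT] <- NA_integer_; a2[dropT] <- NA_integer_
  }
  SummarizedExperiment::assay(snp, "geno") <- geno
  SummarizedExperiment::assays(strSE) <- list(a1 = a1, a2 = a2)
  metadata <- as.data.frame(SummarizedExperiment::colData(strSE))
  out <- list(snp = snp, str = strSE, metadata = metadata, truth = sim@truth,
              founders = sim@founders)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      snp = file.path(dir, "snp_genotypes.tsv"),
      map = file.path(dir, "marker_map.tsv"),
      vcf = file.path(dir, "str_genotypes.vcf"),
      metadata = file.path(dir, "metadata.tsv"),
      truth = file.path(dir, "truth_table.tsv"))
    writeSnpTable(snp, paths$snp, paths$map)
    writeStrVcf(strSE, sim@founders, paths$vcf)
    data.table::fwrite(data.table::data.table(
      strain_id = metadata$strainId, epoch = metadata$epoch,
      n_generations = metadata$nGenerations), paths$metadata, sep = "\t")
    tr <- sim@truth
    data.table::fwrite(data.table::data.table(
      strain_id = tr$strainId, locus_id = tr$locusId,
      founder_label = tr$founderLabel, founder_ru = tr$founderRu,
      final_ru = tr$finalRu), paths$truth, sep = "\t")
    out$paths <- paths
  }
  invisible(out)
}
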