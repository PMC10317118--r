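#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration; user configs (nested
#' lists or YAML files) override fields by deep merge.  Every run logs the
#' resolved configuration and seed next to its outputs.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    input = list(dir = NULL),   # when set: ingest files instead of simulating
    simulate = list(
      nChromosomes = 5L, nMarkersPerChrom = 200L, nStrsPerChrom = 1000L,
      fracSnpInformative = 0.9, fracStrPolymorphic = 0.3,
      fracFounderMissing = 0.05, chromLengthBp = 1e8, chromLengthCM = 60,
      epochs = list(epochId = paste0("epoch", 1:5), nStrains = rep(30L, 5),
                    nGenerations = c(20L, 40L, 60L, 80L, 100L)),
      model = list(baseRate = 1e-4, lengthSlope = 0.04, rateCap = 0.01,
                   stepGeometricP = 0.8, expansionProbB = 0.6,
                   expansionProbD = 0.4, mutatorLocus = NULL),
      stockTransmissionsPerEpoch = 0L,
      missingCallRate = 0.02, hetErrorRate = 0.005),
    inference = list(errorRate = 0.002, minProb = 0.5),
    calling = list(maxStrains = 10L, minMutations = 10L, outlierFold = 2.0,
                   rule = "either-founder"),
    phenotypes = list(pcaComponents = 2L),
    scan = list(phenotypes = c("mutationCount", "expansionPropensity",
                               "meanExpansionSize", "meanContractionSize"),
                nPerm = 100L, alphas = 0.05, lodDrop = 1.5,
                perMotifLength = FALSE),
    patterns = list(binWidthBp = 4, focalMarker = NULL),
    strainSubset = NULL)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the fields of
#'   \code{\link{defaultPipelineConfig}}.
#' @return resolved configuration list.
#' @export
readPipelineConfig <- function(path) {
  .mergeConfig(defaultPipelineConfig(), yaml::read_yaml(path))
}

.configHash <- function(cfg, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(list(config = cfg, seed = seed), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end: simulate (or ingest) genotypes, infer
#' founder labels and haplotype blocks, resolve missing founder STR
#' alleles, call and filter mutations, compute mutator phenotypes and the
#' mutation-sharing PCA, run LMM QTL scans with permutation thresholds, and
#' produce mutation-spectrum summaries.  All artifacts are written under
#' \code{outDir}, which is self-describing (resolved config, seed and a
#' reconciling record-count manifest).  With \code{resume = TRUE}, stages
#' whose serialized outputs already exist for an identical config + seed
#' (verified by config hash and input checksums) are loaded instead of
#' recomputed.  The recurrence / per-strain filter thresholds may be given
#' as vectors, producing one scan set per combination (filter-sensitivity
#' sweep); \code{scan$perMotifLength} repeats the expansion-propensity scan
#' per repeat-unit length.
#'
#' @param config nested list (see \code{\link{defaultPipelineConfig}}) or a
#'   YAML path.
#' @param outDir output directory.
#' @param seed integer master seed for every stochastic stage.
#' @param resume reuse serialized intermediates when valid.
#' @return (invisibly) list with the main in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(config = list(), outDir, seed = 1, resume = TRUE) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else .mergeConfig(defaultPipelineConfig(), config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  hash <- .configHash(cfg, seed)
  manifestPath <- file.path(outDir, "manifest.json")
  prevHash <- if (resume && file.exists(manifestPath))
    tryCatch(jsonlite::read_json(manifestPath)$configHash,
             error = function(e) NULL) else NULL
  resume <- resume && identical(prevHash, hash)
  yaml::write_yaml(list(config = cfg, seed = seed),
                   file.path(outDir, "config.yaml"))
  manifest <- newManifest(cfg, seed)
  manifest$configHash <- hash

  ## stage 1: data (simulate + render, or ingest)
  dataDir <- if (!is.null(cfg$input$dir)) cfg$input$dir
             else file.path(outDir, "data")
  dataFiles <- file.path(dataDir, c("snp_genotypes.tsv", "marker_map.tsv",
                                    "str_genotypes.vcf", "metadata.tsv"))
  simulated <- is.null(cfg$input$dir)
  if (simulated && !(resume && all(file.exists(dataFiles)))) {
    founders <- generateFounders(
      nChromosomes = cfg$simulate$nChromosomes,
      nMarkersPerChrom = cfg$simulate$nMarkersPerChrom,
      nStrsPerChrom = cfg$simulate$nStrsPerChrom,
      fracSnpInformative = cfg$simulate$fracSnpInformative,
      fracStrPolymorphic = cfg$simulate$fracStrPolymorphic,
      fracFounderMissing = cfg$simulate$fracFounderMissing,
      chromLengthBp = cfg$simulate$chromLengthBp,
      chromLengthCM = cfg$simulate$chromLengthCM, seed = seed)
    sim <- simulatePanel(founders,
                         plan = breedingPlan(as.data.frame(cfg$simulate$epochs)),
                         model = do.call(mutationModel, cfg$simulate$model),
                         seed = seed + 1L,
                         stockTransmissionsPerEpoch =
                           cfg$simulate$stockTransmissionsPerEpoch)
    renderPanel(sim, missingCallRate = cfg$simulate$missingCallRate,
                hetErrorRate = cfg$simulate$hetErrorRate, seed = seed + 2L,
                dir = dataDir)
  }
  snp <- readSnpTable(dataFiles[1], dataFiles[2])
  strSE <- readStrVcf(dataFiles[3])
  metadata <- readMetadata(dataFiles[4])
  .checkStrains(colnames(snp), metadata$strainId, "the SNP table")
  .checkStrains(colnames(strSE), metadata$strainId, "the STR VCF")
  idx <- match(colnames(strSE), metadata$strainId)
  SummarizedExperiment::colData(strSE)$epoch <- metadata$epoch[idx]
  SummarizedExperiment::colData(strSE)$nGenerations <- metadata$nGenerations[idx]
  founders <- assembleFounderPanel(snp, strSE)
  manifest <- addManifestInputs(manifest, stats::setNames(dataFiles,
    c("snp", "map", "vcf", "metadata")))
  manifest <- addManifestStage(manifest, "data",
                               input = nrow(strSE), retained = nrow(strSE))

  ## stage 2: founder inference
  fls <- imputeFounderLabels(assignFounderLabels(snp, founders),
                             errorRate = cfg$inference$errorRate,
                             minProb = cfg$inference$minProb)
  blocks <- buildHaplotypeBlocks(fls)
  infDir <- file.path(outDir, "founders")
  dir.create(infDir, showWarnings = FALSE)
  writeBlocksBed(blocks, file.path(infDir, "blocks.tsv"))
  inf <- inferMissingFounderStr(founders, strSE, blocks)
  founders <- inf$founders
  writeLines(inf$droppedLoci, file.path(infDir, "dropped_loci.txt"))
  if (nrow(inf$log))
    data.table::fwrite(inf$log, file.path(infDir, "inference_log.tsv"),
                       sep = "\t")
  st <- founders@strLoci
  unresolved <- sum(is.na(st$ruB) | is.na(st$ruD))
  manifest <- addManifestStage(manifest, "founder_inference",
    input = nrow(strSE),
    retained = nrow(strSE) - length(inf$droppedLoci) - unresolved,
    dropped = list(modal_rule = length(inf$droppedLoci),
                   unresolved_founder = unresolved))

  ## stage 3: mutation calling + filters (possibly a threshold sweep)
  callDir <- file.path(outDir, "calls")
  dir.create(callDir, showWarnings = FALSE)
  rawPath <- file.path(callDir, "calls_raw.tsv")
  if (resume && file.exists(rawPath)) {
    callsRaw <- data.table::setDF(data.table::fread(rawPath, sep = "\t"))
  } else {
    callsRaw <- callNewMutations(strSE, founders, blocks,
                                 droppedLoci = inf$droppedLoci,
                                 rule = cfg$calling$rule)
    data.table::fwrite(callsRaw, rawPath, sep = "\t")
  }
  prob <- founderGenoProb(fls)
  kinship <- calcKinshipLoco(prob)
  results <- list()
  sweep <- expand.grid(maxStrains = cfg$calling$maxStrains,
                       minMutations = cfg$calling$minMutations)
  for (w in seq_len(nrow(sweep))) {
    tag <- if (nrow(sweep) > 1L)
      sprintf("_max%d_min%d", sweep$maxStrains[w], sweep$minMutations[w])
    else ""
    res <- .runAnalysisSet(callsRaw, sweep$maxStrains[w],
                           sweep$minMutations[w], cfg, metadata, strSE,
                           founders, blocks, fls, prob, kinship, outDir,
                           tag, seed)
    manifest <- addManifestStage(manifest, paste0("calling", tag),
      input = nrow(callsRaw), retained = nrow(res$callsRetained),
      dropped = list(recurrent = nrow(callsRaw) - res$nAfterRecurrent,
                     outlier_strain = res$nOutlierCalls,
                     strain_subset = res$nSubsetCalls,
                     low_count_strain = res$nAfterRecurrent -
                       res$nOutlierCalls - res$nSubsetCalls -
                       nrow(res$callsRetained)))
    results[[paste0("set", tag)]] <- res
  }
  validateManifest(manifest)
  writeManifest(manifest, manifestPath)
  invisible(list(config = cfg, founders = founders, blocks = blocks,
                 fls = fls, callsRaw = callsRaw, results = results,
                 metadata = metadata, manifest = manifest))
}

# one filtered analysis set: filters -> phenotypes -> PCA -> scans -> patterns
.runAnalysisSet <- function(callsRaw, maxStrains, minMutations, cfg,
                            metadata, strSE, founders, blocks, fls, prob,
                            kinship, outDir, tag, seed) {
  calls <- filterRecurrent(callsRaw, maxStrains)
  nAfterRecurrent <- nrow(calls)
  outliers <- flagOutlierStrains(calls, metadata, fold = cfg$calling$outlierFold)
  nOutlierCalls <- sum(calls$strainId %in% outliers)
  calls <- calls[!(calls$strainId %in% outliers), , drop = FALSE]
  nAfterOutlier <- nrow(calls)
  if (!is.null(cfg$strainSubset)) {
    keep <- metadata$strainId[metadata$epoch %in% cfg$strainSubset |
                                metadata$strainId %in% cfg$strainSubset]
    calls <- calls[calls$strainId %in% keep, , drop = FALSE]
  }
  nSubsetCalls <- nAfterOutlier - nrow(calls)
  fs <- filterStrains(calls, minMutations)
  retained <- fs$calls[fs$calls$strainIncluded, , drop = FALSE]

  phenoDir <- file.path(outDir, "phenotypes")
  dir.create(phenoDir, showWarnings = FALSE)
  pheno <- mutatorPhenotypes(retained, strSE, strains = fs$includedStrains)
  data.table::fwrite(pheno, file.path(phenoDir, paste0("phenotypes", tag, ".tsv")),
                     sep = "\t")
  pca <- if (length(unique(calls$strainId)) >= 2L &&
             nrow(calls) >= 2L)
    tryCatch(mutationPCA(calls, nComponents = cfg$phenotypes$pcaComponents),
             error = function(e) NULL) else NULL
  if (!is.null(pca))
    data.table::fwrite(data.table::as.data.table(pca$scores,
                                                 keep.rownames = "strainId"),
                       file.path(phenoDir, paste0("pca_scores", tag, ".tsv")),
                       sep = "\t")

  scanDir <- file.path(outDir, "scan")
  dir.create(scanDir, showWarnings = FALSE)
  scans <- list()
  covar <- as.matrix(pheno[, "nGenerations", drop = FALSE])
  for (ph in cfg$scan$phenotypes) {
    y <- stats::setNames(pheno[[ph]], pheno$strainId)
    if (sum(is.finite(y)) < 3L) next
    sc <- scanQTL(prob, y, covariates = covar, kinship = kinship,
                  nPerm = cfg$scan$nPerm, alphas = cfg$scan$alphas,
                  seed = seed + 10L, lodDrop = cfg$scan$lodDrop)
    scans[[ph]] <- sc
    .writeScan(sc, scanDir, paste0(ph, tag), seed)
  }
  if (isTRUE(cfg$scan$perMotifLength)) {
    for (ml in sort(unique(retained$motifLen))) {
      sub <- retained[retained$motifLen == ml, , drop = FALSE]
      ph <- mutatorPhenotypes(sub, strSE, strains = fs$includedStrains)
      y <- stats::setNames(ph$expansionPropensity, ph$strainId)
      if (sum(is.finite(y)) < 3L) next
      sc <- scanQTL(prob, y, covariates = covar, kinship = kinship,
                    nPerm = cfg$scan$nPerm, alphas = cfg$scan$alphas,
                    seed = seed + 10L, lodDrop = cfg$scan$lodDrop)
      scans[[paste0("expansionPropensity_motif", ml)]] <- sc
      .writeScan(sc, scanDir, paste0("expansionPropensity_motif", ml, tag),
                 seed)
    }
  }

  patDir <- file.path(outDir, "patterns")
  dir.create(patDir, showWarnings = FALSE)
  binned <- binnedMutationRate(retained, strSE, founders, blocks,
                               binWidthBp = cfg$patterns$binWidthBp,
                               groupBy = "motifLen")
  data.table::fwrite(binned, file.path(patDir, paste0("binned_rates", tag, ".tsv")),
                     sep = "\t")
  focal <- cfg$patterns$focalMarker
  if (is.null(focal) && "expansionPropensity" %in% names(scans)) {
    pk <- peaks(scans[["expansionPropensity"]])
    focal <- pk$marker[which.max(pk$lod)]
  }
  contrast <- if (!is.null(focal)) {
    ct <- suppressWarnings(haplotypeContrast(retained, focal, fls, strSE,
                                             founders, blocks))
    data.table::fwrite(ct, file.path(patDir, paste0("haplotype_contrast",
                                                    tag, ".tsv")), sep = "\t")
    ct
  } else NULL

  list(callsRetained = retained, excludedStrains = fs$excludedStrains,
       outlierStrains = outliers, phenotypes = pheno, pca = pca,
       scans = scans, binned = binned, contrast = contrast,
       focalMarker = focal, nAfterRecurrent = nAfterRecurrent,
       nOutlierCalls = nOutlierCalls, nSubsetCalls = nSubsetCalls)
}

.writeScan <- function(sc, dir, name, seed) {
  data.table::fwrite(lodCurve(sc), file.path(dir, paste0("scan_", name, ".tsv")),
                     sep = "\t")
  jsonlite::write_json(
    list(thresholds = as.list(thresholds(sc)), h2 = as.list(sc@h2),
         nStrains = sc@nStrains, seed = seed,
         peaks = peaks(sc)),
    file.path(dir, paste0("scan_", name, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
}
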