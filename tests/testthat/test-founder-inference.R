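# exhaustive-enumeration oracle for the 2-state founder HMM: sums the joint
# probability of every state path (independent of the forward-backward code)
enumPosterior <- function(lab, cM, errorRate) {
  M <- length(lab)
  r <- 0.5 * (1 - exp(-2 * diff(cM) / 100))
  R <- 4 * r / (1 + 6 * r)
  emis <- function(obs, state) {
    if (is.na(obs)) 1
    else if (obs == state) 1 - errorRate
    else errorRate
  }
  states <- c("B", "D")
  paths <- expand.grid(rep(list(1:2), M))
  pB <- numeric(M); tot <- 0
  for (i in seq_len(nrow(paths))) {
    s <- as.integer(paths[i, ])
    p <- 0.5 * emis(lab[1], states[s[1]])
    for (m in 2:M) {
      p <- p * (if (s[m] == s[m - 1]) 1 - R[m - 1] else R[m - 1]) *
        emis(lab[m], states[s[m]])
    }
    tot <- tot + p
    pB[s == 1] <- pB[s == 1] + p
  }
  pB / tot
}

test_that("founder labels follow the homozygote/heterozygote assignment rules", {
  fp <- manualPanel(markerPos = c(10, 20, 30, 40) * 1e5,
                    strPos = c(15, 25) * 1e5, ruB = c(6, 8), ruD = c(9, 8))
  mk <- markers(fp)
  mk$alleleD[4] <- mk$alleleB[4]   # uninformative marker
  fp@markers <- mk
  geno <- matrix(c("B", "H", "D", "B",
                   "D", "B", "X", "D"), nrow = 4,
                 dimnames = list(names(mk), c("s1", "s2")))
  snp <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno), rowRanges = mk,
    colData = S4Vectors::DataFrame(row.names = c("s1", "s2")))
  lab <- SummarizedExperiment::assay(assignFounderLabels(snp, fp), "label")
  expect_equal(unname(lab[, "s1"]), c("B", NA, "D", NA))
  expect_equal(unname(lab[, "s2"]), c("D", "B", NA, NA))
})

test_that("HMM posteriors match exhaustive path enumeration", {
  fp <- manualPanel(markerPos = seq(1e6, 8e6, by = 1e6), strPos = 2.5e6,
                    ruB = 6, ruD = 9)
  cases <- list(
    c("B", "B", NA, "B", "B", NA, "D", "D"),
    c("B", NA, NA, "D", "B", "D", NA, "D"),
    c(NA, "D", "D", NA, NA, "B", "B", NA))
  for (labs in cases) {
    m <- matrix(labs, ncol = 1, dimnames = list(NULL, "s1"))
    fls <- manualLabelSet(fp, m)
    out <- imputeFounderLabels(fls, errorRate = 0.01)
    got <- SummarizedExperiment::assay(out, "probB")[, 1]
    want <- enumPosterior(labs, markers(fp)$cM, 0.01)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("imputation fills confident gaps, keeps ties missing, and is a no-op on complete tracks", {
  fp <- manualPanel(markerPos = c(1, 2, 3, 4, 5) * 1e6, strPos = 2.5e6,
                    ruB = 6, ruD = 9)
  # single-state chromosome: interior missing becomes B
  m <- matrix(c("B", "B", NA, "B", "B"), ncol = 1,
              dimnames = list(NULL, "s1"))
  out <- imputeFounderLabels(manualLabelSet(fp, m))
  expect_equal(SummarizedExperiment::assay(out, "label")[3, 1], "B")
  # marker exactly midway between equal-length B and D runs: posterior is
  # exactly 0.5, the tie stays missing
  m2 <- matrix(c("B", "B", NA, "D", "D"), ncol = 1,
               dimnames = list(NULL, "s1"))
  out2 <- imputeFounderLabels(manualLabelSet(fp, m2), errorRate = 0.01)
  expect_equal(SummarizedExperiment::assay(out2, "probB")[3, 1], 0.5,
               tolerance = 1e-12)
  expect_true(is.na(SummarizedExperiment::assay(out2, "label")[3, 1]))
  # complete track with errorRate 0: unchanged
  m3 <- matrix(c("B", "B", "D", "D", "D"), ncol = 1,
               dimnames = list(NULL, "s1"))
  out3 <- imputeFounderLabels(manualLabelSet(fp, m3), errorRate = 0)
  expect_equal(SummarizedExperiment::assay(out3, "label"),
               SummarizedExperiment::assay(manualLabelSet(fp, m3), "label"))
})

test_that("haplotype blocks are maximal runs split by unresolved gaps", {
  fp <- manualPanel(markerPos = c(1, 2, 3, 4, 5) * 1e6, strPos = 2.5e6,
                    ruB = 6, ruD = 9)
  lab <- matrix(c("B", "B", "B", "D", "D",
                  "B", NA, "B", NA, NA,
                  NA, NA, NA, NA, NA), ncol = 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  blocks <- buildHaplotypeBlocks(manualLabelSet(fp, lab))
  b1 <- blocks[blocks$strain == "s1"]
  expect_length(b1, 2L)
  expect_equal(GenomicRanges::end(b1)[1], 3e6)
  expect_equal(GenomicRanges::start(b1)[2], 4e6)
  expect_equal(b1$label, c("B", "D"))
  # unresolved interior missing splits same-label runs into two blocks
  b2 <- blocks[blocks$strain == "s2"]
  expect_length(b2, 2L)
  expect_equal(b2$label, c("B", "B"))
  expect_length(blocks[blocks$strain == "s3"], 0L)
  # partition property: every labelled marker sits in a block of its label
  fp2 <- tinyPanel()
  sim <- tinySim(fp2, seed = 77)
  r <- renderPanel(sim, missingCallRate = 0.05, hetErrorRate = 0.01, seed = 1)
  fls <- imputeFounderLabels(assignFounderLabels(r$snp, fp2))
  bl <- buildHaplotypeBlocks(fls)
  labm <- SummarizedExperiment::assay(fls, "label")
  mk <- markers(fp2)
  for (s in sample(colnames(labm), 3)) {
    got <- strpanel:::.blockLabelsAt(bl[bl$strain == s], s,
                                     as.character(GenomeInfoDb::seqnames(mk)),
                                     GenomicRanges::start(mk))
    has <- !is.na(labm[, s])
    expect_equal(got[has], unname(labm[has, s]))
  }
})

test_that("modal-allele founder inference applies the majority and de novo rules", {
  fp <- manualPanel(markerPos = c(1, 10) * 1e6,
                    strPos = c(2, 4, 6) * 1e6,
                    ruB = c(NA, NA, NA), ruD = c(9, 9, 9))
  strains <- paste0("s", 1:5)
  blocks <- manualBlocks("chr1", rep(1e6, 5), rep(1e7, 5), strains, "B")
  # locus 1: {12,12,12,13} -> founder 12; locus 2: {12,12,13,13,14} -> drop;
  # locus 3: {12,12} (three strains missing) -> founder 12
  a1 <- rbind(c(12L, 12L, 12L, 13L, NA),
              c(12L, 12L, 13L, 13L, 14L),
              c(12L, 12L, NA, NA, NA))
  colnames(a1) <- strains
  se <- manualStrSE(fp, a1)
  out <- inferMissingFounderStr(fp, se, blocks)
  st <- strLoci(out$founders)
  expect_equal(st$ruB[1], 12L)
  expect_true("S002" %in% out$droppedLoci)
  expect_equal(st$ruB[3], 12L)
  # zero usable strains in the group -> drop
  blocksD <- manualBlocks("chr1", rep(1e6, 5), rep(1e7, 5), strains, "D")
  outD <- inferMissingFounderStr(fp, se, blocksD)
  expect_setequal(outD$droppedLoci, c("S001", "S002", "S003"))
})

test_that("noise-free round trip recovers the simulated mosaics and founder alleles", {
  fp <- tinyPanel(seed = 50)
  sim <- tinySim(fp, gens = c(25L, 50L), nStrains = 10L, seed = 51)
  r <- renderPanel(sim, missingCallRate = 0, hetErrorRate = 0, seed = 1)
  ri <- runInference(r, fp)
  lab <- SummarizedExperiment::assay(ri$fls, "label")
  informative <- markers(fp)$alleleB != markers(fp)$alleleD
  truth <- sim@trueMarkerLabels[informative, ]
  got <- lab[informative, ]
  # accuracy over markers fixed for one founder (unfixed markers have no
  # single true label); an unimputed NA counts as an error
  fixed <- truth %in% c("B", "D")
  acc <- sum(!is.na(got[fixed]) & got[fixed] == truth[fixed]) / sum(fixed)
  expect_gte(acc, 0.995)
  # modal rule, when it does not drop, recovers the true founder allele
  st0 <- strLoci(fp); st1 <- strLoci(ri$inf$founders)
  filled <- which((is.na(st0$ruB) | is.na(st0$ruD)) &
                    !(st0$locusId %in% ri$inf$droppedLoci))
  expect_gt(length(filled), 0L)
  expect_true(all(st1$ruB[filled] == st0$trueRuB[filled] &
                    st1$ruD[filled] == st0$trueRuD[filled]))
})
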