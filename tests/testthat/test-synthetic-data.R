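test_that("generateFounders honours counts, sorting and masking fractions", {
  fp <- generateFounders(nChromosomes = 2L, nMarkersPerChrom = 100L,
                         nStrsPerChrom = 80L, fracFounderMissing = 0,
                         seed = 3)
  expect_length(markers(fp), 200L)
  expect_length(strLoci(fp), 160L)
  expect_true(S4Vectors::isSorted(markers(fp)))
  expect_false(anyNA(strLoci(fp)$ruB) || anyNA(strLoci(fp)$ruD))
  # cM non-decreasing within chromosomes
  cm <- split(markers(fp)$cM,
              as.character(GenomeInfoDb::seqnames(markers(fp))))
  expect_false(any(vapply(cm, is.unsorted, logical(1))))
  # requested fractions realised exactly
  fp2 <- generateFounders(nChromosomes = 2L, nMarkersPerChrom = 100L,
                          nStrsPerChrom = 100L, fracSnpInformative = 0.5,
                          fracStrPolymorphic = 0.25,
                          fracFounderMissing = 0.1, seed = 4)
  expect_equal(sum(markers(fp2)$alleleB != markers(fp2)$alleleD), 100L)
  st <- strLoci(fp2)
  expect_equal(sum(is.na(st$ruB)) + sum(is.na(st$ruD)), 20L)
  expect_equal(sum(st$trueRuB != st$trueRuD), 50L)
  expect_error(generateFounders(nChromosomes = 0L), "positive")
})

test_that("same seed reproduces the panel and the simulation exactly", {
  expect_identical(tinyPanel(seed = 9), tinyPanel(seed = 9))
  fp <- tinyPanel()
  s1 <- tinySim(fp, seed = 11)
  s2 <- tinySim(fp, seed = 11)
  expect_identical(truthTable(s1), truthTable(s2))
  expect_identical(SummarizedExperiment::assay(strGeno(s1), "a1"),
                   SummarizedExperiment::assay(strGeno(s2), "a1"))
  expect_identical(s1@trueMarkerLabels, s2@trueMarkerLabels)
})

test_that("mutateStr implements the stepwise law and its limits", {
  expect_error(mutateStr(0L, 4L), ">= 1")
  m0 <- mutationModel(baseRate = 0)
  expect_identical(mutateStr(rep(10L, 500), 4L, "B", m0), rep(10L, 500))
  # forced mutation with expansion probability driven to 1: always expands
  m1 <- mutationModel(baseRate = 0.999, rateCap = 1)
  m1$expansionProbB <- 1
  set.seed(1)
  out <- mutateStr(rep(10L, 200), 2L, "B", m1)
  expect_true(all(out > 10L))
  # conditioned expansion fraction within 3 binomial SDs of 0.6
  m <- mutationModel(baseRate = 0.999, rateCap = 1, expansionProbB = 0.6)
  set.seed(2)
  parent <- rep(50L, 20000)
  out <- mutateStr(parent, 4L, "B", m)
  mut <- out != parent
  # steps can cancel to zero delta only via the floor; none here (len 50)
  frac <- mean(out[mut] > parent[mut])
  se3 <- 3 * sqrt(0.6 * 0.4 / sum(mut))
  expect_gt(sum(mut), 15000)
  expect_lt(abs(frac - 0.6), se3)
})

test_that("empirical mutation rate increases with parent length", {
  m <- mutationModel(baseRate = 1e-3, lengthSlope = 0.05, rateCap = 0.5)
  set.seed(3)
  lens <- sample(5:30, 1.2e5, replace = TRUE)
  out <- mutateStr(lens, 2L, "H", m)
  bp <- lens * 2L
  bins <- cut(bp, breaks = seq(8, 62, by = 6), include.lowest = TRUE)
  rate <- tapply(out != lens, bins, mean)
  expect_false(is.unsorted(rate))
})

test_that("F1 strains are fully heterozygous and 30 generations of sib-mating fix the genome", {
  fp <- tinyPanel()
  f1 <- simulateStrain(fp, nGenerations = 1L, mutationModel(baseRate = 0),
                       seed = 21)
  informative <- markers(fp)$alleleB != markers(fp)$alleleD
  expect_true(all(f1$markerLabels[informative] == "H"))
  # no-mutation limit: every STR genotype equals one founder allele
  s50 <- simulateStrain(fp, nGenerations = 50L, mutationModel(baseRate = 0),
                        seed = 22)
  st <- strLoci(fp)
  ok <- s50$strLen[, 1] == st$trueRuB | s50$strLen[, 1] == st$trueRuD
  expect_true(all(ok))
  # sib-mating heterozygosity recursion oracle: H(1) = 1 at the F1,
  # H(2) = 1/2, H(t+1) = H(t)/2 + H(t-1)/4
  H <- numeric(30); H[1] <- 1; H[2] <- 0.5
  for (t in 3:30) H[t] <- H[t - 1] / 2 + H[t - 2] / 4
  hets <- vapply(1:20, function(i) {
    s <- simulateStrain(fp, nGenerations = 30L, mutationModel(baseRate = 0),
                        seed = 100 + i)
    mean(s$markerLabels[informative] == "H")
  }, numeric(1))
  expect_gte(mean(1 - hets), 0.99)
  # observed heterozygosity is consistent with the recursion's scale
  expect_lt(mean(hets), 10 * H[30] + 0.005)
})

test_that("mean mutation burden increases with generations of inbreeding", {
  sim <- tinySim(gens = c(20L, 40L, 80L), nStrains = 8L, seed = 31)
  tr <- truthTable(sim)
  md <- as.data.frame(SummarizedExperiment::colData(strGeno(sim)))
  cnt <- table(factor(tr$strainId, levels = md$strainId))
  byEpoch <- tapply(as.integer(cnt), md$epoch, mean)
  expect_true(all(diff(byEpoch[paste0("e", 1:3)]) > 0))
})

test_that("renderPanel injects noise at the stated rates and keeps the truth table", {
  sim <- tinySim(seed = 41)
  clean <- renderPanel(sim, missingCallRate = 0, hetErrorRate = 0, seed = 1)
  expect_identical(SummarizedExperiment::assay(clean$str, "a1"),
                   SummarizedExperiment::assay(strGeno(sim), "a1"))
  expect_identical(SummarizedExperiment::assay(clean$str, "a2"),
                   SummarizedExperiment::assay(strGeno(sim), "a2"))
  expect_identical(clean$truth, truthTable(sim))
  # truth rows are exactly the fixed (strain, locus) pairs differing from
  # the transmitted founder allele
  st <- strLoci(founderPanel(sim))
  a1 <- SummarizedExperiment::assay(strGeno(sim), "a1")
  a2 <- SummarizedExperiment::assay(strGeno(sim), "a2")
  lab <- sim@trueStrLabels
  fRu <- ifelse(lab == "B", st$trueRuB, ifelse(lab == "D", st$trueRuD, NA))
  expect_equal(nrow(truthTable(sim)),
               sum(a1 == a2 & !is.na(fRu) & a1 != fRu, na.rm = TRUE))
  # spurious heterozygous calls appear at the requested rate (3 SD band,
  # >= 1e5 calls); a shallow-pedigree panel keeps this fast
  fpBig <- generateFounders(nChromosomes = 2L, nMarkersPerChrom = 20L,
                            nStrsPerChrom = 2000L, seed = 44)
  simBig <- tinySim(fpBig, gens = c(2L, 2L), nStrains = 15L,
                    model = mutationModel(baseRate = 0), seed = 45)
  b1 <- SummarizedExperiment::assay(strGeno(simBig), "a1")
  b2 <- SummarizedExperiment::assay(strGeno(simBig), "a2")
  noisy <- renderPanel(simBig, missingCallRate = 0, hetErrorRate = 0.01,
                       seed = 2)
  n1 <- SummarizedExperiment::assay(noisy$str, "a1")
  n2 <- SummarizedExperiment::assay(noisy$str, "a2")
  wasHom <- b1 == b2
  injected <- wasHom & n1 != n2
  n <- sum(wasHom)
  expect_gt(n, 1e5)
  expect_lt(abs(sum(injected) / n - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  # missing calls at the requested rate
  noisy2 <- renderPanel(simBig, missingCallRate = 0.05, hetErrorRate = 0,
                        seed = 3)
  miss <- is.na(SummarizedExperiment::assay(noisy2$str, "a1"))
  expect_lt(abs(mean(miss) - 0.05), 3 * sqrt(0.05 * 0.95 / length(miss)))
})

test_that("canonicalMotif folds rotations and reverse complements together", {
  expect_equal(canonicalMotif(c("TCTA", "AGAT", "ATCT")),
               rep(canonicalMotif("AGAT"), 3))
  expect_equal(canonicalMotif("AC"), "AC")
  expect_equal(canonicalMotif("GT"), "AC")
})
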