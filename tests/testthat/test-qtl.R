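# genotype probabilities for a hand-set toy panel
toyProb <- function(pB, chrom, posBp = seq_along(chrom) * 1e6) {
  list(pB = pB, marker = paste0("m", seq_along(chrom)), chrom = chrom,
       posBp = posBp, cM = posBp / 2e6)
}

test_that("kinship entries follow the probability cross-product definition", {
  # identical fully resolved mosaics: K12 equals the self-kinship
  pB <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(0, 0, 1, 1))
  prob <- toyProb(pB, chrom = c("c1", "c1", "c2", "c2"))
  K <- calcKinshipLoco(prob)
  expect_equal(K$overall["s1", "s2"], K$overall["s1", "s1"])
  # complementary mosaics: kinship 0
  expect_equal(K$overall["s1", "s3"], 0)
  # hand-set probabilities against an explicit double loop
  set.seed(1)
  pB2 <- matrix(runif(12), 3, 4, dimnames = list(paste0("s", 1:3), NULL))
  prob2 <- toyProb(pB2, chrom = c("c1", "c1", "c2", "c2"))
  K2 <- calcKinshipLoco(prob2)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (m in 1:4)
    oracle[i, j] <- oracle[i, j] +
      (pB2[i, m] * pB2[j, m] + (1 - pB2[i, m]) * (1 - pB2[j, m])) / 4
  expect_equal(unname(K2$overall), oracle)
  # LOCO excludes the chromosome's own markers
  oracleC1 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (m in 3:4)
    oracleC1[i, j] <- oracleC1[i, j] +
      (pB2[i, m] * pB2[j, m] + (1 - pB2[i, m]) * (1 - pB2[j, m])) / 2
  expect_equal(unname(K2$loco[["c1"]]), oracleC1)
  # single chromosome: fall back with a warning
  expect_warning(K3 <- calcKinshipLoco(toyProb(pB2[, 1:2],
                                               chrom = c("c1", "c1"))),
                 "LOCO")
  expect_equal(K3$loco[["c1"]], K3$overall)
})

test_that("null model heritability estimation handles degenerate and known cases", {
  set.seed(2)
  # identity kinship: likelihood flat in h2, pinned to 0
  y <- rnorm(40)
  f <- fitNullLMM(y, K = diag(40) / 2)
  expect_equal(f$h2, 0)
  # phenotype exactly linear in the covariate: variance floor, no error
  x <- 1:40
  f2 <- fitNullLMM(2 + 3 * x, covariates = cbind(x = x), K = diag(40) / 2)
  expect_true(is.finite(f2$logLik))
  # estimator agrees with a grid search over the same likelihood, and
  # recovers a known h2 on simulated strain structure
  fp <- tinyPanel(seed = 80)
  sim <- tinySim(fp, gens = c(20L, 20L), nStrains = 50L,
                 model = mutationModel(baseRate = 0), seed = 81)
  r <- renderPanel(sim, missingCallRate = 0, hetErrorRate = 0, seed = 1)
  fls <- imputeFounderLabels(assignFounderLabels(r$snp, fp))
  K <- calcKinshipLoco(founderGenoProb(fls))$overall
  n <- nrow(K)
  ev <- eigen(2 * K, symmetric = TRUE)
  h2true <- 0.5
  h2hat <- replicate(10, {
    g <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n))
    y <- sqrt(h2true) * as.numeric(g) + sqrt(1 - h2true) * rnorm(n)
    fit <- fitNullLMM(y, K = K)
    # grid-search oracle on the identical profiled likelihood
    grid <- seq(0, 0.99, by = 1e-3)
    ll <- vapply(grid, strpanel:::.profileLogLik, numeric(1),
                 lambda = fit$lambda,
                 yr = crossprod(fit$U, y),
                 Xr = crossprod(fit$U, matrix(1, n)))
    expect_lt(abs(fit$h2 - grid[which.max(ll)]), 2e-3)
    fit$h2
  })
  expect_lt(abs(mean(h2hat) - h2true), 0.15)
})

test_that("scan reduces to OLS without kinship and matches brute-force GLS", {
  set.seed(3)
  n <- 12
  pB <- matrix(sample(c(0, 1), n * 8, TRUE), n, 8,
               dimnames = list(paste0("s", 1:n), NULL))
  pB[1, 1] <- 0.3   # one partially resolved marker
  prob <- toyProb(pB, chrom = rep(c("c1", "c2"), each = 4))
  y <- setNames(rnorm(n), rownames(pB))
  covar <- cbind(gen = rnorm(n))
  # identity kinship pins h2 = 0, so the LOD must equal the OLS LOD
  idK <- list(loco = list(c1 = diag(n) / 2, c2 = diag(n) / 2),
              overall = diag(n) / 2)
  dimnames(idK$loco$c1) <- dimnames(idK$loco$c2) <-
    dimnames(idK$overall) <- list(rownames(pB), rownames(pB))
  sc <- scanQTL(prob, y, covariates = covar, kinship = idK)
  lodDf <- lodCurve(sc)
  X0 <- cbind(1, covar)
  for (k in seq_len(nrow(lodDf))) {
    m <- match(lodDf$marker[k], prob$marker)
    r0 <- sum(lm.fit(X0, y)$residuals^2)
    r1 <- sum(lm.fit(cbind(X0, pB[, m]), y)$residuals^2)
    expect_equal(lodDf$lod[k], n / 2 * log10(r0 / r1), tolerance = 1e-8)
  }
  # full-kinship scan matches explicit matrix-inversion GLS at each marker
  sim <- tinySim(tinyPanel(seed = 90), gens = c(15L, 15L), nStrains = 6L,
                 model = mutationModel(baseRate = 0), seed = 91)
  r <- renderPanel(sim, missingCallRate = 0, hetErrorRate = 0, seed = 1)
  fls <- imputeFounderLabels(assignFounderLabels(r$snp, tinyPanel(seed = 90)))
  prob2 <- founderGenoProb(fls)
  kin <- calcKinshipLoco(prob2)
  y2 <- setNames(rnorm(12), rownames(prob2$pB))
  sc2 <- scanQTL(prob2, y2, kinship = kin)
  lod2 <- lodCurve(sc2)
  n2 <- 12
  for (ch in unique(lod2$chrom)) {
    h2 <- sc2@h2[[ch]]
    V <- h2 * 2 * kin$loco[[ch]] + (1 - h2) * diag(n2)
    Vi <- solve(V)
    gls <- function(X) {
      b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y2)
      as.numeric(t(y2 - X %*% b) %*% Vi %*% (y2 - X %*% b))
    }
    d <- lod2[lod2$chrom == ch, ]
    for (k in sample(nrow(d), 5)) {
      m <- match(d$marker[k], prob2$marker)
      lodBf <- n2 / 2 * log10(gls(matrix(1, n2)) /
                                gls(cbind(1, prob2$pB[, m])))
      expect_equal(d$lod[k], lodBf, tolerance = 1e-6)
    }
  }
})

test_that("scan degeneracies give zero LOD and affine phenotype changes nothing", {
  set.seed(4)
  n <- 20
  pB <- matrix(sample(c(0, 1), n * 6, TRUE), n, 6,
               dimnames = list(paste0("s", 1:n), NULL))
  prob <- toyProb(pB, chrom = rep(c("c1", "c2"), each = 3))
  yc <- setNames(rep(1, n), rownames(pB))
  expect_true(all(lodCurve(scanQTL(prob, yc))$lod == 0))
  # marker identical to a covariate column adds nothing
  y <- setNames(rnorm(n), rownames(pB))
  sc <- scanQTL(prob, y, covariates = cbind(m1 = pB[, 1]))
  expect_equal(lodCurve(sc)$lod[lodCurve(sc)$marker == "m1"], 0,
               tolerance = 1e-8)
  # scale invariance
  s1 <- lodCurve(scanQTL(prob, y))$lod
  s2 <- lodCurve(scanQTL(prob, setNames(5 - 3 * y, names(y))))$lod
  expect_equal(s1, s2, tolerance = 1e-8)
  # monomorphic markers are removed before scanning
  pB2 <- pB; pB2[, 2] <- 1
  sc3 <- scanQTL(toyProb(pB2, chrom = rep(c("c1", "c2"), each = 3)), y)
  expect_false("m2" %in% lodCurve(sc3)$marker)
})

test_that("permutation thresholds are deterministic, monotone and quantile-type-7", {
  set.seed(5)
  n <- 25
  pB <- matrix(sample(c(0, 1), n * 10, TRUE), n, 10,
               dimnames = list(paste0("s", 1:n), NULL))
  prob <- toyProb(pB, chrom = rep(c("c1", "c2"), each = 5))
  y <- setNames(rnorm(n), rownames(pB))
  p1 <- permutationThreshold(prob, y, nPerm = 40, alphas = c(0.05, 0.2),
                             seed = 7)
  p2 <- permutationThreshold(prob, y, nPerm = 40, alphas = c(0.05, 0.2),
                             seed = 7)
  expect_identical(p1, p2)
  expect_gte(p1$thresholds[["0.05"]], p1$thresholds[["0.2"]])
  expect_equal(unname(p1$thresholds[["0.05"]]),
               unname(quantile(p1$maxima, 0.95, type = 7)))
  expect_warning(permutationThreshold(prob, y, nPerm = 5, seed = 1),
                 "permutations")
})

test_that("LOD support intervals honour the drop rule and flanking extension", {
  mkScan <- function(lod, pos = seq_along(lod) * 1e6) {
    methods::new("QTLScan",
                 lod = data.frame(marker = paste0("m", seq_along(lod)),
                                  chrom = "c1", posBp = pos, lod = lod),
                 h2 = c(c1 = 0), nStrains = 10L,
                 covariateNames = character(), thresholds = numeric(),
                 permMax = numeric(), peaks = data.frame())
  }
  # single marker above peak-1.5: interval is that marker +- one flank
  sc <- mkScan(c(0.2, 0.1, 5, 0.3, 0.2))
  expect_equal(unname(lodSupportInterval(sc, "c1")), c(2e6, 4e6))
  # drop = Inf: whole chromosome
  expect_equal(unname(lodSupportInterval(sc, "c1", drop = Inf)),
               c(1e6, 5e6))
  # two peaks separated by a deep dip: interval confined to the peak's run;
  # oracle: exhaustive scan over the contiguous run containing the argmax
  lod <- c(4.8, 0.2, 0.1, 5, 4.2, 0.3)
  sc2 <- mkScan(lod)
  peak <- which.max(lod)
  inRun <- function(i) {
    all(lod[min(i, peak):max(i, peak)] >= max(lod) - 1.5)
  }
  run <- range(which(vapply(seq_along(lod), inRun, logical(1))))
  want <- c(max(1, run[1] - 1), min(length(lod), run[2] + 1)) * 1e6
  expect_equal(unname(lodSupportInterval(sc2, "c1")), want)
  # all-equal curve: whole chromosome
  expect_equal(unname(lodSupportInterval(mkScan(rep(1, 4)), "c1")),
               c(1e6, 4e6))
})
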