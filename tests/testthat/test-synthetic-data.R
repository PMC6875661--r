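test_that("environmental fields honour the target inter-layer correlation", {
  # independent layers stay near zero correlation
  e0 <- makeEnvStack(2, c(100, 100), spatialRange = 3, seed = 3)
  r0 <- cor(as.vector(getLayer(e0, "PRJ")), as.vector(getLayer(e0, "PRS")))
  expect_lt(abs(r0), 0.2)

  # a strong target correlation is recovered on a large grid
  C <- matrix(c(1, 0.9, 0.9, 1), 2)
  e1 <- makeEnvStack(2, c(200, 200), spatialRange = 3,
                     interLayerCorrelation = C, seed = 4)
  r1 <- cor(as.vector(getLayer(e1, "PRJ")), as.vector(getLayer(e1, "PRS")))
  expect_lt(abs(r1 - 0.9), 0.1)

  # determinism and PSD validation
  e2 <- makeEnvStack(2, c(100, 100), spatialRange = 3, seed = 3)
  expect_identical(e0@layers, e2@layers)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(makeEnvStack(2, c(20, 20), interLayerCorrelation = bad),
               "positive semi-definite")
})

test_that("occurrence sampling follows the suitability surface", {
  env <- makeEnvStack(1, c(10, 10), spatialRange = 0, seed = 5)
  # flat suitability: occupancy approximately uniform over the 100 cells
  occ <- sampleOccurrences(env, NULL, n = 5000, seed = 6)
  tabulated <- tabulate(occ$cell, nbins = 100)
  expect_gt(chisq.test(tabulated)$p.value, 0.01)

  # hard left/right split concentrates all the mass
  suit <- matrix(0, 10, 10); suit[, 1:5] <- 1
  occL <- sampleOccurrences(env, n = 200, seed = 7, suitability = suit)
  expect_true(all(occL$lon <= 5))

  expect_identical(nrow(sampleOccurrences(env, NULL, n = 0)), 0L)
  expect_error(sampleOccurrences(env, n = 10, suitability = matrix(0, 10, 10)),
               "zero everywhere")
})

test_that("genotype simulation recovers the divergence parameter", {
  env <- testEnv()
  sim <- simulateGenotypes(env, nPops = 30, nPerPop = 10, nSnps = 2000,
                           baselineFst = 0.1, nCausal = 0,
                           missingRate = 0, admixed = FALSE, seed = 11)
  g <- genoCalls(sim$genotypes)
  Q <- ancestryQ(sim$genotypes)
  anc <- apply(Q, 1, which.max)
  # mean per-SNP WC theta between the three ancestral groups
  th <- vapply(seq_len(500), function(s) {
    oracleWcTheta(lapply(1:3, function(a)
      g[s, anc == a, drop = FALSE]))
  }, 0)
  expect_lt(abs(mean(th, na.rm = TRUE) - 0.1), 0.02 + 0.1 * 0.2)
})

test_that("missingness is completely at random and clines are planted", {
  sim <- testClineSim()
  g <- genoCalls(sim$genotypes)
  expect_equal(mean(is.na(g)), 0.185, tolerance = 0.02)

  # no-missing contract
  s0 <- simulateGenotypes(testEnv(), nPops = 12, nPerPop = 4, nSnps = 50,
                          baselineFst = 0.1, nCausal = 0, missingRate = 0,
                          seed = 1)
  expect_false(anyNA(genoCalls(s0$genotypes)))

  # missing rate equal across genotype classes (CAR): compare the observed
  # class mix against the underlying population-frequency expectation
  sim2 <- simulateGenotypes(testEnv(), nPops = 40, nPerPop = 10, nSnps = 300,
                            baselineFst = 0.1, nCausal = 0,
                            missingRate = 0.3, seed = 33)
  simFull <- simulateGenotypes(testEnv(), nPops = 40, nPerPop = 10,
                               nSnps = 300, baselineFst = 0.1, nCausal = 0,
                               missingRate = 0, seed = 33)
  gMiss <- genoCalls(sim2$genotypes); gFull <- genoCalls(simFull$genotypes)
  # same seed, missingness applied after: per-class missing rates equal
  for (cls in 0:2) {
    atRisk <- sum(gFull == cls)
    observedMissing <- sum(is.na(gMiss[gFull == cls]))
    expect_lt(abs(observedMissing / atRisk - 0.3),
              4 * sqrt(0.3 * 0.7 / atRisk))
  }

  # causal population frequencies track the predictor
  truth <- sim$truth
  zPred <- scale(truth@popEnv[, truth@clinePredictor])
  rho <- vapply(truth@causalSnpIds, function(s)
    abs(cor(truth@popFreq[, s], zPred, method = "spearman")), 0)
  expect_gt(median(rho), 0.6)

  # determinism of the full generator
  simA <- simulateGenotypes(testEnv(), nPops = 10, nPerPop = 3, nSnps = 40,
                            baselineFst = 0.1, nCausal = 5,
                            clineStrength = 2, seed = 9)
  simB <- simulateGenotypes(testEnv(), nPops = 10, nPerPop = 3, nSnps = 40,
                            baselineFst = 0.1, nCausal = 5,
                            clineStrength = 2, seed = 9)
  expect_identical(genoCalls(simA$genotypes), genoCalls(simB$genotypes))
})

test_that("landmark simulation plants shape effects and is deterministic", {
  # zero effects, zero noise: identical up to similarity transform
  lm0 <- simulateLandmarks(groups = "A", nPerGroup = 8, noiseSd = 0,
                           seed = 2)
  sh <- gpa(lm0)
  ref <- alignedCoords(sh)[1, , ]
  for (i in 2:8)
    expect_lt(max(abs(alignedCoords(sh)[i, , ] - ref)), 1e-8)

  expect_error(simulateLandmarks(groups = "A", nPerGroup = 3,
                                 noiseSd = -1), "non-negative")

  lmA <- simulateLandmarks(groups = c("A", "B"), nPerGroup = 5, seed = 4)
  lmB <- simulateLandmarks(groups = c("A", "B"), nPerGroup = 5, seed = 4)
  expect_identical(lmA@coords, lmB@coords)
})

test_that("writers round-trip through their plain-text formats", {
  tmp <- withr::local_tempdir()
  env <- makeEnvStack(2, c(12, 15), spatialRange = 2, seed = 8)
  writeEnvStack(env, file.path(tmp, "env"))
  env2 <- readEnvStack(file.path(tmp, "env"))
  expect_equal(sort(layerNames(env2)), sort(layerNames(env)))
  expect_equal(getLayer(env2, "PRJ"), getLayer(env, "PRJ"),
               tolerance = 1e-8)

  occ <- sampleOccurrences(env, NULL, n = 25, seed = 3)
  f <- file.path(tmp, "occ.csv")
  writeOccurrencesCsv(occ, f)
  expect_equal(readOccurrencesCsv(f)$lon, occ$lon)

  sim <- simulateGenotypes(env, nPops = 6, nPerPop = 4, nSnps = 30,
                           baselineFst = 0.2, nCausal = 0, seed = 5)
  G <- sim$genotypes
  writeGeno012(G, file.path(tmp, "g.tsv"))
  writePopMap(G, file.path(tmp, "pops.tsv"))
  writeQMatrix(G, file.path(tmp, "q.tsv"))
  G2 <- readGeno012(file.path(tmp, "g.tsv"), file.path(tmp, "pops.tsv"),
                    file.path(tmp, "q.tsv"), locus = locusMap(G))
  expect_equal(unname(genoCalls(G2)), unname(genoCalls(G)))
  expect_identical(popLabels(G2), popLabels(G))
  expect_equal(unname(ancestryQ(G2)), unname(ancestryQ(G)), tolerance = 1e-8)

  # VCF writer: independent read-back through vcfR
  skip_if_not_installed("vcfR")
  vf <- file.path(tmp, "g.vcf")
  writeVcfGt(G, vf)
  v <- suppressWarnings(vcfR::read.vcfR(vf, verbose = FALSE))
  gt <- vcfR::extract.gt(v, as.numeric = FALSE)
  dosage <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow(gt))
  expect_equal(unname(dosage), unname(genoCalls(G)))
})
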