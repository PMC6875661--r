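test_that("occurrence thinning keeps exactly one point per cell", {
  env <- makeEnvStack(1, c(10, 10), seed = 1)
  occ <- data.frame(lon = c(1, 2, 3), lat = c(1, 1, 1))
  expect_identical(nrow(thinOccurrences(occ, env)), 3L)

  dup <- data.frame(lon = rep(4, 10), lat = rep(7, 10))
  expect_identical(nrow(thinOccurrences(dup, env)), 1L)

  set.seed(2)
  rnd <- data.frame(lon = sample(1:10, 200, TRUE),
                    lat = sample(1:10, 200, TRUE))
  thinned <- thinOccurrences(rnd, env, seed = 3)
  expect_identical(nrow(thinned),
                   nrow(unique(rnd[, c("lon", "lat")])))
})

test_that("surface-range-envelope pseudo-absences fall outside the envelope", {
  env <- testEnv()
  tab <- envTable(env)
  # presences clustered where MTP is high
  pres <- tab[tab$MTP > quantile(tab$MTP, 0.8), ]
  pa <- srePseudoAbsences(env, pres, n = 100, nSets = 5, seed = 4)
  expect_length(pa, 5)
  for (s in pa) {
    expect_identical(nrow(s), 100L)
    expect_identical(anyDuplicated(s$cell), 0L)
    lo <- vapply(layerNames(env), function(v) quantile(pres[[v]], 0.025), 0)
    hi <- vapply(layerNames(env), function(v) quantile(pres[[v]], 0.975), 0)
    outside <- rep(FALSE, nrow(s))
    for (v in layerNames(env))
      outside <- outside | s[[v]] < lo[[v]] | s[[v]] > hi[[v]]
    expect_true(all(outside))
  }
  # presences spanning everything with quantile 0: nothing outside
  expect_error(srePseudoAbsences(env, tab, n = 10, quantile = 0),
               "outside the presence envelope")
})

test_that("TSS matches its confusion-matrix definition", {
  # hand-built confusion: TP=45 FN=5 TN=40 FP=10 -> sens .9 spec .8 tss .7
  labels <- c(rep(1, 50), rep(0, 50))
  scores <- c(rep(0.9, 45), rep(0.1, 5), rep(0.1, 40), rep(0.9, 10))
  expect_equal(tss(labels, scores, 0.5), 0.7, tolerance = 1e-12)

  # perfect separation
  expect_equal(tss(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 0.5), 1)
  # scores independent of labels stay near zero
  set.seed(5)
  expect_lt(abs(tss(rbinom(2000, 1, 0.5), runif(2000), 0.5)), 0.1)
  expect_error(tss(rep(1, 10), runif(10), 0.5), "both classes")

  # invariance under joint monotone rescaling of scores and threshold
  sc <- runif(200); lab <- rbinom(200, 1, 0.5)
  lab[1:2] <- c(0, 1)
  expect_equal(tss(lab, sc, 0.4), tss(lab, exp(sc), exp(0.4)))
})

test_that("calibration bookkeeping and null behaviour are correct", {
  env <- testEnv()
  tab <- envTable(env)
  set.seed(6)
  # shuffled labels: held-out TSS near zero
  idx <- sample(nrow(tab), 2000)
  dat <- tab[idx, ]
  pres <- dat[1:1000, ]; abs0 <- dat[1001:2000, ]
  res <- calibrateModels(pres, list(abs0), learners = c("glm", "rf"),
                         nRepeats = 1, seed = 7)
  expect_length(res, 2)     # bookkeeping: learners x sets x repeats
  expect_true(all(abs(vapply(res, `[[`, 0, "tss")) < 0.15))

  # separable data: high held-out TSS for every learner family
  pres2 <- tab[tab$MTP > quantile(tab$MTP, 0.75), ]
  abs2 <- tab[tab$MTP < quantile(tab$MTP, 0.25), ]
  set.seed(8)
  pres2 <- pres2[sample(nrow(pres2), 400), ]
  abs2 <- abs2[sample(nrow(abs2), 400), ]
  res2 <- calibrateModels(pres2, list(abs2), nRepeats = 1, seed = 9)
  expect_length(res2, 5)
  expect_gt(mean(vapply(res2, `[[`, 0, "tss")), 0.9)
})

test_that("permutation importance isolates the driving variable", {
  env <- testEnv()
  tab <- envTable(env)
  set.seed(10)
  dat <- tab[sample(nrow(tab), 1500), ]
  dat$pa <- rbinom(nrow(dat), 1, plogis(3 * dat$MTP))
  m <- invadapt:::.fitLearner("glm", dat, c("MTP", "HF"))

  # HF is absent from the generating function: importance near zero
  expect_lt(variableImportance(m, dat, "HF", nPerm = 5, seed = 1), 0.05)

  # single-variable model: matches the brute-force 1 - cor oracle
  m1 <- invadapt:::.fitLearner("glm", dat, "MTP")
  p0 <- invadapt:::.predictLearner(m1, dat)
  set.seed(99)
  oracle <- mean(vapply(1:5, function(i) {
    d <- dat; d$MTP <- sample(d$MTP)
    1 - cor(p0, invadapt:::.predictLearner(m1, d))
  }, 0))
  got <- variableImportance(m1, dat, "MTP", nPerm = 5, seed = 99)
  expect_equal(got, oracle, tolerance = 0.05)

  # reproducible under a fixed seed
  expect_identical(variableImportance(m, dat, "MTP", nPerm = 5, seed = 3),
                   variableImportance(m, dat, "MTP", nPerm = 5, seed = 3))
})

test_that("ensemble projection weights members by TSS", {
  env <- testEnv()
  tab <- envTable(env)
  set.seed(11)
  dat <- tab[sample(nrow(tab), 800), ]
  dat$pa <- as.integer(dat$MTP > 0)
  fits <- lapply(1:3, function(i)
    invadapt:::.fitLearner("glm", dat[sample(nrow(dat), 300), ],
                           layerNames(env)))
  mkres <- function(fit, tssVal) list(learner = "glm", paSet = 1, rep = 1,
                                      model = fit, tss = tssVal, auc = 0.9,
                                      threshold = 0.5)
  results <- Map(mkres, fits, c(0.5, 0.6, 0.9))

  # single member: ensemble equals that member's map
  one <- ensembleProject(results[3], env, dat)
  pm <- invadapt:::.predictLearner(fits[[3]], tab)
  expect_equal(as.vector(one$suitability), pm, tolerance = 1e-12)

  # three members: weighted mean with weights proportional to TSS
  ens <- ensembleProject(results, env, dat)
  w <- c(0.5, 0.6, 0.9) / 2
  manual <- Reduce(`+`, Map(function(f, wi)
    wi * invadapt:::.predictLearner(f, tab), fits, w))
  expect_equal(as.vector(ens$suitability), manual, tolerance = 1e-12)

  # members below the cutoff are dropped; none passing is an error
  expect_equal(length(ensembleProject(results, env, dat,
                                      tssMin = 0.7)$weights), 1L)
  expect_error(ensembleProject(results, env, dat, tssMin = 0.95),
               "no ensemble member")
})

test_that("niche-change metrics match brute-force set arithmetic", {
  A <- matrix(FALSE, 10, 10); A[1:5, 1:10] <- TRUE   # 50 cells
  B <- matrix(FALSE, 10, 10); B[1:10, 1:10] <- TRUE  # 100 cells, A subset
  m <- nicheChangeMetrics(A, B)
  expect_equal(m$stability, 1)
  expect_equal(m$expansion, 0)
  expect_equal(m$unfilling, 0.5)

  expect_equal(nicheChangeMetrics(A, A),
               list(stability = 1, expansion = 0, unfilling = 0,
                    counts = c(A = 50, B = 50, both = 50)))
  D1 <- matrix(c(TRUE, FALSE), 10, 10); D2 <- !D1
  md <- nicheChangeMetrics(D1, D2)
  expect_equal(md$stability, 0); expect_equal(md$expansion, 1)
  expect_equal(md$unfilling, 1)

  # random maps against explicit set computation
  set.seed(12)
  for (i in 1:10) {
    X <- matrix(runif(100) < 0.4, 10)
    Y <- matrix(runif(100) < 0.5, 10)
    if (!any(X) || !any(Y)) next
    mm <- nicheChangeMetrics(X, Y)
    sA <- which(X); sB <- which(Y)
    expect_equal(mm$stability, length(intersect(sA, sB)) / length(sA))
    expect_equal(mm$expansion, length(setdiff(sA, sB)) / length(sA))
    expect_equal(mm$unfilling, length(setdiff(sB, sA)) / length(sB))
    expect_equal(mm$stability + mm$expansion, 1)
  }
})

test_that("occurrence prediction rate counts points on the binary map", {
  all1 <- matrix(TRUE, 5, 5); all0 <- matrix(FALSE, 5, 5)
  occ <- data.frame(lon = c(1, 3, 5), lat = c(2, 4, 1))
  expect_equal(as.numeric(occurrencePredictionRate(all1, occ)), 1)
  expect_equal(as.numeric(occurrencePredictionRate(all0, occ)), 0)

  chk <- outer(1:5, 1:5, function(r, c) (r + c) %% 2 == 0)
  pts <- data.frame(lon = c(1, 2, 3, 9), lat = c(1, 1, 2, 9))
  r <- occurrencePredictionRate(chk, pts)
  # hand count: (1,1) TRUE, (1,2) FALSE, (2,3) FALSE -> 1/3, one excluded
  expect_equal(as.numeric(r), 1 / 3)
  expect_identical(attr(r, "excluded"), 1L)
})
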