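test_that("Weir-Cockerham theta matches the brute-force oracle", {
  # fixed difference
  calls <- matrix(c(rep(2, 10), rep(0, 10)), 1, 20,
                  dimnames = list("s1", paste0("i", 1:20)))
  G <- quickGeno(calls, population = rep(c("A", "B"), each = 10))
  expect_equal(wcFstPerLocus(G)$s1$fst["A", "B"], 1, tolerance = 1e-12)

  # equal frequencies, large n: near zero (floored at 0)
  set.seed(1)
  g2 <- matrix(rbinom(800, 2, 0.5), 1, 800,
               dimnames = list("s", paste0("i", 1:800)))
  G2 <- quickGeno(g2, population = rep(c("A", "B"), each = 400))
  expect_lt(wcFstPerLocus(G2)$s$fst[1, 2], 0.02)

  # textbook two-population case against the independently coded oracle
  set.seed(2)
  gA <- rbinom(10, 2, 0.2); gB <- rbinom(10, 2, 0.8)
  g3 <- matrix(c(gA, gB), 1, 20, dimnames = list("s", paste0("i", 1:20)))
  G3 <- quickGeno(g3, population = rep(c("A", "B"), each = 10))
  got <- wcFstPerLocus(G3)$s$fst["A", "B"]
  want <- oracleWcTheta(list(matrix(gA, 1), matrix(gB, 1)))
  expect_equal(got, max(0, want), tolerance = 1e-10)

  # multi-SNP loci and up to 4 populations, with missing calls
  set.seed(3)
  for (rep in 1:5) {
    nPop <- sample(2:4, 1); nSnp <- sample(1:3, 1); nInd <- 12
    freqs <- runif(nPop, 0.1, 0.9)
    g <- do.call(cbind, lapply(freqs, function(f)
      matrix(rbinom(nSnp * nInd, 2, f), nSnp, nInd)))
    g[sample(length(g), round(0.05 * length(g)))] <- NA
    rownames(g) <- paste0("s", seq_len(nSnp))
    colnames(g) <- paste0("i", seq_len(ncol(g)))
    pops <- rep(LETTERS[1:nPop], each = nInd)
    Gm <- quickGeno(g, population = pops, locus = rep("L", nSnp))
    f <- wcFstPerLocus(Gm, minN = 5)$L
    for (i in 1:(nPop - 1)) for (j in (i + 1):nPop) {
      pi <- LETTERS[i]; pj <- LETTERS[j]
      if (!(pi %in% f$pops && pj %in% f$pops)) next
      want <- oracleWcTheta(list(g[, pops == pi, drop = FALSE],
                                 g[, pops == pj, drop = FALSE]))
      expect_equal(f$fst[pi, pj], max(0, want), tolerance = 1e-10)
    }
  }
})

test_that("population roster respects the minimum sample size", {
  set.seed(4)
  g <- matrix(rbinom(60, 2, 0.5), 2, 30,
              dimnames = list(c("a", "b"), paste0("i", 1:30)))
  g[, 25:30] <- NA      # six of the third population's ten lack the locus
  G <- quickGeno(g, population = rep(c("A", "B", "C"), each = 10),
                 locus = c("L", "L"))
  f <- wcFstPerLocus(G, minN = 8)$L
  expect_false("C" %in% f$pops)
  expect_true(all(c("A", "B") %in% f$pops))
  # rescaled copy lives in [0,1] with zero diagonal
  expect_true(all(f$rescaled >= 0 & f$rescaled <= 1))
  expect_true(all(diag(f$rescaled) == 0))
})

test_that("I-spline basis matches numerical integration of M-splines", {
  kn <- c(0, 0.4, 1)
  B <- isplineBasis(c(0, 1), knots = kn)
  expect_equal(unname(B[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(B[2, ]), c(1, 1, 1), tolerance = 1e-12)

  # numerical oracle: integrate the order-2 M-splines on the augmented
  # knot vector (a,a,b,c,c)
  mspline <- function(x, i, a, b, cc) {
    if (i == 1) ifelse(x >= a & x <= b, 2 * (b - x) / (b - a)^2, 0)
    else if (i == 2) ifelse(x < a | x > cc, 0,
      ifelse(x <= b, 2 * (x - a) / ((b - a) * (cc - a)),
             2 * (cc - x) / ((cc - b) * (cc - a))))
    else ifelse(x >= b & x <= cc, 2 * (x - b) / (cc - b)^2, 0)
  }
  xs <- c(0.1, 0.25, 0.4, 0.55, 0.9)
  Bx <- isplineBasis(xs, knots = kn)
  for (i in 1:3) for (k in seq_along(xs)) {
    oracle <- integrate(mspline, 0, xs[k], i = i, a = 0, b = 0.4, cc = 1,
                        rel.tol = 1e-10)$value
    expect_equal(unname(Bx[k, i]), oracle, tolerance = 1e-6)
  }
  # monotone in x
  grid <- isplineBasis(seq(0, 1, 0.01), knots = kn)
  expect_true(all(diff(grid[, 1]) >= -1e-12))
  expect_true(all(diff(grid[, 2]) >= -1e-12))
  expect_true(all(diff(grid[, 3]) >= -1e-12))
  expect_error(isplineBasis(c(1, 1, 1)), "distinct")
})

test_that("dissimilarity model recovers planted turnover", {
  set.seed(5)
  ns <- 40
  envS <- cbind(P1 = runif(ns), P2 = runif(ns))
  kn <- c(0, 0.5, 1)
  Btrue <- isplineBasis(envS[, 1], knots = kn)
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  bTrue <- c(0.5, 0.3, 0.4)
  eta <- 0.2 + abs(Btrue[pairs[, 1], ] - Btrue[pairs[, 2], ]) %*% bTrue
  y <- pmin(pmax(1 - exp(-eta) + rnorm(length(eta), 0, 0.02), 0), 0.999)
  Dm <- matrix(0, ns, ns); Dm[pairs] <- y; Dm <- Dm + t(Dm)
  m <- fitGdm(Dm, envS)

  ends <- isplineBasis(c(kn[1], min(envS[, 1]), max(envS[, 1]), kn[3]),
                       knots = kn)
  trueHeight <- sum(bTrue * (ends[3, ] - ends[2, ]))
  expect_lt(abs(partialTurnover(m, "P1") - trueHeight) / trueHeight, 0.10)
  expect_lt(partialTurnover(m, "P2"), 0.1)
  expect_gt(pctDeviance(m), 90)
  expect_true(all(m@fitted >= 0 & m@fitted < 1))

  # constant-zero dissimilarity: no turnover, no explained deviance
  m0 <- fitGdm(matrix(0, 20, 20), cbind(P1 = runif(20)))
  expect_equal(unname(partialTurnovers(m0)), 0)
  expect_equal(pctDeviance(m0), 0)

  # shuffled dissimilarities: explained deviance collapses
  ysh <- sample(y)
  Ds <- matrix(0, ns, ns); Ds[pairs] <- ysh; Ds <- Ds + t(Ds)
  msh <- fitGdm(Ds, envS)
  expect_lt(pctDeviance(msh), 10)
})

test_that("partial turnover is the sum of a predictor's coefficients", {
  m <- new("GdmModel", intercept = 0.1,
           coefs = list(P = c(0.2, 0.1, 0.1), geography = c(0, 0, 0)),
           knots = list(P = c(0, 0.5, 1), geography = c(0, 1, 2)),
           predictors = c("P", "geography"), nullDeviance = 10,
           explainedDeviance = 5, pctDeviance = 50,
           observed = 0.5, fitted = 0.5, siteEnv = matrix(0, 1, 1),
           coords = matrix(0, 0, 2), dissimilarity = matrix(0, 1, 1))
  expect_equal(partialTurnover(m, "P"), 0.4)
  expect_equal(partialTurnover(m, "geography"), 0)
  expect_error(partialTurnover(m, "nope"), "unknown predictor")
})

test_that("reference group gives a stable null level", {
  sim <- testNullSim()
  G <- sim$genotypes
  se <- sim$truth@popEnv
  co <- sim$truth@popCoords
  r1 <- referenceGroupGdm(G, se, co, nRef = 200, seed = 1)
  r2 <- referenceGroupGdm(G, se, co, nRef = 200, seed = 2)
  # structure-only data: little deviance explained by environment
  expect_lt(pctDeviance(r1), 25)
  # different draws, similar answer
  expect_lt(abs(pctDeviance(r1) - pctDeviance(r2)), 5)
})

test_that("candidate classification applies all three criteria", {
  # synthetic models: one weak locus (below reference), one geography-
  # driven locus, built directly
  mk <- function(coefs, pct, siteEnv, Dm) {
    preds <- names(coefs)
    new("GdmModel", intercept = 0.1, coefs = coefs,
        knots = lapply(coefs, function(x) c(0, 0.5, 1)),
        predictors = preds, nullDeviance = 100,
        explainedDeviance = pct, pctDeviance = pct,
        observed = 0.5, fitted = 0.5, siteEnv = siteEnv,
        coords = matrix(0, 0, 2), dissimilarity = Dm)
  }
  set.seed(6)
  ns <- 25
  envS <- cbind(P1 = runif(ns))
  Dm <- matrix(0.3, ns, ns); diag(Dm) <- 0
  ref <- mk(list(P1 = c(0.01, 0, 0), geography = c(0.01, 0, 0)), 2, envS, Dm)
  weak <- mk(list(P1 = c(0.3, 0, 0), geography = c(0, 0, 0)), 1, envS, Dm)
  geo <- mk(list(P1 = c(0.1, 0, 0), geography = c(0.5, 0, 0)), 30, envS, Dm)
  out <- classifyCandidates(list(weak = weak, geo = geo), ref)
  expect_identical(out$status[out$locus == "weak"], "not_candidate")
  expect_false(out$C1[out$locus == "weak"])
  expect_identical(out$status[out$locus == "geo"], "false_positive")
})

test_that("turnover maps apply the fitted monotone transform", {
  set.seed(7)
  ns <- 30
  envS <- cbind(PRJ = runif(ns, -2, 2))
  B <- isplineBasis(envS[, 1])
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  eta <- 0.1 + abs(B[pairs[, 1], ] - B[pairs[, 2], ]) %*% c(0.4, 0.2, 0.2)
  y <- 1 - exp(-eta)
  Dm <- matrix(0, ns, ns); Dm[pairs] <- y; Dm <- Dm + t(Dm)
  m <- fitGdm(Dm, envS)

  env <- testEnv()
  mp <- predictTurnoverMap(m, env, "PRJ")
  # constant raster: constant map
  envC <- new("EnvStack", layers = array(0.5, c(10, 10, 1),
              dimnames = list(NULL, NULL, "PRJ")))
  mc <- predictTurnoverMap(m, envC, "PRJ")
  expect_equal(max(mc) - min(mc), 0)

  # monotone raster gradient gives a monotone map
  envM <- new("EnvStack", layers = array(rep(seq(-2, 2, length.out = 10),
              each = 10), c(10, 10, 1), dimnames = list(NULL, NULL, "PRJ")))
  mm <- predictTurnoverMap(m, envM, "PRJ")
  expect_true(all(diff(mm[1, ]) >= -1e-12))

  # span of the map over the full gradient equals the partial turnover
  kn <- m@knots$PRJ
  envE <- new("EnvStack", layers = array(c(kn[1], kn[3]), c(10, 10, 1),
              dimnames = list(NULL, NULL, "PRJ")))
  me <- predictTurnoverMap(m, envE, "PRJ")
  expect_equal(max(me) - min(me), partialTurnover(m, "PRJ"),
               tolerance = 1e-10)
})

test_that("observed-vs-predicted diagnostics behave at the extremes", {
  set.seed(8)
  ns <- 30
  envS <- cbind(P = runif(ns))
  B <- isplineBasis(envS[, 1])
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  y <- as.vector(1 - exp(-(0.1 + abs(B[pairs[, 1], ] - B[pairs[, 2], ])
                           %*% c(0.5, 0.3, 0.2))))
  Dm <- matrix(0, ns, ns); Dm[pairs] <- y; Dm <- Dm + t(Dm)
  m <- fitGdm(Dm, envS)
  d <- observedVsPredicted(m)
  expect_gt(d$pearson, 0.99)
  # deterministic given model
  expect_identical(d$pearson, observedVsPredicted(m)$pearson)
})
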