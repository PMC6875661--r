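# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small 6-layer landscape shared across modules
testEnv <- function() cached("env6", makeEnvStack(6, c(50, 50),
                                                  spatialRange = 4, seed = 42))

# study-scale genotype simulation with planted clines
testClineSim <- function() cached("clineSim", {
  simulateGenotypes(testEnv(), nPops = 90, nPerPop = 6, nSnps = 2000,
                    baselineFst = 0.1, nCausal = 20, clinePredictor = "PRJ",
                    clineStrength = 3, seed = 101)
})

# structure-only simulation (no environmental effect)
testNullSim <- function() cached("nullSim", {
  simulateGenotypes(testEnv(), nPops = 90, nPerPop = 6, nSnps = 2000,
                    baselineFst = 0.1, nCausal = 0, clineStrength = 0,
                    seed = 202)
})

# a small aligned shape sample with two groups, one landmark displaced
testShapes <- function() cached("shapes", {
  eff <- matrix(0, 20, 2); eff[5, ] <- c(0.1, 0.1)
  lms <- simulateLandmarks(groups = c("A", "B"), nPerGroup = 25,
                           groupShapeEffects = list(B = eff),
                           noiseSd = 0.02, seed = 7)
  gpa(lms)
})

# brute-force Weir-Cockerham theta from genotype count tables; written
# directly from the variance-component definitions, loops and all, as an
# independent oracle for the vectorized implementation
oracleWcTheta <- function(genoList) {
  # genoList: per population, a matrix SNPs x individuals of 0/1/2 (NA ok)
  r <- length(genoList)
  nSnp <- nrow(genoList[[1]])
  sumA <- 0; sumAll <- 0
  for (s in seq_len(nSnp)) {
    n <- p <- h <- numeric(r)
    for (i in seq_len(r)) {
      x <- genoList[[i]][s, ]
      x <- x[!is.na(x)]
      n[i] <- length(x)
      p[i] <- sum(x) / (2 * length(x))
      h[i] <- mean(x == 1)
    }
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sumA <- sumA + a
    sumAll <- sumAll + a + b + cc
  }
  sumA / sumAll
}

# build a GenotypeCalls object from a plain matrix with minimal metadata
quickGeno <- function(calls, population, locus = NULL) {
  if (is.null(rownames(calls))) rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("i", seq_len(ncol(calls)))
  if (is.null(locus)) locus <- rownames(calls)
  GenotypeCalls(calls, population = population, locus = locus)
}
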