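#' Generate a stack of spatially autocorrelated environmental layers
#'
#' Each layer is Gaussian white noise smoothed by circular convolution with
#' a Gaussian kernel of width \code{spatialRange} (in cells) and then
#' standardized; cross-layer correlation is imposed afterwards by mixing the
#' independent fields through the Cholesky factor of the target correlation
#' matrix, so the per-cell correlation between layers matches the target in
#' expectation while each layer keeps its spatial autocorrelation.
#'
#' @param nLayers number of layers
#' @param gridShape integer(2): rows, cols (at least 10 x 10)
#' @param spatialRange Gaussian kernel standard deviation in cells
#' @param interLayerCorrelation target correlation matrix (positive
#'   semi-definite); default identity
#' @param layerNames names for the layers; defaults to the six predictors
#'   used throughout (PRJ, PRS, MTP, ISO, NPP, HF) when \code{nLayers <= 6}
#' @param seed integer seed
#' @return an \linkS4class{EnvStack}
#' @examples
#' env <- makeEnvStack(2, c(40, 40), spatialRange = 3, seed = 1)
#' @export
makeEnvStack <- function(nLayers, gridShape, spatialRange = 3,
                         interLayerCorrelation = diag(nLayers),
                         layerNames = NULL, seed = 1) {
  stopifnot(nLayers >= 1, length(gridShape) == 2)
  if (any(gridShape < 10)) stop("gridShape must be at least 10 x 10")
  C <- as.matrix(interLayerCorrelation)
  if (nrow(C) != nLayers || ncol(C) != nLayers)
    stop("interLayerCorrelation must be ", nLayers, " x ", nLayers)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("interLayerCorrelation is not positive semi-definite")
  U <- chol(C + diag(1e-10, nLayers))
  if (is.null(layerNames)) {
    defaults <- c("PRJ", "PRS", "MTP", "ISO", "NPP", "HF")
    layerNames <- if (nLayers <= 6) defaults[seq_len(nLayers)] else
      paste0("env", seq_len(nLayers))
  }
  set.seed(seed)
  nr <- gridShape[1]; nc <- gridShape[2]
  fields <- matrix(0, nr * nc, nLayers)
  for (l in seq_len(nLayers))
    fields[, l] <- as.vector(.smoothField(matrix(rnorm(nr * nc), nr, nc),
                                          spatialRange))
  fields <- scale(fields)              # unit variance before mixing
  mixed <- fields %*% U
  arr <- array(mixed, dim = c(nr, nc, nLayers),
               dimnames = list(NULL, NULL, layerNames))
  new("EnvStack", layers = arr)
}

# Gaussian smoothing by FFT-based circular convolution.
.smoothField <- function(mat, range) {
  if (range <= 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * range^2))
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(mat) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  out
}

#' Sample presence points from a logistic suitability surface
#'
#' Suitability per cell is \code{plogis(intercept + sum(coef * layer))};
#' presences are drawn with probability proportional to suitability (with
#' replacement, emulating repeated observation of favourable cells).  A
#' pre-computed suitability matrix may be supplied instead of parameters.
#'
#' @param env an \linkS4class{EnvStack}
#' @param suitabilityParams list with \code{intercept} and named \code{coefs}
#'   over layers; ignored when \code{suitability} is given
#' @param n number of presence points (0 allowed)
#' @param seed integer seed
#' @param suitability optional rows x cols suitability matrix in [0, 1]
#' @return data.frame with columns lon (column index), lat (row index),
#'   cell, and the environmental value of every layer at the point
#' @export
sampleOccurrences <- function(env, suitabilityParams = NULL, n, seed = 1,
                              suitability = NULL) {
  stopifnot(is(env, "EnvStack"))
  d <- gridDim(env)
  if (is.null(suitability)) {
    eta <- matrix(0, d[1], d[2])
    if (!is.null(suitabilityParams)) {
      eta <- eta + suitabilityParams$intercept
      for (nm in names(suitabilityParams$coefs))
        eta <- eta + suitabilityParams$coefs[[nm]] * getLayer(env, nm)
    }
    suitability <- plogis(eta)
  }
  if (!all(dim(suitability) == d)) stop("suitability grid mismatch")
  w <- as.vector(suitability)
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("suitability is zero everywhere")
  tab <- envTable(env)
  if (n == 0) return(tab[0, , drop = FALSE])
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  names(out)[names(out) == "col"] <- "lon"
  names(out)[names(out) == "row"] <- "lat"
  out[, c("lon", "lat", "cell", layerNames(env))]
}

#' Simulate structured genotypes with optional environmental clines
#'
#' Populations are placed at distinct raster cells and assigned to one of
#' \code{nAncestries} spatially blocked ancestral groups (vertical bands of
#' the grid).  Ancestral allele frequencies are drawn once per SNP; each
#' ancestry diverges from them by a Balding-Nichols beta draw parameterized
#' by \code{baselineFst}; population frequencies are the Q-weighted mixture
#' of ancestry frequencies plus a small extra within-ancestry drift
#' (\code{fstWithin}).  Causal SNPs are additionally shifted on the logit
#' scale by \code{clineStrength} times the standardized value of
#' \code{clinePredictor} at the population's cell (clamped to [0.01, 0.99]).
#' Genotypes are Binomial(2, population frequency); missingness is applied
#' completely at random.  Monomorphic SNPs are redrawn (up to
#' \code{maxRetry} rounds).
#'
#' @param env an \linkS4class{EnvStack} providing predictor surfaces
#' @param nAncestries number of ancestral groups (default 3)
#' @param nPops,nPerPop populations and diploid individuals per population
#' @param nSnps number of biallelic SNPs
#' @param baselineFst Balding-Nichols divergence of ancestries, in (0,1)
#' @param nCausal number of SNPs given an environmental cline
#' @param clinePredictor layer name driving the cline
#' @param clineStrength logit slope per standardized predictor unit
#' @param missingRate completely-at-random missing call rate (study-scale
#'   default 0.185)
#' @param fstWithin extra population-level drift within ancestries
#' @param admixed when TRUE (default) population ancestry coefficients are
#'   Dirichlet draws concentrated on the home ancestry; when FALSE they are
#'   one-hot (used for divergence-parameter recovery checks, where the
#'   between-ancestry divergence is only well defined without admixture)
#' @param snpsPerLocusMax SNPs are grouped into RAD loci of 1..this many SNPs
#' @param maxRetry redraw rounds for monomorphic SNPs
#' @param seed integer seed
#' @return list with \code{genotypes} (a \linkS4class{GenotypeCalls}) and
#'   \code{truth} (a \linkS4class{SyntheticTruth})
#' @export
simulateGenotypes <- function(env, nAncestries = 3, nPops = 90, nPerPop = 6,
                              nSnps = 2000, baselineFst = 0.1, nCausal = 20,
                              clinePredictor = layerNames(env)[1],
                              clineStrength = 0, missingRate = 0.185,
                              fstWithin = 0.02, admixed = TRUE,
                              snpsPerLocusMax = 3, maxRetry = 10, seed = 1) {
  stopifnot(is(env, "EnvStack"), nCausal <= nSnps,
            baselineFst > 0, baselineFst < 1)
  set.seed(seed)
  d <- gridDim(env)
  ncell <- d[1] * d[2]
  if (nPops > ncell) stop("more populations than raster cells")
  cells <- sample.int(ncell, nPops)
  popRow <- (cells - 1L) %% d[1] + 1L
  popCol <- (cells - 1L) %/% d[1] + 1L
  popEnv <- vapply(layerNames(env),
                   function(nm) getLayer(env, nm)[cbind(popRow, popCol)],
                   numeric(nPops))
  popCoords <- cbind(x = popCol, y = popRow)

  band <- pmin(nAncestries, 1L + (popCol - 1L) %/%
                 ceiling(d[2] / nAncestries))
  Qpop <- matrix(0, nPops, nAncestries)
  if (admixed) {
    for (i in seq_len(nPops)) {
      alpha <- rep(0.75, nAncestries); alpha[band[i]] <- 12
      g <- rgamma(nAncestries, alpha)
      Qpop[i, ] <- g / sum(g)
    }
  } else {
    Qpop[cbind(seq_len(nPops), band)] <- 1
  }

  zPred <- as.vector(scale(popEnv[, clinePredictor]))
  causal <- sort(sample.int(nSnps, nCausal))
  isCausal <- seq_len(nSnps) %in% causal

  drawFreqs <- function(m) {
    # returns nPops x m population frequency matrix
    p0 <- runif(m, 0.05, 0.95)
    shapeA <- (1 - baselineFst) / baselineFst
    pa <- matrix(rbeta(nAncestries * m, rep(p0, each = nAncestries) * shapeA,
                       rep(1 - p0, each = nAncestries) * shapeA),
                 nAncestries, m)
    pmix <- Qpop %*% pa
    if (fstWithin > 0) {
      shapeW <- (1 - fstWithin) / fstWithin
      pmix[] <- rbeta(length(pmix), pmix * shapeW, (1 - pmix) * shapeW)
    }
    pmix
  }

  pop <- rep(sprintf("pop%02d", seq_len(nPops)), each = nPerPop)
  nInd <- nPops * nPerPop
  G <- matrix(NA_integer_, nSnps, nInd)
  popFreq <- matrix(NA_real_, nPops, nSnps)
  todo <- seq_len(nSnps)
  for (round in seq_len(maxRetry)) {
    if (!length(todo)) break
    pf <- drawFreqs(length(todo))
    shift <- outer(zPred, clineStrength * as.numeric(isCausal[todo]))
    pf <- plogis(qlogis(pmin(pmax(pf, 1e-6), 1 - 1e-6)) + shift)
    pf <- pmin(pmax(pf, 0.01), 0.99)
    probs <- t(pf)[, rep(seq_len(nPops), each = nPerPop), drop = FALSE]
    g <- matrix(rbinom(length(probs), 2, probs), nrow(probs), ncol(probs))
    poly <- apply(g, 1, function(x) length(unique(x)) > 1)
    keep <- which(poly)
    G[todo[keep], ] <- g[keep, , drop = FALSE]
    popFreq[, todo[keep]] <- pf[, keep, drop = FALSE]
    todo <- todo[!poly]
  }
  if (length(todo)) {               # retry cap hit: keep last draw as-is
    warning(length(todo), " SNPs remained monomorphic after retries")
    pf <- drawFreqs(length(todo))
    probs <- t(pf)[, rep(seq_len(nPops), each = nPerPop), drop = FALSE]
    G[todo, ] <- matrix(rbinom(length(probs), 2, probs),
                        nrow(probs), ncol(probs))
    popFreq[, todo] <- pf
  }
  lociSizes <- integer(0)
  while (sum(lociSizes) < nSnps)
    lociSizes <- c(lociSizes, sample.int(snpsPerLocusMax, 1))
  lociSizes[length(lociSizes)] <- nSnps - sum(lociSizes[-length(lociSizes)])
  locus <- rep(sprintf("locus%05d", seq_along(lociSizes)), lociSizes)

  if (missingRate > 0) {
    # whole-tag dropout: a locus is missing for an individual as a block,
    # independent of genotype (emulates RAD locus dropout)
    drop <- matrix(runif(length(lociSizes) * nInd) < missingRate,
                   length(lociSizes), nInd)
    G[drop[rep(seq_along(lociSizes), lociSizes), , drop = FALSE]] <-
      NA_integer_
  }
  snpIds <- sprintf("snp%05d", seq_len(nSnps))
  rownames(G) <- snpIds
  colnames(G) <- sprintf("ind%04d", seq_len(nInd))

  Qind <- Qpop[rep(seq_len(nPops), each = nPerPop), , drop = FALSE]
  geno <- GenotypeCalls(G, population = pop, locus = locus,
                        position = unlist(lapply(lociSizes, seq_len)) * 10L,
                        Q = Qind)
  colnames(popEnv) <- layerNames(env)
  colnames(popFreq) <- snpIds
  popNames <- sprintf("pop%02d", seq_len(nPops))
  rownames(popEnv) <- rownames(popCoords) <- rownames(popFreq) <- popNames
  truth <- new("SyntheticTruth", causalSnpIds = snpIds[causal],
               clinePredictor = clinePredictor,
               clineStrength = clineStrength, baselineFst = baselineFst,
               popEnv = popEnv, popCoords = popCoords, popFreq = popFreq)
  list(genotypes = geno, truth = truth)
}

#' A fixed 20-landmark mean wing shape
#'
#' Deterministic landmark template used as the default mean configuration:
#' vein intersections and termini along the leading and trailing edges of
#' an elongated wing outline.
#'
#' @return 20 x 2 coordinate matrix
#' @export
wingMeanShape <- function() {
  t_up <- seq(0, pi / 2, length.out = 10)
  t_lo <- seq(pi / 2, pi, length.out = 10)
  up <- cbind(3 * cos(t_up), 1.0 * sin(t_up) + 0.15 * cos(3 * t_up))
  lo <- cbind(3 * cos(t_lo), 0.6 * sin(t_lo) - 0.10 * cos(2 * t_lo))
  rbind(up, lo)
}

#' Simulate landmark configurations with group effects
#'
#' Each configuration is mean shape + its group's displacement + isotropic
#' landmark noise, scaled by a per-individual size (log-normal around the
#' group's size effect) and placed at a random orientation and position.
#'
#' @param meanShape k x 2 mean configuration (default \code{wingMeanShape()})
#' @param groups character vector of group names
#' @param nPerGroup individuals per group (recycled)
#' @param groupShapeEffects named list of k x 2 displacement matrices (or
#'   NULL for none)
#' @param sizeEffects named numeric of per-group log-size offsets (or NULL)
#' @param noiseSd isotropic landmark noise standard deviation (>= 0)
#' @param baseSize mean centroid-size scale factor
#' @param seed integer seed
#' @return a \linkS4class{LandmarkSet} with factor \code{group}
#' @export
simulateLandmarks <- function(meanShape = wingMeanShape(), groups,
                              nPerGroup, groupShapeEffects = NULL,
                              sizeEffects = NULL, noiseSd = 0.02,
                              baseSize = 1, seed = 1) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  k <- nrow(meanShape)
  cs0 <- sqrt(sum(scale(meanShape, scale = FALSE)^2))
  if (cs0 <= 0) stop("degenerate mean shape")
  nPerGroup <- rep(nPerGroup, length.out = length(groups))
  n <- sum(nPerGroup)
  set.seed(seed)
  coords <- array(0, c(n, k, 2))
  grp <- character(n)
  i <- 0
  for (g in seq_along(groups)) {
    eff <- if (!is.null(groupShapeEffects) &&
               !is.null(groupShapeEffects[[groups[g]]]))
      groupShapeEffects[[groups[g]]] else matrix(0, k, 2)
    sz <- if (!is.null(sizeEffects) && !is.na(sizeEffects[groups[g]]))
      sizeEffects[[groups[g]]] else 0
    for (j in seq_len(nPerGroup[g])) {
      i <- i + 1
      cfg <- meanShape + eff + matrix(rnorm(2 * k, 0, noiseSd), k, 2)
      s <- baseSize * exp(sz + rnorm(1, 0, 0.05))
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      cfg <- s * cfg %*% R
      cfg <- sweep(cfg, 2, runif(2, -10, 10), "+")
      coords[i, , ] <- cfg
      grp[i] <- groups[g]
    }
  }
  new("LandmarkSet", coords = coords,
      factors = data.frame(group = grp, stringsAsFactors = FALSE))
}
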