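#' @importFrom stats rgamma
NULL

# Weir-Cockerham variance components for one SNP between two populations.
# p: allele freqs, h: observed heterozygote freqs, n: sample sizes.
.wcComponents <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# per-population allele freq, het freq and n for a block of SNP calls
.popSnpStats <- function(calls) {
  n <- rowSums(!is.na(calls))
  p <- rowSums(calls, na.rm = TRUE) / (2 * n)
  h <- rowSums(calls == 1, na.rm = TRUE) / n
  list(p = p, h = h, n = n)
}

#' Pairwise Weir-Cockerham FST per SNP locus
#'
#' For every RAD locus (or a supplied SNP grouping) computes the pairwise
#' Weir-Cockerham theta between populations, combining the SNPs of a
#' multi-SNP locus by ratio of summed variance components.  Populations
#' with fewer than \code{minN} individuals genotyped at the locus (a call
#' at any of its SNPs) are excluded from that locus's roster.  Negative estimates are
#' floored at zero; a min-max rescaled copy across pairs is attached.
#'
#' @param G a \linkS4class{GenotypeCalls}
#' @param loci optional subset of locus ids (default: all)
#' @param minN minimum genotyped individuals per population (default 5)
#' @return named list; per locus a list with \code{pops}, \code{fst}
#'   (floored theta matrix), \code{rescaled} (min-max in [0,1]), and
#'   \code{nPop}.  Loci with fewer than two eligible populations are
#'   dropped with a message.
#' @export
wcFstPerLocus <- function(G, loci = NULL, minN = 5) {
  g <- genoCalls(G)
  lmap <- locusMap(G)
  pop <- popLabels(G)
  if (is.null(loci)) loci <- unique(lmap)
  popsAll <- sort(unique(pop))
  out <- list()
  for (loc in loci) {
    rows <- which(lmap == loc)
    sub <- g[rows, , drop = FALSE]
    stats <- lapply(popsAll, function(pp)
      .popSnpStats(sub[, pop == pp, drop = FALSE]))
    names(stats) <- popsAll
    nAtLocus <- vapply(popsAll, function(pp)
      sum(colSums(!is.na(sub[, pop == pp, drop = FALSE])) > 0), 0L)
    elig <- popsAll[nAtLocus >= minN]
    if (length(elig) < 2) {
      message("locus ", loc, ": fewer than two eligible populations; skipped")
      next
    }
    k <- length(elig)
    fst <- matrix(0, k, k, dimnames = list(elig, elig))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      s1 <- stats[[elig[i]]]; s2 <- stats[[elig[j]]]
      comp <- vapply(seq_along(rows), function(s)
        .wcComponents(s1$p[s], s2$p[s], s1$h[s], s2$h[s], s1$n[s], s2$n[s]),
        c(a = 0, b = 0, c = 0))
      # SNPs unobserved in one of the two populations contribute nothing
      comp <- comp[, colSums(!is.finite(comp)) == 0, drop = FALSE]
      den <- sum(comp)
      if (!length(comp)) den <- 0
      th <- if (den <= 0) 0 else sum(comp["a", ]) / den
      fst[i, j] <- fst[j, i] <- max(0, th)
    }
    up <- fst[upper.tri(fst)]
    rng <- range(up)
    resc <- if (diff(rng) > 0) (fst - rng[1]) / diff(rng) else fst * 0
    diag(resc) <- 0
    resc[resc < 0] <- 0
    out[[loc]] <- list(locus = loc, pops = elig, fst = fst,
                       rescaled = resc, nPop = k)
  }
  out
}

#' Monotone I-spline basis
#'
#' Order-2 I-splines (integrated M-splines) on the knot vector
#' \code{knots}; each basis function rises monotonically from 0 at the
#' gradient minimum to 1 at the maximum.  Values outside the knot range are
#' clamped.  Three splines with knots at the 0/50/100th percentiles of
#' \code{x} are the default, following the originating-dissimilarity-model
#' convention.
#'
#' @param x numeric gradient values
#' @param knots numeric(3) increasing knot positions, or NULL for the
#'   percentile default
#' @return n x 3 basis matrix with attribute \code{knots}
#' @export
isplineBasis <- function(x, knots = NULL) {
  if (is.null(knots)) {
    if (length(unique(x)) < 3)
      stop("fewer distinct gradient values than knots")
    knots <- as.numeric(quantile(x, c(0, 0.5, 1), names = FALSE))
  }
  a <- knots[1]; b <- knots[2]; cc <- knots[3]
  if (!(a < b && b < cc)) stop("knots must be strictly increasing")
  x <- pmin(pmax(x, a), cc)
  I1 <- ifelse(x <= b, ((b - a)^2 - (b - x)^2) / (b - a)^2, 1)
  I2 <- ifelse(x <= b, (x - a)^2 / ((b - a) * (cc - a)),
               (b - a) / (cc - a) +
                 ((cc - b)^2 - (cc - x)^2) / ((cc - b) * (cc - a)))
  I3 <- ifelse(x <= b, 0, (x - b)^2 / (cc - b)^2)
  out <- cbind(I1, I2, I3)
  attr(out, "knots") <- knots
  out
}

# site-pair design matrix: per predictor |I(x_i) - I(x_j)|; geography uses
# the I-spline of the pairwise distance itself.
.gdmDesign <- function(siteEnv, coords, includeGeography, knots = NULL) {
  k <- nrow(siteEnv)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  preds <- colnames(siteEnv)
  X <- NULL; kn <- list()
  for (pp in preds) {
    kp <- if (!is.null(knots)) knots[[pp]] else NULL
    B <- isplineBasis(siteEnv[, pp], kp)
    kn[[pp]] <- attr(B, "knots")
    D <- abs(B[pairs[, 1], , drop = FALSE] - B[pairs[, 2], , drop = FALSE])
    colnames(D) <- paste0(pp, "_", 1:3)
    X <- cbind(X, D)
  }
  if (includeGeography) {
    dmat <- as.matrix(dist(coords))
    dv <- dmat[cbind(pairs[, 1], pairs[, 2])]
    kp <- if (!is.null(knots)) knots[["geography"]] else NULL
    B <- isplineBasis(dv, kp)
    kn[["geography"]] <- attr(B, "knots")
    colnames(B) <- paste0("geography_", 1:3)
    X <- cbind(X, B)
  }
  list(X = X, pairs = pairs, knots = kn,
       predictors = c(preds, if (includeGeography) "geography"))
}

.gdmDeviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# IRLS with non-negative least squares on the link eta = -log(1 - mu).
# Converges on coefficient stability or on a stalled deviance (the NNLS
# active set can oscillate between near-identical solutions).
.gdmIrls <- function(y, X, maxIter = 500, tol = 1e-6) {
  A0 <- cbind(intercept = 1, X)
  beta <- rep(0, ncol(A0))
  beta[1] <- -log(1 - min(max(mean(y), 1e-3), 1 - 1e-3))
  devOf <- function(b) .gdmDeviance(y, 1 - exp(-pmax(as.vector(A0 %*% b), 0)))
  devOld <- devOf(beta)
  for (it in seq_len(maxIter)) {
    eta <- pmax(as.vector(A0 %*% beta), 0)
    mu <- pmin(pmax(1 - exp(-eta), 1e-6), 1 - 1e-6)
    w <- (1 - mu) / mu
    zw <- eta + (y - mu) / (1 - mu)
    sw <- sqrt(w)
    sol <- pracma::lsqnonneg(A0 * sw, zw * sw)$x
    # step-halving keeps the deviance monotone when the working-response
    # step overshoots (the NNLS active set can otherwise cycle)
    t <- 1
    cand <- sol
    dev <- devOf(cand)
    while (dev > devOld && t > 1e-4) {
      t <- t / 2
      cand <- beta + t * (sol - beta)
      dev <- devOf(cand)
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    if (delta < tol || abs(devOld - dev) < 1e-9 * (dev + 0.1)) break
    devOld <- dev
    if (it == maxIter)
      stop("GDM IRLS failed to converge; last step change ", signif(delta, 3))
  }
  eta <- pmax(as.vector(A0 %*% beta), 0)
  list(beta = beta, fitted = 1 - exp(-eta))
}

#' Fit a generalized dissimilarity model of allelic turnover
#'
#' Models pairwise rescaled FST as d = 1 - exp(-eta) with eta an intercept
#' plus non-negative I-spline expansions of predictor differences (and,
#' optionally, of the pairwise geographic distance), fitted by iteratively
#' reweighted non-negative least squares on the link scale.  Reports the
#' binomial-type null deviance, explained deviance and their percentage.
#'
#' @param dissimilarity symmetric pairwise dissimilarity matrix in [0,1]
#'   (e.g. the \code{rescaled} element of \code{\link{wcFstPerLocus}})
#' @param siteEnv sites x predictors matrix, rows aligned with the
#'   dissimilarity matrix
#' @param coords sites x 2 coordinates; required when
#'   \code{includeGeography}
#' @param includeGeography add straight-line distance as a predictor
#' @return a \linkS4class{GdmModel}
#' @export
fitGdm <- function(dissimilarity, siteEnv, coords = NULL,
                   includeGeography = FALSE) {
  D <- as.matrix(dissimilarity)
  siteEnv <- as.matrix(siteEnv)
  if (is.null(colnames(siteEnv)))
    colnames(siteEnv) <- paste0("env", seq_len(ncol(siteEnv)))
  if (nrow(D) != nrow(siteEnv)) stop("site mismatch")
  if (includeGeography && is.null(coords))
    stop("coords required when includeGeography")
  des <- .gdmDesign(siteEnv, coords, includeGeography)
  y <- D[cbind(des$pairs[, 1], des$pairs[, 2])]
  if (length(y) < 10) stop("need at least 10 population pairs")
  if (any(y < 0 | y > 1)) stop("dissimilarities must lie in [0,1]")
  y <- pmin(y, 1 - 1e-9)
  fullFit <- .gdmIrls(y, des$X)
  nullFit <- .gdmIrls(y, matrix(0, length(y), 0))
  devFull <- .gdmDeviance(y, fullFit$fitted)
  devNull <- .gdmDeviance(y, nullFit$fitted)
  dDev <- max(0, devNull - devFull)
  pct <- if (devNull > 0) 100 * dDev / devNull else 0
  coefs <- list()
  beta <- fullFit$beta[-1]
  nm <- colnames(des$X)
  for (pp in des$predictors)
    coefs[[pp]] <- unname(beta[grep(paste0("^", pp, "_"), nm)])
  new("GdmModel", intercept = unname(fullFit$beta[1]), coefs = coefs,
      knots = des$knots, predictors = des$predictors,
      nullDeviance = devNull, explainedDeviance = dDev,
      pctDeviance = min(pct, 100), observed = y, fitted = fullFit$fitted,
      siteEnv = siteEnv,
      coords = if (is.null(coords)) matrix(0, 0, 2) else as.matrix(coords),
      dissimilarity = D)
}

#' Partial allelic turnover of one predictor
#'
#' The total height of the fitted monotone function over the observed
#' gradient; since every I-spline spans 0 to 1 this is the sum of the
#' predictor's coefficients.
#'
#' @param model a \linkS4class{GdmModel}
#' @param predictor predictor name ("geography" for the distance term)
#' @return non-negative turnover height
#' @export
partialTurnover <- function(model, predictor) {
  if (!predictor %in% model@predictors) stop("unknown predictor: ", predictor)
  sum(model@coefs[[predictor]])
}

#' All partial turnovers of a model
#'
#' @param model a \linkS4class{GdmModel}
#' @return named numeric of turnover heights
#' @export
partialTurnovers <- function(model)
  vapply(model@predictors, function(p) partialTurnover(model, p), 0)

#' Reference-group dissimilarity model
#'
#' Draws \code{nRef} random SNPs, computes the multi-SNP pairwise FST over
#' that set as a single locus, and fits the same dissimilarity model; this
#' provides the null level of explained deviance and turnover for the
#' candidate classification.
#'
#' @param G a \linkS4class{GenotypeCalls}
#' @param siteEnv populations x predictors matrix (rownames = population
#'   labels)
#' @param coords populations x 2 coordinates (rownames = population labels)
#' @param nRef number of reference SNPs (default 200)
#' @param minN per-population minimum sample size (default 5)
#' @param includeGeography include the distance predictor (default TRUE)
#' @param seed integer seed
#' @return a \linkS4class{GdmModel}
#' @export
referenceGroupGdm <- function(G, siteEnv, coords = NULL, nRef = 200,
                              minN = 5, includeGeography = !is.null(coords),
                              seed = 1) {
  g <- genoCalls(G)
  if (nrow(g) < nRef) stop("fewer than ", nRef, " SNPs available")
  set.seed(seed)
  pick <- sort(sample.int(nrow(g), nRef))
  sub <- G[pick, ]
  SummarizedExperiment::rowData(sub)$locus <- "reference"
  f <- wcFstPerLocus(sub, loci = "reference", minN = minN)[["reference"]]
  if (is.null(f)) stop("reference group has too few eligible populations")
  se <- as.matrix(siteEnv)[f$pops, , drop = FALSE]
  co <- if (!is.null(coords)) as.matrix(coords)[f$pops, , drop = FALSE]
  fitGdm(f$rescaled, se, coords = co, includeGeography = includeGeography)
}

#' Three-criterion candidate classification
#'
#' C1: the locus explains more deviance than the reference group.  C2: its
#' largest environmental turnover exceeds both the reference group's
#' turnover for that predictor and the locus's own geography turnover (a
#' locus whose largest turnover belongs to geography is flagged a false
#' positive).  C3: refitting the model with the winning predictor alone
#' retains at least \code{threshold} of the full model's explained-deviance
#' percentage.  A locus is a candidate iff all three hold.
#'
#' @param locusModels named list of \linkS4class{GdmModel}s fitted with
#'   geography included
#' @param referenceModel the \code{\link{referenceGroupGdm}} fit
#' @param threshold share of %deviance the winning predictor must retain
#'   (default 0.40)
#' @return data.frame: one row per locus with %deviance, winning predictor,
#'   criterion flags and status (\code{candidate} / \code{false_positive} /
#'   \code{not_candidate})
#' @export
classifyCandidates <- function(locusModels, referenceModel,
                               threshold = 0.40) {
  refT <- partialTurnovers(referenceModel)
  refPct <- pctDeviance(referenceModel)
  rows <- lapply(names(locusModels), function(loc) {
    m <- locusModels[[loc]]
    if (!"geography" %in% m@predictors)
      stop("locus ", loc, " was fitted without geography")
    tv <- partialTurnovers(m)
    geoT <- tv[["geography"]]
    envT <- tv[setdiff(names(tv), "geography")]
    winner <- names(envT)[which.max(envT)]
    c1 <- pctDeviance(m) > refPct
    geoDominant <- geoT >= max(envT)
    c2 <- !geoDominant &&
      envT[[winner]] > (refT[winner] %||% 0) && envT[[winner]] > geoT
    singleFit <- fitGdm(m@dissimilarity,
                        m@siteEnv[, winner, drop = FALSE])
    share <- if (pctDeviance(m) > 0)
      pctDeviance(singleFit) / pctDeviance(m) else 0
    c3 <- share >= threshold
    status <- if (geoDominant) "false_positive"
    else if (c1 && c2 && c3) "candidate" else "not_candidate"
    data.frame(locus = loc, pctGDM = pctDeviance(m), refPctGDM = refPct,
               winner = winner, winnerTurnover = envT[[winner]],
               geographyTurnover = geoT, winnerShare = share,
               C1 = c1, C2 = c2, C3 = c3, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predicted allelic-turnover map for one predictor
#'
#' Every raster cell is mapped through the fitted monotone I-spline
#' transform of its predictor value: the predicted cumulative change in
#' rescaled FST from the gradient minimum.  Cells outside the fitted
#' gradient are clamped (count attached as attribute \code{clamped}).
#'
#' @param model a \linkS4class{GdmModel}
#' @param env an \linkS4class{EnvStack} containing \code{predictor}
#' @param predictor predictor name
#' @return matrix map with attribute \code{clamped}
#' @export
predictTurnoverMap <- function(model, env, predictor) {
  if (!predictor %in% model@predictors) stop("unknown predictor: ", predictor)
  vals <- getLayer(env, predictor)
  kn <- model@knots[[predictor]]
  clamped <- sum(vals < kn[1] | vals > kn[3], na.rm = TRUE)
  B <- isplineBasis(as.vector(vals), kn)
  m <- matrix(B %*% model@coefs[[predictor]], nrow(vals), ncol(vals))
  structure(m, clamped = clamped)
}

#' Observed versus predicted dissimilarities
#'
#' @param model a \linkS4class{GdmModel}
#' @return list with Pearson and Spearman correlations and residual
#'   quantiles
#' @export
observedVsPredicted <- function(model) {
  obs <- model@observed; fit <- model@fitted
  res <- obs - fit
  pear <- if (sd(fit) > 0 && sd(obs) > 0) cor(obs, fit) else NA_real_
  spear <- if (sd(fit) > 0 && sd(obs) > 0)
    cor(obs, fit, method = "spearman") else NA_real_
  list(pearson = pear, spearman = spear,
       residualQuantiles = quantile(res, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Observed alternative-allele frequencies per population at a locus
#'
#' @param G a \linkS4class{GenotypeCalls}
#' @param locus locus id
#' @return named numeric of mean alternative-allele frequency
#' @export
populationAlleleFreqs <- function(G, locus) {
  g <- genoCalls(G)[locusMap(G) == locus, , drop = FALSE]
  pop <- popLabels(G)
  vapply(sort(unique(pop)), function(pp) {
    sub <- g[, pop == pp, drop = FALSE]
    mean(colMeans(sub / 2, na.rm = TRUE), na.rm = TRUE)
  }, 0)
}
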