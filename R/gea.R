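#' Filter SNPs on missingness and minor allele count
#'
#' Removes SNPs with more than \code{maxMissing} missing calls or a minor
#' allele count below \code{mac} (the count rule is a floor: a SNP at
#' exactly \code{mac} is retained).
#'
#' @param G a \linkS4class{GenotypeCalls}
#' @param maxMissing maximum missing fraction per SNP (default 0.30)
#' @param mac minimum minor allele count (default 40)
#' @return the filtered \linkS4class{GenotypeCalls}, with a removal report
#'   in \code{metadata(.)$filterReport}
#' @export
filterGenotypes <- function(G, maxMissing = 0.30, mac = 40) {
  g <- genoCalls(G)
  miss <- rowMeans(is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(g))
  macObs <- pmin(alt, tot - alt)
  failMiss <- miss > maxMissing
  failMac <- macObs < mac
  keep <- !(failMiss | failMac)
  if (!any(keep)) stop("no SNP passes the filters")
  out <- G[keep, ]
  S4Vectors::metadata(out)$filterReport <- c(
    input = nrow(g), removedMissing = sum(failMiss),
    removedMac = sum(failMac & !failMiss), retained = sum(keep))
  out
}

#' Mean-impute missing genotype calls
#'
#' Missing calls are replaced by the per-SNP mean of the observed calls;
#' the missingness mask is kept as assay \code{"missing"}.
#'
#' @param G a filtered \linkS4class{GenotypeCalls}
#' @return numeric matrix (individuals x SNPs) of imputed dosages; the mask
#'   is attached as attribute \code{missingMask} (same orientation)
#' @export
imputeMissing <- function(G) {
  g <- genoCalls(G)
  if (any(rowSums(!is.na(g)) == 0)) stop("all-missing SNP present; filter first")
  mu <- rowMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %% nrow(g) + 1]
  out <- t(g)
  attr(out, "missingMask") <- t(is.na(genoCalls(G)))
  out
}

# K latent factors of the env-residualized genotype matrix, by alternating
# ridge least squares from a random start (repeat-to-repeat variation comes
# from the initialization).
.latentFactors <- function(R, K, nIter = 30, ridge = 1e-6) {
  n <- nrow(R)
  W <- matrix(rnorm(n * K), n, K)
  for (it in seq_len(nIter)) {
    H <- solve(crossprod(W) + diag(ridge, K), crossprod(W, R))
    W <- t(solve(tcrossprod(H) + diag(ridge, K), H %*% t(R)))
  }
  qr.Q(qr(W))
}

#' Latent-factor association scan of SNPs against one predictor
#'
#' For each repeat: the environmental variable is regressed out of the
#' (column-centred) genotype matrix, K latent factors are estimated from
#' the residual by alternating least squares from a random initialization,
#' and each SNP is regressed on the predictor plus the factors; the
#' returned statistic is the z-score of the environmental effect.
#'
#' @param G imputed genotype matrix, individuals x SNPs (from
#'   \code{\link{imputeMissing}})
#' @param envVariable numeric vector per individual (standardized
#'   internally)
#' @param K number of latent factors (default 3)
#' @param nRepeats repeats over random initializations (default 5)
#' @param seed integer seed
#' @return matrix of z-scores, SNPs x repeats
#' @export
lfmmFit <- function(G, envVariable, K = 3, nRepeats = 5, seed = 1) {
  G <- as.matrix(G)
  n <- nrow(G); p <- ncol(G)
  if (K >= min(n, p)) stop("K must be smaller than both dimensions")
  x <- as.numeric(scale(envVariable))
  Gc <- scale(G, scale = FALSE)
  set.seed(seed)
  Z <- matrix(NA_real_, p, nRepeats,
              dimnames = list(colnames(G), NULL))
  for (r in seq_len(nRepeats)) {
    bx <- crossprod(x, Gc) / sum(x^2)
    Rm <- Gc - x %*% bx
    U <- .latentFactors(Rm, K)
    D <- cbind(1, x, U)
    DtDinv <- solve(crossprod(D))
    B <- DtDinv %*% crossprod(D, G)
    resid <- G - D %*% B
    df <- n - ncol(D)
    s2 <- colSums(resid^2) / df
    se <- sqrt(s2 * DtDinv[2, 2])
    Z[, r] <- ifelse(se > 0, B[2, ] / se, 0)
  }
  Z
}

#' Combine repeat z-scores and calibrate with a genomic inflation factor
#'
#' The per-SNP statistic is the median z across repeats; the inflation
#' factor is lambda = median(z^2) / 0.456 (0.456 being the median of a
#' 1-df chi-square), and adjusted p-values come from z^2 / lambda against
#' chi-square(1).
#'
#' @param Z z-score matrix, SNPs x repeats
#' @return list with \code{z} (combined), \code{lambda}, \code{p}
#'   (GIF-adjusted), and \code{pRaw}
#' @export
combineZGif <- function(Z) {
  Z <- as.matrix(Z)
  z <- apply(Z, 1, median)
  bad <- !is.finite(z)
  lambda <- median(z[!bad]^2) / qchisq(0.5, 1)
  p <- pchisq(z^2 / lambda, df = 1, lower.tail = FALSE)
  pRaw <- pchisq(z^2, df = 1, lower.tail = FALSE)
  p[bad] <- NA; pRaw[bad] <- NA
  list(z = z, lambda = lambda, p = p, pRaw = pRaw)
}

#' Ancestry-conditioned partial redundancy analysis of genotypes
#'
#' Wraps \code{vegan::rda(G, env, condition)}: the genotype matrix is
#' residualized on the conditioning ancestry coefficients (one column
#' dropped to avoid the sum-to-one singularity), then regressed on the
#' residualized predictors; returns the per-SNP loadings on the constrained
#' axes.
#'
#' @param G imputed genotype matrix, individuals x SNPs (centred internally
#'   by the ordination; not scaled)
#' @param envMatrix individuals x predictors matrix
#' @param Q individuals x K ancestry coefficients used as the condition
#' @return list with \code{loadings} (SNPs x constrained axes), \code{eig}
#'   (constrained eigenvalues), \code{propConstrained}, and the vegan
#'   \code{model}
#' @export
partialRdaGenotypes <- function(G, envMatrix, Q = NULL) {
  envMatrix <- as.matrix(envMatrix)
  if (qr(scale(envMatrix))$rank < ncol(envMatrix)) {
    stop("environmental matrix is rank-deficient")
  }
  cond <- NULL
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    cond <- Q[, -ncol(Q), drop = FALSE]      # drop one ancestry column
  }
  m <- if (is.null(cond)) vegan::rda(X = G, Y = envMatrix)
  else vegan::rda(X = G, Y = envMatrix, Z = cond)
  V <- m$CCA$v
  list(loadings = V, eig = m$CCA$eig,
       propConstrained = sum(m$CCA$eig) / m$tot.chi, model = m)
}

#' Outlier p-values from constrained-axis loadings
#'
#' Per-SNP robust Mahalanobis distance of the loading vector (axes
#' standardized by median and MAD), calibrated by a genomic inflation
#' factor against chi-square with \code{nAxes} degrees of freedom, with
#' Storey q-values attached.
#'
#' @param loadings SNPs x axes loading matrix
#' @param nAxes number of leading constrained axes to use
#' @return list with \code{stat}, \code{lambda}, \code{p}, \code{q}
#' @export
rdaOutlierPvalues <- function(loadings, nAxes = ncol(loadings)) {
  loadings <- as.matrix(loadings)
  if (nAxes > ncol(loadings)) stop("nAxes exceeds available axes")
  L <- loadings[, seq_len(nAxes), drop = FALSE]
  if (any(!is.finite(L))) stop("non-finite loadings")
  Ls <- scale(L, center = apply(L, 2, median), scale = apply(L, 2, mad))
  d2 <- rowSums(Ls^2)
  lambda <- median(d2) / qchisq(0.5, nAxes)
  p <- pchisq(d2 / lambda, df = nAxes, lower.tail = FALSE)
  list(stat = d2, lambda = lambda, p = p, q = storeyQvalues(p))
}

#' Storey q-values with smoother pi0 estimation
#'
#' The proportion of true nulls pi0 is estimated by fitting a cubic
#' smoothing spline to pi0(lambda) = mean(p > lambda) / (1 - lambda) over a
#' lambda grid and evaluating it at the largest lambda; q-values are the
#' usual monotone step-down transform of pi0 * p * m / rank.
#'
#' @param p p-values in (0, 1]
#' @return q-values, same order as \code{p}
#' @export
storeyQvalues <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0,1]")
  m <- length(p)
  lam <- seq(0.05, 0.9, 0.05)
  pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- if (m >= 100) {
    fit <- smooth.spline(lam, pi0l, df = 3)
    min(1, max(predict(fit, x = max(lam))$y, 0))
  } else min(1, max(pi0l[length(pi0l)], 0))
  if (pi0 <= 0) pi0 <- 1 / m
  o <- order(p, decreasing = TRUE)
  q <- pi0 * p[o] * m / rank(p, ties.method = "max")[o]
  q <- cummin(q)[order(o)]
  pmin(q, 1)
}

#' Intersect outliers across the two association methods
#'
#' A SNP is an outlier when its q-value is below the threshold in both the
#' latent-factor scan (any variable) and the loading-based scan; outlier
#' SNPs are grouped into parent RAD loci, and the per-locus counts of each
#' method's hits are reported (one-method hits included for reference).
#'
#' @param lfmmQ SNPs x variables matrix of latent-factor q-values
#' @param rdaQ per-SNP q-values from \code{\link{rdaOutlierPvalues}}
#' @param locus RAD-locus id per SNP
#' @param qThreshold q-value cutoff (default 0.05)
#' @return list with \code{snps} (per-SNP logical hits and q minima) and
#'   \code{loci} (per-locus counts: lfmm, rda, common)
#' @export
intersectOutliers <- function(lfmmQ, rdaQ, locus, qThreshold = 0.05) {
  lfmmQ <- as.matrix(lfmmQ)
  qMin <- apply(lfmmQ, 1, min)
  hitL <- qMin < qThreshold
  hitR <- rdaQ < qThreshold
  common <- hitL & hitR
  snps <- data.frame(snp = rownames(lfmmQ) %||% seq_along(rdaQ),
                     locus = locus, lfmmQ = qMin, rdaQ = rdaQ,
                     lfmmHit = hitL, rdaHit = hitR, common = common)
  loci <- aggregate(cbind(lfmm = hitL, rda = hitR, common = common) ~ locus,
                    data = snps, FUN = sum)
  loci <- loci[loci$lfmm + loci$rda > 0, , drop = FALSE]
  rownames(loci) <- NULL
  list(snps = snps, loci = loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full dual-method association scan
#'
#' Convenience wrapper running the latent-factor scan per variable, the
#' conditioned loading scan across all variables, GIF calibration,
#' q-values, and the intersection.
#'
#' @param G a filtered \linkS4class{GenotypeCalls}
#' @param envMatrix populations-or-individuals x variables matrix; when it
#'   has one row per population it is expanded by population label
#' @param K latent factors / ancestry components (default 3)
#' @param nRepeats latent-factor repeats (default 5)
#' @param qThreshold intersection cutoff (default 0.05)
#' @param seed integer seed
#' @return list with \code{lfmm} (per variable: z, lambda, p, q),
#'   \code{rda}, \code{outliers}, \code{lambdas}
#' @export
geaScan <- function(G, envMatrix, K = 3, nRepeats = 5, qThreshold = 0.05,
                    seed = 1) {
  X <- imputeMissing(G)
  envMatrix <- as.matrix(envMatrix)
  if (nrow(envMatrix) != nrow(X)) {
    pops <- sort(unique(popLabels(G)))
    if (nrow(envMatrix) != length(pops))
      stop("envMatrix rows match neither individuals nor populations")
    rownames(envMatrix) <- pops
    envMatrix <- envMatrix[popLabels(G), , drop = FALSE]
  }
  vars <- colnames(envMatrix) %||% paste0("env", seq_len(ncol(envMatrix)))
  colnames(envMatrix) <- vars
  lf <- list(); lambdas <- numeric(0)
  qMat <- matrix(NA_real_, ncol(X), length(vars),
                 dimnames = list(colnames(X), vars))
  for (i in seq_along(vars)) {
    Z <- lfmmFit(X, envMatrix[, i], K = K, nRepeats = nRepeats,
                 seed = seed + i)
    cg <- combineZGif(Z)
    cg$q <- storeyQvalues(cg$p)
    qMat[, i] <- cg$q
    lf[[vars[i]]] <- cg
    lambdas[vars[i]] <- cg$lambda
  }
  pr <- partialRdaGenotypes(X, envMatrix, Q = ancestryQ(G))
  ro <- rdaOutlierPvalues(pr$loadings, nAxes = min(ncol(pr$loadings), K))
  out <- intersectOutliers(qMat, ro$q, locusMap(G), qThreshold)
  list(lfmm = lf, lfmmQ = qMat, rda = c(pr["propConstrained"], ro),
       outliers = out, lambdas = lambdas)
}
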