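#' Greedy selection of mutually uncorrelated variables
#'
#' Variables are scanned in input order; one is retained iff its absolute
#' Pearson correlation with every already-retained variable is below the
#' threshold.  Constant variables (undefined correlation) are excluded with
#' a warning.
#'
#' @param values occurrences x variables data.frame or matrix
#' @param threshold absolute-correlation cutoff (default 0.50)
#' @return character vector of retained variable names
#' @export
selectUncorrelatedVariables <- function(values, threshold = 0.50) {
  values <- as.data.frame(values)
  if (ncol(values) < 2) stop("need at least two variables")
  kept <- character(0)
  for (nm in names(values)) {
    v <- values[[nm]]
    if (sd(v, na.rm = TRUE) == 0 || !is.finite(sd(v, na.rm = TRUE))) {
      warning("variable '", nm, "' is constant; excluded")
      next
    }
    ok <- all(vapply(kept, function(k)
      abs(cor(v, values[[k]], use = "complete.obs")) < threshold, TRUE))
    if (ok) kept <- c(kept, nm)
  }
  kept
}

#' Build the two-axis environmental ordination space
#'
#' Principal component analysis of the standardized occurrence-level
#' environmental values; background cells are projected into the same space
#' with the occurrence centering and scaling.
#'
#' @param occValues occurrences x variables matrix/data.frame (all regions
#'   pooled)
#' @param backgroundValues background cells x variables
#' @return an \linkS4class{EnvSpace}
#' @export
buildEnvSpace <- function(occValues, backgroundValues) {
  X <- as.matrix(occValues)
  if (nrow(X) < 3) stop("need at least three occurrences")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) stop("constant variable; filter first")
  Xs <- scale(X, center = ctr, scale = scl)
  p <- prcomp(Xs, center = FALSE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  bg <- scale(as.matrix(backgroundValues)[, colnames(X), drop = FALSE],
              center = ctr, scale = scl) %*% p$rotation[, 1:2]
  new("EnvSpace",
      axisScores = p$x[, 1:2, drop = FALSE],
      loadings = p$rotation[, 1:2, drop = FALSE],
      varianceExplained = ve,
      backgroundScores = bg, center = ctr, scaleSd = scl)
}

# shared kde grid: Gaussian kernel density on an R x R grid over `extent`
.kdeGrid <- function(scores, R, extent, bandwidth = NULL) {
  x <- scores[, 1]; y <- scores[, 2]
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
    if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
      stop("bandwidth rule failed (too few points?); supply one")
  }
  bandwidth <- rep(bandwidth, length.out = 2)
  k <- MASS::kde2d(x, y, h = bandwidth, n = R,
                   lims = extent)
  k$z
}

#' Occurrence-density grid on the ordination space
#'
#' Occurrence scores and background scores are kernel-smoothed onto a
#' shared R x R grid; the corrected occupancy z is the occurrence density
#' divided by the background prevalence, set to zero where the background
#' is absent and normalized to sum to one.
#'
#' @param scores occurrence scores (n x 2) on the first two axes
#' @param backgroundScores background cell scores (m x 2)
#' @param R grid resolution per axis (>= 10; default 100)
#' @param bandwidth numeric(2) kernel bandwidth per axis, or NULL for the
#'   normal-reference rule
#' @param correction "background" (z = o/e, the prevalence-corrected
#'   occupancy) or "none" (z = o)
#' @param extent optional numeric(4) xmin,xmax,ymin,ymax; defaults to the
#'   padded background range
#' @return a \linkS4class{NicheGrid}
#' @export
occurrenceDensityGrid <- function(scores, backgroundScores, R = 100,
                                  bandwidth = NULL,
                                  correction = c("background", "none"),
                                  extent = NULL) {
  correction <- match.arg(correction)
  scores <- as.matrix(scores); backgroundScores <- as.matrix(backgroundScores)
  if (R < 10) stop("R must be at least 10")
  if (nrow(scores) == 0) stop("zero occurrences")
  if (is.null(extent)) {
    rx <- range(backgroundScores[, 1]); ry <- range(backgroundScores[, 2])
    px <- 0.1 * diff(rx); py <- 0.1 * diff(ry)
    extent <- c(rx[1] - px, rx[2] + px, ry[1] - py, ry[2] + py)
  }
  o <- .kdeGrid(scores, R, extent, bandwidth)
  e <- .kdeGrid(backgroundScores, R, extent, bandwidth)
  o[o < 0] <- 0; e[e < 0] <- 0
  e[e < max(e) * 1e-10] <- 0          # numerically absent background
  if (correction == "background") {
    z <- matrix(0, R, R)
    z[e > 0] <- o[e > 0] / e[e > 0]
  } else z <- o
  s <- sum(z)
  if (s <= 0) stop("no occupancy mass on the grid")
  new("NicheGrid", R = as.integer(R), o = o, e = e, z = z / s,
      extent = as.numeric(extent))
}

#' Schoener's D niche overlap
#'
#' D = 1 - 0.5 * sum |z1 - z2| over grid cells, after normalizing both
#' occupancy surfaces to sum to one.  Accepts two \linkS4class{NicheGrid}s
#' on the same grid, or two plain matrices/vectors of equal shape.
#'
#' @param z1,z2 niche grids or numeric arrays of occupancy
#' @return overlap in [0, 1] (0 = disjoint, 1 = identical)
#' @export
schoenerD <- function(z1, z2) {
  if (is(z1, "NicheGrid") && is(z2, "NicheGrid")) {
    if (z1@R != z2@R || max(abs(z1@extent - z2@extent)) > 1e-9)
      stop("niche grids are on different grids")
    a <- z1@z; b <- z2@z
  } else {
    a <- as.array(z1); b <- as.array(z2)
    if (!all(dim(a) == dim(b))) stop("occupancy arrays differ in shape")
  }
  if (sum(a) <= 0 || sum(b) <= 0) stop("empty occupancy surface")
  a <- a / sum(a); b <- b / sum(b)
  max(0, 1 - 0.5 * sum(abs(a - b)))
}

# density grid for one occurrence set against a fixed background density
.occGridFixedBg <- function(scores, e, R, extent, bandwidth) {
  o <- .kdeGrid(scores, R, extent, bandwidth)
  o[o < 0] <- 0
  z <- matrix(0, R, R)
  z[e > 0] <- o[e > 0] / e[e > 0]
  s <- sum(z)
  if (s <= 0) return(matrix(0, R, R))
  z / s
}

#' Niche equivalency test
#'
#' Pools the two occurrence sets and reassigns labels at random (preserving
#' sample sizes), recomputing Schoener's D each time.  The one-sided
#' alternative asks whether the observed overlap is lower than expected for
#' equivalent niches: p = (1 + #\{null D <= observed D\}) / (nPerm + 1),
#' small when the niches are less overlapping than exchangeable samples.
#'
#' @param occ1,occ2 occurrence score matrices (n x 2) in a shared ordination
#'   space
#' @param background1,background2 background score matrices for each range
#' @param R grid resolution
#' @param nPerm number of permutations (default 1000)
#' @param bandwidth optional fixed kernel bandwidth (numeric(2)); by default
#'   the normal-reference rule on the pooled occurrences, held fixed across
#'   permutations
#' @param seed integer seed
#' @return an \linkS4class{OverlapTest}
#' @export
equivalencyTest <- function(occ1, occ2, background1, background2, R = 100,
                            nPerm = 1000, bandwidth = NULL, seed = 1) {
  occ1 <- as.matrix(occ1); occ2 <- as.matrix(occ2)
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (!nrow(occ1) || !nrow(occ2)) stop("empty occurrence set")
  allbg <- rbind(as.matrix(background1), as.matrix(background2))
  rx <- range(allbg[, 1]); ry <- range(allbg[, 2])
  extent <- c(rx[1] - 0.1 * diff(rx), rx[2] + 0.1 * diff(rx),
              ry[1] - 0.1 * diff(ry), ry[2] + 0.1 * diff(ry))
  pool <- rbind(occ1, occ2)
  if (is.null(bandwidth))
    bandwidth <- c(MASS::bandwidth.nrd(pool[, 1]),
                   MASS::bandwidth.nrd(pool[, 2]))
  e1 <- .kdeGrid(as.matrix(background1), R, extent, bandwidth)
  e2 <- .kdeGrid(as.matrix(background2), R, extent, bandwidth)
  e1[e1 < max(e1) * 1e-10] <- 0; e2[e2 < max(e2) * 1e-10] <- 0
  dOf <- function(a, b) {
    z1 <- .occGridFixedBg(a, e1, R, extent, bandwidth)
    z2 <- .occGridFixedBg(b, e2, R, extent, bandwidth)
    schoenerD(z1, z2)
  }
  obs <- dOf(occ1, occ2)
  n1 <- nrow(occ1)
  set.seed(seed)
  nullD <- vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(nrow(pool), n1)
    dOf(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
  }, 0)
  p <- (1 + sum(nullD <= obs)) / (nPerm + 1)
  new("OverlapTest", observedD = obs, nullD = nullD, pValue = p,
      nPerm = as.integer(nPerm), kind = "equivalency",
      alternative = "observed overlap lower than under label exchange")
}

#' Niche similarity test
#'
#' The reference niche is held fixed; the shifted (invasive) niche is
#' relocated by random translation of its occurrence centroid within its
#' own background, densities recomputed, and D compared with the observed
#' value.  The one-sided alternative asks whether the two niches are more
#' similar than random placement: p = (1 + #\{null D >= observed D\}) /
#' (nPerm + 1).
#'
#' @param occRef reference occurrence scores (n x 2)
#' @param occShifted occurrence scores of the niche being randomized
#' @param backgroundShifted background scores of the shifted niche's range
#' @param backgroundRef optional background for the reference niche
#'   (defaults to \code{backgroundShifted})
#' @param R grid resolution
#' @param nPerm permutations
#' @param bandwidth optional fixed bandwidth
#' @param maxTry resampling cap for translations that push occurrences
#'   outside the background extent
#' @param seed integer seed
#' @return an \linkS4class{OverlapTest}
#' @export
similarityTest <- function(occRef, occShifted, backgroundShifted,
                           backgroundRef = backgroundShifted, R = 100,
                           nPerm = 1000, bandwidth = NULL, maxTry = 100,
                           seed = 1) {
  occRef <- as.matrix(occRef); occShifted <- as.matrix(occShifted)
  bg <- as.matrix(backgroundShifted)
  if (nPerm < 1) stop("nPerm must be >= 1")
  allbg <- rbind(bg, as.matrix(backgroundRef))
  rx <- range(allbg[, 1]); ry <- range(allbg[, 2])
  extent <- c(rx[1] - 0.1 * diff(rx), rx[2] + 0.1 * diff(rx),
              ry[1] - 0.1 * diff(ry), ry[2] + 0.1 * diff(ry))
  # each niche is smoothed with its own bandwidth; the shifted niche's rule
  # is translation-invariant, keeping the null exchangeable with the
  # observed placement
  if (is.null(bandwidth)) {
    bwRef <- c(MASS::bandwidth.nrd(occRef[, 1]),
               MASS::bandwidth.nrd(occRef[, 2]))
    bwShift <- c(MASS::bandwidth.nrd(occShifted[, 1]),
                 MASS::bandwidth.nrd(occShifted[, 2]))
  } else bwRef <- bwShift <- rep(bandwidth, length.out = 2)
  eS <- .kdeGrid(bg, R, extent, bwShift)
  eR <- .kdeGrid(as.matrix(backgroundRef), R, extent, bwRef)
  eS[eS < max(eS) * 1e-10] <- 0; eR[eR < max(eR) * 1e-10] <- 0
  zRef <- .occGridFixedBg(occRef, eR, R, extent, bwRef)
  zObs <- .occGridFixedBg(occShifted, eS, R, extent, bwShift)
  obs <- schoenerD(zRef, zObs)
  # translate the occurrence centroid anywhere its whole cloud still fits
  # inside the shifted range's background bounding box; a shift that would
  # push density outside the background is never drawn
  ctr <- colMeans(occShifted)
  bxr <- range(bg[, 1]); byr <- range(bg[, 2])
  lo <- c(bxr[1] + (ctr[1] - min(occShifted[, 1])),
          byr[1] + (ctr[2] - min(occShifted[, 2])))
  hi <- c(bxr[2] - (max(occShifted[, 1]) - ctr[1]),
          byr[2] - (max(occShifted[, 2]) - ctr[2]))
  if (any(hi < lo)) stop("background too small for any shift")
  set.seed(seed)
  nullD <- vapply(seq_len(nPerm), function(i) {
    for (t in seq_len(maxTry)) {
      target <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      moved <- sweep(occShifted, 2, target - ctr, "+")
      z <- .occGridFixedBg(moved, eS, R, extent, bwShift)
      if (sum(z) > 0) return(schoenerD(zRef, z))
    }
    stop("no valid shift produced occupancy mass")
  }, 0)
  p <- (1 + sum(nullD >= obs)) / (nPerm + 1)
  new("OverlapTest", observedD = obs, nullD = nullD, pValue = p,
      nPerm = as.integer(nPerm), kind = "similarity",
      alternative = "observed overlap higher than random placement")
}

#' Niche centroid displacement
#'
#' Difference between the mean ordination-space positions of two occurrence
#' sets; reported descriptively (no test is attached).
#'
#' @param occ1,occ2 occurrence score matrices
#' @return numeric(2) displacement vector (centroid2 - centroid1)
#' @export
nicheCentroidShift <- function(occ1, occ2)
  colMeans(as.matrix(occ2)) - colMeans(as.matrix(occ1))
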