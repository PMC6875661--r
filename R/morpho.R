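#' Read landmark configurations from a TPS file
#'
#' Parses "LM=" records of two-dimensional landmark coordinates with "ID="
#' labels; every record must carry \code{expectLm} landmarks (malformed
#' records are rejected with their line number).
#'
#' @param path TPS file path
#' @param expectLm required landmark count per record (default 20)
#' @return a \linkS4class{LandmarkSet} (factor \code{id} from ID records)
#' @export
readTps <- function(path, expectLm = 20) {
  lines <- readLines(path)
  starts <- grep("^LM=", lines)
  if (!length(starts)) stop("no LM= records in ", path)
  configs <- list(); ids <- character(0)
  for (s in starts) {
    k <- as.integer(sub("^LM=", "", lines[s]))
    if (is.na(k) || k != expectLm)
      stop("record at line ", s, " declares LM=", lines[s],
           "; expected ", expectLm, " landmarks")
    block <- lines[(s + 1):(s + k)]
    xy <- do.call(rbind, lapply(seq_along(block), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(block[i]), "\\s+")[[1]]))
      if (length(v) != 2 || anyNA(v))
        stop("malformed coordinate at line ", s + i)
      v
    }))
    idLine <- lines[s + k + 1]
    id <- if (length(idLine) && grepl("^ID=", idLine))
      sub("^ID=", "", idLine) else as.character(length(configs) + 1)
    configs[[length(configs) + 1]] <- xy
    ids <- c(ids, id)
  }
  arr <- array(0, c(length(configs), expectLm, 2))
  for (i in seq_along(configs)) arr[i, , ] <- configs[[i]]
  new("LandmarkSet", coords = arr,
      factors = data.frame(id = ids, stringsAsFactors = FALSE))
}

#' Write a LandmarkSet to TPS format
#'
#' @param landmarks a \linkS4class{LandmarkSet}
#' @param path output path
#' @export
writeTps <- function(landmarks, path) {
  arr <- landmarks@coords
  ids <- if ("id" %in% names(landmarks@factors)) landmarks@factors$id
  else as.character(seq_len(dim(arr)[1]))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(arr)[1])) {
    writeLines(paste0("LM=", dim(arr)[2]), con)
    writeLines(apply(format(arr[i, , ], digits = 12, trim = TRUE), 1, paste,
                     collapse = " "), con)
    writeLines(paste0("ID=", ids[i]), con)
  }
  invisible(path)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; invariant to translation and rotation, homogeneous of degree
#' one in scale.
#'
#' @param config landmarks x 2 coordinate matrix
#' @return centroid size
#' @export
centroidSize <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3) stop("need at least three landmarks")
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

# optimal rotation of A onto B without reflection (determinant +1)
.rotateOnto <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment
#'
#' Centres every configuration, scales it to unit centroid size, and
#' iteratively rotates all configurations onto their consensus (mean shape)
#' by least squares until the consensus stabilizes (change below
#' \code{tol}).  Rotations are proper (determinant +1): reflections are not
#' allowed, since all configurations come from the same side (left wings).
#'
#' @param landmarks a \linkS4class{LandmarkSet}
#' @param tol consensus convergence tolerance (default 1e-10)
#' @param maxIter iteration cap
#' @return a \linkS4class{ShapeSet}
#' @export
gpa <- function(landmarks, tol = 1e-10, maxIter = 100) {
  arr <- landmarks@coords
  n <- dim(arr)[1]; k <- dim(arr)[2]
  if (n < 2) stop("need at least two configurations")
  cs <- numeric(n)
  aligned <- array(0, dim(arr))
  for (i in seq_len(n)) {
    cfg <- scale(arr[i, , ], scale = FALSE)
    cs[i] <- sqrt(sum(cfg^2))
    if (cs[i] == 0) stop("degenerate configuration ", i)
    aligned[i, , ] <- cfg / cs[i]
  }
  consensus <- aligned[1, , ]
  for (it in seq_len(maxIter)) {
    for (i in seq_len(n))
      aligned[i, , ] <- aligned[i, , ] %*% .rotateOnto(aligned[i, , ],
                                                       consensus)
    newCons <- apply(aligned, c(2, 3), mean)
    newCons <- newCons - matrix(colMeans(newCons), k, 2, byrow = TRUE)
    newCons <- newCons / sqrt(sum(newCons^2))
    if (max(abs(newCons - consensus)) < tol) { consensus <- newCons; break }
    consensus <- newCons
  }
  new("ShapeSet", aligned = aligned, centroidSizes = cs,
      consensus = unclass(consensus), factors = landmarks@factors)
}

#' Principal components of aligned shape
#'
#' Decomposition of the flattened Procrustes coordinates.
#'
#' @param shapes a \linkS4class{ShapeSet}
#' @return list with \code{scores}, \code{varianceFractions} and the
#'   \code{prcomp} object
#' @export
shapePca <- function(shapes) {
  arr <- alignedCoords(shapes)
  n <- dim(arr)[1]
  if (n < 3) stop("need at least three shapes")
  flat <- matrix(arr, n)
  p <- prcomp(flat, center = TRUE, scale. = FALSE)
  list(scores = p$x, varianceFractions = p$sdev^2 / sum(p$sdev^2), pca = p)
}

#' Type II MANOVA of shape on a grouping factor
#'
#' Multivariate test on the Procrustes coordinates with type II sums of
#' squares, reporting Pillai's trace and its F approximation.  Because the
#' aligned coordinates have only 2k - 4 free dimensions (and groups may be
#' small), the test is run on the leading principal components capturing
#' \code{pcVariance} of the variance; the dimension used is reported.
#'
#' @param shapes a \linkS4class{ShapeSet}
#' @param groups factor per individual
#' @param pcVariance variance fraction retained (default 0.95)
#' @return list with \code{pillai}, \code{F}, \code{df}, \code{p},
#'   \code{dimensionUsed}
#' @export
shapeManova <- function(shapes, groups, pcVariance = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 shapes")
  pc <- shapePca(shapes)
  cum <- cumsum(pc$varianceFractions)
  d <- which(cum >= pcVariance)[1]
  d <- min(d, length(groups) - nlevels(groups) - 1)
  if (d < 1) stop("not enough observations for any dimension; reduce groups")
  Y <- pc$scores[, seq_len(d), drop = FALSE]
  fit <- lm(Y ~ groups)
  av <- car::Anova(fit, type = "II", test.statistic = "Pillai")
  st <- .extractPillai(av)
  list(pillai = st["stat"], F = st["F"], df = unname(st[c("df1", "df2")]),
       p = st["p"], dimensionUsed = d)
}

.extractPillai <- function(av) {
  SSPE <- av$SSPE
  SSPH <- av$SSP[["groups"]]
  dfh <- av$df[["groups"]]
  dfe <- av$error.df
  ev <- Re(eigen(SSPH %*% solve(SSPE), only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  pil <- sum(ev / (1 + ev))
  p <- ncol(SSPE); q <- dfh
  ss <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (dfe - p - 1) / 2
  Fst <- ((2 * nn + ss + 1) / (2 * m + ss + 1)) * (pil / (ss - pil))
  df1 <- ss * (2 * m + ss + 1)
  df2 <- ss * (2 * nn + ss + 1)
  c(stat = pil, F = Fst, df1 = df1, df2 = df2,
    p = pf(Fst, df1, df2, lower.tail = FALSE))
}

#' Type II ANOVA of log centroid size
#'
#' @param logCs log-transformed centroid sizes
#' @param groups factor per individual
#' @param pairwise also run pairwise comparisons on groups with at least
#'   \code{minPerGroup} individuals
#' @param minPerGroup pairwise eligibility floor (default 5)
#' @return list with \code{F}, \code{df}, \code{p}, \code{anova}, and
#'   optionally \code{pairwise} (pairwise t-test p-value matrix)
#' @export
sizeAnova <- function(logCs, groups, pairwise = FALSE, minPerGroup = 5) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  fit <- lm(logCs ~ groups)
  av <- car::Anova(fit, type = "II")
  out <- list(F = av$`F value`[1], df = c(av$Df[1], av$Df[2]),
              p = av$`Pr(>F)`[1], anova = av)
  if (pairwise) {
    big <- names(which(table(groups) >= minPerGroup))
    keep <- groups %in% big
    out$pairwise <- stats::pairwise.t.test(
      logCs[keep], droplevels(groups[keep]), p.adjust.method = "holm")$p.value
  }
  out
}

#' Environment-conditioned redundancy analysis of morphometric traits
#'
#' Partial RDA of shape (Procrustes coordinates) or size on per-population
#' environmental values, conditioned on population-averaged ancestry
#' coefficients; significance by permutation of residuals under the
#' reduced model.  One-factor models per variable give the per-variable
#' constrained fractions.
#'
#' @param response individuals x traits matrix (flattened aligned shapes or
#'   a one-column log-size matrix)
#' @param populations population label per individual
#' @param popEnv populations x variables matrix (rownames = labels)
#' @param popQ populations x K ancestry coefficients (rownames = labels);
#'   one column is dropped internally
#' @param nPerm permutations (default 999)
#' @param seed integer seed
#' @return list with \code{constrainedFraction}, \code{p}, \code{F},
#'   \code{perVariable} (one-factor fractions and p-values), \code{model}
#' @export
morphoRda <- function(response, populations, popEnv, popQ = NULL,
                      nPerm = 999, seed = 1) {
  response <- as.matrix(response)
  popEnv <- as.matrix(popEnv)
  missing <- setdiff(unique(populations), rownames(popEnv))
  if (length(missing))
    stop("populations without environmental values: ",
         paste(missing, collapse = ", "))
  E <- popEnv[populations, , drop = FALSE]
  Z <- NULL
  if (!is.null(popQ)) {
    popQ <- as.matrix(popQ)
    missing <- setdiff(unique(populations), rownames(popQ))
    if (length(missing))
      stop("populations without ancestry coefficients: ",
           paste(missing, collapse = ", "))
    Z <- popQ[populations, -ncol(popQ), drop = FALSE]
  }
  runOne <- function(X) {
    m <- if (is.null(Z)) vegan::rda(X = response, Y = X)
    else vegan::rda(X = response, Y = X, Z = Z)
    set.seed(seed)
    an <- vegan::anova.cca(m, permutations = nPerm)
    list(fraction = sum(m$CCA$eig) / m$tot.chi,
         F = an$F[1], p = an$`Pr(>F)`[1], model = m)
  }
  glob <- runOne(E)
  per <- lapply(colnames(popEnv), function(v)
    runOne(E[, v, drop = FALSE])[c("fraction", "F", "p")])
  names(per) <- colnames(popEnv)
  list(constrainedFraction = glob$fraction, F = glob$F, p = glob$p,
       perVariable = per, model = glob$model)
}
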