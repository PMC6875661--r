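#' @import methods
#' @importFrom stats median quantile sd cor var rnorm runif rbinom rbeta
#'   prcomp pchisq qchisq pnorm lm anova plogis qlogis complete.cases
#'   smooth.spline predict mad aggregate dist ks.test pf
NULL

#' EnvStack: named environmental raster layers on a shared grid
#'
#' A minimal in-memory raster stack: a rows x cols x layers numeric array
#' with layer names.  Grid cells are indexed by (row, col); the x coordinate
#' of a cell is its column index and the y coordinate its row index, which
#' is sufficient for the synthetic landscapes this package analyses.
#'
#' @slot layers numeric array, rows x cols x n_layers, with dimnames on the
#'   third margin giving layer names.
#' @export
setClass("EnvStack", representation(layers = "array"))

setValidity("EnvStack", function(object) {
  d <- dim(object@layers)
  if (length(d) != 3) return("layers must be a rows x cols x n_layers array")
  if (is.null(dimnames(object@layers)[[3]])) return("layers must be named")
  if (d[1] < 1 || d[2] < 1) return("empty grid")
  TRUE
})

#' @describeIn EnvStack number of layers
#' @param x,object an EnvStack
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @export
setMethod("nLayers", "EnvStack", function(x) dim(x@layers)[3])

#' @describeIn EnvStack layer names
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @export
setMethod("layerNames", "EnvStack", function(x) dimnames(x@layers)[[3]])

#' @describeIn EnvStack extract one layer as a matrix
#' @param name layer name
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @export
setMethod("getLayer", "EnvStack", function(x, name) x@layers[, , name])

#' @describeIn EnvStack grid dimension (rows, cols)
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @export
setMethod("gridDim", "EnvStack", function(x) dim(x@layers)[1:2])

setMethod("show", "EnvStack", function(object) {
  d <- dim(object@layers)
  cat("EnvStack:", d[3], "layers on a", d[1], "x", d[2], "grid\n")
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
})

#' Per-cell values of all layers as a data.frame
#'
#' One row per grid cell with its (row, col) index and the value of every
#' layer; the tabular view used by the distribution-modelling functions.
#'
#' @param x an \linkS4class{EnvStack}
#' @return data.frame with columns \code{row}, \code{col}, \code{cell} and
#'   one column per layer.
#' @export
envTable <- function(x) {
  stopifnot(is(x, "EnvStack"))
  d <- gridDim(x)
  out <- data.frame(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1])
  )
  out$cell <- (out$col - 1L) * d[1] + out$row
  for (nm in layerNames(x)) out[[nm]] <- as.vector(x@layers[, , nm])
  out
}

#' NicheGrid: corrected occupancy density on a gridded environment space
#'
#' Kernel-smoothed occurrence density \code{o}, background prevalence
#' \code{e} and corrected occupancy \code{z} on an R x R grid spanning the
#' first two ordination axes.  \code{z} sums to one over cells and is zero
#' wherever the background is absent.
#'
#' @slot R grid resolution per axis
#' @slot o occurrence density matrix (R x R)
#' @slot e background prevalence matrix (R x R)
#' @slot z corrected, normalized occupancy matrix (R x R)
#' @slot extent numeric(4): xmin, xmax, ymin, ymax of the grid
#' @export
setClass("NicheGrid", representation(
  R = "integer", o = "matrix", e = "matrix", z = "matrix", extent = "numeric"
))

setValidity("NicheGrid", function(object) {
  if (any(object@o < 0) || any(object@e < 0) || any(object@z < 0))
    return("o, e, z must be non-negative")
  if (any(object@z[object@e == 0] != 0))
    return("z must be zero where e is zero")
  s <- sum(object@z)
  if (s > 0 && abs(s - 1) > 1e-8) return("z must sum to 1")
  if (length(object@extent) != 4) return("extent must be length 4")
  TRUE
})

setMethod("show", "NicheGrid", function(object) {
  cat("NicheGrid: ", object@R, "x", object@R, " cells, occupied cells: ",
      sum(object@z > 0), "\n", sep = "")
})

#' @describeIn NicheGrid the normalized occupancy matrix z
#' @param x a NicheGrid
#' @export
setGeneric("nicheZ", function(x) standardGeneric("nicheZ"))
#' @export
setMethod("nicheZ", "NicheGrid", function(x) x@z)

#' OverlapTest: a niche equivalency or similarity permutation test
#'
#' @slot observedD observed Schoener's D
#' @slot nullD permuted D values
#' @slot pValue add-one permutation p-value
#' @slot nPerm number of permutations
#' @slot kind "equivalency" or "similarity"
#' @slot alternative direction of the one-sided test
#' @export
setClass("OverlapTest", representation(
  observedD = "numeric", nullD = "numeric", pValue = "numeric",
  nPerm = "integer", kind = "character", alternative = "character"
))

setValidity("OverlapTest", function(object) {
  if (object@observedD < -1e-12 || object@observedD > 1 + 1e-12)
    return("observedD outside [0,1]")
  if (object@pValue <= 0 || object@pValue > 1) return("pValue outside (0,1]")
  TRUE
})

setMethod("show", "OverlapTest", function(object) {
  cat("Niche ", object@kind, " test: D = ", signif(object@observedD, 4),
      ", p = ", signif(object@pValue, 4), " (", object@nPerm,
      " permutations, alternative: ", object@alternative, ")\n", sep = "")
})

#' EnvSpace: two-axis ordination of environmental conditions
#'
#' Principal-component scores of occurrences on the first two axes, the
#' variable loadings, variance fractions and the background cells projected
#' with the same centering and scaling.
#'
#' @slot axisScores occurrences x 2 score matrix
#' @slot loadings variables x 2 loading matrix
#' @slot varianceExplained fraction of variance per retained axis
#' @slot backgroundScores background cells x 2 score matrix
#' @slot center,scaleSd centering/scaling used for projection
#' @export
setClass("EnvSpace", representation(
  axisScores = "matrix", loadings = "matrix", varianceExplained = "numeric",
  backgroundScores = "matrix", center = "numeric", scaleSd = "numeric"
))

setMethod("show", "EnvSpace", function(object) {
  cat("EnvSpace: ", nrow(object@axisScores), " occurrences, axis variance ",
      paste(signif(object@varianceExplained, 3), collapse = " / "), "\n",
      sep = "")
})

#' GenotypeCalls: SNP genotype matrix with population metadata
#'
#' Extends \link[SummarizedExperiment]{RangedSummarizedExperiment}-free
#' \code{SummarizedExperiment}: rows are SNPs, columns individuals, the
#' single assay \code{"calls"} holds 0/1/2 allele-dosage calls with NA for
#' missing.  \code{rowData} carries the RAD-locus id and position of every
#' SNP; \code{colData} the population label and the K ancestry coefficients
#' (columns \code{Q1..QK}, rows summing to one).
#'
#' @export
#' @import SummarizedExperiment
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' required")
  g <- SummarizedExperiment::assay(object, "calls")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% 0:2)) return("calls must be in {0,1,2,NA}")
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must carry 'population'")
  if (!"locus" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must carry 'locus'")
  qc <- grep("^Q[0-9]+$", colnames(SummarizedExperiment::colData(object)))
  if (length(qc)) {
    qs <- rowSums(as.matrix(SummarizedExperiment::colData(object)[, qc]))
    if (any(abs(qs - 1) > 1e-6)) return("ancestry Q rows must sum to 1")
  }
  TRUE
})

#' Construct a GenotypeCalls object
#'
#' @param calls SNPs x individuals matrix in {0,1,2,NA}
#' @param population factor/character of population labels per individual
#' @param locus RAD-locus id per SNP
#' @param position position per SNP (optional)
#' @param Q individuals x K ancestry-coefficient matrix (rows sum to 1), or
#'   NULL
#' @return a \linkS4class{GenotypeCalls}
#' @export
GenotypeCalls <- function(calls, population, locus,
                          position = seq_len(nrow(calls)), Q = NULL) {
  cd <- S4Vectors::DataFrame(population = as.character(population))
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    colnames(Q) <- paste0("Q", seq_len(ncol(Q)))
    cd <- cbind(cd, S4Vectors::DataFrame(Q))
  }
  rownames(cd) <- colnames(calls)
  rd <- S4Vectors::DataFrame(locus = as.character(locus), position = position)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), colData = cd, rowData = rd)
  new("GenotypeCalls", se)
}

#' @describeIn GenotypeCalls the calls matrix (SNPs x individuals)
#' @param x a GenotypeCalls
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))
#' @export
setMethod("genoCalls", "GenotypeCalls", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @describeIn GenotypeCalls population label per individual
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' @export
setMethod("popLabels", "GenotypeCalls", function(x)
  SummarizedExperiment::colData(x)$population)

#' @describeIn GenotypeCalls ancestry coefficient matrix (individuals x K)
#' @export
setGeneric("ancestryQ", function(x) standardGeneric("ancestryQ"))
#' @export
setMethod("ancestryQ", "GenotypeCalls", function(x) {
  cd <- SummarizedExperiment::colData(x)
  qc <- grep("^Q[0-9]+$", colnames(cd), value = TRUE)
  if (!length(qc)) return(NULL)
  as.matrix(cd[, qc, drop = FALSE])
})

#' @describeIn GenotypeCalls RAD-locus id per SNP
#' @export
setGeneric("locusMap", function(x) standardGeneric("locusMap"))
#' @export
setMethod("locusMap", "GenotypeCalls", function(x)
  SummarizedExperiment::rowData(x)$locus)

setMethod("show", "GenotypeCalls", function(object) {
  g <- genoCalls(object)
  cat("GenotypeCalls: ", nrow(g), " SNPs x ", ncol(g), " individuals, ",
      length(unique(popLabels(object))), " populations, ",
      signif(100 * mean(is.na(g)), 3), "% missing\n", sep = "")
})

#' GdmModel: a generalized dissimilarity model of allelic turnover
#'
#' Fits dissimilarity d_ij = 1 - exp(-eta_ij) with eta a non-negative
#' I-spline expansion of predictor differences (and optionally geographic
#' distance).  Keeps the data it was fitted to so that single-predictor
#' refits (used by the candidate classification) are reproducible.
#'
#' @slot intercept fitted intercept (>= 0)
#' @slot coefs named list: per predictor, the non-negative I-spline
#'   coefficients
#' @slot knots named list: per predictor, the knot vector
#' @slot predictors predictor names, in fitting order ("geography" last when
#'   included)
#' @slot nullDeviance deviance of the intercept-only model
#' @slot explainedDeviance null minus residual deviance
#' @slot pctDeviance 100 * explained / null
#' @slot observed,fitted per-pair observed and fitted dissimilarities
#' @slot siteEnv site x predictor values used in the fit
#' @slot coords site coordinates (or 0-row matrix when geography unused)
#' @slot dissimilarity the pairwise dissimilarity matrix fitted
#' @export
setClass("GdmModel", representation(
  intercept = "numeric", coefs = "list", knots = "list",
  predictors = "character", nullDeviance = "numeric",
  explainedDeviance = "numeric", pctDeviance = "numeric",
  observed = "numeric", fitted = "numeric",
  siteEnv = "matrix", coords = "matrix", dissimilarity = "matrix"
))

setValidity("GdmModel", function(object) {
  if (any(unlist(object@coefs) < -1e-10)) return("coefficients must be >= 0")
  if (object@pctDeviance < -1e-8 || object@pctDeviance > 100 + 1e-8)
    return("pctDeviance outside [0,100]")
  if (any(object@fitted < 0 | object@fitted >= 1))
    return("fitted dissimilarities must be in [0,1)")
  TRUE
})

setMethod("show", "GdmModel", function(object) {
  cat("GdmModel: intercept ", signif(object@intercept, 3),
      ", null deviance ", signif(object@nullDeviance, 4),
      ", %deviance ", signif(object@pctDeviance, 3), "\n", sep = "")
  tv <- vapply(object@predictors, function(p) sum(object@coefs[[p]]), 0)
  cat("  turnover:", paste(sprintf("%s=%.3g", names(tv), tv),
                           collapse = ", "), "\n")
})

#' @describeIn GdmModel percent of null deviance explained
#' @param x a GdmModel
#' @export
setGeneric("pctDeviance", function(x) standardGeneric("pctDeviance"))
#' @export
setMethod("pctDeviance", "GdmModel", function(x) x@pctDeviance)

#' LandmarkSet: raw landmark configurations with grouping factors
#'
#' @slot coords individuals x landmarks x 2 array of raw coordinates
#' @slot factors data.frame of per-individual factors (group, sex, ...)
#' @export
setClass("LandmarkSet", representation(coords = "array",
                                       factors = "data.frame"))

setValidity("LandmarkSet", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 2) return("coords must be n x k x 2")
  if (anyNA(object@coords)) return("missing coordinates not allowed")
  if (nrow(object@factors) && nrow(object@factors) != d[1])
    return("factors rows must match configurations")
  TRUE
})

setMethod("show", "LandmarkSet", function(object) {
  d <- dim(object@coords)
  cat("LandmarkSet:", d[1], "configurations of", d[2], "landmarks\n")
})

#' ShapeSet: Procrustes-aligned shapes with centroid sizes
#'
#' @slot aligned individuals x landmarks x 2 array, each configuration
#'   centred at the origin with unit centroid size
#' @slot centroidSizes original centroid size per individual
#' @slot consensus mean shape (landmarks x 2)
#' @slot factors per-individual factors carried over from the landmarks
#' @export
setClass("ShapeSet", representation(
  aligned = "array", centroidSizes = "numeric", consensus = "matrix",
  factors = "data.frame"
))

setValidity("ShapeSet", function(object) {
  n <- dim(object@aligned)[1]
  for (i in seq_len(min(n, 5))) {
    cfg <- object@aligned[i, , ]
    if (max(abs(colMeans(cfg))) > 1e-6) return("aligned shapes must be centred")
    if (abs(sqrt(sum(cfg^2)) - 1) > 1e-6)
      return("aligned shapes must have unit centroid size")
  }
  TRUE
})

setMethod("show", "ShapeSet", function(object) {
  d <- dim(object@aligned)
  cat("ShapeSet:", d[1], "aligned configurations of", d[2], "landmarks\n")
})

#' @describeIn ShapeSet aligned coordinates array
#' @param x a ShapeSet
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))
#' @export
setMethod("alignedCoords", "ShapeSet", function(x) x@aligned)

#' @describeIn ShapeSet centroid sizes of the raw configurations
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))
#' @export
setMethod("centroidSizes", "ShapeSet", function(x) x@centroidSizes)

#' @describeIn ShapeSet consensus (mean) shape
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))
#' @export
setMethod("consensusShape", "ShapeSet", function(x) x@consensus)

#' SyntheticTruth: planted ground truth of a simulated genotype dataset
#'
#' @slot causalSnpIds ids of SNPs carrying a planted environmental cline
#' @slot clinePredictor name of the driving environmental variable
#' @slot clineStrength logit-scale slope per standardized predictor unit
#' @slot baselineFst Balding-Nichols divergence parameter
#' @slot popEnv populations x predictors matrix of environmental values
#' @slot popCoords populations x 2 cell coordinates
#' @slot popFreq populations x SNPs allele-frequency matrix
#' @export
setClass("SyntheticTruth", representation(
  causalSnpIds = "character", clinePredictor = "character",
  clineStrength = "numeric", baselineFst = "numeric",
  popEnv = "matrix", popCoords = "matrix", popFreq = "matrix"
))

setValidity("SyntheticTruth", function(object) {
  if (!is.finite(object@clineStrength)) return("clineStrength must be finite")
  if (object@baselineFst <= 0 || object@baselineFst >= 1)
    return("baselineFst must be in (0,1)")
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", length(object@causalSnpIds), " causal SNPs on ",
      object@clinePredictor, ", strength ", object@clineStrength,
      ", Fst ", object@baselineFst, "\n", sep = "")
})
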