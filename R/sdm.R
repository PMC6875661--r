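#' Thin occurrences to one per raster cell
#'
#' When several presence points fall in the same cell, one is kept uniformly
#' at random; reduces spatial pseudo-replication before model calibration.
#'
#' @param occ data.frame with \code{cell} (or \code{lon}/\code{lat}) columns
#' @param env an \linkS4class{EnvStack} defining the grid (used to derive
#'   cell ids when absent)
#' @param seed integer seed
#' @return the thinned occurrence data.frame
#' @export
thinOccurrences <- function(occ, env, seed = 1) {
  if (!"cell" %in% names(occ)) {
    d <- gridDim(env)
    occ$cell <- (occ$lon - 1L) * d[1] + occ$lat
  }
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(occ)), occ$cell), function(i)
    if (length(i) == 1) i else sample(i, 1)), use.names = FALSE)
  out <- occ[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Surface-range-envelope pseudo-absence sets
#'
#' The envelope is the per-variable [quantile, 1-quantile] interval of
#' presence values; pseudo-absences are sampled uniformly (without
#' replacement) from cells falling outside the envelope in at least one
#' variable.
#'
#' @param env an \linkS4class{EnvStack}
#' @param presences data.frame of presence points carrying the layer values
#' @param n pseudo-absences per set (default 5000)
#' @param nSets number of independent sets (default 5)
#' @param quantile envelope quantile (default 0.025)
#' @param seed integer seed
#' @return list of \code{nSets} data.frames shaped like \code{envTable(env)}
#' @export
srePseudoAbsences <- function(env, presences, n = 5000, nSets = 5,
                              quantile = 0.025, seed = 1) {
  if (nrow(presences) < 10) stop("need at least 10 presences")
  vars <- layerNames(env)
  tab <- envTable(env)
  lo <- vapply(vars, function(v) stats::quantile(presences[[v]], quantile), 0)
  hi <- vapply(vars, function(v)
    stats::quantile(presences[[v]], 1 - quantile), 0)
  outside <- rep(FALSE, nrow(tab))
  for (v in vars)
    outside <- outside | tab[[v]] < lo[v] | tab[[v]] > hi[v]
  pool <- which(outside)
  if (!length(pool))
    stop("no cells outside the presence envelope (envelope covers the ",
         "whole landscape); widen the grid or raise the quantile")
  if (length(pool) < n)
    stop("only ", length(pool), " cells outside the envelope; asked for ", n)
  set.seed(seed)
  lapply(seq_len(nSets), function(s) {
    out <- tab[sample(pool, n), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' True skill statistic
#'
#' TSS = sensitivity + specificity - 1 for scores binarized at a threshold.
#'
#' @param labels 0/1 vector (1 = presence)
#' @param scores numeric prediction scores
#' @param threshold binarization threshold (prediction >= threshold is a
#'   presence call)
#' @return TSS in [-1, 1]
#' @export
tss <- function(labels, scores, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pred <- as.integer(scores >= threshold)
  sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' TSS-maximizing threshold
#'
#' @param labels 0/1 vector
#' @param scores numeric scores
#' @return list with \code{threshold} and the \code{tss} it achieves
#' @export
tssMaxThreshold <- function(labels, scores) {
  cand <- unique(stats::quantile(scores, seq(0.005, 0.995, length.out = 199),
                                 names = FALSE))
  vals <- vapply(cand, function(th) tss(labels, scores, th), 0)
  i <- which.max(vals)
  list(threshold = cand[i], tss = vals[i])
}

# ---- pluggable learner contract -------------------------------------------
# A fitted learner is a list(learner=, fit=, predictors=); .predictLearner
# returns presence probabilities on new data.

.fitLearner <- function(learner, data, predictors, seed = 1) {
  y <- data$pa
  X <- data[, predictors, drop = FALSE]
  set.seed(seed)
  fit <- switch(
    learner,
    glm = suppressWarnings(stats::glm(
      stats::reformulate(predictors, "pa"), data = data,
      family = stats::binomial())),
    gam = {
      f <- stats::as.formula(paste("pa ~",
        paste(sprintf("s(%s, k = 4)", predictors), collapse = " + ")))
      mgcv::gam(f, data = data, family = stats::binomial(), method = "REML")
    },
    brt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(X), label = y), nrounds = 100),
    mars = {
      # adaptive spline family: natural-spline basis per variable with
      # lasso term selection
      B <- do.call(cbind, lapply(predictors, function(v)
        splines::ns(data[[v]], df = 4)))
      cv <- glmnet::cv.glmnet(B, y, family = "binomial", nfolds = 5)
      list(cv = cv, basisFrom = as.matrix(X), predictors = predictors)
    },
    rf = randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)), ntree = 200),
    stop("unknown learner: ", learner)
  )
  list(learner = learner, fit = fit, predictors = predictors)
}

.predictLearner <- function(model, newdata) {
  X <- newdata[, model$predictors, drop = FALSE]
  switch(
    model$learner,
    glm = as.numeric(predict(model$fit, newdata = X, type = "response")),
    gam = as.numeric(predict(model$fit, newdata = X, type = "response")),
    brt = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(as.matrix(X)))),
    mars = {
      B <- do.call(cbind, lapply(seq_along(model$predictors), function(i) {
        v <- model$predictors[i]
        ref <- splines::ns(model$fit$basisFrom[, v], df = 4)
        predict(ref, X[[v]])
      }))
      as.numeric(predict(model$fit$cv, B, s = "lambda.min",
                         type = "response"))
    },
    rf = as.numeric(predict(model$fit, newdata = X, type = "prob")[, "1"]),
    ensemble = {
      p <- vapply(model$members, .predictLearner, numeric(nrow(newdata)),
                  newdata = newdata)
      as.numeric(p %*% model$weights)
    },
    stop("unknown learner: ", model$learner)
  )
}

#' Calibrate the distribution-model ensemble members
#'
#' For every (learner x pseudo-absence set x repeat) combination the model
#' is fitted on a random, class-stratified 70\% of the data and evaluated
#' on the held-out 30\% with TSS (at its maximizing threshold) and ROC-AUC.
#' Failing learners are logged and skipped.
#'
#' @param presences data.frame of presence points with layer-value columns
#' @param paSets list of pseudo-absence data.frames (from
#'   \code{\link{srePseudoAbsences}})
#' @param learners learner family ids among "glm" (linear-additive), "gam"
#'   (smooth-additive), "brt" (boosted trees), "mars" (adaptive splines),
#'   "rf" (randomized tree ensemble)
#' @param predictors predictor column names (default: intersection of
#'   presence and pseudo-absence columns, minus coordinates)
#' @param split calibration fraction (default 0.7)
#' @param nRepeats random-split repeats (default 3)
#' @param seed integer seed
#' @return list of calibration results: each a list with \code{learner},
#'   \code{paSet}, \code{rep}, \code{model}, \code{tss}, \code{auc},
#'   \code{threshold}
#' @export
calibrateModels <- function(presences, paSets,
                            learners = c("glm", "gam", "brt", "mars", "rf"),
                            predictors = NULL, split = 0.7, nRepeats = 3,
                            seed = 1) {
  if (is.null(predictors))
    predictors <- setdiff(intersect(names(presences), names(paSets[[1]])),
                          c("lon", "lat", "row", "col", "cell"))
  results <- list()
  set.seed(seed)
  for (s in seq_along(paSets)) {
    dat <- rbind(
      cbind(pa = 1, presences[, predictors, drop = FALSE]),
      cbind(pa = 0, paSets[[s]][, predictors, drop = FALSE]))
    for (r in seq_len(nRepeats)) {
      i1 <- which(dat$pa == 1); i0 <- which(dat$pa == 0)
      tr <- c(sample(i1, round(split * length(i1))),
              sample(i0, round(split * length(i0))))
      train <- dat[tr, , drop = FALSE]; test <- dat[-tr, , drop = FALSE]
      for (ln in learners) {
        res <- tryCatch({
          m <- suppressWarnings(.fitLearner(ln, train, predictors,
                                            seed = sample.int(1e6, 1)))
          sc <- suppressWarnings(.predictLearner(m, test))
          th <- tssMaxThreshold(test$pa, sc)
          a <- as.numeric(pROC::auc(test$pa, sc, quiet = TRUE,
                                    direction = "<", levels = c(0, 1)))
          list(learner = ln, paSet = s, rep = r, model = m,
               tss = th$tss, auc = a, threshold = th$threshold)
        }, error = function(e) {
          message("learner ", ln, " failed (paSet ", s, ", rep ", r, "): ",
                  conditionMessage(e))
          NULL
        })
        if (!is.null(res)) results[[length(results) + 1]] <- res
      }
    }
  }
  results
}

#' Summarize calibration results as a table
#'
#' @param results output of \code{\link{calibrateModels}}
#' @return data.frame with learner, paSet, rep, tss, auc, threshold
#' @export
calibrationTable <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(learner = r$learner, paSet = r$paSet, rep = r$rep,
               tss = r$tss, auc = r$auc, threshold = r$threshold)))
}

#' Permutation variable importance
#'
#' Importance = 1 - mean Pearson correlation between the model's
#' predictions and its predictions after permuting one variable's column,
#' over \code{nPerm} permutations.
#'
#' @param model a fitted learner handle (element \code{model} of a
#'   calibration result, or an ensemble handle)
#' @param data data.frame of predictor values
#' @param variable variable to permute
#' @param nPerm number of permutations (default 10)
#' @param seed integer seed
#' @return importance in [0, 1]
#' @export
variableImportance <- function(model, data, variable, nPerm = 10, seed = 1) {
  p0 <- .predictLearner(model, data)
  if (sd(p0) == 0) {
    warning("constant predictions; importance set to 0")
    return(0)
  }
  set.seed(seed)
  rs <- vapply(seq_len(nPerm), function(i) {
    d <- data
    d[[variable]] <- sample(d[[variable]])
    p1 <- .predictLearner(model, d)
    if (sd(p1) == 0) 0 else cor(p0, p1)
  }, 0)
  max(0, min(1, 1 - mean(rs)))
}

#' Project the TSS-weighted ensemble onto an environmental stack
#'
#' Members with held-out TSS at or above \code{tssMin} contribute with
#' weight proportional to TSS; the continuous map is their weighted mean
#' probability, binarized at the ensemble's own TSS-maximizing threshold on
#' the calibration data.
#'
#' @param results calibration results
#' @param env an \linkS4class{EnvStack} to project onto
#' @param calibData data.frame with \code{pa} labels and predictor columns
#'   used to set the ensemble threshold (e.g. presences plus one PA set)
#' @param tssMin member-inclusion cutoff (default 0.4)
#' @return list with \code{suitability} and \code{binary} matrices (grid
#'   shaped), \code{threshold}, \code{weights}, and the ensemble
#'   \code{model} handle
#' @export
ensembleProject <- function(results, env, calibData, tssMin = 0.4) {
  keep <- Filter(function(r) is.finite(r$tss) && r$tss >= tssMin, results)
  if (!length(keep)) stop("no ensemble member reaches TSS >= ", tssMin)
  w <- vapply(keep, `[[`, 0, "tss")
  w <- w / sum(w)
  handle <- list(learner = "ensemble",
                 members = lapply(keep, `[[`, "model"), weights = w,
                 predictors = keep[[1]]$model$predictors)
  tab <- envTable(env)
  suit <- .predictLearner(handle, tab)
  d <- gridDim(env)
  calScores <- .predictLearner(handle, calibData)
  th <- tssMaxThreshold(calibData$pa, calScores)
  list(suitability = matrix(suit, d[1], d[2]),
       binary = matrix(suit >= th$threshold, d[1], d[2]),
       threshold = th$threshold, weights = w, model = handle)
}

#' Map-agreement niche-change metrics
#'
#' Within the analysis mask, with A the cells predicted by the
#' invaded-range model and B those predicted by the source-range model:
#' stability = |A and B| / |A|, expansion = |A minus B| / |A| (so stability
#' + expansion = 1), unfilling = |B minus A| / |B|.
#'
#' @param binaryInvaded,binarySource logical matrices on the same grid
#' @param mask optional logical matrix restricting the analysis region
#' @return list with stability, expansion, unfilling and the cell counts
#'   behind each
#' @export
nicheChangeMetrics <- function(binaryInvaded, binarySource, mask = NULL) {
  if (!all(dim(binaryInvaded) == dim(binarySource)))
    stop("maps are on different grids")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(binaryInvaded),
                                    ncol(binaryInvaded))
  A <- binaryInvaded & mask
  B <- binarySource & mask
  nA <- sum(A); nB <- sum(B)
  if (nA == 0 || nB == 0) stop("empty predicted range within the mask")
  both <- sum(A & B)
  list(stability = both / nA,
       expansion = sum(A & !B) / nA,
       unfilling = sum(B & !A) / nB,
       counts = c(A = nA, B = nB, both = both))
}

#' Fraction of occurrences falling in predicted-presence cells
#'
#' @param binaryMap logical matrix (rows x cols)
#' @param occ data.frame with \code{lon} (column index) and \code{lat}
#'   (row index)
#' @return fraction predicted; occurrences outside the raster are excluded
#'   and their count attached as attribute \code{excluded}
#' @export
occurrencePredictionRate <- function(binaryMap, occ) {
  r <- round(occ$lat); c <- round(occ$lon)
  ok <- r >= 1 & r <= nrow(binaryMap) & c >= 1 & c <= ncol(binaryMap)
  if (!any(ok)) stop("no occurrence falls on the raster")
  hit <- binaryMap[cbind(r[ok], c[ok])]
  structure(mean(hit), excluded = sum(!ok))
}
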