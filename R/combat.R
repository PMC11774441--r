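## Parametric empirical-Bayes ComBat for one categorical acquisition
## parameter. Model per feature g, scan j in batch i:
##   y_ijg = alpha_g + X_j beta_g + gamma_ig + delta_ig * eps_ijg
## Estimation: (1) least squares for alpha, beta and per-batch offsets
## under the constraint sum_i n_i gamma_ig = 0, pooled residual variance
## with denominator N; (2) standardize; (3) parametric EB shrinkage of
## per-batch location/scale with method-of-moments hyperparameters
## (Normal prior on gamma, inverse-gamma on delta^2), iterating the
## standard conditional posterior updates to convergence.

.EB_CONV <- 1e-4
.EB_MAX_ITER <- 500L

## One-hot covariate encoding, reference = most frequent level
## (ties broken alphabetically). Returns n x (L-1) matrix.
.covariateDesign <- function(labels, levels, reference) {
  keep <- setdiff(levels, reference)
  X <- matrix(0, length(labels), length(keep),
              dimnames = list(NULL, keep))
  for (lv in keep) X[labels == lv, lv] <- 1
  X
}

## Iterative conditional posterior updates for one batch, on the
## standardized scale. sdat: features x n_i.
.ebSolve <- function(sdat, gHat, dHat, gBar, t2, aPrior, bPrior,
                     conv = .EB_CONV, maxIter = .EB_MAX_ITER) {
  n <- ncol(sdat)
  gOld <- gHat
  dOld <- dHat
  change <- 1
  iter <- 0L
  while (change > conv && iter < maxIter) {
    gNew <- (t2 * n * gHat + dOld * gBar) / (t2 * n + dOld)
    sum2 <- rowSums((sdat - gNew)^2)
    dNew <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / gOld, abs(dNew - dOld) / dOld)
    gOld <- gNew
    dOld <- dNew
    iter <- iter + 1L
  }
  list(gamma = gOld, delta = dOld, iterations = iter)
}

#' Fit a ComBat harmonization model for one acquisition parameter
#'
#' Fits the location/scale empirical-Bayes batch model to the scans of
#' \code{x}, treating the instances of \code{parameter} as batches.
#' With a \code{covariate} (a categorical \code{colData} column, e.g.
#' \code{"subgroup"}), the covariate's effect on each feature is
#' estimated jointly and preserved: scans in different covariate levels
#' receive batch corrections with the same slope but different
#' intercept. Features that are constant within some batch level cannot
#' be standardized and are passed through unharmonized with a warning.
#'
#' @param x a \linkS4class{RadiomicExperiment} (already restricted to
#'   the fitting scope, e.g. one subgroup for separate harmonization).
#' @param parameter name of the acquisition parameter to harmonize.
#' @param covariate optional name of a categorical \code{colData} column
#'   to preserve, or \code{NULL}.
#' @param minBatchSize smallest admissible scan count per instance
#'   (default 3); an instance below it raises an unharmonizable-level
#'   error so that the caller can apply the exclusion rule.
#' @param scope label recorded in the model (\code{"all"} or a
#'   subgroup name).
#' @return A \linkS4class{CombatModel}.
#' @seealso [applyCombat()] to transform (possibly unseen) scans.
#' @examples
#' x <- simulateCohort(cohortConfig("shared", seed = 3))
#' m <- fitCombat(x, "CE", covariate = "subgroup")
#' m
#' @export
fitCombat <- function(x, parameter, covariate = NULL, minBatchSize = 3L,
                      scope = "all") {
  .fitCombatCore(featureMatrix(x), colData(x), parameter, covariate,
                 minBatchSize, scope)
}

.fitCombatCore <- function(dat, cd, parameter, covariate = NULL,
                           minBatchSize = 3L, scope = "all") {
  .assertThat(parameter %in% colnames(cd), "opncb_schema",
              sprintf("unknown acquisition parameter '%s'", parameter))
  .assertThat(minBatchSize >= 2, "opncb_config",
              "minBatchSize must be at least 2 (scale estimation needs replicates)")
  batch <- factor(as.character(cd[[parameter]]))
  levs <- levels(batch)
  if (length(levs) < 2L)
    .opncbStop("opncb_single_level",
               sprintf("parameter '%s' has a single instance ('%s'); no harmonization possible",
                       parameter, levs[1L]))
  counts <- table(batch)
  small <- names(counts)[counts < minBatchSize]
  if (length(small))
    .opncbStop("opncb_unharmonizable_level",
               sprintf("instance(s) %s of '%s' have fewer than %d scans",
                       paste(shQuote(small), collapse = ", "),
                       parameter, minBatchSize),
               levels = small, parameter = parameter)

  covLevels <- character()
  covRef <- NA_character_
  covName <- if (is.null(covariate)) NA_character_ else covariate
  X <- matrix(0, ncol(dat), 0L)
  if (!is.null(covariate)) {
    .assertThat(covariate %in% colnames(cd), "opncb_schema",
                sprintf("unknown covariate column '%s'", covariate))
    cv <- as.character(cd[[covariate]])
    covLevels <- sort(unique(cv))
    if (length(covLevels) >= 2L) {
      tab <- table(cv)
      covRef <- names(tab)[order(-tab, names(tab))][1L]
      X <- .covariateDesign(cv, covLevels, covRef)
    } else {
      ## degenerate covariate (single level): collapses to collective
      covLevels <- character()
      covName <- NA_character_
    }
  }

  batchMod <- .covariateDesign(as.character(batch), levs, reference = "")
  batchMod <- batchMod[, levs, drop = FALSE]
  design <- cbind(batchMod, X)
  if (qr(design)$rank < ncol(design))
    .opncbStop("opncb_confounded",
               "covariate is confounded with the batch variable; design is singular")

  ## features constant within some batch level cannot be adjusted
  zeroVar <- Reduce(union, lapply(levs, function(l) {
    which(.rowVars(dat[, batch == l, drop = FALSE]) == 0)
  }))
  passthrough <- rownames(dat)[zeroVar]
  if (length(passthrough)) {
    warning(sprintf(
      "%d feature(s) constant within a batch level left unharmonized: %s",
      length(passthrough), paste(passthrough, collapse = ", ")))
  }
  fitRows <- setdiff(rownames(dat), passthrough)
  .assertThat(length(fitRows) > 0, "opncb_degenerate_features",
              "all features are constant within some batch level")
  d <- dat[fitRows, , drop = FALSE]

  nBatches <- as.integer(counts[levs])
  nArray <- sum(nBatches)
  Bhat <- solve(crossprod(design), t(design) %*% t(d))
  grand <- drop(crossprod(nBatches / nArray, Bhat[seq_along(levs), , drop = FALSE]))
  varPooled <- drop(((d - t(design %*% Bhat))^2) %*% rep(1 / nArray, nArray))
  .assertThat(all(varPooled > 0), "opncb_degenerate_features",
              "zero pooled residual variance encountered")

  covCoef <- t(Bhat[-seq_along(levs), , drop = FALSE]) # features x q
  standMean <- grand + if (ncol(X)) tcrossprod(covCoef, X) else 0
  sData <- (d - standMean) / sqrt(varPooled)

  gammaHat <- t(vapply(levs, function(l)
    rowMeans(sData[, batch == l, drop = FALSE]), numeric(nrow(sData))))
  deltaHat <- t(vapply(levs, function(l)
    .rowVars(sData[, batch == l, drop = FALSE]), numeric(nrow(sData))))
  if (nrow(sData) == 1L) {
    gammaHat <- matrix(gammaHat, ncol = 1L, dimnames = list(levs, fitRows))
    deltaHat <- matrix(deltaHat, ncol = 1L, dimnames = list(levs, fitRows))
  }

  prior <- list()
  gammaStar <- gammaHat
  deltaStar <- deltaHat
  if (nrow(sData) >= 2L) {
    for (i in seq_along(levs)) {
      gBar <- mean(gammaHat[i, ])
      t2 <- stats::var(gammaHat[i, ])
      mD <- mean(deltaHat[i, ])
      s2D <- stats::var(deltaHat[i, ])
      aPrior <- (2 * s2D + mD^2) / s2D
      bPrior <- (mD * s2D + mD^3) / s2D
      prior[[levs[i]]] <- c(gammaBar = gBar, tau2 = t2,
                            lambda = aPrior, theta = bPrior)
      if (is.finite(t2) && t2 > 0 && is.finite(aPrior) && is.finite(bPrior)) {
        sol <- .ebSolve(sData[, batch == levs[i], drop = FALSE],
                        gammaHat[i, ], deltaHat[i, ], gBar, t2,
                        aPrior, bPrior)
        gammaStar[i, ] <- sol$gamma
        deltaStar[i, ] <- sol$delta
      }
    }
  } else {
    ## method-of-moments hyperparameters are undefined across a single
    ## feature: fall back to the unshrunk estimates
    prior <- stats::setNames(
      rep(list(c(gammaBar = NA, tau2 = NA, lambda = NA, theta = NA)), length(levs)),
      levs)
  }
  dimnames(gammaStar) <- dimnames(deltaStar) <- list(levs, fitRows)
  dimnames(gammaHat) <- dimnames(deltaHat) <- list(levs, fitRows)

  new("CombatModel",
      parameter = parameter,
      scope = scope,
      batchLevels = levs,
      batchCounts = stats::setNames(nBatches, levs),
      grandEffects = stats::setNames(grand, fitRows),
      covariate = covName,
      covariateLevels = covLevels,
      covariateReference = covRef,
      covariateCoefficients = covCoef,
      pooledSD = stats::setNames(sqrt(varPooled), fitRows),
      ebLocation = gammaStar,
      ebScale = deltaStar,
      rawLocation = gammaHat,
      rawScale = deltaHat,
      priorHyperparams = prior,
      passthroughFeatures = passthrough,
      featureNames = rownames(dat))
}

#' Apply a fitted ComBat model
#'
#' Transforms the scans of \code{x} with the corrections learned at fit
#' time; nothing is refitted. Every scan's instance of the model's
#' parameter (and, when the model has a covariate, its covariate level)
#' must have been seen at fit time; otherwise an unseen-level error is
#' raised and the caller decides about exclusion.
#'
#' @param model a \linkS4class{CombatModel}.
#' @param x a \linkS4class{RadiomicExperiment} with the same features.
#' @return A \linkS4class{RadiomicExperiment} of harmonized values.
#' @export
applyCombat <- function(model, x) {
  .withFeatures(x, .applyCombatCore(model, featureMatrix(x), colData(x)))
}

.applyCombatCore <- function(model, dat, cd) {
  .assertThat(all(model@featureNames %in% rownames(dat)), "opncb_schema",
              "table lacks features the model was fitted on")
  batch <- as.character(cd[[model@parameter]])
  unseen <- setdiff(unique(batch), model@batchLevels)
  if (length(unseen))
    .opncbStop("opncb_unseen_level",
               sprintf("instance(s) %s of '%s' were not seen at fit time",
                       paste(shQuote(unseen), collapse = ", "),
                       model@parameter),
               levels = unseen, parameter = model@parameter,
               scans = cd$scan_id[batch %in% unseen])
  Xc <- matrix(0, ncol(dat), 0L)
  if (!is.na(model@covariate)) {
    cv <- as.character(cd[[model@covariate]])
    bad <- setdiff(unique(cv), model@covariateLevels)
    if (length(bad))
      .opncbStop("opncb_unseen_level",
                 sprintf("covariate level(s) %s were not seen at fit time",
                         paste(shQuote(bad), collapse = ", ")),
                 levels = bad, parameter = model@covariate,
                 scans = cd$scan_id[cv %in% bad])
    Xc <- .covariateDesign(cv, model@covariateLevels,
                           model@covariateReference)
  }
  fitRows <- setdiff(model@featureNames, model@passthroughFeatures)
  d <- dat[fitRows, , drop = FALSE]
  standMean <- model@grandEffects[fitRows] +
    if (ncol(Xc)) tcrossprod(model@covariateCoefficients[fitRows, , drop = FALSE], Xc) else 0
  z <- (d - standMean) / model@pooledSD[fitRows]
  bi <- match(batch, model@batchLevels)
  adj <- (z - t(model@ebLocation[bi, fitRows, drop = FALSE])) /
    t(sqrt(model@ebScale[bi, fitRows, drop = FALSE]))
  out <- dat
  out[fitRows, ] <- model@pooledSD[fitRows] * adj + standMean
  out
}

setMethod("show", "CombatModel", function(object) {
  cat(sprintf("CombatModel for '%s' (scope: %s)\n",
              object@parameter, object@scope))
  cat(sprintf("  %d batch levels: %s\n", length(object@batchLevels),
              paste(sprintf("%s (n=%d)", object@batchLevels,
                            object@batchCounts), collapse = ", ")))
  if (!is.na(object@covariate))
    cat(sprintf("  covariate: %s (reference %s)\n", object@covariate,
                object@covariateReference))
  cat(sprintf("  %d features fitted", length(object@grandEffects)))
  if (length(object@passthroughFeatures))
    cat(sprintf(", %d passed through", length(object@passthroughFeatures)))
  cat("\n")
})

#' Serialize ComBat models to and from JSON
#'
#' @param model a \linkS4class{CombatModel}.
#' @param path JSON file path.
#' @return \code{readCombatModel} returns the restored model;
#'   \code{writeCombatModel} returns \code{path} invisibly.
#' @export
writeCombatModel <- function(model, path) {
  jsonlite::write_json(.modelToList(model), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCombatModel
#' @export
readCombatModel <- function(path) {
  .modelFromList(jsonlite::read_json(path, simplifyVector = TRUE))
}

.modelToList <- function(m) {
  list(parameter = m@parameter, scope = m@scope,
       batchLevels = m@batchLevels,
       batchCounts = unname(m@batchCounts),
       grandEffects = unname(m@grandEffects),
       covariate = m@covariate,
       covariateLevels = m@covariateLevels,
       covariateReference = m@covariateReference,
       covariateCoefficients = m@covariateCoefficients,
       covariateColumns = colnames(m@covariateCoefficients),
       pooledSD = unname(m@pooledSD),
       ebLocation = m@ebLocation,
       ebScale = m@ebScale,
       rawLocation = m@rawLocation,
       rawScale = m@rawScale,
       priorHyperparams = m@priorHyperparams,
       passthroughFeatures = m@passthroughFeatures,
       featureNames = m@featureNames)
}

.modelFromList <- function(l) {
  fitRows <- setdiff(l$featureNames, l$passthroughFeatures)
  asMat <- function(m, cols = fitRows) {
    m <- as.matrix(m)
    dimnames(m) <- list(l$batchLevels, cols)
    m
  }
  covCoef <- as.matrix(l$covariateCoefficients)
  if (!length(covCoef)) covCoef <- matrix(0, length(fitRows), 0L)
  rownames(covCoef) <- fitRows
  colnames(covCoef) <- l$covariateColumns
  new("CombatModel",
      parameter = l$parameter, scope = l$scope,
      batchLevels = l$batchLevels,
      batchCounts = stats::setNames(as.integer(l$batchCounts), l$batchLevels),
      grandEffects = stats::setNames(as.numeric(l$grandEffects), fitRows),
      covariate = if (is.null(l$covariate)) NA_character_ else l$covariate,
      covariateLevels = as.character(l$covariateLevels %||% character()),
      covariateReference = if (is.null(l$covariateReference)) NA_character_
                           else l$covariateReference,
      covariateCoefficients = covCoef,
      pooledSD = stats::setNames(as.numeric(l$pooledSD), fitRows),
      ebLocation = asMat(l$ebLocation),
      ebScale = asMat(l$ebScale),
      rawLocation = asMat(l$rawLocation),
      rawScale = asMat(l$rawScale),
      priorHyperparams = lapply(l$priorHyperparams, unlist),
      passthroughFeatures = as.character(l$passthroughFeatures %||% character()),
      featureNames = l$featureNames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
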