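#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
NULL

#' Radiomic feature table with per-scan metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one assay named
#' \code{"features"} (radiomic features in rows, scans in columns) plus
#' per-scan metadata in \code{colData}: \code{scan_id}, \code{patient_id},
#' \code{nodule_id}, \code{subgroup} (one of \code{benign},
#' \code{malignant}, \code{LCS}), the binary \code{malignancy_label}
#' (for lung-cancer-screening scans, 1 iff the nodule was later found
#' malignant), and one column per categorical acquisition parameter.
#' The names of the acquisition-parameter columns are recorded in
#' \code{metadata(x)$acquisitionParameters}.
#'
#' @slot .placeholder inherited slots only; see
#'   \linkS4class{SummarizedExperiment}.
#' @seealso [RadiomicExperiment()] for the constructor,
#'   [readFeatureTable()] / [writeFeatureTable()] for CSV interchange.
#' @export
setClass("RadiomicExperiment", contains = "SummarizedExperiment")

setValidity("RadiomicExperiment", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- colData(object)
  need <- c("scan_id", "patient_id", "nodule_id", "subgroup",
            "malignancy_label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  ap <- metadata(object)$acquisitionParameters
  if (is.null(ap) || !length(ap))
    msg <- c(msg, "metadata(x)$acquisitionParameters must name >= 1 column")
  else if (!all(ap %in% colnames(cd)))
    msg <- c(msg, "acquisition parameter columns missing from colData")
  else {
    for (p in ap) {
      if (anyNA(cd[[p]]))
        msg <- c(msg, sprintf("acquisition parameter '%s' has missing values", p))
    }
  }
  m <- assay(object, "features")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "feature values must all be finite")
  sg <- as.character(cd$subgroup)
  if (!all(sg %in% SUBGROUP_LEVELS))
    msg <- c(msg, "subgroup must be one of benign/malignant/LCS")
  lab <- cd$malignancy_label
  if (!all(lab %in% c(0L, 1L)))
    msg <- c(msg, "malignancy_label must be 0/1")
  if (any(sg == "benign" & lab != 0L))
    msg <- c(msg, "benign scans must have malignancy_label 0")
  if (any(sg == "malignant" & lab != 1L))
    msg <- c(msg, "malignant scans must have malignancy_label 1")
  ## a nodule belongs to exactly one patient
  map <- unique(data.frame(nodule = as.character(cd$nodule_id),
                           patient = as.character(cd$patient_id)))
  if (anyDuplicated(map$nodule))
    msg <- c(msg, "nodule_id must determine patient_id")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic radiomic cohorts
#'
#' Describes a cohort with three biological subgroups (benign, malignant,
#' lung cancer screening), per-feature Gaussian baselines with an additive
#' malignancy shift, a categorical acquisition schema, subgroup-dependent
#' instance frequencies, and location/scale batch effects per
#' (parameter, instance, subgroup, feature).
#'
#' @slot nPatients,nNodules,nScans named integer vectors
#'   (names \code{benign}, \code{malignant}, \code{LCS}).
#' @slot schema list with \code{parameters} (ordered character) and
#'   \code{levels} (named list of instance labels per parameter).
#' @slot instanceFrequencies named list; per parameter a matrix of
#'   sampling probabilities with subgroups in rows, instances in columns
#'   (rows sum to 1).
#' @slot nFeatures number of features.
#' @slot baselineMeans,baselineSDs,malignancyEffects per-feature baseline
#'   mean, baseline standard deviation, and benign-to-malignant mean
#'   shift (in original units).
#' @slot batchLocation,batchScale named list; per parameter an array of
#'   dimension (instances x subgroups x features) of additive location
#'   offsets / multiplicative scale factors applied to the noise part.
#' @slot effectSharing \code{"shared_across_subgroups"} or
#'   \code{"subgroup_specific"}.
#' @slot lcsFutureMalignantFraction fraction of screening nodules flagged
#'   as later malignant.
#' @slot lcsAttenuation multiplier on the malignancy shift for screening
#'   scans of later-malignant nodules (their malignancy status at scan
#'   time is unknown).
#' @slot equicorrelation common pairwise correlation of the per-feature
#'   noise (0 = independent features).
#' @slot seed integer root seed for all randomness in [simulateCohort()].
#' @seealso [simulationConfig()], [cohortConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig", representation(
  nPatients = "integer",
  nNodules = "integer",
  nScans = "integer",
  schema = "list",
  instanceFrequencies = "list",
  nFeatures = "integer",
  baselineMeans = "numeric",
  baselineSDs = "numeric",
  malignancyEffects = "numeric",
  batchLocation = "list",
  batchScale = "list",
  effectSharing = "character",
  lcsFutureMalignantFraction = "numeric",
  lcsAttenuation = "numeric",
  equicorrelation = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (nm in c("nPatients", "nNodules", "nScans")) {
    v <- slot(object, nm)
    if (!identical(sort(names(v)), sort(SUBGROUP_LEVELS)))
      msg <- c(msg, sprintf("%s must be named benign/malignant/LCS", nm))
    if (any(v < 0L)) msg <- c(msg, sprintf("%s must be non-negative", nm))
  }
  ok <- all(object@nScans[SUBGROUP_LEVELS] >= object@nNodules[SUBGROUP_LEVELS]) &&
    all(object@nNodules[SUBGROUP_LEVELS] >= object@nPatients[SUBGROUP_LEVELS])
  if (!ok) msg <- c(msg, "need n_scans >= n_nodules >= n_patients per subgroup")
  pars <- object@schema$parameters
  if (anyDuplicated(pars)) msg <- c(msg, "parameter names must be unique")
  for (p in pars) {
    lv <- object@schema$levels[[p]]
    if (length(lv) < 2L)
      msg <- c(msg, sprintf("parameter '%s' needs >= 2 instance labels", p))
    fr <- object@instanceFrequencies[[p]]
    if (is.null(fr) || !all(abs(rowSums(fr) - 1) < 1e-9))
      msg <- c(msg, sprintf("instance frequencies for '%s' must sum to 1", p))
    bl <- object@batchLocation[[p]]
    bs <- object@batchScale[[p]]
    dims <- c(length(lv), length(SUBGROUP_LEVELS), object@nFeatures)
    if (!identical(dim(bl), dims) || !identical(dim(bs), dims))
      msg <- c(msg, sprintf("batch effect arrays for '%s' must be %s",
                            p, paste(dims, collapse = " x ")))
    else {
      if (any(bs <= 0)) msg <- c(msg, "all batch scale factors must be > 0")
      if (object@effectSharing == "shared_across_subgroups") {
        same <- function(a) all(abs(sweep(a, c(1, 3), a[, 1, ])) < 1e-12)
        if (!same(bl) || !same(bs))
          msg <- c(msg, sprintf(
            "'%s': shared_across_subgroups requires identical effects per subgroup", p))
      }
    }
  }
  if (object@nFeatures <= 0L) msg <- c(msg, "nFeatures must be positive")
  for (nm in c("baselineMeans", "baselineSDs", "malignancyEffects")) {
    if (length(slot(object, nm)) != object@nFeatures)
      msg <- c(msg, sprintf("%s must have length nFeatures", nm))
  }
  if (any(object@baselineSDs <= 0)) msg <- c(msg, "baselineSDs must be > 0")
  if (object@lcsFutureMalignantFraction < 0 || object@lcsFutureMalignantFraction > 1)
    msg <- c(msg, "lcsFutureMalignantFraction must be in [0,1]")
  if (object@equicorrelation < 0 || object@equicorrelation >= 1)
    msg <- c(msg, "equicorrelation must be in [0,1)")
  if (!object@effectSharing %in% c("shared_across_subgroups", "subgroup_specific"))
    msg <- c(msg, "unknown effectSharing value")
  if (length(msg)) msg else TRUE
})

#' Fitted ComBat model for one acquisition parameter
#'
#' Location/scale empirical-Bayes harmonization model for the categorical
#' batch variable \code{parameter}, fitted within one scope (all scans,
#' or a single subgroup for separate harmonization). Stores everything
#' needed to transform unseen scans: per-feature grand effects, optional
#' covariate coefficients, the pooled residual scale, and per-batch
#' posterior location (\code{ebLocation}) and scale (\code{ebScale},
#' a variance-scale factor) adjustments on the standardized scale.
#'
#' @slot parameter harmonized acquisition parameter (batch variable).
#' @slot scope \code{"all"} or the subgroup whose scans were used to fit.
#' @slot batchLevels,batchCounts instance labels seen at fit time and
#'   their scan counts.
#' @slot grandEffects per-feature pooled location (alpha-hat).
#' @slot covariate,covariateLevels,covariateReference optional categorical
#'   covariate preserved during harmonization (one-hot, reference = most
#'   frequent level); \code{NA} when absent.
#' @slot covariateCoefficients features x covariate-columns matrix of
#'   fitted slopes (0 columns when no covariate).
#' @slot pooledSD per-feature pooled residual standard deviation.
#' @slot ebLocation,ebScale levels x features matrices of posterior batch
#'   location offsets and variance-scale factors (standardized scale).
#' @slot rawLocation,rawScale the pre-shrinkage per-batch estimates
#'   (gamma-hat, delta-hat), kept for diagnostics.
#' @slot priorHyperparams per-level method-of-moments hyperparameters
#'   (location prior mean/variance, inverse-gamma shape/scale).
#' @slot passthroughFeatures features left unharmonized because they were
#'   constant within some batch level.
#' @slot featureNames all feature names the model covers, in order.
#' @export
setClass("CombatModel", representation(
  parameter = "character",
  scope = "character",
  batchLevels = "character",
  batchCounts = "integer",
  grandEffects = "numeric",
  covariate = "character",
  covariateLevels = "character",
  covariateReference = "character",
  covariateCoefficients = "matrix",
  pooledSD = "numeric",
  ebLocation = "matrix",
  ebScale = "matrix",
  rawLocation = "matrix",
  rawScale = "matrix",
  priorHyperparams = "list",
  passthroughFeatures = "character",
  featureNames = "character"
))

setValidity("CombatModel", function(object) {
  msg <- character()
  if (length(object@batchLevels) < 2L)
    msg <- c(msg, "a ComBat model needs >= 2 batch levels")
  if (any(object@pooledSD <= 0, na.rm = TRUE))
    msg <- c(msg, "pooledSD must be positive")
  if (any(object@ebScale <= 0, na.rm = TRUE))
    msg <- c(msg, "ebScale must be positive")
  ## estimation constraint: batch-size-weighted raw offsets sum to zero
  if (nrow(object@rawLocation)) {
    s <- drop(object@batchCounts %*% object@rawLocation)
    if (any(abs(s) > 1e-8 * max(1, sum(object@batchCounts))))
      msg <- c(msg, "weighted raw batch offsets must sum to ~0 per feature")
  }
  if (length(msg)) msg else TRUE
})

#' Sequential multi-parameter harmonization plan
#'
#' The result of nested ComBat fitting: a harmonization mode, an ordering
#' of the acquisition parameters, and the ComBat models fitted
#' sequentially in that order (model k was fitted on data already
#' transformed by models 1..k-1). In \code{separate} mode there is one
#' model per (parameter, subgroup); otherwise one per parameter.
#'
#' @slot mode \code{"collective"}, \code{"covariate"} or \code{"separate"}.
#' @slot parameterOrder permutation of the schema parameters, in fitting
#'   order.
#' @slot models named list of \linkS4class{CombatModel}; names are
#'   \code{"<parameter>"} or \code{"<parameter>|<subgroup>"}.
#' @slot exclusionLog data.frame of scans removed before fitting.
#' @slot alpha significance threshold used when scoring permutations.
#' @slot score number of acquisition-independent features on the
#'   harmonized training data under this plan.
#' @slot minBatchSize smallest admissible per-instance scan count.
#' @export
setClass("HarmonizationPlan", representation(
  mode = "character",
  parameterOrder = "character",
  models = "list",
  exclusionLog = "data.frame",
  alpha = "numeric",
  score = "numeric",
  minBatchSize = "integer"
))

setValidity("HarmonizationPlan", function(object) {
  msg <- character()
  if (!object@mode %in% c("collective", "covariate", "separate"))
    msg <- c(msg, "unknown harmonization mode")
  if (anyDuplicated(object@parameterOrder))
    msg <- c(msg, "parameterOrder must be a permutation (no repeats)")
  pars <- vapply(object@models, function(m) m@parameter, character(1))
  if (!all(pars %in% object@parameterOrder))
    msg <- c(msg, "every model must correspond to an ordered parameter")
  if (object@mode != "separate" &&
      length(object@models) != length(object@parameterOrder))
    msg <- c(msg, "collective/covariate plans need exactly one model per parameter")
  if (length(msg)) msg else TRUE
})

#' Acquisition-independence report
#'
#' Per-(feature, parameter, subgroup) Kruskal-Wallis results and the
#' resulting acquisition-independent feature set: a feature is
#' independent iff no test over any parameter, in either tested
#' subgroup, returned p <= alpha.
#'
#' @slot pvalues long data.frame with columns \code{feature},
#'   \code{parameter}, \code{subgroup}, \code{H}, \code{p},
#'   \code{flagged}.
#' @slot alpha the significance threshold of the gate.
#' @slot independentFeatures features passing every test.
#' @slot failureCounts parameters x subgroups matrix of flagged-feature
#'   counts.
#' @slot skipped scopes that could not be tested (fewer than two
#'   instances present); counted as passes.
#' @export
setClass("IndependenceReport", representation(
  pvalues = "data.frame",
  alpha = "numeric",
  independentFeatures = "character",
  failureCounts = "matrix",
  skipped = "data.frame"
))

setValidity("IndependenceReport", function(object) {
  pv <- object@pvalues
  if (nrow(pv)) {
    if (any(pv$p <= 0 | pv$p > 1)) return("p-values must lie in (0, 1]")
    bad <- unique(pv$feature[pv$flagged])
    indep <- setdiff(unique(pv$feature), bad)
    if (!setequal(indep, object@independentFeatures))
      return("independentFeatures inconsistent with flagged p-values")
  }
  TRUE
})

#' LASSO-selected linear SVM malignancy classifier
#'
#' Feature selection and classifier state needed to score unseen scans:
#' the selected feature names, their training-set standardization, the
#' SVM hyperplane (weights and bias on the standardized scale), and the
#' degenerate fallback flag. When LASSO selects no feature the model
#' predicts the benign class with a constant negative score.
#'
#' @slot selectedFeatures ordered selected feature names.
#' @slot center,scale per-selected-feature training mean and standard
#'   deviation.
#' @slot weights,bias linear decision function on standardized features;
#'   positive scores predict malignancy.
#' @slot fallback TRUE when no feature was selected.
#' @export
setClass("PredictiveModel", representation(
  selectedFeatures = "character",
  center = "numeric",
  scale = "numeric",
  weights = "numeric",
  bias = "numeric",
  fallback = "logical"
))

setValidity("PredictiveModel", function(object) {
  if (length(object@weights) != length(object@selectedFeatures))
    return("weights must align with selectedFeatures")
  if (object@fallback && length(object@selectedFeatures))
    return("fallback models carry no selected features")
  TRUE
})

#' Cross-validated experiment summary
#'
#' Per-trial, per-method harmonization and prediction results from the
#' repeated stratified cross-validation harness, with aggregate means,
#' 95% t-intervals, and pairwise DeLong ROC-AUC comparisons adjusted by
#' Holm-Bonferroni.
#'
#' @slot trials long data.frame, one row per (trial, method).
#' @slot summary per-method aggregate metrics with confidence intervals.
#' @slot comparisons per-(method pair, trial) DeLong results with
#'   Holm-adjusted p-values and per-direction significance counts.
#' @slot k,repeats,seed the cross-validation design.
#' @slot droppedTrials trial ids dropped because exclusion emptied a
#'   fitting scope.
#' @export
setClass("ExperimentSummary", representation(
  trials = "data.frame",
  summary = "data.frame",
  comparisons = "data.frame",
  k = "integer",
  repeats = "integer",
  seed = "integer",
  droppedTrials = "character"
))
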