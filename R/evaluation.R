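## Repeated stratified cross-validation harness: per-trial
## harmonization + gating + LASSO-SVM, per-method metrics overall and
## on the screening subgroup, DeLong ROC-AUC comparisons with
## Holm-Bonferroni adjustment, and the uniform-acquisition sanity
## check.

#' Repeated stratified K-fold splits
#'
#' Splits scans into \code{k} folds, stratified on the crossing of
#' subgroup and malignancy label, repeated \code{repeats} times. Within
#' each repeat the test folds partition the scans. Deterministic given
#' the seed.
#'
#' @param x a \linkS4class{RadiomicExperiment}.
#' @param k folds per repeat (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed.
#' @return list of \code{k * repeats} splits, each a list with
#'   \code{repeat_}, \code{fold}, \code{train} and \code{test} (column
#'   indices into \code{x}).
#' @export
makeSplits <- function(x, k = 5L, repeats = 10L, seed = 1L) {
  strata <- interaction(subgroups(x), malignancyLabels(x), drop = TRUE)
  tooSmall <- names(which(table(strata) < k))
  if (length(tooSmall))
    .opncbStop("opncb_stratification",
               sprintf("stratum/strata %s hold fewer than k = %d scans",
                       paste(shQuote(tooSmall), collapse = ", "), k))
  set.seed(seed)
  splits <- list()
  for (r in seq_len(repeats)) {
    fold <- integer(ncol(x))
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      splits[[length(splits) + 1L]] <- list(
        repeat_ = r, fold = f,
        train = which(fold != f), test = which(fold == f))
    }
  }
  splits
}

#' Classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced accuracy
#' (their mean), and the rank-statistic ROC-AUC of the scores. Metrics
#' undefined on the subset (e.g. sensitivity without positives) are
#' \code{NA}.
#'
#' @param scores real decision scores (higher = more malignant).
#' @param predicted 0/1 predicted labels.
#' @param truth 0/1 true labels.
#' @param subset optional logical or integer subset of the scans.
#' @return named list: \code{sensitivity}, \code{specificity},
#'   \code{balanced_accuracy}, \code{auc}, all on the [0, 1] scale.
#' @examples
#' computeMetrics(c(.9, .3, .6, .2), c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
computeMetrics <- function(scores, predicted, truth, subset = NULL) {
  if (!is.null(subset)) {
    scores <- scores[subset]
    predicted <- predicted[subset]
    truth <- truth[subset]
  }
  if (!length(truth))
    return(list(sensitivity = NA_real_, specificity = NA_real_,
                balanced_accuracy = NA_real_, auc = NA_real_))
  pos <- truth == 1L
  sens <- if (any(pos)) mean(predicted[pos] == 1L) else NA_real_
  spec <- if (any(!pos)) mean(predicted[!pos] == 0L) else NA_real_
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  auc <- NA_real_
  if (any(pos) && any(!pos)) {
    r <- rank(scores)
    n1 <- sum(pos)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * (length(truth) - n1))
  }
  list(sensitivity = sens, specificity = spec, balanced_accuracy = bal,
       auc = auc)
}

#' Paired DeLong test for two correlated ROC-AUCs
#'
#' Compares the AUCs of two score vectors over the same scans using the
#' structural-components (placement-value) decomposition: the variance
#' of the AUC difference is assembled from the per-positive and
#' per-negative placement covariances, and the two-sided p-value comes
#' from the normal approximation. Identical score vectors give an AUC
#' difference of 0 and p = 1.
#'
#' @param scoresA,scoresB decision scores of the two models over the
#'   same scans.
#' @param truth 0/1 true labels; both classes must be present.
#' @return list with \code{aucA}, \code{aucB} and \code{p.value}.
#' @export
delongTest <- function(scoresA, scoresB, truth) {
  truth <- as.integer(truth)
  .assertThat(length(scoresA) == length(truth) &&
                length(scoresB) == length(truth),
              "opncb_data", "score vectors must align with the labels")
  if (length(unique(truth)) < 2L)
    .opncbStop("opncb_test_inapplicable",
               "DeLong test needs both classes present")
  pos <- which(truth == 1L)
  neg <- which(truth == 0L)
  m <- length(pos)
  n <- length(neg)
  placements <- function(s) {
    psi <- outer(s[pos], s[neg],
                 function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi),
         auc = mean(psi))
  }
  a <- placements(scoresA)
  b <- placements(scoresB)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(1 - a$v01, 1 - b$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  p <- if (varDiff <= .Machine$double.eps) {
    if (abs(diff) <= .Machine$double.eps) 1 else NA_real_
  } else {
    2 * stats::pnorm(-abs(diff) / sqrt(varDiff))
  }
  list(aucA = a$auc, aucB = b$auc, p.value = p)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @examples
#' holmBonferroni(c(0.01, 0.04, 0.03))
#' @export
holmBonferroni <- function(pvalues) {
  .assertThat(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "opncb_data", "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

.METHODS <- c("unharmonized", "collective", "covariate", "separate")

## One method on one trial. Returns per-trial row fields plus the test
## scores needed for DeLong comparisons.
.runMethodOnTrial <- function(method, train, test, alpha, lassoAlpha,
                              svmCost, minBatchSize, optimize,
                              parameterOrder) {
  plan <- NULL
  harmTrain <- train
  if (method != "unharmonized") {
    plan <- if (optimize) {
      optimizePermutation(train, mode = method, alpha = alpha,
                          minBatchSize = minBatchSize)
    } else {
      fitPlan(train, mode = method,
              parameterOrder = parameterOrder %||%
                acquisitionParameters(train),
              alpha = alpha, minBatchSize = minBatchSize)
    }
    harmTrain <- applyPlan(plan, train)
  }
  gate <- independenceReport(harmTrain, alpha = alpha)
  indep <- independentFeatures(gate)
  yTr <- malignancyLabels(harmTrain)
  Xtr <- t(featureMatrix(harmTrain))
  sel <- if (length(indep)) {
    lassoSelect(Xtr[, indep, drop = FALSE], yTr, alpha = lassoAlpha)
  } else character()
  model <- trainClassifier(Xtr[, sel, drop = FALSE], yTr, C = svmCost)
  harmTest <- if (is.null(plan)) test else applyPlan(plan, test)
  pred <- predictScores(model, t(featureMatrix(harmTest)))
  yTe <- malignancyLabels(harmTest)
  lcs <- subgroups(harmTest) == "LCS"
  list(
    plan = plan,
    nIndependent = length(indep),
    selected = sel,
    model = model,
    usable = !model@fallback,
    scores = pred$scores,
    truth = yTe,
    overall = computeMetrics(pred$scores, pred$labels, yTe),
    lcs = computeMetrics(pred$scores, pred$labels, yTe, subset = lcs)
  )
}

#' Run the full harmonization-comparison experiment
#'
#' For every trial of a repeated stratified K-fold design: applies the
#' shared exclusion rules, then for each requested method fits the
#' (permutation-optimized) nested harmonization plan on the training
#' scans, gates features with the Kruskal-Wallis test, selects features
#' by LASSO, trains the linear SVM, applies plan and model to the
#' unseen test scans, and computes metrics overall and on the screening
#' (LCS) subgroup. Per-trial DeLong comparisons between methods are
#' Holm-adjusted across trials. Trials whose exclusion step empties a
#' fitting scope are dropped entirely; methods whose pipeline yields no
#' usable feature fall back to the constant benign predictor and are
#' excluded from that method's mean prediction metrics.
#'
#' @param input a \linkS4class{SimulationConfig} (a cohort is generated)
#'   or a \linkS4class{RadiomicExperiment}.
#' @param k,repeats cross-validation design (default 5 x 10).
#' @param seed integer seed driving the splits.
#' @param methods subset of \code{"unharmonized"}, \code{"collective"},
#'   \code{"covariate"}, \code{"separate"}.
#' @param alpha Kruskal-Wallis gate threshold (default 0.05).
#' @param lassoAlpha LASSO penalty (default 0.05).
#' @param svmCost SVM soft-margin cost (default 1).
#' @param minBatchSize smallest admissible per-instance scan count.
#' @param optimize if TRUE (default), re-optimize the parameter
#'   permutation per trial; otherwise use \code{parameterOrder}.
#' @param parameterOrder fixed order when \code{optimize = FALSE}.
#' @return An \linkS4class{ExperimentSummary}.
#' @export
runExperiment <- function(input, k = 5L, repeats = 10L, seed = 1L,
                          methods = .METHODS,
                          alpha = 0.05, lassoAlpha = 0.05, svmCost = 1,
                          minBatchSize = 3L, optimize = TRUE,
                          parameterOrder = NULL) {
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  x <- if (is(input, "SimulationConfig")) simulateCohort(input) else input
  .assertThat(is(x, "RadiomicExperiment"), "opncb_data",
              "input must be a SimulationConfig or RadiomicExperiment")
  seeds <- .childSeeds(seed, 1L)
  splits <- makeSplits(x, k = k, repeats = repeats, seed = seeds[1L])
  nFeat <- nrow(x)

  trialRows <- list()
  cmpRows <- list()
  dropped <- character()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    trialId <- sprintf("r%02d_f%d", sp$repeat_, sp$fold)
    excl <- tryCatch(
      excludeUnharmonizable(x[, sp$train], x[, sp$test],
                            minBatchSize = minBatchSize,
                            mode = "separate"),
      opncb_trial_unusable = function(e) NULL)
    if (is.null(excl)) {
      dropped <- c(dropped, trialId)
      next
    }
    results <- list()
    for (method in methods) {
      res <- tryCatch(
        .runMethodOnTrial(method, excl$train, excl$test, alpha,
                          lassoAlpha, svmCost, minBatchSize,
                          optimize = optimize,
                          parameterOrder = parameterOrder),
        opncb_trial_unusable = function(e) NULL)
      if (is.null(res)) next
      results[[method]] <- res
      trialRows[[length(trialRows) + 1L]] <- data.frame(
        trial = trialId, repeat_ = sp$repeat_, fold = sp$fold,
        method = method,
        n_train = ncol(excl$train), n_test = ncol(excl$test),
        n_excluded = nrow(excl$exclusionLog),
        independent_fraction = res$nIndependent / nFeat,
        n_selected = length(res$selected),
        usable = res$usable,
        sensitivity = res$overall$sensitivity,
        specificity = res$overall$specificity,
        balanced_accuracy = res$overall$balanced_accuracy,
        auc = res$overall$auc,
        lcs_sensitivity = res$lcs$sensitivity,
        lcs_specificity = res$lcs$specificity,
        lcs_balanced_accuracy = res$lcs$balanced_accuracy,
        lcs_auc = res$lcs$auc,
        stringsAsFactors = FALSE)
    }
    avail <- intersect(methods, names(results))
    prs <- if (length(avail) >= 2L)
      utils::combn(avail, 2L, simplify = FALSE) else list()
    for (pr in prs) {
      ra <- results[[pr[1L]]]
      rb <- results[[pr[2L]]]
      dl <- tryCatch(delongTest(ra$scores, rb$scores, ra$truth),
                     opncb_test_inapplicable = function(e) NULL)
      if (is.null(dl)) next
      cmpRows[[length(cmpRows) + 1L]] <- data.frame(
        trial = trialId, method_a = pr[1L], method_b = pr[2L],
        auc_a = dl$aucA, auc_b = dl$aucB, p = dl$p.value,
        stringsAsFactors = FALSE)
    }
  }
  .assertThat(length(trialRows) > 0, "opncb_experiment",
              "every trial was unusable")
  trials <- do.call(rbind, trialRows)
  comparisons <- if (length(cmpRows)) do.call(rbind, cmpRows) else
    data.frame(trial = character(), method_a = character(),
               method_b = character(), auc_a = numeric(),
               auc_b = numeric(), p = numeric())
  if (nrow(comparisons)) {
    comparisons$p_adjusted <- NA_real_
    for (key in unique(paste(comparisons$method_a, comparisons$method_b))) {
      idx <- paste(comparisons$method_a, comparisons$method_b) == key
      comparisons$p_adjusted[idx] <- holmBonferroni(comparisons$p[idx])
    }
    comparisons$significant <- !is.na(comparisons$p_adjusted) &
      comparisons$p_adjusted <= 0.05
    comparisons$favours <- ifelse(
      comparisons$auc_a > comparisons$auc_b, comparisons$method_a,
      ifelse(comparisons$auc_b > comparisons$auc_a,
             comparisons$method_b, NA_character_))
  }

  metricCols <- c("independent_fraction", "sensitivity", "specificity",
                  "balanced_accuracy", "auc", "lcs_sensitivity",
                  "lcs_specificity", "lcs_balanced_accuracy", "lcs_auc")
  sumRows <- list()
  for (method in unique(trials$method)) {
    tm <- trials[trials$method == method, ]
    for (mc in metricCols) {
      ## prediction metrics are averaged over usable trials only; the
      ## independent-feature fraction over all trials
      v <- if (mc == "independent_fraction") tm[[mc]] else
        tm[[mc]][tm$usable]
      st <- .tSummary(v)
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        method = method, metric = mc, mean = st[["mean"]],
        ci_lo = st[["lo"]], ci_hi = st[["hi"]], n_trials = st[["n"]],
        stringsAsFactors = FALSE)
    }
  }
  new("ExperimentSummary",
      trials = trials,
      summary = do.call(rbind, sumRows),
      comparisons = comparisons,
      k = as.integer(k), repeats = as.integer(repeats),
      seed = as.integer(seed),
      droppedTrials = dropped)
}

setMethod("show", "ExperimentSummary", function(object) {
  cat(sprintf("ExperimentSummary: %d-fold x %d repeats (%d trial-method runs",
              object@k, object@repeats, nrow(object@trials)))
  if (length(object@droppedTrials))
    cat(sprintf(", %d trial(s) dropped", length(object@droppedTrials)))
  cat(")\n  mean independent-feature fraction by method:\n")
  s <- object@summary
  s <- s[s$metric == "independent_fraction", ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-12s %5.1f%% (95%% CI %.1f-%.1f)\n", s$method[i],
                100 * s$mean[i], 100 * s$ci_lo[i], 100 * s$ci_hi[i]))
})

#' Uniform-acquisition sanity check of the Kruskal-Wallis gate
#'
#' Identifies maximal groups of scans sharing every acquisition-
#' parameter instance (uniform groups), splits each into \code{k}
#' folds, and runs the Kruskal-Wallis test between the train and test
#' portions per feature per subgroup. With no acquisition variability
#' inside a group the tests are null, so the non-significant fraction
#' should sit near \code{1 - alpha}; a deficit signals acquisition
#' structure the schema does not capture.
#'
#' @param x an (unharmonized) \linkS4class{RadiomicExperiment}.
#' @param k folds (default 5); groups smaller than \code{2k} scans are
#'   skipped.
#' @param alpha significance threshold (default 0.05).
#' @param seed integer seed for the fold assignment.
#' @param subgroups subgroups tested separately (default benign and
#'   malignant).
#' @return list with \code{overall} (mean non-significant fraction
#'   across groups), \code{groups} (per-group data.frame) and
#'   \code{skipped} (uniform groups too small to test).
#' @export
uniformGroupCheck <- function(x, k = 5L, alpha = 0.05, seed = 1L,
                              subgroups = c("benign", "malignant")) {
  cd <- colData(x)
  params <- acquisitionParameters(x)
  key <- do.call(paste, c(lapply(params, function(p)
    as.character(cd[[p]])), sep = "|"))
  tab <- table(key)
  eligible <- names(tab)[tab >= 2L * k]
  skipped <- data.frame(group = names(tab)[tab < 2L * k],
                        n = as.integer(tab[tab < 2L * k]))
  if (!length(eligible))
    .opncbStop("opncb_check_inapplicable",
               sprintf("no uniform group holds at least %d scans", 2L * k))
  set.seed(seed)
  groupRows <- list()
  for (gkey in eligible) {
    idx <- which(key == gkey)
    sub <- x[, idx]
    sg <- subgroups(sub)
    ## stratify fold assignment on subgroup where possible
    fold <- integer(length(idx))
    for (s in unique(sg)) {
      w <- sample(which(sg == s))
      fold[w] <- rep_len(seq_len(k), length(w))
    }
    fracs <- numeric(0)
    for (f in seq_len(k)) {
      for (s in subgroups) {
        inS <- sg == s
        tr <- inS & fold != f
        te <- inS & fold == f
        if (!any(tr) || !any(te)) next
        vals <- t(featureMatrix(sub)[, tr | te, drop = FALSE])
        r <- .kwCore(vals, factor(ifelse(fold[tr | te] == f, "test",
                                         "train")))
        fracs <- c(fracs, mean(r$p > alpha))
      }
    }
    if (!length(fracs)) {
      ## no tested subgroup is represented on both sides of any fold
      skipped <- rbind(skipped,
                       data.frame(group = gkey, n = length(idx)))
      next
    }
    groupRows[[length(groupRows) + 1L]] <- data.frame(
      group = gkey, n = length(idx),
      pass_rate = mean(fracs), stringsAsFactors = FALSE)
  }
  if (!length(groupRows))
    .opncbStop("opncb_check_inapplicable",
               "no uniform group holds testable subgroup scans")
  groups <- do.call(rbind, groupRows)
  list(overall = mean(groups$pass_rate), groups = groups,
       skipped = skipped)
}
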