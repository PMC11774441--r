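## Optimized Permutation Nested ComBat: sequential harmonization over
## several acquisition parameters, in the permutation that leaves the
## most features acquisition-independent.

.modeScopes <- function(mode, table) {
  if (mode == "separate") intersect(SUBGROUP_LEVELS, unique(subgroups(table)))
  else "all"
}

#' Exclude scans that cannot be harmonized
#'
#' Applies the two exclusion rules needed before nested ComBat fitting:
#' training scans whose (parameter, instance) cell - evaluated within
#' each subgroup for separate mode - holds fewer than
#' \code{minBatchSize} scans are removed (reason \code{rare_instance}),
#' iterating until stable; then test scans carrying an instance absent
#' from the surviving training scans of their fitting scope are removed
#' (reason \code{unseen_instance}).
#'
#' @param train,test \linkS4class{RadiomicExperiment} tables sharing a
#'   schema; \code{test} may be \code{NULL}.
#' @param minBatchSize smallest admissible per-instance scan count.
#' @param mode harmonization mode the exclusion is computed for;
#'   \code{"separate"} counts cells within subgroups and is the
#'   strictest.
#' @return list with elements \code{train}, \code{test} (pruned tables)
#'   and \code{exclusionLog} (data.frame: scan_id, set, parameter,
#'   instance, reason).
#' @export
excludeUnharmonizable <- function(train, test = NULL, minBatchSize = 3L,
                                  mode = c("separate", "collective",
                                           "covariate")) {
  mode <- match.arg(mode)
  params <- acquisitionParameters(train)
  log <- list()
  scopes0 <- .modeScopes(mode, train)

  repeat {
    cd <- colData(train)
    drop <- rep(FALSE, ncol(train))
    for (p in params) {
      for (sc in scopes0) {
        inScope <- if (sc == "all") rep(TRUE, ncol(train))
                   else as.character(cd$subgroup) == sc
        if (!any(inScope)) next
        inst <- as.character(cd[[p]])[inScope]
        cnt <- table(inst)
        rare <- names(cnt)[cnt < minBatchSize]
        if (length(rare)) {
          hit <- inScope & as.character(cd[[p]]) %in% rare
          newHit <- which(hit & !drop)
          if (length(newHit)) {
            log[[length(log) + 1L]] <- data.frame(
              scan_id = as.character(cd$scan_id)[newHit], set = "train",
              parameter = p,
              instance = as.character(cd[[p]])[newHit],
              reason = "rare_instance", stringsAsFactors = FALSE)
            drop[newHit] <- TRUE
          }
        }
      }
    }
    if (!any(drop)) break
    train <- train[, !drop]
    if (ncol(train) == 0L)
      .opncbStop("opncb_trial_unusable",
                 "exclusion removed every training scan")
  }

  ## a fitting scope present initially must survive
  for (sc in scopes0) {
    left <- if (sc == "all") ncol(train)
            else sum(subgroups(train) == sc)
    if (left == 0L)
      .opncbStop("opncb_trial_unusable",
                 sprintf("exclusion emptied fitting scope '%s'", sc))
  }

  if (!is.null(test)) {
    cdTr <- colData(train)
    cdTe <- colData(test)
    drop <- rep(FALSE, ncol(test))
    for (p in params) {
      for (sc in .modeScopes(mode, test)) {
        teIn <- if (sc == "all") rep(TRUE, ncol(test))
                else as.character(cdTe$subgroup) == sc
        trIn <- if (sc == "all") rep(TRUE, ncol(train))
                else as.character(cdTr$subgroup) == sc
        seen <- unique(as.character(cdTr[[p]])[trIn])
        bad <- teIn & !(as.character(cdTe[[p]]) %in% seen)
        newHit <- which(bad & !drop)
        if (length(newHit)) {
          log[[length(log) + 1L]] <- data.frame(
            scan_id = as.character(cdTe$scan_id)[newHit], set = "test",
            parameter = p,
            instance = as.character(cdTe[[p]])[newHit],
            reason = "unseen_instance", stringsAsFactors = FALSE)
          drop[newHit] <- TRUE
        }
      }
    }
    test <- test[, !drop]
  }

  list(train = train, test = test,
       exclusionLog = if (length(log)) do.call(rbind, log) else
         data.frame(scan_id = character(), set = character(),
                    parameter = character(), instance = character(),
                    reason = character()))
}

## Fit a plan and keep the harmonized working table (internal; the
## exported fitPlan discards the table so that applyPlan remains the
## single transformation path).
.fitPlanCore <- function(train, mode, parameterOrder, alpha = 0.05,
                         minBatchSize = 3L,
                         exclusionLog = data.frame()) {
  dat <- featureMatrix(train)
  cd <- colData(train)
  sg <- as.character(cd$subgroup)
  models <- list()
  for (p in parameterOrder) {
    res <- tryCatch({
      if (mode == "separate") {
        for (s in intersect(SUBGROUP_LEVELS, unique(sg))) {
          idx <- which(sg == s)
          m <- .fitCombatCore(dat[, idx, drop = FALSE], cd[idx, ], p,
                              covariate = NULL,
                              minBatchSize = minBatchSize, scope = s)
          models[[paste(p, s, sep = "|")]] <- m
          dat[, idx] <- .applyCombatCore(m, dat[, idx, drop = FALSE],
                                         cd[idx, ])
        }
      } else {
        cov <- if (mode == "covariate") "subgroup" else NULL
        m <- .fitCombatCore(dat, cd, p, covariate = cov,
                            minBatchSize = minBatchSize, scope = "all")
        models[[p]] <- m
        dat <- .applyCombatCore(m, dat, cd)
      }
      NULL
    }, opncb_error = function(e) e)
    if (!is.null(res))
      .opncbStop(c("opncb_plan_error", class(res)[1L]),
                 sprintf("fitting '%s' (mode %s) failed: %s",
                         p, mode, conditionMessage(res)),
                 parameter = p, mode = mode, parent = res)
  }
  rep <- .independenceCore(dat, cd, acquisitionParameters(train),
                           alpha = alpha)
  plan <- new("HarmonizationPlan",
              mode = mode,
              parameterOrder = parameterOrder,
              models = models,
              exclusionLog = exclusionLog,
              alpha = alpha,
              score = length(independentFeatures(rep)),
              minBatchSize = as.integer(minBatchSize))
  list(plan = plan, harmonized = .withFeatures(train, dat), report = rep)
}

#' Fit a nested harmonization plan with a fixed parameter order
#'
#' Sequentially fits one ComBat model per acquisition parameter in the
#' given order - collective: one fit over all scans; covariate: one fit
#' with the subgroup as preserved covariate; separate: one fit per
#' subgroup on that subgroup's scans - replacing the working table with
#' its harmonized values before fitting the next parameter. The
#' returned plan's score is the number of acquisition-independent
#' features of the harmonized training table.
#'
#' @param train a \linkS4class{RadiomicExperiment} that already passed
#'   [excludeUnharmonizable()] for this mode.
#' @param mode \code{"collective"}, \code{"covariate"} or
#'   \code{"separate"}.
#' @param parameterOrder permutation of the schema parameters (default:
#'   schema order).
#' @param alpha significance threshold used to score the plan.
#' @param minBatchSize smallest admissible per-instance scan count.
#' @return A \linkS4class{HarmonizationPlan}.
#' @seealso [optimizePermutation()] for the order-optimizing variant,
#'   [applyPlan()] to transform tables.
#' @export
fitPlan <- function(train, mode = c("collective", "covariate", "separate"),
                    parameterOrder = acquisitionParameters(train),
                    alpha = 0.05, minBatchSize = 3L) {
  mode <- match.arg(mode)
  .assertThat(setequal(parameterOrder, acquisitionParameters(train)) &&
                !anyDuplicated(parameterOrder),
              "opncb_schema",
              "parameterOrder must be a permutation of the schema parameters")
  .fitPlanCore(train, mode, parameterOrder, alpha, minBatchSize)$plan
}

#' Optimized Permutation Nested ComBat
#'
#' Fits a nested plan for every permutation of the acquisition
#' parameters, scores each by the number of features the Kruskal-Wallis
#' gate declares acquisition-independent on the harmonized training
#' table, and returns the plan with the maximal score. Ties are broken
#' deterministically in favour of the earliest permutation in
#' lexicographic order of parameter names.
#'
#' @inheritParams fitPlan
#' @return The winning \linkS4class{HarmonizationPlan}.
#' @export
optimizePermutation <- function(train,
                                mode = c("collective", "covariate",
                                         "separate"),
                                alpha = 0.05, minBatchSize = 3L) {
  mode <- match.arg(mode)
  perms <- .permutations(acquisitionParameters(train))
  best <- NULL
  failures <- character()
  for (perm in perms) {
    res <- tryCatch(
      .fitPlanCore(train, mode, perm, alpha, minBatchSize),
      opncb_error = function(e) e)
    if (inherits(res, "condition")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    if (is.null(best) || res$plan@score > best$plan@score) best <- res
  }
  if (is.null(best))
    .opncbStop("opncb_trial_unusable",
               paste("every permutation failed to fit;",
                     failures[1L]))
  best$plan
}

#' Apply a harmonization plan
#'
#' Applies the plan's fitted models to \code{table} in the plan's
#' parameter order, without refitting. In separate mode every scan is
#' routed to the models of its own subgroup; a scan whose subgroup has
#' no fitted models raises an unseen-level error.
#'
#' @param plan a \linkS4class{HarmonizationPlan}.
#' @param table a \linkS4class{RadiomicExperiment} that passed the
#'   test-side exclusion rule.
#' @return The harmonized \linkS4class{RadiomicExperiment}.
#' @export
applyPlan <- function(plan, table) {
  dat <- featureMatrix(table)
  cd <- colData(table)
  sg <- as.character(cd$subgroup)
  for (p in plan@parameterOrder) {
    if (plan@mode == "separate") {
      for (s in unique(sg)) {
        key <- paste(p, s, sep = "|")
        if (is.null(plan@models[[key]]))
          .opncbStop("opncb_unseen_level",
                     sprintf("no '%s' model for subgroup '%s'", p, s),
                     parameter = p, levels = s)
        idx <- which(sg == s)
        dat[, idx] <- .applyCombatCore(plan@models[[key]],
                                       dat[, idx, drop = FALSE],
                                       cd[idx, ])
      }
    } else {
      dat <- .applyCombatCore(plan@models[[p]], dat, cd)
    }
  }
  .withFeatures(table, dat)
}

#' Accessors for HarmonizationPlan
#'
#' @param x a \linkS4class{HarmonizationPlan}.
#' @return \code{parameterOrder}: the fitted parameter permutation;
#'   \code{exclusionLog}: scans removed before fitting.
#' @name HarmonizationPlan-accessors
NULL

#' @rdname HarmonizationPlan-accessors
#' @export
setMethod("parameterOrder", "HarmonizationPlan",
          function(x) x@parameterOrder)

#' @rdname HarmonizationPlan-accessors
#' @export
setMethod("exclusionLog", "HarmonizationPlan",
          function(x) x@exclusionLog)

setMethod("show", "HarmonizationPlan", function(object) {
  cat(sprintf("HarmonizationPlan (%s mode)\n", object@mode))
  cat("  parameter order:", paste(object@parameterOrder, collapse = " -> "),
      "\n")
  cat(sprintf("  %d fitted model(s); score %d acquisition-independent features (alpha = %g)\n",
              length(object@models), object@score, object@alpha))
  if (nrow(object@exclusionLog))
    cat(sprintf("  %d scan(s) excluded before fitting\n",
                length(unique(object@exclusionLog$scan_id))))
})

#' Serialize harmonization plans to and from JSON
#'
#' The plan is stored as one JSON document embedding every fitted
#' ComBat model, sufficient to harmonize unseen scans later.
#'
#' @param plan a \linkS4class{HarmonizationPlan}.
#' @param path JSON file path.
#' @return \code{readPlan} returns the restored plan; \code{writePlan}
#'   returns \code{path} invisibly.
#' @export
writePlan <- function(plan, path) {
  jsonlite::write_json(list(
    mode = plan@mode,
    parameterOrder = plan@parameterOrder,
    alpha = plan@alpha,
    score = plan@score,
    minBatchSize = plan@minBatchSize,
    exclusionLog = plan@exclusionLog,
    models = lapply(plan@models, .modelToList)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePlan
#' @export
readPlan <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- as.data.frame(l$exclusionLog)
  new("HarmonizationPlan",
      mode = l$mode,
      parameterOrder = l$parameterOrder,
      models = lapply(l$models, .modelFromList),
      exclusionLog = ex,
      alpha = l$alpha,
      score = l$score,
      minBatchSize = as.integer(l$minBatchSize))
}
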