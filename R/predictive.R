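## LASSO feature selection over acquisition-independent features,
## followed by a soft-margin linear SVM malignancy classifier.

#' LASSO feature selection
#'
#' Z-scores each feature on the training data and fits an L1-penalized
#' least-squares regression of the 0/1 malignancy label, returning the
#' features with nonzero coefficients in their original column order.
#' The penalty parameter follows the \code{(1/2n) RSS + alpha * ||b||_1}
#' parameterization (glmnet's \code{lambda}), so \code{alpha = 0.05}
#' means the same thing for every z-scored feature.
#'
#' @param features numeric matrix, scans in rows, candidate features in
#'   (named) columns; typically restricted to the
#'   acquisition-independent set.
#' @param labels binary 0/1 malignancy labels.
#' @param alpha L1 penalty weight (default 0.05).
#' @return Character vector of selected feature names (possibly empty).
#' @export
lassoSelect <- function(features, labels, alpha = 0.05) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  .assertThat(all(is.finite(features)), "opncb_data",
              "features must be finite")
  .assertThat(nrow(features) == length(labels) && nrow(features) >= 2L,
              "opncb_data", "need one label per scan and >= 2 scans")
  if (length(unique(labels)) < 2L)
    .opncbStop("opncb_selection_inapplicable",
               "LASSO selection needs both classes in the training labels")
  if (ncol(features) == 0L) return(character())
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  usable <- which(scl > 0)
  if (!length(usable)) return(character())
  z <- sweep(sweep(features[, usable, drop = FALSE], 2L, ctr[usable]),
             2L, scl[usable], "/")
  ## glmnet needs >= 2 columns; a constant dummy never gets a nonzero
  ## coefficient
  pad <- ncol(z) < 2L
  if (pad) z <- cbind(z, `.dummy.` = 0)
  fit <- glmnet::glmnet(z, as.numeric(labels), family = "gaussian",
                        lambda = alpha, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-10)
  beta <- drop(as.matrix(fit$beta))
  sel <- names(beta)[beta != 0]
  sel <- setdiff(sel, ".dummy.")
  colnames(features)[colnames(features) %in% sel]
}

#' Train the linear SVM malignancy classifier
#'
#' Fits a soft-margin linear support vector machine (hinge loss, L2
#' penalty, cost \code{C}) on the training scans, using features
#' z-scored with training statistics. When called with zero features
#' (empty LASSO selection) the returned model is the degenerate
#' fallback that predicts the benign class with a constant negative
#' score.
#'
#' @param features numeric matrix, scans in rows, restricted to the
#'   selected features (0 columns allowed).
#' @param labels binary 0/1 malignancy labels.
#' @param C soft-margin cost (default 1).
#' @return A \linkS4class{PredictiveModel}; positive decision scores
#'   predict malignancy.
#' @export
trainClassifier <- function(features, labels, C = 1) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (ncol(features) == 0L) {
    return(new("PredictiveModel", selectedFeatures = character(),
               center = numeric(), scale = numeric(),
               weights = numeric(), bias = -1,
               fallback = TRUE))
  }
  .assertThat(all(is.finite(features)), "opncb_data",
              "features must be finite")
  .assertThat(length(unique(labels)) == 2L, "opncb_data",
              "SVM training needs both classes")
  .assertThat(!is.null(colnames(features)), "opncb_schema",
              "feature columns must be named")
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  y <- factor(labels, levels = c(0L, 1L))
  fit <- e1071::svm(z, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## e1071's decision values are oriented towards its first stored
  ## class label; flip so that positive always means malignant (1)
  if (fit$labels[1L] != 2L) { # internal label of factor level "1"
    w <- -w
    b <- -b
  }
  new("PredictiveModel",
      selectedFeatures = colnames(features),
      center = ctr, scale = scl,
      weights = stats::setNames(w, colnames(features)),
      bias = b, fallback = FALSE)
}

#' Score scans with a trained classifier
#'
#' Computes signed distances to the fitted hyperplane (on the training
#' standardization) and the implied class labels; scores greater than
#' zero predict malignancy. Fallback models return a constant negative
#' score and all-benign labels.
#'
#' @param model a \linkS4class{PredictiveModel}.
#' @param features numeric matrix containing (at least) every selected
#'   feature column.
#' @return list with \code{scores} and binary \code{labels}.
#' @export
predictScores <- function(model, features) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (model@fallback) {
    return(list(scores = rep(model@bias, n), labels = rep(0L, n)))
  }
  miss <- setdiff(model@selectedFeatures, colnames(features))
  if (length(miss))
    .opncbStop("opncb_schema",
               sprintf("missing selected feature column(s): %s",
                       paste(miss, collapse = ", ")))
  z <- sweep(sweep(features[, model@selectedFeatures, drop = FALSE],
                   2L, model@center), 2L, model@scale, "/")
  s <- drop(z %*% model@weights) + model@bias
  list(scores = s, labels = as.integer(s > 0))
}

#' @rdname PredictiveModel-accessors
#' @param x a \linkS4class{PredictiveModel}.
#' @export
setMethod("selectedFeatures", "PredictiveModel",
          function(x) x@selectedFeatures)

setMethod("show", "PredictiveModel", function(object) {
  if (object@fallback) {
    cat("PredictiveModel: degenerate fallback (constant benign prediction)\n")
  } else {
    cat(sprintf("PredictiveModel: linear SVM on %d feature(s)\n",
                length(object@selectedFeatures)))
    cat("  features:", paste(object@selectedFeatures, collapse = ", "),
        "\n")
  }
})

#' Serialize predictive models to and from JSON
#'
#' @param model a \linkS4class{PredictiveModel}.
#' @param path JSON file path.
#' @return \code{readPredictiveModel} returns the restored model;
#'   \code{writePredictiveModel} returns \code{path} invisibly.
#' @export
writePredictiveModel <- function(model, path) {
  jsonlite::write_json(list(
    selectedFeatures = model@selectedFeatures,
    center = unname(model@center), scale = unname(model@scale),
    weights = unname(model@weights), bias = model@bias,
    fallback = model@fallback
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePredictiveModel
#' @export
readPredictiveModel <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- as.character(l$selectedFeatures %||% character())
  new("PredictiveModel",
      selectedFeatures = sel,
      center = stats::setNames(as.numeric(l$center), sel),
      scale = stats::setNames(as.numeric(l$scale), sel),
      weights = stats::setNames(as.numeric(l$weights), sel),
      bias = l$bias, fallback = l$fallback)
}
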