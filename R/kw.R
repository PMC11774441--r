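## Kruskal-Wallis acquisition-dependence testing.
##
## The gate evaluates thousands of tests per permutation search, so the
## statistic is computed in a batched form over a whole feature matrix
## at a fixed grouping (midranks, the standard tie correction
## 1 - sum(t^3 - t)/(N^3 - N), chi-square upper tail on k - 1 df).
## Equality with stats::kruskal.test is asserted in the test suite.

## values: N x F matrix (scans in rows), g: factor of length N with >= 2
## non-empty levels. Returns list of per-column H, p, df.
.kwCore <- function(values, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  N <- nrow(values)
  R <- apply(values, 2L, rank)             # midranks
  if (is.null(dim(R))) R <- matrix(R, nrow = N)
  S <- rowsum(R, g)                        # k x F rank sums
  n <- tabulate(g)
  H0 <- 12 / (N * (N + 1)) * colSums(S^2 / n) - 3 * (N + 1)
  tieSum <- vapply(seq_len(ncol(values)), function(j) {
    t <- rle(sort.int(values[, j]))$lengths
    sum(t^3 - t)
  }, numeric(1))
  C <- 1 - tieSum / (N^3 - N)
  H <- ifelse(C > 0, H0 / C, 0)            # all-tied column: H = 0, p = 1
  p <- ifelse(C > 0, stats::pchisq(H, k - 1, lower.tail = FALSE), 1)
  list(H = H, p = p, df = k - 1L)
}

#' Kruskal-Wallis rank test
#'
#' Tests whether the groups of \code{values} share one distribution,
#' using midranks with the standard tie correction and the chi-square
#' approximation on (number of groups - 1) degrees of freedom. When all
#' values are identical the statistic is 0 and p = 1. Agrees with
#' [stats::kruskal.test()] to machine precision.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length; empty groups are
#'   dropped.
#' @return list with \code{statistic} (H), \code{p.value} and \code{df}.
#' @examples
#' kruskalWallisTest(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskalWallisTest <- function(values, groups) {
  .assertThat(length(values) == length(groups), "opncb_schema",
              "values and groups must have the same length")
  .assertThat(all(is.finite(values)), "opncb_schema",
              "values must be finite")
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L)
    .opncbStop("opncb_test_inapplicable",
               "Kruskal-Wallis needs at least 2 non-empty groups")
  r <- .kwCore(matrix(values, ncol = 1L), g)
  list(statistic = unname(r$H), p.value = unname(r$p), df = r$df)
}

#' Acquisition-independence report
#'
#' Runs the Kruskal-Wallis test for every (feature, acquisition
#' parameter, subgroup) cell, grouping a subgroup's scans by the
#' instances of the parameter, and applies the either-subgroup rule: a
#' feature is acquisition-independent iff no test over any parameter in
#' any tested subgroup returns p <= alpha. Cells where a subgroup holds
#' fewer than two instances of a parameter cannot exhibit dependence;
#' they are skipped, logged, and counted as passes.
#'
#' @param x a \linkS4class{RadiomicExperiment} (typically a harmonized
#'   training table).
#' @param parameters acquisition parameters to test (default: all).
#' @param subgroups subgroups tested (default benign and malignant; the
#'   screening subgroup mixes unknown biology and is not gated on).
#' @param alpha significance threshold (default 0.05).
#' @return An \linkS4class{IndependenceReport}.
#' @examples
#' x <- simulateCohort(cohortConfig("none", seed = 2))
#' rep <- independenceReport(x)
#' length(independentFeatures(rep))
#' @export
independenceReport <- function(x, parameters = acquisitionParameters(x),
                               subgroups = c("benign", "malignant"),
                               alpha = 0.05) {
  .independenceCore(featureMatrix(x), colData(x), parameters, subgroups,
                    alpha)
}

.independenceCore <- function(dat, cd, parameters,
                              subgroups = c("benign", "malignant"),
                              alpha = 0.05) {
  feats <- rownames(dat)
  rows <- list()
  skipped <- list()
  for (sg in subgroups) {
    idx <- which(as.character(cd$subgroup) == sg)
    if (!length(idx)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(parameter = NA_character_, subgroup = sg,
                   reason = "empty_subgroup")
      next
    }
    vals <- t(dat[, idx, drop = FALSE]) # scans x features
    for (p in parameters) {
      g <- droplevels(factor(as.character(cd[[p]][idx])))
      if (nlevels(g) < 2L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(parameter = p, subgroup = sg,
                     reason = "single_instance")
        next
      }
      r <- .kwCore(vals, g)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feats, parameter = p, subgroup = sg,
        H = r$H, p = r$p, flagged = r$p <= alpha,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  pv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), parameter = character(),
               subgroup = character(), H = numeric(), p = numeric(),
               flagged = logical())
  dep <- unique(pv$feature[pv$flagged])
  fc <- matrix(0L, nrow = length(parameters), ncol = length(subgroups),
               dimnames = list(parameters, subgroups))
  if (nrow(pv)) {
    agg <- stats::aggregate(flagged ~ parameter + subgroup, pv, sum)
    fc[cbind(agg$parameter, agg$subgroup)] <- as.integer(agg$flagged)
  }
  new("IndependenceReport",
      pvalues = pv,
      alpha = alpha,
      independentFeatures = setdiff(feats, dep),
      failureCounts = fc,
      skipped = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(parameter = character(), subgroup = character(),
                   reason = character()))
}

#' Accessors for IndependenceReport
#'
#' @param x an \linkS4class{IndependenceReport}.
#' @return \code{independentFeatures}: names of features passing every
#'   test; \code{failureCounts}: parameters x subgroups matrix of
#'   flagged-feature counts.
#' @name IndependenceReport-accessors
NULL

#' @rdname IndependenceReport-accessors
#' @export
setMethod("independentFeatures", "IndependenceReport",
          function(x) x@independentFeatures)

#' @rdname IndependenceReport-accessors
#' @export
setMethod("failureCounts", "IndependenceReport",
          function(x) x@failureCounts)

setMethod("show", "IndependenceReport", function(object) {
  nf <- length(unique(object@pvalues$feature))
  cat(sprintf("IndependenceReport: %d/%d features acquisition-independent at alpha = %g\n",
              length(object@independentFeatures), nf, object@alpha))
  cat("  flagged features per (parameter, subgroup):\n")
  print(object@failureCounts)
  if (nrow(object@skipped))
    cat(sprintf("  %d scope(s) skipped (untestable)\n", nrow(object@skipped)))
})

#' Write an independence report
#'
#' Writes the full long-format table (feature, parameter, subgroup, H,
#' p, flagged) as CSV, or the whole report (p-values, threshold,
#' independent set, failure counts, skipped scopes) as JSON.
#'
#' @param report an \linkS4class{IndependenceReport}.
#' @param path output path; format chosen by extension (.csv or .json).
#' @return \code{path}, invisibly.
#' @export
writeIndependenceReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      alpha = report@alpha,
      pvalues = report@pvalues,
      independentFeatures = report@independentFeatures,
      failureCounts = as.data.frame(as.table(report@failureCounts)),
      skipped = report@skipped
    ), path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(report@pvalues, path, row.names = FALSE)
  }
  invisible(path)
}
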