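#' Construct a RadiomicExperiment
#'
#' Bundles a features-by-scans matrix with per-scan metadata into the
#' container used throughout the package.
#'
#' @param features numeric matrix, features in rows (rownames = feature
#'   names), scans in columns.
#' @param scanInfo data.frame or DataFrame with one row per scan and at
#'   least the columns \code{scan_id}, \code{patient_id},
#'   \code{nodule_id}, \code{subgroup}, \code{malignancy_label}, plus one
#'   column per acquisition parameter.
#' @param acquisitionParameters character vector naming the
#'   acquisition-parameter columns of \code{scanInfo}, in schema order.
#' @return A \linkS4class{RadiomicExperiment}.
#' @examples
#' cfg <- cohortConfig("none", seed = 1, nFeatures = 5,
#'                     nScans = c(benign = 20, malignant = 20, LCS = 20),
#'                     nNodules = c(benign = 10, malignant = 10, LCS = 10),
#'                     nPatients = c(benign = 5, malignant = 5, LCS = 5))
#' x <- simulateCohort(cfg)
#' x2 <- RadiomicExperiment(featureMatrix(x),
#'                          as.data.frame(SummarizedExperiment::colData(x)),
#'                          acquisitionParameters(x))
#' @export
RadiomicExperiment <- function(features, scanInfo, acquisitionParameters) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("feat%03d", seq_len(nrow(features)))
  cd <- S4Vectors::DataFrame(scanInfo, check.names = FALSE)
  cd$subgroup <- as.character(cd$subgroup)
  cd$malignancy_label <- as.integer(cd$malignancy_label)
  se <- SummarizedExperiment(
    assays = list(features = features),
    colData = cd,
    metadata = list(acquisitionParameters = as.character(acquisitionParameters))
  )
  colnames(se) <- as.character(cd$scan_id)
  new("RadiomicExperiment", se)
}

#' Accessors for RadiomicExperiment
#'
#' @param x a \linkS4class{RadiomicExperiment}.
#' @return \code{featureMatrix}: the features-by-scans matrix;
#'   \code{acquisitionParameters}: parameter column names;
#'   \code{acquisitionSchema}: list with \code{parameters} and observed
#'   \code{levels}; \code{subgroups}, \code{malignancyLabels},
#'   \code{scanIds}: per-scan vectors.
#' @name RadiomicExperiment-accessors
NULL

#' @rdname RadiomicExperiment-accessors
#' @export
setMethod("featureMatrix", "RadiomicExperiment",
          function(x) assay(x, "features"))

#' @rdname RadiomicExperiment-accessors
#' @export
setMethod("acquisitionParameters", "RadiomicExperiment",
          function(x) metadata(x)$acquisitionParameters)

#' @rdname RadiomicExperiment-accessors
#' @export
setMethod("acquisitionSchema", "RadiomicExperiment", function(x) {
  ap <- acquisitionParameters(x)
  lv <- lapply(ap, function(p) sort(unique(as.character(colData(x)[[p]]))))
  names(lv) <- ap
  list(parameters = ap, levels = lv)
})

#' @rdname RadiomicExperiment-accessors
#' @export
setMethod("subgroups", "RadiomicExperiment",
          function(x) as.character(colData(x)$subgroup))

#' @rdname RadiomicExperiment-accessors
#' @export
setMethod("malignancyLabels", "RadiomicExperiment",
          function(x) as.integer(colData(x)$malignancy_label))

#' @rdname RadiomicExperiment-accessors
#' @export
setMethod("scanIds", "RadiomicExperiment",
          function(x) as.character(colData(x)$scan_id))

setMethod("show", "RadiomicExperiment", function(object) {
  sg <- table(factor(subgroups(object), levels = SUBGROUP_LEVELS))
  cat(sprintf("RadiomicExperiment: %d features x %d scans\n",
              nrow(object), ncol(object)))
  cat(sprintf("  subgroups: benign %d | malignant %d | LCS %d\n",
              sg[["benign"]], sg[["malignant"]], sg[["LCS"]]))
  cat(sprintf("  nodules %d, patients %d\n",
              length(unique(colData(object)$nodule_id)),
              length(unique(colData(object)$patient_id))))
  cat("  acquisition parameters:",
      paste(acquisitionParameters(object), collapse = ", "), "\n")
})

## replace the feature assay, keeping everything else
.withFeatures <- function(x, m) {
  dimnames(m) <- dimnames(assay(x, "features"))
  assay(x, "features") <- m
  x
}

#' Read and write feature-table CSVs
#'
#' The CSV dialect has a header row and the columns \code{scan_id},
#' \code{patient_id}, \code{nodule_id}, \code{subgroup},
#' \code{malignancy_label}, one column per acquisition parameter, then
#' one numeric column per feature.
#'
#' @param path file path.
#' @param acquisitionParameters names of the acquisition-parameter
#'   columns; when \code{NULL}, every non-numeric column after the five
#'   identifier columns is taken as a parameter.
#' @param x a \linkS4class{RadiomicExperiment}.
#' @return \code{readFeatureTable} returns a
#'   \linkS4class{RadiomicExperiment}; \code{writeFeatureTable} returns
#'   \code{path} invisibly.
#' @export
readFeatureTable <- function(path, acquisitionParameters = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("scan_id", "patient_id", "nodule_id", "subgroup",
             "malignancy_label")
  .assertThat(all(fixed %in% colnames(df)), "opncb_schema",
              "feature-table CSV is missing identifier columns")
  rest <- setdiff(colnames(df), fixed)
  if (is.null(acquisitionParameters)) {
    acquisitionParameters <- rest[!vapply(df[rest], is.numeric, logical(1))]
  }
  featCols <- setdiff(rest, acquisitionParameters)
  m <- t(as.matrix(df[, featCols, drop = FALSE]))
  colnames(m) <- df$scan_id
  RadiomicExperiment(m, df[, c(fixed, acquisitionParameters), drop = FALSE],
                     acquisitionParameters)
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(x, path) {
  ap <- acquisitionParameters(x)
  cd <- as.data.frame(colData(x))
  out <- cbind(
    cd[, c("scan_id", "patient_id", "nodule_id", "subgroup",
           "malignancy_label")],
    cd[, ap, drop = FALSE],
    as.data.frame(t(featureMatrix(x)))
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
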