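# Shared fixture builders. Everything is generated in code at test time.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# A minimal hand-built table: nScans scans, one two-level parameter,
# optional extra metadata overrides.
makeTinyTable <- function(values, batch, subgroup = NULL, label = NULL,
                          param = "CE") {
  n <- length(batch)
  if (is.null(subgroup)) subgroup <- rep("malignant", n)
  if (is.null(label))
    label <- ifelse(subgroup == "malignant", 1L, 0L)
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  rownames(m) <- sprintf("feat%03d", seq_len(nrow(m)))
  info <- data.frame(
    scan_id = sprintf("S%04d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    nodule_id = sprintf("N%03d", seq_len(n)),
    subgroup = subgroup, malignancy_label = label,
    stringsAsFactors = FALSE)
  info[[param]] <- as.character(batch)
  RadiomicExperiment(m, info, param)
}

# Small cohort configuration for fast pipeline tests.
smallCohortConfig <- function(scenario = "shared", seed = 1,
                              nFeatures = 20, scale = 1) {
  cohortConfig(scenario, seed = seed, nFeatures = nFeatures,
               nScans = round(scale * c(benign = 58, malignant = 186,
                                        LCS = 323)),
               nNodules = round(scale * c(benign = 37, malignant = 57,
                                          LCS = 211)),
               nPatients = round(scale * c(benign = 27, malignant = 57,
                                           LCS = 109)))
}

# Two-parameter schema config used for the brute-force permutation
# checks; frequencies and effects are randomized per seed.
twoParamConfig <- function(seed, nFeatures = 15) {
  schema <- list(parameters = c("A", "B"),
                 levels = list(A = c("a1", "a2"), B = c("b1", "b2")))
  set.seed(seed)
  G <- nFeatures
  mkEff <- function() {
    a <- array(0, dim = c(2, 3, G))
    # random feature-wise shifts on the second instance, shared scale
    a[2, , ] <- rep(stats::runif(G, -2, 2), each = 3)
    a
  }
  mkScl <- function() {
    a <- array(1, dim = c(2, 3, G))
    a[2, , ] <- rep(stats::runif(G, 0.7, 1.6), each = 3)
    a
  }
  simulationConfig(
    nScans = c(benign = 60, malignant = 80, LCS = 0),
    nNodules = c(benign = 30, malignant = 40, LCS = 0),
    nPatients = c(benign = 20, malignant = 30, LCS = 0),
    schema = schema,
    instanceFrequencies = list(A = c(0.5, 0.5), B = c(0.6, 0.4)),
    nFeatures = G, malignancyEffects = 0.5,
    batchLocation = list(A = mkEff(), B = mkEff()),
    batchScale = list(A = mkScl(), B = mkScl()),
    seed = seed)
}

# Exact two-group Kruskal-Wallis p-values by full enumeration of all
# group assignments (oracle for small N; the observed statistic comes
# from stats::kruskal.test, the permutation values from the closed-form
# rank-sum identity). Returns P(H >= obs) and the mid-p variant.
exactKWp <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2)
  N <- length(values)
  n1 <- sum(groups == levels(groups)[1])
  r <- rank(values)
  obs <- suppressWarnings(kruskal.test(values, groups)$statistic)
  ties <- rle(sort(values))$lengths
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  Hof <- function(R1) {
    R2 <- N * (N + 1) / 2 - R1
    (12 / (N * (N + 1)) * (R1^2 / n1 + R2^2 / (N - n1)) - 3 * (N + 1)) / C
  }
  R1s <- colSums(matrix(r[utils::combn(N, n1)], nrow = n1))
  H <- Hof(R1s)
  c(ge = mean(H >= obs - 1e-9),
    mid = mean(H > obs + 1e-9) + 0.5 * mean(abs(H - obs) <= 1e-9))
}

# Monte-Carlo permutation mid-p for two groups at sizes where full
# enumeration is infeasible.
mcKWp <- function(values, groups, B = 20000) {
  groups <- droplevels(as.factor(groups))
  N <- length(values)
  n1 <- sum(groups == levels(groups)[1])
  r <- rank(values)
  obs <- suppressWarnings(kruskal.test(values, groups)$statistic)
  ties <- rle(sort(values))$lengths
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  Hof <- function(R1) {
    R2 <- N * (N + 1) / 2 - R1
    (12 / (N * (N + 1)) * (R1^2 / n1 + R2^2 / (N - n1)) - 3 * (N + 1)) / C
  }
  H <- Hof(replicate(B, sum(sample(r, n1))))
  mean(H > obs + 1e-9) + 0.5 * mean(abs(H - obs) <= 1e-9)
}
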