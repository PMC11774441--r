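test_that("default cohort reproduces the emulated cohort structure", {
  x <- simulateCohort(cohortConfig("divergent", seed = 3))
  expect_equal(ncol(x), 567)
  sg <- table(subgroups(x))
  expect_equal(unname(sg[["LCS"]]), 323)
  expect_equal(unname(sg[["benign"]]), 58)
  expect_equal(unname(sg[["malignant"]]), 186)
  cd <- colData(x)
  expect_equal(length(unique(cd$nodule_id)), 305)
  expect_equal(length(unique(cd$patient_id)), 193)
  ## benign/malignant label invariants
  expect_true(all(malignancyLabels(x)[subgroups(x) == "benign"] == 0L))
  expect_true(all(malignancyLabels(x)[subgroups(x) == "malignant"] == 1L))
  ## screening nodules flagged at the configured rate
  lcsNod <- unique(cd$nodule_id[cd$subgroup == "LCS"])
  flagged <- unique(cd$nodule_id[cd$subgroup == "LCS" &
                                   cd$malignancy_label == 1L])
  expect_equal(length(flagged), round(0.076 * length(lcsNod)))
})

test_that("the generator is bit-reproducible for a fixed seed", {
  a <- simulateCohort(cohortConfig("shared", seed = 9))
  b <- simulateCohort(cohortConfig("shared", seed = 9))
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  c <- simulateCohort(cohortConfig("shared", seed = 10))
  expect_false(identical(featureMatrix(a), featureMatrix(c)))
})

test_that("with no biology and no batch effects the benign/malignant KW test has nominal size", {
  cfg <- simulationConfig(
    nScans = c(benign = 1000, malignant = 1000, LCS = 0),
    nNodules = c(benign = 500, malignant = 500, LCS = 0),
    nPatients = c(benign = 300, malignant = 300, LCS = 0),
    schema = list(parameters = "CE", levels = list(CE = c("no", "yes"))),
    instanceFrequencies = list(CE = c(0.5, 0.5)),
    nFeatures = 107, malignancyEffects = 0, seed = 21)
  x <- simulateCohort(cfg)
  g <- factor(subgroups(x))
  ## oracle: stats::kruskal.test per feature, independent of the package path
  p <- apply(featureMatrix(x), 1L, function(v) kruskal.test(v, g)$p.value)
  expect_gt(mean(p <= 0.05), 0.03)
  expect_lt(mean(p <= 0.05), 0.07)
})

test_that("zero location and unit scale effects leave the table unchanged", {
  cfg <- smallCohortConfig("none", seed = 4)
  x <- simulateCohort(cfg)
  y <- injectBatchEffects(x, cfg)
  expect_identical(featureMatrix(x), featureMatrix(y))
})

test_that("injected location shifts match their configured magnitude", {
  ## 2-sd shift on (CE = yes, malignant) for every feature
  G <- 3L
  loc <- array(0, dim = c(2, 3, G))
  loc[2, 2, ] <- 2  # instance "yes", subgroup malignant
  cfg <- simulationConfig(
    nScans = c(benign = 0, malignant = 10000, LCS = 0),
    nNodules = c(benign = 0, malignant = 5000, LCS = 0),
    nPatients = c(benign = 0, malignant = 2000, LCS = 0),
    schema = list(parameters = "CE", levels = list(CE = c("no", "yes"))),
    instanceFrequencies = list(CE = c(0.5, 0.5)),
    nFeatures = G, malignancyEffects = 0,
    batchLocation = list(CE = loc),
    effectSharing = "subgroup_specific", seed = 7)
  x <- simulateCohort(cfg)
  ce <- colData(x)$CE
  d <- rowMeans(featureMatrix(x)[, ce == "yes"]) -
    rowMeans(featureMatrix(x)[, ce == "no"])
  expect_true(all(abs(d - 2) < 0.1))
})

test_that("injected scale effects match their configured variance ratio", {
  G <- 3L
  scl <- array(1, dim = c(2, 3, G))
  scl[2, , ] <- 2  # doubles the noise scale for instance "yes"
  cfg <- simulationConfig(
    nScans = c(benign = 0, malignant = 10000, LCS = 0),
    nNodules = c(benign = 0, malignant = 5000, LCS = 0),
    nPatients = c(benign = 0, malignant = 2000, LCS = 0),
    schema = list(parameters = "CE", levels = list(CE = c("no", "yes"))),
    instanceFrequencies = list(CE = c(0.5, 0.5)),
    nFeatures = G, malignancyEffects = 0,
    batchScale = list(CE = scl), seed = 8)
  x <- simulateCohort(cfg)
  ce <- colData(x)$CE
  vr <- apply(featureMatrix(x)[, ce == "yes"], 1L, var) /
    apply(featureMatrix(x)[, ce == "no"], 1L, var)
  expect_true(all(abs(vr - 4) < 0.4))
})

test_that("acquisition frequencies follow the configured subgroup mix", {
  x <- simulateCohort(cohortConfig("shared", seed = 6))
  ce <- colData(x)$CE
  for (sg in c("benign", "malignant", "LCS")) {
    idx <- subgroups(x) == sg
    want <- c(benign = 0.25, malignant = 0.85, LCS = 0.10)[[sg]]
    got <- mean(ce[idx] == "yes")
    halfCI <- 1.96 * sqrt(want * (1 - want) / sum(idx))
    expect_lt(abs(got - want), halfCI + 0.02)
  }
})

test_that("shared effects act identically on benign and malignant scans", {
  ## under shared effects the CE-by-subgroup interaction is null:
  ## a per-feature linear-model interaction test should reject at ~1%
  cfg <- smallCohortConfig("shared", seed = 13, nFeatures = 60)
  x <- simulateCohort(cfg)
  keep <- subgroups(x) %in% c("benign", "malignant")
  ce <- factor(colData(x)$CE[keep])
  sg <- factor(subgroups(x)[keep])
  pInt <- apply(featureMatrix(x)[, keep], 1L, function(v) {
    summary(lm(v ~ ce * sg))$coefficients["ceyes:sgmalignant", 4]
  })
  expect_gte(mean(pInt > 0.01), 0.95)
})

test_that("feature-table CSV round-trips through read/write", {
  x <- simulateCohort(smallCohortConfig("shared", seed = 2, nFeatures = 6))
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(x, f)
  y <- readFeatureTable(f)
  expect_equal(featureMatrix(y), featureMatrix(x), tolerance = 1e-12)
  expect_identical(acquisitionParameters(y), acquisitionParameters(x))
  expect_identical(subgroups(y), subgroups(x))
  unlink(f)
})

test_that("configurations round-trip through YAML and JSON", {
  cfg <- smallCohortConfig("divergent", seed = 19, nFeatures = 7)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writeSimulationConfig(cfg, f)
    cfg2 <- readSimulationConfig(f)
    expect_equal(cfg2@batchLocation, cfg@batchLocation,
                 ignore_attr = TRUE)
    ## decimal text interchange may drop the last bit of a double
    expect_equal(featureMatrix(simulateCohort(cfg2)),
                 featureMatrix(simulateCohort(cfg)), tolerance = 1e-12)
    unlink(f)
  }
})

test_that("invalid configurations are rejected", {
  schema <- list(parameters = "CE", levels = list(CE = c("no", "yes")))
  expect_error(simulationConfig(
    nScans = c(benign = 10, malignant = 10, LCS = 0),
    nNodules = c(benign = 5, malignant = 5, LCS = 0),
    nPatients = c(benign = 2, malignant = 2, LCS = 0),
    schema = schema, instanceFrequencies = list(CE = c(0.5, 0.6)),
    nFeatures = 3), "sum to 1")
  expect_error(simulationConfig(
    nScans = c(benign = 10, malignant = 10, LCS = 0),
    nNodules = c(benign = 5, malignant = 5, LCS = 0),
    nPatients = c(benign = 2, malignant = 2, LCS = 0),
    schema = schema, instanceFrequencies = list(CE = c(0.5, 0.5)),
    nFeatures = 0))
  ## single-level parameter
  expect_error(simulationConfig(
    nScans = c(benign = 10, malignant = 10, LCS = 0),
    nNodules = c(benign = 5, malignant = 5, LCS = 0),
    nPatients = c(benign = 2, malignant = 2, LCS = 0),
    schema = list(parameters = "CE", levels = list(CE = "no")),
    instanceFrequencies = list(CE = 1), nFeatures = 3),
    ">= 2 instance labels")
})
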