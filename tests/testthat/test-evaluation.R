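test_that("repeated stratified splits partition the cohort", {
  x <- simulateCohort(smallCohortConfig("shared", seed = 41,
                                        nFeatures = 4))
  sp <- makeSplits(x, k = 5, repeats = 10, seed = 9)
  expect_length(sp, 50)
  for (r in 1:10) {
    folds <- Filter(function(s) s$repeat_ == r, sp)
    tests <- lapply(folds, `[[`, "test")
    expect_equal(sort(unlist(tests)), seq_len(ncol(x))) # disjoint cover
    for (s in folds)
      expect_equal(sort(c(s$train, s$test)), seq_len(ncol(x)))
  }
  ## determinism
  sp2 <- makeSplits(x, k = 5, repeats = 10, seed = 9)
  expect_identical(sp, sp2)
  expect_false(identical(sp, makeSplits(x, 5, 10, seed = 10)))
})

test_that("splits are stratified to within one scan per class", {
  info <- data.frame(
    scan_id = sprintf("S%03d", 1:100), patient_id = sprintf("P%03d", 1:100),
    nodule_id = sprintf("N%03d", 1:100),
    subgroup = rep(c("benign", "malignant"), 50),
    malignancy_label = rep(c(0L, 1L), 50), CE = rep(c("no", "yes"), 50))
  x <- RadiomicExperiment(matrix(rnorm(100), 1, 100,
                                 dimnames = list("f1", info$scan_id)),
                          info, "CE")
  sp <- makeSplits(x, k = 5, repeats = 1, seed = 3)
  for (s in sp) {
    expect_equal(length(s$test), 20)
    lab <- malignancyLabels(x)[s$test]
    expect_lte(abs(sum(lab == 1) - 10), 1)
  }
  ## a stratum smaller than k is an error
  info$subgroup[1] <- "LCS"
  y <- RadiomicExperiment(matrix(rnorm(100), 1, 100,
                                 dimnames = list("f1", info$scan_id)),
                          info, "CE")
  expect_error(makeSplits(y, k = 5), class = "opncb_stratification")
})

test_that("metrics match their definitions on fixtures", {
  ## AUC by concordant pairs: 3 of 4
  m <- computeMetrics(c(0.9, 0.3, 0.6, 0.2), c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(m$auc, 0.75)
  ## perfect predictor
  m <- computeMetrics(c(2, 3, -1, -2), c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$auc, 1)
  ## all-benign predictor
  m <- computeMetrics(rep(-1, 6), rep(0, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 0.5)
  ## one-class subset: undefined metrics are NA, defined ones reported
  m <- computeMetrics(c(1, -1), c(1, 0), c(1, 1))
  expect_equal(m$sensitivity, 0.5)
  expect_true(is.na(m$specificity))
  expect_true(is.na(m$auc))
  ## empty subset
  m <- computeMetrics(numeric(), integer(), integer())
  expect_true(all(is.na(unlist(m))))
})

test_that("identical score vectors give a DeLong p of 1", {
  set.seed(701)
  s <- rnorm(30)
  y <- rbinom(30, 1, 0.5)
  r <- delongTest(s, s, y)
  expect_equal(r$aucA, r$aucB)
  expect_equal(r$p.value, 1)
})

test_that("the DeLong p-value matches the reference implementation", {
  set.seed(702)
  for (i in 1:10) {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    a <- rnorm(n) + y
    b <- rnorm(n) + 0.8 * y
    mine <- delongTest(a, b, y)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(sort(c(mine$aucA, mine$aucB)),
                 sort(as.numeric(c(ref$estimate))), tolerance = 1e-12)
  }
})

test_that("Holm-Bonferroni reproduces the hand-worked step-down", {
  expect_equal(holmBonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmBonferroni(0.03), 0.03)
  expect_equal(holmBonferroni(rep(1, 4)), rep(1, 4))
  expect_error(holmBonferroni(c(0.1, 1.2)), class = "opncb_data")
})

test_that("a small experiment is reproducible end to end", {
  cfg <- smallCohortConfig("divergent", seed = 42, nFeatures = 15)
  run <- function() runExperiment(cfg, k = 3, repeats = 1, seed = 5,
                                  methods = c("covariate", "separate"),
                                  optimize = FALSE)
  a <- run()
  b <- run()
  expect_identical(a@trials, b@trials)
  expect_identical(a@comparisons, b@comparisons)
  expect_equal(nrow(a@trials), 6) # 3 folds x 2 methods
  expect_true(all(a@trials$independent_fraction >= 0 &
                    a@trials$independent_fraction <= 1))
  ## aggregate CIs recompute exactly from the stored per-trial values
  s <- a@summary
  for (m in c("covariate", "separate")) {
    v <- a@trials$auc[a@trials$method == m & a@trials$usable]
    half <- qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
    row <- s[s$method == m & s$metric == "auc", ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$ci_hi - row$mean, half, tolerance = 1e-12)
  }
})

test_that("shuffling test labels changes no fitted object and no test score", {
  x <- simulateCohort(smallCohortConfig("shared", seed = 43,
                                        nFeatures = 12))
  sp <- makeSplits(x, k = 5, repeats = 1, seed = 7)[[1]]
  runOnce <- function(test) {
    ex <- excludeUnharmonizable(x[, sp$train], test, mode = "separate")
    plan <- fitPlan(ex$train, "covariate")
    h <- applyPlan(plan, ex$train)
    gate <- independenceReport(h)
    sel <- lassoSelect(t(featureMatrix(h))[, independentFeatures(gate),
                                           drop = FALSE],
                       malignancyLabels(h))
    m <- trainClassifier(t(featureMatrix(h))[, sel, drop = FALSE],
                         malignancyLabels(h))
    list(plan = plan, gate = gate, sel = sel, model = m,
         scores = predictScores(m, t(featureMatrix(
           applyPlan(plan, ex$test))))$scores)
  }
  test1 <- x[, sp$test]
  ## mutate the test labels (within LCS, where labels are free to vary)
  test2 <- test1
  set.seed(99)
  lcs <- which(subgroups(test1) == "LCS")
  SummarizedExperiment::colData(test2)$malignancy_label[lcs] <-
    sample(malignancyLabels(test1)[lcs])
  a <- runOnce(test1)
  b <- runOnce(test2)
  expect_equal(a$plan@models, b$plan@models)
  expect_identical(a$sel, b$sel)
  expect_equal(a$model@weights, b$model@weights)
  expect_identical(a$scores, b$scores)
})

test_that("uniform-acquisition groups pass the gate at the nominal rate", {
  ## one dominant uniform group plus a handful of too-small ones
  cfg <- simulationConfig(
    nScans = c(benign = 100, malignant = 100, LCS = 0),
    nNodules = c(benign = 60, malignant = 60, LCS = 0),
    nPatients = c(benign = 40, malignant = 40, LCS = 0),
    schema = list(parameters = "CE", levels = list(CE = c("no", "yes"))),
    instanceFrequencies = list(CE = c(0.97, 0.03)),
    nFeatures = 107, malignancyEffects = 0.8, seed = 61)
  x <- simulateCohort(cfg)
  res <- uniformGroupCheck(x, k = 5, seed = 2)
  expect_gte(nrow(res$groups), 1)
  big <- res$groups[which.max(res$groups$n), ]
  expect_lt(abs(big$pass_rate - 0.95), 0.02)
  if (nrow(res$skipped)) expect_true(all(res$skipped$n < 10))
})

test_that("the uniform-group check stays calibrated under unmodeled acquisition structure", {
  ## generate with a strong second batch factor, then hide it from the
  ## schema: random folds share the hidden mixture, so the train/test
  ## comparison must remain null (calibrated or conservative, never
  ## collapsed)
  G <- 107
  bShift <- array(0, dim = c(2, 3, G)); bShift[2, , ] <- 4
  cfg <- simulationConfig(
    nScans = c(benign = 150, malignant = 150, LCS = 0),
    nNodules = c(benign = 80, malignant = 80, LCS = 0),
    nPatients = c(benign = 50, malignant = 50, LCS = 0),
    schema = list(parameters = c("A", "B"),
                  levels = list(A = c("a1", "a2"), B = c("b1", "b2"))),
    instanceFrequencies = list(A = c(0.97, 0.03), B = c(0.5, 0.5)),
    nFeatures = G, malignancyEffects = 0.5,
    batchLocation = list(A = array(0, dim = c(2, 3, G)), B = bShift),
    seed = 71)
  x <- simulateCohort(cfg)
  hidden <- RadiomicExperiment(
    featureMatrix(x),
    as.data.frame(colData(x))[, c("scan_id", "patient_id", "nodule_id",
                                  "subgroup", "malignancy_label", "A")],
    "A")
  res <- uniformGroupCheck(hidden, k = 5, seed = 3)
  expect_gt(res$overall, 0.90)
  expect_lte(res$overall, 1)
})

test_that("the experiment records fallback methods as unusable with fallback metrics", {
  ## unharmonized divergent data gates out everything -> fallback model
  cfg <- smallCohortConfig("divergent", seed = 45, nFeatures = 15)
  es <- runExperiment(cfg, k = 3, repeats = 1, seed = 8,
                      methods = "unharmonized", optimize = FALSE)
  tr <- es@trials
  expect_true(all(!tr$usable))
  expect_true(all(tr$sensitivity == 0))
  expect_true(all(tr$specificity == 1))
  expect_true(all(tr$balanced_accuracy == 0.5))
})
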