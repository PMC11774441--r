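test_that("a single batch level cannot be harmonized", {
  x <- makeTinyTable(rnorm(10), batch = rep("yes", 10))
  expect_error(fitCombat(x, "CE"), class = "opncb_single_level")
})

test_that("an instance below the minimum batch size raises the exclusion error", {
  x <- makeTinyTable(rnorm(10), batch = c(rep("no", 8), "yes", "yes"))
  err <- tryCatch(fitCombat(x, "CE", minBatchSize = 3),
                  opncb_unharmonizable_level = function(e) e)
  expect_s3_class(err, "opncb_unharmonizable_level")
  expect_identical(err$levels, "yes")
})

test_that("two shifted Gaussian batches are moment-matched after harmonization", {
  set.seed(101)
  n <- 5000
  vals <- c(rnorm(n, 0, 1), rnorm(n, 3, 2))
  x <- makeTinyTable(vals, batch = rep(c("no", "yes"), each = n))
  m <- fitCombat(x, "CE")
  ## single feature: EB falls back to the unshrunk per-batch moments,
  ## so the location estimate is the standardized mean offset
  sdPool <- m@pooledSD[[1]]
  expect_equal(m@ebLocation["yes", 1],
               (mean(vals[(n + 1):(2 * n)]) - m@grandEffects[[1]]) / sdPool,
               tolerance = 1e-8, ignore_attr = TRUE)
  h <- featureMatrix(applyCombat(m, x))[1, ]
  d <- mean(h[(n + 1):(2 * n)]) - mean(h[1:n])
  expect_lt(abs(d), 0.05)
  vr <- var(h[(n + 1):(2 * n)]) / var(h[1:n])
  expect_gt(vr, 0.9)
  expect_lt(vr, 1.1)
})

test_that("covariate harmonization preserves the simulated class gap", {
  set.seed(102)
  n <- 2000 # per (class, batch) cell
  kappa <- 1
  shift <- 1.5
  cl <- rep(c("benign", "malignant"), each = 2 * n)
  ce <- rep(c("no", "yes", "no", "yes"), each = n)
  vals <- rnorm(4 * n) + kappa * (cl == "malignant") + shift * (ce == "yes")
  x <- makeTinyTable(matrix(rep(vals, 4), nrow = 4, byrow = TRUE),
                     batch = ce, subgroup = cl)
  m <- fitCombat(x, "CE", covariate = "subgroup")
  h <- featureMatrix(applyCombat(m, x))[1, ]
  gap <- mean(h[cl == "malignant"]) - mean(h[cl == "benign"])
  expect_lt(abs(gap - kappa), 0.1)
  ## the fitted covariate slope itself recovers kappa
  expect_lt(abs(m@covariateCoefficients[1, "malignant"] - kappa), 0.1)
  ## and the batch shift is gone
  d <- mean(h[ce == "yes"]) - mean(h[ce == "no"])
  expect_lt(abs(d), 0.1)
})

test_that("collective and covariate ComBat match the independent reference implementation", {
  x <- simulateCohort(smallCohortConfig("divergent", seed = 33,
                                        nFeatures = 40))
  dat <- featureMatrix(x)
  batch <- colData(x)$manufacturer
  relErr <- function(a, b) max(abs(a - b) / (abs(b) + 1e-8))

  mine <- featureMatrix(applyCombat(fitCombat(x, "manufacturer"), x))
  ref <- suppressMessages(sva::ComBat(dat, batch = batch))
  expect_lt(relErr(mine, ref), 1e-6)

  mineCov <- featureMatrix(
    applyCombat(fitCombat(x, "manufacturer", covariate = "subgroup"), x))
  mod <- model.matrix(~ factor(subgroups(x)))
  refCov <- suppressMessages(sva::ComBat(dat, batch = batch, mod = mod))
  expect_lt(relErr(mineCov, refCov), 1e-6)
})

test_that("a fitted model transforms held-out scans without refitting", {
  set.seed(103)
  cfg <- smallCohortConfig("shared", seed = 44, nFeatures = 8)
  x <- simulateCohort(cfg)
  idx <- sample(ncol(x), 100)
  train <- x[, -idx]
  test <- x[, idx]
  m <- fitCombat(train, "CE")
  hAll <- applyCombat(m, x)
  hTest <- applyCombat(m, test)
  ## transforming scans alone or within a larger table is identical
  expect_equal(featureMatrix(hTest),
               featureMatrix(hAll)[, idx], tolerance = 1e-12)
  expect_true(all(is.finite(featureMatrix(hTest))))
})

test_that("unseen batch and covariate levels are rejected on apply", {
  x <- makeTinyTable(rnorm(20), batch = rep(c("no", "yes"), 10))
  m <- fitCombat(x, "CE")
  y <- makeTinyTable(rnorm(4), batch = c("no", "maybe", "yes", "maybe"))
  err <- tryCatch(applyCombat(m, y),
                  opncb_unseen_level = function(e) e)
  expect_s3_class(err, "opncb_unseen_level")
  expect_identical(err$levels, "maybe")
})

test_that("null batch effects induce only small corrections at large n", {
  cfg <- simulationConfig(
    nScans = c(benign = 0, malignant = 4000, LCS = 0),
    nNodules = c(benign = 0, malignant = 2000, LCS = 0),
    nPatients = c(benign = 0, malignant = 1000, LCS = 0),
    schema = list(parameters = "CE", levels = list(CE = c("no", "yes"))),
    instanceFrequencies = list(CE = c(0.5, 0.5)),
    nFeatures = 30, malignancyEffects = 0, seed = 55)
  x <- simulateCohort(cfg)
  h <- applyCombat(fitCombat(x, "CE"), x)
  change <- rowMeans(abs(featureMatrix(h) - featureMatrix(x)))
  expect_true(all(change < 0.05)) # baseline sd is 1
})

test_that("harmonization is nearly idempotent in the large-n limit", {
  set.seed(105)
  n <- 5000 # per level
  G <- 50
  m <- matrix(rnorm(G * 2 * n), nrow = G)
  m[, (n + 1):(2 * n)] <- 2 * m[, (n + 1):(2 * n)] + 1.5
  x <- makeTinyTable(m, batch = rep(c("no", "yes"), each = n))
  h1 <- applyCombat(fitCombat(x, "CE"), x)
  h2 <- applyCombat(fitCombat(h1, "CE"), h1)
  change <- mean(abs(featureMatrix(h2) - featureMatrix(h1)))
  expect_lt(change, 0.01) # < 1% of the unit baseline sd
})

test_that("EB shrinkage adapts to the prior spread of batch effects", {
  makeFit <- function(shifts, seed) {
    set.seed(seed)
    n <- 200
    G <- length(shifts)
    m <- matrix(rnorm(G * 2 * n), nrow = G)
    m[, (n + 1):(2 * n)] <- m[, (n + 1):(2 * n)] + shifts
    x <- makeTinyTable(m, batch = rep(c("no", "yes"), each = n))
    fitCombat(x, "CE")
  }
  gap <- function(fit) mean(abs(fit@ebLocation - fit@rawLocation))
  ## homogeneous effects: the prior concentrates at the common truth,
  ## so the posterior is pulled towards it - closer than gamma-hat
  hom <- makeFit(rep(1, 400), 201)
  truthStd <- (1 / 2) / hom@pooledSD # standardized true offset of "yes"
  errStar <- mean(abs(hom@ebLocation["yes", ] - truthStd))
  errHat <- mean(abs(hom@rawLocation["yes", ] - truthStd))
  expect_lt(errStar, errHat)
  ## heterogeneous effects: a diffuse prior leaves the estimates alone
  het <- makeFit(runif(400, -3, 3), 202)
  expect_lt(gap(het), 0.2 * gap(hom))
})

test_that("models survive a JSON round-trip", {
  x <- simulateCohort(smallCohortConfig("divergent", seed = 77,
                                        nFeatures = 6))
  for (cov in list(NULL, "subgroup")) {
    m <- fitCombat(x, "CE", covariate = cov)
    f <- tempfile(fileext = ".json")
    writeCombatModel(m, f)
    m2 <- readCombatModel(f)
    expect_equal(featureMatrix(applyCombat(m2, x)),
                 featureMatrix(applyCombat(m, x)), tolerance = 1e-12)
    unlink(f)
  }
})

test_that("features constant within a batch level pass through with a warning", {
  set.seed(104)
  m <- rbind(rnorm(40), c(rep(5, 20), rnorm(20)))
  x <- makeTinyTable(m, batch = rep(c("no", "yes"), each = 20))
  expect_warning(fit <- fitCombat(x, "CE"), "unharmonized")
  expect_identical(fit@passthroughFeatures, "feat002")
  h <- applyCombat(fit, x)
  expect_identical(featureMatrix(h)["feat002", ],
                   featureMatrix(x)["feat002", ])
  expect_false(identical(featureMatrix(h)["feat001", ],
                         featureMatrix(x)["feat001", ]))
})

test_that("confounded covariate designs are rejected", {
  ## covariate perfectly aligned with batch
  x <- makeTinyTable(rnorm(20), batch = rep(c("no", "yes"), each = 10),
                     subgroup = rep(c("benign", "malignant"), each = 10))
  expect_error(fitCombat(x, "CE", covariate = "subgroup"),
               class = "opncb_confounded")
})
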