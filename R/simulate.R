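#' Build a simulation configuration
#'
#' Low-level constructor giving full control over the generative model:
#' per-feature Gaussian baselines, an additive benign-to-malignant mean
#' shift, a categorical acquisition schema with subgroup-dependent
#' instance frequencies, and location/scale batch effects per
#' (parameter, instance, subgroup, feature). [cohortConfig()] builds
#' ready-made configurations shaped like a clinical chest-CT cohort.
#'
#' @param nScans,nNodules,nPatients named counts per subgroup
#'   (\code{benign}, \code{malignant}, \code{LCS}); scans nest in
#'   nodules, nodules in patients.
#' @param schema list with \code{parameters} (ordered character vector)
#'   and \code{levels} (named list of >= 2 instance labels each).
#' @param instanceFrequencies named list, one entry per parameter: either
#'   a probability vector over instances (shared by all subgroups) or a
#'   subgroups-by-instances matrix whose rows sum to 1.
#' @param nFeatures number of radiomic-style features.
#' @param baselineMeans,baselineSDs,malignancyEffects per-feature values,
#'   recycled if scalar. \code{malignancyEffects} is the mean shift added
#'   to malignant scans (original units).
#' @param batchLocation,batchScale named lists of
#'   (instances x subgroups x features) arrays of additive location
#'   offsets and multiplicative scale factors; \code{NULL} means no
#'   effect (zeros / ones).
#' @param effectSharing \code{"shared_across_subgroups"} (arrays must be
#'   identical across the subgroup dimension) or
#'   \code{"subgroup_specific"}.
#' @param lcsFutureMalignantFraction fraction of screening nodules
#'   flagged as later malignant (default 0.076, the screening-subgroup
#'   nodule malignancy rate of the emulated cohort).
#' @param lcsAttenuation multiplier on the malignancy shift for scans of
#'   flagged screening nodules, whose malignancy status at scan time is
#'   unknown (default 0.5).
#' @param equicorrelation common pairwise noise correlation across
#'   features (default 0, independent features).
#' @param seed integer root seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nScans, nNodules, nPatients, schema,
                             instanceFrequencies,
                             nFeatures = 107,
                             baselineMeans = 0, baselineSDs = 1,
                             malignancyEffects = 0,
                             batchLocation = NULL, batchScale = NULL,
                             effectSharing = "shared_across_subgroups",
                             lcsFutureMalignantFraction = 0.076,
                             lcsAttenuation = 0.5,
                             equicorrelation = 0,
                             seed = 1L) {
  .assertThat(nFeatures >= 1, "opncb_config", "nFeatures must be positive")
  G <- as.integer(nFeatures)
  featNames <- sprintf("feat%03d", seq_len(G))
  rec <- function(v) {
    v <- rep_len(as.numeric(v), G)
    names(v) <- featNames
    v
  }
  pars <- schema$parameters
  freq <- lapply(pars, function(p) {
    f <- instanceFrequencies[[p]]
    lv <- schema$levels[[p]]
    if (is.null(dim(f))) f <- matrix(f, nrow = 3, ncol = length(lv),
                                     byrow = TRUE)
    dimnames(f) <- list(SUBGROUP_LEVELS, lv)
    .assertThat(all(abs(rowSums(f) - 1) < 1e-9), "opncb_config",
                sprintf("instance frequencies for '%s' must sum to 1", p))
    f
  })
  names(freq) <- pars
  mkArr <- function(lst, fill) {
    out <- lapply(pars, function(p) {
      lv <- schema$levels[[p]]
      a <- if (!is.null(lst)) lst[[p]] else NULL
      if (is.null(a)) a <- array(fill, dim = c(length(lv), 3L, G))
      dimnames(a) <- list(lv, SUBGROUP_LEVELS, featNames)
      a
    })
    names(out) <- pars
    out
  }
  cfg <- new("SimulationConfig",
             nPatients = structure(as.integer(nPatients[SUBGROUP_LEVELS]),
                                   names = SUBGROUP_LEVELS),
             nNodules = structure(as.integer(nNodules[SUBGROUP_LEVELS]),
                                  names = SUBGROUP_LEVELS),
             nScans = structure(as.integer(nScans[SUBGROUP_LEVELS]),
                                names = SUBGROUP_LEVELS),
             schema = schema,
             instanceFrequencies = freq,
             nFeatures = G,
             baselineMeans = rec(baselineMeans),
             baselineSDs = rec(baselineSDs),
             malignancyEffects = rec(malignancyEffects),
             batchLocation = mkArr(batchLocation, 0),
             batchScale = mkArr(batchScale, 1),
             effectSharing = effectSharing,
             lcsFutureMalignantFraction = lcsFutureMalignantFraction,
             lcsAttenuation = lcsAttenuation,
             equicorrelation = equicorrelation,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Ready-made cohort configurations
#'
#' Builds a \linkS4class{SimulationConfig} shaped like a heterogeneous
#' clinical chest-CT cohort: 567 scans of 305 nodules from 193 patients
#' split 58 benign / 186 malignant / 323 lung-cancer-screening scans,
#' four categorical acquisition parameters (contrast enhancement,
#' scanner manufacturer, tube voltage, focal spot size), and contrast
#' enhancement quasi-systematically confounded with malignancy (CE is
#' far more frequent for diagnostic scans of malignant nodules than for
#' screening scans).
#'
#' Three batch-effect scenarios are provided:
#' \describe{
#'   \item{\code{"none"}}{no acquisition effects (null data).}
#'   \item{\code{"shared"}}{every feature carries the same location/scale
#'     effects in all subgroups (the assumption under which covariate
#'     harmonization is exact).}
#'   \item{\code{"divergent"}}{60\% of features carry subgroup-specific
#'     effects (opposite sign in benign vs malignant tissue, half
#'     strength in screening scans); the remaining 40\% are shared.}
#' }
#' Location magnitudes per baseline SD are 1.5 (CE), 0.8 (manufacturer),
#' 0.6 (KVP) and 0.7 (focal spot), modulated per feature by a fixed
#' weight in [0.6, 1.4]; scale effects are modest (up to 1.3-fold).
#' All features carry a malignancy shift (1.2 SD for 20 strong features,
#' 0.8 SD otherwise) and the noise is equicorrelated at 0.4, giving
#' moderate, realistic class separability.
#'
#' @param scenario one of \code{"divergent"}, \code{"shared"},
#'   \code{"none"}.
#' @param seed integer root seed.
#' @param nFeatures number of features (default 107).
#' @param nScans,nNodules,nPatients per-subgroup cohort sizes; defaults
#'   reproduce the emulated cohort exactly.
#' @param effectSize global multiplier on all batch location magnitudes.
#' @param equicorrelation common noise correlation (default 0.4).
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' x <- simulateCohort(cohortConfig("divergent", seed = 7))
#' x
#' @export
cohortConfig <- function(scenario = c("divergent", "shared", "none"),
                         seed = 1L, nFeatures = 107,
                         nScans = c(benign = 58, malignant = 186, LCS = 323),
                         nNodules = c(benign = 37, malignant = 57, LCS = 211),
                         nPatients = c(benign = 27, malignant = 57, LCS = 109),
                         effectSize = 1, equicorrelation = 0.4) {
  scenario <- match.arg(scenario)
  G <- as.integer(nFeatures)
  schema <- list(
    parameters = c("CE", "manufacturer", "KVP", "focal_spot"),
    levels = list(CE = c("no", "yes"),
                  manufacturer = c("vendorA", "vendorB", "vendorC"),
                  KVP = c("kvp100", "kvp120"),
                  focal_spot = c("small", "large"))
  )
  ## CE confounded with malignancy; other parameters balanced.
  freq <- list(
    CE = rbind(benign    = c(no = 0.75, yes = 0.25),
               malignant = c(no = 0.15, yes = 0.85),
               LCS       = c(no = 0.90, yes = 0.10)),
    manufacturer = c(vendorA = 0.45, vendorB = 0.35, vendorC = 0.20),
    KVP = c(kvp100 = 0.35, kvp120 = 0.65),
    focal_spot = c(small = 0.70, large = 0.30)
  )
  kappa <- ifelse(seq_len(G) <= 20, 1.2, 0.8)
  w <- 0.6 + 0.8 * ((seq_len(G) - 1) %% 7) / 6   # feature-wise effect weight
  divergent <- (seq_len(G) %% 5) %in% c(1, 2, 3) # 60% subgroup-specific
  mag <- c(CE = 1.5, manufacturer = 0.8, KVP = 0.6, focal_spot = 0.7)
  scaleUp <- c(CE = 1.3, manufacturer = 1.15, KVP = 1.15, focal_spot = 1.15)
  mult <- switch(scenario,
    none = NULL,
    shared = rbind(benign = rep(1, G), malignant = rep(1, G),
                   LCS = rep(1, G)),
    divergent = rbind(benign = rep(1, G),
                      malignant = ifelse(divergent, -1, 1),
                      LCS = ifelse(divergent, 0.5, 1))
  )
  loc <- scl <- NULL
  if (scenario != "none") {
    loc <- scl <- list()
    for (p in schema$parameters) {
      L <- length(schema$levels[[p]])
      cvec <- c(0, 1, -0.7)[seq_len(L)]
      svec <- c(1, scaleUp[[p]], 0.85)[seq_len(L)]
      a <- array(0, dim = c(L, 3L, G))
      b <- array(1, dim = c(L, 3L, G))
      for (l in seq_len(L)) {
        for (s in seq_len(3L)) {
          a[l, s, ] <- effectSize * mag[[p]] * cvec[l] * w * mult[s, ]
          b[l, s, ] <- svec[l]
        }
      }
      loc[[p]] <- a
      scl[[p]] <- b
    }
  }
  simulationConfig(
    nScans = nScans, nNodules = nNodules, nPatients = nPatients,
    schema = schema, instanceFrequencies = freq, nFeatures = G,
    baselineMeans = 0, baselineSDs = 1, malignancyEffects = kappa,
    batchLocation = loc, batchScale = scl,
    effectSharing = if (scenario == "divergent") "subgroup_specific"
                    else "shared_across_subgroups",
    equicorrelation = if (scenario == "none") 0 else equicorrelation,
    seed = seed
  )
}

#' Read and write simulation configurations
#'
#' Serializes a \linkS4class{SimulationConfig} to YAML or JSON (chosen
#' by file extension) and restores it through the validating
#' [simulationConfig()] constructor, so a configuration can be kept
#' alongside the analyses it generated.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path file path ending in \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return \code{readSimulationConfig} returns the restored
#'   configuration; \code{writeSimulationConfig} returns \code{path}
#'   invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  packArr <- function(lst) lapply(lst, function(a)
    list(dim = dim(a), values = as.numeric(a)))
  obj <- list(
    nPatients = as.list(config@nPatients),
    nNodules = as.list(config@nNodules),
    nScans = as.list(config@nScans),
    schema = config@schema,
    instanceFrequencies = lapply(config@instanceFrequencies, function(m)
      list(dim = dim(m), values = as.numeric(m))),
    nFeatures = config@nFeatures,
    baselineMeans = unname(config@baselineMeans),
    baselineSDs = unname(config@baselineSDs),
    malignancyEffects = unname(config@malignancyEffects),
    batchLocation = packArr(config@batchLocation),
    batchScale = packArr(config@batchScale),
    effectSharing = config@effectSharing,
    lcsFutureMalignantFraction = config@lcsFutureMalignantFraction,
    lcsAttenuation = config@lcsAttenuation,
    equicorrelation = config@equicorrelation,
    seed = config@seed
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  l <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unpackArr <- function(lst) lapply(lst, function(a)
    array(as.numeric(unlist(a$values)), dim = unlist(a$dim)))
  schema <- list(parameters = unlist(l$schema$parameters),
                 levels = lapply(l$schema$levels, unlist))
  freq <- lapply(l$instanceFrequencies, function(m)
    matrix(as.numeric(unlist(m$values)), nrow = unlist(m$dim)[1L]))
  simulationConfig(
    nScans = unlist(l$nScans), nNodules = unlist(l$nNodules),
    nPatients = unlist(l$nPatients), schema = schema,
    instanceFrequencies = freq, nFeatures = l$nFeatures,
    baselineMeans = as.numeric(unlist(l$baselineMeans)),
    baselineSDs = as.numeric(unlist(l$baselineSDs)),
    malignancyEffects = as.numeric(unlist(l$malignancyEffects)),
    batchLocation = unpackArr(l$batchLocation),
    batchScale = unpackArr(l$batchScale),
    effectSharing = l$effectSharing,
    lcsFutureMalignantFraction = l$lcsFutureMalignantFraction,
    lcsAttenuation = l$lcsAttenuation,
    equicorrelation = l$equicorrelation,
    seed = l$seed)
}

## Malignancy-signal multiplier per scan: 1 for confirmed malignant,
## the attenuation factor for screening scans of later-malignant
## nodules, 0 otherwise.
.signalMultiplier <- function(subgroup, label, attenuation) {
  ifelse(subgroup == "malignant", 1,
         ifelse(subgroup == "LCS" & label == 1L, attenuation, 0))
}

#' Generate a synthetic radiomic cohort
#'
#' Draws a cohort under \code{config}: patients, nodules and repeat scans
#' are allocated per subgroup (scans per nodule follow a truncated
#' geometric law with the configured mean), acquisition instances are
#' sampled from the subgroup's frequencies, clean feature values follow
#' \code{y = mu_g + kappa_g * s + sigma_g * eps} where \code{s} is the
#' malignancy-signal multiplier and \code{eps} is (equicorrelated)
#' standard Gaussian noise, and batch effects are then injected with
#' [injectBatchEffects()]. A fixed fraction of screening nodules is
#' flagged as later malignant; their scans carry
#' \code{malignancy_label = 1} and an attenuated malignancy shift.
#'
#' Fully reproducible: the same configuration (including its seed)
#' yields an identical cohort.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{RadiomicExperiment} with
#'   \code{sum(config@nScans)} scans.
#' @examples
#' x <- simulateCohort(cohortConfig("shared", seed = 1))
#' table(subgroups(x))
#' @export
simulateCohort <- function(config) {
  validObject(config)
  seeds <- .childSeeds(config@seed, 4L)
  G <- config@nFeatures
  featNames <- names(config@baselineMeans)

  ## -- cohort structure: patients > nodules > scans, per subgroup
  set.seed(seeds[1L])
  rows <- list()
  for (sg in SUBGROUP_LEVELS) {
    nP <- config@nPatients[[sg]]
    nN <- config@nNodules[[sg]]
    nS <- config@nScans[[sg]]
    if (nS == 0L) next
    pat <- c(seq_len(nP),
             if (nN > nP) sample.int(nP, nN - nP, replace = TRUE))
    cnt <- 1L + stats::rgeom(nN, prob = min(1, nN / nS))
    while (sum(cnt) > nS) {
      i <- sample(which(cnt > 1L), 1L)
      cnt[i] <- cnt[i] - 1L
    }
    while (sum(cnt) < nS) {
      i <- sample.int(nN, 1L)
      cnt[i] <- cnt[i] + 1L
    }
    pre <- substr(sg, 1, 1)
    rows[[sg]] <- data.frame(
      patient_id = sprintf("%s_P%03d", pre, rep(pat, cnt)),
      nodule_id = sprintf("%s_N%03d", pre, rep(seq_len(nN), cnt)),
      subgroup = sg,
      stringsAsFactors = FALSE
    )
  }
  info <- do.call(rbind, rows)
  info$scan_id <- sprintf("S%04d", seq_len(nrow(info)))
  rownames(info) <- NULL
  n <- nrow(info)

  ## -- later-malignant screening nodules
  set.seed(seeds[2L])
  lcsNod <- unique(info$nodule_id[info$subgroup == "LCS"])
  nFlag <- round(config@lcsFutureMalignantFraction * length(lcsNod))
  flagged <- if (nFlag > 0L) sample(lcsNod, nFlag) else character()
  info$malignancy_label <- ifelse(
    info$subgroup == "malignant", 1L,
    ifelse(info$nodule_id %in% flagged, 1L, 0L))

  ## -- acquisition instances per scan
  set.seed(seeds[3L])
  for (p in config@schema$parameters) {
    lv <- config@schema$levels[[p]]
    fr <- config@instanceFrequencies[[p]]
    v <- character(n)
    for (sg in SUBGROUP_LEVELS) {
      idx <- which(info$subgroup == sg)
      if (length(idx))
        v[idx] <- sample(lv, length(idx), replace = TRUE, prob = fr[sg, ])
    }
    info[[p]] <- v
  }

  ## -- clean feature values
  set.seed(seeds[4L])
  rho <- config@equicorrelation
  z <- matrix(stats::rnorm(G * n), nrow = G, ncol = n)
  if (rho > 0) {
    u <- stats::rnorm(n)
    z <- sqrt(1 - rho) * z + sqrt(rho) * matrix(u, G, n, byrow = TRUE)
  }
  s <- .signalMultiplier(info$subgroup, info$malignancy_label,
                         config@lcsAttenuation)
  m <- config@baselineMeans + outer(config@malignancyEffects, s) +
    config@baselineSDs * z
  dimnames(m) <- list(featNames, info$scan_id)

  clean <- RadiomicExperiment(m, info, config@schema$parameters)
  injectBatchEffects(clean, config)
}

#' Inject acquisition batch effects into a clean feature table
#'
#' Deterministically applies the configured batch effects: for a scan
#' with instance i of parameter p in subgroup s, feature g is updated as
#' \code{mu-part + sum_p location[p,i,s,g] + prod_p scale[p,i,s,g] *
#' eps-part}, where the mu-part is the clean systematic value
#' (baseline plus malignancy shift) and the eps-part is the clean
#' residual. Location effects compose additively and scale effects
#' multiplicatively across parameters, so the result does not depend on
#' parameter order.
#'
#' @param clean a \linkS4class{RadiomicExperiment} of clean values drawn
#'   under \code{config}.
#' @param config the \linkS4class{SimulationConfig}.
#' @return A \linkS4class{RadiomicExperiment} with perturbed features.
#' @export
injectBatchEffects <- function(clean, config) {
  y <- featureMatrix(clean)
  cd <- colData(clean)
  n <- ncol(y)
  s <- .signalMultiplier(as.character(cd$subgroup), cd$malignancy_label,
                         config@lcsAttenuation)
  muPart <- config@baselineMeans + outer(config@malignancyEffects, s)
  eps <- y - muPart
  loc <- matrix(0, nrow(y), n)
  scl <- matrix(1, nrow(y), n)
  sgIdx <- match(as.character(cd$subgroup), SUBGROUP_LEVELS)
  for (p in config@schema$parameters) {
    lv <- config@schema$levels[[p]]
    inst <- as.character(cd[[p]])
    .assertThat(all(inst %in% lv), "opncb_schema",
                sprintf("unknown instance label for parameter '%s'", p))
    li <- match(inst, lv)
    bl <- config@batchLocation[[p]]
    bs <- config@batchScale[[p]]
    for (l in unique(li)) {
      for (sgi in unique(sgIdx[li == l])) {
        cols <- which(li == l & sgIdx == sgi)
        loc[, cols] <- loc[, cols] + bl[l, sgi, ]
        scl[, cols] <- scl[, cols] * bs[l, sgi, ]
      }
    }
  }
  .withFeatures(clean, muPart + loc + scl * eps)
}
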