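# Synthetic resurvey worlds with known truth.
#
# The generator mirrors the resurvey design the model assumes: two regions
# with contrasting century-scale climate and land-use change, historic visits
# 1-11 consecutive days (mean ~3.15), modern surveys of 3 consecutive days,
# and species pooled through community hyperdistributions. A single root seed
# feeds independent per-stage child seeds so e.g. changing the visit plan
# does not perturb the parameter draws.

#' Construct CommunityHyperparams
#'
#' @param mean,sd named lists with numeric vectors `p`, `psi`, `phi`,
#'   `gamma`; names of each vector are the design terms.
#' @return a validated [CommunityHyperparams-class].
#' @export
communityHyperparams <- function(mean, sd) {
  g <- function(f) {
    m <- rbind(mean = mean[[f]], sd = sd[[f]])
    colnames(m) <- names(mean[[f]])
    m
  }
  new("CommunityHyperparams", p = g("p"), psi = g("psi"), phi = g("phi"),
      gamma = g("gamma"))
}

#' Default community hyperparameters for the generator
#'
#' Logit-scale community means/SDs chosen to echo the qualitative structure
#' reported for century-scale avian resurveys: precipitation (and its
#' change) the strongest positive driver of occupancy and colonization,
#' urbanization change strongly negative for persistence but mildly positive
#' for colonization of human-tolerant species, a quadratic seasonal
#' detection curve, and lower historic detectability (era effect -0.3).
#'
#' @return a [CommunityHyperparams-class] matching [modelSpec()]'s default
#'   terms.
#' @export
defaultHyperparams <- function() {
  communityHyperparams(
    mean = list(
      p = c(intercept = 0, day = 0.2, day2 = -0.3, era = -0.3),
      psi = c(intercept = -0.5, temperature = -0.2, precipitation = 0.5,
              water = 0.1, urban = -0.2, agriculture = 0.2),
      phi = c(intercept = 1.0, d_temperature = -0.1, d_precipitation = 0.4,
              d_water = 0.05, d_urban = -0.8, d_agriculture = -0.3),
      gamma = c(intercept = -1.5, d_temperature = 0.05,
                d_precipitation = 0.8, d_water = 0.05, d_urban = 0.3,
                d_agriculture = 0)),
    sd = list(
      p = c(intercept = 0.7, day = 0.3, day2 = 0.3, era = 0.3),
      psi = c(intercept = 1.0, temperature = 0.5, precipitation = 0.5,
              water = 0.3, urban = 0.4, agriculture = 0.4),
      phi = c(intercept = 0.7, d_temperature = 0.4, d_precipitation = 0.4,
              d_water = 0.3, d_urban = 0.5, d_agriculture = 0.4),
      gamma = c(intercept = 0.7, d_temperature = 0.4, d_precipitation = 0.4,
                d_water = 0.3, d_urban = 0.4, d_agriculture = 0.3)))
}

#' Default two-region covariate design
#'
#' Mimics the published regional contrast: an urbanizing, strongly warming
#' (+1.8 degC) and drying (-77.2 mm) region ("LA", 28 sites) against an
#' agriculture-expanding, moderately warming (+0.9 degC) and wetting
#' (+11.2 mm) region ("CV", 43 sites). Historic land use is mostly natural
#' in both. Covariate order: temperature, precipitation, water, urban,
#' agriculture.
#'
#' @param nSitesA,nSitesB sites per region.
#' @return list of per-region designs for [simulateCovariates()].
#' @export
defaultRegionDesign <- function(nSitesA = 28L, nSitesB = 43L) {
  list(
    LA = list(nSites = nSitesA,
              historicMean = c(15.5, 500, 3, 5, 8),
              historicSD = c(1.5, 120, 2, 3, 5),
              deltaMean = c(1.8, -77.2, -2, 31, -6),
              deltaSD = c(0.4, 30, 1.5, 12, 4)),
    CV = list(nSites = nSitesB,
              historicMean = c(16.5, 350, 4, 4, 15),
              historicSD = c(1.5, 100, 2.5, 2.5, 8),
              deltaMean = c(0.9, 11.2, 0, 4, 22),
              deltaSD = c(0.3, 25, 2, 3, 10)))
}

#' Simulate two-region site covariates
#'
#' Historic values and deltas are drawn from region-specific normals; modern
#' = historic + delta; percent covers are clipped to [0, 100] in both eras
#' (deltas are always re-derived as modern minus historic, so the identity
#' holds exactly even after clipping).
#'
#' @param design per-region list as from [defaultRegionDesign()].
#' @param seed integer seed.
#' @return a [SiteCovariates-class].
#' @export
simulateCovariates <- function(design = defaultRegionDesign(), seed = 1L) {
  if (any(vapply(design, function(d) as.numeric(d$nSites), 1) < 1))
    stop("configuration error: region sizes must be >= 1")
  if (any(unlist(lapply(design, function(d) c(d$historicSD, d$deltaSD))) < 0))
    stop("configuration error: SDs must be >= 0")
  set.seed(as.integer(seed))
  h <- list(); m <- list(); reg <- character(0)
  for (rn in names(design)) {
    d <- design[[rn]]
    J <- d$nSites
    hi <- sapply(seq_along(.covNames), function(c)
      rnorm(J, d$historicMean[c], d$historicSD[c]))
    de <- sapply(seq_along(.covNames), function(c)
      rnorm(J, d$deltaMean[c], d$deltaSD[c]))
    hi <- matrix(hi, J); de <- matrix(de, J)
    colnames(hi) <- .covNames
    hi[, .pctNames] <- pmin(pmax(hi[, .pctNames], 0), 100)
    mo <- hi + de
    colnames(mo) <- .covNames
    mo[, .pctNames] <- pmin(pmax(mo[, .pctNames], 0), 100)
    h[[rn]] <- hi; m[[rn]] <- mo
    reg <- c(reg, rep(rn, J))
  }
  h <- do.call(rbind, h); m <- do.call(rbind, m)
  siteCovariates(h, m, sprintf("site%03d", seq_along(reg)), reg)
}

#' Draw species coefficients from community hyperdistributions
#'
#' Each coefficient is an independent normal draw from its family's
#' hyperdistribution (the species-level random effect).
#'
#' @param hyper a [CommunityHyperparams-class].
#' @param nSpecies number of species (>= 1).
#' @param seed integer seed.
#' @return a [SpeciesParams-class].
#' @export
drawSpeciesParams <- function(hyper, nSpecies, seed = 1L) {
  if (nSpecies < 1L) stop("configuration error: nSpecies must be >= 1")
  for (f in .famNames)
    if (any(slot(hyper, f)["sd", ] <= 0))
      stop("validation error: nonpositive hyper-SD in family ", f)
  set.seed(as.integer(seed))
  sp <- sprintf("sp%03d", seq_len(nSpecies))
  g <- function(f) {
    hm <- slot(hyper, f)
    m <- sapply(seq_len(ncol(hm)), function(c)
      rnorm(nSpecies, hm["mean", c], hm["sd", c]))
    m <- matrix(m, nSpecies, dimnames = list(sp, colnames(hm)))
    m
  }
  new("SpeciesParams", p = g("p"), psi = g("psi"), phi = g("phi"),
      gamma = g("gamma"))
}

.siteDesignFromZ <- function(terms, zmat) {
  X <- matrix(0, nrow(zmat), length(terms), dimnames = list(NULL, terms))
  for (tm in terms) {
    if (tm == "intercept") X[, tm] <- 1
    else X[, tm] <- zmat[, tm]
  }
  X
}

#' Simulate latent incidence from the dynamic occupancy process
#'
#' z1 ~ Bernoulli(psi1); z2 ~ Bernoulli(phi z1 + gamma (1 - z1)), with psi1,
#' phi, gamma from the species' logit-linear models on the standardized
#' covariates.
#'
#' @param params a [SpeciesParams-class].
#' @param std standardized covariates as returned by
#'   [standardizeCovariates()] (z-scored historic and delta matrices).
#' @param seed integer seed.
#' @return integer array species x site x 2.
#' @export
simulateIncidence <- function(params, std, seed = 1L) {
  set.seed(as.integer(seed))
  zd <- std$delta
  colnames(zd) <- paste0("d_", .covNames)
  Xpsi <- .siteDesignFromZ(colnames(params@psi), std$historic)
  Xphi <- .siteDesignFromZ(colnames(params@phi), zd)
  Xgam <- .siteDesignFromZ(colnames(params@gamma), zd)
  psi <- plogis(params@psi %*% t(Xpsi))
  phi <- plogis(params@phi %*% t(Xphi))
  gam <- plogis(params@gamma %*% t(Xgam))
  S <- nrow(psi); J <- ncol(psi)
  z <- array(0L, c(S, J, 2))
  z[, , 1] <- rbinom(S * J, 1L, psi)
  z[, , 2] <- rbinom(S * J, 1L, phi * z[, , 1] + gam * (1 - z[, , 1]))
  dimnames(z) <- list(rownames(params@psi), rownames(std$historic), .eraNames)
  z
}

#' Simulate detection histories from latent incidence
#'
#' Historic visit counts are 1 + Binomial(10, 0.215) consecutive days (mean
#' 3.15, range 1-11); modern surveys are `modernVisits` consecutive days.
#' Start days are uniform in the breeding window. Detections are
#' Bernoulli(z * p) with p from the species' detection model (standardized
#' day, its square, era effect); the day scale is the pooled mean/SD of the
#' realized visit days, the same convention the fitting step applies.
#' Historic site/eras drawn as "first_detection_only" are re-encoded per
#' [encodeHistory()] (later days masked).
#'
#' @param z integer array species x site x 2 of latent incidence.
#' @param params a [SpeciesParams-class].
#' @param region factor/character per site.
#' @param visitPlan list: `window` (first/last allowed Julian day),
#'   `modernVisits`, `historicSize`, `historicProb` (visit count is
#'   1 + Binomial(historicSize, historicProb)).
#' @param historicModeProbs named probabilities over the three historic
#'   collection modes; modern surveys are always "standard".
#' @param seed integer seed.
#' @return a [DetectionDataset-class].
#' @export
simulateSurveys <- function(z, params, region,
                            visitPlan = list(window = c(80L, 200L),
                                             modernVisits = 3L,
                                             historicSize = 10L,
                                             historicProb = 0.215),
                            historicModeProbs = c(standard = 0.15,
                                                  daily_list = 0.75,
                                                  first_detection_only = 0.10),
                            seed = 1L) {
  set.seed(as.integer(seed))
  S <- dim(z)[1]; J <- dim(z)[2]
  win <- as.integer(visitPlan$window)
  if (win[1] < 1L || win[2] > 366L || win[1] > win[2])
    stop("validation error: visit window must lie within 1..366")
  nVisits <- cbind(
    historic = 1L + rbinom(J, visitPlan$historicSize, visitPlan$historicProb),
    modern = rep(as.integer(visitPlan$modernVisits), J))
  if (any(nVisits < 1L)) stop("validation error: visit counts must be >= 1")
  K <- max(nVisits)
  visitDay <- array(NA_integer_, c(J, K, 2))
  for (t in 1:2) for (j in seq_len(J)) {
    nv <- nVisits[j, t]
    start <- sample(win[1]:(win[2] - nv + 1L), 1L)
    visitDay[j, seq_len(nv), t] <- start + seq_len(nv) - 1L
  }
  mode <- cbind(historic = sample(names(historicModeProbs), J, TRUE,
                                  historicModeProbs),
                modern = rep("standard", J))

  days <- visitDay[!is.na(visitDay)]
  dm <- mean(days); dsd <- .popSD(days)
  if (dsd == 0) dsd <- 1
  y <- array(0L, c(S, J, K, 2))
  pt <- params@p
  pterms <- colnames(pt)
  for (t in 1:2) for (j in seq_len(J)) {
    nv <- nVisits[j, t]
    for (k in seq_len(nv)) {
      zd <- (visitDay[j, k, t] - dm) / dsd
      x <- c(intercept = 1, day = zd, day2 = zd^2,
             era = as.numeric(t == 1L))[pterms]
      p <- plogis(as.vector(pt %*% x))
      y[, j, k, t] <- rbinom(S, 1L, z[, j, t] * p)
    }
  }
  mask <- array(1L, c(S, J, K, 2))
  for (t in 1:2) for (j in seq_len(J)) {
    if (mode[j, t] != "first_detection_only") next
    nv <- nVisits[j, t]
    if (nv < 2L) next
    for (i in seq_len(S)) {
      hit <- which(y[i, j, seq_len(nv), t] == 1L)
      if (length(hit) && hit[1] < nv) {
        y[i, j, (hit[1] + 1L):nv, t] <- 0L
        mask[i, j, (hit[1] + 1L):nv, t] <- 0L
      }
    }
  }
  detectionDataset(y, visitDay, nVisits,
                   species = rownames(params@psi) %||%
                     sprintf("sp%03d", seq_len(S)),
                   sites = dimnames(z)[[2]] %||%
                     sprintf("site%03d", seq_len(J)),
                   region = region, mode = mode, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic world to plain-text files
#'
#' Emits the detection CSV, the covariate CSV, and truth tables (species
#' coefficients per family, hyperparameters, latent incidence in long form)
#' so recovery studies can be run from disk.
#'
#' @param tb a [TruthBundle-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
writeTruthBundle <- function(tb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             covariates = file.path(dir, "covariates.csv"),
             params = file.path(dir, "truth_params.csv"),
             hyper = file.path(dir, "truth_hyper.csv"),
             incidence = file.path(dir, "truth_incidence.csv"))
  writeDetectionData(tb@dataset, paths["detections"])
  writeSiteCovariates(tb@covariates, paths["covariates"])
  long <- do.call(rbind, lapply(.famNames, function(f) {
    m <- slot(tb@params, f)
    data.frame(family = f, species = rep(rownames(m), ncol(m)),
               term = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  write.csv(long, paths["params"], row.names = FALSE, quote = FALSE)
  hy <- do.call(rbind, lapply(.famNames, function(f) {
    m <- slot(tb@hyper, f)
    data.frame(family = f, term = rep(colnames(m), each = 2),
               stat = rep(c("mean", "sd"), ncol(m)), value = as.vector(m))
  }))
  write.csv(hy, paths["hyper"], row.names = FALSE, quote = FALSE)
  zi <- expand.grid(species = dimnames(tb@z)[[1]] %||%
                      speciesNames(tb@dataset),
                    site = dimnames(tb@z)[[2]] %||% siteNames(tb@dataset),
                    era = .eraNames, stringsAsFactors = FALSE)
  zi$z <- as.vector(tb@z)
  write.csv(zi, paths["incidence"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Generate a full synthetic resurvey world with known truth
#'
#' Runs covariate simulation, species-parameter draws, incidence simulation
#' and survey simulation with independent child seeds derived from one root
#' seed; the same seed regenerates the bundle bit-identically.
#'
#' @param nSpecies community size (default 150, the study scale).
#' @param design region design, see [defaultRegionDesign()].
#' @param hyper community hyperparameters, see [defaultHyperparams()].
#' @param seed integer root seed.
#' @param visitPlan,historicModeProbs passed to [simulateSurveys()].
#' @return a [TruthBundle-class].
#' @export
simulateResurvey <- function(nSpecies = 150L, design = defaultRegionDesign(),
                             hyper = defaultHyperparams(), seed = 1L,
                             visitPlan = list(window = c(80L, 200L),
                                              modernVisits = 3L,
                                              historicSize = 10L,
                                              historicProb = 0.215),
                             historicModeProbs = c(standard = 0.15,
                                                   daily_list = 0.75,
                                                   first_detection_only = 0.10)) {
  seed <- as.integer(seed)
  base <- seed %% 500000000L  # keep per-stage child seeds below 2^31
  covariates <- simulateCovariates(design, seed = base * 4L + 1L)
  params <- drawSpeciesParams(hyper, nSpecies, seed = base * 4L + 2L)
  std <- standardizeCovariates(covariates)
  z <- simulateIncidence(params, std, seed = base * 4L + 3L)
  dataset <- simulateSurveys(z, params, region = regions(covariates),
                             visitPlan = visitPlan,
                             historicModeProbs = historicModeProbs,
                             seed = base * 4L + 4L)
  new("TruthBundle", hyper = hyper, params = params, z = z,
      covariates = covariates, dataset = dataset, seed = seed,
      design = list(regions = design, visitPlan = visitPlan,
                    historicModeProbs = historicModeProbs))
}
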