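# Central S4 data containers. Era index 1 = historic, 2 = modern throughout.

.covNames <- c("temperature", "precipitation", "water", "urban", "agriculture")
.deltaNames <- function() paste0("d_", .covNames)
.pctNames <- c("water", "urban", "agriculture")
.famNames <- c("p", "psi", "phi", "gamma")
.eraNames <- c("historic", "modern")

#' DetectionDataset: detection/nondetection histories for two survey eras
#'
#' Binary detections `y` indexed by (species, site, visit, era) with an
#' availability mask of the same shape. Masked cells (mask = 0) are padding
#' beyond a site's recorded visits, or days a first-detection-only historic
#' surveyor stopped recording a species; they never enter any likelihood.
#'
#' @slot y integer array, species x site x visit x era, 0/1 (0 where masked).
#' @slot mask integer array, same shape, 1 where the cell carries data.
#' @slot visitDay integer array site x visit x era, Julian day (1 = Jan 1),
#'   NA beyond a site's recorded visits.
#' @slot nVisits integer matrix site x era, recorded visits per site and era.
#' @slot species,sites character labels.
#' @slot region factor of length n_sites.
#' @slot mode character matrix site x era, one of "standard", "daily_list",
#'   "first_detection_only".
#' @export
setClass("DetectionDataset",
  representation(y = "array", mask = "array", visitDay = "array",
                 nVisits = "matrix", species = "character",
                 sites = "character", region = "factor", mode = "matrix"))

setValidity("DetectionDataset", function(object) {
  d <- dim(object@y)
  if (length(d) != 4L || d[4] != 2L)
    return("y must be a species x site x visit x 2 array")
  if (!identical(dim(object@mask), d))
    return("mask dimensions must match y")
  if (length(object@species) != d[1]) return("species labels must match dim 1")
  if (length(object@sites) != d[2]) return("site labels must match dim 2")
  if (length(object@region) != d[2]) return("region must have one entry per site")
  if (!all(object@mask %in% c(0L, 1L))) return("mask must be 0/1")
  if (!all(object@y[object@mask == 1L] %in% c(0L, 1L)))
    return("y must be 0/1 wherever mask = 1")
  if (any(object@y[object@mask == 0L] != 0L))
    return("masked y cells must be stored as 0")
  dy <- object@visitDay[!is.na(object@visitDay)]
  if (length(dy) && (any(dy < 1L) || any(dy > 366L)))
    return("visit days must lie in 1..366")
  if (d[2] > 0L) {
    surveyed <- object@nVisits > 0L
    avail <- apply(object@mask, c(2, 4), function(m) any(m == 1L))
    if (any(surveyed & !avail))
      return("every surveyed site must keep at least one unmasked visit per era")
  }
  TRUE
})

#' SiteCovariates: raw era-level site covariates for both eras
#'
#' One row per site; columns temperature (degC mean annual), precipitation
#' (mm total annual), water, urban, agriculture (percent cover in 0..100).
#' Deltas (modern minus historic) are always derived, never stored, so the
#' delta = modern - historic identity holds exactly.
#'
#' @slot historic,modern numeric matrices, site x 5, columns as above.
#' @slot sites character site labels.
#' @slot region factor of length n_sites.
#' @export
setClass("SiteCovariates",
  representation(historic = "matrix", modern = "matrix",
                 sites = "character", region = "factor"))

setValidity("SiteCovariates", function(object) {
  for (era in c("historic", "modern")) {
    m <- slot(object, era)
    if (!identical(colnames(m), .covNames))
      return(sprintf("%s columns must be: %s", era,
                     paste(.covNames, collapse = ", ")))
    if (nrow(m) != length(object@sites))
      return("covariate rows must match site labels")
    pct <- m[, .pctNames, drop = FALSE]
    if (length(pct) && (any(pct < 0) || any(pct > 100)))
      return("percent covers must lie in [0, 100]")
  }
  if (length(object@region) != length(object@sites))
    return("region must have one entry per site")
  TRUE
})

#' StandardizationInfo: pooled centering/scaling constants for z-scores
#'
#' Population-SD convention (divide by n), pooled over all sites of both
#' regions. Era-level covariates, delta covariates and Julian day each carry
#' their own row; `zApply`/`zInvert` use them so raw -> z -> raw round-trips
#' exactly.
#'
#' @slot table data.frame with columns covariate, mean, sd, group
#'   (one of "era", "delta", "visit").
#' @slot convention character, SD convention ("population").
#' @export
setClass("StandardizationInfo",
  representation(table = "data.frame", convention = "character"))

setValidity("StandardizationInfo", function(object) {
  need <- c("covariate", "mean", "sd", "group")
  if (!all(need %in% names(object@table)))
    return("table must have columns covariate, mean, sd, group")
  if (any(object@table$sd <= 0)) return("all SDs must be > 0")
  if (anyDuplicated(object@table$covariate)) return("duplicate covariate rows")
  TRUE
})

#' CommunityHyperparams: community-level means and SDs per coefficient family
#'
#' One matrix per family (detection p, initial occupancy psi, persistence phi,
#' colonization gamma) with rows "mean" and "sd" and one column per design
#' term, all on the logit scale. These are the hyperparameters of the normal
#' hyperdistributions that pool species-specific coefficients.
#'
#' @slot p,psi,phi,gamma numeric matrices, rows c("mean", "sd").
#' @export
setClass("CommunityHyperparams",
  representation(p = "matrix", psi = "matrix", phi = "matrix",
                 gamma = "matrix"))

setValidity("CommunityHyperparams", function(object) {
  for (f in .famNames) {
    m <- slot(object, f)
    if (!identical(rownames(m), c("mean", "sd")))
      return(sprintf("family %s must have rows mean, sd", f))
    if (any(!is.finite(m))) return("hyperparameters must be finite")
    if (any(m["sd", ] <= 0)) return("hyper-SDs must be > 0")
  }
  TRUE
})

#' SpeciesParams: species-specific logit-scale coefficients
#'
#' @slot p,psi,phi,gamma numeric matrices, species x terms, with term
#'   colnames matching the model design.
#' @export
setClass("SpeciesParams",
  representation(p = "matrix", psi = "matrix", phi = "matrix",
                 gamma = "matrix"))

setValidity("SpeciesParams", function(object) {
  n <- nrow(object@p)
  for (f in .famNames) {
    m <- slot(object, f)
    if (nrow(m) != n) return("all families must have the same species count")
    if (any(!is.finite(m))) return("coefficients must be finite")
  }
  TRUE
})

#' ModelSpec: covariate design and prior settings for the MSOM
#'
#' @slot pTerms detection design terms (subset of intercept, day, day2, era).
#' @slot psiTerms initial-occupancy terms (intercept + era-level covariates).
#' @slot phiTerms,gammaTerms turnover terms (intercept + delta covariates).
#' @slot priorConvention "variance" (hypermean SD 1.5, half-Cauchy scale 1.5)
#'   or "precision" (both 2/3); see [modelSpec()].
#' @slot hypermeanSD,hyperSdScale numeric prior scales implied by the
#'   convention (stored explicitly for transparency).
#' @export
setClass("ModelSpec",
  representation(pTerms = "character", psiTerms = "character",
                 phiTerms = "character", gammaTerms = "character",
                 priorConvention = "character", hypermeanSD = "numeric",
                 hyperSdScale = "numeric"))

setValidity("ModelSpec", function(object) {
  for (nm in c("pTerms", "psiTerms", "phiTerms", "gammaTerms")) {
    tm <- slot(object, nm)
    if (anyDuplicated(tm)) return(sprintf("%s has duplicated terms", nm))
    if (length(tm) < 1L) return(sprintf("%s needs at least one term", nm))
  }
  if (object@hypermeanSD <= 0 || object@hyperSdScale <= 0)
    return("prior scales must be > 0")
  if (!object@priorConvention %in% c("variance", "precision"))
    return("priorConvention must be 'variance' or 'precision'")
  TRUE
})

#' MCMCConfig: chain bookkeeping for the sampler
#'
#' @slot nChains,nIter,nBurnin,thin,adaptInterval integers; retained draws per
#'   chain are floor((nIter - nBurnin) / thin).
#' @slot seed integer root seed; chain c uses seed + c.
#' @export
setClass("MCMCConfig",
  representation(nChains = "integer", nIter = "integer", nBurnin = "integer",
                 thin = "integer", adaptInterval = "integer", seed = "integer"))

setValidity("MCMCConfig", function(object) {
  if (object@nIter <= object@nBurnin) return("nIter must exceed nBurnin")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@nChains < 1L) return("need at least one chain")
  if (object@adaptInterval < 1L) return("adaptInterval must be >= 1")
  TRUE
})

#' PosteriorSamples: retained MCMC draws plus provenance
#'
#' @slot draws numeric matrix, (total retained draws) x n_parameters, with
#'   parameter labels as colnames.
#' @slot chain,iteration integer index per row of draws.
#' @slot paramInfo data.frame describing each column: param, kind
#'   ("species", "hypermean", "hypersd"), family, term, species.
#' @slot spec,config the ModelSpec and MCMCConfig used.
#' @slot designs list of design arrays built from the data (see
#'   [buildDesigns()]); NULL for prior-only runs.
#' @slot dataset,covariates,stdInfo the inputs (may be NULL for prior-only).
#' @slot diagnostics list: rhat (named vector over monitored parameters),
#'   acceptance summaries.
#' @slot provenance list: dims, data checksum.
#' @export
setClass("PosteriorSamples",
  representation(draws = "matrix", chain = "integer", iteration = "integer",
                 paramInfo = "data.frame", spec = "ModelSpec",
                 config = "MCMCConfig", designs = "ANY", dataset = "ANY",
                 covariates = "ANY", stdInfo = "ANY", diagnostics = "list",
                 provenance = "list"))

setValidity("PosteriorSamples", function(object) {
  if (nrow(object@draws) != length(object@chain) ||
      nrow(object@draws) != length(object@iteration))
    return("chain/iteration indices must match draw rows")
  if (ncol(object@draws) != nrow(object@paramInfo))
    return("paramInfo must describe every draw column")
  expect <- object@config@nChains *
    ((object@config@nIter - object@config@nBurnin) %/% object@config@thin)
  if (nrow(object@draws) != expect)
    return("draw count must equal nChains x floor((nIter - nBurnin)/thin)")
  TRUE
})

#' TruthBundle: a synthetic resurvey world with its generating truth
#'
#' @slot hyper CommunityHyperparams used to draw species.
#' @slot params SpeciesParams truth.
#' @slot z integer array species x site x 2, latent incidence truth.
#' @slot covariates SiteCovariates.
#' @slot dataset DetectionDataset.
#' @slot seed integer root seed (same seed regenerates the bundle exactly).
#' @slot design list of generator settings.
#' @export
setClass("TruthBundle",
  representation(hyper = "CommunityHyperparams", params = "SpeciesParams",
                 z = "array", covariates = "SiteCovariates",
                 dataset = "DetectionDataset", seed = "integer",
                 design = "list"))

#' ScenarioSpec: counterfactual setting per delta covariate
#'
#' Each delta covariate is set to either "regional_change" (the region's mean
#' realized change) or "no_change" (raw change 0, on the pooled z-scale).
#' Presets: CC (climate at regional change, land use frozen), LU (converse),
#' CT (control, everything frozen).
#'
#' @slot name scenario label.
#' @slot settings named character over d_temperature, d_precipitation,
#'   d_water, d_urban, d_agriculture.
#' @export
setClass("ScenarioSpec",
  representation(name = "character", settings = "character"))

setValidity("ScenarioSpec", function(object) {
  need <- paste0("d_", .covNames)
  if (!identical(sort(names(object@settings)), sort(need)))
    return("settings must cover every delta covariate exactly once")
  if (!all(object@settings %in% c("regional_change", "no_change")))
    return("settings must be 'regional_change' or 'no_change'")
  TRUE
})

#' ImpactSummary: counterfactual climate/land-use impacts per species
#'
#' @slot table data.frame per species: dpsi_cc / dpsi_lu mean and CRI,
#'   quadrant, quadrant probability, tie flag.
#' @slot correlation list: posterior mean and CRI of the across-species
#'   Pearson correlation between the two impacts.
#' @slot region character region label.
#' @slot draws list with per-draw impact matrices (draws x species).
#' @export
setClass("ImpactSummary",
  representation(table = "data.frame", correlation = "list",
                 region = "character", draws = "list"))
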