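# Generics, accessor methods and show methods.

#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @export
setGeneric("detectionMask", function(x) standardGeneric("detectionMask"))
#' @export
setGeneric("covariateDeltas", function(x) standardGeneric("covariateDeltas"))
#' @export
setGeneric("eraCovariates", function(x, era = "historic")
  standardGeneric("eraCovariates"))
#' @export
setGeneric("retainedDraws", function(x) standardGeneric("retainedDraws"))
#' @export
setGeneric("paramDraws", function(x, pattern = NULL)
  standardGeneric("paramDraws"))
#' @export
setGeneric("latentIncidence", function(x) standardGeneric("latentIncidence"))

#' @describeIn DetectionDataset-class number of species
#' @param x object
#' @export
setMethod("nSpecies", "DetectionDataset", function(x) dim(x@y)[1])
#' @describeIn DetectionDataset-class number of sites
#' @export
setMethod("nSites", "DetectionDataset", function(x) dim(x@y)[2])
#' @describeIn DetectionDataset-class species labels
#' @export
setMethod("speciesNames", "DetectionDataset", function(x) x@species)
#' @describeIn DetectionDataset-class site labels
#' @export
setMethod("siteNames", "DetectionDataset", function(x) x@sites)
#' @describeIn DetectionDataset-class per-site region factor
#' @export
setMethod("regions", "DetectionDataset", function(x) x@region)
#' @describeIn DetectionDataset-class the 0/1 detection array
#' @export
setMethod("detections", "DetectionDataset", function(x) x@y)
#' @describeIn DetectionDataset-class the availability mask
#' @export
setMethod("detectionMask", "DetectionDataset", function(x) x@mask)

#' @describeIn SiteCovariates-class number of sites
#' @param x object
#' @export
setMethod("nSites", "SiteCovariates", function(x) length(x@sites))
#' @describeIn SiteCovariates-class site labels
#' @export
setMethod("siteNames", "SiteCovariates", function(x) x@sites)
#' @describeIn SiteCovariates-class per-site region factor
#' @export
setMethod("regions", "SiteCovariates", function(x) x@region)
#' @describeIn SiteCovariates-class era-level covariate matrix
#' @param era "historic" or "modern"
#' @export
setMethod("eraCovariates", "SiteCovariates", function(x, era = "historic") {
  era <- match.arg(era, .eraNames)
  slot(x, era)
})
#' @describeIn SiteCovariates-class modern-minus-historic deltas (computed,
#'   never stored, so the identity is exact)
#' @export
setMethod("covariateDeltas", "SiteCovariates", function(x) {
  d <- x@modern - x@historic
  colnames(d) <- paste0("d_", .covNames)
  d
})

#' @describeIn MCMCConfig-class retained draws over all chains:
#'   nChains x floor((nIter - nBurnin) / thin)
#' @param x object
#' @export
setMethod("retainedDraws", "MCMCConfig", function(x)
  x@nChains * ((x@nIter - x@nBurnin) %/% x@thin))

#' @describeIn PosteriorSamples-class total retained draws
#' @param x object
#' @export
setMethod("retainedDraws", "PosteriorSamples", function(x) nrow(x@draws))
#' @describeIn PosteriorSamples-class number of species in the fitted data
#' @export
setMethod("nSpecies", "PosteriorSamples", function(x)
  x@provenance$dims[1])
#' @describeIn PosteriorSamples-class draw matrix, optionally restricted to
#'   parameters whose label matches `pattern` (regular expression)
#' @param pattern optional regular expression on parameter labels
#' @export
setMethod("paramDraws", "PosteriorSamples", function(x, pattern = NULL) {
  if (is.null(pattern)) return(x@draws)
  x@draws[, grepl(pattern, colnames(x@draws)), drop = FALSE]
})

#' @describeIn TruthBundle-class latent incidence truth (species x site x era)
#' @param x object
#' @export
setMethod("latentIncidence", "TruthBundle", function(x) x@z)
#' @describeIn TruthBundle-class number of species
#' @export
setMethod("nSpecies", "TruthBundle", function(x) dim(x@z)[1])
#' @describeIn TruthBundle-class number of sites
#' @export
setMethod("nSites", "TruthBundle", function(x) dim(x@z)[2])

setMethod("show", "DetectionDataset", function(object) {
  d <- dim(object@y)
  cat(sprintf("DetectionDataset: %d species x %d sites x up to %d visits x 2 eras\n",
              d[1], d[2], d[3]))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s (%d)", levels(object@region),
                            tabulate(object@region)), collapse = ", ")))
  cat(sprintf("  unmasked cells: %d; naive detection rate %.3f\n",
              sum(object@mask), mean(object@y[object@mask == 1L])))
  invisible(object)
})

setMethod("show", "SiteCovariates", function(object) {
  cat(sprintf("SiteCovariates: %d sites, regions %s\n", length(object@sites),
              paste(levels(object@region), collapse = ", ")))
  d <- covariateDeltas(object)
  cat("  mean deltas (modern - historic):\n")
  print(round(colMeans(d), 2))
  invisible(object)
})

setMethod("show", "StandardizationInfo", function(object) {
  cat(sprintf("StandardizationInfo (%s-SD convention):\n", object@convention))
  print(object@table, row.names = FALSE, digits = 4)
  invisible(object)
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec (dynamic MSOM)\n")
  cat("  p     ~", paste(object@pTerms, collapse = " + "), "\n")
  cat("  psi1  ~", paste(object@psiTerms, collapse = " + "), "\n")
  cat("  phi   ~", paste(object@phiTerms, collapse = " + "), "\n")
  cat("  gamma ~", paste(object@gammaTerms, collapse = " + "), "\n")
  cat(sprintf("  priors (%s convention): hypermean ~ N(0, %.3g^2); hyper-SD ~ half-Cauchy(%.3g)\n",
              object@priorConvention, object@hypermeanSD, object@hyperSdScale))
  invisible(object)
})

setMethod("show", "MCMCConfig", function(object) {
  cat(sprintf("MCMCConfig: %d chains x %d iterations (%d burn-in, thin %d) -> %d retained draws\n",
              object@nChains, object@nIter, object@nBurnin, object@thin,
              retainedDraws(object)))
  invisible(object)
})

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf("PosteriorSamples: %d draws x %d parameters (%d chains)\n",
              nrow(object@draws), ncol(object@draws),
              object@config@nChains))
  rh <- object@diagnostics$rhat
  if (!is.null(rh))
    cat(sprintf("  max monitored R-hat: %.3f (%d monitored)\n", max(rh),
                length(rh)))
  invisible(object)
})

setMethod("show", "TruthBundle", function(object) {
  cat(sprintf("TruthBundle: %d species x %d sites (seed %d)\n",
              dim(object@z)[1], dim(object@z)[2], object@seed))
  cat(sprintf("  occupied fraction: historic %.3f, modern %.3f\n",
              mean(object@z[, , 1]), mean(object@z[, , 2])))
  invisible(object)
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec '%s':\n", object@name))
  print(object@settings)
  invisible(object)
})

setMethod("show", "ImpactSummary", function(object) {
  cat(sprintf("ImpactSummary (%s): %d species\n", object@region,
              nrow(object@table)))
  print(table(object@table$quadrant))
  cat(sprintf("  impact correlation r = %.3f (%.3f, %.3f)\n",
              object@correlation$mean, object@correlation$lower,
              object@correlation$upper))
  invisible(object)
})
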