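# Occupancy-change sensitivities and counterfactual climate/land-use
# impact decomposition.

#' One-step Markov occupancy update
#'
#' psi_modern = psi_historic * phi + (1 - psi_historic) * gamma: occupied
#' sites persist with probability phi, unoccupied ones are colonized with
#' probability gamma, so the result is a convex combination of phi and
#' gamma.
#'
#' @param psiH,phi,gamma probabilities in [0, 1] (vectorized).
#' @return modern occupancy probability.
#' @export
markovOccupancy <- function(psiH, phi, gamma) {
  if (any(psiH < 0 | psiH > 1 | phi < 0 | phi > 1 | gamma < 0 | gamma > 1))
    stop("validation error: probabilities must lie in [0, 1]")
  psiH * phi + (1 - psiH) * gamma
}

#' Sensitivity of occupancy change to a covariate's change
#'
#' The derivative of delta-psi = psi_m - psi_h with respect to the change in
#' one covariate, combining the persistence and colonization channels:
#' d(delta psi)/dx = psi_h * phi(1-phi) * deltaSlope +
#' (1 - psi_h) * gamma(1-gamma) * epsilonSlope. Positive values mean
#' occupancy increases when the covariate's change increases; the absolute
#' value is the magnitude of sensitivity.
#'
#' @param psiH,phi,gamma probabilities in [0, 1] (vectorized).
#' @param deltaSlope persistence (phi) slope for the covariate.
#' @param epsilonSlope colonization (gamma) slope for the covariate.
#' @return derivative on the covariate's z-scale.
#' @export
sensitivity <- function(psiH, phi, gamma, deltaSlope, epsilonSlope)
  psiH * phi * (1 - phi) * deltaSlope +
    (1 - psiH) * gamma * (1 - gamma) * epsilonSlope

#' Counterfactual scenario presets
#'
#' CC: climate deltas (d_temperature, d_precipitation) at the region's mean
#' realized change, land-use deltas (d_water, d_urban, d_agriculture) frozen
#' at no change. LU: the converse. CT: everything frozen (the control,
#' capturing occupancy change from unmodelled causes absorbed in the
#' intercepts).
#'
#' @param name "CC", "LU" or "CT".
#' @return a [ScenarioSpec-class].
#' @export
scenarioPreset <- function(name = c("CC", "LU", "CT")) {
  name <- match.arg(name)
  climate <- c("d_temperature", "d_precipitation")
  landuse <- c("d_water", "d_urban", "d_agriculture")
  s <- stats::setNames(rep("no_change", 5), c(climate, landuse))
  if (name == "CC") s[climate] <- "regional_change"
  if (name == "LU") s[landuse] <- "regional_change"
  new("ScenarioSpec", name = name, settings = s)
}

#' Delta-covariate z-scores for a counterfactual scenario
#'
#' Because deltas are z-scored on the pooled (both regions) raw-delta mean
#' and SD, "no change" is the z-score of a raw change of zero,
#' (0 - pooled mean)/pooled SD, and "regional change" is the z-score of the
#' region's mean raw delta.
#'
#' @param info a [StandardizationInfo-class] carrying the delta rows.
#' @param covariates a [SiteCovariates-class] (source of regional means).
#' @param region region level.
#' @param scenario a [ScenarioSpec-class].
#' @return named z-score vector over the delta covariates.
#' @export
scenarioZscores <- function(info, covariates, region, scenario) {
  d <- covariateDeltas(covariates)
  inRegion <- regions(covariates) == region
  if (!any(inRegion)) stop("configuration error: unknown region '", region, "'")
  regMean <- colMeans(d[inRegion, , drop = FALSE])
  vapply(names(scenario@settings), function(cv) {
    raw <- if (scenario@settings[[cv]] == "no_change") 0 else regMean[[cv]]
    zApply(info, cv, raw)
  }, numeric(1))
}

# coefficient draw arrays aligned with a (possibly thinned) incidence
# array: zDraws carries the retained-draw index it was imputed from
.alignedCoefDraws <- function(ps, zDraws) {
  cd <- coefDraws(ps)
  idx <- attr(zDraws, "drawIndex")
  if (is.null(idx)) idx <- seq_len(nrow(ps@draws))
  if (dim(zDraws)[1] != length(idx))
    stop("integrity error: incidence draws do not carry a usable draw index")
  lapply(cd, function(a) a[idx, , , drop = FALSE])
}

# regional psi_h per species per draw: mean of imputed z1 over the region's
# sites (default), or the mean of the psi1 link values (link = TRUE)
.psiHDraws <- function(ps, zDraws, region, link = FALSE) {
  sites <- which(regions(ps@dataset) == region)
  if (!length(sites)) stop("configuration error: unknown region '", region, "'")
  if (!link)
    return(apply(zDraws[, , sites, 1, drop = FALSE], c(1, 2), mean))
  cd <- .alignedCoefDraws(ps, zDraws)
  Xpsi <- ps@designs$Xpsi[sites, , drop = FALSE]
  N <- dim(cd$psi)[1]; S <- dim(cd$psi)[2]
  out <- matrix(0, N, S)
  for (j in seq_len(nrow(Xpsi)))
    out <- out + plogis(apply(cd$psi, c(1, 2),
                              function(b) sum(b * Xpsi[j, ])))
  out / nrow(Xpsi)
}

#' Counterfactual occupancy per species per draw
#'
#' For each retained draw: persistence and colonization are evaluated at the
#' scenario's delta z-scores, and modern occupancy follows the Markov update
#' from the species' regional historic occupancy (the per-draw regional mean
#' of imputed latent incidence z1).
#'
#' @param ps a [PosteriorSamples-class] from a data fit.
#' @param zDraws incidence array from [drawIncidence()] (same draws).
#' @param region region level.
#' @param scenario a [ScenarioSpec-class].
#' @param psiHLink use the psi1 link values instead of incidence for
#'   historic occupancy.
#' @return matrix draws x species of scenario occupancy.
#' @export
counterfactualOccupancy <- function(ps, zDraws, region, scenario,
                                    psiHLink = FALSE) {
  zs <- scenarioZscores(ps@stdInfo, ps@covariates, region, scenario)
  psiH <- .psiHDraws(ps, zDraws, region, link = psiHLink)
  cd <- .alignedCoefDraws(ps, zDraws)
  lp <- function(a, terms) {
    # a: draws x species x terms; scenario vector indexed by term name
    out <- a[, , "intercept"]
    for (tm in setdiff(terms, "intercept")) out <- out + a[, , tm] * zs[[tm]]
    out
  }
  phi <- plogis(lp(cd$phi, ps@spec@phiTerms))
  gam <- plogis(lp(cd$gamma, ps@spec@gammaTerms))
  markovOccupancy(psiH, phi, gam)
}

#' Counterfactual impact decomposition with quadrant classification
#'
#' Computes scenario occupancies psi_CC, psi_LU, psi_CT per draw, subtracts
#' the control (impacts dpsi_CC = psi_CC - psi_CT, dpsi_LU = psi_LU -
#' psi_CT), classifies each species' mean impact pair into windfall (+, +),
#' double_whammy (-, -) or the two opposing quadrants, with the quadrant
#' probability the fraction of joint posterior draws falling in the mean's
#' quadrant, and summarizes the across-species Pearson correlation of the
#' two impacts per draw. A species whose mean impact is exactly zero on an
#' axis is assigned the quadrant holding most of its draws and flagged.
#'
#' @param ps a [PosteriorSamples-class] from a data fit.
#' @param region region level.
#' @param zDraws optional incidence array (imputed if missing).
#' @param exclude optional character vector of species to drop (e.g.
#'   non-natives absent historically).
#' @param psiHLink see [counterfactualOccupancy()].
#' @param seed seed for incidence imputation when zDraws is missing.
#' @param level credible level.
#' @return an [ImpactSummary-class].
#' @export
counterfactualImpacts <- function(ps, region, zDraws = NULL,
                                  exclude = character(0), psiHLink = FALSE,
                                  seed = 1L, level = 0.95) {
  if (is.null(zDraws)) zDraws <- drawIncidence(ps, seed = seed)
  psiCC <- counterfactualOccupancy(ps, zDraws, region, scenarioPreset("CC"),
                                   psiHLink)
  psiLU <- counterfactualOccupancy(ps, zDraws, region, scenarioPreset("LU"),
                                   psiHLink)
  psiCT <- counterfactualOccupancy(ps, zDraws, region, scenarioPreset("CT"),
                                   psiHLink)
  impacts(psiCC, psiLU, psiCT, species = speciesNames(ps@dataset),
          region = region, exclude = exclude, level = level)
}

#' Impacts from aligned scenario occupancy draws
#'
#' @param psiCC,psiLU,psiCT matrices draws x species, draw-aligned.
#' @param species optional species labels.
#' @param region region label for the summary.
#' @param exclude species labels to drop before summarizing.
#' @param level credible level.
#' @return an [ImpactSummary-class].
#' @export
impacts <- function(psiCC, psiLU, psiCT, species = NULL, region = "all",
                    exclude = character(0), level = 0.95) {
  if (!all(dim(psiCC) == dim(psiCT)) || !all(dim(psiLU) == dim(psiCT)))
    stop("integrity error: scenario draws are not aligned")
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(ncol(psiCT)))
  keep <- !species %in% exclude
  dCC <- (psiCC - psiCT)[, keep, drop = FALSE]
  dLU <- (psiLU - psiCT)[, keep, drop = FALSE]
  species <- species[keep]
  sCC <- posteriorSummary(dCC, level)
  sLU <- posteriorSummary(dLU, level)
  qa <- quadrantAssignment(dCC, dLU)
  tab <- data.frame(species = species,
                    dpsi_cc = sCC$mean, cc_lower = sCC$lower,
                    cc_upper = sCC$upper,
                    dpsi_lu = sLU$mean, lu_lower = sLU$lower,
                    lu_upper = sLU$upper,
                    quadrant = qa$quadrant, probability = qa$probability,
                    tie = qa$tie)
  corr <- impactCorrelation(dCC, dLU, level)
  new("ImpactSummary", table = tab, correlation = corr, region = region,
      draws = list(dpsi_cc = dCC, dpsi_lu = dLU))
}

.quadrantOf <- function(x, y)
  ifelse(x > 0 & y > 0, "windfall",
         ifelse(x < 0 & y < 0, "double_whammy",
                ifelse(x > 0, "opposing_CC+", "opposing_LU+")))

#' Quadrant assignment with posterior probability
#'
#' The quadrant of the posterior-mean impact pair (climate axis first), and
#' the fraction of joint draws in that quadrant. Exact zero means (a
#' measure-zero event) fall back to the quadrant containing the most draws
#' and are flagged.
#'
#' @param dCC,dLU matrices draws x species of climate and land-use impacts.
#' @return data.frame: quadrant, probability, tie flag.
#' @export
quadrantAssignment <- function(dCC, dLU) {
  qnames <- c("windfall", "double_whammy", "opposing_CC+", "opposing_LU+")
  drawQ <- .quadrantOf(dCC, dLU)  # draws x species
  out <- data.frame(quadrant = character(ncol(dCC)),
                    probability = numeric(ncol(dCC)),
                    tie = logical(ncol(dCC)))
  mCC <- colMeans(dCC); mLU <- colMeans(dLU)
  for (i in seq_len(ncol(dCC))) {
    counts <- table(factor(drawQ[, i], levels = qnames)) / nrow(dCC)
    if (mCC[i] == 0 || mLU[i] == 0) {
      q <- qnames[which.max(counts)]
      out$tie[i] <- TRUE
    } else q <- .quadrantOf(mCC[i], mLU[i])
    out$quadrant[i] <- q
    out$probability[i] <- counts[[q]]
  }
  out
}

#' Posterior of an across-species Pearson correlation
#'
#' Correlates two species-level vectors within each draw; draws where either
#' vector is constant are undefined and excluded (their count is reported).
#'
#' @param x,y matrices draws x species.
#' @param level credible level.
#' @return list: mean, lower, upper, nUndefined.
#' @export
impactCorrelation <- function(x, y, level = 0.95) {
  if (ncol(x) < 3L) stop("estimation error: need >= 3 species")
  r <- vapply(seq_len(nrow(x)), function(i) {
    if (sd(x[i, ]) == 0 || sd(y[i, ]) == 0) return(NA_real_)
    cor(x[i, ], y[i, ])
  }, numeric(1))
  nUndefined <- sum(is.na(r))
  r <- r[!is.na(r)]
  a <- (1 - level) / 2
  list(mean = mean(r), lower = quantile(r, a, names = FALSE),
       upper = quantile(r, 1 - a, names = FALSE), nUndefined = nUndefined)
}

#' Posterior sensitivities of occupancy change per species and covariate
#'
#' Evaluates the occupancy-change derivative per draw at draw-specific
#' phi, gamma and psi_h: psi_h is the per-draw regional mean of imputed
#' latent historic incidence; phi and gamma are evaluated at the region's
#' mean realized delta z-scores (every delta at "regional_change").
#' Sensitivities are on each delta covariate's pooled z-scale;
#' `rawUnits = TRUE` divides by the pooled raw-delta SD to give change in
#' occupancy per raw covariate unit.
#'
#' @param ps a [PosteriorSamples-class] from a data fit.
#' @param region region level.
#' @param zDraws optional incidence array (imputed if missing).
#' @param rawUnits report per raw covariate unit instead of per z-unit.
#' @param seed seed for incidence imputation when zDraws is missing.
#' @param level credible level.
#' @return list: `table` (species x covariate long data.frame with mean and
#'   CRI) and `draws` (list of draws x species matrices per covariate).
#' @export
sensitivityTable <- function(ps, region, zDraws = NULL, rawUnits = FALSE,
                             seed = 1L, level = 0.95) {
  if (is.null(zDraws)) zDraws <- drawIncidence(ps, seed = seed)
  psiH <- .psiHDraws(ps, zDraws, region)
  cd <- .alignedCoefDraws(ps, zDraws)
  allChange <- new("ScenarioSpec", name = "realized",
                   settings = stats::setNames(rep("regional_change", 5),
                                              paste0("d_", .covNames)))
  zs <- scenarioZscores(ps@stdInfo, ps@covariates, region, allChange)
  lp <- function(a, terms) {
    out <- a[, , "intercept"]
    for (tm in setdiff(terms, "intercept")) out <- out + a[, , tm] * zs[[tm]]
    out
  }
  phi <- plogis(lp(cd$phi, ps@spec@phiTerms))
  gam <- plogis(lp(cd$gamma, ps@spec@gammaTerms))
  covs <- intersect(ps@spec@phiTerms, ps@spec@gammaTerms)
  covs <- setdiff(covs, "intercept")
  species <- speciesNames(ps@dataset)
  drawsOut <- list(); rows <- list()
  for (cv in covs) {
    s <- sensitivity(psiH, phi, gam, cd$phi[, , cv], cd$gamma[, , cv])
    if (rawUnits) s <- s / .zRow(ps@stdInfo, cv)$sd
    drawsOut[[cv]] <- s
    sm <- posteriorSummary(s, level)
    rows[[cv]] <- data.frame(species = species, covariate = cv,
                             units = if (rawUnits) "raw" else "z",
                             mean = sm$mean, lower = sm$lower,
                             upper = sm$upper)
  }
  list(table = do.call(rbind, rows), draws = drawsOut)
}
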