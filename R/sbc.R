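# Simulation-based calibration of the sampler: draw parameters from the
# prior, simulate data, fit, and rank the true value among thinned posterior
# draws. If the sampler targets the right posterior, ranks are uniform.

#' Simulation-based calibration ranks for hyperparameters
#'
#' For each replicate: hypermeans are drawn from Normal(0, hypermeanSD^2)
#' and hyper-SDs from half-Cauchy(hyperSdScale); species coefficients from
#' the resulting hyperdistributions; a dataset is simulated under the model;
#' the posterior is sampled; and the rank of each true monitored
#' hyperparameter among `nRanks` evenly thinned posterior draws is recorded
#' (possible ranks 0..nRanks, uniform under a correct sampler).
#'
#' @param nReplicates number of prior replicates.
#' @param nSpecies,covariates community size and a [SiteCovariates-class]
#'   defining the sites.
#' @param spec a [ModelSpec-class] (keep designs small: ranks need many
#'   fits).
#' @param config per-replicate [MCMCConfig-class].
#' @param monitorParams character vector of hyperparameter labels (e.g.
#'   "mu.gamma.d_precipitation").
#' @param nRanks posterior draws used for ranking.
#' @param visitPlan passed to [simulateSurveys()].
#' @param seed integer root seed.
#' @return matrix nReplicates x length(monitorParams) of integer ranks.
#' @export
sbcRanks <- function(nReplicates, nSpecies, covariates, spec, config,
                     monitorParams, nRanks = 50L,
                     visitPlan = list(window = c(80L, 200L),
                                      modernVisits = 3L, historicSize = 10L,
                                      historicProb = 0.215), seed = 1L) {
  std <- standardizeCovariates(covariates)
  tm <- .specTerms(spec)
  ranks <- matrix(NA_integer_, nReplicates, length(monitorParams),
                  dimnames = list(NULL, monitorParams))
  for (rep in seq_len(nReplicates)) {
    repSeed <- (seed * 1000L + rep) %% 2147483L
    set.seed(repSeed)
    P <- sum(.nterms(spec))
    hm <- rnorm(P, 0, spec@hypermeanSD)
    hs <- abs(rcauchy(P, 0, spec@hyperSdScale))
    hyper <- .hyperFromVectors(spec, hm, hs)
    params <- drawSpeciesParams(hyper, nSpecies, seed = repSeed + 1L)
    z <- simulateIncidence(params, std, seed = repSeed + 2L)
    dataset <- simulateSurveys(z, params, region = regions(covariates),
                               visitPlan = visitPlan,
                               historicModeProbs = c(standard = 1,
                                                     daily_list = 0,
                                                     first_detection_only = 0),
                               seed = repSeed + 3L)
    cfg <- mcmcConfig(config@nChains, config@nIter, config@nBurnin,
                      config@thin, config@adaptInterval,
                      seed = repSeed + 4L)
    fit <- suppressWarnings(runMCMC(dataset, covariates, spec, cfg))
    truth <- c(hm, hs)
    info <- fit@paramInfo
    names(truth) <- info$param[info$kind %in% c("hypermean", "hypersd")]
    for (m in monitorParams) {
      d <- fit@draws[, m]
      idx <- unique(round(seq(1, length(d), length.out = nRanks)))
      ranks[rep, m] <- sum(d[idx] < truth[[m]])
    }
  }
  ranks
}
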