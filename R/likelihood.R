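# The marginalized MSOM likelihood and priors.

#' Numerically stable inverse logit
#'
#' `invLogit(-x) = 1 - invLogit(x)`; saturates smoothly (never exactly 0 or 1
#' for finite input on log-space paths, which use log(plogis) internally).
#'
#' @param x real vector.
#' @return probabilities in (0, 1).
#' @examples invLogit(0) # 0.5
#' @export
invLogit <- function(x) plogis(x)

# log(invLogit(x)), stable for large |x|
.logInvLogit <- function(x) ifelse(x < 0, x - log1p(exp(x)), -log1p(exp(-x)))

#' Site-level detection probability across repeat visits
#'
#' p* = 1 - (1 - p)^k: the probability a present species is detected at
#' least once over k independent visits with per-visit detection p.
#'
#' @param p per-visit detection probability.
#' @param nVisits number of visits k.
#' @return p* in [0, 1].
#' @examples siteDetectionProb(0.24, 3) # 0.561
#' @export
siteDetectionProb <- function(p, nVisits) {
  if (any(p < 0 | p > 1)) stop("validation error: p must lie in [0, 1]")
  1 - (1 - p)^nVisits
}

#' Logit-linear predictor
#'
#' @param intercept scalar intercept.
#' @param slopes numeric slope vector.
#' @param covariates covariate row of the same length as slopes (all-zero at
#'   a z-score mean site, so the predictor reduces to the intercept).
#' @return intercept + dot product.
#' @export
linearPredictor <- function(intercept, slopes, covariates) {
  if (length(slopes) != length(covariates))
    stop("shape error: ", length(slopes), " slopes vs ",
         length(covariates), " covariates")
  intercept + sum(slopes * covariates)
}

#' Marginal log-likelihood of one species x site detection history
#'
#' Sums the joint probability over the four latent-incidence paths
#' (z1, z2) in {0,1}^2: P(z1 | psi1), P(z2 | z1, phi, gamma) and the
#' Bernoulli detection likelihood per era, skipping masked visits. Kept in
#' log space with log-sum-exp; an era with a detection forces its z = 1
#' (the z = 0 branch contributes zero probability).
#'
#' @param y list of two 0/1 vectors, detections per visit (historic, modern).
#' @param p list of two vectors of per-visit detection probabilities.
#' @param psi,phi,gamma scalar occupancy, persistence, colonization
#'   probabilities.
#' @param mask optional list of two 0/1 vectors; masked visits are skipped.
#' @return scalar log-probability.
#' @export
marginalLoglikUnit <- function(y, p, psi, phi, gamma, mask = NULL) {
  if (is.null(mask)) mask <- lapply(y, function(v) rep(1L, length(v)))
  lldet <- numeric(2); anydet <- logical(2)
  for (t in 1:2) {
    keep <- mask[[t]] == 1L
    yt <- y[[t]][keep]; pt <- p[[t]][keep]
    lldet[t] <- sum(ifelse(yt == 1, log(pt), log1p(-pt)))
    anydet[t] <- any(yt == 1)
  }
  paths <- c(log(psi) + log(phi) + lldet[1] + lldet[2],
             log(psi) + log1p(-phi) + lldet[1] +
               if (anydet[2]) -Inf else 0,
             log1p(-psi) + log(gamma) + lldet[2] +
               if (anydet[1]) -Inf else 0,
             log1p(-psi) + log1p(-gamma) +
               if (anydet[1] || anydet[2]) -Inf else 0)
  m <- max(paths)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(paths - m)))
}

#' Pointwise marginal log-likelihood matrix
#'
#' One entry per species x site, each the latent-incidence-marginalized
#' log-likelihood of that unit's full two-era history. The total
#' log-likelihood is the sum (units are independent given parameters).
#'
#' @param dataset a [DetectionDataset-class].
#' @param covariates a [SiteCovariates-class].
#' @param spec a [ModelSpec-class].
#' @param params a [SpeciesParams-class].
#' @return species x site numeric matrix.
#' @export
loglikMatrix <- function(dataset, covariates, spec, params) {
  dn <- buildDesigns(dataset, covariates, spec)
  .loglikMatrixC(dn, .packParams(params))
}

.loglikMatrixC <- function(dn, C)
  msomLoglikMatrix(dn$y, dn$mask, dn$dim, dn$Xp, dn$Xpsi, dn$Xphi, dn$Xgam,
                   C, dn$nterms)

#' Total marginal log-likelihood of a dataset
#'
#' @inheritParams loglikMatrix
#' @return scalar log-likelihood, the sum of [loglikMatrix()].
#' @export
fullLoglik <- function(dataset, covariates, spec, params)
  sum(loglikMatrix(dataset, covariates, spec, params))

#' Half-Cauchy density
#'
#' The folded Cauchy (Student-t with 1 df censored above zero):
#' f(x; s) = 2 / (pi s (1 + (x/s)^2)) for x >= 0.
#'
#' @param x nonnegative values.
#' @param scale scale s > 0.
#' @param log return log density?
#' @return (log) density; zero (or -Inf) for x < 0.
#' @export
dHalfCauchy <- function(x, scale, log = FALSE) {
  ld <- ifelse(x < 0, -Inf, log(2) + dcauchy(x, 0, scale, log = TRUE))
  if (log) ld else exp(ld)
}

#' Joint log prior density of a parameter state
#'
#' Sum of (i) normal log-densities of the community hypermeans, (ii)
#' half-Cauchy log-densities of the community hyper-SDs, and (iii) normal
#' log-densities of every species coefficient given its family's
#' hyperparameters. Any nonpositive hyper-SD gives -Inf (a rejected state).
#'
#' @param params a [SpeciesParams-class].
#' @param hyper a [CommunityHyperparams-class] (or a list with numeric
#'   vectors `mean`, `sd` over the packed coefficient layout).
#' @param spec a [ModelSpec-class].
#' @return scalar log-density.
#' @export
logPrior <- function(params, hyper, spec) {
  if (is(hyper, "CommunityHyperparams")) {
    hm <- .packHyper(hyper, "mean"); hs <- .packHyper(hyper, "sd")
  } else { hm <- hyper$mean; hs <- hyper$sd }
  if (any(hs <= 0)) return(-Inf)
  C <- .packParams(params)
  sum(dnorm(hm, 0, spec@hypermeanSD, log = TRUE)) +
    sum(dHalfCauchy(hs, spec@hyperSdScale, log = TRUE)) +
    sum(dnorm(t(C), hm, hs, log = TRUE))
}

#' Exact conditional probabilities of the latent-incidence paths
#'
#' For each species x site, the posterior probability of the four (z1, z2)
#' paths given the detection history and a parameter state. Any era with an
#' unmasked detection has z = 1 with probability 1.
#'
#' @inheritParams loglikMatrix
#' @return array species x site x 4, path order (1,1), (1,0), (0,1), (0,0).
#' @export
conditionalIncidenceProbs <- function(dataset, covariates, spec, params) {
  dn <- buildDesigns(dataset, covariates, spec)
  pr <- msomZPathProbs(dn$y, dn$mask, dn$dim, dn$Xp, dn$Xpsi, dn$Xphi,
                       dn$Xgam, .packParams(params), dn$nterms)
  array(pr, c(dn$dim[1], dn$dim[2], 4))
}

#' Draw latent incidence from its exact conditional
#'
#' Samples (z1, z2) per species x site from the four-path conditional given
#' the data and a parameter state (era-pairwise enumeration, no MCMC).
#'
#' @inheritParams loglikMatrix
#' @param seed optional integer seed.
#' @return integer array species x site x 2.
#' @export
drawConditionalIncidence <- function(dataset, covariates, spec, params,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dn <- buildDesigns(dataset, covariates, spec)
  msomDrawZ(dn$y, dn$mask, dn$dim, dn$Xp, dn$Xpsi, dn$Xphi, dn$Xgam,
            .packParams(params), dn$nterms)
}
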