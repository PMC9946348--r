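# Posterior sampling: adaptive Metropolis-within-Gibbs on the marginalized
# model. Species coefficients are updated in family blocks (compiled sweep);
# community hypermeans are conjugate Gibbs draws; hyper-SDs use log-scale
# random-walk Metropolis against the half-Cauchy prior. Proposal scales adapt
# during burn-in only (diminishing to fixed), targeting ~30% block and ~44%
# scalar acceptance.

#' Construct an MCMCConfig
#'
#' @param nChains,nIter,nBurnin,thin chain bookkeeping; retained draws per
#'   chain are floor((nIter - nBurnin) / thin).
#' @param adaptInterval iterations between proposal-scale adaptations during
#'   burn-in.
#' @param seed integer root seed; chain c seeds with seed + c.
#' @return an [MCMCConfig-class].
#' @export
mcmcConfig <- function(nChains = 4L, nIter = 4000L, nBurnin = 1000L,
                       thin = 3L, adaptInterval = 50L, seed = 1L) {
  new("MCMCConfig", nChains = as.integer(nChains), nIter = as.integer(nIter),
      nBurnin = as.integer(nBurnin), thin = as.integer(thin),
      adaptInterval = as.integer(adaptInterval), seed = as.integer(seed))
}

#' Named MCMC presets
#'
#' "desk": 4 chains x 4000 iterations (1000 burn-in, thin 3), the default
#' working scale. "replica": 12 chains x 65000 (40000 burn-in, thin 50),
#' the full published-study configuration, retaining 6000 draws.
#'
#' @param name "desk" or "replica".
#' @param seed integer root seed.
#' @return an [MCMCConfig-class].
#' @export
mcmcPreset <- function(name = c("desk", "replica"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         desk = mcmcConfig(4L, 4000L, 1000L, 3L, seed = seed),
         replica = mcmcConfig(12L, 65000L, 40000L, 50L, seed = seed))
}

.dhcLog <- function(x, scale) log(2) + dcauchy(x, 0, scale, log = TRUE)

#' Sample the MSOM posterior
#'
#' Runs adaptive Metropolis-within-Gibbs on the latent-incidence-marginalized
#' posterior (four-path enumeration per species x site). With `dataset =
#' NULL` the likelihood is empty and the sampler draws from the prior (a
#' validation mode). Families listed in `fixedFamilies` are pinned at their
#' initial values and excluded from hyperparameter updates, which turns the
#' remaining species coefficients into a model with known normal priors
#' (used by the calibration suite).
#'
#' @param dataset a [DetectionDataset-class], or NULL for prior-only.
#' @param covariates a [SiteCovariates-class] (ignored when dataset NULL).
#' @param spec a [ModelSpec-class].
#' @param config an [MCMCConfig-class].
#' @param fixedFamilies character subset of c("p","psi","phi","gamma") to
#'   hold fixed at `init` values.
#' @param updateHyper update community hyperparameters? If FALSE they stay
#'   at their initial values (species coefficients then have fixed normal
#'   priors).
#' @param init optional list with any of `coefs` (species x P matrix or
#'   [SpeciesParams-class]), `hypermean`, `hypersd` (packed vectors).
#'   Defaults: hypermeans 0 plus chain-seeded jitter (SD 0.25), hyper-SDs
#'   0.5, species coefficients drawn from the initial hyperdistribution.
#' @param nSpeciesPriorOnly community size when dataset is NULL.
#' @param monitor parameter kinds whose R-hat is computed (default the
#'   hyperparameters).
#' @return a [PosteriorSamples-class]; warns (not fails) if any monitored
#'   R-hat exceeds 1.1.
#' @export
runMCMC <- function(dataset, covariates, spec, config,
                    fixedFamilies = character(0), updateHyper = TRUE,
                    init = NULL, nSpeciesPriorOnly = 1L,
                    monitor = c("hypermean", "hypersd")) {
  priorOnly <- is.null(dataset)
  if (priorOnly) {
    dn <- .priorOnlyDesigns(spec, nSpeciesPriorOnly)
    species <- sprintf("sp%03d", seq_len(nSpeciesPriorOnly))
  } else {
    dn <- buildDesigns(dataset, covariates, spec)
    species <- speciesNames(dataset)
  }
  S <- dn$dim[1]
  nt <- dn$nterms
  P <- sum(nt)
  fam <- rep(.famNames, nt)
  famFree <- !(.famNames %in% fixedFamilies)
  freeP <- fam %in% .famNames[famFree]
  if (!updateHyper) freeP[] <- FALSE

  nret <- (config@nIter - config@nBurnin) %/% config@thin
  npar <- S * P + 2L * P
  pinfo <- .paramInfo(spec, species)
  stopifnot(nrow(pinfo) == npar)
  allDraws <- vector("list", config@nChains)
  s0 <- spec@hypermeanSD
  hcScale <- spec@hyperSdScale

  for (ch in seq_len(config@nChains)) {
    set.seed(config@seed + ch)
    hm <- init$hypermean %||% rnorm(P, 0, 0.25)
    hs <- init$hypersd %||% rep(0.5, P)
    C <- init$coefs %||% matrix(rnorm(S * P, rep(hm, each = S),
                                      rep(hs, each = S)), S, P)
    if (is(C, "SpeciesParams")) C <- .packParams(C)
    C <- matrix(as.numeric(C), S, P)
    stateLL0 <- sum(.loglikMatrixC(dn, C))
    if (!is.finite(stateLL0))
      stop("init error: non-finite log-likelihood at initialization")
    step <- matrix(0.3, S, 4)
    hstep <- rep(0.3, P)
    stepMu <- rep(0.2, P)
    stepSig <- rep(0.3, P)
    accC <- matrix(0L, S, 4)
    accH <- numeric(P)
    accA <- matrix(0L, P, 2)
    draws <- matrix(NA_real_, nret, npar)
    r <- 0L
    for (it in seq_len(config@nIter)) {
      acc <- msomSweep(C, hm, hs, step, famFree, dn$y, dn$mask, dn$dim,
                       dn$Xp, dn$Xpsi, dn$Xphi, dn$Xgam, dn$nterms)
      accC <- accC + acc
      if (any(freeP)) {
        Ct <- t(C)
        prec <- 1 / s0^2 + S / hs^2
        pm <- (rowSums(Ct) / hs^2) / prec
        draw <- rnorm(P, pm, sqrt(1 / prec))
        hm[freeP] <- draw[freeP]
        prop <- hs * exp(hstep * rnorm(P))
        logr <- rowSums(dnorm(Ct, hm, prop, log = TRUE)) -
          rowSums(dnorm(Ct, hm, hs, log = TRUE)) +
          .dhcLog(prop, hcScale) - .dhcLog(hs, hcScale) +
          log(prop) - log(hs)
        ok <- freeP & (log(runif(P)) < logr)
        hs[ok] <- prop[ok]
        accH <- accH + ok
        # interleaved non-centered move: breaks the hyper-SD funnel
        accA <- accA + msomAsisUpdate(C, hm, hs, stepMu, stepSig, freeP,
                                      s0, hcScale, dn$y, dn$mask, dn$dim,
                                      dn$Xp, dn$Xpsi, dn$Xphi, dn$Xgam,
                                      dn$nterms)
      }
      if (it <= config@nBurnin && it %% config@adaptInterval == 0L) {
        rate <- accC / config@adaptInterval
        step <- pmin(pmax(step * exp(rate - 0.3), 1e-3), 10)
        accC[] <- 0L
        rateH <- accH / config@adaptInterval
        hstep <- pmin(pmax(hstep * exp(rateH - 0.44), 1e-3), 10)
        accH[] <- 0
        rateA <- accA / config@adaptInterval
        stepMu <- pmin(pmax(stepMu * exp(rateA[, 1] - 0.44), 1e-3), 10)
        stepSig <- pmin(pmax(stepSig * exp(rateA[, 2] - 0.44), 1e-3), 10)
        accA[] <- 0L
      }
      if (it > config@nBurnin &&
          (it - config@nBurnin) %% config@thin == 0L) {
        r <- r + 1L
        draws[r, ] <- c(C, hm, hs)
      }
    }
    allDraws[[ch]] <- draws[seq_len(nret), , drop = FALSE]
  }

  draws <- do.call(rbind, allDraws)
  colnames(draws) <- pinfo$param
  chain <- rep(seq_len(config@nChains), each = nret)
  iteration <- rep(seq_len(nret), config@nChains)

  monIdx <- which(pinfo$kind %in% monitor & freeP[.colCoord(pinfo, nt, S)])
  rhat <- NULL
  if (length(monIdx) && config@nChains >= 2L && nret >= 2L) {
    perChain <- lapply(seq_len(config@nChains), function(ch)
      draws[chain == ch, monIdx, drop = FALSE])
    rhat <- gelmanRubin(perChain)
  }
  ps <- new("PosteriorSamples", draws = draws, chain = chain,
            iteration = iteration, paramInfo = pinfo, spec = spec,
            config = config, designs = dn,
            dataset = if (priorOnly) NULL else dataset,
            covariates = if (priorOnly) NULL else covariates,
            stdInfo = dn$info,
            diagnostics = list(rhat = rhat),
            provenance = list(dims = dn$dim,
                              checksum = sum(dn$y) + sum(dn$mask)))
  if (!is.null(rhat) && any(rhat > 1.1))
    warning(sprintf("convergence: %d monitored parameter(s) have R-hat > 1.1 (max %.3f)",
                    sum(rhat > 1.1), max(rhat)))
  ps
}

# map paramInfo rows to the packed-coefficient coordinate (for hyper rows,
# the coordinate within 1..P); used to restrict monitoring to free families
.colCoord <- function(pinfo, nt, S) {
  P <- sum(nt)
  n <- nrow(pinfo)
  coord <- integer(n)
  coord[seq_len(S * P)] <- rep(seq_len(P), each = S)
  coord[S * P + seq_len(2L * P)] <- rep(seq_len(P), 2L)
  coord
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-part form: with m chains of n draws, W the mean within-chain
#' variance and B/n the variance of chain means, R-hat = sqrt(((n-1)/n W +
#' B/n) / W). Values near 1 indicate the chains are sampling the same
#' distribution; the conventional acceptance rule is R-hat <= 1.1.
#'
#' @param x list of per-chain draw matrices (iterations x parameters) with
#'   equal dimensions, or a [PosteriorSamples-class].
#' @param pattern optional parameter-label regex (PosteriorSamples method).
#' @return named vector of R-hat per parameter.
#' @export
gelmanRubin <- function(x, pattern = NULL) {
  if (is(x, "PosteriorSamples")) {
    keep <- if (is.null(pattern)) seq_len(ncol(x@draws)) else
      grep(pattern, colnames(x@draws))
    x <- lapply(seq_len(x@config@nChains), function(ch)
      x@draws[x@chain == ch, keep, drop = FALSE])
  }
  m <- length(x)
  if (m < 2L) stop("diagnostic error: need >= 2 chains")
  n <- nrow(x[[1]])
  if (n < 2L) stop("diagnostic error: need >= 2 draws per chain")
  means <- sapply(x, colMeans)
  vars <- sapply(x, function(d) apply(d, 2, var))
  means <- matrix(means, ncol = m); vars <- matrix(vars, ncol = m)
  W <- rowMeans(vars)
  B.n <- apply(means, 1, var)  # = B/n
  vhat <- (n - 1) / n * W + B.n
  r <- sqrt(vhat / W)
  r[W == 0 & B.n == 0] <- 1
  names(r) <- colnames(x[[1]])
  r
}

#' Extract per-draw species coefficient arrays
#'
#' @param ps a [PosteriorSamples-class].
#' @return list of arrays (draws x species x terms), one per family.
#' @export
coefDraws <- function(ps) {
  dn <- ps@designs
  S <- dn$dim[1]; nt <- dn$nterms
  N <- nrow(ps@draws)
  tm <- .specTerms(ps@spec)
  species <- unique(ps@paramInfo$species[ps@paramInfo$kind == "species"])
  out <- list()
  off <- 0L
  for (f in .famNames) {
    a <- array(ps@draws[, off + seq_len(S * nt[[f]])],
               c(N, S, nt[[f]]),
               dimnames = list(NULL, species, tm[[f]]))
    out[[f]] <- a
    off <- off + S * nt[[f]]
  }
  out
}

#' Hyperparameter draws
#'
#' @param ps a [PosteriorSamples-class].
#' @return list with matrices `mean` and `sd` (draws x packed coordinates,
#'   labelled family.term).
#' @export
hyperDraws <- function(ps) {
  info <- ps@paramInfo
  list(mean = ps@draws[, info$kind == "hypermean", drop = FALSE],
       sd = ps@draws[, info$kind == "hypersd", drop = FALSE])
}

#' Posterior mean, equal-tailed credible interval and significance
#'
#' @param draws numeric vector, or matrix with one column per quantity
#'   (rows are draws).
#' @param level credible level (default 0.95, equal-tailed percentiles).
#' @return data.frame with mean, lower, upper, significant (interval
#'   excludes 0).
#' @export
posteriorSummary <- function(draws, level = 0.95) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  a <- (1 - level) / 2
  q <- apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(mean = colMeans(draws), lower = q[1, ], upper = q[2, ])
  out$significant <- out$lower > 0 | out$upper < 0
  cn <- colnames(draws)
  if (!is.null(cn) && !anyDuplicated(cn)) rownames(out) <- cn
  out
}

#' Summarize a function of the parameters over the posterior
#'
#' Evaluates `f` on each retained draw (passed as a named parameter vector)
#' and returns the posterior mean and equal-tailed 95% credible interval of
#' its result.
#'
#' @param ps a [PosteriorSamples-class].
#' @param f function of one draw (named numeric vector) returning a numeric
#'   vector.
#' @param level credible level.
#' @return data.frame as [posteriorSummary()].
#' @export
summarizeFunction <- function(ps, f, level = 0.95) {
  vals <- t(apply(ps@draws, 1, f))
  if (nrow(vals) == 1L && nrow(ps@draws) > 1L) vals <- t(vals)
  posteriorSummary(vals, level)
}

#' Widely applicable information criterion (WAIC)
#'
#' Pointwise unit = species x site marginal (latent-incidence-integrated)
#' likelihood. WAIC = -2 (lppd - pWAIC) with the variance form of the
#' effective-parameter count (pWAIC2 = sum of pointwise posterior variances
#' of the log-likelihood).
#'
#' @param ps a [PosteriorSamples-class] from a data fit.
#' @param thinTo optionally subsample to at most this many draws (evenly)
#'   before evaluating pointwise likelihoods.
#' @return list: waic, lppd, pWAIC, and the pointwise data.frame.
#' @export
waic <- function(ps, thinTo = NULL) {
  if (is.null(ps@dataset)) stop("estimation error: WAIC needs a data fit")
  N <- nrow(ps@draws)
  if (N < 2L) stop("estimation error: need >= 2 draws")
  idx <- seq_len(N)
  if (!is.null(thinTo) && thinTo < N)
    idx <- unique(round(seq(1, N, length.out = thinTo)))
  dn <- ps@designs
  S <- dn$dim[1]; P <- sum(dn$nterms)
  ll <- matrix(NA_real_, length(idx), S * dn$dim[2])
  for (i in seq_along(idx)) {
    C <- matrix(ps@draws[idx[i], seq_len(S * P)], S, P)
    ll[i, ] <- as.vector(.loglikMatrixC(dn, C))
  }
  waicFromPointwise(ll)
}

#' WAIC from a pointwise log-likelihood matrix
#'
#' @param ll matrix, draws x units, of pointwise log-likelihoods.
#' @return list: waic, lppd, pWAIC, pointwise data.frame (lppd_i, pwaic_i,
#'   waic_i with waic = sum(waic_i)).
#' @export
waicFromPointwise <- function(ll) {
  if (nrow(ll) < 2L) stop("estimation error: need >= 2 draws")
  n <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx)))) # log mean exp, stable
  pwaic_i <- apply(ll, 2, var)
  waic_i <- -2 * (lppd_i - pwaic_i)
  list(waic = sum(waic_i), lppd = sum(lppd_i), pWAIC = sum(pwaic_i),
       pointwise = data.frame(lppd = lppd_i, pwaic = pwaic_i,
                              waic = waic_i))
}

#' Flat CSV export of posterior draws
#'
#' Long format (chain, iteration, parameter, value), optionally restricted
#' by a parameter-label regex — hyperparameters only by default, since the
#' full species-coefficient table is large.
#'
#' @param ps a [PosteriorSamples-class].
#' @param path output CSV path.
#' @param pattern parameter-label regex (default: the hyperparameters).
#' @return invisibly, the path.
#' @export
writePosterior <- function(ps, path, pattern = "^(mu|sd)\\.") {
  keep <- grep(pattern, colnames(ps@draws))
  df <- data.frame(chain = rep(ps@chain, length(keep)),
                   iteration = rep(ps@iteration, length(keep)),
                   parameter = rep(colnames(ps@draws)[keep],
                                   each = nrow(ps@draws)),
                   value = as.vector(ps@draws[, keep]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute latent incidence for every retained draw
#'
#' Re-imputes z from its exact conditional (four-path enumeration) per
#' retained draw; this is the incidence posterior all diversity metrics use.
#'
#' @param ps a [PosteriorSamples-class] from a data fit.
#' @param seed integer seed.
#' @param thinTo optionally subsample draws as in [waic()].
#' @return integer array draws x species x site x era, with the draw index
#'   used stored as attribute "drawIndex".
#' @export
drawIncidence <- function(ps, seed = 1L, thinTo = NULL) {
  if (is.null(ps@dataset))
    stop("estimation error: incidence needs a data fit")
  set.seed(as.integer(seed))
  dn <- ps@designs
  S <- dn$dim[1]; J <- dn$dim[2]; P <- sum(dn$nterms)
  N <- nrow(ps@draws)
  idx <- seq_len(N)
  if (!is.null(thinTo) && thinTo < N)
    idx <- unique(round(seq(1, N, length.out = thinTo)))
  z <- array(NA_integer_, c(length(idx), S, J, 2))
  for (i in seq_along(idx)) {
    C <- matrix(ps@draws[idx[i], seq_len(S * P)], S, P)
    z[i, , , ] <- msomDrawZ(dn$y, dn$mask, dn$dim, dn$Xp, dn$Xpsi, dn$Xphi,
                            dn$Xgam, C, dn$nterms)
  }
  attr(z, "drawIndex") <- idx
  z
}
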