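# Independent oracles and small fixture builders shared across tests.

# Brute-force enumeration of the species x site marginal likelihood over the
# four (z1, z2) paths, in plain probability space (independent of the
# package's log-space implementation).
enumLoglikUnit <- function(y, p, psi, phi, gamma, mask = NULL) {
  if (is.null(mask)) mask <- lapply(y, function(v) rep(1L, length(v)))
  obsProb <- function(t, z) {
    keep <- mask[[t]] == 1L
    yt <- y[[t]][keep]; pt <- p[[t]][keep]
    prob <- ifelse(yt == 1, z * pt, 1 - z * pt)
    prod(prob)
  }
  tot <- 0
  for (z1 in 0:1) for (z2 in 0:1) {
    pz1 <- if (z1 == 1) psi else 1 - psi
    pz2 <- if (z1 == 1) (if (z2 == 1) phi else 1 - phi)
           else (if (z2 == 1) gamma else 1 - gamma)
    tot <- tot + pz1 * pz2 * obsProb(1, z1) * obsProb(2, z2)
  }
  log(tot)
}

# Central finite difference of the occupancy change delta-psi with respect
# to one covariate's change, through the logit-linear turnover models and
# the Markov update (independent of the closed-form derivative).
finiteDiffSensitivity <- function(psiH, phiIntercept, deltaSlope,
                                  gammaIntercept, epsilonSlope, x = 0,
                                  h = 1e-4) {
  dpsi <- function(xx) {
    phi <- plogis(phiIntercept + deltaSlope * xx)
    gam <- plogis(gammaIntercept + epsilonSlope * xx)
    psiH * phi + (1 - psiH) * gam - psiH
  }
  (dpsi(x + h) - dpsi(x - h)) / (2 * h)
}

# A tiny deterministic two-region covariate object.
toyCovariates <- function(J = 6L, seed = 42L) {
  set.seed(seed)
  h <- cbind(temperature = rnorm(J, 16, 1.5),
             precipitation = rnorm(J, 450, 90),
             water = runif(J, 0, 8), urban = runif(J, 0, 10),
             agriculture = runif(J, 0, 20))
  m <- h + cbind(rnorm(J, 1.2, 0.4), rnorm(J, -30, 20), rnorm(J, 0, 1),
                 runif(J, 0, 25), runif(J, 0, 10))
  m[, 3:5] <- pmin(pmax(m[, 3:5], 0), 100)
  siteCovariates(h, m, sprintf("site%03d", 1:J),
                 rep(c("A", "B"), length.out = J))
}

# Hand-built dataset: S species x J sites, fixed visit counts, days spread
# through the season.
toyDataset <- function(S = 3L, J = 4L, nHist = 2L, nMod = 3L, seed = 99L,
                       region = NULL) {
  set.seed(seed)
  K <- max(nHist, nMod)
  y <- array(rbinom(S * J * K * 2, 1, 0.4), c(S, J, K, 2))
  nVisits <- cbind(historic = rep(nHist, J), modern = rep(nMod, J))
  visitDay <- array(NA_integer_, c(J, K, 2))
  for (t in 1:2) for (j in 1:J)
    visitDay[j, seq_len(nVisits[j, t]), t] <-
      100L + 10L * j + seq_len(nVisits[j, t])
  detectionDataset(y, visitDay, nVisits, sprintf("sp%02d", 1:S),
                   sprintf("site%03d", 1:J),
                   region %||% rep(c("A", "B"), length.out = J))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random species coefficients matching a spec's design.
randomParams <- function(spec, S, seed = 1L, sd = 0.8) {
  set.seed(seed)
  tm <- list(p = spec@pTerms, psi = spec@psiTerms, phi = spec@phiTerms,
             gamma = spec@gammaTerms)
  mats <- lapply(tm, function(terms)
    matrix(rnorm(S * length(terms), 0, sd), S,
           dimnames = list(sprintf("sp%02d", 1:S), terms)))
  new("SpeciesParams", p = mats$p, psi = mats$psi, phi = mats$phi,
      gamma = mats$gamma)
}

# Evaluate the package likelihood unit-by-unit from raw design pieces, used
# to cross-check the compiled matrix version against the R scalar version.
unitProbsFromParams <- function(dataset, covariates, spec, params, i, j) {
  dn <- buildDesigns(dataset, covariates, spec)
  K <- dn$dim[3]; J <- dn$dim[2]
  Xp <- array(dn$Xp, c(J, K, 2, dn$nterms[[1]]))
  p <- lapply(1:2, function(t)
    plogis(sapply(seq_len(K), function(k) sum(Xp[j, k, t, ] * params@p[i, ]))))
  list(p = p,
       psi = plogis(sum(dn$Xpsi[j, ] * params@psi[i, ])),
       phi = plogis(sum(dn$Xphi[j, ] * params@phi[i, ])),
       gamma = plogis(sum(dn$Xgam[j, ] * params@gamma[i, ])),
       y = lapply(1:2, function(t) dataset@y[i, j, , t]),
       mask = lapply(1:2, function(t) dataset@mask[i, j, , t]))
}

writeDetectionCSV <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
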