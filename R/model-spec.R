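# Model specification and design-matrix construction.

#' Specify the dynamic MSOM design and priors
#'
#' Detection p is logit-linear in standardized Julian day, its square
#' (squared after scaling) and a historic-era indicator; initial occupancy
#' psi1 in the standardized historic era covariates; persistence phi and
#' colonization gamma in the standardized modern-minus-historic deltas.
#' Community hypermeans get Normal(0, hypermeanSD^2) priors and hyper-SDs
#' half-Cauchy(hyperSdScale) priors (a Student-t with 1 df censored above
#' zero). The literature's "2.25" prior constant is read as a variance by
#' default (SD 1.5, the weakly-informative logit-scale choice);
#' `priorConvention = "precision"` reads it as a precision (SD 2/3).
#'
#' @param pTerms detection terms, subset of c("intercept","day","day2","era").
#' @param psiCovariates era-level covariates for initial occupancy.
#' @param turnoverCovariates delta covariates for persistence/colonization
#'   (without the "d_" prefix).
#' @param priorConvention "variance" or "precision".
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(pTerms = c("intercept", "day", "day2", "era"),
                      psiCovariates = .covNames,
                      turnoverCovariates = .covNames,
                      priorConvention = c("variance", "precision")) {
  priorConvention <- match.arg(priorConvention)
  s <- if (priorConvention == "variance") sqrt(2.25) else 1 / sqrt(2.25)
  dTerms <- paste0("d_", turnoverCovariates, recycle0 = TRUE)
  new("ModelSpec", pTerms = pTerms,
      psiTerms = c("intercept", psiCovariates),
      phiTerms = c("intercept", dTerms),
      gammaTerms = c("intercept", dTerms),
      priorConvention = priorConvention, hypermeanSD = s, hyperSdScale = s)
}

#' Serialize a ModelSpec to/from YAML
#'
#' @param spec a [ModelSpec-class].
#' @param path YAML file path.
#' @return `writeModelSpec` returns the path invisibly; `readModelSpec`
#'   returns a reconstructed, validated [ModelSpec-class].
#' @export
writeModelSpec <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("configuration error: the 'yaml' package is required")
  yaml::write_yaml(list(pTerms = spec@pTerms,
                        psiCovariates = spec@psiTerms[-1],
                        turnoverCovariates = sub("^d_", "",
                                                 spec@phiTerms[-1]),
                        priorConvention = spec@priorConvention), path)
  invisible(path)
}

#' @rdname writeModelSpec
#' @export
readModelSpec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("configuration error: the 'yaml' package is required")
  cfg <- yaml::read_yaml(path)
  modelSpec(pTerms = unlist(cfg$pTerms),
            psiCovariates = unlist(cfg$psiCovariates) %||% character(0),
            turnoverCovariates = unlist(cfg$turnoverCovariates) %||%
              character(0),
            priorConvention = cfg$priorConvention %||% "variance")
}

.specTerms <- function(spec)
  list(p = spec@pTerms, psi = spec@psiTerms, phi = spec@phiTerms,
       gamma = spec@gammaTerms)

.nterms <- function(spec) vapply(.specTerms(spec), length, 1L)

# parameter labels for one coefficient layout
.paramInfo <- function(spec, species) {
  tm <- .specTerms(spec)
  sp <- data.frame(kind = "species",
                   family = rep(rep(.famNames, .nterms(spec)),
                                each = length(species)),
                   term = rep(unlist(tm, use.names = FALSE),
                              each = length(species)),
                   species = rep(species,
                                 times = sum(.nterms(spec))))
  sp$param <- sprintf("%s.%s[%s]", sp$family, sp$term, sp$species)
  hy <- data.frame(kind = rep(c("hypermean", "hypersd"),
                              each = sum(.nterms(spec))),
                   family = rep(rep(.famNames, .nterms(spec)), 2),
                   term = rep(unlist(tm, use.names = FALSE), 2),
                   species = NA_character_)
  hy$param <- sprintf("%s.%s.%s", ifelse(hy$kind == "hypermean", "mu", "sd"),
                      hy$family, hy$term)
  rbind(sp, hy)[, c("param", "kind", "family", "term", "species")]
}

#' Build the design arrays the likelihood consumes
#'
#' Standardizes covariates (pooled over all sites, population SD) and Julian
#' day (pooled over all recorded visits of both eras; the quadratic term is
#' the square of the scaled day), then assembles the per-visit detection
#' design and the site-level psi1/phi/gamma designs in the term order of the
#' ModelSpec. The era indicator is 1 for historic visits.
#'
#' @param dataset a [DetectionDataset-class].
#' @param covariates a [SiteCovariates-class] over the same sites.
#' @param spec a [ModelSpec-class].
#' @return list with y/mask vectors, dim, design arrays Xp (site x visit x
#'   era x terms), Xpsi/Xphi/Xgam (site x terms), nterms, the
#'   [StandardizationInfo-class] (including the day row) and the z-scored
#'   covariate matrices.
#' @export
buildDesigns <- function(dataset, covariates, spec) {
  if (!identical(siteNames(dataset), siteNames(covariates)))
    stop("integrity error: dataset and covariate sites differ")
  S <- nSpecies(dataset); J <- nSites(dataset); K <- dim(dataset@y)[3]
  std <- standardizeCovariates(covariates)

  days <- numeric(0)
  for (t in 1:2) for (j in seq_len(J)) {
    nv <- dataset@nVisits[j, t]
    if (nv > 0L) days <- c(days, dataset@visitDay[j, seq_len(nv), t])
  }
  dm <- mean(days); dsd <- .popSD(days)
  if (!is.finite(dsd) || dsd == 0) dsd <- 1  # single shared day: centered only
  info <- std$info
  info@table <- rbind(info@table,
                      data.frame(covariate = "day", mean = dm, sd = dsd,
                                 group = "visit"))

  zday <- (dataset@visitDay - dm) / dsd
  zday[is.na(zday)] <- 0
  Pp <- length(spec@pTerms)
  Xp <- array(0, c(J, K, 2, Pp))
  for (p in seq_len(Pp)) {
    Xp[, , , p] <- switch(spec@pTerms[p],
      intercept = 1,
      day = zday,
      day2 = zday^2,
      era = rep(c(1, 0), each = J * K),
      stop("configuration error: unknown detection term '",
           spec@pTerms[p], "'"))
  }

  siteDesign <- function(terms, zmat) {
    X <- matrix(0, J, length(terms), dimnames = list(NULL, terms))
    for (tm in terms) {
      if (tm == "intercept") X[, tm] <- 1
      else if (tm %in% colnames(zmat)) X[, tm] <- zmat[, tm]
      else stop("configuration error: unknown covariate term '", tm, "'")
    }
    X
  }
  colnames(std$delta) <- paste0("d_", .covNames)
  list(y = as.integer(dataset@y), mask = as.integer(dataset@mask),
       dim = c(S, J, K), Xp = as.numeric(Xp),
       Xpsi = siteDesign(spec@psiTerms, std$historic),
       Xphi = siteDesign(spec@phiTerms, std$delta),
       Xgam = siteDesign(spec@gammaTerms, std$delta),
       nterms = .nterms(spec), info = info,
       zHistoric = std$historic, zDelta = std$delta)
}

# empty-data designs: the posterior is then the prior
.priorOnlyDesigns <- function(spec, nSpeciesPrior) {
  nt <- .nterms(spec)
  list(y = integer(0), mask = integer(0),
       dim = c(nSpeciesPrior, 0L, 1L), Xp = numeric(0),
       Xpsi = matrix(0, 0, nt[2]), Xphi = matrix(0, 0, nt[3]),
       Xgam = matrix(0, 0, nt[4]), nterms = nt, info = NULL,
       zHistoric = NULL, zDelta = NULL)
}

# SpeciesParams <-> flat coefficient matrix (families contiguous, order
# p, psi, phi, gamma as the C++ core expects)
.packParams <- function(params)
  cbind(params@p, params@psi, params@phi, params@gamma)

.unpackParams <- function(C, spec, species = NULL) {
  tm <- .specTerms(spec)
  off <- cumsum(c(0, .nterms(spec)))
  g <- function(i) {
    m <- C[, (off[i] + 1):off[i + 1], drop = FALSE]
    colnames(m) <- tm[[i]]
    rownames(m) <- species
    m
  }
  new("SpeciesParams", p = g(1), psi = g(2), phi = g(3), gamma = g(4))
}

.packHyper <- function(hyper, row)
  c(hyper@p[row, ], hyper@psi[row, ], hyper@phi[row, ], hyper@gamma[row, ])

.hyperFromVectors <- function(spec, mean, sd) {
  tm <- .specTerms(spec)
  off <- cumsum(c(0, .nterms(spec)))
  g <- function(i) {
    idx <- (off[i] + 1):off[i + 1]
    matrix(c(mean[idx], sd[idx]), 2, byrow = TRUE,
           dimnames = list(c("mean", "sd"), tm[[i]]))
  }
  new("CommunityHyperparams", p = g(1), psi = g(2), phi = g(3), gamma = g(4))
}
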