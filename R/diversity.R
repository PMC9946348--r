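# Posterior diversity-change metrics, computed from imputed latent
# incidence so imperfect detection and parameter uncertainty propagate.

#' Species richness per site for one incidence draw
#'
#' @param zDraw integer array species x site x era (one posterior draw).
#' @param era "historic" or "modern".
#' @return integer vector of species counts per site.
#' @export
richness <- function(zDraw, era = c("historic", "modern")) {
  era <- match.arg(era)
  colSums(zDraw[, , match(era, .eraNames), drop = FALSE][, , 1])
}

#' Posterior change in species richness per site
#'
#' @param zDraws integer array draws x species x site x era, as from
#'   [drawIncidence()].
#' @param level credible level.
#' @return list: `perSite` data.frame (historic/modern mean richness and the
#'   change with CRI) and `regional` means if a region factor is supplied.
#' @param region optional factor per site for regional averaging.
#' @export
richnessChange <- function(zDraws, region = NULL, level = 0.95) {
  rh <- apply(zDraws[, , , 1, drop = FALSE], c(1, 3), sum)
  rm <- apply(zDraws[, , , 2, drop = FALSE], c(1, 3), sum)
  ch <- rm - rh
  s <- posteriorSummary(ch, level)
  perSite <- data.frame(site = seq_len(ncol(ch)),
                        historic = colMeans(rh), modern = colMeans(rm),
                        change = s$mean, lower = s$lower, upper = s$upper)
  out <- list(perSite = perSite)
  if (!is.null(region)) {
    regDraw <- sapply(levels(as.factor(region)), function(r)
      rowMeans(ch[, as.factor(region) == r, drop = FALSE]))
    out$regional <- cbind(region = levels(as.factor(region)),
                          posteriorSummary(matrix(regDraw, nrow(ch)), level))
  }
  out
}

#' Per-species regional occupancy change with significance class
#'
#' Occupancy is the fraction of a region's sites with latent incidence 1.
#' Per draw, change = modern fraction - historic fraction; the class is
#' "increase" if the CRI lower bound is > 0, "decrease" if the upper bound
#' is < 0, otherwise "none".
#'
#' @param zDraws integer array draws x species x site x era.
#' @param region factor per site.
#' @param which region level to evaluate (default: all sites as one region).
#' @param level credible level.
#' @return data.frame per species: mean change, CRI, class.
#' @export
occupancyChange <- function(zDraws, region = NULL, which = NULL,
                            level = 0.95) {
  J <- dim(zDraws)[3]
  keep <- seq_len(J)
  if (!is.null(which)) {
    if (is.null(region)) stop("configuration error: 'which' needs 'region'")
    keep <- which(as.factor(region) == which)
    if (!length(keep)) stop("configuration error: empty region '", which, "'")
  }
  if (dim(zDraws)[1] < 2L) stop("estimation error: need >= 2 draws")
  occ <- function(t) apply(zDraws[, , keep, t, drop = FALSE], c(1, 2), mean)
  ch <- occ(2) - occ(1)
  s <- posteriorSummary(ch, level)
  cls <- ifelse(s$lower > 0, "increase", ifelse(s$upper < 0, "decrease",
                                                "none"))
  data.frame(species = seq_len(ncol(ch)), change = s$mean, lower = s$lower,
             upper = s$upper, class = cls)
}

#' Partition temporal beta diversity (Sorensen = nestedness + turnover)
#'
#' From the shared (a), historic-only (b) and modern-only (c) species counts
#' of one site: beta_sor = (b+c)/(2a+b+c); beta_sim = min(b,c)/(a+min(b,c))
#' (turnover, Simpson); beta_nested = beta_sor - beta_sim (species-loss
#' component; algebraically the nested-resultant index). Vectorized over
#' sites/draws.
#'
#' @param a,b,c nonnegative integer vectors, not all zero elementwise.
#' @return data.frame with columns sor, nested, sim, each in [0, 1].
#' @export
betaPartition <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0))
    stop("validation error: counts must be nonnegative")
  if (any(a + b + c == 0))
    stop("undefined-input error: site empty in both eras (a = b = c = 0)")
  sor <- (b + c) / (2 * a + b + c)
  # min(b,c) = 0 means no balanced replacement: turnover 0 (also covers the
  # 0/0 case a = 0 with one era empty, which is pure nestedness)
  sim <- ifelse(pmin(b, c) == 0, 0, pmin(b, c) / (a + pmin(b, c)))
  data.frame(sor = sor, nested = sor - sim, sim = sim)
}

#' Posterior temporal dissimilarity partition per site
#'
#' Computes (a, b, c) per site per incidence draw from the two eras and
#' applies [betaPartition()]. Site-draws empty in both eras are undefined;
#' they are excluded from the summaries and counted in `nUndefined`.
#'
#' @param zDraws integer array draws x species x site x era.
#' @param region optional factor per site for regional assemblage means.
#' @param level credible level.
#' @return list: `perSite` data.frame (mean + CRI for each partition),
#'   `regional` data.frame of regional means per draw summarized, and
#'   `nUndefined`.
#' @export
temporalDissimilarity <- function(zDraws, region = NULL, level = 0.95) {
  if (dim(zDraws)[1] < 2L) stop("estimation error: need >= 2 draws")
  z1 <- zDraws[, , , 1, drop = FALSE][, , , 1]
  z2 <- zDraws[, , , 2, drop = FALSE][, , , 1]
  a <- apply(z1 * z2, c(1, 3), sum)
  b <- apply(z1 * (1 - z2), c(1, 3), sum)
  cc <- apply((1 - z1) * z2, c(1, 3), sum)
  empty <- a + b + cc == 0
  nUndefined <- sum(empty)
  a[empty] <- NA
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- ifelse(pmin(b, cc) == 0, 0, pmin(b, cc) / (a + pmin(b, cc)))
  sim[empty] <- NA
  nested <- sor - sim
  summ <- function(m) {
    q <- apply(m, 2, quantile, probs = c(0.5 - level / 2, 0.5 + level / 2),
               na.rm = TRUE, names = FALSE)
    data.frame(mean = colMeans(m, na.rm = TRUE), lower = q[1, ],
               upper = q[2, ])
  }
  perSite <- cbind(site = seq_len(ncol(sor)),
                   stats::setNames(summ(sor), paste0("sor_",
                                                     c("mean", "lower", "upper"))),
                   stats::setNames(summ(nested), paste0("nested_",
                                                        c("mean", "lower", "upper"))),
                   stats::setNames(summ(sim), paste0("sim_",
                                                     c("mean", "lower", "upper"))))
  out <- list(perSite = perSite, nUndefined = nUndefined)
  if (!is.null(region)) {
    region <- as.factor(region)
    reg <- lapply(list(sor = sor, nested = nested, sim = sim), function(m)
      sapply(levels(region), function(r)
        rowMeans(m[, region == r, drop = FALSE], na.rm = TRUE)))
    out$regional <- do.call(rbind, lapply(names(reg), function(nm)
      cbind(metric = nm, region = levels(region),
            posteriorSummary(matrix(reg[[nm]], nrow(sor)), level))))
  }
  out
}

#' Regional assemblage occupancy summary
#'
#' Mean occupancy across the assemblage per era, with the across-species
#' dispersion (SD and SE = SD/sqrt(n), a descriptive spread across species)
#' and the posterior CRI of the assemblage mean (model uncertainty) reported
#' separately and labelled.
#'
#' @param zDraws integer array draws x species x site x era.
#' @param region factor per site; @param which region level.
#' @param which region level to evaluate.
#' @param level credible level.
#' @return data.frame, one row per era plus one for the change.
#' @export
assemblageOccupancy <- function(zDraws, region = NULL, which = NULL,
                                level = 0.95) {
  keep <- seq_len(dim(zDraws)[3])
  if (!is.null(which)) keep <- which(as.factor(region) == which)
  occ <- lapply(1:2, function(t)
    apply(zDraws[, , keep, t, drop = FALSE], c(1, 2), mean))
  sp <- lapply(occ, colMeans)           # posterior-mean occupancy per species
  asm <- lapply(occ, rowMeans)          # assemblage mean per draw
  ch <- asm[[2]] - asm[[1]]
  sm <- posteriorSummary(cbind(asm[[1]], asm[[2]], ch), level)
  data.frame(quantity = c("historic", "modern", "change"),
             mean = sm$mean, lower = sm$lower, upper = sm$upper,
             acrossSpeciesSD = c(sd(sp[[1]]), sd(sp[[2]]),
                                 sd(sp[[2]] - sp[[1]])),
             acrossSpeciesSE = c(sd(sp[[1]]), sd(sp[[2]]),
                                 sd(sp[[2]] - sp[[1]])) /
               sqrt(length(sp[[1]])))
}
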