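# Reading, encoding and standardizing resurvey data.

#' Construct a DetectionDataset from components
#'
#' Pads ragged visit structures: cells beyond a site's recorded visit count
#' are masked and their y stored as 0. An explicit mask (e.g. from
#' first-detection-only encoding) can be supplied; it is intersected with the
#' visit-padding mask.
#'
#' @param y integer array species x site x visit x era (era 1 = historic).
#' @param visitDay integer array site x visit x era of Julian days.
#' @param nVisits integer matrix site x era of recorded visit counts.
#' @param species,sites character labels.
#' @param region factor or character of length n_sites.
#' @param mode character matrix site x era ("standard", "daily_list",
#'   "first_detection_only"); defaults to "standard" everywhere.
#' @param mask optional integer array like y; 0 marks unavailable cells.
#' @return a validated [DetectionDataset-class].
#' @export
detectionDataset <- function(y, visitDay, nVisits, species, sites, region,
                             mode = NULL, mask = NULL) {
  d <- dim(y)
  storage.mode(y) <- "integer"
  pad <- array(0L, d)
  for (t in 1:2)
    for (j in seq_len(d[2]))
      if (nVisits[j, t] > 0L) pad[, j, seq_len(nVisits[j, t]), t] <- 1L
  if (is.null(mask)) mask <- pad else {
    storage.mode(mask) <- "integer"
    mask <- mask * pad
  }
  y <- y * mask
  if (is.null(mode))
    mode <- matrix("standard", d[2], 2, dimnames = list(NULL, .eraNames))
  storage.mode(visitDay) <- "integer"
  storage.mode(nVisits) <- "integer"
  dimnames(y) <- dimnames(mask) <-
    list(species, sites, NULL, .eraNames)
  dimnames(visitDay) <- list(sites, NULL, .eraNames)
  dimnames(nVisits) <- list(sites, .eraNames)
  new("DetectionDataset", y = y, mask = mask, visitDay = visitDay,
      nVisits = nVisits, species = as.character(species),
      sites = as.character(sites), region = as.factor(region), mode = mode)
}

#' Reduce per-visit counts to detection/nondetection
#'
#' @param counts nonnegative integer vector of individuals counted per visit.
#' @return integer 0/1 vector, 1 wherever count > 0.
#' @examples reduceCounts(c(0, 3, 1)) # 0 1 1
#' @export
reduceCounts <- function(counts) {
  if (any(counts < 0)) stop("validation error: negative count")
  as.integer(counts > 0)
}

#' Encode per-day species lists as detection histories
#'
#' Historic surveyors recorded either full daily species lists
#' ("standard"/"daily_list": detection 1 on recorded days, 0 otherwise) or
#' first detections only ("first_detection_only": 1 on the first day a
#' species appears; later days are masked as unavailable because the
#' surveyor stopped recording that species, days before first detection are
#' informative nondetections). A species never recorded yields all-zero,
#' fully unmasked history under every mode.
#'
#' @param dayLists list, one character vector of species recorded per day,
#'   ordered by day within a site/era.
#' @param species character vector of all species to encode.
#' @param mode one of "standard", "daily_list", "first_detection_only".
#' @return list with integer matrices `y` and `mask`, species x day.
#' @export
encodeHistory <- function(dayLists, species, mode = "standard") {
  if (!mode %in% c("standard", "daily_list", "first_detection_only"))
    stop("configuration error: unknown encoding mode '", mode, "'")
  K <- length(dayLists)
  S <- length(species)
  y <- matrix(0L, S, K, dimnames = list(species, NULL))
  mask <- matrix(1L, S, K, dimnames = list(species, NULL))
  for (k in seq_len(K)) y[species %in% dayLists[[k]], k] <- 1L
  if (mode == "first_detection_only") {
    for (i in seq_len(S)) {
      hit <- which(y[i, ] == 1L)
      if (length(hit)) {
        first <- hit[1]
        if (first < K) {
          y[i, (first + 1L):K] <- 0L
          mask[i, (first + 1L):K] <- 0L
        }
      }
    }
  }
  list(y = y, mask = mask)
}

#' Read detection histories from delimited text
#'
#' Expects columns species_id, site_id, region, era (historic/modern), visit,
#' julian_day, value, mode. Species absent from a surveyed site/era get
#' all-zero unmasked histories over that site's recorded visits.
#' First-detection-only site/eras are re-masked per [encodeHistory()] rules.
#'
#' @param path CSV file path.
#' @return a [DetectionDataset-class] with deterministic ordering by
#'   (species, site, era, visit).
#' @export
loadDetectionData <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "site_id", "region", "era", "visit", "julian_day",
            "value", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]) |
               !df$era %in% .eraNames |
               suppressWarnings(is.na(as.integer(df$visit))))
  if (length(bad))
    stop("parse error: malformed row at line ", bad[1] + 1L, " of ", path)
  if (!all(df$value %in% c(0, 1)))
    stop("validation error: detection value outside {0,1} at line ",
         which(!df$value %in% c(0, 1))[1] + 1L)
  key <- paste(df$species_id, df$site_id, df$era, df$visit, sep = "\r")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (species, site, era, visit) at line ",
         which(duplicated(key))[1] + 1L)
  df <- df[order(df$species_id, df$site_id, df$era, df$visit), ]

  species <- sort(unique(df$species_id))
  sites <- sort(unique(df$site_id))
  S <- length(species); J <- length(sites)
  ei <- match(df$era, .eraNames)
  si <- match(df$site_id, sites)
  nVisits <- matrix(0L, J, 2, dimnames = list(sites, .eraNames))
  agg <- stats::aggregate(df$visit, list(site = si, era = ei), max)
  nVisits[cbind(agg$site, agg$era)] <- as.integer(agg$x)
  K <- max(nVisits)

  reg <- vapply(sites, function(s) df$region[df$site_id == s][1], "")
  visitDay <- array(NA_integer_, c(J, K, 2))
  mode <- matrix("standard", J, 2, dimnames = list(sites, .eraNames))
  for (r in seq_len(nrow(df))) {
    j <- si[r]; t <- ei[r]; k <- df$visit[r]
    prev <- visitDay[j, k, t]
    if (!is.na(prev) && prev != df$julian_day[r])
      stop("integrity error: conflicting julian_day for site ", sites[j],
           " era ", df$era[r], " visit ", k)
    visitDay[j, k, t] <- as.integer(df$julian_day[r])
    mode[j, t] <- df$mode[r]
  }
  dy <- visitDay[!is.na(visitDay)]
  if (any(dy < 1L | dy > 366L))
    stop("validation error: julian_day outside 1..366")

  y <- array(0L, c(S, J, K, 2))
  y[cbind(match(df$species_id, species), si, df$visit, ei)] <-
    as.integer(df$value)
  # first-detection-only: mask days after each species' first detection
  mask <- NULL
  if (any(mode == "first_detection_only")) {
    mask <- array(1L, c(S, J, K, 2))
    for (t in 1:2) for (j in seq_len(J)) {
      if (mode[j, t] != "first_detection_only" || nVisits[j, t] < 2L) next
      for (i in seq_len(S)) {
        hit <- which(y[i, j, seq_len(nVisits[j, t]), t] == 1L)
        if (length(hit) && hit[1] < nVisits[j, t])
          mask[i, j, (hit[1] + 1L):nVisits[j, t], t] <- 0L
      }
    }
  }
  detectionDataset(y, visitDay, nVisits, species, sites, reg, mode, mask)
}

#' Write a DetectionDataset to CSV (inverse of [loadDetectionData()])
#'
#' Masked cells beyond recorded visits are not written; species-level
#' first-detection masks are implied by the mode column and detection values.
#'
#' @param x a DetectionDataset.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeDetectionData <- function(x, path) {
  rows <- list()
  for (t in 1:2) for (j in seq_len(nSites(x))) {
    nv <- x@nVisits[j, t]
    if (nv == 0L) next
    for (k in seq_len(nv)) {
      keep <- x@mask[, j, k, t] == 1L
      if (x@mode[j, t] == "first_detection_only") {
        # write only unmasked cells; detections imply the mask on re-read
      } else keep <- rep(TRUE, nSpecies(x))
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = x@species[keep], site_id = x@sites[j],
        region = as.character(x@region[j]), era = .eraNames[t], visit = k,
        julian_day = x@visitDay[j, k, t], value = x@y[keep, j, k, t],
        mode = x@mode[j, t])
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$species_id, df$site_id, df$era, df$visit), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct SiteCovariates
#'
#' @param historic,modern numeric matrices site x 5 with columns temperature,
#'   precipitation, water, urban, agriculture.
#' @param sites character labels; @param region factor/character per site.
#' @param region region labels per site.
#' @return a validated [SiteCovariates-class].
#' @export
siteCovariates <- function(historic, modern, sites, region) {
  colnames(historic) <- .covNames
  colnames(modern) <- .covNames
  new("SiteCovariates", historic = historic, modern = modern,
      sites = as.character(sites), region = as.factor(region))
}

#' Read site covariates from CSV
#'
#' One row per site: site_id, region, then era-suffixed columns
#' (temperature_historic, temperature_modern, ...). Deltas are always
#' computed, never read.
#'
#' @param path CSV path.
#' @return a [SiteCovariates-class].
#' @export
loadSiteCovariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "region", as.vector(outer(.covNames, .eraNames,
                                                 paste, sep = "_")))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing columns: ", paste(miss, collapse = ", "))
  h <- as.matrix(df[paste0(.covNames, "_historic")])
  m <- as.matrix(df[paste0(.covNames, "_modern")])
  siteCovariates(h, m, df$site_id, df$region)
}

#' Write site covariates to CSV
#' @param x a SiteCovariates; @param path output path.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeSiteCovariates <- function(x, path) {
  df <- data.frame(site_id = x@sites, region = as.character(x@region))
  for (era in .eraNames) {
    m <- slot(x, era)
    colnames(m) <- paste0(.covNames, "_", era)
    df <- cbind(df, m)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Light wrapper: file paths for detection/covariate CSVs, a default
#' collection mode, and prior/standardization options, merged over
#' defaults. Unknown keys are kept as-is so callers can carry their own
#' settings.
#'
#' @param path YAML file path.
#' @return named list with at least detection_file, covariate_file,
#'   default_mode, prior_convention.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("configuration error: the 'yaml' package is required")
  cfg <- yaml::read_yaml(path)
  defaults <- list(detection_file = NULL, covariate_file = NULL,
                   default_mode = "standard",
                   prior_convention = "variance")
  utils::modifyList(defaults, as.list(cfg))
}

.popSD <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize covariates to pooled z-scores
#'
#' Centers each covariate at 0 and scales it to SD 1, pooled over all sites
#' of both regions, with the population-SD convention (divide by n). Era
#' (historic) covariates and delta covariates are standardized separately; a
#' shared pooled scale across regions is what lets counterfactual scenarios
#' place both regions on one z-scale.
#'
#' @param cov a [SiteCovariates-class] with at least 2 sites.
#' @return list: `historic` (z-scored site x 5 matrix), `delta` (z-scored
#'   site x 5 matrix of modern-minus-historic changes, columns `d_*`) and
#'   `info`, a [StandardizationInfo-class].
#' @export
standardizeCovariates <- function(cov) {
  if (nSites(cov) < 2L)
    stop("validation error: need >= 2 sites to standardize")
  h <- cov@historic
  d <- covariateDeltas(cov)
  tab <- data.frame(covariate = c(colnames(h), colnames(d)),
                    mean = c(colMeans(h), colMeans(d)),
                    sd = c(apply(h, 2, .popSD), apply(d, 2, .popSD)),
                    group = rep(c("era", "delta"), each = ncol(h)))
  degen <- tab$covariate[tab$sd == 0]
  if (length(degen))
    stop("degenerate covariate '", degen[1], "': zero pooled SD")
  info <- new("StandardizationInfo", table = tab, convention = "population")
  zh <- scale(h, tab$mean[tab$group == "era"],
              tab$sd[tab$group == "era"])[, , drop = FALSE]
  zd <- scale(d, tab$mean[tab$group == "delta"],
              tab$sd[tab$group == "delta"])[, , drop = FALSE]
  rownames(zh) <- rownames(zd) <- cov@sites
  list(historic = zh, delta = zd, info = info)
}

.zRow <- function(info, covariate) {
  i <- match(covariate, info@table$covariate)
  if (is.na(i))
    stop("configuration error: no standardization entry for '", covariate, "'")
  info@table[i, ]
}

#' Raw-to-z and z-to-raw transforms
#'
#' @param info a [StandardizationInfo-class].
#' @param covariate covariate name (e.g. "precipitation" or
#'   "d_precipitation").
#' @param x raw values (for `zApply`) or z-scores (for `zInvert`).
#' @return transformed numeric vector; `zInvert(zApply(x))` recovers x
#'   exactly up to floating-point rounding.
#' @export
zApply <- function(info, covariate, x) {
  r <- .zRow(info, covariate)
  (x - r$mean) / r$sd
}

#' @rdname zApply
#' @export
zInvert <- function(info, covariate, x) {
  r <- .zRow(info, covariate)
  x * r$sd + r$mean
}
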