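# Sensitivities, counterfactual scenarios, quadrants and correlations.

test_that("Markov occupancy update is the convex combination", {
  expect_equal(markovOccupancy(1, 0.7, 0.2), 0.7)
  expect_equal(markovOccupancy(0, 0.7, 0.2), 0.2)
  expect_equal(markovOccupancy(0.43, 0.6, 0.2), 0.372)
  x <- markovOccupancy(runif(50), 0.6, 0.2)
  expect_true(all(x >= 0.2 & x <= 0.6))
  expect_error(markovOccupancy(1.2, 0.5, 0.5), "validation error")
})

test_that("the sensitivity derivative matches its closed form and the
           finite-difference oracle", {
  expect_equal(sensitivity(0.5, 0.5, 0.5, 0, 0), 0)
  expect_equal(sensitivity(0.5, 0.5, 0.5, 1, 1), 0.25)
  # psi_h = 1: the colonization channel vanishes
  expect_equal(sensitivity(1, 0.7, 0.123, 2, 9), 0.7 * 0.3 * 2)
  expect_equal(sensitivity(1, 0.7, 0.9, 2, 9), 0.42)
  # fuzz against the central finite difference of delta-psi
  set.seed(47)
  for (r in 1:1000) {
    psiH <- runif(1)
    d0 <- rnorm(1, 0, 1.5); d1 <- rnorm(1, 0, 1)
    e0 <- rnorm(1, 0, 1.5); e1 <- rnorm(1, 0, 1)
    x <- rnorm(1)
    got <- sensitivity(psiH, plogis(d0 + d1 * x), plogis(e0 + e1 * x),
                       d1, e1)
    expect_lt(abs(got - finiteDiffSensitivity(psiH, d0, d1, e0, e1, x)),
              1e-6)
  }
})

test_that("scenario z-scores translate raw change onto the pooled scale", {
  cv <- toyCovariates(10, seed = 53)
  std <- standardizeCovariates(cv)
  info <- std$info
  ct <- scenarioPreset("CT")
  zs <- scenarioZscores(info, cv, "A", ct)
  # no change: z of raw 0
  row <- info@table[info@table$covariate == "d_precipitation", ]
  expect_equal(zs[["d_precipitation"]], (0 - row$mean) / row$sd)
  # regional change: z of the region's mean raw delta
  cc <- scenarioPreset("CC")
  zsa <- scenarioZscores(info, cv, "A", cc)
  d <- covariateDeltas(cv)
  regMean <- mean(d[regions(cv) == "A", "d_precipitation"])
  expect_equal(zsa[["d_precipitation"]], (regMean - row$mean) / row$sd)
  # land-use deltas stay frozen under CC
  expect_equal(zsa[["d_urban"]], zs[["d_urban"]])
  # a "region" whose mean delta equals the pooled mean maps to z = 0
  all_rc <- new("ScenarioSpec", name = "all",
                settings = setNames(rep("regional_change", 5),
                                    paste0("d_", colnames(cv@historic))))
  cv2 <- siteCovariates(cv@historic, cv@modern, siteNames(cv),
                        rep("one", 10))
  zs2 <- scenarioZscores(std$info, cv2, "one", all_rc)
  expect_lt(max(abs(zs2)), 1e-10)
  expect_error(scenarioZscores(info, cv, "Z", ct), "configuration error")
  # hand numbers: pooled delta mean 10, SD 5, no change -> z = -2
  h2 <- cbind(temperature = c(0, 1), precipitation = c(0, 2),
              water = c(10, 12), urban = c(20, 24), agriculture = c(0, 3))
  m2 <- h2 + cbind(c(5, 15), c(5, 15), c(5, 15), c(5, 15), c(5, 15))
  cvh <- siteCovariates(h2, m2, c("x", "y"), c("r", "r"))
  infoh <- standardizeCovariates(cvh)$info
  zh <- scenarioZscores(infoh, cvh, "r", ct)
  expect_equal(unname(zh), rep(-2, 5))
})

test_that("counterfactual machinery reproduces a by-hand composition and
           the control identity", {
  tb <- simulateResurvey(nSpecies = 6, seed = 71,
                         design = defaultRegionDesign(4, 5))
  fit <- suppressWarnings(
    runMCMC(tb@dataset, tb@covariates, modelSpec(),
            mcmcConfig(2, 500, 200, 3, seed = 3)))
  z <- drawIncidence(fit, seed = 5)
  psiCT <- counterfactualOccupancy(fit, z, "LA", scenarioPreset("CT"))
  psiCC <- counterfactualOccupancy(fit, z, "LA", scenarioPreset("CC"))
  # composition oracle: rebuild one draw/species by hand via
  # linearPredictor + markovOccupancy
  cd <- coefDraws(fit)
  zs <- scenarioZscores(fit@stdInfo, fit@covariates, "LA",
                        scenarioPreset("CC"))
  spec <- fit@spec
  i <- 3; dr <- 7
  laSites <- which(regions(tb@dataset) == "LA")
  psiH <- mean(z[dr, i, laSites, 1])
  phi <- plogis(linearPredictor(cd$phi[dr, i, "intercept"],
                                cd$phi[dr, i, -1],
                                zs[spec@phiTerms[-1]]))
  gam <- plogis(linearPredictor(cd$gamma[dr, i, "intercept"],
                                cd$gamma[dr, i, -1],
                                zs[spec@gammaTerms[-1]]))
  expect_equal(unname(psiCC[dr, i]),
               unname(markovOccupancy(psiH, phi, gam)), tolerance = 1e-12)
  # control identity: CT minus CT is exactly zero everywhere
  imp <- impacts(psiCT, psiCT, psiCT, species = speciesNames(tb@dataset),
                 region = "LA")
  expect_true(all(imp@table$dpsi_cc == 0))
  expect_true(all(imp@table$dpsi_lu == 0))
  # constant shift: CRI width zero at +0.1
  impS <- impacts(psiCT + 0.1, psiCT, psiCT,
                  species = speciesNames(tb@dataset), region = "LA")
  expect_equal(impS@table$dpsi_cc, rep(0.1, 6), tolerance = 1e-12)
  expect_equal(impS@table$cc_lower, impS@table$cc_upper, tolerance = 1e-12)
})

test_that("scenarios collapse when a region experienced no modelled change", {
  # all deltas exactly zero in region "r": CC equals CT by construction
  set.seed(83)
  h <- cbind(temperature = rnorm(8, 15), precipitation = rnorm(8, 400, 50),
             water = runif(8, 1, 5), urban = runif(8, 1, 5),
             agriculture = runif(8, 5, 20))
  delta <- cbind(rnorm(8, 1, .3), rnorm(8, -20, 10), rnorm(8, 0, .5),
                 runif(8, 0, 10), runif(8, 0, 5))
  delta[1:4, ] <- 0                       # region r: frozen world
  cv <- siteCovariates(h, h + delta, sprintf("s%d", 1:8),
                       rep(c("r", "q"), each = 4))
  info <- standardizeCovariates(cv)$info
  zsCC <- scenarioZscores(info, cv, "r", scenarioPreset("CC"))
  zsCT <- scenarioZscores(info, cv, "r", scenarioPreset("CT"))
  expect_equal(zsCC, zsCT, tolerance = 1e-12)
})

test_that("quadrant assignment covers the plane with probability one", {
  # constructed draws: uniform over the four quadrants, mean forced into
  # one quadrant
  set.seed(59)
  n <- 400
  dCC <- matrix(rep(c(1, 1, -1, -1), each = n / 4) + 0.001, n, 2)
  dLU <- matrix(rep(c(1, -1, 1, -1), each = n / 4) + 0.001, n, 2)
  qa <- quadrantAssignment(dCC, dLU)
  expect_equal(qa$probability, c(0.25, 0.25))
  # mean is (+0.001, +0.001): windfall
  expect_equal(qa$quadrant, c("windfall", "windfall"))
  # all-negative draws: double whammy with probability 1
  qn <- quadrantAssignment(matrix(-abs(rnorm(40)), 20, 2),
                           matrix(-abs(rnorm(40)), 20, 2))
  expect_equal(qn$quadrant, c("double_whammy", "double_whammy"))
  expect_equal(qn$probability, c(1, 1))
  expect_false(any(qn$tie))
  # probabilities over quadrants sum to 1 per species
  drawQ <- msomResurvey:::.quadrantOf(dCC, dLU)
  tot <- apply(drawQ, 2, function(q) sum(table(q)) / n)
  expect_equal(tot, rep(1, 2), ignore_attr = TRUE)
  # exact-zero mean on an axis: majority quadrant, flagged
  dz <- cbind(c(1, -1, 1, -1), c(2, -2, 2, -2))
  qz <- quadrantAssignment(dz, abs(dz))
  expect_true(qz$tie[1])
  expect_equal(qz$quadrant[1], "windfall")
})

test_that("across-species correlations behave under construction", {
  set.seed(61)
  x <- matrix(rnorm(50 * 8), 50, 8)
  self <- impactCorrelation(x, x)
  expect_equal(self$mean, 1, tolerance = 1e-12)
  flip <- impactCorrelation(x, -x)
  expect_equal(flip$mean, -1, tolerance = 1e-12)
  # independent vectors: interval covers 0
  y <- matrix(rnorm(50 * 8), 50, 8)
  ind <- impactCorrelation(x, y)
  expect_lt(ind$lower, 0); expect_gt(ind$upper, 0)
  # constant draws are excluded and counted
  x2 <- x; x2[3, ] <- 5
  cc <- impactCorrelation(x2, y)
  expect_equal(cc$nUndefined, 1)
  expect_error(impactCorrelation(x[, 1:2], y[, 1:2]), "estimation error")
})

test_that("sensitivity tables compose the per-draw derivative elementwise", {
  tb <- simulateResurvey(nSpecies = 5, seed = 91,
                         design = defaultRegionDesign(4, 4))
  fit <- suppressWarnings(
    runMCMC(tb@dataset, tb@covariates, modelSpec(),
            mcmcConfig(2, 400, 150, 5, seed = 13)))
  z <- drawIncidence(fit, seed = 2)
  st <- sensitivityTable(fit, "CV", zDraws = z)
  expect_equal(sort(unique(st$table$covariate)),
               sort(paste0("d_", c("agriculture", "precipitation",
                                   "temperature", "urban", "water"))))
  # recompute one covariate by hand from the draws
  cd <- coefDraws(fit)
  allChange <- new("ScenarioSpec", name = "x",
                   settings = setNames(rep("regional_change", 5),
                                       paste0("d_", c("temperature",
                                                      "precipitation",
                                                      "water", "urban",
                                                      "agriculture"))))
  zs <- scenarioZscores(fit@stdInfo, fit@covariates, "CV", allChange)
  cvSites <- which(regions(tb@dataset) == "CV")
  psiH <- apply(z[, , cvSites, 1], c(1, 2), mean)
  lpOf <- function(a, terms) {
    out <- a[, , "intercept"]
    for (tm in setdiff(terms, "intercept")) out <- out + a[, , tm] * zs[[tm]]
    out
  }
  phi <- plogis(lpOf(cd$phi, fit@spec@phiTerms))
  gam <- plogis(lpOf(cd$gamma, fit@spec@gammaTerms))
  manual <- sensitivity(psiH, phi, gam, cd$phi[, , "d_urban"],
                        cd$gamma[, , "d_urban"])
  expect_equal(st$draws$d_urban, manual, tolerance = 1e-12)
  # degenerate posterior: a single repeated draw gives zero-width intervals
  fit0 <- fit
  one <- fit@draws[5, , drop = FALSE]
  fit0@draws <- one[rep(1, nrow(fit@draws)), ]
  z0 <- z[rep(5, dim(z)[1]), , , , drop = FALSE]
  st0 <- sensitivityTable(fit0, "CV", zDraws = z0)
  expect_equal(st0$table$lower, st0$table$upper, tolerance = 1e-12)
})
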