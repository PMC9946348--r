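# Sampler bookkeeping, diagnostics, WAIC, summaries, and small exact
# posterior checks.

test_that("retained-draw bookkeeping is exact for any legal config", {
  cfg <- mcmcConfig(nChains = 3, nIter = 1000, nBurnin = 250, thin = 7)
  expect_equal(retainedDraws(cfg), 3 * ((1000 - 250) %/% 7))
  expect_error(mcmcConfig(nIter = 100, nBurnin = 100), "exceed")
  expect_error(mcmcConfig(thin = 0), "thin")
  expect_equal(retainedDraws(mcmcPreset("desk")), 4 * 1000)
})

test_that("Gelman-Rubin diagnostic behaves on constructed chains", {
  set.seed(71)
  # identical chains: within variance = total variance
  d <- matrix(rnorm(400), 200, 2)
  expect_lt(max(abs(gelmanRubin(list(d, d)) - 1)), 0.01)
  # grossly separated chains
  r <- gelmanRubin(list(matrix(rnorm(200, 0), ncol = 1),
                        matrix(rnorm(200, 10), ncol = 1)))
  expect_gt(r, 5)
  # iid chains from one normal: R-hat in [1, 1.05] across 100 replicates
  # (the two-part estimator can dip just below 1 by sampling noise)
  rr <- replicate(100, gelmanRubin(
    lapply(1:4, function(i) matrix(rnorm(500), ncol = 1))))
  expect_true(all(rr >= 0.99 & rr <= 1.05))
  expect_error(gelmanRubin(list(d)), "diagnostic error")
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(72)
  chains <- lapply(1:3, function(i)
    matrix(rnorm(3000, mean = 0.05 * i), 1000, 3))
  mine <- gelmanRubin(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE, multivariate = FALSE)
  # coda applies a small-sample df correction; agree closely at n = 1000
  expect_equal(unname(mine), unname(ref$psrf[, 1]), tolerance = 0.02)
})

test_that("WAIC matches hand arithmetic and its degenerate case", {
  ll <- rbind(log(c(0.20, 0.50)), log(c(0.25, 0.45)), log(c(0.30, 0.55)))
  w <- waicFromPointwise(ll)
  expect_equal(w$lppd, log(0.25) + log(0.5), tolerance = 1e-10)
  expect_equal(w$pWAIC, 0.05131496, tolerance = 1e-7)
  expect_equal(w$waic, 4.2615130, tolerance = 1e-6)
  expect_equal(sum(w$pointwise$waic), w$waic, tolerance = 1e-10)
  # degenerate posterior: all draws identical
  lld <- rbind(ll[1, ], ll[1, ])
  wd <- waicFromPointwise(lld)
  expect_equal(wd$pWAIC, 0)
  expect_equal(wd$waic, -2 * sum(ll[1, ]))
  expect_error(waicFromPointwise(ll[1, , drop = FALSE]), "estimation error")
})

test_that("posterior summaries use equal-tailed percentiles", {
  expect_equal(posteriorSummary(rep(2.5, 100))$lower, 2.5)
  expect_equal(posteriorSummary(rep(2.5, 100))$upper, 2.5)
  s <- posteriorSummary(c(-1, 0, 1, -2, 2, -3, 3))
  expect_equal(s$mean, 0)
  expect_equal(s$lower, -s$upper)
  expect_false(s$significant)
  set.seed(73)
  big <- posteriorSummary(rnorm(1e6))
  expect_lt(abs(big$lower + 1.96), 0.01)
  expect_lt(abs(big$upper - 1.96), 0.01)
})

test_that("with no data the sampler reproduces the prior", {
  spec <- modelSpec(pTerms = "intercept", psiCovariates = "precipitation",
                    turnoverCovariates = "precipitation")
  fit <- runMCMC(NULL, NULL, spec, mcmcConfig(2, 6000, 1000, 2, seed = 9),
                 nSpeciesPriorOnly = 2)
  hd <- hyperDraws(fit)
  # hypermeans ~ N(0, 1.5^2)
  expect_lt(max(abs(colMeans(hd$mean))), 0.12)
  expect_lt(max(abs(apply(hd$mean, 2, sd) - 1.5)), 0.15)
  # hyper-SD ~ half-Cauchy(1.5): median 1.5
  expect_lt(max(abs(apply(hd$sd, 2, median) - 1.5)), 0.25)
  # species coefficients are marginally a heavy-tailed (Cauchy-mixture)
  # distribution centered at 0: check the median, not the mean
  cd <- coefDraws(fit)
  expect_lt(abs(median(cd$psi[, , "intercept"])), 0.15)
})

test_that("a one-dimensional posterior matches dense-grid quadrature", {
  # single species, two sites, flat visit design; detection, persistence
  # and colonization pinned at known values, hyperparameters frozen, so the
  # only free parameter is the psi1 intercept with prior N(0, 1.5^2)
  spec <- modelSpec(pTerms = "intercept", psiCovariates = character(0),
                    turnoverCovariates = character(0))
  cv <- toyCovariates(2, seed = 51)
  y <- array(0L, c(1, 2, 3, 2))
  y[1, 1, , 1] <- c(1L, 0L, 1L)   # detected historically at site 1
  y[1, 2, , 2] <- c(0L, 1L, 0L)   # detected modern at site 2
  nV <- cbind(historic = c(3L, 3L), modern = c(3L, 3L))
  vd <- array(rep(c(120L, 121L, 122L), each = 2), c(2, 3, 2))
  d <- detectionDataset(y, vd, nV, "sp01", siteNames(cv), regions(cv))
  pDet <- 0.4; phi <- 0.6; gam <- 0.3
  init <- list(coefs = matrix(c(qlogis(pDet), 0, qlogis(phi), qlogis(gam)),
                              1, 4),
               hypermean = rep(0, 4), hypersd = rep(1.5, 4))
  fit <- runMCMC(d, cv, spec, mcmcConfig(2, 6000, 1000, 2, seed = 17),
                 fixedFamilies = c("p", "phi", "gamma"),
                 updateHyper = FALSE, init = init)
  b <- paramDraws(fit, "^psi\\.intercept")
  # quadrature oracle
  grid <- seq(-12, 12, by = 0.01)
  lw <- dnorm(grid, 0, 1.5, log = TRUE)
  for (j in 1:2) {
    yj <- list(y[1, j, , 1], y[1, j, , 2])
    lw <- lw + vapply(grid, function(g)
      enumLoglikUnit(yj, list(rep(pDet, 3), rep(pDet, 3)), plogis(g), phi,
                     gam), numeric(1))
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  oracle <- sum(plogis(grid) * w)
  expect_lt(abs(mean(plogis(b)) - oracle), 0.01)
})

test_that("hypermean recovery on a moderate synthetic fit", {
  # 12 species x 22 sites, short chains: posterior means of the two
  # structural hypermeans should land on the correct side of zero
  tb <- simulateResurvey(nSpecies = 12, seed = 31,
                         design = defaultRegionDesign(10, 12))
  fit <- suppressWarnings(
    runMCMC(tb@dataset, tb@covariates, modelSpec(),
            mcmcConfig(2, 1500, 500, 2, seed = 4)))
  hd <- hyperDraws(fit)
  expect_gt(mean(hd$mean[, "mu.gamma.d_precipitation"]), 0)
  expect_lt(mean(hd$mean[, "mu.phi.d_urban"]), 0.3)
  # provenance and draw bookkeeping
  expect_equal(nrow(fit@draws), retainedDraws(fit@config))
  expect_true(all(table(fit@chain) == 500))
})

test_that("model specs and posterior draws round-trip through disk", {
  skip_if_not_installed("yaml")
  spec <- modelSpec(pTerms = c("intercept", "era"),
                    psiCovariates = c("precipitation", "urban"),
                    turnoverCovariates = "urban",
                    priorConvention = "precision")
  path <- tempfile(fileext = ".yaml")
  writeModelSpec(spec, path)
  back <- readModelSpec(path)
  expect_identical(back@psiTerms, spec@psiTerms)
  expect_identical(back@phiTerms, spec@phiTerms)
  expect_identical(back@priorConvention, "precision")

  fit <- suppressWarnings(
    runMCMC(NULL, NULL, modelSpec(pTerms = "intercept",
                                  psiCovariates = "urban",
                                  turnoverCovariates = "urban"),
            mcmcConfig(2, 300, 100, 4, seed = 3),
            nSpeciesPriorOnly = 2))
  csv <- tempfile(fileext = ".csv")
  writePosterior(fit, csv)
  df <- read.csv(csv)
  hy <- hyperDraws(fit)
  expect_identical(sort(unique(df$parameter)),
                   sort(c(colnames(hy$mean), colnames(hy$sd))))
  one <- df[df$parameter == "mu.psi.urban" & df$chain == 1, ]
  expect_equal(one$value, unname(fit@draws[fit@chain == 1,
                                           "mu.psi.urban"]))
})

test_that("WAIC evaluates the marginal species-by-site pointwise likelihood", {
  tb <- simulateResurvey(nSpecies = 5, seed = 61,
                         design = defaultRegionDesign(4, 5))
  fit <- suppressWarnings(
    runMCMC(tb@dataset, tb@covariates, modelSpec(),
            mcmcConfig(2, 600, 200, 2, seed = 2)))
  w <- waic(fit, thinTo = 50)
  expect_equal(nrow(w$pointwise), 5 * 9)
  expect_equal(sum(w$pointwise$waic), w$waic, tolerance = 1e-10)
  expect_gt(w$pWAIC, 0)
  # the fitted model should beat a parameter state from the wrong prior
  llTruth <- sum(loglikMatrix(tb@dataset, tb@covariates, modelSpec(),
                              tb@params))
  expect_lt(w$waic / -2, llTruth + 200)  # same order of magnitude
})
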