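test_that("leave-one-out excludes every record sharing the sampling key", {
  set.seed(31)
  S <- randomSpectra(5)
  P <- t(vapply(taxonGroups()[1:5], pureComp, numeric(9)))
  # records 1 and 2 share (cruise, station, depth); others distinct
  db <- tinyDb(S, P, station = c("S1", "S1", "S2", "S3", "S4"))
  cv <- loocvConversion(db)
  expect_equal(cv$excluded, c(2L, 2L, 1L, 1L, 1L))
  # the shared-key pair cannot inform each other: with pure, distinct
  # compositions, neither target can recover its own group
  expect_lt(cv$estimated[1, taxonGroups()[1]], 0.999)
  # distinct-station records are converted against all 4 others
  expect_equal(nrow(cv$estimated), 5)
})

test_that("a degenerate database of identical records round-trips exactly", {
  s <- standardizeSpectrum(setNames(runif(9, 0.5, 1), channelNames()))
  S <- matrix(rep(s, each = 4), 4)
  P <- matrix(rep(c(0.5, 0.5, rep(0, 7)), each = 4), 4)
  db <- tinyDb(S, P)
  cv <- loocvConversion(db)
  expect_equal(cv$estimated, cv$truth, tolerance = 1e-6)
})

test_that("leave-area-out uses only references from other areas", {
  set.seed(32)
  S <- randomSpectra(6)
  P <- t(vapply(taxonGroups()[1:6], pureComp, numeric(9)))
  db <- tinyDb(S, P, area = rep(c("North", "South"), each = 3))
  cv <- leaveAreaOutConversion(db)
  expect_equal(cv$excluded, rep(3L, 6))
  dbOne <- tinyDb(S, P, area = rep("North", 6))
  expect_error(leaveAreaOutConversion(dbOne), "2 areas")
})

test_that("area transfer works when areas share generative structure", {
  sim <- simulateReferenceDb(simulationConfig(nSamples = 120, seed = 33))
  cv <- leaveAreaOutConversion(sim$db)
  st <- comparisonStats(cv$estimated, cv$truth)
  # common archetypes across areas: positive slopes for the major groups
  major <- st$group %in% c("diatoms", "prochlorophytes", "cyanophytes",
                           "cryptophytes", "dinoflagellates")
  expect_true(all(st$slope[major] > 0))
  expect_true(all(st$t[major] > 2))
})

test_that("comparison statistics recover identity, noise scale and sign", {
  set.seed(34)
  truth <- t(replicate(400, .rdirichletTest(9)))
  colnames(truth) <- taxonGroups()
  st <- suppressWarnings(comparisonStats(truth, truth))  # perfect fits
  expect_equal(st$slope, rep(1, 9), tolerance = 1e-9)
  expect_equal(st$r2, rep(1, 9), tolerance = 1e-9)
  expect_equal(st$meanAbsDiff, rep(0, 9))
  expect_equal(st$ciHalfWidth, rep(0, 9))
  # additive gaussian noise: mean |diff| approaches the folded-normal mean
  sigma <- 0.03
  est <- truth + matrix(rnorm(length(truth), 0, sigma), nrow(truth))
  st2 <- comparisonStats(est, truth)
  expect_equal(st2$meanAbsDiff, rep(100 * sigma * sqrt(2 / pi), 9),
               tolerance = 0.12)
  # anti-correlation is reported, not clamped
  st3 <- suppressWarnings(comparisonStats(1 - truth, truth))
  expect_true(all(st3$slope < 0))
  # zero-variance truth is skipped
  tz <- truth; tz[, 1] <- 0.2
  st4 <- comparisonStats(est, tz)
  expect_true(st4$skipped[1])
  expect_true(is.na(st4$slope[1]))
})

test_that("bootstrap sensitivity is reproducible and vanishes for identical refs", {
  s <- standardizeSpectrum(setNames(runif(9, 0.5, 1), channelNames()))
  S <- matrix(rep(s, each = 12), 12)
  P <- matrix(rep(c(0.3, 0.7, rep(0, 7)), each = 12), 12)
  db <- tinyDb(S, P)
  bs <- bootstrapSensitivity(db, R = 20, seed = 35)
  expect_equal(max(bs$cvJM, na.rm = TRUE), 0, tolerance = 1e-6)
  expect_equal(bs$summary$upper95, rep(0, 9), tolerance = 1e-6)
  sim <- simulateReferenceDb(simulationConfig(nSamples = 25, seed = 36))
  b1 <- bootstrapSensitivity(sim$db, R = 30, seed = 37)
  b2 <- bootstrapSensitivity(sim$db, R = 30, seed = 37)
  expect_identical(b1, b2)
  expect_true(all(b1$summary$upper95 >= b1$summary$meanCV))
  expect_error(bootstrapSensitivity(sim$db, R = 1, seed = 1), "R must be")
})

test_that("PERMANOVA decomposes variance and detects a driving channel", {
  sim <- simulateReferenceDb(simulationConfig(nSamples = 60, seed = 38))
  pv <- permanovaFluorescence(sim$db, nPerm = 199, seed = 39)
  expect_equal(pv$sumR2 + pv$residualR2, 1, tolerance = 1e-9)
  expect_true(all(pv$table$R2 >= 0))
  # compositions a deterministic function of one channel: that term dominates
  set.seed(40)
  n <- 40
  drv <- runif(n)
  S <- cbind(drv, matrix(runif(n * 8), n))
  S <- S / rowSums(S)
  P <- cbind(drv, 1 - drv, matrix(0, n, 7))
  db <- tinyDb(S, P)
  pv2 <- permanovaFluorescence(db, nPerm = 999, seed = 41)
  r2 <- pv2$table$R2[pv2$table$term == "f375"]
  expect_gt(r2, max(pv2$table$R2[pv2$table$term %in% channelNames()[-1]]))
  expect_lte(pv2$table$p[pv2$table$term == "f375"], 1 / (999 + 1) + 1e-12)
})

test_that("estimation error grows monotonically with spectral noise", {
  mad <- vapply(c(0, 0.05, 0.15), function(ns) {
    sim <- simulateReferenceDb(simulationConfig(
      nSamples = 100, spectralNoiseSD = ns, seed = 42))
    cv <- loocvConversion(sim$db)
    mean(comparisonStats(cv$estimated, cv$truth)$meanAbsDiff)
  }, numeric(1))
  expect_true(all(diff(mad) > 0))
})
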