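# minimal flat cast: t seconds at a fixed depth, constant channels
flatCast <- function(t0, t1, depth, value = 1, hz = 10) {
  t <- seq(t0, t1, by = 1 / hz)
  ch <- matrix(value, length(t), 9, dimnames = list(NULL, channelNames()))
  data.frame(time_s = t, depth_m = depth, temp_c = 15, ch,
             check.names = FALSE)
}

test_that("observation segmentation follows the depth/duration rule", {
  expect_length(segmentObservations(flatCast(0, 400, 10)), 1)
  # a short deep run, a surface excursion, then a long deep run
  cast <- rbind(flatCast(0, 200, 10), flatCast(200.1, 219.9, 0.5),
                flatCast(220, 570, 10))
  obs <- segmentObservations(cast)
  expect_length(obs, 1)
  expect_equal(min(obs[[1]]$time_s), 220)
  expect_length(segmentObservations(flatCast(0, 1000, 1.5)), 0)
  # idempotence: re-segmenting an observation returns it unchanged
  expect_equal(segmentObservations(obs[[1]])[[1]], obs[[1]])
})

test_that("1-s medians remove spikes and keep constants", {
  cast <- flatCast(0, 59.9, 10)
  out <- medianResample1s(cast)
  expect_equal(nrow(out), 60)
  expect_true(all(out$f435 == 1))
  spiked <- cast
  spiked[5, channelNames()] <- 100
  out2 <- medianResample1s(spiked)
  expect_equal(out2$f435[1], 1)
  # even-count window: midpoint-average convention of the median
  c4 <- flatCast(0, 0.3, 10)
  c4$f435 <- c(1, 2, 3, 4)
  expect_equal(medianResample1s(c4)$f435, 2.5)
})

test_that("depth binning uses half-open 1-m bins and converts per bin", {
  # layer compositions drawn from the reference manifold so the conversion
  # can represent them: diatom-bloom water over picocyanobacterial water
  A <- communityArchetypes()
  qTop <- setNames(A["bloom", ], taxonGroups())
  qBot <- setNames(A["pico", ], taxonGroups())
  cast <- simulateCast(
    layers = list(
      list(top = 0, bottom = 20, composition = qTop, tchla = 1),
      list(top = 20, bottom = 40, composition = qBot, tchla = 1)),
    noiseSD = 0, seed = 51)
  sim <- simulateReferenceDb(simulationConfig(nSamples = 60,
                                              spectralNoiseSD = 0,
                                              pigmentNoiseSD = 0, seed = 51))
  pr <- binProfile1m(medianResample1s(cast), sim$db, sim$calibration)
  expect_true(all(diff(pr$depth) > 0))
  expect_equal(pr$depth[1], 2)
  # boundary: a sample at exactly 3.0 m belongs to bin [3, 4)
  one <- flatCast(0, 10, 3.0)
  prb <- binProfile1m(medianResample1s(one), sim$db, sim$calibration)
  expect_equal(prb$depth, 3)
  # layered cast: dominant group switches at the boundary +- 1 bin
  top <- pr[pr$depth <= 18, ]; bottom <- pr[pr$depth >= 22, ]
  expect_true(all(top$diatoms > 0.45))
  expect_true(all(top$diatoms > top$prochlorophytes))
  expect_true(all(bottom$prochlorophytes > 0.3))
  expect_true(all(bottom$prochlorophytes > bottom$diatoms))
})

test_that("QCoD follows its quartile arithmetic", {
  expect_equal(qcod(rep(0.4, 10)), 0)
  v <- c(1, 1, 1, 3, 3, 3)  # Q1 = 1, Q3 = 3 by linear interpolation
  expect_equal(qcod(v), 0.5)
  expect_warning(q0 <- qcod(rep(0, 5)), "undefined")
  expect_true(is.na(q0))
  expect_error(qcod(c(1, 2, 3)), "at least 4")
  expect_equal(qcodThreshold(0.134, 0.0912), 0.3164)
})

test_that("heterogeneity report flags only genuinely layered profiles", {
  mkProfile <- function(fracs) {
    depth <- 2:41
    pr <- data.frame(depth = depth, tchla = 1)
    for (g in taxonGroups()) pr[[g]] <- fracs[[g]]
    pr$n <- 10
    pr
  }
  flat <- mkProfile(as.list(pureComp("diatoms") * 0.5 +
                            pureComp("cyanophytes") * 0.5))
  flats <- rep(list(flat), 10)
  rep0 <- heterogeneityReport(flats)
  # zero-proportion groups have undefined QCoD; the constant ones are 0
  expect_equal(max(rep0$qcod, na.rm = TRUE), 0)
  expect_equal(rep0$nUndefined, 70)
  expect_equal(rep0$threshold, 0)
  expect_false(any(rep0$flags))
  layered <- flat
  layered$diatoms <- c(rep(0.9, 20), rep(0.1, 20))
  layered$cyanophytes <- 1 - layered$diatoms
  rep1 <- heterogeneityReport(c(flats, list(layered)))
  expect_true(rep1$flags[11, "diatoms"])
  expect_false(any(rep1$flags[1:10, ]))
})

test_that("water-column integration is exact on analytic profiles", {
  depth <- 2:102
  pr <- data.frame(depth = depth, tchla = 1)
  for (g in taxonGroups()) pr[[g]] <- as.numeric(g == "diatoms")
  wc <- integrateWaterColumn(pr, zmin = 2, zmax = 102)
  expect_equal(unname(wc$integrated["diatoms"]), 100)
  expect_equal(wc$total, 100)
  expect_equal(unname(wc$shares["diatoms"]), 1)
  # constant fractions integrate to the same shares
  pr2 <- pr
  for (g in taxonGroups()) pr2[[g]] <- 1 / 9
  wc2 <- integrateWaterColumn(pr2, zmin = 2, zmax = 102)
  expect_equal(unname(wc2$shares), rep(1 / 9, 9), tolerance = 1e-12)
  # triangular TChla peak: trapezoid equals the closed-form area
  pr3 <- pr
  pr3$tchla <- pmax(0, 1 - abs(depth - 52) / 50)
  wc3 <- integrateWaterColumn(pr3, zmin = 2, zmax = 102)
  expect_equal(wc3$total, 50, tolerance = 1e-9)
  # additivity: group integrals sum to the TChla integral
  set.seed(52)
  pr4 <- pr
  fr <- t(replicate(nrow(pr4), .rdirichletTest(9)))
  for (k in 1:9) pr4[[taxonGroups()[k]]] <- fr[, k]
  pr4$tchla <- runif(nrow(pr4), 0.1, 2)
  pr4 <- pr4[-c(10, 50), ]  # missing bins get interpolated
  wc4 <- integrateWaterColumn(pr4, zmin = 2, zmax = 100)
  expect_equal(sum(wc4$integrated), wc4$total, tolerance = 1e-9)
  expect_error(integrateWaterColumn(pr, zmin = 2, zmax = 300), "coverage")
})

test_that("ordination separates clusters and respects distance bounds", {
  set.seed(53)
  a <- c(0.8, 0.1, 0.1, rep(0, 6)); b <- c(0, 0, 0.1, 0.1, 0.8, rep(0, 4))
  shares <- rbind(t(replicate(5, a + runif(9, 0, 0.02))),
                  t(replicate(5, b + runif(9, 0, 0.02))))
  shares <- shares / rowSums(shares)
  colnames(shares) <- taxonGroups()
  ord <- suppressWarnings(stationSimilarity(shares, seed = 54))  # near-zero stress warning
  D <- as.matrix(ord$dist)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 10))
  # embedded within-cluster distances smaller than between-cluster ones
  pts <- ord$points
  dd <- as.matrix(dist(pts))
  within <- c(dd[1:5, 1:5][upper.tri(diag(5))], dd[6:10, 6:10][upper.tri(diag(5))])
  between <- dd[1:5, 6:10]
  expect_lt(max(within), min(between))
  # disjoint support means maximal Bray-Curtis dissimilarity
  expect_equal(max(D[1:5, 6:10]), 1, tolerance = 0.15)
})
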