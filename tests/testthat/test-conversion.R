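test_that("standardization normalizes, preserves shape and is idempotent", {
  u <- setNames(rep(5, 9), channelNames())
  expect_equal(unname(standardizeSpectrum(u)), rep(1 / 9, 9))
  s <- setNames(c(9, rep(0, 8)), channelNames())
  expect_equal(unname(standardizeSpectrum(s)), c(1, rep(0, 8)))
  set.seed(21)
  r <- setNames(runif(9), channelNames())
  once <- standardizeSpectrum(r)
  expect_equal(standardizeSpectrum(once), once)
  expect_equal(sum(once), 1, tolerance = 1e-12)
  expect_error(standardizeSpectrum(setNames(numeric(9), channelNames())),
               "all-zero")
})

test_that("an in-database spectrum decomposes onto its own record", {
  set.seed(22)
  S <- randomSpectra(5)
  P <- t(vapply(taxonGroups()[1:5], pureComp, numeric(9)))
  db <- tinyDb(S, P)
  dec <- decomposeSpectrum(refSpectra(db)[3, ], db)
  expect_lt(dec$residualNorm, 1e-6)
  expect_equal(unname(dec$alphas["3"]), 1, tolerance = 1e-5)
  expect_true(all(dec$alphas[names(dec$alphas) != "3"] < 1e-5))
})

test_that("two-reference mixtures are recovered and match the grid oracle", {
  set.seed(23)
  S <- randomSpectra(2)
  db <- tinyDb(S, rbind(pureComp("diatoms"), pureComp("cyanophytes")))
  f <- standardizeSpectrum(setNames(0.4 * S[1, ] + 0.6 * S[2, ],
                                    channelNames()))
  # 0.4 F_a + 0.6 F_b already sums to 1, so standardization is a no-op
  dec <- decomposeSpectrum(f, db)
  expect_equal(unname(dec$alphas), c(0.4, 0.6), tolerance = 1e-4)
  oracle <- gridDecompose(t(S), as.numeric(f))
  expect_lt(max(abs(unname(dec$alphas) - oracle)), 1e-3)
})

test_that("off-span targets report their residual honestly", {
  set.seed(24)
  S <- randomSpectra(2)
  db <- tinyDb(S, rbind(pureComp("diatoms"), pureComp("cyanophytes")))
  f <- setNames(c(rep(0, 7), 0.5, 0.5), channelNames())  # red-only spectrum
  dec <- decomposeSpectrum(f, db)
  expect_gt(dec$residualNorm, 0.05)
})

test_that("reconstruction is the coefficient-weighted composition sum", {
  set.seed(25)
  S <- randomSpectra(3)
  P <- rbind(pureComp("diatoms"), pureComp("cyanophytes"),
             pureComp("cryptophytes"))
  db <- tinyDb(S, P)
  mk <- function(a) list(alphas = setNames(a, 1:3), residualNorm = 0)
  expect_equal(reconstructComposition(mk(c(0, 1, 0)), db)$composition,
               setNames(P[2, ], taxonGroups()))
  r1 <- reconstructComposition(mk(c(0.5, 0.5, 0)), db)
  expect_equal(unname(r1$composition[c("diatoms", "cyanophytes")]), c(0.5, 0.5))
  # same proportions after renormalization when coefficients are scaled down
  r2 <- reconstructComposition(mk(c(0.2, 0.2, 0)), db)
  expect_equal(r2$composition, r1$composition, tolerance = 1e-12)
  expect_equal(r2$alphaSum, 0.4)
  expect_error(reconstructComposition(mk(c(0, 0, 0)), db),
               "no reference support")
})

test_that("full conversion round-trips database members and ignores scale", {
  set.seed(26)
  S <- randomSpectra(6)
  P <- t(vapply(1:6, function(i) {
    q <- rgamma(9, 1); q / sum(q)
  }, numeric(9)))
  db <- tinyDb(S, P)
  raw <- setNames(refSpectra(db)[4, ] * 7.3, channelNames())  # scaled member
  out <- convertSpectrum(raw, db)
  expect_equal(unname(out$composition), unname(P[4, ] / sum(P[4, ])),
               tolerance = 1e-5)
  expect_equal(out$tchla, 0.54095 * raw["f435"], ignore_attr = TRUE)
  # composition invariant to overall intensity; TChla proportional to it
  out2 <- convertSpectrum(raw * 3, db)
  expect_equal(out2$composition, out$composition, tolerance = 1e-6)
  expect_equal(out2$tchla, out$tchla * 3, tolerance = 1e-12)
  expect_equal(sum(out$composition), 1, tolerance = 1e-9)
})

test_that("decomposition matches the grid oracle on small random databases", {
  set.seed(27)
  for (i in 1:8) {
    n <- sample(1:3, 1)
    S <- randomSpectra(n)
    P <- t(vapply(sample(taxonGroups(), n), pureComp, numeric(9)))
    db <- tinyDb(S, P)
    f <- if (runif(1) < 0.5 && n >= 2) {
      w <- .rdirichletTest(n)
      standardizeSpectrum(setNames(colSums(S * w), channelNames()))
    } else standardizeSpectrum(setNames(runif(9), channelNames()))
    dec <- decomposeSpectrum(f, db)
    oracle <- gridDecompose(t(S), as.numeric(f))
    expect_lt(max(abs(unname(dec$alphas) - oracle)), 1e-3)
  }
})

test_that("self-consistency holds across a simulated reference database", {
  # on a full-column-rank database (records <= channels) the decomposition of
  # a member spectrum is unique, so the round trip is exact
  sim9 <- simulateReferenceDb(simulationConfig(nSamples = 10, seed = 29))
  db9 <- sim9$db[activeRecords(sim9$db)[1:min(9, length(activeRecords(sim9$db)))]]
  for (j in seq_len(length(db9))) {
    out <- convertSpectrum(setNames(refSpectra(db9)[j, ], channelNames()), db9)
    expect_equal(unname(out$composition), unname(refCompositions(db9)[j, ]),
                 tolerance = 1e-5)
  }
  # with more records than channels the coefficients are non-unique; any
  # zero-residual combination reconstructs the member's composition up to the
  # noise scale of the database (the documented tie-handling bound)
  sim <- simulateReferenceDb(simulationConfig(nSamples = 40, seed = 28))
  db <- sim$db
  idx <- activeRecords(db)
  for (j in idx[seq(1, length(idx), by = 4)]) {
    out <- convertSpectrum(setNames(refSpectra(db)[j, ], channelNames()), db)
    expect_equal(unname(out$composition), unname(refCompositions(db)[j, ]),
                 tolerance = 0.05)
    expect_equal(sum(out$composition), 1, tolerance = 1e-9)
  }
})
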