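test_that("count windows aggregate 10 ms bins and report exclusions", {
  rec <- smallSession(nTrials = 5L, nChannels = 2L, duration = 0.4, seed = 21L)
  cnt <- counts(rec)
  cnt[] <- 1L
  SummarizedExperiment::assay(rec, "counts") <- cnt
  cw <- countWindow(rec, window = c(0.4, 0.6))
  expect_true(all(cw == 20))                      # 20 bins of ones
  expect_equal(attr(cw, "dropped"), 0L)
  ## a later window excludes the short trials with a count
  rec2 <- generateSession(sessionConfig(nTrialsPerCondition = 20L,
                                        attentionLevels = "attend_rf",
                                        orientations = 0, seed = 22L))
  cw2 <- countWindow(rec2, window = c(1.6, 1.8))
  expect_gt(attr(cw2, "dropped"), 0L)
  expect_equal(nrow(cw2) + attr(cw2, "dropped"), 20L)
  expect_error(countWindow(rec, window = c(2.0, 2.2)), "window")
})

test_that("window counts have the configured Poisson mean", {
  rec <- smallSession(nTrials = 400L, nChannels = 1L, duration = 0.3,
                      sessionType = "one_phase", seed = 23L,
                      rateDistribution = list(meanlog_off = log(50),
                                              sdlog_off = 0,
                                              meanlog_dr = log(1),
                                              sdlog_dr = 0))
  cw <- countWindow(rec)
  expect_lt(abs(mean(cw) - 10), 3 * sqrt(10 / 400))
})

test_that("noise correlation is the Pearson coefficient with guards", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(noiseCorrelation(x, x), 1)
  expect_equal(noiseCorrelation(x, -x + 10), -1)
  set.seed(24)
  a <- rpois(1e4, 5); b <- rpois(1e4, 5)
  expect_lt(abs(noiseCorrelation(a, b)), 3 / sqrt(1e4))
  expect_warning(r <- noiseCorrelation(rep(2, 5), x[1:5]), "zero-variance")
  expect_true(is.na(r))
  expect_error(noiseCorrelation(1:2, 1:2), "trials")
})

test_that("Fano factor uses the unbiased variance", {
  expect_equal(fanoFactor(rep(4, 10)), 0)
  expect_equal(fanoFactor(c(0, 2)), 2)            # var 2 over mean 1
  set.seed(25)
  expect_lt(abs(fanoFactor(rpois(5000, 7)) - 1), 3 * sqrt(2 / 4999))
  expect_warning(f <- fanoFactor(rep(0, 5)), "zero mean")
  expect_true(is.na(f))
})

test_that("modulation indices are exact ratios with exclusions", {
  expect_equal(modulationIndex(0.2, 0.2)[1], 0)
  expect_equal(modulationIndex(0.1, 0.3)[1], -0.5)
  expect_equal(modulationIndex(0.4, 0)[1], 1)
  mi <- modulationIndex(c(1, 0, 2), c(1, 0, 1))
  expect_true(is.na(mi[2]))
  expect_equal(attr(mi, "excluded"), 1L)
  ## bounded for non-negative statistics
  set.seed(26)
  x <- runif(100); y <- runif(100)
  expect_true(all(abs(modulationIndex(x, y)) <= 1))
})

test_that("cortical magnification converts RF distances", {
  expect_equal(corticalDistance(0, 3), 0)
  expect_equal(corticalDistance(1, 1), 3.1)
  expect_equal(corticalDistance(1, 2), 3.1 * 2^(-0.9))
  expect_error(corticalDistance(1, 0), "eccentricity")
  expect_error(corticalDistance(-1, 2), "rfDistance")
})

test_that("distance regressions recover slopes and calibrate their nulls", {
  d <- seq(0, 5, length.out = 40)
  y <- 0.3 - 0.09 * d
  ## lm warns about the noiseless exact fit; the recovery is the point
  fit <- suppressWarnings(
    distanceRegression(data.frame(rf_distance = d, rsc = y), "rsc"))
  expect_equal(fit$slope, -0.09, tolerance = 1e-12)
  expect_lt(fit$p, 1e-10)
  ## permutation null: one-sided p roughly uniform
  set.seed(27)
  yn <- rnorm(40)
  ps <- replicate(200, distanceRegression(
    data.frame(rf_distance = d, rsc = sample(yn)), "rsc")$p)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_error(distanceRegression(data.frame(rf_distance = rep(1, 20),
                                             rsc = rnorm(20)), "rsc"),
               "constant")
  expect_error(distanceRegression(data.frame(rf_distance = d[1:5],
                                             rsc = y[1:5]), "rsc"), "pairs")
})

test_that("correlation-length fits are exact on noiseless curves", {
  d <- 0:8
  y <- 0.3 * exp(-d / 2)
  fit <- fitCorrelationLength(d, y)
  expect_equal(fit$A, 0.3, tolerance = 1e-8)
  expect_equal(fit$L, 2, tolerance = 1e-8)
  ## non-decaying data flagged as infinite
  up <- fitCorrelationLength(0:5, c(0.1, 0.12, 0.15, 0.14, 0.16, 0.18))
  expect_true(up$infinite)
  expect_true(is.infinite(up$L))
  expect_error(fitCorrelationLength(0:2, c(1, 0.5, 0.2)), "bins")
  ## Ornstein-Zernike form is exact on its own family
  yoz <- 0.5 * exp(-d[-1] / 1.5) / sqrt(d[-1])
  foz <- fitCorrelationLength(d[-1], yoz, form = "oz")
  expect_equal(foz$L, 1.5, tolerance = 1e-6)
})

test_that("decile grouping is stable, equal-sized and monotone", {
  set.seed(28)
  g <- rnorm(100)
  dc <- decileComparison(g, g + rnorm(100, 0, 0.01), g)
  expect_equal(dc$n, rep(10, 10))
  expect_true(all(diff(dc$measured) > 0))          # grouping == measured
  expect_true(all(diff(dc$grouping) > 0))
  expect_error(decileComparison(g[1:40], g[1:40], g[1:40]), "50")
})

test_that("pair tables carry layered geometry and bounded correlations", {
  rec <- generateSession(sessionConfig(nTrialsPerCondition = 30L,
                                       orientations = 0, seed = 29L,
                                       windowRange = c(0.6, 0.6)))
  ps <- pairStatistics(rec)
  expect_true(all(ps$layer %in% c("superficial", "deep")))
  expect_true(all(ps$rf_distance >= 0))
  expect_true(all(ps$cortical_distance >= 0))
  ok <- is.finite(ps$rsc_att)
  expect_true(all(abs(ps$rsc_att[ok]) <= 1))
  ## within-layer pairs only
  expect_true(all((ps$i <= 8 & ps$j <= 8) | (ps$i > 8 & ps$j > 8)))
})

test_that("measured changes track theory predictions across deciles", {
  ## end-to-end: sessions with heterogeneous attentional Delta-r gains ->
  ## per-condition HMM fits -> closed-form FF/noise-correlation changes ->
  ## decile comparison of measured vs predicted (regression slope near 1)
  rd <- sessionConfig()@rateDistribution
  rd$meanlog_gain <- 0.05
  rd$sdlog_gain <- 0.15
  T <- 0.2
  ffm <- ffp <- dgrp <- ncm <- ncp <- pgrp <- c()
  for (s in 1:2) {
    cfg <- sessionConfig(nChannels = 32L, nTrialsPerCondition = 150L,
                         attentionLevels = c("attend_rf", "attend_away1"),
                         orientations = 0, windowRange = c(0.8, 0.8),
                         ratesControl = markovRates(10, 10),
                         ratesAttention = markovRates(12, 8),
                         rateDistribution = rd, rfShift = 0.1,
                         seed = 100L + s)
    rec <- generateSession(cfg)
    fitA <- fitHMM(rec, "attend_rf:0", nRestarts = 2, seed = 1)
    fitC <- fitHMM(rec, "attend_away1:0", nRestarts = 2, seed = 1)
    rA <- hmmMarkovRates(fitA); rC <- hmmMarkovRates(fitC)
    lamA <- fitA@params@rates; lamC <- fitC@params@rates
    drA <- lamA[, 2] - lamA[, 1]; drC <- lamC[, 2] - lamC[, 1]
    cw <- countWindow(rec)
    att <- rec$attention[attr(cw, "trials")] == "attend_rf"
    ffm <- c(ffm, apply(cw[att, ], 2, fanoFactor) -
                    apply(cw[!att, ], 2, fanoFactor))
    ffp <- c(ffp, fanoFactorPred(rA, lamA[, 2], lamA[, 1], T) -
                    fanoFactorPred(rC, lamC[, 2], lamC[, 1], T))
    dgrp <- c(dgrp, drA - drC)
    pr <- which(upper.tri(matrix(0, 32, 32)), arr.ind = TRUE)
    set.seed(200 + s)
    pr <- pr[sample(nrow(pr), 200), ]
    for (p in seq_len(nrow(pr))) {
      i <- pr[p, 1]; j <- pr[p, 2]
      ncm <- c(ncm, noiseCorrelation(cw[att, i], cw[att, j]) -
                      noiseCorrelation(cw[!att, i], cw[!att, j]))
      pA <- noiseCorrelationPred(rA, lamA[i, 2], lamA[i, 1],
                                 lamA[j, 2], lamA[j, 1], T)
      pC <- noiseCorrelationPred(rC, lamC[i, 2], lamC[i, 1],
                                 lamC[j, 2], lamC[j, 1], T)
      ncp <- c(ncp, amplitude(pA) - amplitude(pC))
      pgrp <- c(pgrp, sqrt(drA[i] * drA[j]) - sqrt(drC[i] * drC[j]))
    }
  }
  dcFF <- decileComparison(ffm, ffp, dgrp)
  slopeFF <- unname(coef(lm(dcFF$measured ~ dcFF$predicted))[2])
  expect_gt(slopeFF, 0.8); expect_lt(slopeFF, 1.2)
  dcNC <- decileComparison(ncm, ncp, pgrp)
  slopeNC <- unname(coef(lm(dcNC$measured ~ dcNC$predicted))[2])
  expect_gt(slopeNC, 0.8); expect_lt(slopeNC, 1.2)
})
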