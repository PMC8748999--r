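test_that("generation is bit-identical under a fixed seed", {
  cfg <- sessionConfig(nTrialsPerCondition = 3L, orientations = c(0, 90),
                       seed = 7L)
  r1 <- generateSession(cfg)
  r2 <- generateSession(cfg)
  expect_identical(counts(r1), counts(r2))
  expect_identical(groundTruth(r1)$states, groundTruth(r2)$states)
})

test_that("session structure and metadata obey the configuration", {
  rec <- generateSession(sessionConfig(nTrialsPerCondition = 2L))
  expect_s4_class(rec, "SessionRecording")
  expect_equal(dim(counts(rec))[1:2], c(16L, 2L * 4L * 8L))
  cd <- SummarizedExperiment::colData(rec)
  expect_true(all(cd$duration >= 0.2 - 1e-9 & cd$duration <= 1.9 + 1e-9))
  expect_equal(length(unique(cd$condition)), 32L)
  v <- counts(rec)[!is.na(counts(rec))]
  expect_true(all(v >= 0 & v == round(v)))
  ## RF centers drift monotonically along channels
  rd <- SummarizedExperiment::rowData(rec)
  expect_true(all(diff(rd$rf_x) > 0))
  expect_equal(sort(unique(rd$layer)), c("deep", "superficial"))
})

test_that("invalid rate configurations are rejected by name", {
  expect_error(generateSession(sessionConfig(ratesControl = markovRates(-1, 10))),
               "alpha1")
  expect_error(sessionConfig(binWidth = 0), "binWidth")
  expect_error(sampleRatePairs(5, list(meanlog_off = 1, sdlog_off = -1,
                                       meanlog_dr = 1, sdlog_dr = 0)),
               "sdlog")
})

test_that("one-phase sessions are pure Poisson: per-channel Fano near 1", {
  rec <- smallSession(nTrials = 2000L, nChannels = 4L, duration = 0.3,
                      sessionType = "one_phase", seed = 3L)
  cw <- countWindow(rec, window = c(0.4, 0.6))
  ff <- apply(cw, 2, fanoFactor)
  se <- sqrt(2 / (nrow(cw) - 1))        # SE of FF for Poisson counts
  expect_true(all(abs(ff - 1) < 3 * se))
  expect_true(all(groundTruth(rec)$dr == 0))
})

test_that("state occupancy matches the stationary two-state solution", {
  rec <- smallSession(nTrials = 500L, nChannels = 1L, duration = 1,
                      seed = 4L, rates = markovRates(10, 10))
  st <- groundTruth(rec)$states
  expect_equal(mean(st, na.rm = TRUE),
               stationaryOnProb(markovRates(10, 10)), tolerance = 0.03)
  ## asymmetric rates: the binned chain equilibrates at p01/(p01 + p10),
  ## within O((alpha dt)^2) of alpha1/(alpha1 + alpha2)
  rec2 <- smallSession(nTrials = 300L, nChannels = 1L, duration = 1,
                       seed = 5L, rates = markovRates(15, 5))
  p01 <- 1 - exp(-0.15); p10 <- 1 - exp(-0.05)
  expect_equal(mean(groundTruth(rec2)$states, na.rm = TRUE),
               p01 / (p01 + p10), tolerance = 0.025)
  expect_equal(p01 / (p01 + p10), 0.75, tolerance = 0.02)
})

test_that("the latent chain's episode law is exponential at 1/alpha", {
  ## interior episodes of one long chain: no window-censoring bias
  set.seed(1)
  s <- OnOffDynamics:::simulateStateChain(markovRates(10, 10), 2e6, 0.01)
  ep <- episodeDurations(s, dt = 0.01)
  expect_gt(nrow(ep), 2e4)
  for (ph in c("on", "off")) {
    d <- ep$duration[ep$phase == ph]
    ## bin quantization adds half a bin on average; jitter restores the
    ## within-bin switch time before comparing with the continuous law
    dc <- d - 0.005 + runif(length(d), -0.005, 0.005)
    expect_lt(abs(mean(dc) - 0.1) / 0.1, 0.05)
    expect_gt(stats::ks.test(dc, "pexp", 10)$p.value, 0.01)
  }
})

test_that("session ground-truth episodes carry the configured timescales", {
  rec <- smallSession(nTrials = 700L, nChannels = 1L, duration = 1.9,
                      seed = 6L, rates = markovRates(10, 10))
  ep <- truthEpisodes(rec)
  expect_gt(length(ep$on) + length(ep$off), 1e4)
  expect_lt(abs(mean(ep$on) - 0.1) / 0.1, 0.05)
  expect_lt(abs(mean(ep$off) - 0.1) / 0.1, 0.05)
})

test_that("counts conditioned on the latent state are Poisson-dispersed", {
  rec <- smallSession(nTrials = 400L, nChannels = 3L, duration = 1, seed = 8L)
  st <- groundTruth(rec)$states
  cnt <- counts(rec)
  for (ch in 1:3) for (s in 0:1) {
    y <- cnt[ch, , ][st == s]
    y <- y[!is.na(y)]
    disp <- var(y) / mean(y)
    expect_lt(abs(disp - 1), 3 * sqrt(2 / length(y)))
  }
})

test_that("rate-pair sampler enforces r_on >= r_off >= 0 and its moments", {
  rp <- sampleRatePairs(1e5, seed = 9L)
  expect_true(all(rp$dr >= 0))
  expect_true(all(rp$r_on >= rp$r_off))
  rd <- sessionConfig()@rateDistribution
  expect_equal(mean(rp$dr), exp(rd$meanlog_dr + rd$sdlog_dr^2 / 2),
               tolerance = 0.02)
  ## degenerate distribution collapses to a point
  rp0 <- sampleRatePairs(10, list(meanlog_off = log(20), sdlog_off = 0,
                                  meanlog_dr = log(40), sdlog_dr = 0))
  expect_equal(rp0$r_on, rep(60, 10))
  expect_equal(rp0$r_off, rep(20, 10))
  expect_error(sampleRatePairs(0), "positive")
})

test_that("RF maps have exact centers of mass", {
  grid <- list(n = 6L, spacing = 1.5, origin = c(-9, -9))
  ## point mass
  m <- matrix(0, 6, 6); m[3, 5] <- 2
  expect_equal(unname(generateRFMap(1, responseMap = m, grid = grid)),
               c(-9 + 2 * 1.5, -9 + 4 * 1.5))
  ## symmetric map about the grid center
  sym <- outer(c(1, 2, 3, 3, 2, 1), c(1, 2, 3, 3, 2, 1))
  expect_equal(unname(generateRFMap(1, responseMap = sym, grid = grid)),
               c(-9 + 2.5 * 1.5, -9 + 2.5 * 1.5))
  ## drift: 15 channel steps x 0.3 dva
  c1 <- generateRFMap(1, rfShift = 0.3, grid = grid)
  c16 <- generateRFMap(16, rfShift = 0.3, grid = grid)
  expect_equal(sqrt(sum((c16 - c1)^2)), 4.5, tolerance = 1e-10)
  expect_error(generateRFMap(1, responseMap = matrix(0, 6, 6), grid = grid),
               "center of mass")
})
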