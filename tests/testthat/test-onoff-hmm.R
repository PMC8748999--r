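test_that("forward-backward equals brute-force path enumeration", {
  set.seed(11)
  cases <- list(list(B = 8L, nCh = 3L, n = 2L), list(B = 12L, nCh = 1L, n = 2L),
                list(B = 6L, nCh = 2L, n = 3L))
  for (cs in cases) {
    lam <- matrix(runif(cs$nCh * cs$n, 0.05, 1.2), cs$nCh, cs$n)
    A <- matrix(runif(cs$n^2, 0.05, 1), cs$n, cs$n)
    A <- A / rowSums(A)
    pi0 <- rep(1 / cs$n, cs$n)
    y <- matrix(rpois(cs$nCh * cs$B, 0.5), cs$nCh, cs$B)
    ell <- OnOffDynamics:::emissionLogLik(y, lam)
    fb <- OnOffDynamics:::forwardBackward(ell, log(A), log(pi0))
    or <- enumeratePosteriors(ell, A, pi0)
    expect_lt(max(abs(fb$gamma - or$gamma)), 1e-10)
    expect_lt(abs(fb$loglik - or$loglik), 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, cs$B), tolerance = 1e-12)
  }
})

test_that("a two-phase 16-channel model has 34 free parameters", {
  rec <- smallSession(nTrials = 4L, nChannels = 16L, duration = 0.3)
  fit <- fitHMM(rec, nPhases = 2, nRestarts = 1, maxIter = 5)
  expect_identical(nFreeParams(fit@params), 34L)
  ## general formula: channels x phases + n(n-1)
  fit3 <- fitHMM(rec, nPhases = 3, nRestarts = 1, maxIter = 3)
  expect_identical(nFreeParams(fit3@params), 16L * 3L + 6L)
})

test_that("EM log-likelihood is non-decreasing and labels are ordered", {
  rec <- smallSession(nTrials = 15L, nChannels = 4L, seed = 12L)
  fit <- fitHMM(rec, nRestarts = 2, seed = 3)
  expect_true(all(diff(loglikTrace(fit)) > -1e-8))
  rates <- fit@params@rates
  expect_gt(mean(rates[, 2]), mean(rates[, 1]))   # phase 2 is On
  A <- transitionMatrix(fit)
  expect_equal(rowSums(A), c(1, 1), tolerance = 1e-12)
  ## posteriors normalized per bin
  expect_true(all(abs(rowSums(posteriors(fit)[[1]]) - 1) < 1e-10))
})

test_that("the one-phase fit is the closed-form Poisson MLE", {
  rec <- smallSession(nTrials = 10L, nChannels = 3L, sessionType = "one_phase",
                      seed = 13L)
  fit <- fitHMM(rec, nPhases = 1)
  tc <- trialCounts(rec)
  tot <- Reduce(`+`, lapply(tc$counts, rowSums))
  nb <- sum(vapply(tc$counts, ncol, integer(1)))
  expect_equal(unname(fit@params@rates[, 1]), tot / nb / binWidth(rec),
               tolerance = 1e-12)
})

test_that("transition probabilities convert exactly to Markov rates", {
  mr <- ratesFromTransitionProbs(pOn = 0.95, pOff = 0.9, binWidth = 0.01)
  expect_equal(alpha1(mr), 10)
  expect_equal(alpha2(mr), 5)
  expect_equal(alpha1(ratesFromTransitionProbs(0.5, 1, 0.01)), 0)
  expect_error(ratesFromTransitionProbs(1.2, 0.5), "pOn")
  expect_error(ratesFromTransitionProbs(0.5, -0.1), "pOff")
})

test_that("decoding recovers separable state sequences and flags censoring", {
  rec <- separableSession(seed = 14L)
  fit <- fitHMM(rec, nRestarts = 2, seed = 4)
  dec <- decodeStates(fit, rec)
  st <- groundTruth(rec)$states
  match <- vapply(seq_along(dec$states), function(i) {
    truth <- st[i, !is.na(st[i, ])]
    mean(dec$states[[i]] == truth)
  }, numeric(1))
  expect_gt(mean(match), 0.97)
  ## first and last episodes of every trial are censored
  ep <- dec$episodes
  expect_true(all(ep$censored[!duplicated(ep$trial)]))
  expect_error(decodeStates(fitHMM(rec, nPhases = 1), rec), "two-phase")
})

test_that("decoded episode durations match the generator timescales", {
  rec <- separableSession(nTrials = 150L, seed = 15L)
  fit <- fitHMM(rec, nRestarts = 2, seed = 5)
  dec <- decodeStates(fit, rec)
  ep <- dec$episodes[!dec$episodes$censored, ]
  tauOn <- mean(ep$duration[ep$phase == "on"])
  ## censoring in 0.8 s windows biases dwell means slightly below 1/alpha2
  expect_lt(abs(tauOn - 0.1) / 0.1, 0.10)
})

test_that("variance explained behaves as a coefficient of determination", {
  ## deterministic counts: expected rates observed exactly -> R^2 ~ 1
  rec <- smallSession(nTrials = 6L, nChannels = 2L, duration = 0.6, seed = 16L)
  st <- groundTruth(rec)$states
  cnt <- counts(rec)
  for (tr in seq_len(dim(cnt)[2])) {
    s <- st[tr, !is.na(st[tr, ])]
    cnt[1, tr, seq_along(s)] <- 1L + 7L * s   # exact phase-coded counts
    cnt[2, tr, seq_along(s)] <- 2L + 5L * s
  }
  SummarizedExperiment::assay(rec, "counts") <- cnt
  fit <- fitHMM(rec, nRestarts = 2, seed = 6)
  expect_gt(varianceExplained(fit, rec), 0.999)
  ## nothing to explain when Delta-r = 0
  rec0 <- smallSession(nTrials = 40L, nChannels = 4L,
                       sessionType = "one_phase", seed = 17L)
  fit0 <- fitHMM(rec0, nRestarts = 2, seed = 7)
  expect_lt(abs(varianceExplained(fit0, rec0)), 0.05)
})

test_that("R-squared increases with the On-Off rate difference", {
  r2 <- vapply(c(40, 120, 360), function(drMean) {
    rec <- smallSession(nTrials = 30L, nChannels = 4L, seed = 18L,
                        rateDistribution = list(meanlog_off = log(10),
                                                sdlog_off = 0,
                                                meanlog_dr = log(drMean),
                                                sdlog_dr = 0))
    varianceExplained(fitHMM(rec, nRestarts = 2, seed = 8), rec)
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("cross-validation self-normalizes and guards its preconditions", {
  rec <- smallSession(nTrials = 8L, nChannels = 4L, seed = 19L)
  sel <- selectNumPhases(rec, candidates = 1:2, nRestarts = 1L,
                         maxIter = 10L, tol = 1e-3, seed = 1)
  expect_equal(unname(sel$cvErrors["1"]), 1)
  expect_true(sel$nPhases %in% 1:2)
  rec3 <- smallSession(nTrials = 3L)
  expect_error(selectNumPhases(rec3, candidates = 1:2), "trials")
})

test_that("degenerate inputs are rejected", {
  rec <- smallSession(nTrials = 2L)
  cnt <- counts(rec)
  cnt[] <- 0L
  SummarizedExperiment::assay(rec, "counts") <- cnt
  expect_error(fitHMM(rec), "all-zero")
  expect_error(trialCounts(smallSession(), condition = "nope"), "no trials")
})
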