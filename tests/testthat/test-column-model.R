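test_that("the piecewise-linear self-coupling follows its branches", {
  expect_equal(Fr(0), 0)
  expect_equal(Fr(1), 0)
  expect_equal(Fr(-0.75), -0.25)
  expect_equal(Fr(c(-2, -0.5, 0.25, 0.5, 2)), c(1, -0.5, 0.25, 0.5, -1))
})

test_that("nullcline algebra finds the bistable fixed-point structure", {
  nc <- nullclines(canonicalColumnParams())
  expect_true(nc$bistable)
  expect_equal(nrow(nc$fixedPoints), 3L)
  expect_equal(sum(nc$fixedPoints$stable), 2L)
  ## a-nullcline passes through a = f at r = 0
  p <- columnParams(f = 0.3)
  expect_equal(nullclines(p)$aNullcline$a[nullclines(p)$aNullcline$r == 0], 0.3)
  ## large attentional input removes the Off fixed point
  ncAtt <- nullclines(canonicalColumnParams(Iatt = 0.6))
  expect_false("off" %in% ncAtt$fixedPoints$branch)
  expect_true("on" %in% ncAtt$fixedPoints$branch)
})

test_that("the deterministic system stays at a stable fixed point", {
  p <- canonicalColumnParams()
  p@Q <- 0
  for (br in c("off", "on")) {
    tr <- simulateColumn(p, 5, seed = 1, init = br)
    fp <- nullclines(p)$fixedPoints
    rStar <- fp$r[fp$branch == br]
    expect_lt(max(abs(tr@r - rStar)), 1e-6)
    expect_equal(length(unique(tr@S)), 1L)
  }
})

test_that("the stability guard rejects oversized steps only without substepping", {
  p <- canonicalColumnParams()        # dt/tau = 14.6 >> epsilon/2
  expect_error(simulateColumn(p, 1, subSteps = 1), "epsilon")
  expect_s4_class(simulateColumn(p, 1, subSteps = "auto"), "ColumnTrace")
})

test_that("canonical episode durations are exponential at the 100 ms scale", {
  tr <- simulateColumn(canonicalColumnParams(), 2000, seed = 3)
  ep <- episodeDurations(tr)
  set.seed(2)
  for (ph in c("on", "off")) {
    d <- ep$duration[ep$phase == ph]
    expect_gt(length(d), 8000)
    expect_lt(abs(mean(d) - 0.1) / 0.1, 0.12)   # alpha ~ 10 /s
    ## sampled binarization quantizes up by half a recording bin
    dj <- d - tr@dt / 2 + runif(length(d), -tr@dt / 2, tr@dt / 2)
    expect_gt(stats::ks.test(dj, "pexp", 1 / mean(d))$p.value, 0.01)
  }
  ## renewal identity: stationary On fraction = tau_on / (tau_on + tau_off)
  tOn <- mean(ep$duration[ep$phase == "on"])
  tOff <- mean(ep$duration[ep$phase == "off"])
  expect_equal(mean(tr@S), tOn / (tOn + tOff), tolerance = 0.02)
})

test_that("attentional input lengthens On and shortens Off episodes", {
  for (p in list(canonicalColumnParams(Iatt = 0.01),
                 networkColumnParams(Iatt = 0.05, Istim = 0))) {
    pc <- p; pc@Iatt <- 0
    epA <- episodeDurations(simulateColumn(p, 300, seed = 4))
    epC <- episodeDurations(simulateColumn(pc, 300, seed = 4))
    expect_gt(mean(epA$duration[epA$phase == "on"]),
              mean(epC$duration[epC$phase == "on"]))
    expect_lt(mean(epA$duration[epA$phase == "off"]),
              mean(epC$duration[epC$phase == "off"]))
  }
})

test_that("noise in the rate variable gives qualitatively similar switching", {
  tr <- simulateColumn(canonicalColumnParams(), 400, seed = 5,
                       noiseInRate = TRUE)
  ep <- episodeDurations(tr)
  expect_gt(sum(ep$phase == "on"), 100)
  d <- ep$duration[ep$phase == "on"]
  expect_gt(sd(d) / mean(d), 0.7)      # irregular, near-exponential spread
  expect_lt(sd(d) / mean(d), 1.3)
})

test_that("doubly stochastic spike counts match their conditional laws", {
  ## S == 0: homogeneous Poisson at r_off
  rp <- data.frame(r_on = 50, r_off = 20)
  S0 <- matrix(0L, 400, 20)
  cnt <- generateSpikes(S0, rp, binWidth = 0.01, seed = 6)
  expect_lt(abs(mean(cnt) - 20 * 0.2), 3 * sqrt(20 * 0.2 / 400))
  ## Delta-r = 0: Fano -> 1 regardless of the state sequence
  rp0 <- data.frame(r_on = 30, r_off = 30)
  S <- matrix(rbinom(400 * 20, 1, 0.5), 400, 20)
  cnt0 <- generateSpikes(S, rp0, binWidth = 0.01, seed = 7)
  expect_lt(abs(fanoFactor(cnt0[, 1]) - 1), 3 * sqrt(2 / 399))
  expect_error(generateSpikes(S0, data.frame(r_on = 5, r_off = 10)), "r_on")
})

test_that("count variance from exact chains matches the closed form", {
  m <- markovRates(10, 10)
  on <- simulateOnOffChain(m, T = 0.2, nTrials = 2e4, seed = 8)
  cnt <- generateSpikes(onTime = on, T = 0.2,
                        ratePairs = data.frame(r_on = 50, r_off = 10))
  th <- countMoments(m, 50, 10, 0.2)
  expect_equal(var(as.numeric(cnt)), th$variance, tolerance = 0.03)
  expect_equal(mean(cnt), th$mean, tolerance = 0.02)
  ## occupancy itself: mean T/2, variance V
  expect_equal(mean(on), 0.1, tolerance = 0.02)
  expect_equal(var(on), onTimeVariance(m, 0.2), tolerance = 0.03)
})

test_that("uncoupled clamps recover baseline rates and zero coupling", {
  p <- canonicalColumnParams(W = 0)
  er <- estimateEffectiveRates(p, duration = 120, seed = 9)
  expect_lt(abs(er$beta1), 2 * er$beta1_se)
  expect_lt(abs(er$beta2), 2 * er$beta2_se)
  ## with W = 0 the Laplacian term vanishes: every clamp level gives the
  ## isolated-unit rates
  iso <- episodeDurations(simulateColumn(p, 120, seed = 21))
  a1 <- 1 / mean(iso$duration[iso$phase == "off"])
  expect_equal(unname(er$alpha1), a1, tolerance = 0.15)
  expect_error(estimateEffectiveRates(p, duration = 2, seed = 1), "episodes")
})
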