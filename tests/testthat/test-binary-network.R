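test_that("the discrete Laplacian counts neighbor-state differences", {
  S <- matrix(0L, 5, 5)
  expect_equal(discreteLaplacian(S, c(3, 3)), 0)           # uniform Off
  expect_equal(discreteLaplacian(1L - S, c(3, 3)), 0)      # uniform On
  S[2, 3] <- S[4, 3] <- S[3, 2] <- S[3, 4] <- 1L
  expect_equal(discreteLaplacian(S, c(3, 3)), 4)           # Off amid 4 On
  S2 <- 1L - S
  expect_equal(discreteLaplacian(S2, c(3, 3)), -4)         # sign symmetry
  ## 1-D and periodic wrap
  expect_equal(discreteLaplacian(c(1L, 0L, 0L, 1L), 1), -1)
  expect_error(discreteLaplacian(S, c(9, 1)), "outside")
})

test_that("uncoupled units reach the two-state stationary occupancy", {
  bp <- binaryNetParams(15, 5, beta1 = 0, side = 24L)
  fld <- simulateBinary(bp, duration = 60, seed = 1)
  occ <- mean(stateArrays(fld)[[1]][, , -(1:100)])
  expect_equal(occ, 0.75, tolerance = 0.02)
})

test_that("all-Off is absorbing when alpha1 = 0", {
  bp <- binaryNetParams(0, 10, beta1 = 3, side = 8L)
  S0 <- matrix(0L, 8, 8)
  fld <- simulateBinary(bp, duration = 5, seed = 2, S0 = S0)
  expect_true(all(stateArrays(fld)[[1]] == 0L))
})

test_that("oversized per-bin rates trigger the discretization warning", {
  bp <- binaryNetParams(80, 80, side = 8L)     # w * dt = 0.8
  expect_warning(simulateBinary(bp, duration = 1, seed = 3), "0.5")
})

test_that("exact master-equation solutions match known small systems", {
  ## single unit: (alpha2, alpha1) / (alpha1 + alpha2)
  ex1 <- solveMasterEquation(binaryNetParams(15, 5), nUnits = 1,
                             topology = matrix(-1L, 1, 1))
  expect_equal(ex1$probability, c(0.25, 0.75), tolerance = 1e-12)
  ## two uncoupled units: product of marginals
  ex2 <- solveMasterEquation(binaryNetParams(12, 4, 0, 0, side = 2L,
                                             dimension = 1L), nUnits = 2)
  pOn <- 0.75
  expect_equal(ex2$probability,
               c((1 - pOn)^2, pOn * (1 - pOn), pOn * (1 - pOn), pOn^2),
               tolerance = 1e-12)
  ## fully disconnected rate graph reports every state as its own class
  exM <- solveMasterEquation(binaryNetParams(0, 0, 0, 0, side = 2L),
                             nUnits = 4)
  expect_equal(length(exM$classes), 16L)
  expect_true(all(is.na(exM$probability)))
})

test_that("coupled-pair statistics agree between exact and simulated chains", {
  bp <- binaryNetParams(10, 6, beta1 = 3, beta2 = 3, side = 2L,
                        dimension = 1L)
  ex <- solveMasterEquation(bp, nUnits = 2)
  fld <- simulateBinary(bp, duration = 4000, seed = 4,
                        update = "asynchronous")
  arr <- stateArrays(fld)[[1]]
  dim(arr) <- c(2, dim(arr)[3])
  emp <- tabulate(1 + colSums(arr * c(1, 2)), 4) / ncol(arr)
  expect_lt(sum(abs(emp - ex$probability)) / 2, 0.02)
})

test_that("detailed balance fails for asymmetric coupling", {
  ## stationary probability currents are nonzero when beta1 != beta2
  bp <- binaryNetParams(10, 6, beta1 = 4, beta2 = 1, side = 4L,
                        dimension = 1L)
  ex <- solveMasterEquation(bp, nUnits = 4)
  nbr <- OnOffDynamics:::latticeNeighbors(4L, 1L)
  flow <- function(prob, states) {
    mx <- 0
    for (k in seq_len(nrow(states))) for (u in 1:4) {
      s <- states[k, ]
      lap <- sum(s[nbr[, u] + 1]) - 2 * s[u]
      w <- if (s[u] == 1) max(bp@alpha2 - bp@beta2 * lap, 0)
           else max(bp@alpha1 + bp@beta1 * lap, 0)
      k2 <- k + (if (s[u] == 1) -1 else 1) * 2^(u - 1)
      s2 <- states[k2, ]
      lap2 <- sum(s2[nbr[, u] + 1]) - 2 * s2[u]
      w2 <- if (s2[u] == 1) max(bp@alpha2 - bp@beta2 * lap2, 0)
            else max(bp@alpha1 + bp@beta1 * lap2, 0)
      mx <- max(mx, abs(prob[k] * w - prob[k2] * w2))
    }
    mx
  }
  expect_gt(flow(ex$probability, ex$states), 1e-3)
})

test_that("synchronous and asynchronous schemes share stationary statistics", {
  bp <- binaryNetParams(10, 10, beta1 = 2, beta2 = 2, side = 8L)
  fs <- simulateBinary(bp, duration = 300, seed = 5, update = "synchronous")
  fa <- simulateBinary(bp, duration = 300, seed = 6, update = "asynchronous")
  expect_equal(mean(stateArrays(fs)[[1]]), mean(stateArrays(fa)[[1]]),
               tolerance = 0.03)
})

test_that("moment equations reach the exact uncoupled steady state", {
  bp <- binaryNetParams(15, 5, beta1 = 0, side = 16L)
  im <- integrateMoments(bp, m0 = 0.2, duration = 2)
  expect_equal(im$steadyState$m, 0.75, tolerance = 1e-6)
  ## uncorrelated steady pairs at independence
  far <- im$pairMoments[im$distances > 3]
  expect_true(all(abs(far - 0.75^2) < 1e-6))
  ## occupancy is preserved as uniform (translation invariance)
  expect_true(all(abs(im$C[1, 1] - im$m[length(im$m)]) < 1e-8))
})

test_that("steady pair moments follow the continuum law in 1-D", {
  ## L = 3 lattice units: continuum regime where the exponential form is
  ## the exact Green's function
  bp <- binaryNetParams(10, 10, beta1 = 180, side = 48L, dimension = 1L)
  im <- integrateMoments(bp, duration = 3)
  G <- pairStateCorrelation(im$distances, markovRates(10, 10), 180)
  sel <- im$distances <= 9
  expect_lt(max(abs(im$pairMoments[sel] - G[sel]) / G[sel]), 0.02)
})

test_that("simulated occupancy trajectories track the moment equations", {
  bp <- binaryNetParams(12, 8, beta1 = 1.5, beta2 = 1.5, side = 24L)
  fld <- simulateBinary(bp, duration = 150, seed = 7)
  occ <- mean(stateArrays(fld)[[1]][, , -(1:50)])
  im <- integrateMoments(bp, duration = 2)
  expect_equal(occ, im$steadyState$m, tolerance = 0.03)
})
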