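#' Piecewise-linear recurrent self-coupling
#'
#' The inverted-N shaped r-nullcline of the rate-adaptation column model,
#' approximated branch-wise: `-1 - r` for `r <= -1/2`, `r` for
#' `-1/2 < r < 1/2`, and `1 - r` for `r >= 1/2`.
#'
#' @param r rate variable (vectorized).
#' @return `F(r)`.
#' @examples
#' Fr(c(-0.75, 0, 1))  # -0.25, 0, 0
#' @export
Fr <- function(r) {
  ifelse(r <= -0.5, -1 - r, ifelse(r >= 0.5, 1 - r, r))
}

#' @param epsilon,g,f,Q,W,Istim,Iatt,tau,dt see [ColumnParams-class].
#' @rdname ColumnParams-class
#' @export
columnParams <- function(epsilon = 0.1, g = 0.5, f = 0, Q = 0.005,
                         W = 0.01, Istim = 0, Iatt = 0, tau = 0.000343,
                         dt = 0.005) {
  new("ColumnParams", epsilon = as.numeric(epsilon), g = as.numeric(g),
      f = as.numeric(f), Q = as.numeric(Q), W = as.numeric(W),
      Istim = as.numeric(Istim), Iatt = as.numeric(Iatt),
      tau = as.numeric(tau), dt = as.numeric(dt))
}

#' Canonical bistable column parameters
#'
#' The frozen default parameter set of the single-column model, calibrated
#' once (see the methods vignette) so that the isolated unit with no
#' external input switches at `alpha1 ~ alpha2 ~ 10` per second, i.e. mean
#' episode durations near 100 ms, while remaining clearly bistable at
#' `Q = 0`.
#'
#' @param Iatt attentional current (positive values stabilize the On state).
#' @param Istim stimulus current.
#' @param W lateral interaction strength (used by the lattice network).
#' @return a [ColumnParams-class].
#' @export
canonicalColumnParams <- function(Iatt = 0, Istim = 0, W = 0.01) {
  columnParams(epsilon = 0.1, g = 0.5, f = 0, Q = 0.005, W = W,
               Istim = Istim, Iatt = Iatt, tau = 0.000343, dt = 0.005)
}

#' Network operating point of the column model
#'
#' The frozen default parameter set for lattice-network studies: a
#' weak-barrier operating point (larger noise, faster model clock) where
#' the clamped-neighbor transition rates are nearly linear in the binary
#' discrete Laplacian — so the binary-unit reduction is accurate — and the
#' control condition sits at an input offset `eta0 = +0.05` from the
#' symmetric point of the bistable system. The model depends on external
#' input and the adaptation offset only through `eta = I - f` and is
#' mirror-symmetric in its sign, so the correlation length is an even
#' function of `eta` with its maximum at `eta = 0`; the offset control
#' baseline is what makes excitatory attentional input shorten (and
#' inhibitory input lengthen) the correlation length. Isolated-unit rates
#' remain near `alpha1 ~ alpha2 ~ 10` per second.
#'
#' @param Iatt attentional current (order +-0.05 for sizable effects).
#' @param Istim stimulus current applied to the stimulus patches.
#' @param W lateral interaction strength.
#' @return a [ColumnParams-class].
#' @export
networkColumnParams <- function(Iatt = 0, Istim = 0.01, W = 0.25) {
  columnParams(epsilon = 0.1, g = 0.5, f = -0.05, Q = 0.08, W = W,
               Istim = Istim, Iatt = Iatt, tau = 0.025, dt = 0.005)
}

#' Nullclines and fixed points of the column model
#'
#' Solves the branch-wise fixed-point conditions `F(r) - a + I = 0` (the
#' r-nullcline, shifted by the total external current `I = Istim + Iatt`)
#' against the a-nullcline `a = g r + f`, classifies each crossing (outer
#' branches stable, middle branch unstable) and reports the nullcline
#' curves. Bistability means exactly two stable crossings (On and Off) with
#' one unstable crossing between them; a sufficiently large `Iatt`
#' eliminates the Off fixed point.
#'
#' @param params a [ColumnParams-class].
#' @param rGrid grid of r values for the returned nullcline curves.
#' @return list with `fixedPoints` (data.frame: r, a, branch, stable),
#'   `rNullcline` and `aNullcline` (data.frames over `rGrid`), and
#'   `bistable` (logical).
#' @export
nullclines <- function(params, rGrid = seq(-1.6, 1.6, by = 0.01)) {
  I <- params@Istim + params@Iatt
  g <- params@g; f <- params@f
  fp <- list()
  ## upper branch: 1 - r + I = g r + f  -> r = (1 + I - f) / (1 + g), r >= 1/2
  r <- (1 + I - f) / (1 + g)
  if (r >= 0.5) fp <- c(fp, list(data.frame(r = r, a = g * r + f,
                                            branch = "on", stable = TRUE)))
  ## middle branch: r + I = g r + f -> r = (f - I) / (1 - g), |r| < 1/2
  if (g != 1) {
    r <- (f - I) / (1 - g)
    if (r > -0.5 && r < 0.5)
      fp <- c(fp, list(data.frame(r = r, a = g * r + f,
                                  branch = "middle", stable = FALSE)))
  }
  ## lower branch: -1 - r + I = g r + f -> r = (I - 1 - f) / (1 + g), r <= -1/2
  r <- (I - 1 - f) / (1 + g)
  if (r <= -0.5) fp <- c(fp, list(data.frame(r = r, a = g * r + f,
                                             branch = "off", stable = TRUE)))
  fixedPoints <- do.call(rbind, fp)
  list(fixedPoints = fixedPoints,
       rNullcline = data.frame(r = rGrid, a = Fr(rGrid) + I),
       aNullcline = data.frame(r = rGrid, a = g * rGrid + f),
       bistable = !is.null(fixedPoints) && sum(fixedPoints$stable) == 2)
}

#' Simulate the single-column rate-adaptation model
#'
#' Euler-Maruyama integration of the bistable column
#' \deqn{\epsilon \dot r = F(r) - a + W(\Sigma_{nb} r_{nb} - n_{nb} r) + I,
#'       \qquad \dot a = g r - a + f + \sqrt{2Q}\,\xi,}
#' with the binary state read out as `S(t) = Theta[r(t)]` (exactly 0 counts
#' as Off). Lateral input enters through `neighborSum`, the summed rate
#' variable of `nNeighbors` neighbors (a constant clamp or a per-step
#' series); zero neighbors gives the isolated unit.
#'
#' @param params a [ColumnParams-class]; integration steps `params@dt`
#'   seconds, internally converted to model time via `params@tau` and
#'   sub-stepped to satisfy the `epsilon / 2` stability guard.
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param neighborSum constant or per-step sum of neighbor r values.
#' @param nNeighbors number of neighbors contributing to `neighborSum`.
#' @param init `"off"`, `"on"`, or a numeric `c(r0, a0)`.
#' @param recordEvery record every this many steps of `params@dt`.
#' @param noiseInRate place the white noise in the r-equation instead of the
#'   a-equation (robustness check; qualitatively similar dynamics).
#' @param subSteps integration substeps per `dt` step, or `"auto"` to
#'   choose the smallest count satisfying the stability guard. With
#'   `subSteps = 1` a `dt` exceeding `epsilon/2` (model units) is an error.
#' @return a [ColumnTrace-class].
#' @export
simulateColumn <- function(params, duration, seed = 1L, neighborSum = 0,
                           nNeighbors = 0L, init = "off", recordEvery = 1L,
                           noiseInRate = FALSE, subSteps = "auto") {
  stopifnot(is(params, "ColumnParams"))
  validObject(params)
  dtm <- params@dt / params@tau                 # model-time step
  nSub <- resolveSubSteps(subSteps, dtm, params@epsilon, params@dt, params@tau)
  nsteps <- as.integer(round(duration / params@dt))
  if (nsteps < 1) stop("duration shorter than one time step")
  recPhysical <- as.integer(recordEvery)
  nsteps <- nsteps * nSub
  recordEvery <- recPhysical * nSub
  dtm <- dtm / nSub
  nc <- nullclines(params)
  fps <- nc$fixedPoints
  if (is.character(init)) {
    br <- match.arg(init, c("off", "on"))
    row <- fps[fps$branch == br, , drop = FALSE]
    if (nrow(row) == 0) row <- fps[fps$stable, , drop = FALSE][1, ]
    r0 <- row$r[1]; a0 <- row$a[1]
  } else {
    r0 <- init[1]; a0 <- init[2]
  }
  set.seed(seed)
  out <- cpp_simulate_column(r0, a0, nsteps, dtm, params@epsilon,
                             params@g, params@f, params@Q, params@W,
                             params@Istim + params@Iatt,
                             as.numeric(neighborSum), as.integer(nNeighbors),
                             as.integer(recordEvery), noiseInRate)
  new("ColumnTrace", r = out$r, a = out$a, S = as.integer(out$S),
      dt = params@dt * recPhysical, duration = duration,
      seed = as.integer(seed))
}

## substep count so the effective model-time step obeys dtm <= epsilon / 2
resolveSubSteps <- function(subSteps, dtm, epsilon, dt, tau) {
  if (identical(subSteps, "auto"))
    return(max(1L, as.integer(ceiling(dtm / (epsilon / 2)))))
  nSub <- as.integer(subSteps)
  if (dtm / nSub > epsilon / 2)
    stop("dt = ", dt, " s too large for epsilon = ", epsilon, " at tau = ",
         tau, " s (require dt/(tau*subSteps) <= epsilon/2)")
  nSub
}

#' Episode durations of a binary state sequence
#'
#' Run-length encodes a 0/1 sequence into On and Off episodes. Episodes
#' touching either boundary are censored and excluded from duration
#' averages by default.
#'
#' @param S integer 0/1 vector (or [ColumnTrace-class]).
#' @param dt time step of `S` (s); taken from the trace if one is given.
#' @param dropCensored exclude boundary-touching episodes.
#' @return data.frame with columns `phase` ("on"/"off"), `duration` (s),
#'   `censored`.
#' @export
episodeDurations <- function(S, dt = NULL, dropCensored = TRUE) {
  if (is(S, "ColumnTrace")) { dt <- S@dt; S <- S@S }
  if (is.null(dt)) stop("dt required when S is a plain vector")
  r <- rle(as.integer(S))
  nr <- length(r$lengths)
  out <- data.frame(phase = ifelse(r$values == 1L, "on", "off"),
                    duration = r$lengths * dt,
                    censored = seq_len(nr) %in% c(1L, nr))
  if (dropCensored) out[!out$censored, , drop = FALSE] else out
}

#' Exact continuous-time two-state On-Off chain
#'
#' Simulates the two-state Markov process with exponential waiting times
#' (initial state drawn from the stationary distribution) and returns the
#' exact On-occupancy time of each trial's `[0, T]` window. This is the
#' reference state generator for comparing doubly stochastic spike counts
#' with the closed-form count moments, which are continuous-time results.
#'
#' @param rates a [MarkovRates-class].
#' @param T window duration (s).
#' @param nTrials number of independent trials.
#' @param seed integer seed.
#' @return numeric vector of On times in `[0, T]`, one per trial.
#' @export
simulateOnOffChain <- function(rates, T, nTrials, seed = NULL) {
  stopifnot(T > 0, nTrials >= 1)
  a1 <- alpha1(rates); a2 <- alpha2(rates)
  if (a1 + a2 <= 0) stop("alpha1 + alpha2 must be > 0")
  if (!is.null(seed)) set.seed(seed)
  onTime <- numeric(nTrials)
  pOn <- a1 / (a1 + a2)
  for (tr in seq_len(nTrials)) {
    s <- runif(1) < pOn
    t <- 0; ton <- 0
    while (t < T) {
      rate <- if (s) a2 else a1
      tau <- if (rate > 0) rexp(1, rate) else Inf
      seg <- min(tau, T - t)
      if (s) ton <- ton + seg
      t <- t + seg
      s <- !s
    }
    onTime[tr] <- ton
  }
  onTime
}

#' Doubly stochastic Poisson spike counts
#'
#' Generates spike counts of pseudo-neurons attached to a shared On-Off
#' state: each neuron fires as an inhomogeneous Poisson process with rate
#' `r_off + Delta-r * S(t)`, so its window count is Poisson with mean
#' `r_off * T + Delta-r * t_on`. The state can be given either as binary
#' bins (`S`, trials x bins, occupancy `t_on = binWidth * sum(S)`) or as
#' exact per-trial On times (`onTime` with window `T`).
#'
#' @param S binary matrix trials x bins (or a vector for one trial).
#' @param ratePairs data.frame with columns `r_on`, `r_off` (Hz), one row
#'   per neuron, as from [sampleRatePairs()].
#' @param binWidth bin width of `S` (s).
#' @param onTime,T alternative exact-occupancy interface.
#' @param seed optional integer seed.
#' @return integer matrix of counts, trials x neurons.
#' @export
generateSpikes <- function(S = NULL, ratePairs, binWidth = 0.010,
                           onTime = NULL, T = NULL, seed = NULL) {
  if (any(ratePairs$r_off < 0) || any(ratePairs$r_on < ratePairs$r_off))
    stop("rates must satisfy r_on >= r_off >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(onTime)) {
    if (is.null(S)) stop("provide either S or onTime")
    if (is.vector(S)) S <- matrix(S, nrow = 1)
    onTime <- rowSums(S) * binWidth
    T <- ncol(S) * binWidth
  } else if (is.null(T)) stop("T required with onTime")
  if (any(onTime > T + 1e-12)) stop("onTime exceeds window T")
  dr <- ratePairs$r_on - ratePairs$r_off
  mu <- outer(onTime, dr) + rep(ratePairs$r_off * T, each = length(onTime))
  matrix(rpois(length(mu), mu), nrow = length(onTime))
}

#' Effective binary-unit rates of the column model
#'
#' Estimates the transition rates of the binary-unit reduction by clamping
#' the four lattice neighbors of one column to `k` On and `4 - k` Off fixed
#' points, simulating, and reading switching rates off the mean decoded
#' episode durations. The Off-to-On rate is regressed on the binary discrete
#' Laplacian seen by an Off unit (`k`), the On-to-Off rate on the Laplacian
#' seen by an On unit (`k - 4`); the slopes are the effective couplings
#' `beta1` and `-beta2`, the intercepts the baseline rates.
#'
#' @param params a [ColumnParams-class] (its `W` sets the physical
#'   coupling).
#' @param duration simulated time per clamp level (s).
#' @param seed integer seed.
#' @param kLevels clamp levels (number of On neighbors).
#' @param minTransitions minimum usable episodes per level.
#' @return list with `beta1`, `beta2` (1/s per Laplacian unit), `alpha1`,
#'   `alpha2` (regression intercepts, 1/s), and `perLevel` (data.frame of
#'   rates per clamp level).
#' @export
estimateEffectiveRates <- function(params, duration = 200, seed = 1L,
                                   kLevels = 0:4, minTransitions = 50L) {
  base <- nullclines(params)$fixedPoints
  rOn <- base$r[base$branch == "on"]
  rOffFP <- base$r[base$branch == "off"]
  if (length(rOn) == 0 || length(rOffFP) == 0)
    stop("parameters are not bistable; cannot clamp neighbors to On/Off")
  per <- lapply(seq_along(kLevels), function(i) {
    k <- kLevels[i]
    tr <- simulateColumn(params, duration, seed = seed + i,
                         neighborSum = k * rOn + (4 - k) * rOffFP,
                         nNeighbors = 4L)
    ep <- episodeDurations(tr)
    on <- ep$duration[ep$phase == "on"]
    off <- ep$duration[ep$phase == "off"]
    if (length(on) < minTransitions || length(off) < minTransitions)
      stop("only ", min(length(on), length(off)), " episodes at k = ", k,
           "; lengthen duration to estimate rates")
    data.frame(k = k, alpha1_hat = 1 / mean(off), alpha2_hat = 1 / mean(on),
               n_on = length(on), n_off = length(off))
  })
  per <- do.call(rbind, per)
  ## binary Laplacian: k for an Off unit, k - 4 for an On unit
  f1 <- lm(alpha1_hat ~ I(k), data = per)
  f2 <- lm(alpha2_hat ~ I(k - 4), data = per)
  list(beta1 = unname(coef(f1)[2]), beta2 = -unname(coef(f2)[2]),
       alpha1 = unname(coef(f1)[1]), alpha2 = unname(coef(f2)[1]),
       beta1_se = summary(f1)$coefficients[2, 2],
       beta2_se = summary(f2)$coefficients[2, 2],
       perLevel = per)
}
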