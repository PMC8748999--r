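#' Configuration of the 2-D lattice network
#'
#' A square lattice of columns obeying the rate-adaptation dynamics with
#' diffusive 4-neighbor coupling. Per trial the protocol runs a spontaneous
#' period, a stimulus period (current `Istim` into two local square
#' patches) and an attention-cue period (`Iatt` additionally into one of
#' the patches); states are recorded during the cue period.
#'
#' @slot size lattice side length (256 at paper scale; 32-64 for desk work).
#' @slot columnParams a [ColumnParams-class] (supplies `dt`, `W`, `Istim`,
#'   `Iatt`).
#' @slot stimPatches list of two patches, each `list(x0, y0, w, h)`
#'   (1-based corners).
#' @slot attentionPatch index (1 or 2) of the patch receiving `Iatt`.
#' @slot trialProtocol named durations (s): `spont`, `stim`, `cue`.
#' @slot nTrials number of trials.
#' @slot boundary `"periodic"` or `"reflecting"`.
#' @slot recordBin state recording bin (s).
#' @slot seed integer seed.
#' @export
setClass("LatticeConfig",
  representation(size = "integer", columnParams = "ColumnParams",
                 stimPatches = "list", attentionPatch = "integer",
                 trialProtocol = "numeric", nTrials = "integer",
                 boundary = "character", recordBin = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nTrials < 1) return("nTrials must be >= 1")
    if (!object@boundary %in% c("periodic", "reflecting"))
      return("boundary must be 'periodic' or 'reflecting'")
    for (p in object@stimPatches) {
      if (p$x0 < 1 || p$y0 < 1 || p$x0 + p$w - 1 > object@size ||
          p$y0 + p$h - 1 > object@size)
        return("stimPatches must lie inside the lattice")
    }
    if (!object@attentionPatch %in% seq_along(object@stimPatches))
      return("attentionPatch must index one of stimPatches")
    if (!all(c("spont", "stim", "cue") %in% names(object@trialProtocol)))
      return("trialProtocol must name spont, stim, cue durations")
    TRUE
  })

#' @param size,nTrials,boundary,seed see slots.
#' @param columnParams column dynamics; its `Istim`/`Iatt` are the patch
#'   currents.
#' @param patchSize side of the two square stimulus patches (default scales
#'   with the lattice: 50 at size 256).
#' @param trialProtocol named durations in seconds.
#' @param recordBin recording bin (s).
#' @rdname LatticeConfig-class
#' @export
latticeConfig <- function(size = 64L, columnParams = canonicalColumnParams(),
                          patchSize = max(4L, as.integer(round(size * 50 / 256))),
                          trialProtocol = c(spont = 0.2, stim = 0.2, cue = 1.0),
                          nTrials = 20L, boundary = "periodic",
                          recordBin = 0.010, seed = 1L) {
  size <- as.integer(size)
  gap <- max(1L, (size - 2L * patchSize) %/% 3L)
  y0 <- max(1L, (size - patchSize) %/% 2L + 1L)
  patches <- list(list(x0 = gap + 1L, y0 = y0, w = patchSize, h = patchSize),
                  list(x0 = size - gap - patchSize + 1L, y0 = y0,
                       w = patchSize, h = patchSize))
  new("LatticeConfig", size = size, columnParams = columnParams,
      stimPatches = patches, attentionPatch = 1L,
      trialProtocol = trialProtocol, nTrials = as.integer(nTrials),
      boundary = boundary, recordBin = as.numeric(recordBin),
      seed = as.integer(seed))
}

setMethod("show", "LatticeConfig", function(object) {
  cat(sprintf("LatticeConfig: %dx%d lattice, %d trials, %s boundary\n",
              object@size, object@size, object@nTrials, object@boundary))
  cat(sprintf("  protocol (s): spont %g, stim %g, cue %g; patches %dx%d\n",
              object@trialProtocol["spont"], object@trialProtocol["stim"],
              object@trialProtocol["cue"], object@stimPatches[[1]]$w,
              object@stimPatches[[1]]$h))
})

patchMask <- function(size, patch) {
  m <- matrix(0, size, size)
  m[patch$x0:(patch$x0 + patch$w - 1), patch$y0:(patch$y0 + patch$h - 1)] <- 1
  m
}

#' Simulate the lattice network of coupled columns
#'
#' Integrates every site's rate-adaptation dynamics with the 4-neighbor
#' discrete Laplacian through the trial protocol. Unit activities start
#' randomly each trial; the binary field `S = Theta[r]` is recorded during
#' the attention-cue period in `recordBin` bins.
#'
#' @param config a [LatticeConfig-class].
#' @return a [StateField-class] with one cue-period field per trial.
#' @export
simulateLattice <- function(config) {
  stopifnot(is(config, "LatticeConfig"))
  validObject(config)
  cp <- config@columnParams
  size <- config@size
  dt <- cp@dt
  dtm <- dt / cp@tau                      # model-time step
  nSub <- resolveSubSteps("auto", dtm, cp@epsilon, dt, cp@tau)
  dtm <- dtm / nSub
  recEvery <- max(1L, as.integer(round(config@recordBin / dt)))
  stimMask <- Reduce(`+`, lapply(config@stimPatches, patchMask, size = size))
  attMask <- patchMask(size, config@stimPatches[[config@attentionPatch]])
  Ispont <- matrix(0, size, size)
  Istim <- cp@Istim * stimMask
  Icue <- Istim + cp@Iatt * attMask
  periodic <- config@boundary == "periodic"
  steps <- unname(vapply(config@trialProtocol[c("spont", "stim", "cue")],
                         function(d) as.integer(round(d / dt)) * nSub,
                         integer(1)))
  recEvery <- recEvery * nSub
  set.seed(config@seed)
  fields <- vector("list", config@nTrials)
  for (tr in seq_len(config@nTrials)) {
    r <- matrix(runif(size^2, -0.9, 0.9), size, size)
    a <- cp@g * r + cp@f
    if (steps[1] > 0) {
      st <- cpp_simulate_lattice(r, a, steps[1], dtm, cp@epsilon, cp@g, cp@f,
                                 cp@Q, cp@W, Ispont, steps[1], periodic)
      r <- st$r_final; a <- st$a_final
    }
    if (steps[2] > 0) {
      st <- cpp_simulate_lattice(r, a, steps[2], dtm, cp@epsilon, cp@g, cp@f,
                                 cp@Q, cp@W, Istim, steps[2], periodic)
      r <- st$r_final; a <- st$a_final
    }
    st <- cpp_simulate_lattice(r, a, steps[3], dtm, cp@epsilon, cp@g, cp@f,
                               cp@Q, cp@W, Icue, recEvery, periodic)
    fields[[tr]] <- array(as.integer(st$S),
                          dim = c(size, size, steps[3] %/% recEvery))
  }
  new("StateField", fields = fields, dt = config@recordBin,
      meta = list(config = config, seed = config@seed))
}

#' Empirical distance-resolved noise correlations of a simulated field
#'
#' Attaches doubly stochastic Poisson pseudo-neurons to lattice sites
#' (rates per site drawn once from `ratePairs`), counts spikes in a window
#' `T` per trial, computes the pairwise Pearson noise correlation and bins
#' it by lattice distance. Site pairs are sampled within a patch (or the
#' whole lattice) at each integer distance along a random direction.
#'
#' @param field a [StateField-class] with >= 2 trials.
#' @param ratePairs data.frame of `(r_on, r_off)` rows ([sampleRatePairs()]).
#' @param T count window (s), at most the recorded trial duration.
#' @param distances integer lattice distances to probe.
#' @param patch optional `list(x0, y0, w, h)` restricting sites.
#' @param nPairsPerDistance site pairs sampled per distance bin.
#' @param seed integer seed.
#' @return data.frame with `d`, `rsc` (mean), `se`, `n`; the pair-level
#'   records (one row per sampled pair) are attached as attribute
#'   `"pairs"`.
#' @export
fieldNoiseCorrelations <- function(field, ratePairs, T = 0.2,
                                   distances = 0:10, patch = NULL,
                                   nPairsPerDistance = 100L, seed = 1L) {
  arrs <- stateArrays(field)
  if (length(arrs) < 2) stop("need >= 2 trials")
  dims <- dim(arrs[[1]])
  nBinsT <- as.integer(round(T / field@dt))
  if (nBinsT > dims[3]) stop("count window T exceeds the recorded trial duration")
  xr <- if (is.null(patch)) c(1, dims[1]) else c(patch$x0, patch$x0 + patch$w - 1)
  yr <- if (is.null(patch)) c(1, dims[2]) else c(patch$y0, patch$y0 + patch$h - 1)
  set.seed(seed)
  nTrials <- length(arrs)
  ## occupancy time of the count window per site and trial
  occ <- vapply(arrs, function(a)
    rowSums(a[, , seq_len(nBinsT), drop = FALSE], dims = 2) * field@dt,
    matrix(0, dims[1], dims[2]))
  pairRows <- list()
  res <- lapply(distances, function(d) {
    rs <- numeric(0)
    for (p in seq_len(nPairsPerDistance)) {
      ang <- runif(1, 0, 2 * pi)
      dx <- round(d * cos(ang)); dy <- round(d * sin(ang))
      x1 <- sample(seq(xr[1], xr[2]), 1); y1 <- sample(seq(yr[1], yr[2]), 1)
      x2 <- x1 + dx; y2 <- y1 + dy
      pr <- ratePairs[sample(nrow(ratePairs), 2, replace = TRUE), ]
      if (x2 < xr[1] || x2 > xr[2] || y2 < yr[1] || y2 > yr[2]) next
      t1 <- occ[x1, y1, ]; t2 <- occ[x2, y2, ]
      n1 <- rpois(nTrials, pr$r_off[1] * T + pr$dr[1] * t1)
      n2 <- rpois(nTrials, pr$r_off[2] * T + pr$dr[2] * t2)
      if (var(n1) > 0 && var(n2) > 0) {
        rs <- c(rs, cor(n1, n2))
        pairRows[[length(pairRows) + 1]] <<-
          data.frame(d = d, pair = p, rsc = cor(n1, n2))
      }
    }
    data.frame(d = d, rsc = mean(rs), se = sd(rs) / sqrt(length(rs)),
               n = length(rs))
  })
  out <- do.call(rbind, res)
  attr(out, "pairs") <- do.call(rbind, pairRows)
  out
}

#' Simulate a uniformly driven lattice
#'
#' Runs the lattice with the same external current `Istim + Iatt` into
#' every site (no patches): the stationary-regime workhorse for measuring
#' spatial correlations and effective couplings. A burn-in period is
#' simulated and discarded before recording.
#'
#' @param params a [ColumnParams-class].
#' @param size lattice side.
#' @param duration recorded duration (s).
#' @param seed integer seed.
#' @param burnIn discarded initial period (s).
#' @param recordBin recording bin (s).
#' @return a [StateField-class] with one trial.
#' @export
simulateUniformLattice <- function(params, size = 48L, duration = 60,
                                   seed = 1L, burnIn = 2, recordBin = 0.010) {
  dtm <- params@dt / params@tau
  nSub <- resolveSubSteps("auto", dtm, params@epsilon, params@dt, params@tau)
  dtm <- dtm / nSub
  I <- matrix(params@Istim + params@Iatt, size, size)
  recEvery <- max(1L, as.integer(round(recordBin / params@dt))) * nSub
  set.seed(seed)
  r <- matrix(runif(size^2, -0.9, 0.9), size, size)
  a <- params@g * r + params@f
  nBurn <- as.integer(round(burnIn / params@dt)) * nSub
  if (nBurn > 0) {
    st <- cpp_simulate_lattice(r, a, nBurn, dtm, params@epsilon, params@g,
                               params@f, params@Q, params@W, I, nBurn, TRUE)
    r <- st$r_final; a <- st$a_final
  }
  nsteps <- as.integer(round(duration / params@dt)) * nSub
  st <- cpp_simulate_lattice(r, a, nsteps, dtm, params@epsilon, params@g,
                             params@f, params@Q, params@W, I, recEvery, TRUE)
  arr <- array(as.integer(st$S), dim = c(size, size, nsteps %/% recEvery))
  new("StateField", fields = list(arr), dt = recordBin,
      meta = list(params = params, seed = as.integer(seed)))
}

#' Effective network coupling from full-lattice simulations
#'
#' Estimates the single effective coupling strength of the binary-unit
#' reduction from a simulation of the full dynamical-system network:
#' fits the exponential decay of the spatial state correlation to get the
#' correlation length `L`, pools On/Off episode durations across sites to
#' get the transition rates, and inverts the correlation-length law,
#' `beta = L^2 (alpha1 + alpha2)`.
#'
#' @param params a [ColumnParams-class] (e.g. [networkColumnParams()]).
#' @param size,duration,seed,burnIn passed to [simulateUniformLattice()].
#' @param fitRange distance range (lattice units) for the exponential fit.
#' @param nSitesEpisodes number of sites whose episode durations are pooled.
#' @return list with `beta` (1/s), `L` (lattice units), `alpha1`, `alpha2`
#'   (1/s), and the underlying `fit` and correlation profile.
#' @export
estimateNetworkCoupling <- function(params, size = 48L, duration = 60,
                                    seed = 1L, burnIn = 2,
                                    fitRange = c(1, 8),
                                    nSitesEpisodes = 64L) {
  fld <- simulateUniformLattice(params, size = size, duration = duration,
                                seed = seed, burnIn = burnIn)
  sc <- stateCorrelationByDistance(fld, maxDist = max(fitRange))
  sel <- sc$d >= fitRange[1] & sc$d <= fitRange[2]
  fit <- fitCorrelationLength(sc$d[sel], sc$corr[sel], weights = sc$n[sel])
  arr <- stateArrays(fld)[[1]]
  sites <- seq(1, size^2, length.out = min(nSitesEpisodes, size^2))
  durOn <- c(); durOff <- c()
  dim(arr) <- c(size^2, dim(arr)[3])
  for (s in as.integer(sites)) {
    ep <- episodeDurations(arr[s, ], dt = fld@dt)
    durOn <- c(durOn, ep$duration[ep$phase == "on"])
    durOff <- c(durOff, ep$duration[ep$phase == "off"])
  }
  a1 <- 1 / mean(durOff); a2 <- 1 / mean(durOn)
  list(beta = fit$L^2 * (a1 + a2), L = fit$L, alpha1 = a1, alpha2 = a2,
       fit = fit, corr = sc)
}

#' Attention-versus-control contrast of two simulated patches
#'
#' Compares the attended patch with the unattended (control) patch of the
#' same simulation: mean On/Off episode durations per patch (censored
#' episodes excluded) and the exponential correlation length fitted to the
#' within-patch spatial state correlation.
#'
#' @param field a [StateField-class] from [simulateLattice()].
#' @param maxDist largest distance for the correlation-length fit.
#' @param minPairs minimum offset pairs per distance bin.
#' @return list with one entry per patch (`attention`, `control`), each
#'   carrying `tauOn`, `tauOff` (s), `L`, `corr` (distance profile), plus
#'   `ratio = L_att / L_ctl`.
#' @export
attentionContrast <- function(field, maxDist = 12, minPairs = 20L) {
  cfg <- field@meta$config
  if (is.null(cfg)) stop("field carries no lattice config")
  attIdx <- cfg@attentionPatch
  ctlIdx <- setdiff(seq_along(cfg@stimPatches), attIdx)[1]
  analyze <- function(patch) {
    reg <- list(x = patch$x0:(patch$x0 + patch$w - 1),
                y = patch$y0:(patch$y0 + patch$h - 1))
    ## episode durations pooled over sites and trials
    durOn <- c(); durOff <- c()
    for (a in stateArrays(field)) {
      sub <- a[reg$x, reg$y, , drop = FALSE]
      nSites <- length(reg$x) * length(reg$y)
      dim(sub) <- c(nSites, dim(sub)[3])
      for (s in seq_len(nSites)) {
        ep <- episodeDurations(sub[s, ], dt = field@dt)
        durOn <- c(durOn, ep$duration[ep$phase == "on"])
        durOff <- c(durOff, ep$duration[ep$phase == "off"])
      }
    }
    sc <- stateCorrelationByDistance(field, maxDist = maxDist, region = reg)
    sc <- sc[sc$n >= minPairs & sc$d >= 1, ]
    if (nrow(sc) < 4) stop("fewer than 4 usable distance bins (", nrow(sc),
                           "); enlarge the patch or lower minPairs")
    fit <- fitCorrelationLength(sc$d, sc$corr, weights = sc$n)
    list(tauOn = mean(durOn), tauOff = mean(durOff), L = fit$L,
         fit = fit, corr = sc)
  }
  att <- analyze(cfg@stimPatches[[attIdx]])
  ctl <- analyze(cfg@stimPatches[[ctlIdx]])
  list(attention = att, control = ctl, ratio = att$L / ctl$L)
}
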