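## Shared-latent-state Poisson HMM for multi-channel spike counts.
##
## All channels share one latent phase sequence per trial; emissions are
## independent Poisson counts per channel and bin with phase-dependent
## rates. Everything runs in log space (log-sum-exp) to avoid underflow.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Per-bin, per-phase emission log-likelihood: sum over channels of Poisson
## log-pmf. y: channels x bins; lambda: channels x phases (expected counts
## per bin). Returns bins x phases.
emissionLogLik <- function(y, lambda) {
  nPh <- ncol(lambda)
  out <- matrix(0, ncol(y), nPh)
  for (s in seq_len(nPh))
    out[, s] <- colSums(dpois(y, lambda[, s], log = TRUE))
  out
}

## Log-space forward-backward for one trial.
## ell: bins x phases emission log-likelihoods; logA, logPi in log space.
## Returns gamma (posteriors), xi sums (expected transition counts), loglik.
forwardBackward <- function(ell, logA, logPi) {
  B <- nrow(ell); n <- ncol(ell)
  logalpha <- matrix(-Inf, B, n)
  logbeta <- matrix(0, B, n)
  logalpha[1, ] <- logPi + ell[1, ]
  if (B > 1) {
    for (b in 2:B) {
      for (s in seq_len(n))
        logalpha[b, s] <- logSumExp(logalpha[b - 1, ] + logA[, s]) + ell[b, s]
      for (s in seq_len(n))
        logbeta[B - b + 1, s] <-
          logSumExp(logA[s, ] + ell[B - b + 2, ] + logbeta[B - b + 2, ])
    }
  }
  loglik <- logSumExp(logalpha[B, ])
  lg <- logalpha + logbeta - loglik
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, n, n)
  if (B > 1) {
    for (b in seq_len(B - 1)) {
      lx <- outer(logalpha[b, ], ell[b + 1, ] + logbeta[b + 1, ], "+") + logA - loglik
      xi <- xi + exp(lx)
    }
  }
  list(gamma = gamma, xi = xi, loglik = loglik)
}

## Viterbi path (1-based phase indices) for one trial.
viterbiPath <- function(ell, logA, logPi) {
  B <- nrow(ell); n <- ncol(ell)
  delta <- matrix(-Inf, B, n)
  psi <- matrix(0L, B, n)
  delta[1, ] <- logPi + ell[1, ]
  if (B > 1) {
    for (b in 2:B) {
      for (s in seq_len(n)) {
        v <- delta[b - 1, ] + logA[, s]
        psi[b, s] <- which.max(v)
        delta[b, s] <- v[psi[b, s]] + ell[b, s]
      }
    }
  }
  path <- integer(B)
  path[B] <- which.max(delta[B, ])
  if (B > 1) for (b in (B - 1):1) path[b] <- psi[b + 1, path[b + 1]]
  path
}

## Deterministic label ordering: phases sorted by population mean rate so
## that the last phase is "On" (highest rate).
orderPhases <- function(rates, A, pi0) {
  o <- order(colMeans(rates))
  list(rates = rates[, o, drop = FALSE], A = A[o, o, drop = FALSE], pi = pi0[o])
}

#' Number of free parameters of an HMM parameterization
#'
#' Per-channel firing rates for each phase plus the off-diagonal transition
#' probabilities; the initial phase distribution is fixed (uniform), not
#' fitted, because fitted trials open 400 ms after the cue when the
#' population state has equilibrated. For a two-phase, 16-channel model this
#' gives 16 x 2 + 2 = 34.
#'
#' @param params an [HMMParams-class].
#' @return integer count of free parameters.
#' @export
nFreeParams <- function(params) {
  n <- params@nPhases
  as.integer(nrow(params@rates) * n + n * (n - 1L))
}

#' Fit a shared-latent-state Poisson HMM by EM
#'
#' Fits spike counts of all channels with a single latent phase sequence per
#' trial (Baum-Welch EM; E-step via log-space forward-backward on the
#' product-Poisson emissions, closed-form M-step for rates and transition
#' probabilities). The best of `nRestarts` random restarts is returned.
#' Restarts initialize per-channel rates at the 30th/70th count percentiles
#' (spread across phases for more than two) with multiplicative jitter. For
#' `nPhases = 1` the exact maximum likelihood (per-channel mean rate) is
#' returned directly.
#'
#' @param recording a [SessionRecording-class] (bins are the fit window
#'   starting 400 ms post-cue).
#' @param condition condition label to fit, or `NULL` for all trials
#'   (fitting is per condition in the analysis pipeline).
#' @param nPhases number of latent phases.
#' @param nRestarts random EM restarts.
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param maxIter maximum EM iterations.
#' @param seed integer seed for the restarts.
#' @return an [HMMFit-class].
#' @export
fitHMM <- function(recording, condition = NULL, nPhases = 2L, nRestarts = 5L,
                   tol = 1e-4, maxIter = 200L, seed = 1L) {
  tc <- trialCounts(recording, condition)
  ys <- tc$counts
  if (length(ys) < 2) stop("need at least 2 trials to fit the HMM")
  if (all(vapply(ys, function(y) all(y == 0), logical(1))))
    stop("all-zero counts on every channel: nothing to fit")
  if (sum(vapply(ys, ncol, integer(1))) == 0) stop("empty fit window")
  bw <- binWidth(recording)
  nCh <- nrow(ys[[1]])
  n <- as.integer(nPhases)

  if (n == 1L) {
    tot <- Reduce(`+`, lapply(ys, rowSums))
    nb <- sum(vapply(ys, ncol, integer(1)))
    lambda <- matrix(tot / nb, ncol = 1)         # expected counts per bin
    ll <- sum(vapply(ys, function(y)
      sum(dpois(y, lambda[, 1], log = TRUE)), numeric(1)))
    params <- new("HMMParams", nPhases = 1L, rates = lambda / bw,
                  transitionMatrix = matrix(1, 1, 1), initialDistribution = 1)
    post <- lapply(ys, function(y) matrix(1, ncol(y), 1))
    return(new("HMMFit", params = params, loglikTrace = ll, posteriors = post,
               trials = as.integer(tc$trials),
               condition = condition %||% "", binWidth = bw,
               cvErrors = numeric(0)))
  }

  set.seed(seed)
  pooled <- do.call(cbind, ys)
  best <- NULL
  for (rs in seq_len(nRestarts)) {
    ## init: per-channel percentile split plus jitter
    qs <- seq(0.3, 0.7, length.out = n)
    lambda0 <- t(vapply(seq_len(nCh), function(ch)
      pmax(quantile(pooled[ch, ], qs), 0.01), numeric(n)))
    dim(lambda0) <- c(nCh, n)
    lambda0 <- lambda0 * matrix(exp(rnorm(nCh * n, 0, 0.15)), nCh, n)
    A <- matrix(0.1 / (n - 1), n, n); diag(A) <- 0.9
    pi0 <- rep(1 / n, n)
    fit <- emPoissonHMM(ys, lambda0, A, pi0, tol, maxIter)
    if (is.null(best) || tail(fit$trace, 1) > tail(best$trace, 1)) best <- fit
  }

  ord <- orderPhases(best$lambda, best$A, best$pi)
  ells <- lapply(ys, emissionLogLik, lambda = ord$rates)
  logA <- log(ord$A); logPi <- log(ord$pi)
  post <- lapply(ells, function(e) forwardBackward(e, logA, logPi)$gamma)

  params <- new("HMMParams", nPhases = n, rates = ord$rates / bw,
                transitionMatrix = ord$A, initialDistribution = ord$pi)
  new("HMMFit", params = params, loglikTrace = best$trace, posteriors = post,
      trials = as.integer(tc$trials), condition = condition %||% "",
      binWidth = bw, cvErrors = numeric(0))
}

## EM core. lambda: channels x phases expected counts per bin.
## Initial distribution is held fixed (not an EM parameter).
emPoissonHMM <- function(ys, lambda, A, pi0, tol, maxIter) {
  trace <- numeric(0)
  n <- ncol(lambda)
  for (it in seq_len(maxIter)) {
    logA <- log(pmax(A, 1e-300)); logPi <- log(pi0)
    num <- matrix(0, nrow(lambda), n); den <- numeric(n)
    xiSum <- matrix(0, n, n); ll <- 0
    for (y in ys) {
      fb <- forwardBackward(emissionLogLik(y, lambda), logA, logPi)
      ll <- ll + fb$loglik
      num <- num + y %*% fb$gamma
      den <- den + colSums(fb$gamma)
      xiSum <- xiSum + fb$xi
    }
    trace <- c(trace, ll)
    lambda <- sweep(num, 2, pmax(den, 1e-12), "/")
    lambda <- pmax(lambda, 1e-8)
    rs <- rowSums(xiSum)
    keep <- rs > 0
    A[keep, ] <- xiSum[keep, ] / rs[keep]
    A <- A / rowSums(A)
    if (it > 1 && trace[it] - trace[it - 1] < tol) break
  }
  list(lambda = lambda, A = A, pi = pi0, trace = trace)
}

#' Convert HMM transition probabilities to Markov rates
#'
#' Exact conversion used throughout: `alpha1 = (1 - p_off) / dt` and
#' `alpha2 = (1 - p_on) / dt`, where `p_off`/`p_on` are the per-bin Off/On
#' stay probabilities and `dt` the HMM bin width (10 ms).
#'
#' @param pOn,pOff stay probabilities in `[0, 1]`.
#' @param binWidth bin width in seconds.
#' @return a [MarkovRates-class].
#' @examples
#' ratesFromTransitionProbs(pOn = 0.95, pOff = 0.9, binWidth = 0.01)
#' @export
ratesFromTransitionProbs <- function(pOn, pOff, binWidth = 0.010) {
  if (pOn < 0 || pOn > 1) stop("pOn must be in [0, 1]")
  if (pOff < 0 || pOff > 1) stop("pOff must be in [0, 1]")
  if (binWidth <= 0) stop("binWidth must be > 0")
  markovRates((1 - pOff) / binWidth, (1 - pOn) / binWidth)
}

#' Markov rates of a fitted two-phase HMM
#'
#' @param fit an [HMMFit-class] with two phases (phase 1 = Off, 2 = On).
#' @return a [MarkovRates-class].
#' @export
hmmMarkovRates <- function(fit) {
  if (nPhases(fit) != 2) stop("Markov rates are defined for two-phase fits")
  A <- transitionMatrix(fit)
  ratesFromTransitionProbs(pOn = A[2, 2], pOff = A[1, 1], binWidth = fit@binWidth)
}

#' Cross-validated selection of the number of HMM phases
#'
#' Computes a normalized `nFolds`-fold cross-validation error for each
#' candidate phase count and applies an explicit elbow rule. The CV error of
#' a candidate is the mean squared error between observed spike counts
#' aggregated in `cvWindow` (200 ms) windows on held-out trials and their
#' posterior-expected counts, where the posterior for each channel is
#' computed from the remaining channels only (leave-one-channel-out, so that
#' extra phases cannot trivially fit the held-out channel's own noise).
#' Errors are averaged across channels, folds (and conditions when
#' `condition = NULL`) and normalized by the 1-phase error, so candidate 1
#' scores exactly 1. The chosen count is the smallest candidate whose error
#' is within `elbowTol` (2 percent) of the minimum; a session whose chosen
#' count is 1 is classified one-phase.
#'
#' @param recording a [SessionRecording-class].
#' @param condition condition label, or `NULL` to average over all
#'   conditions as in the full pipeline.
#' @param candidates candidate phase counts (1..8).
#' @param nFolds number of CV folds (requires at least `nFolds` trials per
#'   condition).
#' @param cvWindow aggregation window for the error (s).
#' @param elbowTol relative tolerance of the elbow rule.
#' @param seed seed controlling fold assignment and EM restarts.
#' @param ... passed to [fitHMM()] (e.g. `nRestarts`, `maxIter`).
#' @return list with `nPhases` (chosen count), `cvErrors` (named numeric per
#'   candidate), `onePhase` (logical).
#' @export
selectNumPhases <- function(recording, condition = NULL, candidates = 1:8,
                            nFolds = 4L, cvWindow = 0.200, elbowTol = 0.02,
                            seed = 1L, ...) {
  conds <- if (is.null(condition))
    unique(SummarizedExperiment::colData(recording)$condition) else condition
  bw <- binWidth(recording)
  wBins <- max(1L, as.integer(round(cvWindow / bw)))
  err <- matrix(0, length(candidates), 0)

  for (cond in conds) {
    tc <- trialCounts(recording, cond)
    nT <- length(tc$counts)
    if (nT < nFolds)
      stop("condition '", cond, "' has ", nT, " trials; need at least ", nFolds)
    set.seed(seed)
    fold <- sample(rep_len(seq_len(nFolds), nT))
    condErr <- matrix(NA_real_, length(candidates), nFolds)
    for (k in seq_len(nFolds)) {
      trainIdx <- tc$trials[fold != k]
      testYs <- tc$counts[fold == k]
      sub <- recording[, trainIdx]
      for (ci in seq_along(candidates)) {
        fit <- fitHMM(sub, condition = NULL, nPhases = candidates[ci],
                      seed = seed + k, ...)
        condErr[ci, k] <- cvPredictionError(fit, testYs, wBins)
      }
    }
    err <- cbind(err, rowMeans(condErr))
  }
  cv <- rowMeans(err)
  cv <- cv / cv[candidates == 1L]
  names(cv) <- as.character(candidates)
  chosen <- candidates[min(which(cv <= min(cv) * (1 + elbowTol)))]
  list(nPhases = as.integer(chosen), cvErrors = cv, onePhase = chosen == 1L)
}

## Leave-one-channel-out posterior prediction error on held-out trials,
## aggregated in windows of wBins bins.
cvPredictionError <- function(fit, testYs, wBins) {
  lambda <- fit@params@rates * fit@binWidth       # expected counts per bin
  n <- nPhases(fit)
  logA <- log(pmax(transitionMatrix(fit), 1e-300))
  logPi <- log(fit@params@initialDistribution)
  se <- 0; nw <- 0
  for (y in testYs) {
    B <- ncol(y)
    nWin <- B %/% wBins
    if (nWin == 0) next
    for (ch in seq_len(nrow(y))) {
      if (n == 1L) {
        predBin <- rep(lambda[ch, 1], B)
      } else {
        ell <- emissionLogLik(y[-ch, , drop = FALSE],
                              lambda[-ch, , drop = FALSE])
        g <- forwardBackward(ell, logA, logPi)$gamma
        predBin <- as.numeric(g %*% lambda[ch, ])
      }
      idx <- rep(seq_len(nWin), each = wBins)
      obsW <- tapply(y[ch, seq_len(nWin * wBins)], idx, sum)
      predW <- tapply(predBin[seq_len(nWin * wBins)], idx, sum)
      se <- se + sum((obsW - predW)^2)
      nw <- nw + nWin
    }
  }
  if (nw == 0) stop("no complete CV window in the held-out trials")
  se / nw
}

#' Decode On/Off episodes with a fitted two-phase HMM
#'
#' Viterbi-decodes the latent phase path of every fitted trial (phase
#' identity resolved by population mean rate: On = higher) and run-length
#' encodes it into episodes. Episodes touching a trial boundary are flagged
#' censored; censored episodes should be excluded from duration averages.
#'
#' @param fit a two-phase [HMMFit-class].
#' @param recording the [SessionRecording-class] that was fitted.
#' @param condition condition label used in the fit.
#' @return list with `states` (list of per-trial 0/1 integer vectors) and
#'   `episodes` (data.frame: trial, phase ("on"/"off"), duration in s,
#'   censored flag).
#' @export
decodeStates <- function(fit, recording, condition = NULL) {
  if (nPhases(fit) != 2) stop("decodeStates requires a two-phase fit")
  tc <- trialCounts(recording, condition)
  lambda <- fit@params@rates * fit@binWidth
  logA <- log(pmax(transitionMatrix(fit), 1e-300))
  logPi <- log(fit@params@initialDistribution)
  states <- lapply(tc$counts, function(y)
    as.integer(viterbiPath(emissionLogLik(y, lambda), logA, logPi) - 1L))
  eps <- do.call(rbind, lapply(seq_along(states), function(i) {
    r <- rle(states[[i]])
    nr <- length(r$lengths)
    data.frame(trial = tc$trials[i],
               phase = ifelse(r$values == 1L, "on", "off"),
               duration = r$lengths * fit@binWidth,
               censored = seq_len(nr) %in% c(1L, nr))
  }))
  list(states = states, episodes = eps)
}

#' Variance explained by a fitted HMM
#'
#' Coefficient of determination of the posterior-expected per-bin counts
#' against the observed counts, computed per channel and averaged: the
#' fraction of spike-count variance the shared latent phase sequence
#' accounts for.
#'
#' @param fit an [HMMFit-class].
#' @param recording,condition the fitted data.
#' @return mean R-squared across channels.
#' @export
varianceExplained <- function(fit, recording, condition = NULL) {
  tc <- trialCounts(recording, condition)
  lambda <- fit@params@rates * fit@binWidth
  post <- posteriors(fit)
  if (length(post) != length(tc$counts))
    stop("fit and recording/condition disagree on the trial set")
  obs <- do.call(cbind, tc$counts)
  pred <- do.call(cbind, lapply(post, function(g) t(g %*% t(lambda))))
  r2 <- vapply(seq_len(nrow(obs)), function(ch) {
    sst <- sum((obs[ch, ] - mean(obs[ch, ]))^2)
    if (sst == 0) stop("zero-variance counts on channel ", ch)
    1 - sum((obs[ch, ] - pred[ch, ])^2) / sst
  }, numeric(1))
  mean(r2)
}
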