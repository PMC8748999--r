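## Shared miniature session builders. All fixtures are generated in code.

## single-condition session, fixed-length trials
smallSession <- function(nTrials = 20L, nChannels = 4L, duration = 0.5,
                         sessionType = "two_phase", seed = 1L,
                         rates = markovRates(10, 10), ...) {
  generateSession(sessionConfig(
    nChannels = as.integer(nChannels),
    nTrialsPerCondition = as.integer(nTrials),
    attentionLevels = "attend_rf", orientations = 0,
    windowRange = c(duration, duration), sessionType = sessionType,
    ratesControl = rates, ratesAttention = rates, seed = as.integer(seed),
    ...))
}

## strongly separable session: large Delta-r, low noise floor
separableSession <- function(nTrials = 30L, seed = 2L) {
  smallSession(nTrials = nTrials, nChannels = 6L, duration = 0.8, seed = seed,
               rateDistribution = list(meanlog_off = log(5), sdlog_off = 0,
                                       meanlog_dr = log(300), sdlog_dr = 0))
}

## pooled ground-truth episode durations (s) of a recording
truthEpisodes <- function(rec) {
  st <- groundTruth(rec)$states
  bw <- binWidth(rec)
  out <- list(on = numeric(0), off = numeric(0))
  for (tr in seq_len(nrow(st))) {
    s <- st[tr, !is.na(st[tr, ])]
    ep <- episodeDurations(s, dt = bw)
    out$on <- c(out$on, ep$duration[ep$phase == "on"])
    out$off <- c(out$off, ep$duration[ep$phase == "off"])
  }
  out
}

## chop a single long StateField run into pseudo-trials of winBins bins,
## strided to decorrelate adjacent windows
chopField <- function(field, winBins = 25L, strideBins = 40L) {
  arr <- stateArrays(field)[[1]]
  nW <- (dim(arr)[3] - winBins) %/% strideBins + 1L
  trials <- lapply(seq_len(nW), function(k) {
    b0 <- (k - 1L) * strideBins + 1L
    arr[, , b0:(b0 + winBins - 1L), drop = FALSE]
  })
  new("StateField", fields = trials, dt = field@dt, meta = field@meta)
}

## brute-force posterior over all n^B latent paths (oracle for forward-backward)
enumeratePosteriors <- function(ell, A, pi0) {
  B <- nrow(ell); n <- ncol(ell)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), B)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + ell[1, p[1]]
    if (B > 1)
      v <- v + sum(log(A[cbind(p[-B], p[-1])])) + sum(ell[cbind(2:B, p[-1])])
    v
  })
  m <- max(lp)
  w <- exp(lp - m)
  loglik <- m + log(sum(w))
  w <- w / sum(w)
  gamma <- vapply(seq_len(B), function(b)
    vapply(seq_len(n), function(s) sum(w[paths[, b] == s]), numeric(1)),
    numeric(n))
  list(gamma = t(gamma), loglik = loglik)
}
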