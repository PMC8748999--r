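#' Configuration of a synthetic columnar session
#'
#' Describes a laminar-recording-like session: 16 channels of multi-unit
#' spike counts in 10 ms bins, 32 task conditions (4 attention states x 8
#' grating orientations), per-trial post-cue fit windows of 0.2-1.9 s
#' (starting 400 ms after the attention cue), a shared two-state Markov
#' population state with condition-dependent transition rates, and
#' heterogeneous per-channel On/Off Poisson rates.
#'
#' @slot nChannels number of recording channels.
#' @slot binWidth spike-count bin width (s).
#' @slot nTrialsPerCondition trials generated per condition.
#' @slot attentionLevels labels of the attention states; the first is the
#'   attend-to-RF state and receives `ratesAttention`, all others are
#'   control states.
#' @slot orientations grating orientation labels (degrees).
#' @slot windowRange min/max duration (s) of the per-trial fit window.
#' @slot sessionType `"two_phase"` (shared On-Off switching) or
#'   `"one_phase"` (constant rates: Delta-r is forced to 0 so no detectable
#'   switching exists).
#' @slot ratesControl,ratesAttention [MarkovRates-class] of the population
#'   state in control and attend-to-RF conditions.
#' @slot rateDistribution lognormal parameters of the per-channel rate
#'   sampler, list with `meanlog_off`, `sdlog_off`, `meanlog_dr`, `sdlog_dr`
#'   (r_off and Delta-r = r_on - r_off in Hz). Optional entries
#'   `meanlog_gain`, `sdlog_gain` (default 0, 0) draw a per-channel
#'   lognormal gain applied to Delta-r in the attend-to-RF condition,
#'   emulating heterogeneous attentional modulation of the On-Off rate
#'   difference; the default leaves rates identical across conditions.
#' @slot rfShift lateral RF-center drift per channel step (dva).
#' @slot rfGrid stimulus-grid geometry for RF mapping: list with `n` (6),
#'   `spacing` (dva) and `origin` (dva pair).
#' @slot seed integer seed.
#' @export
setClass("SessionConfig",
  representation(nChannels = "integer", binWidth = "numeric",
                 nTrialsPerCondition = "integer", attentionLevels = "character",
                 orientations = "numeric", windowRange = "numeric",
                 sessionType = "character",
                 ratesControl = "MarkovRates", ratesAttention = "MarkovRates",
                 rateDistribution = "list", rfShift = "numeric",
                 rfGrid = "list", seed = "integer"),
  validity = function(object) {
    if (object@binWidth <= 0) return("binWidth must be > 0")
    if (object@nChannels < 1) return("nChannels must be >= 1")
    if (object@nTrialsPerCondition < 1) return("nTrialsPerCondition must be >= 1")
    wr <- object@windowRange
    if (length(wr) != 2 || wr[1] <= 0 || wr[2] < wr[1])
      return("windowRange must be positive and ordered (min, max)")
    if (!object@sessionType %in% c("two_phase", "one_phase"))
      return("sessionType must be 'two_phase' or 'one_phase'")
    rd <- object@rateDistribution
    need <- c("meanlog_off", "sdlog_off", "meanlog_dr", "sdlog_dr")
    if (!all(need %in% names(rd)))
      return(paste("rateDistribution must contain:", paste(need, collapse = ", ")))
    if (rd$sdlog_off < 0 || rd$sdlog_dr < 0)
      return("rateDistribution sdlog parameters must be >= 0")
    if (object@rfShift < 0) return("rfShift must be >= 0")
    TRUE
  })

#' @param nChannels,binWidth,nTrialsPerCondition,attentionLevels,orientations
#'   see slots.
#' @param windowRange,sessionType,ratesControl,ratesAttention see slots.
#' @param rateDistribution,rfShift,rfGrid,seed see slots. Default rate
#'   distribution gives a median multi-unit mean rate near 100 Hz with a
#'   broad Delta-r spread.
#' @rdname SessionConfig-class
#' @export
sessionConfig <- function(nChannels = 16L, binWidth = 0.010,
                          nTrialsPerCondition = 20L,
                          attentionLevels = c("attend_rf", "attend_away1",
                                              "attend_away2", "attend_away3"),
                          orientations = seq(0, 157.5, by = 22.5),
                          windowRange = c(0.200, 1.900),
                          sessionType = c("two_phase", "one_phase"),
                          ratesControl = markovRates(10, 10),
                          ratesAttention = markovRates(11, 8),
                          rateDistribution = list(meanlog_off = log(50),
                                                  sdlog_off = 0.4,
                                                  meanlog_dr = log(90),
                                                  sdlog_dr = 0.5),
                          rfShift = 0.3,
                          rfGrid = list(n = 6L, spacing = 1.5, origin = c(-9, -9)),
                          seed = 1L) {
  sessionType <- match.arg(sessionType)
  new("SessionConfig", nChannels = as.integer(nChannels),
      binWidth = as.numeric(binWidth),
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      attentionLevels = attentionLevels, orientations = as.numeric(orientations),
      windowRange = as.numeric(windowRange), sessionType = sessionType,
      ratesControl = ratesControl, ratesAttention = ratesAttention,
      rateDistribution = rateDistribution, rfShift = as.numeric(rfShift),
      rfGrid = rfGrid, seed = as.integer(seed))
}

setMethod("show", "SessionConfig", function(object) {
  cat(sprintf("SessionConfig: %d channels, %d x %d conditions x %d trials, %s\n",
              object@nChannels, length(object@attentionLevels),
              length(object@orientations), object@nTrialsPerCondition,
              object@sessionType))
})

## Discrete-bin two-state chain; per-bin switch probabilities 1 - exp(-alpha dt)
## (never negative, matches the HMM bin width). Starts from the stationary
## distribution.
simulateStateChain <- function(rates, nBins, binWidth) {
  a1 <- alpha1(rates); a2 <- alpha2(rates)
  if (a1 + a2 == 0) return(rep(0L, nBins))
  p01 <- 1 - exp(-a1 * binWidth)   # Off -> On
  p10 <- 1 - exp(-a2 * binWidth)   # On -> Off
  s <- integer(nBins)
  s[1] <- as.integer(runif(1) < a1 / (a1 + a2))
  if (nBins > 1) {
    u <- runif(nBins - 1)
    for (b in 2:nBins) {
      s[b] <- if (s[b - 1] == 1L) as.integer(u[b - 1] >= p10)
              else as.integer(u[b - 1] < p01)
    }
  }
  s
}

#' Sample per-neuron (r_on, r_off) firing-rate pairs
#'
#' Draws `r_off` and `Delta-r = r_on - r_off` independently from lognormal
#' distributions (so `r_on >= r_off >= 0` holds by construction), emulating
#' the broad, right-skewed On/Off rate distributions that population-state
#' HMM fits produce for multi-unit activity.
#'
#' @param n number of pseudo-neurons to draw.
#' @param rateDistribution list with `meanlog_off`, `sdlog_off`,
#'   `meanlog_dr`, `sdlog_dr`; `sdlog = 0` gives a degenerate
#'   (all-identical) sample.
#' @param seed optional integer seed.
#' @return a data.frame with columns `r_on`, `r_off`, `dr` (Hz), one row per
#'   pseudo-neuron.
#' @export
sampleRatePairs <- function(n, rateDistribution = sessionConfig()@rateDistribution,
                            seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n <= 0)
    stop("n must be a positive count")
  rd <- rateDistribution
  need <- c("meanlog_off", "sdlog_off", "meanlog_dr", "sdlog_dr")
  if (!all(need %in% names(rd)))
    stop("rateDistribution must contain: ", paste(need, collapse = ", "))
  if (rd$sdlog_off < 0 || rd$sdlog_dr < 0) stop("sdlog parameters must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rOff <- rlnorm(n, rd$meanlog_off, rd$sdlog_off)
  dr <- rlnorm(n, rd$meanlog_dr, rd$sdlog_dr)
  data.frame(r_on = rOff + dr, r_off = rOff, dr = dr)
}

#' Generate a synthetic columnar recording session
#'
#' Simulates a session per its [SessionConfig-class]: each trial of a
#' two-phase session carries one shared two-state Markov population state
#' (discrete 10 ms bins, per-bin switch probabilities `1 - exp(-alpha dt)`;
#' rates per condition), and each channel emits Poisson counts with per-bin
#' rate `r_off + Delta-r * S(t)`. One-phase sessions use `Delta-r = 0`
#' (constant-rate Poisson, no detectable switching). Channel RF centers
#' drift laterally with channel index ([generateRFMap()]); the first half of
#' the channels is labeled superficial, the second half deep.
#'
#' @param config a [SessionConfig-class].
#' @return a [SessionRecording-class] with ground truth attached.
#' @examples
#' rec <- generateSession(sessionConfig(nTrialsPerCondition = 2L,
#'                                      orientations = c(0, 90)))
#' rec
#' @export
generateSession <- function(config) {
  stopifnot(is(config, "SessionConfig"))
  validObject(config)
  for (nm in c("ratesControl", "ratesAttention")) validObject(slot(config, nm))
  rd <- config@rateDistribution

  set.seed(config@seed)
  nCh <- config@nChannels
  bw <- config@binWidth

  ## per-channel On/Off rates (r_on >= r_off >= 0 by construction)
  pairs <- sampleRatePairs(nCh, rd)
  dr <- if (config@sessionType == "one_phase") rep(0, nCh) else pairs$dr
  rOff <- pairs$r_off
  if (any(rOff < 0) || any(dr < 0)) stop("rate_distribution produced negative rates")
  gain <- rlnorm(nCh, rd$meanlog_gain %||% 0, rd$sdlog_gain %||% 0)
  drAtt <- dr * gain                      # Delta-r in the attend-to-RF state

  meta <- expand.grid(attention = config@attentionLevels,
                      orientation = config@orientations,
                      rep = seq_len(config@nTrialsPerCondition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nTrials <- nrow(meta)
  meta$condition <- paste(meta$attention, meta$orientation, sep = ":")
  meta$duration <- round(runif(nTrials, config@windowRange[1],
                               config@windowRange[2]) / bw) * bw
  meta$t_start <- 0.400                      # fit window opens 400 ms post-cue
  meta$n_bins <- as.integer(round(meta$duration / bw))
  maxBins <- max(meta$n_bins)

  cnt <- array(NA_integer_, dim = c(nCh, nTrials, maxBins))
  states <- matrix(NA_integer_, nTrials, maxBins)
  attended <- meta$attention == config@attentionLevels[1]
  for (tr in seq_len(nTrials)) {
    nb <- meta$n_bins[tr]
    rates <- if (attended[tr]) config@ratesAttention else config@ratesControl
    s <- simulateStateChain(rates, nb, bw)
    states[tr, seq_len(nb)] <- s
    drTr <- if (attended[tr]) drAtt else dr
    lam <- outer(rOff, rep(1, nb)) + outer(drTr, s)   # channels x bins, Hz
    cnt[, tr, seq_len(nb)] <- rpois(nCh * nb, lam * bw)
  }

  rf <- t(vapply(seq_len(nCh), function(ch)
    generateRFMap(ch, rfShift = config@rfShift, grid = config@rfGrid),
    numeric(2)))
  channelMeta <- S4Vectors::DataFrame(
    channel = seq_len(nCh),
    layer = rep(c("superficial", "deep"), each = ceiling(nCh / 2))[seq_len(nCh)],
    rf_x = rf[, 1], rf_y = rf[, 2])

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = channelMeta,
    colData = S4Vectors::DataFrame(meta),
    metadata = list(
      bin_width = bw,
      session_type = config@sessionType,
      config = config,
      ground_truth = list(states = states,
                          r_on = rOff + dr, r_off = rOff, dr = dr,
                          dr_attention = drAtt,
                          rates_control = config@ratesControl,
                          rates_attention = config@ratesAttention)))
  as(se, "SessionRecording")
}

#' Synthetic RF center from a stimulus-grid response map
#'
#' Builds a synthetic response map on the 6 x 6 stimulus grid for one
#' channel and returns its center of mass, the standard RF-center estimate.
#' The map allocates the channel's response to the four grid cells
#' surrounding a peak that drifts diagonally with channel index by `rfShift`
#' dva per channel step (bilinear allocation, so the center of mass
#' reproduces the continuous peak position exactly); optional Poisson-like
#' jitter can be added.
#'
#' @param channelIndex 1-based channel number.
#' @param rfShift lateral drift (dva per channel step) of the RF center.
#' @param grid list with `n` (grid side), `spacing` (dva between grid
#'   positions) and `origin` (dva coordinates of grid position (1,1)).
#' @param responseMap optionally, a ready-made `n x n` response map whose
#'   center of mass is returned directly (the other arguments are ignored).
#' @param noise standard deviation of truncated-at-zero Gaussian jitter
#'   added to the map (response units); 0 for a noiseless map.
#' @param seed optional seed for the jitter.
#' @return RF center as a named numeric `c(x, y)` in dva.
#' @export
generateRFMap <- function(channelIndex, rfShift = 0.3,
                          grid = list(n = 6L, spacing = 1.5, origin = c(-9, -9)),
                          responseMap = NULL, noise = 0, seed = NULL) {
  if (is.null(responseMap)) {
    n <- grid$n
    sp <- grid$spacing
    ## peak drifts diagonally; components rfShift/sqrt(2) per step in x and y
    step <- rfShift / sqrt(2)
    base <- grid$origin + sp            # one cell of margin from the grid edge
    peak <- base + (channelIndex - 1) * step
    gx <- grid$origin[1] + (seq_len(n) - 1) * sp
    gy <- grid$origin[2] + (seq_len(n) - 1) * sp
    if (peak[1] > gx[n] || peak[2] > gy[n])
      stop("RF peak drifted outside the stimulus grid; enlarge the grid or reduce rfShift")
    responseMap <- matrix(0, n, n)
    ix <- findInterval(peak[1], gx); iy <- findInterval(peak[2], gy)
    fx <- (peak[1] - gx[ix]) / sp; fy <- (peak[2] - gy[iy]) / sp
    responseMap[ix, iy] <- (1 - fx) * (1 - fy)
    if (ix < n) responseMap[ix + 1, iy] <- fx * (1 - fy)
    if (iy < n) responseMap[ix, iy + 1] <- (1 - fx) * fy
    if (ix < n && iy < n) responseMap[ix + 1, iy + 1] <- fx * fy
    if (noise > 0) {
      if (!is.null(seed)) set.seed(seed)
      responseMap <- pmax(responseMap + rnorm(n * n, 0, noise), 0)
    }
  } else {
    n <- nrow(responseMap)
    gx <- grid$origin[1] + (seq_len(n) - 1) * grid$spacing
    gy <- grid$origin[2] + (seq_len(n) - 1) * grid$spacing
  }
  tot <- sum(responseMap)
  if (tot <= 0) stop("all-zero response map: center of mass undefined")
  c(x = sum(rowSums(responseMap) * gx) / tot,
    y = sum(colSums(responseMap) * gy) / tot)
}

#' Extract per-trial count matrices from a recording
#'
#' @param recording a [SessionRecording-class].
#' @param condition condition label (`trialMeta$condition`) to restrict to,
#'   or `NULL` for all trials.
#' @return list with `trials` (indices) and `counts` (list of channels x
#'   bins matrices trimmed to each trial's valid bins).
#' @export
trialCounts <- function(recording, condition = NULL) {
  cd <- SummarizedExperiment::colData(recording)
  idx <- if (is.null(condition)) seq_len(nrow(cd))
         else which(cd$condition == condition)
  if (length(idx) == 0) stop("no trials in condition '", condition, "'")
  cnt <- counts(recording)
  list(trials = idx,
       counts = lapply(idx, function(tr) {
         nb <- cd$n_bins[tr]
         m <- cnt[, tr, seq_len(nb), drop = FALSE]
         dim(m) <- c(dim(cnt)[1], nb)
         m
       }))
}
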