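#' Spike counts in an analysis window
#'
#' Sums the 10 ms bins of each trial over a fixed post-cue window (default
#' 400-600 ms after cue onset, i.e. one 200 ms count per trial and
#' channel). Trials whose recorded window does not cover the requested
#' window are dropped and counted.
#'
#' @param recording a [SessionRecording-class].
#' @param window `c(start, end)` in seconds relative to cue onset.
#' @param condition optional condition label.
#' @return matrix trials x channels of window counts, with attributes
#'   `trials` (kept trial indices) and `dropped` (number excluded).
#' @export
countWindow <- function(recording, window = c(0.400, 0.600), condition = NULL) {
  cd <- SummarizedExperiment::colData(recording)
  bw <- binWidth(recording)
  idx <- if (is.null(condition)) seq_len(nrow(cd))
         else which(cd$condition == condition)
  tStart <- cd$t_start[idx]
  tEnd <- tStart + cd$duration[idx]
  ok <- tStart <= window[1] + 1e-9 & tEnd >= window[2] - 1e-9
  dropped <- sum(!ok)
  keep <- idx[ok]
  if (length(keep) == 0) stop("no trial covers the requested window")
  cnt <- counts(recording)
  out <- t(vapply(keep, function(tr) {
    b0 <- as.integer(round((window[1] - cd$t_start[tr]) / bw)) + 1L
    b1 <- as.integer(round((window[2] - cd$t_start[tr]) / bw))
    rowSums(cnt[, tr, b0:b1, drop = FALSE], dims = 1)
  }, numeric(dim(cnt)[1])))
  attr(out, "trials") <- keep
  attr(out, "dropped") <- dropped
  out
}

#' Noise correlation of two channels
#'
#' Pearson correlation coefficient of trial-to-trial spike counts.
#'
#' @param countsI,countsJ numeric vectors of per-trial counts.
#' @return `r_sc` in `[-1, 1]`, or `NA` (with a warning) for zero-variance
#'   input.
#' @export
noiseCorrelation <- function(countsI, countsJ) {
  if (length(countsI) < 3 || length(countsJ) != length(countsI))
    stop("need >= 3 paired trials")
  if (var(countsI) == 0 || var(countsJ) == 0) {
    warning("zero-variance counts: noise correlation undefined")
    return(NA_real_)
  }
  cor(countsI, countsJ)
}

#' Fano factor of trial spike counts
#'
#' Unbiased (n - 1) sample variance over the sample mean.
#'
#' @param counts numeric vector of per-trial counts with positive mean.
#' @return Fano factor.
#' @export
fanoFactor <- function(counts) {
  m <- mean(counts)
  if (is.na(m) || m <= 0) {
    warning("zero mean count: Fano factor undefined")
    return(NA_real_)
  }
  var(counts) / m
}

#' Attentional modulation index
#'
#' `(x_att - x_ctl) / (x_att + x_ctl)`; lies in `[-1, 1]` when both inputs
#' are non-negative. Pairs with a zero denominator are returned as `NA` and
#' counted.
#'
#' @param xAtt,xCtl statistic in attention and control conditions
#'   (vectorized).
#' @return numeric vector of modulation indices with attribute `excluded`.
#' @export
modulationIndex <- function(xAtt, xCtl) {
  denom <- xAtt + xCtl
  bad <- !is.na(denom) & denom == 0
  out <- ifelse(bad, NA_real_, (xAtt - xCtl) / denom)
  attr(out, "excluded") <- sum(bad)
  out
}

#' Convert an RF-center distance to a cortical distance
#'
#' Applies the cortical magnification factor `M(E) = 3.1 * E^-0.9` (mm per
#' dva at eccentricity `E` dva): `d_cortical = M(E) * d_RF`.
#'
#' @param rfDistance RF-center distance (dva), >= 0.
#' @param eccentricity eccentricity (dva), > 0; for a pair, the mean RF
#'   eccentricity of its two channels.
#' @return cortical distance in mm.
#' @export
corticalDistance <- function(rfDistance, eccentricity) {
  if (any(rfDistance < 0)) stop("rfDistance must be >= 0")
  if (any(eccentricity <= 0)) stop("eccentricity must be > 0")
  3.1 * eccentricity^(-0.9) * rfDistance
}

#' Pairwise statistics table of a recording
#'
#' Builds one row per within-layer channel pair: RF-center distance,
#' cortical distance (pair-mean eccentricity), noise correlation and
#' per-channel Fano factors per attention condition (attend-to-RF trials
#' versus all others pooled as control), using the standard 400-600 ms
#' count window.
#'
#' @param recording a [SessionRecording-class] generated with the default
#'   attention labels.
#' @param attLevel label of the attend-to-RF state.
#' @param window analysis window (s, post-cue).
#' @return data.frame of pair records.
#' @export
pairStatistics <- function(recording, attLevel = "attend_rf",
                           window = c(0.400, 0.600)) {
  cd <- SummarizedExperiment::colData(recording)
  rd <- SummarizedExperiment::rowData(recording)
  cw <- countWindow(recording, window)
  trialAtt <- cd$attention[attr(cw, "trials")] == attLevel
  nCh <- ncol(cw)
  pairs <- which(upper.tri(matrix(0, nCh, nCh)), arr.ind = TRUE)
  pairs <- pairs[rd$layer[pairs[, 1]] == rd$layer[pairs[, 2]], , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dRF <- sqrt((rd$rf_x[i] - rd$rf_x[j])^2 + (rd$rf_y[i] - rd$rf_y[j])^2)
    ecc <- mean(c(sqrt(rd$rf_x[i]^2 + rd$rf_y[i]^2),
                  sqrt(rd$rf_x[j]^2 + rd$rf_y[j]^2)))
    data.frame(
      i = i, j = j, layer = rd$layer[i], rf_distance = dRF,
      cortical_distance = corticalDistance(dRF, ecc),
      rsc_att = suppressWarnings(noiseCorrelation(cw[trialAtt, i], cw[trialAtt, j])),
      rsc_ctl = suppressWarnings(noiseCorrelation(cw[!trialAtt, i], cw[!trialAtt, j])),
      ff_i_att = suppressWarnings(fanoFactor(cw[trialAtt, i])),
      ff_i_ctl = suppressWarnings(fanoFactor(cw[!trialAtt, i])),
      ff_j_att = suppressWarnings(fanoFactor(cw[trialAtt, j])),
      ff_j_ctl = suppressWarnings(fanoFactor(cw[!trialAtt, j])))
  })
  do.call(rbind, res)
}

#' Linear regression of a pair statistic on lateral distance
#'
#' Ordinary least squares of a response (e.g. `r_sc` or the attentional
#' change `Delta r_sc`) on RF-center distance, with a one-sided t-test on
#' the slope sign.
#'
#' @param pairs data.frame with a distance column and the response.
#' @param response name of the response column.
#' @param distance name of the distance column.
#' @param layer optional layer filter (requires a `layer` column).
#' @param alternative `"less"` tests slope < 0, `"greater"` slope > 0.
#' @return list with `slope`, `se`, `p` (one-sided), `n`.
#' @export
distanceRegression <- function(pairs, response, distance = "rf_distance",
                               layer = NULL, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.null(layer)) pairs <- pairs[pairs$layer == layer, , drop = FALSE]
  pairs <- pairs[is.finite(pairs[[response]]) & is.finite(pairs[[distance]]), ,
                 drop = FALSE]
  if (nrow(pairs) < 10) stop("need >= 10 pairs for the distance regression")
  if (var(pairs[[distance]]) == 0) stop("constant distances: slope undefined")
  fit <- lm(pairs[[response]] ~ pairs[[distance]])
  sm <- summary(fit)$coefficients
  tstat <- sm[2, 3]
  df <- fit$df.residual
  p <- if (alternative == "less") pt(tstat, df) else pt(tstat, df, lower.tail = FALSE)
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]), p = unname(p),
       n = nrow(pairs))
}

#' Fit an exponential decay to a correlation-distance curve
#'
#' Nonlinear least squares of `A * exp(-d / L)` (Levenberg-Marquardt,
#' initialized from a log-linear fit on the positive values, which also
#' serves as a fallback). Non-decaying data are reported as `L = Inf`.
#'
#' @param d distances.
#' @param rsc correlations per distance.
#' @param weights optional weights (e.g. pair counts per bin).
#' @param form `"exp"` fits `A exp(-d/L)`; `"oz"` fits the 2-D
#'   Ornstein-Zernike asymptote `A exp(-d/L)/sqrt(d)` (requires `d > 0`),
#'   which removes the power-law prefactor bias of 2-D lattice
#'   correlations at distances beyond the correlation length.
#' @return list with `A`, `L`, standard errors `A_se`/`L_se` (NA for the
#'   fallback), `method`, and `infinite` flag for non-decaying input.
#' @export
fitCorrelationLength <- function(d, rsc, weights = NULL,
                                 form = c("exp", "oz")) {
  form <- match.arg(form)
  ok <- is.finite(d) & is.finite(rsc)
  d <- d[ok]; rsc <- rsc[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(unique(d)) < 4) stop("need >= 4 distance bins")
  pos <- rsc > 0
  if (sum(pos) >= 2) {
    ll <- lm(log(rsc[pos]) ~ d[pos],
             weights = if (is.null(weights)) NULL else weights[pos])
    slope <- coef(ll)[2]
  } else slope <- NA_real_
  if (!is.finite(slope) || slope >= 0) {
    return(list(A = mean(rsc), L = Inf, A_se = NA_real_, L_se = NA_real_,
                method = "loglinear", infinite = TRUE))
  }
  start <- list(A = exp(unname(coef(ll)[1])), L = -1 / unname(slope))
  w <- if (is.null(weights)) rep(1, length(d)) else weights
  fit <- if (form == "exp") {
    try(minpack.lm::nlsLM(rsc ~ A * exp(-d / L), start = start, weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
  } else {
    if (any(d <= 0)) stop("form = 'oz' requires d > 0")
    start$A <- start$A * sqrt(min(d))
    try(minpack.lm::nlsLM(rsc ~ A * exp(-d / L) / sqrt(d), start = start,
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    return(list(A = start$A, L = start$L, A_se = NA_real_, L_se = NA_real_,
                method = "loglinear", infinite = FALSE))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  list(A = unname(cf["A"]), L = unname(cf["L"]),
       A_se = unname(se[1]), L_se = unname(se[2]),
       method = "nls", infinite = FALSE)
}

#' Decile comparison of measured versus predicted changes
#'
#' Sorts items by a grouping statistic (e.g. the attentional change in
#' `Delta-r` for Fano factors, or in `sqrt(Delta-r_i Delta-r_j)` for
#' pairs), splits them into 10 equally sized groups (stable ordering breaks
#' ties) and returns the per-group means of the measured and predicted
#' changes.
#'
#' @param measured,predicted numeric vectors of per-item changes.
#' @param grouping the grouping statistic, same length.
#' @param nGroups number of groups (default 10).
#' @return data.frame with one row per group: `group`, `n`, `grouping`,
#'   `measured`, `predicted` (group means).
#' @export
decileComparison <- function(measured, predicted, grouping, nGroups = 10L) {
  ok <- is.finite(measured) & is.finite(predicted) & is.finite(grouping)
  measured <- measured[ok]; predicted <- predicted[ok]; grouping <- grouping[ok]
  n <- length(measured)
  if (n < 50) stop("need >= 50 items for a decile comparison")
  o <- order(grouping)                      # stable: ties keep input order
  grp <- rep(seq_len(nGroups), diff(floor(seq(0, n, length.out = nGroups + 1))))
  idx <- o
  data.frame(group = seq_len(nGroups),
             n = as.numeric(table(grp)),
             grouping = tapply(grouping[idx], grp, mean),
             measured = tapply(measured[idx], grp, mean),
             predicted = tapply(predicted[idx], grp, mean))
}
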