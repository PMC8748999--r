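## Closed-form predictions of the binary-unit network: stationary occupancy,
## spatial pair correlation, correlation length, doubly stochastic count
## moments, Fano factor and distance-dependent noise correlations.

#' Stationary On probability of the two-state process
#'
#' `S(inf) = alpha1 / (alpha1 + alpha2)`.
#'
#' @param rates a [MarkovRates-class].
#' @return probability in `[0, 1]`.
#' @export
stationaryOnProb <- function(rates) {
  a1 <- alpha1(rates); a2 <- alpha2(rates)
  if (a1 + a2 <= 0) stop("alpha1 + alpha2 must be > 0")
  a1 / (a1 + a2)
}

#' Correlation length of the coupled binary network
#'
#' `L = sqrt(beta1 / (alpha1 + alpha2))` in dimensionless units of the
#' lattice constant.
#'
#' @param beta1 Off-to-On coupling rate (1/s per Laplacian unit), >= 0.
#' @param rates a [MarkovRates-class].
#' @return correlation length in lattice units.
#' @export
correlationLength <- function(beta1, rates) {
  if (beta1 < 0) stop("beta1 must be >= 0")
  a <- alpha1(rates) + alpha2(rates)
  if (a <= 0) stop("alpha1 + alpha2 must be > 0")
  sqrt(beta1 / a)
}

#' Steady-state pair moment at lattice distance d
#'
#' `G(d; inf) = S(inf)^2 + S(inf)(1 - S(inf)) exp(-d / L)`. At `d = 0` this
#' is `S(inf)` (binary identity `<S^2> = <S>`); at large distance it tends
#' to the independence value `S(inf)^2`.
#'
#' @param d lattice distance(s), >= 0.
#' @param rates a [MarkovRates-class].
#' @param beta1 coupling rate defining `L` via [correlationLength()].
#' @return pair moment(s) `<S_i S_j>`.
#' @export
pairStateCorrelation <- function(d, rates, beta1) {
  if (any(d < 0)) stop("d must be >= 0")
  s <- stationaryOnProb(rates)
  L <- correlationLength(beta1, rates)
  decay <- ifelse(d == 0, 1, if (L > 0) exp(-d / L) else 0)
  s^2 + s * (1 - s) * decay
}

#' On-time variance kernel of the two-state process
#'
#' The variance of the On-occupancy time of a stationary two-state chain
#' over a window `T`:
#' \deqn{V = \frac{2\alpha_1\alpha_2}{(\alpha_1+\alpha_2)^3}
#'   \left[T - \frac{1 - e^{-(\alpha_1+\alpha_2)T}}{\alpha_1+\alpha_2}\right].}
#'
#' @param rates a [MarkovRates-class].
#' @param T window duration (s).
#' @return variance kernel V (s^2).
#' @export
onTimeVariance <- function(rates, T) {
  if (any(T < 0)) stop("T must be >= 0")
  a1 <- alpha1(rates); a2 <- alpha2(rates)
  a <- a1 + a2
  if (a <= 0) stop("alpha1 + alpha2 must be > 0")
  2 * a1 * a2 / a^3 * (T - (1 - exp(-a * T)) / a)
}

#' Closed-form spike-count moments of a doubly stochastic neuron
#'
#' Mean and variance of the window count of a neuron with On/Off rates
#' riding on the shared two-state process:
#' `E[N] = (r_off + S(inf) * Delta-r) * T` and
#' `Var[N] = Delta-r^2 * V + r_off * T + S(inf) * T * Delta-r` with the
#' On-time variance kernel `V` of [onTimeVariance()] (the non-Poisson term
#' vanishes when `Delta-r = 0`).
#'
#' @param rates a [MarkovRates-class] shared by the population.
#' @param rOn,rOff On and Off firing rates (Hz), `rOn >= rOff >= 0`.
#' @param T count window (s), > 0.
#' @return list with `mean`, `variance` and `dr`.
#' @export
countMoments <- function(rates, rOn, rOff, T) {
  if (any(T <= 0)) stop("T must be > 0")
  if (any(rOff < 0) || any(rOn < rOff)) stop("need r_on >= r_off >= 0")
  dr <- rOn - rOff
  s <- stationaryOnProb(rates)
  V <- onTimeVariance(rates, T)
  list(mean = (rOff + s * dr) * T,
       variance = dr^2 * V + rOff * T + s * T * dr,
       dr = dr)
}

#' Predicted Fano factor
#'
#' Ratio of the closed-form count variance to the count mean; always >= 1,
#' equal to 1 for a pure Poisson neuron (`Delta-r = 0`), and asymptotically
#' proportional to `Delta-r` in the strong-modulation regime.
#'
#' @inheritParams countMoments
#' @return Fano factor(s).
#' @export
fanoFactorPred <- function(rates, rOn, rOff, T) {
  m <- countMoments(rates, rOn, rOff, T)
  if (any(m$mean <= 0)) stop("count mean must be > 0")
  m$variance / m$mean
}

#' Predicted noise correlation of a neuron pair
#'
#' For two neurons riding on the same network statistics (shared
#' `alpha1, alpha2`), the zero-distance amplitude is
#' \deqn{A = \frac{V \Delta r_i \Delta r_j}{\sqrt{Var[N_i] Var[N_j]}},}
#' and at lattice distance `d` the prediction is `A exp(-d / L)` with `L`
#' from [correlationLength()].
#'
#' @param rates shared [MarkovRates-class].
#' @param rOnI,rOffI,rOnJ,rOffJ firing rates (Hz) of neurons i and j.
#' @param T count window (s).
#' @param d lattice distance(s), default 0.
#' @param beta1 coupling rate; required when any `d > 0`.
#' @param ratesJ optional second [MarkovRates-class]; must equal `rates`
#'   (cross-rate pairs are rejected, the formula assumes shared statistics).
#' @return a [CorrelationPrediction-class] (single `d`) or numeric vector
#'   of predictions along `d`.
#' @export
noiseCorrelationPred <- function(rates, rOnI, rOffI, rOnJ, rOffJ, T,
                                 d = 0, beta1 = NULL, ratesJ = NULL) {
  if (!is.null(ratesJ) &&
      (alpha1(ratesJ) != alpha1(rates) || alpha2(ratesJ) != alpha2(rates)))
    stop("both neurons of a pair must share (alpha1, alpha2)")
  mi <- countMoments(rates, rOnI, rOffI, T)
  mj <- countMoments(rates, rOnJ, rOffJ, T)
  if (any(mi$variance == 0) || any(mj$variance == 0))
    stop("zero count variance: prediction undefined")
  V <- onTimeVariance(rates, T)
  A <- V * mi$dr * mj$dr / sqrt(mi$variance * mj$variance)
  if (all(d == 0)) {
    if (length(A) > 1) return(A)
    return(new("CorrelationPrediction", amplitude = A, length = 0,
               distances = 0, curve = A))
  }
  if (is.null(beta1)) stop("beta1 required for d > 0")
  L <- correlationLength(beta1, rates)
  curve <- A * ifelse(d == 0, 1, if (L > 0) exp(-d / L) else 0)
  if (length(A) == 1)
    new("CorrelationPrediction", amplitude = A, length = L,
        distances = d, curve = curve)
  else curve
}

#' Distribution-averaged zero-distance noise correlation
#'
#' Averages the closed-form zero-distance prediction over sampled
#' `(r_on, r_off)` pairs: consecutive rows of `ratePairs` form the neuron
#' pairs (rows 1-2, 3-4, ...). This is the population-level prediction that
#' simulation of the doubly stochastic model reproduces to better than 1
#' percent relative difference.
#'
#' @param ratePairs data.frame from [sampleRatePairs()] (even row count,
#'   >= 2).
#' @param rates shared [MarkovRates-class].
#' @param T count window (s).
#' @return list with `meanPrediction`, `perPair` (vector of amplitudes) and
#'   `n` (number of neuron pairs).
#' @export
averagedZeroDistancePrediction <- function(ratePairs, rates, T) {
  n <- nrow(ratePairs)
  if (n < 2) stop("need at least 2 rate pairs")
  if (n %% 2 == 1) ratePairs <- ratePairs[-n, , drop = FALSE]
  i <- seq(1, nrow(ratePairs), by = 2)
  j <- i + 1
  A <- noiseCorrelationPred(rates,
                            rOnI = ratePairs$r_on[i], rOffI = ratePairs$r_off[i],
                            rOnJ = ratePairs$r_on[j], rOffJ = ratePairs$r_off[j],
                            T = T)
  list(meanPrediction = mean(A), perPair = A, n = length(A))
}
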