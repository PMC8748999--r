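#' @import methods
#' @importFrom stats rpois rlnorm runif rexp rnorm dpois var sd cor coef
#'   pt lm nls vcov optimize quantile setNames aggregate approx fft
#' @importFrom utils head tail write.csv read.csv
NULL

#' Off-to-On transition rate
#'
#' Accessors for the two rates of the two-state (On-Off) Markov process:
#' `alpha1` is the Off-to-On rate and `alpha2` the On-to-Off rate, both in
#' 1/s. Mean episode durations are their reciprocals
#' (`tau_on = 1/alpha2`, `tau_off = 1/alpha1`).
#'
#' @param object a [MarkovRates-class] object.
#' @return a numeric scalar rate (1/s).
#' @export
setGeneric("alpha1", function(object) standardGeneric("alpha1"))

#' @rdname alpha1
#' @export
setGeneric("alpha2", function(object) standardGeneric("alpha2"))

#' Spike-count bin width of a recording
#'
#' @param object a [SessionRecording-class].
#' @return bin width in seconds.
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' Ground-truth latent state information of a synthetic session
#'
#' @param object a [SessionRecording-class].
#' @return a list with per-trial On/Off state sequences and the true
#'   generator parameters, or `NULL` for sessions without ground truth.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' Number of latent phases of a fitted HMM
#'
#' @param object an [HMMFit-class] or [HMMParams-class].
#' @export
setGeneric("nPhases", function(object) standardGeneric("nPhases"))

#' Per-bin phase transition matrix of a fitted HMM
#'
#' @param object an [HMMFit-class] or [HMMParams-class].
#' @return a row-stochastic matrix, phases x phases.
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' Per-trial posterior phase probabilities
#'
#' @param object an [HMMFit-class].
#' @return a list with one bins x phases matrix per trial.
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' EM log-likelihood trace
#'
#' @param object an [HMMFit-class].
#' @return numeric vector, one total log-likelihood per EM iteration.
#' @export
setGeneric("loglikTrace", function(object) standardGeneric("loglikTrace"))

#' Amplitude and length of a predicted correlation-distance curve
#'
#' @param object a [CorrelationPrediction-class].
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))

#' @rdname amplitude
#' @export
setGeneric("corrLength", function(object) standardGeneric("corrLength"))

#' Binary state fields
#'
#' @param object a [StateField-class].
#' @return a list with one `x` x `y` x bins binary array per trial.
#' @export
setGeneric("stateArrays", function(object) standardGeneric("stateArrays"))
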