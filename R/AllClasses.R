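#' Two-state Markov transition rates
#'
#' The common currency linking the HMM fits, the binary-unit network and the
#' closed-form theory: the Off-to-On rate \eqn{\alpha_1} and the On-to-Off
#' rate \eqn{\alpha_2}, in 1/s. Mean episode durations are
#' \eqn{\tau_{on} = 1/\alpha_2} and \eqn{\tau_{off} = 1/\alpha_1}.
#'
#' @slot alpha1 Off-to-On rate (1/s), non-negative.
#' @slot alpha2 On-to-Off rate (1/s), non-negative.
#' @export
setClass("MarkovRates",
  representation(alpha1 = "numeric", alpha2 = "numeric"),
  validity = function(object) {
    if (length(object@alpha1) != 1 || !is.finite(object@alpha1) || object@alpha1 < 0)
      return("alpha1 must be a single non-negative finite number")
    if (length(object@alpha2) != 1 || !is.finite(object@alpha2) || object@alpha2 < 0)
      return("alpha2 must be a single non-negative finite number")
    TRUE
  })

#' @param alpha1,alpha2 non-negative rates in 1/s.
#' @rdname MarkovRates-class
#' @export
markovRates <- function(alpha1, alpha2) {
  new("MarkovRates", alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2))
}

setMethod("alpha1", "MarkovRates", function(object) object@alpha1)
setMethod("alpha2", "MarkovRates", function(object) object@alpha2)

setMethod("show", "MarkovRates", function(object) {
  cat(sprintf("MarkovRates: alpha1 (Off->On) = %.4g /s, alpha2 (On->Off) = %.4g /s\n",
              object@alpha1, object@alpha2))
  if (object@alpha1 + object@alpha2 > 0)
    cat(sprintf("  stationary On probability = %.4g\n",
                object@alpha1 / (object@alpha1 + object@alpha2)))
})

#' Columnar spike-count recording
#'
#' A laminar-recording-like session: spike counts of `n_channels` channels
#' over trials in fixed-width time bins. Extends
#' \linkS4class{SummarizedExperiment} with channels as rows and trials as
#' columns; the `"counts"` assay is a 3-D integer array (channels x trials x
#' bins) NA-padded past each trial's post-cue window. `rowData` holds
#' channel metadata (cortical layer, RF center in degrees of visual angle);
#' `colData` holds trial metadata (attention state, orientation, condition
#' label, window start relative to cue onset, duration, number of valid
#' bins). `metadata(x)$bin_width` is the bin width in seconds and
#' `metadata(x)$ground_truth` optionally carries the generating latent state
#' sequences and true parameters for synthetic sessions.
#'
#' @export
#' @import SummarizedExperiment
setClass("SessionRecording", contains = "SummarizedExperiment",
  validity = function(object) {
    a <- SummarizedExperiment::assays(object)
    if (!"counts" %in% names(a)) return("assay 'counts' is required")
    cnt <- a[["counts"]]
    if (length(dim(cnt)) != 3) return("counts must be channels x trials x bins")
    v <- cnt[!is.na(cnt)]
    if (any(v < 0) || any(v != round(v)))
      return("counts must be non-negative integers")
    cd <- SummarizedExperiment::colData(object)
    need <- c("condition", "duration", "n_bins")
    if (!all(need %in% colnames(cd)))
      return(paste("trial metadata must contain:", paste(need, collapse = ", ")))
    bw <- S4Vectors::metadata(object)$bin_width
    if (is.null(bw) || bw <= 0) return("bin_width must be a positive number of seconds")
    TRUE
  })

setMethod("binWidth", "SessionRecording",
          function(object) S4Vectors::metadata(object)$bin_width)

setMethod("groundTruth", "SessionRecording",
          function(object) S4Vectors::metadata(object)$ground_truth)

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "SessionRecording",
          function(object) SummarizedExperiment::assay(object, "counts"))

setMethod("show", "SessionRecording", function(object) {
  cnt <- counts(object)
  cat(sprintf("SessionRecording: %d channels x %d trials x <=%d bins of %g ms\n",
              dim(cnt)[1], dim(cnt)[2], dim(cnt)[3], 1000 * binWidth(object)))
  cat(sprintf("  conditions: %d (%s...)\n",
              length(unique(object$condition)),
              paste(head(unique(object$condition), 3), collapse = ", ")))
  cat(sprintf("  session type: %s; ground truth: %s\n",
              S4Vectors::metadata(object)$session_type %||% "unknown",
              if (is.null(groundTruth(object))) "absent" else "present"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters of a shared-latent-state Poisson HMM
#'
#' @slot nPhases number of latent phases.
#' @slot rates channels x phases matrix of firing rates (Hz).
#' @slot transitionMatrix phases x phases row-stochastic matrix of per-bin
#'   transition probabilities. For two phases the Off-stay probability
#'   `p_off` is entry (1,1) and the On-stay probability `p_on` entry (2,2).
#' @slot initialDistribution initial phase probabilities (fixed, not fitted;
#'   see [fitHMM()]).
#' @export
setClass("HMMParams",
  representation(nPhases = "integer", rates = "matrix",
                 transitionMatrix = "matrix", initialDistribution = "numeric"),
  validity = function(object) {
    n <- object@nPhases
    if (ncol(object@rates) != n) return("rates must be channels x nPhases")
    if (any(object@rates < 0)) return("rates must be >= 0")
    if (!all(dim(object@transitionMatrix) == c(n, n)))
      return("transitionMatrix must be nPhases x nPhases")
    if (any(abs(rowSums(object@transitionMatrix) - 1) > 1e-12))
      return("rows of transitionMatrix must sum to 1 (tol 1e-12)")
    if (any(object@transitionMatrix < 0)) return("transition probabilities must be >= 0")
    if (abs(sum(object@initialDistribution) - 1) > 1e-12)
      return("initialDistribution must sum to 1")
    TRUE
  })

setMethod("nPhases", "HMMParams", function(object) object@nPhases)
setMethod("transitionMatrix", "HMMParams", function(object) object@transitionMatrix)

#' Fitted shared-latent-state Poisson HMM
#'
#' @slot params the fitted [HMMParams-class].
#' @slot loglikTrace total data log-likelihood per EM iteration
#'   (non-decreasing).
#' @slot posteriors list of bins x phases posterior matrices, one per fitted
#'   trial.
#' @slot trials indices (into the recording) of the trials that were fitted.
#' @slot condition condition label the fit was restricted to ("" = all).
#' @slot binWidth bin width in seconds.
#' @slot cvErrors normalized cross-validation error per candidate phase
#'   count (filled by [selectNumPhases()]), or length-0.
#' @export
setClass("HMMFit",
  representation(params = "HMMParams", loglikTrace = "numeric",
                 posteriors = "list", trials = "integer",
                 condition = "character", binWidth = "numeric",
                 cvErrors = "numeric"))

setMethod("nPhases", "HMMFit", function(object) object@params@nPhases)
setMethod("transitionMatrix", "HMMFit", function(object) object@params@transitionMatrix)
setMethod("posteriors", "HMMFit", function(object) object@posteriors)
setMethod("loglikTrace", "HMMFit", function(object) object@loglikTrace)

setMethod("show", "HMMFit", function(object) {
  cat(sprintf("HMMFit: %d phases, %d channels, %d trials (condition '%s')\n",
              nPhases(object), nrow(object@params@rates), length(object@trials),
              object@condition))
  cat(sprintf("  final log-likelihood %.2f after %d EM iterations; %d free parameters\n",
              tail(object@loglikTrace, 1), length(object@loglikTrace),
              nFreeParams(object@params)))
  if (nPhases(object) == 2) {
    mr <- hmmMarkovRates(object)
    cat(sprintf("  alpha1 = %.3g /s, alpha2 = %.3g /s\n", alpha1(mr), alpha2(mr)))
  }
})

#' Single-column rate-adaptation model parameters
#'
#' Parameters of the bistable two-variable dynamical system for one column:
#' a fast mean-rate variable r with piecewise-linear self-coupling [Fr()]
#' and a slow adaptation variable a carrying the white noise,
#' \deqn{\epsilon \dot r = F(r) - a + W \nabla^2 r + I_{stim} + I_{att},
#'       \qquad \dot a = g r - a + f + \sqrt{2Q}\,\xi.}
#'
#' The system is dimensionless; the slot `tau` (seconds per model time
#' unit, numerically the adaptation time constant) maps model time to
#' physical time, and `dt` (s) is converted internally.
#'
#' @slot epsilon timescale separation constant (dimensionless, << 1).
#' @slot g,f adaptation gain and offset (dimensionless).
#' @slot Q noise intensity (>= 0, model units).
#' @slot W lateral (diffusive) interaction strength.
#' @slot Istim,Iatt external stimulus and attention currents.
#' @slot tau seconds per model time unit (> 0).
#' @slot dt Euler-Maruyama integration step (s); must satisfy
#'   `dt / tau <= epsilon / 2`.
#' @export
setClass("ColumnParams",
  representation(epsilon = "numeric", g = "numeric", f = "numeric",
                 Q = "numeric", W = "numeric", Istim = "numeric",
                 Iatt = "numeric", tau = "numeric", dt = "numeric"),
  validity = function(object) {
    if (object@epsilon <= 0) return("epsilon must be > 0")
    if (object@Q < 0) return("Q must be >= 0")
    if (object@tau <= 0) return("tau must be > 0")
    if (object@dt <= 0) return("dt must be > 0")
    TRUE
  })

setMethod("show", "ColumnParams", function(object) {
  cat(sprintf(paste0("ColumnParams: epsilon=%g g=%g f=%g Q=%g W=%g ",
                     "Istim=%g Iatt=%g tau=%g s dt=%g s\n"),
              object@epsilon, object@g, object@f, object@Q, object@W,
              object@Istim, object@Iatt, object@tau, object@dt))
})

#' Simulated single-column trace
#'
#' @slot r,a recorded rate and adaptation time series.
#' @slot S binary state series, `S = 1` exactly when `r > 0`.
#' @slot dt recording step (s).
#' @slot duration total simulated time (s).
#' @slot seed seed used.
#' @export
setClass("ColumnTrace",
  representation(r = "numeric", a = "numeric", S = "integer",
                 dt = "numeric", duration = "numeric", seed = "integer"),
  validity = function(object) {
    if (!identical(as.integer(object@r > 0), object@S))
      return("S must equal Theta[r] (1 iff r > 0)")
    TRUE
  })

setMethod("show", "ColumnTrace", function(object) {
  cat(sprintf("ColumnTrace: %g s at %g ms resolution, On fraction %.3f\n",
              object@duration, 1000 * object@dt, mean(object@S)))
})

#' Binary On/Off occupancy field
#'
#' Output of the lattice and binary-unit simulators: per-trial binary arrays
#' of site occupancy, `x` x `y` x time-bins.
#'
#' @slot fields list with one binary (0/1) 3-D array per trial.
#' @slot dt time-bin width of the recorded fields (s).
#' @slot meta list of provenance (parameters, patches, seed).
#' @export
setClass("StateField",
  representation(fields = "list", dt = "numeric", meta = "list"),
  validity = function(object) {
    for (f in object@fields) {
      if (length(dim(f)) != 3) return("each field must be an x-by-y-by-bins array")
      if (!all(f %in% c(0L, 1L))) return("fields must be binary (0/1)")
    }
    TRUE
  })

setMethod("stateArrays", "StateField", function(object) object@fields)

setMethod("show", "StateField", function(object) {
  d <- dim(object@fields[[1]])
  cat(sprintf("StateField: %d trial(s) of %dx%d sites x %d bins (%g ms)\n",
              length(object@fields), d[1], d[2], d[3], 1000 * object@dt))
})

#' Binary-unit network parameters
#'
#' Glauber-type transition rates on a periodic lattice: a unit flips
#' Off-to-On at rate `alpha1 + beta1 * Lap(S)` and On-to-Off at
#' `alpha2 - beta2 * Lap(S)`, where `Lap(S)` is the discrete Laplacian of
#' the binary neighborhood ([discreteLaplacian()]). Negative instantaneous
#' rates are clipped at zero.
#'
#' @slot alpha1,alpha2 baseline transition rates (1/s).
#' @slot beta1,beta2 coupling rates (1/s per unit of the discrete Laplacian).
#' @slot side lattice side length.
#' @slot dimension 1 or 2.
#' @slot updateBin synchronous update bin (s), default 0.010.
#' @export
setClass("BinaryNetParams",
  representation(alpha1 = "numeric", alpha2 = "numeric",
                 beta1 = "numeric", beta2 = "numeric",
                 side = "integer", dimension = "integer", updateBin = "numeric"),
  validity = function(object) {
    for (nm in c("alpha1", "alpha2", "beta1", "beta2"))
      if (slot(object, nm) < 0) return(paste(nm, "must be >= 0"))
    if (object@side < 1) return("side must be >= 1")
    if (!object@dimension %in% c(1L, 2L)) return("dimension must be 1 or 2")
    if (object@updateBin <= 0) return("updateBin must be > 0")
    TRUE
  })

#' @param alpha1,alpha2,beta1,beta2 rates in 1/s.
#' @param side,dimension lattice geometry (periodic boundary).
#' @param updateBin synchronous update bin in seconds.
#' @rdname BinaryNetParams-class
#' @export
binaryNetParams <- function(alpha1, alpha2, beta1 = 0, beta2 = beta1,
                            side = 64L, dimension = 2L, updateBin = 0.010) {
  new("BinaryNetParams", alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
      beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      side = as.integer(side), dimension = as.integer(dimension),
      updateBin = as.numeric(updateBin))
}

setMethod("alpha1", "BinaryNetParams", function(object) object@alpha1)
setMethod("alpha2", "BinaryNetParams", function(object) object@alpha2)

setMethod("show", "BinaryNetParams", function(object) {
  cat(sprintf("BinaryNetParams: alpha=(%g, %g)/s beta=(%g, %g)/s, %d-D side %d, bin %g s\n",
              object@alpha1, object@alpha2, object@beta1, object@beta2,
              object@dimension, object@side, object@updateBin))
})

#' Closed-form correlation-distance prediction
#'
#' Noise correlations predicted to decay exponentially with lateral
#' distance: `r_sc(d) = A exp(-d / L)` with amplitude `A` set by the On-Off
#' transition rates and firing-rate differences and correlation length
#' `L = sqrt(beta1 / (alpha1 + alpha2))` in lattice units.
#'
#' @slot amplitude dimensionless amplitude `A`, |A| <= 1.
#' @slot length correlation length `L` (lattice units), >= 0.
#' @slot distances,curve the evaluated `r_sc(d)` curve.
#' @export
setClass("CorrelationPrediction",
  representation(amplitude = "numeric", length = "numeric",
                 distances = "numeric", curve = "numeric"),
  validity = function(object) {
    if (abs(object@amplitude) > 1 + 1e-12) return("amplitude must satisfy |A| <= 1")
    if (object@length < 0) return("length must be >= 0")
    TRUE
  })

setMethod("amplitude", "CorrelationPrediction", function(object) object@amplitude)
setMethod("corrLength", "CorrelationPrediction", function(object) object@length)

setMethod("show", "CorrelationPrediction", function(object) {
  cat(sprintf("CorrelationPrediction: A = %.4g, L = %.4g lattice units\n",
              object@amplitude, object@length))
})
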