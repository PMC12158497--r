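#' @import methods
NULL

GRADUAL_ALPHAS <- round(seq(1, 0, by = -0.2), 10)
VARIANT_IDS <- c("M1", "M2", "M3", "M4")
CONDITIONS <- c("NU", "UN", "BINARY")

#' ModelParams: hyperparameters of the sequential Bayesian observer
#'
#' Container for the observer's free quantities: the recognition threshold
#' \code{C} on the naturalness axis, the prior-persistence weight
#' \code{lam} (lambda) that balances carried-over prior against the current
#' image likelihood, optional condition-specific weights \code{lamNU} /
#' \code{lamUN} (used by model variant M4 only), and the spread
#' \code{sigma} of the naturalness distribution, shared across images and
#' participants.
#'
#' @slot C numeric(1), threshold on the naturalness axis, dimensionless.
#' @slot lam numeric(1), prior-persistence weight in [0, 1]; \code{NA}
#'   when condition-specific weights are used.
#' @slot lamNU,lamUN numeric(1), condition-specific persistence weights
#'   for descending (NU) and ascending (UN) blocks; \code{NA} unless M4.
#' @slot sigma numeric(1), standard deviation of the naturalness
#'   distribution, strictly positive.
#'
#' @seealso [modelParams()] for the user constructor.
#' @exportClass ModelParams
setClass("ModelParams",
  representation(C = "numeric", lam = "numeric", lamNU = "numeric",
                 lamUN = "numeric", sigma = "numeric"),
  prototype(C = 0.5, lam = NA_real_, lamNU = NA_real_, lamUN = NA_real_,
            sigma = 0.3))

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@C) != 1L || !is.finite(object@C))
    msg <- c(msg, "'C' must be a single finite number")
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive number")
  for (nm in c("lam", "lamNU", "lamUN")) {
    v <- slot(object, nm)
    if (length(v) != 1L)
      msg <- c(msg, sprintf("'%s' must have length 1", nm))
    else if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})

#' ModelVariant: one of the four hyperparameter settings
#'
#' The four variants fix or free the persistence weight: M1 frees both C
#' and lambda (k = 2 free parameters per participant), M2 fixes lambda at
#' 0 (pure likelihood, k = 1), M3 fixes lambda at 1 (frozen prior, k = 1),
#' and M4 fits separate lambdas for the two gradual presentation orders
#' (k = 3).
#'
#' @slot id character(1), one of "M1".."M4".
#' @slot freeParams character, names of the free parameters.
#' @slot k integer(1), number of free parameters per participant.
#'
#' @seealso [modelVariant()]
#' @exportClass ModelVariant
setClass("ModelVariant",
  representation(id = "character", freeParams = "character", k = "integer"))

setValidity("ModelVariant", function(object) {
  if (!(object@id %in% VARIANT_IDS))
    return("'id' must be one of M1, M2, M3, M4")
  if (length(object@freeParams) != object@k)
    return("'k' must equal the number of free parameters")
  TRUE
})

#' BlockDesign: the ordered naturalness levels of one block
#'
#' A block presents six images whose naturalness level alpha descends
#' 1.0 -> 0.0 in steps of 0.2 (condition "NU"), ascends 0.0 -> 1.0
#' ("UN"), or alternates between the endpoints 0.0 and 1.0 ("BINARY").
#'
#' @slot condition character(1), "NU", "UN" or "BINARY".
#' @slot alphas numeric, the ordered naturalness levels.
#'
#' @seealso [blockDesign()]
#' @exportClass BlockDesign
setClass("BlockDesign",
  representation(condition = "character", alphas = "numeric"))

setValidity("BlockDesign", function(object) {
  if (!(object@condition %in% CONDITIONS))
    return("'condition' must be one of NU, UN, BINARY")
  a <- round(object@alphas, 10)
  if (object@condition == "NU") {
    if (length(a) != 6L || max(abs(a - GRADUAL_ALPHAS)) > 1e-9)
      return("NU blocks must descend 1.0 -> 0.0 in steps of 0.2")
  } else if (object@condition == "UN") {
    if (length(a) != 6L || max(abs(a - rev(GRADUAL_ALPHAS))) > 1e-9)
      return("UN blocks must ascend 0.0 -> 1.0 in steps of 0.2")
  } else {
    if (length(a) != 6L || !all(a %in% c(0, 1)))
      return("BINARY blocks draw alphas from {0, 1} only, length 6")
  }
  TRUE
})

#' PosteriorTrace: likelihood/prior/posterior along one block
#'
#' The per-trial record of a sequential update: the naturalness level
#' \code{alpha}, the image likelihood \code{P(alpha | Yes)}, the prior
#' \code{P(Yes)} in force before the trial, and the updated posterior
#' \code{P(Yes | alpha)}. The posterior of trial t becomes the prior of
#' trial t + 1. All probabilities are clipped to the open unit interval;
#' this is the object the fMRI regressors are computed from.
#'
#' @slot alpha numeric, per-trial naturalness level.
#' @slot likelihood numeric, per-trial image likelihood.
#' @slot prior numeric, prior in force before each trial.
#' @slot posterior numeric, posterior after each trial.
#' @slot condition character(1), the block condition the trace was run on.
#'
#' @seealso [runBlock()], accessors [likelihoods()], [priors()],
#'   [posteriors()], [alphas()].
#' @exportClass PosteriorTrace
setClass("PosteriorTrace",
  representation(alpha = "numeric", likelihood = "numeric",
                 prior = "numeric", posterior = "numeric",
                 condition = "character"))

setValidity("PosteriorTrace", function(object) {
  n <- length(object@alpha)
  if (length(object@likelihood) != n || length(object@prior) != n ||
      length(object@posterior) != n)
    return("per-trial slots must share one length")
  p <- c(object@likelihood, object@prior, object@posterior)
  if (any(p <= 0 | p >= 1))
    return("probabilities must lie strictly inside (0, 1) after clipping")
  if (n > 1L &&
      max(abs(object@prior[-1L] - object@posterior[-n])) > 1e-12)
    return("the prior of trial t+1 must equal the posterior of trial t")
  TRUE
})

#' FitResult: one participant x variant grid-search fit
#'
#' @slot participant character(1), participant identifier.
#' @slot variant ModelVariant, the fitted variant.
#' @slot params ModelParams, the maximizing grid point.
#' @slot loglik numeric(1), maximized response log-likelihood in nats.
#' @slot nObs integer(1), number of scored (non-missed) trials.
#' @slot bic numeric(1), k * ln(nObs) - 2 * loglik.
#' @slot grid list, the searched grid (C and lambda values).
#'
#' @seealso [gridFit()], accessors [bic()], [params()], [nObs()].
#' @exportClass FitResult
setClass("FitResult",
  representation(participant = "character", variant = "ModelVariant",
                 params = "ModelParams", loglik = "numeric",
                 nObs = "integer", bic = "numeric", grid = "list"))

setValidity("FitResult", function(object) {
  expected <- object@variant@k * log(object@nObs) - 2 * object@loglik
  if (abs(object@bic - expected) > 1e-9)
    return("bic must equal k * ln(nObs) - 2 * loglik")
  TRUE
})

#' FixationDensityMap: normalized gaze density over the display
#'
#' A discrete density grid obtained by anisotropic Gaussian kernel density
#' estimation over valid gaze samples. Cells are non-negative and sum to
#' one; maps on identical grids are compared with [fdmMse()].
#'
#' @slot density numeric matrix (rows = vertical cells, columns =
#'   horizontal cells), non-negative, summing to 1.
#' @slot bandwidths numeric(2), kernel standard deviations (bx, by) in
#'   pixels.
#' @slot nSamples integer(1), number of valid gaze samples used.
#' @slot extent numeric(2), display size (width, height) in pixels.
#'
#' @seealso [computeFdm()], [fdmMse()]
#' @exportClass FixationDensityMap
setClass("FixationDensityMap",
  representation(density = "matrix", bandwidths = "numeric",
                 nSamples = "integer", extent = "numeric"))

setValidity("FixationDensityMap", function(object) {
  if (any(object@density < 0))
    return("density cells must be non-negative")
  if (abs(sum(object@density) - 1) > 1e-6)
    return("density cells must sum to 1")
  if (length(object@bandwidths) != 2L || any(object@bandwidths <= 0))
    return("'bandwidths' must be two positive numbers")
  TRUE
})

#' CohortSpec: parameters of the synthetic behavioral cohort
#'
#' Defaults reproduce the study design: 30 participants, 36 gradual
#' blocks (half descending, half ascending) plus 12 binary blocks spread
#' over 6 sessions, per-participant thresholds C ~ Normal(0.55, 0.08)
#' truncated to [0.05, 0.95] and persistence weights
#' lambda ~ Normal(0.23, 0.11) truncated to [0, 1], a shared naturalness
#' spread sigma = 0.3, and a 3.33% missed-trial rate.
#'
#' @slot nParticipants integer(1).
#' @slot CMean,CSd numeric(1), threshold distribution.
#' @slot lamMean,lamSd numeric(1), persistence-weight distribution.
#' @slot sigma numeric(1), shared naturalness spread.
#' @slot nGradualBlocks,nBinaryBlocks integer(1), per-participant counts.
#' @slot missedRate numeric(1), probability a trial is missed.
#' @slot lapse numeric(1), lapse rate of the binary-block response rule.
#' @slot seed integer(1), RNG seed; every draw flows from it.
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nParticipants = "integer", CMean = "numeric",
                 CSd = "numeric", lamMean = "numeric", lamSd = "numeric",
                 sigma = "numeric", nGradualBlocks = "integer",
                 nBinaryBlocks = "integer", missedRate = "numeric",
                 lapse = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "need >= 1 participant")
  if (object@sigma <= 0) msg <- c(msg, "'sigma' must be positive")
  if (object@CSd < 0 || object@lamSd < 0)
    msg <- c(msg, "distribution SDs must be non-negative")
  if (object@nGradualBlocks %% 2L != 0L)
    msg <- c(msg, "'nGradualBlocks' must be even (half NU, half UN)")
  if (object@missedRate < 0 || object@missedRate >= 1)
    msg <- c(msg, "'missedRate' must lie in [0, 1)")
  if (object@lapse < 0 || object@lapse > 0.5)
    msg <- c(msg, "'lapse' must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' GazeSpec: parameters of the synthetic gaze generator
#'
#' Scanpaths are built from piecewise-constant fixations at
#' \code{fixationRate} Hz, sampled at \code{sampleRate} Hz with Gaussian
#' jitter. In \code{"saliency_anchored"} mode every fixation target is
#' drawn from the weighted salient loci regardless of naturalness level
#' (the generated images preserve the saliency map); in \code{"uniform"}
#' mode a fixation is anchored to the loci with probability alpha and
#' uniform over the screen otherwise (full pixel scrambling destroys the
#' saliency map, the intact alpha = 1 image retains it).
#'
#' @slot mode character(1), "saliency_anchored" or "uniform".
#' @slot salientLoci numeric matrix with columns x, y, weight; weights
#'   sum to 1, loci inside the screen.
#' @slot fixationRate numeric(1), fixations per second.
#' @slot trialDuration numeric(1), seconds of image presentation.
#' @slot sampleRate numeric(1), gaze samples per second.
#' @slot noiseSd numeric(1), jitter around the fixation target, pixels.
#' @slot screen numeric(2), display size (width, height) in pixels.
#' @slot seed integer(1), RNG seed.
#'
#' @seealso [gazeSpec()], [simulateGaze()]
#' @exportClass GazeSpec
setClass("GazeSpec",
  representation(mode = "character", salientLoci = "matrix",
                 fixationRate = "numeric", trialDuration = "numeric",
                 sampleRate = "numeric", noiseSd = "numeric",
                 screen = "numeric", seed = "integer"))

setValidity("GazeSpec", function(object) {
  msg <- character()
  if (!(object@mode %in% c("saliency_anchored", "uniform")))
    msg <- c(msg, "'mode' must be saliency_anchored or uniform")
  L <- object@salientLoci
  if (ncol(L) != 3L)
    msg <- c(msg, "'salientLoci' needs columns x, y, weight")
  else {
    if (abs(sum(L[, 3L]) - 1) > 1e-9)
      msg <- c(msg, "saliency weights must sum to 1")
    if (any(L[, 1L] < 0 | L[, 1L] >= object@screen[1L] |
            L[, 2L] < 0 | L[, 2L] >= object@screen[2L]))
      msg <- c(msg, "salient loci must lie within the screen")
  }
  if (object@fixationRate <= 0 || object@sampleRate <= 0 ||
      object@trialDuration <= 0)
    msg <- c(msg, "rates and durations must be positive")
  if (length(msg)) msg else TRUE
})
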