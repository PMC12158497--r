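#' Accessors for sceneBayes S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `alphas()`, `likelihoods()`, `priors()`, `posteriors()` read the
#' per-trial vectors of a [PosteriorTrace-class]; `params()`, `bic()`,
#' `nObs()` read a [FitResult-class]; `fdmDensity()`, `bandwidths()` and
#' `nSamples()` read a [FixationDensityMap-class].
#'
#' @param object an S4 object of this package.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases alphas likelihoods priors posteriors params bic nObs
#'   fdmDensity bandwidths nSamples
NULL

#' @rdname accessors
#' @export
setGeneric("alphas", function(object) standardGeneric("alphas"))
#' @rdname accessors
#' @export
setGeneric("likelihoods", function(object) standardGeneric("likelihoods"))
#' @rdname accessors
#' @export
setGeneric("priors", function(object) standardGeneric("priors"))
#' @rdname accessors
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))
#' @rdname accessors
#' @export
setGeneric("params", function(object) standardGeneric("params"))
#' @rdname accessors
#' @export
setGeneric("bic", function(object) standardGeneric("bic"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("fdmDensity", function(object) standardGeneric("fdmDensity"))
#' @rdname accessors
#' @export
setGeneric("bandwidths", function(object) standardGeneric("bandwidths"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

setMethod("alphas", "PosteriorTrace", function(object) object@alpha)
setMethod("likelihoods", "PosteriorTrace", function(object) object@likelihood)
setMethod("priors", "PosteriorTrace", function(object) object@prior)
setMethod("posteriors", "PosteriorTrace", function(object) object@posterior)

setMethod("params", "FitResult", function(object) object@params)
setMethod("bic", "FitResult", function(object) object@bic)
setMethod("nObs", "FitResult", function(object) object@nObs)

setMethod("fdmDensity", "FixationDensityMap", function(object) object@density)
setMethod("bandwidths", "FixationDensityMap", function(object) object@bandwidths)
setMethod("nSamples", "FixationDensityMap", function(object) object@nSamples)

setMethod("show", "ModelParams", function(object) {
  lam <- if (is.na(object@lam))
    sprintf("lamNU=%.3g lamUN=%.3g", object@lamNU, object@lamUN)
  else sprintf("lam=%.3g", object@lam)
  cat(sprintf("ModelParams: C=%.3g %s sigma=%.3g\n",
              object@C, lam, object@sigma))
})

setMethod("show", "ModelVariant", function(object) {
  cat(sprintf("ModelVariant %s (k=%d free: %s)\n", object@id, object@k,
              paste(object@freeParams, collapse = ", ")))
})

setMethod("show", "PosteriorTrace", function(object) {
  cat(sprintf("PosteriorTrace (%s, %d trials)\n", object@condition,
              length(object@alpha)))
  print(round(data.frame(alpha = object@alpha,
                         likelihood = object@likelihood,
                         prior = object@prior,
                         posterior = object@posterior), 4))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: participant %s, variant %s\n",
              object@participant, object@variant@id))
  show(object@params)
  cat(sprintf("  loglik=%.4f  nObs=%d  BIC=%.4f\n", object@loglik,
              object@nObs, object@bic))
})

setMethod("show", "FixationDensityMap", function(object) {
  cat(sprintf(
    "FixationDensityMap: %d x %d grid, bandwidths (%.1f, %.1f) px, %d samples\n",
    ncol(object@density), nrow(object@density), object@bandwidths[1L],
    object@bandwidths[2L], object@nSamples))
})
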