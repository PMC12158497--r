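# Sequential Bayesian recognition model: per-image likelihood,
# persistence-weighted posterior update, block-wise trace, and
# response-transition probabilities.

PROB_EPS <- 1e-9

#' Clip probabilities away from 0 and 1
#'
#' Posterior updating raises probabilities to fractional powers and the
#' regressors take logs, both undefined at exact 0/1; all probabilities
#' are therefore kept inside [eps, 1 - eps].
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping margin, default 1e-9.
#' @return clipped vector.
#' @export
clipProb <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

#' Construct model hyperparameters
#'
#' @param C recognition threshold on the naturalness axis. Smaller values
#'   make the observer more likely to call an image recognizable.
#' @param lam prior-persistence weight in [0, 1]: 0 ignores the carried
#'   prior (pure likelihood), 1 ignores the current image (frozen prior).
#' @param lamNU,lamUN condition-specific persistence weights (variant M4).
#' @param sigma spread of the naturalness distribution shared across
#'   images and participants; default 0.3.
#' @return a [ModelParams-class] object.
#' @examples
#' modelParams(C = 0.55, lam = 0.23)
#' @export
modelParams <- function(C, lam = NA_real_, lamNU = NA_real_,
                        lamUN = NA_real_, sigma = 0.3) {
  new(Class = "ModelParams", C = as.numeric(C), lam = as.numeric(lam),
      lamNU = as.numeric(lamNU), lamUN = as.numeric(lamUN),
      sigma = as.numeric(sigma))
}

#' Construct a model variant
#'
#' @param id one of "M1" (C and lambda free), "M2" (lambda fixed at 0),
#'   "M3" (lambda fixed at 1), "M4" (separate lambda per gradual
#'   condition).
#' @return a [ModelVariant-class] object.
#' @export
modelVariant <- function(id = c("M1", "M2", "M3", "M4")) {
  id <- match.arg(id)
  fp <- switch(id,
    M1 = c("C", "lam"),
    M2 = "C",
    M3 = "C",
    M4 = c("C", "lamNU", "lamUN"))
  new("ModelVariant", id = id, freeParams = fp, k = length(fp))
}

#' Construct a block design
#'
#' @param condition "NU" (naturalness descending 1.0 -> 0.0), "UN"
#'   (ascending) or "BINARY" (endpoints only).
#' @param alphas ordered naturalness levels; filled in automatically for
#'   gradual conditions, required for BINARY.
#' @return a [BlockDesign-class] object.
#' @examples
#' blockDesign("NU")
#' blockDesign("BINARY", alphas = c(1, 0, 0, 1, 1, 0))
#' @export
blockDesign <- function(condition = c("NU", "UN", "BINARY"),
                        alphas = NULL) {
  condition <- match.arg(condition)
  if (is.null(alphas)) {
    if (condition == "BINARY")
      stop("'alphas' must be given for BINARY blocks")
    alphas <- if (condition == "NU") GRADUAL_ALPHAS else rev(GRADUAL_ALPHAS)
  }
  new("BlockDesign", condition = condition, alphas = as.numeric(alphas))
}

#' Per-image recognition likelihood
#'
#' The probability that the current image alone supports scene
#' recognition. The naturalness of an image at level alpha is modelled as
#' Normal(alpha, sigma); the likelihood is the area of that distribution
#' to the right of the participant's threshold C, written via the CDF
#' Phi of Normal(alpha, sigma) as Phi(2 * alpha - C) (the reflection of C
#' about the mean), equal to 1 - Phi(C) by symmetry.
#'
#' @param alpha naturalness level(s) in [0, 1] (vectorized).
#' @param params a [ModelParams-class] object (only C and sigma used),
#'   or a single threshold value together with \code{sigma}.
#' @param sigma spread override when \code{params} is a plain number.
#' @return probability vector, strictly increasing in alpha and strictly
#'   decreasing in C.
#' @examples
#' sceneLikelihood(0.6, modelParams(C = 0.55, lam = 0.23, sigma = 0.3))
#' @export
sceneLikelihood <- function(alpha, params, sigma = NULL) {
  if (is(params, "ModelParams")) {
    C <- params@C; s <- params@sigma
  } else {
    C <- as.numeric(params)
    s <- if (is.null(sigma)) 0.3 else as.numeric(sigma)
  }
  if (!all(is.finite(s)) || any(s <= 0))
    stop("'sigma' must be positive and finite")
  if (!all(is.finite(alpha))) stop("'alpha' must be finite")
  stats::pnorm(2 * alpha - C, mean = alpha, sd = s)
}

#' Persistence-weighted Bayesian posterior update
#'
#' Combines the carried prior q = P(Yes) with the current image
#' likelihood L = P(alpha | Yes) through the persistence weight lambda:
#' the evidence for "Yes" is e_y = q^lambda * L^(1 - lambda), the
#' evidence for "No" is e_n = (1 - q)^lambda * (1 - L)^(1 - lambda), and
#' the posterior is e_y / (e_y + e_n). lambda = 0 returns the likelihood,
#' lambda = 1 returns the prior; the update is monotone non-decreasing in
#' both arguments.
#'
#' @param prior,likelihood probabilities (clipped internally).
#' @param lam persistence weight in [0, 1].
#' @return posterior probability vector.
#' @examples
#' posteriorUpdate(prior = 0.5, likelihood = 0.9, lam = 0.5)  # 0.75
#' @export
posteriorUpdate <- function(prior, likelihood, lam) {
  if (!all(is.finite(lam)) || any(lam < 0 | lam > 1))
    stop("'lam' must lie in [0, 1]")
  q <- clipProb(prior)
  L <- clipProb(likelihood)
  ey <- q^lam * L^(1 - lam)
  en <- (1 - q)^lam * (1 - L)^(1 - lam)
  ey / (ey + en)
}

.lambdaFor <- function(params, variant, condition) {
  switch(variant@id,
    M1 = params@lam,
    M2 = 0,
    M3 = 1,
    M4 = if (condition == "UN") params@lamUN else params@lamNU)
}

#' Run the sequential model over one block
#'
#' Iterates [sceneLikelihood()] and [posteriorUpdate()] along the block's
#' naturalness sequence; the posterior of each trial becomes the prior of
#' the next. The trace depends only on the stimulus sequence, not on the
#' participant's responses.
#'
#' @param design a [BlockDesign-class] object.
#' @param params a [ModelParams-class] object.
#' @param variant a [ModelVariant-class] object (default M1). Variants
#'   M2/M3 force lambda to 0/1; M4 picks \code{lamNU} or \code{lamUN}
#'   according to the design's condition.
#' @param initialPrior P(Yes) in force before the first trial, default
#'   0.5 (maximally uninformative).
#' @return a [PosteriorTrace-class] object.
#' @examples
#' runBlock(blockDesign("NU"), modelParams(C = 0.55, lam = 0.23))
#' @export
runBlock <- function(design, params, variant = modelVariant("M1"),
                     initialPrior = 0.5) {
  stopifnot(is(design, "BlockDesign"), is(params, "ModelParams"),
            is(variant, "ModelVariant"))
  if (length(design@alphas) == 0L) stop("empty block design")
  if (initialPrior <= 0 || initialPrior >= 1)
    stop("'initialPrior' must lie strictly inside (0, 1)")
  lam <- .lambdaFor(params, variant, design@condition)
  if (is.na(lam))
    stop(sprintf("variant %s needs its lambda parameter(s) set",
                 variant@id))
  n <- length(design@alphas)
  L <- clipProb(sceneLikelihood(design@alphas, params))
  q <- p <- numeric(n)
  cur <- clipProb(initialPrior)
  for (t in seq_len(n)) {
    q[t] <- cur
    p[t] <- posteriorUpdate(cur, L[t], lam)
    cur <- p[t]
  }
  new("PosteriorTrace", alpha = design@alphas, likelihood = L,
      prior = q, posterior = clipProb(p), condition = design@condition)
}

#' Joint probabilities of consecutive response pairs
#'
#' Under the model, the previous response is Bernoulli(prior) and the
#' current response Bernoulli(posterior), independently, giving the four
#' joint probabilities P(Yes -> Yes) = q * p, P(Yes -> No) = q * (1 - p),
#' P(No -> Yes) = (1 - q) * p, P(No -> No) = (1 - q) * (1 - p).
#'
#' @param prior P(Yes) of the previous trial.
#' @param posterior P(Yes | alpha) of the current trial.
#' @return named numeric vector \code{c(yy, yn, ny, nn)} summing to 1.
#' @examples
#' transitionProbs(0.5, 0.75)
#' @export
transitionProbs <- function(prior, posterior) {
  if (any(prior < 0 | prior > 1) || any(posterior < 0 | posterior > 1))
    stop("'prior' and 'posterior' must lie in [0, 1]")
  c(yy = prior * posterior,
    yn = prior * (1 - posterior),
    ny = (1 - prior) * posterior,
    nn = (1 - prior) * (1 - posterior))
}
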