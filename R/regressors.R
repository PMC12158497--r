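# Model-based trial-wise parametric modulators for fMRI GLMs:
# likelihood certainty, prior certainty, Bayesian surprise, and the
# serial orthogonalization scheme applied before export.

#' Likelihood certainty
#'
#' Natural log of the per-trial image likelihood P(alpha | Yes), the
#' modulator tracking how strongly the current image alone supports
#' recognition. Always <= 0 after clipping.
#'
#' @param trace a [PosteriorTrace-class] object.
#' @return numeric vector of per-trial values in nats.
#' @export
likelihoodCertainty <- function(trace) log(clipProb(likelihoods(trace)))

#' Prior certainty
#'
#' Natural log of the prior P(Yes) in force before each trial (the
#' previous trial's posterior). Always <= 0 after clipping.
#'
#' @param trace a [PosteriorTrace-class] object.
#' @return numeric vector of per-trial values in nats.
#' @export
priorCertainty <- function(trace) log(clipProb(priors(trace)))

#' Bayesian surprise
#'
#' How much the current image moves the carried-over recognition
#' probability. Two renderings are provided: \code{"bernoulli_kl"}, the
#' Kullback-Leibler divergence between the Bernoulli distributions with
#' success probabilities L and q, \code{L ln(L/q) + (1-L) ln((1-L)/(1-q))},
#' non-negative and zero iff L = q; and \code{"as_printed"}, the same
#' expression with a minus sign on the second term,
#' \code{L ln(L/q) - (1-L) ln((1-L)/(1-q))}, which can take either sign.
#' Operands default to (likelihood, prior); the (posterior, prior) pair
#' used when computing surprise from a trace is selected via
#' \code{operands} in [regressorSet()].
#'
#' @param likelihood,prior probabilities (clipped internally), vectorized.
#' @param formula \code{"bernoulli_kl"} (default) or \code{"as_printed"}.
#' @return surprise in nats.
#' @examples
#' bayesianSurprise(0.9, 0.5)                         # 0.3681
#' bayesianSurprise(0.9, 0.5, formula = "as_printed") # 0.6900
#' @export
bayesianSurprise <- function(likelihood, prior,
                             formula = c("bernoulli_kl", "as_printed")) {
  formula <- match.arg(formula)
  L <- clipProb(likelihood)
  q <- clipProb(prior)
  a <- L * log(L / q)
  b <- (1 - L) * log((1 - L) / (1 - q))
  if (formula == "bernoulli_kl") a + b else a - b
}

#' Serial orthogonalization of regressor columns
#'
#' Replaces each target column, in the given order, by its least-squares
#' residual against the listed predecessor columns plus an intercept
#' (so every orthogonalized column is also mean-centered). Predecessors
#' that were themselves orthogonalized earlier in the scheme enter in
#' their residualized form. The default scheme mirrors the serial
#' orthogonalization used for the three modulators: surprise is left
#' untouched, likelihood certainty is residualized on surprise, and
#' prior certainty on (residualized) likelihood certainty and surprise.
#'
#' @param mat numeric matrix with named columns, rows = trials.
#' @param scheme named list: for each target column, the character vector
#'   of predictor columns it is residualized against.
#' @return matrix of the same shape with targets replaced by residuals.
#' @examples
#' m <- cbind(surprise = rnorm(8), lik_cert = rnorm(8), prior_cert = rnorm(8))
#' serialOrthogonalize(m)
#' @export
serialOrthogonalize <- function(mat,
    scheme = list(lik_cert = "surprise",
                  prior_cert = c("lik_cert", "surprise"))) {
  if (!is.matrix(mat) || is.null(colnames(mat)))
    stop("'mat' must be a matrix with column names")
  for (target in names(scheme)) {
    preds <- scheme[[target]]
    if (!all(c(target, preds) %in% colnames(mat)))
      stop("scheme names columns absent from 'mat'")
    X <- cbind(`(Intercept)` = 1, mat[, preds, drop = FALSE])
    if (nrow(X) < ncol(X) + 1L)
      stop("need more rows than predictors plus intercept")
    qd <- qr(X)
    if (qd$rank < ncol(X))
      stop(sprintf(
        "rank-deficient predictor set for '%s' (rank %d of %d columns)",
        target, qd$rank, ncol(X)))
    mat[, target] <- qr.resid(qd, mat[, target])
  }
  mat
}

#' Trial-wise regressor set for one block
#'
#' Assembles the three modulators from a posterior trace, together with
#' onsets and the 4 s image-presentation duration, and appends their
#' serially orthogonalized copies (columns suffixed \code{_orth};
#' surprise is not residualized, its orthogonalized copy is merely
#' mean-centered by convention of the scheme).
#'
#' @param trace a [PosteriorTrace-class] object (or list of traces, which
#'   are concatenated in order, e.g. the blocks of one session).
#' @param onset numeric vector of image onsets in seconds; defaults to a
#'   6 s trial spacing (0.5 s fixation + 4 s image + 1.5 s choice).
#' @param duration image presentation duration in seconds, default 4.
#' @param surpriseFormula passed to [bayesianSurprise()].
#' @param surpriseOperands \code{"likelihood_prior"} (default; the
#'   operands of the printed surprise expression) or
#'   \code{"posterior_prior"} (divergence of the updated from the
#'   carried-over recognition probability).
#' @param orthogonalize logical; append the orthogonalized copies.
#' @return data.frame: onset, duration, alpha, lik_cert, prior_cert,
#'   surprise (+ \code{*_orth} columns).
#' @export
regressorSet <- function(trace, onset = NULL, duration = 4,
                         surpriseFormula = c("bernoulli_kl", "as_printed"),
                         surpriseOperands = c("likelihood_prior",
                                              "posterior_prior"),
                         orthogonalize = TRUE) {
  surpriseFormula <- match.arg(surpriseFormula)
  surpriseOperands <- match.arg(surpriseOperands)
  traces <- if (is(trace, "PosteriorTrace")) list(trace) else trace
  a <- unlist(lapply(traces, alphas))
  L <- unlist(lapply(traces, likelihoods))
  q <- unlist(lapply(traces, priors))
  p <- unlist(lapply(traces, posteriors))
  n <- length(a)
  if (is.null(onset)) onset <- (seq_len(n) - 1) * 6
  if (length(onset) != n) stop("'onset' length must match trial count")
  first <- if (surpriseOperands == "likelihood_prior") L else p
  out <- data.frame(
    onset = onset, duration = duration, alpha = a,
    lik_cert = log(clipProb(L)),
    prior_cert = log(clipProb(q)),
    surprise = bayesianSurprise(first, q, formula = surpriseFormula))
  if (orthogonalize) {
    m <- serialOrthogonalize(
      cbind(surprise = out$surprise, lik_cert = out$lik_cert,
            prior_cert = out$prior_cert))
    out$lik_cert_orth <- m[, "lik_cert"]
    out$prior_cert_orth <- m[, "prior_cert"]
    out$surprise_orth <- m[, "surprise"] - mean(m[, "surprise"])
  }
  out
}

#' Build and write BIDS-style events tables
#'
#' Runs the fitted model over every gradual block of each participant x
#' session and writes one tab-separated events file per combination:
#' onset, duration, trial_type, naturalness level, and one column per
#' modulator, raw and orthogonalized. Ready for ingestion by external
#' GLM software; no HRF convolution or filtering is applied.
#'
#' @param trials multi-participant trial table.
#' @param fits result of [compareModels()], or a named list mapping
#'   participant id to [ModelParams-class]; per-participant parameters of
#'   \code{variant} are used.
#' @param variant variant id whose fitted parameters to use, default "M1".
#' @param dir output directory; created if needed. \code{NULL} returns
#'   the tables without writing.
#' @param initialPrior,surpriseFormula,surpriseOperands see
#'   [regressorSet()].
#' @param complexity optional data.frame (alpha, complexity) merged in as
#'   an extra nuisance column.
#' @return (invisibly) named list of events data.frames, one per
#'   participant x session ("sub-X_ses-Y").
#' @export
writeEventsTsv <- function(trials, fits, variant = "M1", dir = NULL,
                           initialPrior = 0.5,
                           surpriseFormula = "bernoulli_kl",
                           surpriseOperands = "likelihood_prior",
                           complexity = NULL) {
  paramFor <- function(pid) {
    if (is.list(fits) && !is.null(fits$fits)) {
      f <- fits$fits
      row <- f[f$participant == as.character(pid) & f$variant == variant, ]
      if (nrow(row) != 1L) stop("no fit for participant ", pid)
      modelParams(C = row$C, lam = row$lam, lamNU = row$lamNU,
                  lamUN = row$lamUN, sigma = row$sigma)
    } else fits[[as.character(pid)]]
  }
  vv <- modelVariant(variant)
  out <- list()
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (pid in unique(trials$participant)) {
    tp <- trials[trials$participant == pid &
                   trials$condition %in% c("NU", "UN"), , drop = FALSE]
    pars <- paramFor(pid)
    for (ses in unique(tp$session)) {
      ts <- tp[tp$session == ses, , drop = FALSE]
      key <- interaction(ts$block, drop = TRUE)
      blocks <- lapply(split(ts, key), function(b)
        b[order(b$position), , drop = FALSE])
      blocks <- blocks[order(vapply(blocks, function(b) b$block[1L], 1))]
      traces <- lapply(blocks, function(b)
        runBlock(blockDesign(b$condition[1L], b$alpha), pars, vv,
                 initialPrior))
      onsets <- unlist(lapply(seq_along(blocks), function(i)
        (i - 1) * 40 + (seq_len(6L) - 1) * 6))
      ev <- regressorSet(traces, onset = onsets,
                         surpriseFormula = surpriseFormula,
                         surpriseOperands = surpriseOperands)
      ev <- cbind(
        onset = ev$onset, duration = ev$duration,
        data.frame(trial_type = rep(vapply(blocks, function(b)
          paste0("gradual_", b$condition[1L]), ""), each = 6L),
          stringsAsFactors = FALSE),
        ev[, setdiff(names(ev), c("onset", "duration")), drop = FALSE])
      if (!is.null(complexity))
        ev$complexity <- complexity$complexity[
          match(round(ev$alpha, 10), round(complexity$alpha, 10))]
      nm <- sprintf("sub-%s_ses-%s", pid, ses)
      out[[nm]] <- ev
      if (!is.null(dir))
        utils::write.table(ev,
          file.path(dir, paste0(nm, "_events.tsv")), sep = "\t",
          quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out)
}
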