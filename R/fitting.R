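# Per-participant grid-search maximum-likelihood estimation and
# BIC-based comparison of the four model variants.

#' Specify the hyperparameter search grid
#'
#' @param CStep,lamStep grid steps for the threshold C and the
#'   persistence weight lambda; defaults 0.01 on [0, 1].
#' @param CRange,lamRange inclusive search ranges, subsets of [0, 1].
#' @return list with components \code{C} and \code{lam}, the grid values.
#' @export
fitGrid <- function(CStep = 0.01, lamStep = 0.01, CRange = c(0, 1),
                    lamRange = c(0, 1)) {
  if (CStep <= 0 || lamStep <= 0) stop("grid steps must be positive")
  if (any(CRange < 0 | CRange > 1) || any(lamRange < 0 | lamRange > 1))
    stop("grid ranges must be subsets of [0, 1]")
  C <- seq(CRange[1L], CRange[2L], by = CStep)
  lam <- seq(lamRange[1L], lamRange[2L], by = lamStep)
  if (!length(C) || !length(lam)) stop("degenerate grid")
  list(C = round(C, 10), lam = round(lam, 10))
}

# Split one participant's gradual trials into blocks, ordered by position.
.splitBlocks <- function(trials) {
  g <- trials[trials$condition %in% c("NU", "UN"), , drop = FALSE]
  if (!nrow(g)) stop("no gradual-block trials")
  key <- interaction(g$session, g$block, drop = TRUE)
  lapply(split(g, key), function(b) b[order(b$position), , drop = FALSE])
}

# Yes/No counts per (condition, trial position) over scored trials.
# The posterior trace of a gradual block depends only on its condition
# (the alpha sequence is fixed by design), so these counts are a
# sufficient statistic for the response log-likelihood.
.gradualCounts <- function(trials) {
  blocks <- .splitBlocks(trials)
  counts <- list(
    NU = matrix(0, nrow = 6L, ncol = 2L,
                dimnames = list(NULL, c("yes", "no"))),
    UN = matrix(0, nrow = 6L, ncol = 2L,
                dimnames = list(NULL, c("yes", "no"))))
  for (b in blocks) {
    cond <- b$condition[1L]
    ref <- if (cond == "NU") GRADUAL_ALPHAS else rev(GRADUAL_ALPHAS)
    if (nrow(b) != 6L || max(abs(b$alpha - ref)) > 1e-9)
      stop("gradual block does not follow the canonical alpha sequence")
    keep <- !b$missed & b$response %in% c("yes", "no")
    for (t in which(keep))
      counts[[cond]][t, b$response[t]] <-
        counts[[cond]][t, b$response[t]] + 1
  }
  counts
}

#' Response log-likelihood of one participant's gradual blocks
#'
#' Independent-Bernoulli log-likelihood of the observed yes/no responses
#' under the model's per-trial posterior: each scored trial contributes
#' ln p_t for a "yes" and ln(1 - p_t) for a "no", with p_t from
#' [runBlock()]. Missed trials contribute nothing to the sum but the
#' trace still advances over them (the model is stimulus-driven).
#'
#' @param trials trial table of a single participant (see
#'   [readTrials()] for the schema); binary blocks are ignored.
#' @param params a [ModelParams-class] object.
#' @param variant a [ModelVariant-class] object.
#' @param initialPrior prior at each block start, default 0.5.
#' @return log-likelihood in nats, with attribute \code{nObs} (number of
#'   scored trials).
#' @export
responseLogLik <- function(trials, params, variant = modelVariant("M1"),
                           initialPrior = 0.5) {
  if (length(unique(trials$participant)) > 1L)
    stop("'trials' must belong to a single participant")
  blocks <- .splitBlocks(trials)
  ll <- 0
  n <- 0L
  for (b in blocks) {
    tr <- runBlock(blockDesign(b$condition[1L], b$alpha), params,
                   variant, initialPrior)
    p <- posteriors(tr)
    keep <- !b$missed & b$response %in% c("yes", "no")
    if (!any(keep)) next
    yes <- keep & b$response == "yes"
    no <- keep & b$response == "no"
    ll <- ll + sum(log(p[yes])) + sum(log(1 - p[no]))
    n <- n + sum(keep)
  }
  if (n == 0L) stop("no scorable trials after exclusions")
  structure(ll, nObs = n)
}

# Log-likelihood surface over a (C, lam) grid for one gradual condition.
# Returns an nLam x nC matrix; row = lambda (ascending), col = C
# (ascending). Vectorized over the whole grid: the six-trial trace is
# advanced with vector arithmetic, identically to runBlock.
.llSurface <- function(counts, cond, CGrid, lamGrid, sigma, initialPrior) {
  aSeq <- if (cond == "NU") GRADUAL_ALPHAS else rev(GRADUAL_ALPHAS)
  nC <- length(CGrid); nL <- length(lamGrid)
  Cv <- rep(CGrid, each = nL)          # C-major: ties resolve to low C,
  Lv <- rep(lamGrid, times = nC)       # then low lambda
  ll <- numeric(nC * nL)
  q <- rep(clipProb(initialPrior), nC * nL)
  for (t in seq_along(aSeq)) {
    lik <- clipProb(stats::pnorm((aSeq[t] - Cv) / sigma))
    p <- posteriorUpdate(q, lik, Lv)
    ps <- clipProb(p)
    ll <- ll + counts[t, "yes"] * log(ps) + counts[t, "no"] * log1p(-ps)
    q <- p
  }
  matrix(ll, nrow = nL, ncol = nC)
}

#' Bayesian Information Criterion
#'
#' @param loglik maximized log-likelihood in nats.
#' @param k number of free parameters.
#' @param n number of scored observations (>= 1).
#' @return k * ln(n) - 2 * loglik.
#' @examples
#' bicScore(-100, k = 2, n = 216)
#' @export
bicScore <- function(loglik, k, n) {
  if (n < 1) stop("'n' must be at least 1")
  k * log(n) - 2 * loglik
}

#' Grid-search maximum-likelihood fit for one participant
#'
#' Evaluates [responseLogLik()] on every point of the declared grid and
#' returns the maximizer. Because the gradual designs are fixed per
#' condition, the search is carried out on the per-(condition, position)
#' response counts with the six-trial trace advanced in vectorized form
#' over the whole grid; the result is identical to looping
#' [responseLogLik()] over grid points. Ties are broken deterministically
#' toward the lowest C, then the lowest lambda. For variant M4 the two
#' condition-specific lambdas enter the log-likelihood additively (NU
#' blocks involve only lamNU, UN blocks only lamUN), so they are
#' maximized independently at each C.
#'
#' @param trials single-participant trial table.
#' @param variant a [ModelVariant-class] object or variant id string.
#' @param grid search grid from [fitGrid()].
#' @param sigma shared naturalness spread, default 0.3.
#' @param initialPrior prior at block start, default 0.5.
#' @return a [FitResult-class] object.
#' @export
gridFit <- function(trials, variant = modelVariant("M1"),
                    grid = fitGrid(), sigma = 0.3, initialPrior = 0.5) {
  if (is.character(variant)) variant <- modelVariant(variant)
  if (!length(grid$C) || (variant@id %in% c("M1", "M4") && !length(grid$lam)))
    stop("degenerate grid")
  counts <- .gradualCounts(trials)
  n <- as.integer(sum(counts$NU) + sum(counts$UN))
  if (n == 0L) stop("no scorable trials after exclusions")

  lamGrid <- switch(variant@id, M1 = grid$lam, M2 = 0, M3 = 1,
                    M4 = grid$lam)
  sNU <- .llSurface(counts$NU, "NU", grid$C, lamGrid, sigma, initialPrior)
  sUN <- .llSurface(counts$UN, "UN", grid$C, lamGrid, sigma, initialPrior)

  if (variant@id == "M4") {
    # per-C maxima of the two independent lambda profiles
    iNU <- apply(sNU, 2L, which.max)
    iUN <- apply(sUN, 2L, which.max)
    tot <- sNU[cbind(iNU, seq_along(grid$C))] +
           sUN[cbind(iUN, seq_along(grid$C))]
    iC <- which.max(tot)
    best <- modelParams(C = grid$C[iC], lamNU = lamGrid[iNU[iC]],
                        lamUN = lamGrid[iUN[iC]], sigma = sigma)
    ll <- tot[iC]
  } else {
    tot <- sNU + sUN
    i <- which.max(tot)           # column-major = C-major, low C wins ties
    iC <- (i - 1L) %/% length(lamGrid) + 1L
    iL <- (i - 1L) %% length(lamGrid) + 1L
    lamHat <- switch(variant@id, M1 = lamGrid[iL], M2 = 0, M3 = 1)
    best <- modelParams(C = grid$C[iC], lam = lamHat, sigma = sigma)
    ll <- tot[i]
  }
  new("FitResult",
      participant = as.character(trials$participant[1L]),
      variant = variant, params = best, loglik = ll, nObs = n,
      bic = bicScore(ll, variant@k, n),
      grid = list(C = grid$C, lam = lamGrid))
}

.fitRow <- function(fit) {
  p <- params(fit)
  data.frame(participant = fit@participant, variant = fit@variant@id,
             C = p@C, lam = p@lam, lamNU = p@lamNU, lamUN = p@lamUN,
             sigma = p@sigma, loglik = as.numeric(fit@loglik),
             nObs = nObs(fit), k = fit@variant@k, bic = bic(fit),
             stringsAsFactors = FALSE)
}

#' Fit and compare the four model variants across participants
#'
#' Fits every variant to every participant on identical trial sets and
#' tabulates BIC. The group winner minimizes the BIC summed over
#' participants (each with its own scored-trial count n); a pooled-n
#' variant of the group BIC (total free parameters, total scored trials)
#' is reported alongside, as is each participant's own winner.
#'
#' @param trials multi-participant trial table.
#' @param variants character vector of variant ids, default all four.
#' @param grid,sigma,initialPrior passed to [gridFit()].
#' @return list with \code{fits} (one row per participant x variant),
#'   \code{group} (per-variant summed and pooled BIC, parameter means and
#'   SDs), \code{winner} (group winner by summed BIC) and
#'   \code{participantWinners}.
#' @export
compareModels <- function(trials, variants = VARIANT_IDS,
                          grid = fitGrid(), sigma = 0.3,
                          initialPrior = 0.5) {
  pids <- unique(trials$participant)
  rows <- vector("list", length(pids) * length(variants))
  i <- 0L
  for (pid in pids) {
    tp <- trials[trials$participant == pid, , drop = FALSE]
    nobs <- NULL
    for (v in variants) {
      fit <- gridFit(tp, v, grid = grid, sigma = sigma,
                     initialPrior = initialPrior)
      if (is.null(nobs)) nobs <- nObs(fit)
      else if (nobs != nObs(fit))
        stop(sprintf("inconsistent nObs across variants for participant %s",
                     pid))
      i <- i + 1L
      rows[[i]] <- .fitRow(fit)
    }
  }
  fits <- do.call(rbind, rows[seq_len(i)])

  group <- do.call(rbind, lapply(variants, function(v) {
    fv <- fits[fits$variant == v, , drop = FALSE]
    data.frame(variant = v,
               sumBic = sum(fv$bic),
               pooledBic = bicScore(sum(fv$loglik),
                                    k = sum(fv$k), n = sum(fv$nObs)),
               sumLoglik = sum(fv$loglik),
               meanC = mean(fv$C), sdC = stats::sd(fv$C),
               meanLam = mean(fv$lam), sdLam = stats::sd(fv$lam),
               stringsAsFactors = FALSE)
  }))
  winner <- group$variant[which.min(group$sumBic)]
  pw <- vapply(split(fits, fits$participant), function(f)
    f$variant[which.min(f$bic)], character(1L))
  list(fits = fits, group = group, winner = winner,
       participantWinners = pw)
}
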