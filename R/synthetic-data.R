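# Seeded generators for behavioral cohorts, gaze scanpaths and image
# families with the statistical structure the analysis assumes, so the
# whole pipeline runs and is testable without any recorded data.

# run expr with a private RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0L)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Specify a synthetic behavioral cohort
#'
#' Defaults are the study conditions: 30 participants, thresholds
#' C ~ Normal(0.55, 0.08) truncated to [0.05, 0.95], persistence
#' weights lambda ~ Normal(0.23, 0.11) truncated to [0, 1], shared
#' spread sigma = 0.3, 36 gradual + 12 binary blocks per participant,
#' a 3.33% missed-trial rate, and a 2.5% lapse rate for the binary
#' response rule.
#'
#' @param nParticipants,CMean,CSd,lamMean,lamSd,sigma see
#'   [CohortSpec-class].
#' @param nGradualBlocks,nBinaryBlocks per-participant block counts.
#' @param missedRate probability a trial is missed.
#' @param lapse binary-block lapse rate.
#' @param seed integer RNG seed.
#' @return a [CohortSpec-class] object.
#' @export
cohortSpec <- function(nParticipants = 30L, CMean = 0.55, CSd = 0.08,
                       lamMean = 0.23, lamSd = 0.11, sigma = 0.3,
                       nGradualBlocks = 36L, nBinaryBlocks = 12L,
                       missedRate = 0.0333, lapse = 0.025, seed = 1L) {
  new("CohortSpec", nParticipants = as.integer(nParticipants),
      CMean = CMean, CSd = CSd, lamMean = lamMean, lamSd = lamSd,
      sigma = sigma, nGradualBlocks = as.integer(nGradualBlocks),
      nBinaryBlocks = as.integer(nBinaryBlocks),
      missedRate = missedRate, lapse = lapse, seed = as.integer(seed))
}

#' Simulate a behavioral cohort
#'
#' Draws per-participant (C, lambda) from the spec's truncated normals,
#' runs the sequential model over every gradual block and samples each
#' response as Bernoulli of the model posterior (the trace depends only
#' on the stimulus sequence, so responses do not feed back). Binary
#' blocks are answered by thresholding the image likelihood at 0.5
#' (equivalently alpha > C) with the spec's lapse rate. Trials are
#' marked missed at the spec's rate; missed trials carry no response.
#' Blocks are interleaved into sessions of eight (six gradual, two
#' binary) as in the study design when the counts permit.
#'
#' @param spec a [CohortSpec-class] object.
#' @return list: \code{trials} (the trial table, schema of
#'   [readTrials()]) and \code{truth} (per-participant generating C and
#'   lambda).
#' @examples
#' sim <- simulateCohort(cohortSpec(nParticipants = 2, seed = 7))
#' head(sim$trials)
#' @export
simulateCohort <- function(spec) .withSeed(spec@seed, {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  nG <- spec@nGradualBlocks; nB <- spec@nBinaryBlocks
  perSession <- 8L
  nSessions <- if ((nG + nB) %% perSession == 0L)
    (nG + nB) %/% perSession else 1L
  truth <- data.frame(
    participant = seq_len(spec@nParticipants),
    C = .rtruncnorm(spec@nParticipants, spec@CMean, spec@CSd, 0.05, 0.95),
    lam = .rtruncnorm(spec@nParticipants, spec@lamMean, spec@lamSd, 0, 1))
  m1 <- modelVariant("M1")
  rows <- vector("list", spec@nParticipants)
  for (i in seq_len(spec@nParticipants)) {
    pars <- modelParams(C = truth$C[i], lam = truth$lam[i],
                        sigma = spec@sigma)
    if (nG %% (2L * nSessions) == 0L && nB %% nSessions == 0L) {
      # study layout: gradual and binary blocks interleaved per session
      gs <- nG %/% (2L * nSessions); bs <- nB %/% nSessions
      conds <- unlist(lapply(seq_len(nSessions), function(s)
        sample(c(rep("NU", gs), rep("UN", gs), rep("BINARY", bs)))))
    } else {
      conds <- sample(c(rep("NU", nG %/% 2L), rep("UN", nG - nG %/% 2L),
                        rep("BINARY", nB)))
    }
    session <- rep(seq_len(nSessions), each = length(conds) %/% nSessions)
    blk <- lapply(seq_along(conds), function(b) {
      cond <- conds[b]
      if (cond == "BINARY") {
        a <- sample(rep(c(0, 1), each = 3L))
        L <- sceneLikelihood(a, pars)
        yes <- (L > 0.5) != (stats::runif(6L) < spec@lapse)
      } else {
        des <- blockDesign(cond)
        a <- des@alphas
        p <- posteriors(runBlock(des, pars, m1))
        yes <- stats::runif(6L) < p
      }
      missed <- stats::runif(6L) < spec@missedRate
      data.frame(
        participant = truth$participant[i], session = session[b],
        block = b, condition = cond, position = 1:6, alpha = a,
        response = ifelse(missed, NA_character_,
                          ifelse(yes, "yes", "no")),
        rt = ifelse(missed, NA_real_,
                    pmin(1.5, stats::rlnorm(6L, log(0.7), 0.25))),
        missed = missed, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, blk)
  }
  list(trials = do.call(rbind, rows), truth = truth)
})

#' Specify a synthetic gaze generator
#'
#' @param mode "saliency_anchored" (fixations always drawn from the
#'   salient loci, as for generated images that preserve the saliency
#'   map) or "uniform" (a fixation is anchored with probability alpha
#'   and uniform otherwise, as for scrambled images whose saliency
#'   structure degrades with the shuffled fraction 1 - alpha).
#' @param salientLoci matrix with columns x, y, weight; default three
#'   loci. Held fixed across naturalness levels.
#' @param fixationRate fixations per second, default 3.
#' @param trialDuration seconds of image presentation, default 4.
#' @param sampleRate recorder rate in Hz, default 120.
#' @param noiseSd jitter SD around the fixation target in pixels.
#' @param screen display size (width, height) in pixels, default the
#'   960 x 1280 stimulus raster.
#' @param seed integer RNG seed.
#' @return a [GazeSpec-class] object.
#' @export
gazeSpec <- function(mode = c("saliency_anchored", "uniform"),
                     salientLoci = NULL, fixationRate = 3,
                     trialDuration = 4, sampleRate = 120, noiseSd = 40,
                     screen = c(1280, 960), seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(salientLoci))
    salientLoci <- cbind(
      x = screen[1L] * c(0.35, 0.65, 0.5),
      y = screen[2L] * c(0.4, 0.5, 0.7),
      weight = c(0.5, 0.3, 0.2))
  new("GazeSpec", mode = mode, salientLoci = salientLoci,
      fixationRate = fixationRate, trialDuration = trialDuration,
      sampleRate = sampleRate, noiseSd = noiseSd,
      screen = as.numeric(screen), seed = as.integer(seed))
}

#' Simulate gaze scanpaths
#'
#' Generates piecewise-constant fixations with Gaussian sample jitter
#' for every participant x condition x naturalness level cell, labelled
#' with the stimulus class implied by the spec's mode ("gansid" for
#' saliency-anchored, "scrambled" for the alpha-mixture mode). A small
#' fraction of samples is flagged invalid (tracker dropout) and carries
#' no coordinates.
#'
#' @param spec a [GazeSpec-class] object.
#' @param participants participant ids, default 1:20.
#' @param conditions default c("NU", "UN").
#' @param alphas naturalness levels, default the six study levels.
#' @param nTrialsPerCell trials pooled into each cell, default 3.
#' @param invalidRate probability a sample is invalid, default 0.02.
#' @return gaze sample table: participant, condition, stimulus, alpha,
#'   trial, t, x, y, valid.
#' @export
simulateGaze <- function(spec, participants = 1:20,
                         conditions = c("NU", "UN"),
                         alphas = seq(0, 1, by = 0.2),
                         nTrialsPerCell = 3L, invalidRate = 0.02) {
  stopifnot(is(spec, "GazeSpec"))
  validObject(spec)
  .withSeed(spec@seed, {
    nFix <- max(1L, ceiling(spec@trialDuration * spec@fixationRate))
    perFix <- max(1L, round(spec@sampleRate / spec@fixationRate))
    nSamp <- nFix * perFix
    W <- spec@screen[1L]; H <- spec@screen[2L]
    loci <- spec@salientLoci
    cells <- expand.grid(participant = participants,
                         condition = conditions, alpha = alphas,
                         trial = seq_len(nTrialsPerCell),
                         stringsAsFactors = FALSE)
    out <- vector("list", nrow(cells))
    for (r in seq_len(nrow(cells))) {
      a <- cells$alpha[r]
      pAnchor <- if (spec@mode == "saliency_anchored") 1 else a
      anchored <- stats::runif(nFix) < pAnchor
      li <- sample.int(nrow(loci), nFix, replace = TRUE,
                       prob = loci[, "weight"])
      fx <- ifelse(anchored, loci[li, "x"], stats::runif(nFix, 0, W))
      fy <- ifelse(anchored, loci[li, "y"], stats::runif(nFix, 0, H))
      x <- rep(fx, each = perFix) + stats::rnorm(nSamp, 0, spec@noiseSd)
      y <- rep(fy, each = perFix) + stats::rnorm(nSamp, 0, spec@noiseSd)
      x <- pmin(pmax(x, 0), W - 1e-6)
      y <- pmin(pmax(y, 0), H - 1e-6)
      valid <- stats::runif(nSamp) >= invalidRate
      x[!valid] <- NA_real_; y[!valid] <- NA_real_
      out[[r]] <- data.frame(
        participant = cells$participant[r],
        condition = cells$condition[r],
        stimulus = if (spec@mode == "saliency_anchored") "gansid"
                   else "scrambled",
        alpha = a, trial = cells$trial[r],
        t = (seq_len(nSamp) - 1) / spec@sampleRate,
        x = x, y = y, valid = valid, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Synthetic image family over naturalness levels
#'
#' Builds a smooth textured base field (low-pass-filtered Gaussian
#' noise) and derives one image per naturalness level. Two
#' constructions are available. \code{"blend"} (default) mixes the base
#' with an independent higher-variance noise field at ratio alpha,
#' mirroring how the generated stimuli mix the image latent with
#' standard-normal noise, so the non-DC spectral power genuinely grows
#' as alpha falls. \code{"shuffle"} randomly permutes a fraction
#' 1 - alpha of the pixels, the construction of the scrambled
#' eye-tracking stimuli; note that a permutation preserves the pixel
#' multiset and hence the total and DC power exactly, so the
#' DC-excluded mean spectral power is invariant under this construction
#' (a property the test suite asserts).
#'
#' @param baseSeed integer RNG seed.
#' @param alphas naturalness levels, default the six study levels.
#' @param dim image size (rows, cols), default 64 x 64.
#' @param method "blend" or "shuffle".
#' @param baseSd,noiseSd pixel SD of the base field and of the blend
#'   noise field.
#' @return named list of image matrices (names "alpha_<level>"), with
#'   the levels in attribute \code{"alphas"}.
#' @export
synthImageFamily <- function(baseSeed, alphas = seq(1, 0, by = -0.2),
                             dim = c(64L, 64L),
                             method = c("blend", "shuffle"),
                             baseSd = 0.1, noiseSd = 0.45) {
  method <- match.arg(method)
  .withSeed(baseSeed, {
    n <- prod(dim)
    white <- matrix(stats::rnorm(n), dim[1L], dim[2L])
    # low-pass in the Fourier domain -> smooth "natural-like" texture
    fr <- outer(
      pmin(0:(dim[1L] - 1L), dim[1L] - 0:(dim[1L] - 1L)) / dim[1L],
      pmin(0:(dim[2L] - 1L), dim[2L] - 0:(dim[2L] - 1L)) / dim[2L],
      function(u, v) sqrt(u^2 + v^2))
    base <- Re(stats::fft(stats::fft(white) * exp(-(fr / 0.06)^2),
                          inverse = TRUE)) / n
    base <- 0.5 + baseSd * (base - mean(base)) / stats::sd(base)
    noise <- matrix(stats::rnorm(n, 0.5, noiseSd), dim[1L], dim[2L])
    out <- lapply(alphas, function(a) {
      if (method == "blend") {
        a * base + (1 - a) * noise
      } else {
        img <- base
        k <- round((1 - a) * n)
        if (k >= 2L) {
          idx <- sample.int(n, k)
          img[idx] <- img[sample(idx)]
        }
        img
      }
    })
    names(out) <- sprintf("alpha_%g", alphas)
    attr(out, "alphas") <- alphas
    out
  })
}
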