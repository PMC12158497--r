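# Behavioral summaries: recognition-rate curves by naturalness level and
# condition, four-way response-transition proportions, and the paired
# nonparametric group tests.

#' Drop missed (no-choice) trials
#'
#' Removes trials on which no response was registered within the deadline
#' and records the per-participant missed fraction in the
#' \code{"missedFraction"} attribute of the result.
#'
#' @param trials trial table with a logical \code{missed} column.
#' @return the table without missed trials.
#' @export
excludeMissed <- function(trials) {
  frac <- vapply(split(trials$missed, trials$participant), mean, 1)
  out <- trials[!trials$missed, , drop = FALSE]
  if (!nrow(out)) warning("all trials are missed")
  structure(out, missedFraction = frac)
}

.se <- function(x) stats::sd(x) / sqrt(length(x))

#' Recognition rates by naturalness level and condition
#'
#' Per participant, the fraction of "yes" responses for each
#' (condition, alpha) cell of the gradual blocks (missed trials
#' excluded), plus group mean and standard error (SD across participants
#' over the square root of n).
#'
#' @param trials trial table; missed trials are excluded internally.
#' @param conditions which conditions to tabulate; defaults to the
#'   gradual ones. Pass \code{"BINARY"} for the endpoint rates of the
#'   control blocks.
#' @return list with \code{perParticipant} (participant, condition,
#'   alpha, rate, nTrials) and \code{summary} (condition, alpha, mean,
#'   se, nParticipants).
#' @export
recognitionRates <- function(trials, conditions = c("NU", "UN")) {
  tr <- excludeMissed(trials)
  tr <- tr[tr$condition %in% conditions &
             tr$response %in% c("yes", "no"), , drop = FALSE]
  if (!nrow(tr)) stop("no scorable trials")
  agg <- stats::aggregate(
    cbind(rate = tr$response == "yes"),
    by = list(participant = tr$participant, condition = tr$condition,
              alpha = tr$alpha), FUN = mean)
  nt <- stats::aggregate(
    cbind(nTrials = rep(1L, nrow(tr))),
    by = list(participant = tr$participant, condition = tr$condition,
              alpha = tr$alpha), FUN = sum)
  per <- merge(agg, nt)
  per <- per[order(per$condition, per$alpha, per$participant), ]
  summ <- stats::aggregate(per$rate,
    by = list(condition = per$condition, alpha = per$alpha),
    FUN = function(x) c(mean = mean(x), se = .se(x), n = length(x)))
  summ <- data.frame(condition = summ$condition, alpha = summ$alpha,
                     mean = summ$x[, "mean"], se = summ$x[, "se"],
                     nParticipants = summ$x[, "n"])
  summ <- summ[order(summ$condition, summ$alpha), ]
  rownames(per) <- rownames(summ) <- NULL
  list(perParticipant = per, summary = summ)
}

PATTERNS <- c("NN", "NY", "YN", "YY")

#' Response-transition proportions
#'
#' Classifies each pair of consecutive gradual-block trials by the
#' previous and current response (No->No, No->Yes, Yes->No, Yes->Yes)
#' and tabulates per-participant proportions per (condition, alpha of
#' the current trial), plus group mean and standard error. Block-initial
#' trials contribute no pair; pairs spanning a missed trial are dropped
#' entirely.
#'
#' @param trials trial table.
#' @return list with \code{perParticipant} (participant, condition,
#'   alpha, pattern, proportion, nPairs) and \code{summary}.
#' @export
transitionProportions <- function(trials) {
  g <- trials[trials$condition %in% c("NU", "UN"), , drop = FALSE]
  key <- interaction(g$participant, g$session, g$block, drop = TRUE)
  pairs <- do.call(rbind, lapply(split(g, key), function(b) {
    b <- b[order(b$position), , drop = FALSE]
    i <- seq_len(nrow(b))[-1L]
    ok <- !b$missed[i] & !b$missed[i - 1L] &
      b$response[i] %in% c("yes", "no") &
      b$response[i - 1L] %in% c("yes", "no")
    if (!any(ok)) return(NULL)
    i <- i[ok]
    data.frame(participant = b$participant[i], condition = b$condition[i],
               alpha = b$alpha[i],
               pattern = paste0(
                 ifelse(b$response[i - 1L] == "yes", "Y", "N"),
                 ifelse(b$response[i] == "yes", "Y", "N")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) stop("no scorable response pairs")
  cells <- split(pairs, interaction(pairs$participant, pairs$condition,
                                    pairs$alpha, drop = TRUE))
  per <- do.call(rbind, lapply(cells, function(d) {
    tab <- table(factor(d$pattern, levels = PATTERNS))
    data.frame(participant = d$participant[1L],
               condition = d$condition[1L], alpha = d$alpha[1L],
               pattern = PATTERNS,
               proportion = as.numeric(tab) / nrow(d),
               nPairs = nrow(d), stringsAsFactors = FALSE)
  }))
  summ <- stats::aggregate(per$proportion,
    by = list(condition = per$condition, alpha = per$alpha,
              pattern = per$pattern),
    FUN = function(x) c(mean = mean(x), se = .se(x), n = length(x)))
  summ <- data.frame(condition = summ$condition, alpha = summ$alpha,
                     pattern = summ$pattern, mean = summ$x[, "mean"],
                     se = summ$x[, "se"], nParticipants = summ$x[, "n"])
  per <- per[order(per$condition, per$alpha, per$pattern,
                   per$participant), ]
  summ <- summ[order(summ$condition, summ$alpha, summ$pattern), ]
  rownames(per) <- rownames(summ) <- NULL
  list(perParticipant = per, summary = summ)
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-sided paired signed-rank test (zero differences dropped, exact
#' p-value when the sample permits, normal approximation otherwise, as
#' in [stats::wilcox.test()]) with the p-value multiplied by the number
#' of comparisons in the family and capped at 1.
#'
#' @param a,b paired per-participant values.
#' @param m number of comparisons in the family (m = 6 for the
#'   alpha-wise family of gradual blocks).
#' @return list: \code{statistic} (V, sum of positive-difference ranks),
#'   \code{pRaw}, \code{pCorrected}, \code{nEffective} (pairs after
#'   dropping zero differences).
#' @export
pairedWilcoxonBonferroni <- function(a, b, m = 1L) {
  stopifnot(length(a) == length(b), m >= 1)
  d <- a - b
  nEff <- sum(d != 0)
  if (nEff == 0L)
    return(list(statistic = 0, pRaw = 1, pCorrected = 1, nEffective = 0L))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), pRaw = wt$p.value,
       pCorrected = min(1, wt$p.value * m), nEffective = nEff)
}

#' Condition contrast of recognition rates at each naturalness level
#'
#' The alpha-wise family of paired signed-rank tests comparing NU and UN
#' recognition rates across participants, Bonferroni-corrected for the
#' six levels.
#'
#' @param trials trial table.
#' @return data.frame: alpha, meanNU, meanUN, statistic, pRaw,
#'   pCorrected.
#' @export
conditionContrast <- function(trials) {
  per <- recognitionRates(trials)$perParticipant
  lv <- sort(unique(per$alpha))
  do.call(rbind, lapply(lv, function(a) {
    nu <- per[per$condition == "NU" & per$alpha == a, ]
    un <- per[per$condition == "UN" & per$alpha == a, ]
    common <- intersect(nu$participant, un$participant)
    x <- nu$rate[match(common, nu$participant)]
    y <- un$rate[match(common, un$participant)]
    w <- pairedWilcoxonBonferroni(x, y, m = length(lv))
    data.frame(alpha = a, meanNU = mean(x), meanUN = mean(y),
               statistic = w$statistic, pRaw = w$pRaw,
               pCorrected = w$pCorrected)
  }))
}
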