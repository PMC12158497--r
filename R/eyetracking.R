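# Fixation-density maps by anisotropic Gaussian KDE and their MSE-based
# comparison across naturalness levels and presentation orders.

# Silverman's rule per axis; guarded for degenerate samples.
.silverman <- function(v, extent) {
  if (length(v) >= 2L && stats::sd(v) > 0) stats::bw.nrd0(v)
  else 0.05 * extent
}

#' Fixation density map from gaze samples
#'
#' Anisotropic Gaussian kernel density estimate of the valid gaze
#' samples, evaluated at the centers of a regular grid over the display
#' and normalized so the cells sum to one. Separate bandwidths are used
#' for the horizontal and vertical axes; when not supplied they are set
#' per axis by Silverman's rule on the pooled samples.
#'
#' @param x,y gaze coordinates in pixels (origin top-left), or a
#'   data.frame with columns \code{x}, \code{y} and optionally
#'   \code{valid}.
#' @param valid logical vector; invalid samples are ignored.
#' @param gridShape integer(2), cells along (x, y); default c(64, 48).
#' @param extent numeric(2), display size (width, height) in pixels;
#'   default c(1280, 960).
#' @param bandwidths numeric(2), kernel SDs (bx, by) in pixels; default
#'   Silverman per axis.
#' @return a [FixationDensityMap-class] object (rows = vertical cells).
#' @examples
#' computeFdm(x = c(600, 700), y = c(400, 500), bandwidths = c(30, 20))
#' @export
computeFdm <- function(x, y = NULL, valid = NULL,
                       gridShape = c(64L, 48L), extent = c(1280, 960),
                       bandwidths = NULL) {
  if (is.data.frame(x)) {
    valid <- if ("valid" %in% names(x)) x$valid else NULL
    y <- x$y
    x <- x$x
  }
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  keep <- valid & is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) stop("no valid gaze samples")
  if (is.null(bandwidths))
    bandwidths <- c(.silverman(x, extent[1L]), .silverman(y, extent[2L]))
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  xc <- (seq_len(gridShape[1L]) - 0.5) * extent[1L] / gridShape[1L]
  yc <- (seq_len(gridShape[2L]) - 0.5) * extent[2L] / gridShape[2L]
  # separable kernel: density[r, c] = sum_i Ky[r, i] * Kx[c, i]
  Kx <- outer(xc, x, function(g, s) stats::dnorm(g, s, bandwidths[1L]))
  Ky <- outer(yc, y, function(g, s) stats::dnorm(g, s, bandwidths[2L]))
  dens <- Ky %*% t(Kx)
  dens <- dens / sum(dens)
  new("FixationDensityMap", density = dens,
      bandwidths = as.numeric(bandwidths), nSamples = n,
      extent = as.numeric(extent))
}

#' Mean squared error between two fixation density maps
#'
#' @param a,b [FixationDensityMap-class] objects (or bare matrices) on
#'   identical grids.
#' @return mean over cells of the squared density difference.
#' @export
fdmMse <- function(a, b) {
  da <- if (is(a, "FixationDensityMap")) fdmDensity(a) else a
  db <- if (is(b, "FixationDensityMap")) fdmDensity(b) else b
  if (!identical(dim(da), dim(db)))
    stop("FDM grids have different shapes")
  mean((da - db)^2)
}

# One FDM per participant x condition x stimulus x alpha, pooling all
# samples of that cell.
.fdmCells <- function(gaze, ...) {
  req <- c("participant", "condition", "stimulus", "alpha", "x", "y")
  if (!all(req %in% names(gaze)))
    stop("gaze table needs columns: ", paste(req, collapse = ", "))
  key <- interaction(gaze$participant, gaze$condition, gaze$stimulus,
                     gaze$alpha, drop = TRUE)
  lapply(split(gaze, key), function(d)
    list(participant = d$participant[1L], condition = d$condition[1L],
         stimulus = d$stimulus[1L], alpha = d$alpha[1L],
         fdm = computeFdm(d, ...)))
}

.mseTable <- function(cells, refOf, pairLabel) {
  do.call(rbind, Filter(Negate(is.null), lapply(cells, function(cl) {
    ref <- refOf(cl)
    if (is.null(ref)) return(NULL)
    data.frame(participant = cl$participant, stimulus = cl$stimulus,
               alpha = cl$alpha, comparison = pairLabel(cl),
               mse = fdmMse(cl$fdm, ref), stringsAsFactors = FALSE)
  })))
}

.groupTests <- function(per, by, m) {
  lv <- sort(unique(per$alpha))
  do.call(rbind, Filter(Negate(is.null), lapply(lv, function(a) {
    d <- per[per$alpha == a, ]
    g <- split(d, d[[by]])
    if (length(g) != 2L) return(NULL)
    common <- intersect(g[[1L]]$participant, g[[2L]]$participant)
    if (length(common) < 2L) return(NULL)
    x <- g[[1L]]$mse[match(common, g[[1L]]$participant)]
    y <- g[[2L]]$mse[match(common, g[[2L]]$participant)]
    w <- pairedWilcoxonBonferroni(x, y, m = m)
    data.frame(alpha = a, groupA = names(g)[1L], groupB = names(g)[2L],
               meanA = mean(x), meanB = mean(y),
               statistic = w$statistic, pRaw = w$pRaw,
               pCorrected = w$pCorrected, stringsAsFactors = FALSE)
  })))
}

#' FDM comparison across naturalness levels
#'
#' For each participant, condition and stimulus class (generated-like
#' vs scrambled-like), computes the MSE between the fixation density map
#' at each naturalness level and the map for the natural images
#' (alpha = 1.0), then summarizes across participants (mean, SE) and
#' contrasts the two stimulus classes per level with paired signed-rank
#' tests, Bonferroni-corrected over the five non-reference levels.
#'
#' @param gaze gaze sample table with columns participant, condition,
#'   stimulus, alpha, x, y (and optionally valid).
#' @param ... passed to [computeFdm()] (grid shape, extent, bandwidths).
#' @return list: \code{perParticipant}, \code{summary}, \code{tests}.
#' @export
naturalnessComparison <- function(gaze, ...) {
  cells <- .fdmCells(gaze, ...)
  keyOf <- function(cl, a) paste(cl$participant, cl$condition,
                                 cl$stimulus, a, sep = "\r")
  refs <- new.env(parent = emptyenv())
  for (cl in cells) if (abs(cl$alpha - 1) < 1e-9)
    assign(keyOf(cl, "ref"), cl$fdm, envir = refs)
  per <- .mseTable(
    Filter(function(cl) abs(cl$alpha - 1) >= 1e-9, cells),
    refOf = function(cl) {
      k <- keyOf(cl, "ref")
      if (exists(k, envir = refs)) get(k, envir = refs) else NULL
    },
    pairLabel = function(cl) cl$condition)
  if (is.null(per)) stop("no alpha = 1.0 reference maps found")
  summ <- stats::aggregate(per$mse,
    by = list(comparison = per$comparison, stimulus = per$stimulus,
              alpha = per$alpha),
    FUN = function(x) c(mean = mean(x), se = .se(x), n = length(x)))
  summ <- data.frame(condition = summ$comparison,
                     stimulus = summ$stimulus, alpha = summ$alpha,
                     mean = summ$x[, "mean"], se = summ$x[, "se"],
                     nParticipants = summ$x[, "n"])
  tests <- do.call(rbind, lapply(unique(per$comparison), function(cc) {
    tt <- .groupTests(per[per$comparison == cc, ], "stimulus",
                      m = length(unique(per$alpha)))
    if (!is.null(tt)) cbind(condition = cc, tt)
  }))
  list(perParticipant = per, summary = summ, tests = tests)
}

#' FDM comparison between presentation orders
#'
#' For each participant, stimulus class and naturalness level, the MSE
#' between the fixation density maps of the descending (NU) and
#' ascending (UN) presentations of the same images, summarized across
#' participants and contrasted between stimulus classes per level
#' (Bonferroni over the six levels).
#'
#' @inheritParams naturalnessComparison
#' @return list: \code{perParticipant}, \code{summary}, \code{tests}.
#' @export
orderComparison <- function(gaze, ...) {
  cells <- .fdmCells(gaze, ...)
  byPSA <- split(cells, vapply(cells, function(cl)
    paste(cl$participant, cl$stimulus, cl$alpha, sep = "\r"), ""))
  per <- do.call(rbind, Filter(Negate(is.null), lapply(byPSA, function(g) {
    conds <- vapply(g, `[[`, "", "condition")
    if (!all(c("NU", "UN") %in% conds)) return(NULL)
    a <- g[[match("NU", conds)]]
    b <- g[[match("UN", conds)]]
    data.frame(participant = a$participant, stimulus = a$stimulus,
               alpha = a$alpha, comparison = "NUvsUN",
               mse = fdmMse(a$fdm, b$fdm), stringsAsFactors = FALSE)
  })))
  if (is.null(per)) stop("no participant has both NU and UN maps")
  summ <- stats::aggregate(per$mse,
    by = list(stimulus = per$stimulus, alpha = per$alpha),
    FUN = function(x) c(mean = mean(x), se = .se(x), n = length(x)))
  summ <- data.frame(stimulus = summ$stimulus, alpha = summ$alpha,
                     mean = summ$x[, "mean"], se = summ$x[, "se"],
                     nParticipants = summ$x[, "n"])
  tests <- .groupTests(per, "stimulus", m = length(unique(per$alpha)))
  list(perParticipant = per, summary = summ, tests = tests)
}

#' Write a fixation density map as a plain-text matrix
#'
#' @param fdm a [FixationDensityMap-class] object.
#' @param path output file; tab-separated cells, rows = vertical cells.
#' @export
writeFdm <- function(fdm, path) {
  utils::write.table(fdmDensity(fdm), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}
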