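# Low-level visual complexity: mean 2-D Fourier power of the grayscale
# image, and its rank correlation with the naturalness level.

#' Spectral complexity of an image
#'
#' Mean squared magnitude of the two-dimensional discrete Fourier
#' coefficients of the grayscale image under the unitary normalization
#' (transform divided by sqrt of the pixel count), so that the mean power
#' over all coefficients equals the mean squared pixel intensity
#' (Parseval). The DC coefficient reflects mean luminance rather than
#' structure and is excluded by default; with \code{includeDC = TRUE} the
#' value is exactly the mean squared intensity. Color arrays (third
#' dimension 3 or 4) are converted to luminance first with weights
#' (0.299, 0.587, 0.114).
#'
#' @param image 2-D numeric matrix of intensities, or a HxWx3(4) array.
#' @param includeDC keep the DC term in the average; default FALSE.
#' @param grayWeights RGB luminance weights.
#' @return non-negative scalar in squared intensity units.
#' @examples
#' spectralComplexity(matrix(1, 8, 8))  # constant image -> 0
#' @export
spectralComplexity <- function(image, includeDC = FALSE,
                               grayWeights = c(0.299, 0.587, 0.114)) {
  if (is.array(image) && length(dim(image)) == 3L) {
    image <- grayWeights[1L] * image[, , 1L] +
      grayWeights[2L] * image[, , 2L] + grayWeights[3L] * image[, , 3L]
  }
  if (!is.matrix(image) || !nrow(image) || !ncol(image))
    stop("'image' must be a non-empty 2-D array")
  n <- length(image)
  P <- Mod(stats::fft(image))^2 / n        # unitary: |F|^2 / N
  if (includeDC) mean(P)
  else if (n == 1L) 0
  else (sum(P) - P[1L, 1L]) / (n - 1L)
}

#' Rank correlation between complexity and naturalness
#'
#' Spearman correlation between the naturalness level and the spectral
#' complexity over a set of image records.
#'
#' @param records data.frame with columns \code{alpha} and
#'   \code{complexity} (see [imageComplexityTable()]).
#' @return Spearman's rho.
#' @export
complexityAlphaCorrelation <- function(records) {
  if (nrow(records) < 3L || length(unique(records$alpha)) < 2L)
    stop("need >= 3 records with non-constant alpha")
  stats::cor(records$alpha, records$complexity, method = "spearman")
}

#' Complexity records for a list of images
#'
#' @param images named list of image matrices (or arrays).
#' @param alpha numeric vector of naturalness levels, one per image.
#' @param ... passed to [spectralComplexity()].
#' @return data.frame: image, alpha, complexity.
#' @export
imageComplexityTable <- function(images, alpha, ...) {
  stopifnot(length(images) == length(alpha))
  data.frame(
    image = if (is.null(names(images))) seq_along(images)
            else names(images),
    alpha = alpha,
    complexity = vapply(images, spectralComplexity, 1, ...),
    row.names = NULL)
}

#' Read a PNG image as a grayscale intensity matrix
#'
#' @param path PNG file.
#' @param grayWeights RGB luminance weights for color inputs.
#' @return numeric matrix of intensities in [0, 1].
#' @export
readImageGray <- function(path, grayWeights = c(0.299, 0.587, 0.114)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L)
    img <- grayWeights[1L] * img[, , 1L] + grayWeights[2L] * img[, , 2L] +
      grayWeights[3L] * img[, , 3L]
  img
}
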