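#' @include utils.R
NULL

# Reflect-pad a matrix by p pixels on every side (edge pixel included in the
# mirror, the usual "reflect" boundary).
padReflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(p, nr))), seq_len(nr),
          rev(seq_len(nr))[seq_len(min(p, nr))])
  ci <- c(rev(seq_len(min(p, nc))), seq_len(nc),
          rev(seq_len(nc))[seq_len(min(p, nc))])
  m[ri, ci, drop = FALSE]
}

# 2-D convolution with a small kernel, reflect boundary.
conv2Reflect <- function(m, kern) {
  k <- nrow(kern)
  p <- (k - 1L) %/% 2L
  if (p == 0L) return(m * kern[1, 1])
  mp <- padReflect(m, p)
  out <- matrix(0, nrow(m), ncol(m))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    w <- kern[a, b]
    if (w == 0) next
    out <- out + w * mp[(a - 1) + seq_len(nrow(m)),
                        (b - 1) + seq_len(ncol(m)), drop = FALSE]
  }
  out
}

boxMean <- function(m, k) {
  conv2Reflect(m, matrix(1 / (k * k), k, k))
}

# Adaptive (local mean/variance) Wiener filter, the MATLAB wiener2 scheme:
# the noise power is estimated as the average local variance.
wiener2 <- function(m, k) {
  if (k == 1L) return(m)
  mu <- boxMean(m, k)
  sig2 <- pmax(boxMean(m * m, k) - mu^2, 0)
  nu <- mean(sig2)
  den <- pmax(sig2, nu)
  gain <- ifelse(den > 0, pmax(sig2 - nu, 0) / den, 0)
  mu + gain * (m - mu)
}

gaussianKernel2D <- function(k, sigma) {
  if (k == 1L) return(matrix(1, 1, 1))
  r <- (k - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

#' Slice-wise Wiener and Gaussian smoothing of an image stack
#'
#' Applies an adaptive Wiener filter followed by normalized Gaussian
#' smoothing to every axial slice, the standard noise-filtering step before
#' segmentation-based volumetry. Both kernels default to 3 x 3; kernel size 1
#' disables the corresponding filter. Reflect boundary handling preserves the
#' image sum under the Gaussian.
#'
#' @param image 2-D matrix or 3-D array (slices along the third axis)
#' @param wienerKernel odd Wiener window size (default 3)
#' @param gaussianKernel odd Gaussian kernel size (default 3)
#' @param gaussianSigma Gaussian standard deviation in pixels (default 0.5)
#' @return the filtered image, same shape
#' @export
preprocessImage <- function(image, wienerKernel = 3L, gaussianKernel = 3L,
                            gaussianSigma = 0.5) {
  wienerKernel <- as.integer(wienerKernel)
  gaussianKernel <- as.integer(gaussianKernel)
  if (wienerKernel < 1L || wienerKernel %% 2L == 0L)
    stop("wienerKernel must be odd and >= 1", call. = FALSE)
  if (gaussianKernel < 1L || gaussianKernel %% 2L == 0L)
    stop("gaussianKernel must be odd and >= 1", call. = FALSE)
  kern <- gaussianKernel2D(gaussianKernel, gaussianSigma)
  one <- function(sl) {
    sl <- wiener2(sl, wienerKernel)
    if (gaussianKernel > 1L) sl <- conv2Reflect(sl, kern)
    sl
  }
  if (length(dim(image)) == 2L || is.null(dim(image))) {
    one(as.matrix(image))
  } else {
    out <- image
    for (k in seq_len(dim(image)[3])) out[, , k] <- one(image[, , k])
    out
  }
}
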