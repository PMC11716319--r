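#' @include AllClasses.R utils.R skeleton.R
NULL

#' Dual-echo subtraction contrast for fast-decaying tissue
#'
#' Subtracts the short-TE echo from the ultrashort-TE echo voxelwise, which
#' suppresses slowly decaying tissue and maximizes the signal of
#' fast-decaying collagenous sheets such as deep fascia. Negative differences
#' are clipped to zero.
#'
#' @param te1 ultrashort-echo image (array)
#' @param te2 short-echo image, same shape
#' @param rescale rescale the result to [0, 1] by its maximum (default TRUE)
#' @return array of the same shape as the inputs
#' @export
dualEchoSubtract <- function(te1, te2, rescale = TRUE) {
  if (!identical(dim(te1), dim(te2)))
    stop("echo images must share their shape", call. = FALSE)
  out <- pmax(te1 - te2, 0)
  if (rescale) {
    mx <- max(out)
    if (mx > 0) out <- out / mx
  }
  out
}

#' Threshold segmentation of a subtraction image (demonstration only)
#'
#' A plain global-threshold segmenter for subtraction images, provided so the
#' pipeline can be exercised end-to-end on simulated echoes. It is a stand-in
#' for expert manual segmentation, not a validated method.
#'
#' @param image subtraction image (3-D array, values in [0, 1])
#' @param spacing voxel spacing (mm)
#' @param threshold foreground threshold (default 0.5)
#' @return a binary \linkS4class{LabeledMask3D} (label 1 = "fascia")
#' @export
segmentFascia <- function(image, spacing, threshold = 0.5) {
  LabeledMask3D(array(as.integer(image > threshold), dim(image)),
                spacing, c(`1` = "fascia"))
}

#' Slice-wise medial-axis thickness map of a thin-sheet mask
#'
#' For every slice, extracts the band centerline
#' (\code{\link{sliceCenterline}}) and samples the local thickness at every
#' retained centerline pixel as twice the Euclidean distance transform of the
#' foreground (distance to the nearest background pixel): at a medial pixel
#' the two boundaries are equidistant, so twice the distance is the local
#' sheet thickness. Samples are pooled across slices.
#'
#' @param mask binary \linkS4class{LabeledMask3D} of the sheet; in-plane
#'   spacing must be isotropic
#' @param pruneLen spur-pruning length in pixels
#' @param minSamples minimum number of pooled samples required (default 100)
#' @param weights arclength calibration passed to
#'   \code{\link{sliceCenterline}} (affects the per-slice arclengths stored in
#'   the flags, not the thickness samples)
#' @return a \linkS4class{ThicknessMap}
#' @export
thicknessMap <- function(mask, pruneLen = 5L, minSamples = 100,
                         weights = c("kulpa", "chain")) {
  stopifnot(is(mask, "LabeledMask3D"))
  weights <- match.arg(weights)
  sp <- mask@spacing
  if (abs(sp[1] - sp[2]) > 1e-9 * sp[1])
    stop("in-plane spacing must be isotropic for the distance transform",
         call. = FALSE)
  vox <- mask@voxels
  if (!any(vox != 0)) stop("empty mask", call. = FALSE)
  nz <- dim(vox)[3]
  pitch <- sp[1]
  out <- vector("list", nz)
  flags <- list(emptySlices = integer(0), thinSlices = integer(0),
                arclengthMm = rep(NA_real_, nz))
  for (k in seq_len(nz)) {
    sl <- vox[, , k]
    cl <- sliceCenterline(sl, pitch, pruneLen, weights)
    if (cl$empty) {
      flags$emptySlices <- c(flags$emptySlices, k)
      next
    }
    if (cl$thin) flags$thinSlices <- c(flags$thinSlices, k)
    flags$arclengthMm[k] <- cl$arclengthMm
    d <- EBImage::distmap(matrix(as.integer(sl != 0), nrow(sl), ncol(sl)))
    th <- 2 * d[cl$pixels] * pitch
    keep <- th > 0
    out[[k]] <- data.frame(
      slice = k,
      x_mm = (cl$pixels[keep, 1] - 0.5) * sp[1],
      y_mm = (cl$pixels[keep, 2] - 0.5) * sp[2],
      thickness_mm = th[keep])
  }
  samples <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(samples) || nrow(samples) < minSamples)
    stop("only ", if (is.null(samples)) 0L else nrow(samples),
         " thickness samples (minimum ", minSamples,
         "); use a finer in-plane resolution", call. = FALSE)
  rownames(samples) <- NULL
  new("ThicknessMap", samples = samples, spacing = sp, flags = flags)
}

#' Algebraic mean sheet thickness: volume / (length x width)
#'
#' Cross-checks the medial-axis estimator with bulk arithmetic: the voxel-sum
#' sheet volume V divided by the mean per-slice centerline arclength L and the
#' sheet width W, where W is the number of non-empty slices times the slice
#' thickness. For a sheet of near-constant thickness V / (L W) is the mean
#' thickness.
#'
#' @inheritParams thicknessMap
#' @return mean thickness in mm
#' @export
meanThicknessAlgebraic <- function(mask, pruneLen = 5L,
                                   weights = c("kulpa", "chain")) {
  stopifnot(is(mask, "LabeledMask3D"))
  weights <- match.arg(weights)
  sp <- mask@spacing
  vox <- mask@voxels
  nz <- dim(vox)[3]
  arcs <- numeric(0)
  for (k in seq_len(nz)) {
    cl <- sliceCenterline(vox[, , k], sp[1], pruneLen, weights)
    if (!cl$empty) arcs <- c(arcs, cl$arclengthMm)
  }
  if (!length(arcs)) stop("no non-empty slice in mask", call. = FALSE)
  V <- sum(vox != 0) * prod(sp)          # mm^3
  W <- length(arcs) * sp[3]              # mm
  V / (mean(arcs) * W)
}

#' Histogram of a thickness map
#'
#' Fixed-width bins from 0 to the maximum sample rounded up to a whole bin;
#' unnormalized counts conserve the sample number.
#'
#' @param map a \linkS4class{ThicknessMap}
#' @param binWidth bin width in mm (default 0.05)
#' @param density normalize counts to a density (default FALSE)
#' @param maxMm optional upper edge override (rounded up to a whole bin), for
#'   histograms on shared breaks
#' @return a \linkS4class{ThicknessHistogram}
#' @export
thicknessHistogram <- function(map, binWidth = 0.05, density = FALSE,
                               maxMm = NULL) {
  stopifnot(is(map, "ThicknessMap"))
  if (binWidth <= 0) stop("binWidth must be > 0", call. = FALSE)
  x <- map@samples$thickness_mm
  if (!length(x)) stop("thickness map has no samples", call. = FALSE)
  top <- max(x, maxMm %||% 0)
  breaks <- seq(0, ceiling(top / binWidth + 1e-12) * binWidth, by = binWidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  new("ThicknessHistogram", breaks = h$breaks,
      counts = if (density) h$density else as.numeric(h$counts),
      density = density)
}

#' Compare pre and post thickness maps
#'
#' Reports the percent change of the global mean and of the median thickness
#' (100 (post - pre) / pre) plus the two histograms on shared breaks, the
#' quantities used to describe a rightward shift of a sheet-thickness
#' distribution after an intervention.
#'
#' @param preMap,postMap \linkS4class{ThicknessMap} objects
#' @param binWidth histogram bin width (mm)
#' @return a \linkS4class{ThicknessShift}
#' @export
compareThickness <- function(preMap, postMap, binWidth = 0.05) {
  stopifnot(is(preMap, "ThicknessMap"), is(postMap, "ThicknessMap"))
  pre <- preMap@samples$thickness_mm
  post <- postMap@samples$thickness_mm
  if (!length(pre) || !length(post))
    stop("both maps must be non-empty", call. = FALSE)
  top <- max(pre, post)
  new("ThicknessShift",
      meanShiftPct = 100 * (mean(post) - mean(pre)) / mean(pre),
      medianShiftPct = 100 * (stats::median(post) - stats::median(pre)) /
        stats::median(pre),
      preHist = thicknessHistogram(preMap, binWidth, maxMm = top),
      postHist = thicknessHistogram(postMap, binWidth, maxMm = top))
}
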