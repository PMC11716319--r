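#' @include AllClasses.R utils.R tensor.R
NULL

#' Tracking parameter set for deterministic streamline tractography
#'
#' Defaults follow common skeletal-muscle DTI practice: 1 mm steps, a 30
#' degree per-step turning limit, FA gating to exclude non-muscle and noisy
#' voxels, 1000 target tracts with lengths restricted to 5-200 mm.
#'
#' @param stepMm integration step (mm)
#' @param maxAngleDeg maximum turning angle per step (degrees)
#' @param faMin,faMax FA bounds for propagation
#' @param targetCount accepted tracts to aim for
#' @param maxSeedAttempts seeding budget
#' @param minLengthMm,maxLengthMm accepted raw length range (mm); tracking
#'   also stops at maxLengthMm
#' @return list of class "trackingParams"
#' @export
trackingParams <- function(stepMm = 1, maxAngleDeg = 30, faMin = 0.05,
                           faMax = 0.6, targetCount = 1000,
                           maxSeedAttempts = 50000, minLengthMm = 5,
                           maxLengthMm = 200) {
  stopifnot(stepMm > 0, maxAngleDeg > 0, faMin >= 0, faMax > faMin,
            targetCount >= 1, maxSeedAttempts >= targetCount,
            minLengthMm >= 0, maxLengthMm > minLengthMm)
  structure(list(stepMm = stepMm, maxAngleDeg = maxAngleDeg, faMin = faMin,
                 faMax = faMax, targetCount = as.integer(targetCount),
                 maxSeedAttempts = as.integer(maxSeedAttempts),
                 minLengthMm = minLengthMm, maxLengthMm = maxLengthMm),
            class = "trackingParams")
}

# March one direction from seed point p0 with initial direction d0 until a
# stop condition; returns the matrix of points (excluding the seed).
marchStreamline <- function(p0, d0, e1x, e1y, e1z, trackable, sp, dims,
                            stepMm, cosMax, maxLen, lenSoFar = 0) {
  pts <- matrix(NA_real_, ceiling(maxLen / stepMm) + 2L, 3L)
  np <- 0L
  p <- p0
  d <- d0
  len <- lenSoFar
  repeat {
    pn <- p + stepMm * d
    i <- floor(pn[1] / sp[1]) + 1
    j <- floor(pn[2] / sp[2]) + 1
    k <- floor(pn[3] / sp[3]) + 1
    if (i < 1 || j < 1 || k < 1 || i > dims[1] || j > dims[2] ||
        k > dims[3] || !trackable[i, j, k]) break
    dn <- c(e1x[i, j, k], e1y[i, j, k], e1z[i, j, k])
    if (sum(dn * d) < 0) dn <- -dn       # eigenvector sign continuity
    if (sum(dn * d) < cosMax) break      # turning angle exceeded
    np <- np + 1L
    pts[np, ] <- pn
    p <- pn
    d <- dn
    len <- len + stepMm
    if (len >= maxLen) break
  }
  pts[seq_len(np), , drop = FALSE]
}

#' Deterministic streamline tractography through a tensor field
#'
#' Fixed-step Euler integration along the principal eigenvector,
#' bidirectionally from seed points sampled uniformly inside the mask (voxel
#' chosen uniformly among mask voxels, position uniform within the voxel).
#' The eigenvector sign is chosen for continuity with the previous step. A
#' streamline stops on mask exit, FA outside bounds, turning-angle violation,
#' or at the maximum length; tracts shorter than the minimum length are
#' discarded. Seeding continues until the target count is accepted or the
#' attempt budget is exhausted (then a partial set is returned with a
#' warning). Identical inputs and seed give bit-identical output.
#'
#' @param field a \linkS4class{TensorField}
#' @param mask \linkS4class{LabeledMask3D} or logical array delimiting the
#'   muscle
#' @param params a \code{\link{trackingParams}} list
#' @param seed integer RNG seed for seeding
#' @return a \linkS4class{TractSet} with per-tract status "raw"
#' @export
trackFibers <- function(field, mask, params = trackingParams(), seed = NULL) {
  stopifnot(is(field, "TensorField"), inherits(params, "trackingParams"))
  sp <- field@spacing
  dims <- dim(field@tensors)[1:3]
  inMask <- if (is(mask, "LabeledMask3D")) mask@voxels != 0L
            else array(as.logical(mask), dims)
  stopifnot(identical(dim(inMask), dims))

  nvox <- prod(dims)
  comp <- matrix(field@tensors, nvox, 6L)
  valid <- as.vector(field@valid) & as.vector(inMask)
  fa <- rep(NA_real_, nvox)
  e1 <- matrix(NA_real_, nvox, 3L)
  if (any(valid)) {
    ev <- symEigenvalues(comp[valid, , drop = FALSE])
    mdv <- rowMeans(ev)
    fav <- sqrt(1.5) * sqrt((ev[, 1] - mdv)^2 + (ev[, 2] - mdv)^2 +
                            (ev[, 3] - mdv)^2) /
      sqrt(pmax(rowSums(ev^2), 1e-300))
    fa[valid] <- pmin(pmax(fav, 0), 1)
    e1[valid, ] <- symPrincipalEigenvector(comp[valid, , drop = FALSE], ev)
  }
  trackable <- array(valid & !is.na(fa) & fa >= params$faMin &
                       fa <= params$faMax, dims)
  e1x <- array(e1[, 1], dims); e1y <- array(e1[, 2], dims)
  e1z <- array(e1[, 3], dims)
  seedable <- which(trackable)
  if (!length(seedable)) {
    warning("no trackable voxels inside the mask", call. = FALSE)
    return(new("TractSet", tracts = list(), stepMm = params$stepMm,
               seed = as.integer(seed %||% NA_integer_), nSeeded = 0L))
  }
  seedIJK <- arrayInd(seedable, dims)
  cosMax <- cos(params$maxAngleDeg * pi / 180)

  tracts <- withSeed(seed, {
    acc <- vector("list", params$targetCount)
    nAcc <- 0L
    attempts <- 0L
    while (nAcc < params$targetCount && attempts < params$maxSeedAttempts) {
      attempts <- attempts + 1L
      row <- seedIJK[sample.int(nrow(seedIJK), 1L), ]
      p0 <- (row - stats::runif(3)) * sp
      d0 <- c(e1x[row[1], row[2], row[3]], e1y[row[1], row[2], row[3]],
              e1z[row[1], row[2], row[3]])
      fwd <- marchStreamline(p0, d0, e1x, e1y, e1z, trackable, sp, dims,
                             params$stepMm, cosMax, params$maxLengthMm / 2)
      bwd <- marchStreamline(p0, -d0, e1x, e1y, e1z, trackable, sp, dims,
                             params$stepMm, cosMax, params$maxLengthMm / 2)
      pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                   matrix(p0, 1, 3), fwd)
      len <- polylineLength(pts)
      if (len < params$minLengthMm) next
      nAcc <- nAcc + 1L
      acc[[nAcc]] <- list(points = pts, raw_length = len,
                          extrapolated_length = NA_real_, status = "raw",
                          reason = NA_character_)
    }
    attr(acc, "attempts") <- attempts
    attr(acc, "n") <- nAcc
    acc
  })
  nAcc <- attr(tracts, "n")
  attempts <- attr(tracts, "attempts")
  if (nAcc < params$targetCount)
    warning(sprintf("seed budget exhausted: %d of %d tracts accepted",
                    nAcc, params$targetCount), call. = FALSE)
  new("TractSet", tracts = tracts[seq_len(nAcc)], stepMm = params$stepMm,
      seed = as.integer(seed %||% NA_integer_), nSeeded = attempts)
}

# Fit one coordinate as a polynomial of (scaled) arclength; returns the
# coefficient vector for a Vandermonde basis on u in [-1, 1].
polyFitCoefs <- function(u, y, order) {
  X <- outer(u, 0:order, `^`)
  qr.coef(qr(X), y)
}

polyEval <- function(coefs, u) {
  drop(outer(u, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Extrapolate a fiber tract to the muscle boundary by polynomial fitting
#'
#' Fits each coordinate as a polynomial of arclength by least squares, then
#' extends the fitted curve from both ends in steps of half the tracking step
#' until it first leaves the mask; the boundary crossing is located by
#' bisection to 0.1 mm. Each end may extend by at most 50% of the raw length;
#' if an end hits that cap without leaving the mask the tract is rejected
#' ("no-boundary"). Successful tracts get status "extrapolated" and keep
#' their raw points with fitted extensions appended at both ends.
#'
#' @param tract one tract list (see \linkS4class{TractSet})
#' @param mask \linkS4class{LabeledMask3D} or logical array (the muscle)
#' @param spacing voxel spacing of the mask (mm); taken from the mask when it
#'   is a LabeledMask3D
#' @param polyOrder polynomial order per coordinate (default 3; cubic
#'   captures curved fascicles without oscillation)
#' @param stepMm tracking step (mm), used to pace the extension search
#' @return the tract with updated points, extrapolated_length and status
#' @export
extrapolateTract <- function(tract, mask, spacing = NULL, polyOrder = 3,
                             stepMm = 1) {
  fore <- if (is(mask, "LabeledMask3D")) mask@voxels != 0L else mask
  sp <- if (is(mask, "LabeledMask3D")) mask@spacing else as.numeric(spacing)
  dims <- dim(fore)
  pts <- tract$points
  n <- nrow(pts)
  if (n < polyOrder + 1) {
    tract$status <- "rejected"
    tract$reason <- "short"
    return(tract)
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[n]
  if (L <= 0) {
    tract$status <- "rejected"
    tract$reason <- "short"
    return(tract)
  }
  u <- 2 * s / L - 1                       # scale to [-1, 1] for conditioning
  cf <- lapply(1:3, function(a) polyFitCoefs(u, pts[, a], polyOrder))
  curveAt <- function(uu) vapply(cf, polyEval, numeric(length(uu)), u = uu)

  cap <- 0.5 * L
  du <- (stepMm / 2) * 2 / L               # half tracking step, in u units
  extendEnd <- function(uStart, dirSign) {
    # walk outward until the curve leaves the mask, then bisect the crossing
    uIn <- uStart
    uOut <- NA_real_
    travelled <- 0
    while (travelled < cap) {
      uNext <- uIn + dirSign * du
      pA <- curveAt(uIn); pB <- curveAt(uNext)
      travelled <- travelled + sqrt(sum((pB - pA)^2))
      if (!pointInMask(pB, fore, sp, dims)) {
        uOut <- uNext
        break
      }
      uIn <- uNext
    }
    if (is.na(uOut)) return(NULL)          # cap hit inside the mask
    repeat {
      pA <- curveAt(uIn); pB <- curveAt(uOut)
      if (sqrt(sum((pB - pA)^2)) <= 0.1) break
      uMid <- (uIn + uOut) / 2
      if (pointInMask(curveAt(uMid), fore, sp, dims)) uIn <- uMid
      else uOut <- uMid
    }
    uIn
  }

  uHi <- extendEnd(1, 1)
  uLo <- extendEnd(-1, -1)
  if (is.null(uHi) || is.null(uLo)) {
    tract$status <- "rejected"
    tract$reason <- "no-boundary"
    return(tract)
  }
  sampleCurve <- function(uFrom, uTo) {
    if (abs(uTo - uFrom) < 1e-12) return(NULL)
    nSteps <- max(1L, ceiling(abs(uTo - uFrom) / (2 * du)))
    uu <- seq(uFrom, uTo, length.out = nSteps + 1L)[-1]
    matrix(curveAt(uu), ncol = 3)
  }
  lowExt <- sampleCurve(-1, uLo)          # walks outward; reverse for order
  hiExt <- sampleCurve(1, uHi)
  newPts <- rbind(
    if (!is.null(lowExt)) lowExt[rev(seq_len(nrow(lowExt))), , drop = FALSE],
    pts,
    hiExt)
  tract$points <- newPts
  tract$extrapolated_length <- polylineLength(newPts)
  tract$status <- "extrapolated"
  tract$reason <- NA_character_
  tract
}

#' Extrapolate every tract of a set
#'
#' @param tractSet a \linkS4class{TractSet} of raw tracts
#' @param mask the muscle mask
#' @param polyOrder polynomial order (default 3)
#' @return the set with per-tract extrapolation applied
#' @export
extrapolateTracts <- function(tractSet, mask, polyOrder = 3) {
  stopifnot(is(tractSet, "TractSet"))
  tractSet@tracts <- lapply(tractSet@tracts, extrapolateTract, mask = mask,
                            polyOrder = polyOrder, stepMm = tractSet@stepMm)
  tractSet
}

#' Apply the fascicle inclusion filter
#'
#' Keeps tracts that reached the muscle boundary (status "extrapolated"),
#' whose extrapolated length is within 30% of the raw length
#' (extrapolated <= maxRatio x raw), and whose extrapolated length lies in
#' the accepted range. Rejected tracts stay in the set with status "rejected"
#' and exactly one reason ("overextended", "too-short", "too-long", or the
#' extrapolation-stage reason).
#'
#' @param tractSet a \linkS4class{TractSet} after extrapolation
#' @param maxRatio maximum extrapolated/raw length ratio (default 1.3)
#' @param lengthRange accepted extrapolated length range in mm (default
#'   c(5, 200))
#' @return the filtered set; use \code{\link{acceptedTracts}} to extract the
#'   accepted subset and \code{\link{tractCounts}} for the bookkeeping
#' @export
filterTracts <- function(tractSet, maxRatio = 1.3, lengthRange = c(5, 200)) {
  stopifnot(is(tractSet, "TractSet"))
  tractSet@tracts <- lapply(tractSet@tracts, function(t) {
    if (t$status != "extrapolated") {
      if (t$status == "raw") {
        t$status <- "rejected"
        t$reason <- "not-extrapolated"
      }
      return(t)
    }
    if (t$extrapolated_length > maxRatio * t$raw_length) {
      t$status <- "rejected"; t$reason <- "overextended"
    } else if (t$extrapolated_length < lengthRange[1]) {
      t$status <- "rejected"; t$reason <- "too-short"
    } else if (t$extrapolated_length > lengthRange[2]) {
      t$status <- "rejected"; t$reason <- "too-long"
    }
    t
  })
  tractSet
}

#' Tract bookkeeping counts
#'
#' @param tractSet a \linkS4class{TractSet}
#' @return named integer vector: seeded (seed attempts), tracked (tracts in
#'   the set), extrapolated (reached the boundary at any point), accepted
#'   (still "extrapolated" after filtering)
#' @export
tractCounts <- function(tractSet) {
  st <- tractStatus(tractSet)
  reasons <- vapply(tractSet@tracts, `[[`, character(1), "reason")
  extrapolated <- sum(st == "extrapolated" |
                        (st == "rejected" &
                           reasons %in% c("overextended", "too-short",
                                          "too-long")))
  c(seeded = tractSet@nSeeded, tracked = length(st),
    extrapolated = as.integer(extrapolated),
    accepted = sum(st == "extrapolated"))
}
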