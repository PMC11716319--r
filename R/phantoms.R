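#' @include AllClasses.R utils.R
NULL

#' Angular/axial thickness and radius profile for the fascia tube phantom
#'
#' Describes the deep-fascia sheet as an irregular tube: local thickness and
#' centerline radius are low-order Fourier perturbations over in-plane angle
#' theta and slice index. Integer harmonics make the analytic mean thickness
#' equal the base thickness exactly.
#'
#' @param thicknessMean base thickness (mm); the crural fascia is about 1 mm
#' @param thicknessAmp amplitude of the angular thickness perturbation (mm)
#' @param thicknessHarmonic integer angular harmonic (>= 1) of the thickness
#'   perturbation
#' @param radiusAmp amplitude of the angular radius perturbation (mm)
#' @param radiusHarmonic integer angular harmonic of the radius perturbation
#' @param axialAmp amplitude of the slice-to-slice thickness perturbation (mm)
#' @param axialHarmonic integer axial harmonic (cycles over the stack)
#' @param twistPerSlice slice-to-slice rotation of the angular perturbations
#'   (radians per slice): the irregular tube twists along the limb, so slices
#'   are not copies of one another. Leaves the analytic mean thickness
#'   untouched (the angular terms are zero-mean at every phase).
#' @param phases optional numeric length-3 (thickness, radius, axial phases in
#'   radians); when NULL, \code{\link{makeFasciaPhantom}} draws them from its
#'   seed
#' @return a list of class "fasciaProfile"
#' @export
fasciaProfile <- function(thicknessMean = 1.2, thicknessAmp = 0,
                          thicknessHarmonic = 2L, radiusAmp = 0,
                          radiusHarmonic = 3L, axialAmp = 0,
                          axialHarmonic = 1L, twistPerSlice = 0,
                          phases = NULL) {
  stopifnot(thicknessMean > 0, thicknessAmp >= 0, radiusAmp >= 0,
            axialAmp >= 0, thicknessHarmonic >= 1, radiusHarmonic >= 1,
            axialHarmonic >= 1)
  structure(list(thicknessMean = thicknessMean, thicknessAmp = thicknessAmp,
                 thicknessHarmonic = as.integer(thicknessHarmonic),
                 radiusAmp = radiusAmp,
                 radiusHarmonic = as.integer(radiusHarmonic),
                 axialAmp = axialAmp, axialHarmonic = as.integer(axialHarmonic),
                 twistPerSlice = twistPerSlice,
                 phases = phases),
            class = "fasciaProfile")
}

#' Synthesize an irregular-tube fascia phantom with analytic ground truth
#'
#' Rasterizes the annular band between the inner and outer boundary of an
#' irregular tube onto a voxel grid (a voxel is foreground when its center
#' falls inside the band), and returns the analytic thickness field as ground
#' truth. Defaults emulate a deep-fascia acquisition: ~1.2 mm sheet at 0.3 mm
#' in-plane resolution and 3 mm slices.
#'
#' @param baseRadius mean centerline radius of the tube (mm); must exceed the
#'   maximum local thickness
#' @param profile a \code{\link{fasciaProfile}}
#' @param spacing voxel spacing (dx, dy, dz) in mm
#' @param nSlices number of axial slices (> 0)
#' @param seed integer seed for the perturbation phases (reproducible masks)
#' @param margin in-plane margin beyond the outer boundary (mm)
#' @return list with elements \code{mask} (\linkS4class{LabeledMask3D}, label
#'   1 = "fascia") and \code{truth} (\linkS4class{FasciaPhantomTruth})
#' @examples
#' ph <- makeFasciaPhantom(nSlices = 4)
#' ph$truth@meanThickness
#' @export
makeFasciaPhantom <- function(baseRadius = 12.6, profile = fasciaProfile(),
                              spacing = c(0.3, 0.3, 3), nSlices = 10,
                              seed = NULL, margin = 3) {
  stopifnot(inherits(profile, "fasciaProfile"))
  if (nSlices < 1) stop("nSlices must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  nSlices <- as.integer(nSlices)

  phases <- profile$phases
  if (is.null(phases))
    phases <- withSeed(seed, stats::runif(3, 0, 2 * pi))
  pr <- profile
  tMin <- pr$thicknessMean - pr$thicknessAmp - pr$axialAmp
  tMax <- pr$thicknessMean + pr$thicknessAmp + pr$axialAmp
  if (tMin <= 0)
    stop("profile allows non-positive thickness (min ", signif(tMin, 3),
         " mm); reduce perturbation amplitudes", call. = FALSE)
  if (baseRadius <= tMax)
    stop("baseRadius must exceed the maximum thickness", call. = FALSE)
  if (baseRadius - pr$radiusAmp - tMax / 2 <= 0)
    stop("inner boundary would cross the tube axis", call. = FALSE)

  thicknessField <- function(slice, theta) {
    tw <- pr$twistPerSlice * (slice - 1)
    pr$thicknessMean +
      pr$thicknessAmp * cos(pr$thicknessHarmonic * theta + phases[1] + tw) +
      pr$axialAmp * cos(2 * pi * pr$axialHarmonic * (slice - 0.5) / nSlices +
                        phases[3])
  }
  radiusField <- function(slice, theta) {
    baseRadius + pr$radiusAmp * cos(pr$radiusHarmonic * theta + phases[2] +
                                    pr$twistPerSlice * (slice - 1))
  }

  half <- baseRadius + pr$radiusAmp + tMax / 2 + margin
  nx <- ceiling(2 * half / spacing[1])
  ny <- ceiling(2 * half / spacing[2])
  cx <- nx * spacing[1] / 2
  cy <- ny * spacing[2] / 2
  ux <- axisCenters(nx, spacing[1]) - cx
  uy <- axisCenters(ny, spacing[2]) - cy
  r <- sqrt(outer(ux^2, uy^2, `+`))
  th <- atan2(matrix(uy, nx, ny, byrow = TRUE), matrix(ux, nx, ny))

  vox <- array(0L, c(nx, ny, nSlices))
  for (k in seq_len(nSlices)) {
    tk <- thicknessField(k, th)
    rk <- radiusField(k, th)
    vox[, , k] <- as.integer(abs(r - rk) <= tk / 2)
  }
  coarse <- tMin < 2 * max(spacing[1], spacing[2])
  if (coarse)
    warning("band thinner than 2 in-plane pixels somewhere; ",
            "thickness estimates will be resolution-limited", call. = FALSE)
  mask <- LabeledMask3D(vox, spacing, c(`1` = "fascia"))
  truth <- new("FasciaPhantomTruth", thicknessField = thicknessField,
               radiusField = radiusField,
               meanThickness = pr$thicknessMean, centerlineRadius = baseRadius,
               nSlices = nSlices, spacing = spacing, coarse = coarse)
  list(mask = mask, truth = truth)
}

#' Analytic annulus band area per slice of a fascia phantom (mm^2)
#'
#' Integrates the band area of the truth geometry numerically over angle
#' (independent of the rasterizer), for checking rasterization accuracy.
#' The band between radii r - t/2 and r + t/2 has area element
#' ((r + t/2)^2 - (r - t/2)^2) / 2 = r t per unit angle.
#'
#' @param truth a \linkS4class{FasciaPhantomTruth}
#' @param nTheta quadrature points over angle
#' @return numeric vector of per-slice band areas (mm^2)
#' @export
annulusAreaPerSlice <- function(truth, nTheta = 4096) {
  th <- (seq_len(nTheta) - 0.5) / nTheta * 2 * pi
  vapply(seq_len(truth@nSlices), function(k) {
    sum(truth@radiusField(k, th) * truth@thicknessField(k, th)) *
      (2 * pi / nTheta)
  }, numeric(1))
}

#' Build a labeled limb phantom from elliptic-cylinder shape specs
#'
#' Each label is a solid elliptic cylinder (axis along z) specified by a
#' target volume, so the rasterized voxel-sum volume can be checked against a
#' closed form. Shapes must be disjoint.
#'
#' @param labelSpec named list; each element is a list with fields
#'   \code{center} (length-3, mm), \code{volume_cm3}, \code{height_mm} and
#'   optional \code{axisRatio} (b/a, default 1)
#' @param spacing voxel spacing in mm (default the 0.5 x 0.5 x 5 mm grid of a
#'   proton-density acquisition)
#' @param gridDims optional grid dimensions; derived from the shapes plus
#'   \code{margin} when NULL
#' @param margin margin around the shapes (mm)
#' @return a \linkS4class{LabeledMask3D} with one integer label per shape
#' @examples
#' spec <- list(femur = list(center = c(20, 20, 50), volume_cm3 = 67,
#'                           height_mm = 100))
#' m <- makeLimbPhantom(spec, spacing = c(1, 1, 5))
#' @export
makeLimbPhantom <- function(labelSpec, spacing = c(0.5, 0.5, 5),
                            gridDims = NULL, margin = 5) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (!length(labelSpec)) {
    dims <- if (is.null(gridDims)) c(20L, 20L, 4L) else as.integer(gridDims)
    return(LabeledMask3D(array(0L, dims), spacing))
  }
  if (is.null(names(labelSpec)) || any(!nzchar(names(labelSpec))))
    stop("labelSpec must be a named list", call. = FALSE)

  shp <- lapply(labelSpec, function(s) {
    stopifnot(length(s$center) == 3, s$volume_cm3 > 0, s$height_mm > 0)
    ratio <- s$axisRatio %||% 1
    vmm3 <- s$volume_cm3 * 1000
    a <- sqrt(vmm3 / (pi * ratio * s$height_mm))
    list(center = as.numeric(s$center), a = a, b = ratio * a,
         h = s$height_mm)
  })
  if (is.null(gridDims)) {
    lo <- sapply(shp, function(s) s$center - c(s$a, s$b, s$h / 2)) - margin
    hi <- sapply(shp, function(s) s$center + c(s$a, s$b, s$h / 2)) + margin
    if (any(apply(lo, 1, min) < 0))
      stop("shape extents fall below the grid origin; shift centers or ",
           "pass gridDims", call. = FALSE)
    dims <- ceiling(apply(hi, 1, max) / spacing)
  } else dims <- gridDims
  dims <- as.integer(dims)

  xs <- axisCenters(dims[1], spacing[1])
  ys <- axisCenters(dims[2], spacing[2])
  zs <- axisCenters(dims[3], spacing[3])
  vox <- array(0L, dims)
  owner <- rep(NA_character_, length(labelSpec))
  for (li in seq_along(shp)) {
    s <- shp[[li]]
    ex <- ((xs - s$center[1]) / s$a)^2
    ey <- ((ys - s$center[2]) / s$b)^2
    inPlane <- outer(ex, ey, `+`) <= 1
    zin <- abs(zs - s$center[3]) <= s$h / 2
    for (k in which(zin)) {
      sl <- vox[, , k]
      clash <- inPlane & sl != 0L
      if (any(clash)) {
        other <- names(labelSpec)[sl[which(clash)[1]]]
        stop("overlapping shapes: '", names(labelSpec)[li], "' and '",
             other, "'", call. = FALSE)
      }
      sl[inPlane] <- li
      vox[, , k] <- sl
    }
  }
  LabeledMask3D(vox, spacing,
                stats::setNames(names(labelSpec), seq_along(labelSpec)))
}

#' Build a unipennate muscle phantom with a constant diffusion tensor field
#'
#' A box-shaped muscle whose line of action is the z axis and whose fibers run
#' at a fixed pennation angle in the x-z plane. Every foreground voxel carries
#' the same tensor with principal eigenvector
#' (sin(alpha), 0, cos(alpha)). The true fascicle length is the aponeurosis
#' separation (box extent along x) divided by sin(alpha).
#'
#' @param pennationAngleDeg pennation angle in degrees, strictly inside
#'   (0, 90): at 0 the fascicle length is undefined and at 90 the unipennate
#'   model degenerates
#' @param boxDims box extents (x, y, z) in mm; the default long z extent keeps
#'   fascicle truncation at the muscle ends negligible
#' @param eigenvalues tensor eigenvalues (mm^2/s), descending; defaults are
#'   typical skeletal-muscle values
#' @param spacing voxel spacing (mm); box extents are rounded up to whole
#'   voxels and the truth reflects the actual rasterized box
#' @return list with \code{mask} (\linkS4class{LabeledMask3D}, label
#'   "muscle"), \code{tensors} (\linkS4class{TensorField}) and \code{truth}
#'   (\linkS4class{PennatePhantomTruth})
#' @examples
#' ph <- makePennatePhantom(30, boxDims = c(20, 20, 60), spacing = c(2, 2, 2))
#' ph$truth@fascicleLengthMm  # 20 / sin(30 deg) = 40
#' @export
makePennatePhantom <- function(pennationAngleDeg,
                               boxDims = c(10, 20, 400),
                               eigenvalues = c(2.1e-3, 1.6e-3, 1.4e-3),
                               spacing = c(1, 2, 2)) {
  if (pennationAngleDeg <= 0 || pennationAngleDeg >= 90)
    stop("pennation angle must be strictly inside (0, 90) degrees ",
         "(fascicle length is degenerate at the ends)", call. = FALSE)
  ev <- as.numeric(eigenvalues)
  if (length(ev) != 3 || any(ev <= 0) || is.unsorted(rev(ev)))
    stop("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  n <- as.integer(ceiling(boxDims / spacing - 1e-9))
  dims <- n * spacing

  a <- pennationAngleDeg * pi / 180
  s <- sin(a); cz <- cos(a)
  # D = l1 e1 e1' + l2 e2 e2' + l3 e3 e3', e1 = (s, 0, cz), e2 = (0, 1, 0)
  comp <- c(ev[1] * s^2 + ev[3] * cz^2,           # Dxx
            ev[2],                                # Dyy
            ev[1] * cz^2 + ev[3] * s^2,           # Dzz
            0,                                    # Dxy
            (ev[1] - ev[3]) * s * cz,             # Dxz
            0)                                    # Dyz
  tens <- array(rep(comp, each = prod(n)), c(n, 6L))
  field <- new("TensorField", tensors = tens,
               valid = array(TRUE, n), spacing = spacing)
  mask <- LabeledMask3D(array(1L, n), spacing, c(`1` = "muscle"))
  truth <- new("PennatePhantomTruth", pennationAngleDeg = pennationAngleDeg,
               fascicleLengthMm = dims[1] / s, lineOfAction = c(0, 0, 1),
               muscleVolumeMm3 = prod(dims), eigenvalues = ev)
  list(mask = mask, tensors = field, truth = truth)
}

#' Deterministic diffusion gradient table
#'
#' Generates n approximately uniform unit directions on the sphere by the
#' Fibonacci-lattice construction; deterministic, so simulated acquisitions
#' are reproducible.
#'
#' @param n number of diffusion directions (default 20, a common muscle DTI
#'   protocol)
#' @return n x 3 matrix of unit vectors
#' @export
gradientTable <- function(n = 20) {
  stopifnot(n >= 6)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' Monoexponential single-tensor signal model
#' \eqn{S(g) = S_0 \exp(-b\, g^T D g)} per voxel and direction, preceded by
#' one b = 0 reference volume. Optional Rician noise: independent Gaussian
#' noise on two quadrature channels followed by the magnitude.
#'
#' @param field a \linkS4class{TensorField}
#' @param gradients n x 3 matrix of diffusion directions; non-unit rows are
#'   normalized with a warning
#' @param bValue diffusion weighting (s/mm^2), >= 0; default 500, with 20
#'   directions a standard muscle protocol
#' @param S0 non-diffusion-weighted signal (> 0)
#' @param noiseSigma Gaussian channel noise standard deviation (>= 0, signal
#'   units); 0 gives a noiseless acquisition
#' @param seed integer seed for the noise
#' @return a \linkS4class{DWIStack}; invalid voxels carry zero signal
#' @export
simulateDWI <- function(field, gradients = gradientTable(20), bValue = 500,
                        S0 = 1, noiseSigma = 0, seed = NULL) {
  stopifnot(is(field, "TensorField"))
  if (S0 <= 0) stop("S0 must be positive", call. = FALSE)
  if (bValue < 0) stop("bValue must be >= 0", call. = FALSE)
  if (noiseSigma < 0) stop("noiseSigma must be >= 0", call. = FALSE)
  gradients <- as.matrix(gradients)
  stopifnot(ncol(gradients) == 3)
  nrm <- sqrt(rowSums(gradients^2))
  if (any(nrm == 0)) stop("zero gradient vector in table", call. = FALSE)
  if (any(abs(nrm - 1) > 1e-8)) {
    warning("non-unit gradient vectors normalized", call. = FALSE)
    gradients <- gradients / nrm
  }

  dims <- dim(field@tensors)[1:3]
  nvox <- prod(dims)
  Tm <- matrix(field@tensors, nvox, 6L)
  g <- gradients
  # quadratic form coefficients against the (xx, yy, zz, xy, xz, yz) layout
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  att <- exp(-bValue * Tm %*% t(Q))               # nvox x ndir
  S <- cbind(1, att) * S0                         # prepend b = 0 volume
  dimnames(gradients) <- NULL
  S[!as.vector(field@valid), ] <- 0

  if (noiseSigma > 0) {
    S <- withSeed(seed, {
      n1 <- matrix(stats::rnorm(length(S), sd = noiseSigma), nrow(S))
      n2 <- matrix(stats::rnorm(length(S), sd = noiseSigma), nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
  }
  new("DWIStack", signal = array(S, c(dims, ncol(S))),
      gradients = rbind(0, gradients),
      bValues = c(0, rep(bValue, nrow(gradients))), spacing = field@spacing)
}

#' Default limb label specification used by the pre/post pair generator
#'
#' A femur-like bone and a gastrocnemius-like muscle, sized after the printed
#' bone volumes of a partial thigh acquisition (femur segment ~67 cm^3).
#'
#' @return a named list suitable for \code{\link{makeLimbPhantom}}
#' @export
defaultLimbSpec <- function() {
  list(femur = list(center = c(20, 25, 60), volume_cm3 = 67,
                    height_mm = 100),
       medial_gastrocnemius = list(center = c(58, 25, 60), volume_cm3 = 110,
                                   height_mm = 100, axisRatio = 0.8))
}

#' Generate a matched pre/post phantom pair with known structural changes
#'
#' Emulates a pre-injury vs post-immobilization comparison: per-label
#' fractional volume changes are applied to a labeled limb phantom (in-plane
#' radius scaled by sqrt(1 + change), height fixed) and the fascia thickness
#' profile is multiplied by a scale factor. Both timepoints share the same
#' perturbation phases so only the specified changes differ.
#'
#' @param changeSpec list with \code{volumeChanges} (named numeric of
#'   fractional changes, e.g. c(femur = -0.0222)) and \code{fasciaScale}
#'   (thickness scale factor, > 0)
#' @param seed integer seed (fascia perturbation phases)
#' @param limbSpec limb label specification (default
#'   \code{\link{defaultLimbSpec}})
#' @param fasciaProfilePre fascia profile of the pre timepoint
#' @param fasciaSpacing,nSlices fascia phantom grid parameters
#' @return list with \code{pre}, \code{post} (each: \code{limb} mask,
#'   \code{fascia} mask, \code{fasciaTruth}) and \code{truth} (the requested
#'   changes)
#' @export
makePrePostPair <- function(changeSpec = list(volumeChanges = c(femur = -0.0222),
                                              fasciaScale = 1.09),
                            seed = NULL, limbSpec = defaultLimbSpec(),
                            fasciaProfilePre = fasciaProfile(
                              thicknessMean = 1.2, thicknessAmp = 0.15,
                              radiusAmp = 0.8, axialAmp = 0.05,
                              twistPerSlice = 0.5),
                            fasciaSpacing = c(0.3, 0.3, 3), nSlices = 10) {
  fs <- changeSpec$fasciaScale %||% 1
  if (fs <= 0) stop("fasciaScale must be > 0", call. = FALSE)
  vc <- changeSpec$volumeChanges %||% numeric(0)
  if (any(1 + vc <= 0))
    stop("volume change factors must stay positive", call. = FALSE)
  if (length(vc) && !all(names(vc) %in% names(limbSpec)))
    stop("volumeChanges name unknown labels: ",
         paste(setdiff(names(vc), names(limbSpec)), collapse = ", "),
         call. = FALSE)

  limbPre <- makeLimbPhantom(limbSpec)
  postSpec <- limbSpec
  for (nm in names(vc))
    postSpec[[nm]]$volume_cm3 <- postSpec[[nm]]$volume_cm3 * (1 + vc[[nm]])
  limbPost <- makeLimbPhantom(postSpec)

  phases <- withSeed(seed, stats::runif(3, 0, 2 * pi))
  profPre <- fasciaProfilePre
  profPre$phases <- phases
  profPost <- profPre
  profPost$thicknessMean <- profPre$thicknessMean * fs
  profPost$thicknessAmp <- profPre$thicknessAmp * fs
  profPost$axialAmp <- profPre$axialAmp * fs
  fascPre <- makeFasciaPhantom(profile = profPre, spacing = fasciaSpacing,
                               nSlices = nSlices)
  fascPost <- makeFasciaPhantom(profile = profPost, spacing = fasciaSpacing,
                                nSlices = nSlices)

  list(pre = list(limb = limbPre, fascia = fascPre$mask,
                  fasciaTruth = fascPre$truth),
       post = list(limb = limbPost, fascia = fascPost$mask,
                   fasciaTruth = fascPost$truth),
       truth = list(volumeChanges = vc, fasciaScale = fs))
}
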