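# Central S4 containers. All geometry is in mm; voxel (i, j, k) (1-based) has
# world center ((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz).

#' LabeledMask3D: an integer-labeled voxel grid
#'
#' The substrate for volumetry, fascia thickness mapping and tract masking: a
#' 3-D integer array of label ids, the voxel spacing in mm, and a dictionary
#' mapping label ids to anatomical names. Label id 0 is background.
#'
#' @slot voxels 3-D integer array of label ids (0 = background)
#' @slot spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm,
#'   all strictly positive
#' @slot labels named character vector; names are label ids as strings,
#'   values are label names. Every nonzero voxel value must appear here.
#' @export
setClass("LabeledMask3D",
  representation(voxels = "array", spacing = "numeric", labels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values (mm)")
    vals <- unique(as.vector(object@voxels))
    vals <- vals[vals != 0]
    known <- suppressWarnings(as.numeric(names(object@labels)))
    if (length(vals) && !all(vals %in% known))
      msg <- c(msg, sprintf("voxel values without a label map entry: %s",
                            paste(setdiff(vals, known), collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Construct a LabeledMask3D
#'
#' @param voxels 3-D integer array of label ids (0 = background)
#' @param spacing voxel spacing (dx, dy, dz) in mm
#' @param labels named character vector mapping label ids (names) to label
#'   names; defaults to "label<k>" for each nonzero value present
#' @return a \linkS4class{LabeledMask3D}
#' @examples
#' m <- LabeledMask3D(array(0L, c(4, 4, 2)), spacing = c(1, 1, 5))
#' spacing(m)
#' @export
LabeledMask3D <- function(voxels, spacing, labels = NULL) {
  storage.mode(voxels) <- "integer"
  if (is.null(labels)) {
    vals <- sort(unique(as.vector(voxels)))
    vals <- vals[vals != 0]
    labels <- if (length(vals)) {
      stats::setNames(paste0("label", vals), as.character(vals))
    } else {
      stats::setNames(character(0), character(0))
    }
  }
  new("LabeledMask3D", voxels = voxels, spacing = as.numeric(spacing),
      labels = labels)
}

#' DWIStack: a diffusion-weighted image series
#'
#' 4-D signal array (x, y, z, volume) with one gradient direction and b-value
#' per volume. At least one b = 0 reference volume is required by tensor
#' fitting; its gradient row is ignored.
#'
#' @slot signal 4-D numeric array (x, y, z, volume)
#' @slot gradients n x 3 matrix of gradient directions (unit vectors for
#'   diffusion-weighted volumes; the b = 0 row may be zero)
#' @slot bValues numeric vector of b-values (s/mm^2), one per volume
#' @slot spacing voxel spacing (mm)
#' @export
setClass("DWIStack",
  representation(signal = "array", gradients = "matrix", bValues = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@signal)
    if (length(d) != 4L) msg <- c(msg, "signal must be a 4-D array")
    if (length(d) == 4L && (nrow(object@gradients) != d[4] ||
                            length(object@bValues) != d[4]))
      msg <- c(msg, "gradient count and b-value count must match volume count")
    if (ncol(object@gradients) != 3L) msg <- c(msg, "gradients must be n x 3")
    if (!any(object@bValues == 0))
      msg <- c(msg, "at least one b = 0 reference volume is required")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (is.null(msg)) TRUE else msg
  })

#' TensorField: per-voxel symmetric diffusion tensors
#'
#' Tensors are stored as the 6 unique components in the order
#' (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), units mm^2/s, so symmetry holds by
#' construction. `valid` flags voxels with a usable fit.
#'
#' @slot tensors 4-D array (x, y, z, 6)
#' @slot valid 3-D logical array
#' @slot spacing voxel spacing (mm)
#' @export
setClass("TensorField",
  representation(tensors = "array", valid = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@tensors)
    if (length(d) != 4L || d[4] != 6L)
      msg <- c(msg, "tensors must be (x, y, z, 6)")
    if (!identical(dim(object@valid), d[1:3]))
      msg <- c(msg, "valid mask must match the tensor grid")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (is.null(msg)) TRUE else msg
  })

#' TractSet: a collection of fiber tracts
#'
#' Each tract is a list with elements `points` (m x 3 matrix of world
#' coordinates, mm), `raw_length` (mm), `extrapolated_length` (mm or NA),
#' `status` ("raw", "extrapolated" or "rejected") and `reason` (NA or one
#' rejection reason).
#'
#' @slot tracts list of per-tract lists (see Details)
#' @slot stepMm integration step used by tracking, mm
#' @slot seed integer seed used for seeding (NA if none)
#' @slot nSeeded number of seed points attempted
#' @export
setClass("TractSet",
  representation(tracts = "list", stepMm = "numeric", seed = "integer",
                 nSeeded = "integer"))

#' ThicknessMap: slice-wise medial-axis thickness samples
#'
#' @slot samples data.frame with columns slice, x_mm, y_mm, thickness_mm
#' @slot spacing voxel spacing of the source mask (mm)
#' @slot flags list of per-slice warning flags (empty slices, thin band)
#' @export
setClass("ThicknessMap",
  representation(samples = "data.frame", spacing = "numeric", flags = "list"),
  validity = function(object) {
    msg <- NULL
    need <- c("slice", "x_mm", "y_mm", "thickness_mm")
    if (!all(need %in% names(object@samples)))
      msg <- c(msg, "samples must have columns slice, x_mm, y_mm, thickness_mm")
    if (nrow(object@samples) && any(object@samples$thickness_mm <= 0))
      msg <- c(msg, "all thickness samples must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' ThicknessHistogram: fixed-width histogram of thickness samples
#'
#' @slot breaks bin edges (mm), strictly increasing, starting at 0
#' @slot counts bin counts (or densities when `density` is TRUE)
#' @slot density logical: counts normalized to a density
#' @export
setClass("ThicknessHistogram",
  representation(breaks = "numeric", counts = "numeric", density = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@breaks) != length(object@counts) + 1L)
      msg <- c(msg, "breaks must be one longer than counts")
    if (any(diff(object@breaks) <= 0))
      msg <- c(msg, "breaks must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' ThicknessShift: pre-vs-post thickness comparison
#'
#' @slot meanShiftPct percent change of the global mean thickness
#' @slot medianShiftPct percent change of the median thickness
#' @slot preHist,postHist \linkS4class{ThicknessHistogram} on shared breaks
#' @export
setClass("ThicknessShift",
  representation(meanShiftPct = "numeric", medianShiftPct = "numeric",
                 preHist = "ThicknessHistogram", postHist = "ThicknessHistogram"))

#' VolumeReport: per-label and per-compartment volumes
#'
#' Both slots are data.frames with columns name, pre_cm3, post_cm3 (NA in
#' single-timepoint reports), percent_change and change_label (the signed
#' change rendered as "loss of x%" / "gain of x%").
#'
#' @slot labels per-label table
#' @slot compartments per-compartment table (possibly empty)
#' @export
setClass("VolumeReport",
  representation(labels = "data.frame", compartments = "data.frame"))

#' ArchitectureReport: per-muscle DTI architecture summary
#'
#' PCSA is defined as muscle volume divided by mean fascicle length, so
#' `pcsaCm2 * meanFascicleLengthCm == volumeCm3` holds to numerical precision.
#'
#' @slot muscle muscle name
#' @slot volumeCm3 muscle volume (cm^3)
#' @slot meanFascicleLengthCm,sdFascicleLengthCm fascicle length stats (cm)
#' @slot meanPennationDeg,sdPennationDeg pennation angle stats (degrees)
#' @slot pcsaCm2 physiological cross-sectional area (cm^2)
#' @slot lineOfAction unit 3-vector
#' @slot counts named integer vector: seeded, tracked, extrapolated, accepted
#' @export
setClass("ArchitectureReport",
  representation(muscle = "character", volumeCm3 = "numeric",
                 meanFascicleLengthCm = "numeric", sdFascicleLengthCm = "numeric",
                 meanPennationDeg = "numeric", sdPennationDeg = "numeric",
                 pcsaCm2 = "numeric", lineOfAction = "numeric",
                 counts = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@meanPennationDeg < 0 || object@meanPennationDeg > 90)
      msg <- c(msg, "mean pennation angle must be in [0, 90] degrees")
    rel <- abs(object@pcsaCm2 * object@meanFascicleLengthCm - object@volumeCm3)
    if (rel > 1e-9 * max(object@volumeCm3, 1e-300))
      msg <- c(msg, "PCSA x mean fascicle length must equal volume")
    if (abs(sqrt(sum(object@lineOfAction^2)) - 1) > 1e-9)
      msg <- c(msg, "line of action must be unit norm")
    if (is.null(msg)) TRUE else msg
  })

#' FasciaPhantomTruth: analytic ground truth for the fascia tube phantom
#'
#' @slot thicknessField function(slice, theta) returning local thickness (mm)
#' @slot radiusField function(slice, theta) returning the local centerline
#'   radius (mm)
#' @slot meanThickness analytic mean thickness over the sampled domain (mm)
#' @slot centerlineRadius mean tube radius (mm)
#' @slot nSlices number of slices
#' @slot spacing grid spacing (mm)
#' @slot coarse TRUE when the grid resolves the band with < 2 in-plane pixels
#'   somewhere (rasterization warning flag)
#' @export
setClass("FasciaPhantomTruth",
  representation(thicknessField = "function", radiusField = "function",
                 meanThickness = "numeric",
                 centerlineRadius = "numeric", nSlices = "integer",
                 spacing = "numeric", coarse = "logical"))

#' PennatePhantomTruth: ground truth for the unipennate muscle phantom
#'
#' @slot pennationAngleDeg true pennation angle (degrees, in (0, 90))
#' @slot fascicleLengthMm true fascicle length: aponeurosis separation along x
#'   divided by sin(pennation angle), mm
#' @slot lineOfAction unit 3-vector, (0, 0, 1) for the box phantom
#' @slot muscleVolumeMm3 analytic muscle volume (mm^3)
#' @slot eigenvalues diffusion tensor eigenvalues (lambda1 >= lambda2 >=
#'   lambda3 > 0), mm^2/s
#' @export
setClass("PennatePhantomTruth",
  representation(pennationAngleDeg = "numeric", fascicleLengthMm = "numeric",
                 lineOfAction = "numeric", muscleVolumeMm3 = "numeric",
                 eigenvalues = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@pennationAngleDeg < 0 || object@pennationAngleDeg > 90)
      msg <- c(msg, "pennation angle must be in [0, 90] degrees")
    ev <- object@eigenvalues
    if (length(ev) != 3L || any(ev <= 0) || is.unsorted(rev(ev)))
      msg <- c(msg, "eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0")
    if (is.null(msg)) TRUE else msg
  })

#' ComparisonReport: aggregated pre-vs-post study report
#'
#' @slot volumes a \linkS4class{VolumeReport}
#' @slot fascia a \linkS4class{ThicknessShift} or NULL
#' @slot architecture list of per-muscle lists with elements pre, post
#'   (\linkS4class{ArchitectureReport}) and deltas
#' @slot provenance list: seed, config, package version
#' @export
setClass("ComparisonReport",
  representation(volumes = "VolumeReport", fascia = "ANY",
                 architecture = "list", provenance = "list"))
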