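#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn LabeledMask3D voxel spacing (mm)
#' @param x,object a \code{LabeledMask3D}
#' @export
setMethod("spacing", "LabeledMask3D", function(x) x@spacing)

#' @describeIn DWIStack voxel spacing (mm)
#' @param x,object a \code{DWIStack}
#' @export
setMethod("spacing", "DWIStack", function(x) x@spacing)

#' @describeIn TensorField voxel spacing (mm)
#' @param x,object a \code{TensorField}
#' @export
setMethod("spacing", "TensorField", function(x) x@spacing)

#' @describeIn LabeledMask3D the label-id array
#' @export
setMethod("voxels", "LabeledMask3D", function(x) x@voxels)

#' @describeIn LabeledMask3D the id -> name label dictionary
#' @export
setMethod("labelNames", "LabeledMask3D", function(x) x@labels)

#' @describeIn TractSet number of tracts
#' @param x,object a \code{TractSet}
#' @export
setMethod("nTracts", "TractSet", function(x) length(x@tracts))

#' @describeIn TractSet per-tract status vector
#' @export
setMethod("tractStatus", "TractSet",
          function(x) vapply(x@tracts, `[[`, character(1), "status"))

#' Extract the tracts accepted by filtering
#'
#' @param x a \linkS4class{TractSet}
#' @return a TractSet containing only tracts with status "extrapolated"
#' @export
acceptedTracts <- function(x) {
  stopifnot(is(x, "TractSet"))
  new("TractSet", tracts = x@tracts[tractStatus(x) == "extrapolated"],
      stepMm = x@stepMm, seed = x@seed, nSeeded = x@nSeeded)
}

#' Per-tract lengths
#'
#' @param x a \linkS4class{TractSet}
#' @param which "raw" or "extrapolated"
#' @return numeric vector of lengths in mm (NA where not available)
#' @export
tractLengths <- function(x, which = c("raw", "extrapolated")) {
  which <- match.arg(which)
  fld <- if (which == "raw") "raw_length" else "extrapolated_length"
  vapply(x@tracts, function(t) as.numeric(t[[fld]] %||% NA_real_), numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn ThicknessMap the sample table
#' @param x,object a \code{ThicknessMap}
#' @export
setMethod("thicknessSamples", "ThicknessMap", function(x) x@samples)

#' @describeIn ThicknessMap global mean thickness (mm)
#' @export
setMethod("meanThickness", "ThicknessMap",
          function(x) mean(x@samples$thickness_mm))

#' Standard deviation of thickness samples (mm)
#' @param x a \linkS4class{ThicknessMap}
#' @return numeric scalar
#' @export
sdThickness <- function(x) {
  stopifnot(is(x, "ThicknessMap"))
  stats::sd(x@samples$thickness_mm)
}

#' Per-slice mean thickness (mm)
#' @param x a \linkS4class{ThicknessMap}
#' @return data.frame with columns slice, mean_mm, n
#' @export
perSliceMean <- function(x) {
  stopifnot(is(x, "ThicknessMap"))
  s <- x@samples
  agg <- stats::aggregate(s$thickness_mm, by = list(slice = s$slice),
                          FUN = mean)
  n <- as.vector(table(s$slice)[as.character(agg$slice)])
  data.frame(slice = agg$slice, mean_mm = agg$x, n = n)
}

setMethod("show", "LabeledMask3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabeledMask3D: %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  if (length(object@labels))
    cat("  labels:", paste(sprintf("%s=%s", names(object@labels),
                                   object@labels), collapse = ", "), "\n")
  else cat("  labels: (none)\n")
})

setMethod("show", "DWIStack", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DWIStack: %d x %d x %d voxels, %d volumes (%d with b = 0)\n",
              d[1], d[2], d[3], d[4], sum(object@bValues == 0)))
  cat(sprintf("  b-values: %s s/mm^2\n",
              paste(unique(object@bValues), collapse = ", ")))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("TensorField: %d x %d x %d voxels, %d valid\n",
              d[1], d[2], d[3], sum(object@valid)))
})

setMethod("show", "TractSet", function(object) {
  st <- tractStatus(object)
  cat(sprintf("TractSet: %d tracts (%d raw, %d extrapolated, %d rejected)\n",
              length(st), sum(st == "raw"), sum(st == "extrapolated"),
              sum(st == "rejected")))
  if (length(st)) {
    rl <- tractLengths(object, "raw")
    cat(sprintf("  raw length: %.1f-%.1f mm (median %.1f)\n",
                min(rl), max(rl), stats::median(rl)))
  }
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap: %d samples over %d slices\n",
              nrow(object@samples), length(unique(object@samples$slice))))
  if (nrow(object@samples))
    cat(sprintf("  mean %.3f mm, sd %.3f mm\n",
                meanThickness(object), sdThickness(object)))
})

setMethod("show", "ThicknessShift", function(object) {
  cat(sprintf("ThicknessShift: mean %+.2f%%, median %+.2f%%\n",
              object@meanShiftPct, object@medianShiftPct))
})

setMethod("show", "VolumeReport", function(object) {
  cat(sprintf("VolumeReport: %d labels, %d compartments\n",
              nrow(object@labels), nrow(object@compartments)))
})

setMethod("show", "ArchitectureReport", function(object) {
  cat(sprintf("ArchitectureReport: %s\n", object@muscle))
  cat(sprintf("  volume %.2f cm^3, PCSA %.2f cm^2\n",
              object@volumeCm3, object@pcsaCm2))
  cat(sprintf("  fascicle length %.2f +/- %.2f cm, pennation %.1f +/- %.1f deg\n",
              object@meanFascicleLengthCm, object@sdFascicleLengthCm,
              object@meanPennationDeg, object@sdPennationDeg))
  cat(sprintf("  tracts: %s\n",
              paste(sprintf("%s=%d", names(object@counts), object@counts),
                    collapse = ", ")))
})
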