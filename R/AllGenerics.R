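#' @include AllClasses.R
NULL

#' Voxel spacing of a gridded object
#'
#' Returns the voxel edge lengths in mm, ordered (dx, dy, dz).
#'
#' @param x a gridded object (\linkS4class{LabeledMask3D},
#'   \linkS4class{DWIStack}, \linkS4class{TensorField}, ...)
#' @return numeric vector of length 3, mm
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Voxel data of a gridded object
#'
#' @param x a gridded object
#' @return the underlying array
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Label dictionary of a labeled mask
#'
#' @param x a \linkS4class{LabeledMask3D}
#' @return named character vector: names are integer label ids (as strings),
#'   values are label names
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' Number of tracts in a tract set
#' @param x a \linkS4class{TractSet}
#' @return integer
#' @export
setGeneric("nTracts", function(x) standardGeneric("nTracts"))

#' Per-tract status
#' @param x a \linkS4class{TractSet}
#' @return character vector ("raw", "extrapolated", "rejected")
#' @export
setGeneric("tractStatus", function(x) standardGeneric("tractStatus"))

#' Thickness samples of a thickness map
#' @param x a \linkS4class{ThicknessMap}
#' @return data.frame with columns slice, x_mm, y_mm, thickness_mm
#' @export
setGeneric("thicknessSamples", function(x) standardGeneric("thicknessSamples"))

#' Global mean of a thickness map (mm)
#' @param x a \linkS4class{ThicknessMap}
#' @return numeric scalar, mm
#' @export
setGeneric("meanThickness", function(x) standardGeneric("meanThickness"))
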