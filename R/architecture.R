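#' @include AllClasses.R utils.R
NULL

#' Line of action of a muscle from its segmented voxels
#'
#' The principal axis of the voxel-coordinate cloud: the eigenvector of the
#' covariance of foreground voxel world coordinates with the largest
#' eigenvalue, sign-oriented to positive z (falling back to the first
#' nonzero component for axes perpendicular to z).
#'
#' @param mask a \linkS4class{LabeledMask3D}
#' @param label label name or id (default: the first label)
#' @return unit 3-vector
#' @export
lineOfAction <- function(mask, label = NULL) {
  stopifnot(is(mask, "LabeledMask3D"))
  id <- if (is.null(label)) as.integer(names(mask@labels)[1])
        else resolveLabel(mask, label)
  idx <- which(mask@voxels == id)
  if (length(idx) < 4)
    stop("label region too small for a 3-D principal axis", call. = FALSE)
  ijk <- arrayInd(idx, dim(mask@voxels))
  xyz <- sweep(ijk - 0.5, 2, mask@spacing, `*`)
  cv <- stats::cov(xyz)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[3] <= 1e-9 * e$values[1])
    stop("degenerate (planar or smaller) label region", call. = FALSE)
  v <- e$vectors[, 1]
  if (abs(v[3]) > 1e-12) {
    if (v[3] < 0) v <- -v
  } else {
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) v <- -v
  }
  v / sqrt(sum(v^2))
}

#' Muscle architecture metrics from accepted fascicle tracts
#'
#' Fascicle length is the polyline arclength of each accepted (extrapolated)
#' tract. The fascicle vector is the unit chord from first to last point;
#' pennation is \eqn{\arccos(|v_f \cdot v_{loa}|)} in degrees (the absolute
#' value folds the arbitrary tract orientation into [0, 90]). PCSA is the
#' muscle volume divided by the mean fascicle length, so
#' PCSA x mean fascicle length reproduces the volume exactly.
#'
#' @param tractSet a filtered \linkS4class{TractSet}
#'   (\code{\link{filterTracts}}); only tracts with status "extrapolated"
#'   contribute
#' @param loa unit line-of-action vector (\code{\link{lineOfAction}})
#' @param muscleVolumeCm3 muscle volume (cm^3, > 0)
#' @param muscle muscle name for the report
#' @return an \linkS4class{ArchitectureReport}
#' @examples
#' tr <- list(points = rbind(c(0, 0, 0), c(0, 0, 100)), raw_length = 100,
#'            extrapolated_length = 100, status = "extrapolated",
#'            reason = NA_character_)
#' ts <- new("TractSet", tracts = list(tr), stepMm = 1, seed = NA_integer_,
#'           nSeeded = 1L)
#' architectureMetrics(ts, c(0, 0, 1), 100)  # PCSA 10 cm^2, pennation 0
#' @export
architectureMetrics <- function(tractSet, loa, muscleVolumeCm3,
                                muscle = "muscle") {
  stopifnot(is(tractSet, "TractSet"))
  if (abs(sqrt(sum(loa^2)) - 1) > 1e-9)
    stop("loa must be unit norm", call. = FALSE)
  if (muscleVolumeCm3 <= 0) stop("muscle volume must be > 0", call. = FALSE)
  acc <- tractSet@tracts[tractStatus(tractSet) == "extrapolated"]
  if (!length(acc))
    stop("no accepted tracts; inspect tracking/extrapolation diagnostics ",
         "(tractCounts) before computing architecture", call. = FALSE)
  lenCm <- vapply(acc, function(t) polylineLength(t$points), numeric(1)) / 10
  penDeg <- vapply(acc, function(t) {
    chord <- t$points[nrow(t$points), ] - t$points[1, ]
    chord <- chord / sqrt(sum(chord^2))
    acos(pmin(1, abs(sum(chord * loa)))) * 180 / pi
  }, numeric(1))
  meanLen <- mean(lenCm)
  new("ArchitectureReport", muscle = muscle, volumeCm3 = muscleVolumeCm3,
      meanFascicleLengthCm = meanLen,
      sdFascicleLengthCm = if (length(lenCm) > 1) stats::sd(lenCm) else 0,
      meanPennationDeg = mean(penDeg),
      sdPennationDeg = if (length(penDeg) > 1) stats::sd(penDeg) else 0,
      pcsaCm2 = muscleVolumeCm3 / meanLen,
      lineOfAction = loa / sqrt(sum(loa^2)),
      counts = tractCounts(tractSet))
}

#' Full DTI muscle-architecture stage on one muscle
#'
#' Convenience wrapper: tensor fit, tracking, extrapolation, inclusion
#' filtering and architecture metrics in one call.
#'
#' @param dwi a \linkS4class{DWIStack}
#' @param mask muscle \linkS4class{LabeledMask3D}
#' @param label muscle label (default first)
#' @param params \code{\link{trackingParams}}
#' @param seed tracking seed
#' @param polyOrder extrapolation polynomial order
#' @return list: \code{report} (\linkS4class{ArchitectureReport}),
#'   \code{tracts} (filtered \linkS4class{TractSet}), \code{tensors},
#'   \code{fa}, \code{md}
#' @export
muscleArchitecture <- function(dwi, mask, label = NULL,
                               params = trackingParams(), seed = NULL,
                               polyOrder = 3) {
  field <- fitTensors(dwi, mask)
  maps <- faMD(field)
  tracts <- trackFibers(field, mask, params, seed)
  tracts <- extrapolateTracts(tracts, mask, polyOrder)
  tracts <- filterTracts(tracts, lengthRange = c(params$minLengthMm,
                                                 params$maxLengthMm))
  id <- if (is.null(label)) as.integer(names(mask@labels)[1])
        else resolveLabel(mask, label)
  vol <- sum(mask@voxels == id) * prod(mask@spacing) / 1000
  loa <- lineOfAction(mask, label)
  nm <- mask@labels[[as.character(id)]]
  list(report = architectureMetrics(tracts, loa, vol, muscle = nm),
       tracts = tracts, tensors = field, fa = maps$fa, md = maps$md)
}
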