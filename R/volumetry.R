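#' @include AllClasses.R utils.R
NULL

#' Volume of one label in a mask (cm^3)
#'
#' Sums the voxels carrying the label over all slices and multiplies by the
#' voxel volume, i.e. segmentation-based volumetry on the acquisition grid.
#'
#' @param mask a \linkS4class{LabeledMask3D}
#' @param label label name or integer id; must exist in the label dictionary
#' @return volume in cm^3 (0 for a present-but-empty label)
#' @examples
#' v <- array(0L, c(10, 10, 10)); v[1:10, 1:10, 1:10] <- 1L
#' labelVolume(LabeledMask3D(v, c(1, 1, 1), c(`1` = "muscle")), "muscle")
#' @export
labelVolume <- function(mask, label) {
  stopifnot(is(mask, "LabeledMask3D"))
  id <- resolveLabel(mask, label)
  sum(mask@voxels == id) * prod(mask@spacing) / 1000
}

#' Signed percent change between a pre and a post value
#'
#' 100 (post - pre) / pre; negative values are losses. The table renderer
#' (\code{\link{volumeReport}}) also carries the unsigned "loss of x%" /
#' "gain of x%" phrasing used in longitudinal reports.
#'
#' @param pre baseline value (> 0)
#' @param post follow-up value
#' @return percent change (signed)
#' @examples
#' percentChange(67, 65.51)   # -2.22: a 2.22% loss
#' @export
percentChange <- function(pre, post) {
  if (any(pre <= 0)) stop("pre value must be > 0", call. = FALSE)
  100 * (post - pre) / pre
}

renderChange <- function(pct) {
  ifelse(is.na(pct), NA_character_,
         ifelse(pct < 0, sprintf("loss of %.2f%%", -pct),
                ifelse(pct > 0, sprintf("gain of %.2f%%", pct), "no change")))
}

#' Per-label volume report for one or two timepoints
#'
#' @param maskPre baseline \linkS4class{LabeledMask3D}
#' @param maskPost optional follow-up mask (same label dictionary); when
#'   given, percent changes are computed per label
#' @return a \linkS4class{VolumeReport} (compartment table empty; see
#'   \code{\link{groupCompartments}})
#' @export
volumeReport <- function(maskPre, maskPost = NULL) {
  stopifnot(is(maskPre, "LabeledMask3D"))
  nms <- unname(maskPre@labels)
  pre <- vapply(nms, function(n) labelVolume(maskPre, n), numeric(1))
  if (!is.null(maskPost)) {
    stopifnot(is(maskPost, "LabeledMask3D"))
    post <- vapply(nms, function(n) labelVolume(maskPost, n), numeric(1))
    pct <- ifelse(pre > 0, 100 * (post - pre) / pre, NA_real_)
  } else {
    post <- rep(NA_real_, length(nms))
    pct <- rep(NA_real_, length(nms))
  }
  lab <- data.frame(name = nms, pre_cm3 = unname(pre), post_cm3 = unname(post),
                    percent_change = unname(pct),
                    change_label = renderChange(unname(pct)),
                    stringsAsFactors = FALSE)
  new("VolumeReport", labels = lab,
      compartments = lab[0, , drop = FALSE])
}

#' Default anatomical compartment groupings of the calf and thigh
#'
#' Calf: superficial posterior (medial/lateral gastrocnemius, soleus),
#' anterior (tibialis anterior, digital extensors, popliteus), deep posterior
#' (tibialis posterior), lateral (peroneals). Thigh: quadriceps/anterior,
#' hamstrings/posterior, medial (adductors, gracilis).
#'
#' @return named list: compartment name -> character vector of member labels
#' @export
defaultCompartments <- function() {
  list(
    calf_superficial_posterior = c("medial_gastrocnemius",
                                   "lateral_gastrocnemius", "soleus"),
    calf_anterior = c("tibialis_anterior", "extensor_digitorum_longus",
                      "extensor_hallucis_longus", "popliteus"),
    calf_deep_posterior = "tibialis_posterior",
    calf_lateral = "peroneals",
    thigh_quadriceps_anterior = c("rectus_femoris", "vastus_medialis",
                                  "vastus_lateralis", "vastus_intermedius"),
    thigh_hamstrings_posterior = c("biceps_femoris_short_head",
                                   "biceps_femoris_long_head",
                                   "semitendinosus", "semimembranosus"),
    thigh_medial = c("adductors", "gracilis"))
}

#' Group a per-label volume report into anatomical compartments
#'
#' Compartment volumes are exact sums of member-label volumes; percent change
#' is recomputed from the summed volumes (sum-then-ratio), never averaged
#' from member percentages.
#'
#' @param report a \linkS4class{VolumeReport}
#' @param compartmentMap named list mapping compartment names to member label
#'   names (see \code{\link{defaultCompartments}}); compartments with no
#'   member present in the report are dropped, but a partially present
#'   compartment is an error
#' @return the report with its compartment table filled in
#' @export
groupCompartments <- function(report, compartmentMap = defaultCompartments()) {
  stopifnot(is(report, "VolumeReport"))
  lab <- report@labels
  rows <- lapply(names(compartmentMap), function(cn) {
    members <- compartmentMap[[cn]]
    if (!length(members)) stop("compartment '", cn, "' has no members",
                               call. = FALSE)
    present <- members %in% lab$name
    if (!any(present)) return(NULL)
    if (!all(present))
      stop("compartment '", cn, "' is missing member labels: ",
           paste(members[!present], collapse = ", "), call. = FALSE)
    sel <- lab[match(members, lab$name), ]
    pre <- sum(sel$pre_cm3)
    post <- if (all(!is.na(sel$post_cm3))) sum(sel$post_cm3) else NA_real_
    pct <- if (!is.na(post) && pre > 0) 100 * (post - pre) / pre else NA_real_
    data.frame(name = cn, pre_cm3 = pre, post_cm3 = post,
               percent_change = pct, change_label = renderChange(pct),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) rows <- lab[0, , drop = FALSE]
  new("VolumeReport", labels = lab, compartments = rows)
}

#' Align two mask stacks on a bony-landmark slice and trim to the overlap
#'
#' Shifts the stacks so the landmark slices coincide and trims both to the
#' common z-range; a pure integer slice alignment with no resampling, the
#' programmatic analogue of registering image stacks on a bony landmark.
#'
#' @param maskPre,maskPost \linkS4class{LabeledMask3D} objects sharing the
#'   in-plane grid and spacing
#' @param landmarkPre,landmarkPost slice index of the landmark in each stack
#' @return list with trimmed \code{pre} and \code{post} masks of identical
#'   shape
#' @export
alignStacksByLandmark <- function(maskPre, maskPost, landmarkPre,
                                  landmarkPost) {
  stopifnot(is(maskPre, "LabeledMask3D"), is(maskPost, "LabeledMask3D"))
  d1 <- dim(maskPre@voxels); d2 <- dim(maskPost@voxels)
  if (!isTRUE(all.equal(maskPre@spacing, maskPost@spacing)) ||
      d1[1] != d2[1] || d1[2] != d2[2])
    stop("stacks must share the in-plane grid and spacing ",
         "(full registration is out of scope)", call. = FALSE)
  if (landmarkPre < 1 || landmarkPre > d1[3] ||
      landmarkPost < 1 || landmarkPost > d2[3])
    stop("landmark slice index out of range", call. = FALSE)
  off <- landmarkPost - landmarkPre      # pre slice i <-> post slice i + off
  lo <- max(1L, 1L - off)
  hi <- min(d1[3], d2[3] - off)
  if (lo > hi) stop("no overlapping slices after landmark alignment",
                    call. = FALSE)
  idx <- lo:hi
  list(pre = LabeledMask3D(maskPre@voxels[, , idx, drop = FALSE],
                           maskPre@spacing, maskPre@labels),
       post = LabeledMask3D(maskPost@voxels[, , idx + off, drop = FALSE],
                            maskPost@spacing, maskPost@labels))
}
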