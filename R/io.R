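#' @include AllClasses.R utils.R
NULL

#' Write a labeled mask as NIfTI with a JSON label sidecar
#'
#' @param mask a \linkS4class{LabeledMask3D}
#' @param path output NIfTI path (.nii or .nii.gz)
#' @param labelsPath optional JSON sidecar path for the label dictionary
#'   (default: path with extension replaced by .labels.json)
#' @return invisibly, the NIfTI path
#' @export
writeMaskNifti <- function(mask, path, labelsPath = NULL) {
  stopifnot(is(mask, "LabeledMask3D"))
  img <- RNifti::asNifti(mask@voxels)
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path)
  if (is.null(labelsPath))
    labelsPath <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(as.list(mask@labels), labelsPath, auto_unbox = TRUE)
  invisible(path)
}

#' Read a labeled mask from NIfTI
#'
#' The label dictionary comes from a sidecar: either a JSON map (id -> name)
#' or an ITK-SNAP label description text file. Without a sidecar, labels are
#' named "label<k>".
#'
#' @param path NIfTI path
#' @param labelsPath optional sidecar path (JSON or ITK-SNAP .txt); when
#'   NULL, a .labels.json next to the image is used if present
#' @return a \linkS4class{LabeledMask3D}
#' @export
readMaskNifti <- function(path, labelsPath = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (is.null(labelsPath)) {
    cand <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
    if (file.exists(cand)) labelsPath <- cand
  }
  labels <- if (!is.null(labelsPath)) readLabelTable(labelsPath) else NULL
  LabeledMask3D(array(as.integer(round(img)), dim(img)), sp, labels)
}

#' Read a label dictionary (JSON map or ITK-SNAP label descriptions)
#'
#' ITK-SNAP label description files have whitespace-separated columns
#' IDX R G B A VIS MSH "NAME" with '#' comments; the JSON form is a plain
#' object mapping ids to names.
#'
#' @param path sidecar path
#' @return named character vector (names = ids)
#' @export
readLabelTable <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^\\s*\\{", first))) {
    lst <- jsonlite::read_json(path)
    return(stats::setNames(vapply(lst, as.character, character(1)),
                           names(lst)))
  }
  tb <- utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tb) < 8) stop("unrecognized label description format",
                         call. = FALSE)
  keep <- tb[[1]] != 0
  stats::setNames(as.character(tb[[8]][keep]), as.character(tb[[1]][keep]))
}

#' Write a scalar image as NIfTI
#' @param image 3-D array
#' @param spacing voxel spacing (mm)
#' @param path output path
#' @return invisibly, the path
#' @export
writeImageNifti <- function(image, spacing, path) {
  img <- RNifti::asNifti(image)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar image from NIfTI
#' @param path NIfTI path
#' @return list with \code{data} (array) and \code{spacing} (mm)
#' @export
readImageNifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Write a DWI stack as NIfTI plus FSL-style bval/bvec text files
#'
#' @param dwi a \linkS4class{DWIStack}
#' @param prefix output path prefix; writes prefix.nii, prefix.bval,
#'   prefix.bvec
#' @return invisibly, the prefix
#' @export
writeDWI <- function(dwi, prefix) {
  stopifnot(is(dwi, "DWIStack"))
  img <- RNifti::asNifti(dwi@signal)
  RNifti::pixdim(img) <- c(dwi@spacing, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii"))
  writeLines(paste(format(dwi@bValues, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(dwi@gradients), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read a DWI stack from NIfTI plus FSL bval/bvec files
#'
#' @param niiPath 4-D NIfTI path
#' @param bvalPath one row of b-values
#' @param bvecPath three rows (x, y, z) of gradient components
#' @return a \linkS4class{DWIStack}
#' @export
readDWI <- function(niiPath, bvalPath, bvecPath) {
  img <- RNifti::readNifti(niiPath)
  bvals <- scan(bvalPath, quiet = TRUE)
  bvec <- matrix(scan(bvecPath, quiet = TRUE), nrow = 3, byrow = TRUE)
  new("DWIStack", signal = array(as.numeric(img), dim(img)),
      gradients = t(bvec), bValues = bvals,
      spacing = RNifti::pixdim(img)[1:3])
}

#' Write a tract set as a TSV polyline table
#'
#' Columns: tract, point, x_mm, y_mm, z_mm, status.
#'
#' @param tractSet a \linkS4class{TractSet}
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeTractsTSV <- function(tractSet, path) {
  stopifnot(is(tractSet, "TractSet"))
  rows <- lapply(seq_along(tractSet@tracts), function(i) {
    t <- tractSet@tracts[[i]]
    data.frame(tract = i, point = seq_len(nrow(t$points)),
               x_mm = t$points[, 1], y_mm = t$points[, 2],
               z_mm = t$points[, 3], status = t$status)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a volume report as TSV (and optionally JSON)
#'
#' @param report a \linkS4class{VolumeReport}
#' @param path TSV path for the per-label table
#' @param jsonPath optional JSON path carrying both tables
#' @return invisibly, the TSV path
#' @export
writeVolumeReport <- function(report, path, jsonPath = NULL) {
  stopifnot(is(report, "VolumeReport"))
  utils::write.table(report@labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(labels = report@labels,
                              compartments = report@compartments),
                         jsonPath, dataframe = "rows", na = "null")
  invisible(path)
}

#' Write thickness samples as TSV
#'
#' @param map a \linkS4class{ThicknessMap}
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeThicknessTSV <- function(map, path) {
  stopifnot(is(map, "ThicknessMap"))
  utils::write.table(map@samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
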