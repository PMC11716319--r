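# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# World coordinates (mm) of voxel centers along one axis.
axisCenters <- function(n, d) (seq_len(n) - 0.5) * d

# Voxel index containing world coordinate x along an axis (1-based); may fall
# outside [1, n] for out-of-grid points.
worldToIndex <- function(x, d) floor(x / d) + 1L

# TRUE when world point p (length-3) lies in a foreground voxel of `fore`
# (3-D logical array) with spacing sp.
pointInMask <- function(p, fore, sp, dims) {
  i <- floor(p[1] / sp[1]) + 1
  j <- floor(p[2] / sp[2]) + 1
  k <- floor(p[3] / sp[3]) + 1
  if (i < 1 || j < 1 || k < 1 || i > dims[1] || j > dims[2] || k > dims[3])
    return(FALSE)
  fore[i, j, k]
}

# Polyline arclength (mm) of an m x 3 matrix of points.
polylineLength <- function(pts) {
  if (is.null(dim(pts)) || nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

# Resolve a label given by name or id against a mask's dictionary; returns the
# integer id or stops with the offending label.
resolveLabel <- function(mask, label) {
  labs <- mask@labels
  if (is.character(label)) {
    hit <- names(labs)[labs == label]
    if (!length(hit)) stop("unknown label: '", label, "'", call. = FALSE)
    return(as.integer(hit[1]))
  }
  id <- as.integer(label)
  if (!as.character(id) %in% names(labs))
    stop("unknown label id: ", id, call. = FALSE)
  id
}
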