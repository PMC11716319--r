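# Binary 2-D skeletonization (Zhang-Suen thinning), spur pruning, and
# chain-code arclength. The centerline is the backbone of the thin-sheet
# thickness estimator, so these primitives are implemented in-package.

# out[i, j] = m[i + di, j + dj], zero-padded at the borders.
shiftMat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(si) && length(sj))
    out[si - di, sj - dj] <- m[si, sj]
  out
}

# 8-neighborhood in the cyclic order N, NE, E, SE, S, SW, W, NW.
neighborStack <- function(m) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(offs, function(o) shiftMat(m, o[1], o[2]))
}

# Guo-Hall two-subiteration thinning of a 0/1 matrix. Connectivity (C == 1)
# and endpoint conditions preserve topology, and the result is a minimal
# 8-connected chain without the staircase artifacts of simpler schemes, so an
# already one-pixel-wide structure is a fixed point and chain-code arclengths
# are well defined.
thinBinary <- function(m) {
  m <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  repeat {
    changed <- FALSE
    for (pass in 0:1) {
      p2 <- shiftMat(m, -1, 0);  p3 <- shiftMat(m, -1, 1)
      p4 <- shiftMat(m, 0, 1);   p5 <- shiftMat(m, 1, 1)
      p6 <- shiftMat(m, 1, 0);   p7 <- shiftMat(m, 1, -1)
      p8 <- shiftMat(m, 0, -1);  p9 <- shiftMat(m, -1, -1)
      C <- (1L - p2) * pmax(p3, p4) + (1L - p4) * pmax(p5, p6) +
        (1L - p6) * pmax(p7, p8) + (1L - p8) * pmax(p9, p2)
      N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      N <- pmin(N1, N2)
      mm <- if (pass == 0) pmax(p6, p7, 1L - p9) * p8
            else pmax(p2, p3, 1L - p5) * p4
      del <- m == 1L & C == 1L & N >= 2L & N <= 3L & mm == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Remove spur branches by iteratively deleting endpoints (pixels with at most
# one 8-neighbor) pruneLen times. Closed loops have no endpoints and survive.
pruneSpurs <- function(skel, pruneLen = 5L) {
  for (i in seq_len(pruneLen)) {
    b <- Reduce(`+`, neighborStack(skel))
    ends <- skel == 1L & b <= 1L
    if (!any(ends)) break
    skel[ends] <- 0L
  }
  skel
}

# Chain arclength of a skeleton: straight (4-adjacent) and diagonal
# (8-only-adjacent) steps, each counted once. A diagonal step is skipped when
# a skeleton pixel 4-adjacent to both of its endpoints exists (the chain runs
# through that pixel, and the diagonal is a redundant chord). Default weights
# are the Kulpa-calibrated step lengths, which remove the ~5% overestimate of
# naive (1, sqrt(2)) chain codes on smooth curves; weights = "chain" gives
# the naive code.
chainArclength <- function(skel, pitch, weights = c("kulpa", "chain")) {
  weights <- match.arg(weights)
  w <- if (weights == "kulpa") c(0.948, 1.340) else c(1, sqrt(2))
  s <- skel == 1L
  e <- shiftMat(skel, 1, 0) == 1L   # south neighbor
  se <- shiftMat(skel, 0, 1) == 1L  # east neighbor
  nStraight <- sum(s & e) + sum(s & se)
  d1 <- s & shiftMat(skel, 1, 1) == 1L &
    !(shiftMat(skel, 1, 0) == 1L | shiftMat(skel, 0, 1) == 1L)
  d2 <- s & shiftMat(skel, 1, -1) == 1L &
    !(shiftMat(skel, 1, 0) == 1L | shiftMat(skel, 0, -1) == 1L)
  nDiag <- sum(d1) + sum(d2)
  (w[1] * nStraight + w[2] * nDiag) * pitch
}

#' Extract the centerline (middle line) of a thin band in one slice
#'
#' Skeletonizes the binary band to a one-pixel-wide topological centerline
#' (Guo-Hall thinning), prunes rasterization-induced spur branches, and
#' measures the centerline arclength from the chain of inter-pixel steps.
#'
#' @param binarySlice 2-D matrix; nonzero = band
#' @param pitch in-plane pixel pitch (mm); pixels must be square
#' @param pruneLen spur-pruning length in pixels (default 5, enough to
#'   suppress rasterization branches without eroding the main loop)
#' @param weights step-length calibration: "kulpa" (default, corrects the
#'   systematic chain-code overestimate on smooth curves) or "chain"
#'   (1 and sqrt(2) times the pitch)
#' @return list: \code{pixels} (n x 2 matrix of row/col indices),
#'   \code{arclengthMm}, \code{empty} flag, \code{thin} flag (TRUE when the
#'   band is thinner than ~2 pixels somewhere along the centerline)
#' @export
sliceCenterline <- function(binarySlice, pitch, pruneLen = 5L,
                            weights = c("kulpa", "chain")) {
  weights <- match.arg(weights)
  stopifnot(pitch > 0)
  m <- matrix(as.integer(binarySlice != 0), nrow(binarySlice),
              ncol(binarySlice))
  if (!any(m == 1L))
    return(list(pixels = matrix(numeric(0), 0, 2), arclengthMm = 0,
                empty = TRUE, thin = FALSE))
  skel <- pruneSpurs(thinBinary(m), as.integer(pruneLen))
  if (!any(skel == 1L))      # band so small that pruning consumed it
    return(list(pixels = matrix(numeric(0), 0, 2), arclengthMm = 0,
                empty = TRUE, thin = TRUE))
  d <- EBImage::distmap(m)
  px <- which(skel == 1L, arr.ind = TRUE)
  thin <- any(d[px] <= 1)
  list(pixels = px, arclengthMm = chainArclength(skel, pitch, weights),
       empty = FALSE, thin = thin)
}
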