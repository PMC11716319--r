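#' @include AllClasses.R utils.R
NULL

# Closed-form eigenvalues of symmetric 3x3 tensors, vectorized over voxels.
# comp is an n x 6 matrix (xx, yy, zz, xy, xz, yz); returns n x 3 descending.
# Trigonometric (Cardano) solution on the deviatoric part; exact for the
# symmetric case and orders of magnitude faster than calling eigen() per
# voxel.
symEigenvalues <- function(comp) {
  a11 <- comp[, 1]; a22 <- comp[, 2]; a33 <- comp[, 3]
  a12 <- comp[, 4]; a13 <- comp[, 5]; a23 <- comp[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

# Principal (largest-eigenvalue) unit eigenvectors, vectorized. Uses the
# spectral projector (A - l2 I)(A - l3 I), whose columns are all parallel to
# e1; the largest column is taken. Near-degenerate voxels (l1 ~ l2) fall back
# to eigen(). Sign is arbitrary; callers orient as needed.
symPrincipalEigenvector <- function(comp, ev = symEigenvalues(comp)) {
  a11 <- comp[, 1]; a22 <- comp[, 2]; a33 <- comp[, 3]
  a12 <- comp[, 4]; a13 <- comp[, 5]; a23 <- comp[, 6]
  l2 <- ev[, 2]; l3 <- ev[, 3]
  # M = A^2 - (l2 + l3) A + l2 l3 I, computed columnwise
  s <- l2 + l3; pr <- l2 * l3
  m11 <- a11^2 + a12^2 + a13^2 - s * a11 + pr
  m21 <- a12 * (a11 + a22) + a13 * a23 - s * a12
  m31 <- a13 * (a11 + a33) + a12 * a23 - s * a13
  m12 <- m21
  m22 <- a12^2 + a22^2 + a23^2 - s * a22 + pr
  m32 <- a23 * (a22 + a33) + a12 * a13 - s * a23
  m13 <- m31; m23 <- m32
  m33 <- a13^2 + a23^2 + a33^2 - s * a33 + pr
  n1 <- m11^2 + m21^2 + m31^2
  n2 <- m12^2 + m22^2 + m32^2
  n3 <- m13^2 + m23^2 + m33^2
  best <- max.col(cbind(n1, n2, n3), ties.method = "first")
  vx <- ifelse(best == 1, m11, ifelse(best == 2, m12, m13))
  vy <- ifelse(best == 1, m21, ifelse(best == 2, m22, m23))
  vz <- ifelse(best == 1, m31, ifelse(best == 2, m32, m33))
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  scaleRef <- pmax(abs(ev[, 1]), abs(ev[, 3]), 1e-300)^2
  bad <- !is.finite(nrm) | nrm <= 1e-8 * scaleRef
  if (any(bad)) {
    for (i in which(bad)) {
      A <- matrix(c(a11[i], a12[i], a13[i],
                    a12[i], a22[i], a23[i],
                    a13[i], a23[i], a33[i]), 3, 3)
      e <- eigen(A, symmetric = TRUE)
      vx[i] <- e$vectors[1, 1]; vy[i] <- e$vectors[2, 1]
      vz[i] <- e$vectors[3, 1]
      nrm[i] <- 1
    }
  }
  cbind(vx / nrm, vy / nrm, vz / nrm)
}

#' Reconstruct diffusion tensors from a DWI stack by log-linear least squares
#'
#' Per masked voxel solves \eqn{\ln S(g) = \ln S_0 - b\, g^T D g} for the six
#' unique tensor components and \eqn{\ln S_0} by ordinary least squares. The
#' design matrix is shared by all voxels, so the fit is a single matrix
#' product. Voxels with any non-positive signal are flagged invalid and not
#' fitted.
#'
#' @param dwi a \linkS4class{DWIStack} with at least 7 volumes (6 directions
#'   plus one b = 0 reference)
#' @param mask optional \linkS4class{LabeledMask3D} or logical array limiting
#'   the fit; default all voxels
#' @return a \linkS4class{TensorField}
#' @export
fitTensors <- function(dwi, mask = NULL) {
  stopifnot(is(dwi, "DWIStack"))
  d <- dim(dwi@signal)
  if (d[4] < 7)
    stop("need at least 7 volumes (6 directions + b = 0)", call. = FALSE)
  inMask <- if (is.null(mask)) {
    array(TRUE, d[1:3])
  } else if (is(mask, "LabeledMask3D")) {
    mask@voxels != 0L
  } else {
    array(as.logical(mask), d[1:3])
  }
  if (!any(inMask)) stop("mask selects no voxels", call. = FALSE)

  g <- dwi@gradients
  b <- dwi@bValues
  X <- cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3]))
  pinv <- solve(crossprod(X), t(X))          # 7 x nvol

  nvox <- prod(d[1:3])
  S <- matrix(dwi@signal, nvox, d[4])
  idx <- which(as.vector(inMask))
  Sm <- S[idx, , drop = FALSE]
  ok <- rowSums(Sm <= 0) == 0L
  tens <- array(0, c(d[1:3], 6L))
  valid <- array(FALSE, d[1:3])
  if (any(ok)) {
    beta <- pinv %*% t(log(Sm[ok, , drop = FALSE]))   # 7 x nfit
    Tm <- matrix(0, nvox, 6L)
    Tm[idx[ok], ] <- t(beta[2:7, , drop = FALSE])
    tens <- array(Tm, c(d[1:3], 6L))
    valid[idx[ok]] <- TRUE
  }
  new("TensorField", tensors = tens, valid = valid, spacing = dwi@spacing)
}

#' Fractional anisotropy and mean diffusivity maps
#'
#' MD is the eigenvalue mean \eqn{(\lambda_1+\lambda_2+\lambda_3)/3}; FA is
#' \eqn{\sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\mathrm{MD})^2}/\sqrt{\sum_i
#' \lambda_i^2}}, clamped to [0, 1]. Voxels with a negative eigenvalue are
#' flagged invalid (NA in both maps).
#'
#' @param field a \linkS4class{TensorField}
#' @return list with 3-D arrays \code{fa}, \code{md} (NA outside the valid
#'   set) and the updated logical \code{valid} array
#' @examples
#' # a single-voxel field with eigenvalues (1.5, 0.3, 0.3) x 1e-3 mm^2/s
#' tf <- new("TensorField",
#'           tensors = array(c(1.5e-3, 3e-4, 3e-4, 0, 0, 0), c(1, 1, 1, 6)),
#'           valid = array(TRUE, c(1, 1, 1)), spacing = c(1, 1, 1))
#' faMD(tf)$md[1]   # 0.7e-3
#' @export
faMD <- function(field) {
  stopifnot(is(field, "TensorField"))
  d <- dim(field@tensors)[1:3]
  nvox <- prod(d)
  comp <- matrix(field@tensors, nvox, 6L)
  valid <- as.vector(field@valid)
  fa <- md <- rep(NA_real_, nvox)
  if (any(valid)) {
    ev <- symEigenvalues(comp[valid, , drop = FALSE])
    # negative beyond round-off of the closed-form (trigonometric) solution,
    # whose eigenvalue accuracy is of order sqrt(machine eps) relative
    neg <- ev[, 3] < -1e-6 * pmax(abs(ev[, 1]), 1e-300)
    mdv <- rowMeans(ev)
    dev2 <- (ev[, 1] - mdv)^2 + (ev[, 2] - mdv)^2 + (ev[, 3] - mdv)^2
    den <- rowSums(ev^2)
    fav <- sqrt(1.5) * sqrt(dev2) / sqrt(pmax(den, 1e-300))
    fav <- pmin(pmax(fav, 0), 1)
    fav[neg] <- NA_real_
    mdv[neg] <- NA_real_
    fa[valid] <- fav
    md[valid] <- mdv
    valid[valid] <- !neg
  }
  list(fa = array(fa, d), md = array(md, d), valid = array(valid, d))
}
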