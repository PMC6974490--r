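# Exact Euclidean distance transform (squared-distance lower envelope of
# parabolas, composed separably per axis) with physical voxel spacing.
# Used by the lesion geometry module; verified against a brute-force
# all-pairs oracle in the test suite.

# 1D squared-distance transform with sample spacing s.
# f: squared distances so far (Inf where no feature reachable yet).
.dt1d <- function(f, s) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(f)
  x <- (fin - 1) * s
  fv <- f[fin]
  m <- length(fin)
  v <- integer(m); z <- numeric(m + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  if (m > 1L) for (q in 2:m) {
    repeat {
      p <- v[k]
      sInt <- ((fv[q] + x[q]^2) - (fv[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (k > 1L && sInt <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- sInt; z[k + 1L] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    xq <- (q - 1) * s
    while (z[k + 1L] < xq) k <- k + 1L
    p <- v[k]
    out[q] <- (xq - x[p])^2 + fv[p]
  }
  out
}

# squared EDT along one axis of a 3D array
.dtAxis <- function(g, axis, spacing) {
  dm <- dim(g)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  gp <- aperm(g, perm)
  dmp <- dim(gp)
  gp <- matrix(gp, dmp[1L], dmp[2L] * dmp[3L])
  for (j in seq_len(ncol(gp))) gp[, j] <- .dt1d(gp[, j], spacing)
  gp <- array(gp, dmp)
  aperm(gp, order(perm))
}

#' Euclidean distance to the nearest feature voxel
#'
#' Exact Euclidean distance transform: for every voxel, the distance in mm
#' (via the physical voxel spacing) to the nearest TRUE voxel of
#' \code{feature}. Distance is measured between voxel centers; feature
#' voxels get 0. In \code{"2d"} mode distances are computed independently
#' within each axial (third-axis) slice, matching in-plane ROI definitions;
#' slices without any feature voxel get Inf.
#'
#' @param feature 3D logical array.
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param mode \code{"3d"} (default) or \code{"2d"} (in-plane, per axial
#'   slice; requires square in-plane voxels).
#' @return 3D numeric array of distances in mm (Inf where unreachable).
#' @export
distanceToMask <- function(feature, voxelSize, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  stopifnot(is.logical(feature), length(dim(feature)) == 3L)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (mode == "2d" && abs(voxelSize[1L] - voxelSize[2L]) > 1e-9)
    stop("in-plane 2D distance requires square in-plane voxels")
  g <- array(ifelse(feature, 0, Inf), dim(feature))
  g <- .dtAxis(g, 1L, voxelSize[1L])
  g <- .dtAxis(g, 2L, voxelSize[2L])
  if (mode == "3d") g <- .dtAxis(g, 3L, voxelSize[3L])
  sqrt(g)
}
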