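# Lesion-centric mask algebra: NAWM, perilesional rings, intralesional
# depth layers, resolution-based lesion filtering, and the DVR cutoff mask
# for impaired white matter.

#' Normal-appearing white matter mask
#'
#' NAWM = white matter minus the union of the T1 and T2 lesion masks.
#' Lesion voxels lying outside the white-matter mask are tolerated with a
#' warning (they cannot contribute to NAWM anyway).
#'
#' @param wmMask,t1Lesions,t2Lesions 3D logical arrays on one grid.
#' @return 3D logical NAWM mask.
#' @export
nawmMask <- function(wmMask, t1Lesions, t2Lesions) {
  stopifnot(identical(dim(wmMask), dim(t1Lesions)),
            identical(dim(wmMask), dim(t2Lesions)))
  les <- t1Lesions | t2Lesions
  outside <- sum(les & !wmMask)
  if (outside > 0L)
    warning(outside, " lesion voxel(s) lie outside the white-matter mask")
  wmMask & !les
}

#' Perilesional distance rings around each lesion
#'
#' For every labelled lesion, computes the Euclidean distance from the
#' lesion (distance to the nearest voxel of that lesion) outside the lesion
#' and bins it into rings, by default 0-4 mm (inner) and 4-8 mm (outer).
#' In \code{"2d"} mode (the default, matching in-plane ROI drawing)
#' distances are computed independently per axial slice. Rings are clipped
#' to white matter, exclude the voxels of every lesion, and - conservatively
#' - a voxel claimed by the rings of two different lesions is excluded from
#' both.
#'
#' @param lesionLabels 3D integer array, 0 = background, k = lesion k.
#' @param boundsMm list of \code{c(lower, upper)} distance bands in mm
#'   (half-open: lower < d <= upper).
#' @param mode \code{"2d"} (per axial slice) or \code{"3d"}.
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param wmMask optional 3D logical array to clip rings to white matter.
#' @param excludeOverlap drop voxels within ring range of more than one
#'   lesion (default TRUE).
#' @return A [LayerSet-class] whose masks are named
#'   \code{"lesion<k>.perilesional_inner"} / \code{"...outer"} (band names
#'   \code{ring<j>} beyond two bands).
#' @export
perilesionalRings <- function(lesionLabels, boundsMm = list(c(0, 4), c(4, 8)),
                              mode = c("2d", "3d"), voxelSize,
                              wmMask = NULL, excludeOverlap = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(dim(lesionLabels)) == 3L)
  ks <- sort(setdiff(unique(as.integer(lesionLabels)), 0L))
  if (!length(ks)) stop("no lesion in the labelled mask")
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  maxBound <- max(vapply(boundsMm, max, numeric(1L)))
  anyLesion <- lesionLabels > 0L

  dists <- lapply(ks, function(k)
    distanceToMask(lesionLabels == k, voxelSize, mode))
  names(dists) <- as.character(ks)

  # voxels within ring range of >1 lesion are dropped from every ring
  if (excludeOverlap && length(ks) > 1L) {
    claims <- Reduce(`+`, lapply(dists, function(d) (d > 0 & d <= maxBound) * 1L))
    shared <- claims > 1L
  } else shared <- array(FALSE, dim(lesionLabels))

  bandName <- function(j) {
    if (length(boundsMm) == 2L) c("perilesional_inner", "perilesional_outer")[j]
    else sprintf("ring%d", j)
  }
  maskList <- list()
  rows <- list()
  for (k in ks) {
    d <- dists[[as.character(k)]]
    for (j in seq_along(boundsMm)) {
      b <- boundsMm[[j]]
      ring <- d > b[1L] & d <= b[2L] & !anyLesion & !shared
      if (!is.null(wmMask)) ring <- ring & wmMask
      nm <- sprintf("lesion%d.%s", k, bandName(j))
      maskList[[nm]] <- ring
      rows[[nm]] <- data.frame(lesion = k, layer = bandName(j),
                              n_voxels = sum(ring),
                              volume_mm3 = sum(ring) * prod(voxelSize),
                              lower_mm = b[1L], upper_mm = b[2L])
    }
  }
  new("LayerSet", maskList = maskList,
      catalogue = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      distanceMode = mode, voxelSize = voxelSize)
}

#' Intralesional depth layers
#'
#' Splits each labelled lesion into \code{nLayers} concentric depth bands of
#' equal depth range, where depth is the Euclidean distance from a lesion
#' voxel to the nearest voxel outside that lesion. Layer 1 (the outer layer)
#' is the shallow band at the lesion edge; the last layer is the deep core.
#' The layers partition the lesion exactly. A lesion whose voxels all share
#' one depth (e.g. a single voxel) cannot be split: all its voxels go to the
#' outer layer with a warning.
#'
#' @param lesionLabels 3D integer array, 0 = background, k = lesion k.
#' @param nLayers number of depth bands (default 2).
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param mode \code{"3d"} (default) or \code{"2d"} depth.
#' @return A [LayerSet-class] with masks
#'   \code{"lesion<k>.intralesional_outer"} / \code{"...inner"} for two
#'   layers (\code{layer<j>} otherwise; \code{"...core"} for one).
#' @export
intralesionalLayers <- function(lesionLabels, nLayers = 2L, voxelSize,
                                mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  ks <- sort(setdiff(unique(as.integer(lesionLabels)), 0L))
  if (!length(ks)) stop("no lesion in the labelled mask")
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  layerName <- function(j, n) {
    if (n == 1L) "core"
    else if (n == 2L) c("intralesional_outer", "intralesional_inner")[j]
    else sprintf("layer%d", j)
  }
  maskList <- list()
  rows <- list()
  for (k in ks) {
    les <- lesionLabels == k
    depth <- distanceToMask(!les, voxelSize, mode)   # distance to outside
    dmax <- max(depth[les])
    dmin <- min(depth[les])
    degenerate <- nLayers > 1L && (dmax - dmin) < 1e-9
    if (degenerate)
      warning(sprintf("lesion %d has uniform depth; all voxels assigned to the outer layer", k))
    for (j in seq_len(nLayers)) {
      if (degenerate) {
        layer <- if (j == 1L) les else array(FALSE, dim(les))
        lo <- 0; hi <- dmax
      } else {
        lo <- dmax * (j - 1) / nLayers
        hi <- dmax * j / nLayers
        layer <- les & depth > lo & depth <= hi
      }
      nm <- sprintf("lesion%d.%s", k, layerName(j, nLayers))
      maskList[[nm]] <- layer
      rows[[nm]] <- data.frame(lesion = k, layer = layerName(j, nLayers),
                              n_voxels = sum(layer),
                              volume_mm3 = sum(layer) * prod(voxelSize),
                              lower_mm = lo, upper_mm = hi)
    }
  }
  new("LayerSet", maskList = maskList,
      catalogue = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      distanceMode = mode, voxelSize = voxelSize)
}

#' Drop lesions smaller than the scanner resolution
#'
#' Removes labelled components whose equivalent-sphere diameter
#' \code{(6 V / pi)^(1/3)} is below \code{minDiameterMm}, the standard
#' partial-volume precaution of excluding lesions smaller than the PET
#' spatial resolution (4.3 mm here). Idempotent.
#'
#' @param lesionLabels 3D integer array, 0 = background, k = lesion k.
#' @param minDiameterMm minimum equivalent-sphere diameter in mm
#'   (default 4.3).
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @return The filtered labelled mask (dropped labels zeroed; attributes
#'   \code{retained} and \code{dropped} carry the label vectors).
#' @export
filterSmallLesions <- function(lesionLabels, minDiameterMm = 4.3, voxelSize) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  vvol <- prod(voxelSize)
  ks <- sort(setdiff(unique(as.integer(lesionLabels)), 0L))
  out <- lesionLabels
  dropped <- integer(0)
  for (k in ks) {
    vol <- sum(lesionLabels == k) * vvol
    eqDiam <- (6 * vol / pi)^(1 / 3)
    if (eqDiam < minDiameterMm) {
      out[out == k] <- 0L
      dropped <- c(dropped, k)
    }
  }
  message(sprintf("lesion filter (>= %.1f mm): %d retained, %d dropped",
                  minDiameterMm, length(ks) - length(dropped), length(dropped)))
  attr(out, "retained") <- setdiff(ks, dropped)
  attr(out, "dropped") <- dropped
  out
}

#' Impaired white-matter mask from a DVR cutoff
#'
#' The myelin-integrity cutoff is \code{refMean - 1.96 * refSd}, i.e. the
#' lower tail of the reference (healthy-control white matter) DVR
#' distribution. White-matter voxels with DVR below the cutoff form the
#' impaired mask; the rest of the white matter is "unaffected".
#'
#' @param dvr a [ParametricMap-class] with quantity "DVR" (or 3D array).
#' @param wmMask 3D logical white-matter mask.
#' @param refMean,refSd mean and SD of reference white-matter DVR
#'   (\code{refSd > 0}).
#' @return List with \code{impaired}, \code{unaffected} (3D logical masks
#'   partitioning \code{wmMask}) and \code{cutoff}.
#' @export
impairedWMMask <- function(dvr, wmMask, refMean, refSd) {
  stopifnot(refSd > 0)
  vals <- if (is(dvr, "ParametricMap")) dvr@values else dvr
  cutoff <- refMean - 1.96 * refSd
  impaired <- wmMask & !is.na(vals) & vals < cutoff
  list(impaired = impaired, unaffected = wmMask & !impaired, cutoff = cutoff)
}
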