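#' @import methods
NULL

#' Frame scheme of a dynamic acquisition
#'
#' Per-frame start times and durations (seconds from injection) of a dynamic
#' PET acquisition. Frames are contiguous: each frame starts where the
#' previous one ends, and the first frame starts at injection (t = 0).
#' The frame midpoints, in minutes, are the time axis for all kinetic
#' computations in the package.
#'
#' @slot start_s numeric, per-frame start time in seconds.
#' @slot duration_s numeric, per-frame duration in seconds (all > 0).
#'
#' @seealso [parseFrameScheme()], [frameMid()], [nFrames()]
#' @export
setClass("FrameScheme",
  representation(start_s = "numeric", duration_s = "numeric"),
  validity = function(object) {
    s <- object@start_s; d <- object@duration_s
    if (length(s) != length(d)) return("start_s and duration_s lengths differ")
    if (length(s) == 0L) return("a frame scheme needs at least one frame")
    if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite frame times")
    if (any(d <= 0)) return("all frame durations must be > 0")
    if (abs(s[1L]) > 1e-9) return("first frame must start at t = 0")
    if (length(s) > 1L && any(abs(s[-1L] - (s[-length(s)] + d[-length(d)])) > 1e-6))
      return("frames must be contiguous (start[i+1] = start[i] + duration[i])")
    TRUE
  }
)

#' Dynamic (4D) PET image
#'
#' A 4D array of activity concentration (kBq/ml), one volume per frame of a
#' [FrameScheme-class], with isotropic-or-not voxel size in mm and a flag
#' recording whether radioactive-decay correction has been applied. The flag
#' makes decay correction idempotent: [decayCorrect()] refuses an image that
#' is already corrected.
#'
#' @slot data 4D numeric array, x-y-z-frame, in kBq/ml.
#' @slot scheme the [FrameScheme-class] (4th dimension must match).
#' @slot voxelSize numeric length 3, voxel edge lengths in mm.
#' @slot decayCorrected logical flag.
#'
#' @export
setClass("DynamicImage",
  representation(data = "array", scheme = "FrameScheme",
                 voxelSize = "numeric", decayCorrected = "logical"),
  validity = function(object) {
    dm <- dim(object@data)
    if (length(dm) != 4L) return("data must be a 4D array")
    if (dm[4L] != length(object@scheme@start_s))
      return("4th dimension must equal the number of frames")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive lengths (mm)")
    if (length(object@decayCorrected) != 1L) return("decayCorrected must be a single logical")
    TRUE
  }
)

#' Kinetic class set for supervised cluster analysis
#'
#' The three normalized class time-activity curves used by SVCA: normal
#' grey matter (class 1, the reference-like kinetic), blood pool (class 2,
#' early-peaking), and white matter (class 3). Curves are z-scored per frame
#' and therefore unitless.
#'
#' @slot classes numeric matrix, frames x 3, columns named
#'   \code{c("gm", "blood", "wm")}.
#' @slot nControls integer, number of control scans averaged.
#'
#' @export
setClass("KineticClassSet",
  representation(classes = "matrix", nControls = "integer"),
  validity = function(object) {
    cl <- object@classes
    if (ncol(cl) != 3L) return("exactly three kinetic classes are required")
    if (!identical(colnames(cl), c("gm", "blood", "wm")))
      return('class columns must be named "gm", "blood", "wm"')
    if (any(!is.finite(cl))) return("non-finite class values")
    for (i in 1:2) for (j in (i + 1):3)
      if (max(abs(cl[, i] - cl[, j])) < 1e-12)
        return("kinetic classes must be pairwise distinct")
    if (object@nControls < 1L) return("nControls must be >= 1")
    TRUE
  }
)

#' Reference region extracted by supervised cluster analysis
#'
#' Voxels whose normalized kinetics load almost exclusively on the grey-matter
#' class (class-1 weight ratio above the selection threshold), together with
#' the mean raw (non-normalized) time-activity curve over those voxels and
#' the per-voxel weight-ratio map.
#'
#' @slot mask 3D logical array of selected voxels.
#' @slot refTac numeric, mean raw TAC over the mask (kBq/ml per frame).
#' @slot weightMap 3D numeric array, class-1 weight ratio in [0, 1]
#'   (NA outside the search mask).
#' @slot threshold numeric, the ratio threshold used for selection.
#'
#' @export
setClass("ReferenceRegion",
  representation(mask = "array", refTac = "numeric",
                 weightMap = "array", threshold = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("reference mask is empty")
    if (any(!is.finite(object@refTac))) return("refTac must be finite")
    TRUE
  }
)

#' Parametric map of a derived quantity
#'
#' A 3D map of a voxelwise quantity derived from the dynamic or static data:
#' DVR, SUV, SUVR or CBF. \code{provenance} records the stage and parameters
#' that produced the map (e.g. Logan t*, SUV window, reference description)
#' so every output is re-runnable.
#'
#' @slot values 3D numeric array (NA marks invalid voxels).
#' @slot quantity one of "DVR", "SUV", "SUVR", "CBF".
#' @slot units unit string ("unitless" or "ml/100g/min").
#' @slot provenance named list of stage parameters.
#'
#' @export
setClass("ParametricMap",
  representation(values = "array", quantity = "character",
                 units = "character", provenance = "list"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (!object@quantity %in% c("DVR", "SUV", "SUVR", "CBF"))
      return('quantity must be one of "DVR", "SUV", "SUVR", "CBF"')
    TRUE
  }
)

#' Lesion layer set
#'
#' Labelled masks for lesion-centric geometry: per-lesion cores, intralesional
#' depth layers, and perilesional distance rings, with the distance mode
#' (in-plane 2D or full 3D) and voxel size used. The \code{catalogue} is a
#' tidy data.frame (lesion, layer, voxel count, volume, distance bounds).
#'
#' @slot maskList named list of 3D logical arrays, names
#'   \code{"lesion<k>.<layer>"}.
#' @slot catalogue data.frame with columns lesion, layer, n_voxels,
#'   volume_mm3, lower_mm, upper_mm.
#' @slot distanceMode "2d" or "3d".
#' @slot voxelSize numeric length 3 (mm).
#'
#' @export
setClass("LayerSet",
  representation(maskList = "list", catalogue = "data.frame",
                 distanceMode = "character", voxelSize = "numeric"),
  validity = function(object) {
    if (!object@distanceMode %in% c("2d", "3d")) return('distanceMode must be "2d" or "3d"')
    TRUE
  }
)

#' ROC analysis result
#'
#' Area under the ROC curve for a voxelwise score discriminating lesion from
#' normal-appearing white matter, with the empirical curve, class counts and
#' the DeLong variance estimate of the AUC.
#'
#' @slot auc numeric in [0, 1] (trapezoidal rule; equals the Mann-Whitney
#'   concordance probability with half-credit ties).
#' @slot nPos,nNeg integer class counts.
#' @slot variance DeLong variance estimate of the AUC.
#' @slot curve data.frame with columns fpr, tpr (starts (0,0), ends (1,1)).
#' @slot direction "high" if larger scores indicate the positive class,
#'   "low" otherwise.
#'
#' @export
setClass("RocResult",
  representation(auc = "numeric", nPos = "integer", nNeg = "integer",
                 variance = "numeric", curve = "data.frame",
                 direction = "character"),
  validity = function(object) {
    if (object@auc < -1e-12 || object@auc > 1 + 1e-12) return("auc must lie in [0, 1]")
    cv <- object@curve
    if (!all(c("fpr", "tpr") %in% names(cv))) return("curve needs fpr and tpr columns")
    if (any(diff(cv$fpr) < -1e-12) || any(diff(cv$tpr) < -1e-12))
      return("curve coordinates must be non-decreasing")
    TRUE
  }
)

# ---- show methods ----

setMethod("show", "FrameScheme", function(object) {
  cat(sprintf("FrameScheme: %d frames, %.1f min total (%s)\n",
              nFrames(object), totalDuration(object) / 60,
              formatFrameScheme(object)))
})

setMethod("show", "DynamicImage", function(object) {
  dm <- dim(object@data)
  cat(sprintf("DynamicImage: %dx%dx%d voxels x %d frames, voxel %s mm, %sdecay-corrected\n",
              dm[1], dm[2], dm[3], dm[4],
              paste(format(object@voxelSize, trim = TRUE), collapse = "x"),
              if (object@decayCorrected) "" else "NOT "))
})

setMethod("show", "KineticClassSet", function(object) {
  cat(sprintf("KineticClassSet: 3 classes (gm, blood, wm) over %d frames, from %d control scan(s)\n",
              nrow(object@classes), object@nControls))
})

setMethod("show", "ReferenceRegion", function(object) {
  cat(sprintf("ReferenceRegion: %d voxels (class-1 weight ratio > %.2f)\n",
              sum(object@mask), object@threshold))
})

setMethod("show", "ParametricMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("ParametricMap [%s, %s]: %s voxels, range %.3g..%.3g (%d invalid)\n",
              object@quantity, object@units,
              paste(dim(object@values), collapse = "x"),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(!is.finite(object@values))))
})

setMethod("show", "LayerSet", function(object) {
  cat(sprintf("LayerSet (%s distance): %d masks\n", object@distanceMode,
              length(object@maskList)))
  if (nrow(object@catalogue)) print(utils::head(object@catalogue, 10))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f (n_pos = %d, n_neg = %d, DeLong SE = %.4f)\n",
              object@auc, object@nPos, object@nNeg, sqrt(object@variance)))
})
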