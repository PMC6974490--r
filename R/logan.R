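# Voxelwise Logan graphical reference-tissue analysis: the slope of the
# late linear segment of Y = int(Ct)/Ct versus X = int(Cref)/Ct is the DVR.

#' Voxelwise Logan reference DVR map
#'
#' For every voxel, regresses
#' \deqn{Y(t) = \int_0^t C_t d\tau / C_t(t)}
#' on
#' \deqn{X(t) = [\int_0^t C_{ref} d\tau + C_{ref}(t)/k_2'] / C_t(t)}
#' (the \code{1/k2'} term only when \code{k2prime} is given) over frames with
#' midpoints at or beyond \code{tStarMin}, by unweighted ordinary least
#' squares. Integrals use the trapezoidal rule on frame midpoints anchored at
#' C(0) = 0. The fitted slope is the distribution volume ratio (DVR).
#'
#' Voxels whose activity is not strictly positive over the fit window cannot
#' be transformed; they are set to NA and counted in the provenance.
#'
#' @param img a decay-corrected [DynamicImage-class].
#' @param refTac reference-region TAC (kBq/ml per frame), positive over the
#'   fit window; a [ReferenceRegion-class] is also accepted.
#' @param tStarMin start of the linear segment, minutes (default 30).
#' @param k2prime optional reference efflux rate (1/min) for the intercept
#'   correction term; omitted by default.
#' @param mask optional 3D logical array restricting computation (default:
#'   all voxels).
#' @return A [ParametricMap-class] with quantity "DVR".
#' @export
loganDVR <- function(img, refTac, tStarMin = 30, k2prime = NULL, mask = NULL) {
  stopifnot(is(img, "DynamicImage"))
  if (is(refTac, "ReferenceRegion")) refTac <- refTac@refTac
  sch <- img@scheme
  nf <- nFrames(sch)
  if (length(refTac) != nf) stop("refTac length does not match the scheme")
  mid <- frameMid(sch)
  fit <- which(mid >= tStarMin)
  if (length(fit) < 3L)
    stop("need at least 3 frames with midpoints at or beyond tStarMin")
  if (any(refTac[fit] <= 0)) stop("reference TAC must be positive over the fit window")

  # cumulative trapezoid over (0, mid) with C(0) = 0
  cumTrap <- function(tac) {
    tt <- c(0, mid); cc <- c(0, tac)
    cumsum(c(0, diff(tt) * (cc[-1L] + cc[-length(cc)]) / 2))[-1L]
  }
  intRef <- cumTrap(refTac)

  dm <- dim(img@data)
  nvox <- prod(dm[1:3])
  vidx <- if (is.null(mask)) seq_len(nvox) else which(mask)
  C <- matrix(0, nf, length(vidx))
  for (f in seq_len(nf)) C[f, ] <- img@data[vidx + (f - 1L) * nvox]

  intC <- apply(C, 2L, cumTrap)
  ok <- colSums(C[fit, , drop = FALSE] <= 0) == 0L

  refNum <- intRef[fit]
  if (!is.null(k2prime)) {
    stopifnot(k2prime > 0)
    refNum <- refNum + refTac[fit] / k2prime
  }
  Ct <- C[fit, , drop = FALSE]
  X <- refNum / Ct
  Y <- intC[fit, , drop = FALSE] / Ct
  n <- length(fit)
  sx <- colSums(X); sy <- colSums(Y)
  slope <- (colSums(X * Y) - sx * sy / n) / (colSums(X^2) - sx^2 / n)
  slope[!ok] <- NA_real_

  vals <- array(NA_real_, dm[1:3])
  vals[vidx] <- slope
  nInvalid <- sum(!ok)
  if (nInvalid > 0L)
    message(nInvalid, " voxel(s) with non-positive late activity flagged NA")
  new("ParametricMap", values = vals, quantity = "DVR", units = "unitless",
      provenance = list(stage = "logan", t_star_min = tStarMin,
                        k2prime = if (is.null(k2prime)) NA_real_ else k2prime,
                        n_fit_frames = n, n_invalid = nInvalid))
}

#' ROI summary of a parametric map
#'
#' @param map a [ParametricMap-class] (or bare 3D array).
#' @param roiMask 3D logical array.
#' @return List with \code{mean}, \code{sd}, \code{n} (valid voxels used).
#' @export
roiMean <- function(map, roiMask) {
  vals <- if (is(map, "ParametricMap")) map@values else map
  v <- vals[roiMask]
  v <- v[is.finite(v)]
  if (!length(v)) stop("ROI is empty after intersecting with valid voxels")
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v))
}
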