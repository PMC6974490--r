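# Supervised cluster analysis (SVCA): frame-wise z-normalization, kinetic
# class construction from control scans, and reference-region extraction by
# per-voxel non-negative regression on the class curves.

#' Frame-wise z-normalization of a dynamic image
#'
#' For every frame, subtracts the mean activity over the brain mask and
#' divides by the frame standard deviation, so that each frame has brain
#' mean 0 and SD 1. Voxels outside the brain are set to NA.
#'
#' @param img a [DynamicImage-class].
#' @param brainMask 3D logical array.
#' @return 4D numeric array of normalized (unitless) values.
#' @export
normalizeFrames <- function(img, brainMask) {
  stopifnot(is(img, "DynamicImage"), any(brainMask))
  nf <- nFrames(img@scheme)
  out <- array(NA_real_, dim(img@data))
  idx <- which(brainMask)
  nvox <- prod(dim(img@data)[1:3])
  for (f in seq_len(nf)) {
    v <- img@data[idx + (f - 1L) * nvox]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("frame %d has zero variance over the brain mask", f))
    out[idx + (f - 1L) * nvox] <- (v - mean(v)) / s
  }
  out
}

#' Select the blood-pool voxels from early frames
#'
#' Ranks brain voxels by their duration-weighted activity over the frames
#' wholly contained in the first \code{windowS} seconds of the acquisition
#' and returns the top \code{n} (big-vessel voxels peak early). Ties at rank
#' \code{n} are broken by lexicographic voxel index so the selection is
#' deterministic.
#'
#' @param img a [DynamicImage-class] (raw, non-normalized activity).
#' @param brainMask 3D logical array with at least \code{n} voxels.
#' @param n number of voxels to select (default 30).
#' @param windowS early window in seconds (default 60; frames are included
#'   when \code{start + duration <= windowS}).
#' @return 3D logical array with exactly \code{n} TRUE voxels.
#' @export
selectBloodVoxels <- function(img, brainMask, n = 30L, windowS = 60) {
  stopifnot(is(img, "DynamicImage"))
  idx <- which(brainMask)
  if (length(idx) < n)
    stop(sprintf("brain mask has %d voxels; %d required", length(idx), n))
  sch <- img@scheme
  fr <- which(frameStart(sch) + frameDuration(sch) <= windowS + 1e-9)
  if (!length(fr)) stop("no frame lies wholly within the early window")
  nvox <- prod(dim(img@data)[1:3])
  score <- numeric(length(idx))
  for (f in fr)
    score <- score + frameDuration(sch)[f] * img@data[idx + (f - 1L) * nvox]
  sel <- idx[order(score, decreasing = TRUE)[seq_len(n)]]  # stable: ties by index
  out <- array(FALSE, dim(img@data)[1:3])
  out[sel] <- TRUE
  out
}

# mean normalized TAC over a voxel index set
.meanTac <- function(z, idx) {
  nvox <- prod(dim(z)[1:3])
  vapply(seq_len(dim(z)[4L]),
         function(f) mean(z[idx + (f - 1L) * nvox]), numeric(1L))
}

#' Build the three SVCA kinetic classes from control scans
#'
#' Class 1 (grey matter) and class 3 (white matter) are grand means of the
#' frame-normalized TACs over the respective masks across all control scans.
#' Class 2 (blood pool) is, per control, the mean normalized TAC of the 30
#' voxels with the highest raw activity over the first 60 s, averaged across
#' controls.
#'
#' @param imgs list of control [DynamicImage-class] scans on one scheme.
#' @param gmMasks,wmMasks,brainMasks lists of 3D logical arrays (one per
#'   control; a single array is recycled).
#' @param nBlood voxels per control in the blood class (default 30).
#' @param windowS early window for blood selection (default 60 s).
#' @return A [KineticClassSet-class].
#' @export
buildKineticClasses <- function(imgs, gmMasks, wmMasks, brainMasks,
                                nBlood = 30L, windowS = 60) {
  if (is(imgs, "DynamicImage")) imgs <- list(imgs)
  asList <- function(m) if (is.list(m)) m else rep(list(m), length(imgs))
  gmMasks <- asList(gmMasks); wmMasks <- asList(wmMasks)
  brainMasks <- asList(brainMasks)
  stopifnot(length(imgs) >= 1L, length(gmMasks) == length(imgs),
            length(wmMasks) == length(imgs), length(brainMasks) == length(imgs))
  nf <- nFrames(imgs[[1L]]@scheme)
  acc <- matrix(0, nf, 3L, dimnames = list(NULL, c("gm", "blood", "wm")))
  for (i in seq_along(imgs)) {
    img <- imgs[[i]]
    if (nFrames(img@scheme) != nf) stop("control scans use different schemes")
    blood <- selectBloodVoxels(img, brainMasks[[i]], nBlood, windowS)
    z <- normalizeFrames(img, brainMasks[[i]])
    acc[, "gm"] <- acc[, "gm"] + .meanTac(z, which(gmMasks[[i]] & brainMasks[[i]]))
    acc[, "wm"] <- acc[, "wm"] + .meanTac(z, which(wmMasks[[i]] & brainMasks[[i]]))
    acc[, "blood"] <- acc[, "blood"] + .meanTac(z, which(blood))
  }
  new("KineticClassSet", classes = acc / length(imgs),
      nControls = length(imgs))
}

# Exact non-negative least squares for a 3-column design, vectorised over
# voxels: enumerate the 7 non-empty supports (plus the zero solution), solve
# the restricted OLS for each, and keep the feasible solution with minimal
# residual sum of squares. For p = 3 this is the exact NNLS optimum.
.nnls3 <- function(X, Z) {
  p <- ncol(X); V <- ncol(Z)
  best <- matrix(0, p, V)
  bestRss <- colSums(Z^2)                      # zero solution
  supports <- lapply(1:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
  for (S in supports) {
    XS <- X[, S, drop = FALSE]
    XtX <- crossprod(XS)
    if (rcond(XtX) < 1e-12) next   # degenerate support (collinear classes)
    W <- solve(XtX, crossprod(XS, Z))                    # |S| x V
    feas <- colSums(W < -1e-10) == 0L
    if (!any(feas)) next
    R <- Z - XS %*% W
    rss <- colSums(R^2)
    upd <- feas & rss < bestRss - 1e-12
    if (any(upd)) {
      bestRss[upd] <- rss[upd]
      best[, upd] <- 0
      best[S, upd] <- pmax(W[, upd, drop = FALSE], 0)
    }
  }
  best
}

#' Extract the SVCA reference region
#'
#' Normalizes the scan, then models every voxel TAC in the search mask as a
#' non-negative linear combination of the three kinetic classes. The class-1
#' weight ratio \code{w1 / (w1 + w2 + w3)} (defined as 0 when all weights
#' vanish) selects reference voxels: those with ratio above
#' \code{threshold}. The reference TAC is the mean of the raw
#' (non-normalized) TACs over the selected voxels.
#'
#' @param img a [DynamicImage-class].
#' @param classes a [KineticClassSet-class] on the same scheme.
#' @param searchMask 3D logical array, voxels to classify (typically the
#'   grey-matter mask).
#' @param brainMask 3D logical array used for frame normalization.
#' @param threshold class-1 weight-ratio cut (default 0.9).
#' @param solver \code{"nnls"} (default; weights constrained non-negative so
#'   the ratio lies in [0, 1]) or \code{"ols"} for comparison.
#' @return A [ReferenceRegion-class].
#' @export
extractReference <- function(img, classes, searchMask, brainMask,
                             threshold = 0.9, solver = c("nnls", "ols")) {
  solver <- match.arg(solver)
  stopifnot(is(img, "DynamicImage"), is(classes, "KineticClassSet"))
  if (nrow(classes@classes) != nFrames(img@scheme))
    stop("class curves are not defined on the image's frame scheme")
  searchMask <- searchMask & brainMask
  if (!any(searchMask)) stop("empty search mask")
  z <- normalizeFrames(img, brainMask)
  idx <- which(searchMask)
  nvox <- prod(dim(img@data)[1:3])
  nf <- nFrames(img@scheme)
  Z <- matrix(0, nf, length(idx))
  for (f in seq_len(nf)) Z[f, ] <- z[idx + (f - 1L) * nvox]
  X <- classes@classes
  W <- if (solver == "nnls") .nnls3(X, Z) else solve(crossprod(X), crossprod(X, Z))
  tot <- colSums(W)
  ratio <- ifelse(abs(tot) < 1e-12, 0, W[1L, ] / tot)
  weightMap <- array(NA_real_, dim(img@data)[1:3])
  weightMap[idx] <- ratio
  sel <- idx[ratio > threshold]
  if (!length(sel))
    stop(sprintf("no voxel exceeds the class-1 weight-ratio threshold %g: empty reference region", threshold))
  mask <- array(FALSE, dim(img@data)[1:3])
  mask[sel] <- TRUE
  refTac <- vapply(seq_len(nf),
                   function(f) mean(img@data[sel + (f - 1L) * nvox]),
                   numeric(1L))
  new("ReferenceRegion", mask = mask, refTac = refTac,
      weightMap = weightMap, threshold = threshold)
}
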