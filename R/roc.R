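# Discrimination analysis: ROC/AUC with the DeLong correlated-curve
# comparison, and tidy per-ROI export for downstream modelling.

# placement values: psi-mean of each positive against all negatives (and
# vice versa), with half credit for ties; the grand mean is the AUC
.placements <- function(pos, neg) {
  allv <- c(pos, neg)
  r <- rank(allv, ties.method = "average")
  m <- length(pos); n <- length(neg)
  rPos <- r[seq_len(m)]
  rNeg <- r[m + seq_len(n)]
  rPosWithin <- rank(pos, ties.method = "average")
  rNegWithin <- rank(neg, ties.method = "average")
  v10 <- (rPos - rPosWithin) / n          # per-positive P(pos > neg) + ties/2
  v01 <- 1 - (rNeg - rNegWithin) / m      # per-negative, same orientation
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve and AUC for a voxelwise score
#'
#' Computes the empirical ROC curve over all thresholds and its area by the
#' trapezoidal rule, which (with half-credit for ties) equals the
#' Mann-Whitney concordance probability: the chance that a random positive
#' (lesion) voxel scores on the lesion side of a random negative (NAWM)
#' voxel. Demyelination lowers uptake, so lower scores typically indicate
#' lesion; set \code{direction = "low"} (the default \code{"auto"} picks the
#' orientation with AUC >= 0.5 and records it).
#'
#' @param scores numeric per-sample values (e.g. voxel DVR or SUV).
#' @param labels logical (or 0/1): TRUE = positive class (lesion).
#' @param direction \code{"high"} if larger scores indicate lesion,
#'   \code{"low"} if smaller do, or \code{"auto"}.
#' @return A [RocResult-class].
#' @export
rocAuc <- function(scores, labels, direction = c("auto", "high", "low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both classes must be present for a ROC analysis")
  if (direction == "auto") {
    a <- .placements(scores[labels], scores[!labels])$auc
    direction <- if (a >= 0.5) "high" else "low"
  }
  s <- if (direction == "low") -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  m <- length(pos); n <- length(neg)

  # empirical curve: sweep thresholds over the sorted unique scores
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(pos >= t), numeric(1L)) / m)
  fpr <- c(0, vapply(thr, function(t) sum(neg >= t), numeric(1L)) / n)
  aucTrap <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)

  pl <- .placements(pos, neg)
  vr <- if (m > 1L) stats::var(pl$v10) / m else 0
  vc <- if (n > 1L) stats::var(pl$v01) / n else 0
  new("RocResult", auc = aucTrap, nPos = m, nNeg = n,
      variance = vr + vc,
      curve = data.frame(fpr = fpr, tpr = tpr), direction = direction)
}

#' DeLong test comparing two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same samples (e.g. DVR
#' and SUV on the same voxels) with the DeLong placement-value method for
#' paired ROC curves: the variance of the AUC difference accounts for the
#' covariance induced by the shared samples. Returns the difference, its
#' z-statistic and the two-sided p-value.
#'
#' @param scores1,scores2 paired numeric scores (same samples, same order).
#' @param labels logical: TRUE = positive class.
#' @param direction score orientation, as in [rocAuc()]; applied to both
#'   scores (\code{"auto"} orients each by its own AUC).
#' @return List with \code{auc1}, \code{auc2}, \code{delta}, \code{z},
#'   \code{p}.
#' @export
compareAuc <- function(scores1, scores2, labels,
                       direction = c("auto", "high", "low")) {
  direction <- match.arg(direction)
  if (length(scores1) != length(scores2))
    stop("scores must be paired: equal lengths required")
  labels <- as.logical(labels)
  keep <- is.finite(scores1) & is.finite(scores2) & !is.na(labels)
  scores1 <- scores1[keep]; scores2 <- scores2[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) stop("both classes must be present")

  orient <- function(s) {
    if (direction == "high") return(s)
    if (direction == "low") return(-s)
    a <- .placements(s[labels], s[!labels])$auc
    if (a >= 0.5) s else -s
  }
  s1 <- orient(scores1); s2 <- orient(scores2)
  p1 <- .placements(s1[labels], s1[!labels])
  p2 <- .placements(s2[labels], s2[!labels])
  m <- sum(labels); n <- sum(!labels)

  S10 <- stats::cov(cbind(p1$v10, p2$v10))
  S01 <- stats::cov(cbind(p1$v01, p2$v01))
  varDiff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  delta <- p1$auc - p2$auc
  if (varDiff <= 0) {
    z <- if (abs(delta) < 1e-12) 0 else Inf * sign(delta)
  } else z <- delta / sqrt(varDiff)
  list(auc1 = p1$auc, auc2 = p2$auc, delta = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Tidy per-ROI summary table
#'
#' One row per parametric map x ROI with mean, SD, voxel count and volume -
#' the export format consumed by downstream (mixed-effect) modelling outside
#' this package. Empty ROIs are omitted with a warning.
#'
#' @param maps named list of [ParametricMap-class] objects.
#' @param rois named list of 3D logical ROI masks, or a [LayerSet-class].
#' @param subject subject identifier recorded in every row.
#' @param voxelSize voxel edge lengths in mm (length 1 or 3) for volumes.
#' @return data.frame with columns subject, roi, quantity, mean, sd,
#'   n_voxels, volume_mm3.
#' @export
exportRoiTable <- function(maps, rois, subject = "subject01", voxelSize = 1) {
  if (is(rois, "LayerSet")) {
    voxelSize <- rois@voxelSize
    rois <- rois@maskList
  }
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  stopifnot(length(maps) >= 1L, !is.null(names(maps)), !is.null(names(rois)))
  rows <- list()
  for (q in names(maps)) for (r in names(rois)) {
    mask <- rois[[r]]
    vals <- maps[[q]]@values[mask]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) {
      warning(sprintf("ROI '%s' empty for map '%s'; row omitted", r, q))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, roi = r, quantity = q,
      mean = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0,
      n_voxels = length(vals),
      volume_mm3 = length(vals) * prod(voxelSize))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
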